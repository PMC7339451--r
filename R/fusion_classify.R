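# Fusion classification by breakpoint annotation, junction orientation
# (transcription concordance), and enumeration of UIB/DIB target
# candidates around intergenic breakends.

# direction of travel when walking from the junction INTO the retained
# segment at a breakend (LEFT-retained segments extend to lower coords)
.walk_dir <- function(side) ifelse(side == "LEFT", "-", "+")
# direction of travel when leaving a retained segment THROUGH the junction
.exit_dir <- function(side) ifelse(side == "LEFT", "+", "-")

.calls_of <- function(x) {
  if (inherits(x, "cohort_data")) return(x$calls)
  if (inherits(x, "call_set")) return(x$calls)
  if (is.list(x) && !is.data.frame(x) &&
      all(vapply(x, inherits, TRUE, "call_set")))
    return(data.table::rbindlist(lapply(x, `[[`, "calls")))
  data.table::as.data.table(x)
}

# long (one row per breakend) view of a calls table, with genic status
.breakends_long <- function(calls, ann) {
  b <- rbind(
    calls[, .(sample_id, call_id, bnd = 1L, chrom = chrom1, pos = pos1,
              side = side1, sv_type,
              partner_chrom = chrom2, partner_pos = pos2, partner_side = side2)],
    calls[, .(sample_id, call_id, bnd = 2L, chrom = chrom2, pos = pos2,
              side = side2, sv_type,
              partner_chrom = chrom1, partner_pos = pos1, partner_side = side1)])
  bad <- setdiff(unique(b$chrom), names(ann$chrom_sizes))
  if (length(bad))
    stop("call chromosomes not in annotation: ", paste(bad, collapse = ","),
         "; annotation has: ",
         paste(sort(names(ann$chrom_sizes)), collapse = ","))
  lev <- sort(names(ann$chrom_sizes))
  gr <- GenomicRanges::GRanges(factor(b$chrom, levels = lev),
                               IRanges::IRanges(b$pos, b$pos))
  ov <- GenomicRanges::findOverlaps(gr, ann$gr, ignore.strand = TRUE)
  b[, is_genic := FALSE]
  b$is_genic[unique(S4Vectors::queryHits(ov))] <- TRUE
  b
}

#' Classify one fusion call by its breakend annotations
#'
#' `GENE_GENE` when both breakends fall inside gene bodies,
#' `GENE_INTERGENIC` when exactly one does, `INTERGENIC_INTERGENIC`
#' otherwise.
#'
#' @param call a single SV call: a list or one-row data.frame with
#'   `chrom1`, `pos1`, `chrom2`, `pos2`.
#' @param ann a [genome_annotation()].
#' @return One of `"GENE_GENE"`, `"GENE_INTERGENIC"`,
#'   `"INTERGENIC_INTERGENIC"`.
#' @export
classify_fusion <- function(call, ann) {
  g1 <- annotate_position(ann, call$chrom1, call$pos1)$status == "GENIC"
  g2 <- annotate_position(ann, call$chrom2, call$pos2)$status == "GENIC"
  if (g1 && g2) "GENE_GENE"
  else if (g1 || g2) "GENE_INTERGENIC"
  else "INTERGENIC_INTERGENIC"
}

#' Classify every call in a set
#'
#' Vectorized version of [classify_fusion()].
#'
#' @param x a [call_set()], list of call sets, or calls data.table.
#' @param ann a [genome_annotation()].
#' @return The calls data.table with `status1`, `status2` and
#'   `fusion_class` columns appended.
#' @export
classify_calls <- function(x, ann) {
  calls <- data.table::copy(.calls_of(x))
  if (!nrow(calls)) {
    calls[, `:=`(status1 = character(), status2 = character(),
                 fusion_class = character())]
    return(calls[])
  }
  b <- .breakends_long(calls, ann)
  st <- data.table::dcast(b, sample_id + call_id ~ bnd, value.var = "is_genic")
  data.table::setnames(st, c("1", "2"), c("g1", "g2"))
  calls <- merge(calls, st, by = c("sample_id", "call_id"), sort = FALSE)
  calls[, status1 := ifelse(g1, "GENIC", "INTERGENIC")]
  calls[, status2 := ifelse(g2, "GENIC", "INTERGENIC")]
  calls[, fusion_class := data.table::fcase(
    g1 & g2, "GENE_GENE",
    xor(g1, g2), "GENE_INTERGENIC",
    default = "INTERGENIC_INTERGENIC")]
  calls[, c("g1", "g2") := NULL]
  calls[]
}

#' Is a fusion junction transcription-concordant for a target gene?
#'
#' Walking the derived junction from the retained segment at the partner
#' breakend into the retained segment at the target-side breakend, the
#' walk must run in the target gene's transcriptional direction, so that
#' transcription initiated on the partner side reads into the target.
#' When `five_gene` is supplied, the walk must additionally leave that
#' gene in its own sense direction (sense-to-sense junction).
#'
#' @param call a single SV call (list or one-row data.frame with `chrom1`,
#'   `pos1`, `side1`, `chrom2`, `pos2`, `side2`).
#' @param ann a [genome_annotation()].
#' @param target gene id of the putative 3' target; must be adjacent to
#'   (inside or within 10 Mb of) one breakend.
#' @param five_gene optional gene id of the putative 5' partner at the
#'   other breakend.
#' @return Logical scalar.
#' @export
is_transcription_concordant <- function(call, ann, target, five_gene = NULL) {
  tg <- ann$genes[gene_id == target]
  if (!nrow(tg)) stop("unknown target gene: ", target)
  near <- function(chrom, pos)
    chrom == tg$chrom & abs(pos - pmax(pmin(pos, tg$end), tg$start)) <= 1e7
  n1 <- near(call$chrom1, call$pos1)
  n2 <- near(call$chrom2, call$pos2)
  if (!n1 && !n2)
    stop("target gene ", target, " is not adjacent to either breakend")
  t_bnd <- if (n1 && n2) {
    d1 <- min(abs(call$pos1 - tg$start), abs(call$pos1 - tg$end))
    d2 <- min(abs(call$pos2 - tg$start), abs(call$pos2 - tg$end))
    if (d1 <= d2) 1L else 2L
  } else if (n1) 1L else 2L
  t_side <- if (t_bnd == 1L) call$side1 else call$side2
  p_side <- if (t_bnd == 1L) call$side2 else call$side1
  ok <- .walk_dir(t_side) == tg$strand
  if (!is.null(five_gene)) {
    fg <- ann$genes[gene_id == five_gene]
    if (!nrow(fg)) stop("unknown five_gene: ", five_gene)
    ok <- ok && .exit_dir(p_side) == fg$strand
  }
  ok
}

# does the retained segment at an intergenic breakend face (contain) the
# gene body? This is the orientation requirement for a UIB/DIB breakend to
# keep the target joined to the partner-side material.
.faces_gene <- function(pos, side, g_start, g_end) {
  (pos < g_start & side == "RIGHT") | (pos > g_end & side == "LEFT")
}

# vectorized cytoband names (NA outside the tiled range or without bands)
.cytoband_lookup <- function(bands, chrom, pos) {
  out <- rep(NA_character_, length(chrom))
  if (is.null(bands)) return(out)
  b <- bands$bands
  for (ch in unique(chrom)) {
    bb <- b[which(b$chrom == ch)]
    if (!nrow(bb)) next
    idx <- which(chrom == ch)
    j <- findInterval(pos[idx] - 1L, bb$start)
    ok <- j >= 1L & (pos[idx] - 1L) < bb$end[pmax(j, 1L)]
    out[idx[ok]] <- bb$band[j[ok]]
  }
  out
}

#' Enumerate UIB/DIB target candidates for one call
#'
#' For each intergenic breakend of the call, emits one candidate per gene
#' for which the breakend lies upstream (mode `UIB`) or downstream
#' (`DIB`) within `window` bp, with the strand-aware distance, a
#' concordance flag (retained segment faces the gene), and a summary of
#' the other breakend.
#'
#' @param call a single SV call (list or one-row data.frame).
#' @param ann a [genome_annotation()].
#' @param bands optional `cytoband_map` for intergenic partner labels.
#' @param window search window in bp (default 4 Mb).
#' @return data.table, one row per candidate, sorted by distance.
#' @export
enumerate_target_candidates <- function(call, ann, bands = NULL,
                                        window = 4e6) {
  stopifnot(window > 0)
  calls <- data.table::as.data.table(call)
  if (!"sample_id" %in% names(calls)) calls[, sample_id := NA_character_]
  if (!"call_id" %in% names(calls)) calls[, call_id := "call1"]
  if (!"sv_type" %in% names(calls)) calls[, sv_type := "OTHER"]
  out <- candidate_table(calls, ann, bands = bands, window = window)
  data.table::setorder(out, distance, target_gene)
  out[]
}

#' Candidate table for a whole cohort of calls
#'
#' Vectorized candidate enumeration over every intergenic breakend of
#' every call: the work-horse behind the recurrence screen.
#'
#' @param x a [call_set()], list of call sets, or calls data.table.
#' @param ann a [genome_annotation()].
#' @param bands optional `cytoband_map`.
#' @param window search window in bp.
#' @return data.table with one row per (breakend, candidate gene):
#'   `sample_id`, `call_id`, `target_gene`, `mode` (UIB/DIB), `distance`,
#'   `concordant`, breakend and partner coordinates, `partner_genic`,
#'   `partner_desc`, `partner_cytoband`.
#' @export
candidate_table <- function(x, ann, bands = NULL, window = 4e6) {
  calls <- .calls_of(x)
  empty <- data.table::data.table(
    sample_id = character(), call_id = character(), target_gene = character(),
    mode = character(), distance = numeric(), concordant = logical(),
    bnd_chrom = character(), bnd_pos = integer(), bnd_side = character(),
    sv_type = character(), partner_chrom = character(),
    partner_pos = integer(), partner_side = character(),
    partner_genic = logical(), partner_desc = character(),
    partner_cytoband = character())
  if (!nrow(calls)) return(empty)
  b <- .breakends_long(calls, ann)
  b <- b[is_genic == FALSE]
  if (!nrow(b)) return(empty)

  g <- ann$genes
  # strand-aware upstream / downstream flanking windows per gene
  up_start <- ifelse(g$strand == "+", pmax(1, g$start - window), g$end + 1)
  up_end <- ifelse(g$strand == "+", g$start - 1, g$end + window)
  dn_start <- ifelse(g$strand == "+", g$end + 1, pmax(1, g$start - window))
  dn_end <- ifelse(g$strand == "+", g$end + window, g$start - 1)
  win <- data.table::data.table(
    gene_id = rep(g$gene_id, 2L),
    chrom = rep(g$chrom, 2L),
    w_start = c(up_start, dn_start), w_end = c(up_end, dn_end),
    mode = rep(c("UIB", "DIB"), each = nrow(g)))
  win <- win[w_start <= w_end]
  lev <- sort(names(ann$chrom_sizes))
  wgr <- GenomicRanges::GRanges(factor(win$chrom, levels = lev),
                                IRanges::IRanges(win$w_start, win$w_end))
  bgr <- GenomicRanges::GRanges(factor(b$chrom, levels = lev),
                                IRanges::IRanges(b$pos, b$pos))
  ov <- GenomicRanges::findOverlaps(bgr, wgr, ignore.strand = TRUE)
  if (!length(ov)) return(empty)

  hit <- cbind(b[S4Vectors::queryHits(ov)],
               win[S4Vectors::subjectHits(ov),
                   .(target_gene = gene_id, mode)])
  hit <- merge(hit,
               g[, .(target_gene = gene_id, g_start = start, g_end = end,
                     g_strand = strand)],
               by = "target_gene")
  # distance to the transcription start (UIB) or end (DIB), strand-aware
  hit[, distance := data.table::fifelse(
    mode == "UIB",
    data.table::fifelse(g_strand == "+", g_start - pos, pos - g_end),
    data.table::fifelse(g_strand == "+", pos - g_end, g_start - pos))]
  hit[, concordant := .faces_gene(pos, side, g_start, g_end)]

  # partner summaries (computed once per unique partner breakend)
  pk <- unique(hit[, .(partner_chrom, partner_pos)])
  pk[, partner_genic := FALSE]
  pgr <- GenomicRanges::GRanges(
    factor(pk$partner_chrom, levels = sort(names(ann$chrom_sizes))),
    IRanges::IRanges(pk$partner_pos, pk$partner_pos))
  pov <- GenomicRanges::findOverlaps(pgr, ann$gr, ignore.strand = TRUE)
  first_hit <- tapply(S4Vectors::subjectHits(pov),
                      S4Vectors::queryHits(pov), min)
  genic_q <- as.integer(names(first_hit))
  pk$partner_genic[genic_q] <- TRUE
  cb <- .cytoband_lookup(bands, pk$partner_chrom, pk$partner_pos)
  pk[, partner_cytoband := ifelse(is.na(cb), NA_character_,
                                  paste0(partner_chrom, cb))]
  pk[, partner_desc := ifelse(
    is.na(cb), sprintf("INTERGENIC(%s:%d)", partner_chrom, partner_pos),
    sprintf("INTERGENIC(%s%s)", partner_chrom, cb))]
  if (length(genic_q)) {
    gids <- names(ann$gr)[first_hit]
    pk$partner_desc[genic_q] <- vapply(seq_along(genic_q), function(k) {
      el <- .exon_intron_index(ann, gids[k], pk$partner_pos[genic_q[k]])
      sprintf("GENIC(%s,%s %d)", gids[k], el$element, el$index)
    }, "")
  }
  hit <- merge(hit, pk, by = c("partner_chrom", "partner_pos"))
  out <- hit[, .(sample_id, call_id, target_gene, mode, distance,
                 concordant, bnd_chrom = chrom, bnd_pos = pos,
                 bnd_side = side, sv_type, partner_chrom, partner_pos,
                 partner_side, partner_genic, partner_desc,
                 partner_cytoband)]
  data.table::setorder(out, sample_id, call_id, mode, distance)
  out[]
}

#' Class counts, fractions and the uniform-breakpoint null
#'
#' Tabulates the three fusion classes and compares the observed gene-gene
#' count with the expectation under a null in which breakpoints fall
#' uniformly over the genome: with genic fraction `f` (union of gene
#' bodies over genome length), the expected gene-gene count is `N * f^2`.
#' A one-proportion test (exact binomial, plus normal approximation) is
#' reported via [proportion_test()].
#'
#' @param x a [call_set()], list of call sets, or calls data.table.
#' @param ann a [genome_annotation()].
#' @return list with `counts`, `fractions`, `n`, `genic_fraction`,
#'   `expected_gene_gene`, `p_value` (exact) and `p_value_normal`.
#' @export
class_proportions <- function(x, ann) {
  calls <- classify_calls(x, ann)
  if (!nrow(calls)) stop("empty call set")
  lev <- c("GENE_GENE", "GENE_INTERGENIC", "INTERGENIC_INTERGENIC")
  counts <- table(factor(calls$fusion_class, levels = lev))
  n <- nrow(calls)
  genic_bp <- sum(IRanges::width(GenomicRanges::reduce(ann$gr,
                                                       ignore.strand = TRUE)))
  f <- genic_bp / sum(ann$chrom_sizes)
  obs_gg <- as.integer(counts[["GENE_GENE"]])
  degenerate <- f^2 <= 0 || f^2 >= 1   # null is deterministic, no test
  list(counts = counts,
       fractions = counts / n,
       n = n,
       genic_fraction = f,
       expected_gene_gene = n * f^2,
       p_value = if (degenerate) NA_real_ else
         proportion_test(obs_gg, n, f^2, method = "exact"),
       p_value_normal = if (degenerate) NA_real_ else
         proportion_test(obs_gg, n, f^2, method = "normal"))
}
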