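# Chimeric-mRNA prediction under the first-exon-skipping splicing model.
#
# A gene-intergenic fusion with (i) an intronic breakpoint in the 5' gene
# (A) and (ii) the other breakpoint in the intergenic region upstream of a
# 3' gene (B), juxtaposed sense-to-sense, is spliced so that the whole
# segment between A's last retained exon and B's exon 2 behaves as one
# intron: B's exon 1 is skipped because it lacks a splice-acceptor signal.
# A conventional gene-gene fusion (both breakpoints intronic) splices A's
# last retained exon to B's first exon after the breakpoint.

# coding bp of one exon (overlap of exon with the CDS interval)
.exon_coding_bp <- function(ex_start, ex_end, cds_start, cds_end) {
  if (is.na(cds_start)) return(0)
  pmax(0, pmin(ex_end, cds_end) - pmax(ex_start, cds_start) + 1)
}

# total coding bp over a set of transcription-order exon indices
.coding_len <- function(ann, gid, idx) {
  g <- ann$genes[gene_id == gid]
  ex <- ann$exons[.(gid)][exon_index %in% idx]
  if (!nrow(ex)) return(0)
  sum(vapply(seq_len(nrow(ex)), function(i)
    .exon_coding_bp(ex$start[i], ex$end[i], g$cds_start, g$cds_end), 0))
}

# 3' genomic boundary of an exon in its gene's orientation
.exon_3p <- function(ann, gid, idx) {
  g <- ann$genes[gene_id == gid]
  ex <- ann$exons[.(gid)][exon_index == idx]
  if (g$strand == "+") ex$end else ex$start
}
# 5' genomic boundary
.exon_5p <- function(ann, gid, idx) {
  g <- ann$genes[gene_id == gid]
  ex <- ann$exons[.(gid)][exon_index == idx]
  if (g$strand == "+") ex$start else ex$end
}

.new_chimera <- function(sample_id, call_id, five_gene, five_last_exon,
                         three_gene, three_first_exon, donor_chrom,
                         donor_pos, acceptor_chrom, acceptor_pos,
                         uib_distance, mode) {
  structure(list(sample_id = sample_id, call_id = call_id,
                 five_gene = five_gene, five_last_exon = five_last_exon,
                 three_gene = three_gene, three_first_exon = three_first_exon,
                 donor_chrom = donor_chrom, donor_pos = donor_pos,
                 acceptor_chrom = acceptor_chrom, acceptor_pos = acceptor_pos,
                 uib_distance = uib_distance, mode = mode),
            class = "chimera_prediction")
}

#' @export
print.chimera_prediction <- function(x, ...) {
  cat(sprintf("chimera_prediction [%s]: %s exon %d -> %s exon %d (%s:%d -> %s:%d)%s\n",
              x$mode, x$five_gene, x$five_last_exon, x$three_gene,
              x$three_first_exon, x$donor_chrom, x$donor_pos,
              x$acceptor_chrom, x$acceptor_pos,
              if (x$uib_distance > 0)
                sprintf(", UIB distance %d bp", as.integer(x$uib_distance))
              else ""))
  invisible(x)
}

# breakend annotation shortcuts for one call
.bnd_view <- function(call, ann) {
  lapply(1:2, function(i) {
    chrom <- call[[paste0("chrom", i)]]
    pos <- call[[paste0("pos", i)]]
    side <- call[[paste0("side", i)]]
    a <- annotate_position(ann, chrom, pos)
    list(chrom = chrom, pos = pos, side = side, ann = a)
  })
}

# intronic hit of a breakend in a specific orientation role
.intronic_gene <- function(bv) {
  h <- bv$ann$hit_genes[element == "INTRON"]
  if (nrow(h)) h else NULL
}

#' Predict the chimeric mRNA of a fusion call
#'
#' Applies the splicing model to a classified call. In UIB mode (one
#' breakend intronic in gene A, the other intergenic upstream of a gene B
#' within `chimera_window`, sense-to-sense), the junction joins the 3'
#' boundary of A's last exon before the breakpoint to the 5' boundary of
#' B's exon 2, skipping B's exon 1. In gene-gene mode (both breakends
#' intronic, sense-to-sense), the acceptor is the 5' boundary of B's first
#' exon after the breakpoint. Returns `NULL` when no sense-to-sense
#' assignment exists or when the 5'-gene breakpoint is exonic (the model
#' is defined for intronic 5' breakpoints only).
#'
#' @param call a single SV call (list or one-row data.frame with
#'   `chrom1`, `pos1`, `side1`, `chrom2`, `pos2`, `side2`; `sample_id` and
#'   `call_id` are carried through when present).
#' @param ann a [genome_annotation()].
#' @param chimera_window maximum UIB distance (bp) at which a chimera is
#'   predicted; default 100 kb, the scale below which nearly all introns
#'   fall.
#' @return A `chimera_prediction` or `NULL`.
#' @export
predict_chimera <- function(call, ann, chimera_window = 1e5) {
  call <- as.list(call)
  sample_id <- if (!is.null(call$sample_id)) call$sample_id else NA_character_
  call_id <- if (!is.null(call$call_id)) call$call_id else NA_character_
  bv <- .bnd_view(call, ann)
  genic <- vapply(bv, function(b) b$ann$status == "GENIC", TRUE)

  try_gene_gene <- function(ai, bi) {
    A <- bv[[ai]]; B <- bv[[bi]]
    ha <- .intronic_gene(A); hb <- .intronic_gene(B)
    if (is.null(ha) || is.null(hb)) return(NULL)
    for (ia in seq_len(nrow(ha))) for (ib in seq_len(nrow(hb))) {
      ga <- ha$gene_id[ia]; gb <- hb$gene_id[ib]
      if (ga == gb) next
      sa <- ann$genes[gene_id == ga, strand]
      sb <- ann$genes[gene_id == gb, strand]
      if (.exit_dir(A$side) != sa || .walk_dir(B$side) != sb) next
      k <- ha$index[ia]                    # A intron k -> retain exons 1..k
      j <- hb$index[ib] + 1L               # B intron -> first exon after it
      if (k < 1L || j > max(ann$exons[.(gb)]$exon_index)) next
      return(.new_chimera(sample_id, call_id, ga, k, gb, j,
                          A$chrom, .exon_3p(ann, ga, k),
                          B$chrom, .exon_5p(ann, gb, j),
                          0, "GENE_GENE"))
    }
    NULL
  }

  try_uib <- function(ai, bi) {
    A <- bv[[ai]]; B <- bv[[bi]]
    ha <- .intronic_gene(A)
    if (is.null(ha)) return(NULL)
    up <- genes_within_window(ann, B$chrom, B$pos, chimera_window, "UPSTREAM")
    if (!nrow(up)) return(NULL)
    for (ia in seq_len(nrow(ha))) {
      ga <- ha$gene_id[ia]
      sa <- ann$genes[gene_id == ga, strand]
      if (.exit_dir(A$side) != sa) next
      for (ib in seq_len(nrow(up))) {
        gb <- up$gene_id[ib]
        sb <- ann$genes[gene_id == gb, strand]
        if (.walk_dir(B$side) != sb) next
        if (max(ann$exons[.(gb)]$exon_index) < 2L) next
        k <- ha$index[ia]
        return(.new_chimera(sample_id, call_id, ga, k, gb, 2L,
                            A$chrom, .exon_3p(ann, ga, k),
                            B$chrom, .exon_5p(ann, gb, 2L),
                            up$distance[ib], "UIB"))
      }
    }
    NULL
  }

  if (genic[1L] && genic[2L])
    return(try_gene_gene(1L, 2L) %||% try_gene_gene(2L, 1L))
  if (genic[1L] && !genic[2L]) return(try_uib(1L, 2L))
  if (genic[2L] && !genic[1L]) return(try_uib(2L, 1L))
  NULL
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Frame and UTR status of a chimera prediction
#'
#' Classifies the predicted transcript:
#' * `NON_CODING` - either gene lacks a CDS;
#' * `FIVE_UTR_ONLY` - the retained 5'-gene exons carry no coding
#'   sequence, so the product is the intact 3'-gene protein driven by the
#'   5' partner's promoter;
#' * `THREE_EXON1_UTR_ORF_INTACT` - the skipped 3'-gene exon(s) carry no
#'   coding sequence (exon 1 entirely 5' UTR), so the 3'-gene ORF is
#'   intact from the joined exon onward;
#' * `IN_FRAME` / `OUT_OF_FRAME` - both sides contribute coding sequence;
#'   in-frame when the retained 5' coding length and the skipped 3' coding
#'   prefix are congruent modulo 3.
#'
#' @param pred a `chimera_prediction` from [predict_chimera()].
#' @param ann a [genome_annotation()].
#' @return One of the five status strings.
#' @export
frame_status <- function(pred, ann) {
  stopifnot(inherits(pred, "chimera_prediction"))
  ga <- ann$genes[gene_id == pred$five_gene]
  gb <- ann$genes[gene_id == pred$three_gene]
  if (!nrow(ga) || !nrow(gb))
    stop("prediction genes not present in the annotation")
  if (is.na(ga$cds_start) || is.na(gb$cds_start)) return("NON_CODING")
  a_coding <- .coding_len(ann, pred$five_gene,
                          seq_len(pred$five_last_exon))
  b_skipped <- .coding_len(ann, pred$three_gene,
                           seq_len(pred$three_first_exon - 1L))
  if (a_coding == 0) return("FIVE_UTR_ONLY")
  if (b_skipped == 0) return("THREE_EXON1_UTR_ORF_INTACT")
  if (a_coding %% 3 == b_skipped %% 3) "IN_FRAME" else "OUT_OF_FRAME"
}

#' Read RNA junction evidence from a TSV file
#'
#' Expects columns `sample_id`, `chrom_donor`, `donor_pos`,
#' `chrom_acceptor`, `acceptor_pos`, `read_count`.
#'
#' @param path TSV path.
#' @return data.table of junction records.
#' @export
read_junction_evidence <- function(path) {
  j <- data.table::fread(path)
  req <- c("sample_id", "chrom_donor", "donor_pos", "chrom_acceptor",
           "acceptor_pos", "read_count")
  miss <- setdiff(req, names(j))
  if (length(miss)) stop("junction table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (any(j$read_count < 1)) stop("read_count must be >= 1")
  j[]
}

#' Verify a chimera prediction against junction read evidence
#'
#' Sums split-read counts over evidence records whose donor and acceptor
#' positions match the prediction within `tol` bp (and the prediction's
#' sample, when both carry sample ids).
#'
#' @param pred a `chimera_prediction`.
#' @param evidence junction table (see [read_junction_evidence()]).
#' @param min_reads minimum supporting reads (default 3).
#' @param tol positional tolerance in bp (default 0: exact splice sites).
#' @return list with `verified` (logical) and `reads` (count).
#' @export
verify_junction_support <- function(pred, evidence, min_reads = 3L,
                                    tol = 0L) {
  stopifnot(min_reads >= 1L)
  ev <- data.table::as.data.table(evidence)
  if (!is.na(pred$sample_id) && "sample_id" %in% names(ev))
    ev <- ev[sample_id == pred$sample_id]
  m <- ev[chrom_donor == pred$donor_chrom &
            abs(donor_pos - pred$donor_pos) <= tol &
            chrom_acceptor == pred$acceptor_chrom &
            abs(acceptor_pos - pred$acceptor_pos) <= tol]
  reads <- if (nrow(m)) sum(m$read_count) else 0L
  list(verified = reads >= min_reads, reads = as.integer(reads))
}
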