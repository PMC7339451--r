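# Recurrent-fusion screens: the distance-ordered split-search over UIB/DIB
# breakpoints with rank-sum testing and expression/copy-number filters,
# the recurrent gene-gene screen, and the nearest-upstream-gene screen.

#' Assemble a cohort: SV calls, expression, copy number, tumor types
#'
#' @param callsets list of [call_set()] objects (or a single calls
#'   data.table covering all samples).
#' @param expr numeric genes x samples matrix of TPM values (>= 0).
#' @param cna integer genes x samples matrix of GISTIC-style scores
#'   (2 = high-level amplification); may be `NULL` (treated as all 0).
#' @param tumor_type named character vector, one label per sample.
#' @param junctions optional RNA junction evidence table (see
#'   [read_junction_evidence()]).
#' @return An object of class `cohort_data`.
#' @export
cohort_data <- function(callsets, expr, cna = NULL, tumor_type,
                        junctions = NULL) {
  calls <- .calls_of(callsets)
  samples <- colnames(expr)
  if (is.null(samples)) stop("expression matrix needs sample column names")
  if (any(expr < 0)) stop("TPM values must be >= 0")
  if (is.null(cna)) {
    cna <- matrix(0L, nrow(expr), ncol(expr),
                  dimnames = dimnames(expr))
  }
  if (!identical(colnames(cna), samples))
    stop("expression and copy-number matrices have different samples")
  if (!all(names(tumor_type) %in% samples) || !all(samples %in% names(tumor_type)))
    stop("tumor_type labels and expression samples are inconsistent")
  extra <- setdiff(unique(calls$sample_id), samples)
  if (length(extra))
    stop("call samples missing from the expression matrix: ",
         paste(utils::head(extra, 5L), collapse = ", "))
  structure(list(calls = calls, expr = expr, cna = cna,
                 tumor_type = tumor_type[samples], junctions = junctions),
            class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  cat("cohort_data:", ncol(x$expr), "samples (",
      paste(sprintf("%s=%d", names(table(x$tumor_type)),
                    table(x$tumor_type)), collapse = ", "),
      "),", nrow(x$expr), "genes,", nrow(x$calls), "SV calls\n")
  invisible(x)
}

.type_samples <- function(cohort, type)
  names(cohort$tumor_type)[cohort$tumor_type == type]

# Two-sided rank-sum p-values for every prefix split S1..Si of the
# distance-ordered candidate samples, against the rest of the tumor type
# ("rest") or the remaining candidates ("literal"). Normal approximation
# with tie correction and continuity correction, the same arithmetic as
# wilcox.test(exact = FALSE, correct = TRUE); fully tied data give p = 1.
# Ranks are computed once because the combined sample set is the same for
# every split.
.split_ps <- function(y_ts, s_ord, comparison) {
  n <- length(s_ord)
  if (comparison == "rest") {
    N <- length(y_ts)
    r <- rank(y_ts)
    csum <- cumsum(r[s_ord])
    i <- seq_len(n)
  } else {
    if (n < 2L) return(NA_real_)
    N <- n
    r <- rank(y_ts[s_ord])
    csum <- cumsum(r)
    i <- seq_len(n - 1L)
    csum <- csum[i]
  }
  nt <- table(r)
  tie_term <- sum(nt^3 - nt) / (N * (N - 1))
  nx <- i
  ny <- N - i
  W <- csum - i * (i + 1) / 2
  sigma <- sqrt((nx * ny / 12) * ((N + 1) - tie_term))
  z <- W - nx * ny / 2
  z <- (z - sign(z) * 0.5) / sigma
  p <- 2 * pmin(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE))
  p[sigma == 0] <- 1          # fully tied expression values
  p[ny == 0] <- NA_real_      # no comparison group left
  unname(pmin(p, 1))
}

#' Split-search for the best fusion-positive sample group
#'
#' Orders the concordant intergenic breakpoints upstream (UIB) or
#' downstream (DIB) of a target gene by distance (S1 closest; a sample
#' with several qualifying breakpoints contributes its closest; distance
#' ties broken by sample id), then for every split i tests target-gene
#' expression in samples S1..Si against a comparison group with the
#' two-sided Wilcoxon rank-sum test and returns the split with the lowest
#' p-value.
#'
#' The default comparison group (`"rest"`) is all remaining samples of
#' the tumor type, which tests upregulation against the cohort
#' background; `"literal"` compares against samples S(i+1)..Sn only.
#'
#' @param target_gene gene id (must be a row of the expression matrix).
#' @param mode `"UIB"` or `"DIB"`.
#' @param cohort a [cohort_data()].
#' @param ann a [genome_annotation()].
#' @param tumor_type tumor-type label to screen within; default: the type
#'   of the first candidate sample.
#' @param window maximum breakpoint distance in bp (default 4 Mb).
#' @param comparison `"rest"` or `"literal"`.
#' @param permutations if > 0, a label-permutation empirical p-value for
#'   the minimum-over-splits statistic is computed with this many
#'   shuffles (uses the current RNG state; seed upstream).
#' @param candidates optional precomputed [candidate_table()] (an
#'   optimization for cohort-wide screens).
#' @return An object of class `split_search_result`, or `NULL` when no
#'   sample has a qualifying breakpoint.
#' @export
split_search_best_group <- function(target_gene, mode, cohort, ann,
                                    tumor_type = NULL, window = 4e6,
                                    comparison = c("rest", "literal"),
                                    permutations = 0L,
                                    candidates = NULL) {
  comparison <- match.arg(comparison)
  if (!target_gene %in% rownames(cohort$expr))
    stop("target gene absent from the expression matrix: ", target_gene)
  if (is.null(candidates))
    candidates <- candidate_table(cohort$calls, ann, window = window)
  sel <- candidates$target_gene == target_gene & candidates$mode == mode &
    candidates$concordant & candidates$distance <= window
  cand <- candidates[which(sel)]
  if (!nrow(cand)) return(NULL)
  if (is.null(tumor_type))
    tumor_type <- unname(cohort$tumor_type[cand$sample_id[1L]])
  ts <- .type_samples(cohort, tumor_type)
  cand <- cand[which(cand$sample_id %in% ts)]
  if (!nrow(cand)) return(NULL)

  per_sample <- cand[, .(distance = min(distance)), by = sample_id]
  data.table::setorder(per_sample, distance, sample_id)
  s_ord <- per_sample$sample_id
  d_ord <- per_sample$distance
  n <- length(s_ord)
  y <- cohort$expr[target_gene, ts]

  ps <- .split_ps(y, s_ord, comparison)
  if (all(is.na(ps))) return(NULL)
  chosen_i <- which.min(ps)
  p_min <- ps[chosen_i]

  empirical_p <- NA_real_
  if (permutations > 0L) {
    hits <- 0L
    yp <- y
    for (b in seq_len(permutations)) {
      yp[] <- sample(unname(y))
      if (min(.split_ps(yp, s_ord, comparison), na.rm = TRUE) <= p_min)
        hits <- hits + 1L
    }
    empirical_p <- (hits + 1L) / (permutations + 1L)
  }

  structure(list(target_gene = target_gene, mode = mode,
                 tumor_type = tumor_type,
                 samples = s_ord, distances = d_ord,
                 chosen_i = chosen_i,
                 positive_samples = s_ord[seq_len(chosen_i)],
                 p_value = p_min,
                 n_splits_tested = sum(!is.na(ps)),
                 empirical_p = empirical_p,
                 comparison = comparison),
            class = "split_search_result")
}

#' @export
print.split_search_result <- function(x, ...) {
  cat(sprintf("split_search_result: %s^%s [%s], n=%d, chosen i=%d, p=%.3g\n",
              x$target_gene, x$mode, x$tumor_type, length(x$samples),
              x$chosen_i, x$p_value))
  invisible(x)
}

#' Expression and copy-number filters on a split-search result
#'
#' Samples with a high-level amplification of the target (copy-number
#' score 2) are excluded from the analysis first: amplified positives are
#' removed from the fusion-positive group, and amplified non-positives
#' from the control group, so that amplification neither mimics nor masks
#' a fusion effect. Each remaining case's fold change is its TPM over the
#' median TPM of the control samples (pseudocount 0.1 on numerator and
#' denominator); cases at or below `min_case_fold` are flagged out. The
#' surviving group passes when its mean TPM exceeds `min_mean_fold` times
#' the control mean.
#'
#' @param result a `split_search_result`.
#' @param cohort a [cohort_data()].
#' @param min_case_fold per-case fold threshold (strict, default 4).
#' @param min_mean_fold group-mean fold threshold (strict, default 5).
#' @param pseudocount added to numerator and denominator of folds.
#' @return list with `positive_samples` (survivors), `case_folds` (named,
#'   survivors), `group_mean_fold`, `passes` (survivors non-empty and
#'   mean-fold criterion met), `removed_amplified`, `removed_low_fold`,
#'   `control_samples`.
#' @export
apply_expression_filters <- function(result, cohort, min_case_fold = 4,
                                     min_mean_fold = 5, pseudocount = 0.1) {
  stopifnot(inherits(result, "split_search_result"))
  g <- result$target_gene
  ts <- .type_samples(cohort, result$tumor_type)
  pos <- result$positive_samples
  control <- setdiff(ts, pos)
  control <- control[cohort$cna[g, control] != 2]
  if (!length(control)) stop("control group is empty for ", g)

  amp <- pos[cohort$cna[g, pos] == 2]
  pos2 <- setdiff(pos, amp)
  ctl_med <- stats::median(cohort$expr[g, control])
  folds <- (cohort$expr[g, pos2] + pseudocount) / (ctl_med + pseudocount)
  low <- pos2[folds <= min_case_fold]
  surv <- setdiff(pos2, low)
  gmf <- if (length(surv))
    (mean(cohort$expr[g, surv]) + pseudocount) /
      (mean(cohort$expr[g, control]) + pseudocount)
  else NA_real_
  list(positive_samples = surv,
       case_folds = if (length(surv)) folds[surv] else stats::setNames(numeric(), character()),
       group_mean_fold = gmf,
       passes = length(surv) > 0 && isTRUE(gmf > min_mean_fold),
       removed_amplified = amp,
       removed_low_fold = low,
       control_samples = control)
}

# CP labeling: does any surviving positive sample carry a verified chimera
# prediction for this target?
.cp_status <- function(target, surv, cand_rows, cohort, ann,
                       chimera_window, min_junction_reads) {
  junctions <- cohort$junctions
  n_verified <- 0L
  for (s in surv) {
    rows <- cand_rows[cand_rows$sample_id == s & cand_rows$partner_genic]
    if (!nrow(rows)) next
    for (ci in unique(rows$call_id)) {
      call <- cohort$calls[sample_id == s & call_id == ci]
      pred <- predict_chimera(call[1L], ann, chimera_window = chimera_window)
      if (is.null(pred) || pred$three_gene != target) next
      if (!is.null(junctions)) {
        v <- verify_junction_support(pred, junctions,
                                     min_reads = min_junction_reads)
        if (v$verified) { n_verified <- n_verified + 1L; break }
      }
    }
  }
  list(label = if (n_verified > 0L) "CP" else "N_CP",
       n_verified = n_verified)
}

#' Screen for recurrent target-upregulating UIB/DIB fusions
#'
#' For every gene and tumor type with enough candidate breakpoints, runs
#' [split_search_best_group()] followed by [apply_expression_filters()]
#' and emits an event when the surviving fusion-positive group has at
#' least `min_samples` samples. Events are labelled `CP` when at least
#' one positive sample has a junction-verified chimera prediction for the
#' target, `N_CP` otherwise, and carry breakpoint-distance summaries and
#' cytoband-level partner recurrence.
#'
#' @param cohort a [cohort_data()].
#' @param ann a [genome_annotation()].
#' @param bands optional `cytoband_map` for partner labels.
#' @param min_samples minimum surviving positive samples (default 4).
#' @param window breakpoint search window in bp (default 4 Mb).
#' @param modes subset of `c("UIB", "DIB")`.
#' @param min_case_fold,min_mean_fold,pseudocount see
#'   [apply_expression_filters()].
#' @param chimera_window,min_junction_reads chimera verification settings.
#' @param comparison,permutations see [split_search_best_group()].
#' @param max_p report only events with split-search p-value below this
#'   (default 1: report all passing the fold filters, sorted by p).
#' @return list with `events` (data.table, one row per event) and
#'   `evidence` (data.table, one row per positive sample).
#' @export
screen_uib_dib <- function(cohort, ann, bands = NULL, min_samples = 4L,
                           window = 4e6, modes = c("UIB", "DIB"),
                           min_case_fold = 4, min_mean_fold = 5,
                           pseudocount = 0.1, chimera_window = 1e5,
                           min_junction_reads = 3L,
                           comparison = c("rest", "literal"),
                           permutations = 0L, max_p = 1) {
  comparison <- match.arg(comparison)
  cand <- candidate_table(cohort$calls, ann, bands = bands, window = window)
  cand <- cand[cand$concordant & cand$target_gene %in% rownames(cohort$expr)]
  cand$tumor_type <- unname(cohort$tumor_type[cand$sample_id])

  ev_rows <- list(); sample_rows <- list()
  if (nrow(cand)) {
    groups <- cand[, .(n_samp = data.table::uniqueN(sample_id)),
                   by = .(tumor_type, target_gene, mode)]
    groups <- groups[n_samp >= min_samples & mode %in% modes]
    for (k in seq_len(nrow(groups))) {
      tt <- groups$tumor_type[k]; g <- groups$target_gene[k]
      md <- groups$mode[k]
      res <- split_search_best_group(g, md, cohort, ann, tumor_type = tt,
                                     window = window,
                                     comparison = comparison,
                                     permutations = permutations,
                                     candidates = cand)
      if (is.null(res)) next
      filt <- apply_expression_filters(res, cohort,
                                       min_case_fold = min_case_fold,
                                       min_mean_fold = min_mean_fold,
                                       pseudocount = pseudocount)
      surv <- filt$positive_samples
      if (length(surv) < min_samples || !filt$passes) next
      if (!is.na(res$p_value) && res$p_value > max_p) next

      rows <- cand[cand$target_gene == g & cand$mode == md &
                     cand$sample_id %in% surv]
      per_s <- rows[, .SD[which.min(distance)], by = sample_id]
      cp <- .cp_status(g, surv, rows, cohort, ann, chimera_window,
                       min_junction_reads)
      cb <- per_s$partner_cytoband[!is.na(per_s$partner_cytoband)]
      cb_rec <- length(cb) >= 2L && any(table(cb) >= 2L)
      d <- per_s$distance
      ev_rows[[length(ev_rows) + 1L]] <- data.table::data.table(
        target_gene = g, tumor_type = tt, mode = md,
        n_samples = length(surv),
        samples = paste(sort(surv), collapse = ","),
        p_value = res$p_value, empirical_p = res$empirical_p,
        n_splits_tested = res$n_splits_tested, chosen_i = res$chosen_i,
        group_mean_fold = filt$group_mean_fold,
        cp_label = cp$label, n_verified_chimeras = cp$n_verified,
        partner_recurrent_at_cytoband = cb_rec,
        dist_mean = mean(d), dist_max = max(d),
        frac_gt_1mb = mean(d > 1e6), frac_gt_2mb = mean(d > 2e6),
        n_removed_amplified = length(filt$removed_amplified),
        n_removed_low_fold = length(filt$removed_low_fold))
      sample_rows[[length(sample_rows) + 1L]] <- data.table::data.table(
        target_gene = g, tumor_type = tt, mode = md,
        sample_id = per_s$sample_id, distance = per_s$distance,
        partner_cytoband = per_s$partner_cytoband,
        partner_desc = per_s$partner_desc,
        fold = unname(filt$case_folds[per_s$sample_id]))
    }
  }
  empty_ev <- data.table::data.table(
    target_gene = character(), tumor_type = character(), mode = character(),
    n_samples = integer(), samples = character(), p_value = numeric(),
    empirical_p = numeric(), n_splits_tested = integer(),
    chosen_i = integer(), group_mean_fold = numeric(),
    cp_label = character(), n_verified_chimeras = integer(),
    partner_recurrent_at_cytoband = logical(), dist_mean = numeric(),
    dist_max = numeric(), frac_gt_1mb = numeric(), frac_gt_2mb = numeric(),
    n_removed_amplified = integer(), n_removed_low_fold = integer())
  events <- if (length(ev_rows)) data.table::rbindlist(ev_rows) else empty_ev
  if (nrow(events)) data.table::setorder(events, p_value)
  evidence <- if (length(sample_rows)) data.table::rbindlist(sample_rows)
  else data.table::data.table(
    target_gene = character(), tumor_type = character(), mode = character(),
    sample_id = character(), distance = numeric(),
    partner_cytoband = character(), partner_desc = character(),
    fold = numeric())
  list(events = events, evidence = evidence)
}

#' Screen for recurrent gene-gene fusions
#'
#' A gene pair is recurrent when both breakpoints fall inside the two
#' genes and at least `min_samples` distinct samples share the pair.
#' When the junction orientation determines a 5' to 3' direction
#' (sense-to-sense), pairs are keyed directionally; otherwise the
#' unordered pair is used.
#'
#' @param cohort a [cohort_data()] (or anything [classify_calls()]
#'   accepts).
#' @param ann a [genome_annotation()].
#' @param min_samples recurrence threshold (default 2).
#' @return data.table with one row per recurrent pair: `pair_key`,
#'   `five_gene`, `three_gene`, `oriented`, `n_samples`, `samples`.
#' @export
screen_recurrent_gene_gene <- function(cohort, ann, min_samples = 2L) {
  calls <- classify_calls(if (inherits(cohort, "cohort_data"))
    cohort$calls else cohort, ann)
  gg <- calls[fusion_class == "GENE_GENE"]
  empty <- data.table::data.table(
    pair_key = character(), five_gene = character(),
    three_gene = character(), oriented = logical(),
    n_samples = integer(), samples = character())
  if (!nrow(gg)) return(empty)
  keys <- lapply(seq_len(nrow(gg)), function(i) {
    r <- gg[i]
    a1 <- annotate_position(ann, r$chrom1, r$pos1)$hit_genes
    a2 <- annotate_position(ann, r$chrom2, r$pos2)$hit_genes
    g1 <- a1$gene_id[1L]; g2 <- a2$gene_id[1L]
    if (g1 == g2) return(NULL)
    s1 <- ann$genes[gene_id == g1, strand]
    s2 <- ann$genes[gene_id == g2, strand]
    fwd <- .exit_dir(r$side1) == s1 && .walk_dir(r$side2) == s2
    rev_ <- .exit_dir(r$side2) == s2 && .walk_dir(r$side1) == s1
    if (fwd && !rev_)
      data.table::data.table(sample_id = r$sample_id, five_gene = g1,
                             three_gene = g2, oriented = TRUE)
    else if (rev_ && !fwd)
      data.table::data.table(sample_id = r$sample_id, five_gene = g2,
                             three_gene = g1, oriented = TRUE)
    else {
      p <- sort(c(g1, g2))
      data.table::data.table(sample_id = r$sample_id, five_gene = p[1L],
                             three_gene = p[2L], oriented = FALSE)
    }
  })
  keys <- data.table::rbindlist(Filter(Negate(is.null), keys))
  if (!nrow(keys)) return(empty)
  keys[, pair_key := ifelse(oriented, paste0(five_gene, "->", three_gene),
                            paste0(five_gene, "~", three_gene))]
  out <- keys[, .(five_gene = five_gene[1L], three_gene = three_gene[1L],
                  oriented = oriented[1L],
                  n_samples = data.table::uniqueN(sample_id),
                  samples = paste(sort(unique(sample_id)), collapse = ",")),
              by = pair_key]
  out <- out[n_samples >= min_samples]
  data.table::setorder(out, -n_samples, pair_key)
  out[]
}

#' Nearest-upstream-gene recurrence screen
#'
#' The simpler initial scenario: candidate breakpoints are restricted to
#' the interval between a target gene's transcription start and the
#' nearest upstream gene. A target is reported when at least
#' `min_samples` samples carry such a breakpoint, every case lies on the
#' same side of the control median (consistent up- or downregulation),
#' and a two-sided rank-sum test of the positive group against the rest
#' of the tumor type is below `alpha`.
#'
#' @param cohort a [cohort_data()].
#' @param ann a [genome_annotation()].
#' @param min_samples recurrence threshold (default 2).
#' @param alpha rank-sum significance threshold (default 0.05).
#' @param pseudocount for fold computation.
#' @return data.table with one row per event: `target_gene`,
#'   `tumor_type`, `direction` (`UP`/`DOWN`), `n_samples`, `samples`,
#'   `p_value`, `median_fold`.
#' @export
screen_nearest_gene <- function(cohort, ann, min_samples = 2L,
                                alpha = 0.05, pseudocount = 0.1) {
  cand <- candidate_table(cohort$calls, ann, window = 4e6)
  cand <- cand[cand$mode == "UIB" & cand$target_gene %in% rownames(cohort$expr)]
  empty <- data.table::data.table(
    target_gene = character(), tumor_type = character(),
    direction = character(), n_samples = integer(), samples = character(),
    p_value = numeric(), median_fold = numeric())
  if (!nrow(cand)) return(empty)

  # per gene: distance from tx start to the nearest upstream gene body
  limit <- vapply(unique(cand$target_gene), function(gid) {
    g <- ann$genes[gene_id == gid]
    others <- ann$genes[chrom == g$chrom & gene_id != gid]
    if (g$strand == "+") {
      ups <- others[end < g$start]
      if (nrow(ups)) g$start - max(ups$end) else g$start
    } else {
      ups <- others[start > g$end]
      if (nrow(ups)) min(ups$start) - g$end else
        ann$chrom_sizes[[g$chrom]] - g$end + 1
    }
  }, 0)
  cand <- cand[cand$distance < limit[cand$target_gene]]
  if (!nrow(cand)) return(empty)
  cand$tumor_type <- unname(cohort$tumor_type[cand$sample_id])

  rows <- list()
  grp <- unique(cand[, .(target_gene, tumor_type)])
  for (k in seq_len(nrow(grp))) {
    g <- grp$target_gene[k]; tt <- grp$tumor_type[k]
    pos <- unique(cand[cand$target_gene == g & cand$tumor_type == tt,
                       sample_id])
    if (length(pos) < min_samples) next
    ts <- .type_samples(cohort, tt)
    ctl <- setdiff(ts, pos)
    if (!length(ctl)) next
    med <- stats::median(cohort$expr[g, ctl])
    folds <- (cohort$expr[g, pos] + pseudocount) / (med + pseudocount)
    if (all(folds > 1)) dir_ <- "UP"
    else if (all(folds < 1)) dir_ <- "DOWN"
    else next
    p <- suppressWarnings(stats::wilcox.test(
      cohort$expr[g, pos], cohort$expr[g, ctl], exact = FALSE)$p.value)
    if (is.na(p) || p >= alpha) next
    rows[[length(rows) + 1L]] <- data.table::data.table(
      target_gene = g, tumor_type = tt, direction = dir_,
      n_samples = length(pos),
      samples = paste(sort(pos), collapse = ","),
      p_value = p, median_fold = stats::median(folds))
  }
  if (!length(rows)) return(empty)
  out <- data.table::rbindlist(rows)
  data.table::setorder(out, p_value)
  out[]
}
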