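# Supporting statistics: proportion test, Fisher enrichment, pairwise
# mutual exclusivity, group differential expression, and the correlation
# screen with Benjamini-Hochberg adjustment.

#' One-proportion test
#'
#' Tests `k` successes out of `n` against a null proportion `p0`.
#' `"exact"` is the two-sided exact binomial test; `"normal"` uses the
#' z-statistic `(k/n - p0) / sqrt(p0 (1 - p0) / n)`.
#'
#' @param k,n successes and trials.
#' @param p0 null proportion, strictly between 0 and 1.
#' @param method `"exact"` or `"normal"`.
#' @return Two-sided p-value.
#' @export
proportion_test <- function(k, n, p0, method = c("exact", "normal")) {
  method <- match.arg(method)
  if (!(p0 > 0 && p0 < 1)) stop("p0 must be in (0, 1)")
  stopifnot(k >= 0, k <= n)
  if (method == "exact") {
    stats::binom.test(k, n, p = p0)$p.value
  } else {
    z <- (k / n - p0) / sqrt(p0 * (1 - p0) / n)
    2 * stats::pnorm(-abs(z))
  }
}

#' Fisher enrichment of a gene set in a reference list
#'
#' One-sided (enrichment) Fisher exact test of the overlap between
#' `targets` and `reference` within `universe`.
#'
#' @param targets,reference,universe character vectors of gene ids;
#'   `targets` and `reference` must be subsets of `universe`.
#' @return list of class `enrichment_result`: `overlap`, `set_a_size`,
#'   `set_b_size`, `universe_size`, `odds_ratio`, `p_value`, and the 2x2
#'   `table`.
#' @export
fisher_enrichment <- function(targets, reference, universe) {
  targets <- unique(targets); reference <- unique(reference)
  universe <- unique(universe)
  if (!all(targets %in% universe) || !all(reference %in% universe))
    stop("targets and reference must be subsets of the universe")
  a <- length(intersect(targets, reference))
  b <- length(targets) - a
  c_ <- length(reference) - a
  d <- length(universe) - a - b - c_
  tab <- matrix(c(a, b, c_, d), nrow = 2,
                dimnames = list(c("in_ref", "not_ref"),
                                c("target", "not_target")))
  ft <- stats::fisher.test(tab, alternative = "greater")
  structure(list(overlap = a, set_a_size = length(targets),
                 set_b_size = length(reference),
                 universe_size = length(universe),
                 odds_ratio = unname(ft$estimate),
                 p_value = ft$p.value, table = tab),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment: %d/%d targets in a %d-gene reference (universe %d); OR=%.3g, p=%.3g\n",
              x$overlap, x$set_a_size, x$set_b_size, x$universe_size,
              x$odds_ratio, x$p_value))
  invisible(x)
}

#' Pairwise mutual exclusivity / co-occurrence
#'
#' For every pair of alterations in a binary sample-by-alteration matrix,
#' a Fisher exact test on the 2x2 co-occurrence table, reporting both
#' one-sided tails: `p_exclusive` (fewer co-occurrences than expected)
#' and `p_cooccur` (more). Constant (all-0 or all-1) alterations yield
#' `NA`.
#'
#' @param events binary matrix, rows = samples, columns = alterations.
#' @return data.table with one row per unordered pair.
#' @export
mutual_exclusivity <- function(events) {
  events <- as.matrix(events)
  if (ncol(events) < 2L || nrow(events) < 2L)
    stop("need >= 2 alterations and >= 2 samples")
  stopifnot(all(events %in% c(0, 1)))
  cn <- colnames(events)
  if (is.null(cn)) cn <- paste0("alt", seq_len(ncol(events)))
  pairs <- utils::combn(ncol(events), 2L)
  res <- lapply(seq_len(ncol(pairs)), function(i) {
    x <- events[, pairs[1L, i]]; y <- events[, pairs[2L, i]]
    if (length(unique(x)) < 2L || length(unique(y)) < 2L)
      return(data.table::data.table(
        alt_a = cn[pairs[1L, i]], alt_b = cn[pairs[2L, i]],
        n_both = NA_integer_, p_exclusive = NA_real_, p_cooccur = NA_real_))
    tab <- table(factor(x, c(1, 0)), factor(y, c(1, 0)))
    data.table::data.table(
      alt_a = cn[pairs[1L, i]], alt_b = cn[pairs[2L, i]],
      n_both = as.integer(tab[1L, 1L]),
      p_exclusive = stats::fisher.test(tab, alternative = "less")$p.value,
      p_cooccur = stats::fisher.test(tab, alternative = "greater")$p.value)
  })
  data.table::rbindlist(res)
}

#' Group differential expression
#'
#' Per-gene two-sided test (two-sample t or Wilcoxon rank-sum) between a
#' positive and a negative sample group, with the group-mean fold change
#' (pseudocount 0.1 on both means).
#'
#' @param expr numeric matrix, genes x samples (e.g. TPM).
#' @param positive,negative sample-id (column) vectors.
#' @param method `"t"` or `"ranksum"`.
#' @return data.table with `gene_id`, `statistic`, `p_value`, `fold`.
#' @export
group_de_test <- function(expr, positive, negative,
                          method = c("t", "ranksum")) {
  method <- match.arg(method)
  missing_s <- setdiff(c(positive, negative), colnames(expr))
  if (length(missing_s)) stop("samples not in expression matrix: ",
                              paste(missing_s, collapse = ", "))
  min_n <- if (method == "t") 2L else 1L
  if (length(positive) < min_n || length(negative) < min_n)
    stop("groups too small for the ", method, " test (need >= ", min_n,
         " per group) for all genes: ",
         paste(utils::head(rownames(expr), 3L), collapse = ", "), ", ...")
  res <- lapply(rownames(expr), function(g) {
    xp <- expr[g, positive]; xn <- expr[g, negative]
    tst <- if (method == "t") {
      if (stats::sd(c(xp, xn)) == 0)
        list(statistic = 0, p.value = 1)
      else stats::t.test(xp, xn)
    } else
      suppressWarnings(stats::wilcox.test(xp, xn, exact = FALSE))
    data.table::data.table(
      gene_id = g,
      statistic = unname(tst$statistic),
      p_value = tst$p.value,
      fold = (mean(xp) + 0.1) / (mean(xn) + 0.1))
  })
  data.table::rbindlist(res)
}

#' Correlation screen against a target gene
#'
#' Pearson correlation of every gene's expression with the target gene
#' across samples; p-values from the t-transform with n-2 degrees of
#' freedom and Benjamini-Hochberg q-values across all tested genes.
#' Zero-variance genes are skipped; the target itself is excluded.
#'
#' @param expr genes x samples matrix.
#' @param target_gene row name of the target.
#' @param q_threshold report genes with q below this value (default 0.05).
#' @return list with `hits` (data.table `gene_id`, `r`, `p_value`,
#'   `q_value` for q < threshold, sorted by q), `all` (the full table),
#'   `n_tested` and `n_skipped`.
#' @export
correlation_screen <- function(expr, target_gene, q_threshold = 0.05) {
  if (!target_gene %in% rownames(expr))
    stop("target gene not in expression matrix: ", target_gene)
  n <- ncol(expr)
  if (n < 3L) stop("need >= 3 samples")
  y <- expr[target_gene, ]
  others <- setdiff(rownames(expr), target_gene)
  v <- apply(expr[others, , drop = FALSE], 1L, stats::sd)
  skipped <- others[v == 0 | is.na(v)]
  if (length(skipped))
    message("correlation_screen: skipping ", length(skipped),
            " zero-variance gene(s)")
  tested <- setdiff(others, skipped)
  if (stats::sd(y) == 0) stop("target gene has zero variance")
  r <- as.numeric(stats::cor(t(expr[tested, , drop = FALSE]), y))
  tstat <- r * sqrt((n - 2) / pmax(1e-300, 1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  q <- stats::p.adjust(p, method = "BH")
  all_dt <- data.table::data.table(gene_id = tested, r = r,
                                   p_value = p, q_value = q)
  data.table::setorder(all_dt, q_value, p_value)
  list(hits = all_dt[q_value < q_threshold],
       all = all_dt, n_tested = length(tested),
       n_skipped = length(skipped))
}
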