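# Split-search screen, expression/copy-number filters, gene-gene and
# nearest-upstream-gene recurrence.

# one "+" target gene 5 Mb into a 9 Mb chromosome, second chromosome for
# translocation partners
split_ann <- function() {
  genome_annotation(
    data.frame(gene_id = "T1", chrom = "c1", strand = "+",
               start = 5000001, end = 5010000,
               cds_start = 5000101, cds_end = 5009900),
    data.frame(gene_id = rep("T1", 3),
               start = c(5000001, 5003001, 5009001),
               end = c(5000200, 5003200, 5009990)),
    chrom_sizes = c(c1 = 9e6, c2 = 9e6))
}

uib_call <- function(sample, d, id = sample) mk_call(
  "c1", 5000001 - d, "RIGHT", "c2", 100000 + d, "LEFT",
  sample_id = sample, call_id = id)

test_that("split search picks the same group as an exhaustive oracle", {
  ann <- split_ann()
  d <- c(0.1e6, 0.2e6, 0.3e6, 2.5e6, 3.0e6, 3.9e6)
  bp_samples <- sprintf("TT_S%02d", 1:6)
  calls <- data.table::rbindlist(lapply(1:6, function(i)
    uib_call(bp_samples[i], d[i])))
  withr::with_seed(21, {
    tpm <- rlnorm(56, meanlog = 2, sdlog = 0.2)
    tpm[1:3] <- tpm[1:3] * 10
  })
  cohort <- mk_cohort(calls, ann, n_samples = 56, target = "T1",
                      target_tpm = tpm)
  res <- split_search_best_group("T1", "UIB", cohort, ann)
  expect_equal(res$chosen_i, 3L)
  expect_equal(res$positive_samples, bp_samples[1:3])
  expect_equal(res$distances, d)

  # independent exhaustive oracle over every split, using wilcox.test
  ts <- colnames(cohort$expr)
  y <- cohort$expr["T1", ]
  oracle <- sapply(1:6, function(i) suppressWarnings(
    wilcox.test(y[bp_samples[1:i]], y[setdiff(ts, bp_samples[1:i])],
                exact = FALSE)$p.value))
  expect_equal(res$p_value, min(oracle), tolerance = 1e-12)
  expect_equal(res$chosen_i, which.min(oracle))
  expect_equal(res$n_splits_tested, 6L)
})

test_that("single-sample and fully tied inputs behave as defined", {
  ann <- split_ann()
  cohort <- mk_cohort(uib_call("TT_S01", 5e5), ann, n_samples = 20,
                      target = "T1", target_tpm = 80)
  res <- split_search_best_group("T1", "UIB", cohort, ann)
  expect_equal(res$chosen_i, 1L)
  expect_equal(res$n_splits_tested, 1L)

  flat <- mk_cohort(uib_call("TT_S01", 5e5), ann, n_samples = 20)
  res2 <- split_search_best_group("T1", "UIB", flat, ann)
  expect_equal(res2$p_value, 1)

  expect_error(split_search_best_group("nope", "UIB", cohort, ann),
               "absent")
  expect_null(split_search_best_group("T1", "DIB", cohort, ann))
})

test_that("the literal split variant compares against the remaining candidates", {
  ann <- split_ann()
  d <- c(1e5, 2e5, 3e5, 2.5e6, 3e6, 3.9e6)
  bp_samples <- sprintf("TT_S%02d", 1:6)
  calls <- data.table::rbindlist(lapply(1:6, function(i)
    uib_call(bp_samples[i], d[i])))
  tpm <- c(100, 90, 95, 10, 11, 9)
  cohort <- mk_cohort(calls, ann, n_samples = 30, target = "T1",
                      target_tpm = tpm)
  res <- split_search_best_group("T1", "UIB", cohort, ann,
                                 comparison = "literal")
  expect_equal(res$chosen_i, 3L)
  expect_equal(res$n_splits_tested, 5L)   # i = n has no comparison group
  y <- cohort$expr["T1", ]
  oracle <- sapply(1:5, function(i) suppressWarnings(
    wilcox.test(y[bp_samples[1:i]], y[bp_samples[(i + 1):6]],
                exact = FALSE)$p.value))
  expect_equal(res$p_value, min(oracle), tolerance = 1e-12)
})

test_that("permutation calibration gives a small empirical p for a real effect", {
  ann <- split_ann()
  calls <- data.table::rbindlist(lapply(1:4, function(i)
    uib_call(sprintf("TT_S%02d", i), i * 1e5)))
  withr::with_seed(3, {
    tpm <- rlnorm(40, 2, 0.2); tpm[1:4] <- tpm[1:4] * 50
    cohort <- mk_cohort(calls, ann, n_samples = 40, target = "T1",
                        target_tpm = tpm)
    res <- split_search_best_group("T1", "UIB", cohort, ann,
                                   permutations = 200L)
  })
  expect_lt(res$empirical_p, 0.05)
})

test_that("expression filters implement fold floors and amplification exclusion", {
  ann <- split_ann()
  samples <- sprintf("TT_S%02d", 1:20)
  mk_res <- function(pos) structure(
    list(target_gene = "T1", mode = "UIB", tumor_type = "TT",
         samples = pos, distances = seq_along(pos) * 1e5,
         chosen_i = length(pos), positive_samples = pos,
         p_value = 0.01, n_splits_tested = length(pos),
         empirical_p = NA_real_, comparison = "rest"),
    class = "split_search_result")
  base_expr <- function(vals) {
    expr <- matrix(10, 1, 20, dimnames = list("T1", samples))
    expr[1, seq_along(vals)] <- vals
    expr
  }

  # control median 10: 50 TPM ~ 5-fold (kept), 35 TPM ~ 3.5-fold (out)
  cna <- matrix(0L, 1, 20, dimnames = list("T1", samples))
  cohort <- cohort_data(uibscreen:::.empty_calls(),
                        base_expr(c(50, 35)), cna,
                        stats::setNames(rep("TT", 20), samples))
  f <- apply_expression_filters(mk_res(samples[1:2]), cohort)
  expect_equal(f$positive_samples, samples[1])
  expect_equal(f$removed_low_fold, samples[2])
  expect_equal(unname(f$case_folds), (50 + 0.1) / (10 + 0.1))

  # a positive with GISTIC score 2 leaves the positive group before any
  # fold is computed
  cna2 <- cna; cna2["T1", samples[2]] <- 2L
  cohort2 <- cohort_data(uibscreen:::.empty_calls(),
                         base_expr(c(90, 95, 85)), cna2,
                         stats::setNames(rep("TT", 20), samples))
  f2 <- apply_expression_filters(mk_res(samples[1:3]), cohort2)
  expect_equal(f2$removed_amplified, samples[2])
  expect_equal(f2$positive_samples, samples[c(1, 3)])

  # an amplified non-positive sample is excluded from the control too
  cna3 <- cna; cna3["T1", samples[10]] <- 2L
  expr3 <- base_expr(c(90, 95)); expr3["T1", samples[10]] <- 500
  cohort3 <- cohort_data(uibscreen:::.empty_calls(), expr3, cna3,
                         stats::setNames(rep("TT", 20), samples))
  f3 <- apply_expression_filters(mk_res(samples[1:2]), cohort3)
  expect_false(samples[10] %in% f3$control_samples)
  expect_gt(f3$group_mean_fold, 5)
})

test_that("dropping the highest-TPM positive never raises the group mean fold", {
  ann <- split_ann()
  samples <- sprintf("TT_S%02d", 1:30)
  withr::with_seed(14, {
    for (k in 1:20) {
      tpm <- rlnorm(30, 2, 0.6); tpm[1:5] <- tpm[1:5] * 8
      cohort <- mk_cohort(uibscreen:::.empty_calls()[0], ann,
                          n_samples = 30, target = "T1", target_tpm = tpm)
      mk_res <- function(pos) structure(
        list(target_gene = "T1", mode = "UIB", tumor_type = "TT",
             samples = pos, distances = seq_along(pos),
             chosen_i = length(pos), positive_samples = pos,
             p_value = 0.01, n_splits_tested = length(pos),
             empirical_p = NA_real_, comparison = "rest"),
        class = "split_search_result")
      pos <- samples[1:5]
      top <- pos[which.max(cohort$expr["T1", pos])]
      f_all <- apply_expression_filters(mk_res(pos), cohort,
                                        min_case_fold = 0,
                                        min_mean_fold = 0)
      f_less <- apply_expression_filters(mk_res(setdiff(pos, top)), cohort,
                                         min_case_fold = 0,
                                         min_mean_fold = 0)
      expect_lte(f_less$group_mean_fold, f_all$group_mean_fold)
    }
  })
})

test_that("the cohort screen recovers a planted event and honours thresholds", {
  base_events <- function(n_pos, fold, n_amp = 0L) list(list(
    kind = "UIB_NCP", sv_type = "TRA", distance = 1.2e6,
    n_pos = n_pos, fold = fold, n_pos_amplified = n_amp))

  run <- function(seed, n_pos, fold, n_amp = 0L) {
    cfg <- sim_config(seed = seed, n_genes = 50, n_chroms = 2,
                      chrom_len = 2e7, n_samples = c(TT = 50L),
                      events = base_events(n_pos, fold, n_amp),
                      n_amplified_confounders = 1L)
    ann <- simulate_annotation(cfg)
    sim <- simulate_cohort(cfg, ann)
    list(sim = sim,
         events = screen_uib_dib(sim$cohort, ann, bands = sim$bands))
  }

  r <- run(31, n_pos = 4L, fold = 10)
  tgt <- r$sim$manifest$events[[1]]$target_gene
  expect_equal(r$events$events$target_gene, tgt)
  expect_equal(r$events$events$mode, "UIB")
  expect_equal(r$events$events$n_samples, 4L)
  expect_equal(r$events$events$cp_label, "N_CP")
  expect_gt(r$events$events$group_mean_fold, 5)
  expect_equal(sort(r$events$evidence$sample_id),
               sort(r$sim$manifest$events[[1]]$samples))

  # three positives never satisfy the >= 4-sample recurrence rule
  r3 <- run(32, n_pos = 3L, fold = 10)
  expect_equal(nrow(r3$events$events), 0L)

  # four positives with one amplified leave three survivors: dropped
  ra <- run(33, n_pos = 4L, fold = 10, n_amp = 1L)
  expect_equal(nrow(ra$events$events), 0L)
})

test_that("gene-gene recurrence keys are orientation-aware", {
  ann <- toy_ann()
  # GA -> GB junctions (GA "+" exits LEFT, GB "+" receives RIGHT)
  fwd <- function(s, id) mk_call("chrA", 30000, "LEFT", "chrB", 525000,
                                 "RIGHT", sample_id = s, call_id = id)
  # GB -> GA: reversed roles
  rev_ <- function(s, id) mk_call("chrA", 30000, "RIGHT", "chrB", 525000,
                                  "LEFT", sample_id = s, call_id = id)
  calls <- data.table::rbindlist(list(
    fwd("S1", "c1"), fwd("S2", "c2"), rev_("S3", "c3")))
  out <- screen_recurrent_gene_gene(calls, ann)
  expect_equal(nrow(out), 1L)
  expect_equal(out$pair_key, "GA->GB")
  expect_equal(out$n_samples, 2L)

  # a single shared sample is not recurrence
  out1 <- screen_recurrent_gene_gene(
    data.table::rbindlist(list(fwd("S1", "c1"), rev_("S1", "c2"))), ann)
  expect_equal(nrow(out1), 0L)
})

test_that("nearest-upstream-gene screen requires direction consistency", {
  ann <- toy_ann()
  # GE ("+", start 401001) has GD (end 351100) as nearest upstream gene:
  # candidate breakpoints must lie within 49,900 bp of GE's start
  near <- function(s, id) mk_call("chrB", 3e6, "LEFT", "chrA", 381001,
                                  "RIGHT", sample_id = s, call_id = id)
  far <- function(s, id) mk_call("chrB", 3e6, "LEFT", "chrA", 250000,
                                 "RIGHT", sample_id = s, call_id = id)
  samples <- sprintf("TT_S%02d", 1:30)

  tpm <- rep(10, 30); tpm[1:2] <- 60
  cohort <- mk_cohort(data.table::rbindlist(list(near("TT_S01", "c1"),
                                                 near("TT_S02", "c2"))),
                      ann, n_samples = 30, target = "GE",
                      target_tpm = tpm)
  out <- screen_nearest_gene(cohort, ann)
  expect_equal(out$target_gene, "GE")
  expect_equal(out$direction, "UP")
  expect_equal(out$n_samples, 2L)

  # inconsistent directions are dropped
  tpm2 <- rep(10, 30); tpm2[1] <- 60; tpm2[2] <- 1
  cohort2 <- mk_cohort(data.table::rbindlist(list(near("TT_S01", "c1"),
                                                  near("TT_S02", "c2"))),
                       ann, n_samples = 30, target = "GE",
                       target_tpm = tpm2)
  expect_equal(nrow(screen_nearest_gene(cohort2, ann)), 0L)

  # breakpoints beyond the nearest upstream gene do not qualify
  cohort3 <- mk_cohort(data.table::rbindlist(list(far("TT_S01", "c1"),
                                                  far("TT_S02", "c2"))),
                       ann, n_samples = 30, target = "GE",
                       target_tpm = tpm)
  expect_equal(nrow(screen_nearest_gene(cohort3, ann)), 0L)

  # consistent downregulation is reported with direction DOWN
  tpm4 <- rep(60, 30); tpm4[1:2] <- 5
  cohort4 <- mk_cohort(data.table::rbindlist(list(near("TT_S01", "c1"),
                                                  near("TT_S02", "c2"))),
                       ann, n_samples = 30, target = "GE",
                       target_tpm = tpm4)
  out4 <- screen_nearest_gene(cohort4, ann)
  expect_equal(out4$direction, "DOWN")
})

test_that("cohort_data validates sample consistency", {
  expr <- matrix(1, 2, 3, dimnames = list(c("g1", "g2"), c("a", "b", "c")))
  tt <- stats::setNames(rep("T", 3), c("a", "b", "c"))
  expect_error(cohort_data(uibscreen:::.empty_calls(), expr,
                           cna = matrix(0, 2, 2), tt))
  expect_error(cohort_data(uibscreen:::.empty_calls(), -expr, NULL, tt),
               "TPM")
  calls <- data.table::as.data.table(mk_call("c1", 1, "LEFT", "c1", 2,
                                             "RIGHT", sample_id = "zz"))
  expect_error(cohort_data(calls, expr, NULL, tt), "missing")
})
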