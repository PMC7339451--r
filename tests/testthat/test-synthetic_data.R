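# The seeded cohort simulator: determinism, geometry of planted events,
# expression arithmetic, fixture round trips.

small_cfg <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_genes = 40L, n_chroms = 2L, chrom_len = 2e7,
             n_samples = c(TT = 30L), ...)
}

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- small_cfg(seed = 5L)
  a1 <- simulate_annotation(cfg)
  a2 <- simulate_annotation(cfg)
  expect_equal(a1$genes, a2$genes)
  expect_equal(a1$exons, a2$exons)

  s1 <- simulate_cohort(cfg, a1)
  s2 <- simulate_cohort(cfg, a2)
  expect_equal(s1$cohort$calls, s2$cohort$calls)
  expect_equal(s1$cohort$expr, s2$cohort$expr)
  expect_equal(s1$manifest, s2$manifest)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixture_files(s1, a1, d1)
  write_fixture_files(s2, a2, d2)
  expect_identical(readLines(file.path(d1, "genes.gtf"))[-3],
                   readLines(file.path(d2, "genes.gtf"))[-3])  # date line
  expect_identical(readLines(file.path(d1, "expr.tsv")),
                   readLines(file.path(d2, "expr.tsv")))
})

test_that("the requested number of genes is emitted with valid structure", {
  cfg <- sim_config(seed = 2L, n_genes = 100L, n_chroms = 3L,
                    chrom_len = 3e7)
  ann <- simulate_annotation(cfg)
  expect_equal(nrow(ann$genes), 100L)
  # constructor invariants (non-overlap, CDS inside exons) held, plus
  # gene bodies do not overlap each other on a chromosome
  for (ch in names(ann$chrom_sizes)) {
    gsel <- which(ann$genes$chrom == ch)
    g <- ann$genes[gsel][order(start)]
    expect_true(all(g$start[-1L] > head(g$end, -1L)))
  }
})

test_that("first introns are systematically larger than later introns", {
  ratios <- sapply(1:8, function(s) {
    ann <- simulate_annotation(small_cfg(seed = s))
    ex <- merge(ann$exons, ann$genes[, c("gene_id", "strand")],
                by = "gene_id")
    data.table::setorder(ex, gene_id, exon_index)
    intr <- ex[, {
      # genomic-order intron sizes; the transcription-first intron is the
      # genomically last one for "-" genes
      gs <- sort(start); ge <- sort(end)
      if (.N > 1L) {
        sz <- gs[-1L] - ge[-.N] - 1L
        first_tx <- if (strand[1L] == "+") seq_along(sz) == 1L
        else seq_along(sz) == length(sz)
        list(size = sz, which_first = first_tx)
      } else list(size = integer(), which_first = logical())
    }, by = gene_id]
    mean(intr$size[intr$which_first]) / mean(intr$size[!intr$which_first])
  })
  expect_gt(mean(ratios > 1), 0.9)
  expect_gt(mean(ratios), 2)
})

test_that("planted events have concordant geometry and correct expression", {
  cfg <- small_cfg(seed = 8L, events = list(
    list(kind = "UIB_CP", sv_type = "TRA", distance = 2e4, n_pos = 4L,
         fold = 10),
    list(kind = "UIB_NCP", sv_type = "DEL", distance = 1.5e6, n_pos = 5L,
         fold = 8)))
  ann <- simulate_annotation(cfg)
  sim <- simulate_cohort(cfg, ann)
  co <- sim$cohort
  cand <- candidate_table(co$calls, ann)

  for (ev in sim$manifest$events) {
    tgt <- ev$target_gene
    # every planted sample carries a concordant candidate at the
    # manifest's distance
    hits <- cand[cand$target_gene == tgt & cand$mode == ev$mode &
                   cand$concordant]
    expect_true(all(ev$samples %in% hits$sample_id))
    for (k in seq_along(ev$samples))
      expect_true(ev$distances[k] %in%
                    hits$distance[hits$sample_id == ev$samples[k]])
    # planted folds with sigma 0.25 multiplicative noise: case TPM over
    # the control median stays within ~3 sigma of the planted fold
    ctl <- setdiff(colnames(co$expr), ev$samples)
    folds <- co$expr[tgt, ev$samples] / median(co$expr[tgt, ctl])
    expect_true(all(folds > ev$fold * 0.4 & folds < ev$fold * 2.5))
  }

  # CP events emit junction evidence at the model-predicted junction
  cp <- sim$manifest$events[[1L]]
  expect_equal(cp$expected_label, "CP")
  for (s in cp$samples) {
    sel <- which(co$calls$sample_id == s &
                   co$calls$sv_type == "TRA")
    found <- FALSE
    for (i in sel) {
      pred <- predict_chimera(co$calls[i], ann)
      if (is.null(pred) || pred$three_gene != cp$target_gene) next
      v <- verify_junction_support(pred, co$junctions)
      found <- found || v$verified
    }
    expect_true(found)
  }

  # N-CP events emit no junction evidence for their target
  ncp <- sim$manifest$events[[2L]]
  tgt_ex <- ann$exons[ann$exons$gene_id == ncp$target_gene]
  expect_false(any(co$junctions$acceptor_pos %in%
                     c(tgt_ex$start, tgt_ex$end)))
})

test_that("amplified confounders carry score 2 without any SV", {
  cfg <- small_cfg(seed = 9L, n_amplified_confounders = 2L)
  ann <- simulate_annotation(cfg)
  sim <- simulate_cohort(cfg, ann)
  amp <- sim$manifest$amplified_confounders
  tgt <- sim$manifest$events[[1L]]$target_gene
  expect_length(amp, 2L)
  expect_true(all(sim$cohort$cna[tgt, amp] == 2L))
  expect_false(any(amp %in% sim$manifest$events[[1L]]$samples))
})

test_that("germline events are mirrored in the panel of normals", {
  cfg <- small_cfg(seed = 10L)
  ann <- simulate_annotation(cfg)
  sim <- simulate_cohort(cfg, ann)
  expect_equal(nrow(sim$pon$calls), cfg$n_germline_events)
  # each PON event appears at identical coordinates in >= 1 tumor sample
  for (i in seq_len(nrow(sim$pon$calls))) {
    p <- sim$pon$calls[i]
    m <- sim$cohort$calls[sim$cohort$calls$chrom1 == p$chrom1 &
                            sim$cohort$calls$pos1 == p$pos1 &
                            sim$cohort$calls$pos2 == p$pos2]
    expect_gte(nrow(m), 1L)
  }
  # and the germline filter removes them
  s <- sim$cohort$calls$sample_id[1L]
  ssel <- which(sim$cohort$calls$sample_id == s)
  cs <- call_set(sim$cohort$calls[ssel], s, "HIGH")
  flt <- filter_germline_and_repeats(cs, pon = sim$pon,
                                     repeats = sim$repeats)
  counts <- attr(flt, "filter_counts")
  expect_gte(sum(counts), 1L)
})

test_that("fixture files round-trip the cohort exactly", {
  cfg <- small_cfg(seed = 12L)
  ann <- simulate_annotation(cfg)
  sim <- simulate_cohort(cfg, ann)
  d <- withr::local_tempdir()
  write_fixture_files(sim, ann, d)
  back <- read_cohort_dir(d)

  cols <- c("gene_id", "chrom", "strand", "start", "end", "cds_start",
            "cds_end")
  expect_equal(data.frame(back$ann$genes[, cols, with = FALSE]),
               data.frame(ann$genes[order(gene_id), cols, with = FALSE]))
  expect_equal(back$cohort$expr, sim$cohort$expr)
  expect_equal(back$cohort$cna, sim$cohort$cna)
  expect_equal(back$cohort$tumor_type, sim$cohort$tumor_type)
  key <- function(dt) do.call(paste, c(dt[, c("sample_id", "chrom1",
                                              "pos1", "side1", "chrom2",
                                              "pos2", "side2", "sv_type",
                                              "n_discordant", "n_split")],
                                       sep = "|"))
  expect_setequal(key(back$cohort$calls), key(sim$cohort$calls))
  expect_equal(data.table::setorder(back$cohort$junctions, sample_id,
                                    donor_pos),
               data.table::setorder(sim$cohort$junctions, sample_id,
                                    donor_pos))
  expect_equal(back$manifest$events$target_gene,
               sapply(sim$manifest$events, `[[`, "target_gene"))

  # BEDPE files are 0-based half-open: a written start is pos - 1
  s1 <- back$cohort$tumor_type[1]
  f <- file.path(d, "sv", paste0(names(s1), ".bedpe"))
  line1 <- strsplit(readLines(f, 1L), "\t")[[1L]]
  csel <- which(sim$cohort$calls$sample_id == names(s1))
  expect_equal(as.integer(line1[2L]) + 1L,
               sim$cohort$calls$pos1[csel][1L])
})

test_that("impossible planted geometry fails with a clear message", {
  cfg <- small_cfg(seed = 13L, events = list(
    list(kind = "UIB_NCP", sv_type = "TRA", distance = 4e6, n_pos = 40L,
         fold = 10)))
  ann <- simulate_annotation(cfg)
  # 40 positives exceed the 30 available samples
  expect_error(simulate_cohort(cfg, ann), "not enough unused samples")
})
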