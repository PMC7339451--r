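# The first-exon-skipping splicing model: junction geometry, frame/UTR
# status, and junction-evidence verification.
#
# toy_ann() coding arithmetic used below (1-based inclusive):
#   GA "+" exon1 UTR; exon2 coding 130 bp; exon3 coding 150 bp
#   GB "+" exon1 UTR; exon2 coding 150 bp; exon3 coding 250 bp
#   GC "+" exon1 coding 60 bp; exon2 200 bp; exon3 200 bp
#   GD "-" exon1(tx) coding 80 bp; exon2 150 bp; exon3 150 bp

test_that("UIB prediction joins A's last retained exon to B's exon 2", {
  ann <- toy_ann()
  call <- mk_call("chrA", 30000, "LEFT", "chrB", 501001 - 20000, "RIGHT")
  pred <- predict_chimera(call, ann)
  expect_s3_class(pred, "chimera_prediction")
  expect_equal(pred$mode, "UIB")
  expect_equal(pred$five_gene, "GA")
  expect_equal(pred$five_last_exon, 1L)
  expect_equal(pred$three_gene, "GB")
  expect_equal(pred$three_first_exon, 2L)   # exon 1 of B is skipped
  expect_equal(pred$donor_pos, 1200)        # 3' end of GA exon 1
  expect_equal(pred$acceptor_pos, 521001)   # 5' end of GB exon 2
  expect_equal(pred$uib_distance, 20000)
})

test_that("gene-gene prediction uses the first exon after B's breakpoint", {
  ann <- toy_ann()
  # GA intron 1 -> GB intron 2: acceptor must be GB exon 3
  call <- mk_call("chrA", 30000, "LEFT", "chrB", 525000, "RIGHT")
  pred <- predict_chimera(call, ann)
  expect_equal(pred$mode, "GENE_GENE")
  expect_equal(pred$five_last_exon, 1L)
  expect_equal(pred$three_first_exon, 3L)
  expect_equal(pred$acceptor_pos, 531001)
  expect_equal(pred$uib_distance, 0)
})

test_that("discordant, exonic or out-of-window configurations predict nothing", {
  ann <- toy_ann()
  # discordant orientation at the target side
  expect_null(predict_chimera(
    mk_call("chrA", 30000, "LEFT", "chrB", 501001 - 20000, "LEFT"), ann))
  # discordant at the 5' side
  expect_null(predict_chimera(
    mk_call("chrA", 30000, "RIGHT", "chrB", 501001 - 20000, "RIGHT"), ann))
  # exonic 5' breakpoint: the splicing model is undefined
  expect_null(predict_chimera(
    mk_call("chrA", 1100, "LEFT", "chrB", 501001 - 20000, "RIGHT"), ann))
  # UIB distance beyond the chimera window
  expect_null(predict_chimera(
    mk_call("chrA", 30000, "LEFT", "chrB", 501001 - 2e5, "RIGHT"), ann,
    chimera_window = 1e5))
  # intergenic-intergenic: no genic anchor
  expect_null(predict_chimera(
    mk_call("chrA", 2.5e6, "LEFT", "chrB", 501001 - 2e4, "RIGHT"), ann))
})

test_that("frame status reproduces the UTR and frame archetypes", {
  ann <- toy_ann()
  # A retains only its untranslated exon 1: the product is B's intact
  # protein driven by A's promoter
  p1 <- predict_chimera(
    mk_call("chrA", 30000, "LEFT", "chrB", 501001 - 20000, "RIGHT"), ann)
  expect_equal(frame_status(p1, ann), "FIVE_UTR_ONLY")

  # A contributes coding sequence but B's skipped exon 1 is pure 5' UTR:
  # B's ORF is intact from exon 2
  p2 <- predict_chimera(
    mk_call("chrA", 65000, "LEFT", "chrB", 501001 - 20000, "RIGHT"), ann)
  expect_equal(p2$five_last_exon, 2L)
  expect_equal(frame_status(p2, ann), "THREE_EXON1_UTR_ORF_INTACT")

  # GD (exons 1-2: 230 coding bp, 230 %% 3 == 2) joined to GC after its
  # intron 2 (skipped prefix 260 bp, 260 %% 3 == 2): in-frame
  p3 <- predict_chimera(
    mk_call("chrA", 320000, "RIGHT", "chrB", 825000, "RIGHT"), ann)
  expect_equal(p3$five_gene, "GD")
  expect_equal(p3$three_gene, "GC")
  expect_equal(p3$donor_pos, 341001)   # 3' end of GD exon 2 on "-"
  expect_equal(frame_status(p3, ann), "IN_FRAME")

  # GA exons 1-2 (130 %% 3 == 1) to GC exon 2 (skipped 60 %% 3 == 0)
  p4 <- predict_chimera(
    mk_call("chrA", 65000, "LEFT", "chrB", 801001 - 20000, "RIGHT"), ann)
  expect_equal(p4$three_gene, "GC")
  expect_equal(frame_status(p4, ann), "OUT_OF_FRAME")

  # non-coding partner
  p5 <- predict_chimera(
    mk_call("chrA", 405000, "LEFT", "chrB", 501001 - 20000, "RIGHT"), ann)
  expect_equal(p5$five_gene, "GE")
  expect_equal(frame_status(p5, ann), "NON_CODING")
})

test_that("mod-3 frame arithmetic matches a hand-built 301/1 case", {
  # A's retained exon 1 carries 301 coding bp; B's skipped exon 1 carries
  # exactly 1 coding bp: 301 %% 3 == 1 %% 3 -> in frame
  genes <- data.frame(
    gene_id = c("A1", "B1"), chrom = c("c1", "c2"), strand = "+",
    start = c(1001, 1e6 + 1), end = c(2400, 1e6 + 2300),
    cds_start = c(1100, 1e6 + 100), cds_end = c(2300, 1e6 + 2200))
  exons <- data.frame(
    gene_id = c("A1", "A1", "B1", "B1", "B1"),
    start = c(1001, 2001, 1e6 + 1, 1e6 + 1001, 1e6 + 2001),
    end = c(1400, 2400, 1e6 + 100, 1e6 + 1300, 1e6 + 2300))
  ann <- genome_annotation(genes, exons,
                           chrom_sizes = c(c1 = 1e7, c2 = 1e7))
  pred <- predict_chimera(
    mk_call("c1", 1700, "LEFT", "c2", 1e6 + 1 - 2e4, "RIGHT"), ann)
  expect_equal(pred$five_last_exon, 1L)
  expect_equal(pred$three_first_exon, 2L)
  expect_equal(frame_status(pred, ann), "IN_FRAME")

  # shift A's CDS start by one base: 300 %% 3 == 0 != 1 -> out of frame
  genes$cds_start[1] <- 1101
  ann2 <- genome_annotation(genes, exons,
                            chrom_sizes = c(c1 = 1e7, c2 = 1e7))
  pred2 <- predict_chimera(
    mk_call("c1", 1700, "LEFT", "c2", 1e6 + 1 - 2e4, "RIGHT"), ann2)
  expect_equal(frame_status(pred2, ann2), "OUT_OF_FRAME")
})

test_that("predictions are strand-consistent under genome mirroring", {
  ann <- toy_ann()
  L <- ann$chrom_sizes
  mirror_ann <- genome_annotation(
    transform(data.frame(ann$genes),
              start = L[chrom] + 1 - data.frame(ann$genes)$end,
              end = L[chrom] + 1 - data.frame(ann$genes)$start,
              cds_start = L[chrom] + 1 - data.frame(ann$genes)$cds_end,
              cds_end = L[chrom] + 1 - data.frame(ann$genes)$cds_start,
              strand = ifelse(data.frame(ann$genes)$strand == "+", "-", "+")),
    local({
      e <- merge(data.frame(ann$exons),
                 data.frame(ann$genes)[, c("gene_id", "chrom")])
      data.frame(gene_id = e$gene_id,
                 start = L[e$chrom] + 1 - e$end,
                 end = L[e$chrom] + 1 - e$start)
    }),
    chrom_sizes = L)
  call <- mk_call("chrA", 30000, "LEFT", "chrB", 501001 - 20000, "RIGHT")
  mcall <- mk_call("chrA", L["chrA"] + 1 - 30000, "RIGHT",
                   "chrB", L["chrB"] + 1 - (501001 - 20000), "LEFT")
  p <- predict_chimera(call, ann)
  mp <- predict_chimera(mcall, mirror_ann)
  expect_equal(mp$five_gene, p$five_gene)
  expect_equal(mp$three_gene, p$three_gene)
  expect_equal(mp$five_last_exon, p$five_last_exon)
  expect_equal(mp$three_first_exon, p$three_first_exon)
  expect_equal(mp$uib_distance, p$uib_distance)
  expect_equal(mp$donor_pos, unname(L["chrA"] + 1 - p$donor_pos))
  expect_equal(mp$acceptor_pos, unname(L["chrB"] + 1 - p$acceptor_pos))
  expect_equal(frame_status(mp, mirror_ann), frame_status(p, ann))
})

test_that("junction support counts reads at the exact splice sites", {
  ann <- toy_ann()
  pred <- predict_chimera(
    mk_call("chrA", 30000, "LEFT", "chrB", 501001 - 20000, "RIGHT"), ann)
  ev <- data.table::data.table(
    sample_id = "S1",
    chrom_donor = "chrA", donor_pos = 1200,
    chrom_acceptor = "chrB", acceptor_pos = 521001,
    read_count = 3L)
  expect_true(verify_junction_support(pred, ev)$verified)
  ev$read_count <- 2L
  v <- verify_junction_support(pred, ev)
  expect_false(v$verified)
  expect_equal(v$reads, 2L)
  # a 1-bp offset with zero tolerance contributes nothing
  ev$read_count <- 10L
  ev$donor_pos <- 1201
  expect_equal(verify_junction_support(pred, ev)$reads, 0L)
  expect_equal(verify_junction_support(pred, ev, tol = 1L)$reads, 10L)
  # reads from other samples never support this prediction
  ev$donor_pos <- 1200
  ev$sample_id <- "OTHER"
  expect_equal(verify_junction_support(pred, ev)$reads, 0L)
})
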