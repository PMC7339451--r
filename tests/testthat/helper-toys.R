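# Shared toy fixtures: small hand-placed annotations with known exon,
# intron and CDS arithmetic, plus builders for single calls and minimal
# cohorts. All coordinates 1-based inclusive.

# Five genes with distinct archetypes:
#  GA chrA "+"  exon1 entirely 5' UTR (CDS starts in exon 2), large first
#               intron (~60 kb)
#  GD chrA "-"  minus-strand coding gene (CDS spans all three exons)
#  GE chrA "+"  non-coding two-exon gene
#  GB chrB "+"  exon1 entirely 5' UTR (ETV4-like target)
#  GC chrB "+"  CDS starts inside exon 1 (RSPO3-like target)
toy_ann <- function() {
  genes <- data.frame(
    gene_id = c("GA", "GD", "GE", "GB", "GC"),
    chrom = c("chrA", "chrA", "chrA", "chrB", "chrB"),
    strand = c("+", "-", "+", "+", "+"),
    start = c(1001, 301001, 401001, 501001, 801001),
    end = c(71200, 351100, 411100, 531300, 831240),
    cds_start = c(61021, 301051, NA, 521051, 801041),
    cds_end = c(71150, 351080, NA, 531250, 831200))
  exons <- data.frame(
    gene_id = c("GA", "GA", "GA",
                "GD", "GD", "GD",
                "GE", "GE",
                "GB", "GB", "GB",
                "GC", "GC", "GC"),
    start = c(1001, 61001, 71001,
              301001, 341001, 351001,
              401001, 411001,
              501001, 521001, 531001,
              801001, 821001, 831001),
    end = c(1200, 61150, 71200,
            301200, 341150, 351100,
            401100, 411100,
            501150, 521200, 531300,
            801100, 821200, 831240))
  genome_annotation(genes, exons,
                    chrom_sizes = c(chrA = 5e6, chrB = 9e6))
}

# one-row call as a list; sides default to a junction that reads
# sense-to-sense into a "+" target approached from upstream
mk_call <- function(chrom1, pos1, side1, chrom2, pos2, side2,
                    sv_type = "TRA", sample_id = "S1", call_id = "c1") {
  list(sample_id = sample_id, call_id = call_id,
       chrom1 = chrom1, pos1 = pos1, side1 = side1,
       chrom2 = chrom2, pos2 = pos2, side2 = side2,
       sv_type = sv_type, n_discordant = 10L, n_split = 5L,
       coverage_tier = "HIGH")
}

# minimal cohort: one tumor type, explicit calls table and expression
# for a single screened gene (other genes at baseline 10)
mk_cohort <- function(calls, ann, n_samples = 56L, target = NULL,
                      target_tpm = NULL, baseline = 10,
                      tumor = "TT", cna = NULL, junctions = NULL) {
  samples <- sprintf("%s_S%02d", tumor, seq_len(n_samples))
  genes <- ann$genes$gene_id
  expr <- matrix(baseline, length(genes), n_samples,
                 dimnames = list(genes, samples))
  if (!is.null(target)) {
    stopifnot(length(target_tpm) <= n_samples)
    expr[target, seq_along(target_tpm)] <- target_tpm
  }
  calls <- data.table::as.data.table(calls)
  if (nrow(calls) && !all(calls$sample_id %in% samples))
    stop("mk_cohort: call sample ids must be among ", samples[1], "...")
  if (!nrow(calls)) calls <- uibscreen:::.empty_calls()
  if (!"call_id" %in% names(calls) || anyNA(calls$call_id))
    calls$call_id <- sprintf("c%03d", seq_len(nrow(calls)))
  if (!"coverage_tier" %in% names(calls)) calls$coverage_tier <- "HIGH"
  cohort_data(calls, expr, cna,
              tumor_type = stats::setNames(rep(tumor, n_samples), samples),
              junctions = junctions)
}

# independent linear-scan annotation oracle used against annotate_position
oracle_annotate <- function(ann, chrom, pos) {
  hits <- list()
  for (i in seq_len(nrow(ann$genes))) {
    g <- ann$genes[i]
    if (g$chrom != chrom || pos < g$start || pos > g$end) next
    ex <- ann$exons[ann$exons$gene_id == g$gene_id]
    in_ex <- which(pos >= ex$start & pos <= ex$end)
    if (length(in_ex)) {
      hits[[length(hits) + 1L]] <- list(gene = g$gene_id, element = "EXON",
                                        index = ex$exon_index[in_ex[1L]])
    } else {
      idx <- if (g$strand == "+") sum(ex$end < pos) else sum(ex$start > pos)
      hits[[length(hits) + 1L]] <- list(gene = g$gene_id,
                                        element = "INTRON", index = idx)
    }
  }
  hits
}
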