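# uibscreen

Joint interpretation of tumor structural-variant (SV) calls and matched
expression data, focused on fusions with **intergenic breakpoints** —
the majority of somatic SV junctions, which conventional gene-gene
fusion analysis sets aside.

`uibscreen` is for cancer genomicists with per-sample WGS SV call sets
(BEDPE), a gene×sample TPM matrix, and discrete copy-number scores who
want to know:

* which fusions are gene-gene, gene-intergenic or
  intergenic-intergenic, and whether gene-gene junctions are
  over-represented relative to a uniform-breakpoint null
  (expected fraction `f²` for genic fraction `f`);
* which **gene-intergenic** fusions produce chimeric mRNAs through the
  first-exon-skipping splicing model: an intronic breakpoint in a 5′
  gene A joined sense-to-sense to a breakpoint upstream of a 3′ gene B
  splices A's last retained exon onto **B's exon 2**, skipping B's exon
  1 (which has no splice-acceptor signal ahead of it) — with frame/UTR
  status (`FIVE_UTR_ONLY`, `THREE_EXON1_UTR_ORF_INTACT`, `IN_FRAME`,
  `OUT_OF_FRAME`, `NON_CODING`) and verification against RNA
  split-read junction evidence (≥ 3 reads);
* which genes are recurrently upregulated by upstream- or
  downstream-intergenic breakpoints (UIB/DIB, up to 4 Mb away): for
  each target the distance-ordered breakpoints `S₁ ≤ … ≤ Sₙ` are
  scanned over all prefix groups `S₁..Sᵢ` with a Wilcoxon rank-sum
  test of target expression, the minimum-p group is kept, and events
  must then survive per-case (> 4×) and group-mean (> 5×) fold filters
  with copy-number-amplified samples excluded — recurrence in ≥ 4
  samples, labelled CP/N-CP by junction-verified chimera predictions.

A fully seeded cohort simulator (annotation with enlarged first
introns, planted UIB/DIB/gene-gene events, log-normal expression noise,
amplified confounders, germline/panel-of-normals events, repeats,
junction evidence, ground-truth manifest) makes the entire pipeline
testable without controlled-access human data.

## Worked example

Simulate a 60-sample cohort with four planted events, apply the ingest
filters, and run the screens:

```r
library(uibscreen)

cfg <- sim_config(seed = 42)
ann <- simulate_annotation(cfg)
sim <- simulate_cohort(cfg, ann)
co  <- filter_cohort(sim$cohort, pon = sim$pon, repeats = sim$repeats)

ann
#> genome_annotation: 90 genes on 3 chromosomes; 575 exons (canonical transcripts)
sim
#> sim_cohort (seed 42 ): 4 planted events; 209 raw calls; 60 samples

pr <- class_proportions(co, ann)
round(unclass(pr$fractions), 3)
#>             GENE_GENE       GENE_INTERGENIC INTERGENIC_INTERGENIC
#>                 0.027                 0.068                 0.904
```

With only 2.4% of this toy genome genic, almost all junctions are
intergenic-intergenic — and the planted gene-gene events still make the
gene-gene class over-represented (`pr$p_value` ≈ 8e-4 against the
`f² ≈ 0.0006` null). The recurrence screen recovers exactly the three
planted UIB/DIB events, with the chimera-producing one labelled CP:

```r
sc <- screen_uib_dib(co, ann, bands = sim$bands)
sc$events[, c("target_gene", "mode", "n_samples", "p_value",
              "group_mean_fold", "cp_label", "dist_mean")]
#>    target_gene   mode n_samples     p_value group_mean_fold cp_label  dist_mean
#> 1:        G051    UIB         4 0.000952214       26.458965       CP   16730.75
#> 2:        G033    DIB         4 0.000952214        7.338902     N_CP  691456.50
#> 3:        G069    UIB         6 0.006281592        9.411829     N_CP 1047927.83
```

Reading the first row: target `G051` is upregulated 26-fold (group mean
over control mean) in 4 samples whose upstream intergenic breakpoints
sit ~17 kb from the gene, and at least one sample carries a
junction-verified chimeric transcript (CP) — the planted 25-fold
chimera-producing event. The 8- and 10-fold non-chimera events are
recovered at 0.7–1 Mb mean breakpoint distance. The planted recurrent
gene-gene pair is found by its own screen:

```r
screen_recurrent_gene_gene(co, ann)
#>      pair_key five_gene three_gene oriented n_samples               samples
#> 1: G083->G031      G083       G031     TRUE         2 COHORT_S19,COHORT_S24
```

`predict_chimera()`, `frame_status()` and `verify_junction_support()`
expose the splicing model for single calls; `run_pipeline()` (or the
thin CLI in `inst/scripts/uibscreen.R`) chains ingest → classify →
chimera → screen over a fixture directory and writes TSV/JSON outputs
with a config-hashed run manifest.

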