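# Seeded synthetic cohorts: genome annotation, SV call sets with planted
# UIB/DIB and gene-gene events, log-normal expression with planted fold
# effects, GISTIC-style amplified confounders, germline/panel-of-normals
# events, repeat regions, cytobands, and a ground-truth manifest.

#' Simulation configuration
#'
#' Defaults describe a compact cohort with the regimes the screens are
#' designed for: multi-exon genes with enlarged first introns, planted
#' fusion events with fold effects from ~8x to ~25x at UIB distances from
#' tens of kb (chimera-producing) to megabases (non-chimera-producing),
#' log-normal expression noise, amplified confounders and germline events.
#'
#' @param seed integer seed; every simulated structure derives from it.
#' @param n_chroms,chrom_len genome shape (default 3 x 30 Mb).
#' @param n_genes number of genes (default 90).
#' @param n_exons_range inclusive range of exon counts per gene.
#' @param exon_meanlog,exon_sdlog log-normal exon width law (bp).
#' @param intron_meanlog,intron_sdlog log-normal intron width law (bp).
#' @param first_intron_scale multiplier on the first intron width
#'   (default 4: first introns are systematically larger).
#' @param utr_first_exon_frac fraction of coding genes whose first exon is
#'   entirely untranslated.
#' @param noncoding_frac fraction of genes without a CDS.
#' @param n_samples named integer vector: samples per tumor type.
#' @param baseline_meanlog,baseline_sdlog per-gene baseline TPM law.
#' @param noise_sdlog log-normal expression noise sigma (default 0.25).
#' @param events list of planted events; each a list with `kind` in
#'   `UIB_CP`, `UIB_NCP`, `DIB_NCP`, `GENE_GENE`, plus `sv_type`,
#'   `distance` (bp, UIB/DIB kinds), `n_pos`, `fold`, and optionally
#'   `target`, `tumor_type`, `n_pos_amplified`.
#' @param n_amplified_confounders samples given a copy-number score of 2
#'   and elevated expression of the first event's target, without any SV.
#' @param amplified_fold expression multiplier for amplified confounders.
#' @param n_germline_events events present in tumor call sets and in the
#'   panel of normals.
#' @param n_background_svs expected random somatic SVs per sample. The
#'   default of 1 reproduces, on the default 60 Mb toy genome, the
#'   breakpoint density of real tumor WGS cohorts (roughly 50 SVs per
#'   3 Gb genome, i.e. ~0.017 SV/Mb/sample).
#' @param repeat_fraction fraction of the genome covered by repeats.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chroms = 3L, chrom_len = 3e7,
                       n_genes = 90L, n_exons_range = c(3L, 10L),
                       exon_meanlog = log(150), exon_sdlog = 0.4,
                       intron_meanlog = log(2000), intron_sdlog = 0.8,
                       first_intron_scale = 4,
                       utr_first_exon_frac = 0.35, noncoding_frac = 0.1,
                       n_samples = c(COHORT = 60L),
                       baseline_meanlog = 3, baseline_sdlog = 1,
                       noise_sdlog = 0.25,
                       events = default_events(),
                       n_amplified_confounders = 2L, amplified_fold = 8,
                       n_germline_events = 5L, n_background_svs = 1,
                       repeat_fraction = 0.05) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_genes > 0, cfg$chrom_len > 0, cfg$n_chroms > 0,
            all(unlist(n_samples) > 0))
  for (ev in cfg$events)
    if (ev$kind %in% c("UIB_CP", "UIB_NCP", "DIB_NCP") &&
        (is.null(ev$distance) || ev$distance > 4e6))
      stop("UIB/DIB planted events need a distance <= 4 Mb")
  class(cfg) <- "sim_config"
  cfg
}

#' Default planted events
#'
#' One chimera-producing UIB event at short range (20 kb, 25-fold), one
#' long-range non-chimera UIB event (1.5 Mb, 10-fold), one DIB event
#' (1 Mb, 8-fold) and one recurrent gene-gene fusion.
#'
#' @return list of event specifications for [sim_config()].
#' @export
default_events <- function() {
  list(
    list(kind = "UIB_CP", sv_type = "TRA", distance = 2e4, n_pos = 4L,
         fold = 25),
    list(kind = "UIB_NCP", sv_type = "DEL", distance = 1.5e6, n_pos = 6L,
         fold = 10),
    list(kind = "DIB_NCP", sv_type = "TDUP", distance = 1e6, n_pos = 4L,
         fold = 8),
    list(kind = "GENE_GENE", sv_type = "TRA", n_pos = 2L, fold = 5))
}

# transcript-coordinate -> genomic position for an exon set (ascending
# genomic order), walking in transcription order for the given strand
.tx2genomic <- function(ex_starts, ex_ends, strand, tx_pos) {
  widths <- ex_ends - ex_starts + 1
  if (strand == "+") {
    cum <- cumsum(widths)
    i <- which(tx_pos <= cum)[1L]
    off <- tx_pos - (if (i > 1L) cum[i - 1L] else 0)
    ex_starts[i] + off - 1
  } else {
    ord <- rev(seq_along(widths))
    cum <- cumsum(widths[ord])
    i <- which(tx_pos <= cum)[1L]
    off <- tx_pos - (if (i > 1L) cum[i - 1L] else 0)
    ex_ends[ord[i]] - off + 1
  }
}

#' Simulate a genome annotation
#'
#' Non-overlapping multi-exon genes with log-normal exon and intron
#' widths, enlarged first introns, a configurable fraction of genes with
#' fully untranslated first exons (so that every frame status of the
#' chimera model occurs), and CDS lengths that are multiples of 3.
#' Deterministic under `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return A [genome_annotation()].
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
    per_chrom <- rep(floor(cfg$n_genes / cfg$n_chroms), cfg$n_chroms)
    per_chrom[seq_len(cfg$n_genes - sum(per_chrom))] <-
      per_chrom[seq_len(max(0L, cfg$n_genes - sum(per_chrom)))] + 1L
    genes <- list(); exons <- list(); gi <- 0L
    for (ci in seq_len(cfg$n_chroms)) {
      ng <- per_chrom[ci]
      if (ng == 0L) next
      # draw structures first, then place with random gaps
      structs <- lapply(seq_len(ng), function(i) {
        ne <- sample(seq(cfg$n_exons_range[1L], cfg$n_exons_range[2L]), 1L)
        ew <- pmax(30, round(stats::rlnorm(ne, cfg$exon_meanlog,
                                           cfg$exon_sdlog)))
        iw <- pmax(100, round(stats::rlnorm(max(ne - 1L, 0L),
                                            cfg$intron_meanlog,
                                            cfg$intron_sdlog)))
        strand <- sample(c("+", "-"), 1L)
        if (length(iw)) {
          # the first intron in transcription order is enlarged
          fi <- if (strand == "+") 1L else length(iw)
          iw[fi] <- round(iw[fi] * cfg$first_intron_scale)
        }
        list(ew = ew, iw = iw, strand = strand, len = sum(ew) + sum(iw))
      })
      total <- sum(vapply(structs, `[[`, 0, "len"))
      margin <- 1e5
      min_gap <- 1e4
      avail <- cfg$chrom_len - 2 * margin - total - ng * min_gap
      if (avail <= 0)
        stop("genes do not fit on ", chroms[ci],
             ": increase chrom_len or reduce n_genes/intron sizes")
      w <- stats::runif(ng)
      gaps <- min_gap + avail * w / sum(w)
      pos <- margin
      for (i in seq_len(ng)) {
        pos <- round(pos + gaps[i])
        st <- structs[[i]]
        gi <- gi + 1L
        gid <- sprintf("G%03d", gi)
        ne <- length(st$ew)
        ex_starts <- integer(ne); ex_ends <- integer(ne)
        p <- pos
        for (e in seq_len(ne)) {
          ex_starts[e] <- p
          ex_ends[e] <- p + st$ew[e] - 1L
          p <- ex_ends[e] + (if (e < ne) st$iw[e] else 0L) + 1L
        }
        g_start <- ex_starts[1L]; g_end <- ex_ends[ne]
        cds_start <- NA_real_; cds_end <- NA_real_
        if (stats::runif(1L) > cfg$noncoding_frac && ne >= 2L) {
          tx_len <- sum(st$ew)
          # exon widths in transcription order
          ew_t <- if (st$strand == "+") st$ew else rev(st$ew)
          utr_first <- stats::runif(1L) < cfg$utr_first_exon_frac
          cds_from <- if (utr_first) ew_t[1L] + 1L +
            sample.int(max(ew_t[2L] - 10L, 1L), 1L) - 1L
          else sample.int(max(floor(ew_t[1L] * 0.8), 1L), 1L)
          utr3 <- sample(5:40, 1L)
          cds_to <- tx_len - utr3
          if (cds_to <= cds_from + 8L) cds_to <- min(tx_len, cds_from + 9L)
          cds_to <- cds_from + (floor((cds_to - cds_from + 1L) / 3L) * 3L) - 1L
          if (cds_to > cds_from) {
            gpos <- c(.tx2genomic(ex_starts, ex_ends, st$strand, cds_from),
                      .tx2genomic(ex_starts, ex_ends, st$strand, cds_to))
            cds_start <- min(gpos); cds_end <- max(gpos)
          }
        }
        genes[[gi]] <- data.table::data.table(
          gene_id = gid, chrom = chroms[ci], strand = st$strand,
          start = g_start, end = g_end,
          cds_start = cds_start, cds_end = cds_end)
        exons[[gi]] <- data.table::data.table(
          gene_id = gid, start = ex_starts, end = ex_ends)
        pos <- p
      }
    }
    genome_annotation(
      data.table::rbindlist(genes), data.table::rbindlist(exons),
      chrom_sizes = stats::setNames(rep(cfg$chrom_len, cfg$n_chroms),
                                    chroms))
  })
}

# equal-width cytobands (4 p + 4 q per chromosome), 0-based half-open
.simulate_cytobands <- function(cfg) {
  bands <- lapply(sprintf("chr%d", seq_len(cfg$n_chroms)), function(ch) {
    bounds <- round(seq(0, cfg$chrom_len, length.out = 9L))
    data.table::data.table(
      chrom = ch, start = bounds[-9L], end = bounds[-1L],
      band = c(paste0("p", 4:1), paste0("q", 1:4)),
      stain = rep(c("gneg", "gpos50"), 4L))
  })
  cytoband_map(data.table::rbindlist(bands))
}

.simulate_repeats <- function(cfg) {
  n_per_chrom <- max(1L, round(cfg$repeat_fraction * cfg$chrom_len / 2e4))
  reps <- lapply(sprintf("chr%d", seq_len(cfg$n_chroms)), function(ch) {
    starts <- sort(sample.int(cfg$chrom_len - 6e4, n_per_chrom))
    widths <- sample(5e3:3e4, n_per_chrom, replace = TRUE)
    data.table::data.table(chrom = ch, start = starts,
                           end = pmin(starts + widths, cfg$chrom_len))
  })
  out <- data.table::rbindlist(reps)
  data.table::setkey(out, chrom, start, end)
  out
}

.is_intergenic_pos <- function(ann, chrom, pos) {
  g <- ann$genes
  !any(g$chrom == chrom & g$start <= pos & g$end >= pos)
}

.random_intergenic <- function(ann, chrom, n_try = 200L) {
  size <- ann$chrom_sizes[[chrom]]
  for (i in seq_len(n_try)) {
    p <- sample.int(size - 2L, 1L) + 1L
    if (.is_intergenic_pos(ann, chrom, p)) return(p)
  }
  stop("could not place an intergenic position on ", chrom)
}

# sides of an intra-chromosomal adjacency for each SV type, ordered
# (lower position, higher position)
.type_sides <- list(DEL = c("LEFT", "RIGHT"), TDUP = c("RIGHT", "LEFT"),
                    INV = c("LEFT", "LEFT"))

# realized SV type from geometry
.realized_type <- function(chrom1, pos1, side1, chrom2, pos2, side2) {
  if (chrom1 != chrom2) return("TRA")
  lo_side <- if (pos1 <= pos2) side1 else side2
  hi_side <- if (pos1 <= pos2) side2 else side1
  if (lo_side == "LEFT" && hi_side == "RIGHT") "DEL"
  else if (lo_side == "RIGHT" && hi_side == "LEFT") "TDUP"
  else "INV"
}

# target-side breakend for a UIB/DIB event (position and concordant side)
.target_breakend <- function(ann, g, mode, d) {
  if (mode == "UIB") {
    if (g$strand == "+") list(pos = g$start - d, side = "RIGHT")
    else list(pos = g$end + d, side = "LEFT")
  } else {
    if (g$strand == "+") list(pos = g$end + d, side = "LEFT")
    else list(pos = g$start - d, side = "RIGHT")
  }
}

#' Simulate a cohort over a simulated annotation
#'
#' Generates per-sample SV call sets realizing each planted event with
#' junction-orientation-concordant breakends, a TPM matrix with planted
#' fold effects and log-normal noise, a GISTIC-style copy-number matrix
#' with amplified confounders, RNA junction evidence for
#' chimera-producing events (>= 3 supporting reads at the spliced
#' junction), germline events mirrored in a panel of normals, repeat
#' regions, background SVs, and a ground-truth manifest. Deterministic
#' under `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param ann annotation from [simulate_annotation()].
#' @return list of class `sim_cohort` with elements `cohort`
#'   (a [cohort_data()], raw unfiltered calls), `pon` (a [call_set()]),
#'   `repeats`, `bands`, `manifest`, `cfg`.
#' @export
simulate_cohort <- function(cfg, ann) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed((cfg$seed + 1L) %% .Machine$integer.max, {
    types <- names(cfg$n_samples)
    samples <- unlist(lapply(types, function(tt)
      sprintf("%s_S%02d", tt, seq_len(cfg$n_samples[[tt]]))))
    tumor_type <- stats::setNames(
      rep(types, times = unlist(cfg$n_samples)), samples)
    genes <- ann$genes$gene_id
    ng <- length(genes); ns <- length(samples)

    baseline <- stats::rlnorm(ng, cfg$baseline_meanlog, cfg$baseline_sdlog)
    expr <- matrix(stats::rlnorm(ng * ns, 0, cfg$noise_sdlog), ng, ns) *
      baseline
    dimnames(expr) <- list(genes, samples)
    cna <- matrix(0L, ng, ns, dimnames = dimnames(expr))

    n_ex <- ann$exons[, .(n = max(exon_index)), by = gene_id]
    coding <- ann$genes[!is.na(cds_start), gene_id]
    eligible_target <- intersect(coding, n_ex[n >= 3L, gene_id])

    calls <- list(); junctions <- list(); manifest_events <- list()
    used_targets <- character(); used_samples <- character()

    add_call <- function(s, c1, p1, sd1, c2, p2, sd2, svt = NA, dp = NULL,
                         sr = NULL) {
      calls[[length(calls) + 1L]] <<- list(
        sample_id = s, chrom1 = c1, pos1 = as.integer(p1), side1 = sd1,
        chrom2 = c2, pos2 = as.integer(p2), side2 = sd2,
        sv_type = if (is.na(svt)) .realized_type(c1, p1, sd1, c2, p2, sd2)
        else svt,
        n_discordant = if (is.null(dp)) sample(6:15, 1L) else dp,
        n_split = if (is.null(sr)) sample(2:8, 1L) else sr)
    }

    for (ei in seq_along(cfg$events)) {
      ev <- cfg$events[[ei]]
      tt <- if (!is.null(ev$tumor_type)) ev$tumor_type else types[1L]
      ts <- samples[tumor_type == tt]
      avail <- setdiff(ts, used_samples)
      if (length(avail) < ev$n_pos)
        stop("planted event ", ei, " (", ev$kind,
             "): not enough unused samples of type ", tt)
      pos_samples <- sort(sample(avail, ev$n_pos))
      used_samples <- c(used_samples, pos_samples)

      if (ev$kind == "GENE_GENE") {
        pool <- setdiff(eligible_target, used_targets)
        gb_id <- if (!is.null(ev$target)) ev$target else sample(pool, 1L)
        ga_id <- sample(setdiff(intersect(coding, n_ex[n >= 2L, gene_id]),
                                c(gb_id, used_targets)), 1L)
        used_targets <- c(used_targets, ga_id, gb_id)
        ga <- ann$genes[gene_id == ga_id]; gb <- ann$genes[gene_id == gb_id]
        exa <- ann$exons[.(ga_id)]; exb <- ann$exons[.(gb_id)]
        # A breakpoint in intron 1, B in intron 1 (transcription order)
        int1 <- function(g, ex) {
          e1 <- ex[exon_index == 1L]; e2 <- ex[exon_index == 2L]
          if (g$strand == "+") c(e1$end + 1L, e2$start - 1L)
          else c(e2$end + 1L, e1$start - 1L)
        }
        ia <- int1(ga, exa); ib <- int1(gb, exb)
        side_a <- if (ga$strand == "+") "LEFT" else "RIGHT"
        side_b <- if (gb$strand == "+") "RIGHT" else "LEFT"
        dists <- integer(ev$n_pos)
        for (si in seq_along(pos_samples)) {
          s <- pos_samples[si]
          pa <- sample(seq(ia[1L], ia[2L]), 1L)
          pb <- sample(seq(ib[1L], ib[2L]), 1L)
          add_call(s, ga$chrom, pa, side_a, gb$chrom, pb, side_b)
          # spliced junction: A exon 1 3' end -> B exon 2 5' end
          junctions[[length(junctions) + 1L]] <- data.table::data.table(
            sample_id = s,
            chrom_donor = ga$chrom,
            donor_pos = if (ga$strand == "+") exa[exon_index == 1L, end]
            else exa[exon_index == 1L, start],
            chrom_acceptor = gb$chrom,
            acceptor_pos = if (gb$strand == "+") exb[exon_index == 2L, start]
            else exb[exon_index == 2L, end],
            read_count = sample(3:10, 1L))
        }
        expr[gb_id, pos_samples] <- expr[gb_id, pos_samples] * ev$fold
        manifest_events[[ei]] <- list(
          event_id = sprintf("E%02d", ei), kind = ev$kind,
          mode = "GENE_GENE", target_gene = gb_id, partner = ga_id,
          tumor_type = tt, fold = ev$fold, samples = pos_samples,
          distances = rep(0, ev$n_pos), expected_label = "CP")
        next
      }

      mode <- if (startsWith(ev$kind, "UIB")) "UIB" else "DIB"
      # target must leave room for the breakend inside the chromosome and
      # the breakend must land intergenic
      pick_target <- function() {
        pool <- if (!is.null(ev$target)) ev$target
        else sample(setdiff(eligible_target, used_targets))
        for (gid in pool) {
          g <- ann$genes[gene_id == gid]
          tb <- .target_breakend(ann, g, mode, ev$distance)
          if (tb$pos < 1 || tb$pos > ann$chrom_sizes[[g$chrom]]) next
          return(gid)
        }
        stop("planted event ", ei, " (", ev$kind,
             "): no gene admits a ", mode, " breakend at distance ",
             ev$distance)
      }
      tg_id <- pick_target()
      used_targets <- c(used_targets, tg_id)
      tg <- ann$genes[gene_id == tg_id]

      partner_gene <- NULL
      if (ev$kind == "UIB_CP") {
        pool <- setdiff(intersect(coding, n_ex[n >= 2L, gene_id]),
                        c(tg_id, used_targets))
        if (!is.null(ev$sv_type) && ev$sv_type == "TRA")
          pool <- intersect(pool,
                            ann$genes[chrom != tg$chrom, gene_id])
        partner_gene <- sample(pool, 1L)
        used_targets <- c(used_targets, partner_gene)
      }

      dists <- numeric(ev$n_pos)
      for (si in seq_along(pos_samples)) {
        s <- pos_samples[si]
        d <- NA_real_
        for (try in 1:200) {
          d_try <- max(1000, round(ev$distance * stats::runif(1L, 0.5, 1)))
          tb <- .target_breakend(ann, tg, mode, d_try)
          if (tb$pos >= 1 && tb$pos <= ann$chrom_sizes[[tg$chrom]] &&
              .is_intergenic_pos(ann, tg$chrom, tb$pos)) {
            d <- d_try; break
          }
        }
        if (is.na(d))
          stop("planted event ", ei, ": cannot place an intergenic ",
               mode, " breakend near ", tg_id)
        dists[si] <- d
        tb <- .target_breakend(ann, tg, mode, d)

        if (ev$kind == "UIB_CP") {
          pg <- ann$genes[gene_id == partner_gene]
          exp_ <- ann$exons[.(partner_gene)]
          e1 <- exp_[exon_index == 1L]; e2 <- exp_[exon_index == 2L]
          intr <- if (pg$strand == "+") c(e1$end + 1L, e2$start - 1L)
          else c(e2$end + 1L, e1$start - 1L)
          pp <- sample(seq(intr[1L], intr[2L]), 1L)
          side_p <- if (pg$strand == "+") "LEFT" else "RIGHT"
          add_call(s, pg$chrom, pp, side_p, tg$chrom, tb$pos, tb$side,
                   svt = if (pg$chrom != tg$chrom) "TRA" else NA)
          junctions[[length(junctions) + 1L]] <- data.table::data.table(
            sample_id = s,
            chrom_donor = pg$chrom,
            donor_pos = if (pg$strand == "+") e1$end else e1$start,
            chrom_acceptor = tg$chrom,
            acceptor_pos = ann$exons[.(tg_id)][exon_index == 2L,
                                               if (tg$strand == "+") start else end],
            read_count = sample(3:10, 1L))
        } else {
          # non-chimera-producing: intergenic partner breakend, kept out
          # of the target's own 4 Mb search region so that the manifest
          # fully describes the breakpoints near the target
          svt <- if (!is.null(ev$sv_type)) ev$sv_type else "TRA"
          placed <- FALSE
          if (svt != "TRA") {
            sides <- .type_sides[[svt]]
            # the adjacency pattern fixes which side of the target
            # breakend the partner must sit on
            dir_ <- if (tb$side == sides[2L]) -1 else 1
            side_p <- if (dir_ < 0) sides[1L] else sides[2L]
            excl_lo <- tg$start - 4e6 - 1e5
            excl_hi <- tg$end + 4e6 + 1e5
            for (try2 in 1:200) {
              pp <- tb$pos + dir_ * round(stats::runif(1L, 5e6, 9e6))
              if (pp < 1 || pp > ann$chrom_sizes[[tg$chrom]]) next
              if (pp >= excl_lo && pp <= excl_hi) next
              if (!.is_intergenic_pos(ann, tg$chrom, pp)) next
              add_call(s, tg$chrom, pp, side_p, tg$chrom, tb$pos,
                       tb$side, svt = svt)
              placed <- TRUE
              break
            }
          }
          if (!placed) {   # translocation partner on another chromosome
            other <- sample(setdiff(names(ann$chrom_sizes), tg$chrom), 1L)
            pp <- .random_intergenic(ann, other)
            add_call(s, other, pp, sample(c("LEFT", "RIGHT"), 1L),
                     tg$chrom, tb$pos, tb$side, svt = "TRA")
          }
        }
      }
      n_amp <- if (!is.null(ev$n_pos_amplified)) ev$n_pos_amplified else 0L
      if (n_amp > 0L)
        cna[tg_id, pos_samples[seq_len(min(n_amp, ev$n_pos))]] <- 2L
      expr[tg_id, pos_samples] <- expr[tg_id, pos_samples] * ev$fold
      manifest_events[[ei]] <- list(
        event_id = sprintf("E%02d", ei), kind = ev$kind, mode = mode,
        target_gene = tg_id,
        partner = if (!is.null(partner_gene)) partner_gene else "intergenic",
        tumor_type = tt, fold = ev$fold, samples = pos_samples,
        distances = dists,
        expected_label = if (ev$kind == "UIB_CP") "CP" else "N_CP")
    }

    # amplified confounders: no SV, score-2 amplification + elevated TPM
    amp_samples <- character()
    if (cfg$n_amplified_confounders > 0L && length(manifest_events)) {
      tg0 <- manifest_events[[1L]]$target_gene
      pool <- setdiff(samples, used_samples)
      amp_samples <- sort(sample(pool, min(cfg$n_amplified_confounders,
                                           length(pool))))
      cna[tg0, amp_samples] <- 2L
      expr[tg0, amp_samples] <- expr[tg0, amp_samples] * cfg$amplified_fold
    }

    repeats <- .simulate_repeats(cfg)
    bands <- .simulate_cytobands(cfg)

    # germline events: identical coordinates in some tumor samples + PON
    pon_rows <- list()
    chroms <- names(ann$chrom_sizes)
    for (gi in seq_len(cfg$n_germline_events)) {
      ch <- sample(chroms, 1L)
      p1 <- sample.int(cfg$chrom_len - 1e5, 1L)
      p2 <- p1 + sample(2e4:8e4, 1L)
      sides <- c(sample(c("LEFT", "RIGHT"), 1L),
                 sample(c("LEFT", "RIGHT"), 1L))
      pon_rows[[gi]] <- data.table::data.table(
        sample_id = "PON", chrom1 = ch, pos1 = p1, side1 = sides[1L],
        chrom2 = ch, pos2 = p2, side2 = sides[2L],
        sv_type = .realized_type(ch, p1, sides[1L], ch, p2, sides[2L]),
        n_discordant = 10L, n_split = 5L)
      for (s in sample(samples, min(3L, length(samples))))
        add_call(s, ch, p1, sides[1L], ch, p2, sides[2L])
    }
    pon <- call_set(data.table::rbindlist(pon_rows), "PON", "HIGH")

    # background somatic SVs + one repeat artifact and one low-support
    # call per sample
    for (s in samples) {
      nb <- stats::rpois(1L, cfg$n_background_svs)
      for (b in seq_len(nb)) {
        c1 <- sample(chroms, 1L); c2 <- sample(chroms, 1L)
        add_call(s, c1, sample.int(cfg$chrom_len, 1L),
                 sample(c("LEFT", "RIGHT"), 1L),
                 c2, sample.int(cfg$chrom_len, 1L),
                 sample(c("LEFT", "RIGHT"), 1L))
      }
      ri <- repeats[sample.int(nrow(repeats), 2L)]
      add_call(s, ri$chrom[1L],
               round((ri$start[1L] + ri$end[1L]) / 2),
               sample(c("LEFT", "RIGHT"), 1L),
               ri$chrom[2L], round((ri$start[2L] + ri$end[2L]) / 2),
               sample(c("LEFT", "RIGHT"), 1L))
      add_call(s, sample(chroms, 1L), sample.int(cfg$chrom_len, 1L),
               "LEFT", sample(chroms, 1L), sample.int(cfg$chrom_len, 1L),
               "RIGHT", dp = 2L, sr = 0L)
    }

    all_calls <- data.table::rbindlist(calls)
    all_calls[, call_id := sprintf("%s_c%04d", sample_id,
                                   data.table::rowid(sample_id))]
    all_calls[, coverage_tier := "HIGH"]
    all_calls <- .normalize_calls(all_calls)
    data.table::setcolorder(all_calls, names(.empty_calls()))
    expr <- round(expr, 6)
    junc <- if (length(junctions)) data.table::rbindlist(junctions) else NULL
    cohort <- cohort_data(all_calls, expr, cna, tumor_type,
                          junctions = junc)
    manifest <- list(seed = cfg$seed,
                     events = manifest_events,
                     amplified_confounders = amp_samples,
                     n_germline_events = cfg$n_germline_events)
    structure(list(cohort = cohort, pon = pon, repeats = repeats,
                   bands = bands, manifest = manifest, cfg = cfg),
              class = "sim_cohort")
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("sim_cohort (seed", x$cfg$seed, "):",
      length(x$manifest$events), "planted events;",
      nrow(x$cohort$calls), "raw calls;",
      ncol(x$cohort$expr), "samples\n")
  invisible(x)
}

#' Write a simulated cohort to fixture files
#'
#' Emits the full plain-text fixture set: `genes.gtf`, one BEDPE per
#' sample under `sv/`, `expr.tsv`, `cna.tsv`, `junctions.tsv`,
#' `cytobands.tsv`, `repeats.bed`, `pon.bedpe`, and `manifest.json`.
#' [read_cohort_dir()] reproduces the in-memory structures.
#'
#' @param sim a `sim_cohort` from [simulate_cohort()].
#' @param ann the matching [genome_annotation()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_fixture_files <- function(sim, ann, outdir) {
  dir.create(file.path(outdir, "sv"), recursive = TRUE, showWarnings = FALSE)
  write_gene_models(ann, file.path(outdir, "genes.gtf"))
  ch <- sim$cohort
  samples <- colnames(ch$expr)
  for (s in samples)
    write_bedpe(call_set(ch$calls[sample_id == s], s, "HIGH"),
                file.path(outdir, "sv", paste0(s, ".bedpe")))
  ex <- data.table::data.table(gene_id = rownames(ch$expr))
  expr_dt <- cbind(ex, data.table::as.data.table(ch$expr))
  data.table::fwrite(expr_dt, file.path(outdir, "expr.tsv"), sep = "\t")
  cna_dt <- cbind(ex, data.table::as.data.table(ch$cna))
  data.table::fwrite(cna_dt, file.path(outdir, "cna.tsv"), sep = "\t")
  if (!is.null(ch$junctions))
    data.table::fwrite(ch$junctions, file.path(outdir, "junctions.tsv"),
                       sep = "\t")
  data.table::fwrite(sim$bands$bands, file.path(outdir, "cytobands.tsv"),
                     sep = "\t", col.names = FALSE)
  rep_bed <- data.table::data.table(chrom = sim$repeats$chrom,
                                    start = sim$repeats$start - 1L,
                                    end = sim$repeats$end)
  data.table::fwrite(rep_bed, file.path(outdir, "repeats.bed"),
                     sep = "\t", col.names = FALSE)
  write_bedpe(sim$pon, file.path(outdir, "pon.bedpe"))
  tt <- data.table::data.table(sample_id = samples,
                               tumor_type = unname(ch$tumor_type))
  data.table::fwrite(tt, file.path(outdir, "samples.tsv"), sep = "\t")
  jsonlite::write_json(sim$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Read a fixture directory back into a cohort
#'
#' @param dir directory written by [write_fixture_files()].
#' @return list with `ann`, `cohort`, `pon`, `repeats`, `bands`,
#'   `manifest`.
#' @export
read_cohort_dir <- function(dir) {
  ann <- read_gene_models(file.path(dir, "genes.gtf"))
  tt <- data.table::fread(file.path(dir, "samples.tsv"))
  tumor_type <- stats::setNames(tt$tumor_type, tt$sample_id)
  expr_dt <- data.table::fread(file.path(dir, "expr.tsv"))
  expr <- as.matrix(expr_dt[, -1L])
  rownames(expr) <- expr_dt$gene_id
  cna_dt <- data.table::fread(file.path(dir, "cna.tsv"))
  cna <- as.matrix(cna_dt[, -1L])
  rownames(cna) <- cna_dt$gene_id
  junc_path <- file.path(dir, "junctions.tsv")
  junctions <- if (file.exists(junc_path)) read_junction_evidence(junc_path)
  else NULL
  callsets <- lapply(tt$sample_id, function(s)
    read_bedpe(file.path(dir, "sv", paste0(s, ".bedpe")), s, "HIGH"))
  names(callsets) <- tt$sample_id
  pon <- read_bedpe(file.path(dir, "pon.bedpe"), "PON", "HIGH")
  repeats <- read_repeats(file.path(dir, "repeats.bed"))
  bands <- read_cytobands(file.path(dir, "cytobands.tsv"))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  list(ann = ann,
       cohort = cohort_data(callsets, expr, cna, tumor_type,
                            junctions = junctions),
       pon = pon, repeats = repeats, bands = bands, manifest = manifest)
}
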