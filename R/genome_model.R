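# Gene-model container and breakend-level genome annotation.
#
# Internal coordinates are 1-based inclusive (the GRanges/GTF dialect);
# BED/BEDPE files are converted at the I/O boundary. Exon indices are in
# transcription order: exon 1 is the 5'-most exon, so for "-" genes it has
# the highest genomic coordinates.

#' Build a genome annotation from gene and exon tables
#'
#' Constructs the annotation container used throughout the package: one
#' canonical transcript per gene, an exon table in transcription order, and
#' an interval index over gene bodies.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `start`, `end` (1-based inclusive gene body), and
#'   optionally `name`, `tx_id`, `cds_start`, `cds_end` (NA for non-coding).
#' @param exons data.frame with columns `gene_id`, `start`, `end`
#'   (1-based inclusive). Exon indices are derived from genomic order and
#'   strand; a pre-computed `exon_index` column is honoured if present.
#' @param chrom_sizes named numeric vector of chromosome lengths (bp). If
#'   `NULL`, the per-chromosome maximum gene end is used.
#' @return An object of class `genome_annotation`: a list with elements
#'   `genes` (data.table), `exons` (data.table), `chrom_sizes`, and `gr`
#'   (a [GenomicRanges::GRanges] over gene bodies).
#' @export
genome_annotation <- function(genes, exons, chrom_sizes = NULL) {
  genes <- data.table::as.data.table(genes)
  exons <- data.table::as.data.table(exons)
  req <- c("gene_id", "chrom", "strand", "start", "end")
  miss <- setdiff(req, names(genes))
  if (length(miss)) stop("genes table lacks columns: ", paste(miss, collapse = ", "))
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'; got: ",
         paste(unique(setdiff(genes$strand, c("+", "-"))), collapse = ", "))
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id: ", genes$gene_id[duplicated(genes$gene_id)][1L])
  if (!"name" %in% names(genes)) genes[, name := gene_id]
  if (!"tx_id" %in% names(genes)) genes[, tx_id := paste0(gene_id, ".t1")]
  if (!"cds_start" %in% names(genes)) genes[, cds_start := NA_real_]
  if (!"cds_end" %in% names(genes)) genes[, cds_end := NA_real_]

  if (!"exon_index" %in% names(exons)) {
    data.table::setorder(exons, gene_id, start)
    exons[, exon_index := seq_len(.N), by = gene_id]
    neg <- genes[strand == "-", gene_id]
    exons[gene_id %in% neg, exon_index := rev(exon_index), by = gene_id]
  }
  data.table::setorder(exons, gene_id, exon_index)

  # invariants: exons within the gene body, non-overlapping; CDS inside exons
  chk <- merge(exons, genes[, .(gene_id, g_start = start, g_end = end)],
               by = "gene_id")
  if (chk[, any(start < g_start | end > g_end | start > end)])
    stop("exon outside its gene body (or start > end)")
  ov <- exons[order(gene_id, start),
              .(bad = any(start[-1L] <= head(end, -1L))), by = gene_id]
  if (any(ov$bad)) stop("overlapping exons in gene ", ov[bad == TRUE, gene_id][1L])
  cg <- genes[!is.na(cds_start)]
  if (nrow(cg)) {
    for (i in seq_len(nrow(cg))) {
      ex <- exons[gene_id == cg$gene_id[i]]
      for (p in c(cg$cds_start[i], cg$cds_end[i]))
        if (!any(p >= ex$start & p <= ex$end))
          stop("CDS boundary of ", cg$gene_id[i], " not inside an exon")
    }
  }

  if (is.null(chrom_sizes)) {
    cs <- genes[, .(size = max(end)), by = chrom]
    chrom_sizes <- stats::setNames(cs$size, cs$chrom)
  } else {
    bad <- genes[end > chrom_sizes[chrom] | !(chrom %in% names(chrom_sizes))]
    if (nrow(bad))
      stop("gene ", bad$gene_id[1L], " does not fit in chrom_sizes; ",
           "annotation chroms: ", paste(sort(unique(genes$chrom)), collapse = ","),
           "; chrom_sizes chroms: ", paste(sort(names(chrom_sizes)), collapse = ","))
  }

  gr <- GenomicRanges::GRanges(
    seqnames = factor(genes$chrom, levels = sort(names(chrom_sizes))),
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand)
  names(gr) <- genes$gene_id

  data.table::setkey(exons, gene_id, exon_index)
  ann <- list(genes = genes, exons = exons, chrom_sizes = chrom_sizes, gr = gr)
  class(ann) <- "genome_annotation"
  ann
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$genes), "genes on",
      length(x$chrom_sizes), "chromosomes;",
      nrow(x$exons), "exons (canonical transcripts)\n")
  invisible(x)
}

#' Read gene models from a GTF file
#'
#' Parses `exon` (and optional `CDS`) features and reduces each gene to one
#' canonical transcript: the transcript with the longest total CDS, ties
#' broken by the longest exonic length, then by lexicographic transcript id.
#' GTF 1-based inclusive coordinates are kept as-is internally.
#'
#' @param path GTF file path.
#' @param chrom_sizes optional named vector of chromosome lengths.
#' @return A [genome_annotation()] object.
#' @export
read_gene_models <- function(path, chrom_sizes = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  g <- rtracklayer::import(path, format = "gtf")
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(g)),
    start = GenomicRanges::start(g),
    end = GenomicRanges::end(g),
    strand = as.character(GenomicRanges::strand(g)),
    type = as.character(g$type),
    gene_id = as.character(g$gene_id),
    tx_id = if (!is.null(g$transcript_id)) as.character(g$transcript_id) else NA_character_,
    gene_name = if (!is.null(g$gene_name)) as.character(g$gene_name) else NA_character_)
  dt <- dt[type %in% c("exon", "CDS")]
  if (!nrow(dt)) stop("GTF contains no exon features: ", path)
  if (!all(dt$strand %in% c("+", "-")))
    stop("GTF strand must be '+' or '-'")
  if (anyNA(dt$tx_id)) dt[is.na(tx_id), tx_id := paste0(gene_id, ".t1")]

  # canonical transcript per gene
  per_tx <- dt[, .(
    cds_len = sum(ifelse(type == "CDS", end - start + 1L, 0L)),
    ex_len = sum(ifelse(type == "exon", end - start + 1L, 0L))),
    by = .(gene_id, tx_id)]
  data.table::setorder(per_tx, gene_id, -cds_len, -ex_len, tx_id)
  canon <- per_tx[, .SD[1L], by = gene_id]

  dt <- merge(dt, canon[, .(gene_id, tx_id)], by = c("gene_id", "tx_id"))
  ex <- dt[type == "exon", .(gene_id, start, end)]
  cds_rows <- dt[type == "CDS"]
  cds <- if (nrow(cds_rows))
    cds_rows[, .(cds_start = min(start), cds_end = max(end)), by = gene_id]
  else data.table::data.table(gene_id = character(),
                              cds_start = numeric(), cds_end = numeric())
  genes <- dt[, .(chrom = chrom[1L], strand = strand[1L],
                  start = min(start), end = max(end),
                  name = {
                    nm <- gene_name[!is.na(gene_name)]
                    if (length(nm)) nm[1L] else gene_id[1L]
                  },
                  tx_id = tx_id[1L]), by = gene_id]
  genes <- merge(genes, cds, by = "gene_id", all.x = TRUE)
  genome_annotation(genes, ex, chrom_sizes)
}

#' Write an annotation back to GTF
#'
#' Emits exon and CDS features of the canonical transcripts, 1-based
#' inclusive, so that `read_gene_models(write_gene_models(ann))`
#' round-trips the gene-model set.
#'
#' @param ann a [genome_annotation()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(ann, path) {
  ex <- merge(ann$exons,
              ann$genes[, .(gene_id, chrom, strand, tx_id, name,
                            cds_start, cds_end)],
              by = "gene_id")
  feats <- ex[, .(chrom, start, end, strand, type = "exon",
                  gene_id, tx_id, name, phase = NA_integer_)]
  cds <- ex[!is.na(cds_start) & end >= cds_start & start <= cds_end,
            .(chrom, start = pmax(start, as.integer(cds_start)),
              end = pmin(end, as.integer(cds_end)), strand, type = "CDS",
              gene_id, tx_id, name, exon_index)]
  # GTF phase: bases to skip before the first complete codon
  data.table::setorder(cds, gene_id, exon_index)
  cds[, phase := {
    w <- end - start + 1L
    prior <- cumsum(c(0L, utils::head(w, -1L)))
    as.integer((3L - prior %% 3L) %% 3L)
  }, by = gene_id]
  cds[, exon_index := NULL]
  feats <- rbind(feats, cds)
  gr <- GenomicRanges::GRanges(
    seqnames = feats$chrom,
    ranges = IRanges::IRanges(feats$start, feats$end),
    strand = feats$strand,
    type = feats$type, gene_id = feats$gene_id,
    transcript_id = feats$tx_id, gene_name = feats$name,
    phase = feats$phase,
    source = "uibscreen")
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

.check_chrom <- function(ann, chrom) {
  if (!chrom %in% names(ann$chrom_sizes))
    stop("unknown chromosome '", chrom, "'; annotation has: ",
         paste(sort(names(ann$chrom_sizes)), collapse = ", "))
}

#' Annotate a genomic position relative to the gene models
#'
#' A position inside any gene body is `GENIC` and reports, per overlapped
#' gene, whether it falls in an exon or intron and the (transcription-order)
#' index of that element. Otherwise it is `INTERGENIC` and the nearest gene
#' on each genomic side is reported with a strand-aware relation:
#' `UPSTREAM` means the position lies 5' of that gene's transcription start
#' (for a "-" gene, at higher coordinate), with `distance` measured to the
#' transcription start; `DOWNSTREAM` is measured to the transcription end.
#'
#' @param ann a [genome_annotation()].
#' @param chrom chromosome name (matched verbatim).
#' @param pos 1-based position.
#' @return An object of class `breakend_annotation`: list with `status`,
#'   `hit_genes` (data.table gene_id/element/index) and `flanking`
#'   (data.table gene_id/relation/distance).
#' @export
annotate_position <- function(ann, chrom, pos) {
  .check_chrom(ann, chrom)
  if (pos < 1 || pos > ann$chrom_sizes[[chrom]])
    stop("position ", pos, " outside chromosome ", chrom,
         " (size ", ann$chrom_sizes[[chrom]], ")")
  gsel <- ann$genes$chrom == chrom & ann$genes$start <= pos &
    ann$genes$end >= pos
  g <- ann$genes[which(gsel)]
  if (nrow(g)) {
    hits <- data.table::rbindlist(lapply(seq_len(nrow(g)), function(i) {
      el <- .exon_intron_index(ann, g$gene_id[i], pos)
      data.table::data.table(gene_id = g$gene_id[i],
                             element = el$element, index = el$index)
    }))
    out <- list(status = "GENIC", hit_genes = hits,
                flanking = data.table::data.table(
                  gene_id = character(), relation = character(),
                  distance = numeric()))
  } else {
    csel <- which(ann$genes$chrom == chrom)
    gg <- ann$genes[csel]
    fl <- list()
    left <- gg[gg$end < pos]
    if (nrow(left)) {
      nb <- left[which.max(left$end)]
      fl[[length(fl) + 1L]] <- .flank_row(nb, pos)
    }
    right <- gg[gg$start > pos]
    if (nrow(right)) {
      nb <- right[which.min(right$start)]
      fl[[length(fl) + 1L]] <- .flank_row(nb, pos)
    }
    flanking <- if (length(fl)) data.table::rbindlist(fl) else
      data.table::data.table(gene_id = character(), relation = character(),
                             distance = numeric())
    out <- list(status = "INTERGENIC",
                hit_genes = data.table::data.table(
                  gene_id = character(), element = character(),
                  index = integer()),
                flanking = flanking)
  }
  class(out) <- "breakend_annotation"
  out
}

# relation of an intergenic pos to one gene row, in the gene's orientation
.flank_row <- function(g, pos) {
  if (pos < g$start) {
    rel <- if (g$strand == "+") "UPSTREAM" else "DOWNSTREAM"
    d <- g$start - pos
  } else {
    rel <- if (g$strand == "+") "DOWNSTREAM" else "UPSTREAM"
    d <- pos - g$end
  }
  data.table::data.table(gene_id = g$gene_id, relation = rel, distance = d)
}

# exon/intron element and transcription-order index for a genic position
.exon_intron_index <- function(ann, gid, pos) {
  ex <- ann$exons[.(gid)]
  inside <- ex[pos >= start & pos <= end]
  if (nrow(inside))
    return(list(element = "EXON", index = inside$exon_index[1L]))
  st <- ann$genes[gene_id == gid, strand]
  idx <- if (st == "+") sum(ex$end < pos) else sum(ex$start > pos)
  list(element = "INTRON", index = as.integer(idx))
}

#' @export
print.breakend_annotation <- function(x, ...) {
  cat("breakend_annotation:", x$status, "\n")
  if (x$status == "GENIC") print(x$hit_genes) else print(x$flanking)
  invisible(x)
}

#' Genes for which a position lies upstream/downstream within a window
#'
#' Strand-aware: the position is `UPSTREAM` of a gene when it lies 5' of
#' the gene's transcription start in the gene's own orientation.
#'
#' @param ann a [genome_annotation()].
#' @param chrom,pos position to query.
#' @param window maximum distance in bp (inclusive).
#' @param relation `"UPSTREAM"` or `"DOWNSTREAM"`.
#' @return data.table with `gene_id` and `distance`, sorted by distance.
#' @export
genes_within_window <- function(ann, chrom, pos, window,
                                relation = c("UPSTREAM", "DOWNSTREAM")) {
  relation <- match.arg(relation)
  stopifnot(window > 0)
  .check_chrom(ann, chrom)
  csel <- which(ann$genes$chrom == chrom)
  gg <- ann$genes[csel]
  if (relation == "UPSTREAM") {
    plus <- gg[strand == "+" & start > pos & start - pos <= window,
               .(gene_id, distance = start - pos)]
    minus <- gg[strand == "-" & end < pos & pos - end <= window,
                .(gene_id, distance = pos - end)]
  } else {
    plus <- gg[strand == "+" & end < pos & pos - end <= window,
               .(gene_id, distance = pos - end)]
    minus <- gg[strand == "-" & start > pos & start - pos <= window,
                .(gene_id, distance = start - pos)]
  }
  out <- rbind(plus, minus)
  data.table::setorder(out, distance, gene_id)
  out[]
}

# ---- cytobands ------------------------------------------------------------

#' Read a UCSC-style cytoband table
#'
#' Expects the tab-separated `cytoBand` layout: chrom, start (0-based),
#' end, band name, stain. Bands must tile each chromosome without overlap.
#'
#' @param path file path.
#' @return An object of class `cytoband_map`.
#' @export
read_cytobands <- function(path) {
  b <- data.table::fread(path, header = FALSE)
  data.table::setnames(b, seq_len(min(5L, ncol(b))),
                       c("chrom", "start", "end", "band", "stain")[seq_len(min(5L, ncol(b)))])
  cytoband_map(b)
}

#' Construct a cytoband map from a table
#'
#' @param bands data.frame with `chrom`, `start` (0-based half-open),
#'   `end`, `band` (and optionally `stain`).
#' @return An object of class `cytoband_map`.
#' @export
cytoband_map <- function(bands) {
  b <- data.table::as.data.table(bands)
  data.table::setorder(b, chrom, start)
  gap <- b[, .(bad = any(start[-1L] != head(end, -1L))), by = chrom]
  if (any(gap$bad))
    stop("cytobands do not tile chromosome ", gap[bad == TRUE, chrom][1L])
  data.table::setkey(b, chrom, start)
  structure(list(bands = b), class = "cytoband_map")
}

#' Cytoband containing a position
#'
#' @param bands a `cytoband_map`.
#' @param chrom,pos 1-based position. Band intervals are half-open in the
#'   native 0-based convention, so a position at a band's first base maps
#'   to that band.
#' @return band name (character scalar).
#' @export
cytoband_of <- function(bands, chrom, pos) {
  csel <- which(bands$bands$chrom == chrom)
  b <- bands$bands[csel]
  if (!nrow(b)) stop("no cytobands for chromosome '", chrom, "'")
  hit <- b[pos - 1L >= start & pos - 1L < end]
  if (!nrow(hit))
    stop("position ", pos, " outside the tiled cytoband range of ", chrom)
  hit$band[1L]
}

#' Read repeat regions from a BED file
#'
#' 0-based half-open BED converted to 1-based inclusive intervals.
#'
#' @param path BED file path.
#' @return data.table with `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_repeats <- function(path) {
  r <- data.table::fread(path, header = FALSE, select = 1:3,
                         col.names = c("chrom", "start", "end"))
  r[, start := start + 1L]
  data.table::setkey(r, chrom, start, end)
  r[]
}
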