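# SV call-set ingest and the read-support / germline / repeat filters.
#
# A breakend is (chrom, pos, side): side LEFT means the retained segment
# lies at coordinates lower than pos and is joined at pos to the partner
# breakend; RIGHT means it lies higher. BEDPE strand "+" maps to LEFT,
# "-" to RIGHT.

.side_from_strand <- function(s) ifelse(s == "+", "LEFT", "RIGHT")
.strand_from_side <- function(s) ifelse(s == "LEFT", "+", "-")

.empty_calls <- function() {
  data.table::data.table(
    sample_id = character(), call_id = character(),
    chrom1 = character(), pos1 = integer(), side1 = character(),
    chrom2 = character(), pos2 = integer(), side2 = character(),
    sv_type = character(), n_discordant = integer(), n_split = integer(),
    coverage_tier = character())
}

.normalize_calls <- function(calls) {
  # intra-chromosomal calls ordered bnd1.pos <= bnd2.pos
  flip <- calls$chrom1 == calls$chrom2 & calls$pos1 > calls$pos2
  if (any(flip)) {
    tmp <- calls[flip, .(chrom1, pos1, side1)]
    calls[flip, `:=`(chrom1 = chrom2, pos1 = pos2, side1 = side2)]
    calls[flip, `:=`(chrom2 = tmp$chrom1, pos2 = tmp$pos1, side2 = tmp$side1)]
  }
  calls
}

#' Construct a call set from a table of SV calls
#'
#' @param calls data.frame with columns `chrom1`, `pos1`, `side1`,
#'   `chrom2`, `pos2`, `side2` (sides `"LEFT"`/`"RIGHT"`), and optionally
#'   `sv_type`, `n_discordant`, `n_split`.
#' @param sample_id sample identifier applied to all calls.
#' @param coverage_tier `"HIGH"` or `"LOW"`; selects the support filter.
#' @return An object of class `call_set` wrapping a data.table of calls.
#' @export
call_set <- function(calls, sample_id, coverage_tier = c("HIGH", "LOW")) {
  coverage_tier <- match.arg(coverage_tier)
  calls <- data.table::as.data.table(calls)
  if (!nrow(calls)) calls <- .empty_calls()
  if (!"sv_type" %in% names(calls)) calls[, sv_type := "OTHER"]
  if (!"n_discordant" %in% names(calls)) calls[, n_discordant := 0L]
  if (!"n_split" %in% names(calls)) calls[, n_split := 0L]
  calls[is.na(sv_type), sv_type := "OTHER"]
  calls[!sv_type %in% c("DEL", "INV", "TDUP", "TRA"), sv_type := "OTHER"]
  if (any(calls$n_discordant < 0 | calls$n_split < 0))
    stop("read-support counts must be >= 0")
  if (!all(c(calls$side1, calls$side2) %in% c("LEFT", "RIGHT")))
    stop("sides must be 'LEFT' or 'RIGHT'")
  calls$sample_id <- sample_id
  calls$coverage_tier <- coverage_tier
  if (!"call_id" %in% names(calls) || anyNA(calls$call_id))
    calls$call_id <- sprintf("%s_c%04d", sample_id, seq_len(nrow(calls)))
  calls <- .normalize_calls(calls)
  data.table::setcolorder(calls, names(.empty_calls()))
  structure(list(sample_id = sample_id, calls = calls[],
                 coverage_tier = coverage_tier),
            class = "call_set")
}

#' @export
print.call_set <- function(x, ...) {
  cat("call_set:", x$sample_id, "-", nrow(x$calls), "calls (",
      x$coverage_tier, "coverage )\n")
  invisible(x)
}

#' Read an SV call set from a BEDPE file
#'
#' Requires the 10-column BEDPE layout (chrom1, start1, end1, chrom2,
#' start2, end2, name, score, strand1, strand2); an optional 11th column
#' holds `KEY=VALUE;...` pairs with `SVTYPE`, `DP` (discordant pairs) and
#' `SR` (split reads). Breakend positions are taken as `start + 1`
#' (1-based); strand `+` maps to side `LEFT`, `-` to `RIGHT`.
#'
#' @param path BEDPE file path.
#' @param sample_id sample identifier.
#' @param coverage_tier `"HIGH"` or `"LOW"`.
#' @return A [call_set()].
#' @export
read_bedpe <- function(path, sample_id, coverage_tier = c("HIGH", "LOW")) {
  coverage_tier <- match.arg(coverage_tier)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines))
    return(call_set(.empty_calls(), sample_id, coverage_tier))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 10L))
    stop("BEDPE line ", which(nf < 10L)[1L], " has ", nf[nf < 10L][1L],
         " columns; >= 10 required: ", path)
  parse_info <- function(s) {
    if (is.na(s) || !nzchar(s)) return(character())
    kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], "=", fixed = TRUE)
    stats::setNames(vapply(kv, function(x) x[2L], ""),
                    vapply(kv, function(x) x[1L], ""))
  }
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    p1 <- suppressWarnings(as.integer(f[2L]))
    p2 <- suppressWarnings(as.integer(f[5L]))
    if (is.na(p1) || is.na(p2))
      stop("BEDPE line ", i, ": non-numeric start coordinate: ", path)
    if (!all(f[c(9L, 10L)] %in% c("+", "-")))
      stop("BEDPE line ", i, ": strands must be '+'/'-': ", path)
    info <- parse_info(if (length(f) >= 11L) f[11L] else NA_character_)
    data.table::data.table(
      chrom1 = f[1L], pos1 = p1 + 1L, side1 = .side_from_strand(f[9L]),
      chrom2 = f[4L], pos2 = p2 + 1L, side2 = .side_from_strand(f[10L]),
      sv_type = if ("SVTYPE" %in% names(info)) info[["SVTYPE"]] else NA_character_,
      n_discordant = if ("DP" %in% names(info)) as.integer(info[["DP"]]) else 0L,
      n_split = if ("SR" %in% names(info)) as.integer(info[["SR"]]) else 0L,
      call_id = if (length(f) >= 7L && nzchar(f[7L]) && f[7L] != ".")
        f[7L] else NA_character_)
  })
  call_set(data.table::rbindlist(rows), sample_id, coverage_tier)
}

#' Write a call set to BEDPE
#'
#' Inverse of [read_bedpe()]: positions become 0-based starts, sides
#' become strands, and SVTYPE/DP/SR are carried in column 11. A
#' `FILTER_REASON` attribute column is appended when present.
#'
#' @param cs a [call_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(cs, path) {
  calls <- cs$calls
  info <- sprintf("SVTYPE=%s;DP=%d;SR=%d", calls$sv_type,
                  calls$n_discordant, calls$n_split)
  out <- data.table::data.table(
    chrom1 = calls$chrom1, start1 = calls$pos1 - 1L, end1 = calls$pos1,
    chrom2 = calls$chrom2, start2 = calls$pos2 - 1L, end2 = calls$pos2,
    name = calls$call_id, score = ".",
    strand1 = .strand_from_side(calls$side1),
    strand2 = .strand_from_side(calls$side2),
    info = info)
  if (!is.null(calls$filter_reason)) out[, reason := calls$filter_reason]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Filter calls by read support
#'
#' High-coverage call sets keep calls with combined discordant plus split
#' read support of at least `high_min_total` (default 6); low-coverage
#' call sets keep calls with at least `low_min_discordant` discordant
#' pairs and `low_min_split` split reads (defaults 2 and 1).
#'
#' @param cs a [call_set()].
#' @param high_min_total,low_min_discordant,low_min_split thresholds.
#' @return A filtered [call_set()]; removal counts are in
#'   `attr(, "filter_counts")`.
#' @export
filter_support <- function(cs, high_min_total = 6L,
                           low_min_discordant = 2L, low_min_split = 1L) {
  calls <- cs$calls
  keep <- if (cs$coverage_tier == "HIGH")
    calls$n_discordant + calls$n_split >= high_min_total
  else
    calls$n_discordant >= low_min_discordant & calls$n_split >= low_min_split
  out <- call_set(calls[keep], cs$sample_id, cs$coverage_tier)
  attr(out, "filter_counts") <- c(support = sum(!keep))
  out
}

.bnd_match <- function(c1, p1, c2, p2, pon, slop) {
  # both breakends of a call match both breakends of any PON call (either
  # orientation of the pairing), same chromosomes, within slop bp
  direct <- pon$chrom1 == c1 & abs(pon$pos1 - p1) <= slop &
    pon$chrom2 == c2 & abs(pon$pos2 - p2) <= slop
  crossed <- pon$chrom1 == c2 & abs(pon$pos1 - p2) <= slop &
    pon$chrom2 == c1 & abs(pon$pos2 - p1) <= slop
  any(direct | crossed)
}

.in_repeat <- function(chrom, pos, repeats) {
  any(repeats$chrom == chrom & repeats$start <= pos & repeats$end >= pos)
}

#' Remove germline (panel-of-normals) and repeat-artifact calls
#'
#' A call is dropped when both of its breakends match a panel-of-normals
#' call within `slop` bp on the same chromosome pair, or when both
#' breakends fall inside repeat intervals. A call with only one breakend
#' in a repeat is kept.
#'
#' @param cs a [call_set()].
#' @param pon a [call_set()], list of call sets, or a calls data.table
#'   holding panel-of-normals events; `NULL` to skip.
#' @param repeats data.table of repeat intervals (`chrom`, `start`, `end`,
#'   1-based inclusive, e.g. from [read_repeats()]); `NULL` to skip.
#' @param slop breakend matching tolerance in bp (default 100).
#' @return Filtered [call_set()] with removal counts per reason in
#'   `attr(, "filter_counts")`.
#' @export
filter_germline_and_repeats <- function(cs, pon = NULL, repeats = NULL,
                                        slop = 100L) {
  stopifnot(slop >= 0)
  calls <- cs$calls
  pon_dt <- NULL
  if (!is.null(pon)) {
    if (inherits(pon, "call_set")) pon_dt <- pon$calls
    else if (is.list(pon) && all(vapply(pon, inherits, TRUE, "call_set")))
      pon_dt <- data.table::rbindlist(lapply(pon, `[[`, "calls"))
    else pon_dt <- data.table::as.data.table(pon)
  }
  n <- nrow(calls)
  germ <- rep(FALSE, n)
  rep_hit <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (!is.null(pon_dt) && nrow(pon_dt))
      germ[i] <- .bnd_match(calls$chrom1[i], calls$pos1[i],
                            calls$chrom2[i], calls$pos2[i], pon_dt, slop)
    if (!is.null(repeats) && nrow(repeats))
      rep_hit[i] <- .in_repeat(calls$chrom1[i], calls$pos1[i], repeats) &&
        .in_repeat(calls$chrom2[i], calls$pos2[i], repeats)
  }
  keep <- !(germ | rep_hit)
  out <- call_set(calls[keep], cs$sample_id, cs$coverage_tier)
  attr(out, "filter_counts") <- c(germline = sum(germ & !rep_hit),
                                  repeats = sum(rep_hit))
  out
}

#' Apply the ingest filters to every sample of a cohort
#'
#' Runs [filter_support()] and [filter_germline_and_repeats()] per sample
#' and returns a cohort with the surviving calls; the expression,
#' copy-number, tumor-type and junction components are untouched. This is
#' the stage that precedes classification and screening.
#'
#' @param cohort a cohort (see [cohort_data()]).
#' @param pon,repeats,slop see [filter_germline_and_repeats()].
#' @param high_min_total,low_min_discordant,low_min_split see
#'   [filter_support()].
#' @return A filtered cohort of the same class.
#' @export
filter_cohort <- function(cohort, pon = NULL, repeats = NULL, slop = 100L,
                          high_min_total = 6L, low_min_discordant = 2L,
                          low_min_split = 1L) {
  samples <- colnames(cohort$expr)
  filtered <- lapply(samples, function(s) {
    sel <- which(cohort$calls$sample_id == s)
    if (!length(sel)) return(NULL)
    tier <- cohort$calls$coverage_tier[sel[1L]]
    if (is.na(tier)) tier <- "HIGH"
    cs <- call_set(cohort$calls[sel], s, tier)
    cs <- filter_support(cs, high_min_total = high_min_total,
                         low_min_discordant = low_min_discordant,
                         low_min_split = low_min_split)
    filter_germline_and_repeats(cs, pon = pon, repeats = repeats,
                                slop = slop)$calls
  })
  calls <- data.table::rbindlist(Filter(Negate(is.null), filtered))
  if (!nrow(calls)) calls <- .empty_calls()
  cohort_data(calls, cohort$expr, cohort$cna, cohort$tumor_type,
              junctions = cohort$junctions)
}

#' Positional union of call sets with slop (plumbing)
#'
#' Merges calls from multiple callers for one sample: calls whose breakend
#' pairs match within `slop` bp are collapsed, keeping the record with the
#' highest combined read support.
#'
#' @param cs_list list of [call_set()] objects for the same sample.
#' @param slop matching tolerance in bp.
#' @return A single [call_set()].
#' @export
union_call_sets <- function(cs_list, slop = 100L) {
  stopifnot(length(cs_list) >= 1L)
  all_calls <- data.table::rbindlist(lapply(cs_list, `[[`, "calls"))
  data.table::setorder(all_calls, -n_discordant, -n_split)
  kept <- all_calls[0L]
  for (i in seq_len(nrow(all_calls))) {
    r <- all_calls[i]
    if (nrow(kept) == 0L ||
        !.bnd_match(r$chrom1, r$pos1, r$chrom2, r$pos2, kept, slop))
      kept <- rbind(kept, r)
  }
  call_set(kept, cs_list[[1L]]$sample_id, cs_list[[1L]]$coverage_tier)
}
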