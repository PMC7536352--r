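#' Parameters for chloroplast read classification
#'
#' Thresholds for deciding whether a WGS read is chloroplast-derived from
#' its alignments to a panel of reference cp genomes, and for the quality
#' trimming applied to short reads beforehand.
#'
#' Defaults follow the rules used for cp read extraction in hybrid plastome
#' assembly: long-read alignment records with at least 500 bp aligned are
#' kept, and a long read is accepted when at least 1 kb *and* 80% of the
#' read aligns; a short-read pair is accepted when both mates carry an
#' alignment block of at least 100 bp; short reads are first trimmed so
#' every base has Phred quality >= 20 and reads shorter than 100 bp are
#' discarded.
#'
#' @param min_record_query_bp Minimum aligned query span (bp) for a
#'   long-read alignment record to be counted (default 500).
#' @param min_total_query_bp Minimum total aligned query bp (after interval
#'   union) for a long read to be accepted (default 1000).
#' @param min_query_fraction Minimum aligned fraction of the read (default
#'   0.8).
#' @param pair_min_block_bp Minimum alignment block (bp) required on each
#'   mate of a short-read pair (default 100).
#' @param trim_min_quality Minimum per-base Phred quality after trimming
#'   (default 20).
#' @param trim_min_length Minimum read length after trimming (default 100).
#' @return A list of class `classifier_params`.
#' @export
classifier_params <- function(min_record_query_bp = 500L,
                              min_total_query_bp = 1000L,
                              min_query_fraction = 0.8,
                              pair_min_block_bp = 100L,
                              trim_min_quality = 20L,
                              trim_min_length = 100L) {
  p <- list(min_record_query_bp = as.integer(min_record_query_bp),
            min_total_query_bp = as.integer(min_total_query_bp),
            min_query_fraction = min_query_fraction,
            pair_min_block_bp = as.integer(pair_min_block_bp),
            trim_min_quality = as.integer(trim_min_quality),
            trim_min_length = as.integer(trim_min_length))
  if (any(unlist(p) < 0) || p$min_query_fraction > 1) {
    abort("classifier thresholds must be >= 0 and min_query_fraction <= 1",
          class = "cpkit_usage_error")
  }
  structure(p, class = "classifier_params")
}

#' Alignment identity I = M/L
#'
#' The identity of an alignment record is the number of exactly matching
#' base pairs M divided by the span L of the alignment on the reference.
#'
#' @param aln Alignment tibble with columns `match_bp` and `ref_span`.
#' @return `aln` with an added `identity` column.
#' @examples
#' alignment_identity(tibble::tibble(match_bp = 900, ref_span = 1000))$identity
#' @export
alignment_identity <- function(aln) {
  stopifnot(all(c("match_bp", "ref_span") %in% names(aln)))
  if (any(aln$ref_span <= 0)) {
    abort("alignment identity undefined for ref_span <= 0",
          class = "cpkit_domain_error")
  }
  mutate(aln, identity = .data$match_bp / .data$ref_span)
}

# Trim one read: end-trim below-threshold bases, then repeatedly cut at the
# first failing internal base keeping the longer fragment (left on ties),
# until every remaining base passes.  Returns c(start, end) 1-based
# inclusive, or NULL when nothing survives.
trim_interval <- function(q, min_q) {
  lo <- 1L
  hi <- length(q)
  repeat {
    while (lo <= hi && q[lo] < min_q) lo <- lo + 1L
    while (hi >= lo && q[hi] < min_q) hi <- hi - 1L
    if (lo > hi) return(NULL)
    bad <- which(q[lo:hi] < min_q)
    if (length(bad) == 0L) return(c(lo, hi))
    cut <- lo + bad[1L] - 1L
    left_len <- cut - lo
    right_len <- hi - cut
    if (left_len >= right_len) hi <- cut - 1L else lo <- cut + 1L
  }
}

#' Quality-trim short reads
#'
#' Applies the quality rule used before short-read assembly and polishing:
#' every base of a kept read must have Phred quality at least
#' `trim_min_quality` and the trimmed read must be at least
#' `trim_min_length` bp long.  Leading and trailing low-quality bases are
#' removed; if a low-quality base remains internally the read is cut at the
#' first such base and the longer fragment kept (the left one on ties), and
#' the rule is reapplied until the fragment is clean.
#'
#' @param reads Read tibble with `bases` and `quality` (Phred+33) columns.
#' @param params [classifier_params()].
#' @return The tibble of surviving reads with trimmed `bases`/`quality`,
#'   with attributes `n_input` and `n_rejected`.
#' @export
trim_by_quality <- function(reads, params = classifier_params()) {
  validate_reads(reads)
  if (any(is.na(reads$quality) | !nzchar(reads$quality) & nzchar(reads$bases))) {
    abort("trim_by_quality() requires per-base qualities on every read",
          class = "cpkit_usage_error")
  }
  n_input <- nrow(reads)
  if (n_input == 0L) {
    out <- reads
    attr(out, "n_input") <- 0L
    attr(out, "n_rejected") <- 0L
    return(out)
  }
  qs <- qual_to_int(reads$quality)
  # fast path: reads that are already clean
  minq <- map_int(qs, function(q) if (length(q)) min(q) else 0L)
  clean <- minq >= params$trim_min_quality
  iv <- vector("list", n_input)
  iv[clean] <- map(which(clean), function(i) c(1L, nchar(reads$bases[i])))
  iv[!clean] <- map(qs[!clean], trim_interval, min_q = params$trim_min_quality)
  keep <- map_lgl(iv, function(v) !is.null(v) &&
                    (v[2L] - v[1L] + 1L) >= params$trim_min_length)
  out <- reads[keep, , drop = FALSE]
  ivk <- iv[keep]
  out$bases <- map2(out$bases, ivk, function(b, v) substr(b, v[1L], v[2L])) |>
    unlist() %||% character()
  out$quality <- map2(out$quality, ivk, function(q, v) substr(q, v[1L], v[2L])) |>
    unlist() %||% character()
  attr(out, "n_input") <- n_input
  attr(out, "n_rejected") <- n_input - nrow(out)
  out
}

# union of query intervals (0-based half-open) -> total bp
query_union_bp <- function(starts, ends) {
  if (length(starts) == 0L) return(0L)
  r <- IRanges::reduce(IRanges::IRanges(start = starts + 1L, end = ends))
  sum(IRanges::width(r))
}

#' Classify one long read from its alignment records
#'
#' Alignment records whose aligned query span is below
#' `min_record_query_bp` are discarded; the remaining query intervals are
#' unioned so overlapping records are counted once (alignments to any
#' reference genome of the panel count toward the same union, and strand is
#' ignored).  The read is called chloroplast iff the union is at least
#' `min_total_query_bp` *and* at least `min_query_fraction` of the read
#' length.
#'
#' @param read_length Read length in bp.
#' @param alns Alignment tibble for this read (may be empty).
#' @param params [classifier_params()].
#' @return One-row tibble: `read_id`, `is_chloroplast`, `aligned_bp`,
#'   `aligned_fraction`, `n_records_used`.
#' @export
classify_long_read <- function(read_length, alns, params = classifier_params()) {
  read_id <- if (nrow(alns)) alns$query_id[1L] else NA_character_
  if (nrow(alns)) {
    if (length(unique(alns$query_id)) != 1L) {
      abort("classify_long_read(): records must share one query_id",
            class = "cpkit_input_error")
    }
    if (any(alns$query_length != read_length)) {
      abort(sprintf("read '%s': inconsistent query_length across records", read_id),
            class = "cpkit_input_error")
    }
  }
  span <- alns$query_end - alns$query_start
  used <- alns[span >= params$min_record_query_bp, , drop = FALSE]
  aligned <- query_union_bp(used$query_start, used$query_end)
  frac <- if (read_length > 0) aligned / read_length else 0
  tibble(read_id = read_id, is_chloroplast = aligned >= params$min_total_query_bp &&
           frac >= params$min_query_fraction,
         aligned_bp = as.integer(aligned), aligned_fraction = frac,
         n_records_used = nrow(used))
}

#' Classify one short-read pair
#'
#' A pair is called chloroplast iff both mates carry at least one alignment
#' record whose aligned query span is at least `pair_min_block_bp`.
#'
#' @param alns_mate1,alns_mate2 Alignment tibbles for the two mates.
#' @param params [classifier_params()].
#' @return One-row tibble: `read_id`, `is_chloroplast`, `aligned_bp`
#'   (union over both mates), `aligned_fraction` (`NA`, pairs have no
#'   single length), `n_records_used`.
#' @export
classify_read_pair <- function(alns_mate1, alns_mate2,
                               params = classifier_params()) {
  block_ok <- function(a) {
    nrow(a) > 0L && any(a$query_end - a$query_start >= params$pair_min_block_bp)
  }
  id <- if (nrow(alns_mate1)) sub("/[12]$", "", alns_mate1$query_id[1L])
        else if (nrow(alns_mate2)) sub("/[12]$", "", alns_mate2$query_id[1L])
        else NA_character_
  ok <- block_ok(alns_mate1) && block_ok(alns_mate2)
  aligned <- query_union_bp(alns_mate1$query_start, alns_mate1$query_end) +
    query_union_bp(alns_mate2$query_start, alns_mate2$query_end)
  tibble(read_id = id, is_chloroplast = ok, aligned_bp = as.integer(aligned),
         aligned_fraction = NA_real_,
         n_records_used = nrow(alns_mate1) + nrow(alns_mate2))
}

#' Classify a batch of reads against an alignment table
#'
#' Applies [classify_long_read()] to every long read, or the pair rule of
#' [classify_read_pair()] to every short-read pair (alignment `query_id`s of
#' short reads carry a `/1` / `/2` mate suffix).  Alignments referencing a
#' read id absent from `reads` are skipped with a warning.
#'
#' @param reads Read tibble (`id`, `bases`, `platform`, optionally `mate`).
#' @param alignments Alignment tibble ([read_alignment_table()] layout).
#' @param params [classifier_params()].
#' @return A tibble with one row per read (long) or per pair (short),
#'   ordered as in `reads`.  The attribute `summary` holds
#'   `n_input`, `n_accepted` and `total_bp_retained` (total bases of the
#'   accepted reads).
#' @export
classify_batch <- function(reads, alignments, params = classifier_params()) {
  validate_reads(reads)
  platform <- unique(reads$platform)
  if (length(platform) != 1L) {
    abort("classify_batch(): reads must be a single platform",
          class = "cpkit_input_error")
  }
  if (platform == "short") {
    key <- sub("/[12]$", "", alignments$query_id)
  } else {
    key <- alignments$query_id
  }
  known <- unique(reads$id)
  unknown <- setdiff(unique(key), known)
  if (length(unknown)) {
    warn(sprintf("skipping %d alignment record(s) for unknown read id(s): %s",
                 sum(key %in% unknown),
                 paste(head(unknown, 3L), collapse = ", ")))
    keepi <- !key %in% unknown
    alignments <- alignments[keepi, , drop = FALSE]
    key <- key[keepi]
  }
  if (platform == "long") {
    span <- alignments$query_end - alignments$query_start
    used <- span >= params$min_record_query_bp
    au <- alignments[used, , drop = FALSE]
    ku <- key[used]
    idx <- split(seq_len(nrow(au)), factor(ku, levels = known))
    aligned <- map_int(idx, function(i) {
      as.integer(query_union_bp(au$query_start[i], au$query_end[i]))
    })
    nrec <- lengths(idx)
    rl_len <- setNames(nchar(reads$bases), reads$id)[known]
    res <- tibble(
      read_id = known,
      aligned_bp = as.integer(aligned),
      aligned_fraction = ifelse(rl_len > 0, aligned / rl_len, 0),
      n_records_used = as.integer(nrec)
    ) %>%
      mutate(is_chloroplast = .data$aligned_bp >= params$min_total_query_bp &
               .data$aligned_fraction >= params$min_query_fraction) %>%
      select("read_id", "is_chloroplast", "aligned_bp", "aligned_fraction",
             "n_records_used")
    total_bp <- sum(rl_len[res$read_id[res$is_chloroplast]])
  } else {
    mate <- as.integer(sub("^.*/", "", alignments$query_id))
    span <- alignments$query_end - alignments$query_start
    ok_block <- span >= params$pair_min_block_bp
    ids <- unique(reads$id)
    m1 <- tapply(ok_block & mate == 1L, factor(key, levels = ids), any, default = FALSE)
    m2 <- tapply(ok_block & mate == 2L, factor(key, levels = ids), any, default = FALSE)
    ab <- tapply(span, factor(key, levels = ids), sum, default = 0L)
    nr <- tapply(span, factor(key, levels = ids), length, default = 0L)
    res <- tibble(read_id = ids, is_chloroplast = as.logical(m1) & as.logical(m2),
                  aligned_bp = as.integer(ab), aligned_fraction = NA_real_,
                  n_records_used = as.integer(nr))
    pair_bp <- tapply(nchar(reads$bases), factor(reads$id, levels = ids), sum)
    total_bp <- sum(pair_bp[res$read_id[res$is_chloroplast]])
  }
  attr(res, "summary") <- list(n_input = nrow(res),
                               n_accepted = sum(res$is_chloroplast),
                               total_bp_retained = as.numeric(total_bp))
  inform(sprintf("classify_batch: %d input, %d accepted, %.0f bp retained",
                 nrow(res), sum(res$is_chloroplast), as.numeric(total_bp)))
  res
}
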