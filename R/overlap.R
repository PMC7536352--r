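# Internal sequence-matching machinery shared by the contig merger, the
# reference-guided scaffolder and the inverted-repeat detector: exact k-mer
# anchoring, diagonal clustering, mismatch-tolerant extension and edit
# distance verification of candidate overlaps.

# all k-mer start positions (0-based) of s, sampled every `stride` bases
kmer_strings <- function(s, k, stride = 1L) {
  n <- nchar(s)
  if (n < k) return(list(pos = integer(), kmer = character()))
  pos <- seq.int(0L, n - k, by = stride)
  list(pos = pos, kmer = substring(s, pos + 1L, pos + k))
}

# hash of k-mer -> integer positions (0-based) in s
kmer_index <- function(s, k, stride = 1L) {
  ks <- kmer_strings(s, k, stride)
  split(ks$pos, ks$kmer)
}

# shared k-mer hits between a (query, sampled at `stride`) and b (indexed
# at stride 1).  Returns tibble(qpos, tpos, diag = tpos - qpos), 0-based.
kmer_hits <- function(a, b_index, k, stride = 1L) {
  ks <- kmer_strings(a, k, stride)
  if (length(ks$pos) == 0L) return(tibble(qpos = integer(), tpos = integer(), diag = integer()))
  hit <- b_index[ks$kmer]
  nh <- lengths(hit)
  found <- nh > 0L & !is.na(names(hit) %||% "")
  # unmatched names yield NULL entries; lengths() is 0 there
  qpos <- rep.int(ks$pos, nh)
  tpos <- unlist(hit, use.names = FALSE)
  if (is.null(tpos)) tpos <- integer()
  tibble(qpos = qpos, tpos = as.integer(tpos), diag = as.integer(tpos) - qpos)
}

# identity of an alignment between two same-scale segments, via edit
# distance (indel-aware); identity = 1 - dist / max(len)
segment_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) return(0)
  d <- as.integer(adist(a, b))
  1 - d / max(nchar(a), nchar(b))
}

# Mismatch-tolerant extension of an exact seed run along one diagonal.
# eq: logical vector, eq[i] = TRUE when the two sequences agree at offset i
# of the diagonal; [s, e] 1-based seed interval within eq.  A mismatch is
# crossed only when the next `look` positions keep at least `min_match`
# matches and the running mismatch rate over the extended interval stays
# <= max_rate.  The returned interval is trimmed to end on matches.
extend_run <- function(eq, s, e, max_rate = 0.01, look = 20L, min_match = 15L) {
  n <- length(eq)
  mm <- sum(!eq[s:e])
  if (mm / (e - s + 1L) > max_rate) {
    # seed spans beyond the true repeat (e.g. two repeat copies bridged
    # by a random spacer): restart from its longest clean stretch
    r <- rle(eq[s:e])
    if (!any(r$values)) return(NULL)
    ends <- cumsum(r$lengths)
    kbest <- which(r$values)[which.max(r$lengths[r$values])]
    e2 <- s + ends[kbest] - 1L
    s <- e2 - r$lengths[kbest] + 1L
    e <- e2
    mm <- 0L
  }
  step <- function(i, dir) {
    # returns TRUE when position i (a mismatch) should be crossed
    w <- if (dir > 0) eq[seq.int(i, min(n, i + look - 1L))]
         else eq[seq.int(max(1L, i - look + 1L), i)]
    sum(w) >= min(min_match, length(w)) &&
      (mm + 1L) / (e - s + 2L) <= max_rate
  }
  repeat {
    adv <- FALSE
    if (e < n) {
      if (eq[e + 1L]) { e <- e + 1L; adv <- TRUE }
      else if (step(e + 1L, 1L)) { mm <- mm + 1L; e <- e + 1L; adv <- TRUE }
    }
    if (s > 1L) {
      if (eq[s - 1L]) { s <- s - 1L; adv <- TRUE }
      else if (step(s - 1L, -1L)) { mm <- mm + 1L; s <- s - 1L; adv <- TRUE }
    }
    if (!adv) break
  }
  while (s <= e && !eq[s]) { s <- s + 1L; mm <- mm - 1L }
  while (e >= s && !eq[e]) { e <- e - 1L; mm <- mm - 1L }
  if (s > e) return(NULL)
  list(start = s, end = e, mismatches = sum(!eq[s:e]))
}

# Longest suffix(a)-prefix(b) overlap >= min_overlap with identity >=
# min_identity.  Candidate overlap lengths come from shared k-mer
# diagonals (a hit at a-position i / b-position j implies overlap
# L = nchar(a) - i + j); each candidate is verified by edit distance.
# b_index may supply a precomputed kmer_index(b, k).
# Returns list(overlap_bp, identity) or NULL.
find_suffix_prefix <- function(a, b, min_overlap, min_identity, k = 21L,
                               b_index = NULL) {
  la <- nchar(a); lb <- nchar(b)
  cap <- min(la, lb)
  if (cap < min_overlap) return(NULL)
  bi <- b_index %||% kmer_index(b, k)
  hits <- kmer_hits(a, bi, k, stride = 2L)
  if (nrow(hits) == 0L) return(NULL)
  L <- la - hits$qpos + hits$tpos
  keep <- L >= min_overlap & L <= cap
  if (!any(keep)) return(NULL)
  cand <- sort(unique(L[keep]), decreasing = TRUE)
  for (Lc in cand) {
    idt <- segment_identity(substr(a, la - Lc + 1L, la), substr(b, 1L, Lc))
    if (idt >= min_identity) {
      return(list(overlap_bp = as.integer(Lc), identity = idt))
    }
  }
  NULL
}

# Is `b` (whole) contained in `a` at identity >= min_identity?  Candidate
# offsets from shared k-mer diagonals.  Returns list(offset, identity) of
# the best containment or NULL.
find_containment <- function(a, b, min_identity, k = 21L, a_index = NULL) {
  la <- nchar(a); lb <- nchar(b)
  if (lb > la) return(NULL)
  ai <- a_index %||% kmer_index(a, k)
  hits <- kmer_hits(b, ai, k, stride = max(1L, lb %/% 200L))
  if (nrow(hits) == 0L) return(NULL)
  offs <- sort(unique(hits$diag))
  offs <- offs[offs >= 0L & offs + lb <= la]
  if (length(offs) == 0L) return(NULL)
  support <- table(hits$diag)[as.character(offs)]
  offs <- offs[order(-as.integer(support))]
  for (d in head(offs, 5L)) {
    idt <- segment_identity(b, substr(a, d + 1L, d + lb))
    if (idt >= min_identity) return(list(offset = as.integer(d), identity = idt))
  }
  NULL
}

# Maximal local matches of `query` on `target` along exact diagonals
# (substitution-tolerant via extend_run; no indels across a match).
# Returns tibble(q_start, q_end, t_start, t_end, matches, mismatches),
# 0-based half-open, one row per diagonal cluster kept.
diagonal_matches <- function(query, target, target_index, k, stride,
                             min_len, max_rate) {
  hits <- kmer_hits(query, target_index, k, stride)
  if (nrow(hits) == 0L) return(empty_diag_matches())
  qc <- chars(query); tc <- chars(target)
  lq <- length(qc); lt <- length(tc)
  out <- list()
  gap_thresh <- max(100L, 4L * k)
  for (d in unique(hits$diag)) {
    qp <- sort(hits$qpos[hits$diag == d])
    # distinct hit runs on the same diagonal (e.g. period-n repeats of a
    # doubled circular sequence) are seeded separately
    grp <- cumsum(c(1L, diff(qp) > gap_thresh))
    qlo <- max(0L, -d); qhi <- min(lq - 1L, lt - 1L - d)
    if (qhi - qlo + 1L < min_len) next
    eq <- NULL
    for (g in unique(grp)) {
      h <- qp[grp == g]
      if ((max(h) + k - min(h)) < max(k, min_len %/% 4L)) next
      if (is.null(eq)) {
        qr <- qlo:qhi
        eq <- qc[qr + 1L] == tc[qr + d + 1L]
      }
      s <- max(1L, min(h) - qlo + 1L)
      e <- min(max(h) + k, qhi + 1L) - qlo
      run <- extend_run(eq, s, e, max_rate = max_rate)
      if (is.null(run)) next
      len <- run$end - run$start + 1L
      if (len < min_len) next
      q0 <- qlo + run$start - 1L
      out[[length(out) + 1L]] <- tibble(
        q_start = q0, q_end = q0 + len, t_start = q0 + d, t_end = q0 + d + len,
        matches = len - run$mismatches, mismatches = run$mismatches
      )
    }
  }
  if (length(out) == 0L) return(empty_diag_matches())
  res <- bind_rows(out)
  # drop matches wholly contained in a longer one on a different diagonal
  res <- arrange(res, desc(.data$q_end - .data$q_start))
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))[-1L]) {
    prior <- res[keep & seq_len(nrow(res)) < i, , drop = FALSE]
    if (any(prior$q_start <= res$q_start[i] & prior$q_end >= res$q_end[i] &
            prior$t_start <= res$t_start[i] & prior$t_end >= res$t_end[i])) {
      keep[i] <- FALSE
    }
  }
  res[keep, , drop = FALSE]
}

empty_diag_matches <- function() {
  tibble(q_start = integer(), q_end = integer(), t_start = integer(),
         t_end = integer(), matches = integer(), mismatches = integer())
}
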