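# Independent oracles and small fixture builders shared across the suite.
# The oracles deliberately re-derive results with the plainest possible
# code (loops, exhaustive scans) so they share nothing with the package's
# seeded/k-mer implementations.

# literal re-evaluation of the long-read classification rule
oracle_classify_long <- function(read_length, alns, params) {
  kept <- list()
  for (i in seq_len(nrow(alns))) {
    span <- alns$query_end[i] - alns$query_start[i]
    if (span >= params$min_record_query_bp) {
      kept[[length(kept) + 1L]] <- c(alns$query_start[i], alns$query_end[i])
    }
  }
  covered <- logical(read_length)
  for (iv in kept) {
    hi <- min(iv[2], read_length)
    if (iv[1] < hi) covered[(iv[1] + 1):hi] <- TRUE
  }
  # intervals may exceed the read length only in pathological fixtures
  total <- sum(covered)
  total >= params$min_total_query_bp &&
    (read_length > 0 && total / read_length >= params$min_query_fraction)
}

oracle_classify_batch <- function(reads, alignments, params) {
  out <- logical(nrow(reads))
  names(out) <- reads$id
  for (id in reads$id) {
    alns <- alignments[alignments$query_id == id, , drop = FALSE]
    len <- nchar(reads$bases[reads$id == id])
    out[id] <- oracle_classify_long(len, alns, params)
  }
  out
}

# exhaustive maximal exact inverted-repeat search: every diagonal of
# genome x reverse complement, longest run of agreement with the two
# copies disjoint on the circle.  Exact repeats only (mismatch-free).
oracle_max_inverted_repeat <- function(bases, min_len) {
  n <- nchar(bases)
  g <- strsplit(bases, "", fixed = TRUE)[[1]]
  r <- strsplit(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(bases))),
    "", fixed = TRUE)[[1]]
  best <- NULL
  for (d in (-(n - 1)):(n - 1)) {
    i0 <- max(1, 1 + d); i1 <- min(n, n + d)
    if (i1 - i0 + 1 < min_len) next
    eq <- g[i0:i1] == r[(i0 - d):(i1 - d)]
    rl <- rle(eq)
    ends <- cumsum(rl$lengths)
    for (k in which(rl$values & rl$lengths >= min_len)) {
      len <- rl$lengths[k]
      gi <- i0 + ends[k] - len         # 1-based start in g
      rj <- gi - d                     # 1-based start in r
      a0 <- gi - 1L                    # 0-based copy-1 start
      b0 <- n - (rj - 1L) - len        # 0-based copy-2 start
      # disjoint copies only (no wrapping in these fixtures)
      lo <- min(a0, b0); hi <- max(a0, b0)
      if (lo + len <= hi) {
        if (is.null(best) || len > best$len ||
              (len == best$len && lo < min(best$a0, best$b0))) {
          best <- list(len = len, a0 = lo, b0 = hi)
        }
      }
    }
  }
  best
}

# fraction of identical aligned positions for equal-length strings
ident_frac <- function(a, b) {
  if (nchar(a) != nchar(b)) return(0)
  mean(strsplit(a, "", fixed = TRUE)[[1]] == strsplit(b, "", fixed = TRUE)[[1]])
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# inject n_snp substitutions and n_indel 1-3 bp indels into a genome at
# roughly even, well-separated positions; returns the corrupted draft
make_corrupt_draft <- function(truth, n_snp = 20L, n_indel = 5L, seed = 1L) {
  set.seed(seed)
  n <- seq_length(truth)
  b <- strsplit(truth$bases, "", fixed = TRUE)[[1]]
  total <- n_snp + n_indel
  pos <- round(seq(150, n - 150, length.out = total) +
                 sample(-40:40, total, replace = TRUE))
  kinds <- sample(c(rep("snp", n_snp), rep("indel", n_indel)))
  for (i in rev(seq_along(pos))) {          # right-to-left keeps coordinates
    p <- pos[i]
    if (kinds[i] == "snp") {
      b[p] <- setdiff(c("A", "C", "G", "T"), b[p])[sample.int(3, 1)]
    } else if (runif(1) < 0.5) {
      L <- sample(1:3, 1)
      b <- b[-(p:(p + L - 1))]
    } else {
      L <- sample(1:3, 1)
      b <- append(b, sample(c("A", "C", "G", "T"), L, replace = TRUE),
                  after = p)
    }
  }
  nuc_seq("draft", paste(b, collapse = ""), circular = TRUE)
}

# canonical form of the truth genome from the simulator
canonical_truth <- function(sim) canonicalize(sim$seq, sim$structure)$seq$bases
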