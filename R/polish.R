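#' Parameters for pileup consensus polishing
#'
#' @param min_depth Minimum column depth to consider an edit (default 5).
#' @param min_support_fraction Minimum fraction of the column depth
#'   supporting the alternative allele (default 0.7; must be in (0.5, 1],
#'   and a column exactly at the threshold is accepted).
#' @param max_indel_bp Longest insertion/deletion considered (default 10).
#' @return A list of class `polish_params`.
#' @export
polish_params <- function(min_depth = 5L, min_support_fraction = 0.7,
                          max_indel_bp = 10L) {
  if (min_support_fraction <= 0.5 || min_support_fraction > 1) {
    abort("min_support_fraction must be in (0.5, 1]", class = "cpkit_usage_error")
  }
  structure(list(min_depth = as.integer(min_depth),
                 min_support_fraction = min_support_fraction,
                 max_indel_bp = as.integer(max_indel_bp)),
            class = "polish_params")
}

#' Align short reads to a draft sequence
#'
#' Built-in aligner for the polishing stage.  Each read is placed at
#' every well-supported location on the draft, in both orientations:
#' verbatim occurrences are found by exact multi-pattern matching, and
#' additional candidate locations seeded by exact k-mers are aligned with
#' a fast substitution/single-indel reconstruction (a banded pairwise
#' alignment serves as fallback for reads the reconstruction cannot
#' explain).  Reporting all near-exact locations matters in the inverted
#' repeats: a read drawn from one repeat copy that disagrees with the
#' draft would otherwise match the other copy exactly and carry its
#' evidence there, leaving errors inside repeats uncorrectable.  Circular
#' drafts are matched against the doubled sequence, so reads may span
#' the origin.
#'
#' @param draft A [nuc_seq()] (circular or linear).
#' @param reads Read tibble (`id`, `bases`).
#' @param k Seed k-mer size (default 21).
#' @param max_mm Maximum substitutions for a reconstructed placement
#'   (default 6); candidates beyond this fall back to pairwise alignment
#'   and are dropped if still unexplained.
#' @return Alignment tibble: `read_id`, `strand`, `ref_start` (0-based on
#'   the draft), `query_aln`, `ref_aln` (gapped strings).  Reads that
#'   could not be placed at all are omitted; their count is in attribute
#'   `n_unaligned`.
#' @export
align_short_reads <- function(draft, reads, k = 21L, max_mm = 6L) {
  stopifnot(inherits(draft, "nuc_seq"))
  validate_reads(reads)
  n <- seq_length(draft)
  d2 <- if (draft$circular) paste0(draft$bases, draft$bases) else draft$bases
  n2 <- nchar(d2)
  subj <- Biostrings::DNAString(d2)
  idx <- kmer_index(d2, k)
  d2c <- chars(d2)
  rcb <- revcomp_chr(reads$bases)
  acc <- new.env(parent = emptyenv())
  acc$read_id <- list(); acc$strand <- list(); acc$ref_start <- list()
  acc$qa <- list(); acc$ra <- list()
  push <- function(read_id, strand, ref_start, qa, ra) {
    i <- length(acc$read_id) + 1L
    acc$read_id[[i]] <- read_id
    acc$strand[[i]] <- rep(strand, length(read_id))
    acc$ref_start[[i]] <- ref_start
    acc$qa[[i]] <- qa
    acc$ra[[i]] <- ra
  }
  placed <- logical(nrow(reads))
  for (strand in c("+", "-")) {
    bo <- if (strand == "+") reads$bases else rcb
    # exact placements (all occurrences, deduplicated across the doubling)
    exact_starts <- vector("list", length(bo))
    for (w in unique(nchar(bo))) {
      sel <- which(nchar(bo) == w)
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(bo[sel]))
      st <- Biostrings::startIndex(Biostrings::matchPDict(pd, subj))
      for (j in seq_along(sel)) {
        s0 <- st[[j]]
        if (is.null(s0) || length(s0) == 0L) next
        s0 <- s0[s0 - 1L < n] - 1L
        exact_starts[[sel[j]]] <- s0
      }
      hit <- which(lengths(exact_starts[sel]) > 0L)
      if (length(hit)) {
        nh <- lengths(exact_starts[sel][hit])
        b <- rep(bo[sel][hit], nh)
        push(rep(reads$id[sel][hit], nh), strand,
             unlist(exact_starts[sel][hit]), b, b)
        placed[sel][hit] <- TRUE
      }
    }
    # seeded candidate diagonals beyond the exact placements; one batched
    # index lookup for all seeds of all reads
    widths <- nchar(bo)
    seedable <- which(widths >= k)
    if (length(seedable)) {
      sp1 <- rep(0L, length(seedable))
      sp2 <- (widths[seedable] - k) %/% 2L
      sp3 <- widths[seedable] - k
      all_q <- c(sp1, sp2, sp3)
      all_i <- rep(seedable, 3L)
      km <- substring(bo[all_i], all_q + 1L, all_q + k)
      hit <- idx[km]
      nh <- lengths(hit)
      qpos_all <- rep.int(all_q, nh)
      ridx_all <- rep.int(all_i, nh)
      tpos_all <- unlist(hit, use.names = FALSE)
      if (!is.null(tpos_all) && length(tpos_all)) {
        diag_all <- as.integer(tpos_all) - qpos_all
        ok <- diag_all >= 0L & diag_all < n
        by_read <- split(data.frame(qpos = qpos_all[ok], diag = diag_all[ok]),
                         ridx_all[ok])
        for (nm in names(by_read)) {
          i <- as.integer(nm)
          h <- by_read[[nm]]
          keep <- !(h$diag %in% exact_starts[[i]])
          if (!any(keep)) next
          h <- h[keep, , drop = FALSE]
          w <- widths[i]
          rc_ <- resolve_candidate(bo[i], w, h$qpos, h$diag, d2c, n2, max_mm)
          cand <- rc_$aln
          if (is.null(cand)) {
            # fall back to full pairwise alignment only when the candidate
            # shows near-full-length homology; partial mirror matches at
            # repeat boundaries and low-complexity seed collisions do not
            if (rc_$min_mm > min(w %/% 4L, 2L * max_mm)) next
            cand <- fallback_align(bo[i], sort(h$diag)[1L], d2, n2)
            if (is.null(cand)) next
          }
          push(reads$id[i], strand, cand$ref_start, cand$qa, cand$ra)
          placed[i] <- TRUE
        }
      }
    }
  }
  out <- tibble(
    read_id = as.character(unlist(acc$read_id)),
    strand = as.character(unlist(acc$strand)),
    ref_start = as.integer(unlist(acc$ref_start)),
    query_aln = as.character(unlist(acc$qa)),
    ref_aln = as.character(unlist(acc$ra)))
  if (nrow(out) && any(out$ref_start >= n)) {
    out <- out[out$ref_start < n, , drop = FALSE]
  }
  attr(out, "n_unaligned") <- sum(!placed)
  out
}

# Reconstruct an alignment of read b near the candidate diagonal(s).
# Gapless and single-indel (size 1..max_delta, split chosen to maximize
# matches, ties broken leftmost so indels are left-normalized across
# reads) alignments are scored as substitutions + an affine gap cost and
# the cheapest is returned.  Returns list(ref_start, qa, ra) or NULL when
# even the best explanation has more than max_mm substitutions.
resolve_candidate <- function(b, w, qpos, diag, d2c, n2, max_mm,
                              max_delta = 10L) {
  bc <- chars(b)
  gap_cost <- function(delta) if (delta == 0L) 0 else 1.5 + 0.25 * abs(delta)
  # eq vector cache over diagonals near d1
  eq_at <- local({
    cache <- list()
    function(d) {
      key <- as.character(d)
      if (is.null(cache[[key]])) {
        if (d < 0L || d + w > n2) return(NULL)
        cache[[key]] <<- bc == d2c[(d + 1L):(d + w)]
      }
      cache[[key]]
    }
  })
  best <- NULL
  min_mm_seen <- w
  consider <- function(cost, mm, fn) {
    min_mm_seen <<- min(min_mm_seen, mm)
    if (mm <= max_mm && (is.null(best) || cost < best$cost)) {
      best <<- list(cost = cost, mm = mm, build = fn)
    }
  }
  base_diags <- sort(unique(diag))
  for (d in base_diags) {
    eq <- eq_at(d)
    if (is.null(eq)) next
    mm <- w - sum(eq)
    consider(mm, mm, local({
      d0 <- d
      function() list(ref_start = d0, qa = b,
                      ra = paste(d2c[(d0 + 1L):(d0 + w)], collapse = ""))
    }))
  }
  # single-indel alternatives are only worth trying when gapless is imperfect
  if (is.null(best) || best$mm > 1L) {
    deltas <- setdiff(seq.int(-min(max_delta, w %/% 2L),
                              min(max_delta, w %/% 2L)), 0L)
    # an observed diagonal may be either flank of the indel, so try it as
    # the left diagonal and as the right one (left = observed - delta)
    for (delta in deltas) for (d1 in unique(c(base_diags, base_diags - delta))) {
      dR <- d1 + delta
      eqL <- eq_at(d1); eqR <- eq_at(dR)
      if (is.null(eqL) || is.null(eqR) || d1 + w + max(delta, 0L) > n2) next
      pm <- c(0L, cumsum(eqL))            # pm[s+1]: matches in first s at d1
      sm <- c(rev(cumsum(rev(eqR))), 0L)  # sm[j+1]: matches in (j+1)..w at dR
      if (delta > 0L) {
        svals <- 1L:(w - 1L)
        score <- pm[svals + 1L] + sm[svals + 1L]
        s <- svals[which.max(score)]
        mm <- w - max(score)
        consider(mm + gap_cost(delta), mm, local({
          s0 <- s; delta0 <- delta; d10 <- d1
          function() list(
            ref_start = d10,
            qa = paste0(substr(b, 1L, s0), strrep("-", delta0),
                        substr(b, s0 + 1L, w)),
            ra = paste(d2c[(d10 + 1L):(d10 + w + delta0)], collapse = ""))
        }))
      } else {
        ins <- -delta
        if (ins >= w - 1L) next
        svals <- 1L:(w - ins - 1L)
        score <- pm[svals + 1L] + sm[svals + ins + 1L]
        s <- svals[which.max(score)]
        mm <- (w - ins) - max(score)
        consider(mm + gap_cost(delta), mm, local({
          s0 <- s; ins0 <- ins; dR0 <- dR; d10 <- d1
          function() list(
            ref_start = d10,
            qa = b,
            ra = paste0(paste(d2c[(d10 + 1L):(d10 + s0)], collapse = ""),
                        strrep("-", ins0),
                        paste(d2c[(dR0 + s0 + ins0 + 1L):(dR0 + w)],
                              collapse = "")))
        }))
      }
    }
  }
  if (is.null(best)) return(list(aln = NULL, min_mm = min_mm_seen))
  list(aln = best$build(), min_mm = best$mm)
}

# banded pairwise alignment fallback around one candidate diagonal
fallback_align <- function(b, offset, d2, n2) {
  w <- nchar(b)
  pad <- 16L
  ws <- max(0L, offset - pad)
  we <- min(n2, offset + w + pad)
  if (we - ws < w %/% 2L) return(NULL)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(b),
    Biostrings::DNAString(substr(d2, ws + 1L, we)),
    type = "global-local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -4, baseOnly = FALSE),
    gapOpening = 6, gapExtension = 2)
  qa <- as.character(Biostrings::alignedPattern(pa))
  ra <- as.character(Biostrings::alignedSubject(pa))
  if (Biostrings::score(pa) < w) return(NULL)   # mostly-matching reads only
  list(ref_start = ws + IRanges::start(Biostrings::subject(pa)) - 1L,
       qa = qa, ra = ra)
}

#' Build a pileup from placed read alignments
#'
#' Tallies per-column base counts, spanning deletions and inserted strings
#' from gapped read alignments on a draft.  On a circular draft, positions
#' wrap modulo the length, so reads spanning the origin cover both flanks.
#' Every column satisfies `depth = A + C + G + T + N + del`.
#'
#' @param draft A [nuc_seq()].
#' @param alns Alignment tibble from [align_short_reads()] (or a
#'   PAF table whose `qa:Z:`/`ra:Z:` tags were loaded into
#'   `query_aln`/`ref_aln`, with `ref_start`).
#' @return Object of class `pileup`: list with `columns` (tibble:
#'   `position`, `depth`, `A`, `C`, `G`, `T`, `N`, `del`), `insertions`
#'   (tibble: `position`, `inserted`, `count`; an insertion sits before
#'   `position`) and `n`.
#' @export
build_pileup <- function(draft, alns) {
  stopifnot(inherits(draft, "nuc_seq"))
  n <- seq_length(draft)
  need <- setdiff(c("ref_start", "query_aln", "ref_aln"), names(alns))
  if (length(need)) {
    abort(paste0("alignments lack pileup columns: ", paste(need, collapse = ", ")),
          class = "cpkit_input_error")
  }
  span <- nchar(gsub("-", "", alns$ref_aln, fixed = TRUE))
  if (!draft$circular && nrow(alns) && any(alns$ref_start + span > n)) {
    abort("alignment extends past the end of a linear draft",
          class = "cpkit_input_error")
  }
  counts <- matrix(0L, nrow = 5L, ncol = n,
                   dimnames = list(c("A", "C", "G", "T", "N"), NULL))
  del <- integer(n)
  ins <- list()
  dc <- chars(draft$bases)
  exact <- alns$query_aln == alns$ref_aln
  # exact reads: interval coverage, then spread onto the draft's own bases
  if (any(exact)) {
    s <- alns$ref_start[exact]
    L <- span[exact]
    e <- s + L
    wrap <- e > n
    from <- c(s, rep(0L, sum(wrap)))
    to <- c(pmin(e, n), e[wrap] - n)
    dd <- tabulate(from + 1L, nbins = n + 1L) - tabulate(to + 1L, nbins = n + 1L)
    cov <- cumsum(dd[seq_len(n)])
    for (b in rownames(counts)) {
      ix <- which(dc == b)
      counts[b, ix] <- counts[b, ix] + as.integer(cov[ix])
    }
  }
  # gapped / mismatching reads: walk columns
  for (i in which(!exact)) {
    qa <- chars(alns$query_aln[i])
    ra <- chars(alns$ref_aln[i])
    isref <- ra != "-"
    rpos <- (alns$ref_start[i] + cumsum(isref) - 1L) %% n
    # base and deletion columns
    base_cols <- which(isref & qa != "-")
    for (jj in base_cols) {
      counts[qa[jj], rpos[jj] + 1L] <- counts[qa[jj], rpos[jj] + 1L] + 1L
    }
    del_cols <- which(isref & qa == "-")
    del[rpos[del_cols] + 1L] <- del[rpos[del_cols] + 1L] + 1L
    # insertion runs: recorded before the next reference column
    if (any(!isref)) {
      r <- rle(isref)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (g in which(!r$values)) {
        colrange <- starts[g]:ends[g]
        nxt <- if (ends[g] < length(isref)) rpos[ends[g] + 1L]
               else (alns$ref_start[i] + sum(isref)) %% n
        ins[[length(ins) + 1L]] <- tibble(
          position = as.integer(nxt),
          inserted = paste(qa[colrange], collapse = ""))
      }
    }
  }
  ins_tbl <- if (length(ins)) {
    bind_rows(ins) %>%
      group_by(.data$position, .data$inserted) %>%
      summarise(count = dplyr::n(), .groups = "drop")
  } else {
    tibble(position = integer(), inserted = character(), count = integer())
  }
  columns <- tibble(position = 0:(n - 1L), depth = colSums(counts) + del,
                    A = counts["A", ], C = counts["C", ], G = counts["G", ],
                    T = counts["T", ], N = counts["N", ], del = del)
  structure(list(columns = columns, insertions = ins_tbl, n = n,
                 circular = draft$circular),
            class = "pileup")
}

#' Call consensus edits from a pileup
#'
#' At every column with depth at least `min_depth`, if the plurality allele
#' (a base, a spanning deletion, or an inserted string) differs from the
#' draft and its support fraction is at least `min_support_fraction`
#' (ties at the threshold accepted), the corresponding edit is emitted.
#' Adjacent deletion columns are merged into one multi-base deletion;
#' indels longer than `max_indel_bp` are ignored.
#'
#' @param pileup A [build_pileup()] result.
#' @param draft The [nuc_seq()] the pileup was built on.
#' @param params [polish_params()].
#' @return Edits tibble: `position` (0-based), `kind` (`snp`/`ins`/`del`),
#'   `ref_allele`, `alt_allele`, `support_fraction`, `depth`.  An `ins`
#'   inserts `alt_allele` before `position`; a `del` removes `ref_allele`
#'   starting at `position`.
#' @export
call_edits <- function(pileup, draft, params = polish_params()) {
  stopifnot(inherits(pileup, "pileup"), inherits(draft, "nuc_seq"))
  if (pileup$n != seq_length(draft)) {
    abort("pileup and draft lengths differ", class = "cpkit_input_error")
  }
  cols <- pileup$columns
  dc <- chars(draft$bases)
  am <- rbind(A = cols$A, C = cols$C, G = cols$G, T = cols$T, N = cols$N,
              del = cols$del)
  alleles <- rownames(am)
  eligible <- cols$depth >= params$min_depth
  win_idx <- apply(am, 2L, which.max)
  win_cnt <- am[cbind(win_idx, seq_len(ncol(am)))]
  draft_cnt <- am[cbind(match(dc, alleles), seq_len(ncol(am)))]
  winner <- alleles[win_idx]
  support <- ifelse(cols$depth > 0, win_cnt / cols$depth, 0)
  is_edit <- eligible & winner != dc & win_cnt > draft_cnt &
    support >= params$min_support_fraction
  snp_pos <- which(is_edit & winner != "del") - 1L
  del_pos <- which(is_edit & winner == "del") - 1L
  edits <- list()
  if (length(snp_pos)) {
    edits[[length(edits) + 1L]] <- tibble(
      position = snp_pos, kind = "snp", ref_allele = dc[snp_pos + 1L],
      alt_allele = winner[snp_pos + 1L],
      support_fraction = support[snp_pos + 1L],
      depth = cols$depth[snp_pos + 1L])
  }
  if (length(del_pos)) {
    grp <- cumsum(c(1L, diff(del_pos) != 1L))
    for (g in unique(grp)) {
      p <- del_pos[grp == g]
      if (length(p) > params$max_indel_bp) next
      edits[[length(edits) + 1L]] <- tibble(
        position = p[1L], kind = "del",
        ref_allele = paste(dc[p + 1L], collapse = ""), alt_allele = "",
        support_fraction = min(support[p + 1L]),
        depth = min(cols$depth[p + 1L]))
    }
  }
  ins <- pileup$insertions
  if (nrow(ins)) {
    ins <- ins %>%
      mutate(depth = cols$depth[.data$position + 1L],
             support_fraction = ifelse(.data$depth > 0,
                                       .data$count / .data$depth, 0)) %>%
      filter(.data$depth >= params$min_depth,
             nchar(.data$inserted) <= params$max_indel_bp,
             .data$support_fraction >= params$min_support_fraction) %>%
      group_by(.data$position) %>%
      arrange(desc(.data$count), .data$inserted) %>%
      dplyr::slice(1L) %>%
      ungroup()
    if (nrow(ins)) {
      edits[[length(edits) + 1L]] <- tibble(
        position = as.integer(ins$position), kind = "ins", ref_allele = "",
        alt_allele = ins$inserted, support_fraction = ins$support_fraction,
        depth = as.integer(ins$depth))
    }
  }
  out <- if (length(edits)) arrange(bind_rows(edits), .data$position) else
    tibble(position = integer(), kind = character(), ref_allele = character(),
           alt_allele = character(), support_fraction = numeric(),
           depth = integer())
  out
}

#' Apply edits to a draft sequence
#'
#' Edits must be non-overlapping; they are applied in descending position
#' order so earlier coordinates stay valid.  The output length equals the
#' input length plus the net indel size.
#'
#' @param draft A [nuc_seq()].
#' @param edits Edits tibble from [call_edits()].
#' @return The edited [nuc_seq()].
#' @export
apply_edits <- function(draft, edits) {
  stopifnot(inherits(draft, "nuc_seq"))
  if (nrow(edits) == 0L) return(draft)
  iv <- tibble(start = edits$position,
               end = edits$position + nchar(edits$ref_allele),
               kind = edits$kind) %>% arrange(.data$start, .data$end)
  if (nrow(iv) > 1L) {
    bad <- which(iv$start[-1L] < iv$end[-nrow(iv)] &
                   !(iv$kind[-1L] == "ins" & iv$start[-1L] >= iv$end[-nrow(iv)]))
    if (length(bad)) {
      abort(sprintf("overlapping edits at positions %d and %d",
                    iv$start[bad[1L]], iv$start[bad[1L] + 1L]),
            class = "cpkit_input_error")
    }
  }
  s <- draft$bases
  ord <- order(edits$position, decreasing = TRUE)
  for (i in ord) {
    p <- edits$position[i]
    ref <- edits$ref_allele[i]
    alt <- edits$alt_allele[i]
    if (nzchar(ref) &&
        substr(s, p + 1L, p + nchar(ref)) != ref) {
      abort(sprintf("edit at position %d does not match the draft (%s)",
                    p, ref), class = "cpkit_input_error")
    }
    s <- paste0(substr(s, 1L, p), alt, substr(s, p + nchar(ref) + 1L, nchar(s)))
  }
  out <- draft
  out$bases <- s
  out
}

#' Polish a draft genome with short reads
#'
#' Pileup consensus polishing: short reads are aligned to the draft
#' ([align_short_reads()], or a precomputed alignment table), a pileup is
#' built, edits are called by plurality with a support threshold, and the
#' edits are applied.  Circular drafts are polished in circular
#' coordinates, so reads may wrap the origin and no artifacts arise there.
#' Deterministic for fixed inputs.
#'
#' @param draft A [nuc_seq()].
#' @param reads Read tibble (ignored when `alignments` is supplied).
#' @param params [polish_params()].
#' @param rounds Maximum polishing rounds (default 1); iteration stops
#'   early once a round produces no edits.
#' @param alignments Optional precomputed alignment tibble (see
#'   [build_pileup()]); used for the first round only.
#' @return Object of class `polish_result`: `seq` (polished [nuc_seq()]),
#'   `edits` (tibble with a `round` column), `n_reads_aligned`,
#'   `rounds_run`.
#' @export
polish <- function(draft, reads = NULL, params = polish_params(), rounds = 1L,
                   alignments = NULL) {
  stopifnot(inherits(draft, "nuc_seq"))
  cur <- draft
  all_edits <- list()
  n_aligned <- NA_integer_
  r_done <- 0L
  for (r in seq_len(rounds)) {
    aln <- if (r == 1L && !is.null(alignments)) alignments
           else align_short_reads(cur, reads)
    if (nrow(aln) == 0L) {
      abort("no reads aligned to the draft", class = "cpkit_stage_error")
    }
    if (r == 1L) n_aligned <- length(unique(aln$read_id))
    pu <- build_pileup(cur, aln)
    ed <- call_edits(pu, cur, params)
    r_done <- r
    if (nrow(ed) == 0L) break
    all_edits[[r]] <- mutate(ed, round = r)
    cur <- apply_edits(cur, ed)
  }
  structure(list(
    seq = cur,
    edits = if (length(all_edits)) bind_rows(all_edits) else
      tibble(position = integer(), kind = character(), ref_allele = character(),
             alt_allele = character(), support_fraction = numeric(),
             depth = integer(), round = integer()),
    n_reads_aligned = n_aligned, rounds_run = r_done),
    class = "polish_result")
}

#' @export
print.polish_result <- function(x, ...) {
  cat(sprintf("<polish_result> %d edit(s) over %d round(s); %d reads aligned\n",
              nrow(x$edits), x$rounds_run, x$n_reads_aligned))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.polish_result <- function(x, ...) x$edits

#' @exportS3Method generics::glance
glance.polish_result <- function(x, ...) {
  tibble(n_edits = nrow(x$edits),
         n_snp = sum(x$edits$kind == "snp"),
         n_ins = sum(x$edits$kind == "ins"),
         n_del = sum(x$edits$kind == "del"),
         n_reads_aligned = x$n_reads_aligned,
         rounds_run = x$rounds_run,
         length_bp = seq_length(x$seq))
}
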