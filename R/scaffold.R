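#' Parameters for reference-guided scaffolding
#'
#' @param min_anchor_bp Minimum placed span for a contig anchor
#'   (default 500).
#' @param min_identity Minimum anchor identity (default 0.95).
#' @param min_join_overlap_bp Smallest suffix-prefix overlap expected
#'   between neighbouring contigs (default 30).
#' @param max_gap_bp Largest reference gap tolerated in a complete layout;
#'   gaps are N-filled at the reference-estimated size (default 5000).
#' @param kmer_size Anchor seed size (default 17).
#' @return A list of class `scaffold_params`.
#' @export
scaffold_params <- function(min_anchor_bp = 500L, min_identity = 0.95,
                            min_join_overlap_bp = 30L, max_gap_bp = 5000L,
                            kmer_size = 17L) {
  p <- list(min_anchor_bp = as.integer(min_anchor_bp),
            min_identity = min_identity,
            min_join_overlap_bp = as.integer(min_join_overlap_bp),
            max_gap_bp = as.integer(max_gap_bp),
            kmer_size = as.integer(kmer_size))
  if (any(unlist(p) < 0)) {
    abort("scaffold parameters must be >= 0", class = "cpkit_usage_error")
  }
  structure(p, class = "scaffold_params")
}

#' Anchor contigs on a reference genome
#'
#' Reports every placement of each contig on the reference with span at
#' least `min_anchor_bp` and identity at least `min_identity`, found by
#' shared-k-mer seeding, diagonal chaining and mismatch-tolerant
#' extension.  A contig homologous to the inverted repeat yields two
#' placements, one per IR copy on opposite strands; a contig may also
#' yield a partial placement covering only the IR-homologous part of its
#' sequence.  Contigs with no placement are simply absent from the result
#' (not fatal).
#'
#' @param contigs List of [nuc_seq()] contigs.
#' @param reference Canonical-form [nuc_seq()] reference.
#' @param ref_structure [quadripartite_structure()] of the reference (used
#'   downstream; anchoring itself is structure-agnostic).
#' @param params [scaffold_params()].
#' @return Placement tibble: `contig_id`, `query_start`, `query_end`
#'   (0-based on the original contig), `ref_start`, `ref_end`, `strand`,
#'   `identity`, `query_coverage`.
#' @export
anchor_contigs <- function(contigs, reference, ref_structure = NULL,
                           params = scaffold_params()) {
  contigs <- as_contig_list(contigs)
  stopifnot(inherits(reference, "nuc_seq"))
  idx <- kmer_index(reference$bases, params$kmer_size)
  max_rate <- max(0.001, 1 - params$min_identity)
  out <- list()
  for (id in names(contigs)) {
    len <- seq_length(contigs[[id]])
    stride <- max(1L, len %/% 500L)
    for (strand in c("+", "-")) {
      b <- oriented_bases(contigs[[id]], strand)
      m <- diagonal_matches(b, reference$bases, idx, params$kmer_size,
                            stride, params$min_anchor_bp, max_rate)
      if (nrow(m) == 0L) next
      idt <- m$matches / (m$q_end - m$q_start)
      keep <- idt >= params$min_identity
      m <- m[keep, , drop = FALSE]
      idt <- idt[keep]
      if (nrow(m) == 0L) next
      qs <- if (strand == "+") m$q_start else len - m$q_end
      qe <- if (strand == "+") m$q_end else len - m$q_start
      out[[length(out) + 1L]] <- tibble(
        contig_id = id, query_start = qs, query_end = qe,
        ref_start = m$t_start, ref_end = m$t_end, strand = strand,
        identity = idt, query_coverage = (m$q_end - m$q_start) / len)
    }
  }
  if (length(out) == 0L) {
    return(tibble(contig_id = character(), query_start = integer(),
                  query_end = integer(), ref_start = integer(),
                  ref_end = integer(), strand = character(),
                  identity = numeric(), query_coverage = numeric()))
  }
  bind_rows(out) %>% arrange(.data$ref_start, .data$contig_id)
}

# fraction of a placement's reference span inside either IR interval
ir_span_fraction <- function(ref_start, ref_end, ref_structure) {
  ira <- region_interval(ref_structure, "ira")
  irb <- region_interval(ref_structure, "irb")
  ov <- function(iv) pmax(0L, pmin(ref_end, iv[2L]) - pmax(ref_start, iv[1L]))
  (ov(ira) + ov(irb)) / (ref_end - ref_start)
}

#' Select and order placements into a scaffold layout
#'
#' Placements are ranked by identity times aligned length (ties broken by
#' contig id, then reference start) and accepted greedily whenever they
#' cover enough still-uncovered reference bases.  Because an IR-homologous
#' contig anchors at both IR copies, this rule places it twice — once per
#' repeat, on opposite strands — which is how single-copy contigs from a
#' repeat-collapsed assembly are reused to restore both inverted repeats.
#' A contig appearing twice with essentially the same query interval is
#' only allowed when both placements lie (>= 80% of their span) inside the
#' IR intervals; otherwise the lower-scoring placement is dropped with a
#' warning, as are accepted placements conflicting with a higher-scoring
#' overlapping placement on a discordant strand.
#'
#' Neighbouring placements are annotated with their implied suffix-prefix
#' overlap or gap, and the layout is complete when every reference base is
#' covered or inside a gap of at most `max_gap_bp`.
#'
#' @param placements Tibble from [anchor_contigs()].
#' @param ref_structure [quadripartite_structure()] of the reference.
#' @param params [scaffold_params()].
#' @return Object of class `scaffold_layout`: list with `placements`
#'   (accepted, ordered, with `join_type`/`join_bp` to the next placement,
#'   circularly), `reference_length`, `is_complete`, `uncovered` (tibble
#'   of reference intervals no accepted placement covers).
#' @export
select_and_order <- function(placements, ref_structure,
                             params = scaffold_params()) {
  n <- attr(ref_structure, "genome_length")
  pl <- placements %>%
    mutate(score = .data$identity * (.data$ref_end - .data$ref_start)) %>%
    arrange(desc(.data$score), .data$contig_id, .data$ref_start)
  covered <- logical(n)
  acc <- list()
  for (i in seq_len(nrow(pl))) {
    p <- pl[i, ]
    iv <- (p$ref_start + 1L):p$ref_end
    new_bp <- sum(!covered[iv])
    if (new_bp < params$min_anchor_bp) next
    # duplicate-placement rule
    dup_ok <- TRUE
    for (a in acc) {
      if (a$contig_id != p$contig_id) next
      jac <- interval_jaccard(c(p$query_start, p$query_end),
                              c(a$query_start, a$query_end))
      if (jac >= 0.8) {
        fr_new <- ir_span_fraction(p$ref_start, p$ref_end, ref_structure)
        fr_old <- ir_span_fraction(a$ref_start, a$ref_end, ref_structure)
        if (fr_new < 0.8 || fr_old < 0.8) {
          warn(sprintf(
            "dropping duplicate non-IR placement of contig '%s' at [%d,%d)",
            p$contig_id, p$ref_start, p$ref_end))
          dup_ok <- FALSE
        }
      }
    }
    if (!dup_ok) next
    # discordant-strand conflict with an accepted overlapping placement
    conflict <- FALSE
    for (a in acc) {
      ovl <- min(p$ref_end, a$ref_end) - max(p$ref_start, a$ref_start)
      if (ovl > 0.5 * (p$ref_end - p$ref_start) && a$strand != p$strand &&
          a$contig_id == p$contig_id) {
        conflict <- TRUE
      }
    }
    if (conflict) {
      warn(sprintf("dropping strand-discordant placement of contig '%s'",
                   p$contig_id))
      next
    }
    covered[iv] <- TRUE
    acc[[length(acc) + 1L]] <- p
  }
  acc <- if (length(acc)) bind_rows(acc) else pl[0L, ]
  acc <- arrange(acc, .data$ref_start, .data$ref_end, .data$contig_id)
  m <- nrow(acc)
  join_type <- character(m)
  join_bp <- integer(m)
  if (m > 0L) {
    nxt_start <- c(acc$ref_start[-1L], n + acc$ref_start[1L])
    d <- nxt_start - acc$ref_end
    join_type <- ifelse(d < 0L, "overlap", ifelse(d > 0L, "gap", "abut"))
    join_bp <- abs(d)
  }
  acc$join_type <- join_type
  acc$join_bp <- as.integer(join_bp)
  unc <- uncovered_intervals(covered)
  gaps_ok <- m > 0L && (nrow(unc) == 0L ||
                          all(unc$end - unc$start <= params$max_gap_bp))
  structure(list(placements = select(acc, -"score"),
                 reference_length = n,
                 is_complete = gaps_ok,
                 uncovered = unc),
            class = "scaffold_layout")
}

interval_jaccard <- function(a, b) {
  inter <- max(0L, min(a[2L], b[2L]) - max(a[1L], b[1L]))
  uni <- max(a[2L], b[2L]) - min(a[1L], b[1L])
  if (uni <= 0L) 0 else inter / uni
}

uncovered_intervals <- function(covered) {
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  tibble(start = starts[!r$values], end = ends[!r$values])
}

#' @export
print.scaffold_layout <- function(x, ...) {
  cat(sprintf("<scaffold_layout> %d placement(s) on %d bp reference; complete=%s\n",
              nrow(x$placements), x$reference_length, x$is_complete))
  print(x$placements, n = 10)
  invisible(x)
}

#' Join an ordered layout into a circular genome sequence
#'
#' Neighbouring contigs are concatenated through their implied overlap
#' (overlap bases emitted once, verified at `min_identity`; an
#' irreconcilable junction is an error naming the pair), reference gaps
#' are filled with N at the estimated size, and the last placement joins
#' back to the first through the same rule, closing the circle.  A
#' placement on the minus strand contributes the reverse complement of its
#' query interval, so the second instance of a duplicated IR contig is
#' emitted reverse-complemented.
#'
#' @param layout A complete [select_and_order()] layout.
#' @param contigs The contig list the layout places.
#' @return A circular [nuc_seq()] (id `"scaffold"`).
#' @export
join_layout <- function(layout, contigs) {
  stopifnot(inherits(layout, "scaffold_layout"))
  contigs <- as_contig_list(contigs)
  if (!layout$is_complete) {
    abort("layout is not complete; cannot join", class = "cpkit_stage_error")
  }
  pl <- layout$placements
  pieces <- character()
  piece_of <- function(i) {
    p <- pl[i, ]
    s <- substr(contigs[[p$contig_id]]$bases, p$query_start + 1L, p$query_end)
    if (p$strand == "-") s <- revcomp_chr(s)
    s
  }
  cur_pieces <- map_chr(seq_len(nrow(pl)), piece_of)
  out <- character(nrow(pl) * 2L)
  for (i in seq_len(nrow(pl))) {
    piece <- cur_pieces[i]
    prev <- if (i == 1L) nrow(pl) else i - 1L
    jt <- pl$join_type[prev]
    jb <- pl$join_bp[prev]
    if (i == 1L) {
      # the closing junction is handled at the end of the walk
      out[2L * i] <- piece
      next
    }
    if (jt == "overlap") {
      a <- cur_pieces[prev]
      idt <- segment_identity(substr(a, nchar(a) - jb + 1L, nchar(a)),
                              substr(piece, 1L, jb))
      if (idt < 0.9) {
        abort(sprintf("join between '%s' and '%s' fails overlap verification (identity %.3f over %d bp)",
                      pl$contig_id[prev], pl$contig_id[i], idt, jb),
              class = "cpkit_stage_error")
      }
      piece <- substr(piece, jb + 1L, nchar(piece))
    } else if (jt == "gap" && jb > 0L) {
      out[2L * i - 1L] <- strrep("N", jb)
    }
    out[2L * i] <- piece
  }
  # closing junction: last placement joins back to the first
  jt <- pl$join_type[nrow(pl)]
  jb <- pl$join_bp[nrow(pl)]
  closing_gap <- ""
  if (jt == "overlap" && jb > 0L) {
    a <- cur_pieces[nrow(pl)]
    first <- out[2L]
    idt <- segment_identity(substr(a, nchar(a) - jb + 1L, nchar(a)),
                            substr(first, 1L, jb))
    if (idt < 0.9) {
      abort(sprintf("closing join between '%s' and '%s' fails verification",
                    pl$contig_id[nrow(pl)], pl$contig_id[1L]),
            class = "cpkit_stage_error")
    }
    out[2L] <- substr(first, jb + 1L, nchar(first))
  } else if (jt == "gap" && jb > 0L) {
    closing_gap <- strrep("N", jb)
  }
  nuc_seq("scaffold", paste0(paste(out, collapse = ""), closing_gap),
          circular = TRUE)
}

#' Reference-guided scaffolding of fragmented contigs
#'
#' Runs [anchor_contigs()], [select_and_order()] and [join_layout()] in
#' sequence; deterministic.  An incomplete layout (uncovered reference
#' intervals beyond `max_gap_bp`) is an error listing the intervals.
#'
#' @param contigs List of [nuc_seq()] contigs (e.g. from a short-read
#'   assembler with the repeat collapsed).
#' @param reference Canonical-form [nuc_seq()] reference genome.
#' @param ref_structure [quadripartite_structure()] of the reference;
#'   detected from the reference when `NULL`.
#' @param params [scaffold_params()].
#' @return Object of class `scaffold_result`: `seq` (circular
#'   [nuc_seq()]), `layout` ([select_and_order()] result), `placements`
#'   (all anchor placements).
#' @export
scaffold <- function(contigs, reference, ref_structure = NULL,
                     params = scaffold_params()) {
  stopifnot(inherits(reference, "nuc_seq"))
  if (is.null(ref_structure)) {
    circ <- nuc_seq(reference$id, reference$bases, circular = TRUE)
    ref_structure <- detect_quadripartite(circ)
  }
  placements <- anchor_contigs(contigs, reference, ref_structure, params)
  layout <- select_and_order(placements, ref_structure, params)
  if (!layout$is_complete) {
    unc <- layout$uncovered
    abort(paste0("scaffold incomplete; uncovered reference intervals: ",
                 paste(sprintf("[%d,%d)", unc$start, unc$end), collapse = ", ")),
          class = "cpkit_stage_error")
  }
  seqo <- join_layout(layout, contigs)
  structure(list(seq = seqo, layout = layout, placements = placements),
            class = "scaffold_result")
}

#' @export
print.scaffold_result <- function(x, ...) {
  cat(sprintf("<scaffold_result> %d bp circular scaffold from %d placement(s)\n",
              seq_length(x$seq), nrow(x$layout$placements)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.scaffold_result <- function(x, ...) x$layout$placements

#' @exportS3Method generics::glance
glance.scaffold_result <- function(x, ...) {
  tibble(length_bp = seq_length(x$seq),
         n_placements = nrow(x$layout$placements),
         n_contigs_used = length(unique(x$layout$placements$contig_id)),
         n_gap_bp = sum(x$layout$placements$join_bp[
           x$layout$placements$join_type == "gap"]),
         is_complete = x$layout$is_complete)
}
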