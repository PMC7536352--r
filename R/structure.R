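#' Quadripartite plastome structure
#'
#' The canonical plastome layout: a large single-copy region (LSC), a small
#' single-copy region (SSC) and two near-identical inverted repeats (IRA,
#' IRB) separating them, in the cyclic order LSC, IRA, SSC, IRB.  By
#' convention IRA is the IR copy immediately following the LSC.  Intervals
#' are 0-based half-open on the genome they describe; an interval of a
#' region that wraps the origin is stored with `end > genome_length`
#' (taken modulo the length), which [canonicalize()] resolves.
#'
#' @param lsc,ira,ssc,irb Two-element integer vectors `c(start, end)`.
#' @param genome_length Genome length in bp.
#' @param ir_mismatches Substitution differences between IRA and the
#'   reverse complement of IRB under end-anchored comparison.
#' @return Object of class `quadripartite_structure`: a tibble with
#'   columns `region`, `start`, `end`, `length`, plus attributes
#'   `genome_length` and `ir_mismatches`.
#' @examples
#' quadripartite_structure(c(0, 20000), c(20000, 26000),
#'                         c(26000, 29000), c(29000, 35000), 35000)
#' @export
quadripartite_structure <- function(lsc, ira, ssc, irb, genome_length,
                                    ir_mismatches = 0L) {
  regions <- tibble(
    region = c("lsc", "ira", "ssc", "irb"),
    start = as.integer(c(lsc[1L], ira[1L], ssc[1L], irb[1L])),
    end = as.integer(c(lsc[2L], ira[2L], ssc[2L], irb[2L]))
  ) %>% mutate(length = .data$end - .data$start)
  n <- as.integer(genome_length)
  if (any(regions$length <= 0L) || sum(regions$length) != n) {
    abort("the four regions must have positive lengths summing to the genome length",
          class = "cpkit_usage_error")
  }
  # cyclic adjacency in canonical order LSC, IRA, SSC, IRB
  for (i in 1:4) {
    j <- if (i == 4L) 1L else i + 1L
    if ((regions$end[i] %% n) != (regions$start[j] %% n)) {
      abort(sprintf("regions %s and %s are not adjacent on the circle",
                    regions$region[i], regions$region[j]),
            class = "cpkit_usage_error")
    }
  }
  if (regions$length[regions$region == "lsc"] <=
        regions$length[regions$region == "ssc"]) {
    abort("LSC must be longer than SSC", class = "cpkit_usage_error")
  }
  structure(regions, class = c("quadripartite_structure", class(regions)),
            genome_length = n, ir_mismatches = as.integer(ir_mismatches))
}

#' Build a canonical structure from the four region lengths
#'
#' Convenience constructor placing LSC at the origin followed by IRA, SSC
#' and IRB, as in a canonicalized assembly.
#'
#' @param lsc_bp,ira_bp,ssc_bp,irb_bp Region lengths in bp.
#' @param ir_mismatches See [quadripartite_structure()].
#' @return A [quadripartite_structure()].
#' @examples
#' # the printed sweetpotato region sizes reproduce the printed genome size
#' s <- structure_from_lengths(87489, 30874, 12076, 30835)
#' attr(s, "genome_length")  # 161274
#' @export
structure_from_lengths <- function(lsc_bp, ira_bp, ssc_bp, irb_bp,
                                   ir_mismatches = 0L) {
  b <- cumsum(c(0L, lsc_bp, ira_bp, ssc_bp, irb_bp))
  quadripartite_structure(c(b[1L], b[2L]), c(b[2L], b[3L]), c(b[3L], b[4L]),
                          c(b[4L], b[5L]), b[5L], ir_mismatches)
}

region_interval <- function(structure, region) {
  r <- structure[structure$region == region, ]
  c(r$start, r$end)
}

#' @export
print.quadripartite_structure <- function(x, ...) {
  cat(sprintf("<quadripartite_structure> genome %d bp, IR mismatches %d\n",
              attr(x, "genome_length"), attr(x, "ir_mismatches")))
  NextMethod()
}

#' Detect the quadripartite structure of a circular genome
#'
#' Finds the highest-scoring pair of disjoint, oppositely oriented repeats
#' of at least `min_ir_bp` (seed k-mers shared between the genome and its
#' reverse complement, chained along diagonals, then extended outward
#' across isolated mismatches while the running mismatch rate stays within
#' `max_mismatch_rate`; boundaries end on the outermost matching base).
#' The single-copy regions are named by size (the larger is the LSC) and
#' IRA is the IR copy immediately following the LSC.  Score ties are
#' broken toward the leftmost start after canonical rotation.
#'
#' @param genome A circular [nuc_seq()] with length > 4 * `min_ir_bp`.
#' @param min_ir_bp Minimum IR length (default 1000).
#' @param max_mismatch_rate Maximum substitution rate between the two IR
#'   copies (default 0.01).
#' @return A [quadripartite_structure()] in the genome's own coordinates.
#' @export
detect_quadripartite <- function(genome, min_ir_bp = 1000L,
                                 max_mismatch_rate = 0.01) {
  stopifnot(inherits(genome, "nuc_seq"))
  if (!genome$circular) {
    abort("detect_quadripartite() requires a circular genome",
          class = "cpkit_usage_error")
  }
  n <- seq_length(genome)
  if (n <= 4L * min_ir_bp) {
    abort(sprintf("genome (%d bp) too short for min_ir_bp = %d", n, min_ir_bp),
          class = "cpkit_usage_error")
  }
  k <- 17L
  g2 <- paste0(genome$bases, genome$bases)
  r2 <- revcomp_chr(g2)
  idx <- kmer_index(r2, k)
  stride <- max(1L, min_ir_bp %/% 50L)
  cand <- ir_candidates(g2, r2, idx, k, stride, min_ir_bp, max_mismatch_rate, n)
  if (nrow(cand) == 0L) {
    abort("no quadripartite structure: no inverted repeat of sufficient length",
          class = "cpkit_no_structure_error")
  }
  best <- cand %>%
    mutate(score = .data$length - .data$mismatches) %>%
    arrange(desc(.data$score), .data$a_start, .data$b_start) %>%
    dplyr::slice(1L)
  build_structure_from_ir(best, n)
}

# enumerate candidate IR pairs: tibble(a_start, b_start, length, mismatches)
# with copy intervals [a_start, a_start+length), [b_start, b_start+length)
# on the circle (0-based starts in [0, n))
ir_candidates <- function(g2, r2, idx, k, stride, min_ir_bp, max_rate, n) {
  m <- diagonal_matches(g2, r2, idx, k, stride, min_ir_bp, max_rate)
  if (nrow(m) == 0L) return(tibble(a_start = integer(), b_start = integer(),
                                   length = integer(), mismatches = integer()))
  out <- list()
  for (i in seq_len(nrow(m))) {
    len <- m$q_end[i] - m$q_start[i]
    if (len > n %/% 2L) next   # cannot be one of two disjoint copies
    a0 <- m$q_start[i] %% n
    # r2 position j corresponds to genome position (2n - 1 - j) %% n;
    # the matched block in r2 is [t_start, t_end) -> genome interval
    b0 <- (2L * n - m$t_end[i]) %% n
    key_a <- min(a0, b0); key_b <- max(a0, b0)
    out[[length(out) + 1L]] <- tibble(a_start = key_a, b_start = key_b,
                                      length = as.integer(len),
                                      mismatches = m$mismatches[i])
  }
  cand <- bind_rows(out) %>% dplyr::distinct()
  # keep only pairs whose two copies are disjoint on the circle
  keep <- map_lgl(seq_len(nrow(cand)), function(i) {
    circ_disjoint(cand$a_start[i], cand$length[i],
                  cand$b_start[i], cand$length[i], n)
  })
  cand[keep, , drop = FALSE]
}

circ_disjoint <- function(s1, l1, s2, l2, n) {
  iv <- function(s, l) {
    if (s + l <= n) list(c(s, s + l)) else list(c(s, n), c(0L, s + l - n))
  }
  for (x in iv(s1, l1)) for (y in iv(s2, l2)) {
    if (max(x[1L], y[1L]) < min(x[2L], y[2L])) return(FALSE)
  }
  TRUE
}

build_structure_from_ir <- function(best, n) {
  a0 <- best$a_start; b0 <- best$b_start; len <- best$length
  a1 <- a0 + len; b1 <- b0 + len      # ends may exceed n (wrap)
  # single-copy arcs: from end of one copy to start of the other
  arc1 <- (b0 - a1) %% n              # following copy A
  arc2 <- (a0 - b1) %% n              # following copy B
  if (arc1 == 0L || arc2 == 0L) {
    abort("degenerate structure: inverted repeats are adjacent",
          class = "cpkit_no_structure_error")
  }
  if (arc1 >= arc2) {
    # LSC follows copy A; the IR after the LSC (IRA) is copy B
    lsc <- c(a1 %% n, a1 %% n + arc1)
    ira <- c(b0, b1)
    ssc <- c(b1 %% n, b1 %% n + arc2)
    irb <- c(a0, a1)
  } else {
    lsc <- c(b1 %% n, b1 %% n + arc2)
    ira <- c(a0, a1)
    ssc <- c(a1 %% n, a1 %% n + arc1)
    irb <- c(b0, b1)
  }
  norm <- function(iv) {
    s <- iv[1L] %% n
    c(s, s + (iv[2L] - iv[1L]))
  }
  quadripartite_structure(norm(lsc), norm(ira), norm(ssc), norm(irb), n,
                          ir_mismatches = best$mismatches)
}

#' Canonicalize a circular genome to start at the LSC
#'
#' Rotates the genome so the LSC starts at position 0 and, of the two
#' strand choices (each rotated to its own LSC start), emits the
#' lexicographically smaller full sequence — a deterministic, data-free
#' orientation convention.  Region intervals are remapped accordingly, in
#' the order LSC, IRA, SSC, IRB.  Idempotent.
#'
#' @param genome A circular [nuc_seq()].
#' @param structure Optional [quadripartite_structure()] for `genome`;
#'   detected when `NULL`.
#' @param ... Passed to [detect_quadripartite()] when detecting.
#' @return List with `seq` (the canonical circular [nuc_seq()]) and
#'   `structure` (remapped [quadripartite_structure()]).
#' @export
canonicalize <- function(genome, structure = NULL, ...) {
  stopifnot(inherits(genome, "nuc_seq"))
  if (is.null(structure)) structure <- detect_quadripartite(genome, ...)
  n <- seq_length(genome)
  if (attr(structure, "genome_length") != n) {
    abort("structure does not match genome length", class = "cpkit_input_error")
  }
  len <- setNames(structure$length, structure$region)
  lsc_start <- region_interval(structure, "lsc")[1L] %% n
  fwd <- rotate(genome, lsc_start)
  # reverse strand: LSC maps to [n - lsc_end, n - lsc_start); rotate there
  lsc_end <- (lsc_start + len[["lsc"]]) %% n
  rc <- reverse_complement(genome)
  rev <- rotate(rc, (n - lsc_end) %% n)
  if (fwd$bases <= rev$bases) {
    seqo <- fwd
    lens <- c(len[["lsc"]], len[["ira"]], len[["ssc"]], len[["irb"]])
  } else {
    seqo <- rev
    lens <- c(len[["lsc"]], len[["irb"]], len[["ssc"]], len[["ira"]])
  }
  st <- structure_from_lengths(lens[1L], lens[2L], lens[3L], lens[4L],
                               ir_mismatches = attr(structure, "ir_mismatches"))
  seqo$id <- genome$id
  list(seq = seqo, structure = st)
}

#' Region lengths and GC content
#'
#' Lengths and GC fractions per region, for the two IRs combined (both
#' copies concatenated, as conventionally reported) and for the whole
#' genome.  GC excludes N from the denominator.  Region lengths are
#' checked to sum to the genome length.
#'
#' @param genome Canonical circular [nuc_seq()].
#' @param structure Matching [quadripartite_structure()].
#' @return Tibble: `region` (`lsc`, `ira`, `ssc`, `irb`, `ir_combined`,
#'   `overall`), `start`, `end` (`NA` for composites), `length`,
#'   `gc_fraction`.
#' @export
region_stats <- function(genome, structure) {
  stopifnot(inherits(genome, "nuc_seq"),
            inherits(structure, "quadripartite_structure"))
  n <- seq_length(genome)
  if (attr(structure, "genome_length") != n) {
    abort("structure does not match genome length", class = "cpkit_input_error")
  }
  seq_of <- function(region) {
    iv <- region_interval(structure, region)
    subseq_circular(genome$bases, iv[1L], iv[2L] - iv[1L])
  }
  rs <- map_chr(structure$region, seq_of)
  stopifnot(sum(nchar(rs)) == n)
  ir_both <- paste0(rs[structure$region == "ira"], rs[structure$region == "irb"])
  tibble(
    region = c(structure$region, "ir_combined", "overall"),
    start = c(structure$start, NA_integer_, NA_integer_),
    end = c(structure$end, NA_integer_, NA_integer_),
    length = c(structure$length, nchar(ir_both), n),
    gc_fraction = c(map_dbl(rs, gc_fraction), gc_fraction(ir_both),
                    gc_fraction(genome$bases))
  )
}

#' Census of a gene annotation table
#'
#' Tallies gene copies per functional system and the copy-number spectrum
#' (single-, double- and triple-copy genes) from an annotation table of
#' one row per distinct gene with its copy count.
#'
#' @param rows Annotation tibble (`gene`, `functional_system`, `copies`),
#'   e.g. from [read_annotation_table()].  Gene names must be unique.
#' @return Object of class `annotation_census`: list with `by_system`
#'   (tibble: `functional_system`, `n_genes`, `n_copies`) and `totals`
#'   (list: `distinct_genes`, `total_copies`, `n_single`, `n_double`,
#'   `n_triple`).  The invariants
#'   `total_copies = n_single + 2 n_double + 3 n_triple` and
#'   `distinct_genes = n_single + n_double + n_triple` hold whenever no
#'   gene exceeds three copies.
#' @export
annotation_census <- function(rows) {
  validate_annotation(rows, context = "annotation_census()")
  by_system <- rows %>%
    group_by(.data$functional_system) %>%
    summarise(n_genes = dplyr::n(), n_copies = sum(.data$copies),
              .groups = "drop")
  totals <- list(
    distinct_genes = nrow(rows),
    total_copies = sum(rows$copies),
    n_single = sum(rows$copies == 1L),
    n_double = sum(rows$copies == 2L),
    n_triple = sum(rows$copies == 3L)
  )
  structure(list(by_system = by_system, totals = totals),
            class = "annotation_census")
}

#' @export
print.annotation_census <- function(x, ...) {
  t <- x$totals
  cat(sprintf(paste0("<annotation_census> %d genes, %d copies ",
                     "(%d single, %d double, %d triple)\n"),
              t$distinct_genes, t$total_copies, t$n_single, t$n_double,
              t$n_triple))
  print(x$by_system, n = Inf)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.annotation_census <- function(x, ...) x$by_system

#' @exportS3Method generics::glance
glance.annotation_census <- function(x, ...) as_tibble(x$totals)

#' Total gene count including rRNA and tRNA genes
#'
#' The annotation census counts protein-coding gene copies; rRNA and tRNA
#' genes are annotated separately and added here.
#'
#' @param census An [annotation_census()].
#' @param n_rrna,n_trna rRNA and tRNA gene counts (>= 0).
#' @return Integer total gene count.
#' @examples
#' \dontrun{gene_totals(census, n_rrna = 8, n_trna = 48)}
#' @export
gene_totals <- function(census, n_rrna, n_trna) {
  stopifnot(inherits(census, "annotation_census"), n_rrna >= 0, n_trna >= 0)
  as.integer(census$totals$total_copies + n_rrna + n_trna)
}

#' Plot a quadripartite structure as a linear region diagram
#'
#' @param object A [quadripartite_structure()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.quadripartite_structure <- function(object, ...) {
  df <- as_tibble(object)
  df$region <- toupper(df$region)
  ggplot2::ggplot(df, ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                   ymin = 0, ymax = 1, fill = .data$region)) +
    ggplot2::geom_rect(colour = "grey20") +
    ggplot2::geom_text(ggplot2::aes(x = (.data$start + .data$end) / 2, y = 0.5,
                                    label = .data$region), size = 3) +
    ggplot2::scale_y_continuous(NULL, breaks = NULL) +
    ggplot2::labs(x = "position (bp)", fill = NULL,
                  title = "Quadripartite structure") +
    ggplot2::theme_minimal()
}

#' Plot an annotation census as a per-system bar chart
#'
#' @param object An [annotation_census()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.annotation_census <- function(object, ...) {
  df <- object$by_system
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$functional_system,
                                                      .data$n_copies),
                                   y = .data$n_copies)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "gene copies") +
    ggplot2::theme_minimal()
}
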