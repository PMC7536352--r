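#' Parameters for contig merging and circularization
#'
#' @param min_overlap_bp Minimum suffix-prefix overlap length (default 500).
#' @param min_identity Minimum overlap identity (default 0.95).
#' @param kmer_size K-mer size used to anchor candidate overlaps
#'   (default 21; must not exceed `min_overlap_bp`).
#' @return A list of class `merge_params`.
#' @export
merge_params <- function(min_overlap_bp = 500L, min_identity = 0.95,
                         kmer_size = 21L) {
  if (min_overlap_bp < kmer_size) {
    abort("min_overlap_bp must be >= kmer_size", class = "cpkit_usage_error")
  }
  structure(list(min_overlap_bp = as.integer(min_overlap_bp),
                 min_identity = min_identity,
                 kmer_size = as.integer(kmer_size)),
            class = "merge_params")
}

as_contig_list <- function(contigs) {
  if (inherits(contigs, "nuc_seq")) contigs <- list(contigs)
  stopifnot(length(contigs) >= 1L, all(map_lgl(contigs, inherits, "nuc_seq")))
  if (any(map_int(contigs, seq_length) == 0L)) {
    abort("contigs must be non-empty", class = "cpkit_usage_error")
  }
  setNames(contigs, map_chr(contigs, "id"))
}

oriented_bases <- function(contig, orientation) {
  if (orientation == "+") contig$bases else revcomp_chr(contig$bases)
}

#' Find suffix-prefix overlaps between contigs
#'
#' For each ordered pair of distinct contigs and each orientation
#' combination, reports the longest suffix-of-A / prefix-of-B match of at
#' least `min_overlap_bp` with identity at least `min_identity`.
#' Candidates are anchored by shared k-mers and verified by edit distance.
#' An edge and its reverse-complement dual describe the same junction, so
#' only one representative is reported.  Contigs wholly contained in
#' another contig (at `min_identity`) are reported separately and carry no
#' edges.
#'
#' @param contigs List of [nuc_seq()] contigs (unique ids).
#' @param params [merge_params()].
#' @return List with `edges` (tibble: `from_id`, `from_orientation`,
#'   `to_id`, `to_orientation`, `overlap_bp`, `identity`) and `contained`
#'   (tibble: `contained_id`, `container_id`, `identity`).  Zero edges is a
#'   valid outcome.
#' @export
find_overlaps <- function(contigs, params = merge_params()) {
  contigs <- as_contig_list(contigs)
  ids <- names(contigs)
  # one oriented-sequence and k-mer-index cache per contig
  fwd <- map(contigs, "bases")
  rev <- map(fwd, revcomp_chr)
  oriented <- function(id, o) if (o == "+") fwd[[id]] else rev[[id]]
  idx_cache <- new.env(parent = emptyenv())
  idx_of <- function(id, o) {
    key <- paste0(id, o)
    if (is.null(idx_cache[[key]])) {
      idx_cache[[key]] <- kmer_index(oriented(id, o), params$kmer_size)
    }
    idx_cache[[key]]
  }
  # containment first: contained contigs are redundancy, not path members
  contained <- list()
  if (length(ids) > 1L) {
    ord <- order(map_int(contigs, seq_length), decreasing = TRUE)
    for (i in seq_along(ids)) {
      ci <- ids[ord[i]]
      for (j in seq_along(ids)) {
        cj <- ids[ord[j]]
        if (i == j || seq_length(contigs[[cj]]) > seq_length(contigs[[ci]])) next
        if (cj %in% map_chr(contained, function(x) x$contained_id %||% "")) next
        hit <- find_containment(fwd[[ci]], fwd[[cj]], params$min_identity,
                                k = params$kmer_size, a_index = idx_of(ci, "+"))
        if (is.null(hit)) {
          hit <- find_containment(fwd[[ci]], rev[[cj]], params$min_identity,
                                  k = params$kmer_size, a_index = idx_of(ci, "+"))
        }
        if (!is.null(hit) && seq_length(contigs[[cj]]) < seq_length(contigs[[ci]])) {
          contained[[length(contained) + 1L]] <-
            list(contained_id = cj, container_id = ci, identity = hit$identity)
        }
      }
    }
  }
  contained_ids <- map_chr(contained, "contained_id") %||% character()
  live <- setdiff(ids, contained_ids)
  edges <- list()
  seen <- character()
  for (a in live) for (b in live) {
    if (a == b) next
    for (oa in c("+", "-")) for (ob in c("+", "-")) {
      # dual of (a,oa)->(b,ob) is (b,flip ob)->(a,flip oa)
      key <- paste(a, oa, b, ob, sep = "|")
      dual <- paste(b, flip(ob), a, flip(oa), sep = "|")
      if (dual %in% seen) next
      seen <- c(seen, key)
      hit <- find_suffix_prefix(oriented(a, oa), oriented(b, ob),
                                params$min_overlap_bp, params$min_identity,
                                k = params$kmer_size, b_index = idx_of(b, ob))
      if (!is.null(hit)) {
        edges[[length(edges) + 1L]] <- tibble(
          from_id = a, from_orientation = oa, to_id = b, to_orientation = ob,
          overlap_bp = hit$overlap_bp, identity = hit$identity)
      }
    }
  }
  list(
    edges = if (length(edges)) bind_rows(edges) else
      tibble(from_id = character(), from_orientation = character(),
             to_id = character(), to_orientation = character(),
             overlap_bp = integer(), identity = numeric()),
    contained = if (length(contained)) bind_rows(map(contained, as_tibble)) else
      tibble(contained_id = character(), container_id = character(),
             identity = numeric())
  )
}

flip <- function(o) ifelse(o == "+", "-", "+")

#' Merge contigs along their overlap graph
#'
#' Builds an overlap graph from the edges and walks maximal simple paths
#' greedily by descending overlap length (ties broken lexicographically),
#' concatenating neighbours through their overlap so each overlap is
#' counted once.  Every input contig is consumed at most once; contained
#' contigs are dropped as redundancy.  An edge that would close a cycle is
#' skipped (the cycle is broken at its weakest edge) and reported in the
#' result metadata.  Where overlap identities are below 1, the overlap
#' bases are taken from the longer of the two contigs (the polisher is the
#' error-fixing stage).
#'
#' @param contigs List of [nuc_seq()] contigs.
#' @param overlaps Result of [find_overlaps()] (or a compatible list with
#'   `edges` and `contained`).
#' @return List of class `merge_result`: `contigs` (merged [nuc_seq()]
#'   list), `layout` (tibble: `merged_id`, `order`, `contig_id`,
#'   `orientation`, `overlap_to_next`), `dropped` (contained contig ids)
#'   and `cycles_broken` (edge tibble).
#' @export
merge_layout <- function(contigs, overlaps) {
  contigs <- as_contig_list(contigs)
  edges <- overlaps$edges
  dropped <- overlaps$contained$contained_id %||% character()
  live <- setdiff(names(contigs), dropped)
  bad <- setdiff(unique(c(edges$from_id, edges$to_id)), live)
  if (length(bad)) {
    abort(sprintf("edges reference unknown or contained contig '%s'", bad[1L]),
          class = "cpkit_input_error")
  }
  edges <- arrange(edges, desc(.data$overlap_bp), .data$from_id, .data$to_id,
                   .data$from_orientation)
  # out/in slots per (contig, orientation); duals marked used together
  out_used <- new.env(parent = emptyenv())
  in_used <- new.env(parent = emptyenv())
  slot <- function(id, o) paste0(id, o)
  comp <- setNames(live, live)   # union-find over contig ids
  find <- function(x) { while (comp[[x]] != x) x <- comp[[x]]; x }
  accepted <- list()
  cycles <- list()
  for (i in seq_len(nrow(edges))) {
    e <- edges[i, ]
    so <- slot(e$from_id, e$from_orientation); si <- slot(e$to_id, e$to_orientation)
    so2 <- slot(e$to_id, flip(e$to_orientation)); si2 <- slot(e$from_id, flip(e$from_orientation))
    if (!is.null(out_used[[so]]) || !is.null(in_used[[si]]) ||
        !is.null(out_used[[so2]]) || !is.null(in_used[[si2]])) next
    ra <- find(e$from_id); rb <- find(e$to_id)
    if (ra == rb) { cycles[[length(cycles) + 1L]] <- e; next }
    out_used[[so]] <- TRUE; in_used[[si]] <- TRUE
    out_used[[so2]] <- TRUE; in_used[[si2]] <- TRUE
    comp[[ra]] <- rb
    accepted[[length(accepted) + 1L]] <- e
  }
  acc <- if (length(accepted)) bind_rows(accepted) else edges[0L, ]
  # walk paths: successor map keyed by (id, orientation)
  succ <- new.env(parent = emptyenv()); pred <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(acc))) {
    e <- acc[i, ]
    succ[[slot(e$from_id, e$from_orientation)]] <- e
    pred[[slot(e$to_id, e$to_orientation)]] <- e
    # dual direction
    de <- tibble(from_id = e$to_id, from_orientation = flip(e$to_orientation),
                 to_id = e$from_id, to_orientation = flip(e$from_orientation),
                 overlap_bp = e$overlap_bp, identity = e$identity)
    succ[[slot(de$from_id, de$from_orientation)]] <- de
    pred[[slot(de$to_id, de$to_orientation)]] <- de
  }
  visited <- character()
  merged <- list(); layout <- list()
  walk_from <- function(id, o) {
    path <- list()
    repeat {
      path[[length(path) + 1L]] <- list(id = id, o = o)
      e <- succ[[slot(id, o)]]
      if (is.null(e)) break
      id <- e$to_id; o <- e$to_orientation
    }
    path
  }
  for (id in sort(live)) {
    if (id %in% visited) next
    # locate the start of this contig's path: walk predecessors from (id, "+")
    o <- "+"
    cur <- list(id = id, o = o)
    steps <- 0L
    repeat {
      e <- pred[[slot(cur$id, cur$o)]]
      if (is.null(e)) break
      cur <- list(id = e$from_id, o = e$from_orientation)
      steps <- steps + 1L
      if (steps > length(live)) {
        abort("internal error: predecessor walk did not terminate")
      }
    }
    path <- walk_from(cur$id, cur$o)
    pids <- map_chr(path, "id")
    visited <- c(visited, pids)
    # deterministic path orientation: emit so the first contig id of the
    # emitted order is the lexicographically smaller path endpoint
    if (pids[length(pids)] < pids[1L]) {
      path <- rev(map(path, function(p) list(id = p$id, o = flip(p$o))))
      pids <- rev(pids)
    }
    mid <- sprintf("merge_%d", length(merged) + 1L)
    bases <- ""
    ovs <- integer()
    for (j in seq_along(path)) {
      p <- path[[j]]
      cur_b <- oriented_bases(contigs[[p$id]], p$o)
      if (j == 1L) {
        bases <- cur_b
      } else {
        prev <- path[[j - 1L]]
        ov <- edge_overlap(acc, prev, p)
        ovs <- c(ovs, ov)
        if (seq_length(contigs[[prev$id]]) >= seq_length(contigs[[p$id]])) {
          bases <- paste0(bases, substr(cur_b, ov + 1L, nchar(cur_b)))
        } else {
          bases <- paste0(substr(bases, 1L, nchar(bases) - ov), cur_b)
        }
      }
    }
    merged[[mid]] <- nuc_seq(mid, bases)
    layout[[length(layout) + 1L]] <- tibble(
      merged_id = mid, order = seq_along(path), contig_id = pids,
      orientation = map_chr(path, "o"),
      overlap_to_next = c(ovs, NA_integer_))
  }
  structure(list(contigs = merged, layout = bind_rows(layout),
                 dropped = dropped,
                 cycles_broken = if (length(cycles)) bind_rows(cycles) else acc[0L, ]),
            class = "merge_result")
}

edge_overlap <- function(acc, from, to) {
  hit <- acc[(acc$from_id == from$id & acc$from_orientation == from$o &
                acc$to_id == to$id & acc$to_orientation == to$o) |
               (acc$from_id == to$id & acc$from_orientation == flip(to$o) &
                  acc$to_id == from$id & acc$to_orientation == flip(from$o)), ]
  stopifnot(nrow(hit) >= 1L)
  hit$overlap_bp[1L]
}

#' Circularize a contig by trimming its terminal self-overlap
#'
#' A merged organelle contig typically carries the same sequence at both
#' ends (terminal redundancy).  The longest prefix/suffix match of at least
#' `min_overlap_bp` with identity at least `min_identity` is located and
#' the suffix copy trimmed, producing a circular sequence.  An already
#' circular input is returned unchanged (fixed point).  If no terminal
#' overlap exists the input is returned unchanged with status
#' `"not_circularizable"`.  A terminal overlap longer than half the contig
#' is an error (degenerate, likely a tandem artifact).
#'
#' @param contig A [nuc_seq()].
#' @param params [merge_params()].
#' @return List of class `circularization`: `seq` (the possibly
#'   circularized [nuc_seq()]), `status` (`"circular"` or
#'   `"not_circularizable"`) and `overlap_bp` (trimmed bases).
#' @export
circularize <- function(contig, params = merge_params()) {
  stopifnot(inherits(contig, "nuc_seq"))
  if (contig$circular) {
    return(structure(list(seq = contig, status = "circular", overlap_bp = 0L),
                     class = "circularization"))
  }
  a <- contig$bases
  la <- nchar(a)
  half <- la %/% 2L
  k <- params$kmer_size
  # candidates: shared k-mers between the whole contig and its prefix,
  # excluding the trivial full self-match (diagonal 0, L == la)
  cap <- la - 1L
  bi <- kmer_index(substr(a, 1L, min(cap, la - params$min_overlap_bp + k)), k)
  hits <- kmer_hits(a, bi, k, stride = 1L)
  L <- la - hits$qpos + hits$tpos
  keep <- L >= params$min_overlap_bp & L < la
  cand <- sort(unique(L[keep]), decreasing = TRUE)
  # never verify implausibly long candidates by edit distance; a strongly
  # supported candidate beyond half the contig is the degenerate case
  long_cand <- cand[cand > half]
  if (length(long_cand)) {
    support <- table(L[keep])[as.character(long_cand)]
    strong <- long_cand[as.integer(support) >= pmax(20L, (long_cand - k) %/% 4L)]
    if (length(strong)) {
      abort(sprintf("terminal overlap of %d bp exceeds half the contig (%d bp)",
                    strong[1L], la), class = "cpkit_degenerate_error")
    }
  }
  for (Lc in cand[cand <= half]) {
    idt <- segment_identity(substr(a, la - Lc + 1L, la), substr(a, 1L, Lc))
    if (idt >= params$min_identity) {
      out <- nuc_seq(contig$id, substr(a, 1L, la - Lc), circular = TRUE,
                     desc = contig$desc)
      return(structure(list(seq = out, status = "circular", overlap_bp = as.integer(Lc)),
                       class = "circularization"))
    }
  }
  structure(list(seq = contig, status = "not_circularizable", overlap_bp = 0L),
            class = "circularization")
}

#' @export
print.circularization <- function(x, ...) {
  cat(sprintf("<circularization> status=%s trimmed=%d bp -> %d bp (%s)\n",
              x$status, x$overlap_bp, seq_length(x$seq),
              if (x$seq$circular) "circular" else "linear"))
  invisible(x)
}

#' Assemble a draft circular genome from contigs
#'
#' Runs [find_overlaps()], [merge_layout()] and [circularize()] in
#' sequence.  Fails loudly when more than one merged contig remains (the
#' overlap graph is disconnected), listing the components.
#'
#' @param contigs List of [nuc_seq()] draft contigs.
#' @param params [merge_params()].
#' @return List of class `draft_assembly`: `seq` (circular [nuc_seq()]
#'   when circularizable), `status`, `overlap_trimmed_bp`, `merge`
#'   (the [merge_layout()] result).
#' @export
assemble_draft <- function(contigs, params = merge_params()) {
  contigs <- as_contig_list(contigs)
  ov <- find_overlaps(contigs, params)
  m <- merge_layout(contigs, ov)
  if (length(m$contigs) > 1L) {
    comps <- split(m$layout$contig_id, m$layout$merged_id)
    abort(paste0("overlap graph is disconnected; components: ",
                 paste(map_chr(comps, paste, collapse = "+"), collapse = " | ")),
          class = "cpkit_stage_error")
  }
  circ <- circularize(m$contigs[[1L]], params)
  structure(list(seq = circ$seq, status = circ$status,
                 overlap_trimmed_bp = circ$overlap_bp, merge = m),
            class = "draft_assembly")
}
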