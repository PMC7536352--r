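#' Pairwise substitution distance between aligned sequences
#'
#' The p-distance on the scale of substitutions per bp: the number of
#' differing columns divided by the number of comparable columns.  Only
#' columns where both symbols are in A, C, G, T are comparable; gap and N
#' columns are excluded from numerator and denominator alike.
#'
#' @param aligned_a,aligned_b Character scalars of equal length (gapped
#'   aligned sequences; gaps as `-`).
#' @return Numeric distance in substitutions per bp.
#' @examples
#' p_distance("ACGT", "ACGA")   # 0.25
#' p_distance("AC-T", "ACGT")   # 0 over 3 comparable columns
#' @export
p_distance <- function(aligned_a, aligned_b) {
  stopifnot(is.character(aligned_a), is.character(aligned_b),
            length(aligned_a) == 1L, length(aligned_b) == 1L)
  if (nchar(aligned_a) != nchar(aligned_b)) {
    abort("aligned sequences must have equal length", class = "cpkit_usage_error")
  }
  a <- chars(toupper(aligned_a))
  b <- chars(toupper(aligned_b))
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(ok)) {
    abort("no comparable columns (both sequences gap/N everywhere)",
          class = "cpkit_domain_error")
  }
  sum(a[ok] != b[ok]) / sum(ok)
}

# children list representation of a phylo tree: list indexed by node id,
# each element the integer child node ids; plus branch length of the edge
# above every node (NA for the root)
tree_children <- function(tree) {
  nn <- ape::Ntip(tree) + tree$Nnode
  kids <- vector("list", nn)
  blen <- rep(NA_real_, nn)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]; c <- tree$edge[i, 2L]
    kids[[p]] <- c(kids[[p]], c)
    blen[c] <- if (is.null(tree$edge.length)) NA_real_ else tree$edge.length[i]
  }
  list(kids = kids, blen = blen, ntip = ape::Ntip(tree),
       root = ape::Ntip(tree) + 1L)
}

#' Collapse short branches of a tree into polytomies
#'
#' Contracts every internal branch strictly shorter than `threshold`
#' (the child's children re-attach to its parent), producing polytomies.
#' Leaf branches are never contracted, so the leaf set is preserved.
#' With `threshold = 0` the tree is returned unchanged (strict
#' inequality).
#'
#' @param tree A `phylo` tree with branch lengths in substitutions per bp.
#' @param threshold Collapse threshold (default `2e-4` substitutions per
#'   bp; must be >= 0).
#' @return The collapsed `phylo` tree.
#' @export
collapse_short_branches <- function(tree, threshold = 2e-4) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0) {
    abort("threshold must be a single number >= 0", class = "cpkit_usage_error")
  }
  if (is.null(tree$edge.length)) {
    abort("tree has no branch lengths", class = "cpkit_usage_error")
  }
  tc <- tree_children(tree)
  lab <- function(i) tree$tip.label[i]
  # recursive newick writer contracting short internal edges
  write_node <- function(i) {
    if (i <= tc$ntip) {
      return(sprintf("%s:%.10g", lab(i), tc$blen[i]))
    }
    parts <- unlist(map(tc$kids[[i]], write_part))
    inner <- paste0("(", paste(parts, collapse = ","), ")")
    if (is.na(tc$blen[i])) paste0(inner, ";") else
      sprintf("%s:%.10g", inner, tc$blen[i])
  }
  # a child that is internal and short is dissolved into its parent
  write_part <- function(c) {
    if (c > tc$ntip && !is.na(tc$blen[c]) && tc$blen[c] < threshold) {
      unlist(map(tc$kids[[c]], write_part))
    } else {
      write_node(c)
    }
  }
  ape::read.tree(text = write_node(tc$root))
}

#' Report clades whose branches are all short
#'
#' Finds the maximal clades in which every branch inside the clade —
#' terminal branches included, by default, since near-identical cultivars
#' have short terminal branches too — is strictly shorter than
#' `threshold`; reports their leaf memberships sorted by decreasing size,
#' with remaining leaves as singletons.  `all_branches = FALSE` restricts
#' the criterion to internal branches (under that reading any cherry
#' qualifies trivially, so the default is the stricter one).
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param threshold Substitutions-per-bp threshold (default `2e-4`).
#' @param all_branches Require terminal branches inside the clade to be
#'   below the threshold as well (default `TRUE`).
#' @return Tibble: `clade`, `size`, `leaves` (comma-joined labels),
#'   sorted by decreasing size.
#' @export
clade_report <- function(tree, threshold = 2e-4, all_branches = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  tc <- tree_children(tree)
  nn <- tc$ntip + tree$Nnode
  qualifies <- rep(NA, nn)
  leaves_under <- vector("list", nn)
  walk <- function(i) {
    if (i <= tc$ntip) {
      qualifies[i] <<- TRUE
      leaves_under[[i]] <<- tree$tip.label[i]
      return(invisible())
    }
    for (c in tc$kids[[i]]) walk(c)
    kq <- map_lgl(tc$kids[[i]], function(c) qualifies[c])
    edge_ok <- map_lgl(tc$kids[[i]], function(c) {
      if (c <= tc$ntip) {
        !all_branches || tc$blen[c] < threshold
      } else {
        tc$blen[c] < threshold
      }
    })
    qualifies[i] <<- all(kq) && all(edge_ok)
    leaves_under[[i]] <<- unlist(leaves_under[tc$kids[[i]]])
    invisible()
  }
  walk(tc$root)
  # maximal qualifying nodes: qualifying, with a non-qualifying parent
  parent <- rep(NA_integer_, nn)
  for (i in seq_len(nrow(tree$edge))) parent[tree$edge[i, 2L]] <- tree$edge[i, 1L]
  is_max <- map_lgl(seq_len(nn), function(i) {
    isTRUE(qualifies[i]) && (is.na(parent[i]) || !isTRUE(qualifies[parent[i]]))
  })
  cl <- map(which(is_max), function(i) sort(leaves_under[[i]]))
  cl <- cl[order(-lengths(cl), map_chr(cl, 1L))]
  tibble(clade = seq_along(cl), size = lengths(cl),
         leaves = map_chr(cl, paste, collapse = ","))
}
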