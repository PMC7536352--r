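#' Nucleotide sequence record
#'
#' The universal currency of the toolkit: a named DNA sequence over the
#' alphabet A, C, G, T, N together with a circularity flag.  Plastomes are
#' circular molecules whose rotation and strand are arbitrary until
#' canonicalized, so the flag travels with the sequence through every stage
#' and survives FASTA round trips (see [write_fasta()]).
#'
#' @param id Character scalar, the sequence name (first word of a FASTA
#'   header).
#' @param bases Character scalar.  Lowercase letters are uppercased and U is
#'   mapped to T; any character outside A, C, G, T, N is an error (IUPAC
#'   ambiguity codes other than N are rejected rather than silently mapped).
#' @param circular Logical; is the molecule circular?  A circular sequence of
#'   length zero is invalid.
#' @param desc Optional free-text description (rest of the FASTA header).
#'
#' @return An object of class `nuc_seq`: a list with fields `id`, `bases`,
#'   `circular` and `desc`.
#' @examples
#' s <- nuc_seq("toy", "acgtn")
#' s$bases
#' seq_length(s)
#' @export
nuc_seq <- function(id, bases, circular = FALSE, desc = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(bases), length(bases) == 1L,
            is.logical(circular), length(circular) == 1L)
  bases <- chartr("u", "t", bases)
  bases <- toupper(bases)
  bases <- chartr("U", "T", bases)
  bad <- gregexpr("[^ACGTN]", bases)[[1L]]
  if (bad[1L] != -1L) {
    abort(sprintf("illegal character '%s' in sequence '%s'",
                  substr(bases, bad[1L], bad[1L]), id),
          class = "cpkit_format_error")
  }
  if (circular && nchar(bases) == 0L) {
    abort("a circular sequence must have length > 0", class = "cpkit_usage_error")
  }
  structure(list(id = id, bases = bases, circular = circular, desc = desc),
            class = "nuc_seq")
}

#' @export
print.nuc_seq <- function(x, ...) {
  n <- nchar(x$bases)
  shape <- if (x$circular) "circular" else "linear"
  preview <- if (n > 60) paste0(substr(x$bases, 1, 57), "...") else x$bases
  cat(sprintf("<nuc_seq> %s (%s, %d bp)\n  %s\n", x$id, shape, n, preview))
  invisible(x)
}

#' Sequence length in base pairs
#'
#' @param x A [nuc_seq()].
#' @return Integer length.
#' @export
seq_length <- function(x) {
  stopifnot(inherits(x, "nuc_seq"))
  nchar(x$bases)
}

# reverse complement of plain character vector over ACGTN
revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

#' Reverse complement
#'
#' Standard Watson-Crick complement with N mapping to N, applied to the
#' reversed sequence.  Applying it twice returns the input (involution).
#'
#' @param x A [nuc_seq()] or a character vector of sequences.
#' @return An object of the same type as `x`.
#' @examples
#' reverse_complement("AAAC")
#' @export
reverse_complement <- function(x) {
  if (is.character(x)) {
    return(unname(revcomp_chr(x)))
  }
  stopifnot(inherits(x, "nuc_seq"))
  out <- x
  out$bases <- revcomp_chr(x$bases)
  out
}

#' Rotate a circular sequence
#'
#' Moves the origin of a circular sequence so that position `offset`
#' (0-based) becomes position 0.  Rotation is the primitive behind starting
#' the genome at the LSC during canonicalization.
#'
#' @param x A circular [nuc_seq()].
#' @param offset Integer in `[0, length)`.
#' @return The rotated `nuc_seq` (same length, still circular).
#' @examples
#' rotate(nuc_seq("s", "ACGT", circular = TRUE), 1)$bases  # "CGTA"
#' @export
rotate <- function(x, offset) {
  stopifnot(inherits(x, "nuc_seq"))
  if (!x$circular) {
    abort("rotate() requires a circular sequence", class = "cpkit_usage_error")
  }
  n <- nchar(x$bases)
  offset <- as.integer(offset)
  if (length(offset) != 1L || is.na(offset) || offset < 0L || offset >= n) {
    abort(sprintf("offset must be in [0, %d)", n), class = "cpkit_usage_error")
  }
  if (offset == 0L) return(x)
  out <- x
  out$bases <- paste0(substr(x$bases, offset + 1L, n), substr(x$bases, 1L, offset))
  out
}

#' GC fraction of a sequence
#'
#' G+C over A+C+G+T; N is excluded from the denominator so unplaced gap
#' bases do not dilute composition.
#'
#' @param x A [nuc_seq()] or character scalar.
#' @return Numeric fraction in `[0, 1]` (`NaN` for an all-N sequence).
#' @export
gc_fraction <- function(x) {
  s <- if (inherits(x, "nuc_seq")) x$bases else x
  stopifnot(is.character(s), length(s) == 1L)
  if (nchar(s) == 0L) return(NaN)
  cnt <- Biostrings::letterFrequency(Biostrings::DNAString(s), c("A", "C", "G", "T"))
  denom <- sum(cnt)
  if (denom == 0) return(NaN)
  unname((cnt[["C"]] + cnt[["G"]]) / denom)
}

# Extract a (possibly origin-wrapping) substring of a circular sequence.
# start is 0-based; len may wrap past the end at most once.
subseq_circular <- function(bases, start, len) {
  n <- nchar(bases)
  stopifnot(len <= n)
  start <- start %% n
  if (start + len <= n) {
    substr(bases, start + 1L, start + len)
  } else {
    paste0(substr(bases, start + 1L, n), substr(bases, 1L, start + len - n))
  }
}

# split a string into a character vector of single characters
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]
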