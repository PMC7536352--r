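#' Read a FASTA file
#'
#' Multi-record FASTA reader.  Bases are uppercased, U is mapped to T, and
#' any character outside A, C, G, T, N raises a format error naming the
#' offending line.  FASTA has no standard for circularity, so the flag is
#' carried as a `circular=true` key-value token in the header description;
#' the token is parsed out of the description and restored by
#' [write_fasta()], making the round trip exact.  Gzipped files are read
#' transparently.
#'
#' @param path Path to a FASTA file (optionally gzipped).
#' @return A named list of [nuc_seq()] records (possibly empty).
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  lines <- read_text_lines(path)
  hdr_idx <- which(startsWith(lines, ">"))
  if (length(hdr_idx) == 0L) {
    if (any(nzchar(trimws(lines)))) {
      abort(sprintf("%s: line 1: expected FASTA header", path),
            class = "cpkit_format_error")
    }
    return(list())
  }
  if (hdr_idx[1L] != 1L && any(nzchar(trimws(lines[seq_len(hdr_idx[1L] - 1L)])))) {
    abort(sprintf("%s: line 1: sequence data before first header", path),
          class = "cpkit_format_error")
  }
  ends <- c(hdr_idx[-1L] - 1L, length(lines))
  out <- vector("list", length(hdr_idx))
  for (i in seq_along(hdr_idx)) {
    h <- hdr_idx[i]
    header <- sub("^>", "", lines[h])
    id <- sub("\\s.*$", "", header)
    if (!nzchar(id)) {
      abort(sprintf("%s: line %d: malformed header (empty id)", path, h),
            class = "cpkit_format_error")
    }
    desc <- if (grepl("\\s", header)) sub("^\\S+\\s+", "", header) else ""
    circular <- grepl("(^|\\s)circular=true(\\s|$)", desc, ignore.case = TRUE)
    desc <- trimws(gsub("(^|\\s)circular=(true|false)(?=\\s|$)", "", desc,
                        ignore.case = TRUE, perl = TRUE))
    body <- if (h + 1L > ends[i]) character() else lines[(h + 1L):ends[i]]
    body <- toupper(chartr("Uu", "Tt", body))
    bad <- regexpr("[^ACGTN]", gsub("\\s", "", body))
    if (any(bad != -1L)) {
      j <- which(bad != -1L)[1L]
      abort(sprintf("%s: line %d: illegal character in sequence '%s'",
                    path, h + j, id),
            class = "cpkit_format_error")
    }
    out[[i]] <- nuc_seq(id, paste(gsub("\\s", "", body), collapse = ""),
                        circular = circular,
                        desc = if (nzchar(desc)) desc else NULL)
  }
  setNames(out, map_chr(out, "id"))
}

#' Write sequences to a FASTA file
#'
#' Inverse of [read_fasta()]: ids, bases, descriptions and the circular flag
#' (emitted as a `circular=true` header token) all survive the round trip.
#'
#' @param seqs A [nuc_seq()] or list of them.
#' @param path Output path (gzipped when it ends in `.gz`).
#' @param line_width Bases per sequence line (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, line_width = 70L) {
  if (inherits(seqs, "nuc_seq")) seqs <- list(seqs)
  lines <- unlist(map(seqs, function(s) {
    stopifnot(inherits(s, "nuc_seq"))
    hdr <- paste0(">", s$id,
                  if (s$circular) " circular=true" else "",
                  if (!is.null(s$desc) && nzchar(s$desc)) paste0(" ", s$desc) else "")
    n <- nchar(s$bases)
    if (n == 0L) return(hdr)
    starts <- seq(1L, n, by = line_width)
    c(hdr, substring(s$bases, starts, pmin(starts + line_width - 1L, n)))
  }))
  write_text_lines(lines %||% character(), path)
  invisible(path)
}

#' Read a FASTQ file into a read table
#'
#' Reads are returned as a tibble (one row per read) rather than a list of
#' objects, so downstream steps can use ordinary data-frame verbs.
#' Qualities are kept in Phred+33 encoding in the `quality` column; use
#' [qual_to_int()] to decode.  For short (paired) reads the mate number is
#' parsed from a trailing `/1` or `/2` on the read id.
#'
#' @param path Path to a FASTQ file (optionally gzipped).
#' @param platform `"long"` (single-pass long reads) or `"short"`
#'   (paired short reads).
#' @return A tibble with columns `id`, `bases`, `quality`, `platform`,
#'   `mate` (integer, `NA` for long reads).
#' @export
read_fastq <- function(path, platform = c("long", "short")) {
  platform <- match.arg(platform)
  lines <- read_text_lines(path)
  if (length(lines) %% 4L != 0L) {
    abort(sprintf("%s: truncated FASTQ (line count %d not a multiple of 4)",
                  path, length(lines)), class = "cpkit_format_error")
  }
  n <- length(lines) %/% 4L
  if (n == 0L) {
    return(tibble(id = character(), bases = character(), quality = character(),
                  platform = character(), mate = integer()))
  }
  at <- function(k) lines[seq.int(k, by = 4L, length.out = n)]
  hdr <- at(1L)
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) {
    abort(sprintf("%s: line %d: expected '@' header", path, (bad[1L] - 1L) * 4L + 1L),
          class = "cpkit_format_error")
  }
  ids <- sub("\\s.*$", "", sub("^@", "", hdr))
  bases <- toupper(chartr("Uu", "Tt", at(2L)))
  qual <- at(4L)
  bad <- which(nchar(bases) != nchar(qual))
  if (length(bad)) {
    abort(sprintf("%s: record %d: quality length differs from sequence length",
                  path, bad[1L]), class = "cpkit_format_error")
  }
  bad <- which(grepl("[^ACGTN]", bases))
  if (length(bad)) {
    abort(sprintf("%s: line %d: illegal character in read '%s'",
                  path, (bad[1L] - 1L) * 4L + 2L, ids[bad[1L]]),
          class = "cpkit_format_error")
  }
  mate <- rep(NA_integer_, n)
  if (platform == "short") {
    m <- regmatches(ids, regexpr("/[12]$", ids))
    has <- grepl("/[12]$", ids)
    mate[has] <- as.integer(substring(m, 2L))
    ids <- sub("/[12]$", "", ids)
  }
  tibble(id = ids, bases = bases, quality = qual,
         platform = platform, mate = mate)
}

#' Write a read table to FASTQ
#'
#' Inverse of [read_fastq()].  Short-read mate numbers are appended to the
#' id as `/1` or `/2`.  Long reads without qualities are written with a
#' uniform placeholder quality (`"I"`, Phred 40).
#'
#' @param reads Read tibble as returned by [read_fastq()] or the simulators.
#' @param path Output path (gzipped when it ends in `.gz`).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  validate_reads(reads)
  ids <- reads$id
  if ("mate" %in% names(reads)) {
    has <- !is.na(reads$mate)
    ids[has] <- paste0(ids[has], "/", reads$mate[has])
  }
  qual <- reads$quality
  missing_q <- is.na(qual) | !nzchar(qual)
  qual[missing_q] <- strrep("I", nchar(reads$bases[missing_q]))
  lines <- as.vector(rbind(paste0("@", ids), reads$bases, "+", qual))
  write_text_lines(lines, path)
  invisible(path)
}

#' Decode Phred+33 quality strings
#'
#' @param quality Character vector of Phred+33 encoded quality strings.
#' @return A list of integer vectors of per-base Phred scores.
#' @export
qual_to_int <- function(quality) {
  map(quality, function(q) if (is.na(q)) integer() else utf8ToInt(q) - 33L)
}

#' Encode integer Phred scores as a Phred+33 string
#'
#' @param q Integer vector of Phred scores.
#' @return Character scalar.
#' @export
int_to_qual <- function(q) {
  if (length(q) == 0L) return("")
  intToUtf8(as.integer(q) + 33L)
}

paf_core_cols <- c("query_id", "query_length", "query_start", "query_end",
                   "strand", "ref_id", "ref_length", "ref_start", "ref_end",
                   "match_bp", "ref_span", "mapq")

#' Read a PAF-style alignment table
#'
#' Alignment interchange uses the 12-column PAF layout (tab-separated,
#' 0-based half-open coordinates): query name, query length, query start,
#' query end, strand, target name, target length, target start, target end,
#' number of exact matching bases (M), alignment span on the target (L) and
#' mapping quality.  M and L are the quantities entering the alignment
#' identity I = M/L.  Two optional SAM-style tags, `qa:Z:` and `ra:Z:`,
#' carry gapped query/reference alignment strings for pileup construction.
#'
#' Records violating the coordinate invariants (e.g. `match_bp > ref_span`,
#' or an empty query interval) raise a format error with the record index.
#'
#' @param path Path to the TSV (optionally gzipped).
#' @return A tibble with the 12 core columns plus `query_aln`, `ref_aln`
#'   (`NA` when absent).
#' @export
read_alignment_table <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(empty_alignment_table())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 12L)
  if (length(bad)) {
    abort(sprintf("%s: record %d: expected >= 12 tab-separated columns, got %d",
                  path, bad[1L], lengths(fields)[bad[1L]]),
          class = "cpkit_format_error")
  }
  get <- function(i) map_chr(fields, i)
  num <- function(i, name) {
    v <- suppressWarnings(as.integer(get(i)))
    bad <- which(is.na(v))
    if (length(bad)) {
      abort(sprintf("%s: record %d: non-numeric %s '%s'",
                    path, bad[1L], name, get(i)[bad[1L]]),
            class = "cpkit_format_error")
    }
    v
  }
  tag <- function(prefix) {
    map_chr(fields, function(f) {
      hit <- f[startsWith(f, prefix)]
      if (length(hit)) substring(hit[1L], nchar(prefix) + 1L) else NA_character_
    })
  }
  aln <- tibble(
    query_id = get(1L), query_length = num(2L, "query length"),
    query_start = num(3L, "query start"), query_end = num(4L, "query end"),
    strand = get(5L), ref_id = get(6L), ref_length = num(7L, "target length"),
    ref_start = num(8L, "target start"), ref_end = num(9L, "target end"),
    match_bp = num(10L, "match count"), ref_span = num(11L, "alignment span"),
    mapq = num(12L, "mapping quality"),
    query_aln = tag("qa:Z:"), ref_aln = tag("ra:Z:")
  )
  validate_alignments(aln, context = path)
  aln
}

empty_alignment_table <- function() {
  tibble(query_id = character(), query_length = integer(),
         query_start = integer(), query_end = integer(), strand = character(),
         ref_id = character(), ref_length = integer(), ref_start = integer(),
         ref_end = integer(), match_bp = integer(), ref_span = integer(),
         mapq = integer(), query_aln = character(), ref_aln = character())
}

#' Validate an alignment table against its coordinate invariants
#'
#' Checks `0 <= query_start < query_end <= query_length`,
#' `0 <= ref_start < ref_end`, `ref_span == ref_end - ref_start`,
#' `0 <= match_bp <= min(query interval, ref_span)` and `strand` in `+`/`-`.
#' For idealized alignments on a circular reference, `ref_end` may exceed
#' the reference length (the interval wraps the origin), so no upper bound
#' is imposed on reference coordinates.
#'
#' @param aln Alignment tibble (see [read_alignment_table()]).
#' @param context Label used in error messages.
#' @return `aln`, invisibly.
#' @export
validate_alignments <- function(aln, context = "alignment table") {
  need <- setdiff(paf_core_cols, names(aln))
  if (length(need)) {
    abort(sprintf("%s: missing columns: %s", context, paste(need, collapse = ", ")),
          class = "cpkit_format_error")
  }
  fail <- function(cond, msg) {
    bad <- which(cond)
    if (length(bad)) {
      abort(sprintf("%s: record %d: %s", context, bad[1L], msg),
            class = "cpkit_format_error")
    }
  }
  fail(!aln$strand %in% c("+", "-"), "strand must be '+' or '-'")
  fail(aln$query_start < 0L | aln$query_start >= aln$query_end |
         aln$query_end > aln$query_length,
       "query interval violates 0 <= start < end <= length")
  fail(aln$ref_start < 0L | aln$ref_start >= aln$ref_end,
       "reference interval violates 0 <= start < end")
  fail(aln$ref_span != aln$ref_end - aln$ref_start,
       "ref_span must equal ref_end - ref_start")
  fail(aln$match_bp < 0L |
         aln$match_bp > pmin(aln$query_end - aln$query_start, aln$ref_span),
       "match_bp exceeds min(query interval, ref_span)")
  invisible(aln)
}

#' Write a PAF-style alignment table
#'
#' Inverse of [read_alignment_table()]; gapped alignment strings, when
#' present, are emitted as `qa:Z:`/`ra:Z:` tags.
#'
#' @param aln Alignment tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_table <- function(aln, path) {
  validate_alignments(aln)
  core <- map(paf_core_cols, function(cn) as.character(aln[[cn]]))
  lines <- do.call(paste, c(core, sep = "\t"))
  if ("query_aln" %in% names(aln)) {
    has <- !is.na(aln$query_aln)
    lines[has] <- paste0(lines[has], "\tqa:Z:", aln$query_aln[has],
                         "\tra:Z:", aln$ref_aln[has])
  }
  write_text_lines(lines, path)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Tab-separated with a header line: `gene`, `functional_system`, `copies`.
#' Copy counts must be integers >= 1 and gene names unique.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `gene`, `functional_system`, `copies`.
#' @seealso [annotation_census()]
#' @export
read_annotation_table <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    abort(sprintf("%s: empty annotation table", path), class = "cpkit_format_error")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (!identical(tolower(fields[[1L]]), c("gene", "functional_system", "copies"))) {
    abort(sprintf("%s: line 1: expected header 'gene\tfunctional_system\tcopies'",
                  path), class = "cpkit_format_error")
  }
  fields <- fields[-1L]
  bad <- which(lengths(fields) != 3L)
  if (length(bad)) {
    abort(sprintf("%s: record %d: expected 3 columns", path, bad[1L]),
          class = "cpkit_format_error")
  }
  rows <- tibble(
    gene = map_chr(fields, 1L),
    functional_system = map_chr(fields, 2L),
    copies = suppressWarnings(as.integer(map_chr(fields, 3L)))
  )
  validate_annotation(rows, context = path)
  rows
}

validate_annotation <- function(rows, context = "annotation table") {
  bad <- which(is.na(rows$copies) | rows$copies < 1L)
  if (length(bad)) {
    abort(sprintf("%s: record %d: copies must be an integer >= 1", context, bad[1L]),
          class = "cpkit_format_error")
  }
  dup <- rows$gene[duplicated(rows$gene)]
  if (length(dup)) {
    abort(sprintf("%s: duplicate gene name '%s'", context, dup[1L]),
          class = "cpkit_format_error")
  }
  invisible(rows)
}

#' Write a gene annotation table
#'
#' @param rows Annotation tibble (`gene`, `functional_system`, `copies`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(rows, path) {
  validate_annotation(rows)
  lines <- c("gene\tfunctional_system\tcopies",
             paste(rows$gene, rows$functional_system, rows$copies, sep = "\t"))
  write_text_lines(lines, path)
  invisible(path)
}

#' Read / write newick trees
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()]; trees are
#' `phylo` objects with branch lengths in substitutions per bp.
#'
#' @param path Path to a newick file.
#' @return For `read_newick()`, a `phylo` object.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) {
    abort(sprintf("%s: not a parseable newick tree", path),
          class = "cpkit_format_error")
  }
  tr
}

#' @rdname read_newick
#' @param tree A `phylo` object.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

validate_reads <- function(reads) {
  need <- setdiff(c("id", "bases"), names(reads))
  if (length(need)) {
    abort(paste0("read table is missing columns: ", paste(need, collapse = ", ")),
          class = "cpkit_usage_error")
  }
  if (!"quality" %in% names(reads)) reads$quality <- NA_character_
  if ("mate" %in% names(reads) && "platform" %in% names(reads)) {
    bad <- which(!is.na(reads$mate) & reads$platform != "short")
    if (length(bad)) {
      abort(sprintf("record %d: mate numbers are only valid for short reads", bad[1L]),
            class = "cpkit_usage_error")
    }
  }
  invisible(reads)
}

# -- shared plain-text helpers ------------------------------------------------

read_text_lines <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "cpkit_io_error")
  }
  con <- gzfile(path, "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

write_text_lines <- function(lines, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  tryCatch(writeLines(lines, con), error = function(e) {
    close(con)
    abort(sprintf("cannot write to %s: %s", path, conditionMessage(e)),
          class = "cpkit_io_error")
  })
  close(con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
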