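#' Hybrid assembly pipeline: merge, circularize, polish, canonicalize
#'
#' The long-read arm of the workflow, starting from draft contigs: contigs
#' are merged along their overlaps and circularized; the circle is
#' polished with short reads (when supplied); the quadripartite structure
#' is detected, the genome canonicalized to start at the LSC, and region
#' statistics computed.  Every intermediate is written to `out_dir` when
#' given.
#'
#' @param contigs List of [nuc_seq()] draft contigs (or path to a FASTA).
#' @param short_reads Optional read tibble (or path to a FASTQ) for
#'   polishing.
#' @param merge_params,polish_params,min_ir_bp,max_mismatch_rate Stage
#'   parameters.
#' @param out_dir Optional output directory.
#' @return List of class `pipeline_result`: `genome` (canonical circular
#'   [nuc_seq()]), `structure`, `stats` ([region_stats()] tibble),
#'   `assembly` ([assemble_draft()] result), `polish`
#'   ([polish()] result or `NULL`).
#' @export
run_pipeline_hybrid <- function(contigs, short_reads = NULL,
                                merge_params = cpkit::merge_params(),
                                polish_params = cpkit::polish_params(),
                                min_ir_bp = 1000L, max_mismatch_rate = 0.01,
                                out_dir = NULL) {
  if (is.character(contigs)) contigs <- read_fasta(contigs)
  if (is.character(short_reads)) short_reads <- read_fastq(short_reads, "short")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            class = "cpkit_stage_error")
    })
  }
  asm <- stage("merge+circularize", assemble_draft(contigs, merge_params))
  if (asm$status != "circular") {
    abort("stage 'circularize' failed: draft is not circularizable",
          class = "cpkit_stage_error")
  }
  pol <- NULL
  genome <- asm$seq
  if (!is.null(short_reads)) {
    pol <- stage("polish", polish(genome, short_reads, polish_params))
    genome <- pol$seq
  }
  st <- stage("structure", detect_quadripartite(genome, min_ir_bp,
                                                max_mismatch_rate))
  can <- stage("canonicalize", canonicalize(genome, st))
  stats <- stage("stats", region_stats(can$seq, can$structure))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(asm$seq, file.path(out_dir, "draft_circular.fasta"))
    write_fasta(can$seq, file.path(out_dir, "genome_canonical.fasta"))
    if (!is.null(pol)) {
      readr_write_tsv(pol$edits, file.path(out_dir, "polish_edits.tsv"))
    }
    readr_write_tsv(structure_table(can$structure),
                    file.path(out_dir, "structure.tsv"))
    readr_write_tsv(stats, file.path(out_dir, "region_stats.tsv"))
  }
  structure(list(genome = can$seq, structure = can$structure, stats = stats,
                 assembly = asm, polish = pol),
            class = "pipeline_result")
}

#' Reference-guided assembly pipeline: scaffold, canonicalize
#'
#' The short-read arm of the workflow: fragmented contigs are scaffolded
#' against a finished reference (restoring the collapsed inverted repeat),
#' the structure of the result is detected, and the genome is
#' canonicalized and summarized.
#'
#' @param contigs List of [nuc_seq()] contigs (or path to a FASTA).
#' @param reference Canonical [nuc_seq()] reference (or path to a FASTA
#'   whose first record is used).
#' @param ref_structure Optional [quadripartite_structure()] of the
#'   reference (detected when `NULL`).
#' @param scaffold_params [scaffold_params()].
#' @param out_dir Optional output directory.
#' @return List of class `pipeline_result`: `genome`, `structure`,
#'   `stats`, `scaffold` ([scaffold()] result).
#' @export
run_pipeline_reference <- function(contigs, reference, ref_structure = NULL,
                                   scaffold_params = cpkit::scaffold_params(),
                                   out_dir = NULL) {
  if (is.character(contigs)) contigs <- read_fasta(contigs)
  if (is.character(reference)) reference <- read_fasta(reference)[[1L]]
  sc <- scaffold(contigs, reference, ref_structure, scaffold_params)
  st <- detect_quadripartite(sc$seq)
  can <- canonicalize(sc$seq, st)
  stats <- region_stats(can$seq, can$structure)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(can$seq, file.path(out_dir, "genome_canonical.fasta"))
    readr_write_tsv(sc$layout$placements, file.path(out_dir, "layout.tsv"))
    readr_write_tsv(structure_table(can$structure),
                    file.path(out_dir, "structure.tsv"))
    readr_write_tsv(stats, file.path(out_dir, "region_stats.tsv"))
  }
  structure(list(genome = can$seq, structure = can$structure, stats = stats,
                 scaffold = sc),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> canonical genome %d bp\n", seq_length(x$genome)))
  print(x$stats)
  invisible(x)
}

# structure as a 1-based inclusive table for reports
structure_table <- function(structure) {
  tibble(region = structure$region,
         start = structure$start + 1L,
         end = structure$end,
         length = structure$length)
}

readr_write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  for (cn in names(df)) if (is.list(df[[cn]])) df[[cn]] <- NULL
  lines <- c(paste(names(df), collapse = "\t"),
             do.call(paste, c(lapply(df, as.character), sep = "\t")))
  write_text_lines(lines, path)
}
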