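aln_row <- function(id, qlen, qs, qe, m = qe - qs, rs = 0L) {
  tibble::tibble(query_id = id, query_length = qlen, query_start = qs,
                 query_end = qe, strand = "+", ref_id = "cp",
                 ref_length = 200000L, ref_start = rs, ref_end = rs + (qe - qs),
                 match_bp = m, ref_span = qe - qs, mapq = 60L)
}

test_that("alignment identity is M over L", {
  expect_equal(alignment_identity(
    tibble::tibble(match_bp = 900, ref_span = 1000))$identity, 0.9)
  expect_equal(alignment_identity(
    tibble::tibble(match_bp = 0, ref_span = 10))$identity, 0)
  expect_equal(alignment_identity(
    tibble::tibble(match_bp = 750, ref_span = 750))$identity, 1)
  expect_error(alignment_identity(tibble::tibble(match_bp = 0, ref_span = 0)),
               class = "cpkit_domain_error")
})

test_that("quality trimming applies the end-trim, cut and length rules", {
  mk <- function(q) tibble::tibble(
    id = "r", bases = strrep("A", length(q)), quality = int_to_qual(q),
    platform = "short", mate = 1L)
  # all high quality: unchanged
  out <- trim_by_quality(mk(rep(30L, 150)))
  expect_equal(nchar(out$bases), 150L)
  # 60 low-quality leading bases leave 90 < 100: rejected
  out <- trim_by_quality(mk(c(rep(10L, 60), rep(30L, 90))))
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "n_rejected"), 1L)
  # 99 bp of perfect quality: rejected on length alone
  expect_equal(nrow(trim_by_quality(mk(rep(40L, 99)))), 0L)
  # internal low-quality base: longer fragment kept, then length-checked
  q <- c(rep(30L, 120), 5L, rep(30L, 160))
  out <- trim_by_quality(mk(q))
  expect_equal(nchar(out$bases), 160L)
  expect_equal(nchar(out$quality), 160L)
  # every surviving base passes the threshold
  expect_true(all(qual_to_int(out$quality)[[1]] >= 20L))
  expect_error(trim_by_quality(tibble::tibble(id = "r", bases = "ACGT",
                                              quality = NA_character_)),
               class = "cpkit_usage_error")
})

test_that("long-read rule: record filter, interval union, both thresholds", {
  p <- classifier_params()
  # 1200 bp read: [0,1000) kept, 400 bp record discarded -> union 1000,
  # fraction 0.833 -> accepted
  alns <- rbind(aln_row("r", 1200L, 0L, 1000L), aln_row("r", 1200L, 800L, 1200L))
  res <- classify_long_read(1200L, alns, p)
  expect_true(res$is_chloroplast)
  expect_equal(res$aligned_bp, 1000L)
  expect_equal(res$n_records_used, 1L)
  # union 1200 >= 1000 but fraction 0.6 < 0.8 -> rejected
  alns <- rbind(aln_row("r", 2000L, 0L, 600L), aln_row("r", 2000L, 1000L, 1600L))
  res <- classify_long_read(2000L, alns, p)
  expect_false(res$is_chloroplast)
  expect_equal(res$aligned_bp, 1200L)
  # no alignments -> rejected with aligned_bp 0
  res <- classify_long_read(1500L, aln_row("x", 1L, 0L, 1L)[0, ], p)
  expect_false(res$is_chloroplast)
  expect_equal(res$aligned_bp, 0L)
  # duplicated identical records do not inflate the union
  alns <- rbind(aln_row("r", 1200L, 0L, 1000L), aln_row("r", 1200L, 0L, 1000L))
  expect_equal(classify_long_read(1200L, alns, p)$aligned_bp, 1000L)
  # inconsistent query_length is an input error
  bad <- rbind(aln_row("r", 1200L, 0L, 1000L), aln_row("r", 1300L, 0L, 600L))
  expect_error(classify_long_read(1200L, bad, p), class = "cpkit_input_error")
})

test_that("pair rule requires a sufficient block on both mates", {
  p <- classifier_params()
  m1 <- aln_row("p/1", 251L, 0L, 150L)
  m2 <- aln_row("p/2", 251L, 0L, 120L)
  expect_true(classify_read_pair(m1, m2, p)$is_chloroplast)
  m2$query_end <- 80L; m2$ref_end <- 80L; m2$ref_span <- 80L; m2$match_bp <- 80L
  expect_false(classify_read_pair(m1, m2, p)$is_chloroplast)
  expect_false(classify_read_pair(m1, m1[0, ], p)$is_chloroplast)
})

test_that("batch classification matches a brute-force oracle and is monotone", {
  g <- simulate_genome(genome_spec(6000, 1500, 800), seed = 2)
  mix <- simulate_wgs_mixture(
    g$seq, long_read_spec(sub_rate = 0, ins_rate = 0, del_rate = 0),
    background_bp = 30000L, cp_read_fraction = 0.4, n_reads = 50L, seed = 9)
  p <- classifier_params()
  res <- suppressMessages(classify_batch(mix$reads, mix$alignments, p))
  oracle <- oracle_classify_batch(mix$reads, mix$alignments, p)
  expect_equal(setNames(res$is_chloroplast, res$read_id), oracle[res$read_id])
  # summary counts agree with the rows
  s <- attr(res, "summary")
  expect_equal(s$n_accepted, sum(res$is_chloroplast))
  expect_equal(s$n_input, nrow(res))
  # sensitivity/specificity of the rules on idealized alignments
  m <- dplyr::left_join(res, mix$truth, by = c(read_id = "id"))
  expect_true(all(m$is_chloroplast.x[m$is_chloroplast.y & m$length >= 1250]))
  expect_true(all(!m$is_chloroplast.x[!m$is_chloroplast.y]))
  # raising any threshold never increases the accepted set
  accepted <- function(p) {
    r <- suppressMessages(classify_batch(mix$reads, mix$alignments, p))
    r$read_id[r$is_chloroplast]
  }
  base <- accepted(p)
  for (pp in list(classifier_params(min_record_query_bp = 900),
                  classifier_params(min_total_query_bp = 2500),
                  classifier_params(min_query_fraction = 0.95))) {
    expect_true(all(accepted(pp) %in% base))
  }
  # relaxed to zero: every read with at least one alignment is accepted
  p0 <- classifier_params(min_record_query_bp = 0, min_total_query_bp = 0,
                          min_query_fraction = 0)
  r0 <- suppressMessages(classify_batch(mix$reads, mix$alignments, p0))
  with_aln <- unique(mix$alignments$query_id)
  expect_true(all(r0$is_chloroplast[r0$read_id %in% with_aln]))
  # empty alignment table: nothing accepted
  r_empty <- suppressMessages(classify_batch(mix$reads, mix$alignments[0, ], p))
  expect_equal(sum(r_empty$is_chloroplast), 0L)
  # unknown read ids in the table are skipped with a warning
  stray <- mix$alignments[1, ]
  stray$query_id <- "not_a_read"
  expect_warning(
    suppressMessages(classify_batch(mix$reads, rbind(mix$alignments, stray), p)),
    "unknown read")
})

test_that("short-read pair batches apply the block rule per mate", {
  reads <- tibble::tibble(
    id = rep(c("a", "b", "c"), each = 2L),
    bases = strrep("A", 251), quality = strrep("I", 251),
    platform = "short", mate = rep(c(1L, 2L), 3L))
  alns <- rbind(
    aln_row("a/1", 251L, 0L, 150L), aln_row("a/2", 251L, 0L, 120L),
    aln_row("b/1", 251L, 0L, 150L), aln_row("b/2", 251L, 0L, 80L),
    aln_row("c/1", 251L, 0L, 251L))
  res <- suppressMessages(classify_batch(reads, alns, classifier_params()))
  expect_equal(setNames(res$is_chloroplast, res$read_id),
               c(a = TRUE, b = FALSE, c = FALSE))
})
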