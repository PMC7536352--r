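test_that("simulate_genome builds the requested quadripartite circle deterministically", {
  spec <- genome_spec(8000, 2000, 1200)
  g1 <- simulate_genome(spec, seed = 91)
  g2 <- simulate_genome(spec, seed = 91)
  g3 <- simulate_genome(spec, seed = 92)
  expect_identical(g1$seq$bases, g2$seq$bases)
  expect_false(identical(g1$seq$bases, g3$seq$bases))
  expect_equal(seq_length(g1$seq), 8000L + 2000L + 1200L + 2000L)
  expect_true(g1$seq$circular)
  expect_equal(g1$structure$length, c(8000L, 2000L, 1200L, 2000L))
  # IRB is the reverse complement of IRA
  ira <- substr(g1$seq$bases, 8001, 10000)
  irb <- substr(g1$seq$bases, 11201, 13200)
  expect_equal(reverse_complement(ira), irb)
  # with divergence, exactly that many substitutions separate the copies
  gd <- simulate_genome(genome_spec(8000, 2000, 1200, ir_divergence_sites = 7L),
                        seed = 93)
  ira <- substr(gd$seq$bases, 8001, 10000)
  irb <- substr(gd$seq$bases, 11201, 13200)
  expect_equal(sum(strsplit(reverse_complement(irb), "")[[1]] !=
                     strsplit(ira, "")[[1]]), 7L)
  expect_error(genome_spec(1000, 2000, 3000), class = "cpkit_usage_error")
})

test_that("realized region GC lies within three standard errors of target", {
  spec <- genome_spec(8000, 2000, 1200)
  g <- simulate_genome(spec, seed = 94)
  st <- g$structure
  for (r in c("lsc", "ira", "ssc")) {
    iv <- st[st$region == r, ]
    gc <- gc_fraction(substr(g$seq$bases, iv$start + 1, iv$end))
    target <- switch(r, lsc = spec$gc_lsc, ira = spec$gc_ir, ssc = spec$gc_ssc)
    se <- sqrt(target * (1 - target) / iv$length)
    expect_lt(abs(gc - target), 3 * se)
  }
})

test_that("long reads are exact circle substrings when error-free", {
  g <- simulate_genome(genome_spec(6000, 1500, 900), seed = 95)
  spec0 <- long_read_spec(coverage = 5, sub_rate = 0, ins_rate = 0, del_rate = 0)
  lr <- simulate_long_reads(g$seq, spec0, seed = 96)
  expect_identical(lr$reads,
                   simulate_long_reads(g$seq, spec0, seed = 96)$reads)
  doubled <- paste0(g$seq$bases, g$seq$bases)
  doubled_rc <- reverse_complement(doubled)
  hits <- vapply(lr$reads$bases, function(b) {
    grepl(b, doubled, fixed = TRUE) || grepl(b, doubled_rc, fixed = TRUE)
  }, logical(1))
  expect_true(all(hits))
  # total bases within 10% of the requested coverage
  expect_lt(abs(sum(nchar(lr$reads$bases)) / seq_length(g$seq) - 5) / 5, 0.1)
  # truth table matches read origins
  i <- 3L
  expect_equal(nchar(lr$reads$bases[i]), lr$truth$length[i])
})

test_that("short pairs behave like real paired-end fragments", {
  g <- simulate_genome(genome_spec(6000, 1500, 900), seed = 97)
  sp <- short_pair_spec(coverage = 8)
  pr <- simulate_short_pairs(g$seq, sp, seed = 98)
  expect_identical(pr$reads, simulate_short_pairs(g$seq, sp, seed = 98)$reads)
  expect_equal(nrow(pr$reads) %% 2L, 0L)
  doubled <- paste0(g$seq$bases, g$seq$bases)
  doubled_rc <- reverse_complement(doubled)
  hits <- vapply(pr$reads$bases[1:40], function(b) {
    grepl(b, doubled, fixed = TRUE) || grepl(b, doubled_rc, fixed = TRUE)
  }, logical(1))
  expect_true(all(hits))
  cov <- sum(nchar(pr$reads$bases)) / seq_length(g$seq)
  expect_lt(abs(cov - 8) / 8, 0.1)
  # constant Q40 qualities pass quality trimming untouched
  trimmed <- trim_by_quality(pr$reads[1:20, ])
  expect_equal(trimmed$bases, pr$reads$bases[1:20])
  # the 3' decay model produces decreasing tail qualities
  dec <- simulate_short_pairs(g$seq, short_pair_spec(coverage = 1,
                                                     quality_decay_bp = 40L),
                              seed = 99)
  q <- qual_to_int(dec$reads$quality[1])[[1]]
  expect_lt(q[length(q)], q[1])
})

test_that("draft contigs reproduce the IR-boundary break pattern", {
  g <- simulate_genome(genome_spec(8000, 2000, 1200), seed = 100)
  d <- simulate_draft_contigs(g$seq, g$structure, terminal_overlap_bp = 700L)
  expect_length(d$contigs, 3L)
  expect_equal(unname(sapply(d$contigs, seq_length)),
               d$truth_layout$length)
  # total redundancy equals three junction overlaps
  expect_equal(sum(d$truth_layout$length) - seq_length(g$seq), 3L * 700L)
  expect_error(simulate_draft_contigs(g$seq, g$structure,
                                      terminal_overlap_bp = 1300L),
               class = "cpkit_usage_error")
})

test_that("collapsed contigs drop one IR copy and shuffle deterministically", {
  g <- simulate_genome(genome_spec(8000, 2000, 1200), seed = 101)
  cc <- simulate_collapsed_contigs(g$seq, g$structure, n_breaks = 4L,
                                   spacing_bp = 900L,
                                   boundary_margin_bp = 900L, seed = 102)
  expect_length(cc$contigs, 5L)
  expect_identical(
    sapply(cc$contigs, function(x) x$bases),
    sapply(simulate_collapsed_contigs(g$seq, g$structure, n_breaks = 4L,
                                      spacing_bp = 900L,
                                      boundary_margin_bp = 900L,
                                      seed = 102)$contigs,
           function(x) x$bases))
  # union of fragments covers LSC+IRA+SSC once, with 50 bp extra per break
  collapsed_len <- sum(g$structure$length) - 2000L
  expect_equal(sum(sapply(cc$contigs, seq_length)), collapsed_len + 4L * 50L)
  expect_error(simulate_collapsed_contigs(g$seq, g$structure, n_breaks = 500L),
               class = "cpkit_usage_error")
})

test_that("the WGS mixture carries truth labels and idealized alignments", {
  g <- simulate_genome(genome_spec(6000, 1500, 900), seed = 103)
  spec0 <- long_read_spec(coverage = 5, sub_rate = 0, ins_rate = 0, del_rate = 0)
  mix <- simulate_wgs_mixture(g$seq, spec0, background_bp = 50000L,
                              cp_read_fraction = 0.4, n_reads = 1000L,
                              seed = 104)
  # binomial sampling property for the cp fraction
  n_cp <- sum(mix$truth$is_chloroplast)
  expect_lt(abs(n_cp - 400), 3 * sqrt(1000 * 0.4 * 0.6))
  # alignments exist exactly for the cp reads
  expect_setequal(unique(mix$alignments$query_id),
                  mix$truth$id[mix$truth$is_chloroplast])
  validate_alignments(mix$alignments)
  expect_error(simulate_wgs_mixture(g$seq, spec0, cp_read_fraction = 1),
               class = "cpkit_usage_error")
})
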