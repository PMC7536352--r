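toy_ref <- function(seed = 51) {
  simulate_genome(genome_spec(8000, 2000, 1200), seed = seed)
}

test_that("anchor_contigs places exact, inverted-repeat and random contigs", {
  g <- toy_ref()
  ref <- nuc_seq("ref", g$seq$bases)   # canonical linear reference
  # a contig equal to reference[1000:4000) anchors once on the plus strand
  c1 <- nuc_seq("c1", substr(ref$bases, 1001, 4000))
  pl <- anchor_contigs(list(c1), ref, g$structure)
  expect_equal(nrow(pl), 1L)
  expect_equal(pl$ref_start, 1000L)
  expect_equal(pl$ref_end, 4000L)
  expect_equal(pl$strand, "+")
  expect_equal(pl$identity, 1)
  expect_equal(pl$query_coverage, 1)
  # a contig equal to the IR anchors at both copies on opposite strands
  ira <- substr(ref$bases, 8001, 10000)
  pl2 <- anchor_contigs(list(nuc_seq("ir", ira)), ref, g$structure)
  expect_equal(nrow(pl2), 2L)
  expect_setequal(pl2$strand, c("+", "-"))
  # IRA starts at 8000, IRB at LSC+IRA+SSC = 11200
  expect_setequal(pl2$ref_start, c(8000L, 11200L))
  # random sequence stays unplaced
  pl3 <- anchor_contigs(list(nuc_seq("r", random_seq(2000, seed = 3))),
                        ref, g$structure)
  expect_equal(nrow(pl3), 0L)
})

test_that("select_and_order computes joins and completeness", {
  g <- toy_ref(seed = 52)
  ref <- nuc_seq("ref", g$seq$bases)
  cc <- simulate_collapsed_contigs(g$seq, g$structure, n_breaks = 4L,
                                   spacing_bp = 900L,
                                   boundary_margin_bp = 900L, seed = 53)
  pl <- anchor_contigs(cc$contigs, ref, g$structure)
  lay <- select_and_order(pl, g$structure)
  expect_true(lay$is_complete)
  expect_equal(nrow(lay$uncovered), 0L)
  # overlap joins carry the simulated 50 bp terminal overlaps
  ov <- lay$placements$join_bp[lay$placements$join_type == "overlap"]
  expect_true(all(ov == 50L))
  # deleting a middle single-copy contig leaves an N-fillable gap
  lsc_only <- lay$placements
  victim <- lsc_only$contig_id[lsc_only$ref_start > 500 &
                                 lsc_only$ref_end < 7500][1]
  pl_gap <- pl[pl$contig_id != victim, ]
  lay_gap <- select_and_order(pl_gap, g$structure)
  expect_true(lay_gap$is_complete)
  gap_bp <- sum(lay_gap$placements$join_bp[lay_gap$placements$join_type == "gap"])
  expect_gt(gap_bp, 0L)
  joined <- join_layout(lay_gap, cc$contigs)
  expect_equal(stringr::str_count(joined$bases, "N"), gap_bp)
})

test_that("scaffold restores both inverted repeats from a collapsed assembly", {
  for (seed in c(54, 55)) {
    g <- toy_ref(seed = seed)
    ref <- nuc_seq("ref", g$seq$bases)
    cc <- simulate_collapsed_contigs(g$seq, g$structure, n_breaks = 5L,
                                     spacing_bp = 800L,
                                     boundary_margin_bp = 850L,
                                     seed = seed + 100)
    out <- scaffold(cc$contigs, ref, g$structure)
    expect_true(out$seq$circular)
    can <- canonicalize(out$seq)
    expect_equal(can$seq$bases, canonical_truth(g))
    # the two IRs in the output are exact reverse complements
    st <- can$structure
    ira <- substr(can$seq$bases, st$start[st$region == "ira"] + 1,
                  st$end[st$region == "ira"])
    irb <- substr(can$seq$bases, st$start[st$region == "irb"] + 1,
                  st$end[st$region == "irb"])
    expect_equal(reverse_complement(irb), ira)
    # byte-identical on a rerun (determinism)
    out2 <- scaffold(cc$contigs, ref, g$structure)
    expect_identical(out$seq$bases, out2$seq$bases)
  }
})

test_that("a single collapsed contig is enough to restore the second IR", {
  g <- toy_ref(seed = 56)
  cc <- simulate_collapsed_contigs(g$seq, g$structure, n_breaks = 0L, seed = 57)
  expect_length(cc$contigs, 1L)
  out <- scaffold(cc$contigs, nuc_seq("ref", g$seq$bases), g$structure)
  expect_equal(canonicalize(out$seq)$seq$bases, canonical_truth(g))
})

test_that("scaffolding tolerates contig noise and reference divergence", {
  g <- toy_ref(seed = 58)
  ref <- nuc_seq("ref", g$seq$bases)
  cc <- simulate_collapsed_contigs(g$seq, g$structure, n_breaks = 4L,
                                   spacing_bp = 900L,
                                   boundary_margin_bp = 900L, seed = 59)
  substitute_at_rate <- function(s, rate, seed) {
    set.seed(seed)
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    at <- which(runif(length(b)) < rate)
    for (p in at) b[p] <- setdiff(c("A", "C", "G", "T"), b[p])[sample.int(3, 1)]
    paste(b, collapse = "")
  }
  # 1% substitution noise in the contigs: the noise itself caps the
  # attainable identity at ~0.99 in expectation, so require that the
  # reconstruction adds at most a small amount on top of it
  noisy <- lapply(cc$contigs, function(ct) {
    nuc_seq(ct$id, substitute_at_rate(ct$bases, 0.01, seed = 60))
  })
  out_noisy <- scaffold(noisy, ref, g$structure)
  can_noisy <- canonicalize(out_noisy$seq)
  expect_equal(seq_length(can_noisy$seq), seq_length(g$seq))
  expect_gte(ident_frac(can_noisy$seq$bases, canonical_truth(g)), 0.985)
  # the restored IRs mirror each other, noise included
  stn <- can_noisy$structure
  ira_n <- substr(can_noisy$seq$bases, stn$start[stn$region == "ira"] + 1,
                  stn$end[stn$region == "ira"])
  irb_n <- substr(can_noisy$seq$bases, stn$start[stn$region == "irb"] + 1,
                  stn$end[stn$region == "irb"])
  expect_equal(reverse_complement(irb_n), ira_n)
  # 2% diverged reference still yields a complete layout
  divref <- nuc_seq("divref", substitute_at_rate(g$seq$bases, 0.02, seed = 61))
  out_div <- scaffold(cc$contigs, divref, g$structure)
  expect_true(out_div$layout$is_complete)
  expect_gte(ident_frac(canonicalize(out_div$seq)$seq$bases,
                        canonical_truth(g)), 0.99)
})

test_that("an uncoverable reference interval is a stage error", {
  g <- toy_ref(seed = 62)
  ref <- nuc_seq("ref", g$seq$bases)
  cc <- simulate_collapsed_contigs(g$seq, g$structure, n_breaks = 5L,
                                   spacing_bp = 800L,
                                   boundary_margin_bp = 850L, seed = 63)
  # drop every contig touching an LSC window wider than max_gap_bp
  keep <- purrr::keep(cc$contigs, function(ct) {
    pl <- anchor_contigs(list(ct), ref, g$structure)
    nrow(pl) > 0 && all(pl$ref_end <= 2000 | pl$ref_start >= 5000)
  })
  expect_gt(length(keep), 0L)
  expect_error(scaffold(keep, ref, g$structure,
                        scaffold_params(max_gap_bp = 1000L)),
               "uncovered", class = "cpkit_stage_error")
})
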