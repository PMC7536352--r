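test_that("detect_quadripartite recovers simulated structures exactly", {
  for (seed in c(71, 72)) {
    g <- simulate_genome(genome_spec(8000, 2000, 1200), seed = seed)
    st <- detect_quadripartite(g$seq)
    expect_equal(as.data.frame(st), as.data.frame(g$structure))
    expect_equal(attr(st, "ir_mismatches"), 0L)
  }
  # injected IR divergence is counted and the boundaries still recovered
  g <- simulate_genome(genome_spec(8000, 2000, 1200, ir_divergence_sites = 5L),
                       seed = 73)
  st <- detect_quadripartite(g$seq)
  expect_equal(st$length, g$structure$length)
  expect_equal(attr(st, "ir_mismatches"), 5L)
  # random sequence has no quadripartite structure
  r <- nuc_seq("r", random_seq(40000, seed = 74), circular = TRUE)
  expect_error(detect_quadripartite(r), class = "cpkit_no_structure_error")
  # linear input is refused
  expect_error(detect_quadripartite(nuc_seq("l", random_seq(9000, seed = 1))),
               class = "cpkit_usage_error")
})

test_that("canonicalize is idempotent and rotation/strand invariant", {
  g <- simulate_genome(genome_spec(6000, 1500, 900), seed = 75)
  can <- canonicalize(g$seq, g$structure)
  # already canonical: fixed point
  again <- canonicalize(can$seq, can$structure)
  expect_identical(again$seq$bases, can$seq$bases)
  # any rotation and either strand give the same canonical sequence and
  # the same region lengths
  set.seed(76)
  for (i in 1:8) {
    x <- rotate(g$seq, sample.int(seq_length(g$seq) - 1L, 1L))
    if (i %% 2 == 0) x <- reverse_complement(x)
    cx <- canonicalize(x)
    expect_identical(cx$seq$bases, can$seq$bases)
    expect_equal(cx$structure$length, can$structure$length)
  }
})

test_that("structure validation enforces the quadripartite invariants", {
  st <- structure_from_lengths(20000, 6000, 3000, 6000)
  expect_equal(attr(st, "genome_length"), 35000L)
  expect_equal(st$region, c("lsc", "ira", "ssc", "irb"))
  # LSC must exceed SSC
  expect_error(structure_from_lengths(3000, 6000, 20000, 6000),
               class = "cpkit_usage_error")
  # regions must tile the circle
  expect_error(quadripartite_structure(c(0, 10), c(15, 20), c(20, 25),
                                       c(25, 30), 30),
               class = "cpkit_usage_error")
})

test_that("region_stats computes lengths and GC per region", {
  # constructed 40 bp genome: AT-rich single copies, GC-rich repeats
  lsc <- strrep("AT", 10)                       # 20 bp, gc 0
  ira <- strrep("GC", 4)                        # 8 bp, gc 1
  ssc <- "AATT"                                 # 4 bp, gc 0
  irb <- reverse_complement(ira)                # 8 bp, gc 1
  genome <- nuc_seq("g", paste0(lsc, ira, ssc, irb), circular = TRUE)
  st <- structure_from_lengths(20, 8, 4, 8)
  rs <- region_stats(genome, st)
  expect_equal(rs$length[rs$region == "overall"], 40L)
  expect_equal(rs$gc_fraction[rs$region == "lsc"], 0)
  expect_equal(rs$gc_fraction[rs$region == "ssc"], 0)
  expect_equal(rs$gc_fraction[rs$region == "ira"], 1)
  expect_equal(rs$gc_fraction[rs$region == "ir_combined"], 1)
  expect_equal(sum(rs$length[1:4]), 40L)
  # mismatched genome length is an error
  expect_error(region_stats(nuc_seq("g", "ACGT", circular = TRUE), st),
               class = "cpkit_input_error")
})

test_that("annotation census tallies systems and copy numbers", {
  rows <- tibble::tibble(
    gene = c("a", "b", "c", "d"),
    functional_system = c("S1", "S1", "S2", "S2"),
    copies = c(1L, 2L, 3L, 1L))
  cen <- annotation_census(rows)
  expect_equal(cen$totals$distinct_genes, 4L)
  expect_equal(cen$totals$total_copies, 7L)
  expect_equal(cen$totals$n_single, 2L)
  expect_equal(cen$totals$n_double, 1L)
  expect_equal(cen$totals$n_triple, 1L)
  expect_equal(cen$totals$total_copies,
               cen$totals$n_single + 2L * cen$totals$n_double +
                 3L * cen$totals$n_triple)
  expect_equal(sort(tidy(cen)$n_copies), c(3L, 4L))
  # empty table gives all zeros
  cen0 <- annotation_census(rows[0, ])
  expect_equal(unlist(cen0$totals), c(distinct_genes = 0L, total_copies = 0L,
                                      n_single = 0L, n_double = 0L,
                                      n_triple = 0L))
  # duplicate gene names are rejected
  expect_error(annotation_census(rbind(rows, rows[1, ])),
               class = "cpkit_format_error")
})

test_that("gene totals add rRNA and tRNA counts and are additive", {
  rows <- tibble::tibble(gene = letters[1:3], functional_system = "S",
                         copies = c(1L, 2L, 1L))
  cen <- annotation_census(rows)
  expect_equal(gene_totals(cen, 8, 48), 4L + 8L + 48L)
  expect_equal(gene_totals(cen, 0, 0), 4L)
  rows2 <- tibble::tibble(gene = letters[4:5], functional_system = "S",
                          copies = c(1L, 1L))
  both <- annotation_census(rbind(rows, rows2))
  expect_equal(gene_totals(both, 0, 0),
               gene_totals(cen, 0, 0) + gene_totals(annotation_census(rows2), 0, 0))
})

test_that("autoplot methods return ggplot objects", {
  st <- structure_from_lengths(20000, 6000, 3000, 6000)
  expect_s3_class(autoplot(st), "ggplot")
  rows <- tibble::tibble(gene = c("a", "b"), functional_system = c("S1", "S2"),
                         copies = c(1L, 2L))
  expect_s3_class(autoplot(annotation_census(rows)), "ggplot")
})
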