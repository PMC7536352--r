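exact_aln <- function(id, start, seqs) {
  tibble::tibble(read_id = id, strand = "+", ref_start = start,
                 query_aln = seqs, ref_aln = seqs)
}

test_that("build_pileup tallies agreement, splits and wrap-around coverage", {
  set.seed(31)
  draft <- nuc_seq("d", random_seq(100), circular = TRUE)
  piece <- substr(draft$bases, 21, 80)
  # ten identical error-free reads: depth 10, consensus equals the draft
  aln <- exact_aln(sprintf("r%02d", 1:10), 20L, rep(piece, 10))
  pu <- build_pileup(draft, aln)
  expect_s3_class(pu, "pileup")
  expect_equal(pu$columns$depth[21:80], rep(10L, 60))
  expect_equal(pu$columns$depth[1:20], rep(0L, 20))
  expect_equal(nrow(call_edits(pu, draft)), 0L)
  # depth = sum of base counts + deletions everywhere
  cols <- pu$columns
  expect_equal(cols$depth, cols$A + cols$C + cols$G + cols$T + cols$N + cols$del)
  # one read with a substitution at position 50 gives a 9:1 split
  mut <- piece
  at <- 50 - 20   # position 50 (0-based) is offset 30 within the piece
  substr(mut, at + 1, at + 1) <- setdiff(c("A", "C", "G", "T"),
                                         substr(mut, at + 1, at + 1))[1]
  aln2 <- aln
  aln2$query_aln[10] <- mut
  pu2 <- build_pileup(draft, aln2)
  cc <- pu2$columns[51, c("A", "C", "G", "T")]
  expect_equal(sort(as.integer(cc), decreasing = TRUE)[1:2], c(9L, 1L))
  # wrap-around read covers both flanks of the origin
  wrap <- paste0(substr(draft$bases, 91, 100), substr(draft$bases, 1, 10))
  pu3 <- build_pileup(draft, exact_aln("w", 90L, wrap))
  expect_equal(pu3$columns$depth[c(1:10, 91:100)], rep(1L, 20))
  expect_equal(sum(pu3$columns$depth), 20L)
  # alignments past the end of a linear draft are rejected
  lin <- nuc_seq("l", draft$bases)
  expect_error(build_pileup(lin, exact_aln("w", 90L, wrap)),
               class = "cpkit_input_error")
})

test_that("call_edits applies plurality with depth and support thresholds", {
  draft <- nuc_seq("d", strrep("A", 20), circular = FALSE)
  mk_pileup <- function(a, g, del = 0L, pos = 9L) {
    cols <- tibble::tibble(position = 0:19, depth = 0L, A = 0L, C = 0L,
                           G = 0L, T = 0L, N = 0L, del = 0L)
    cols$A[pos + 1] <- a; cols$G[pos + 1] <- g; cols$del[pos + 1] <- del
    cols$depth <- cols$A + cols$C + cols$G + cols$T + cols$N + cols$del
    structure(list(columns = cols,
                   insertions = tibble::tibble(position = integer(),
                                               inserted = character(),
                                               count = integer()),
                   n = 20L, circular = FALSE), class = "pileup")
  }
  # 9 G vs draft A at full support: snp
  ed <- call_edits(mk_pileup(a = 0L, g = 9L), draft)
  expect_equal(ed$kind, "snp")
  expect_equal(ed$position, 9L)
  expect_equal(ed$alt_allele, "G")
  # draft allele still plurality: no edit
  expect_equal(nrow(call_edits(mk_pileup(a = 6L, g = 4L), draft)), 0L)
  # depth below min_depth: no edit regardless of the split
  expect_equal(nrow(call_edits(mk_pileup(a = 0L, g = 3L), draft)), 0L)
  # support exactly at the threshold is accepted (>=)
  ed <- call_edits(mk_pileup(a = 3L, g = 7L), draft)
  expect_equal(ed$kind, "snp")
  expect_equal(ed$support_fraction, 0.7)
  # deletion plurality becomes a del edit
  ed <- call_edits(mk_pileup(a = 2L, g = 0L, del = 8L), draft)
  expect_equal(ed$kind, "del")
  expect_equal(ed$ref_allele, "A")
})

test_that("apply_edits handles snp, ins, del and rejects overlaps", {
  draft <- nuc_seq("d", "ACGTACGTAC")
  snp <- tibble::tibble(position = 2L, kind = "snp", ref_allele = "G",
                        alt_allele = "T", support_fraction = 1, depth = 10L)
  expect_equal(apply_edits(draft, snp)$bases, "ACTTACGTAC")
  del <- tibble::tibble(position = 4L, kind = "del", ref_allele = "AC",
                        alt_allele = "", support_fraction = 1, depth = 10L)
  expect_equal(apply_edits(draft, del)$bases, "ACGTGTAC")
  ins <- tibble::tibble(position = 4L, kind = "ins", ref_allele = "",
                        alt_allele = "TT", support_fraction = 1, depth = 10L)
  expect_equal(apply_edits(draft, ins)$bases, "ACGTTTACGTAC")
  expect_equal(apply_edits(draft, snp[0, ])$bases, draft$bases)
  both <- rbind(snp, del, ins)
  expect_equal(apply_edits(draft, both)$bases, "ACTTTTGTAC")
  clash <- rbind(del, tibble::tibble(position = 5L, kind = "snp",
                                     ref_allele = "C", alt_allele = "A",
                                     support_fraction = 1, depth = 10L))
  expect_error(apply_edits(draft, clash), class = "cpkit_input_error")
})

test_that("polishing the truth genome with its own reads is a fixed point", {
  g <- simulate_genome(genome_spec(4000, 1200, 700), seed = 41)
  pairs <- simulate_short_pairs(g$seq, seed = 42)
  pol <- polish(g$seq, pairs$reads)
  expect_equal(nrow(pol$edits), 0L)
  expect_equal(pol$seq$bases, g$seq$bases)
})

test_that("polish recovers injected SNPs and small indels exactly", {
  g <- simulate_genome(genome_spec(4000, 1200, 700), seed = 43)
  pairs <- simulate_short_pairs(g$seq, seed = 44)
  draft <- make_corrupt_draft(g$seq, n_snp = 8L, n_indel = 3L, seed = 45)
  expect_false(identical(draft$bases, g$seq$bases))
  pol <- polish(draft, pairs$reads, rounds = 3)
  expect_equal(pol$seq$bases, g$seq$bases)
  # convergence: polishing again produces zero edits
  pol2 <- polish(pol$seq, pairs$reads)
  expect_equal(nrow(pol2$edits), 0L)
  # a 3-bp deletion in the draft comes back as one insertion edit
  b <- g$seq$bases
  draft3 <- nuc_seq("d3", paste0(substr(b, 1, 1000), substr(b, 1004, nchar(b))),
                    circular = TRUE)
  pol3 <- polish(draft3, pairs$reads)
  ins <- pol3$edits[pol3$edits$kind == "ins", ]
  expect_equal(nrow(ins), 1L)
  expect_equal(ins$alt_allele, substr(b, 1001, 1003))
  expect_equal(pol3$seq$bases, b)
  # zero aligned reads is an error
  junk <- tibble::tibble(id = "j", bases = random_seq(150, seed = 1),
                         quality = NA_character_, platform = "short",
                         mate = NA_integer_)
  expect_error(polish(draft, junk), class = "cpkit_stage_error")
})

test_that("tidy and glance summarize a polish result", {
  g <- simulate_genome(genome_spec(4000, 1200, 700), seed = 46)
  pairs <- simulate_short_pairs(g$seq, seed = 47)
  draft <- make_corrupt_draft(g$seq, n_snp = 4L, n_indel = 0L, seed = 48)
  pol <- polish(draft, pairs$reads)
  expect_s3_class(tidy(pol), "tbl_df")
  gl <- glance(pol)
  expect_equal(gl$n_edits, nrow(pol$edits))
  expect_equal(gl$length_bp, seq_length(pol$seq))
})
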