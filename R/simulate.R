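#' Specification of a synthetic quadripartite genome
#'
#' Defaults describe the toy genome used throughout the test suite — a
#' 35 kb plastome-shaped circle (LSC 20 kb, IRs 6 kb, SSC 3 kb), a
#' faithful scale-down of the real sweetpotato-type plastome geometry
#' (LSC ~87 kb, IRs ~31 kb, SSC ~12 kb).  Region GC targets default to
#' the values characteristic of plastomes, where the IRs are markedly
#' GC-richer than the single-copy regions.
#'
#' @param lsc_bp,ir_bp,ssc_bp Region lengths (LSC must exceed SSC).
#' @param gc_lsc,gc_ir,gc_ssc Target GC fractions in (0, 1).
#' @param ir_divergence_sites Substitution differences injected between
#'   the two IR copies (default 0: exact IRs).
#' @return A list of class `genome_spec`.
#' @export
genome_spec <- function(lsc_bp = 20000L, ir_bp = 6000L, ssc_bp = 3000L,
                        gc_lsc = 0.3614, gc_ir = 0.4057, gc_ssc = 0.3220,
                        ir_divergence_sites = 0L) {
  if (!(lsc_bp > ssc_bp && ssc_bp > 0L)) {
    abort("need lsc_bp > ssc_bp > 0", class = "cpkit_usage_error")
  }
  gc <- c(gc_lsc, gc_ir, gc_ssc)
  if (any(gc <= 0 | gc >= 1)) {
    abort("GC targets must be in (0, 1)", class = "cpkit_usage_error")
  }
  if (ir_divergence_sites < 0L || ir_divergence_sites > ir_bp) {
    abort("ir_divergence_sites must be in [0, ir_bp]", class = "cpkit_usage_error")
  }
  structure(list(lsc_bp = as.integer(lsc_bp), ir_bp = as.integer(ir_bp),
                 ssc_bp = as.integer(ssc_bp), gc_lsc = gc_lsc, gc_ir = gc_ir,
                 gc_ssc = gc_ssc,
                 ir_divergence_sites = as.integer(ir_divergence_sites)),
            class = "genome_spec")
}

# ensure the first base of a single-copy region is not the complement of
# its last base, so an inverted repeat flanked by this region cannot be
# extended across the region boundary by a chance match
break_ir_flank <- function(s) {
  first <- substr(s, 1L, 1L)
  last <- substr(s, nchar(s), nchar(s))
  if (identical(revcomp_chr(last), first)) {
    repl <- setdiff(c("A", "C", "G", "T"),
                    c(last, revcomp_chr(first)))[1L]
    substr(s, nchar(s), nchar(s)) <- repl
  }
  s
}

random_dna <- function(n, gc) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

substitute_base <- function(base) {
  alts <- setdiff(c("A", "C", "G", "T"), base)
  alts[sample.int(3L, length(base), replace = TRUE)[seq_along(base)]]
}

#' Simulate a quadripartite circular genome
#'
#' LSC, IRA and SSC are drawn i.i.d. per base at their target GC; IRB is
#' the reverse complement of IRA with `ir_divergence_sites` substitutions
#' at seeded random positions.  The genome is the circle LSC-IRA-SSC-IRB
#' (canonical order, LSC first) and the matching truth structure is
#' returned.  Byte-identical output per seed.
#'
#' @param spec A [genome_spec()].
#' @param seed Integer seed.
#' @return List with `seq` (circular [nuc_seq()]) and `structure`
#'   (truth [quadripartite_structure()]).
#' @export
simulate_genome <- function(spec = genome_spec(), seed = 1L) {
  stopifnot(inherits(spec, "genome_spec"))
  withr::with_seed(seed, {
    lsc <- random_dna(spec$lsc_bp, spec$gc_lsc)
    ira <- random_dna(spec$ir_bp, spec$gc_ir)
    ssc <- random_dna(spec$ssc_bp, spec$gc_ssc)
    # pin the single-copy bases flanking the IR boundaries so the repeats
    # are maximal exactly at the region boundaries: otherwise a chance
    # match would legitimately extend the maximal inverted repeat beyond
    # the generated intervals and the truth structure would be wrong
    lsc <- break_ir_flank(lsc)
    ssc <- break_ir_flank(ssc)
    irb <- revcomp_chr(ira)
    if (spec$ir_divergence_sites > 0L) {
      # keep divergence sites off the IR edges: an edge substitution would
      # shorten the maximal repeat and silently change the truth intervals
      margin <- if (spec$ir_bp >= 200L) 30L else 0L
      pool <- seq.int(1L + margin, spec$ir_bp - margin)
      pos <- sample(pool, spec$ir_divergence_sites)
      bc <- chars(irb)
      for (p in pos) bc[p] <- substitute_base(bc[p])
      irb <- paste(bc, collapse = "")
    }
    bases <- paste0(lsc, ira, ssc, irb)
    st <- structure_from_lengths(spec$lsc_bp, spec$ir_bp, spec$ssc_bp,
                                 spec$ir_bp,
                                 ir_mismatches = spec$ir_divergence_sites)
    list(seq = nuc_seq("sim_genome", bases, circular = TRUE), structure = st)
  })
}

#' Specification of simulated long reads
#'
#' Defaults emulate low-coverage nanopore-style WGS scaled to the toy
#' genome: ~30x coverage, mean read 3 kb, and indel-biased errors
#' (insertions plus deletions exceeding substitutions, as on that
#' platform).  Set the three rates to 0 for error-free reads.
#'
#' @param coverage Fold coverage of the source genome.
#' @param length_mean,length_sd Read length distribution (truncated normal,
#'   minimum 200 bp).
#' @param sub_rate,ins_rate,del_rate Per-base error rates in [0, 0.2].
#' @return A list of class `long_read_spec`.
#' @export
long_read_spec <- function(coverage = 30, length_mean = 3000, length_sd = 1000,
                           sub_rate = 0.03, ins_rate = 0.04, del_rate = 0.05) {
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(rates < 0 | rates > 0.2) || coverage <= 0) {
    abort("error rates must be in [0, 0.2] and coverage > 0",
          class = "cpkit_usage_error")
  }
  structure(list(coverage = coverage, length_mean = length_mean,
                 length_sd = length_sd, sub_rate = sub_rate,
                 ins_rate = ins_rate, del_rate = del_rate),
            class = "long_read_spec")
}

inject_errors <- function(s, sub_rate, ins_rate, del_rate) {
  if (sub_rate == 0 && ins_rate == 0 && del_rate == 0) return(s)
  b <- chars(s)
  n <- length(b)
  subs <- runif(n) < sub_rate
  if (any(subs)) {
    for (p in which(subs)) b[p] <- substitute_base(b[p])
  }
  dels <- runif(n) < del_rate
  inss <- runif(n) < ins_rate
  if (any(inss)) {
    extra <- sample(c("A", "C", "G", "T"), sum(inss), replace = TRUE)
    b[inss] <- paste0(b[inss], extra)
  }
  if (any(dels)) b <- b[!dels]
  paste(b, collapse = "")
}

#' Simulate long reads from a circular genome
#'
#' Start positions are uniform on the circle (reads may wrap the origin),
#' lengths follow a truncated normal, strands are random, and errors are
#' injected at the specified per-base rates.  Long reads carry no
#' qualities.  Deterministic per seed.
#'
#' @param genome Circular [nuc_seq()].
#' @param spec A [long_read_spec()].
#' @param seed Integer seed.
#' @return List with `reads` (tibble: `id`, `bases`, `quality` (`NA`),
#'   `platform`, `mate`) and `truth` (tibble: `id`, `start`, `length`,
#'   `strand`; `start` is the 0-based origin on the forward strand).
#' @export
simulate_long_reads <- function(genome, spec = long_read_spec(), seed = 1L) {
  stopifnot(inherits(genome, "nuc_seq"), inherits(spec, "long_read_spec"))
  n <- seq_length(genome)
  withr::with_seed(seed, {
    n_reads <- max(1L, ceiling(spec$coverage * n / spec$length_mean))
    lens <- pmin(n, pmax(200L, round(rnorm(n_reads, spec$length_mean,
                                           spec$length_sd))))
    starts <- sample.int(n, n_reads, replace = TRUE) - 1L
    strands <- sample(c("+", "-"), n_reads, replace = TRUE)
    g2 <- paste0(genome$bases, genome$bases)
    frag <- substring(g2, starts + 1L, starts + lens)
    neg <- strands == "-"
    if (any(neg)) frag[neg] <- revcomp_chr(frag[neg])
    if (spec$sub_rate > 0 || spec$ins_rate > 0 || spec$del_rate > 0) {
      frag <- map_chr(frag, inject_errors, sub_rate = spec$sub_rate,
                      ins_rate = spec$ins_rate, del_rate = spec$del_rate)
    }
    ids <- sprintf("lr_%05d", seq_len(n_reads))
    list(reads = tibble(id = ids, bases = frag, quality = NA_character_,
                        platform = "long", mate = NA_integer_),
         truth = tibble(id = ids, start = starts, length = lens,
                        strand = strands))
  })
}

#' Specification of simulated short read pairs
#'
#' Defaults emulate accurate paired-end sequencing scaled to the toy
#' genome: 30x coverage, 150 bp reads, 400 +/- 40 bp inserts, constant
#' Phred 40 qualities.  `quality_decay_bp` > 0 switches on a 3'-end
#' quality decay (linear drop to `decay_floor` over the last
#' `quality_decay_bp` bases) to exercise quality trimming.
#'
#' @param coverage Fold coverage.
#' @param read_bp Read length.
#' @param insert_mean,insert_sd Insert size distribution (truncated at
#'   `read_bp`).
#' @param sub_rate Per-base substitution error rate in [0, 0.2].
#' @param base_quality Constant Phred quality (default 40).
#' @param quality_decay_bp,decay_floor Optional 3' decay model.
#' @return A list of class `short_pair_spec`.
#' @export
short_pair_spec <- function(coverage = 30, read_bp = 150L, insert_mean = 400,
                            insert_sd = 40, sub_rate = 0,
                            base_quality = 40L, quality_decay_bp = 0L,
                            decay_floor = 10L) {
  if (sub_rate < 0 || sub_rate > 0.2 || coverage <= 0) {
    abort("sub_rate must be in [0, 0.2] and coverage > 0",
          class = "cpkit_usage_error")
  }
  structure(list(coverage = coverage, read_bp = as.integer(read_bp),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 sub_rate = sub_rate, base_quality = as.integer(base_quality),
                 quality_decay_bp = as.integer(quality_decay_bp),
                 decay_floor = as.integer(decay_floor)),
            class = "short_pair_spec")
}

#' Simulate paired short reads from a circular genome
#'
#' Fragments start uniformly on the circle with per-pair insert sizes;
#' mate 1 is the fragment prefix, mate 2 the reverse complement of the
#' fragment suffix, and the whole fragment is strand-flipped at random.
#' With error rate 0 both mates are exact substrings of the doubled
#' genome or its reverse complement.
#'
#' @param genome Circular [nuc_seq()].
#' @param spec A [short_pair_spec()].
#' @param seed Integer seed.
#' @return List with `reads` (tibble; two rows per pair, `mate` 1 and 2,
#'   shared `id`) and `truth` (tibble: `id`, `start`, `insert`, `strand`).
#' @export
simulate_short_pairs <- function(genome, spec = short_pair_spec(), seed = 1L) {
  stopifnot(inherits(genome, "nuc_seq"), inherits(spec, "short_pair_spec"))
  n <- seq_length(genome)
  withr::with_seed(seed, {
    n_pairs <- max(1L, ceiling(spec$coverage * n / (2L * spec$read_bp)))
    inserts <- pmin(n, pmax(spec$read_bp,
                            round(rnorm(n_pairs, spec$insert_mean,
                                        spec$insert_sd))))
    starts <- sample.int(n, n_pairs, replace = TRUE) - 1L
    strands <- sample(c("+", "-"), n_pairs, replace = TRUE)
    qual <- short_quality(spec)
    g2 <- paste0(genome$bases, genome$bases)
    frag <- substring(g2, starts + 1L, starts + inserts)
    neg <- strands == "-"
    if (any(neg)) frag[neg] <- revcomp_chr(frag[neg])
    r1 <- substring(frag, 1L, spec$read_bp)
    r2 <- revcomp_chr(substring(frag, nchar(frag) - spec$read_bp + 1L,
                                nchar(frag)))
    if (spec$sub_rate > 0) {
      r1 <- map_chr(r1, inject_errors, sub_rate = spec$sub_rate,
                    ins_rate = 0, del_rate = 0)
      r2 <- map_chr(r2, inject_errors, sub_rate = spec$sub_rate,
                    ins_rate = 0, del_rate = 0)
    }
    ids <- sprintf("sr_%06d", seq_len(n_pairs))
    reads <- tibble(
      id = rep(ids, each = 2L),
      bases = as.vector(rbind(r1, r2)),
      quality = qual,
      platform = "short",
      mate = rep(c(1L, 2L), n_pairs)
    )
    list(reads = reads,
         truth = tibble(id = ids, start = starts, insert = inserts,
                        strand = strands))
  })
}

short_quality <- function(spec) {
  q <- rep(spec$base_quality, spec$read_bp)
  if (spec$quality_decay_bp > 0L) {
    d <- min(spec$quality_decay_bp, spec$read_bp)
    tail_q <- round(seq(spec$base_quality, spec$decay_floor, length.out = d))
    q[(spec$read_bp - d + 1L):spec$read_bp] <- tail_q
  }
  int_to_qual(q)
}

#' Simulate draft contigs broken at the IR boundaries
#'
#' Emulates the long-read assembler output pattern for a quadripartite
#' genome: three linear contigs split at IR boundaries, each extending
#' `terminal_overlap_bp` past its junction into the next contig, so the
#' merged contig carries a terminal redundancy that circularization must
#' trim.  Contig 1 is the LSC (plus overlap into IRA), contig 2 the IRA
#' (plus overlap into SSC), contig 3 spans SSC and IRB and wraps into the
#' LSC start.
#'
#' @param genome Circular [nuc_seq()] in canonical order.
#' @param structure Truth [quadripartite_structure()].
#' @param terminal_overlap_bp Duplicated bases at each junction
#'   (default 2000; must be smaller than every region).
#' @return List with `contigs` (named [nuc_seq()] list) and `truth_layout`
#'   (tibble: `contig_id`, `start`, `length`).
#' @export
simulate_draft_contigs <- function(genome, structure,
                                   terminal_overlap_bp = 2000L) {
  stopifnot(inherits(genome, "nuc_seq"),
            inherits(structure, "quadripartite_structure"))
  ov <- as.integer(terminal_overlap_bp)
  if (ov >= min(structure$length)) {
    abort("terminal_overlap_bp must be smaller than every region",
          class = "cpkit_usage_error")
  }
  lsc <- region_interval(structure, "lsc")
  ira <- region_interval(structure, "ira")
  ssc <- region_interval(structure, "ssc")
  irb <- region_interval(structure, "irb")
  cuts <- tibble(
    contig_id = c("ctg1", "ctg2", "ctg3"),
    start = c(lsc[1L], ira[1L], ssc[1L]),
    length = c(lsc[2L] - lsc[1L] + ov, ira[2L] - ira[1L] + ov,
               irb[2L] - ssc[1L] + ov)
  )
  contigs <- map(seq_len(nrow(cuts)), function(i) {
    nuc_seq(cuts$contig_id[i],
            subseq_circular(genome$bases, cuts$start[i], cuts$length[i]))
  })
  list(contigs = setNames(contigs, cuts$contig_id), truth_layout = cuts)
}

#' Simulate repeat-collapsed contigs (short-read assembler pattern)
#'
#' Emulates a short-read assembly in which the two inverted repeats
#' collapse to a single copy: the genome with IRB deleted (LSC-IRA-SSC) is
#' fragmented at `n_breaks` seeded random positions, with neighbouring
#' fragments sharing `join_overlap_bp` of sequence (the fragment after a
#' break starts that many bases before it).  Breaks are kept at least
#' `spacing_bp` apart and `boundary_margin_bp` away from the IR
#' boundaries, so every fragment remains long enough to anchor.  With
#' `n_breaks = 0` a single IR-collapsed contig is emitted.  Contig order
#' and names are shuffled.  The scaffolder must restore both IR copies
#' from the single one present.
#'
#' @param genome Circular [nuc_seq()] in canonical order.
#' @param structure Truth [quadripartite_structure()].
#' @param n_breaks Random break count (default 12).
#' @param join_overlap_bp Terminal overlap at breaks (default 50).
#' @param spacing_bp Minimum distance between breaks (default 600).
#' @param boundary_margin_bp Minimum distance between a break and an IR
#'   boundary or sequence end (default 800).
#' @param seed Integer seed.
#' @return List with `contigs` (named, shuffled [nuc_seq()] list) and
#'   `truth_layout` (tibble: `contig_id`, `start`, `length` on the
#'   IR-collapsed sequence).
#' @export
simulate_collapsed_contigs <- function(genome, structure, n_breaks = 12L,
                                       join_overlap_bp = 50L,
                                       spacing_bp = 600L,
                                       boundary_margin_bp = 800L, seed = 1L) {
  stopifnot(inherits(genome, "nuc_seq"),
            inherits(structure, "quadripartite_structure"))
  lsc <- region_interval(structure, "lsc")
  ira <- region_interval(structure, "ira")
  ssc <- region_interval(structure, "ssc")
  stopifnot(lsc[1L] == 0L)  # canonical order required
  collapsed <- substr(genome$bases, 1L, ssc[2L])
  L <- nchar(collapsed)
  boundary <- c(0L, ira[1L], ira[2L], L)
  allowed <- setdiff(seq_len(L - 1L),
                     unlist(map(boundary, function(b) {
                       seq(max(1L, b - boundary_margin_bp),
                           min(L - 1L, b + boundary_margin_bp))
                     })))
  if (n_breaks > 0L && length(allowed) < n_breaks * 2L) {
    abort("n_breaks too large for this genome", class = "cpkit_usage_error")
  }
  withr::with_seed(seed, {
    rand <- integer()
    if (n_breaks > 0L) {
      ok <- FALSE
      for (tries in 1:2000) {
        rand <- sort(sample(allowed, n_breaks))
        if (n_breaks == 1L || min(diff(rand)) >= spacing_bp) { ok <- TRUE; break }
      }
      if (!ok) {
        abort("could not place spaced breaks; reduce n_breaks",
              class = "cpkit_usage_error")
      }
    }
    breaks <- c(0L, rand)
    starts <- pmax(0L, breaks - c(0L, rep(join_overlap_bp, length(rand))))
    ends <- c(breaks[-1L], L)
    cuts <- tibble(start = starts, length = ends - starts)
    ord <- sample.int(nrow(cuts))
    cuts <- cuts[ord, , drop = FALSE]
    cuts$contig_id <- sprintf("sctg_%02d", seq_len(nrow(cuts)))
    contigs <- map(seq_len(nrow(cuts)), function(i) {
      nuc_seq(cuts$contig_id[i],
              substr(collapsed, cuts$start[i] + 1L,
                     cuts$start[i] + cuts$length[i]))
    })
    list(contigs = setNames(contigs, cuts$contig_id),
         truth_layout = select(cuts, "contig_id", "start", "length"))
  })
}

#' Simulate a WGS mixture of chloroplast and background reads
#'
#' Emulates the enrichment phenomenon by which WGS data contains many
#' chloroplast copies: each read originates from the cp genome with
#' probability `cp_read_fraction`, otherwise from a seeded random
#' background genome with no cp homology.  Truth labels are returned
#' together with an idealized alignment table against the cp reference
#' (one exact full-length record per cp read, reference coordinates
#' possibly extending past the length where a read wraps the circular
#' origin; no records for background reads), for classifier testing.
#'
#' @param cp_genome Circular [nuc_seq()] chloroplast genome.
#' @param read_spec A [long_read_spec()] (length model; errors are not
#'   applied to the idealized alignment coordinates).
#' @param background_bp Background genome size (default 100000).
#' @param cp_read_fraction Probability a read is chloroplast-derived
#'   (must be in (0, 1)).
#' @param n_reads Number of reads (default: enough for
#'   `read_spec$coverage` on the cp genome given the fraction).
#' @param seed Integer seed.
#' @return List with `reads` (tibble), `truth` (tibble: `id`,
#'   `is_chloroplast`, `start`, `length`, `strand`) and `alignments`
#'   (idealized alignment tibble).
#' @export
simulate_wgs_mixture <- function(cp_genome, read_spec = long_read_spec(),
                                 background_bp = 100000L,
                                 cp_read_fraction = 0.3, n_reads = NULL,
                                 seed = 1L) {
  stopifnot(inherits(cp_genome, "nuc_seq"))
  if (cp_read_fraction <= 0 || cp_read_fraction >= 1) {
    abort("cp_read_fraction must be strictly inside (0, 1)",
          class = "cpkit_usage_error")
  }
  n <- seq_length(cp_genome)
  withr::with_seed(seed, {
    if (is.null(n_reads)) {
      n_reads <- max(1L, ceiling(read_spec$coverage * n /
                                   (read_spec$length_mean * cp_read_fraction)))
    }
    bg <- random_dna(background_bp, 0.42)
    is_cp <- runif(n_reads) < cp_read_fraction
    lens <- pmax(200L, round(rnorm(n_reads, read_spec$length_mean,
                                   read_spec$length_sd)))
    lens <- pmin(lens, ifelse(is_cp, n, background_bp))
    strands <- sample(c("+", "-"), n_reads, replace = TRUE)
    starts <- integer(n_reads)
    starts[is_cp] <- sample.int(n, sum(is_cp), replace = TRUE) - 1L
    starts[!is_cp] <- map_int(lens[!is_cp], function(l) {
      sample.int(background_bp - l + 1L, 1L) - 1L
    })
    cp2 <- paste0(cp_genome$bases, cp_genome$bases)
    bases <- character(n_reads)
    bases[is_cp] <- substring(cp2, starts[is_cp] + 1L, starts[is_cp] + lens[is_cp])
    bases[!is_cp] <- substring(bg, starts[!is_cp] + 1L,
                               starts[!is_cp] + lens[!is_cp])
    neg <- strands == "-"
    if (any(neg)) bases[neg] <- revcomp_chr(bases[neg])
    if (read_spec$sub_rate > 0 || read_spec$ins_rate > 0 ||
          read_spec$del_rate > 0) {
      bases <- map_chr(bases, inject_errors, sub_rate = read_spec$sub_rate,
                       ins_rate = read_spec$ins_rate,
                       del_rate = read_spec$del_rate)
    }
    ids <- sprintf("wgs_%05d", seq_len(n_reads))
    reads <- tibble(id = ids, bases = bases, quality = NA_character_,
                    platform = "long", mate = NA_integer_)
    cp_i <- which(is_cp)
    alignments <- tibble(
      query_id = ids[cp_i],
      query_length = nchar(bases[cp_i]),
      query_start = 0L,
      query_end = lens[cp_i],
      strand = strands[cp_i],
      ref_id = cp_genome$id,
      ref_length = n,
      ref_start = starts[cp_i],
      ref_end = starts[cp_i] + lens[cp_i],
      mapq = 60L
    ) %>%
      mutate(query_end = pmin(.data$query_end, .data$query_length),
             match_bp = .data$query_end - .data$query_start,
             ref_span = .data$ref_end - .data$ref_start) %>%
      select(dplyr::all_of(paf_core_cols))
    list(reads = reads,
         truth = tibble(id = ids, is_chloroplast = is_cp, start = starts,
                        length = lens, strand = strands),
         alignments = alignments)
  })
}
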