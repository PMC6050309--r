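test_that("motif canonicalization pools rotations and reverse complements", {
  # independent oracle: enumerate all rotations of unit and its RC, take min
  enum_canon <- function(u) {
    k <- nchar(u)
    d <- paste0(u, u)
    rots <- vapply(seq_len(k), function(i) substr(d, i, i + k - 1L), "")
    rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(u, "")[[1]]), collapse = ""))
    drc <- paste0(rc, rc)
    rots_rc <- vapply(seq_len(k), function(i) substr(drc, i, i + k - 1L), "")
    min(c(rots, rots_rc))
  }
  expect_equal(enum_canon("TAGAA"), "AATAG")  # frozen from the enumeration
  expect_equal(as.character(canonicalize_motif("TAGAA")), "AATAG")
  expect_equal(as.character(canonicalize_motif("GT")), "AC")
  red <- canonicalize_motif("ATAT")
  expect_true(attr(red, "reducible"))
  expect_equal(as.character(red), "AT")
  expect_error(canonicalize_motif("AXT"), "A,C,G,T")

  # idempotence and class-consistency over random units
  set.seed(3)
  for (i in seq_len(200)) {
    u <- random_dna_string(sample(2:6, 1L))
    cm <- as.character(canonicalize_motif(u))
    expect_equal(as.character(canonicalize_motif(cm)), cm)
    if (!attr(canonicalize_motif(u), "reducible")) {
      expect_equal(cm, enum_canon(u))
    } else {
      # reducible units canonicalize through their primitive root
      expect_lt(nchar(cm), nchar(u))
    }
    # every rotation and the RC map to the same class
    k <- nchar(u)
    rot <- substr(paste0(u, u), 2L, k + 1L)
    expect_equal(as.character(canonicalize_motif(rot)), cm)
  }
})

test_that("scanner applies the length thresholds", {
  g <- as_genome_assembly(c(a = "ACACACACACAC",        # 12 bp: kept
                            b = "ACACACACAC",          # 10 bp: below threshold
                            c = "AATAGAATAGAATAGAATAG", # 20 bp 5mer: kept
                            d = "AATAGAATAGAATAG",      # 15 bp 5mer: not > 15
                            e = "ACGATCACGATCACGATC"))  # 18 bp 6mer: kept
  loci <- scan_ssrs(g)
  expect_equal(sort(loci$contig), c("a", "c", "e"))
  a <- loci[loci$contig == "a", ]
  expect_equal(a$unit, "AC"); expect_equal(a$n_units, 6L)
  cc <- loci[loci$contig == "c", ]
  expect_equal(cc$unit, "AATAG"); expect_equal(cc$n_units, 4L)
})

test_that("N breaks arrays and homopolymers stay out of landscape totals", {
  g <- as_genome_assembly(c(x = "ACACACNACACACACACACAC", h = "AAAAAAAAAAAAAAA"))
  loci <- scan_ssrs(g)
  expect_equal(loci$contig, "x")
  expect_equal(loci$start, 7L)   # array restarts after the N
  expect_equal(loci$array_length, 14L)
  expect_false(any(loci$unit_length == 1L))
  withhomo <- scan_ssrs(g, report_homopolymers = TRUE)
  expect_true(any(withhomo$unit_length == 1L))
  ls <- summarize_landscape(withhomo, 1e6)
  expect_false("A" %in% ls$per_motif$canonical_motif)
})

test_that("scanner equals brute-force enumeration (exhaustive + random)", {
  cols <- c("start", "end", "unit", "unit_length", "n_units", "array_length")
  check_one <- function(s) {
    got <- scan_ssrs(as_genome_assembly(c(z = s)))
    expect_identical(got[, cols], oracle_scan_ssrs(s),
                     label = paste("scanner on", s))
  }
  # exhaustive over the binary alphabet up to length 14
  for (len in 12:14) for (s in all_strings(len)) check_one(s)
  # random longer binary strings reach the 5/6-mer thresholds
  set.seed(11)
  for (i in seq_len(3000)) check_one(random_dna_string(sample(15:24, 1L), c("A", "C")))
  # random 200-mers over the full alphabet (the acceptance suite runs 1000)
  for (i in seq_len(100)) check_one(random_dna_string(200))
})

test_that("landscape densities follow their definitions", {
  loci <- data.frame(contig = "c", start = seq(0, 900, by = 100)[1:10],
                     end = seq(0, 900, by = 100)[1:10] + 20L,
                     unit = "AC", canonical_motif = "AC", unit_length = 2L,
                     n_units = 10L, array_length = 20L)
  ls <- summarize_landscape(loci, 1e6)
  expect_equal(unname(ls$totals["loci_per_mbp"]), 10)
  expect_equal(unname(ls$totals["bp_per_mbp"]), 200)
  empty <- summarize_landscape(loci[0, ], 1e6)
  expect_equal(unname(empty$totals["bp_per_mbp"]), 0)
})

test_that("bp/Mbp totals are conserved across groupings", {
  set.seed(21)
  g <- as_genome_assembly(c(c1 = random_dna_string(30000)))
  loci <- scan_ssrs(g)
  ls <- summarize_landscape(loci, 30000)
  expect_equal(sum(ls$per_motif$bp_per_mbp), unname(ls$totals["bp_per_mbp"]))
  expect_equal(sum(ls$per_unit_length$bp_per_mbp), unname(ls$totals["bp_per_mbp"]))
  expect_equal(sum(ls$per_motif$loci_per_mbp), unname(ls$totals["loci_per_mbp"]))
})

test_that("densities are invariant to contig splitting at non-repeat positions", {
  set.seed(31)
  left <- random_dna_string(5000)
  right <- random_dna_string(5000)
  joined <- as_genome_assembly(c(j = paste0(left, "GATC", right)))
  split2 <- as_genome_assembly(c(l = paste0(left, "GATC"), r = right))
  ls1 <- summarize_landscape(scan_ssrs(joined), 10004)
  ls2 <- summarize_landscape(scan_ssrs(split2), 10004)
  expect_equal(ls1$totals, ls2$totals)
})

test_that("fold variation reproduces the published worked examples", {
  expect_equal(round(fold_variation(c(262, 2845)), 1), 10.9)
  expect_gte(fold_variation(c(4.08, 67.94)), 16.6)
  expect_equal(fold_variation(c(5, 5, 5)), 1.0)
  expect_error(fold_variation(c(-1, 5)), "positive")
  expect_error(fold_variation(3), "at least 2")
})

test_that("gc content excludes Ns from the denominator", {
  expect_equal(gc_content(c(x = "GCGC")), 1.0)
  expect_equal(gc_content(c(x = "ATGC")), 0.5)
  expect_equal(gc_content(c(x = "ATGCNN")), 0.5)
  expect_error(gc_content(c(x = "NNNN")), "non-N")
})

test_that("TE landscape merges overlapping annotations", {
  ann <- data.frame(contig = "c", start = c(100L, 100L), end = c(200L, 200L),
                    strand = "+", family = "CR1-L3", te_class = "LINE")
  ts <- te_landscape_summary(ann, 1000)
  expect_equal(ts$per_family$percent, 10)     # counted once, not twice
  expect_equal(ts$total_percent, 10)
  one <- te_landscape_summary(ann[1, ], 1000)
  expect_equal(one$per_class$percent[one$per_class$te_class == "LINE"], 10)
  bad <- ann; bad$end[1] <- 2000L
  expect_error(te_landscape_summary(bad, 1000, lengths = c(c = 1000L)), "past contig")
})

test_that("planted synthetic densities are recovered exactly", {
  fam <- te_family_config("CR1-L3", consensus_length = 400, copy_number = 10,
                          divergence = 0.03)
  cfg <- simulation_config(seed = 5, genome_length = 50000,
                           te_families = list(fam),
                           background_ssr = data.frame(motif = "AATAG",
                                                       n_units = 6, count = 12))
  sim <- simulate_genome(cfg)
  loci <- scan_ssrs(sim$genome)
  aatag <- loci[loci$canonical_motif == "AATAG", ]
  # every planted locus recovered at its exact interval
  truth <- sim$truth$ssr_loci
  expect_equal(nrow(aatag), nrow(truth))
  expect_setequal(aatag$start, truth$start)
  ls <- summarize_landscape(aatag, 50000)
  expect_equal(unname(ls$totals["bp_per_mbp"]), sum(truth$end - truth$start) / 0.05)
  # TE percent matches planted bp
  ts <- te_landscape_summary(truth_annotations(sim$truth, include_tails = FALSE),
                             50000)
  expect_equal(ts$per_family$bp[ts$per_family$family == "CR1-L3"],
               unname(sim$truth$per_family_bp[["CR1-L3"]]))
})

test_that("read subsampling is deterministic and respects the target", {
  set.seed(41)
  reads <- stats::setNames(vapply(1:400, function(i) random_dna_string(100), ""),
                           paste0("r", 1:400))
  s1 <- subsample_reads(reads, 0.01, seed = 9)
  s2 <- subsample_reads(reads, 0.01, seed = 9)
  expect_identical(s1, s2)
  expect_gte(sum(nchar(s1)), 1e4)
  expect_lt(sum(nchar(s1)) - 1e4, 100)   # first crossing of the target
  expect_identical(subsample_reads(reads, 0.04, seed = 1), reads)
  expect_error(subsample_reads(reads, 1, seed = 1), "exceeds")
})

test_that("TE percent is stable across nested subsamples", {
  fam <- te_family_config("CR1-L3", consensus_length = 500, copy_number = 30,
                          divergence = 0.02)
  sim <- simulate_genome(simulation_config(seed = 6, genome_length = 60000,
                                           te_families = list(fam)))
  reads <- simulate_reads(sim$genome, depth = 60, read_length = 100,
                          error_rate = 0.005, seed = 61)
  cons <- sim$truth$consensus[["CR1-L3"]]
  te_pct <- function(rd) {
    mp <- map_reads(rd, cons)
    100 * nrow(mp$alignments) / length(rd)
  }
  targets <- c(0.5, 1, 1.5, 2, 3)   # Mbp, scaled down from 3..250
  est <- vapply(targets, function(t) te_pct(subsample_reads(reads, t, seed = 7)), 0)
  expect_lt(max(est) - min(est), 2)   # percentage points
})
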