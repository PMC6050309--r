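toy_loci <- function(starts, ends, contig = "c1") {
  data.frame(contig = contig, start = starts, end = ends,
             unit = "AATAG", canonical_motif = "AATAG", unit_length = 5L,
             n_units = (ends - starts) %/% 5L, array_length = ends - starts)
}

test_that("flank extraction clips at contig bounds and drops empties", {
  lens <- c(c1 = 10000L)
  fl <- extract_flanks(toy_loci(500L, 520L), lens, width = 400)
  expect_equal(fl$regions$start, c(100L, 520L))
  expect_equal(fl$regions$end, c(500L, 920L))
  expect_equal(fl$regions$side, c("5p", "3p"))
  # locus at position 0: only the 3' region survives
  fl0 <- extract_flanks(toy_loci(0L, 30L), lens, width = 400)
  expect_equal(nrow(fl0$regions), 1L)
  expect_equal(fl0$regions$side, "3p")
  expect_error(extract_flanks(toy_loci(0L, 30L), lens, width = 0), "positive")
})

test_that("total flank bases equal the sum of clipped widths on a 20-locus fixture", {
  set.seed(13)
  lens <- c(c1 = 5000L, c2 = 3000L)
  starts <- c(sample(0:4950, 12L), sample(0:2950, 8L))
  loci <- toy_loci(starts, starts + 25L,
                   contig = rep(c("c1", "c2"), c(12L, 8L)))
  fl <- extract_flanks(loci, lens, width = 400)
  # hand count: per locus, clipped widths on each side
  hand <- sum(pmin(starts, 400)) +
    sum(pmin(lens[loci$contig] - (starts + 25L), 400))
  expect_equal(sum(fl$regions$end - fl$regions$start), as.integer(hand))
})

test_that("backgrounds match the flank length multiset and are seeded", {
  set.seed(17)
  g <- as_genome_assembly(c(c1 = random_dna_string(20000)))
  loci <- toy_loci(sample(500:19000, 10L), 0L)
  loci$end <- loci$start + 30L
  fl <- extract_flanks(loci, g, width = 400)
  bgs <- sample_background(g, fl, n_replicates = 5L, seed = 3)
  expect_length(bgs, 5L)
  for (bg in bgs) {
    expect_equal(sort(bg$end - bg$start),
                 sort(fl$regions$end - fl$regions$start))
    expect_true(all(bg$start >= 0L & bg$end <= 20000L))
  }
  expect_identical(sample_background(g, fl, 5L, seed = 3), bgs)
  expect_false(identical(sample_background(g, fl, 5L, seed = 4), bgs))
})

test_that("background regions avoid assembly gaps", {
  set.seed(19)
  gap <- strrep("N", 500)
  g <- as_genome_assembly(c(c1 = paste0(random_dna_string(2000), gap,
                                        random_dna_string(2000))))
  loci <- toy_loci(c(100L, 700L, 1500L), c(130L, 730L, 1530L))
  fl <- extract_flanks(loci, g, width = 200)
  bgs <- sample_background(g, fl, n_replicates = 20L, seed = 5)
  for (bg in bgs)
    expect_true(all(bg$end <= 2000L | bg$start >= 2500L))
})

test_that("background family content converges to the genome-wide fraction", {
  fam <- te_family_config("CR1-L3", consensus_length = 500, copy_number = 40,
                          divergence = 0.02)
  sim <- simulate_genome(simulation_config(seed = 23, genome_length = 100000,
                                           te_families = list(fam)))
  ann <- truth_annotations(sim$truth)
  loci <- toy_loci(as.integer(seq(1000L, 96000L, length.out = 20L)), 0L,
                   contig = "chr1")
  loci$end <- loci$start + 30L
  fl <- extract_flanks(loci, sim$genome, width = 400)
  bgs <- sample_background(sim$genome, fl, n_replicates = 100L, seed = 29)
  fracs <- vapply(bgs, function(bg) {
    rc <- region_te_content(bg, ann, families = "CR1-L3")
    rc$content
  }, 0)
  genome_frac <- sum(sim$truth$per_family_bp) / 100000
  se <- stats::sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - genome_frac), 2 * se + 0.005)
})

test_that("region TE content matches the naive intersection oracle", {
  ann <- data.frame(contig = "c1", start = c(0L, 50L, 500L),
                    end = c(100L, 80L, 600L), strand = "+",
                    family = c("CR1-L3", "Rex", "CR1-L3"), te_class = "LINE")
  # region fully covered by one annotation
  r1 <- data.frame(contig = "c1", start = 10L, end = 60L)
  rc <- region_te_content(r1, ann)
  expect_equal(rc$content[rc$family == "CR1-L3"], 1.0)
  expect_equal(rc$n_regions_hit[rc$family == "CR1-L3"], 1L)
  expect_equal(rc$content[rc$family == "Rex"], 10 / 50)
  # disjoint
  r2 <- data.frame(contig = "c1", start = 200L, end = 300L)
  expect_equal(region_te_content(r2, ann)$content, c(0, 0))
  # 20-region random fixture vs oracle
  set.seed(37)
  ann2 <- data.frame(contig = sample(c("c1", "c2"), 30L, TRUE),
                     start = sample(0:5000, 30L), strand = "+",
                     family = sample(c("CR1-L3", "Rex", "BovB"), 30L, TRUE),
                     te_class = "LINE")
  ann2$end <- ann2$start + sample(50:400, 30L, TRUE)
  regions <- data.frame(contig = sample(c("c1", "c2"), 20L, TRUE),
                        start = sample(0:5000, 20L))
  regions$end <- regions$start + 400L
  rc <- region_te_content(regions, ann2)
  for (fam in rc$family) {
    orc <- oracle_region_content(regions, ann2, fam)
    expect_equal(rc$bp[rc$family == fam], orc$bp)
    expect_equal(rc$n_regions_hit[rc$family == fam], orc$hits)
    expect_equal(rc$content[rc$family == fam], orc$content)
  }
})

test_that("one-tailed exact p equals direct hypergeometric summation", {
  cases <- expand.grid(a = c(0L, 1L, 5L, 10L), b = c(0L, 3L, 10L),
                       c_ = c(0L, 1L, 8L), d = c(1L, 20L, 50L))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    expect_equal(exact_enrichment_p(cs$a, cs$b, cs$c_, cs$d),
                 oracle_exact_tail(cs$a, cs$b, cs$c_, cs$d), tolerance = 1e-12)
  }
  # the spec's worked case: flank hits 10/10, background 1/50
  expect_equal(exact_enrichment_p(10, 0, 1, 49), oracle_exact_tail(10, 0, 1, 49),
               tolerance = 1e-12)
})

test_that("enrichment is flagged for the seeded family only", {
  fam_seed <- te_family_config("CR1-L3", consensus_length = 600, copy_number = 30,
                               divergence = 0.05,
                               ssr_tail = list(motif = "AATAG", n_units = 6))
  fam_null <- te_family_config("L2", consensus_length = 500, copy_number = 20,
                               divergence = 0.05)
  sim <- simulate_genome(simulation_config(seed = 42, genome_length = 150000,
                                           te_families = list(fam_seed, fam_null)))
  loci <- scan_ssrs(sim$genome)
  aatag <- loci[loci$canonical_motif == "AATAG", ]
  expect_equal(nrow(aatag), 30L)   # one tail per copy
  fl <- extract_flanks(aatag, sim$genome, width = 400, target_motif = "AATAG")
  bgs <- sample_background(sim$genome, fl, n_replicates = 5L, seed = 7)
  res <- enrichment_test(fl, bgs, truth_annotations(sim$truth), alpha = 0.01)
  expect_true(res$flagged[res$family == "CR1-L3"])
  expect_gt(res$ratio[res$family == "CR1-L3"], 1)
  expect_false(res$flagged[res$family == "L2"])
  # log-ratio sign consistency
  expect_true(all((res$ratio > 1) == (res$log2_ratio > 0), na.rm = TRUE))
})

test_that("flanks tested against themselves give ratio 1 and p near 1", {
  set.seed(51)
  ann <- data.frame(contig = "c1", start = sample(0:9000, 40L), strand = "+",
                    family = "CR1-L3", te_class = "LINE")
  ann$end <- ann$start + 100L
  fl <- structure(list(target_motif = "AATAG", flank_width = 400L,
                       regions = data.frame(contig = "c1",
                                            start = seq(0L, 9500L, by = 500L),
                                            end = seq(0L, 9500L, by = 500L) + 400L,
                                            side = "3p",
                                            source_locus = seq_len(20L))),
                  class = "flank_set")
  res <- enrichment_test(fl, list(fl$regions), ann, alpha = 0.01)
  expect_equal(res$ratio, 1)
  expect_gt(res$p_value, 0.4)   # identical tables: no enrichment signal
})

test_that("zero-content families get ratio 1 with a message", {
  fl <- structure(list(target_motif = "AATAG", flank_width = 400L,
                       regions = data.frame(contig = "c1", start = 0L, end = 400L,
                                            side = "3p", source_locus = 1L)),
                  class = "flank_set")
  ann <- data.frame(contig = "c1", start = 5000L, end = 5100L, strand = "+",
                    family = "CR1-L3", te_class = "LINE")
  bg <- list(data.frame(contig = "c1", start = 1000L, end = 1400L))
  expect_message(res <- enrichment_test(fl, bg, ann, families = c("CR1-L3", "Rex")),
                 "ratio set to 1")
  expect_equal(res$ratio[res$family == "Rex"], 1)
  expect_error(enrichment_test(fl, bg, ann, alpha = 2), "alpha")
})

test_that("co-occurrence probabilities match hand-computed fractions", {
  # 5-tile toy genome: tiles of 1000 on a 5000 bp contig
  lens <- c(c1 = 5000L)
  loci <- toy_loci(c(100L, 1200L, 3100L), c(130L, 1230L, 3130L))
  ann <- data.frame(contig = "c1",
                    start = c(300L, 3300L, 4200L), end = c(500L, 3500L, 4400L),
                    strand = "+", family = "CR1-L3", te_class = "LINE")
  co <- co_occurrence(loci, ann, lens, flank_width = 400L, tile_width = 1000L)
  # tiles: [0,1000) SSR+TE; [1000,2000) SSR only; [2000,3000) none;
  #        [3000,4000) SSR+TE; [4000,5000) TE only -> joint = 2/5
  expect_equal(co$joint_prob, 2 / 5)
  # loci at 100 and 3100 have a TE within 400 bp; locus at 1200 does not
  expect_equal(co$conditional_prob, 2 / 3)
  # family absent from genome
  co0 <- co_occurrence(loci, ann[0, ], lens, families = "BovB", tile_width = 1000L)
  expect_equal(co0$joint_prob, 0)
  expect_equal(co0$conditional_prob, 0)
  # saturation: every tile contains both, every locus flanked
  ann_all <- data.frame(contig = "c1", start = seq(0L, 4900L, 100L), strand = "+",
                        family = "CR1-L3", te_class = "LINE")
  ann_all$end <- ann_all$start + 50L
  loci_all <- toy_loci(seq(10L, 4910L, 700L), seq(10L, 4910L, 700L) + 30L)
  co1 <- co_occurrence(loci_all, ann_all, lens, flank_width = 400L,
                       tile_width = 1000L)
  expect_equal(co1$joint_prob, 1)
  expect_equal(co1$conditional_prob, 1)
})
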