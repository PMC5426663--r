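test_that("splice-proximity masking uses an inclusive 2 bp margin", {
  sites <- data.frame(chrom = "Gm01", pos = c(97, 98, 100, 102, 103),
                      stringsAsFactors = FALSE)
  junc <- data.frame(chrom = "Gm01", pos = 100)
  m <- mask_splice_proximal(sites, junc, margin = 2)
  expect_setequal(m$masked$pos, c(98, 100, 102))
  expect_setequal(m$kept$pos, c(97, 103))
  # empty junction list keeps everything
  m0 <- mask_splice_proximal(sites, junc[0, ])
  expect_equal(nrow(m0$kept), 5)
  # disjoint chromosomes: warning, no masking
  expect_warning(
    m1 <- mask_splice_proximal(sites, data.frame(chrom = "Gm09", pos = 100)),
    "no chromosome")
  expect_equal(nrow(m1$masked), 0)
})

test_that("BED junction intervals convert to flanking exonic boundaries", {
  bed <- data.frame(chrom = "Gm02", start = 99, end = 150)
  j <- junctions_from_bed(bed)
  expect_setequal(j$pos, c(99, 151))
})

test_that("parent-specific SNP calling enforces every textual criterion", {
  sheet <- toy_sample_sheet()
  clean <- lapply(sheet$sample, function(s) {
    g <- sheet$genotype[sheet$sample == s]
    if (g == "NMS4") c(0, 20) else if (g == "N7103") c(20, 0) else c(10, 10)
  })
  names(clean) <- sheet$sample
  # site 1: clean NMS4-specific
  s1 <- toy_site("Gm01", 100, "C", "T", clean)
  # site 2: alt reads in both parents (not unique)
  c2 <- clean; c2[["N7103_L1_1"]] <- c(0, 20)
  s2 <- toy_site("Gm01", 200, "A", "G", c2)
  # site 3: one origin replicate heterozygous ("all parental plots" fails)
  c3 <- clean; c3[["NMS4_L2_2"]] <- c(10, 10)
  s3 <- toy_site("Gm01", 300, "G", "A", c3)
  # site 4: depth failure in one parental replicate
  c4 <- clean; c4[["N7103_L1_2"]] <- c(3, 0)
  s4 <- toy_site("Gm01", 400, "T", "C", c4)
  # site 5: zero-depth parental replicate is a rejection, not an error
  c5 <- clean; c5[["NMS4_L1_1"]] <- c(0, 0)
  s5 <- toy_site("Gm01", 500, "C", "G", c5)
  # site 6: N7103-specific (origin on the other side)
  c6 <- lapply(sheet$sample, function(s) {
    g <- sheet$genotype[sheet$sample == s]
    if (g == "N7103") c(0, 20) else if (g == "NMS4") c(20, 0) else c(10, 10)
  }); names(c6) <- sheet$sample
  s6 <- toy_site("Gm02", 600, "C", "T", c6)
  sites <- rbind(s1, s2, s3, s4, s5, s6)
  got <- call_parent_specific_snps(sites, sheet, min_depth = 8)
  expect_setequal(got$pos, c(100, 600))
  expect_equal(got$origin[got$pos == 100], "NMS4")
  expect_equal(got$origin[got$pos == 600], "N7103")
})

test_that("filter chain equals the brute-force criteria on random toy tables", {
  sheet <- toy_sample_sheet()
  for (seed in 1:5) {
    set.seed(seed)
    n_sites <- sample(5:20, 1)
    sites <- do.call(rbind, lapply(seq_len(n_sites), function(i) {
      counts <- lapply(sheet$sample, function(s) {
        depth <- sample(0:30, 1)
        alt <- rbinom(1, depth, sample(c(0, 0.05, 0.5, 0.95, 1), 1))
        c(depth - alt, alt)
      })
      names(counts) <- sheet$sample
      toy_site("Gm01", i * 10, "C", "T", counts)
    }))
    got <- call_parent_specific_snps(sites, sheet, min_depth = 8)
    want <- oracle_parent_specific(sites, sheet, min_depth = 8)
    expect_setequal(paste(got$pos, got$origin),
                    paste(want$pos, want$origin))
  }
})

test_that("increasing min_depth never grows the parent-specific set", {
  at <- ase_truth(n_snps = 80, depth_mean = 15, seed = 6)
  sim <- simulate_allele_counts(at)
  ns <- vapply(c(2, 8, 15, 25), function(d)
    nrow(call_parent_specific_snps(sim$sites, sim$samples, d)), 0L)
  expect_true(all(diff(ns) <= 0))
  # wider margins never keep more sites
  kept <- vapply(c(0, 2, 10), function(m)
    nrow(mask_splice_proximal(sim$sites, sim$junctions, m)$kept), 0L)
  expect_true(all(diff(kept) <= 0))
})

test_that("F1 allele fractions pool read counts, not per-replicate fractions", {
  sheet <- toy_sample_sheet()
  counts <- list(F1_L1_1 = c(2, 8), F1_L1_2 = c(4, 6))
  sites <- toy_site("Gm01", 100, "C", "T", counts)
  snp <- data.frame(chrom = "Gm01", pos = 100, ref = "C", alt = "T",
                    origin = "NMS4", stringsAsFactors = FALSE)
  call <- f1_allele_fractions(snp, sites, sheet, "L1", min_depth = 8)
  expect_equal(sort(attr(call, "replicate_fractions")), c(0.6, 0.8))
  expect_equal(call$pooled_fraction, 14 / 20)
  expect_equal(call$total_depth, 20)
  # all origin reads: fraction 1; symmetric counts: 0.5
  c1 <- f1_allele_fractions(snp, toy_site("Gm01", 100, "C", "T",
                                          list(F1_L1_1 = c(0, 10))),
                            sheet, "L1")
  expect_equal(c1$pooled_fraction, 1)
  c2 <- f1_allele_fractions(snp, toy_site("Gm01", 100, "C", "T",
                                          list(F1_L1_1 = c(5, 5),
                                               F1_L1_2 = c(5, 5))),
                            sheet, "L1")
  expect_equal(c2$pooled_fraction, 0.5)
  # no replicate passing depth: unevaluable, not an error
  c3 <- f1_allele_fractions(snp, toy_site("Gm01", 100, "C", "T",
                                          list(F1_L1_1 = c(2, 3))),
                            sheet, "L1", min_depth = 8)
  expect_false(c3$evaluable)
})

test_that("bias threshold is strict and the consistency rule binds", {
  sheet <- toy_sample_sheet(n_reps = 4)
  snp <- data.frame(chrom = "Gm01", pos = 1, ref = "C", alt = "T",
                    origin = "NMS4", stringsAsFactors = FALSE)
  mk <- function(fracs, depth = 100) {
    counts <- lapply(seq_along(fracs), function(i)
      c(round(depth * (1 - fracs[i])), round(depth * fracs[i])))
    names(counts) <- paste0("F1_L1_", seq_along(fracs))
    classify_bias(f1_allele_fractions(
      snp, toy_site("Gm01", 1, "C", "T", counts), sheet, "L1"),
      threshold = 0.73, other_parent = "N7103")
  }
  # pooled exactly 0.73: never biased (strict >)
  expect_false(mk(c(0.73, 0.73, 0.73, 0.73))$biased)
  # just above, all replicates on the same side: biased toward origin
  b <- mk(c(0.70, 0.76, 0.75, 0.75))
  expect_true(b$biased)
  expect_equal(b$favored_allele, "NMS4")
  # pooled high but one replicate on the wrong side: not biased
  expect_false(mk(c(0.95, 0.92, 0.88, 0.40))$biased)
  # mirror-image bias favors the other parent
  lo <- mk(c(0.20, 0.25, 0.22, 0.24))
  expect_true(lo$biased)
  expect_equal(lo$favored_allele, "N7103")
})

test_that("ref/alt relabelling flips fractions but not the biased set", {
  at <- ase_truth(n_snps = 60, depth_mean = 60, seed = 14)
  sim <- simulate_allele_counts(at)
  snps <- call_parent_specific_snps(sim$sites, sim$samples)
  a <- bias_calls(snps, sim$sites, sim$samples, "Kinston")
  # swap ref<->alt everywhere: origin parent becomes the ref carrier
  sw <- sim$sites
  names(sw)[match(c("ref_count", "alt_count"), names(sw))] <-
    c("alt_count", "ref_count")
  names(sw)[match(c("ref", "alt"), names(sw))] <- c("alt", "ref")
  snps2 <- call_parent_specific_snps(sw, sim$samples)
  # the same physical sites pass, with the alt-carrying parent flipped
  expect_setequal(paste(snps2$chrom, snps2$pos), paste(snps$chrom, snps$pos))
  expect_true(all(snps2$origin[match(paste(snps$chrom, snps$pos),
                                     paste(snps2$chrom, snps2$pos))] !=
                    snps$origin))
  b <- bias_calls(snps2, sw, sim$samples, "Kinston")
  key <- paste(a$chrom, a$pos)
  b <- b[match(key, paste(b$chrom, b$pos)), ]
  # fractions flip, biased set and favored parent are invariant
  expect_equal(b$pooled_fraction, 1 - a$pooled_fraction, tolerance = 1e-12)
  expect_equal(b$biased, a$biased)
  expect_equal(b$favored_allele[b$biased %in% TRUE],
               a$favored_allele[a$biased %in% TRUE])
})

test_that("empirical threshold is 0.5 plus twice the fraction SD", {
  expect_equal(suppressWarnings(empirical_threshold(rep(0.5, 40))), 0.5)
  set.seed(2)
  f <- pmin(pmax(rnorm(100, 0.5, 0.115), 0), 1)
  expect_equal(empirical_threshold(f), 0.5 + 2 * sd(f))
  # the published 73% cut corresponds to a fraction SD of 0.115
  v <- rep(c(-1, 1), 50)
  f2 <- 0.5 + v * 0.115 / sd(v)
  expect_equal(empirical_threshold(f2), 0.73)
  expect_warning(empirical_threshold(rep(0.5, 10)), "fewer than 30")
})

test_that("cross-location fraction concordance and switching behave", {
  mk <- function(frac, biased, fav) data.frame(
    chrom = "Gm01", pos = seq_along(frac), origin = "NMS4", location = "X",
    n_reps = 4, pooled_fraction = frac, total_depth = 100,
    evaluable = TRUE, biased = biased, favored_allele = fav,
    stringsAsFactors = FALSE)
  f <- c(0.9, 0.85, 0.5, 0.55, 0.2)
  a <- mk(f, c(TRUE, TRUE, FALSE, FALSE, TRUE),
          c("NMS4", "NMS4", NA, NA, "N7103"))
  cc <- cross_location_bias_concordance(a, a)
  expect_equal(cc$r_squared_all, 1)
  expect_equal(cc$switched, 0)
  # hand-computed Pearson-squared on a 5-SNP fixture
  g <- c(0.88, 0.8, 0.52, 0.5, 0.25)
  b <- mk(g, c(TRUE, TRUE, FALSE, FALSE, TRUE),
          c("NMS4", "NMS4", NA, NA, "NMS4"))
  cc2 <- cross_location_bias_concordance(a, b)
  expect_equal(cc2$r_squared_all, cor(f, g)^2)
  expect_equal(cc2$switched, 1)  # SNP 5 flips favored parent
  # planted bias with independent noise never switches direction
  for (seed in c(17, 18, 19)) {
    at <- ase_truth(n_snps = 60, depth_mean = 100, bias_level = 0.9,
                    residual_het_rate = 0, seed = seed)
    sim <- simulate_allele_counts(at)
    snps <- call_parent_specific_snps(sim$sites, sim$samples)
    ca <- bias_calls(snps, sim$sites, sim$samples, "Kinston")
    cb <- bias_calls(snps, sim$sites, sim$samples, "Clayton")
    expect_equal(cross_location_bias_concordance(ca, cb)$switched, 0)
  }
})

test_that("gene-level summaries count SNPs and direction consistency", {
  calls <- data.frame(chrom = "Gm01", pos = 1:4, origin = "NMS4",
                      location = "L1", n_reps = 4,
                      pooled_fraction = c(0.9, 0.88, 0.1, 0.5),
                      total_depth = 100, evaluable = TRUE,
                      biased = c(TRUE, TRUE, TRUE, FALSE),
                      favored_allele = c("NMS4", "NMS4", "N7103", NA),
                      stringsAsFactors = FALSE)
  map <- data.frame(chrom = "Gm01", pos = 1:4,
                    gene = c("gA", "gA", "gB", "gB"), stringsAsFactors = FALSE)
  s <- summarize_gene_bias(calls, map)
  expect_equal(s$n_biased[s$gene == "gA"], 2)
  expect_true(s$consistent[s$gene == "gA"])
  expect_true(s$consistent[s$gene == "gB"])  # one biased direction only
  # opposite favored alleles in one gene: inconsistent
  map2 <- map; map2$gene <- "gX"
  s2 <- summarize_gene_bias(calls, map2)
  expect_false(s2$consistent)
  # truth round-trip of gene/SNP totals on a planted simulation
  at <- ase_truth(n_snps = 120, biased_fraction = 0.3, depth_mean = 80,
                  residual_het_rate = 0, seed = 19)
  sim <- simulate_allele_counts(at)
  snps <- call_parent_specific_snps(sim$sites, sim$samples)
  bc <- bias_calls(snps, sim$sites, sim$samples, "Kinston")
  sg <- summarize_gene_bias(bc, sim$snp_genes)
  expect_equal(sum(sg$n_biased), sum(sim$truth_labels$biased))
  expect_equal(sum(sg$n_biased > 0),
               length(unique(sim$truth_labels$gene[sim$truth_labels$biased])))
})

test_that("substitution-class test matches hypergeometric enumeration", {
  # methylation class membership
  b <- data.frame(ref = c("C", "G", "A"), alt = c("T", "A", "T"),
                  stringsAsFactors = FALSE)
  u <- data.frame(ref = "C", alt = "G", stringsAsFactors = FALSE)
  r <- substitution_class_test(b, u)
  expect_equal(unname(r$table["biased", "meth"]), 2)
  expect_equal(unname(r$table["unbiased", "meth"]), 0)
  # symmetric table: p = 1
  b2 <- data.frame(ref = rep(c("C", "A"), each = 5),
                   alt = rep(c("T", "C"), each = 5), stringsAsFactors = FALSE)
  r2 <- substitution_class_test(b2, b2)
  expect_equal(r2$p_value, 1)
  # [[8,2],[1,9]] fixture vs direct two-sided enumeration of tables
  mkdf <- function(meth, other) data.frame(
    ref = c(rep("C", meth), rep("A", other)),
    alt = c(rep("T", meth), rep("C", other)), stringsAsFactors = FALSE)
  r3 <- substitution_class_test(mkdf(8, 2), mkdf(1, 9))
  probs <- dhyper(0:9, 10, 10, 9)  # margin: 9 meth total, rows of 10
  expect_equal(r3$p_value, sum(probs[probs <= dhyper(8, 10, 10, 9) *
                                       (1 + 1e-7)]))
  # empty stratum: degenerate, p = 1
  r4 <- substitution_class_test(mkdf(0, 0), mkdf(1, 9))
  expect_true(r4$degenerate)
  expect_equal(r4$p_value, 1)
})

test_that("fraction histogram matches direct counting and sums to 100", {
  set.seed(9)
  calls <- data.frame(origin = rep(c("NMS4", "N7103"), each = 25),
                      pooled_fraction = runif(50), stringsAsFactors = FALSE)
  h <- bias_histogram(calls, n_bins = 20)
  for (org in c("NMS4", "N7103")) {
    sub <- h[h$origin == org, ]
    expect_equal(sum(sub$percent), 100)
    f <- calls$pooled_fraction[calls$origin == org]
    direct <- vapply(seq_len(20), function(i) {
      lo <- (i - 1) / 20; hi <- i / 20
      sum(f >= lo & (f < hi | (i == 20 & f <= hi)))
    }, 0L)
    expect_equal(sub$count, direct)
  }
  # degenerate: all fractions at 0.5 land in one bin
  h2 <- bias_histogram(data.frame(origin = "NMS4", pooled_fraction = 0.5),
                       n_bins = 20)
  expect_equal(sum(h2$percent > 0), 1)
  expect_equal(h2$percent[h2$bin_lo == 0.5], 100)
})
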