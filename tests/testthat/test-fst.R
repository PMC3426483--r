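test_that("wc_theta reproduces the published two-population genotype tables", {
  # balanced polymorphism, identical in both populations
  expect_equal(round(wc_theta(rbind(c(5, 10, 5), c(5, 10, 5))), 3), -0.026)
  # near-monomorphic locus with one heterozygote in one population
  expect_equal(round(wc_theta(rbind(c(20, 0, 0), c(19, 1, 0))), 3), 0.000)
  # fixed difference
  expect_equal(wc_theta(rbind(c(20, 0, 0), c(0, 0, 20))), 1)
})

test_that("wc_theta rejects degenerate input", {
  expect_error(wc_theta(rbind(c(20, 0, 0), c(20, 0, 0))), "monomorphic")
  expect_error(wc_theta(rbind(c(5, 10, 5), c(0, 0, 0))), "at least one")
  expect_error(wc_theta(matrix(1, 2, 2)), "2 x 3")
})

test_that("wc_theta matches an independent ANOVA-decomposition oracle", {
  set.seed(42)
  for (i in 1:1000) {
    tab <- random_genotype_table()
    expect_equal(wc_theta(tab), theta_anova_oracle(tab), tolerance = 1e-12)
  }
})

test_that("haplotype diversity equals the pair-enumeration probability", {
  # every biallelic pool of up to 12 genomes, exactly
  for (n in 2:12) {
    for (c1 in 1:(n - 1)) {
      expect_equal(radscan:::haplotype_diversity(c(c1, n - c1)),
                   diversity_pair_oracle(c(c1, n - c1)), tolerance = 1e-12)
    }
  }
})

test_that("haplotype_fst evaluates the diversity partition", {
  # fixed difference: H_S = 0
  expect_equal(haplotype_fst(rbind(c(30, 0), c(0, 30))), 1)
  # identical balanced pools: within-diversity exceeds pooled, raw negative
  raw <- haplotype_fst(rbind(c(10, 10), c(10, 10)))
  expect_equal(raw, 1 - (20 / 19) / (40 / 39), tolerance = 1e-12)
  expect_lt(raw, 0)
  expect_equal(clip_fst(raw), 0)
  # a pooled singleton is constrained to near-zero FST wherever it sits
  for (m in c(27, 30, 54)) {
    expect_lt(clip_fst(haplotype_fst(rbind(c(m - 1, 1), c(m, 0)))), 0.02)
    expect_lt(clip_fst(haplotype_fst(rbind(c(m, 0), c(m - 1, 1)))), 0.02)
  }
  expect_error(haplotype_fst(rbind(c(30, 0), c(30, 0))), "monomorphic")
  expect_error(haplotype_fst(rbind(c(1, 0), c(30, 0))), "two genomes")
})

test_that("both estimators are invariant to population and allele relabeling", {
  set.seed(7)
  for (i in 1:50) {
    tab <- random_genotype_table()
    expect_equal(wc_theta(tab), wc_theta(tab[2:1, ]), tolerance = 1e-12)
    expect_equal(wc_theta(tab), wc_theta(tab[, 3:1]), tolerance = 1e-12)
    cnt <- rbind(c(2 * tab[1, 1] + tab[1, 2],
                   2 * tab[1, 3] + tab[1, 2]),
                 c(2 * tab[2, 1] + tab[2, 2],
                   2 * tab[2, 3] + tab[2, 2]))
    expect_equal(haplotype_fst(cnt), haplotype_fst(cnt[2:1, ]),
                 tolerance = 1e-9)
    expect_equal(haplotype_fst(cnt), haplotype_fst(cnt[, 2:1]),
                 tolerance = 1e-9)
  }
})

test_that("theta and haplotype FST agree on large balanced diploid samples", {
  # cross-estimator sanity at moderate allele frequencies (difference 0.2,
  # both frequencies inside [0.3, 0.7], genotypes at Hardy-Weinberg
  # proportions); the two estimators diverge by construction near fixation
  set.seed(11)
  n <- 500
  for (i in 1:20) {
    p1 <- runif(1, 0.3, 0.5)
    p2 <- p1 + 0.2
    g1 <- round(n * c((1 - p1)^2, 2 * p1 * (1 - p1), p1^2))
    g2 <- round(n * c((1 - p2)^2, 2 * p2 * (1 - p2), p2^2))
    tab <- rbind(g1, g2)
    cnt <- rbind(c(2 * g1[1] + g1[2], 2 * g1[3] + g1[2]),
                 c(2 * g2[1] + g2[2], 2 * g2[3] + g2[2]))
    expect_lt(abs(wc_theta(tab) - haplotype_fst(cnt)), 0.05)
  }
})

test_that("scan_rad_site aggregates per-position clipped values", {
  mk <- function(pos, c1, c2, m = 54L) {
    cnt <- rbind(c(m - c1, c1), c(m - c2, c2))
    if (sum(cnt[, 2]) > sum(cnt[, 1])) cnt <- cnt[, 2:1]
    snp_site("chr1", pos, "siteX", c("T", "C"), cnt)
  }
  pool <- list(mk(10, 5, 25), mk(20, 3, 3), mk(30, 1, 0))
  raw <- sapply(pool, radscan:::site_fst, estimator = "haplotype")
  clipped <- clip_fst(raw)
  rec_max <- scan_rad_site(pool, "haplotype", "max")
  expect_equal(rec_max$fst, max(clipped))
  expect_equal(rec_max$position, 10)
  rec_mean <- scan_rad_site(pool, "haplotype", "mean")
  expect_equal(rec_mean$fst, mean(clipped))
  rec_rand <- scan_rad_site(pool, "haplotype", "random", seed = 3)
  expect_true(rec_rand$fst %in% clipped)
  # a single-SNP site gives the same record under every aggregation rule
  single <- list(mk(10, 5, 25))
  fsts <- sapply(c("max", "mean", "random"), function(a)
    scan_rad_site(single, "haplotype", a, seed = 1)$fst)
  expect_true(all(fsts == fsts[1]))
  # no variable positions -> no record
  expect_null(scan_rad_site(list(), "haplotype"))
})

test_that("per-position clipping precedes aggregation", {
  cnts <- list(c(1, 0), c(0, 1))   # two singleton placements, raw < 0 or tiny
  pool <- lapply(seq_along(cnts), function(i) {
    c1 <- cnts[[i]]
    snp_site("chr1", i, "siteY", c("T", "C"),
             rbind(c(27 - c1[1], c1[1]), c(27 - c1[2], c1[2])))
  })
  rec <- scan_rad_site(pool, "haplotype", "mean")
  expect_gte(rec$fst, 0)
})
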