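test_that("filter_bases masks exactly the bases above the error threshold", {
  cfg <- genotyping_config()
  st <- uniform_stack(c("T", "C", "G"), depth = 4, error_prob = 0.001)
  expect_identical(filter_bases(st, cfg)$bases, st$bases)
  st$error_probs[] <- 0.5
  expect_true(all(filter_bases(st, cfg)$bases == "N"))
  # strict inequality at the boundary: 0.009 kept, 0.011 masked
  st2 <- uniform_stack(c("T", "C"), depth = 4)
  st2$error_probs[, 1] <- c(0.009, 0.011, 0.009, 0.011)
  out <- filter_bases(st2, cfg)
  expect_identical(out$bases[, 1], c("T", "N", "T", "N"))
  expect_identical(out$bases[, 2], rep("C", 4))
  st2$error_probs[, 1] <- 0.01   # exactly at the threshold: kept
  expect_identical(filter_bases(st2, cfg)$bases[, 1], rep("T", 4))
})

test_that("the binomial heterozygote test follows the point-probability rule", {
  expect_identical(het_test(5, 10), "heterozygous")  # 252/1024
  expect_identical(het_test(1, 10), "homozygous")    # 10/1024 < 0.01
  expect_identical(het_test(2, 10), "heterozygous")  # 45/1024
  expect_identical(het_test(0, 10), "homozygous")
  expect_true(is.na(het_test(0, 0)))
  # symmetry in k and n - k
  for (n in 1:30) for (k in 0:n)
    expect_identical(het_test(k, n), het_test(n - k, n))
})

test_that("call_consensus applies the diploid depth rule", {
  cfg <- genotyping_config()
  # depth 10, one position split 5T/5C -> heterozygous diploid
  b <- matrix("A", 10, 3)
  b[, 2] <- rep(c("T", "C"), each = 5)
  st <- read_stack("s", "i", "pop1", b, matrix(0.001, 10, 3))
  g <- call_consensus(st, cfg)
  expect_equal(g$ploidy, 2L)
  expect_setequal(g$calls[, 2], c("T", "C"))
  expect_equal(g$calls[, 1], c("A", "A"))
  # depth 10, 9T/1C -> homozygous TT (point probability 10/1024 < 0.01)
  b[, 2] <- c(rep("T", 9), "C")
  g2 <- call_consensus(read_stack("s", "i", "pop1", b,
                                  matrix(0.001, 10, 3)), cfg)
  expect_equal(g2$calls[, 2], c("T", "T"))
  # depth 9 -> haploid majority call
  g3 <- call_consensus(uniform_stack(c("T", "G"), 9), cfg)
  expect_equal(g3$ploidy, 1L)
  expect_equal(g3$calls[1, ], c("T", "G"))
  # empty stack -> haploid, depth 0, all missing
  g4 <- call_consensus(read_stack("s", "i", "pop1",
                                  matrix(character(0), 0, 3),
                                  matrix(numeric(0), 0, 3)), cfg)
  expect_equal(g4$ploidy, 1L)
  expect_equal(g4$depth, 0L)
  expect_true(all(is.na(g4$calls)))
})

test_that("masked bases change depth and positions become missing", {
  cfg <- genotyping_config()
  b <- matrix("T", 12, 2)
  ep <- matrix(0.001, 12, 2)
  ep[1:3, ] <- 0.5            # three whole reads fail quality
  st <- filter_bases(read_stack("s", "i", "pop1", b, ep), cfg)
  g <- call_consensus(st, cfg)
  expect_equal(g$depth, 9L)   # below 10 -> haploid
  expect_equal(g$ploidy, 1L)
  ep2 <- matrix(0.001, 12, 2)
  ep2[, 2] <- 0.5             # one position entirely masked
  g2 <- call_consensus(filter_bases(read_stack("s", "i", "pop1", b, ep2),
                                    cfg), cfg)
  expect_equal(g2$ploidy, 2L)
  expect_true(all(is.na(g2$calls[, 2])))
  expect_equal(g2$calls[, 1], c("T", "T"))
})

test_that("more than two bases at a position: the top two enter the test", {
  cfg <- genotyping_config()
  b <- matrix(c(rep("T", 6), rep("C", 5), "G"), ncol = 1)
  st <- read_stack("s", "i", "pop1", b, matrix(0.001, 12, 1))
  g <- call_consensus(st, cfg)
  # het test on (5, 11): dbinom = 0.22 > 0.01 -> T/C; G ignored
  expect_setequal(g$calls[, 1], c("T", "C"))
})

test_that("raising max_base_error never removes bases from the test", {
  set.seed(5)
  for (i in 1:20) {
    d <- sample(5:15, 1)
    b <- matrix(sample(c("A", "C", "G", "T"), d * 4, replace = TRUE), d, 4)
    ep <- matrix(runif(d * 4, 0, 0.05), d, 4)
    st <- read_stack("s", "i", "pop1", b, ep)
    n_pass <- function(thr) {
      cfg <- genotyping_config(max_base_error = thr)
      sum(filter_bases(st, cfg)$bases != "N")
    }
    thr <- sort(runif(3, 0.001, 0.05))
    expect_true(n_pass(thr[1]) <= n_pass(thr[2]))
    expect_true(n_pass(thr[2]) <= n_pass(thr[3]))
  }
})

test_that("genotyping recovers simulated truth at high depth", {
  # ~1,000 site-individuals at depth 30, per-base error 0.001
  cfg <- sim_config(seed = 99, n_rad_sites = 19, n_individuals_per_pop = 27,
                    read_length = 10, mean_coverage_per_pop = c(30, 30),
                    coverage_dispersion = 50, base_error_rate = 0.001,
                    high_error_fraction = 0.02, drift_F = 0.1)
  sim <- simulate_populations(cfg)
  stacks <- simulate_read_stacks(sim)
  genos <- genotype_stacks(stacks)
  correct <- 0L; total <- 0L
  for (g in genos) {
    i <- match(g$individual_id, sim$individuals)
    s <- match(g$site_id, sim$sites$site_id)
    off <- sim$sites$offset[s]
    truth <- switch(as.character(sim$genotypes[s, i]),
      "0" = rep(sim$sites$ref[s], 2),
      "1" = c(sim$sites$ref[s], sim$sites$alt[s]),
      "2" = rep(sim$sites$alt[s], 2))
    call <- g$calls[, off]
    if (g$ploidy == 2L && !any(is.na(call))) {
      total <- total + 1L
      if (setequal(sort(call), sort(truth)) &&
          sum(call == truth[1]) == sum(truth == truth[1]))
        correct <- correct + 1L
    }
  }
  expect_gt(total, 900)
  expect_gt(correct / total, 0.99)
})

test_that("error-free stacks at depth >= 10 reproduce the true diploid genotype", {
  cfg <- sim_config(seed = 41, n_rad_sites = 10, n_individuals_per_pop = 10,
                    read_length = 8, mean_coverage_per_pop = c(40, 40),
                    coverage_dispersion = 100, base_error_rate = 0,
                    drift_F = 0)
  sim <- simulate_populations(cfg)
  stacks <- simulate_read_stacks(sim)
  genos <- genotype_stacks(stacks)
  for (idx in seq_along(stacks)) {
    st <- stacks[[idx]]; g <- genos[[idx]]
    if (g$ploidy != 2L) next
    i <- match(g$individual_id, sim$individuals)
    s <- match(g$site_id, sim$sites$site_id)
    off <- sim$sites$offset[s]
    truth <- sort(switch(as.character(sim$genotypes[s, i]),
      "0" = rep(sim$sites$ref[s], 2),
      "1" = c(sim$sites$ref[s], sim$sites$alt[s]),
      "2" = rep(sim$sites$alt[s], 2)))
    if (identical(truth[1], truth[2])) {
      # error-free homozygote: every read carries the true base
      expect_equal(sort(g$calls[, off]), truth)
    } else {
      # heterozygote recovered whenever the rarer haplotype's read count
      # keeps the binomial point probability above the threshold
      k <- min(sum(st$bases[, off] == sim$sites$alt[s]),
               sum(st$bases[, off] == sim$sites$ref[s]))
      n <- nrow(st$bases)
      if (stats::dbinom(k, n, 0.5) > 0.01)
        expect_equal(sort(g$calls[, off]), truth)
    }
  }
})
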