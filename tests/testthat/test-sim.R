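test_that("simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 5, n_rad_sites = 100, drift_F = 0.1,
                    singleton_fraction_target = 0.4)
  s1 <- simulate_populations(cfg)
  s2 <- simulate_populations(cfg)
  expect_identical(s1, s2)
  st1 <- simulate_read_stacks(s1, sites = s1$sites$site_id[1:3])
  st2 <- simulate_read_stacks(s2, sites = s2$sites$site_id[1:3])
  expect_identical(st1, st2)
  f1 <- tempfile(); f2 <- tempfile()
  write_stacks(st1, f1); write_stacks(st2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("no drift and no selection gives identical population frequencies", {
  cfg <- sim_config(seed = 3, n_rad_sites = 17000, drift_F = 0)
  sim <- simulate_populations(cfg)
  expect_equal(sim$sites$p1, sim$sites$p_anc)
  expect_equal(sim$sites$p2, sim$sites$p_anc)
  tab <- add_fst(sim_snp_table(sim), "haplotype")
  informative <- tab[tab$minor_allele_count >= 4, ]
  expect_gt(nrow(informative), 5000)
  expect_lt(mean(informative$fst), 0.01)
})

test_that("the singleton fraction calibrates to its target", {
  cfg <- sim_config(seed = 13, n_rad_sites = 20000, drift_F = 0.05,
                    singleton_fraction_target = 0.45)
  sim <- simulate_populations(cfg)
  expect_lt(abs(singleton_fraction(sim) - 0.45), 0.02)
})

test_that("singleton fraction is non-decreasing in the near-fixed weight", {
  fracs <- sapply(c(0, 0.25, 0.5, 0.75), function(w) {
    cfg <- sim_config(seed = 21, n_rad_sites = 8000, drift_F = 0.05,
                      near_fixed_weight = w)
    singleton_fraction(simulate_populations(cfg))
  })
  expect_true(all(diff(fracs) >= 0))
})

test_that("hitchhiking displacement decays with distance from the center", {
  # averaged over 100 replicate simulations, true differentiation |p1 - p2|
  # is largest near the selected center and decays outward
  reg <- list(list(center = 5e5, max_effect = 0.6, decay_per_bp = 2e-5))
  bins <- c(0, 5e4, 1.5e5, 5e5)
  acc <- matrix(0, 100, 3)
  for (r in 1:100) {
    cfg <- sim_config(seed = 7000 + r, n_rad_sites = 300, drift_F = 0.02,
                      selected_regions = reg, chromosome_length = 1e6)
    sim <- suppressWarnings(simulate_populations(cfg))
    d <- abs(sim$sites$position - 5e5)
    dif <- abs(sim$sites$p1 - sim$sites$p2)
    acc[r, ] <- tapply(dif, cut(d, bins), mean)
  }
  m <- colMeans(acc, na.rm = TRUE)
  expect_true(all(diff(m) < 0))
  # clamping is reported, and strict mode fails instead
  cfg_big <- sim_config(seed = 2, n_rad_sites = 500, drift_F = 0.05,
                        selected_regions = list(list(center = 5e5,
                                                     max_effect = 0.9,
                                                     decay_per_bp = 1e-5)))
  expect_warning(simulate_populations(cfg_big), "clamped")
  cfg_strict <- sim_config(seed = 2, n_rad_sites = 500, drift_F = 0.05,
                           strict = TRUE,
                           selected_regions = cfg_big$selected_regions)
  expect_error(simulate_populations(cfg_strict), "strict")
})

test_that("selected-region centers must lie on the chromosome", {
  expect_error(sim_config(selected_regions = list(
    list(center = 2e6, max_effect = 0.5, decay_per_bp = 1e-5)),
    chromosome_length = 1e6), "within the chromosome")
})

test_that("read stacks respect coverage, haplotypes and the error switch", {
  cfg <- sim_config(seed = 31, n_rad_sites = 20, n_individuals_per_pop = 25,
                    read_length = 6, mean_coverage_per_pop = c(30, 30),
                    coverage_dispersion = 8, base_error_rate = 0,
                    drift_F = 0.1)
  sim <- simulate_populations(cfg)
  stacks <- simulate_read_stacks(sim)
  depths <- vapply(stacks, function(s) nrow(s$bases), integer(1))
  # 1,000 site-individuals: empirical mean depth within 5% of the target
  expect_equal(length(depths), 1000L)
  expect_lt(abs(mean(depths) / 30 - 1), 0.05)
  # error-free: every read matches one of the two true haplotypes
  for (st in stacks[1:100]) {
    if (nrow(st$bases) == 0L) next
    s <- match(st$site_id, sim$sites$site_id)
    i <- match(st$individual_id, sim$individuals)
    off <- sim$sites$offset[s]
    allowed <- switch(as.character(sim$genotypes[s, i]),
                      "0" = sim$sites$ref[s],
                      "1" = c(sim$sites$ref[s], sim$sites$alt[s]),
                      "2" = sim$sites$alt[s])
    expect_true(all(st$bases[, off] %in% allowed))
    expect_true(all(st$error_probs == 0))
    # off-SNP columns are monomorphic within the stack
    expect_true(all(apply(st$bases[, -off, drop = FALSE], 2,
                          function(cl) length(unique(cl))) == 1L))
  }
})

test_that("a deep error-free heterozygote shows a balanced allele ratio", {
  st <- read_stack("s", "i", "pop1",
                   matrix(c("T", "C")[1 + (runif(1000) < 0.5)], ncol = 1),
                   matrix(0, 1000, 1))
  prop <- mean(st$bases[, 1] == "T")
  expect_lt(abs(prop - 0.5), 0.05)
})

test_that("hitchhiking scenarios order the marker signal as expected", {
  a <- hitchhiking_scenario("A")
  b <- hitchhiking_scenario("B")
  cc <- hitchhiking_scenario("C")
  # rare allele unlinked to the sweep: marker FST near zero at both times
  expect_lt(a$fst_t0, 0.05)
  expect_lt(a$fst_t1, 0.05)
  # balanced marker, identical counts before selection: clips to exactly 0
  expect_identical(cc$fst_t0, 0)
  # sweep visible when linked to the rare allele or a balanced marker
  expect_gt(b$fst_t1, a$fst_t1)
  expect_gt(cc$fst_t1, 0.05)
  expect_error(hitchhiking_scenario("D"))
})
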