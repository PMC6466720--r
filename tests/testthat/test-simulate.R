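test_that("configuration validation rejects degenerate designs", {
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.6, 0.7)), "maf_range")
  expect_s3_class(sim_config(maf_range = c(0.3, 0.3)), "sim_config")
  expect_error(sim_config(n_families = 1), "n_families")
  expect_error(sim_config(n_snps = 5), "n_snps")
  expect_error(sim_config(genetic_cov = matrix(-1, 5, 5)), "semi-definite")
  # a diet below baseline cannot trace new nutrients
  expect_error(sim_config(diet_atom = c(N15 = 0.2, C13 = 2.0)), "baseline")
  # isotopic equilibrium within the window is rejected
  expect_error(sim_config(turnover_mean = c(muscle = 0.8, liver = 0.9,
                                            adipose = 0.2)),
               "equilibrium")
})

test_that("genotype simulation is deterministic and family-structured", {
  sc <- tiny_config(seed = 21)
  g1 <- simulate_genotypes(sc)
  g2 <- simulate_genotypes(sc)
  expect_identical(g1$M, g2$M)
  g3 <- simulate_genotypes(sc, seed = 22)
  expect_false(identical(g1$M, g3$M))
  expect_true(all(g1$M %in% 0:2))
  expect_equal(nrow(g1$M), 4 * 2 * 10)
  expect_equal(length(unique(g1$family)), 4)
})

test_that("phenotype simulation is deterministic and conserves intake", {
  sc <- tiny_config(seed = 31)
  g <- simulate_genotypes(sc)
  s1 <- simulate_phenotypes(g, sc)
  s2 <- simulate_phenotypes(g, sc)
  expect_identical(s1$individuals, s2$individuals)
  expect_identical(s1$tanks, s2$tanks)
  # conservation: tank FI equals the sum of member true intakes
  by_tank <- tapply(s1$truth$intake,
                    factor(s1$individuals$tank, levels = s1$tanks$tank), sum)
  expect_equal(as.numeric(by_tank), s1$tanks$fi, tolerance = 1e-12)
  expect_equal(s1$tanks$fi, as.numeric(s1$truth$fi_true), tolerance = 1e-12)
})

test_that("atom percent stays within the physical band", {
  dat <- tiny_dataset(seed = 41)
  cfg <- dat$config
  for (col in c("amn", "amc", "aln", "alc", "aac")) {
    diet <- cfg$diet_atom[[if (col %in% c("amn", "aln")) "N15" else "C13"]]
    base <- cfg$baseline_atom[[col]]
    x <- dat$individuals[[col]]
    expect_true(all(x < diet), label = paste(col, "below diet"))
    expect_true(all(x > base - 3 * cfg$atom_noise_sd),
                label = paste(col, "above baseline band"))
  }
})

test_that("a no-growth no-turnover no-noise population sits at baseline", {
  sc <- sim_config(n_families = 2, n_fish_per_tank = 5, n_snps = 50,
                   wg_mean = 0,
                   turnover_mean = c(muscle = 0, liver = 0, adipose = 0),
                   genetic_cov = diag(c(0, 0, 0, 0, 1e-4)),
                   env_cov = diag(c(0, 0, 0, 0, 1e-4)),
                   tank_var = rep(0, 5), atom_noise_sd = 0, seed = 51)
  g <- simulate_genotypes(sc)
  s <- simulate_phenotypes(g, sc)
  for (col in c("amn", "amc", "aln", "alc", "aac"))
    expect_equal(s$individuals[[col]],
                 rep(sc$baseline_atom[[col]], nrow(s$individuals)),
                 tolerance = 1e-12)
  expect_equal(s$individuals$fw, s$individuals$iw, tolerance = 1e-12)
})

test_that("default architecture lands in the observed descriptive window", {
  dat <- tiny_dataset(seed = 61, n_fish_per_tank = 25)
  ind <- dat$individuals
  # muscle 15N population mean in the plausible mid-experiment window
  expect_gt(mean(ind$amn), 0.5)
  expect_lt(mean(ind$amn), 1.8)
  der <- suppressWarnings(derive_phenotypes(ind, dat$tanks))
  expect_gt(mean(der$tanks$fcr), 0.5)
  expect_lt(mean(der$tanks$fcr), 0.95)
  # growth filter removes only a small fraction under defaults
  expect_lt(sum(der$filter_counts) / nrow(ind), 0.08)
})

test_that("simulated phenotypes carry the configured heritability", {
  # regression of the observed trait on the true breeding value has unit
  # slope, and the BV share of variance matches the truth record
  reps <- 12
  slope <- share <- truth <- numeric(reps)
  for (r in seq_len(reps)) {
    sc <- h2_config(0.4, seed = 300 + r, n_families = 4,
                    n_fish_per_tank = 15, n_snps = 300)
    g <- simulate_genotypes(sc)
    s <- simulate_phenotypes(g, sc)
    wg <- s$individuals$fw - s$individuals$iw
    bv <- s$truth$bv[, "growth"]
    slope[r] <- coef(lm(wg ~ bv))[2]
    share[r] <- var(bv) / var(wg)
    truth[r] <- s$truth$h2_estimand[["growth"]]
  }
  expect_lt(abs(mean(slope) - 1), 3 * sd(slope) / sqrt(reps) + 0.02)
  expect_lt(abs(mean(share - truth)), 3 * sd(share - truth) / sqrt(reps) + 0.02)
})

test_that("tank trait pair generator honours the requested architecture", {
  K <- family_K(6, 2)  # 12 "tanks" in 6 family pairs
  T0 <- matrix(c(1, 0.9 * 2, 0.9 * 2, 4), 2, 2)
  set.seed(7)
  td <- simulate_tank_traits(K, T0, R = diag(c(0.1, 0.1)),
                             day = rep(1:4, 3), day_beta = c(2, 0))
  expect_equal(nrow(td), 12)
  expect_true(cor(td$y1, td$y2) > 0)  # strongly positively coupled
  expect_error(simulate_tank_traits(K, matrix(c(1, 2, 2, 1), 2, 2),
                                    diag(2)), "semi-definite")
})
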