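test_that("growth traits follow the endpoint definitions", {
  gt <- growth_traits(21.8, 32.6)
  expect_equal(gt$wg, 10.8)
  expect_equal(gt$rg, 100 * 10.8 / 32.6, tolerance = 1e-12)  # 33.13%
  expect_equal(growth_traits(10, 10), data.frame(wg = 0, rg = 0))
  # shrinkage is allowed (negative gain), left to the filter
  expect_lt(growth_traits(10, 8)$wg, 0)
  expect_error(growth_traits(-1, 5), "positive")
  expect_true(is.na(growth_traits(NA, 5)$wg))
})

test_that("growth filter flags strictly outside (6.4, 49) and is idempotent", {
  # rg supplied directly so the threshold comparison is exact
  rec <- data.frame(iw = c(20, 20, 20, 20, 20, NA),
                    fw = c(21, 26, 31, 21.4, 39.2, 30),
                    wg = c(1, 6, 11, 1.4, 19.2, NA),
                    rg = c(5.0, 30, 55, 6.4, 49, NA))
  out <- filter_growth_outliers(rec)
  expect_equal(out$missing_reason,
               c("low_growth", NA, "high_growth", NA, NA, "weight_missing"))
  # exactly at the thresholds is retained (strict inequalities)
  expect_true(is.na(out$missing_reason[4]))
  expect_true(is.na(out$missing_reason[5]))
  expect_identical(filter_growth_outliers(out)$missing_reason,
                   out$missing_reason)
})

test_that("tank FCR divides intake by summed non-missing gain", {
  expect_equal(tank_fcr(363, c(250, 276.1)), 363 / 526.1)  # ~0.690
  expect_equal(tank_fcr(0, c(1, 2)), 0)
  # invariant to member ordering
  wg <- c(3.2, NA, 5.1, 2.7)
  expect_equal(tank_fcr(10, wg), tank_fcr(10, rev(wg)))
  expect_error(tank_fcr(10, c(NA, NA)), "positive")
  expect_error(tank_fcr(10, c(-2, 1)), "positive")
})

test_that("indicator ratios are reciprocal and use the FW-weighted excess", {
  ir <- indicator_ratios(21.8, 32.6, 0.64)
  expect_equal(ir$ifcr, 32.6 * 0.64 / 10.8, tolerance = 1e-12)  # 1.9319
  expect_equal(ir$ifer, 10.8 / (32.6 * 0.64), tolerance = 1e-12)  # 0.5176
  # reciprocal identity over a spread of records
  set.seed(1)
  iw <- runif(50, 10, 30); fw <- iw + runif(50, 1, 15)
  ape <- runif(50, 0.05, 1.2)
  ir2 <- indicator_ratios(iw, fw, ape)
  expect_equal(ir2$ifcr * ir2$ifer, rep(1, 50), tolerance = 1e-12)
  # degenerate cases
  expect_true(is.na(indicator_ratios(10, 10, 0.5)$ifcr))
  z <- indicator_ratios(10, 15, 0)
  expect_equal(z$ifcr, 0)
  expect_true(is.na(z$ifer))
})

test_that("dry-matter intake applies leaching and dry-matter corrections", {
  expect_equal(dry_matter_intake(100, 10, 0, 0.9125), 82.125)
  expect_equal(dry_matter_intake(100, 0, 0, 1), 100)
  # leaching inflates the recovered waste before subtraction
  expect_equal(dry_matter_intake(100, 10, 0.5, 1), 80)
  expect_error(dry_matter_intake(100, 99, 0.5, 1), "exceeds")
})

test_that("tank means average non-missing members with counts", {
  d <- data.frame(tank = c("a", "a", "b", "b", "b"),
                  x = c(1, 2, 3, NA, 5))
  tm <- tank_means(d, "x")
  expect_equal(tm$mean, c(1.5, 4))
  expect_equal(tm$n, c(2L, 2L))
  d$x[1:2] <- NA
  expect_error(tank_means(d, "x"), "no non-missing")
})

test_that("derive_phenotypes assembles traits, filters and tank summaries", {
  dat <- tiny_dataset(seed = 5)
  der <- suppressWarnings(derive_phenotypes(dat$individuals, dat$tanks))
  ind <- der$individuals
  tk <- der$tanks
  expect_true(all(c("wg", "rg", "ape_amn", "ifcr_amn", "ifer_amn",
                    "missing_reason") %in% names(ind)))
  expect_true(all(c("fcr", "sum_wg", "rg_bar", "amn_bar") %in% names(tk)))
  # tank FCR consistent with the flag-aware sum of member gains
  t1 <- tk$tank[1]
  keep <- ind$tank == t1 & is.na(ind$missing_reason)
  expect_equal(tk$fcr[1], tk$fi[1] / sum(ind$wg[keep]))
  # flagged fish carry no indicator traits
  flagged <- !is.na(ind$missing_reason)
  if (any(flagged)) expect_true(all(is.na(ind$ifcr_amn[flagged])))
  # sensitivity switch: including flagged fish restores the full-tank sum
  der2 <- suppressWarnings(derive_phenotypes(dat$individuals, dat$tanks,
                                             include_filtered_in_fcr = TRUE))
  full_sum <- tapply(ind$wg, factor(ind$tank, levels = tk$tank),
                     function(x) sum(x, na.rm = TRUE))
  expect_equal(der2$tanks$sum_wg, as.numeric(full_sum), tolerance = 1e-12)
})

test_that("delta-valued input columns are converted before derivation", {
  dat <- tiny_dataset(seed = 6)
  std <- isotope_standards()
  ind_delta <- dat$individuals
  for (col in c("amn", "aln"))
    ind_delta[[col]] <- atom_percent_to_delta(ind_delta[[col]], std$r_n15)
  for (col in c("amc", "alc", "aac"))
    ind_delta[[col]] <- atom_percent_to_delta(ind_delta[[col]], std$r_c13)
  d1 <- suppressWarnings(derive_phenotypes(dat$individuals, dat$tanks))
  d2 <- suppressWarnings(derive_phenotypes(ind_delta, dat$tanks,
                                           delta_input = TRUE))
  expect_equal(d2$individuals$ape_amn, d1$individuals$ape_amn,
               tolerance = 1e-9)
  expect_equal(d2$tanks$fcr, d1$tanks$fcr)
})
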