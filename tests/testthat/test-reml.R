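test_that("REML matches a dense grid-search maximizer on a tiny instance", {
  set.seed(9)
  n <- 24
  K <- family_K(6, 4)
  L <- chol(K)
  a <- as.numeric(t(L) %*% rnorm(n)) * sqrt(1.5)
  d <- data.frame(id = rownames(K), day = rep(1:5, length.out = n),
                  y = 2 + 0.1 * rep(1:5, length.out = n) + a + rnorm(n))
  fit <- reml_fit(model_spec("y", level = "tank", id_col = "id"), d, K)
  va <- fit$components$genetic[1, 1]
  ve <- fit$components$residual[1, 1]
  h_grid <- grid_reml_h(d$y, cbind(1, d$day), K)
  expect_equal(va / (va + ve), h_grid, tolerance = 1e-3)
  expect_true(fit$converged)
})

test_that("with an identity K the fit matches the ANOVA intraclass estimate", {
  set.seed(42)
  m <- 12; k <- 6
  a <- rnorm(m, 0, sqrt(2))
  d <- data.frame(id = rep(sprintf("g%02d", 1:m), each = k),
                  day = rep(1:5, length.out = m * k),
                  y = rep(a, each = k) + rnorm(m * k, 0, sqrt(3)))
  K <- diag(m); rownames(K) <- colnames(K) <- sprintf("g%02d", 1:m)
  fit <- reml_fit(model_spec("y", level = "tank", id_col = "id"), d, K)
  av <- anova(lm(y ~ day + factor(id), d))
  msw <- av["Residuals", "Mean Sq"]
  va_anova <- (av["factor(id)", "Mean Sq"] - msw) / k
  expect_equal(fit$components$genetic[1, 1], va_anova, tolerance = 0.02)
  expect_equal(fit$components$residual[1, 1], msw, tolerance = 0.02)
})

test_that("zero genetic variance is recovered at the boundary with LR ~ 0", {
  # iid phenotypes against a strongly structured K (pure family blocks, so
  # the genetic variance is well identified): over replicates the genetic
  # component should sit at (numerically near) zero on average
  fam <- rep(1:16, each = 10)
  K <- 1 * outer(fam, fam, "==")
  rownames(K) <- colnames(K) <- sprintf("i%03d", seq_along(fam))
  spec1 <- model_spec("y", level = "tank", id_col = "id")
  spec0 <- model_spec("y", level = "tank", id_col = "id", genetic = FALSE)
  reps <- 6
  h2 <- lr <- numeric(reps)
  for (r in seq_len(reps)) {
    set.seed(500 + r)
    d <- data.frame(id = rownames(K), day = rep(1:5, 32), y = rnorm(160))
    h1 <- suppressWarnings(reml_fit(spec1, d, K,
                                    control = reml_control(n_starts = 1)))
    h0 <- reml_fit(spec0, d, NULL, control = reml_control(n_starts = 1))
    h2[r] <- ratio_estimates(h1)$h2
    lr[r] <- suppressWarnings(lr_test(h1, h0))$lr
  }
  expect_lt(mean(h2), 0.08)
  expect_lt(mean(lr), 2)
})

test_that("a singular fixed-effects design is rejected outright", {
  K <- family_K(4, 3)
  d <- data.frame(id = rownames(K), day = 2, y = rnorm(12))
  expect_error(reml_fit(model_spec("y", level = "tank", id_col = "id"),
                        d, K),
               "singular fixed-effects")
})

test_that("restricted likelihood is invariant to fixed-effect scaling", {
  set.seed(12)
  K <- family_K(5, 4)
  d <- data.frame(id = rownames(K), day = rep(1:5, 4),
                  y = rnorm(20, 10, 2))
  spec <- model_spec("y", level = "tank", id_col = "id")
  f1 <- reml_fit(spec, d, K)
  d2 <- transform(d, day = 2 * day + 5)  # full-rank affine reparameterization
  f2 <- reml_fit(spec, d2, K)
  # variance components are invariant; the restricted log-likelihood shifts
  # by the constant log|det J| of the design transform (here log 2),
  # independent of the variance parameters
  expect_equal(f1$logLik - f2$logLik, log(2), tolerance = 1e-6)
  expect_equal(f1$components$genetic[1, 1], f2$components$genetic[1, 1],
               tolerance = 1e-3)
  expect_equal(f1$components$residual[1, 1], f2$components$residual[1, 1],
               tolerance = 1e-3)
})

test_that("distinct starting values reach the same optimum", {
  set.seed(8)
  K <- family_K(6, 3)
  L <- chol(K)
  d <- data.frame(id = rownames(K), day = rep(1:3, 6),
                  y = as.numeric(t(L) %*% rnorm(18)) + rnorm(18, 0, 0.8))
  fit <- reml_fit(model_spec("y", level = "tank", id_col = "id"), d, K,
                  control = reml_control(n_starts = 3))
  expect_true(fit$start_agreement)
  expect_lt(fit$optim$spread, 1e-4)
})

test_that("bivariate tank fits estimate the genetic correlation", {
  set.seed(5)
  K <- family_K(10, 2)  # 20 tanks, paired by family
  T0 <- matrix(c(2, -0.7 * sqrt(2 * 3), -0.7 * sqrt(2 * 3), 3), 2, 2)
  td <- simulate_tank_traits(K, T0, R = diag(c(0.2, 0.3)),
                             day = rep(1:5, 4))
  fit <- reml_fit(model_spec(c("y1", "y2"), level = "tank",
                             id_col = "tank"), td, K)
  cr <- correlations(fit)
  expect_lt(cr$genetic, 0)        # sign recovered
  expect_true(abs(cr$genetic) <= 1)
  rat <- ratio_estimates(fit)
  expect_equal(nrow(rat), 2L)
  expect_true(all(rat$h2 >= 0 & rat$h2 <= 1))
})

test_that("a perfectly correlated pair is clamped and flagged at +/- 1", {
  set.seed(6)
  K <- family_K(8, 2)
  T0 <- matrix(c(2, sqrt(2 * 3), sqrt(2 * 3), 3), 2, 2)  # r_g = 1
  td <- simulate_tank_traits(K, T0, R = diag(c(0.01, 0.01)),
                             day = rep(1:4, 4))
  fit <- suppressWarnings(
    reml_fit(model_spec(c("y1", "y2"), level = "tank", id_col = "tank"),
             td, K))
  cr <- correlations(fit)
  expect_true(cr$boundary)
  expect_equal(abs(cr$genetic), 1)
})

test_that("likelihood-ratio test follows the chi-square reference", {
  f1 <- structure(list(logLik = -10, n = 30L, theta = 1:3,
                       spec = list(traits = "y")),
                  class = "bivariate_fit")
  f0 <- structure(list(logLik = -12, n = 30L, theta = 1:2,
                       spec = list(traits = "y")),
                  class = "bivariate_fit")
  out <- lr_test(f1, f0)
  expect_equal(out$lr, 4)
  expect_equal(out$p_value, pchisq(4, 1, lower.tail = FALSE),
               tolerance = 1e-12)  # ~0.0455
  # identical fits
  out0 <- lr_test(f1, structure(list(logLik = -10, n = 30L, theta = 1:2,
                                     spec = list(traits = "y")),
                                class = "bivariate_fit"))
  expect_equal(out0$lr, 0)
  expect_equal(out0$p_value, 1)
  # numerical noise is clamped with a warning
  fn <- structure(list(logLik = -10.000001, n = 30L, theta = 1:4,
                       spec = list(traits = "y")),
                  class = "bivariate_fit")
  expect_warning(outn <- lr_test(fn, f1), "clamped")
  expect_equal(outn$lr, 0)
  # non-nested fits are rejected
  expect_error(lr_test(f0, f1), "fewer parameters")
  expect_error(lr_test(f1, structure(list(logLik = -12, n = 29L,
                                          theta = 1:2,
                                          spec = list(traits = "y")),
                                     class = "bivariate_fit")),
               "different data")
})

test_that("variance-ratio arithmetic handles tabulated component forms", {
  # tank level: direct two-component ratio
  expect_equal(h2_from_components(50.99, 4.68, level = "tank")$h2,
               50.99 / 55.67, tolerance = 1e-12)
  # individual level with the tank fraction reported instead of its variance
  r <- h2_from_components(5.82, 6.44, c2 = 0.06)
  expect_equal(r$h2, 5.82 / ((5.82 + 6.44) / 0.94), tolerance = 1e-12)
  expect_equal(r$c2, 0.06, tolerance = 1e-12)
  expect_equal(h2_from_components(0, 3, c2 = 0)$h2, 0)
  expect_error(h2_from_components(0, 0, level = "tank"), "zero total")
})
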