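# Shared fixtures for the test suite: small simulated designs built in code.

tiny_config <- function(seed = 1, ...) {
  args <- utils::modifyList(list(n_families = 4, n_fish_per_tank = 10,
                                 n_snps = 300, seed = seed), list(...))
  do.call(sim_config, args)
}

tiny_dataset <- function(seed = 1, ...) {
  sc <- tiny_config(seed = seed, ...)
  geno <- simulate_genotypes(sc)
  sim <- simulate_phenotypes(geno, sc)
  list(config = sc, geno = geno, individuals = sim$individuals,
       tanks = sim$tanks, truth = sim$truth)
}

# architecture with a configured weight-gain heritability; additive growth
# model so the observed-trait variance decomposition is exact
h2_config <- function(h2, seed, total_var = 40, tank_v = 0.8,
                      n_families = 8, n_fish_per_tank = 25, n_snps = 1000) {
  va <- total_var * h2
  size_var <- (10.8 / 21.8)^2 * 64  # slope^2 * iw_sd^2 at the default scale
  ve <- total_var - va - tank_v - size_var
  stopifnot(ve > 0)
  sim_config(n_families = n_families, n_fish_per_tank = n_fish_per_tank,
             n_snps = n_snps, growth_model = "additive",
             genetic_cov = diag(c(va, 1e-4, 1e-4, 1e-4, 0.25)),
             env_cov = diag(c(ve, 1e-4, 1e-4, 1e-4, 0.25)),
             tank_var = c(tank_v, 0, 0, 0, 0.05), seed = seed)
}

# family-block relationship matrix (full sibs 0.5, self 1)
family_K <- function(n_fam, fam_size) {
  fam <- rep(seq_len(n_fam), each = fam_size)
  K <- 0.5 * outer(fam, fam, "==") + 0.5 * diag(length(fam))
  ids <- sprintf("i%03d", seq_along(fam))
  rownames(K) <- colnames(K) <- ids
  K
}

# dense grid-search maximizer of the restricted likelihood for the
# one-ratio model y = Xb + a + e, a ~ N(0, h * s * K), e ~ N(0, (1-h) * s I),
# with the overall scale s profiled out analytically. Independent of the
# package's optimizer path.
grid_reml_h <- function(y, X, K, grid = seq(0.001, 0.999, by = 5e-4)) {
  n <- length(y)
  prof <- function(h) {
    V0 <- h * K + (1 - h) * diag(n)
    L <- chol(V0)
    Viy <- backsolve(L, forwardsolve(t(L), y))
    ViX <- backsolve(L, forwardsolve(t(L), X))
    XtViX <- crossprod(X, ViX)
    beta <- solve(XtViX, crossprod(X, Viy))
    quad <- sum(y * Viy) - sum(crossprod(X, Viy) * beta)
    np <- n - ncol(X)
    s <- quad / np
    -0.5 * (2 * sum(log(diag(L))) + np * log(s) +
              as.numeric(determinant(XtViX)$modulus) + np)
  }
  ll <- vapply(grid, prof, numeric(1))
  grid[which.max(ll)]
}

# explicit leave-one-out PRESS by refitting n times (oracle for the
# leverage identity)
press_by_refit <- function(formula, data) {
  n <- nrow(data)
  resp <- all.vars(formula)[1]
  loo <- vapply(seq_len(n), function(i) {
    f <- stats::lm(formula, data = data[-i, , drop = FALSE])
    data[[resp]][i] - unname(stats::predict(f, newdata = data[i, , drop = FALSE]))
  }, numeric(1))
  list(press = sum(loo^2), bias = mean(loo))
}
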