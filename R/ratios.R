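#' Heritability and variance ratios from raw components
#'
#' Scalar helper implementing the ratio definitions used throughout:
#' at the tank level `h_t^2 = sigma_a^2 / (sigma_a^2 + sigma_e^2)` (the
#' fraction of between-tank variance explained by genetics); at the
#' individual level `h^2 = sigma_a^2 / (sigma_a^2 + sigma_t^2 + sigma_e^2)`
#' and `c^2 = sigma_t^2 / (sigma_a^2 + sigma_t^2 + sigma_e^2)`. When only
#' `c2` is reported alongside the genetic and residual components (the usual
#' tabulated form), the tank variance is recovered from
#' `total = (sigma_a^2 + sigma_e^2) / (1 - c^2)`.
#'
#' @param sigma_a2 additive-genetic variance.
#' @param sigma_e2 residual variance.
#' @param sigma_t2 tank environmental variance (individual level); may be
#'   NULL if `c2` is supplied instead.
#' @param c2 fraction of phenotypic variance due to tank, used to recover
#'   `sigma_t2` when that component is not reported.
#' @param level `"individual"` or `"tank"`.
#' @return named list with `h2` (and `c2` at the individual level).
#' @export
h2_from_components <- function(sigma_a2, sigma_e2, sigma_t2 = NULL,
                               c2 = NULL, level = c("individual", "tank")) {
  level <- match.arg(level)
  stopifnot(sigma_a2 >= 0, sigma_e2 >= 0)
  if (level == "tank") {
    total <- sigma_a2 + sigma_e2
    if (total <= 0) stop("zero total variance")
    return(list(h2 = sigma_a2 / total))
  }
  if (is.null(sigma_t2)) {
    if (is.null(c2)) c2 <- 0
    stopifnot(c2 >= 0, c2 < 1)
    total <- (sigma_a2 + sigma_e2) / (1 - c2)
    sigma_t2 <- total - sigma_a2 - sigma_e2
  }
  total <- sigma_a2 + sigma_t2 + sigma_e2
  if (total <= 0) stop("zero total variance")
  list(h2 = sigma_a2 / total, c2 = sigma_t2 / total)
}

#' Variance ratios from a REML fit
#'
#' Derives per-trait heritabilities (and the tank variance fraction `c^2` at
#' the individual level, or `h_t^2` at the tank level) from a
#' [reml_fit()] result, with delta-method standard errors when component
#' standard errors are available.
#'
#' @param fit a `bivariate_fit`.
#' @return data.frame with one row per trait: `trait`, `h2`, `c2` (NA at
#'   tank level), `se_h2` when computable.
#' @export
ratio_estimates <- function(fit) {
  stopifnot(inherits(fit, "bivariate_fit"))
  if (!fit$converged)
    warning("ratios derived from a fit flagged as non-converged")
  q <- length(fit$spec$traits)
  cm <- fit$components
  if (is.null(cm$genetic)) stop("fit has no genetic component")
  out <- lapply(seq_len(q), function(j) {
    va <- cm$genetic[j, j]
    vt <- if (!is.null(cm$tank)) cm$tank[j, j] else NULL
    ve <- cm$residual[j, j]
    if (fit$spec$level == "tank") {
      r <- h2_from_components(va, ve, level = "tank")
      data.frame(trait = fit$spec$traits[j], h2 = r$h2, c2 = NA_real_)
    } else {
      r <- h2_from_components(va, ve, sigma_t2 = vt %||% 0)
      data.frame(trait = fit$spec$traits[j], h2 = r$h2, c2 = r$c2)
    }
  })
  out <- do.call(rbind, out)
  out$se_h2 <- ratio_se(fit)
  out
}

# delta-method SE of h2 per trait from the component covariance implied by
# per-component SEs (treats components as independent, a first-order
# approximation; NA when SEs are unavailable)
ratio_se <- function(fit) {
  if (is.null(fit$se)) return(rep(NA_real_, length(fit$spec$traits)))
  vapply(seq_along(fit$spec$traits), function(j) {
    va <- fit$components$genetic[j, j]
    ve <- fit$components$residual[j, j]
    vt <- if (!is.null(fit$components$tank)) fit$components$tank[j, j] else 0
    tot <- va + vt + ve
    g <- c((tot - va) / tot^2, -va / tot^2, -va / tot^2)
    s <- c(fit$se$genetic[j, j], fit$se$residual[j, j],
           if (!is.null(fit$se$tank)) fit$se$tank[j, j] else 0)
    sqrt(sum((g * s)^2))
  }, numeric(1))
}

#' Genetic and phenotypic correlations from a bivariate fit
#'
#' Genetic correlation `r_g = cov_a / (sigma_a1 sigma_a2)`; phenotypic
#' correlation from the summed (co)variance matrices across the included
#' random terms. Correlations estimated at the boundary of the parameter
#' space are reported as +/- 1 with `boundary = TRUE`.
#'
#' @param fit a converged bivariate `bivariate_fit`.
#' @return list with `genetic`, `phenotypic`, `boundary` (logical, genetic
#'   correlation clamped).
#' @export
correlations <- function(fit) {
  stopifnot(inherits(fit, "bivariate_fit"))
  if (length(fit$spec$traits) != 2L)
    stop("correlations require a bivariate fit")
  cm <- fit$components
  if (is.null(cm$genetic)) stop("fit has no genetic component")
  va <- diag(cm$genetic)
  if (any(va <= 0)) stop("zero genetic variance in one of the traits")
  rg <- cm$genetic[1, 2] / sqrt(va[1] * va[2])
  boundary <- isTRUE(fit$boundary$genetic)
  if (boundary) rg <- sign(rg)
  P <- cm$genetic
  if (!is.null(cm$tank)) P <- P + cm$tank
  P <- P + cm$residual
  rp <- P[1, 2] / sqrt(P[1, 1] * P[2, 2])
  list(genetic = rg, phenotypic = rp, boundary = boundary)
}

#' Likelihood-ratio test for a variance component
#'
#' `LR = 2 (logL_H1 - logL_H0)` comparing a model with the additive-genetic
#' term (H1) to the nested model without it (H0), referred to a chi-squared
#' distribution with `df` degrees of freedom. Negative LR from numerical
#' noise is clamped at zero with a warning. Significance requires LR to
#' exceed the critical value (i.e. small p).
#'
#' @param fit_h1,fit_h0 fits on the same data; `fit_h0` must be the nested
#'   model (no genetic term, or otherwise fewer parameters).
#' @param df test degrees of freedom (default 1, one variance component).
#' @return list with `lr`, `df`, `p_value`.
#' @export
lr_test <- function(fit_h1, fit_h0, df = 1) {
  stopifnot(inherits(fit_h1, "bivariate_fit"), inherits(fit_h0, "bivariate_fit"))
  if (fit_h1$n != fit_h0$n)
    stop("fits are on different data (record counts differ); not nested")
  if (length(fit_h1$theta) <= length(fit_h0$theta))
    stop("H0 must have fewer parameters than H1 (nested models)")
  if (!identical(fit_h1$spec$traits, fit_h0$spec$traits))
    stop("fits are for different traits; not nested")
  lr <- 2 * (fit_h1$logLik - fit_h0$logLik)
  if (lr < 0) {
    warning(sprintf("LR = %.3g < 0 (numerical noise); clamped to 0", lr))
    lr <- 0
  }
  list(lr = lr, df = df,
       p_value = stats::pchisq(lr, df = df, lower.tail = FALSE))
}
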