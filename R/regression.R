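#' Tank-level regression of FCR on sampling day and covariates
#'
#' Ordinary least squares of tank feed conversion ratio on sampling day
#' (always included, as a linear covariate) plus any tank-mean covariates,
#' with leave-one-out prediction diagnostics (PRESS, predictive R-hat^2,
#' bias) computed by the leverage identity.
#'
#' @param tanks tank-level data.frame.
#' @param covariates character vector of covariate column names (may be
#'   empty for the day-only model).
#' @param response response column (default `"fcr"`).
#' @param day_col sampling-day column (default `"day"`).
#' @return object of class `tank_regression`: list with `fit` (the `lm`),
#'   `covariates`, `r2`, `adj_r2`, `press`, `r2_pred`, `bias` (mean
#'   observed minus leave-one-out prediction), `bias_insample`,
#'   `loo_pred`, `coef_table`.
#' @export
fit_tank_model <- function(tanks, covariates = character(),
                           response = "fcr", day_col = "day") {
  stopifnot(is.data.frame(tanks))
  cols <- c(response, day_col, covariates)
  miss <- setdiff(cols, names(tanks))
  if (length(miss))
    stop("tank table is missing column(s): ", paste(miss, collapse = ", "))
  d <- tanks[stats::complete.cases(tanks[, cols, drop = FALSE]), cols,
             drop = FALSE]
  n <- nrow(d)
  p <- length(cols) + 1L  # intercept + day + covariates
  if (n <= p)
    stop(sprintf("need more tanks (%d) than parameters (%d)", n, p - 1L))
  rhs <- paste(c(day_col, sprintf("`%s`", covariates)), collapse = " + ")
  fml <- stats::as.formula(sprintf("`%s` ~ %s", response, rhs))
  fit <- stats::lm(fml, data = d)
  if (fit$rank < length(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  loo <- loo_press(fit)
  cf <- summary(fit)$coefficients
  structure(list(fit = fit, covariates = covariates, response = response,
                 n = n, r2 = summary(fit)$r.squared,
                 adj_r2 = summary(fit)$adj.r.squared,
                 press = loo$press, r2_pred = loo$r2_pred, bias = loo$bias,
                 bias_insample = mean(stats::residuals(fit)),
                 loo_pred = loo$loo_pred,
                 coef_table = cf),
            class = "tank_regression")
}

#' Leave-one-out PRESS, predictive R-squared and bias
#'
#' For an OLS fit, the leave-one-out residual is `e_i / (1 - h_ii)` (the
#' leverage identity), so `PRESS = sum((e_i / (1 - h_ii))^2)`,
#' `R-hat^2 = 1 - PRESS / SS_tot` with `SS_tot` the total sum of squares of
#' the response about its mean, and the bias is the average difference
#' between observed values and their leave-one-out predictions.
#'
#' @param fit an `lm` object (or a `tank_regression`, whose inner fit is
#'   used).
#' @return list with `press`, `r2_pred`, `bias`, `loo_pred`, `loo_resid`.
#' @export
loo_press <- function(fit) {
  if (inherits(fit, "tank_regression")) fit <- fit$fit
  stopifnot(inherits(fit, "lm"))
  n <- length(stats::residuals(fit))
  p <- fit$rank
  if (n < p + 2L)
    stop("too few observations for leave-one-out prediction")
  h <- stats::hatvalues(fit)
  if (any(h >= 1 - 1e-12))
    stop("a leave-one-out subset is rank-deficient (leverage 1)")
  e <- stats::residuals(fit)
  loo_resid <- e / (1 - h)
  y <- e + stats::fitted(fit)
  press <- sum(loo_resid^2)
  ss_tot <- sum((y - mean(y))^2)
  list(press = press, r2_pred = 1 - press / ss_tot,
       bias = mean(loo_resid), loo_pred = y - loo_resid,
       loo_resid = loo_resid)
}

#' Backward elimination by PRESS minimization
#'
#' Starting from the model with all candidate covariates (plus sampling
#' day, which is never eliminated), repeatedly removes the single covariate
#' whose removal most reduces the leave-one-out PRESS, stopping when no
#' removal reduces it. Ties are broken in favour of the first-listed
#' covariate, making the procedure deterministic given column order.
#'
#' Retained coefficients' p-values are reported for reference (the selection
#' criterion itself is pure PRESS minimization).
#'
#' @param tanks tank-level data.frame.
#' @param candidates character vector of candidate covariate columns; an
#'   empty set returns the day-only model.
#' @param interactions also offer all pairwise products of the candidates
#'   as derived candidate columns (default FALSE).
#' @inheritParams fit_tank_model
#' @return the selected `tank_regression`, with an extra element `trace`
#'   (data.frame of the elimination path: step, dropped covariate, PRESS).
#' @export
backward_eliminate <- function(tanks, candidates, response = "fcr",
                               day_col = "day", interactions = FALSE) {
  candidates <- as.character(candidates)
  if (interactions && length(candidates) >= 2L) {
    pairs <- utils::combn(candidates, 2L, simplify = FALSE)
    for (pr in pairs) {
      nm <- paste(pr, collapse = "_x_")
      tanks[[nm]] <- tanks[[pr[1]]] * tanks[[pr[2]]]
      candidates <- c(candidates, nm)
    }
  }
  current <- candidates
  best <- fit_tank_model(tanks, current, response, day_col)
  trace <- data.frame(step = 0L, dropped = NA_character_,
                      press = best$press, n_covariates = length(current))
  step <- 0L
  repeat {
    if (length(current) == 0L) break
    press_wo <- vapply(seq_along(current), function(j) {
      fit_tank_model(tanks, current[-j], response, day_col)$press
    }, numeric(1))
    j_best <- which.min(press_wo)  # ties -> first listed
    if (press_wo[j_best] >= best$press) break
    step <- step + 1L
    dropped <- current[j_best]
    current <- current[-j_best]
    best <- fit_tank_model(tanks, current, response, day_col)
    trace <- rbind(trace, data.frame(step = step, dropped = dropped,
                                     press = best$press,
                                     n_covariates = length(current)))
  }
  best$trace <- trace
  best
}

#' Single-covariate regression scan
#'
#' Regresses the response on sampling day plus each covariate, one at a
#' time, reporting fit and leave-one-out prediction summaries per covariate
#' (one row each). Covariates producing a rank-deficient design (e.g.
#' constants) are flagged with NA statistics rather than failing the scan.
#'
#' @param tanks tank-level data.frame.
#' @param covariates character vector of covariate columns to scan.
#' @inheritParams fit_tank_model
#' @return data.frame with columns `covariate`, `r2`, `adj_r2`, `r2_pred`,
#'   `bias`, `press`, `note`.
#' @export
single_covariate_scan <- function(tanks, covariates, response = "fcr",
                                  day_col = "day") {
  rows <- lapply(covariates, function(cv) {
    res <- tryCatch(fit_tank_model(tanks, cv, response, day_col),
                    error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(covariate = cv, r2 = NA_real_, adj_r2 = NA_real_,
                 r2_pred = NA_real_, bias = NA_real_, press = NA_real_,
                 note = conditionMessage(res))
    } else {
      data.frame(covariate = cv, r2 = res$r2, adj_r2 = res$adj_r2,
                 r2_pred = res$r2_pred, bias = res$bias, press = res$press,
                 note = "")
    }
  })
  do.call(rbind, rows)
}

#' @export
print.tank_regression <- function(x, ...) {
  cat(sprintf("tank regression: %s ~ day%s%s (n = %d)\n", x$response,
              if (length(x$covariates)) " + " else "",
              paste(x$covariates, collapse = " + "), x$n))
  cat(sprintf("R2 = %.3f, adj R2 = %.3f, R2-pred = %.3f, PRESS = %.4g, bias = %.3g\n",
              x$r2, x$adj_r2, x$r2_pred, x$press, x$bias))
  invisible(x)
}
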