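#' Specify a uni- or bivariate mixed model
#'
#' Two model families are supported, mirroring the two levels of recording
#' in a family-tank feed-efficiency trial:
#' \describe{
#'   \item{tank level}{one record per tank; random additive-genetic tank
#'     effect with covariance `T0 (x) G_T`, independent tank residuals with
#'     trait covariance `R` (diagonal across traits by default).}
#'   \item{individual level}{one record per fish; random additive-genetic
#'     effect with covariance `G0 (x) G`, a common-tank environmental effect
#'     `T (x) I`, and residuals `R (x) I` (both full 2x2 by default).}
#' }
#' Fixed effects are a trait-specific intercept and sampling day, entered as
#' a linear covariate (values 1-5) or optionally as a factor.
#'
#' @param traits character vector of one or two trait column names.
#' @param level `"tank"` or `"individual"`.
#' @param id_col column holding the entity id matching the relationship
#'   matrix rownames (tank id at tank level, fish id at individual level).
#' @param tank_col column holding the tank id (individual level only;
#'   NULL drops the common-tank term).
#' @param day_col column holding the sampling day.
#' @param day_as_factor treat day as a factor instead of a covariate.
#' @param residual `"diagonal"` or `"unstructured"` cross-trait residual.
#' @param genetic include the additive-genetic term (set FALSE for the null
#'   model of a likelihood-ratio test).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(traits, level = c("tank", "individual"),
                       id_col = if (level == "tank") "tank" else "id",
                       tank_col = if (level == "individual") "tank" else NULL,
                       day_col = "day", day_as_factor = FALSE,
                       residual = if (level == "tank") "diagonal"
                                  else "unstructured",
                       genetic = TRUE) {
  level <- match.arg(level)
  stopifnot(length(traits) %in% 1:2, is.character(traits))
  residual <- match.arg(residual, c("diagonal", "unstructured"))
  if (level == "tank" && !is.null(tank_col))
    stop("a separate tank term is not identifiable at the tank level")
  structure(list(traits = traits, level = level, id_col = id_col,
                 tank_col = tank_col, day_col = day_col,
                 day_as_factor = day_as_factor, residual = residual,
                 genetic = genetic),
            class = "model_spec")
}

#' REML optimizer control
#'
#' @param maxit maximum Nelder-Mead iterations.
#' @param reltol relative convergence tolerance passed to [stats::optim()].
#' @param logl_tol,comp_tol declared convergence requires the restart
#'   improvement in log-likelihood below `logl_tol` and the maximum relative
#'   component change below `comp_tol`.
#' @param jitter relative ridge added to the diagonal when a covariance
#'   matrix fails to factorize.
#' @param n_starts number of optimizer starts (best kept).
#' @param boundary_tol correlations with `|r| > 1 - boundary_tol` are
#'   reported as clamped at +/- 1. The default 1e-3 reflects that the
#'   tanh-parameterized optimizer approaches, but never formally reaches,
#'   the correlation boundary.
#' @export
reml_control <- function(maxit = 4000, reltol = 1e-12, logl_tol = 1e-6,
                         comp_tol = 1e-4, jitter = 1e-8, n_starts = 2,
                         boundary_tol = 1e-3) {
  list(maxit = maxit, reltol = reltol, logl_tol = logl_tol,
       comp_tol = comp_tol, jitter = jitter, n_starts = n_starts,
       boundary_tol = boundary_tol)
}

# ---- parameter packing -------------------------------------------------
# each 2x2 covariance is parameterized (log v1, log v2, z) with
# cov = tanh(z) sqrt(v1 v2); diagonal blocks drop z; univariate blocks are
# a single log-variance. Enforces PSD and |r| <= 1 by construction.

component_layout <- function(q, spec) {
  comps <- list()
  if (spec$genetic)
    comps$genetic <- if (q == 2L) "full" else "var"
  if (!is.null(spec$tank_col))
    comps$tank <- if (q == 2L) "full" else "var"
  comps$residual <- if (q == 2L) {
    if (spec$residual == "unstructured") "full" else "diag"
  } else "var"
  comps
}

n_params <- function(kind) switch(kind, var = 1L, diag = 2L, full = 3L)

unpack_component <- function(theta, kind) {
  if (kind == "var") return(matrix(exp(theta[1L]), 1L, 1L))
  v <- exp(theta[1:2])
  r <- if (kind == "full") tanh(theta[3L]) else 0
  matrix(c(v[1L], r * sqrt(v[1L] * v[2L]), r * sqrt(v[1L] * v[2L]), v[2L]),
         2L, 2L)
}

pack_start <- function(v_traits, comps) {
  n_active <- length(comps)
  unlist(lapply(comps, function(kind) {
    v <- v_traits / n_active
    switch(kind,
           var = log(v[1L]),
           diag = log(v),
           full = c(log(v), 0))
  }), use.names = FALSE)
}

unpack_all <- function(theta, comps) {
  out <- list()
  i <- 0L
  for (nm in names(comps)) {
    k <- n_params(comps[[nm]])
    out[[nm]] <- unpack_component(theta[i + seq_len(k)], comps[[nm]])
    i <- i + k
  }
  out
}

# ---- restricted log-likelihood ----------------------------------------

# A: n x n genetic similarity among records (K[idx, idx]); B: tank-sharing
# indicator (or NULL); the full covariance of the stacked record vector is
# sum over components of C[q, r] * S for S in (A, B, I).
reml_logl <- function(theta, comps, A, B, y, X, n, q, jitter) {
  cm <- unpack_all(theta, comps)
  V <- matrix(0, n * q, n * q)
  for (nm in names(cm)) {
    S <- switch(nm, genetic = A, tank = B, residual = diag(n))
    C <- cm[[nm]]
    for (a in seq_len(q)) for (b in seq_len(q)) {
      if (C[a, b] == 0) next
      ra <- (a - 1L) * n + seq_len(n)
      rb <- (b - 1L) * n + seq_len(n)
      V[ra, rb] <- V[ra, rb] + C[a, b] * S
    }
  }
  L <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(L)) {
    V <- V + diag(jitter * mean(diag(V)), n * q)
    L <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(L)) return(-Inf)
  }
  logdet_V <- 2 * sum(log(diag(L)))
  Vi_y <- backsolve(L, forwardsolve(t(L), y))
  Vi_X <- backsolve(L, forwardsolve(t(L), X))
  XtViX <- crossprod(X, Vi_X)
  Lx <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(Lx)) return(-Inf)
  logdet_X <- 2 * sum(log(diag(Lx)))
  XtViy <- crossprod(X, Vi_y)
  beta <- backsolve(Lx, forwardsolve(t(Lx), XtViy))
  quad <- sum(y * Vi_y) - sum(XtViy * beta)
  -0.5 * (logdet_V + logdet_X + quad)
}

build_design <- function(spec, data, K) {
  q <- length(spec$traits)
  cols <- c(spec$traits, spec$day_col, spec$id_col, spec$tank_col)
  miss <- setdiff(cols, names(data))
  if (length(miss))
    stop("data is missing column(s): ", paste(miss, collapse = ", "))
  keep <- stats::complete.cases(data[, cols, drop = FALSE])
  d <- data[keep, , drop = FALSE]
  n <- nrow(d)
  if (n < 3L) stop("too few complete records to fit the model")
  Kmat <- unclass(K)
  idx <- match(as.character(d[[spec$id_col]]), rownames(Kmat))
  if (spec$genetic) {
    if (is.null(rownames(Kmat)))
      stop("relationship matrix must carry entity ids as rownames")
    if (anyNA(idx))
      stop("relationship matrix does not cover all entities; first missing: ",
           as.character(d[[spec$id_col]])[which(is.na(idx))[1L]])
  }
  day <- d[[spec$day_col]]
  Xt <- if (spec$day_as_factor) {
    stats::model.matrix(~ factor(day))
  } else {
    cbind(`(Intercept)` = 1, day = as.numeric(day))
  }
  if (qr(Xt)$rank < ncol(Xt))
    stop("singular fixed-effects design (is the day covariate constant?)")
  X <- kronecker(diag(q), Xt)
  y <- unlist(lapply(spec$traits, function(tr) d[[tr]]), use.names = FALSE)
  A <- if (spec$genetic) Kmat[idx, idx, drop = FALSE] else NULL
  B <- NULL
  if (!is.null(spec$tank_col)) {
    tk <- factor(d[[spec$tank_col]])
    if (nlevels(tk) < 2L) stop("tank term requires at least two tanks")
    B <- tcrossprod(stats::model.matrix(~ 0 + tk))
  }
  list(y = y, X = X, A = A, B = B, n = n, q = q, data = d)
}

#' Fit a uni- or bivariate mixed model by REML
#'
#' Maximizes the restricted likelihood of the Gaussian mixed model defined
#' by `spec` over the variance components, parameterized as log-variances
#' with cross-trait correlations in tanh space (so estimates respect
#' positive semi-definiteness and `|r| <= 1` by construction). Optimization
#' uses Nelder-Mead from `n_starts` starting points; the fit is flagged
#' non-converged if the restarts disagree beyond the configured tolerances.
#'
#' @param spec a [model_spec()].
#' @param data data.frame with trait, day and id columns; records with any
#'   missing value among the used columns are dropped (complete-case).
#' @param K relationship matrix with entity ids as rownames ([vanraden_g()],
#'   [tank_g()], or an identity for a plain family/tank grouping). Ignored
#'   when `spec$genetic` is FALSE.
#' @param control a [reml_control()].
#' @return object of class `bivariate_fit` with elements `components`
#'   (named list of 1x1 or 2x2 covariance matrices: `genetic`, `tank`,
#'   `residual`), `logLik` (restricted, up to an additive constant shared by
#'   fits on the same data), `converged`, `boundary` (per-component
#'   correlation clamping flags), `se` (component standard errors from the
#'   inverse observed information, or NULL), `spec`, `n`.
#' @export
reml_fit <- function(spec, data, K = NULL, control = reml_control()) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$genetic && is.null(K))
    stop("a relationship matrix is required when the genetic term is included")
  ds <- build_design(spec, data, K)
  comps <- component_layout(ds$q, spec)
  v_traits <- vapply(seq_len(ds$q), function(j) {
    yj <- ds$y[(j - 1L) * ds$n + seq_len(ds$n)]
    stats::var(yj)
  }, numeric(1))
  if (any(v_traits <= 0)) stop("a trait has zero phenotypic variance")

  negll <- function(th) {
    ll <- reml_logl(th, comps, ds$A, ds$B, ds$y, ds$X, ds$n, ds$q,
                    control$jitter)
    if (!is.finite(ll)) 1e10 else -ll
  }

  th0 <- pack_start(v_traits, comps)
  starts <- list(th0)
  if (control$n_starts > 1L) {
    for (s in seq_len(control$n_starts - 1L))
      starts[[s + 1L]] <- th0 + (s %% 2L * 2L - 1L) * 0.5 * seq_along(th0) /
        length(th0)
  }
  fits <- lapply(starts, function(st) {
    if (length(st) == 1L) {
      stats::optim(st, negll, method = "Brent", lower = st - 25,
                   upper = st + 25,
                   control = list(maxit = control$maxit))
    } else {
      stats::optim(st, negll, method = "Nelder-Mead",
                   control = list(maxit = control$maxit,
                                  reltol = control$reltol))
    }
  })
  vals <- vapply(fits, `[[`, numeric(1), "value")
  best <- fits[[which.min(vals)]]
  # agreement across starts (optimum uniqueness check)
  agree <- if (length(fits) > 1L) {
    max(vals) - min(vals) < max(control$logl_tol, 1e-4)
  } else TRUE
  converged <- best$convergence == 0L

  cm <- unpack_all(best$par, comps)
  boundary <- lapply(names(comps), function(nm) {
    if (comps[[nm]] != "full") return(FALSE)
    C <- cm[[nm]]
    r <- C[1, 2] / sqrt(C[1, 1] * C[2, 2])
    abs(r) > 1 - control$boundary_tol
  })
  names(boundary) <- names(comps)

  se <- tryCatch({
    H <- stats::optimHess(best$par, negll)
    Sig <- solve(H)
    if (any(diag(Sig) < 0)) stop("indefinite Hessian")
    comp_fun <- function(th) unlist(unpack_all(th, comps))
    J <- numeric_jacobian(comp_fun, best$par)
    se_vec <- sqrt(pmax(diag(J %*% Sig %*% t(J)), 0))
    relist_components(se_vec, comps)
  }, error = function(e) {
    warning("standard errors unavailable: ", conditionMessage(e),
            call. = FALSE)
    NULL
  })

  structure(list(components = cm, logLik = -best$value,
                 converged = converged && agree,
                 start_agreement = agree,
                 optim = list(counts = best$counts,
                              convergence = best$convergence,
                              n_starts = length(starts),
                              spread = max(vals) - min(vals)),
                 boundary = boundary, se = se, spec = spec, n = ds$n,
                 theta = best$par, layout = comps),
            class = "bivariate_fit")
}

numeric_jacobian <- function(f, x, h = 1e-5) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

relist_components <- function(vec, comps) {
  out <- list()
  i <- 0L
  for (nm in names(comps)) {
    q <- if (comps[[nm]] == "var") 1L else 2L
    k <- q * q
    out[[nm]] <- matrix(vec[i + seq_len(k)], q, q)
    i <- i + k
  }
  out
}

#' @export
print.bivariate_fit <- function(x, ...) {
  cat(sprintf("%s-level REML fit: traits %s, n = %d, logL = %.4f%s\n",
              x$spec$level, paste(x$spec$traits, collapse = " / "), x$n,
              x$logLik, if (x$converged) "" else " (NOT converged)"))
  for (nm in names(x$components)) {
    cat(nm, "(co)variance:\n")
    print(round(x$components[[nm]], 6))
  }
  invisible(x)
}
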