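#' Observed allele frequencies from a dosage matrix
#'
#' @param M individuals x SNPs matrix of allele dosages in \{0, 1, 2\};
#'   NA allowed.
#' @param mono_eps frequencies outside `(mono_eps, 1 - mono_eps)` are flagged
#'   monomorphic.
#' @return numeric vector of frequencies with a logical attribute
#'   `"monomorphic"`.
#' @export
allele_frequencies <- function(M, mono_eps = 1e-12) {
  M <- as.matrix(M)
  n_called <- colSums(!is.na(M))
  if (any(n_called == 0))
    stop(sprintf("%d locus/loci with no non-missing calls", sum(n_called == 0)))
  p <- colMeans(M, na.rm = TRUE) / 2
  attr(p, "monomorphic") <- p <= mono_eps | p >= 1 - mono_eps
  p
}

#' Quality-control filter for genotype matrices
#'
#' Removes loci failing a minor-allele-frequency or call-rate threshold.
#'
#' @param M dosage matrix (individuals x SNPs).
#' @param maf_min minimum minor allele frequency in `[0, 0.5]`.
#' @param call_rate_min minimum fraction of non-missing calls in `[0, 1]`.
#' @return the filtered matrix, with an attribute `"qc_report"` listing the
#'   number of loci removed per rule.
#' @export
qc_filter <- function(M, maf_min = 0.01, call_rate_min = 0.9) {
  M <- as.matrix(M)
  stopifnot(maf_min >= 0, maf_min <= 0.5, call_rate_min >= 0,
            call_rate_min <= 1)
  call_rate <- colMeans(!is.na(M))
  fail_call <- call_rate < call_rate_min
  p <- colMeans(M, na.rm = TRUE) / 2
  p[is.nan(p)] <- 0
  maf <- pmin(p, 1 - p)
  fail_maf <- maf < maf_min
  keep <- !(fail_call | fail_maf)
  if (!any(keep)) stop("all loci removed by QC")
  out <- M[, keep, drop = FALSE]
  attr(out, "qc_report") <- c(n_input = ncol(M), n_retained = sum(keep),
                              fail_call_rate = sum(fail_call),
                              fail_maf = sum(fail_maf))
  out
}

# centered dosages with mean-imputation of missing calls (zero deviation)
center_dosages <- function(M, p) {
  Z <- sweep(M, 2L, 2 * p)
  Z[is.na(Z)] <- 0
  Z
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' G = Z Z' / (2 sum p_j (1 - p_j)) with Z the column-centered dosage matrix
#' (M - 2P). Missing genotypes are mean-imputed to 2 p_j, i.e. contribute a
#' zero deviation.
#'
#' @param M individuals x SNPs dosage matrix; rownames are individual ids.
#' @param p optional allele frequencies; computed from `M` when NULL.
#'   Monomorphic loci are dropped before construction.
#' @return symmetric matrix of class `relationship_matrix` with attributes
#'   `kind = "individual"` and `denominator`.
#' @export
vanraden_g <- function(M, p = NULL) {
  M <- as.matrix(M)
  if (nrow(M) < 2L) stop("at least two individuals are required")
  if (is.null(p)) p <- allele_frequencies(M)
  mono <- attr(p, "monomorphic") %||% (p <= 0 | p >= 1)
  if (any(mono)) {
    M <- M[, !mono, drop = FALSE]
    p <- p[!mono]
  }
  if (ncol(M) == 0L) stop("no polymorphic loci left; cannot build G")
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("zero denominator: all retained loci monomorphic")
  Z <- center_dosages(M, p)
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(rownames(M), rownames(M))
  structure(G, class = c("relationship_matrix", "matrix"),
            kind = "individual", denominator = denom)
}

#' Tank-level genomic relationship matrix
#'
#' Builds T with row t the mean centered genotype of the tank's members,
#' T_tj = (1/n_t) sum_i (M_ij - 2 p_j), forms G_T = T T', and rescales by a
#' single scalar so that the mean diagonal element equals 1.0 exactly.
#'
#' @param M individuals x SNPs dosage matrix; rownames are individual ids.
#' @param tank_assignment vector (length nrow(M)) of tank ids per individual.
#' @param p optional allele frequencies (computed from `M` when NULL).
#' @return symmetric tanks x tanks matrix of class `relationship_matrix` with
#'   attributes `kind = "tank"`, `scale_factor` (the divisor applied to the
#'   raw T T') and `n_t` (members per tank).
#' @export
tank_g <- function(M, tank_assignment, p = NULL) {
  M <- as.matrix(M)
  if (length(tank_assignment) != nrow(M))
    stop("`tank_assignment` must have one entry per row of `M`")
  if (anyNA(tank_assignment)) stop("tank assignment contains missing values")
  if (is.null(p)) p <- allele_frequencies(M)
  mono <- attr(p, "monomorphic") %||% (p <= 0 | p >= 1)
  if (any(mono)) {
    M <- M[, !mono, drop = FALSE]
    p <- p[!mono]
  }
  tk <- factor(tank_assignment)
  n_t <- as.integer(table(tk))
  Z <- center_dosages(M, p)
  Tm <- rowsum(Z, tk) / n_t
  GT_raw <- tcrossprod(Tm)
  scale_factor <- mean(diag(GT_raw))
  if (scale_factor <= 0) stop("degenerate tank matrix: zero mean diagonal")
  GT <- GT_raw / scale_factor
  dimnames(GT) <- list(levels(tk), levels(tk))
  structure(GT, class = c("relationship_matrix", "matrix"),
            kind = "tank", scale_factor = scale_factor,
            n_t = stats::setNames(n_t, levels(tk)))
}

#' @export
print.relationship_matrix <- function(x, ...) {
  kind <- attr(x, "kind")
  cat(sprintf("%s-level genomic relationship matrix: %d x %d\n",
              kind, nrow(x), ncol(x)))
  cat(sprintf("mean diagonal %.4f; range [%.4f, %.4f]\n",
              mean(diag(x)), min(x), max(x)))
  invisible(x)
}
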