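#' Read a pipeline configuration file
#'
#' The configuration is a single YAML file with per-stage sections:
#' `simulate` (any [sim_config()] field; `genetic_cov`/`env_cov` may be
#' given as matrices), `derive` (filter thresholds, `include_filtered_in_fcr`,
#' `delta_input`), `grm` (`maf_min`, `call_rate_min`), `fit` (list of trait
#' `pairs`, each with `traits` and `level`), `regress` (`candidates`,
#' `interactions`).
#'
#' @param path path to a YAML file.
#' @return named list of stage sections.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping")
  cfg
}

stage_order <- c("simulate", "derive", "grm", "fit", "regress")

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order:
#' `simulate` (synthetic genotypes and phenotypes), `derive` (trait
#' derivation and filtering), `grm` (individual and tank relationship
#' matrices), `fit` (REML variance components per configured trait pair)
#' and `regress` (single-covariate scan plus backward elimination on tank
#' FCR). Each stage reads its inputs from `out_dir`, so stages can be run
#' in separate invocations; a missing upstream output is a hard error.
#' A JSON manifest recording the configuration, seed, stage timings, file
#' digests and package version is written at the end.
#'
#' @param config configuration list (see [read_pipeline_config()]), or a
#'   path to a YAML file.
#' @param out_dir output directory (created if absent).
#' @param stages character subset of
#'   `c("simulate", "derive", "grm", "fit", "regress")` or `"all"`.
#' @param seed integer seed overriding `config$simulate$seed`.
#' @return (invisibly) the manifest list.
#' @export
run_pipeline <- function(config = list(), out_dir, stages = "all",
                         seed = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- read_pipeline_config(config)
  stopifnot(is.list(config))
  if (identical(stages, "all")) stages <- stage_order
  if (!length(stages)) stop("stage list is empty")
  stages <- match.arg(stages, stage_order, several.ok = TRUE)
  stages <- stage_order[stage_order %in% stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  path <- function(f) file.path(out_dir, f)
  need <- function(f, stage, from) {
    if (!file.exists(path(f)))
      stop(sprintf("stage '%s' requires %s from stage '%s'; run it first",
                   stage, f, from))
    path(f)
  }
  timings <- c()
  log_lines <- character()
  note <- function(...) {
    msg <- sprintf(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    force(expr)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
  }

  if ("simulate" %in% stages) timed("simulate", {
    sc_args <- config$simulate %||% list()
    if (!is.null(seed)) sc_args$seed <- seed
    if (!is.null(sc_args$genetic_cov))
      sc_args$genetic_cov <- matrix(unlist(sc_args$genetic_cov), 5, 5)
    if (!is.null(sc_args$env_cov))
      sc_args$env_cov <- matrix(unlist(sc_args$env_cov), 5, 5)
    sc <- do.call(sim_config, sc_args)
    geno <- simulate_genotypes(sc)
    sim <- simulate_phenotypes(geno, sc)
    write_tsv(sim$individuals, path("individuals.tsv"))
    write_tsv(sim$tanks, path("tanks.tsv"))
    gm <- data.frame(id = rownames(geno$M), geno$M, check.names = FALSE)
    names(gm)[-1] <- sprintf("snp%05d", seq_len(ncol(geno$M)))
    write_tsv(gm, path("genotypes.tsv"))
    write_tsv(data.frame(id = rownames(geno$M), family = geno$family,
                         sim$truth$bv, intake = sim$truth$intake,
                         check.names = FALSE),
              path("truth_individuals.tsv"))
    note("simulate: %d fish, %d tanks, %d SNPs", nrow(sim$individuals),
         nrow(sim$tanks), ncol(geno$M))
  })

  if ("derive" %in% stages) timed("derive", {
    ind <- utils::read.delim(need("individuals.tsv", "derive", "simulate"))
    tk <- utils::read.delim(need("tanks.tsv", "derive", "simulate"))
    dv_args <- config$derive %||% list()
    der <- do.call(derive_phenotypes, c(list(individuals = ind, tanks = tk),
                                        dv_args))
    write_tsv(der$individuals, path("individuals_derived.tsv"))
    write_tsv(der$tanks, path("tanks_derived.tsv"))
    fc <- der$filter_counts
    note("derive: flagged %d weight_missing, %d low_growth, %d high_growth (%.1f%% of %d fish)",
         fc[["weight_missing"]], fc[["low_growth"]], fc[["high_growth"]],
         100 * sum(fc) / nrow(der$individuals), nrow(der$individuals))
  })

  if ("grm" %in% stages) timed("grm", {
    gm <- utils::read.delim(need("genotypes.tsv", "grm", "simulate"))
    M <- as.matrix(gm[, -1, drop = FALSE])
    rownames(M) <- gm$id
    qc <- config$grm %||% list()
    M <- qc_filter(M, maf_min = qc$maf_min %||% 0.01,
                   call_rate_min = qc$call_rate_min %||% 0.9)
    rep_qc <- attr(M, "qc_report")
    ind <- utils::read.delim(need("individuals.tsv", "grm", "simulate"))
    G <- vanraden_g(M)
    GT <- tank_g(M, ind$tank[match(rownames(M), ind$id)])
    write_matrix_tsv(G, path("grm_individual.tsv"))
    write_matrix_tsv(GT, path("grm_tank.tsv"))
    note("grm: %d/%d loci retained (QC); G %dx%d, G_T %dx%d (mean diag %.3f)",
         rep_qc[["n_retained"]], rep_qc[["n_input"]], nrow(G), ncol(G),
         nrow(GT), ncol(GT), mean(diag(GT)))
  })

  if ("fit" %in% stages) timed("fit", {
    ind <- utils::read.delim(need("individuals_derived.tsv", "fit", "derive"))
    tk <- utils::read.delim(need("tanks_derived.tsv", "fit", "derive"))
    G <- read_matrix_tsv(need("grm_individual.tsv", "fit", "grm"))
    GT <- read_matrix_tsv(need("grm_tank.tsv", "fit", "grm"))
    pairs <- config$fit$pairs %||% list(
      list(traits = c("fcr", "rg_bar"), level = "tank"),
      list(traits = c("wg", "amn"), level = "individual"))
    res <- lapply(pairs, function(pr) {
      lvl <- pr$level
      spec <- model_spec(pr$traits, level = lvl)
      data <- if (lvl == "tank") tk else ind
      K <- if (lvl == "tank") GT else G
      fit <- reml_fit(spec, data, K)
      h0 <- reml_fit(model_spec(pr$traits[1], level = lvl, genetic = FALSE,
                                tank_col = if (lvl == "individual") "tank"),
                     data, NULL)
      h1 <- reml_fit(model_spec(pr$traits[1], level = lvl,
                                tank_col = if (lvl == "individual") "tank"),
                     data, K)
      lrt <- lr_test(h1, h0)
      rat <- ratio_estimates(fit)
      cr <- if (length(pr$traits) == 2L) correlations(fit) else
        list(genetic = NA, phenotypic = NA, boundary = FALSE)
      if (!fit$converged)
        note("fit %s/%s: flagged non-converged",
             pr$traits[1], pr$traits[2] %||% "")
      if (isTRUE(cr$boundary))
        note("fit %s/%s: genetic correlation restricted on boundary",
             pr$traits[1], pr$traits[2])
      data.frame(trait1 = pr$traits[1],
                 trait2 = pr$traits[2] %||% NA_character_, level = lvl,
                 h2_trait1 = rat$h2[1], h2_trait2 = rat$h2[2] %||% NA_real_,
                 c2_trait1 = rat$c2[1],
                 r_genetic = cr$genetic, r_phenotypic = cr$phenotypic,
                 boundary = cr$boundary, logLik = fit$logLik,
                 lr_trait1 = lrt$lr, p_trait1 = lrt$p_value,
                 converged = fit$converged)
    })
    write_tsv(do.call(rbind, res), path("fit_results.tsv"))
    note("fit: %d trait pair(s) analysed", length(res))
  })

  if ("regress" %in% stages) timed("regress", {
    tk <- utils::read.delim(need("tanks_derived.tsv", "regress", "derive"))
    rg_cfg <- config$regress %||% list()
    candidates <- rg_cfg$candidates %||%
      intersect(c("fi", "rg_bar", "wg_bar", "amc_bar", "amn_bar", "alc_bar",
                  "aln_bar", "aac_bar"), names(tk))
    scan <- single_covariate_scan(tk, candidates)
    write_tsv(scan, path("regression_scan.tsv"))
    sel <- backward_eliminate(tk, setdiff(candidates, "wg_bar"),
                              interactions = isTRUE(rg_cfg$interactions))
    write_tsv(data.frame(covariate = c("(day)", sel$covariates),
                         retained = TRUE), path("regression_selected.tsv"))
    write_tsv(sel$trace, path("regression_trace.tsv"))
    note("regress: selected %d covariate(s) [%s], R2 = %.3f, R2-pred = %.3f, PRESS = %.4g",
         length(sel$covariates), paste(sel$covariates, collapse = ", "),
         sel$r2, sel$r2_pred, sel$press)
  })

  outputs <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(
    package = "isofcr",
    version = as.character(utils::packageVersion("isofcr")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed %||% config$simulate$seed %||% NA,
    stages = stages,
    config = config,
    timings_sec = as.list(timings),
    log = log_lines,
    digests = as.list(tools::md5sum(outputs))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  invisible(manifest)
}
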