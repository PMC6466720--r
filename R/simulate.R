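#' Simulation configuration
#'
#' Defines the family-tank design, genotyping, and the genetic architecture
#' of the latent traits driving the simulated phenotypes. Defaults emulate
#' the study design the package targets: 23 full-sib families, two replicate
#' tanks per family, 50 fish per tank, a 12-day feeding window on a diet
#' enriched to 2.7 atom\% 15N and 2.0 atom\% 13C, sampling spread over 5
#' days, and initial weights around 21.8 g.
#'
#' The latent traits, in order, are `growth` (weight-gain deviation, g),
#' `turn_muscle`, `turn_liver`, `turn_adipose` (tissue turnover rate over the
#' window, as a fraction of final weight), and `intake_dev` (feed-intake
#' deviation, g dry matter). `genetic_cov`, `env_cov` and `tank_var` are
#' specified over these five latents.
#'
#' @param n_families number of full-sib families (>= 2).
#' @param n_tanks_per_family replicate tanks per family.
#' @param n_fish_per_tank fish per tank.
#' @param n_snps number of biallelic SNPs (>= 10).
#' @param maf_range founder allele-frequency range, within (0, 0.5];
#'   zero width allowed.
#' @param days length of the enriched-feed window (days).
#' @param n_sampling_days tanks are terminated round-robin over this many
#'   sampling days.
#' @param diet_atom named atom percent of the enriched diet (`N15`, `C13`).
#' @param baseline_atom named baseline IA\% per measurement column
#'   (`amn`, `amc`, `aln`, `alc`, `aac`).
#' @param iw_mean,iw_sd initial-weight distribution (g).
#' @param wg_mean mean weight gain over the window (g).
#' @param growth_model how weight gain scales with initial size.
#'   `"proportional"` (default): `WG = (IW / iw_mean) * (wg_mean + latent)`,
#'   i.e. relative growth is size-independent (realistic for parr; RG then
#'   has the latent's distribution regardless of fish size).
#'   `"additive"`: `WG = wg_mean + slope (IW - iw_mean) + latent`, which
#'   keeps the genetic architecture of WG exactly additive (useful for
#'   parameter-recovery studies).
#' @param growth_iw_slope slope of the additive model (default
#'   `wg_mean / iw_mean`; ignored for `"proportional"`). The size-driven
#'   share of the weight-gain variance is environmental and is accounted
#'   for in the truth record's variance ratios.
#' @param turnover_mean named mean turnover per tissue (muscle, liver,
#'   adipose); may be negative when the new-nutrient fraction of a tissue
#'   lags the whole-body growth fraction (e.g. adipose carbon).
#' @param fi_per_gain direct feed cost per gram of gain (g dry matter / g).
#' @param fi_per_fw maintenance feed cost per gram of body mass over the
#'   window (g dry matter / g). Because this cost is diluted by growth,
#'   fast-growing fish convert feed more efficiently, giving the
#'   tank-level FCR its negative genetic association with growth.
#' @param turnover_cost additional maintenance cost per unit of
#'   muscle-turnover deviation (the latent's departure from its mean),
#'   linking high tissue exchange to poor feed conversion.
#' @param genetic_cov 5x5 additive-genetic (co)variance matrix of the latent
#'   traits (symmetric PSD).
#' @param env_cov 5x5 residual (co)variance matrix (symmetric PSD).
#' @param tank_var length-5 between-tank environmental variances.
#' @param sampling_day_effects numeric length `n_sampling_days`, additive
#'   shift of the intake-per-gain ratio per sampling day.
#' @param atom_noise_sd measurement noise SD of atom percent readings;
#'   draws are truncated at +/- 3 SD.
#' @param tank_fi_noise_sd SD of tank-level feed-intake recording noise
#'   added after the member intakes are summed (default 0).
#' @param seed integer RNG seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_families = 23,
                       n_tanks_per_family = 2,
                       n_fish_per_tank = 50,
                       n_snps = 2000,
                       maf_range = c(0.05, 0.5),
                       days = 12,
                       n_sampling_days = 5,
                       diet_atom = c(N15 = 2.7, C13 = 2.0),
                       baseline_atom = c(amn = 0.370, amc = 1.087,
                                         aln = 0.370, alc = 1.086,
                                         aac = 1.082),
                       iw_mean = 21.8, iw_sd = 8.0,
                       wg_mean = 10.8,
                       growth_model = c("proportional", "additive"),
                       growth_iw_slope = NULL,
                       turnover_mean = c(muscle = -0.047, liver = 0.222,
                                         adipose = -0.237),
                       fi_per_gain = 0.35,
                       fi_per_fw = 0.113,
                       turnover_cost = 0.3,
                       genetic_cov = NULL,
                       env_cov = NULL,
                       tank_var = c(growth = 1.2, turn_muscle = 0,
                                    turn_liver = 0, turn_adipose = 0,
                                    intake_dev = 0.05),
                       sampling_day_effects = NULL,
                       atom_noise_sd = 0.005,
                       tank_fi_noise_sd = 0,
                       seed = 1L) {
  latents <- c("growth", "turn_muscle", "turn_liver", "turn_adipose",
               "intake_dev")
  if (is.null(genetic_cov)) genetic_cov <- default_genetic_cov()
  if (is.null(env_cov)) env_cov <- default_env_cov()
  if (is.null(sampling_day_effects))
    sampling_day_effects <- (seq_len(n_sampling_days) -
                               (n_sampling_days + 1) / 2) * 0.005
  stopifnot(n_families >= 2, n_snps >= 10, n_tanks_per_family >= 1,
            n_fish_per_tank >= 1, days > 0, n_sampling_days >= 1,
            length(sampling_day_effects) == n_sampling_days)
  if (length(maf_range) != 2L || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop("`maf_range` must be an increasing pair within (0, 0.5]")
  if (!is_symmetric_psd(genetic_cov) || !is_symmetric_psd(env_cov))
    stop("`genetic_cov` and `env_cov` must be symmetric positive semi-definite")
  stopifnot(nrow(genetic_cov) == 5L, nrow(env_cov) == 5L,
            length(tank_var) == 5L, all(tank_var >= 0))
  diet_of <- c(amn = "N15", amc = "C13", aln = "N15", alc = "C13",
               aac = "C13")
  if (any(baseline_atom >= diet_atom[diet_of[names(baseline_atom)]]))
    stop("baseline atom% must be below the diet atom% for every tissue/isotope")
  # reject configurations that would push tissues to isotopic equilibrium
  growth_model <- match.arg(growth_model)
  if (is.null(growth_iw_slope)) growth_iw_slope <- wg_mean / iw_mean
  growth_frac <- wg_mean / (iw_mean + wg_mean)
  if (any(growth_frac + turnover_mean >= 1))
    stop("configuration implies a new-nutrient fraction >= 1 (isotopic ",
         "equilibrium would be reached); shorten the window or reduce ",
         "growth/turnover")
  dimnames(genetic_cov) <- list(latents, latents)
  dimnames(env_cov) <- list(latents, latents)
  names(tank_var) <- latents
  structure(list(n_families = as.integer(n_families),
                 n_tanks_per_family = as.integer(n_tanks_per_family),
                 n_fish_per_tank = as.integer(n_fish_per_tank),
                 n_snps = as.integer(n_snps), maf_range = maf_range,
                 days = days, n_sampling_days = as.integer(n_sampling_days),
                 diet_atom = diet_atom, baseline_atom = baseline_atom,
                 iw_mean = iw_mean, iw_sd = iw_sd, wg_mean = wg_mean,
                 growth_model = growth_model,
                 growth_iw_slope = growth_iw_slope,
                 turnover_mean = turnover_mean, fi_per_gain = fi_per_gain,
                 fi_per_fw = fi_per_fw,
                 turnover_cost = turnover_cost, genetic_cov = genetic_cov,
                 env_cov = env_cov, tank_var = tank_var,
                 sampling_day_effects = sampling_day_effects,
                 atom_noise_sd = atom_noise_sd,
                 tank_fi_noise_sd = tank_fi_noise_sd,
                 seed = as.integer(seed), latents = latents),
            class = "sim_config")
}

# Default additive-genetic architecture: WG heritability ~0.45 with c2 ~0.06
# (tank_var default 1.2 against a total near 20 g^2); moderate positive
# genetic association of growth with tissue turnover; turnover correlated
# across tissues; intake deviation weakly linked to growth.
default_genetic_cov <- function() {
  sd <- c(growth = 3.0, turn_muscle = 0.025, turn_liver = 0.030,
          turn_adipose = 0.015, intake_dev = 0.7)
  cor <- diag(5)
  rownames(cor) <- colnames(cor) <- names(sd)
  cor["growth", "turn_muscle"] <- cor["turn_muscle", "growth"] <- 0.2
  cor["growth", "turn_liver"] <- cor["turn_liver", "growth"] <- 0.2
  cor["growth", "turn_adipose"] <- cor["turn_adipose", "growth"] <- 0.2
  cor["turn_muscle", "turn_liver"] <- cor["turn_liver", "turn_muscle"] <- 0.7
  cor["turn_muscle", "turn_adipose"] <- cor["turn_adipose", "turn_muscle"] <- 0.4
  cor["turn_liver", "turn_adipose"] <- cor["turn_adipose", "turn_liver"] <- 0.3
  cor["growth", "intake_dev"] <- cor["intake_dev", "growth"] <- 0.3
  diag(sd) %*% cor %*% diag(sd)
}

default_env_cov <- function() {
  sd <- c(growth = sqrt(10), turn_muscle = 0.030, turn_liver = 0.035,
          turn_adipose = 0.018, intake_dev = 1.0)
  cor <- diag(5)
  rownames(cor) <- colnames(cor) <- names(sd)
  cor["turn_muscle", "turn_liver"] <- cor["turn_liver", "turn_muscle"] <- 0.3
  cor["turn_muscle", "turn_adipose"] <- cor["turn_adipose", "turn_muscle"] <- 0.2
  cor["turn_liver", "turn_adipose"] <- cor["turn_adipose", "turn_liver"] <- 0.2
  diag(sd) %*% cor %*% diag(sd)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: %d families x %d tanks x %d fish, ",
                     "%d SNPs, %g-day window, seed %d\n"),
              x$n_families, x$n_tanks_per_family, x$n_fish_per_tank,
              x$n_snps, x$days, x$seed))
  invisible(x)
}

#' Simulate family-structured SNP genotypes
#'
#' For each full-sib family, two unrelated founders are drawn in
#' Hardy-Weinberg proportions at locus frequencies sampled uniformly from
#' `maf_range`, and offspring dosages are generated by Mendelian transmission
#' (one allele sampled per parent per locus, loci independent). Full sibs
#' therefore share an expected genomic relationship of ~0.5.
#'
#' @param config a [sim_config()].
#' @param seed optional override of `config$seed`.
#' @return list of class `genotype_sim` with elements `M` (offspring dosage
#'   matrix, individuals x SNPs, rownames = fish ids), `family` (family id
#'   per offspring) and `founder_freq` (the sampled locus frequencies).
#' @export
simulate_genotypes <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed %||% config$seed)
  S <- config$n_snps
  n_off_fam <- config$n_tanks_per_family * config$n_fish_per_tank
  p <- stats::runif(S, config$maf_range[1], config$maf_range[2])
  fam_ids <- sprintf("F%02d", seq_len(config$n_families))
  M <- matrix(0L, nrow = config$n_families * n_off_fam, ncol = S)
  fam <- character(nrow(M))
  row0 <- 0L
  for (f in seq_len(config$n_families)) {
    # founder haplotypes: sire (h1, h2) and dam (h3, h4)
    H <- matrix(stats::rbinom(4L * S, 1L, rep(p, each = 4L)), nrow = 4L)
    pick_s <- matrix(stats::rbinom(n_off_fam * S, 1L, 0.5),
                     nrow = n_off_fam)
    pick_d <- matrix(stats::rbinom(n_off_fam * S, 1L, 0.5),
                     nrow = n_off_fam)
    h_s <- matrix(H[1L, ], n_off_fam, S, byrow = TRUE) * (1L - pick_s) +
      matrix(H[2L, ], n_off_fam, S, byrow = TRUE) * pick_s
    h_d <- matrix(H[3L, ], n_off_fam, S, byrow = TRUE) * (1L - pick_d) +
      matrix(H[4L, ], n_off_fam, S, byrow = TRUE) * pick_d
    M[row0 + seq_len(n_off_fam), ] <- h_s + h_d
    fam[row0 + seq_len(n_off_fam)] <- fam_ids[f]
    row0 <- row0 + n_off_fam
  }
  rownames(M) <- sprintf("%s_%03d", fam, stats::ave(seq_along(fam), fam,
                                                    FUN = seq_along))
  structure(list(M = M, family = fam, founder_freq = p),
            class = "genotype_sim")
}

#' Simulate growth, intake and isotope phenotypes
#'
#' Builds breeding values for the latent traits as linear combinations of
#' the simulated SNP dosages (rescaled so the realized genomic (co)variance
#' equals `genetic_cov` exactly), assigns fish to replicate tanks and tanks
#' to sampling days round-robin, and generates:
#' \itemize{
#'   \item weight gain `WG = wg_mean + bv_growth + tank effect + residual`
#'     over the feeding window (linear gain, endpoint weights only);
#'   \item a per-tissue new-nutrient fraction
#'     `f = clamp(WG/FW + turnover, 0, 1 - 1e-6)` (single-compartment
#'     mixing, endpoint based);
#'   \item recorded atom percent `IA + f (diet - IA)` plus truncated
#'     measurement noise, strictly below the diet enrichment;
#'   \item individual feed intake
#'     `fi_per_gain * WG + turnover_cost * f_muscle * FW + intake deviation`,
#'     observable only as the tank sum.
#' }
#'
#' @param genotypes result of [simulate_genotypes()].
#' @param config the same [sim_config()].
#' @param seed optional override; defaults to `config$seed + 1` so that the
#'   genotype and phenotype draws are distinct but jointly reproducible.
#' @return list with `individuals` (id, family, tank, day, iw, fw, amc, amn,
#'   alc, aln, aac), `tanks` (tank, family, day, n_members, fi) and `truth`
#'   (breeding-value matrix, tank effects, true individual intakes, and the
#'   true per-latent variance ratios implied by the configuration).
#' @export
simulate_phenotypes <- function(genotypes, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(genotypes, "genotype_sim"))
  set.seed(seed %||% (config$seed + 1L))
  M <- genotypes$M
  n <- nrow(M)
  k <- length(config$latents)
  n_fam_exp <- config$n_families * config$n_tanks_per_family *
    config$n_fish_per_tank
  if (n != n_fam_exp)
    stop("genotypes do not cover the configured individuals")

  # breeding values: per-SNP effects i.i.d. within latent, then an exact
  # linear rescaling so the realized genomic (co)variance matches target
  p_hat <- colMeans(M) / 2
  Z <- sweep(M, 2L, 2 * p_hat)
  U <- matrix(stats::rnorm(ncol(M) * k), ncol(M), k)
  bv_raw <- Z %*% U
  bv <- exact_cov_transform(bv_raw, config$genetic_cov)
  colnames(bv) <- config$latents

  # design: split each family into consecutive tanks, round-robin days
  fam <- genotypes$family
  within <- stats::ave(seq_len(n), fam, FUN = seq_along)
  tank_idx <- ceiling(within / config$n_fish_per_tank)
  tank <- sprintf("%s_T%d", fam, tank_idx)
  tank_levels <- unique(tank)
  n_tanks <- length(tank_levels)
  day_of_tank <- ((seq_len(n_tanks) - 1L) %% config$n_sampling_days) + 1L
  names(day_of_tank) <- tank_levels
  day <- day_of_tank[tank]

  # tank environmental effects and residuals on the latent scale
  tank_eff <- sapply(config$tank_var,
                     function(v) stats::rnorm(n_tanks, 0, sqrt(v)))
  if (is.null(dim(tank_eff))) tank_eff <- matrix(tank_eff, nrow = n_tanks)
  rownames(tank_eff) <- tank_levels
  E <- matrix(stats::rnorm(n * k), n, k) %*% mat_sqrt(config$env_cov)
  colnames(E) <- config$latents
  tank_row <- match(tank, tank_levels)

  latent <- bv + tank_eff[tank_row, , drop = FALSE] + E

  iw <- pmax(stats::rnorm(n, config$iw_mean, config$iw_sd), 1)
  wg <- if (config$growth_model == "proportional") {
    (iw / config$iw_mean) * (config$wg_mean + latent[, "growth"])
  } else {
    config$wg_mean + config$growth_iw_slope * (iw - config$iw_mean) +
      latent[, "growth"]
  }
  fw <- pmax(iw + wg, 0.5)
  wg <- fw - iw

  eps <- 1e-6
  growth_frac <- pmax(wg, 0) / fw
  tissue_of <- c(amn = "muscle", amc = "muscle", aln = "liver",
                 alc = "liver", aac = "adipose")
  diet_of <- c(amn = "N15", amc = "C13", aln = "N15", alc = "C13",
               aac = "C13")
  f <- sapply(c("muscle", "liver", "adipose"), function(ts) {
    pmin(pmax(growth_frac + config$turnover_mean[[ts]] +
                latent[, paste0("turn_", ts)], 0), 1 - eps)
  })

  atom <- sapply(names(config$baseline_atom), function(col) {
    ia <- config$baseline_atom[[col]]
    diet <- config$diet_atom[[diet_of[[col]]]]
    noise <- pmin(pmax(stats::rnorm(n, 0, config$atom_noise_sd),
                       -3 * config$atom_noise_sd), 3 * config$atom_noise_sd)
    pmin(ia + f[, tissue_of[[col]]] * (diet - ia) + noise,
         ia + (1 - eps) * (diet - ia))
  })

  # intake: direct growth cost, size-dependent maintenance modulated by the
  # muscle-turnover deviation, an intake deviation, and the day drift
  intake <- pmax(config$fi_per_gain * pmax(wg, 0) +
                   (config$fi_per_fw +
                      config$turnover_cost * latent[, "turn_muscle"]) * fw +
                   latent[, "intake_dev"] +
                   config$sampling_day_effects[day] * pmax(wg, 0), 0)

  individuals <- data.frame(id = rownames(M), family = fam, tank = tank,
                            day = as.integer(day), iw = iw, fw = fw,
                            amc = atom[, "amc"], amn = atom[, "amn"],
                            alc = atom[, "alc"], aln = atom[, "aln"],
                            aac = atom[, "aac"], row.names = NULL)

  fi_true <- as.numeric(rowsum(intake, factor(tank, levels = tank_levels)))
  fi_obs <- fi_true
  if (config$tank_fi_noise_sd > 0)
    fi_obs <- fi_true + stats::rnorm(n_tanks, 0, config$tank_fi_noise_sd)
  tanks <- data.frame(tank = tank_levels,
                      family = fam[match(tank_levels, tank)],
                      day = as.integer(day_of_tank),
                      n_members = as.integer(table(factor(tank,
                        levels = tank_levels))),
                      fi = fi_obs, row.names = NULL)

  # Exact variance accounting for the observed WG trait. Proportional
  # model: WG = s (m + L) with s = IW/iw_mean independent of the latent L,
  # so var(WG) = (1 + cv^2) var(L) + m^2 cv^2 and the genetic component
  # s * bv has variance (1 + cv^2) Va; a GRM-based analysis attributes the
  # size-heterogeneity diagonal to the residual, so its estimand for the
  # genetic variance is Va itself (`h2_estimand`). Additive model: the
  # size term is pure extra residual variance and the two ratios coincide.
  va <- diag(config$genetic_cov)
  vt <- config$tank_var
  ve <- diag(config$env_cov)
  cv2 <- (config$iw_sd / config$iw_mean)^2
  if (config$growth_model == "proportional") {
    tot_g <- (1 + cv2) * (va[1] + vt[1] + ve[1]) + config$wg_mean^2 * cv2
    h2 <- c((1 + cv2) * va[1], va[-1]) /
      c(tot_g, (va + vt + ve)[-1])
    h2_estimand <- c(va[1] / tot_g, (va / (va + vt + ve))[-1])
    c2 <- c((1 + cv2) * vt[1] / tot_g, (vt / (va + vt + ve))[-1])
  } else {
    extra <- config$growth_iw_slope^2 * config$iw_sd^2
    tot <- va + vt + ve + c(extra, 0, 0, 0, 0)
    h2 <- va / tot
    h2_estimand <- h2
    c2 <- vt / tot
  }
  names(h2) <- names(h2_estimand) <- names(c2) <- config$latents
  truth <- list(bv = bv, tank_effects = tank_eff, intake = stats::setNames(
                  intake, rownames(M)), fi_true = stats::setNames(
                  fi_true, tank_levels),
                h2 = h2, h2_estimand = h2_estimand, c2 = c2)

  list(individuals = individuals, tanks = tanks, truth = truth)
}

#' Simulate a tank-level trait pair with known genetic architecture
#'
#' Draws a pair of tank-recorded traits (an FCR-like and a growth-like
#' trait) directly from the tank-level model: genetic tank effects
#' `a ~ N(0, T0 (x) G_T)`, independent residuals `e ~ N(0, R (x) I)`, and an
#' optional linear sampling-day effect. Used for parameter-recovery studies
#' where the true between-trait genetic correlation must be known exactly.
#'
#' @param GT tank-level relationship matrix (e.g. from [tank_g()]).
#' @param T0 2x2 additive-genetic (co)variance matrix between the traits.
#' @param R 2x2 diagonal residual covariance matrix (between-tank residual).
#' @param day integer sampling day per tank (covariate effect `day_beta`).
#' @param day_beta length-2 fixed day slopes (default `c(0, 0)`).
#' @param mu length-2 trait intercepts.
#' @return data.frame with columns `tank`, `day`, `y1`, `y2`.
#' @export
simulate_tank_traits <- function(GT, T0, R, day = NULL,
                                 day_beta = c(0, 0), mu = c(0, 0)) {
  GT <- unclass(GT)
  m <- nrow(GT)
  stopifnot(nrow(T0) == 2L, nrow(R) == 2L)
  if (!is_symmetric_psd(T0) || !is_symmetric_psd(R))
    stop("`T0` and `R` must be symmetric positive semi-definite")
  if (is.null(day)) day <- rep(1L, m)
  L <- mat_sqrt(kronecker(T0, GT))
  a <- as.numeric(L %*% stats::rnorm(2L * m))
  e <- c(stats::rnorm(m, 0, sqrt(R[1, 1])), stats::rnorm(m, 0, sqrt(R[2, 2])))
  y <- a + e + rep(mu, each = m) + rep(day_beta, each = m) * rep(day, 2L)
  data.frame(tank = rownames(GT) %||% sprintf("T%02d", seq_len(m)),
             day = as.integer(day),
             y1 = y[seq_len(m)], y2 = y[m + seq_len(m)], row.names = NULL)
}
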