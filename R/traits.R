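#' Individual growth traits
#'
#' Weight gain WG = FW - IW (g) and relative weight gain
#' RG = 100 (FW - IW) / FW (%). Missing weights propagate to NA.
#'
#' @param iw initial body weight (g), positive.
#' @param fw final body weight (g), positive.
#' @return data.frame with columns `wg` and `rg`.
#' @export
growth_traits <- function(iw, fw) {
  if (length(iw) != length(fw)) stop("`iw` and `fw` must have equal length")
  bad <- (!is.na(iw) & iw <= 0) | (!is.na(fw) & fw <= 0)
  if (any(bad)) stop("body weights must be positive where present")
  data.frame(wg = fw - iw, rg = 100 * (fw - iw) / fw)
}

#' Flag growth outliers for exclusion
#'
#' Applies the growth-plausibility filter: fish with relative weight gain
#' strictly below `rg_low` (abnormally low growth) or strictly above
#' `rg_high` (growth not matched by the isotope profile, i.e. a likely
#' phenotyping error) are set missing for the growth-based analyses, as are
#' fish lacking a weight record. The filter is idempotent.
#'
#' @param records data.frame with columns `iw`, `fw` and (optionally)
#'   precomputed `wg`, `rg`.
#' @param rg_low lower RG threshold in percent (default 6.4; strict `<`).
#' @param rg_high upper RG threshold in percent (default 49; strict `>`).
#' @return `records` with `wg`/`rg` filled in and a character column
#'   `missing_reason` (NA when retained; otherwise one of
#'   `"weight_missing"`, `"low_growth"`, `"high_growth"`).
#' @export
filter_growth_outliers <- function(records, rg_low = 6.4, rg_high = 49) {
  stopifnot(is.data.frame(records), all(c("iw", "fw") %in% names(records)))
  if (!all(c("wg", "rg") %in% names(records))) {
    gt <- growth_traits(records$iw, records$fw)
    records$wg <- gt$wg
    records$rg <- gt$rg
  }
  reason <- rep(NA_character_, nrow(records))
  reason[is.na(records$iw) | is.na(records$fw)] <- "weight_missing"
  low <- !is.na(records$rg) & records$rg < rg_low
  high <- !is.na(records$rg) & records$rg > rg_high
  reason[is.na(reason) & low] <- "low_growth"
  reason[is.na(reason) & high] <- "high_growth"
  records$missing_reason <- reason
  records
}

#' Tank-level feed conversion ratio
#'
#' FCR_t = FI_t / sum(WG) over the tank's non-missing members. Fish flagged
#' by the growth filter carry NA weight gain and are excluded from the
#' denominator.
#'
#' @param fi tank feed intake (g dry matter), non-negative.
#' @param member_wg numeric vector of member weight gains (g); NA = excluded.
#' @return FCR (dimensionless).
#' @export
tank_fcr <- function(fi, member_wg) {
  assert_scalar_number(fi, "fi")
  if (fi < 0) stop("feed intake must be non-negative")
  total_wg <- sum(member_wg, na.rm = TRUE)
  if (!any(!is.na(member_wg)) || total_wg <= 0)
    stop("total non-missing weight gain must be positive to compute FCR")
  fi / total_wg
}

#' Isotope indicator ratio traits
#'
#' Individual indicator traits for feed conversion and feed efficiency:
#' IFCR = FW * APE / (FW - IW) and its reciprocal IFER. IFCR is proportional
#' to the mass of newly deposited nutrients per gram of body-weight gain;
#' a fish exchanging a larger fraction of its body mass per unit growth is
#' less feed-efficient.
#'
#' @param iw,fw initial and final weights (g).
#' @param ape atom percent excess of the tracked isotope in the tissue.
#' @return data.frame with columns `ifcr`, `ifer`; records with `fw == iw`
#'   (undefined ratio) or `ape == 0` (undefined IFER) yield NA.
#' @export
indicator_ratios <- function(iw, fw, ape) {
  n <- length(fw)
  if (length(iw) != n || length(ape) != n)
    stop("`iw`, `fw`, `ape` must have equal length")
  denom <- fw - iw
  ifcr <- ifelse(!is.na(denom) & denom != 0, fw * ape / denom, NA_real_)
  ifer <- ifelse(!is.na(ifcr) & ifcr != 0, 1 / ifcr, NA_real_)
  data.frame(ifcr = ifcr, ifer = ifer)
}

#' Dry-matter feed intake from feeding records
#'
#' FI = (fed - waste / (1 - leaching)) * dm_fraction, i.e. recovered uneaten
#' feed is inflated for leaching losses before subtraction, and the result is
#' expressed on a dry-matter basis.
#'
#' @param fed total feed offered (g as fed).
#' @param waste_recovered uneaten feed recovered from the waste screen (g).
#' @param leaching_correction fraction of waste lost to leaching, in `[0, 1)`.
#' @param dm_fraction dry-matter fraction of the feed, in `(0, 1]`.
#' @return feed intake in g dry matter.
#' @export
dry_matter_intake <- function(fed, waste_recovered, leaching_correction = 0,
                              dm_fraction = 1) {
  stopifnot(all(fed >= 0), all(waste_recovered >= 0),
            all(leaching_correction >= 0), all(leaching_correction < 1),
            all(dm_fraction > 0), all(dm_fraction <= 1))
  corrected <- waste_recovered / (1 - leaching_correction)
  if (any(corrected > fed))
    stop("leaching-corrected waste exceeds the amount fed")
  (fed - corrected) * dm_fraction
}

#' Per-tank trait means
#'
#' Arithmetic mean of a trait over each tank's non-missing members, with
#' member counts.
#'
#' @param records individual data.frame containing `tank_col` and `trait`.
#' @param trait name of the trait column.
#' @param tank_col name of the tank id column (default "tank").
#' @return data.frame with columns `tank`, `mean`, `n`.
#' @export
tank_means <- function(records, trait, tank_col = "tank") {
  stopifnot(is.data.frame(records), trait %in% names(records),
            tank_col %in% names(records))
  f <- factor(records[[tank_col]])
  x <- records[[trait]]
  n <- tapply(!is.na(x), f, sum)
  if (any(n == 0))
    stop(sprintf("tank(s) with no non-missing `%s`: %s", trait,
                 paste(levels(f)[n == 0], collapse = ", ")))
  m <- tapply(x, f, mean, na.rm = TRUE)
  data.frame(tank = levels(f), mean = as.numeric(m), n = as.integer(n),
             row.names = NULL)
}

#' Derive all individual and tank phenotypes
#'
#' One-stop trait derivation: growth traits and outlier flags, atom percent
#' excess per isotope column, muscle indicator ratio traits (IFCR/IFER for
#' 15N and 13C), tank FCR, and tank means of every derived trait.
#'
#' Expected individual columns: `id`, `tank`, `day`, `iw`, `fw`, and any of
#' the atom-percent columns `amc`, `amn`, `alc`, `aln`, `aac` (muscle C,
#' muscle N, liver C, liver N, adipose C). If `delta_input = TRUE` these
#' columns instead hold delta values and are converted first. Expected tank
#' columns: `tank`, `day`, `fi`.
#'
#' APE values below `-3 * ia_sd` for the element are flagged invalid (set to
#' NA for indicators); mildly negative values (measurement noise around the
#' baseline) are retained.
#'
#' @param individuals individual phenotype data.frame (see Details).
#' @param tanks tank data.frame with feed intake.
#' @param standards an [isotope_standards()] object.
#' @param rg_low,rg_high growth-filter thresholds in percent RG.
#' @param include_filtered_in_fcr if TRUE, growth-flagged fish keep their WG
#'   in the tank FCR denominator (sensitivity analysis); default FALSE.
#' @param delta_input are isotope columns delta values rather than atom\%?
#' @return list with elements `individuals` (derived columns appended),
#'   `tanks` (FCR and per-trait means appended) and `filter_counts`
#'   (named integer vector of exclusions per reason).
#' @export
derive_phenotypes <- function(individuals, tanks,
                              standards = isotope_standards(),
                              rg_low = 6.4, rg_high = 49,
                              include_filtered_in_fcr = FALSE,
                              delta_input = FALSE) {
  stopifnot(is.data.frame(individuals), is.data.frame(tanks))
  need <- c("id", "tank", "iw", "fw")
  if (!all(need %in% names(individuals)))
    stop("individual table must contain columns: ", paste(need, collapse = ", "))
  if (!all(c("tank", "fi") %in% names(tanks)))
    stop("tank table must contain columns: tank, fi")

  atom_cols <- intersect(c("amc", "amn", "alc", "aln", "aac"),
                         names(individuals))
  element <- c(amc = "C13", amn = "N15", alc = "C13", aln = "N15",
               aac = "C13")

  ind <- filter_growth_outliers(individuals, rg_low = rg_low,
                                rg_high = rg_high)

  for (col in atom_cols) {
    el <- element[[col]]
    if (delta_input) {
      r <- if (el == "N15") standards$r_n15 else standards$r_c13
      ok <- !is.na(ind[[col]])
      conv <- rep(NA_real_, nrow(ind))
      conv[ok] <- delta_to_atom_percent(ind[[col]][ok], r)
      ind[[col]] <- conv
    }
    ia <- unname(standards$ia_tissue[col])
    if (is.null(standards$ia_tissue) || is.na(ia)) ia <- standards$ia[[el]]
    ape <- ind[[col]] - ia
    invalid <- !is.na(ape) & ape < -3 * standards$ia_sd[[el]]
    if (any(invalid)) {
      warning(sprintf("%d %s record(s) more than 3 baseline SDs below IA%%; set invalid",
                      sum(invalid), col))
      ape[invalid] <- NA_real_
    }
    ind[[paste0("ape_", col)]] <- ape
  }

  # muscle-based indicator ratio traits; undefined for growth-flagged fish
  for (col in intersect(c("amn", "amc"), atom_cols)) {
    ir <- indicator_ratios(ind$iw, ind$fw, ind[[paste0("ape_", col)]])
    drop <- !is.na(ind$missing_reason)
    ir$ifcr[drop] <- NA_real_
    ir$ifer[drop] <- NA_real_
    ind[[paste0("ifcr_", col)]] <- ir$ifcr
    ind[[paste0("ifer_", col)]] <- ir$ifer
  }

  filter_counts <- c(
    weight_missing = sum(ind$missing_reason == "weight_missing", na.rm = TRUE),
    low_growth = sum(ind$missing_reason == "low_growth", na.rm = TRUE),
    high_growth = sum(ind$missing_reason == "high_growth", na.rm = TRUE)
  )

  # tank aggregation
  wg_use <- ind$wg
  if (!include_filtered_in_fcr) wg_use[!is.na(ind$missing_reason)] <- NA_real_
  tanks$n_members <- as.integer(table(factor(ind$tank,
                                             levels = tanks$tank))[tanks$tank])
  agg <- tapply(wg_use, factor(ind$tank, levels = tanks$tank),
                function(x) sum(x, na.rm = TRUE))
  tanks$sum_wg <- as.numeric(agg)
  tanks$fcr <- mapply(function(fi, t) {
    wg <- wg_use[ind$tank == t]
    tryCatch(tank_fcr(fi, wg), error = function(e) {
      warning(sprintf("tank %s: %s", t, conditionMessage(e)), call. = FALSE)
      NA_real_
    })
  }, tanks$fi, tanks$tank)

  # per-trait tank means: growth-linked traits respect the growth filter,
  # isotope contents use all fish with a measurement
  growth_linked <- intersect(
    c("wg", "rg", "ifcr_amn", "ifcr_amc", "ifer_amn", "ifer_amc"),
    names(ind))
  ind_masked <- ind
  for (tr in c("wg", "rg"))
    ind_masked[[tr]][!is.na(ind$missing_reason)] <- NA_real_
  for (tr in c(growth_linked, atom_cols)) {
    src <- if (tr %in% growth_linked) ind_masked else ind
    m <- tapply(src[[tr]], factor(src$tank, levels = tanks$tank),
                mean, na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    tanks[[paste0(tr, "_bar")]] <- as.numeric(m)
  }

  list(individuals = ind, tanks = tanks, filter_counts = filter_counts)
}
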