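---
title: "Isotope-based indicator traits for feed efficiency: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotope-based indicator traits for feed efficiency: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isofcr)
```

## The problem

Feed is the dominant cost of fish production, and feed conversion ratio
(FCR = feed intake per unit of weight gain) the trait a breeding program
would like to improve. In group-housed fish, feed intake — and hence FCR —
can only be recorded per tank, not per fish, which blocks direct individual
selection. `isofcr` implements an analysis route around that constraint:
during a short window the fish are fed a diet enriched in the stable
isotopes ^15^N and ^13^C. The enrichment a tissue accumulates above its
pre-experiment baseline is proportional to the fraction of newly deposited
nutrients in that tissue, so isotope profiling turns nutrient turnover —
an individual quantity — into a measurable phenotype.

## Traits

Isotope-ratio mass spectrometry reports measurements in delta notation,
converted to atom percent with

$$\mathrm{atom\%} = \frac{\delta + 1000}{\delta + 1000 + 1000 / R_{std}}
  \times 100,$$

where $R_{std}$ is the heavy/light isotope ratio of the reference standard
(0.003676 for air nitrogen; 0.0112372 for VPDB carbon). The map is strictly
increasing and exactly invertible, which the test suite exercises as a
round-trip property. Atom percent excess (APE) subtracts the baseline
("initial") atom percent IA%: 0.370% for ^15^N and 1.087% for ^13^C, with
tissue-specific carbon baselines (liver 1.086, adipose 1.082) available as
overrides. The muscle-based indicator ratios keep the common per-element
IA%, which is the convention the derived traits are defined under.

From endpoint weights, weight gain $WG = FW - IW$ and relative gain
$RG = 100\,(FW - IW)/FW$. The individual indicator ratio traits are

$$\mathrm{IFCR} = \frac{FW \cdot \mathrm{APE}}{FW - IW}, \qquad
  \mathrm{IFER} = \mathrm{IFCR}^{-1}.$$

IFCR is proportional to the mass of newly deposited nutrients per gram of
gain: a fish that exchanges a large fraction of its body mass per unit of
growth is less feed-efficient. Tank FCR is $FI_t / \sum WG$ over the tank's
retained members.

Fish with $RG < 6.4$ or $RG > 49$ (strict inequalities) are set missing:
the former indicates abnormal development, the latter growth unaccompanied
by a matching isotope shift, i.e. a probable phenotyping error. A companion
threshold on absolute gain is redundant with the relative rule at the
weights this design targets, so only the RG rule is applied. Flagged fish
are excluded from the tank FCR denominator by default; because their intake
still sits in the numerator the resulting FCR carries a small upward bias
when exclusions are rare, and `include_filtered_in_fcr = TRUE` restores
them for sensitivity analysis.

## Relationship matrices

The individual genomic relationship matrix follows VanRaden's first method,
$G = ZZ' / (2\sum_j p_j(1-p_j))$ with $Z$ the column-centered dosages.
Missing genotypes are mean-imputed to $2p_j$ (zero deviation), and allele
frequencies default to the observed sample frequencies. The tank-level
matrix averages member genotype deviations per tank,
$T_{tj} = n_t^{-1}\sum_i (M_{ij} - 2p_j)$, forms $G_T = TT'$, and rescales
by a single scalar so the mean diagonal equals 1.0 exactly; the scalar is
kept in the object's metadata. Only $G_T$ is rescaled — the individual $G$
is left on its natural VanRaden scale, since the unit-mean-diagonal
convention is specific to the tank-level analysis.

## Mixed models

Two bivariate Gaussian models cover the two recording levels:

* **Tank level** (FCR, FI and tank means of other traits): fixed
  trait-specific intercepts and sampling day, a random additive-genetic
  tank effect with covariance $T_0 \otimes G_T$, and independent tank
  residuals with a diagonal cross-trait covariance. The genetic fraction of
  between-tank variance is $h_t^2 = \sigma_{a_t}^2 / (\sigma_{a_t}^2 +
  \sigma_{e_t}^2)$.
* **Individual level**: random genetic effect with covariance
  $G_0 \otimes G$, a common-tank environmental effect $T \otimes I$, and
  residuals $R \otimes I$, the latter two full 2×2. Heritability is
  $h^2 = \sigma_a^2/(\sigma_a^2+\sigma_t^2+\sigma_e^2)$ and the tank
  fraction $c^2 = \sigma_t^2/(\sigma_a^2+\sigma_t^2+\sigma_e^2)$.

Sampling day enters both models as a linear covariate on both traits by
default (`day_as_factor = TRUE` switches to a 5-level factor). The REML
engine maximizes the restricted likelihood directly on a dense covariance
of the stacked record vector, with components parameterized as
log-variances and correlations in tanh space, so positive
semi-definiteness and $|r| \le 1$ hold by construction. Convergence is
declared when Nelder-Mead terminates (relative tolerance $10^{-12}$, Brent
for one-parameter problems) and independent restarts agree to $10^{-4}$ in
log-likelihood; correlations with $|r| > 1 - 10^{-3}$ are reported as
restricted to the boundary — the tanh parameterization approaches but
never formally reaches $\pm 1$, so a tighter detection threshold would
never fire. Standard errors come from the inverse observed information at
the optimum and are omitted with a warning when the Hessian is indefinite,
which is expected at boundary solutions.

Significance of a genetic component is assessed with
$LR = 2(\log L_{H_1} - \log L_{H_0})$ against $\chi^2_1$; the effect is
significant when LR *exceeds* the critical value. Negative LR from
numerical noise is clamped at zero with a warning. Because the restricted
likelihood is computed through $\log|X'V^{-1}X|$, reparameterizing the
fixed effects shifts it by a data-independent constant; variance
components and LR statistics are invariant, which the suite checks
explicitly.

When only the tabulated form of a variance decomposition is available
(genetic and residual components plus the tank fraction $c^2$),
`h2_from_components()` recovers the total as
$(\sigma_a^2+\sigma_e^2)/(1-c^2)$ before forming the ratios.

## Tank regression and model selection

`fit_tank_model()` regresses tank FCR on sampling day (always retained)
plus tank-mean covariates by OLS. Leave-one-out prediction uses the
leverage identity $e_{(i)} = e_i/(1-h_{ii})$, giving
$\mathrm{PRESS} = \sum e_{(i)}^2$, predictive
$\hat R^2 = 1 - \mathrm{PRESS}/SS_{tot}$, and bias as the mean difference
between observations and their leave-one-out predictions (the in-sample
mean residual, an exact zero for OLS with intercept, is reported
alongside — published bias values at numerical-zero magnitude do not
distinguish the two, so both are exposed). `backward_eliminate()` removes,
at each step, the covariate whose removal most reduces PRESS, stopping when
no removal helps; ties break toward the first-listed covariate so the
procedure is deterministic given column order. Retained-coefficient
p-values are reported for reference only — selection is pure PRESS
minimization. Pairwise product terms can be added to the candidate pool
with `interactions = TRUE` (off by default). Covariates enter on their raw
scale; no standardization is applied, so coefficient signs are directly
interpretable.

## The synthetic-data generator

Real trial data of this kind are not publicly deposited, so the package
ships a generator that emulates the design: 23 full-sib families, two
replicate 50-fish tanks per family, a 12-day window on a diet at 2.7 atom%
^15^N and 2.0 atom% ^13^C, termination round-robin over 5 sampling days,
and initial weights of 21.8 ± 8.0 g. Five latent traits (growth potential,
per-tissue turnover for muscle/liver/adipose, and an intake deviation)
receive breeding values built from per-SNP effects and rescaled linearly so
the realized genomic (co)variance equals the configured matrix exactly —
by construction, GRM-based REML is then an unbiased estimator of the
configured components. Founder genotypes are drawn in Hardy-Weinberg
proportions at frequencies uniform on `maf_range`, and offspring dosages by
Mendelian transmission without linkage.

Key modelling choices, made where the design was genuinely open:

* **Growth**: linear over the window (only endpoint weights are analysed).
  By default expected gain is proportional to initial weight
  (`growth_model = "proportional"`), which makes relative gain
  size-independent and reproduces a realistic outlier rate (~1–2% of fish
  beyond the RG filter thresholds); the alternative `"additive"` model
  keeps the architecture of WG exactly additive, which is what the
  parameter-recovery studies use. In both cases the size-driven share of
  variance is environmental, and the truth record reports the exact
  variance ratios — including, for the proportional model, the slightly
  smaller ratio a GRM-based analysis targets (`h2_estimand`), since the
  size-heterogeneity it induces on the diagonal is absorbed by the
  residual.
* **Isotope kinetics**: single-compartment endpoint mixing. The
  new-nutrient fraction is $f = \mathrm{clamp}(WG/FW + \tau, 0, 1-10^{-6})$
  per tissue, and recorded atom% is $IA + f(\mathrm{diet} - IA)$ plus
  measurement noise truncated at ±3 SD, so simulated values stay strictly
  inside the physical band. Per-tissue mean turnover defaults
  (muscle −0.047, liver 0.222, adipose −0.237) were set so the implied
  population means match the observed mid-experiment tissue enrichments;
  negative values express that a tissue's new-nutrient fraction can lag the
  whole-body growth fraction (pronounced for adipose carbon, where lipid
  stores turn over slowly). Configurations whose expected fraction reaches
  1 — isotopic equilibrium, under which individual variation becomes
  invisible — are rejected outright.
* **Intake**: individual intake = a direct cost per gram of gain
  (0.35 g/g) + a maintenance cost per gram of body mass (0.113 g/g over
  the window), the latter modulated by the fish's muscle-turnover
  deviation (0.3 g per unit), plus an intake deviation observable only as
  the tank sum. The two baseline costs were chosen so the implied mean
  tank FCR is ≈ 0.69 at the default growth scale. Because maintenance is
  proportional to body mass rather than gain, fast growth dilutes it and
  the emergent tank-level genetic correlation between FCR and relative
  gain is negative, while high tissue turnover pushes FCR up — the sign
  structure the indicator-trait idea relies on. The within-tank
  decomposition of intake is an assumption of the generator, not an
  inference about real fish — tank-level recording is precisely what the
  real design cannot see through.
* **Day effects** shift the intake-per-gain ratio by ±0.5% per day around
  the middle sampling day, a small systematic drift of the kind the
  day covariate is meant to absorb.

What passing recovery tests on these data do **not** show: robustness to
genotyping error, linkage and LD structure, non-Gaussian residuals,
within-day feeding dynamics, or tank environmental gradients beyond a
single shared effect. The generator is a validation instrument for the
estimation machinery, not a model of salmon physiology.

## Problem sizes and numerical choices

The shipped validation studies run at a deliberately scaled design —
8 families × 2 tanks × 25 fish and 1,000 SNPs, 50 replicates — which keeps
a full parameter-recovery sweep at a few minutes while leaving the
between-family information structure intact. Dense Cholesky factorization
of the stacked covariance (at most a few hundred records per fit) is
exact and fast at this scale; a diagonal jitter of $10^{-8}$ relative to
the mean diagonal is added only if factorization fails, and fits at
correlation boundaries routinely produce indefinite Hessians, reported as
missing standard errors rather than numbers of spurious precision.

## Worked example

```{r example, eval = FALSE}
sc <- sim_config(n_families = 8, n_fish_per_tank = 25, n_snps = 1000,
                 seed = 42)
geno <- simulate_genotypes(sc)
sim <- simulate_phenotypes(geno, sc)
der <- derive_phenotypes(sim$individuals, sim$tanks)

G <- vanraden_g(geno$M)
GT <- tank_g(geno$M, sim$individuals$tank)

fit <- reml_fit(model_spec("wg", level = "individual"),
                der$individuals, G)
ratio_estimates(fit)

sel <- backward_eliminate(der$tanks,
                          c("fi", "rg_bar", "amn_bar", "alc_bar", "aac_bar"))
sel
```

## Known limitations

The REML engine is dense and intended for designs up to a few thousand
records; it does not exploit sparsity or average-information updates, and
it fits at most two traits jointly. Genomic prediction (breeding-value
output), pedigree-based relationship matrices, LD pruning and imputation
beyond mean-fill are out of scope. Standard errors of ratios use a
first-order delta method that ignores sampling covariance between
components and should be read as indicative.
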