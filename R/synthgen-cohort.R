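#' Default latent correlation structure of the synthetic cohort
#'
#' Correlation matrix of the five per-case latent Gaussian variables
#' (age, hptau, abeta, si, wmh) used by the Gaussian-copula cohort
#' generator. The defaults encode the qualitative structure the analysis is
#' designed to detect: tau and amyloid burden travel together and both track
#' the white-matter-hyperintensity latent moderately, vessel-wall sclerosis
#' tracks it weakly, and age pulls on everything a little.
#'
#' @return 5x5 correlation matrix with dimnames.
#' @export
default_latent_corr <- function() {
  v <- c("age", "hptau", "abeta", "si", "wmh")
  m <- diag(5)
  dimnames(m) <- list(v, v)
  set <- function(a, b, r) {
    m[a, b] <<- r
    m[b, a] <<- r
  }
  set("age", "hptau", 0.10)
  set("age", "abeta", 0.10)
  set("age", "si", 0.20)
  set("age", "wmh", 0.30)
  set("hptau", "abeta", 0.60)
  set("hptau", "si", 0.10)
  set("hptau", "wmh", 0.45)
  set("abeta", "si", 0.10)
  set("abeta", "wmh", 0.40)
  set("si", "wmh", 0.25)
  m
}

#' Configuration of a synthetic cohort
#'
#' @param n_cases number of cases.
#' @param prop_ad fraction of cases labelled AD; the AD count is
#'   `round(n_cases * prop_ad)` (defaults mirror a 23 AD / 13 control study).
#' @param latent_corr symmetric PSD correlation matrix over
#'   `(age, hptau, abeta, si, wmh)`.
#' @param group_shift named numeric: mean offsets added to the AD group's
#'   latents (controls get zero). Defaults lift tau, amyloid and the WMH
#'   latent in AD while leaving age and vessel sclerosis alone.
#' @param arwmc_cutpoints three strictly increasing thresholds mapping the
#'   WMH latent to the ordinal 0-3 score.
#' @param region_noise SD of the independent Gaussian perturbation applied to
#'   the shared latent to produce each region's latent (0 = all regions equal).
#' @param seed integer seed.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_cases = 36L, prop_ad = 23 / 36,
                          latent_corr = default_latent_corr(),
                          group_shift = c(age = 0, hptau = 1.2, abeta = 1.0,
                                          si = 0, wmh = 0.5),
                          arwmc_cutpoints = c(-0.8, 0.4, 1.4),
                          region_noise = 0.3,
                          seed = 1L) {
  vars <- c("age", "hptau", "abeta", "si", "wmh")
  stopifnot(n_cases >= 1, prop_ad >= 0, prop_ad <= 1, region_noise >= 0)
  if (!is.matrix(latent_corr) || any(dim(latent_corr) != 5L) ||
      !isTRUE(all.equal(latent_corr, t(latent_corr), tolerance = 1e-10)) ||
      any(abs(diag(latent_corr) - 1) > 1e-10)) {
    stop("latent_corr must be a symmetric 5x5 matrix with unit diagonal")
  }
  if (min(eigen(latent_corr, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-8) {
    stop("latent_corr is not positive semidefinite")
  }
  if (length(arwmc_cutpoints) != 3L || any(diff(arwmc_cutpoints) <= 0)) {
    stop("arwmc_cutpoints must be three strictly increasing values")
  }
  if (is.null(dimnames(latent_corr))) dimnames(latent_corr) <- list(vars, vars)
  missing_shift <- setdiff(vars, names(group_shift))
  if (length(missing_shift)) {
    stop("group_shift must name all of: ", paste(vars, collapse = ", "))
  }
  structure(
    list(n_cases = as.integer(n_cases), prop_ad = prop_ad,
         latent_corr = latent_corr, group_shift = group_shift[vars],
         arwmc_cutpoints = arwmc_cutpoints, region_noise = region_noise,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# monotone maps from latent scale to observed scales
.latent_to_pct <- function(z, mu, sigma) pmin(exp(mu + sigma * z), 100)
.latent_to_si <- function(z) 0.2 + 0.4 * stats::pnorm(z)

#' Generate a synthetic cohort table
#'
#' Draws one five-variate latent Gaussian per case (correlation
#' `latent_corr`), adds the AD group shift, then maps latents to observed
#' scales by strictly monotone transforms: age to years (84.4 +/- 7.7),
#' pathology latents to nonnegative percent burdens (lognormal-style),
#' vessel sclerosis to SI in (0.2, 0.6), and the WMH latent through the
#' probit cutpoints to the ordinal 0-3 ARWMC score. Regional values reuse
#' the case latent with small independent regional noise; totals apply the
#' package's own aggregation rules (regional means; parieto-occipital
#' maximum for ARWMC).
#'
#' @param config a [cohort_config()].
#' @return data.frame (class `cohort_table`) with one row per case: `id`,
#'   `group`, `age`, `pmd`, `mmse`, `braak_stage`, `thal_phase`, regional and
#'   total `hptau_*`, `abeta_*`, `si_*`, `arwmc_*` columns. The latent draws
#'   are attached as attribute `latents` for calibration checks.
#' @export
make_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, .make_cohort_impl(config))
}

.make_cohort_impl <- function(config) {
  n <- config$n_cases
  n_ad <- round(n * config$prop_ad)
  group <- c(rep("AD", n_ad), rep("control", n - n_ad))
  z <- MASS::mvrnorm(n, mu = rep(0, 5), Sigma = config$latent_corr)
  if (n == 1L) z <- matrix(z, 1L)
  colnames(z) <- colnames(config$latent_corr)
  shift <- outer(as.numeric(group == "AD"), config$group_shift)
  zs <- z + shift

  regions <- c("frontal", "temporal", "parietal", "occipital")
  tab <- data.frame(
    id = sprintf("case_%03d", seq_len(n)),
    group = group,
    age = round(84.4 + 7.7 * zs[, "age"], 1),
    pmd = round(pmax(stats::rnorm(n, 49, 23), 4), 1),
    mmse = ifelse(group == "AD",
                  pmin(pmax(round(stats::rnorm(n, 4.33, 3.9)), 0), 30),
                  pmin(pmax(round(stats::rnorm(n, 28, 2.09)), 0), 30)),
    braak_stage = ifelse(group == "AD", 6L,
                         sample(0:4, n, replace = TRUE,
                                prob = c(2, 1, 3, 6, 1))),
    thal_phase = ifelse(group == "AD", 5L,
                        sample(0:4, n, replace = TRUE,
                               prob = c(5, 3, 3, 1, 1))),
    stringsAsFactors = FALSE
  )

  rn <- config$region_noise
  att <- sqrt(1 / (1 + rn^2))  # keep regional latents unit-variance
  reg_si <- matrix(NA_real_, n, 4, dimnames = list(NULL, regions))
  reg_hp <- reg_ab <- reg_si
  reg_wm <- matrix(NA_integer_, n, 4, dimnames = list(NULL, regions))
  for (r in regions) {
    zh <- att * (zs[, "hptau"] + stats::rnorm(n, 0, rn))
    za <- att * (zs[, "abeta"] + stats::rnorm(n, 0, rn))
    zv <- att * (zs[, "si"] + stats::rnorm(n, 0, rn))
    zw <- att * (zs[, "wmh"] + stats::rnorm(n, 0, rn))
    reg_hp[, r] <- .latent_to_pct(zh, -1.0, 0.8)
    reg_ab[, r] <- .latent_to_pct(za, -0.7, 0.8)
    reg_si[, r] <- .latent_to_si(zv)
    reg_wm[, r] <- findInterval(zw, config$arwmc_cutpoints)
  }
  for (r in regions) {
    tab[[paste0("hptau_", r)]] <- reg_hp[, r]
    tab[[paste0("abeta_", r)]] <- reg_ab[, r]
    tab[[paste0("si_", r)]] <- reg_si[, r]
    tab[[paste0("arwmc_", r)]] <- reg_wm[, r]
  }
  tab$hptau_total <- rowMeans(reg_hp)
  tab$abeta_total <- rowMeans(reg_ab)
  tab$si_total <- rowMeans(reg_si)
  po <- pmax(reg_wm[, "parietal"], reg_wm[, "occipital"])
  tab$arwmc_parieto_occipital <- po
  tab$arwmc_total <- (reg_wm[, "frontal"] + reg_wm[, "temporal"] + po) / 3

  attr(tab, "latents") <- zs
  class(tab) <- c("cohort_table", "data.frame")
  tab
}
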