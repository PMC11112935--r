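#' Configuration for the synthetic cohort generator
#'
#' Bundles every parameter of the simulated study: the Thomas-type cluster
#' process generating lymphocyte positions, phenotype fractions, the
#' patient-level CCR8+ fraction among Foxp3+ cells (logit-normal across
#' patients), the local-suppression link that depresses GzmB expression in
#' CD8+ T cells near CCR8+ Treg accumulations, and the
#' proportional-hazards model tying progression-free survival to the
#' patient's GzmB/CCR8 ratio. Defaults describe an 81-patient cohort with
#' heterogeneous, clustered infiltration; effect magnitudes are
#' illustrative (see the methods vignette), not estimates.
#'
#' @param n_patients cohort size.
#' @param slide_width_um,slide_height_um slide (tumor mask) extent, um.
#' @param n_clusters mean number of infiltrate clusters per slide
#'   (Poisson).
#' @param cluster_sd_um isotropic Gaussian spread of cells around a
#'   cluster center, um.
#' @param cells_per_cluster mean cells per cluster (Poisson).
#' @param background_intensity uniform background lymphocytes per mm^2.
#' @param frac_cd8,frac_foxp3 phenotype fractions (CD8+, Foxp3+; the rest
#'   are marker-negative lymphocytes); must sum to at most 1.
#' @param frac_ccr8_mean,frac_ccr8_sd location (probability scale) and
#'   logit-scale SD of the patient-level CCR8+ fraction among Foxp3+
#'   cells.
#' @param beta0 baseline GzmB logit for a CD8+ cell with no CCR8+ Treg
#'   neighbors.
#' @param beta1 suppression coefficient (>= 0), per CCR8+ Treg
#'   cells/field of local density.
#' @param suppression_radius_um neighborhood radius for the local Treg
#'   count, um.
#' @param baseline_hazard progression hazard, events/month, at the cohort
#'   mean of the standardized log GzmB/CCR8 ratio.
#' @param log_hr_per_unit log hazard ratio per SD of log GzmB/CCR8 ratio
#'   (negative: a high ratio is protective).
#' @param censor_rate target proportion censored by the independent
#'   exponential censoring process, in `[0, 1)`.
#' @param follow_up_months administrative censoring horizon.
#' @param covariate_prevalence named vector of Bernoulli prevalences for
#'   binary clinicopathological covariates (drawn independently of
#'   everything else).
#' @param seed RNG seed (integer) or `NULL`.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 81,
                       slide_width_um = 4000,
                       slide_height_um = 3000,
                       n_clusters = 30,
                       cluster_sd_um = 80,
                       cells_per_cluster = 60,
                       background_intensity = 40,
                       frac_cd8 = 0.45,
                       frac_foxp3 = 0.25,
                       frac_ccr8_mean = 0.35,
                       frac_ccr8_sd = 0.8,
                       beta0 = 0.5,
                       beta1 = 0.08,
                       suppression_radius_um = 150,
                       baseline_hazard = 0.015,
                       log_hr_per_unit = -0.6,
                       censor_rate = 0.30,
                       follow_up_months = 60,
                       covariate_prevalence = c(
                         sex_male = 0.90,
                         smoking_current_former = 0.96,
                         tumor_location_lower = 0.42,
                         pT_34 = 0.21,
                         pN_positive = 0.23,
                         pStage_II_III = 0.43,
                         lymphatic_invasion = 0.14,
                         vascular_invasion = 0.12,
                         pleural_invasion = 0.14),
                       seed = NULL) {
  cfg <- list(
    n_patients = n_patients, slide_width_um = slide_width_um,
    slide_height_um = slide_height_um, n_clusters = n_clusters,
    cluster_sd_um = cluster_sd_um, cells_per_cluster = cells_per_cluster,
    background_intensity = background_intensity, frac_cd8 = frac_cd8,
    frac_foxp3 = frac_foxp3, frac_ccr8_mean = frac_ccr8_mean,
    frac_ccr8_sd = frac_ccr8_sd, beta0 = beta0, beta1 = beta1,
    suppression_radius_um = suppression_radius_um,
    baseline_hazard = baseline_hazard, log_hr_per_unit = log_hr_per_unit,
    censor_rate = censor_rate, follow_up_months = follow_up_months,
    covariate_prevalence = covariate_prevalence, seed = seed
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  pos <- c("slide_width_um", "slide_height_um", "cluster_sd_um",
           "suppression_radius_um", "baseline_hazard", "follow_up_months")
  for (p in pos) {
    if (!is.numeric(cfg[[p]]) || length(cfg[[p]]) != 1 || cfg[[p]] <= 0) {
      stop("sim_config: ", p, " must be a positive number", call. = FALSE)
    }
  }
  nonneg <- c("n_clusters", "cells_per_cluster", "background_intensity",
              "beta1")
  for (p in nonneg) {
    if (!is.numeric(cfg[[p]]) || cfg[[p]] < 0) {
      stop("sim_config: ", p, " must be non-negative", call. = FALSE)
    }
  }
  fr <- c("frac_cd8", "frac_foxp3", "frac_ccr8_mean", "censor_rate")
  for (p in fr) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      stop("sim_config: ", p, " must lie in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$frac_cd8 + cfg$frac_foxp3 > 1) {
    stop("sim_config: frac_cd8 + frac_foxp3 must be <= 1", call. = FALSE)
  }
  if (cfg$censor_rate >= 1) {
    stop("sim_config: censor_rate must be < 1", call. = FALSE)
  }
  if (cfg$n_patients < 1) stop("sim_config: n_patients must be >= 1",
                               call. = FALSE)
  if (any(cfg$covariate_prevalence < 0 | cfg$covariate_prevalence > 1)) {
    stop("sim_config: covariate prevalences must lie in [0, 1]",
         call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  cohort: %d patients, slide %g x %g um\n", x$n_patients,
              x$slide_width_um, x$slide_height_um))
  cat(sprintf("  clusters: Pois(%g) x Pois(%g) cells, sd %g um, bg %g/mm^2\n",
              x$n_clusters, x$cells_per_cluster, x$cluster_sd_um,
              x$background_intensity))
  cat(sprintf("  phenotypes: CD8 %.2f, Foxp3 %.2f, CCR8|Foxp3 ~ logitN(%.2f, %.2f)\n",
              x$frac_cd8, x$frac_foxp3, x$frac_ccr8_mean, x$frac_ccr8_sd))
  cat(sprintf("  suppression: logit(GzmB) = %.2f - %.3f x (Treg cells/field within %g um)\n",
              x$beta0, x$beta1, x$suppression_radius_um))
  cat(sprintf("  survival: h0 %.4f/mo, logHR/SD %.2f, censor %.2f, follow-up %g mo\n",
              x$baseline_hazard, x$log_hr_per_unit, x$censor_rate,
              x$follow_up_months))
  invisible(x)
}
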