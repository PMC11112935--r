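# Synthetic cohort generator: a marked Thomas-type cluster process for
# lymphocyte positions, a logistic local-suppression link for GzmB
# expression, and an exponential proportional-hazards model for
# progression-free survival driven by the patient's GzmB/CCR8 ratio.

#' Simulate one patient's pair of stained slides
#'
#' Lymphocyte positions follow a Thomas-type cluster process (Poisson
#' number of uniformly placed cluster centers, Poisson offspring with
#' isotropic Gaussian spread) plus uniform background; offspring falling
#' outside the tumor mask are discarded. Each cell receives one phenotype
#' (CD8+, Foxp3+, or marker-negative). The two stain panels are
#' independent realizations of the same process in one shared coordinate
#' frame, mimicking serially sectioned tissue: regional densities
#' correspond across panels, individual cells do not. Foxp3+ cells on
#' panel A are CCR8+ with the patient's drawn fraction; GzmB on panel B
#' follows [assign_gzmb()] against panel A's CCR8+ Tregs.
#'
#' @param config a [sim_config()].
#' @param patient_seed optional integer seed fixing this slide's draws.
#' @param patient_id,slide_id identifiers stamped on the tables.
#' @param frac_ccr8 optional fixed CCR8+ fraction among Foxp3+ cells;
#'   drawn logit-normal from `config` when `NULL`.
#' @return list with `panel_a`, `panel_b` ([panel_table()]s), `mask`
#'   ([tumor_mask()]) and the realized `frac_ccr8`.
#' @export
simulate_slide <- function(config, patient_seed = NULL,
                           patient_id = "patient1", slide_id = NULL,
                           frac_ccr8 = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(patient_seed)) set.seed(patient_seed)
  if (is.null(slide_id)) slide_id <- paste0(patient_id, "_s1")
  w <- config$slide_width_um
  h <- config$slide_height_um
  mask <- tumor_mask(rect_poly(w, h))
  if (is.null(frac_ccr8)) {
    frac_ccr8 <- stats::plogis(stats::rnorm(
      1, stats::qlogis(config$frac_ccr8_mean), config$frac_ccr8_sd))
  }

  # Shared cluster parents across the two panels (serial sections of one
  # tissue): regional infiltrate structure corresponds, individual cells
  # are independent redraws.
  n_par <- stats::rpois(1, config$n_clusters)
  parents <- cbind(stats::runif(n_par, 0, w), stats::runif(n_par, 0, h))
  a <- sim_lymphocytes(config, parents)
  b <- sim_lymphocytes(config, parents)

  cells_a <- data.frame(
    cell_id = sprintf("%s_A_%05d", slide_id, seq_len(nrow(a))),
    x_um = a$x, y_um = a$y,
    CCR8 = a$class == "foxp3" &
      stats::runif(nrow(a)) < frac_ccr8,
    FOXP3 = a$class == "foxp3",
    stringsAsFactors = FALSE)
  cells_b <- data.frame(
    cell_id = sprintf("%s_B_%05d", slide_id, seq_len(nrow(b))),
    x_um = b$x, y_um = b$y,
    CD8 = b$class == "cd8",
    GZMB = rep(FALSE, nrow(b)),
    stringsAsFactors = FALSE)

  treg <- cells_a[cells_a$CCR8 & cells_a$FOXP3, c("x_um", "y_um")]
  is_cd8 <- which(cells_b$CD8)
  if (length(is_cd8) > 0) {
    cells_b$GZMB[is_cd8] <- assign_gzmb(
      cells_b[is_cd8, c("x_um", "y_um")], treg,
      beta0 = config$beta0, beta1 = config$beta1,
      radius_um = config$suppression_radius_um)
  }

  pa <- panel_table(cells_a, PANEL_A, slide_id, patient_id)
  pb <- panel_table(cells_b, PANEL_B, slide_id, patient_id)
  attr(pa, "bbox") <- attr(pb, "bbox") <- mask_bbox(mask)
  list(panel_a = pa, panel_b = pb, mask = mask, frac_ccr8 = frac_ccr8)
}

rect_poly <- function(w, h) {
  matrix(c(0, 0, w, 0, w, h, 0, h), ncol = 2, byrow = TRUE)
}

# One realization of offspring + background around given cluster parents,
# with phenotype classes attached. Returns data.frame(x, y, class).
sim_lymphocytes <- function(config, parents) {
  w <- config$slide_width_um
  h <- config$slide_height_um
  xs <- ys <- numeric(0)
  if (nrow(parents) > 0) {
    n_off <- stats::rpois(nrow(parents), config$cells_per_cluster)
    xs <- rep(parents[, 1], n_off) +
      stats::rnorm(sum(n_off), 0, config$cluster_sd_um)
    ys <- rep(parents[, 2], n_off) +
      stats::rnorm(sum(n_off), 0, config$cluster_sd_um)
  }
  n_bg <- stats::rpois(1, config$background_intensity * w * h / 1e6)
  xs <- c(xs, stats::runif(n_bg, 0, w))
  ys <- c(ys, stats::runif(n_bg, 0, h))
  keep <- xs >= 0 & xs <= w & ys >= 0 & ys <= h
  xs <- xs[keep]
  ys <- ys[keep]
  u <- stats::runif(length(xs))
  cls <- ifelse(u < config$frac_cd8, "cd8",
                ifelse(u < config$frac_cd8 + config$frac_foxp3, "foxp3",
                       "other"))
  data.frame(x = xs, y = ys, class = cls, stringsAsFactors = FALSE)
}

#' Assign GzmB positivity to CD8+ cells under local Treg suppression
#'
#' For each CD8+ cell, `P(GzmB+) = plogis(beta0 - beta1 * d)` where `d` is
#' the number of CCR8+ Treg cells within `radius_um`, rescaled to
#' cells/field units (field area 0.0972 mm^2), so `beta1` is comparable
#' across neighborhood radii.
#'
#' @param cd8_cells,ccr8_treg_cells data.frames with `x_um`, `y_um`.
#' @param beta0 baseline logit.
#' @param beta1 suppression slope (>= 0), per cells/field.
#' @param radius_um neighborhood radius (> 0).
#' @param seed optional seed for the Bernoulli draws.
#' @return logical vector of GzmB flags, one per CD8+ cell (empty input
#'   gives an empty vector). The local densities used are attached as the
#'   `density_cells_per_field` attribute.
#' @export
assign_gzmb <- function(cd8_cells, ccr8_treg_cells, beta0, beta1,
                        radius_um, seed = NULL) {
  if (radius_um <= 0) stop("radius_um must be > 0", call. = FALSE)
  if (beta1 < 0) stop("beta1 must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cd8_cells)
  if (n == 0) return(logical(0))
  cnt <- neighbor_counts(cd8_cells$x_um, cd8_cells$y_um,
                         ccr8_treg_cells$x_um, ccr8_treg_cells$y_um,
                         radius_um)
  circle_mm2 <- pi * (radius_um / 1000)^2
  d <- cnt * FIELD_AREA_MM2 / circle_mm2
  lin <- beta0 - ifelse(d == 0, 0, beta1 * d) # beta1 = Inf with d = 0 stays at beta0
  flags <- stats::runif(n) < stats::plogis(lin)
  attr(flags, "density_cells_per_field") <- d
  flags
}

# Number of (rx, ry) points within `radius` of each (px, py), chunked to
# bound the distance-matrix memory.
neighbor_counts <- function(px, py, rx, ry, radius, chunk = 2000L) {
  n <- length(px)
  if (length(rx) == 0) return(integer(n))
  r2 <- radius^2
  out <- integer(n)
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    dx <- outer(px[s:e], rx, "-")
    dy <- outer(py[s:e], ry, "-")
    out[s:e] <- rowSums(dx * dx + dy * dy <= r2)
  }
  out
}

#' Simulate a full cohort: slides, ROI analysis and clinical outcomes
#'
#' Per patient, a slide pair is generated with [simulate_slide()], the
#' region-of-interest protocol (Hot/Cold-Spot selection with the
#' parameters in `roi`) is run to obtain the GzmB/CCR8 ratio, and a
#' progression time is drawn from an exponential proportional-hazards
#' model whose linear predictor is `log_hr_per_unit` times the
#' cohort-standardized log ratio. Censoring combines an independent
#' exponential process calibrated to `censor_rate` with administrative
#' censoring at `follow_up_months`. Binary clinicopathological covariates
#' are drawn independently of everything else.
#'
#' @param config a [sim_config()].
#' @param roi ROI-protocol parameters, see [roi_params()].
#' @return list with `slides` (named list of [simulate_slide()] outputs),
#'   `clinical` (data.frame: `patient_id`, `pfs_months`, `event`,
#'   covariates), `summaries` (per-patient ROI+WTA summary, see
#'   [patient_roi_summary()]), `fields` (per-field metrics across the
#'   cohort) and `config`.
#' @export
simulate_cohort <- function(config, roi = roi_params()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  ids <- sprintf("P%03d", seq_len(config$n_patients))

  slides <- vector("list", config$n_patients)
  names(slides) <- ids
  summaries <- vector("list", config$n_patients)
  fields <- vector("list", config$n_patients)
  for (i in seq_along(ids)) {
    sl <- simulate_slide(config, patient_id = ids[i])
    an <- analyze_patient(sl$panel_a, sl$panel_b, sl$mask, roi)
    slides[[i]] <- sl
    summaries[[i]] <- an$summary
    fields[[i]] <- an$fields
  }
  summaries <- do.call(rbind, summaries)
  fields <- do.call(rbind, fields)

  ratio <- summaries$gzmb_ccr8_ratio
  z <- rep(0, length(ratio))
  ok <- is.finite(ratio) & ratio > 0
  if (sum(ok) >= 2 && stats::sd(log(ratio[ok])) > 0) {
    z[ok] <- scale(log(ratio[ok]))[, 1]
  }
  lp <- config$log_hr_per_unit * z
  t_event <- stats::rexp(length(z), rate = config$baseline_hazard * exp(lp))
  if (config$censor_rate > 0) {
    cens_rate <- config$baseline_hazard *
      config$censor_rate / (1 - config$censor_rate)
    t_cens <- stats::rexp(length(z), rate = cens_rate)
  } else {
    t_cens <- rep(Inf, length(z))
  }
  horizon <- pmin(t_cens, config$follow_up_months)
  pfs <- pmin(t_event, horizon)
  event <- as.integer(t_event <= horizon)

  clinical <- data.frame(patient_id = ids, pfs_months = pfs, event = event,
                         stringsAsFactors = FALSE)
  for (v in names(config$covariate_prevalence)) {
    clinical[[v]] <- stats::rbinom(length(ids), 1,
                                   config$covariate_prevalence[[v]])
  }

  list(slides = slides, clinical = clinical, summaries = summaries,
       fields = fields, config = config)
}
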