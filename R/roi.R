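# Region-of-interest (ROI) protocol: box-count density maps on a stride
# grid of 360 x 270 um candidate fields, greedy Hot/Cold-Spot selection,
# per-field immune metrics and the per-patient summary including the
# GzmB/CCR8 ratio.

#' ROI-protocol parameters
#'
#' @param field_w_um,field_h_um analysis field size (um). The 360 x 270 um
#'   default is the size of one high-power microscope field.
#' @param stride_um candidate-grid stride (um); default one quarter of the
#'   field width so neighbouring candidates overlap by 3/4.
#' @param k_hot,k_cold number of Hot and Cold Spots to select per slide.
#' @param min_lymph Cold-Spot lymphocyte floor: a candidate field is
#'   excluded when it has fewer than `min_lymph` CD8+ cells AND fewer than
#'   `min_lymph` Foxp3+ cells (an "area with no lymphocytes").
#' @param allow_overlap if `TRUE`, selected fields may overlap (plain
#'   top-k); the default forbids overlap so one dense cluster cannot
#'   occupy all five spots.
#' @return list of class `roi_params`.
#' @export
roi_params <- function(field_w_um = FIELD_W_UM, field_h_um = FIELD_H_UM,
                       stride_um = 90, k_hot = 5, k_cold = 5,
                       min_lymph = 10, allow_overlap = FALSE) {
  stopifnot(field_w_um > 0, field_h_um > 0, stride_um > 0,
            k_hot >= 1, k_cold >= 0, min_lymph >= 0)
  structure(list(field_w_um = field_w_um, field_h_um = field_h_um,
                 stride_um = stride_um, k_hot = k_hot, k_cold = k_cold,
                 min_lymph = min_lymph, allow_overlap = allow_overlap),
            class = "roi_params")
}

# Built-in marker predicates on a panel's cell data.frame.
marker_predicate <- function(predicate) {
  if (is.function(predicate)) return(predicate)
  switch(predicate,
    ccr8_treg = function(cells) cells$CCR8 & cells$FOXP3,
    foxp3 = function(cells) cells$FOXP3,
    cd8 = function(cells) cells$CD8,
    gzmb_cd8 = function(cells) cells$CD8 & cells$GZMB,
    stop("unknown marker predicate: ", predicate, call. = FALSE)
  )
}

#' Box-count density map over a candidate field grid
#'
#' Enumerates candidate fields of size `field_w_um` x `field_h_um` on a
#' stride grid covering the bounding box, and counts the cells satisfying
#' `predicate` inside each half-open field extent
#' `[x0, x0 + w) x [y0, y0 + h)`. Pure box counts - no kernel smoothing.
#'
#' @param table a [panel_table()].
#' @param predicate `"ccr8_treg"`, `"foxp3"`, `"cd8"`, `"gzmb_cd8"`, or a
#'   function of the cell data.frame returning a logical vector.
#' @param field_w_um,field_h_um field size (um).
#' @param stride_um grid stride (um), > 0.
#' @param bbox numeric `c(xmin, ymin, xmax, ymax)`; defaults to the
#'   table's `bbox` attribute (set by [filter_to_tumor()] and the
#'   simulator), falling back to the cells' bounding box.
#' @return data.frame of class `density_map` with columns `x0_um`,
#'   `y0_um`, `count`, ordered by `y0_um` then `x0_um`; field geometry is
#'   attached as attributes.
#' @export
density_map <- function(table, predicate, field_w_um = FIELD_W_UM,
                        field_h_um = FIELD_H_UM, stride_um = 90,
                        bbox = NULL) {
  stopifnot(inherits(table, "panel_table"), stride_um > 0)
  if (is.null(bbox)) bbox <- attr(table, "bbox")
  if (is.null(bbox)) {
    if (n_cells(table) == 0) {
      stop("no bbox available: empty table without a bbox attribute",
           call. = FALSE)
    }
    bbox <- c(min(table$cells$x_um), min(table$cells$y_um),
              max(table$cells$x_um), max(table$cells$y_um))
  }
  bw <- bbox[3] - bbox[1]
  bh <- bbox[4] - bbox[2]
  if (field_w_um > bw || field_h_um > bh) {
    stop("analysis field exceeds the slide bounding box", call. = FALSE)
  }
  nx <- floor((bw - field_w_um) / stride_um) + 1
  ny <- floor((bh - field_h_um) / stride_um) + 1

  pred <- marker_predicate(predicate)
  keep <- if (n_cells(table) > 0) pred(table$cells) else logical(0)
  xs <- table$cells$x_um[keep]
  ys <- table$cells$y_um[keep]

  counts <- integer(nx * ny)
  if (length(xs) > 0) {
    # a cell at x lies in fields with index i s.t. x0 <= x < x0 + w,
    # x0 = xmin + i * stride  =>  (x - xmin - w)/s < i <= (x - xmin)/s
    i_min <- pmax(0, floor((xs - bbox[1] - field_w_um) / stride_um) + 1)
    i_max <- pmin(nx - 1, floor((xs - bbox[1]) / stride_um))
    j_min <- pmax(0, floor((ys - bbox[2] - field_h_um) / stride_um) + 1)
    j_max <- pmin(ny - 1, floor((ys - bbox[2]) / stride_um))
    ok <- i_min <= i_max & j_min <= j_max
    if (any(ok)) {
      ni <- i_max[ok] - i_min[ok] + 1
      nj <- j_max[ok] - j_min[ok] + 1
      # expand i ranges per cell, then cross with that cell's j range
      ii <- sequence(ni) - 1L + rep(i_min[ok], ni)
      cell_of_i <- rep(seq_along(ni), ni)
      nj_i <- nj[cell_of_i]
      jj <- sequence(nj_i) - 1L + rep(j_min[ok][cell_of_i], nj_i)
      ii <- rep(ii, nj_i)
      counts <- tabulate(jj * nx + ii + 1L, nbins = nx * ny)
    }
  }
  grid <- expand.grid(x0_um = bbox[1] + (seq_len(nx) - 1) * stride_um,
                      y0_um = bbox[2] + (seq_len(ny) - 1) * stride_um)
  out <- data.frame(x0_um = grid$x0_um, y0_um = grid$y0_um, count = counts)
  structure(out, class = c("density_map", "data.frame"),
            field_w_um = field_w_um, field_h_um = field_h_um,
            stride_um = stride_um, bbox = bbox, nx = nx, ny = ny,
            predicate = if (is.character(predicate)) predicate else "custom")
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$x0_um, b$x0_um)) &&
    isTRUE(all.equal(a$y0_um, b$y0_um)) &&
    identical(attr(a, "field_w_um"), attr(b, "field_w_um")) &&
    identical(attr(a, "field_h_um"), attr(b, "field_h_um"))
}

# Greedy non-overlapping selection shared by Hot and Cold Spots: scan
# candidates in `ord`, keep a candidate unless it overlaps an already
# selected field or a field in `avoid` (equal-sized axis-aligned fields
# overlap iff both |dx| < w and |dy| < h).
greedy_select <- function(map, ord, k, allow_overlap, avoid = NULL) {
  w <- attr(map, "field_w_um")
  h <- attr(map, "field_h_um")
  ax <- if (is.null(avoid)) numeric(0) else avoid$x0_um
  ay <- if (is.null(avoid)) numeric(0) else avoid$y0_um
  sel <- integer(0)
  for (cand in ord) {
    if (length(sel) >= k) break
    if (length(ax) > 0 &&
        any(abs(ax - map$x0_um[cand]) < w &
              abs(ay - map$y0_um[cand]) < h)) next
    if (!allow_overlap && length(sel) > 0) {
      dx <- abs(map$x0_um[sel] - map$x0_um[cand])
      dy <- abs(map$y0_um[sel] - map$y0_um[cand])
      if (any(dx < w & dy < h)) next
    }
    sel <- c(sel, cand)
  }
  data.frame(x0_um = map$x0_um[sel], y0_um = map$y0_um[sel],
             width_um = rep(w, length(sel)), height_um = rep(h, length(sel)),
             count = map$count[sel])
}

#' Select Hot Spots from a CCR8+ Treg density map
#'
#' Greedy maximal selection: repeatedly take the highest-count candidate
#' field that does not overlap any already-selected field, until `k`
#' fields are chosen or the candidates are exhausted. Ties are broken by
#' (count descending, y0 ascending, x0 ascending), so the selection is
#' fully determined by the map, not by enumeration order.
#'
#' @param map a [density_map()] computed with the `"ccr8_treg"` predicate.
#' @param k number of fields (default 5).
#' @param allow_overlap permit overlapping selections (plain top-k).
#' @return data.frame of selected fields (`x0_um`, `y0_um`, `width_um`,
#'   `height_um`, `count`); fewer than `k` rows, with a warning, when
#'   candidates run out.
#' @export
select_hot_spots <- function(map, k = 5, allow_overlap = FALSE) {
  stopifnot(inherits(map, "density_map"))
  if (nrow(map) == 0) {
    warning("empty candidate set: no Hot Spots selected", call. = FALSE)
    return(greedy_select(map, integer(0), 0, allow_overlap))
  }
  ord <- order(-map$count, map$y0_um, map$x0_um)
  out <- greedy_select(map, ord, k, allow_overlap)
  if (nrow(out) < k) {
    warning(sprintf("only %d of %d Hot Spots available", nrow(out), k),
            call. = FALSE)
  }
  attr(out, "spot_class") <- "HOT"
  out
}

#' Select Cold Spots: low-Treg fields that still contain lymphocytes
#'
#' A candidate field is eligible unless it has fewer than `min_lymph` CD8+
#' cells AND fewer than `min_lymph` Foxp3+ cells (one stain clearing the
#' floor suffices). Among eligible candidates the `k` lowest CCR8+ Treg
#' counts are selected greedily without overlap, ties broken by (count
#' ascending, y0 ascending, x0 ascending).
#'
#' @param map_ccr8_treg,map_cd8,map_foxp3 [density_map()]s on one common
#'   candidate grid (CCR8+Foxp3+ from panel A; CD8+ from panel B; Foxp3+
#'   from panel A).
#' @param k number of fields (default 5).
#' @param min_lymph lymphocyte floor (default 10 cells).
#' @param allow_overlap permit overlapping selections.
#' @param avoid optional data.frame of already-selected fields (the Hot
#'   Spots) that Cold Spots must not overlap: a field cannot represent
#'   both a high- and a low-density region of the same slide.
#' @return data.frame of selected fields as in [select_hot_spots()];
#'   possibly empty, with a warning, if no field is eligible.
#' @export
select_cold_spots <- function(map_ccr8_treg, map_cd8, map_foxp3, k = 5,
                              min_lymph = 10, allow_overlap = FALSE,
                              avoid = NULL) {
  stopifnot(inherits(map_ccr8_treg, "density_map"))
  if (!same_grid(map_ccr8_treg, map_cd8) ||
      !same_grid(map_ccr8_treg, map_foxp3)) {
    stop("the three density maps must share one candidate grid",
         call. = FALSE)
  }
  eligible <- !(map_cd8$count < min_lymph & map_foxp3$count < min_lymph)
  if (!any(eligible)) {
    warning("no eligible Cold-Spot candidates (all fields lymphocyte-poor)",
            call. = FALSE)
    out <- greedy_select(map_ccr8_treg, integer(0), 0, allow_overlap)
    attr(out, "spot_class") <- "COLD"
    return(out)
  }
  idx <- which(eligible)
  ord <- idx[order(map_ccr8_treg$count[idx], map_ccr8_treg$y0_um[idx],
                   map_ccr8_treg$x0_um[idx])]
  out <- greedy_select(map_ccr8_treg, ord, k, allow_overlap, avoid = avoid)
  if (nrow(out) < k) {
    warning(sprintf("only %d of %d Cold Spots available", nrow(out), k),
            call. = FALSE)
  }
  attr(out, "spot_class") <- "COLD"
  out
}

#' Immune metrics of matched fields across both stain panels
#'
#' Counts CCR8+Foxp3+, Foxp3+, CD8+ and GzmB+CD8+ cells inside each
#' field's half-open extent on the two co-registered panels, and derives
#' `%GzmB+ in CD8+ T` (NA when the field has no CD8+ cell).
#'
#' @param fields data.frame of fields (`x0_um`, `y0_um`, `width_um`,
#'   `height_um`), e.g. from [select_hot_spots()].
#' @param panel_a,panel_b the patient's two [panel_table()]s; their
#'   `frame` tags must match.
#' @param spot_class label stored in the result (defaults to the fields'
#'   `spot_class` attribute).
#' @return data.frame with one row per field: `patient_id`, `spot_class`,
#'   `x0_um`, `y0_um`, `ccr8_treg_count`, `foxp3_count`, `cd8_count`,
#'   `gzmb_cd8_count`, `pct_gzmb_in_cd8`.
#' @export
field_metrics <- function(fields, panel_a, panel_b, spot_class = NULL) {
  stopifnot(inherits(panel_a, "panel_table"),
            inherits(panel_b, "panel_table"))
  if (!identical(panel_a$frame, panel_b$frame)) {
    stop("panel frames differ; fields cannot be matched across panels",
         call. = FALSE)
  }
  if (is.null(spot_class)) {
    spot_class <- attr(fields, "spot_class")
    if (is.null(spot_class)) spot_class <- NA_character_
  }
  a <- panel_a$cells
  b <- panel_b$cells
  n <- nrow(fields)
  res <- data.frame(
    patient_id = rep(panel_a$patient_id, n),
    spot_class = rep(spot_class, n),
    x0_um = fields$x0_um, y0_um = fields$y0_um,
    ccr8_treg_count = integer(n), foxp3_count = integer(n),
    cd8_count = integer(n), gzmb_cd8_count = integer(n),
    pct_gzmb_in_cd8 = rep(NA_real_, n),
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    in_a <- in_field(a, fields$x0_um[i], fields$y0_um[i],
                     fields$width_um[i], fields$height_um[i])
    in_b <- in_field(b, fields$x0_um[i], fields$y0_um[i],
                     fields$width_um[i], fields$height_um[i])
    res$ccr8_treg_count[i] <- sum(a$CCR8[in_a] & a$FOXP3[in_a])
    res$foxp3_count[i] <- sum(a$FOXP3[in_a])
    res$cd8_count[i] <- sum(b$CD8[in_b])
    res$gzmb_cd8_count[i] <- sum(b$CD8[in_b] & b$GZMB[in_b])
    if (res$cd8_count[i] > 0) {
      res$pct_gzmb_in_cd8[i] <- 100 * res$gzmb_cd8_count[i] /
        res$cd8_count[i]
    }
  }
  res
}

in_field <- function(cells, x0, y0, w, h) {
  which(cells$x_um >= x0 & cells$x_um < x0 + w &
          cells$y_um >= y0 & cells$y_um < y0 + h)
}

#' Per-patient summary of the ROI protocol
#'
#' Unweighted means of the field metrics over the selected Hot Spots (and
#' Cold Spots when available); fields with undefined `%GzmB+` (no CD8+
#' cell) are excluded from the percentage mean. The patient's composite
#' scores are ratios of Hot-Spot means: `gzmb_ccr8_ratio = hot mean %GzmB+
#' / hot mean CCR8+ Treg count`, and the alternative CD8/Foxp3,
#' GzmB/Foxp3 and CD8/CCR8 ratios built the same way. A ratio is `NA`
#' exactly when its denominator mean is zero; such patients are excluded
#' from groupings on that ratio but stay in the cohort.
#'
#' @param hot [field_metrics()] rows of the Hot Spots (>= 1 row).
#' @param cold optional [field_metrics()] rows of the Cold Spots.
#' @param wta optional [wta_metrics()] row, appended with `wta_` prefix.
#' @param patient_id identifier (defaults to the one in `hot`).
#' @return one-row data.frame.
#' @export
patient_roi_summary <- function(hot, cold = NULL, wta = NULL,
                                patient_id = NULL) {
  if (is.null(hot) || nrow(hot) == 0) {
    stop("patient has no Hot Spots; cannot summarize", call. = FALSE)
  }
  if (is.null(patient_id)) patient_id <- hot$patient_id[1]
  mean_pct <- function(x) {
    def <- !is.na(x)
    if (!all(def)) {
      message(sum(!def), " field(s) with undefined %GzmB excluded from mean")
    }
    if (any(def)) mean(x[def]) else NA_real_
  }
  out <- data.frame(
    patient_id = patient_id,
    n_hot = nrow(hot),
    n_cold = if (is.null(cold)) 0L else nrow(cold),
    hot_mean_ccr8_treg = mean(hot$ccr8_treg_count),
    hot_mean_foxp3 = mean(hot$foxp3_count),
    hot_mean_cd8 = mean(hot$cd8_count),
    hot_mean_gzmb_cd8 = mean(hot$gzmb_cd8_count),
    hot_mean_pct_gzmb = mean_pct(hot$pct_gzmb_in_cd8),
    stringsAsFactors = FALSE)
  if (!is.null(cold) && nrow(cold) > 0) {
    out$cold_mean_ccr8_treg <- mean(cold$ccr8_treg_count)
    out$cold_mean_foxp3 <- mean(cold$foxp3_count)
    out$cold_mean_cd8 <- mean(cold$cd8_count)
    out$cold_mean_gzmb_cd8 <- mean(cold$gzmb_cd8_count)
    out$cold_mean_pct_gzmb <- mean_pct(cold$pct_gzmb_in_cd8)
  } else {
    out$cold_mean_ccr8_treg <- out$cold_mean_foxp3 <- out$cold_mean_cd8 <-
      out$cold_mean_gzmb_cd8 <- out$cold_mean_pct_gzmb <- NA_real_
  }
  safe_ratio <- function(num, den) {
    if (is.na(den) || den == 0 || is.na(num)) NA_real_ else num / den
  }
  out$gzmb_ccr8_ratio <- safe_ratio(out$hot_mean_pct_gzmb,
                                    out$hot_mean_ccr8_treg)
  out$cd8_foxp3_ratio <- safe_ratio(out$hot_mean_cd8, out$hot_mean_foxp3)
  out$gzmb_foxp3_ratio <- safe_ratio(out$hot_mean_pct_gzmb,
                                     out$hot_mean_foxp3)
  out$cd8_ccr8_ratio <- safe_ratio(out$hot_mean_cd8,
                                   out$hot_mean_ccr8_treg)
  if (!is.null(wta)) {
    w <- as.data.frame(wta)
    names(w) <- paste0("wta_", names(w))
    out <- cbind(out, w)
  }
  out
}

#' Run the full WTA + ROI analysis for one patient
#'
#' Restricts both panels to the tumor mask, computes WTA densities, builds
#' the CCR8+ Treg, CD8 and Foxp3 density maps on one candidate grid,
#' selects Hot and Cold Spots, measures the matched fields on both panels
#' and assembles the patient summary.
#'
#' @param panel_a,panel_b the patient's [panel_table()]s.
#' @param mask the patient's [tumor_mask()].
#' @param params [roi_params()].
#' @return list with elements `wta`, `hot`, `cold` (selected fields),
#'   `fields` (field metrics, HOT and COLD rows) and `summary`.
#' @export
analyze_patient <- function(panel_a, panel_b, mask, params = roi_params()) {
  stopifnot(inherits(params, "roi_params"))
  pa <- filter_to_tumor(panel_a, mask)
  pb <- filter_to_tumor(panel_b, mask)
  wta <- wta_metrics(pa, pb, mask)
  bbox <- mask_bbox(mask)
  dm <- function(tab, pred) {
    density_map(tab, pred, field_w_um = params$field_w_um,
                field_h_um = params$field_h_um,
                stride_um = params$stride_um, bbox = bbox)
  }
  map_treg <- dm(pa, "ccr8_treg")
  map_foxp3 <- dm(pa, "foxp3")
  map_cd8 <- dm(pb, "cd8")
  hot <- select_hot_spots(map_treg, k = params$k_hot,
                          allow_overlap = params$allow_overlap)
  cold <- select_cold_spots(map_treg, map_cd8, map_foxp3,
                            k = params$k_cold,
                            min_lymph = params$min_lymph,
                            allow_overlap = params$allow_overlap,
                            avoid = hot)
  fm_hot <- field_metrics(hot, pa, pb, spot_class = "HOT")
  fm_cold <- field_metrics(cold, pa, pb, spot_class = "COLD")
  fields <- rbind(fm_hot, fm_cold)
  summary <- patient_roi_summary(fm_hot,
                                 cold = if (nrow(fm_cold) > 0) fm_cold,
                                 wta = wta)
  list(wta = wta, hot = hot, cold = cold, fields = fields,
       summary = summary, maps = list(ccr8_treg = map_treg,
                                      foxp3 = map_foxp3, cd8 = map_cd8))
}
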