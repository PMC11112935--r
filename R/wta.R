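#' Whole-tumor-area (WTA) metrics for one patient
#'
#' Computes, over the entire tumor mask, the densities
#' `[CCR8+ Treg] = CCR8+Foxp3+ cells/mm^2`, `[Total Foxp3+] = Foxp3+
#' cells/mm^2`, `[Total CD8+ T] = CD8+ cells/mm^2`, `[GzmB+ CD8+ T] =
#' GzmB+CD8+ cells/mm^2`, and `[%GzmB+ in CD8+ T] = 100 x GzmB+CD8+ /
#' CD8+`. Foxp3+CCR8- cells count toward the total-Foxp3 density only;
#' CCR8+Foxp3- cells count toward neither Treg metric. The percentage is
#' `NA` exactly when no CD8+ cell is present.
#'
#' @param panel_a CCR8/Foxp3 [panel_table()], already restricted to the
#'   tumor mask (see [filter_to_tumor()]).
#' @param panel_b CD8/GzmB [panel_table()], likewise restricted.
#' @param mask the [tumor_mask()] whose area is the denominator.
#' @return one-row data.frame of class `wta_metrics` with columns
#'   `ccr8_treg_per_mm2`, `foxp3_per_mm2`, `cd8_per_mm2`,
#'   `gzmb_cd8_per_mm2`, `pct_gzmb_in_cd8`, `area_mm2`.
#' @export
wta_metrics <- function(panel_a, panel_b, mask) {
  stopifnot(inherits(panel_a, "panel_table"),
            inherits(panel_b, "panel_table"),
            inherits(mask, "tumor_mask"))
  if (panel_a$panel != PANEL_A || panel_b$panel != PANEL_B) {
    stop("wta_metrics expects panel A (CCR8/Foxp3) then panel B (CD8/GzmB)",
         call. = FALSE)
  }
  if (!identical(panel_a$frame, panel_b$frame)) {
    stop("panel frames differ; panels are not co-registered", call. = FALSE)
  }
  area <- mask$area_mm2
  if (!is.finite(area) || area <= 0) {
    stop("tumor mask area must be positive", call. = FALSE)
  }
  a <- panel_a$cells
  b <- panel_b$cells
  n_treg <- sum(a$CCR8 & a$FOXP3)
  n_foxp3 <- sum(a$FOXP3)
  n_cd8 <- sum(b$CD8)
  n_gzmb_cd8 <- sum(b$CD8 & b$GZMB)
  out <- data.frame(
    ccr8_treg_per_mm2 = n_treg / area,
    foxp3_per_mm2 = n_foxp3 / area,
    cd8_per_mm2 = n_cd8 / area,
    gzmb_cd8_per_mm2 = n_gzmb_cd8 / area,
    pct_gzmb_in_cd8 = if (n_cd8 > 0) 100 * n_gzmb_cd8 / n_cd8 else NA_real_,
    area_mm2 = area
  )
  class(out) <- c("wta_metrics", class(out))
  out
}
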