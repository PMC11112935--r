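# Shared fixtures: scaled-down simulator configurations and hand-built
# tables used across the test files.

# Scaled-down study conditions used for replicate-heavy checks: same
# 81-patient cohort structure and analysis grid, smaller slides.
small_sim_config <- function(seed, ...) {
  args <- list(slide_width_um = 1600, slide_height_um = 1200,
               n_clusters = 8, cells_per_cluster = 35,
               background_intensity = 25, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

# A panel table built from explicit coordinates and marker flags.
make_panel <- function(panel, x, y, m1, m2, patient_id = "p1") {
  markers <- tilspot:::panel_markers(panel)
  cells <- data.frame(cell_id = sprintf("c%04d", seq_along(x)),
                      x_um = x, y_um = y)
  cells[[markers[1]]] <- m1
  cells[[markers[2]]] <- m2
  panel_table(cells, panel, slide_id = paste0(patient_id, "_s1"),
              patient_id = patient_id)
}

rect_mask <- function(w, h, x0 = 0, y0 = 0) {
  tumor_mask(matrix(c(x0, y0, x0 + w, y0, x0 + w, y0 + h, x0, y0 + h),
                    ncol = 2, byrow = TRUE))
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
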