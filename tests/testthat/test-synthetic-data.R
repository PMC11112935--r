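test_that("degenerate process yields empty panels", {
  cfg <- small_sim_config(1, n_clusters = 0, background_intensity = 0)
  sl <- simulate_slide(cfg, patient_seed = 1)
  expect_equal(n_cells(sl$panel_a), 0L)
  expect_equal(n_cells(sl$panel_b), 0L)
})

test_that("fixed seeds reproduce slides and cohorts exactly", {
  cfg <- small_sim_config(123)
  s1 <- simulate_slide(cfg, patient_seed = 5)
  s2 <- simulate_slide(cfg, patient_seed = 5)
  expect_identical(s1$panel_a$cells, s2$panel_a$cells)
  expect_identical(s1$panel_b$cells, s2$panel_b$cells)

  c1 <- quiet(simulate_cohort(small_sim_config(9, n_patients = 5)))
  c2 <- quiet(simulate_cohort(small_sim_config(9, n_patients = 5)))
  expect_identical(c1$clinical, c2$clinical)
  expect_identical(c1$summaries, c2$summaries)
})

test_that("mean cell count matches the cluster-process intensity", {
  cfg <- sim_config(n_clusters = 20, cells_per_cluster = 50,
                    background_intensity = 5, seed = 1)
  area <- cfg$slide_width_um * cfg$slide_height_um / 1e6
  expected <- 20 * 50 + 5 * area
  counts <- vapply(1:10, function(i)
    n_cells(simulate_slide(cfg, patient_seed = 100 + i)$panel_a),
    numeric(1))
  # per-slide variance of a Poisson cluster process:
  # Var(N) = lambda * mu * (1 + mu) + background
  sd_slide <- sqrt(20 * 50 * 51 + 5 * area)
  expect_lt(abs(mean(counts) - expected), 3 * sd_slide / sqrt(10))
})

test_that("all simulated cells lie inside the tumor mask", {
  for (s in 1:5) {
    sl <- simulate_slide(small_sim_config(1), patient_seed = s)
    for (p in list(sl$panel_a, sl$panel_b)) {
      expect_equal(n_cells(filter_to_tumor(p, sl$mask)), n_cells(p))
    }
  }
})

test_that("gzmb assignment reduces to logistic(beta0) when beta1 = 0", {
  set.seed(42)
  n <- 10000
  cd8 <- data.frame(x_um = runif(n, 0, 4000), y_um = runif(n, 0, 3000))
  treg <- data.frame(x_um = runif(300, 0, 4000), y_um = runif(300, 0, 3000))
  flags <- assign_gzmb(cd8, treg, beta0 = 0.5, beta1 = 0, radius_um = 150,
                       seed = 7)
  expect_equal(mean(flags), plogis(0.5), tolerance = 0.02)
  d <- attr(flags, "density_cells_per_field")
  expect_lt(abs(cor(d, as.numeric(flags))), 0.05)
})

test_that("infinite suppression silences every CD8 cell near a Treg", {
  set.seed(1)
  cd8 <- data.frame(x_um = runif(500, 0, 2000), y_um = runif(500, 0, 2000))
  treg <- data.frame(x_um = runif(8, 0, 2000), y_um = runif(8, 0, 2000))
  flags <- assign_gzmb(cd8, treg, beta0 = 5, beta1 = Inf, radius_um = 150,
                       seed = 2)
  d <- attr(flags, "density_cells_per_field")
  expect_false(any(flags[d > 0]))
  expect_true(mean(flags[d == 0]) > 0.9) # plogis(5) = 0.993

  expect_identical(assign_gzmb(cd8[0, ], treg, 0, 1, 150), logical(0))
  expect_error(assign_gzmb(cd8, treg, 0, 1, radius_um = 0), "radius")
})

test_that("clustered Tregs induce a negative field-level GzmB correlation", {
  cfg <- sim_config(beta0 = 0, beta1 = 0.1, seed = NULL)
  set.seed(31)
  sl <- simulate_slide(cfg, patient_seed = 31, frac_ccr8 = 0.5)
  pa <- sl$panel_a
  pb <- sl$panel_b
  expect_gt(sum(pb$cells$CD8), 500)
  # non-overlapping fields (stride = field size), counted per panel
  mt <- density_map(pa, "ccr8_treg", stride_um = 360)
  fields <- data.frame(x0_um = mt$x0_um, y0_um = mt$y0_um,
                       width_um = 360, height_um = 270)
  fm <- field_metrics(fields, pa, pb)
  ok <- !is.na(fm$pct_gzmb_in_cd8)
  r <- cor(fm$ccr8_treg_count[ok], fm$pct_gzmb_in_cd8[ok])
  expect_lt(r, -0.2)
})

test_that("raising beta1 never raises mean GzmB under common random numbers", {
  frac <- numeric(0)
  for (b1 in c(0, 0.04, 0.08, 0.2)) {
    cfg <- small_sim_config(1, beta1 = b1)
    sl <- simulate_slide(cfg, patient_seed = 77, frac_ccr8 = 0.4)
    b <- sl$panel_b$cells
    frac <- c(frac, sum(b$GZMB) / sum(b$CD8))
  }
  expect_true(all(diff(frac) <= 0))
})

test_that("cohorts carry clinical covariates and censoring behaves", {
  co <- quiet(simulate_cohort(small_sim_config(3, n_patients = 12,
                                               censor_rate = 0,
                                               follow_up_months = Inf)))
  expect_equal(nrow(co$clinical), 12)
  expect_true(all(co$clinical$event == 1)) # nothing can censor
  expect_true(all(c("pN_positive", "pleural_invasion") %in%
                    names(co$clinical)))
  expect_identical(co$clinical$patient_id, co$summaries$patient_id)
  expect_true(all(co$clinical$pfs_months > 0))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(slide_width_um = -1), "positive")
  expect_error(sim_config(frac_cd8 = 0.7, frac_foxp3 = 0.5), "<= 1")
  expect_error(sim_config(beta1 = -0.1), "non-negative")
  expect_error(sim_config(censor_rate = 1), "< 1")
})
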