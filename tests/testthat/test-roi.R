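fab_map <- function(x0, y0, count, w = 360, h = 270, stride = 90) {
  structure(data.frame(x0_um = x0, y0_um = y0, count = count),
            class = c("density_map", "data.frame"),
            field_w_um = w, field_h_um = h, stride_um = stride)
}

test_that("density map respects the half-open field convention", {
  tab <- make_panel("A_CCR8_FOXP3", c(10, 360), c(10, 10), c(TRUE, TRUE),
                    c(TRUE, TRUE))
  m <- density_map(tab, "ccr8_treg", stride_um = 360,
                   bbox = c(0, 0, 720, 270))
  expect_equal(m$count[m$x0_um == 0], 1) # (10,10) only; (360,10) excluded
  expect_equal(m$count[m$x0_um == 360], 1) # (360,10) belongs here

  empty <- make_panel("A_CCR8_FOXP3", numeric(0), numeric(0), logical(0),
                      logical(0))
  me <- density_map(empty, "ccr8_treg", bbox = c(0, 0, 1000, 1000))
  expect_true(all(me$count == 0))

  expect_error(density_map(tab, "ccr8_treg", bbox = c(0, 0, 100, 100)),
               "exceeds")
})

test_that("density maps equal brute-force recounts for arbitrary strides", {
  set.seed(8)
  x <- runif(800, 0, 2000)
  y <- runif(800, 0, 1500)
  keepv <- runif(800) < 0.4
  tab <- make_panel("A_CCR8_FOXP3", x, y, keepv, keepv)
  bbox <- c(0, 0, 2000, 1500)
  for (stride in c(90, 75, 113, 360)) {
    m <- density_map(tab, "ccr8_treg", stride_um = stride, bbox = bbox)
    o <- oracle_density_map(tab$cells, keepv & keepv, bbox, 360, 270,
                            stride)
    expect_equal(m$x0_um, o$x0_um)
    expect_equal(m$y0_um, o$y0_um)
    expect_equal(m$count, o$count)
  }
})

test_that("a single dense region is captured by the first Hot Spot", {
  set.seed(3)
  x <- runif(60, 500, 860)
  y <- runif(60, 500, 770)
  tab <- make_panel("A_CCR8_FOXP3", x, y, rep(TRUE, 60), rep(TRUE, 60))
  m <- density_map(tab, "ccr8_treg", bbox = c(0, 0, 2000, 1500))
  hot <- suppressWarnings(select_hot_spots(m, k = 5))
  expect_equal(hot$count[1], max(m$count))
  expect_true(all(hot$count[-1] < hot$count[1]))
})

test_that("all-zero maps select deterministically by tie-break order", {
  tab <- make_panel("A_CCR8_FOXP3", numeric(0), numeric(0), logical(0),
                    logical(0))
  m <- density_map(tab, "ccr8_treg", stride_um = 90,
                   bbox = c(0, 0, 1440, 1080))
  hot <- select_hot_spots(m, k = 5)
  o <- oracle_greedy_select(m, 5, decreasing = TRUE, w = 360, h = 270)
  expect_equal(hot$x0_um, o$x0)
  expect_equal(hot$y0_um, o$y0)
  expect_equal(hot$x0_um[1], 0) # top-left first
  expect_equal(hot$y0_um[1], 0)
})

test_that("selection is invariant to candidate enumeration order", {
  set.seed(5)
  sl <- simulate_slide(small_sim_config(1), patient_seed = 44)
  pa <- sl$panel_a
  m <- density_map(pa, "ccr8_treg")
  hot <- select_hot_spots(m, k = 5)
  perm <- sample(nrow(m))
  m2 <- fab_map(m$x0_um[perm], m$y0_um[perm], m$count[perm])
  hot2 <- select_hot_spots(m2, k = 5)
  expect_equal(hot[order(hot$x0_um, hot$y0_um), ],
               hot2[order(hot2$x0_um, hot2$y0_um), ],
               ignore_attr = TRUE)
})

test_that("cold-spot eligibility excludes only doubly sparse fields", {
  m_treg <- fab_map(c(0, 360, 720), c(0, 0, 0), c(5, 0, 2))
  m_cd8 <- fab_map(c(0, 360, 720), c(0, 0, 0), c(3, 12, 11))
  m_fox <- fab_map(c(0, 360, 720), c(0, 0, 0), c(2, 0, 10))
  cold <- suppressWarnings(
    select_cold_spots(m_treg, m_cd8, m_fox, k = 5, min_lymph = 10))
  # field 1 (cd8=3, foxp3=2): ineligible; field 2 (cd8=12, foxp3=0,
  # treg=0): eligible and ranked first; field 3 eligible, treg=2
  expect_equal(cold$x0_um, c(360, 720))
  expect_equal(cold$count, c(0, 2))
})

test_that("hot and cold selections match the exhaustive oracle", {
  set.seed(77)
  for (rep in 1:20) {
    sl <- simulate_slide(small_sim_config(1), patient_seed = 600 + rep)
    pa <- sl$panel_a
    pb <- sl$panel_b
    mt <- density_map(pa, "ccr8_treg")
    mf <- density_map(pa, "foxp3")
    mc <- density_map(pb, "cd8")
    hot <- suppressWarnings(select_hot_spots(mt, k = 5))
    o_hot <- oracle_greedy_select(mt, 5, decreasing = TRUE, w = 360,
                                  h = 270)
    expect_equal(hot$x0_um, o_hot$x0)
    expect_equal(hot$y0_um, o_hot$y0)
    cold <- suppressWarnings(
      select_cold_spots(mt, mc, mf, k = 5, min_lymph = 10, avoid = hot))
    o_cold <- oracle_greedy_select(
      mt, 5, decreasing = FALSE, w = 360, h = 270,
      eligible = !(mc$count < 10 & mf$count < 10), avoid = hot)
    expect_equal(cold$x0_um, o_cold$x0)
    expect_equal(cold$y0_um, o_cold$y0)
  }
})

test_that("hot-spot counts dominate cold-spot counts within a slide", {
  for (rep in 1:5) {
    sl <- simulate_slide(small_sim_config(1), patient_seed = 900 + rep,
                         frac_ccr8 = 0.5)
    an <- quiet(analyze_patient(sl$panel_a, sl$panel_b, sl$mask))
    if (nrow(an$hot) == 5 && nrow(an$cold) == 5) {
      expect_gte(min(an$hot$count), max(an$cold$count))
    }
  }
})

test_that("field metrics count both panels and guard the frame tag", {
  pa <- make_panel("A_CCR8_FOXP3", c(10, 20, 30), c(10, 20, 30),
                   c(TRUE, TRUE, FALSE), c(TRUE, TRUE, TRUE))
  pb <- make_panel("B_CD8_GZMB", c(15, 25, 500), c(15, 25, 500),
                   c(TRUE, TRUE, TRUE), c(FALSE, TRUE, TRUE))
  f <- data.frame(x0_um = 0, y0_um = 0, width_um = 360, height_um = 270)
  fm <- field_metrics(f, pa, pb, spot_class = "HOT")
  expect_equal(fm$ccr8_treg_count, 2)
  expect_equal(fm$foxp3_count, 3)
  expect_equal(fm$cd8_count, 2)
  expect_equal(fm$gzmb_cd8_count, 1)
  expect_equal(fm$pct_gzmb_in_cd8, 50)

  f_empty <- data.frame(x0_um = 5000, y0_um = 5000, width_um = 360,
                        height_um = 270)
  fe <- field_metrics(f_empty, pa, pb)
  expect_equal(fe$cd8_count, 0)
  expect_true(is.na(fe$pct_gzmb_in_cd8))

  pb$frame <- "shifted"
  expect_error(field_metrics(f, pa, pb), "frame")
})

test_that("field metrics equal recounts on a simulated slide", {
  sl <- simulate_slide(small_sim_config(1), patient_seed = 321)
  an <- quiet(analyze_patient(sl$panel_a, sl$panel_b, sl$mask))
  a <- sl$panel_a$cells
  b <- sl$panel_b$cells
  for (i in seq_len(nrow(an$fields))) {
    r <- an$fields[i, ]
    expect_equal(r$ccr8_treg_count,
                 oracle_field_count(a, a$CCR8 & a$FOXP3, r$x0_um, r$y0_um,
                                    360, 270))
    expect_equal(r$cd8_count,
                 oracle_field_count(b, b$CD8, r$x0_um, r$y0_um, 360, 270))
    expect_equal(r$gzmb_cd8_count,
                 oracle_field_count(b, b$CD8 & b$GZMB, r$x0_um, r$y0_um,
                                    360, 270))
  }
})

test_that("patient summary averages fields and forms ratios", {
  one <- data.frame(patient_id = "p", spot_class = "HOT", x0_um = 0,
                    y0_um = 0, ccr8_treg_count = 15, foxp3_count = 20,
                    cd8_count = 40, gzmb_cd8_count = 12,
                    pct_gzmb_in_cd8 = 30)
  hot <- one[rep(1, 5), ]
  s <- patient_roi_summary(hot)
  expect_equal(s$hot_mean_ccr8_treg, 15)
  expect_equal(s$hot_mean_pct_gzmb, 30)
  expect_equal(s$gzmb_ccr8_ratio, 2.0) # 30 / 15
  expect_equal(s$cd8_foxp3_ratio, 2.0) # 40 / 20
  expect_equal(s$cd8_ccr8_ratio, 40 / 15)

  # undefined pct fields drop out of the mean; zero denominator -> NA
  hot$pct_gzmb_in_cd8[3] <- NA
  expect_message(s2 <- patient_roi_summary(hot), "excluded")
  expect_equal(s2$hot_mean_pct_gzmb, 30)
  hot$ccr8_treg_count <- 0
  s3 <- quiet(patient_roi_summary(hot))
  expect_true(is.na(s3$gzmb_ccr8_ratio))

  expect_error(patient_roi_summary(hot[0, ]), "no Hot Spots")
})

test_that("per-patient summaries equal a hand recomputation on a cohort", {
  co <- quiet(simulate_cohort(small_sim_config(6, n_patients = 4)))
  for (pid in co$summaries$patient_id) {
    f <- co$fields[co$fields$patient_id == pid, ]
    hot <- f[f$spot_class == "HOT", ]
    s <- co$summaries[co$summaries$patient_id == pid, ]
    expect_equal(s$hot_mean_ccr8_treg, mean(hot$ccr8_treg_count))
    expect_equal(s$hot_mean_cd8, mean(hot$cd8_count))
    expect_equal(s$gzmb_ccr8_ratio,
                 mean(hot$pct_gzmb_in_cd8, na.rm = TRUE) /
                   mean(hot$ccr8_treg_count))
  }
})
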