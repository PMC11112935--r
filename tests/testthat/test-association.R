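test_that("median split labels strictly-above-median as high", {
  ms <- median_split(c(1, 2, 3))
  expect_equal(as.character(ms$labels), c("low", "low", "high"))
  expect_equal(ms$split_value, 2)

  set.seed(10)
  v <- sample(seq_len(81)) # 81 distinct values
  ms81 <- median_split(v)
  expect_equal(ms81$n_high, 40)
  expect_equal(ms81$n_low, 41)

  expect_warning(ms_tie <- median_split(rep(7, 10)), "low")
  expect_true(all(ms_tie$labels == "low"))

  v2 <- c(5, NA, 1, 9)
  ms_na <- median_split(v2, ids = letters[1:4])
  expect_true(is.na(ms_na$labels["b"]))
  expect_equal(ms_na$n_high + ms_na$n_low, 3)

  expect_error(median_split(c(NA, NA, 3)), "at least 2")
})

test_that("OLS correlation matches the normal-equation oracle", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2.1, 3.9, 6.2, 8.1, 9.8)
  fit <- linreg_correlation(x, y)
  # closed form: slope = Sxy/Sxx, intercept = ybar - slope xbar
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  expect_equal(fit$slope, sxy / sxx, tolerance = 1e-9)
  expect_equal(fit$intercept, mean(y) - (sxy / sxx) * mean(x),
               tolerance = 1e-9)
  expect_equal(fit$pearson_r, sxy / sqrt(sxx * sum((y - mean(y))^2)),
               tolerance = 1e-9)

  exact <- linreg_correlation(x, 2 * x + 1)
  expect_equal(exact$slope, 2)
  expect_equal(exact$pearson_r, 1)
  expect_lt(exact$p_value, 1e-10)

  set.seed(6)
  null <- linreg_correlation(rnorm(1000), rnorm(1000))
  expect_lt(abs(null$pearson_r), 0.1)

  expect_error(linreg_correlation(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_message(linreg_correlation(c(1, 2, 3, NA), c(1, 2, 3, 4)),
                 "dropped")
})

test_that("Mann-Whitney U is exact on small tie-free samples", {
  a <- c(1, 2, 3)
  b <- c(4, 5, 6)
  mw <- mann_whitney_u(a, b)
  expect_equal(mw$U, 0)
  expect_equal(mw$method, "exact")
  expect_equal(mw$p_value, 0.1) # 2/C(6,3) = 2/20
  expect_equal(mw$p_value, oracle_mw_exact_p(a, b))

  set.seed(2)
  a2 <- rnorm(8)
  b2 <- rnorm(9)
  expect_equal(mann_whitney_u(a2, b2)$p_value, oracle_mw_exact_p(a2, b2))
})

test_that("Mann-Whitney is a rank statistic with symmetric null", {
  s <- c(1.2, 3.4, 0.5, 2.2)
  expect_equal(mann_whitney_u(s, s)$p_value, 1.0)

  set.seed(3)
  a <- rnorm(30)
  b <- rnorm(25, 0.5)
  raw <- mann_whitney_u(a, b)
  mono <- mann_whitney_u(exp(a), exp(b))
  expect_equal(raw$U, mono$U)
  expect_equal(raw$p_value, mono$p_value)

  expect_error(mann_whitney_u(numeric(0), b), "non-empty")
})

test_that("Fisher exact reproduces the published association p-values", {
  rep <- replay_crosstabs()
  sig <- rep[rep$printed_p < 0.05, ]
  expect_equal(nrow(sig), 5)
  expect_equal(signif(sig$p_value, 2), sig$printed_p)
  expect_true(all(rep$p_value > 0 & rep$p_value <= 1))
})

test_that("Fisher exact is invariant to row and column swaps", {
  t0 <- matrix(c(26, 14, 36, 5), 2, byrow = TRUE)
  p0 <- fisher_exact_2x2(t0)$p_value
  expect_equal(fisher_exact_2x2(t0[2:1, ])$p_value, p0)
  expect_equal(fisher_exact_2x2(t0[, 2:1])$p_value, p0)

  flat <- fisher_exact_2x2(5, 5, 5, 5)
  expect_equal(flat$p_value, 1.0)
  expect_equal(flat$odds_ratio, 1.0, tolerance = 1e-6)

  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")
})

test_that("identical 2x2 tables yield identical p-values across groupings", {
  rep <- replay_crosstabs()
  a <- rep[rep$variable == "lymphatic_invasion" & rep$grouping == "pct_gzmb", ]
  b <- rep[rep$variable == "pleural_invasion" &
             rep$grouping == "gzmb_ccr8_ratio", ]
  expect_equal(a[, c("high_level1", "high_level2", "low_level1",
                     "low_level2")],
               b[, c("high_level1", "high_level2", "low_level1",
                     "low_level2")],
               ignore_attr = TRUE)
  expect_identical(a$p_value, b$p_value)
})

test_that("association table dispatches by variable type", {
  set.seed(12)
  n <- 40
  clinical <- data.frame(
    patient_id = sprintf("p%02d", 1:n),
    pfs_months = rexp(n, 0.02) + 1, event = rbinom(n, 1, 0.5),
    age = round(runif(n, 40, 85)),
    node_positive = rbinom(n, 1, 0.3),
    constant = 1)
  grp <- median_split(rnorm(n), ids = clinical$patient_id)
  expect_warning(tab <- clinico_association_table(clinical, grp),
                 "single observed level")
  expect_setequal(tab$variable, c("age", "node_positive"))
  expect_equal(tab$type[tab$variable == "age"], "continuous")
  expect_equal(tab$type[tab$variable == "node_positive"], "categorical")
  expect_true(all(tab$p_value > 0 & tab$p_value <= 1))

  # a perfectly balanced variable across identical groups is null
  clinical2 <- data.frame(patient_id = sprintf("p%02d", 1:8),
                          flag = rep(c(0, 1), 4))
  grp2 <- median_split(rep(c(1, 2), each = 4),
                       ids = clinical2$patient_id)
  tab2 <- clinico_association_table(clinical2, grp2,
                                    exclude = "patient_id")
  expect_equal(tab2$p_value, 1)
})
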