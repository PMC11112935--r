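# Independent oracles, deliberately naive: per-point loops and per-field
# recounts that share no code with the implementation under test.

# Brute-force recount of one half-open field on a cell data.frame.
oracle_field_count <- function(cells, keep, x0, y0, w, h) {
  sum(keep & cells$x_um >= x0 & cells$x_um < x0 + w &
        cells$y_um >= y0 & cells$y_um < y0 + h)
}

# Brute-force density map: loop over every candidate field.
oracle_density_map <- function(cells, keep, bbox, w, h, stride) {
  x0s <- bbox[1] + (0:floor((bbox[3] - bbox[1] - w) / stride)) * stride
  y0s <- bbox[2] + (0:floor((bbox[4] - bbox[2] - h) / stride)) * stride
  out <- expand.grid(x0_um = x0s, y0_um = y0s)
  out$count <- mapply(function(x0, y0)
    oracle_field_count(cells, keep, x0, y0, w, h),
    out$x0_um, out$y0_um)
  out[order(out$y0_um, out$x0_um), ]
}

# Exhaustive greedy selection oracle: sort all candidates by the stated
# tie-break, then scan with pairwise overlap checks against everything
# already chosen (and the `avoid` set).
oracle_greedy_select <- function(map, k, decreasing, w, h,
                                 eligible = rep(TRUE, nrow(map)),
                                 avoid = NULL, allow_overlap = FALSE) {
  df <- data.frame(x0 = map$x0_um, y0 = map$y0_um, count = map$count)
  df <- df[eligible, ]
  o <- if (decreasing) order(-df$count, df$y0, df$x0)
       else order(df$count, df$y0, df$x0)
  df <- df[o, ]
  chosen <- df[0, ]
  for (i in seq_len(nrow(df))) {
    cand <- df[i, ]
    clash <- FALSE
    if (!is.null(avoid) && nrow(avoid) > 0) {
      for (j in seq_len(nrow(avoid))) {
        if (abs(cand$x0 - avoid$x0_um[j]) < w &&
            abs(cand$y0 - avoid$y0_um[j]) < h) clash <- TRUE
      }
    }
    if (!allow_overlap && nrow(chosen) > 0) {
      for (j in seq_len(nrow(chosen))) {
        if (abs(cand$x0 - chosen$x0[j]) < w &&
            abs(cand$y0 - chosen$y0[j]) < h) clash <- TRUE
      }
    }
    if (!clash) chosen <- rbind(chosen, cand)
    if (nrow(chosen) == k) break
  }
  chosen
}

# Point-in-polygon by winding angle, independent of the ray-casting
# implementation. Ambiguous exactly on the boundary, so callers keep test
# points away from edges.
oracle_point_in_polygon <- function(px, py, poly) {
  vapply(seq_along(px), function(i) {
    dx <- poly[, 1] - px[i]
    dy <- poly[, 2] - py[i]
    ang <- atan2(dy, dx)
    d <- diff(c(ang, ang[1]))
    d <- ifelse(d > pi, d - 2 * pi, ifelse(d < -pi, d + 2 * pi, d))
    abs(sum(d)) > pi # winding number != 0
  }, logical(1))
}

# Area of a polygon star-shaped around `center`, by fan triangulation
# from that center (the triangles partition the polygon exactly).
oracle_star_area <- function(poly, center) {
  a <- 0
  n <- nrow(poly)
  for (i in seq_len(n)) {
    v1 <- poly[i, ] - center
    v2 <- poly[if (i == n) 1 else i + 1, ] - center
    a <- a + abs(v1[1] * v2[2] - v1[2] * v2[1]) / 2
  }
  a
}

# Two-group log-rank statistic computed directly from the O-E/V formula.
oracle_logrank_chi2 <- function(time, event, group) {
  g <- as.integer(factor(group)) # 1 or 2
  ts <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Product-limit estimator computed as an explicit running product.
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = ts, surv = NA_real_)
  for (i in seq_along(ts)) {
    n <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / n)
    out$surv[i] <- s
  }
  out
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
oracle_mw_exact_p <- function(a, b) {
  vals <- c(a, b)
  n <- length(vals)
  u_of <- function(idx) {
    x <- vals[idx]
    y <- vals[-idx]
    sum(outer(x, y, ">"))
  }
  u_obs <- sum(outer(a, b, ">"))
  combos <- utils::combn(n, length(a))
  us <- apply(combos, 2, u_of)
  mu <- length(a) * length(b) / 2
  mean(abs(us - mu) >= abs(u_obs - mu))
}
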