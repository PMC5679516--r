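# Independent brute-force oracles. These deliberately avoid the package's own
# code paths: plain loops, dense boundary sampling, winding-number tests and
# textbook formulas.

# Collapse panel by nested loops straight from the definition.
oracle_collapse_panel <- function(counts, window = 3) {
  years <- seq(min(counts$year), max(counts$year))
  out <- list()
  for (id in sort(unique(counts$lek_id))) {
    sub <- counts[counts$lek_id == id, ]
    rec <- stats::setNames(rep(NA_real_, length(years)), years)
    rec[as.character(sub$year)] <- sub$males
    for (t in years[years >= min(years) + window - 1]) {
      win <- rec[as.character((t - window + 1):t)]
      eligible <- all(!is.na(win))
      out[[length(out) + 1]] <- data.frame(
        lek_id = id, year = t,
        eligible = eligible,
        collapsed = eligible && all(win == 0)
      )
    }
  }
  do.call(rbind, out)
}

# Winding-number point-in-polygon (different algorithm from the package's
# even-odd crossing test).
oracle_in_polygon <- function(px, py, poly) {
  vx <- c(poly[, 1], poly[1, 1])
  vy <- c(poly[, 2], poly[1, 2])
  ang <- 0
  for (i in seq_len(nrow(poly))) {
    a1 <- atan2(vy[i] - py, vx[i] - px)
    a2 <- atan2(vy[i + 1] - py, vx[i + 1] - px)
    d <- a2 - a1
    if (d > pi) d <- d - 2 * pi
    if (d < -pi) d <- d + 2 * pi
    ang <- ang + d
  }
  abs(ang) > pi
}

# Distance to boundary via densely sampled boundary vertices.
oracle_boundary_distance <- function(px, py, polygons, spacing = 0.5) {
  best <- Inf
  for (poly in polygons) {
    vx <- c(poly[, 1], poly[1, 1])
    vy <- c(poly[, 2], poly[1, 2])
    for (i in seq_len(nrow(poly))) {
      len <- sqrt((vx[i + 1] - vx[i])^2 + (vy[i + 1] - vy[i])^2)
      t <- seq(0, 1, length.out = max(2, ceiling(len / spacing)))
      sx <- vx[i] + t * (vx[i + 1] - vx[i])
      sy <- vy[i] + t * (vy[i + 1] - vy[i])
      best <- min(best, sqrt((sx - px)^2 + (sy - py)^2))
    }
  }
  best
}

# Ring membership for one point: outside every polygon, within buffer of the
# boundary (winding test + sampled-boundary distance).
oracle_in_ring <- function(px, py, polygons, buffer_m, spacing = 1) {
  inside_any <- any(vapply(polygons, function(p) oracle_in_polygon(px, py, p), logical(1)))
  !inside_any && oracle_boundary_distance(px, py, polygons, spacing) <= buffer_m
}

# Textbook simple linear regression via explicit normal equations.
oracle_ols <- function(x, y) {
  n <- length(x)
  X <- cbind(1, x)
  xtx <- t(X) %*% X
  est <- solve(xtx, t(X) %*% y)
  resid <- y - X %*% est
  s2 <- sum(resid^2) / (n - 2)
  se <- sqrt(diag(s2 * solve(xtx)))
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sum(resid^2) / sst
  f <- (r2 / (1 - r2)) * (n - 2)
  list(
    intercept = unname(est[1]), beta = unname(est[2]), se_beta = unname(se[2]),
    r2 = r2, f = f, p = stats::pf(f, 1, n - 2, lower.tail = FALSE)
  )
}

# Textbook Welch statistic with Satterthwaite degrees of freedom.
oracle_welch <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Beta quantile by root-finding on the numerically integrated density.
oracle_beta_quantile <- function(p, a, b) {
  cdf <- function(q) stats::integrate(function(u) stats::dbeta(u, a, b),
    0, q,
    rel.tol = 1e-12, abs.tol = 1e-14
  )$value
  stats::uniroot(function(q) cdf(q) - p, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
}
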