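#' Beta prior specification for the binomial collapse probability
#'
#' @param preset `"uniform"` (Beta(1, 1), the flat prior) or `"jeffreys"`
#'   (Beta(0.5, 0.5)). Ignored when `alpha`/`beta` are supplied.
#' @param alpha,beta Optional explicit positive shape parameters.
#' @return A named list with `alpha`, `beta` and `label`, class `beta_prior`.
#' @export
beta_prior <- function(preset = c("uniform", "jeffreys"), alpha = NULL, beta = NULL) {
  if (!is.null(alpha) || !is.null(beta)) {
    alpha <- alpha %||% 1
    beta <- beta %||% 1
    label <- sprintf("beta(%g,%g)", alpha, beta)
  } else {
    preset <- match.arg(preset)
    alpha <- if (preset == "uniform") 1 else 0.5
    beta <- alpha
    label <- preset
  }
  if (alpha <= 0 || beta <= 0) {
    abort("Prior shapes must be positive.", class = "lekshed_validation_error")
  }
  structure(list(alpha = alpha, beta = beta, label = label), class = "beta_prior")
}

hpd_beta <- function(a, b, level) {
  # shortest interval holding `level` posterior mass; numeric search on the
  # lower-tail mass to 1e-10 (well inside the 1e-8 mass tolerance)
  if (a <= 1 && b <= 1) {
    # flat or U-shaped: fall back to central (HPD ill-defined/degenerate)
    return(c(qbeta((1 - level) / 2, a, b), qbeta(1 - (1 - level) / 2, a, b)))
  }
  if (a <= 1) return(c(0, qbeta(level, a, b)))
  if (b <= 1) return(c(qbeta(1 - level, a, b), 1))
  width <- function(p) qbeta(p + level, a, b) - qbeta(p, a, b)
  opt <- optimize(width, c(0, 1 - level), tol = 1e-10)
  c(qbeta(opt$minimum, a, b), qbeta(opt$minimum + level, a, b))
}

#' Conjugate beta-binomial posterior of a collapse probability
#'
#' Updates the Beta prior with `x` collapsed out of `n` eligible leks:
#' posterior Beta(alpha + x, beta + n - x). Reports the posterior mean and a
#' 95% (by default) credible interval, either central (equal-tailed Beta
#' quantiles) or highest posterior density.
#'
#' @param x Number of collapsed leks (vectorized).
#' @param n Number of eligible leks (vectorized).
#' @param prior A [beta_prior()].
#' @param ci `"central"` or `"hpd"`.
#' @param level Credible level.
#' @return Tibble `x, n, post_alpha, post_beta, mean, ci_low, ci_high, ci_type,
#'   level, prior`.
#' @examples
#' collapse_posterior(1, 10) # mean (1+1)/(10+2) = 1/6
#' @export
collapse_posterior <- function(x, n, prior = beta_prior(), ci = c("central", "hpd"),
                               level = 0.95) {
  ci <- match.arg(ci)
  if (any(x < 0) || any(n < 0) || any(x > n)) {
    abort("Need 0 <= x <= n.", class = "lekshed_validation_error")
  }
  a <- prior$alpha + x
  b <- prior$beta + n - x
  lo <- (1 - level) / 2
  if (ci == "central") {
    ci_low <- qbeta(lo, a, b)
    ci_high <- qbeta(1 - lo, a, b)
  } else {
    hp <- vapply(seq_along(a), function(i) hpd_beta(a[i], b[i], level), numeric(2))
    ci_low <- hp[1, ]
    ci_high <- hp[2, ]
  }
  tibble(
    x = x, n = n, post_alpha = a, post_beta = b,
    mean = a / (a + b), ci_low = ci_low, ci_high = ci_high,
    ci_type = ci, level = level, prior = prior$label
  )
}

#' Yearly posterior series of collapse probability per stratum
#'
#' One independent conjugate update per (year, stratum) cell of the collapse
#' counts - no pooling across years, matching the year-independent framing of
#' the collapse metric.
#'
#' @param counts Output of [aggregate_collapse()] (`year, stratum, x, n`).
#' @param prior,ci,level Passed to [collapse_posterior()].
#' @return Tibble `year, stratum, x, n, mean, ci_low, ci_high, ci_type, level,
#'   prior`.
#' @seealso [stratum_mean_collapse()] for the across-year average.
#' @export
posterior_series <- function(counts, prior = beta_prior(), ci = "central",
                             level = 0.95) {
  if (nrow(counts) == 0L) {
    abort("Empty collapse counts.", class = "lekshed_validation_error")
  }
  post <- collapse_posterior(counts$x, counts$n, prior = prior, ci = ci, level = level)
  dplyr::bind_cols(counts[, c("year", "stratum")], post)
}

#' Across-year mean posterior collapse probability per stratum
#'
#' The unweighted arithmetic mean of the yearly posterior means (not a pooled
#' x/n), consistent with treating each year as an independent assessment.
#'
#' @param series Output of [posterior_series()].
#' @return Tibble `stratum, mean_probability, n_years`.
#' @export
stratum_mean_collapse <- function(series) {
  series %>%
    group_by(stratum = .data$stratum) %>%
    summarise(
      mean_probability = mean(.data$mean),
      n_years = dplyr::n(),
      .groups = "drop"
    )
}

#' Do two credible intervals overlap?
#'
#' Closed-interval test per year between two strata of a posterior series:
#' touching endpoints count as overlapping.
#'
#' @param a,b Posterior tibbles (rows of [posterior_series()]) covering the
#'   same years at the same level.
#' @return Tibble `year, overlap`.
#' @export
interval_overlap <- function(a, b) {
  a <- arrange(a, .data$year)
  b <- arrange(b, .data$year)
  if (!identical(as.integer(a$year), as.integer(b$year))) {
    abort("Years of the two series do not match.", class = "lekshed_validation_error")
  }
  if (!isTRUE(all.equal(a$level, b$level))) {
    abort("Credible levels do not match.", class = "lekshed_validation_error")
  }
  tibble(
    year = as.integer(a$year),
    overlap = a$ci_low <= b$ci_high & b$ci_low <= a$ci_high
  )
}
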