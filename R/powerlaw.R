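# Maximum-likelihood power-law fitting (Clauset-Shalizi-Newman):
# discrete (Hurwitz-zeta normalised) for tick-quantized encounter
# durations, continuous Pareto for cumulative contact minutes; x_min by
# minimal Kolmogorov-Smirnov distance over candidate values.

# Hurwitz zeta(s, q) = sum_{k>=0} (q + k)^-s for s > 1, q > 0, via
# Euler-Maclaurin after an explicit head sum. Accurate to ~1e-12 for the
# s in (1, 8] used here.
hurwitz_zeta <- function(s, q) {
  stopifnot(s > 1, q > 0)
  N <- 25
  k <- 0:(N - 1)
  head_sum <- sum((q + k)^(-s))
  a <- q + N
  tail_sum <- a^(1 - s) / (s - 1) + 0.5 * a^(-s) +
    s * a^(-s - 1) / 12 -
    s * (s + 1) * (s + 2) * a^(-s - 3) / 720 +
    s * (s + 1) * (s + 2) * (s + 3) * (s + 4) * a^(-s - 5) / 30240
  head_sum + tail_sum
}

# P(X >= x) for the discrete power law with pmf x^-alpha / zeta(alpha, xmin)
displ_sf <- function(x, alpha, xmin) {
  vapply(x, function(xi) hurwitz_zeta(alpha, xi), numeric(1)) /
    hurwitz_zeta(alpha, xmin)
}

mle_discrete_alpha <- function(x, xmin) {
  slx <- sum(log(x))
  n <- length(x)
  nll <- function(alpha) n * log(hurwitz_zeta(alpha, xmin)) + alpha * slx
  optimize(nll, interval = c(1.000001, 8))$minimum
}

ks_discrete <- function(x, alpha, xmin) {
  # both CDFs are right-continuous step functions jumping at the same
  # atoms, so the sup distance is attained at the observed values
  tab <- sort(unique(x))
  n <- length(x)
  ecdf_hi <- cumsum(tabulate(match(x, tab))) / n
  model <- 1 - displ_sf(tab + 1L, alpha, xmin)
  max(abs(ecdf_hi - model))
}

ks_continuous <- function(x, alpha, xmin) {
  x <- sort(x)
  n <- length(x)
  model <- 1 - (x / xmin)^(1 - alpha)
  max(pmax(abs(seq_len(n) / n - model), abs((seq_len(n) - 1) / n - model)))
}

#' Fit a power law to a duration sample
#'
#' Maximum-likelihood fit of `P(w) ~ w^beta` following the
#' Clauset-Shalizi-Newman procedure: for each candidate `x_min` the tail
#' exponent is estimated by MLE (exact discrete likelihood through the
#' Hurwitz zeta function, or the closed-form continuous Pareto MLE) and
#' the `x_min` minimising the Kolmogorov-Smirnov distance between tail
#' and model is kept. `beta` is reported as the (negative) density
#' exponent, i.e. `beta = -alpha`.
#'
#' @param values Positive sample (integer ticks for the discrete fit,
#'   e.g. encounter durations; any positive reals for the continuous
#'   fit, e.g. cumulative contact minutes).
#' @param discrete Use the discrete power law? Defaults to `TRUE` when
#'   all values are (near-)integer.
#' @param xmin Fix `x_min` instead of scanning (skips the KS scan).
#' @param min_tail Candidate `x_min` values leaving fewer than this many
#'   tail observations are not considered (default 50).
#' @return A `power_law_fit` object: list with `beta`, `alpha`, `xmin`,
#'   `ks`, `n_tail`, `n`, `discrete`; has [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @examples
#' x <- rpowerlaw(2000, beta = -2.5, xmin = 1, discrete = TRUE, seed = 7)
#' fit_power_law(x, xmin = 1)
#' @export
fit_power_law <- function(values, discrete = NULL, xmin = NULL, min_tail = 50) {
  values <- values[is.finite(values)]
  if (length(values) == 0 || any(values <= 0)) {
    abort("need a positive sample", class = "schoolcontacts_fit_error")
  }
  if (is.null(discrete)) {
    discrete <- all(abs(values - round(values)) < 1e-9)
  }
  if (discrete) values <- round(values)  # keep numeric: tails can pass 2^31
  if (length(unique(values)) < 2L) {
    abort("degenerate sample: all values identical, no power law to fit",
          class = "schoolcontacts_fit_error")
  }
  candidates <- if (!is.null(xmin)) xmin else sort(unique(values))
  if (length(candidates) > 200L) {
    # quantile-spaced candidate grid keeps the KS scan tractable on
    # large continuous samples
    candidates <- sort(unique(stats::quantile(
      candidates, probs = seq(0, 0.99, length.out = 200L), type = 1, names = FALSE
    )))
  }
  fits <- list()
  for (xm in candidates) {
    tail_x <- values[values >= xm]
    if (length(tail_x) < max(min_tail, 2L) || length(unique(tail_x)) < 2L) next
    if (discrete) {
      alpha <- mle_discrete_alpha(tail_x, xm)
      ks <- ks_discrete(tail_x, alpha, xm)
    } else {
      alpha <- 1 + length(tail_x) / sum(log(tail_x / xm))
      ks <- ks_continuous(tail_x, alpha, xm)
    }
    fits[[length(fits) + 1L]] <- list(alpha = alpha, xmin = xm, ks = ks,
                                      n_tail = length(tail_x))
  }
  if (!length(fits)) {
    abort(sprintf(
      "too few points for a power-law fit: no x_min candidate leaves >= %d tail values",
      min_tail
    ), class = "schoolcontacts_fit_error")
  }
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "ks"))]]
  structure(
    list(
      beta = -best$alpha, alpha = best$alpha, xmin = best$xmin,
      ks = best$ks, n_tail = best$n_tail, n = length(values),
      discrete = discrete
    ),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "<power_law_fit> %s MLE: beta = %.3f (alpha = %.3f), x_min = %g, KS = %.4f, tail n = %d of %d\n",
    if (x$discrete) "discrete" else "continuous",
    x$beta, x$alpha, x$xmin, x$ks, x$n_tail, x$n
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.power_law_fit <- function(x, ...) {
  tibble(term = c("beta", "xmin"), estimate = c(x$beta, x$xmin))
}

#' @exportS3Method generics::glance
glance.power_law_fit <- function(x, ...) {
  tibble(
    beta = x$beta, alpha = x$alpha, xmin = x$xmin, ks = x$ks,
    n_tail = x$n_tail, n = x$n, discrete = x$discrete
  )
}

#' Sample from a power law
#'
#' Discrete sampling inverts the exact Hurwitz-zeta survival function on
#' a precomputed support (extended until the truncated tail mass is below
#' `tail_tol`); continuous sampling inverts the Pareto CDF.
#'
#' @param n Sample size.
#' @param beta Density exponent (negative, `< -1`).
#' @param xmin Lower support bound.
#' @param discrete Integer-valued (zeta) or continuous (Pareto) law.
#' @param tail_tol Truncated tail mass for the discrete support table.
#' @param seed Optional seed applied locally.
#' @return Numeric (or integer) vector of length `n`.
#' @export
rpowerlaw <- function(n, beta, xmin = 1, discrete = TRUE, tail_tol = 1e-7,
                      seed = NULL) {
  alpha <- -beta
  stopifnot(alpha > 1, xmin > 0)
  if (!is.null(seed)) set.seed(seed)
  if (!discrete) {
    return(xmin * (1 - runif(n))^(-1 / (alpha - 1)))
  }
  xmin <- as.integer(xmin)
  # lookup table over the bulk; exact zeta-inversion for the far tail,
  # which matters for shallow exponents (alpha near 1)
  cap <- xmin * 2L
  z <- hurwitz_zeta(alpha, xmin)
  repeat {
    tail_mass <- hurwitz_zeta(alpha, cap + 1L) / z
    if (tail_mass < tail_tol || cap >= 1e6) break
    cap <- cap * 2L
  }
  supp <- seq.int(xmin, cap)
  pmf <- supp^(-alpha) / z
  cdf <- cumsum(pmf)
  u <- runif(n)
  out <- supp[pmin(findInterval(u, cdf) + 1L, length(supp))]
  in_tail <- u > cdf[length(cdf)]
  if (any(in_tail)) {
    sf_target <- 1 - u[in_tail]  # find largest x with P(X >= x) >= sf_target
    out[in_tail] <- vapply(sf_target, function(s) {
      lo <- cap
      hi <- cap * 2
      while (hurwitz_zeta(alpha, hi) / z >= s) {
        lo <- hi
        hi <- hi * 2
      }
      # stop at integer resolution or double-precision granularity,
      # whichever comes first (far-tail draws can exceed 2^53)
      while (hi - lo > 1 && (hi - lo) > hi * 1e-12) {
        mid <- floor((lo + hi) / 2)
        if (hurwitz_zeta(alpha, mid) / z >= s) lo <- mid else hi <- mid
      }
      lo
    }, numeric(1))
  }
  out
}
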