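#' Truncated lognormal exposure distributions
#'
#' Environmental concentrations and per-body-mass intake rates are modelled
#' as lognormal variates described by a population median and a geometric
#' standard deviation (GSD), truncated symmetrically in log space a fixed
#' number of GSDs either side of the median. The default truncation
#' half-width of 3 GSDs reflects the empirical absence of biological and
#' environmental measurements beyond roughly three GSDs from the median.
#'
#' Truncation is implemented by restricting the standard normal variate
#' `Z` of `X = median * gsd^Z` to `[-trunc, +trunc]` and renormalising its
#' mass; sampling uses inverse-CDF transforms of uniforms on the restricted
#' range, so every draw is guaranteed to lie inside the support
#' `[median / gsd^trunc, median * gsd^trunc]` without rejection loops.
#'
#' Two degenerate limits are permitted because the exposure model needs
#' them: `median = 0` is the "absent component" point mass at zero (e.g.
#' thiocyanate in drinking water), and `gsd = 1` is a point mass at the
#' median (no inter-subject spread).
#'
#' @param median Population median, in the units of the quantity modelled.
#'   Must be finite and non-negative; zero gives the point mass at zero.
#' @param gsd Geometric standard deviation, dimensionless, `>= 1`.
#' @param trunc Truncation half-width in units of GSDs (default 3). May be
#'   `Inf` for an untruncated lognormal.
#' @return An object of class `trunc_lognormal`.
#' @examples
#' d <- trunc_lognormal(10, 1.5)
#' range(tln_sample(d, 1000, seed = 1)) # within [10/1.5^3, 10*1.5^3]
#' tln_quantile(d, 0.5)                 # 10
#' @export
trunc_lognormal <- function(median, gsd, trunc = 3) {
  ok_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!ok_num(median) || median < 0)
    gr_abort("`median` must be a finite non-negative number",
             "goitrisk_invalid_distribution")
  if (!ok_num(gsd) || gsd < 1)
    gr_abort("`gsd` must be a finite number >= 1",
             "goitrisk_invalid_distribution")
  if (!(is.numeric(trunc) && length(trunc) == 1L && !is.na(trunc) && trunc > 0))
    gr_abort("`trunc` must be a positive number (possibly Inf)",
             "goitrisk_invalid_distribution")
  structure(
    list(median = as.numeric(median), gsd = as.numeric(gsd),
         trunc = as.numeric(trunc)),
    class = "trunc_lognormal"
  )
}

#' @export
print.trunc_lognormal <- function(x, ...) {
  cat(sprintf("<trunc_lognormal median=%g gsd=%g trunc=%g support=[%g, %g]>\n",
              x$median, x$gsd, x$trunc, tln_support(x)[1], tln_support(x)[2]))
  invisible(x)
}

#' @noRd
is_degenerate_tln <- function(d) d$median == 0 || d$gsd == 1

# Probability mass of the untruncated standard normal below -trunc / +trunc.
#' @noRd
tln_band <- function(d) {
  if (is.infinite(d$trunc)) c(0, 1) else c(stats::pnorm(-d$trunc), stats::pnorm(d$trunc))
}

#' Support of a truncated lognormal
#'
#' @param d A [trunc_lognormal()] object.
#' @return Numeric vector `c(lower, upper)`, equal to
#'   `median / gsd^trunc` and `median * gsd^trunc`.
#' @export
tln_support <- function(d) {
  if (is_degenerate_tln(d)) return(c(d$median, d$median))
  c(d$median / d$gsd^d$trunc, d$median * d$gsd^d$trunc)
}

#' Sample from a truncated lognormal
#'
#' Inverse-CDF sampling on the renormalised restricted normal in log space;
#' all draws fall inside the truncated support.
#'
#' @param d A [trunc_lognormal()] object.
#' @param n Number of draws (positive integer).
#' @param seed Optional integer seed; when supplied the draws are
#'   reproducible and the caller's RNG state is untouched.
#' @return Numeric vector of `n` non-negative draws.
#' @export
tln_sample <- function(d, n, seed = NULL) {
  stopifnot(inherits(d, "trunc_lognormal"))
  if (!(is.numeric(n) && length(n) == 1L && is.finite(n) && n >= 1))
    gr_abort("`n` must be a positive integer", "goitrisk_domain_error")
  n <- as.integer(n)
  if (is_degenerate_tln(d)) return(rep(d$median, n))
  u <- if (is.null(seed)) {
    stats::runif(n)
  } else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(as.integer(seed))
    stats::runif(n)
  }
  ab <- tln_band(d)
  z <- stats::qnorm(ab[1] + u * (ab[2] - ab[1]))
  d$median * d$gsd^z
}

#' Quantile of a truncated lognormal
#'
#' Closed form `median * gsd^z(p)` where `z(p)` is the quantile of a
#' standard normal restricted to `[-trunc, trunc]` with renormalised mass.
#' The median identity `tln_quantile(d, 0.5) == d$median` holds for every
#' `gsd` and `trunc` because the truncation is symmetric in log space.
#'
#' @param d A [trunc_lognormal()] object.
#' @param p Probabilities, all strictly inside (0, 1).
#' @return Numeric vector of quantiles, strictly increasing in `p`.
#' @export
tln_quantile <- function(d, p) {
  stopifnot(inherits(d, "trunc_lognormal"))
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    gr_abort("`p` must lie strictly inside (0, 1)", "goitrisk_domain_error")
  if (is_degenerate_tln(d)) return(rep(d$median, length(p)))
  ab <- tln_band(d)
  z <- stats::qnorm(ab[1] + p * (ab[2] - ab[1]))
  d$median * d$gsd^z
}

#' CDF of a truncated lognormal
#'
#' @param d A [trunc_lognormal()] object.
#' @param x Numeric vector of evaluation points.
#' @return `P(X <= x)`, clamped to `[0, 1]` outside the support.
#' @export
tln_cdf <- function(d, x) {
  stopifnot(inherits(d, "trunc_lognormal"))
  if (is_degenerate_tln(d)) return(as.numeric(x >= d$median))
  ab <- tln_band(d)
  z <- log(pmax(x, .Machine$double.xmin) / d$median) / log(d$gsd)
  pmin(pmax((stats::pnorm(z) - ab[1]) / (ab[2] - ab[1]), 0), 1)
}

#' Mean of a truncated lognormal
#'
#' Closed form: with `s = log(gsd)` and truncation at `t` GSDs,
#' `E[X] = median * exp(s^2/2) * (pnorm(t - s) - pnorm(-t - s)) / (pnorm(t) - pnorm(-t))`.
#'
#' @param d A [trunc_lognormal()] object.
#' @return The arithmetic mean of the distribution.
#' @export
tln_mean <- function(d) {
  stopifnot(inherits(d, "trunc_lognormal"))
  if (is_degenerate_tln(d)) return(d$median)
  d$median * tln_mean_factor(log(d$gsd), d$trunc)
}

# E[exp(s Z)] for Z standard normal truncated to [-t, t].
#' @noRd
tln_mean_factor <- function(s, t) {
  if (is.infinite(t)) return(exp(s^2 / 2))
  exp(s^2 / 2) * (stats::pnorm(t - s) - stats::pnorm(-t - s)) /
    (stats::pnorm(t) - stats::pnorm(-t))
}

#' Fit a truncated lognormal to percentile targets
#'
#' Finds the `(median, gsd)` pair whose quantiles minimise the sum of
#' squared log-errors against the supplied percentile targets. With exactly
#' two targets and no effective truncation the closed-form two-point
#' solution is exact: `gsd = exp((log v2 - log v1) / (z2 - z1))`. With
#' finite truncation the closed form seeds a numerical refinement.
#'
#' @param targets Named numeric vector mapping probabilities (names, e.g.
#'   `"0.5"`) to positive values, or a list with elements `p` and `value`.
#' @param trunc Truncation half-width in GSDs for the fitted distribution
#'   (default 3; `Inf` for untruncated).
#' @param fix_median Optional: hold the median at this value and fit only
#'   the GSD.
#' @param fix_gsd Optional: hold the GSD and fit only the median.
#' @return A [trunc_lognormal()] object.
#' @export
tln_fit <- function(targets, trunc = 3, fix_median = NULL, fix_gsd = NULL) {
  if (is.list(targets)) {
    p <- as.numeric(targets$p); v <- as.numeric(targets$value)
  } else {
    p <- as.numeric(names(targets)); v <- as.numeric(targets)
  }
  if (length(p) == 0 || anyNA(p) || anyNA(v))
    gr_abort("targets must map probabilities to values", "goitrisk_domain_error")
  if (any(p <= 0 | p >= 1) || any(v <= 0))
    gr_abort("target probabilities must lie in (0,1) and values be positive",
             "goitrisk_domain_error")
  o <- order(p); p <- p[o]; v <- v[o]
  if (any(duplicated(p)))
    gr_abort("duplicate target probabilities", "goitrisk_inconsistent_targets")
  if (any(diff(v) <= 0))
    gr_abort("target values must increase strictly with probability",
             "goitrisk_inconsistent_targets")
  n_free <- 2L - !is.null(fix_median) - !is.null(fix_gsd)
  if (length(p) < n_free)
    gr_abort(sprintf("%d target(s) cannot determine %d free parameter(s)",
                     length(p), n_free), "goitrisk_underdetermined")

  # closed-form initialisation from the two most extreme targets (or the
  # single target plus the fixed parameter)
  z <- stats::qnorm(p)
  if (is.null(fix_gsd)) {
    if (length(p) >= 2) {
      g0 <- exp((log(v[length(v)]) - log(v[1])) / (z[length(z)] - z[1]))
    } else {
      g0 <- 1.5
    }
    g0 <- max(g0, 1 + 1e-9)
  } else {
    g0 <- fix_gsd
  }
  m0 <- fix_median %||% exp(mean(log(v) - z * log(g0)))

  obj <- function(par) {
    m <- if (is.null(fix_median)) exp(par[["lm"]]) else fix_median
    g <- if (is.null(fix_gsd)) 1 + exp(par[["lg"]]) else fix_gsd
    q <- tln_quantile(trunc_lognormal(m, g, trunc), p)
    sum((log(q) - log(v))^2)
  }
  par <- c(
    if (is.null(fix_median)) c(lm = log(m0)),
    if (is.null(fix_gsd)) c(lg = log(max(g0 - 1, 1e-9)))
  )
  if (length(par) == 0L) {
    fit <- trunc_lognormal(fix_median, fix_gsd, trunc)
  } else if (length(par) == 1L) {
    which_free <- names(par)
    f1 <- function(x) obj(stats::setNames(x, which_free))
    opt <- stats::optimize(f1, interval = c(par[[1]] - 10, par[[1]] + 10),
                           tol = 1e-10)
    if (which_free == "lm") {
      fit <- trunc_lognormal(exp(opt$minimum), fix_gsd, trunc)
    } else {
      fit <- trunc_lognormal(fix_median, 1 + exp(opt$minimum), trunc)
    }
  } else {
    opt <- stats::optim(par, obj, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-12))
    fit <- trunc_lognormal(exp(opt$par[["lm"]]), 1 + exp(opt$par[["lg"]]), trunc)
  }
  fit
}
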