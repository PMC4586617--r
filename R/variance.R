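#' Contribution-to-variance decomposition
#'
#' Estimates the fraction of the inter-subject variation in composite PEC
#' intake attributable to each of the eight input factors: the six
#' agent-by-route concentrations (raw draws, before PEC weighting) and the
#' two exposure factors. The default estimator is the normalised squared
#' Spearman rank correlation between each factor's draws and the composite
#' total, `share_f = 100 * rho_f^2 / sum_g rho_g^2`, which sums to 100
#' exactly before rounding. Degenerate factors (zero spread, e.g.
#' thiocyanate in water) receive a share of 0.
#'
#' `method = "moment"` is a first-order variance-share cross-check for the
#' additive-in-components part of the model: each concentration factor
#' contributes `Var(C_f) * E[EF_r]^2 / d^2` and each exposure factor
#' `Var(EF_r) * (sum of mean route concentrations / d)^2`, normalised to
#' 100. It ignores product interaction terms and is not the default.
#'
#' @param samples An `adri_samples` object retaining `conc_draws` and
#'   `ef_draws` (as produced by [simulate_adri()]).
#' @param method `"spearman"` (default) or `"moment"`.
#' @return An object of class `cv_result`: list with `shares` (named
#'   percentages over the eight factors), `rho` (the raw correlations,
#'   spearman method only) and `method`.
#' @export
contribution_to_variance <- function(samples, method = c("spearman", "moment")) {
  method <- match.arg(method)
  if (is.null(samples$conc_draws) || is.null(samples$ef_draws))
    gr_abort("sample set does not retain per-factor draws", "goitrisk_insufficient_trace")
  draws <- c(samples$conc_draws, list(samples$ef_draws$water, samples$ef_draws$food))
  names(draws) <- cv_factor_names()

  if (method == "spearman") {
    rho <- vapply(draws, function(x) {
      if (stats::sd(x) == 0 || stats::sd(samples$total) == 0) return(0)
      suppressWarnings(stats::cor(x, samples$total, method = "spearman"))
    }, numeric(1))
    rho[!is.finite(rho)] <- 0
    denom <- sum(rho^2)
    shares <- if (denom > 0) 100 * rho^2 / denom else rho * 0
    return(structure(list(shares = shares, rho = rho, method = method),
                     class = "cv_result"))
  }

  # moment method: first-order additive variance shares
  div <- pec_divisors(samples$basis)
  endo <- 1 # endogenous multiplier already folded into components; shares unaffected
  agents <- names(div)
  mean_ef <- c(water = mean(samples$ef_draws$water), food = mean(samples$ef_draws$food))
  contrib <- numeric(8)
  names(contrib) <- cv_factor_names()
  for (route in c("water", "food")) {
    for (a in agents) {
      f <- paste0(a, "_", route, "_conc")
      contrib[[f]] <- stats::var(draws[[paste0(a, "_", route, "_conc")]]) *
        (mean_ef[[route]] / div[[a]])^2 * endo
    }
    conc_sum <- sum(vapply(agents, function(a)
      mean(draws[[paste0(a, "_", route, "_conc")]]) / div[[a]], numeric(1)))
    contrib[[paste0(route, "_EF")]] <-
      stats::var(samples$ef_draws[[route]]) * conc_sum^2
  }
  shares <- 100 * contrib / sum(contrib)
  structure(list(shares = shares, rho = NULL, method = method), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result (%s): sum=%.6f>\n", x$method, sum(x$shares)))
  print(round(x$shares, 1))
  invisible(x)
}
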