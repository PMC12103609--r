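# Monte Carlo simulation envelopes and Diggle's goodness-of-fit test.
#
# For any fitted model, `n_sims` patterns are drawn from it and each is
# summarised by the same homogeneous PCF estimator (identical grid,
# bandwidth and edge correction) applied to the observed pattern.  The
# pointwise envelope discards the `n_drop` most extreme simulated values in
# each tail at every radius; study fidelity is 9999 simulations with 500
# trimmed per tail, while tests and examples run at reduced counts.
#
# Diggle's test ranks the integrated squared deviation of each curve from
# the leave-one-out mean of all the others; p_d near 0 flags a poor fit of
# the observed pattern to the model, p_d near 1 a good one.

#' Monte Carlo simulation envelope for a fitted model
#'
#' @param fit a [fit_model()] object (with a stored pattern).
#' @param n_sims number of simulated patterns (study fidelity: 9999).
#' @param n_drop simulations discarded per tail at each radius; default
#'   `(n_sims + 1) / 20`, i.e. 5 percent (500 of 9999).
#' @param seed optional integer seed; replicate sub-streams are split
#'   deterministically.
#' @return an object of class `"coral_envelope"`: fields `r`, `obs`
#'   (observed g), `lo`, `hi` (envelope bounds), `sims` (the full simulated
#'   g matrix, radii x simulations), `n_sims`, `n_drop`, `fit`.
#' @examples
#' p <- simulate_csr(study_window(), 0.005, seed = 1)
#' env <- mc_envelope(fit_model(p, "csr"), n_sims = 39, seed = 2)
#' @export
mc_envelope <- function(fit, n_sims = 199, n_drop = (n_sims + 1) %/% 20,
                        seed = NULL) {
  stopifnot(inherits(fit, "coral_ppm"))
  if (is.null(fit$pattern))
    stop("the fit does not store its pattern; refit with fit_model()", call. = FALSE)
  if (n_drop < 0 || 2 * n_drop >= n_sims)
    stop("'n_drop' must satisfy 0 <= 2 n_drop < n_sims", call. = FALSE)
  st <- fit$settings
  obs <- pair_correlation(fit$pattern, r_max = st$r_max, step = st$step,
                          bandwidth = st$bandwidth, correction = st$correction)
  pats <- simulate(fit, nsim = n_sims, seed = seed)
  degenerate <- 0L
  sims <- vapply(pats, function(p) {
    if (p$n < 2) { degenerate <<- degenerate + 1L; rep(1, length(obs$r)) }
    else pair_correlation(p, r_max = st$r_max, step = st$step,
                          bandwidth = st$bandwidth, correction = st$correction)$g
  }, numeric(length(obs$r)))
  if (degenerate > 0L)
    warning(sprintf("%d simulated pattern(s) had fewer than 2 points; their g was recorded as the CSR reference value 1",
                    degenerate), call. = FALSE)
  sorted <- apply(sims, 1, sort)           # n_sims x n_r
  structure(list(r = obs$r, obs = obs$g, lo = sorted[n_drop + 1L, ],
                 hi = sorted[n_sims - n_drop, ], sims = sims,
                 n_sims = n_sims, n_drop = n_drop, fit = fit, seed = seed,
                 obs_pcf = obs),
            class = "coral_envelope")
}

#' @export
print.coral_envelope <- function(x, ...) {
  cat(sprintf("Monte Carlo envelope: %d simulations of the %s model, %d trimmed per tail\n",
              x$n_sims, x$fit$model, x$n_drop))
  invisible(x)
}

#' @export
plot.coral_envelope <- function(x, ...) {
  plot(x$obs_pcf, envelope = x, ...)
}

trapz_weights <- function(r, step) {
  w <- rep(step, length(r)); w[c(1, length(r))] <- step / 2; w
}

#' Diggle's goodness-of-fit test
#'
#' For the observed curve and each simulated curve the statistic
#' `u_i = integral over r_range of (g_i(r) - gbar_{-i}(r))^2 dr` is computed
#' (trapezoid rule on the estimation grid), where `gbar_{-i}` is the mean of
#' all the *other* curves.  The rank p-value is
#' `p_d = #(u_sim >= u_obs) / (n_sims + 1)`, the observation counted once in
#' the denominator, with floor `1 / (n_sims + 1)`.
#'
#' @param envelope a [mc_envelope()] (the stored simulation matrix is
#'   reused; no new simulation is run).
#' @param r_range radii (cm) over which the deviation is integrated; default
#'   the full estimation grid.  Cluster-model fits in the study design are
#'   additionally tested on restricted 10 cm and 20 cm ranges.
#' @return an object of class `"coral_gof"`: fields `u_obs`, `u_sims`,
#'   `p_d`, `r_range`, `n_sims`.
#' @export
diggle_gof <- function(envelope, r_range = NULL) {
  stopifnot(inherits(envelope, "coral_envelope"))
  if (is.null(r_range)) r_range <- range(envelope$r)
  if (r_range[1] < min(envelope$r) - 1e-9 || r_range[2] > max(envelope$r) + 1e-9)
    stop("r_range lies outside the estimation grid", call. = FALSE)
  idx <- which(envelope$r >= r_range[1] - 1e-9 & envelope$r <= r_range[2] + 1e-9)
  if (length(idx) < 2) stop("r_range covers too few grid points", call. = FALSE)
  X <- cbind(envelope$obs[idx], envelope$sims[idx, , drop = FALSE])
  N <- ncol(X)
  wts <- trapz_weights(envelope$r[idx], envelope$fit$settings$step)
  tot <- rowSums(X)
  dev <- (N * X - tot) / (N - 1)       # X_i - mean of the others
  u <- colSums(wts * dev * dev)
  p_d <- max(1, sum(u[-1] >= u[1])) / (envelope$n_sims + 1)
  structure(list(u_obs = u[1], u_sims = u[-1], p_d = p_d,
                 r_range = r_range, n_sims = envelope$n_sims,
                 model = envelope$fit$model),
            class = "coral_gof")
}

#' @export
print.coral_gof <- function(x, ...) {
  cat(sprintf("Diggle GoF (%s model): u_obs = %.4g over (%.1f, %.1f) cm, p_d = %.4f (%d sims)\n",
              x$model, x$u_obs, x$r_range[1], x$r_range[2], x$p_d, x$n_sims))
  invisible(x)
}

#' Fit and test all candidate models for one site and morph
#'
#' Runs the full single-pattern model comparison: fits CSR and TC always,
#' HP and HTC when a substrate mask is available (otherwise they are skipped
#' with a message), builds a Monte Carlo envelope for each fitted model, and
#' evaluates Diggle's test — over the full radius range for CSR/HP/HTC and
#' over both restricted 10 cm and 20 cm ranges for TC (the headline TC value
#' being the 10 cm range).  The best model is the one with the largest p_d.
#'
#' @param site a [coral_site()].
#' @param morph `"orange"` or `"pink"`; the pattern must have at least 30
#'   points.
#' @param n_sims,n_drop envelope settings, see [mc_envelope()].
#' @param seed integer seed; model sub-streams are derived from
#'   (seed, site_id, morph, model).
#' @param fit_range minimum-contrast range (cm).
#' @param tc_gof_ranges upper GoF radii (cm) for the TC model.
#' @param r_max,step,bandwidth,correction PCF settings.
#' @param models candidate models to consider.
#' @return an object of class `"model_comparison"`: fields `fits`,
#'   `envelopes`, `gofs` (named `csr`, `hp`, `tc10`, `tc20`, `htc` as
#'   available), `pd` (named vector), `best`.
#' @export
evaluate_models <- function(site, morph, n_sims = 199,
                            n_drop = (n_sims + 1) %/% 20, seed = 1L,
                            fit_range = c(0.1, 25), tc_gof_ranges = c(10, 20),
                            r_max = 50, step = 0.1, bandwidth = 5,
                            correction = "translation",
                            models = c("csr", "hp", "tc", "htc")) {
  stopifnot(inherits(site, "coral_site"))
  pattern <- site$patterns[[morph]]
  if (is.null(pattern)) stop(sprintf("site %s has no %s pattern", site$site_id, morph),
                             call. = FALSE)
  if (pattern$n < MIN_ANALYSABLE)
    stop(sprintf("pattern has %d < %d points and is not analysable",
                 pattern$n, MIN_ANALYSABLE), call. = FALSE)
  if (is.null(site$mask) && any(c("hp", "htc") %in% models)) {
    message(sprintf("site %s: no substrate mask; HP/HTC skipped", site$site_id))
    models <- setdiff(models, c("hp", "htc"))
  }
  fits <- list(); envs <- list(); gofs <- list()
  for (m in models) {
    fit <- fit_model(pattern, m, mask = site$mask, fit_range = fit_range,
                     r_max = r_max, step = step, bandwidth = bandwidth,
                     correction = correction)
    env <- mc_envelope(fit, n_sims = n_sims, n_drop = n_drop,
                       seed = derive_seed(seed, site$site_id, morph, m))
    fits[[m]] <- fit; envs[[m]] <- env
    if (m == "tc") {
      for (rr in tc_gof_ranges)
        gofs[[sprintf("tc%g", rr)]] <- diggle_gof(env, c(step, rr))
    } else {
      gofs[[m]] <- diggle_gof(env, c(step, r_max))
    }
  }
  pd <- vapply(gofs, function(g) g$p_d, 0)
  # headline comparison: one value per model, TC represented by its first
  # (10 cm) restricted range
  headline <- pd[setdiff(names(pd), sprintf("tc%g", tc_gof_ranges[-1]))]
  names(headline)[names(headline) == sprintf("tc%g", tc_gof_ranges[1])] <- "tc"
  best <- names(headline)[which.max(headline)]
  structure(list(site_id = site$site_id, morph = morph, fits = fits,
                 envelopes = envs, gofs = gofs, pd = pd,
                 pd_headline = headline, best = best),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Model comparison for %s / %s\n", x$site_id, x$morph))
  for (nm in names(x$pd))
    cat(sprintf("  %-5s p_d = %.4f\n", nm, x$pd[[nm]]))
  cat("  best model:", x$best, "\n")
  invisible(x)
}
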