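# Candidate generative models and their fitting.
#
# Four processes are entertained for each observed pattern:
#   csr  homogeneous Poisson (complete spatial randomness),
#   hp   heterogeneous Poisson with piecewise-constant intensity per
#        substrate category,
#   tc   Thomas cluster process (Poisson parents, Poisson offspring,
#        Gaussian dispersal) fitted by minimum contrast on the PCF,
#   htc  Thomas cluster process independently thinned by the normalised
#        substrate intensities, fitted by minimum contrast on the
#        inhomogeneous PCF (which is invariant under independent thinning).
#
# Minimum contrast matches the *smoothed* theoretical curve to the smoothed
# empirical estimate: the expectation of the kernel PCF estimator at grid
# radius r is T(r) = (1/r) * integral k(r - s) s g(s) ds, so contrasting
# against T rather than g removes the smoothing bias that would otherwise
# inflate the fitted dispersal scale when the kernel half-width (5 cm) is
# comparable to sigma (2-3 cm).

#' Theoretical pair correlation function of a Thomas process
#'
#' `g(r) = 1 + exp(-r^2 / (4 sigma^2)) / (4 pi kappa sigma^2)`: always
#' >= 1, strictly decreasing in r, approaching 1 as r grows.
#'
#' @param r radii (cm), vectorised.
#' @param kappa parent intensity (parents/cm^2, > 0).
#' @param sigma dispersal scale (cm, > 0).
#' @return g(r) values.
#' @examples
#' thomas_pcf(0, kappa = 1 / (4 * pi), sigma = 1)  # 2
#' @export
thomas_pcf <- function(r, kappa, sigma) {
  if (!is.numeric(kappa) || length(kappa) != 1L || is.na(kappa) || kappa <= 0)
    stop("'kappa' must be a single number > 0", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma <= 0)
    stop("'sigma' must be a single number > 0", call. = FALSE)
  1 + exp(-r^2 / (4 * sigma^2)) / (4 * pi * kappa * sigma^2)
}

# Linear operator mapping a theoretical g(s) on the s grid to the expected
# value of the kernel estimator on the r grid:
#   T(r) = sum_s trapz_w(s) k(r - s) g(s) / c(r)
# where c(r) is the boundary renormalisation of pair_correlation().
# Returns a matrix K so that T = K %*% g(s_grid); for a constant g = 1 the
# result is exactly 1 at every r, matching the estimator's expectation under
# complete spatial randomness.
smoothing_operator <- function(r, bandwidth, step) {
  s <- seq(0, max(r) + bandwidth, by = step)
  wts <- rep(step, length(s)); wts[c(1, length(s))] <- step / 2
  u <- outer(r, s, "-") / bandwidth
  K <- 0.75 / bandwidth * pmax(1 - u * u, 0)
  K <- K * rep(wts, each = length(r)) / kernel_mass(r, bandwidth)
  list(K = K, s = s)
}

#' Mean offspring in a non-empty cluster
#'
#' Conditional on a cluster containing at least one settled recruit, its
#' expected size under Poisson(mu) offspring is the zero-truncated Poisson
#' mean `mu / (1 - exp(-mu))`; the continuous limit at mu = 0 is 1.
#'
#' @param mu mean offspring per parent (>= 0), vectorised.
#' @return expected size of a non-empty cluster (always >= max(1, mu)).
#' @examples
#' offspring_nonempty(1)  # 1.582...
#' @export
offspring_nonempty <- function(mu) {
  if (!is.numeric(mu) || any(is.na(mu)) || any(mu < 0))
    stop("'mu' must be >= 0", call. = FALSE)
  ifelse(mu < 1e-12, 1, mu / (-expm1(-mu)))
}

#' Probability that an individual belongs to a cluster
#'
#' Under the Palm distribution of a Thomas process the number of same-cluster
#' siblings of a typical point is Poisson(mu), so the probability of having
#' at least one sibling — i.e. of belonging to a cluster of size >= 2 — is
#' `1 - exp(-mu)`.
#'
#' @param mu mean offspring per parent (>= 0), vectorised.
#' @return probability in [0, 1).
#' @examples
#' prob_in_cluster(log(2))  # 0.5
#' @export
prob_in_cluster <- function(mu) {
  if (!is.numeric(mu) || any(is.na(mu)) || any(mu < 0))
    stop("'mu' must be >= 0", call. = FALSE)
  -expm1(-mu)
}

#' Fit a Thomas cluster process by minimum contrast
#'
#' Minimises `integral over fit_range of (g^(r)^q - T_theta(r)^q)^2 dr`
#' (q = 1/4, trapezoid rule on the estimate's grid) over (kappa, sigma),
#' where `T_theta` is the theoretical Thomas PCF passed through the same
#' kernel smoothing as the empirical estimate (no smoothing is applied when
#' the estimate declares `bandwidth = 0`).  `mu` is derived as
#' `lambda / kappa`.  The optimiser is a deterministic Nelder-Mead search in
#' log-parameter space from a moment-based start, so the fit is a pure
#' function of the estimate.
#'
#' @param pcf a [pair_correlation()] estimate (homogeneous or
#'   inhomogeneous).
#' @param fit_range radii (cm) over which the contrast is integrated.
#' @param q contrast exponent.
#' @param lambda overall intensity used for `mu = lambda / kappa`; defaults
#'   to the estimate's.
#' @param kappa_bounds,sigma_bounds admissible parameter boxes; a fit ending
#'   on a bound is flagged `converged = FALSE`.
#' @return an object of class `"coral_ppm"` with `model = "tc"`.
#' @export
fit_thomas_min_contrast <- function(pcf, fit_range = c(0.1, 25), q = 0.25,
                                    lambda = NULL,
                                    kappa_bounds = c(1e-6, 1),
                                    sigma_bounds = c(0.1, 50)) {
  stopifnot(inherits(pcf, "coral_pcf"))
  if (is.null(lambda)) lambda <- pcf$lambda
  idx <- which(pcf$r >= fit_range[1] - 1e-9 & pcf$r <= fit_range[2] + 1e-9)
  if (length(idx) < 5) stop("fit_range covers too few grid points", call. = FALSE)
  r <- pcf$r[idx]
  gobs <- pmax(pcf$g[idx], 0)
  wts <- rep(pcf$step, length(r)); wts[c(1, length(r))] <- pcf$step / 2
  gq <- gobs^q

  smooth <- pcf$bandwidth > 0
  if (smooth) op <- smoothing_operator(r, pcf$bandwidth, pcf$step)

  theo <- function(kappa, sigma) {
    if (smooth) {
      gth <- thomas_pcf(op$s, kappa, sigma)
      gth[op$s == 0] <- thomas_pcf(0, kappa, sigma)
      pmax(drop(op$K %*% gth), 0)
    } else thomas_pcf(r, kappa, sigma)
  }
  objective <- function(par) {
    kappa <- exp(par[1]); sigma <- exp(par[2])
    sum(wts * (gq - theo(kappa, sigma)^q)^2)
  }

  # moment-based start: excess amplitude gives kappa, half-decay radius
  # gives sigma (excess halves at r = 2 sigma sqrt(log 2))
  excess <- gobs - 1
  e0 <- max(excess)
  if (e0 > 0.01) {
    i0 <- which.max(excess)
    past <- which(excess <= e0 / 2 & seq_along(excess) > i0)
    r_half <- if (length(past)) r[past[1]] else r[length(r)] / 2
    sigma0 <- max(sigma_bounds[1], min(sigma_bounds[2], r_half / (2 * sqrt(log(2)))))
    kappa0 <- max(kappa_bounds[1], min(kappa_bounds[2], 1 / (4 * pi * sigma0^2 * e0)))
  } else {
    sigma0 <- 2; kappa0 <- max(kappa_bounds[1], min(kappa_bounds[2], lambda))
  }
  lower <- log(c(kappa_bounds[1], sigma_bounds[1]))
  upper <- log(c(kappa_bounds[2], sigma_bounds[2]))
  fit <- optim(log(c(kappa0, sigma0)), objective, method = "L-BFGS-B",
               lower = lower, upper = upper,
               control = list(factr = 10, maxit = 500))
  fit <- optim(fit$par, objective, method = "L-BFGS-B",
               lower = lower, upper = upper,
               control = list(factr = 10, maxit = 500))
  kappa <- exp(fit$par[1]); sigma <- exp(fit$par[2])

  tol <- 1e-6
  at_bound <- kappa <= kappa_bounds[1] * (1 + tol) || kappa >= kappa_bounds[2] * (1 - tol) ||
    sigma <= sigma_bounds[1] * (1 + tol) || sigma >= sigma_bounds[2] * (1 - tol)
  if (at_bound)
    warning("minimum-contrast optimum at a parameter bound; fit flagged non-converged",
            call. = FALSE)

  structure(list(model = "tc", lambda = lambda, kappa = kappa, sigma = sigma,
                 mu = lambda / kappa, category_intensities = NULL,
                 contrast = fit$value, fit_range = fit_range, q = q,
                 converged = !at_bound, pcf = pcf, pattern = NULL,
                 mask = NULL, window = pcf$window,
                 settings = list(step = pcf$step, bandwidth = pcf$bandwidth,
                                 correction = pcf$correction,
                                 r_max = max(pcf$r))),
            class = "coral_ppm")
}

#' Fit a point process model to an observed pattern
#'
#' The central model-fitting interface.  `"csr"` fits the homogeneous
#' Poisson intensity; `"hp"` fits one intensity per substrate category
#' (`lambda_c = n_c / area_c`); `"tc"` estimates the PCF and fits a Thomas
#' process by minimum contrast; `"htc"` first fits the substrate
#' intensities, then fits the Thomas parameters by minimum contrast on the
#' inhomogeneous PCF with those plug-in intensities.
#'
#' @param pattern a [point_pattern()].
#' @param model one of `"csr"`, `"hp"`, `"tc"`, `"htc"`.
#' @param mask a [substrate_mask()]; required for `"hp"` and `"htc"`.
#' @param fit_range minimum-contrast integration range (cm).
#' @param r_max,step,bandwidth,correction PCF settings, see
#'   [pair_correlation()].
#' @return an object of class `"coral_ppm"`; see [coef.coral_ppm()],
#'   [summary.coral_ppm()], [simulate.coral_ppm()].
#' @examples
#' p <- simulate_thomas(study_window(), 0.002, 2, 2, seed = 1)
#' fit <- fit_model(p, "tc")
#' coef(fit)
#' @export
fit_model <- function(pattern, model = c("csr", "hp", "tc", "htc"),
                      mask = NULL, fit_range = c(0.1, 25), r_max = 50,
                      step = 0.1, bandwidth = 5,
                      correction = c("translation", "isotropic")) {
  stopifnot(is_ppp(pattern))
  model <- match.arg(model)
  correction <- match.arg(correction)
  lambda <- pattern_intensity(pattern)
  win <- pattern$window
  settings <- list(step = step, bandwidth = bandwidth,
                   correction = correction, r_max = r_max)
  base <- list(model = model, lambda = lambda, kappa = NULL, sigma = NULL,
               mu = NULL, category_intensities = NULL, contrast = NULL,
               fit_range = NULL, q = NULL, converged = TRUE, pcf = NULL,
               pattern = pattern, mask = mask, window = win,
               settings = settings)

  if (model %in% c("hp", "htc")) {
    if (is.null(mask)) stop(sprintf("model '%s' requires a substrate mask", model),
                            call. = FALSE)
    areas <- category_areas(mask)
    counts <- tabulate(point_category(mask, pattern$x, pattern$y),
                       nbins = length(mask$categories))
    names(counts) <- mask$categories
    if (any(counts > 0 & areas == 0))
      stop("points assigned to a zero-area substrate category", call. = FALSE)
    lam_c <- ifelse(areas > 0, counts / areas, 0)
    base$category_intensities <- setNames(lam_c, mask$categories)
  }

  if (model == "csr") {
    out <- base
  } else if (model == "hp") {
    out <- base
  } else if (model == "tc") {
    if (pattern$n < MIN_ANALYSABLE)
      warning(sprintf("pattern has %d < %d points; cluster fit may be unstable",
                      pattern$n, MIN_ANALYSABLE), call. = FALSE)
    est <- pair_correlation(pattern, r_max = r_max, step = step,
                            bandwidth = bandwidth, correction = correction)
    out <- unclass(fit_thomas_min_contrast(est, fit_range = fit_range,
                                           lambda = lambda))
    out$pattern <- pattern; out$mask <- mask; out$settings <- settings
  } else { # htc
    if (pattern$n < MIN_ANALYSABLE)
      warning(sprintf("pattern has %d < %d points; cluster fit may be unstable",
                      pattern$n, MIN_ANALYSABLE), call. = FALSE)
    lam_pts <- base$category_intensities[point_category(mask, pattern$x, pattern$y)]
    est <- pair_correlation(pattern, r_max = r_max, step = step,
                            bandwidth = bandwidth, correction = correction,
                            lambda_points = unname(lam_pts))
    tc <- unclass(fit_thomas_min_contrast(est, fit_range = fit_range,
                                          lambda = lambda))
    out <- base
    out[c("kappa", "sigma", "mu", "contrast", "fit_range", "q",
          "converged", "pcf")] <-
      tc[c("kappa", "sigma", "mu", "contrast", "fit_range", "q",
           "converged", "pcf")]
    out$model <- "htc"
  }
  structure(out, class = "coral_ppm")
}

#' @export
print.coral_ppm <- function(x, ...) {
  label <- c(csr = "Homogeneous Poisson (CSR)",
             hp = "Heterogeneous Poisson",
             tc = "Thomas cluster",
             htc = "Heterogeneous Thomas cluster")[x$model]
  cat(label, "model fit\n")
  cat(sprintf("  intensity lambda: %.6g points/cm2 (%.1f /m2)\n",
              x$lambda, x$lambda * 1e4))
  if (!is.null(x$category_intensities)) {
    for (nm in names(x$category_intensities))
      cat(sprintf("  lambda[%s]: %.6g points/cm2\n", nm,
                  x$category_intensities[[nm]]))
  }
  if (!is.null(x$kappa)) {
    cat(sprintf("  kappa: %.6g parents/cm2, sigma: %.3g cm, mu: %.3g offspring/parent\n",
                x$kappa, x$sigma, x$mu))
    cat(sprintf("  contrast %.4g over (%.1f, %.1f) cm%s\n", x$contrast,
                x$fit_range[1], x$fit_range[2],
                if (x$converged) "" else "  [NOT converged]"))
  }
  invisible(x)
}

#' Model coefficients
#' @param object a fitted [fit_model()] object.
#' @param ... unused.
#' @return named vector: `lambda`, plus `kappa`, `sigma`, `mu` for cluster
#'   models and per-category intensities for heterogeneous models.
#' @export
coef.coral_ppm <- function(object, ...) {
  out <- c(lambda = object$lambda)
  if (!is.null(object$kappa))
    out <- c(out, kappa = object$kappa, sigma = object$sigma, mu = object$mu)
  if (!is.null(object$category_intensities))
    out <- c(out, setNames(object$category_intensities,
                           paste0("lambda.", names(object$category_intensities))))
  out
}

#' Summary of a fitted point process model
#'
#' For cluster models the summary adds the reproductive diagnostics derived
#' from the fitted `mu`: the zero-truncated mean cluster size
#' ([offspring_nonempty()]) and the cluster-membership probability
#' ([prob_in_cluster()]).
#'
#' @param object a fitted [fit_model()] object.
#' @param ... unused.
#' @return an object of class `"summary.coral_ppm"`.
#' @export
summary.coral_ppm <- function(object, ...) {
  out <- list(model = object$model, coef = coef(object),
              n = if (!is.null(object$pattern)) object$pattern$n else NA_integer_,
              converged = object$converged)
  if (!is.null(object$mu)) {
    out$offspring_nonempty <- offspring_nonempty(object$mu)
    out$prob_in_cluster <- prob_in_cluster(object$mu)
  }
  structure(out, class = "summary.coral_ppm")
}

#' @export
print.summary.coral_ppm <- function(x, ...) {
  cat(sprintf("Model %s (n = %s)%s\n", x$model, x$n,
              if (x$converged) "" else "  [NOT converged]"))
  print(round(x$coef, 6))
  if (!is.null(x$offspring_nonempty))
    cat(sprintf("  offspring per non-empty cluster: %.4f\n  P(individual in a cluster): %.4f\n",
                x$offspring_nonempty, x$prob_in_cluster))
  invisible(x)
}

#' Simulate from a fitted model
#'
#' Draws patterns from the fitted generative process in the fitted window:
#' CSR and HP simulate Poisson processes at the fitted intensities; TC
#' simulates a Thomas process at the fitted `(kappa, sigma, mu)` (counts
#' vary across replicates as the model implies, rather than conditioning on
#' the observed n); HTC simulates a Thomas process at the maximal category
#' intensity and thins it by the normalised substrate intensities.
#'
#' @param object a fitted [fit_model()] object.
#' @param nsim number of patterns.
#' @param seed optional integer seed (sub-streams split per replicate).
#' @param ... unused.
#' @return a list of [point_pattern()]s of length `nsim`.
#' @export
simulate.coral_ppm <- function(object, nsim = 1, seed = NULL, ...) {
  one <- function(k) {
    s <- if (is.null(seed)) NULL else derive_seed(seed, "sim", k)
    switch(object$model,
           csr = simulate_csr(object$window, object$lambda, seed = s),
           hp = simulate_hetero_poisson(
             intensity_map(object$mask, object$category_intensities), seed = s),
           tc = simulate_thomas(object$window, object$kappa, object$sigma,
                                object$mu, seed = s),
           htc = {
             lam_c <- object$category_intensities
             lmax <- max(lam_c)
             base <- simulate_thomas(object$window, object$kappa, object$sigma,
                                     lmax / object$kappa, seed = s)
             if (base$n == 0) base
             else {
               retain <- (lam_c / lmax)[point_category(object$mask, base$x, base$y)]
               keep <- with_seed(if (is.null(s)) NULL else derive_seed(s, "thin"),
                                 runif(base$n) < retain)
               point_pattern(base$x[keep], base$y[keep], object$window)
             }
           })
  }
  lapply(seq_len(nsim), one)
}

#' Predicted intensity surface
#'
#' @param object a fitted [fit_model()] object.
#' @param newdata optional data.frame with `x_cm`, `y_cm`; defaults to the
#'   fitted pattern's locations.
#' @param ... unused.
#' @return intensity (points/cm^2) at each location: constant `lambda` for
#'   homogeneous models, the category intensity for heterogeneous ones.
#' @export
predict.coral_ppm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    if (is.null(object$pattern)) stop("no fitted pattern stored; supply newdata",
                                      call. = FALSE)
    newdata <- data.frame(x_cm = object$pattern$x, y_cm = object$pattern$y)
  }
  if (is.null(object$category_intensities))
    rep(object$lambda, nrow(newdata))
  else
    unname(object$category_intensities[
      point_category(object$mask, newdata$x_cm, newdata$y_cm)])
}

#' Plot an observed PCF against the fitted cluster model
#'
#' @param x a fitted [fit_model()] object with a stored PCF (tc/htc).
#' @param ... forwarded to [plot.coral_pcf()].
#' @export
plot.coral_ppm <- function(x, ...) {
  if (is.null(x$pcf)) stop("no PCF stored for this model", call. = FALSE)
  plot(x$pcf, ...)
  if (!is.null(x$kappa)) {
    op <- smoothing_operator(x$pcf$r, x$pcf$bandwidth, x$pcf$step)
    lines(x$pcf$r, drop(op$K %*% thomas_pcf(op$s, x$kappa, x$sigma)),
          col = "red3", lwd = 1.5, lty = 2)
    legend("topright", legend = c("observed", "fitted"), lwd = 1.5,
           lty = c(1, 2), col = c("black", "red3"), bty = "n")
  }
  invisible(x)
}
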