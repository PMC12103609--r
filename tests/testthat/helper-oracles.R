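# Independent oracles used across the suite.  These deliberately use the
# slowest, most literal formulation of each quantity (double loops, numeric
# integration, pmf enumeration) and share no code with the package
# internals they check.

# kernel mass above zero distance, by numerical quadrature (independent of
# the package's closed form)
kernel_mass_numeric <- function(r, h) {
  sapply(r, function(rr)
    integrate(function(s) ifelse(abs(rr - s) < h,
                                 0.75 / h * (1 - ((rr - s) / h)^2), 0),
              max(0, rr - h), rr + h, rel.tol = 1e-12)$value)
}

# brute-force kernel PCF with translation edge correction (divisor-d)
brute_pcf_translation <- function(p, r, h) {
  n <- p$n; W <- p$window$width; H <- p$window$height; A <- W * H
  cr <- kernel_mass_numeric(r, h)
  g <- numeric(length(r))
  for (jj in seq_along(r)) {
    s <- 0
    for (i in 1:n) for (j in 1:n) if (i != j) {
      dxx <- abs(p$x[i] - p$x[j]); dyy <- abs(p$y[i] - p$y[j])
      d <- sqrt(dxx^2 + dyy^2); u <- r[jj] - d
      if (abs(u) < h)
        s <- s + 0.75 / h * (1 - (u / h)^2) / ((W - dxx) * (H - dyy)) / (2 * pi * d)
    }
    g[jj] <- s * A * A / (n * (n - 1)) / cr[jj]
  }
  g
}

# circle-inside-window fraction by angular quadrature (isotropic oracle)
arc_fraction_numeric <- function(x, y, d, W, H, K = 40000) {
  th <- (seq_len(K) - 0.5) / K * 2 * pi
  px <- x + d * cos(th); py <- y + d * sin(th)
  mean(px >= 0 & px <= W & py >= 0 & py <= H)
}

brute_pcf_isotropic <- function(p, r, h) {
  n <- p$n; W <- p$window$width; H <- p$window$height; A <- W * H
  cr <- kernel_mass_numeric(r, h)
  g <- numeric(length(r))
  for (jj in seq_along(r)) {
    s <- 0
    for (i in 1:n) for (j in 1:n) if (i != j) {
      d <- sqrt((p$x[i] - p$x[j])^2 + (p$y[i] - p$y[j])^2); u <- r[jj] - d
      if (abs(u) < h)
        s <- s + 0.75 / h * (1 - (u / h)^2) /
          arc_fraction_numeric(p$x[i], p$y[i], d, W, H) / A / (2 * pi * d)
    }
    g[jj] <- s * A * A / (n * (n - 1)) / cr[jj]
  }
  g
}

# O(n^2) nearest-neighbour distances
brute_nn <- function(p) {
  sapply(seq_len(p$n), function(i) {
    min(sqrt((p$x[i] - p$x[-i])^2 + (p$y[i] - p$y[-i])^2))
  })
}

# zero-truncated Poisson mean by pmf enumeration
ztp_mean_enumerated <- function(mu, kmax = 100) {
  k <- 1:kmax
  pmf <- exp(-mu) * mu^k / factorial(k)
  sum(k * pmf) / sum(pmf)
}

# tiny deterministic site fixture: n_orange / n_pink jittered grid points
fixture_site <- function(n_orange, n_pink, window = study_window(),
                         site_id = "fix1", seed = 99, mask = NULL) {
  set.seed(seed)
  mk <- function(n, m) {
    if (n == 0) return(NULL)
    point_pattern(runif(n, 0, window$width), runif(n, 0, window$height),
                  window, morph = m)
  }
  pats <- Filter(Negate(is.null),
                 list(orange = mk(n_orange, "orange"), pink = mk(n_pink, "pink")))
  coral_site(site_id, pats, mask = mask)
}
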