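# Candidate processes: closed forms, minimum-contrast fitting, reproductive
# diagnostics.

test_that("Thomas closed-form PCF has the right limits and monotonicity", {
  expect_equal(thomas_pcf(100 * 1, 0.01, 1), 1, tolerance = 1e-12)
  # kappa sigma^2 = 1/(4 pi) makes the excess at r = 0 exactly 1
  expect_equal(thomas_pcf(0, 1 / (4 * pi), 1), 2)
  expect_error(thomas_pcf(1, 0, 1), "kappa")
  expect_error(thomas_pcf(1, 0.01, -2), "sigma")

  # strict monotonicity where the excess is above floating-point underflow
  r <- seq(0, 12, 0.5)
  g <- thomas_pcf(r, 0.004, 2)
  expect_true(all(diff(g) < 0))
  expect_true(all(g >= 1))
  expect_true(all(thomas_pcf(seq(0, 100, 1), 0.004, 2) >= 1))
  # decreasing in kappa at fixed r, sigma
  expect_true(all(thomas_pcf(r, 0.008, 2) < g))
})

test_that("minimum contrast recovers parameters exactly from a noiseless curve", {
  w <- study_window()
  r <- seq(0.1, 25, 0.1)
  exact <- structure(list(r = r, g = thomas_pcf(r, 0.004, 2), bandwidth = 0,
                          correction = "translation", lambda = 0.012, n = 300,
                          window = w, step = 0.1, inhomogeneous = FALSE),
                     class = "coral_pcf")
  fit <- fit_thomas_min_contrast(exact)
  expect_lt(abs(fit$kappa - 0.004) / 0.004, 1e-4)
  expect_lt(abs(fit$sigma - 2) / 2, 1e-4)
  expect_equal(fit$mu, fit$lambda / fit$kappa)   # identity by construction
  expect_true(fit$converged)
})

test_that("minimum contrast is invariant to point relabelling", {
  w <- study_window()
  p <- simulate_thomas(w, 0.003, 2, 1.5, seed = 77)
  perm <- sample(p$n)
  f1 <- fit_model(p, "tc")
  f2 <- fit_model(point_pattern(p$x[perm], p$y[perm], w), "tc")
  expect_equal(coef(f1), coef(f2))
})

test_that("cluster parameters are recovered from simulated patterns", {
  w <- study_window()
  kappa <- 0.004; sigma <- 2; mu <- 3
  res <- vapply(1:60, function(b) {
    p <- simulate_thomas(w, kappa, sigma, mu, seed = 800 + b)
    f <- fit_model(p, "tc")
    c(f$kappa, f$sigma, f$mu)
  }, numeric(3))
  expect_lt(median(abs(res[1, ] - kappa) / kappa), 0.2)
  expect_lt(median(abs(res[2, ] - sigma) / sigma), 0.2)
  expect_lt(median(abs(res[3, ] - mu) / mu), 0.2)
})

test_that("a CSR pattern yields a near-flat fitted cluster model", {
  w <- study_window()
  r <- seq(0.1, 25, 0.1)
  op <- coralpp:::smoothing_operator(r, 5, 0.1)
  flat <- vapply(1:20, function(b) {
    p <- simulate_csr(w, 150 / w$area_cm2, seed = 900 + b)
    f <- suppressWarnings(fit_model(p, "tc"))
    # fitted (smoothed) curve over the dispersal scales; the region below
    # 2 cm is excluded as single close pairs dominate the estimate there
    Tg <- drop(op$K %*% thomas_pcf(op$s, f$kappa, f$sigma))
    max(abs(Tg[r >= 2] - 1))
  }, 0)
  expect_gte(mean(flat < 0.5), 0.9)
})

test_that("heterogeneous Poisson fit is the per-category count/area ratio", {
  w <- study_window(100, 100)
  grid <- matrix("flat", 20, 20); grid[, 11:20] <- "boulder"
  mask <- substrate_mask(grid, w)
  # all points on the boulder half
  set.seed(4)
  p <- point_pattern(runif(40, 51, 100), runif(40, 0, 100), w)
  fit <- fit_model(p, "hp", mask = mask)
  expect_equal(unname(fit$category_intensities["boulder"]), 40 / 5e3)
  expect_equal(unname(fit$category_intensities["flat"]), 0)
  expect_equal(sum(fit$category_intensities * category_areas(mask)), 40)

  # uniform mask: identical to the CSR intensity
  fitu <- fit_model(p, "hp", mask = substrate_mask(matrix("flat", 10, 10), w))
  expect_equal(unname(fitu$category_intensities["flat"]), fit$lambda)
})

test_that("heterogeneous Poisson recovery matches the thinning simulator", {
  w <- study_window(100, 100)
  grid <- matrix("flat", 20, 20); grid[1:10, ] <- "boulder"; grid[, 16:20] <- "gulley"
  mask <- substrate_mask(grid, w)
  truth <- c(boulder = 0.03, flat = 0.01, gulley = 0)
  imap <- intensity_map(mask, truth)
  est <- matrix(0, 3, 200)
  for (b in 1:200) {
    p <- simulate_hetero_poisson(imap, seed = 600 + b)
    est[, b] <- fit_model(p, "hp", mask = mask)$category_intensities
  }
  avg <- rowMeans(est)
  areas <- category_areas(mask)
  se <- sqrt(truth / areas / 200)        # Poisson rate standard errors
  expect_lt(abs(avg[1] - 0.03), 3 * se["boulder"])
  expect_lt(abs(avg[2] - 0.01), 3 * se["flat"])
  expect_equal(avg[3], 0)
})

test_that("HTC with a uniform mask coincides with the plain Thomas fit", {
  w <- study_window()
  p <- simulate_thomas(w, 0.003, 2, 1, seed = 11)
  mask <- substrate_mask(matrix("flat", 35, 35), w)
  tc <- fit_model(p, "tc")
  htc <- fit_model(p, "htc", mask = mask)
  expect_lt(abs(tc$kappa - htc$kappa), 1e-6)
  expect_lt(abs(tc$sigma - htc$sigma), 1e-6)
})

test_that("HTC recovers the dispersal scale of a substrate-thinned Thomas process", {
  w <- study_window()
  grid <- matrix("flat", 35, 35); grid[, 18:35] <- "boulder"
  mask <- substrate_mask(grid, w)
  sig_err <- vapply(1:40, function(b) {
    base <- simulate_thomas(w, 0.003, 2, 3, seed = 1200 + b)
    retain <- c(boulder = 1, flat = 1 / 3, gulley = 1)[
      coralpp:::SUBSTRATE_CATEGORIES[coralpp:::point_category(mask, base$x, base$y)]]
    keep <- coralpp:::with_seed(derive_seed(1200 + b, "thin"),
                                runif(base$n) < retain)
    p <- point_pattern(base$x[keep], base$y[keep], w)
    f <- fit_model(p, "htc", mask = mask)
    abs(f$sigma - 2) / 2
  }, 0)
  expect_lt(median(sig_err), 0.25)
})

test_that("reproductive diagnostics follow the truncated-Poisson algebra", {
  expect_equal(offspring_nonempty(0), 1)
  expect_equal(offspring_nonempty(1e-14), 1)
  expect_equal(offspring_nonempty(10), 10.000454, tolerance = 1e-4)
  expect_equal(offspring_nonempty(1), ztp_mean_enumerated(1), tolerance = 1e-12)
  expect_equal(offspring_nonempty(1), 1.5820, tolerance = 1e-4)
  expect_error(offspring_nonempty(-0.1), "mu")
  mu <- seq(0, 8, 0.25)
  expect_true(all(offspring_nonempty(mu) >= pmax(1, mu)))

  expect_equal(prob_in_cluster(0), 0)
  expect_equal(prob_in_cluster(log(2)), 0.5)
  expect_equal(prob_in_cluster(1), 0.6321206, tolerance = 1e-6)
  expect_error(prob_in_cluster(-1), "mu")

  # simulator cross-check: fraction of points with >= 1 sibling among
  # Poisson(mu)-sized clusters, mu = 1
  set.seed(2024)
  sizes <- rpois(1e5, 1)
  sizes <- sizes[sizes > 0]
  # a point in a cluster of size k has >= 1 sibling iff k >= 2; the typical
  # *point* is drawn size-biased
  frac <- sum(sizes[sizes >= 2]) / sum(sizes)
  # size-biased P(sibling) = 1 - e^-mu under the Palm law
  expect_equal(frac, prob_in_cluster(1), tolerance = 0.01)
})

test_that("fitted models expose the standard modelling methods", {
  w <- study_window()
  p <- simulate_thomas(w, 0.002, 2, 2, seed = 21, morph = "orange")
  fit <- fit_model(p, "tc")
  expect_named(coef(fit), c("lambda", "kappa", "sigma", "mu"))
  s <- summary(fit)
  expect_equal(s$offspring_nonempty, offspring_nonempty(fit$mu))
  expect_output(print(fit), "Thomas cluster")

  sims <- simulate(fit, nsim = 3, seed = 5)
  expect_length(sims, 3)
  expect_s3_class(sims[[1]], "coral_ppp")
  sims2 <- simulate(fit, nsim = 3, seed = 5)
  expect_identical(sims[[2]]$x, sims2[[2]]$x)

  expect_equal(predict(fit, data.frame(x_cm = 1, y_cm = 1)), fit$lambda)
})
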