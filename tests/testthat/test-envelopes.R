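# Monte Carlo envelopes and Diggle's goodness-of-fit rank test.

test_that("envelope bounds are the trimmed order statistics of the sims", {
  w <- study_window()
  p <- simulate_csr(w, 120 / w$area_cm2, seed = 31)
  fit <- fit_model(p, "csr")

  # n_drop = 0: pointwise min and max
  env0 <- mc_envelope(fit, n_sims = 9, n_drop = 0, seed = 1)
  expect_equal(env0$lo, apply(env0$sims, 1, min))
  expect_equal(env0$hi, apply(env0$sims, 1, max))

  # trimmed: (n_drop + 1)-th order statistic from each tail, by sort oracle
  env <- mc_envelope(fit, n_sims = 39, n_drop = 2, seed = 2)
  for (j in c(1, 100, 250, 499)) {
    srt <- sort(env$sims[j, ])
    expect_identical(env$lo[j], srt[3])
    expect_identical(env$hi[j], srt[37])
  }
  expect_true(all(env$lo <= env$hi))
  expect_error(mc_envelope(fit, n_sims = 9, n_drop = 5), "n_drop")
})

test_that("envelope bounds widen as fewer simulations are trimmed", {
  w <- study_window()
  p <- simulate_csr(w, 120 / w$area_cm2, seed = 32)
  fit <- fit_model(p, "csr")
  env5 <- mc_envelope(fit, n_sims = 99, n_drop = 5, seed = 3)
  # re-trim the same stored matrix with a smaller n_drop
  sorted <- apply(env5$sims, 1, sort)
  lo2 <- sorted[3, ]; hi2 <- sorted[97, ]
  expect_true(all(lo2 <= env5$lo))
  expect_true(all(hi2 >= env5$hi))
})

test_that("a CSR envelope contains the theoretical flat line", {
  w <- study_window()
  p <- simulate_csr(w, 150 / w$area_cm2, seed = 33)
  env <- mc_envelope(fit_model(p, "csr"), n_sims = 199, seed = 4)
  expect_gte(mean(env$lo <= 1 & env$hi >= 1), 0.99)
})

test_that("degenerate simulated patterns fall back to the flat reference", {
  w <- study_window()
  # lambda so small that most replicates have < 2 points
  p <- simulate_csr(w, 3 / w$area_cm2, seed = 34)
  p <- point_pattern(c(p$x, 10, 20), c(p$y, 10, 20), w)  # ensure obs has >= 2
  fit <- fit_model(p, "csr")
  expect_warning(env <- mc_envelope(fit, n_sims = 19, seed = 5),
                 "fewer than 2 points")
  expect_true(any(apply(env$sims == 1, 2, all)))
})

test_that("Diggle ranks follow the plus-one convention with floor and ties", {
  w <- study_window()
  r <- seq(0.1, 50, 0.1)
  fit <- fit_model(simulate_csr(w, 100 / w$area_cm2, seed = 36), "csr")
  mk_env <- function(obs, sims) structure(
    list(r = r, obs = obs, sims = sims, lo = apply(sims, 1, min),
         hi = apply(sims, 1, max), n_sims = ncol(sims), n_drop = 0,
         fit = fit), class = "coral_envelope")

  # observation identical to every simulation: all u tie -> p = n/(n+1)
  flat <- matrix(1, length(r), 9)
  g <- diggle_gof(mk_env(rep(1, length(r)), flat))
  expect_equal(g$p_d, 9 / 10)

  # u_obs strictly the largest -> floor 1/(n+1)
  sims <- matrix(1, length(r), 9) + matrix(rnorm(9 * length(r), 0, 1e-4),
                                           length(r), 9)
  g2 <- diggle_gof(mk_env(rep(2, length(r)), sims))
  expect_equal(g2$u_sims >= g2$u_obs, rep(FALSE, 9))
  expect_equal(g2$p_d, 1 / 10)

  # constructed curves with known deviations: ranks re-derived by an
  # explicit leave-one-out loop with trapezoid integration
  amp <- c(4, 5, 6, 1, 0.5, 0.25, 2, 0.1, 0.05, 3)  # obs first, then sims
  curves <- sapply(amp, function(a) 1 + a * sin(r))
  wts <- rep(0.1, length(r)); wts[c(1, length(r))] <- 0.05
  u_manual <- sapply(1:10, function(i) {
    mbar <- rowMeans(curves[, -i, drop = FALSE])
    sum(wts * (curves[, i] - mbar)^2)
  })
  n_ge <- sum(u_manual[-1] >= u_manual[1])
  g3 <- diggle_gof(mk_env(curves[, 1], curves[, -1]))
  expect_equal(g3$u_obs, u_manual[1])
  expect_equal(g3$u_sims, u_manual[-1])
  expect_equal(g3$p_d, max(1, n_ge) / 10)

  expect_error(diggle_gof(mk_env(rep(1, length(r)), flat), c(0.1, 60)),
               "outside")
})

test_that("p_d is invariant to the integration grid's common scale of u", {
  # doubling every curve's deviation from the common mean rescales all u by
  # 4 and cannot change any rank
  w <- study_window()
  r <- seq(0.1, 50, 0.1)
  fit <- fit_model(simulate_csr(w, 100 / w$area_cm2, seed = 37), "csr")
  set.seed(9)
  sims <- matrix(1 + rnorm(9 * length(r), 0, 0.1), length(r), 9)
  obs <- 1 + rnorm(length(r), 0, 0.1)
  env1 <- structure(list(r = r, obs = obs, sims = sims, lo = 0, hi = 2,
                         n_sims = 9, n_drop = 0, fit = fit),
                    class = "coral_envelope")
  env2 <- env1
  env2$obs <- 1 + 2 * (obs - 1); env2$sims <- 1 + 2 * (sims - 1)
  expect_equal(diggle_gof(env1)$p_d, diggle_gof(env2)$p_d)
})

test_that("the GoF pipeline is reproducible given a seed", {
  w <- study_window()
  p <- simulate_thomas(w, 0.002, 2, 2, seed = 38)
  fit <- fit_model(p, "tc")
  g1 <- diggle_gof(mc_envelope(fit, n_sims = 49, seed = 11), c(0.1, 10))
  g2 <- diggle_gof(mc_envelope(fit, n_sims = 49, seed = 11), c(0.1, 10))
  expect_identical(g1$u_obs, g2$u_obs)
  expect_identical(g1$p_d, g2$p_d)
})

test_that("model comparison prefers the generating process", {
  w <- study_window()
  site <- coral_site("sim1",
                     list(orange = simulate_thomas(w, 0.002, 2, 2.5,
                                                   seed = 41, morph = "orange")))
  cmp <- evaluate_models(site, "orange", n_sims = 99, seed = 13)
  expect_setequal(names(cmp$gofs), c("csr", "tc10", "tc20"))
  expect_lt(cmp$pd[["csr"]], 0.05)
  expect_gt(cmp$pd[["tc10"]], cmp$pd[["csr"]])
  expect_equal(cmp$best, "tc")

  # a 29-point pattern is refused
  small <- coral_site("s29", list(orange = fixture_site(29, 0)$patterns$orange))
  expect_error(evaluate_models(small, "orange", n_sims = 9), "not analysable")
})

test_that("HP and HTC are skipped with a message when no mask is present", {
  w <- study_window()
  site <- coral_site("sim2",
                     list(pink = simulate_thomas(w, 0.003, 2, 1.2,
                                                 seed = 42, morph = "pink")))
  expect_message(cmp <- evaluate_models(site, "pink", n_sims = 49, seed = 14),
                 "HP/HTC skipped")
  expect_false(any(c("hp", "htc") %in% names(cmp$gofs)))
})
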