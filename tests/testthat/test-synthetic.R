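# Generative models: CSR, Thomas cluster, thinned heterogeneous Poisson,
# and the scenario/site generator.

test_that("CSR simulator matches Poisson count moments and rejects bad input", {
  w <- study_window()
  expect_equal(simulate_csr(w, 0, seed = 1)$n, 0)
  expect_error(simulate_csr(w, -1), ">= 0")

  lambda <- 100 / w$area_cm2
  counts <- vapply(1:2000, function(b) simulate_csr(w, lambda, seed = b)$n, 0L)
  # mean of 2000 Poisson(100) draws: tolerance 3 * sqrt(100/2000)
  expect_lt(abs(mean(counts) - 100), 3 * sqrt(100 / 2000))
  expect_lt(abs(var(counts) / 100 - 1), 0.15)
})

test_that("CSR patterns have flat pair correlation", {
  w <- study_window()
  gbar <- rowMeans(vapply(1:80, function(b) {
    p <- simulate_csr(w, 500 / w$area_cm2, seed = 100 + b)
    pair_correlation(p)$g
  }, numeric(500)))
  r <- seq(0.1, 50, 0.1)
  expect_lt(abs(mean(gbar[r >= 5 & r <= 40]) - 1), 0.02)
})

test_that("Thomas simulator matches its closed-form intensity", {
  w <- study_window()
  expect_equal(simulate_thomas(w, 0.005, 2, 0, seed = 1)$n, 0)
  expect_error(simulate_thomas(w, 0.005, 0, 2), "sigma")

  kappa <- 0.005; mu <- 2
  counts <- vapply(1:1000, function(b)
    simulate_thomas(w, kappa, 2, mu, seed = b)$n, 0L)
  expected <- kappa * mu * w$area_cm2          # 306.25
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("empirical Thomas pair correlation matches the closed form", {
  # narrow-bandwidth estimate averaged over replicates vs the analytic PCF
  w <- study_window()
  kappa <- 0.005; sigma <- 2; mu <- 2
  gbar <- rowMeans(vapply(1:200, function(b) {
    p <- simulate_thomas(w, kappa, sigma, mu, seed = 400 + b)
    pair_correlation(p, r_max = 25, bandwidth = 1)$g
  }, numeric(250)))
  r <- seq(0.1, 25, 0.1)
  idx <- r >= 2 & r <= 20
  rel <- (gbar[idx] - thomas_pcf(r[idx], kappa, sigma)) / thomas_pcf(r[idx], kappa, sigma)
  expect_lt(max(abs(rel)), 0.05)
})

test_that("heterogeneous Poisson thinning respects the intensity surface", {
  w <- study_window(100, 100)
  grid <- matrix("flat", 20, 20); grid[, 11:20] <- "gulley"
  mask <- substrate_mask(grid, w)

  # zero intensity on gulleys -> never a point there
  imap0 <- intensity_map(mask, c(boulder = 0, flat = 0.02, gulley = 0))
  for (b in 1:20) {
    p <- simulate_hetero_poisson(imap0, seed = b)
    expect_true(all(p$x <= 50))
  }

  # all-zero map -> empty pattern, not an error
  expect_equal(simulate_hetero_poisson(
    intensity_map(mask, c(boulder = 0, flat = 0, gulley = 0)), seed = 1)$n, 0)

  # 3:1 ratio on equal areas -> per-category count ratio within 3 SE
  imap <- intensity_map(mask, c(boulder = 0, flat = 0.03, gulley = 0.01))
  left <- right <- 0
  for (b in 1:1000) {
    p <- simulate_hetero_poisson(imap, seed = 5000 + b)
    left <- left + sum(p$x <= 50); right <- right + sum(p$x > 50)
  }
  frac <- left / (left + right)           # binomial with p = 3/4
  se <- sqrt(0.75 * 0.25 / (left + right))
  expect_lt(abs(frac - 0.75), 3 * se)
})

test_that("uniform intensity map degenerates to CSR", {
  w <- study_window(100, 100)
  imap <- intensity_map(substrate_mask(matrix("flat", 10, 10), w),
                        c(boulder = 0, flat = 0.01, gulley = 0))
  counts <- vapply(1:500, function(b) simulate_hetero_poisson(imap, seed = b)$n, 0L)
  expect_lt(abs(mean(counts) - 100), 3 * sqrt(100 / 500))
  expect_lt(abs(var(counts) / 100 - 1), 0.2)
})

test_that("simulators are pure functions of (parameters, seed)", {
  w <- study_window()
  a <- simulate_thomas(w, 0.002, 2, 2, seed = 42)
  b <- simulate_thomas(w, 0.002, 2, 2, seed = 42)
  expect_identical(a$x, b$x)

  # simulation must not disturb the caller's RNG stream
  set.seed(7); before <- runif(1)
  set.seed(7); invisible(simulate_csr(w, 0.001, seed = 3)); after <- runif(1)
  expect_identical(before, after)
})

test_that("generated sites honour the community-type defaults", {
  cfgO <- scenario_config("O", seed = 5)
  sO <- generate_site(cfgO, "o1")
  expect_named(sO$patterns, "orange")

  # same seed -> identical files
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_site(scenario_config("M", seed = 9), "m1", dir = d1)
  generate_site(scenario_config("M", seed = 9), "m1", dir = d2)
  expect_identical(readLines(file.path(d1, "sites", "m1.csv")),
                   readLines(file.path(d2, "sites", "m1.csv")))
})

test_that("mixed-community defaults give both morphs study-like counts", {
  inside <- vapply(1:200, function(b) {
    s <- generate_site(scenario_config("M", seed = b), "m")
    all(vapply(s$patterns, function(p) p$n >= 31 && p$n <= 121, TRUE))
  }, TRUE)
  expect_gte(mean(inside), 0.9)
})

test_that("substrate effects thin patterns without losing expected count", {
  cfg <- scenario_config("P", substrate_effect = c(boulder = 3, flat = 1, gulley = 0),
                         seed = 31)
  s <- generate_site(cfg, "p1")
  expect_false(is.null(s$mask))
  cat_codes <- coralpp:::point_category(s$mask, s$patterns$pink$x, s$patterns$pink$y)
  gulley_cells <- s$mask$categories[cat_codes] == "gulley"
  expect_equal(sum(gulley_cells), 0)
})
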