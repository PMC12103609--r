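# Generative models and the synthetic-study generator.
#
# All simulators are pure functions of (parameters, seed): the RNG state is
# restored on exit, and the study generator derives per-site/per-morph
# sub-stream seeds with derive_seed(), so adding a morph or a site never
# perturbs another pattern's randomness.

#' Simulate complete spatial randomness (homogeneous Poisson)
#'
#' @param window a [study_window()].
#' @param lambda intensity in points/cm^2 (>= 0).
#' @param seed optional integer seed.
#' @param morph optional label attached to the result.
#' @return a [point_pattern()] with a Poisson(lambda * area) number of
#'   independently uniform points.
#' @examples
#' simulate_csr(study_window(), 100 / 30625, seed = 1)
#' @export
simulate_csr <- function(window, lambda, seed = NULL, morph = NULL) {
  stopifnot(is_window(window))
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) || lambda < 0)
    stop("'lambda' must be a single number >= 0", call. = FALSE)
  with_seed(seed, {
    n <- rpois(1, lambda * window$area_cm2)
    point_pattern(runif(n, 0, window$width), runif(n, 0, window$height),
                  window, morph = morph)
  })
}

#' Simulate a Thomas cluster process
#'
#' Parents follow a Poisson process of intensity `kappa` on the window
#' dilated by `4 * sigma` on every side (so clusters seeded just outside
#' the frame still contribute offspring, avoiding deflated density near the
#' borders); each parent receives a Poisson(`mu`) number of offspring
#' displaced by an isotropic Gaussian with standard deviation `sigma` per
#' axis.  Only offspring inside the window are returned; parents are latent.
#'
#' @param window a [study_window()].
#' @param kappa parent intensity (parents/cm^2, >= 0).
#' @param sigma dispersal scale (cm, > 0): per-axis standard deviation of
#'   the offspring displacement.
#' @param mu mean offspring per parent (>= 0).
#' @param seed optional integer seed.
#' @param morph optional label.
#' @return a [point_pattern()]; expected count is `kappa * mu * area`.
#' @examples
#' simulate_thomas(study_window(), 0.001, 2, 2, seed = 1)
#' @export
simulate_thomas <- function(window, kappa, sigma, mu, seed = NULL, morph = NULL) {
  stopifnot(is_window(window))
  if (!is.numeric(kappa) || kappa < 0) stop("'kappa' must be >= 0", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma <= 0)
    stop("'sigma' must be a single number > 0", call. = FALSE)
  if (!is.numeric(mu) || mu < 0) stop("'mu' must be >= 0", call. = FALSE)
  with_seed(seed, {
    guard <- 4 * sigma
    Wd <- window$width + 2 * guard; Hd <- window$height + 2 * guard
    n_par <- rpois(1, kappa * Wd * Hd)
    if (n_par == 0)
      return(point_pattern(numeric(0), numeric(0), window, morph = morph))
    px <- runif(n_par, -guard, window$width + guard)
    py <- runif(n_par, -guard, window$height + guard)
    n_off <- rpois(n_par, mu)
    x <- rep(px, n_off) + rnorm(sum(n_off), 0, sigma)
    y <- rep(py, n_off) + rnorm(sum(n_off), 0, sigma)
    keep <- x >= 0 & x <= window$width & y >= 0 & y <= window$height
    point_pattern(x[keep], y[keep], window, morph = morph)
  })
}

#' Simulate a heterogeneous (inhomogeneous) Poisson process
#'
#' Simulation is by independent thinning: a homogeneous Poisson pattern is
#' generated at the maximum cell intensity and each proposed point is kept
#' with probability `lambda(x) / lambda_max`.  An all-zero intensity map
#' yields an empty pattern.
#'
#' @param imap an [intensity_map()] (piecewise-constant lambda(x) from a
#'   substrate mask).
#' @param seed optional integer seed.
#' @param morph optional label.
#' @return a [point_pattern()].
#' @export
simulate_hetero_poisson <- function(imap, seed = NULL, morph = NULL) {
  stopifnot(inherits(imap, "intensity_map"))
  win <- imap$window
  lmax <- max(imap$values)
  if (lmax == 0)
    return(point_pattern(numeric(0), numeric(0), win, morph = morph))
  with_seed(seed, {
    prop <- simulate_csr(win, lmax)
    if (prop$n == 0)
      return(point_pattern(numeric(0), numeric(0), win, morph = morph))
    lam <- lambda_at(imap, prop$x, prop$y)
    keep <- runif(prop$n) < lam / lmax
    point_pattern(prop$x[keep], prop$y[keep], win, morph = morph)
  })
}

# intensity surface value at point locations
lambda_at <- function(imap, x, y) {
  m <- imap$mask
  ix <- pmin(pmax(floor(x / m$cell_w) + 1, 1), ncol(imap$values))
  iy <- pmin(pmax(floor(y / m$cell_h) + 1, 1), nrow(imap$values))
  imap$values[cbind(iy, ix)]
}

# ---------------------------------------------------------------------------
# Scenario configuration and whole-study generation

#' Scenario configuration for one synthetic site
#'
#' Describes the generative conditions of one site: community type, one
#' process per morph (Thomas cluster parameters, or a CSR intensity), and an
#' optional substrate effect.  The packaged defaults emulate the three
#' community types observed in the study system: `"O"` (orange-dominant,
#' pink absent), `"P"` (pink-dominant, orange absent) and `"M"` (mixed, the
#' two morphs at comparable expected counts, the pink morph with the larger
#' dispersal scale and offspring number).
#'
#' @param community_type `"O"`, `"P"` or `"M"`.
#' @param morphs named list (names in `c("orange", "pink")`); each element
#'   is either `list(kappa =, sigma =, mu =)` for a Thomas process or
#'   `list(lambda =)` for CSR.  `NULL` selects the documented defaults for
#'   `community_type`.
#' @param substrate_effect optional named per-category intensity multipliers
#'   (e.g. `c(boulder = 3, flat = 1, gulley = 0)`); when supplied a random
#'   substrate mask is generated and patterns are thinned accordingly,
#'   with offspring rates rescaled so expected counts are preserved.
#' @param window a [study_window()].
#' @param seed integer seed for the site.
#' @return an object of class `"scenario_config"`.
#' @examples
#' scenario_config("M", seed = 7)
#' @export
scenario_config <- function(community_type = c("M", "O", "P"), morphs = NULL,
                            substrate_effect = NULL, window = study_window(),
                            seed = 1L) {
  community_type <- match.arg(community_type)
  if (is.null(morphs)) morphs <- default_morph_params(community_type)
  if (!all(names(morphs) %in% MORPH_LEVELS))
    stop("morph names must be in {orange, pink}", call. = FALSE)
  for (m in morphs) {
    rates <- unlist(m)
    if (any(rates < 0)) stop("all rates must be >= 0", call. = FALSE)
    if (!is.null(m$sigma) && m$sigma <= 0)
      stop("'sigma' must be > 0", call. = FALSE)
  }
  structure(list(community_type = community_type, morphs = morphs,
                 substrate_effect = substrate_effect, window = window,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

# Default per-morph generative parameters for the three community types.
# Chosen once to sit inside the observed study conditions: expected counts
# O orange ~46, P pink ~123, M ~61 per morph (site densities ~10-145 /m2
# across types), dispersal scales 2-3 cm, and a larger sigma and mu for the
# pink morph in mixed communities.
default_morph_params <- function(community_type) {
  switch(community_type,
         O = list(orange = list(kappa = 0.0015, sigma = 2.0, mu = 1.0)),
         P = list(pink   = list(kappa = 0.0040, sigma = 2.0, mu = 1.0)),
         M = list(orange = list(kappa = 0.0030, sigma = 2.0, mu = 0.66),
                  pink   = list(kappa = 0.0015, sigma = 3.0, mu = 1.3)))
}

#' Generate one synthetic site
#'
#' Draws each morph's pattern from its configured process (Thomas cluster
#' or CSR), optionally under a substrate effect, and (optionally) writes the
#' annotation CSV and mask PNG through the package's I/O layer.  The result
#' is a pure function of the configuration (including its seed): morph
#' sub-streams are split with [derive_seed()], so the orange pattern is
#' unchanged whether or not a pink morph is configured.
#'
#' @param config a [scenario_config()].
#' @param site_id site identifier.
#' @param dir optional directory; when given, writes
#'   `<dir>/sites/<site_id>.csv` (and `<dir>/masks/<site_id>.png` if a
#'   substrate effect is configured).
#' @return a [coral_site()].
#' @export
generate_site <- function(config, site_id = "site1", dir = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  win <- config$window
  mask <- NULL
  imap_mult <- NULL
  if (!is.null(config$substrate_effect)) {
    mask <- random_substrate_mask(win, seed = derive_seed(config$seed, site_id, "mask"))
    mult <- config$substrate_effect[SUBSTRATE_CATEGORIES]
    mult[is.na(mult)] <- 1
    imap_mult <- intensity_map(mask, mult / max(mult))  # retention probabilities
    # fraction of area retained under thinning, to rescale offspring rates
    keep_frac <- sum(category_areas(mask) * (mult / max(mult))) / win$area_cm2
  }
  patterns <- list()
  for (m in names(config$morphs)) {
    p <- config$morphs[[m]]
    sd_seed <- derive_seed(config$seed, site_id, m)
    if (!is.null(p$lambda)) {
      pat <- simulate_csr(win, if (is.null(imap_mult)) p$lambda else p$lambda / keep_frac,
                          seed = sd_seed, morph = m)
    } else {
      pat <- simulate_thomas(win, p$kappa, p$sigma,
                             if (is.null(imap_mult)) p$mu else p$mu / keep_frac,
                             seed = sd_seed, morph = m)
    }
    if (!is.null(imap_mult) && pat$n > 0) {
      keep <- with_seed(derive_seed(config$seed, site_id, m, "thin"),
                        runif(pat$n) < lambda_at(imap_mult, pat$x, pat$y))
      pat <- point_pattern(pat$x[keep], pat$y[keep], win, morph = m)
    }
    patterns[[m]] <- pat
  }
  site <- coral_site(site_id, patterns, mask = mask)
  if (!is.null(dir)) {
    dir.create(file.path(dir, "sites"), recursive = TRUE, showWarnings = FALSE)
    write_site_annotations(site, file.path(dir, "sites", paste0(site_id, ".csv")))
    if (!is.null(mask)) {
      dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
      write_substrate_mask(mask, file.path(dir, "masks", paste0(site_id, ".png")))
    }
  }
  site
}

#' Generate a whole synthetic study
#'
#' Produces one site per entry of `types`, with per-site seeds derived from
#' the global seed, and (optionally) writes a study directory layout that
#' [run_study()] can consume: `study.yaml`, `sites/*.csv`, `masks/*.png`.
#'
#' @param types character vector of community types, e.g.
#'   `rep(c("O", "P", "M"), c(6, 21, 9))`.
#' @param seed global integer seed.
#' @param dir optional output directory.
#' @param substrate_effect optional multipliers forwarded to every site's
#'   [scenario_config()].
#' @param window a [study_window()].
#' @param site_ids optional site identifiers (default `site001`, ...).
#' @return named list of [coral_site()]s.
#' @export
simulate_study <- function(types, seed = 1L, dir = NULL,
                           substrate_effect = NULL, window = study_window(),
                           site_ids = sprintf("site%03d", seq_along(types))) {
  stopifnot(length(types) == length(site_ids))
  sites <- vector("list", length(types))
  names(sites) <- site_ids
  for (k in seq_along(types)) {
    cfg <- scenario_config(types[k], substrate_effect = substrate_effect,
                           window = window,
                           seed = derive_seed(seed, "site", site_ids[k]))
    sites[[k]] <- generate_site(cfg, site_id = site_ids[k], dir = dir)
  }
  if (!is.null(dir)) {
    meta <- list(window = list(width = window$width, height = window$height),
                 types = as.list(setNames(as.character(types), site_ids)),
                 colour_map = list(`#804020` = "boulder", `#C0C0C0` = "flat",
                                   `#204080` = "gulley"))
    yaml::write_yaml(meta, file.path(dir, "study.yaml"))
  }
  sites
}
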