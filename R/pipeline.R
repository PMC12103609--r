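# End-to-end study orchestration: load or simulate sites, apply the
# >= 30-point analysability rule, assign community groups, run the per-site
# model comparison, extract reproductive and nearest-neighbour summaries,
# and write result tables, curves and (advisory) figures.

#' Apply the 30-point analysability rule
#'
#' Retains, within each site, the morph patterns with at least `min_points`
#' individuals; sites left with no analysable pattern are dropped.  Each
#' exclusion is recorded.
#'
#' @param sites list of [coral_site()]s.
#' @param min_points threshold (default 30, the minimum needed to describe
#'   an observed spatial pattern).
#' @return list with `sites` (filtered list) and `exclusions` (data.frame
#'   site_id, morph, n, reason).
#' @export
filter_analysable <- function(sites, min_points = MIN_ANALYSABLE) {
  exclusions <- data.frame(site_id = character(0), morph = character(0),
                           n = integer(0), reason = character(0))
  kept <- list()
  for (site in sites) {
    ok <- vapply(site$patterns, function(p) p$n >= min_points, TRUE)
    for (m in names(site$patterns)[!ok])
      exclusions <- rbind(exclusions, data.frame(
        site_id = site$site_id, morph = m, n = site$patterns[[m]]$n,
        reason = sprintf("fewer than %d individuals", min_points)))
    if (any(ok)) {
      kept[[site$site_id]] <- site
    } else if (length(site$patterns)) {
      exclusions <- rbind(exclusions, data.frame(
        site_id = site$site_id, morph = "(site)", n = sum(vapply(site$patterns, function(p) p$n, 0L)),
        reason = "no analysable pattern"))
    }
  }
  list(sites = kept, exclusions = exclusions)
}

#' Load a study directory
#'
#' Reads the layout written by [simulate_study()]: `study.yaml` (window
#' size, optional mask colour map), one annotation CSV per site under
#' `sites/`, and optional mask PNGs under `masks/`.
#'
#' @param dir study directory.
#' @param flip_y forwarded to [read_site_annotations()].
#' @return named list of [coral_site()]s.
#' @export
load_study <- function(dir, flip_y = FALSE) {
  meta_path <- file.path(dir, "study.yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  win <- if (!is.null(meta$window))
    study_window(meta$window$width, meta$window$height) else study_window()
  files <- sort(list.files(file.path(dir, "sites"), pattern = "\\.csv$",
                           full.names = TRUE))
  if (!length(files)) stop("no site annotation files under ", dir, call. = FALSE)
  colour_map <- if (!is.null(meta$colour_map)) unlist(meta$colour_map) else NULL
  sites <- lapply(files, function(f) {
    site_id <- sub("\\.csv$", "", basename(f))
    mask_path <- file.path(dir, "masks", paste0(site_id, ".png"))
    mask <- if (file.exists(mask_path) && !is.null(colour_map))
      read_substrate_mask(mask_path, colour_map, win) else NULL
    read_site_annotations(f, win, flip_y = flip_y, mask = mask)
  })
  names(sites) <- vapply(sites, function(s) s$site_id, "")
  sites
}

#' Run the full study pipeline
#'
#' Orchestrates the complete analysis over a set of sites: applies the
#' analysability rule, assigns community groups from morph compositions,
#' runs the per-pattern model comparison ([evaluate_models()]) with
#' deterministic per-site/morph sub-stream seeds, computes nearest-neighbour
#' medians and reproductive diagnostics, and writes the summary table,
#' group assignments, per-pattern envelope curves, a manifest and advisory
#' figures to `output_dir`.  Re-running with the same inputs and seed
#' reproduces every output byte.
#'
#' @param input a study directory (see [load_study()]) or a list of
#'   [coral_site()]s.
#' @param output_dir results directory (created if needed).
#' @param n_sims,n_drop envelope settings; study fidelity is
#'   `n_sims = 9999`, `n_drop = 500`.
#' @param seed global integer seed.
#' @param fit_range,tc_gof_ranges,r_max,step,bandwidth,correction analysis
#'   settings, see [evaluate_models()].
#' @param models candidate models (HP/HTC are skipped per site when no mask
#'   is available).
#' @param figures write advisory PDF figures?
#' @return an object of class `"coral_study"`: fields `summary` (the
#'   summary data.frame), `groups`, `exclusions`, `nn_test` (pink P-vs-M
#'   nearest-neighbour comparison, when estimable), `output_dir`.
#' @export
run_study <- function(input, output_dir, n_sims = 199,
                      n_drop = (n_sims + 1) %/% 20, seed = 1L,
                      fit_range = c(0.1, 25), tc_gof_ranges = c(10, 20),
                      r_max = 50, step = 0.1, bandwidth = 5,
                      correction = "translation",
                      models = c("csr", "hp", "tc", "htc"),
                      figures = TRUE) {
  sites <- if (is.character(input)) load_study(input) else input
  if (!length(sites)) stop("no input sites", call. = FALSE)
  flt <- filter_analysable(sites)
  if (!length(flt$sites)) stop("no analysable sites", call. = FALSE)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(output_dir, "curves"), showWarnings = FALSE)

  # community groups from full compositions of the retained sites
  comp <- do.call(rbind, lapply(flt$sites, function(s) data.frame(
    site_id = s$site_id,
    orange = if (is.null(s$patterns$orange)) 0L else s$patterns$orange$n,
    pink = if (is.null(s$patterns$pink)) 0L else s$patterns$pink$n)))
  grouping <- assign_groups(comp)

  rows <- list()
  for (s in flt$sites) {
    for (m in names(s$patterns)) {
      pat <- s$patterns[[m]]
      if (pat$n < MIN_ANALYSABLE) next
      cmp <- evaluate_models(s, m, n_sims = n_sims, n_drop = n_drop,
                             seed = seed, fit_range = fit_range,
                             tc_gof_ranges = tc_gof_ranges, r_max = r_max,
                             step = step, bandwidth = bandwidth,
                             correction = correction, models = models)
      tc_fit <- cmp$fits$tc
      nn_med <- median(nn_distances(pat))
      for (model_name in names(cmp$envelopes)) {
        env <- cmp$envelopes[[model_name]]
        utils::write.csv(data.frame(r_cm = env$r, g_obs = env$obs,
                                    env_lo = env$lo, env_hi = env$hi),
                         file.path(output_dir, "curves",
                                   sprintf("%s_%s_%s.csv", s$site_id, m, model_name)),
                         row.names = FALSE)
      }
      rows[[paste(s$site_id, m)]] <- data.frame(
        site_id = s$site_id, morph = m,
        group = unname(grouping$groups[s$site_id]),
        n = pat$n, density_m2 = site_density(pat$n, pat$window),
        nn_median_cm = nn_med, best_model = cmp$best,
        pd_csr = unname(cmp$pd["csr"]),
        pd_hp = if ("hp" %in% names(cmp$pd)) unname(cmp$pd["hp"]) else NA_real_,
        pd_tc10 = unname(cmp$pd[sprintf("tc%g", tc_gof_ranges[1])]),
        pd_tc20 = if (length(tc_gof_ranges) > 1)
          unname(cmp$pd[sprintf("tc%g", tc_gof_ranges[2])]) else NA_real_,
        pd_htc = if ("htc" %in% names(cmp$pd)) unname(cmp$pd["htc"]) else NA_real_,
        kappa = tc_fit$kappa, sigma = tc_fit$sigma, mu = tc_fit$mu,
        offspring_nonempty = offspring_nonempty(tc_fit$mu),
        prob_cluster = prob_in_cluster(tc_fit$mu))
    }
  }
  summary_df <- do.call(rbind, rows)
  rownames(summary_df) <- NULL

  # pink nearest-neighbour comparison between dominant and mixed communities
  nn_test <- NULL
  pink_p <- summary_df$nn_median_cm[summary_df$morph == "pink" & summary_df$group == "P"]
  pink_m <- summary_df$nn_median_cm[summary_df$morph == "pink" & summary_df$group == "M"]
  if (length(pink_p) >= 2 && length(pink_m) >= 2)
    nn_test <- compare_nn_groups(pink_p, pink_m)

  write_summary_table(summary_df, file.path(output_dir, "summary.csv"))
  utils::write.csv(data.frame(site_id = names(grouping$groups),
                              group = unname(grouping$groups)),
                   file.path(output_dir, "groups.csv"), row.names = FALSE)
  if (nrow(flt$exclusions))
    utils::write.csv(flt$exclusions, file.path(output_dir, "exclusions.csv"),
                     row.names = FALSE)
  manifest <- list(
    package_version = as.character(packageVersion("coralpp")),
    seed = seed,
    settings = list(n_sims = n_sims, n_drop = n_drop, r_max = r_max,
                    step = step, bandwidth = bandwidth,
                    correction = correction, fit_range = fit_range,
                    tc_gof_ranges = tc_gof_ranges, models = models),
    n_sites_in = length(sites), n_sites_analysed = length(flt$sites),
    n_patterns = nrow(summary_df))
  yaml::write_yaml(manifest, file.path(output_dir, "manifest.yaml"))
  if (figures) study_figures(summary_df, output_dir)

  structure(list(summary = summary_df, groups = grouping,
                 exclusions = flt$exclusions, nn_test = nn_test,
                 output_dir = output_dir),
            class = "coral_study")
}

#' @export
print.coral_study <- function(x, ...) {
  cat(sprintf("Study run: %d site x morph patterns analysed\n", nrow(x$summary)))
  print(x$groups)
  cat("Best-model counts:\n")
  print(table(x$summary$best_model))
  if (!is.null(x$nn_test))
    cat(sprintf("Pink NN distance, dominant vs mixed: p = %.4f (%s)\n",
                x$nn_test$p_value, x$nn_test$method))
  cat("Outputs in", x$output_dir, "\n")
  invisible(x)
}

# advisory figures; CSVs are the tested surface
study_figures <- function(summary_df, output_dir) {
  dir.create(file.path(output_dir, "figures"), showWarnings = FALSE)
  cols <- c(orange = "darkorange", pink = "violetred1")

  pdf(file.path(output_dir, "figures", "counts_by_site.pdf"), width = 8, height = 4)
  counts <- tapply(summary_df$n, list(summary_df$morph, summary_df$site_id), sum)
  counts[is.na(counts)] <- 0
  barplot(counts, beside = TRUE, col = cols[rownames(counts)],
          las = 2, ylab = "corals per site", cex.names = 0.6)
  legend("topright", legend = rownames(counts), fill = cols[rownames(counts)], bty = "n")
  dev.off()

  pdf(file.path(output_dir, "figures", "gof_by_group.pdf"), width = 8, height = 4)
  op <- par(mfrow = c(1, 3))
  for (g in intersect(c("O", "P", "M"), unique(summary_df$group))) {
    sel <- summary_df$group == g
    dat <- summary_df[sel, c("pd_hp", "pd_tc10", "pd_htc")]
    boxplot(dat, names = c("HP", "TC", "HTC"), ylim = c(0, 1),
            main = paste("Group", g), ylab = "Diggle p_d")
  }
  par(op)
  dev.off()

  pdf(file.path(output_dir, "figures", "dispersal_by_group.pdf"), width = 8, height = 4)
  op2 <- par(mfrow = c(1, 2))
  for (field in c("offspring_nonempty", "nn_median_cm")) {
    stripchart(summary_df[[field]] ~ factor(paste(summary_df$group, summary_df$morph)),
               vertical = TRUE, method = "jitter", pch = 19,
               col = adjustcolor("grey30", 0.7),
               ylab = c(offspring_nonempty = "offspring per non-empty cluster",
                        nn_median_cm = "site NN median (cm)")[field])
  }
  par(op2)
  dev.off()
  invisible(NULL)
}
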