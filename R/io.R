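# Annotation-table and result-table I/O.
#
# On-disk dialect: comma-separated UTF-8 text with "." as the decimal mark,
# written and read with the C locale conventions of read.csv/write.csv, so
# files round-trip identically across machines.

MORPH_LEVELS <- c("orange", "pink")
MIN_ANALYSABLE <- 30L  # minimum points for a pattern to enter spatial analysis

#' Bundle point patterns, mask and metadata for one site
#'
#' @param site_id site identifier (e.g. `"img0483"`).
#' @param patterns named list of [point_pattern()]s, names in
#'   `c("orange", "pink")`, all sharing one window.
#' @param mask optional [substrate_mask()].
#' @param metadata optional named list (longitude, latitude, depth, ...).
#' @return an object of class `"coral_site"`.
#' @export
coral_site <- function(site_id, patterns, mask = NULL, metadata = NULL) {
  if (!length(patterns) || !all(names(patterns) %in% MORPH_LEVELS))
    stop("pattern names must be drawn from {orange, pink}", call. = FALSE)
  if (!all(vapply(patterns, is_ppp, TRUE)))
    stop("all patterns must be point_pattern objects", call. = FALSE)
  w <- patterns[[1]]$window
  same <- vapply(patterns, function(p)
    isTRUE(all.equal(c(p$window$width, p$window$height), c(w$width, w$height))), TRUE)
  if (!all(same)) stop("all patterns must share one window", call. = FALSE)
  if (!is.null(mask) && !is_mask(mask))
    stop("'mask' must be a substrate_mask", call. = FALSE)
  structure(list(site_id = as.character(site_id), patterns = patterns,
                 window = w, mask = mask, metadata = metadata),
            class = "coral_site")
}

#' @export
print.coral_site <- function(x, ...) {
  cat(sprintf("Site %s (%g x %g cm window)\n", x$site_id,
              x$window$width, x$window$height))
  for (m in names(x$patterns))
    cat(sprintf("  %-7s %4d points%s\n", m, x$patterns[[m]]$n,
                if (x$patterns[[m]]$n >= MIN_ANALYSABLE) "" else "  [below analysis threshold]"))
  if (!is.null(x$mask)) cat("  substrate mask present\n")
  invisible(x)
}

#' Read site annotations from a delimited text file
#'
#' Expects a CSV with header columns `site_id, morph, x_cm, y_cm` (renames
#' are tolerated via `columns`).  Coordinates must be finite and lie inside
#' the window; any offending row is reported by number.  Exports that use
#' image-style y-down coordinates can be flipped at read time.
#'
#' @param path CSV file holding one site's annotations.
#' @param window the [study_window()] the coordinates refer to.
#' @param flip_y if `TRUE`, y is replaced by `height - y` (image-origin
#'   exports).
#' @param columns named character vector mapping the canonical names
#'   `site_id`, `morph`, `x_cm`, `y_cm` to the file's actual headers.
#' @param mask,metadata forwarded to [coral_site()].
#' @return a [coral_site()].
#' @export
read_site_annotations <- function(path, window = study_window(),
                                  flip_y = FALSE,
                                  columns = c(site_id = "site_id", morph = "morph",
                                              x_cm = "x_cm", y_cm = "y_cm"),
                                  mask = NULL, metadata = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- columns[c("site_id", "morph", "x_cm", "y_cm")]
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop(sprintf("annotation file lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  df <- df[need]
  names(df) <- c("site_id", "morph", "x_cm", "y_cm")
  site_from_annotations(df, window, flip_y = flip_y, mask = mask,
                        metadata = metadata, origin = path)
}

# build one coral_site from a canonical annotation data.frame (one site id)
site_from_annotations <- function(df, window, flip_y = FALSE, mask = NULL,
                                  metadata = NULL, origin = "annotations") {
  if (!nrow(df)) stop("no annotation rows", call. = FALSE)
  ids <- unique(df$site_id)
  if (length(ids) != 1L)
    stop("expected a single site_id per site file", call. = FALSE)
  bad_morph <- which(!df$morph %in% MORPH_LEVELS)
  if (length(bad_morph))
    stop(sprintf("%s: morph label not in {orange, pink} at row %d ('%s')",
                 origin, bad_morph[1], df$morph[bad_morph[1]]), call. = FALSE)
  x <- as.numeric(df$x_cm); y <- as.numeric(df$y_cm)
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y)))
    stop(sprintf("%s: non-finite coordinate", origin), call. = FALSE)
  if (flip_y) y <- window$height - y
  out_of_bounds <- which(x < 0 | x > window$width | y < 0 | y > window$height)
  if (length(out_of_bounds))
    stop(sprintf("%s: coordinate outside the %g x %g cm window at row %d",
                 origin, window$width, window$height, out_of_bounds[1]),
         call. = FALSE)
  patterns <- lapply(intersect(MORPH_LEVELS, unique(df$morph)), function(m) {
    sel <- df$morph == m
    point_pattern(x[sel], y[sel], window, morph = m)
  })
  names(patterns) <- intersect(MORPH_LEVELS, unique(df$morph))
  coral_site(ids, patterns, mask = mask, metadata = metadata)
}

#' Write site annotations
#'
#' Inverse of [read_site_annotations()]; coordinates are written with 17
#' significant digits so a read-back reproduces every double bit-exactly.
#'
#' @param site a [coral_site()].
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_site_annotations <- function(site, path) {
  stopifnot(inherits(site, "coral_site"))
  rows <- do.call(rbind, lapply(names(site$patterns), function(m) {
    p <- site$patterns[[m]]
    data.frame(site_id = rep(site$site_id, p$n), morph = rep(m, p$n),
               x_cm = sprintf("%.17g", p$x), y_cm = sprintf("%.17g", p$y))
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

SUMMARY_COLUMNS <- c("site_id", "morph", "group", "n", "density_m2",
                     "nn_median_cm", "best_model", "pd_csr", "pd_hp",
                     "pd_tc10", "pd_tc20", "pd_htc", "kappa", "sigma", "mu",
                     "offspring_nonempty", "prob_cluster")

#' Write the study summary table
#'
#' One row per analysed site x morph with count, density, community group,
#' per-model goodness-of-fit, fitted Thomas parameters and reproductive
#' diagnostics, in a stable column order.  Values are written in full double
#' precision so a reload reproduces them.
#'
#' @param summaries data.frame with (a subset of) the canonical summary
#'   columns; missing columns are added as `NA`.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(summaries, path) {
  if (!is.data.frame(summaries) || !nrow(summaries))
    stop("'summaries' must be a non-empty data.frame", call. = FALSE)
  for (cn in setdiff(SUMMARY_COLUMNS, names(summaries))) summaries[[cn]] <- NA
  summaries <- summaries[SUMMARY_COLUMNS]
  num <- vapply(summaries, is.numeric, TRUE)
  for (cn in names(summaries)[num])
    summaries[[cn]] <- ifelse(is.na(summaries[[cn]]), NA,
                              format(summaries[[cn]], digits = 15, trim = TRUE,
                                     scientific = FALSE))
  write.csv(summaries, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a study summary table written by [write_summary_table()]
#' @param path CSV file.
#' @return data.frame with the canonical summary columns.
#' @export
read_summary_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  missing_cols <- setdiff(SUMMARY_COLUMNS, names(df))
  if (length(missing_cols))
    stop(sprintf("summary table lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  df[SUMMARY_COLUMNS]
}
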