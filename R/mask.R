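# Substrate category masks.
#
# The seabed inside each sample box is classified into three substrate
# categories: elevated boulders, flat rock, and debris-filled gulleys.  A
# mask is a regular grid of category codes aligned to the observation
# window, row 1 at the bottom (same lower-left origin as point patterns).

SUBSTRATE_CATEGORIES <- c("boulder", "flat", "gulley")

#' Substrate category mask
#'
#' @param grid matrix of category labels (character) or integer codes
#'   indexing `categories`; `grid[1, 1]` is the lower-left cell, rows run
#'   upward in y and columns rightward in x.
#' @param window the [study_window()] the mask covers.
#' @param categories category labels; defaults to
#'   `c("boulder", "flat", "gulley")`.
#' @return an object of class `"substrate_mask"` with fields `grid`
#'   (integer matrix), `categories`, `window`, `cell_w`, `cell_h` (cm).
#' @examples
#' m <- substrate_mask(matrix("flat", 35, 35), study_window())
#' category_areas(m)
#' @export
substrate_mask <- function(grid, window, categories = SUBSTRATE_CATEGORIES) {
  if (!is_window(window)) stop("'window' must be a study_window", call. = FALSE)
  if (!is.matrix(grid) || !nrow(grid) || !ncol(grid))
    stop("'grid' must be a non-empty matrix", call. = FALSE)
  if (is.character(grid)) {
    codes <- match(grid, categories)
    if (anyNA(codes))
      stop("grid contains labels outside the declared categories", call. = FALSE)
    grid <- matrix(codes, nrow(grid), ncol(grid))
  }
  grid <- matrix(as.integer(grid), nrow(grid), ncol(grid))
  if (anyNA(grid) || any(grid < 1L) || any(grid > length(categories)))
    stop("every cell must carry exactly one valid category code", call. = FALSE)
  structure(list(grid = grid, categories = categories, window = window,
                 cell_w = window$width / ncol(grid),
                 cell_h = window$height / nrow(grid)),
            class = "substrate_mask")
}

is_mask <- function(x) inherits(x, "substrate_mask")

#' @export
print.substrate_mask <- function(x, ...) {
  a <- category_areas(x)
  cat(sprintf("Substrate mask: %d x %d cells (%.2f x %.2f cm)\n",
              nrow(x$grid), ncol(x$grid), x$cell_w, x$cell_h))
  for (nm in names(a))
    cat(sprintf("  %-8s %8.1f cm2 (%.1f%%)\n", nm, a[[nm]],
                100 * a[[nm]] / x$window$area_cm2))
  invisible(x)
}

#' Per-category substrate areas
#'
#' Area covered by each category, `cell count * cell area`; the values sum
#' exactly to the window area.
#'
#' @param mask a [substrate_mask()].
#' @return named numeric vector of areas in cm^2, one per category.
#' @export
category_areas <- function(mask) {
  stopifnot(is_mask(mask))
  counts <- tabulate(mask$grid, nbins = length(mask$categories))
  setNames(counts * mask$cell_w * mask$cell_h, mask$categories)
}

# category code of the mask cell containing each point (vectorised)
point_category <- function(mask, x, y) {
  ix <- pmin(pmax(floor(x / mask$cell_w) + 1, 1), ncol(mask$grid))
  iy <- pmin(pmax(floor(y / mask$cell_h) + 1, 1), nrow(mask$grid))
  mask$grid[cbind(iy, ix)]
}

# uniform single-category mask covering a window (degenerate case helper)
uniform_mask <- function(window, category = "flat", n = 35L) {
  substrate_mask(matrix(match(category, SUBSTRATE_CATEGORIES), n, n), window)
}

normalise_hex <- function(x) toupper(sub("^#?", "#", x))

#' Read a substrate mask from a PNG raster
#'
#' Reads an exported polygon raster and assigns each pixel one substrate
#' category by matching its colour against `colour_map`.  The raster must
#' have the same aspect ratio as the window; pixel rows are flipped so the
#' mask shares the pattern's lower-left origin.
#'
#' @param path PNG file.
#' @param colour_map named character vector mapping hex colours to category
#'   labels, e.g. `c("#804020" = "boulder", "#C0C0C0" = "flat",
#'   "#204080" = "gulley")`.
#' @param window the [study_window()].
#' @param fallback optional category assigned to pixels whose colour is not
#'   in `colour_map`; when `NULL` (default) an unmapped colour is an error.
#' @return a [substrate_mask()].
#' @export
read_substrate_mask <- function(path, colour_map, window, fallback = NULL) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3L), c(dim(arr), 3L))
  h <- dim(arr)[1]; w <- dim(arr)[2]
  if (abs(w / h - window$width / window$height) > 0.02)
    stop("raster aspect ratio does not match the window", call. = FALSE)
  hex <- grDevices::rgb(arr[, , 1], arr[, , 2], arr[, , 3])
  names(colour_map) <- normalise_hex(names(colour_map))
  cat_lab <- unname(colour_map[normalise_hex(hex)])
  if (anyNA(cat_lab)) {
    if (is.null(fallback)) {
      missing_cols <- unique(normalise_hex(hex)[is.na(cat_lab)])
      stop(sprintf("unmapped raster colour(s): %s",
                   paste(utils::head(missing_cols, 5L), collapse = ", ")),
           call. = FALSE)
    }
    cat_lab[is.na(cat_lab)] <- fallback
  }
  lab <- matrix(cat_lab, h, w)          # row 1 = top row of the image
  lab <- lab[rev(seq_len(h)), , drop = FALSE]  # flip to y-up
  substrate_mask(lab, window)
}

#' Write a substrate mask as a PNG raster
#'
#' Inverse of [read_substrate_mask()]; colours are taken from `colour_map`
#' (category -> hex).
#'
#' @param mask a [substrate_mask()].
#' @param path output PNG file.
#' @param colour_map named character vector, names = categories, values =
#'   hex colours.
#' @return `path`, invisibly.
#' @export
write_substrate_mask <- function(mask, path,
                                 colour_map = c(boulder = "#804020",
                                                flat = "#C0C0C0",
                                                gulley = "#204080")) {
  stopifnot(is_mask(mask))
  hexes <- normalise_hex(colour_map[mask$categories[mask$grid]])
  rgbm <- grDevices::col2rgb(hexes) / 255
  h <- nrow(mask$grid); w <- ncol(mask$grid)
  arr <- array(0, c(h, w, 3))
  for (k in 1:3) arr[, , k] <- matrix(rgbm[k, ], h, w)[rev(seq_len(h)), ]
  png::writePNG(arr, path)
  invisible(path)
}

#' Generate a blocky random substrate mask
#'
#' Divides the window into square blocks (default 25 cm, the boulder-scale
#' clast size of the classification scheme) and assigns each block one
#' category with the given probabilities, then refines to the requested cell
#' size.  Used by the synthetic-study generator.
#'
#' @param window a [study_window()].
#' @param cell_size mask cell size in cm (default 0.5).
#' @param block_size block size in cm controlling spatial grain.
#' @param props category probabilities (named, any positive weights).
#' @param seed optional integer seed.
#' @return a [substrate_mask()].
#' @export
random_substrate_mask <- function(window, cell_size = 0.5, block_size = 25,
                                  props = c(boulder = 0.4, flat = 0.4, gulley = 0.2),
                                  seed = NULL) {
  with_seed(seed, {
    props <- props[SUBSTRATE_CATEGORIES]
    props[is.na(props)] <- 0
    nbx <- max(1L, ceiling(window$width / block_size))
    nby <- max(1L, ceiling(window$height / block_size))
    blocks <- matrix(sample.int(3L, nbx * nby, replace = TRUE,
                                prob = props / sum(props)), nby, nbx)
    ncx <- max(1L, round(window$width / cell_size))
    ncy <- max(1L, round(window$height / cell_size))
    bx <- pmin(ceiling(seq_len(ncx) / (ncx / nbx)), nbx)
    by <- pmin(ceiling(seq_len(ncy) / (ncy / nby)), nby)
    substrate_mask(blocks[by, bx, drop = FALSE], window)
  })
}

#' Per-cell intensity surface from a mask
#'
#' Builds the piecewise-constant intensity surface lambda(x) used by the
#' heterogeneous Poisson machinery: each mask cell gets the intensity of its
#' substrate category.
#'
#' @param mask a [substrate_mask()].
#' @param values named numeric vector of intensities (points/cm^2), one per
#'   category present in the mask; all must be >= 0.
#' @return an object of class `"intensity_map"` with fields `values`
#'   (matrix aligned to the mask grid), `mask`, `window`.
#' @export
intensity_map <- function(mask, values) {
  stopifnot(is_mask(mask))
  v <- values[mask$categories]
  if (anyNA(v)) stop("'values' must name every mask category", call. = FALSE)
  if (any(v < 0)) stop("intensities must be >= 0", call. = FALSE)
  structure(list(values = matrix(as.numeric(v)[mask$grid],
                                 nrow(mask$grid), ncol(mask$grid)),
                 mask = mask, window = mask$window),
            class = "intensity_map")
}
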