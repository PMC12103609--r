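#' Rectangular observation window
#'
#' The sampling frame within which coral positions are recorded.  The study
#' design places a 1.75 m x 1.75 m sample box on each seabed photograph, so
#' the default window is 175 cm x 175 cm (3.0625 m^2, printed as 3.06 m^2
#' coverage at 2 decimals).  Coordinates are in centimetres with the origin
#' at the lower-left corner, x rightward, y upward.
#'
#' @param width,height side lengths in cm; both must be positive.
#' @return an object of class `"study_window"` with fields `width`, `height`,
#'   `area_cm2` and `area_m2`.
#' @examples
#' w <- study_window()
#' w$area_m2   # 3.0625
#' @export
study_window <- function(width = 175, height = 175) {
  if (!is.numeric(width) || !is.numeric(height) ||
      length(width) != 1L || length(height) != 1L ||
      !is.finite(width) || !is.finite(height) || width <= 0 || height <= 0)
    stop("window sides must be single positive numbers (cm)", call. = FALSE)
  structure(list(width = as.numeric(width), height = as.numeric(height),
                 area_cm2 = as.numeric(width) * as.numeric(height),
                 area_m2 = as.numeric(width) * as.numeric(height) / 1e4),
            class = "study_window")
}

#' @export
print.study_window <- function(x, ...) {
  cat(sprintf("Observation window: %g x %g cm (%.4f m2)\n",
              x$width, x$height, x$area_m2))
  invisible(x)
}

is_window <- function(x) inherits(x, "study_window")

#' Planar point pattern of one morph in one window
#'
#' Container for the positions of all individuals of one colour morph inside
#' a rectangular observation window.  All coordinates must be finite and lie
#' inside the window (closed boundaries).
#'
#' @param x,y numeric coordinate vectors (cm) of equal length.
#' @param window a [study_window()].
#' @param morph optional label, e.g. `"orange"` or `"pink"`.
#' @return an object of class `"coral_ppp"` with fields `x`, `y`, `n`,
#'   `window` and `morph`.
#' @examples
#' p <- point_pattern(c(10, 20), c(10, 30), study_window())
#' p$n
#' @export
point_pattern <- function(x, y, window, morph = NULL) {
  if (!is_window(window)) stop("'window' must be a study_window", call. = FALSE)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) && (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y))))
    stop("coordinates must be finite and non-missing", call. = FALSE)
  bad <- which(x < 0 | x > window$width | y < 0 | y > window$height)
  if (length(bad))
    stop(sprintf("point(s) outside window: index %s",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  structure(list(x = x, y = y, n = length(x), window = window,
                 morph = if (is.null(morph)) NA_character_ else as.character(morph)),
            class = "coral_ppp")
}

is_ppp <- function(x) inherits(x, "coral_ppp")

# estimated first-order intensity (points per cm^2), whole-window count
pattern_intensity <- function(pattern) pattern$n / pattern$window$area_cm2

#' @export
print.coral_ppp <- function(x, ...) {
  cat(sprintf("Point pattern: %d points%s in %g x %g cm window\n", x$n,
              if (is.na(x$morph)) "" else paste0(" (", x$morph, ")"),
              x$window$width, x$window$height))
  invisible(x)
}

#' @export
as.data.frame.coral_ppp <- function(x, ...) {
  data.frame(x_cm = x$x, y_cm = x$y,
             morph = rep(x$morph, x$n))
}

#' @export
plot.coral_ppp <- function(x, pch = 19, cex = 0.6,
                           col = if (identical(x$morph, "pink")) "violetred1" else "darkorange",
                           ...) {
  plot(NA, xlim = c(0, x$window$width), ylim = c(0, x$window$height),
       asp = 1, xlab = "x (cm)", ylab = "y (cm)",
       main = if (is.na(x$morph)) "point pattern" else x$morph, ...)
  rect(0, 0, x$window$width, x$window$height, border = "grey40")
  points(x$x, x$y, pch = pch, cex = cex, col = col)
  invisible(x)
}
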