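# Study-level community summaries: densities, community-type grouping,
# per-group medians and the between-group nearest-neighbour comparison.

#' Density of individuals per square metre
#'
#' @param count number of individuals (>= 0).
#' @param window a [study_window()].
#' @param digits optional rounding (report tables use 1 decimal); `NULL`
#'   returns the raw value, which is exactly linear in `count`.
#' @return individuals/m^2.
#' @examples
#' site_density(441, study_window(), digits = 1)  # 144.0
#' @export
site_density <- function(count, window, digits = NULL) {
  stopifnot(is_window(window))
  if (any(count < 0)) stop("'count' must be >= 0", call. = FALSE)
  d <- count / window$area_m2
  if (is.null(digits)) d else round(d, digits)
}

#' Assign sites to community-type groups
#'
#' Sites are clustered on their morph composition: the per-site proportion
#' vectors (orange, pink) are compared with the Bray-Curtis dissimilarity,
#' clustered agglomeratively (average linkage by default) and the tree is
#' cut into three groups.  Groups are labelled by their mean orange
#' proportion: highest -> `"O"` (orange-dominant), lowest -> `"P"`
#' (pink-dominant), middle -> `"M"` (mixed).  Sites where one morph is
#' absent get proportion vectors (1, 0) or (0, 1); no pseudo-counts.
#'
#' @param compositions data.frame with columns `site_id`, `orange`, `pink`
#'   (counts).
#' @param k number of groups.
#' @param method linkage passed to [stats::hclust()].
#' @return an object of class `"coral_groups"`: fields `groups` (named
#'   character vector site_id -> label), `tree` (the hclust object),
#'   `proportions`.
#' @examples
#' comp <- data.frame(site_id = c("a", "b", "c"),
#'                    orange = c(100, 0, 50), pink = c(0, 100, 50))
#' assign_groups(comp)$groups
#' @export
assign_groups <- function(compositions, k = 3, method = "average") {
  need <- c("site_id", "orange", "pink")
  if (!all(need %in% names(compositions)))
    stop("'compositions' needs columns site_id, orange, pink", call. = FALSE)
  n <- nrow(compositions)
  if (n < k) stop(sprintf("need at least %d sites to form %d groups", k, k),
                  call. = FALSE)
  tot <- compositions$orange + compositions$pink
  if (any(tot <= 0)) stop("every site must contain at least one coral", call. = FALSE)
  prop <- cbind(orange = compositions$orange / tot,
                pink = compositions$pink / tot)
  rownames(prop) <- compositions$site_id
  d <- vegan::vegdist(prop, method = "bray")
  tree <- hclust(d, method = method)
  cl <- cutree(tree, k = k)
  mean_orange <- tapply(prop[, "orange"], cl, mean)
  ord <- order(mean_orange, decreasing = TRUE)   # highest orange first
  labels <- character(k)
  labels[ord[1]] <- "O"; labels[ord[k]] <- "P"
  if (k > 2) labels[ord[seq(2, k - 1)]] <- "M"
  groups <- setNames(labels[cl], compositions$site_id)
  structure(list(groups = groups, tree = tree, proportions = prop),
            class = "coral_groups")
}

#' @export
print.coral_groups <- function(x, ...) {
  tab <- table(factor(x$groups, levels = c("O", "P", "M")))
  cat(sprintf("Community groups: O = %d site(s), P = %d, M = %d\n",
              tab[["O"]], tab[["P"]], tab[["M"]]))
  invisible(x)
}

#' Median of a per-site summary field within a group
#'
#' @param summaries summary data.frame (see [write_summary_table()]) with at
#'   least `group`, `morph` and the requested field.
#' @param group group label (`"O"`, `"P"`, `"M"`).
#' @param morph morph label.
#' @param field column name, e.g. `"nn_median_cm"`, `"offspring_nonempty"`,
#'   `"n"`, `"density_m2"`.
#' @return the median over contributing sites (even counts: midpoint).
#' @export
group_median <- function(summaries, group, morph, field) {
  sel <- summaries$group == group & summaries$morph == morph
  vals <- summaries[[field]][sel]
  vals <- vals[!is.na(vals)]
  if (!length(vals))
    stop(sprintf("no sites contribute to group %s / %s / %s", group, morph, field),
         call. = FALSE)
  median(vals)
}

#' Compare nearest-neighbour distances between two groups
#'
#' Two-sided Wilcoxon rank-sum test on per-site nearest-neighbour medians
#' (the site, not the individual coral, is the sampling unit).  The exact
#' distribution is enumerated for combined n <= 25 without ties; otherwise
#' the normal approximation with tie correction is used.
#'
#' @param a,b numeric vectors of per-site values for the two groups.
#' @return list with `statistic` (rank-sum W), `p_value`, `method`.
#' @examples
#' compare_nn_groups(c(1, 2, 3), c(10, 11, 12))$p_value  # 0.1
#' @export
compare_nn_groups <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty", call. = FALSE)
  if (length(a) < 2 || length(b) < 2) {
    warning("a group has fewer than 2 sites; p not estimable", call. = FALSE)
    return(list(statistic = NA_real_, p_value = NA_real_,
                method = "Wilcoxon rank-sum (not estimable)"))
  }
  exact <- (length(a) + length(b)) <= 25 && !anyDuplicated(c(a, b))
  ht <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided",
                                     exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = ht$method)
}

#' Percent change between two values
#'
#' @param before reference value (> 0).
#' @param after new value.
#' @param digits rounding; the default reports whole percent as in study
#'   tables.
#' @return `100 * (after - before) / before`, rounded.
#' @examples
#' percent_change(6.3, 9.4)  # 49
#' @export
percent_change <- function(before, after, digits = 0) {
  if (any(before <= 0)) stop("'before' must be > 0", call. = FALSE)
  round(100 * (after - before) / before, digits)
}
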