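.sc_index_names <- c("r_max", "x_max", "x_minus", "x_plus", "pro_r", "deg_r")

#' Average resistance profiles over a group of subjects
#'
#' Subjects differ in SC thickness, so profiles are made commensurable by
#' evaluating each subject's interpolated curve on a common uniform grid over
#' normalized depth and averaging pointwise.  Per-subject indices are
#' computed individually and then summarised (the mean of per-subject indices,
#' not the indices of the mean profile, is the default cohort summary;
#' subjects with a flagged-undefined rate are excluded from that rate's mean
#' and counted).
#'
#' @param profiles Non-empty list of `"sc_resistance"` objects.
#' @param grid_size Common grid resolution, default 101.
#' @param group_label Label for the group (default: taken from the first
#'   profile carrying one).
#' @param threshold Threshold fraction passed to [sc_indices()].
#' @return An object of class `"sc_group"`: list with `group_label`, `grid_x`,
#'   `mean_r`, `n`, `per_subject_indices` (list of [sc_indices()] results),
#'   `index_table` (data frame, one row per subject), `index_means`,
#'   `index_sds`, `index_n` (usable counts per index), and `indices_of_mean`
#'   (indices computed on the mean profile, for comparison).
#' @export
mean_profile <- function(profiles, grid_size = 101, group_label = NULL,
                         threshold = 0.8) {
  if (!is.list(profiles) || length(profiles) == 0L)
    stop("profiles must be a non-empty list of sc_resistance objects")
  if (inherits(profiles, "sc_resistance")) profiles <- list(profiles)
  if (!all(vapply(profiles, inherits, logical(1), "sc_resistance")))
    stop("all elements must be sc_resistance objects")
  grid_x <- seq(0, 1, length.out = grid_size)
  mat <- vapply(profiles, function(p) predict(p, grid_x), numeric(grid_size))
  mean_r <- rowMeans(mat)
  ixs <- lapply(profiles, sc_indices, threshold = threshold,
                grid_size = grid_size)
  tab <- do.call(rbind, lapply(ixs, as.data.frame))
  vals <- as.matrix(tab[, .sc_index_names, drop = FALSE])
  if (is.null(group_label)) {
    gl <- vapply(profiles, `[[`, character(1), "group_label")
    group_label <- if (any(!is.na(gl))) unname(gl[!is.na(gl)][1L]) else "group"
  }
  mp <- resistance_profile(grid_x, mean_r, subject_id = group_label,
                           group_label = group_label)
  structure(
    list(group_label = group_label, grid_x = grid_x, mean_r = mean_r,
         n = length(profiles), per_subject_indices = ixs, index_table = tab,
         index_means = colMeans(vals, na.rm = TRUE),
         index_sds = apply(vals, 2, sd, na.rm = TRUE),
         index_n = colSums(!is.na(vals)),
         indices_of_mean = sc_indices(mp, threshold = threshold,
                                      grid_size = grid_size)),
    class = "sc_group")
}

#' @export
print.sc_group <- function(x, ...) {
  cat("Cohort mean resistance profile: ", x$group_label, " (n = ", x$n,
      ", grid ", length(x$grid_x), ")\n", sep = "")
  m <- rbind(mean = x$index_means, sd = x$index_sds, n = x$index_n)
  print(round(m, 4))
  invisible(x)
}

#' @export
as.data.frame.sc_group <- function(x, ...) {
  data.frame(group_label = x$group_label, x_normalized = x$grid_x,
             mean_resistance_au = x$mean_r, n = x$n,
             stringsAsFactors = FALSE)
}

.sc_usable <- function(group, index_name) {
  v <- group$index_table[[index_name]]
  v[!is.na(v)]
}

#' Compare an index between groups
#'
#' Tests whether the mean of one profile index differs between cohorts: for
#' two groups a two-sided pooled-variance Student's t-test (a Welch option is
#' available), for three or more groups a one-way ANOVA F-test.  Subjects
#' whose index is flagged undefined are excluded, and every group must retain
#' at least two usable values.  Significance stars follow the usual
#' convention (* p<0.05, ** p<0.01, *** p<0.001).
#'
#' @param groups List of two or more `"sc_group"` objects.
#' @param index_name One of `"r_max"`, `"x_max"`, `"x_minus"`, `"x_plus"`,
#'   `"pro_r"`, `"deg_r"`.
#' @param welch Use the Welch (unequal-variance) t-test for two groups?
#'   Default `FALSE` (classical pooled Student's t).
#' @param method `"auto"` (default: t-test for two groups, ANOVA for more),
#'   or force `"t"` / `"anova"`.  With equal variances assumed, the two-group
#'   ANOVA F equals the squared pooled t.
#' @return An object of class `"sc_comparison"`: list with `index`,
#'   `group_labels`, `test` ("t" or "anova"), `statistic`, `df`, `p_value`,
#'   `stars`, `group_means`, `group_sds`, `group_n`.
#' @export
compare_indices <- function(groups, index_name, welch = FALSE,
                            method = c("auto", "t", "anova")) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least two groups")
  if (!all(vapply(groups, inherits, logical(1), "sc_group")))
    stop("all elements must be sc_group objects (see mean_profile)")
  method <- match.arg(method)
  index_name <- match.arg(index_name, .sc_index_names)
  vals <- lapply(groups, .sc_usable, index_name)
  labs <- vapply(groups, `[[`, character(1), "group_label")
  short <- vapply(vals, length, integer(1)) < 2L
  if (any(short))
    stop("group(s) with fewer than 2 usable values for ", index_name, ": ",
         paste(labs[short], collapse = ", "))
  if (method == "t" && length(groups) != 2L)
    stop("the t-test path needs exactly two groups")

  use_t <- if (method == "auto") length(groups) == 2L else method == "t"
  if (use_t) {
    tt <- t.test(vals[[1L]], vals[[2L]], var.equal = !welch,
                 alternative = "two.sided")
    test <- "t"; statistic <- unname(tt$statistic)
    df <- unname(tt$parameter); p <- tt$p.value
  } else {
    y <- unlist(vals)
    g <- factor(rep(labs, vapply(vals, length, integer(1))), levels = labs)
    ow <- oneway.test(y ~ g, var.equal = TRUE)
    test <- "anova"; statistic <- unname(ow$statistic)
    df <- unname(ow$parameter); p <- ow$p.value
  }
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**"
           else if (p < 0.05) "*" else ""
  structure(
    list(index = index_name, group_labels = labs, test = test,
         statistic = statistic, df = df, p_value = p, stars = stars,
         group_means = vapply(vals, mean, numeric(1)),
         group_sds = vapply(vals, sd, numeric(1)),
         group_n = vapply(vals, length, integer(1))),
    class = "sc_comparison")
}

#' @export
print.sc_comparison <- function(x, ...) {
  cat("Comparison of ", x$index, " across ",
      paste(x$group_labels, collapse = " / "), "\n", sep = "")
  cat("  means:", paste(sprintf("%.4g", x$group_means), collapse = " / "), "\n")
  if (x$test == "t") {
    cat(sprintf("  t = %.4g, df = %s, p = %.4g %s\n", x$statistic,
                format(x$df, digits = 4), x$p_value, x$stars))
  } else {
    cat(sprintf("  F(%s, %s) = %.4g, p = %.4g %s\n",
                format(x$df[1L], digits = 4), format(x$df[2L], digits = 4),
                x$statistic, x$p_value, x$stars))
  }
  invisible(x)
}

#' @export
as.data.frame.sc_comparison <- function(x, ...) {
  data.frame(index = x$index,
             contrast = paste(x$group_labels, collapse = " vs "),
             test = x$test, statistic = x$statistic,
             df1 = x$df[1L], df2 = if (length(x$df) > 1L) x$df[2L] else NA_real_,
             p_value = x$p_value, stars = x$stars,
             stringsAsFactors = FALSE)
}

#' Depth-resolved treatment (oil) effect on the mean resistance profile
#'
#' Quantifies the effect of a topical treatment as the relative change of the
#' group mean resistance at each normalized depth,
#' `100 * (after - before) / before` (percent), plus scalar summaries (maximum
#' and mean over depth).  Occlusive oils raise resistance across the whole SC
#' depth in a depth-dependent manner; this curve shows where.
#'
#' Grid points with non-positive baseline resistance are reported as `NA` and
#' excluded from the summaries with a warning.
#'
#' @param before,after `"sc_group"` objects sharing the same `grid_x`.
#' @return An object of class `"sc_effect"`: list with `grid_x`,
#'   `rel_change_pct`, `max_change_pct`, `mean_change_pct`, `n_undefined`,
#'   `labels`.
#' @export
treatment_effect <- function(before, after) {
  stopifnot(inherits(before, "sc_group"), inherits(after, "sc_group"))
  if (length(before$grid_x) != length(after$grid_x) ||
      max(abs(before$grid_x - after$grid_x)) > 1e-12)
    stop("before and after groups must share the same normalized-depth grid")
  bad <- before$mean_r <= 0
  rel <- 100 * (after$mean_r - before$mean_r) / before$mean_r
  rel[bad] <- NA_real_
  if (any(bad))
    warning(sum(bad), " grid point(s) with non-positive baseline resistance ",
            "reported as NA and excluded from summaries")
  structure(
    list(grid_x = before$grid_x, rel_change_pct = rel,
         max_change_pct = max(rel, na.rm = TRUE),
         mean_change_pct = mean(rel, na.rm = TRUE),
         n_undefined = sum(bad),
         labels = c(before = before$group_label, after = after$group_label)),
    class = "sc_effect")
}

#' @export
print.sc_effect <- function(x, ...) {
  cat("Treatment effect on mean resistance: ", x$labels[["before"]], " -> ",
      x$labels[["after"]], "\n", sep = "")
  cat(sprintf("  max over depth: %+.2f%%   mean over depth: %+.2f%%\n",
              x$max_change_pct, x$mean_change_pct))
  if (x$n_undefined)
    cat("  ", x$n_undefined, "grid point(s) undefined (baseline <= 0)\n")
  invisible(x)
}

#' @export
as.data.frame.sc_effect <- function(x, ...) {
  data.frame(x_normalized = x$grid_x, rel_change_pct = x$rel_change_pct,
             stringsAsFactors = FALSE)
}
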