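#' Construct a water concentration depth profile
#'
#' Bundles one subject's depth-resolved water concentrations (as measured by
#' confocal Raman spectroscopy, % mass ratio water/protein) with the subject's
#' TEWL measurement.  Depth 0 is the skin surface; depth increases into the
#' skin.  Sampling must be uniform (2 um for standard Raman profilers).
#'
#' @param subject_id Character scalar identifying the subject.
#' @param depths Numeric vector of depths in um, starting at 0, strictly
#'   increasing and uniformly spaced (tolerance 1e-6 um).
#' @param water Numeric vector of water concentrations in mass%, same length
#'   as `depths`; finite and non-negative.
#' @param tewl Positive scalar, transepidermal water loss in g h^-1 m^-2.
#' @param group_label Optional cohort / site / treatment label.
#' @return An object of class `"water_profile"`.
#' @examples
#' wp <- water_profile("a", depths = c(0, 2, 4), water = c(30, 40, 50),
#'                     tewl = 10)
#' wp
#' @export
water_profile <- function(subject_id, depths, water, tewl, group_label = NULL) {
  subject_id <- as.character(subject_id)
  if (length(subject_id) != 1L || is.na(subject_id) || !nzchar(subject_id))
    stop("subject_id must be a non-empty string")
  depths <- as.numeric(depths)
  water <- as.numeric(water)
  if (length(depths) != length(water))
    stop("depths and water must have the same length (subject ", subject_id, ")")
  if (length(depths) < 3L)
    stop("at least 3 depth samples are required (subject ", subject_id, ")")
  if (!all(is.finite(depths)) || !all(is.finite(water)))
    stop("depths and water must be finite (subject ", subject_id, ")")
  if (abs(depths[1L]) > 1e-9)
    stop("first depth must be 0 (skin surface; subject ", subject_id, ")")
  dd <- diff(depths)
  if (any(dd <= 0))
    stop("depths must be strictly increasing (subject ", subject_id, ")")
  if (max(dd) - min(dd) > 1e-6)
    stop("non-uniform depth spacing (subject ", subject_id,
         "): steps range from ", format(min(dd)), " to ", format(max(dd)), " um")
  if (any(water < 0))
    stop("negative water concentration (subject ", subject_id, ")")
  if (!is.numeric(tewl) || length(tewl) != 1L || !is.finite(tewl) || tewl <= 0)
    stop("tewl must be a single positive number (subject ", subject_id, ")")
  structure(
    list(subject_id = subject_id,
         depths = depths,
         water = water,
         tewl = as.numeric(tewl),
         group_label = if (is.null(group_label)) NA_character_
                       else as.character(group_label)[1L],
         step = mean(dd)),
    class = "water_profile")
}

#' @export
print.water_profile <- function(x, ...) {
  cat("Water concentration profile: subject", x$subject_id)
  if (!is.na(x$group_label)) cat(" [", x$group_label, "]", sep = "")
  cat("\n  ", length(x$depths), " samples, 0-", max(x$depths), " um (step ",
      format(x$step), " um)\n", sep = "")
  cat("  water: ", format(min(x$water), digits = 4), "-",
      format(max(x$water), digits = 4), " mass%   TEWL: ",
      format(x$tewl, digits = 4), " g/h/m^2\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.water_profile <- function(x, ...) {
  data.frame(subject_id = x$subject_id,
             depth_um = x$depths,
             water_masspct = x$water,
             stringsAsFactors = FALSE)
}

#' Validate a cohort of water profiles
#'
#' Runs non-destructive quality checks over a set of profiles: per-subject
#' warnings (water not monotone non-decreasing with depth, fewer than 5
#' samples) and global consistency checks (same depth spacing across
#' subjects).  Warnings flag features that downstream code tolerates (e.g. a
#' local dip in water yields a negative compartment resistance) but that merit
#' inspection; none of them is an error.
#'
#' @param profiles A non-empty list of [water_profile()] objects.
#' @return A `"cohort_validation"` object: a data frame of warnings with
#'   columns `subject_id`, `check`, `message` (zero rows when clean) plus a
#'   `n_subjects` attribute.
#' @export
validate_cohort <- function(profiles) {
  if (!is.list(profiles) || length(profiles) == 0L)
    stop("profiles must be a non-empty list of water_profile objects")
  if (inherits(profiles, "water_profile")) profiles <- list(profiles)
  ok <- vapply(profiles, inherits, logical(1), "water_profile")
  if (!all(ok)) stop("all elements must be water_profile objects")

  rows <- list()
  add <- function(id, check, msg)
    rows[[length(rows) + 1L]] <<- data.frame(subject_id = id, check = check,
                                             message = msg,
                                             stringsAsFactors = FALSE)
  for (p in profiles) {
    if (any(diff(p$water) < 0)) {
      i <- which(diff(p$water) < 0)[1L]
      add(p$subject_id, "non-monotone",
          sprintf("water decreases between %g and %g um",
                  p$depths[i], p$depths[i + 1L]))
    }
    if (length(p$depths) < 5L)
      add(p$subject_id, "few-samples",
          sprintf("only %d depth samples", length(p$depths)))
  }
  steps <- vapply(profiles, `[[`, numeric(1), "step")
  if (max(steps) - min(steps) > 1e-6)
    add("<cohort>", "spacing",
        sprintf("mixed depth spacings across subjects: %s um",
                paste(format(sort(unique(round(steps, 9)))), collapse = ", ")))

  report <- if (length(rows)) do.call(rbind, rows)
            else data.frame(subject_id = character(), check = character(),
                            message = character(), stringsAsFactors = FALSE)
  structure(report, n_subjects = length(profiles),
            class = c("cohort_validation", class(report)))
}

#' @export
print.cohort_validation <- function(x, ...) {
  cat("Cohort validation:", attr(x, "n_subjects"), "subject(s),",
      nrow(x), "warning(s)\n")
  if (nrow(x)) print.data.frame(x, row.names = FALSE)
  invisible(x)
}
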