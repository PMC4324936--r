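# Synthetic cohorts with known ground truth.
#
# Ground truth is specified in resistance space (a piecewise-linear curve over
# normalized depth, in the same per-compartment a.u. the pipeline estimates)
# and water profiles are *derived* from it by inverting the compartment
# relation W_i = W_0 + TEWL * sum_{j<=i} R_j.  This makes recovery tests exact
# by construction at zero noise.

#' Ground-truth specification for synthetic profiles
#'
#' Defines the true resistance curve (over normalized depth) and the
#' measurement conditions used to synthesise water profiles.  Defaults
#' emulate healthy adult volar forearm skin: SC thickness 20 um sampled every
#' 2 um, surface water around 30 mass% rising to about 70 mass% at the
#' viable epidermis, TEWL about 10 g/h/m^2 with 30% between-subject lognormal
#' variation, and 2 mass% additive Gaussian measurement noise on water
#' values.
#'
#' Shapes: `"tent"` — unimodal piecewise-linear curve from `r0` at the
#' surface to `r_peak` at `x_peak` down to `r1` at the SC/SG interface;
#' `"two_peak"` — two local maxima with a valley between (as seen after
#' petrolatum application); `"constant"` — flat curve (degenerate for the
#' threshold indices).
#'
#' @param shape `"tent"`, `"two_peak"` or `"constant"`.
#' @param r0,r1 Resistance at the surface / SC-SG interface (a.u.).
#' @param r_peak Peak resistance (tent), or vector of two peaks (two_peak).
#' @param x_peak Peak location(s) in (0, 1).
#' @param r_valley Valley value between the peaks (two_peak only).
#' @param x_valley Valley location (two_peak only; default midway).
#' @param r_const Constant level (constant shape).
#' @param tewl_mean,tewl_cv Mean and coefficient of variation of the
#'   between-subject lognormal TEWL distribution (g/h/m^2).
#' @param w0_mean Surface water concentration (mass%).
#' @param sc_thickness True SC thickness (um); a positive multiple of `step`
#'   so recovery is exact at compartment resolution.
#' @param step Sampling step (um), default 2.
#' @param noise_sd Additive Gaussian noise on water values (mass%).
#' @param seed Integer seed; together with the subject id it fully determines
#'   each synthesised profile.
#' @return An object of class `"sc_truth"` with the parameters plus `knots`
#'   (the piecewise-linear truth curve).
#' @export
synthetic_truth <- function(shape = c("tent", "two_peak", "constant"),
                            r0 = 0.1, r_peak = 0.7, x_peak = 0.5, r1 = 0.1,
                            r_valley = 0.4, x_valley = NULL, r_const = 0.5,
                            tewl_mean = 10, tewl_cv = 0.3, w0_mean = 30,
                            sc_thickness = 20, step = 2, noise_sd = 2,
                            seed = 1L) {
  shape <- match.arg(shape)
  if (sc_thickness <= 0 || step <= 0 ||
      abs(sc_thickness / step - round(sc_thickness / step)) > 1e-9)
    stop("sc_thickness must be a positive multiple of step")
  if (round(sc_thickness / step) < 2) stop("need at least 2 compartments")
  knots <- switch(shape,
    tent = {
      stopifnot(length(r_peak) == 1L, x_peak > 0, x_peak < 1)
      list(x = c(0, x_peak, 1), r = c(r0, r_peak, r1))
    },
    two_peak = {
      if (length(r_peak) == 1L) r_peak <- c(r_peak, 0.85 * r_peak)
      if (length(x_peak) == 1L) x_peak <- c(0.35, 0.75)
      stopifnot(length(r_peak) == 2L, length(x_peak) == 2L,
                x_peak[1L] < x_peak[2L], x_peak[1L] > 0, x_peak[2L] < 1)
      xv <- if (is.null(x_valley)) mean(x_peak) else x_valley
      list(x = c(0, x_peak[1L], xv, x_peak[2L], 1),
           r = c(r0, r_peak[1L], r_valley, r_peak[2L], r1))
    },
    constant = list(x = c(0, 1), r = c(r_const, r_const)))
  if (any(knots$r < 0))
    stop("truth resistance curve must be non-negative")
  structure(
    list(shape = shape, knots = knots, tewl_mean = tewl_mean,
         tewl_cv = tewl_cv, w0_mean = w0_mean, sc_thickness = sc_thickness,
         step = step, noise_sd = noise_sd, seed = as.integer(seed)),
    class = "sc_truth")
}

#' @export
print.sc_truth <- function(x, ...) {
  cat("Synthetic ground truth: ", x$shape, " resistance curve, peak ",
      format(max(x$knots$r)), " a.u.\n", sep = "")
  cat("  SC ", x$sc_thickness, " um @ ", x$step, " um; TEWL ~ lognormal(mean ",
      x$tewl_mean, ", cv ", x$tewl_cv, "); W0 ", x$w0_mean,
      " mass%; noise sd ", x$noise_sd, " mass%; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# Evaluate the piecewise-linear truth curve.
.sc_truth_eval <- function(truth, x) {
  approx(truth$knots$x, truth$knots$r, xout = x, rule = 2)$y
}

# Exact average of the piecewise-linear truth curve over [a, b] in normalized
# depth (trapezoid over the segment-refined breakpoints).
.sc_truth_avg <- function(truth, a, b) {
  xs <- sort(unique(c(a, b, truth$knots$x[truth$knots$x > a &
                                          truth$knots$x < b])))
  ys <- .sc_truth_eval(truth, xs)
  sum((ys[-1L] + ys[-length(ys)]) / 2 * diff(xs)) / (b - a)
}

# Compartment-averaged truth resistances for the truth's own sampling grid:
# cumulative trapezoid of the piecewise-linear curve at the union of knots
# and compartment edges (exact), differenced at the edges.
.sc_truth_compartments <- function(truth) {
  n <- round(truth$sc_thickness / truth$step)
  edges <- seq(0, 1, length.out = n + 1L)
  xs <- sort(unique(c(edges, truth$knots$x)))
  ys <- .sc_truth_eval(truth, xs)
  cum <- c(0, cumsum((ys[-1L] + ys[-length(ys)]) / 2 * diff(xs)))
  at_edges <- cum[match(edges, xs)]
  diff(at_edges) / diff(edges)
}

#' Closed-form indices of a synthetic truth curve
#'
#' Computes the six profile indices analytically from the piecewise-linear
#' segment geometry of the truth curve — peak from the knot values,
#' threshold crossings from exact line–threshold intersections — with no
#' interpolation object or evaluation grid involved.  This is the independent
#' reference the pipeline's grid-based [sc_indices()] is checked against.
#'
#' @param truth An [synthetic_truth()] object.
#' @param threshold Threshold fraction of the peak, default 0.8.
#' @return An `"sc_indices"` object (degenerate flags set for the constant
#'   shape, whose rates are undefined).
#' @export
truth_indices <- function(truth, threshold = 0.8) {
  stopifnot(inherits(truth, "sc_truth"))
  x <- truth$knots$x; r <- truth$knots$r
  r_max <- max(r)
  x_max <- x[which.max(r)]               # first (shallowest) attaining knot
  thr <- threshold * r_max
  eps <- 1e-12 * max(r_max, 1)
  pts <- x[r >= thr - eps]
  for (i in seq_len(length(x) - 1L)) {
    if ((r[i] - thr) * (r[i + 1L] - thr) < 0)
      pts <- c(pts, x[i] + (thr - r[i]) / (r[i + 1L] - r[i]) *
                             (x[i + 1L] - x[i]))
  }
  x_minus <- min(pts); x_plus <- max(pts)
  flags <- character(0)
  if (x_minus <= 0) { x_minus <- 0; flags <- c(flags, "no_top_crossing") }
  if (x_plus >= 1) { x_plus <- 1; flags <- c(flags, "no_bottom_crossing") }
  pro_r <- if ("no_bottom_crossing" %in% flags) NA_real_
           else (thr - r[length(r)]) / (1 - x_plus)
  deg_r <- if ("no_top_crossing" %in% flags) NA_real_
           else (thr - r[1L]) / x_minus
  structure(
    list(subject_id = "truth", r_max = r_max, x_max = x_max,
         x_minus = x_minus, x_plus = x_plus, pro_r = pro_r, deg_r = deg_r,
         threshold_fraction = threshold, flags = flags,
         r0 = r[1L], r1 = r[length(r)]),
    class = "sc_indices")
}

# Deterministic per-subject stream seed from the truth seed and a string id.
.sc_subseed <- function(seed, subject_id) {
  h <- 0
  for (k in utf8ToInt(as.character(subject_id)))
    h <- (h * 31 + k) %% 2147483629
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483629)
}

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
.sc_with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Synthesise one subject's water profile from a ground truth
#'
#' Draws the subject's TEWL from the lognormal between-subject distribution,
#' inverts the compartment relation to obtain noiseless water values
#' `W_i = w0_mean + TEWL * sum(R*_j, j <= i)` on the sampling grid out to the
#' true SC thickness (with `R*_j` the truth curve averaged over compartment
#' `j`), appends a plateau beyond the SC — a logistic transition to the
#' viable-epidermis water level, so thickness estimators see realistic
#' shapes — and adds i.i.d. Gaussian measurement noise.  Output is fully
#' determined by `truth$seed` and `subject_id`.
#'
#' @param truth An [synthetic_truth()].
#' @param subject_id Subject identifier (also seeds the subject's RNG stream).
#' @param group_label Optional group label carried into the profile.
#' @return A [water_profile()].
#' @export
synthesize_profile <- function(truth, subject_id, group_label = NULL) {
  stopifnot(inherits(truth, "sc_truth"))
  n <- round(truth$sc_thickness / truth$step)
  rstar <- .sc_truth_compartments(truth)
  .sc_with_seed(.sc_subseed(truth$seed, subject_id), {
    sdlog <- sqrt(log(1 + truth$tewl_cv^2))
    tewl <- rlnorm(1, meanlog = log(truth$tewl_mean) - sdlog^2 / 2,
                   sdlog = sdlog)
    w_sc <- truth$w0_mean + tewl * c(0, cumsum(rstar))
    wn <- w_sc[n + 1L]
    # viable-epidermis plateau: logistic rise of ~4 mass% over ~3 um,
    # appended for 10 um beyond the SC so thickness estimation is exercised
    d_extra <- seq(truth$step, 10, by = truth$step)
    w_ve <- wn + 4 / (1 + exp(-(d_extra - 3) / 1.2))
    depths <- seq(0, truth$sc_thickness + max(d_extra), by = truth$step)
    water <- c(w_sc, w_ve)
    if (truth$noise_sd > 0)
      water <- water + rnorm(length(water), sd = truth$noise_sd)
    water <- pmax(water, 0)
    water_profile(subject_id, depths, water, tewl, group_label = group_label)
  })
}

#' Synthesise a multi-group cohort with a truth record
#'
#' Generates `n` subjects per group.  Each subject's truth curve is a
#' perturbation of the group truth: resistance knot values are scaled by a
#' common per-subject lognormal factor (`between_cv`), preserving the curve
#' shape, so the subject's true `r_max` is the group `r_max` times that
#' factor.  An *oil-effect* mode scales a base group's resistances by a
#' depth-dependent factor to create paired before/after sets.
#'
#' @param group_specs Named list: one element per group, each a list with
#'   elements `truth` (an [synthetic_truth()]) and `n` (subjects).
#' @param seed Integer master seed (overrides each truth's own seed).
#' @param between_cv Between-subject lognormal CV of the resistance scale,
#'   default 0.15.
#' @param oil_factor Optional: either a single number or a function of
#'   normalized depth.  For each group `g` an additional group `"g_after"` is
#'   generated from the *same subjects* with resistances multiplied by the
#'   factor (paired before/after design).
#' @return List with `profiles` (named list of [water_profile()]s),
#'   `truth_table` (data frame: subject, group, true tewl scale, true r_max,
#'   true sc thickness), and `group_truths`.
#' @export
synthesize_cohort <- function(group_specs, seed = 1L, between_cv = 0.15,
                              oil_factor = NULL) {
  stopifnot(is.list(group_specs), length(group_specs) >= 1L)
  if (is.null(names(group_specs)) || any(!nzchar(names(group_specs))))
    stop("group_specs must be a named list")
  profiles <- list()
  rows <- list()
  for (g in names(group_specs)) {
    spec <- group_specs[[g]]
    stopifnot(inherits(spec$truth, "sc_truth"), spec$n >= 1)
    base <- spec$truth
    base$seed <- as.integer(seed)
    for (j in seq_len(spec$n)) {
      sid <- sprintf("%s_%02d", g, j)
      scale_j <- .sc_with_seed(.sc_subseed(seed, paste0(sid, "|scale")), {
        sdl <- sqrt(log(1 + between_cv^2))
        rlnorm(1, meanlog = -sdl^2 / 2, sdlog = sdl)
      })
      tr_j <- base
      tr_j$knots$r <- base$knots$r * scale_j
      profiles[[sid]] <- synthesize_profile(tr_j, sid, group_label = g)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid, group_label = g, r_scale = scale_j,
        true_r_max = max(tr_j$knots$r),
        true_sc_thickness = tr_j$sc_thickness,
        tewl = profiles[[sid]]$tewl, stringsAsFactors = FALSE)
      if (!is.null(oil_factor)) {
        tr_a <- tr_j
        fac <- if (is.function(oil_factor))
          vapply(tr_a$knots$x, oil_factor, numeric(1)) else oil_factor
        tr_a$knots$r <- tr_j$knots$r * fac
        sid_a <- paste0(sid, "_after")
        ga <- paste0(g, "_after")
        pa <- synthesize_profile(tr_a, sid, group_label = ga)
        pa$subject_id <- sid_a
        profiles[[sid_a]] <- pa
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid_a, group_label = ga, r_scale = scale_j,
          true_r_max = max(tr_a$knots$r),
          true_sc_thickness = tr_a$sc_thickness,
          tewl = pa$tewl, stringsAsFactors = FALSE)
      }
    }
  }
  list(profiles = profiles, truth_table = do.call(rbind, rows),
       group_truths = lapply(group_specs, `[[`, "truth"))
}
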