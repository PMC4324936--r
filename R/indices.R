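#' Locate the resistance peak
#'
#' Finds the maximum of the interpolated resistance curve over a uniform grid
#' on `[0, 1]` refined to include every anchor node (for linear interpolation
#' the maximum is always at a knot, so this is exact); with monotone-cubic
#' interpolation the bracketing interval around the best grid point is further
#' refined with [stats::optimize()].  Ties are broken towards the surface
#' (smaller x).
#'
#' @param rp An `"sc_resistance"` object.
#' @param grid_size Uniform grid resolution (>= 101).
#' @return List with `r_max` and `x_max`.
#' @export
locate_peak <- function(rp, grid_size = 101) {
  stopifnot(inherits(rp, "sc_resistance"))
  if (grid_size < 101) stop("grid_size must be at least 101")
  f <- .sc_interpolant(rp)
  g <- sort(unique(c(seq(0, 1, length.out = grid_size), 0, 1, rp$node_x)))
  v <- f(g)
  k <- which.max(v)                      # which.max takes the first maximum
  r_max <- v[k]; x_max <- g[k]
  if (identical(rp$interp_scheme, "monotone-cubic")) {
    lo <- g[max(1L, k - 1L)]; hi <- g[min(length(g), k + 1L)]
    if (hi > lo) {
      op <- optimize(f, c(lo, hi), maximum = TRUE,
                     tol = .Machine$double.eps^0.5)
      if (op$objective > r_max + 1e-12) {
        r_max <- op$objective; x_max <- op$maximum
      }
    }
  }
  list(r_max = r_max, x_max = x_max)
}

#' Bounds of the above-threshold (barrier maintenance) region
#'
#' Computes `x_minus = min S` and `x_plus = max S` for
#' `S = { x : R(x) >= threshold_fraction * r_max }`.  For unimodal profiles
#' these are the depths where resistance decays through the threshold towards
#' the surface and rises through it from the bottom; defining them through the
#' super-threshold *set* also covers multi-peaked profiles (e.g. after
#' petrolatum application).  Crossings are solved exactly on linear segments;
#' with monotone-cubic interpolation they are refined by [stats::uniroot()]
#' between grid sign changes.
#'
#' @param rp An `"sc_resistance"` object.
#' @param r_max Peak resistance (from [locate_peak()]).
#' @param threshold_fraction Threshold as a fraction of the peak, in (0, 1).
#' @param grid_size Scan resolution for the cubic scheme.
#' @return List with `x_minus`, `x_plus` and `flags` (character vector, any of
#'   `"no_top_crossing"` when `x_minus = 0`, `"no_bottom_crossing"` when
#'   `x_plus = 1`).
#' @export
threshold_bounds <- function(rp, r_max, threshold_fraction = 0.8,
                             grid_size = 1001) {
  stopifnot(inherits(rp, "sc_resistance"))
  if (!(threshold_fraction > 0 && threshold_fraction < 1))
    stop("threshold_fraction must be in (0, 1)")
  thr <- threshold_fraction * r_max

  if (identical(rp$interp_scheme, "linear")) {
    kn <- .sc_knots(rp)
    x <- kn$x; r <- kn$r
    pts <- numeric(0)
    above <- r >= thr - 1e-12 * max(abs(r_max), 1)
    if (above[1L]) pts <- c(pts, x[1L])
    for (i in seq_len(length(x) - 1L)) {
      r0 <- r[i]; r1 <- r[i + 1L]
      if (above[i + 1L]) pts <- c(pts, x[i + 1L])
      if ((r0 - thr) * (r1 - thr) < 0) {      # strict sign change: crossing
        pts <- c(pts, x[i] + (thr - r0) / (r1 - r0) * (x[i + 1L] - x[i]))
      }
    }
  } else {
    f <- .sc_interpolant(rp)
    g <- sort(unique(c(seq(0, 1, length.out = max(grid_size, 1001)),
                       rp$node_x)))
    v <- f(g) - thr
    pts <- g[v >= -1e-12 * max(abs(r_max), 1)]
    sgn <- sign(v)
    ch <- which(sgn[-1L] * sgn[-length(sgn)] < 0)
    for (i in ch) {
      rt <- uniroot(function(q) f(q) - thr, c(g[i], g[i + 1L]),
                    tol = .Machine$double.eps^0.5)
      pts <- c(pts, rt$root)
    }
  }
  x_minus <- min(pts); x_plus <- max(pts)
  flags <- character(0)
  if (x_minus <= 0) { x_minus <- 0; flags <- c(flags, "no_top_crossing") }
  if (x_plus >= 1) { x_plus <- 1; flags <- c(flags, "no_bottom_crossing") }
  list(x_minus = x_minus, x_plus = x_plus, flags = flags)
}

#' Functional and structural indices of a resistance profile
#'
#' Summarises a resistance profile by the six indices describing barrier
#' formation, maintenance and degradation:
#'
#' * `r_max`, `x_max` — peak resistance and the normalized depth where it is
#'   attained (functional / structural).
#' * `x_minus`, `x_plus` — bounds of the middle region where resistance is
#'   maintained above `threshold * r_max` (default 80% of peak; the threshold
#'   is a convention, configurable).
#' * `pro_r = (threshold*r_max - R(1)) / (1 - x_plus)` — rate at which the
#'   barrier is built up from the SC/SG interface (bottom region).
#' * `deg_r = (threshold*r_max - R(0)) / x_minus` — rate at which it is
#'   degraded towards the surface (top region).
#'
#' When the profile never drops below the threshold at the bottom
#' (`x_plus = 1`) or top (`x_minus = 0`), the corresponding rate is undefined
#' and reported as `NA` with a flag (`"no_bottom_crossing"` /
#' `"no_top_crossing"`), never as an infinity, so cohort statistics can drop
#' such subjects explicitly.
#'
#' @param rp An `"sc_resistance"` object.
#' @param threshold Threshold fraction of the peak, default 0.8.
#' @param grid_size Peak-scan grid resolution (>= 101), default 101.
#' @return An object of class `"sc_indices"`: list with `subject_id`, `r_max`,
#'   `x_max`, `x_minus`, `x_plus`, `pro_r`, `deg_r`, `threshold_fraction`,
#'   `flags`, `r0`, `r1`.
#' @examples
#' tent <- resistance_profile(c(0, 0.5, 1), c(0, 1, 0))
#' sc_indices(tent)  # r_max 1 at 0.5; x-/x+ 0.4/0.6; both rates 2
#' @export
sc_indices <- function(rp, threshold = 0.8, grid_size = 101) {
  stopifnot(inherits(rp, "sc_resistance"))
  pk <- locate_peak(rp, grid_size = grid_size)
  tb <- threshold_bounds(rp, pk$r_max, threshold_fraction = threshold)
  r0 <- predict(rp, 0)
  r1 <- predict(rp, 1)
  pro_r <- if ("no_bottom_crossing" %in% tb$flags) NA_real_
           else (threshold * pk$r_max - r1) / (1 - tb$x_plus)
  deg_r <- if ("no_top_crossing" %in% tb$flags) NA_real_
           else (threshold * pk$r_max - r0) / tb$x_minus
  structure(
    list(subject_id = rp$subject_id,
         r_max = pk$r_max, x_max = pk$x_max,
         x_minus = tb$x_minus, x_plus = tb$x_plus,
         pro_r = pro_r, deg_r = deg_r,
         threshold_fraction = threshold,
         flags = tb$flags, r0 = r0, r1 = r1),
    class = "sc_indices")
}

#' @export
print.sc_indices <- function(x, ...) {
  cat("Resistance profile indices (threshold ",
      format(100 * x$threshold_fraction), "% of peak)\n", sep = "")
  cat(sprintf("  functional: R_max = %.4g   proR = %s   degR = %s\n",
              x$r_max,
              if (is.na(x$pro_r)) "undefined" else format(x$pro_r, digits = 4),
              if (is.na(x$deg_r)) "undefined" else format(x$deg_r, digits = 4)))
  cat(sprintf("  structural: X_max = %.4g   X- = %.4g   X+ = %.4g\n",
              x$x_max, x$x_minus, x$x_plus))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.sc_indices <- function(x, ...) {
  data.frame(subject_id = x$subject_id, r_max = x$r_max, x_max = x$x_max,
             x_minus = x$x_minus, x_plus = x$x_plus, pro_r = x$pro_r,
             deg_r = x$deg_r,
             flags = paste(x$flags, collapse = ";"),
             stringsAsFactors = FALSE)
}
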