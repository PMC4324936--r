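#' Fit a depth-dependent SC resistance profile
#'
#' The central estimator of the package.  Under Fick's first law applied to a
#' stack of uniform compartments, the steady water flux through every
#' compartment equals TEWL, so each compartment's resistance to water
#' diffusion is identified as
#' \deqn{R_i = (W_i - W_{i-1}) / \mathrm{TEWL},}
#' with \eqn{W_{i-1}}, \eqn{W_i} the water concentrations at the compartment's
#' top and bottom boundaries.  Only samples within the stratum corneum (depth
#' \eqn{\le} SC thickness) are used; the deepest retained sample defines
#' \eqn{W_n}, the water concentration at the top of the viable epidermis.
#' Depth is normalized by the retained SC span (0 = surface, 1 = SC/SG
#' interface) and each \eqn{R_i} is anchored at its compartment midpoint; the
#' interpolated curve is extended as a constant beyond the outermost
#' midpoints, so \eqn{R(0)} equals the outermost compartment's resistance and
#' \eqn{R(1)} the innermost's.
#'
#' A telescoping identity holds exactly for every fit:
#' \eqn{\mathrm{TEWL} \cdot \sum_i R_i = W_n - W_0}.
#'
#' A locally decreasing water profile yields a negative compartment
#' resistance; such values are retained (clamping would break the identity
#' above) and flagged with a warning.
#'
#' @param profile A [water_profile()].
#' @param sc_thickness SC thickness in um.  `NULL` (default) estimates it with
#'   [estimate_sc_thickness()].  If the thickness is not a multiple of the
#'   sampling step, the deepest sampled boundary at or below it is used and
#'   normalized depth is rescaled so that boundary maps to 1 (no water values
#'   are extrapolated).
#' @param interp Interpolation scheme for evaluating the profile between
#'   anchors: `"linear"` (default; no overshoot, so no spurious threshold
#'   crossings) or `"monotone-cubic"` (Fritsch–Carlson shape-preserving).
#' @param thickness_args List of extra arguments for
#'   [estimate_sc_thickness()] when `sc_thickness` is `NULL`.
#' @return An object of class `"sc_resistance"` with fields `subject_id`,
#'   `node_x` (normalized midpoint depths), `node_r` (resistances, a.u.),
#'   `sc_thickness` (um, as requested/estimated), `boundary_depth` (um, the
#'   retained SC span actually mapped to x = 1), `tewl`, `w0`, `wn`,
#'   `w_boundaries` (retained water samples), `interp_scheme`,
#'   `thickness_method`, and `group_label`.
#' @seealso [predict.sc_resistance()], [sc_indices()],
#'   [simulate.sc_resistance()], [mean_profile()]
#' @examples
#' wp <- water_profile("s", seq(0, 10, 2), c(30, 40, 50, 60, 70, 80), tewl = 10)
#' fit <- sc_resistance(wp, sc_thickness = 10)
#' coef(fit)           # R_i = 1 a.u. in every compartment
#' predict(fit, 0.5)
#' @export
sc_resistance <- function(profile, sc_thickness = NULL,
                          interp = c("linear", "monotone-cubic"),
                          thickness_args = list()) {
  stopifnot(inherits(profile, "water_profile"))
  interp <- match.arg(interp)
  th_method <- "supplied"
  if (is.null(sc_thickness)) {
    sc_thickness <- do.call(estimate_sc_thickness,
                            c(list(profile = profile), thickness_args))
    th_method <- attr(sc_thickness, "method")
    sc_thickness <- as.numeric(sc_thickness)
  }
  if (!is.finite(sc_thickness) || sc_thickness <= 0)
    stop("sc_thickness must be positive")
  if (sc_thickness > max(profile$depths) + 1e-9)
    stop("sc_thickness (", format(sc_thickness),
         " um) exceeds the deepest measured sample (",
         max(profile$depths), " um)")

  keep <- which(profile$depths <= sc_thickness + 1e-9)
  m <- length(keep)                      # number of retained boundaries
  if (m < 3L)
    stop("fewer than 2 compartments fit within the SC (subject ",
         profile$subject_id, "): need at least 3 samples at or above ",
         format(sc_thickness), " um")
  d <- profile$depths[keep]
  w <- profile$water[keep]
  span <- d[m]                           # deepest retained boundary -> x = 1
  r <- diff(w) / profile$tewl            # R_i, i = 1..m-1
  if (any(r < 0))
    warning(sum(r < 0), " negative compartment resistance(s) for subject ",
            profile$subject_id,
            " (water decreases locally with depth); retained")
  mid_x <- (d[-m] + d[-1L]) / 2 / span

  structure(
    list(subject_id = profile$subject_id,
         node_x = mid_x,
         node_r = r,
         sc_thickness = sc_thickness,
         boundary_depth = span,
         tewl = profile$tewl,
         w0 = w[1L],
         wn = w[m],
         w_boundaries = w,
         interp_scheme = interp,
         thickness_method = th_method,
         group_label = profile$group_label),
    class = "sc_resistance")
}

#' Assemble a resistance profile from known node values
#'
#' Builds an `"sc_resistance"` object directly from resistances anchored at
#' normalized depths, bypassing the water-profile fit.  Used for synthetic
#' truth curves, user-specified profiles fed to the dynamic model, and tests.
#'
#' @param node_x Strictly increasing normalized depths in `[0, 1]`.
#' @param node_r Resistances (a.u.) at those depths, same length (>= 2).
#' @param subject_id,tewl,sc_thickness,interp,group_label Metadata; see
#'   [sc_resistance()].
#' @return An `"sc_resistance"` object (with `w0`/`wn` unset).
#' @export
resistance_profile <- function(node_x, node_r, subject_id = "profile",
                               tewl = NA_real_, sc_thickness = NA_real_,
                               interp = c("linear", "monotone-cubic"),
                               group_label = NULL) {
  interp <- match.arg(interp)
  node_x <- as.numeric(node_x); node_r <- as.numeric(node_r)
  if (length(node_x) != length(node_r) || length(node_x) < 2L)
    stop("node_x and node_r must have equal length >= 2")
  if (any(!is.finite(node_x)) || any(node_x < 0) || any(node_x > 1))
    stop("node_x must lie in [0, 1]")
  if (any(diff(node_x) <= 0)) stop("node_x must be strictly increasing")
  if (any(!is.finite(node_r))) stop("node_r must be finite")
  structure(
    list(subject_id = as.character(subject_id), node_x = node_x,
         node_r = node_r, sc_thickness = sc_thickness,
         boundary_depth = sc_thickness, tewl = tewl,
         w0 = NA_real_, wn = NA_real_, w_boundaries = NULL,
         interp_scheme = interp, thickness_method = "none",
         group_label = if (is.null(group_label)) NA_character_
                       else as.character(group_label)[1L]),
    class = "sc_resistance")
}

# Interpolant over all of [0, 1]: scheme through the anchor nodes, constant
# extension outside the outermost anchors (so R(0) = first node's value and
# R(1) = last node's value, the conventions used by the profile indices).
.sc_interpolant <- function(rp) {
  x <- rp$node_x; r <- rp$node_r
  if (x[1L] > 0) { x <- c(0, x); r <- c(r[1L], r) }
  n <- length(x)
  if (x[n] < 1) { x <- c(x, 1); r <- c(r, r[n]) }
  if (identical(rp$interp_scheme, "monotone-cubic")) {
    # shape-preserving piecewise-cubic Hermite: zero slope at interior
    # extrema, so the curve never overshoots its anchor values
    function(q) pracma::pchip(x, r, q)
  } else {
    function(q) approx(x, r, xout = q, method = "linear", rule = 2)$y
  }
}

# Knot representation of the extended piecewise-linear curve (linear scheme).
.sc_knots <- function(rp) {
  x <- rp$node_x; r <- rp$node_r
  if (x[1L] > 0) { x <- c(0, x); r <- c(r[1L], r) }
  n <- length(x)
  if (x[n] < 1) { x <- c(x, 1); r <- c(r, r[n]) }
  list(x = x, r = r)
}

#' Evaluate a resistance profile at normalized depths
#'
#' Interpolates the anchored compartment resistances with the profile's
#' scheme; outside the outermost anchor midpoints the curve is extended as a
#' constant, so `predict(fit, 0)` is the outermost compartment's resistance
#' and `predict(fit, 1)` the innermost's.
#'
#' @param object An `"sc_resistance"` object.
#' @param x Numeric vector of normalized depths in `[0, 1]` (default: the
#'   anchor nodes).
#' @param ... Unused.
#' @return Numeric vector of resistances (a.u.).
#' @export
predict.sc_resistance <- function(object, x = object$node_x, ...) {
  x <- as.numeric(x)
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop("normalized depth x must lie in [0, 1]")
  .sc_interpolant(object)(x)
}

#' @export
print.sc_resistance <- function(x, ...) {
  cat("SC resistance profile: subject", x$subject_id)
  if (!is.na(x$group_label)) cat(" [", x$group_label, "]", sep = "")
  cat("\n  ", length(x$node_r), " compartments",
      if (is.finite(x$sc_thickness))
        paste0(", SC thickness ", format(x$sc_thickness, digits = 4), " um (",
               x$thickness_method, ")"), "\n", sep = "")
  if (is.finite(x$tewl))
    cat("  TEWL ", format(x$tewl, digits = 4), " g/h/m^2",
        if (is.finite(x$w0))
          paste0("; W0 ", format(x$w0, digits = 4), " -> Wn ",
                 format(x$wn, digits = 4), " mass%"), "\n", sep = "")
  cat("  R range: ", format(min(x$node_r), digits = 4), " to ",
      format(max(x$node_r), digits = 4), " a.u. (", x$interp_scheme,
      " interpolation)\n", sep = "")
  invisible(x)
}

#' Functional and structural indices of a fitted profile
#'
#' `coef()` returns the six profile indices as a named numeric vector (see
#' [sc_indices()]); `summary()` prints them together with the fit metadata.
#'
#' @param object An `"sc_resistance"` object.
#' @param ... Passed to [sc_indices()] (e.g. `threshold`, `grid_size`).
#' @return For `coef`: named numeric vector `r_max`, `x_max`, `x_minus`,
#'   `x_plus`, `pro_r`, `deg_r` (undefined rates are `NA`).
#' @export
coef.sc_resistance <- function(object, ...) {
  ix <- sc_indices(object, ...)
  c(r_max = ix$r_max, x_max = ix$x_max, x_minus = ix$x_minus,
    x_plus = ix$x_plus, pro_r = ix$pro_r, deg_r = ix$deg_r)
}

#' @rdname coef.sc_resistance
#' @export
summary.sc_resistance <- function(object, ...) {
  ix <- sc_indices(object, ...)
  out <- list(fit = object, indices = ix)
  class(out) <- "summary.sc_resistance"
  out
}

#' @export
print.summary.sc_resistance <- function(x, ...) {
  print(x$fit)
  print(x$indices)
  invisible(x)
}

#' @export
as.data.frame.sc_resistance <- function(x, ...) {
  data.frame(subject_id = x$subject_id,
             x_normalized = x$node_x,
             resistance_au = x$node_r,
             sc_thickness_um = x$sc_thickness,
             tewl = x$tewl,
             stringsAsFactors = FALSE)
}

#' Plot a resistance profile
#'
#' Draws the interpolated resistance curve against normalized depth with the
#' compartment anchors, and optionally the 80%-of-peak threshold region.
#'
#' @param x An `"sc_resistance"` object.
#' @param show_indices Draw `R_max`, the threshold level and `X-`/`X+`?
#' @param grid_size Curve evaluation grid.
#' @param ... Passed to `plot()`.
#' @export
plot.sc_resistance <- function(x, show_indices = TRUE, grid_size = 201, ...) {
  g <- seq(0, 1, length.out = grid_size)
  r <- predict(x, g)
  plot(g, r, type = "l", xlab = "normalized depth (0 = surface)",
       ylab = "resistance (a.u.)",
       main = paste("Subject", x$subject_id), ...)
  points(x$node_x, x$node_r, pch = 16, cex = 0.6)
  if (show_indices) {
    ix <- sc_indices(x)
    abline(h = ix$threshold_fraction * ix$r_max, lty = 3)
    abline(v = c(ix$x_minus, ix$x_plus), lty = 2, col = "grey40")
    points(ix$x_max, ix$r_max, pch = 4, col = 2)
  }
  invisible(x)
}
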