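# Shared fixture builders (all fixtures are generated in code).

# Water profile rising linearly w0 -> w_top over [0, rise_to] um, then flat.
linear_plateau_profile <- function(id = "s", w0 = 30, w_top = 70,
                                   rise_to = 14, depth_max = 30, step = 2,
                                   tewl = 10) {
  d <- seq(0, depth_max, by = step)
  w <- ifelse(d <= rise_to, w0 + (w_top - w0) * d / rise_to, w_top)
  water_profile(id, d, w, tewl)
}

# Piecewise-linear resistance fixture anchored at explicit nodes.
tent <- function(peak = 1, x_peak = 0.5, r0 = 0, r1 = 0, id = "tent",
                 interp = "linear") {
  resistance_profile(c(0, x_peak, 1), c(r0, peak, r1), subject_id = id,
                     interp = interp)
}

# Cohort of sc_resistance tents whose r_max are exactly `peaks`.
tent_group <- function(peaks, label) {
  mean_profile(lapply(seq_along(peaks), function(i)
    tent(peak = peaks[i], id = paste0(label, i))), group_label = label)
}

# Full-pipeline fit that falls back to the plateau-fraction thickness
# estimator when the two-segment fit finds no plateau (rare under heavy
# noise).
fit_subject <- function(p) {
  tryCatch(sc_resistance(p), error = function(e)
    sc_resistance(p, thickness_args = list(method = "plateau_fraction")))
}

# One seeded two-group comparison of recovered r_max on synthetic cohorts;
# returns the p-value.  Groups share `truth_a`/`truth_b` (identical for
# type-I calibration, separated for power).
cohort_pvalue <- function(seed, truth_a, truth_b, n = 10) {
  coh <- suppressWarnings(synthesize_cohort(
    list(A = list(truth = truth_a, n = n), B = list(truth = truth_b, n = n)),
    seed = seed))
  fits <- suppressWarnings(lapply(coh$profiles, fit_subject))
  labels <- vapply(fits, function(f) f$group_label, character(1))
  groups <- lapply(split(fits, labels), mean_profile)
  compare_indices(groups, "r_max")$p_value
}

expect_index_equal <- function(ix, expected, tol = 1e-12) {
  got <- c(ix$r_max, ix$x_max, ix$x_minus, ix$x_plus, ix$pro_r, ix$deg_r)
  expect_equal(got, unname(expected), tolerance = tol)
}
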