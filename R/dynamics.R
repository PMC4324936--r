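#' Steady-state interior water concentrations
#'
#' At steady state the water flux through every compartment equals TEWL, so
#' the interior concentrations follow in closed form from the boundary values
#' and the resistances: with flux `J = (wn - w0) / sum(R)`,
#' `W_i = w0 + J * (R_1 + ... + R_i)` for `i = 1 .. n-1`.
#'
#' @param resistances Positive compartment resistances `R_1 .. R_n` (a.u.).
#' @param w0 Surface boundary water concentration (mass%).
#' @param wn Bottom boundary (viable epidermis) water concentration (mass%).
#' @return List with `w` (interior concentrations, length `n - 1`) and `flux`
#'   (the steady flux `J`, mass% per a.u.; equals TEWL when the resistances
#'   were derived from data with these boundaries).
#' @examples
#' steady_state_profile(c(1, 1, 1), 30, 60)  # interior 40, 50; flux 10
#' @export
steady_state_profile <- function(resistances, w0, wn) {
  r <- as.numeric(resistances)
  if (length(r) < 2L) stop("need at least 2 compartments")
  if (any(!is.finite(r)) || any(r <= 0))
    stop("all resistances must be positive and finite")
  s <- sum(r)
  if (s == 0) stop("sum of resistances is zero")
  flux <- (wn - w0) / s
  w <- w0 + flux * cumsum(r)[-length(r)]
  list(w = w, flux = flux)
}

#' Piecewise-constant surface boundary schedule
#'
#' Describes the water concentration applied at the skin surface, `W_0(t)`,
#' as a right-continuous step function: `value[k]` holds on
#' `[times[k], times[k+1])`.
#'
#' @param times Strictly increasing change points (s); `times[1]` must not be
#'   after the start of any simulation using the schedule.
#' @param values Boundary values (mass%), same length.
#' @return A `"w0_schedule"` object (callable breakpoint table).
#' @export
w0_schedule <- function(times, values) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values) || length(times) < 1L)
    stop("times and values must have equal positive length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(values))) stop("values must be finite")
  structure(list(times = times, values = values), class = "w0_schedule")
}

.sc_schedule_at <- function(sched, t) {
  sched$values[pmax(1L, findInterval(t, sched$times))]
}

#' Define a compartment system for dynamic simulation
#'
#' @param resistances Positive resistances `R_1 .. R_n` (a.u.).  Negative or
#'   zero values (possible for resistances derived from noisy, locally
#'   non-monotone water profiles) make the dynamics ill-posed and are rejected
#'   unless `repair = TRUE`, which floors them at
#'   `1e-6 * median(positive R)` with a warning.
#' @param w0 Either a single baseline value (mass%) or a [w0_schedule()].
#' @param wn Fixed bottom boundary (mass%); the viable epidermis acts as an
#'   infinite reservoir.
#' @param initial_w Interior initial concentrations `W_1 .. W_{n-1}`; default
#'   is the steady state for the schedule's initial `W_0`.
#' @param capacity Global compartment capacity constant scaling time (the
#'   dynamic equations carry an implicit unit capacity; expose it only if a
#'   physical time calibration is needed).  Default 1.
#' @param repair Floor non-positive resistances instead of erroring?
#' @return A `"compartment_system"` object.
#' @export
compartment_system <- function(resistances, w0, wn, initial_w = NULL,
                               capacity = 1, repair = FALSE) {
  r <- as.numeric(resistances)
  if (length(r) < 2L) stop("need at least 2 compartments")
  if (any(!is.finite(r))) stop("resistances must be finite")
  if (any(r <= 0)) {
    if (!repair)
      stop(sum(r <= 0), " non-positive resistance(s): dynamics are ill-posed. ",
           "Use repair = TRUE to floor them at a small positive epsilon.")
    eps <- 1e-6 * median(r[r > 0])
    warning(sum(r <= 0), " non-positive resistance(s) floored at ",
            format(eps))
    r[r <= 0] <- eps
  }
  sched <- if (inherits(w0, "w0_schedule")) w0
           else w0_schedule(-Inf, as.numeric(w0)[1L])
  if (!is.numeric(wn) || length(wn) != 1L || !is.finite(wn))
    stop("wn must be a finite scalar")
  if (!is.finite(capacity) || capacity <= 0)
    stop("capacity must be positive")
  n <- length(r)
  if (is.null(initial_w))
    initial_w <- steady_state_profile(r, sched$values[1L], wn)$w
  initial_w <- as.numeric(initial_w)
  if (length(initial_w) != n - 1L)
    stop("initial_w must have length n - 1 = ", n - 1L)
  structure(list(resistances = r, w0 = sched, wn = wn,
                 initial_w = initial_w, capacity = capacity),
            class = "compartment_system")
}

#' Simulate the compartment dynamic model
#'
#' Integrates the water balance of the interior compartments,
#' \deqn{dW_i/dt = (W_{i-1} - W_i)/R_i + (W_{i+1} - W_i)/R_{i+1},
#'   \quad i = 1, \dots, n-1,}
#' with `W_0(t)` given by the system's boundary schedule and `W_n` held fixed,
#' using the adaptive explicit Runge–Kutta pair `ode45` (via \pkg{deSolve}).
#' Integration is restarted exactly at every schedule discontinuity inside
#' the requested window, so square boundary pulses are resolved without
#' smoothing.
#'
#' @param system A [compartment_system()].
#' @param times Increasing output time grid (s).
#' @param rtol,atol Solver tolerances (defaults 1e-6, 1e-9).
#' @return An object of class `"sc_simulation"`: list with `times`, `w`
#'   (matrix, `length(times)` rows by `n - 1` interior compartments), `w0`
#'   (boundary trace), `wn`, `total_content` (row sums of `w`, mass%),
#'   `baseline_total` (sum of the initial interior state), `resistances`.
#' @export
simulate_compartments <- function(system, times, rtol = 1e-6, atol = 1e-9) {
  stopifnot(inherits(system, "compartment_system"))
  times <- as.numeric(times)
  if (length(times) < 2L || any(diff(times) <= 0))
    stop("times must be an increasing grid with at least 2 points")
  r <- system$resistances
  n <- length(r)
  cap <- system$capacity
  wn <- system$wn

  deriv <- function(t, w, parms) {
    wall <- c(parms$w0val, w, wn)
    i <- seq_len(n - 1L)
    dw <- (wall[i] - wall[i + 1L]) / r[i] +
          (wall[i + 2L] - wall[i + 1L]) / r[i + 1L]
    list(dw / cap)
  }

  cuts <- system$w0$times
  cuts <- cuts[cuts > times[1L] & cuts < times[length(times)]]
  edges <- sort(unique(c(times[1L], cuts, times[length(times)])))

  state <- system$initial_w
  out_t <- numeric(0)
  out_w <- NULL
  for (k in seq_len(length(edges) - 1L)) {
    t0 <- edges[k]; t1 <- edges[k + 1L]
    seg_t <- sort(unique(c(t0, times[times > t0 & times < t1], t1)))
    w0val <- .sc_schedule_at(system$w0, (t0 + t1) / 2)
    sol <- deSolve::ode(y = state, times = seg_t, func = deriv,
                        parms = list(w0val = w0val), method = "ode45",
                        rtol = rtol, atol = atol)
    ist <- attr(sol, "istate")
    if (!is.null(ist) && ist[1L] < 0)
      stop("ODE solver failed on segment [", t0, ", ", t1, "]")
    m <- unname(as.matrix(sol[, -1L, drop = FALSE]))
    if (any(!is.finite(m))) stop("non-finite state encountered in simulation")
    keep <- seg_t %in% times & !(seg_t %in% out_t)
    out_t <- c(out_t, seg_t[keep])
    out_w <- rbind(out_w, m[keep, , drop = FALSE])
    state <- m[nrow(m), ]
  }
  ord <- order(out_t)
  out_t <- out_t[ord]; out_w <- out_w[ord, , drop = FALSE]
  structure(
    list(times = out_t, w = out_w,
         w0 = .sc_schedule_at(system$w0, out_t),
         wn = wn,
         total_content = rowSums(out_w),
         baseline_total = sum(system$initial_w),
         resistances = r),
    class = "sc_simulation")
}

#' @export
print.sc_simulation <- function(x, ...) {
  cat("Compartment simulation: ", ncol(x$w), " interior compartments, t = ",
      format(min(x$times)), "-", format(max(x$times)), " s (",
      length(x$times), " points)\n", sep = "")
  cat(sprintf("  total content: baseline %.4g, range %.4g-%.4g mass%%\n",
              x$baseline_total, min(x$total_content), max(x$total_content)))
  invisible(x)
}

#' @export
as.data.frame.sc_simulation <- function(x, ...) {
  data.frame(time_s = rep(x$times, ncol(x$w)),
             compartment_index = rep(seq_len(ncol(x$w)), each = length(x$times)),
             water_masspct = as.vector(x$w),
             stringsAsFactors = FALSE)
}

#' Absorption–desorption protocol
#'
#' Topical water application: the surface boundary `W_0` is raised by `w_exp`
#' during the application window and returns to baseline when the water is
#' wiped off.  Defaults follow the standard in-silico experiment: 50 s
#' horizon, application during t = 10–20 s, `w_exp` = 60 mass% (so a typical
#' baseline `W_0` of 30 mass% reaches about 90 mass% under the water pool).
#'
#' @param t_start,t_end Simulation window (s).
#' @param a_on,a_off Application window (s), `t_start <= a_on < a_off <= t_end`.
#' @param w_exp Boundary increment during application (mass%).
#' @return A `"protocol"` list.
#' @export
absorption_protocol <- function(t_start = 0, t_end = 50, a_on = 10,
                                a_off = 20, w_exp = 60) {
  if (!(t_start <= a_on && a_on < a_off && a_off <= t_end))
    stop("need t_start <= a_on < a_off <= t_end")
  structure(list(t_start = t_start, t_end = t_end, a_on = a_on,
                 a_off = a_off, w_exp = w_exp), class = "protocol")
}

#' Run an in-silico absorption–desorption experiment
#'
#' Initialises the compartment system at the steady state for the baseline
#' boundaries, applies the square boundary pulse of the protocol, and returns
#' the simulation together with the total-water-content change from baseline.
#'
#' @param resistances Positive compartment resistances (a.u.).
#' @param baseline_w0 Baseline surface water concentration (mass%), default 30.
#' @param wn Bottom boundary (mass%).
#' @param protocol An [absorption_protocol()].
#' @param n_times Number of output time points, default 501.
#' @param ... Passed to [simulate_compartments()] (tolerances) and
#'   [compartment_system()] (`capacity`, `repair`).
#' @return An `"sc_simulation"` with an extra element `content_change`
#'   (`total_content - baseline_total`) and the protocol attached.
#' @export
run_absorption_desorption <- function(resistances, baseline_w0 = 30, wn,
                                      protocol = absorption_protocol(),
                                      n_times = 501, rtol = 1e-6, atol = 1e-9,
                                      capacity = 1, repair = FALSE) {
  stopifnot(inherits(protocol, "protocol"))
  sched <- w0_schedule(c(protocol$t_start, protocol$a_on, protocol$a_off),
                       c(baseline_w0, baseline_w0 + protocol$w_exp,
                         baseline_w0))
  sys <- compartment_system(resistances, sched, wn, capacity = capacity,
                            repair = repair)
  times <- seq(protocol$t_start, protocol$t_end, length.out = n_times)
  times <- sort(unique(c(times, protocol$a_on, protocol$a_off)))
  sim <- simulate_compartments(sys, times, rtol = rtol, atol = atol)
  sim$content_change <- sim$total_content - sim$baseline_total
  sim$protocol <- protocol
  sim
}

#' Simulate an absorption–desorption experiment from a fitted profile
#'
#' `simulate()` method for [sc_resistance()] fits: uses the fitted compartment
#' resistances and the profile's own boundary water concentrations to run
#' [run_absorption_desorption()].
#'
#' @param object An `"sc_resistance"` fit (derived from a water profile, so
#'   that `w0`/`wn` are available; supply `baseline_w0`/`wn` otherwise).
#' @param nsim,seed Unused (the model is deterministic); kept for the generic.
#' @param protocol An [absorption_protocol()].
#' @param baseline_w0,wn Boundary overrides (mass%).
#' @param ... Passed to [run_absorption_desorption()].
#' @return An `"sc_simulation"`.
#' @export
simulate.sc_resistance <- function(object, nsim = 1, seed = NULL,
                                   protocol = absorption_protocol(),
                                   baseline_w0 = object$w0, wn = object$wn,
                                   ...) {
  if (!is.finite(baseline_w0) || !is.finite(wn))
    stop("profile has no stored boundaries; supply baseline_w0 and wn")
  run_absorption_desorption(object$node_r, baseline_w0 = baseline_w0,
                            wn = wn, protocol = protocol, ...)
}

#' Total SC water content over time
#'
#' Sums the interior compartment water concentrations at each time point
#' (boundary nodes are reservoirs, not SC water); optionally as the change
#' from the steady-state baseline.
#'
#' @param sim An `"sc_simulation"`.
#' @param as_change Subtract the baseline total?
#' @return Numeric time series aligned with `sim$times`.
#' @export
total_water_content <- function(sim, as_change = FALSE) {
  stopifnot(inherits(sim, "sc_simulation"))
  tc <- sim$total_content
  if (as_change) tc - sim$baseline_total else tc
}

#' Fit the conductance unit-conversion scaling
#'
#' Simulated total water content is in mass% while experimental total content
#' (skin conductance) is in instrument units; the two are aligned by a single
#' multiplicative scaling `k` minimising the sum of squared errors
#' `sum((k * simulated - measured)^2)`, which has the closed-form solution
#' `k = sum(s * m) / sum(s^2)` (the least-squares normal equation, so no
#' iterative minimiser or starting value is involved).
#'
#' @param simulated,measured Equal-length numeric series at aligned time
#'   points; `simulated` must not be identically zero.
#' @return A `"scaling_fit"` list with `k` and `sse`.
#' @export
fit_content_scaling <- function(simulated, measured) {
  s <- as.numeric(simulated); m <- as.numeric(measured)
  if (length(s) != length(m) || length(s) == 0L)
    stop("simulated and measured must be equal-length non-empty series")
  if (any(!is.finite(s)) || any(!is.finite(m)))
    stop("series must be finite")
  ss <- sum(s^2)
  if (ss == 0) stop("simulated series is identically zero; scaling undefined")
  k <- sum(s * m) / ss
  structure(list(k = k, sse = sum((k * s - m)^2)), class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("Conductance scaling fit: k = %.6g (SSE = %.6g)\n", x$k, x$sse))
  invisible(x)
}
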