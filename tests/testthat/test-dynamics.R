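test_that("steady states follow the closed-form flux relation", {
  s1 <- steady_state_profile(c(1, 1, 1), 30, 60)
  expect_equal(s1$w, c(40, 50))
  expect_equal(s1$flux, 10)

  s2 <- steady_state_profile(c(1, 3, 1), 30, 55)
  expect_equal(s2$w, c(35, 50))
  expect_equal(s2$flux, 5)

  # oracle: solve the tridiagonal balance equations directly
  set.seed(61)
  r <- runif(20, 0.2, 2)
  n <- length(r); w0 <- 28; wn <- 71
  A <- matrix(0, n - 1, n - 1)
  for (i in 1:(n - 1)) {
    A[i, i] <- -(1 / r[i] + 1 / r[i + 1])
    if (i > 1) A[i, i - 1] <- 1 / r[i]
    if (i < n - 1) A[i, i + 1] <- 1 / r[i + 1]
  }
  b <- c(w0 / r[1], rep(0, n - 3), wn / r[n])
  expect_equal(steady_state_profile(r, w0, wn)$w, solve(A, -b),
               tolerance = 1e-12)

  expect_error(steady_state_profile(c(1, -1, 1), 30, 60), "positive")
  expect_error(steady_state_profile(1, 30, 60), "at least 2")
})

test_that("a steady-state initial condition is a fixed point of the dynamics", {
  r <- c(0.5, 1, 2, 1, 0.5)
  sys <- compartment_system(r, 30, 70)
  sim <- simulate_compartments(sys, seq(0, 40, 2))
  drift <- apply(sim$w, 2, function(col) max(abs(col - col[1])))
  expect_lt(max(drift), 1e-6)

  # uniform equilibrium: W0 = Wn = all interior values, zero flux
  syse <- compartment_system(r, 50, 50, initial_w = rep(50, 4))
  sime <- simulate_compartments(syse, seq(0, 40, 2))
  expect_equal(max(abs(sime$w - 50)), 0, tolerance = 1e-9)
})

test_that("the integrator matches the matrix-exponential solution", {
  n <- 10; r <- rep(1, n); w0 <- 30; wn <- 70
  sys <- compartment_system(r, w0, wn, initial_w = rep(30, n - 1))
  tt <- seq(0, 50, by = 1)
  sim <- simulate_compartments(sys, tt)
  A <- matrix(0, n - 1, n - 1)
  for (i in 1:(n - 1)) {
    A[i, i] <- -2
    if (i > 1) A[i, i - 1] <- 1
    if (i < n - 1) A[i, i + 1] <- 1
  }
  b <- c(w0, rep(0, n - 3), wn)
  winf <- solve(A, -b)
  err <- max(vapply(seq_along(tt), function(k) {
    wex <- winf + as.vector(Matrix::expm(A * tt[k]) %*% (rep(30, n - 1) - winf))
    max(abs(sim$w[k, ] - wex))
  }, numeric(1)))
  expect_lt(err, 1e-5)
})

test_that("with constant boundaries the dynamics converge to the steady state", {
  set.seed(62)
  r <- runif(8, 0.3, 1)
  ss <- steady_state_profile(r, 30, 70)$w
  sys <- compartment_system(r, 30, 70, initial_w = rep(30, 7))
  t_end <- 50 * max(r) * length(r)
  sim <- simulate_compartments(sys, c(0, t_end), rtol = 1e-8, atol = 1e-11)
  expect_lt(max(abs(sim$w[2, ] - ss)), 1e-6)
})

test_that("resistances derived from a profile reproduce it at stationarity", {
  tr <- synthetic_truth(noise_sd = 0, seed = 3)
  p <- synthesize_profile(tr, "rt")
  fit <- sc_resistance(p, sc_thickness = tr$sc_thickness)
  sys <- compartment_system(fit$node_r, fit$w0, fit$wn,
                            initial_w = rep(mean(c(fit$w0, fit$wn)),
                                            length(fit$node_r) - 1))
  t_end <- 50 * max(fit$node_r) * length(fit$node_r)
  sim <- simulate_compartments(sys, c(0, t_end))
  interior <- fit$w_boundaries[-c(1, length(fit$w_boundaries))]
  expect_lt(max(abs(sim$w[2, ] - interior) / abs(interior)), 1e-6)
})

test_that("the absorption-desorption protocol drives the boundary as stated", {
  r <- rep(0.4, 10)
  sim <- run_absorption_desorption(r, baseline_w0 = 30, wn = 70)
  inwin <- sim$times >= 10 & sim$times < 20
  expect_true(all(sim$w0[inwin] == 90))        # 30 + 60 during application
  expect_true(all(sim$w0[sim$times < 10] == 30))
  cc <- sim$content_change
  expect_equal(max(abs(cc[sim$times < 10])), 0, tolerance = 1e-7)
  expect_true(all(cc[sim$times > 10.5] > 0))
  peak <- max(cc)
  expect_lt(cc[length(cc)], 0.05 * peak)       # decays back toward baseline

  # no applied water, no response
  sim0 <- run_absorption_desorption(r, baseline_w0 = 30, wn = 70,
    protocol = absorption_protocol(w_exp = 0))
  expect_equal(max(abs(sim0$content_change)), 0, tolerance = 1e-7)
})

test_that("doubling all resistances lowers the peak and slows the decay", {
  base <- run_absorption_desorption(rep(0.4, 10), baseline_w0 = 30, wn = 70)
  dbl <- run_absorption_desorption(rep(0.8, 10), baseline_w0 = 30, wn = 70)
  expect_lt(max(dbl$content_change), max(base$content_change))
  d <- dbl$content_change - base$content_change
  inwin <- base$times > 10 & base$times <= 20
  expect_true(all(d[inwin] <= 1e-9))           # slower absorption
  expect_true(all(d[base$times >= 30] > 0))    # slower desorption (late)
  # relative to its own peak, the doubled system retains more content
  nb <- base$content_change / max(base$content_change)
  nd <- dbl$content_change / max(dbl$content_change)
  post <- base$times >= 20.5
  expect_true(all((nd - nb)[post] > -1e-9))
})

test_that("total water content sums interior compartments", {
  sys <- compartment_system(c(1, 1, 1), 30, 60)   # interior 40, 50
  sim <- simulate_compartments(sys, c(0, 5, 10))
  expect_equal(total_water_content(sim), rep(90, 3), tolerance = 1e-6)
  expect_equal(total_water_content(sim, as_change = TRUE), rep(0, 3),
               tolerance = 1e-6)
})

test_that("boundary pulses superpose (linearity in the boundary forcing)", {
  r <- rep(0.4, 10)
  tt <- seq(0, 50, 0.5)
  mk <- function(br, v) compartment_system(r, w0_schedule(br, v), 70)
  s0 <- simulate_compartments(mk(0, 30), tt)
  s1 <- simulate_compartments(mk(c(0, 10, 20), c(30, 90, 30)), tt)
  s2 <- simulate_compartments(mk(c(0, 25, 35), c(30, 60, 30)), tt)
  s12 <- simulate_compartments(mk(c(0, 10, 20, 25, 35),
                                  c(30, 90, 30, 60, 30)), tt)
  err <- max(abs((s12$w - s0$w) - ((s1$w - s0$w) + (s2$w - s0$w))))
  expect_lt(err, 1e-4)
})

test_that("non-positive resistances block simulation unless repaired", {
  expect_error(compartment_system(c(1, -0.2, 1), 30, 60), "ill-posed")
  expect_warning(sys <- compartment_system(c(1, -0.2, 1), 30, 60,
                                           repair = TRUE), "floored")
  expect_true(all(sys$resistances > 0))
})

test_that("simulate() on a fitted profile runs the standard protocol", {
  tr <- synthetic_truth(noise_sd = 0, seed = 7)
  fit <- sc_resistance(synthesize_profile(tr, "s"), sc_thickness = 20)
  sim <- simulate(fit)
  expect_s3_class(sim, "sc_simulation")
  expect_equal(range(sim$times), c(0, 50))
  expect_true(max(sim$content_change) > 0)
  bare <- resistance_profile(c(0.25, 0.75), c(1, 1))
  expect_error(simulate(bare), "boundaries")
})

test_that("the conductance scaling fit solves the normal equation", {
  s <- c(0, 1, 3, 2, 1, 0.5)
  expect_equal(fit_content_scaling(s, 2 * s)$k, 2)
  expect_equal(fit_content_scaling(s, 2 * s)$sse, 0)
  expect_equal(fit_content_scaling(s, s)$k, 1)

  set.seed(63)
  sim <- rnorm(40)^2
  meas <- 3.3 * sim + rnorm(40, sd = 0.2)
  f <- fit_content_scaling(sim, meas)
  num <- optimize(function(k) sum((k * sim - meas)^2), c(-100, 100),
                  tol = 1e-12)$minimum
  expect_equal(f$k, num, tolerance = 1e-8)
  expect_equal(f$k, sum(sim * meas) / sum(sim^2), tolerance = 1e-14)

  expect_error(fit_content_scaling(rep(0, 5), rnorm(5)), "identically zero")
  expect_error(fit_content_scaling(1:3, 1:4), "equal-length")
})

test_that("schedules and protocols validate their structure", {
  expect_error(w0_schedule(c(0, 0), c(1, 2)), "strictly increasing")
  expect_error(absorption_protocol(a_on = 20, a_off = 10), "t_start")
  sch <- w0_schedule(c(0, 10, 20), c(30, 90, 30))
  expect_equal(scresist:::.sc_schedule_at(sch, c(-1, 5, 10, 15, 20, 30)),
               c(30, 30, 90, 90, 30, 30))
})
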