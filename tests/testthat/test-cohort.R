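test_that("mean profiles average pointwise on the common grid", {
  p1 <- tent(peak = 2, x_peak = 0.4, r0 = 0.1, r1 = 0.2, id = "a")
  g1 <- mean_profile(list(p1), group_label = "solo")
  expect_equal(g1$mean_r, predict(p1, g1$grid_x))

  c1 <- resistance_profile(c(0, 1), c(1, 1), subject_id = "c1")
  c3 <- resistance_profile(c(0, 1), c(3, 3), subject_id = "c3")
  g <- mean_profile(list(c1, c3), group_label = "const")
  expect_equal(g$mean_r, rep(2, 101))

  # brute-force oracle: per-point average over 10 random tents
  set.seed(41)
  ps <- lapply(1:10, function(i)
    tent(peak = runif(1, 1, 4), x_peak = runif(1, 0.2, 0.8),
         r0 = runif(1, 0, 0.5), r1 = runif(1, 0, 0.5), id = paste0("t", i)))
  gm <- mean_profile(ps, group_label = "rand")
  brute <- sapply(gm$grid_x, function(x)
    mean(vapply(ps, function(p) predict(p, x), numeric(1))))
  expect_equal(gm$mean_r, brute, tolerance = 1e-12)

  # commutes with uniform scaling
  ps_c <- lapply(ps, function(p) resistance_profile(p$node_x, 2.5 * p$node_r))
  expect_equal(mean_profile(ps_c)$mean_r, 2.5 * gm$mean_r, tolerance = 1e-12)

  expect_error(mean_profile(list()), "non-empty")
})

test_that("index summaries carry per-subject variance and usable counts", {
  g <- tent_group(c(1, 2, 3), "g")
  expect_equal(unname(g$index_means["r_max"]), 2)
  expect_equal(unname(g$index_sds["r_max"]), 1)
  expect_equal(unname(g$index_n["r_max"]), 3)
  # constant member: its rates are flagged-undefined and dropped from means
  mixed <- mean_profile(list(tent(peak = 2, id = "t"),
                             resistance_profile(c(0, 1), c(2, 2), "c"),
                             tent(peak = 3, id = "t2")))
  expect_equal(unname(mixed$index_n["pro_r"]), 2)
  expect_false(any(is.na(mixed$index_means)))
})

test_that("two-group comparisons reproduce the pooled Student t", {
  gA <- tent_group(c(1, 2, 3), "A")
  gB <- tent_group(c(1, 2, 3), "B")
  same <- compare_indices(list(gA, gB), "r_max")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_identical(same$stars, "")

  gC <- tent_group(c(2, 3, 4), "C")
  cmp <- compare_indices(list(gA, gC), "r_max")
  # textbook pooled-variance formula
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  sp <- sqrt(((2 * var(a)) + (2 * var(b))) / 4)
  t_hand <- (mean(a) - mean(b)) / (sp * sqrt(1 / 3 + 1 / 3))
  expect_equal(cmp$statistic, t_hand, tolerance = 1e-12)
  expect_equal(cmp$statistic, -1.224744871, tolerance = 1e-8)
  expect_equal(cmp$df, 4)
  expect_identical(cmp$test, "t")

  # two groups through the ANOVA path: F = t^2, same p
  f2 <- compare_indices(list(gA, gC), "r_max", method = "anova")
  expect_equal(f2$statistic, cmp$statistic^2, tolerance = 1e-12)
  expect_equal(f2$p_value, cmp$p_value, tolerance = 1e-12)

  # three groups dispatch to one-way ANOVA
  three <- compare_indices(list(gA, gC, tent_group(c(4, 5, 7), "D")), "r_max")
  expect_identical(three$test, "anova")
  expect_true(three$p_value >= 0 && three$p_value <= 1)

  expect_error(
    compare_indices(list(gA, mean_profile(list(tent(peak = 9, id = "x")),
                                          group_label = "tiny")), "r_max"),
    "tiny")
  # a group of constant profiles has no usable rate values
  consts <- mean_profile(lapply(1:3, function(i)
    resistance_profile(c(0, 1), c(i, i), paste0("c", i))),
    group_label = "flat")
  expect_error(compare_indices(list(gA, consts), "pro_r"), "flat")
})

test_that("stars follow the 0.05 / 0.01 / 0.001 convention", {
  gA <- tent_group(c(1, 1.1, 0.9, 1.05), "A")
  gBig <- tent_group(c(5, 5.1, 4.9, 5.05), "B")
  cmp <- compare_indices(list(gA, gBig), "r_max")
  expect_lt(cmp$p_value, 0.001)
  expect_identical(cmp$stars, "***")
})

test_that("pooled-t p-values agree with a permutation oracle", {
  set.seed(51)
  a <- rnorm(10, 1.5, 0.5); b <- rnorm(10, 2.0, 0.5)
  gA <- tent_group(a, "A"); gB <- tent_group(b, "B")
  p_t <- compare_indices(list(gA, gB), "r_max")$p_value
  obs <- abs(mean(a) - mean(b))
  pool <- c(a, b)
  perm <- replicate(10000, {
    i <- sample(20, 10)
    abs(mean(pool[i]) - mean(pool[-i]))
  })
  expect_lt(abs(p_t - mean(perm >= obs)), 0.03)
})

test_that("treatment effects quantify relative resistance change by depth", {
  before <- mean_profile(lapply(1:4, function(i)
    tent(peak = 1 + i / 4, r0 = 0.2, r1 = 0.3, id = paste0("b", i))),
    group_label = "before")
  doubled <- mean_profile(lapply(1:4, function(i)
    tent(peak = 2 * (1 + i / 4), r0 = 0.4, r1 = 0.6, id = paste0("a", i))),
    group_label = "after")
  eff <- treatment_effect(before, doubled)
  expect_equal(eff$rel_change_pct, rep(100, 101), tolerance = 1e-9)
  expect_equal(eff$max_change_pct, 100, tolerance = 1e-9)

  same <- treatment_effect(before, before)
  expect_equal(same$rel_change_pct, rep(0, 101))

  up20 <- mean_profile(lapply(1:4, function(i)
    tent(peak = 1.2 * (1 + i / 4), r0 = 0.24, r1 = 0.36, id = paste0("u", i))),
    group_label = "up20")
  eff20 <- treatment_effect(before, up20)
  expect_equal(eff20$max_change_pct, 20, tolerance = 1e-9)
  expect_equal(eff20$mean_change_pct, 20, tolerance = 1e-9)

  # zero-baseline grid points are excluded with a warning
  zb <- mean_profile(list(tent(peak = 1, r0 = 0, r1 = 0.1, id = "z")))
  za <- mean_profile(list(tent(peak = 1.2, r0 = 0, r1 = 0.12, id = "z2")))
  expect_warning(ez <- treatment_effect(zb, za), "non-positive")
  expect_true(is.na(ez$rel_change_pct[1]))
  expect_equal(ez$n_undefined, 1)
  expect_equal(ez$max_change_pct, 20, tolerance = 1e-9)

  off <- mean_profile(list(tent(peak = 1, id = "o")), grid_size = 151)
  expect_error(treatment_effect(before, off), "grid")
})
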