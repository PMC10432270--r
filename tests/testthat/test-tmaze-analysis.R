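test_that("preference index follows its definition and bounds", {
  expect_equal(preference_index(50, 100), 0)
  expect_equal(preference_index(100, 100), 1)
  expect_equal(preference_index(0, 100), -1)
  expect_equal(preference_index(58, 100), 0.16)
  expect_error(preference_index(5, 0), "n_total")
  expect_error(preference_index(101, 100), "n_magnetic")
  # complement antisymmetry
  m <- c(3, 41, 77, 100, 0)
  expect_equal(preference_index(100 - m, 100), -preference_index(m, 100))
})

test_that("the group GLM flags a strong group difference", {
  a <- simulate_tmaze_experiment(50, 100, 0.3, 0, group = "A", seed = 31)
  b <- simulate_tmaze_experiment(50, 100, 0.7, 0, group = "B", seed = 32)
  sets <- rbind(as.data.frame(a), as.data.frame(b))
  for (disp in c("quasi", "binomial")) {
    r <- glm_group_test(sets, disp)
    expect_lt(r$terms$p_value, 1e-3)
  }
  est <- glm_group_test(sets)$group_estimates
  expect_equal(est$group, c("A", "B"))
  expect_lt(abs(est$p_magnetic[1] - 0.3), 0.03)
  expect_lt(abs(est$p_magnetic[2] - 0.7), 0.03)
})

test_that("identical counts set-for-set give a zero group effect", {
  a <- simulate_tmaze_experiment(10, 100, 0.5, 0.05, group = "A", seed = 33)
  b <- as.data.frame(a)
  b$group <- "B"
  sets <- rbind(as.data.frame(a), b)
  expect_lt(abs(glm_group_test(sets)$terms$value), 1e-10)
  expect_lt(abs(glm_group_test(sets)$estimate), 1e-8)
  expect_equal(pseudoreplicated_test(sets)$estimate, 0)
})

test_that("beta-binomial dispersion fits overdispersed choice data", {
  a <- simulate_tmaze_experiment(40, 100, 0.45, 0.08, group = "A",
                                 seed = 34)
  b <- simulate_tmaze_experiment(40, 100, 0.55, 0.08, group = "B",
                                 seed = 35)
  sets <- rbind(as.data.frame(a), as.data.frame(b))
  r <- glm_group_test(sets, "beta_binomial")
  expect_true(is.finite(r$terms$p_value))
  expect_true(r$terms$p_value >= 0 && r$terms$p_value <= 1)
  # overdispersion must widen the quasi test relative to plain binomial
  p_quasi <- glm_group_test(sets, "quasi")$terms$p_value
  p_binom <- glm_group_test(sets, "binomial")$terms$p_value
  expect_gt(p_quasi, p_binom)
})

test_that("the pseudoreplicated test works even with one set per group", {
  sets <- data.frame(group = c("A", "B"), n_magnetic = c(45, 58),
                     n_total = 100)
  r <- pseudoreplicated_test(sets, "per_fly_t")
  expect_true(is.finite(r$terms$p_value))
  expect_match(r$method, "comparison only")
  r2 <- pseudoreplicated_test(sets, "pooled")
  expect_true(is.finite(r2$terms$p_value))
})

test_that("Cohen's h has its closed-form properties", {
  expect_equal(cohens_h(0.3, 0.3), 0)
  expect_equal(cohens_h(0, 1), pi)
  expect_equal(cohens_h(0.445, 0.585), 0.2810527, tolerance = 1e-6)
  # antisymmetry and monotonicity in p2
  expect_equal(cohens_h(0.2, 0.7), -cohens_h(0.7, 0.2))
  p2 <- seq(0.05, 0.95, by = 0.05)
  hs <- vapply(p2, function(p) cohens_h(0.3, p), numeric(1))
  expect_true(all(diff(hs) > 0))
  expect_error(cohens_h(-0.1, 0.5), "probability")
})

test_that("analytic power has its exact limits and monotonicities", {
  # null effect: power equals alpha exactly
  expect_equal(power_two_proportions(h = 0, n1 = 10, n2 = 12,
                                     alpha = 0.05), 0.05)
  expect_equal(power_two_proportions(h = 0, n1 = 50, n2 = 50,
                                     alpha = 0.11), 0.11)
  # consistency: power -> 1 as n grows
  expect_gt(power_two_proportions(h = 0.28, n1 = 5000, n2 = 5000), 0.9999)
  # monotone in n, |h| and alpha
  ns <- c(5, 10, 20, 40, 80)
  pw_n <- vapply(ns, function(n)
    power_two_proportions(h = 0.3, n1 = n, n2 = n), numeric(1))
  expect_true(all(diff(pw_n) > 0))
  hs <- seq(0.1, 1, by = 0.1)
  pw_h <- vapply(hs, function(h)
    power_two_proportions(h = h, n1 = 15, n2 = 15), numeric(1))
  expect_true(all(diff(pw_h) > 0))
  expect_gt(power_two_proportions(0.4, 0.6, 20, 20, alpha = 0.1),
            power_two_proportions(0.4, 0.6, 20, 20, alpha = 0.01))
})

test_that("sample size inversion brackets the target power", {
  h <- cohens_h(0.445, 0.585)
  n <- sample_size_for_power(h, 0.8, 0.05)
  expect_gte(power_two_proportions(h = h, n1 = n, n2 = n), 0.8)
  expect_lt(power_two_proportions(h = h, n1 = n - 1, n2 = n - 1), 0.8)
  # doubling the effect size shrinks n roughly fourfold
  n2 <- sample_size_for_power(2 * h, 0.8, 0.05)
  expect_lt(abs(n / n2 - 4), 0.8)
  expect_error(sample_size_for_power(0, 0.8), "non-zero")
})

test_that("the type-I study is deterministic and shows the inflation", {
  st1 <- type1_error_study(c(0, 0.05), n_sets = 10, flies_per_set = 50,
                           n_reps = 100, seed = 40)
  st2 <- type1_error_study(c(0, 0.05), n_sets = 10, flies_per_set = 50,
                           n_reps = 100, seed = 40)
  expect_identical(st1, st2)
  wide <- function(st, icc, test)
    st$rejection_rate[st$icc == icc & st$test == test]
  expect_gt(wide(st1, 0.05, "per_fly"), wide(st1, 0.05, "per_set_glm"))
})
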