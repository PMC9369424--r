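test_that("k factor matches a direct transcription and its lower bound", {
  s <- mech_surface() # B: (85, 14, 2.6), A: (79, 20, 1.5)
  k_oracle <- (85 / 79) * (1 + (20 / 7)^1.5) - 1
  expect_equal(k_factor(s, 7), k_oracle, tolerance = 1e-12)
  # for any a, k > E_B/E_A - 1 > 0 when E_B > E_A
  a <- c(0.01, 1, 7, 50, 1e4, 1e8)
  expect_true(all(k_factor(s, a) > 85 / 79 - 1))
  expect_identical(k_factor(s, 0), Inf)
})

test_that("B-equivalent dose satisfies the dose-equivalence identity", {
  for (s in list(mech_surface(), acet_surface())) {
    a <- c(0.5, 2, 7, 11, 20, 60, 150)
    beq <- b_equivalent(s, a)
    eff_b <- hill_effect(beq, s$params_b$emax, s$params_b$ed50, s$params_b$hill)
    eff_a <- hill_effect(a, s$params_a$emax, s$params_a$ed50, s$params_a$hill)
    expect_equal(eff_b, eff_a, tolerance = 1e-9)
  }
  expect_equal(b_equivalent(mech_surface(), 0), 0)
  # symmetric case: equal maxima and slopes map half-max to half-max
  s_sym <- additive_surface(hill_params(80, 10, 2), hill_params(80, 25, 2))
  expect_equal(b_equivalent(s_sym, s_sym$params_a$ed50), s_sym$params_b$ed50,
               tolerance = 1e-9)
})

test_that("B-equivalent agrees with a root-finder oracle on the acetone surface", {
  s <- acet_surface()
  target <- hill_effect(10, s$params_a$emax, s$params_a$ed50, s$params_a$hill)
  oracle <- uniroot(
    function(b) hill_effect(b, s$params_b$emax, s$params_b$ed50,
                            s$params_b$hill) - target,
    c(1e-8, 1e6), tol = 1e-12
  )$root
  expect_equal(b_equivalent(s, 10), oracle, tolerance = 1e-8)
})

test_that("the additive surface reduces to the single-drug curves on the axes", {
  for (s in list(mech_surface(), acet_surface())) {
    pb <- s$params_b; pa <- s$params_a
    expect_equal(additive_effect(s, 0, pb$ed50), pb$emax / 2, tolerance = 1e-12)
    b <- c(0.1, 1, 14, 100)
    expect_equal(additive_effect(s, 0, b),
                 hill_effect(b, pb$emax, pb$ed50, pb$hill), tolerance = 1e-9)
    a <- c(0.1, 1, 20, 100)
    expect_equal(additive_effect(s, a, 0),
                 hill_effect(a, pa$emax, pa$ed50, pa$hill), tolerance = 1e-9)
    expect_equal(additive_effect(s, 0, 0), 0)
  }
})

test_that("additive effect matches an independent transcription at an interior point", {
  # direct evaluation with E_B=85, C_B=14, p=2.6, E_A=79, C_A=20, q=1.5, a=b=7
  k <- (85 / 79) * (1 + 20^1.5 / 7^1.5) - 1
  beq <- 14 / k^(1 / 2.6)
  oracle <- 85 * (7 + beq)^2.6 / (14^2.6 + (7 + beq)^2.6)
  expect_equal(additive_effect(mech_surface(), 7, 7), oracle, tolerance = 1e-12)
})

test_that("additive effect is non-decreasing in both doses with supremum E_B", {
  s <- mech_surface()
  grid <- seq(0, 200, by = 2.5)
  expect_true(all(diff(additive_effect(s, grid, 5)) >= 0))
  expect_true(all(diff(additive_effect(s, 5, grid)) >= 0))
  ray <- additive_effect(s, grid / 2, grid / 2)
  expect_true(all(diff(ray) >= 0))
  expect_lt(max(ray), s$params_b$emax)
  expect_equal(additive_effect(s, 5e5, 5e5), s$params_b$emax, tolerance = 1e-3)
})

test_that("sham combination: a drug combined with itself reproduces its own curve", {
  p <- hill_params(85, 14, 2.6)
  for (frac in list(c(0.5, 0.5), c(0.25, 0.75), c(0.9, 0.1))) {
    s <- additive_surface(p, hill_params(85, 14, 2.6), frac = frac)
    D <- c(0.5, 2, 7, 14, 50, 178)
    expect_equal(additive_effect(s, frac[1] * D, frac[2] * D),
                 hill_effect(D, 85, 14, 2.6), tolerance = 1e-9)
    expect_equal(predicted_ed50(s, se = FALSE)$ed50, 14, tolerance = 1e-8)
  }
})

test_that("predicted ED50 reproduces the published values and is label-invariant", {
  p_mech <- predicted_ed50(mech_surface(), se = FALSE)
  expect_equal(p_mech$ed50, 14, tolerance = 1.6 / 14) # within printed se
  expect_equal(p_mech$effect_level, 42.5)
  p_acet <- predicted_ed50(acet_surface(), se = FALSE)
  expect_equal(p_acet$ed50, 20, tolerance = 2.1 / 20)
  # swapping the input order must not change the result (roles re-assigned)
  swapped <- additive_surface(mech_thc(), mech_cbd())
  expect_equal(predicted_ed50(swapped, se = FALSE)$ed50, p_mech$ed50,
               tolerance = 1e-10)
  expect_identical(swapped$params_b$drug, "THC")
})

test_that("unreachable effect levels on the ray are reported", {
  s <- mech_surface()
  expect_error(predicted_ed50(s, level = 90), "unreachable")
  expect_error(nonlinear_isobole(s, 85, 0:10), "unreachable")
})

test_that("the reciprocal (as-printed) k orientation breaks dose equivalence", {
  s <- additive_surface(mech_cbd(), mech_thc(), k_form = "reciprocal")
  a <- 7
  beq <- b_equivalent(s, a)
  eff_b <- hill_effect(beq, 85, 14, 2.6)
  eff_a <- hill_effect(a, 79, 20, 1.5)
  expect_gt(abs(eff_b - eff_a), 1) # the identity fails by whole %MPE points
})

test_that("delta-method SE is zero without parameter uncertainty and step-robust", {
  s0 <- additive_surface(hill_params(79, 20, 1.5), hill_params(85, 14, 2.6))
  expect_equal(predicted_ed50(s0)$se, 0)
  s <- mech_surface()
  se1 <- predicted_ed50(s, se_step = 1e-5)$se
  se2 <- predicted_ed50(s, se_step = 1e-6)$se
  expect_gt(se1, 0)
  expect_equal(se1, se2, tolerance = 1e-4)
})

test_that("delta-method SE matches Monte-Carlo propagation of the fixed-role estimator", {
  set.seed(404)
  for (s in list(mech_surface(), acet_surface())) {
    pe <- predicted_ed50(s)
    th <- c(s$params_a$emax, s$params_a$ed50, s$params_a$hill,
            s$params_b$emax, s$params_b$ed50, s$params_b$hill)
    se <- c(s$params_a$se, s$params_b$se)
    draws <- matrix(stats::rnorm(6 * 1e4, th, se), ncol = 6, byrow = TRUE)
    vals <- apply(draws, 1, function(x) {
      s2 <- s
      s2$params_a$emax <- x[1]; s2$params_a$ed50 <- x[2]; s2$params_a$hill <- x[3]
      s2$params_b$emax <- x[4]; s2$params_b$ed50 <- x[5]; s2$params_b$hill <- x[6]
      tryCatch(predicted_ed50(s2, se = FALSE)$ed50, error = function(e) NA_real_)
    })
    expect_lt(mean(is.na(vals)), 0.001)
    expect_equal(pe$se, sd(vals, na.rm = TRUE), tolerance = 0.10)
  }
})

test_that("non-PSD covariance from upstream is caught", {
  bad <- mech_cbd()
  bad$cov[1, 2] <- bad$cov[2, 1] <- 10 # off-diagonal larger than the variances
  s <- mech_surface()
  s$params_a <- bad
  expect_error(predicted_ed50(s), "positive-semi-definite|fit failure")
})

test_that("ray curve and tidy output expose the predicted-additive results", {
  s <- mech_surface()
  rc <- ray_curve(s, c(1, 10, 13.5183, 100))
  expect_named(rc, c("total_dose", "predicted_effect"))
  expect_equal(rc$predicted_effect[3], 42.5, tolerance = 1e-3)
  td <- tidy(predicted_ed50(s))
  expect_equal(td$term, "predicted_ed50")
  expect_equal(td$df, 90)
  expect_s3_class(autoplot(s), "ggplot")
})
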