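test_that("ANOVA fit matches the hand-worked two-by-two example", {
  tr <- make_trial(group = c(0, 0, 1, 1), baseline = rep(0, 4),
                   outcome = c(0, 1, 1, 2))
  f <- fit_anova(tr)
  expect_equal(f$beta, 1)
  expect_equal(f$se, sqrt(0.5), tolerance = 1e-10)
  expect_identical(f$df, 2L)
  # closed form for df = 2: P(T > t) = (1 - t/sqrt(t^2+2)) / 2
  t0 <- 1 / sqrt(0.5)
  expect_equal(f$p_value, 2 * (1 - t0 / sqrt(t0^2 + 2)) / 2,
               tolerance = 1e-10)
  expect_equal(f$p_value, 0.29289, tolerance = 1e-4)
})

test_that("identical arms give a zero ANOVA effect and equal change a zero CSA effect", {
  tr <- make_trial(group = c(0, 0, 1, 1), baseline = rep(0, 4),
                   outcome = c(1, 2, 1, 2))
  expect_equal(fit_anova(tr)$beta, 0)
  tr2 <- make_trial(group = c(0, 0, 1, 1), baseline = c(0, 0, 1, 1),
                    outcome = c(0, 1, 1, 2))
  expect_equal(fit_csa(tr2)$beta, 0)
})

test_that("ANCOVA solves the perfectly linear toy exactly", {
  tr <- make_trial(group = c(0, 0, 1, 1), baseline = c(-1, 1, 0, 2),
                   outcome = c(-0.5, 0.5, 0.2, 1.2))
  f <- fit_ancova(tr)
  expect_equal(f$beta, 0.2, tolerance = 1e-12)
  expect_equal(f$slope, 0.5, tolerance = 1e-12)
  expect_equal(f$se, 0)
  expect_true(f$degenerate)
  expect_true(is.na(f$p_value))
  expect_equal(fit_anova(tr)$beta, 0.7, tolerance = 1e-12)
  expect_equal(fit_csa(tr)$beta, -0.3, tolerance = 1e-12)
})

test_that("per-trial algebraic identities hold to machine precision", {
  for (tr in random_trials(24)) {
    imb <- observed_imbalance(tr)
    a <- fit_anova(tr)
    cs <- fit_csa(tr)
    ac <- fit_ancova(tr)
    expect_equal(cs$beta, a$beta - imb, tolerance = 1e-10)
    expect_equal(ac$beta, a$beta - ac$slope * imb, tolerance = 1e-10)
    expect_identical(a$df, cs$df)
    expect_identical(ac$df, a$df - 1L)
  }
})

test_that("closed-form fits agree with lm() and the pooled t-test", {
  for (tr in random_trials(12, seed_base = 4000)) {
    df <- as.data.frame(tr)
    a <- fit_anova(tr)
    oa <- lm_oracle(outcome ~ group, df)
    expect_equal(a$beta, oa$beta, tolerance = 1e-10)
    expect_equal(a$se, oa$se, tolerance = 1e-10)
    expect_equal(a$p_value, oa$p_value, tolerance = 1e-10)
    tt <- t.test(outcome ~ group, data = df, var.equal = TRUE)
    expect_equal(a$p_value, tt$p.value, tolerance = 1e-10)
    expect_equal(abs(a$beta), abs(diff(tt$estimate))[[1]], tolerance = 1e-10)

    cs <- fit_csa(tr)
    oc <- lm_oracle(change ~ group, df)
    expect_equal(cs$beta, oc$beta, tolerance = 1e-10)
    expect_equal(cs$se, oc$se, tolerance = 1e-10)
    expect_equal(cs$p_value, oc$p_value, tolerance = 1e-10)

    ac <- fit_ancova(tr)
    ob <- lm_oracle(outcome ~ group + baseline, df)
    expect_equal(ac$beta, ob$beta, tolerance = 1e-10)
    expect_equal(ac$se, ob$se, tolerance = 1e-10)
    expect_equal(ac$p_value, ob$p_value, tolerance = 1e-10)
    expect_equal(ac$slope, ob$coef[["baseline"]], tolerance = 1e-10)
  }
})

test_that("shifting every outcome by a constant leaves beta and se unchanged", {
  tr <- generate_trial(scenario_spec(0.5, 0.5, 1.28, 26), seed = 99)
  shifted <- make_trial(tr$group, tr$baseline, tr$outcome + 5, tr$spec)
  for (fit in list(fit_anova, fit_csa, fit_ancova)) {
    f0 <- fit(tr)
    f1 <- fit(shifted)
    expect_equal(f1$beta, f0$beta, tolerance = 1e-10)
    expect_equal(f1$se, f0$se, tolerance = 1e-10)
  }
})

test_that("degenerate and non-estimable designs are flagged", {
  # constant baseline: ANCOVA design matrix is collinear
  tr <- make_trial(group = c(0, 0, 1, 1), baseline = rep(2, 4),
                   outcome = c(0, 1, 1, 2))
  expect_error(fit_ancova(tr), "not estimable")
  # too few observations in an arm
  tiny <- make_trial(group = c(0, 1, 1), baseline = c(0, 0, 0),
                     outcome = c(1, 2, 3))
  expect_error(fit_anova(tiny), "at least 2")
  # zero pooled variance: se = 0, undefined p rather than p = 0
  flat <- make_trial(group = c(0, 0, 1, 1), baseline = rep(0, 4),
                     outcome = c(1, 1, 2, 2))
  f <- fit_anova(flat)
  expect_equal(f$se, 0)
  expect_true(is.na(f$p_value))
})

test_that("rejection uses a strict two-sided threshold", {
  f <- fit_anova(make_trial(c(0, 0, 1, 1), rep(0, 4), c(0, 1, 1, 2)))
  expect_false(reject(f, 0.05)) # p ~ 0.293
  f$p_value <- 0.049
  expect_true(reject(f, 0.05))
  f$p_value <- 0.05
  expect_false(reject(f, 0.05))
  f$p_value <- NA_real_
  expect_error(reject(f, 0.05), "undefined")
  expect_error(reject(fit_anova(make_trial(c(0, 0, 1, 1), rep(0, 4),
                                           c(0, 1, 1, 2))), 1),
               "alpha")
})
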