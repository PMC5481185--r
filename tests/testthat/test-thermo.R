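test_that("p_on matches closed-form values and monotonicity", {
  expect_equal(p_on(thermo_params(P = 0, R = 5)), 0)          # no polymerase
  expect_equal(p_on(thermo_params(P = 1, R = 0)), 0.5)        # 1/(1+1)
  expect_equal(p_on(thermo_params(P = 1, R = 1)), 1 / 3)      # equal weights
  pars <- thermo_params(P = 2, R = 3)
  ## strictly decreasing in p, strictly increasing in r
  ps <- seq(-3, 3, by = 0.5)
  vals_p <- vapply(ps, function(p) p_on(pars, mutation_effect(p = p)), 0)
  vals_r <- vapply(ps, function(r) p_on(pars, mutation_effect(r = r)), 0)
  expect_true(all(diff(vals_p) < 0))
  expect_true(all(diff(vals_r) > 0))
  ## log-space evaluation survives huge effects
  expect_true(is.finite(p_on(pars, mutation_effect(p = 50, r = -50))))
  expect_error(thermo_params(P = -1), "activities")
  expect_error(mutation_effect(p = Inf), "finite")
})

test_that("thermo_epistasis matches the closed form and its symmetries", {
  pars <- thermo_params(P = 1, R = 0)   # A = 0, B = 1
  m <- mutation_effect(p = log(2))
  expect_equal(thermo_epistasis(pars, m, m), 0.9)   # (1.5*1.5)/(2*1.25)
  ## neutral mutations
  m0 <- mutation_effect(0, 0)
  expect_equal(thermo_epistasis(pars, m0, m0), 1)
  ## equals the ratio of p_on values
  pars2 <- thermo_params(E_P = 1, E_R = -0.5, P = 2, R = 3)
  m1 <- mutation_effect(0.7, -1.2); m2 <- mutation_effect(-0.3, 2.1)
  m12 <- mutation_effect(m1$p + m2$p, m1$r + m2$r)
  eps_ratio <- p_on(pars2) * p_on(pars2, m12) /
    (p_on(pars2, m1) * p_on(pars2, m2))
  expect_equal(thermo_epistasis(pars2, m1, m2), eps_ratio, tolerance = 1e-12)
  ## opposite-sign RNAP effects without repressor: positive epistasis
  expect_gt(thermo_epistasis(pars, mutation_effect(p = 1), mutation_effect(p = -1)), 1)
  expect_error(thermo_epistasis(thermo_params(P = 0), m, m), "B = 0")
})

test_that("epsilon is symmetric and independent of r at A = 0", {
  set.seed(42)
  for (i in 1:200) {
    A <- stats::runif(1, 0, 100); B <- stats::runif(1, 0.01, 100)
    m1 <- mutation_effect(stats::rnorm(1, 0, 2), stats::rnorm(1, 0, 2))
    m2 <- mutation_effect(stats::rnorm(1, 0, 2), stats::rnorm(1, 0, 2))
    pars <- thermo_params(P = B, R = A)
    expect_equal(thermo_epistasis(pars, m1, m2), thermo_epistasis(pars, m2, m1),
                 tolerance = 1e-12)
  }
  ## at A = 0 the repressor components are irrelevant
  for (i in 1:50) {
    B <- stats::runif(1, 0.01, 100)
    p1 <- stats::rnorm(1); p2 <- stats::rnorm(1)
    e_a <- thermo_epistasis(thermo_params(P = B),
                            mutation_effect(p1, stats::rnorm(1, 0, 5)),
                            mutation_effect(p2, stats::rnorm(1, 0, 5)))
    e_b <- thermo_epistasis(thermo_params(P = B),
                            mutation_effect(p1, stats::rnorm(1, 0, 5)),
                            mutation_effect(p2, stats::rnorm(1, 0, 5)))
    expect_equal(e_a, e_b, tolerance = 1e-12)
  }
})

test_that("sign_no_repressor agrees with brute-force epsilon on a grid", {
  expect_identical(sign_no_repressor(1, 2), "negative")
  expect_identical(sign_no_repressor(1, -1), "positive")
  expect_identical(sign_no_repressor(0, 3), "none")
  grid <- seq(-3, 3, by = 0.1)
  for (B in c(0.01, 1, 100)) {
    pars <- thermo_params(P = B)
    for (p1 in grid) for (p2 in grid) {
      eps <- thermo_epistasis(pars, mutation_effect(p = p1), mutation_effect(p = p2))
      brute <- if (abs(eps - 1) <= 1e-12) "none" else
        if (eps > 1) "positive" else "negative"
      expect_identical(sign_no_repressor(p1, p2), brute)
    }
  }
})

test_that("sign_at_concentration thresholds epsilon around 1", {
  pars <- thermo_params(P = 1, R = 0)
  m0 <- mutation_effect(0, 0)
  expect_identical(sign_at_concentration(pars, m0, m0), "none")  # eps exactly 1
  m <- mutation_effect(p = log(2))
  expect_identical(sign_at_concentration(pars, m, m, tol = 1e-6), "negative")
  ## huge repressor excess: epsilon pinned to 1
  m1 <- mutation_effect(0.5, 0.5); m2 <- mutation_effect(-0.5, 0.8)
  B <- 1
  A <- 1e8 * (1 + B * max(1, exp(-m1$p - m2$p))) * 100
  huge <- thermo_params(P = B, R = A)
  expect_identical(sign_at_concentration(huge, m1, m2, tol = 1e-6), "none")
  expect_error(sign_at_concentration(pars, m, m, tol = 0), "tol")
})

test_that("sign_trajectory classifies the canonical sweeps with breakpoints", {
  ## one mutation weakens mostly the repressor, the other mostly RNAP:
  ## negative without repressor, positive once repression is strong
  tr <- sign_trajectory(0, 0, 5, mutation_effect(0.3, 4), mutation_effect(4, 0.3))
  expect_identical(tr$category, "neg_to_pos")
  expect_true(length(tr$breakpoints) >= 1)
  expect_true(all(diff(tr$breakpoints) > 0))
  ## breakpoint really is a sign change: bracket it
  bp <- tr$breakpoints[1]
  s_lo <- sign_at_concentration(thermo_params(P = 5, R = bp * 0.99),
                                mutation_effect(0.3, 4), mutation_effect(4, 0.3))
  s_hi <- sign_at_concentration(thermo_params(P = 5, R = bp * 1.01),
                                mutation_effect(0.3, 4), mutation_effect(4, 0.3))
  expect_false(s_lo == s_hi)

  ## RNAP-only / repressor-only pair: no epistasis at low repressor,
  ## positive at intermediate, back to none at saturation
  tr2 <- sign_trajectory(0, 0, 1, mutation_effect(1, 0), mutation_effect(0, 1))
  expect_identical(tr2$category, "zero_then_pos")

  tr3 <- sign_trajectory(0, 0, 1, mutation_effect(0, 0), mutation_effect(0, 0))
  expect_identical(tr3$category, "no_epistasis")
  expect_length(tr3$breakpoints, 0)

  ## same-sign RNAP effects with equal repressor effects: the model
  ## degenerates to single-factor competition, negative throughout
  tr4 <- sign_trajectory(0, 0, 1, mutation_effect(1, 1), mutation_effect(1, 1))
  expect_identical(tr4$category, "always_negative")

  expect_error(sign_trajectory(0, 0, 1, mutation_effect(1), mutation_effect(1),
                               R_grid = c(0, 1, 10)), "12 decades")
})

test_that("unmatchable sign sequences raise a classified error", {
  err <- tryCatch(
    epistherm:::.classify_sign_sequence(c("none", "negative", "positive")),
    error = identity)
  expect_s3_class(err, "epistherm_unclassified_trajectory")
  expect_identical(err$sequence, c("none", "negative", "positive"))
})

test_that("derive_sign_table reproduces the anchor behaviors and symmetry", {
  tab <- derive_sign_table()
  get <- function(a, b, c, d)
    tab$trajectory[tab$p1 == a & tab$r1 == b & tab$p2 == c & tab$r2 == d]
  ## both mutations weaken both factors: negative -> positive sweep
  expect_identical(get("-", "-", "-", "-"), "neg_to_pos")
  ## one hits RNAP only, the other repressor only
  expect_identical(get("-", "0", "0", "-"), "zero_then_pos")
  ## opposed cross effects: constant in repressor concentration
  expect_true(get("-", "+", "+", "-") %in% c("always_positive", "always_negative"))
  ## symmetric under swapping the two mutations
  swapped <- merge(tab, tab, by.x = c("p1", "r1", "p2", "r2"),
                   by.y = c("p2", "r2", "p1", "r1"))
  expect_true(all(swapped$trajectory.x == swapped$trajectory.y))
  expect_identical(nrow(tab), 64L)
  expect_error(derive_sign_table(magnitude = -1), "magnitude")
})

test_that("epsilon converges to 1 at saturating repressor activity", {
  set.seed(7)
  for (i in 1:100) {
    B <- stats::runif(1, 0.01, 1000)
    m1 <- mutation_effect(stats::runif(1, -1, 1), stats::runif(1, -1, 1))
    m2 <- mutation_effect(stats::runif(1, -1, 1), stats::runif(1, -1, 1))
    A <- 1e8 * (1 + B * max(1, exp(-m1$p - m2$p)))
    eps <- thermo_epistasis(thermo_params(P = B, R = A), m1, m2)
    expect_lte(abs(eps - 1), 1e-6)
  }
})
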