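test_that("normalize_fluorescence computes blank-corrected ratios with SDs", {
  rec <- manual_records(list(WT = 100, mA = 200, mB = 60), blank = 20)
  norm <- normalize_fluorescence(rec)
  f <- stats::setNames(norm$f, norm$genotype)
  expect_equal(f[["WT"]], 1)
  expect_equal(f[["mA"]], (200 - 20) / (100 - 20))  # 2.25
  expect_equal(f[["mB"]], 0.5)
  expect_equal(norm$sd_f, rep(0, 3))                # zero-variance replicates
  ## mutant exactly 2x wildtype, no blank
  rec2 <- manual_records(list(WT = 100, m = 200))
  norm2 <- normalize_fluorescence(rec2)
  expect_equal(norm2$f[norm2$genotype == "m"], 2)

  expect_error(normalize_fluorescence(manual_records(list(WT = 10), blank = 20)),
               "wildtype mean <= blank")
  expect_warning(normalize_fluorescence(manual_records(list(WT = 100, low = 5),
                                                       blank = 20)),
                 "floored")
})

test_that("epistasis_estimates implements eps = f12/(f1 f2) with delta-method t", {
  mk_norm <- function(f12) data.frame(
    genotype = c("WT", "a", "b", "ab"), environment = "e", n = 6L,
    f = c(1, 0.5, 0.5, f12), sd_f = c(0.02, 0.02, 0.02, 0.02),
    floored = FALSE, stringsAsFactors = FALSE)
  pairs <- data.frame(double = "ab", single1 = "a", single2 = "b",
                      stringsAsFactors = FALSE)
  est1 <- epistasis_estimates(mk_norm(0.25), pairs)
  expect_equal(est1$epsilon, 1)          # exact multiplicativity
  expect_false(est1$significant)
  expect_identical(est1$sign, "none")
  est2 <- epistasis_estimates(mk_norm(0.1), pairs)
  expect_equal(est2$epsilon, 0.4)
  expect_identical(est2$df, 5L)
  ## t is log eps over the propagated SE
  se <- sqrt(sum((0.02 / c(0.5, 0.5, 0.1))^2))
  expect_equal(est2$t, log(0.4) / se)
  expect_true(est2$significant)
  expect_identical(est2$sign, "negative")
  expect_error(epistasis_estimates(mk_norm(-1), pairs), "> 0")
})

test_that("epsilon is invariant to rescaling all raw fluorescence", {
  study <- simulate_study(quick_config(seed = 2))
  est <- epistasis_estimates(normalize_fluorescence(study$records),
                             study$library$pairs)
  rec2 <- study$records
  rec2$fluorescence <- rec2$fluorescence * 37.5
  est2 <- epistasis_estimates(normalize_fluorescence(rec2), study$library$pairs)
  expect_equal(est$epsilon, est2$epsilon, tolerance = 1e-12)
  expect_equal(est$q, est2$q, tolerance = 1e-12)
})

test_that("classify_epistasis applies the background-flip rules", {
  mk <- function(f1, f2, f12, sig) {
    eps <- f12 / (f1 * f2)
    data.frame(genotype = "g", environment = "e", f_m1 = f1, f_m2 = f2,
               f_m12 = f12, epsilon = eps, significant = sig,
               stringsAsFactors = FALSE)
  }
  ## each single deleterious, double above wildtype: both flip
  expect_identical(classify_epistasis(mk(0.5, 0.5, 1.5, TRUE))$class,
                   "reciprocal_sign")
  ## one flip only: m2 beneficial alone, deleterious on m1's background
  expect_identical(classify_epistasis(mk(0.5, 2, 0.4, TRUE))$class, "sign")
  ## no flips, significant, eps = 0.4
  out <- classify_epistasis(mk(0.5, 0.5, 0.1, TRUE))
  expect_identical(out$class, "negative_magnitude")
  expect_false(out$caveat)
  expect_identical(classify_epistasis(mk(0.5, 0.5, 0.35, TRUE))$class,
                   "positive_magnitude")
  ## not significant, no flips
  expect_identical(classify_epistasis(mk(0.5, 0.5, 0.2, FALSE))$class,
                   "no_epistasis")
  ## flips without significance are kept but flagged
  out2 <- classify_epistasis(mk(0.5, 0.5, 1.5, FALSE))
  expect_identical(out2$class, "reciprocal_sign")
  expect_true(out2$caveat)
  ## f exactly 1: zero effect, cannot flip
  expect_identical(classify_epistasis(mk(1, 0.5, 0.25, TRUE))$class,
                   "negative_magnitude")
})

test_that("environment_comparison flags sign changes and indeterminates", {
  mk <- function(env, eps, sig) data.frame(
    genotype = c("g1", "g2", "g3"), environment = env, epsilon = eps,
    significant = sig, sign = ifelse(sig, ifelse(eps > 1, "positive", "negative"),
                                     "none"), stringsAsFactors = FALSE)
  est <- rbind(mk("no_rep", c(0.5, 0.5, 2.0), c(TRUE, TRUE, TRUE)),
               mk("rep",    c(2.0, 0.4, 2.5), c(TRUE, TRUE, FALSE)))
  cmp <- environment_comparison(est, env_order = c("no_rep", "rep"))
  per <- cmp$per_mutant
  expect_true(per$changed[per$genotype == "g1"])
  expect_false(per$changed[per$genotype == "g2"])
  expect_true(per$indeterminate[per$genotype == "g3"])
  expect_identical(cmp$summary$changed, 1L)
  expect_identical(cmp$summary$always_negative, 1L)
  ## lenient mode uses point-estimate signs: g3 becomes always positive
  cmp2 <- environment_comparison(est, env_order = c("no_rep", "rep"),
                                 lenient = TRUE)
  expect_identical(cmp2$summary$always_positive, 1L)
  expect_identical(cmp2$summary$indeterminate, 0L)
  ## Fig-4-style coordinates
  expect_equal(per$delta_log10_eps[per$genotype == "g1"],
               log10(2) - log10(0.5))
  ## missing environment: excluded with a warning
  est_miss <- est[-4, ]
  expect_warning(environment_comparison(est_miss,
                                        env_order = c("no_rep", "rep")),
                 "missing one environment")
})

test_that("sign_bias_test matches the Pearson formula", {
  mk <- function(n_pos, n_neg) data.frame(
    sign = c(rep("positive", n_pos), rep("negative", n_neg)),
    stringsAsFactors = FALSE)
  expect_equal(unname(sign_bias_test(mk(50, 50))$statistic), 0)
  ## 94 vs 19: 2 * 37.5^2 / 56.5
  expect_equal(unname(sign_bias_test(mk(19, 94))$statistic),
               2 * 37.5^2 / 56.5, tolerance = 1e-12)
  expect_equal(unname(sign_bias_test(mk(0, 12))$statistic), 12)  # all one cell
  expect_error(sign_bias_test(mk(0, 0)), "no significant")
})

test_that("gxgxe_test detects environment-dependent epistasis", {
  mk <- function(eps_a, eps_b) data.frame(
    genotype = rep(sprintf("g%02d", seq_along(eps_a)), 2),
    environment = rep(c("a", "b"), each = length(eps_a)),
    epsilon = c(eps_a, eps_b), stringsAsFactors = FALSE)
  ## identical deviations in both environments: F = 0
  eps <- exp(stats::rnorm(20, 0, 0.3))
  res0 <- gxgxe_test(mk(eps, eps))
  expect_equal(unname(res0$statistic), 0, tolerance = 1e-12)
  expect_equal(unname(res0$parameter), c(1, 38))
  ## built-in environment effect: strongly significant
  set.seed(31)
  n <- 60
  res1 <- gxgxe_test(mk(exp(stats::rnorm(n, -0.4, 0.2)),
                        exp(stats::rnorm(n, 0.4, 0.2))))
  expect_lt(res1$p.value, 1e-6)
  ## permutation p agrees in order of magnitude of evidence
  res2 <- gxgxe_test(mk(exp(stats::rnorm(n, -0.4, 0.2)),
                        exp(stats::rnorm(n, 0.4, 0.2))), n_perm = 99, seed = 4)
  expect_lt(res2$perm.p.value, 0.05)
  expect_error(gxgxe_test(mk(eps, eps)[-1, ]), "without one estimate")
})

test_that("conformity_test measures agreement against predicted categories", {
  pred <- stats::setNames(rep(c("negative", "positive"), each = 10),
                          sprintf("g%02d", 1:20))
  res <- conformity_test(pred, pred)
  expect_equal(unname(res$estimate["agreement"]), 1)
  expect_equal(unname(res$statistic), 0)
  ## random predictions agree about half the time
  set.seed(12)
  n <- 400
  obs <- stats::setNames(sample(c("negative", "positive"), n, replace = TRUE),
                         sprintf("m%03d", 1:n))
  rnd <- stats::setNames(sample(c("negative", "positive"), n, replace = TRUE),
                         names(obs))
  agree <- unname(conformity_test(rnd, obs)$estimate["agreement"])
  expect_gt(agree, 0.4); expect_lt(agree, 0.6)
  ## significance filter restricts the comparison
  sig <- stats::setNames(rep(c(TRUE, FALSE), 10), names(pred))
  res2 <- conformity_test(pred, pred, significant = sig)
  expect_equal(unname(res2$estimate["n"]), 10)
  expect_error(conformity_test(pred["g01"], obs["m001"]), "no overlapping")
})
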