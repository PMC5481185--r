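#' Wildtype-normalized relative expression from replicate fluorescence
#'
#' Raw replicate fluorescence is corrected for media autofluorescence
#' (the mean of the blank rows in the same environment) and normalized
#' by the blank-corrected wildtype mean:
#' \deqn{f_g = (\bar{X}_g - b) / (\bar{X}_{WT} - b).}
#' The standard deviation of `f` is propagated by the ratio delta
#' method, with the blank mean treated as a known constant:
#' `var(f) = var(Xbar)/(WT-b)^2 + (X-b)^2 var(WTbar)/(WT-b)^4`, where
#' the variances of the means are `s^2/n` from the replicates.
#'
#' @param records A data.frame with columns `genotype`, `environment`,
#'   `replicate`, `fluorescence` (raw, >= 0); blank wells carry the
#'   genotype id given by `blank` (optional — absent means blank 0).
#' @param wildtype Genotype id of the wildtype (must be present in
#'   every environment).
#' @param blank Genotype id of the media blank rows.
#' @param eps_floor Non-positive blank-corrected means are floored at
#'   `eps_floor` times the corrected wildtype mean, with a warning.
#' @return A data.frame with one row per genotype and environment:
#'   `genotype`, `environment`, `n`, `f` (relative expression), `sd_f`,
#'   `floored`.
#' @export
normalize_fluorescence <- function(records, wildtype = "WT", blank = "blank",
                                   eps_floor = 1e-4) {
  need <- c("genotype", "environment", "fluorescence")
  if (!all(need %in% names(records)))
    stop("normalize_fluorescence: records needs columns ",
         paste(need, collapse = ", "))
  if (any(records$fluorescence < 0))
    stop("normalize_fluorescence: raw fluorescence must be >= 0")
  out <- NULL
  for (env in unique(records$environment)) {
    rec <- records[records$environment == env, ]
    b <- rec$fluorescence[rec$genotype == blank]
    b_mean <- if (length(b)) mean(b) else 0
    rec <- rec[rec$genotype != blank, ]
    if (!wildtype %in% rec$genotype)
      stop(sprintf("normalize_fluorescence: wildtype '%s' missing in environment '%s'",
                   wildtype, env))
    gmean <- tapply(rec$fluorescence, rec$genotype, mean)
    gvar  <- tapply(rec$fluorescence, rec$genotype, stats::var)
    gn    <- tapply(rec$fluorescence, rec$genotype, length)
    if (any(gn < 2))
      stop("normalize_fluorescence: every genotype needs >= 2 replicates")
    wt_num <- gmean[[wildtype]] - b_mean
    if (wt_num <= 0)
      stop(sprintf("normalize_fluorescence: wildtype mean <= blank in environment '%s'", env))
    num <- gmean - b_mean
    floored <- num <= 0
    if (any(floored)) {
      warning(sprintf("%d genotype(s) with corrected mean <= 0 floored at %g x wildtype in environment '%s'",
                      sum(floored), eps_floor, env))
      num[floored] <- eps_floor * wt_num
    }
    f <- num / wt_num
    var_f <- (gvar / gn) / wt_num^2 +
      num^2 * (gvar[[wildtype]] / gn[[wildtype]]) / wt_num^4
    out <- rbind(out, data.frame(
      genotype = names(gmean), environment = env, n = as.integer(gn),
      f = as.numeric(f), sd_f = sqrt(as.numeric(var_f)),
      floored = as.logical(floored),
      stringsAsFactors = FALSE, row.names = NULL))
  }
  out
}

#' Multiplicative epistasis estimates with uncertainty and FDR calls
#'
#' For every double mutant, epistasis relative to the wildtype is
#' \deqn{\varepsilon = f_{m12} / (f_{m1} f_{m2}),}
#' with all `f` wildtype-normalized relative expression.  Uncertainty is
#' propagated on the log scale,
#' `var(log eps) = sum (sd_f/f)^2` over the three terms (each `f`'s
#' propagated SD already carries the wildtype contribution), giving a
#' one-sample t statistic `t = log eps / sd(log eps)` on
#' `df = n - 1` degrees of freedom, and Benjamini-Hochberg q-values
#' across the mutant set within each environment.
#'
#' @param norm Output of [normalize_fluorescence()].
#' @param pairs A data.frame keying each double mutant to its singles:
#'   columns `double`, `single1`, `single2` (genotype ids).
#' @param alpha FDR level for calling epistasis significant.
#' @param se_floor Lower bound on `sd(log eps)`; keeps the t statistic
#'   defined for noiseless data.
#' @return A data.frame of class `epistasis_estimates`: one row per
#'   double per environment with `f_m1`, `f_m2`, `f_m12`, `epsilon`,
#'   `sd_epsilon`, `se_log`, `t`, `df`, `p`, `q`, `significant`, `sign`.
#' @export
epistasis_estimates <- function(norm, pairs, alpha = 0.05, se_floor = 1e-12) {
  need <- c("double", "single1", "single2")
  if (!all(need %in% names(pairs)))
    stop("epistasis_estimates: pairs needs columns ", paste(need, collapse = ", "))
  if (!(alpha > 0 && alpha < 1)) stop("epistasis_estimates: alpha must be in (0,1)")
  out <- NULL
  for (env in unique(norm$environment)) {
    nv <- norm[norm$environment == env, ]
    row_of <- function(ids) match(ids, nv$genotype)
    i12 <- row_of(pairs$double); i1 <- row_of(pairs$single1); i2 <- row_of(pairs$single2)
    if (anyNA(c(i12, i1, i2))) {
      miss <- unique(c(pairs$double[is.na(i12)], pairs$single1[is.na(i1)],
                       pairs$single2[is.na(i2)]))
      stop(sprintf("epistasis_estimates: genotypes missing in environment '%s': %s",
                   env, paste(miss, collapse = ", ")))
    }
    f1 <- nv$f[i1]; f2 <- nv$f[i2]; f12 <- nv$f[i12]
    if (any(c(f1, f2, f12) <= 0))
      stop("epistasis_estimates: all relative expressions must be > 0")
    log_eps <- log(f12) - log(f1) - log(f2)
    var_log <- (nv$sd_f[i1] / f1)^2 + (nv$sd_f[i2] / f2)^2 + (nv$sd_f[i12] / f12)^2
    se <- pmax(sqrt(var_log), se_floor)
    df <- nv$n[i12] - 1L
    t <- log_eps / se
    p <- 2 * stats::pt(-abs(t), df = df)
    q <- stats::p.adjust(p, method = "BH")
    significant <- q <= alpha
    eps <- exp(log_eps)
    out <- rbind(out, data.frame(
      genotype = pairs$double, environment = env,
      f_m1 = f1, f_m2 = f2, f_m12 = f12,
      epsilon = eps, sd_epsilon = eps * sqrt(var_log), se_log = se,
      t = t, df = df, p = p, q = q, significant = significant,
      sign = ifelse(significant, ifelse(eps > 1, "positive", "negative"), "none"),
      stringsAsFactors = FALSE, row.names = NULL))
  }
  class(out) <- c("epistasis_estimates", "data.frame")
  out
}

#' Classify the type of epistasis of each double mutant
#'
#' The effect of mutation i on the wildtype background is
#' `sign(f_mi - 1)`; on the other single's background it is
#' `sign(f_m12 / f_mj - 1)`.  A mutation whose direction reverses
#' between the two backgrounds "flips".  Two flips give reciprocal sign
#' epistasis, one flip sign epistasis; with no flip, a significant
#' epsilon is positive or negative magnitude epistasis and a
#' non-significant one is no epistasis.  A relative expression of
#' exactly 1 is a zero effect and cannot flip.  A flip-based class
#' without significant epsilon is kept but flagged via `caveat`.
#'
#' @param estimates An [epistasis_estimates()] data.frame.
#' @return The input with columns `class` (one of `no_epistasis`,
#'   `positive_magnitude`, `negative_magnitude`, `sign`,
#'   `reciprocal_sign`) and `caveat` appended.
#' @export
classify_epistasis <- function(estimates) {
  st <- function(x) sign(x)   # -1 / 0 / 1
  e1_wt <- st(estimates$f_m1 - 1)
  e2_wt <- st(estimates$f_m2 - 1)
  e1_bg <- st(estimates$f_m12 / estimates$f_m2 - 1)
  e2_bg <- st(estimates$f_m12 / estimates$f_m1 - 1)
  flip1 <- e1_wt != 0 & e1_bg != 0 & e1_wt != e1_bg
  flip2 <- e2_wt != 0 & e2_bg != 0 & e2_wt != e2_bg
  nflip <- flip1 + flip2
  cls <- ifelse(nflip == 2, "reciprocal_sign",
         ifelse(nflip == 1, "sign",
         ifelse(estimates$significant,
                ifelse(estimates$epsilon > 1, "positive_magnitude",
                       "negative_magnitude"),
                "no_epistasis")))
  estimates$class <- cls
  estimates$caveat <- nflip > 0 & !estimates$significant
  estimates
}

#' Compare the sign of epistasis between two environments
#'
#' Pairs each double mutant's estimates in the two environments and
#' reports the per-mutant signs, whether the sign changed, and the
#' log10-epistasis coordinates (log10 epsilon without repressor against
#' the difference of log10 epsilon with minus without).  By default
#' signs come from the FDR calls, and a mutant non-significant in
#' either environment is `indeterminate` (excluded from the
#' changed/unchanged counts); with `lenient = TRUE` point-estimate signs
#' are used for all mutants.
#'
#' @param estimates An [epistasis_estimates()] data.frame covering
#'   exactly two environments.
#' @param env_order Character vector of the two environment labels,
#'   reference (repressor absent) first.
#' @param lenient Use point-estimate signs instead of FDR calls.
#' @return A list with `per_mutant` (data.frame) and `summary`
#'   (data.frame of counts: always positive, always negative, changed,
#'   indeterminate, significant in both).
#' @export
environment_comparison <- function(estimates, env_order = NULL, lenient = FALSE) {
  envs <- unique(estimates$environment)
  if (length(envs) != 2)
    stop("environment_comparison: estimates must cover exactly two environments")
  if (is.null(env_order)) env_order <- envs
  if (!setequal(env_order, envs))
    stop("environment_comparison: env_order must name the two environments")
  a <- estimates[estimates$environment == env_order[1], ]
  b <- estimates[estimates$environment == env_order[2], ]
  common <- intersect(a$genotype, b$genotype)
  dropped <- setdiff(union(a$genotype, b$genotype), common)
  if (length(dropped))
    warning(sprintf("%d mutant(s) missing one environment excluded: %s",
                    length(dropped), paste(utils::head(dropped, 5), collapse = ", ")))
  a <- a[match(common, a$genotype), ]
  b <- b[match(common, b$genotype), ]
  pt_sign <- function(eps) ifelse(eps > 1, "positive", ifelse(eps < 1, "negative", "none"))
  s1 <- if (lenient) pt_sign(a$epsilon) else a$sign
  s2 <- if (lenient) pt_sign(b$epsilon) else b$sign
  determinate <- s1 != "none" & s2 != "none"
  changed <- determinate & s1 != s2
  per <- data.frame(
    genotype = common,
    sign_ref = s1, sign_alt = s2,
    changed = ifelse(determinate, changed, NA),
    indeterminate = !determinate,
    log10_eps_ref = log10(a$epsilon), log10_eps_alt = log10(b$epsilon),
    delta_log10_eps = log10(b$epsilon) - log10(a$epsilon),
    significant_both = a$significant & b$significant,
    stringsAsFactors = FALSE, row.names = NULL)
  summary <- data.frame(
    n = length(common),
    always_positive = sum(determinate & s1 == "positive" & s2 == "positive"),
    always_negative = sum(determinate & s1 == "negative" & s2 == "negative"),
    changed = sum(changed),
    indeterminate = sum(!determinate),
    significant_both = sum(per$significant_both))
  list(per_mutant = per, summary = summary)
}

.htest <- function(statistic, parameter, p.value, method, data.name,
                   estimate = NULL) {
  structure(list(statistic = statistic, parameter = parameter,
                 p.value = p.value, method = method, data.name = data.name,
                 estimate = estimate), class = "htest")
}

#' Chi-squared test for a bias in the sign of epistasis
#'
#' Pearson chi-squared test of the counts of significantly positive and
#' significantly negative double mutants against equal expected
#' proportions.
#'
#' @param estimates An [epistasis_estimates()] data.frame (typically one
#'   environment).
#' @return An object of class `htest` with the chi-squared statistic,
#'   df = 1 and p-value; `estimate` carries the observed counts.
#' @export
sign_bias_test <- function(estimates) {
  n_pos <- sum(estimates$sign == "positive")
  n_neg <- sum(estimates$sign == "negative")
  n <- n_pos + n_neg
  if (n == 0) stop("sign_bias_test: no significant estimates")
  chisq <- sum((c(n_pos, n_neg) - n / 2)^2 / (n / 2))
  .htest(statistic = c("X-squared" = chisq), parameter = c(df = 1),
         p.value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
         method = "Pearson chi-squared test for sign bias of epistasis (equal expected proportions)",
         data.name = deparse(substitute(estimates)),
         estimate = c(positive = n_pos, negative = n_neg))
}

#' ANOVA for a genotype-by-genotype-by-environment interaction
#'
#' Tests whether the deviation of double mutants from the multiplicative
#' expectation — `log epsilon`, the pairwise genotype interaction —
#' differs between the two environments, i.e. a GxGxE interaction.  With
#' n mutant pairs measured in both environments the test is an ANOVA of
#' `log epsilon ~ environment` over the 2n per-pair estimates
#' (`F` on 1 and `2n - 2` degrees of freedom).  An optional permutation
#' p-value swaps environment labels within pairs.
#'
#' @param estimates An [epistasis_estimates()] data.frame covering two
#'   environments, every mutant in both.
#' @param n_perm Number of within-pair label permutations for a
#'   permutation p-value (0 = analytic only).
#' @param seed Seed for the permutations.
#' @return An `htest` with the F statistic, dfs and p-value(s).
#' @export
gxgxe_test <- function(estimates, n_perm = 0, seed = 1) {
  envs <- unique(estimates$environment)
  if (length(envs) != 2) stop("gxgxe_test: need exactly two environments")
  wide <- table(estimates$genotype, estimates$environment)
  bad <- rownames(wide)[rowSums(wide) != 2 | apply(wide, 1, max) > 1]
  if (length(bad))
    stop("gxgxe_test: mutants without one estimate per environment: ",
         paste(utils::head(bad, 5), collapse = ", "))
  y <- log(estimates$epsilon)
  env <- factor(estimates$environment)
  fit <- stats::lm(y ~ env)
  an <- stats::anova(fit)
  Fobs <- an$`F value`[1]
  res <- .htest(statistic = c(F = Fobs),
                parameter = c(df1 = an$Df[1], df2 = an$Df[2]),
                p.value = an$`Pr(>F)`[1],
                method = "ANOVA for GxGxE: log epistasis ~ environment",
                data.name = deparse(substitute(estimates)))
  if (n_perm > 0) {
    set.seed(seed)
    g <- factor(estimates$genotype)
    Fperm <- replicate(n_perm, {
      flip <- stats::runif(nlevels(g)) < 0.5
      env_p <- ifelse(xor(env == envs[1], flip[as.integer(g)]), envs[2], envs[1])
      a <- stats::anova(stats::lm(y ~ factor(env_p)))
      a$`F value`[1]
    })
    res$perm.p.value <- (1 + sum(Fperm >= Fobs)) / (n_perm + 1)
  }
  res
}

#' Conformity of observed epistasis categories to model predictions
#'
#' Restricted to mutants with significant observed epistasis, compares
#' the observed distribution over categories (e.g. sign of epsilon, or
#' the environment-dependence category) with the predicted distribution
#' by a Pearson chi-squared goodness-of-fit test, and reports the
#' per-mutant agreement fraction.
#'
#' @param predicted Named character vector (or data.frame with columns
#'   `genotype`, `predicted`) of predicted categories per mutant.
#' @param observed Named character vector (or data.frame with columns
#'   `genotype`, `observed`) of observed categories.
#' @param significant Optional named logical vector; non-significant
#'   mutants are dropped before the comparison (default: keep all).
#' @return An `htest` with the chi-squared statistic, df (number of
#'   predicted categories minus 1) and p-value; `estimate` carries the
#'   `agreement` fraction and the number of mutants compared.
#' @export
conformity_test <- function(predicted, observed, significant = NULL) {
  as_named <- function(x, col) {
    if (is.data.frame(x)) stats::setNames(x[[col]], x$genotype) else x
  }
  predicted <- as_named(predicted, "predicted")
  observed <- as_named(observed, "observed")
  ids <- intersect(names(predicted), names(observed))
  if (!is.null(significant)) ids <- ids[significant[ids] %in% TRUE]
  if (length(ids) == 0) stop("conformity_test: no overlapping (significant) mutants")
  pred <- predicted[ids]; obs <- observed[ids]
  lev <- sort(unique(pred))
  if (any(!obs %in% lev))
    stop("conformity_test: observed categories absent from predictions: ",
         paste(setdiff(unique(obs), lev), collapse = ", "))
  pred_counts <- table(factor(pred, levels = lev))
  obs_counts <- table(factor(obs, levels = lev))
  expected <- as.numeric(pred_counts)
  chisq <- sum((as.numeric(obs_counts) - expected)^2 / expected)
  df <- length(lev) - 1L
  .htest(statistic = c("X-squared" = chisq), parameter = c(df = df),
         p.value = stats::pchisq(chisq, df = df, lower.tail = FALSE),
         method = "Pearson chi-squared conformity test of predicted vs observed epistasis categories",
         data.name = sprintf("%d mutants", length(ids)),
         estimate = c(agreement = mean(pred == obs), n = length(ids)))
}
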