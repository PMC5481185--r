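#' Predict epistasis for a library of double mutants
#'
#' Composes [mutation_effects()] with [thermo_epistasis()]: each double
#' mutant's two point mutations are scored against the RNAP and
#' repressor energy matrices, and the closed-form epsilon is evaluated
#' at the given effective concentrations.  In the no-repressor
#' environment (`R = 0`, so `A = 0`) the predictions depend only on the
#' RNAP matrix.
#'
#' @param doubles List of [genotype()]s, each with exactly two
#'   mutations (a genotype with no mutations predicts `epsilon = 1`).
#' @param rnap,rep [energy_matrix()] objects.
#' @param wt_seq Wildtype CRE sequence.
#' @param params A [thermo_params()] object for the environment.
#' @return A data.frame with `genotype`, `p1`, `r1`, `p2`, `r2` and
#'   `epsilon_pred`.
#' @export
predict_epistasis <- function(doubles, rnap, rep, wt_seq, params) {
  stopifnot(inherits(params, "thermo_params"))
  if (params$B == 0) stop("predict_epistasis: B = 0 makes epsilon undefined")
  eff <- lapply(doubles, function(g) {
    if (nrow(g$mutations) == 0) {
      list(id = g$id, p1 = 0, r1 = 0, p2 = 0, r2 = 0)
    } else if (nrow(g$mutations) == 2) {
      e1 <- mutation_effects(genotype(g$id, g$mutations[1, ]), rnap, rep, wt_seq)
      e2 <- mutation_effects(genotype(g$id, g$mutations[2, ]), rnap, rep, wt_seq)
      list(id = g$id, p1 = e1$p, r1 = e1$r, p2 = e2$p, r2 = e2$r)
    } else stop(sprintf("predict_epistasis: genotype '%s' is not a double mutant", g$id))
  })
  df <- data.frame(genotype = vapply(eff, `[[`, "", "id"),
                   p1 = vapply(eff, `[[`, 0, "p1"), r1 = vapply(eff, `[[`, 0, "r1"),
                   p2 = vapply(eff, `[[`, 0, "p2"), r2 = vapply(eff, `[[`, 0, "r2"),
                   stringsAsFactors = FALSE)
  df$epsilon_pred <- exp(.log_epsilon(params$A, params$B,
                                      df$p1, df$r1, df$p2, df$r2))
  df
}

#' Estimate effective TF concentrations by correlation maximization
#'
#' The magnitude of predicted epistasis depends on the effective RNAP
#' and repressor activities, which are not measured.  Following the
#' correlation-maximization approach, this fits `(P, R)` by maximizing
#' the Pearson correlation between predicted and measured log epsilon,
#' pooled over both environments (predictions use `A = 0` in the
#' no-repressor environment and `A = R e^{-E_R}` with repressor), via a
#' deterministic log10 grid search followed by Nelder-Mead refinement.
#' A linear regression of measured on predicted log epsilon is reported
#' per environment.
#'
#' Identifiability: only the Boltzmann weights `A = R e^{-E_R}` and
#' `B = P e^{-E_P}` enter the model, so the energy baselines are
#' absorbed into the fitted activities; `P_hat` and `R_hat` are
#' effective activities at the given `E_P`, `E_R`.
#'
#' @param doubles List of double-mutant [genotype()]s.
#' @param rnap,rep,wt_seq Matrices and wildtype sequence as in
#'   [predict_epistasis()].
#' @param estimates An [epistasis_estimates()] data.frame covering the
#'   two environments.
#' @param env_no_repressor,env_repressor Environment labels in
#'   `estimates`.
#' @param significant_only Drop mutants without significant measured
#'   epistasis (per environment) before fitting.
#' @param E_P,E_R Energy baselines (kT), absorbed into the activities.
#' @param grid_n Grid points per axis for the coarse search.
#' @param grid_range log10 activity range searched, each axis.
#' @return A list of class `fit_result`: `P_hat`, `R_hat`, `objective`
#'   (the achieved correlation), `per_environment` regression table and
#'   `n` (mutant-environment pairs fitted).
#' @export
fit_concentrations <- function(doubles, rnap, rep, wt_seq, estimates,
                               env_no_repressor = "no_repressor",
                               env_repressor = "repressor",
                               significant_only = TRUE,
                               E_P = 0, E_R = 0,
                               grid_n = 25, grid_range = c(-6, 6)) {
  est <- estimates[estimates$environment %in% c(env_no_repressor, env_repressor), ]
  if (significant_only) est <- est[est$significant, ]
  if (nrow(est) < 3) stop("fit_concentrations: fewer than 3 estimates after filtering")
  ids <- vapply(doubles, function(g) g$id, "")
  eff <- predict_epistasis(doubles, rnap, rep, wt_seq,
                           thermo_params(P = 1, R = 0))  # only p/r columns used
  row <- match(est$genotype, ids)
  if (anyNA(row))
    stop("fit_concentrations: estimates contain genotypes absent from `doubles`")
  p1 <- eff$p1[row]; r1 <- eff$r1[row]; p2 <- eff$p2[row]; r2 <- eff$r2[row]
  with_rep <- est$environment == env_repressor
  meas <- log(est$epsilon)
  pred_log_eps <- function(log10P, log10R) {
    B <- 10^log10P * exp(-E_P)
    A <- ifelse(with_rep, 10^log10R * exp(-E_R), 0)
    .log_epsilon(A, B, p1, r1, p2, r2)
  }
  objective <- function(theta) {
    pred <- pred_log_eps(theta[1], theta[2])
    if (stats::sd(pred) == 0) return(NA_real_)
    stats::cor(pred, meas)
  }
  ax <- seq(grid_range[1], grid_range[2], length.out = grid_n)
  grid <- as.matrix(expand.grid(log10P = ax, log10R = ax))
  vals <- apply(grid, 1, objective)
  if (all(is.na(vals)))
    stop("fit_concentrations: predictions degenerate (no variance) over the whole grid")
  best <- grid[which.max(vals), ]
  opt <- stats::optim(best, function(th) {
    v <- objective(th)
    if (is.na(v)) 1 else -v
  }, method = "Nelder-Mead")
  P_hat <- 10^opt$par[1]; R_hat <- 10^opt$par[2]
  pred <- pred_log_eps(opt$par[1], opt$par[2])
  per_env <- NULL
  for (env in c(env_no_repressor, env_repressor)) {
    i <- est$environment == env
    if (sum(i) >= 3 && stats::sd(pred[i]) > 0) {
      fit <- stats::lm(meas[i] ~ pred[i])
      an <- stats::anova(fit)
      per_env <- rbind(per_env, data.frame(
        environment = env, n = sum(i),
        slope = unname(stats::coef(fit)[2]), intercept = unname(stats::coef(fit)[1]),
        F = an$`F value`[1], df1 = an$Df[1], df2 = an$Df[2],
        p = an$`Pr(>F)`[1], stringsAsFactors = FALSE))
    }
  }
  structure(list(P_hat = unname(P_hat), R_hat = unname(R_hat),
                 objective = -opt$value, per_environment = per_env,
                 n = nrow(est), E_P = E_P, E_R = E_R,
                 note = "activities are effective: energy baselines are absorbed into P_hat, R_hat"),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Effective-concentration fit (correlation maximization)\n")
  cat(sprintf("  P_hat = %.4g, R_hat = %.4g  (correlation %.3f over %d estimates)\n",
              x$P_hat, x$R_hat, x$objective, x$n))
  if (!is.null(x$per_environment)) {
    for (i in seq_len(nrow(x$per_environment))) {
      e <- x$per_environment[i, ]
      cat(sprintf("  %s: slope %.3f, intercept %.3f, F(%d,%d) = %.2f, p = %.3g\n",
                  e$environment, e$slope, e$intercept, e$df1, e$df2, e$F, e$p))
    }
  }
  cat(" ", x$note, "\n")
  invisible(x)
}
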