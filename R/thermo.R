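#' Thermodynamic parameters of the two-factor competition model
#'
#' The promoter is modelled as a single site for which an RNA
#' polymerase-like activator ("RNAP") and a repressor compete.  Three
#' configurations are possible: empty (Boltzmann weight 1), RNAP bound
#' (weight \eqn{B = P e^{-E_P}}) and repressor bound (weight
#' \eqn{A = R e^{-E_R}}).  Energies are measured in kT (natural units,
#' \eqn{\beta = 1}); `P` and `R` are dimensionless activities (the
#' exponential of each factor's chemical potential, treated as an
#' effective concentration).
#'
#' @param E_P RNAP binding free energy, kT.
#' @param E_R Repressor binding free energy, kT.
#' @param P RNAP activity, >= 0.
#' @param R Repressor activity, >= 0.
#' @return An object of class `thermo_params` with fields `E_P`, `E_R`,
#'   `P`, `R`, `beta` (fixed at 1) and the derived Boltzmann weights `A`
#'   (repressor) and `B` (RNAP).
#' @examples
#' pars <- thermo_params(E_P = 0, E_R = 0, P = 1, R = 1)
#' p_on(pars)  # 1/3: three equal-weight configurations
#' @export
thermo_params <- function(E_P = 0, E_R = 0, P = 1, R = 0) {
  for (v in list(E_P = E_P, E_R = E_R, P = P, R = R)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("thermo_params: all fields must be finite numeric scalars")
  }
  if (P < 0 || R < 0) stop("thermo_params: activities P and R must be >= 0")
  A <- R * exp(-E_R)
  B <- P * exp(-E_P)
  if (!is.finite(A) || !is.finite(B))
    stop("thermo_params: derived weights A, B must be finite; reduce |E| or activity")
  structure(list(E_P = E_P, E_R = E_R, P = P, R = R, beta = 1, A = A, B = B),
            class = "thermo_params")
}

#' @export
print.thermo_params <- function(x, ...) {
  cat("Thermodynamic parameters (beta = 1, energies in kT)\n")
  cat(sprintf("  RNAP:      E_P = %g, P = %g  (weight B = %g)\n", x$E_P, x$P, x$B))
  cat(sprintf("  repressor: E_R = %g, R = %g  (weight A = %g)\n", x$E_R, x$R, x$A))
  invisible(x)
}

#' A mutation's perturbation of the two binding energies
#'
#' A cis-regulatory point mutation perturbs the RNAP binding energy by
#' `p` and the repressor binding energy by `r`, both additively and in
#' kT.  Positive values weaken binding.  `(0, 0)` is a neutral mutation.
#'
#' @param p Perturbation of RNAP binding energy, kT (signed).
#' @param r Perturbation of repressor binding energy, kT (signed).
#' @return An object of class `mutation_effect`.
#' @export
mutation_effect <- function(p = 0, r = 0) {
  if (!is.numeric(p) || !is.numeric(r) || length(p) != 1L || length(r) != 1L ||
      !is.finite(p) || !is.finite(r))
    stop("mutation_effect: p and r must be finite numeric scalars")
  structure(list(p = p, r = r), class = "mutation_effect")
}

#' @export
print.mutation_effect <- function(x, ...) {
  cat(sprintf("Mutation effect: p = %g kT (RNAP), r = %g kT (repressor)\n", x$p, x$r))
  invisible(x)
}

## log(1 + A e^-r + B e^-p), vectorised, evaluated by log-sum-exp so that
## |p|, |r| up to ~50 kT and A, B up to ~1e300 stay finite.
.log_partition <- function(A, B, p, r) {
  n <- max(length(A), length(B), length(p), length(r))
  A <- rep_len(A, n); B <- rep_len(B, n)
  p <- rep_len(p, n); r <- rep_len(r, n)
  tA <- ifelse(A > 0, log(A) - r, -Inf)
  tB <- ifelse(B > 0, log(B) - p, -Inf)
  m <- pmax(0, tA, tB)
  m + log(exp(-m) + exp(tA - m) + exp(tB - m))
}

## log epsilon of the closed form
##   eps = (1 + A e^-r1 + B e^-p1)(1 + A e^-r2 + B e^-p2) /
##         ((1 + A + B)(1 + A e^-(r1+r2) + B e^-(p1+p2)))
## Vectorised over all arguments.
.log_epsilon <- function(A, B, p1, r1, p2, r2) {
  .log_partition(A, B, p1, r1) + .log_partition(A, B, p2, r2) -
    .log_partition(A, B, 0, 0) - .log_partition(A, B, p1 + p2, r1 + r2)
}

#' Probability that the promoter is transcriptionally active
#'
#' Evaluates \eqn{p_{ON} = B e^{-p} / (1 + A e^{-r} + B e^{-p})}, the
#' equilibrium probability that RNAP occupies the site, for the wildtype
#' (`effect = NULL`) or a mutant whose binding-energy perturbations are
#' given by `effect`.  Computed in log space to guard against overflow.
#'
#' @param params A [thermo_params()] object.
#' @param effect A [mutation_effect()] object, or `NULL` for the wildtype.
#' @return A probability in `[0, 1]`, strictly decreasing in `p` and (for
#'   `A > 0`) strictly increasing in `r`.
#' @examples
#' p_on(thermo_params(P = 1))                        # 0.5
#' p_on(thermo_params(P = 1, R = 1))                 # 1/3
#' p_on(thermo_params(P = 1), mutation_effect(p = log(2)))  # 1/3
#' @export
p_on <- function(params, effect = NULL) {
  stopifnot(inherits(params, "thermo_params"))
  if (is.null(effect)) effect <- mutation_effect(0, 0)
  stopifnot(inherits(effect, "mutation_effect"))
  if (params$B == 0) return(0)   # no polymerase, no transcription
  lnum <- log(params$B) - effect$p
  exp(lnum - .log_partition(params$A, params$B, effect$p, effect$r))
}

#' Multiplicative epistasis between two mutations under the model
#'
#' Epistasis is the deviation of the double mutant from the
#' multiplicative expectation of the singles on the \eqn{p_{ON}} scale:
#' \deqn{\varepsilon = \frac{p_{ON}^{WT}\, p_{ON}^{m12}}
#'                          {p_{ON}^{m1}\, p_{ON}^{m2}}}
#' with additive double-mutant energies
#' (\eqn{E_P^{m12} = E_P + p_1 + p_2}, likewise for the repressor).  The
#' \eqn{p_{ON}} numerators cancel, leaving a ratio of partition sums that
#' is evaluated in log space.  `epsilon > 1` is positive epistasis,
#' `< 1` negative.
#'
#' @param params A [thermo_params()] object; requires `B > 0` (an absent
#'   activator makes all \eqn{p_{ON}} zero and epsilon undefined).
#' @param m1,m2 [mutation_effect()] objects.
#' @param log Return log epsilon instead of epsilon.
#' @return A positive scalar (or its log).  Symmetric in `m1`, `m2`.
#' @examples
#' pars <- thermo_params(P = 1)  # no repressor
#' thermo_epistasis(pars, mutation_effect(p = log(2)), mutation_effect(p = log(2)))
#' # 0.9: two mutations weakening RNAP binding interact negatively
#' @export
thermo_epistasis <- function(params, m1, m2, log = FALSE) {
  stopifnot(inherits(params, "thermo_params"),
            inherits(m1, "mutation_effect"), inherits(m2, "mutation_effect"))
  if (params$B == 0)
    stop("thermo_epistasis: B = 0 (no activator) makes epsilon undefined")
  le <- .log_epsilon(params$A, params$B, m1$p, m1$r, m2$p, m2$r)
  if (log) le else exp(le)
}

.SIGNS <- c("positive", "negative", "none")

.sign_from_log_eps <- function(log_eps, tol) {
  ## tolerance is on |eps - 1| per the sign definition
  eps <- exp(log_eps)
  ifelse(abs(eps - 1) <= tol, "none", ifelse(eps > 1, "positive", "negative"))
}

#' Sign of epistasis in the absence of repressor
#'
#' With no repressor (`A = 0`) epsilon depends only on the RNAP
#' perturbations, and its sign follows a closed-form rule:
#' \eqn{\mathrm{sign}(\varepsilon - 1) = -\mathrm{sign}\{(1 - e^{-p_1})(1 - e^{-p_2})\}}.
#' Two mutations with the same strict sign of effect on RNAP binding are
#' always in negative epistasis; opposite signs give positive epistasis;
#' if either is neutral there is no epistasis.  The rule holds for every
#' RNAP weight `B > 0`.
#'
#' @param p1,p2 Effects on RNAP binding energy, kT (signed).
#' @return One of `"positive"`, `"negative"`, `"none"`.
#' @export
sign_no_repressor <- function(p1, p2) {
  if (!is.finite(p1) || !is.finite(p2))
    stop("sign_no_repressor: p1 and p2 must be finite")
  s1 <- sign(p1); s2 <- sign(p2)
  if (s1 == 0 || s2 == 0) return("none")
  if (s1 == s2) "negative" else "positive"
}

#' Sign of epistasis at a given repressor concentration
#'
#' Thresholded wrapper around [thermo_epistasis()]: `"positive"` if
#' `epsilon > 1 + tol`, `"negative"` if `epsilon < 1 - tol`, otherwise
#' `"none"`.
#'
#' @inheritParams thermo_epistasis
#' @param tol Tolerance on `|epsilon - 1|` below which epistasis is
#'   called absent; must be > 0.
#' @return One of `"positive"`, `"negative"`, `"none"`.
#' @export
sign_at_concentration <- function(params, m1, m2, tol = 1e-9) {
  if (!is.numeric(tol) || tol <= 0) stop("sign_at_concentration: tol must be > 0")
  le <- thermo_epistasis(params, m1, m2, log = TRUE)
  .sign_from_log_eps(le, tol)
}

#' Default repressor-activity sweep
#'
#' `R = 0` plus 241 log-spaced activities over `[1e-12, 1e12] * exp(E_R)`,
#' bracketing the weak- and strong-repression limits for mutation
#' effects up to about 10 kT.
#'
#' @param E_R Repressor binding energy, kT (centres the sweep on `A = 1`).
#' @param n Number of nonzero grid points.
#' @return Numeric vector of repressor activities, starting at 0.
#' @export
default_R_grid <- function(E_R = 0, n = 241) {
  c(0, exp(E_R) * 10^seq(-12, 12, length.out = n))
}

## collapse consecutive duplicates, keeping first index of each run
.collapse_runs <- function(x) {
  keep <- c(TRUE, x[-1] != x[-length(x)])
  list(values = x[keep], start = which(keep))
}

.TRAJECTORIES <- c("always_positive", "always_negative", "neg_to_pos",
                   "pos_to_neg", "zero_then_pos", "zero_then_neg",
                   "no_epistasis")

## classify a collapsed sign sequence (characters in "positive"/"negative"/"none")
## Rules: epsilon -> 1 as R -> Inf, so a trailing "none" run is stripped;
## a "none" run sandwiched between two different signs is the crossing
## itself and is merged away; a leading "none" run marks zero epistasis
## at low repressor concentration.
.classify_sign_sequence <- function(vals) {
  if (all(vals == "none")) return("no_epistasis")
  s <- vals
  while (length(s) && s[length(s)] == "none") s <- s[-length(s)]
  if (!length(s)) return("no_epistasis")
  lead0 <- s[1] == "none"
  core <- .collapse_runs(s[s != "none"])$values
  key <- paste(c(if (lead0) "0", ifelse(core == "positive", "+", "-")),
               collapse = "")
  out <- switch(key,
    "+"  = "always_positive",
    "-"  = "always_negative",
    "-+" = "neg_to_pos",
    "+-" = "pos_to_neg",
    "0+" = "zero_then_pos",
    "0-" = "zero_then_neg",
    NULL)
  if (is.null(out)) {
    cond <- structure(
      class = c("epistherm_unclassified_trajectory", "error", "condition"),
      list(message = sprintf(
             "sign sequence '%s' does not match any trajectory category",
             paste(vals, collapse = " -> ")),
           call = sys.call(-1), sequence = vals))
    stop(cond)
  }
  out
}

## locate the R where the sign changes between two grid points, by
## bisection to relative precision rel (arithmetic bisection if lo == 0,
## geometric otherwise)
.bisect_sign_change <- function(E_P, E_R, P, m1, m2, lo, hi, tol, rel = 1e-6) {
  B <- P * exp(-E_P)
  sgn <- function(R) {
    A <- R * exp(-E_R)
    .sign_from_log_eps(.log_epsilon(A, B, m1$p, m1$r, m2$p, m2$r), tol)
  }
  s_lo <- sgn(lo)
  for (i in 1:200) {
    mid <- if (lo == 0) (lo + hi) / 2 else sqrt(lo * hi)
    if (sgn(mid) == s_lo) lo <- mid else hi <- mid
    if (hi - lo <= rel * hi) break
  }
  sqrt(max(lo, .Machine$double.xmin) * hi)
}

#' Sign of epistasis along a repressor-concentration sweep
#'
#' Holding the RNAP activity fixed, sweeps the repressor activity from 0
#' upwards, evaluates the sign of epistasis at each concentration, and
#' classifies the resulting sign sequence into one of seven trajectory
#' categories.  Breakpoints (the activities at which the sign changes)
#' are located by bisection to relative precision `1e-6`.
#'
#' Categories: `always_positive`, `always_negative`, `neg_to_pos`,
#' `pos_to_neg`, `zero_then_pos`, `zero_then_neg`, `no_epistasis`.  The
#' limit \eqn{\varepsilon \to 1} at very high repressor activity is a
#' property of the model, so a trailing return to "no epistasis" does
#' not alter the category.  A sign sequence that fits no category raises
#' an error of class `epistherm_unclassified_trajectory` carrying the
#' sequence.
#'
#' @param E_P,E_R Binding energies of RNAP and repressor, kT.
#' @param P RNAP activity (> 0), held constant through the sweep.
#' @param m1,m2 [mutation_effect()] objects.
#' @param R_grid Repressor activities to scan; must start at 0 and span
#'   at least 12 decades (default [default_R_grid()]).
#' @param tol Tolerance on `|epsilon - 1|` for calling the sign.
#' @return An object of class `sign_trajectory`: list with `category`,
#'   `breakpoints` (repressor activities, strictly increasing), `signs`
#'   (the collapsed sign sequence) and the inputs.
#' @examples
#' m <- mutation_effect(p = -1, r = -1)
#' sign_trajectory(0, 0, 1, m, m)$category   # "neg_to_pos"
#' @export
sign_trajectory <- function(E_P, E_R, P, m1, m2, R_grid = default_R_grid(E_R),
                            tol = 1e-9) {
  stopifnot(inherits(m1, "mutation_effect"), inherits(m2, "mutation_effect"))
  if (P <= 0) stop("sign_trajectory: RNAP activity P must be > 0")
  if (tol <= 0) stop("sign_trajectory: tol must be > 0")
  R_grid <- sort(unique(R_grid))
  if (R_grid[1] != 0) stop("sign_trajectory: R_grid must include 0")
  pos <- R_grid[R_grid > 0]
  if (log10(max(pos)) - log10(min(pos)) < 12)
    stop("sign_trajectory: R_grid must span at least 12 decades")
  A <- R_grid * exp(-E_R)
  B <- P * exp(-E_P)
  signs <- .sign_from_log_eps(.log_epsilon(A, B, m1$p, m1$r, m2$p, m2$r), tol)
  runs <- .collapse_runs(signs)
  category <- .classify_sign_sequence(runs$values)
  breakpoints <- numeric(0)
  if (length(runs$values) > 1) {
    for (k in 2:length(runs$values)) {
      i <- runs$start[k]
      breakpoints <- c(breakpoints,
                       .bisect_sign_change(E_P, E_R, P, m1, m2,
                                           R_grid[i - 1], R_grid[i], tol))
    }
  }
  structure(list(category = category, breakpoints = breakpoints,
                 signs = runs$values, E_P = E_P, E_R = E_R, P = P,
                 m1 = m1, m2 = m2, tol = tol),
            class = "sign_trajectory")
}

#' @export
print.sign_trajectory <- function(x, ...) {
  cat(sprintf("Sign trajectory: %s\n", x$category))
  cat(sprintf("  sign sequence: %s\n", paste(x$signs, collapse = " -> ")))
  if (length(x$breakpoints))
    cat(sprintf("  breakpoints (repressor activity): %s\n",
                paste(signif(x$breakpoints, 6), collapse = ", ")))
  invisible(x)
}

#' Sign-of-epistasis table over all combinations of mutation-effect signs
#'
#' Enumerates every combination of per-mutation effect signs on RNAP
#' (`p`) and repressor (`r`) binding and classifies, for each pair of
#' mutations, the sign trajectory of epistasis across the repressor
#' sweep.  Signs are given in the binding convention of such tables:
#' `"-"` means the mutation *weakens* binding of that factor (a positive
#' kT perturbation), `"+"` that it strengthens it, `"0"` that the factor
#' is unaffected.  The doubly-neutral mutation `(0, 0)` is excluded.
#'
#' A sign combination fixes only the directions of the four effects, and
#' some trajectory categories are not constant over a combination's
#' whole magnitude region.  Each cell is therefore evaluated at a
#' representative configuration in which the two mutations primarily
#' target different factors — mutation 1 the repressor, mutation 2 the
#' RNAP — with the primary effect of size `magnitude` and the secondary
#' of size `minor` (a mutation touching a single factor gets `magnitude`
#' on it).  This is the regime in which the effects of mutations on
#' repressor binding dominate at high repressor concentration; at fully
#' symmetric magnitudes (every `p_i = r_i`) the model degenerates to
#' single-factor competition and the concentration dependence of the
#' sign disappears.  Cells are computed once per unordered pair, so the
#' table is symmetric under swapping the two mutations.
#'
#' @param magnitude Primary (dominant-factor) effect size in kT (> 0).
#' @param minor Secondary-factor effect size in kT (>= 0, < `magnitude`).
#' @param E_P,E_R,P Model parameters as in [sign_trajectory()]; the
#'   default `P = 5` corresponds to a strong promoter (wildtype
#'   occupancy 5/6 without repressor).
#' @param tol Sign tolerance.
#' @return A data.frame with columns `p1`, `r1`, `p2`, `r2` (characters
#'   `"-"`, `"0"`, `"+"`, binding convention) and `trajectory`.
#' @export
derive_sign_table <- function(magnitude = 4, minor = 0.3, E_P = 0, E_R = 0,
                              P = 5, tol = 1e-9) {
  if (magnitude <= 0) stop("derive_sign_table: magnitude must be > 0")
  if (minor < 0 || minor >= magnitude)
    stop("derive_sign_table: need 0 <= minor < magnitude")
  sgn_chr <- c("-", "0", "+")
  sgn_val <- c(1, 0, -1)  # binding "-" = weaker = +kT energy perturbation
  combos <- expand.grid(p = 1:3, r = 1:3)
  combos <- combos[!(combos$p == 2 & combos$r == 2), , drop = FALSE]  # drop (0,0)
  ## energy-scale effect for a sign class under a dominance role
  class_effect <- function(cls, primary = c("repressor", "rnap")) {
    primary <- match.arg(primary)
    sp <- sgn_val[cls$p]; sr <- sgn_val[cls$r]
    if (primary == "repressor") {
      mag_r <- magnitude
      mag_p <- if (sr == 0) magnitude else minor
    } else {
      mag_p <- magnitude
      mag_r <- if (sp == 0) magnitude else minor
    }
    mutation_effect(sp * mag_p, sr * mag_r)
  }
  n <- nrow(combos)
  cell <- matrix(NA_character_, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    tr <- sign_trajectory(E_P, E_R, P,
                          class_effect(combos[i, ], "repressor"),
                          class_effect(combos[j, ], "rnap"),
                          tol = tol)
    cell[i, j] <- tr$category
    cell[j, i] <- tr$category
  }
  grid <- expand.grid(i = seq_len(n), j = seq_len(n))
  data.frame(p1 = sgn_chr[combos$p[grid$i]], r1 = sgn_chr[combos$r[grid$i]],
             p2 = sgn_chr[combos$p[grid$j]], r2 = sgn_chr[combos$r[grid$j]],
             trajectory = cell[cbind(grid$i, grid$j)],
             stringsAsFactors = FALSE)
}
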