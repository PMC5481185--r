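#' Configuration of a synthetic epistasis study
#'
#' Bundles the design of a simulated study: a 43-bp cis-regulatory
#' element carrying overlapping RNAP and repressor footprints, a random
#' library of double mutants with both corresponding singles, six
#' replicate fluorescence measurements per genotype, and two
#' environments (repressor absent / present).  The noise model is
#' multiplicative lognormal on each replicate (fluorescence is positive
#' and analysed as ratios); the noise level, blank level and matrix
#' scales are synthetic stand-ins chosen to emulate typical plate-reader
#' data, not published values.
#'
#' @param seed Integer seed for the whole study.
#' @param cre_length CRE length in bp.
#' @param n_doubles Number of random double mutants.
#' @param replicates Replicates per genotype and environment.
#' @param noise_sd Lognormal sd of replicate fluorescence.
#' @param blank_level Media autofluorescence as a fraction of
#'   `wildtype_scale`.
#' @param wildtype_scale Signal of the wildtype above blank, arbitrary
#'   fluorescence units.
#' @param params_no_repressor,params_repressor [thermo_params()] for the
#'   two environments; defaults give a strong promoter (`B = 5`) and,
#'   with repressor, ~99 percent repression (`A = 500`).
#' @param rnap_scale,rep_scale Mean non-reference entry (kT) of the
#'   sampled RNAP and repressor matrices; the repressor site is the more
#'   specific one.
#' @param rnap_offset,rnap_length,rep_offset,rep_length Footprint
#'   geometry (0-based, half-open); defaults overlap on the 3' part of
#'   the RNAP site.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1, cre_length = 43, n_doubles = 141,
                              replicates = 6, noise_sd = 0.1,
                              blank_level = 0.05, wildtype_scale = 1000,
                              params_no_repressor = thermo_params(P = 5, R = 0),
                              params_repressor = thermo_params(P = 5, R = 500),
                              rnap_scale = 1.5, rep_scale = 3,
                              rnap_offset = 0, rnap_length = 35,
                              rep_offset = 17, rep_length = 26) {
  stopifnot(cre_length >= 1, n_doubles >= 1, replicates >= 1, noise_sd >= 0,
            wildtype_scale > 0, blank_level >= 0)
  if (rnap_offset + rnap_length > cre_length ||
      rep_offset + rep_length > cre_length)
    stop("simulation_config: footprints must lie inside the CRE")
  ov <- min(rnap_offset + rnap_length, rep_offset + rep_length) -
    max(rnap_offset, rep_offset)
  if (ov <= 0)
    stop("simulation_config: footprints must overlap (binding-site competition)")
  structure(list(seed = seed, cre_length = cre_length, n_doubles = n_doubles,
                 replicates = replicates, noise_sd = noise_sd,
                 blank_level = blank_level, wildtype_scale = wildtype_scale,
                 params_no_repressor = params_no_repressor,
                 params_repressor = params_repressor,
                 rnap_scale = rnap_scale, rep_scale = rep_scale,
                 rnap_offset = rnap_offset, rnap_length = rnap_length,
                 rep_offset = rep_offset, rep_length = rep_length),
            class = "simulation_config")
}

#' Sample a synthetic position-specific energy matrix
#'
#' Reference-base entries are 0 and every non-reference entry is drawn
#' from a Gaussian of mean `scale` truncated at 0, so the reference
#' sequence is the strongest binder (a strong site: essentially every
#' mutation weakens binding).
#'
#' @param length Footprint length in bp (>= 1).
#' @param scale Mean non-reference entry in kT (> 0); sd is `scale/2`.
#' @param seed Optional integer seed (`NULL` = use current RNG state).
#' @param reference_sequence Optional reference sequence; random if
#'   `NULL`.
#' @param name,offset Passed to [energy_matrix()].
#' @return An [energy_matrix()].
#' @export
sample_energy_matrix <- function(length, scale, seed = NULL,
                                 reference_sequence = NULL,
                                 name = "synthetic", offset = 0L) {
  stopifnot(length >= 1, scale > 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(reference_sequence))
    reference_sequence <- paste(sample(.BASES, length, replace = TRUE),
                                collapse = "")
  entries <- matrix(0, nrow = length, ncol = 4,
                    dimnames = list(NULL, .BASES))
  ref_idx <- match(strsplit(toupper(reference_sequence), "")[[1]], .BASES)
  nonref <- cbind(rep(seq_len(length), each = 3),
                  unlist(lapply(ref_idx, function(i) setdiff(1:4, i))))
  draw <- function(n) {
    x <- stats::rnorm(n, mean = scale, sd = scale / 2)
    while (any(x <= 0)) x[x <= 0] <- stats::rnorm(sum(x <= 0), scale, scale / 2)
    x
  }
  entries[nonref] <- draw(nrow(nonref))
  energy_matrix(entries, reference_sequence = reference_sequence,
                name = name, offset = offset)
}

.single_id <- function(position, ref, alt) sprintf("%d%s>%s", position, ref, alt)

#' Sample a random library of double mutants with their singles
#'
#' Draws `n_doubles` distinct double mutants (two point mutations at
#' distinct positions) uniformly without replacement from all possible
#' doubles on `wt_seq`, and includes each implied single mutant exactly
#' once.
#'
#' @param wt_seq Wildtype CRE sequence.
#' @param n_doubles Number of doubles (at most the number of distinct
#'   double mutants).
#' @param seed Optional integer seed (`NULL` = use current RNG state).
#' @return A list with `doubles` and `singles` (lists of [genotype()])
#'   and `pairs` (data.frame `double`, `single1`, `single2`).
#' @export
sample_library <- function(wt_seq, n_doubles, seed = NULL) {
  wt_seq <- .check_seq(wt_seq, "wt_seq")
  if (!is.null(seed)) set.seed(seed)
  chars <- strsplit(wt_seq, "")[[1]]
  L <- length(chars)
  singles <- do.call(rbind, lapply(seq_len(L), function(j) {
    data.frame(position = j - 1L, ref = chars[j],
               alt = setdiff(.BASES, chars[j]), stringsAsFactors = FALSE)
  }))
  ns <- nrow(singles)
  pair_idx <- utils::combn(ns, 2)
  pair_idx <- pair_idx[, singles$position[pair_idx[1, ]] !=
                         singles$position[pair_idx[2, ]], drop = FALSE]
  if (n_doubles > ncol(pair_idx))
    stop(sprintf("sample_library: n_doubles (%d) exceeds the %d distinct double mutants",
                 n_doubles, ncol(pair_idx)))
  sel <- pair_idx[, sample.int(ncol(pair_idx), n_doubles), drop = FALSE]
  mk_single <- function(i) {
    s <- singles[i, ]
    genotype(.single_id(s$position, s$ref, s$alt), s)
  }
  used_singles <- sort(unique(as.vector(sel)))
  singles_list <- lapply(used_singles, mk_single)
  doubles_list <- vector("list", n_doubles)
  pairs <- data.frame(double = character(n_doubles),
                      single1 = character(n_doubles),
                      single2 = character(n_doubles),
                      stringsAsFactors = FALSE)
  for (k in seq_len(n_doubles)) {
    i <- sel[1, k]; j <- sel[2, k]
    s1 <- singles[i, ]; s2 <- singles[j, ]
    id1 <- .single_id(s1$position, s1$ref, s1$alt)
    id2 <- .single_id(s2$position, s2$ref, s2$alt)
    did <- paste(id1, id2, sep = "|")
    doubles_list[[k]] <- genotype(did, rbind(s1, s2))
    pairs[k, ] <- c(did, id1, id2)
  }
  list(doubles = doubles_list, singles = singles_list, pairs = pairs)
}

#' Simulate replicate fluorescence for a genotype library
#'
#' For each genotype and environment the expected fluorescence is
#' `blank + wildtype_scale * pON(genotype) / pON(wildtype)`; each
#' replicate is the expectation times lognormal noise
#' `exp(N(0, noise_sd))`.  Blank wells are simulated the same way around
#' `blank_level * wildtype_scale`.  A ground-truth table (model pON,
#' relative expression, epsilon and its sign per environment) is
#' returned alongside; it is computed directly from the thermodynamic
#' model and is never consumed by the estimation pipeline.
#'
#' @param config A [simulation_config()].
#' @param library A library as returned by [sample_library()].
#' @param rnap,rep [energy_matrix()] objects.
#' @param wt_seq Wildtype CRE sequence.
#' @return A list with `records` (data.frame `genotype`, `environment`,
#'   `replicate`, `fluorescence`, including wildtype `"WT"` and
#'   `"blank"` rows) and `truth` (list of data.frames `genotypes` and
#'   `doubles`).
#' @export
simulate_fluorescence <- function(config, library, rnap, rep, wt_seq) {
  stopifnot(inherits(config, "simulation_config"))
  genos <- c(list(genotype("WT")), library$singles, library$doubles)
  ids <- vapply(genos, function(g) g$id, "")
  eff <- lapply(genos, mutation_effects, rnap = rnap, rep = rep, wt_seq = wt_seq)
  p_eff <- vapply(eff, function(e) e$p, 0)
  r_eff <- vapply(eff, function(e) e$r, 0)
  envs <- list(no_repressor = config$params_no_repressor,
               repressor = config$params_repressor)
  blank_abs <- config$blank_level * config$wildtype_scale
  records <- NULL
  truth_g <- NULL
  for (env in names(envs)) {
    par <- envs[[env]]
    lpon <- log(par$B) - p_eff - .log_partition(par$A, par$B, p_eff, r_eff)
    rel <- exp(lpon - lpon[1])   # genotype 1 is WT
    mean_f <- blank_abs + config$wildtype_scale * rel
    n_rep <- config$replicates
    noise <- exp(stats::rnorm((length(ids) + 1L) * n_rep, 0, config$noise_sd))
    vals <- c(rep(mean_f, each = n_rep), rep(blank_abs, n_rep)) * noise
    records <- rbind(records, data.frame(
      genotype = c(rep(ids, each = n_rep), rep("blank", n_rep)),
      environment = env,
      replicate = rep(seq_len(n_rep), times = length(ids) + 1L),
      fluorescence = vals, stringsAsFactors = FALSE))
    truth_g <- rbind(truth_g, data.frame(
      genotype = ids, environment = env, p = p_eff, r = r_eff,
      p_on = exp(lpon), rel_expression = rel, stringsAsFactors = FALSE))
  }
  pairs <- library$pairs
  i1 <- match(pairs$single1, ids); i2 <- match(pairs$single2, ids)
  truth_d <- NULL
  for (env in names(envs)) {
    par <- envs[[env]]
    le <- .log_epsilon(par$A, par$B, p_eff[i1], r_eff[i1], p_eff[i2], r_eff[i2])
    truth_d <- rbind(truth_d, data.frame(
      genotype = pairs$double, environment = env, epsilon = exp(le),
      sign = .sign_from_log_eps(le, 1e-9), stringsAsFactors = FALSE))
  }
  list(records = records,
       truth = list(genotypes = truth_g, doubles = truth_d))
}

#' Generate a complete synthetic study
#'
#' Seeds the RNG once from `config$seed`, then samples the wildtype CRE
#' and the two energy matrices, draws the random mutant library and
#' simulates replicate fluorescence in both environments.
#'
#' @param config A [simulation_config()].
#' @return A list with `wt_seq`, `rnap`, `rep` (matrices), `library`,
#'   `records`, `truth` and `config`.
#' @export
simulate_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  wt_seq <- paste(sample(.BASES, config$cre_length, replace = TRUE),
                  collapse = "")
  rnap <- sample_energy_matrix(
    config$rnap_length, config$rnap_scale, name = "RNAP",
    offset = config$rnap_offset,
    reference_sequence = substr(wt_seq, config$rnap_offset + 1L,
                                config$rnap_offset + config$rnap_length))
  rep <- sample_energy_matrix(
    config$rep_length, config$rep_scale, name = "repressor",
    offset = config$rep_offset,
    reference_sequence = substr(wt_seq, config$rep_offset + 1L,
                                config$rep_offset + config$rep_length))
  library <- sample_library(wt_seq, config$n_doubles)
  sim <- simulate_fluorescence(config, library, rnap, rep, wt_seq)
  list(wt_seq = wt_seq, rnap = rnap, rep = rep, library = library,
       records = sim$records, truth = sim$truth, config = config)
}
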