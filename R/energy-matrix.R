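.BASES <- c("A", "C", "G", "T")

#' Position-specific binding-energy matrix
#'
#' Per-position, per-base additive contributions (kT) to a protein's
#' DNA-binding free energy.  The matrix is anchored to a cis-regulatory
#' element (CRE) by a 0-based `offset`: it scores the half-open window
#' `[offset, offset + L)` of the CRE on the sense strand.  Larger energy
#' means weaker binding.
#'
#' @param entries Numeric matrix, one row per position, columns
#'   `A`, `C`, `G`, `T`; all entries finite.
#' @param reference_sequence The bound sequence the matrix is anchored
#'   to (string of length `nrow(entries)`).
#' @param name Identifier for the factor (e.g. `"RNAP"`).
#' @param offset 0-based start of the footprint within the CRE.
#' @return An object of class `energy_matrix`.
#' @examples
#' m <- energy_matrix(matrix(0, 4, 4, dimnames = list(NULL, c("A","C","G","T"))),
#'                    reference_sequence = "ACGT")
#' sequence_energy("ACGT", m)  # 0
#' @export
energy_matrix <- function(entries, reference_sequence, name = "matrix",
                          offset = 0L) {
  entries <- as.matrix(entries)
  if (is.null(colnames(entries))) colnames(entries) <- .BASES
  if (!identical(colnames(entries), .BASES))
    stop("energy_matrix: entries must have exactly the columns A, C, G, T")
  if (!is.numeric(entries) || !all(is.finite(entries)))
    stop("energy_matrix: all entries must be finite numbers")
  reference_sequence <- toupper(reference_sequence)
  if (nchar(reference_sequence) != nrow(entries))
    stop("energy_matrix: reference_sequence length must equal the number of positions")
  if (!grepl("^[ACGT]+$", reference_sequence))
    stop("energy_matrix: reference_sequence may contain only A, C, G, T")
  offset <- as.integer(offset)
  if (is.na(offset) || offset < 0L) stop("energy_matrix: offset must be a non-negative integer")
  rownames(entries) <- NULL
  structure(list(name = name, entries = entries,
                 reference_sequence = reference_sequence, offset = offset),
            class = "energy_matrix")
}

#' @export
length.energy_matrix <- function(x) nrow(x$entries)

#' @export
print.energy_matrix <- function(x, ...) {
  cat(sprintf("Energy matrix '%s': %d positions, CRE offset %d (0-based)\n",
              x$name, length(x), x$offset))
  cat(sprintf("  reference: %s\n", x$reference_sequence))
  cat(sprintf("  entry range: [%.3g, %.3g] kT\n",
              min(x$entries), max(x$entries)))
  invisible(x)
}

.check_seq <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L)
    stop(sprintf("%s must be a single string", what))
  seq <- toupper(seq)
  bad <- regmatches(seq, regexpr("[^ACGT]", seq))
  if (length(bad) && nchar(bad))
    stop(sprintf("%s contains non-ACGT character '%s'", what, bad))
  seq
}

#' Additive binding energy of a sequence under an energy matrix
#'
#' Sums, over the matrix footprint, the entry for the base observed at
#' each position.  `seq` is the full CRE (or any sequence whose window
#' `[offset, offset + L)` covers the footprint).
#'
#' @param seq Nucleotide string covering the footprint.
#' @param matrix An [energy_matrix()].
#' @return Binding energy in kT.
#' @export
sequence_energy <- function(seq, matrix) {
  stopifnot(inherits(matrix, "energy_matrix"))
  seq <- .check_seq(seq)
  L <- length(matrix)
  if (nchar(seq) < matrix$offset + L)
    stop(sprintf("sequence_energy: sequence (length %d) does not cover footprint [%d, %d)",
                 nchar(seq), matrix$offset, matrix$offset + L))
  window <- substr(seq, matrix$offset + 1L, matrix$offset + L)
  idx <- match(strsplit(window, "")[[1]], .BASES)
  sum(matrix$entries[cbind(seq_len(L), idx)])
}

#' A cis-regulatory point mutation
#'
#' @param position 0-based index within the CRE.
#' @param ref,alt Reference and alternate base (`A`, `C`, `G` or `T`;
#'   must differ).
#' @return An object of class `cre_mutation` (a one-row data.frame).
#' @export
cre_mutation <- function(position, ref, alt) {
  position <- as.integer(position)
  ref <- toupper(ref); alt <- toupper(alt)
  if (is.na(position) || position < 0L) stop("cre_mutation: position must be >= 0")
  if (!ref %in% .BASES || !alt %in% .BASES)
    stop("cre_mutation: ref and alt must be A, C, G or T")
  if (ref == alt) stop("cre_mutation: ref and alt must differ")
  structure(data.frame(position = position, ref = ref, alt = alt,
                       stringsAsFactors = FALSE),
            class = c("cre_mutation", "data.frame"))
}

#' A genotype: a set of 0, 1 or 2 point mutations on the wildtype CRE
#'
#' @param id Genotype identifier.
#' @param mutations A data.frame with columns `position`, `ref`, `alt`
#'   (0 rows = wildtype), e.g. built by rbinding [cre_mutation()]s.
#' @return An object of class `genotype`.
#' @export
genotype <- function(id, mutations = NULL) {
  if (is.null(mutations))
    mutations <- data.frame(position = integer(), ref = character(),
                            alt = character(), stringsAsFactors = FALSE)
  mutations <- as.data.frame(mutations)[, c("position", "ref", "alt")]
  if (anyDuplicated(mutations$position))
    stop("genotype: mutation positions must be distinct")
  for (i in seq_len(nrow(mutations)))
    cre_mutation(mutations$position[i], mutations$ref[i], mutations$alt[i])
  structure(list(id = as.character(id), mutations = mutations),
            class = "genotype")
}

#' @export
print.genotype <- function(x, ...) {
  lab <- if (nrow(x$mutations) == 0) "wildtype" else
    paste(sprintf("%d%s>%s", x$mutations$position, x$mutations$ref,
                  x$mutations$alt), collapse = " + ")
  cat(sprintf("Genotype '%s': %s\n", x$id, lab))
  invisible(x)
}

#' Apply a genotype's mutations to the wildtype CRE
#'
#' @param wt_seq Wildtype CRE sequence.
#' @param g A [genotype()].
#' @return The mutated sequence.
#' @export
apply_genotype <- function(wt_seq, g) {
  stopifnot(inherits(g, "genotype"))
  wt_seq <- .check_seq(wt_seq, "wt_seq")
  chars <- strsplit(wt_seq, "")[[1]]
  for (i in seq_len(nrow(g$mutations))) {
    pos <- g$mutations$position[i]
    if (pos >= length(chars))
      stop(sprintf("genotype '%s': position %d outside CRE of length %d",
                   g$id, pos, length(chars)))
    if (chars[pos + 1L] != g$mutations$ref[i])
      stop(sprintf("genotype '%s': ref base '%s' at position %d does not match CRE base '%s'",
                   g$id, g$mutations$ref[i], pos, chars[pos + 1L]))
    chars[pos + 1L] <- g$mutations$alt[i]
  }
  paste(chars, collapse = "")
}

#' Binding-energy perturbations (p, r) of a genotype
#'
#' Scores the genotype's sequence against the RNAP and repressor energy
#' matrices and returns the change relative to wildtype.  Mutations
#' outside a matrix footprint contribute 0 to that matrix's delta;
#' additivity makes a double mutant's effect the sum of its singles'.
#'
#' @param g A [genotype()].
#' @param rnap,rep [energy_matrix()] objects for RNAP and repressor.
#' @param wt_seq Wildtype CRE sequence covering both footprints.
#' @return A [mutation_effect()] with `p` (RNAP) and `r` (repressor)
#'   deltas in kT; the wildtype genotype gives `(0, 0)`.
#' @export
mutation_effects <- function(g, rnap, rep, wt_seq) {
  wt_seq <- .check_seq(wt_seq, "wt_seq")
  mut_seq <- apply_genotype(wt_seq, g)
  mutation_effect(
    p = sequence_energy(mut_seq, rnap) - sequence_energy(wt_seq, rnap),
    r = sequence_energy(mut_seq, rep) - sequence_energy(wt_seq, rep))
}

#' Drop the lowest-impact spacer position from an energy matrix
#'
#' Published promoter matrices sometimes carry one more spacer position
#' than the element under study; this removes, within the given spacer
#' region, the position whose entries can change binding the least.
#' Impact of a position is the range (max minus min) of its four base
#' entries; ties go to the 5'-most position.  All other entries are
#' preserved bit-exactly and the footprint shortens by one.
#'
#' @param matrix An [energy_matrix()].
#' @param spacer_interval Integer vector of candidate positions,
#'   0-based, local to the matrix (within `[0, L)`).
#' @return An [energy_matrix()] of length `L - 1`.
#' @export
reduce_spacer_position <- function(matrix, spacer_interval) {
  stopifnot(inherits(matrix, "energy_matrix"))
  spacer_interval <- as.integer(spacer_interval)
  if (length(spacer_interval) == 0) stop("reduce_spacer_position: empty spacer interval")
  L <- length(matrix)
  if (any(spacer_interval < 0L) || any(spacer_interval >= L))
    stop("reduce_spacer_position: spacer interval must lie inside the footprint")
  spacer_interval <- sort(unique(spacer_interval))
  impact <- apply(matrix$entries[spacer_interval + 1L, , drop = FALSE], 1,
                  function(e) max(e) - min(e))
  drop <- spacer_interval[which.min(impact)] + 1L   # which.min: first = 5'-most
  energy_matrix(matrix$entries[-drop, , drop = FALSE],
                reference_sequence = paste(strsplit(matrix$reference_sequence, "")[[1]][-drop],
                                           collapse = ""),
                name = matrix$name, offset = matrix$offset)
}

## enumerate all single point mutations of wt_seq with their (p, r)
## effects under the two matrices; returns a data.frame
.enumerate_singles <- function(rnap, rep, wt_seq) {
  wt_seq <- .check_seq(wt_seq, "wt_seq")
  chars <- strsplit(wt_seq, "")[[1]]
  L <- length(chars)
  delta_for <- function(m) {
    d <- numeric(0); pos <- integer(0); alt <- character(0)
    for (j in seq_len(L)) {
      ref <- chars[j]
      for (b in setdiff(.BASES, ref)) {
        pos <- c(pos, j - 1L); alt <- c(alt, b)
        within <- (j - 1L) >= m$offset && (j - 1L) < m$offset + length(m)
        d <- c(d, if (within) {
          i <- j - m$offset
          m$entries[i, b] - m$entries[i, ref]
        } else 0)
      }
    }
    data.frame(position = pos, alt = alt, delta = d, stringsAsFactors = FALSE)
  }
  dp <- delta_for(rnap); dr <- delta_for(rep)
  data.frame(position = dp$position, ref = chars[dp$position + 1L],
             alt = dp$alt, p = dp$delta, r = dr$delta,
             stringsAsFactors = FALSE)
}

.effect_sign <- function(x, threshold = 1e-9) {
  ifelse(abs(x) <= threshold, 0L, ifelse(x > 0, 1L, -1L))
}

.sign_chr_to_int <- function(s) {
  if (is.numeric(s)) return(as.integer(sign(s)))
  out <- c("-" = -1L, "0" = 0L, "+" = 1L)[as.character(s)]
  if (anyNA(out)) stop("signs must be '-', '0', '+' or numeric")
  unname(out)
}

#' Design a panel of double mutants by sign category of single effects
#'
#' For each requested category — a pair of per-mutation `(sign p,
#' sign r)` patterns in the energy convention (positive = weaker
#' binding) — samples `n_per_category` double mutants, uniformly without
#' replacement over all qualifying pairs of single point mutations at
#' distinct positions, such that the two singles' effect signs match the
#' pattern.  Categories with no qualifying single mutation are flagged
#' infeasible rather than failing (for strong sites, mutations that
#' simultaneously improve the binding of both factors typically do not
#' exist).
#'
#' @param rnap,rep [energy_matrix()] objects.
#' @param wt_seq Wildtype CRE sequence.
#' @param categories List of categories; each is a list/matrix of two
#'   sign pairs, e.g. `list(c(p = 1, r = 1), c(p = 1, r = -1))`, signs
#'   in `{-1, 0, 1}` or `"-"/"0"/"+"`.
#' @param n_per_category Double mutants per feasible category (>= 1).
#' @param seed Integer seed controlling the sampling.
#' @param threshold |delta| below which an effect counts as 0 (kT).
#' @return A list with `genotypes` (list of [genotype()]; ids encode
#'   category and mutations), and `summary` (data.frame with per-category
#'   counts and a `feasible` flag).
#' @export
design_sign_category_panel <- function(rnap, rep, wt_seq, categories,
                                       n_per_category = 5, seed = 1,
                                       threshold = 1e-9) {
  if (n_per_category < 1) stop("design_sign_category_panel: n_per_category must be >= 1")
  singles <- .enumerate_singles(rnap, rep, wt_seq)
  singles$sp <- .effect_sign(singles$p, threshold)
  singles$sr <- .effect_sign(singles$r, threshold)
  set.seed(seed)
  genotypes <- list()
  summary <- NULL
  for (k in seq_along(categories)) {
    cat_k <- categories[[k]]
    c1 <- .sign_chr_to_int(cat_k[[1]]); c2 <- .sign_chr_to_int(cat_k[[2]])
    i1 <- which(singles$sp == c1[1] & singles$sr == c1[2])
    i2 <- which(singles$sp == c2[1] & singles$sr == c2[2])
    pairs <- expand.grid(a = i1, b = i2)
    pairs <- pairs[singles$position[pairs$a] != singles$position[pairs$b], , drop = FALSE]
    ## unordered pairs: canonicalise and deduplicate
    key <- paste(pmin(pairs$a, pairs$b), pmax(pairs$a, pairs$b))
    pairs <- pairs[!duplicated(key), , drop = FALSE]
    n_avail <- nrow(pairs)
    feasible <- n_avail > 0
    take <- min(n_per_category, n_avail)
    if (feasible) {
      sel <- pairs[sample.int(n_avail, take), , drop = FALSE]
      for (q in seq_len(take)) {
        s1 <- singles[sel$a[q], ]; s2 <- singles[sel$b[q], ]
        ord <- order(c(s1$position, s2$position))
        muts <- rbind(s1[, c("position", "ref", "alt")],
                      s2[, c("position", "ref", "alt")])[ord, ]
        id <- sprintf("cat%d_%d:%s", k, q,
                      paste(sprintf("%d%s>%s", muts$position, muts$ref, muts$alt),
                            collapse = "|"))
        genotypes[[length(genotypes) + 1L]] <- genotype(id, muts)
      }
    }
    summary <- rbind(summary, data.frame(
      category = k,
      m1 = sprintf("(%+d,%+d)", c1[1], c1[2]),
      m2 = sprintf("(%+d,%+d)", c2[1], c2[2]),
      n_requested = n_per_category, n_available = n_avail,
      n_sampled = if (feasible) take else 0L, feasible = feasible,
      stringsAsFactors = FALSE))
  }
  list(genotypes = genotypes, summary = summary, seed = seed)
}
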