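## Small deterministic fixtures shared across tests; everything is
## built in code at test time.

## 8-bp CRE with a 6-bp RNAP footprint (offset 0) and a 5-bp repressor
## footprint (offset 3): overlap at positions 3..5.
tiny_cre <- function() "ACGTACGT"

tiny_matrix <- function(name, offset, ref, fill = 0) {
  L <- nchar(ref)
  entries <- matrix(fill, L, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  ref_idx <- match(strsplit(ref, "")[[1]], c("A", "C", "G", "T"))
  entries[cbind(seq_len(L), ref_idx)] <- 0
  energy_matrix(entries, reference_sequence = ref, name = name,
                offset = offset)
}

tiny_rnap <- function(fill = 1) tiny_matrix("RNAP", 0L, "ACGTAC", fill)
tiny_rep <- function(fill = 2) tiny_matrix("repressor", 3L, "TACGT", fill)

## a quick synthetic study, small enough for fast tests
quick_config <- function(seed = 1, ...) {
  simulation_config(seed = seed, n_doubles = 25, ...)
}

## replicate fluorescence records with exact means (no noise) for
## hand-checkable normalization tests
manual_records <- function(means, blank = 0, n = 3, environment = "env") {
  rows <- NULL
  for (g in names(means)) {
    rows <- rbind(rows, data.frame(
      genotype = g, environment = environment, replicate = seq_len(n),
      fluorescence = rep(means[[g]], n), stringsAsFactors = FALSE))
  }
  if (blank > 0)
    rows <- rbind(rows, data.frame(genotype = "blank", environment = environment,
                                   replicate = seq_len(n),
                                   fluorescence = rep(blank, n),
                                   stringsAsFactors = FALSE))
  rows
}
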