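#' Read and write energy matrices (TSV + JSON sidecar)
#'
#' The TSV has header `pos A C G T` (0-based position within the
#' footprint, energies in kT); a JSON sidecar at `<path>.json` carries
#' `name`, `offset` and `reference_sequence`.
#'
#' @param path TSV path.
#' @param matrix An [energy_matrix()] (for writing).
#' @return `read_energy_matrix` returns an [energy_matrix()];
#'   `write_energy_matrix` returns `path` invisibly.
#' @export
read_energy_matrix <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!identical(names(tab), c("pos", "A", "C", "G", "T")))
    stop(sprintf("%s: expected header 'pos A C G T', got '%s'",
                 path, paste(names(tab), collapse = " ")))
  if (!identical(tab$pos, seq_len(nrow(tab)) - 1L))
    stop(sprintf("%s: pos column must run 0..%d", path, nrow(tab) - 1L))
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop(sprintf("%s: sidecar %s not found", path, side))
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  energy_matrix(as.matrix(tab[, .BASES]),
                reference_sequence = meta$reference_sequence,
                name = meta$name, offset = meta$offset)
}

#' @rdname read_energy_matrix
#' @export
write_energy_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "energy_matrix"))
  tab <- data.frame(pos = seq_len(length(matrix)) - 1L, matrix$entries)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(name = matrix$name, offset = matrix$offset,
                            reference_sequence = matrix$reference_sequence),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write the wildtype CRE as FASTA
#'
#' @param path FASTA path.
#' @param seq Sequence string (for writing).
#' @param name FASTA record name.
#' @return `read_cre_fasta` returns the (upper-case) sequence string.
#' @export
read_cre_fasta <- function(path) {
  fa <- seqinr::read.fasta(path, seqtype = "DNA", as.string = TRUE,
                           forceDNAtolower = FALSE)
  if (length(fa) != 1) stop(sprintf("%s: expected exactly one FASTA record", path))
  .check_seq(toupper(as.character(fa[[1]])), basename(path))
}

#' @rdname read_cre_fasta
#' @export
write_cre_fasta <- function(seq, path, name = "CRE") {
  seqinr::write.fasta(list(strsplit(seq, "")[[1]]), names = name,
                      file.out = path)
  invisible(path)
}

#' Read and write genotype tables (CSV, one row per mutation)
#'
#' Columns `id`, `position` (0-based), `ref`, `alt`; a genotype's rows
#' share its `id`.  On reading, every `ref` is validated against the
#' wildtype sequence and mismatches are reported with their line
#' numbers.
#'
#' @param path CSV path.
#' @param wt_seq Wildtype CRE sequence for validation.
#' @param genotypes List of [genotype()]s (for writing).
#' @return `read_genotypes` returns a list of [genotype()]s in order of
#'   first appearance.
#' @export
read_genotypes <- function(path, wt_seq) {
  wt_seq <- .check_seq(wt_seq, "wt_seq")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "position", "ref", "alt")
  if (!all(need %in% names(tab)))
    stop(sprintf("%s: expected columns %s", path, paste(need, collapse = ", ")))
  chars <- strsplit(wt_seq, "")[[1]]
  bad <- which(tab$position < 0 | tab$position >= length(chars) |
                 chars[pmin(tab$position + 1L, length(chars))] != toupper(tab$ref))
  if (length(bad))
    stop(sprintf("%s: ref base mismatch with wildtype CRE at line(s) %s",
                 path, paste(bad + 1L, collapse = ", ")))  # +1 for header
  ids <- unique(tab$id)
  lapply(ids, function(i) genotype(i, tab[tab$id == i, c("position", "ref", "alt")]))
}

#' @rdname read_genotypes
#' @export
write_genotypes <- function(genotypes, path) {
  rows <- do.call(rbind, lapply(genotypes, function(g) {
    if (nrow(g$mutations) == 0) return(NULL)
    data.frame(id = g$id, g$mutations, stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write replicate fluorescence tables (CSV)
#'
#' Columns `genotype`, `environment`, `replicate`, `fluorescence`;
#' blank (media) wells use the genotype id `"blank"`.
#'
#' @param path CSV path.
#' @param records Data.frame (for writing).
#' @return `read_fluorescence` returns the validated data.frame.
#' @export
read_fluorescence <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("genotype", "environment", "replicate", "fluorescence")
  if (!all(need %in% names(tab)))
    stop(sprintf("%s: expected columns %s", path, paste(need, collapse = ", ")))
  bad <- which(!is.finite(tab$fluorescence) | tab$fluorescence < 0)
  if (length(bad))
    stop(sprintf("%s: negative or non-finite fluorescence at line(s) %s",
                 path, paste(utils::head(bad, 5) + 1L, collapse = ", ")))
  tab
}

#' @rdname read_fluorescence
#' @export
write_fluorescence <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write epistasis estimates to CSV
#'
#' One row per double mutant per environment, mirroring the layout of
#' per-mutant epistasis source-data tables: relative expression of the
#' singles and double, epsilon with its SD, the t statistic and the
#' FDR-corrected p value.
#'
#' @param estimates An [epistasis_estimates()] data.frame.
#' @param path CSV path.
#' @export
write_estimates <- function(estimates, path) {
  utils::write.csv(as.data.frame(estimates), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_estimates
#' @export
read_estimates <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("genotype", "environment", "epsilon", "significant", "sign")
  if (!all(need %in% names(tab)))
    stop(sprintf("%s: expected columns %s", path, paste(need, collapse = ", ")))
  class(tab) <- c("epistasis_estimates", "data.frame")
  tab
}
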