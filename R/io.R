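# Plain-text readers and writers for cohort data.

AIRR_COLUMNS <- c(junction_aa_alpha = "cdr3a", junction_aa_beta = "cdr3b",
                  v_call_alpha = "va", j_call_alpha = "ja",
                  v_call_beta = "vb", j_call_beta = "jb",
                  clonotype_id = "clonotype_id", patient_id = "patient_id")

#' Write an AIRR-style clonotype table
#'
#' Tab-separated with columns `junction_aa_alpha`, `junction_aa_beta`,
#' `v_call_alpha`, `j_call_alpha`, `v_call_beta`, `j_call_beta`,
#' `clonotype_id`, `patient_id`.
#'
#' @param clonotypes Clonotype table in internal column naming.
#' @param path Output TSV path.
#' @export
write_clonotypes <- function(clonotypes, path) {
  out <- clonotypes[, AIRR_COLUMNS]
  names(out) <- names(AIRR_COLUMNS)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an AIRR-style clonotype table
#'
#' @param path TSV path written by [write_clonotypes()] (or any table with
#'   the same column names).
#' @return Clonotype data.frame in internal column naming (`cdr3a`, `cdr3b`,
#'   `va`, `ja`, `vb`, `jb`, `clonotype_id`, `patient_id`).
#' @export
read_clonotypes <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(names(AIRR_COLUMNS), names(x))
  if (length(miss) > 0) {
    stop("AIRR table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- x[, names(AIRR_COLUMNS)]
  names(out) <- unname(AIRR_COLUMNS)
  out
}

#' Write a simulated cohort to a directory of plain-text files
#'
#' Writes the clonotype table (AIRR TSV), cell table (TSV), gene counts
#' (matrix-market `.mtx` plus `genes.txt` / `barcodes.txt`), surface-protein,
#' plasma, HLA and cDC matrices (CSV), totals (TSV), and ground truth (JSON).
#'
#' @param sim Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_clonotypes(sim$clonotypes, file.path(dir, "clonotypes.tsv"))
  utils::write.table(sim$cells, file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  Matrix::writeMM(sim$counts, file.path(dir, "counts.mtx"))
  writeLines(rownames(sim$counts), file.path(dir, "genes.txt"))
  writeLines(colnames(sim$counts), file.path(dir, "barcodes.txt"))
  utils::write.csv(as.data.frame(as.matrix(sim$surface)),
                   file.path(dir, "surface.csv"))
  utils::write.csv(as.data.frame(sim$plasma), file.path(dir, "plasma.csv"))
  utils::write.csv(as.data.frame(sim$hla), file.path(dir, "hla.csv"))
  utils::write.csv(as.data.frame(sim$cdc), file.path(dir, "cdc.csv"))
  utils::write.table(sim$totals, file.path(dir, "totals.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$activity <- NULL  # large per-cell matrix; regenerate from config
  truth$true_cluster <- as.list(truth$true_cluster)  # keep names in JSON
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

#' Read a gene count matrix written by [write_cohort()]
#'
#' @param dir Directory with `counts.mtx`, `genes.txt`, `barcodes.txt`.
#' @return Sparse gene x cell count matrix.
#' @export
read_counts <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "counts.mtx"))
  dimnames(m) <- list(readLines(file.path(dir, "genes.txt")),
                      readLines(file.path(dir, "barcodes.txt")))
  methods::as(m, "CsparseMatrix")
}
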