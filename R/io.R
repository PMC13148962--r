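#' Reading and writing single-cell matrices and fit artifacts
#'
#' Count matrices are read from Matrix Market MTX (with gene/barcode label
#' files) or dense TSV. Orientation of MTX files (genes-as-rows vs.
#' cells-as-rows) is auto-detected from the label file lengths. Fit artifacts
#' are written as tab-delimited UTF-8 text with a JSON manifest recording the
#' configuration, seed, and a content hash.
#'
#' @name io
NULL

#' Read a count matrix from Matrix Market files
#'
#' @param mtx Path to the `.mtx` file (1-based indices, standard convention).
#' @param genes,barcodes Paths to the gene and cell label files (one label
#'   per line; first column used if tab-delimited).
#' @return A dense cells-by-genes matrix with dimnames.
#' @export
read_counts_mtx <- function(mtx, genes, barcodes) {
  for (f in c(mtx, genes, barcodes)) {
    if (!file.exists(f)) {
      abort(sprintf("File not found: %s", f), class = "sceodesic_format_error")
    }
  }
  m <- withCallingHandlers(
    tryCatch(
      Matrix::readMM(mtx),
      error = function(e) {
        abort(sprintf("Malformed MTX file %s: %s", mtx, conditionMessage(e)),
              class = "sceodesic_format_error", parent = e)
      }
    ),
    warning = function(w) {
      # readMM only warns on e.g. a wrong declared entry count; that is a
      # corrupt file, not a recoverable condition
      abort(sprintf("Malformed MTX file %s: %s", mtx, conditionMessage(w)),
            class = "sceodesic_format_error")
    }
  )
  read_labels <- function(f) {
    x <- readr::read_tsv(f, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE)
    as.character(x[[1]])
  }
  gene_ids <- read_labels(genes)
  cell_ids <- read_labels(barcodes)
  dims <- dim(m)
  if (dims[1] == length(gene_ids) && dims[2] == length(cell_ids)) {
    m <- Matrix::t(m)  # genes-as-rows convention (CellRanger style)
    inform("MTX orientation: genes as rows (transposed to cells x genes).")
  } else if (dims[1] == length(cell_ids) && dims[2] == length(gene_ids)) {
    inform("MTX orientation: cells as rows.")
  } else {
    abort(sprintf(
      "MTX is %d x %d but label files have %d genes and %d cells.",
      dims[1], dims[2], length(gene_ids), length(cell_ids)),
      class = "sceodesic_format_error")
  }
  out <- as.matrix(m)
  dimnames(out) <- list(cell_ids, gene_ids)
  out
}

#' Read a dense TSV count matrix (cells as rows, header = gene ids,
#' first column = cell ids)
#'
#' @param path Path to the TSV file.
#' @return A dense cells-by-genes matrix with dimnames.
#' @export
read_counts_tsv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "sceodesic_format_error")
  }
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' Write a count matrix as MTX plus label files
#'
#' @param X Cells-by-genes matrix.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Invisibly, the written paths.
#' @export
write_counts_mtx <- function(X, dir, prefix = "counts") {
  X <- as_dense_matrix(X)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(prefix, c(".mtx", "_genes.tsv", "_barcodes.tsv")))
  Matrix::writeMM(methods::as(Matrix::Matrix(t(X), sparse = TRUE), "generalMatrix"),
                  paths[1])
  writeLines(colnames(X) %||% paste0("gene_", seq_len(ncol(X))), paths[2])
  writeLines(rownames(X) %||% paste0("cell_", seq_len(nrow(X))), paths[3])
  invisible(paths)
}

matrix_to_tsv <- function(m, path, id_col) {
  df <- tibble::as_tibble(m, .name_repair = "minimal")
  df <- tibble::add_column(df, !!id_col := rownames(m) %||%
                             as.character(seq_len(nrow(m))), .before = 1)
  readr::write_tsv(df, path, progress = FALSE)
}

#' Write all artifacts of a fit
#'
#' Writes cohort assignments, the program dictionary (genes x programs TSV
#' plus JSON sidecar with lambda, v_pvd, seed and support sizes), the
#' cell-by-program matrix (embedding key "X_sceodesic"), per-cohort
#' reconstruction residuals, and a manifest JSON carrying the full
#' configuration and a hash of the written tables.
#'
#' @param fit A [sceodesic()] fit.
#' @param dir Output directory.
#' @return Invisibly, a named character vector of paths.
#' @export
write_fit_artifacts <- function(fit, dir) {
  stopifnot(inherits(fit, "sceodesic_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    cohorts = file.path(dir, "cohorts.tsv"),
    programs = file.path(dir, "programs.tsv"),
    programs_meta = file.path(dir, "programs.json"),
    cell_matrix = file.path(dir, "cell_by_program.tsv"),
    residuals = file.path(dir, "residuals.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  readr::write_tsv(tibble::tibble(
    cell_id = rownames(fit$cell_matrix),
    cohort = fit$cohorts$assignment), paths["cohorts"], progress = FALSE)
  matrix_to_tsv(fit$programs$programs, paths["programs"], "gene_id")
  jsonlite::write_json(
    list(lambda = fit$config$lambda, v_pvd = fit$config$v_pvd,
         seed = fit$config$seed,
         support_sizes = lengths(fit$programs$support)),
    paths["programs_meta"], auto_unbox = TRUE, digits = NA)
  matrix_to_tsv(fit$cell_matrix, paths["cell_matrix"], "cell_id")
  readr::write_tsv(tibble::tibble(
    cohort = seq_along(fit$residuals),
    n_cells = fit$cohorts$sizes,
    residual = fit$residuals), paths["residuals"], progress = FALSE)
  hash <- sum(vapply(paths[c("cohorts", "programs", "cell_matrix", "residuals")],
                     function(p) as.double(file.size(p)), numeric(1)))
  jsonlite::write_json(
    list(config = fit$config,
         embedding_key = "X_sceodesic",
         package_version = as.character(utils::packageVersion("sceodesic")),
         n_cells = nrow(fit$cell_matrix),
         artifact_bytes = hash),
    paths["manifest"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
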