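#' Read a gene-by-sample TPM matrix from delimited text
#'
#' Reads the standard gene x sample expression table: a header row of sample
#' identifiers, a first column of gene identifiers (conventionally named
#' `gene_id`), and one nonnegative TPM value per cell. The result is validated
#' on the way in: duplicate gene or sample identifiers, negative values,
#' non-numeric cells and empty matrices are all hard errors that name the
#' offending coordinate.
#'
#' @param path Path to the delimited text file.
#' @param delimiter Field delimiter, tab by default.
#'
#' @return A numeric matrix with genes as rows (rownames = gene identifiers)
#'   and samples as columns (colnames = sample identifiers).
#'
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' m <- matrix(c(0, 5, 2, 8), 2, 2, dimnames = list(c("A", "B"), c("s1", "s2")))
#' write_expression_matrix(m, tf)
#' read_expression_matrix(tf)
#' @export
read_expression_matrix <- function(path, delimiter = "\t") {
  if (!file.exists(path)) {
    rlang::abort(paste0("expression matrix file not found: ", path))
  }
  raw <- readr::read_delim(
    path,
    delim = delimiter,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (ncol(raw) < 2L || nrow(raw) == 0L) {
    rlang::abort("empty expression matrix: need at least one gene row and one sample column")
  }
  gene_ids <- raw[[1L]]
  sample_ids <- colnames(raw)[-1L]
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup) > 0L) {
    rlang::abort(paste0("duplicate gene id(s): ", paste(unique(dup), collapse = ", ")))
  }
  dup_s <- sample_ids[duplicated(sample_ids)]
  if (length(dup_s) > 0L) {
    rlang::abort(paste0("duplicate sample id(s): ", paste(unique(dup_s), collapse = ", ")))
  }
  vals <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw)))
  )
  vals <- matrix(vals, nrow = nrow(raw), dimnames = list(gene_ids, sample_ids))
  bad <- which(is.na(vals) | !is.finite(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    rlang::abort(paste0(
      "non-numeric or non-finite cell at (gene ", gene_ids[bad[1L, 1L]],
      ", sample ", sample_ids[bad[1L, 2L]], ")"
    ))
  }
  neg <- which(vals < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L) {
    rlang::abort(paste0(
      "negative TPM value ", vals[neg[1L, , drop = FALSE]],
      " at (gene ", gene_ids[neg[1L, 1L]],
      ", sample ", sample_ids[neg[1L, 2L]], ")"
    ))
  }
  validate_expression_matrix(vals)
}

#' Validate a gene-by-sample expression matrix
#'
#' Checks the invariants every downstream step relies on: a numeric matrix,
#' all values finite and nonnegative, unique non-empty gene and sample
#' identifiers, and at least one gene and one sample. Data frames with a
#' `gene_id` first column are converted.
#'
#' @param m Numeric matrix (genes x samples) with dimnames, or a data frame
#'   whose first column holds gene identifiers.
#' @return The validated numeric matrix, invisibly identical to the input.
#' @export
validate_expression_matrix <- function(m) {
  m <- as_tpm_matrix(m)
  if (nrow(m) == 0L || ncol(m) == 0L) {
    rlang::abort("empty expression matrix")
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    rlang::abort("expression matrix must carry gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(m))) {
    rlang::abort(paste0(
      "duplicate gene id(s): ",
      paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", ")
    ))
  }
  if (anyDuplicated(colnames(m))) {
    rlang::abort(paste0(
      "duplicate sample id(s): ",
      paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", ")
    ))
  }
  if (!is.numeric(m)) rlang::abort("expression values must be numeric")
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    rlang::abort(paste0(
      "non-finite value at (gene ", rownames(m)[bad[1L, 1L]],
      ", sample ", colnames(m)[bad[1L, 2L]], ")"
    ))
  }
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L) {
    rlang::abort(paste0(
      "negative TPM value at (gene ", rownames(m)[neg[1L, 1L]],
      ", sample ", colnames(m)[neg[1L, 2L]], ")"
    ))
  }
  m
}

#' Write a gene-by-sample matrix as tab-separated text
#'
#' Inverse of [read_expression_matrix()]: writes a `gene_id` first column,
#' a sample-id header row, and one value per cell.
#'
#' @param m Numeric matrix (genes x samples) with dimnames.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  m <- as_tpm_matrix(m)
  out <- tibble::as_tibble(m, rownames = "gene_id")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a results table as tab-separated text
#'
#' Writes any per-gene results tibble (plasticity profile, sorting table,
#' candidate table) with a header row; floating-point columns are serialized
#' at 6 significant digits so tables round-trip stably through text.
#'
#' @param records A data frame of results sharing one column schema.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- dplyr::mutate(
    tibble::as_tibble(records),
    dplyr::across(dplyr::where(is.double), ~ signif(.x, 6L))
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

# Coerce data-frame input (gene_id first column) to the internal numeric
# matrix representation; matrices pass through untouched.
as_tpm_matrix <- function(m) {
  if (is.data.frame(m)) {
    ids <- as.character(m[[1L]])
    vals <- as.matrix(m[-1L])
    storage.mode(vals) <- "double"
    rownames(vals) <- ids
    return(vals)
  }
  if (!is.matrix(m)) {
    rlang::abort("expected a genes x samples matrix or a data frame with a gene_id column")
  }
  m
}
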