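#' Construct a single-subject connectome
#'
#' A connectome is one subject's square symmetric connectivity matrix with a
#' zero diagonal (no self-loops), tagged with the subject id, the modality
#' and the units of its entries. Diffusion (streamline-count) entries must be
#' nonnegative; functional entries are Pearson correlations or their Fisher z
#' transforms.
#'
#' @param values An `n x n` numeric matrix, symmetric with zero diagonal.
#' @param subject_id Subject identifier.
#' @param modality `"dmri"` or `"rsfmri"`.
#' @param units `"streamline-count"`, `"pearson-r"` or `"fisher-z"`.
#' @return The matrix with class `connectome` and metadata attributes.
#' @export
connectome <- function(values, subject_id, modality = c("dmri", "rsfmri"),
                       units = c("streamline-count", "pearson-r", "fisher-z")) {
  modality <- match.arg(modality)
  units <- match.arg(units)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("connectome matrix must be square", call. = FALSE)
  if (!all(is.finite(values))) stop("connectome entries must be finite", call. = FALSE)
  if (max(abs(values - t(values))) > 1e-8) {
    stop("connectome matrix must be symmetric (use symmetrize() first)", call. = FALSE)
  }
  diag(values) <- 0
  if (units == "streamline-count" && any(values < 0)) {
    stop("streamline counts must be nonnegative", call. = FALSE)
  }
  structure(values, subject_id = as.character(subject_id),
            modality = modality, units = units,
            class = c("connectome", "matrix", "array"))
}

conn_units <- function(x) attr(x, "units")
conn_modality <- function(x) attr(x, "modality")

# rebuild a connectome with new values, keeping metadata
conn_update <- function(x, values, units = conn_units(x)) {
  connectome(values, attr(x, "subject_id"), conn_modality(x), units)
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> subject %s, %s [%s], %d x %d, %d nonzero edges\n",
              attr(x, "subject_id"), conn_modality(x), conn_units(x),
              nrow(x), ncol(x), sum(upper_values(x) != 0)))
  invisible(x)
}

#' Symmetrize a square matrix and zero its diagonal
#'
#' Raw probabilistic-tractography count matrices are directional; analyses of
#' unordered node pairs need one value per pair. `method = "mean"` averages
#' the two directions, `"min"`/`"max"` take the elementwise extreme.
#'
#' @param values A square numeric matrix.
#' @param method One of `"mean"`, `"min"`, `"max"`.
#' @return A symmetric matrix with zero diagonal.
#' @export
symmetrize <- function(values, method = c("mean", "min", "max")) {
  method <- match.arg(method)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("matrix must be square", call. = FALSE)
  out <- switch(method,
    mean = (values + t(values)) / 2,
    min  = pmin(values, t(values)),
    max  = pmax(values, t(values))
  )
  diag(out) <- 0
  out
}

#' Absolute-threshold quality control for connectomes
#'
#' `apply_dmri_threshold()` removes spurious streamline-count edges: entries
#' below `min_count` are set to zero and entries at or above it are kept
#' unchanged (the default of 10 treats "thresholded at 10 counts" as the
#' minimum retained value). `apply_rsfmri_threshold()` keeps correlation
#' edges with `|r|` strictly greater than `r_min` (default 0.05), preserving
#' the sign; weaker edges are zeroed. Both are idempotent.
#'
#' @param x A `connectome` (or plain matrix) in the required units.
#' @param min_count Minimum streamline count retained.
#' @return An object of the same kind as `x` with sub-threshold entries
#'   zeroed.
#' @export
apply_dmri_threshold <- function(x, min_count = 10) {
  if (inherits(x, "connectome") && conn_units(x) != "streamline-count") {
    stop("dMRI threshold needs streamline-count units, got ", conn_units(x),
         call. = FALSE)
  }
  v <- unclass(x)
  v[v < min_count] <- 0
  if (inherits(x, "connectome")) conn_update(x, v) else v
}

#' @rdname apply_dmri_threshold
#' @param r_min Correlation magnitude that must be exceeded for an edge to
#'   be retained.
#' @export
apply_rsfmri_threshold <- function(x, r_min = 0.05) {
  if (inherits(x, "connectome") && conn_units(x) != "pearson-r") {
    stop("rsfMRI threshold needs pearson-r units, got ", conn_units(x),
         call. = FALSE)
  }
  v <- unclass(x)
  if (any(abs(v) > 1 + 1e-12)) stop("|r| > 1 in a correlation connectome", call. = FALSE)
  v[abs(v) <= r_min] <- 0
  if (inherits(x, "connectome")) conn_update(x, v) else v
}

#' Fisher r-to-z transform of a correlation connectome
#'
#' Variance-stabilises retained Pearson correlations: each nonzero entry `r`
#' becomes `atanh(r) = log((1 + r) / (1 - r)) / 2`; structural zeros (edges
#' removed by thresholding) stay zero. Applied after absolute thresholding.
#'
#' @param x A `connectome` (or matrix) in `pearson-r` units with all
#'   retained `|r| < 1`.
#' @return The transformed connectome in `fisher-z` units.
#' @export
fisher_z_transform <- function(x) {
  if (inherits(x, "connectome") && conn_units(x) != "pearson-r") {
    stop("Fisher z needs pearson-r units, got ", conn_units(x), call. = FALSE)
  }
  v <- unclass(x)
  if (any(abs(v) >= 1)) stop("|r| >= 1: Fisher z undefined", call. = FALSE)
  z <- atanh(v)
  if (inherits(x, "connectome")) conn_update(x, z, units = "fisher-z") else z
}

#' Read or write a connectivity matrix
#'
#' Two plain-text formats are supported: dense TSV (`n` rows by `n` numeric
#' columns, no header) and MatrixMarket coordinate format (1-based). Symmetry
#' is not enforced on read, since raw tractography counts may be directional.
#'
#' @param path File path; with `format = "auto"`, `.mtx` selects
#'   MatrixMarket and anything else dense TSV.
#' @param format `"auto"`, `"dense-tsv"` or `"matrix-market"`.
#' @param n Optional expected dimension; a mismatch is an error.
#' @return `read_matrix()` returns a square numeric matrix.
#' @export
read_matrix <- function(path, format = c("auto", "dense-tsv", "matrix-market"),
                        n = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "matrix-market" else "dense-tsv"
  }
  m <- switch(format,
    "dense-tsv" = {
      df <- utils::read.table(path, header = FALSE, sep = "\t",
                              colClasses = "numeric")
      as.matrix(df)
    },
    "matrix-market" = as.matrix(Matrix::readMM(path))
  )
  dimnames(m) <- NULL
  if (!is.numeric(m)) stop("non-numeric cells in ", path, call. = FALSE)
  if (nrow(m) != ncol(m)) {
    stop("matrix in ", path, " is not square (", nrow(m), " x ", ncol(m), ")",
         call. = FALSE)
  }
  if (!is.null(n) && nrow(m) != n) {
    stop("matrix dimension ", nrow(m), " does not match atlas size ", n,
         call. = FALSE)
  }
  m
}

#' @rdname read_matrix
#' @param values A square numeric matrix to write.
#' @export
write_matrix <- function(values, path,
                         format = c("auto", "dense-tsv", "matrix-market")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "matrix-market" else "dense-tsv"
  }
  values <- unclass(as.matrix(values))
  if (format == "dense-tsv") {
    lines <- apply(values, 1, function(r) {
      paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
            collapse = "\t")
    })
    writeLines(lines, path)
  } else {
    Matrix::writeMM(methods::as(Matrix::Matrix(values, sparse = TRUE),
                                "generalMatrix"), path)
  }
  invisible(path)
}

#' Read or write the sidecar JSON header of a connectome file
#'
#' The header records `subject_id`, `modality`, `units` and `n_parcels` next
#' to the matrix file, as `<matrix path>.json`.
#'
#' @param matrix_path Path of the matrix file the header describes.
#' @return `read_connectome_header()` returns a named list.
#' @export
read_connectome_header <- function(matrix_path) {
  jsonlite::read_json(paste0(matrix_path, ".json"), simplifyVector = TRUE)
}

#' @rdname read_connectome_header
#' @param x A `connectome`.
#' @export
write_connectome_header <- function(x, matrix_path) {
  jsonlite::write_json(
    list(subject_id = attr(x, "subject_id"), modality = conn_modality(x),
         units = conn_units(x), n_parcels = nrow(x)),
    paste0(matrix_path, ".json"), auto_unbox = TRUE)
  invisible(matrix_path)
}
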