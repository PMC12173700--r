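#' Construct an atlas table
#'
#' An atlas is a tibble with one row per parcel and columns `node_id`
#' (1-based, exactly `1:n`), `hemisphere` (`"L"` or `"R"`), `network_label`
#' (a named functional network or `"None"`) and `region_label` (free-text
#' anatomical label). Both connectivity modalities share the atlas, so every
#' connectome matrix must have `nrow(atlas)` rows and columns.
#'
#' @param node_id Integer vector of parcel ids; must be exactly `1:n`.
#' @param hemisphere Character vector of `"L"`/`"R"`.
#' @param network_label Character vector of network labels.
#' @param region_label Character vector of anatomical labels.
#' @return A tibble of class `cd_atlas`.
#' @export
atlas_table <- function(node_id, hemisphere,
                        network_label = "None",
                        region_label = NA_character_) {
  out <- tibble::tibble(
    node_id = as.integer(node_id),
    hemisphere = as.character(hemisphere),
    network_label = as.character(network_label),
    region_label = as.character(region_label)
  )
  validate_atlas(out)
}

#' @rdname atlas_table
#' @param atlas An atlas tibble to validate.
#' @export
validate_atlas <- function(atlas) {
  need <- c("node_id", "hemisphere", "network_label", "region_label")
  if (!all(need %in% names(atlas))) {
    stop("atlas must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  n <- nrow(atlas)
  if (n < 2) stop("atlas needs at least 2 parcels", call. = FALSE)
  if (!identical(as.integer(atlas$node_id), seq_len(n))) {
    stop("atlas node_id must be exactly 1..n in order", call. = FALSE)
  }
  if (!all(atlas$hemisphere %in% c("L", "R"))) {
    stop("hemisphere must be 'L' or 'R'", call. = FALSE)
  }
  class(atlas) <- unique(c("cd_atlas", class(tibble::as_tibble(atlas))))
  atlas
}

# default atlas for simulations: alternate hemispheres, no anatomical labels
default_atlas <- function(n, n_networks = 6) {
  atlas_table(
    node_id = seq_len(n),
    hemisphere = ifelse(seq_len(n) <= n / 2, "L", "R"),
    network_label = paste0("Net", ((seq_len(n) - 1L) %% n_networks) + 1L),
    region_label = sprintf("parcel_%03d", seq_len(n))
  )
}

#' Read or write an atlas metadata TSV
#'
#' The on-disk format is a TSV with columns `node_id`, `hemisphere`,
#' `network_label`, `region_label`.
#'
#' @param path File path.
#' @return `read_atlas()` returns a validated atlas tibble; `write_atlas()`
#'   returns `path` invisibly.
#' @export
read_atlas <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          node_id = readr::col_integer(),
                          .default = readr::col_character()
                        ))
  validate_atlas(tb)
}

#' @rdname read_atlas
#' @param atlas An atlas tibble.
#' @export
write_atlas <- function(atlas, path) {
  readr::write_tsv(validate_atlas(atlas), path)
  invisible(path)
}
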