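# File formats: TSV is the canonical dialect (tab-delimited, UTF-8, '.'
# decimal); CSV is accepted on read by file extension. Matrices are written
# with labels in the first column and resource labels as the header.

delim_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

dedupe_labels <- function(labels) {
  dup <- labels[duplicated(labels)]
  if (length(dup) == 0) return(labels)
  for (lab in unique(dup)) {
    idx <- which(labels == lab)
    labels[idx] <- paste0(lab, "_", seq_along(idx))
  }
  labels
}

#' Read and write labelled flux matrices
#'
#' `read_flux_matrix()` reads a TSV/CSV matrix whose first column holds
#' strain labels and whose header holds resource labels. Duplicate labels
#' (e.g. the same metabolite measured by several analytical methods) are
#' preserved by appending numeric suffixes (`X`, `X` becomes `X_1`, `X_2`).
#' Ragged rows, non-numeric cells or missing values raise a parse error with
#' the offending line.
#'
#' @param path File path (`.tsv`/`.txt` tab-delimited, `.csv`
#'   comma-delimited).
#' @return A numeric matrix with dimnames.
#' @export
read_flux_matrix <- function(path) {
  raw <- readr::read_delim(path, delim = delim_for(path),
                           col_types = readr::cols(.default = readr::col_character()),
                           name_repair = "minimal", progress = FALSE)
  if (ncol(raw) < 2) stop("flux matrix needs a label column and >= 1 data column",
                          call. = FALSE)
  labels <- dedupe_labels(as.character(raw[[1]]))
  resources <- dedupe_labels(names(raw)[-1])
  mat <- suppressWarnings(
    vapply(raw[-1], function(x) as.numeric(x), numeric(nrow(raw)))
  )
  mat <- matrix(mat, nrow = nrow(raw))
  bad <- which(is.na(mat) & !is.na(as.matrix(raw[-1])), arr.ind = TRUE)
  if (nrow(bad) > 0 || anyNA(mat)) {
    line <- if (nrow(bad) > 0) bad[1, 1] + 1 else which(rowSums(is.na(mat)) > 0)[1] + 1
    stop("non-numeric or missing cell in ", path, " at line ", line, call. = FALSE)
  }
  dimnames(mat) <- list(labels, resources)
  mat
}

#' @rdname read_flux_matrix
#' @param mat Numeric matrix with dimnames.
#' @param label Header name for the label column; default `"strain"`.
#' @export
write_flux_matrix <- function(mat, path, label = "strain") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE)
  names(df) <- c(label, colnames(mat))
  readr::write_delim(df, path, delim = delim_for(path), progress = FALSE)
  invisible(path)
}

#' Read a consumption/production matrix pair as a flux set
#'
#' @param consumption_path Path to the consumption matrix.
#' @param production_path Optional path to the total production matrix (zero
#'   if omitted).
#' @return A [flux_set()].
#' @export
read_flux_set <- function(consumption_path, production_path = NULL) {
  C <- read_flux_matrix(consumption_path)
  P <- if (is.null(production_path)) NULL else read_flux_matrix(production_path)
  if (!is.null(P)) {
    if (!identical(dim(P), dim(C))) {
      stop("consumption and production matrices must have the same shape",
           call. = FALSE)
    }
    dimnames(P) <- dimnames(C)
  }
  flux_set(C, P)
}

#' Read and write long-format abundance tables
#'
#' The long format has one row per (strain, passage, replicate) with columns
#' `strain`, `passage`, `replicate`, `abundance`. Negative abundances or
#' missing required columns raise an error.
#'
#' @param path File path (TSV canonical, CSV accepted).
#' @return A tibble with the four columns above.
#' @export
read_abundance_table <- function(path) {
  tbl <- readr::read_delim(path, delim = delim_for(path),
                           col_types = readr::cols(
                             strain = readr::col_character(),
                             passage = readr::col_integer(),
                             replicate = readr::col_integer(),
                             abundance = readr::col_double()
                           ), progress = FALSE)
  need <- c("strain", "passage", "replicate", "abundance")
  miss <- setdiff(need, names(tbl))
  if (length(miss) > 0) {
    stop("abundance table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(tbl$abundance)) {
    stop("non-numeric or missing abundance at line ",
         which(is.na(tbl$abundance))[1] + 1, call. = FALSE)
  }
  if (any(tbl$abundance < 0)) {
    stop("negative abundance at line ", which(tbl$abundance < 0)[1] + 1,
         call. = FALSE)
  }
  tbl[, need]
}

#' @rdname read_abundance_table
#' @param abundance Long abundance tibble.
#' @export
write_abundance_table <- function(abundance, path) {
  readr::write_delim(abundance, path, delim = delim_for(path), progress = FALSE)
  invisible(path)
}

#' Read and write named per-resource or per-strain value vectors
#'
#' Two-column tables (`id`, `value`), used for fitted resource
#' concentrations (mirroring a fitted-concentration table sorted by cluster)
#' and monoculture biomasses.
#'
#' @param path File path.
#' @param id Header name of the label column on write.
#' @return `read_named_vector()` returns a named numeric vector.
#' @export
read_named_vector <- function(path) {
  tbl <- readr::read_delim(path, delim = delim_for(path),
                           col_types = readr::cols(
                             readr::col_character(), readr::col_double()
                           ), progress = FALSE)
  setNames(tbl[[2]], tbl[[1]])
}

#' @rdname read_named_vector
#' @param x Named numeric vector.
#' @export
write_named_vector <- function(x, path, id = "id") {
  df <- data.frame(names(x), unname(x))
  names(df) <- c(id, "value")
  readr::write_delim(df, path, delim = delim_for(path), progress = FALSE)
  invisible(path)
}

#' Write an interaction network as edge-list TSV and GraphML
#'
#' @param network A `crm_network`.
#' @param edges_path Path for the edge-list TSV (`source`, `target`, `sign`,
#'   `weight`).
#' @param graphml_path Optional path for a GraphML export (via igraph).
#' @export
write_network <- function(network, edges_path, graphml_path = NULL) {
  readr::write_delim(network$edges, edges_path, delim = "\t", progress = FALSE)
  if (!is.null(graphml_path)) {
    igraph::write_graph(as_igraph(network), graphml_path, format = "graphml")
  }
  invisible(edges_path)
}

#' Write a metabolite cluster assignment table
#'
#' @param map A `cluster_map` from [cluster_metabolites()].
#' @param path Output TSV path; columns `metabolite`, `cluster_id`, `kind`,
#'   with dropped metabolites listed with cluster `"(dropped)"`.
#' @export
write_cluster_map <- function(map, path) {
  out <- tibble::tibble(metabolite = map$metabolite, cluster_id = map$cluster,
                        kind = map$kind)
  dropped <- attr(map, "dropped")
  if (length(dropped) > 0) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      metabolite = dropped, cluster_id = "(dropped)", kind = "dropped"
    ))
  }
  readr::write_delim(out, path, delim = "\t", progress = FALSE)
  invisible(path)
}

#' Write a provenance record for a pipeline run
#'
#' Records the subcommand and every parameter in effect (thresholds, floors,
#' seeds) as pretty-printed JSON so each output directory is
#' self-describing and byte-reproducible.
#'
#' @param params Named list of parameters.
#' @param path Output JSON path.
#' @export
write_provenance <- function(params, path) {
  jsonlite::write_json(params, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
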