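## Readers/writers: delimited text matrices and per-area tables, each with a
## JSON sidecar recording shape, modality and vertex ordering so files are
## self-describing.

#' Write a connectome (or plain matrix) as TSV with a JSON sidecar
#'
#' @param x a `connectome` or numeric matrix.
#' @param path output `.tsv` path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_connectome_matrix <- function(x, path) {
  W <- if (inherits(x, "connectome")) x$weights else x
  meta <- list(shape = dim(W),
               modality = if (inherits(x, "connectome")) x$modality else NULL,
               task_tag = if (inherits(x, "connectome")) x$task_tag else NULL,
               sparsified = if (inherits(x, "connectome")) x$sparsified else FALSE,
               vertex_ordering = "row-major, 1-based, hemispheres stacked left then right")
  write.table(format(W, digits = 17, trim = TRUE, scientific = TRUE),
              path, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' Read a matrix written by [write_connectome_matrix()]
#'
#' @param path the `.tsv` path.
#' @return a `connectome` when the sidecar declares a modality, else a
#'   matrix. Errors name the expected vs found shape.
#' @export
read_connectome_matrix <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  W <- as.matrix(read.table(path, sep = "\t", header = FALSE,
                            colClasses = "numeric"))
  dimnames(W) <- NULL
  if (!all(dim(W) == meta$shape)) {
    stop_fmt("matrix in %s has shape %dx%d, sidecar declares %dx%d",
             path, nrow(W), ncol(W), meta$shape[1], meta$shape[2])
  }
  if (!is.null(meta$modality)) {
    connectome(W, meta$modality, task_tag = meta$task_tag,
               sparsified = isTRUE(meta$sparsified))
  } else {
    W
  }
}

#' Write a per-area table
#' @param df data.frame with an `area` column.
#' @param path output `.tsv` path.
#' @return `path`, invisibly.
#' @export
write_area_table <- function(df, path) {
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

## Stable hash of an R object via its canonical JSON serialization (used for
## provenance; tools::md5sum operates on files).
config_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  unname(tools::md5sum(tmp))
}
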