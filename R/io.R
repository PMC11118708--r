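# Plain-text file formats: cell tables and matrices as CSV (full float
# precision), structured results as JSON. Pixel coordinates are 0-based in
# files and 1-based in memory.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a labeled-cell table to CSV
#'
#' Columns `cell_id`, `x_px`, `y_px` (0-based in the file), `po_deg`,
#' `injection_id`; numeric values at 17 significant digits so round-trips
#' are lossless.
#'
#' @param cells a `cell_set` data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  need <- c("cell_id", "x_px", "y_px", "po_deg", "injection_id")
  miss <- setdiff(need, names(cells))
  if (length(miss)) {
    stop(sprintf("cell table missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(
    cell_id = cells$cell_id,
    x_px = fmt_num(cells$x_px - 1),
    y_px = fmt_num(cells$y_px - 1),
    po_deg = fmt_num(cells$po_deg),
    injection_id = cells$injection_id
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a labeled-cell table from CSV
#'
#' @param path CSV path written by [write_cell_table()].
#' @return `cell_set` data.frame with 1-based pixel coordinates.
#' @export
read_cell_table <- function(path) {
  df <- utils::read.csv(path)
  need <- c("cell_id", "x_px", "y_px", "po_deg", "injection_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("cell table %s missing column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  df$x_px <- df$x_px + 1
  df$y_px <- df$y_px + 1
  class(df) <- c("cell_set", "data.frame")
  df
}

#' Write a numeric matrix to CSV at full precision
#'
#' @param m numeric matrix.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  txt <- apply(m, 1, function(r) paste(fmt_num(r), collapse = ","))
  writeLines(txt, path)
  invisible(path)
}

#' Read a numeric matrix from CSV
#'
#' @param path path written by [write_matrix_csv()].
#' @return numeric matrix.
#' @export
read_matrix_csv <- function(path) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  m
}

#' Write an orientation map set as plain text
#'
#' One CSV matrix per orientation plane plus a JSON sidecar with the
#' orientations, dimensions, vessel mask (as 0/1 CSV) and optional ground
#' truth.
#'
#' @param maps an [orientation_map_set()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_map_set <- function(maps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(maps$orientations)) {
    write_matrix_csv(maps$responses[, , k],
                     file.path(dir, sprintf("map_%02d.csv", k)))
  }
  write_matrix_csv(maps$vessel_mask * 1, file.path(dir, "vessel_mask.csv"))
  if (!is.null(maps$po_true)) {
    write_matrix_csv(maps$po_true, file.path(dir, "po_true.csv"))
  }
  meta <- list(orientations = maps$orientations,
               height = dim(maps$responses)[1],
               width = dim(maps$responses)[2],
               has_truth = !is.null(maps$po_true))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an orientation map set written by [write_map_set()]
#'
#' @param dir directory path.
#' @return an [orientation_map_set()].
#' @export
read_map_set <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  responses <- array(NA_real_, c(meta$height, meta$width,
                                 length(meta$orientations)))
  for (k in seq_along(meta$orientations)) {
    responses[, , k] <- read_matrix_csv(
      file.path(dir, sprintf("map_%02d.csv", k)))
  }
  vessel <- read_matrix_csv(file.path(dir, "vessel_mask.csv")) > 0
  po_true <- if (isTRUE(meta$has_truth)) {
    read_matrix_csv(file.path(dir, "po_true.csv"))
  }
  orientation_map_set(responses, meta$orientations, vessel, po_true)
}

#' Write structured results as JSON
#'
#' @param x list of results (numbers written at full precision).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_results <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
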