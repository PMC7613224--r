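#' Read a spectrum from a two-column text file
#'
#' Accepts CSV (`ppm,intensity` header optional) or whitespace-delimited
#' two-column text.
#'
#' @param path File path.
#' @param sample_id Sample identifier (default: file name without
#'   extension).
#' @return An [new_spectrum()] object.
#' @export
read_spectrum <- function(path, sample_id = NULL) {
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  header <- grepl("[A-Za-z]", first)
  d <- utils::read.table(path, header = header, sep = sep)
  new_spectrum(d[[1]], d[[2]], sample_id = sample_id)
}

#' Write a spectrum as a ppm,intensity CSV
#'
#' @param s An [new_spectrum()] object.
#' @param path Output path.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "nmr_spectrum"))
  utils::write.csv(data.frame(ppm = s$ppm, intensity = s$intensity),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a bucket table as CSV (bucket centers as header)
#'
#' @param t A `bucket_table`.
#' @param path Output path; a sidecar `<path>.json` records bucket width,
#'   exclusions and labels.
#' @export
write_bucket_table <- function(t, path) {
  stopifnot(inherits(t, "bucket_table"))
  d <- as.data.frame(t$matrix)
  names(d) <- sprintf("%.3f", t$bucket_centers)
  d <- cbind(sample_id = t$sample_ids, d)
  utils::write.csv(d, path, row.names = FALSE)
  jsonlite::write_json(
    list(bucket_width = t$bucket_width,
         excluded_regions = t$excluded_regions,
         labels = t$labels),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a bucket table written by [write_bucket_table()]
#'
#' @param path CSV path (sidecar JSON expected alongside).
#' @return A `bucket_table`.
#' @export
read_bucket_table <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  mat <- as.matrix(d[, -1, drop = FALSE])
  rownames(mat) <- d$sample_id
  structure(list(matrix = mat,
                 bucket_centers = as.numeric(colnames(mat)),
                 bucket_width = side$bucket_width,
                 sample_ids = d$sample_id,
                 labels = if (length(side$labels)) side$labels else NULL,
                 excluded_regions = side$excluded_regions),
            class = "bucket_table")
}
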