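# File formats: CSV for all tabular data (diffable, round-trips exactly at
# full double precision), JSON for nested reports and parameter sidecars,
# single-channel TIFF for images (16-bit) and masks (8-bit).

#' Read and write profile tables
#'
#' Long-format CSV with columns `cell_id`, `k`, `arc_position`,
#' `grey_value`, one block of rows per cell. This is the interchange format
#' between simulation/extraction and batch scoring.
#'
#' @param profiles Data frame with those columns, or a single
#'   [intensity_profile()] (written with `cell_id = "cell1"`).
#' @param path File path.
#' @return `read_profiles_csv()` returns a tibble; the writer returns
#'   `path` invisibly.
#' @export
write_profiles_csv <- function(profiles, path) {
  if (is_profile(profiles)) {
    profiles <- dplyr::mutate(as_tibble(profiles), cell_id = "cell1",
      .before = 1)
  }
  stopifnot(all(c("cell_id", "k", "grey_value") %in% names(profiles)))
  if (!"arc_position" %in% names(profiles)) profiles$arc_position <- profiles$k
  readr::write_csv(
    profiles[, c("cell_id", "k", "arc_position", "grey_value")], path)
  invisible(path)
}

#' @rdname write_profiles_csv
#' @export
read_profiles_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(c("cell_id", "k", "grey_value"), names(df))
  if (length(missing) > 0) {
    abort(paste0("profiles CSV lacks column(s): ",
      paste(missing, collapse = ", ")), class = "crescentr_error")
  }
  df$cell_id <- as.character(df$cell_id)
  df
}

#' Read a cell outline from CSV
#'
#' Expects a header `x,y` and 0-based subpixel image coordinates
#' (y increasing downward), one vertex per row, implicitly closed.
#'
#' @param path File path.
#' @return A `cell_outline` tibble.
#' @export
read_outline_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("x", "y") %in% names(df))) {
    abort("outline CSV must have columns x and y", class = "crescentr_error")
  }
  if (nrow(df) < 3) {
    abort("outline CSV needs at least 3 vertices", class = "crescentr_error")
  }
  structure(tibble(x = as.numeric(df$x), y = as.numeric(df$y)),
    class = c("cell_outline", class(tibble())))
}

#' Read and write division record tables
#'
#' CSV with columns `cell_id`, `intensity_a`, `intensity_b`, `axis_dx`,
#' `axis_dy`, `ap_dx`, `ap_dy`; the short aliases `i_a`, `i_b`, `ax_dx`,
#' `ax_dy` are accepted on read.
#'
#' @param records Division record data frame (a `profile` list column, if
#'   present, is dropped on write).
#' @param path File path.
#' @return `read_divisions_csv()` returns a tibble; the writer returns
#'   `path` invisibly.
#' @export
write_divisions_csv <- function(records, path) {
  cols <- c("cell_id", "intensity_a", "intensity_b", "axis_dx", "axis_dy",
    "ap_dx", "ap_dy")
  stopifnot(all(cols %in% names(records)))
  readr::write_csv(as_tibble(records)[, cols], path)
  invisible(path)
}

#' @rdname write_divisions_csv
#' @export
read_divisions_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  aliases <- c(i_a = "intensity_a", i_b = "intensity_b",
    ax_dx = "axis_dx", ax_dy = "axis_dy")
  for (short in names(aliases)) {
    if (short %in% names(df) && !aliases[[short]] %in% names(df)) {
      names(df)[names(df) == short] <- aliases[[short]]
    }
  }
  needed <- c("intensity_a", "intensity_b", "axis_dx", "axis_dy")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    abort(paste0("divisions CSV lacks column(s): ",
      paste(missing, collapse = ", ")), class = "crescentr_error")
  }
  df
}

#' Read and write contingency tables
#'
#' CSV with defect categories as column headers and genotypes in the first
#' column.
#'
#' @param counts Integer matrix with row and column names.
#' @param path File path.
#' @return `read_contingency_csv()` returns an integer matrix; the writer
#'   returns `path` invisibly.
#' @export
write_contingency_csv <- function(counts, path) {
  counts <- as.matrix(counts)
  df <- data.frame(genotype = rownames(counts) %||%
    paste0("group", seq_len(nrow(counts))), counts, check.names = FALSE)
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_contingency_csv
#' @export
read_contingency_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "integer"
  m
}

#' Read and write single-channel TIFF images
#'
#' Images are written as 16-bit single-channel TIFF (grey values 0..65535)
#' and masks as 8-bit TIFF; reading returns the matrix back on the grey
#' value scale (rows = y).
#'
#' @param image Numeric matrix of grey values in \[0, 65535\].
#' @param mask Logical/0-1 matrix.
#' @param path File path.
#' @return Readers return a numeric matrix (grey values) or logical matrix
#'   (mask); writers return `path` invisibly.
#' @export
write_image_tiff <- function(image, path) {
  stopifnot(is.matrix(image))
  if (any(image < 0) || any(image > 65535)) {
    abort("grey values must lie in [0, 65535] for 16-bit TIFF output",
      class = "crescentr_error")
  }
  tiff::writeTIFF(round(image) / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img * 65535
}

#' @rdname write_image_tiff
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF(mask_matrix(mask), path, bits.per.sample = 8)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_mask_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0.5
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
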