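#' @name nuclei_io
#' @title Nuclei table input/output
#' @description
#' Per-patch nuclei tables are the interface between upstream nuclei
#' segmentation/classification (which reports, for every nucleus, its
#' centroid, cell type, orientation, prediction confidence and ten
#' morphology features) and graph construction.  One delimited text file
#' (comma or tab) holds one image patch; a manifest table groups patches
#' into slides and patients.
#'
#' Canonical columns, in order:
#' `nucleus_id, x, y, cell_type, orientation, confidence, area, convex_area,
#' eccentricity, extent, filled_area, major_axis_length, minor_axis_length,
#' perimeter_sq_over_area, perimeter, solidity`.
#'
#' Coordinates are 0-based pixels (x rightward, y downward).  Orientation is
#' the angle between the image x-axis and the nuclear major axis; it is an
#' axial quantity and is stored in radians in `[-pi/2, pi/2)`.
NULL

# the 11 model node features, canonical order (confidence + 10 morphology)
NODE_FEATURES <- c(
  "confidence", "area", "convex_area", "eccentricity", "extent",
  "filled_area", "major_axis_length", "minor_axis_length",
  "perimeter_sq_over_area", "perimeter", "solidity"
)

NUCLEI_COLUMNS <- c("nucleus_id", "x", "y", "cell_type", "orientation",
                    NODE_FEATURES)

#' Canonical node feature names
#'
#' The 11 per-nucleus features the network consumes: detection confidence
#' plus the 10 morphology features, in canonical column order.
#' @return Character vector of length 11.
#' @export
node_feature_names <- function() NODE_FEATURES

# wrap an axial angle into [-pi/2, pi/2)
wrap_axial <- function(theta) {
  ((theta + pi / 2) %% pi) - pi / 2
}

# validate a nuclei data.frame in place; returns it with canonical types.
validate_nuclei <- function(df, scheme) {
  missing_cols <- setdiff(setdiff(NUCLEI_COLUMNS, "nucleus_id"), names(df))
  if (length(missing_cols) > 0L) {
    stop("nuclei table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  n <- nrow(df)
  if (is.null(df$nucleus_id)) df$nucleus_id <- seq_len(n) - 1L

  # cell types: case-insensitive match against scheme labels
  ct <- tolower(trimws(as.character(df$cell_type)))
  idx <- match(ct, tolower(scheme$labels))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop(sprintf("unknown cell type '%s' at row %d (scheme '%s')",
                 df$cell_type[bad], bad, scheme$name))
  }
  df$cell_type <- scheme$labels[idx]

  num_cols <- setdiff(NUCLEI_COLUMNS, c("nucleus_id", "cell_type"))
  for (cl in num_cols) {
    v <- as.numeric(df[[cl]])
    if (anyNA(v) || any(!is.finite(v))) {
      bad <- which(!is.finite(v))[1L]
      stop(sprintf("non-finite value in column '%s' at row %d", cl, bad))
    }
    df[[cl]] <- v
  }

  chk <- function(ok, what) {
    if (!all(ok)) {
      stop(sprintf("%s violated at row %d", what, which(!ok)[1L]))
    }
  }
  chk(df$area > 0, "area > 0")
  chk(df$minor_axis_length > 0, "minor_axis_length > 0")
  chk(df$major_axis_length >= df$minor_axis_length,
      "major_axis_length >= minor_axis_length")
  chk(df$convex_area >= df$area * (1 - 1e-9), "convex_area >= area")
  chk(df$eccentricity >= 0 & df$eccentricity < 1, "eccentricity in [0, 1)")
  chk(df$solidity > 0 & df$solidity <= 1, "solidity in (0, 1]")
  chk(df$extent > 0 & df$extent <= 1, "extent in (0, 1]")
  chk(df$confidence > 0 & df$confidence <= 1, "confidence in (0, 1]")
  rel <- abs(df$perimeter_sq_over_area - df$perimeter^2 / df$area) /
    pmax(df$perimeter_sq_over_area, .Machine$double.eps)
  chk(rel <= 1e-6, "perimeter_sq_over_area = perimeter^2 / area")

  df$orientation <- wrap_axial(df$orientation)
  df <- df[, NUCLEI_COLUMNS]
  rownames(df) <- NULL
  attr(df, "scheme") <- scheme
  class(df) <- c("nuclei_table", "data.frame")
  df
}

#' Read a per-patch nuclei table
#'
#' Reads a delimited text file (comma or tab, auto-detected from the header
#' line), validates it against the canonical schema and a cell type scheme,
#' and normalizes orientation into `[-pi/2, pi/2)` radians.
#'
#' @param path Path to the file.
#' @param scheme A [cell_type_scheme()]; `cell_type` values must match its
#'   labels (case-insensitively).
#' @param degrees If `TRUE`, the `orientation` column is interpreted as
#'   degrees and converted to radians before wrapping.
#' @return A validated `nuclei_table` data.frame with the canonical columns;
#'   row order preserved; `nucleus_id` assigned 0-based by row if absent.
#' @export
read_nuclei_table <- function(path, scheme, degrees = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = TRUE)
  if (degrees) df$orientation <- df$orientation * pi / 180
  validate_nuclei(df, scheme)
}

#' Write a nuclei table
#'
#' Writes the canonical delimited format with full numeric precision so
#' that a read/write round trip is the identity on validated records.
#'
#' @param nuclei A validated `nuclei_table`.
#' @param path Output path.
#' @param sep Field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_nuclei_table <- function(nuclei, path, sep = ",") {
  df <- as.data.frame(nuclei)
  num <- vapply(df, is.numeric, logical(1))
  for (cl in names(df)[num]) df[[cl]] <- sprintf("%.17g", df[[cl]])
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Patch informativeness filter
#'
#' A patch is kept for a task only if it holds enough nuclei of the types
#' the task cares about: at least 20 tumor cells for histology
#' classification, at least 50 epithelial nuclei for the risk task.
#'
#' @param nuclei A `nuclei_table` (or data.frame with a `cell_type` column).
#' @param counted_labels Labels whose nuclei are counted.
#' @param min_count Minimum count (inclusive); `>= 0`.
#' @param scheme Optional scheme used to check that `counted_labels` are
#'   valid; defaults to the scheme attached to `nuclei`.
#' @return `TRUE` iff the number of nuclei with type in `counted_labels` is
#'   at least `min_count`.
#' @export
filter_patch <- function(nuclei, counted_labels, min_count,
                         scheme = attr(nuclei, "scheme")) {
  stopifnot(min_count >= 0)
  if (!is.null(scheme)) {
    bad <- setdiff(counted_labels, scheme$labels)
    if (length(bad) > 0L) {
      stop("counted_labels not in scheme: ", paste(bad, collapse = ", "))
    }
  }
  sum(nuclei$cell_type %in% counted_labels) >= min_count
}

#' Read / write a patch manifest
#'
#' The manifest is a tab-separated table with columns `patch_id, slide_id,
#' patient_id, label, path` (and optionally `split` and `orientation_unit`)
#' that groups per-patch nuclei tables into slides and patients.
#'
#' @param path Manifest file path.
#' @return `read_manifest`: a data.frame. `write_manifest`: `path`,
#'   invisibly.
#' @export
read_manifest <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("patch_id", "slide_id", "patient_id", "label", "path")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("manifest missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df
}

#' @rdname read_manifest
#' @param manifest Data.frame to write.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
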