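#' Cell type schemes
#'
#' A cell type scheme names the ordered set of cell type labels a nuclei
#' segmentation model emits, together with the subset of labels over which
#' subgroup mean pooling averages node outputs.
#'
#' @param name Short scheme name.
#' @param labels Character vector of unique cell type labels, ordered.  The
#'   position of a label in this vector is its 0-based type index, used when
#'   encoding categorical edge types.
#' @param pooled_labels Subset of `labels` averaged by subgroup mean pooling
#'   (e.g. tumor nuclei only).
#' @return An object of class `cell_type_scheme`.
#' @examples
#' cell_type_scheme("toy", c("a", "b"), "a")
#' @export
cell_type_scheme <- function(name, labels, pooled_labels = labels) {
  stopifnot(is.character(name), length(name) == 1L)
  labels <- as.character(labels)
  if (length(labels) < 1L) stop("a scheme needs at least one label")
  if (anyDuplicated(labels)) stop("scheme labels must be unique")
  pooled_labels <- as.character(pooled_labels)
  bad <- setdiff(pooled_labels, labels)
  if (length(bad) > 0L) {
    stop("pooled_labels not in scheme labels: ", paste(bad, collapse = ", "))
  }
  structure(
    list(name = name, labels = labels, pooled_labels = pooled_labels),
    class = "cell_type_scheme"
  )
}

#' @export
print.cell_type_scheme <- function(x, ...) {
  cat("<cell_type_scheme>", x$name, "\n")
  cat("  labels:", paste(x$labels, collapse = ", "), "\n")
  cat("  pooled:", paste(x$pooled_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Built-in scheme: lung cancer microenvironment
#'
#' Six cell types (tumor, stroma, lymphocyte, red blood cell, macrophage,
#' karyorrhexis); subgroup pooling focuses on tumor nuclei.  The 6x6 = 36
#' ordered type pairs define the categorical edge types.
#'
#' @return A `cell_type_scheme`.
#' @export
lung_scheme <- function() {
  cell_type_scheme(
    "lung",
    labels = c("tumor", "stroma", "lymphocyte", "red_blood_cell",
               "macrophage", "karyorrhexis"),
    pooled_labels = "tumor"
  )
}

#' Built-in scheme: oral epithelium
#'
#' Four cell types; subgroup pooling averages over the three epithelial
#' strata (everything except non-epithelium).  4x4 = 16 edge types.
#'
#' @return A `cell_type_scheme`.
#' @export
oral_scheme <- function() {
  cell_type_scheme(
    "oral",
    labels = c("stratum_corneum", "stratum_basale", "other_strata",
               "non_epithelium"),
    pooled_labels = c("stratum_corneum", "stratum_basale", "other_strata")
  )
}

#' Number of cell types in a scheme
#' @param scheme A `cell_type_scheme`.
#' @return Integer count of labels.
#' @export
n_types <- function(scheme) length(scheme$labels)

# internal: 0-based type index for a label vector
type_index <- function(labels, scheme) {
  idx <- match(labels, scheme$labels)
  if (anyNA(idx)) {
    stop("unknown cell type(s): ",
         paste(unique(labels[is.na(idx)]), collapse = ", "))
  }
  idx - 1L
}
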