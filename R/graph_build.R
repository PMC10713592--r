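#' @name graph_build
#' @title Cell spatial graph construction
#' @description
#' Turns a validated nuclei table into a directed k-nearest-neighbour cell
#' spatial graph.  Each nucleus is a node carrying 11 globally standardized
#' features (confidence + 10 morphology); each node points to its k nearest
#' other nuclei by Euclidean centroid distance.  Every edge carries three
#' features: a categorical edge type (the ordered pair of cell types, T^2
#' categories for T types), nuclear parallelism (|cos| of the angle between
#' the two major axes, in [0,1]) and nuclear closeness (reciprocal of the
#' edge length in pixels).
NULL

#' Fit a global node feature scaler
#'
#' Node features are globally centered and scaled: means and population
#' standard deviations (divisor N) are computed over all nuclei pooled
#' across the training graphs, then frozen and reused for validation and
#' test data.
#'
#' @param nuclei A `nuclei_table` (or an rbind of several) pooling all
#'   training nuclei; at least two rows.
#' @return A `feature_scaler` with `feature_names`, `means`, `sds`.
#' @export
fit_scaler <- function(nuclei) {
  X <- as.matrix(as.data.frame(nuclei)[, NODE_FEATURES])
  if (nrow(X) < 2L) stop("need at least 2 nuclei to fit a scaler")
  means <- colMeans(X)
  sds <- sqrt(colMeans(sweep(X, 2, means)^2))  # population sd
  if (any(sds <= 0)) {
    stop("constant feature(s): ",
         paste(NODE_FEATURES[sds <= 0], collapse = ", "))
  }
  structure(list(feature_names = NODE_FEATURES, means = means, sds = sds),
            class = "feature_scaler")
}

#' Apply a fitted scaler
#' @param scaler A `feature_scaler`.
#' @param nuclei A `nuclei_table`.
#' @return N x 11 matrix of standardized feature values.
#' @export
scale_features <- function(scaler, nuclei) {
  X <- as.matrix(as.data.frame(nuclei)[, scaler$feature_names])
  sweep(sweep(X, 2, scaler$means), 2, scaler$sds, "/")
}

#' Directed kNN edges
#'
#' For every node, edges point to its `min(k, N - 1)` nearest other nodes
#' by Euclidean distance.  Distance ties are broken by ascending node
#' index.  Duplicate centroids are an error (closeness, 1/distance, would
#' be infinite).
#'
#' @param centroids N x 2 matrix of pixel coordinates, N >= 2.
#' @param k Number of neighbours, >= 1.
#' @return Integer matrix with columns `src`, `dst` (1-based node indices),
#'   ordered by source node, then by neighbour rank.
#' @export
knn_edges <- function(centroids, k) {
  centroids <- as.matrix(centroids)
  n <- nrow(centroids)
  stopifnot(n >= 2L, k >= 1L)
  d <- as.matrix(stats::dist(centroids))
  diag(d) <- Inf
  if (any(d == 0)) {
    w <- which(d == 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("duplicate centroid coordinates (nodes %d and %d)",
                 w[2L], w[1L]))
  }
  kk <- min(k, n - 1L)
  idx <- seq_len(n)
  src <- rep(idx, each = kk)
  dst <- integer(n * kk)
  for (i in idx) {
    # order() is stable: ties resolve to the lower node index
    dst[((i - 1L) * kk + 1L):(i * kk)] <- order(d[i, ])[seq_len(kk)]
  }
  cbind(src = src, dst = dst)
}

#' Nuclear parallelism
#'
#' Structural concordance between two nuclei: the absolute cosine of the
#' angle between their major axes.  1 means parallel axes, 0 perpendicular.
#' Because orientations are axial, the value is invariant to adding pi to
#' either angle.
#'
#' @param theta_n,theta_m Orientations in radians.
#' @return Value(s) in `[0, 1]`; vectorized.
#' @export
parallelism <- function(theta_n, theta_m) {
  stopifnot(all(is.finite(theta_n)), all(is.finite(theta_m)))
  abs(cos(theta_n - theta_m))
}

#' Nuclear closeness
#'
#' Interaction strength between two nuclei: the reciprocal of the Euclidean
#' distance between their centroids, in 1/pixels.
#'
#' @param p_n,p_m Points as length-2 vectors, or matrices of row points.
#' @return Closeness value(s), > 0.
#' @export
closeness <- function(p_n, p_m) {
  p_n <- rbind(p_n); p_m <- rbind(p_m)
  d <- sqrt(rowSums((p_n - p_m)^2))
  if (any(d == 0)) stop("coincident centroids: closeness undefined")
  as.vector(1 / d)
}

#' Categorical edge type index
#'
#' Encodes the ordered pair (source cell type, target cell type) as a
#' single integer in `[0, T^2)` using the row-major convention
#' `source * T + target`, so that T cell types yield exactly T^2 distinct
#' edge types (36 for the lung scheme, 16 for the oral scheme).
#'
#' @param source_type,target_type 0-based type indices in `[0, T)`.
#' @param T_types Number of cell types T.
#' @return Integer edge type(s) in `[0, T^2)`; vectorized.
#' @export
edge_type_index <- function(source_type, target_type, T_types) {
  if (any(source_type < 0 | source_type >= T_types) ||
      any(target_type < 0 | target_type >= T_types)) {
    stop("type index out of range [0, T)")
  }
  as.integer(source_type) * as.integer(T_types) + as.integer(target_type)
}

#' Build a cell spatial graph from a nuclei table
#'
#' @param nuclei A validated `nuclei_table`.
#' @param scheme The `cell_type_scheme` (defaults to the one attached to
#'   `nuclei`).
#' @param scaler A `feature_scaler` fitted on training nuclei.
#' @param k Neighbour count; 8 covers the adjacent neighbours of a nucleus.
#' @param meta Named list with `patch_id`, `slide_id`, `patient_id`,
#'   `label` (any may be `NA`).
#' @return A `cell_graph`: list with `n` (nodes), `X` (N x 11 standardized
#'   features), `node_types` (0-based integer types), `edges` (e x 2,
#'   1-based src/dst), `edge_type` (0-based, in `[0, T^2)`), `parallelism`,
#'   `closeness`, `scheme`, `meta`.
#' @export
build_graph <- function(nuclei, scheme = attr(nuclei, "scheme"), scaler, k = 8,
                        meta = list(patch_id = NA, slide_id = NA,
                                    patient_id = NA, label = NA)) {
  stopifnot(inherits(scaler, "feature_scaler"))
  df <- as.data.frame(nuclei)
  X <- scale_features(scaler, nuclei)
  types <- type_index(df$cell_type, scheme)
  edges <- knn_edges(cbind(df$x, df$y), k)
  src <- edges[, 1L]; dst <- edges[, 2L]
  tt <- edge_type_index(types[src], types[dst], n_types(scheme))
  a <- parallelism(df$orientation[src], df$orientation[dst])
  w <- closeness(cbind(df$x[src], df$y[src]), cbind(df$x[dst], df$y[dst]))
  structure(
    list(n = nrow(df), X = unname(X), node_types = types, edges = edges,
         edge_type = tt, parallelism = unname(a), closeness = unname(w),
         scheme = scheme, meta = meta),
    class = "cell_graph"
  )
}

#' @export
print.cell_graph <- function(x, ...) {
  cat(sprintf("<cell_graph> %d nodes, %d edges (scheme '%s')\n",
              x$n, nrow(x$edges), x$scheme$name))
  if (!is.null(x$meta$patch_id) && !is.na(x$meta$patch_id)) {
    cat(sprintf("  patch %s | slide %s | patient %s | label %s\n",
                x$meta$patch_id, x$meta$slide_id, x$meta$patient_id,
                x$meta$label))
  }
  invisible(x)
}

#' Merge all graphs from one slide into a single disconnected graph
#'
#' For slide-level prediction every patch graph from one slide is embedded
#' in one disconnected union graph: node ids are offset per component and
#' no cross-component edges are added.
#'
#' @param graphs List of `cell_graph` objects sharing one scheme.
#' @return A `cell_graph`; its `meta` carries the slide id (label/patient
#'   taken from the first graph).
#' @export
merge_slide_graphs <- function(graphs) {
  stopifnot(length(graphs) >= 1L)
  schemes <- unique(vapply(graphs, function(g) g$scheme$name, character(1)))
  if (length(schemes) != 1L) {
    stop("cannot merge graphs with mixed schemes: ",
         paste(schemes, collapse = ", "))
  }
  if (length(graphs) == 1L) return(graphs[[1L]])
  offs <- cumsum(c(0L, vapply(graphs, `[[`, integer(1), "n")))
  g1 <- graphs[[1L]]
  structure(
    list(
      n = offs[length(offs)],
      X = do.call(rbind, lapply(graphs, `[[`, "X")),
      node_types = unlist(lapply(graphs, `[[`, "node_types")),
      edges = do.call(rbind, Map(function(g, o) g$edges + o, graphs,
                                 offs[-length(offs)])),
      edge_type = unlist(lapply(graphs, `[[`, "edge_type")),
      parallelism = unlist(lapply(graphs, `[[`, "parallelism")),
      closeness = unlist(lapply(graphs, `[[`, "closeness")),
      scheme = g1$scheme,
      meta = list(patch_id = NA, slide_id = g1$meta$slide_id,
                  patient_id = g1$meta$patient_id, label = g1$meta$label)
    ),
    class = "cell_graph"
  )
}

#' Save / load a graph bundle
#'
#' A graph bundle is a self-describing JSON container holding the graph
#' matrices, metadata and (optionally) the scaler used to standardize the
#' node features.
#'
#' @param graph A `cell_graph`.
#' @param path Output path (`.json`).
#' @param scaler Optional `feature_scaler` to store alongside.
#' @return `path` invisibly; `read_graph_bundle` returns a `cell_graph`
#'   (with the scaler, if stored, in attribute `"scaler"`).
#' @export
write_graph_bundle <- function(graph, path, scaler = NULL) {
  obj <- list(
    format = "cellgraphnet/graph", version = 1L,
    n = graph$n, X = graph$X, node_types = graph$node_types,
    edges = graph$edges, edge_type = graph$edge_type,
    parallelism = graph$parallelism, closeness = graph$closeness,
    scheme = unclass(graph$scheme), meta = graph$meta
  )
  if (!is.null(scaler)) obj$scaler <- unclass(scaler)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_graph_bundle
#' @export
read_graph_bundle <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (is.null(obj$format) || obj$format != "cellgraphnet/graph") {
    stop("not a graph bundle: ", path)
  }
  scheme <- cell_type_scheme(obj$scheme$name, obj$scheme$labels,
                             obj$scheme$pooled_labels)
  g <- structure(
    list(n = as.integer(obj$n), X = matrix(obj$X, nrow = obj$n),
         node_types = as.integer(obj$node_types),
         edges = cbind(src = as.integer(obj$edges[, 1L]),
                       dst = as.integer(obj$edges[, 2L])),
         edge_type = as.integer(obj$edge_type),
         parallelism = as.numeric(obj$parallelism),
         closeness = as.numeric(obj$closeness),
         scheme = scheme, meta = as.list(obj$meta)),
    class = "cell_graph"
  )
  if (!is.null(obj$scaler)) {
    attr(g, "scaler") <- structure(
      list(feature_names = obj$scaler$feature_names,
           means = stats::setNames(as.numeric(obj$scaler$means),
                                   obj$scaler$feature_names),
           sds = stats::setNames(as.numeric(obj$scaler$sds),
                                 obj$scaler$feature_names)),
      class = "feature_scaler")
  }
  g
}
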