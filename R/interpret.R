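#' @name interpret
#' @title Gradient-based model interpretation
#' @description
#' Because graph-level supervision acts as weak supervision at the nucleus
#' level, per-nucleus class probabilities (softmax of each pooled node's
#' final-layer logits) localize which cells drive the graph prediction.
#' Feature-level attribution takes the partial derivative of a
#' cross-entropy objective — the graph probabilities scored against a
#' presumptive category k — with respect to every derivable input feature:
#' the 11 standardized node features of every nucleus and the closeness and
#' parallelism of every edge.  The categorical edge type is not derivable
#' and is not attributed.
#'
#' Sign convention: a positive partial derivative means increasing the
#' feature increases the loss, i.e. the feature works *against* category k.
NULL

#' Per-nucleus and graph-level class probabilities
#'
#' @param model A `cellgraph_net`.
#' @param graph A `cell_graph`.
#' @return List with `node_probabilities` (N x K; rows of nuclei outside
#'   the pooled subset are `NA`), `graph_probabilities` (length K), and
#'   `pooled_mask`.
#' @export
node_contributions <- function(model, graph) {
  fwd <- forward(model, graph, training = FALSE)
  P <- matrix(NA_real_, graph$n, model$config$K)
  if (any(fwd$pooled_mask)) {
    P[fwd$pooled_mask, ] <- t(apply(
      fwd$node_logits[fwd$pooled_mask, , drop = FALSE], 1, softmax))
  }
  colnames(P) <- model$config$classes
  list(node_probabilities = P,
       graph_probabilities = stats::setNames(fwd$probabilities,
                                             model$config$classes),
       pooled_mask = fwd$pooled_mask)
}

#' Feature-level contribution map
#'
#' Computes, in one backward pass, the partial derivative of the
#' cross-entropy loss `L = CE(P_graph, k)` with respect to each node
#' feature of every nucleus (on the standardized scale the model sees) and
#' with respect to closeness and parallelism of every edge.  Dropout is
#' disabled so gradients are deterministic.
#'
#' @param model A `cellgraph_net`.
#' @param graph A `cell_graph`.
#' @param k Presumptive category: 1-based class index, or a class name.
#' @return A `contribution_map`: list with `node_probabilities` (N x K,
#'   `NA` rows for non-pooled nuclei), `node_feature_contributions`
#'   (N x 11, named columns), `edge_feature_contributions` (e x 2 matrix,
#'   columns `closeness` and `parallelism`), `k`, `loss`,
#'   `graph_probabilities`.
#' @export
feature_contributions <- function(model, graph, k) {
  cfg <- model$config
  if (is.character(k)) {
    kk <- match(k, cfg$classes)
    if (is.na(kk)) stop("unknown class: ", k)
    k <- kk
  }
  if (k < 1L || k > cfg$K) stop("presumptive category out of range")
  res <- graph_loss_grads(model, graph, label_idx = k, training = FALSE)
  nodeP <- matrix(NA_real_, graph$n, cfg$K)
  if (any(res$fwd$pooled_mask)) {
    nodeP[res$fwd$pooled_mask, ] <- t(apply(
      res$fwd$node_logits[res$fwd$pooled_mask, , drop = FALSE], 1, softmax))
  }
  colnames(nodeP) <- cfg$classes
  nf <- res$dX
  if (ncol(nf) == length(node_feature_names())) {
    colnames(nf) <- node_feature_names()
  }
  structure(
    list(node_probabilities = nodeP,
         node_feature_contributions = nf,
         edge_feature_contributions = cbind(closeness = res$dw,
                                            parallelism = res$da),
         k = k, loss = res$loss,
         graph_probabilities = stats::setNames(res$fwd$probabilities,
                                               cfg$classes)),
    class = "contribution_map"
  )
}

#' Summarize contribution maps across graphs
#'
#' Pools per-cell and per-edge contributions from many graphs into a long
#' table grouped by cell type (node features) or by edge type (edge
#' features), the form used for dataset-wide contribution boxplots.  Node
#' feature contributions are reported both on the standardized scale the
#' model sees and on the raw feature scale (chain rule: divided by the
#' scaler standard deviation).
#'
#' @param maps List of `contribution_map` objects.
#' @param graphs The matching list of `cell_graph` objects.
#' @param scaler Optional `feature_scaler` used to add raw-scale values.
#' @return List with `values` — long data.frame with columns `kind`
#'   ("node"/"edge"), `group` (cell type label, or "src->dst" edge type
#'   label), `feature`, `contribution`, `contribution_raw` — and `summary`
#'   — per (kind, group, feature) mean, median, quartiles and n.
#' @export
summarize_contributions <- function(maps, graphs, scaler = NULL) {
  stopifnot(length(maps) == length(graphs), length(maps) >= 1L)
  pieces <- Map(function(m, g) {
    labels <- g$scheme$labels
    nf <- m$node_feature_contributions
    node_df <- data.frame(
      kind = "node",
      group = rep(labels[g$node_types + 1L], times = ncol(nf)),
      feature = rep(colnames(nf), each = nrow(nf)),
      contribution = as.vector(nf),
      stringsAsFactors = FALSE
    )
    tsrc <- g$node_types[g$edges[, 1L]]
    tdst <- g$node_types[g$edges[, 2L]]
    egroup <- paste0(labels[tsrc + 1L], "->", labels[tdst + 1L])
    ef <- m$edge_feature_contributions
    edge_df <- data.frame(
      kind = "edge",
      group = rep(egroup, times = 2L),
      feature = rep(colnames(ef), each = nrow(ef)),
      contribution = as.vector(ef),
      stringsAsFactors = FALSE
    )
    rbind(node_df, edge_df)
  }, maps, graphs)
  values <- do.call(rbind, pieces)
  rownames(values) <- NULL

  values$contribution_raw <- values$contribution
  if (!is.null(scaler)) {
    is_node <- values$kind == "node"
    sds <- scaler$sds[values$feature[is_node]]
    values$contribution_raw[is_node] <- values$contribution[is_node] / sds
  }

  qs <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    c(mean = mean(v), q1 = q[1], median = q[2], q3 = q[3],
      n = length(v))
  }
  summ <- stats::aggregate(contribution ~ kind + group + feature,
                           data = values, FUN = qs)
  summ <- cbind(summ[, c("kind", "group", "feature")],
                as.data.frame(summ$contribution))
  list(values = values, summary = summ)
}

#' Plot a contribution map over the tissue
#'
#' Draws nuclei centroids colored by the signed contribution of one node
#' feature (diverging palette: red = works against the presumptive
#' category, blue = supports it), mirroring per-cell attribution overlays.
#'
#' @param map A `contribution_map`.
#' @param nuclei The `nuclei_table` the graph was built from (for
#'   centroids).
#' @param feature Node feature name to display.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the plotted contribution values.
#' @export
plot_contribution_map <- function(map, nuclei, feature = "eccentricity",
                                  ...) {
  v <- map$node_feature_contributions[, feature]
  lim <- max(abs(v), .Machine$double.eps)
  pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(256)
  col <- pal[pmin(256L, pmax(1L, floor((v + lim) / (2 * lim) * 255) + 1L))]
  graphics::plot(nuclei$x, -nuclei$y, col = col, pch = 16,
                 xlab = "x (px)", ylab = "-y (px)",
                 main = paste("contribution:", feature), ...)
  invisible(v)
}
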