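#' @name csigc
#' @title Cell spatial interaction-conditioned graph convolution
#' @description
#' One CSIGC layer updates every node's feature vector from (a) the node
#' itself through a learned linear map theta, and (b) its out-neighbours
#' through per-edge linear maps that are *conditioned on the spatial
#' interaction*: the categorical edge type t selects a row of an embedding
#' matrix EM (a flattened x-by-c map), which is then modulated
#' elementwise by feature-wise linear modulation (FiLM) driven by the two
#' continuous edge features, closeness w and parallelism a:
#'
#'   mo = gamma(w, a) * EM\[t\] + beta(w, a),   gamma, beta affine in (w, a)
#'
#' The per-edge message is `S %*% mo` (with S the neighbour's features by
#' default), messages are averaged over each node's out-edges, added to the
#' self message `X %*% theta`, and passed through ReLU and dropout on all
#' but the final layer (the final layer emits unconstrained per-node
#' logits for pooling and softmax).
#'
#' Both the forward pass and the exact backward pass (gradients with
#' respect to all layer parameters and, for attribution, with respect to
#' the node features and the w/a edge features) are implemented in
#' vectorised base R; networks in this family are a few thousand
#' parameters, so no compiled autodiff framework is required.
NULL

# ---- single layer ----------------------------------------------------------

# One CSIGC layer's learnable state. x = input width, cw = output channels,
# t2 = number of categorical edge types (T^2).
new_csigc_layer <- function(x, cw, t2, dropout = 0.2) {
  xc <- x * cw
  sd0 <- 1 / sqrt(x)  # variance-preserving for width-x inputs
  structure(
    list(
      x = x, cw = cw, t2 = t2, dropout = dropout,
      EM = matrix(stats::rnorm(t2 * xc, 0, sd0), t2, xc),
      gamma_w = numeric(xc), gamma_a = numeric(xc), gamma_b = rep(1, xc),
      beta_w = numeric(xc), beta_a = numeric(xc), beta_b = numeric(xc),
      theta = matrix(stats::rnorm(xc, 0, sd0), x, cw)
    ),
    class = "csigc_layer"
  )
}

layer_param_names <- c("EM", "gamma_w", "gamma_a", "gamma_b",
                       "beta_w", "beta_a", "beta_b", "theta")

#' Feature-wise linear modulation of an edge modulator
#'
#' Applies `gamma(w, a) * mo + beta(w, a)` where gamma and beta are affine
#' maps from the two continuous edge features (closeness w, parallelism a)
#' to a vector the length of `mo`.  At initialization gamma is the constant
#' 1 map and beta the constant 0 map, so modulation starts as the identity.
#'
#' @param mo Flattened modulator vector (length x*c), e.g. a row of the
#'   edge type embedding.
#' @param w,a Scalar closeness and parallelism for the edge.
#' @param params A `csigc_layer` (or list with `gamma_w`, `gamma_a`,
#'   `gamma_b`, `beta_w`, `beta_a`, `beta_b`).
#' @return Modulated vector, same length as `mo`.
#' @export
film_modulate <- function(mo, w, a, params) {
  stopifnot(is.finite(w), is.finite(a))
  gam <- params$gamma_w * w + params$gamma_a * a + params$gamma_b
  bet <- params$beta_w * w + params$beta_a * a + params$beta_b
  gam * mo + bet
}

#' Create one CSIGC layer
#'
#' @param x Input feature width.
#' @param cw Output channel count.
#' @param t2 Number of categorical edge types (T^2 for T cell types).
#' @param dropout Dropout rate used after ReLU on non-final layers.
#' @return A `csigc_layer` with freshly initialized parameters (drawn from
#'   the current RNG state).
#' @export
new_csigc_layer_params <- function(x, cw, t2, dropout = 0.2) {
  new_csigc_layer(x, cw, t2, dropout)
}

#' Apply one CSIGC layer
#'
#' Runs a single cell spatial interaction-conditioned convolution over a
#' graph view: per-edge modulators from the edge type embedding, FiLM
#' modulation by closeness and parallelism, neighbour message averaging,
#' self transform, then ReLU and (training only) dropout unless the layer
#' is final.
#'
#' @param layer A `csigc_layer`.
#' @param X N x x input node features.
#' @param graph A `cell_graph` providing edges, edge types, closeness and
#'   parallelism.
#' @param message_source `"neighbor"` or `"self"` (see [task_config()]).
#' @param training Enable dropout.
#' @param final If `TRUE`, skip activation and dropout (logit layer).
#' @return N x cw output matrix.
#' @export
csigc_forward <- function(layer, X, graph, message_source = "neighbor",
                          training = FALSE, final = FALSE) {
  layer_forward(layer, X, graph, message_source, training, final)$out
}

# Forward pass of one layer over a graph view.
# X: N x x input features. Returns list(out, cache).
layer_forward <- function(layer, X, graph, message_source, training, final) {
  n <- graph$n
  if (n < 2L) stop("CSIGC layer requires a graph with at least 2 nodes")
  x <- layer$x; cw <- layer$cw; xc <- x * cw
  stopifnot(ncol(X) == x)
  src <- graph$edges[, 1L]; dst <- graph$edges[, 2L]
  w <- graph$closeness; a <- graph$parallelism
  if (any(graph$edge_type >= layer$t2)) {
    stop("edge type index out of range for this layer's embedding")
  }

  E0 <- layer$EM[graph$edge_type + 1L, , drop = FALSE]          # e x xc
  G <- outer(w, layer$gamma_w) + outer(a, layer$gamma_a)
  G <- sweep(G, 2, layer$gamma_b, "+")
  B <- outer(w, layer$beta_w) + outer(a, layer$beta_a)
  B <- sweep(B, 2, layer$beta_b, "+")
  M <- G * E0 + B                                               # modulators

  sidx <- if (message_source == "neighbor") dst else src
  S <- X[sidx, , drop = FALSE]                                  # e x x
  e <- length(src)
  me <- matrix(0, e, cw)
  for (ch in seq_len(cw)) {
    cols <- ((ch - 1L) * x + 1L):(ch * x)
    me[, ch] <- rowSums(S * M[, cols, drop = FALSE])
  }

  outdeg <- tabulate(src, nbins = n)
  if (any(outdeg == 0L)) stop("node with out-degree 0: invalid cell graph")
  agg <- rowsum(me, group = src, reorder = TRUE) / outdeg       # N x cw
  pre <- unname(X %*% layer$theta) + unname(agg)

  mask <- NULL
  if (final) {
    out <- pre
  } else {
    out <- pmax(pre, 0)
    if (training && layer$dropout > 0) {
      keep <- 1 - layer$dropout
      mask <- matrix(stats::rbinom(length(out), 1L, keep) / keep,
                     nrow(out), ncol(out))
      out <- out * mask
    }
  }
  list(out = out,
       cache = list(X = X, S = S, sidx = sidx, src = src, outdeg = outdeg,
                    E0 = E0, G = G, M = M, w = w, a = a,
                    t = graph$edge_type, pre = pre, mask = mask,
                    final = final))
}

# Exact backward pass of one layer. dOut: N x cw gradient at the layer
# output. Returns param gradients and gradients w.r.t. the layer input X
# and the continuous edge features (w, a).
layer_backward <- function(layer, cache, dOut) {
  x <- layer$x; cw <- layer$cw
  if (cache$final) {
    dPre <- dOut
  } else {
    if (!is.null(cache$mask)) dOut <- dOut * cache$mask
    dPre <- dOut * (cache$pre > 0)
  }

  dTheta <- crossprod(cache$X, dPre)
  dX <- dPre %*% t(layer$theta)

  dMe <- dPre[cache$src, , drop = FALSE] / cache$outdeg[cache$src]
  e <- nrow(dMe)
  dM <- matrix(0, e, x * cw)
  dS <- matrix(0, e, x)
  for (ch in seq_len(cw)) {
    cols <- ((ch - 1L) * x + 1L):(ch * x)
    dM[, cols] <- cache$S * dMe[, ch]
    dS <- dS + cache$M[, cols, drop = FALSE] * dMe[, ch]
  }

  # accumulate neighbour-path input gradients
  acc <- rowsum(dS, group = cache$sidx, reorder = TRUE)
  rows <- as.integer(rownames(acc))
  dX[rows, ] <- dX[rows, , drop = FALSE] + acc

  dG <- dM * cache$E0
  dE0 <- dM * cache$G
  dEM <- matrix(0, layer$t2, x * cw)
  accE <- rowsum(dE0, group = cache$t, reorder = TRUE)
  dEM[as.integer(rownames(accE)) + 1L, ] <- accE

  grads <- list(
    EM = dEM,
    gamma_w = colSums(dG * cache$w), gamma_a = colSums(dG * cache$a),
    gamma_b = colSums(dG),
    beta_w = colSums(dM * cache$w), beta_a = colSums(dM * cache$a),
    beta_b = colSums(dM),
    theta = dTheta
  )
  dw <- as.numeric(dG %*% layer$gamma_w + dM %*% layer$beta_w)
  da <- as.numeric(dG %*% layer$gamma_a + dM %*% layer$beta_a)
  list(grads = grads, dX = dX, dw = dw, da = da)
}

# ---- network ---------------------------------------------------------------

#' Task configuration for a cell graph network
#'
#' @param scheme A [cell_type_scheme()].
#' @param widths Output width per convolution layer; the last entry is the
#'   number of prediction categories K (>= 2).
#' @param classes Character vector of the K class names, in logit order;
#'   graph labels are matched against these.
#' @param pooling `"subgroup"` (average final-layer outputs over nuclei of
#'   `pooled_labels` only) or `"global"` (all nuclei).
#' @param pooled_labels Cell types pooled under subgroup pooling; defaults
#'   to the scheme's `pooled_labels`.
#' @param message_source `"neighbor"`: the per-edge message carries the
#'   neighbour's features through the modulated map (edge-conditioned
#'   convolution convention, the default); `"self"`: it carries the source
#'   node's own features.
#' @param dropout Dropout rate applied after ReLU on non-final layers
#'   during training.
#' @param n_features Input node feature width (11).
#' @return A `task_config`.
#' @export
task_config <- function(scheme, widths, classes,
                        pooling = c("subgroup", "global"),
                        pooled_labels = scheme$pooled_labels,
                        message_source = c("neighbor", "self"),
                        dropout = 0.2, n_features = 11L) {
  pooling <- match.arg(pooling)
  message_source <- match.arg(message_source)
  widths <- as.integer(widths)
  K <- widths[length(widths)]
  stopifnot(length(widths) >= 1L, K >= 2L, dropout >= 0, dropout < 1)
  if (length(classes) != K) stop("length(classes) must equal the last width")
  bad <- setdiff(pooled_labels, scheme$labels)
  if (length(bad) > 0L) {
    stop("pooled_labels not in scheme: ", paste(bad, collapse = ", "))
  }
  structure(
    list(scheme = scheme, n_layers = length(widths), widths = widths,
         K = K, classes = as.character(classes), pooling = pooling,
         pooled_labels = pooled_labels, message_source = message_source,
         dropout = dropout, n_features = as.integer(n_features)),
    class = "task_config"
  )
}

#' Preset task configurations
#'
#' `config_histology`: 3 convolution layers (11 -> 8 -> 8 -> K) with
#' subgroup mean pooling over tumor nuclei — the patch histology
#' classification head.  `config_risk`: 4 layers (11 -> 8 -> 8 -> 8 -> K)
#' pooling over epithelial strata — the malignant transformation risk
#' head.  `config_response`: 3 layers with global mean pooling over all
#' cell types — the treatment response head, applied to per-slide
#' disconnected union graphs.
#'
#' @param scheme Cell type scheme (lung for histology/response, oral for
#'   risk).
#' @param classes The K class names.
#' @param ... Passed on to [task_config()].
#' @return A `task_config`.
#' @export
config_histology <- function(scheme = lung_scheme(),
                             classes = c("ADC", "SCC"), ...) {
  task_config(scheme, widths = c(8L, 8L, length(classes)), classes = classes,
              pooling = "subgroup", ...)
}

#' @rdname config_histology
#' @export
config_risk <- function(scheme = oral_scheme(),
                        classes = c("low_risk", "high_risk"), ...) {
  task_config(scheme, widths = c(8L, 8L, 8L, length(classes)),
              classes = classes, pooling = "subgroup", ...)
}

#' @rdname config_histology
#' @export
config_response <- function(scheme = lung_scheme(),
                            classes = c("non_benefitting", "benefitting"),
                            ...) {
  task_config(scheme, widths = c(8L, 8L, length(classes)), classes = classes,
              pooling = "global", ...)
}

#' Create a cell graph network
#'
#' Initializes the stack of CSIGC layers described by a [task_config()].
#' Edge type embeddings and self-transforms start from zero-mean normals
#' with sd `1/sqrt(x)`; the FiLM maps start at the identity (gamma = 1,
#' beta = 0).
#'
#' @param config A `task_config`.
#' @param seed Integer seed for parameter initialization.
#' @param scaler Optional `feature_scaler` carried with the model so that
#'   checkpoints are self-contained.
#' @return A `cellgraph_net` model object.
#' @export
new_cellgraph_net <- function(config, seed = 1L, scaler = NULL) {
  stopifnot(inherits(config, "task_config"))
  set.seed(seed)
  t2 <- n_types(config$scheme)^2
  ins <- c(config$n_features, config$widths[-config$n_layers])
  layers <- vector("list", config$n_layers)
  for (i in seq_len(config$n_layers)) {
    layers[[i]] <- new_csigc_layer(ins[i], config$widths[i], t2,
                                   dropout = config$dropout)
  }
  structure(list(config = config, layers = layers, scaler = scaler),
            class = "cellgraph_net")
}

#' @export
print.cellgraph_net <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<cellgraph_net> %d CSIGC layers (%s), %s pooling, %d parameters\n",
    cfg$n_layers,
    paste(c(cfg$n_features, cfg$widths), collapse = " -> "),
    cfg$pooling, n_params(x)))
  cat("  classes:", paste(cfg$classes, collapse = ", "),
      "| scheme:", cfg$scheme$name, "\n")
  invisible(x)
}

#' Trainable parameter count
#' @param model A `cellgraph_net`.
#' @return Integer number of trainable scalars.
#' @export
n_params <- function(model) {
  sum(vapply(model$layers, function(l) {
    sum(vapply(layer_param_names, function(nm) length(l[[nm]]), numeric(1)))
  }, numeric(1)))
}

#' Subgroup mean pooling
#'
#' Averages final-layer node outputs over a designated node subset (e.g.
#' tumor nuclei), per channel.
#'
#' @param node_outputs N x K matrix.
#' @param mask Logical vector selecting at least one node.
#' @return Length-K vector of per-channel means over the masked rows.
#' @export
subgroup_mean_pool <- function(node_outputs, mask) {
  stopifnot(length(mask) == nrow(node_outputs))
  if (!any(mask)) stop("subgroup mean pooling over an empty node set")
  colMeans(node_outputs[mask, , drop = FALSE])
}

softmax <- function(z) {
  z <- z - max(z)
  ez <- exp(z)
  ez / sum(ez)
}

pooled_mask <- function(model, graph) {
  cfg <- model$config
  if (cfg$pooling == "global") return(rep(TRUE, graph$n))
  pooled_idx <- type_index(cfg$pooled_labels, cfg$scheme)
  graph$node_types %in% pooled_idx
}

#' Forward pass of a cell graph network
#'
#' Runs the CSIGC stack over a graph, pools the final-layer node logits
#' over the task's node subset (arithmetic mean), and applies softmax.
#' The final layer uses no ReLU or dropout, so per-node logits are
#' unconstrained.
#'
#' @param model A `cellgraph_net`.
#' @param graph A `cell_graph` whose scheme matches the model's.
#' @param training Enable dropout on non-final layers.
#' @param keep_cache Keep per-layer caches for a subsequent backward pass.
#' @return List with `node_logits` (N x K), `graph_logits` (length K),
#'   `probabilities` (length K, softmax of `graph_logits`), `pooled_mask`,
#'   and (if requested) `caches`.
#' @export
forward <- function(model, graph, training = FALSE, keep_cache = FALSE) {
  cfg <- model$config
  if (ncol(graph$X) != cfg$n_features) {
    stop(sprintf("graph has %d node features, model expects %d",
                 ncol(graph$X), cfg$n_features))
  }
  if (graph$scheme$name != cfg$scheme$name) {
    stop("graph scheme does not match model scheme")
  }
  X <- graph$X
  caches <- if (keep_cache) vector("list", cfg$n_layers) else NULL
  for (i in seq_len(cfg$n_layers)) {
    res <- layer_forward(model$layers[[i]], X, graph, cfg$message_source,
                         training = training, final = i == cfg$n_layers)
    X <- res$out
    if (keep_cache) caches[[i]] <- res$cache
  }
  mask <- pooled_mask(model, graph)
  graph_logits <- subgroup_mean_pool(X, mask)
  out <- list(node_logits = X, graph_logits = graph_logits,
              probabilities = softmax(graph_logits), pooled_mask = mask)
  if (keep_cache) out$caches <- caches
  out
}

# Backward pass from a gradient at the graph logits down to parameters and
# (optionally) inputs. fwd must come from forward(..., keep_cache = TRUE).
network_backward <- function(model, graph, fwd, d_graph_logits) {
  cfg <- model$config
  n_mask <- sum(fwd$pooled_mask)
  dNode <- matrix(0, graph$n, cfg$K)
  dNode[fwd$pooled_mask, ] <- matrix(d_graph_logits / n_mask, n_mask, cfg$K,
                                     byrow = TRUE)
  grads <- vector("list", cfg$n_layers)
  e <- nrow(graph$edges)
  dw <- numeric(e); da <- numeric(e)
  dX <- dNode
  for (i in rev(seq_len(cfg$n_layers))) {
    res <- layer_backward(model$layers[[i]], fwd$caches[[i]], dX)
    grads[[i]] <- res$grads
    dw <- dw + res$dw
    da <- da + res$da
    dX <- res$dX
  }
  list(layer_grads = grads, dX = dX, dw = dw, da = da)
}

# Cross-entropy loss and its gradients for one labelled graph.
# label_idx: 1-based class index. Returns loss, param grads, input grads.
graph_loss_grads <- function(model, graph, label_idx, training = FALSE) {
  fwd <- forward(model, graph, training = training, keep_cache = TRUE)
  p <- fwd$probabilities
  loss <- -log(max(p[label_idx], .Machine$double.xmin))
  dgl <- p
  dgl[label_idx] <- dgl[label_idx] - 1
  bwd <- network_backward(model, graph, fwd, dgl)
  list(loss = loss, fwd = fwd, layer_grads = bwd$layer_grads,
       dX = bwd$dX, dw = bwd$dw, da = bwd$da)
}

# ---- checkpoint serialization ---------------------------------------------

#' Save / load a model checkpoint
#'
#' A checkpoint is a versioned JSON container holding the task
#' configuration, cell type scheme, feature scaler (if attached) and all
#' layer parameters at full precision; save/load round-trips exactly.
#'
#' @param model A `cellgraph_net`.
#' @param path Output path (`.json`).
#' @return `path` invisibly; `load_checkpoint` returns the model.
#' @export
save_checkpoint <- function(model, path) {
  cfg <- model$config
  obj <- list(
    format = "cellgraphnet/checkpoint", version = 1L,
    config = list(scheme = unclass(cfg$scheme), widths = cfg$widths,
                  classes = cfg$classes, pooling = cfg$pooling,
                  pooled_labels = cfg$pooled_labels,
                  message_source = cfg$message_source,
                  dropout = cfg$dropout, n_features = cfg$n_features),
    layers = lapply(model$layers, function(l) {
      c(list(x = l$x, cw = l$cw, t2 = l$t2, dropout = l$dropout),
        lapply(stats::setNames(layer_param_names, layer_param_names),
               function(nm) l[[nm]]))
    })
  )
  if (!is.null(model$scaler)) obj$scaler <- unclass(model$scaler)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (is.null(obj$format) || obj$format != "cellgraphnet/checkpoint") {
    stop("not a model checkpoint: ", path)
  }
  scheme <- cell_type_scheme(obj$config$scheme$name, obj$config$scheme$labels,
                             obj$config$scheme$pooled_labels)
  cfg <- task_config(scheme, widths = obj$config$widths,
                     classes = obj$config$classes,
                     pooling = obj$config$pooling,
                     pooled_labels = obj$config$pooled_labels,
                     message_source = obj$config$message_source,
                     dropout = obj$config$dropout,
                     n_features = obj$config$n_features)
  layers <- lapply(obj$layers, function(l) {
      x <- as.integer(l$x); cw <- as.integer(l$cw)
      structure(
        list(x = x, cw = cw, t2 = as.integer(l$t2),
             dropout = as.numeric(l$dropout),
             EM = matrix(as.numeric(t(l$EM)), as.integer(l$t2), x * cw,
                         byrow = TRUE),
             gamma_w = as.numeric(l$gamma_w), gamma_a = as.numeric(l$gamma_a),
             gamma_b = as.numeric(l$gamma_b), beta_w = as.numeric(l$beta_w),
             beta_a = as.numeric(l$beta_a), beta_b = as.numeric(l$beta_b),
             theta = matrix(as.numeric(t(l$theta)), x, cw, byrow = TRUE)),
        class = "csigc_layer")
  })
  scaler <- NULL
  if (!is.null(obj$scaler)) {
    scaler <- structure(
      list(feature_names = obj$scaler$feature_names,
           means = stats::setNames(as.numeric(obj$scaler$means),
                                   obj$scaler$feature_names),
           sds = stats::setNames(as.numeric(obj$scaler$sds),
                                 obj$scaler$feature_names)),
      class = "feature_scaler")
  }
  structure(list(config = cfg, layers = layers, scaler = scaler),
            class = "cellgraph_net")
}
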