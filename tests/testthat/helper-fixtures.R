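# Shared fixtures, all generated in code.

# a minimal hand-written nuclei data.frame with internally consistent
# ellipse morphology (axes a >= b, area = pi*a*b/4, etc.)
toy_nuclei_df <- function(n = 3, cell_type = "tumor",
                          x = NULL, y = NULL, orientation = NULL,
                          major = 20, ecc = 0.6) {
  if (is.null(x)) x <- seq_len(n) * 30
  if (is.null(y)) y <- rep(10, n)
  if (is.null(orientation)) orientation <- rep(0.2, n)
  major <- rep_len(major, n)
  ecc <- rep_len(ecc, n)
  minor <- major * sqrt(1 - ecc^2)
  area <- pi * major * minor / 4
  A <- major / 2; B <- minor / 2
  per <- pi * (3 * (A + B) - sqrt((3 * A + B) * (A + 3 * B)))
  solidity <- seq(0.93, 0.97, length.out = n)
  data.frame(
    x = x, y = y, cell_type = rep_len(cell_type, n),
    orientation = rep_len(orientation, n),
    confidence = rep(0.9, n), area = area, convex_area = area / solidity,
    eccentricity = ecc, extent = seq(0.60, 0.75, length.out = n),
    filled_area = area,
    major_axis_length = major, minor_axis_length = minor,
    perimeter_sq_over_area = per^2 / area, perimeter = per,
    solidity = solidity, stringsAsFactors = FALSE
  )
}

write_toy_table <- function(df, sep = ",") {
  f <- tempfile(fileext = ".csv")
  utils::write.table(df, f, sep = sep, quote = FALSE, row.names = FALSE)
  f
}

# a random but valid cell_graph built straight from simulated nuclei
random_graph <- function(seed, n_nuclei = 20, scheme = lung_scheme(),
                         k = 8, label = "A") {
  mix <- if (scheme$name == "lung") lung_mixture() else NULL
  spec <- synthetic_spec(scheme, label, n_nuclei = n_nuclei,
                         field_size = 60 * sqrt(n_nuclei),
                         min_separation = 4, type_mixture = mix)
  tab <- generate_patch(spec, seed)
  scaler <- fit_scaler(tab)
  build_graph(tab, scheme = scheme, scaler = scaler, k = k,
              meta = list(patch_id = paste0("p", seed),
                          slide_id = paste0("s", seed),
                          patient_id = paste0("pt", seed), label = label))
}

# model with non-trivial FiLM weights so gradients w.r.t. edge features do
# not vanish (at identity initialization gamma/beta ignore w and a)
random_model <- function(config, seed, film_sd = 0.3) {
  m <- new_cellgraph_net(config, seed = seed)
  set.seed(seed + 1000L)
  for (i in seq_along(m$layers)) {
    xc <- m$layers[[i]]$x * m$layers[[i]]$cw
    for (nm in c("gamma_w", "gamma_a", "beta_w", "beta_a")) {
      m$layers[[i]][[nm]] <- stats::rnorm(xc, 0, film_sd)
    }
  }
  m
}

# loss of the network on a graph for presumptive class k (1-based)
graph_loss <- function(model, graph, k) {
  -log(forward(model, graph)$probabilities[k])
}

# central finite-difference gradients w.r.t. every node and edge feature
fd_contributions <- function(model, graph, k, eps = 1e-4) {
  dX <- matrix(0, graph$n, ncol(graph$X))
  for (i in seq_len(graph$n)) {
    for (j in seq_len(ncol(graph$X))) {
      gp <- graph; gp$X[i, j] <- graph$X[i, j] + eps
      gm <- graph; gm$X[i, j] <- graph$X[i, j] - eps
      dX[i, j] <- (graph_loss(model, gp, k) - graph_loss(model, gm, k)) /
        (2 * eps)
    }
  }
  e <- nrow(graph$edges)
  dw <- numeric(e); da <- numeric(e)
  for (ei in seq_len(e)) {
    gp <- graph; gp$closeness[ei] <- graph$closeness[ei] + eps
    gm <- graph; gm$closeness[ei] <- graph$closeness[ei] - eps
    dw[ei] <- (graph_loss(model, gp, k) - graph_loss(model, gm, k)) / (2 * eps)
    gp <- graph; gp$parallelism[ei] <- graph$parallelism[ei] + eps
    gm <- graph; gm$parallelism[ei] <- graph$parallelism[ei] - eps
    da[ei] <- (graph_loss(model, gp, k) - graph_loss(model, gm, k)) / (2 * eps)
  }
  list(dX = dX, dw = dw, da = da)
}

# agreement check at the stated tolerance: 1e-3 relative or 1e-6 absolute
grad_close <- function(got, want, rel = 1e-3, abs_tol = 1e-6) {
  all(abs(got - want) <= pmax(abs_tol, rel * abs(want)))
}

# hand-built two-node graph with fully controlled features, one edge each
# way; node 1 is tumor (pooled under the lung scheme), node 2 stroma.
controlled_graph <- function(X, scheme = lung_scheme(),
                             node_types = c(0L, 1L),
                             a = c(0.5, 0.5), w = c(0.1, 0.1)) {
  X <- as.matrix(X)
  structure(
    list(n = nrow(X), X = X, node_types = node_types,
         edges = cbind(src = c(1L, 2L), dst = c(2L, 1L)),
         edge_type = edge_type_index(node_types[c(1L, 2L)],
                                     node_types[c(2L, 1L)],
                                     n_types(scheme)),
         parallelism = a, closeness = w, scheme = scheme,
         meta = list(patch_id = "c1", slide_id = "cs1", patient_id = "cp1",
                     label = NA)),
    class = "cell_graph")
}

# zero out a model so the forward pass is exactly X %*% theta per layer
zero_messages <- function(model) {
  for (i in seq_along(model$layers)) {
    model$layers[[i]]$EM[] <- 0
    model$layers[[i]]$gamma_w[] <- 0; model$layers[[i]]$gamma_a[] <- 0
    model$layers[[i]]$gamma_b[] <- 1
    model$layers[[i]]$beta_w[] <- 0; model$layers[[i]]$beta_a[] <- 0
    model$layers[[i]]$beta_b[] <- 0
  }
  model
}
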