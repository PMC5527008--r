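#' SOM training configuration
#'
#' Parameters of the Kohonen self-organizing map trained on ternary ADME
#' fingerprints. Defaults follow standard SOM practice on a rectangular
#' (non-toroidal) grid: Gaussian neighborhood, initial radius half the larger
#' grid side, initial learning rate 0.5, exponential decay of both over the
#' run, random uniform weight initialization in `[-1, 1]`.
#'
#' @param rows,cols Grid dimensions (>= 2 each); 50 x 50 = 2500 nodes by
#'   default, the resolution used for maps trained on tens of thousands of
#'   molecules. Smaller datasets warrant smaller grids.
#' @param epochs Number of passes over the training set (>= 1).
#' @param initial_learning_rate Starting learning rate (> 0).
#' @param initial_neighborhood_radius Starting Gaussian radius in grid units
#'   (> 0); defaults to `max(rows, cols) / 2`.
#' @param seed Integer seed controlling initialization and presentation order.
#' @return A `som_config` list.
#' @export
som_config <- function(rows = 50L, cols = 50L, epochs = 10L,
                       initial_learning_rate = 0.5,
                       initial_neighborhood_radius = max(rows, cols) / 2,
                       seed = 1L) {
  if (!is.numeric(rows) || !is.numeric(cols) || rows < 2 || cols < 2 ||
      rows != round(rows) || cols != round(cols))
    stop_classed("invalid_config", "rows and cols must be integers >= 2")
  if (!is.numeric(epochs) || epochs < 1 || epochs != round(epochs))
    stop_classed("invalid_config", "epochs must be an integer >= 1")
  if (initial_learning_rate <= 0 || initial_neighborhood_radius <= 0)
    stop_classed("invalid_config", "learning rate and radius must be positive")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 epochs = as.integer(epochs),
                 initial_learning_rate = initial_learning_rate,
                 initial_neighborhood_radius = initial_neighborhood_radius,
                 seed = as.integer(seed)),
            class = "som_config")
}

#' Initialize an untrained map
#'
#' Weights are drawn uniformly at random in `[-1, 1]` per coordinate from the
#' config seed; member counts are zero and every node is OFF until training.
#' Grid coordinates are 0-based `(row, col)`; node labels are formatted
#' `row_col`.
#'
#' @param config A [som_config()].
#' @param dim Fingerprint dimensionality (20 for the standard catalog).
#' @return A `som_map` object.
#' @export
som_init <- function(config, dim = 20L) {
  if (!inherits(config, "som_config"))
    stop_classed("invalid_config", "config must be a som_config")
  n_nodes <- config$rows * config$cols
  set.seed(config$seed)
  weights <- matrix(stats::runif(n_nodes * dim, -1, 1), nrow = n_nodes)
  # node k (1-based, row-major) has 0-based grid coords:
  grid_row <- (seq_len(n_nodes) - 1L) %/% config$cols
  grid_col <- (seq_len(n_nodes) - 1L) %% config$cols
  structure(list(config = config, dim = as.integer(dim),
                 weights = weights,
                 grid_row = grid_row, grid_col = grid_col,
                 member_counts = integer(n_nodes),
                 status = rep("OFF", n_nodes),
                 outlier_cutoff = NA_real_,
                 quantization_errors = numeric(0),
                 trained = FALSE,
                 catalog_version = catalog_version()),
            class = "som_map")
}

#' @export
print.som_map <- function(x, ...) {
  s <- map_summary_or_na(x)
  cat(sprintf("SOM map %dx%d (%d nodes), dim %d, %s\n",
              x$config$rows, x$config$cols, length(x$grid_row), x$dim,
              if (x$trained)
                sprintf("trained: %d ON (%.1f%%), outlier cutoff %.3f",
                        s$n_on, 100 * s$on_fraction, x$outlier_cutoff)
              else "untrained"))
  invisible(x)
}

map_summary_or_na <- function(map) {
  list(n_nodes = length(map$grid_row), n_on = sum(map$status == "ON"),
       on_fraction = mean(map$status == "ON"))
}

# Squared Euclidean distances between all data rows and all node weights
# (n x n_nodes), via the expansion trick; clipped at 0 for rounding noise.
cross_dist2 <- function(X, W) {
  d2 <- outer(rowSums(X^2), rowSums(W^2), "+") - 2 * tcrossprod(X, W)
  pmax(d2, 0)
}

as_fp_matrix <- function(fps, dim) {
  m <- if (is.data.frame(fps)) fingerprint_matrix(fps) else {
    m0 <- as.matrix(fps); storage.mode(m0) <- "double"; m0
  }
  if (is.null(dim(m)) || ncol(m) != dim)
    stop_classed("malformed_fingerprint",
                 sprintf("fingerprints must have %d coordinates", dim))
  m
}

#' Best matching unit
#'
#' The node whose weight vector minimizes the Euclidean distance to the
#' fingerprint. Ties are broken by the lowest `(row, col)` in lexicographic
#' order (the row-major node ordering guarantees this).
#'
#' @param map A `som_map`.
#' @param fp A numeric vector of length `map$dim` (ternary for ADME use, but
#'   any numeric vector is accepted).
#' @return A list with `row`, `col` (0-based), `node` (1-based row-major
#'   index) and `distance`.
#' @export
best_matching_unit <- function(map, fp) {
  fp <- as.numeric(fp)
  if (length(fp) != map$dim)
    stop_classed("malformed_fingerprint",
                 sprintf("fingerprint length %d != map dim %d",
                         length(fp), map$dim))
  d2 <- rowSums(sweep(map$weights, 2, fp)^2)
  k <- which.min(d2)  # first minimum = lexicographically smallest (row, col)
  list(row = map$grid_row[k], col = map$grid_col[k], node = k,
       distance = sqrt(d2[k]))
}

# Batch BMU: returns list(node = 1-based indices, distance).
bmu_batch <- function(map, X) {
  d2 <- cross_dist2(X, map$weights)
  k <- max.col(-d2, ties.method = "first")
  list(node = k, distance = sqrt(d2[cbind(seq_len(nrow(X)), k)]))
}

#' Train the map on ADME fingerprints
#'
#' Classical online Kohonen training: molecules are presented one at a time
#' in a seeded random order; at each presentation the best matching unit and
#' its Gaussian grid neighborhood move toward the fingerprint, with the
#' learning rate and neighborhood radius decaying exponentially over the run
#' (to 0.01 and 0.5 respectively). Weights are clamped to `[-1, 1]`, the
#' range of the ternary inputs.
#'
#' After the final epoch each training fingerprint is assigned to its BMU:
#' node member counts are recorded, nodes holding at least one molecule are
#' labelled ON (populated) and the rest OFF, and the outlier cutoff is set to
#' the maximum BMU distance over the training set, so no training molecule is
#' an outlier of its own map.
#'
#' @param map An initialized `som_map` (see [som_init()]).
#' @param fps An `adme_fingerprints` table or numeric matrix with `map$dim`
#'   columns.
#' @return The trained `som_map`, with per-epoch quantization errors (mean
#'   BMU distance) in `$quantization_errors`.
#' @export
som_train <- function(map, fps) {
  X <- as_fp_matrix(fps, map$dim)
  n <- nrow(X)
  if (n < 1L) stop_classed("no_training_data", "no fingerprints to train on")
  cfg <- map$config
  W <- map$weights
  gr <- map$grid_row; gc <- map$grid_col
  total <- cfg$epochs * n
  eta0 <- cfg$initial_learning_rate; eta1 <- 0.01
  sig0 <- cfg$initial_neighborhood_radius; sig1 <- 0.5
  set.seed(derive_seed(cfg$seed, 1L))
  qe <- numeric(cfg$epochs)
  t_step <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    for (i in ord) {
      frac <- if (total > 1) t_step / (total - 1) else 1
      eta <- eta0 * (eta1 / eta0)^frac
      sig <- sig0 * (sig1 / sig0)^frac
      fp <- X[i, ]
      d2 <- rowSums(W^2) - 2 * drop(W %*% fp) + sum(fp^2)
      k <- which.min(d2)
      h <- exp(-((gr - gr[k])^2 + (gc - gc[k])^2) / (2 * sig^2))
      W <- W + (eta * h) * (rep(fp, each = nrow(W)) - W)
      t_step <- t_step + 1L
    }
    W <- pmin(pmax(W, -1), 1)
    d2 <- cross_dist2(X, W)
    qe[epoch] <- mean(sqrt(d2[cbind(seq_len(n),
                                    max.col(-d2, ties.method = "first"))]))
  }
  map$weights <- W
  bm <- bmu_batch(map, X)
  counts <- tabulate(bm$node, nbins = nrow(W))
  map$member_counts <- counts
  map$status <- ifelse(counts >= 1L, "ON", "OFF")
  map$outlier_cutoff <- max(bm$distance)
  map$quantization_errors <- qe
  map$trained <- TRUE
  map
}

#' Ternary ADME fingerprint of a map node
#'
#' Thresholds the node's continuous weight vector into the three-level
#' profile shown on per-property map layers: a coordinate above `tau` is +1,
#' below `-tau` is -1, and the band between is the uncertain class 0. The
#' default `tau = 1/3` splits `[-1, 1]` into three equal bands.
#'
#' OFF (unpopulated) nodes carry no information; requesting their fingerprint
#' signals a `no_information` condition unless `allow_off = TRUE`, in which
#' case the thresholded raw weight vector is returned anyway.
#'
#' @param map A trained `som_map`.
#' @param node `c(row, col)` 0-based grid coordinates.
#' @param tau Threshold in (0, 1).
#' @param allow_off Return a fingerprint even for OFF nodes.
#' @return An integer vector of length `map$dim` in `{-1, 0, 1}`.
#' @export
node_fingerprint <- function(map, node, tau = 1 / 3, allow_off = FALSE) {
  if (!is.numeric(tau) || tau <= 0 || tau >= 1)
    stop_classed("invalid_argument", "tau must lie in (0, 1)")
  k <- node_index(map, node)
  if (map$status[k] == "OFF" && !allow_off)
    stop_classed("no_information",
                 sprintf("node %d_%d is OFF (unpopulated); no fingerprint",
                         node[1], node[2]))
  w <- map$weights[k, ]
  as.integer(ifelse(w > tau, 1L, ifelse(w < -tau, -1L, 0L)))
}

node_index <- function(map, node) {
  r <- node[1]; c <- node[2]
  if (r < 0 || r >= map$config$rows || c < 0 || c >= map$config$cols)
    stop_classed("invalid_argument", sprintf("node (%s, %s) outside grid", r, c))
  as.integer(r * map$config$cols + c + 1L)
}

#' Project molecules onto a trained map
#'
#' Each fingerprint is assigned to its best matching unit. A molecule whose
#' BMU distance exceeds the map's outlier cutoff is an outlier with respect
#' to the training set: the map makes no prediction for it. Molecules landing
#' on OFF nodes are reported but carry no node fingerprint either (OFF nodes
#' are outside the map's applicability domain).
#'
#' @param map A trained `som_map`.
#' @param fps An `adme_fingerprints` table or numeric matrix.
#' @param tau Node-fingerprint threshold, see [node_fingerprint()].
#' @return A data frame with one row per molecule: `molecule_id`, `row`,
#'   `col` (0-based), `node_label` (`row_col`), `distance`, `is_outlier`,
#'   `node_on`, and a list column `node_fingerprint` (integer vector for
#'   non-outlier ON hits, `NULL` otherwise).
#' @export
som_project <- function(map, fps, tau = 1 / 3) {
  if (!isTRUE(map$trained))
    stop_classed("model_not_trained", "map must be trained before projection")
  X <- as_fp_matrix(fps, map$dim)
  ids <- rownames(X)
  if (is.null(ids)) ids <- paste0("mol", seq_len(nrow(X)))
  bm <- bmu_batch(map, X)
  on <- map$status[bm$node] == "ON"
  # small relative tolerance so the training molecule that set the cutoff is
  # never flagged as an outlier after a serialization round trip
  outlier <- bm$distance > map$outlier_cutoff + 1e-9 * (1 + map$outlier_cutoff)
  nfp <- lapply(seq_len(nrow(X)), function(i) {
    if (outlier[i] || !on[i]) return(NULL)
    node_fingerprint(map, c(map$grid_row[bm$node[i]], map$grid_col[bm$node[i]]),
                     tau = tau)
  })
  out <- data.frame(molecule_id = ids,
                    row = map$grid_row[bm$node],
                    col = map$grid_col[bm$node],
                    node_label = paste0(map$grid_row[bm$node], "_",
                                        map$grid_col[bm$node]),
                    distance = bm$distance,
                    is_outlier = outlier,
                    node_on = on,
                    stringsAsFactors = FALSE)
  out$node_fingerprint <- nfp
  class(out) <- c("som_projection", "data.frame")
  out
}

#' Map occupancy summary
#'
#' @param map A trained `som_map`.
#' @return A list with `n_nodes`, `n_on` (populated nodes) and `on_fraction`.
#' @export
map_summary <- function(map) {
  if (!isTRUE(map$trained))
    stop_classed("model_not_trained", "map must be trained first")
  map_summary_or_na(map)
}

## ---- serialization ------------------------------------------------------

.map_schema <- "admespace-map/1"

#' Save / load a trained map as JSON
#'
#' The map file records the schema version, training configuration, catalog
#' version, flattened weight matrix (node-major), member counts, ON/OFF
#' status, outlier cutoff and per-epoch quantization errors. The round trip
#' is lossless to serialization precision (17 significant digits, enough to
#' reproduce IEEE doubles exactly).
#'
#' @param map A `som_map`.
#' @param path File path (JSON).
#' @return `save_map()` returns `path` invisibly; `load_map()` a `som_map`.
#' @export
save_map <- function(map, path) {
  obj <- list(schema = .map_schema,
              config = unclass(map$config),
              dim = map$dim,
              catalog_version = map$catalog_version,
              weights = as.vector(t(map$weights)),  # node-major
              member_counts = map$member_counts,
              status = map$status,
              outlier_cutoff = map$outlier_cutoff,
              quantization_errors = map$quantization_errors,
              trained = map$trained)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_map
#' @export
load_map <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop_classed("incompatible_map_file",
                                 "cannot parse map file: ", path))
  if (!identical(obj$schema, .map_schema))
    stop_classed("incompatible_map_file",
                 "unrecognized map schema in ", path)
  cfg <- do.call(som_config, obj$config)
  n_nodes <- cfg$rows * cfg$cols
  if (length(obj$weights) != n_nodes * obj$dim ||
      length(obj$member_counts) != n_nodes || length(obj$status) != n_nodes)
    stop_classed("incompatible_map_file", "map file dimensions inconsistent")
  map <- som_init(cfg, dim = obj$dim)
  map$weights <- matrix(obj$weights, nrow = n_nodes, byrow = TRUE)
  map$member_counts <- as.integer(obj$member_counts)
  map$status <- obj$status
  map$outlier_cutoff <- obj$outlier_cutoff
  map$quantization_errors <- as.numeric(obj$quantization_errors)
  map$trained <- isTRUE(obj$trained)
  map$catalog_version <- obj$catalog_version
  map
}
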