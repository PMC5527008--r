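# Shared builders for the test suite. Everything is generated in code; no
# stored fixtures.

# A map_layer built directly from a value matrix (bypasses training).
make_layer <- function(values, key = "TEST") {
  admespace:::new_layer(key, as.matrix(values))
}

# A hand-built "trained" map with full control over weights and occupancy.
# `weights` is an (rows*cols) x dim matrix in node-major (row-major grid)
# order; nodes with member_counts >= 1 are ON.
fake_trained_map <- function(weights, rows, cols,
                             member_counts = rep(1L, rows * cols),
                             outlier_cutoff = 1e6, seed = 1L) {
  stopifnot(nrow(weights) == rows * cols)
  map <- som_init(som_config(rows, cols, epochs = 1L, seed = seed),
                  dim = ncol(weights))
  map$weights <- weights
  map$member_counts <- as.integer(member_counts)
  map$status <- ifelse(member_counts >= 1L, "ON", "OFF")
  map$outlier_cutoff <- outlier_cutoff
  map$trained <- TRUE
  map
}

# Train a small map on archetype-clustered synthetic fingerprints; returns
# the map together with the generator's ground truth.
train_archetype_map <- function(n = 600L, rows = 12L, cols = 12L,
                                epochs = 8L, seed = 42L,
                                flip_rate = 0.05, uncertain_rate = 0.05,
                                n_archetypes = 3L) {
  arch <- generate_archetypes(n_archetypes, seed = seed)
  spec <- archetype_spec(arch, flip_rate = flip_rate,
                         uncertain_rate = uncertain_rate)
  gen <- generate_fingerprints(spec, n, seed = seed + 1L)
  map <- som_train(som_init(som_config(rows, cols, epochs = epochs,
                                       seed = seed + 2L)),
                   gen$fingerprints)
  list(map = map, fingerprints = gen$fingerprints,
       archetype = gen$archetype, archetypes = arch)
}

# Memoised mid-size archetype map shared by layer/overlay tests.
shared_archetype_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- train_archetype_map()
    cache
  }
})

# Per-molecule labels equal to the value the map itself predicts at each
# molecule's BMU (NA for outliers/OFF hits) — the self-consistent overlay.
self_labels <- function(map, projections, property_key,
                        catalog = adme_catalog()) {
  j <- match(property_key, catalog$key)
  vapply(seq_len(nrow(projections)), function(i) {
    nfp <- projections$node_fingerprint[[i]]
    if (is.null(nfp)) NA_integer_ else nfp[j]
  }, integer(1)) |>
    stats::setNames(projections$molecule_id)
}
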