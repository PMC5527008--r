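#' Sample well-separated fingerprint archetypes
#'
#' Draws `n_archetypes` binary (+1/-1) fingerprint prototypes by rejection
#' sampling until every pair differs in at least `min_hamming` of the
#' `n_props` coordinates. Archetypes stand in for the dense clusters of
#' recurring ADME profiles a large compound collection exhibits; the
#' separation guarantee keeps map-region-formation tests well posed.
#'
#' @param n_archetypes Number of prototypes (>= 1).
#' @param n_props Fingerprint length (default 20).
#' @param min_hamming Minimum pairwise Hamming distance (default 8).
#' @param seed Integer seed.
#' @return A `n_archetypes x n_props` matrix with entries in `{-1, 1}`.
#' @export
generate_archetypes <- function(n_archetypes, n_props = 20L, min_hamming = 8L,
                                seed = 1L) {
  if (n_archetypes < 1) stop_classed("invalid_argument", "n_archetypes >= 1 required")
  if (min_hamming > n_props)
    stop_classed("invalid_argument", "min_hamming cannot exceed n_props")
  set.seed(seed)
  out <- matrix(NA_real_, n_archetypes, n_props)
  for (i in seq_len(n_archetypes)) {
    for (attempt in seq_len(10000L)) {
      cand <- sample(c(-1, 1), n_props, replace = TRUE)
      ok <- i == 1L || all(apply(out[seq_len(i - 1L), , drop = FALSE], 1,
                                 function(a) sum(a != cand)) >= min_hamming)
      if (ok) { out[i, ] <- cand; break }
    }
    if (anyNA(out[i, ]))
      stop_classed("invalid_argument",
                   "could not place archetypes at the requested separation")
  }
  out
}

#' Archetype mixture specification
#'
#' @param archetypes Matrix of prototypes from [generate_archetypes()] (or
#'   hand-built, rows = archetypes, entries in `{-1, 0, 1}`).
#' @param flip_rate Per-coordinate probability in `[0, 0.5)` of flipping a
#'   value to the opposite class (molecular individuality / model error).
#' @param uncertain_rate Per-coordinate probability in `[0, 0.5)` of
#'   replacing the value with 0 (an abstaining or out-of-domain prediction).
#' @param weights Mixture proportions (default uniform); must sum to 1.
#' @return An `archetype_spec` list.
#' @export
archetype_spec <- function(archetypes, flip_rate = 0.05, uncertain_rate = 0.05,
                           weights = NULL) {
  archetypes <- as.matrix(archetypes)
  if (!is_ternary(archetypes))
    stop_classed("invalid_argument", "archetype entries must be -1, 0 or 1")
  if (flip_rate < 0 || flip_rate >= 0.5 || uncertain_rate < 0 || uncertain_rate >= 0.5)
    stop_classed("invalid_argument", "rates must lie in [0, 0.5)")
  k <- nrow(archetypes)
  if (is.null(weights)) weights <- rep(1 / k, k)
  if (length(weights) != k || abs(sum(weights) - 1) > 1e-8 || any(weights < 0))
    stop_classed("invalid_argument", "weights must be non-negative and sum to 1")
  structure(list(archetypes = archetypes, flip_rate = flip_rate,
                 uncertain_rate = uncertain_rate, weights = weights),
            class = "archetype_spec")
}

#' Generate archetype-clustered ternary fingerprints
#'
#' Each molecule is drawn from a mixture component, then each coordinate is
#' independently flipped to the opposite class with probability `flip_rate`
#' and set to 0 (uncertain) with probability `uncertain_rate`. The true
#' component is returned as ground truth for purity / region-recovery tests.
#'
#' @param spec An [archetype_spec()].
#' @param n Number of molecules (>= 1).
#' @param seed Integer seed; the same seed reproduces the sample exactly.
#' @param catalog Property catalog naming the columns (its size must match
#'   the archetype length).
#' @return A list: `fingerprints` (an `adme_fingerprints` table) and
#'   `archetype` (integer vector of true component indices).
#' @export
generate_fingerprints <- function(spec, n, seed = 1L, catalog = adme_catalog()) {
  if (!inherits(spec, "archetype_spec"))
    stop_classed("invalid_argument", "spec must be an archetype_spec")
  if (n < 1) stop_classed("invalid_argument", "n must be >= 1")
  d <- ncol(spec$archetypes)
  if (d != nrow(catalog))
    stop_classed("invalid_argument",
                 sprintf("archetype length %d != catalog size %d", d, nrow(catalog)))
  set.seed(seed)
  comp <- sample.int(nrow(spec$archetypes), n, replace = TRUE,
                     prob = spec$weights)
  vals <- spec$archetypes[comp, , drop = FALSE]
  flip <- matrix(stats::runif(n * d) < spec$flip_rate, n, d)
  vals[flip] <- -vals[flip]
  zero <- matrix(stats::runif(n * d) < spec$uncertain_rate, n, d)
  vals[zero] <- 0
  ids <- sprintf("SYN%05d", seq_len(n))
  list(fingerprints = adme_fingerprints(ids, vals, catalog = catalog),
       archetype = comp)
}

#' Generate a synthetic QSPR classification dataset
#'
#' Two Gaussian class-conditional descriptor clouds (unit spread per
#' coordinate) whose means are `separation` apart along a random direction,
#' with stratified exact class counts and labels flipped at `noise_rate`.
#' Emulates the descriptor-matrix-plus-binary-labels inputs the per-property
#' classifiers are trained on.
#'
#' @param n_molecules Total number of molecules.
#' @param n_descriptors Number of descriptor columns (>= 2).
#' @param class_balance Fraction of +1 molecules (stratified, exact count).
#' @param separation Distance between class means in units of the
#'   per-coordinate spread (>= 0).
#' @param noise_rate Label flip probability in `[0, 0.5)`.
#' @param seed Integer seed.
#' @return A list: `descriptors` (a `descriptor_matrix`), `labels` (named
#'   vector in `{-1, 1}`) and `true_labels` (before noise).
#' @export
generate_qspr_dataset <- function(n_molecules, n_descriptors = 10L,
                                  class_balance = 0.5, separation = 4,
                                  noise_rate = 0, seed = 1L) {
  if (n_molecules < 4 || n_descriptors < 2)
    stop_classed("invalid_argument", "need n_molecules >= 4 and n_descriptors >= 2")
  if (separation < 0) stop_classed("invalid_argument", "separation must be >= 0")
  if (noise_rate < 0 || noise_rate >= 0.5)
    stop_classed("invalid_argument", "noise_rate must lie in [0, 0.5)")
  if (class_balance <= 0 || class_balance >= 1)
    stop_classed("invalid_argument", "class_balance must lie in (0, 1)")
  set.seed(seed)
  n_pos <- round(n_molecules * class_balance)
  n_pos <- max(2L, min(n_molecules - 2L, n_pos))
  truth <- c(rep(1L, n_pos), rep(-1L, n_molecules - n_pos))
  u <- stats::rnorm(n_descriptors)
  u <- u / sqrt(sum(u^2))
  X <- matrix(stats::rnorm(n_molecules * n_descriptors), n_molecules) +
    outer(truth * separation / 2, u)
  colnames(X) <- paste0("desc", seq_len(n_descriptors))
  labels <- truth
  flip <- stats::runif(n_molecules) < noise_rate
  labels[flip] <- -labels[flip]
  ids <- sprintf("QSPR%05d", seq_len(n_molecules))
  list(descriptors = descriptor_matrix(ids, X),
       labels = stats::setNames(labels, ids),
       true_labels = stats::setNames(truth, ids))
}

#' Correlated "naive" property labels
#'
#' Copies one in-map property's per-molecule value and flips the decided
#' values with probability `(1 - r) / 2`, so the expected product (match
#' coefficient) between decided source and naive values is `r`, i.e. raw
#' agreement `(1 + r) / 2`. Used to emulate a property not included in the
#' map (e.g. solubility) that is nevertheless linked to the mapped ADME
#' behaviour.
#'
#' @param fp An `adme_fingerprints` table.
#' @param property_key Source property to correlate with.
#' @param r Target association strength in `(0, 1]`.
#' @param seed Integer seed.
#' @return A named ternary vector (names = molecule ids).
#' @export
generate_correlated_property <- function(fp, property_key, r = 0.9, seed = 1L) {
  if (!property_key %in% colnames(fp))
    stop_classed("unknown_property", "no such property column: ", property_key)
  if (r <= 0 || r > 1) stop_classed("invalid_argument", "r must lie in (0, 1]")
  v <- as.integer(fp[[property_key]])
  set.seed(seed)
  flip <- stats::runif(length(v)) < (1 - r) / 2
  v[flip] <- -v[flip]
  stats::setNames(v, fp$molecule_id)
}

#' Write a deterministic fixture mini-world
#'
#' Generates and writes, under `dir`: archetype-clustered fingerprints for
#' 3 archetypes x 400 molecules (`fingerprints.csv`, plus `archetypes.csv`
#' with the ground-truth component of each molecule), a correlated naive
#' property (`naive_labels.csv`, correlation 0.9 with `CACO2_PERM`), one
#' QSPR descriptor/label dataset for each of three representative properties
#' (`qspr_<KEY>_descriptors.csv` / `_labels.csv`, shaped like small versions
#' of the published datasets), the property catalog (`catalog.json`) and a
#' manifest recording seeds, counts and the archetype purity obtained by
#' training a map on the fixture fingerprints (`manifest.json`).
#'
#' Two invocations with the same seed produce byte-identical files.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed driving every generator.
#' @param som_rows,som_cols,som_epochs Map size/epochs used for the recorded
#'   purity check.
#' @return The manifest, invisibly.
#' @export
make_fixture_suite <- function(dir, seed = 1L, som_rows = 14L, som_cols = 14L,
                               som_epochs = 8L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- 1200L
  arch <- generate_archetypes(3L, seed = derive_seed(seed, 11L))
  spec <- archetype_spec(arch, flip_rate = 0.05, uncertain_rate = 0.05)
  gen <- generate_fingerprints(spec, n, seed = derive_seed(seed, 12L))
  write_fingerprints(gen$fingerprints, file.path(dir, "fingerprints.csv"))
  utils::write.csv(data.frame(molecule_id = gen$fingerprints$molecule_id,
                              archetype = gen$archetype),
                   file.path(dir, "archetypes.csv"), row.names = FALSE,
                   quote = FALSE)
  naive <- generate_correlated_property(gen$fingerprints, "CACO2_PERM",
                                        r = 0.9, seed = derive_seed(seed, 13L))
  utils::write.csv(data.frame(molecule_id = names(naive), label = naive),
                   file.path(dir, "naive_labels.csv"), row.names = FALSE,
                   quote = FALSE)
  qspr_props <- c(PGP_INHIB = 300L, BCRP_INHIB = 240L, METASTAB_human = 300L)
  for (i in seq_along(qspr_props)) {
    key <- names(qspr_props)[i]
    ds <- generate_qspr_dataset(qspr_props[[i]], n_descriptors = 10L,
                                separation = 6, noise_rate = 0,
                                seed = derive_seed(seed, 20L + i))
    utils::write.csv(
      data.frame(molecule_id = ds$descriptors$molecule_id, ds$descriptors$X,
                 check.names = FALSE),
      file.path(dir, paste0("qspr_", key, "_descriptors.csv")),
      row.names = FALSE, quote = FALSE)
    utils::write.csv(data.frame(molecule_id = names(ds$labels),
                                label = ds$labels),
                     file.path(dir, paste0("qspr_", key, "_labels.csv")),
                     row.names = FALSE, quote = FALSE)
  }
  write_catalog_json(adme_catalog(), file.path(dir, "catalog.json"))
  map <- som_train(som_init(som_config(som_rows, som_cols, epochs = som_epochs,
                                       seed = derive_seed(seed, 30L))),
                   gen$fingerprints)
  purity <- archetype_purity(map, gen$fingerprints, gen$archetype)
  manifest <- list(schema = "admespace-fixtures/1", seed = seed,
                   n_molecules = n, n_archetypes = 3L,
                   flip_rate = 0.05, uncertain_rate = 0.05,
                   naive_property = list(source = "CACO2_PERM", r = 0.9),
                   qspr_properties = as.list(qspr_props),
                   som = list(rows = som_rows, cols = som_cols,
                              epochs = som_epochs),
                   archetype_purity = purity,
                   catalog_version = catalog_version())
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Purity of BMU assignments against ground-truth archetypes
#'
#' Assigns every molecule to its BMU, gives each node the majority archetype
#' of its members, and returns the fraction of molecules whose own archetype
#' matches their node's majority. A well-formed map separates archetypes into
#' distinct regions, driving purity toward 1.
#'
#' @param map A trained `som_map`.
#' @param fps The fingerprints used for training.
#' @param archetype Integer vector of true components.
#' @return A number in `[0, 1]`.
#' @export
archetype_purity <- function(map, fps, archetype) {
  X <- as_fp_matrix(fps, map$dim)
  bm <- bmu_batch(map, X)
  correct <- 0L
  for (k in unique(bm$node)) {
    members <- archetype[bm$node == k]
    correct <- correct + max(tabulate(members))
  }
  correct / length(archetype)
}
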