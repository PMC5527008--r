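#' Per-property map layers
#'
#' A layer is the distribution of one ADME property over the map: the value
#' at each ON node is that property's coordinate of the node fingerprint
#' (+1 / -1 / 0), and OFF nodes carry `NA` (no data — unpopulated nodes hold
#' no information). Stacking the twenty layers recovers the per-node ADME
#' fingerprints: the vector that goes perpendicularly through all layers at
#' one grid position is that node's profile.
#'
#' @param map A trained `som_map`.
#' @param property_key A catalog property key.
#' @param tau Node-fingerprint threshold (see [node_fingerprint()]).
#' @param catalog The property catalog.
#' @return A `map_layer`: list with `property_key` and `values`, a
#'   `rows x cols` integer matrix in `{-1, 0, 1, NA}` indexed by 0-based grid
#'   coordinates (`values[r + 1, c + 1]`).
#' @export
extract_layer <- function(map, property_key, tau = 1 / 3,
                          catalog = adme_catalog()) {
  if (!property_key %in% catalog$key)
    stop_classed("unknown_property", "unknown property key: ", property_key)
  if (!isTRUE(map$trained))
    stop_classed("model_not_trained", "map must be trained first")
  j <- match(property_key, catalog$key)
  w <- map$weights[, j]
  v <- ifelse(w > tau, 1L, ifelse(w < -tau, -1L, 0L))
  v[map$status == "OFF"] <- NA_integer_
  new_layer(property_key, matrix(v, nrow = map$config$rows, byrow = TRUE))
}

new_layer <- function(property_key, values) {
  structure(list(property_key = property_key, values = values),
            class = "map_layer")
}

#' @export
print.map_layer <- function(x, ...) {
  cat(sprintf("Map layer %s (%dx%d): %d decided, %d uncertain, %d no-data\n",
              x$property_key, nrow(x$values), ncol(x$values),
              sum(x$values != 0, na.rm = TRUE),
              sum(x$values == 0, na.rm = TRUE), sum(is.na(x$values))))
  invisible(x)
}

check_same_grid <- function(...) {
  layers <- list(...)
  dims <- vapply(layers, function(l) dim(l$values), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_classed("layer_mismatch", "layers come from maps of different size")
  invisible(dims[, 1])
}

new_region_coloring <- function(name, categories, palette) {
  stopifnot(all(categories %in% palette))
  structure(list(name = name, categories = categories, palette = palette),
            class = "region_coloring")
}

#' @export
print.region_coloring <- function(x, ...) {
  cat(sprintf("Region coloring '%s' (%dx%d):\n", x$name,
              nrow(x$categories), ncol(x$categories)))
  print(table(factor(x$categories, levels = x$palette)))
  invisible(x)
}

#' Permeability / active-transport regions
#'
#' Multi-layer combination for absorption triage: keeps only the nodes with
#' low Caco-2 permeability, then colors them by the efflux protein whose
#' transport can explain it — purple for Pgp recognition only, orange for
#' BCRP only, black when both substrates' layers light up. Low-permeability
#' nodes where neither transporter is implicated stay uncolored (`"none"`):
#' their low permeability could be due to other factors such as high
#' polarity. Nodes that are not low-permeability (including uncertain and
#' no-data nodes) are `"none"` as well.
#'
#' @param perm Caco-2 permeability layer (`CACO2_PERM`).
#' @param pgp Pgp recognition layer (`PGP_RECOG`).
#' @param bcrp BCRP recognition layer (`BCRP_RECOG`).
#' @return A `region_coloring` with palette
#'   `c("purple", "orange", "black", "none")`.
#' @export
transport_permeability_regions <- function(perm, pgp, bcrp) {
  check_same_grid(perm, pgp, bcrp)
  low <- eqv(perm$values, -1)
  p <- eqv(pgp$values, 1); b <- eqv(bcrp$values, 1)
  cats <- matrix("none", nrow(perm$values), ncol(perm$values))
  cats[low & p & !b] <- "purple"
  cats[low & b & !p] <- "orange"
  cats[low & p & b]  <- "black"
  new_region_coloring("transport_permeability", cats,
                      c("purple", "orange", "black", "none"))
}

#' Metabolism / CYP-implication regions
#'
#' Keeps only the nodes predicted metabolically unstable in human, then
#' colors them by which CYP isoform is highly implicated: orange for 1A2
#' only, pink for 2D6 only, cyan for 3A4 only, black when two or more
#' isoforms are involved (lower drug-drug-interaction risk via metabolism,
#' but harder metabolite prediction). Uncertain (0) isoform values never
#' count as implicated. Stable, uncertain and no-data nodes are `"none"`.
#'
#' @param metastab Human metabolic stability layer (`METASTAB_human`).
#' @param cyp_layers Named list of the three CYP-implication layers, names
#'   `CYP1A2_PERC`, `CYP2D6_PERC`, `CYP3A4_PERC`.
#' @return A `region_coloring` with palette
#'   `c("orange", "pink", "cyan", "black", "none")`.
#' @export
metabolism_implication_overlay <- function(metastab, cyp_layers) {
  wanted <- c("CYP1A2_PERC", "CYP2D6_PERC", "CYP3A4_PERC")
  if (!all(wanted %in% names(cyp_layers)))
    stop_classed("layer_mismatch", "cyp_layers must be named ",
                 paste(wanted, collapse = ", "))
  cyp_layers <- cyp_layers[wanted]
  do.call(check_same_grid, c(list(metastab), cyp_layers))
  unstable <- eqv(metastab$values, -1)
  hi <- lapply(cyp_layers, function(l) eqv(l$values, 1))
  n_hi <- Reduce("+", hi)
  cats <- matrix("none", nrow(metastab$values), ncol(metastab$values))
  cats[unstable & n_hi == 1 & hi$CYP1A2_PERC] <- "orange"
  cats[unstable & n_hi == 1 & hi$CYP2D6_PERC] <- "pink"
  cats[unstable & n_hi == 1 & hi$CYP3A4_PERC] <- "cyan"
  cats[unstable & n_hi >= 2] <- "black"
  new_region_coloring("metabolism_implication", cats,
                      c("orange", "pink", "cyan", "black", "none"))
}

#' Bioavailability and DDI-risk regions
#'
#' Flags "risky" nodes — low absorption, low metabolic stability, exactly one
#' CYP isoform implicated and Pgp recognition — where bioavailability is
#' expected to be poor and a single inhibited enzyme or transporter can block
#' clearance (high drug-drug-interaction risk). "Safe" nodes show the
#' opposite profile: high absorption, high stability, two or more isoforms
#' implicated and no Pgp recognition. A 0 (uncertain) in any required
#' property fails the conjunction, so such nodes are `"neutral"`.
#'
#' @param caco2 Caco-2 permeability layer.
#' @param metastab Human metabolic stability layer.
#' @param pgp_recog Pgp recognition layer.
#' @param cyp_layers Named list of the three CYP-implication layers (see
#'   [metabolism_implication_overlay()]).
#' @return A `region_coloring` with palette `c("risky", "safe", "neutral")`.
#' @export
bioavailability_risk <- function(caco2, metastab, pgp_recog, cyp_layers) {
  wanted <- c("CYP1A2_PERC", "CYP2D6_PERC", "CYP3A4_PERC")
  if (!all(wanted %in% names(cyp_layers)))
    stop_classed("layer_mismatch", "cyp_layers must be named ",
                 paste(wanted, collapse = ", "))
  cyp_layers <- cyp_layers[wanted]
  do.call(check_same_grid, c(list(caco2, metastab, pgp_recog), cyp_layers))
  n_hi <- Reduce("+", lapply(cyp_layers, function(l) eqv(l$values, 1)))
  risky <- eqv(caco2$values, -1) & eqv(metastab$values, -1) &
    n_hi == 1 & eqv(pgp_recog$values, 1)
  safe <- eqv(caco2$values, 1) & eqv(metastab$values, 1) &
    n_hi >= 2 & eqv(pgp_recog$values, -1)
  cats <- matrix("neutral", nrow(caco2$values), ncol(caco2$values))
  cats[risky] <- "risky"
  cats[safe] <- "safe"
  new_region_coloring("bioavailability_risk", cats,
                      c("risky", "safe", "neutral"))
}

#' Aggregate per-molecule labels into a per-node layer
#'
#' Builds an experimental (or naive-property) overlay: each node hit by at
#' least one labeled, non-outlier projected molecule gets the strict majority
#' of the +1/-1 labels of its molecules (ties and 0-only nodes give 0);
#' unhit nodes carry `NA`. This is how experimentally measured values — or a
#' property not used to build the map at all — are painted onto the map for
#' comparison with the predicted layers.
#'
#' @param map The trained `som_map` the projections came from.
#' @param projections A `som_projection` data frame (see [som_project()]).
#' @param labels Named ternary vector (names = molecule ids) or unnamed
#'   vector aligned with `projections`.
#' @param property_key Name recorded on the resulting layer.
#' @param include_outliers Count molecules flagged as outliers (default
#'   FALSE: the map makes no claim about them).
#' @return A `map_layer`.
#' @export
aggregate_node_labels <- function(map, projections, labels,
                                  property_key = "overlay",
                                  include_outliers = FALSE) {
  if (!is.null(names(labels)))
    labels <- labels[match(projections$molecule_id, names(labels))]
  if (length(labels) != nrow(projections))
    stop_classed("invalid_argument", "one label per projected molecule required")
  keep <- !is.na(labels) & labels %in% c(-1, 0, 1)
  if (!include_outliers) keep <- keep & !projections$is_outlier
  vals <- matrix(NA_integer_, map$config$rows, map$config$cols)
  if (any(keep)) {
    key <- paste(projections$row[keep], projections$col[keep])
    pos <- tapply(labels[keep] == 1, key, sum)
    neg <- tapply(labels[keep] == -1, key, sum)
    rc <- do.call(rbind, lapply(strsplit(names(pos), " "), as.integer))
    v <- ifelse(pos > neg, 1L, ifelse(neg > pos, -1L, 0L))
    vals[rc + 1L] <- v
  }
  new_layer(property_key, vals)
}

#' @rdname aggregate_node_labels
#' @export
naive_property_overlay <- function(map, projections, labels,
                                   property_key = "naive_property") {
  aggregate_node_labels(map, projections, labels, property_key = property_key)
}

#' Agreement between a predicted layer and an overlay
#'
#' Fraction of nodes carrying both a decided (+1/-1) predicted value and a
#' decided overlay value on which the two agree. Uncertain (0) and no-data
#' nodes on either side are not comparable and are excluded.
#'
#' @param predicted A `map_layer` from [extract_layer()].
#' @param overlay A `map_layer` from [aggregate_node_labels()].
#' @return A number in `[0, 1]`.
#' @export
experimental_agreement <- function(predicted, overlay) {
  check_same_grid(predicted, overlay)
  comparable <- !is.na(predicted$values) & predicted$values != 0 &
    !is.na(overlay$values) & overlay$values != 0
  if (!any(comparable))
    stop_classed("empty_comparison", "no nodes carry both decided values")
  mean(predicted$values[comparable] == overlay$values[comparable])
}

#' Dispersion of a projected molecule series on the map
#'
#' For a series of analogues projected onto the map: counts the molecules
#' landing outside the applicability domain (outliers or OFF nodes, which are
#' not considered further), then measures Euclidean grid-coordinate distances
#' within and between the given groups. Structural analogues with divergent
#' ADME behaviour (ADME-cliffs) show up as groups in distant map regions:
#' between-group distance well above within-group distance.
#'
#' @param projections A `som_projection` data frame.
#' @param groups Group label per molecule (named by molecule id, or aligned).
#' @return A list: `n_off` (outlier or OFF-node hits), `n_used`,
#'   `within_group_distance` (named per group; `NA` for singleton groups),
#'   `between_group_distance` (mean over pairs in different groups; `NA` if
#'   fewer than two groups remain).
#' @export
series_dispersion <- function(projections, groups) {
  if (!is.null(names(groups)))
    groups <- groups[match(projections$molecule_id, names(groups))]
  if (length(groups) != nrow(projections))
    stop_classed("invalid_argument", "one group label per molecule required")
  off <- projections$is_outlier | !projections$node_on
  keep <- !off
  if (sum(keep) < 2L)
    stop_classed("insufficient_projections",
                 "fewer than 2 molecules inside the applicability domain")
  r <- projections$row[keep]; c <- projections$col[keep]; g <- groups[keep]
  d <- as.matrix(stats::dist(cbind(r, c)))
  same <- outer(g, g, "==")
  pair <- upper.tri(d)
  within <- vapply(unique(g), function(gi) {
    m <- pair & same & outer(g == gi, g == gi, "&")
    if (!any(m)) NA_real_ else mean(d[m])
  }, numeric(1))
  between <- if (any(pair & !same)) mean(d[pair & !same]) else NA_real_
  list(n_off = sum(off), n_used = sum(keep),
       within_group_distance = within,
       between_group_distance = between)
}

#' Write a layer or coloring to CSV
#'
#' Layers are written as `row,col,value` (0-based coordinates, value in
#' `{-1,0,1,NA}`); colorings as `row,col,category`.
#' @param x A `map_layer` or `region_coloring`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_layer_csv <- function(x, path) {
  rows <- nrow(if (inherits(x, "map_layer")) x$values else x$categories)
  cols <- ncol(if (inherits(x, "map_layer")) x$values else x$categories)
  grid <- expand.grid(col = seq_len(cols) - 1L, row = seq_len(rows) - 1L)
  df <- if (inherits(x, "map_layer")) {
    data.frame(row = grid$row, col = grid$col,
               value = as.vector(t(x$values)))
  } else {
    data.frame(row = grid$row, col = grid$col,
               category = as.vector(t(x$categories)))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
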