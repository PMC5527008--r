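#' ADME fingerprint tables
#'
#' An ADME fingerprint is the ordered vector of the twenty ternary predicted
#' classes, one per catalog property; it replaces structural descriptors as
#' the molecular description. A fingerprint table (`adme_fingerprints`) is a
#' data frame with a `molecule_id` column followed by the twenty property
#' columns in catalog order, every cell in `{-1, 0, 1}`.
#'
#' @param molecule_id Character vector of unique molecule identifiers
#'   (opaque strings; no structure parsing is done).
#' @param values An `n x 20` matrix (or data frame) of ternary values whose
#'   columns follow catalog order. Column names, if present, must equal the
#'   catalog keys.
#' @param catalog The property catalog.
#' @return A data frame of class `adme_fingerprints`.
#' @export
adme_fingerprints <- function(molecule_id, values, catalog = adme_catalog()) {
  values <- as.matrix(values)
  if (ncol(values) != nrow(catalog))
    stop_classed("malformed_fingerprint",
                 sprintf("fingerprints must have %d property columns, got %d",
                         nrow(catalog), ncol(values)))
  if (!is_ternary(values))
    stop_classed("malformed_fingerprint", "fingerprint values must be -1, 0 or 1")
  if (!is.null(colnames(values)) && !identical(colnames(values), catalog$key))
    stop_classed("malformed_fingerprint",
                 "fingerprint columns must follow catalog order")
  if (length(molecule_id) != nrow(values))
    stop_classed("malformed_fingerprint", "one molecule_id per row required")
  if (anyDuplicated(molecule_id))
    stop_classed("malformed_fingerprint", "duplicate molecule_id")
  df <- data.frame(molecule_id = as.character(molecule_id),
                   values, stringsAsFactors = FALSE, check.names = FALSE)
  colnames(df) <- c("molecule_id", catalog$key)
  class(df) <- c("adme_fingerprints", "data.frame")
  df
}

# Numeric matrix of the ternary values (rows = molecules, cols = properties).
fingerprint_matrix <- function(fp) {
  m <- as.matrix(fp[, setdiff(colnames(fp), "molecule_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- fp$molecule_id
  m
}

#' Interpret a fingerprint in words
#'
#' Maps each ternary value to the property's class meaning: +1 to the
#' positive label, -1 to the negative label, 0 to `"uncertain"` (the model
#' was not able to classify the molecule, or it fell outside the
#' applicability domain).
#'
#' @param fp A numeric vector of 20 ternary values in catalog order, or a
#'   one-row `adme_fingerprints` table.
#' @param catalog The property catalog.
#' @return A data frame with columns `key` and `label`.
#' @export
#' @examples
#' v <- rep(0, 20); v[19] <- 1  # PGP_INHIB
#' interpret_fingerprint(v)$label[19]  # "Inhibitor"
interpret_fingerprint <- function(fp, catalog = adme_catalog()) {
  if (is.data.frame(fp)) {
    if (nrow(fp) != 1L)
      stop_classed("malformed_fingerprint", "expected a single fingerprint")
    fp <- as.numeric(fingerprint_matrix(fp)[1, ])
  }
  if (length(fp) != nrow(catalog))
    stop_classed("malformed_fingerprint",
                 sprintf("fingerprint length %d != catalog size %d",
                         length(fp), nrow(catalog)))
  if (!is_ternary(fp))
    stop_classed("malformed_fingerprint", "fingerprint values must be -1, 0 or 1")
  label <- ifelse(fp == 1, catalog$positive_label,
                  ifelse(fp == -1, catalog$negative_label, "uncertain"))
  data.frame(key = catalog$key, label = label, stringsAsFactors = FALSE)
}

#' Euclidean distance between two ADME fingerprints
#'
#' Distance over the raw ternary coordinates, so the uncertain class 0 sits
#' equidistant from both decided classes. This is the metric the SOM engine
#' uses for best-matching-unit search.
#'
#' @param a,b Numeric vectors of equal length with entries in `{-1, 0, 1}`.
#' @return A non-negative number; 0 iff `a` and `b` are identical.
#' @export
fingerprint_distance <- function(a, b) {
  if (length(a) != length(b))
    stop_classed("malformed_fingerprint", "fingerprints differ in length")
  sqrt(sum((as.numeric(a) - as.numeric(b))^2))
}

#' Number of possible ADME profiles
#'
#' `levels ^ n_props`: with 20 properties at two decided levels (omitting the
#' grey zone) there are `2^20 = 1,048,576` distinct ADME fingerprints — more
#' than a million — which a 2500-node map condenses.
#'
#' @param n_props Number of properties (>= 1).
#' @param levels Number of levels per property (>= 1).
#' @return The exact count as a double.
#' @export
#' @examples
#' count_possible_profiles(20, 2)  # 1048576
count_possible_profiles <- function(n_props, levels) {
  if (!is.numeric(n_props) || !is.numeric(levels) ||
      n_props < 1 || levels < 1 ||
      n_props != round(n_props) || levels != round(levels))
    stop_classed("invalid_argument", "n_props and levels must be positive integers")
  as.numeric(levels)^as.numeric(n_props)
}

#' Read / write fingerprint CSV
#'
#' The on-disk form is a CSV with header `molecule_id` plus the twenty
#' canonical property keys, cells exactly `-1`, `0` or `1`.
#'
#' @param fp An `adme_fingerprints` table.
#' @param path File path.
#' @param catalog The property catalog.
#' @return `write_fingerprints()` returns `path` invisibly;
#'   `read_fingerprints()` returns an `adme_fingerprints` table.
#' @export
write_fingerprints <- function(fp, path) {
  utils::write.csv(as.data.frame(fp), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(path, catalog = adme_catalog()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!identical(colnames(df), c("molecule_id", catalog$key)))
    stop_classed("malformed_fingerprint",
                 "fingerprint CSV header must be molecule_id + catalog keys: ", path)
  adme_fingerprints(df$molecule_id, as.matrix(df[, -1, drop = FALSE]),
                    catalog = catalog)
}
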