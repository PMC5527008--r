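#' The ADME property catalog
#'
#' The twenty ADME endpoints that define the fingerprint, in their fixed
#' canonical order (alphabetical by property key, which is also the order the
#' endpoints are conventionally tabulated in). The order is versioned: it
#' defines the column order of every fingerprint table and the coordinate
#' order of every SOM weight vector, so it must never change within a catalog
#' version.
#'
#' Each property carries the human-readable meaning of the +1 and -1 classes
#' (e.g. Inhibitor / Non-inhibitor) and, where the class assignment is derived
#' from an experimental measurement, the thresholds that define the two
#' classes. The gap between the two thresholds is a deliberate grey zone:
#' measurements falling there are labelled 0 (uncertain).
#'
#' @return A data frame of class `adme_catalog` with one row per property:
#'   `key`, `positive_label`, `negative_label`, `measurement_kinds`
#'   (comma-separated kinds accepted by [label_from_measurement()], `""` when
#'   classes come pre-assigned).
#' @seealso [label_from_measurement()], [interpret_fingerprint()]
#' @export
#' @examples
#' cat20 <- adme_catalog()
#' nrow(cat20)          # 20
#' cat20$key[1]         # "BCRP_INHIB"
adme_catalog <- function() {
  df <- data.frame(
    key = c("BCRP_INHIB", "BCRP_RECOG", "BRAIN_PERM", "CACO2_PERM", "CLEAR",
            "CYP1A2_INHIB", "CYP1A2_PERC", "CYP2C9_INHIB", "CYP2D6_INHIB",
            "CYP2D6_PERC", "CYP3A4_INHIB", "CYP3A4_PERC", "METASTAB_human",
            "METASTAB_mouse", "METASTAB_rat", "MRDD", "OATP_INHIB",
            "OCT2_INHIB", "PGP_INHIB", "PGP_RECOG"),
    positive_label = c("Inhibitor", "Substrate", "Permeable", "Permeable",
                       "Metabolic", "Inhibitor", "High implication",
                       "Inhibitor", "Inhibitor", "High implication",
                       "Inhibitor", "High implication", "Stable", "Stable",
                       "Stable", "Low", "Inhibitor", "Inhibitor", "Inhibitor",
                       "Substrate"),
    negative_label = c("Non-inhibitor", "Non-substrate", "Non-permeable",
                       "Non-permeable", "Renal", "Non-inhibitor",
                       "Low implication", "Non-inhibitor", "Non-inhibitor",
                       "Low implication", "Non-inhibitor", "Low implication",
                       "Unstable", "Unstable", "Unstable", "High",
                       "Non-inhibitor", "Non-inhibitor", "Non-inhibitor",
                       "Non-substrate"),
    stringsAsFactors = FALSE
  )
  df$measurement_kinds <- vapply(df$key, function(k) {
    r <- .threshold_rules()[[k]]
    if (is.null(r)) "" else paste(names(r), collapse = ",")
  }, character(1))
  class(df) <- c("adme_catalog", "data.frame")
  df
}

#' Catalog version tag
#'
#' Identifies the property set and its column order. Stored in fingerprint
#' files and trained maps so mismatched artifacts are detected at load time.
#' @return A character scalar.
#' @export
catalog_version <- function() "adme-catalog/1"

# Experimental class-assignment thresholds, one rule set per property that is
# labelled from measurements rather than shipped with pre-assigned classes.
# Each rule is pos/neg predicates on the measurement value; inequalities are
# honoured exactly as printed (strict vs non-strict), and the gap between the
# two predicates is the grey zone (label 0).
.threshold_rules <- function() {
  list(
    BCRP_INHIB = list(
      IC50_uM        = list(pos = function(v) v <= 15, neg = function(v) v > 50),
      inhibition_pct = list(pos = function(v) v >= 50, neg = function(v) v < 30)
    ),
    BRAIN_PERM = list(
      Kp_ratio = list(pos = function(v) v > 0.8, neg = function(v) v < 0.2)
    ),
    CACO2_PERM = list(
      fraction_absorbed_pct = list(pos = function(v) v > 90, neg = function(v) v < 40)
    ),
    CYP1A2_PERC = list(
      cyp_implication_pct = list(pos = function(v) v > 70, neg = function(v) v < 10)
    ),
    CYP2D6_PERC = list(
      cyp_implication_pct = list(pos = function(v) v > 70, neg = function(v) v < 10)
    ),
    CYP3A4_PERC = list(
      cyp_implication_pct = list(pos = function(v) v > 70, neg = function(v) v < 10)
    ),
    CYP1A2_INHIB = list(
      IC50_uM = list(pos = function(v) v < 2, neg = function(v) v > 15)
    ),
    CYP2C9_INHIB = list(
      IC50_uM = list(pos = function(v) v < 2, neg = function(v) v > 8)
    ),
    CYP2D6_INHIB = list(
      IC50_uM = list(pos = function(v) v < 1, neg = function(v) v > 10)
    ),
    CYP3A4_INHIB = list(
      IC50_uM = list(pos = function(v) v < 1, neg = function(v) v > 10)
    ),
    METASTAB_human = list(
      metabolic_stability_pct = list(pos = function(v) v > 60, neg = function(v) v < 30)
    ),
    METASTAB_rat = list(
      metabolic_stability_pct = list(pos = function(v) v > 60, neg = function(v) v < 30)
    ),
    METASTAB_mouse = list(
      metabolic_stability_pct = list(pos = function(v) v > 60, neg = function(v) v < 30)
    ),
    BCRP_RECOG = list(
      boolean_transport = list(pos = function(v) v >= 0.5, neg = function(v) v < 0.5)
    )
  )
}

.measurement_kinds <- c("IC50_uM", "inhibition_pct", "fraction_absorbed_pct",
                        "Kp_ratio", "cyp_implication_pct",
                        "metabolic_stability_pct", "boolean_transport",
                        "class_label")

#' Construct an experimental measurement
#'
#' @param kind One of `"IC50_uM"`, `"inhibition_pct"`,
#'   `"fraction_absorbed_pct"`, `"Kp_ratio"`, `"cyp_implication_pct"`,
#'   `"metabolic_stability_pct"`, `"boolean_transport"`, or `"class_label"`
#'   (a pre-assigned ternary class, accepted by every property).
#' @param value Numeric value in the units implied by `kind`. Percent kinds
#'   must lie in `[0, 100]`; IC50 and Kp must be non-negative; `class_label`
#'   must be -1, 0 or +1.
#' @return A `measurement` object.
#' @export
measurement <- function(kind, value) {
  kind <- match.arg(kind, .measurement_kinds)
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value))
    stop("measurement value must be a single finite number", call. = FALSE)
  pct <- c("inhibition_pct", "fraction_absorbed_pct", "cyp_implication_pct",
           "metabolic_stability_pct")
  if (kind %in% pct && (value < 0 || value > 100))
    stop(sprintf("%s must lie in [0, 100]", kind), call. = FALSE)
  if (kind %in% c("IC50_uM", "Kp_ratio") && value < 0)
    stop(sprintf("%s must be non-negative", kind), call. = FALSE)
  if (kind == "class_label" && !value %in% c(-1, 0, 1))
    stop("class_label must be -1, 0 or +1", call. = FALSE)
  structure(list(kind = kind, value = value), class = "measurement")
}

#' Ternary class label from an experimental measurement
#'
#' Applies a property's class-assignment thresholds to one or more
#' measurements. Where a property accepts two measurement kinds (e.g. BCRP
#' inhibition is defined on either IC50 or percent inhibition), either
#' criterion suffices; if the supplied measurements disagree (one says +1,
#' another -1) the conservative result is 0, mirroring the exclusion of
#' ambiguous compounds at dataset-assembly time. A measurement whose value
#' falls between the two thresholds lands in the grey zone and is labelled 0.
#'
#' Properties whose public datasets ship pre-assigned categories (e.g. Pgp
#' inhibition) carry no threshold rule; they accept only `class_label`
#' measurements, which pass through unchanged.
#'
#' @param property_key A catalog property key, e.g. `"BCRP_INHIB"`.
#' @param m A [measurement()] or a list of them.
#' @param catalog The property catalog (defaults to [adme_catalog()]).
#' @return An integer in `{-1, 0, +1}`.
#' @export
#' @examples
#' label_from_measurement("BCRP_INHIB", measurement("IC50_uM", 10))   # +1
#' label_from_measurement("BCRP_INHIB", measurement("IC50_uM", 60))   # -1
#' label_from_measurement("BRAIN_PERM", measurement("Kp_ratio", 0.5)) #  0
label_from_measurement <- function(property_key, m, catalog = adme_catalog()) {
  if (!property_key %in% catalog$key)
    stop_classed("unknown_property", "unknown property key: ", property_key)
  if (inherits(m, "measurement")) m <- list(m)
  if (!length(m) || !all(vapply(m, inherits, logical(1), "measurement")))
    stop_classed("incompatible_measurement", "m must be measurement objects")
  rules <- .threshold_rules()[[property_key]]
  labels <- vapply(m, function(mi) {
    if (mi$kind == "class_label") return(as.integer(mi$value))
    rule <- rules[[mi$kind]]
    if (is.null(rule))
      stop_classed("incompatible_measurement",
                   sprintf("measurement kind '%s' is not applicable to %s",
                           mi$kind, property_key))
    if (rule$pos(mi$value)) 1L else if (rule$neg(mi$value)) -1L else 0L
  }, integer(1))
  if (any(labels == 1L) && any(labels == -1L)) return(0L)  # conflict -> 0
  if (any(labels == 1L)) return(1L)
  if (any(labels == -1L)) return(-1L)
  0L
}

#' @export
print.adme_catalog <- function(x, ...) {
  cat(sprintf("ADME property catalog (%s): %d properties\n",
              catalog_version(), nrow(x)))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Write / read the catalog as versioned JSON
#'
#' The JSON form records the schema tag, the catalog version and the ordered
#' property definitions, so downstream artifacts can verify they were built
#' against the same column order.
#' @param catalog An [adme_catalog()].
#' @param path File path.
#' @return `write_catalog_json()` returns `path` invisibly;
#'   `read_catalog_json()` returns an `adme_catalog`.
#' @export
write_catalog_json <- function(catalog, path) {
  obj <- list(schema = "admespace-catalog/1",
              version = catalog_version(),
              properties = catalog[, c("key", "positive_label",
                                       "negative_label", "measurement_kinds")])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_catalog_json
#' @export
read_catalog_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "admespace-catalog/1"))
    stop_classed("incompatible_file", "not an admespace catalog file: ", path)
  df <- as.data.frame(obj$properties, stringsAsFactors = FALSE)
  class(df) <- c("adme_catalog", "data.frame")
  df
}

#' Table of model dataset sizes and splits
#'
#' Documentation of the dataset shapes the twenty published models were built
#' from: total size, class counts, training/test split, member algorithms and
#' data source. Shipped as metadata (e.g. to parameterise synthetic datasets
#' of matching shape); the package does not reconcile the few rows whose
#' printed counts are internally inconsistent (OCT2 inhibition class counts,
#' the Pgp-inhibition and brain-permeability splits).
#'
#' @return A data frame with columns `key`, `n_total`, `n_positive`,
#'   `n_negative`, `n_train`, `n_test`, `algorithms`, `source`.
#' @export
adme_dataset_info <- function() {
  data.frame(
    key = c("PGP_INHIB", "PGP_RECOG", "BCRP_INHIB", "BCRP_RECOG",
            "OCT2_INHIB", "OATP_INHIB", "CLEAR", "MRDD", "CACO2_PERM",
            "BRAIN_PERM", "CYP1A2_PERC", "CYP2D6_PERC", "CYP3A4_PERC",
            "CYP1A2_INHIB", "CYP2C9_INHIB", "CYP2D6_INHIB", "CYP3A4_INHIB",
            "METASTAB_human", "METASTAB_rat", "METASTAB_mouse"),
    n_total = c(1272L, 925L, 935L, 385L, 392L, 911L, 469L, 1191L, 10109L,
                307L, 465L, 448L, 1442L, 922L, 715L, 479L, 913L, 10056L,
                10056L, 7026L),
    n_positive = c(664L, 444L, 418L, 193L, 196L, 194L, 286L, 591L, 8374L,
                   208L, 82L, 89L, 1366L, 144L, 233L, 161L, 375L, 3774L,
                   2892L, 2671L),
    n_negative = c(608L, 481L, 517L, 192L, 287L, 717L, 183L, 600L, 1735L,
                   99L, 383L, 359L, 76L, 778L, 482L, 318L, 538L, 6282L,
                   7164L, 4355L),
    n_train = c(772L, 805L, 668L, 288L, 312L, 685L, NA, 1046L, 6741L, 78L,
                310L, 299L, 961L, 615L, 476L, 319L, 609L, 6705L, 6705L,
                4684L),
    n_test = c(503L, 120L, 267L, 97L, 80L, 226L, NA, 145L, 3368L, 282L,
               155L, 149L, 481L, 307L, 239L, 160L, 304L, 3351L, 3351L,
               2342L),
    algorithms = c("RF,SVM,AB,ETC,LDA", "RF,SVM,AB,ETC,LDA,DT",
                   "RF,SVM,AB,ETC,GB", "RF,SVM,ETC", "RF,SVM,AB,ETC,GB",
                   "PLS", "RF,SVM,AB,ETC,LDA,DT", "RF,SVM,ETC,LDA", "RF",
                   "PLS", "SVM", "SVM", "RF", "RF", "SVM", "SVM", "SVM",
                   "SVM", "SVM", "SVM"),
    source = c(rep("public", 8), rep("private", 12)),
    stringsAsFactors = FALSE
  )
}
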