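#' Pipeline configuration
#'
#' Collects every input path, output path and stochastic seed of an
#' end-to-end run, so any artifact can be reproduced exactly from the
#' recorded log.
#'
#' @param fingerprints Path to a fingerprint CSV (required): the molecules
#'   the map is trained on.
#' @param out_dir Output directory (created if needed).
#' @param qspr Optional named list, one entry per property to fit a
#'   consensus model for, each a list with `descriptors` and `labels` CSV
#'   paths (and optionally `algorithms`). The fitted models are validated on
#'   a held-out split and their predictions written alongside the map.
#' @param rows,cols,epochs Map dimensions and training epochs.
#' @param seed Master integer seed; stage seeds are derived from it.
#' @param tau Node-fingerprint threshold.
#' @param agreement_fraction Consensus supermajority fraction.
#' @param domain_quantile Applicability-domain distance quantile.
#' @param naive_labels Optional path to a `molecule_id,label` CSV of a
#'   property not used to build the map; its per-node overlay is written.
#' @param layer_properties Property keys whose layers are exported
#'   (default: the layers feeding the three shipped region recipes).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fingerprints, out_dir, qspr = NULL,
                            rows = 20L, cols = 20L, epochs = 10L, seed = 1L,
                            tau = 1 / 3, agreement_fraction = 0.8,
                            domain_quantile = 1, naive_labels = NULL,
                            layer_properties = c("CACO2_PERM", "PGP_RECOG",
                                                 "BCRP_RECOG", "METASTAB_human",
                                                 "CYP1A2_PERC", "CYP2D6_PERC",
                                                 "CYP3A4_PERC")) {
  structure(list(fingerprints = fingerprints, out_dir = out_dir, qspr = qspr,
                 rows = rows, cols = cols, epochs = epochs, seed = seed,
                 tau = tau, agreement_fraction = agreement_fraction,
                 domain_quantile = domain_quantile,
                 naive_labels = naive_labels,
                 layer_properties = layer_properties),
            class = "pipeline_config")
}

stage_fail <- function(stage, e) {
  stop_classed("pipeline_stage_error",
               sprintf("[stage %s] %s", stage, conditionMessage(e)))
}

#' Run the end-to-end pipeline
#'
#' Executes, in order: optional consensus-model fitting per property (with a
#' held-out validation report), map training on the fingerprint table,
#' projection of the training molecules, per-property layer extraction, the
#' three shipped region colorings, and an optional naive-property overlay.
#' Every intermediate is written under `config$out_dir`; a structured
#' `log.json` records versions, seeds, input digests and counts. Two runs
#' with identical inputs and seeds write identical artifacts.
#'
#' @param config A [pipeline_config()].
#' @return The log (a list), invisibly. Errors abort with a stage-tagged
#'   `pipeline_stage_error`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop_classed("invalid_argument", "config must be a pipeline_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(package_version = as.character(utils::packageVersion("admespace")),
              catalog_version = catalog_version(),
              seed = config$seed,
              inputs = list(), stages = list())

  digest_of <- function(path) unname(tools::md5sum(path))

  # stage: fit (optional)
  if (!is.null(config$qspr)) {
    fit_log <- list()
    for (key in names(config$qspr)) {
      item <- config$qspr[[key]]
      res <- tryCatch({
        dm <- read_descriptors(item$descriptors)
        y <- read_labels(item$labels)
        y <- y[dm$molecule_id]
        sp <- split_train_test(dm$molecule_id, 0.8,
                               seed = derive_seed(config$seed, 100L))
        tr <- match(sp$train, dm$molecule_id)
        te <- match(sp$test, dm$molecule_id)
        model <- fit_consensus(
          descriptor_matrix(dm$molecule_id[tr], dm$X[tr, , drop = FALSE]),
          y[tr],
          algorithms = item$algorithms %||% c("RF", "SVM", "AB", "ETC", "LDA"),
          agreement_fraction = config$agreement_fraction,
          seed = derive_seed(config$seed, 101L),
          property_key = key,
          domain_quantile = config$domain_quantile)
        save_model_bundle(model, file.path(config$out_dir, "models", key))
        pred <- predict(model, descriptor_matrix(dm$molecule_id[te],
                                                 dm$X[te, , drop = FALSE]))
        rep <- evaluate_predictions(pred, y[te])
        list(n_train = length(tr), n_test = length(te),
             accuracy = rep$accuracy, mcc = rep$mcc, coverage = rep$coverage)
      }, error = function(e) stage_fail(paste0("fit:", key), e))
      fit_log[[key]] <- res
      log$inputs[[paste0("qspr_", key)]] <-
        list(descriptors = digest_of(item$descriptors),
             labels = digest_of(item$labels))
    }
    log$stages$fit <- fit_log
  }

  # stage: train-map
  map <- tryCatch({
    fp <- read_fingerprints(config$fingerprints)
    log$inputs$fingerprints <- digest_of(config$fingerprints)
    m <- som_train(som_init(som_config(config$rows, config$cols,
                                       epochs = config$epochs,
                                       seed = derive_seed(config$seed, 200L))),
                   fp)
    save_map(m, file.path(config$out_dir, "map.json"))
    m
  }, error = function(e) stage_fail("train-map", e))
  fp <- read_fingerprints(config$fingerprints)
  s <- map_summary(map)
  log$stages$train_map <- list(n_molecules = nrow(fp), n_nodes = s$n_nodes,
                               n_on = s$n_on, on_fraction = s$on_fraction,
                               outlier_cutoff = map$outlier_cutoff)

  # stage: project
  proj <- tryCatch({
    p <- som_project(map, fp, tau = config$tau)
    out <- p[, c("molecule_id", "row", "col", "node_label", "distance",
                 "is_outlier", "node_on")]
    utils::write.csv(out, file.path(config$out_dir, "projections.csv"),
                     row.names = FALSE, quote = FALSE)
    p
  }, error = function(e) stage_fail("project", e))
  log$stages$project <- list(n = nrow(proj), n_outliers = sum(proj$is_outlier))

  # stage: layers + region recipes
  tryCatch({
    layers <- lapply(config$layer_properties, function(k)
      extract_layer(map, k, tau = config$tau))
    names(layers) <- config$layer_properties
    for (k in names(layers))
      write_layer_csv(layers[[k]],
                      file.path(config$out_dir, paste0("layer_", k, ".csv")))
    cyps <- layers[c("CYP1A2_PERC", "CYP2D6_PERC", "CYP3A4_PERC")]
    recipes <- list(
      transport = transport_permeability_regions(layers$CACO2_PERM,
                                                 layers$PGP_RECOG,
                                                 layers$BCRP_RECOG),
      metabolism = metabolism_implication_overlay(layers$METASTAB_human, cyps),
      risk = bioavailability_risk(layers$CACO2_PERM, layers$METASTAB_human,
                                  layers$PGP_RECOG, cyps))
    for (k in names(recipes))
      write_layer_csv(recipes[[k]],
                      file.path(config$out_dir, paste0("regions_", k, ".csv")))
    log$stages$layers <- list(properties = names(layers),
                               recipes = names(recipes))
  }, error = function(e) stage_fail("layers", e))

  # stage: naive overlay (optional)
  if (!is.null(config$naive_labels)) {
    tryCatch({
      lab <- utils::read.csv(config$naive_labels, stringsAsFactors = FALSE)
      labels <- stats::setNames(as.integer(lab$label), lab$molecule_id)
      ov <- naive_property_overlay(map, proj, labels)
      write_layer_csv(ov, file.path(config$out_dir, "overlay_naive.csv"))
      log$inputs$naive_labels <- digest_of(config$naive_labels)
      log$stages$overlay <- list(n_nodes_with_data = sum(!is.na(ov$values)))
    }, error = function(e) stage_fail("overlay", e))
  }

  jsonlite::write_json(log, file.path(config$out_dir, "log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(log)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate an artifact file against its schema
#'
#' Checks the structural contract of the package's file formats without
#' loading them into model objects: header layout, value domains (fingerprint
#' cells in `{-1, 0, 1}`), duplicate molecule ids, and dimension consistency
#' for map JSON files.
#'
#' @param path File path.
#' @param schema_kind One of `"fingerprints"`, `"labels"`, `"descriptors"`,
#'   `"map"`, `"layer"`.
#' @return A data frame of violations with columns `where` and `problem`
#'   (zero rows when the file is valid).
#' @export
validate_file <- function(path, schema_kind = c("fingerprints", "labels",
                                                "descriptors", "map", "layer")) {
  schema_kind <- match.arg(schema_kind)
  if (!file.exists(path))
    stop_classed("io_error", "file does not exist: ", path)
  bad <- function(where, problem) data.frame(where = where, problem = problem,
                                             stringsAsFactors = FALSE)
  v <- list()
  if (schema_kind == "map") {
    obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                    error = function(e) NULL)
    if (is.null(obj)) return(bad(path, "not parseable as JSON"))
    if (!identical(obj$schema, .map_schema))
      v[[length(v) + 1]] <- bad("schema", "missing or unrecognized schema tag")
    n_nodes <- tryCatch(obj$config$rows * obj$config$cols,
                        error = function(e) NA)
    if (!is.na(n_nodes) && length(obj$weights) != n_nodes * obj$dim)
      v[[length(v) + 1]] <- bad("weights",
        sprintf("weights length %d != rows*cols*dim = %d",
                length(obj$weights), n_nodes * obj$dim))
    if (!is.na(n_nodes) && length(obj$status) != n_nodes)
      v[[length(v) + 1]] <- bad("status", "status length != rows*cols")
  } else {
    df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE,
                                   check.names = FALSE),
                   error = function(e) NULL)
    if (is.null(df)) return(bad(path, "not parseable as CSV"))
    if (schema_kind == "fingerprints") {
      want <- c("molecule_id", adme_catalog()$key)
      if (!identical(colnames(df), want)) {
        v[[length(v) + 1]] <- bad("header",
          "header must be molecule_id + the 20 catalog keys in order")
      } else {
        if (anyDuplicated(df$molecule_id))
          v[[length(v) + 1]] <- bad("molecule_id", "duplicate molecule ids")
        for (k in adme_catalog()$key) {
          ok <- df[[k]] %in% c(-1, 0, 1)
          if (!all(ok))
            v[[length(v) + 1]] <- bad(
              sprintf("column %s, row %d", k, which(!ok)[1]),
              sprintf("value %s outside {-1,0,1}", df[[k]][which(!ok)[1]]))
        }
      }
    } else if (schema_kind == "labels") {
      if (!all(c("molecule_id", "label") %in% colnames(df)))
        v[[length(v) + 1]] <- bad("header", "need molecule_id,label columns")
      else if (!all(df$label %in% c(-1, 0, 1)))
        v[[length(v) + 1]] <- bad("label", "labels outside {-1,0,1}")
    } else if (schema_kind == "descriptors") {
      if (!"molecule_id" %in% colnames(df))
        v[[length(v) + 1]] <- bad("header", "need a molecule_id column")
      else {
        num <- df[, setdiff(colnames(df), "molecule_id"), drop = FALSE]
        if (ncol(num) < 2)
          v[[length(v) + 1]] <- bad("header", "need >= 2 descriptor columns")
        if (!all(vapply(num, is.numeric, logical(1))) ||
            any(!is.finite(as.matrix(num))))
          v[[length(v) + 1]] <- bad("values", "non-numeric or non-finite descriptors")
        if (anyDuplicated(df$molecule_id))
          v[[length(v) + 1]] <- bad("molecule_id", "duplicate molecule ids")
      }
    } else if (schema_kind == "layer") {
      if (!all(c("row", "col") %in% colnames(df)) ||
          !any(c("value", "category") %in% colnames(df)))
        v[[length(v) + 1]] <- bad("header", "need row,col,value|category columns")
      else if ("value" %in% colnames(df) &&
               !all(df$value %in% c(-1, 0, 1) | is.na(df$value)))
        v[[length(v) + 1]] <- bad("value", "layer values outside {-1,0,1,NA}")
    }
  }
  if (!length(v)) data.frame(where = character(0), problem = character(0),
                             stringsAsFactors = FALSE)
  else do.call(rbind, v)
}
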