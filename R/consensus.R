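#' Descriptor matrices
#'
#' Container for the X-matrix of continuous molecular descriptors used to
#' train the per-property classifiers (rows = molecules, columns =
#' descriptors). All entries must be finite after ingestion.
#'
#' @param molecule_id Character vector of unique molecule identifiers.
#' @param X Numeric matrix or data frame of descriptors (>= 2 columns).
#' @return A list of class `descriptor_matrix` with elements `molecule_id`,
#'   `X` and `descriptor_names`.
#' @export
descriptor_matrix <- function(molecule_id, X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (ncol(X) < 2L)
    stop_classed("invalid_argument", "at least 2 descriptor columns required")
  if (any(!is.finite(X)))
    stop_classed("invalid_argument", "descriptor matrix contains non-finite values")
  if (length(molecule_id) != nrow(X))
    stop_classed("invalid_argument", "one molecule_id per descriptor row required")
  if (anyDuplicated(molecule_id))
    stop_classed("invalid_argument", "duplicate molecule_id")
  if (is.null(colnames(X))) colnames(X) <- paste0("d", seq_len(ncol(X)))
  structure(list(molecule_id = as.character(molecule_id), X = X,
                 descriptor_names = colnames(X)),
            class = "descriptor_matrix")
}

as_descriptor_matrix <- function(x) {
  if (inherits(x, "descriptor_matrix")) return(x)
  if (is.data.frame(x) && "molecule_id" %in% colnames(x)) {
    ids <- x$molecule_id
    return(descriptor_matrix(ids, x[, setdiff(colnames(x), "molecule_id"),
                                    drop = FALSE]))
  }
  x <- as.matrix(x)
  ids <- rownames(x)
  if (is.null(ids)) ids <- paste0("mol", seq_len(nrow(x)))
  descriptor_matrix(ids, x)
}

#' Read a descriptor or label CSV
#'
#' Descriptor CSV: a `molecule_id` column plus numeric descriptor columns.
#' Label CSV: columns `molecule_id,label` with labels in `{-1, 1}`.
#' @param path File path.
#' @return A `descriptor_matrix`, or for labels a named integer vector.
#' @export
read_descriptors <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"molecule_id" %in% colnames(df))
    stop_classed("schema_mismatch", "descriptor CSV needs a molecule_id column: ", path)
  as_descriptor_matrix(df)
}

#' @rdname read_descriptors
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("molecule_id", "label") %in% colnames(df)))
    stop_classed("schema_mismatch", "label CSV needs molecule_id,label columns: ", path)
  if (!all(df$label %in% c(-1L, 1L)))
    stop_classed("invalid_argument", "labels must be -1 or 1")
  stats::setNames(as.integer(df$label), df$molecule_id)
}

#' Random training/test split
#'
#' Disjoint exhaustive split with `round(n * train_fraction)` training
#' records, reproducible from the seed.
#'
#' @param ids Vector of record identifiers (n >= 2).
#' @param train_fraction Fraction in (0, 1).
#' @param seed Integer seed.
#' @return A list with components `train` and `test`.
#' @export
#' @examples
#' s <- split_train_test(paste0("m", 1:100), 0.8, seed = 1)
#' lengths(s)  # 80, 20
split_train_test <- function(ids, train_fraction, seed) {
  if (length(ids) < 2L)
    stop_classed("too_few_records", "need at least 2 records to split")
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    stop_classed("invalid_argument", "train_fraction must be in (0, 1)")
  n_train <- round(length(ids) * train_fraction)
  n_train <- max(1L, min(length(ids) - 1L, n_train))
  rng <- local({ set.seed(seed); sample.int(length(ids)) })
  list(train = ids[sort(rng[seq_len(n_train)])],
       test  = ids[sort(rng[-seq_len(n_train)])])
}

#' Supermajority consensus vote
#'
#' Combines strictly binary member votes into a ternary class: a class is
#' assigned only when at least `ceiling(agreement_fraction * n)` members
#' agree (80% by default, i.e. 4 out of 5); otherwise the doubtful case is
#' labelled 0 (uncertain). Because the agreement fraction exceeds 1/2, at
#' most one class can reach the required count, so ties are impossible.
#'
#' @param votes Vector of member votes in `{-1, 1}`.
#' @param agreement_fraction Number in (0.5, 1].
#' @return An integer in `{-1, 0, 1}`.
#' @export
#' @examples
#' consensus_vote(c(1, 1, 1, 1, -1), 0.8)   # +1 (4 of 5 agree)
#' consensus_vote(c(1, 1, 1, -1, -1), 0.8)  #  0 (only 3 of 5)
consensus_vote <- function(votes, agreement_fraction = 0.8) {
  if (!length(votes))
    stop_classed("no_members", "empty vote vector")
  if (!all(votes %in% c(-1, 1)))
    stop_classed("invalid_argument", "member votes must be -1 or 1")
  if (!is.numeric(agreement_fraction) ||
      agreement_fraction <= 0.5 || agreement_fraction > 1)
    stop_classed("invalid_argument", "agreement_fraction must be in (0.5, 1]")
  required <- ceiling(agreement_fraction * length(votes))
  n_pos <- sum(votes == 1)
  if (n_pos >= required) return(1L)
  if (length(votes) - n_pos >= required) return(-1L)
  0L
}

## ---- applicability domain ----------------------------------------------

#' Fit an applicability domain on training descriptors
#'
#' The domain is the intersection of (a) the descriptor-wise training
#' min/max box and (b) a standardized Euclidean distance to the training
#' centroid no larger than the given quantile of the training distances.
#' Molecules predicted outside the domain are assigned class 0. With the
#' default `quantile = 1` (the maximum training distance) every training
#' molecule lies inside its own domain.
#'
#' @param X A `descriptor_matrix` (or coercible).
#' @param quantile Quantile of training centroid distances used as cutoff.
#' @return An `applicability_domain` object.
#' @export
fit_applicability_domain <- function(X, quantile = 1) {
  X <- as_descriptor_matrix(X)$X
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  d <- sqrt(rowSums(Z^2))
  structure(list(mins = apply(X, 2, min), maxs = apply(X, 2, max),
                 center = mu, scale = sdv,
                 cutoff = as.numeric(stats::quantile(d, quantile)),
                 quantile = quantile),
            class = "applicability_domain")
}

#' @rdname fit_applicability_domain
#' @param domain An `applicability_domain`.
#' @return `in_domain()` returns a logical vector, one entry per molecule.
#' @export
in_domain <- function(domain, X) {
  X <- as_descriptor_matrix(X)$X
  # boundary tolerance: training molecules defining a bound must stay inside
  # even after serialization rounds the stored bound in its last bits
  lo <- domain$mins - 1e-8 * (1 + abs(domain$mins))
  hi <- domain$maxs + 1e-8 * (1 + abs(domain$maxs))
  in_box <- rowSums(sweep(X, 2, lo, "<") | sweep(X, 2, hi, ">")) == 0
  Z <- sweep(sweep(X, 2, domain$center), 2, domain$scale, "/")
  in_box & sqrt(rowSums(Z^2)) <= domain$cutoff + 1e-8 * (1 + domain$cutoff)
}

## ---- member classifiers -------------------------------------------------

.known_algorithms <- c("RF", "SVM", "AB", "ETC", "LDA", "GB", "DT", "PLS")

# Fit one member model. Members are thin adapters over established
# implementations with library-default hyperparameters; each emits strictly
# binary predictions — only the consensus or the domain introduces 0.
fit_member <- function(tag, X, y, seed) {
  tag <- match.arg(tag, .known_algorithms)
  yf <- factor(y, levels = c(-1, 1))
  set.seed(seed)
  fit <- switch(tag,
    RF  = randomForest::randomForest(x = X, y = yf, ntree = 200),
    ETC = ranger::ranger(x = as.data.frame(X), y = yf, num.trees = 200,
                         splitrule = "extratrees", num.random.splits = 1,
                         seed = seed),
    SVM = e1071::svm(x = X, y = yf),
    LDA = MASS::lda(x = X, grouping = yf),
    DT  = rpart::rpart(y ~ ., data = data.frame(y = yf, X),
                       method = "class"),
    GB  = xgboost::xgb.train(
            params = list(objective = "binary:logistic", max_depth = 3,
                          learning_rate = 0.3, nthread = 1, seed = seed),
            data = xgboost::xgb.DMatrix(X, label = (y + 1) / 2, nthread = 1),
            nrounds = 50),
    AB  = fit_adaboost_stumps(X, y, n_rounds = 50),
    PLS = fit_pls_member(X, y)
  )
  structure(list(algorithm_tag = tag, fit = fit, seed = seed),
            class = "member_model")
}

predict_member <- function(member, X) {
  fit <- member$fit
  out <- switch(member$algorithm_tag,
    RF  = as.integer(as.character(stats::predict(fit, X))),
    ETC = as.integer(as.character(
            stats::predict(fit, data = as.data.frame(X))$predictions)),
    SVM = as.integer(as.character(stats::predict(fit, X))),
    LDA = as.integer(as.character(stats::predict(fit, X)$class)),
    DT  = as.integer(as.character(
            stats::predict(fit, newdata = as.data.frame(X), type = "class"))),
    GB  = ifelse(stats::predict(fit, xgboost::xgb.DMatrix(X, nthread = 1)) > 0.5,
                 1L, -1L),
    AB  = predict_adaboost_stumps(fit, X),
    PLS = predict_pls_member(fit, X)
  )
  if (!all(out %in% c(-1L, 1L)))
    stop_classed("invalid_member", "member produced a non-binary prediction")
  out
}

# Discrete AdaBoost (SAMME with two classes) over depth-1 rpart stumps.
fit_adaboost_stumps <- function(X, y, n_rounds = 50) {
  n <- nrow(X)
  df <- data.frame(y = factor(y, levels = c(-1, 1)), X)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  for (t in seq_len(n_rounds)) {
    stump <- rpart::rpart(y ~ ., data = df, weights = w, method = "class",
                          control = rpart::rpart.control(maxdepth = 1,
                                                         cp = 0, minsplit = 2))
    pred <- as.integer(as.character(
      stats::predict(stump, newdata = df, type = "class")))
    err <- sum(w * (pred != y)) / sum(w)
    if (err >= 0.5 && length(stumps)) break
    err <- min(max(err, 1e-10), 0.5 - 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- stump
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
    if (err <= 1e-10) break
  }
  list(stumps = stumps, alphas = alphas)
}

predict_adaboost_stumps <- function(fit, X) {
  df <- as.data.frame(X)
  score <- rowSums(vapply(seq_along(fit$stumps), function(t) {
    fit$alphas[t] * as.integer(as.character(
      stats::predict(fit$stumps[[t]], newdata = df, type = "class")))
  }, numeric(nrow(df))))
  ifelse(score >= 0, 1L, -1L)
}

# PLS regression member (mixOmics backend): predicted Y thresholded at 0.
fit_pls_member <- function(X, y) {
  if (!requireNamespace("mixOmics", quietly = TRUE))
    stop_classed("missing_dependency", "the PLS member requires mixOmics")
  ncomp <- min(2L, ncol(X) - 1L)
  list(fit = mixOmics::pls(X, y, ncomp = ncomp), ncomp = ncomp)
}

predict_pls_member <- function(fit, X) {
  p <- stats::predict(fit$fit, newdata = X)$predict[, 1, fit$ncomp]
  ifelse(p >= 0, 1L, -1L)
}

## ---- consensus model ----------------------------------------------------

#' Fit a consensus QSPR classifier for one property
#'
#' Fits each member algorithm on the same training data, together with an
#' applicability domain on the training descriptors. At prediction time the
#' final class is assigned only by the supermajority of member votes
#' ([consensus_vote()]); molecules outside the domain are assigned 0
#' unconditionally.
#'
#' @param X Training `descriptor_matrix` (or coercible).
#' @param labels Vector of strictly binary class labels in `{-1, 1}`, one per
#'   training molecule, with at least 2 molecules per class.
#' @param algorithms Character vector of member tags among RF, SVM, AB, ETC,
#'   LDA, GB, DT, PLS.
#' @param agreement_fraction Supermajority fraction in (0.5, 1], default 0.8.
#' @param seed Integer seed (each member gets a derived sub-seed).
#' @param property_key Catalog key this model predicts (metadata).
#' @param domain_quantile Passed to [fit_applicability_domain()].
#' @return A `consensus_model`.
#' @export
fit_consensus <- function(X, labels, algorithms = c("RF", "SVM", "AB", "ETC", "LDA"),
                          agreement_fraction = 0.8, seed = 1,
                          property_key = "", domain_quantile = 1) {
  dm <- as_descriptor_matrix(X)
  labels <- as.integer(labels)
  if (length(labels) != nrow(dm$X))
    stop_classed("invalid_argument", "one label per training molecule required")
  if (!all(labels %in% c(-1L, 1L)))
    stop_classed("invalid_argument", "training labels must be strictly binary (-1/1)")
  if (min(table(factor(labels, levels = c(-1, 1)))) < 2L)
    stop_classed("degenerate_training", "need at least 2 molecules per class")
  algorithms <- vapply(algorithms, match.arg, character(1),
                       choices = .known_algorithms)
  if (!is.numeric(agreement_fraction) ||
      agreement_fraction <= 0.5 || agreement_fraction > 1)
    stop_classed("invalid_argument", "agreement_fraction must be in (0.5, 1]")
  Xs <- dm$X
  colnames(Xs) <- paste0("x", seq_len(ncol(Xs)))  # syntactic names for formulas
  members <- lapply(seq_along(algorithms), function(i)
    fit_member(algorithms[[i]], Xs, labels, derive_seed(seed, i)))
  structure(list(property_key = property_key,
                 algorithms = unname(algorithms),
                 members = members,
                 agreement_fraction = agreement_fraction,
                 domain = fit_applicability_domain(dm),
                 descriptor_names = dm$descriptor_names,
                 seed = seed,
                 catalog_version = catalog_version()),
            class = "consensus_model")
}

#' @export
print.consensus_model <- function(x, ...) {
  cat(sprintf("Consensus QSPR model%s: %d member(s) [%s], agreement %.2f\n",
              if (nzchar(x$property_key)) paste0(" for ", x$property_key) else "",
              length(x$members), paste(x$algorithms, collapse = ","),
              x$agreement_fraction))
  invisible(x)
}

# Strictly binary votes of every member on every molecule (n x m matrix).
member_votes <- function(model, X) {
  dm <- as_descriptor_matrix(X)
  if (!identical(dm$descriptor_names, model$descriptor_names))
    stop_classed("schema_mismatch",
                 "descriptor columns do not match the training columns")
  Xs <- dm$X
  colnames(Xs) <- paste0("x", seq_len(ncol(Xs)))
  vapply(model$members, function(m) predict_member(m, Xs), integer(nrow(Xs)))
}

#' Predict ternary classes with a consensus model
#'
#' @param object A `consensus_model`.
#' @param newdata A `descriptor_matrix` (or coercible) with the training
#'   descriptor columns.
#' @param ... Unused.
#' @return A named integer vector in `{-1, 0, 1}`: 0 for molecules outside
#'   the applicability domain or without a supermajority of member votes.
#' @export
predict.consensus_model <- function(object, newdata, ...) {
  dm <- as_descriptor_matrix(newdata)
  votes <- member_votes(object, dm)
  if (is.null(dim(votes))) votes <- matrix(votes, ncol = length(object$members))
  out <- vapply(seq_len(nrow(votes)), function(i)
    consensus_vote(votes[i, ], object$agreement_fraction), integer(1))
  out[!in_domain(object$domain, dm)] <- 0L
  stats::setNames(out, dm$molecule_id)
}

#' Threshold classification of PLS-predicted scores
#'
#' For the endpoints modelled with PLS regression the predicted Y is compared
#' with given thresholds for the final class assignment: scores above `hi`
#' are +1, below `lo` are -1, and the band between is the uncertain class 0.
#'
#' @param scores Numeric vector of predicted Y values.
#' @param lo,hi Class thresholds with `lo <= hi`.
#' @return An integer vector in `{-1, 0, 1}`.
#' @export
pls_threshold_classify <- function(scores, lo, hi) {
  if (!is.numeric(lo) || !is.numeric(hi) || lo > hi)
    stop_classed("invalid_thresholds", "need lo <= hi")
  ifelse(scores > hi, 1L, ifelse(scores < lo, -1L, 0L))
}

#' Validation metrics for ternary predictions against binary truth
#'
#' Predictions of 0 (uncertain / out of domain) are excluded from the
#' confusion matrix but counted against coverage, so abstention stays
#' visible. Accuracy is `(TP+TN)/(TP+TN+FP+FN)`; the Matthews correlation
#' coefficient uses the standard formula, defined as 0 when its denominator
#' vanishes (e.g. when the model predicts a single class).
#'
#' @param predictions Integer vector in `{-1, 0, 1}`.
#' @param truth Integer vector in `{-1, 1}` of the same length.
#' @return A `validation_report` list: `tp`, `tn`, `fp`, `fn`, `accuracy`,
#'   `mcc`, `coverage`, `n`.
#' @export
evaluate_predictions <- function(predictions, truth) {
  if (length(predictions) != length(truth))
    stop_classed("invalid_argument", "predictions and truth differ in length")
  if (!all(truth %in% c(-1, 1)))
    stop_classed("invalid_argument", "truth must be strictly binary (-1/1)")
  if (!all(predictions %in% c(-1, 0, 1)))
    stop_classed("invalid_argument", "predictions must be in {-1, 0, 1}")
  decided <- predictions != 0
  if (!any(decided))
    stop_classed("empty_evaluation", "no non-zero predictions to evaluate")
  p <- predictions[decided]; t <- truth[decided]
  tp <- sum(p == 1 & t == 1);  tn <- sum(p == -1 & t == -1)
  fp <- sum(p == 1 & t == -1); fn <- sum(p == -1 & t == 1)
  denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 accuracy = (tp + tn) / (tp + tn + fp + fn),
                 mcc = mcc,
                 coverage = mean(decided),
                 n = length(predictions)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "Validation: n=%d coverage=%.3f accuracy=%.3f MCC=%.3f (TP %d TN %d FP %d FN %d)\n",
    x$n, x$coverage, x$accuracy, x$mcc, x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Build ADME fingerprints from one model per property
#'
#' Projects every molecule on all twenty property models; the ternary results
#' compose its ADME fingerprint, in catalog column order.
#'
#' @param models Named list of `consensus_model`s (or any objects with a
#'   `predict` method returning ternary values), one per catalog key.
#' @param X A `descriptor_matrix` (or coercible).
#' @param catalog The property catalog.
#' @return An `adme_fingerprints` table.
#' @export
build_fingerprints <- function(models, X, catalog = adme_catalog()) {
  missing <- setdiff(catalog$key, names(models))
  if (length(missing))
    stop_classed("incomplete_model_set",
                 "no model for: ", paste(missing, collapse = ", "))
  dm <- as_descriptor_matrix(X)
  vals <- vapply(catalog$key, function(k)
    as.integer(stats::predict(models[[k]], dm)), integer(length(dm$molecule_id)))
  if (is.null(dim(vals))) vals <- matrix(vals, ncol = nrow(catalog))
  colnames(vals) <- catalog$key
  adme_fingerprints(dm$molecule_id, vals, catalog = catalog)
}

## ---- model bundle serialization ----------------------------------------

#' Save / load a fitted consensus model bundle
#'
#' A bundle is a directory holding a JSON manifest (property key, member
#' algorithms, agreement fraction, domain parameters, seed, catalog version)
#' plus the opaque fitted member objects.
#'
#' @param model A `consensus_model`.
#' @param dir Directory to create/use.
#' @return `save_model_bundle()` returns `dir` invisibly;
#'   `load_model_bundle()` returns the `consensus_model`.
#' @export
save_model_bundle <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(schema = "admespace-model/1",
                   property_key = model$property_key,
                   algorithms = model$algorithms,
                   agreement_fraction = model$agreement_fraction,
                   seed = model$seed,
                   catalog_version = model$catalog_version,
                   descriptor_names = model$descriptor_names,
                   domain = model$domain[c("mins", "maxs", "center", "scale",
                                           "cutoff", "quantile")])
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  saveRDS(model$members, file.path(dir, "members.rds"))
  invisible(dir)
}

#' @rdname save_model_bundle
#' @export
load_model_bundle <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path))
    stop_classed("incompatible_file", "no manifest.json in ", dir)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  if (!identical(mf$schema, "admespace-model/1"))
    stop_classed("incompatible_file", "unrecognized model bundle schema")
  domain <- structure(
    list(mins = unlist(mf$domain$mins), maxs = unlist(mf$domain$maxs),
         center = unlist(mf$domain$center), scale = unlist(mf$domain$scale),
         cutoff = mf$domain$cutoff, quantile = mf$domain$quantile),
    class = "applicability_domain")
  structure(list(property_key = mf$property_key,
                 algorithms = mf$algorithms,
                 members = readRDS(file.path(dir, "members.rds")),
                 agreement_fraction = mf$agreement_fraction,
                 domain = domain,
                 descriptor_names = mf$descriptor_names,
                 seed = mf$seed,
                 catalog_version = mf$catalog_version),
            class = "consensus_model")
}
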