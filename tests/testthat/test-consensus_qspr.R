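test_that("train/test splits are sized, disjoint, exhaustive and reproducible", {
  s <- split_train_test(paste0("m", 1:100), 0.8, seed = 1)
  expect_length(s$train, 80L)
  expect_length(s$test, 20L)

  big <- split_train_test(paste0("m", 1:1272), 0.61, seed = 5)
  expect_length(big$train, 776L)  # round(1272 * 0.61)
  expect_length(big$test, 496L)
  expect_identical(big, split_train_test(paste0("m", 1:1272), 0.61, seed = 5))
  expect_false(identical(big, split_train_test(paste0("m", 1:1272), 0.61, 6)))

  # set-algebra oracle, exhaustively for n <= 10 over several fractions
  for (n in 2:10) for (f in c(0.25, 0.5, 0.61, 0.8)) {
    ids <- paste0("x", seq_len(n))
    sp <- split_train_test(ids, f, seed = n)
    expect_length(intersect(sp$train, sp$test), 0L)
    expect_setequal(c(sp$train, sp$test), ids)
  }
  expect_error(split_train_test("only-one", 0.5, 1), class = "too_few_records")
  expect_error(split_train_test(1:10, 1.2, 1), class = "invalid_argument")
})

test_that("consensus voting matches a counting oracle on every pattern up to n = 6", {
  vote_oracle <- function(votes, frac) {
    need <- ceiling(frac * length(votes))
    npos <- 0; nneg <- 0
    for (v in votes) if (v == 1) npos <- npos + 1 else nneg <- nneg + 1
    if (npos >= need) 1L else if (nneg >= need) -1L else 0L
  }
  for (n in 1:6) {
    patterns <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    for (frac in c(0.6, 0.8, 1)) {
      for (i in seq_len(nrow(patterns))) {
        v <- patterns[i, ]
        expect_identical(consensus_vote(v, frac), vote_oracle(v, frac))
        # sign-flip symmetry
        expect_identical(consensus_vote(-v, frac), -consensus_vote(v, frac))
      }
    }
  }
  # the published 80% rule on five members
  expect_identical(consensus_vote(c(1, 1, 1, 1, -1), 0.8), 1L)   # 4 of 5
  expect_identical(consensus_vote(c(1, 1, 1, -1, -1), 0.8), 0L)  # 3 of 5
  expect_identical(consensus_vote(rep(-1, 5), 0.8), -1L)
  # three members at 80%: ceiling(2.4) = 3, only unanimity decides
  expect_identical(consensus_vote(c(1, 1, -1), 0.8), 0L)
  expect_identical(consensus_vote(c(1, 1, 1), 0.8), 1L)
  expect_error(consensus_vote(integer(0)), class = "no_members")
  expect_error(consensus_vote(c(1, -1), 0.5), class = "invalid_argument")
})

test_that("raising the agreement fraction only ever abstains, never flips", {
  fracs <- seq(0.55, 1, by = 0.05)
  for (n in 1:6) {
    patterns <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    for (i in seq_len(nrow(patterns))) {
      decisions <- vapply(fracs, function(f)
        consensus_vote(patterns[i, ], f), integer(1))
      decided <- decisions[decisions != 0]
      expect_lte(length(unique(decided)), 1L)  # never both +1 and -1
      # once abstaining, stays abstaining as the fraction grows
      if (any(decisions == 0))
        expect_true(all(decisions[seq(which(decisions == 0)[1], length(fracs))] == 0))
    }
  }
})

test_that("a consensus fitted on well-separated classes is accurate, covering and deterministic", {
  ds <- generate_qspr_dataset(240, n_descriptors = 8, separation = 6,
                              noise_rate = 0, seed = 21)
  sp <- split_train_test(ds$descriptors$molecule_id, 0.75, seed = 22)
  tr <- match(sp$train, ds$descriptors$molecule_id)
  te <- match(sp$test, ds$descriptors$molecule_id)
  Xtr <- descriptor_matrix(ds$descriptors$molecule_id[tr],
                           ds$descriptors$X[tr, ])
  Xte <- descriptor_matrix(ds$descriptors$molecule_id[te],
                           ds$descriptors$X[te, ])
  model <- fit_consensus(Xtr, ds$labels[tr],
                         algorithms = c("RF", "SVM", "AB", "ETC", "LDA"),
                         seed = 23, property_key = "PGP_INHIB")

  pred_tr <- predict(model, Xtr)
  rep_tr <- evaluate_predictions(pred_tr, ds$labels[tr])
  expect_equal(rep_tr$coverage, 1.0)  # every training molecule in-domain
  expect_gte(rep_tr$accuracy, 0.95)

  rep_te <- evaluate_predictions(predict(model, Xte), ds$labels[te])
  expect_gte(rep_te$accuracy, 0.95)
  expect_equal(rep_te$coverage + mean(predict(model, Xte) == 0), 1.0)

  # determinism: refit with the same seed, identical held-out predictions
  model2 <- fit_consensus(Xtr, ds$labels[tr],
                          algorithms = c("RF", "SVM", "AB", "ETC", "LDA"),
                          seed = 23, property_key = "PGP_INHIB")
  expect_identical(predict(model2, Xte), predict(model, Xte))

  # consensus is no worse than the best member on the decided subset
  votes <- admespace:::member_votes(model, Xte)
  cons <- predict(model, Xte)
  decided <- cons != 0
  member_acc <- apply(votes[decided, , drop = FALSE], 2,
                      function(v) mean(v == ds$labels[te][decided]))
  cons_acc <- mean(cons[decided] == ds$labels[te][decided])
  expect_gte(cons_acc, max(member_acc) - 0.02)
})

test_that("every member algorithm fits, predicts binarily and round-trips a bundle", {
  skip_if_not_installed("mixOmics")
  ds <- generate_qspr_dataset(120, n_descriptors = 6, separation = 5, seed = 31)
  model <- fit_consensus(ds$descriptors, ds$labels,
                         algorithms = c("RF", "SVM", "AB", "ETC", "LDA",
                                        "GB", "DT", "PLS"),
                         agreement_fraction = 0.8, seed = 32)
  votes <- admespace:::member_votes(model, ds$descriptors)
  expect_true(all(votes %in% c(-1L, 1L)))  # members never abstain
  expect_gte(evaluate_predictions(predict(model, ds$descriptors),
                                  ds$labels)$accuracy, 0.95)

  dir <- withr::local_tempdir()
  save_model_bundle(model, dir)
  back <- load_model_bundle(dir)
  expect_identical(predict(back, ds$descriptors), predict(model, ds$descriptors))
})

test_that("a single-member consensus degenerates to that member", {
  ds <- generate_qspr_dataset(80, n_descriptors = 5, separation = 5, seed = 41)
  model <- fit_consensus(ds$descriptors, ds$labels, algorithms = "LDA",
                         agreement_fraction = 0.8, seed = 42)
  votes <- admespace:::member_votes(model, ds$descriptors)
  pred <- predict(model, ds$descriptors)
  inside <- in_domain(model$domain, ds$descriptors)
  expect_identical(pred[inside], stats::setNames(votes[inside, 1],
                                                 names(pred)[inside]))
})

test_that("degenerate training inputs are rejected", {
  ds <- generate_qspr_dataset(40, n_descriptors = 5, seed = 51)
  one_class <- rep(1L, 40)
  expect_error(fit_consensus(ds$descriptors, one_class),
               class = "degenerate_training")
  expect_error(fit_consensus(ds$descriptors, ds$labels[1:10]),
               class = "invalid_argument")
})

test_that("out-of-domain molecules are assigned 0 unconditionally", {
  ds <- generate_qspr_dataset(100, n_descriptors = 5, separation = 6, seed = 61)
  model <- fit_consensus(ds$descriptors, ds$labels, algorithms = c("LDA", "DT", "RF"),
                         seed = 62)
  far <- ds$descriptors$X[1:3, ]
  far[, 1] <- max(ds$descriptors$X[, 1]) * 10  # 10x outside the training range
  pred <- predict(model, descriptor_matrix(paste0("far", 1:3), far))
  expect_identical(unname(pred), rep(0L, 3))
  # schema mismatch is detected
  wrong <- descriptor_matrix(paste0("w", 1:3),
                             matrix(0, 3, 5, dimnames = list(NULL, paste0("z", 1:5))))
  expect_error(predict(model, wrong), class = "schema_mismatch")
})

test_that("consensus predictions equal a manual member-vote tally", {
  ds <- generate_qspr_dataset(90, n_descriptors = 5, separation = 3, seed = 71)
  model <- fit_consensus(ds$descriptors, ds$labels,
                         algorithms = c("RF", "LDA", "DT", "SVM", "AB"),
                         agreement_fraction = 0.8, seed = 72)
  votes <- admespace:::member_votes(model, ds$descriptors)
  manual <- vapply(seq_len(nrow(votes)), function(i)
    consensus_vote(votes[i, ], 0.8), integer(1))
  manual[!in_domain(model$domain, ds$descriptors)] <- 0L
  expect_identical(unname(predict(model, ds$descriptors)), manual)
})

test_that("PLS-score thresholding assigns the three classes by band", {
  expect_identical(pls_threshold_classify(c(-0.9, 0, 0.9), -0.5, 0.5),
                   c(-1L, 0L, 1L))
  # lo = hi = 0 degenerates to a sign function with 0 only at exactly 0
  expect_identical(pls_threshold_classify(c(-2, 0, 2), 0, 0), c(-1L, 0L, 1L))
  set.seed(81)
  s <- stats::rnorm(500)
  oracle <- integer(500)
  for (i in seq_along(s)) {
    if (s[i] > 0.3) oracle[i] <- 1L else if (s[i] < -0.2) oracle[i] <- -1L
  }
  expect_identical(pls_threshold_classify(s, -0.2, 0.3), oracle)
  expect_error(pls_threshold_classify(s, 1, -1), class = "invalid_thresholds")
})

test_that("validation reports exclude abstentions and use the standard MCC", {
  perfect <- evaluate_predictions(c(1, 1, -1, -1), c(1, 1, -1, -1))
  expect_equal(perfect$accuracy, 1.0)
  expect_equal(perfect$mcc, 1.0)
  expect_equal(perfect$coverage, 1.0)

  # frozen confusion counts: TP=40 TN=45 FP=5 FN=10; MCC from the standard
  # formula computed independently below
  pred <- c(rep(1, 40), rep(-1, 45), rep(1, 5), rep(-1, 10), rep(0, 10))
  truth <- c(rep(1, 40), rep(-1, 45), rep(-1, 5), rep(1, 10),
             rep(c(1, -1), 5))
  rep_ <- evaluate_predictions(pred, truth)
  expect_equal(rep_$tp, 40); expect_equal(rep_$tn, 45)
  expect_equal(rep_$fp, 5);  expect_equal(rep_$fn, 10)
  mcc_direct <- (40 * 45 - 5 * 10) /
    sqrt((40 + 5) * (40 + 10) * (45 + 5) * (45 + 10))
  expect_equal(rep_$mcc, mcc_direct)
  expect_equal(rep_$accuracy, 85 / 100)
  expect_equal(rep_$coverage, 100 / 110)

  # single-class predictions: zero denominator, MCC defined as 0
  allpos <- evaluate_predictions(rep(1, 10), rep(c(1, -1), 5))
  expect_equal(allpos$mcc, 0)

  expect_error(evaluate_predictions(rep(0, 5), rep(1, 5)),
               class = "empty_evaluation")
  expect_error(evaluate_predictions(c(1, -1), c(1, 0)),
               class = "invalid_argument")
})

test_that("fingerprint building projects every molecule on all twenty models", {
  cat20 <- adme_catalog()
  # lightweight stand-in models exercising the assembly plumbing
  const_model <- function(value) structure(list(value = value),
                                           class = "const_ternary_model")
  assign("predict.const_ternary_model",
         function(object, newdata, ...)
           rep(object$value, length(newdata$molecule_id)),
         envir = globalenv())
  on.exit(rm("predict.const_ternary_model", envir = globalenv()), add = TRUE)

  X <- descriptor_matrix(paste0("m", 1:4), matrix(stats::rnorm(12), 4, 3))
  models <- stats::setNames(lapply(rep(1L, 20), const_model), cat20$key)
  fp <- build_fingerprints(models, X)
  expect_s3_class(fp, "adme_fingerprints")
  expect_true(all(fingerprint_matrix(fp) == 1))

  # per-model loop oracle: each column equals the model called singly
  vary <- stats::setNames(lapply(seq_len(20) %% 3 - 1, const_model), cat20$key)
  fp2 <- build_fingerprints(vary, X)
  for (k in cat20$key)
    expect_true(all(fp2[[k]] == stats::predict(vary[[k]], X)))

  expect_error(build_fingerprints(models[-1], X),
               class = "incomplete_model_set")
})

test_that("one out-of-domain model yields exactly one uncertain entry", {
  cat20 <- adme_catalog()
  ds <- generate_qspr_dataset(60, n_descriptors = 5, separation = 6, seed = 91)
  real <- fit_consensus(ds$descriptors, ds$labels, algorithms = "LDA", seed = 92)
  # a probe molecule far outside the training box is out-of-domain for the
  # real model; the 19 constant stand-ins always answer
  const_model <- function(value) structure(list(value = value),
                                           class = "const_ternary_model2")
  assign("predict.const_ternary_model2",
         function(object, newdata, ...) rep(object$value, length(newdata$molecule_id)),
         envir = globalenv())
  on.exit(rm("predict.const_ternary_model2", envir = globalenv()), add = TRUE)
  models <- stats::setNames(lapply(rep(1L, 20), const_model), cat20$key)
  models[["PGP_INHIB"]] <- real
  probe <- ds$descriptors$X[1, , drop = FALSE] + 100
  fp <- build_fingerprints(models, descriptor_matrix("probe", probe))
  m <- fingerprint_matrix(fp)
  expect_equal(sum(m == 0), 1L)
  expect_equal(unname(m[1, "PGP_INHIB"]), 0)
})
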