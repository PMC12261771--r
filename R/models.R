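# Model bench: mutual-information feature selection, patient-level
# splitting, five base learners plus a greedy weighted ensemble, metric
# evaluation with patient-level bootstrap confidence intervals, importance
# reporting and logistic confirmation.

#' Rank features by mutual information with the label
#'
#' Plug-in mutual information (nats) between each feature and the binary
#' label. Features with few distinct values are treated as discrete;
#' continuous features are discretized into equal-frequency bins. The
#' estimator is deterministic; ties in MI are broken by catalog (column)
#' order.
#'
#' @param features Data frame of numeric feature columns (imputed).
#' @param labels Binary vector (0/1), one per row.
#' @param bins Number of quantile bins for continuous features.
#' @return Data frame `feature`, `mi`, sorted descending (stable).
#' @export
mutual_information_rank <- function(features, labels, bins = 8) {
  y <- as.integer(labels)
  if (length(unique(y)) < 2) stop("label is constant")
  mi <- vapply(seq_along(features), function(j) {
    x <- features[[j]]
    ok <- is.finite(x)
    if (sum(ok) < 4) return(0)
    xx <- x[ok]; yy <- y[ok]
    ux <- unique(xx)
    b <- if (length(ux) <= bins) {
      match(xx, ux)
    } else {
      br <- unique(quantile(xx, probs = seq(0, 1, length.out = bins + 1)))
      if (length(br) < 3) return(0)
      findInterval(xx, br, rightmost.closed = TRUE, all.inside = TRUE)
    }
    tab <- table(b, yy)
    p <- tab / sum(tab)
    px <- rowSums(p); py <- colSums(p)
    nz <- p > 0
    sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
  }, 0)
  ord <- order(-mi, seq_along(mi))
  data.frame(feature = names(features)[ord], mi = mi[ord])
}

#' Select the top-k features
#'
#' @param ranking Data frame from [mutual_information_rank()].
#' @param k Number of features (default 65, the study's operating point).
#' @return Character vector of `k` feature names, rank order preserved.
#' @export
select_top_k <- function(ranking, k = 65) {
  if (k < 1 || k > nrow(ranking)) stop("k out of range")
  ranking$feature[seq_len(k)]
}

#' Sweep the selection size on validation performance
#'
#' Evaluates candidate top-k subsets on the validation set with a compact
#' reference learner and reports the AUC per k.
#'
#' @param ranking MI ranking.
#' @param train,validation Feature data frames with `label`.
#' @param ks Candidate sizes (default 30-100 by 5).
#' @param seed RNG seed.
#' @return Data frame `k`, `auc`, attribute `best_k`.
#' @export
sweep_selection_size <- function(ranking, train, validation,
                                 ks = seq(30, 100, by = 5), seed = 1L) {
  aucs <- vapply(ks, function(k) {
    feats <- select_top_k(ranking, k)
    m <- .fit_xgb(train, feats, seed = seed, max_depth = 6, nrounds = 60)
    fast_auc(validation$label, .predict_xgb(m, validation, feats))
  }, 0)
  out <- data.frame(k = ks, auc = aucs)
  attr(out, "best_k") <- ks[which.max(aucs)]
  out
}

#' Patient-level train/validation/test split
#'
#' Shuffles patient ids under the seed and assigns 60/20/20 by position;
#' every row of a patient inherits its assignment, so the three sets are
#' disjoint at the patient level.
#'
#' @param patients Character vector of unique patient ids (>= 5).
#' @param proportions Length-3 proportions summing to 1.
#' @param seed RNG seed.
#' @return Named character vector patient -> `train`/`validation`/`test`.
#' @export
patient_split <- function(patients, proportions = c(0.6, 0.2, 0.2),
                          seed = 1L) {
  patients <- unique(patients)
  n <- length(patients)
  if (n < 5) stop("too few patients to split")
  stopifnot(abs(sum(proportions) - 1) < 1e-9)
  set.seed(seed)
  shuffled <- sample(patients)
  n_train <- floor(proportions[1] * n)
  n_val <- floor(proportions[2] * n)
  grp <- rep("test", n)
  grp[seq_len(n_train)] <- "train"
  grp[n_train + seq_len(n_val)] <- "validation"
  setNames(grp, shuffled)[patients]
}

# ---- learners ------------------------------------------------------------

.model_matrix <- function(rows, feats) {
  m <- as.matrix(rows[, feats, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

.fit_xgb <- function(train, feats, seed, max_depth = 6, nrounds = 100,
                     leafwise = FALSE) {
  params <- list(objective = "binary:logistic", eta = 0.1, nthread = 1,
                 lambda = 1, seed = seed)
  if (leafwise) {
    params <- c(params, list(tree_method = "hist",
                             grow_policy = "lossguide", max_depth = 0,
                             max_leaves = 31))
  } else {
    params$max_depth <- max_depth
  }
  dtrain <- xgboost::xgb.DMatrix(.model_matrix(train, feats),
                                 label = train$label)
  set.seed(seed)
  fit <- xgboost::xgb.train(params = params, data = dtrain,
                            nrounds = nrounds, verbose = 0)
  list(fit = fit, feats = feats)
}

.predict_xgb <- function(model, rows, feats = model$feats) {
  predict(model$fit, xgboost::xgb.DMatrix(.model_matrix(rows, feats)))
}

#' Fit the base learner bench
#'
#' Five seeded base learners on the selected features: a depth-wise
#' gradient-boosted tree model (logistic objective with L2 regularization,
#' maximum depth 6), a leaf-wise histogram gradient-boosted tree model
#' (31 leaves), a random forest (100 trees, Gini criterion), extremely
#' randomized trees (100 trees) and an L2-regularized logistic regression
#' baseline.
#'
#' @param train,validation Feature data frames with `label` (validation is
#'   retained for the ensemble stage).
#' @param feats Selected feature names.
#' @param seed RNG seed (models are deterministic given it).
#' @return List of class `model_bench`: named models, each with a
#'   `predict_prob(rows)` closure.
#' @export
fit_models <- function(train, validation, feats, seed = 1L) {
  if (length(unique(train$label)) < 2)
    stop("training data contains a single class")
  Xtr <- .model_matrix(train, feats)
  ytr <- factor(train$label, levels = c(0, 1))

  gbt_depth <- .fit_xgb(train, feats, seed)
  gbt_leaf <- .fit_xgb(train, feats, seed, leafwise = TRUE)

  set.seed(seed)
  rf <- randomForest::randomForest(x = Xtr, y = ytr, ntree = 100)
  et <- ranger::ranger(x = Xtr, y = ytr, num.trees = 100,
                       splitrule = "extratrees", probability = TRUE,
                       seed = seed, num.threads = 1)
  lam <- 0.01
  # glmnet requires >= 2 columns; pad single-feature fits with a zero
  pad <- function(m) if (ncol(m) >= 2) m else cbind(m, `.pad.` = 0)
  lg <- glmnet::glmnet(pad(Xtr), ytr, family = "binomial", alpha = 0,
                       lambda = lam, standardize = TRUE)

  models <- list(
    gbt_depthwise = list(name = "gbt_depthwise", type = "xgb",
                         fit = gbt_depth,
                         predict_prob = function(rows)
                           .predict_xgb(gbt_depth, rows)),
    gbt_leafwise = list(name = "gbt_leafwise", type = "xgb",
                        fit = gbt_leaf,
                        predict_prob = function(rows)
                          .predict_xgb(gbt_leaf, rows)),
    random_forest = list(name = "random_forest", type = "rf", fit = rf,
                         predict_prob = function(rows)
                           predict(rf, .model_matrix(rows, feats),
                                   type = "prob")[, "1"]),
    extra_trees = list(name = "extra_trees", type = "ranger", fit = et,
                       predict_prob = function(rows)
                         predict(et, .model_matrix(rows, feats),
                                 num.threads = 1)$predictions[, "1"]),
    logit_l2 = list(name = "logit_l2", type = "glmnet", fit = lg,
                    predict_prob = function(rows)
                      as.numeric(predict(lg,
                                         pad(.model_matrix(rows, feats)),
                                         type = "response"))))
  structure(list(models = models, feats = feats, seed = seed,
                 validation = validation),
            class = "model_bench")
}

#' Greedy weighted ensemble over the base learners
#'
#' Forward selection with replacement (Caruana-style) of base-model
#' predicted probabilities, maximizing validation AUC; the search starts
#' from the best single model and stops when no addition improves, so the
#' ensemble's validation AUC is never below the best base learner's.
#' Weights are nonnegative and sum to one.
#'
#' @param bench A [fit_models()] bench.
#' @param validation Validation rows (default: those stored in the bench).
#' @param max_iter Maximum number of greedy additions.
#' @return The bench with an added `weighted_ensemble` model (weights in
#'   `$weights`).
#' @export
build_weighted_ensemble <- function(bench, validation = bench$validation,
                                    max_iter = 50) {
  if (is.null(validation) || !nrow(validation))
    stop("no validation rows for ensemble construction")
  preds <- vapply(bench$models, function(m) m$predict_prob(validation),
                  numeric(nrow(validation)))
  y <- validation$label
  counts <- setNames(rep(0L, ncol(preds)), colnames(preds))
  best <- which.max(apply(preds, 2, function(p) fast_auc(y, p)))
  counts[best] <- 1L
  ens <- preds[, best]
  best_auc <- fast_auc(y, ens)
  for (it in seq_len(max_iter)) {
    cand <- vapply(seq_len(ncol(preds)), function(j)
      fast_auc(y, (ens * sum(counts) + preds[, j]) / (sum(counts) + 1)), 0)
    j <- which.max(cand)
    if (cand[j] <= best_auc + 1e-12) break
    ens <- (ens * sum(counts) + preds[, j]) / (sum(counts) + 1)
    counts[j] <- counts[j] + 1L
    best_auc <- cand[j]
  }
  w <- counts / sum(counts)
  models <- bench$models
  bench$weights <- w
  bench$models$weighted_ensemble <- list(
    name = "weighted_ensemble", type = "ensemble", fit = w,
    predict_prob = function(rows) {
      pm <- vapply(models, function(m) m$predict_prob(rows),
                   numeric(nrow(rows)))
      as.numeric(pm %*% w)
    })
  bench
}

# Rank-statistic AUC (equivalent to the Wilcoxon estimator).
#' @export
fast_auc <- function(y, p) {
  y <- as.integer(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(p, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.threshold_metrics <- function(y, p, threshold = 0.5) {
  pred <- as.integer(p >= threshold)
  tp <- sum(pred == 1 & y == 1); tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0); fn <- sum(pred == 0 & y == 1)
  c(accuracy = (tp + tn) / length(y),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    auc = fast_auc(y, p))
}

#' Evaluate a model with patient-level bootstrap confidence intervals
#'
#' Accuracy, AUC, sensitivity and specificity at the probability threshold
#' (default 0.5) on the supplied rows, with percentile bootstrap intervals
#' formed by resampling patients (not rows) with replacement. Accuracy,
#' sensitivity and specificity are reported as percentages.
#'
#' @param model One element of a `model_bench$models` list.
#' @param rows Evaluation rows (must contain both classes).
#' @param n_boot Bootstrap replicates.
#' @param seed RNG seed.
#' @param threshold Classification threshold on predicted probability.
#' @return Object of class `model_report`.
#' @export
evaluate_model <- function(model, rows, n_boot = 1000, seed = 1L,
                           threshold = 0.5) {
  if (length(unique(rows$label)) < 2)
    stop("evaluation rows contain a single class")
  p <- model$predict_prob(rows)
  y <- rows$label
  point <- .threshold_metrics(y, p, threshold)
  pats <- unique(rows$patient_id)
  idx_by_pat <- split(seq_len(nrow(rows)), rows$patient_id)
  set.seed(seed)
  boots <- matrix(NA_real_, n_boot, 4)
  for (b in seq_len(n_boot)) {
    take <- unlist(idx_by_pat[sample(length(pats), replace = TRUE)],
                   use.names = FALSE)
    if (length(unique(y[take])) < 2) next
    boots[b, ] <- .threshold_metrics(y[take], p[take], threshold)
  }
  ci <- apply(boots, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  colnames(ci) <- names(point)
  pred <- as.integer(p >= threshold)
  cm <- table(factor(pred, levels = c(0, 1)), factor(y, levels = c(0, 1)),
              dnn = c("predicted", "actual"))
  structure(list(model = model$name, metrics = point, ci = ci,
                 confusion = cm, n_rows = nrow(rows),
                 n_patients = length(pats), threshold = threshold),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  m <- x$metrics; ci <- x$ci
  fmt <- function(k, pct) {
    v <- if (pct) 100 * c(m[k], ci[, k]) else c(m[k], ci[, k])
    sprintf("%.2f (%.2f, %.2f)%s", v[1], v[2], v[3], if (pct) "%" else "")
  }
  cat("<model_report ", x$model, "> n=", x$n_rows, " rows / ",
      x$n_patients, " patients\n",
      "  accuracy    ", fmt("accuracy", TRUE), "\n",
      "  sensitivity ", fmt("sensitivity", TRUE), "\n",
      "  specificity ", fmt("specificity", TRUE), "\n",
      "  AUC         ", fmt("auc", FALSE), "\n", sep = "")
  invisible(x)
}

#' Feature-importance report
#'
#' For the gradient-boosted tree models, per-feature mean absolute SHAP
#' (tree-explainer) contributions; for other models, permutation
#' importance (AUC drop when a feature column is permuted, averaged over
#' repeats).
#'
#' @param model One element of a `model_bench$models` list.
#' @param rows Evaluation rows.
#' @param feats Feature names (needed for non-tree models).
#' @param n_perm Permutation repeats for the fallback path.
#' @param seed RNG seed.
#' @return Data frame `feature`, `importance`, descending.
#' @export
importance_report <- function(model, rows, feats = NULL, n_perm = 5,
                              seed = 1L) {
  if (model$type == "xgb") {
    feats <- model$fit$feats
    contrib <- predict(model$fit$fit,
                       xgboost::xgb.DMatrix(.model_matrix(rows, feats)),
                       predcontrib = TRUE)
    imp <- colMeans(abs(contrib[, feats, drop = FALSE]))
    out <- data.frame(feature = feats, importance = as.numeric(imp))
    return(out[order(-out$importance), ])
  }
  stopifnot(!is.null(feats))
  base <- fast_auc(rows$label, model$predict_prob(rows))
  set.seed(seed)
  drop <- vapply(feats, function(f) {
    mean(vapply(seq_len(n_perm), function(r) {
      rp <- rows
      rp[[f]] <- sample(rp[[f]])
      base - fast_auc(rp$label, model$predict_prob(rp))
    }, 0))
  }, 0)
  out <- data.frame(feature = feats, importance = as.numeric(drop))
  out[order(-out$importance), ]
}

#' SHAP additivity check helper
#'
#' Returns per-row `sum(contributions) + bias - margin prediction` for a
#' gradient-boosted tree model; values should vanish to numerical
#' tolerance.
#' @keywords internal
#' @export
shap_additivity_gap <- function(model, rows) {
  stopifnot(model$type == "xgb")
  feats <- model$fit$feats
  dm <- xgboost::xgb.DMatrix(.model_matrix(rows, feats))
  contrib <- predict(model$fit$fit, dm, predcontrib = TRUE)
  margin <- predict(model$fit$fit, dm, outputmargin = TRUE)
  rowSums(contrib) - margin
}

#' Per-feature logistic confirmation
#'
#' For each feature: a simple (unadjusted) logistic regression of the
#' window label on the feature, and a multivariable model adjusted for
#' age, sex, body-mass index, and neck and waist circumference. Reports
#' odds ratios per unit with Wald 95% confidence intervals, two-sided p
#' values, significance stars at 0.05/0.01 and a separation flag.
#'
#' @param rows Feature data frame with `label` and covariate columns.
#' @param feats Feature names to test.
#' @param covariates Covariate column names for the adjusted model.
#' @return Data frame, one row per feature.
#' @export
logistic_confirmation <- function(rows, feats,
                                  covariates = c("age", "sex", "bmi",
                                                 "neck", "waist")) {
  covariates <- covariates[covariates %in% names(rows)]
  one <- function(f) {
    fit_one <- function(fml) {
      fit <- suppressWarnings(glm(fml, data = rows, family = binomial()))
      co <- summary(fit)$coefficients
      if (!(f %in% rownames(co)))
        return(c(NA_real_, NA_real_, NA_real_, NA_real_, 1))
      b <- co[f, 1]; se <- co[f, 2]; pval <- co[f, 4]
      sep <- as.numeric(abs(b) > 20 || se > 100)  # quasi-separation flag
      c(exp(b), exp(b - 1.96 * se), exp(b + 1.96 * se), pval, sep)
    }
    u <- fit_one(stats::reformulate(f, response = "label"))
    a <- fit_one(stats::reformulate(c(f, covariates), response = "label"))
    data.frame(feature = f,
               or = u[1], or_low = u[2], or_high = u[3], p = u[4],
               adj_or = a[1], adj_or_low = a[2], adj_or_high = a[3],
               adj_p = a[4],
               stars = if (is.na(u[4])) "" else if (u[4] < 0.01) "**"
                       else if (u[4] < 0.05) "*" else "",
               separation = (u[5] + a[5]) > 0)
  }
  do.call(rbind, lapply(feats, one))
}
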