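# Synthetic feature tables for the modeling stage: patient-structured rows
# with a controllable signal feature.
make_rows <- function(n_pat = 30, rows_per = 10, signal = 2, seed = 1,
                      n_noise = 10) {
  set.seed(seed)
  pid <- rep(sprintf("P%03d", seq_len(n_pat)), each = rows_per)
  label <- rep(rep(c(1L, 0L), each = rows_per / 2), n_pat)
  df <- data.frame(patient_id = pid, label = label)
  df$sig <- rnorm(nrow(df)) + signal * label
  for (j in seq_len(n_noise)) df[[paste0("noise", j)]] <- rnorm(nrow(df))
  df$age <- rep(round(rnorm(n_pat, 65, 10)), each = rows_per)
  df$sex <- rep(sample(c("M", "F"), n_pat, TRUE), each = rows_per)
  df$bmi <- rep(rnorm(n_pat, 29, 5), each = rows_per)
  df$neck <- rep(rnorm(n_pat, 38, 3), each = rows_per)
  df$waist <- rep(rnorm(n_pat, 100, 10), each = rows_per)
  df
}

feat_cols <- function(df) setdiff(names(df),
                                  c("patient_id", "label", "age", "sex",
                                    "bmi", "neck", "waist", "set"))

test_that("mutual information: perfect predictor carries ln 2 nats", {
  y <- rep(c(0, 1), 50)
  df <- data.frame(perfect = y, junk = seq_len(100))
  r <- mutual_information_rank(df, y)
  expect_equal(r$mi[r$feature == "perfect"], log(2), tolerance = 1e-12)
  expect_equal(r$feature[1], "perfect")
})

test_that("mutual information of independent features sits at the null", {
  set.seed(7)
  y <- rep(c(0, 1), 100)
  x <- rnorm(200)
  mi <- mutual_information_rank(data.frame(x = x), y)$mi
  null <- replicate(200, {
    mutual_information_rank(data.frame(x = sample(x)), y)$mi
  })
  expect_lte(mi, quantile(null, 0.95) + 1e-12)
  expect_error(mutual_information_rank(data.frame(x = x), rep(1, 200)),
               "constant")
})

test_that("duplicated columns tie and resolve by column order", {
  set.seed(8)
  y <- rep(c(0, 1), 60)
  x <- rnorm(120) + y
  df <- data.frame(b_copy = x, a_copy = x, other = rnorm(120))
  r <- mutual_information_rank(df, y)
  expect_equal(r$mi[1], r$mi[2])
  expect_identical(r$feature[1:2], c("b_copy", "a_copy"))  # input order
})

test_that("top-k selection returns exactly k names in rank order", {
  rk <- data.frame(feature = letters[1:10], mi = 10:1)
  expect_identical(select_top_k(rk, 3), c("a", "b", "c"))
  expect_identical(select_top_k(rk, 10), letters[1:10])
  expect_error(select_top_k(rk, 11), "out of range")
  expect_error(select_top_k(rk, 0), "out of range")
})

test_that("patient split is disjoint, exhaustive and 60/20/20", {
  ids <- sprintf("P%03d", 1:100)
  for (seed in 1:25) {
    sp <- patient_split(ids, seed = seed)
    expect_setequal(names(sp), ids)
    expect_equal(sum(sp == "train"), 60)
    expect_equal(sum(sp == "validation"), 20)
    expect_equal(sum(sp == "test"), 20)
  }
  expect_identical(patient_split(ids, seed = 4), patient_split(ids, seed = 4))
  expect_error(patient_split(ids[1:3]), "too few")
})

test_that("base learners separate an easy problem and respect seeds", {
  df <- make_rows(signal = 6)
  sp <- patient_split(unique(df$patient_id), seed = 2)
  df$set <- sp[df$patient_id]
  train <- df[df$set == "train", ]; val <- df[df$set == "validation", ]
  bench <- fit_models(train, val, feat_cols(df), seed = 11)
  for (m in bench$models) {
    expect_gte(fast_auc(train$label, m$predict_prob(train)), 0.99)
  }
  bench2 <- fit_models(train, val, feat_cols(df), seed = 11)
  for (nm in names(bench$models))
    expect_equal(bench$models[[nm]]$predict_prob(val),
                 bench2$models[[nm]]$predict_prob(val))
  expect_error(fit_models(train[train$label == 1, ], val, feat_cols(df)),
               "single class")
})

test_that("permuted labels leave every model near chance", {
  df <- make_rows(signal = 0, seed = 3, n_pat = 60)
  set.seed(33)
  df$label <- sample(df$label)
  sp <- patient_split(unique(df$patient_id), seed = 3)
  df$set <- sp[df$patient_id]
  train <- df[df$set == "train", ]; val <- df[df$set == "validation", ]
  bench <- fit_models(train, val, feat_cols(df), seed = 5)
  for (m in bench$models) {
    auc <- fast_auc(val$label, m$predict_prob(val))
    expect_gt(auc, 0.3); expect_lt(auc, 0.7)
  }
})

test_that("weighted ensemble never falls below the best base learner", {
  df <- make_rows(signal = 1.2, seed = 4)
  sp <- patient_split(unique(df$patient_id), seed = 4)
  df$set <- sp[df$patient_id]
  train <- df[df$set == "train", ]; val <- df[df$set == "validation", ]
  bench <- build_weighted_ensemble(fit_models(train, val, feat_cols(df),
                                              seed = 7))
  w <- bench$weights
  expect_true(all(w >= 0))
  expect_equal(sum(w), 1)
  base_aucs <- vapply(bench$models[names(w)], function(m)
    fast_auc(val$label, m$predict_prob(val)), 0)
  ens_auc <- fast_auc(val$label,
                      bench$models$weighted_ensemble$predict_prob(val))
  expect_gte(ens_auc, max(base_aucs) - 1e-9)
  # dominant model receives the largest weight
  expect_equal(names(which.max(w)), names(which.max(base_aucs)))
})

test_that("evaluation metrics and bootstrap CIs behave at the extremes", {
  df <- make_rows(signal = 0, seed = 5, n_pat = 20)
  perfect <- list(name = "perfect", type = "fn",
                  predict_prob = function(rows) rows$label * 0.98 + 0.01)
  rep1 <- evaluate_model(perfect, df, n_boot = 50, seed = 1)
  expect_equal(unname(rep1$metrics["accuracy"]), 1)
  expect_equal(unname(rep1$metrics["auc"]), 1)
  expect_equal(unname(rep1$ci["2.5%", "auc"]), 1)
  allpos <- list(name = "allpos", type = "fn",
                 predict_prob = function(rows) rep(0.9, nrow(rows)))
  rep2 <- evaluate_model(allpos, df, n_boot = 10, seed = 1)
  expect_equal(unname(rep2$metrics["sensitivity"]), 1)
  expect_equal(unname(rep2$metrics["specificity"]), 0)
  coin <- list(name = "coin", type = "fn",
               predict_prob = function(rows) {
                 set.seed(9); runif(nrow(rows))
               })
  rep3 <- evaluate_model(coin, df, n_boot = 10, seed = 1)
  expect_gt(unname(rep3$metrics["accuracy"]), 0.38)
  expect_lt(unname(rep3$metrics["accuracy"]), 0.62)
  expect_error(evaluate_model(perfect, df[df$label == 1, ], n_boot = 5),
               "single class")
})

test_that("fast_auc agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  for (i in 1:10) {
    y <- rbinom(80, 1, 0.4)
    if (length(unique(y)) < 2) next
    p <- runif(80)
    ref <- pROC::roc(y, p, direction = "<", levels = c(0, 1),
                     quiet = TRUE)
    expect_equal(fast_auc(y, p), as.numeric(pROC::auc(ref)),
                 tolerance = 1e-12)
  }
})

test_that("tree-SHAP importance is additive and finds the only signal", {
  df <- make_rows(signal = 3, seed = 6)
  sp <- patient_split(unique(df$patient_id), seed = 6)
  df$set <- sp[df$patient_id]
  train <- df[df$set == "train", ]; val <- df[df$set == "validation", ]
  test <- df[df$set == "test", ]
  bench <- fit_models(train, val, feat_cols(df), seed = 8)
  imp <- importance_report(bench$models$gbt_depthwise, test)
  expect_identical(imp$feature[1], "sig")
  # a model fit on the single informative feature attributes everything
  # to it
  solo <- .subset2(fit_models(train, val, "sig", seed = 8), "models")
  imps <- importance_report(solo$gbt_depthwise, test)
  expect_identical(imps$feature[1], "sig")
  expect_gte(imps$importance[imps$feature == "sig"] /
               sum(imps$importance), 0.99)
  gap <- shap_additivity_gap(bench$models$gbt_depthwise, test)
  expect_lt(max(abs(gap)), 1e-4)
  # permutation fallback for non-tree models agrees on the winner
  impp <- importance_report(bench$models$logit_l2, test,
                            feats = feat_cols(df), seed = 8)
  expect_identical(impp$feature[1], "sig")
})

test_that("permuting a top feature hurts more than a bottom feature", {
  df <- make_rows(signal = 2.5, seed = 9)
  sp <- patient_split(unique(df$patient_id), seed = 9)
  df$set <- sp[df$patient_id]
  train <- df[df$set == "train", ]; val <- df[df$set == "validation", ]
  bench <- fit_models(train, val, feat_cols(df), seed = 9)
  m <- bench$models$gbt_depthwise
  base <- fast_auc(val$label, m$predict_prob(val))
  set.seed(10)
  perm_drop <- function(f) {
    v <- val; v[[f]] <- sample(v[[f]])
    base - fast_auc(v$label, m$predict_prob(v))
  }
  expect_gt(perm_drop("sig"), perm_drop("noise1") + 0.05)
})

test_that("logistic confirmation recovers the 2x2 closed-form odds ratio", {
  # counts [40, 10; 10, 40] -> OR = (40*40)/(10*10) = 16
  df <- data.frame(
    label = c(rep(1, 50), rep(0, 50)),
    x = c(rep(1, 40), rep(0, 10), rep(1, 10), rep(0, 40)))
  out <- logistic_confirmation(df, "x", covariates = character(0))
  expect_equal(out$or, 16, tolerance = 1e-6)
  expect_identical(out$stars, "**")
  # scaling a feature by c scales ln(OR) by 1/c
  df$xs <- df$x * 10
  out2 <- logistic_confirmation(df, "xs", covariates = character(0))
  expect_equal(log(out2$or), log(out$or) / 10, tolerance = 1e-6)
})

test_that("logistic CI covers 1 for independent features", {
  set.seed(13)
  cover <- vapply(1:30, function(i) {
    df <- data.frame(label = rbinom(120, 1, 0.5), x = rnorm(120))
    out <- logistic_confirmation(df, "x", covariates = character(0))
    out$or_low <= 1 && out$or_high >= 1
  }, logical(1))
  expect_gte(mean(cover), 0.8)   # nominal 95% coverage, 30 draws
})

test_that("adjusted model conditions on covariates without breaking", {
  df <- make_rows(signal = 1.5, seed = 14)
  out <- logistic_confirmation(df, c("sig", "noise1"))
  expect_equal(nrow(out), 2)
  expect_gt(out$adj_or[out$feature == "sig"], 1)
  expect_false(any(out$separation[is.finite(out$or)] &
                     out$feature == "noise1"))
})

test_that("selection-size sweep evaluates candidate k and reports the best", {
  df <- make_rows(signal = 2, seed = 15, n_pat = 25, n_noise = 40)
  sp <- patient_split(unique(df$patient_id), seed = 15)
  df$set <- sp[df$patient_id]
  train <- df[df$set == "train", ]; val <- df[df$set == "validation", ]
  rk <- mutual_information_rank(train[feat_cols(df)], train$label)
  sw <- sweep_selection_size(rk, train, val, ks = c(5, 10, 20), seed = 2)
  expect_equal(sw$k, c(5, 10, 20))
  expect_true(all(sw$auc >= 0 & sw$auc <= 1))
  expect_true(attr(sw, "best_k") %in% sw$k)
})
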