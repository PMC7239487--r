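make_linear_table <- function(n = 800, seed = 1, slope = 2) {
  set.seed(seed)
  d <- data.frame(x_mean = runif(n, 0, 10), x_sd = rnorm(n),
                  y_mean = rnorm(n), z_mean = rnorm(n), vm_mean = rnorm(n))
  d$ee_kcal_min <- slope * d$x_mean
  d
}

test_that("all three learners fit a constant target", {
  tab <- small_cohort_table()
  tab$ee_kcal_min <- 1.5
  for (alg in c("rf", "svm_rbf", "ann")) {
    run <- suppressWarnings(train_model(model_config(alg, seed = 4), tab))
    p <- predict_ee(run, tab)
    tol <- if (alg == "rf") 1e-6 else 1e-3
    expect_lt(max(abs(p - 1.5)), tol)
  }
})

test_that("training is deterministic given the seed", {
  tab <- small_cohort_table()
  for (alg in c("rf", "svm_rbf", "ann")) {
    r1 <- train_model(model_config(alg, seed = 11), tab)
    r2 <- train_model(model_config(alg, seed = 11), tab)
    expect_identical(predict_ee(r1, tab), predict_ee(r2, tab))
  }
})

test_that("a noiseless linear signal is learnable by every architecture", {
  train <- make_linear_table(800, seed = 1)
  test <- make_linear_table(400, seed = 2)
  feats <- setdiff(names(train), "ee_kcal_min")
  sdy <- sd(test$ee_kcal_min)
  for (alg in c("rf", "svm_rbf", "ann")) {
    run <- train_model(model_config(alg, seed = 3), train, feats)
    err <- rmse(predict_ee(run, test), test$ee_kcal_min)
    expect_lt(err, 0.05 * sdy)
  }
})

test_that("predictions are non-negative, ordered, and empty-safe", {
  tab <- small_cohort_table()
  run <- train_model(model_config("rf", seed = 2), tab)
  expect_identical(predict_ee(run, tab[0, ]), numeric(0))
  p <- predict_ee(run, tab)
  expect_true(all(p >= 0))
  perm <- sample(nrow(tab))
  expect_equal(predict_ee(run, tab[perm, ]), p[perm], tolerance = 1e-12)
  expect_error(predict_ee(run, tab[, 1:3]), "lack feature")
  # in-sample optimism: training error well below leave-subject-out error
  loso <- loso_cv(model_config("rf", k_features = 10, seed = 2), tab)
  expect_lt(rmse(p, tab$ee_kcal_min), mean(loso$per_subject$rmse_kcal))
})

test_that("LOSO partitions subjects exactly once with no leakage", {
  tab <- small_cohort_table()
  subjects <- unique(tab$participant_id)
  res <- loso_cv(model_config("rf", k_features = 10, seed = 5), tab)
  expect_setequal(res$per_subject$participant_id, subjects)
  expect_equal(nrow(res$per_subject), length(subjects))
  expect_equal(anyDuplicated(res$per_subject$participant_id), 0)
  # predictions cover each subject's windows exactly
  cnt <- table(tab$participant_id)
  expect_equal(unname(table(res$predictions$participant_id)[names(cnt)]),
               unname(cnt))
  # per-subject metrics recomputable from the exported predictions
  for (s in subjects) {
    ps <- res$predictions[res$predictions$participant_id == s, ]
    expect_equal(rmse(ps$pred, ps$obs),
                 res$per_subject$rmse_kcal[
                   res$per_subject$participant_id == s],
                 tolerance = 1e-12)
    expect_equal(as.numeric(mape(ps$pred, ps$obs)),
                 res$per_subject$mape[res$per_subject$participant_id == s],
                 tolerance = 1e-12)
  }
  # summary recomputable from per-subject values
  expect_equal(unname(res$summary$rmse_kcal["mean"]),
               mean(res$per_subject$rmse_kcal), tolerance = 1e-12)
  expect_error(loso_cv(model_config("rf"),
                       tab[tab$participant_id == subjects[1], ]),
               "2 subjects")
})

test_that("MET-scale metrics equal kcal metrics divided by subject REE", {
  tab <- small_cohort_table()
  res <- loso_cv(model_config("rf", k_features = 10, seed = 5), tab)
  ree <- tapply(tab$ree, tab$participant_id, function(x) x[1])
  per <- res$per_subject
  expect_equal(per$rmse_met,
               per$rmse_kcal / as.numeric(ree[per$participant_id]),
               tolerance = 1e-9)
})

test_that("hold-out evaluation rejects train/test subject overlap", {
  tab <- small_cohort_table()
  subjects <- unique(tab$participant_id)
  train_tab <- tab[tab$participant_id %in% subjects[1:2], ]
  ho_tab <- tab[tab$participant_id %in% subjects[3:4], ]
  run <- train_model(model_config("rf", k_features = 10, seed = 1),
                     train_tab)
  res <- holdout_evaluate(list(rf = run), ho_tab)
  expect_equal(rownames(res$error_matrix), subjects[3:4])
  expect_error(holdout_evaluate(list(rf = run), train_tab), "overlap")
  # metrics equal the evaluation primitives applied to exported predictions
  pr <- res$predictions
  for (s in subjects[3:4]) {
    ps <- pr[pr$participant_id == s, ]
    expect_equal(rmse(ps$pred, ps$obs),
                 res$per_model$rf$rmse_kcal[
                   res$per_model$rf$participant_id == s],
                 tolerance = 1e-12)
  }
})
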