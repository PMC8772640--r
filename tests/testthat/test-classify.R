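test_that("kernel evaluations match their closed forms", {
  u <- c(1, 2); v <- c(1, 2)
  expect_equal(kernel_eval(svm_spec("rbf", gamma = 1), u, v), 1)
  expect_equal(kernel_eval(svm_spec("sigmoid", gamma = 0.5, coeff = 0),
                           c(1, 0), c(0, 1)), 0)
  expect_equal(kernel_eval(svm_spec("polynomial", gamma = 1, coeff = 1,
                                    degree = 2), c(1, 1), c(1, 1)), 9)
  expect_error(kernel_eval(svm_spec("rbf"), c(1, 2), c(1, 2, 3)),
               "dimension")

  set.seed(30)
  for (i in 1:100) {
    u <- stats::rnorm(3); v <- stats::rnorm(3)
    g <- stats::runif(1, 0.1, 2); c0 <- stats::runif(1, 0, 1)
    d <- sample(2:3, 1)
    expect_equal(kernel_eval(svm_spec("rbf", g), u, v),
                 exp(-g * sum((u - v)^2)))
    expect_equal(kernel_eval(svm_spec("sigmoid", g, c0), u, v),
                 tanh(g * sum(u * v) + c0))
    expect_equal(kernel_eval(svm_spec("polynomial", g, c0, d), u, v),
                 (g * sum(u * v) + c0)^d)
  }
})

test_that("spec constructors validate their parameters", {
  expect_error(svm_spec("rbf", gamma = -1), "gamma")
  expect_error(knn_spec(0), "k must")
  expect_error(rf_spec(0), "n_trees")
  expect_s3_class(knn_spec(18, "chebyshev"), "ofs_knn_spec")
})

test_that("1-NN memorizes distinct training points", {
  blobs <- make_blobs(30, sep = 3, sd = 1, seed = 41)
  m <- ofs_train(blobs, knn_spec(1, "chebyshev"))
  expect_equal(ofs_evaluate(m, blobs)$global_accuracy, 1)
})

test_that("separable blobs are classified perfectly by every method", {
  train <- make_blobs(50, sep = 8, sd = 0.5, seed = 42)
  test <- make_blobs(30, sep = 8, sd = 0.5, seed = 43)
  for (spec in list(svm_spec("rbf", gamma = 0.5),
                    knn_spec(5, "euclidean"),
                    rf_spec(50))) {
    ev <- ofs_evaluate(ofs_train(train, spec, seed = 1), test)
    expect_equal(ev$global_accuracy, 1)
  }
})

test_that("kNN metrics give the expected nearest neighbours", {
  # Chebyshev vs Manhattan disagree on this geometry:
  # query (0,0); A at (3,3) (cheb 3, manh 6), B at (0,5) (cheb 5, manh 5)
  train <- data.frame(hrv_z = c(3, 0), pd_z = c(3, 5),
                      label = factor(c("low", "high"),
                                     levels = c("low", "high")))
  q <- data.frame(hrv_z = 0, pd_z = 0)
  cheb <- ofs_train(train, knn_spec(1, "chebyshev"))
  manh <- ofs_train(train, knn_spec(1, "manhattan"))
  expect_equal(as.character(predict(cheb, q)), "low")
  expect_equal(as.character(predict(manh, q)), "high")
  # squared euclidean ranks like euclidean
  se <- ofs_train(train, knn_spec(1, "squared_euclidean"))
  eu <- ofs_train(train, knn_spec(1, "euclidean"))
  expect_equal(predict(se, q), predict(eu, q))
})

test_that("training demands at least two classes and is seed-deterministic", {
  blobs <- make_blobs(40, seed = 44)
  single <- blobs[blobs$label == "low", ]
  expect_error(ofs_train(single, rf_spec(10)), "single class")

  test <- make_blobs(40, seed = 45)
  for (spec in list(svm_spec("sigmoid", 0.5, 0), knn_spec(3, "manhattan"),
                    rf_spec(30))) {
    p1 <- predict(ofs_train(blobs, spec, seed = 7), test)
    p2 <- predict(ofs_train(blobs, spec, seed = 7), test)
    expect_identical(p1, p2)
  }
})

test_that("more trees stabilize random-forest predictions across seeds", {
  train <- make_blobs(40, sep = 2, sd = 2, seed = 46)
  test <- make_blobs(40, sep = 2, sd = 2, seed = 47)
  acc <- function(n_trees) sapply(1:10, function(s)
    ofs_evaluate(ofs_train(train, rf_spec(n_trees), seed = s),
                 test)$global_accuracy)
  expect_lt(stats::sd(acc(68)), stats::sd(acc(1)))
})

test_that("evaluation reports recall per class and a consistent global rate", {
  # constant-"high" predictor: train 1-NN where every test point's
  # neighbour is the high centroid
  train <- data.frame(hrv_z = c(100, 100, 0), pd_z = c(100, -100, 0),
                      label = factor(c("low", "medium", "high"),
                                     levels = c("low", "medium", "high")))
  test <- data.frame(hrv_z = stats::rnorm(30), pd_z = stats::rnorm(30),
                     label = factor(rep(c("low", "medium", "high"), each = 10),
                                    levels = c("low", "medium", "high")))
  ev <- ofs_evaluate(ofs_train(train, knn_spec(1, "euclidean")), test)
  expect_equal(ev$global_accuracy, 1 / 3, tolerance = 1e-12)
  expect_equal(unname(ev$class_accuracy), c(0, 0, 1))

  # global accuracy equals the prior-weighted mean of per-class recalls
  blobs <- make_blobs(25, sep = 1.5, sd = 1.5, seed = 48)
  m <- ofs_train(blobs, rf_spec(20), seed = 1)
  test2 <- make_blobs(40, sep = 1.5, sd = 1.5, seed = 49)
  ev2 <- ofs_evaluate(m, test2)
  priors <- prop.table(table(test2$label))
  expect_equal(ev2$global_accuracy,
               sum(priors * ev2$class_accuracy))

  expect_error(ofs_evaluate(m, test2[0, ]), "empty")
})

test_that("grid search maximizes cross-validated accuracy", {
  blobs <- make_blobs(40, sep = 6, sd = 0.8, seed = 50)
  single <- grid_search(blobs, list(knn_spec(3, "euclidean")), seed = 1)
  expect_equal(single$best_spec, knn_spec(3, "euclidean"))
  expect_error(grid_search(blobs, list()), "empty grid")

  g <- default_grid("knn")
  res <- grid_search(blobs, g, seed = 2)
  expect_gte(res$cv_accuracy, max(res$results$cv_accuracy) - 1e-12)
  # separable data: the selected spec achieves (near-)perfect CV accuracy
  expect_gte(res$cv_accuracy, 0.98)

  # every printed best setting is reachable in the default grids
  fmt <- function(g) vapply(g, format, character(1))
  expect_true(format(best_setting("svm", 3)) %in% fmt(default_grid("svm")))
  expect_true(format(best_setting("svm", 2)) %in% fmt(default_grid("svm")))
  expect_true(format(best_setting("knn", 3)) %in% fmt(default_grid("knn")))
  expect_true(format(best_setting("knn", 2)) %in% fmt(default_grid("knn")))
  expect_true(format(best_setting("rf", 3)) %in% fmt(default_grid("rf")))
  expect_true(format(best_setting("rf", 2)) %in% fmt(default_grid("rf")))
})

test_that("permuted labels drop every method to chance", {
  set.seed(51)
  blobs <- make_blobs(80, sep = 6, sd = 0.8, seed = 51)
  blobs$label <- sample(blobs$label)
  sp <- individual_split(blobs$label, seed = 1)
  n_te <- length(sp$test)
  for (spec in list(svm_spec("rbf", 0.5), knn_spec(25, "euclidean"),
                    rf_spec(68))) {
    ev <- ofs_evaluate(ofs_train(blobs[sp$train, ], spec, seed = 1),
                       blobs[sp$test, ])
    # chance is 1/3; allow 4 binomial SDs
    expect_lt(abs(ev$global_accuracy - 1 / 3),
              4 * sqrt(1 / 3 * 2 / 3 / n_te))
  }
})

test_that("the two-layer experiment reports the full protocol structure", {
  cfg <- short_scenario()
  # drift-free participants keep the layers exchangeable: the slow pupil
  # drift is a per-session process that individual splits can exploit
  pop <- participant_params(pupil_drift_sd = 0, pupil_load_gain = 0.4)
  coh <- generate_cohort(cfg, n_participants = 6, heterogeneity = 0,
                         seed = 52, population = pop)
  ex <- run_two_layer_experiment(coh, methods = c("knn", "rf"),
                                 n_classes = 3, seed = 1)
  expect_s3_class(ex, "ofs_experiment")
  r <- ex$results[["3"]][["knn"]]
  expect_named(r$individual,
               c("accuracies", "mean", "sd", "min", "max", "specs"))
  expect_length(r$individual$accuracies, 6)
  expect_true(all(r$pooled$class_accuracy >= 0 &
                    r$pooled$class_accuracy <= 1))
  expect_equal(names(r$pooled$class_accuracy), c("low", "medium", "high"))
  # probe-aligned predictions available for subjective validation
  expect_true(all(c("ofs", "isa") %in% names(ex$predictions)))

  # exchangeable participants: pooled and individual accuracy agree
  expect_lt(abs(r$pooled$global_accuracy - r$individual$mean), 0.12)
})
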