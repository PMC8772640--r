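#' Classifier specifications
#'
#' Lightweight descriptions of the three supervised methods compared in
#' the package: support vector machines with RBF, sigmoid or polynomial
#' kernels; k-nearest neighbours under four distance metrics; and random
#' forests with a given number of trees.
#'
#' @param kernel Kernel family: `"rbf"`, `"sigmoid"` or `"polynomial"`.
#' @param gamma Kernel scale parameter (> 0 for RBF).
#' @param coeff Kernel offset (sigmoid/polynomial).
#' @param degree Polynomial degree (integer >= 1).
#' @return An object of class `c("ofs_svm_spec", "ofs_spec")`,
#'   `c("ofs_knn_spec", "ofs_spec")` or `c("ofs_rf_spec", "ofs_spec")`.
#' @export
svm_spec <- function(kernel = c("sigmoid", "rbf", "polynomial"),
                     gamma = 0.5, coeff = 0, degree = 3L) {
  kernel <- match.arg(kernel)
  if (kernel == "rbf" && gamma <= 0)
    stop("RBF kernel needs gamma > 0", call. = FALSE)
  degree <- as.integer(degree)
  if (degree < 1) stop("degree must be a positive integer", call. = FALSE)
  structure(list(method = "svm", kernel = kernel, gamma = gamma,
                 coeff = coeff, degree = degree),
            class = c("ofs_svm_spec", "ofs_spec"))
}

#' @rdname svm_spec
#' @param k Number of neighbours (>= 1).
#' @param metric Distance: `"chebyshev"`, `"euclidean"`,
#'   `"squared_euclidean"` or `"manhattan"`.
#' @export
knn_spec <- function(k = 1L, metric = c("chebyshev", "euclidean",
                                        "squared_euclidean", "manhattan")) {
  metric <- match.arg(metric)
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  structure(list(method = "knn", k = k, metric = metric),
            class = c("ofs_knn_spec", "ofs_spec"))
}

#' @rdname svm_spec
#' @param n_trees Number of trees in the forest (>= 1).
#' @export
rf_spec <- function(n_trees = 68L) {
  n_trees <- as.integer(n_trees)
  if (n_trees < 1) stop("n_trees must be >= 1", call. = FALSE)
  structure(list(method = "rf", n_trees = n_trees),
            class = c("ofs_rf_spec", "ofs_spec"))
}

#' @export
format.ofs_spec <- function(x, ...) {
  switch(x$method,
         svm = sprintf("SVM %s kernel (gamma = %g, coeff = %g%s)",
                       x$kernel, x$gamma, x$coeff,
                       if (x$kernel == "polynomial")
                         sprintf(", degree = %d", x$degree) else ""),
         knn = sprintf("kNN (%s distance, k = %d)", x$metric, x$k),
         rf = sprintf("random forest (%d trees)", x$n_trees))
}

#' @export
print.ofs_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Evaluate a kernel function
#'
#' Standard kernel definitions: RBF `exp(-gamma * ||u - v||^2)`, sigmoid
#' `tanh(gamma * u'v + coeff)`, polynomial `(gamma * u'v + coeff)^degree`.
#'
#' @param spec An [svm_spec()] object.
#' @param u,v Numeric vectors of equal length.
#' @return Scalar kernel value.
#' @export
#' @examples
#' kernel_eval(svm_spec("rbf", gamma = 1), c(1, 2), c(1, 2))  # 1
kernel_eval <- function(spec, u, v) {
  stopifnot(inherits(spec, "ofs_svm_spec"))
  if (length(u) != length(v))
    stop("u and v must have the same dimension", call. = FALSE)
  switch(spec$kernel,
         rbf = exp(-spec$gamma * sum((u - v)^2)),
         sigmoid = tanh(spec$gamma * sum(u * v) + spec$coeff),
         polynomial = (spec$gamma * sum(u * v) + spec$coeff)^spec$degree)
}

feature_matrix <- function(ds) as.matrix(ds[, c("hrv_z", "pd_z")])

#' Train a classifier on a labelled dataset
#'
#' Fits the classifier described by `spec` on the `hrv_z`/`pd_z` features
#' and `label` column of a labelled dataset. SVMs use one-vs-one
#' multiclass decomposition; k-nearest neighbours is a lazy learner and
#' stores the training set; random forests are seeded for
#' reproducibility. Features are already z-scores, so no further scaling
#' is applied.
#'
#' @param ds An `ofs_dataset` (or data frame with `hrv_z`, `pd_z`,
#'   `label`).
#' @param spec An `ofs_spec` from [svm_spec()], [knn_spec()] or
#'   [rf_spec()].
#' @param seed Integer seed controlling any training randomness.
#' @return An object of class `ofs_model`.
#' @export
ofs_train <- function(ds, spec, seed = 1) {
  stopifnot(inherits(spec, "ofs_spec"), is.data.frame(ds))
  y <- droplevels(factor(ds$label))
  if (nlevels(y) < 2)
    stop("training set contains a single class", call. = FALSE)
  x <- feature_matrix(ds)
  set.seed(seed)
  fit <- switch(spec$method,
    # tolerance 0.01: the sigmoid kernel is non-PSD and polynomial
    # kernels can be numerically extreme on z-scored HRV; the libsvm
    # default tolerance can hit the internal iteration cap on such fits
    svm = e1071::svm(x, y,
                     kernel = switch(spec$kernel, rbf = "radial",
                                     sigmoid = "sigmoid",
                                     polynomial = "polynomial"),
                     gamma = spec$gamma, coef0 = spec$coeff,
                     degree = spec$degree, scale = FALSE,
                     tolerance = 0.01),
    knn = list(x = x, y = y),
    rf = randomForest::randomForest(x, y, ntree = spec$n_trees))
  structure(list(spec = spec, fit = fit, levels = levels(y),
                 n_train = nrow(x), seed = seed), class = "ofs_model")
}

# pairwise distances between rows of a (m x p) and b (n x p)
pairwise_dist <- function(a, b, metric) {
  m <- nrow(a); n <- nrow(b); p <- ncol(a)
  acc <- matrix(0, m, n)
  for (j in seq_len(p)) {
    d <- abs(outer(a[, j], b[, j], "-"))
    acc <- switch(metric,
                  chebyshev = pmax(acc, d),
                  manhattan = acc + d,
                  acc + d^2)   # euclidean / squared_euclidean
  }
  if (metric == "euclidean") acc <- sqrt(acc)
  acc
}

knn_predict <- function(fit, spec, newx) {
  lv <- levels(fit$y)
  yi <- as.integer(fit$y)
  k <- min(spec$k, nrow(fit$x))
  pred <- integer(nrow(newx))
  chunk <- max(1L, floor(4e6 / nrow(fit$x)))
  for (s in seq(1, nrow(newx), by = chunk)) {
    idx <- s:min(s + chunk - 1L, nrow(newx))
    D <- pairwise_dist(newx[idx, , drop = FALSE], fit$x, spec$metric)
    if (k == 1L) {
      pred[idx] <- yi[max.col(-D, ties.method = "first")]
      next
    }
    for (r in seq_along(idx)) {
      d <- D[r, ]
      nb <- order(d)[seq_len(k)]
      votes <- tabulate(yi[nb], length(lv))
      top <- which(votes == max(votes))
      pred[idx[r]] <- if (length(top) == 1L) top else {
        # tie: closest mean neighbour distance, then level order
        md <- vapply(top, function(cl)
          mean(d[nb[yi[nb] == cl]]), numeric(1))
        top[order(md, top)][1]
      }
    }
  }
  factor(lv[pred], levels = lv)
}

#' Predict classes for new data
#'
#' @param object An `ofs_model`.
#' @param newdata A data frame with `hrv_z` and `pd_z` columns.
#' @param ... Unused.
#' @return Factor of predicted class labels.
#' @export
predict.ofs_model <- function(object, newdata, ...) {
  x <- feature_matrix(newdata)
  switch(object$spec$method,
         svm = stats::predict(object$fit, x),
         knn = knn_predict(object$fit, object$spec, x),
         rf = stats::predict(object$fit, x))
}

#' @export
print.ofs_model <- function(x, ...) {
  cat("OFS classifier: ", format(x$spec), "\n", sep = "")
  cat(sprintf("  trained on %d rows, classes: %s\n", x$n_train,
              paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' @export
summary.ofs_model <- function(object, ...) {
  print(object)
  if (object$spec$method == "rf")
    cat(sprintf("  OOB error: %.1f%%\n",
                100 * object$fit$err.rate[object$fit$ntree, "OOB"]))
  invisible(object)
}

#' Evaluate a classifier on a held-out test set
#'
#' Global accuracy is the fraction of correctly classified rows;
#' per-class accuracy is the recall of each class (correct / actual).
#'
#' @param model An `ofs_model`.
#' @param test A labelled dataset with `hrv_z`, `pd_z`, `label`.
#' @return An object of class `ofs_eval` with elements
#'   `global_accuracy`, `class_accuracy` (named by class), `confusion`
#'   (actual x predicted) and `n`.
#' @export
ofs_evaluate <- function(model, test) {
  stopifnot(is.data.frame(test))
  if (nrow(test) == 0) stop("empty test set", call. = FALSE)
  pred <- predict(model, test)
  actual <- factor(test$label, levels = model$levels)
  cm <- table(actual = actual, predicted = factor(pred, levels = model$levels))
  per_class <- diag(cm) / rowSums(cm)
  structure(list(global_accuracy = sum(diag(cm)) / sum(cm),
                 class_accuracy = per_class, confusion = cm,
                 n = nrow(test)), class = "ofs_eval")
}

#' @export
print.ofs_eval <- function(x, ...) {
  cat(sprintf("Global accuracy: %.1f%% (n = %d)\n",
              100 * x$global_accuracy, x$n))
  for (cl in names(x$class_accuracy))
    cat(sprintf("  %s class: %.1f%%\n", cl, 100 * x$class_accuracy[cl]))
  invisible(x)
}

#' Grid search over classifier settings by cross-validation
#'
#' Exhaustive evaluation of a list of specifications by stratified
#' k-fold cross-validation on the training rows; selects the setting
#' with the highest mean CV accuracy. Ties go to the earliest grid entry,
#' so grids should be ordered simple-to-complex (the defaults are:
#' ascending k, fewest trees, smallest gamma).
#'
#' @param ds Labelled training dataset.
#' @param grid Non-empty list of `ofs_spec` objects.
#' @param folds Number of CV folds (default 4).
#' @param seed Integer seed for fold assignment and training.
#' @return A list with `best_spec`, `cv_accuracy` and a data frame
#'   `results` of all grid points.
#' @export
grid_search <- function(ds, grid, folds = 4, seed = 1) {
  if (!length(grid)) stop("empty grid", call. = FALSE)
  y <- droplevels(factor(ds$label))
  set.seed(seed)
  fold <- stratified_folds(y, folds)
  acc <- vapply(grid, function(spec) {
    mean(vapply(seq_len(folds), function(f) {
      tr <- ds[fold != f, , drop = FALSE]
      te <- ds[fold == f, , drop = FALSE]
      m <- ofs_train(tr, spec, seed = seed)
      ofs_evaluate(m, te)$global_accuracy
    }, numeric(1)))
  }, numeric(1))
  best <- which.max(acc)  # first max: grids are ordered simple-to-complex
  list(best_spec = grid[[best]], cv_accuracy = acc[best],
       results = data.frame(spec = vapply(grid, format, character(1)),
                            cv_accuracy = acc))
}

#' Default tuning grids
#'
#' Grids covering the settings explored for each method, ordered so that
#' ties in cross-validated accuracy resolve to the simplest model. Every
#' best setting reported for this protocol (sigmoid gamma 0.5 with coeff
#' 0 or 1; Chebyshev k = 1 and k = 18; 23 and 68 trees) is contained in
#' its grid.
#'
#' @param method `"svm"`, `"knn"` or `"rf"`.
#' @return List of `ofs_spec` objects.
#' @export
default_grid <- function(method = c("svm", "knn", "rf")) {
  method <- match.arg(method)
  switch(method,
    svm = {
      g <- list()
      for (kernel in c("rbf", "sigmoid", "polynomial"))
        # polynomial gamma capped at 0.5: larger values overflow the
        # kernel on features tens of baseline SDs from rest
        for (gamma in if (kernel == "polynomial") c(0.1, 0.5) else
             c(0.1, 0.5, 1, 2))
          for (coeff in if (kernel == "rbf") 0 else c(0, 1))
            for (degree in if (kernel == "polynomial") c(2L, 3L) else 3L)
              g[[length(g) + 1L]] <- svm_spec(kernel, gamma, coeff, degree)
      g
    },
    knn = {
      g <- list()
      for (k in c(1L, 3L, 5L, 9L, 13L, 18L, 25L))
        for (metric in c("euclidean", "squared_euclidean", "manhattan",
                         "chebyshev"))
          g[[length(g) + 1L]] <- knn_spec(k, metric)
      g
    },
    rf = lapply(c(10L, 23L, 40L, 68L, 100L), rf_spec))
}

#' Reported best settings for each method and class count
#'
#' The tuned settings used by default when no grid search is requested:
#' 3-class -- SVM sigmoid (gamma 0.5, coeff 0), kNN Chebyshev k = 1,
#' RF 68 trees; 2-class -- SVM sigmoid (gamma 0.5, coeff 1), kNN
#' Chebyshev k = 18, RF 23 trees.
#'
#' @param method `"svm"`, `"knn"` or `"rf"`.
#' @param n_classes 2 or 3.
#' @return An `ofs_spec`.
#' @export
best_setting <- function(method = c("svm", "knn", "rf"), n_classes = 3) {
  method <- match.arg(method)
  stopifnot(n_classes %in% c(2, 3))
  if (n_classes == 3) {
    switch(method,
           svm = svm_spec("sigmoid", gamma = 0.5, coeff = 0),
           knn = knn_spec(1L, "chebyshev"),
           rf = rf_spec(68L))
  } else {
    switch(method,
           svm = svm_spec("sigmoid", gamma = 0.5, coeff = 1),
           knn = knn_spec(18L, "chebyshev"),
           rf = rf_spec(23L))
  }
}

#' Run the full two-layer classification experiment on a cohort
#'
#' Reproduces the evaluation protocol at both layers. Pooled layer: the
#' cohort is split by participant (13 train / 4 test for 17
#' participants), one model per method is trained on the pooled training
#' rows and evaluated on the held-out participants' rows. Individual
#' layer: each participant's rows are split 75/25 (stratified), a model
#' is trained per participant and the global accuracies are summarized
#' as mean, SD, minimum and maximum. With `tune = TRUE` settings are
#' chosen by fourfold cross-validated grid search on each training set;
#' otherwise the reported best settings ([best_setting()]) are used.
#'
#' @param cohort An `ofs_cohort`.
#' @param methods Character vector among `"svm"`, `"knn"`, `"rf"`.
#' @param n_classes Integer vector among 3 and 2 (label granularities).
#' @param tune Logical: grid-search the settings per training set.
#' @param binarize_scheme Passed to [binarize_labels()].
#' @param seed Integer seed governing splits and training.
#' @param datasets Optional precomputed result of the internal feature
#'   assembly, to avoid recomputation across calls.
#' @return An object of class `ofs_experiment`: nested list indexed by
#'   `[[n_classes]][[method]]` with elements `pooled` (an `ofs_eval`
#'   plus `spec`) and `individual` (per-participant accuracies and
#'   summary), plus `predictions`: 3-class individual-layer predictions
#'   at probe-aligned seconds (one block per method, `method` column)
#'   paired with the ISA/Likert responses for subjective validation.
#' @export
run_two_layer_experiment <- function(cohort, methods = c("svm", "knn", "rf"),
                                     n_classes = c(3, 2), tune = FALSE,
                                     binarize_scheme = "merge_low",
                                     seed = 1, datasets = NULL) {
  stopifnot(inherits(cohort, "ofs_cohort"))
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(datasets)) datasets <- cohort_datasets(cohort)
  ids <- vapply(cohort, `[[`, character(1), "id")
  names(datasets) <- ids
  split <- pooled_split(ids, seed = seed)
  out <- list()
  probe_preds <- list()

  for (nc in n_classes) {
    dsets <- if (nc == 2) lapply(datasets, binarize_labels,
                                 scheme = binarize_scheme) else datasets
    pooled_train <- do.call(rbind, dsets[split$train])
    pooled_test <- do.call(rbind, dsets[split$test])
    res_nc <- list()
    for (method in methods) {
      spec <- if (tune)
        grid_search(pooled_train, default_grid(method), seed = seed)$best_spec
      else best_setting(method, nc)
      model <- ofs_train(pooled_train, spec, seed = seed)
      pooled_eval <- ofs_evaluate(model, pooled_test)
      pooled_eval$spec <- spec

      # individual layer
      ind <- lapply(seq_along(dsets), function(i) {
        ds <- dsets[[i]]
        sp <- individual_split(ds$label, seed = seed + i)
        ispec <- if (tune)
          grid_search(ds[sp$train, ], default_grid(method),
                      seed = seed)$best_spec else best_setting(method, nc)
        m <- ofs_train(ds[sp$train, ], ispec, seed = seed)
        ev <- ofs_evaluate(m, ds[sp$test, ])
        # predictions at probe-aligned seconds, for subjective validation
        probes <- cohort[[i]]$probes
        at <- ds[ds$t_s %in% probes$t_s, , drop = FALSE]
        pp <- if (nrow(at)) data.frame(
          method = method, participant = ids[i], t_s = at$t_s,
          ofs = as.integer(factor(predict(m, at),
                                  levels = levels(ds$label))),
          isa = probes$isa[match(at$t_s, probes$t_s)],
          likert = probes$likert[match(at$t_s, probes$t_s)],
          true_td = probes$true_td[match(at$t_s, probes$t_s)]) else NULL
        list(accuracy = ev$global_accuracy, spec = ispec, probe_pred = pp)
      })
      accs <- vapply(ind, `[[`, numeric(1), "accuracy")
      res_nc[[method]] <- list(
        pooled = pooled_eval,
        individual = list(accuracies = stats::setNames(accs, ids),
                          mean = mean(accs), sd = stats::sd(accs),
                          min = min(accs), max = max(accs),
                          specs = lapply(ind, `[[`, "spec")))
      if (nc == 3)
        probe_preds <- c(probe_preds, lapply(ind, `[[`, "probe_pred"))
    }
    out[[as.character(nc)]] <- res_nc
  }
  structure(list(results = out, split = split,
                 predictions = do.call(rbind, probe_preds),
                 methods = methods, n_classes = n_classes, seed = seed,
                 tuned = tune),
            class = "ofs_experiment")
}

#' @export
print.ofs_experiment <- function(x, ...) {
  for (nc in names(x$results)) {
    cat(sprintf("== %s-class classification ==\n", nc))
    for (method in names(x$results[[nc]])) {
      r <- x$results[[nc]][[method]]
      cat(sprintf("%-4s pooled (%d/%d participants): global %.0f%%",
                  toupper(method), length(x$split$train),
                  length(x$split$test), 100 * r$pooled$global_accuracy))
      pc <- r$pooled$class_accuracy
      cat(" [", paste(sprintf("%s %.0f%%", names(pc), 100 * pc),
                      collapse = ", "), "]\n", sep = "")
      cat(sprintf("     individual: mean %.0f%%, sd %.0f%%, min %.0f%%, max %.0f%%\n",
                  100 * r$individual$mean, 100 * r$individual$sd,
                  100 * r$individual$min, 100 * r$individual$max))
    }
  }
  invisible(x)
}

#' Plot per-participant accuracies of an experiment
#'
#' Box plot of individual-layer global accuracy per method, one panel
#' per class count.
#'
#' @param x An `ofs_experiment`.
#' @param ... Passed to [graphics::boxplot()].
#' @export
plot.ofs_experiment <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, length(x$results)))
  on.exit(graphics::par(old))
  for (nc in names(x$results)) {
    accs <- lapply(x$results[[nc]], function(r) 100 * r$individual$accuracies)
    graphics::boxplot(accs, ylab = "global accuracy (%)",
                      main = sprintf("%s-class, individual layer", nc), ...)
  }
  invisible(x)
}
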