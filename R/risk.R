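COST_GRID <- 2^(-2:6)  # nine geometric candidates, 0.25 ... 64

#' Median-pairwise-distance heuristic for the radial-kernel width
#'
#' Sets the RBF width as `sigma = 1 / (2 * m^2)` where `m` is the median
#' Euclidean distance between training rows (kernel
#' `k(x, y) = exp(-sigma * ||x - y||^2)`, the kernlab convention). A
#' dataset-specific quantity, re-estimated for every training set.
#'
#' @param x numeric matrix of training features.
#' @return positive scalar sigma.
#' @export
rbf_sigma_median <- function(x) {
  d <- stats::dist(x)
  m <- stats::median(d[d > 0])
  if (!is.finite(m) || m <= 0) m <- 1
  1 / (2 * m^2)
}

#' Fit the feature preprocessing on a training matrix
#'
#' Median centering and column scaling: each of the 16 bin columns is
#' centred on its training median and divided by its training standard
#' deviation (floored at 1e-8 for constant columns). The parameters are
#' frozen and re-applied verbatim to any later data.
#'
#' @param train a `feature_matrix` with a two-class `label` column.
#' @return list of class `edtar_preprocessing` with `center` and
#'   `scale` vectors.
#' @export
fit_preprocessing <- function(train) {
  check_two_class(train)
  x <- feature_columns(train)
  center <- apply(x, 2, stats::median)
  scale <- pmax(apply(x, 2, stats::sd), 1e-8)
  structure(list(center = center, scale = scale),
            class = "edtar_preprocessing")
}

#' @rdname fit_preprocessing
#' @param prep an `edtar_preprocessing` object.
#' @param x numeric matrix (or `feature_matrix`) to transform.
#' @export
apply_preprocessing <- function(prep, x) {
  if (is.data.frame(x)) x <- feature_columns(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1,
                                   dimnames = list(NULL, names(prep$center)))
  sweep(sweep(x, 2, prep$center, "-"), 2, prep$scale, "/")
}

check_two_class <- function(fm, min_per_class = 1L) {
  if (nrow(fm) < 2L)
    stop("at least 2 cases are required", call. = FALSE)
  tab <- table(fm$label)
  if (length(tab) < 2L)
    stop("training data must contain both classes (normal and oscc); ",
         "got only: ", paste(names(tab), collapse = ", "), call. = FALSE)
  if (any(tab < min_per_class))
    stop("every class needs at least ", min_per_class, " cases",
         call. = FALSE)
  invisible(tab)
}

risk_labels <- function(fm) {
  factor(fm$label, levels = c("normal", "oscc"))
}

#' Tune and train the radial-kernel SVM risk model
#'
#' Fits the OCRI classifier on a two-class (normal vs OSCC) feature
#' matrix: features are median-centred and column-scaled with
#' parameters frozen from the training set; the RBF width sigma comes
#' from the median-pairwise-distance heuristic; the cost parameter is
#' selected by leave-one-out cross-validated accuracy over the
#' nine-value geometric grid 2^-2 ... 2^6 = 64 (ties broken toward the
#' smaller cost); and the final machine is refitted on all training
#' cases with Platt-type probability calibration.
#'
#' @param train a `feature_matrix` with labels `normal` / `oscc`;
#'   at least 10 cases are required for a stable LOOCV.
#' @param seed integer seed (calibration folds and any model
#'   randomness).
#' @return an object of class `ocri_model`: preprocessing parameters,
#'   the fitted `kernlab::ksvm` machine, chosen `cost`, `sigma`, the
#'   searched grid, per-cost LOOCV accuracies and the seed.
#' @export
tune_and_train_svm <- function(train, seed = 1L) {
  train <- train[train$label %in% c("normal", "oscc"), , drop = FALSE]
  if (nrow(train) < 10L)
    stop("LOOCV tuning needs at least 10 training cases (got ",
         nrow(train), ")", call. = FALSE)
  check_two_class(train, min_per_class = 2L)

  prep <- fit_preprocessing(train)
  x <- apply_preprocessing(prep, train)
  y <- risk_labels(train)
  sigma <- rbf_sigma_median(x)

  loo_acc <- vapply(COST_GRID, function(cost) {
    hits <- vapply(seq_len(nrow(x)), function(i) {
      fit <- kernlab::ksvm(x[-i, , drop = FALSE], y[-i],
                           type = "C-svc", kernel = "rbfdot",
                           kpar = list(sigma = sigma), C = cost,
                           prob.model = FALSE, scaled = FALSE)
      pred <- kernlab::predict(fit, x[i, , drop = FALSE])
      as.character(pred) == as.character(y[i])
    }, logical(1))
    mean(hits)
  }, numeric(1))
  cost <- COST_GRID[which.max(loo_acc)]  # which.max takes the first
                                         # maximum: the smallest cost

  fit <- withr::with_seed(as.integer(seed),
    kernlab::ksvm(x, y, type = "C-svc", kernel = "rbfdot",
                  kpar = list(sigma = sigma), C = cost,
                  prob.model = TRUE, scaled = FALSE))

  structure(list(preprocessing = prep, fit = fit, cost = cost,
                 sigma = sigma, cost_grid = COST_GRID,
                 loo_accuracy = stats::setNames(loo_acc,
                                                format(COST_GRID)),
                 n_train = nrow(train), seed = as.integer(seed)),
            class = "ocri_model")
}

#' @export
print.ocri_model <- function(x, ...) {
  cat(sprintf(paste0("OCRI model: radial-kernel SVM, cost = %g, ",
                     "sigma = %.4f, %d training cases\n"),
              x$cost, x$sigma, x$n_train))
  cat("LOOCV accuracy over cost grid:\n")
  print(round(x$loo_accuracy, 4))
  invisible(x)
}

#' Compute the Oral Cancer Risk Index of a case
#'
#' OCRI is the calibrated probability that the case's 16-bin feature
#' vector belongs to the OSCC class, after applying the frozen
#' training-set preprocessing. It ranges between 0 (lowest risk) and 1
#' (highest risk); `above_threshold` flags OCRI > 0.5.
#'
#' @param model an `ocri_model`.
#' @param features an `edtar_features` vector (length 16), or a
#'   `feature_matrix` row set.
#' @return data frame with `case_id`, `ocri` and `above_threshold`.
#' @export
compute_ocri <- function(model, features) {
  stopifnot(inherits(model, "ocri_model"))
  if (is.data.frame(features)) {
    ids <- if ("case_id" %in% names(features)) features$case_id
           else sprintf("case_%d", seq_len(nrow(features)))
    x <- feature_columns(features)
  } else {
    fv <- as.numeric(features)
    if (length(fv) != 16L)
      stop("a feature vector must have exactly 16 bins (got ",
           length(fv), ")", call. = FALSE)
    ids <- attr(features, "case_id")
    if (is.null(ids)) ids <- "case_1"
    x <- matrix(fv, nrow = 1, dimnames = list(NULL, feature_bin_names()))
  }
  xs <- apply_preprocessing(model$preprocessing, x)
  p <- kernlab::predict(model$fit, xs, type = "probabilities")[, "oscc"]
  p <- pmin(pmax(as.numeric(p), 0), 1)
  data.frame(case_id = ids, ocri = p, above_threshold = p > 0.5,
             stringsAsFactors = FALSE)
}

#' Score a cohort and stratify by OCRI
#'
#' @param model an `ocri_model`.
#' @param features a `feature_matrix` for the cohort (any labels).
#' @return data frame of per-case OCRI sorted in decreasing risk order,
#'   with attribute `n_above_threshold` (cases with OCRI > 0.5).
#' @export
stratify_cohort <- function(model, features) {
  if (nrow(features) == 0L) {
    out <- data.frame(case_id = character(0), label = character(0),
                      ocri = numeric(0), above_threshold = logical(0))
    attr(out, "n_above_threshold") <- 0L
    return(out)
  }
  res <- compute_ocri(model, features)
  res$label <- if ("label" %in% names(features)) features$label
               else NA_character_
  res <- res[order(-res$ocri), c("case_id", "label", "ocri",
                                 "above_threshold")]
  rownames(res) <- NULL
  attr(res, "n_above_threshold") <- sum(res$above_threshold)
  res
}

BENCHMARK_MODELS <- c("svm", "rf", "plr", "nnet", "knn", "cart")

#' Benchmark classifier families with repeated cross-validation
#'
#' Evaluates up to six model families — radial-kernel SVM, random
#' forest, penalized (ridge) logistic regression, single-hidden-layer
#' neural network, k-nearest neighbours and a classification tree — on
#' a two-class feature matrix with 10-fold cross-validation repeated 5
#' times (50 resamples). Every model sees the identical fold
#' assignments, drawn once from `seed`, so differences reflect the
#' models and not the resampling. Per resample the area under the ROC
#' curve, sensitivity and specificity are recorded with OSCC as the
#' positive class and a class-probability cutoff of 0.5; models are
#' ranked by median ROC, then median sensitivity, then median
#' specificity.
#'
#' @param features a `feature_matrix` with labels `normal` / `oscc`
#'   (each class needs >= 10 cases).
#' @param seed integer seed controlling folds and model fits.
#' @param models subset of `c("svm","rf","plr","nnet","knn","cart")`.
#' @param folds,repeats cross-validation geometry (default 10 x 5).
#' @return object of class `edtar_benchmark`: `resamples` (long data
#'   frame: model, resample, roc, sensitivity, specificity), `summary`
#'   (medians, ranked), `folds`, `seed`.
#' @export
benchmark_models <- function(features, seed = 1L,
                             models = BENCHMARK_MODELS,
                             folds = 10L, repeats = 5L) {
  models <- match.arg(models, BENCHMARK_MODELS, several.ok = TRUE)
  features <- features[features$label %in% c("normal", "oscc"), ,
                       drop = FALSE]
  tab <- check_two_class(features)
  if (any(tab < 10L))
    stop("benchmarking needs >= 10 cases per class (got ",
         paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), ")",
         call. = FALSE)
  y <- risk_labels(features)
  x <- feature_columns(features)

  fold_list <- withr::with_seed(as.integer(seed),
    caret::createMultiFolds(y, k = folds, times = repeats))
  resample_seeds <- withr::with_seed(as.integer(seed) + 1L,
    sample.int(.Machine$integer.max, length(fold_list)))

  rows <- list()
  for (m in models) {
    for (r in seq_along(fold_list)) {
      tr <- fold_list[[r]]          # createMultiFolds returns train idx
      te <- setdiff(seq_along(y), tr)
      prep <- list(center = apply(x[tr, , drop = FALSE], 2, stats::median),
                   scale = pmax(apply(x[tr, , drop = FALSE], 2, stats::sd),
                                1e-8))
      class(prep) <- "edtar_preprocessing"
      xtr <- apply_preprocessing(prep, x[tr, , drop = FALSE])
      xte <- apply_preprocessing(prep, x[te, , drop = FALSE])
      p_oscc <- withr::with_seed(resample_seeds[r] %% 1000000L + match(m, BENCHMARK_MODELS),
        fit_predict_prob(m, xtr, y[tr], xte))
      met <- resample_metrics(y[te], p_oscc)
      rows[[length(rows) + 1L]] <-
        data.frame(model = m, resample = names(fold_list)[r],
                   roc = met["roc"], sensitivity = met["sensitivity"],
                   specificity = met["specificity"],
                   stringsAsFactors = FALSE)
    }
  }
  resamples <- do.call(rbind, rows)
  rownames(resamples) <- NULL

  summary <- do.call(rbind, lapply(split(resamples, resamples$model),
    function(d) data.frame(model = d$model[1],
                           roc = stats::median(d$roc),
                           sensitivity = stats::median(d$sensitivity),
                           specificity = stats::median(d$specificity))))
  summary <- summary[order(-summary$roc, -summary$sensitivity,
                           -summary$specificity), ]
  summary$rank <- seq_len(nrow(summary))
  rownames(summary) <- NULL

  structure(list(resamples = resamples, summary = summary,
                 folds = fold_list, seed = as.integer(seed),
                 scheme = sprintf("%d-fold CV x %d repeats", folds,
                                  repeats)),
            class = "edtar_benchmark")
}

## one train/predict round for each model family; returns P(oscc) on
## the test rows. Families are configured close to their package
## defaults; the comparison is descriptive, not a tuning contest.
fit_predict_prob <- function(model, xtr, ytr, xte) {
  ytr <- droplevels(ytr)
  switch(model,
    svm = {
      fit <- kernlab::ksvm(xtr, ytr, type = "C-svc", kernel = "rbfdot",
                           kpar = list(sigma = rbf_sigma_median(xtr)),
                           C = 1, prob.model = FALSE, scaled = FALSE)
      dv <- kernlab::predict(fit, xte, type = "decision")[, 1]
      # orient the decision values so larger means oscc (the sign
      # convention depends on the factor level order), then map through
      # a logistic link for a probability-scaled score
      dv_tr <- kernlab::predict(fit, xtr, type = "decision")[, 1]
      if (mean(dv_tr[ytr == "oscc"]) < mean(dv_tr[ytr == "normal"]))
        dv <- -dv
      stats::plogis(dv)
    },
    rf = {
      fit <- randomForest::randomForest(xtr, ytr, ntree = 500)
      stats::predict(fit, xte, type = "prob")[, "oscc"]
    },
    plr = {
      fit <- glmnet::cv.glmnet(xtr, ytr, family = "binomial",
                               alpha = 0, nfolds = 5)
      as.numeric(stats::predict(fit, xte, s = "lambda.min",
                                type = "response"))
    },
    nnet = {
      fit <- nnet::nnet(xtr, as.numeric(ytr == "oscc"), size = 5,
                        decay = 0.1, maxit = 300, trace = FALSE)
      as.numeric(stats::predict(fit, xte))
    },
    knn = {
      fit <- caret::knn3(xtr, ytr, k = 5)
      stats::predict(fit, xte, type = "prob")[, "oscc"]
    },
    cart = {
      dtr <- data.frame(xtr, y = ytr, check.names = FALSE)
      fit <- rpart::rpart(y ~ ., data = dtr, method = "class")
      stats::predict(fit, data.frame(xte, check.names = FALSE),
                     type = "prob")[, "oscc"]
    })
}

resample_metrics <- function(y_true, p_oscc) {
  pred <- ifelse(p_oscc > 0.5, "oscc", "normal")
  sens <- if (any(y_true == "oscc"))
    mean(pred[y_true == "oscc"] == "oscc") else NA_real_
  spec <- if (any(y_true == "normal"))
    mean(pred[y_true == "normal"] == "normal") else NA_real_
  auc <- if (length(unique(y_true)) == 2L) {
    as.numeric(pROC::auc(pROC::roc(response = y_true,
                                   predictor = p_oscc,
                                   levels = c("normal", "oscc"),
                                   direction = "<", quiet = TRUE)))
  } else NA_real_
  c(roc = auc, sensitivity = sens, specificity = spec)
}

#' @export
print.edtar_benchmark <- function(x, ...) {
  cat("Model benchmark (", x$scheme, ", ",
      length(x$folds), " resamples, seed ", x$seed, ")\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
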