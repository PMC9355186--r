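## Feature fusion, standardisation, SVM and the repeated-split protocol.
##
## One experiment: draw 15 + 15 training subjects (without replacement),
## leave the rest as the test set, then — using training data only — fit
## PCA on the training embeddings, impute missing training CLR ratios from
## their labels, form the similarity-ratio criterion, impute missing test
## CLR ratios label-free from that criterion, standardise on training
## statistics, train a linear SVM, and score the test set. Accuracy,
## sensitivity (strabismic images flagged) and specificity (normal images
## cleared) are averaged over repeated experiments with a normal-theory
## 95% confidence interval.

#' Assemble a fused feature vector
#'
#' Fixed ordering: the k PCA scores, then the position-similarity ratio S,
#' then the CLR ratio.
#'
#' @param pca_scores Numeric vector of PCA scores.
#' @param S Position-similarity ratio (>= 1).
#' @param clr CLR ratio (>= 0; measured or imputed).
#' @return Named numeric vector `(pc1..pck, S, clr)`.
#' @export
assemble_features <- function(pca_scores, S, clr) {
  if (!all(is.finite(c(pca_scores, S, clr)))) {
    stop("non-finite feature value", call. = FALSE)
  }
  if (S < 1) stop("similarity ratio S must be >= 1", call. = FALSE)
  if (clr < 0) stop("CLR ratio must be >= 0", call. = FALSE)
  stats::setNames(c(pca_scores, S, clr),
                  c(paste0("pc", seq_along(pca_scores)), "S", "clr"))
}

#' Learn and apply per-dimension standardisation
#'
#' `fit_standardizer()` learns training means and population (1/n)
#' standard deviations — the usual feature-scaling convention, under which
#' the two training points `{0, 2}` map to `{-1, +1}`;
#' `apply_standardizer()` rescales any vectors with those statistics, so
#' test data never contributes to them.
#'
#' @param train An n x d matrix (n >= 2) of training feature vectors.
#' @return `fit_standardizer()`: an object of class `standardizer` with
#'   `mean` and `sd`; errors naming the dimension if one has zero variance.
#' @export
fit_standardizer <- function(train) {
  train <- as.matrix(train)
  if (nrow(train) < 2) stop("need at least 2 training vectors", call. = FALSE)
  mu <- colMeans(train)
  sdv <- sqrt(colMeans(sweep(train, 2, mu)^2))
  if (any(sdv == 0)) {
    bad <- which(sdv == 0)[1]
    nm <- colnames(train)[bad]
    stop(sprintf("zero variance in feature dimension %s: cannot standardise",
                 if (is.null(nm)) bad else paste0(bad, " ('", nm, "')")),
         call. = FALSE)
  }
  structure(list(mean = mu, sd = sdv), class = "standardizer")
}

#' @rdname fit_standardizer
#' @param state A `standardizer`.
#' @param x A vector or n x d matrix to rescale.
#' @export
apply_standardizer <- function(state, x) {
  if (is.null(dim(x))) return((x - state$mean) / state$sd)
  sweep(sweep(x, 2, state$mean), 2, state$sd, `/`)
}

#' Train the screening SVM
#'
#' A support vector machine (linear kernel by default) on standardised
#' fused features. Inputs are expected pre-standardised; the SVM itself
#' does no rescaling.
#'
#' @param x n x d matrix of standardised features.
#' @param labels Character or factor labels, `"normal"` / `"strabismus"`;
#'   both classes must be present.
#' @param C Soft-margin cost (default 1).
#' @param kernel Kernel name passed to [e1071::svm()] (default "linear").
#' @return An object of class `screening_svm`.
#' @export
train_screening_svm <- function(x, labels, C = 1, kernel = "linear") {
  y <- factor(labels, levels = c("normal", "strabismus"))
  if (nlevels(droplevels(y)) < 2) {
    stop("training set must contain both classes", call. = FALSE)
  }
  fit <- e1071::svm(x = as.matrix(x), y = y, kernel = kernel, cost = C,
                    scale = FALSE)
  structure(list(fit = fit), class = "screening_svm")
}

#' Predict screening labels
#'
#' Classifies by the sign of the SVM decision value; an exact zero score is
#' resolved to `"strabismus"` (the sensitivity-favouring convention for a
#' screening tool).
#'
#' @param object A `screening_svm`.
#' @param x Matrix of standardised feature vectors.
#' @return Character vector of `"normal"` / `"strabismus"`.
#' @export
predict_screening <- function(object, x) {
  pred <- predict(object$fit, as.matrix(x), decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  sides <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]]
  out <- ifelse(dv[, 1] > 0, sides[1], sides[2])
  out[dv[, 1] == 0] <- "strabismus"
  unname(out)
}

#' Run one repeated-split screening experiment
#'
#' @param features A per-subject feature tibble (see [process_cohort()] or
#'   [truth_features()]) with columns `subject_id`, `label`, `S`,
#'   `clr_measured` (`NA` when no reflex was detected) and `embedding`
#'   (list of equal-length numeric vectors).
#' @param seed Seed controlling the train/test draw.
#' @param k PCA components fitted on the training embeddings (default 5).
#' @param C,kernel SVM hyperparameters.
#' @param n_train_per_class Training subjects drawn per class (default 15).
#' @param return_details Also return the training artifacts (PCA model,
#'   criterion, standardiser, SVM) and the split ids?
#' @return A one-row tibble of confusion counts (`tp` strabismic flagged,
#'   `tn` normal cleared, `fp`, `fn`), the derived `accuracy`,
#'   `sensitivity`, `specificity`, and the split (`train_ids`, `test_ids`
#'   list-columns); with `return_details = TRUE`, a list
#'   `(result, details)`.
#' @export
run_experiment <- function(features, seed, k = 5L, C = 1, kernel = "linear",
                           n_train_per_class = 15L, return_details = FALSE) {
  stopifnot(all(c("subject_id", "label", "S", "clr_measured", "embedding")
                %in% names(features)))
  idx_n <- which(features$label == "normal")
  idx_s <- which(features$label == "strabismus")
  if (length(idx_n) < n_train_per_class || length(idx_s) < n_train_per_class) {
    stop(sprintf("need at least %d subjects per class", n_train_per_class),
         call. = FALSE)
  }
  train_idx <- withr::with_seed(as.integer(seed), {
    c(sample(idx_n, n_train_per_class), sample(idx_s, n_train_per_class))
  })
  test_idx <- setdiff(seq_len(nrow(features)), train_idx)

  E <- do.call(rbind, features$embedding)
  pca <- fit_pca(E[train_idx, , drop = FALSE], k = k)
  scores <- project_pca(pca, E)

  S <- features$S
  clr <- features$clr_measured
  lab <- features$label
  miss_tr <- train_idx[is.na(clr[train_idx])]
  clr[miss_tr] <- impute_clr_train(lab[miss_tr])
  criterion <- clr_criterion(S[intersect(train_idx, idx_n)],
                             S[intersect(train_idx, idx_s)])
  miss_te <- test_idx[is.na(clr[test_idx])]
  clr[miss_te] <- impute_clr_test(S[miss_te], criterion)

  X <- t(vapply(seq_len(nrow(features)),
                function(i) assemble_features(scores[i, ], S[i], clr[i]),
                numeric(k + 2)))
  std <- fit_standardizer(X[train_idx, , drop = FALSE])
  Z <- apply_standardizer(std, X)
  svm_fit <- train_screening_svm(Z[train_idx, , drop = FALSE], lab[train_idx],
                                 C = C, kernel = kernel)
  pred <- predict_screening(svm_fit, Z[test_idx, , drop = FALSE])
  truth <- lab[test_idx]
  tp <- sum(pred == "strabismus" & truth == "strabismus")
  tn <- sum(pred == "normal" & truth == "normal")
  fp <- sum(pred == "strabismus" & truth == "normal")
  fn <- sum(pred == "normal" & truth == "strabismus")
  result <- tibble::tibble(
    seed = as.integer(seed), tp = tp, tn = tn, fp = fp, fn = fn,
    accuracy = (tp + tn) / length(truth),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    train_ids = list(features$subject_id[sort(train_idx)]),
    test_ids = list(features$subject_id[sort(test_idx)])
  )
  if (!return_details) return(result)
  list(result = result,
       details = list(train_ids = features$subject_id[sort(train_idx)],
                      test_ids = features$subject_id[sort(test_idx)],
                      pca = pca, criterion = criterion, standardizer = std,
                      svm = svm_fit))
}

#' Repeated-split evaluation of the screening pipeline
#'
#' Runs [run_experiment()] `n_experiments` times with per-experiment seeds
#' `base_seed, base_seed + 1, ...` (a documented counter scheme, so any
#' single experiment can be re-run in isolation) and summarises accuracy,
#' sensitivity and specificity with normal-approximation 95% confidence
#' intervals (`mean +/- 1.96 * sd / sqrt(n)`; zero-width for a single
#' experiment).
#'
#' @inheritParams run_experiment
#' @param n_experiments Number of repeated random splits (default 5000,
#'   the full protocol; scale down for quick checks).
#' @param base_seed First experiment seed.
#' @return An object of class `screening_eval` with `summary` (one row per
#'   metric: mean, ci_low, ci_high), `experiments` (per-experiment tibble)
#'   and the evaluation settings. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @export
evaluate_screening <- function(features, n_experiments = 5000L,
                               base_seed = 1L, k = 5L, C = 1,
                               kernel = "linear", n_train_per_class = 15L) {
  stopifnot(n_experiments >= 1)
  seeds <- as.integer(base_seed) + seq_len(n_experiments) - 1L
  experiments <- dplyr::bind_rows(lapply(seeds, function(s) {
    run_experiment(features, seed = s, k = k, C = C, kernel = kernel,
                   n_train_per_class = n_train_per_class)
  }))
  summarise_metric <- function(x) {
    m <- mean(x)
    se <- if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
    c(mean = m, ci_low = m - 1.96 * se, ci_high = m + 1.96 * se)
  }
  summ <- dplyr::bind_rows(lapply(
    c("accuracy", "sensitivity", "specificity"),
    function(metric) {
      v <- unname(summarise_metric(experiments[[metric]]))
      tibble::tibble(metric = metric, mean = v[1], ci_low = v[2],
                     ci_high = v[3])
    }
  ))
  structure(
    list(summary = summ, experiments = experiments,
         n_experiments = as.integer(n_experiments),
         base_seed = as.integer(base_seed), k = as.integer(k), C = C,
         kernel = kernel, n_train_per_class = as.integer(n_train_per_class)),
    class = "screening_eval"
  )
}

#' @export
print.screening_eval <- function(x, ...) {
  cat(sprintf("Screening evaluation: %d experiments (base seed %d, %d+%d split)\n",
              x$n_experiments, x$base_seed, x$n_train_per_class,
              x$n_train_per_class))
  for (i in seq_len(nrow(x$summary))) {
    r <- x$summary[i, ]
    cat(sprintf("  %-11s %.3f (95%% CI %.3f-%.3f)\n",
                r$metric, r$mean, r$ci_low, r$ci_high))
  }
  invisible(x)
}
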