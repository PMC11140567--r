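# LOOCV linear-SVM discrimination of smokers vs controls from cluster-level
# dFC-variance features, with rank AUC and label-permutation testing.

#' Cluster-mean feature matrix
#'
#' One feature per surviving cluster: the mean dFC variance over the
#' cluster's voxels in each subject's map for the cluster's seed.
#'
#' @param maps_by_seed named list: seed name -> list of per-subject maps
#'   (`dfc_map` objects or 3D arrays, one per subject, same order across
#'   seeds).
#' @param clusters a `cluster_table` from [grf_cluster_correction], or a
#'   list of linear voxel index vectors.
#' @param cluster_seeds seed name for each cluster (recycled if length 1).
#' @param labels per-subject group labels (`"smoker"` / `"control"`).
#' @return subjects x clusters numeric matrix with `labels` attribute and
#'   column names `clusterN_<seed>`.
#' @export
extract_cluster_features <- function(maps_by_seed, clusters, cluster_seeds,
                                     labels) {
  vox_list <- if (inherits(clusters, "cluster_table")) clusters$clusters
              else clusters
  if (!length(vox_list)) stop("no clusters to extract features from")
  cluster_seeds <- rep_len(cluster_seeds, length(vox_list))
  bad <- setdiff(unique(cluster_seeds), names(maps_by_seed))
  if (length(bad)) stop("no maps for seed(s): ", paste(bad, collapse = ", "))
  n <- length(maps_by_seed[[1]])
  if (length(labels) != n) stop("labels do not match the number of subjects")
  feat <- matrix(NA_real_, n, length(vox_list))
  colnames(feat) <- sprintf("cluster%d_%s", seq_along(vox_list),
                            gsub("\\s+", "_", cluster_seeds))
  for (j in seq_along(vox_list)) {
    vox <- vox_list[[j]]
    if (!length(vox)) stop("cluster ", j, " is empty")
    maps <- maps_by_seed[[cluster_seeds[j]]]
    feat[, j] <- vapply(maps, function(m) {
      a <- if (inherits(m, "dfc_map")) m$data else m
      if (max(vox) > length(a)) stop("cluster voxels outside the map grid")
      mean(a[vox])
    }, 0)
  }
  if (anyNA(feat)) stop("missing values in the feature matrix")
  attr(feat, "labels") <- as.character(labels)
  feat
}

#' Rank-based AUC
#'
#' Probability that a random positive outscores a random negative, counting
#' ties as one half (Mann-Whitney formulation). Invariant under strictly
#' increasing transforms of the scores.
#'
#' @param scores per-subject decision values (larger = more positive-like).
#' @param labels per-subject class labels.
#' @param positive label counted as positive (default `"smoker"`).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels, positive = "smoker") {
  pos <- labels == positive
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to compute an AUC")
  r <- rank(scores)  # midranks handle ties
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

standardize_by <- function(x, mu, sdev) {
  sweep(sweep(x, 2, mu, "-"), 2, pmax(sdev, .Machine$double.eps), "/")
}

# decision scores oriented so that larger = more `positive`-like
svm_scores <- function(fit, newdata, positive) {
  pred <- stats::predict(fit, newdata, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  first <- strsplit(colnames(dv)[1], "/")[[1]][1]
  s <- as.numeric(dv[, 1])
  if (first != positive) s <- -s
  list(label = as.character(pred), score = s)
}

#' Leave-one-out cross-validated linear SVM
#'
#' For each of the n folds a linear-kernel SVM (cost `cost`) is fit on the
#' remaining n-1 subjects, with features z-scored by the training fold's
#' mean and SD, and the held-out subject is predicted. Accuracy, sensitivity
#' (positives = smokers), specificity and the rank AUC of the pooled
#' held-out decision scores are reported.
#'
#' @param features subjects x features matrix (e.g. from
#'   [extract_cluster_features]); labels taken from its `labels` attribute
#'   unless given.
#' @param labels optional per-subject labels.
#' @param positive positive class (default `"smoker"`).
#' @param cost SVM margin-cost parameter (default 1).
#' @param kernel SVM kernel (default `"linear"`).
#' @param class_weights `"balanced"` (default) scales each class's
#'   margin-cost inversely to its training-fold frequency. Leave-one-out
#'   folds always under-represent the held-out subject's class by one;
#'   without the correction a label-noise fit drifts toward the majority
#'   class and permuted-label accuracy sits well below chance. `"none"`
#'   disables the reweighting.
#' @return An object of class `classification_report`: `accuracy`,
#'   `sensitivity`, `specificity`, `auc`, `predicted`, `scores`, `labels`.
#' @export
loocv_svm <- function(features, labels = NULL, positive = "smoker",
                      cost = 1, kernel = "linear",
                      class_weights = c("balanced", "none")) {
  class_weights <- match.arg(class_weights)
  x <- as.matrix(features)
  if (is.null(labels)) labels <- attr(features, "labels")
  labels <- as.character(labels)
  if (length(labels) != nrow(x)) stop("labels do not match features")
  if (anyNA(x)) stop("missing values in features")
  classes <- sort(unique(labels))
  if (length(classes) != 2L) stop("need exactly 2 classes")
  if (min(table(labels)) < 2L) stop("need >= 2 subjects per class")
  n <- nrow(x)
  predicted <- character(n)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    xtr <- x[-i, , drop = FALSE]
    ytr <- labels[-i]
    if (length(unique(ytr)) < 2L)
      stop("a training fold lost a whole class")
    mu <- colMeans(xtr)
    sdev <- apply(xtr, 2, stats::sd)
    wts <- if (class_weights == "balanced") {
      tb <- table(factor(ytr, levels = classes))
      stats::setNames(as.numeric(length(ytr) / (2 * tb)), classes)
    } else NULL
    fit <- e1071::svm(standardize_by(xtr, mu, sdev),
                      factor(ytr, levels = classes),
                      kernel = kernel, cost = cost, scale = FALSE,
                      class.weights = wts)
    out <- svm_scores(fit, standardize_by(x[i, , drop = FALSE], mu, sdev),
                      positive)
    predicted[i] <- out$label
    scores[i] <- out$score
  }
  pos <- labels == positive
  report <- list(accuracy = mean(predicted == labels),
                 sensitivity = mean(predicted[pos] == labels[pos]),
                 specificity = mean(predicted[!pos] == labels[!pos]),
                 auc = roc_auc(scores, labels, positive),
                 predicted = predicted, scores = scores, labels = labels,
                 positive = positive)
  class(report) <- "classification_report"
  report
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(paste0("<classification_report> accuracy %.2f%%, ",
                     "sensitivity %.2f%%, specificity %.2f%%, AUC %.3f\n"),
              100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity,
              x$auc))
  if (!is.null(x$permutation_p))
    cat(sprintf("  permutation p = %.4g (%d iterations)\n",
                x$permutation_p, x$n_perm))
  invisible(x)
}

#' Label-permutation test of LOOCV accuracy
#'
#' Re-runs the full LOOCV in every iteration with the class labels randomly
#' permuted, and reports the add-one estimate
#' `p = (1 + #(permuted accuracy >= observed)) / (1 + n_perm)`.
#'
#' @inheritParams loocv_svm
#' @param n_perm number of permutations (the study design uses 10,000;
#'   smaller values give coarser p resolution).
#' @param rng_seed integer seed; the same seed reproduces the same p.
#' @param observed optional precomputed `classification_report` for the
#'   unpermuted labels.
#' @return The observed `classification_report` with `permutation_p`,
#'   `n_perm` and the vector of `perm_accuracies` attached.
#' @export
permutation_test <- function(features, labels = NULL, n_perm = 10000L,
                             rng_seed = 1L, positive = "smoker", cost = 1,
                             kernel = "linear", observed = NULL) {
  stopifnot(n_perm >= 1L)
  if (is.null(labels)) labels <- attr(features, "labels")
  if (is.null(observed))
    observed <- loocv_svm(features, labels, positive, cost, kernel)
  set.seed(as.integer(rng_seed))
  perm_acc <- vapply(seq_len(n_perm), function(i) {
    loocv_svm(features, sample(labels), positive, cost, kernel)$accuracy
  }, 0)
  observed$permutation_p <- (1 + sum(perm_acc >= observed$accuracy)) /
    (1 + n_perm)
  observed$n_perm <- as.integer(n_perm)
  observed$perm_accuracies <- perm_acc
  observed
}
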