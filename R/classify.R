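#' Per-link functional feature table
#'
#' Builds the feature vector used to characterise retained versus
#' discarded links: cross-correlation peak `C_P`, raw peak count `C_O`,
#' peak lag `C_tau` (ms), correlogram entropy `C_H` (bits) and the mean
#' firing rates of the two electrodes (`MFR_x`, `MFR_y`). All features
#' derive from the original spike trains only, so they are unaffected by
#' the structural prior that defined the labels. The identity
#' `C_O = C_P * T * sqrt(MFR_x * MFR_y)` (with `T` the recording length)
#' is verified to integer rounding for every link.
#'
#' @param rg A [refine_functional()] result (supplies the link rows and
#'   `retained` labels).
#' @param spikes The [spike_train_set()] the links were computed from.
#' @return Data frame with columns `a`, `b`, `C_P`, `C_O`, `C_tau_ms`,
#'   `C_H`, `MFR_x`, `MFR_y`, `label` (factor retained/discarded).
#' @export
extract_features <- function(rg, spikes) {
  l <- rg$links
  el <- spikes$electrodes
  mfr <- setNames(el$mfr, el$index)
  f <- data.frame(
    a = l$a, b = l$b,
    C_P = l$C_P, C_O = l$C_O, C_tau_ms = l$C_tau * 1e3, C_H = l$C_H,
    MFR_x = unname(mfr[as.character(l$a)]),
    MFR_y = unname(mfr[as.character(l$b)]),
    label = factor(ifelse(l$retained, "retained", "discarded"),
                   levels = c("discarded", "retained")))
  pred <- f$C_P * spikes$t_r * sqrt(f$MFR_x * f$MFR_y)
  if (any(abs(pred - f$C_O) > 0.5 + 1e-6)) {
    stop("C_O does not satisfy C_P * T * sqrt(MFR_x * MFR_y) within rounding")
  }
  f
}

#' Analytic noise level of a two-class table
#'
#' Accuracy (in percent, one decimal) of the majority-class classifier:
#' the plateau that uninformative feature subsets converge to.
#'
#' @param n_retained,n_discarded Class counts.
#' @return Percentage in \[50, 100\].
#' @export
noise_level <- function(n_retained, n_discarded) {
  total <- n_retained + n_discarded
  stopifnot(total > 0, n_retained >= 0, n_discarded >= 0)
  round(100 * max(n_retained, n_discarded) / total, 1)
}

# Stratified fold assignment: within each class, shuffled round-robin.
stratified_folds <- function(labels, folds) {
  id <- integer(length(labels))
  for (cl in levels(labels)) {
    i <- which(labels == cl)
    id[i] <- sample(rep_len(seq_len(folds), length(i)))
  }
  id
}

#' Linear-SVM feature-subset ranking
#'
#' Quantifies the discriminative power of functional features for the
#' retained/discarded link classes. The five feature groups (`C_P`,
#' `C_O`, `C_tau`, `C_H`, `{MFR_x, MFR_y}`) generate all 31 non-empty
#' subsets; for each subset a linear SVM is trained and tested under
#' seeded stratified 10-fold cross-validation (features standardised to
#' zero mean / unit variance using the training fold only) and subsets
#' are ranked by mean accuracy. The analytic noise level of the table is
#' reported alongside.
#'
#' @param features Table from [extract_features()].
#' @param folds Number of CV folds (default 10).
#' @param seed Integer seed controlling fold assignment.
#' @param cost SVM regularisation constant (default 1).
#' @param subsets Optional list of character vectors of group names
#'   (subset of `C_P`, `C_O`, `C_tau`, `C_H`, `MFR`); default all 31.
#' @return Object of class `svm_ranking`: data frame `results` (`subset`,
#'   `features`, `mean_acc`, `sd_acc`, `rank`, in percent), `acc_eta`,
#'   `folds`, `seed`.
#' @export
svm_feature_ranking <- function(features, folds = 10, seed = 1L, cost = 1,
                                subsets = NULL) {
  labels <- features$label
  if (nlevels(droplevels(labels)) < 2 || min(table(labels)) < folds) {
    stop("need at least `folds` examples in each of the two classes")
  }
  groups <- list(C_P = "C_P", C_O = "C_O", C_tau = "C_tau_ms",
                 C_H = "C_H", MFR = c("MFR_x", "MFR_y"))
  if (is.null(subsets)) {
    subsets <- unlist(lapply(seq_along(groups), function(k) {
      utils::combn(names(groups), k, simplify = FALSE)
    }), recursive = FALSE)
  }
  set.seed(as.integer(seed))
  fold_id <- stratified_folds(labels, folds)
  res <- data.frame(subset = vapply(subsets, paste, "", collapse = "+"),
                    mean_acc = NA_real_, sd_acc = NA_real_)
  for (s in seq_along(subsets)) {
    cols <- unlist(groups[subsets[[s]]])
    X <- as.matrix(features[, cols, drop = FALSE])
    acc <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      mu <- colMeans(X[tr, , drop = FALSE])
      sd <- apply(X[tr, , drop = FALSE], 2, stats::sd)
      sd[sd == 0 | is.na(sd)] <- 1
      Xs <- sweep(sweep(X, 2, mu), 2, sd, "/")
      fit <- e1071::svm(Xs[tr, , drop = FALSE], labels[tr],
                        kernel = "linear", cost = cost, scale = FALSE)
      pred <- stats::predict(fit, Xs[!tr, , drop = FALSE])
      acc[f] <- 100 * mean(pred == labels[!tr])
    }
    res$mean_acc[s] <- mean(acc)
    res$sd_acc[s] <- stats::sd(acc)
  }
  res <- res[order(-res$mean_acc), ]
  res$rank <- seq_len(nrow(res))
  tab <- table(labels)
  structure(list(results = res,
                 acc_eta = noise_level(tab[["retained"]], tab[["discarded"]]),
                 folds = folds, seed = as.integer(seed), cost = cost),
            class = "svm_ranking")
}

#' @export
print.svm_ranking <- function(x, ...) {
  cat(sprintf("<svm_ranking> %d subsets, %d-fold CV, ACC_eta = %.1f%%\n",
              nrow(x$results), x$folds, x$acc_eta))
  top <- utils::head(x$results, 5)
  for (i in seq_len(nrow(top))) {
    cat(sprintf("  %2d. %-26s %5.1f +- %.1f %%\n", top$rank[i],
                top$subset[i], top$mean_acc[i], top$sd_acc[i]))
  }
  invisible(x)
}
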