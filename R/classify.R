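#' @title Three-group naive Bayes classification
#'
#' @description
#' Non-responders, responders and controls are classified from modularity
#' and transitivity features with a Gaussian naive Bayes classifier under
#' stratified 10-fold cross-validation. Because the control pool is larger
#' than the patient groups, evaluation repeatedly (1000x) draws a balanced
#' control subsample (14 of the available controls), runs the
#' cross-validation on the resulting 9/14/14 cohort, and averages the
#' confusion matrix and the per-class sensitivity, specificity, positive
#' predictive value, one-vs-rest accuracy and AUC over the repetitions.
#' @name vnsclassify
NULL

#' Fit a Gaussian naive Bayes model
#'
#' Empirical class priors; per class and feature, Gaussian mean and ML
#' variance, floored at 1e-9 times the largest overall feature variance so
#' degenerate classes keep a proper density.
#'
#' @param features numeric matrix (subjects x features).
#' @param labels class labels (factor or character).
#' @return object of class `gnb_model`.
#' @export
fit_gnb <- function(features, labels) {
  x <- as.matrix(features)
  labels <- as.character(labels)
  if (nrow(x) != length(labels)) stop("features/labels length mismatch")
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least two classes in training data")
  floor_var <- 1e-9 * max(apply(x, 2L, stats::var), 1e-300)
  par <- lapply(classes, function(cl) {
    xi <- x[labels == cl, , drop = FALSE]
    v <- apply(xi, 2L, function(col) mean((col - mean(col))^2))  # ML variance
    list(prior = nrow(xi) / nrow(x), mean = colMeans(xi),
         var = pmax(v, floor_var))
  })
  names(par) <- classes
  structure(list(classes = classes, par = par, n_features = ncol(x)),
            class = "gnb_model")
}

#' Posterior probabilities and labels from a Gaussian naive Bayes model
#'
#' Product of per-feature Gaussian likelihoods times the class prior,
#' normalized (computed in log space). Posterior ties go to the
#' lexicographically first class.
#'
#' @param model a `gnb_model`.
#' @param features numeric matrix (subjects x features) with the model's
#'   feature dimension.
#' @return list: `posterior` (subjects x classes matrix) and `label`.
#' @export
predict_gnb <- function(model, features) {
  x <- as.matrix(features)
  if (ncol(x) != model$n_features) stop("feature dimension mismatch")
  logp <- vapply(model$classes, function(cl) {
    p <- model$par[[cl]]
    rowSums(stats::dnorm(x, mean = rep(p$mean, each = nrow(x)),
                         sd = rep(sqrt(p$var), each = nrow(x)),
                         log = TRUE)) + log(p$prior)
  }, numeric(nrow(x)))
  logp <- matrix(logp, nrow = nrow(x),
                 dimnames = list(NULL, model$classes))
  post <- exp(logp - apply(logp, 1L, max))
  post <- post / rowSums(post)
  # which.max returns the first (lexicographically first class) on ties
  list(posterior = post, label = model$classes[apply(post, 1L, which.max)])
}

# stratified fold assignment: within each class, a seeded shuffle is dealt
# into k folds as evenly as integer counts allow, with the fold receiving
# the remainder rotating across classes.
stratified_folds <- function(labels, k, seed) {
  labels <- as.character(labels)
  n <- length(labels)
  if (k > n) stop("k exceeds the number of subjects")
  fold <- integer(n)
  with_seed(seed, {
    offset <- 0L
    for (cl in sort(unique(labels))) {
      idx <- sample(which(labels == cl))
      f <- (seq_along(idx) - 1L + offset) %% k + 1L
      fold[idx] <- f
      offset <- offset + length(idx)
    }
  })
  fold
}

#' Out-of-fold predictions under stratified k-fold cross-validation
#'
#' Folds preserve class proportions as nearly as integer counts allow;
#' every subject is predicted exactly once, by a model never trained on it.
#'
#' @param features subjects x features matrix.
#' @param labels class labels (every class needs >= 1 member).
#' @param k folds (default 10).
#' @param seed RNG seed for the fold assignment.
#' @return list: `posterior`, `label` (predicted), `fold`.
#' @export
stratified_kfold_predict <- function(features, labels, k = 10L, seed = 1L) {
  x <- as.matrix(features)
  labels <- as.character(labels)
  fold <- stratified_folds(labels, k, seed)
  classes <- sort(unique(labels))
  post <- matrix(NA_real_, nrow(x), length(classes),
                 dimnames = list(NULL, classes))
  pred <- character(nrow(x))
  for (f in seq_len(k)) {
    test <- fold == f
    if (!any(test)) next
    model <- fit_gnb(x[!test, , drop = FALSE], labels[!test])
    pr <- predict_gnb(model, x[test, , drop = FALSE])
    post[test, model$classes] <- pr$posterior
    pred[test] <- pr$label
  }
  list(posterior = post, label = pred, fold = fold)
}

#' Per-class and weighted metrics from a 3-group confusion matrix
#'
#' One-vs-rest per class: sensitivity = TP / actual positives, specificity
#' = TN / actual negatives, PPV = TP / predicted positives (`NA` when the
#' class is never predicted), accuracy = (TP + TN) / total. The weighted
#' average weights classes by their actual sizes.
#'
#' @param confusion actual x predicted matrix (real-valued entries are
#'   allowed: averaged confusion matrices).
#' @param class_sizes actual class sizes (default row sums).
#' @return data.frame with one row per class plus a `weighted` row.
#' @export
metrics_from_confusion <- function(confusion,
                                   class_sizes = rowSums(confusion)) {
  cm <- as.matrix(confusion)
  stopifnot(nrow(cm) == ncol(cm), all(cm >= 0))
  total <- sum(cm)
  classes <- rownames(cm)
  if (is.null(classes)) classes <- as.character(seq_len(nrow(cm)))
  per <- lapply(seq_len(nrow(cm)), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    data.frame(class = classes[i],
               sensitivity = tp / (tp + fn),
               specificity = tn / (tn + fp),
               ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               accuracy = (tp + tn) / total)
  })
  out <- do.call(rbind, per)
  w <- class_sizes / sum(class_sizes)
  wavg <- vapply(c("sensitivity", "specificity", "ppv", "accuracy"),
                 function(col) {
                   v <- out[[col]]
                   ok <- !is.na(v)
                   sum(v[ok] * w[ok]) / sum(w[ok])
                 }, numeric(1))
  rbind(out, data.frame(class = "weighted",
                        sensitivity = wavg[["sensitivity"]],
                        specificity = wavg[["specificity"]],
                        ppv = wavg[["ppv"]],
                        accuracy = wavg[["accuracy"]]))
}

#' One-vs-rest AUC from posterior scores
#'
#' For each class, the AUC of its posterior probability as the score for
#' class-vs-rest, in the Mann-Whitney formulation with ties counted 1/2.
#'
#' @param posteriors subjects x classes matrix (rows sum to 1).
#' @param labels actual labels (every class needs >= 1 member).
#' @return named numeric vector of per-class AUCs.
#' @export
auc_one_vs_rest <- function(posteriors, labels) {
  labels <- as.character(labels)
  classes <- colnames(posteriors)
  vapply(classes, function(cl) {
    pos <- labels == cl
    if (!any(pos) || all(pos)) stop("class '", cl, "' has zero members in one group")
    s <- posteriors[, cl]
    r <- rank(s)
    n1 <- sum(pos); n0 <- sum(!pos)
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1))
}

#' Repeated balanced-subsample cross-validation report
#'
#' Per repetition: draw `n_controls_drawn` controls without replacement from
#' the control pool, pool them with all patients, run stratified k-fold
#' cross-validation, and record the confusion matrix (rows = actual
#' non_responder / responder / control), per-class metrics and one-vs-rest
#' AUCs. The report averages everything over repetitions.
#'
#' @param features subjects x features matrix for the full cohort.
#' @param labels labels (`non_responder`, `responder`, `control`).
#' @param n_reps repetitions (default 1000).
#' @param n_controls_drawn controls per repetition (default 14).
#' @param k folds (default 10).
#' @param seed RNG seed (each repetition derives its own child seed, so the
#'   first repetitions are identical across calls that share `seed`).
#' @return object of class `classifier_report`: `confusion` (averaged),
#'   `metrics` (per-class + weighted, including `auc`), `n_reps`,
#'   `class_sizes`.
#' @export
balanced_repeated_cv <- function(features, labels, n_reps = 1000L,
                                 n_controls_drawn = 14L, k = 10L,
                                 seed = 1L) {
  x <- as.matrix(features)
  labels <- as.character(labels)
  ctrl_idx <- which(labels == "control")
  pat_idx <- which(labels != "control")
  if (length(ctrl_idx) < n_controls_drawn)
    stop("fewer controls than the requested draw")
  classes <- sort(unique(labels))
  cm_sum <- matrix(0, length(classes), length(classes),
                   dimnames = list(classes, classes))
  metr_sum <- NULL
  auc_sum <- stats::setNames(numeric(length(classes)), classes)
  for (rep in seq_len(n_reps)) {
    rs <- child_seed(seed, rep)
    draw <- with_seed(rs, sample(ctrl_idx, n_controls_drawn))
    idx <- c(pat_idx, draw)
    cv <- stratified_kfold_predict(x[idx, , drop = FALSE], labels[idx],
                                   k = k, seed = child_seed(rs, 1L))
    cm <- table(factor(labels[idx], levels = classes),
                factor(cv$label, levels = classes))
    cm_sum <- cm_sum + unclass(cm)
    m <- metrics_from_confusion(cm)
    metr_sum <- if (is.null(metr_sum)) m[, -1] else metr_sum + m[, -1]
    auc_sum <- auc_sum + auc_one_vs_rest(cv$posterior, labels[idx])
  }
  confusion <- cm_sum / n_reps
  metrics <- metr_sum / n_reps
  metrics <- cbind(class = c(classes, "weighted"), metrics)
  class_sizes <- rowSums(confusion)
  w <- class_sizes / sum(class_sizes)
  auc <- auc_sum / n_reps
  metrics$auc <- c(auc, sum(auc * w))
  structure(list(confusion = confusion, metrics = metrics,
                 n_reps = n_reps, class_sizes = class_sizes),
            class = "classifier_report")
}

#' The four classifier feature sets
#'
#' Modularity and transitivity in one band (2 features) or in all three
#' bands (6 features). Characteristic path length is excluded from the menu
#' by design, following the feature selection of the analysis this package
#' mirrors (where CPL did not separate the patient groups).
#'
#' @param averaged run-averaged feature table from [cohort_features()].
#' @param bands `"theta"`, `"alpha"`, `"beta"`, or `"all"`.
#' @return list: `x` (feature matrix), `labels`, `feature_names`.
#' @export
classifier_features <- function(averaged, bands = "theta") {
  use <- if (identical(bands, "all")) c("theta", "alpha", "beta") else bands
  ids <- unique(averaged$subject_id)
  cols <- list()
  for (b in use) {
    sub <- averaged[averaged$band == b, ]
    sub <- sub[match(ids, sub$subject_id), ]
    cols[[paste0("transitivity_", b)]] <- sub$transitivity
    cols[[paste0("modularity_", b)]] <- sub$modularity
  }
  x <- do.call(cbind, cols)
  rownames(x) <- ids
  lab <- averaged$group[match(ids, averaged$subject_id)]
  list(x = x, labels = lab, feature_names = colnames(x))
}
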