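#' Build a 2x2 confusion matrix (cough = positive)
#'
#' @param predicted,truth logical vectors (`TRUE` = cough), or a
#'   score/threshold pair via `scores > threshold`
#' @return a `ConfusionMatrix` list with `tp`, `fn`, `fp`, `tn`
#' @export
confusion_matrix <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  structure(list(tp = sum(predicted & truth),
                 fn = sum(!predicted & truth),
                 fp = sum(predicted & !truth),
                 tn = sum(!predicted & !truth)),
            class = "ConfusionMatrix")
}

#' Detection metrics and Cohen's kappa from a confusion matrix
#'
#' Accuracy, sensitivity (recall), specificity, PPV (precision), NPV and
#' chance-corrected agreement
#' `kappa = (p_o - p_e) / (1 - p_e)` with the expected agreement `p_e`
#' from the marginal products. Metrics with a zero denominator are
#' reported as `NA` (undefined), never as 0.
#'
#' @param cm a [confusion_matrix()] or list with `tp`, `fn`, `fp`, `tn`
#' @return a `MetricsReport` list of fractions (`kappa` in \[-1, 1\])
#' @export
metrics_from_confusion <- function(cm) {
  tp <- cm$tp; fn <- cm$fn; fp <- cm$fp; tn <- cm$tn
  total <- tp + fn + fp + tn
  stopifnot(total > 0)
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  p_o <- (tp + tn) / total
  p_yes <- ((tp + fp) / total) * ((tp + fn) / total)
  p_no <- ((fn + tn) / total) * ((fp + tn) / total)
  p_e <- p_yes + p_no
  structure(list(
    accuracy = p_o,
    sensitivity = safe(tp, tp + fn),
    specificity = safe(tn, tn + fp),
    ppv = safe(tp, tp + fp),
    npv = safe(tn, tn + fn),
    kappa = if (p_e < 1) (p_o - p_e) / (1 - p_e) else NA_real_),
    class = "MetricsReport")
}

#' ROC and precision-recall curves with trapezoidal AUCs
#'
#' Curves are traced over all distinct score thresholds (tied scores are
#' grouped); the classification rule is `score > threshold`.
#'
#' @param scores numeric scores (higher = more cough-like)
#' @param labels logical truth (`TRUE` = cough)
#' @return list with `roc` (threshold, sensitivity, specificity),
#'   `pr` (threshold, recall, precision), `roc_auc`, `pr_auc`
#' @export
roc_pr_curves <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    stop("both classes must be present to trace ROC/PR curves")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  keep <- c(diff(s) != 0, TRUE)
  tp <- cumsum(y)[keep]
  fp <- cumsum(!y)[keep]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  sens <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  prec <- c(1, tp / (tp + fp))
  thr <- c(Inf, s[keep])
  trap <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  list(roc = data.frame(threshold = thr, sensitivity = sens,
                        specificity = 1 - fpr),
       pr = data.frame(threshold = thr, recall = sens, precision = prec),
       roc_auc = trap(fpr, sens),
       pr_auc = trap(sens, prec))
}

#' Largest threshold achieving a target sensitivity
#'
#' With the rule `score > threshold`, returns the largest threshold whose
#' sensitivity on the given split is at least `target_sensitivity`.
#'
#' @param scores numeric scores
#' @param labels logical truth (`TRUE` = cough)
#' @param target_sensitivity fraction in (0, 1\]
#' @return threshold value
#' @export
choose_threshold <- function(scores, labels, target_sensitivity) {
  stopifnot(target_sensitivity > 0, target_sensitivity <= 1)
  pos <- sort(scores[as.logical(labels)], decreasing = TRUE)
  n_pos <- length(pos)
  if (n_pos == 0) stop("no positive events")
  k <- ceiling(target_sensitivity * n_pos)   # need at least k positives above
  if (k > n_pos) stop("target sensitivity unattainable")
  # any threshold strictly below the k-th positive score keeps >= k positives
  thr <- pos[k] - .Machine$double.eps * max(1, abs(pos[k]))
  # back off further if ties straddle the k-th score
  thr <- min(thr, pos[k] - 1e-12)
  thr
}

#' J-optimal LLR threshold on a labelled split
#'
#' Sweeps all distinct thresholds and returns the one maximising
#' `J = (sensitivity + PPV)/2` under the rule `score > threshold`.
#'
#' @inheritParams roc_pr_curves
#' @return list with `threshold`, `J`, `sensitivity`, `ppv`
#' @export
j_optimal_threshold <- function(scores, labels) {
  labels <- as.logical(labels)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  keep <- which(c(diff(s) != 0, FALSE))      # thresholds between groups
  if (length(keep) == 0) keep <- length(s)
  tp <- cumsum(y)[keep]
  fp <- cumsum(!y)[keep]
  sens <- tp / sum(labels)
  ppv <- tp / (tp + fp)
  J <- (sens + ppv) / 2
  i <- which.max(J)
  thr <- if (keep[i] < length(s))
    (s[keep[i]] + s[keep[i] + 1]) / 2
  else s[length(s)] - 1       # accept everything

  list(threshold = thr, J = J[i], sensitivity = sens[i], ppv = ppv[i])
}

#' Subject-wise k-fold cross-validation of a classifier system
#'
#' Subjects are assigned to folds greedily to balance per-fold cough
#' counts (no subject appears in two folds). For each fold the classifier
#' is trained on the remaining subjects and evaluated on the held-out
#' fold at its J-optimal threshold.
#'
#' @param features feature matrix
#' @param labels event labels (`cough`/`snore`/`noise`)
#' @param subjects subject id per event
#' @param k number of folds (default 5)
#' @param classifier `"gmm"` or `"dnn"`
#' @param seed RNG seed
#' @param ... further arguments passed to [train_gmm_system()] or
#'   [train_dnn()] (e.g. `orders`, `config`)
#' @return list with `per_fold` (data.frame of metrics), `mean`, `sd`
#' @export
kfold_cv <- function(features, labels, subjects, k = 5,
                     classifier = c("gmm", "dnn"), seed = 1, ...) {
  classifier <- match.arg(classifier)
  subj <- unique(subjects)
  if (k > length(subj)) stop("k exceeds the number of subjects")
  counts <- vapply(subj, function(s)
    sum(labels == "cough" & subjects == s), numeric(1))
  set.seed(seed)
  ord <- order(counts + runif(length(counts)) * 1e-9, decreasing = TRUE)
  fold_of <- integer(length(subj))
  load <- numeric(k)
  for (i in ord) {                    # greedy balance of cough counts
    f <- which.min(load)
    fold_of[i] <- f
    load[f] <- load[f] + counts[i]
  }
  rows <- lapply(seq_len(k), function(f) {
    test_subj <- subj[fold_of == f]
    te <- subjects %in% test_subj
    if (classifier == "gmm") {
      sys <- train_gmm_system(features[!te, , drop = FALSE], labels[!te],
                              seed = seed, ...)
      scores <- gmm_llr(sys, features[te, , drop = FALSE])
    } else {
      model <- train_dnn(features[!te, , drop = FALSE], labels[!te], ...)
      scores <- dnn_llr(model, features[te, , drop = FALSE])
    }
    truth <- labels[te] == "cough"
    thr <- j_optimal_threshold(scores, truth)$threshold
    m <- metrics_from_confusion(confusion_matrix(scores > thr, truth))
    data.frame(fold = f, accuracy = m$accuracy, sensitivity = m$sensitivity,
               specificity = m$specificity, ppv = m$ppv, npv = m$npv,
               kappa = m$kappa)
  })
  per_fold <- do.call(rbind, rows)
  list(per_fold = per_fold,
       mean = colMeans(per_fold[-1], na.rm = TRUE),
       sd = apply(per_fold[-1], 2, sd, na.rm = TRUE),
       fold_subjects = split(subj, fold_of))
}
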