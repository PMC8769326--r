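#' Feature-selection criterion: mean of sensitivity and PPV
#'
#' `J = (sensitivity + PPV) / 2`, the wrapper criterion maximised during
#' sequential forward selection.
#'
#' @param sensitivity,ppv fractions in \[0, 1\]
#' @return scalar in \[0, 1\]
#' @export
criterion_J <- function(sensitivity, ppv) {
  if (any(sensitivity < 0 | sensitivity > 1) || any(ppv < 0 | ppv > 1))
    stop("sensitivity and PPV must lie in [0, 1]")
  (sensitivity + ppv) / 2
}

#' Sequential Forward Selection over the acoustic features
#'
#' Greedy wrapper selection: at each step the candidate feature whose
#' addition maximises the criterion `J` of the GMM classifier — trained on
#' the training split and scored on the development split at the
#' development-optimal LLR threshold — is added. The subset at the
#' trajectory maximum is returned. Model orders stay fixed during the
#' search (default (1, 1, 16), the final operating point) to keep the
#' inner loop tractable.
#'
#' @param train_x,train_y training feature matrix and labels
#'   (`cough`/`snore`/`noise`)
#' @param dev_x,dev_y development split (subject-disjoint from training)
#' @param max_features largest subset size explored (default: all)
#' @param orders GMM component counts used inside the wrapper
#' @param seed RNG seed for EM initialisation
#' @return a `SelectionResult`: list with `selected` (ordered names of the
#'   best subset), `order_added` (full greedy path),
#'   `criterion_trajectory`, `best_subset_size`
#' @export
sfs_select <- function(train_x, train_y, dev_x, dev_y,
                       max_features = ncol(train_x),
                       orders = c(cough = 1, snore = 1, noise = 16),
                       seed = 1) {
  stopifnot(ncol(train_x) == ncol(dev_x))
  nm <- colnames(train_x)
  if (is.null(nm)) nm <- paste0("f", seq_len(ncol(train_x)))
  pos <- dev_y == "cough"
  chosen <- integer(0)
  trajectory <- numeric(0)
  for (step in seq_len(min(max_features, ncol(train_x)))) {
    cand <- setdiff(seq_len(ncol(train_x)), chosen)
    Js <- vapply(cand, function(f) {
      cols <- c(chosen, f)
      sys <- tryCatch(
        train_gmm_system(train_x[, cols, drop = FALSE], train_y,
                         orders = orders, seed = seed),
        error = function(e) NULL)
      if (is.null(sys)) return(NA_real_)
      .best_J(gmm_llr(sys, dev_x[, cols, drop = FALSE]), pos)
    }, numeric(1))
    if (all(is.na(Js))) {
      warning("all remaining candidates failed GMM training; stopping")
      break
    }
    best <- cand[which.max(Js)]
    chosen <- c(chosen, best)
    trajectory <- c(trajectory, max(Js, na.rm = TRUE))
  }
  k <- which.max(trajectory)
  structure(list(selected = nm[chosen[seq_len(k)]],
                 order_added = nm[chosen],
                 criterion_trajectory = trajectory,
                 best_subset_size = k),
            class = "SelectionResult")
}

#' The published default feature mask
#'
#' Logical mask over [feature_names()] reproducing the reference
#' configuration in which 31 of the 34 features are kept: one of the
#' twelve first-part MFCCs and the two distribution-moment features
#' (kurtosis, skewness) are dropped.
#'
#' @param mfcc1_dropped which first-part MFCC index is excluded (the
#'   published table reports 11 of 12 kept without naming the dropped one;
#'   default 12)
#' @return named logical vector of length 34 with 31 `TRUE` entries
#' @export
paper_feature_mask <- function(mfcc1_dropped = 12) {
  nm <- feature_names()
  keep <- rep(TRUE, length(nm))
  names(keep) <- nm
  keep[c(paste0("mfcc1_", mfcc1_dropped), "kurtosis", "skewness")] <- FALSE
  keep
}
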