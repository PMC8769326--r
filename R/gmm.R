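# ---- diagonal-covariance Gaussian mixtures fitted by EM ----

# log N(x; mu, diag(v)) for all rows of X against all components;
# returns a components x observations matrix
.log_comp_dens <- function(X, means, vars) {
  D <- ncol(X)
  out <- matrix(0, nrow(means), nrow(X))
  tX <- t(X)
  for (i in seq_len(nrow(means))) {
    out[i, ] <- -0.5 * (D * log(2 * pi) + sum(log(vars[i, ])) +
                          colSums((tX - means[i, ])^2 / vars[i, ]))
  }
  out
}

.logsumexp <- function(M) {          # over rows (components)
  mx <- apply(M, 2, max)
  mx + log(colSums(exp(sweep(M, 2, mx))))
}

#' Fit a diagonal-covariance Gaussian mixture by EM
#'
#' K-means initialisation with `restarts` seeded restarts (best final
#' log-likelihood kept), variance floor, convergence on the relative
#' log-likelihood improvement. Order 1 reduces to the closed-form
#' single-Gaussian MLE.
#'
#' @param X numeric matrix (observations in rows)
#' @param order number of mixture components
#' @param seed RNG seed controlling initialisation (deterministic fit)
#' @param max_iter,tol EM stopping rule
#' @param restarts number of k-means initialisations
#' @param var_floor lower bound applied to all variances
#' @return a `GaussianMixture`: list with `weights`, `means`, `vars`
#'   (components in rows), `order`, `loglik` (per-iteration trajectory of
#'   the best restart), `converged`
#' @export
fit_gmm <- function(X, order, seed = 1, max_iter = 200, tol = 1e-6,
                    restarts = 5, var_floor = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X); D <- ncol(X)
  if (order > n) stop("mixture order (", order, ") exceeds ", n, " rows")
  if (order == 1) {
    v <- pmax(apply(X, 2, function(c) mean((c - mean(c))^2)), var_floor)
    ll <- sum(.log_comp_dens(X, matrix(colMeans(X), 1), matrix(v, 1)))
    return(structure(list(weights = 1, means = matrix(colMeans(X), 1),
                          vars = matrix(v, 1), order = 1L,
                          loglik = ll, converged = TRUE),
                     class = "GaussianMixture"))
  }
  best <- NULL
  for (r in seq_len(restarts)) {
    set.seed(seed * 1000L + r)
    km <- suppressWarnings(
      kmeans(X, centers = order, nstart = 1, iter.max = 50))
    means <- km$centers
    vars <- matrix(pmax(apply(X, 2, var), var_floor), order, D,
                   byrow = TRUE)
    weights <- pmax(tabulate(km$cluster, order), 1) / n
    weights <- weights / sum(weights)
    ll_hist <- numeric(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      lp <- .log_comp_dens(X, means, vars) + log(weights)
      norm <- .logsumexp(lp)
      ll <- sum(norm)
      ll_hist <- c(ll_hist, ll)
      if (it > 1 &&
          abs(ll - ll_hist[it - 1]) < tol * (abs(ll_hist[it - 1]) + 1)) {
        converged <- TRUE
        break
      }
      R <- exp(sweep(lp, 2, norm))              # responsibilities (comp x n)
      nk <- rowSums(R)
      nk <- pmax(nk, 1e-10)
      weights <- nk / n
      means <- (R %*% X) / nk
      for (i in seq_len(order)) {
        d2 <- (t(X) - means[i, ])^2
        vars[i, ] <- pmax((d2 %*% R[i, ]) / nk[i], var_floor)
      }
    }
    if (is.null(best) || tail(ll_hist, 1) > tail(best$loglik, 1)) {
      best <- list(weights = weights, means = means, vars = vars,
                   order = as.integer(order), loglik = ll_hist,
                   converged = converged)
    }
  }
  structure(best, class = "GaussianMixture")
}

#' Mixture likelihood of feature vectors
#'
#' `S = sum_i w_i N(beta; mu_i, Sigma_i)` with diagonal Gaussian
#' components, computed in the log domain for stability.
#'
#' @param model a `GaussianMixture`
#' @param beta feature vector, or matrix with vectors in rows
#' @param log return the log-likelihood instead of the likelihood
#' @return numeric vector, one (log-)likelihood per row of `beta`
#' @export
gmm_likelihood <- function(model, beta, log = FALSE) {
  if (is.null(dim(beta))) beta <- matrix(beta, nrow = 1)
  if (ncol(beta) != ncol(model$means))
    stop("feature dimension ", ncol(beta), " does not match model (",
         ncol(model$means), ")")
  lp <- .log_comp_dens(beta, model$means, model$vars) + log(model$weights)
  ll <- if (nrow(model$means) == 1) as.numeric(lp) else .logsumexp(lp)
  if (log) ll else exp(ll)
}

#' Train the three-class GMM cough/snore/noise system
#'
#' Features are z-scored with training statistics (stored with the model);
#' one mixture is fitted per class at the given orders (paper operating
#' point: 1 cough, 1 snore, 16 noise Gaussians).
#'
#' @param features training matrix (rows = events)
#' @param labels character labels in `{cough, snore, noise}`
#' @param orders named or positional component counts for
#'   (cough, snore, noise)
#' @param seed RNG seed for EM initialisation
#' @return a `GmmSystem`: class models plus normalisation stats
#' @export
train_gmm_system <- function(features, labels, orders = c(1, 1, 16),
                             seed = 1) {
  stopifnot(nrow(features) == length(labels),
            all(labels %in% c("cough", "snore", "noise")))
  mu <- colMeans(features)
  sdv <- pmax(apply(features, 2, sd), 1e-8)
  Z <- sweep(sweep(features, 2, mu), 2, sdv, "/")
  cls <- c("cough", "snore", "noise")
  if (is.null(names(orders))) names(orders) <- cls
  models <- lapply(cls, function(cl) {
    Xc <- Z[labels == cl, , drop = FALSE]
    fit_gmm(Xc, order = min(orders[[cl]], nrow(Xc)), seed = seed)
  })
  names(models) <- cls
  structure(list(models = models, center = mu, scale = sdv,
                 orders = orders),
            class = "GmmSystem")
}

#' Cough log-likelihood-ratio scores from a three-class GMM system
#'
#' `LLR = log(S_cough / max(S_snore, S_noise))`, computed in the log
#' domain; the two competing classes are fused by the max. Events with
#' `LLR > threshold` are called coughs.
#'
#' @param system a `GmmSystem` from [train_gmm_system()]
#' @param features matrix of events (raw scale; normalisation is applied
#'   internally)
#' @return numeric LLR vector with attribute `class_loglik` (3-column
#'   matrix of per-class log-likelihoods)
#' @export
gmm_llr <- function(system, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  Z <- sweep(sweep(features, 2, system$center), 2, system$scale, "/")
  L <- vapply(system$models, gmm_likelihood, numeric(nrow(Z)),
              beta = Z, log = TRUE)
  if (is.null(dim(L))) L <- matrix(L, nrow = 1,
                                   dimnames = list(NULL, names(system$models)))
  llr <- L[, "cough"] - pmax(L[, "snore"], L[, "noise"])
  attr(llr, "class_loglik") <- L
  llr
}

#' Select per-class GMM orders on a development split
#'
#' Each class model is fitted once at every order `1..max_order`; all
#' order triples are then scored on the development set and the triple
#' maximising the selection criterion `J` (at the J-optimal LLR threshold)
#' is returned.
#'
#' @param train_x,train_y,dev_x,dev_y feature matrices and labels
#' @param max_order largest component count searched per class (paper: 20)
#' @param seed RNG seed
#' @return list with `orders` (named triple), `J` (best criterion value)
#' @export
select_orders <- function(train_x, train_y, dev_x, dev_y, max_order = 20,
                          seed = 1) {
  mu <- colMeans(train_x)
  sdv <- pmax(apply(train_x, 2, sd), 1e-8)
  Zt <- sweep(sweep(train_x, 2, mu), 2, sdv, "/")
  Zd <- sweep(sweep(dev_x, 2, mu), 2, sdv, "/")
  cls <- c("cough", "snore", "noise")
  # log-likelihood of every dev event under every class at every order
  ll <- lapply(cls, function(cl) {
    Xc <- Zt[train_y == cl, , drop = FALSE]
    ords <- seq_len(min(max_order, nrow(Xc)))
    vapply(ords, function(m)
      gmm_likelihood(fit_gmm(Xc, m, seed = seed), Zd, log = TRUE),
      numeric(nrow(Zd)))
  })
  names(ll) <- cls
  pos <- dev_y == "cough"
  best <- list(J = -Inf)
  for (m1 in seq_len(ncol(ll$cough)))
    for (m2 in seq_len(ncol(ll$snore)))
      for (m3 in seq_len(ncol(ll$noise))) {
        llr <- ll$cough[, m1] - pmax(ll$snore[, m2], ll$noise[, m3])
        J <- .best_J(llr, pos)
        if (J > best$J)
          best <- list(orders = c(cough = m1, snore = m2, noise = m3),
                       J = J)
      }
  best
}

# best attainable J = (sensitivity + PPV)/2 over all LLR thresholds
.best_J <- function(scores, positive) {
  o <- order(scores, decreasing = TRUE)
  pos <- positive[o]
  tp <- cumsum(pos)
  fp <- cumsum(!pos)
  n_pos <- sum(pos)
  keep <- c(diff(scores[o]) != 0, TRUE)   # group tied scores
  sens <- tp[keep] / n_pos
  ppv <- tp[keep] / (tp[keep] + fp[keep])
  max((sens + ppv) / 2)
}
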