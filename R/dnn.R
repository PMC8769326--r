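#' Specify the two-hidden-layer cough/non-cough network
#'
#' A fully connected network: input, two 100-unit ReLU hidden layers with
#' 50% dropout between them, and a 2-unit softmax output (S1 = cough,
#' S2 = non-cough). With 31 input features it has 13,502 learnable
#' parameters.
#'
#' @param input_dim number of input features (>= 1)
#' @param hidden hidden-layer widths (default `c(100, 100)`)
#' @param dropout dropout rate applied between the hidden layers
#' @param n_classes output units (2)
#' @return a `NetworkSpec` list with `dims` (layer sizes) and `dropout`
#' @export
build_network <- function(input_dim, hidden = c(100, 100), dropout = 0.5,
                          n_classes = 2) {
  if (input_dim < 1) stop("input_dim must be >= 1")
  structure(list(dims = c(input_dim, hidden, n_classes), dropout = dropout),
            class = "NetworkSpec")
}

#' Count the learnable parameters of a network spec
#'
#' Sum over consecutive layers of `fan_in * fan_out + fan_out`
#' (weights plus biases). A spec with fewer than two layers has none.
#'
#' @param spec a `NetworkSpec` (or any list with a `dims` vector)
#' @return integer parameter count
#' @export
count_parameters <- function(spec) {
  d <- spec$dims
  if (length(d) < 2) return(0L)
  as.integer(sum(d[-length(d)] * d[-1] + d[-1]))
}

#' Training configuration for the network
#'
#' Defaults are the reference recipe: Adam, learning rate 5e-6, batch
#' size 32, 250 epochs, inverse-frequency class weights.
#'
#' @param learning_rate Adam step size
#' @param batch_size minibatch size
#' @param epochs number of passes over the training set
#' @param class_weights optional named weights for `cough`/`noncough`;
#'   `NULL` uses `n_total / (2 * n_class)`
#' @param seed RNG seed (initialisation, shuffling, dropout)
#' @return a `TrainingConfig` list
#' @export
dnn_config <- function(learning_rate = 5e-6, batch_size = 32, epochs = 250,
                       class_weights = NULL, seed = 1) {
  stopifnot(learning_rate > 0, epochs >= 1)
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 epochs = epochs, class_weights = class_weights,
                 seed = seed),
            class = "TrainingConfig")
}

.glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

.softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# forward pass; dropout mask applied between the hidden layers when given
.dnn_forward <- function(p, X, drop_mask = NULL) {
  H1 <- pmax(X %*% p$W1 + rep(p$b1, each = nrow(X)), 0)
  H1d <- if (is.null(drop_mask)) H1 else H1 * drop_mask
  H2 <- pmax(H1d %*% p$W2 + rep(p$b2, each = nrow(X)), 0)
  Z <- H2 %*% p$W3 + rep(p$b3, each = nrow(X))
  list(H1 = H1, H1d = H1d, H2 = H2, P = .softmax_rows(Z))
}

#' Train the cough/non-cough network
#'
#' Minimises class-weighted cross-entropy with Adam. Inputs are z-scored
#' with training statistics (stored in the model); dropout is active only
#' during training; a fixed seed makes training bit-reproducible on one
#' CPU.
#'
#' @param x training feature matrix
#' @param y labels; anything equal to `"cough"` is the positive class,
#'   everything else is merged into `non-cough`
#' @param spec a [build_network()] spec (default built from `ncol(x)`)
#' @param config a [dnn_config()]
#' @return a `NetworkModel` with weights, normalisation stats, the spec
#'   and the per-epoch mean training loss (`loss_history`)
#' @export
train_dnn <- function(x, y, spec = build_network(ncol(x)),
                      config = dnn_config()) {
  x <- as.matrix(x)
  yb <- ifelse(y == "cough", 1L, 2L)       # column index: 1 cough, 2 non
  if (length(unique(yb)) < 2)
    stop("training set must contain both classes")
  n <- nrow(x)
  cw <- config$class_weights
  if (is.null(cw)) {
    cnt <- tabulate(yb, 2)
    cw <- n / (2 * cnt)
  }
  mu <- colMeans(x)
  sdv <- pmax(apply(x, 2, sd), 1e-8)
  X <- sweep(sweep(x, 2, mu), 2, sdv, "/")

  set.seed(config$seed)
  d <- spec$dims
  p <- list(W1 = .glorot(d[1], d[2]), b1 = numeric(d[2]),
            W2 = .glorot(d[2], d[3]), b2 = numeric(d[3]),
            W3 = .glorot(d[3], d[4]), b3 = numeric(d[4]))
  mom <- lapply(p, function(w) w * 0)
  vel <- lapply(p, function(w) w * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t_step <- 0
  keep <- 1 - spec$dropout
  loss_history <- numeric(config$epochs)

  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    ep_loss <- 0; ep_n <- 0
    for (i0 in seq(1, n, by = config$batch_size)) {
      idx <- perm[i0:min(n, i0 + config$batch_size - 1L)]
      Xb <- X[idx, , drop = FALSE]
      yi <- yb[idx]
      m <- length(idx)
      mask <- if (keep < 1)
        matrix(rbinom(m * d[2], 1, keep) / keep, m, d[2]) else NULL
      fw <- .dnn_forward(p, Xb, mask)
      Pi <- pmax(fw$P[cbind(seq_len(m), yi)], 1e-12)
      wb <- cw[yi]
      ep_loss <- ep_loss + sum(-wb * log(Pi)); ep_n <- ep_n + m

      dZ <- fw$P
      dZ[cbind(seq_len(m), yi)] <- dZ[cbind(seq_len(m), yi)] - 1
      dZ <- dZ * wb / m
      g <- list()
      g$W3 <- crossprod(fw$H2, dZ); g$b3 <- colSums(dZ)
      dH2 <- tcrossprod(dZ, p$W3) * (fw$H2 > 0)
      g$W2 <- crossprod(fw$H1d, dH2); g$b2 <- colSums(dH2)
      dH1 <- tcrossprod(dH2, p$W2)
      if (!is.null(mask)) dH1 <- dH1 * mask
      dH1 <- dH1 * (fw$H1 > 0)
      g$W1 <- crossprod(Xb, dH1); g$b1 <- colSums(dH1)

      t_step <- t_step + 1
      for (nm in names(p)) {
        mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * g[[nm]]
        vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * g[[nm]]^2
        mhat <- mom[[nm]] / (1 - b1^t_step)
        vhat <- vel[[nm]] / (1 - b2^t_step)
        p[[nm]] <- p[[nm]] - config$learning_rate * mhat / (sqrt(vhat) + eps)
      }
    }
    loss_history[epoch] <- ep_loss / ep_n
  }
  structure(list(params = p, center = mu, scale = sdv, spec = spec,
                 config = config, class_weights = cw,
                 loss_history = loss_history),
            class = "NetworkModel")
}

#' Class probabilities from a trained network
#'
#' @param model a `NetworkModel`
#' @param x feature matrix or single vector (raw scale)
#' @return matrix with columns `cough` (S1) and `noncough` (S2)
#' @export
predict_dnn <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  X <- sweep(sweep(as.matrix(x), 2, model$center), 2, model$scale, "/")
  P <- .dnn_forward(model$params, X)$P
  colnames(P) <- c("cough", "noncough")
  P
}

#' Network log-likelihood-ratio scores
#'
#' `LLR = log(S1) - log(S2)` with probabilities clipped to
#' `[1e-12, 1]`. Events with `LLR > threshold` are called coughs.
#'
#' @inheritParams predict_dnn
#' @return numeric LLR vector
#' @export
dnn_llr <- function(model, x) {
  P <- pmax(predict_dnn(model, x), 1e-12)
  as.numeric(log(P[, "cough"]) - log(P[, "noncough"]))
}

#' Class-weighted cross-entropy loss (helper, exposed for testing)
#'
#' @param probs matrix of predicted class probabilities
#' @param y integer class indices (columns of `probs`)
#' @param weights per-class weights (recycled over classes)
#' @return mean weighted negative log-likelihood
#' @export
weighted_cross_entropy <- function(probs, y, weights = rep(1, ncol(probs))) {
  p <- pmax(probs[cbind(seq_along(y), y)], 1e-12)
  mean(-weights[y] * log(p))
}
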