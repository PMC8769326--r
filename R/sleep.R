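#' Hypnogram objects
#'
#' A `Hypnogram` is a sequence of sleep-stage labels
#' (`W`, `REM`, `N1`, `N2`, `N3`), one per 30-s epoch.
#'
#' @param stages character vector of stage labels
#' @param epoch_length epoch length in seconds (30 by convention)
#' @param start_time recording time of the first epoch (s)
#' @return an object of class `Hypnogram`
#' @export
hypnogram <- function(stages, epoch_length = 30, start_time = 0) {
  stages <- as.character(stages)
  if (!all(stages %in% STAGES))
    stop("unknown stage labels: ",
         paste(setdiff(stages, STAGES), collapse = ", "))
  structure(list(stages = stages, epoch_length = epoch_length,
                 start_time = start_time),
            class = "Hypnogram")
}

#' @export
print.Hypnogram <- function(x, ...) {
  cat(sprintf("<Hypnogram: %d x %g-s epochs (%.2f h)>\n", length(x$stages),
              x$epoch_length, length(x$stages) * x$epoch_length / 3600))
  print(table(factor(x$stages, STAGES)))
  invisible(x)
}

#' Read / write hypnograms as TSV
#'
#' The on-disk format is two tab-separated columns, `epoch_index` (0-based)
#' and `stage`; a single-column stage-per-line export is also accepted on
#' read.
#'
#' @param path TSV path
#' @param hyp a [hypnogram()]
#' @param epoch_length epoch length in seconds assumed on read
#' @return a `Hypnogram` (read) or `path` (write)
#' @export
read_hypnogram_tsv <- function(path, epoch_length = 30) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) == 1) {
    stages <- df[[1]]
  } else {
    stages <- df$stage[order(df$epoch_index)]
  }
  hypnogram(stages, epoch_length = epoch_length)
}

#' @rdname read_hypnogram_tsv
#' @export
write_hypnogram_tsv <- function(hyp, path) {
  utils::write.table(
    data.frame(epoch_index = seq_along(hyp$stages) - 1L,
               stage = hyp$stages),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Sleep stage of each event
#'
#' Events are assigned the stage of the epoch containing their onset;
#' epochs are half-open intervals `[t, t + 30)`.
#'
#' @param onset_s event onset times in seconds
#' @param hyp a [hypnogram()]
#' @return character vector of stage labels
#' @export
assign_stage <- function(onset_s, hyp) {
  rel <- onset_s - hyp$start_time
  idx <- floor(rel / hyp$epoch_length) + 1L
  if (any(rel < 0 | idx > length(hyp$stages)))
    stop("event onset outside the hypnogram span")
  hyp$stages[idx]
}

#' Duration-normalised cough rate per sleep stage
#'
#' Counts the events whose onset falls in each stage and divides by that
#' stage's total duration in hours. Stages with zero duration get an
#' undefined (`NA`) rate, never 0. When a lights-off/lights-on window is
#' given, both events and epochs are restricted to it.
#'
#' @param onset_s cough onset times (s)
#' @param hyp a [hypnogram()]
#' @param lights optional `c(lights_off, lights_on)` window in seconds
#' @return a `CoughRateTable` data.frame: `stage`, `count`,
#'   `duration_h`, `rate` (coughs/h)
#' @export
cough_rate_by_stage <- function(onset_s, hyp, lights = NULL) {
  ep_start <- hyp$start_time +
    (seq_along(hyp$stages) - 1L) * hyp$epoch_length
  keep_ep <- rep(TRUE, length(hyp$stages))
  if (!is.null(lights)) {
    keep_ep <- ep_start >= lights[1] & ep_start < lights[2]
    onset_s <- onset_s[onset_s >= lights[1] & onset_s < lights[2]]
  }
  stages_kept <- hyp$stages[keep_ep]
  dur_h <- vapply(STAGES, function(s)
    sum(stages_kept == s) * hyp$epoch_length / 3600, numeric(1))
  st <- assign_stage(onset_s, hyp)
  cnt <- vapply(STAGES, function(s) sum(st == s), integer(1))
  structure(data.frame(stage = STAGES, count = cnt, duration_h = dur_h,
                       rate = ifelse(dur_h > 0, cnt / dur_h, NA_real_),
                       row.names = NULL),
            class = c("CoughRateTable", "data.frame"))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact permutation enumeration for samples of at most `exact_max` per
#' group (ties handled through average ranks), otherwise a tie-corrected
#' normal approximation with continuity correction.
#'
#' @param x,y numeric samples
#' @param exact_max largest per-group size for the exact path (default 8)
#' @return list with `statistic` (rank sum of `x`), `p_value`, `method`
#' @export
rank_sum_test <- function(x, y, exact_max = 8) {
  stopifnot(length(x) > 0, length(y) > 0)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    combos <- combn(N, n1)
    Ws <- colSums(matrix(r[combos], nrow = n1))
    dev <- abs(W - mu)
    p <- mean(abs(Ws - mu) >= dev - 1e-9)
    method <- "exact"
  } else {
    ties <- table(r)
    sigma2 <- (n1 * n2 / 12) *
      ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    dev <- W - mu
    cc <- sign(dev) * 0.5
    z <- (dev - cc) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal-approximation"
  }
  list(statistic = W, p_value = p, method = method)
}

#' Pearson, Spearman and partial correlation with p-values
#'
#' Spearman is Pearson on average ranks; partial correlation is the
#' Pearson correlation of the residuals after regressing both variables
#' on the controls, with degrees of freedom reduced accordingly. p-values
#' come from the t distribution.
#'
#' @param x,y numeric vectors (length >= 3)
#' @param method `"pearson"`, `"spearman"` or `"partial"`
#' @param controls data.frame/matrix of control variables (required for
#'   `"partial"`)
#' @return list with `R`, `p_value`, `df`, `method`
#' @export
correlate <- function(x, y, method = c("pearson", "spearman", "partial"),
                      controls = NULL) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3)
  n <- length(x)
  q <- 0
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
  } else if (method == "partial") {
    if (is.null(controls)) stop("partial correlation requires controls")
    C <- as.matrix(controls)
    q <- ncol(C)
    x <- stats::residuals(stats::lm(x ~ C))
    y <- stats::residuals(stats::lm(y ~ C))
  }
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(list(R = NA_real_, p_value = NA_real_, df = n - 2 - q,
                method = method))
  }
  R <- cor(x, y)
  df <- n - 2 - q
  t_stat <- R * sqrt(df / max(1 - R^2, .Machine$double.eps))
  p <- 2 * pt(-abs(t_stat), df)
  list(R = R, p_value = p, df = df, method = method)
}

#' Sleep-stage transitions following coughs
#'
#' For each cough, records the stage of its epoch and the stage of the
#' next epoch, aggregated into a from-to percentage table (rows sum to
#' 100). Coughs in the final epoch have no successor; they are excluded
#' from the table and counted separately.
#'
#' @param onset_s cough onset times (s)
#' @param hyp a [hypnogram()]
#' @return list with `counts` (5x5 matrix), `percent` (row percentages),
#'   `n_excluded_final`
#' @export
transition_after_cough <- function(onset_s, hyp) {
  rel <- onset_s - hyp$start_time
  idx <- floor(rel / hyp$epoch_length) + 1L
  if (any(rel < 0 | idx > length(hyp$stages)))
    stop("event onset outside the hypnogram span")
  final <- idx == length(hyp$stages)
  from <- hyp$stages[idx[!final]]
  to <- hyp$stages[idx[!final] + 1L]
  counts <- table(factor(from, STAGES), factor(to, STAGES))
  counts <- matrix(counts, 5, 5, dimnames = list(from = STAGES, to = STAGES))
  pct <- counts / pmax(rowSums(counts), 1) * 100
  list(counts = counts, percent = pct, n_excluded_final = sum(final))
}
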