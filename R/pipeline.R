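#' Split subjects into train/development/test groups
#'
#' Subject-disjoint splits with greedy balancing of per-split cough counts
#' toward the target fractions: subjects are visited in decreasing count
#' order (ties shuffled by the seed) and each goes to the split with the
#' largest remaining deficit relative to its target share.
#'
#' @param subjects subject identifiers
#' @param cough_counts per-subject cough counts (same order)
#' @param fractions target shares for train/dev/test (sum to 1)
#' @param seed RNG seed for tie shuffling
#' @return named list of subject-id vectors: `train`, `dev`, `test`
#' @export
split_subjects <- function(subjects, cough_counts,
                           fractions = c(train = 0.4, dev = 0.3,
                                         test = 0.3),
                           seed = 1) {
  stopifnot(length(subjects) == length(cough_counts),
            abs(sum(fractions) - 1) < 1e-8)
  if (length(subjects) < length(fractions))
    stop("need at least ", length(fractions), " subjects")
  set.seed(seed)
  ord <- order(cough_counts + runif(length(subjects)) * 1e-9,
               decreasing = TRUE)
  total <- sum(cough_counts) + length(subjects) * 1e-9
  load <- numeric(length(fractions))
  assign <- integer(length(subjects))
  n_assigned <- integer(length(fractions))
  for (i in ord) {
    deficit <- fractions - load / total
    # every split must receive at least one subject
    left <- length(subjects) - sum(n_assigned)
    need <- n_assigned == 0
    g <- if (sum(need) >= left) which(need)[which.max(deficit[need])]
         else which.max(deficit)
    assign[i] <- g
    load[g] <- load[g] + cough_counts[i] + 1e-9
    n_assigned[g] <- n_assigned[g] + 1L
  }
  out <- lapply(seq_along(fractions), function(g) subjects[assign == g])
  names(out) <- names(fractions) %||% c("train", "dev", "test")
  out
}

#' Label detected events against ground-truth annotations
#'
#' Each detected event takes the label of the annotation it overlaps most
#' (in seconds); events overlapping no annotation are labelled `"noise"`
#' (spurious detections behave like noise downstream).
#'
#' @param events a `SoundEvents` data.frame
#' @param annotations data.frame with `onset_s`, `offset_s`, `label`,
#'   optionally `voiced`
#' @return data.frame with `label`, `voiced`, `matched` (annotation row or
#'   `NA`) per detected event
#' @export
match_events <- function(events, annotations) {
  n <- nrow(events)
  label <- rep("noise", n)
  voiced <- rep(FALSE, n)
  matched <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    ov <- pmin(events$end_s[i], annotations$offset_s) -
      pmax(events$start_s[i], annotations$onset_s)
    j <- which.max(ov)
    if (length(j) && ov[j] > 0) {
      label[i] <- annotations$label[j]
      voiced[i] <- isTRUE(annotations$voiced[j])
      matched[i] <- j
    }
  }
  data.frame(label = label, voiced = voiced, matched = matched)
}

#' Generate, detect and featurise a multi-subject synthetic corpus
#'
#' One synthetic night per subject (seeded per subject for
#' reproducibility), run through the detector and the feature extractor.
#' Detected events are labelled by overlap with the ground-truth
#' annotations.
#'
#' @param n_subjects number of subjects
#' @param config a [synth_config()] shared by all subjects
#' @param seed base RNG seed; subject `i` uses `seed + i`
#' @param A detector threshold factor (see [compute_thresholds()])
#' @return list with `features` (matrix), `labels`, `subjects`, `events`
#'   (per-subject detected events), `nights` summary (annotation counts),
#'   `hypnograms`
#' @export
build_corpus <- function(n_subjects, config = synth_config(), seed = 1,
                         A = 100) {
  feats <- list(); labs <- list(); subj <- list()
  events_by_subject <- list(); hyps <- list(); ann_counts <- list()
  for (i in seq_len(n_subjects)) {
    set.seed(seed + i)
    night <- generate_night(config)
    rec <- recording(night$samples, night$sample_rate,
                     subject_id = sprintf("S%02d", i))
    ev <- detect_recording(rec, A = A)
    id <- sprintf("S%02d", i)
    events_by_subject[[id]] <- ev
    hyps[[id]] <- night$hypnogram
    ann_counts[[id]] <- table(factor(night$annotations$label,
                                     c("cough", "snore", "noise")))
    if (nrow(ev) == 0) next
    m <- match_events(ev, night$annotations)
    feats[[id]] <- extract_feature_matrix(ev, night$sample_rate)
    labs[[id]] <- m$label
    subj[[id]] <- rep(id, nrow(ev))
  }
  list(features = do.call(rbind, feats),
       labels = unlist(labs, use.names = FALSE),
       subjects = unlist(subj, use.names = FALSE),
       events = events_by_subject,
       annotation_counts = ann_counts,
       hypnograms = hyps)
}

#' Default pipeline configuration
#'
#' All detection/training constants at their reference operating points:
#' 20 ms frames with 50% overlap, histogram tail fraction `B = 0.08`,
#' duration filter 0.15–1.1 s, part-1 window 0.079 s, voiced threshold
#' 0.45, GMM orders (1, 1, 16), Adam at 5e-6 with batch 32 for 250
#' epochs, LLR operating thresholds 1.17 (GMM) and -2.22 (network).
#'
#' @param n_subjects,synth synthetic-corpus settings
#' @param classifier `"gmm"`, `"dnn"` or `"both"`
#' @param fractions train/dev/test subject shares
#' @param seed master seed
#' @param A detector threshold factor
#' @param gmm_threshold,dnn_threshold fixed LLR operating thresholds;
#'   `NULL` selects the J-optimal threshold on the development split
#' @param dnn_epochs override for quick smoke runs
#' @return a `PipelineConfig` list
#' @export
pipeline_config <- function(n_subjects = 6, synth = synth_config(),
                            classifier = "both",
                            fractions = c(train = 0.4, dev = 0.3,
                                          test = 0.3),
                            seed = 1, A = 100,
                            gmm_threshold = NULL, dnn_threshold = NULL,
                            dnn_epochs = 250) {
  structure(list(n_subjects = n_subjects, synth = synth,
                 classifier = classifier, fractions = fractions,
                 seed = seed, A = A,
                 gmm_threshold = gmm_threshold,
                 dnn_threshold = dnn_threshold,
                 dnn_epochs = dnn_epochs),
            class = "PipelineConfig")
}

#' Run the full synthetic end-to-end pipeline
#'
#' Generates the corpus, splits subjects, trains the requested
#' classifier(s) on the training split, picks the J-optimal LLR threshold
#' on the development split (unless a fixed threshold is configured) and
#' reports test-split metrics. When `out_dir` is given, features, scores,
#' metrics and a manifest (config hash, seed, package version) are
#' written there; a rerun with the same config is bit-identical.
#'
#' @param config a [pipeline_config()]
#' @param out_dir optional output directory
#' @return list with `corpus`, `splits`, and per-classifier `models`,
#'   `thresholds`, `scores`, `metrics`
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  corpus <- build_corpus(config$n_subjects, config$synth,
                         seed = config$seed, A = config$A)
  if (is.null(corpus$features) || nrow(corpus$features) == 0 ||
      sum(corpus$labels == "cough") == 0) {
    message("no (cough) events detected; evaluation skipped")
    return(list(corpus = corpus, splits = NULL, results = list()))
  }
  subj_ids <- unique(corpus$subjects)
  counts <- vapply(subj_ids, function(s)
    sum(corpus$labels == "cough" & corpus$subjects == s), numeric(1))
  splits <- split_subjects(subj_ids, counts, config$fractions,
                           seed = config$seed)
  part <- function(ids) corpus$subjects %in% ids
  tr <- part(splits$train); de <- part(splits$dev); te <- part(splits$test)
  X <- corpus$features; y <- corpus$labels
  results <- list()
  want <- if (config$classifier == "both") c("gmm", "dnn")
          else config$classifier
  for (clf in want) {
    if (clf == "gmm") {
      model <- train_gmm_system(X[tr, ], y[tr], seed = config$seed)
      sc_dev <- gmm_llr(model, X[de, ])
      sc_te <- gmm_llr(model, X[te, ])
      fixed <- config$gmm_threshold
    } else {
      model <- train_dnn(X[tr, ], y[tr],
                         config = dnn_config(epochs = config$dnn_epochs,
                                             seed = config$seed))
      sc_dev <- dnn_llr(model, X[de, ])
      sc_te <- dnn_llr(model, X[te, ])
      fixed <- config$dnn_threshold
    }
    thr <- fixed %||%
      j_optimal_threshold(sc_dev, y[de] == "cough")$threshold
    m <- metrics_from_confusion(
      confusion_matrix(sc_te > thr, y[te] == "cough"))
    curves <- roc_pr_curves(sc_te, y[te] == "cough")
    results[[clf]] <- list(model = model, threshold = thr,
                           dev_scores = sc_dev, test_scores = sc_te,
                           metrics = m, roc_auc = curves$roc_auc,
                           pr_auc = curves$pr_auc)
  }
  out <- list(corpus = corpus, splits = splits, results = results)
  if (!is.null(out_dir)) .write_pipeline_artifacts(out, config, out_dir)
  out
}

.write_pipeline_artifacts <- function(out, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_features_csv(out$corpus$features,
                     file.path(out_dir, "features.csv"))
  write.csv(data.frame(subject = out$corpus$subjects,
                       label = out$corpus$labels),
            file.path(out_dir, "labels.csv"), row.names = FALSE)
  for (clf in names(out$results)) {
    r <- out$results[[clf]]
    write.csv(data.frame(score = r$test_scores),
              file.path(out_dir, paste0("scores_", clf, ".csv")),
              row.names = FALSE)
    jsonlite::write_json(
      list(threshold = r$threshold, metrics = unclass(r$metrics),
           roc_auc = r$roc_auc, pr_auc = r$pr_auc),
      file.path(out_dir, paste0("metrics_", clf, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  cfg_json <- jsonlite::toJSON(
    list(seed = config$seed, n_subjects = config$n_subjects,
         classifier = config$classifier, A = config$A,
         fractions = config$fractions,
         synth = config$synth[!vapply(config$synth, is.null, logical(1))]),
    auto_unbox = TRUE, digits = NA)
  cfg_path <- file.path(out_dir, "config.json")
  writeLines(cfg_json, cfg_path)
  manifest <- list(
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("noctcough")),
    artifact_md5 = as.list(tools::md5sum(
      list.files(out_dir, full.names = TRUE,
                 pattern = "\\.(csv|json)$"))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
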