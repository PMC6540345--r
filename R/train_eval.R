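# Cross-validated and hold-out training/evaluation of the classifier on
# MFM datasets, one independent binary run per affective dimension.

local_seed <- function(seed, code) {
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old))
  set.seed(seed)
  code
}

#' Split indices into k balanced folds
#'
#' A seeded random permutation of `1:n` dealt into `k` disjoint sets whose
#' sizes differ by at most one.
#'
#' @param n Dataset size (`n >= k`).
#' @param k Number of folds.
#' @param seed Integer seed; the split is deterministic given it.
#' @return List of `k` integer index vectors partitioning `1:n`.
#' @export
#' @examples
#' lengths(kfold_split(11, 10, seed = 1))
kfold_split <- function(n, k = 10, seed = 1L) {
  if (n < k) stop("n must be at least k", call. = FALSE)
  perm <- local_seed(seed, sample.int(n))
  fold_of <- rep_len(seq_len(k), n)  # sizes differ by <= 1
  unname(split(perm, fold_of))
}

#' Stratified train/validation/test split
#'
#' Within each label, indices are shuffled and allocated to the three sets
#' in the given proportions (largest-remainder rounding, remainder to the
#' training set).
#'
#' @param labels Vector of class labels, one per sample.
#' @param proportions Length-3 nonnegative weights for train/val/test,
#'   summing to 1 after normalization (default 8:1:1).
#' @param seed Integer seed.
#' @param min_per_label Minimum samples required per label.
#' @return List of integer index vectors `train`, `val`, `test`.
#' @export
holdout_split <- function(labels, proportions = c(8, 1, 1) / 10, seed = 1L,
                          min_per_label = 10L) {
  stopifnot(length(proportions) == 3L, all(proportions >= 0))
  proportions <- proportions / sum(proportions)
  cnt <- table(labels)
  if (any(cnt < min_per_label))
    stop("label(s) too rare for a stratified split: ",
         paste(names(cnt)[cnt < min_per_label], collapse = ", "),
         call. = FALSE)
  out <- list(train = integer(), val = integer(), test = integer())
  for (lv in names(cnt)) {
    idx <- which(labels == lv)
    idx <- local_seed(seed + match(lv, names(cnt)), sample(idx))
    nl <- length(idx)
    n_val <- floor(nl * proportions[2])
    n_test <- floor(nl * proportions[3])
    n_train <- nl - n_val - n_test
    out$train <- c(out$train, idx[seq_len(n_train)])
    out$val <- c(out$val, idx[n_train + seq_len(n_val)])
    out$test <- c(out$test, idx[n_train + n_val + seq_len(n_test)])
  }
  out
}

#' Evaluation protocol
#'
#' @param mode `"kfold"` or `"holdout"`.
#' @param dimension Affective dimension to classify: `"arousal"`,
#'   `"valence"` or `"dominance"`.
#' @param k Folds for `"kfold"` (protocol default 10).
#' @param proportions Train/val/test weights for `"holdout"` (default
#'   8:1:1).
#' @param epochs,batch_size Training schedule per fold (protocol defaults
#'   400 and 40).
#' @param seed Shuffle seed for the split.
#' @param group_by_trial Assign whole trials to folds (leakage-safe
#'   variant); default `FALSE` splits by segment, so segments of one
#'   trial may land in different folds, matching the pooled sample-level
#'   protocol.
#' @return An `eval_protocol` list.
#' @export
eval_protocol <- function(mode = c("kfold", "holdout"),
                          dimension = c("arousal", "valence", "dominance"),
                          k = 10, proportions = c(8, 1, 1) / 10,
                          epochs = 400, batch_size = 40, seed = 1L,
                          group_by_trial = FALSE) {
  mode <- match.arg(mode)
  dimension <- match.arg(dimension)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  structure(list(mode = mode, dimension = dimension, k = k,
                 proportions = proportions, epochs = epochs,
                 batch_size = batch_size, seed = as.integer(seed),
                 group_by_trial = group_by_trial),
            class = "eval_protocol")
}

mfm_labels <- function(mfms, dimension) {
  col <- paste0(dimension, "_label")
  if (!col %in% names(mfms$meta))
    stop("mfm_set metadata lacks ", col, call. = FALSE)
  mfms$meta[[col]]
}

#' Accuracy and confusion counts of a trained model
#'
#' @param model A trained `capsnet`.
#' @param mfms MFMs (array or `mfm_set`).
#' @param labels Binary labels (0/1), one per MFM.
#' @return List with `accuracy`, `confusion` (named counts `tp`, `tn`,
#'   `fp`, `fn`, positive class = 1) and `predicted`.
#' @export
evaluate_model <- function(model, mfms, labels) {
  pred <- predict(model, mfms)
  labels <- as.integer(labels)
  stopifnot(length(pred) == length(labels))
  list(accuracy = mean(pred == labels),
       confusion = c(tp = sum(pred == 1L & labels == 1L),
                     tn = sum(pred == 0L & labels == 0L),
                     fp = sum(pred == 1L & labels == 0L),
                     fn = sum(pred == 0L & labels == 1L)),
       predicted = pred)
}

#' Cross-validated (or hold-out) training and evaluation
#'
#' For `"kfold"`, trains a freshly initialized model per fold on the
#' remaining folds and scores the held-out fold; for `"holdout"`, trains
#' once on the stratified training set and scores the test set. A fold
#' whose training data contains a single class is skipped with a warning.
#'
#' @param mfms An `mfm_set` (or `list(mfm = array, meta = data.frame)`).
#' @param cfg A [capsnet_config()]; each fold's model is reinitialized
#'   from a fold-specific seed derived from it.
#' @param protocol An [eval_protocol()].
#' @param labels Optional explicit 0/1 labels overriding the metadata
#'   column of `protocol$dimension`.
#' @param verbose Print per-fold progress.
#' @return An `eval_result`: list with `fold_accuracy`, `mean_accuracy`,
#'   `confusion` (summed counts), `folds` (index sets), `protocol`,
#'   and `models` omitted to keep results light.
#' @export
run_cv <- function(mfms, cfg, protocol = eval_protocol(), labels = NULL,
                   verbose = FALSE) {
  stopifnot(inherits(cfg, "capsnet_config"))
  if (is.null(labels)) labels <- mfm_labels(mfms, protocol$dimension)
  labels <- as.integer(labels)
  X <- as_input_matrix(mfms, cfg$input_side)
  n <- nrow(X)
  stopifnot(length(labels) == n, n > 0L)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present", call. = FALSE)
  if (protocol$mode == "holdout") {
    sp <- holdout_split(labels, protocol$proportions, protocol$seed)
    folds <- list(sp$test)
    train_sets <- list(sp$train)
  } else if (protocol$group_by_trial) {
    key <- interaction(mfms$meta$subject_id, mfms$meta$trial_id, drop = TRUE)
    tf <- kfold_split(nlevels(key), protocol$k, protocol$seed)
    folds <- lapply(tf, function(f) which(as.integer(key) %in% f))
    train_sets <- lapply(folds, function(f) setdiff(seq_len(n), f))
  } else {
    folds <- kfold_split(n, protocol$k, protocol$seed)
    train_sets <- lapply(folds, function(f) setdiff(seq_len(n), f))
  }
  acc <- rep(NA_real_, length(folds))
  conf <- c(tp = 0L, tn = 0L, fp = 0L, fn = 0L)
  for (f in seq_along(folds)) {
    tr <- train_sets[[f]]
    te <- folds[[f]]
    if (length(unique(labels[tr])) < 2L) {
      warning(sprintf("fold %d skipped: single-class training set", f))
      next
    }
    fold_cfg <- cfg
    fold_cfg$seed <- cfg$seed + f
    model <- capsnet_init(fold_cfg)
    model <- capsnet_train(model, X[tr, , drop = FALSE], labels[tr],
                           epochs = protocol$epochs,
                           batch_size = protocol$batch_size)
    ev <- evaluate_model(model, X[te, , drop = FALSE], labels[te])
    acc[f] <- ev$accuracy
    conf <- conf + ev$confusion
    if (verbose)
      message(sprintf("fold %d/%d: accuracy %.4f", f, length(folds), acc[f]))
  }
  structure(list(fold_accuracy = acc,
                 mean_accuracy = mean(acc, na.rm = TRUE),
                 confusion = conf, folds = folds, protocol = protocol),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %s on %s: mean accuracy %.4f over %d fold(s)\n",
              x$protocol$mode, x$protocol$dimension, x$mean_accuracy,
              sum(!is.na(x$fold_accuracy))))
  invisible(x)
}
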