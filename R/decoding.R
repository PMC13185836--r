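#' Undersample the majority class
#'
#' Balances Hit/Miss labels by randomly retaining majority-class trials
#' to match the minority class size (uniform, without replacement,
#' seeded). With fewer than `min_per_class` trials in either class the
#' session cannot support 4-fold decoding and is flagged skipped.
#'
#' @param labels logical or 0/1 vector (1 = Hit).
#' @param seed integer seed.
#' @param min_per_class minimum class size for decoding (4, one per
#'   outer fold).
#' @return list with `idx` (sorted retained indices), `skipped`
#'   (logical) and `reason`.
#' @export
balance_classes <- function(labels, seed = NULL, min_per_class = 4) {
  y <- as.integer(as.logical(labels))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (min(n1, n0) < min_per_class) {
    return(list(idx = integer(), skipped = TRUE,
                reason = sprintf("minority class has %d < %d trials",
                                 min(n1, n0), min_per_class)))
  }
  m <- min(n1, n0)
  idx <- with_rng_seed(seed, {
    keep1 <- which(y == 1)
    keep0 <- which(y == 0)
    if (n1 > m) keep1 <- sort(sample(keep1, m))
    if (n0 > m) keep0 <- sort(sample(keep0, m))
    sort(c(keep1, keep0))
  })
  list(idx = idx, skipped = FALSE, reason = NA_character_)
}

# Fit L2-penalized logistic models over the C grid and return validation
# accuracy for each C.  glmnet's lambda maps to scikit-learn-style C as
# lambda = 1 / (n_train * C).
ridge_logistic_path <- function(X, y, C_grid, X_new) {
  keep <- which(apply(X, 2, function(col) stats::sd(col) > 0))
  n <- nrow(X)
  lambdas <- 1 / (n * C_grid)
  ord <- order(lambdas, decreasing = TRUE)
  if (length(keep) == 0) {
    p <- rep(mean(y), nrow(X_new))
    return(matrix(p, nrow = nrow(X_new), ncol = length(C_grid)))
  }
  Xk <- X[, keep, drop = FALSE]
  if (ncol(Xk) == 1) Xk <- cbind(Xk, 0) # glmnet needs >= 2 columns
  Xn <- X_new[, keep, drop = FALSE]
  if (ncol(Xn) == 1) Xn <- cbind(Xn, 0)
  # small folds are routine here; glmnet's small-class warning is noise
  fit <- withCallingHandlers(
    glmnet::glmnet(Xk, y, family = "binomial", alpha = 0,
                   lambda = lambdas[ord], standardize = FALSE),
    warning = function(w) {
      if (grepl("fewer than 8\\s+observations", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  pr <- stats::predict(fit, newx = Xn, s = lambdas, type = "response")
  matrix(as.numeric(pr), nrow = nrow(X_new), ncol = length(C_grid))
}

# Nested cross-validated ridge logistic classification of one design
# matrix.  Outer stratified k-fold; inner stratified CV on each training
# split selects C from the grid; test-fold predictions are pooled.
# shuffle = TRUE permutes the training labels within each outer fold
# (the test labels stay intact), giving the chance-level baseline under
# identical folds.
cv_logistic <- function(X, y, C_grid = c(1e-4, 1e-3, 1e-2, 0.1, 1),
                        outer_folds = 4, inner_folds = 3,
                        fold = NULL, seed = NULL, shuffle = FALSE) {
  n <- length(y)
  if (is.null(fold)) fold <- stratified_folds(y, outer_folds, seed)
  pred <- rep(NA_integer_, n)
  chosen <- numeric(outer_folds)
  for (k in seq_len(outer_folds)) {
    tr <- which(fold != k); te <- which(fold == k)
    y_tr <- y[tr]
    if (shuffle) {
      y_tr <- with_rng_seed(child_seed(seed, paste0("shuf", k)),
                            sample(y_tr))
    }
    acc <- matrix(NA_real_, inner_folds, length(C_grid))
    ifold <- stratified_folds(y_tr, inner_folds,
                              child_seed(seed, paste0("inner", k)))
    for (ik in seq_len(inner_folds)) {
      itr <- which(ifold != ik); ite <- which(ifold == ik)
      if (length(unique(y_tr[itr])) < 2 || length(ite) == 0) next
      p <- ridge_logistic_path(X[tr[itr], , drop = FALSE], y_tr[itr],
                               C_grid, X[tr[ite], , drop = FALSE])
      acc[ik, ] <- colMeans((p > 0.5) == y_tr[ite])
    }
    mean_acc <- colMeans(acc, na.rm = TRUE)
    # ties break toward stronger regularization (smaller C)
    best <- if (all(is.nan(mean_acc))) 1L else which.max(mean_acc)
    chosen[k] <- C_grid[best]
    if (length(unique(y_tr)) < 2) {
      pred[te] <- as.integer(mean(y_tr) > 0.5)
    } else {
      p <- ridge_logistic_path(X[tr, , drop = FALSE], y_tr,
                               C_grid[best], X[te, , drop = FALSE])
      pred[te] <- as.integer(p[, 1] > 0.5)
    }
  }
  list(pred = pred, fold = fold, chosen_C = chosen)
}

decode_metrics <- function(pred, y) {
  c(accuracy = mean(pred == y),
    hit_accuracy = if (any(y == 1)) mean(pred[y == 1] == 1) else NA_real_,
    miss_error = if (any(y == 0)) mean(pred[y == 0] == 1) else NA_real_)
}

#' Frame-by-frame decoding of trial detection (Hit vs Miss)
#'
#' For every imaging frame of the aligned window, trains an L2-penalized
#' logistic regression on the population's single-frame activity (one
#' scalar per neuron per trial) to classify Hit vs Miss, using outer
#' 4-fold stratified cross-validation with an inner cross-validated
#' choice of the regularization strength C from
#' \{1e-4, 1e-3, 1e-2, 0.1, 1\}. Classes are balanced beforehand by
#' random undersampling of the majority class. For every frame a second
#' model is trained on label-shuffled training data with identical folds,
#' giving the chance-level baseline. Test-fold predictions are pooled to
#' per-frame rates: overall accuracy, Hit accuracy (P(pred Hit | Hit))
#' and Miss error (P(pred Hit | Miss)).
#'
#' @param at an `aligned_tensor`.
#' @param neurons optional neuron index vector (e.g. a cell-type
#'   restriction); default all non-excluded neurons.
#' @param feature `"dff"` (default) decodes raw dF/F values; `"z"` uses
#'   z-scores.
#' @param frames which frames of the aligned window to decode (indices
#'   1..window length); default all.
#' @param C_grid,outer_folds,inner_folds cross-validation settings.
#' @param seed integer seed governing undersampling, folds and shuffles.
#' @param n_shuffles how many independent label permutations to average
#'   for the chance-level baseline (more permutations give a less noisy
#'   estimate of the same quantity).
#' @return an object of class `decoding_result`: list with `frames`
#'   (tibble: `frame`, `rel_frame` (0 = onset), `time_ms`, `accuracy`,
#'   `hit_accuracy`, `miss_error`, `shuffled_accuracy`,
#'   `shuffled_hit_accuracy`, `shuffled_miss_error`), `window`, `folds`,
#'   `trial_idx` (retained trials), `n_trials`, `skipped`, `reason`.
#' @seealso [window_accuracy()], [decode_celltype()]
#' @export
decode_frames <- function(at, neurons = NULL,
                          feature = c("dff", "z"), frames = NULL,
                          C_grid = c(1e-4, 1e-3, 1e-2, 0.1, 1),
                          outer_folds = 4, inner_folds = 3, seed = 1,
                          n_shuffles = 1) {
  feature <- match.arg(feature)
  neurons <- neurons %||% which(!at$neurons$excluded)
  assert_that(length(neurons) >= 1, "empty neuron restriction")
  wlen <- dim(at$z)[3]
  frames <- frames %||% seq_len(wlen)

  rows <- which(at$meta$trial_type == "go" & at$meta$included &
                  at$meta$outcome %in% c("hit", "miss"))
  y_all <- as.integer(at$meta$outcome[rows] == "hit")
  bal <- balance_classes(y_all, seed = child_seed(seed, "balance"))
  if (bal$skipped) {
    return(structure(list(frames = tibble::tibble(), skipped = TRUE,
                          reason = bal$reason, window = at$window),
                     class = "decoding_result"))
  }
  rows <- rows[bal$idx]
  y <- y_all[bal$idx]
  feat <- if (feature == "dff") at$dff else at$z
  fr <- at$window$frame_rate_hz

  fold <- stratified_folds(y, outer_folds, child_seed(seed, "folds"))
  res <- purrr::map_dfr(frames, function(f) {
    X <- feat[rows, neurons, f, drop = FALSE]
    dim(X) <- c(length(rows), length(neurons))
    X[is.na(X)] <- 0
    true <- cv_logistic(X, y, C_grid, outer_folds, inner_folds,
                        fold = fold, seed = child_seed(seed, paste0("f", f)))
    ms_all <- sapply(seq_len(n_shuffles), function(r) {
      shuf <- cv_logistic(X, y, C_grid, outer_folds, inner_folds,
                          fold = fold,
                          seed = child_seed(seed, paste0("f", f, "r", r)),
                          shuffle = TRUE)
      decode_metrics(shuf$pred, y)
    })
    m <- decode_metrics(true$pred, y)
    ms <- rowMeans(ms_all)
    tibble::tibble(frame = f, rel_frame = f - at$window$pre - 1L,
                   time_ms = (f - at$window$pre - 1L) * 1000 / fr,
                   accuracy = m["accuracy"],
                   hit_accuracy = m["hit_accuracy"],
                   miss_error = m["miss_error"],
                   shuffled_accuracy = ms["accuracy"],
                   shuffled_hit_accuracy = ms["hit_accuracy"],
                   shuffled_miss_error = ms["miss_error"])
  })
  structure(list(frames = res, window = at$window, folds = fold,
                 trial_idx = at$meta$trial_idx[rows], n_trials = length(y),
                 skipped = FALSE, reason = NA_character_),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  if (isTRUE(x$skipped)) {
    cat(sprintf("<decoding_result> skipped: %s\n", x$reason))
    return(invisible(x))
  }
  cat(sprintf("<decoding_result> %d frames, %d balanced trials\n",
              nrow(x$frames), x$n_trials))
  st <- try(window_accuracy(x, "stimulation"), silent = TRUE)
  if (!inherits(st, "try-error")) {
    cat(sprintf("  stimulation-window accuracy %.3f (shuffled %.3f)\n",
                st, window_accuracy(x, "stimulation", shuffled = TRUE)))
  }
  invisible(x)
}

#' Cell-type-restricted decoding
#'
#' Runs [decode_frames()] on the subset of neurons of one cell type.
#'
#' @param at an `aligned_tensor`.
#' @param celltype `"pyr"` or `"inh"`.
#' @param min_neurons minimum population size after restriction.
#' @param ... forwarded to [decode_frames()].
#' @return a `decoding_result`.
#' @export
decode_celltype <- function(at, celltype, min_neurons = 2, ...) {
  idx <- which(at$neurons$celltype == celltype & !at$neurons$excluded)
  assert_that(length(idx) >= min_neurons,
              "only %d %s neurons; need >= %d", length(idx), celltype,
              min_neurons)
  decode_frames(at, neurons = idx, ...)
}

#' Decoding from mean stimulation-window activity
#'
#' Single-window variant: one classifier on the per-trial, per-neuron
#' mean z-score over valid stimulation frames (rather than one model per
#' frame). Used for pooled summaries of stimulus-period information.
#'
#' @param at an `aligned_tensor`.
#' @param neurons optional neuron restriction.
#' @param seed,C_grid,outer_folds,inner_folds as in [decode_frames()].
#' @return one-row tibble with `accuracy`, `hit_accuracy`, `miss_error`,
#'   shuffled analogues, and `n_trials`.
#' @export
decode_window_mean <- function(at, neurons = NULL, seed = 1,
                               C_grid = c(1e-4, 1e-3, 1e-2, 0.1, 1),
                               outer_folds = 4, inner_folds = 3) {
  neurons <- neurons %||% which(!at$neurons$excluded)
  m <- trial_mean_stim_z(at)
  rows <- which(at$meta$trial_type == "go" & at$meta$included &
                  at$meta$outcome %in% c("hit", "miss"))
  y_all <- as.integer(at$meta$outcome[rows] == "hit")
  bal <- balance_classes(y_all, seed = child_seed(seed, "balance"))
  assert_that(!bal$skipped, "too few trials per class: %s", bal$reason)
  rows <- rows[bal$idx]; y <- y_all[bal$idx]
  X <- m[rows, neurons, drop = FALSE]
  X[is.na(X)] <- 0
  fold <- stratified_folds(y, outer_folds, child_seed(seed, "folds"))
  true <- cv_logistic(X, y, C_grid, outer_folds, inner_folds, fold = fold,
                      seed = child_seed(seed, "w"))
  shuf <- cv_logistic(X, y, C_grid, outer_folds, inner_folds, fold = fold,
                      seed = child_seed(seed, "w"), shuffle = TRUE)
  m1 <- decode_metrics(true$pred, y); m2 <- decode_metrics(shuf$pred, y)
  tibble::tibble(accuracy = m1["accuracy"], hit_accuracy = m1["hit_accuracy"],
                 miss_error = m1["miss_error"],
                 shuffled_accuracy = m2["accuracy"],
                 shuffled_hit_accuracy = m2["hit_accuracy"],
                 shuffled_miss_error = m2["miss_error"],
                 n_trials = length(y))
}

#' Average decoding accuracy over a time window
#'
#' @param result a `decoding_result`.
#' @param window `"stimulation"` (0-500 ms after onset), `"prestim"`
#'   (the 200 ms before onset), or a numeric length-2 range in ms
#'   (half-open, relative to onset).
#' @param measure which per-frame column to average (default
#'   `"accuracy"`; e.g. `"hit_accuracy"`, `"miss_error"`).
#' @param shuffled average the shuffled-label analogue instead.
#' @return scalar mean over the frames inside the window.
#' @export
window_accuracy <- function(result, window = "stimulation",
                            measure = "accuracy", shuffled = FALSE) {
  fr <- result$window$frame_rate_hz
  f <- result$frames
  sel <- if (is.numeric(window)) {
    f$time_ms >= window[1] & f$time_ms < window[2]
  } else if (window == "stimulation") {
    f$rel_frame >= 0 & f$rel_frame < result$window$stim
  } else if (window == "prestim") {
    npre <- round(0.2 * fr)
    f$rel_frame >= -npre & f$rel_frame < 0
  } else {
    stopf("unknown window '%s'", window)
  }
  assert_that(any(sel), "no decoded frames inside the requested window")
  col <- if (shuffled) paste0("shuffled_", measure) else measure
  mean(f[[col]][sel])
}
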