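#' Temporal voting parameters
#'
#' The voting window at frame `t` covers frames `max(0, t-k)` to
#' `min(n-1, t+k)` (truncated at the sequence ends, no padding). The voted
#' label is 1 iff the number of raw climbing labels in the window strictly
#' exceeds `vote_fraction` times the window size; the default 0.5 is a strict
#' majority. The window removes isolated single-frame detections and heals
#' single-frame gaps that would otherwise split a long bout.
#'
#' @param half_width window half-width `k` in frames (>= 0).
#' @param vote_fraction fraction in (0, 1] of the window that must be
#'   climbing.
#' @return An object of class `voting_params`.
#' @export
voting_params <- function(half_width = 0, vote_fraction = 0.5) {
  if (half_width < 0) stop("half_width must be >= 0")
  if (vote_fraction <= 0 || vote_fraction > 1)
    stop("vote_fraction must be in (0, 1]")
  structure(list(half_width = as.integer(half_width),
                 vote_fraction = vote_fraction),
            class = "voting_params")
}

as_sample_matrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (is(x, "dgCMatrix")) return(x)
  if (!is(x, "Matrix")) x <- Matrix::Matrix(as.matrix(x), sparse = TRUE)
  as(as(as(x, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}

#' Train the linear max-margin frame classifier
#'
#' Minimizes L2-regularized hinge loss at strength `C` (an L1-loss linear
#' support vector machine, solved in the dual by coordinate descent; the bias
#' enters as a regularized constant feature). The raw prediction for a frame
#' is 1 iff `weights . x + bias > 0`; a frame exactly on the decision
#' boundary is classified non-climbing.
#'
#' @param x feature matrix, frames in rows (dense or `dgCMatrix`).
#' @param y binary frame labels (0/1), one per row of `x`.
#' @param C positive regularization strength.
#' @param voting a [voting_params()] stored with the model and used by
#'   [predict_labels()].
#' @param class_weights optional named vector `c("0" = w0, "1" = w1)` scaling
#'   the per-class misclassification cost (default unweighted).
#' @param max_epochs,tol solver budget and duality-gap style stopping
#'   tolerance on the projected gradient spread.
#' @return An object of class `climb_model` with elements `weights`, `bias`,
#'   `C`, `voting`.
#' @export
svm_train <- function(x, y, C = 1, voting = voting_params(),
                      class_weights = NULL, max_epochs = 200, tol = 1e-3) {
  x <- as_sample_matrix(x)
  y <- as.integer(y)
  if (length(y) != nrow(x)) stop("labels not aligned with features")
  if (length(unique(y)) < 2)
    stop("training labels are single-class; need both climbing and non-climbing examples")
  if (C <= 0) stop("C must be positive")
  ys <- ifelse(y == 1, 1, -1)
  cost <- rep(C, length(ys))
  if (!is.null(class_weights)) {
    cost[y == 0] <- C * class_weights[["0"]]
    cost[y == 1] <- C * class_weights[["1"]]
  }
  xt <- Matrix::t(x)  # features x samples; columns are samples
  fit <- svm_dcd_cpp(xt@p, xt@i, xt@x, nrow(xt), ncol(xt), ys, cost,
                     as.integer(max_epochs), tol, 12345L)
  structure(list(weights = fit$w, bias = fit$b, C = C, voting = voting,
                 converged = fit$converged, epochs = fit$epochs),
            class = "climb_model")
}

#' @export
print.climb_model <- function(x, ...) {
  cat(sprintf("<climb_model> %d-dim linear decision function, C = %g, voting k = %d, theta = %g\n",
              length(x$weights), x$C, x$voting$half_width,
              x$voting$vote_fraction))
  invisible(x)
}

#' Raw per-frame predictions
#'
#' @param model a `climb_model`.
#' @param x feature matrix, frames in rows.
#' @return Integer 0/1 vector, one label per frame: 1 iff
#'   `weights . x + bias > 0`.
#' @export
predict_raw <- function(model, x) {
  x <- as_sample_matrix(x)
  if (ncol(x) != length(model$weights))
    stop("feature dimension does not match the model")
  as.integer(as.numeric(x %*% model$weights) + model$bias > 0)
}

#' Temporal voting over raw frame labels
#'
#' @param raw binary (0/1) label sequence.
#' @param voting a [voting_params()].
#' @return Voted 0/1 sequence of the same length: `out[t] = 1` iff the sum of
#'   raw labels over the truncated window strictly exceeds
#'   `vote_fraction * window size`.
#' @export
temporal_vote <- function(raw, voting = voting_params()) {
  n <- length(raw)
  if (n == 0) stop("empty label sequence")
  k <- voting$half_width
  if (k == 0) return(as.integer(raw))
  cs <- c(0, cumsum(raw))
  t <- seq_len(n)
  lo <- pmax(t - k, 1L)
  hi <- pmin(t + k, n)
  sums <- cs[hi + 1] - cs[lo]
  size <- hi - lo + 1L
  as.integer(sums > voting$vote_fraction * size)
}

#' Voted predictions for a segment
#' @inheritParams predict_raw
#' @return 0/1 labels after applying the model's voting window.
#' @export
predict_labels <- function(model, x) {
  temporal_vote(predict_raw(model, x), model$voting)
}

#' Default cross-validation grid
#'
#' @return Data frame of `(C, k, theta)` candidates: C in
#'   \{0.01, 0.1, 1, 10\}, k in \{0, 3, 6, 12, 25\} frames, theta 0.5.
#' @export
default_cv_grid <- function() {
  expand.grid(C = c(0.01, 0.1, 1, 10), k = c(0L, 3L, 6L, 12L, 25L),
              theta = 0.5, KEEP.OUT.ATTRS = FALSE)
}

score_metric <- function(pred, gold, metric) {
  if (metric == "accuracy") return(mean(pred == gold))
  # balanced accuracy: mean of per-class recalls present in the gold
  recalls <- c(if (any(gold == 1)) mean(pred[gold == 1] == 1),
               if (any(gold == 0)) mean(pred[gold == 0] == 0))
  mean(recalls)
}

#' Leave-one-segment-out cross-validation
#'
#' For every `(C, k, theta)` candidate and every fold, trains on all segments
#' but one, applies [predict_raw()] then [temporal_vote()] to the held-out
#' segment, and scores it with `metric`. The selected candidate maximizes the
#' fold-mean score, with ties broken toward smaller `C`, then smaller `k`,
#' then smaller `theta` (simpler, smoother models). The returned model is
#' retrained on all segments at the selected parameters. Everything is
#' deterministic: identical inputs give identical results.
#'
#' @param segments list of segments, each a list with elements `features`
#'   (frames x dim matrix) and `labels` (0/1 per frame). Each training fold
#'   must contain both classes.
#' @param grid data frame with columns `C`, `k`, `theta` (default
#'   [default_cv_grid()]).
#' @param metric `"accuracy"` (default, raw frame-by-frame accuracy) or
#'   `"balanced_accuracy"`.
#' @param ... passed to [svm_train()].
#' @return An object of class `climb_cv`: list with `grid`, `fold_table`
#'   (one row per candidate x fold), `selected` (row of `grid`), `metric`,
#'   `model` (final `climb_model`), and `heldout_raw` (per `C`, the raw
#'   held-out predictions of every fold, for out-of-sample evaluation).
#' @export
leave_one_segment_out <- function(segments, grid = default_cv_grid(),
                                  metric = c("accuracy", "balanced_accuracy"),
                                  ...) {
  metric <- match.arg(metric)
  if (length(segments) < 2) stop("need at least 2 segments for cross-validation")
  Cs <- sort(unique(grid$C))
  folds <- seq_along(segments)
  rows <- vector("list", length(folds) * nrow(grid))
  ri <- 0L
  heldout_raw <- setNames(
    rep(list(vector("list", length(folds))), length(Cs)), as.character(Cs))
  for (f in folds) {
    train_idx <- setdiff(folds, f)
    xtr <- do.call(rbind, lapply(segments[train_idx], `[[`, "features"))
    ytr <- unlist(lapply(segments[train_idx], `[[`, "labels"))
    if (length(unique(ytr)) < 2)
      stop("fold ", f, " has single-class training data")
    xte <- segments[[f]]$features
    gold <- segments[[f]]$labels
    for (C in Cs) {
      m <- svm_train(xtr, ytr, C = C, ...)
      raw <- predict_raw(m, xte)
      heldout_raw[[as.character(C)]][[f]] <- raw
      cand <- grid[grid$C == C, , drop = FALSE]
      for (g in seq_len(nrow(cand))) {
        voted <- temporal_vote(raw, voting_params(cand$k[g], cand$theta[g]))
        ri <- ri + 1L
        rows[[ri]] <- data.frame(C = C, k = cand$k[g], theta = cand$theta[g],
                                 fold = f, score = score_metric(voted, gold, metric))
      }
    }
  }
  fold_table <- do.call(rbind, rows[seq_len(ri)])
  means <- aggregate(score ~ C + k + theta, fold_table, mean)
  ord <- order(-means$score, means$C, means$k, means$theta)
  selected <- means[ord[1], c("C", "k", "theta")]
  rownames(selected) <- NULL
  xall <- do.call(rbind, lapply(segments, `[[`, "features"))
  yall <- unlist(lapply(segments, `[[`, "labels"))
  model <- svm_train(xall, yall, C = selected$C,
                     voting = voting_params(selected$k, selected$theta), ...)
  structure(list(grid = grid, fold_table = fold_table, selected = selected,
                 metric = metric, model = model, heldout_raw = heldout_raw),
            class = "climb_cv")
}

#' Held-out voted predictions at the selected parameters
#'
#' For each cross-validation fold, the raw predictions of the model trained
#' without that segment, smoothed with the selected voting window — an
#' out-of-sample label series per segment.
#'
#' @param cv a `climb_cv` result.
#' @return List of 0/1 vectors, one per segment in input order.
#' @export
heldout_predictions <- function(cv) {
  sel <- cv$selected
  lapply(cv$heldout_raw[[as.character(sel$C)]], temporal_vote,
         voting = voting_params(sel$k, sel$theta))
}

#' @export
print.climb_cv <- function(x, ...) {
  cat(sprintf("<climb_cv> %d candidates x %d folds; selected C = %g, k = %d, theta = %g (%s %.4f)\n",
              nrow(x$grid), length(unique(x$fold_table$fold)), x$selected$C,
              x$selected$k, x$selected$theta, x$metric,
              mean(x$fold_table$score[x$fold_table$C == x$selected$C &
                                      x$fold_table$k == x$selected$k &
                                      x$fold_table$theta == x$selected$theta])))
  invisible(x)
}
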