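#' Frame-level agreement metrics
#'
#' Confusion-matrix summary of predicted against gold frame labels, computed
#' with exact integer counts. The identity
#' `accuracy = prevalence * recall_climbing + (1 - prevalence) * recall_nonclimbing`
#' holds exactly on every input.
#'
#' @param pred,gold equal-length 0/1 label vectors.
#' @return List of class `frame_metrics`: `accuracy`, `recall_climbing`
#'   (fraction of gold climbing frames predicted climbing; `NA` if the gold
#'   has no climbing frames), `recall_nonclimbing`, `prevalence` (gold
#'   climbing fraction), `n_frames`.
#' @export
frame_metrics <- function(pred, gold) {
  if (length(pred) != length(gold)) stop("length mismatch between pred and gold")
  if (length(pred) == 0) stop("empty label series")
  pred <- as.integer(pred); gold <- as.integer(gold)
  n <- length(gold)
  npos <- sum(gold == 1)
  nneg <- n - npos
  tp <- sum(pred == 1 & gold == 1)
  tn <- sum(pred == 0 & gold == 0)
  structure(list(
    accuracy = (tp + tn) / n,
    recall_climbing = if (npos > 0) tp / npos else NA_real_,
    recall_nonclimbing = if (nneg > 0) tn / nneg else NA_real_,
    prevalence = npos / n,
    n_frames = n
  ), class = "frame_metrics")
}

#' @export
print.frame_metrics <- function(x, ...) {
  cat(sprintf(
    "<frame_metrics> n = %d: accuracy %.1f%% (climbing %.1f%%, non-climbing %.1f%% correct; prevalence %.1f%%)\n",
    x$n_frames, 100 * x$accuracy, 100 * x$recall_climbing,
    100 * x$recall_nonclimbing, 100 * x$prevalence))
  invisible(x)
}

spearman_pvalue <- function(rho, n, exact = FALSE, xr = NULL, yr = NULL) {
  if (exact && n <= 10) {
    # exact permutation distribution of rho under independence
    perms <- do.call(rbind, combinat_perms(n))
    rhos <- apply(perms, 1, function(p) cor(xr, yr[p]))
    return(mean(abs(rhos) >= abs(rho) - 1e-12))
  }
  if (abs(rho) >= 1) return(max(2 * pt(-Inf, n - 2), 1e-300))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  max(2 * pt(-abs(tstat), df = n - 2), 1e-300)
}

combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- combinat_perms(n - 1L)
  out <- list()
  for (p in sub) for (k in seq_len(n))
    out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  out
}

#' Time-binned agreement between automated and human annotation
#'
#' Splits two aligned frame-label series into consecutive bins of
#' `bin_length_s` seconds, converts each bin's climbing-frame count to
#' seconds, and reports Spearman's rank correlation between the automated
#' and human per-bin climbing times. Ties receive average ranks; the
#' two-sided p-value uses the asymptotic t approximation (an exact
#' permutation p is available for `n_bins <= 10` via `exact = TRUE`). A
#' trailing partial bin is dropped with a warning.
#'
#' @param pred,gold equal-length 0/1 frame-label vectors (automated, human).
#' @param bin_length_s bin length in seconds (default 300, i.e. 5 min).
#' @param frame_duration_ms frame duration (default 40 ms).
#' @param exact use the exact permutation p-value (only for `n_bins <= 10`).
#' @return List of class `bin_agreement`: `bin_length_s`, `auto_s`,
#'   `human_s` (per-bin seconds), `spearman_rho`, `n_bins`, `p_value`.
#' @export
binned_agreement <- function(pred, gold, bin_length_s = 300,
                             frame_duration_ms = 40, exact = FALSE) {
  if (length(pred) != length(gold)) stop("length mismatch between pred and gold")
  fpb <- bin_length_s * 1000 / frame_duration_ms
  if (abs(fpb - round(fpb)) > 1e-9)
    stop("bin length is not an integer number of frames")
  fpb <- as.integer(round(fpb))
  nb <- length(pred) %/% fpb
  if (nb < 3) stop("fewer than 3 complete bins")
  if (nb * fpb < length(pred))
    warning("dropping trailing partial bin", call. = FALSE)
  bin <- rep(seq_len(nb), each = fpb)
  used <- seq_len(nb * fpb)
  auto_s <- frames_to_seconds(
    tapply(as.integer(pred[used]), bin, sum), frame_duration_ms)
  human_s <- frames_to_seconds(
    tapply(as.integer(gold[used]), bin, sum), frame_duration_ms)
  rho <- suppressWarnings(cor(auto_s, human_s, method = "spearman"))
  p <- if (is.na(rho)) NA_real_ else  # constant bins: rank correlation undefined
    spearman_pvalue(rho, nb, exact = exact,
                    xr = rank(auto_s), yr = rank(human_s))
  structure(list(bin_length_s = bin_length_s,
                 auto_s = as.numeric(auto_s), human_s = as.numeric(human_s),
                 spearman_rho = rho, n_bins = nb, p_value = p),
            class = "bin_agreement")
}

#' @export
print.bin_agreement <- function(x, ...) {
  cat(sprintf("<bin_agreement> Spearman rho = %.3f over %d bins of %g s (p = %.3g)\n",
              x$spearman_rho, x$n_bins, x$bin_length_s, x$p_value))
  invisible(x)
}
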