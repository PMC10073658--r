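#' Box-Cox power transform
#'
#' `y = (x^lambda - 1) / lambda` for `lambda != 0`, `log(x)` at `lambda = 0`.
#' With `lambda = "mle"` the exponent maximizing the profile log-likelihood
#' of the normal model is chosen: a coarse scan over `[-3, 3]` brackets the
#' optimum, which is then refined by golden-section search. Values must be
#' positive; with `shift = TRUE` non-positive inputs are first shifted by
#' `1 - min(x)` (so the minimum maps to 1), with a warning.
#'
#' @param x numeric vector.
#' @param lambda numeric exponent, or `"mle"`.
#' @param shift allow shifting non-positive inputs (default `FALSE`: error).
#' @return List of class `boxcox_transform`: `y` (transformed values),
#'   `lambda`, `shift_offset` (0 when no shift was applied).
#' @export
boxcox_transform <- function(x, lambda = "mle", shift = FALSE) {
  if (!is.numeric(x) || length(x) < 2) stop("x must be a numeric vector")
  offset <- 0
  if (any(x <= 0)) {
    if (!shift) stop("non-positive values; set shift = TRUE to offset them")
    offset <- 1 - min(x)
    warning("shifting values by ", format(offset),
            " to make them positive before the Box-Cox transform",
            call. = FALSE)
    x <- x + offset
  }
  if (identical(lambda, "mle")) lambda <- boxcox_lambda_mle(x)
  y <- if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
  structure(list(y = y, lambda = lambda, shift_offset = offset),
            class = "boxcox_transform")
}

# profile log-likelihood of the normal model for the transformed data,
# intercept-only (matches MASS::boxcox with formula x ~ 1)
boxcox_loglik <- function(lambda, x, lx = log(x)) {
  y <- if (abs(lambda) < 1e-12) lx else (x^lambda - 1) / lambda
  n <- length(x)
  -n / 2 * log(mean((y - mean(y))^2)) + (lambda - 1) * sum(lx)
}

boxcox_lambda_mle <- function(x, lower = -3, upper = 3) {
  lx <- log(x)
  grid <- seq(lower, upper, by = 0.25)
  ll <- vapply(grid, boxcox_loglik, 0, x = x, lx = lx)
  k <- which.max(ll)
  lo <- grid[max(1, k - 1)]
  hi <- grid[min(length(grid), k + 1)]
  optimize(boxcox_loglik, c(lo, hi), x = x, lx = lx, maximum = TRUE)$maximum
}

#' Fit the activity linear mixed-effects model
#'
#' Fits `response ~ fixed + (day | cage)` by REML: categorical fixed effects
#' (by default the full Age x Genotype x Sex factorial, so that every cell
#' mean is estimable for the marginal-means contrasts) with a random
#' intercept per cage and a random day-of-recording slope, accounting for
#' repeated measures over the days of recording. The response is Box-Cox
#' transformed first (exponent by maximum likelihood, per response) unless
#' `transform = "none"`. If the full random structure yields a singular fit,
#' the day slope is dropped and the model refit with the cage intercept
#' only; this simplification is recorded, never hidden.
#'
#' @param data data frame with the response column, factor columns named in
#'   `fixed`, a cage column and a numeric day column.
#' @param response_col name of the response column (positive values for the
#'   Box-Cox transform).
#' @param fixed one-sided formula for the fixed effects (default
#'   `~ Age * Genotype * Sex`).
#' @param cage_col,day_col grouping and slope columns (defaults `"cage_id"`,
#'   `"day"`).
#' @param random `"day_slope"` (default: random intercept and
#'   day-of-recording slope per cage) or `"intercept"` (cage intercept only).
#' @param transform `"boxcox"` (default) or `"none"`.
#' @return Object of class `climb_lmm`: list with `fit` (a `lmerModLmerTest`
#'   fitted by REML), `lambda` (Box-Cox exponent or `NA`), `singular`,
#'   `dropped_day_slope`, `optimizer_notes` (optimizer convergence messages,
#'   captured rather than re-emitted), `formula`, `response_col`, `data`
#'   (with the transformed response in column `.y`).
#' @export
fit_lmm <- function(data, response_col, fixed = ~ Age * Genotype * Sex,
                    cage_col = "cage_id", day_col = "day",
                    random = c("day_slope", "intercept"),
                    transform = c("boxcox", "none")) {
  transform <- match.arg(transform)
  random <- match.arg(random)
  if (length(unique(data[[cage_col]])) < 2) stop("fewer than 2 cages")
  y <- data[[response_col]]
  if (sd(y) < 1e-12)
    stop("response is constant: zero residual variance, model is degenerate")
  lambda <- NA_real_
  if (transform == "boxcox") {
    bc <- boxcox_transform(y, "mle", shift = TRUE)
    y <- bc$y
    lambda <- bc$lambda
  }
  d <- data
  d$.y <- y
  rhs <- deparse(fixed[[2]])
  f_int <- as.formula(paste0(".y ~ ", rhs, " + (1 | ", cage_col, ")"))
  dropped <- FALSE
  # optimizer chatter is collected on the result, not re-emitted; singular
  # fits are flagged separately below
  notes <- character()
  quiet_lmer <- function(f) withCallingHandlers(
    suppressMessages(lmerTest::lmer(f, data = d, REML = TRUE)),
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (random == "day_slope") {
    f_full <- as.formula(paste0(".y ~ ", rhs, " + (", day_col, " | ",
                                cage_col, ")"))
    fit <- quiet_lmer(f_full)
    if (lme4::isSingular(fit, tol = 1e-4)) {
      fit <- quiet_lmer(f_int)
      dropped <- TRUE
    }
  } else {
    fit <- quiet_lmer(f_int)
  }
  structure(list(fit = fit, lambda = lambda, transform = transform,
                 singular = lme4::isSingular(fit, tol = 1e-4),
                 dropped_day_slope = dropped, optimizer_notes = notes,
                 formula = formula(fit), response_col = response_col,
                 data = d),
            class = "climb_lmm")
}

#' @export
print.climb_lmm <- function(x, ...) {
  cat(sprintf("<climb_lmm> %s; Box-Cox lambda = %s%s%s\n",
              deparse(x$formula),
              if (is.na(x$lambda)) "none" else format(x$lambda, digits = 3),
              if (x$dropped_day_slope) "; day slope dropped (singular)" else "",
              if (x$singular) "; fit singular" else ""))
  print(summary(x$fit), ...)
  invisible(x)
}

#' Fixed-effect coefficient table with Satterthwaite intervals
#'
#' @param x a [fit_lmm()] result.
#' @param level confidence level (default 0.95).
#' @return Data frame: `term`, `estimate`, `se`, `df` (Satterthwaite),
#'   `ci_lo`, `ci_hi`, `p_value`.
#' @export
lmm_coef <- function(x, level = 0.95) {
  ct <- as.data.frame(summary(x$fit)$coefficients)
  tq <- qt(1 - (1 - level) / 2, ct$df)
  data.frame(term = rownames(ct), estimate = ct$Estimate,
             se = ct$`Std. Error`, df = ct$df,
             ci_lo = ct$Estimate - tq * ct$`Std. Error`,
             ci_hi = ct$Estimate + tq * ct$`Std. Error`,
             p_value = ct$`Pr(>|t|)`, row.names = NULL)
}

#' Likelihood-ratio comparison of nested mixed models
#'
#' Refits each model by maximum likelihood (REML likelihoods are not
#' comparable across fixed-effect structures) and reports the likelihood-
#' ratio chi-square between successive models: `chisq = 2 * delta logLik`
#' on `delta parameters` degrees of freedom. Models must be nested and are
#' compared in order of increasing parameter count.
#'
#' @param ... two or more [fit_lmm()] results (or `merMod` objects) fitted to
#'   the same data.
#' @return Data frame: `model`, `n_par`, `logLik`, `chisq`, `chi_df`,
#'   `p_value` (first row has no comparison).
#' @export
compare_models <- function(...) {
  fits <- list(...)
  mods <- lapply(fits, function(f) if (inherits(f, "climb_lmm")) f$fit else f)
  ml <- lapply(mods, function(m)
    if (lme4::isREML(m)) suppressMessages(lme4::refitML(m)) else m)
  npar <- vapply(ml, function(m) attr(logLik(m), "df"), 0)
  ord <- order(npar)
  ml <- ml[ord]; npar <- npar[ord]
  ll <- vapply(ml, function(m) as.numeric(logLik(m)), 0)
  chisq <- c(NA, 2 * diff(ll))
  chi_df <- c(NA, diff(npar))
  if (any(chi_df[-1] < 0)) stop("models are not nested")
  p <- rep(NA_real_, length(ml))
  for (k in seq_along(ml)[-1]) {
    p[k] <- if (chi_df[k] == 0) {
      if (abs(chisq[k]) < 1e-8) 1 else NA_real_
    } else {
      pchisq(max(chisq[k], 0), chi_df[k], lower.tail = FALSE)
    }
  }
  data.frame(model = ord, n_par = npar, logLik = ll,
             chisq = chisq, chi_df = chi_df, p_value = p)
}

#' Estimated-marginal-means contrasts with Benjamini-Hochberg correction
#'
#' Computes estimated marginal means (least-squares means) at each level
#' combination of the `specs` factors — model-predicted means averaged with
#' equal weight over the levels of factors not in `specs` — and all pairwise
#' differences, with standard errors from the fixed-effect covariance and
#' Satterthwaite degrees of freedom. Raw p-values are adjusted by the
#' Benjamini-Hochberg step-up rule across all reported contrasts. Estimates
#' are on the model (transformed) scale. Non-estimable combinations (empty
#' cells) are reported with `NA`.
#'
#' @param x a [fit_lmm()] result.
#' @param specs factors to contrast, e.g. `~ Genotype` or `~ Genotype | Sex`
#'   (anything `emmeans` accepts).
#' @return Data frame of class `contrast_result`: contrast label (plus any
#'   `by` columns), `estimate`, `se`, `df`, `p_value`, `p_adj`, `signif`
#'   (the ns/*/**/***/**** convention).
#' @export
emmeans_contrasts <- function(x, specs = ~ Genotype) {
  fit <- if (inherits(x, "climb_lmm")) x$fit else x
  emm <- suppressMessages(emmeans::emmeans(fit, specs,
                                           lmer.df = "satterthwaite"))
  prs <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "none"))
  keep <- setdiff(names(prs), c("t.ratio", "p.value", "estimate", "SE", "df"))
  out <- prs[keep]
  out$estimate <- prs$estimate
  out$se <- prs$SE
  out$df <- prs$df
  out$p_value <- prs$p.value
  out$p_adj <- benjamini_hochberg(out$p_value)
  out$signif <- significance_stars(out$p_adj)
  class(out) <- c("contrast_result", "data.frame")
  out
}

significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' The step-up false-discovery-rate rule: with m p-values sorted ascending,
#' adjusted p of rank i is `min over j >= i of min(1, m * p_(j) / j)`,
#' returned in the original order. Adjusted values are always >= the raw
#' ones and monotone in raw-p order.
#'
#' @param p p-values in `[0, 1]` (`NA` preserved).
#' @return Adjusted p-values (delegates to [stats::p.adjust()]).
#' @export
benjamini_hochberg <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
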