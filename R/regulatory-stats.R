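#' Pair cis-sRNA and target fold-changes
#'
#' Builds the scatter behind the sRNA/target co-regulation analysis: one
#' (sRNA log2fc, target log2fc) pair per cis sRNA whose assigned target has
#' a differential-expression record. Pairs lacking either fold-change are
#' dropped with a message.
#'
#' @param calls sRNA call tibble; only cis calls are used.
#' @param cis_targets Tibble from [assign_cis_targets()].
#' @param de_results DE tibble containing both sRNA and target features.
#' @return A tibble with `srna_id`, `srna_log2fc`, `target_locus`,
#'   `target_log2fc`.
#' @export
pair_fold_changes <- function(calls, cis_targets, de_results) {
  cis <- calls[calls$mode == "cis", , drop = FALSE]
  abort_if(anyDuplicated(cis$id) > 0, "duplicate sRNA ids")
  i <- match(cis$id, cis_targets$srna_id)
  pairs <- tibble::tibble(
    srna_id = cis$id,
    srna_log2fc = de_results$log2fc[match(cis$id, de_results$feature)],
    target_locus = cis_targets$target_locus[i],
    target_log2fc = de_results$log2fc[
      match(cis_targets$target_locus[i], de_results$feature)])
  ok <- complete.cases(pairs)
  if (any(!ok))
    message(sprintf("dropping %d cis sRNA(s) without paired fold-changes",
                    sum(!ok)))
  pairs[ok, , drop = FALSE]
}

#' Ordinary least-squares regression of target on sRNA fold-change
#'
#' @param pairs Tibble from [pair_fold_changes()] (or any table with
#'   `srna_log2fc`, `target_log2fc`).
#' @return A list with `n`, `intercept`, `slope`, `r2`, `f` (the F statistic
#'   on (1, n-2) df; `Inf` when the fit is exact), `df`.
#' @export
fit_fc_regression <- function(pairs) {
  x <- pairs$srna_log2fc
  y <- pairs$target_log2fc
  n <- length(x)
  abort_if(n < 3, "need at least 3 pairs")
  abort_if(var(x) == 0, "zero variance in sRNA fold-changes")
  abort_if(var(y) == 0, "zero variance in target fold-changes")
  fit <- lm(y ~ x)
  r2 <- 1 - sum(residuals(fit)^2) / sum((y - mean(y))^2)
  f <- if (r2 >= 1) Inf else (n - 2) * r2 / (1 - r2)
  list(n = n, intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       r2 = r2, f = f, df = c(1L, n - 2L))
}

# F statistics for many permutations at once; x fixed, columns of Y permuted
perm_f_stats <- function(x, Y) {
  n <- length(x)
  r2 <- as.vector(cor(x, Y))^2
  ifelse(r2 >= 1, Inf, (n - 2) * r2 / (1 - r2))
}

#' Random re-pairing null for the fold-change regression F statistic
#'
#' Destroys the sRNA-target pairing while keeping both marginal
#' distributions: each iteration permutes the target fold-change vector
#' against the fixed sRNA vector and records the OLS F statistic. Under
#' independence this null follows F(1, n-2).
#'
#' @param pairs Tibble with `srna_log2fc`, `target_log2fc`.
#' @param n_iter Number of random re-pairings.
#' @param seed RNG seed for the permutations.
#' @param replace Re-pair with replacement instead of permutation
#'   (a bootstrap variant; the default re-pairing matches the idea of
#'   pairing the two vectors randomly).
#' @return A list of class `bootstrap_null` with `null_f`, `median_f`,
#'   `observed_f`, `p_emp` (exceedance with +1 smoothing), `n_iter`, `seed`.
#' @export
bootstrap_f_null <- function(pairs, n_iter = 10000, seed = 1L,
                             replace = FALSE) {
  x <- pairs$srna_log2fc
  y <- pairs$target_log2fc
  n <- length(x)
  abort_if(n < 3, "need at least 3 pairs")
  observed <- if (var(x) > 0 && var(y) > 0) fit_fc_regression(pairs)$f else 0
  set.seed(seed)
  if (var(x) == 0 || var(y) == 0) {
    null_f <- rep(0, n_iter)
  } else {
    Y <- vapply(seq_len(n_iter),
                function(i) y[sample.int(n, n, replace = replace)],
                numeric(n))
    null_f <- perm_f_stats(x, Y)
  }
  structure(list(null_f = null_f, median_f = median(null_f),
                 observed_f = observed,
                 p_emp = (1 + sum(null_f >= observed)) / (n_iter + 1),
                 n_iter = n_iter, seed = seed, n = n),
            class = "bootstrap_null")
}

#' @export
print.bootstrap_null <- function(x, ...) {
  cat(sprintf(paste0("<bootstrap_null> %d re-pairings of %d pairs\n",
                     "  observed F = %.3g, null median F = %.3g, ",
                     "empirical p = %.3g\n"),
              x$n_iter, x$n, x$observed_f, x$median_f, x$p_emp))
  invisible(x)
}

#' Two-proportion Z-test (pooled)
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @return A list with `z`, `p` (two-sided), and the two proportions.
#' @export
two_proportion_ztest <- function(k1, n1, k2, n2) {
  abort_if(n1 <= 0 || n2 <= 0 || k1 < 0 || k2 < 0 || k1 > n1 || k2 > n2,
           "need 0 <= k <= n with n > 0 in both groups")
  p1 <- k1 / n1; p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  if (pp == 0 || pp == 1)
    return(list(z = 0, p = 1, p1 = p1, p2 = p2))
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  list(z = z, p = 2 * pnorm(-abs(z)), p1 = p1, p2 = p2)
}

#' Calibrate RNA size against gel migration distance
#'
#' Fits a gamma GLM with inverse link (`mean size = 1 / (b0 + b1 *
#' distance)`) to ladder standards by maximum likelihood (IRLS), the
#' classical model for electrophoretic mobility of nucleic acids.
#'
#' @param standards Data frame with `size_nt` and `distance`.
#' @return A list of class `ladder_calibration` with `b0`, `b1`, `vcov`,
#'   `shape` (moment estimate), `n_standards`, `distance_range`, `fit`.
#' @export
calibrate_ladder <- function(standards) {
  abort_if(nrow(standards) < 3, "need at least 3 standards")
  abort_if(anyDuplicated(standards$distance) > 0,
           "standards must have distinct distances")
  abort_if(any(standards$size_nt <= 0), "sizes must be positive")
  # a noiseless ladder gives a zero-deviance fit whose AIC is NaN; harmless
  fit <- withCallingHandlers(
    glm(size_nt ~ distance, data = standards,
        family = Gamma(link = "inverse")),
    warning = function(w) {
      if (grepl("NaNs produced", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  abort_if(!fit$converged, "gamma GLM did not converge (deviance %.4g)",
           fit$deviance)
  eta <- fit$linear.predictors
  abort_if(any(eta <= 0),
           "fitted mean non-positive over the standards' range")
  co <- coef(fit)
  disp <- summary(fit)$dispersion
  structure(list(b0 = unname(co[1]), b1 = unname(co[2]),
                 vcov = vcov(fit), shape = 1 / disp,
                 n_standards = nrow(standards),
                 distance_range = range(standards$distance), fit = fit),
            class = "ladder_calibration")
}

#' @export
print.ladder_calibration <- function(x, ...) {
  cat(sprintf(paste0("<ladder_calibration> %d standards\n",
                     "  size = 1 / (%.4g + %.4g x distance), ",
                     "gamma shape %.3g\n"),
              x$n_standards, x$b0, x$b1, x$shape))
  invisible(x)
}

#' Predict RNA size from migration distance
#'
#' Point estimate `1 / (b0 + b1 d)` with a 95% interval obtained by the
#' delta method on the linear predictor (a t interval on `b0 + b1 d`,
#' inverted), plus a helper comparison against an independently measured
#' size.
#'
#' @param calibration A [calibrate_ladder()] result.
#' @param distance Migration distance(s).
#' @param compare_size Optional size(s) (e.g., from the transcriptome) to
#'   test for inclusion in the interval.
#' @param level Confidence level.
#' @return A tibble with `distance`, `size`, `lower`, `upper`,
#'   `extrapolated`, and (if `compare_size` given) `compare_size`,
#'   `inside_interval`.
#' @export
predict_size <- function(calibration, distance, compare_size = NULL,
                         level = 0.95) {
  rng <- calibration$distance_range
  half <- diff(rng) / 2
  guard <- c(mean(rng) - 1.5 * half, mean(rng) + 1.5 * half)
  extrapolated <- distance < guard[1] | distance > guard[2]
  if (any(extrapolated))
    warning("distance beyond 1.5x the fitted range; flagged as extrapolated",
            call. = FALSE)
  X <- cbind(1, distance)
  eta <- as.vector(X %*% c(calibration$b0, calibration$b1))
  se <- sqrt(pmax(rowSums((X %*% calibration$vcov) * X), 0))
  tq <- qt(1 - (1 - level) / 2, df = calibration$n_standards - 2)
  hi_eta <- eta + tq * se
  lo_eta <- eta - tq * se
  out <- tibble::tibble(
    distance = distance, size = 1 / eta,
    lower = ifelse(hi_eta > 0, 1 / hi_eta, NA_real_),
    upper = ifelse(lo_eta > 0, 1 / lo_eta, Inf),
    extrapolated = extrapolated)
  if (!is.null(compare_size)) {
    out$compare_size <- compare_size
    out$inside_interval <- compare_size >= out$lower &
      compare_size <= out$upper
  }
  out
}
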