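#' Feature statistics contrasting original and knockoff importance scores
#'
#' Converts the per-window p-values of the original cohort and its `M`
#' knockoff copies into importance scores `T = -log10 p` and the filter
#' statistics:
#'
#' * single knockoff (`M = 1`): `W = T0 - T1`;
#' * multiple knockoffs: `kappa` is the index (0 = original) of the largest
#'   of `(T0, T1, ..., TM)`; `tau` is the gap between that maximum and the
#'   median of the remaining `M` scores; and
#'   `W = (T0 - median(T1..TM)) * 1{T0 >= max(T1..TM)}`, so `W > 0` only
#'   when the original beats every knockoff. The median (rather than the
#'   maximum) of the knockoff scores makes the statistic markedly more
#'   stable across knockoff redraws.
#'
#' Ties at the maximum are resolved in favor of the original (the
#' indicator uses `>=`), a mildly anti-conservative convention; set
#' `strict_ties = TRUE` for the strict inequality.
#'
#' @param p0 Vector of original-cohort p-values (one per window).
#' @param p_knockoffs Matrix of knockoff p-values, windows in rows, `M`
#'   columns (a vector is treated as `M = 1`).
#' @param strict_ties Resolve original/knockoff ties against the original.
#' @param statistic Gap summary over the non-maximal scores: `"median"`
#'   (the stable default) or `"max"` (the earlier multiple-knockoff
#'   convention, kept for stability comparisons).
#' @return Tibble with columns `T0`, `W`, `kappa`, `tau`.
#' @export
feature_stats <- function(p0, p_knockoffs, strict_ties = FALSE,
                          statistic = c("median", "max")) {
  statistic <- match.arg(statistic)
  gap_fn <- if (statistic == "median") stats::median else max
  pk <- as.matrix(p_knockoffs)
  stopifnot(length(p0) == nrow(pk), all(p0 > 0), all(pk > 0),
            all(p0 <= 1), all(pk <= 1))
  M <- ncol(pk)
  T0 <- -log10(p0)
  Tm <- -log10(pk)
  if (M == 1L) {
    W <- T0 - Tm[, 1]
    kappa <- ifelse(if (strict_ties) T0 > Tm[, 1] else T0 >= Tm[, 1], 0L, 1L)
    tau <- abs(W)
    return(tibble::tibble(T0 = T0, W = W, kappa = kappa, tau = tau))
  }
  gap_k <- apply(Tm, 1, gap_fn)
  max_k <- apply(Tm, 1, max)
  beats <- if (strict_ties) T0 > max_k else T0 >= max_k
  W <- (T0 - gap_k) * beats
  kappa <- integer(length(T0))
  tau <- numeric(length(T0))
  for (i in seq_along(T0)) {
    all_T <- c(T0[i], Tm[i, ])
    k <- if (beats[i]) 0L else which.max(Tm[i, ])
    kappa[i] <- k
    tau[i] <- all_T[k + 1L] - gap_fn(all_T[-(k + 1L)])
  }
  tibble::tibble(T0 = T0, W = W, kappa = kappa, tau = tau)
}

#' Single-knockoff selection threshold
#'
#' The knockoff filter threshold: the smallest candidate `t` (taken over
#' the observed positive `|W|`) with
#' `(1 + #\{W <= -t\}) / max(1, #\{W >= t\}) <= q`. Because the numerator
#' is at least 1, no selection is possible unless at least `1/q` windows
#' have `W >= t` -- the detection threshold of the single-knockoff filter.
#'
#' @param W Vector of feature statistics.
#' @param q Target FDR in (0, 1).
#' @return List with `tau_hat` (`Inf` when nothing qualifies) and the
#'   logical `selected` vector (`W >= tau_hat`).
#' @export
threshold_single <- function(W, q) {
  stopifnot(q > 0, q < 1)
  cand <- sort(unique(abs(W[abs(W) > 0])))
  tau_hat <- Inf
  for (t in cand) {
    ratio <- (1 + sum(W <= -t)) / max(1, sum(W >= t))
    if (ratio <= q) { tau_hat <- t; break }
  }
  list(tau_hat = tau_hat, selected = W >= tau_hat)
}

#' Multiple-knockoff selection threshold
#'
#' The multiple-knockoff analogue: candidates are the positive `tau` values
#' of windows with `kappa = 0`, and the threshold is the smallest `t` with
#' `(1/M + (1/M) #\{kappa >= 1, tau >= t\}) / max(1, #\{kappa = 0, tau >= t\}) <= q`.
#' Selection is `kappa = 0 & tau >= tau_hat`. At `M = 1` this reduces
#' exactly to [threshold_single()]. The `1/M` offset lowers the detection
#' threshold from `1/q` to `1/(Mq)` windows.
#'
#' @param stats Tibble from [feature_stats()] (columns `kappa`, `tau`).
#' @param M Number of knockoffs.
#' @param q Target FDR in (0, 1).
#' @return List with `tau_hat` and `selected`.
#' @export
threshold_multiple <- function(stats, M, q) {
  stopifnot(q > 0, q < 1, M >= 1)
  kappa <- stats$kappa
  tau <- stats$tau
  cand <- sort(unique(tau[kappa == 0 & tau > 0]))
  tau_hat <- Inf
  for (t in cand) {
    ratio <- (1 / M + sum(kappa >= 1 & tau >= t) / M) /
      max(1, sum(kappa == 0 & tau >= t))
    if (ratio <= q) { tau_hat <- t; break }
  }
  list(tau_hat = tau_hat, selected = kappa == 0 & tau >= tau_hat)
}

#' Knockoff Q-values
#'
#' The knockoff Q-value of a window is the smallest target FDR at which the
#' filter would select it: the minimum, over candidate thresholds
#' `t <= tau` (or `t <= W` for a single knockoff), of the knockoff FDR
#' estimate, capped at 1. Windows that can never be selected (`W <= 0`,
#' or `kappa != 0`) get Q-value 1. Selecting `\{q_window <= q\}` is
#' identical to running the threshold filter at target `q`.
#'
#' @param stats Tibble from [feature_stats()].
#' @param M Number of knockoffs (1 for the single-knockoff filter).
#' @return Numeric vector of Q-values in (0, 1].
#' @export
knockoff_qvalues <- function(stats, M = 1) {
  if (M == 1L) {
    W <- stats$W
    cand <- sort(unique(abs(W[abs(W) > 0])))
    ratios <- vapply(cand, function(t) {
      (1 + sum(W <= -t)) / max(1, sum(W >= t))
    }, numeric(1))
    return(vapply(seq_along(W), function(i) {
      if (W[i] <= 0) return(1)
      ok <- cand <= W[i]
      min(1, min(ratios[ok]))
    }, numeric(1)))
  }
  kappa <- stats$kappa
  tau <- stats$tau
  cand <- sort(unique(tau[kappa == 0 & tau > 0]))
  ratios <- vapply(cand, function(t) {
    (1 / M + sum(kappa >= 1 & tau >= t) / M) /
      max(1, sum(kappa == 0 & tau >= t))
  }, numeric(1))
  vapply(seq_along(tau), function(i) {
    if (kappa[i] != 0 || tau[i] <= 0) return(1)
    ok <- cand <= tau[i]
    min(1, min(ratios[ok]))
  }, numeric(1))
}
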