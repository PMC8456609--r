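# Inferential layer: paired TOST equivalence, Steel-Dwass all-pairs
# nonparametric comparisons, and Tukey HSD. The Steel-Dwass and Tukey
# statistics are computed here from their definitions; the studentized-range
# distribution itself comes from stats::ptukey.

#' Paired TOST equivalence test
#'
#' Two one-sided t tests on the paired differences `d = a - b` against the
#' symmetric equivalence bounds `+/- margin`:
#' `p = max(P(T >= (dbar + margin)/se), P(T <= (dbar - margin)/se))` with
#' `df = n - 1`. Small p rejects non-equivalence, i.e. supports
#' `|mean difference| < margin`. The mean absolute difference is reported
#' alongside a t confidence interval for the signed mean difference (the
#' CI can therefore be negative while the mean absolute difference is not).
#' A TOST on the absolute differences is also emitted (`p_tost_abs`); the
#' signed version is primary.
#'
#' @param values_a,values_b equal-length paired measurements, mm.
#' @param margin equivalence margin, mm (> 0).
#' @param conf_level confidence level of the CI.
#' @return list of class `equivalence_result`: `mean_abs_diff`, `mean_diff`,
#'   `ci_low`, `ci_high`, `p_tost`, `p_tost_abs`, `margin`, `n`.
#' @export
tost_equivalence <- function(values_a, values_b, margin = 3,
                             conf_level = 0.95) {
  stopifnot(length(values_a) == length(values_b), length(values_a) >= 2,
            margin > 0, !anyNA(values_a), !anyNA(values_b))
  tost_p <- function(d) {
    n <- length(d)
    m <- mean(d)
    s <- stats::sd(d)
    if (s < 1e-12) return(if (abs(m) < margin) 0 else 1)
    se <- s / sqrt(n)
    p_lower <- stats::pt((m + margin) / se, n - 1, lower.tail = FALSE)
    p_upper <- stats::pt((m - margin) / se, n - 1)
    max(p_lower, p_upper)
  }
  d <- values_a - values_b
  n <- length(d)
  m <- mean(d)
  s <- stats::sd(d)
  se <- if (s < 1e-12) 0 else s / sqrt(n)
  half <- if (se == 0) 0 else stats::qt(1 - (1 - conf_level) / 2, n - 1) * se
  structure(list(mean_abs_diff = mean(abs(d)), mean_diff = m,
                 ci_low = m - half, ci_high = m + half,
                 p_tost = tost_p(d), p_tost_abs = tost_p(abs(d)),
                 margin = margin, n = n),
            class = "equivalence_result")
}

#' @export
print.equivalence_result <- function(x, ...) {
  cat(sprintf("TOST (margin %.3g mm, n = %d): mean |diff| = %.3f mm, CI [%.3f, %.3f], p = %.4g\n",
              x$margin, x$n, x$mean_abs_diff, x$ci_low, x$ci_high, x$p_tost))
  invisible(x)
}

# Tie-corrected standardized Wilcoxon rank-sum statistic for one group pair.
pairwise_rank_stat <- function(gi, gj) {
  pooled <- c(gi, gj)
  r <- rank(pooled)  # mid-ranks
  ni <- length(gi); nj <- length(gj); N <- ni + nj
  W <- sum(r[seq_len(ni)])
  E <- ni * (N + 1) / 2
  V <- ni * nj / (N * (N - 1)) * (sum(r^2) - N * (N + 1)^2 / 4)
  if (V <= 1e-12) return(NA_real_)  # every pooled value tied
  (W - E) / sqrt(V)
}

#' Steel-Dwass all-pairs nonparametric comparison
#'
#' For every pair of groups the tie-corrected standardized Wilcoxon
#' rank-sum statistic `t` is computed on the pooled pair (mid-ranks), and
#' the p value is referenced to the studentized range distribution with
#' `k` means and infinite degrees of freedom:
#' `p = P(Q_{k,Inf} >= sqrt(2) |t|)`. For `k = 2` this reduces exactly to
#' the two-sided normal-approximation Wilcoxon test. Pairs whose pooled
#' values are all tied get p = 1.
#'
#' @param groups list of numeric vectors (k >= 2, each length >= 2).
#' @return list of class `pairwise_table`: `labels`, symmetric `p` and
#'   `statistic` matrices, `method`.
#' @export
steel_dwass <- function(groups) {
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 2))
  k <- length(groups)
  labels <- names(groups)
  if (is.null(labels)) labels <- paste0("group", seq_len(k))
  P <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  S <- P
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      t_ij <- pairwise_rank_stat(groups[[i]], groups[[j]])
      if (is.na(t_ij)) {
        p <- 1
        t_ij <- 0
      } else {
        p <- stats::ptukey(sqrt(2) * abs(t_ij), nmeans = k, df = Inf,
                           lower.tail = FALSE)
      }
      P[i, j] <- P[j, i] <- p
      S[i, j] <- S[j, i] <- t_ij
    }
  }
  diag(P) <- 1
  diag(S) <- 0
  structure(list(labels = labels, p = P, statistic = S,
                 method = "Steel-Dwass"), class = "pairwise_table")
}

#' Tukey HSD all-pairs comparison
#'
#' Pooled within-group variance (MSW), Tukey-Kramer statistic
#' `q = |mean_i - mean_j| / sqrt(MSW/2 (1/n_i + 1/n_j))`, p from the
#' studentized range with `df = N - k`. Zero within-group variance yields
#' exact 0/1 p values by mean equality.
#'
#' @param groups list of numeric vectors (k >= 2, each length >= 2).
#' @return a `pairwise_table` (see [steel_dwass()]).
#' @export
tukey_hsd <- function(groups) {
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 2))
  k <- length(groups)
  labels <- names(groups)
  if (is.null(labels)) labels <- paste0("group", seq_len(k))
  ns <- lengths(groups)
  N <- sum(ns)
  means <- vapply(groups, mean, numeric(1))
  msw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))) /
    (N - k)
  P <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  S <- P
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (msw < 1e-12) {
        q <- if (abs(means[i] - means[j]) < 1e-12) 0 else Inf
        p <- if (is.finite(q)) 1 else 0
      } else {
        q <- abs(means[i] - means[j]) /
          sqrt(msw / 2 * (1 / ns[i] + 1 / ns[j]))
        p <- stats::ptukey(q, nmeans = k, df = N - k, lower.tail = FALSE)
      }
      P[i, j] <- P[j, i] <- p
      S[i, j] <- S[j, i] <- q
    }
  }
  diag(P) <- 1
  diag(S) <- 0
  structure(list(labels = labels, p = P, statistic = S,
                 method = "Tukey HSD"), class = "pairwise_table")
}

#' @export
print.pairwise_table <- function(x, ...) {
  cat("<pairwise_table>", x$method, "\n")
  print(round(x$p, 4))
  invisible(x)
}
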