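#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided test of paired differences. Zero differences are discarded
#' (classic treatment) and the number of informative pairs is reported.
#' For up to 15 informative pairs the p-value is exact, from the full
#' permutation distribution of signed midranks (so rank ties are handled
#' exactly); otherwise a tie-corrected normal approximation with
#' continuity correction is used. The two-sided p is twice the smaller
#' tail, capped at 1.
#'
#' @param x,y paired numeric vectors (differences are `x - y`), or a
#'   single vector of differences if `y` is `NULL`.
#' @param exact_max largest number of informative pairs for which the
#'   exact distribution is enumerated.
#' @return object of class `glyco_test`: list with `statistic` (V, the sum
#'   of positive-difference ranks), `p_value`, `n_used`, `method`,
#'   `flagged` (TRUE when no informative pairs remain, p set to 1).
#' @export
signed_rank_test <- function(x, y = NULL, exact_max = 15L) {
  d <- if (is.null(y)) x else x - y
  stopifnot(all(is.finite(d)))
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(structure(list(statistic = NA_real_, p_value = 1, n_used = 0L,
                          method = "degenerate", flagged = TRUE),
                     class = "glyco_test"))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_max) {
    # all 2^n sign assignments of the observed midranks
    sums <- 0
    for (ri in r) sums <- c(sums, sums + ri)
    eps <- 1e-9
    p <- min(1, 2 * min(mean(sums >= v - eps), mean(sums <= v + eps)))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  structure(list(statistic = v, p_value = p, n_used = n, method = method,
                 flagged = FALSE),
            class = "glyco_test")
}

# exact null distribution of the rank-sum W of group A: counts of subsets
# of {1..n} of size na with each possible sum, by dynamic programming
.ranksum_counts <- function(n, na) {
  maxw <- sum((n - na + 1):n)
  f <- matrix(0, na + 1, maxw + 1)
  f[1, 1] <- 1
  for (v in seq_len(n)) {
    for (k in min(na, v):1) {
      w_idx <- (maxw + 1):(v + 1)
      f[k + 1, w_idx] <- f[k + 1, w_idx] + f[k, w_idx - v]
    }
  }
  f[na + 1, ]
}

#' Wilcoxon rank-sum test for two independent groups
#'
#' Two-sided. Exact when `min(nA, nB) <= 10` and the pooled sample has no
#' ties; otherwise a tie-corrected normal approximation with continuity
#' correction. The two-sided p is twice the smaller tail, capped at 1.
#'
#' @param a,b numeric vectors for the two groups.
#' @param exact_max exact-path limit on the smaller group size.
#' @return a `glyco_test`: `statistic` is W, the sum of the ranks of `a`
#'   in the pooled sample; also reports `n_used = c(nA, nB)`.
#' @export
rank_sum_test <- function(a, b, exact_max = 10L) {
  stopifnot(length(a) >= 1, length(b) >= 1,
            all(is.finite(a)), all(is.finite(b)))
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)
  w <- sum(r[seq_len(na)])
  has_ties <- anyDuplicated(pooled) > 0
  if (min(na, nb) <= exact_max && !has_ties) {
    counts <- .ranksum_counts(n, na)
    tot <- sum(counts)
    ws <- seq_along(counts) - 1
    p <- min(1, 2 * min(sum(counts[ws <= w]) / tot,
                        sum(counts[ws >= w]) / tot))
    method <- "exact"
  } else {
    mu <- na * (n + 1) / 2
    ties <- table(r)
    sig2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- if (sig2 > 0) (w - mu - sign(w - mu) * 0.5) / sqrt(sig2) else 0
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  structure(list(statistic = w, p_value = p, n_used = c(na, nb),
                 method = method, flagged = FALSE),
            class = "glyco_test")
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order: `q_(i) = min_(j >= i)
#'   p_(j) * m / j` over the sorted p-values, capped at 1.
#' @export
bh_fdr <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  m <- length(pvalues)
  if (m == 0) return(numeric(0))
  o <- order(pvalues)
  q <- numeric(m)
  q[o] <- pmin(1, rev(cummin(rev(pvalues[o] * m / seq_len(m)))))
  q
}

#' Paired tumor-vs-adjacent elevation tests with FDR
#'
#' Runs a two-sided signed-rank test per marker on complete tumor/adjacent
#' pairs and adjusts across exactly the tested markers with
#' Benjamini-Hochberg.
#'
#' @param tumor,adjacent data.frames (or matrices) with one column per
#'   marker, rows paired by position. Incomplete pairs (NA in either
#'   member) are dropped per marker.
#' @param min_pairs minimum complete pairs per marker (default 6).
#' @return data.frame with columns `marker`, `statistic`, `p`, `q`,
#'   `n_used`, `flagged`.
#' @export
paired_elevation_tests <- function(tumor, adjacent, min_pairs = 6L) {
  tumor <- as.data.frame(tumor); adjacent <- as.data.frame(adjacent)
  stopifnot(identical(names(tumor), names(adjacent)),
            nrow(tumor) == nrow(adjacent))
  res <- lapply(names(tumor), function(mk) {
    ok <- is.finite(tumor[[mk]]) & is.finite(adjacent[[mk]])
    if (sum(ok) < min_pairs)
      stop("fewer than ", min_pairs, " complete pairs for marker ", mk)
    tst <- signed_rank_test(tumor[[mk]][ok], adjacent[[mk]][ok])
    data.frame(marker = mk, statistic = tst$statistic, p = tst$p_value,
               n_used = tst$n_used, flagged = tst$flagged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_fdr(out$p)
  out[, c("marker", "statistic", "p", "q", "n_used", "flagged")]
}

#' Dichotomize time-to-progression at a cutoff
#'
#' Progression before the cutoff is `short`; follow-up reaching the cutoff
#' (progression or censoring at/after it) is `long`; censoring before the
#' cutoff without progression is `indeterminate` and is excluded from
#' classification analyses.
#'
#' @param time follow-up months (positive).
#' @param event 1 = progressed, 0 = censored.
#' @param cutoff_months dichotomy cutoff, default 24 (2 years; short is
#'   strictly below).
#' @return factor with levels `short`, `long`, `indeterminate`.
#' @export
dichotomize_ttp <- function(time, event, cutoff_months = 24) {
  stopifnot(all(time > 0), all(event %in% c(0, 1)))
  out <- ifelse(time >= cutoff_months, "long",
                ifelse(event == 1, "short", "indeterminate"))
  factor(out, levels = c("short", "long", "indeterminate"))
}

#' Median split of marker values
#'
#' @param values numeric vector, `n >= 2`.
#' @return factor `low`/`high`: low strictly below the median, ties at the
#'   median go high.
#' @export
median_split <- function(values) {
  stopifnot(length(values) >= 2, all(is.finite(values)))
  med <- median(values)
  factor(ifelse(values < med, "low", "high"), levels = c("low", "high"))
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time follow-up months.
#' @param event 1 = progressed, 0 = censored.
#' @return data.frame (class `km_estimate`): `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv` (right-continuous, starting at 1), `std_err`
#'   (Greenwood).
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) >= 1, all(time > 0), all(event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv, std_err = fit$std.err * fit$surv)
  class(out) <- c("km_estimate", "data.frame")
  out
}

#' Log-rank (Mantel-Cox) test for two survival curves
#'
#' @param time,event survival data as in [km_estimate()].
#' @param group two-level grouping vector.
#' @return a `glyco_test` with the 1-df chi-square statistic and two-sided
#'   p; when neither group has any event the test is degenerate and p = 1
#'   with `flagged = TRUE`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  stopifnot(nlevels(droplevels(group)) == 2, all(time > 0),
            all(event %in% c(0, 1)))
  if (sum(event) == 0)
    return(structure(list(statistic = 0, p_value = 1,
                          n_used = length(time), method = "degenerate",
                          flagged = TRUE),
                     class = "glyco_test"))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  p <- pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  structure(list(statistic = unname(sd$chisq), p_value = p,
                 n_used = length(time), method = "logrank",
                 flagged = FALSE),
            class = "glyco_test")
}

#' @export
print.glyco_test <- function(x, ...) {
  cat(sprintf("%s test: statistic = %s, p = %.4g, n = %s%s\n",
              x$method, format(x$statistic), x$p_value,
              paste(x$n_used, collapse = "/"),
              if (isTRUE(x$flagged)) " [flagged]" else ""))
  invisible(x)
}
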