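#' Estimate the per-site error rate f
#'
#' `f = n_errors / n_bases`: the frequency of deviations from the
#' consensus over all comparable bases. Kept at full precision
#' internally; round only for presentation.
#'
#' @param n_errors number of observed deviations (errors).
#' @param n_bases number of comparable bases scored (denominator).
#' @return An object of class `error_rate_estimate`: list with
#'   `n_errors`, `n_bases`, `f`.
#' @examples
#' estimate_error_rate(95, 58592)$f # 1.62e-3
#' @export
estimate_error_rate <- function(n_errors, n_bases) {
  if (length(n_bases) != 1L || is.na(n_bases) || n_bases <= 0) {
    stop("n_bases must be a positive count")
  }
  if (length(n_errors) != 1L || is.na(n_errors) || n_errors < 0) {
    stop("n_errors must be a non-negative count")
  }
  structure(
    list(
      n_errors = as.numeric(n_errors),
      n_bases = as.numeric(n_bases),
      f = n_errors / n_bases
    ),
    class = "error_rate_estimate"
  )
}

#' @export
print.error_rate_estimate <- function(x, ...) {
  cat(sprintf(
    "error_rate_estimate: %g errors / %g bases; f = %.3g per site\n",
    x$n_errors, x$n_bases, x$f
  ))
  invisible(x)
}

#' Per-site per-duplication misincorporation rate m
#'
#' Hayes' conversion `m = 2 (f / d)` from the observed per-site error
#' frequency `f` in the final PCR product to the rate per site per
#' template duplication, where `d` is the number of doublings. Using the
#' pre-cloning cycle count for `d` is conservative: true doublings are
#' fewer because amplification plateaus in late cycles, so `d` is
#' real-valued and effective doubling counts can be supplied.
#'
#' @param f per-site error frequency (or an `error_rate_estimate`).
#' @param d number of doublings, > 0.
#' @return the rate `m` (numeric scalar).
#' @examples
#' per_duplication_rate(95 / 58592, 35) # 9.26e-5
#' @export
per_duplication_rate <- function(f, d) {
  if (inherits(f, "error_rate_estimate")) f <- f$f
  if (length(d) != 1L || is.na(d) || d <= 0) {
    stop("d (number of doublings) must be > 0")
  }
  if (f < 0) stop("f must be non-negative")
  2 * (f / d)
}

#' Binomial clone error model
#'
#' The number of errors in a clone of `L` scored sites is modelled as
#' `X ~ Binomial(L, p)` with `p` the per-site error probability in the
#' final PCR product (typically the estimated `f`).
#'
#' @param L sequence length in sites (>= 0).
#' @param p per-site error probability in `[0, 1]`.
#' @return object of class `binom_error_model`: list with `L`, `p`.
#' @export
binom_error_model <- function(L, p) {
  if (length(L) != 1L || is.na(L) || L < 0 || L != floor(L)) {
    stop("L must be a non-negative integer")
  }
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("p must be a probability in [0, 1]")
  }
  structure(list(L = as.integer(L), p = as.numeric(p)),
    class = "binom_error_model"
  )
}

#' @export
print.binom_error_model <- function(x, ...) {
  cat(sprintf("binom_error_model: L = %d sites, p = %.4g per site\n", x$L, x$p))
  invisible(x)
}

#' Binomial probability of exactly k errors
#'
#' `P(X = k) = C(L, k) p^k (1 - p)^(L - k)`, evaluated in log space.
#'
#' @param k error count(s), each in `0..L`.
#' @param model a [binom_error_model()].
#' @return probability vector, same length as `k`.
#' @export
error_pmf <- function(k, model) {
  stopifnot(inherits(model, "binom_error_model"))
  if (any(is.na(k)) || any(k < 0) || any(k > model$L) || any(k != floor(k))) {
    stop(sprintf("k must be integer(s) in 0..%d", model$L))
  }
  dbinom(k, size = model$L, prob = model$p)
}

#' Probability that a clone is completely error free
#'
#' `(1 - p)^L`. For an amplicon of 2000 bp at typical multi-template
#' PCR-cloning error rates this is below 5%: even sequences accepted as
#' genuine alleles are likely to carry some error.
#'
#' @param model a [binom_error_model()].
#' @return probability scalar.
#' @examples
#' error_free_probability(binom_error_model(2000, 95 / 58592)) # 0.039
#' @export
error_free_probability <- function(model) {
  stopifnot(inherits(model, "binom_error_model"))
  exp(model$L * log1p(-model$p))
}

#' Upper-tail probability of an observed error count
#'
#' `P(X >= k_obs)` under the binomial clone error model: the probability
#' that polymerase error alone produces at least as many deviations as
#' observed. Small values are evidence that a clone carries genuine
#' variation.
#'
#' @param k_obs observed error count(s), each in `0..L`.
#' @param model a [binom_error_model()].
#' @return tail probability vector.
#' @export
clone_tail_pvalue <- function(k_obs, model) {
  stopifnot(inherits(model, "binom_error_model"))
  if (any(is.na(k_obs)) || any(k_obs < 0) || any(k_obs > model$L) ||
    any(k_obs != floor(k_obs))) {
    stop(sprintf("k_obs must be integer(s) in 0..%d", model$L))
  }
  ifelse(
    k_obs == 0, 1,
    pbinom(k_obs - 1, size = model$L, prob = model$p, lower.tail = FALSE)
  )
}

#' Expected error-count distribution for N clones
#'
#' Tabulates `N * P(X = k)` for `k = 0..k_max`: the expected number of
#' clones showing each number of deviations from the consensus, under
#' the binomial model at the calibration error rate. Rounded counts use
#' nearest-integer, half away from zero.
#'
#' @param N number of clone sequences.
#' @param model a [binom_error_model()].
#' @param k_max largest error count tabulated; default: smallest k with
#'   raw expected count below 0.5 (at least 1).
#' @return object of class `expected_distribution`: list with `N`,
#'   `model`, `k`, `raw` (numeric expected counts), `rounded` (integer),
#'   and `tail` (probability mass beyond `k_max`).
#' @examples
#' m <- binom_error_model(1847, 95 / 58592)
#' expected_distribution(44, m, k_max = 7)$rounded
#' @export
expected_distribution <- function(N, model, k_max = NULL) {
  stopifnot(inherits(model, "binom_error_model"))
  if (length(N) != 1L || is.na(N) || N < 0) stop("N must be a count >= 0")
  if (is.null(k_max)) {
    k <- 0L
    while (k < model$L && N * error_pmf(k, model) >= 0.5) k <- k + 1L
    k_max <- max(1L, k)
  }
  if (k_max < 0 || k_max > model$L) stop("k_max must be in 0..L")
  k <- 0:k_max
  raw <- N * error_pmf(k, model)
  structure(
    list(
      N = N, model = model, k = k,
      raw = raw,
      rounded = as.integer(round_half_away(raw)),
      tail = if (N > 0) {
        pbinom(k_max, model$L, model$p, lower.tail = FALSE)
      } else {
        0
      }
    ),
    class = "expected_distribution"
  )
}

#' @export
print.expected_distribution <- function(x, ...) {
  cat(sprintf(
    "expected_distribution: N = %g clones, L = %d, p = %.4g\n",
    x$N, x$model$L, x$model$p
  ))
  print(data.frame(k = x$k, expected = signif(x$raw, 4), rounded = x$rounded))
  invisible(x)
}

#' Chi-square goodness of fit of observed vs expected error counts
#'
#' `chi^2 = sum (O - E)^2 / E` over bins with `E > 0`, comparing an
#' observed histogram of per-clone deviation counts with a binomial
#' expectation. The default degrees of freedom are `bins - 1` (the error
#' rate is estimated from independent calibration data); `bins - 2` can
#' be selected when the rate was fitted on the same data. Trailing bins
#' with expected count below 1 can optionally be pooled.
#'
#' @param observed observed counts per k (k = 0, 1, ...).
#' @param expected expected counts per k, same length; may be an
#'   [expected_distribution()] (its `raw` counts are used).
#' @param pooling one of `"none"` (default) or `"tail"` (pool trailing
#'   bins while the last expected count is < 1).
#' @param df_policy `"bins-1"` (default) or `"bins-2"`.
#' @return object of class `gof_result`: list with `chi2`, `df`,
#'   `p_value`, `bins` (number used), `observed`, `expected` (after
#'   pooling).
#' @export
gof_chi_square <- function(observed, expected,
                           pooling = c("none", "tail"),
                           df_policy = c("bins-1", "bins-2")) {
  pooling <- match.arg(pooling)
  df_policy <- match.arg(df_policy)
  if (inherits(expected, "expected_distribution")) expected <- expected$raw
  if (length(observed) != length(expected)) {
    stop("observed and expected must have the same number of bins")
  }
  if (any(observed < 0) || any(expected < 0)) {
    stop("counts must be non-negative")
  }
  if (sum(observed) <= 0) stop("degenerate input: no observations")
  if (all(expected == 0)) stop("degenerate input: all expected counts zero")
  if (pooling == "tail") {
    while (length(expected) > 2L && expected[length(expected)] < 1) {
      n <- length(expected)
      expected[n - 1L] <- expected[n - 1L] + expected[n]
      observed[n - 1L] <- observed[n - 1L] + observed[n]
      expected <- expected[-n]
      observed <- observed[-n]
    }
  }
  keep <- expected > 0
  if (sum(keep) < 2L) {
    stop("degenerate input: fewer than 2 usable bins after pooling")
  }
  O <- observed[keep]
  E <- expected[keep]
  chi2 <- sum((O - E)^2 / E)
  df <- sum(keep) - if (df_policy == "bins-1") 1L else 2L
  if (df < 1L) stop("degenerate input: not enough bins for df policy")
  structure(
    list(
      chi2 = chi2, df = df,
      p_value = pchisq(chi2, df = df, lower.tail = FALSE),
      bins = sum(keep), observed = O, expected = E,
      pooling = pooling, df_policy = df_policy
    ),
    class = "gof_result"
  )
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf(
    "gof_result: chi2 = %.3g on %d df (%d bins), P = %.3g\n",
    x$chi2, x$df, x$bins, x$p_value
  ))
  invisible(x)
}

#' Polymorphism-acceptance threshold k*
#'
#' The minimal number of deviations `k*` at which a clone should be
#' treated as evidence of a genuine polymorphism rather than accumulated
#' polymerase error, for a screen of `N` clones. Four criteria are
#' offered; none is privileged, because the trade-off between accepting
#' erroneous alleles and rejecting genuine ones is study-specific:
#'
#' * `uncorrected`: smallest k with `P(X >= k) < alpha`;
#' * `bonferroni_tail`: smallest k with `P(X >= k) < alpha / N`
#'   (family-wise control over the N clones screened);
#' * `familywise_exact`: smallest k with `1 - (1 - P(X >= k))^N < alpha`
#'   (Sidak-style exact family-wise bound);
#' * `expected_count`: smallest k with `N * P(X >= k) < 1` (fewer than
#'   one clone expected to reach k by error alone).
#'
#' @param N number of clones screened (>= 1).
#' @param model a [binom_error_model()].
#' @param alpha family significance level in (0, 1).
#' @param criterion one of the four criteria above (no default in the
#'   command-line interface; callers must choose).
#' @return object of class `threshold_result`: list with `N`, `model`,
#'   `alpha`, `criterion`, `k_star` (NA if not attainable), `attainable`,
#'   and `tail` (tail probabilities for k = 1..k_star, or up to L).
#' @export
polymorphism_threshold <- function(N, model, alpha,
                                   criterion = c(
                                     "uncorrected", "bonferroni_tail",
                                     "familywise_exact", "expected_count"
                                   )) {
  stopifnot(inherits(model, "binom_error_model"))
  criterion <- match.arg(criterion)
  if (length(N) != 1L || is.na(N) || N < 1) stop("N must be >= 1")
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)")
  }
  meets <- function(tail) {
    switch(criterion,
      uncorrected = tail < alpha,
      bonferroni_tail = tail < alpha / N,
      familywise_exact = -expm1(N * log1p(-tail)) < alpha,
      expected_count = N * tail < 1
    )
  }
  k_star <- NA_integer_
  tails <- numeric(0)
  for (k in seq_len(max(model$L, 1L))) {
    if (k > model$L) break
    tail_k <- clone_tail_pvalue(k, model)
    tails[k] <- tail_k
    if (meets(tail_k)) {
      k_star <- k
      break
    }
  }
  structure(
    list(
      N = N, model = model, alpha = alpha, criterion = criterion,
      k_star = k_star, attainable = !is.na(k_star), tail = tails
    ),
    class = "threshold_result"
  )
}

#' @export
print.threshold_result <- function(x, ...) {
  if (x$attainable) {
    cat(sprintf(
      "threshold_result (%s, alpha = %g, N = %g): k* = %d (tail %.3g)\n",
      x$criterion, x$alpha, x$N, x$k_star, x$tail[x$k_star]
    ))
  } else {
    cat(sprintf(
      "threshold_result (%s): not attainable for L = %d\n",
      x$criterion, x$model$L
    ))
  }
  invisible(x)
}

#' Sequential Bonferroni (Holm step-down) correction
#'
#' Sorts the p-values ascending and rejects the i-th smallest while
#' `p_(i) < alpha / (n - i + 1)`, stopping at the first failure. Equally
#' capable of detecting a single significant case as the fixed
#' Bonferroni correction, but less likely to reject additional genuine
#' cases; Holm rejections are always a superset of fixed-Bonferroni
#' rejections.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @param alpha family significance level.
#' @return logical vector of rejection flags, in input order.
#' @examples
#' sequential_bonferroni(c(0.001, 0.02, 0.2), 0.05) # TRUE TRUE FALSE
#' @export
sequential_bonferroni <- function(pvalues, alpha = 0.05) {
  if (length(pvalues) == 0L) return(logical(0))
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must be in [0, 1]")
  }
  n <- length(pvalues)
  ord <- order(pvalues)
  reject <- logical(n)
  for (i in seq_len(n)) {
    if (pvalues[ord[i]] < alpha / (n - i + 1)) {
      reject[ord[i]] <- TRUE
    } else {
      break
    }
  }
  reject
}
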