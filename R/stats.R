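# Statistical validation suite: exact paired tests, binomial tests,
# bootstrap CIs, permutation nulls, chi-squared weight tests.

#' One-sided exact McNemar test on discordant pairs
#'
#' Given a paired 2x2 prediction table, tests whether the first (composite)
#' method achieves higher paired accuracy than the second using the exact
#' binomial tail over the discordant pairs:
#' `p = sum_{k = n10}^{n} C(n, k) (1/2)^n` with `n = n10 + n01`. With
#' `n01 = 0` this reduces to `0.5^n10`.
#'
#' @param n10 Pairs where only the first method is correct.
#' @param n01 Pairs where only the second method is correct.
#' @return The one-sided exact p-value.
#' @export
mcnemar_exact_one_sided <- function(n10, n01) {
  stopifnot(n10 >= 0, n01 >= 0)
  n <- n10 + n01
  if (n < 1) abort("McNemar's test is undefined with zero discordant pairs.")
  stats::pbinom(n10 - 1, n, 0.5, lower.tail = FALSE)
}

#' One-sided exact binomial test (upper tail)
#'
#' `p = sum_{k = successes}^{trials} C(trials, k) p0^k (1 - p0)^(trials - k)`.
#'
#' @param successes,trials Nonnegative integers, `successes <= trials`.
#' @param p0 Null success probability in (0, 1).
#' @return The upper-tail p-value.
#' @export
binomial_one_sided <- function(successes, trials, p0) {
  stopifnot(successes >= 0, successes <= trials, p0 > 0, p0 < 1)
  stats::pbinom(successes - 1, trials, p0, lower.tail = FALSE)
}

#' Percentile bootstrap confidence interval for an accuracy proportion
#'
#' Resamples the 0/1 outcome vector with replacement at full length and
#' returns the percentile interval of the resampled means.
#'
#' @param outcomes Vector of 0/1 (or logical) outcomes.
#' @param iterations Bootstrap iterations (>= 100). Default 10000.
#' @param seed RNG seed.
#' @param level Interval level. Default 0.95.
#' @return Tibble `estimate`, `ci_low`, `ci_high`, `iterations`.
#' @export
bootstrap_accuracy_ci <- function(outcomes, iterations = 10000, seed = NULL,
                                  level = 0.95) {
  outcomes <- as.numeric(outcomes)
  if (length(outcomes) == 0) abort("`outcomes` is empty.")
  if (iterations < 100) abort("Use at least 100 bootstrap iterations.")
  check_seed(seed)
  n <- length(outcomes)
  means <- with_seed(seed, {
    vapply(seq_len(iterations),
           function(i) mean(outcomes[sample.int(n, n, replace = TRUE)]),
           numeric(1))
  })
  alpha <- (1 - level) / 2
  q <- stats::quantile(means, c(alpha, 1 - alpha), names = FALSE, type = 7)
  tibble(estimate = mean(outcomes), ci_low = q[1], ci_high = q[2],
         iterations = iterations)
}

#' Permutation p-value for an observed rank under a uniform-rank null
#'
#' The direct p-value of a drug is `rank_obs / n_cand`. The permutation
#' p-value compares it to `iterations` uniform draws on `[0, 1]` using the
#' add-one estimator `p = (1 + #\{u_i <= direct_p\}) / (iterations + 1)`,
#' which can never return zero.
#'
#' @param rank_obs Observed rank (1 = best).
#' @param n_cand Number of evaluated candidates.
#' @param iterations Number of uniform null draws (>= 100). Default 10000.
#' @param seed RNG seed.
#' @return The permutation p-value.
#' @export
permutation_rank_pvalue <- function(rank_obs, n_cand, iterations = 10000, seed = NULL) {
  stopifnot(rank_obs >= 1, rank_obs <= n_cand)
  if (iterations < 100) abort("Use at least 100 iterations.")
  check_seed(seed)
  direct_p <- rank_obs / n_cand
  with_seed(seed, {
    u <- stats::runif(iterations)
    (1 + sum(u <= direct_p)) / (iterations + 1)
  })
}

#' Top-fraction enrichment test for validated drugs
#'
#' Tests whether `hits` of `total` validated drugs landing in the top
#' `fraction` of candidate rankings exceeds the `fraction` random
#' expectation. `method = "exact_binomial"` uses the closed-form upper
#' binomial tail; `method = "permutation"` simulates `total` uniform ranks
#' per iteration and counts iterations with at least `hits` in the top
#' fraction, with the add-one estimator.
#'
#' @param hits Number of validated drugs in the top fraction.
#' @param total Number of validated drugs.
#' @param fraction Top fraction under the null. Default 0.10.
#' @param method `"exact_binomial"` or `"permutation"`.
#' @param iterations Permutation iterations. Default 10000.
#' @param seed RNG seed (permutation mode).
#' @return The enrichment p-value.
#' @export
topdecile_enrichment <- function(hits, total, fraction = 0.10,
                                 method = c("exact_binomial", "permutation"),
                                 iterations = 10000, seed = NULL) {
  method <- match.arg(method)
  stopifnot(hits >= 0, hits <= total)
  if (method == "exact_binomial") {
    return(binomial_one_sided(hits, total, fraction))
  }
  check_seed(seed)
  with_seed(seed, {
    exceed <- sum(vapply(seq_len(iterations), function(i) {
      sum(stats::runif(total) <= fraction) >= hits
    }, logical(1)))
    (1 + exceed) / (iterations + 1)
  })
}

#' Chi-squared goodness-of-fit of a weight vector against equal weights
#'
#' Weights are proportions, so the test requires a pseudo-count basis:
#' observed counts are `O_j = w_j * pseudo_n` against expected
#' `E_j = pseudo_n / m` for `m` metrics (df = m - 1). The statistic scales
#' linearly in `pseudo_n`, which is always reported alongside; by
#' convention `pseudo_n` is the network node count.
#'
#' @param w A `tihs_weights` tibble.
#' @param pseudo_n Pseudo-count basis. Values below `5 * m` trigger an
#'   expected-count advisory.
#' @return Tibble `statistic`, `df`, `p_value`, `pseudo_n`.
#' @export
chisq_weight_gof <- function(w, pseudo_n) {
  check_weights(w)
  m <- nrow(w)
  if (pseudo_n < 5 * m) {
    inform(sprintf("pseudo_n = %g gives expected counts below 5; interpret with caution.", pseudo_n))
  }
  O <- w$weight * pseudo_n
  E <- pseudo_n / m
  stat <- sum((O - E)^2 / E)
  tibble(statistic = stat, df = m - 1,
         p_value = stats::pchisq(stat, df = m - 1, lower.tail = FALSE),
         pseudo_n = pseudo_n)
}

#' Chi-squared homogeneity test across dataset weight vectors
#'
#' Standard contingency chi-squared on the pseudo-count matrix
#' (datasets x metrics), df = (rows - 1)(cols - 1). The count basis is a
#' convention (see [chisq_weight_gof()]) and is reported with the result.
#'
#' @param weight_matrix Numeric matrix of weight proportions, one row per
#'   dataset, columns = metrics; rows must each sum to 1.
#' @param pseudo_n Pseudo-count basis per dataset (scalar or one per row).
#' @return Tibble `statistic`, `df`, `p_value`.
#' @export
chisq_homogeneity <- function(weight_matrix, pseudo_n) {
  if (nrow(weight_matrix) < 2) abort("Need at least 2 datasets.")
  counts <- weight_matrix * pseudo_n
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  tibble(statistic = unname(res$statistic), df = unname(res$parameter),
         p_value = unname(res$p.value))
}

#' Full validation report for a curated drug-phenotype pair table
#'
#' Computes directional accuracy with a bootstrap CI, the exact binomial
#' test of accuracy against 0.5, per-drug direct and permutation rank
#' p-values, and the top-fraction enrichment p-value (both exact and
#' permutation modes).
#'
#' @param pairs Tibble from [read_validation_pairs()] or
#'   [curated_validation_pairs()].
#' @param top_fraction Enrichment fraction. Default 0.10.
#' @param iterations Monte-Carlo iterations. Default 10000.
#' @param seed RNG seed.
#' @return Object of class `tihs_validation`: list with `summary` (tibble)
#'   and `per_drug` (tibble with direct and permutation p-values).
#' @export
validate_predictions <- function(pairs, top_fraction = 0.10,
                                 iterations = 10000, seed = NULL) {
  check_seed(seed)
  correct <- pairs$correct
  n <- length(correct)
  boot <- bootstrap_accuracy_ci(correct, iterations = iterations, seed = seed)
  rf <- pairs$rank_obs / pairs$n_cand
  hits <- sum(correct & !is.na(rf) & rf <= top_fraction)
  perm_seed <- if (is.null(seed)) NULL else seed + 1
  per_drug <- pairs |>
    dplyr::mutate(direct_p = .data$rank_obs / .data$n_cand) |>
    dplyr::mutate(permutation_p = purrr::map2_dbl(
      .data$rank_obs, .data$n_cand,
      function(r, nc) {
        if (is.na(r) || is.na(nc)) return(NA_real_)
        permutation_rank_pvalue(r, nc, iterations = iterations, seed = perm_seed)
      }))
  summary <- tibble(
    n_pairs = n,
    n_correct = sum(correct),
    accuracy = mean(correct),
    accuracy_ci_low = boot$ci_low,
    accuracy_ci_high = boot$ci_high,
    binomial_p = binomial_one_sided(sum(correct), n, 0.5),
    top_hits = hits,
    enrichment_p_exact = topdecile_enrichment(hits, n, top_fraction),
    enrichment_p_perm = topdecile_enrichment(
      hits, n, top_fraction, method = "permutation",
      iterations = iterations, seed = if (is.null(seed)) NULL else seed + 2),
    top_fraction = top_fraction,
    iterations = iterations
  )
  structure(list(summary = summary, per_drug = per_drug),
            class = "tihs_validation")
}

#' @export
print.tihs_validation <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<tihs_validation> %d pairs: accuracy %.1f%% (%d/%d), 95%% CI [%.3f, %.3f]\n",
              s$n_pairs, 100 * s$accuracy, s$n_correct, s$n_pairs,
              s$accuracy_ci_low, s$accuracy_ci_high))
  cat(sprintf("  binomial p vs 0.5: %.4g; top-%.0f%% hits %d/%d, enrichment p: exact %.4g, permutation %.4g\n",
              s$binomial_p, 100 * s$top_fraction, s$top_hits, s$n_pairs,
              s$enrichment_p_exact, s$enrichment_p_perm))
  invisible(x)
}
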