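# Binomial homogeneity model and the mixed-state depletion statistic.
#
# If every cell of a population imports a fraction P of its target
# amino-acid residues, label incorporation at each of the n sites of a
# peptide is an independent Bernoulli trial, so the k-of-n imported-state
# abundances follow Binomial(n, P). Distinct producer and consumer
# subpopulations instead put all mass on the pure states; depletion of the
# mixed states relative to the binomial expectation is therefore evidence
# of metabolic heterogeneity.

check_fractions <- function(fractions, tol = 1e-6) {
  if (any(fractions < -tol))
    stop("state fractions must be nonnegative", call. = FALSE)
  if (abs(sum(fractions) - 1) > tol)
    stop("state fractions must sum to 1 (got ",
         format(sum(fractions)), ")", call. = FALSE)
  pmax(fractions, 0) / sum(pmax(fractions, 0))
}

#' Overall import probability from a labelling-state profile
#'
#' The fraction of imported (light) residues across all labelling states:
#' \eqn{P = \sum_k k f_k / n} for state fractions \eqn{f_k} over
#' \eqn{k = 0..n} imported sites. For two sites this is
#' (0·producer + 1·mixed + 2·consumer)/2.
#'
#' @param fractions Numeric vector of state fractions ordered by `k`
#'   (length n+1, summing to 1), or a `dilac_profile`.
#' @param condition Condition to extract when a profile is given.
#' @return P in \[0, 1\].
#' @examples
#' import_probability(c(0.30, 0.15, 0.55))  # 0.625
#' @export
import_probability <- function(fractions, condition = NULL) {
  if (inherits(fractions, "dilac_profile"))
    fractions <- profile_fractions(fractions, condition)
  f <- check_fractions(fractions)
  n <- length(f) - 1L
  if (n < 1L) stop("need at least two states", call. = FALSE)
  sum((0:n) * f) / n
}

#' Expected labelling-state distribution under homogeneity
#'
#' Binomial probabilities \eqn{r_k = \binom{n}{k} P^k (1-P)^{n-k}} of
#' observing k imported sites out of n.
#'
#' @param P Per-site import probability in \[0, 1\].
#' @param n_sites Number of target sites (default 2).
#' @return Named numeric vector `r_0..r_n`.
#' @examples
#' expected_distribution(0.625, 2)  # mixed state = 0.46875
#' @export
expected_distribution <- function(P, n_sites = 2L) {
  if (!(is.numeric(P) && length(P) == 1L && P >= 0 && P <= 1))
    stop("P must be a probability in [0, 1]", call. = FALSE)
  stopifnot(n_sites >= 1L)
  stats::setNames(stats::dbinom(0:n_sites, n_sites, P), 0:n_sites)
}

#' Expected mixed-state fraction under homogeneity
#'
#' @inheritParams expected_distribution
#' @return \eqn{\sum_{0<k<n} r_k}; for n = 2 this is \eqn{2P(1-P)}.
#' @export
expected_mixed_fraction <- function(P, n_sites = 2L) {
  r <- expected_distribution(P, n_sites)
  sum(r[-c(1L, length(r))])
}

#' Mixed-state depletion test for metabolic heterogeneity
#'
#' Estimates the import probability from the observed profile, compares
#' the observed mixed-state abundance with its binomial expectation, and
#' reports the depletion ratio expected/observed. A ratio well above 1
#' indicates that single cells do not mix synthesis and import, i.e. that
#' producer and consumer subpopulations exist. When an effective
#' observation count `m` is supplied, a chi-square goodness-of-fit of the
#' observed counts against the fitted binomial (df = n − 1, one parameter
#' estimated) is attached.
#'
#' @param observed Observed state fractions over `k = 0..n` imported
#'   sites (vector summing to 1), or a `dilac_profile`.
#' @param n_sites Number of target sites; default inferred from the input.
#' @param m Optional effective number of observations behind the
#'   fractions; fractions alone carry no sample size, so the chi-square
#'   is only computed when `m` is given.
#' @param ratio_threshold Depletion ratio above which the verdict is
#'   "heterogeneous" (default 2).
#' @param alpha Significance level for the chi-square verdict.
#' @param condition Condition to extract when a profile is given.
#' @return Object of class `dilac_heterogeneity`: list with `P`,
#'   `expected` and `observed` state vectors, `expected_mixed`,
#'   `observed_mixed`, `depletion_ratio` (`Inf` with
#'   `degenerate = TRUE` when no mixed signal was observed), optional
#'   `chisq`/`df`/`p_value`, and `verdict`
#'   ("heterogeneous"/"homogeneous").
#' @examples
#' depletion_test(c(0.30, 0.15, 0.55))
#' @export
depletion_test <- function(observed, n_sites = NULL, m = NULL,
                           ratio_threshold = 2, alpha = 0.05,
                           condition = NULL) {
  if (inherits(observed, "dilac_profile")) {
    if (is.null(n_sites)) n_sites <- observed$n_sites
    observed <- profile_fractions(observed, condition)
  }
  f <- check_fractions(observed)
  if (is.null(n_sites)) n_sites <- length(f) - 1L
  if (length(f) != n_sites + 1L)
    stop("observed fractions must have length n_sites + 1", call. = FALSE)
  P <- import_probability(f)
  r <- expected_distribution(P, n_sites)
  exp_mixed <- sum(r[-c(1L, length(r))])
  obs_mixed <- sum(f[-c(1L, length(f))])
  degenerate <- obs_mixed == 0
  ratio <- if (degenerate) Inf else exp_mixed / obs_mixed

  chisq <- df <- p_value <- NULL
  if (!is.null(m)) {
    stopifnot(m > 0)
    counts <- f * m
    keep <- r > 0
    chisq <- sum((counts[keep] - m * r[keep])^2 / (m * r[keep]))
    df <- n_sites - 1L
    p_value <- if (df >= 1L)
      stats::pchisq(chisq, df = df, lower.tail = FALSE) else NA_real_
  }
  verdict <- if (ratio > ratio_threshold ||
                 (!is.null(p_value) && !is.na(p_value) &&
                  p_value < alpha && ratio > 1))
    "heterogeneous" else "homogeneous"
  structure(list(P = P, expected = r,
                 observed = stats::setNames(f, 0:n_sites),
                 expected_mixed = exp_mixed, observed_mixed = obs_mixed,
                 depletion_ratio = ratio, degenerate = degenerate,
                 chisq = chisq, df = df, p_value = p_value,
                 ratio_threshold = ratio_threshold, alpha = alpha,
                 verdict = verdict),
            class = "dilac_heterogeneity")
}

#' @export
print.dilac_heterogeneity <- function(x, ...) {
  cat("Mixed-state depletion test\n")
  cat(sprintf("  import probability P = %.4f\n", x$P))
  cat(sprintf("  mixed fraction: expected %.4f, observed %.4f\n",
              x$expected_mixed, x$observed_mixed))
  cat(sprintf("  depletion ratio = %s%s\n",
              format(x$depletion_ratio, digits = 4),
              if (x$degenerate) " (no mixed signal observed)" else ""))
  if (!is.null(x$p_value))
    cat(sprintf("  chi-square = %.3f (df = %d), p = %.3g\n",
                x$chisq, x$df, x$p_value))
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}
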