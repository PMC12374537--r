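#' Null-model parameters for the expected fraction of identical genes
#'
#' The no-recombination null models per-gene substitution counts as Poisson
#' with a gamma-distributed (shape `alpha`, mean 1) rate multiplier shared by
#' the two genomes: divergence acts genome-wide, but genes differ in how fast
#' they accumulate substitutions. `alpha` controls the among-gene rate
#' heterogeneity (smaller = heavier tail of slow and fast genes); the default
#' 0.88 places the expectation at 98% ANI in the 6-7% band reported for this
#' class of genome collections. `mean_gene_len` is the average gene length in
#' bp; `tau` is the identity threshold in percent: 100 for F100 itself, 99.8
#' for the near-identity band used in recombination calling.
#'
#' @param alpha Gamma shape of the per-gene rate multipliers (> 0).
#' @param mean_gene_len Mean gene length in bp (> 0).
#' @param tau Identity threshold in percent (0 < tau <= 100).
#' @return A list of class `null_model_params`.
#' @export
null_model_params <- function(alpha = 0.88, mean_gene_len = 900, tau = 100) {
  stopifnot(is_scalar_number(alpha), alpha > 0,
            is_scalar_number(mean_gene_len), mean_gene_len > 0,
            is_scalar_number(tau), tau > 0, tau <= 100)
  structure(list(alpha = alpha, mean_gene_len = mean_gene_len, tau = tau),
            class = "null_model_params")
}

#' F100: fraction of (near-)identical reciprocal best matches
#'
#' The F100 statistic is the number of RBMs at or above `tau` percent
#' identity divided by the total number of RBMs between two genomes. With the
#' default `tau = 100` this is the fraction of perfectly identical shared
#' genes; an excess over the null expectation at the pair's ANI signals
#' recent homologous recombination.
#'
#' @param identities Numeric vector of RBM percent identities for one genome
#'   pair.
#' @param tau Identity threshold in percent.
#' @return Fraction in `[0, 1]`; `NA` for an empty input.
#' @examples
#' f100_statistic(c(rep(100, 3), rep(99, 7)))          # 0.3
#' f100_statistic(c(99.9, 99.7), tau = 99.8)           # 0.5
#' @export
f100_statistic <- function(identities, tau = 100) {
  identities <- identities[!is.na(identities)]
  if (length(identities) == 0) return(NA_real_)
  mean(identities >= tau)
}

#' Expected fraction of (near-)identical genes with no recent recombination
#'
#' Closed form under the gamma-Poisson null: per-gene substitution count is
#' Poisson(r * d * L) with r ~ gamma(alpha, mean 1), d = 1 - ANI/100 and L the
#' mean gene length; marginally the count is negative binomial with size
#' `alpha` and mean `d * L`. A gene clears the identity threshold `tau` when
#' it carries at most `floor((1 - tau/100) * L)` substitutions, so
#'
#'   E\[F_tau\] = P(NB(alpha, d * L) <= m_max).
#'
#' At `tau = 100` (`m_max = 0`) this reduces to `(1 + d * L / alpha)^(-alpha)`,
#' which tends to `exp(-d * L)` as `alpha` grows (rate homogeneity).
#'
#' @param ani Percent ANI of the genome pair (0-100), may be a vector.
#' @param params Null-model parameters ([null_model_params()]).
#' @param tau Identity threshold; defaults to `params$tau`.
#' @return Expected fraction(s) in `[0, 1]`.
#' @examples
#' expected_f100(98)   # ~0.067: the 6-7% no-recombination anchor
#' expected_f100(100)  # 1
#' @export
expected_f100 <- function(ani, params = null_model_params(), tau = NULL) {
  stopifnot(inherits(params, "null_model_params"))
  tau <- tau %||% params$tau
  if (any(!is.na(ani) & (ani < 0 | ani > 100))) rb_abort("ani must be within [0, 100]")
  d <- 1 - ani / 100
  m_max <- floor((1 - tau / 100) * params$mean_gene_len)
  out <- ifelse(d <= 0, 1,
                pnbinom(m_max, size = params$alpha, mu = d * params$mean_gene_len))
  as.numeric(out)
}

#' Monte-Carlo oracle for the null expectation
#'
#' Simulates `n_genes` independent genes: rate r ~ gamma(alpha, mean 1),
#' length L from `gene_len_sampler` (default: all genes at
#' `params$mean_gene_len`), substitution count ~ Poisson(r * d * L); a gene
#' counts as identical at threshold tau when its count is at most
#' `floor((1 - tau/100) * L)`. Returns the identical fraction. This is the
#' independent simulation route against which the closed form
#' [expected_f100()] is validated.
#'
#' @param ani Percent ANI.
#' @param params Null-model parameters.
#' @param n_genes Number of simulated genes.
#' @param gene_len_sampler Function `n -> lengths`, or `NULL` for fixed
#'   lengths at `params$mean_gene_len`.
#' @param seed Integer seed (required for reproducibility).
#' @param tau Identity threshold; defaults to `params$tau`.
#' @return Fraction of identical genes, with attribute `se` (binomial
#'   standard error).
#' @export
simulate_null_f100 <- function(ani, params = null_model_params(),
                               n_genes = 1e5, gene_len_sampler = NULL,
                               seed = 1, tau = NULL) {
  stopifnot(n_genes >= 1)
  tau <- tau %||% params$tau
  d <- 1 - ani / 100
  if (d < 0) rb_abort("ani must be <= 100")
  set.seed(seed)
  r <- rgamma(n_genes, shape = params$alpha, rate = params$alpha)
  L <- if (is.null(gene_len_sampler)) rep(params$mean_gene_len, n_genes) else gene_len_sampler(n_genes)
  m <- rpois(n_genes, r * d * L)
  identical <- m <= floor((1 - tau / 100) * L)
  p <- mean(identical)
  attr(p, "se") <- sqrt(max(p * (1 - p), 1 / n_genes) / n_genes)
  p
}

#' One-sided exact test for excess identical genes
#'
#' Tests whether `k_identical` of `n_rbm` RBM genes at 100% (or near-)
#' identity exceeds the no-recombination expectation: p = P(X >= k) with
#' X ~ Binomial(n, expected). Genes are treated as independent, which is the
#' null model's own assumption (rates are drawn independently per gene).
#'
#' @param k_identical Observed count of identical RBMs (0 <= k <= n).
#' @param n_rbm Total RBMs.
#' @param expected Null expectation in (0, 1); the degenerate values 0 and 1
#'   return the indicator p-values 1/0 and 1.
#' @return One-sided p-value.
#' @examples
#' f100_excess_test(10, 10, 0.5)   # 0.5^10
#' f100_excess_test(35, 100, 0.06) # vanishingly small
#' @export
f100_excess_test <- function(k_identical, n_rbm, expected) {
  stopifnot(is_scalar_number(k_identical), is_scalar_number(n_rbm),
            is_scalar_number(expected),
            k_identical >= 0, n_rbm >= k_identical,
            expected >= 0, expected <= 1)
  if (expected == 0) return(if (k_identical == 0) 1 else 0)
  if (expected == 1) return(1)
  pbinom(k_identical - 1, n_rbm, expected, lower.tail = FALSE)
}
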