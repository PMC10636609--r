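#' Two-component Poisson mixture log-probability of a per-read mutation count
#'
#' The observation model for nucleotide-recoding RNA-seq: the number of
#' retained T-to-C mutations `tc` on a single read is Poisson with rate
#' `exp(lambda_n)` if the read comes from a transcript made during the
#' labeling window (probability `theta`, the fraction new), and Poisson with
#' rate `exp(lambda_o)` (background: sequencing / RT error) otherwise. Reads
#' from unlabeled control libraries (`labeled = FALSE`) are pure background
#' regardless of `theta`.
#'
#' Both rate parameters live on the natural-log scale; the Poisson rate is
#' their exponential. The mixture is evaluated by log-sum-exp of the two
#' weighted component log-densities, so it is stable for extreme rates, and
#' a vanishing component (`theta` of exactly 0 or 1, or an unlabeled read)
#' is dropped rather than evaluated as `log(0)`.
#'
#' @param tc Non-negative integer vector of per-read T-to-C mutation counts.
#' @param theta Fraction of new transcripts, in `[0, 1]`. Recycled against
#'   `tc`.
#' @param lambda_n Log-scale mutation rate of the new-transcript component.
#' @param lambda_o Log-scale background mutation rate.
#' @param labeled Logical (or 0/1) indicator: was the sample fed
#'   4-thiouridine? Unlabeled reads collapse to the background component.
#' @return Numeric vector of log-probabilities, one per element after
#'   recycling.
#' @examples
#' mixture_log_pmf(0:3, theta = 0.5, lambda_n = -1, lambda_o = -3)
#' # unlabeled reads ignore theta entirely:
#' mixture_log_pmf(1, theta = 0.9, -1, -3, labeled = FALSE) ==
#'   dpois(1, exp(-3), log = TRUE)
#' @export
mixture_log_pmf <- function(tc, theta, lambda_n, lambda_o, labeled = TRUE) {
  if (length(tc) == 0) return(numeric(0))
  if (any(!is.finite(tc)) || any(tc < 0) || any(tc != round(tc))) {
    abort("`tc` must contain non-negative integers.")
  }
  if (any(theta < 0 | theta > 1)) {
    abort("`theta` must lie in [0, 1].")
  }
  n <- max(length(tc), length(theta), length(lambda_n), length(lambda_o),
           length(labeled))
  tc <- rep_len(tc, n)
  theta <- rep_len(theta, n)
  lambda_n <- rep_len(lambda_n, n)
  lambda_o <- rep_len(lambda_o, n)
  w <- rep_len(as.numeric(labeled), n) * theta

  log_new <- dpois(tc, exp(lambda_n), log = TRUE)
  log_old <- dpois(tc, exp(lambda_o), log = TRUE)

  out <- numeric(n)
  pure_old <- w == 0
  pure_new <- w == 1
  mix <- !pure_old & !pure_new
  out[pure_old] <- log_old[pure_old]
  out[pure_new] <- log_new[pure_new]
  if (any(mix)) {
    a <- log(w[mix]) + log_new[mix]
    b <- log1p(-w[mix]) + log_old[mix]
    m <- pmax(a, b)
    out[mix] <- m + log(exp(a - m) + exp(b - m))
  }
  out
}

#' Joint log-likelihood of a mutation-count table under given parameters
#'
#' Sums [mixture_log_pmf()] over every read in a per-read mutation count
#' table, looking up the gene- and condition-specific parameters for each
#' read. Reads are independent given the parameters, so the result is
#' additive over any partition of the table.
#'
#' @param table A mutation count table: a data frame with columns `gene_id`,
#'   `condition`, `s4u` (0/1 labeling indicator) and `tc`.
#' @param params A data frame with one row per (condition, gene) giving
#'   columns `condition`, `gene_id`, `theta`, `lambda_n`, `lambda_o`.
#' @return A single number, the joint log-likelihood (0 for an empty table).
#' @export
dataset_log_likelihood <- function(table, params) {
  stopifnot(is.data.frame(table), is.data.frame(params))
  if (nrow(table) == 0) return(0)
  needed <- distinct(table, .data$condition, .data$gene_id)
  missing <- anti_join(needed, params, by = c("condition", "gene_id"))
  if (nrow(missing) > 0) {
    abort(paste0(
      "No parameters for observed gene(s): ",
      paste(head(unique(missing$gene_id), 5), collapse = ", ")
    ))
  }
  joined <- left_join(table, params, by = c("condition", "gene_id"))
  sum(mixture_log_pmf(joined$tc, joined$theta, joined$lambda_n,
                      joined$lambda_o, labeled = joined$s4u))
}

#' Grid maximum-likelihood estimate of the fraction new at fixed rates
#'
#' A deliberately simple estimator of the fraction-new parameter used as an
#' independent reference for the MCMC sampler: with both mixture rates held
#' fixed and known, the per-gene likelihood is a one-dimensional function of
#' `theta`, maximized here by exhaustive evaluation on a regular grid.
#'
#' @param tc Integer vector of per-read mutation counts for one gene's
#'   labeled reads.
#' @param lambda_n,lambda_o Fixed log-scale rates of the two components.
#' @param step Grid resolution on `[0, 1]`.
#' @return The grid value of `theta` maximizing the likelihood.
#' @export
theta_grid_map <- function(tc, lambda_n, lambda_o, step = 0.001) {
  stopifnot(length(tc) > 0, step > 0, step < 1)
  grid <- seq(0, 1, by = step)
  tab <- tabulate(tc + 1L, nbins = max(tc) + 1L)
  k <- seq_along(tab) - 1L
  log_new <- dpois(k, exp(lambda_n), log = TRUE)
  log_old <- dpois(k, exp(lambda_o), log = TRUE)
  ll <- vapply(grid, function(th) {
    if (th == 0) return(sum(tab * log_old))
    if (th == 1) return(sum(tab * log_new))
    a <- log(th) + log_new
    b <- log1p(-th) + log_old
    m <- pmax(a, b)
    sum(tab * (m + log(exp(a - m) + exp(b - m))))
  }, numeric(1))
  grid[which.max(ll)]
}
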