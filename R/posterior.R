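# Split-half potential scale reduction factor for one scalar parameter.
# x: iterations x chains matrix of post-warmup draws.
rhat_split <- function(x) {
  n2 <- floor(nrow(x) / 2)
  if (n2 < 2) return(NA_real_)
  halves <- cbind(x[seq_len(n2), , drop = FALSE],
                  x[(nrow(x) - n2 + 1):nrow(x), , drop = FALSE])
  mns <- colMeans(halves)
  vars <- apply(halves, 2, var)
  W <- mean(vars)
  B <- n2 * var(mns)
  if (!is.finite(W) || W <= 0) {
    return(if (isTRUE(all.equal(min(halves), max(halves)))) 1 else NA_real_)
  }
  sqrt(((n2 - 1) / n2 * W + B / n2) / W)
}

# Effective sample size summed over chains (coda's spectral estimator).
ess_chains <- function(x) {
  sum(vapply(seq_len(ncol(x)), function(ch) {
    xi <- x[, ch]
    if (var(xi) == 0) return(length(xi))
    as.numeric(coda::effectiveSize(coda::mcmc(xi)))
  }, numeric(1)))
}

equal_tailed_ci <- function(x, mass) {
  a <- (1 - mass) / 2
  unname(quantile(x, c(a, 1 - a), names = FALSE, type = 7))
}

summarise_series <- function(x, interval) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  v <- as.vector(x)
  ci <- equal_tailed_ci(v, interval)
  tibble(median = median(v), ci_low = ci[1], ci_high = ci[2],
         rhat = rhat_split(x), ess = ess_chains(x))
}

#' Summarize posterior draws into point estimates and credible intervals
#'
#' Reports, for every model parameter, the posterior median (the point
#' estimate used throughout the package), an equal-tailed credible interval
#' of the requested mass, the split-chain potential scale reduction factor
#' (Rhat) and the effective sample size.
#'
#' @param fit A [fit_hierarchical()] result.
#' @param interval Credible-interval probability mass in (0, 1).
#' @return A tibble with columns `parameter`, `condition`, `gene_id`,
#'   `median`, `ci_low`, `ci_high`, `rhat`, `ess`.
#' @export
summarize_posterior <- function(fit, interval = 0.8) {
  stopifnot(inherits(fit, "tl_fit"))
  if (interval <= 0 || interval >= 1) {
    abort("`interval` must lie strictly inside (0, 1).")
  }
  d <- fit$draws
  J <- length(fit$conditions)
  G <- length(fit$genes)
  rows <- list()
  add <- function(param, condition, gene_id, x) {
    rows[[length(rows) + 1]] <<- mutate(
      summarise_series(x, interval),
      parameter = param, condition = condition, gene_id = gene_id,
      .before = 1
    )
  }
  add("lambda_o_bar", NA_character_, NA_character_, d$lambda_o_bar)
  add("sigma_o", NA_character_, NA_character_, d$sigma_o)
  for (j in seq_len(J)) {
    cj <- fit$conditions[j]
    add("lambda_n_bar", cj, NA_character_, d$lambda_n_bar[, , j])
    add("sigma_n", cj, NA_character_, d$sigma_n[, , j])
  }
  for (g in seq_len(G)) {
    add("lambda_o", NA_character_, fit$genes[g], d$lambda_o[, , g])
    for (j in seq_len(J)) {
      cj <- fit$conditions[j]
      add("theta", cj, fit$genes[g], d$theta[, , j, g])
      add("lambda_n", cj, fit$genes[g], d$lambda_n[, , j, g])
    }
  }
  bind_rows(rows)
}

#' @rdname summarize_posterior
#' @param x A `tl_fit` object.
#' @param ... Unused.
#' @export
tidy.tl_fit <- function(x, interval = 0.8, ...) {
  summarize_posterior(x, interval = interval)
}

#' One-row convergence overview of a fitted model
#'
#' @param x A `tl_fit` object.
#' @param ... Unused.
#' @return Tibble with gene/condition/draw counts, the worst Rhat and
#'   smallest effective sample size across all parameters, and a
#'   `converged` flag (all Rhat below 1.05).
#' @export
glance.tl_fit <- function(x, ...) {
  s <- summarize_posterior(x, interval = 0.8)
  max_rhat <- suppressWarnings(max(s$rhat, na.rm = TRUE))
  tibble(
    n_genes = length(x$genes),
    n_conditions = length(x$conditions),
    n_skipped_genes = length(x$skipped_genes),
    chains = x$sampler$chains,
    draws_per_chain = x$sampler$draws,
    max_rhat = max_rhat,
    min_ess = suppressWarnings(min(s$ess, na.rm = TRUE)),
    converged = is.finite(max_rhat) && max_rhat < 1.05
  )
}

#' @export
print.tl_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<tl_fit> %d genes x %d condition(s); %d chain(s) x %d draws ",
           "(%d warmup), seed %d\n"),
    length(x$genes), length(x$conditions), x$sampler$chains,
    x$sampler$draws, x$sampler$warmup, x$sampler$seed
  ))
  if (length(x$skipped_genes) > 0) {
    cat(sprintf("  %d gene(s) skipped (missing reads in some sample)\n",
                length(x$skipped_genes)))
  }
  invisible(x)
}

# Flatten a parameter's draws to a (iterations*chains) vector or matrix,
# preserving (iteration, chain) pairing across parameters so that derived
# quantities are computed draw-wise.
flat_draws <- function(fit, param, j = NULL, g = NULL) {
  d <- fit$draws[[param]]
  if (is.null(d)) abort(sprintf("Unknown parameter '%s'.", param))
  nd <- length(dim(d))
  if (nd == 2) return(as.vector(d))
  if (nd == 3) return(as.vector(d[, , j %||% g]))
  as.vector(d[, , j, g])
}
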