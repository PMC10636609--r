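#' Upper-quartile normalization factors for a count matrix
#'
#' Computes per-sample scale factors proportional to the 75th percentile of
#' each sample's nonzero gene counts divided by its library size, rescaled
#' so the factors have geometric mean 1 (the `calcNormFactors`
#' upper-quartile scheme of edgeR, which performs the computation here).
#' Depth cancels exactly: doubling every count of a sample leaves its
#' factor unchanged.
#'
#' @param counts Gene-by-sample count matrix, or a wide data frame with a
#'   `gene_id` column.
#' @return A tibble of class `tl_norm_factors` with columns `sample_id`,
#'   `lib_size`, `upper_quartile`, `norm_factor`.
#' @export
upper_quartile_factors <- function(counts) {
  m <- count_matrix_any(counts)
  lib <- colSums(m)
  if (any(lib == 0)) {
    abort(sprintf("Sample(s) with all-zero counts: %s",
                  paste(colnames(m)[lib == 0], collapse = ", ")))
  }
  nf <- edgeR::calcNormFactors(m, method = "upperquartile")
  uq <- vapply(seq_len(ncol(m)), function(i) {
    x <- m[, i]
    unname(quantile(x[x > 0], 0.75, type = 7))
  }, numeric(1))
  out <- tibble(
    sample_id = colnames(m),
    lib_size = unname(lib),
    upper_quartile = uq,
    norm_factor = unname(nf)
  )
  class(out) <- c("tl_norm_factors", class(out))
  out
}

count_matrix_any <- function(counts) {
  if (is.matrix(counts)) {
    stopifnot(!is.null(colnames(counts)))
    return(counts)
  }
  count_matrix(counts)
}

#' Normalize a count matrix by library size and upper-quartile factors
#'
#' Divides each sample by its effective library size (library size times
#' normalization factor) and rescales by the geometric mean of the
#' effective sizes, keeping normalized values on the scale of raw counts.
#'
#' @inheritParams upper_quartile_factors
#' @param factors Optional precomputed [upper_quartile_factors()].
#' @return Numeric matrix of normalized counts.
#' @export
normalized_counts <- function(counts, factors = NULL) {
  m <- count_matrix_any(counts)
  factors <- factors %||% upper_quartile_factors(m)
  eff <- factors$lib_size * factors$norm_factor
  eff <- eff[match(colnames(m), factors$sample_id)]
  sweep(m, 2, eff, "/") * exp(mean(log(eff)))
}

#' Convert a fraction-new estimate into a degradation rate constant
#'
#' Under first-order decay, the fraction of a gene's transcripts that are
#' new after a labeling window of `t` hours satisfies
#' `theta = 1 - exp(-kdeg * t)`; this inverts that relationship,
#' `kdeg = -log(1 - theta) / t`, and is applied draw-wise to whole
#' posterior arrays to propagate uncertainty.
#'
#' @param theta Fraction new, in `[0, 1]`; values of exactly 1 are clipped
#'   to `1 - 1e-9` with a warning.
#' @param t Labeling time in hours.
#' @return Degradation rate constants (per hour), same shape as `theta`.
#' @export
theta_to_kdeg <- function(theta, t) {
  stopifnot(t > 0)
  if (any(theta < 0 | theta > 1, na.rm = TRUE)) {
    abort("`theta` must lie in [0, 1].")
  }
  if (any(theta == 1, na.rm = TRUE)) {
    warn("theta of exactly 1 clipped to 1 - 1e-9.")
    theta <- pmin(theta, 1 - 1e-9)
  }
  -log1p(-theta) / t
}

#' @rdname theta_to_kdeg
#' @param kdeg Degradation rate constants (per hour).
#' @export
kdeg_to_theta <- function(kdeg, t) {
  stopifnot(t > 0)
  if (any(kdeg < 0, na.rm = TRUE)) abort("`kdeg` must be non-negative.")
  -expm1(-kdeg * t)
}

#' Synthesis rate from expression level and degradation rate
#'
#' At steady state the expression level is the ratio of synthesis to
#' degradation, `N = ksyn / kdeg`, so `ksyn = N * kdeg`; applied draw-wise.
#'
#' @param N Normalized expression level (non-negative scalar per gene).
#' @param kdeg_draws Degradation-rate posterior draws.
#' @return Synthesis-rate draws, same shape as `kdeg_draws`.
#' @export
compute_ksyn <- function(N, kdeg_draws) {
  if (any(N < 0, na.rm = TRUE)) abort("`N` must be non-negative.")
  N * kdeg_draws
}

#' Kinetic parameter estimates from a fitted mixture model
#'
#' Converts fraction-new posterior draws into degradation rates through the
#' exponential-decay relationship, attaches normalized expression levels
#' `N` (mean upper-quartile-normalized count across each condition's
#' labeled libraries), and derives synthesis-rate draws `ksyn = N * kdeg`.
#'
#' @param fit A [fit_hierarchical()] result.
#' @param counts Gene-by-sample counts covering the fitted genes (matrix or
#'   wide data frame); samples must appear in the fit's metadata.
#' @param t Labeling time (hours).
#' @param interval Credible-interval mass for summaries.
#' @return Object of class `tl_kinetics`: posterior draw arrays for
#'   `theta`, `kdeg`, `ksyn`, the `N` matrix, and a per-(gene, condition)
#'   summary tibble.
#' @export
kinetic_estimates <- function(fit, counts, t = 2, interval = 0.8) {
  stopifnot(inherits(fit, "tl_fit"), t > 0)
  m <- count_matrix_any(counts)
  missing_genes <- setdiff(fit$genes, rownames(m))
  if (length(missing_genes) > 0) {
    abort(sprintf("Count matrix lacks fitted gene(s): %s",
                  paste(head(missing_genes, 5), collapse = ", ")))
  }
  norm <- normalized_counts(m)
  meta <- fit$samples
  G <- length(fit$genes)
  J <- length(fit$conditions)
  N <- matrix(NA_real_, G, J, dimnames = list(fit$genes, fit$conditions))
  for (j in seq_len(J)) {
    smp <- meta$sample_id[meta$condition == fit$conditions[j] &
                            meta$s4u == 1]
    smp <- intersect(smp, colnames(norm))
    if (length(smp) == 0) {
      abort(sprintf("No labeled samples of condition '%s' in counts.",
                    fit$conditions[j]))
    }
    N[, j] <- rowMeans(norm[fit$genes, smp, drop = FALSE])
  }

  theta <- fit$draws$theta
  kdeg <- theta_to_kdeg(theta, t)
  ksyn <- kdeg
  for (j in seq_len(J)) {
    for (g in seq_len(G)) {
      ksyn[, , j, g] <- N[g, j] * kdeg[, , j, g]
    }
  }

  summ <- list()
  for (j in seq_len(J)) {
    for (g in seq_len(G)) {
      row <- tibble(
        gene_id = fit$genes[g], condition = fit$conditions[j],
        N = N[g, j]
      )
      for (p in c("theta", "kdeg", "ksyn")) {
        x <- switch(p, theta = theta, kdeg = kdeg, ksyn = ksyn)[, , j, g]
        ci <- equal_tailed_ci(as.vector(x), interval)
        row[[paste0(p, "_median")]] <- median(as.vector(x))
        row[[paste0(p, "_ci_low")]] <- ci[1]
        row[[paste0(p, "_ci_high")]] <- ci[2]
      }
      summ[[length(summ) + 1]] <- row
    }
  }

  structure(
    list(draws = list(theta = theta, kdeg = kdeg, ksyn = ksyn),
         N = N, genes = fit$genes, conditions = fit$conditions,
         t = t, interval = interval, summary = bind_rows(summ)),
    class = "tl_kinetics"
  )
}

#' @export
tidy.tl_kinetics <- function(x, ...) x$summary

#' @export
print.tl_kinetics <- function(x, ...) {
  cat(sprintf("<tl_kinetics> %d genes x %d condition(s), t = %g h\n",
              length(x$genes), length(x$conditions), x$t))
  invisible(x)
}

#' Fraction of an expression change attributable to degradation
#'
#' For a gene whose total-RNA log2 fold change decomposes as
#' `L2FC_N = L2FC_ksyn - L2FC_kdeg`, the degradation contribution is
#' `frac_deg = ((|L2FC_kdeg| - |L2FC_ksyn|) / |L2FC_N| + 1) / 2`,
#' which the reverse triangle inequality confines to `[0, 1]`: 1 means the
#' change is purely a stability effect, 0 purely synthesis, 0.5 equal
#' contributions. Genes with essentially no expression change
#' (`|L2FC_N| <= eps`) have no defined decomposition and return `NA`.
#'
#' @param l2fc_kdeg,l2fc_ksyn Log2 fold changes of the degradation and
#'   synthesis rates (draws or scalars; vectorized).
#' @param l2fc_n Log2 fold change of total RNA.
#' @param eps Threshold below which `|l2fc_n|` is treated as no change.
#' @return Values in `[0, 1]`, or `NA` where undefined.
#' @export
frac_deg <- function(l2fc_kdeg, l2fc_ksyn, l2fc_n, eps = 1e-6) {
  out <- ((abs(l2fc_kdeg) - abs(l2fc_ksyn)) / abs(l2fc_n) + 1) / 2
  # the reverse triangle inequality bounds the ratio in exact arithmetic;
  # clamp the last-ulp float spill so downstream interval logic can rely
  # on the bound
  out <- pmin(pmax(out, 0), 1)
  out[abs(l2fc_n) <= eps] <- NA_real_
  out
}

#' Classify one gene's degradation contribution from posterior draws
#'
#' A gene is confidently stability-driven when the equal-tailed credible
#' interval of its `frac_deg` draws lies entirely above 0.5, confidently
#' synthesis-driven when entirely below, and ambiguous when the interval
#' overlaps 0.5. Genes whose draws are all undefined (no expression
#' change) are classed `"undefined"`.
#'
#' @param fracdeg_draws Numeric vector of `frac_deg` posterior draws (`NA`
#'   allowed).
#' @param interval Credible-interval mass.
#' @return One of `"stability_driven"`, `"synthesis_driven"`,
#'   `"ambiguous"`, `"undefined"`.
#' @export
classify_gene <- function(fracdeg_draws, interval = 0.8) {
  x <- fracdeg_draws[!is.na(fracdeg_draws)]
  if (length(x) < 2) return("undefined")
  ci <- equal_tailed_ci(x, interval)
  if (ci[1] > 0.5) return("stability_driven")
  if (ci[2] < 0.5) return("synthesis_driven")
  "ambiguous"
}

#' Decompose expression fold changes into stability and synthesis parts
#'
#' Compares a perturbed condition against a reference: per gene, the total
#' expression log2 fold change `L2FC_N` is computed from mean normalized
#' counts (with a pseudocount), degradation-rate fold changes are computed
#' draw-wise from paired posterior draws, and the synthesis fold change is
#' defined through the steady-state identity
#' `L2FC_ksyn = L2FC_N + L2FC_kdeg`, which enforces
#' `L2FC_N = L2FC_ksyn - L2FC_kdeg` exactly on every draw. The
#' [frac_deg()] statistic and its credible interval then classify each
#' gene.
#'
#' @param kin A [kinetic_estimates()] result covering both conditions.
#' @param reference,perturbed Condition labels (default: first and second
#'   condition of the fit).
#' @param pseudocount Added to mean normalized counts before the expression
#'   log-ratio.
#' @param interval Credible-interval mass used for classification.
#' @return A tibble of class `tl_decomposition` with one row per gene:
#'   `gene_id`, `l2fc_n`, `l2fc_kdeg_median`, `l2fc_ksyn_median`,
#'   `fracdeg_median`, `fracdeg_ci_low`, `fracdeg_ci_high`, `class`.
#'   Posterior draw matrices are attached as the `"draws"` attribute for
#'   downstream calling.
#' @export
l2fc_decompose <- function(kin, reference = NULL, perturbed = NULL,
                           pseudocount = 0.5, interval = 0.8) {
  stopifnot(inherits(kin, "tl_kinetics"))
  if (length(kin$conditions) < 2) {
    abort("Decomposition needs at least two conditions.")
  }
  reference <- reference %||% kin$conditions[1]
  perturbed <- perturbed %||% kin$conditions[2]
  ja <- match(reference, kin$conditions)
  jb <- match(perturbed, kin$conditions)
  if (is.na(ja) || is.na(jb)) abort("Unknown condition label.")

  G <- length(kin$genes)
  nd <- dim(kin$draws$kdeg)[1] * dim(kin$draws$kdeg)[2]
  l2fc_kdeg <- matrix(NA_real_, nd, G)
  for (g in seq_len(G)) {
    l2fc_kdeg[, g] <- log2(as.vector(kin$draws$kdeg[, , jb, g]) /
                             as.vector(kin$draws$kdeg[, , ja, g]))
  }
  l2fc_n <- log2((kin$N[, jb] + pseudocount) / (kin$N[, ja] + pseudocount))
  l2fc_ksyn <- sweep(l2fc_kdeg, 2, l2fc_n, "+")
  fd <- frac_deg(l2fc_kdeg, l2fc_ksyn, rep(l2fc_n, each = nd))

  res <- tibble(
    gene_id = kin$genes,
    l2fc_n = unname(l2fc_n),
    l2fc_kdeg_median = apply(l2fc_kdeg, 2, median),
    l2fc_ksyn_median = apply(l2fc_ksyn, 2, median),
    fracdeg_median = apply(fd, 2, function(x) {
      if (all(is.na(x))) NA_real_ else median(x, na.rm = TRUE)
    }),
    fracdeg_ci_low = apply(fd, 2, function(x) {
      if (all(is.na(x))) NA_real_ else
        equal_tailed_ci(x[!is.na(x)], interval)[1]
    }),
    fracdeg_ci_high = apply(fd, 2, function(x) {
      if (all(is.na(x))) NA_real_ else
        equal_tailed_ci(x[!is.na(x)], interval)[2]
    }),
    class = apply(fd, 2, classify_gene, interval = interval)
  )
  attr(res, "draws") <- list(l2fc_kdeg = l2fc_kdeg, l2fc_ksyn = l2fc_ksyn,
                             fracdeg = fd)
  attr(res, "reference") <- reference
  attr(res, "perturbed") <- perturbed
  attr(res, "interval") <- interval
  class(res) <- c("tl_decomposition", class(res))
  res
}

#' Call genes with a confident stability change
#'
#' Destabilized genes are those whose degradation-rate log2 fold change has
#' a credible interval (default mass 0.95) entirely above zero and whose
#' expression change is classified as stability-driven; stabilized genes
#' are the symmetric case (interval entirely below zero). Results are
#' ranked by the magnitude of the posterior-median fold change.
#'
#' @param results A [l2fc_decompose()] result (with draws attached).
#' @param direction `"destabilized"` or `"stabilized"`.
#' @param mass Credible-interval mass for the fold-change significance
#'   criterion.
#' @return A tibble of called genes, ranked, with the fold-change interval
#'   at `mass` and the classification columns.
#' @export
call_stability_changes <- function(results,
                                   direction = c("destabilized",
                                                 "stabilized"),
                                   mass = 0.95) {
  direction <- match.arg(direction)
  stopifnot(inherits(results, "tl_decomposition"))
  draws <- attr(results, "draws")
  if (is.null(draws)) abort("Decomposition result lacks posterior draws.")
  ci <- apply(draws$l2fc_kdeg, 2, equal_tailed_ci, mass = mass)
  sig <- if (direction == "destabilized") ci[1, ] > 0 else ci[2, ] < 0
  out <- results %>%
    mutate(l2fc_kdeg_ci_low = ci[1, ], l2fc_kdeg_ci_high = ci[2, ],
           called = sig & .data$class == "stability_driven",
           direction = direction) %>%
    filter(.data$called) %>%
    arrange(desc(abs(.data$l2fc_kdeg_median)))
  as_tibble(out)
}
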