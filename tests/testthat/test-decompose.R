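test_that("upper-quartile factors are symmetric and depth-invariant", {
  m <- matrix(rpois(400, 50), ncol = 4,
              dimnames = list(sprintf("g%d", 1:100), sprintf("s%d", 1:4)))
  same <- cbind(s1 = m[, 1], s2 = m[, 1], s3 = m[, 1])
  f_same <- upper_quartile_factors(same)
  expect_equal(f_same$norm_factor, rep(1, 3), tolerance = 1e-12)
  # doubling a sample's depth leaves its factor unchanged
  doubled <- cbind(s1 = m[, 1], s2 = 2L * m[, 1])
  f_doub <- upper_quartile_factors(doubled)
  expect_equal(f_doub$norm_factor[1], f_doub$norm_factor[2],
               tolerance = 1e-12)
  # geometric mean of factors is one
  f <- upper_quartile_factors(m)
  expect_equal(exp(mean(log(f$norm_factor))), 1, tolerance = 1e-12)
})

test_that("toy-matrix factors match direct percentile arithmetic", {
  m <- matrix(c(10, 20, 30, 40, 10, 40, 30, 20), ncol = 2,
              dimnames = list(sprintf("g%d", 1:4), c("a", "b")))
  f <- upper_quartile_factors(m)
  # by hand: UQ of each sample / library size, rescaled to geometric mean 1
  uq <- apply(m, 2, function(x) unname(quantile(x[x > 0], 0.75)))
  raw <- uq / colSums(m)
  expected <- raw / exp(mean(log(raw)))
  expect_equal(f$norm_factor, unname(expected), tolerance = 1e-12)
  expect_equal(f$upper_quartile, unname(uq))
  zero <- cbind(a = c(1, 2), bad = c(0, 0))
  rownames(zero) <- c("g1", "g2")
  expect_error(upper_quartile_factors(zero), "bad")
})

test_that("theta and kdeg conversions are mutual inverses", {
  theta <- seq(0, 1 - 1e-6, length.out = 500)
  for (t in c(0.5, 2, 8)) {
    expect_equal(kdeg_to_theta(theta_to_kdeg(theta, t), t), theta,
                 tolerance = 1e-12)
  }
  expect_equal(theta_to_kdeg(0.5, 2), log(2) / 2, tolerance = 1e-12)
  expect_identical(theta_to_kdeg(0, 2), 0)
  expect_equal(theta_to_kdeg(1 - exp(-1), 1), 1, tolerance = 1e-9)
  expect_warning(k1 <- theta_to_kdeg(1, 2), "clipped")
  expect_true(is.finite(k1))
  expect_error(theta_to_kdeg(1.1, 2), "0, 1")
  expect_error(theta_to_kdeg(-0.1, 2), "0, 1")
})

test_that("ksyn is a draw-wise product with endpoint-mapped intervals", {
  draws <- matrix(rlnorm(1000, log(0.35), 0.2), ncol = 2)
  expect_identical(compute_ksyn(0, draws), draws * 0)
  ks <- compute_ksyn(100, draws)
  expect_equal(median(ks), 100 * median(draws), tolerance = 1e-12)
  ci_k <- quantile(draws, c(0.1, 0.9))
  ci_s <- quantile(ks, c(0.1, 0.9))
  expect_equal(unname(ci_s), unname(100 * ci_k), tolerance = 1e-12)
  expect_error(compute_ksyn(-1, draws), "non-negative")
})

test_that("frac_deg reproduces the canonical pure and balanced cases", {
  expect_identical(frac_deg(1, 0, -1), 1)    # pure stability change
  expect_identical(frac_deg(0, 1, 1), 0)     # pure synthesis change
  expect_identical(frac_deg(1, -1, -2), 0.5) # equal contributions
  expect_true(is.na(frac_deg(1, 1, 0)))      # undefined without a change
})

test_that("frac_deg is bounded and condition-swap invariant", {
  set.seed(31)
  n <- 1e4
  l2fc_kdeg <- rnorm(n, 0, 2)
  l2fc_n <- rnorm(n, 0, 2)
  l2fc_ksyn <- l2fc_n + l2fc_kdeg   # identity-consistent draws
  fd <- frac_deg(l2fc_kdeg, l2fc_ksyn, l2fc_n)
  defined <- !is.na(fd)
  expect_true(all(fd[defined] >= 0 & fd[defined] <= 1))
  # swapping conditions negates every fold change
  fd_swap <- frac_deg(-l2fc_kdeg, -l2fc_ksyn, -l2fc_n)
  expect_equal(fd, fd_swap, tolerance = 1e-12)
})

test_that("classification follows the credible-interval rule", {
  expect_identical(classify_gene(rep(0.9, 100)), "stability_driven")
  expect_identical(classify_gene(seq(0.12, 0.31, length.out = 100)),
                   "synthesis_driven")
  expect_identical(classify_gene(seq(0.4, 0.6, length.out = 100)),
                   "ambiguous")
  expect_identical(classify_gene(c(NA_real_, NA_real_)), "undefined")
  # widening the interval never converts ambiguous into confident
  set.seed(33)
  for (i in 1:50) {
    draws <- runif(200, min = runif(1, 0, 0.5), max = runif(1, 0.5, 1))
    classes <- vapply(c(0.5, 0.8, 0.95, 0.99), function(m) {
      classify_gene(draws, interval = m)
    }, character(1))
    confident <- classes != "ambiguous"
    # once ambiguous at some mass, all wider masses stay ambiguous
    expect_true(all(diff(confident) <= 0))
  }
})

test_that("the decomposition identity holds on every posterior draw", {
  set.seed(35)
  G <- 12
  theta_true <- runif(G, 0.2, 0.8)
  tbl <- make_mutation_table(G, 80, theta = theta_true,
                             conditions = c("WT", "KO"), seed = 35)
  tbl$replicate <- 1L
  fit <- fit_hierarchical(tbl, chains = 2, warmup = 200, draws = 100,
                          seed = 36)
  counts <- matrix(rpois(G * 2, 200), ncol = 2,
                   dimnames = list(fit$genes, c("WT_s4U", "KO_s4U")))
  kin <- kinetic_estimates(fit, counts, t = 2)
  dec <- l2fc_decompose(kin, reference = "WT", perturbed = "KO")
  dr <- attr(dec, "draws")
  reconstructed <- dr$l2fc_ksyn - dr$l2fc_kdeg
  expect_equal(reconstructed,
               matrix(rep(dec$l2fc_n, each = nrow(dr$l2fc_kdeg)),
                      nrow = nrow(dr$l2fc_kdeg)),
               tolerance = 1e-12)
  # per-draw theta/kdeg identity after conversion
  expect_equal(kin$draws$theta,
               1 - exp(-kin$draws$kdeg * 2), tolerance = 1e-12)
  # identical conditions give all-zero fold changes
  kin0 <- kin
  kin0$draws$kdeg[, , 2, ] <- kin0$draws$kdeg[, , 1, ]
  kin0$N[, 2] <- kin0$N[, 1]
  dec0 <- l2fc_decompose(kin0, reference = "WT", perturbed = "KO")
  expect_true(all(dec0$l2fc_n == 0))
  expect_true(all(dec0$l2fc_kdeg_median == 0))
  expect_true(all(dec0$l2fc_ksyn_median == 0))
})

test_that("a single confident gene is called in the right direction", {
  res <- tibble::tibble(
    gene_id = "g1", l2fc_n = -1, l2fc_kdeg_median = 1,
    l2fc_ksyn_median = 0, fracdeg_median = 1, fracdeg_ci_low = 1,
    fracdeg_ci_high = 1, class = "stability_driven"
  )
  attr(res, "draws") <- list(l2fc_kdeg = matrix(1, 100, 1))
  class(res) <- c("tl_decomposition", class(res))
  called <- call_stability_changes(res, "destabilized")
  expect_identical(called$gene_id, "g1")
  expect_identical(nrow(call_stability_changes(res, "stabilized")), 0L)
})
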