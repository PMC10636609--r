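#' Prior specification for the hierarchical mixture model
#'
#' Weakly informative priors on the log-scale mutation rates, centered on
#' typical recoding (-1) and background (-3) log rates and wide enough to
#' cover the range seen across nucleotide-recoding experiments. Gene-level
#' rates are non-centered: `lambda = lambda_bar + sigma * z` with standard
#' half-Cauchy scales and Normal(0, 1.5) standardized offsets. The fraction
#' new has a flat prior on `[0, 1]`.
#'
#' @param lambda_o_mean,lambda_o_sd Normal prior on the global background
#'   log rate.
#' @param lambda_n_mean,lambda_n_sd Normal prior on each condition's global
#'   new-transcript log rate.
#' @param sigma_scale Scale of the half-Cauchy (Cauchy truncated to the
#'   positive axis) priors on both gene-level standard deviations.
#' @param z_sd Standard deviation of the standardized gene offsets.
#' @return A list of class `tl_priors`.
#' @export
prior_spec <- function(lambda_o_mean = -3, lambda_o_sd = 1.5,
                       lambda_n_mean = -1, lambda_n_sd = 1.5,
                       sigma_scale = 1.5, z_sd = 1.5) {
  stopifnot(lambda_o_sd > 0, lambda_n_sd > 0, sigma_scale > 0, z_sd > 0)
  structure(
    list(lambda_o_mean = lambda_o_mean, lambda_o_sd = lambda_o_sd,
         lambda_n_mean = lambda_n_mean, lambda_n_sd = lambda_n_sd,
         sigma_scale = sigma_scale, z_sd = z_sd),
    class = "tl_priors"
  )
}

# Collapse a per-read mutation table into per-gene tally matrices over tc
# values: one pooled matrix for unlabeled controls (the background rate is
# shared across conditions) and one matrix per condition for labeled reads.
prepare_model_data <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("sample_id", "condition", "s4u", "gene_id", "tc") %in%
                  names(table)))
  n_samples <- dplyr::n_distinct(table$sample_id)
  per_gene <- table %>%
    distinct(.data$gene_id, .data$sample_id) %>%
    count(.data$gene_id, name = "n_samples_seen")
  keep <- per_gene$gene_id[per_gene$n_samples_seen == n_samples]
  skipped <- sort(setdiff(per_gene$gene_id, keep))
  genes <- sort(keep)
  conditions <- unique(table$condition)
  tab <- table[table$gene_id %in% genes, ]
  if (!any(tab$s4u == 0)) {
    warn(paste("No unlabeled control reads: the background rate is",
               "identified only through the mixture."))
  }
  if (!any(tab$s4u == 1)) {
    warn(paste("Mutation table contains no labeled (s4u = 1) reads:",
               "fraction-new parameters will follow their prior."))
  }
  K <- max(tab$tc)
  gfac <- factor(tab$gene_id, levels = genes)
  tfac <- factor(tab$tc, levels = 0:K)
  tally <- function(rows) {
    m <- table(gfac[rows], tfac[rows])
    matrix(as.integer(m), nrow = length(genes),
           dimnames = list(genes, 0:K))
  }
  ctrl <- tally(tab$s4u == 0)
  lab <- lapply(conditions, function(cj) {
    tally(tab$s4u == 1 & tab$condition == cj)
  })
  names(lab) <- conditions
  kvec <- 0:K
  lfact <- lgamma(kvec + 1)
  list(
    genes = genes, conditions = conditions, skipped_genes = skipped,
    K = K, kvec = kvec, lfact = lfact,
    ctrl = ctrl,
    ctrl_S0 = rowSums(ctrl),
    ctrl_S1 = as.numeric(ctrl %*% kvec),
    ctrl_C = as.numeric(ctrl %*% lfact),
    lab = lab,
    lab_active = lapply(lab, function(m) which(colSums(m) > 0) - 1L),
    samples = distinct(tab, .data$sample_id, .data$condition, .data$s4u)
  )
}

# Poisson log-likelihood of the pooled control reads, per gene, as a
# function of the gene-level background log rate (exponential-family
# sufficient statistics, O(G)).
ctrl_loglik <- function(md, lo) {
  md$ctrl_S1 * lo - md$ctrl_S0 * exp(lo) - md$ctrl_C
}

# Mixture log-likelihood of one condition's labeled reads, per gene.
# lth/l1mth are log(theta), log(1 - theta) (stable via plogis of the logit).
lab_loglik <- function(md, j, lth, l1mth, ln, lo) {
  m <- md$lab[[j]]
  ks <- md$lab_active[[j]]
  ll <- numeric(length(md$genes))
  rn <- exp(ln)
  ro <- exp(lo)
  for (k in ks) {
    a <- lth + k * ln - rn - md$lfact[k + 1]
    b <- l1mth + k * lo - ro - md$lfact[k + 1]
    mx <- pmax(a, b)
    ll <- ll + m[, k + 1] * (mx + log(exp(a - mx) + exp(b - mx)))
  }
  ll
}

#' Fit the hierarchical Bayesian Poisson-mixture model
#'
#' Models each read's retained T-to-C count as a two-component Poisson
#' mixture whose mixing weight is the gene's fraction of new transcripts in
#' its condition (zero for unlabeled controls), with gene-level log
#' mutation rates drawn from global, non-centered hierarchical
#' distributions: one global new-transcript rate per condition, one global
#' background rate shared across conditions. Posterior sampling uses an
#' adaptive random-walk Metropolis-within-Gibbs scheme that updates all
#' genes' local parameters in vectorized blocks (genes are conditionally
#' independent given the global parameters) and the global parameters one
#' at a time; proposal scales adapt toward a 44% acceptance rate during
#' warmup and are frozen afterwards.
#'
#' Genes with zero reads in any sample are excluded before fitting (their
#' parameters would be weakly identified and slow convergence) and listed
#' in the result's `skipped_genes`.
#'
#' @param table Per-read mutation count table (`sample_id`, `condition`,
#'   `s4u`, `gene_id`, `tc`), e.g. from [count_mutations()] or
#'   [simulate_experiment()].
#' @param priors A [prior_spec()].
#' @param chains,warmup,draws MCMC layout: number of chains, warmup
#'   (adaptation) iterations discarded per chain, and retained draws per
#'   chain.
#' @param seed Integer seed; together with the settings it fully determines
#'   the draws.
#' @param theta_by `"condition"` (default) shares one fraction-new per
#'   (condition, gene) across replicates; `"replicate"` gives every
#'   (condition, replicate) pair its own group.
#' @param fix_rates Optional calibration mode: a list with elements
#'   `lambda_n` (scalar or one per condition) and `lambda_o` holding the
#'   log mutation rates fixed at known values, so that only the
#'   fraction-new parameters are sampled. Useful when rates have been
#'   calibrated externally and for validating the sampler against
#'   fixed-rate estimators such as [theta_grid_map()].
#' @return An object of class `tl_fit` holding posterior draw arrays
#'   (`theta`, `lambda_n`, `lambda_o`, `z_n`, `z_o`, `lambda_n_bar`,
#'   `lambda_o_bar`, `sigma_n`, `sigma_o`), the gene/condition index, the
#'   sampler settings and acceptance rates.
#' @export
fit_hierarchical <- function(table, priors = prior_spec(), chains = 4,
                             warmup = 1000, draws = 1000, seed = 1L,
                             theta_by = c("condition", "replicate"),
                             fix_rates = NULL) {
  theta_by <- match.arg(theta_by)
  stopifnot(chains >= 1, warmup >= 100, draws >= 1)
  if (theta_by == "replicate") {
    stopifnot("replicate" %in% names(table))
    table$condition <- paste(table$condition, table$replicate, sep = ":rep")
  }
  md <- prepare_model_data(table)
  G <- length(md$genes)
  J <- length(md$conditions)
  if (G == 0) abort("No gene has at least one read in every sample.")

  out_draws <- list(
    theta = array(NA_real_, c(draws, chains, J, G)),
    lambda_n = array(NA_real_, c(draws, chains, J, G)),
    z_n = array(NA_real_, c(draws, chains, J, G)),
    lambda_o = array(NA_real_, c(draws, chains, G)),
    z_o = array(NA_real_, c(draws, chains, G)),
    lambda_n_bar = array(NA_real_, c(draws, chains, J)),
    sigma_n = array(NA_real_, c(draws, chains, J)),
    lambda_o_bar = array(NA_real_, c(draws, chains)),
    sigma_o = array(NA_real_, c(draws, chains))
  )
  accept <- vector("list", chains)

  for (ch in seq_len(chains)) {
    set.seed(as.integer(seed) + (ch - 1L) * 1000L)
    res <- run_chain(md, priors, warmup, draws, fix_rates = fix_rates)
    out_draws$theta[, ch, , ] <- res$theta
    out_draws$lambda_n[, ch, , ] <- res$lambda_n
    out_draws$z_n[, ch, , ] <- res$z_n
    out_draws$lambda_o[, ch, ] <- res$lambda_o
    out_draws$z_o[, ch, ] <- res$z_o
    out_draws$lambda_n_bar[, ch, ] <- res$lambda_n_bar
    out_draws$sigma_n[, ch, ] <- res$sigma_n
    out_draws$lambda_o_bar[, ch] <- res$lambda_o_bar
    out_draws$sigma_o[, ch] <- res$sigma_o
    accept[[ch]] <- res$accept
  }

  structure(
    list(draws = out_draws, genes = md$genes, conditions = md$conditions,
         skipped_genes = md$skipped_genes, samples = md$samples,
         priors = priors,
         sampler = list(method = "adaptive_rw_metropolis_within_gibbs",
                        chains = chains, warmup = warmup, draws = draws,
                        seed = as.integer(seed), theta_by = theta_by,
                        fixed_rates = !is.null(fix_rates)),
         accept = accept),
    class = "tl_fit"
  )
}

# One MCMC chain. Local parameters are updated as vectorized element-wise
# Metropolis blocks; cached per-gene log-likelihood vectors are refreshed
# only for accepted components.
run_chain <- function(md, priors, warmup, draws, fix_rates = NULL) {
  G <- length(md$genes)
  J <- length(md$conditions)
  total_iter <- warmup + draws
  fixed <- !is.null(fix_rates)

  # initialization: prior centers with mild jitter, moment-based theta
  lo_bar <- priors$lambda_o_mean + rnorm(1, 0, 0.1)
  if (sum(md$ctrl_S0) > 0 && sum(md$ctrl_S1) > 0) {
    lo_bar <- log(sum(md$ctrl_S1) / sum(md$ctrl_S0)) + rnorm(1, 0, 0.05)
  }
  ln_bar <- rep(priors$lambda_n_mean, J) + rnorm(J, 0, 0.1)
  log_so <- log(0.3) + rnorm(1, 0, 0.1)
  log_sn <- rep(log(0.3), J) + rnorm(J, 0, 0.1)
  z_o <- rnorm(G, 0, 0.1)
  z_n <- matrix(rnorm(J * G, 0, 0.1), nrow = J)
  if (fixed) {
    lo_bar <- fix_rates$lambda_o
    ln_bar <- rep_len(fix_rates$lambda_n, J)
    log_so <- -Inf
    log_sn <- rep(-Inf, J)
    z_o <- numeric(G)
    z_n <- matrix(0, nrow = J, ncol = G)
  }
  eta <- matrix(0, nrow = J, ncol = G)
  for (j in seq_len(J)) {
    reads_j <- rowSums(md$lab[[j]])
    mean_tc <- ifelse(reads_j > 0,
                      as.numeric(md$lab[[j]] %*% md$kvec) / pmax(reads_j, 1),
                      NA_real_)
    th0 <- (mean_tc - exp(lo_bar)) / (exp(ln_bar[j]) - exp(lo_bar))
    th0[!is.finite(th0)] <- 0.5
    eta[j, ] <- qlogis(pmin(pmax(th0, 0.05), 0.95)) + rnorm(G, 0, 0.2)
  }

  so <- exp(log_so)
  sn <- exp(log_sn)
  lo <- lo_bar + so * z_o
  ln <- ln_bar + sn * z_n          # J x G (column recycling of ln_bar/sn)
  lth <- matrix(plogis(eta, log.p = TRUE), nrow = J)
  l1mth <- matrix(plogis(-eta, log.p = TRUE), nrow = J)

  Lc <- ctrl_loglik(md, lo)
  Ll <- lapply(seq_len(J), function(j) {
    lab_loglik(md, j, lth[j, ], l1mth[j, ], ln[j, ], lo)
  })

  # adaptive proposal scales; the last J global slots belong to the joint
  # ridge move (lambda_n_bar shifted together with a compensating shear on
  # that condition's logit-theta values, the slow direction of the
  # posterior)
  sc_eta <- matrix(0.5, J, G); sc_zn <- matrix(0.4, J, G)
  sc_zo <- rep(0.4, G)
  sc_glob <- c(lo_bar = 0.05, log_so = 0.15, rep(0.1, J), rep(0.2, J),
               rep(0.05, J))
  ridge_b <- matrix(pmin(1 / (1 - plogis(eta)), 20), nrow = J)
  acc_eta <- matrix(0, J, G); acc_zn <- matrix(0, J, G)
  acc_zo <- rep(0, G); acc_glob <- numeric(length(sc_glob))
  batch <- 25L
  target <- 0.44
  n_kept <- 0L

  store <- list(
    theta = array(NA_real_, c(draws, J, G)),
    lambda_n = array(NA_real_, c(draws, J, G)),
    z_n = array(NA_real_, c(draws, J, G)),
    lambda_o = matrix(NA_real_, draws, G),
    z_o = matrix(NA_real_, draws, G),
    lambda_n_bar = matrix(NA_real_, draws, J),
    sigma_n = matrix(NA_real_, draws, J),
    lambda_o_bar = numeric(draws),
    sigma_o = numeric(draws)
  )

  z_prior <- function(z) dnorm(z, 0, priors$z_sd, log = TRUE)
  sigma_logpost_terms <- function(log_s) {
    s <- exp(log_s)
    dcauchy(s, 0, priors$sigma_scale, log = TRUE) + log(2) + log_s
  }

  for (it in seq_len(total_iter)) {
    # --- theta blocks (per condition, vectorized over genes) ---
    for (j in seq_len(J)) {
      prop <- eta[j, ] + rnorm(G, 0, sc_eta[j, ])
      plth <- plogis(prop, log.p = TRUE)
      pl1mth <- plogis(-prop, log.p = TRUE)
      Lp <- lab_loglik(md, j, plth, pl1mth, ln[j, ], lo)
      ratio <- (Lp + plth + pl1mth) - (Ll[[j]] + lth[j, ] + l1mth[j, ])
      acc <- log(runif(G)) < ratio
      if (any(acc)) {
        eta[j, acc] <- prop[acc]
        lth[j, acc] <- plth[acc]
        l1mth[j, acc] <- pl1mth[acc]
        Ll[[j]][acc] <- Lp[acc]
      }
      acc_eta[j, ] <- acc_eta[j, ] + acc
    }
    # --- z_n blocks ---
    if (!fixed) for (j in seq_len(J)) {
      prop <- z_n[j, ] + rnorm(G, 0, sc_zn[j, ])
      ln_prop <- ln_bar[j] + sn[j] * prop
      Lp <- lab_loglik(md, j, lth[j, ], l1mth[j, ], ln_prop, lo)
      ratio <- (Lp + z_prior(prop)) - (Ll[[j]] + z_prior(z_n[j, ]))
      acc <- log(runif(G)) < ratio
      if (any(acc)) {
        z_n[j, acc] <- prop[acc]
        ln[j, acc] <- ln_prop[acc]
        Ll[[j]][acc] <- Lp[acc]
      }
      acc_zn[j, ] <- acc_zn[j, ] + acc
    }
    # --- z_o block (touches controls and every condition's mixture) ---
    if (!fixed) {
      prop <- z_o + rnorm(G, 0, sc_zo)
      lo_prop <- lo_bar + so * prop
      Lc_prop <- ctrl_loglik(md, lo_prop)
      Ll_prop <- lapply(seq_len(J), function(j) {
        lab_loglik(md, j, lth[j, ], l1mth[j, ], ln[j, ], lo_prop)
      })
      ratio <- (Lc_prop + Reduce(`+`, Ll_prop) + z_prior(prop)) -
        (Lc + Reduce(`+`, Ll) + z_prior(z_o))
      acc <- log(runif(G)) < ratio
      if (any(acc)) {
        z_o[acc] <- prop[acc]
        lo[acc] <- lo_prop[acc]
        Lc[acc] <- Lc_prop[acc]
        for (j in seq_len(J)) Ll[[j]][acc] <- Ll_prop[[j]][acc]
      }
      acc_zo <- acc_zo + acc
    }
    # --- global parameters (scalar random-walk updates) ---
    if (!fixed) {
    # lambda_o_bar
    gidx <- 1L
    prop <- lo_bar + rnorm(1, 0, sc_glob[gidx])
    lo_prop <- prop + so * z_o
    Lc_prop <- ctrl_loglik(md, lo_prop)
    Ll_prop <- lapply(seq_len(J), function(j) {
      lab_loglik(md, j, lth[j, ], l1mth[j, ], ln[j, ], lo_prop)
    })
    ratio <- sum(Lc_prop) + sum(unlist(lapply(Ll_prop, sum))) +
      dnorm(prop, priors$lambda_o_mean, priors$lambda_o_sd, log = TRUE) -
      (sum(Lc) + sum(unlist(lapply(Ll, sum))) +
         dnorm(lo_bar, priors$lambda_o_mean, priors$lambda_o_sd,
               log = TRUE))
    if (log(runif(1)) < ratio) {
      lo_bar <- prop; lo <- lo_prop; Lc <- Lc_prop; Ll <- Ll_prop
      acc_glob[gidx] <- acc_glob[gidx] + 1
    }
    # log sigma_o
    gidx <- 2L
    prop <- log_so + rnorm(1, 0, sc_glob[gidx])
    so_prop <- exp(prop)
    lo_prop <- lo_bar + so_prop * z_o
    Lc_prop <- ctrl_loglik(md, lo_prop)
    Ll_prop <- lapply(seq_len(J), function(j) {
      lab_loglik(md, j, lth[j, ], l1mth[j, ], ln[j, ], lo_prop)
    })
    ratio <- sum(Lc_prop) + sum(unlist(lapply(Ll_prop, sum))) +
      sigma_logpost_terms(prop) -
      (sum(Lc) + sum(unlist(lapply(Ll, sum))) + sigma_logpost_terms(log_so))
    if (log(runif(1)) < ratio) {
      log_so <- prop; so <- so_prop; lo <- lo_prop
      Lc <- Lc_prop; Ll <- Ll_prop
      acc_glob[gidx] <- acc_glob[gidx] + 1
    }
    # lambda_n_bar[j] and log sigma_n[j]
    for (j in seq_len(J)) {
      gidx <- 2L + j
      prop <- ln_bar[j] + rnorm(1, 0, sc_glob[gidx])
      ln_prop <- prop + sn[j] * z_n[j, ]
      Lp <- lab_loglik(md, j, lth[j, ], l1mth[j, ], ln_prop, lo)
      ratio <- sum(Lp) +
        dnorm(prop, priors$lambda_n_mean, priors$lambda_n_sd, log = TRUE) -
        (sum(Ll[[j]]) +
           dnorm(ln_bar[j], priors$lambda_n_mean, priors$lambda_n_sd,
                 log = TRUE))
      if (log(runif(1)) < ratio) {
        ln_bar[j] <- prop; ln[j, ] <- ln_prop; Ll[[j]] <- Lp
        acc_glob[gidx] <- acc_glob[gidx] + 1
      }
      gidx <- 2L + J + j
      prop <- log_sn[j] + rnorm(1, 0, sc_glob[gidx])
      sn_prop <- exp(prop)
      ln_prop <- ln_bar[j] + sn_prop * z_n[j, ]
      Lp <- lab_loglik(md, j, lth[j, ], l1mth[j, ], ln_prop, lo)
      ratio <- sum(Lp) + sigma_logpost_terms(prop) -
        (sum(Ll[[j]]) + sigma_logpost_terms(log_sn[j]))
      if (log(runif(1)) < ratio) {
        log_sn[j] <- prop; sn[j] <- sn_prop; ln[j, ] <- ln_prop
        Ll[[j]] <- Lp
        acc_glob[gidx] <- acc_glob[gidx] + 1
      }
    }
    # joint ridge move: lambda_n_bar[j] and all of condition j's theta
    # values slide together along theta * exp(lambda_n) ~ constant
    for (j in seq_len(J)) {
      if (length(md$lab_active[[j]]) == 0) next  # no labeled reads: theta
                                                 # has no ridge to follow
      gidx <- 2L + 2L * J + j
      delta <- rnorm(1, 0, sc_glob[gidx])
      bar_prop <- ln_bar[j] + delta
      eta_prop <- eta[j, ] - delta * ridge_b[j, ]
      plth <- plogis(eta_prop, log.p = TRUE)
      pl1mth <- plogis(-eta_prop, log.p = TRUE)
      ln_prop <- bar_prop + sn[j] * z_n[j, ]
      Lp <- lab_loglik(md, j, plth, pl1mth, ln_prop, lo)
      ratio <- sum(Lp) + sum(plth + pl1mth) +
        dnorm(bar_prop, priors$lambda_n_mean, priors$lambda_n_sd,
              log = TRUE) -
        (sum(Ll[[j]]) + sum(lth[j, ] + l1mth[j, ]) +
           dnorm(ln_bar[j], priors$lambda_n_mean, priors$lambda_n_sd,
                 log = TRUE))
      if (log(runif(1)) < ratio) {
        ln_bar[j] <- bar_prop
        eta[j, ] <- eta_prop
        lth[j, ] <- plth
        l1mth[j, ] <- pl1mth
        ln[j, ] <- ln_prop
        Ll[[j]] <- Lp
        acc_glob[gidx] <- acc_glob[gidx] + 1
      }
    }
    }

    # --- adaptation during warmup ---
    if (it <= warmup && it %% batch == 0) {
      delta <- min(0.25, 2 / sqrt(it / batch))
      adapt <- function(scale, acc_count) {
        rate <- acc_count / batch
        scale * exp(delta * (rate - target))
      }
      sc_eta <- adapt(sc_eta, acc_eta)
      sc_zn <- adapt(sc_zn, acc_zn)
      sc_zo <- adapt(sc_zo, acc_zo)
      sc_glob <- adapt(sc_glob, acc_glob)
      acc_eta[] <- 0; acc_zn[] <- 0; acc_zo[] <- 0; acc_glob[] <- 0
      # re-aim the ridge shear at the current state (warmup only; frozen
      # afterwards so the kernel is a fixed symmetric shear)
      ridge_b <- matrix(pmin(1 / (1 - plogis(eta)), 20), nrow = J)
    }
    if (it == warmup) {
      acc_eta[] <- 0; acc_zn[] <- 0; acc_zo[] <- 0; acc_glob[] <- 0
    }

    # --- store post-warmup draws ---
    if (it > warmup) {
      n_kept <- n_kept + 1L
      store$theta[n_kept, , ] <- plogis(eta)
      store$lambda_n[n_kept, , ] <- ln
      store$z_n[n_kept, , ] <- z_n
      store$lambda_o[n_kept, ] <- lo
      store$z_o[n_kept, ] <- z_o
      store$lambda_n_bar[n_kept, ] <- ln_bar
      store$sigma_n[n_kept, ] <- sn
      store$lambda_o_bar[n_kept] <- lo_bar
      store$sigma_o[n_kept] <- so
    }
  }

  store$accept <- list(
    eta = acc_eta / draws, z_n = acc_zn / draws, z_o = acc_zo / draws,
    global = acc_glob / draws
  )
  store
}
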