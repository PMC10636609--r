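#' Configuration for the synthetic nucleotide-recoding experiment generator
#'
#' Collects every knob of the generative model the simulator shares with the
#' inference model: a two-condition (by default WT vs KO) design with
#' replicate s4U-labeled libraries and matched unlabeled controls, per-gene
#' degradation (`kdeg_truth`, per hour) and synthesis (`ksyn_truth`) rate
#' constants, hierarchical log-scale mutation rates, and optional SNP sites
#' and read-end / low-quality artifact events for exercising the mutation
#' filters.
#'
#' The fraction of new transcripts after a labeling window of
#' `labeling_time_t` hours is `theta = 1 - exp(-kdeg * t)` exactly; expected
#' read depth per gene scales with the steady-state expression level
#' `N = ksyn / kdeg` and a per-library log-normal size factor (sd
#' `library_sd`). Global log-scale mutation rates default to the centers of
#' the model priors (new: -1, background: -3).
#'
#' @param n_genes Number of genes.
#' @param conditions Character vector of condition labels; the first is
#'   treated as the reference downstream.
#' @param replicates_per_condition Replicate pairs (one labeled library plus
#'   one unlabeled control each) per condition.
#' @param reads_per_gene Baseline reads per gene per library (scalar or
#'   per-gene vector); realized depth also scales with relative expression
#'   and the library size factor.
#' @param labeling_time_t s4U labeling time in hours.
#' @param lambda_n_bar Global log mutation rate of new transcripts, scalar or
#'   one per condition.
#' @param lambda_o_bar Global log background mutation rate (shared).
#' @param sigma_n,sigma_o Gene-level standard deviations of the log rates.
#' @param kdeg_truth Per-gene degradation rates (h^-1): a vector (shared
#'   across conditions) or an `n_genes x n_conditions` matrix. `NULL` draws
#'   log-normal rates (meanlog `log(0.25)`, sdlog 0.5) shared across
#'   conditions.
#' @param ksyn_truth Synthesis rates, same shapes as `kdeg_truth`. `NULL`
#'   sets `ksyn = N_base * kdeg[, 1]` in every condition with per-gene
#'   `N_base` log-normal (sdlog 0.5), i.e. synthesis unchanged relative to
#'   the reference condition.
#' @param snp_fraction Proportion of reference-T sites simulated as
#'   heterozygous SNPs (mutation probability `snp_mut_prob` in every
#'   library, labeled or not).
#' @param library_sd Standard deviation of the log-normal library size
#'   factors; 0 gives equal depth.
#' @param end_artifact_rate,low_quality_rate Expected number per read of
#'   spurious T-to-C events within 3 nt of a read end, resp. internal events
#'   with base quality below 40.
#' @param snp_mut_prob Per-read mutation probability at a SNP site.
#' @param gene_length,read_length,t_site_density Geometry used when
#'   event-level output is generated: gene span (nt), read span (nt), and
#'   the fraction of gene positions that are reference Ts.
#' @param emit_events Generate per-event positions/qualities/offsets for each
#'   read? `NULL` (default) turns events on exactly when SNPs or artifacts
#'   are requested.
#' @param seed Integer seed; fully determines the simulated dataset.
#' @return A list of class `tl_sim_config`.
#' @export
sim_config <- function(n_genes = 100,
                       conditions = c("WT", "KO"),
                       replicates_per_condition = 3,
                       reads_per_gene = 300,
                       labeling_time_t = 2,
                       lambda_n_bar = -1,
                       lambda_o_bar = -3,
                       sigma_n = 0.2,
                       sigma_o = 0.1,
                       kdeg_truth = NULL,
                       ksyn_truth = NULL,
                       snp_fraction = 0,
                       library_sd = 0.1,
                       end_artifact_rate = 0,
                       low_quality_rate = 0,
                       snp_mut_prob = 0.5,
                       gene_length = 150,
                       read_length = 100,
                       t_site_density = 0.25,
                       emit_events = NULL,
                       seed = 1L) {
  stopifnot(
    n_genes >= 0, length(conditions) >= 1, !anyDuplicated(conditions),
    replicates_per_condition >= 1, all(reads_per_gene >= 0),
    labeling_time_t > 0, all(sigma_n >= 0), sigma_o >= 0,
    snp_fraction >= 0, snp_fraction <= 1, library_sd >= 0,
    end_artifact_rate >= 0, low_quality_rate >= 0,
    snp_mut_prob >= 0, snp_mut_prob <= 1,
    read_length <= gene_length
  )
  J <- length(conditions)
  cfg <- list(
    n_genes = as.integer(n_genes),
    conditions = as.character(conditions),
    replicates_per_condition = as.integer(replicates_per_condition),
    reads_per_gene = rep_len(reads_per_gene, max(n_genes, 1L)),
    labeling_time_t = labeling_time_t,
    lambda_n_bar = setNames(rep_len(lambda_n_bar, J), conditions),
    lambda_o_bar = lambda_o_bar,
    sigma_n = setNames(rep_len(sigma_n, J), conditions),
    sigma_o = sigma_o,
    kdeg_truth = kdeg_truth,
    ksyn_truth = ksyn_truth,
    snp_fraction = snp_fraction,
    library_sd = library_sd,
    end_artifact_rate = end_artifact_rate,
    low_quality_rate = low_quality_rate,
    snp_mut_prob = snp_mut_prob,
    gene_length = as.integer(gene_length),
    read_length = as.integer(read_length),
    t_site_density = t_site_density,
    emit_events = emit_events %||%
      (snp_fraction > 0 || end_artifact_rate > 0 || low_quality_rate > 0),
    seed = as.integer(seed)
  )
  structure(cfg, class = "tl_sim_config")
}

#' Simulate per-read T-to-C mutation counts for one gene
#'
#' Draws `n_reads` independent reads from the two-component Poisson mixture:
#' each read comes from a new transcript with probability `labeled * theta`
#' (count Poisson with rate `exp(lambda_n)`), otherwise from the background
#' component (rate `exp(lambda_o)`). Uses the current RNG state, so results
#' are reproducible under `set.seed()`.
#'
#' @inheritParams mixture_log_pmf
#' @param n_reads Number of reads to draw.
#' @return Integer vector of length `n_reads` of mutation counts.
#' @export
simulate_gene_reads <- function(theta, lambda_n, lambda_o, n_reads,
                                labeled = TRUE) {
  if (length(theta) != 1 || !is.finite(theta) || theta < 0 || theta > 1) {
    abort("`theta` must be a single value in [0, 1].")
  }
  stopifnot(n_reads >= 0)
  if (n_reads == 0) return(integer(0))
  new_component <- rbinom(n_reads, 1L, as.numeric(labeled) * theta)
  rpois(n_reads, ifelse(new_component == 1L, exp(lambda_n), exp(lambda_o)))
}

resolve_truth_matrix <- function(x, n_genes, J, what) {
  if (is.matrix(x)) {
    stopifnot(nrow(x) == n_genes, ncol(x) == J)
    return(x)
  }
  matrix(rep_len(x, n_genes), nrow = n_genes, ncol = J)
}

#' Simulate a complete nucleotide-recoding RNA-seq experiment
#'
#' Generates, per condition and replicate, one s4U-labeled library and one
#' unlabeled control, emitting a per-read mutation table, a gene-by-sample
#' count matrix and the full ground truth (kinetic rates, fraction new,
#' gene-level mutation rates, SNP sites). Per-gene read depth is the
#' baseline depth scaled by relative steady-state expression
#' `N = ksyn/kdeg` (within-condition) and the library size factor, then
#' rounded, so a flat-expression, equal-depth configuration yields exactly
#' `reads_per_gene` reads per gene per library.
#'
#' When event-level output is on, each read covers a random window of the
#' gene; mixture-model mutations are placed at covered reference-T sites
#' away from read ends at base quality 41, heterozygous SNP sites mutate
#' reads in all libraries, and optional artifact events land near read ends
#' or at low base quality so that the mutation-calling filters have real
#' work to do.
#'
#' @param config A [sim_config()].
#' @return A list of class `tl_sim` with elements `reads`, `counts` (wide
#'   tibble, genes x samples), `truth`, `samples`, `snp_sites`, `config`.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "tl_sim_config"))
  set.seed(config$seed)
  G <- config$n_genes
  J <- length(config$conditions)
  genes <- if (G > 0) sprintf("gene%04d", seq_len(G)) else character(0)

  kdeg <- if (is.null(config$kdeg_truth)) {
    matrix(rlnorm(G, log(0.25), 0.5), nrow = G, ncol = J)
  } else {
    resolve_truth_matrix(config$kdeg_truth, G, J, "kdeg")
  }
  ksyn <- if (is.null(config$ksyn_truth)) {
    n_base <- rlnorm(G, 0, 0.5)
    matrix(rep(n_base * kdeg[, 1], J), nrow = G, ncol = J)
  } else {
    resolve_truth_matrix(config$ksyn_truth, G, J, "ksyn")
  }
  stopifnot(all(kdeg >= 0), all(ksyn >= 0))
  theta <- 1 - exp(-kdeg * config$labeling_time_t)

  z_o <- rnorm(G)
  lambda_o_gene <- config$lambda_o_bar + config$sigma_o * z_o
  z_n <- matrix(rnorm(G * J), nrow = G, ncol = J)
  lambda_n_gene <- sweep(config$sigma_n * t(z_n), 1,
                         config$lambda_n_bar, "+") |> t()

  truth <- tibble(
    gene_id = rep(genes, times = J),
    condition = rep(config$conditions, each = G),
    theta = as.vector(theta),
    kdeg = as.vector(kdeg),
    ksyn = as.vector(ksyn),
    lambda_n = as.vector(lambda_n_gene),
    lambda_o = rep(lambda_o_gene, times = J)
  )

  samples <- tidyr::expand_grid(
    condition = config$conditions,
    replicate = seq_len(config$replicates_per_condition),
    s4u = c(1L, 0L)
  ) %>%
    mutate(
      sample_id = sprintf("%s_rep%d_%s", .data$condition, .data$replicate,
                          if_else(.data$s4u == 1L, "s4U", "ctrl")),
      lib_factor = rlnorm(n(), 0, config$library_sd)
    ) %>%
    select("sample_id", "condition", "replicate", "s4u", "lib_factor")

  # SNP sites and per-gene reference-T geometry (only when events requested)
  n_sites <- max(1L, round(config$t_site_density * config$gene_length))
  site_list <- snp_list <- vector("list", G)
  if (config$emit_events && G > 0) {
    for (g in seq_len(G)) {
      sites <- sort(sample.int(config$gene_length, n_sites) - 1L)
      is_snp <- rbinom(n_sites, 1L, config$snp_fraction) == 1L
      site_list[[g]] <- sites
      snp_list[[g]] <- sites[is_snp]
    }
  }
  snp_sites <- tibble(
    gene_id = rep(genes, times = vapply(snp_list, length, integer(1))),
    ref_pos = as.integer(unlist(snp_list) %||% integer(0))
  )

  N <- ksyn / ifelse(kdeg > 0, kdeg, 1)
  rel_expr <- if (G > 0) {
    sweep(N, 2, colMeans(N), "/")
  } else {
    N
  }

  read_chunks <- vector("list", nrow(samples))
  count_cols <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    smp <- samples[i, ]
    j <- match(smp$condition, config$conditions)
    n_reads <- as.integer(round(config$reads_per_gene * rel_expr[, j] *
                                  smp$lib_factor))
    count_cols[[i]] <- n_reads
    if (G == 0 || sum(n_reads) == 0) {
      read_chunks[[i]] <- NULL
      next
    }
    gene_idx <- rep(seq_len(G), times = n_reads)
    th <- theta[gene_idx, j] * smp$s4u
    new_component <- rbinom(length(gene_idx), 1L, th)
    rate <- exp(ifelse(new_component == 1L,
                       lambda_n_gene[gene_idx, j],
                       lambda_o_gene[gene_idx]))
    tc <- rpois(length(gene_idx), rate)
    chunk <- tibble(
      sample_id = smp$sample_id,
      condition = smp$condition,
      replicate = smp$replicate,
      s4u = smp$s4u,
      gene_id = genes[gene_idx],
      read_id = sprintf("%s_r%06d", smp$sample_id, seq_along(gene_idx)),
      tc = as.integer(tc),
      n_t_sites = n_sites
    )
    if (config$emit_events) {
      chunk <- place_read_events(chunk, gene_idx, site_list, snp_list, config)
    }
    read_chunks[[i]] <- chunk
  }

  reads <- bind_rows(read_chunks)
  if (nrow(reads) == 0) {
    reads <- tibble(
      sample_id = character(0), condition = character(0),
      replicate = integer(0), s4u = integer(0), gene_id = character(0),
      read_id = character(0), tc = integer(0), n_t_sites = integer(0)
    )
  }

  counts <- tibble(gene_id = genes)
  for (i in seq_len(nrow(samples))) {
    counts[[samples$sample_id[i]]] <- count_cols[[i]] %||% integer(0)
  }

  structure(
    list(reads = reads, counts = counts, truth = truth, samples = samples,
         snp_sites = snp_sites, config = config),
    class = "tl_sim"
  )
}

# Assign event-level detail (positions, qualities, end offsets) to the reads
# of one library. Model mutations go to covered non-SNP reference-T sites at
# least 3 nt from either read end, at base quality 41; SNP sites mutate reads
# with probability snp_mut_prob; artifact events violate the end-offset or
# base-quality rules on purpose.
place_read_events <- function(chunk, gene_idx, site_list, snp_list, config) {
  rl <- config$read_length
  gl <- config$gene_length
  n <- nrow(chunk)
  starts <- sample.int(gl - rl + 1L, n, replace = TRUE) - 1L
  n_end <- rpois(n, config$end_artifact_rate)
  n_lowq <- rpois(n, config$low_quality_rate)
  events <- character(n)
  tc_placed <- integer(n)
  n_t <- integer(n)
  for (i in seq_len(n)) {
    g <- gene_idx[i]
    s0 <- starts[i]
    sites <- site_list[[g]]
    covered <- sites[sites >= s0 & sites < s0 + rl]
    n_t[i] <- length(covered)
    off5 <- covered - s0
    off3 <- rl - 1L - off5
    snp_cov <- covered[covered %in% snp_list[[g]]]
    eligible <- covered[off5 >= 3L & off3 >= 3L & !(covered %in% snp_cov)]

    ev_pos <- integer(0); ev_q <- integer(0)
    k <- min(chunk$tc[i], length(eligible))
    if (k > 0) {
      pos <- eligible[sample.int(length(eligible), k)]
      ev_pos <- c(ev_pos, pos); ev_q <- c(ev_q, rep(41L, k))
    }
    tc_placed[i] <- k
    if (length(snp_cov) > 0) {
      hit <- snp_cov[rbinom(length(snp_cov), 1L, config$snp_mut_prob) == 1L]
      ev_pos <- c(ev_pos, hit); ev_q <- c(ev_q, rep(41L, length(hit)))
    }
    if (n_end[i] > 0) {
      off <- sample(0:2, n_end[i], replace = TRUE)
      from5 <- rbinom(n_end[i], 1L, 0.5) == 1L
      pos <- ifelse(from5, s0 + off, s0 + rl - 1L - off)
      ev_pos <- c(ev_pos, pos); ev_q <- c(ev_q, rep(41L, n_end[i]))
    }
    if (n_lowq[i] > 0) {
      pos <- s0 + sample(3:(rl - 4L), n_lowq[i], replace = TRUE)
      ev_pos <- c(ev_pos, pos)
      ev_q <- c(ev_q, sample(20:39, n_lowq[i], replace = TRUE))
    }
    if (length(ev_pos) > 0) {
      o5 <- ev_pos - s0
      events[i] <- paste(sprintf("%d:%d:%d:%d", ev_pos, ev_q, o5,
                                 rl - 1L - o5), collapse = ";")
    }
  }
  chunk$tc <- tc_placed
  chunk$n_t_sites <- n_t
  chunk$events <- events
  chunk$read_start <- starts
  chunk$read_len <- rl
  chunk
}

#' Extract the gene-by-sample count matrix of a simulated dataset
#'
#' @param x A `tl_sim` object or a wide counts tibble whose first column is
#'   `gene_id`.
#' @return An integer matrix with gene rownames and sample colnames.
#' @export
count_matrix <- function(x) {
  counts <- if (inherits(x, "tl_sim")) x$counts else x
  stopifnot(is.data.frame(counts), "gene_id" %in% names(counts))
  m <- as.matrix(counts[setdiff(names(counts), "gene_id")])
  storage.mode(m) <- "integer"
  rownames(m) <- counts$gene_id
  m
}

#' @export
print.tl_sim <- function(x, ...) {
  cat(sprintf(
    "<tl_sim> %d genes, %d samples (%s), %d reads, labeling t = %g h\n",
    x$config$n_genes, nrow(x$samples),
    paste(x$config$conditions, collapse = "/"),
    nrow(x$reads), x$config$labeling_time_t
  ))
  invisible(x)
}
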