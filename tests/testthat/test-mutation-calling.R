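test_that("proper-pair selection keeps exactly the 83/163 and 99/147 pairs", {
  reads <- tibble::tibble(
    read_id = sprintf("r%d", 1:10),
    flag = c(99, 83, 77, 99, 163, 147, 355, 99, 83, 113),
    mate_flag = c(147, 163, 141, 147, 83, 99, 403, 147, 163, 177)
  )
  kept <- select_proper_pairs(reads)
  expect_identical(kept$read_id,
                   c("r1", "r2", "r4", "r5", "r6", "r8", "r9"))
  stats <- attr(kept, "pair_filter")
  expect_identical(unname(stats[c("kept", "dropped")]), c(7L, 3L))
  # malformed flags are skipped with a warning
  bad <- tibble::tibble(read_id = "x", flag = NA_integer_, mate_flag = 99L)
  expect_warning(out <- select_proper_pairs(bad), "malformed")
  expect_identical(nrow(out), 0L)
})

test_that("quality and end-proximity filters reproduce hand enumeration", {
  # quality below 40 is excluded even far from the ends
  expect_identical(
    filter_mutations(events_tbl(list(q = 39, o5 = 10, o3 = 80))), 0L
  )
  # within 3 nt of the 3' end is excluded despite high quality
  expect_identical(
    filter_mutations(events_tbl(list(q = 41, o5 = 88, o3 = 2))), 0L
  )
  # offsets 0,1,2 excluded; offset 3 retained (strict less-than-3 rule)
  expect_identical(
    filter_mutations(events_tbl(list(q = 41, o5 = 2, o3 = 88))), 0L
  )
  expect_identical(
    filter_mutations(events_tbl(list(q = 41, o5 = 3, o3 = 88))), 1L
  )
  # quality exactly 40 is retained (threshold is "less than 40")
  expect_identical(
    filter_mutations(events_tbl(list(q = 40, o5 = 10, o3 = 10))), 1L
  )
  # three events: q41/off10 kept, q41/off1 dropped, q39/off10 dropped
  ev <- events_tbl(list(q = 41, o5 = 10, o3 = 80),
                   list(q = 41, o5 = 1, o3 = 89),
                   list(q = 39, o5 = 12, o3 = 78))
  expect_identical(filter_mutations(ev), 1L)
  # non-T>C mismatches never count
  ev2 <- events_tbl(list(q = 41, o5 = 10, o3 = 80, ref = "G", alt = "A"))
  expect_identical(filter_mutations(ev2), 0L)
  expect_error(
    filter_mutations(events_tbl(list(q = 41, o5 = -1, o3 = 80))),
    "non-negative"
  )
})

test_that("SNP-masked sites are excluded from the count", {
  ev <- events_tbl(list(q = 41, o5 = 10, o3 = 80, pos = 55),
                   list(q = 41, o5 = 20, o3 = 70, pos = 60))
  mask <- tibble::tibble(gene_id = "gX", ref_pos = 55L)
  expect_identical(filter_mutations(ev, snp_mask = mask, gene_id = "gX"),
                   1L)
  expect_identical(filter_mutations(ev, snp_mask = mask, gene_id = "gY"),
                   2L)
})

test_that("filtering is monotone in both thresholds", {
  set.seed(41)
  for (i in 1:25) {
    n <- sample(1:8, 1)
    ev <- tibble::tibble(
      ref_pos = sample(0:99, n),
      base_quality = sample(25:41, n, replace = TRUE),
      offset_from_5p = sample(0:49, n, replace = TRUE),
      ref_base = "T", alt_base = "C"
    )
    ev$offset_from_3p <- 99L - ev$offset_from_5p
    base <- filter_mutations(ev, min_quality = 30, end_exclusion_nt = 1)
    for (q in c(35, 40, 42)) {
      for (e in c(2, 3, 6)) {
        expect_lte(filter_mutations(ev, min_quality = q,
                                    end_exclusion_nt = e), base)
      }
    }
  }
})

test_that("binomial SNP test reproduces hand-computed tails", {
  # 25/50 mutated control reads at background 0.001: tail << 0.05
  sc <- tibble::tibble(gene_id = "g", ref_pos = 1L,
                       mutations = 25L, coverage = 50L)
  mask <- identify_snp_sites(sc, background_rate = 0.001)
  expect_identical(nrow(mask), 1L)
  expect_lt(mask$p_value, 1e-20)
  # 0/50: tail probability 1, never masked
  sc0 <- tibble::tibble(gene_id = "g", ref_pos = 2L,
                        mutations = 0L, coverage = 50L)
  expect_identical(nrow(identify_snp_sites(sc0, background_rate = 0.001)),
                   0L)
  # 1/10 at background 0.1: tail = 1 - (1-0.1)^10 ~ 0.651, not masked
  sc1 <- tibble::tibble(gene_id = "g", ref_pos = 3L,
                        mutations = 1L, coverage = 10L)
  m1 <- identify_snp_sites(sc1, background_rate = 0.1)
  expect_identical(nrow(m1), 0L)
  expect_equal(pbinom(0, 10, 0.1, lower.tail = FALSE), 0.6513216,
               tolerance = 1e-6)
})

test_that("alpha extremes behave as degenerate masks", {
  set.seed(7)
  sc <- tibble::tibble(
    gene_id = "g", ref_pos = 1:30,
    mutations = c(rpois(28, 0.5), 20L, 0L),
    coverage = 40L
  )
  sc$mutations <- pmin(sc$mutations, sc$coverage)
  expect_identical(nrow(identify_snp_sites(sc, background_rate = 0.01,
                                           alpha = 0)), 0L)
  m_all <- identify_snp_sites(sc, background_rate = 0.01, alpha = 1)
  expect_identical(sort(m_all$ref_pos),
                   sort(sc$ref_pos[sc$mutations >= 1]))
  expect_error(identify_snp_sites(sc, background_rate = 1.5), "0, 1")
})

test_that("external blacklists merge into the mask", {
  sc <- tibble::tibble(gene_id = "g", ref_pos = 1L,
                       mutations = 30L, coverage = 50L)
  bl <- tibble::tibble(gene_id = c("g", "h"), ref_pos = c(1L, 9L))
  mask <- identify_snp_sites(sc, background_rate = 0.001, blacklist = bl)
  expect_identical(nrow(mask), 2L)
  expect_setequal(mask$source, c("binomial", "blacklist"))
})

test_that("injected SNP sites are recovered from simulated controls", {
  cfg <- sim_config(n_genes = 200, reads_per_gene = 60,
                    snp_fraction = 0.01, seed = 77)
  sim <- simulate_experiment(cfg)
  ctrl <- dplyr::filter(sim$reads, s4u == 0)
  sites <- site_mutation_counts(ctrl)
  mask <- identify_snp_sites(sites, alpha = 0.05)
  deep <- dplyr::semi_join(
    dplyr::filter(sites, coverage >= 50),
    sim$snp_sites, by = c("gene_id", "ref_pos")
  )
  found <- dplyr::semi_join(deep, mask, by = c("gene_id", "ref_pos"))
  expect_gte(nrow(sim$snp_sites), 10)  # fixture actually plants SNPs
  expect_gte(nrow(found) / nrow(deep), 0.95)
})

test_that("count_mutations handles empty and all-filtered streams", {
  empty <- tibble::tibble(sample_id = character(0),
                          condition = character(0), s4u = integer(0),
                          gene_id = character(0), read_id = character(0),
                          tc = integer(0))
  out <- count_mutations(empty)
  expect_identical(nrow(out), 0L)
  expect_named(out, c("sample_id", "condition", "s4u", "gene_id",
                      "read_id", "tc"))
  # reads whose events all fail filters stay as rows with tc = 0
  reads <- tibble::tibble(
    sample_id = "s1", condition = "A", s4u = 1L, gene_id = "g1",
    read_id = c("r1", "r2"),
    tc = 1L, n_t_sites = 10L,
    events = c("5:39:10:80", "7:41:1:89")
  )
  out2 <- count_mutations(reads)
  expect_identical(out2$tc, c(0L, 0L))
  expect_identical(nrow(out2), 2L)
})

test_that("reads from unknown samples are dropped with a warning", {
  reads <- tibble::tibble(
    sample_id = c("known", "unknown"), gene_id = "g", read_id = c("a", "b"),
    tc = 1L
  )
  meta <- tibble::tibble(sample_id = "known", condition = "A", s4u = 1L)
  expect_warning(out <- count_mutations(reads, sample_meta = meta),
                 "dropped")
  expect_identical(out$read_id, "a")
  expect_identical(attr(out, "dropped_reads"), 1L)
})

test_that("pooled control mutation rate matches the background truth", {
  cfg <- sim_config(n_genes = 50, reads_per_gene = 400,
                    replicates_per_condition = 2, conditions = "WT",
                    sigma_n = 0, sigma_o = 0, library_sd = 0, seed = 13)
  sim <- simulate_experiment(cfg)
  ctrl <- dplyr::filter(sim$reads, s4u == 0)
  rate <- mean(ctrl$tc)
  se <- sqrt(exp(-3) / nrow(ctrl))
  expect_lt(abs(rate - exp(-3)), 3 * se)
})
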