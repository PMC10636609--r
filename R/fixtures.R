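#' Write a simulated dataset to a directory of plain-text files
#'
#' Serializes every table of a [simulate_experiment()] result as
#' tab-separated text plus a YAML snapshot of the generating configuration,
#' so that a fixture bundle round-trips losslessly through
#' [read_fixture_bundle()] and can be consumed by the command-line pipeline.
#'
#' @param dataset A `tl_sim` object.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the file paths written.
#' @export
write_fixture_bundle <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "tl_sim"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("Cannot create output directory '%s'.", out_dir))
  }
  paths <- c(
    reads = file.path(out_dir, "reads.tsv"),
    counts = file.path(out_dir, "counts.tsv"),
    truth = file.path(out_dir, "truth.tsv"),
    samples = file.path(out_dir, "samples.tsv"),
    snp_sites = file.path(out_dir, "snp_sites.tsv"),
    config = file.path(out_dir, "config.yaml")
  )
  readr::write_tsv(dataset$reads, paths[["reads"]])
  readr::write_tsv(dataset$counts, paths[["counts"]])
  readr::write_tsv(dataset$truth, paths[["truth"]])
  readr::write_tsv(dataset$samples, paths[["samples"]])
  readr::write_tsv(dataset$snp_sites, paths[["snp_sites"]])
  cfg <- unclass(dataset$config)
  cfg$reads_per_gene <- as.numeric(cfg$reads_per_gene)
  # yaml serializes named atomic vectors as plain sequences; keep the
  # per-condition names by writing maps
  cfg$lambda_n_bar <- as.list(cfg$lambda_n_bar)
  cfg$sigma_n <- as.list(cfg$sigma_n)
  for (nm in c("kdeg_truth", "ksyn_truth")) {
    if (is.matrix(cfg[[nm]])) cfg[[nm]] <- as.data.frame(cfg[[nm]])
  }
  yaml::write_yaml(cfg, paths[["config"]])
  invisible(paths)
}

#' Read a fixture bundle written by [write_fixture_bundle()]
#'
#' @param dir Directory containing the bundle.
#' @return A list of class `tl_sim` equivalent to the written dataset.
#' @export
read_fixture_bundle <- function(dir) {
  path <- function(f) file.path(dir, f)
  if (!file.exists(path("reads.tsv"))) {
    abort(sprintf("'%s' does not look like a fixture bundle.", dir))
  }
  spec_reads <- readr::cols(
    sample_id = "c", condition = "c", replicate = "i", s4u = "i",
    gene_id = "c", read_id = "c", tc = "i", n_t_sites = "i",
    .default = readr::col_guess()
  )
  reads <- readr::read_tsv(path("reads.tsv"), col_types = spec_reads,
                           progress = FALSE)
  if ("events" %in% names(reads)) {
    reads$events <- dplyr::coalesce(as.character(reads$events), "")
  }
  counts <- readr::read_tsv(path("counts.tsv"),
                            col_types = readr::cols(gene_id = "c",
                                                    .default = "i"),
                            progress = FALSE)
  truth <- readr::read_tsv(path("truth.tsv"),
                           col_types = readr::cols(gene_id = "c",
                                                   condition = "c",
                                                   .default = "d"),
                           progress = FALSE)
  samples <- readr::read_tsv(path("samples.tsv"),
                             col_types = readr::cols(sample_id = "c",
                                                     condition = "c",
                                                     replicate = "i",
                                                     s4u = "i",
                                                     .default = "d"),
                             progress = FALSE)
  snp_sites <- readr::read_tsv(path("snp_sites.tsv"),
                               col_types = readr::cols(gene_id = "c",
                                                       ref_pos = "i"),
                               progress = FALSE)
  cfg <- yaml::read_yaml(path("config.yaml"))
  for (nm in c("kdeg_truth", "ksyn_truth")) {
    if (is.list(cfg[[nm]]) && length(cfg[[nm]])) {
      cfg[[nm]] <- as.matrix(as.data.frame(cfg[[nm]]))
      dimnames(cfg[[nm]]) <- NULL
    }
  }
  cfg$lambda_n_bar <- unlist(cfg$lambda_n_bar)
  cfg$sigma_n <- unlist(cfg$sigma_n)
  class(cfg) <- "tl_sim_config"
  structure(
    list(reads = reads, counts = counts, truth = truth, samples = samples,
         snp_sites = snp_sites, config = cfg),
    class = "tl_sim"
  )
}
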