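# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except files the helpers themselves write to tempdirs.

events_tbl <- function(...) {
  # build an event table from quality/offset rows:
  # ev(q = 41, o5 = 10, o3 = 80, pos = 0, ref = "T", alt = "C")
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(
      ref_pos = r$pos %||% 0L,
      base_quality = r$q,
      offset_from_5p = r$o5,
      offset_from_3p = r$o3,
      ref_base = r$ref %||% "T",
      alt_base = r$alt %||% "C"
    )
  }))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# A small mutation table drawn straight from the mixture model, bypassing
# the event layer: one labeled + one control library per condition.
make_mutation_table <- function(n_genes, reads, theta, lambda_n = -1,
                                lambda_o = -3, conditions = "A",
                                seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  theta <- rep_len(theta, n_genes)
  out <- list()
  for (cond in conditions) {
    for (lab in c(1L, 0L)) {
      sid <- paste0(cond, if (lab == 1) "_s4U" else "_ctrl")
      for (g in seq_len(n_genes)) {
        tc <- simulate_gene_reads(theta[g], lambda_n, lambda_o, reads,
                                  labeled = lab == 1L)
        out[[length(out) + 1]] <- tibble::tibble(
          sample_id = sid, condition = cond, s4u = lab,
          gene_id = genes[g],
          read_id = sprintf("%s_%s_%d", sid, genes[g], seq_len(reads)),
          tc = tc
        )
      }
    }
  }
  dplyr::bind_rows(out)
}

# Hand-built two-gene SAM file with MD tags. geneA: chr1:1001-1100 (+),
# geneB: chr1:2001-2100 (-). Returns the SAM path and a GRanges annotation.
write_test_sam <- function(records,
                           path = tempfile(fileext = ".sam")) {
  header <- c("@HD\tVN:1.6\tSO:unsorted", "@SQ\tSN:chr1\tLN:10000")
  writeLines(c(header, records), path)
  path
}

test_annotation <- function() {
  GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(c(1001, 2001), c(1100, 2100)),
    strand = c("+", "-"),
    gene_id = c("geneA", "geneB")
  )
}

sam_record <- function(qname, flag, pos, seq, qual, md,
                       cigar = paste0(nchar(seq), "M"), mapq = 60,
                       rnext = "=", pnext = pos, tlen = 0) {
  paste(qname, flag, "chr1", pos, mapq, cigar, rnext, pnext, tlen,
        seq, qual, paste0("MD:Z:", md), sep = "\t")
}
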