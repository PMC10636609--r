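# Hand-built single-read SAM records with manually decoded MD tags; base
# quality "J" is phred 41, "5" is phred 20.

test_that("reads without mismatches yield empty event sets", {
  seq <- paste(rep("ACGT", 7), collapse = "")
  seq <- paste0(seq, "AC")   # 30 bases, 7 Ts
  sam <- write_test_sam(sam_record("r1", 99, 1010, seq,
                                   strrep("J", 30), "30"))
  reads <- parse_sam(sam, test_annotation(), sample_id = "s1")
  expect_identical(nrow(reads), 1L)
  expect_identical(reads$gene_id, "geneA")
  expect_null(reads$events[[1]])
  expect_identical(reads$n_t_sites, 7L)
  expect_identical(reads$read_start, 1009L)  # 0-based
})

test_that("a forward-strand T>C mismatch is reconstructed from the MD tag", {
  # 30M alignment at genomic 1020; ref T at aligned position 21 (1-based),
  # read shows C there: MD = 20T9
  seq <- paste0(strrep("A", 20), "C", strrep("A", 9))
  sam <- write_test_sam(sam_record("r2", 99, 1020, seq,
                                   strrep("J", 30), "20T9"))
  reads <- parse_sam(sam, test_annotation(), sample_id = "s1")
  ev <- reads$events[[1]]
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$ref_pos, 1039L)           # 0-based genomic
  expect_identical(ev$base_quality, 41L)
  expect_identical(ev$offset_from_5p, 20L)
  expect_identical(ev$offset_from_3p, 9L)
  expect_identical(ev$ref_base, "T")
  expect_identical(ev$alt_base, "C")
  # with the filters this read contributes tc = 1
  expect_identical(filter_mutations(ev), 1L)
})

test_that("minus-strand genes report genomic A>G as T-to-C", {
  # geneB is on the minus strand: an A>G genomic mismatch is a transcript
  # T-to-C conversion
  seq <- paste0(strrep("C", 5), "G", strrep("C", 24))
  sam <- write_test_sam(sam_record("r3", 99, 2010, seq,
                                   strrep("J", 30), "5A24"))
  reads <- parse_sam(sam, test_annotation(), sample_id = "s1")
  expect_identical(reads$gene_id, "geneB")
  ev <- reads$events[[1]]
  expect_identical(ev$ref_pos, 2014L)
  expect_identical(ev$ref_base, "T")
  expect_identical(ev$alt_base, "C")
  # the read itself carries one reference A (the mismatched site)
  expect_identical(reads$n_t_sites, 1L)
})

test_that("reverse-complemented alignments flip the end offsets", {
  # flag 83 sets the reverse bit: the sequenced 5' end is the right end of
  # the aligned segment
  seq <- paste0(strrep("A", 9), "C", strrep("A", 20))
  sam <- write_test_sam(sam_record("r4", 83, 1020, seq,
                                   strrep("J", 30), "9T20"))
  reads <- parse_sam(sam, test_annotation(), sample_id = "s1")
  ev <- reads$events[[1]]
  expect_identical(ev$offset_from_5p, 20L)   # 30 - 10
  expect_identical(ev$offset_from_3p, 9L)
})

test_that("low-quality bases carry their phred scores into events", {
  seq <- paste0(strrep("A", 20), "C", strrep("A", 9))
  qual <- paste0(strrep("J", 20), "5", strrep("J", 9))
  sam <- write_test_sam(sam_record("r5", 99, 1020, seq, qual, "20T9"))
  reads <- parse_sam(sam, test_annotation(), sample_id = "s1")
  ev <- reads$events[[1]]
  expect_identical(ev$base_quality, 20L)
  expect_identical(filter_mutations(ev), 0L)   # fails the quality-40 rule
})

test_that("reads lacking MD tags or gene overlap are dropped and counted", {
  seq <- strrep("A", 30)
  recs <- c(
    paste("nomd", 99, "chr1", 1010, 60, "30M", "=", 1010, 0, seq,
          strrep("J", 30), sep = "\t"),
    sam_record("nogene", 99, 5000, seq, strrep("J", 30), "30")
  )
  sam <- write_test_sam(recs)
  expect_warning(reads <- parse_sam(sam, test_annotation()), "skipped")
  expect_identical(nrow(reads), 0L)
  stats <- attr(reads, "parse_stats")
  expect_identical(unname(stats[["no_md"]]), 1L)
  expect_identical(unname(stats[["no_gene"]]), 1L)
})

test_that("mates are paired by query name and pass the pair filter", {
  seq <- strrep("A", 30)
  recs <- c(
    sam_record("pair1", 99, 1010, seq, strrep("J", 30), "30"),
    sam_record("pair1", 147, 1040, seq, strrep("J", 30), "30"),
    sam_record("orphan", 65, 1010, seq, strrep("J", 30), "30")
  )
  sam <- write_test_sam(recs)
  reads <- parse_sam(sam, test_annotation())
  p1 <- reads[reads$read_id == "pair1", ]
  expect_setequal(p1$mate_flag, c(147L, 99L))
  kept <- select_proper_pairs(reads[!is.na(reads$mate_flag), ])
  expect_identical(sort(kept$flag), c(99L, 147L))
  # deletions shift reference coordinates but not read offsets
  sam2 <- write_test_sam(sam_record("indel", 99, 1010,
                                    paste0(strrep("A", 19), "C",
                                           strrep("A", 10)),
                                    strrep("J", 30), "10^GG9T10",
                                    cigar = "10M2D20M"))
  r2 <- parse_sam(sam2, test_annotation())
  ev <- r2$events[[1]]
  # MD: 10 matches, 2-base deletion, 9 matches, then a T>C mismatch at the
  # 20th aligned base: read offset 19, genomic 1010+10+2+9 = 1031 (1-based)
  expect_identical(ev$ref_pos, 1030L)
  expect_identical(ev$offset_from_5p, 19L)
})

test_that("malformed SAM input raises a parse error", {
  bad <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "not a sam line at all"), bad)
  expect_error(suppressWarnings(parse_sam(bad, test_annotation())),
               "Malformed SAM line 2")
})
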