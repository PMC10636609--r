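#' Load gene intervals for read assignment
#'
#' Accepts a `GRanges` directly, or a BED / GTF file path imported through
#' `rtracklayer`. For GTF input, rows with `type == "gene"` are used when a
#' `type` column exists. Gene identifiers come from a `gene_id` metadata
#' column, then a `name` column, then the names of the ranges.
#'
#' @param annotation `GRanges` or file path.
#' @return A `GRanges` whose names are gene identifiers.
#' @export
load_gene_annotation <- function(annotation) {
  for (pkg in c("rtracklayer", "GenomicRanges", "S4Vectors")) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      abort(sprintf("Package '%s' is required for annotation import.", pkg))
    }
  }
  gr <- if (is.character(annotation)) {
    rtracklayer::import(annotation)
  } else {
    annotation
  }
  mc <- S4Vectors::mcols(gr)
  if (!is.null(mc$type) && any(mc$type == "gene")) {
    gr <- gr[mc$type == "gene"]
    mc <- S4Vectors::mcols(gr)
  }
  ids <- if (!is.null(mc$gene_id)) {
    as.character(mc$gene_id)
  } else if (!is.null(mc$name)) {
    as.character(mc$name)
  } else {
    names(gr)
  }
  if (is.null(ids) || anyNA(ids)) {
    abort("Annotation must carry gene identifiers (gene_id, name or names).")
  }
  names(gr) <- ids
  gr
}

#' Parse aligned reads into per-read T-to-C mutation evidence
#'
#' Reads a SAM/BAM file (MD tags required), reconstructs every reference
#' mismatch from the MD tag, CIGAR, sequence and base qualities, assigns
#' each read to a gene by interval overlap, and reports candidate T-to-C
#' events in transcriptional orientation: for a gene on the minus strand a
#' genomic A>G mismatch is a T-to-C conversion of the transcript. End
#' offsets are measured from the sequenced read's own 5'/3' ends (so for a
#' reverse-complemented alignment the 5' offset counts from the right end
#' of the aligned segment).
#'
#' @param path SAM or BAM file. SAM input is converted with
#'   `Rsamtools::asBam()` first.
#' @param annotation Gene intervals, see [load_gene_annotation()].
#' @param sample_id Sample label attached to every read (defaults to the
#'   file name).
#' @return A tibble with one row per gene-assigned read: `sample_id`,
#'   `gene_id`, `read_id`, `flag`, `mate_flag`, `events` (list-column of
#'   event tibbles with `ref_pos` 0-based genomic, `base_quality`,
#'   `offset_from_5p`, `offset_from_3p`, `ref_base`, `alt_base`),
#'   `n_t_sites`, `read_start`, `read_len`. Reads without an MD tag or
#'   without a unique gene assignment are dropped; counts are in the
#'   `"parse_stats"` attribute.
#' @export
parse_sam <- function(path, annotation, sample_id = NULL) {
  for (pkg in c("Rsamtools", "GenomicRanges", "IRanges", "S4Vectors")) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      abort(sprintf("Package '%s' is required for SAM/BAM parsing.", pkg))
    }
  }
  stopifnot(file.exists(path))
  sample_id <- sample_id %||% sub("\\.(sam|bam)$", "", basename(path))
  genes <- load_gene_annotation(annotation)

  bam <- if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    body <- readLines(path, warn = FALSE)
    is_aln <- !startsWith(body, "@")
    n_fields <- lengths(strsplit(body[is_aln], "\t", fixed = TRUE))
    if (any(n_fields < 11)) {
      abort(sprintf("Malformed SAM line %d in '%s' (fewer than 11 fields).",
                    which(is_aln)[which(n_fields < 11)[1]], path))
    }
    tryCatch(
      Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                       indexDestination = FALSE),
      error = function(e) abort(sprintf("Malformed SAM '%s': %s", path,
                                        conditionMessage(e)))
    )
  } else {
    path
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "qwidth", "cigar", "seq",
             "qual"),
    tag = "MD"
  )
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(x$qname)
  stats <- c(total = n, no_md = 0L, unmapped = 0L, no_gene = 0L,
             ambiguous = 0L)
  if (n == 0) {
    out <- tibble(sample_id = character(0), gene_id = character(0),
                  read_id = character(0), flag = integer(0),
                  mate_flag = integer(0), events = list(),
                  n_t_sites = integer(0), read_start = integer(0),
                  read_len = integer(0))
    attr(out, "parse_stats") <- stats
    return(out)
  }

  seqs <- as.character(x$seq)
  quals <- as.character(x$qual)
  md <- x$tag$MD
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    if (is.na(x$pos[i]) || is.na(x$rname[i])) {
      stats[["unmapped"]] <- stats[["unmapped"]] + 1L
      next
    }
    if (is.null(md) || is.na(md[i])) {
      stats[["no_md"]] <- stats[["no_md"]] + 1L
      next
    }
    aln <- walk_alignment(x$cigar[i], x$pos[i], seqs[i], md[i])
    if (is.null(aln)) {
      stats[["no_md"]] <- stats[["no_md"]] + 1L
      next
    }
    span <- GenomicRanges::GRanges(
      as.character(x$rname[i]),
      IRanges::IRanges(x$pos[i], x$pos[i] + aln$ref_width - 1L)
    )
    hit <- GenomicRanges::findOverlaps(span, genes, ignore.strand = TRUE)
    hit_genes <- unique(S4Vectors::subjectHits(hit))
    if (length(hit_genes) == 0) {
      stats[["no_gene"]] <- stats[["no_gene"]] + 1L
      next
    }
    if (length(hit_genes) > 1) {
      stats[["ambiguous"]] <- stats[["ambiguous"]] + 1L
      next
    }
    g <- hit_genes[1]
    gene_id <- names(genes)[g]
    minus <- as.character(GenomicRanges::strand(genes)[g]) == "-"
    ref_t <- if (minus) "A" else "T"
    alt_c <- if (minus) "G" else "C"

    qw <- x$qwidth[i]
    reverse_read <- bitwAnd(x$flag[i], 16L) != 0L
    qv <- utf8ToInt(quals[i]) - 33L
    n_t <- sum(aln$ref == ref_t)

    is_tc <- aln$ref == ref_t & aln$read == alt_c
    ev <- if (any(is_tc)) {
      qpos <- aln$qpos[is_tc]
      off5 <- if (reverse_read) qw - qpos else qpos - 1L
      tibble(
        ref_pos = aln$rpos[is_tc] - 1L,
        base_quality = qv[qpos],
        offset_from_5p = as.integer(off5),
        offset_from_3p = as.integer(qw - 1L - off5),
        ref_base = "T",
        alt_base = "C"
      )
    } else {
      NULL
    }
    rows[[i]] <- tibble(
      sample_id = sample_id, gene_id = gene_id, read_id = x$qname[i],
      flag = x$flag[i], events = list(ev), n_t_sites = n_t,
      read_start = x$pos[i] - 1L, read_len = aln$ref_width
    )
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(sample_id = character(0), gene_id = character(0),
                  read_id = character(0), flag = integer(0),
                  events = list(), n_t_sites = integer(0),
                  read_start = integer(0), read_len = integer(0))
  }
  # mate flag: pair records that share a query name
  mate <- out %>%
    group_by(.data$read_id) %>%
    mutate(mate_flag = if (n() == 2) rev(.data$flag) else NA_integer_) %>%
    ungroup() %>%
    pull(.data$mate_flag)
  out$mate_flag <- mate
  out <- out[, c("sample_id", "gene_id", "read_id", "flag", "mate_flag",
                 "events", "n_t_sites", "read_start", "read_len")]
  dropped <- stats[["no_md"]] + stats[["unmapped"]]
  if (dropped > 0) {
    warn(sprintf("%d read(s) skipped (unmapped or missing MD tag).",
                 dropped))
  }
  attr(out, "parse_stats") <- stats
  out
}

# Walk CIGAR + MD to recover, for every aligned (non-clipped, non-inserted)
# read base: its 1-based position in SEQ (qpos), 1-based reference
# coordinate (rpos), the read base, and the inferred reference base.
walk_alignment <- function(cigar, pos, seq, md) {
  ops_len <- as.integer(regmatches(cigar, gregexpr("\\d+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  if (length(ops) == 0 || length(ops) != length(ops_len)) return(NULL)
  qpos <- integer(0)
  rpos <- integer(0)
  q <- 1L
  r <- pos
  for (k in seq_along(ops)) {
    len <- ops_len[k]
    op <- ops[k]
    if (op %in% c("M", "=", "X")) {
      qpos <- c(qpos, seq.int(q, length.out = len))
      rpos <- c(rpos, seq.int(r, length.out = len))
      q <- q + len
      r <- r + len
    } else if (op %in% c("I", "S")) {
      q <- q + len
    } else if (op %in% c("D", "N")) {
      r <- r + len
    }
  }
  read_bases <- strsplit(seq, "")[[1]][qpos]
  ref_bases <- read_bases
  toks <- regmatches(md, gregexpr("[0-9]+|\\^[A-Za-z]+|[A-Za-z]",
                                  md))[[1]]
  i <- 1L
  for (tok in toks) {
    if (grepl("^[0-9]+$", tok)) {
      i <- i + as.integer(tok)
    } else if (startsWith(tok, "^")) {
      # deleted reference bases: consume nothing from the aligned vector
    } else {
      if (i > length(ref_bases)) return(NULL)
      ref_bases[i] <- toupper(tok)
      i <- i + 1L
    }
  }
  list(qpos = qpos, rpos = rpos, read = read_bases, ref = ref_bases,
       ref_width = r - pos)
}
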