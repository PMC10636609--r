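#' Keep only uniquely mapped, properly paired reads
#'
#' Retains read pairs whose pair of SAM flags is exactly \{83, 163\} or
#' \{99, 147\} — the two orientations of a proper, uniquely mapped
#' forward/reverse pair — and drops everything else. The number of dropped
#' pairs and of records with malformed flags is attached as the
#' `"pair_filter"` attribute and reported via a message.
#'
#' @param records A data frame of reads carrying integer columns `flag` and
#'   `mate_flag`.
#' @return The retained rows, with a `pair_filter` attribute listing
#'   `kept`, `dropped` and `malformed` counts.
#' @export
select_proper_pairs <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("flag", "mate_flag") %in% names(records)))
  f1 <- suppressWarnings(as.integer(records$flag))
  f2 <- suppressWarnings(as.integer(records$mate_flag))
  malformed <- is.na(f1) | is.na(f2)
  lo <- pmin(f1, f2)
  hi <- pmax(f1, f2)
  ok <- !malformed & ((lo == 83L & hi == 163L) | (lo == 99L & hi == 147L))
  ok[is.na(ok)] <- FALSE
  out <- records[ok, , drop = FALSE]
  stats <- c(kept = sum(ok),
             dropped = sum(!ok & !malformed),
             malformed = sum(malformed))
  if (stats[["malformed"]] > 0) {
    warn(sprintf("%d record(s) with malformed SAM flags skipped.",
                 stats[["malformed"]]))
  }
  attr(out, "pair_filter") <- stats
  out
}

#' Count the T-to-C mutations on one read that survive all filters
#'
#' An event is retained if and only if it is a reference-T to read-C
#' mismatch, its base quality is at least `min_quality`, it lies at least
#' `end_exclusion_nt` nucleotides from both read ends, and its site is not
#' in the SNP mask. The defaults (quality 40, 3 nt) are the thresholds the
#' chemistry and typical Illumina error profiles motivate: real
#' recoding-induced mutations are high-confidence internal mismatches,
#' whereas end-proximal and low-quality mismatches are dominated by
#' artifacts.
#'
#' @param events A data frame of candidate events with columns `ref_pos`,
#'   `base_quality`, `offset_from_5p`, `offset_from_3p` and optionally
#'   `ref_base` / `alt_base` (assumed T>C when absent, as in synthetic
#'   tables that only record T-to-C candidates).
#' @param min_quality Minimum phred base quality (events below are dropped).
#' @param end_exclusion_nt Events with either end offset strictly smaller
#'   than this are dropped; the default 3 excludes offsets 0, 1, 2.
#' @param snp_mask Optional SNP mask (see [identify_snp_sites()]) or any
#'   data frame with columns `gene_id`, `ref_pos`.
#' @param gene_id Gene the read is assigned to; required to apply a mask.
#' @return The integer count of retained events (`tc`).
#' @export
filter_mutations <- function(events, min_quality = 40, end_exclusion_nt = 3,
                             snp_mask = NULL, gene_id = NULL) {
  if (is.null(events) || nrow(events) == 0) return(0L)
  if (any(events$offset_from_5p < 0) || any(events$offset_from_3p < 0)) {
    abort("Event offsets must be non-negative.")
  }
  keep <- events$base_quality >= min_quality &
    pmin(events$offset_from_5p, events$offset_from_3p) >= end_exclusion_nt
  if ("ref_base" %in% names(events)) {
    keep <- keep & events$ref_base == "T" & events$alt_base == "C"
  }
  if (!is.null(snp_mask) && nrow(snp_mask) > 0 && !is.null(gene_id)) {
    masked <- snp_mask$ref_pos[snp_mask$gene_id == gene_id]
    keep <- keep & !(events$ref_pos %in% masked)
  }
  sum(keep)
}

#' Identify SNP and artifact sites from unlabeled control libraries
#'
#' A genuine heterozygous SNP or recurrent alignment artifact produces
#' T-to-C mismatches in control libraries that never saw s4U, at a rate far
#' above the sequencing-error background. A site is masked when the
#' one-sided binomial tail probability of seeing at least the observed
#' number of mutated control reads, given its control coverage and the
#' background per-read per-site mutation rate, falls below `alpha`.
#'
#' When `background_rate` is not supplied it is estimated as the pooled
#' control mutation fraction; sites masked in a first pass are excluded and
#' the rate re-estimated once, so a handful of strong SNPs cannot inflate
#' the background against which the remaining sites are judged.
#'
#' @param site_counts Per-site control evidence: data frame with columns
#'   `gene_id`, `ref_pos`, `mutations` (mutated control reads) and
#'   `coverage` (control reads covering the site). See
#'   [site_mutation_counts()].
#' @param background_rate Per-read probability of a background mutation at a
#'   single site, in (0, 1); estimated from the data when `NULL`.
#' @param alpha Binomial tail threshold below which a site is masked.
#' @param blacklist Optional externally supplied variant sites (data frame
#'   with `gene_id`, `ref_pos`), e.g. from a variant caller; merged into the
#'   mask unconditionally.
#' @return A tibble of class `tl_snp_mask` with one row per masked site:
#'   `gene_id`, `ref_pos`, `mutations`, `coverage`, `p_value`, `source`.
#' @export
identify_snp_sites <- function(site_counts, background_rate = NULL,
                               alpha = 0.05, blacklist = NULL) {
  stopifnot(is.data.frame(site_counts))
  if (!is.null(background_rate) &&
      (background_rate <= 0 || background_rate >= 1)) {
    abort("`background_rate` must lie strictly inside (0, 1).")
  }
  empty <- tibble(gene_id = character(0), ref_pos = integer(0),
                  mutations = integer(0), coverage = integer(0),
                  p_value = numeric(0), source = character(0))
  sc <- as_tibble(site_counts)
  tail_p <- function(rate) {
    pbinom(sc$mutations - 1, sc$coverage, rate, lower.tail = FALSE)
  }
  if (nrow(sc) > 0) {
    stopifnot(all(sc$coverage >= 1), all(sc$mutations <= sc$coverage))
    if (is.null(background_rate)) {
      bg <- max(sum(sc$mutations) / sum(sc$coverage), 1e-6)
      first_pass <- tail_p(bg) < alpha
      if (any(first_pass) && !all(first_pass)) {
        bg <- max(sum(sc$mutations[!first_pass]) /
                    sum(sc$coverage[!first_pass]), 1e-6)
      }
      background_rate <- min(bg, 1 - 1e-6)
    }
    p <- tail_p(background_rate)
    mask <- sc[p < alpha, , drop = FALSE]
    mask$p_value <- p[p < alpha]
    mask$source <- "binomial"
  } else {
    mask <- empty
    background_rate <- background_rate %||% NA_real_
  }
  if (!is.null(blacklist) && nrow(blacklist) > 0) {
    extra <- as_tibble(blacklist) %>%
      select("gene_id", "ref_pos") %>%
      anti_join(mask, by = c("gene_id", "ref_pos")) %>%
      mutate(mutations = NA_integer_, coverage = NA_integer_,
             p_value = NA_real_, source = "blacklist")
    mask <- bind_rows(mask, extra)
  }
  out <- arrange(as_tibble(mask), .data$gene_id, .data$ref_pos)
  attr(out, "background_rate") <- background_rate
  attr(out, "alpha") <- alpha
  class(out) <- c("tl_snp_mask", class(out))
  out
}

#' Tally per-site mutation evidence from a read table with events
#'
#' Aggregates a per-read table (typically the unlabeled controls) into
#' per-site mutated-read counts and coverage, the input to
#' [identify_snp_sites()]. Coverage is computed from the read spans
#' (`read_start`, `read_len` columns); mutated reads from the event
#' positions.
#'
#' @param reads Per-read table with `gene_id`, `events`,
#'   `read_start`, `read_len` columns (as produced by
#'   [simulate_experiment()] with events on, or [parse_sam()]).
#' @return Tibble with `gene_id`, `ref_pos`, `mutations`, `coverage` for
#'   every site carrying at least one mutated read.
#' @export
site_mutation_counts <- function(reads) {
  stopifnot(is.data.frame(reads),
            all(c("gene_id", "read_start", "read_len") %in% names(reads)))
  ev <- unnest_events(reads)
  if (nrow(ev) == 0) {
    return(tibble(gene_id = character(0), ref_pos = integer(0),
                  mutations = integer(0), coverage = integer(0)))
  }
  hits <- ev %>%
    distinct(.data$gene_id, .data$ref_pos, .data$.read) %>%
    count(.data$gene_id, .data$ref_pos, name = "mutations")
  starts_by_gene <- split(reads$read_start, reads$gene_id)
  ends_by_gene <- split(reads$read_start + reads$read_len, reads$gene_id)
  hits$coverage <- vapply(seq_len(nrow(hits)), function(i) {
    s <- starts_by_gene[[hits$gene_id[i]]]
    e <- ends_by_gene[[hits$gene_id[i]]]
    sum(s <= hits$ref_pos[i] & hits$ref_pos[i] < e)
  }, integer(1))
  hits
}

# Expand the per-read `events` column (string "pos:qual:off5:off3;..." or a
# list-column of data frames) into one row per event, tagged with the source
# read's row index (.read).
unnest_events <- function(reads) {
  empty <- tibble(.read = integer(0), gene_id = character(0),
                  ref_pos = integer(0), base_quality = integer(0),
                  offset_from_5p = integer(0), offset_from_3p = integer(0))
  if (nrow(reads) == 0 || !("events" %in% names(reads))) return(empty)
  if (is.list(reads$events)) {
    ev <- reads %>%
      mutate(.read = row_number()) %>%
      select(".read", "gene_id", "events") %>%
      filter(!vapply(.data$events, is.null, logical(1))) %>%
      unnest("events")
    return(ev)
  }
  has <- !is.na(reads$events) & reads$events != ""
  if (!any(has)) return(empty)
  idx <- which(has)
  parts <- strsplit(reads$events[idx], ";", fixed = TRUE)
  n_ev <- lengths(parts)
  fields <- strsplit(unlist(parts), ":", fixed = TRUE)
  m <- matrix(as.integer(unlist(fields)), ncol = 4, byrow = TRUE)
  tibble(
    .read = rep(idx, times = n_ev),
    gene_id = rep(reads$gene_id[idx], times = n_ev),
    ref_pos = m[, 1],
    base_quality = m[, 2],
    offset_from_5p = m[, 3],
    offset_from_3p = m[, 4]
  )
}

#' Apply the mutation filters to a read table and produce per-read tc counts
#'
#' The workhorse of mutation calling: applies [filter_mutations()] to every
#' read of a stream, joins sample metadata (condition, s4U status), and
#' returns the per-read mutation count table consumed by the kinetic model.
#' Reads whose events all fail the filters are retained with `tc = 0` —
#' a read without mutations is still an observation, and discarding it
#' would bias the fraction-new estimate upward.
#'
#' Tables without event-level detail (no `events` column) are passed
#' through with their existing `tc`, since there is nothing to filter.
#'
#' @param reads Per-read table with `sample_id`, `gene_id`, `read_id` and
#'   either an `events` column or a precomputed `tc` column.
#' @param snp_mask Optional `tl_snp_mask` (or `gene_id`/`ref_pos` data
#'   frame) of sites to ignore.
#' @param sample_meta Data frame mapping `sample_id` to `condition` and
#'   `s4u`; defaults to those columns of `reads` when present.
#' @param min_quality,end_exclusion_nt Passed to [filter_mutations()].
#' @return A tibble (`sample_id`, `condition`, `s4u`, `gene_id`, `read_id`,
#'   `tc`) with one row per retained read. Reads whose `sample_id` is
#'   missing from `sample_meta` are dropped with a warning; the count is in
#'   the `"dropped_reads"` attribute.
#' @export
count_mutations <- function(reads, snp_mask = NULL, sample_meta = NULL,
                            min_quality = 40, end_exclusion_nt = 3) {
  stopifnot(is.data.frame(reads))
  if (is.null(sample_meta)) {
    if (!all(c("condition", "s4u") %in% names(reads))) {
      abort("Provide `sample_meta` or `condition`/`s4u` columns in `reads`.")
    }
    sample_meta <- distinct(reads, .data$sample_id, .data$condition,
                            .data$s4u)
  }
  out_cols <- c("sample_id", "condition", "s4u", "gene_id", "read_id", "tc")
  if (nrow(reads) == 0) {
    out <- tibble(sample_id = character(0), condition = character(0),
                  s4u = integer(0), gene_id = character(0),
                  read_id = character(0), tc = integer(0))
    attr(out, "dropped_reads") <- 0L
    return(out)
  }

  if (!("events" %in% names(reads))) {
    stopifnot("tc" %in% names(reads))
    kept <- reads
  } else {
    ev <- unnest_events(reads)
    if (nrow(ev) > 0 && (any(ev$offset_from_5p < 0) ||
                         any(ev$offset_from_3p < 0))) {
      abort("Event offsets must be non-negative.")
    }
    keep <- ev$base_quality >= min_quality &
      pmin(ev$offset_from_5p, ev$offset_from_3p) >= end_exclusion_nt
    if ("ref_base" %in% names(ev)) {
      keep <- keep & ev$ref_base == "T" & ev$alt_base == "C"
    }
    if (!is.null(snp_mask) && nrow(snp_mask) > 0) {
      key <- paste(ev$gene_id, ev$ref_pos)
      keep <- keep & !(key %in% paste(snp_mask$gene_id, snp_mask$ref_pos))
    }
    tc_new <- tabulate(ev$.read[keep], nbins = nrow(reads))
    kept <- reads
    kept$tc <- as.integer(tc_new)
  }

  meta <- distinct(as_tibble(sample_meta), .data$sample_id, .data$condition,
                   .data$s4u)
  kept <- kept[setdiff(names(kept), c("condition", "s4u"))]
  joined <- inner_join(kept, meta, by = "sample_id")
  dropped <- nrow(kept) - nrow(joined)
  if (dropped > 0) {
    warn(sprintf("%d read(s) dropped: sample_id missing from sample_meta.",
                 dropped))
  }
  out <- as_tibble(joined[, out_cols])
  out$tc <- as.integer(out$tc)
  attr(out, "dropped_reads") <- dropped
  out
}
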