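#' Quantification settings for targeted bisulfite counts
#'
#' @param min_coverage Minimum merged read depth for a CpG to be called;
#'   probes below threshold become missing and are later imputed by
#'   [harmonize_to_panel()]. Default 10, a standard floor for targeted
#'   panels; set 1 to call every observed CpG.
#' @param strand_mode `"merge_cpg"` (default): reads reported on the reverse
#'   strand cytosine (position + 1) are summed into the forward-strand CpG,
#'   matching strand-agnostic array beta values. `"forward_only"` uses
#'   forward-strand records as-is.
#' @param dialect Coordinate convention of coverage files, see
#'   [read_coverage_file()].
#' @return A `quant_config` list.
#' @export
quant_config <- function(min_coverage = 10,
                         strand_mode = c("merge_cpg", "forward_only"),
                         dialect = c("one_based_inclusive",
                                     "zero_based_half_open")) {
  strand_mode <- match.arg(strand_mode)
  dialect <- match.arg(dialect)
  stopifnot(min_coverage >= 1)
  structure(list(min_coverage = as.integer(min_coverage),
                 strand_mode = strand_mode, dialect = dialect),
            class = "quant_config")
}

#' Read a Bismark-style coverage file
#'
#' Parses the 6-column coverage format (chrom, start, end, percent
#' methylation, methylated count, unmethylated count) into per-CpG count
#' records with coordinates normalised to the 1-based position of the
#' cytosine. Malformed rows and negative counts raise an error naming the
#' line.
#'
#' @param path Path to a headerless coverage file.
#' @param dialect `"one_based_inclusive"` (start is already the 1-based
#'   cytosine, Bismark's convention) or `"zero_based_half_open"` (BED-like,
#'   position = start + 1).
#' @return A `meth_counts` tibble: `chrom`, `position`, `count_methylated`,
#'   `count_unmethylated`.
#' @export
read_coverage_file <- function(path,
                               dialect = c("one_based_inclusive",
                                           "zero_based_half_open")) {
  dialect <- match.arg(dialect)
  raw <- suppressWarnings(
    readr::read_tsv(path, col_names = c("chrom", "start", "end", "pct",
                                        "m", "u"),
                    col_types = "ciidii", progress = FALSE)
  )
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    stop(sprintf("malformed coverage row at line %d of '%s' (%s)",
                 prob$row[1], path, prob$expected[1]), call. = FALSE)
  }
  bad <- which(is.na(raw$m) | is.na(raw$u) | raw$m < 0 | raw$u < 0)
  if (length(bad) > 0) {
    stop(sprintf("negative or missing count at line %d of '%s'",
                 bad[1], path), call. = FALSE)
  }
  position <- if (dialect == "one_based_inclusive") raw$start
              else raw$start + 1L
  tibble::tibble(chrom = raw$chrom, position = as.integer(position),
                 count_methylated = raw$m, count_unmethylated = raw$u)
}

#' Merge reverse-strand CpG records into the forward-strand position
#'
#' CpG methylation is symmetric across strands; a record at `position + 1`
#' of a manifest CpG is the reverse-strand cytosine of the same dinucleotide
#' and its counts are summed into the forward position. Records not
#' adjacent to a manifest CpG are left unchanged; the operation is
#' idempotent and conserves total reads. Duplicate records at one position
#' (multi-lane merges) are summed with a warning.
#'
#' @param counts A `meth_counts` tibble.
#' @param manifest Probe manifest defining forward-strand CpG positions.
#' @return A merged `meth_counts` tibble.
#' @export
merge_strands <- function(counts, manifest) {
  validate_manifest(manifest)
  fwd <- paste(manifest$chrom, manifest$position)
  key <- paste(counts$chrom, counts$position)
  rev_key <- paste(counts$chrom, counts$position - 1L)
  is_rev <- !(key %in% fwd) & (rev_key %in% fwd)
  pos <- ifelse(is_rev, counts$position - 1L, counts$position)
  if (anyDuplicated(key) > 0) {
    warning("duplicate records at one position were summed", call. = FALSE)
  }
  dplyr::tibble(chrom = counts$chrom, position = as.integer(pos),
                count_methylated = counts$count_methylated,
                count_unmethylated = counts$count_unmethylated) |>
    dplyr::group_by(.data$chrom, .data$position) |>
    dplyr::summarise(count_methylated = sum(.data$count_methylated),
                     count_unmethylated = sum(.data$count_unmethylated),
                     .groups = "drop") |>
    dplyr::arrange(.data$chrom, .data$position)
}

#' Convert per-CpG counts into a classifier-ready beta row
#'
#' Computes the methylation ratio beta = M / (M + U) for every panel probe
#' whose (strand-merged) coverage reaches `min_coverage`; probes below
#' threshold or absent from the counts become missing, to be imputed by
#' [harmonize_to_panel()] against the trained model. A per-probe coverage
#' report is attached as the `"coverage_report"` attribute.
#'
#' @param counts A `meth_counts` tibble (one sample).
#' @param manifest Probe manifest with panel coordinates.
#' @param panel Character vector of panel probe ids.
#' @param cfg A [quant_config()].
#' @param sample_id Sample id for the resulting row.
#' @return A one-row beta tibble over the panel probes.
#' @export
counts_to_beta <- function(counts, manifest, panel, cfg = quant_config(),
                           sample_id = "sample") {
  stopifnot(inherits(cfg, "quant_config"))
  validate_manifest(manifest)
  missing_coord <- setdiff(panel, manifest$probe_id)
  if (length(missing_coord) > 0) {
    stop("panel probes without manifest coordinates: ",
         paste(head(missing_coord, 5), collapse = ", "), call. = FALSE)
  }
  if (cfg$strand_mode == "merge_cpg") {
    counts <- merge_strands(counts, manifest)
  }
  coords <- manifest[match(panel, manifest$probe_id),
                     c("probe_id", "chrom", "position")]
  joined <- dplyr::left_join(coords, counts, by = c("chrom", "position"))
  coverage <- joined$count_methylated + joined$count_unmethylated
  if (all(is.na(coverage))) {
    stop("no overlap between counts and the panel", call. = FALSE)
  }
  called <- !is.na(coverage) & coverage >= cfg$min_coverage
  beta <- ifelse(called, joined$count_methylated / coverage, NA_real_)

  row <- tibble::as_tibble(as.list(stats::setNames(beta, panel)))
  res <- dplyr::bind_cols(tibble::tibble(sample_id = sample_id), row)
  attr(res, "coverage_report") <- tibble::tibble(
    probe_id = panel,
    coverage = ifelse(is.na(coverage), 0L, as.integer(coverage)),
    count_methylated = joined$count_methylated,
    count_unmethylated = joined$count_unmethylated,
    called = called
  )
  res
}
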