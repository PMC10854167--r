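#' Read a methylation beta-value matrix from a delimited file
#'
#' Reads a tab-delimited table of methylation beta values (fraction
#' methylated, in \[0, 1\]) with one header row and one id column. Array
#' exports come in both orientations, so `orientation` states whether rows
#' are samples (the package's on-disk convention) or probes; the result is
#' always samples in rows. Empty cells and `NA` become missing values.
#'
#' @param path Path to a TSV file.
#' @param orientation `"samples_in_rows"` (default) or `"probes_in_rows"`.
#' @return A beta tibble: `sample_id` column plus one numeric column per
#'   probe, validated with [validate_beta()].
#' @export
read_beta_matrix <- function(path,
                             orientation = c("samples_in_rows",
                                             "probes_in_rows")) {
  orientation <- match.arg(orientation)
  raw <- suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_double()
  ), na = c("", "NA"), progress = FALSE, name_repair = "minimal"))
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    stop(sprintf("non-numeric cell at line %d, column %d of '%s'",
                 prob$row[1] + 1L, prob$col[1], path), call. = FALSE)
  }
  names(raw)[1] <- if (orientation == "samples_in_rows") "sample_id" else "probe_id"
  if (orientation == "probes_in_rows") {
    m <- as.matrix(raw[, -1, drop = FALSE])
    rownames(m) <- raw$probe_id
    raw <- matrix_to_beta(t(m))
  }
  validate_beta(raw)
  raw
}

#' Write a beta-value matrix to disk
#'
#' Samples in rows, probes in columns, tab-delimited, `NA` for missing.
#' Values round-trip through [read_beta_matrix()] to within 1e-10.
#'
#' @param beta A beta tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path) {
  validate_beta(beta)
  readr::write_tsv(beta, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read sample class labels
#'
#' Two-column TSV mapping `sample_id` to `class` (cancer type or merged
#' cohort). Sample ids must be unique.
#'
#' @param path Path to a TSV with columns `sample_id`, `class`.
#' @return A tibble with columns `sample_id` and `class`.
#' @export
read_sample_labels <- function(path) {
  lab <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  names(lab)[1:2] <- c("sample_id", "class")
  if (anyDuplicated(lab$sample_id)) {
    stop("duplicate sample ids in labels file", call. = FALSE)
  }
  if (nrow(lab) == 0) stop("empty labels file", call. = FALSE)
  lab
}

#' @rdname read_sample_labels
#' @param labels A labels tibble.
#' @export
write_sample_labels <- function(labels, path) {
  readr::write_tsv(labels[, c("sample_id", "class")], path, progress = FALSE)
  invisible(path)
}

#' Read a probe manifest
#'
#' A manifest maps each probe id to the genomic coordinate of its CpG:
#' 1-based position of the cytosine of the CpG dinucleotide on the forward
#' strand (the array-manifest convention — count files may be 0- or 1-based
#' and are normalised on read, see [read_coverage_file()]).
#'
#' @param path TSV with columns `probe_id`, `chrom`, `position`, `strand`.
#' @return A manifest tibble.
#' @export
read_probe_manifest <- function(path) {
  man <- readr::read_tsv(path, col_types = "ccic", progress = FALSE)
  names(man)[1:4] <- c("probe_id", "chrom", "position", "strand")
  validate_manifest(man)
  man
}

#' @rdname read_probe_manifest
#' @param manifest A manifest tibble.
#' @export
write_probe_manifest <- function(manifest, path) {
  readr::write_tsv(manifest[, c("probe_id", "chrom", "position", "strand")],
                   path, progress = FALSE)
  invisible(path)
}

validate_manifest <- function(manifest) {
  stopifnot(all(c("probe_id", "chrom", "position") %in% names(manifest)))
  if (anyDuplicated(manifest$probe_id)) {
    stop("duplicate probe ids in manifest", call. = FALSE)
  }
  if (anyDuplicated(manifest[, c("chrom", "position")])) {
    stop("duplicate (chrom, position) in manifest", call. = FALSE)
  }
  if (any(manifest$position < 1)) {
    stop("manifest positions must be >= 1", call. = FALSE)
  }
  invisible(manifest)
}

#' Harmonize a beta matrix to a trained panel
#'
#' Restricts and reorders a beta matrix to exactly the probes of a panel, in
#' panel order. Probes absent from the input (e.g. a 450K-designed probe
#' scored on an EPIC array, or a low-coverage CpG from a sequencing panel)
#' are filled according to `impute`; missing cells within present probes are
#' filled the same way. Imputed cells are recorded in the `"imputed"`
#' attribute of the result so provenance is never silent.
#'
#' @param beta A beta tibble.
#' @param panel Character vector of probe ids, in panel order.
#' @param impute `"training_mean"` (default; requires `impute_values`),
#'   `"constant"`, or `"fail"`.
#' @param impute_values Named numeric vector of per-probe training-set means
#'   (as stored in a fitted classifier).
#' @param constant Fill value for `impute = "constant"`.
#' @return A beta tibble with exactly the panel's probes in panel order and
#'   attribute `imputed` (tibble of `sample_id`, `probe_id`, `reason`).
#' @export
harmonize_to_panel <- function(beta, panel,
                               impute = c("training_mean", "constant", "fail"),
                               impute_values = NULL, constant = 0.5) {
  impute <- match.arg(impute)
  validate_beta(beta)
  absent <- setdiff(panel, probe_ids(beta))
  if (impute == "fail" && length(absent) > 0) {
    stop("probes missing from input: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  if (impute == "training_mean") {
    if (is.null(impute_values)) {
      stop("impute = 'training_mean' requires impute_values", call. = FALSE)
    }
    uncovered <- setdiff(panel, names(impute_values))
    fill <- impute_values
  } else {
    fill <- stats::setNames(rep(constant, length(panel)), panel)
    uncovered <- character()
  }

  m <- beta_to_matrix(beta)
  out <- matrix(NA_real_, nrow(m), length(panel),
                dimnames = list(rownames(m), panel))
  present <- intersect(panel, colnames(m))
  out[, present] <- m[, present, drop = FALSE]

  imputed <- tibble::tibble(sample_id = character(), probe_id = character(),
                            reason = character())
  if (impute != "fail") {
    na_cells <- which(is.na(out), arr.ind = TRUE)
    if (nrow(na_cells) > 0) {
      pid <- colnames(out)[na_cells[, 2]]
      need <- intersect(unique(pid), uncovered)
      if (length(need) > 0) {
        stop("no imputation value stored for probes: ",
             paste(need, collapse = ", "), call. = FALSE)
      }
      out[na_cells] <- fill[pid]
      imputed <- tibble::tibble(
        sample_id = rownames(out)[na_cells[, 1]],
        probe_id = pid,
        reason = ifelse(pid %in% absent, "probe_absent", "missing_value")
      )
    }
  }
  res <- matrix_to_beta(out)
  attr(res, "imputed") <- imputed
  res
}
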