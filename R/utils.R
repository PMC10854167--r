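# Internal helpers shared across the package.

# Deterministic fan-out of one user-facing seed into per-stage seeds.
# Small string hash keeps derived seeds independent across stages while
# staying inside R's 32-bit integer range.
derive_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483647L
  as.integer((as.numeric(seed) + h) %% 2147483647L)
}

# A beta matrix travels as a tibble: first column `sample_id`, one numeric
# column per probe. These two convert to/from the base matrix used by the
# numeric kernels.
beta_to_matrix <- function(beta) {
  stopifnot(is.data.frame(beta), names(beta)[1] == "sample_id")
  m <- as.matrix(beta[, -1, drop = FALSE])
  rownames(m) <- beta$sample_id
  storage.mode(m) <- "double"
  m
}

matrix_to_beta <- function(m) {
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)), out)
}

#' Validate a beta-value tibble
#'
#' Checks the invariants of the samples-by-probes methylation table used
#' throughout the package: a `sample_id` first column with unique ids,
#' unique probe columns, and all non-missing values in \[0, 1\].
#'
#' @param beta A tibble with a `sample_id` column and one numeric column per
#'   CpG probe.
#' @return `beta`, invisibly, if valid; otherwise an error.
#' @export
validate_beta <- function(beta) {
  if (!is.data.frame(beta) || names(beta)[1] != "sample_id") {
    stop("beta matrix must be a data frame with first column 'sample_id'",
         call. = FALSE)
  }
  if (anyDuplicated(beta$sample_id)) {
    stop("duplicate sample ids: ",
         paste(unique(beta$sample_id[duplicated(beta$sample_id)]),
               collapse = ", "), call. = FALSE)
  }
  probes <- names(beta)[-1]
  if (anyDuplicated(probes)) {
    stop("duplicate probe ids: ",
         paste(unique(probes[duplicated(probes)]), collapse = ", "),
         call. = FALSE)
  }
  m <- beta_to_matrix(beta)
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "beta values outside [0,1]: first offending cell sample '%s', probe '%s' (%g)",
      rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]], m[bad[1, 1], bad[1, 2]]
    ), call. = FALSE)
  }
  invisible(beta)
}

# align a labels tibble (sample_id, class) to the rows of a beta tibble,
# returning a factor with sorted class levels
align_labels <- function(beta, labels) {
  stopifnot(all(c("sample_id", "class") %in% names(labels)))
  if (anyDuplicated(labels$sample_id)) {
    stop("duplicate sample ids in labels", call. = FALSE)
  }
  miss <- setdiff(beta$sample_id, labels$sample_id)
  if (length(miss) > 0) {
    stop("samples without labels: ", paste(head(miss, 5), collapse = ", "),
         call. = FALSE)
  }
  cls <- labels$class[match(beta$sample_id, labels$sample_id)]
  factor(cls, levels = sort(unique(labels$class)))
}

probe_ids <- function(beta) names(beta)[-1]
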