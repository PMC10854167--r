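#' Configuration for the synthetic methylation cohort generator
#'
#' The generator plants a stated world in which every downstream stage is
#' testable with known ground truth: a multi-class tumour cohort measured on
#' an array-like probe set, with class-specific differentially methylated
#' CpGs on a bimodal background. Defaults describe an 8-class cohort of 40
#' samples per class over 5000 probes with 20 informative CpGs per class
#' shifted by 0.35 in mean beta — strong, clean class signal of the kind a
#' pan-cancer 450K cohort exhibits at its most informative CpGs.
#'
#' Per-sample noise is a beta distribution parameterised by mean `m` and
#' precision `phi` (shape1 = m*phi, shape2 = (1-m)*phi): bounded on \[0, 1\]
#' and heteroscedastic like array beta values. `precision = 30` gives
#' SD ~ 0.09 at beta = 0.5, shrinking toward the extremes. Background probe
#' baselines are a low/high mixture (means ~0.15 / ~0.85) mirroring the
#' global bimodality of methylation arrays; `bimodal_mix` is the fraction of
#' high-baseline probes.
#'
#' @param n_classes Number of tumour classes.
#' @param samples_per_class Samples per class.
#' @param n_probes Total probes on the synthetic platform.
#' @param informative_per_class Planted differentially methylated probes per
#'   class (disjoint across classes).
#' @param effect_delta Mean beta shift of a planted probe in its class, in
#'   (0, 1). The shift direction is chosen to keep the class mean in range;
#'   all planted means are clipped to \[0.02, 0.98\].
#' @param precision Concentration of the per-sample beta noise.
#' @param bimodal_mix Fraction of background probes with a high baseline.
#' @param missing_rate Fraction of cells set to missing, uniformly at random.
#' @param seed Integer seed; fully determines the generated cohort.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_classes = 8, samples_per_class = 40, n_probes = 5000,
                       informative_per_class = 20, effect_delta = 0.35,
                       precision = 30, bimodal_mix = 0.4, missing_rate = 0,
                       seed = 1) {
  cfg <- list(n_classes = as.integer(n_classes),
              samples_per_class = as.integer(samples_per_class),
              n_probes = as.integer(n_probes),
              informative_per_class = as.integer(informative_per_class),
              effect_delta = effect_delta, precision = precision,
              bimodal_mix = bimodal_mix, missing_rate = missing_rate,
              seed = as.integer(seed))
  stopifnot(cfg$n_classes >= 2, cfg$samples_per_class >= 1, cfg$n_probes >= 1,
            cfg$informative_per_class >= 0,
            cfg$effect_delta >= 0, cfg$effect_delta < 1,
            cfg$precision > 0, cfg$bimodal_mix >= 0, cfg$bimodal_mix <= 1,
            cfg$missing_rate >= 0, cfg$missing_rate < 1)
  if (cfg$informative_per_class * cfg$n_classes > cfg$n_probes) {
    stop("informative_per_class * n_classes exceeds n_probes", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic multi-class methylation cohort
#'
#' Draws a cohort under the model described in [sim_config()]: background
#' probe baselines from a low/high beta mixture, planted class-specific
#' shifts of `effect_delta`, beta-distributed per-sample noise with the
#' configured precision, optional missingness, and a synthetic manifest with
#' evenly spaced coordinates plus CpG-island and gene-model tracks so the
#' annotation stage is exercisable too.
#'
#' @param cfg A [sim_config()].
#' @return A `meth_simulation` list with elements `beta` (beta tibble),
#'   `labels` (sample_id, class), `truth` (planted probe map and configured
#'   means), `manifest`, `cgi` (island intervals), `genes` (gene models) and
#'   `config`.
#' @export
simulate_methylation <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::local_seed(cfg$seed)

  k <- cfg$n_classes
  n <- k * cfg$samples_per_class
  p <- cfg$n_probes
  classes <- sprintf("C%02d", seq_len(k))
  samples <- sprintf("S%04d", seq_len(n))
  probes <- sprintf("cg%07d", seq_len(p))
  cls <- rep(classes, each = cfg$samples_per_class)

  high <- runif(p) < cfg$bimodal_mix
  baseline <- ifelse(high, rbeta(p, 17, 3), rbeta(p, 3, 17))
  baseline <- pmin(pmax(baseline, 0.02), 0.98)

  n_inf <- cfg$informative_per_class
  planted_idx <- if (n_inf > 0) sample(p, n_inf * k) else integer()
  planted <- split(probes[planted_idx], rep(classes, each = n_inf))

  # class mean per (class, probe): baseline everywhere except each class's
  # planted probes, shifted up when room allows, else down
  mu <- matrix(baseline, nrow = k, ncol = p, byrow = TRUE,
               dimnames = list(classes, probes))
  if (n_inf > 0) {
    for (ci in seq_len(k)) {
      idx <- planted_idx[seq((ci - 1) * n_inf + 1, ci * n_inf)]
      up <- baseline[idx] + cfg$effect_delta <= 0.98
      shifted <- ifelse(up, baseline[idx] + cfg$effect_delta,
                        baseline[idx] - cfg$effect_delta)
      mu[ci, idx] <- pmin(pmax(shifted, 0.02), 0.98)
    }
  }

  mu_samples <- mu[match(cls, classes), , drop = FALSE]
  phi <- cfg$precision
  vals <- matrix(rbeta(n * p, c(mu_samples) * phi, (1 - c(mu_samples)) * phi),
                 nrow = n, ncol = p, dimnames = list(samples, probes))
  if (cfg$missing_rate > 0) {
    vals[runif(n * p) < cfg$missing_rate] <- NA_real_
  }

  # synthetic genome: probes round-robin over 22 chromosomes, 500 bp apart;
  # every 5th probe of a chromosome sits inside a 301 bp island
  chrom <- paste0("chr", ((seq_len(p) - 1) %% 22) + 1)
  within_idx <- ((seq_len(p) - 1) %/% 22) + 1
  position <- 10000L + within_idx * 500L
  manifest <- tibble::tibble(probe_id = probes, chrom = chrom,
                             position = as.integer(position), strand = "+")
  in_island <- within_idx %% 5L == 0L
  cgi <- tibble::tibble(chrom = chrom[in_island],
                        start = position[in_island] - 150L,
                        end = position[in_island] + 150L) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$chrom, .data$start)

  # sparse synthetic gene models: a + strand gene anchored every 20th probe
  anchor <- which(within_idx %% 20L == 3L)
  genes <- tibble::tibble(
    gene = sprintf("G%05d", seq_along(anchor)),
    chrom = chrom[anchor], strand = "+",
    tss = as.integer(position[anchor]),
    utr5_start = as.integer(position[anchor] + 1L),
    utr5_end = as.integer(position[anchor] + 200L),
    first_exon_start = as.integer(position[anchor] + 201L),
    first_exon_end = as.integer(position[anchor] + 600L),
    body_start = as.integer(position[anchor] + 601L),
    body_end = as.integer(position[anchor] + 4000L),
    utr3_start = as.integer(position[anchor] + 4001L),
    utr3_end = as.integer(position[anchor] + 4500L)
  )

  truth <- list(
    planted = planted,
    baseline_mean = stats::setNames(baseline, probes),
    class_means = tibble::as_tibble(as.data.frame.table(
      mu, responseName = "mean", stringsAsFactors = FALSE
    )) |>
      stats::setNames(c("class", "probe_id", "mean"))
  )

  structure(list(beta = matrix_to_beta(vals),
                 labels = tibble::tibble(sample_id = samples, class = cls),
                 truth = truth, manifest = manifest, cgi = cgi, genes = genes,
                 config = cfg),
            class = "meth_simulation")
}

#' Drop a random subset of probes, emulating a platform mismatch
#'
#' Keeps a seeded uniform sample of `ceiling(keep_fraction * n_probes)`
#' probes and removes the rest entirely, as happens when a panel designed on
#' one array generation is scored on another.
#'
#' @param beta A beta tibble.
#' @param keep_fraction Fraction of probes to retain, in (0, 1\].
#' @param seed Integer seed.
#' @return A beta tibble with the retained probes in their original order.
#' @export
apply_platform_dropout <- function(beta, keep_fraction, seed = 1) {
  stopifnot(keep_fraction > 0, keep_fraction <= 1)
  probes <- probe_ids(beta)
  n_keep <- ceiling(keep_fraction * length(probes))
  if (n_keep == length(probes)) return(beta)
  withr::local_seed(as.integer(seed))
  keep <- sort(sample(length(probes), n_keep))
  beta[, c(1L, keep + 1L), drop = FALSE]
}

#' Simulate targeted bisulfite sequencing counts from beta values
#'
#' For every (sample, probe) with a non-missing beta value, draws a total
#' coverage from a Poisson with the given mean (floored at 1 read) and a
#' methylated read count from a binomial with success probability beta —
#' the count-level data a targeted bisulfite panel produces. Probes with
#' missing beta are omitted for that sample.
#'
#' @param beta A beta tibble.
#' @param manifest Probe manifest supplying coordinates.
#' @param mean_coverage Mean read depth per CpG (>= 1).
#' @param seed Integer seed.
#' @return A tibble of count records: `sample_id`, `probe_id`, `chrom`,
#'   `position`, `count_methylated`, `count_unmethylated`.
#' @export
simulate_bisulfite_counts <- function(beta, manifest, mean_coverage = 200,
                                      seed = 1) {
  stopifnot(mean_coverage >= 1)
  validate_manifest(manifest)
  m <- beta_to_matrix(beta)
  miss <- setdiff(colnames(m), manifest$probe_id)
  if (length(miss) > 0) {
    stop("probes absent from manifest: ", paste(head(miss, 5), collapse = ", "),
         call. = FALSE)
  }
  withr::local_seed(as.integer(seed))
  long <- tidyr::pivot_longer(matrix_to_beta(m), -"sample_id",
                              names_to = "probe_id", values_to = "beta") |>
    dplyr::filter(!is.na(.data$beta))
  cov <- pmax(1L, rpois(nrow(long), mean_coverage))
  meth <- rbinom(nrow(long), cov, long$beta)
  long |>
    dplyr::left_join(manifest[, c("probe_id", "chrom", "position")],
                     by = "probe_id") |>
    dplyr::transmute(.data$sample_id, .data$probe_id, .data$chrom,
                     .data$position,
                     count_methylated = meth,
                     count_unmethylated = cov - meth)
}

#' Write count records for one sample in Bismark coverage format
#'
#' Six tab-separated columns without header: chrom, start, end, percent
#' methylation, methylated count, unmethylated count. `dialect` controls the
#' coordinate convention of the start column.
#'
#' @param counts Count records for a single sample (as produced by
#'   [simulate_bisulfite_counts()], filtered to one `sample_id`).
#' @param path Output path.
#' @param dialect `"one_based_inclusive"` (Bismark's own convention) or
#'   `"zero_based_half_open"` (BED-like exports).
#' @return `path`, invisibly.
#' @export
write_coverage_file <- function(counts, path,
                                dialect = c("one_based_inclusive",
                                            "zero_based_half_open")) {
  dialect <- match.arg(dialect)
  if ("sample_id" %in% names(counts) &&
      length(unique(counts$sample_id)) > 1) {
    stop("coverage files are per-sample; filter to one sample_id first",
         call. = FALSE)
  }
  total <- counts$count_methylated + counts$count_unmethylated
  start <- if (dialect == "one_based_inclusive") counts$position
           else counts$position - 1L
  out <- tibble::tibble(chrom = counts$chrom, start = start,
                        end = counts$position,
                        pct = 100 * counts$count_methylated / pmax(total, 1L),
                        m = counts$count_methylated,
                        u = counts$count_unmethylated)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
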