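#' Read genomic interval and gene-model tracks
#'
#' `read_bed_intervals()` parses a BED file (0-based, half-open) and
#' converts to the package's internal 1-based inclusive intervals at the
#' module boundary. `read_gene_models()` reads a simplified gene-model TSV
#' with one row per gene: `gene`, `chrom`, `strand`, `tss`, and 1-based
#' inclusive interval columns `utr5_start/utr5_end`,
#' `first_exon_start/first_exon_end`, `body_start/body_end`,
#' `utr3_start/utr3_end` (NA when a gene lacks the region).
#'
#' @param path File path.
#' @return A tibble of intervals (`chrom`, `start`, `end`) or gene models.
#' @export
read_bed_intervals <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           readr::col_character(), readr::col_integer(),
                           readr::col_integer(), .default = readr::col_skip()
                         ))
  names(raw)[1:3] <- c("chrom", "start", "end")
  if (any(raw$start >= raw$end) || any(raw$start < 0)) {
    stop("invalid BED intervals (need 0 <= start < end)", call. = FALSE)
  }
  tibble::tibble(chrom = raw$chrom, start = raw$start + 1L, end = raw$end)
}

#' @rdname read_bed_intervals
#' @export
read_gene_models <- function(path) {
  genes <- readr::read_tsv(path, progress = FALSE,
                           col_types = readr::cols(
                             gene = "c", chrom = "c", strand = "c",
                             .default = readr::col_integer()
                           ))
  needed <- c("gene", "chrom", "strand", "tss")
  if (!all(needed %in% names(genes))) {
    stop("gene model file needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  genes
}

CPG_CONTEXTS <- c("Island", "Shore", "Shelf", "OpenSea")
GENE_REGIONS <- c("TSS200", "TSS1500", "5'UTR", "FirstExon", "3'UTR", "Body",
                  "Intergenic")

#' Classify CpG positions by island context
#'
#' Illumina's convention: `Island` inside a CpG island, `Shore` within
#' 2 kb of an island boundary, `Shelf` within 2-4 kb, `OpenSea` beyond.
#' Boundary distances are inclusive toward the nearer category (exactly
#' 2000 bp is Shore, exactly 4000 bp is Shelf). Positions on chromosomes
#' absent from the track fall in OpenSea with a warning.
#'
#' @param chrom,position Vectors of chromosome names and 1-based positions.
#' @param cgi Island intervals (`chrom`, `start`, `end`, 1-based inclusive),
#'   e.g. from [read_bed_intervals()].
#' @return A factor over `Island`, `Shore`, `Shelf`, `OpenSea`.
#' @export
classify_cpg_context <- function(chrom, position, cgi) {
  stopifnot(length(chrom) == length(position))
  dist <- rep(Inf, length(position))
  missing_chroms <- setdiff(unique(chrom), unique(cgi$chrom))
  if (length(missing_chroms) > 0) {
    warning("chromosomes absent from CGI track: ",
            paste(missing_chroms, collapse = ", "), call. = FALSE)
  }
  for (ch in intersect(unique(chrom), unique(cgi$chrom))) {
    sel <- chrom == ch
    iv <- cgi[cgi$chrom == ch, ]
    pos <- position[sel]
    # distance of each position to each interval: 0 inside
    d <- outer(pos, iv$start, function(p, s) s - p)
    d2 <- outer(pos, iv$end, function(p, e) p - e)
    dist[sel] <- apply(pmax(d, d2, 0), 1, min)
  }
  ctx <- ifelse(dist == 0, "Island",
         ifelse(dist <= 2000, "Shore",
         ifelse(dist <= 4000, "Shelf", "OpenSea")))
  factor(ctx, levels = CPG_CONTEXTS)
}

#' Classify CpG positions by functional gene region
#'
#' Strand-aware regions relative to gene models: `TSS200` within 200 bp
#' upstream of a transcription start site (the TSS itself included),
#' `TSS1500` 201-1500 bp upstream, then containment in the 5'UTR, first
#' exon, 3'UTR or gene body; `Intergenic` when no gene is hit. Probes
#' hitting several genes or regions resolve by the priority
#' TSS200 > TSS1500 > 5'UTR > FirstExon > 3'UTR > Body.
#'
#' @inheritParams classify_cpg_context
#' @param genes Gene models, see [read_gene_models()].
#' @return A factor over the region levels.
#' @export
classify_gene_region <- function(chrom, position, genes) {
  stopifnot(length(chrom) == length(position))
  n <- length(position)
  best <- rep(length(GENE_REGIONS), n) # Intergenic
  inside <- function(p, s, e) !is.na(s) & !is.na(e) & p >= s & p <= e
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    sel <- which(chrom == g$chrom)
    if (length(sel) == 0) next
    p <- position[sel]
    upstream <- if (g$strand == "-") p - g$tss else g$tss - p
    cand <- rep(NA_integer_, length(sel))
    cand[inside(p, g$body_start, g$body_end)] <- 6L
    cand[inside(p, g$utr3_start, g$utr3_end)] <- 5L
    cand[inside(p, g$first_exon_start, g$first_exon_end)] <- 4L
    cand[inside(p, g$utr5_start, g$utr5_end)] <- 3L
    cand[upstream >= 201 & upstream <= 1500] <- 2L
    cand[upstream >= 0 & upstream <= 200] <- 1L
    hit <- !is.na(cand) & cand < best[sel]
    best[sel][hit] <- cand[hit]
  }
  factor(GENE_REGIONS[best], levels = GENE_REGIONS)
}

#' Annotate and summarise a CpG panel
#'
#' Assigns every panel probe its island context, functional gene region and
#' chromosome, and summarises the panel composition: fraction of probes per
#' context and per region (each summing to 1) and probe counts per
#' chromosome (summing to the panel size) — the standard descriptive view
#' of a methylation panel.
#'
#' @param panel Character vector of probe ids.
#' @param manifest Probe manifest with coordinates for every panel probe.
#' @param cgi Island intervals.
#' @param genes Gene models.
#' @return A `panel_annotation` list: `probes` (per-probe tibble),
#'   `context`, `region` (fraction tables), `chromosome` (counts).
#' @export
summarize_panel_annotation <- function(panel, manifest, cgi, genes) {
  validate_manifest(manifest)
  missing <- setdiff(panel, manifest$probe_id)
  if (length(missing) > 0) {
    stop("panel probes absent from manifest: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  coords <- manifest[match(panel, manifest$probe_id), ]
  probes <- tibble::tibble(
    probe_id = panel,
    chrom = coords$chrom,
    context = classify_cpg_context(coords$chrom, coords$position, cgi),
    region = classify_gene_region(coords$chrom, coords$position, genes)
  )
  tab_frac <- function(f) {
    tb <- table(f)
    tibble::tibble(category = names(tb), n = as.integer(tb),
                   fraction = as.integer(tb) / length(f))
  }
  structure(list(
    probes = probes,
    context = tab_frac(probes$context),
    region = tab_frac(probes$region),
    chromosome = probes |> dplyr::count(.data$chrom, name = "n")
  ), class = "panel_annotation")
}

#' @export
print.panel_annotation <- function(x, ...) {
  cat(sprintf("<panel_annotation> %d probes\n", nrow(x$probes)))
  cat("context: ",
      paste(sprintf("%s %.0f%%", x$context$category, 100 * x$context$fraction),
            collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy panel_annotation
#' @export
tidy.panel_annotation <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$context, categorization = "context"),
    dplyr::mutate(x$region, categorization = "region"),
    x$chromosome |>
      dplyr::transmute(category = .data$chrom, n = .data$n,
                       fraction = .data$n / sum(.data$n),
                       categorization = "chromosome")
  )
}
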