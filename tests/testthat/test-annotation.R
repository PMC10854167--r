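toy_cgi <- function() {
  tibble::tibble(chrom = "chr1", start = 10000L, end = 11000L)
}

toy_genes <- function() {
  tibble::tibble(
    gene = c("gplus", "gminus"), chrom = "chr1", strand = c("+", "-"),
    tss = c(50000L, 90000L),
    utr5_start = c(50001L, NA), utr5_end = c(50200L, NA),
    first_exon_start = c(50201L, NA), first_exon_end = c(50600L, NA),
    body_start = c(50601L, 89000L), body_end = c(54000L, 89999L),
    utr3_start = c(54001L, NA), utr3_end = c(54500L, NA)
  )
}

test_that("island context follows the 2kb/4kb distance rule with inclusive ties", {
  pos <- c(10500L,              # inside
           11000L + 1500L,      # 1500 bp from edge -> Shore
           11000L + 3000L,      # Shelf
           11000L + 5000L,      # OpenSea
           11000L + 2000L,      # boundary -> Shore
           11000L + 4000L,      # boundary -> Shelf
           10000L)              # island edge itself
  ctx <- classify_cpg_context(rep("chr1", length(pos)), pos, toy_cgi())
  expect_equal(as.character(ctx),
               c("Island", "Shore", "Shelf", "OpenSea", "Shore", "Shelf",
                 "Island"))
  expect_warning(
    far <- classify_cpg_context("chrUn", 5L, toy_cgi()),
    "chrUn"
  )
  expect_equal(as.character(far), "OpenSea")
})

test_that("every position gets exactly one context", {
  withr::with_seed(3, pos <- sample.int(40000, 500) + 1L)
  ctx <- classify_cpg_context(rep("chr1", 500), pos, toy_cgi())
  expect_false(anyNA(ctx))
  expect_true(all(ctx %in% c("Island", "Shore", "Shelf", "OpenSea")))
})

test_that("gene regions are strand-aware with the stated priority", {
  g <- toy_genes()
  # + strand: upstream means smaller coordinates
  expect_equal(as.character(classify_gene_region("chr1", 49900L, g)), "TSS200")
  expect_equal(as.character(classify_gene_region("chr1", 49000L, g)), "TSS1500")
  expect_equal(as.character(classify_gene_region("chr1", 50100L, g)), "5'UTR")
  expect_equal(as.character(classify_gene_region("chr1", 50400L, g)),
               "FirstExon")
  expect_equal(as.character(classify_gene_region("chr1", 52000L, g)), "Body")
  expect_equal(as.character(classify_gene_region("chr1", 54100L, g)), "3'UTR")
  expect_equal(as.character(classify_gene_region("chr1", 70000L, g)),
               "Intergenic")
  # - strand gene: upstream means larger coordinates
  expect_equal(as.character(classify_gene_region("chr1", 90100L, g)), "TSS200")
  expect_equal(as.character(classify_gene_region("chr1", 91000L, g)),
               "TSS1500")
  expect_equal(as.character(classify_gene_region("chr1", 89500L, g)), "Body")

  # a TSS200 hit beats a body hit from another gene
  overlap <- dplyr::bind_rows(g, tibble::tibble(
    gene = "gwide", chrom = "chr1", strand = "+", tss = 40000L,
    body_start = 40001L, body_end = 60000L
  ))
  expect_equal(as.character(classify_gene_region("chr1", 49900L, overlap)),
               "TSS200")
})

test_that("BED intervals convert to 1-based inclusive coordinates", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t9999\t11000", "chr2\t0\t100"), path)
  iv <- read_bed_intervals(path)
  expect_equal(iv$start, c(10000L, 1L))
  expect_equal(iv$end, c(11000L, 100L))
  writeLines("chr1\t50\t50", path)
  expect_error(read_bed_intervals(path), "invalid BED")
})

test_that("panel summaries match a constructed fixture exactly", {
  manifest <- tibble::tibble(
    probe_id = paste0("p", 1:6), chrom = c(rep("chr1", 5), "chr2"),
    position = c(10500L, 10200L, 12500L, 16000L, 49900L, 700L),
    strand = "+"
  )
  ann <- suppressWarnings(summarize_panel_annotation(
    manifest$probe_id, manifest, toy_cgi(), toy_genes()
  ))
  # constructed: two islands, one shore, one open sea (chr1), TSS200 at 49900,
  # chr2 probe has no chr2 CGI -> open sea
  ctx <- ann$probes$context
  expect_equal(as.character(ctx[1:2]), c("Island", "Island"))
  expect_equal(as.character(ctx[3]), "Shore")
  expect_equal(as.character(ctx[4]), "OpenSea")
  expect_equal(ann$context$fraction[ann$context$category == "Island"], 2 / 6)
  expect_equal(sum(ann$context$fraction), 1, tolerance = 1e-9)
  expect_equal(sum(ann$region$fraction), 1, tolerance = 1e-9)
  expect_equal(sum(ann$chromosome$n), 6)
  expect_equal(as.character(ann$probes$region[5]), "TSS200")

  td <- tidy(ann)
  expect_setequal(unique(td$categorization),
                  c("context", "region", "chromosome"))

  all_island <- summarize_panel_annotation(
    manifest$probe_id[1:2], manifest, toy_cgi(), toy_genes()
  )
  expect_equal(all_island$context$fraction[
    all_island$context$category == "Island"], 1)
})
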