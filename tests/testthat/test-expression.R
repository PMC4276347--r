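lay <- genome_layout(c("chr1", "chr2"), c(1e6, 1e6))

test_that("gene RPKM matches hand arithmetic and handles zero counts", {
  genes <- tibble::tibble(
    gene_id = c("g1", "g2"), chrom = "chr1", strand = "+",
    start = c(10000, 50000), end = c(12000, 54000)
  )
  # 20 tags on a 2 kb gene in a 100k-tag library: 20/(2 * 0.1) = 100
  inside <- tibble::tibble(
    chrom = "chr1", start = 10000 + seq_len(20) * 10, strand = "+",
    cell_state = "pro_B"
  ) |> dplyr::mutate(end = start + 36)
  filler <- tibble::tibble(
    chrom = "chr2", start = seq_len(100000 - 20) * 5, strand = "+",
    cell_state = "pro_B"
  ) |> dplyr::mutate(end = start + 36)
  out <- suppressMessages(
    gene_rpkm_from_tags(dplyr::bind_rows(inside, filler), genes, lay)
  )
  expect_equal(out$rpkm[out$gene_id == "g1"], 100)
  expect_equal(out$rpkm[out$gene_id == "g2"], 0)
})

test_that("strand-matched counting ignores antisense tags", {
  genes <- tibble::tibble(
    gene_id = "g1", chrom = "chr1", strand = "+",
    start = 1000, end = 3000
  )
  tags <- tibble::tibble(
    chrom = "chr1", start = c(1500, 1600, 1700), end = c(1536, 1636, 1736),
    strand = c("+", "+", "-"), cell_state = "pro_B"
  )
  out <- suppressMessages(gene_rpkm_from_tags(tags, genes))
  expect_equal(out$count, 2L)
})

test_that("tag-path and count-table-path RPKM agree on the same fixture", {
  withr::with_seed(12, {
    genes <- tibble::tibble(
      gene_id = sprintf("g%02d", 1:8), chrom = "chr1", strand = "+",
      start = seq(0, 7e5, by = 1e5)
    ) |> dplyr::mutate(end = start + 1000 + (1:8) * 500)
    tags <- dplyr::bind_rows(
      dplyr::mutate(random_tag_set(4000, lay), cell_state = "pre_pro_B"),
      dplyr::mutate(random_tag_set(6000, lay), cell_state = "pro_B")
    ) |> dplyr::select(-strand) # unstranded so both paths count all tags
    from_tags <- suppressMessages(gene_rpkm_from_tags(tags, genes, lay))
    counts <- from_tags |>
      dplyr::select(gene_id, cell_state, count) |>
      tidyr::pivot_wider(names_from = cell_state, values_from = count,
                        names_prefix = "count_")
    from_table <- gene_rpkm_from_counts(
      counts, genes,
      c(pre_pro_B = 4000, pro_B = 6000)
    )
    joined <- dplyr::inner_join(from_tags, from_table,
                                by = c("gene_id", "cell_state"))
    expect_equal(joined$rpkm.x, joined$rpkm.y)
  })
})

test_that("FPKM tables round-trip and reject bad values with line numbers", {
  x <- tibble::tibble(
    gene_id = c("g1", "g2"),
    fpkm_pre_pro_B = c(12.5, 0),
    fpkm_pro_B = c(3.1, 7.25)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fpkm_table(x, path)
  expect_equal(read_fpkm_table(path), x)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "# comment", "gene_id\tfpkm_pre_pro_B\tfpkm_pro_B",
    "g1\t1.0\t2.0", "g2\t-3.0\t1.0"
  ), bad)
  expect_error(read_fpkm_table(bad), "negative FPKM at line 4")

  mal <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "gene_id\tfpkm_pre_pro_B\tfpkm_pro_B",
    "g1\toops\t2.0"
  ), mal)
  expect_error(suppressWarnings(read_fpkm_table(mal)), "line 2")
})

test_that("peptide aggregation is a median over unambiguous peptides", {
  pep <- tibble::tibble(
    peptide_id = sprintf("p%d", 1:6),
    gene_id = c("g1", "g1", "g1", "g2", "AMBIGUOUS", "AMBIGUOUS"),
    log2_ratio_pro_over_pre = c(1.0, 1.2, 0.8, 0.4, 5, -5)
  )
  out <- aggregate_protein_ratios(pep)
  expect_equal(out$protein_log2_ratio[out$gene_id == "g1"], 1.0)
  expect_equal(out$n_peptides[out$gene_id == "g1"], 3L)
  expect_equal(out$protein_log2_ratio[out$gene_id == "g2"], 0.4)
  # genes with only ambiguous peptides are absent, not zero
  expect_setequal(out$gene_id, c("g1", "g2"))

  # permutation invariance
  shuf <- pep[sample(nrow(pep)), ]
  expect_equal(
    dplyr::arrange(aggregate_protein_ratios(shuf), gene_id),
    dplyr::arrange(out, gene_id)
  )
  # mean mode available by configuration
  out_mean <- aggregate_protein_ratios(pep, method = "mean")
  expect_equal(out_mean$protein_log2_ratio[out_mean$gene_id == "g1"],
               mean(c(1.0, 1.2, 0.8)))
})

test_that("differential log ratios exclude zeros rather than pseudocount", {
  expect_equal(differential_log_ratio(10, 1), 1)
  expect_equal(differential_log_ratio(5, 5), 0)
  expect_true(is.na(differential_log_ratio(0, 5)))
  expect_true(is.na(differential_log_ratio(5, 0)))
  expect_equal(differential_log_ratio(8, 2, base = 2), 2)
  expect_error(differential_log_ratio(1, 1, base = 3), "base")
})

test_that("stability ratios follow the FPKM/RPKM definition", {
  omics <- tibble::tibble(
    gene_id = c("a", "b", "c"),
    rpkm_pre_pro_B = c(100, 4, 0),
    rpkm_pro_B = c(100, 4, 5),
    fpkm_pre_pro_B = c(10, 4, 2),
    fpkm_pro_B = c(10, 4, 2)
  )
  st <- stability_ratios(omics)
  expect_equal(st$ratio_pre_pro_B[1], 0.1)
  expect_equal(st$log10_ratio_pre_pro_B[1], -1)
  expect_equal(st$differential[2], 0)
  # any zero excludes the gene from the ratio analyses
  expect_true(is.na(st$ratio_pre_pro_B[3]))
  expect_true(is.na(st$differential[3]))
})

test_that("stability differential equals the FPKM minus RPKM log ratios", {
  withr::with_seed(4, {
    omics <- tibble::tibble(
      gene_id = sprintf("g%d", 1:200),
      rpkm_pre_pro_B = 10^runif(200, -1, 2),
      rpkm_pro_B = 10^runif(200, -1, 2),
      fpkm_pre_pro_B = 10^runif(200, -1, 2),
      fpkm_pro_B = 10^runif(200, -1, 2)
    )
    st <- stability_ratios(omics)
    lhs <- st$differential
    rhs <- differential_log_ratio(omics$fpkm_pro_B, omics$fpkm_pre_pro_B) -
      differential_log_ratio(omics$rpkm_pro_B, omics$rpkm_pre_pro_B)
    expect_equal(lhs, rhs)
  })
})

test_that("GRO count tables carry library sizes through comments", {
  counts <- tibble::tibble(
    gene_id = c("g1", "g2"),
    count_pre_pro_B = c(10, 0), count_pro_B = c(5, 2)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gro_counts(counts, c(pre_pro_B = 1.5e6, pro_B = 2e6), path)
  back <- read_gro_counts(path)
  expect_equal(back$counts, counts)
  expect_equal(unname(back$library_sizes["pre_pro_B"]), 1.5e6)
  expect_equal(unname(back$library_sizes["pro_B"]), 2e6)
})
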