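#' Define a genome layout
#'
#' A genome layout is the minimal reference context for interval work: a
#' tibble of chromosome names and lengths (base pairs). All coordinates in the
#' package are 0-based half-open.
#'
#' @param chrom Character vector of chromosome names (unique).
#' @param length Numeric vector of chromosome lengths in bp (> 0).
#' @return A tibble with columns `chrom`, `length`.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(2e6, 1e6))
#' @export
genome_layout <- function(chrom, length) {
  out <- tibble(chrom = as.character(chrom), length = as.numeric(length))
  assert_layout(out)
  out
}

#' Derive promoter intervals around each TSS
#'
#' The promoter of each gene model is the window extending `flank` bp on both
#' sides of its strand-aware TSS, i.e. `[tss - flank, tss + flank)`. Intervals
#' running off a chromosome end are clipped and flagged. One interval is
#' produced per input row (per annotated TSS), labelled with the gene id.
#'
#' @param genes Gene-model tibble (`gene_id`, `chrom`, `strand`, `start`,
#'   `end`, 0-based half-open). Multiple rows per `gene_id` (isoform TSSs) are
#'   allowed.
#' @param layout Genome layout tibble; genes on chromosomes absent from it are
#'   an error.
#' @param flank Half-width of the promoter window in bp (default 200, giving
#'   the 400 bp window used for cumulative promoter scoring).
#' @return Tibble of intervals: `chrom`, `start`, `end`, `label`, `clipped`.
#' @examples
#' lay <- genome_layout("chr1", 1e6)
#' g <- tibble::tibble(gene_id = "g1", chrom = "chr1", strand = "+",
#'                     start = 10000, end = 15000)
#' derive_promoters(g, lay)
#' @export
derive_promoters <- function(genes, layout, flank = 200) {
  assert_layout(layout)
  assert_genes(genes, layout)
  if (flank <= 0) abort("flank must be > 0")
  tss <- gene_tss(genes)
  len <- layout$length[match(genes$chrom, layout$chrom)]
  raw_start <- tss - flank
  raw_end <- tss + flank
  tibble(
    chrom = genes$chrom,
    start = pmax(raw_start, 0),
    end = pmin(raw_end, len),
    label = genes$gene_id,
    clipped = raw_start < 0 | raw_end > len
  )
}

#' Derive control windows upstream of each TSS
#'
#' Places a window of the stated width centred `offset` bp upstream of the
#' TSS, strand-aware: on the plus strand the window is
#' `[tss - offset - width/2, tss - offset + width/2)`; on the minus strand it
#' is mirrored downstream in genome coordinates. Windows are clipped to
#' chromosome bounds; windows empty after clipping are kept with
#' `start == end` and flagged.
#'
#' @inheritParams derive_promoters
#' @param offset Distance from the TSS to the window centre, bp (default
#'   2000).
#' @param width Window width, bp (default 400).
#' @return Tibble of intervals: `chrom`, `start`, `end`, `label`, `clipped`.
#' @export
derive_upstream_intervals <- function(genes, layout, offset = 2000,
                                      width = 400) {
  assert_layout(layout)
  assert_genes(genes, layout)
  if (offset <= width / 2) abort("offset must exceed width/2")
  tss <- gene_tss(genes)
  centre <- ifelse(genes$strand == "+", tss - offset, tss + offset)
  len <- layout$length[match(genes$chrom, layout$chrom)]
  raw_start <- centre - width %/% 2
  raw_end <- raw_start + width
  start <- pmax(pmin(raw_start, len), 0)
  end <- pmax(pmin(raw_end, len), 0)
  end <- pmax(end, start)
  tibble(
    chrom = genes$chrom,
    start = start,
    end = end,
    label = genes$gene_id,
    clipped = raw_start < 0 | raw_end > len
  )
}

#' Sample random genomic intervals
#'
#' Uniform random fixed-width intervals: a chromosome is chosen with
#' probability proportional to its length and the start position uniformly
#' over the valid placements. Used to build the random-interval background
#' score distribution against which promoter scores are compared.
#'
#' @param layout Genome layout tibble; every chromosome must be at least
#'   `width` bp long.
#' @param n Number of intervals (> 0).
#' @param width Interval width in bp (default 400).
#' @param seed Optional integer seed; the same seed reproduces the same
#'   intervals.
#' @return Tibble `chrom`, `start`, `end`, `label` (`r1` ... `rn`).
#' @export
sample_random_intervals <- function(layout, n, width = 400, seed = NULL) {
  assert_layout(layout)
  if (n <= 0) abort("n must be > 0")
  if (any(layout$length < width)) {
    abort("every chromosome must be at least `width` bp long")
  }
  local_seed(seed)
  idx <- sample.int(nrow(layout), n, replace = TRUE, prob = layout$length)
  max_start <- layout$length[idx] - width
  start <- floor(runif(n, 0, max_start + 1))
  start <- pmin(start, max_start) # guard the open upper bound
  tibble(
    chrom = layout$chrom[idx],
    start = start,
    end = start + width,
    label = paste0("r", seq_len(n))
  )
}
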