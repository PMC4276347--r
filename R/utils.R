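# Internal helpers: validation and seeded RNG scope.

# Set the RNG seed for the calling function's scope only (restored on exit).
local_seed <- function(seed, env = parent.frame()) {
  if (is.null(seed)) {
    return(invisible(NULL))
  }
  withr::local_seed(as.integer(seed), .local_envir = env)
}

assert_layout <- function(layout) {
  if (!all(c("chrom", "length") %in% names(layout))) {
    abort("genome layout needs columns 'chrom' and 'length'")
  }
  if (anyDuplicated(layout$chrom)) {
    abort("genome layout chromosome names must be unique")
  }
  if (any(layout$length <= 0)) {
    abort("genome layout chromosome lengths must be positive")
  }
  invisible(layout)
}

assert_genes <- function(genes, layout = NULL) {
  need <- c("gene_id", "chrom", "strand", "start", "end")
  if (!all(need %in% names(genes))) {
    abort(paste0(
      "gene models need columns: ", paste(need, collapse = ", ")
    ))
  }
  if (any(genes$end <= genes$start)) {
    bad <- genes$gene_id[genes$end <= genes$start][1]
    abort(paste0("gene '", bad, "' has end <= start"))
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    abort("gene strand must be '+' or '-'")
  }
  if (!is.null(layout)) {
    missing <- setdiff(unique(genes$chrom), layout$chrom)
    if (length(missing) > 0) {
      bad <- genes$gene_id[genes$chrom %in% missing][1]
      abort(paste0(
        "gene '", bad, "' lies on chromosome '",
        genes$chrom[genes$gene_id == bad][1],
        "' absent from the genome layout"
      ))
    }
  }
  invisible(genes)
}

assert_intervals <- function(x) {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(x))) {
    abort("intervals need columns chrom, start, end")
  }
  invisible(x)
}

#' Transcription start sites of gene models
#'
#' Strand-aware TSS in 0-based coordinates: the span start on the plus strand
#' and `end - 1` on the minus strand.
#'
#' @param genes Tibble of gene models with columns `gene_id`, `chrom`,
#'   `strand`, `start`, `end` (0-based half-open).
#' @return Integer vector of TSS positions, one per row of `genes`.
#' @export
gene_tss <- function(genes) {
  assert_genes(genes)
  as.integer(ifelse(genes$strand == "+", genes$start, genes$end - 1L))
}
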