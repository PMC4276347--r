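# Readers and writers for the plain-text interchange formats: BED6, GTF and
# the tab-separated tables (FPKM, GRO counts, peptides). All genomic
# coordinates are converted to 0-based half-open on input; BED is passed
# through, GTF is shifted from 1-based closed.

#' Write intervals or tags as BED6
#'
#' @param x Tibble with `chrom`, `start`, `end` and optionally `label`/`name`
#'   and `strand`; coordinates 0-based half-open (the BED convention).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(x, path) {
  assert_intervals(x)
  name <- if ("label" %in% names(x)) {
    x$label
  } else if ("name" %in% names(x)) {
    x$name
  } else {
    "."
  }
  strand <- if ("strand" %in% names(x)) x$strand else "."
  out <- tibble(
    chrom = x$chrom,
    start = format(x$start, scientific = FALSE, trim = TRUE),
    end = format(x$end, scientific = FALSE, trim = TRUE),
    name = name,
    score = 0L,
    strand = strand
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a BED6 file
#'
#' @param path BED file (3-6 columns, '#' comments allowed).
#' @return Tibble `chrom`, `start`, `end`, `label`, `score`, `strand`.
#' @export
read_bed6 <- function(path) {
  x <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "label", "score", "strand"),
    col_types = "cddcic", comment = "#", progress = FALSE
  )
  x$label <- x$label %||% "."
  x
}

#' Write gene models as a minimal GTF
#'
#' One `transcript` feature per row; `gene_id` and `transcript_id` attributes
#' carry the labels. Coordinates are converted to the 1-based closed GTF
#' convention.
#'
#' @param genes Gene-model tibble (0-based half-open).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  assert_genes(genes)
  tx <- if ("transcript_id" %in% names(genes)) {
    genes$transcript_id
  } else {
    paste0(genes$gene_id, ".1")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  S4Vectors::mcols(gr)$type <- "transcript"
  S4Vectors::mcols(gr)$source <- "regmodes"
  S4Vectors::mcols(gr)$gene_id <- genes$gene_id
  S4Vectors::mcols(gr)$transcript_id <- tx
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read gene models from GTF or BED
#'
#' GTF `transcript` records (falling back to all records if none are typed
#' `transcript`) define one TSS each; BED6/BED12 rows are taken as gene spans
#' directly. Output coordinates are 0-based half-open.
#'
#' @param path Annotation file; format inferred from the extension
#'   (`.gtf`/`.gff` vs `.bed`).
#' @return Gene-model tibble: `gene_id`, `transcript_id`, `chrom`, `strand`,
#'   `start`, `end`.
#' @export
read_gene_models <- function(path) {
  if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) {
    b <- read_bed6(path)
    return(tibble(
      gene_id = b$label, transcript_id = b$label, chrom = b$chrom,
      strand = ifelse(is.na(b$strand) | !b$strand %in% c("+", "-"),
        "+", b$strand
      ),
      start = b$start, end = b$end
    ))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  type <- as.character(S4Vectors::mcols(gr)$type %||% "transcript")
  if (any(type == "transcript")) gr <- gr[type == "transcript"]
  mc <- S4Vectors::mcols(gr)
  tibble(
    gene_id = as.character(mc$gene_id),
    transcript_id = as.character(mc$transcript_id %||% mc$gene_id),
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    strand = as.character(BiocGenerics::strand(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr)
  )
}

# Line number of data row `i` in a headed TSV with `n_comments` leading
# comment lines (1 header line assumed).
tsv_line_of_row <- function(i, n_comments) i + n_comments + 1L

count_leading_comments <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  n <- 0L
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0 || !startsWith(line, "#")) break
    n <- n + 1L
  }
  n
}

#' Read a per-gene FPKM table
#'
#' Tab-separated with a header `gene_id`, `fpkm_pre_pro_B`, `fpkm_pro_B`;
#' lines starting with '#' are comments. Negative values are a hard error
#' naming the offending line.
#'
#' @param path TSV file.
#' @return Tibble `gene_id`, `fpkm_pre_pro_B`, `fpkm_pro_B`.
#' @export
read_fpkm_table <- function(path) {
  nc <- count_leading_comments(path)
  x <- readr::read_tsv(path, comment = "#", col_types = "cdd",
                       progress = FALSE)
  need <- c("gene_id", "fpkm_pre_pro_B", "fpkm_pro_B")
  if (!all(need %in% names(x))) {
    abort(paste0("FPKM table must have columns: ", paste(need, collapse = ", ")))
  }
  vals <- as.matrix(x[, need[-1]])
  if (anyNA(vals)) {
    bad <- which(rowSums(is.na(vals)) > 0)[1]
    abort(paste0(
      "malformed FPKM value at line ", tsv_line_of_row(bad, nc),
      " (gene '", x$gene_id[bad], "')"
    ))
  }
  if (any(vals < 0)) {
    bad <- which(rowSums(vals < 0) > 0)[1]
    abort(paste0(
      "negative FPKM at line ", tsv_line_of_row(bad, nc),
      " (gene '", x$gene_id[bad], "')"
    ))
  }
  x[, need]
}

#' Write a per-gene FPKM table
#' @param x Tibble as returned by [read_fpkm_table()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fpkm_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read a GRO-seq per-gene count table
#'
#' Tab-separated with header `gene_id`, `count_pre_pro_B`, `count_pro_B`.
#' Per-library totals (the RPKM denominators, which include reads outside the
#' tabulated genes) are carried in leading comment lines of the form
#' `# library_size_pre_pro_B=NNN`.
#'
#' @param path TSV file.
#' @return List with `counts` (tibble) and `library_sizes` (named numeric,
#'   per cell state).
#' @export
read_gro_counts <- function(path) {
  header <- readLines(path, n = 20L)
  header <- header[startsWith(header, "#")]
  sizes <- c(pre_pro_B = NA_real_, pro_B = NA_real_)
  for (state in names(sizes)) {
    pat <- paste0("library_size_", state, "\\s*=\\s*([0-9.eE+]+)")
    hit <- regmatches(header, regexec(pat, header))
    hit <- hit[lengths(hit) == 2]
    if (length(hit) > 0) sizes[state] <- as.numeric(hit[[1]][2])
  }
  if (anyNA(sizes)) {
    abort("GRO count table must declare library_size_<state> in '#' comments")
  }
  x <- readr::read_tsv(path, comment = "#", col_types = "cdd",
                       progress = FALSE)
  need <- c("gene_id", "count_pre_pro_B", "count_pro_B")
  if (!all(need %in% names(x))) {
    abort(paste0("GRO count table must have columns: ",
                 paste(need, collapse = ", ")))
  }
  list(counts = x[, need], library_sizes = sizes)
}

#' Write a GRO-seq per-gene count table
#' @param counts Tibble `gene_id`, `count_pre_pro_B`, `count_pro_B`.
#' @param library_sizes Named numeric totals per cell state.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gro_counts <- function(counts, library_sizes, path) {
  con <- file(path, "w")
  for (state in names(library_sizes)) {
    writeLines(sprintf(
      "# library_size_%s=%s", state,
      format(library_sizes[[state]], scientific = FALSE)
    ), con)
  }
  close(con)
  readr::write_tsv(counts, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Read a peptide-level protein quantification table
#'
#' Tab-separated with header `peptide_id`, `gene_id`,
#' `log2_ratio_pro_over_pre`. Peptides that could not be mapped to a single
#' gene carry `gene_id` `"AMBIGUOUS"`.
#'
#' @param path TSV file.
#' @return Tibble with those three columns.
#' @export
read_peptide_table <- function(path) {
  x <- readr::read_tsv(path, comment = "#", col_types = "ccd",
                       progress = FALSE)
  need <- c("peptide_id", "gene_id", "log2_ratio_pro_over_pre")
  if (!all(need %in% names(x))) {
    abort(paste0("peptide table must have columns: ",
                 paste(need, collapse = ", ")))
  }
  x[, need]
}

#' Write a peptide table
#' @param x Peptide tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
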