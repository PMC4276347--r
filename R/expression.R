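# GRO-seq gene-level RPKM, RNA-seq FPKM ingestion, peptide-to-protein ratio
# aggregation, differential log-ratios and the inferred mRNA stability ratio
# (steady-state FPKM over nascent-transcription RPKM).

#' Gene-level RPKM from aligned GRO-seq tags
#'
#' Counts tags over the whole gene span and normalises to gene length and
#' library size: `RPKM = count / (gene_length_kb * library_size_millions)`.
#' When both tags and genes carry strand information, counting is
#' strand-matched (a tag only counts towards genes on its own strand);
#' otherwise it is unstranded, and the mode is reported.
#'
#' @param tags Tag tibble: `chrom`, `start`, `end`, optionally `strand`, and
#'   `cell_state`.
#' @param genes Gene-model tibble (one row per gene; zero-length spans are an
#'   error).
#' @param layout Optional genome layout for off-layout tag filtering.
#' @return Tibble `gene_id`, `cell_state`, `count`, `rpkm`.
#' @export
gene_rpkm_from_tags <- function(tags, genes, layout = NULL) {
  assert_genes(genes)
  if (!"cell_state" %in% names(tags)) abort("tags need a 'cell_state' column")
  if (any(genes$end <= genes$start)) abort("zero-length gene span")
  stranded <- "strand" %in% names(tags) &&
    all(tags$strand %in% c("+", "-"))
  inform(paste0(
    "GRO counting mode: ", if (stranded) "strand-matched" else "unstranded"
  ))
  spans <- tibble(
    chrom = genes$chrom, start = genes$start, end = genes$end,
    label = genes$gene_id
  )
  len_kb <- (genes$end - genes$start) / 1000
  out <- lapply(sort(unique(tags$cell_state)), function(state) {
    lib <- tags[tags$cell_state == state, , drop = FALSE]
    lib_m <- nrow(lib) / 1e6
    if (stranded) {
      cnt <- rep(0L, nrow(genes))
      for (s in c("+", "-")) {
        sel <- genes$strand == s
        cs <- count_overlapping_tags(
          lib[lib$strand == s, , drop = FALSE],
          spans[sel, , drop = FALSE], layout
        )
        cnt[sel] <- cs$count
      }
    } else {
      cnt <- count_overlapping_tags(lib, spans, layout)$count
    }
    tibble(
      gene_id = genes$gene_id, cell_state = state, count = cnt,
      rpkm = cnt / (len_kb * lib_m)
    )
  })
  list_rbind(out)
}

#' Gene-level RPKM from a per-gene count table
#'
#' The table path equivalent of [gene_rpkm_from_tags()]: counts per gene per
#' cell state plus the per-library totals (which may include reads outside
#' the tabulated genes).
#'
#' @param counts Tibble `gene_id`, `count_pre_pro_B`, `count_pro_B`.
#' @param genes Gene-model tibble supplying gene lengths.
#' @param library_sizes Named numeric totals, names `pre_pro_B` and `pro_B`.
#' @return Tibble `gene_id`, `cell_state`, `count`, `rpkm`.
#' @export
gene_rpkm_from_counts <- function(counts, genes, library_sizes) {
  assert_genes(genes)
  if (!all(CELL_STATES %in% names(library_sizes))) {
    abort("library_sizes must name both cell states")
  }
  if (any(library_sizes <= 0)) abort("library sizes must be positive")
  len <- genes$end - genes$start
  if (any(len <= 0)) abort("zero-length gene span")
  len_kb <- setNames(len / 1000, genes$gene_id)
  miss <- setdiff(counts$gene_id, genes$gene_id)
  if (length(miss) > 0) {
    abort(paste0("count table gene '", miss[1], "' absent from annotation"))
  }
  out <- lapply(CELL_STATES, function(state) {
    cnt <- counts[[paste0("count_", state)]]
    tibble(
      gene_id = counts$gene_id, cell_state = state, count = cnt,
      rpkm = unname(cnt / (len_kb[counts$gene_id] *
                             (library_sizes[[state]] / 1e6)))
    )
  })
  list_rbind(out)
}

#' Aggregate peptide ratios to per-gene protein ratios
#'
#' Peptides not unambiguously mapped to a single gene (`gene_id ==
#' "AMBIGUOUS"` or missing) are dropped; each remaining gene's protein ratio
#' is the median (or mean) of its peptide log2 ratios. Genes with no
#' unambiguous peptide are absent from the output, not zero.
#'
#' @param peptides Tibble `peptide_id`, `gene_id`, `log2_ratio_pro_over_pre`.
#' @param method `"median"` (default, robust) or `"mean"`.
#' @return Tibble `gene_id`, `protein_log2_ratio`, `n_peptides`.
#' @export
aggregate_protein_ratios <- function(peptides, method = c("median", "mean")) {
  method <- match.arg(method)
  agg <- if (method == "median") stats::median else base::mean
  peptides |>
    filter(!is.na(.data$gene_id), .data$gene_id != "AMBIGUOUS") |>
    group_by(.data$gene_id) |>
    summarise(
      protein_log2_ratio = agg(.data$log2_ratio_pro_over_pre),
      n_peptides = dplyr::n(),
      .groups = "drop"
    )
}

#' Differential log-ratio of two nonnegative quantities
#'
#' `log_base(a / b)` where both are strictly positive; `NA` otherwise (genes
#' with a zero on either side are excluded from ratio analyses rather than
#' pseudocounted).
#'
#' @param a,b Nonnegative numeric vectors (recycled).
#' @param base Logarithm base, 10 or 2.
#' @return Numeric vector of log ratios with `NA` where undefined.
#' @export
differential_log_ratio <- function(a, b, base = 10) {
  if (!base %in% c(10, 2)) abort("base must be 10 or 2")
  ifelse(!is.na(a) & !is.na(b) & a > 0 & b > 0, log(a / b, base = base),
         NA_real_)
}

#' Inferred mRNA stability ratios
#'
#' For each gene and cell state, the ratio of steady-state abundance (FPKM)
#' to ongoing transcription (RPKM) is an inferred stability index; its
#' between-state differential `log10((FPKM_pro/RPKM_pro) /
#' (FPKM_pre/RPKM_pre))` is defined only when all four inputs are positive.
#'
#' @param omics Wide per-gene tibble with `gene_id`, `rpkm_pre_pro_B`,
#'   `rpkm_pro_B`, `fpkm_pre_pro_B`, `fpkm_pro_B`.
#' @return Tibble `gene_id`, `ratio_pre_pro_B`, `ratio_pro_B`,
#'   `log10_ratio_pre_pro_B`, `log10_ratio_pro_B`, `differential`.
#' @export
stability_ratios <- function(omics) {
  ratio <- function(f, r) ifelse(!is.na(f) & !is.na(r) & f > 0 & r > 0,
                                 f / r, NA_real_)
  rp <- ratio(omics$fpkm_pre_pro_B, omics$rpkm_pre_pro_B)
  rq <- ratio(omics$fpkm_pro_B, omics$rpkm_pro_B)
  tibble(
    gene_id = omics$gene_id,
    ratio_pre_pro_B = rp,
    ratio_pro_B = rq,
    log10_ratio_pre_pro_B = ifelse(is.na(rp), NA_real_, log10(rp)),
    log10_ratio_pro_B = ifelse(is.na(rq), NA_real_, log10(rq)),
    differential = ifelse(is.na(rp) | is.na(rq), NA_real_, log10(rq / rp))
  )
}

#' Join quantifications into a per-gene omics table
#'
#' @param gro Long RPKM tibble from one of the `gene_rpkm_*` functions.
#' @param fpkm FPKM tibble from [read_fpkm_table()].
#' @param protein Per-gene protein tibble from [aggregate_protein_ratios()],
#'   or `NULL`.
#' @return Wide tibble keyed by `gene_id` with `rpkm_*`, `fpkm_*`,
#'   `protein_log2_ratio`, `n_peptides`.
#' @export
build_gene_omics <- function(gro, fpkm, protein = NULL) {
  wide <- gro |>
    select("gene_id", "cell_state", "rpkm") |>
    pivot_wider(names_from = "cell_state", values_from = "rpkm",
                names_prefix = "rpkm_")
  out <- dplyr::full_join(wide, fpkm, by = "gene_id")
  if (!is.null(protein)) {
    out <- left_join(out, protein, by = "gene_id")
  } else {
    out$protein_log2_ratio <- NA_real_
    out$n_peptides <- NA_integer_
  }
  out
}
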