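# End-to-end orchestration: annotation -> promoter scoring -> activity and
# promoter classes -> GRO/RNA/protein quantification -> stability ->
# regulatory calls -> summary tables and statistics, all driven by a single
# config object that is serialised into every report.

#' Pipeline configuration
#'
#' The single source of every tunable. All thresholds default to the study
#' values: promoter flank 200 bp, upstream control window 400 bp at 2 kb,
#' cRPKM activity cutoff 8 (strict), fold thresholds 2 / 2 / 1.5 for
#' transcription / mRNA / protein, expression floor 0.5, histogram bins 0.1
#' (log10 expression) and 0.25 (protein log2).
#'
#' @param flank Promoter half-width, bp.
#' @param upstream_offset,upstream_width Control-window placement, bp.
#' @param crpkm_threshold Activity cutoff on the cumulative score.
#' @param single_mark_epsilon,amplicon_fraction Single-mark guard settings.
#' @param fold_gro,fold_rna,fold_protein Differential fold thresholds.
#' @param expression_floor Floor for zero-vs-nonzero comparisons.
#' @param bin_width_log10,bin_width_protein Histogram bin widths.
#' @param antimode_offset Log offset for antimode estimation.
#' @param n_random_intervals Random intervals for the enrichment checks.
#' @param n_resample Monte-Carlo resamples for the relative-distance test.
#' @param do_enrichment Run the interval-enrichment block (default TRUE).
#' @param seed Seed for the stochastic statistics.
#' @return A `run_config` list.
#' @export
run_config <- function(flank = 200, upstream_offset = 2000,
                       upstream_width = 400, crpkm_threshold = 8,
                       single_mark_epsilon = 0.5, amplicon_fraction = 0.75,
                       fold_gro = 2, fold_rna = 2, fold_protein = 1.5,
                       expression_floor = 0.5, bin_width_log10 = 0.1,
                       bin_width_protein = 0.25, antimode_offset = 0.1,
                       n_random_intervals = 20000, n_resample = 1000,
                       do_enrichment = TRUE, seed = 1) {
  cfg <- as.list(environment())
  if (any(unlist(cfg[c(
    "flank", "crpkm_threshold", "fold_gro", "fold_rna", "fold_protein",
    "bin_width_log10", "bin_width_protein"
  )]) <= 0)) {
    abort("all thresholds must be positive")
  }
  structure(cfg, class = "run_config")
}

# Gene-level score records: per gene and state, the maximum-scoring promoter
# among that gene's TSS intervals.
gene_level_scores <- function(records) {
  records |>
    group_by(.data$label, .data$cell_state) |>
    arrange(dplyr::desc(.data$crpkm), .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    rename(gene_id = "label")
}

#' Run the full analysis pipeline
#'
#' @param dataset A `regmodes_dataset` (from [simulate_dataset()] or
#'   [read_fixture()]).
#' @param config A [run_config()] list.
#' @return A `regmodes_report`: list with the per-gene `master` table,
#'   `crpkm` gene-level score records, `class_counts`, `table1` percentage
#'   matrix, `antimode`, WMW `tests`, `histograms`, `enrichment`,
#'   `excluded` tally, `config` and `provenance`.
#' @export
run_pipeline <- function(dataset, config = run_config()) {
  stopifnot(inherits(dataset, "regmodes_dataset"))
  cfg <- config
  layout <- dataset$layout
  genes <- dataset$genes

  promoters <- derive_promoters(genes, layout, cfg$flank)
  records <- score_intervals(dataset$chip_tags, promoters, layout) |>
    call_active(cfg$crpkm_threshold, cfg$single_mark_epsilon,
                cfg$amplicon_fraction)
  gene_scores <- gene_level_scores(records)

  activity <- gene_scores |>
    select("gene_id", "cell_state", "crpkm", "active", "single_mark",
           "amplicon_suspect") |>
    pivot_wider(
      names_from = "cell_state",
      values_from = c("crpkm", "active", "single_mark", "amplicon_suspect")
    ) |>
    mutate(promoter_class = classify_promoter(
      .data$active_pre_pro_B, .data$active_pro_B
    ))

  antimode <- estimate_antimode(
    gene_scores$crpkm[gene_scores$cell_state == "pro_B"],
    offset = cfg$antimode_offset
  )

  gro <- gene_rpkm_from_counts(
    dataset$gro$counts, genes, dataset$gro$library_sizes
  )
  protein <- aggregate_protein_ratios(dataset$peptides)
  omics <- build_gene_omics(gro, dataset$fpkm, protein)
  stability <- stability_ratios(omics)
  calls <- regulatory_calls(
    omics, cfg$fold_gro, cfg$fold_rna, cfg$fold_protein,
    cfg$expression_floor
  )

  master <- activity |>
    left_join(omics, by = "gene_id") |>
    left_join(
      select(stability, "gene_id", stability_differential = "differential"),
      by = "gene_id"
    ) |>
    left_join(calls, by = "gene_id") |>
    call_de_proteins(cfg$fold_protein) |>
    mutate(exclusion_reason = case_when(
      is.na(.data$protein_log2_ratio) ~ "no_protein_data",
      .default = "none"
    ))

  class_counts <- count(master, .data$promoter_class, name = "n_genes")
  table1 <- summarize_table1(master)

  # rank-sum comparisons of transcription between promoter classes
  tests <- list()
  for (state in CELL_STATES) {
    vals <- gro |>
      filter(.data$cell_state == state) |>
      left_join(select(master, "gene_id", "promoter_class"), by = "gene_id")
    pairs <- utils::combn(PROMOTER_CLASSES, 2, simplify = FALSE)
    for (pr in pairs) {
      x <- vals$rpkm[vals$promoter_class == pr[1]]
      y <- vals$rpkm[vals$promoter_class == pr[2]]
      if (length(x) < 1 || length(y) < 1) next
      res <- wmw_test(log10(x + 1e-3), log10(y + 1e-3))
      res$test <- "wmw_gro_rpkm"
      res$cell_state <- state
      res$group1 <- pr[1]
      res$group2 <- pr[2]
      tests[[length(tests) + 1]] <- res
    }
  }
  tests <- list_rbind(tests)

  gro_wide <- omics
  histograms <- list(
    gro_differential = frequency_distribution(
      ifelse(gro_wide$rpkm_pre_pro_B > 0 & gro_wide$rpkm_pro_B > 0,
        gro_wide$rpkm_pro_B / gro_wide$rpkm_pre_pro_B, NA
      ),
      cfg$bin_width_log10, "log10"
    ),
    protein_log2 = frequency_distribution(
      master$protein_log2_ratio, cfg$bin_width_protein, "identity"
    )
  )

  enrichment <- NULL
  if (isTRUE(cfg$do_enrichment)) {
    enrichment <- enrichment_block(
      dataset, promoters, cfg
    )
  }

  excluded <- count(master, .data$exclusion_reason, name = "n_genes")

  structure(
    list(
      master = master, crpkm = gene_scores, records = records,
      class_counts = class_counts, table1 = table1,
      antimode = antimode, tests = tests, histograms = histograms,
      enrichment = enrichment, excluded = excluded, config = cfg,
      provenance = list(
        package_version = as.character(utils::packageVersion("regmodes")),
        config = unclass(cfg)
      )
    ),
    class = "regmodes_report"
  )
}

# Score random intervals, split them at the activity threshold and compare
# both halves against the promoter set and TSS positions: the above-cutoff
# half should overlap promoters far more than chance (higher Jaccard,
# smaller projection p, TSS-clustered relative distances).
enrichment_block <- function(dataset, promoters, cfg) {
  rnd <- sample_random_intervals(
    dataset$layout, cfg$n_random_intervals, 400,
    seed = cfg$seed
  )
  rnd_scores <- score_intervals(dataset$chip_tags, rnd, dataset$layout) |>
    filter(.data$cell_state == "pro_B")
  over <- rnd_scores$crpkm > cfg$crpkm_threshold
  tss_points <- tibble(
    chrom = dataset$genes$chrom, pos = gene_tss(dataset$genes)
  )
  one_side <- function(sel, side) {
    q <- rnd[sel, , drop = FALSE]
    if (nrow(q) < 2) {
      return(NULL)
    }
    proj <- projection_test(q, promoters, dataset$layout)
    reld <- relative_distance_test(
      q, tss_points,
      n_resample = cfg$n_resample, seed = cfg$seed + 1
    )
    tibble(
      side = side, n = nrow(q),
      jaccard = jaccard_intervals(q, promoters),
      projection_hits = proj$hits,
      expected_fraction = proj$expected_fraction,
      projection_p = proj$p_value,
      reldist_statistic = reld$statistic,
      reldist_p = reld$p_value
    )
  }
  bind_rows(
    one_side(over, "above_threshold"),
    one_side(!over, "below_threshold")
  )
}

#' Summarise regulatory groups by promoter class (percentage matrix)
#'
#' Two blocks — all genes with a defined broad group, and the subset with
#' differentially abundant protein — each giving the percentage of each
#' column's genes (all genes plus the four promoter classes) falling into
#' each broad group. Every column sums to 100.
#'
#' @param master Per-gene master table from [run_pipeline()] (needs
#'   `promoter_class`, `group`, `de_protein`).
#' @return Tidy tibble: `block`, `promoter_class` (including `"all"`),
#'   `group`, `n`, `percent`.
#' @export
summarize_table1 <- function(master) {
  base <- filter(master, !is.na(.data$group))
  blocks <- list(
    all_genes = base,
    de_genes = filter(base, .data$de_protein %in% TRUE)
  )
  out <- list()
  for (bn in names(blocks)) {
    b <- blocks[[bn]]
    cols <- c("all", PROMOTER_CLASSES)
    for (cl in cols) {
      sub <- if (cl == "all") b else filter(b, .data$promoter_class == cl)
      tot <- nrow(sub)
      counts <- vapply(BROAD_GROUPS, function(gp) sum(sub$group == gp),
                       integer(1))
      out[[length(out) + 1]] <- tibble(
        block = bn, promoter_class = cl, group = BROAD_GROUPS,
        n = as.integer(counts),
        percent = if (tot > 0) 100 * counts / tot else NA_real_
      )
    }
  }
  list_rbind(out)
}

#' Write the report tables to a directory
#'
#' Each table goes to a TSV with a provenance header (package version and
#' the full config) in leading comment lines. Re-running the pipeline on
#' the same inputs and config reproduces the tables byte-identically.
#'
#' @param report A `regmodes_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "regmodes_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- report$config
  header <- c(
    paste0("# regmodes ", report$provenance$package_version),
    paste0("# config: ", paste(
      names(unclass(cfg)), unlist(unclass(cfg)),
      sep = "=", collapse = " "
    ))
  )
  emit <- function(x, name) {
    if (is.null(x)) {
      return(invisible(NULL))
    }
    path <- file.path(dir, paste0(name, ".tsv"))
    writeLines(header, path)
    readr::write_tsv(x, path, append = TRUE, col_names = TRUE,
                     progress = FALSE)
  }
  emit(report$master, "master")
  emit(report$crpkm, "crpkm")
  emit(report$class_counts, "class_counts")
  emit(report$table1, "table1")
  emit(report$antimode, "antimode")
  emit(report$tests, "tests")
  emit(report$enrichment, "enrichment")
  emit(report$excluded, "excluded")
  invisible(dir)
}

#' @export
print.regmodes_report <- function(x, ...) {
  cat("regmodes pipeline report\n")
  cat("  genes:", nrow(x$master), "\n")
  cc <- setNames(x$class_counts$n_genes,
                 as.character(x$class_counts$promoter_class))
  for (k in names(cc)) cat(sprintf("    %-24s %d\n", k, cc[[k]]))
  cat("  antimode estimate:",
      formatC(x$antimode$antimode, digits = 3, format = "g"), "\n")
  cat("  DE proteins:", sum(x$master$de_protein, na.rm = TRUE), "\n")
  invisible(x)
}

#' Tidy a pipeline report into per-gene calls
#'
#' @param x A `regmodes_report`.
#' @param ... Unused.
#' @return The per-gene master table (tibble).
#' @exportS3Method generics::tidy
#' @export
tidy.regmodes_report <- function(x, ...) {
  x$master
}

#' One-row summary of a pipeline report
#'
#' @param x A `regmodes_report`.
#' @param ... Unused.
#' @return One-row tibble: gene totals per promoter class, DE-protein
#'   count, post-transcriptional share of DE genes, antimode estimate.
#' @exportS3Method generics::glance
#' @export
glance.regmodes_report <- function(x, ...) {
  cc <- setNames(
    as.list(x$class_counts$n_genes),
    paste0("n_", as.character(x$class_counts$promoter_class))
  )
  de <- filter(x$master, .data$de_protein %in% TRUE, !is.na(.data$group))
  as_tibble(c(
    list(n_genes = nrow(x$master)),
    cc,
    list(
      n_de_proteins = sum(x$master$de_protein, na.rm = TRUE),
      pct_post_transcriptional_de = if (nrow(de) > 0) {
        100 * mean(de$group == "post_transcriptional")
      } else {
        NA_real_
      },
      antimode = x$antimode$antimode
    )
  ))
}
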