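# Four-way promoter classification across the two cell states, per-axis
# differential-state calling at fold thresholds, the 27-combination
# three-axis state space, and its collapse into four broad regulatory
# groupings (with the post-transcriptional split into RNA-level vs
# downstream regulation).

#' Classify promoters by activity in the two cell states
#'
#' Crossing the per-state activity calls yields four classes: active in
#' both, exclusively active in pre-pro-B, exclusively active in pro-B, and
#' inactive in both.
#'
#' @param active_pre,active_pro Logical vectors of activity calls.
#' @return Factor with levels `active_in_both`, `exclusively_pre_pro_B`,
#'   `exclusively_pro_B`, `inactive_in_both`.
#' @export
classify_promoter <- function(active_pre, active_pro) {
  cls <- case_when(
    active_pre & active_pro ~ "active_in_both",
    active_pre & !active_pro ~ "exclusively_pre_pro_B",
    !active_pre & active_pro ~ "exclusively_pro_B",
    !active_pre & !active_pro ~ "inactive_in_both"
  )
  factor(cls, levels = PROMOTER_CLASSES)
}

#' Differential state of one expression axis
#'
#' Fold boundaries are inclusive ("at least" the threshold): `up` when
#' `pro/pre >= fold_threshold`, `down` when `pre/pro >= fold_threshold`,
#' `unchanged` otherwise. A zero on one side with the other side at or above
#' the expression floor is an (infinite-fold) change in that direction; a
#' zero against a value below the floor, or two zeros, is `unchanged` rather
#' than an unsupported infinite fold. Missing values give `undefined`.
#'
#' @param value_pro,value_pre Nonnegative expression values (RPKM or FPKM).
#' @param fold_threshold Fold change calling a difference (> 1).
#' @param floor Expression floor below which a zero-vs-nonzero comparison is
#'   not trusted (default 0.5).
#' @return Character vector over `up`, `unchanged`, `down`, `undefined`.
#' @export
axis_state <- function(value_pro, value_pre, fold_threshold, floor = 0.5) {
  if (fold_threshold <= 1) abort("fold_threshold must be > 1")
  case_when(
    is.na(value_pro) | is.na(value_pre) ~ "undefined",
    value_pro == 0 & value_pre == 0 ~ "unchanged",
    value_pre == 0 & value_pro >= floor ~ "up",
    value_pro == 0 & value_pre >= floor ~ "down",
    value_pre == 0 | value_pro == 0 ~ "unchanged",
    value_pro / value_pre >= fold_threshold ~ "up",
    value_pre / value_pro >= fold_threshold ~ "down",
    .default = "unchanged"
  )
}

#' Differential state of the protein axis from a log2 ratio
#'
#' @param log2_ratio Per-gene protein log2(pro-B / pre-pro-B) ratio.
#' @param fold_threshold Fold change calling a difference (default 1.5,
#'   inclusive).
#' @return Character vector over `up`, `unchanged`, `down`, `undefined`.
#' @export
protein_state <- function(log2_ratio, fold_threshold = 1.5) {
  if (fold_threshold <= 1) abort("fold_threshold must be > 1")
  lt <- log2(fold_threshold)
  case_when(
    is.na(log2_ratio) ~ "undefined",
    log2_ratio >= lt ~ "up",
    log2_ratio <= -lt ~ "down",
    .default = "unchanged"
  )
}

#' Enumerate the three-axis regulatory state space
#'
#' All combinations of (transcription, mRNA, protein) states over
#' `{up, unchanged, down}` in deterministic order: transcription-major, then
#' mRNA, then protein, each ordered up < unchanged < down. The first triple
#' is (up, up, up) and the last (down, down, down).
#'
#' @return Tibble `combination_id` (1..27), `gro_state`, `rna_state`,
#'   `protein_state`.
#' @export
enumerate_combinations <- function() {
  out <- expand_grid(
    gro_state = AXIS_LEVELS, rna_state = AXIS_LEVELS,
    protein_state = AXIS_LEVELS
  )
  dplyr::bind_cols(tibble(combination_id = seq_len(nrow(out))), out)
}

# The verbal grouping rule applied to one fully-defined triple.
group_one <- function(gro, rna, protein) {
  if (protein == "unchanged") {
    return(c("no_protein_change", "n/a"))
  }
  if (gro == protein && rna == protein) {
    return(c("transcriptional", "n/a"))
  }
  if (gro == "unchanged") {
    sub <- if (rna == protein) "rna_level" else "downstream"
    return(c("post_transcriptional", sub))
  }
  c("undetermined_ambiguous", "n/a")
}

#' The default 27-triple to broad-group mapping
#'
#' Collapses every fully-defined triple into one of four broad regulatory
#' groupings: no protein change (protein unchanged, irrespective of the RNA
#' axes); transcriptional (protein change supported by concordant
#' transcription and mRNA changes); post-transcriptional (protein change with
#' unchanged ongoing transcription, irrespective of steady-state mRNA), split
#' into `rna_level` (mRNA moves with the protein, suggesting stability or
#' maturation control) and `downstream` (mRNA flat or discordant, suggesting
#' translation or protein-stability control); and undetermined/ambiguous (all
#' remaining discordant triples). The mapping is data, not code: pass an
#' edited copy to the classifying functions to override it.
#'
#' @return Tibble `gro_state`, `rna_state`, `protein_state`, `group`,
#'   `subgroup` with 27 rows.
#' @export
default_group_mapping <- function() {
  combos <- enumerate_combinations()
  gs <- t(mapply(group_one, combos$gro_state, combos$rna_state,
                 combos$protein_state))
  combos$group <- unname(gs[, 1])
  combos$subgroup <- unname(gs[, 2])
  select(combos, -"combination_id")
}

#' Read a broad-group mapping override table
#'
#' @param path TSV with header `gro_state`, `rna_state`, `protein_state`,
#'   `group`, `subgroup` covering all 27 triples.
#' @return Mapping tibble as from [default_group_mapping()].
#' @export
read_group_mapping <- function(path) {
  x <- readr::read_tsv(path, comment = "#", col_types = "ccccc",
                       progress = FALSE)
  need <- c("gro_state", "rna_state", "protein_state", "group", "subgroup")
  if (!all(need %in% names(x))) {
    abort(paste0("mapping table needs columns: ",
                 paste(need, collapse = ", ")))
  }
  full <- enumerate_combinations()
  joined <- left_join(
    full, x[, need],
    by = c("gro_state", "rna_state", "protein_state")
  )
  if (anyNA(joined$group)) abort("mapping table must cover all 27 triples")
  select(joined, -"combination_id")
}

#' Assign broad regulatory groups to state triples
#'
#' Genes with an undefined protein state are excluded (`NA` group, reported
#' separately); protein `unchanged` is `no_protein_change` irrespective of
#' the other axes (even undefined ones); an undefined transcription or mRNA
#' state alongside a protein change is `undetermined_ambiguous`; all
#' fully-defined triples follow the mapping table.
#'
#' @param gro_state,rna_state,protein_state Character state vectors.
#' @param mapping 27-row mapping tibble (default [default_group_mapping()]).
#' @return Tibble `group`, `subgroup` (same length as input).
#' @export
broad_group <- function(gro_state, rna_state, protein_state,
                        mapping = default_group_mapping()) {
  x <- tibble(
    gro_state = gro_state, rna_state = rna_state,
    protein_state = protein_state
  )
  mapped <- left_join(
    x, mapping,
    by = c("gro_state", "rna_state", "protein_state")
  )
  undef_rna <- gro_state == "undefined" | rna_state == "undefined"
  tibble(
    group = case_when(
      protein_state == "undefined" ~ NA_character_,
      protein_state == "unchanged" ~ "no_protein_change",
      undef_rna ~ "undetermined_ambiguous",
      .default = mapped$group
    ),
    subgroup = case_when(
      protein_state == "undefined" ~ NA_character_,
      protein_state == "unchanged" ~ "n/a",
      undef_rna ~ "n/a",
      .default = mapped$subgroup
    )
  )
}

#' Flag differentially abundant proteins
#'
#' A protein is differential when its absolute log2 ratio reaches
#' `log2(fold)` (boundary inclusive).
#'
#' @param records Tibble with a `protein_log2_ratio` column.
#' @param fold Fold-change threshold (default 1.5).
#' @return `records` with a logical `de_protein` column (`NA` where the
#'   ratio is absent).
#' @export
call_de_proteins <- function(records, fold = 1.5) {
  mutate(records, de_protein = abs(.data$protein_log2_ratio) >= log2(fold))
}

#' Per-gene regulatory calls from the omics table
#'
#' Applies the per-axis state rules (transcription and mRNA at their fold
#' thresholds with the expression floor; protein from its log2 ratio), looks
#' up the combination id, and assigns broad group and subgroup.
#'
#' @param omics Wide per-gene tibble from [build_gene_omics()].
#' @param fold_gro,fold_rna,fold_protein Fold thresholds (defaults 2, 2,
#'   1.5).
#' @param expression_floor Floor for zero-vs-nonzero comparisons (default
#'   0.5).
#' @param mapping Broad-group mapping tibble.
#' @return Tibble `gene_id`, `gro_state`, `rna_state`, `protein_state`,
#'   `combination_id`, `group`, `subgroup`.
#' @export
regulatory_calls <- function(omics, fold_gro = 2, fold_rna = 2,
                             fold_protein = 1.5, expression_floor = 0.5,
                             mapping = default_group_mapping()) {
  gro <- axis_state(omics$rpkm_pro_B, omics$rpkm_pre_pro_B, fold_gro,
                    expression_floor)
  rna <- axis_state(omics$fpkm_pro_B, omics$fpkm_pre_pro_B, fold_rna,
                    expression_floor)
  prot <- protein_state(omics$protein_log2_ratio, fold_protein)
  combos <- enumerate_combinations()
  ids <- left_join(
    tibble(gro_state = gro, rna_state = rna, protein_state = prot),
    combos,
    by = c("gro_state", "rna_state", "protein_state")
  )
  groups <- broad_group(gro, rna, prot, mapping)
  tibble(
    gene_id = omics$gene_id,
    gro_state = gro, rna_state = rna, protein_state = prot,
    combination_id = ids$combination_id,
    group = groups$group, subgroup = groups$subgroup
  )
}
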