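# Synthetic multi-omics generator with full ground truth: a toy genome and
# annotation, ChIP tag libraries realising a bimodal promoter score
# distribution with its antimode near the activity cutoff, GRO-seq counts
# with two transcription populations separated by 2-3 orders of magnitude,
# FPKM values carrying a stability spectrum with cell-state-specific
# unstable transcripts, and peptide-level protein ratios generated under
# transcriptional and post-transcriptional regulatory modes (including one
# designated strongly-protein-down / RNA-flat gene).

#' Parameters of the synthetic-data generator
#'
#' Defaults define the study conditions the generator emulates: promoter
#' class proportions echoing the relative magnitudes of the four observed
#' classes, active/inactive score populations whose density valley sits near
#' the cRPKM cutoff of 8, transcription populations separated by two to
#' three orders of magnitude, a shallower pre-pro-B ChIP library (depth
#' factors 0.30 for H3K4me3, 0.83 for H3ac), and fold-effect distributions
#' per regulatory mode bounded away from the calling thresholds.
#'
#' The genome coordinate span is derived from the library budget:
#' because RPKM self-normalises to the library total, the background RPKM
#' floor per mark fixes `genome_bp ~ (1e6 - 0.4 * sum(target RPKM)) * 1000 /
#' background_rpkm`, which places realised scores on the intended scale.
#'
#' @param n_genes Number of genes (default 5000).
#' @param class_props Named proportions over the four promoter classes
#'   (must sum to 1).
#' @param protein_fraction Fraction of genes with peptide coverage.
#' @param active_crpkm_meanlog10,active_crpkm_sdlog10 Log10-normal
#'   parameters of the active-promoter target score population.
#' @param inactive_crpkm_meanlog10,inactive_crpkm_sdlog10 Same for the
#'   inactive population.
#' @param antimode_target Score the two populations' density valley is
#'   designed to bracket (default 8).
#' @param rate_high_meanlog10,rate_high_sdlog10 Log10-normal parameters of
#'   the transcribed-population GRO RPKM.
#' @param rate_low_meanlog10,rate_low_sdlog10 Same for the inactive
#'   population (medians 2-3 orders of magnitude apart).
#' @param stability_meanlog10,stability_sdlog10 Log10-normal parameters of
#'   the baseline FPKM/RPKM stability multiplier.
#' @param unstable_fraction Fraction of genes given a state-specific
#'   unstable transcript.
#' @param unstable_factor Stability multiplier applied in the unstable
#'   state (default 0.05).
#' @param fold_changed_range,fold_flat_max Fold ranges for changed and
#'   unchanged transcription/mRNA axes (thresold 2 is avoided by design).
#' @param protein_fold_changed_range,protein_fold_flat_max Same for the
#'   protein axis (threshold 1.5).
#' @param chip_library_size Nominal pro-B ChIP library size in tags.
#' @param depth_factors_pre Named per-mark depth factors of the pre-pro-B
#'   libraries relative to pro-B.
#' @param background_rpkm Genome-wide background signal per mark, RPKM.
#' @param tag_length ChIP/GRO tag length in bp.
#' @param mark_share_range Range of the H3K4me3 share of a promoter's
#'   signal.
#' @param n_amplicons Inactive promoters given a spurious single-mark
#'   amplicon stack.
#' @param amplicon_tags Identical-position tags per injected amplicon.
#' @param gro_library_size GRO-seq library total (denominator for RPKM).
#' @param fpkm_noise_sdlog10 Log10 measurement noise on FPKM.
#' @param peptide_sdlog2 Peptide-level noise around the true protein log2
#'   effect.
#' @param peptide_mean_extra Mean extra peptides per protein beyond the
#'   first (Poisson).
#' @param max_peptides Cap on peptides per protein.
#' @param ambiguous_peptide_fraction Fraction of extra ambiguously-mapped
#'   peptide rows.
#' @param gene_length_range Gene span range, bp.
#' @param n_chromosomes Chromosomes in the toy genome.
#' @param noise Global noise switch/scale: 1 applies the full sampling
#'   models; 0 is the deterministic zero-noise limit (expected counts,
#'   no background tags, score populations clamped apart).
#' @param seed Integer seed; the entire fixture is reproducible from it.
#' @return A `generator_params` list.
#' @export
generator_params <- function(
    n_genes = 5000,
    class_props = c(
      active_in_both = 0.45, inactive_in_both = 0.465,
      exclusively_pre_pro_B = 0.015, exclusively_pro_B = 0.07
    ),
    protein_fraction = 0.6,
    active_crpkm_meanlog10 = 1.9, active_crpkm_sdlog10 = 0.25,
    inactive_crpkm_meanlog10 = -0.05, inactive_crpkm_sdlog10 = 0.35,
    antimode_target = 8,
    rate_high_meanlog10 = 1.2, rate_high_sdlog10 = 0.45,
    rate_low_meanlog10 = -1.5, rate_low_sdlog10 = 0.45,
    stability_meanlog10 = 0, stability_sdlog10 = 0.25,
    unstable_fraction = 0.05, unstable_factor = 0.05,
    fold_changed_range = c(2.5, 12), fold_flat_max = 1.3,
    protein_fold_changed_range = c(1.8, 6), protein_fold_flat_max = 1.25,
    chip_library_size = 2e6,
    depth_factors_pre = c(H3K4me3 = 0.30, H3ac = 0.83),
    background_rpkm = 0.4,
    tag_length = 36,
    mark_share_range = c(0.35, 0.65),
    n_amplicons = 5, amplicon_tags = 30,
    gro_library_size = 2e6,
    fpkm_noise_sdlog10 = 0.08,
    peptide_sdlog2 = 0.25, peptide_mean_extra = 3, max_peptides = 10,
    ambiguous_peptide_fraction = 0.02,
    gene_length_range = c(2000, 30000),
    n_chromosomes = 5,
    noise = 1, seed = 1) {
  params <- as.list(environment())
  if (abs(sum(params$class_props) - 1) > 1e-8) {
    abort("class_props must sum to 1")
  }
  if (!setequal(names(params$class_props), PROMOTER_CLASSES)) {
    abort("class_props must name the four promoter classes")
  }
  if (any(unlist(params[c(
    "chip_library_size", "gro_library_size", "background_rpkm",
    "tag_length", "unstable_factor"
  )]) <= 0)) {
    abort("scales must be positive")
  }
  structure(params, class = "generator_params")
}

# Regulatory-mode proportions per promoter class. Flat-chromatin classes
# carry the post-transcriptional modes (among their protein-DE genes the
# post-transcriptional share is ~60%, echoing the observed predominance);
# exclusive classes are mostly transcriptional.
mode_props_for_class <- function(class) {
  switch(class,
    active_in_both = c(
      no_protein_change = 0.50, transcriptional = 0.12,
      post_rna = 0.09, post_down = 0.21, ambiguous = 0.08
    ),
    inactive_in_both = c(no_protein_change = 0.80, post_down = 0.20),
    exclusively_pre_pro_B = ,
    exclusively_pro_B = c(
      transcriptional = 0.70, no_protein_change = 0.20, ambiguous = 0.10
    )
  )
}

runif_log <- function(n, range, base = 10) {
  base^runif(n, log(range[1], base), log(range[2], base))
}

#' Generate the ground truth of a synthetic study
#'
#' Draws the complete latent state of a two-cell-state study: genome layout
#' and gene models, per-state promoter score targets, transcription rates,
#' stability multipliers, per-gene regulatory modes with consistent fold
#' effects (a transcriptional-mode gene's transcription, mRNA and protein
#' folds are concordant by construction), injected single-mark amplicon
#' artifacts, and one designated gene with a 24-fold protein decrease on
#' flat transcription and mRNA. Deterministic given the seed.
#'
#' @param params A [generator_params()] list.
#' @return List of class `regmodes_truth`: `layout`, `genes` (annotation
#'   columns plus all truth columns), `params`.
#' @export
generate_truth <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  local_seed(params$seed)
  n <- params$n_genes

  cls <- sample(names(params$class_props), n,
    replace = TRUE, prob = params$class_props
  )
  # every class with positive proportion is represented
  for (k in names(params$class_props)) {
    if (params$class_props[[k]] > 0 && !any(cls == k)) {
      cls[sample.int(n, 1)] <- k
    }
  }

  active_pre <- cls %in% c("active_in_both", "exclusively_pre_pro_B")
  active_pro <- cls %in% c("active_in_both", "exclusively_pro_B")

  draw_crpkm <- function(active) {
    t <- ifelse(
      active,
      10^rnorm(n, params$active_crpkm_meanlog10,
               params$active_crpkm_sdlog10),
      10^rnorm(n, params$inactive_crpkm_meanlog10,
               params$inactive_crpkm_sdlog10)
    )
    if (params$noise == 0) {
      # zero-noise limit: populations clamped apart so activity calls are
      # deterministic
      t <- ifelse(active, pmax(t, 4 * params$antimode_target),
                  pmin(t, params$antimode_target / 4))
    }
    t
  }
  crpkm_pre <- draw_crpkm(active_pre)
  crpkm_pro <- draw_crpkm(active_pro)
  mark_share <- runif(n, params$mark_share_range[1],
                      params$mark_share_range[2])

  # regulatory mode per gene, conditional on the chromatin class
  mode <- character(n)
  for (k in unique(cls)) {
    props <- mode_props_for_class(k)
    idx <- which(cls == k)
    mode[idx] <- sample(names(props), length(idx),
      replace = TRUE, prob = props
    )
  }

  flat_class <- cls %in% c("active_in_both", "inactive_in_both")
  dir_sign <- sample(c(-1, 1), n, replace = TRUE)
  # exclusive classes have their transcription direction fixed by the class
  dir_sign[cls == "exclusively_pre_pro_B"] <- -1
  dir_sign[cls == "exclusively_pro_B"] <- 1

  flat_fold <- function(m) {
    runif_log(m, c(1 / params$fold_flat_max, params$fold_flat_max))
  }
  changed_fold <- function(m) runif_log(m, params$fold_changed_range)

  gro_fold <- flat_fold(n)
  gro_changed <- (!flat_class) |
    (flat_class & mode %in% c("transcriptional", "ambiguous"))
  gro_fold[gro_changed] <-
    changed_fold(sum(gro_changed))^dir_sign[gro_changed]

  jitter <- runif(n, 0.95, 1.05)
  rna_fold <- flat_fold(n)
  rna_follows <- mode %in% c("transcriptional", "no_protein_change") &
    gro_changed
  rna_fold[rna_follows] <- gro_fold[rna_follows] * jitter[rna_follows]
  post_rna <- mode == "post_rna"
  rna_fold[post_rna] <- changed_fold(sum(post_rna))^dir_sign[post_rna]

  protein_dir <- dir_sign
  protein_log2 <- dir_sign *
    runif(n, 0, log2(params$protein_fold_flat_max))
  prot_changed <- mode %in% c(
    "transcriptional", "post_rna", "post_down", "ambiguous"
  )
  protein_log2[prot_changed] <- (dir_sign * log2(
    runif_log(n, params$protein_fold_changed_range, base = 2)
  ))[prot_changed]

  # transcription rates: reference state draws from the high or low
  # population per its activity; the other state follows the fold
  base_high <- 10^rnorm(n, params$rate_high_meanlog10,
                        params$rate_high_sdlog10)
  base_low <- 10^rnorm(n, params$rate_low_meanlog10,
                       params$rate_low_sdlog10)
  rate_pre <- ifelse(active_pre, base_high, base_low)
  rate_pre[cls == "exclusively_pro_B"] <-
    (base_high / pmax(gro_fold, 1))[cls == "exclusively_pro_B"]
  rate_pro <- rate_pre * gro_fold

  # stability multipliers consistent with the mRNA fold, then the
  # state-specific unstable subset (drawn from flat-transcription
  # no-protein-change genes so the mode stays consistent)
  stab_pre <- 10^rnorm(n, params$stability_meanlog10,
                       params$stability_sdlog10)
  stab_pro <- stab_pre * rna_fold / gro_fold
  pool <- which(cls == "active_in_both" & mode == "no_protein_change")
  n_unstable <- min(length(pool), round(params$unstable_fraction * n))
  unstable_idx <- if (n_unstable > 0) sample(pool, n_unstable) else integer()
  unstable_state <- rep("none", n)
  unstable_state[unstable_idx] <-
    sample(CELL_STATES, n_unstable, replace = TRUE)
  in_pre <- unstable_state == "pre_pro_B"
  stab_pre[in_pre] <- stab_pre[in_pre] * params$unstable_factor
  in_pro <- unstable_state == "pro_B"
  stab_pro[in_pro] <- stab_pro[in_pro] * params$unstable_factor
  rna_fold <- gro_fold * stab_pro / stab_pre

  has_protein <- runif(n) < params$protein_fraction

  # the designated strongly-protein-down / RNA-flat gene
  rik <- which(cls == "active_in_both")[1]
  if (is.na(rik)) abort("no active_in_both gene to designate")
  mode[rik] <- "post_down"
  gro_fold[rik] <- 1
  stab_pro[rik] <- stab_pre[rik]
  rna_fold[rik] <- 1
  rate_pro[rik] <- rate_pre[rik]
  protein_log2[rik] <- -log2(24)
  has_protein[rik] <- TRUE
  riklike <- seq_len(n) == rik

  # spurious single-mark amplicon artifacts at inactive promoters; the
  # artifact is part of the noise model, so the zero-noise limit has none
  inactive_pool <- setdiff(which(cls == "inactive_in_both"), rik)
  n_amp <- if (params$noise == 0) 0L else {
    min(params$n_amplicons, length(inactive_pool))
  }
  amplicon <- seq_len(n) %in%
    (if (n_amp > 0) sample(inactive_pool, n_amp) else integer())

  # genome span from the library budget (see generator_params docs)
  s_mean <- 0.5 * (sum(crpkm_pre) + sum(crpkm_pro)) / 2
  promoter_kb <- 0.4
  budget <- 1e6 - promoter_kb * s_mean
  if (budget <= 0) abort("promoter signal exceeds the library budget")
  genome_bp <- budget * 1000 / params$background_rpkm
  chrom_len <- ceiling(genome_bp / params$n_chromosomes)
  layout <- genome_layout(
    paste0("chr", seq_len(params$n_chromosomes)),
    rep(chrom_len, params$n_chromosomes)
  )

  # gene placement: round-robin over chromosomes, one gene per slot
  chrom_idx <- rep(seq_len(params$n_chromosomes), length.out = n)
  within_idx <- stats::ave(seq_len(n), chrom_idx, FUN = seq_along)
  genes_per_chrom <- tabulate(chrom_idx, params$n_chromosomes)
  slot <- floor(chrom_len / max(genes_per_chrom))
  len <- round(runif_log(n, params$gene_length_range))
  margin <- 25000
  if (slot <= max(len) + 2 * margin) {
    abort("genome too small for the requested gene count")
  }
  start <- (within_idx - 1) * slot + margin +
    floor(runif(n) * (slot - len - 2 * margin))
  strand <- sample(c("+", "-"), n, replace = TRUE)

  genes <- tibble(
    gene_id = sprintf("g%05d", seq_len(n)),
    chrom = layout$chrom[chrom_idx],
    strand = strand,
    start = start,
    end = start + len,
    length = len,
    promoter_class = cls,
    crpkm_pre_pro_B = crpkm_pre,
    crpkm_pro_B = crpkm_pro,
    mark_share = mark_share,
    rate_pre_pro_B = rate_pre,
    rate_pro_B = rate_pro,
    stab_pre_pro_B = stab_pre,
    stab_pro_B = stab_pro,
    gro_fold = gro_fold,
    rna_fold = rna_fold,
    protein_log2 = protein_log2,
    has_protein = has_protein,
    mode = mode,
    unstable_state = unstable_state,
    amplicon = amplicon,
    riklike = riklike
  )
  structure(
    list(layout = layout, genes = genes, params = params),
    class = "regmodes_truth"
  )
}

# Broad group + subgroup implied by a truth mode label.
truth_group <- function(mode) {
  group <- case_when(
    mode %in% c("post_rna", "post_down") ~ "post_transcriptional",
    mode == "ambiguous" ~ "undetermined_ambiguous",
    .default = mode
  )
  subgroup <- case_when(
    mode == "post_rna" ~ "rna_level",
    mode == "post_down" ~ "downstream",
    .default = "n/a"
  )
  tibble(group = group, subgroup = subgroup)
}

# Draw ChIP tag positions realising `counts[i]` tags overlapping promoter i
# (5' positions under a triangular kernel around the TSS, clamped so every
# tag overlaps the +/-200 bp window).
promoter_tag_positions <- function(tss, counts, tag_length) {
  total <- sum(counts)
  if (total == 0) {
    return(integer())
  }
  centre <- rep(tss, counts)
  # triangular kernel; clamped so [p, p + tag_length) always overlaps the
  # +/-200 bp promoter window
  off <- round((runif(total) + runif(total) - 1) * 230)
  off <- pmin(pmax(off, max(-230, -(200 + tag_length) + 1)), 195)
  as.integer(centre + off)
}

#' Simulate the measured dataset from a ground truth
#'
#' Realises all measurements: per-mark per-state ChIP tag libraries
#' (promoter tags Poisson around the score targets, genome-wide uniform
#' background filling each library to its nominal depth, identical-position
#' amplicon stacks at the designated inactive promoters), GRO-seq per-gene
#' counts, an FPKM table with log-normal measurement noise, and a peptide
#' table with peptide-level noise plus ambiguously-mapped rows. With
#' `noise = 0` every measurement equals its expectation and no background
#' tags are drawn.
#'
#' @param truth A `regmodes_truth` object from [generate_truth()].
#' @return List of class `regmodes_dataset`: `layout`, `genes` (annotation
#'   columns), `chip_tags`, `gro` (list of `counts`, `library_sizes`),
#'   `fpkm`, `peptides`, `truth`, `params`.
#' @export
simulate_dataset <- function(truth) {
  stopifnot(inherits(truth, "regmodes_truth"))
  params <- truth$params
  g <- truth$genes
  local_seed(params$seed + 1L)
  n <- nrow(g)
  tss <- gene_tss(g)
  promoter_kb <- 0.4
  noisy <- params$noise > 0

  chip <- list()
  for (state in CELL_STATES) {
    for (mk in MARKS) {
      depth <- if (state == "pre_pro_B") params$depth_factors_pre[[mk]] else 1
      m_nom <- params$chip_library_size * depth / 1e6
      share <- if (mk == "H3K4me3") g$mark_share else 1 - g$mark_share
      lambda <- g[[paste0("crpkm_", state)]] * share * promoter_kb * m_nom
      counts <- if (noisy) rpois(n, lambda) else round(lambda)
      pos <- promoter_tag_positions(tss, counts, params$tag_length)
      tags <- tibble(
        chrom = rep(g$chrom, counts),
        start = pos,
        end = pos + params$tag_length,
        strand = sample(c("+", "-"), length(pos), replace = TRUE)
      )
      # amplicon stacks: many tags sharing one 5' position, H3K4me3 only
      if (mk == "H3K4me3" && any(g$amplicon)) {
        amp <- g[g$amplicon, ]
        amp_pos <- rep(gene_tss(amp) + 50L, each = params$amplicon_tags)
        tags <- bind_rows(tags, tibble(
          chrom = rep(amp$chrom, each = params$amplicon_tags),
          start = amp_pos,
          end = amp_pos + params$tag_length,
          strand = "+"
        ))
      }
      # background tags fill the library to its nominal depth; uniform
      # random at noise > 0, an even deterministic grid in the zero-noise
      # limit (so the RPKM denominators stay on scale without sampling)
      n_bg <- max(0, round(m_nom * 1e6) - nrow(tags))
      if (n_bg > 0) {
        if (noisy) {
          ci <- sample.int(nrow(truth$layout), n_bg,
            replace = TRUE, prob = truth$layout$length
          )
          bg_start <- floor(runif(
            n_bg, 0, truth$layout$length[ci] - params$tag_length
          ))
          bg <- tibble(
            chrom = truth$layout$chrom[ci],
            start = bg_start,
            end = bg_start + params$tag_length,
            strand = sample(c("+", "-"), n_bg, replace = TRUE)
          )
        } else {
          per_chrom <- round(n_bg * truth$layout$length /
                               sum(truth$layout$length))
          bg <- list_rbind(lapply(seq_len(nrow(truth$layout)), function(ci) {
            b <- per_chrom[ci]
            if (b < 1) {
              return(NULL)
            }
            pos <- floor((seq_len(b) - 0.5) * truth$layout$length[ci] / b)
            tibble(
              chrom = truth$layout$chrom[ci], start = pos,
              end = pos + params$tag_length, strand = "+"
            )
          }))
        }
        tags <- bind_rows(tags, bg)
      }
      tags$mark <- mk
      tags$cell_state <- state
      chip[[paste(state, mk, sep = "_")]] <- tags
    }
  }
  chip_tags <- list_rbind(chip)

  len_kb <- g$length / 1000
  m_gro <- params$gro_library_size / 1e6
  gro_lambda_pre <- g$rate_pre_pro_B * len_kb * m_gro
  gro_lambda_pro <- g$rate_pro_B * len_kb * m_gro
  gro_counts <- tibble(
    gene_id = g$gene_id,
    count_pre_pro_B = if (noisy) rpois(n, gro_lambda_pre) else gro_lambda_pre,
    count_pro_B = if (noisy) rpois(n, gro_lambda_pro) else gro_lambda_pro
  )

  fpkm_noise <- function() {
    if (noisy) 10^rnorm(n, 0, params$fpkm_noise_sdlog10) else 1
  }
  fpkm <- tibble(
    gene_id = g$gene_id,
    fpkm_pre_pro_B = g$rate_pre_pro_B * g$stab_pre_pro_B * fpkm_noise(),
    fpkm_pro_B = g$rate_pro_B * g$stab_pro_B * fpkm_noise()
  )

  with_prot <- which(g$has_protein)
  n_pep <- 1L + if (noisy) {
    rpois(length(with_prot), params$peptide_mean_extra)
  } else {
    rep(round(params$peptide_mean_extra), length(with_prot))
  }
  n_pep <- pmin(n_pep, params$max_peptides)
  pep_gene <- rep(g$gene_id[with_prot], n_pep)
  pep_mu <- rep(g$protein_log2[with_prot], n_pep)
  pep_ratio <- pep_mu +
    if (noisy) rnorm(length(pep_mu), 0, params$peptide_sdlog2) else 0
  n_amb <- if (noisy) {
    round(params$ambiguous_peptide_fraction * length(pep_ratio))
  } else {
    0L
  }
  peptides <- tibble(
    peptide_id = sprintf("pep%06d", seq_len(length(pep_ratio) + n_amb)),
    gene_id = c(pep_gene, rep("AMBIGUOUS", n_amb)),
    log2_ratio_pro_over_pre = c(pep_ratio, rnorm(n_amb, 0, 1))
  )

  structure(
    list(
      layout = truth$layout,
      genes = select(
        g, "gene_id", "chrom", "strand", "start", "end"
      ),
      chip_tags = chip_tags,
      gro = list(
        counts = gro_counts,
        library_sizes = c(
          pre_pro_B = params$gro_library_size,
          pro_B = params$gro_library_size
        )
      ),
      fpkm = fpkm,
      peptides = peptides,
      truth = g,
      params = params
    ),
    class = "regmodes_dataset"
  )
}

#' Write a simulated dataset as a plain-text fixture
#'
#' Emits the exact dialects the analysis functions consume: BED6 tag files
#' per (state, mark) library, a GTF annotation, the GRO count, FPKM and
#' peptide TSVs, the genome layout, the ground-truth table and the
#' generator parameters (YAML). [read_fixture()] reproduces the in-memory
#' dataset.
#'
#' @param dataset A `regmodes_dataset` from [simulate_dataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(dataset, dir) {
  stopifnot(inherits(dataset, "regmodes_dataset"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, 2) != 0) {
    abort(paste0("cannot write to directory: ", dir))
  }
  readr::write_tsv(dataset$layout, file.path(dir, "layout.tsv"),
                   progress = FALSE)
  write_gtf(dataset$genes, file.path(dir, "annotation.gtf"))
  for (state in CELL_STATES) {
    for (mk in MARKS) {
      sel <- dataset$chip_tags$cell_state == state &
        dataset$chip_tags$mark == mk
      write_bed6(
        dataset$chip_tags[sel, c("chrom", "start", "end", "strand")],
        file.path(dir, sprintf("chip_%s_%s.bed", state, mk))
      )
    }
  }
  write_gro_counts(
    dataset$gro$counts, dataset$gro$library_sizes,
    file.path(dir, "gro_counts.tsv")
  )
  write_fpkm_table(dataset$fpkm, file.path(dir, "fpkm.tsv"))
  write_peptide_table(dataset$peptides, file.path(dir, "peptides.tsv"))
  readr::write_tsv(dataset$truth, file.path(dir, "truth.tsv"),
                   progress = FALSE)
  prm <- dataset$params
  prm$class_props <- as.list(prm$class_props)
  prm$depth_factors_pre <- as.list(prm$depth_factors_pre)
  yaml::write_yaml(unclass(prm), file.path(dir, "params.yaml"))
  invisible(dir)
}

#' Read a fixture directory back into a dataset
#'
#' @param dir Directory written by [write_fixture()].
#' @return A `regmodes_dataset` list.
#' @export
read_fixture <- function(dir) {
  layout <- readr::read_tsv(file.path(dir, "layout.tsv"), col_types = "cd",
                            progress = FALSE)
  genes <- read_gene_models(file.path(dir, "annotation.gtf")) |>
    select(-"transcript_id")
  chip <- list()
  for (state in CELL_STATES) {
    for (mk in MARKS) {
      b <- read_bed6(file.path(dir, sprintf("chip_%s_%s.bed", state, mk)))
      chip[[paste(state, mk, sep = "_")]] <- tibble(
        chrom = b$chrom, start = b$start, end = b$end, strand = b$strand,
        mark = mk, cell_state = state
      )
    }
  }
  gro <- read_gro_counts(file.path(dir, "gro_counts.tsv"))
  prm <- yaml::read_yaml(file.path(dir, "params.yaml"))
  prm$class_props <- unlist(prm$class_props)
  prm$depth_factors_pre <- unlist(prm$depth_factors_pre)
  params <- do.call(generator_params, prm)
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path)) {
    readr::read_tsv(truth_path, progress = FALSE, show_col_types = FALSE)
  } else {
    NULL
  }
  structure(
    list(
      layout = layout, genes = genes, chip_tags = list_rbind(chip),
      gro = gro, fpkm = read_fpkm_table(file.path(dir, "fpkm.tsv")),
      peptides = read_peptide_table(file.path(dir, "peptides.tsv")),
      truth = truth, params = params
    ),
    class = "regmodes_dataset"
  )
}

#' Score a pipeline report against the generator's ground truth
#'
#' @param report A `regmodes_report` from [run_pipeline()].
#' @param truth Truth tibble (the `truth` element of the dataset).
#' @return One-row tibble: promoter-class, axis-state and broad-group
#'   accuracies, stability-differential sign accuracy on the unstable
#'   subset, and whether the designated protein-down/RNA-flat gene is
#'   called post-transcriptional/downstream.
#' @export
score_against_truth <- function(report, truth) {
  cfg <- report$config
  m <- left_join(
    truth, report$master,
    by = "gene_id", suffix = c(".truth", "")
  )
  class_acc <- mean(m$promoter_class == m$promoter_class.truth)

  implied_gro <- axis_state(m$gro_fold, rep(1, nrow(m)), cfg$fold_gro,
                            floor = 0)
  implied_rna <- axis_state(m$rna_fold, rep(1, nrow(m)), cfg$fold_rna,
                            floor = 0)
  implied_prot <- protein_state(
    ifelse(m$has_protein, m$protein_log2, NA_real_), cfg$fold_protein
  )
  axis_acc <- mean(
    m$gro_state == implied_gro & m$rna_state == implied_rna &
      m$protein_state == implied_prot
  )

  tg <- truth_group(m$mode)
  with_prot <- which(m$has_protein)
  group_acc <- mean(m$group[with_prot] == tg$group[with_prot], na.rm = FALSE)

  uns <- which(m$unstable_state != "none")
  expected_sign <- sign(log10(m$stab_pro_B[uns] / m$stab_pre_pro_B[uns]))
  stab_acc <- if (length(uns) > 0) {
    mean(!is.na(m$stability_differential[uns]) &
           sign(m$stability_differential[uns]) == expected_sign)
  } else {
    NA_real_
  }

  rik <- which(m$riklike)
  rik_ok <- length(rik) == 1 &&
    identical(m$group[rik], "post_transcriptional") &&
    identical(m$subgroup[rik], "downstream")

  tibble(
    promoter_class_accuracy = class_acc,
    axis_state_accuracy = axis_acc,
    broad_group_accuracy = group_acc,
    stability_sign_accuracy = stab_acc,
    riklike_ok = rik_ok
  )
}
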