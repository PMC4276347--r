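# Promoter-activity scoring from ChIP-seq tags: per-interval tag counting,
# per-mark RPKM, the cumulative cRPKM score summed over H3K4me3 and H3ac,
# activity calling at a score threshold with a single-mark/spurious-amplicon
# guard, and data-driven estimation of the activity threshold as the antimode
# of the bimodal score distribution.

#' Count tags overlapping each interval
#'
#' A tag `[start, start + length)` contributes one count to every interval it
#' overlaps by at least 1 bp (a tag spanning two abutting promoters counts in
#' both). Tags on chromosomes absent from the layout are skipped with a
#' tallied message.
#'
#' @param tags Tag tibble: `chrom`, `start`, `end` (0-based half-open),
#'   optionally `strand`.
#' @param intervals Interval tibble (`chrom`, `start`, `end`, `label`).
#' @param layout Optional genome layout; when given, off-layout tags are
#'   dropped before counting.
#' @return `intervals` with an integer `count` column appended.
#' @export
count_overlapping_tags <- function(tags, intervals, layout = NULL) {
  assert_intervals(tags)
  assert_intervals(intervals)
  if (!is.null(layout)) {
    assert_layout(layout)
    off <- !(tags$chrom %in% layout$chrom)
    if (any(off)) {
      inform(sprintf(
        "skipped %d tag(s) on chromosome(s) absent from the layout", sum(off)
      ))
      tags <- tags[!off, , drop = FALSE]
    }
  }
  out <- dplyr::mutate(intervals, count = 0L)
  keep <- intervals$end > intervals$start
  if (nrow(tags) == 0 || !any(keep)) {
    return(out)
  }
  levels <- union(unique(intervals$chrom), unique(tags$chrom))
  iv_gr <- GenomicRanges::GRanges(
    seqnames = factor(intervals$chrom[keep], levels = levels),
    ranges = IRanges::IRanges(
      start = intervals$start[keep] + 1,
      end = intervals$end[keep]
    )
  )
  tag_gr <- GenomicRanges::GRanges(
    seqnames = factor(tags$chrom, levels = levels),
    ranges = IRanges::IRanges(start = tags$start + 1, end = tags$end)
  )
  out$count[keep] <- GenomicRanges::countOverlaps(
    iv_gr, tag_gr, minoverlap = 1L, ignore.strand = TRUE
  )
  out
}

# For each (interval, mark) pair: the largest fraction of its overlapping tags
# sharing one identical 5' position. Used by the spurious-amplicon rule.
max_dup_fraction <- function(tags, intervals) {
  keep <- intervals$end > intervals$start
  res <- rep(0, nrow(intervals))
  if (nrow(tags) == 0 || !any(keep)) {
    return(res)
  }
  levels <- union(unique(intervals$chrom), unique(tags$chrom))
  iv_gr <- GenomicRanges::GRanges(
    seqnames = factor(intervals$chrom[keep], levels = levels),
    ranges = IRanges::IRanges(
      start = intervals$start[keep] + 1,
      end = intervals$end[keep]
    )
  )
  tag_gr <- GenomicRanges::GRanges(
    seqnames = factor(tags$chrom, levels = levels),
    ranges = IRanges::IRanges(start = tags$start + 1, end = tags$end)
  )
  hits <- GenomicRanges::findOverlaps(iv_gr, tag_gr, minoverlap = 1L,
                                      ignore.strand = TRUE)
  if (length(hits) == 0) {
    return(res)
  }
  strand5 <- if ("strand" %in% names(tags)) tags$strand else "+"
  pos5 <- ifelse(strand5 == "-", tags$end - 1, tags$start)
  q <- S4Vectors::queryHits(hits)
  p <- pos5[S4Vectors::subjectHits(hits)]
  tab <- tibble(q = q, p = p) |>
    dplyr::count(.data$q, .data$p) |>
    dplyr::group_by(.data$q) |>
    dplyr::summarise(frac = max(.data$n) / sum(.data$n), .groups = "drop")
  res[which(keep)[tab$q]] <- tab$frac
  res
}

#' Score intervals with the cumulative cRPKM statistic
#'
#' Per cell state and per mark, each interval's tag count is normalised to
#' interval size and library size:
#' `RPKM = count / (width_kb * library_size_millions)`, with the library size
#' taken as the total number of tags supplied for that (mark, state) library.
#' The per-mark RPKMs of the two marks are then summed into the cumulative
#' score `crpkm`. Zero-width (fully clipped) intervals get `NA` RPKMs.
#'
#' @param tags Tag tibble with `chrom`, `start`, `end`, `strand`, and the
#'   library keys `mark` and `cell_state`; exactly one library per mark per
#'   state, both marks present.
#' @param intervals Interval tibble with `label`.
#' @param layout Optional genome layout used to drop off-layout tags.
#' @return Tibble with one row per interval per cell state: `label`,
#'   `cell_state`, per-mark `count_*`, `rpkm_*` and `dupfrac_*` columns (the
#'   latter the largest fraction of a mark's overlapping tags sharing one 5'
#'   position), and `crpkm`.
#' @export
score_intervals <- function(tags, intervals, layout = NULL) {
  if (!all(c("mark", "cell_state") %in% names(tags))) {
    abort("tags need 'mark' and 'cell_state' columns")
  }
  assert_intervals(intervals)
  if (!"label" %in% names(intervals)) abort("intervals need a 'label' column")
  states <- sort(unique(tags$cell_state))
  width_kb <- (intervals$end - intervals$start) / 1000
  per_state <- lapply(states, function(state) {
    st <- tags[tags$cell_state == state, , drop = FALSE]
    missing <- setdiff(MARKS, unique(st$mark))
    if (length(missing) > 0) {
      abort(paste0(
        "cell state '", state, "' is missing mark(s): ",
        paste(missing, collapse = ", ")
      ))
    }
    per_mark <- lapply(MARKS, function(mk) {
      lib <- st[st$mark == mk, , drop = FALSE]
      lib_m <- nrow(lib) / 1e6
      if (lib_m <= 0) {
        abort(paste0("empty ", mk, " library for state '", state, "'"))
      }
      counted <- count_overlapping_tags(lib, intervals, layout)
      rpkm <- ifelse(width_kb > 0, counted$count / (width_kb * lib_m),
                     NA_real_)
      tibble(
        label = intervals$label,
        mark = mk,
        count = counted$count,
        rpkm = rpkm,
        dupfrac = max_dup_fraction(lib, intervals)
      )
    })
    out <- list_rbind(per_mark) |>
      pivot_wider(
        names_from = "mark",
        values_from = c("count", "rpkm", "dupfrac")
      )
    out$cell_state <- state
    out$crpkm <- out$rpkm_H3K4me3 + out$rpkm_H3ac
    dplyr::relocate(out, "label", "cell_state")
  })
  list_rbind(per_state)
}

#' Call active promoters from cRPKM scores
#'
#' A promoter is active when its cumulative score strictly exceeds the
#' threshold (ties are inactive) and the signal is not carried by a single
#' mark: when one mark's RPKM falls below `single_mark_epsilon` while the
#' total still clears the threshold, the score is treated as spurious and the
#' promoter set inactive (`single_mark = TRUE`). Such single-mark promoters
#' are additionally flagged `amplicon_suspect` when at least
#' `amplicon_fraction` of the dominant mark's overlapping tags share one
#' identical 5' position, the signature of a PCR amplicon stack.
#'
#' @param records Score tibble from [score_intervals()].
#' @param threshold Activity cutoff on `crpkm` (default 8, strict `>`).
#' @param single_mark_epsilon RPKM below which a mark counts as absent
#'   (default 0.5).
#' @param amplicon_fraction Duplicate-5'-position fraction flagging an
#'   amplicon stack (default 0.75).
#' @return `records` with logical columns `active`, `single_mark`,
#'   `amplicon_suspect` filled in.
#' @export
call_active <- function(records, threshold = 8, single_mark_epsilon = 0.5,
                        amplicon_fraction = 0.75) {
  if (threshold <= 0) abort("threshold must be > 0")
  over <- !is.na(records$crpkm) & records$crpkm > threshold
  low_mark <- pmin(records$rpkm_H3K4me3, records$rpkm_H3ac)
  single <- over & !is.na(low_mark) & low_mark < single_mark_epsilon
  dominant_dup <- ifelse(
    records$rpkm_H3K4me3 >= records$rpkm_H3ac,
    records$dupfrac_H3K4me3, records$dupfrac_H3ac
  )
  dplyr::mutate(
    records,
    single_mark = single,
    amplicon_suspect = single & dominant_dup >= amplicon_fraction,
    active = over & !single
  )
}

# Deterministic two-component univariate Gaussian mixture via EM:
# median-split initialisation, variance floor against point-mass collapse
# (score distributions contain exact duplicates from low integer counts).
gmm2_fit <- function(z, max_iter = 500, tol = 1e-8, var_floor = 1e-3) {
  mid <- stats::median(z)
  lower <- z[z <= mid]
  upper <- z[z > mid]
  if (length(upper) < 2 || length(lower) < 2) {
    return(NULL)
  }
  mu <- c(mean(lower), mean(upper))
  v <- pmax(c(stats::var(lower), stats::var(upper)), var_floor)
  pi <- c(length(lower), length(upper)) / length(z)
  ll_old <- -Inf
  for (i in seq_len(max_iter)) {
    d1 <- pi[1] * stats::dnorm(z, mu[1], sqrt(v[1]))
    d2 <- pi[2] * stats::dnorm(z, mu[2], sqrt(v[2]))
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r <- d1 / tot
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol) break
    ll_old <- ll
    n1 <- sum(r)
    n2 <- length(z) - n1
    if (n1 < 1 || n2 < 1) {
      return(NULL)
    }
    mu <- c(sum(r * z) / n1, sum((1 - r) * z) / n2)
    v <- pmax(c(
      sum(r * (z - mu[1])^2) / n1,
      sum((1 - r) * (z - mu[2])^2) / n2
    ), var_floor)
    pi <- c(n1, n2) / length(z)
  }
  o <- order(mu)
  list(mu = mu[o], sd = sqrt(v[o]), pi = pi[o])
}

#' Estimate the activity threshold as the score distribution's antimode
#'
#' Promoter score distributions are bimodal: an inactive population near the
#' background and an active population orders of magnitude higher. The
#' threshold separating them is estimated as the density minimum (antimode)
#' between the two modes of a two-component Gaussian mixture fitted to
#' `log10(crpkm + offset)`, back-transformed to the score scale. When the
#' fitted mixture is not bimodal (heavily overlapping components), the
#' estimate is `NA` with a diagnostic.
#'
#' @param crpkm_values Nonnegative scores (at least 100 values).
#' @param offset Pseudo-offset admitting zero scores into the log transform
#'   (default 0.1).
#' @return One-row tibble: `antimode`, `mode_low`, `mode_high` (component
#'   means back-transformed), `n_modes` (2 when bimodal, 1 otherwise), and
#'   `ok`.
#' @export
estimate_antimode <- function(crpkm_values, offset = 0.1) {
  x <- crpkm_values[is.finite(crpkm_values)]
  if (length(x) < 100) abort("need at least 100 score values")
  if (any(x < 0)) abort("cRPKM scores must be nonnegative")
  lx <- log10(x + offset)
  fit <- gmm2_fit(lx)
  failed <- tibble(
    antimode = NA_real_, mode_low = NA_real_, mode_high = NA_real_,
    n_modes = 1L, ok = FALSE
  )
  if (is.null(fit)) {
    return(failed)
  }
  mu <- fit$mu
  sd <- fit$sd
  pi <- fit$pi
  mix <- function(z) {
    pi[1] * stats::dnorm(z, mu[1], sd[1]) +
      pi[2] * stats::dnorm(z, mu[2], sd[2])
  }
  if (diff(mu) < 1e-6) {
    return(failed)
  }
  grid <- seq(mu[1], mu[2], length.out = 512)
  dens <- mix(grid)
  i_min <- which.min(dens)
  # bimodal only if the interior minimum is genuinely below both peaks
  bimodal <- i_min > 1 && i_min < length(grid) &&
    dens[i_min] < 0.99 * min(dens[1], dens[length(grid)])
  if (!bimodal) {
    return(failed)
  }
  tibble(
    antimode = 10^grid[i_min] - offset,
    mode_low = 10^mu[1] - offset,
    mode_high = 10^mu[2] - offset,
    n_modes = 2L,
    ok = TRUE
  )
}
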