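# Distributional comparisons between gene classes (rank-sum test, quartile
# strata, binned frequency distributions) and interval-enrichment statistics
# (Jaccard, projection/binomial and relative-distance tests) used to check
# that score-selected intervals concentrate at transcription start sites.

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-sided test of distributional difference. Small untied samples
#' (`n1 + n2 <= exact_limit`) use the exact U distribution; larger or tied
#' samples use the normal approximation with tie and continuity corrections.
#' Samples identical across both groups short-circuit to p = 1 with a
#' degenerate flag.
#'
#' @param x,y Numeric samples (each nonempty).
#' @param exact_limit Largest `n1 + n2` for the exact path (default 20).
#' @return One-row tibble: `u_statistic`, `p_value`, `method`, `n1`, `n2`,
#'   `degenerate`.
#' @export
wmw_test <- function(x, y, exact_limit = 20) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) abort("both samples must be nonempty")
  if (length(unique(c(x, y))) == 1) {
    return(tibble(
      u_statistic = n1 * n2 / 2, p_value = 1, method = "degenerate",
      n1 = n1, n2 = n2, degenerate = TRUE
    ))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (n1 + n2) <= exact_limit && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = TRUE)
  )
  tibble(
    u_statistic = unname(wt$statistic),
    p_value = min(wt$p.value, 1),
    method = if (use_exact) "exact" else "normal_approx_tie_corrected",
    n1 = n1, n2 = n2, degenerate = FALSE
  )
}

#' Split genes into quartile strata
#'
#' Genes are ranked on the chosen value (ties broken by stable gene id
#' order) and cut into four contiguous strata whose sizes differ by at most
#' one; quartile 1 is the lowest. An all-equal input collapses to one
#' flagged stratum.
#'
#' @param df Per-gene tibble.
#' @param value Column (tidyselect) holding the values to stratify on.
#' @param id Column holding the stable gene identifier (default `gene_id`).
#' @return `df` with integer `quartile` and logical `degenerate` columns.
#' @export
quartile_strata <- function(df, value, id = gene_id) {
  if (nrow(df) < 4) abort("need at least 4 genes")
  v <- dplyr::pull(df, {{ value }})
  key <- dplyr::pull(df, {{ id }})
  if (length(unique(v)) == 1) {
    return(mutate(df, quartile = 1L, degenerate = TRUE))
  }
  n <- length(v)
  ord <- order(v, key)
  sizes <- diff(floor(n * 0:4 / 4))
  q <- integer(n)
  q[ord] <- rep(1:4, times = sizes)
  mutate(df, quartile = q, degenerate = FALSE)
}

#' Binned relative frequency distribution
#'
#' Histogram with left-closed bins anchored at zero (`[k*w, (k+1)*w)`), the
#' binning convention used for the differential-expression frequency plots.
#' Relative frequencies sum to 1 over the finite values retained; with the
#' `log10` transform, nonpositive values are excluded before binning.
#'
#' @param values Numeric vector.
#' @param bin_width Bin width (> 0); 0.1 for log10 expression differentials,
#'   0.25 for protein log2 ratios.
#' @param transform `"identity"` (default) or `"log10"`.
#' @return Tibble `bin_center`, `count`, `freq` (empty for empty input).
#' @export
frequency_distribution <- function(values, bin_width = 0.1,
                                   transform = c("identity", "log10")) {
  transform <- match.arg(transform)
  if (bin_width <= 0) abort("bin_width must be > 0")
  x <- values
  if (transform == "log10") x <- log10(x[!is.na(x) & x > 0])
  x <- x[is.finite(x)]
  if (length(x) == 0) {
    return(tibble(bin_center = numeric(), count = integer(),
                  freq = numeric()))
  }
  idx <- floor(x / bin_width)
  tab <- table(idx)
  k <- as.numeric(names(tab))
  tibble(
    bin_center = (k + 0.5) * bin_width,
    count = as.integer(tab),
    freq = as.integer(tab) / length(x)
  )
}

merged_granges <- function(x) {
  GenomicRanges::reduce(GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end)
  ))
}

#' Jaccard similarity of two interval sets
#'
#' Base-pair intersection over base-pair union after merging overlapping
#' intervals within each set; symmetric and invariant to fragmenting an
#' interval into adjacent pieces.
#'
#' @param a,b Interval tibbles on the same genome.
#' @return Jaccard coefficient in `[0, 1]`, or `NA` when both sets are
#'   empty.
#' @export
jaccard_intervals <- function(a, b) {
  assert_intervals(a); assert_intervals(b)
  a <- a[a$end > a$start, , drop = FALSE]
  b <- b[b$end > b$start, , drop = FALSE]
  if (nrow(a) == 0 && nrow(b) == 0) {
    return(NA_real_)
  }
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(0)
  }
  ga <- merged_granges(a); gb <- merged_granges(b)
  inter <- sum(BiocGenerics::width(GenomicRanges::intersect(ga, gb)))
  uni <- sum(BiocGenerics::width(GenomicRanges::union(ga, gb)))
  inter / uni
}

# Two-sided "minlike" binomial p: sum of all point probabilities no larger
# than that of the observed count.
binom_p_twosided <- function(hits, n, p0) {
  d_obs <- dbinom(hits, n, p0)
  d_all <- dbinom(0:n, n, p0)
  min(1, sum(d_all[d_all <= d_obs * (1 + 1e-7)]))
}

#' Projection (binomial) test of query positions against reference intervals
#'
#' Counts how many query positions (midpoints by default) fall inside the
#' merged reference set and compares against the binomial expectation given
#' the reference's genome coverage fraction; two-sided p by the minimum-
#' likelihood convention.
#'
#' @param query,reference Nonempty interval tibbles.
#' @param layout Genome layout defining total genome size.
#' @param positions `"midpoint"` (default) or `"any_overlap"` (a query hits
#'   if any part of it overlaps the reference).
#' @return One-row tibble: `hits`, `n_query`, `expected_fraction`,
#'   `p_value`.
#' @export
projection_test <- function(query, reference, layout,
                            positions = c("midpoint", "any_overlap")) {
  positions <- match.arg(positions)
  assert_layout(layout)
  assert_intervals(query); assert_intervals(reference)
  if (nrow(query) == 0 || nrow(reference) == 0) {
    abort("query and reference must be nonempty")
  }
  ref <- merged_granges(reference)
  cov_bp <- sum(BiocGenerics::width(ref))
  if (cov_bp == 0) abort("reference covers 0 bp")
  genome_bp <- sum(layout$length)
  p0 <- cov_bp / genome_bp
  if (positions == "midpoint") {
    mid <- floor((query$start + query$end) / 2)
    qg <- GenomicRanges::GRanges(
      seqnames = query$chrom,
      ranges = IRanges::IRanges(start = mid + 1, width = 1)
    )
  } else {
    qg <- GenomicRanges::GRanges(
      seqnames = query$chrom,
      ranges = IRanges::IRanges(start = query$start + 1, end = query$end)
    )
  }
  hits <- sum(GenomicRanges::countOverlaps(qg, ref) > 0)
  n <- nrow(query)
  tibble(
    hits = hits, n_query = n, expected_fraction = p0,
    p_value = binom_p_twosided(hits, n, p0)
  )
}

# Relative distances of query midpoints to reference points: distance to the
# nearest flanking point divided by the distance between the two flanking
# points, in [0, 0.5]. Queries on chromosomes with < 2 points or outside the
# outermost points are skipped.
relative_distances <- function(query, reference_points) {
  mids <- tibble(
    chrom = query$chrom,
    m = floor((query$start + query$end) / 2)
  )
  skipped <- 0L
  out <- numeric(0)
  for (chr in unique(mids$chrom)) {
    pts <- sort(unique(reference_points$pos[reference_points$chrom == chr]))
    m <- mids$m[mids$chrom == chr]
    if (length(pts) < 2) {
      skipped <- skipped + length(m)
      next
    }
    inside <- m >= pts[1] & m <= pts[length(pts)]
    skipped <- skipped + sum(!inside)
    m <- m[inside]
    if (length(m) == 0) next
    idx <- findInterval(m, pts)
    at_last <- idx == length(pts) # exactly on the final point
    d <- numeric(length(m))
    if (any(!at_last)) {
      left <- pts[idx[!at_last]]
      right <- pts[idx[!at_last] + 1]
      mm <- m[!at_last]
      d[!at_last] <- pmin(mm - left, right - mm) / (right - left)
    }
    d[at_last] <- 0
    out <- c(out, d)
  }
  list(d = out, skipped = skipped)
}

# Binned sup-distance of the empirical distribution of relative distances
# from uniform on [0, 0.5]: max abs difference between the empirical and
# uniform CDFs evaluated at the bin edges. Exactly uniform bin counts give 0.
reldist_statistic <- function(d, n_bins) {
  edges <- seq(0, 0.5, length.out = n_bins + 1)
  emp <- stats::ecdf(d)(edges)
  max(abs(emp - edges / 0.5))
}

#' Relative-distance test of query intervals against reference points
#'
#' For each query midpoint lying between two reference points (e.g. TSSs) on
#' its chromosome, the relative distance is the distance to the nearer point
#' divided by the inter-point gap (range 0 to 0.5). Under no spatial
#' association these are uniform on `[0, 0.5]`; clustering at the reference
#' pulls them toward 0. The statistic is the binned sup-distance of the
#' empirical distribution from uniform; its null distribution is obtained by
#' Monte-Carlo resampling of uniforms.
#'
#' @param query Interval tibble.
#' @param reference_points Tibble `chrom`, `pos` of reference positions
#'   (at least 2 per chromosome used; others skipped with a message).
#' @param n_resample Monte-Carlo resamples for the null (default 1000).
#' @param seed Optional RNG seed for the resampling.
#' @param n_bins Bins over `[0, 0.5]` for the statistic (default 10).
#' @return One-row tibble: `statistic`, `p_value`, `n_used`, `n_skipped`.
#' @export
relative_distance_test <- function(query, reference_points,
                                   n_resample = 1000, seed = NULL,
                                   n_bins = 10) {
  assert_intervals(query)
  rd <- relative_distances(query, reference_points)
  if (rd$skipped > 0) {
    inform(sprintf("relative-distance test skipped %d query interval(s)",
                   rd$skipped))
  }
  if (length(rd$d) == 0) abort("no usable query intervals")
  stat <- reldist_statistic(rd$d, n_bins)
  local_seed(seed)
  null_stats <- vapply(
    seq_len(n_resample),
    function(i) reldist_statistic(runif(length(rd$d), 0, 0.5), n_bins),
    numeric(1)
  )
  p <- (1 + sum(null_stats >= stat)) / (n_resample + 1)
  tibble(
    statistic = stat, p_value = p,
    n_used = length(rd$d), n_skipped = rd$skipped
  )
}
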