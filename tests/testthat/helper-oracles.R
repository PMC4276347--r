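# Independent oracles used across the suite.

# Quadratic all-pairs overlap counter (1 bp minimum overlap).
brute_count <- function(tags, intervals) {
  vapply(seq_len(nrow(intervals)), function(i) {
    if (intervals$end[i] <= intervals$start[i]) {
      return(0L)
    }
    sum(
      tags$chrom == intervals$chrom[i] &
        tags$start < intervals$end[i] &
        tags$end > intervals$start[i]
    )
  }, integer(1))
}

# Exact two-sided rank-sum p by exhaustive enumeration of all rank
# assignments (2 * min tail convention, capped at 1).
wmw_enum_p <- function(x, y) {
  n1 <- length(x)
  n <- n1 + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n, n1)
  u_all <- apply(combs, 2, function(idx) {
    sum(sort(r)[idx]) - n1 * (n1 + 1) / 2
  })
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(p, 1)
}

# Two-sided permutation p for the rank-sum statistic.
wmw_perm_p <- function(x, y, n_perm = 1e5, seed = 42) {
  withr::with_seed(seed, {
    n1 <- length(x)
    n <- n1 + length(y)
    r <- rank(c(x, y))
    mu <- n1 * (n - n1) / 2
    u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    dev <- vapply(seq_len(n_perm), function(i) {
      abs(sum(r[sample.int(n, n1)]) - n1 * (n1 + 1) / 2 - mu)
    }, numeric(1))
    (1 + sum(dev >= abs(u_obs - mu))) / (n_perm + 1)
  })
}

random_tag_set <- function(n, layout, tag_len = 36, seed = NULL) {
  withr::with_seed(seed %||% sample.int(1e6, 1), {
    ci <- sample.int(nrow(layout), n, replace = TRUE, prob = layout$length)
    start <- floor(runif(n, 0, layout$length[ci] - tag_len))
    tibble::tibble(
      chrom = layout$chrom[ci], start = start, end = start + tag_len,
      strand = sample(c("+", "-"), n, replace = TRUE)
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
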