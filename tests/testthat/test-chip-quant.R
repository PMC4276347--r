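lay <- genome_layout(c("chr1", "chr2"), c(1e6, 1e6))

test_that("overlap counting honours the 1 bp any-overlap rule", {
  iv <- tibble::tibble(chrom = "chr1", start = 9800, end = 10200,
                       label = "p1")
  tags <- tibble::tibble(
    chrom = "chr1",
    start = c(9790, 9400, 10199, 10200),
    end = c(9826, 9436, 10235, 10236)
  )
  out <- count_overlapping_tags(tags, iv)
  # 26 bp overlap and 1 bp overlap count; disjoint and abutting do not
  expect_equal(out$count, 2L)
})

test_that("counts match a brute-force all-pairs scan", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      tags <- random_tag_set(1000, lay)
      ivs <- sample_random_intervals(lay, 10, width = 500)
      got <- count_overlapping_tags(tags, ivs)$count
      expect_equal(got, brute_count(tags, ivs))
    }
  })
})

test_that("off-layout tags are skipped with a tally", {
  iv <- tibble::tibble(chrom = "chr1", start = 0, end = 100, label = "a")
  tags <- tibble::tibble(chrom = c("chr1", "chrUn"), start = c(10, 10),
                         end = c(50, 50))
  expect_message(
    out <- count_overlapping_tags(tags, iv, lay),
    "skipped 1 tag"
  )
  expect_equal(out$count, 1L)
})

# A two-mark tag set realising given in-interval counts and library sizes.
make_marked_tags <- function(iv, n_k4, lib_k4, n_ac, lib_ac,
                             state = "pro_B") {
  inside <- function(n) {
    tibble::tibble(
      chrom = iv$chrom, start = iv$start + seq_len(n), strand = "+"
    ) |> dplyr::mutate(end = start + 36)
  }
  outside <- function(n) {
    tibble::tibble(
      chrom = "chr2", start = 1000 + seq_len(n), strand = "+"
    ) |> dplyr::mutate(end = start + 36)
  }
  dplyr::bind_rows(
    dplyr::mutate(dplyr::bind_rows(inside(n_k4), outside(lib_k4 - n_k4)),
                  mark = "H3K4me3", cell_state = state),
    dplyr::mutate(dplyr::bind_rows(inside(n_ac), outside(lib_ac - n_ac)),
                  mark = "H3ac", cell_state = state)
  )
}

test_that("cRPKM is per-mark RPKM summed, each on its own library size", {
  iv <- tibble::tibble(chrom = "chr1", start = 10000, end = 10400,
                       label = "p")
  # 4 H3K4me3 tags of a 100k library on a 0.4 kb interval: 4/(0.4*0.1)=100
  # 2 H3ac tags of a 200k library: 2/(0.4*0.2)=25; cumulative 125
  tags <- make_marked_tags(iv, 4, 1e5, 2, 2e5)
  rec <- score_intervals(tags, iv)
  expect_equal(rec$rpkm_H3K4me3, 100)
  expect_equal(rec$rpkm_H3ac, 25)
  expect_equal(rec$crpkm, 125)
  expect_equal(rec$crpkm, rec$rpkm_H3K4me3 + rec$rpkm_H3ac)

  # scale invariance: doubling every tag (and hence both library sizes)
  doubled <- dplyr::bind_rows(tags, tags)
  expect_equal(score_intervals(doubled, iv)$crpkm, 125)

  # an interval with no overlapping tags scores 0
  far <- tibble::tibble(chrom = "chr1", start = 500000, end = 500400,
                        label = "far")
  expect_equal(score_intervals(tags, far)$crpkm, 0)
})

test_that("a missing mark or empty library is an error", {
  iv <- tibble::tibble(chrom = "chr1", start = 0, end = 400, label = "p")
  only_k4 <- tibble::tibble(
    chrom = "chr1", start = 10, end = 46, strand = "+",
    mark = "H3K4me3", cell_state = "pro_B"
  )
  expect_error(score_intervals(only_k4, iv), "missing mark")
})

test_that("adding an overlapping tag never decreases that interval's score", {
  iv <- tibble::tibble(chrom = "chr1", start = 1000, end = 1400,
                       label = "p")
  withr::with_seed(7, {
    for (i in 1:5) {
      n_in <- sample(0:20, 1)
      tags <- make_marked_tags(iv, n_in, 500, 5, 500)
      base <- score_intervals(tags, iv)$crpkm
      extra <- tibble::tibble(
        chrom = "chr1", start = 1100, end = 1136, strand = "+",
        mark = "H3K4me3", cell_state = "pro_B"
      )
      expect_gte(score_intervals(dplyr::bind_rows(tags, extra), iv)$crpkm,
                 base)
    }
  })
})

test_that("activity calls use a strict threshold and the single-mark rule", {
  rec <- tibble::tibble(
    label = c("tie", "just_over", "single_mark_amplicon", "balanced"),
    cell_state = "pro_B",
    rpkm_H3K4me3 = c(4, 4.005, 30, 6),
    rpkm_H3ac = c(4, 4.005, 0, 6),
    dupfrac_H3K4me3 = c(0.1, 0.1, 0.9, 0.1),
    dupfrac_H3ac = c(0.1, 0.1, 0, 0.1),
    crpkm = rpkm_H3K4me3 + rpkm_H3ac
  )
  out <- call_active(rec, threshold = 8)
  expect_equal(out$active,
               c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(out$single_mark, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(out$amplicon_suspect, c(FALSE, FALSE, TRUE, FALSE))
})

test_that("amplicon stacks are detected from duplicated 5' positions", {
  iv <- tibble::tibble(chrom = "chr1", start = 1000, end = 1400,
                       label = "p")
  stack <- tibble::tibble(
    chrom = "chr1", start = rep(1050, 27), end = rep(1086, 27),
    strand = "+"
  )
  spread <- tibble::tibble(
    chrom = "chr1", start = 1100 + 1:3, strand = "+"
  ) |> dplyr::mutate(end = start + 36)
  k4 <- dplyr::mutate(dplyr::bind_rows(stack, spread),
                      mark = "H3K4me3", cell_state = "pro_B")
  ac <- tibble::tibble(
    chrom = "chr2", start = 1:50, end = 1:50 + 36, strand = "+",
    mark = "H3ac", cell_state = "pro_B"
  )
  rec <- score_intervals(dplyr::bind_rows(k4, ac), iv)
  expect_equal(rec$dupfrac_H3K4me3, 27 / 30)
  out <- call_active(rec)
  expect_true(out$single_mark)
  expect_true(out$amplicon_suspect)
  expect_false(out$active)
})

test_that("the antimode estimate recovers a known mixture valley", {
  # two log-normal populations; the true density valley is found by grid
  # search over the generating mixture density
  mu <- c(-0.2, 1.8)
  sd <- c(0.35, 0.3)
  w <- c(0.55, 0.45)
  dens <- function(z) {
    w[1] * dnorm(z, mu[1], sd[1]) + w[2] * dnorm(z, mu[2], sd[2])
  }
  grid <- seq(mu[1], mu[2], length.out = 4000)
  true_valley <- 10^grid[which.min(dens(grid))]
  x <- withr::with_seed(23, {
    k <- rbinom(20000, 1, w[2]) + 1
    10^rnorm(20000, mu[k], sd[k])
  })
  est <- estimate_antimode(x, offset = 0)
  expect_true(est$ok)
  expect_lt(abs(est$antimode - true_valley) / true_valley, 0.2)
})

test_that("a unimodal sample yields an absent antimode, not an error", {
  x <- withr::with_seed(2, 10^rnorm(5000, 1, 0.3))
  est <- estimate_antimode(x)
  expect_false(est$ok)
  expect_true(is.na(est$antimode))
  expect_error(estimate_antimode(10^rnorm(50, 1, 0.3)), "at least 100")
})
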