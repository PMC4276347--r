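test_that("exact WMW p agrees with exhaustive enumeration", {
  expect_equal(wmw_test(c(1, 2), c(3, 4))$p_value, 1 / 3)
  withr::with_seed(101, {
    for (n1 in 1:4) {
      for (n2 in 1:4) {
        x <- runif(n1)
        y <- runif(n2)
        got <- wmw_test(x, y)
        expect_equal(got$method, "exact")
        expect_equal(got$p_value, wmw_enum_p(x, y),
                     tolerance = 1e-12,
                     label = sprintf("n1=%d n2=%d", n1, n2))
      }
    }
  })
})

test_that("identical samples give p = 1 and degeneracy is flagged", {
  same <- wmw_test(c(1, 2, 3), c(1, 2, 3))
  expect_gt(same$p_value, 0.99)
  deg <- wmw_test(rep(2, 5), rep(2, 7))
  expect_equal(deg$p_value, 1)
  expect_equal(deg$method, "degenerate")
})

test_that("the large-sample approximation tracks a permutation oracle", {
  withr::with_seed(55, {
    x <- rnorm(50)
    y <- rnorm(50, 0.45)
  })
  got <- wmw_test(x, y)
  expect_equal(got$method, "normal_approx_tie_corrected")
  p_perm <- wmw_perm_p(x, y, n_perm = 1e5)
  expect_lt(abs(got$p_value - p_perm) / p_perm, 0.10)
})

test_that("quartile strata are balanced, ordered and tie-stable", {
  df <- tibble::tibble(gene_id = sprintf("g%d", 1:8),
                       v = c(5, 1, 7, 3, 8, 2, 6, 4))
  q <- quartile_strata(df, v)
  expect_equal(unname(table(q$quartile)), rep(2L, 4),
               ignore_attr = TRUE)
  expect_gte(min(q$v[q$quartile == 4]), max(q$v[q$quartile == 1]))

  withr::with_seed(3, {
    df2 <- tibble::tibble(gene_id = sprintf("g%03d", 1:101),
                          v = rnorm(101))
    q2 <- quartile_strata(df2, v)
    sizes <- table(q2$quartile)
    expect_lte(max(sizes) - min(sizes), 1)
    expect_gte(min(q2$v[q2$quartile == 4]), max(q2$v[q2$quartile == 1]))
  })

  flat <- quartile_strata(
    tibble::tibble(gene_id = letters[1:6], v = rep(1, 6)), v
  )
  expect_true(all(flat$quartile == 1))
  expect_true(all(flat$degenerate))
})

test_that("frequency distributions use left-closed zero-anchored bins", {
  f <- frequency_distribution(c(0.05, 0.05, 0.15), bin_width = 0.1)
  expect_equal(f$bin_center, c(0.05, 0.15))
  expect_equal(f$freq, c(2 / 3, 1 / 3))
  expect_equal(sum(f$freq), 1)

  # log10 transform excludes nonpositive values before binning
  g <- frequency_distribution(c(10^0.05, 10^0.05, 0, -1), 0.1, "log10")
  expect_equal(g$bin_center, 0.05)
  expect_equal(g$freq, 1)

  withr::with_seed(9, {
    h <- frequency_distribution(rnorm(500), 0.25)
    expect_equal(sum(h$freq), 1)
  })
  empty <- frequency_distribution(numeric(0), 0.1)
  expect_equal(nrow(empty), 0)
})

test_that("interval Jaccard matches hand values and merge invariance", {
  iv <- function(s, e) tibble::tibble(chrom = "c", start = s, end = e)
  a <- iv(0, 100)
  expect_equal(jaccard_intervals(a, a), 1)
  expect_equal(jaccard_intervals(a, iv(200, 300)), 0)
  expect_equal(jaccard_intervals(a, iv(50, 150)), 1 / 3)
  # symmetry and fragmentation invariance
  b <- iv(50, 150)
  expect_equal(jaccard_intervals(a, b), jaccard_intervals(b, a))
  a_frag <- iv(c(0, 40, 70), c(40, 70, 100))
  expect_equal(jaccard_intervals(a_frag, b), 1 / 3)
  expect_true(is.na(jaccard_intervals(iv(numeric(0), numeric(0)),
                                      iv(numeric(0), numeric(0)))))
})

test_that("the projection test behaves at its analytic extremes", {
  lay <- genome_layout("c", 1e6)
  q <- sample_random_intervals(lay, 100, width = 100, seed = 2)
  whole <- tibble::tibble(chrom = "c", start = 0, end = 1e6)
  res <- projection_test(q, whole, lay)
  expect_equal(res$hits, 100)
  expect_equal(res$p_value, 1)

  # all queries inside a reference covering 10% of the genome
  ref10 <- tibble::tibble(chrom = "c", start = 0, end = 1e5)
  inq <- tibble::tibble(chrom = "c", start = seq(100, 90000, length.out = 100))
  inq$end <- inq$start + 50
  res2 <- projection_test(inq, ref10, lay)
  expect_equal(res2$hits, 100)
  expect_lt(res2$p_value, 1e-20)

  expect_error(
    projection_test(q, tibble::tibble(chrom = "c", start = 5,
                                      end = 5), lay),
    "0 bp"
  )
})

test_that("uniform queries hit the reference at the expected rate", {
  lay <- genome_layout("c", 1e6)
  ref <- tibble::tibble(chrom = "c",
                        start = seq(0, 9e5, by = 1e5))
  ref$end <- ref$start + 20000 # 20% coverage
  q <- sample_random_intervals(lay, 2000, width = 2, seed = 77)
  res <- projection_test(q, ref, lay)
  ci <- qbinom(c(0.005, 0.995), res$n_query, res$expected_fraction)
  expect_gte(res$hits, ci[1])
  expect_lte(res$hits, ci[2])
})

test_that("relative distances detect clustering at reference points", {
  pts <- tibble::tibble(chrom = "c", pos = seq(1000, 99000, by = 1000))
  at_pts <- tibble::tibble(chrom = "c", start = pts$pos - 5,
                           end = pts$pos + 5)
  res <- relative_distance_test(at_pts, pts, n_resample = 500, seed = 4)
  expect_lt(res$p_value, 0.01)
  expect_gt(res$statistic, 0.5)
})

test_that("uniform queries are usually compatible with the uniform null", {
  pts <- tibble::tibble(chrom = "c", pos = seq(0, 1e6, by = 5e4))
  hits <- 0
  for (s in 1:20) {
    q <- sample_random_intervals(genome_layout("c", 1e6), 300,
                                 width = 10, seed = 100 + s)
    res <- suppressMessages(
      relative_distance_test(q, pts, n_resample = 400, seed = 200 + s)
    )
    if (res$p_value > 0.05) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("the relative-distance statistic is zero for bin-uniform data", {
  # queries engineered so every relative-distance bin is equally filled
  pts <- tibble::tibble(chrom = "c", pos = c(0, 1000))
  centers <- seq(0.025, 0.475, by = 0.05) # the 10 bin midpoints, x1000 bp
  q <- tibble::tibble(chrom = "c", start = centers * 1000 - 1,
                      end = centers * 1000 + 1)
  res <- relative_distance_test(q, pts, n_resample = 100, seed = 1,
                                n_bins = 10)
  expect_equal(res$statistic, 0)
  expect_true(res$statistic >= 0 && res$statistic <= 1)
})
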