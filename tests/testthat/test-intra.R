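test_that("pearson_r reproduces exact and oracle values", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1.0)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1.0)
  x <- c(1, 2, 3, 5); y <- c(2, 1, 4, 6)
  expect_equal(pearson_r(x, y), oracle_pearson(x, y), tolerance = 1e-12)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_r(1:2, 2:3), "3 timepoints")
})

test_that("pearson_pvalue matches the two-sided t transform", {
  expect_equal(pearson_pvalue(0, 12), 1.0)
  expect_equal(pearson_pvalue(1, 4), 0.0)
  expect_equal(pearson_pvalue(0.576, 12), 0.05, tolerance = 0.002)
  # agreement with cor.test as an independent route
  set.seed(3)
  for (i in 1:5) {
    x <- rnorm(12); y <- rnorm(12)
    expect_equal(pearson_pvalue(cor(x, y), 12), cor.test(x, y)$p.value,
                 tolerance = 1e-12)
  }
  expect_error(pearson_pvalue(0.5, 2), "n >= 3")
})

test_that("critical_r is the exact significance boundary", {
  expect_equal(critical_r(12, 0.05), 0.576, tolerance = 1e-3)
  # pair counting flips exactly at the boundary
  rc <- critical_r(12, 0.05)
  expect_lt(pearson_pvalue(rc + 1e-9, 12), 0.05)
  expect_gt(pearson_pvalue(rc - 1e-9, 12), 0.05)
})

test_that("correlation_matrix matches hand values and the brute-force oracle", {
  s <- series_from(rbind(c(1, 2, 3, 2), c(2, 4, 6, 4), c(3, 2, 1, 2)))
  m <- correlation_matrix(s)
  expect_equal(unname(m$r),
               rbind(c(1, 1, -1), c(1, 1, -1), c(-1, -1, 1)))
  expect_identical(m$r, t(m$r))
  expect_equal(unname(diag(m$r)), rep(1, 3))

  s20 <- make_series(n_genes = 20, seed = 7)
  m20 <- correlation_matrix(s20)
  expect_equal(unname(m20$r), oracle_cor_matrix(s20$values), tolerance = 1e-12)
  expect_error(correlation_matrix(series_from(matrix(1:4, 1))), "2 genes")
})

test_that("summarize_matrix equals the brute-force summary", {
  s <- series_from(rbind(c(1, 2, 3, 2), c(2, 4, 6, 4), c(3, 2, 1, 2)))
  cs <- summarize_matrix(correlation_matrix(s))
  expect_equal(cs$mean_abs_r, 1.0)
  expect_equal(cs$n_significant, 3L)
  expect_equal(cs$n_pairs, 3L)

  # r = 0.5 at n = 12 sits below the 0.576 critical value: not significant
  expect_gt(pearson_pvalue(0.5, 12), 0.05)

  s15 <- make_series(n_genes = 15, seed = 21)
  m15 <- correlation_matrix(s15)
  for (alpha in c(0.01, 0.05, 0.2)) {
    got <- summarize_matrix(m15, alpha)
    want <- oracle_summary(m15$r, m15$n_timepoints, alpha)
    expect_equal(got$mean_abs_r, want$mean_abs_r, tolerance = 1e-12)
    expect_equal(got$n_significant, want$n_significant)
  }
  # n_significant non-increasing as alpha is lowered
  expect_lte(summarize_matrix(m15, 0.01)$n_significant,
             summarize_matrix(m15, 0.05)$n_significant)
})

test_that("mean |r| is invariant to gene order and per-gene affine maps", {
  s <- make_series(n_genes = 12, seed = 31)
  base <- summarize_matrix(correlation_matrix(s))$mean_abs_r
  perm <- sample(12)
  sp <- series_from(s$values[perm, ], timepoints = s$timepoints_h,
                    genes = s$genes[perm])
  expect_equal(summarize_matrix(correlation_matrix(sp))$mean_abs_r, base,
               tolerance = 1e-12)
  scales <- runif(12, 0.5, 3); shifts <- rnorm(12)
  sa <- series_from(s$values * scales + shifts, timepoints = s$timepoints_h,
                    genes = s$genes)
  expect_equal(summarize_matrix(correlation_matrix(sa))$mean_abs_r, base,
               tolerance = 1e-10)
})

test_that("complete-linkage merge heights match the naive oracle", {
  # two identical genes merge at height 0
  s <- series_from(rbind(c(1, 2, 3), c(1, 2, 3) * 2 + 1, c(3, 1, 2)))
  h <- hierarchical_order(correlation_matrix(s))
  expect_equal(min(h$hclust$height), 0)

  # two perfect pairs, r = -1 across: merges at 0, 0, then 2
  v <- rbind(c(0, 1, 0, 1), c(0, 2, 0, 2), c(1, 0, 1, 0), c(2, 0, 2, 0))
  h4 <- hierarchical_order(correlation_matrix(series_from(v)))
  expect_equal(sort(h4$hclust$height), c(0, 0, 2), tolerance = 1e-12)

  for (seed in c(1, 2, 3)) {
    s6 <- make_series(n_genes = 6, seed = seed)
    m <- correlation_matrix(s6)
    hc <- hierarchical_order(m)$hclust
    expect_equal(sort(hc$height),
                 oracle_complete_linkage_heights(1 - m$r), tolerance = 1e-10)
  }
  s12 <- make_series(n_genes = 12, seed = 9)
  m12 <- correlation_matrix(s12)
  expect_equal(sort(hierarchical_order(m12)$hclust$height),
               oracle_complete_linkage_heights(1 - m12$r), tolerance = 1e-10)
})

test_that("cluster waveforms are per-timepoint means and SDs", {
  s <- make_series(n_genes = 10, seed = 17)
  one <- cluster_waveform(s, "g03")
  norm <- minmax_normalize(s)
  expect_equal(one$mean, unname(norm$values["g03", ]))
  expect_equal(one$sd, rep(0, 12))

  two <- cluster_waveform(series_from(rbind(c(0, 1, 0.5), c(1, 0, 0.5))),
                          c("g01", "g02"), normalize = FALSE)
  expect_equal(two$mean, c(0.5, 0.5, 0.5))

  sub <- sprintf("g%02d", 1:10)
  wf <- cluster_waveform(s, sub, normalize = FALSE)
  expect_equal(wf$mean, unname(colMeans(s$values)))
  expect_equal(wf$sd, unname(apply(s$values, 2, sd)))
  expect_error(cluster_waveform(s, "nope"), "nope")
})

test_that("condition comparison reports delta and a pooled t-test", {
  s <- make_series(n_genes = 10, seed = 55)
  m <- correlation_matrix(s)
  same <- compare_intra(m, m)
  expect_equal(same$delta, 0)
  expect_equal(same$p_value, 1)
  expect_identical(same$classification, "unchanged")

  # planted shift: an independent draw with systematically higher |r|
  sB <- make_series(n_genes = 30, seed = 56)
  mA <- correlation_matrix(sB)
  common <- 0.6 * sin(2 * pi * sB$timepoints_h / 24)
  sC <- series_from(sB$values + matrix(rep(common * 8, each = 30), nrow = 30),
                    timepoints = sB$timepoints_h, genes = sB$genes)
  mB <- correlation_matrix(sC)
  cmp <- compare_intra(mA, mB)
  absA <- abs(mA$r[upper.tri(mA$r)]); absB <- abs(mB$r[upper.tri(mB$r)])
  # hand-coded pooled two-sample t
  nA <- length(absA); nB <- length(absB)
  sp <- sqrt(((nA - 1) * var(absA) + (nB - 1) * var(absB)) / (nA + nB - 2))
  t_hand <- (mean(absA) - mean(absB)) / (sp * sqrt(1 / nA + 1 / nB))
  expect_equal(cmp$t, t_hand, tolerance = 1e-10)
  expect_equal(cmp$delta, mean(absB) - mean(absA), tolerance = 1e-12)
})

test_that("significant-pair overlap follows set algebra", {
  s <- make_series(n_genes = 10, seed = 77)
  m <- correlation_matrix(s)
  same <- pair_overlap(m, m)
  expect_equal(same$n_unique_A, 0L)
  expect_equal(same$n_unique_B, 0L)
  expect_gt(same$n_shared, 0L)

  s2 <- make_series(n_genes = 10, seed = 78)
  m2 <- correlation_matrix(s2)
  ov <- pair_overlap(m, m2)
  sig <- function(mm) {
    out <- c()
    for (i in 1:9) for (j in (i + 1):10) {
      tt <- oracle_summary(mm$r[c(i, j), c(i, j)], mm$n_timepoints)$n_significant
      if (tt == 1) out <- c(out, paste(mm$genes[i], mm$genes[j], sep = "|"))
    }
    out
  }
  pa <- sig(m); pb <- sig(m2)
  expect_equal(ov$n_shared, length(intersect(pa, pb)))
  expect_equal(ov$n_unique_A, length(setdiff(pa, pb)))
  expect_equal(ov$n_unique_B, length(setdiff(pb, pa)))
})
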