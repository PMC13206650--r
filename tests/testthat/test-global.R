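# small dataset where gene g01 is in phase everywhere and g02 flips phase
phased_dataset <- function(n_tissues = 4, shift_h = rep(0, n_tissues)) {
  tp <- seq(0, 22, by = 2)
  series <- lapply(seq_len(n_tissues), function(s) {
    v <- rbind(10 + 5 * cos(2 * pi * tp / 24),
               10 + 5 * cos(2 * pi * (tp - shift_h[s]) / 24),
               10 + 3 * sin(2 * pi * tp / 24))
    tsexpr(sprintf("T%02d", s), "ALF", v, timepoints_h = tp,
           genes = c("g01", "g02", "g03"))
  })
  study_dataset(series)
}

test_that("sync_score sums signed same-gene correlations over tissue pairs", {
  ds <- phased_dataset(4)
  ss <- sync_score("g01", ds, "ALF")
  expect_equal(ss$score, 6, tolerance = 1e-10)
  expect_equal(ss$n_pairs_used, 6L)

  # two in-phase tissues plus one 12-h-shifted: 1 - 1 - 1 = -1
  ds3 <- phased_dataset(3, shift_h = c(0, 0, 12))
  expect_equal(sync_score("g02", ds3, "ALF")$score, -1, tolerance = 1e-10)

  ds22 <- phased_dataset(22)
  expect_equal(sync_score("g01", ds22, "ALF")$score, choose(22, 2),
               tolerance = 1e-8)
  expect_error(sync_score("absent", ds, "ALF"), "fewer than 2 tissues")
})

test_that("sync_score is invariant under per-tissue affine rescaling", {
  cfg <- sim_config(n_tissues = 5, n_genes = 8, benchmark_n = 0,
                    benchmark_decoys = 0, conditions = "A",
                    phase_dispersion_h = c(A = 2), amplitude_gain = c(A = 1),
                    seed = 6)
  ds <- generate_dataset(cfg)$dataset
  set.seed(1)
  ds2 <- map_series(ds, function(s) {
    tsexpr(s$tissue, s$condition, s$values * runif(1, 0.5, 2) + rnorm(1),
           s$timepoints_h, genes = s$genes)
  })
  for (g in c("G0001", "G0005"))
    expect_equal(sync_score(g, ds2, "A")$score, sync_score(g, ds, "A")$score,
                 tolerance = 1e-10)
})

test_that("score_table matches the per-gene brute-force loop", {
  cfg <- sim_config(n_tissues = 4, n_genes = 12, benchmark_n = 2,
                    benchmark_decoys = 1, seed = 13)
  ds <- generate_dataset(cfg)$dataset
  st <- score_table(ds, "TRF")
  for (g in names(st$scores)) {
    want <- oracle_sync_score(ds, "TRF", g)
    expect_equal(unname(st$scores[g]), want$score, tolerance = 1e-10)
    expect_equal(unname(st$n_pairs_used[g]), want$n_pairs)
  }
  expect_true(all(abs(st$scores) <= st$n_pairs_used))
})

test_that("threshold calibration finds the documented gaps", {
  scores <- setNames(c(100, 95, 60, 20, 15), c("Dbp", "Arntl", "Nampt", "Pasd1", "Ezh2"))
  cal <- calibrate_threshold(scores, "largest_gap")
  expect_equal(cal$threshold, 40)
  expect_identical(cal$boundary_genes, c("Nampt", "Pasd1"))
  tab <- structure(list(condition = "ALF", scores = sort(scores, decreasing = TRUE),
                        n_pairs_used = rep(231L, 5), tissues_used = letters[1:22]),
                   class = "sync_score_table")
  expect_identical(global_set(tab, cal$threshold), c("Dbp", "Arntl", "Nampt"))
  # a manual threshold at the operating value 60 gives the same pass set
  man <- calibrate_threshold(scores, "manual", manual_threshold = 60)
  expect_identical(global_set(tab, man$threshold), c("Dbp", "Arntl", "Nampt"))

  s2 <- c(a = 100, b = 95, c = 90, d = 60, e = 55)
  first <- calibrate_threshold(s2, "first_gap", gap_factor = 3)
  expect_equal(first$threshold, 75)
  expect_identical(first$boundary_genes, c("c", "d"))

  expect_error(calibrate_threshold(c(1, 2), "largest_gap"), "3 benchmark")
})

test_that("global sets are ordered, thresholded and monotone", {
  tab <- structure(list(condition = "x", scores = c(a = 100, b = 70, c = 10),
                        n_pairs_used = rep(231L, 3), tissues_used = letters[1:3]),
                   class = "sync_score_table")
  expect_identical(global_set(tab, 60), c("a", "b"))
  expect_identical(global_set(tab, 1000), character(0))
  # raising the threshold never adds genes
  sets <- lapply(c(0, 20, 60, 80, 120), function(t) global_set(tab, t))
  for (i in seq_len(length(sets) - 1))
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
})

test_that("overlap arithmetic reproduces the printed count pattern", {
  setA <- sprintf("s%02d", 1:20)
  setB <- sprintf("s%02d", 1:20)
  A <- c(setA, sprintf("a%d", 1:3))     # |A| = 23
  B <- c(setB, sprintf("b%02d", 1:69))  # |B| = 89
  ov <- overlap_sets(A, B)
  expect_equal(ov$n_shared, 20L)
  expect_equal(ov$n_unique_A, 3L)
  expect_equal(ov$n_unique_B, 69L)

  same <- overlap_sets(A, A)
  expect_equal(same$n_shared, 23L)
  expect_equal(same$n_unique_A, 0L)
  disj <- overlap_sets(c("x"), c("y", "z"))
  expect_equal(unlist(disj[1:3], use.names = FALSE), c(0L, 1L, 2L))
})

test_that("whole-body waveforms are per-timepoint means with SEM", {
  tp <- c(0, 8, 16)
  s1 <- tsexpr("A", "c", matrix(c(0, 1, 0.5), 1), tp, genes = "g")
  s2 <- tsexpr("B", "c", matrix(c(1, 0, 0.5), 1), tp, genes = "g")
  ds <- study_dataset(list(s1, s2))
  wb <- whole_body_waveform("g", ds, "c", normalize = FALSE)
  expect_equal(wb$waveform$mean, c(0.5, 0.5, 0.5))
  expect_equal(wb$waveform$sem, c(0.5, 0.5, 0))

  ds22 <- phased_dataset(22)
  wb22 <- whole_body_waveform("g01", ds22, "ALF")
  expect_equal(wb22$waveform$sem, rep(0, 12), tolerance = 1e-12)
  profs <- wb22$tissue_profiles
  expect_equal(wb22$waveform$mean, unname(colMeans(profs)), tolerance = 1e-12)
  expect_equal(wb22$n_tissues, 22L)
})

test_that("wave clustering separates planted anti-phase pairs", {
  tp <- seq(0, 22, by = 2)
  up <- 10 + 5 * cos(2 * pi * tp / 24)
  dn <- 10 + 5 * cos(2 * pi * (tp - 12) / 24)
  mk <- function(t) tsexpr(t, "c", rbind(up, up * 1.3 + 1, dn, dn * 0.7 + 2),
                           tp, genes = c("a1", "a2", "b1", "b2"))
  ds <- study_dataset(lapply(c("T1", "T2"), mk))
  wc <- wave_clusters(c("a1", "a2", "b1", "b2"), ds, "c", cut_height = 1.0)
  expect_equal(wc$n_clusters, 2L)
  expect_equal(wc$labels[["a1"]], wc$labels[["a2"]])
  expect_equal(wc$labels[["b1"]], wc$labels[["b2"]])
  expect_false(wc$labels[["a1"]] == wc$labels[["b1"]])
  # cut above the tree root collapses to one cluster
  expect_equal(wave_clusters(c("a1", "a2", "b1", "b2"), ds, "c",
                             cut_height = 2.5)$n_clusters, 1L)
})

test_that("four planted 6-h waves are recovered at the default cut", {
  cfg <- sim_config(n_tissues = 6, n_genes = 80, aligned_fraction = 1,
                    benchmark_n = 0, benchmark_decoys = 0, conditions = "X",
                    phase_dispersion_h = c(X = 0.5), amplitude_gain = c(X = 1),
                    noise_sd = 0.5, phase_groups_h = c(0, 6, 12, 18), seed = 41)
  g <- generate_dataset(cfg)
  wc <- wave_clusters(g$truth$genes$gene, g$dataset, "X", cut_height = 1.0)
  expect_equal(wc$n_clusters, 4L)
  truth_lab <- g$truth$genes$phase_group_h[match(names(wc$labels), g$truth$genes$gene)]
  expect_gte(oracle_ari(truth_lab, wc$labels), 0.9)

  cfg2 <- sim_config(n_tissues = 6, n_genes = 40, aligned_fraction = 1,
                     benchmark_n = 0, benchmark_decoys = 0, conditions = "X",
                     phase_dispersion_h = c(X = 0.5), amplitude_gain = c(X = 1),
                     noise_sd = 0.5, phase_groups_h = c(0, 12), seed = 42)
  g2 <- generate_dataset(cfg2)
  wc2 <- wave_clusters(g2$truth$genes$gene, g2$dataset, "X", cut_height = 1.0)
  expect_equal(wc2$n_clusters, 2L)
})
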