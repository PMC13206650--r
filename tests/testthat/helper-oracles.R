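# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and stats::cor / hclust) so the tests are two-route checks.

options(circasync.verbose = FALSE)

# Textbook Pearson formula.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# Double-loop all-pairs correlation matrix.
oracle_cor_matrix <- function(values) {
  g <- nrow(values)
  r <- diag(1, g)
  for (i in seq_len(g)) for (j in seq_len(g)) if (i != j)
    r[i, j] <- oracle_pearson(values[i, ], values[j, ])
  r
}

# Brute-force matrix summary: mean |r| over unordered off-diagonal pairs and
# count of pairs with two-sided p < alpha (p from the t CDF directly).
oracle_summary <- function(r, n, alpha = 0.05) {
  g <- nrow(r)
  vals <- c(); nsig <- 0L
  for (i in seq_len(g - 1)) for (j in seq((i + 1), g)) {
    vals <- c(vals, abs(r[i, j]))
    tt <- abs(r[i, j]) * sqrt((n - 2) / max(1 - r[i, j]^2, .Machine$double.eps))
    p <- 2 * (1 - pt(tt, df = n - 2))
    if (abs(r[i, j]) == 1) p <- 0
    if (p < alpha) nsig <- nsig + 1L
  }
  list(mean_abs_r = mean(vals), n_significant = nsig)
}

# Naive O(G^3) complete-linkage agglomeration; returns sorted merge heights.
oracle_complete_linkage_heights <- function(d) {
  d <- as.matrix(d)
  active <- as.list(seq_len(nrow(d)))
  heights <- c()
  while (length(active) > 1) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_len(length(active) - 1)) for (j in seq((i + 1), length(active))) {
      h <- max(d[active[[i]], active[[j]]])
      if (h < best) { best <- h; bi <- i; bj <- j }
    }
    heights <- c(heights, best)
    active[[bi]] <- c(active[[bi]], active[[bj]])
    active[[bj]] <- NULL
  }
  sort(heights)
}

# Per-gene, per-tissue-pair loop for the whole-body synchronization score.
oracle_sync_score <- function(dataset, condition, gene) {
  tissues <- sort(dataset$tissues)
  profs <- list()
  for (t in tissues) {
    s <- get_series(dataset, condition, t)
    i <- match(gene, s$genes)
    if (!is.na(i) && sd(s$values[i, ]) > 0) profs[[t]] <- s$values[i, ]
  }
  total <- 0; np <- 0L
  for (i in seq_len(length(profs) - 1)) for (j in seq((i + 1), length(profs))) {
    total <- total + oracle_pearson(profs[[i]], profs[[j]])
    np <- np + 1L
  }
  list(score = total, n_pairs = np)
}

# Adjusted Rand index between two labelings (closed form on the pair table).
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  s <- function(x) sum(choose(x, 2))
  sij <- s(tab); si <- s(rowSums(tab)); sj <- s(colSums(tab))
  expected <- si * sj / choose(length(a), 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Small deterministic tsexpr fixture with N(0,1)-ish varied profiles.
make_series <- function(n_genes = 10, timepoints = seq(0, 22, by = 2),
                        tissue = "liver", condition = "ALF", seed = 42) {
  set.seed(seed)
  v <- matrix(rnorm(n_genes * length(timepoints), mean = 10, sd = 3),
              nrow = n_genes)
  tsexpr(tissue, condition, v, timepoints_h = timepoints,
         genes = sprintf("g%02d", seq_len(n_genes)))
}

# tsexpr from an explicit matrix of profiles (rows = genes).
series_from <- function(values, timepoints = NULL, tissue = "t", condition = "c",
                        genes = NULL) {
  values <- rbind(values)
  if (is.null(timepoints)) timepoints <- seq(0, by = 2, length.out = ncol(values))
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(values)))
  tsexpr(tissue, condition, values, timepoints_h = timepoints, genes = genes)
}
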