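test_that("term paths expand to one occurrence per hierarchy level", {
  tab <- data.frame(
    gene = c("g1", "g2"),
    pathways = c("Metabolism > Lipid metabolism > Fatty acid oxidation",
                 "OXPHOS > Complex I ; Signaling > Complex I"),
    stringsAsFactors = FALSE)
  ann <- parse_term_paths(tab)
  expect_setequal(ann$gene_to_terms$g1,
                  c("Metabolism", "Lipid metabolism", "Fatty acid oxidation"))
  # a level shared by two paths of one gene counts twice
  expect_equal(sum(ann$gene_to_terms$g2 == "Complex I"), 2L)
  expect_warning(
    parse_term_paths(data.frame(gene = "g3", pathways = "A > > B")), "empty")

  # hand-enumerated 5-gene fixture
  tab5 <- data.frame(
    gene = sprintf("g%d", 1:5),
    pathways = c("R1 > M1 > L1", "R1 > M1 > L2", "R1 > M2", "R2 > M3 > L1",
                 "R2 ; R1 > M1"),
    stringsAsFactors = FALSE)
  ann5 <- parse_term_paths(tab5, excluded_terms = character(0))
  freq <- term_frequency(ann5$universe_genes, ann5)
  expect_equal(unname(freq[c("R1", "M1", "L1", "R2", "M2", "M3", "L2")]),
               c(4L, 3L, 2L, 2L, 1L, 1L, 1L))
})

test_that("term frequency counts occurrences and honors exclusions", {
  ann <- gene_set_annotation(
    list(g1 = c("A", "B"), g2 = "A", g3 = "C"), excluded_terms = character(0))
  f <- term_frequency(c("g1", "g2", "g3"), ann)
  expect_equal(unname(f[c("A", "B", "C")]), c(2L, 1L, 1L))
  expect_length(term_frequency(character(0), ann), 0L)

  ex <- gene_set_annotation(list(g1 = c("A", "B"), g2 = "A", g3 = "C"),
                            excluded_terms = "A")
  f2 <- term_frequency(c("g1", "g2", "g3"), ex)
  expect_false("A" %in% names(f2))
  expect_equal(unname(f2[c("B", "C")]), c(1L, 1L))

  # frequency is additive over a disjoint partition of the cluster
  set.seed(2)
  genes <- sprintf("g%02d", 1:20)
  rand <- gene_set_annotation(setNames(lapply(genes, function(g)
    sample(LETTERS[1:6], sample(1:4, 1), replace = TRUE)), genes),
    excluded_terms = character(0))
  whole <- term_frequency(genes, rand)
  part <- term_frequency(genes[1:7], rand)
  rest <- term_frequency(genes[8:20], rand)
  all_terms <- union(names(part), names(rest))
  sums <- setNames(rep(0L, length(all_terms)), all_terms)
  sums[names(part)] <- sums[names(part)] + part
  sums[names(rest)] <- sums[names(rest)] + rest
  expect_equal(sums[sort(names(whole))], whole[sort(names(whole))])
})

test_that("term ratios divide cluster counts by universe counts", {
  genes <- sprintf("g%02d", 1:10)
  ann <- gene_set_annotation(setNames(lapply(1:10, function(i)
    if (i <= 4) "A" else "B"), genes), excluded_terms = character(0))
  r <- term_ratio(genes[1:2], ann)       # A: 2 of 4
  expect_equal(unname(r["A"]), 0.5)
  full <- term_ratio(genes, ann)         # cluster = universe
  expect_equal(unname(full), c(1, 1))

  set.seed(14)
  rand <- gene_set_annotation(setNames(lapply(genes, function(g)
    sample(LETTERS[1:5], sample(1:3, 1), replace = TRUE)), genes),
    excluded_terms = character(0))
  cluster <- genes[1:4]
  got <- term_ratio(cluster, rand)
  for (term in names(got)) {
    cl <- sum(unlist(rand$gene_to_terms[cluster]) == term)
    un <- sum(unlist(rand$gene_to_terms) == term)
    expect_equal(unname(got[term]), cl / un)
  }
  expect_true(all(got > 0 & got <= 1))
})

test_that("top_terms ranks with the documented tie-breaks", {
  enr <- structure(list(
    cluster_id = "C1",
    table = data.frame(term = c("A", "B", "C"),
                       cluster_count = c(3L, 3L, 1L),
                       universe_count = c(10L, 5L, 2L),
                       ratio = c(0.3, 0.6, 0.5), stringsAsFactors = FALSE),
    excluded = "Metabolism"), class = "term_enrichment")
  expect_identical(top_terms(enr, 2, "frequency"), c("B", "A"))  # tie -> ratio
  expect_identical(top_terms(enr, 10, "frequency"), c("B", "A", "C"))

  # exhaustive sort oracle on a 12-term table
  set.seed(6)
  tab <- data.frame(term = sprintf("t%02d", 1:12),
                    cluster_count = sample(1:4, 12, replace = TRUE),
                    universe_count = sample(5:9, 12, replace = TRUE),
                    stringsAsFactors = FALSE)
  tab$ratio <- tab$cluster_count / tab$universe_count
  enr2 <- structure(list(cluster_id = "C", table = tab, excluded = character(0)),
                    class = "term_enrichment")
  ord <- tab$term[order(-tab$cluster_count, -tab$ratio, tab$term)]
  expect_identical(top_terms(enr2, 5, "frequency"), head(ord, 5))
  ord_r <- tab$term[order(-tab$ratio, -tab$cluster_count, tab$term)]
  expect_identical(top_terms(enr2, 5, "ratio"), head(ord_r, 5))
})

test_that("enrich_cluster never reports excluded terms and bounds ratios", {
  genes <- sprintf("g%02d", 1:12)
  set.seed(10)
  ann <- gene_set_annotation(setNames(lapply(genes, function(g)
    c("Metabolism", sample(c("Lipid", "OXPHOS", "Import", "Signaling"),
                           sample(1:3, 1)))), genes))
  enr <- enrich_cluster(genes[1:5], ann, cluster_id = "C1")
  expect_false("Metabolism" %in% enr$table$term)
  expect_false("Metabolism" %in% enr$top_by_frequency)
  expect_true(all(enr$table$ratio > 0 & enr$table$ratio <= 1))
  expect_true(all(enr$table$cluster_count <= enr$table$universe_count))
})
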