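test_that("best-hit tables hold one row per gene in input order", {
  pair <- small_pair(n = 15L, s = 0.25, seed = 17L)
  tab <- best_hit_table(pair$genes_a, pair$genome_a, pair$genome_b,
                        best_hit_params())
  expect_identical(nrow(tab), 15L)
  expect_identical(tab$gene_id, pair$genes_a$gene_id)
  expect_true(all(tab$has_hit))
  expect_error(best_hit_table(pair$genes_a[0, ], pair$genome_a,
                              pair$genome_b), "empty gene set")
})

test_that("a gene with no ortholog in the target is a no-hit row", {
  pair <- small_pair(n = 10L, s = 0.25, seed = 18L)
  # splice a foreign gene into the query annotations: random sequence that
  # exists in genome A but has no counterpart in genome B
  set.seed(19)
  foreign <- rand_dna(400)
  ga <- paste0(as.character(pair$genome_a)[[1]], foreign)
  glen <- nchar(ga)
  genes <- rbind(pair$genes_a, data.frame(
    gene_id = "foreign", contig_id = "contig_A",
    start = glen - 400L, end = glen, strand = "+"))
  tab <- best_hit_table(genes, stats::setNames(ga, "contig_A"),
                        pair$genome_b, best_hit_params(seed_len = 13L))
  expect_false(tab$has_hit[tab$gene_id == "foreign"])
  expect_identical(tab$flag[tab$gene_id == "foreign"], "no_hit")
})

test_that("screening is deterministic across reruns", {
  pair <- small_pair(n = 8L, s = 0.2, seed = 20L)
  t1 <- best_hit_table(pair$genes_a, pair$genome_a, pair$genome_b)
  t2 <- best_hit_table(pair$genes_a, pair$genome_a, pair$genome_b)
  expect_identical(t1, t2)
})

test_that("candidate classification uses strict thresholds", {
  tab <- make_hit_table(align_len = c(150L, 100L, 200L, 101L),
                        pct_identity = c(98, 99, 96, 96.001))
  tab <- classify_candidates(tab, min_len = 100, min_identity = 96)
  expect_identical(tab$flag,
                   c("candidate", "background", "background", "candidate"))
  th <- attr(tab, "thresholds")
  expect_equal(th$min_len, 100)
  expect_error(classify_candidates(tab, 100, 101), "exceed")
})

test_that("the perfect-identity preset only passes exact matches", {
  tab <- make_hit_table(align_len = c(500L, 500L),
                        pct_identity = c(100, 99.9))
  tab <- classify_candidates(tab, 100, screen_preset("pi"))
  expect_identical(tab$flag, c("candidate", "background"))
  expect_equal(screen_preset("mi"), 96)
  expect_equal(screen_preset("tv"), 97)
})

test_that("background mean identity is an unweighted per-gene mean", {
  tab <- make_hit_table(align_len = rep(200L, 3),
                        pct_identity = c(70, 72, 74))
  tab <- classify_candidates(tab, 100, 96)
  expect_equal(background_mean_identity(tab), 72)

  all_cand <- classify_candidates(
    make_hit_table(align_len = rep(200L, 2), pct_identity = c(99, 98)),
    100, 96)
  expect_error(background_mean_identity(all_cand), "no non-candidate")
})

test_that("raising the identity threshold never adds candidates", {
  pair <- small_pair(n = 40L, s = 0.15, seed = 23L)
  tab <- best_hit_table(pair$genes_a, pair$genome_a, pair$genome_b)
  counts <- vapply(c(50, 70, 80, 85, 90, 96, 99.999), function(th) {
    sum(classify_candidates(tab, 100, th)$flag == "candidate")
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("localization splits candidates into inside and external", {
  tab <- make_hit_table(
    align_len = rep(300L, 5),
    pct_identity = c(99, 98, 97, 70, 99),
    gene_start = c(10000L, 12000L, 14000L, 30000L, 60000L))
  tab <- classify_candidates(tab, 100, 96)
  loc <- localization_check(tab, list(contig_id = "contig_A",
                                      start = 9000L, end = 20000L))
  expect_identical(loc$n_inside, 3L)
  expect_identical(loc$n_outside, 1L)
  expect_equal(loc$fraction_inside, 0.75)
  expect_identical(loc$table$flag[5], "external")
  # flags partition the rows
  expect_true(all(loc$table$flag %in%
                    c("candidate", "background", "external", "no_hit")))

  none <- classify_candidates(
    make_hit_table(align_len = rep(300L, 2), pct_identity = c(70, 71)),
    100, 96)
  expect_error(localization_check(none, c(0, 1000)), "no candidates")
})

test_that("hit-table summaries count classes consistently", {
  tab <- make_hit_table(align_len = c(300L, 300L, NA),
                        pct_identity = c(99, 70, NA))
  tab <- classify_candidates(tab, 100, 96)
  s <- summary(tab)
  expect_identical(s$n_genes, 3L)
  expect_identical(s$n_hits, 2L)
  expect_identical(s$n_candidates, 1L)
  expect_equal(s$background_mean_identity, 70)
})
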