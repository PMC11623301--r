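gene_df <- function(starts, ends, contig = "c1",
                    ids = sprintf("g%02d", seq_along(starts))) {
  data.frame(gene_id = ids, contig_id = contig,
             start = as.integer(starts), end = as.integer(ends),
             strand = "+", stringsAsFactors = FALSE)
}

test_that("three genes within the gap bound form one neighborhood", {
  g <- gene_df(c(1000, 10000, 20000), c(2000, 11000, 21000))
  nb <- find_neighborhoods(g, min_genes = 3, max_gap = 25000)
  expect_length(nb, 1L)
  expect_identical(nb[[1]]$member_gene_ids, g$gene_id)
  expect_equal(nb[[1]]$start, 1000)
  expect_equal(nb[[1]]$end, 21000)
})

test_that("fewer than min_genes genes never form a neighborhood", {
  g <- gene_df(c(1000, 2000), c(1500, 2500))
  expect_length(find_neighborhoods(g), 0L)
  expect_length(find_neighborhoods(g[0, ]), 0L)
})

test_that("chaining is single-linkage: spans may exceed the gap bound", {
  # five genes, consecutive gaps of 20 kb, total span ~84 kb
  starts <- seq(0, by = 21000, length.out = 5)
  g <- gene_df(starts, starts + 1000)
  nb <- find_neighborhoods(g, min_genes = 3, max_gap = 25000)
  expect_length(nb, 1L)
  expect_length(nb[[1]]$member_gene_ids, 5L)
  expect_gt(nb[[1]]$end - nb[[1]]$start, 25000)
})

test_that("clustering equals the brute-force single-linkage oracle", {
  skip_if_not_installed("igraph")
  set.seed(71)
  for (i in 1:120) {
    n <- sample(3:60, 1)
    contigs <- sample(c("c1", "c2"), n, replace = TRUE)
    starts <- sample.int(3e5, n)
    g <- gene_df(starts, starts + sample(200:5000, n, replace = TRUE),
                 contig = contigs)
    min_genes <- sample(2:4, 1)
    max_gap <- sample(c(2000L, 10000L, 25000L), 1)
    mine <- find_neighborhoods(g, min_genes, max_gap)
    ref <- brute_neighborhoods(g, min_genes, max_gap)
    expect_length(mine, length(ref))
    for (j in seq_along(mine)) {
      expect_identical(sort(mine[[j]]$member_gene_ids),
                       ref[[j]]$member_gene_ids)
      expect_equal(mine[[j]]$start, ref[[j]]$start)
      expect_equal(mine[[j]]$end, ref[[j]]$end)
    }
    # no gene belongs to two neighborhoods
    members <- unlist(lapply(mine, `[[`, "member_gene_ids"))
    expect_false(anyDuplicated(members) > 0)
  }
})

test_that("neighborhood counts are monotone in the parameters", {
  set.seed(72)
  starts <- sample.int(2e5, 40)
  g <- gene_df(starts, starts + 800)
  n_by_gap <- vapply(c(1000, 5000, 15000, 40000), function(mg) {
    length(find_neighborhoods(g, 3, mg))
  }, numeric(1))
  counts_total <- vapply(c(1000, 5000, 15000, 40000), function(mg) {
    sum(lengths(lapply(find_neighborhoods(g, 3, mg), `[[`,
                       "member_gene_ids")))
  }, numeric(1))
  # merging monotonicity: growing the gap only merges or extends chains,
  # so total clustered genes never drops
  expect_true(all(diff(counts_total) >= 0))
  n_by_min <- vapply(2:6, function(mg) {
    length(find_neighborhoods(g, mg, 10000))
  }, numeric(1))
  expect_true(all(diff(n_by_min) <= 0))
})

test_that("flank extension adds nearby genes and clips at the contig start", {
  g <- gene_df(c(1000, 10000, 20000), c(2000, 11000, 21000))
  extra <- gene_df(c(16000, 55000), c(16500, 55500),
                   ids = c("near", "far"))
  all_genes <- rbind(g, extra)
  nb <- find_neighborhoods(g, 3, 25000)[[1]]
  ext <- extend_neighborhood(nb, all_genes, flank = 25000)
  expect_true("near" %in% ext$flanked_gene_ids)   # 5 kb away
  expect_false("far" %in% ext$flanked_gene_ids)   # > 25 kb downstream
  # neighborhood at the contig start: flank clipped at 0, no error
  g0 <- gene_df(c(0, 5000, 10000), c(500, 5500, 10500))
  nb0 <- find_neighborhoods(g0, 3, 25000)[[1]]
  ext0 <- extend_neighborhood(nb0, g0, flank = 25000)
  expect_length(ext0$flanked_gene_ids, 3L)
})
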