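test_that("local DP oracle reproduces hand-derived alignments", {
  sc <- align_scoring(1, -1, -2)
  a <- dp_align_oracle("ACGT", "ACGT", sc)
  expect_equal(a$score, 4)
  expect_equal(percent_identity(a), 100)

  # full-length alignment beats the perfect 5-mer suffix (score 5)
  b <- dp_align_oracle("ACGTACGT", "ACCTACGT", sc)
  expect_equal(b$score, 6)
  expect_equal(b$columns, 8)
  expect_equal(b$matches, 7)
  expect_equal(percent_identity(b), 87.5)

  # nothing aligns: reported as no-hit, not an error
  d <- dp_align_oracle("AAAA", "TTTT", sc)
  expect_false(d$hit)
  expect_error(dp_align_oracle("", "ACGT", sc), "empty")
})

test_that("percent identity counts gaps as non-matches and N never matches", {
  expect_equal(percent_identity(list(matches = 96, columns = 100)), 96)
  expect_equal(percent_identity(list(matches = 7, columns = 8)), 87.5)
  expect_error(percent_identity(list(matches = 0, columns = 0)), "zero")
  a <- dp_align_oracle("ACNGTACGTA", "ACNGTACGTA", align_scoring(),
                       type = "glocal")
  expect_equal(a$columns, 10)
  expect_equal(a$matches, 9)  # the N column aligns but is not a match
})

test_that("alignment score is invariant under reverse-complementing both sequences", {
  set.seed(21)
  for (i in 1:20) {
    a <- rand_dna(40)
    b <- rand_dna(60)
    x <- dp_align_oracle(a, b)
    y <- dp_align_oracle(revcomp(a), revcomp(b))
    expect_equal(x$score, y$score)
  }
  # where the optimum is unique, identity is invariant too
  set.seed(22)
  b <- rand_dna(300)
  a <- substr(b, 101, 180)
  x <- dp_align_oracle(a, b)
  y <- dp_align_oracle(revcomp(a), revcomp(b))
  expect_equal(percent_identity(x), percent_identity(y))
  expect_equal(x$columns, y$columns)
})

test_that("an exact substring gene yields a full-length 100% hit", {
  set.seed(5)
  genome <- rand_dna(8000)
  gene <- substr(genome, 3001, 3600)
  hit <- best_hit(gene, genome)
  expect_true(hit$has_hit)
  expect_equal(hit$pct_identity, 100)
  expect_equal(hit$align_len, 600L)
  expect_equal(hit$subject_start, 3000L)
  expect_identical(hit$hit_strand, "+")
})

test_that("hits are found and reported on forward coordinates for - strand genes", {
  set.seed(6)
  genome <- rand_dna(6000)
  gene <- revcomp(substr(genome, 2001, 2500))
  hit <- best_hit(gene, genome)
  expect_true(hit$has_hit)
  expect_identical(hit$hit_strand, "-")
  expect_equal(hit$subject_start, 2000L)
  expect_equal(hit$pct_identity, 100)
})

test_that("seeded banded search matches the exhaustive glocal oracle", {
  set.seed(31)
  params <- best_hit_params(seed_len = 8L, min_score = 5L)
  n_eq <- 0L
  for (i in 1:60) {
    inst <- plant_instance(gene_len = sample(50:110, 1),
                           genome_len = sample(250:600, 1),
                           div = runif(1, 0, 0.08))
    bh <- best_hit(inst$gene, inst$genome, params)
    fwd <- dp_align_oracle(inst$gene, inst$genome, params$scoring, "glocal")
    rev <- dp_align_oracle(revcomp(inst$gene), inst$genome, params$scoring,
                           "glocal")
    expect_true(bh$has_hit)
    expect_equal(bh$score, max(fwd$score, rev$score))
    n_eq <- n_eq + 1L
  }
  expect_identical(n_eq, 60L)
})

test_that("a gene against an unrelated genome returns no-hit, not an error", {
  set.seed(41)
  gene <- rand_dna(500)
  genome <- rand_dna(20000)
  hit <- best_hit(gene, genome, best_hit_params(seed_len = 13L))
  expect_false(hit$has_hit)
  expect_true(is.na(hit$pct_identity))
})

test_that("best_hit is deterministic including tie-breaks", {
  set.seed(51)
  genome <- rand_dna(4000)
  gene <- substr(genome, 1001, 1300)
  # duplicate the gene so two equally scoring placements exist
  genome2 <- paste0(genome, substr(genome, 1001, 1300))
  h1 <- best_hit(gene, genome2)
  h2 <- best_hit(gene, genome2)
  expect_identical(h1, h2)
  # lexicographic tie-break: the earlier subject placement wins
  expect_equal(h1$subject_start, 1000L)
})

test_that("diverged orthologs align near their realized identity", {
  set.seed(61)
  for (i in 1:5) {
    inst <- plant_instance(gene_len = 800, genome_len = 5000, div = 0.28)
    bh <- best_hit(inst$gene, inst$genome)
    orc <- dp_align_oracle(inst$gene, inst$genome, align_scoring(), "glocal")
    expect_true(bh$has_hit)
    expect_lt(abs(bh$pct_identity - percent_identity(orc)), 2)
  }
})
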