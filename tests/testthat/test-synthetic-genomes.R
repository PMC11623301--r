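test_that("zero substitution probability gives identical ortholog pairs", {
  pair <- small_pair(n = 10L, s = 0, seed = 2L)
  expect_true(all(pair$truth$realized_identity == 100))
  sa <- extract_gene_seqs(pair$genome_a, pair$genes_a)
  sb <- extract_gene_seqs(pair$genome_b, pair$genes_b)
  expect_identical(unname(sa), unname(sb))
})

test_that("realized ortholog identity is binomial-consistent with 1 - s", {
  s <- 0.278
  pair <- generate_background_pair(synthetic_pair_config(
    n_background_genes = 200L, gene_length_range = c(1000L, 1000L),
    intergenic_length_range = c(150L, 300L), s = s, seed = 7L))
  r <- pair$truth$realized_identity
  expect_lt(abs(mean(r) - 72.2), 0.5)
  # per-gene spread follows the binomial sd (loose 40% factor)
  sd_theory <- 100 * sqrt(s * (1 - s) / 1000)
  expect_lt(abs(stats::sd(r) - sd_theory), 0.4 * sd_theory)
})

test_that("identical seeds reproduce identical pairs byte for byte", {
  p1 <- small_pair(seed = 9L)
  p2 <- small_pair(seed = 9L)
  expect_identical(as.character(p1$genome_a), as.character(p2$genome_a))
  expect_identical(as.character(p1$genome_b), as.character(p2$genome_b))
  expect_identical(p1$truth, p2$truth)
  p3 <- small_pair(seed = 10L)
  expect_false(identical(as.character(p1$genome_a), as.character(p3$genome_a)))
})

test_that("config validation rejects degenerate settings", {
  expect_error(synthetic_pair_config(s = 1), "\\[0, 1\\)")
  expect_error(synthetic_pair_config(gene_length_range = c(50L, 80L)),
               "min > 100")
  expect_error(synthetic_pair_config(intergenic_length_range = c(10L, 5L)),
               "degenerate")
})

test_that("a planted element is identical across genomes at identity 1", {
  pair <- small_pair(n = 10L, seed = 3L)
  spec <- element_spec("el", data.frame(
    gene_id = "el_cargo01", length = 600L, planted_identity = 1.0))
  pair <- plant_element(pair, spec, seed = 4L)
  sa <- extract_gene_seqs(pair$genome_a, pair$genes_a)
  sb <- extract_gene_seqs(pair$genome_b, pair$genes_b)
  expect_identical(sa[["el_cargo01"]], sb[["el_cargo01"]])
  # element interval length: captain + cargo + fixed spacers
  el <- pair$elements[["el"]]
  expect_equal(diff(el$interval_a), 2000L + 200L + 600L)
  expect_equal(diff(el$interval_b), diff(el$interval_a))
})

test_that("planted cargo realizes its target identity exactly", {
  pair <- small_pair(n = 12L, seed = 5L)
  ident <- c(0.98, 1.0, 0.9)
  spec <- element_spec("el", data.frame(
    gene_id = paste0("c", 1:3), length = c(1000L, 500L, 1000L),
    planted_identity = ident))
  pair <- plant_element(pair, spec, seed = 6L)
  tr <- pair$truth[pair$truth$is_element, ]
  expect_equal(tr$realized_identity, 100 * ident)
  expect_identical(tr$element_id, rep("el", 3))
  # background truth rows untouched
  expect_identical(sum(pair$truth$is_element), 3L)
})

test_that("insertion inside an existing gene is rejected", {
  pair <- small_pair(n = 5L, seed = 8L)
  inside <- pair$genes_a$start[2] + 10L
  spec <- element_spec("el", data.frame(
    gene_id = "c1", length = 300L, planted_identity = 1),
    insertion_site_a = inside)
  expect_error(plant_element(pair, spec), "inside gene")
})

test_that("read simulation honours the count formula and determinism", {
  genome <- stats::setNames(rand_dna(100000), "g")
  rd <- simulate_reads(genome, depth = 10, read_len = 150L, seed = 12L)
  expect_identical(length(rd$reads), 6667L)  # ceiling(10 * 1e5 / 150)
  rd2 <- simulate_reads(genome, depth = 10, read_len = 150L, seed = 12L)
  expect_identical(as.character(rd$reads), as.character(rd2$reads))
  expect_error(simulate_reads(stats::setNames(rand_dna(100), "g"),
                              depth = 1, read_len = 150L), "exceeds")
})

test_that("error-free reads are exact substrings at their truth positions", {
  set.seed(13)
  gseq <- rand_dna(20000)
  rd <- simulate_reads(stats::setNames(gseq, "g"), depth = 2,
                       read_len = 100L, seed = 13L)
  idx <- sample(length(rd$reads), 50)
  for (i in idx) {
    s <- unname(as.character(rd$reads[i]))
    if (rd$truth$strand[i] == "-") s <- revcomp(s)
    expect_identical(s,
                     substr(gseq, rd$truth$start[i] + 1, rd$truth$start[i] + 100))
  }
})

test_that("haploid cross simulation matches its segregation model", {
  # two unlinked loci: ~75% grow at the low concentration,
  # growth at the high concentration cosegregates with the element
  cr <- simulate_cross(cross_model(), n_progeny = 10000L, seed = 14L)
  expect_lt(abs(mean(cr$grows_at_2) - 0.75), 3 * sqrt(0.75 * 0.25 / 10000))
  expect_lt(abs(mean(cr$grows_at_5) - 0.50), 3 * sqrt(0.25 / 10000))
  expect_identical(cr$grows_at_5, cr$locus_element == 1L)

  none <- simulate_cross(cross_model(loci = list(dud = numeric(0))),
                         n_progeny = 50L, seed = 15L)
  expect_false(any(none$grows))
  expect_error(simulate_cross(cross_model(), 0), "positive")
})

test_that("fixture constants are frozen", {
  fc <- starscreen:::.fixture_constants()
  expect_identical(fc$shared$n_background_genes, 400L)
  expect_identical(fc$shared$captain_length, 2000L)
  expect_identical(fc$shared$spacer, 200L)
  expect_identical(fc$shared$min_len, 100L)
  expect_equal(fc$mi_pair$s, 0.278)
  expect_equal(fc$pi_pair$s, 0.277)
  expect_equal(fc$chi_pair$s, 0.275)
  expect_identical(length(fc$mi_pair$cargo_identity), 20L)
  expect_identical(length(fc$pi_pair$cargo_identity), 18L)
  expect_identical(length(fc$chi_pair$cargo_identity), 35L)
  expect_true(all(fc$mi_pair$cargo_identity >= 0.98))
  expect_identical(sum(fc$pi_pair$cargo_identity == 1), 10L)
  expect_true(all(fc$pi_pair$cargo_identity[11:18] >= 0.90 &
                    fc$pi_pair$cargo_identity[11:18] <= 0.955))
  expect_identical(sum(fc$chi_pair$cargo_identity >= 0.97), 29L)
  expect_true(all(fc$chi_pair$cargo_identity[30:35] >= 0.85 &
                    fc$chi_pair$cargo_identity[30:35] <= 0.95))
  expect_equal(fc$mi_pair$min_identity, 96)
  expect_equal(fc$pi_pair$min_identity, 99.999)
  expect_equal(fc$chi_pair$min_identity, 96)
  # checksum over the full frozen constant block
  expect_identical(sum(utf8ToInt(paste(deparse(fc), collapse = ""))), 62514L)
})
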