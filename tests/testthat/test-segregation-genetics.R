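test_that("expected resistant fractions follow 1 - (1-p)^n", {
  expect_equal(expected_resistant_fraction(1), 0.5)
  expect_equal(expected_resistant_fraction(2), 0.75)
  expect_equal(expected_resistant_fraction(0), 0)
  expect_equal(expected_resistant_fraction(3, p = 0.5), 0.875)
  expect_error(expected_resistant_fraction(2, p = 1.5), "\\[0, 1\\]")
  expect_error(expected_resistant_fraction(-1), "non-negative")
})

test_that("exact binomial test reproduces hand-derived p-values", {
  # the modal outcome: every point probability qualifies, p = 1
  expect_equal(exact_binomial_test(11, 22, 0.5)$p_value, 1)
  # only the two extreme outcomes qualify
  expect_equal(exact_binomial_test(22, 22, 0.5)$p_value, 2 * 0.5^22)
  expect_error(exact_binomial_test(5, 0), "at least 1")
  expect_error(exact_binomial_test(23, 22), "\\[0, n\\]")
})

test_that("exact binomial test equals enumeration for all n <= 25", {
  for (p0 in c(0.5, 0.75)) {
    for (n in 1:25) {
      for (k in 0:n) {
        p_enum <- {
          probs <- choose(n, 0:n) * p0^(0:n) * (1 - p0)^(n - (0:n))
          sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
        }
        expect_equal(exact_binomial_test(k, n, p0)$p_value,
                     min(1, p_enum), tolerance = 1e-12)
      }
    }
  }
  # independent cross-check against the established implementation
  for (case in list(c(18, 22), c(3, 20), c(7, 10))) {
    expect_equal(exact_binomial_test(case[1], case[2], 0.5)$p_value,
                 stats::binom.test(case[1], case[2], 0.5)$p.value)
  }
})

test_that("perfect cosegregation yields the extreme hypergeometric p", {
  marker <- rep(c(TRUE, FALSE), each = 11)
  res <- cosegregation_test(marker, marker)
  expect_true(res$perfect)
  expect_equal(res$p_value, 2 / choose(22, 11))
  expect_identical(unname(res$table[1, ]), c(11L, 0L))

  even <- cosegregation_test(rep(c(TRUE, FALSE), 10),
                             rep(c(TRUE, TRUE, FALSE, FALSE), 5))
  expect_equal(even$p_value, 1)
  expect_false(even$perfect)
  expect_error(cosegregation_test(c(TRUE, FALSE), TRUE), "length")
})

test_that("cosegregation p agrees with Fisher's exact test and is symmetric", {
  set.seed(91)
  for (i in 1:25) {
    n <- sample(6:30, 1)
    marker <- stats::runif(n) < 0.5
    pheno <- ifelse(stats::runif(n) < 0.7, marker, stats::runif(n) < 0.5)
    res <- cosegregation_test(marker, pheno)
    expect_equal(res$p_value,
                 stats::fisher.test(res$table)$p.value, tolerance = 1e-9)
    swapped <- cosegregation_test(pheno, marker)
    expect_equal(res$p_value, swapped$p_value, tolerance = 1e-12)
  }
})

test_that("simulated crosses converge to the analytic expectation", {
  cr <- simulate_cross(cross_model(), n_progeny = 10000L, seed = 92L)
  se <- sqrt(0.75 * 0.25 / 10000)
  expect_lt(abs(mean(cr$grows_at_2) - expected_resistant_fraction(2)), 3 * se)
  # marker-phenotype cosegregation at the stringent concentration is
  # perfect under the model
  res <- cosegregation_test(cr$locus_element == 1L, cr$grows_at_5)
  expect_true(res$perfect)
})
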