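# Named fixture genome pairs calibrated to the published per-element
# comparisons: cargo-gene complements, planted identities and background
# divergence are frozen here and covered by a frozen-copy test.

# All fixture constants live in this one function.  Cargo identities are
# placed several binomial standard deviations away from the classification
# thresholds so planted candidate counts are deterministic by construction.
.fixture_constants <- function() {
  list(
    shared = list(
      n_background_genes = 400L,
      gene_length_range = c(1000L, 1800L),
      intergenic_length_range = c(800L, 1600L),
      gc_content = 0.5,
      captain_length = 2000L,
      spacer = 200L,
      backbone_identity = 0.99,
      min_len = 100L
    ),
    mi_pair = list(
      # deep Aspergillus-type comparison: 20 near-identical cargo genes on
      # a 72.2% background, screened at >100 bp and >96% identity
      s = 0.278,
      cargo_identity = round(seq(0.98, 1.00, length.out = 20), 4),
      min_identity = 96,
      seed = 8101L
    ),
    pi_pair = list(
      # perfect-identity screen: 10 cargo genes at 100%, 8 diverged cargo
      # genes below the cutoff, 72.3% background, screened at 100% identity
      s = 0.277,
      cargo_identity = c(rep(1, 10),
                         round(seq(0.90, 0.95, length.out = 8), 4)),
      min_identity = 99.999,
      seed = 8102L
    ),
    chi_pair = list(
      # 35-gene element of which 29 are above the >96% cutoff, 72.5%
      # background
      s = 0.275,
      cargo_identity = c(round(seq(0.98, 1.00, length.out = 29), 4),
                         round(seq(0.85, 0.92, length.out = 6), 4)),
      min_identity = 96,
      seed = 8103L
    )
  )
}

#' Names of the built-in fixture genome pairs
#' @return character vector of fixture names.
#' @export
fixture_names <- function() c("mi_pair", "pi_pair", "chi_pair")

# cargo lengths: deterministic 1-1.6 kb pattern, frozen
.fixture_cargo_lengths <- function(n) 1000L + 40L * ((seq_len(n) - 1L) %% 16L)

#' Generate a named fixture genome pair
#'
#' Each fixture is a background pair at its calibrated divergence with one
#' planted element whose cargo-identity complement reproduces a published
#' per-element comparison; the screening thresholds that comparison used
#' are returned alongside.
#'
#' @param name one of [fixture_names()].
#' @param seed integer seed; `NULL` uses the fixture's pinned seed.
#' @param where which genome(s) receive the element (see [plant_element()]).
#' @return a list with `pair` (the planted `genome_pair`), `element` (the
#'   element record incl. intervals), `thresholds` (`min_len`,
#'   `min_identity`), `truth`, `name` and `seed`.
#' @export
starship_fixture <- function(name = fixture_names(), seed = NULL,
                             where = "both") {
  name <- match.arg(name)
  fc <- .fixture_constants()
  sh <- fc$shared
  fx <- fc[[name]]
  if (is.null(seed)) seed <- fx$seed
  seed <- as.integer(seed)
  cfg <- synthetic_pair_config(
    n_background_genes = sh$n_background_genes,
    gene_length_range = sh$gene_length_range,
    intergenic_length_range = sh$intergenic_length_range,
    s = fx$s, gc_content = sh$gc_content, seed = seed
  )
  pair <- generate_background_pair(cfg)
  nc <- length(fx$cargo_identity)
  cargo <- data.frame(
    gene_id = sprintf("%s_cargo%02d", name, seq_len(nc)),
    length = .fixture_cargo_lengths(nc),
    planted_identity = fx$cargo_identity,
    stringsAsFactors = FALSE
  )
  spec <- element_spec(
    element_id = name, cargo = cargo,
    captain_length = sh$captain_length, spacer = sh$spacer,
    backbone_identity = sh$backbone_identity
  )
  pair <- plant_element(pair, spec, seed = seed + 1L, where = where)
  list(
    pair = pair,
    element = pair$elements[[name]],
    thresholds = list(min_len = sh$min_len, min_identity = fx$min_identity),
    truth = pair$truth,
    name = name,
    seed = seed
  )
}

#' Planted candidate count expected from a fixture's truth table
#'
#' Counts truth-table genes planted above the screening thresholds --
#' the downstream expected answer, derived without touching sequence.
#'
#' @param fixture a [starship_fixture()] result (or any `genome_pair`
#'   truth table plus thresholds).
#' @return integer count.
#' @export
expected_candidate_count <- function(fixture) {
  tr <- fixture$truth
  th <- fixture$thresholds
  sum(tr$is_element & tr$length > th$min_len &
        tr$realized_identity > th$min_identity)
}
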