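# Single-gene-vs-genome alignment: the unit behind each point of the
# best-hit identity scatter.  A seed-and-extend banded search does the work;
# exhaustive dynamic-programming oracles back it in the test suite.

#' Alignment scoring scheme
#'
#' Linear gap penalties.  The default gap penalty (-4) is deliberately
#' steep: with a substitution-only divergence model, cheap gaps let the
#' optimizer trade mismatches for gap pairs and bias percent identity
#' upward, which would distort the genome-wide background calibration.
#'
#' @param match positive match score.
#' @param mismatch negative mismatch score.
#' @param gap negative per-gap-column score.
#' @return a named list used by the alignment functions.
#' @export
align_scoring <- function(match = 1L, mismatch = -1L, gap = -4L) {
  stopifnot(match > 0, mismatch < 0, gap < 0)
  list(match = as.integer(match), mismatch = as.integer(mismatch),
       gap = as.integer(gap))
}

#' Parameters for the best-hit search
#'
#' @param seed_len exact k-mer seed length anchoring candidate diagonals.
#' @param scoring scheme from [align_scoring()].
#' @param min_score minimum alignment score to report a hit.
#' @param band half-width (in diagonals) of the banded extension.
#' @param max_candidates number of top-ranked diagonal clusters rescored by
#'   full banded DP per gene and strand.
#' @return a named parameter list.
#' @export
best_hit_params <- function(seed_len = 11L, scoring = align_scoring(),
                            min_score = 30L, band = 16L,
                            max_candidates = 8L) {
  stopifnot(seed_len >= 4L, seed_len <= 31L, min_score > 0L, band >= 1L,
            max_candidates >= 1L)
  list(seed_len = as.integer(seed_len), scoring = scoring,
       min_score = as.integer(min_score), band = as.integer(band),
       max_candidates = as.integer(max_candidates))
}

.aln_result <- function(raw) {
  if (!raw$hit) {
    return(structure(list(hit = FALSE, score = 0L, columns = 0L,
                          matches = 0L, gaps = 0L,
                          query_span = c(0L, 0L), subject_span = c(0L, 0L),
                          pct_identity = NA_real_),
                     class = "alignment"))
  }
  structure(list(
    hit = TRUE, score = raw$score, columns = raw$columns,
    matches = raw$matches, gaps = raw$gaps,
    query_span = c(raw$query_start, raw$query_end),
    subject_span = c(raw$subject_start, raw$subject_end),
    pct_identity = 100 * raw$matches / raw$columns
  ), class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  if (!x$hit) {
    cat("<alignment> no hit (score <= 0)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<alignment> score %d | %d columns, %d matches, %d gaps | identity %.2f%%\n",
    x$score, x$columns, x$matches, x$gaps, x$pct_identity))
  cat(sprintf("  query [%d, %d)  subject [%d, %d)\n",
              x$query_span[1], x$query_span[2],
              x$subject_span[1], x$subject_span[2]))
  invisible(x)
}

#' Exhaustive dynamic-programming alignment oracle
#'
#' Computes a maximal-scoring alignment by full (unbanded) dynamic
#' programming.  `type = "local"` is Smith-Waterman; `type = "glocal"`
#' aligns the whole of `a` against a free-endpoint window of `b` -- the
#' same contract as the production [best_hit()] extension, so the two can
#' be compared score-for-score.  Intended for small problems (tests cap at
#' about 1e6 cells).  Ties are broken deterministically by smaller subject
#' start, then smaller query start, then shorter alignment.
#'
#' @param a query sequence (character).
#' @param b subject sequence (character).
#' @param scoring scheme from [align_scoring()].
#' @param type `"local"` or `"glocal"`.
#' @return an `alignment` object; local alignments with no positive-scoring
#'   cell are returned as a no-hit.
#' @export
#' @examples
#' dp_align_oracle("ACGTACGT", "ACCTACGT", align_scoring(1, -1, -2))
dp_align_oracle <- function(a, b, scoring = align_scoring(),
                            type = c("local", "glocal")) {
  type <- match.arg(type)
  stopifnot(is.character(a), is.character(b), length(a) == 1L,
            length(b) == 1L)
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty sequence")
  raw <- if (type == "local") {
    cpp_local_align(a, b, scoring$match, scoring$mismatch, scoring$gap)
  } else {
    cpp_glocal_align(a, b, scoring$match, scoring$mismatch, scoring$gap)
  }
  .aln_result(raw)
}

#' Percent identity of an alignment
#'
#' Matches divided by all alignment columns, gap columns included; `N`
#' never counts as a match.
#'
#' @param aln an `alignment` (or anything with `matches` and `columns`).
#' @return percentage in `[0, 100]`.
#' @export
percent_identity <- function(aln) {
  if (is.null(aln$columns) || aln$columns == 0L) {
    stop("alignment has zero columns")
  }
  100 * aln$matches / aln$columns
}

#' Best hit of one gene against a genome
#'
#' Seed-and-extend search: exact `seed_len`-mer matches anchor candidate
#' diagonals; each surviving candidate is rescored by a banded "glocal"
#' alignment (whole query, locally placed subject window), so background
#' identity is not inflated by trimming to conserved cores.  Both strands
#' are searched; hits are reported on the subject's forward coordinates.
#' Absence of seeds or a best score below `min_score` yields a no-hit
#' result, not an error.
#'
#' @param gene query gene sequence (character or `DNAString`).
#' @param genome subject genome (anything [as_genome()] accepts).
#' @param params from [best_hit_params()].
#' @return a one-row data.frame with columns `gene_id`, `has_hit`,
#'   `subject_contig`, `hit_strand`, `subject_start`, `subject_end`,
#'   `align_len`, `matches`, `gaps`, `score`, `pct_identity`.
#' @export
best_hit <- function(gene, genome, params = best_hit_params()) {
  gene <- as.character(gene)
  stopifnot(length(gene) == 1L)
  if (nchar(gene) <= params$seed_len) {
    stop("gene length must exceed the seed length")
  }
  res <- .best_hits_raw(stats::setNames(gene, "gene"), genome, params)
  res$gene_id <- "gene"
  res[, c("gene_id", setdiff(names(res), "gene_id"))]
}

# shared driver: named gene vector -> per-gene best-hit data.frame
.best_hits_raw <- function(genes, genome, params) {
  genome <- as_genome(genome)
  sc <- params$scoring
  df <- cpp_best_hits(unname(genes), as.character(genome),
                      params$seed_len, sc$match, sc$mismatch, sc$gap,
                      params$min_score, params$band, params$max_candidates)
  df$subject_contig <- ifelse(df$has_hit, names(genome)[df$contig_index],
                              NA_character_)
  df$hit_strand <- df$strand
  df$contig_index <- NULL
  df$strand <- NULL
  df
}
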