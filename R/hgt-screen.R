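# The "BLAST-all" screen: one best hit per annotated gene of the query
# strain against the partner assembly, candidate flagging by length and
# identity cutoffs, genome-wide background identity, and localization of
# candidates against a known element interval.

#' Extract gene sequences from a genome
#'
#' Genes on the `-` strand are reverse-complemented, so every returned
#' sequence reads in gene orientation.
#'
#' @param genome genome sequences (anything [as_genome()] accepts).
#' @param ann annotation data.frame (see [read_gff3()]).
#' @return named character vector of gene sequences.
#' @export
extract_gene_seqs <- function(genome, ann) {
  genome <- as_genome(genome)
  validate_annotations(ann, genome)
  gseq <- stats::setNames(as.character(genome), names(genome))
  out <- substring(gseq[ann$contig_id], ann$start + 1L, ann$end)
  neg <- ann$strand == "-"
  out[neg] <- vapply(out[neg], cpp_revcomp, character(1), USE.NAMES = FALSE)
  stats::setNames(out, ann$gene_id)
}

#' Per-gene best-hit table for a genome pair
#'
#' Runs [best_hit()] for every annotated gene of the query genome against
#' the target genome.  Rows preserve the input gene order; genes without a
#' hit are recorded as no-hit rows.  Flags are unset until
#' [classify_candidates()].
#'
#' @param genes annotation data.frame of the query genome.
#' @param genome_query genome the genes are extracted from.
#' @param genome_target partner genome searched against.
#' @param params search parameters from [best_hit_params()].
#' @return a `hit_table`: a data.frame (one row per gene) with the search
#'   parameters attached as attributes.
#' @export
best_hit_table <- function(genes, genome_query, genome_target,
                           params = best_hit_params()) {
  if (is.null(genes) || nrow(genes) == 0L) stop("empty gene set")
  genome_target <- as_genome(genome_target)
  if (sum(Biostrings::width(genome_target)) == 0L) stop("empty target genome")
  seqs <- extract_gene_seqs(genome_query, genes)
  res <- .best_hits_raw(seqs, genome_target, params)
  tab <- data.frame(
    gene_id = genes$gene_id,
    contig_id = genes$contig_id,
    gene_start = genes$start,
    gene_end = genes$end,
    gene_strand = genes$strand,
    has_hit = res$has_hit,
    subject_contig = res$subject_contig,
    hit_strand = res$hit_strand,
    subject_start = res$subject_start,
    subject_end = res$subject_end,
    align_len = res$align_len,
    matches = res$matches,
    gaps = res$gaps,
    score = res$score,
    pct_identity = res$pct_identity,
    flag = ifelse(res$has_hit, "unset", "no_hit"),
    stringsAsFactors = FALSE
  )
  structure(tab, params = params, thresholds = NULL,
            class = c("hit_table", "data.frame"))
}

#' Flag HGT candidates by length and identity cutoffs
#'
#' A gene is a candidate iff its best hit has alignment length strictly
#' greater than `min_len` and percent identity strictly greater than
#' `min_identity` (both strict, following the published ">100 bp, >96%"
#' convention).  All other genes with hits are background; genes without a
#' hit keep the `no_hit` flag.
#'
#' @param table a `hit_table`.
#' @param min_len minimum alignment length in bp (exclusive).
#' @param min_identity minimum percent identity (exclusive); use the
#'   [screen_preset()] value `99.999` for the perfect-identity screen.
#' @return the `hit_table` with `flag` set and thresholds recorded.
#' @export
classify_candidates <- function(table, min_len = 100, min_identity = 96) {
  stopifnot(inherits(table, "hit_table"))
  if (min_len <= 0 || min_identity <= 0) stop("thresholds must be positive")
  if (min_identity > 100) stop("min_identity cannot exceed 100")
  cand <- table$has_hit & table$align_len > min_len &
    table$pct_identity > min_identity
  table$flag <- ifelse(table$has_hit, ifelse(cand, "candidate", "background"),
                       "no_hit")
  attr(table, "thresholds") <- list(min_len = min_len,
                                    min_identity = min_identity)
  table
}

#' Identity threshold presets for the published per-element screens
#'
#' `mi` and `chi` use the >96% screen, `tv` >97%, and `pi` the perfect
#' identity screen (implemented as >99.999 to avoid float equality).
#'
#' @param comparison one of `"mi"`, `"chi"`, `"tv"`, `"pi"`.
#' @return the `min_identity` threshold as a percentage.
#' @export
screen_preset <- function(comparison = c("mi", "chi", "tv", "pi")) {
  comparison <- match.arg(comparison)
  switch(comparison, mi = 96, chi = 96, tv = 97, pi = 99.999)
}

#' Genome-wide background identity
#'
#' Unweighted mean percent identity over genes flagged `background` (hits
#' that are neither candidates nor external); each gene counts once
#' regardless of its alignment length.  This is the vertical-descent
#' baseline against which candidates stand out.
#'
#' @param table a classified `hit_table`.
#' @return mean percent identity.
#' @export
background_mean_identity <- function(table) {
  stopifnot(inherits(table, "hit_table"))
  bg <- table$flag == "background" & table$has_hit
  if (!any(bg)) stop("no non-candidate rows with hits")
  mean(table$pct_identity[bg])
}

#' Check candidate localization against a known element interval
#'
#' Each candidate is inside iff its gene interval overlaps the element
#' interval (half-open overlap on the same contig).  Candidates outside
#' are reflagged `external` -- the class of near-identical genes sitting
#' outside the element in one of the genomes.
#'
#' @param table a classified `hit_table`.
#' @param element_interval list with `contig_id`, `start`, `end` (0-based
#'   half-open), or a numeric `c(start, end)` if the table has one contig.
#' @return list with `table` (externals reflagged), `n_inside`,
#'   `n_outside` and `fraction_inside`.
#' @export
localization_check <- function(table, element_interval) {
  stopifnot(inherits(table, "hit_table"))
  if (is.numeric(element_interval) && length(element_interval) == 2L) {
    element_interval <- list(contig_id = table$contig_id[1],
                             start = element_interval[1],
                             end = element_interval[2])
  }
  if (element_interval$start >= element_interval$end) {
    stop("invalid element interval")
  }
  cand <- which(table$flag == "candidate")
  if (length(cand) == 0L) stop("no candidates to localize")
  inside <- table$contig_id[cand] == element_interval$contig_id &
    table$gene_start[cand] < element_interval$end &
    table$gene_end[cand] > element_interval$start
  table$flag[cand[!inside]] <- "external"
  list(table = table,
       n_inside = sum(inside),
       n_outside = sum(!inside),
       fraction_inside = sum(inside) / length(cand))
}

#' Summarize a hit table
#'
#' @param object a `hit_table`.
#' @param ... unused.
#' @return list with `n_genes`, `n_hits`, `n_candidates`, `n_external` and
#'   `background_mean_identity` (NA before classification).
#' @export
summary.hit_table <- function(object, ...) {
  cls <- !is.null(attr(object, "thresholds"))
  out <- list(
    n_genes = nrow(object),
    n_hits = sum(object$has_hit),
    n_candidates = if (cls) sum(object$flag == "candidate") else NA_integer_,
    n_external = if (cls) sum(object$flag == "external") else NA_integer_,
    background_mean_identity = if (cls && any(object$flag == "background")) {
      background_mean_identity(object)
    } else NA_real_,
    thresholds = attr(object, "thresholds")
  )
  class(out) <- "summary.hit_table"
  out
}

#' @export
print.summary.hit_table <- function(x, ...) {
  cat(sprintf("<hit_table> %d genes, %d with hits\n", x$n_genes, x$n_hits))
  if (!is.na(x$n_candidates)) {
    cat(sprintf("  candidates: %d (align_len > %s bp, identity > %s%%)\n",
                x$n_candidates, x$thresholds$min_len,
                x$thresholds$min_identity))
    if (!is.na(x$n_external) && x$n_external > 0) {
      cat(sprintf("  external: %d\n", x$n_external))
    }
    if (!is.na(x$background_mean_identity)) {
      cat(sprintf("  background mean identity: %.2f%%\n",
                  x$background_mean_identity))
    }
  }
  invisible(x)
}

#' @export
print.hit_table <- function(x, ...) {
  print(summary(x))
  NextMethod()
}

#' Identity-versus-length scatter of a hit table
#'
#' The classic screen figure: one point per gene, alignment length against
#' percent identity, colored by flag (candidates red, externals green,
#' background grey).
#'
#' @param table a classified `hit_table`.
#' @return a ggplot object.
#' @export
plot_hit_scatter <- function(table) {
  stopifnot(inherits(table, "hit_table"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_hit_scatter requires the ggplot2 package")
  }
  df <- as.data.frame(table)
  df <- df[df$has_hit, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$align_len,
                                   y = .data$pct_identity,
                                   colour = .data$flag)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(
      background = "grey40", candidate = "red", external = "forestgreen")) +
    ggplot2::labs(x = "best-hit alignment length (bp)",
                  y = "percent identity", colour = NULL) +
    ggplot2::theme_minimal()
}
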