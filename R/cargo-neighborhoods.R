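# Clustering of flagged genes into genomic neighborhoods: single-linkage
# chaining of nearest-edge gaps, the standard reading of "at least three
# different genes within 25,000 bp of each other".

#' Cluster genes into genomic neighborhoods
#'
#' Per contig, genes are sorted by start and consecutive genes whose
#' nearest-edge gap (start of the next minus end of the previous) is at
#' most `max_gap` are chained; chains with at least `min_genes` distinct
#' genes become neighborhoods.  Chaining is single linkage: a chain may
#' span far more than `max_gap` end to end as long as every consecutive
#' gap is within it.
#'
#' @param genes annotation data.frame (typically the candidate rows of a
#'   classified hit table, or any gene set of interest).
#' @param min_genes minimum distinct genes per neighborhood.
#' @param max_gap maximum nearest-edge gap in bp between consecutive
#'   members.
#' @return list of `neighborhood` objects sorted by (contig, span start);
#'   empty input gives an empty list.
#' @export
find_neighborhoods <- function(genes, min_genes = 3L, max_gap = 25000L) {
  if (is.null(genes) || nrow(genes) == 0L) return(list())
  validate_annotations(genes)
  out <- list()
  for (ct in unique(genes$contig_id)) {
    g <- genes[genes$contig_id == ct, , drop = FALSE]
    g <- g[order(g$start, g$end, g$gene_id), , drop = FALSE]
    n <- nrow(g)
    # running max of interval ends guards against contained intervals
    run_end <- cummax(g$end)
    new_chain <- c(TRUE, g$start[-1L] - run_end[-n] > max_gap)
    chain <- cumsum(new_chain)
    for (cid in unique(chain)) {
      m <- g[chain == cid, , drop = FALSE]
      if (length(unique(m$gene_id)) < min_genes) next
      out[[length(out) + 1L]] <- structure(list(
        contig_id = ct,
        member_gene_ids = m$gene_id,
        start = min(m$start),
        end = max(m$end),
        flanked_gene_ids = NULL
      ), class = "neighborhood")
    }
  }
  ord <- order(vapply(out, `[[`, character(1), "contig_id"),
               vapply(out, `[[`, numeric(1), "start"))
  out[ord]
}

#' @export
print.neighborhood <- function(x, ...) {
  cat(sprintf("<neighborhood> %s:[%d, %d)  %d member genes%s\n",
              x$contig_id, x$start, x$end, length(x$member_gene_ids),
              if (!is.null(x$flanked_gene_ids)) {
                sprintf(", %d with flank", length(x$flanked_gene_ids))
              } else ""))
  invisible(x)
}

#' Extend a neighborhood by a flanking window
#'
#' Adds to the member set every gene whose interval overlaps the span
#' enlarged by `flank` on both sides (clipped at position 0 and, if given,
#' the contig length).
#'
#' @param nbhd a `neighborhood` from [find_neighborhoods()].
#' @param all_genes annotation data.frame to draw flanking genes from.
#' @param flank flank size in bp on each side.
#' @param contig_length optional contig length for right-side clipping.
#' @return the `neighborhood` with `flanked_gene_ids` filled in.
#' @export
extend_neighborhood <- function(nbhd, all_genes, flank = 25000L,
                                contig_length = NULL) {
  stopifnot(inherits(nbhd, "neighborhood"))
  lo <- max(0L, nbhd$start - flank)
  hi <- nbhd$end + flank
  if (!is.null(contig_length)) hi <- min(hi, contig_length)
  g <- all_genes[all_genes$contig_id == nbhd$contig_id, , drop = FALSE]
  keep <- g$start < hi & g$end > lo
  nbhd$flanked_gene_ids <- union(nbhd$member_gene_ids, g$gene_id[keep])
  nbhd
}

#' Write neighborhoods and their gene lists to TSV
#'
#' @param nbhds list of neighborhoods.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_neighborhood_tsv <- function(nbhds, path) {
  rows <- do.call(rbind, lapply(seq_along(nbhds), function(i) {
    nb <- nbhds[[i]]
    data.frame(
      neighborhood = paste0("neighborhood_", i),
      contig_id = nb$contig_id, start = nb$start, end = nb$end,
      n_members = length(nb$member_gene_ids),
      member_gene_ids = paste(nb$member_gene_ids, collapse = ","),
      flanked_gene_ids = if (is.null(nb$flanked_gene_ids)) "" else {
        paste(nb$flanked_gene_ids, collapse = ",")
      },
      stringsAsFactors = FALSE
    )
  }))
  con <- file(path, "w")
  on.exit(close(con))
  if (is.null(rows)) {
    writeLines("#neighborhood\tcontig_id\tstart\tend\tn_members\tmember_gene_ids\tflanked_gene_ids", con)
  } else {
    writeLines(paste0("#", paste(names(rows), collapse = "\t")), con)
    utils::write.table(rows, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
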