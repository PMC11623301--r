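# One-shot rehearsal of the whole inference stack on a named fixture:
# generate the pair, screen, localize, cluster neighborhoods, call element
# presence from simulated reads, and write every intermediate artifact.

#' Run the full pipeline on a fixture genome pair
#'
#' Generates the named fixture, screens genome A's genes against genome B
#' at the fixture's preset thresholds, checks candidate localization
#' against the planted element, clusters candidates into neighborhoods,
#' simulates 10x reads for an element-carrying strain and an element-free
#' control and calls presence, and (optionally) writes a human-readable
#' report plus all intermediate FASTA/GFF3/TSV/BED artifacts.
#'
#' Reports contain no timestamps or absolute paths, so a rerun with the
#' same seed reproduces every output byte.
#'
#' @param fixture one of [fixture_names()].
#' @param seed integer seed; `NULL` uses the fixture's pinned seed.
#' @param outdir output directory for artifacts, or `NULL` to skip
#'   writing.
#' @param read_depth fold coverage of the simulated presence reads.
#' @param params search parameters from [best_hit_params()].
#' @return (invisibly) a `demo_report` list: candidate count, background
#'   mean identity, fraction of candidates inside the element,
#'   neighborhoods, presence calls, the classified hit table and the
#'   fixture itself.
#' @export
run_demo <- function(fixture = fixture_names(), seed = NULL, outdir = NULL,
                     read_depth = 10, params = best_hit_params()) {
  if (length(fixture) != 1L || !fixture %in% fixture_names()) {
    stop("unknown fixture; valid names: ",
         paste(fixture_names(), collapse = ", "))
  }
  fx <- starship_fixture(fixture, seed = seed)
  pair <- fx$pair
  th <- fx$thresholds

  tab <- best_hit_table(pair$genes_a, pair$genome_a, pair$genome_b, params)
  tab <- classify_candidates(tab, min_len = th$min_len,
                             min_identity = th$min_identity)
  bg_mean <- background_mean_identity(tab)
  loc <- localization_check(tab, list(contig_id = "contig_A",
                                      start = fx$element$interval_a[1],
                                      end = fx$element$interval_a[2]))
  tab <- loc$table

  cand <- as.data.frame(tab)[tab$flag == "candidate",
                             c("gene_id", "contig_id", "gene_start",
                               "gene_end", "gene_strand")]
  names(cand) <- c("gene_id", "contig_id", "start", "end", "strand")
  nbhds <- find_neighborhoods(cand)
  nbhds <- lapply(nbhds, extend_neighborhood, all_genes = pair$genes_a,
                  contig_length = Biostrings::width(pair$genome_a)[1])

  # presence: strain A carries the element; the control is genome B with
  # the element interval excised (background retained, element absent)
  elem_ref <- as_genome(stats::setNames(fx$element$sequence_a, fixture))
  reads_pos <- simulate_reads(pair$genome_a, depth = read_depth,
                              seed = fx$seed + 2L)
  bseq <- as.character(pair$genome_b)[[1]]
  iv <- fx$element$interval_b
  control <- paste0(substr(bseq, 1L, iv[1]),
                    substr(bseq, iv[2] + 1L, nchar(bseq)))
  reads_neg <- simulate_reads(stats::setNames(control, "control"),
                              depth = read_depth, seed = fx$seed + 3L)
  call_pos <- call_presence(map_reads(reads_pos$reads, elem_ref),
                            strain_id = "strain_A")
  call_neg <- call_presence(map_reads(reads_neg$reads, elem_ref),
                            strain_id = "control")

  report <- structure(list(
    fixture = fixture, seed = fx$seed,
    thresholds = th,
    n_genes = nrow(tab), n_hits = sum(tab$has_hit),
    n_candidates = sum(tab$flag == "candidate") + loc$n_outside,
    n_inside = loc$n_inside, n_outside = loc$n_outside,
    fraction_inside = loc$fraction_inside,
    background_mean_identity = bg_mean,
    expected_candidates = expected_candidate_count(fx),
    neighborhoods = nbhds,
    presence = list(strain_A = call_pos, control = call_neg),
    hit_table = tab,
    fixture_data = fx
  ), class = "demo_report")

  if (!is.null(outdir)) .write_demo_artifacts(report, outdir)
  invisible(report)
}

#' @export
print.demo_report <- function(x, ...) {
  writeLines(.report_lines(x))
  invisible(x)
}

.report_lines <- function(x) {
  nb <- vapply(seq_along(x$neighborhoods), function(i) {
    n <- x$neighborhoods[[i]]
    sprintf("  neighborhood_%d  %s:[%d, %d)  members=%d  flanked=%d",
            i, n$contig_id, n$start, n$end, length(n$member_gene_ids),
            length(n$flanked_gene_ids))
  }, character(1))
  c(
    sprintf("fixture: %s (seed %d)", x$fixture, x$seed),
    sprintf("thresholds: align_len > %d bp, identity > %s%%",
            x$thresholds$min_len, format(x$thresholds$min_identity)),
    sprintf("genes screened: %d (%d with hits)", x$n_genes, x$n_hits),
    sprintf("candidates: %d (expected from truth table: %d)",
            x$n_candidates, x$expected_candidates),
    sprintf("candidates inside element: %d / %d (fraction %.3f)",
            x$n_inside, x$n_candidates, x$fraction_inside),
    sprintf("background mean identity: %.4f%%", x$background_mean_identity),
    sprintf("neighborhoods: %d", length(x$neighborhoods)),
    nb,
    sprintf("presence strain_A: breadth %.4f -> %s",
            x$presence$strain_A$breadth, x$presence$strain_A$status),
    sprintf("presence control: breadth %.4f -> %s",
            x$presence$control$breadth, x$presence$control$status)
  )
}

.write_demo_artifacts <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fx <- report$fixture_data
  pair <- fx$pair
  p <- function(...) file.path(outdir, ...)
  write_fasta(pair$genome_a, p("genome_A.fa"))
  write_fasta(pair$genome_b, p("genome_B.fa"))
  write_gff3(pair$genes_a, p("genes_A.gff3"))
  write_gff3(pair$genes_b, p("genes_B.gff3"))
  write_fasta(as_genome(stats::setNames(fx$element$sequence_a,
                                        report$fixture)),
              p("element.fa"))
  write_hit_table(report$hit_table, p("hits.tsv"))
  write_neighborhood_bed(report$neighborhoods, p("neighborhoods.bed"))
  write_neighborhood_tsv(report$neighborhoods, p("neighborhoods.tsv"))
  write_presence_tsv(report$presence, p("presence.tsv"))
  tr <- fx$truth
  con <- file(p("truth.tsv"), "w")
  writeLines(paste0("#", paste(names(tr), collapse = "\t")), con)
  utils::write.table(
    data.frame(tr[1:3],
               expected_identity = .fmt_num(tr$expected_identity),
               realized_identity = .fmt_num(tr$realized_identity),
               tr[6:7],
               planted_identity = .fmt_num(tr$planted_identity)),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  close(con)
  writeLines(.report_lines(report), p("report.txt"))
  invisible(outdir)
}
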