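# File-format boundary: FASTA/FASTQ via Biostrings, GFF3 via rtracklayer,
# plus the package's TSV/BED writers.  Internal coordinates are 0-based
# half-open everywhere; GFF3 (1-based inclusive) and BED (0-based half-open)
# are converted only here.

#' Read a FASTA file of genome sequences
#'
#' Sequences are uppercased on ingest and must contain only A/C/G/T/N;
#' record ids (first whitespace-separated token of the header) must be
#' unique and the file must contain at least one record.
#'
#' @param path path to an (optionally gzipped) FASTA file.
#' @return a named [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  x <- withCallingHandlers(
    Biostrings::readDNAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        .report_bad_fasta_chars(path)
      }
      invokeRestart("muffleWarning")
    }
  )
  if (length(x) == 0L) stop("FASTA file is empty: ", path)
  names(x) <- sub("\\s.*$", "", names(x))
  dup <- names(x)[duplicated(names(x))]
  if (length(dup) > 0L) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  }
  x <- Biostrings::DNAStringSet(toupper(as.character(x)))
  .check_alphabet(x)
  x
}

# name the offending characters (the parser would silently drop them)
.report_bad_fasta_chars <- function(path) {
  lines <- readLines(path)
  seq_lines <- lines[!startsWith(lines, ">")]
  chars <- unique(strsplit(paste(seq_lines, collapse = ""), "")[[1]])
  bad <- setdiff(chars, c("A", "C", "G", "T", "N", "a", "c", "g", "t", "n"))
  stop("sequence contains characters outside A/C/G/T/N: ",
       paste(bad, collapse = ", "))
}

.check_alphabet <- function(x) {
  freq <- Biostrings::alphabetFrequency(x, baseOnly = FALSE)
  allowed <- c("A", "C", "G", "T", "N")
  bad <- colnames(freq)[colSums(freq) > 0 & !colnames(freq) %in% allowed]
  if (length(bad) > 0L) {
    stop("sequence contains characters outside A/C/G/T/N: ",
         paste(bad, collapse = ", "))
  }
  invisible(x)
}

#' Write genome sequences to FASTA
#'
#' Records are written in order, wrapped at 60 columns.
#'
#' @param x named [Biostrings::DNAStringSet] or named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  x <- as_genome(x)
  if (anyDuplicated(names(x))) stop("duplicate ids in FASTA records")
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Coerce to a validated genome container
#'
#' Accepts a named character vector, a [Biostrings::DNAStringSet] or a
#' single [Biostrings::DNAString]; returns an uppercase `DNAStringSet`
#' restricted to the A/C/G/T/N alphabet.
#'
#' @param x sequences.
#' @return a named [Biostrings::DNAStringSet].
#' @export
as_genome <- function(x) {
  if (is(x, "DNAString")) x <- Biostrings::DNAStringSet(x)
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    x <- Biostrings::DNAStringSet(x)
  }
  if (!is(x, "DNAStringSet")) stop("cannot interpret input as sequences")
  if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
  s <- stats::setNames(toupper(as.character(x)), names(x))
  x <- Biostrings::DNAStringSet(s)
  .check_alphabet(x)
  x
}

#' Read gene annotations from GFF3
#'
#' Only `gene` features are kept; each must carry an `ID` attribute unique
#' within the file.  GFF3 1-based inclusive coordinates are converted to the
#' package's 0-based half-open convention.
#'
#' @param path path to a GFF3 file.
#' @return a data.frame with columns `gene_id`, `contig_id`, `start`, `end`
#'   (0-based half-open) and `strand`.
#' @export
read_gff3 <- function(path) {
  .prescan_gff3(path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  if (length(gr) == 0L) stop("no gene features in GFF3: ", path)
  ids <- as.character(gr$ID)
  ann <- data.frame(
    gene_id = ids,
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+"),
    stringsAsFactors = FALSE
  )
  validate_annotations(ann)
  ann
}

# line-numbered validation that rtracklayer does not provide
.prescan_gff3 <- function(path) {
  lines <- readLines(path)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L) next
    if (f[3] != "gene") next
    s <- suppressWarnings(as.integer(f[4]))
    e <- suppressWarnings(as.integer(f[5]))
    if (is.na(s) || is.na(e) || s > e) {
      stop("GFF3 line ", i, ": start > end (or unparsable coordinates)")
    }
    if (!grepl("(^|;)ID=", f[9])) {
      stop("GFF3 line ", i, ": gene feature lacks an ID attribute")
    }
  }
  invisible(path)
}

#' Validate an annotation data.frame
#'
#' Checks the internal 0-based half-open contract: `0 <= start < end`,
#' unique `gene_id`, strand in `+`/`-`.  If `genome` is supplied, gene ends
#' are also checked against contig lengths.
#'
#' @param ann annotation data.frame as returned by [read_gff3()].
#' @param genome optional genome the annotations refer to.
#' @return `ann`, invisibly.
#' @export
validate_annotations <- function(ann, genome = NULL) {
  req <- c("gene_id", "contig_id", "start", "end", "strand")
  miss <- setdiff(req, names(ann))
  if (length(miss) > 0L) stop("annotation is missing column(s): ",
                              paste(miss, collapse = ", "))
  if (anyDuplicated(ann$gene_id)) {
    stop("duplicate gene_id(s): ",
         paste(unique(ann$gene_id[duplicated(ann$gene_id)]), collapse = ", "))
  }
  if (any(ann$start < 0L) || any(ann$start >= ann$end)) {
    stop("gene intervals must satisfy 0 <= start < end")
  }
  if (!all(ann$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (!is.null(genome)) {
    genome <- as_genome(genome)
    len <- stats::setNames(Biostrings::width(genome), names(genome))
    if (!all(ann$contig_id %in% names(len))) {
      stop("annotation refers to contig(s) absent from the genome")
    }
    if (any(ann$end > len[ann$contig_id])) {
      stop("gene interval extends past the end of its contig")
    }
  }
  invisible(ann)
}

#' Write gene annotations to GFF3
#'
#' Internal 0-based half-open coordinates are converted back to GFF3
#' 1-based inclusive; the round trip through [read_gff3()] is lossless.
#'
#' @param ann annotation data.frame (see [read_gff3()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(ann, path) {
  validate_annotations(ann)
  gr <- GenomicRanges::GRanges(
    seqnames = ann$contig_id,
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
    strand = ann$strand
  )
  gr$source <- "starscreen"
  gr$type <- "gene"
  gr$ID <- ann$gene_id
  gr$Name <- ann$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read sequencing reads from FASTQ
#'
#' Base qualities are not used by the internal mapper and are discarded.
#'
#' @param path path to a FASTQ file (Sanger Phred+33).
#' @return a named [Biostrings::DNAStringSet].
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  if (length(x) == 0L) stop("FASTQ file is empty: ", path)
  names(x) <- sub("\\s.*$", "", names(x))
  Biostrings::DNAStringSet(toupper(as.character(x)))
}

#' Write reads to FASTQ
#'
#' Constant placeholder qualities (`I`, Phred 40) are emitted: the
#' generator does not model a quality profile.
#'
#' @param reads named [Biostrings::DNAStringSet] or character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  reads <- as_genome(reads)
  quals <- Biostrings::BStringSet(vapply(Biostrings::width(reads), function(w) {
    paste(rep("I", w), collapse = "")
  }, character(1)))
  Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = quals)
  invisible(path)
}

# ---- TSV / BED writers -----------------------------------------------------

.fmt_num <- function(x) ifelse(is.na(x), "", sprintf("%.4f", x))

#' Write a hit table to TSV
#'
#' One row per gene; a `#`-prefixed header line documents the columns;
#' floating point fields carry 4 decimals; genes without a hit have empty
#' subject fields and flag `no_hit`.
#'
#' @param table a `hit_table` (see [best_hit_table()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(table, path) {
  stopifnot(inherits(table, "hit_table"))
  df <- as.data.frame(table)
  flag <- df$flag
  flag[!df$has_hit] <- "no_hit"
  rows <- data.frame(
    gene_id = df$gene_id,
    subject_contig = ifelse(df$has_hit, df$subject_contig, ""),
    subject_start = ifelse(df$has_hit, df$subject_start, ""),
    subject_end = ifelse(df$has_hit, df$subject_end, ""),
    hit_strand = ifelse(df$has_hit, df$hit_strand, ""),
    align_len = ifelse(df$has_hit, df$align_len, ""),
    pct_identity = ifelse(df$has_hit, .fmt_num(df$pct_identity), ""),
    score = ifelse(df$has_hit, df$score, ""),
    flag = flag,
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(rows), collapse = "\t")), con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read back a hit-table TSV written by [write_hit_table()]
#'
#' @param path TSV path.
#' @return a data.frame mirroring the written columns.
#' @export
read_hit_table_tsv <- function(path) {
  header <- sub("^#", "", readLines(path, n = 1L))
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          col.names = strsplit(header, "\t")[[1]],
                          stringsAsFactors = FALSE, fill = TRUE,
                          colClasses = "character")
  df$subject_start <- suppressWarnings(as.integer(df$subject_start))
  df$subject_end <- suppressWarnings(as.integer(df$subject_end))
  df$align_len <- suppressWarnings(as.integer(df$align_len))
  df$score <- suppressWarnings(as.integer(df$score))
  df$pct_identity <- suppressWarnings(as.numeric(df$pct_identity))
  df
}

#' Write neighborhoods to BED6
#'
#' One line per neighborhood span (BED is 0-based half-open, matching the
#' internal convention, so no coordinate shift occurs).  The score column
#' holds the member-gene count.
#'
#' @param nbhds list of `neighborhood` objects from [find_neighborhoods()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_neighborhood_bed <- function(nbhds, path) {
  lines <- vapply(seq_along(nbhds), function(i) {
    nb <- nbhds[[i]]
    paste(nb$contig_id, nb$start, nb$end, paste0("neighborhood_", i),
          length(nb$member_gene_ids), "+", sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write presence calls to TSV
#'
#' @param calls a `presence_call` or list of them (see [call_presence()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_presence_tsv <- function(calls, path) {
  if (inherits(calls, "presence_call")) calls <- list(calls)
  rows <- do.call(rbind, lapply(calls, function(x) {
    data.frame(strain_id = x$strain_id, breadth = .fmt_num(x$breadth),
               status = x$status,
               present_threshold = .fmt_num(x$present_threshold),
               absent_threshold = .fmt_num(x$absent_threshold),
               stringsAsFactors = FALSE)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(rows), collapse = "\t")), con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a precomputed per-base depth table
#'
#' Accepts the two-column `position<TAB>depth` format (positions 0-based)
#' produced by external coverage workflows, as an alternative to the
#' internal [map_reads()] mapper.
#'
#' @param path TSV path.
#' @param ref_length reference length; positions absent from the file get
#'   depth 0.
#' @param ref_id reference identifier stored on the profile.
#' @return a `depth_profile` (see [map_reads()]).
#' @export
read_depth_tsv <- function(path, ref_length, ref_id = "ref") {
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          col.names = c("position", "depth"))
  if (any(df$position < 0L | df$position >= ref_length)) {
    stop("depth table position outside [0, ref_length)")
  }
  depth <- integer(ref_length)
  depth[df$position + 1L] <- as.integer(df$depth)
  structure(list(ref_id = ref_id, depth = depth,
                 n_mapped = NA_integer_, n_reads = NA_integer_,
                 placements = NULL),
            class = "depth_profile")
}
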