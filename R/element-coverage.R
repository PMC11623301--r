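# Presence/absence of an element in a strain from read coverage: exact-seed
# read placement, breadth of coverage, and the >90%-breadth presence call.

#' Map reads to an element reference
#'
#' Internal exact-seed mapper: each read is anchored at its first exact
#' `k`-mer match against the reference (forward, then reverse complement)
#' and the placement is kept if ungapped identity over the clipped placed
#' span is at least `min_identity`.  Reads without a verifying placement
#' are counted unmapped.  Sufficient for substitution-only synthetic
#' reads; externally computed depth tables can be supplied instead via
#' [read_depth_tsv()].
#'
#' @param reads reads (FASTQ path, `DNAStringSet` or character vector).
#' @param reference single reference sequence.
#' @param k exact seed length; must be shorter than the reads and the
#'   reference.
#' @param min_identity read-level identity required to accept a placement.
#' @param max_attempts candidate placements tried per read and strand.
#' @return a `depth_profile`: list with `ref_id`, `depth` (integer per-base
#'   depth over the reference), `n_mapped`, `n_reads` and `placements`
#'   (per-read placement data.frame).
#' @export
map_reads <- function(reads, reference, k = 21L, min_identity = 0.9,
                      max_attempts = 64L) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_fastq(reads)
  }
  reads <- as_genome(reads)
  if (length(reads) == 0L) stop("no reads supplied")
  reference <- as_genome(reference)
  stopifnot(length(reference) == 1L)
  ref_len <- Biostrings::width(reference)[1]
  if (ref_len < k) stop("reference shorter than seed length k")
  if (min(Biostrings::width(reads)) < k) {
    stop("seed length k exceeds the shortest read")
  }
  res <- cpp_map_reads(as.character(reads), as.character(reference)[[1]],
                       as.integer(k), min_identity, as.integer(max_attempts))
  structure(list(
    ref_id = names(reference),
    depth = res$depth,
    n_mapped = res$n_mapped,
    n_reads = res$n_reads,
    placements = data.frame(read_id = names(reads), mapped = res$mapped,
                            start = res$start, strand = res$strand,
                            stringsAsFactors = FALSE)
  ), class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("<depth_profile> %s (%d bp): %s/%s reads mapped, breadth %.3f\n",
              x$ref_id, length(x$depth),
              format(x$n_mapped), format(x$n_reads),
              coverage_breadth(x)))
  invisible(x)
}

#' Breadth of coverage
#'
#' Fraction of reference positions with depth at least `min_depth` --
#' breadth, not mean depth, is what the ">90% read coverage across the
#' reference" presence criterion measures.
#'
#' @param profile a `depth_profile` (or bare integer depth vector).
#' @param min_depth minimum per-position depth to count as covered.
#' @return fraction in `[0, 1]`.
#' @export
coverage_breadth <- function(profile, min_depth = 1L) {
  depth <- if (inherits(profile, "depth_profile")) profile$depth else profile
  if (length(depth) == 0L) stop("empty depth profile")
  mean(depth >= min_depth)
}

#' Presence call from coverage breadth
#'
#' `present` above `present_threshold`, `absent` below `absent_threshold`,
#' `partial` in between (the partial band stands in for truncated element
#' copies).
#'
#' @param breadth coverage breadth in `[0, 1]`, or a `depth_profile` (then
#'   breadth is computed at `min_depth = 1`).
#' @param present_threshold breadth above which the element is present.
#' @param absent_threshold breadth below which it is absent.
#' @param strain_id identifier carried on the call.
#' @return a `presence_call` list with `strain_id`, `breadth`, `status`
#'   and the thresholds used.
#' @export
call_presence <- function(breadth, present_threshold = 0.90,
                          absent_threshold = 0.10, strain_id = "strain") {
  if (inherits(breadth, "depth_profile")) {
    breadth <- coverage_breadth(breadth, min_depth = 1L)
  }
  if (!(absent_threshold >= 0 && absent_threshold < present_threshold &&
        present_threshold <= 1)) {
    stop("thresholds must satisfy 0 <= absent < present <= 1")
  }
  status <- if (breadth > present_threshold) {
    "present"
  } else if (breadth < absent_threshold) {
    "absent"
  } else "partial"
  structure(list(strain_id = strain_id, breadth = breadth, status = status,
                 present_threshold = present_threshold,
                 absent_threshold = absent_threshold),
            class = "presence_call")
}

#' @export
print.presence_call <- function(x, ...) {
  cat(sprintf("<presence_call> %s: breadth %.3f -> %s (present > %.2f, absent < %.2f)\n",
              x$strain_id, x$breadth, x$status,
              x$present_threshold, x$absent_threshold))
  invisible(x)
}
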