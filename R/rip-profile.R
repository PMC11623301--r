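# Dinucleotide-based profiling of repeat-induced point (RIP) mutation.
# RIP converts CpA -> TpA (and, on the opposite strand, TpG -> TpA),
# depleting substrate dinucleotides and enriching the TpA product; the
# standard composite indices make that visible per window.

#' Overlapping dinucleotide counts
#'
#' Counts all 16 A/C/G/T dinucleotides over overlapping windows of width
#' two; windows containing N contribute nothing.
#'
#' @param seq a single sequence (character or `DNAString`).
#' @return named integer vector of the 16 dinucleotide counts.
#' @export
#' @examples
#' dinucleotide_counts("ACGT")
dinucleotide_counts <- function(seq) {
  seq <- as.character(seq)
  stopifnot(length(seq) == 1L)
  if (nchar(seq) < 2L) stop("sequence must be at least 2 bp")
  Biostrings::dinucleotideFrequency(Biostrings::DNAString(toupper(seq)))
}

.rip_window_indices <- function(counts) {
  product <- if (counts[["AT"]] > 0) counts[["TA"]] / counts[["AT"]] else NA_real_
  sub_den <- counts[["AC"]] + counts[["GT"]]
  substrate <- if (sub_den > 0) {
    (counts[["CA"]] + counts[["TG"]]) / sub_den
  } else NA_real_
  composite <- if (!is.na(product) && !is.na(substrate)) {
    product - substrate
  } else NA_real_
  c(product_index = product, substrate_index = substrate,
    composite_index = composite)
}

#' Sliding-window RIP indices
#'
#' Per window: product index `f(TpA)/f(ApT)` (rises under RIP), substrate
#' index `(f(CpA)+f(TpG))/(f(ApC)+f(GpT))` (falls under RIP), and their
#' difference as the composite.  Windows with a zero denominator carry NA
#' rather than a fabricated value.  If the window exceeds the sequence
#' length, a single whole-sequence window is profiled.
#'
#' @param seq a single sequence.
#' @param window window size in bp (>= 2).
#' @param step step size in bp (>= 1).
#' @return a `rip_profile` data.frame with columns `start`, `end`
#'   (0-based half-open), `product_index`, `substrate_index`,
#'   `composite_index`; window and step recorded as attributes.
#' @export
rip_indices <- function(seq, window = 1000L, step = 500L) {
  seq <- toupper(as.character(seq))
  stopifnot(length(seq) == 1L)
  if (window < 2L) stop("window must be at least 2 bp")
  if (step < 1L) stop("step must be at least 1 bp")
  L <- nchar(seq)
  if (L < 2L) stop("sequence must be at least 2 bp")
  starts <- if (window > L) 0L else {
    as.integer(seq(0L, L - window, by = step))
  }
  ends <- as.integer(pmin(starts + window, L))
  rows <- t(vapply(seq_along(starts), function(i) {
    .rip_window_indices(dinucleotide_counts(
      substr(seq, starts[i] + 1L, ends[i])))
  }, numeric(3)))
  out <- data.frame(start = starts, end = ends, rows)
  attr(out, "window") <- as.integer(min(window, L))
  attr(out, "step") <- as.integer(step)
  class(out) <- c("rip_profile", "data.frame")
  out
}

#' Flag RIP-like windows
#'
#' Applies the conventional heuristics (product index above
#' `product_min` and substrate index below `substrate_max`) as an
#' annotation column; thresholds are exposed rather than baked in, since
#' RIP calling conventions vary between studies.
#'
#' @param profile a `rip_profile` from [rip_indices()].
#' @param product_min product-index threshold.
#' @param substrate_max substrate-index threshold.
#' @return the profile with a logical `rip_like` column (NA where either
#'   index is undefined).
#' @export
flag_rip <- function(profile, product_min = 1.1, substrate_max = 0.9) {
  stopifnot(inherits(profile, "rip_profile"))
  profile$rip_like <- profile$product_index > product_min &
    profile$substrate_index < substrate_max
  profile
}

#' Apply RIP-type mutations to a sequence
#'
#' Mutates a chosen fraction of eligible sites: `C` in CpA context becomes
#' `T`, and `G` in TpG context becomes `A` (the same transition seen from
#' the other strand).  Used to build positive controls for the profiler.
#'
#' @param seq a single sequence.
#' @param fraction fraction of eligible sites to mutate, in `[0, 1]`.
#' @param seed integer seed.
#' @return list with `seq` (mutated sequence) and `n_mutated`.
#' @export
rip_mutate <- function(seq, fraction = 0.3, seed = 1L) {
  seq <- toupper(as.character(seq))
  stopifnot(length(seq) == 1L)
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  set.seed(as.integer(seed))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(chars)
  if (L < 2L) stop("sequence must be at least 2 bp")
  ca <- which(chars[-L] == "C" & chars[-1L] == "A")        # mutate the C
  tg <- which(chars[-L] == "T" & chars[-1L] == "G") + 1L   # mutate the G
  eligible <- sort(unique(c(ca, tg)))
  n_mut <- round(fraction * length(eligible))
  pick <- if (n_mut > 0) sort(sample(eligible, n_mut)) else integer(0)
  chars[pick] <- ifelse(chars[pick] == "C", "T", "A")
  list(seq = paste(chars, collapse = ""), n_mutated = length(pick))
}
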