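# Synthetic genome pairs emulating the statistical structure of deep
# inter-species comparisons: orthologous genes diverged by per-site
# substitution on a neutral background, plus a recently transferred
# near-identical multi-gene element, reads, and haploid cross progeny.

.rand_seq <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

.BASES <- c("A", "C", "G", "T")

# uniform integers on [lo, hi]; safe when lo == hi (unlike sample())
.runif_int <- function(lo, hi, n) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

# substitute the given positions, each to a uniformly drawn different base
.substitute_at <- function(chars, idx) {
  if (length(idx) == 0L) return(chars)
  code <- match(chars[idx], .BASES) - 1L
  code <- (code + sample.int(3L, length(idx), replace = TRUE)) %% 4L
  chars[idx] <- .BASES[code + 1L]
  chars
}

# iid per-site substitution with probability s; returns seq + n substituted
.mutate_iid <- function(seq, s) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- which(stats::runif(length(chars)) < s)
  list(seq = paste(.substitute_at(chars, idx), collapse = ""),
       n_sub = length(idx))
}

# exact-count substitution: realized identity is round(L*(1-identity))/L
.mutate_to_identity <- function(seq, identity) {
  L <- nchar(seq)
  n_mut <- round(L * (1 - identity))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- sample.int(L, n_mut)
  list(seq = paste(.substitute_at(chars, idx), collapse = ""),
       n_sub = n_mut)
}

#' Configuration of a synthetic background genome pair
#'
#' Genome B carries an ortholog of every genome-A gene, diverged by
#' independent per-site substitution with probability `s`, so the expected
#' per-gene ungapped identity is exactly `100 * (1 - s)` percent.
#' Intergenic spacers are drawn independently for the two genomes
#' (emulating unalignable intergenic divergence).
#'
#' @param n_background_genes number of orthologous background genes.
#' @param gene_length_range `(min, max)` gene length in bp; min must exceed
#'   100 bp so the candidate length filter is exercisable.
#' @param intergenic_length_range `(min, max)` spacer length in bp.
#' @param s per-site substitution probability in `[0, 1)`.
#' @param gc_content GC fraction of generated sequence.
#' @param seed integer seed; identical seeds reproduce identical pairs.
#' @return a `synthetic_pair_config` list.
#' @export
synthetic_pair_config <- function(n_background_genes = 200L,
                                  gene_length_range = c(1000L, 1800L),
                                  intergenic_length_range = c(800L, 1600L),
                                  s = 0.278,
                                  gc_content = 0.5,
                                  seed = 1L) {
  if (s < 0 || s >= 1) stop("substitution probability s must be in [0, 1)")
  if (length(gene_length_range) != 2L ||
      gene_length_range[1] > gene_length_range[2] ||
      gene_length_range[1] <= 100L) {
    stop("gene_length_range must be (min, max) with min > 100 bp")
  }
  if (length(intergenic_length_range) != 2L ||
      intergenic_length_range[1] > intergenic_length_range[2] ||
      intergenic_length_range[1] < 1L) {
    stop("degenerate intergenic_length_range")
  }
  if (gc_content <= 0 || gc_content >= 1) stop("gc_content must be in (0,1)")
  if (n_background_genes < 1L) stop("need at least one background gene")
  structure(list(
    n_background_genes = as.integer(n_background_genes),
    gene_length_range = as.integer(gene_length_range),
    intergenic_length_range = as.integer(intergenic_length_range),
    s = s, gc_content = gc_content, seed = as.integer(seed)
  ), class = "synthetic_pair_config")
}

#' Generate a diverged orthologous genome pair
#'
#' Genome A carries `n_background_genes` genes separated by random
#' intergenic spacers; genome B carries an ortholog of each, mutated by
#' independent per-site substitution with probability `s`.  The truth table
#' records every ortholog pair with its realized identity.
#'
#' @param config a [synthetic_pair_config()].
#' @return a `genome_pair` list with elements `genome_a`, `genes_a`,
#'   `genome_b`, `genes_b` (annotations in the internal 0-based half-open
#'   convention), `truth`, `elements` (empty until [plant_element()]) and
#'   `config`.
#' @export
generate_background_pair <- function(config) {
  stopifnot(inherits(config, "synthetic_pair_config"))
  set.seed(config$seed)
  n <- config$n_background_genes
  glr <- config$gene_length_range
  ilr <- config$intergenic_length_range
  gc <- config$gc_content

  gene_len <- .runif_int(glr[1], glr[2], n)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  inter_a <- .runif_int(ilr[1], ilr[2], n + 1L)
  inter_b <- .runif_int(ilr[1], ilr[2], n + 1L)

  parts_a <- character(2L * n + 1L)
  parts_b <- character(2L * n + 1L)
  start_a <- integer(n); start_b <- integer(n)
  realized <- numeric(n)
  pos_a <- 0L; pos_b <- 0L
  for (i in seq_len(n)) {
    sp_a <- .rand_seq(inter_a[i], gc)
    sp_b <- .rand_seq(inter_b[i], gc)
    g <- .rand_seq(gene_len[i], gc)
    mut <- .mutate_iid(g, config$s)
    parts_a[2L * i - 1L] <- sp_a
    parts_a[2L * i] <- g
    parts_b[2L * i - 1L] <- sp_b
    parts_b[2L * i] <- mut$seq
    pos_a <- pos_a + inter_a[i]; start_a[i] <- pos_a; pos_a <- pos_a + gene_len[i]
    pos_b <- pos_b + inter_b[i]; start_b[i] <- pos_b; pos_b <- pos_b + gene_len[i]
    realized[i] <- 1 - mut$n_sub / gene_len[i]
  }
  parts_a[2L * n + 1L] <- .rand_seq(inter_a[n + 1L], gc)
  parts_b[2L * n + 1L] <- .rand_seq(inter_b[n + 1L], gc)

  ids <- sprintf("bg%04d", seq_len(n))
  genes_a <- data.frame(gene_id = ids, contig_id = "contig_A",
                        start = start_a, end = start_a + gene_len,
                        strand = strand, stringsAsFactors = FALSE)
  genes_b <- data.frame(gene_id = ids, contig_id = "contig_B",
                        start = start_b, end = start_b + gene_len,
                        strand = strand, stringsAsFactors = FALSE)
  truth <- data.frame(
    gene_id = ids, length = gene_len, strand = strand,
    expected_identity = 100 * (1 - config$s),
    realized_identity = 100 * realized,
    is_element = FALSE, element_id = NA_character_,
    planted_identity = NA_real_, stringsAsFactors = FALSE
  )
  structure(list(
    genome_a = as_genome(stats::setNames(paste(parts_a, collapse = ""), "contig_A")),
    genes_a = genes_a,
    genome_b = as_genome(stats::setNames(paste(parts_b, collapse = ""), "contig_B")),
    genes_b = genes_b,
    truth = truth, elements = list(), config = config
  ), class = "genome_pair")
}

#' @export
print.genome_pair <- function(x, ...) {
  cat(sprintf("<genome_pair> %d background genes | A: %d bp, B: %d bp | s = %.3f\n",
              x$config$n_background_genes,
              Biostrings::width(x$genome_a)[1], Biostrings::width(x$genome_b)[1],
              x$config$s))
  if (length(x$elements) > 0L) {
    for (el in x$elements) {
      cat(sprintf("  element %s: %d cargo genes, %d bp, planted in %s\n",
                  el$element_id, nrow(el$spec$cargo), el$length, el$where))
    }
  }
  invisible(x)
}

#' Specification of a transferable multi-gene element
#'
#' The element consists of the captain gene first (the tyrosine-recombinase
#' backbone of a *Starship*), followed by the cargo genes in order, with a
#' fixed spacer between consecutive genes.
#'
#' @param element_id element name.
#' @param cargo data.frame with columns `gene_id`, `length` (bp) and
#'   `planted_identity` (fraction in (0, 1]) -- the identity at which each
#'   cargo copy in genome B is planted.
#' @param captain_length captain gene length in bp.
#' @param spacer fixed spacer between element genes in bp.
#' @param backbone_identity identity at which the captain and spacers are
#'   copied between genomes.
#' @param insertion_site_a,insertion_site_b 0-based insertion offsets into
#'   the two genomes; `NULL` picks the midpoint of the central intergenic
#'   gap automatically.
#' @return an `element_spec` list.
#' @export
element_spec <- function(element_id, cargo, captain_length = 2000L,
                         spacer = 200L, backbone_identity = 0.99,
                         insertion_site_a = NULL, insertion_site_b = NULL) {
  stopifnot(is.data.frame(cargo),
            all(c("gene_id", "length", "planted_identity") %in% names(cargo)))
  if (any(cargo$planted_identity <= 0 | cargo$planted_identity > 1)) {
    stop("planted_identity must be in (0, 1]")
  }
  if (anyDuplicated(cargo$gene_id)) stop("duplicate cargo gene ids")
  structure(list(
    element_id = element_id, cargo = cargo,
    captain_length = as.integer(captain_length), spacer = as.integer(spacer),
    backbone_identity = backbone_identity,
    insertion_site_a = insertion_site_a, insertion_site_b = insertion_site_b
  ), class = "element_spec")
}

# total element length: captain + per-cargo (spacer + gene)
.element_length <- function(spec) {
  spec$captain_length + sum(spec$spacer + spec$cargo$length)
}

# midpoint of the intergenic gap following the middle gene
.auto_insertion_site <- function(genes) {
  n <- nrow(genes)
  k <- max(1L, n %/% 2L)
  if (k >= n) return(genes$end[n] + 10L)
  as.integer((genes$end[k] + genes$start[k + 1L]) %/% 2L)
}

.check_intergenic <- function(site, genes, genome_len) {
  if (site < 0L || site > genome_len) stop("insertion site outside genome")
  inside <- genes$start < site & site < genes$end
  if (any(inside)) {
    stop("insertion site ", site, " falls inside gene ",
         genes$gene_id[which(inside)[1]])
  }
  invisible(site)
}

#' Plant a near-identical element into a genome pair
#'
#' Inserts the element into intergenic space of genome A and (by default)
#' genome B, emulating the donor/recipient state after a recent horizontal
#' transfer: near-identical element DNA sitting on a deeply diverged
#' background.  Each cargo copy in genome B is mutated to its
#' `planted_identity` by an exact substitution count, so realized cargo
#' identities are deterministic.  Cargo genes are appended to the
#' annotations and flagged in the truth table; the captain and spacers are
#' element backbone and are not annotated as genes.
#'
#' @param pair a `genome_pair` from [generate_background_pair()].
#' @param spec an [element_spec()].
#' @param seed integer seed for element sequence and planted mutations.
#' @param where `"both"` (default), `"A"` or `"B"`: which genome(s)
#'   receive the element.
#' @return the modified `genome_pair`; `pair$elements[[element_id]]` records
#'   the element intervals per genome.
#' @export
plant_element <- function(pair, spec, seed = 1L, where = c("both", "A", "B")) {
  stopifnot(inherits(pair, "genome_pair"), inherits(spec, "element_spec"))
  where <- match.arg(where)
  set.seed(as.integer(seed))
  gc <- pair$config$gc_content
  nc <- nrow(spec$cargo)

  captain_a <- .rand_seq(spec$captain_length, gc)
  spacers_a <- vapply(seq_len(nc), function(i) .rand_seq(spec$spacer, gc),
                      character(1))
  cargo_a <- vapply(spec$cargo$length, .rand_seq, character(1), gc = gc)

  captain_b <- .mutate_to_identity(captain_a, spec$backbone_identity)$seq
  spacers_b <- vapply(spacers_a, function(x) {
    .mutate_to_identity(x, spec$backbone_identity)$seq
  }, character(1), USE.NAMES = FALSE)
  cargo_mut <- lapply(seq_len(nc), function(i) {
    .mutate_to_identity(cargo_a[i], spec$cargo$planted_identity[i])
  })
  cargo_b <- vapply(cargo_mut, `[[`, character(1), "seq")
  realized <- 1 - vapply(cargo_mut, `[[`, numeric(1), "n_sub") / spec$cargo$length

  elem_a <- paste0(captain_a, paste0(spacers_a, cargo_a, collapse = ""))
  elem_b <- paste0(captain_b, paste0(spacers_b, cargo_b, collapse = ""))
  elen <- .element_length(spec)
  stopifnot(nchar(elem_a) == elen, nchar(elem_b) == elen)

  # cargo offsets within the element
  off <- spec$captain_length +
    cumsum(rep(spec$spacer, nc)) +
    c(0L, cumsum(spec$cargo$length))[seq_len(nc)]
  cargo_ids <- spec$cargo$gene_id

  insert_into <- function(genome, genes, site, elem, contig) {
    gseq <- as.character(genome)[[1]]
    site <- .check_intergenic(site, genes, nchar(gseq))
    new_seq <- paste0(substr(gseq, 1L, site), elem,
                      substr(gseq, site + 1L, nchar(gseq)))
    shift <- genes$start >= site
    genes$start[shift] <- genes$start[shift] + elen
    genes$end[shift] <- genes$end[shift] + elen
    cargo_ann <- data.frame(
      gene_id = cargo_ids, contig_id = contig,
      start = site + off, end = site + off + spec$cargo$length,
      strand = "+", stringsAsFactors = FALSE
    )
    genes <- rbind(genes, cargo_ann)
    genes <- genes[order(genes$start), , drop = FALSE]
    rownames(genes) <- NULL
    list(genome = as_genome(stats::setNames(new_seq, contig)), genes = genes,
         interval = c(site, site + elen))
  }

  interval_a <- NULL; interval_b <- NULL
  if (where %in% c("both", "A")) {
    site_a <- if (is.null(spec$insertion_site_a)) {
      .auto_insertion_site(pair$genes_a)
    } else as.integer(spec$insertion_site_a)
    ins <- insert_into(pair$genome_a, pair$genes_a, site_a, elem_a, "contig_A")
    pair$genome_a <- ins$genome; pair$genes_a <- ins$genes
    interval_a <- ins$interval
  }
  if (where %in% c("both", "B")) {
    site_b <- if (is.null(spec$insertion_site_b)) {
      .auto_insertion_site(pair$genes_b)
    } else as.integer(spec$insertion_site_b)
    ins <- insert_into(pair$genome_b, pair$genes_b, site_b, elem_b, "contig_B")
    pair$genome_b <- ins$genome; pair$genes_b <- ins$genes
    interval_b <- ins$interval
  }

  pair$truth <- rbind(pair$truth, data.frame(
    gene_id = cargo_ids, length = spec$cargo$length, strand = "+",
    expected_identity = 100 * spec$cargo$planted_identity,
    realized_identity = 100 * realized,
    is_element = TRUE, element_id = spec$element_id,
    planted_identity = spec$cargo$planted_identity,
    stringsAsFactors = FALSE
  ))
  pair$elements[[spec$element_id]] <- list(
    element_id = spec$element_id, spec = spec, length = elen, where = where,
    interval_a = interval_a, interval_b = interval_b,
    sequence_a = elem_a, sequence_b = elem_b
  )
  pair
}

#' Simulate shotgun reads from a genome
#'
#' Read count is `ceiling(depth * genome_length / read_len)`; start
#' positions are uniform over the valid range; strands are random; per-base
#' errors are independent substitutions with probability `error_rate`.
#'
#' @param genome a single sequence (anything [as_genome()] accepts).
#' @param depth fold coverage (> 0).
#' @param read_len read length in bp; must not exceed the genome length.
#' @param error_rate per-base substitution error probability.
#' @param seed integer seed.
#' @return list with `reads` (a named [Biostrings::DNAStringSet]) and
#'   `truth` (data.frame of true `start` and `strand` per read).
#' @export
simulate_reads <- function(genome, depth, read_len = 150L, error_rate = 0,
                           seed = 1L) {
  genome <- as_genome(genome)
  stopifnot(length(genome) == 1L)
  glen <- Biostrings::width(genome)[1]
  read_len <- as.integer(read_len)
  if (read_len > glen) stop("read_len exceeds genome length")
  if (depth <= 0) stop("depth must be positive")
  set.seed(as.integer(seed))
  n_reads <- as.integer(ceiling(depth * glen / read_len))
  starts <- sample.int(glen - read_len + 1L, n_reads, replace = TRUE) - 1L
  strands <- sample(c("+", "-"), n_reads, replace = TRUE)
  gseq <- as.character(genome)[[1]]
  seqs <- substring(gseq, starts + 1L, starts + read_len)
  if (error_rate > 0) {
    seqs <- vapply(seqs, function(s) .mutate_iid(s, error_rate)$seq,
                   character(1), USE.NAMES = FALSE)
  }
  rc <- strands == "-"
  seqs[rc] <- vapply(seqs[rc], cpp_revcomp, character(1), USE.NAMES = FALSE)
  ids <- sprintf("read%06d", seq_len(n_reads))
  list(
    reads = as_genome(stats::setNames(seqs, ids)),
    truth = data.frame(read_id = ids, start = starts, strand = strands,
                       stringsAsFactors = FALSE)
  )
}

#' Haploid cross model
#'
#' Each locus is inherited independently with probability 0.5 (haploid
#' cross of unlinked loci between a parent carrying every locus and a
#' parent carrying none).  The default two-locus model mirrors an
#' element-borne resistance cluster plus an unlinked background locus: the
#' element confers growth at formalin 2 and 5 ul/ml, the background locus
#' at 2 ul/ml only, so growth at the higher concentration cosegregates
#' perfectly with the element.
#'
#' @param loci named list; each entry is the vector of concentrations at
#'   which that locus confers growth.
#' @return a `cross_model` list.
#' @export
cross_model <- function(loci = list(element = c(2, 5), background = 2)) {
  if (length(loci) > 0 && is.null(names(loci))) stop("loci must be named")
  structure(list(loci = loci, inheritance_prob = 0.5), class = "cross_model")
}

#' Simulate progeny of a haploid cross
#'
#' @param model a [cross_model()].
#' @param n_progeny number of progeny (> 0).
#' @param seed integer seed.
#' @return data.frame with one row per progeny: a 0/1 genotype column
#'   `locus_<name>` per locus and a logical `grows_at_<c>` column per
#'   tested concentration.
#' @export
simulate_cross <- function(model, n_progeny, seed = 1L) {
  stopifnot(inherits(model, "cross_model"))
  if (n_progeny <= 0) stop("n_progeny must be positive")
  set.seed(as.integer(seed))
  n <- as.integer(n_progeny)
  concs <- sort(unique(unlist(model$loci)))
  out <- data.frame(progeny_id = sprintf("progeny%03d", seq_len(n)),
                    stringsAsFactors = FALSE)
  geno <- matrix(0L, nrow = n, ncol = length(model$loci))
  for (j in seq_along(model$loci)) {
    geno[, j] <- stats::rbinom(n, 1L, model$inheritance_prob)
    out[[paste0("locus_", names(model$loci)[j])]] <- geno[, j]
  }
  for (cc in concs) {
    confers <- vapply(model$loci, function(v) cc %in% v, logical(1))
    grows <- if (any(confers)) {
      rowSums(geno[, confers, drop = FALSE]) > 0L
    } else rep(FALSE, n)
    out[[paste0("grows_at_", cc)]] <- grows
  }
  if (length(concs) == 0L) out$grows <- rep(FALSE, n)
  out
}
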