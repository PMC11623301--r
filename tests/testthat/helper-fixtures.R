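# Shared test helpers: small generated pairs, a minimal hit-table
# constructor, a brute-force neighborhood oracle, and memoized full-size
# fixture runs reused across the acceptance blocks.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

small_pair <- function(n = 30L, s = 0.25, seed = 1L,
                       gene_len = c(300L, 500L),
                       intergenic = c(150L, 300L)) {
  generate_background_pair(synthetic_pair_config(
    n_background_genes = n, gene_length_range = gene_len,
    intergenic_length_range = intergenic, s = s, seed = seed
  ))
}

# minimal classified-ready hit table from bare alignment stats
make_hit_table <- function(align_len, pct_identity,
                           gene_start = NULL, gene_end = NULL,
                           contig_id = "contig_A") {
  n <- length(align_len)
  if (is.null(gene_start)) gene_start <- seq_len(n) * 10000L
  if (is.null(gene_end)) gene_end <- gene_start + 1000L
  has_hit <- !is.na(pct_identity)
  tab <- data.frame(
    gene_id = sprintf("g%02d", seq_len(n)), contig_id = contig_id,
    gene_start = gene_start, gene_end = gene_end, gene_strand = "+",
    has_hit = has_hit, subject_contig = ifelse(has_hit, "contig_B", NA),
    hit_strand = ifelse(has_hit, "+", NA),
    subject_start = ifelse(has_hit, 0L, NA),
    subject_end = ifelse(has_hit, align_len, NA),
    align_len = align_len, matches = NA_integer_, gaps = 0L,
    score = align_len, pct_identity = pct_identity,
    flag = ifelse(has_hit, "unset", "no_hit"),
    stringsAsFactors = FALSE
  )
  structure(tab, params = best_hit_params(),
            class = c("hit_table", "data.frame"))
}

# O(n^2) single-linkage oracle: connected components of the
# nearest-edge-gap adjacency graph, per contig
brute_neighborhoods <- function(genes, min_genes = 3L, max_gap = 25000L) {
  out <- list()
  for (ct in unique(genes$contig_id)) {
    g <- genes[genes$contig_id == ct, , drop = FALSE]
    n <- nrow(g)
    d <- outer(seq_len(n), seq_len(n), function(i, j) {
      pmax(0L, pmax(g$start[i], g$start[j]) - pmin(g$end[i], g$end[j]))
    })
    adj <- d <= max_gap
    gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(gr)$membership
    for (cid in unique(comp)) {
      m <- g[comp == cid, , drop = FALSE]
      if (length(unique(m$gene_id)) < min_genes) next
      out[[length(out) + 1L]] <- list(
        contig_id = ct,
        member_gene_ids = sort(m$gene_id),
        start = min(m$start), end = max(m$end)
      )
    }
  }
  ord <- order(vapply(out, `[[`, character(1), "contig_id"),
               vapply(out, `[[`, numeric(1), "start"))
  out[ord]
}

# random (genome, planted gene) instance for oracle-vs-search comparison
plant_instance <- function(gene_len, genome_len, div) {
  gene <- rand_dna(gene_len)
  chars <- strsplit(gene, "", fixed = TRUE)[[1]]
  idx <- which(runif(gene_len) < div)
  if (length(idx) > 0) {
    code <- match(chars[idx], c("A", "C", "G", "T")) - 1L
    code <- (code + sample.int(3L, length(idx), replace = TRUE)) %% 4L
    chars[idx] <- c("A", "C", "G", "T")[code + 1L]
  }
  pos <- sample.int(genome_len - gene_len + 1L, 1L)
  flank_l <- rand_dna(pos - 1L)
  flank_r <- rand_dna(genome_len - gene_len - pos + 1L)
  list(gene = gene,
       genome = paste0(flank_l, paste(chars, collapse = ""), flank_r))
}

# memoized full-size fixture demo runs shared by the acceptance blocks
.acc_env <- new.env(parent = emptyenv())

acc_demo <- function(name) {
  key <- paste0("demo_", name)
  if (!exists(key, envir = .acc_env)) {
    assign(key, run_demo(name), envir = .acc_env)
  }
  get(key, envir = .acc_env)
}
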