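# -- fixture builders ---------------------------------------------------

# one alignment row with sensible defaults; override any field
aln_row <- function(query_id = "C1", subject_id = "H1", pct_identity = 35,
                    q_start = 1L, q_end = 90L, s_start = 1L, s_end = 90L,
                    q_len = 100L, s_len = 100L, bitscore = 150,
                    evalue = 1e-30, aln_len = NULL) {
  if (is.null(aln_len)) aln_len <- max(q_end - q_start, s_end - s_start) + 1L
  tibble::tibble(
    query_id = query_id, subject_id = subject_id,
    pct_identity = pct_identity, aln_len = as.integer(aln_len),
    mismatches = 0L, gap_opens = 0L,
    q_start = as.integer(q_start), q_end = as.integer(q_end),
    s_start = as.integer(s_start), s_end = as.integer(s_end),
    evalue = evalue, bitscore = bitscore,
    q_len = as.integer(q_len), s_len = as.integer(s_len)
  )
}

aln_tbl <- function(...) dplyr::bind_rows(...)

feat_row <- function(cluster_id, feature_index, genome_id = "g1",
                     contig_id = "g1_c1", strand = "+") {
  tibble::tibble(genome_id = genome_id, contig_id = contig_id,
                 strand = strand, feature_index = as.integer(feature_index),
                 cluster_id = cluster_id)
}

small_params <- function(seed = 42, ...) {
  generator_params(n_genomes = 20L, n_human_proteins = 30L, seed = seed, ...)
}

# neighborhood member-set keys for comparing calls against planted truth
split_call_keys <- function(members) {
  if (nrow(members) == 0L) return(character())
  sets <- split(members$query_id, members$neighborhood)
  meta <- members[!duplicated(members$neighborhood), ]
  meta <- meta[order(meta$neighborhood), ]
  paste(meta$subject_id, meta$genome_id,
        vapply(sets[order(names(sets))],
               function(x) paste(sort(unique(x)), collapse = ","), ""))
}

split_truth_keys <- function(truth_split) {
  if (nrow(truth_split) == 0L) return(character())
  sets <- split(truth_split$cluster_id, truth_split$neighborhood_id)
  meta <- truth_split[!duplicated(truth_split$neighborhood_id), ]
  meta <- meta[order(meta$neighborhood_id), ]
  paste(meta$subject_id, meta$genome_id,
        vapply(sets[order(names(sets))],
               function(x) paste(sort(unique(x)), collapse = ","), ""))
}

# distance of every tip from the root, by a root-down edge sweep
node_root_depths <- function(tree) {
  nt <- length(tree$tip.label)
  tree <- ape::reorder.phylo(tree, "cladewise")
  depth <- numeric(max(tree$edge))
  for (i in seq_len(nrow(tree$edge))) {
    depth[tree$edge[i, 2]] <- depth[tree$edge[i, 1]] + tree$edge.length[i]
  }
  stats::setNames(depth[seq_len(nt)], tree$tip.label)
}

# -- independent oracles -------------------------------------------------

# position-bitmask joint coverage
oracle_joint_coverage <- function(intervals, s_len) {
  covered <- logical(s_len)
  for (i in seq_len(nrow(intervals))) {
    covered[intervals[i, 1]:intervals[i, 2]] <- TRUE
  }
  mean(covered)
}

# brute-force transitive closure of the neighborhood relation
oracle_components <- function(contig, strand, idx, max_gap) {
  n <- length(idx)
  adj <- outer(seq_len(n), seq_len(n), function(i, j) {
    contig[i] == contig[j] & strand[i] == strand[j] &
      abs(idx[i] - idx[j]) <= max_gap
  })
  reach <- adj | diag(n)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      comp[reach[i, ]] <- cur
    }
  }
  comp
}

# one-sided hypergeometric upper tail by direct log-binomial summation
oracle_hyper_p <- function(a, study_total, bg_count, bg_total) {
  K <- bg_count
  n <- study_total
  N <- bg_total
  xs <- a:min(K, n)
  xs <- xs[n - xs <= N - K]
  if (length(xs) == 0L) return(0)
  sum(exp(lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)))
}

# ancestor closure by plain BFS over the parent lists
oracle_ancestors <- function(ontology, term) {
  seen <- character()
  queue <- term
  while (length(queue) > 0L) {
    t <- queue[[1]]
    queue <- queue[-1]
    if (t %in% seen) next
    seen <- c(seen, t)
    queue <- c(queue, ontology$parents[[t]])
  }
  sort(seen)
}

# a random DAG over `n` terms: edges only from higher to lower index
random_dag <- function(n, p = 0.3) {
  edges <- NULL
  for (child in seq(2L, n)) {
    parents <- which(stats::runif(child - 1L) < p)
    if (length(parents) == 0L) parents <- sample.int(child - 1L, 1L)
    edges <- rbind(edges, cbind(paste0("T", child), paste0("T", parents)))
  }
  ontology_graph(tibble::tibble(child = edges[, 1], parent = edges[, 2]),
                 tibble::tibble(term = paste0("T", seq_len(n)),
                                namespace = "biological_process",
                                name = paste0("term ", seq_len(n))))
}
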