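#' Parameters for the synthetic homology benchmark generator
#'
#' The generator emulates the statistical structure the detection
#' pipeline assumes: an alignment table between microbial protein
#' clusters and human proteins with a stated identity distribution,
#' planted full-length homologs, planted split homologs (a human
#' protein's span partitioned over 2-3 adjacent same-strand genes),
#' near-identical contaminant alignments, and five labeled decoy
#' configurations that each violate exactly one split filter.
#'
#' Genuine homolog identities are drawn from a Normal truncated to
#' `[10, 50]` percent; the parent SD is inflated so that the moments of
#' the *truncated* distribution equal (`identity_mean`, `identity_sd`),
#' keeping the nominal parameters interpretable. Contaminant identities
#' are truncated to `[90, 100]`.
#'
#' @param n_genomes Number of microbial genomes (each its own species).
#' @param n_human_proteins Number of human proteins.
#' @param human_len_range Range of human protein lengths (aa). The
#'   lower bound must leave room for three fragments of >= 85 aa.
#' @param p_full Probability that a given (human, genome) cell carries a
#'   planted full-length homolog.
#' @param p_split Probability that a given (human, genome) cell carries
#'   a planted split homolog.
#' @param n_fragments Allowed fragment counts for split plants.
#' @param identity_mean,identity_sd Moments (percent) of the genuine
#'   identity distribution.
#' @param contaminant_rate Expected number of contaminant alignments
#'   per human protein.
#' @param decoy_rates Named numeric vector of per-class decoy rates
#'   (expected instances per human protein) for classes `strand_flip`,
#'   `contig_split`, `gap4`, `undercoverage`, `individual_cover`.
#' @param seed Master seed; every output stream derives its own stream
#'   from it, so equal seeds give byte-identical fixture bundles.
#' @return A `gutsplit_sim_params` list.
#' @export
generator_params <- function(n_genomes = 200L,
                             n_human_proteins = 300L,
                             human_len_range = c(350L, 1200L),
                             p_full = 0.3,
                             p_split = 0.2,
                             n_fragments = 2:3,
                             identity_mean = 30,
                             identity_sd = 7.27,
                             contaminant_rate = 0,
                             decoy_rates = c(strand_flip = 0, contig_split = 0,
                                             gap4 = 0, undercoverage = 0,
                                             individual_cover = 0),
                             seed = 1L) {
  stopifnot(
    n_genomes >= 1, n_human_proteins >= 1,
    length(human_len_range) == 2L, human_len_range[1] >= 350,
    human_len_range[1] <= human_len_range[2],
    p_full >= 0, p_full <= 1, p_split >= 0, p_split <= 1,
    all(n_fragments %in% 2:3),
    identity_sd >= 0, identity_mean - 3 * identity_sd >= 0,
    contaminant_rate >= 0, all(decoy_rates >= 0), seed == as.integer(seed)
  )
  classes <- c("strand_flip", "contig_split", "gap4", "undercoverage",
               "individual_cover")
  full_rates <- stats::setNames(rep(0, length(classes)), classes)
  full_rates[names(decoy_rates)] <- decoy_rates
  structure(
    list(
      n_genomes = as.integer(n_genomes),
      n_human_proteins = as.integer(n_human_proteins),
      human_len_range = as.integer(human_len_range),
      p_full = p_full, p_split = p_split,
      n_fragments = as.integer(n_fragments),
      identity_mean = identity_mean, identity_sd = identity_sd,
      contaminant_rate = contaminant_rate,
      decoy_rates = full_rates,
      seed = as.integer(seed)
    ),
    class = "gutsplit_sim_params"
  )
}

# independent sub-seed per output stream, below 2^31
sub_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + k * 7919) %% 2147483629
}

# parent SD such that a Normal truncated symmetrically at mean +/- half
# has the target SD
trunc_parent_sd <- function(target_sd, half) {
  if (target_sd == 0) return(0)
  f <- function(s) {
    a <- half / s
    s * sqrt(1 - 2 * a * stats::dnorm(a) / (2 * stats::pnorm(a) - 1)) - target_sd
  }
  stats::uniroot(f, c(target_sd, 3 * target_sd + half))$root
}

# truncated-normal sample by rejection
rtrunc_norm <- function(n, mean, parent_sd, lower, upper) {
  if (n == 0L) return(numeric())
  if (parent_sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, parent_sd)
  bad <- which(out < lower | out > upper)
  while (length(bad) > 0L) {
    out[bad] <- stats::rnorm(length(bad), mean, parent_sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
  }
  out
}

# partition `total` residues into k integer parts, each >= min_part
partition_span <- function(total, k, min_part = 85L) {
  stopifnot(total >= k * min_part)
  w <- stats::runif(k, 1, 2)
  extra <- total - k * min_part
  parts <- min_part + floor(extra * w / sum(w))
  parts[1] <- parts[1] + (total - sum(parts))
  parts
}

#' Generate a synthetic homology benchmark with known ground truth
#'
#' See [generator_params()] for what is emulated. Planted full-length
#' homologs satisfy the microbe- and human-coverage filters with
#' margin; planted split homologs tile 78-92% of the human span over
#' adjacent same-strand genes (inter-member gaps at most 3 feature
#' ranks) with every fragment individually below the human-coverage
#' threshold; decoys violate exactly one filter each. Each genome
#' corresponds to one species; the species tree is a random bifurcating
#' tree with exponential branch lengths.
#'
#' @param params A [generator_params()] object.
#' @return A list with `alignments`, `features`, `truth` (list `full`,
#'   `split`, `decoys`), `tree`, `species_map`, `cluster_species`,
#'   `ontology`, `annotations`, `families` and the `params` used.
#' @export
generate_synthetic <- function(params = generator_params()) {
  stopifnot(inherits(params, "gutsplit_sim_params"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })

  n_h <- params$n_human_proteins
  n_g <- params$n_genomes
  humans <- tibble::tibble(
    human_id = sprintf("HUM%04d", seq_len(n_h))
  )
  genomes <- tibble::tibble(
    genome_id = sprintf("GEN%04d", seq_len(n_g)),
    species = sprintf("sp%04d", seq_len(n_g))
  )

  ## ---- layout stream: which cells carry which plants -----------------
  set.seed(sub_seed(params$seed, 1L))
  humans$s_len <- sample(params$human_len_range[1]:params$human_len_range[2],
                         n_h, replace = TRUE)
  cell_h <- rep(seq_len(n_h), times = n_g)
  cell_g <- rep(seq_len(n_g), each = n_h)
  full_cell <- stats::runif(n_h * n_g) < params$p_full
  split_cell <- stats::runif(n_h * n_g) < params$p_split
  used <- full_cell | split_cell
  free_cells <- which(!used)
  draw_cells <- function(n) {
    n <- min(n, length(free_cells))
    if (n == 0L) return(integer())
    picked <- free_cells[seq_len(n)]
    free_cells <<- free_cells[-seq_len(n)]
    picked
  }
  free_cells <- sample(free_cells)
  n_decoys <- round(params$decoy_rates * n_h)
  decoy_cells <- lapply(n_decoys, draw_cells)
  contam_cells <- draw_cells(round(params$contaminant_rate * n_h))

  ## ---- member construction -------------------------------------------
  # full-length plants: one member each
  fidx <- which(full_cell)
  full_units <- tibble::tibble(
    unit = sprintf("F%06d", seq_along(fidx)),
    h = cell_h[fidx], g = cell_g[fidx],
    kind = "full",
    # keep full and split plants of one cell on different contigs
    contig = as.character(ifelse(split_cell[fidx], "c1",
                                 sample(c("c1", "c2"), length(fidx),
                                        replace = TRUE))),
    strand = sample(c("+", "-"), length(fidx), replace = TRUE),
    k = 1L
  )

  sidx <- which(split_cell)
  split_units <- tibble::tibble(
    unit = sprintf("S%06d", seq_along(sidx)),
    h = cell_h[sidx], g = cell_g[sidx],
    kind = "split",
    contig = as.character(ifelse(full_cell[sidx], "c2",
                                 sample(c("c1", "c2"), length(sidx),
                                        replace = TRUE))),
    strand = sample(c("+", "-"), length(sidx), replace = TRUE),
    k = sample(rep(params$n_fragments, 2L), length(sidx), replace = TRUE)
  )

  decoy_units <- dplyr::bind_rows(lapply(names(decoy_cells), function(cls) {
    cells <- decoy_cells[[cls]]
    if (length(cells) == 0L) return(NULL)
    tibble::tibble(
      unit = sprintf("D%s%05d", toupper(substr(cls, 1, 2)), seq_along(cells)),
      h = cell_h[cells], g = cell_g[cells],
      kind = cls,
      contig = sample(c("c1", "c2"), length(cells), replace = TRUE),
      strand = sample(c("+", "-"), length(cells), replace = TRUE),
      k = 2L
    )
  }))
  contam_units <- if (length(contam_cells) > 0L) {
    tibble::tibble(
      unit = sprintf("X%05d", seq_along(contam_cells)),
      h = cell_h[contam_cells], g = cell_g[contam_cells],
      kind = "contaminant",
      contig = sample(c("c1", "c2"), length(contam_cells), replace = TRUE),
      strand = sample(c("+", "-"), length(contam_cells), replace = TRUE),
      k = 1L
    )
  } else {
    NULL
  }

  units <- dplyr::bind_rows(full_units, split_units, decoy_units, contam_units)
  if (nrow(units) == 0L) stop("parameters produce an empty benchmark",
                              call. = FALSE)

  # expand units to members (one member = one gene = one alignment)
  members <- units[rep(seq_len(nrow(units)), units$k), ]
  members$frag <- unlist(lapply(units$k, seq_len))
  members$cluster_id <- sprintf("%s_m%d", members$unit, members$frag)
  members$s_len <- humans$s_len[members$h]

  ## ---- coordinate + identity stream ----------------------------------
  set.seed(sub_seed(params$seed, 2L))
  m <- nrow(members)
  s_span <- integer(m)
  s_start <- integer(m)

  single <- members$kind %in% c("full", "contaminant")
  n_single <- sum(single)
  sp <- ceiling(stats::runif(n_single, 0.75, 0.95) * members$s_len[single])
  s_span[single] <- sp
  s_start[single] <- 1L + floor(stats::runif(n_single) *
                                  (members$s_len[single] - sp + 1))

  # split-like tilings: split plants and the adjacency decoys
  tiled <- members$kind %in% c("split", "strand_flip", "contig_split", "gap4")
  if (any(tiled)) {
    t_units <- unique(members$unit[tiled])
    for (u in t_units) {
      rows <- which(members$unit == u)
      sl <- members$s_len[rows[1]]
      total <- ceiling(stats::runif(1, 0.78, 0.92) * sl)
      parts <- partition_span(total, length(rows))
      a <- 1L + floor(stats::runif(1) * (sl - total + 1))
      ends <- a + cumsum(parts) - 1L
      starts <- c(a, utils::head(ends, -1) + 1L)
      s_start[rows] <- starts
      s_span[rows] <- parts
    }
  }
  under <- members$kind == "undercoverage"
  if (any(under)) {
    for (u in unique(members$unit[under])) {
      rows <- which(members$unit == u)
      sl <- members$s_len[rows[1]]
      total <- ceiling(stats::runif(1, 0.52, 0.60) * sl)
      parts <- partition_span(total, length(rows))
      a <- 1L + floor(stats::runif(1) * (sl - total + 1))
      ends <- a + cumsum(parts) - 1L
      s_start[rows] <- c(a, utils::head(ends, -1) + 1L)
      s_span[rows] <- parts
    }
  }
  indiv <- members$kind == "individual_cover"
  if (any(indiv)) {
    big <- indiv & members$frag == 1L
    small <- indiv & members$frag == 2L
    s_span[big] <- ceiling(0.75 * members$s_len[big])
    s_start[big] <- 1L
    s_span[small] <- ceiling(0.28 * members$s_len[small])
    s_start[small] <- members$s_len[small] - s_span[small] + 1L
  }

  # microbe side: coverage in [0.70, 0.95] of a query at least 85 aa
  mic_cov <- stats::runif(m, 0.70, 0.95)
  q_len <- pmax(85L, as.integer(floor(s_span / mic_cov)))
  q_span <- pmin(q_len, s_span)
  # full plants carry longer queries, still covered >= 3/4
  q_len[single] <- pmax(100L, q_len[single])
  q_span[single] <- pmax(q_span[single], ceiling(0.75 * q_len[single]))
  q_start <- 1L + floor(stats::runif(m) * (q_len - q_span + 1))

  genuine <- members$kind != "contaminant"
  identity <- numeric(m)
  identity[genuine] <- rtrunc_norm(
    sum(genuine), params$identity_mean,
    trunc_parent_sd(params$identity_sd,
                    params$identity_mean - 10),
    10, 2 * params$identity_mean - 10
  )
  identity[!genuine] <- rtrunc_norm(sum(!genuine), 95, trunc_parent_sd(2, 5),
                                    90, 100)

  aln_len <- pmax(q_span, s_span)
  bitscore <- round(aln_len * identity / 25)
  evalue <- 10^(-pmin(180, bitscore / 3))
  mismatches <- as.integer(round(aln_len * (1 - identity / 100)))

  alignments <- tibble::tibble(
    query_id = members$cluster_id,
    subject_id = humans$human_id[members$h],
    pct_identity = round(identity, 1),
    aln_len = as.integer(aln_len),
    mismatches = mismatches,
    gap_opens = 0L,
    q_start = as.integer(q_start),
    q_end = as.integer(q_start + q_span - 1L),
    s_start = as.integer(s_start),
    s_end = as.integer(s_start + s_span - 1L),
    evalue = signif(evalue, 3),
    bitscore = as.numeric(bitscore),
    q_len = as.integer(q_len),
    s_len = as.integer(members$s_len)
  )

  ## ---- feature layout stream ------------------------------------------
  set.seed(sub_seed(params$seed, 3L))
  feat <- members
  # strand flips hit the second member; contig splits move it next door
  flip <- feat$kind == "strand_flip" & feat$frag == 2L
  feat$strand[flip] <- ifelse(feat$strand[flip] == "+", "-", "+")
  move <- feat$kind == "contig_split" & feat$frag == 2L
  feat$contig[move] <- ifelse(feat$contig[move] == "c1", "c2", "c1")

  feat$intra_gap <- ifelse(feat$frag == 1L, NA_integer_,
                           sample(1:3, nrow(feat), replace = TRUE))
  feat$intra_gap[feat$kind == "gap4" & feat$frag == 2L] <- 4L

  feat <- feat[sample.int(nrow(feat)), ]                 # shuffle unit order
  feat <- feat[order(feat$g, feat$contig, match(feat$unit, unique(feat$unit)),
                     feat$frag), ]
  first_on_contig <- feat$frag == 1L | feat$contig != ave_lag(feat$contig)
  step <- ifelse(first_on_contig, 5L + sample(0:3, nrow(feat), replace = TRUE),
                 feat$intra_gap)
  grp <- paste(feat$g, feat$contig)
  feat$feature_index <- as.integer(stats::ave(step, grp, FUN = cumsum))

  features <- tibble::tibble(
    genome_id = genomes$genome_id[feat$g],
    contig_id = paste0(genomes$genome_id[feat$g], "_", feat$contig),
    strand = feat$strand,
    feature_index = feat$feature_index,
    cluster_id = feat$cluster_id
  ) %>%
    dplyr::arrange(.data$genome_id, .data$contig_id, .data$feature_index)

  ## ---- truth ----------------------------------------------------------
  fmap <- stats::setNames(feat$feature_index, feat$cluster_id)
  truth_full <- tibble::tibble(
    subject_id = humans$human_id[full_units$h],
    query_id = paste0(full_units$unit, "_m1"),
    genome_id = genomes$genome_id[full_units$g]
  )
  split_members_truth <- members[members$kind == "split", ]
  truth_split <- tibble::tibble(
    neighborhood_id = split_members_truth$unit,
    subject_id = humans$human_id[split_members_truth$h],
    genome_id = genomes$genome_id[split_members_truth$g],
    contig_id = paste0(genomes$genome_id[split_members_truth$g], "_",
                       split_members_truth$contig),
    strand = split_members_truth$strand,
    cluster_id = split_members_truth$cluster_id,
    feature_index = unname(fmap[split_members_truth$cluster_id])
  )
  decoy_members_truth <- members[
    !members$kind %in% c("full", "split"), ]
  truth_decoys <- tibble::tibble(
    class = decoy_members_truth$kind,
    unit = decoy_members_truth$unit,
    subject_id = humans$human_id[decoy_members_truth$h],
    genome_id = genomes$genome_id[decoy_members_truth$g],
    cluster_id = decoy_members_truth$cluster_id
  )

  ## ---- tree stream ----------------------------------------------------
  set.seed(sub_seed(params$seed, 4L))
  tree <- if (n_g >= 2L) {
    tr <- ape::rtree(n_g, br = stats::rexp)
    tr$tip.label <- sample(genomes$species)
    tr
  } else {
    NULL
  }
  species_map <- genomes
  cluster_species <- dplyr::left_join(features, species_map,
                                      by = "genome_id") %>%
    dplyr::distinct(.data$cluster_id, .data$species)

  ## ---- annotation stream ----------------------------------------------
  set.seed(sub_seed(params$seed, 5L))
  ann <- synth_annotations(humans, full_cell, n_h, n_g)

  list(
    alignments = alignments,
    features = features,
    truth = list(full = truth_full, split = truth_split,
                 decoys = truth_decoys),
    tree = tree,
    species_map = species_map,
    cluster_species = cluster_species,
    ontology = ann$ontology,
    annotations = ann$annotations,
    families = ann$families,
    params = params
  )
}

# previous value within a plain vector (no grouping), "" for the first
ave_lag <- function(x) c("", x[-length(x)])

# small ontology + planted annotation structure: mitochondrial
# localization probability grows with full-homolog frequency, and a
# xenobiotic-process term is enriched among frequently-hit proteins
synth_annotations <- function(humans, full_cell, n_h, n_g) {
  terms <- tibble::tibble(
    term = c("SYN:BP", "SYN:XEN", "SYN:NUC", "SYN:PUR", "SYN:ACOA",
             "SYN:CC", "SYN:MITO", "SYN:CYTO", "SYN:MF", "SYN:OXRED"),
    namespace = c(rep("biological_process", 5),
                  rep("cellular_component", 3),
                  rep("molecular_function", 2)),
    name = c("biological_process", "xenobiotic metabolic process",
             "nucleobase-containing compound metabolic process",
             "purine nucleotide metabolic process",
             "acyl-CoA metabolic process",
             "cellular_component", "mitochondrion", "cytosol",
             "molecular_function", "oxidoreductase activity")
  )
  edges <- tibble::tibble(
    child = c("SYN:XEN", "SYN:NUC", "SYN:PUR", "SYN:ACOA", "SYN:MITO",
              "SYN:CYTO", "SYN:OXRED"),
    parent = c("SYN:BP", "SYN:BP", "SYN:NUC", "SYN:BP", "SYN:CC",
               "SYN:CC", "SYN:MF")
  )
  ontology <- ontology_graph(edges, terms)

  n_full <- rowSums(matrix(full_cell, nrow = n_h))
  q <- rank(n_full, ties.method = "average") / n_h
  is_mito <- stats::runif(n_h) < 0.1 + 0.6 * q
  top <- n_full >= stats::quantile(n_full, 2 / 3)
  is_xen <- stats::runif(n_h) < ifelse(top, 0.7, 0.05)
  is_nuc <- stats::runif(n_h) < 0.3
  annotations <- dplyr::bind_rows(
    tibble::tibble(protein = humans$human_id,
                   term = ifelse(is_mito, "SYN:MITO", "SYN:CYTO")),
    tibble::tibble(protein = humans$human_id[is_xen], term = "SYN:XEN"),
    tibble::tibble(protein = humans$human_id[is_nuc], term = "SYN:PUR")
  ) %>%
    dplyr::left_join(terms[c("term", "namespace")], by = "term")

  class_strings <- c(
    "Aldo/keto reductase family", "UDP-glycosyltransferase family",
    "GST superfamily", "Arylamine N-acetyltransferase family",
    "'GDXG' lipolytic enzyme family", "Cytochrome P450 family",
    "Type-B carboxylesterase/lipase family", "FMO family",
    "Short-chain dehydrogenases/reductases (SDR) family",
    "Quinone oxidoreductase subfamily", "Aldehyde dehydrogenase family",
    "Protein kinase superfamily", "Histone H2A family"
  )
  families <- stats::setNames(
    sample(class_strings, n_h, replace = TRUE,
           prob = c(rep(1, 11), 4, 4)),
    humans$human_id
  )
  list(ontology = ontology, annotations = annotations, families = families)
}

#' Write a synthetic benchmark to disk as a fixture bundle
#'
#' Writes every table in the pipeline's external formats (14-column
#' alignment TSV without header, feature/annotation TSVs with
#' provenance headers, Newick tree) plus a `manifest.tsv` listing each
#' file once with its MD5 checksum and the generator parameters.
#' Re-running with the same parameters reproduces the bundle
#' byte-for-byte.
#'
#' @param sim Output of [generate_synthetic()].
#' @param dir Output directory (created if needed).
#' @return Path of the manifest file, invisibly.
#' @export
write_fixture_bundle <- function(sim, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory ", dir, call. = FALSE)
  }
  p <- function(f) file.path(dir, f)
  utils::write.table(sim$alignments, p("alignments.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  prov <- c(seed = as.character(sim$params$seed))
  write_tsv_prov(sim$features, p("features.tsv"), extra = prov)
  write_tsv_prov(sim$truth$full, p("truth_full.tsv"), extra = prov)
  write_tsv_prov(sim$truth$split, p("truth_split.tsv"), extra = prov)
  write_tsv_prov(sim$truth$decoys, p("truth_decoys.tsv"), extra = prov)
  write_tsv_prov(sim$species_map, p("species_map.tsv"), extra = prov)
  write_tsv_prov(sim$ontology$edges, p("ontology_edges.tsv"), extra = prov)
  write_tsv_prov(sim$ontology$terms, p("ontology_terms.tsv"), extra = prov)
  write_tsv_prov(sim$annotations, p("annotations.tsv"), extra = prov)
  write_tsv_prov(
    tibble::tibble(protein = names(sim$families),
                   family = unname(sim$families)),
    p("families.tsv"), extra = prov
  )
  if (!is.null(sim$tree)) write_newick(sim$tree, p("tree.nwk"))

  files <- sort(setdiff(list.files(dir), "manifest.tsv"))
  manifest <- tibble::tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(dir, files)))
  )
  param_str <- paste(
    sprintf("%s=%s", names(unlist(sim$params)), unlist(sim$params)),
    collapse = ";"
  )
  write_tsv_prov(manifest, p("manifest.tsv"),
                 extra = c(params = param_str,
                           identity_truncation = "genuine=[10,50];contaminant=[90,100]"))
  invisible(p("manifest.tsv"))
}
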