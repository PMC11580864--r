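#' Default xenobiotic enzyme family rules
#'
#' Regular-expression rules that classify a protein-family description
#' string into one of eleven enzyme classes with known roles in human
#' xenobiotic metabolism: aldo-keto reductases (akr),
#' UDP-glucuronosyltransferases (udp), glutathione S-transferases (gst),
#' arylamine N-acetyltransferases (aryl), GDXG-like lipolytic enzymes
#' (gdxg), cytochrome P450s (cyto), type-B carboxylesterases (ester),
#' flavin monooxygenases (flavin), short-chain reductases (sdr), quinone
#' oxidoreductases (quin), and aldehyde dehydrogenases (aldh).
#'
#' @return Tibble with columns `class_code`, `pattern`, in match
#'   priority order.
#' @export
family_rules <- function() {
  tibble::tibble(
    class_code = c("akr", "udp", "gst", "aryl", "gdxg", "cyto", "ester",
                   "flavin", "sdr", "quin", "aldh"),
    pattern = c(
      "Aldo/keto reductase family",
      "UDP-glycosyltransferase family",
      "GST superfamily",
      "Arylamine N-acetyltransferase family",
      "GDXG.{0,2} lipolytic enzyme family",
      "Cytochrome P450 family",
      "Type-B carboxylesterase/lipase family",
      "Flavin monoamine oxidase family|FMO family",
      "Short-chain dehydrogenases/reductases \\(SDR\\)",
      "Quinone oxidoreductase subfamily",
      "Aldehyde dehydrogenase family"
    )
  )
}

#' Classify protein family description strings
#'
#' Applies the family rules in declared order; the first matching rule
#' wins, and strings matching no rule are classified `NA`.
#'
#' @param family_strings Character vector of family description strings.
#' @param rules Rule tibble (`class_code`, `pattern`); defaults to
#'   [family_rules()].
#' @return Character vector of class codes (or `NA`), same length.
#' @export
#' @examples
#' classify_family(c("Aldo/keto reductase family", "Protein kinase superfamily"))
classify_family <- function(family_strings, rules = family_rules()) {
  stopifnot(!anyDuplicated(rules$class_code))
  out <- rep(NA_character_, length(family_strings))
  for (i in seq_len(nrow(rules))) {
    hit <- is.na(out) & !is.na(family_strings) &
      grepl(rules$pattern[i], family_strings)
    out[hit] <- rules$class_code[i]
  }
  out
}

#' Midpoint-root a tree
#'
#' Places the root at the midpoint of the longest tip-to-tip path
#' (via [phangorn::midpoint()]); total branch length is preserved.
#'
#' @param tree An [ape::phylo] tree with branch lengths and at least two
#'   tips.
#' @return The midpoint-rooted tree.
#' @export
midpoint_root <- function(tree) {
  validate_tree(tree)
  if (length(tree$tip.label) < 2L) {
    stop("midpoint rooting needs at least two tips", call. = FALSE)
  }
  if (is.null(tree$edge.length) || sum(tree$edge.length) <= 0) {
    stop("midpoint rooting needs positive branch lengths", call. = FALSE)
  }
  phangorn::midpoint(tree)
}

#' Faith's phylogenetic diversity
#'
#' Sum of the branch lengths of the minimal subtree spanning a set of
#' tips. By default the subtree also connects to the root of the tree
#' (the root-inclusive convention, matching `picante::pd` with
#' `include.root = TRUE`), so the PD of a single tip is the length of
#' its full root path; with `include_root = FALSE` only edges below the
#' most recent common ancestor of the tip set are counted.
#'
#' @param tree A rooted [ape::phylo] tree with branch lengths.
#' @param tips Character vector of tip labels (nonempty, all present in
#'   the tree).
#' @param include_root Include the path from the spanning subtree up to
#'   the root.
#' @return Total branch length (numeric scalar).
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' faith_pd(tr, c("A", "B")) # 3
faith_pd <- function(tree, tips, include_root = TRUE) {
  validate_tree(tree)
  if (length(tips) == 0L) stop("tip set is empty", call. = FALSE)
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx)) {
    stop("tip not present in tree: ", tips[which(is.na(idx))[1]], call. = FALSE)
  }
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  # edge row whose child is node k
  edge_of <- match(seq_len(max(tree$edge)), tree$edge[, 2])
  used <- logical(nrow(tree$edge))
  for (node in idx) {
    while (node != root) {
      e <- edge_of[node]
      if (used[e]) break
      used[e] <- TRUE
      node <- tree$edge[e, 1]
    }
  }
  if (!include_root) {
    mrca <- if (length(unique(idx)) == 1L) idx[1] else ape::getMRCA(tree, tips)
    node <- mrca
    while (node != root) {
      e <- edge_of[node]
      used[e] <- FALSE
      node <- tree$edge[e, 1]
    }
  }
  sum(tree$edge.length[used])
}

#' Per-species, per-class homolog presence counts
#'
#' Partitions full-length calls into xenobiotic enzyme classes by the
#' family string of the human protein, resolves each microbial cluster
#' to the species encoding it, and tabulates distinct clusters per
#' (species, class) plus class-level summaries: the number of unique
#' species with at least one homolog and the number of distinct
#' clusters.
#'
#' @param full_calls Full-length call tibble (from
#'   [call_full_length()]), columns `subject_id`, `query_id`.
#' @param cluster_species Tibble mapping `cluster_id` to `species` (one
#'   row per occurrence; a cluster may occur in many species).
#' @param family_map Named character vector: family description string
#'   per human protein accession.
#' @param rules Classification rules, see [family_rules()].
#' @return A list with `by_species` (tibble `species`, `class_code`,
#'   `n_clusters`), `by_class` (tibble `class_code`, `n_species`,
#'   `n_clusters`), and `unresolved` (cluster ids without a species
#'   mapping, surfaced with a warning rather than silently dropped).
#' @export
presence_counts <- function(full_calls, cluster_species,
                            family_map, rules = family_rules()) {
  calls <- full_calls %>%
    dplyr::mutate(class_code = classify_family(
      unname(family_map[.data$subject_id]), rules
    )) %>%
    dplyr::filter(!is.na(.data$class_code))
  unresolved <- setdiff(calls$query_id, cluster_species$cluster_id)
  if (length(unresolved) > 0L) {
    warning(sprintf("%d cluster(s) in calls have no species mapping",
                    length(unresolved)), call. = FALSE)
  }
  placed <- dplyr::inner_join(
    calls, cluster_species[c("cluster_id", "species")],
    by = c(query_id = "cluster_id"), relationship = "many-to-many"
  )
  by_species <- placed %>%
    dplyr::group_by(.data$species, .data$class_code) %>%
    dplyr::summarise(n_clusters = dplyr::n_distinct(.data$query_id),
                     .groups = "drop")
  by_class <- placed %>%
    dplyr::group_by(.data$class_code) %>%
    dplyr::summarise(
      n_species = dplyr::n_distinct(.data$species),
      n_clusters = dplyr::n_distinct(.data$query_id),
      .groups = "drop"
    )
  list(by_species = by_species, by_class = by_class, unresolved = unresolved)
}

#' Rank enzyme classes by Faith's phylogenetic diversity
#'
#' For each enzyme class, computes Faith's PD of the set of species
#' carrying at least one homolog of that class, on a (midpoint-rooted)
#' species tree, and orders classes by descending PD.
#'
#' @param presence Result of [presence_counts()].
#' @param tree Rooted species tree whose tip labels are the species
#'   names used in the presence counts.
#' @param include_root Passed to [faith_pd()].
#' @return Tibble `class_code`, `n_species`, `n_clusters`, `pd`, sorted
#'   by descending `pd`.
#' @export
pd_ranking <- function(presence, tree, include_root = TRUE) {
  species_sets <- split(presence$by_species$species,
                        presence$by_species$class_code)
  pd <- vapply(species_sets, function(sp) {
    faith_pd(tree, unique(sp), include_root = include_root)
  }, numeric(1))
  presence$by_class %>%
    dplyr::mutate(pd = unname(pd[.data$class_code])) %>%
    dplyr::arrange(dplyr::desc(.data$pd), .data$class_code)
}
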