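#' Chemicals of interest in a pharmacogenomic chemical table
#'
#' Drug-metabolism analysis restricts to chemicals whose class is one of
#' `Drug`, `Drug Class`, `Prodrug`, or `Metabolite` (drug metabolites).
#' Endogenous `Biological Intermediate` entries are excluded: they
#' appear in curated pathways but are only peripherally related to drug
#' metabolism. Matching is exact on the controlled-vocabulary class
#' string after whitespace trimming, case-sensitive.
#'
#' @param chemicals Tibble with columns `chemical_id`, `chem_class`.
#' @return Character vector of chemical ids of interest.
#' @export
chemicals_of_interest <- function(chemicals) {
  keep <- trimws(chemicals$chem_class) %in%
    c("Drug", "Drug Class", "Prodrug", "Metabolite")
  unique(chemicals$chemical_id[keep])
}

#' Filter pathway reactions to drug-relevant enzymatic steps
#'
#' Keeps reactions satisfying all four predicates: reactant and product
#' differ; the reaction type is not `Transport`; the controller (the
#' enzyme or regulator) is known; and at least one of reactant or
#' product is a chemical of interest.
#'
#' @param reactions Tibble with columns `reaction_id`, `reactant_id`,
#'   `product_id`, `controller`, `reaction_type`.
#' @param interest_set Character vector from [chemicals_of_interest()].
#' @return The filtered subset, row order preserved.
#' @export
filter_reactions <- function(reactions, interest_set) {
  ctrl <- trimws(as.character(reactions$controller))
  known <- !is.na(reactions$controller) & nzchar(ctrl) &
    tolower(ctrl) != "unknown"
  keep <- reactions$reactant_id != reactions$product_id &
    trimws(reactions$reaction_type) != "Transport" &
    known &
    (reactions$reactant_id %in% interest_set |
       reactions$product_id %in% interest_set)
  reactions[keep, , drop = FALSE]
}

#' Map gene-nomenclature identifiers to protein accessions
#'
#' @param hgnc_table Tibble with columns `hgnc_id` and `uniprot_id`
#'   (one accession per gene; conflicting duplicate mappings are an
#'   error).
#' @param genes Character vector of gene identifiers to map.
#' @return A list with `mapping` (tibble `hgnc_id`, `uniprot_id`,
#'   covering every mappable input gene) and `unmapped` (genes absent
#'   from the table, reported rather than silently dropped).
#' @export
map_identifiers <- function(hgnc_table, genes) {
  tbl <- dplyr::distinct(
    tibble::as_tibble(hgnc_table)[c("hgnc_id", "uniprot_id")]
  )
  conflict <- tbl$hgnc_id[duplicated(tbl$hgnc_id)]
  if (length(conflict) > 0L) {
    stop("conflicting accession mappings for: ",
         paste(unique(conflict), collapse = ", "), call. = FALSE)
  }
  genes <- unique(genes)
  mapping <- tbl[tbl$hgnc_id %in% genes, , drop = FALSE]
  list(
    mapping = mapping,
    unmapped = setdiff(genes, mapping$hgnc_id)
  )
}

#' Proteins in a descendant-closed ontology class, with exclusions
#'
#' Returns the proteins annotated to a root term or any term below it,
#' minus every protein annotated anywhere inside one of the excluded
#' subtrees (gene-level exclusion: one annotation in an excluded
#' subtree removes the protein entirely). With no exclusions this is a
#' plain descendant-closure query, e.g. for an oxidoreductase-activity
#' class.
#'
#' @param ontology A `gutsplit_ontology`.
#' @param annotations_closed Propagated annotations (`protein`, `term`);
#'   see [propagate_annotations()]. Because ancestors are already
#'   closed, membership in a subtree is simply annotation to its root.
#' @param root_term Term id of the class root.
#' @param excluded_roots Character vector of term ids whose subtrees are
#'   excluded.
#' @return Character vector of protein ids.
#' @export
go_class_members <- function(ontology, annotations_closed, root_term,
                             excluded_roots = character()) {
  known <- ontology$terms$term
  bad <- setdiff(c(root_term, excluded_roots), known)
  if (length(bad) > 0L) {
    stop("unknown ontology term: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  in_root <- unique(annotations_closed$protein[
    annotations_closed$term == root_term
  ])
  if (length(excluded_roots) > 0L) {
    excluded <- unique(annotations_closed$protein[
      annotations_closed$term %in% excluded_roots
    ])
    in_root <- setdiff(in_root, excluded)
  }
  in_root
}

#' Homolog count categories
#'
#' Classifies a human protein by its full-length vs split homolog
#' counts: `none` (no homolog), `full-only`, `split-only`,
#' `split-majority` (strictly more split than full, both nonzero), and
#' `full-majority` (at least as many full as split, both nonzero; ties
#' count as full-majority since split-majority is strict).
#'
#' @param n_full,n_split Nonnegative integer vectors.
#' @return Character vector of categories.
#' @export
homolog_category <- function(n_full, n_split) {
  stopifnot(length(n_full) == length(n_split),
            all(n_full >= 0), all(n_split >= 0))
  dplyr::case_when(
    n_full == 0 & n_split == 0 ~ "none",
    n_split == 0 ~ "full-only",
    n_full == 0 ~ "split-only",
    n_split > n_full ~ "split-majority",
    TRUE ~ "full-majority"
  )
}

#' Summarize homolog counts per human protein
#'
#' Counts full-length and split homologs per human protein under a
#' configurable counting unit and assigns the count category. The
#' default unit is distinct protein clusters: for the full-length
#' branch, clusters with an accepted call; for the split branch,
#' clusters participating in at least one split neighborhood.
#' `distinct-genomes` counts genomes instead (the full-length side then
#' needs the `features` table to place clusters in genomes);
#' `distinct-neighborhoods` counts split neighborhoods, with the
#' full-length side counted as distinct clusters (a full-length call is
#' its own locus).
#'
#' @param full_calls Full-length call tibble ([call_full_length()]).
#' @param split_members Split member tibble ([call_split()]`$members`).
#' @param counting_unit One of `"distinct-clusters"`,
#'   `"distinct-genomes"`, `"distinct-neighborhoods"`.
#' @param features Feature tibble, required for `"distinct-genomes"`.
#' @return Tibble `human_id`, `n_full`, `n_split`, `category`, ordered
#'   by descending `n_split`.
#' @export
summarize_counts <- function(full_calls, split_members,
                             counting_unit = c("distinct-clusters",
                                               "distinct-genomes",
                                               "distinct-neighborhoods"),
                             features = NULL) {
  counting_unit <- match.arg(counting_unit)
  full <- if (counting_unit == "distinct-genomes") {
    if (is.null(features)) {
      stop("counting unit 'distinct-genomes' needs the feature table",
           call. = FALSE)
    }
    dplyr::inner_join(
      full_calls, features[c("cluster_id", "genome_id")],
      by = c(query_id = "cluster_id"), relationship = "many-to-many"
    ) %>%
      dplyr::group_by(human_id = .data$subject_id) %>%
      dplyr::summarise(n_full = dplyr::n_distinct(.data$genome_id),
                       .groups = "drop")
  } else {
    full_calls %>%
      dplyr::group_by(human_id = .data$subject_id) %>%
      dplyr::summarise(n_full = dplyr::n_distinct(.data$query_id),
                       .groups = "drop")
  }
  split_unit <- switch(counting_unit,
    "distinct-clusters" = "query_id",
    "distinct-genomes" = "genome_id",
    "distinct-neighborhoods" = "neighborhood"
  )
  split <- split_members %>%
    dplyr::group_by(human_id = .data$subject_id) %>%
    dplyr::summarise(n_split = dplyr::n_distinct(.data[[split_unit]]),
                     .groups = "drop")
  categorize_counts(
    dplyr::full_join(full, split, by = "human_id") %>%
      dplyr::mutate(
        n_full = dplyr::coalesce(.data$n_full, 0L),
        n_split = dplyr::coalesce(.data$n_split, 0L)
      )
  )
}

#' Attach categories to a homolog count table
#'
#' @param counts Tibble with columns `human_id`, `n_full`, `n_split`.
#' @return The table with a `category` column, ordered by descending
#'   `n_split` then `human_id`.
#' @export
categorize_counts <- function(counts) {
  counts %>%
    dplyr::mutate(category = homolog_category(.data$n_full, .data$n_split)) %>%
    dplyr::arrange(dplyr::desc(.data$n_split), .data$human_id)
}

#' Select proteins with more split than full-length homologs
#'
#' Strict inequality: ties are not split-majority. This is the
#' criterion behind the headline list of human proteins detectable only
#' (or mainly) through neighborhood evidence.
#'
#' @param summaries Output of [summarize_counts()] or
#'   [categorize_counts()].
#' @return The subset with `n_split > n_full`.
#' @export
select_split_majority <- function(summaries) {
  summaries[summaries$n_split > summaries$n_full, , drop = FALSE]
}

#' Percentage arithmetic for a homolog survey of annotated enzymes
#'
#' Given counts of reviewed drug-metabolizing enzymes, how many have at
#' least one gut homolog, and how many of those have more full-length
#' than split homologs, recomputes the two headline percentages.
#'
#' @param n_reviewed Number of reviewed enzymes surveyed.
#' @param n_with_homolog Number with at least one full-length or split
#'   homolog.
#' @param n_full_majority Number of those with more full-length than
#'   split homologs.
#' @return Tibble with `pct_with_homolog` (of reviewed) and
#'   `pct_full_majority` (of those with a homolog), in percent.
#' @export
homolog_survey_percentages <- function(n_reviewed, n_with_homolog,
                                       n_full_majority) {
  stopifnot(n_reviewed >= n_with_homolog, n_with_homolog >= n_full_majority)
  tibble::tibble(
    pct_with_homolog = 100 * n_with_homolog / n_reviewed,
    pct_full_majority = 100 * n_full_majority / n_with_homolog
  )
}
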