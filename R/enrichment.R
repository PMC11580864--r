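#' Propagate annotations up the ontology (true-path rule)
#'
#' A protein annotated to a term is implicitly annotated to every
#' ancestor of that term. This closure is required before any term
#' enrichment test; it is idempotent.
#'
#' @param ontology A `gutsplit_ontology` (see [read_ontology()]).
#' @param annotations Tibble `protein`, `term` (a `namespace` column is
#'   carried through from the ontology's term table if present).
#' @return Tibble `protein`, `term`, `namespace` with one row per
#'   (protein, direct-or-ancestral term) pair.
#' @export
propagate_annotations <- function(ontology, annotations) {
  anc <- ancestor_sets(ontology)
  unknown <- setdiff(unique(annotations$term), ontology$terms$term)
  if (length(unknown) > 0L) {
    stop("annotations reference terms absent from the ontology: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  closed <- annotations %>%
    dplyr::mutate(term = anc[.data$term]) %>%
    tidyr::unnest_longer("term") %>%
    dplyr::distinct(.data$protein, .data$term)
  dplyr::left_join(closed, ontology$terms[c("term", "namespace")], by = "term")
}

# named list: term -> sorted character vector of {term} U ancestors;
# memoized bottom-up over a topological order of the DAG
ancestor_sets <- function(ontology) {
  terms <- ontology$terms$term
  parents <- ontology$parents
  anc <- stats::setNames(vector("list", length(terms)), terms)
  visit <- function(t) {
    if (!is.null(anc[[t]])) return(anc[[t]])
    ps <- parents[[t]]
    res <- t
    for (p in ps) res <- c(res, visit(p))
    res <- sort(unique(res))
    anc[[t]] <<- res
    res
  }
  for (t in terms) visit(t)
  anc
}

# named list: term -> {term} U descendants
descendant_sets <- function(ontology) {
  anc <- ancestor_sets(ontology)
  pairs <- tibble::tibble(
    term = rep(names(anc), lengths(anc)),
    ancestor = unlist(anc, use.names = FALSE)
  )
  split(pairs$term, factor(pairs$ancestor, levels = ontology$terms$term))
}

#' Term over-representation by Fisher's exact test
#'
#' For every term annotating at least one background protein, tests
#' over-representation of the term in the study set with a one-sided
#' Fisher exact test on the 2x2 table (study-in-term, study-not-in-term,
#' rest-in-term, rest-not-in-term), then adjusts p-values across all
#' tested terms with Benjamini-Hochberg.
#'
#' @param study Character vector of study proteins (must be a subset of
#'   `background`).
#' @param background Character vector of background proteins.
#' @param annotations_closed Propagated annotation tibble (`protein`,
#'   `term`, optionally `namespace`); see [propagate_annotations()].
#' @param namespace Optional namespace to restrict tested terms to
#'   (e.g. `"biological_process"`).
#' @param algorithm `"classic"` tests every term independently on the
#'   propagated annotations. `"elim"` decorrelates the DAG: terms are
#'   visited from the most specific upward, and proteins annotated to a
#'   term found significant at `elim_cutoff` are removed from that
#'   term's ancestors before those are tested. Requires `ontology`.
#' @param ontology `gutsplit_ontology`, required for `algorithm =
#'   "elim"`.
#' @param elim_cutoff Nominal significance level driving elimination.
#' @return Tibble sorted by `p_adjusted`: `term`, `study_count`,
#'   `study_total`, `background_count`, `background_total`, `p_value`,
#'   `p_adjusted`.
#' @export
fisher_enrichment <- function(study, background, annotations_closed,
                              namespace = NULL,
                              algorithm = c("classic", "elim"),
                              ontology = NULL, elim_cutoff = 0.01) {
  algorithm <- match.arg(algorithm)
  study <- unique(study)
  background <- unique(background)
  if (!all(study %in% background)) {
    stop("study set is not a subset of the background", call. = FALSE)
  }
  ann <- annotations_closed %>%
    dplyr::filter(.data$protein %in% background)
  if (!is.null(namespace) && "namespace" %in% names(ann)) {
    ann <- dplyr::filter(ann, .data$namespace %in% !!namespace)
  }
  ann <- dplyr::distinct(ann, .data$protein, .data$term)
  if (nrow(ann) == 0L) {
    return(tibble::tibble(
      term = character(), study_count = integer(), study_total = integer(),
      background_count = integer(), background_total = integer(),
      p_value = numeric(), p_adjusted = numeric()
    ))
  }
  n_bg <- length(background)
  n_study <- length(study)
  term_sets <- split(ann$protein, ann$term)
  one_sided_p <- function(a, K) {
    tab <- matrix(c(a, n_study - a, K - a, n_bg - n_study - (K - a)), nrow = 2)
    stats::fisher.test(tab, alternative = "greater")$p.value
  }
  if (algorithm == "elim") {
    if (is.null(ontology)) {
      stop("algorithm = 'elim' needs the ontology graph", call. = FALSE)
    }
    # visit most specific terms first (deepest ancestor chain first);
    # proteins of significant terms are pruned from their proper ancestors
    anc <- ancestor_sets(ontology)
    tested <- names(term_sets)
    depth <- lengths(anc[tested])
    ord <- tested[order(-depth, tested)]
    pruned <- term_sets
    p_map <- stats::setNames(numeric(length(tested)), tested)
    for (t in ord) {
      genes <- pruned[[t]]
      a <- sum(genes %in% study)
      p_map[[t]] <- one_sided_p(a, length(genes))
      if (p_map[[t]] < elim_cutoff) {
        for (up in setdiff(intersect(anc[[t]], tested), t)) {
          pruned[[up]] <- setdiff(pruned[[up]], term_sets[[t]])
        }
      }
    }
    counts <- tibble::tibble(
      term = tested,
      background_count = lengths(term_sets[tested]),
      study_count = vapply(term_sets[tested],
                           function(g) sum(g %in% study), integer(1)),
      p_value = unname(p_map[tested])
    )
    return(
      counts %>%
        dplyr::mutate(
          study_total = n_study,
          background_total = n_bg,
          p_adjusted = bh_adjust(.data$p_value)
        ) %>%
        dplyr::select("term", "study_count", "study_total",
                      "background_count", "background_total", "p_value",
                      "p_adjusted") %>%
        dplyr::arrange(.data$p_adjusted, .data$p_value, .data$term)
    )
  }
  counts <- ann %>%
    dplyr::group_by(.data$term) %>%
    dplyr::summarise(
      background_count = dplyr::n_distinct(.data$protein),
      study_count = sum(unique(.data$protein) %in% study),
      .groups = "drop"
    )
  p <- vapply(seq_len(nrow(counts)), function(i) {
    one_sided_p(counts$study_count[i], counts$background_count[i])
  }, numeric(1))
  counts %>%
    dplyr::mutate(
      study_total = n_study,
      background_total = n_bg,
      p_value = p,
      p_adjusted = bh_adjust(p)
    ) %>%
    dplyr::select("term", "study_count", "study_total", "background_count",
                  "background_total", "p_value", "p_adjusted") %>%
    dplyr::arrange(.data$p_adjusted, .data$p_value, .data$term)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment (a validated wrapper around
#' [stats::p.adjust()]): values are clipped to 1, monotone in the sorted
#' order, and returned in the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric())
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Mitochondrial flag from cellular-component annotations
#'
#' A protein counts as mitochondrially localized when any of its
#' cellular-component term names matches the regular expression
#' `"[Mm]itochondr"`.
#'
#' @param annotations Tibble `protein`, `term`, `namespace` (direct or
#'   propagated annotations).
#' @param ontology A `gutsplit_ontology` whose term table carries
#'   `name` strings.
#' @param proteins Proteins to flag.
#' @return Named logical vector over `proteins`.
#' @export
mitochondrial_flags <- function(annotations, ontology, proteins) {
  cc <- annotations
  if ("namespace" %in% names(cc)) {
    cc <- dplyr::filter(cc, is.na(.data$namespace) |
                          .data$namespace == "cellular_component")
  }
  cc <- dplyr::left_join(cc, ontology$terms[c("term", "name")], by = "term")
  mito_prot <- unique(cc$protein[grepl("[Mm]itochondr", cc$name)])
  stats::setNames(proteins %in% mito_prot, proteins)
}

#' Localization odds ratio for a protein group
#'
#' Tests whether a group of proteins is enriched for a binary
#' localization flag (mitochondrial, by default usage) relative to the
#' background, with a two-sided Fisher exact test on the 2x2 table. The
#' headline odds ratio is the conditional maximum-likelihood estimate of
#' [stats::fisher.test()] with its exact confidence interval; the sample
#' odds ratio `ad/bc` is also reported, with a Haldane-Anscombe 0.5
#' correction (and a flag) when any cell is zero.
#'
#' @param group Character vector of proteins (subset of `background`).
#' @param is_flagged Named logical vector over at least the background
#'   proteins (e.g. from [mitochondrial_flags()]).
#' @param background Character vector of background proteins.
#' @return A tibble with one row: cell counts, `odds_ratio`
#'   (conditional MLE), `ci_low`, `ci_high`, `sample_or`,
#'   `haldane_corrected`, `p_value`.
#' @export
localization_odds_ratio <- function(group, is_flagged, background) {
  group <- unique(group)
  background <- unique(background)
  if (length(group) == 0L) stop("empty protein group", call. = FALSE)
  if (!all(group %in% background)) {
    stop("group is not a subset of the background", call. = FALSE)
  }
  rest <- setdiff(background, group)
  a <- sum(is_flagged[group])
  b <- length(group) - a
  c_ <- sum(is_flagged[rest])
  d <- length(rest) - c_
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE)
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  zero <- any(tab == 0)
  h <- if (zero) 0.5 else 0
  sample_or <- ((a + h) * (d + h)) / ((b + h) * (c_ + h))
  tibble::tibble(
    n_flagged_group = a, n_unflagged_group = b,
    n_flagged_rest = c_, n_unflagged_rest = d,
    odds_ratio = unname(ft$estimate),
    ci_low = ft$conf.int[1], ci_high = ft$conf.int[2],
    sample_or = sample_or,
    haldane_corrected = zero,
    p_value = ft$p.value
  )
}

#' Localization enrichment stratified by homolog frequency
#'
#' Splits proteins into ordered bins (e.g. by how many genomes carry a
#' full-length homolog) and computes one localization odds ratio per
#' bin, plus a Spearman trend of the sample odds ratio against bin
#' rank: a positive trend means the enrichment increases with homolog
#' frequency.
#'
#' @param groups Named list of disjoint protein character vectors, in
#'   increasing bin order.
#' @param is_flagged Named logical vector (see
#'   [localization_odds_ratio()]).
#' @param background Background protein vector.
#' @return A list with `per_bin` (tibble: bin name, rank, the odds-ratio
#'   columns) and `trend` (Spearman rho of sample OR vs rank; `NA` with
#'   fewer than two usable bins).
#' @export
stratified_enrichment <- function(groups, is_flagged, background) {
  if (anyDuplicated(unlist(groups))) {
    stop("bins must be disjoint", call. = FALSE)
  }
  rows <- list()
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    nm <- names(groups)[i] %||% as.character(i)
    if (length(g) == 0L) {
      warning("skipping empty bin ", nm, call. = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- dplyr::bind_cols(
      tibble::tibble(bin = nm, rank = i),
      localization_odds_ratio(g, is_flagged, background)
    )
  }
  per_bin <- dplyr::bind_rows(rows)
  trend <- if (nrow(per_bin) >= 2L) {
    suppressWarnings(stats::cor(per_bin$rank, per_bin$sample_or,
                                method = "spearman"))
  } else {
    NA_real_
  }
  list(per_bin = per_bin, trend = trend)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
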