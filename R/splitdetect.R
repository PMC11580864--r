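#' Place alignments onto genomes
#'
#' Joins post-filter alignments (best human hit, microbe coverage) to
#' the genome feature table: one placed alignment per (alignment, gene
#' occurrence) pair, since one protein cluster can occur in many
#' genomes, and more than once in one genome. Genomes encoding fewer
#' than two distinct clusters aligning to a given human protein cannot
#' harbor a split homolog of it and are dropped at this point.
#'
#' @param records Alignment tibble that already passed the best-hit and
#'   microbe-coverage steps.
#' @param features Genome feature tibble (see [read_feature_table()]).
#' @return Placed-alignment tibble: the alignment columns plus
#'   `genome_id`, `contig_id`, `strand`, `feature_index`. Clusters with
#'   no feature occurrence are dropped with a warning.
#' @export
expand_to_genomes <- function(records, features) {
  orphan <- setdiff(records$query_id, features$cluster_id)
  if (length(orphan) > 0L) {
    warning(sprintf(
      "%d cluster(s) have no genome feature occurrence and were dropped (e.g. %s)",
      length(orphan), orphan[1]
    ), call. = FALSE)
  }
  placed <- dplyr::inner_join(
    records,
    features[c("cluster_id", "genome_id", "contig_id", "strand", "feature_index")],
    by = c(query_id = "cluster_id"),
    relationship = "many-to-many"
  )
  placed %>%
    dplyr::group_by(.data$subject_id, .data$genome_id) %>%
    dplyr::filter(dplyr::n_distinct(.data$query_id) >= 2L) %>%
    dplyr::ungroup()
}

#' Joint coverage of a subject by a set of intervals
#'
#' Fraction of subject positions covered by the union of the given
#' 1-based inclusive intervals; overlap and containment are counted
#' once.
#'
#' @param intervals Two-column matrix or data frame of `(start, end)`
#'   pairs, 1-based inclusive, all within `[1, s_len]`.
#' @param s_len Subject length.
#' @return A single fraction in `[0, 1]`; 0 for an empty set.
#' @export
#' @examples
#' joint_coverage(rbind(c(1, 40), c(35, 80)), 100) # 0.8
joint_coverage <- function(intervals, s_len) {
  intervals <- as.matrix(intervals)
  if (nrow(intervals) == 0L) return(0)
  stopifnot(ncol(intervals) == 2L, all(intervals[, 1] >= 1),
            all(intervals[, 2] <= s_len), all(intervals[, 1] <= intervals[, 2]))
  union_length(intervals[, 1], intervals[, 2]) / s_len
}

# total length of the union of 1-based inclusive intervals (sorted sweep)
union_length <- function(start, end) {
  o <- order(start, end)
  start <- start[o]
  end <- end[o]
  hi <- cummax(end)
  prev_hi <- c(0, hi[-length(hi)])
  sum(pmax(0, end - pmax(start, prev_hi + 1) + 1))
}

# grouped union coverage: adds a `joint_cov` column constant per group.
# `placed` must carry s_start, s_end, s_len; `...` are grouping columns.
add_joint_coverage <- function(placed, ...) {
  placed %>%
    dplyr::group_by(...) %>%
    dplyr::arrange(.data$s_start, .data$s_end, .by_group = TRUE) %>%
    dplyr::mutate(
      ..hi = cummax(.data$s_end),
      ..prev = dplyr::lag(.data$..hi, default = 0L),
      ..cov = pmax(0L, .data$s_end - pmax(.data$s_start, .data$..prev + 1L) + 1L)
    ) %>%
    dplyr::mutate(joint_cov = sum(.data$..cov) / .data$s_len[1]) %>%
    dplyr::select(-"..hi", -"..prev", -"..cov") %>%
    dplyr::ungroup()
}

#' Group placed alignments into gene neighborhoods
#'
#' Within one (human protein, genome) pair, placed alignments on the
#' same contig and strand are connected whenever their gene-order ranks
#' differ by at most `max_gap`; connected components under transitive
#' chaining are the candidate neighborhoods. Components containing
#' fewer than two distinct protein clusters are discarded.
#'
#' Because connectivity depends only on consecutive gaps along the
#' sorted rank order, chaining sorted features whose successive gaps are
#' all `<= max_gap` is exactly the connected-component relation.
#'
#' @param placed Placed-alignment tibble for a single
#'   (subject, genome) pair.
#' @param max_gap Maximum feature-rank distance joining two members.
#' @return The input restricted to retained members, with a
#'   `neighborhood` column identifying the component.
#' @export
find_neighborhoods <- function(placed, max_gap = 3L) {
  stopifnot(
    dplyr::n_distinct(placed$subject_id) <= 1L,
    dplyr::n_distinct(placed$genome_id) <= 1L
  )
  add_neighborhoods(placed, max_gap) %>%
    dplyr::group_by(.data$neighborhood) %>%
    dplyr::filter(dplyr::n_distinct(.data$query_id) >= 2L) %>%
    dplyr::ungroup()
}

# vectorized neighborhood labeling across many (subject, genome) groups
add_neighborhoods <- function(placed, max_gap) {
  placed %>%
    dplyr::group_by(.data$subject_id, .data$genome_id, .data$contig_id,
                    .data$strand) %>%
    dplyr::arrange(.data$feature_index, .by_group = TRUE) %>%
    dplyr::mutate(
      ..new = dplyr::coalesce(
        .data$feature_index - dplyr::lag(.data$feature_index) > max_gap, TRUE
      ),
      ..comp = cumsum(.data$..new)
    ) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(
      neighborhood = paste(.data$subject_id, .data$genome_id, .data$contig_id,
                           .data$strand, .data$..comp, sep = "|")
    ) %>%
    dplyr::select(-"..new", -"..comp")
}

# keep neighborhoods with >=2 distinct clusters and joint coverage >= min_cov;
# this is the "repeat the human coverage step" re-check applied per component
recheck_components <- function(placed, thresholds) {
  placed %>%
    add_joint_coverage(.data$neighborhood) %>%
    dplyr::group_by(.data$neighborhood) %>%
    dplyr::filter(
      dplyr::n_distinct(.data$query_id) >= 2L,
      .data$joint_cov[1] >= thresholds$human_cov
    ) %>%
    dplyr::ungroup()
}

#' Call split homologs
#'
#' Detects sets of neighboring genes in one genome that jointly, but
#' not individually, cover a human protein:
#' \enumerate{
#'   \item shared steps: best human hit per query, microbe coverage;
#'   \item same genome: alignments are expanded to every genome encoding
#'     the cluster; genomes with `< 2` distinct clusters per human
#'     protein are dropped;
#'   \item joint human coverage: the interval union over the genome's
#'     alignments to the human protein must reach the coverage
#'     threshold;
#'   \item feature distance: members must lie on one contig and strand,
#'     each within `max_feature_gap` gene ranks of the next (transitive
#'     chaining); the joint-coverage check is re-run per neighborhood;
#'   \item contamination: members above the frozen full-length identity
#'     cutoff are removed, neighborhoods are re-formed from the
#'     survivors, and joint coverage is re-checked once more.
#' }
#' Finally, "jointly but not individually" is enforced: a neighborhood
#' in which any single member already covers the human protein at the
#' full-length threshold is not a split call (such members are
#' full-length calls instead).
#'
#' @param records Raw alignment tibble (the shared steps are applied
#'   internally; they are idempotent).
#' @param features Genome feature tibble.
#' @param thresholds A [pipeline_thresholds()] object.
#' @param cutoff The frozen `gutsplit_cutoff` estimated by
#'   [call_full_length()]; never re-estimated on split candidates. Pass
#'   `NULL` to skip the contamination step (degenerate inputs only).
#' @return A list with `calls`, one row per split call (`subject_id`,
#'   `genome_id`, `contig_id`, `strand`, `neighborhood`, `n_members`,
#'   `n_clusters`, `joint_coverage`, `max_member_coverage`,
#'   `min_feature_index`), ordered by (subject, genome, min feature
#'   rank); and `members`, one row per member alignment with its
#'   `neighborhood` key.
#' @export
call_split <- function(records, features, thresholds = pipeline_thresholds(),
                       cutoff = NULL) {
  validate_alignments(records)
  r <- best_human_hit(records)
  r <- filter_microbe(r, thresholds)

  placed <- expand_to_genomes(r, features)

  # S4: joint coverage over all of a genome's alignments to the protein
  placed <- placed %>%
    add_joint_coverage(.data$subject_id, .data$genome_id) %>%
    dplyr::filter(.data$joint_cov >= thresholds$human_cov) %>%
    dplyr::select(-"joint_cov")

  # S5: same contig + strand, feature distance <= max_gap, then re-check
  placed <- add_neighborhoods(placed, thresholds$max_feature_gap)
  placed <- recheck_components(placed, thresholds)

  # S6: contamination against the frozen full-length cutoff, then
  # neighborhoods re-formed and coverage re-checked
  if (!is.null(cutoff)) {
    placed <- placed[placed$pct_identity <= cutoff$cutoff, , drop = FALSE]
    placed <- add_neighborhoods(placed, thresholds$max_feature_gap)
    placed <- recheck_components(placed, thresholds)
  }

  # jointly but NOT individually
  placed <- placed %>%
    dplyr::mutate(member_cov = (.data$s_end - .data$s_start + 1) / .data$s_len) %>%
    dplyr::group_by(.data$neighborhood) %>%
    dplyr::filter(max(.data$member_cov, -Inf) < thresholds$human_cov) %>%
    dplyr::ungroup()

  members <- placed %>%
    dplyr::select("neighborhood", "subject_id", "genome_id", "contig_id",
                  "strand", "feature_index", query_id = "query_id",
                  "pct_identity", "s_start", "s_end", "s_len", "member_cov",
                  joint_coverage = "joint_cov") %>%
    dplyr::arrange(.data$subject_id, .data$genome_id, .data$contig_id,
                   .data$feature_index)

  calls <- members %>%
    dplyr::group_by(.data$neighborhood) %>%
    dplyr::summarise(
      subject_id = .data$subject_id[1],
      genome_id = .data$genome_id[1],
      contig_id = .data$contig_id[1],
      strand = .data$strand[1],
      n_members = dplyr::n(),
      n_clusters = dplyr::n_distinct(.data$query_id),
      joint_coverage = .data$joint_coverage[1],
      max_member_coverage = max(.data$member_cov, -Inf),
      min_feature_index = min(.data$feature_index, .Machine$integer.max),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$subject_id, .data$genome_id, .data$min_feature_index)

  list(calls = calls, members = members)
}
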