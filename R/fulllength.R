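#' Keep the best human hit per microbial query
#'
#' First filtering step of homolog detection: for each microbial cluster
#' representative, retain only the alignment to the human protein with
#' the highest bitscore. Ties are broken deterministically by lower
#' e-value, then lexicographically smaller subject accession.
#'
#' @param records Alignment tibble (see [read_blast_tab()]).
#' @return The subset with at most one subject per query; input row
#'   order among winners is not guaranteed, output is ordered by
#'   `query_id`.
#' @export
best_human_hit <- function(records) {
  records %>%
    dplyr::arrange(
      .data$query_id,
      dplyr::desc(.data$bitscore),
      .data$evalue,
      .data$subject_id
    ) %>%
    dplyr::distinct(.data$query_id, .keep_all = TRUE)
}

#' Coverage of the microbial query by an alignment
#'
#' Fraction of the query sequence inside the aligned span,
#' `(q_end - q_start + 1) / q_len`, coordinates 1-based inclusive.
#'
#' @param records Alignment tibble.
#' @return Numeric vector of fractions in `(0, 1]`.
#' @export
microbe_coverage <- function(records) {
  (records$q_end - records$q_start + 1) / records$q_len
}

#' Coverage of the human subject by an alignment
#'
#' `(s_end - s_start + 1) / s_len`.
#'
#' @inheritParams microbe_coverage
#' @return Numeric vector of fractions in `(0, 1]`.
#' @export
human_coverage <- function(records) {
  (records$s_end - records$s_start + 1) / records$s_len
}

#' Microbe-side coverage and length filter
#'
#' Retains alignments covering at least `thresholds$microbe_cov` of the
#' microbial query (exact rational 2/3 by default, so the comparison at
#' the boundary is an equality, not a rounding accident) whose query is
#' at least `thresholds$min_microbe_len` amino acids long.
#'
#' @param records Alignment tibble.
#' @param thresholds A [pipeline_thresholds()] object.
#' @return Filtered tibble.
#' @export
filter_microbe <- function(records, thresholds = pipeline_thresholds()) {
  keep <- microbe_coverage(records) >= thresholds$microbe_cov &
    records$q_len >= thresholds$min_microbe_len
  records[keep, , drop = FALSE]
}

#' Human-side coverage filter
#'
#' Retains alignments individually covering at least
#' `thresholds$human_cov` of the human subject.
#'
#' @inheritParams filter_microbe
#' @return Filtered tibble.
#' @export
filter_human <- function(records, thresholds = pipeline_thresholds()) {
  records[human_coverage(records) >= thresholds$human_cov, , drop = FALSE]
}

#' Estimate the contamination identity cutoff
#'
#' Alignments whose percent identity is unusually high relative to the
#' bulk of the full-length identity distribution are likely human-read
#' contamination in microbial assemblies rather than genuine ancient
#' homology. The cutoff is `mean + k * SD` of the observed identities
#' (sample SD, denominator `n - 1`), with `k = 3` by default.
#'
#' @param records Alignment tibble the distribution is estimated from
#'   (by default the set of full-length candidates that passed the
#'   human-coverage filter).
#' @param k SD multiplier.
#' @return An object of class `gutsplit_cutoff` with elements
#'   `mean_pct_id`, `sd_pct_id`, `k`, `cutoff`, `n`.
#' @export
estimate_contamination_cutoff <- function(records, k = 3.0) {
  ids <- records$pct_identity
  if (length(ids) < 2L) {
    stop("need at least 2 alignments to estimate an identity SD", call. = FALSE)
  }
  m <- mean(ids)
  s <- stats::sd(ids)
  structure(
    list(mean_pct_id = m, sd_pct_id = s, k = k, cutoff = m + k * s,
         n = length(ids)),
    class = "gutsplit_cutoff"
  )
}

#' @export
print.gutsplit_cutoff <- function(x, ...) {
  cat(sprintf(
    "contamination cutoff: %.2f%% ID (mean %.2f + %.1f x SD %.4f, n = %d)\n",
    x$cutoff, x$mean_pct_id, x$k, x$sd_pct_id, x$n
  ))
  invisible(x)
}

#' Call full-length homologs
#'
#' Runs the full-length branch of the pipeline on raw alignments:
#' \enumerate{
#'   \item best human hit per microbial query (highest bitscore);
#'   \item microbe coverage >= 2/3 and query length >= 80 aa;
#'   \item human coverage >= 70% (per individual alignment);
#'   \item contamination: the identity cutoff `mean + k*SD` is estimated
#'     on the survivors of step 3, then alignments above it are dropped.
#' }
#' The estimated cutoff is returned alongside the calls so the split
#' branch can reuse the same frozen value (it is never re-estimated on
#' split candidates).
#'
#' @param records Raw alignment tibble.
#' @param thresholds A [pipeline_thresholds()] object.
#' @param cutoff Optional pre-computed `gutsplit_cutoff`; when supplied,
#'   estimation is skipped and the given cutoff is applied.
#' @return A list with `calls` (tibble: `subject_id`, `query_id`,
#'   `human_coverage`, `microbe_coverage`, `pct_identity`, `bitscore`)
#'   and `cutoff` (`gutsplit_cutoff`, or `NULL` for degenerate input
#'   with fewer than two candidates).
#' @export
call_full_length <- function(records, thresholds = pipeline_thresholds(),
                             cutoff = NULL) {
  validate_alignments(records)
  r <- best_human_hit(records)
  r <- filter_microbe(r, thresholds)
  r <- filter_human(r, thresholds)
  if (is.null(cutoff)) {
    cutoff <- if (nrow(r) >= 2L) {
      estimate_contamination_cutoff(r, k = thresholds$contamination_sd)
    } else {
      NULL
    }
  }
  if (!is.null(cutoff)) {
    r <- r[r$pct_identity <= cutoff$cutoff, , drop = FALSE]
  }
  calls <- tibble::tibble(
    subject_id = r$subject_id,
    query_id = r$query_id,
    human_coverage = human_coverage(r),
    microbe_coverage = microbe_coverage(r),
    pct_identity = r$pct_identity,
    bitscore = r$bitscore
  ) %>%
    dplyr::arrange(.data$subject_id, .data$query_id)
  list(calls = calls, cutoff = cutoff)
}
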