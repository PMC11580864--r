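#' Pipeline thresholds
#'
#' Bundle of the filtering thresholds used throughout homolog detection.
#' Defaults correspond to the standard operating point of the pipeline:
#' an alignment must cover at least 2/3 of the microbial query and the
#' query must be at least 80 aa long; a (joint) alignment must cover at
#' least 70% of the human subject; candidate neighborhood members may be
#' at most 3 features apart; and alignments whose percent identity
#' exceeds `mean + contamination_sd * SD` of the full-length identity
#' distribution are discarded as likely contamination.
#'
#' `microbe_cov` defaults to the exact rational `2/3`, so a 60/90
#' alignment sits exactly on the boundary and is retained (all boundary
#' comparisons are inclusive, "at least").
#'
#' @param microbe_cov Minimum fraction of the microbial query covered.
#' @param human_cov Minimum fraction of the human subject covered
#'   (individually for full-length calls, jointly for split calls).
#' @param min_microbe_len Minimum microbial query length in amino acids.
#' @param max_feature_gap Maximum distance, in gene-order ranks, between
#'   neighboring members of a split candidate.
#' @param contamination_sd Multiplier `k` in the identity cutoff
#'   `mean + k * SD`.
#'
#' @return An object of class `gutsplit_thresholds` (a named list).
#' @export
#' @examples
#' pipeline_thresholds()
#' pipeline_thresholds(human_cov = 0.8)
pipeline_thresholds <- function(microbe_cov = 2 / 3,
                                human_cov = 0.70,
                                min_microbe_len = 80L,
                                max_feature_gap = 3L,
                                contamination_sd = 3.0) {
  stopifnot(
    is.numeric(microbe_cov), length(microbe_cov) == 1L,
    microbe_cov > 0, microbe_cov <= 1,
    is.numeric(human_cov), length(human_cov) == 1L,
    human_cov > 0, human_cov <= 1,
    is.numeric(min_microbe_len), length(min_microbe_len) == 1L,
    min_microbe_len >= 1,
    is.numeric(max_feature_gap), length(max_feature_gap) == 1L,
    max_feature_gap >= 1,
    is.numeric(contamination_sd), length(contamination_sd) == 1L,
    contamination_sd >= 0
  )
  structure(
    list(
      microbe_cov = microbe_cov,
      human_cov = human_cov,
      min_microbe_len = as.integer(min_microbe_len),
      max_feature_gap = as.integer(max_feature_gap),
      contamination_sd = contamination_sd
    ),
    class = "gutsplit_thresholds"
  )
}

#' @export
print.gutsplit_thresholds <- function(x, ...) {
  cat("gutsplit pipeline thresholds:\n")
  cat(sprintf("  microbe coverage  >= %.4f\n", x$microbe_cov))
  cat(sprintf("  human coverage    >= %.2f\n", x$human_cov))
  cat(sprintf("  microbe length    >= %d aa\n", x$min_microbe_len))
  cat(sprintf("  feature gap       <= %d\n", x$max_feature_gap))
  cat(sprintf("  identity cutoff   mean + %.1f SD\n", x$contamination_sd))
  invisible(x)
}

# one-line fingerprint used in provenance headers
threshold_fingerprint <- function(th) {
  sprintf(
    "microbe_cov=%.6g;human_cov=%.6g;min_microbe_len=%d;max_feature_gap=%d;contamination_sd=%.6g",
    th$microbe_cov, th$human_cov, th$min_microbe_len,
    th$max_feature_gap, th$contamination_sd
  )
}
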