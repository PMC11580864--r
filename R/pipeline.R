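#' Pipeline run configuration
#'
#' Flat key-value configuration wiring the pipeline stages together.
#' Every threshold default equals the pipeline's standard operating
#' point (see [pipeline_thresholds()]).
#'
#' @param input_dir Directory holding the input bundle
#'   (`alignments.tsv`, `features.tsv`, and optionally
#'   `ontology_edges.tsv`, `ontology_terms.tsv`, `annotations.tsv`,
#'   `families.tsv`, `species_map.tsv`, `tree.nwk`; the layout written
#'   by [write_fixture_bundle()]).
#' @param out_dir Directory results are written to.
#' @param thresholds A [pipeline_thresholds()] object.
#' @param counting_unit Counting unit for homolog summaries (see
#'   [summarize_counts()]).
#' @param seed Seed for the `simulate` stage.
#' @param sim_params Optional [generator_params()] for `simulate`
#'   (overrides `seed`).
#' @return A `gutsplit_config` list.
#' @export
run_config <- function(input_dir, out_dir = input_dir,
                       thresholds = pipeline_thresholds(),
                       counting_unit = "distinct-clusters",
                       seed = 1L, sim_params = NULL) {
  stopifnot(inherits(thresholds, "gutsplit_thresholds"))
  structure(
    list(input_dir = input_dir, out_dir = out_dir, thresholds = thresholds,
         counting_unit = counting_unit, seed = as.integer(seed),
         sim_params = sim_params),
    class = "gutsplit_config"
  )
}

pipeline_input <- function(config, file, stage) {
  path <- file.path(config$input_dir, file)
  if (!file.exists(path)) {
    stop(sprintf("stage '%s' needs input file %s (not found)", stage, path),
         call. = FALSE)
  }
  path
}

stage_log <- function(stage, what, n_in, n_out) {
  message(sprintf("[%s] %s: %d -> %d records", stage, what, n_in, n_out))
}

#' Run pipeline stages
#'
#' Orchestrates the analysis end-to-end over plain TSV inputs and
#' outputs. Stages:
#' \describe{
#'   \item{`simulate`}{generate a synthetic benchmark bundle into
#'     `input_dir`.}
#'   \item{`full`}{full-length homolog calls; writes `full_calls.tsv`
#'     and the contamination-cutoff sidecar `cutoff.tsv`.}
#'   \item{`split`}{split homolog calls; requires the cutoff sidecar
#'     (run `full` first); writes `split_calls.tsv` and
#'     `split_members.tsv`.}
#'   \item{`enrich`}{term enrichment of proteins with full-length calls
#'     and the mitochondrial localization odds ratio; writes
#'     `enrichment.tsv` and `localization.tsv`.}
#'   \item{`pd`}{xenobiotic family classification and Faith's PD
#'     ranking; writes `pd_ranking.tsv`.}
#'   \item{`pharm`}{per-protein homolog count summaries and the
#'     split-majority subset; writes `homolog_counts.tsv` and
#'     `split_majority.tsv`.}
#'   \item{`all`}{`full`, `split`, `enrich`, `pd`, `pharm` in
#'     dependency order.}
#' }
#' Every output TSV carries a provenance header with the package
#' version and thresholds; per-stage record counts are logged via
#' [message()].
#'
#' @param stage One of `simulate`, `full`, `split`, `enrich`, `pd`,
#'   `pharm`, `all`.
#' @param config A [run_config()] object.
#' @return Invisibly, a named character vector of the files written.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "full", "split",
                                   "enrich", "pd", "pharm"),
                         config) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "gutsplit_config"))
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  out <- function(f) file.path(config$out_dir, f)
  th <- config$thresholds
  written <- character()

  if (stage == "simulate") {
    params <- config$sim_params %||% generator_params(seed = config$seed)
    sim <- generate_synthetic(params)
    manifest <- write_fixture_bundle(sim, config$input_dir)
    stage_log("simulate", "alignments", 0L, nrow(sim$alignments))
    return(invisible(c(manifest = manifest)))
  }

  if (stage %in% c("full", "all")) {
    records <- read_blast_tab(pipeline_input(config, "alignments.tsv", "full"))
    res <- call_full_length(records, th)
    stage_log("full", "alignments -> full-length calls",
              nrow(records), nrow(res$calls))
    write_tsv_prov(res$calls, out("full_calls.tsv"), th)
    cut_tbl <- if (is.null(res$cutoff)) {
      tibble::tibble(mean_pct_id = NA_real_, sd_pct_id = NA_real_,
                     k = th$contamination_sd, cutoff = NA_real_, n = 0L)
    } else {
      tibble::as_tibble(res$cutoff[c("mean_pct_id", "sd_pct_id", "k",
                                     "cutoff", "n")])
    }
    write_tsv_prov(cut_tbl, out("cutoff.tsv"), th)
    written <- c(written, full_calls = out("full_calls.tsv"),
                 cutoff = out("cutoff.tsv"))
  }

  if (stage %in% c("split", "all")) {
    cut_path <- out("cutoff.tsv")
    if (!file.exists(cut_path)) {
      stop("split stage needs the contamination-cutoff sidecar ", cut_path,
           "; run the 'full' stage first", call. = FALSE)
    }
    cut_tbl <- utils::read.delim(cut_path, comment.char = "#")
    cutoff <- if (is.na(cut_tbl$cutoff[1])) {
      NULL
    } else {
      structure(as.list(cut_tbl[1, ]), class = "gutsplit_cutoff")
    }
    records <- read_blast_tab(pipeline_input(config, "alignments.tsv", "split"))
    features <- read_feature_table(
      pipeline_input(config, "features.tsv", "split"), format = "tsv"
    )
    res <- call_split(records, features, th, cutoff)
    stage_log("split", "alignments -> split calls",
              nrow(records), nrow(res$calls))
    write_tsv_prov(res$calls, out("split_calls.tsv"), th)
    write_tsv_prov(res$members, out("split_members.tsv"), th)
    written <- c(written, split_calls = out("split_calls.tsv"),
                 split_members = out("split_members.tsv"))
  }

  if (stage %in% c("enrich", "pd", "pharm", "all")) {
    full_calls <- utils::read.delim(out("full_calls.tsv"), comment.char = "#")
    if (!file.exists(out("split_members.tsv"))) {
      stop("downstream stages need split_members.tsv; run the 'split' stage",
           call. = FALSE)
    }
    members <- utils::read.delim(out("split_members.tsv"), comment.char = "#")
  }

  if (stage %in% c("enrich", "all")) {
    ontology <- read_ontology(
      pipeline_input(config, "ontology_edges.tsv", "enrich"),
      pipeline_input(config, "ontology_terms.tsv", "enrich")
    )
    annotations <- read_annotations(
      pipeline_input(config, "annotations.tsv", "enrich"), ontology
    )
    closed <- propagate_annotations(ontology, annotations)
    background <- unique(annotations$protein)
    study <- intersect(unique(full_calls$subject_id), background)
    enr <- fisher_enrichment(study, background, closed,
                             namespace = "biological_process")
    stage_log("enrich", "terms tested", nrow(enr), nrow(enr))
    write_tsv_prov(enr, out("enrichment.tsv"), th)
    flags <- mitochondrial_flags(annotations, ontology, background)
    loc <- localization_odds_ratio(study, flags, background)
    write_tsv_prov(loc, out("localization.tsv"), th)
    written <- c(written, enrichment = out("enrichment.tsv"),
                 localization = out("localization.tsv"))
  }

  if (stage %in% c("pd", "all")) {
    families <- read_family_strings(pipeline_input(config, "families.tsv", "pd"))
    features <- read_feature_table(
      pipeline_input(config, "features.tsv", "pd"), format = "tsv"
    )
    species_map <- read_tsv_strict(
      pipeline_input(config, "species_map.tsv", "pd"),
      c("genome_id", "species")
    )
    cluster_species <- dplyr::distinct(
      dplyr::left_join(features, species_map, by = "genome_id"),
      .data$cluster_id, .data$species
    )
    tree <- midpoint_root(read_newick(pipeline_input(config, "tree.nwk", "pd")))
    pres <- presence_counts(full_calls, cluster_species, families)
    ranking <- pd_ranking(pres, tree)
    stage_log("pd", "classes ranked", nrow(pres$by_class), nrow(ranking))
    write_tsv_prov(ranking, out("pd_ranking.tsv"), th)
    written <- c(written, pd_ranking = out("pd_ranking.tsv"))
  }

  if (stage %in% c("pharm", "all")) {
    summaries <- summarize_counts(full_calls, members,
                                  counting_unit = config$counting_unit)
    stage_log("pharm", "proteins summarized", nrow(summaries), nrow(summaries))
    write_tsv_prov(summaries, out("homolog_counts.tsv"), th,
                   extra = c(counting_unit = config$counting_unit))
    write_tsv_prov(select_split_majority(summaries), out("split_majority.tsv"),
                   th, extra = c(counting_unit = config$counting_unit))
    written <- c(written, homolog_counts = out("homolog_counts.tsv"),
                 split_majority = out("split_majority.tsv"))
  }

  invisible(written)
}
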