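#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

# canonical column order for the 14-column BLAST tabular dialect
# (the 12 standard outfmt-6 columns plus query and subject length)
BLAST14 <- c(
  "query_id", "subject_id", "pct_identity", "aln_len", "mismatches",
  "gap_opens", "q_start", "q_end", "s_start", "s_end", "evalue",
  "bitscore", "q_len", "s_len"
)
BLAST14_NUMERIC <- setdiff(BLAST14, c("query_id", "subject_id"))

#' Read a BLAST tabular alignment file (std 12 columns + qlen + slen)
#'
#' Parses tab-separated local-alignment results in the standard tabular
#' layout extended with query length and subject length, the two extra
#' columns every coverage filter needs. Coordinates are kept 1-based
#' inclusive exactly as in the file and row order is preserved.
#'
#' @param path Path to a tab-separated file. Lines starting with `#` are
#'   ignored.
#' @param columns Character vector naming the 14 columns in file order.
#'   The default is the standard order
#'   `qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#'   evalue bitscore qlen slen`, under the internal names in
#'   [alignment_columns()].
#'
#' @return A tibble with one row per alignment (an `AlignmentRecord`),
#'   validated against the coordinate invariants: `1 <= q_start <= q_end
#'   <= q_len`, `1 <= s_start <= s_end <= s_len`, identity in `[0, 100]`.
#' @export
read_blast_tab <- function(path, columns = alignment_columns()) {
  stopifnot(length(columns) == 14L)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    out <- tibble::as_tibble(stats::setNames(
      c(
        list(character(), character()),
        rep(list(numeric()), 12L)
      ),
      c(columns[1:2], columns[3:14])
    ))
    return(validate_alignments(out[BLAST14]))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 14L)) {
    bad <- line_no[which(nf != 14L)[1]]
    stop(sprintf(
      "malformed alignment row at line %d: expected 14 tab-separated columns, found %d",
      bad, nf[which(nf != 14L)[1]]
    ), call. = FALSE)
  }
  mat <- matrix(unlist(fields), ncol = 14L, byrow = TRUE)
  colnames(mat) <- columns
  out <- tibble::as_tibble(mat)[BLAST14]
  for (col in BLAST14_NUMERIC) {
    v <- suppressWarnings(as.numeric(out[[col]]))
    if (anyNA(v)) {
      bad <- line_no[which(is.na(v))[1]]
      stop(sprintf(
        "malformed alignment row at line %d: non-numeric value '%s' in column %s",
        bad, out[[col]][which(is.na(v))[1]], col
      ), call. = FALSE)
    }
    out[[col]] <- v
  }
  int_cols <- c("aln_len", "mismatches", "gap_opens", "q_start", "q_end",
                "s_start", "s_end", "q_len", "s_len")
  out[int_cols] <- lapply(out[int_cols], as.integer)
  validate_alignments(out)
}

#' Internal column names of the 14-column alignment dialect
#'
#' @return Character vector of length 14, in file order.
#' @export
alignment_columns <- function() BLAST14

#' Validate an alignment table against the coordinate invariants
#'
#' @param records A tibble with the columns of [alignment_columns()]
#'   (the `mismatches`/`gap_opens` columns are optional).
#' @return The input, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_alignments <- function(records) {
  required <- setdiff(BLAST14, c("mismatches", "gap_opens"))
  missing <- setdiff(required, names(records))
  if (length(missing) > 0L) {
    stop("alignment table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  with(records, {
    bad <- which(q_start < 1L | q_start > q_end | q_end > q_len)
    if (length(bad) > 0L) {
      stop(sprintf(
        "invalid query coordinates in alignment row %d (need 1 <= q_start <= q_end <= q_len)",
        bad[1]
      ), call. = FALSE)
    }
    bad <- which(s_start < 1L | s_start > s_end | s_end > s_len)
    if (length(bad) > 0L) {
      stop(sprintf(
        "invalid subject coordinates in alignment row %d (need 1 <= s_start <= s_end <= s_len)",
        bad[1]
      ), call. = FALSE)
    }
    bad <- which(pct_identity < 0 | pct_identity > 100)
    if (length(bad) > 0L) {
      stop(sprintf("percent identity outside [0, 100] in alignment row %d", bad[1]),
           call. = FALSE)
    }
  })
  records
}

#' Read a genome feature table
#'
#' Builds the gene-order table used by neighborhood detection: one row
#' per gene occurrence with its genome, contig, strand, integer
#' feature-order rank along the contig, and the protein cluster it
#' belongs to. Distances between genes are measured in these ranks, not
#' in base pairs.
#'
#' Three input conventions are supported:
#' \describe{
#'   \item{`tsv`}{explicit columns `genome_id`, `contig_id`, `strand`,
#'     `feature_index`, `cluster_id`.}
#'   \item{`id-suffix`}{columns `genome_id`, `contig_id`, `strand`,
#'     `gene_id`, `cluster_id`; the feature index is parsed from the
#'     trailing zero-padded integer of `gene_id` (so
#'     `GUT_GENOME228173_01934` has rank 1934), the convention of
#'     gut-proteome gene identifiers.}
#'   \item{`gff3`}{a standard GFF3 file; CDS features are ranked by start
#'     coordinate within each contig, and the cluster id is taken from
#'     the `cluster` attribute if present, else `ID`. Supply `genome_id`
#'     explicitly (defaults to the file name without extension).}
#' }
#'
#' @param path Input file.
#' @param format One of `"tsv"`, `"id-suffix"`, `"gff3"`.
#' @param genome_id Genome accession used in `gff3` mode.
#' @return A tibble of genome features ordered by
#'   `(genome_id, contig_id, feature_index)`, with `feature_index` unique
#'   within each `(genome_id, contig_id)`.
#' @export
read_feature_table <- function(path, format = c("tsv", "id-suffix", "gff3"),
                               genome_id = NULL) {
  format <- match.arg(format)
  feats <- switch(format,
    "tsv" = {
      tbl <- read_tsv_strict(path, c("genome_id", "contig_id", "strand",
                                     "feature_index", "cluster_id"))
      tbl$feature_index <- as.integer(tbl$feature_index)
      tbl
    },
    "id-suffix" = {
      tbl <- read_tsv_strict(path, c("genome_id", "contig_id", "strand",
                                     "gene_id", "cluster_id"))
      tbl$feature_index <- parse_feature_suffix(tbl$gene_id)
      tbl[c("genome_id", "contig_id", "strand", "feature_index", "cluster_id")]
    },
    "gff3" = read_features_gff3(path, genome_id)
  )
  validate_features(feats)
}

# trailing _<zero-padded integer> of a gene id -> integer rank
parse_feature_suffix <- function(gene_id) {
  m <- regmatches(gene_id, regexpr("_([0-9]+)$", gene_id))
  ok <- lengths(regmatches(gene_id, gregexpr("_[0-9]+$", gene_id))) > 0L
  if (any(!ok)) {
    stop("cannot parse a feature-order suffix from gene id '",
         gene_id[which(!ok)[1]], "'", call. = FALSE)
  }
  as.integer(sub("^_", "", m))
}

read_features_gff3 <- function(path, genome_id = NULL) {
  if (is.null(genome_id)) {
    genome_id <- sub("\\.(gff3?|gff)$", "", basename(path))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == "CDS"]
  if (length(gr) == 0L) stop("no CDS features in ", path, call. = FALSE)
  cluster <- if (!is.null(gr$cluster)) as.character(gr$cluster) else as.character(gr$ID)
  tbl <- tibble::tibble(
    genome_id = genome_id,
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(BiocGenerics::strand(gr)),
    start = BiocGenerics::start(gr),
    cluster_id = cluster
  )
  tbl %>%
    dplyr::group_by(.data$contig_id) %>%
    dplyr::mutate(feature_index = rank(.data$start, ties.method = "first")) %>%
    dplyr::ungroup() %>%
    dplyr::select("genome_id", "contig_id", "strand", "feature_index", "cluster_id")
}

#' Validate a genome feature table
#'
#' @param features Tibble with columns `genome_id`, `contig_id`,
#'   `strand`, `feature_index`, `cluster_id`.
#' @return The table ordered by `(genome_id, contig_id, feature_index)`.
#' @export
validate_features <- function(features) {
  required <- c("genome_id", "contig_id", "strand", "feature_index", "cluster_id")
  missing <- setdiff(required, names(features))
  if (length(missing) > 0L) {
    stop("feature table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(features$strand %in% c("+", "-"))) {
    stop("feature strand must be '+' or '-'", call. = FALSE)
  }
  if (any(features$feature_index < 1L)) {
    stop("feature_index must be a positive integer", call. = FALSE)
  }
  key <- paste(features$genome_id, features$contig_id, features$feature_index,
               sep = "\r")
  if (anyDuplicated(key)) {
    d <- features[duplicated(key), ]
    stop(sprintf(
      "duplicate feature index %d on (%s, %s)",
      d$feature_index[1], d$genome_id[1], d$contig_id[1]
    ), call. = FALSE)
  }
  dplyr::arrange(features, .data$genome_id, .data$contig_id, .data$feature_index)
}

#' Read / write a Newick species tree
#'
#' Thin validated wrappers around [ape::read.tree()] and
#' [ape::write.tree()]. Tip labels must be unique and branch lengths
#' nonnegative; a read-write-read round trip preserves topology, labels,
#' and branch lengths to within 1e-9.
#'
#' @param path Newick file.
#' @return `read_newick()`: an [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(
    ape::read.tree(path),
    error = function(e) stop("failed to parse Newick file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.null(tree)) stop("failed to parse Newick file ", path, call. = FALSE)
  validate_tree(tree)
}

#' @rdname read_newick
#' @param tree An [ape::phylo] tree with branch lengths.
#' @export
write_newick <- function(tree, path) {
  validate_tree(tree)
  ape::write.tree(tree, file = path)
  invisible(path)
}

validate_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) {
    stop("tree tip labels are not unique", call. = FALSE)
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    stop("tree has negative branch lengths", call. = FALSE)
  }
  tree
}

#' Read an ontology as a child-to-parent edge list
#'
#' Builds the term DAG used for annotation propagation (true-path rule)
#' and descendant-closure queries. The edge file is a TSV with columns
#' `child` and `parent` (`is_a`-style edges); an optional term table adds
#' `term`, `namespace`, and `name` columns for terms, including isolated
#' roots that appear in no edge.
#'
#' @param edges_path TSV with columns `child`, `parent`.
#' @param terms_path Optional TSV with columns `term`, `namespace`,
#'   `name`.
#' @return An object of class `gutsplit_ontology`: a list with `terms`
#'   (tibble), `edges` (tibble), and `parents` (named list mapping each
#'   term to its direct parents). The edge set must be acyclic.
#' @export
read_ontology <- function(edges_path, terms_path = NULL) {
  edges <- read_tsv_strict(edges_path, c("child", "parent"))
  terms <- unique(c(edges$child, edges$parent))
  term_tbl <- tibble::tibble(term = terms, namespace = NA_character_,
                             name = NA_character_)
  if (!is.null(terms_path)) {
    tt <- read_tsv_strict(terms_path, c("term", "namespace", "name"))
    extra <- setdiff(tt$term, terms)
    term_tbl <- dplyr::bind_rows(
      tibble::tibble(term = c(terms, extra)) %>%
        dplyr::left_join(tt, by = "term")
    )
  }
  ontology_graph(edges, term_tbl)
}

#' Construct an ontology graph from in-memory tables
#'
#' @param edges Tibble with columns `child`, `parent`.
#' @param terms Optional tibble with columns `term`, `namespace`, `name`.
#' @return A `gutsplit_ontology` object; errors if the edges contain a
#'   cycle or reference no known term.
#' @export
ontology_graph <- function(edges, terms = NULL) {
  edges <- tibble::as_tibble(edges)[c("child", "parent")]
  if (is.null(terms)) {
    terms <- tibble::tibble(term = unique(c(edges$child, edges$parent)),
                            namespace = NA_character_, name = NA_character_)
  }
  terms <- tibble::as_tibble(terms)
  unknown <- setdiff(c(edges$child, edges$parent), terms$term)
  if (length(unknown) > 0L) {
    stop("ontology edges reference unknown terms: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  assert_acyclic(edges, terms$term)
  parents <- split(edges$parent, factor(edges$child, levels = terms$term))
  structure(
    list(terms = terms, edges = edges, parents = parents),
    class = "gutsplit_ontology"
  )
}

# Kahn's algorithm; errors if edges (child -> parent) contain a cycle
assert_acyclic <- function(edges, terms) {
  out_deg <- table(factor(edges$child, levels = terms))
  remaining <- stats::setNames(as.integer(out_deg), terms)
  children_of <- split(edges$child, factor(edges$parent, levels = terms))
  queue <- terms[remaining == 0L]
  seen <- 0L
  while (length(queue) > 0L) {
    node <- queue[[1]]
    queue <- queue[-1]
    seen <- seen + 1L
    for (ch in children_of[[node]]) {
      remaining[[ch]] <- remaining[[ch]] - 1L
      if (remaining[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(terms)) {
    stop("ontology edge set contains a cycle", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.gutsplit_ontology <- function(x, ...) {
  cat(sprintf("gutsplit ontology: %d terms, %d is_a edges\n",
              nrow(x$terms), nrow(x$edges)))
  invisible(x)
}

#' Read protein-to-term annotations
#'
#' @param path TSV with columns `protein`, `term` and optionally
#'   `namespace`.
#' @param ontology Optional `gutsplit_ontology`; annotations to terms
#'   absent from it are collected into the `"unknown_terms"` attribute
#'   (a tibble) rather than silently dropped, and excluded from the
#'   returned mapping.
#' @return A tibble `protein`, `term`, `namespace`, with attribute
#'   `unknown_terms`.
#' @export
read_annotations <- function(path, ontology = NULL) {
  tbl <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", comment.char = "#",
                           check.names = FALSE)
  if (!all(c("protein", "term") %in% names(tbl))) {
    stop("annotation table needs columns 'protein' and 'term'", call. = FALSE)
  }
  if (!"namespace" %in% names(tbl)) tbl$namespace <- NA_character_
  tbl <- tibble::as_tibble(tbl)[c("protein", "term", "namespace")]
  unknown <- tbl[0, ]
  if (!is.null(ontology)) {
    bad <- !(tbl$term %in% ontology$terms$term)
    unknown <- tbl[bad, ]
    if (any(bad)) {
      warning(sprintf("%d annotation(s) reference terms absent from the ontology; see attr(., 'unknown_terms')",
                      sum(bad)), call. = FALSE)
    }
    tbl <- tbl[!bad, ]
  }
  attr(tbl, "unknown_terms") <- unknown
  tbl
}

#' Read protein family description strings
#'
#' @param path TSV with columns `protein`, `family`.
#' @return Named character vector: family description per protein.
#' @export
read_family_strings <- function(path) {
  tbl <- read_tsv_strict(path, c("protein", "family"))
  stats::setNames(tbl$family, tbl$protein)
}

# strict TSV reader: required columns, '#' comments skipped, all character
read_tsv_strict <- function(path, required) {
  tbl <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", comment.char = "#",
                           check.names = FALSE)
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0L) {
    stop(basename(path), " lacks required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(tbl)
}

#' Write a TSV with a provenance header
#'
#' All pipeline outputs are plain TSVs preceded by `#`-prefixed comment
#' lines recording the package version, the thresholds in force, and any
#' extra key-value pairs (e.g. the seed of a simulation).
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @param thresholds Optional `gutsplit_thresholds` stamped into the
#'   header.
#' @param extra Named character vector of extra provenance fields.
#' @return `path`, invisibly.
#' @export
write_tsv_prov <- function(x, path, thresholds = NULL, extra = NULL) {
  header <- sprintf("# gutsplit %s",
                    as.character(utils::packageVersion("gutsplit")))
  if (!is.null(thresholds)) {
    header <- c(header, paste0("# thresholds: ", threshold_fingerprint(thresholds)))
  }
  if (!is.null(extra)) {
    header <- c(header, sprintf("# %s: %s", names(extra), unname(extra)))
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# interval <-> half-open conversion helpers (1-based inclusive on disk)
to_halfopen <- function(start, end) list(start = start - 1L, end = end)
from_halfopen <- function(start, end) list(start = start + 1L, end = end)
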