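test_that("chemicals of interest keep the four drug-related classes only", {
  chem <- tibble::tibble(
    chemical_id = paste0("c", 1:6),
    chem_class = c("Drug", "Drug Class", "Prodrug", "Metabolite",
                   "Biological Intermediate", " Drug ")
  )
  got <- chemicals_of_interest(chem)
  expect_setequal(got, c("c1", "c2", "c3", "c4", "c6"))
  expect_equal(chemicals_of_interest(chem[0, ]), character())
})

test_that("each reaction predicate is individually necessary", {
  interest <- c("drugA", "metB")
  base <- tibble::tibble(
    reaction_id = "r0", reactant_id = "drugA", product_id = "metB",
    controller = "CYP2D6", reaction_type = "Biochemical"
  )
  expect_equal(nrow(filter_reactions(base, interest)), 1L)

  self <- dplyr::mutate(base, product_id = "drugA")
  expect_equal(nrow(filter_reactions(self, interest)), 0L)

  transport <- dplyr::mutate(base, reaction_type = "Transport")
  expect_equal(nrow(filter_reactions(transport, interest)), 0L)

  noctrl <- dplyr::mutate(base, controller = NA_character_)
  expect_equal(nrow(filter_reactions(noctrl, interest)), 0L)
  unknownctrl <- dplyr::mutate(base, controller = "unknown")
  expect_equal(nrow(filter_reactions(unknownctrl, interest)), 0L)

  offtopic <- dplyr::mutate(base, reactant_id = "x", product_id = "y")
  expect_equal(nrow(filter_reactions(offtopic, interest)), 0L)

  # reactant of interest with an unclassified product still passes
  half <- dplyr::mutate(base, product_id = "unclassified")
  expect_equal(nrow(filter_reactions(half, interest)), 1L)
  # output is always a subset of the input
  mixed <- dplyr::bind_rows(base, self, transport, noctrl, offtopic)
  expect_true(all(filter_reactions(mixed, interest)$reaction_id %in%
                    mixed$reaction_id))
})

test_that("identifier mapping is total on mappable genes and loud otherwise", {
  hgnc <- tibble::tibble(hgnc_id = c("HGNC:1", "HGNC:2"),
                         uniprot_id = c("P1", "P2"))
  res <- map_identifiers(hgnc, c("HGNC:1", "HGNC:3"))
  expect_equal(res$mapping$uniprot_id, "P1")
  expect_equal(res$unmapped, "HGNC:3")

  dup <- dplyr::bind_rows(hgnc, tibble::tibble(hgnc_id = "HGNC:1",
                                               uniprot_id = "P9"))
  expect_error(map_identifiers(dup, "HGNC:1"), "HGNC:1")
})

test_that("descendant-closed class membership honors gene-level exclusions", {
  # NUC root with PUR below it; ACOA is an excluded branch off the root
  edges <- tibble::tibble(
    child = c("PUR", "ACOA", "NUC"),
    parent = c("NUC", "ROOT", "ROOT")
  )
  ont <- ontology_graph(edges)
  ann <- tibble::tibble(
    protein = c("inP", "exP", "both"),
    term = c("PUR", "ACOA", "PUR")
  )
  ann <- dplyr::bind_rows(ann, tibble::tibble(protein = "both", term = "ACOA"))
  closed <- propagate_annotations(ont, ann)
  got <- go_class_members(ont, closed, "NUC", excluded_roots = "ACOA")
  expect_setequal(got, "inP") # 'both' removed entirely, gene-level
  expect_setequal(go_class_members(ont, closed, "NUC"), c("inP", "both"))
  expect_error(go_class_members(ont, closed, "NOPE"), "NOPE")
})

test_that("exclusions only ever shrink a class (random DAG set algebra)", {
  set.seed(43)
  for (i in 1:15) {
    ont <- random_dag(sample(6:14, 1))
    terms <- ont$terms$term
    ann <- tibble::tibble(
      protein = sample(paste0("p", 1:8), 20, replace = TRUE),
      term = sample(terms, 20, replace = TRUE)
    )
    closed <- propagate_annotations(ont, ann)
    root <- sample(terms, 1)
    excl <- sample(terms, 2)
    full <- go_class_members(ont, closed, root)
    less <- go_class_members(ont, closed, root, excluded_roots = excl)
    expect_true(all(less %in% full))
    # oracle: closure set algebra via brute-force ancestors
    anc_of <- lapply(stats::setNames(unique(ann$term), unique(ann$term)),
                     oracle_ancestors, ontology = ont)
    prot_terms <- split(ann$term, ann$protein)
    in_closure <- function(p, roots) {
      any(vapply(prot_terms[[p]],
                 function(t) any(roots %in% anc_of[[t]]), logical(1)))
    }
    want <- names(prot_terms)[vapply(names(prot_terms), function(p) {
      in_closure(p, root) && !in_closure(p, excl)
    }, logical(1))]
    expect_setequal(less, want)
  }
})

test_that("homolog categories partition the count space", {
  expect_equal(homolog_category(0, 0), "none")
  expect_equal(homolog_category(3, 0), "full-only")
  expect_equal(homolog_category(0, 200), "split-only")
  expect_equal(homolog_category(24, 26), "split-majority")
  expect_equal(homolog_category(26, 24), "full-majority")
  expect_equal(homolog_category(5, 5), "full-majority") # ties are not split-majority
  # exhaustive and exclusive over a grid
  grid <- expand.grid(n_full = 0:6, n_split = 0:6)
  cats <- homolog_category(grid$n_full, grid$n_split)
  expect_false(anyNA(cats))
  sm <- select_split_majority(
    tibble::tibble(human_id = "x", n_full = 5, n_split = 5)
  )
  expect_equal(nrow(sm), 0L)
})

test_that("count summaries are order-invariant and respect the counting unit", {
  full_calls <- tibble::tibble(
    subject_id = c("H1", "H1", "H2"),
    query_id = c("U1", "U2", "U3")
  )
  members <- tibble::tibble(
    subject_id = c("H1", "H1", "H3", "H3"),
    genome_id = c("g1", "g1", "g2", "g3"),
    neighborhood = c("n1", "n1", "n2", "n3"),
    query_id = c("V1", "V2", "V3", "V3")
  )
  s1 <- summarize_counts(full_calls, members)
  s2 <- summarize_counts(full_calls[c(3, 1, 2), ], members[c(4, 2, 3, 1), ])
  expect_equal(s1, s2)
  expect_equal(s1$n_split[s1$human_id == "H1"], 2L) # distinct clusters
  expect_equal(s1$n_split[s1$human_id == "H3"], 1L) # V3 shared by 2 genomes
  g <- summarize_counts(full_calls, members,
                        counting_unit = "distinct-neighborhoods")
  expect_equal(g$n_split[g$human_id == "H3"], 2L)
  feats <- dplyr::bind_rows(
    feat_row("U1", 1), feat_row("U2", 2), feat_row("U3", 3),
    feat_row("U1", 1, genome_id = "g9", contig_id = "g9_c1")
  )
  gg <- summarize_counts(full_calls, members,
                         counting_unit = "distinct-genomes", features = feats)
  expect_equal(gg$n_full[gg$human_id == "H1"], 2L) # U1 in g1+g9, U2 in g1
  expect_error(summarize_counts(full_calls, members,
                                counting_unit = "distinct-genomes"),
               "feature table")
})

test_that("survey percentage arithmetic is guarded and exact", {
  pct <- homolog_survey_percentages(154, 126, 122)
  expect_equal(round(pct$pct_with_homolog), 82)
  expect_equal(round(pct$pct_full_majority), 97)
  expect_error(homolog_survey_percentages(100, 120, 50))
})
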