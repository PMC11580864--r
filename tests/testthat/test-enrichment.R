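test_that("annotation propagation follows the true-path rule and is idempotent", {
  ont <- ontology_graph(tibble::tibble(child = "B", parent = "A"))
  ann <- tibble::tibble(protein = "p1", term = "B")
  closed <- propagate_annotations(ont, ann)
  expect_setequal(closed$term, c("A", "B"))
  again <- propagate_annotations(ont, closed[c("protein", "term")])
  expect_equal(dplyr::arrange(again, term),
               dplyr::arrange(closed, term))
})

test_that("propagation matches brute-force ancestor BFS on random DAGs", {
  set.seed(17)
  for (i in 1:20) {
    ont <- random_dag(sample(5:15, 1))
    terms <- ont$terms$term
    prots <- paste0("p", 1:6)
    ann <- tibble::tibble(
      protein = sample(prots, 12, replace = TRUE),
      term = sample(terms, 12, replace = TRUE)
    )
    closed <- propagate_annotations(ont, ann)
    for (p in unique(ann$protein)) {
      want <- sort(unique(unlist(
        lapply(ann$term[ann$protein == p], oracle_ancestors, ontology = ont)
      )))
      expect_equal(sort(closed$term[closed$protein == p]), want)
    }
  }
})

test_that("term enrichment p-values are exact hypergeometric tails", {
  # fixed worked case: study 10 of 100, term covers 5 study / 10 background
  prots <- paste0("p", 1:100)
  study <- prots[1:10]
  ann <- tibble::tibble(
    protein = c(study[1:5], prots[11:15]),
    term = "T1", namespace = "biological_process"
  )
  res <- fisher_enrichment(study, prots, ann)
  expect_equal(res$p_value, oracle_hyper_p(5, 10, 10, 100), tolerance = 1e-12)

  # empty term and study == background degenerate to p = 1
  ann0 <- tibble::tibble(protein = "p1", term = "T1")
  res0 <- fisher_enrichment(prots, prots, ann0)
  expect_equal(res0$p_value, 1)

  # random tables against direct summation
  set.seed(19)
  for (i in 1:50) {
    N <- sample(20:200, 1)
    n <- sample(1:(N - 1), 1)
    K <- sample(1:N, 1)
    a <- sample(0:min(K, n), 1)
    if (n - a > N - K) next
    tab <- matrix(c(a, n - a, K - a, N - n - (K - a)), nrow = 2)
    if (any(tab < 0)) next
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    expect_equal(p, oracle_hyper_p(a, n, K, N), tolerance = 1e-10)
  }
})

test_that("study sets outside the background are rejected", {
  ann <- tibble::tibble(protein = "p1", term = "T1")
  expect_error(fisher_enrichment("q9", c("p1", "p2"), ann), "subset")
})

test_that("BH adjustment is the step-up procedure, order preserved", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(1.0), 1.0)
  set.seed(23)
  p <- runif(50)
  adj <- bh_adjust(p)
  o <- sample(50)
  expect_equal(bh_adjust(p[o]), adj[o]) # permutation equivariant
  expect_true(all(adj >= p - 1e-12) && all(adj <= 1))
  expect_true(!is.unsorted(bh_adjust(sort(p))))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the elim variant prunes significant specific terms from ancestors", {
  # leaf L under root R; all study proteins concentrate in L
  ont <- ontology_graph(tibble::tibble(child = "L", parent = "R"))
  prots <- paste0("p", 1:60)
  study <- prots[1:10]
  ann <- tibble::tibble(
    protein = c(study, prots[1:10]),
    term = c(rep("L", 10), rep("R", 10))
  )
  closed <- propagate_annotations(ont, ann)
  classic <- fisher_enrichment(study, prots, closed)
  elim <- fisher_enrichment(study, prots, closed, algorithm = "elim",
                            ontology = ont)
  pr <- function(res, t) res$p_value[res$term == t]
  expect_equal(pr(classic, "L"), pr(elim, "L"))
  expect_gt(pr(elim, "R"), pr(classic, "R")) # root loses the leaf's signal
})

test_that("localization odds ratios report sample and conditional-MLE estimates", {
  prots <- paste0("p", 1:1000)
  group <- prots[1:100]
  flags <- stats::setNames(rep(FALSE, 1000), prots)
  flags[group[1:20]] <- TRUE
  flags[prots[101:110]] <- TRUE
  res <- localization_odds_ratio(group, flags, prots)
  expect_equal(res$sample_or, (20 * 890) / (80 * 10)) # 22.25
  expect_false(res$haldane_corrected)
  expect_true(res$ci_low <= res$odds_ratio && res$odds_ratio <= res$ci_high)
  expect_equal(res$p_value,
               stats::fisher.test(matrix(c(20, 80, 10, 890), 2,
                                         byrow = TRUE))$p.value)

  # equal flag fractions give a sample OR of exactly 1
  flags2 <- stats::setNames(rep(c(TRUE, FALSE), 500), prots)
  res2 <- localization_odds_ratio(prots[1:100], flags2, prots)
  expect_equal(res2$sample_or, 1)

  # zero cells trigger the Haldane-Anscombe correction, flagged
  flags3 <- stats::setNames(rep(FALSE, 1000), prots)
  flags3[group] <- TRUE
  res3 <- localization_odds_ratio(group, flags3, prots)
  expect_true(res3$haldane_corrected)
  expect_true(is.finite(res3$sample_or))

  expect_error(localization_odds_ratio(character(), flags, prots), "empty")
})

test_that("frequency-stratified enrichment detects a planted increasing trend", {
  set.seed(29)
  prots <- paste0("p", 1:900)
  bins <- split(prots, rep(1:3, each = 300))
  names(bins) <- c("low", "mid", "high")
  frac <- c(0.05, 0.25, 0.6)
  flags <- stats::setNames(rep(FALSE, 900), prots)
  for (i in 1:3) {
    flags[bins[[i]][seq_len(300 * frac[i])]] <- TRUE
  }
  res <- stratified_enrichment(bins, flags, prots)
  expect_equal(nrow(res$per_bin), 3L)
  expect_true(all(diff(res$per_bin$sample_or) > 0))
  expect_equal(res$trend, 1)

  # identical bins: equal ORs
  same <- list(a = prots[1:100], b = prots[101:200])
  flags_same <- stats::setNames(rep(c(TRUE, FALSE), length.out = 900), prots)
  res2 <- stratified_enrichment(same, flags_same, prots)
  expect_equal(res2$per_bin$sample_or[1], res2$per_bin$sample_or[2],
               tolerance = 0.2)

  # a single bin degenerates to the plain odds ratio
  res3 <- stratified_enrichment(list(g = prots[1:100]), flags, prots)
  expect_equal(res3$per_bin$odds_ratio,
               localization_odds_ratio(prots[1:100], flags, prots)$odds_ratio)
  expect_true(is.na(res3$trend))

  expect_error(stratified_enrichment(list(a = "p1", b = "p1"), flags, prots),
               "disjoint")
})
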