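test_that("expanding to genomes keeps only genomes with >= 2 clusters", {
  recs <- aln_tbl(
    aln_row("C1", "H1", s_start = 1, s_end = 40),
    aln_row("C2", "H1", s_start = 41, s_end = 80)
  )
  feats <- dplyr::bind_rows(
    feat_row("C1", 1, genome_id = "g1", contig_id = "g1_c1"),
    feat_row("C1", 5, genome_id = "g2", contig_id = "g2_c1"),
    feat_row("C2", 2, genome_id = "g1", contig_id = "g1_c1")
  )
  placed <- expand_to_genomes(recs, feats)
  expect_equal(nrow(placed), 2L)
  expect_setequal(placed$genome_id, "g1")

  # no shared genome
  feats2 <- dplyr::bind_rows(
    feat_row("C1", 1, genome_id = "g1"),
    feat_row("C2", 1, genome_id = "g2", contig_id = "g2_c1")
  )
  expect_equal(nrow(expand_to_genomes(recs, feats2)), 0L)

  # one cluster occurring twice in a genome yields two placed alignments
  feats3 <- dplyr::bind_rows(
    feat_row("C1", 1), feat_row("C1", 9), feat_row("C2", 2)
  )
  placed3 <- expand_to_genomes(recs, feats3)
  expect_equal(sum(placed3$query_id == "C1"), 2L)

  # clusters with no features are dropped with a warning
  expect_warning(expand_to_genomes(recs, feats3[feats3$cluster_id != "C2", ]),
                 "no genome feature")
})

test_that("joint coverage counts union positions exactly", {
  expect_equal(joint_coverage(rbind(c(1, 40), c(35, 80)), 100), 0.80)
  expect_equal(joint_coverage(matrix(numeric(), ncol = 2), 100), 0)
  expect_equal(joint_coverage(rbind(c(1, 100)), 100), 1.0)
  # containment and duplicates collapse
  expect_equal(joint_coverage(rbind(c(10, 90), c(20, 30), c(10, 90)), 100), 0.81)
})

test_that("joint coverage equals the position-bitmask oracle", {
  set.seed(11)
  for (i in 1:300) {
    s_len <- sample(20:500, 1)
    k <- sample(1:8, 1)
    start <- sample(s_len, k, replace = TRUE)
    end <- pmin(s_len, start + sample(0:60, k, replace = TRUE))
    iv <- cbind(start, end)
    expect_equal(joint_coverage(iv, s_len), oracle_joint_coverage(iv, s_len),
                 tolerance = 1e-12)
  }
})

test_that("neighborhoods chain transitively within the gap limit", {
  base <- aln_tbl(
    aln_row("C1", "H1", s_start = 1, s_end = 40),
    aln_row("C2", "H1", s_start = 41, s_end = 80),
    aln_row("C3", "H1", s_start = 20, s_end = 60)
  )
  mk <- function(idx, strands = c("+", "+", "+"), contigs = rep("g1_c1", 3)) {
    placed <- base
    placed$genome_id <- "g1"
    placed$contig_id <- contigs
    placed$strand <- strands
    placed$feature_index <- as.integer(idx)
    placed
  }
  # {3,5} chain, {9} is alone and discarded
  nb <- find_neighborhoods(mk(c(3, 5, 9)), max_gap = 3)
  expect_setequal(nb$query_id, c("C1", "C2"))
  expect_equal(dplyr::n_distinct(nb$neighborhood), 1L)
  # {1,4,7}: 1-7 is too far pairwise but chains through 4
  nb2 <- find_neighborhoods(mk(c(1, 4, 7)), max_gap = 3)
  expect_equal(nrow(nb2), 3L)
  expect_equal(dplyr::n_distinct(nb2$neighborhood), 1L)
  # opposite strands never join
  nb3 <- find_neighborhoods(mk(c(1, 3, 20), strands = c("+", "-", "+")),
                            max_gap = 3)
  expect_equal(nrow(nb3), 0L)
  # different contigs never join
  nb4 <- find_neighborhoods(mk(c(1, 2, 30), contigs = c("g1_c1", "g1_c2", "g1_c1")),
                            max_gap = 3)
  expect_equal(nrow(nb4), 0L)
})

test_that("neighborhood components match brute-force transitive closure", {
  set.seed(13)
  for (i in 1:200) {
    n <- sample(2:12, 1)
    placed <- tibble::tibble(
      query_id = paste0("C", seq_len(n)),
      subject_id = "H1", genome_id = "g1",
      contig_id = sample(c("c1", "c2"), n, replace = TRUE),
      strand = sample(c("+", "-"), n, replace = TRUE),
      feature_index = sample(1:30, n)
    )
    got <- gutsplit:::add_neighborhoods(placed, 3L)
    oracle <- oracle_components(placed$contig_id, placed$strand,
                                placed$feature_index, 3L)
    names(oracle) <- placed$query_id
    got_comp <- got$neighborhood[match(placed$query_id, got$query_id)]
    # same partition: equal labels iff equal oracle components
    expect_equal(outer(got_comp, got_comp, "=="),
                 outer(oracle, oracle, "=="), ignore_attr = TRUE)
  }
})

test_that("split calling accepts planted splits and applies every gate", {
  # planted 3-way split: three adjacent fragments of H1 in one genome
  recs <- aln_tbl(
    aln_row("A1", "H1", s_start = 1, s_end = 100, s_len = 300,
            q_start = 1, q_end = 95, q_len = 110),
    aln_row("A2", "H1", s_start = 101, s_end = 200, s_len = 300,
            q_start = 1, q_end = 95, q_len = 110),
    aln_row("A3", "H1", s_start = 201, s_end = 290, s_len = 300,
            q_start = 1, q_end = 85, q_len = 100)
  )
  feats <- dplyr::bind_rows(
    feat_row("A1", 10), feat_row("A2", 12), feat_row("A3", 15)
  )
  res <- call_split(recs, feats)
  expect_equal(nrow(res$calls), 1L)
  expect_equal(res$calls$n_members, 3L)
  expect_equal(res$calls$joint_coverage, 290 / 300)
  expect_lt(res$calls$max_member_coverage, 0.7)

  # jointly covering but one member individually >= 70%: routed away
  recs2 <- aln_tbl(
    aln_row("B1", "H2", s_start = 1, s_end = 150, s_len = 200,
            q_start = 1, q_end = 150, q_len = 160),
    aln_row("B2", "H2", s_start = 140, s_end = 200, s_len = 200,
            q_start = 1, q_end = 85, q_len = 100)
  )
  feats2 <- dplyr::bind_rows(feat_row("B1", 1), feat_row("B2", 2))
  expect_equal(nrow(call_split(recs2, feats2)$calls), 0L)

  # feature distance 4 is out of reach
  feats3 <- dplyr::bind_rows(feat_row("A1", 10), feat_row("A2", 14),
                             feat_row("A3", 18))
  expect_equal(nrow(call_split(recs, feats3)$calls), 0L)
})

test_that("contaminated members are removed at the last gate and the rest rechecked", {
  cutoff <- structure(list(cutoff = 51.8), class = "gutsplit_cutoff")
  pair <- aln_tbl(
    aln_row("A1", "H1", s_start = 1, s_end = 120, s_len = 300,
            q_start = 1, q_end = 110, q_len = 120),
    aln_row("A2", "H1", s_start = 121, s_end = 240, s_len = 300,
            q_start = 1, q_end = 110, q_len = 120)
  )
  contam <- aln_row("A3", "H1", pct_identity = 95, s_start = 241, s_end = 300,
                    s_len = 300, q_start = 1, q_end = 85, q_len = 100)
  feats <- dplyr::bind_rows(feat_row("A1", 1), feat_row("A2", 3),
                            feat_row("A3", 5))
  # pair still jointly covers 240/300 = 0.8 after the contaminant is removed
  res <- call_split(dplyr::bind_rows(pair, contam), feats, cutoff = cutoff)
  expect_equal(nrow(res$calls), 1L)
  expect_setequal(res$members$query_id, c("A1", "A2"))

  # but when the contaminant was load-bearing, the remainder fails coverage
  pair_short <- aln_tbl(
    aln_row("A1", "H1", s_start = 1, s_end = 95, s_len = 300,
            q_start = 1, q_end = 90, q_len = 100),
    aln_row("A2", "H1", s_start = 96, s_end = 190, s_len = 300,
            q_start = 1, q_end = 90, q_len = 100)
  )
  res2 <- call_split(dplyr::bind_rows(pair_short, contam), feats,
                     cutoff = cutoff)
  expect_equal(nrow(res2$calls), 0L)
})

test_that("removing an articulation member disconnects or undercovers a call", {
  # members at ranks 1,4,7: rank 4 is articulation-critical
  recs <- aln_tbl(
    aln_row("A1", "H1", s_start = 1, s_end = 100, s_len = 300,
            q_start = 1, q_end = 95, q_len = 110),
    aln_row("A2", "H1", s_start = 101, s_end = 200, s_len = 300,
            q_start = 1, q_end = 95, q_len = 110),
    aln_row("A3", "H1", s_start = 201, s_end = 290, s_len = 300,
            q_start = 1, q_end = 85, q_len = 100)
  )
  feats <- dplyr::bind_rows(feat_row("A1", 1), feat_row("A2", 4),
                            feat_row("A3", 7))
  expect_equal(nrow(call_split(recs, feats)$calls), 1L)
  without_mid <- recs[-2, ]
  res <- call_split(without_mid, feats)
  expect_equal(nrow(res$calls), 0L)
})

test_that("no split member individually reaches the full-length threshold", {
  sim <- generate_synthetic(small_params(seed = 21))
  fl <- call_full_length(sim$alignments)
  sp <- call_split(sim$alignments, sim$features, cutoff = fl$cutoff)
  expect_true(all(sp$members$member_cov < 0.7))
  full_keys <- paste(fl$calls$subject_id, fl$calls$query_id)
  member_keys <- paste(sp$members$subject_id, sp$members$query_id)
  expect_false(any(member_keys %in% full_keys))
})
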