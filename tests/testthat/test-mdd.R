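test_that("group scheme covers the 20 amino acids exactly once", {
  sch <- aa_group_scheme()
  expect_equal(sort(names(sch)), sort(c("A","C","D","E","F","G","H","I","K","L",
                                        "M","N","P","Q","R","S","T","V","W","Y")))
  expect_equal(unname(sch["K"]), "basic")
  expect_equal(unname(sch["G"]), "polar")
  expect_error(aa_group_scheme(polar = c("G", "S")), "cover each")
  # overriding is allowed as long as coverage holds
  sch2 <- aa_group_scheme(polar = c("G","S","T","Q","N"),
                          hydrophobic = c("A","V","L","I","M","P","C"))
  expect_equal(unname(sch2["C"]), "hydrophobic")
})

test_that("contingency tables count property-group pairs and skip X", {
  frags <- rep(paste0(strrep("A", 9), "G", "C", strrep("A", 3), "K",
                      strrep("A", 6)), 10)   # G at -1, K at +4
  tab <- build_contingency(frags, -1, 4)
  expect_s3_class(tab, "mdd_contingency")
  expect_equal(tab$counts["polar", "basic"], 10L)
  expect_equal(tab$total, 10L)
  expect_equal(sum(tab$counts), tab$total)

  # X at a tested offset drops the fragment from that table
  fx <- paste0(strrep("A", 9), "G", "C", strrep("A", 3), "X", strrep("A", 6))
  tab2 <- build_contingency(c(frags, fx), -1, 4)
  expect_equal(tab2$total, 10L)
  tab3 <- build_contingency(c(frags, fx), -1, 2)
  expect_equal(tab3$total, 11L)

  expect_error(build_contingency(frags, 3, 3), "distinct")
  expect_error(build_contingency(frags, 0, 3), "offset 0")
  expect_error(build_contingency(frags, 3, 99), "outside window")
})

test_that("chi-square matches the brute-force oracle and its invariances", {
  # exact independence (outer product of margins) gives exactly 0
  ind <- outer(c(10, 20, 5, 5, 10), c(8, 2, 4, 4, 2))
  expect_identical(chi_square(ind), 0)

  # hand-derived two-diagonal table
  diag2 <- matrix(0, 5, 5); diag2[1, 1] <- 10; diag2[2, 2] <- 10
  expect_equal(chi_square(diag2), 20)

  set.seed(42)
  for (i in 1:200) {
    tab <- matrix(rpois(25, lambda = sample(1:8, 1)), 5, 5)
    if (sum(tab) == 0) next
    expect_equal(chi_square(tab), chi2_oracle(tab), tolerance = 1e-9)
    # invariance under simultaneous row and column permutations
    pr <- sample(5); pc <- sample(5)
    expect_equal(chi_square(tab[pr, pc]), chi_square(tab), tolerance = 1e-9)
  }
  expect_error(chi_square(matrix(0, 5, 5)), "empty")
})

test_that("select_split recovers planted multi-position motifs", {
  # between-position dependence exists only when the latent motif class
  # touches several positions; the three-rule mixture world provides it
  hits <- vapply(1:10, function(s) {
    pos <- generate_fragments(three_rule_config(2000 + s, n_pos = 300,
                                                n_neg = 0))
    sp <- select_split(pos$fragment)
    !is.null(sp) && paste0(sp$offset, ":", sp$group) %in% three_rule_planted
  }, logical(1))
  expect_gte(sum(hits), 8L)

  # the winning offset also maximizes the exhaustively computed D(i)
  pos <- generate_fragments(three_rule_config(77, n_pos = 300, n_neg = 0))
  sp <- select_split(pos$fragment)
  codes <- mddpalm:::group_code_matrix(pos$fragment, aa_group_scheme())
  dep <- mddpalm:::pairwise_dependence(codes, mdd_config())
  D <- rowSums(dep$chi)
  eligible <- apply(dep$chi, 1, max) > 34.3
  expect_equal(sp$offset, dep$offsets[eligible][which.max(D[eligible])])
  expect_equal(sp$dependence, max(D[eligible]))
})

test_that("select_split returns none without strong dependence", {
  # single fragment (below min_subgroup_size)
  expect_null(select_split(random_fragments(1, seed = 1)))
  # uniform fragments at a stringent threshold: P(chi2_16 > 60) ~ 5e-7,
  # so even 190 position pairs essentially never qualify
  for (s in 1:5) {
    expect_null(select_split(random_fragments(60, seed = 3000 + s),
                             config = mdd_config(chi2_threshold = 60)))
  }
})

test_that("mdd_cluster partitions its input and respects the size guard", {
  expect_length(mdd_leaves(mdd_cluster(random_fragments(50, seed = 2),
                                       config = mdd_config(max_cluster_size = 100))),
                1L)

  for (s in 1:8) {
    ds <- generate_fragments(three_rule_config(4000 + s, n_pos = 250,
                                               n_neg = 0))
    tree <- mdd_cluster(ds$fragment,
                        config = mdd_config(max_cluster_size = 100))
    leaves <- mdd_leaves(tree)
    members <- unlist(leaves, use.names = FALSE)
    expect_equal(sort(members), seq_len(250))       # disjoint + exhaustive
    expect_equal(names(leaves), paste0("Palm", seq_along(leaves)))
    # every split lies at a planted offset with enough signal, or none at all
    sp <- mddpalm:::mdd_splits(tree)
    if (nrow(sp) > 0) {
      expect_true(all(paste0(sp$offset, ":", sp$group) %in%
                      three_rule_planted | sp$dependence > 0))
    }
  }
})

test_that("assign_subgroup routes by split group, X to the rest branch", {
  ds <- generate_fragments(three_rule_config(5, n_pos = 300, n_neg = 0))
  tree <- mdd_cluster(ds$fragment, config = mdd_config(max_cluster_size = 120))
  leaves <- mdd_leaves(tree)
  expect_gt(length(leaves), 1L)

  # routing training fragments reproduces their training leaf
  routed <- assign_subgroup(ds$fragment, tree)
  for (id in names(leaves)) {
    expect_true(all(routed[leaves[[id]]] == id))
  }

  # single-leaf tree routes everything to that leaf
  tree1 <- mdd_cluster(random_fragments(30, seed = 3),
                       config = mdd_config(max_cluster_size = 100))
  expect_true(all(assign_subgroup(random_fragments(10, seed = 4), tree1) ==
                  "Palm1"))

  # forced routing: fragment carrying the split group goes to the match side
  root <- tree$root
  if (root$type == "split") {
    scheme <- aa_group_scheme()
    res <- names(scheme)[scheme == root$group][1]
    frag <- strsplit(random_fragments(1, seed = 9), "")[[1]]
    frag[root$offset + 11] <- res
    match_ids <- unlist(lapply(list(root$match), function(nd) {
      ids <- c(); walk <- function(x) {
        if (x$type == "leaf") ids <<- c(ids, x$id)
        else { walk(x$match); walk(x$rest) }
      }; walk(nd); ids
    }))
    expect_true(assign_subgroup(paste(frag, collapse = ""), tree) %in% match_ids)
    # X at the split offset goes to the rest branch
    frag[root$offset + 11] <- "X"
    expect_false(assign_subgroup(paste(frag, collapse = ""), tree) %in% match_ids)
  }
})

test_that("tree JSON round-trip preserves structure and routing", {
  ds <- generate_fragments(three_rule_config(6, n_pos = 250, n_neg = 0))
  tree <- mdd_cluster(ds$fragment, config = mdd_config(max_cluster_size = 100))
  path <- tempfile(fileext = ".json")
  write_mdd_tree(tree, path)
  back <- read_mdd_tree(path)
  probe <- random_fragments(50, seed = 10)
  expect_identical(assign_subgroup(probe, back), assign_subgroup(probe, tree))
})

test_that("composition enrichment flags planted residues and is antisymmetric", {
  # identical sets: nothing significant
  frs <- random_fragments(100, seed = 12)
  rep0 <- composition_enrichment(frs, frs)
  expect_true(all(rep0$status == "ns"))

  # K planted at +4 in positives (p = 0.8) vs uniform background
  cfg <- synthetic_config(n = 10, n_pos = 500, n_neg = 0,
                          rules = list(list(rules = list(
                            motif_rule(4, residues = "K", prob = 0.8)),
                            weight = 1)), seed = 13)
  pos <- generate_fragments(cfg)$fragment
  neg <- random_fragments(500, seed = 14)
  rep1 <- composition_enrichment(pos, neg, alpha = 0.01)
  hit <- rep1[rep1$offset == 4 & rep1$residue == "K", ]
  expect_equal(hit$status, "enriched")
  expect_lt(hit$p_value, 0.01)
  # p-value agrees with the independent z-test oracle
  k1 <- round(hit$freq_pos * 500); k2 <- round(hit$freq_neg * 500)
  expect_equal(hit$p_value, ztest_oracle(k1, 500, k2, 500), tolerance = 1e-8)

  # swapping the sets swaps enriched and depleted
  rep2 <- composition_enrichment(neg, pos, alpha = 0.01)
  sig <- rep1$status != "ns"
  expect_equal(rep2$status[sig],
               ifelse(rep1$status[sig] == "enriched", "depleted", "enriched"))
})
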