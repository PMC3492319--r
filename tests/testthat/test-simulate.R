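test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_leaves = 8, mean_markers_per_branch = 2, seed = 123)
  s1 <- simulate_tree_and_markers(cfg)
  s2 <- simulate_tree_and_markers(cfg)
  expect_identical(write_newick_annotated(s1$tree),
                   write_newick_annotated(s2$tree))
  expect_identical(s1$catalog$name, s2$catalog$name)
  g1 <- genotype_panel(s1$tree, s1$catalog, cfg)
  g2 <- genotype_panel(s2$tree, s2$catalog, cfg)
  expect_identical(g1$state, g2$state)
})

test_that("a single-leaf configuration yields a single-branch tree", {
  s <- simulate_tree_and_markers(sim_config(n_leaves = 1, seed = 4))
  expect_equal(nrow(s$tree$nodes), 2L)
})

test_that("per-branch marker counts follow the configured Poisson mean", {
  # many branches across seeds: empirical mean within 3 standard errors
  counts <- integer(0)
  for (seed in 1:6) {
    s <- simulate_tree_and_markers(sim_config(n_leaves = 20,
                                              mean_markers_per_branch = 3,
                                              seed = seed))
    branches <- setdiff(s$tree$nodes$id, ht_root(s$tree))
    counts <- c(counts, lengths(s$tree$markers[branches]))
  }
  expect_gte(length(counts), 200L)
  se <- sqrt(3 / length(counts))
  expect_lt(abs(mean(counts) - 3), 3 * se)
})

test_that("outgroup alleles equal the ancestral root state of every marker", {
  s <- simulate_tree_and_markers(sim_config(n_leaves = 6, seed = 9))
  expect_identical(s$outgroup$allele,
                   s$catalog$ancestral[match(s$outgroup$site, s$catalog$name)])
})

test_that("complete panels are perfectly consistent with the true tree", {
  for (seed in 1:5) {
    cfg <- sim_config(n_leaves = 8, mean_markers_per_branch = 3, seed = seed)
    s <- simulate_tree_and_markers(cfg)
    gm <- genotype_panel(s$tree, s$catalog, cfg)
    # each sample derived exactly at the markers on its root-to-leaf path
    att <- stats::setNames(gm$samples$prior_haplogroup, gm$samples$sample_id)
    for (i in seq_len(nrow(gm$samples))) {
      leaf <- ht_node_by_name(s$tree, att[[i]])
      path_mk <- unlist(s$tree$markers[ht_path_to_root(s$tree, leaf)])
      expect_setequal(gm$markers[gm$state[i, ] == "D"], path_mk)
    }
    # and the perfect phylogeny built from the panel matches the true tree
    # (marker-less true branches are invisible to the panel and compared
    # after contraction)
    built <- build_perfect_phylogeny(gm)
    truth <- s$tree
    for (smp in seq_len(nrow(gm$samples))) {
      leaf <- ht_node_by_name(truth, gm$samples$prior_haplogroup[smp])
      truth$samples[[leaf]] <- c(truth$samples[[leaf]],
                                 gm$samples$sample_id[smp])
    }
    bare <- setdiff(truth$nodes$id[lengths(truth$markers) == 0L],
                    ht_root(truth))
    truth <- ht_contract(truth, bare)
    expect_identical(tree_nontrivial_clades(built),
                     tree_nontrivial_clades(truth))
  }
})

test_that("no-call masking hits the configured rate within binomial tolerance", {
  cfg <- sim_config(n_leaves = 12, mean_markers_per_branch = 4,
                    no_call_rate = 0.3, seed = 21)
  s <- simulate_tree_and_markers(cfg)
  gm <- genotype_panel(s$tree, s$catalog, cfg)
  n <- length(gm$state)
  frac <- mean(gm$state == "N")
  tol <- 4 * sqrt(0.3 * 0.7 / n)
  expect_lt(abs(frac - 0.3), tol)
})

test_that("injected triallelic sites polarize to exactly two events", {
  found <- 0L
  for (seed in 11:25) {
    cfg <- sim_config(n_leaves = 7, mean_markers_per_branch = 2,
                      triallelic_rate = 0.25, seed = seed)
    s <- simulate_tree_and_markers(cfg)
    gm <- genotype_panel(s$tree, s$catalog, cfg)
    inj <- attr(gm, "injections")
    inj <- inj[inj$type == "triallelic", , drop = FALSE]
    if (nrow(inj) == 0L) next
    tree <- s$tree
    att <- stats::setNames(gm$samples$prior_haplogroup, gm$samples$sample_id)
    for (i in seq_len(nrow(gm$samples))) {
      leaf <- ht_node_by_name(tree, att[[i]])
      tree$samples[[leaf]] <- c(tree$samples[[leaf]], gm$samples$sample_id[i])
    }
    for (m in unique(inj$marker)) {
      calls <- gm$raw_allele[, m]
      names(calls) <- rownames(gm$state)
      anc <- s$catalog$ancestral[s$catalog$name == m]
      ev <- polarize_multiallelic(m, calls, anc, tree)
      expect_equal(nrow(ev), 2L)
      found <- found + 1L
    }
  }
  expect_gte(found, 3L)
})

test_that("recurrent markers are rejected as incompatible during placement", {
  found <- 0L
  for (seed in 31:40) {
    cfg <- sim_config(n_leaves = 7, mean_markers_per_branch = 2,
                      recurrent_site_rate = 0.2, seed = seed)
    s <- simulate_tree_and_markers(cfg)
    gm <- genotype_panel(s$tree, s$catalog, cfg)
    inj <- attr(gm, "injections")
    inj <- inj[inj$type == "recurrent", , drop = FALSE]
    if (nrow(inj) == 0L) next
    pruned <- prune_backbone(s$tree, 0, seed = seed)$backbone
    res <- place_markers_on_backbone(pruned, gm)
    truth <- attach_samples(s$tree, gm$samples)
    true_clades <- ht_clade_samples(truth)[setdiff(truth$nodes$id,
                                                   ht_root(truth))]
    for (m in unique(inj$marker)) {
      mode <- res$placements$mode[res$placements$marker == m]
      # a second origin whose combined derived set still nests with every
      # true clade is undetectable homoplasy; a crossing pattern must be
      # rejected as a candidate recurrent mutation
      D <- derived_set(gm, m)$members
      crossing <- any(vapply(true_clades, function(cl) {
        ix <- length(intersect(cl, D))
        ix > 0L && ix < length(cl) && ix < length(D)
      }, TRUE))
      if (crossing) {
        expect_equal(mode, "unplaced_incompatible")
        found <- found + 1L
      }
    }
  }
  expect_gte(found, 2L)
})
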