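ds <- function(members, observed) list(members = members, observed = observed)

test_that("pairwise compatibility is the nested-or-disjoint test", {
  u <- as.character(1:4)
  expect_true(are_compatible(ds(c("1", "2"), u), ds(c("1", "2", "3"), u)))
  expect_false(are_compatible(ds(c("1", "2"), u), ds(c("2", "3"), u)))
  expect_true(are_compatible(ds(c("1", "2"), u), ds(c("3", "4"), u)))
  # restriction to jointly observed samples can rescue a pair
  expect_true(are_compatible(ds(c("1", "2"), c("1", "2", "3")),
                             ds(c("2", "3"), c("2", "3", "4"))))
})

test_that("compatibility agrees with the gamete truth table on random pairs", {
  set.seed(5)
  u <- as.character(1:6)
  for (rep in 1:200) {
    A <- sample(u, sample.int(5, 1))
    B <- sample(u, sample.int(5, 1))
    # enumeration oracle: the pair is incompatible iff samples exhibiting
    # (derived, ancestral), (ancestral, derived) and (derived, derived)
    # all occur -- the directed three-gamete condition
    g_dd <- length(intersect(A, B)) > 0L
    g_da <- length(setdiff(A, B)) > 0L
    g_ad <- length(setdiff(B, A)) > 0L
    expect_equal(are_compatible(ds(A, u), ds(B, u)), !(g_dd && g_da && g_ad))
  }
})

test_that("perfect phylogeny matches exhaustive topology search on random matrices", {
  set.seed(101)
  for (rep in 1:60) {
    n <- sample(3:6, 1)
    m <- sample(4:10, 1)
    gm <- random_compatible_matrix(n, m)
    expect_true(oracle_has_perfect_phylogeny(gm))
    tr <- build_perfect_phylogeny(gm)
    # clades of the built tree == clade family of the minimal realizing tree
    expect_identical(tree_nontrivial_clades(tr), oracle_minimal_clades(gm))
    # every derived set is exactly one branch's leaf set
    cl <- ht_clade_samples(tr)
    for (mk in gm$markers) {
      d <- sort(derived_set(gm, mk)$members)
      if (length(d) == 0L) next
      nd <- ht_marker_node(tr, mk)
      expect_identical(sort(cl[[nd]]), d)
    }
  }
})

test_that("incompatible matrices are rejected, naming an offending pair", {
  set.seed(202)
  for (rep in 1:30) {
    gm <- random_incompatible_matrix(sample(4:6, 1), sample(3:6, 1))
    expect_false(oracle_has_perfect_phylogeny(gm))
    expect_error(build_perfect_phylogeny(gm), "incompatible marker pair")
  }
})

test_that("single-sample and equivalence edge cases build correctly", {
  st <- matrix("D", 1, 4, dimnames = list("s1", paste0("k", 1:4)))
  tr <- build_perfect_phylogeny(genotype_matrix(st))
  expect_equal(nrow(tr$nodes), 2L)  # root + one branch carrying everything
  expect_setequal(tr$markers[[2]], paste0("k", 1:4))
  expect_equal(tr$samples[[2]], "s1")
})

test_that("stem and split structure emerges from shared and private markers", {
  # two chromosomes sharing 19 of 23 markers: stem of 19, two private sets
  shared <- paste0("sh", 1:19)
  only_a <- paste0("pa", 1:4)
  st <- matrix("A", 2, 23, dimnames = list(c("a", "b"), c(shared, only_a)))
  st[, shared] <- "D"
  st["a", only_a] <- "D"
  tr <- build_perfect_phylogeny(genotype_matrix(st))
  stem <- ht_marker_node(tr, "sh1")
  expect_setequal(tr$markers[[stem]], shared)
  priv <- ht_marker_node(tr, "pa1")
  expect_setequal(tr$markers[[priv]], only_a)
  expect_equal(tr$nodes$parent[priv], stem)
  expect_equal(ht_clade_samples(tr)[[priv]], "a")
  expect_true("b" %in% tr$samples[[stem]])
})

make_poly_tree <- function() {
  tr <- haplo_tree("Root")
  p <- ht_add_node(tr, 1L, name = "B2", markers = "M182")
  tr <- p$tree
  for (nm in c("B2a", "B2b", "B2c")) {
    mk <- c(B2a = "M150", B2b = "M112", B2c = "P6")[[nm]]
    tr <- ht_add_node(tr, p$id, name = nm, markers = mk)$tree
  }
  tr
}

poly_matrix <- function(m112_in = c("y2", "y3")) {
  mks <- c("M182", "M150", "M112", "P6")
  st <- matrix("A", 3, 4, dimnames = list(c("y1", "y2", "y3"), mks))
  st[, "M182"] <- "D"
  st["y1", "M150"] <- "D"
  st[m112_in, "M112"] <- "D"
  st["y3", "P6"] <- "D"
  genotype_matrix(st, data.frame(sample_id = c("y1", "y2", "y3"),
                                 prior_haplogroup = c("B2a", "B2b", "B2c"),
                                 origin = NA, stringsAsFactors = FALSE))
}

test_that("a trifurcation resolves by repositioning a marker shared by two children", {
  gm <- poly_matrix()
  tr <- attach_samples(make_poly_tree(), gm$samples)
  b2 <- ht_node_by_name(tr, "B2")
  expect_equal(length(ht_children(tr, b2)), 3L)
  out <- resolve_polytomy(tr, "M112", gm)
  b2 <- ht_node_by_name(out, "B2")
  expect_equal(length(ht_children(out, b2)), 2L)
  nd <- ht_marker_node(out, "M112")
  expect_setequal(sort(ht_clade_samples(out)[[nd]]), c("y2", "y3"))
  # oracle: rebuilding from scratch gives the same clades
  scratch <- build_perfect_phylogeny(gm)
  expect_identical(tree_nontrivial_clades(out), tree_nontrivial_clades(scratch))
})

test_that("a marker derived in a single polytomy child moves nothing", {
  gm <- poly_matrix(m112_in = "y2")
  tr <- attach_samples(make_poly_tree(), gm$samples)
  out <- resolve_polytomy(tr, "M112", gm)
  expect_identical(write_newick_annotated(out), write_newick_annotated(tr))
})

test_that("a marker covering all polytomy children is refused", {
  gm <- poly_matrix(m112_in = c("y1", "y2", "y3"))
  tr <- attach_samples(make_poly_tree(), gm$samples)
  expect_error(resolve_polytomy(tr, "M112", gm), "above")
})

test_that("random polytomies resolve to the scratch-built perfect phylogeny", {
  set.seed(77)
  for (rep in 1:20) {
    gm <- random_compatible_matrix(sample(4:6, 1), sample(5:9, 1))
    full <- build_perfect_phylogeny(gm)
    # coarsen: contract one internal node, lump its markers on the parent,
    # then let placement rediscover the structure
    internal <- setdiff(full$nodes$id[vapply(full$nodes$id, function(id)
      length(ht_children(full, id)) > 0L, TRUE)], ht_root(full))
    if (length(internal) == 0L) next
    coarse <- ht_contract(full, sample(internal, 1L), markers = "parent")
    res <- place_markers_on_backbone(coarse, gm)
    expect_identical(tree_nontrivial_clades(res$tree),
                     tree_nontrivial_clades(full))
  }
})

test_that("placement is idempotent and preserves backbone clades", {
  fx <- get_fixture()
  res1 <- place_markers_on_backbone(attach_samples(fx$backbone, fx$gm$samples),
                                    fx$gm, fx$catalog)
  res2 <- place_markers_on_backbone(res1$tree, fx$gm, fx$catalog)
  expect_identical(write_newick_annotated(res2$tree),
                   write_newick_annotated(res1$tree))
  # refinement monotonicity
  bcl <- ht_clade_samples(attach_samples(fx$backbone, fx$gm$samples))
  rcl <- ht_clade_samples(res1$tree)
  rkeys <- vapply(rcl, paste, "", collapse = "\r")
  for (cl in bcl[lengths(bcl) > 0L])
    expect_true(paste(cl, collapse = "\r") %in% rkeys)
  # marker conservation: every input marker on exactly one branch or rejected
  on_tree <- unlist(res1$tree$markers)
  expect_equal(anyDuplicated(on_tree), 0L)
  rejected <- res1$placements$marker[res1$placements$mode == "unplaced_incompatible"]
  expect_setequal(union(intersect(fx$gm$markers, on_tree), rejected),
                  fx$gm$markers)
})

test_that("no-call-only support flags branches as putative", {
  # one clade fully untyped at its defining marker
  st <- matrix("A", 4, 3, dimnames = list(paste0("s", 1:4), c("t", "u", "v")))
  st[c("s1", "s2"), "t"] <- "D"
  st[c("s3", "s4"), "u"] <- "D"
  st[c("s3", "s4"), "v"] <- "N"
  tr <- haplo_tree("Root")
  a <- ht_add_node(tr, 1L, name = "X", markers = "t"); tr <- a$tree
  b <- ht_add_node(tr, 1L, name = "Y", markers = c("u", "v")); tr <- b$tree
  tr$samples[[a$id]] <- c("s1", "s2")
  tr$samples[[b$id]] <- c("s3", "s4")
  gm <- genotype_matrix(st)
  out <- flag_putative(tr, gm)
  expect_false(out$nodes$putative[ht_node_by_name(out, "X")])
  expect_false(out$nodes$putative[ht_node_by_name(out, "Y")])  # u supports it
  st2 <- st; st2[, "u"] <- "N"
  out2 <- flag_putative(tr, genotype_matrix(st2))
  expect_true(out2$nodes$putative[ht_node_by_name(out2, "Y")])
})
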