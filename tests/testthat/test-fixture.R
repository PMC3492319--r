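test_that("the packaged fixture reproduces the study panel dimensions", {
  fx <- get_fixture()
  expect_equal(nrow(fx$gm$samples), 51L)          # panel size
  expect_equal(nrow(fx$catalog), 227L)            # 22 + 146 + 59 markers
  expect_equal(sum(fx$catalog$source_tag == "new-Table1"), 22L)
  expect_equal(sum(fx$catalog$source_tag == "prior-146"), 146L)
  expect_equal(sum(fx$catalog$source_tag == "backbone-59"), 59L)
})

test_that("per-clade panels carry the documented marker and sample counts", {
  fx <- get_fixture()
  typed_in <- function(markers, samples)
    all(fx$gm$state[samples, markers] != "N")
  # 32 candidate markers in the four basal-branch chromosomes
  expect_equal(length(fx$panels$A1b_candidates), 32L)
  expect_true(typed_in(fx$panels$A1b_candidates, fx$panels$A1b_samples))
  # 23 markers in the two A1a chromosomes
  expect_equal(length(fx$panels$A1a_markers), 23L)
  expect_true(typed_in(fx$panels$A1a_markers, fx$panels$A1a_samples))
  # 41 markers in ten A3 subjects
  expect_equal(length(fx$panels$A3_markers), 41L)
  expect_equal(length(fx$panels$A3_samples), 10L)
  expect_true(typed_in(fx$panels$A3_markers, fx$panels$A3_samples))
  # 33 markers in 13 haplogroup B chromosomes
  expect_equal(length(fx$panels$B_markers), 33L)
  expect_equal(length(fx$panels$B_samples), 13L)
  expect_true(typed_in(fx$panels$B_markers, fx$panels$B_samples))
  # untyped combinations are no-calls: clade-panel markers untyped elsewhere
  expect_true(all(fx$gm$state[fx$panels$A1b_samples, c("V65", "V254")] == "N"))
  expect_true(all(fx$gm$state[fx$panels$B_samples, fx$panels$A1b_candidates] == "N"))
})

test_that("one chromosome is derived at P114; three are ancestral at the basal split", {
  fx <- get_fixture()
  expect_equal(derived_set(fx$gm, "P114")$members, "4")
  # samples 1-3: ancestral at P114 and at the sister-macrohaplogroup markers
  for (s in c("1", "2", "3")) {
    expect_equal(unname(fx$gm$state[s, "P114"]), "A")
    expect_equal(unname(fx$gm$state[s, "V221"]), "A")
  }
  # all four carry the basal-branch stem markers
  expect_true(all(fx$gm$state[as.character(1:4), c("V148", "V161")] == "D"))
})

test_that("fixture genotype files round-trip byte-identically", {
  dir <- tempfile()
  paths <- write_fixture_files(dir)
  gm2 <- read_genotype_matrix(paths[["matrix"]], paths[["raw"]])
  f2 <- tempfile(); r2 <- tempfile()
  write_genotype_matrix(gm2, f2, r2)
  expect_identical(readLines(paths[["matrix"]]), readLines(f2))
  expect_identical(readLines(paths[["raw"]]), readLines(r2))
  cat2 <- parse_marker_table(paths[["catalog"]])
  c2 <- tempfile()
  write_marker_table(cat2, c2)
  expect_identical(readLines(paths[["catalog"]]), readLines(c2))
})

test_that("the refined tree equals the encoded figure topology", {
  fx <- get_fixture()
  res <- get_refined()
  expect_true(ht_clade_equal(res$tree, fx$figure_tree))
  # marker content agrees branch by branch (V161 replaced by its events)
  for (id in fx$figure_tree$nodes$id) {
    nm <- fx$figure_tree$nodes$name[id]
    rid <- ht_node_by_name(res$tree, nm)
    expect_false(is.na(rid))
    expect_setequal(res$tree$markers[[rid]], fx$figure_tree$markers[[id]])
  }
})

test_that("collapsed triangle substructures are preserved and never counted", {
  fx <- get_fixture()
  res <- get_refined()
  rep <- get_report()
  for (nm in c("B-M108.1", "B-50f2(P)")) {
    id <- ht_node_by_name(res$tree, nm)
    expect_gt(res$tree$nodes$collapsed[id], 0L)
    expect_false(nm %in% rep$new_haplogroups$name)
  }
  expect_equal(res$tree$nodes$collapsed[ht_node_by_name(res$tree, "B-M108.1")], 2L)
  expect_equal(res$tree$nodes$collapsed[ht_node_by_name(res$tree, "B-50f2(P)")], 8L)
})

test_that("branches without a positive control are flagged putative (dashed)", {
  res <- get_refined()
  for (nm in c("A-P28", "C6")) {
    id <- ht_node_by_name(res$tree, nm)
    expect_true(res$tree$nodes$putative[id])
  }
  # every sampled branch keeps a positive control
  for (nm in c("A1b", "A-V218", "B-V65", "C-V20")) {
    id <- ht_node_by_name(res$tree, nm)
    expect_false(res$tree$nodes$putative[id])
  }
})

test_that("key equivalences and repositionings from the panel are recovered", {
  res <- get_refined()
  pl <- res$placements
  eq_of <- function(m) pl$equivalence_class[pl$marker == m]
  expect_equal(eq_of("V73"), "M114+V73")
  expect_equal(eq_of("V249"), "PK1+V249")
  # the basal-root marker of the A3 clade moves above both its subclades
  expect_equal(pl$target[pl$marker == "P289"], "A3")
  expect_true(pl$moved[pl$marker == "P289"])
  # seven markers shared by C, R and DE chromosomes sit on the CT branch
  ct7 <- c("V9", "V10", "V12", "V13", "V14", "V15", "V16")
  expect_true(all(pl$target[pl$marker %in% ct7] == "CT"))
  expect_true(all(pl$mode[pl$marker %in% ct7] == "existing_branch"))
  # F/K/P placements of the markers discovered on an R chromosome
  expect_equal(pl$target[pl$marker == "V186"], "F")
  expect_equal(pl$target[pl$marker == "V205"], "F")
  expect_equal(pl$target[pl$marker == "V104"], "K")
  expect_equal(pl$target[pl$marker == "V231"], "P")
})
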