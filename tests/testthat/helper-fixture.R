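# The packaged study fixture and its refinement, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

get_fixture <- function() {
  if (is.null(.fixture_cache$fx)) .fixture_cache$fx <- build_paper_fixture()
  .fixture_cache$fx
}

get_refined <- function() {
  if (is.null(.fixture_cache$res)) {
    fx <- get_fixture()
    .fixture_cache$res <- refine_tree(fx$backbone, fx$gm, fx$catalog,
                                      fx$outgroup)
  }
  .fixture_cache$res
}

get_report <- function(region = c("A", "B")) {
  res <- get_refined()
  diff_trees(res$backbone_attached, res$tree, region_filter = region,
             placements = res$placements)
}
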