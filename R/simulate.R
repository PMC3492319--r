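#' Simulation configuration
#'
#' Parameters of the genotyping-panel simulator.  The simulator emulates
#' the study design this package analyzes: a known haplogroup tree, a
#' marker catalog scattered over its branches, and a panel of one-to-few
#' representative chromosomes per clade typed at every marker, with
#' missing calls and occasional recurrent or triallelic sites.
#'
#' @param n_leaves number of tree leaves (terminal haplogroups).
#' @param mean_markers_per_branch Poisson mean of markers per branch.
#' @param n_panel_samples panel size; defaults to one sample per leaf.
#' @param no_call_rate probability a call is masked to no-call.
#' @param recurrent_site_rate probability a marker receives a second,
#'   independent mutation to the same derived allele (homoplasy).
#' @param triallelic_rate probability a marker receives a second mutation
#'   to a third allele.
#' @param seed integer seed; the same configuration always reproduces the
#'   same tree, catalog and panel.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_leaves, mean_markers_per_branch = 3,
                       n_panel_samples = n_leaves, no_call_rate = 0,
                       recurrent_site_rate = 0, triallelic_rate = 0,
                       seed = 1L) {
  stopifnot(n_leaves >= 1L, mean_markers_per_branch > 0,
            n_panel_samples >= 1L,
            no_call_rate >= 0, no_call_rate <= 1,
            recurrent_site_rate >= 0, recurrent_site_rate <= 1,
            triallelic_rate >= 0, triallelic_rate <= 1)
  structure(list(n_leaves = as.integer(n_leaves),
                 mean_markers_per_branch = mean_markers_per_branch,
                 n_panel_samples = as.integer(n_panel_samples),
                 no_call_rate = no_call_rate,
                 recurrent_site_rate = recurrent_site_rate,
                 triallelic_rate = triallelic_rate,
                 seed = as.integer(seed)), class = "sim_config")
}

#' Simulate a true haplogroup tree and marker catalog
#'
#' Draws a random rooted binary topology on `n_leaves` labelled leaves
#' (random sequential joins), then assigns each non-root branch a
#' Poisson(`mean_markers_per_branch`) number of markers with random
#' distinct ancestral/derived nucleotides.  The outgroup allele of every
#' marker equals its ancestral (root) state.
#'
#' @param config a [sim_config].
#' @return List with `tree` (a [haplo_tree]; leaves `L1..Ln`, internal
#'   nodes `I1..`), `catalog` (a [marker_catalog], markers `S1..`) and
#'   `outgroup` (site/allele data frame).
#' @export
simulate_tree_and_markers <- function(config) {
  set.seed(config$seed)
  n <- config$n_leaves
  tree <- haplo_tree("Root")
  if (n == 1L) {
    tree <- ht_add_node(tree, 1L, name = "L1")$tree
  } else {
    # random sequential joins of subtrees, represented as nested lists
    forest <- lapply(seq_len(n), function(i) paste0("L", i))
    while (length(forest) > 2L) {
      pick <- sample.int(length(forest), 2L)
      joined <- forest[pick]
      forest <- c(forest[-pick], list(joined))
    }
    icount <- 0L
    grow <- function(parent, sub) {
      if (is.character(sub)) {
        tree <<- ht_add_node(tree, parent, name = sub)$tree
      } else {
        icount <<- icount + 1L
        id <- ht_add_node(tree, parent, name = paste0("I", icount))
        tree <<- id$tree
        for (s in sub) grow(id$id, s)
      }
    }
    for (s in forest) grow(1L, s)
  }
  branches <- setdiff(tree$nodes$id, ht_root(tree))
  counts <- stats::rpois(length(branches), config$mean_markers_per_branch)
  k <- 0L
  alle <- c("A", "C", "G", "T")
  names_all <- character(0)
  anc_all <- der_all <- character(0)
  for (i in seq_along(branches)) {
    if (counts[i] == 0L) next
    nm <- paste0("S", k + seq_len(counts[i]))
    k <- k + counts[i]
    tree$markers[[branches[i]]] <- nm
    names_all <- c(names_all, nm)
    pair <- replicate(counts[i], sample(alle, 2L))
    anc_all <- c(anc_all, pair[1, ])
    der_all <- c(der_all, pair[2, ])
  }
  catalog <- marker_catalog(
    name = names_all,
    positions = as.list(seq(2650000L, by = 1000L, length.out = length(names_all))),
    ancestral = anc_all, derived = der_all,
    class = "substitution", source_tag = "simulated")
  list(tree = tree, catalog = catalog,
       outgroup = data.frame(site = names_all, allele = anc_all,
                             stringsAsFactors = FALSE))
}

#' Genotype a simulated panel
#'
#' Draws `n_panel_samples` samples over the leaves (one per leaf first,
#' then extra representatives at random leaves), sets each sample derived
#' exactly at the markers on its root-to-leaf path, then (in order)
#' injects recurrent and triallelic second events and masks calls to
#' no-call independently at `no_call_rate`.  Raw alleles are emitted for
#' all substitution markers so triallelic sites can be polarized.
#'
#' @param true_tree tree from [simulate_tree_and_markers()].
#' @param catalog matching catalog.
#' @param config the [sim_config] (a derived seed keeps panel generation
#'   reproducible on its own).
#' @return A [genotype_matrix]; injected second events are recorded in
#'   `attr(, "injections")` (marker, type, branch, allele).
#' @export
genotype_panel <- function(true_tree, catalog, config) {
  set.seed(config$seed + 999983L)
  leaves <- true_tree$nodes$id[vapply(true_tree$nodes$id, function(id)
    length(ht_children(true_tree, id)) == 0L, TRUE)]
  leaf_names <- true_tree$nodes$name[leaves]
  np <- config$n_panel_samples
  pick <- if (np <= length(leaves)) sample(leaves, np)
          else c(leaves, sample(leaves, np - length(leaves), replace = TRUE))
  sample_ids <- paste0("P", seq_len(np))
  tree <- true_tree
  for (i in seq_len(np)) tree$samples[[pick[i]]] <- c(tree$samples[[pick[i]]],
                                                      sample_ids[i])
  clades <- ht_clade_samples(tree)
  markers <- catalog$name
  mnode <- vapply(markers, function(m) ht_marker_node(tree, m), 1L)
  state <- matrix("A", np, length(markers),
                  dimnames = list(sample_ids, markers))
  raw <- matrix(NA_character_, np, length(markers),
                dimnames = list(sample_ids, markers))
  for (j in seq_along(markers)) {
    raw[, j] <- catalog$ancestral[j]
    below <- intersect(sample_ids, clades[[mnode[j]]])
    state[below, j] <- "D"
    raw[below, j] <- catalog$derived[j]
  }
  # second events: an independent origin on a lineage disjoint from the
  # first (a second event on an ancestor would overwrite the first and on
  # an unsampled branch would be invisible)
  inj <- list()
  branches <- setdiff(tree$nodes$id, ht_root(tree))
  third_of <- function(anc, der) setdiff(c("A", "C", "G", "T"), c(anc, der))[1]
  disjoint_cand <- function(j) {
    own <- intersect(clades[[mnode[j]]], sample_ids)
    branches[vapply(branches, function(b) {
      hit <- intersect(clades[[b]], sample_ids)
      length(hit) > 0L && length(intersect(hit, own)) == 0L
    }, TRUE)]
  }
  for (j in seq_along(markers)) {
    r <- stats::runif(2L)
    cand <- NULL
    if (r[1] < config$recurrent_site_rate ||
        r[2] < config$triallelic_rate) cand <- disjoint_cand(j)
    if (r[1] < config$recurrent_site_rate) {
      if (length(cand) == 0L) next
      b <- if (length(cand) == 1L) cand else sample(cand, 1L)
      hit <- intersect(sample_ids, clades[[b]])
      state[hit, j] <- "D"
      raw[hit, j] <- catalog$derived[j]
      inj[[length(inj) + 1L]] <- data.frame(marker = markers[j],
        type = "recurrent", branch = tree$nodes$name[b],
        allele = catalog$derived[j], stringsAsFactors = FALSE)
    } else if (r[2] < config$triallelic_rate) {
      if (length(cand) == 0L) next
      b <- if (length(cand) == 1L) cand else sample(cand, 1L)
      hit <- intersect(sample_ids, clades[[b]])
      third <- third_of(catalog$ancestral[j], catalog$derived[j])
      raw[hit, j] <- third
      state[hit, j] <- ifelse(raw[hit, j] == catalog$derived[j], "D", "A")
      inj[[length(inj) + 1L]] <- data.frame(marker = markers[j],
        type = "triallelic", branch = tree$nodes$name[b],
        allele = third, stringsAsFactors = FALSE)
    }
  }
  # no-call masking
  if (config$no_call_rate > 0) {
    mask <- matrix(stats::runif(length(state)) < config$no_call_rate,
                   nrow(state), ncol(state))
    state[mask] <- "N"
    raw[mask] <- NA_character_
  }
  samples <- data.frame(sample_id = sample_ids,
                        prior_haplogroup = true_tree$nodes$name[pick],
                        origin = "simulated", stringsAsFactors = FALSE)
  gm <- genotype_matrix(state, samples, raw)
  attr(gm, "injections") <- if (length(inj) > 0L) do.call(rbind, inj)
    else data.frame(marker = character(0), type = character(0),
                    branch = character(0), allele = character(0))
  gm
}

#' Prune a backbone from a true tree
#'
#' Contracts `k` randomly chosen internal (non-root, non-leaf) edges of
#' the true tree and drops their markers, producing a coarser backbone
#' whose missing branches placement should rediscover.
#'
#' @param true_tree tree from [simulate_tree_and_markers()].
#' @param k number of edges to contract (capped at the available count).
#' @param seed integer seed.
#' @return List with `backbone` (pruned [haplo_tree]) and `removed`
#'   (names of the contracted nodes).
#' @export
prune_backbone <- function(true_tree, k, seed = 1L) {
  set.seed(seed)
  internal <- setdiff(true_tree$nodes$id[vapply(true_tree$nodes$id, function(id)
    length(ht_children(true_tree, id)) > 0L, TRUE)], ht_root(true_tree))
  k <- min(k, length(internal))
  drop <- if (k > 0L) sample(internal, k) else integer(0)
  list(backbone = ht_contract(true_tree, drop, markers = "drop"),
       removed = true_tree$nodes$name[drop])
}
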