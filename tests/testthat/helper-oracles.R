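# Independent oracles used across the suite.  These deliberately avoid the
# package's own construction code paths: trees are enumerated as laminar
# clade families, parsimony minima by exhaustive state enumeration.

# -- all rooted multifurcating trees on a labelled leaf set, as clade sets --
# A tree is represented by the set of its non-singleton clades (each clade a
# sorted character vector key).  Memoized per leaf-set size/labels.

.tree_enum_cache <- new.env(parent = emptyenv())

set_partitions <- function(x) {
  if (length(x) == 1L) return(list(list(x)))
  rest <- set_partitions(x[-1])
  out <- list()
  for (p in rest) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(x[1], q[[i]])
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(list(x[1]), p)
  }
  out
}

clade_key <- function(x) paste(sort(x), collapse = "\r")

# returns list of character vectors: each element = keys of non-singleton
# proper clades of one tree (the full leaf set itself is not included)
enumerate_tree_families <- function(leaves) {
  key <- clade_key(leaves)
  hit <- .tree_enum_cache[[key]]
  if (!is.null(hit)) return(hit)
  n <- length(leaves)
  if (n == 1L) return(list(character(0)))
  out <- list()
  for (p in set_partitions(leaves)) {
    if (length(p) < 2L) next  # root must have >= 2 children
    # each non-singleton block is a child clade with its own subtree
    block_opts <- lapply(p, function(b) {
      if (length(b) == 1L) return(list(character(0)))
      subs <- enumerate_tree_families(b)
      lapply(subs, function(fam) c(clade_key(b), fam))
    })
    combos <- list(character(0))
    for (bo in block_opts) {
      combos <- unlist(lapply(combos, function(cmb)
        lapply(bo, function(f) c(cmb, f))), recursive = FALSE)
    }
    out <- c(out, combos)
  }
  out <- lapply(out, function(f) sort(unique(f)))
  out <- out[!duplicated(vapply(out, paste, "", collapse = "|"))]
  .tree_enum_cache[[key]] <- out
  out
}

# -- random complete genotype matrices ---------------------------------------

# draws a random tree-consistent (compatible) matrix by simulating markers
# on a random laminar family; returns the matrix only (the oracle recomputes
# everything from it)
random_compatible_matrix <- function(n_samples, n_markers) {
  ids <- as.character(seq_len(n_samples))
  # random nested family: random subsets made laminar by construction
  fam <- list(ids)
  while (length(fam) < n_markers + 1L) {
    base <- fam[[sample.int(length(fam), 1L)]]
    if (length(base) <= 1L) next
    sub <- sort(sample(base, sample.int(length(base), 1L)))
    ok <- all(vapply(fam, function(f)
      length(intersect(f, sub)) %in% c(0L, length(f), length(sub)), TRUE))
    if (ok) fam[[length(fam) + 1L]] <- sub
  }
  fam <- fam[-1]
  state <- matrix("A", n_samples, n_markers,
                  dimnames = list(ids, paste0("S", seq_len(n_markers))))
  for (j in seq_len(n_markers)) state[fam[[j]], j] <- "D"
  genotype_matrix(state)
}

random_incompatible_matrix <- function(n_samples, n_markers) {
  stopifnot(n_samples >= 3L)
  gm <- random_compatible_matrix(n_samples, max(1L, n_markers - 2L))
  ids <- rownames(gm$state)
  # inject a guaranteed overlapping, non-nested pair: {x,y} vs {y,z}
  trio <- sample(ids, 3L)
  state <- cbind(gm$state, X1 = "A", X2 = "A")
  state[trio[1:2], "X1"] <- "D"
  state[trio[2:3], "X2"] <- "D"
  genotype_matrix(state)
}

# -- oracle checks on a matrix ------------------------------------------------

matrix_derived_family <- function(gm) {
  ids <- rownames(gm$state)
  fam <- lapply(seq_len(ncol(gm$state)), function(j) ids[gm$state[, j] == "D"])
  fam <- fam[lengths(fam) > 0L]
  unique(lapply(fam, sort))
}

# TRUE iff some enumerated tree realizes every derived set as a clade
# (singletons and the full leaf set are always realizable)
oracle_has_perfect_phylogeny <- function(gm) {
  ids <- sort(rownames(gm$state))
  need <- matrix_derived_family(gm)
  need <- need[lengths(need) >= 2L & lengths(need) < length(ids)]
  need_keys <- vapply(need, clade_key, "")
  if (length(need_keys) == 0L) return(TRUE)
  if (length(ids) <= 6L) {
    fams <- enumerate_tree_families(ids)
    return(any(vapply(fams, function(f) all(need_keys %in% f), TRUE)))
  }
  # laminarity check for larger leaf sets
  for (i in seq_along(need)) for (j in seq_len(i - 1L)) {
    ix <- length(intersect(need[[i]], need[[j]]))
    if (ix > 0L && ix < length(need[[i]]) && ix < length(need[[j]]))
      return(FALSE)
  }
  TRUE
}

# the clade family of the minimal realizing tree == the derived family itself
oracle_minimal_clades <- function(gm) {
  need <- matrix_derived_family(gm)
  ids <- sort(rownames(gm$state))
  need <- need[lengths(need) >= 2L & lengths(need) < length(ids)]
  sort(vapply(need, clade_key, ""))
}

tree_nontrivial_clades <- function(tree) {
  cl <- ht_clade_samples(tree)
  n <- sum(lengths(tree$samples))
  cl <- cl[setdiff(tree$nodes$id, ht_root(tree))]
  cl <- cl[lengths(cl) >= 2L & lengths(cl) < n]
  sort(unique(vapply(cl, clade_key, "")))
}

# -- brute-force small parsimony ---------------------------------------------

# minimum number of state changes on `tree` with root fixed to root_allele,
# nodes carrying observed samples fixed to their allele, all other node
# states enumerated exhaustively
oracle_min_events <- function(tree, calls, root_allele) {
  calls <- calls[!is.na(calls)]
  alleles <- sort(unique(c(root_allele, unname(calls))))
  att <- ht_sample_node(tree)
  n <- nrow(tree$nodes)
  fixed <- rep(NA_character_, n)
  fixed[ht_root(tree)] <- root_allele
  for (s in names(calls)) {
    id <- att[[s]]
    if (!is.na(fixed[id]) && fixed[id] != calls[[s]]) return(Inf)
    fixed[id] <- calls[[s]]
  }
  free <- which(is.na(fixed))
  parent <- tree$nodes$parent
  count_changes <- function(st)
    sum(st[!is.na(parent)] != st[parent[!is.na(parent)]])
  if (length(free) == 0L) return(count_changes(fixed))
  best <- Inf
  grid <- rep(1L, length(free))
  repeat {
    st <- fixed
    st[free] <- alleles[grid]
    best <- min(best, count_changes(st))
    k <- 1L
    while (k <= length(free)) {
      grid[k] <- grid[k] + 1L
      if (grid[k] <= length(alleles)) break
      grid[k] <- 1L
      k <- k + 1L
    }
    if (k > length(free)) break
  }
  best
}

# -- small random trees for polarization tests -------------------------------

random_small_tree <- function(n_leaves) {
  cfg <- sim_config(n_leaves = n_leaves, mean_markers_per_branch = 1,
                    seed = sample.int(1e6, 1L))
  simulate_tree_and_markers(cfg)$tree
}
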