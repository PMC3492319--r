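#' Directed character compatibility
#'
#' Two directed binary characters (ancestral state known at the root) are
#' compatible on some rooted tree iff their derived-sample sets, restricted
#' to jointly observed samples, are nested or disjoint.  This is the
#' directed form of the four-gamete test: the forbidden configuration is a
#' pair of overlapping, non-nested derived sets.
#'
#' @param a,b derived-set objects as returned by [derived_set()] (lists
#'   with `members` and `observed`).
#' @return Logical.
#' @export
are_compatible <- function(a, b) {
  joint <- intersect(a$observed, b$observed)
  A <- intersect(a$members, joint)
  B <- intersect(b$members, joint)
  I <- length(intersect(A, B))
  I == 0L || I == length(A) || I == length(B)
}

#' Build the perfect phylogeny of a genotype matrix
#'
#' Constructs the unique minimal rooted tree on which every marker mutates
#' exactly once, i.e. every marker's derived-sample set is exactly the set
#' of samples below one branch.  Markers with identical derived sets are
#' collapsed onto one branch (phylogenetic equivalence).  The root state is
#' all-ancestral; a marker derived in every sample sits on a trunk branch
#' below the root.  No-calls are treated as not-derived here (complete
#' matrices are the intended input; for missing-data placement see
#' [place_markers_on_backbone()]).
#'
#' @param gm a [genotype_matrix].
#' @return A [haplo_tree] with markers on branches and samples attached at
#'   the most derived node they belong to.
#' @export
build_perfect_phylogeny <- function(gm) {
  universe <- gm$samples$sample_id
  dsets <- lapply(gm$markers, function(m) derived_set(gm, m))
  names(dsets) <- gm$markers
  # pairwise compatibility (restricted to jointly observed samples)
  nm <- gm$markers
  for (i in seq_along(dsets)) {
    for (j in seq_len(i - 1L)) {
      if (!are_compatible(dsets[[i]], dsets[[j]]))
        stop("incompatible marker pair: ", nm[j], " / ", nm[i])
    }
  }
  members <- lapply(dsets, function(d) sort(d$members))
  keep <- lengths(members) > 0L
  members <- members[keep]
  keys <- vapply(members, paste, "", collapse = "\r")
  classes <- split(names(members), keys)
  sets <- lapply(split(members, keys), `[[`, 1L)
  ord <- order(-lengths(sets), vapply(classes, function(x) sort(x)[1], ""))
  sets <- sets[ord]
  classes <- classes[ord]

  tree <- haplo_tree("Root")
  node_set <- list(sort(universe))  # clade below each node id
  for (k in seq_along(sets)) {
    S <- sets[[k]]
    # parent = smallest strict superset already in the tree (laminar family);
    # a set equal to the whole sample universe hangs off the root (trunk)
    sup <- which(vapply(seq_along(node_set), function(i)
      all(S %in% node_set[[i]]) &&
        (length(node_set[[i]]) > length(S) || i == 1L), TRUE))
    # ties (trunk set equal to the root universe) break toward the deepest
    sup_min <- sup[lengths(node_set[sup]) == min(lengths(node_set[sup]))]
    par <- max(sup_min)
    res <- ht_add_node(tree, par, markers = sort(classes[[k]]))
    tree <- res$tree
    node_set[[res$id]] <- S
  }
  # re-hang: a node added early may contain later, smaller nodes' sets --
  # cannot happen because sets were inserted in decreasing size order.
  for (s in universe) {
    inn <- which(vapply(node_set, function(L) s %in% L, TRUE))
    inn_min <- inn[lengths(node_set[inn]) == min(lengths(node_set[inn]))]
    at <- max(inn_min)  # deepest containing node
    tree$samples[[at]] <- c(tree$samples[[at]], s)
  }
  validate_haplo_tree(tree)
  tree
}

#' Attach panel samples to a backbone tree
#'
#' Each sample is attached at the node named by its `prior_haplogroup`
#' (the haplogroup it was assigned to by prior genotyping); samples with
#' no prior assignment are attached at the root.  Placement subsequently
#' refines attachments by pulling samples down into newly created branches.
#'
#' @param tree a [haplo_tree] without attached samples.
#' @param samples sample-record data frame (see [genotype_matrix]).
#' @return The tree with samples attached.
#' @export
attach_samples <- function(tree, samples) {
  if (sum(lengths(tree$samples)) > 0L)
    stop("tree already carries samples")
  for (i in seq_len(nrow(samples))) {
    hg <- samples$prior_haplogroup[i]
    id <- if (is.na(hg)) ht_root(tree) else ht_node_by_name(tree, hg)
    if (is.na(id))
      stop("prior haplogroup '", hg, "' of sample ", samples$sample_id[i],
           " is not a node of the backbone")
    tree$samples[[id]] <- c(tree$samples[[id]], samples$sample_id[i])
  }
  tree
}

# Single-marker placement against the current tree.
# Returns list(tree, mode, target_id, candidates, putative, created_id)
place_one <- function(tree, marker, D, Aset) {
  clades <- ht_clade_samples(tree)
  root <- ht_root(tree)
  nonroot <- setdiff(tree$nodes$id, root)
  consistent <- nonroot[vapply(nonroot, function(id) {
    L <- clades[[id]]
    all(D %in% L) && !any(Aset %in% L)
  }, TRUE)]
  cur <- ht_marker_node(tree, marker)

  strip <- function(tr) {
    if (!is.na(cur)) tr$markers[[cur]] <- setdiff(tr$markers[[cur]], marker)
    tr
  }
  # 1. an existing branch whose observed leaf set equals the derived set:
  #    positive evidence of co-location (phylogenetic equivalence)
  exact <- consistent[vapply(consistent, function(id)
    length(setdiff(clades[[id]], D)) == 0L, TRUE)]
  if (length(exact) > 0L) {
    depth <- vapply(exact, function(id) length(ht_path_to_root(tree, id)), 1L)
    tgt <- exact[which.max(depth)]
    tree <- strip(tree)
    tree$markers[[tgt]] <- c(tree$markers[[tgt]], marker)
    return(list(tree = tree, mode = "existing_branch", target = tgt,
                candidates = consistent, putative = FALSE, created = NA_integer_))
  }
  # 2. construct a node capturing the derived set exactly at the MRCA
  att <- ht_sample_node(tree)
  att_nodes <- unique(unname(att[D]))
  paths <- lapply(att_nodes, function(id) rev(ht_path_to_root(tree, id)))
  common <- paths[[1]]
  for (p in paths[-1]) {
    k <- min(length(common), length(p))
    eq <- common[seq_len(k)] == p[seq_len(k)]
    common <- common[seq_len(if (all(eq)) k else which.min(eq) - 1L)]
  }
  X <- common[length(common)]
  kids <- ht_children(tree, X)
  touched <- kids[vapply(kids, function(c) length(intersect(clades[[c]], D)) > 0L, TRUE)]
  crossing <- vapply(touched, function(c) any(Aset %in% clades[[c]]), TRUE)
  if (any(crossing)) {
    tree <- strip(tree)  # a recurrent/incompatible marker comes off the tree
    return(list(tree = tree, mode = "unplaced_incompatible", target = NA_integer_,
                candidates = integer(0), putative = FALSE, created = NA_integer_))
  }
  res_d <- intersect(tree$samples[[X]], D)
  hitch <- unlist(lapply(touched, function(c) setdiff(clades[[c]], D)))
  if (length(touched) == length(kids) && length(kids) > 0L &&
      setequal(res_d, tree$samples[[X]]) && X != root) {
    # capture would duplicate X itself: the marker belongs on X's branch;
    # unobserved samples prevent telling a tighter position apart.  At the
    # root there is no branch above, so a trunk node is created instead.
    tree <- strip(tree)
    tree$markers[[X]] <- c(tree$markers[[X]], marker)
    return(list(tree = tree, mode = "existing_branch", target = X,
                candidates = union(consistent, X), putative = TRUE,
                created = NA_integer_))
  }
  mode <- if (length(touched) >= 2L) "root_of_clade"
          else if (length(touched) == 1L) "split_branch"
          else "new_leaf_branch"
  tree <- strip(tree)
  res <- ht_add_node(tree, X, markers = marker, samples = res_d)
  tree <- res$tree
  new_id <- res$id
  tree$samples[[X]] <- setdiff(tree$samples[[X]], res_d)
  for (c in touched) tree$nodes$parent[c] <- new_id
  putative <- length(hitch) > 0L || length(consistent) > 0L
  list(tree = tree, mode = mode, target = new_id,
       candidates = union(consistent, new_id), putative = putative,
       created = new_id)
}

#' Place markers on a backbone haplogroup tree
#'
#' Maps every marker of the genotype matrix onto the backbone according to
#' its observed derived-sample set, refining the tree as evidence requires:
#'
#' * derived set equal to an existing branch's observed leaf set ->
#'   `existing_branch` (declares phylogenetic equivalence with the markers
#'   already there; a marker arriving from a different branch is recorded
#'   as repositioned);
#' * proper subset of one clade's residue -> `new_leaf_branch` or
#'   `split_branch` (new node below the clade's root);
#' * union of two or more sibling clades -> `root_of_clade` (new internal
#'   node grouping exactly those children, reducing a polytomy);
#' * overlapping but non-nested with some clade -> `unplaced_incompatible`
#'   (candidate recurrent mutation; see [polarize_multiallelic()]);
#' * indistinguishable positions due to no-calls -> the marker is reported
#'   with `putative = TRUE` and the full candidate branch set; when no
#'   exact position exists at all the most rootward candidate is taken.
#'
#' Markers with no derived call keep their backbone branch (no evidence to
#' move them).  Marker classes are processed from largest derived set to
#' smallest (then by name) so rootward structure is built first; the
#' procedure is idempotent and every backbone clade remains a clade of the
#' refined tree.
#'
#' @param backbone a [haplo_tree]; samples are attached via
#'   [attach_samples()] if not already present.
#' @param gm a [genotype_matrix].
#' @param catalog optional [marker_catalog] supplying `source_tag`s for the
#'   placement report.
#' @return A list with `tree` (refined [haplo_tree], putative flags
#'   recomputed) and `placements` (data frame: `marker`, `mode`, `target`,
#'   `candidates`, `equivalence_class`, `putative`, `moved`, `original`,
#'   `source_tag`).
#' @export
place_markers_on_backbone <- function(backbone, gm, catalog = NULL) {
  tree <- backbone
  if (sum(lengths(tree$samples)) == 0L)
    tree <- attach_samples(tree, gm$samples)
  dsets <- lapply(gm$markers, function(m) derived_set(gm, m))
  names(dsets) <- gm$markers
  sizes <- vapply(dsets, function(d) length(d$members), 1L)
  ord <- order(-sizes, gm$markers)
  mk_order <- gm$markers[ord]

  node_label <- function(tr, id) {
    if (is.na(id)) return(NA_character_)
    nm <- tr$nodes$name[id]
    if (nzchar(nm)) nm else paste0("node", id)
  }
  rec <- vector("list", length(mk_order))
  for (k in seq_along(mk_order)) {
    m <- mk_order[k]
    d <- dsets[[m]]
    D <- d$members
    Aset <- setdiff(d$observed, D)
    orig <- ht_marker_node(tree, m)
    orig_lab <- node_label(tree, orig)
    if (length(D) == 0L) {
      rec[[k]] <- list(marker = m, mode = if (is.na(orig)) "ambiguous" else "existing_branch",
                       target = orig, candidates = if (is.na(orig)) integer(0) else orig,
                       putative = TRUE, moved = FALSE, original = orig_lab)
      next
    }
    pl <- place_one(tree, m, D, Aset)
    tree <- pl$tree
    rec[[k]] <- list(marker = m, mode = pl$mode, target = pl$target,
                     candidates = pl$candidates, putative = pl$putative,
                     moved = !is.na(orig) && !identical(orig, pl$target),
                     original = orig_lab)
  }
  tree <- flag_putative(tree, gm)

  # equivalence classes: markers on one branch with identical derived sets
  # over jointly observed samples
  eq_class <- function(m, target) {
    if (is.na(target)) return(NA_character_)
    mates <- intersect(tree$markers[[target]], gm$markers)
    dm <- dsets[[m]]
    cls <- mates[vapply(mates, function(o) {
      do <- dsets[[o]]
      joint <- intersect(dm$observed, do$observed)
      length(joint) > 0L &&
        setequal(intersect(dm$members, joint), intersect(do$members, joint))
    }, TRUE)]
    paste(sort(unique(c(m, cls))), collapse = "+")
  }
  placements <- data.frame(
    marker = vapply(rec, `[[`, "", "marker"),
    mode = vapply(rec, `[[`, "", "mode"),
    target = vapply(rec, function(r) node_label(tree, r$target), ""),
    candidates = vapply(rec, function(r)
      paste(vapply(sort(r$candidates), function(id) node_label(tree, id), ""),
            collapse = "+"), ""),
    equivalence_class = vapply(rec, function(r) eq_class(r$marker, r$target), ""),
    putative = vapply(rec, `[[`, TRUE, "putative"),
    moved = vapply(rec, `[[`, TRUE, "moved"),
    original = vapply(rec, `[[`, "", "original"),
    stringsAsFactors = FALSE)
  if (!is.null(catalog)) {
    placements$source_tag <- catalog$source_tag[match(placements$marker, catalog$name)]
  } else placements$source_tag <- NA_character_
  placements <- placements[order(placements$marker), , drop = FALSE]
  rownames(placements) <- NULL
  validate_haplo_tree(tree)
  list(tree = tree, placements = placements)
}

#' Resolve a polytomy by repositioning one marker
#'
#' New genotype evidence may show that a marker currently assigned to one
#' child branch of a polytomy is derived in the samples of two or more
#' (but not all) children: the marker then moves to a new internal node
#' grouping exactly those children, strictly reducing the polytomy's
#' out-degree.
#'
#' @param tree a [haplo_tree] with samples attached.
#' @param marker marker name currently on a child branch of a polytomy.
#' @param gm a [genotype_matrix] containing the marker.
#' @return The refined [haplo_tree].  If the derived set is confined to
#'   the marker's own branch the tree is returned unchanged; a derived set
#'   covering all children is an error (the marker belongs above the
#'   polytomy and is handled by [place_markers_on_backbone()]).
#' @export
resolve_polytomy <- function(tree, marker, gm) {
  cur <- ht_marker_node(tree, marker)
  if (is.na(cur)) stop("marker ", marker, " is not on the tree")
  par <- tree$nodes$parent[cur]
  if (is.na(par)) stop("marker ", marker, " sits on the root branch")
  kids <- ht_children(tree, par)
  d <- derived_set(gm, marker)
  clades <- ht_clade_samples(tree)
  covered <- kids[vapply(kids, function(c)
    length(intersect(clades[[c]], d$members)) > 0L, TRUE)]
  if (length(covered) <= 1L) return(tree)
  if (length(covered) == length(kids) &&
      all(d$members %in% clades[[par]]) &&
      setequal(intersect(tree$samples[[par]], d$members), tree$samples[[par]]))
    stop("derived set of ", marker, " covers all children of the polytomy; ",
         "the marker belongs above it")
  pl <- place_one(tree, marker, d$members, setdiff(d$observed, d$members))
  if (pl$mode != "root_of_clade")
    stop("repositioning ", marker, " does not group polytomy children (mode ",
         pl$mode, ")")
  pl$tree
}

#' Flag putative (dashed) branches
#'
#' A branch is putative when no sample below it carries a derived call at
#' any marker on the branch -- i.e. the branching is inferred only from
#' absence or no-call patterns, with no positive control.
#'
#' @param tree a [haplo_tree] with samples attached.
#' @param gm a [genotype_matrix].
#' @return The tree with `putative` flags recomputed on every non-root node.
#' @export
flag_putative <- function(tree, gm) {
  clades <- ht_clade_samples(tree)
  for (id in setdiff(tree$nodes$id, ht_root(tree))) {
    mk <- intersect(tree$markers[[id]], gm$markers)
    sm <- intersect(clades[[id]], rownames(gm$state))
    supported <- length(mk) > 0L && length(sm) > 0L &&
      any(gm$state[sm, mk, drop = FALSE] == "D")
    tree$nodes$putative[id] <- !supported
  }
  tree
}
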