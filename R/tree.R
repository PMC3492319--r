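#' Haplogroup trees
#'
#' A `haplo_tree` is a rooted tree of haplogroup nodes.  Each node's
#' *subtending branch* carries a set of marker names (markers sharing a
#' branch are phylogenetically equivalent); nodes carry a haplogroup name,
#' a putative flag (drawn dashed: no positive control, i.e. no sample below
#' the branch has a derived call at any of its markers), an optional
#' collapsed-substructure count (clades drawn as triangles whose internal
#' branching is known but not represented), and the sample ids attached at
#' the node.  Samples attached at an internal node with children form that
#' node's paragroup.  The root state is all-ancestral and the root branch
#' carries no markers.
#'
#' Internals: `nodes` is a data frame (`id` equals row number, `parent` is
#' `NA` for the root, `name`, `putative`, `collapsed`), and `markers` /
#' `samples` are per-node lists.  Sibling order is row order.
#'
#' @name haplo_tree
NULL

#' Create a tree with a single root node
#' @param name root node name.
#' @return A `haplo_tree`.
#' @export
haplo_tree <- function(name = "Root") {
  structure(list(
    nodes = data.frame(id = 1L, parent = NA_integer_, name = name,
                       putative = FALSE, collapsed = 0L,
                       stringsAsFactors = FALSE),
    markers = list(character(0)),
    samples = list(character(0))), class = "haplo_tree")
}

#' Add a child node
#' @param tree a [haplo_tree].
#' @param parent parent node id.
#' @param name node name (may be empty for not-yet-named nodes).
#' @param markers character vector of marker names on the subtending branch.
#' @param samples character vector of sample ids attached at the node.
#' @param putative logical putative-branch flag.
#' @param collapsed integer count of collapsed internal branches (0 = none).
#' @return List with the updated `tree` and the new node `id`.
#' @export
ht_add_node <- function(tree, parent, name = "", markers = character(0),
                        samples = character(0), putative = FALSE,
                        collapsed = 0L) {
  stopifnot(parent >= 1L, parent <= nrow(tree$nodes))
  id <- nrow(tree$nodes) + 1L
  tree$nodes <- rbind(tree$nodes,
                      data.frame(id = id, parent = as.integer(parent),
                                 name = name, putative = putative,
                                 collapsed = as.integer(collapsed),
                                 stringsAsFactors = FALSE))
  tree$markers[[id]] <- as.character(markers)
  tree$samples[[id]] <- as.character(samples)
  list(tree = tree, id = id)
}

#' @export
print.haplo_tree <- function(x, ...) {
  cat("haplo_tree:", nrow(x$nodes), "nodes,",
      sum(lengths(x$markers)), "markers,",
      sum(lengths(x$samples)), "samples attached\n")
  invisible(x)
}

ht_root <- function(tree) tree$nodes$id[is.na(tree$nodes$parent)]

ht_children <- function(tree, id) tree$nodes$id[!is.na(tree$nodes$parent) &
                                                 tree$nodes$parent == id]

ht_path_to_root <- function(tree, id) {
  path <- integer(0)
  while (!is.na(id)) {
    path <- c(path, id)
    id <- tree$nodes$parent[id]
  }
  path
}

#' Preorder traversal of node ids (children in sibling order)
#' @param tree a [haplo_tree].
#' @return Integer vector of node ids.
#' @export
ht_preorder <- function(tree) {
  out <- integer(0)
  stack <- ht_root(tree)
  while (length(stack) > 0L) {
    id <- stack[1]
    stack <- stack[-1]
    out <- c(out, id)
    stack <- c(ht_children(tree, id), stack)
  }
  out
}

#' Samples in the clade below each node
#'
#' @param tree a [haplo_tree].
#' @return Named list, one character vector of sample ids per node id,
#'   each sorted.
#' @export
ht_clade_samples <- function(tree) {
  n <- nrow(tree$nodes)
  clade <- vector("list", n)
  ord <- rev(ht_preorder(tree))  # postorder
  for (id in ord) {
    acc <- tree$samples[[id]]
    for (ch in ht_children(tree, id)) acc <- c(acc, clade[[ch]])
    clade[[id]] <- sort(acc)
  }
  names(clade) <- as.character(seq_len(n))
  clade
}

#' Map sample id to the node it is attached to
#' @param tree a [haplo_tree].
#' @return Named integer vector (names = sample ids).
#' @export
ht_sample_node <- function(tree) {
  ids <- rep.int(tree$nodes$id, lengths(tree$samples))
  stats::setNames(ids, unlist(tree$samples))
}

#' Find a node id by name
#' @param tree a [haplo_tree].
#' @param name node name.
#' @return Node id, or `NA` if absent.
#' @export
ht_node_by_name <- function(tree, name) {
  hit <- tree$nodes$id[tree$nodes$name == name]
  if (length(hit) == 0L) NA_integer_ else hit[1]
}

#' Find the node whose branch carries a marker
#' @param tree a [haplo_tree].
#' @param marker marker name.
#' @return Node id, or `NA` if the marker is on no branch.
#' @export
ht_marker_node <- function(tree, marker) {
  for (id in tree$nodes$id) if (marker %in% tree$markers[[id]]) return(id)
  NA_integer_
}

#' Validate haplo_tree invariants
#'
#' Every marker on at most one branch; every internal non-root node either
#' carries at least one marker on its subtending branch or is flagged
#' putative (only checked when `check_support = TRUE`, i.e. for finished
#' trees -- backbone nodes awaiting marker placement may be bare).
#'
#' @param tree a [haplo_tree].
#' @param check_support check the marker-or-putative invariant.
#' @return `tree` invisibly; stops on violation.
#' @export
validate_haplo_tree <- function(tree, check_support = FALSE) {
  all_mk <- unlist(tree$markers)
  dup <- all_mk[duplicated(all_mk)]
  if (length(dup) > 0L)
    stop("marker(s) on more than one branch: ", paste(unique(dup), collapse = ", "))
  if (length(ht_root(tree)) != 1L) stop("tree must have exactly one root")
  if (check_support) {
    for (id in tree$nodes$id) {
      if (id == ht_root(tree)) next
      if (length(ht_children(tree, id)) > 0L &&
          length(tree$markers[[id]]) == 0L && !tree$nodes$putative[id])
        stop("internal node ", id, " (", tree$nodes$name[id],
             ") has no marker and is not putative")
    }
  }
  invisible(tree)
}

#' Contract a set of edges
#'
#' Each listed node is removed; its children are re-attached to its parent
#' and its attached samples move to the parent.  Markers on a contracted
#' edge either move to the parent edge (`markers = "parent"`) or are
#' dropped from the tree (`markers = "drop"`).  The root cannot be
#' contracted.  Node ids are renumbered.
#'
#' @param tree a [haplo_tree].
#' @param ids node ids to contract.
#' @param markers `"parent"` or `"drop"`.
#' @return The contracted `haplo_tree`.
#' @export
ht_contract <- function(tree, ids, markers = c("parent", "drop")) {
  markers <- match.arg(markers)
  ids <- setdiff(as.integer(ids), ht_root(tree))
  for (id in ids) {
    par <- tree$nodes$parent[id]
    # parent may itself be contracted later; process fine either way
    tree$nodes$parent[!is.na(tree$nodes$parent) & tree$nodes$parent == id] <- par
    tree$samples[[par]] <- c(tree$samples[[par]], tree$samples[[id]])
    tree$samples[[id]] <- character(0)
    if (markers == "parent")
      tree$markers[[par]] <- c(tree$markers[[par]], tree$markers[[id]])
    tree$markers[[id]] <- character(0)
  }
  keep <- setdiff(tree$nodes$id, ids)
  remap <- stats::setNames(seq_along(keep), keep)
  nodes <- tree$nodes[keep, , drop = FALSE]
  nodes$id <- as.integer(remap[as.character(nodes$id)])
  nodes$parent <- ifelse(is.na(nodes$parent), NA_integer_,
                         as.integer(remap[as.character(nodes$parent)]))
  rownames(nodes) <- NULL
  structure(list(nodes = nodes,
                 markers = tree$markers[keep],
                 samples = tree$samples[keep]), class = "haplo_tree")
}

#' Compare two trees by their sample clades
#'
#' Two trees are clade-equal when the sets of non-trivial sample clades
#' (clades of attached samples below each node) coincide.
#'
#' @param a,b `haplo_tree` objects over the same samples.
#' @return Logical.
#' @export
ht_clade_equal <- function(a, b) {
  key <- function(tr) {
    cl <- ht_clade_samples(tr)
    cl <- cl[vapply(cl, length, 1L) > 0L]
    sort(unique(vapply(cl, paste, "", collapse = "\r")))
  }
  identical(key(a), key(b))
}

## ---- annotated Newick ------------------------------------------------------

nwk_escape_check <- function(x, what) {
  bad <- grepl("[],=[]", x) | grepl("[&+;]", x)
  if (any(bad)) stop(what, " contains characters reserved by the Newick dialect: ",
                     paste(x[bad], collapse = ", "))
  x
}

nwk_annot <- function(tree, id) {
  fields <- character(0)
  nm <- tree$nodes$name[id]
  if (nzchar(nm)) fields <- c(fields, paste0("name=", nwk_escape_check(nm, "node name")))
  mk <- tree$markers[[id]]
  if (length(mk) > 0L)
    fields <- c(fields, paste0("markers=", paste(nwk_escape_check(mk, "marker name"),
                                                 collapse = "+")))
  sm <- tree$samples[[id]]
  if (length(sm) > 0L)
    fields <- c(fields, paste0("samples=", paste(nwk_escape_check(sm, "sample id"),
                                                 collapse = "+")))
  if (tree$nodes$putative[id]) fields <- c(fields, "putative")
  if (tree$nodes$collapsed[id] > 0L)
    fields <- c(fields, paste0("collapsed=", tree$nodes$collapsed[id]))
  if (length(fields) == 0L) "[&]" else paste0("[&", paste(fields, collapse = ","), "]")
}

#' Write a haplogroup tree as annotated Newick
#'
#' Branch annotations (`[&name=...,markers=a+b,samples=s1+s2,putative,`
#' `collapsed=k]`) follow each node.  The writer is canonical, so
#' write -> read -> write is byte-identical.
#'
#' @param tree a [haplo_tree].
#' @param file path, or `NULL` to return the string.
#' @return The Newick string, invisibly when written to file.
#' @export
write_newick_annotated <- function(tree, file = NULL) {
  rec <- function(id) {
    ch <- ht_children(tree, id)
    inner <- if (length(ch) > 0L)
      paste0("(", paste(vapply(ch, rec, ""), collapse = ","), ")") else ""
    paste0(inner, nwk_annot(tree, id))
  }
  s <- paste0(rec(ht_root(tree)), ";")
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' Read a haplogroup tree from annotated Newick
#'
#' Accepts the dialect written by [write_newick_annotated()]; bare node
#' labels (plain Newick) are also accepted and treated as names.
#'
#' @param file path to a file, or a Newick string.
#' @return A [haplo_tree].
#' @export
read_newick_annotated <- function(file) {
  s <- if (length(file) == 1L && file.exists(file))
    paste(readLines(file), collapse = "") else paste(file, collapse = "")
  s <- trimws(s)
  if (endsWith(s, ";")) s <- substr(s, 1L, nchar(s) - 1L)
  env <- new.env()
  env$pos <- 1L
  env$chars <- strsplit(s, "", fixed = TRUE)[[1]]
  peek <- function() if (env$pos <= length(env$chars)) env$chars[env$pos] else ""
  advance <- function() env$pos <- env$pos + 1L
  read_annot <- function() {
    # bare label up to a special char, then optional [&...] comment
    label <- ""
    while (!peek() %in% c("(", ")", ",", "[", "")) {
      label <- paste0(label, peek()); advance()
    }
    ann <- list(name = trimws(label), markers = character(0),
                samples = character(0), putative = FALSE, collapsed = 0L)
    if (peek() == "[") {
      advance()
      if (peek() == "&") advance()
      body <- ""
      while (peek() != "]" && peek() != "") {
        body <- paste0(body, peek()); advance()
      }
      if (peek() != "]") stop("unterminated annotation comment")
      advance()
      if (nzchar(body)) {
        for (fld in strsplit(body, ",", fixed = TRUE)[[1]]) {
          kv <- strsplit(fld, "=", fixed = TRUE)[[1]]
          key <- kv[1]
          val <- if (length(kv) > 1L) paste(kv[-1], collapse = "=") else NA
          switch(key,
                 name = ann$name <- val,
                 markers = ann$markers <- strsplit(val, "+", fixed = TRUE)[[1]],
                 samples = ann$samples <- strsplit(val, "+", fixed = TRUE)[[1]],
                 putative = ann$putative <- TRUE,
                 collapsed = ann$collapsed <- as.integer(val),
                 stop("unknown annotation key: ", key))
        }
      }
    }
    ann
  }
  # recursive node reader returning list(children=list(...), ann=)
  read_node <- function() {
    children <- list()
    if (peek() == "(") {
      advance()
      repeat {
        children[[length(children) + 1L]] <- read_node()
        if (peek() == ",") { advance(); next }
        if (peek() == ")") { advance(); break }
        stop("malformed Newick near position ", env$pos)
      }
    }
    list(children = children, ann = read_annot())
  }
  parsed <- read_node()
  if (peek() != "") stop("trailing characters after Newick tree")
  tree <- haplo_tree(name = parsed$ann$name)
  tree$markers[[1]] <- parsed$ann$markers
  tree$samples[[1]] <- parsed$ann$samples
  tree$nodes$putative[1] <- parsed$ann$putative
  tree$nodes$collapsed[1] <- parsed$ann$collapsed
  build <- function(tree, parent, node) {
    for (ch in node$children) {
      res <- ht_add_node(tree, parent, name = ch$ann$name,
                         markers = ch$ann$markers, samples = ch$ann$samples,
                         putative = ch$ann$putative, collapsed = ch$ann$collapsed)
      tree <- build(res$tree, res$id, ch)
    }
    tree
  }
  tree <- build(tree, 1L, parsed)
  validate_haplo_tree(tree)
  tree
}

#' Plain Newick topology string (for cross-checks with other tools)
#'
#' Emits the topology with sanitized node names and no annotations, e.g.
#' for reading with `ape::read.tree`.  Samples and markers are dropped;
#' unnamed nodes get `n<id>` labels and leaves must be uniquely labelled.
#'
#' @param tree a [haplo_tree].
#' @return A Newick string.
#' @export
ht_plain_newick <- function(tree) {
  lab <- function(id) {
    nm <- tree$nodes$name[id]
    if (!nzchar(nm)) nm <- paste0("n", id)
    gsub("[^A-Za-z0-9_.]", "_", nm)
  }
  rec <- function(id) {
    ch <- ht_children(tree, id)
    if (length(ch) == 0L) return(lab(id))
    paste0("(", paste(vapply(ch, rec, ""), collapse = ","), ")", lab(id))
  }
  paste0(rec(ht_root(tree)), ";")
}
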