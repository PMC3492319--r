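#' Assign haplogroup names in a refined tree
#'
#' Backbone names are preserved.  Every unnamed (newly created) node
#' receives a frozen *mutation-based* name: the clade letter of its nearest
#' named ancestor, a dash, and the lexicographically first marker on its
#' branch (e.g. `A-V218`, `C-V20`).  Where the parent carries a
#' lineage-style label (letter/number alternation, e.g. `C`, `A3b1`) a
#' *lineage-based* label is also computed by appending the next free
#' number or letter in sibling order (`C` with children `C1`..`C6` names
#' the next branch `C7`); inserting nodes can re-letter siblings, so
#' lineage labels are reported side by side and never replace the frozen
#' mutation-based name.  A putative node with no marker gets a placeholder
#' name and a warning.
#'
#' @param refined a [haplo_tree] after placement.
#' @return List with `tree` (names filled in) and `names` (data frame:
#'   `node`, `name`, `mutation_based`, `lineage_based`, `new`).
#' @export
assign_names <- function(refined) {
  tree <- refined
  n <- nrow(tree$nodes)
  lineage_style <- function(x) grepl("^[A-Z][0-9a-z]*$", x)
  clade_letter <- function(id) {
    for (anc in ht_path_to_root(tree, id)[-1]) {
      nm <- tree$nodes$name[anc]
      if (nzchar(nm)) {
        m <- regmatches(nm, regexec("^([A-Z])", nm))[[1]]
        if (length(m) == 2L) return(m[2])
      }
    }
    "Y"
  }
  mutation_based <- rep(NA_character_, n)
  lineage_based <- rep(NA_character_, n)
  is_new <- !nzchar(tree$nodes$name)

  # effective lineage label of a node (backbone name, or computed)
  eff_lineage <- rep(NA_character_, n)
  for (id in ht_preorder(tree)) {
    nm <- tree$nodes$name[id]
    if (nzchar(nm)) {
      if (lineage_style(nm)) eff_lineage[id] <- nm
      next
    }
    # mutation-based name
    mk <- sort(tree$markers[[id]])
    if (length(mk) == 0L) {
      mutation_based[id] <- paste0("Unnamed-", id)
      warning("putative node ", id, " has no marker; placeholder name assigned")
    } else {
      mutation_based[id] <- paste0(clade_letter(id), "-", mk[1])
    }
    # lineage-based label from the parent's effective lineage label
    par <- tree$nodes$parent[id]
    plab <- eff_lineage[par]
    if (!is.na(plab)) {
      sibs <- ht_children(tree, par)
      sib_labs <- c(tree$nodes$name[sibs], eff_lineage[sibs])
      numeric_next <- grepl("[a-z']$|^[A-Z]+$", plab)  # label ends in a letter
      pat <- if (numeric_next) paste0("^", plab, "([0-9]+)$")
             else paste0("^", plab, "([a-z])$")
      used <- regmatches(sib_labs, regexec(pat, sib_labs))
      used <- vapply(used, function(x) if (length(x) == 2L) x[2] else NA_character_, "")
      used <- used[!is.na(used)]
      nxt <- if (numeric_next) {
        as.character(if (length(used) == 0L) 1L else max(as.integer(used)) + 1L)
      } else {
        letters[if (length(used) == 0L) 1L else
          max(match(used, letters)) + 1L]
      }
      lineage_based[id] <- paste0(plab, nxt)
      eff_lineage[id] <- lineage_based[id]
    }
    tree$nodes$name[id] <- mutation_based[id]
  }
  if (anyDuplicated(tree$nodes$name[nzchar(tree$nodes$name)]))
    stop("duplicate haplogroup names after assignment")
  list(tree = tree,
       names = data.frame(node = tree$nodes$id, name = tree$nodes$name,
                          mutation_based = mutation_based,
                          lineage_based = lineage_based, new = is_new,
                          stringsAsFactors = FALSE))
}

# clade letter(s) of a sample: leading capitals of the most tipward named
# node on its path (e.g. B2a -> "B", DE -> "DE")
sample_letters <- function(tree) {
  att <- ht_sample_node(tree)
  out <- character(length(att))
  for (i in seq_along(att)) {
    lt <- NA_character_
    for (id in ht_path_to_root(tree, att[[i]])) {  # tipward first
      nm <- tree$nodes$name[id]
      m <- regmatches(nm, regexec("^([A-Z]+)", nm))[[1]]
      if (length(m) == 2L) { lt <- m[2]; break }
    }
    out[i] <- lt
  }
  stats::setNames(out, names(att))
}

#' Diff a refined tree against its backbone
#'
#' Computes the refinement report: new haplogroups (named nodes of the
#' refined tree absent from the backbone), new paragroups (nodes that
#' newly hold samples above named children), resolved polytomies (matched
#' nodes whose out-degree strictly decreased), repositioned markers, and
#' phylogenetically equivalent marker classes.  Nodes are matched between
#' the trees by name or by their attached-sample clade.  A node whose
#' branch carries only repositioned backbone markers records a polytomy
#' resolution, not a new haplogroup.  Collapsed-triangle substructure
#' (drawn but not represented) is excluded from all counts.
#'
#' @param backbone a [haplo_tree] with samples attached (see
#'   [attach_samples()]).
#' @param refined the refined, named [haplo_tree].
#' @param region_filter optional character vector of clade letters
#'   (e.g. `c("A", "B")` for the African clades); only new nodes whose
#'   clades consist entirely of samples in those clades are counted.
#' @param placements optional placement table from
#'   [place_markers_on_backbone()]; used to identify backbone markers that
#'   were repositioned and to report equivalence classes.
#' @return A `refinement_report` list; counts equal the lengths of the
#'   corresponding tables.
#' @export
diff_trees <- function(backbone, refined, region_filter = NULL,
                       placements = NULL) {
  if (sum(lengths(backbone$samples)) == 0L || sum(lengths(refined$samples)) == 0L)
    stop("both trees must carry attached samples")
  bcl <- ht_clade_samples(backbone)
  rcl <- ht_clade_samples(refined)
  key <- function(x) paste(x, collapse = "\r")
  bkeys <- vapply(bcl, key, "")
  rkeys <- vapply(rcl, key, "")
  # refinement monotonicity: every nonempty backbone clade survives
  lost <- setdiff(bkeys[lengths(bcl) > 0L], rkeys)
  if (length(lost) > 0L)
    stop("backbone clade(s) absent from the refined tree: not a refinement")

  broot <- ht_root(backbone)
  match_of <- function(rid) {
    # a non-root refined node never matches the backbone root: a trunk
    # branch subtending every sample is still a branch the backbone lacks
    nm <- refined$nodes$name[rid]
    if (nzchar(nm)) {
      hit <- setdiff(backbone$nodes$id[backbone$nodes$name == nm], broot)
      if (length(hit) > 0L) return(hit[1])
    }
    if (length(rcl[[rid]]) > 0L) {
      hit <- setdiff(backbone$nodes$id[bkeys == rkeys[rid]], broot)
      if (length(hit) > 0L) return(hit[1])
    }
    NA_integer_
  }
  rids <- setdiff(refined$nodes$id, ht_root(refined))
  matched <- vapply(rids, match_of, 1L)

  letters_r <- sample_letters(backbone)
  in_region <- function(rid) {
    if (is.null(region_filter)) return(TRUE)
    cl <- rcl[[rid]]
    length(cl) > 0L && all(letters_r[cl] %in% region_filter)
  }
  repositioned_bb <- character(0)
  if (!is.null(placements)) {
    repositioned_bb <- placements$marker[placements$moved &
      !is.na(placements$source_tag) & placements$source_tag == "backbone-59"]
  }
  only_repositioned <- function(rid) {
    mk <- refined$markers[[rid]]
    length(mk) > 0L && all(mk %in% repositioned_bb)
  }
  # anchor clade for the per-clade breakdown: most rootward matched named
  # ancestor among the basal clade names, else the nearest matched ancestor
  basal <- c("A1b", "A1a", "A2", "A3", "B")
  anchor <- function(rid) {
    chain <- ht_path_to_root(refined, rid)
    if (!refined$nodes$name[rid] %in% basal) chain <- chain[-1]
    nms <- refined$nodes$name[chain]
    hit <- nms[nms %in% basal]
    if (length(hit) > 0L) return(hit[1])
    hit <- nms[nzchar(nms)]
    if (length(hit) > 0L) hit[1] else "Root"
  }

  new_ids <- rids[is.na(matched) & vapply(rids, in_region, TRUE)]
  new_hg_ids <- new_ids[!vapply(new_ids, only_repositioned, TRUE)]
  new_haplogroups <- data.frame(
    name = refined$nodes$name[new_hg_ids],
    clade = vapply(new_hg_ids, anchor, ""),
    n_markers = lengths(refined$markers[new_hg_ids]),
    n_samples = lengths(rcl[new_hg_ids]),
    putative = refined$nodes$putative[new_hg_ids],
    stringsAsFactors = FALSE)
  new_haplogroups <- new_haplogroups[order(new_haplogroups$clade,
                                           new_haplogroups$name), , drop = FALSE]
  rownames(new_haplogroups) <- NULL

  # paragroups: a node with children and attached samples
  is_paragroup <- function(tr, id)
    length(ht_children(tr, id)) > 0L && length(tr$samples[[id]]) > 0L
  r_para <- rids[vapply(rids, function(id) is_paragroup(refined, id), TRUE) &
                   vapply(rids, in_region, TRUE)]
  new_para <- r_para[vapply(r_para, function(rid) {
    b <- match_of(rid)
    is.na(b) || !is_paragroup(backbone, b)
  }, TRUE)]
  new_paragroups <- data.frame(
    name = if (length(new_para) > 0L)
      paste0(refined$nodes$name[new_para], "*") else character(0),
    clade = vapply(new_para, anchor, ""),
    n_samples = lengths(refined$samples[new_para]),
    stringsAsFactors = FALSE)
  new_paragroups <- new_paragroups[order(new_paragroups$clade,
                                         new_paragroups$name), , drop = FALSE]
  rownames(new_paragroups) <- NULL

  # resolved polytomies: matched nodes with strictly smaller out-degree
  poly <- lapply(rids[!is.na(matched)], function(rid) {
    b <- match_of(rid)
    df_b <- length(ht_children(backbone, b))
    df_r <- length(ht_children(refined, rid))
    if (df_r < df_b && df_b > 2L)
      data.frame(node = refined$nodes$name[rid], from_degree = df_b,
                 to_degree = df_r, stringsAsFactors = FALSE)
    else NULL
  })
  resolved_polytomies <- do.call(rbind, poly)
  if (is.null(resolved_polytomies))
    resolved_polytomies <- data.frame(node = character(0),
                                      from_degree = integer(0),
                                      to_degree = integer(0))

  # repositioned markers: on both trees, branch changed
  bb_mk <- unlist(backbone$markers)
  moved <- lapply(bb_mk, function(m) {
    bn <- ht_marker_node(backbone, m)
    rn <- ht_marker_node(refined, m)
    if (is.na(rn)) return(NULL)  # came off the tree (incompatible)
    if (!identical(match_of(rn), bn))
      data.frame(marker = m, from = backbone$nodes$name[bn],
                 to = refined$nodes$name[rn], stringsAsFactors = FALSE)
    else NULL
  })
  repositioned_markers <- do.call(rbind, moved)
  if (is.null(repositioned_markers))
    repositioned_markers <- data.frame(marker = character(0),
                                       from = character(0), to = character(0))
  repositioned_markers <-
    repositioned_markers[order(repositioned_markers$marker), , drop = FALSE]
  rownames(repositioned_markers) <- NULL

  equivalence_classes <- character(0)
  if (!is.null(placements)) {
    eq <- unique(placements$equivalence_class)
    eq <- eq[!is.na(eq) & grepl("+", eq, fixed = TRUE)]
    equivalence_classes <- sort(eq)
  }
  per_clade <- table(factor(new_haplogroups$clade,
                            levels = sort(unique(new_haplogroups$clade))))
  structure(list(
    new_haplogroups = new_haplogroups,
    new_paragroups = new_paragroups,
    resolved_polytomies = resolved_polytomies,
    repositioned_markers = repositioned_markers,
    equivalence_classes = equivalence_classes,
    per_clade = per_clade,
    region_filter = region_filter), class = "refinement_report")
}

#' @export
print.refinement_report <- function(x, ...) {
  cat("Refinement report",
      if (!is.null(x$region_filter))
        paste0(" (clades ", paste(x$region_filter, collapse = ", "), ")"),
      "\n", sep = "")
  cat("  new haplogroups:    ", nrow(x$new_haplogroups), "\n")
  if (nrow(x$new_haplogroups) > 0L) {
    bd <- paste(names(x$per_clade), as.integer(x$per_clade), sep = ":",
                collapse = "  ")
    cat("    per clade:        ", bd, "\n")
  }
  cat("  new paragroups:     ", nrow(x$new_paragroups), "\n")
  cat("  resolved polytomies:", nrow(x$resolved_polytomies), "\n")
  if (nrow(x$resolved_polytomies) > 0L)
    cat("    ", paste(sprintf("%s (%d -> %d)", x$resolved_polytomies$node,
                              x$resolved_polytomies$from_degree,
                              x$resolved_polytomies$to_degree),
                      collapse = "; "), "\n")
  cat("  repositioned markers:", nrow(x$repositioned_markers), "\n")
  cat("  equivalence classes (>1 marker):", length(x$equivalence_classes), "\n")
  invisible(x)
}

#' Write a refinement summary as key-value lines
#'
#' Machine-readable companion to the printed report.
#'
#' @param report a `refinement_report`.
#' @param file path or `NULL`.
#' @return Lines, invisibly.
#' @export
write_refinement_summary <- function(report, file = NULL) {
  kv <- c(
    paste0("new_haplogroups\t", nrow(report$new_haplogroups)),
    paste0("new_paragroups\t", nrow(report$new_paragroups)),
    paste0("resolved_polytomies\t", nrow(report$resolved_polytomies)),
    paste0("repositioned_markers\t", nrow(report$repositioned_markers)),
    vapply(seq_len(nrow(report$new_haplogroups)), function(i)
      paste0("new_haplogroup\t", report$new_haplogroups$name[i], "\t",
             report$new_haplogroups$clade[i]), ""),
    vapply(seq_len(nrow(report$new_paragroups)), function(i)
      paste0("new_paragroup\t", report$new_paragroups$name[i], "\t",
             report$new_paragroups$clade[i]), ""),
    vapply(seq_len(nrow(report$repositioned_markers)), function(i)
      paste0("repositioned\t", report$repositioned_markers$marker[i], "\t",
             report$repositioned_markers$from[i], "\t",
             report$repositioned_markers$to[i]), ""))
  if (!is.null(file)) writeLines(kv, file)
  invisible(kv)
}

#' Write a placement report TSV
#' @param placements placement table from [place_markers_on_backbone()].
#' @param file path or `NULL`.
#' @return Lines, invisibly.
#' @export
write_placement_report <- function(placements, file = NULL) {
  cols <- c("marker", "mode", "target", "equivalence_class", "putative",
            "moved", "original", "source_tag")
  fmt <- function(x) ifelse(is.na(x), "NA", as.character(x))
  lines <- c(paste(cols, collapse = "\t"),
             vapply(seq_len(nrow(placements)), function(i)
               paste(vapply(cols, function(cl) fmt(placements[[cl]][i]), ""),
                     collapse = "\t"), ""))
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
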