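#' Refine a backbone tree from panel genotypes
#'
#' End-to-end pipeline: attach samples, place every marker on the backbone
#' ([place_markers_on_backbone()]), polarize sites that show a third
#' allele against the outgroup or that were rejected as recurrent
#' ([polarize_multiallelic()]), incorporate the resulting mutation events
#' into the tree (the base site is replaced by its `".k"` events on their
#' branches), and assign haplogroup names ([assign_names()]).
#'
#' @param backbone a [haplo_tree] (no samples attached).
#' @param gm a [genotype_matrix].
#' @param catalog a [marker_catalog].
#' @param outgroup outgroup allele table (`site`, `allele`), or `NULL`.
#' @return List with `tree` (refined, named), `backbone_attached` (the
#'   backbone with samples, for diffing), `placements`, `events`
#'   (polarization table), and `names` (name map from [assign_names()]).
#' @export
refine_tree <- function(backbone, gm, catalog, outgroup = NULL) {
  backbone_attached <- attach_samples(backbone, gm$samples)
  pl <- place_markers_on_backbone(backbone_attached, gm, catalog)
  tree <- pl$tree
  events <- NULL
  if (!is.null(outgroup) && !is.null(gm$raw_allele)) {
    for (i in seq_len(nrow(outgroup))) {
      site <- outgroup$site[i]
      if (!site %in% colnames(gm$raw_allele)) next
      calls <- gm$raw_allele[, site]
      names(calls) <- rownames(gm$state)
      obs <- unique(stats::na.omit(c(calls, outgroup$allele[i])))
      incompatible <- site %in%
        pl$placements$marker[pl$placements$mode == "unplaced_incompatible"]
      if (length(obs) < 3L && !incompatible) next
      ev <- polarize_multiallelic(site, calls, outgroup$allele[i], tree)
      tree <- apply_polarization(tree, site, ev)
      events <- rbind(events, ev)
    }
  }
  if (is.null(events))
    events <- data.frame(base_site = character(0), event_name = character(0),
                         from = character(0), to = character(0),
                         branch = character(0), alternatives = character(0))
  nm <- assign_names(tree)
  list(tree = nm$tree, backbone_attached = backbone_attached,
       placements = pl$placements, events = events, names = nm$names)
}

#' Incorporate polarized mutation events into a tree
#'
#' Removes the base site from whatever branch carries it and places each
#' `".k"` event on its assigned branch.
#'
#' @param tree a [haplo_tree].
#' @param site base site name.
#' @param events event table from [polarize_multiallelic()].
#' @return The updated tree.
#' @export
apply_polarization <- function(tree, site, events) {
  cur <- ht_marker_node(tree, site)
  if (!is.na(cur)) tree$markers[[cur]] <- setdiff(tree$markers[[cur]], site)
  for (i in seq_len(nrow(events))) {
    id <- ht_node_by_name(tree, events$branch[i])
    if (is.na(id) && grepl("^node[0-9]+$", events$branch[i]))
      id <- as.integer(sub("^node", "", events$branch[i]))
    if (is.na(id))
      stop("event branch '", events$branch[i], "' not found in tree")
    tree$markers[[id]] <- c(tree$markers[[id]], events$event_name[i])
  }
  tree
}
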