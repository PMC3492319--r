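#' Polarize a multiallelic site into mutation events
#'
#' A site showing three alleles across panel plus outgroup (or two alleles
#' whose derived set is incompatible with the tree) cannot be a single
#' unique-event polymorphism.  Given the outgroup allele (which fixes the
#' root state) and the accepted tree, this resolves the site into the
#' minimum number of mutation events explaining every raw allele call:
#' each event sits on a branch, turning the allele inherited from above
#' (`from`) into its `to` allele for the whole clade below (unless a later
#' event overwrites it).  Events are chained (`from` equals the `to` of an
#' ancestral event) only along ancestor--descendant branches; otherwise
#' they arise independently from the outgroup allele.
#'
#' The minimum is computed by dynamic programming over node states
#' (Sankoff-style, unit cost per change, root state fixed to the outgroup
#' allele, samples attached at a node constrain its state).  Ties among
#' equally parsimonious placements are broken toward the more rootward
#' branch; a tie is reported in the `alternatives` column.
#'
#' Event names carry `".k"` suffixes in branch pre-order (the drawing
#' order of the tree), a naming convention rather than an inference.
#'
#' @param site base marker name (e.g. `"V161"`).
#' @param calls named character vector of raw alleles per sample
#'   (`NA` = untyped); names must be samples attached to `tree`.
#' @param outgroup_allele single nucleotide observed in the outgroup
#'   reference; required -- events cannot be rooted without it.
#' @param tree a [haplo_tree] with samples attached.
#' @return Data frame with columns `base_site`, `event_name`, `from`, `to`,
#'   `branch` (target node name), `alternatives` (empty or a note on
#'   equally parsimonious placements), ordered by pre-order.
#' @export
polarize_multiallelic <- function(site, calls, outgroup_allele, tree) {
  if (missing(outgroup_allele) || is.na(outgroup_allele) ||
      !grepl("^[ACGT-]$", outgroup_allele))
    stop("polarization requires an outgroup allele to root the events")
  calls <- calls[!is.na(calls)]
  alleles <- sort(unique(c(outgroup_allele, unname(calls))))
  att <- ht_sample_node(tree)
  unknown <- setdiff(names(calls), names(att))
  if (length(unknown) > 0L)
    stop("sample(s) not on the tree: ", paste(unknown, collapse = ", "))

  n <- nrow(tree$nodes)
  root <- ht_root(tree)
  INF <- 1e9
  # node-state constraints from samples attached at each node
  node_obs <- vector("list", n)
  for (s in names(calls)) {
    id <- att[[s]]
    node_obs[[id]] <- unique(c(node_obs[[id]], calls[[s]]))
  }
  conflict <- which(vapply(node_obs, function(x) length(x) > 1L, TRUE))
  if (length(conflict) > 0L)
    stop("conflicting raw alleles among samples attached at one node (",
         tree$nodes$name[conflict[1]], "): no event assignment on this tree ",
         "can explain the calls")

  cost <- matrix(0, n, length(alleles), dimnames = list(NULL, alleles))
  for (id in rev(ht_preorder(tree))) {
    own <- rep(0, length(alleles))
    if (!is.null(node_obs[[id]]))
      own <- ifelse(alleles == node_obs[[id]][1], 0, INF)
    acc <- own
    for (ch in ht_children(tree, id)) {
      step <- vapply(seq_along(alleles), function(a)
        min(cost[ch, ] + (alleles != alleles[a])), 0)
      acc <- acc + step
    }
    cost[id, ] <- acc
  }
  total <- cost[root, outgroup_allele]
  if (total >= INF)
    stop("calls at site ", site, " cannot be explained by any event ",
         "assignment on the given tree")

  # traceback, preferring a change on the higher (more rootward) branch on ties
  state <- rep(NA_character_, n)
  state[root] <- outgroup_allele
  events <- list()
  for (id in ht_preorder(tree)) {
    a <- state[id]
    for (ch in ht_children(tree, id)) {
      opts <- cost[ch, ] + (alleles != a)
      best <- alleles[opts == min(opts)]
      tied <- length(best) > 1L
      b <- if (any(best != a)) sort(best[best != a])[1] else a
      state[ch] <- b
      if (b != a) {
        nm <- tree$nodes$name[ch]
        events[[length(events) + 1L]] <- list(
          branch = if (nzchar(nm)) nm else paste0("node", ch),
          from = a, to = b,
          alternatives = if (tied)
            "equally parsimonious placement on a descendant branch" else "")
      }
    }
  }
  stopifnot(length(events) == total)
  data.frame(
    base_site = rep(site, length(events)),
    event_name = if (length(events) > 0L)
      paste0(site, ".", seq_along(events)) else character(0),
    from = vapply(events, `[[`, "", "from"),
    to = vapply(events, `[[`, "", "to"),
    branch = vapply(events, `[[`, "", "branch"),
    alternatives = vapply(events, `[[`, "", "alternatives"),
    stringsAsFactors = FALSE)
}

#' Replay mutation events down a tree
#'
#' Applies a set of events to the tree, starting from the outgroup allele
#' at the root, and returns the allele each attached sample ends up with.
#' Used to verify that a polarization exactly reproduces the raw calls.
#'
#' @param tree a [haplo_tree] with samples attached.
#' @param events data frame as returned by [polarize_multiallelic()].
#' @param outgroup_allele root allele.
#' @return Named character vector of alleles per attached sample.
#' @export
replay_events <- function(tree, events, outgroup_allele) {
  n <- nrow(tree$nodes)
  state <- rep(NA_character_, n)
  root <- ht_root(tree)
  state[root] <- outgroup_allele
  lab <- function(id) {
    nm <- tree$nodes$name[id]
    if (nzchar(nm)) nm else paste0("node", id)
  }
  for (id in ht_preorder(tree)) {
    if (id == root) next
    par <- tree$nodes$parent[id]
    state[id] <- state[par]
    hit <- which(events$branch == lab(id))
    if (length(hit) > 0L) {
      ev <- events[hit[1], ]
      if (ev$from != state[par])
        stop("event ", ev$event_name, " expects allele ", ev$from,
             " above branch ", ev$branch, " but found ", state[par])
      state[id] <- ev$to
    }
  }
  att <- ht_sample_node(tree)
  stats::setNames(state[att], names(att))
}

#' Write a polarization report
#' @param events data frame from [polarize_multiallelic()].
#' @param file path or `NULL`.
#' @return Lines, invisibly.
#' @export
write_polarization_report <- function(events, file = NULL) {
  lines <- c(paste(c("base_site", "event_name", "from", "to", "branch",
                     "alternatives"), collapse = "\t"),
             vapply(seq_len(nrow(events)), function(i)
               paste(unlist(events[i, c("base_site", "event_name", "from",
                                        "to", "branch", "alternatives")]),
                     collapse = "\t"), ""))
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
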