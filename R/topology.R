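#' Topological node depths
#'
#' Depth of every node of a rooted tree, counted in edges from the root
#' (root depth 0). Branch lengths are ignored: the statistics of this
#' module are purely topological.
#'
#' @param tree An [ape::phylo] rooted tree.
#' @return Integer vector indexed by ape node number
#'   (tips `1..Ntip`, then internal nodes).
#' @export
node_depths <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  depth <- integer(ntip + nnode)
  if (is.null(tree$edge) || nrow(tree$edge) == 0L)
    return(depth)
  # cladewise order guarantees a parent's depth is set before its children's
  tree2 <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(tree2$edge))) {
    depth[tree2$edge[i, 2L]] <- depth[tree2$edge[i, 1L]] + 1L
  }
  depth
}

#' Leaf depths
#'
#' Edge-count depth of every leaf of a rooted tree; the root has depth 0,
#' so a leaf's depth is the number of edges on its root-to-leaf path.
#'
#' @param tree An [ape::phylo] rooted tree.
#' @return Named integer vector (names are the leaf labels).
#' @export
leaf_depths <- function(tree) {
  ntip <- length(tree$tip.label)
  d <- node_depths(tree)[seq_len(ntip)]
  names(d) <- tree$tip.label
  d
}

.leaf_classes <- function(tree, records) {
  idx <- match(tree$tip.label, records$protein_id)
  if (anyNA(idx))
    stop(sprintf("leaf '%s' does not resolve to a protein record",
                 tree$tip.label[is.na(idx)][1L]), call. = FALSE)
  records$taxon_class[idx]
}

# descendant tip numbers of every node, as a list indexed by node number
.descendant_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  n <- ntip + tree$Nnode
  out <- vector("list", n)
  for (i in seq_len(ntip)) out[[i]] <- i
  tree2 <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(tree2$edge))) {
    p <- tree2$edge[i, 1L]; ch <- tree2$edge[i, 2L]
    out[[p]] <- c(out[[p]], out[[ch]])
  }
  out
}

#' Find viral clusters (maximal viral-only clades)
#'
#' A viral cluster (VC) is a maximal sub-tree all of whose leaves are viral
#' proteins: a node whose descendant leaves are all of class `virus` and
#' whose parent has at least one non-viral descendant leaf (or the root, if
#' the entire tree is viral). A lone viral leaf with a non-viral sibling is
#' a VC of size 1. Each VC is read as evidence of a single acquisition
#' episode of host sequence by a virus.
#'
#' @param tree An [ape::phylo] rooted tree whose leaf labels are protein ids.
#' @param records data.frame of protein records supplying `taxon_class`.
#' @return data.frame of class `"viral_clusters"`, one row per VC:
#'   `node` (ape node number of the VC root), `depth` (edges from the tree
#'   root), `n_leaves`, and list-column `leaf_ids`. The leaf sets are
#'   pairwise disjoint and their union is the set of viral leaves.
#' @export
find_viral_clusters <- function(tree, records) {
  ntip <- length(tree$tip.label)
  cls <- .leaf_classes(tree, records)
  n <- ntip + tree$Nnode
  allviral <- logical(n)
  allviral[seq_len(ntip)] <- cls == "virus"
  tree2 <- ape::reorder.phylo(tree, "postorder")
  # an internal node is all-viral iff all children are; initialize TRUE and
  # let any non-viral child clear it
  internal <- (ntip + 1L):n
  allviral[internal] <- TRUE
  for (i in seq_len(nrow(tree2$edge))) {
    p <- tree2$edge[i, 1L]; ch <- tree2$edge[i, 2L]
    if (!allviral[ch]) allviral[p] <- FALSE
  }
  parent <- integer(n)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  root <- ntip + 1L
  is_vc <- allviral & (seq_len(n) == root | !allviral[pmax(parent, 1L)])
  vc_nodes <- which(is_vc)
  depth <- node_depths(tree)
  tips <- .descendant_tips(tree)
  out <- data.frame(node = vc_nodes,
                    depth = depth[vc_nodes],
                    n_leaves = vapply(tips[vc_nodes], length, 0L))
  out$leaf_ids <- I(lapply(tips[vc_nodes],
                           function(t) tree$tip.label[t]))
  class(out) <- c("viral_clusters", class(out))
  out
}

#' Normalized depth of a leaf
#'
#' A leaf's edge-count depth divided by the maximum leaf depth of the same
#' tree. In a tree whose deepest leaf is 19 edges from the root, a leaf at
#' depth 9 has normalized depth 9/19 = 0.474.
#'
#' @param tree An [ape::phylo] rooted tree.
#' @param leaf One leaf label.
#' @return A fraction in (0, 1] for non-root leaves.
#' @export
normalized_depth <- function(tree, leaf) {
  d <- leaf_depths(tree)
  if (!leaf %in% names(d))
    stop(sprintf("leaf '%s' not in tree", leaf), call. = FALSE)
  mx <- max(d)
  if (mx == 0L)
    stop("normalized depth undefined: maximum leaf depth is 0", call. = FALSE)
  unname(d[leaf]) / mx
}

#' Normalized depth of a viral cluster
#'
#' The depth of the VC's root node (not of its leaves), in edges from the
#' tree root, divided by the maximum leaf depth of the tree. A VC that is a
#' single leaf has the normalized depth of that leaf.
#'
#' @param tree The tree the cluster was found in.
#' @param vc One row of a [find_viral_clusters()] result, or a node number.
#' @return A fraction in (0, 1].
#' @export
vc_depth <- function(tree, vc) {
  node <- if (is.data.frame(vc)) vc$node[1L] else as.integer(vc)
  d <- leaf_depths(tree)
  mx <- max(d)
  if (mx == 0L)
    stop("normalized depth undefined: maximum leaf depth is 0", call. = FALSE)
  node_depths(tree)[node] / mx
}

#' Selection thresholds for host-to-virus candidate families
#'
#' The two-part selection rule for families likely to contain host-derived
#' viral sequences: the viral presence must be marginal (viral fraction at
#' most `max_viral_fraction`, or at most `max_viral_count_override` viral
#' proteins in total), and the viral leaves must be clustered (at most
#' `max_vc_simple` viral clusters, or at most `max_vc_condensed` clusters
#' with a condensation factor — viral proteins per cluster — of at least
#' `min_condensation`).
#'
#' @param max_viral_fraction Default 0.05 (inclusive).
#' @param max_viral_count_override Default 2.
#' @param max_vc_simple Default 2.
#' @param max_vc_condensed Default 10.
#' @param min_condensation Default 3.
#' @return A list of class `"selection_thresholds"`.
#' @export
selection_thresholds <- function(max_viral_fraction = 0.05,
                                 max_viral_count_override = 2L,
                                 max_vc_simple = 2L,
                                 max_vc_condensed = 10L,
                                 min_condensation = 3) {
  stopifnot(max_viral_fraction > 0, max_viral_count_override > 0,
            max_vc_simple > 0, max_vc_condensed > 0, min_condensation > 0)
  structure(list(max_viral_fraction = max_viral_fraction,
                 max_viral_count_override = as.integer(max_viral_count_override),
                 max_vc_simple = as.integer(max_vc_simple),
                 max_vc_condensed = as.integer(max_vc_condensed),
                 min_condensation = min_condensation),
            class = "selection_thresholds")
}

#' Topology report and selection verdict for one family tree
#'
#' Computes the tree-topology statistics of one cross-taxa family — viral
#' and metazoan leaf counts, viral fraction (viral leaves over all leaves),
#' viral clusters and condensation factor, maximum leaf depth, the depth of
#' the deepest viral leaf (with ties reported in full), and the normalized
#' depths of all viral leaves and of every VC root — and applies the
#' selection rule of [selection_thresholds()].
#'
#' The two clauses combine with AND; within each clause the alternatives
#' combine with OR:
#' `selected = (viral_fraction <= max_viral_fraction | n_viral <=
#' max_viral_count_override) & (n_vc <= max_vc_simple | (n_vc <=
#' max_vc_condensed & condensation >= min_condensation))`.
#'
#' @param tree An [ape::phylo] rooted tree; leaf labels are protein ids.
#' @param records data.frame of protein records.
#' @param thresholds A [selection_thresholds()].
#' @param family_id Optional id carried into the report.
#' @return A list of class `"topology_report"` with fields `family_id`,
#'   `n_viral`, `n_metazoan`, `n_leaves`, `viral_fraction`, `n_vc`,
#'   `condensation`, `max_leaf_depth`, `deepest_viral_depth`,
#'   `deepest_viral_leaves`, `normalized_viral_depths`,
#'   `vc_normalized_depths`, `selected`, `selection_reason`.
#' @export
classify_family <- function(tree, records, thresholds = selection_thresholds(),
                            family_id = NA_character_) {
  cls <- .leaf_classes(tree, records)
  n_viral <- sum(cls == "virus")
  n_metazoan <- sum(cls == "metazoa")
  if (n_viral == 0L)
    stop("family has no viral leaves; it should have been filtered out",
         call. = FALSE)
  d <- leaf_depths(tree)
  mx <- max(d)
  if (mx == 0L)
    stop("single-leaf tree: depth statistics undefined", call. = FALSE)
  vcs <- find_viral_clusters(tree, records)
  n_vc <- nrow(vcs)
  condensation <- n_viral / n_vc
  vd <- d[cls == "virus"]
  deepest <- max(vd)
  frac <- n_viral / length(d)

  marginal <- frac <= thresholds$max_viral_fraction
  few <- n_viral <= thresholds$max_viral_count_override
  simple <- n_vc <= thresholds$max_vc_simple
  condensed <- n_vc <= thresholds$max_vc_condensed &&
    condensation >= thresholds$min_condensation
  selected <- (marginal || few) && (simple || condensed)
  reason <- if (!selected) {
    if (!(marginal || few)) "viral presence not marginal"
    else "viral leaves not clustered"
  } else {
    paste0(if (marginal) "viral_fraction" else "viral_count",
           "+", if (simple) "few_vcs" else "condensed_vcs")
  }
  structure(list(family_id = family_id,
                 n_viral = n_viral,
                 n_metazoan = n_metazoan,
                 n_leaves = length(d),
                 viral_fraction = frac,
                 n_vc = n_vc,
                 condensation = condensation,
                 max_leaf_depth = mx,
                 deepest_viral_depth = unname(deepest),
                 deepest_viral_leaves = names(vd)[vd == deepest],
                 normalized_viral_depths = unname(vd) / mx,
                 vc_normalized_depths = vcs$depth / mx,
                 selected = selected,
                 selection_reason = reason),
            class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat(sprintf("family %s: %d viral / %d leaves (%.1f%%), %d VC(s), condensation %.2f\n",
              x$family_id, x$n_viral, x$n_leaves, 100 * x$viral_fraction,
              x$n_vc, x$condensation))
  cat(sprintf("  max leaf depth %d, deepest viral depth %d (norm. %.3f)\n",
              x$max_leaf_depth, x$deepest_viral_depth,
              x$deepest_viral_depth / x$max_leaf_depth))
  cat(sprintf("  selected: %s (%s)\n", x$selected, x$selection_reason))
  invisible(x)
}

#' Flatten topology reports to a table
#'
#' @param reports List of `"topology_report"` objects.
#' @return data.frame with one row per family; list-valued fields are
#'   comma-collapsed.
#' @export
topology_report_table <- function(reports) {
  row1 <- function(r) data.frame(
    family_id = r$family_id, n_viral = r$n_viral, n_metazoan = r$n_metazoan,
    n_leaves = r$n_leaves, viral_fraction = r$viral_fraction, n_vc = r$n_vc,
    condensation = r$condensation, max_leaf_depth = r$max_leaf_depth,
    deepest_viral_depth = r$deepest_viral_depth,
    deepest_viral_leaves = paste(r$deepest_viral_leaves, collapse = ","),
    normalized_viral_depths = paste(sprintf("%.4f", r$normalized_viral_depths),
                                    collapse = ","),
    vc_normalized_depths = paste(sprintf("%.4f", r$vc_normalized_depths),
                                 collapse = ","),
    selected = r$selected, selection_reason = r$selection_reason,
    stringsAsFactors = FALSE)
  do.call(rbind, lapply(reports, row1))
}
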