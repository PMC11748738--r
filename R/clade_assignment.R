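#' Cluster genomes into species at an ANI threshold
#'
#' Agglomerative average-linkage clustering on the distance 1 - ANI/100,
#' with the tree cut at 1 - threshold/100 so that a species cluster holds
#' genomes whose average pairwise identity is at least `threshold_ani`
#' (the conventional 95% species boundary by default). The full, uncut
#' dendrogram is kept: clade label propagation for unplaced clusters needs
#' the positions of clusters relative to named genomes in the whole tree.
#'
#' Genomes are ordered lexicographically before clustering so the result is
#' invariant to the input order of the matrix.
#'
#' @param ani an `ani_matrix` (see [ani_matrix()]).
#' @param threshold_ani species boundary in ANI percent, 0 < t < 100.
#' @return `species_clusters`: list with `partition` (named integer vector,
#'   genome -> cluster id), `tree` (the hclust object over genomes),
#'   `members` (list of genome ids per cluster), `threshold_ani`.
#' @export
cluster_species <- function(ani, threshold_ani = 95) {
  if (any(is.na(ani))) stop("ANI matrix contains NA")
  if (!(threshold_ani > 0 && threshold_ani < 100))
    stop("threshold_ani must lie in (0, 100)")
  ids <- sort(rownames(ani))
  m <- unclass(ani)[ids, ids, drop = FALSE]
  if (length(ids) == 1L) {
    part <- stats::setNames(1L, ids)
    return(structure(list(partition = part, tree = NULL,
                          members = list(`1` = ids),
                          threshold_ani = threshold_ani),
                     class = "species_clusters"))
  }
  d <- stats::as.dist(1 - m / 100)
  tree <- stats::hclust(d, method = "average")
  part <- stats::cutree(tree, h = 1 - threshold_ani / 100)
  # renumber clusters by their lexicographically smallest member for stability
  first <- vapply(split(names(part), part), min, character(1))
  remap <- stats::setNames(seq_along(first), names(first)[order(first)])
  part <- stats::setNames(as.integer(remap[as.character(part)]), names(part))
  members <- split(names(part), part)
  structure(list(partition = part, tree = tree, members = members,
                 threshold_ani = threshold_ani),
            class = "species_clusters")
}

#' @export
print.species_clusters <- function(x, ...) {
  cat(sprintf("species_clusters: %d genomes in %d clusters (>=%.1f%% ANI)\n",
              length(x$partition), length(x$members), x$threshold_ani))
  invisible(x)
}

# For each internal node of an hclust tree, the set of leaf indices below it.
hclust_node_members <- function(tree) {
  n <- nrow(tree$merge)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    kids <- tree$merge[i, ]
    out[[i]] <- unlist(lapply(kids, function(k)
      if (k < 0) -k else out[[k]]))
  }
  out
}

#' Assign clade labels to species clusters
#'
#' Clusters that contain a named reference species inherit its clade.
#' Unnamed clusters are placed by dendrogram position: the smallest merge
#' node containing the whole cluster plus at least one named genome is
#' located; if that node is the tree root, the cluster is basal to every
#' named clade and is labeled "Unknown", otherwise it attaches inside the
#' named part of the tree and is labeled "Other".
#'
#' @param clusters a `species_clusters` from [cluster_species()].
#' @param named_labels data.frame with columns `species` (genome id of a
#'   named reference genome) and `clade`.
#' @param conflict what to do when one cluster holds named species of two
#'   clades: `"error"` (default) or `"majority"` (majority vote, ties by
#'   clade order, with a warning).
#' @return `clade_map` data.frame: `genome`, `cluster`, `clade`,
#'   `provenance` in {named_reference, propagated, other_rule, unknown_rule}.
#' @export
assign_clades <- function(clusters, named_labels,
                          conflict = c("error", "majority")) {
  conflict <- match.arg(conflict)
  if (!all(c("species", "clade") %in% colnames(named_labels)))
    stop("named_labels needs 'species' and 'clade' columns")
  if (nrow(named_labels) == 0) stop("named_labels is empty")
  part <- clusters$partition
  genomes <- names(part)
  named <- named_labels[named_labels$species %in% genomes, , drop = FALSE]
  if (nrow(named) == 0)
    stop("no named reference species present among the clustered genomes")

  clade_of <- stats::setNames(named$clade, named$species)
  cluster_clade <- character(length(clusters$members))
  names(cluster_clade) <- names(clusters$members)
  for (cl in names(clusters$members)) {
    mem <- clusters$members[[cl]]
    hits <- clade_of[intersect(mem, names(clade_of))]
    if (length(unique(hits)) > 1) {
      msg <- sprintf("cluster %s holds named species of conflicting clades: %s",
                     cl, paste(unique(hits), collapse = ", "))
      if (conflict == "error") stop(msg)
      warning(msg, "; using majority vote")
      tab <- table(factor(hits, levels = CLADE_LABELS))
      hits <- names(tab)[which.max(tab)]
    }
    cluster_clade[cl] <- if (length(hits)) hits[1] else NA_character_
  }

  prov <- character(length(genomes))
  names(prov) <- genomes
  lab <- stats::setNames(cluster_clade[as.character(part)], genomes)
  prov[!is.na(lab)] <- ifelse(genomes[!is.na(lab)] %in% names(clade_of),
                              "named_reference", "propagated")

  unplaced <- names(cluster_clade)[is.na(cluster_clade)]
  if (length(unplaced)) {
    tree <- clusters$tree
    if (is.null(tree))
      stop("cannot place unnamed cluster without a dendrogram")
    node_members <- hclust_node_members(tree)
    leaf_ids <- tree$labels
    named_ids <- intersect(leaf_ids, names(clade_of))
    root <- nrow(tree$merge)
    for (cl in unplaced) {
      mem_idx <- match(clusters$members[[cl]], leaf_ids)
      # smallest node containing the full cluster and >= 1 named genome
      best <- NA_integer_
      best_size <- Inf
      for (nd in seq_len(root)) {
        nm <- node_members[[nd]]
        if (all(mem_idx %in% nm) &&
            any(leaf_ids[nm] %in% named_ids) &&
            length(nm) < best_size) {
          best <- nd
          best_size <- length(nm)
        }
      }
      is_root <- identical(best, root)
      label <- if (is_root) "Unknown" else "Other"
      for (g in clusters$members[[cl]]) {
        lab[g] <- label
        prov[g] <- if (is_root) "unknown_rule" else "other_rule"
      }
    }
  }

  data.frame(genome = genomes, cluster = unname(part),
             clade = unname(lab), provenance = unname(prov),
             stringsAsFactors = FALSE)
}

#' Collapse a genome-level clade map to species names
#'
#' Convenience for joining a clade map onto a species table: keeps one row
#' per genome id interpreted as a species name.
#'
#' @param map result of [assign_clades()] or a data.frame with `species` and
#'   `clade` columns.
#' @return named character vector species -> clade.
#' @export
clade_lookup <- function(map) {
  if (all(c("genome", "clade") %in% colnames(map)))
    return(stats::setNames(map$clade, map$genome))
  if (all(c("species", "clade") %in% colnames(map)))
    return(stats::setNames(map$clade, map$species))
  stop("not a clade map")
}
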