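# Grouping high-likelihood individuals into putative distorter families by
# graph traversal: nodes within `link_radius` pedigree edges of each other
# (2 covers sibling and grandparent-grandchild relationships) join the same
# family, and families extend through chains or webs of such links.

#' Select high-likelihood individuals
#'
#' Ids whose carrier posterior is strictly above the threshold ("above 40%"
#' is read strictly: a posterior of exactly 0.40 is excluded).
#'
#' @param post A carrier posterior (object or named numeric vector).
#' @param threshold Posterior cut-off in `[0, 1]` (default 0.40).
#' @return Sorted character vector of ids.
#' @export
high_likelihood_nodes <- function(post, threshold = 0.40) {
  stopifnot(threshold >= 0, threshold <= 1)
  v <- posterior_values(post)
  sort(names(v)[v > threshold], method = "radix")
}

#' Cluster related high-likelihood individuals into families
#'
#' Builds an auxiliary graph on `nodes` with an edge wherever the
#' undirected pedigree distance is at most `link_radius` (distances are
#' measured in the full pedigree, so low-likelihood relatives can serve as
#' path intermediates), and returns its connected components. Isolated
#' high-likelihood individuals form singleton clusters. The output is
#' invariant to the order of `nodes`.
#'
#' @param ped A [pedigree()].
#' @param nodes Character vector of high-likelihood ids
#'   (from [high_likelihood_nodes()]).
#' @param link_radius Maximum linking distance in edges (default 2).
#' @param posterior Optional carrier posterior used to pick each cluster's
#'   representative (the member with the maximum posterior; otherwise the
#'   alphabetically first member).
#' @return A list of `family_cluster` objects (`member_ids`,
#'   `representative_id`), sorted by first member id.
#' @export
cluster_relatives <- function(ped, nodes, link_radius = 2, posterior = NULL) {
  stopifnot(inherits(ped, "pedigree"), link_radius >= 1)
  nodes <- unique(as.character(nodes))
  unknown <- setdiff(nodes, ped$id)
  if (length(unknown)) {
    stop(sprintf("unknown individual id: %s", unknown[[1L]]))
  }
  if (!length(nodes)) return(list())
  nodes <- sort(nodes, method = "radix")
  g <- ped_igraph(ped)
  d <- igraph::distances(g, v = nodes, to = nodes)
  adj <- is.finite(d) & d <= link_radius
  sub <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
  memb <- igraph::components(sub)$membership
  pv <- if (!is.null(posterior)) posterior_values(posterior) else NULL
  clusters <- lapply(split(nodes, memb), function(members) {
    members <- sort(members, method = "radix")
    rep_id <- if (is.null(pv)) {
      members[[1L]]
    } else {
      members[[which.max(pv[members])]]
    }
    structure(list(member_ids = members, representative_id = rep_id),
              class = "family_cluster")
  })
  clusters <- unname(clusters)
  clusters[order(vapply(clusters, function(cl) cl$member_ids[[1L]], ""),
                 method = "radix")]
}

#' @export
print.family_cluster <- function(x, ...) {
  cat(sprintf("<family_cluster> %d members, representative %s\n",
              length(x$member_ids), x$representative_id))
  invisible(x)
}

#' Tabulate family clusters
#'
#' @param clusters List from [cluster_relatives()].
#' @param posterior Optional carrier posterior to attach per member.
#' @return A data.frame with `cluster_id`, `member_id` and (if available)
#'   `posterior`.
#' @export
cluster_table <- function(clusters, posterior = NULL) {
  if (!length(clusters)) {
    return(data.frame(cluster_id = integer(0), member_id = character(0),
                      posterior = numeric(0)))
  }
  pv <- if (!is.null(posterior)) posterior_values(posterior) else NULL
  do.call(rbind, lapply(seq_along(clusters), function(k) {
    ids <- clusters[[k]]$member_ids
    data.frame(cluster_id = k, member_id = ids,
               posterior = if (is.null(pv)) NA_real_ else unname(pv[ids]),
               stringsAsFactors = FALSE)
  }))
}
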