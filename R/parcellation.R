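#' Random geodesic Voronoi parcellation
#'
#' Draws `n_per_hemisphere` seed vertices uniformly without replacement on
#' each hemisphere and assigns every cortical vertex to its nearest seed by
#' unweighted graph geodesic distance; ties go to the lower seed index,
#' which makes every parcel a connected subgraph. Parcels carry no
#' functional or anatomical meaning by construction. Subcortical nodes are
#' grouped by their structure label (one parcel per structure), not by
#' Voronoi tessellation.
#'
#' @param space a `brain_space`.
#' @param n_per_hemisphere parcels per hemisphere (<= hemisphere size).
#' @param seed RNG seed for seed-vertex sampling.
#' @return A `parcellation`: per-vertex labels (`1..2n` cortical parcels,
#'   then one label per subcortical structure), seed vertices, counts.
#' @export
voronoi_parcellate <- function(space, n_per_hemisphere, seed = 1L) {
  stopifnot(inherits(space, "brain_space"))
  stopifnot_scalar_count(n_per_hemisphere, "n_per_hemisphere")
  np <- as.integer(n_per_hemisphere)
  n <- space$n_per_hemisphere
  if (np > n) stop("`n_per_hemisphere` exceeds hemisphere vertex count", call. = FALSE)

  seeds <- local_seed(seed, list(L = sort(sample.int(n, np)),
                                 R = sort(sample.int(n, np))))

  labels <- integer(space$n_vertices)
  for (h in c("L", "R")) {
    idx <- space_indices(space, h)
    adj_local <- lapply(space$adjacency[idx], function(v) v - (idx[1L] - 1L))
    g <- igraph::graph_from_adj_list(adj_local, mode = "all")
    d <- igraph::distances(g, v = seeds[[h]])  # np x n, unweighted BFS
    # nearest seed, ties to the lower seed index (apply/which.min does this)
    assign_local <- apply(d, 2L, which.min)
    offset <- if (h == "L") 0L else np
    labels[idx] <- offset + assign_local
  }
  sc <- space_indices(space, "SC")
  labels[sc] <- 2L * np + space$structure[sc]

  structure(list(
    labels = labels,
    n_per_hemisphere = np,
    n_cortical_parcels = 2L * np,
    n_parcels = 2L * np + space$n_structures,
    seeds = seeds,
    seed = as.integer(seed)
  ), class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  sizes <- table(x$labels[x$labels <= x$n_cortical_parcels])
  cat(sprintf("parcellation: %d parcels/hemisphere (+%d subcortical), cortical sizes %d-%d\n",
              x$n_per_hemisphere, x$n_parcels - x$n_cortical_parcels,
              min(sizes), max(sizes)))
  invisible(x)
}

#' Per-vertex parcel label table
#'
#' @param parcellation a `parcellation`.
#' @return A data frame with `vertex` and `parcel` columns, suitable for
#'   export as a label file.
#' @export
parcel_table <- function(parcellation) {
  data.frame(vertex = seq_along(parcellation$labels), parcel = parcellation$labels)
}

# TRUE when every parcel induces a connected subgraph of the space.
parcels_connected <- function(space, parcellation) {
  for (p in seq_len(parcellation$n_cortical_parcels)) {
    members <- which(parcellation$labels == p)
    if (length(members) <= 1L) next
    sub <- igraph::graph_from_adjacency_matrix(
      space$A[members, members, drop = FALSE] > 0, mode = "undirected")
    if (igraph::components(sub)$no != 1L) return(FALSE)
  }
  TRUE
}
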