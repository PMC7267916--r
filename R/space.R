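#' Build a synthetic grayordinate space
#'
#' Constructs a small stand-in for the grayordinate analysis domain: two
#' mirrored cortical "hemispheres" sampled on the unit sphere with
#' k-nearest-neighbour adjacency, plus a set of labelled subcortical
#' structures. The right hemisphere is the exact mirror image (x -> -x) of
#' the left, so vertex `i` on the left pairs with vertex `n + i` on the
#' right and both hemisphere graphs are isomorphic by construction.
#'
#' @param n_vertices_per_hemisphere number of cortical vertices per
#'   hemisphere (>= 50).
#' @param n_subcortical_structures number of subcortical structures (>= 1).
#' @param seed RNG seed; identical seeds give identical spaces.
#' @param k_neighbors neighbours per vertex for the cortical mesh (default 6,
#'   the typical vertex degree of a triangulated surface).
#' @param nodes_per_structure subcortical nodes per structure (default 3).
#'
#' @return A `brain_space` object: vertex coordinates, hemisphere labels
#'   (`"L"`, `"R"`, `"SC"`), symmetric cortical adjacency (neighbour lists
#'   and a sparse matrix), subcortical structure labels, and the
#'   left-to-right mirror map.
#' @export
make_space <- function(n_vertices_per_hemisphere, n_subcortical_structures, seed,
                       k_neighbors = 6L, nodes_per_structure = 3L) {
  stopifnot_scalar_count(n_vertices_per_hemisphere, "n_vertices_per_hemisphere")
  stopifnot_scalar_count(n_subcortical_structures, "n_subcortical_structures")
  if (n_vertices_per_hemisphere < 50)
    stop("`n_vertices_per_hemisphere` must be >= 50", call. = FALSE)

  n <- as.integer(n_vertices_per_hemisphere)
  S <- as.integer(n_subcortical_structures)
  m <- as.integer(nodes_per_structure)

  local_seed(seed, {
    # Points on the unit sphere (area-uniform); the right hemisphere reuses
    # the same layout mirrored through the y-z plane so mirrored maps are
    # exact, not approximate.
    z <- stats::runif(n, -1, 1)
    th <- stats::runif(n, 0, 2 * pi)
    r <- sqrt(pmax(0, 1 - z^2))
    left <- cbind(x = r * cos(th), y = r * sin(th), z = z)
    right <- left
    right[, "x"] <- -right[, "x"]

    nbr <- knn_neighbors(left, k_neighbors)
    nbr <- connect_components(left, nbr)

    sc_coords <- matrix(stats::rnorm(S * m * 3, sd = 0.2), ncol = 3)
    colnames(sc_coords) <- c("x", "y", "z")
  })

  n_sc <- S * m
  coords <- rbind(left, right, sc_coords)
  hemisphere <- c(rep("L", n), rep("R", n), rep("SC", n_sc))
  structure_label <- c(rep(0L, 2L * n), rep(seq_len(S), each = m))

  # Right-hemisphere adjacency mirrors the left; subcortical nodes are fully
  # connected within their structure.
  adj <- vector("list", 2L * n + n_sc)
  for (i in seq_len(n)) {
    adj[[i]] <- nbr[[i]]
    adj[[n + i]] <- nbr[[i]] + n
  }
  for (s in seq_len(S)) {
    members <- 2L * n + (s - 1L) * m + seq_len(m)
    for (v in members) adj[[v]] <- setdiff(members, v)
  }

  ij <- do.call(rbind, lapply(seq_len(2L * n), function(i)
    if (length(adj[[i]])) cbind(i, adj[[i]]) else NULL))
  A <- Matrix::sparseMatrix(i = ij[, 1L], j = ij[, 2L], x = 1,
                            dims = c(2L * n + n_sc, 2L * n + n_sc))

  out <- list(
    coords = coords,
    hemisphere = hemisphere,
    structure = structure_label,
    adjacency = adj,
    A = A,
    mirror = c(n + seq_len(n), seq_len(n)),  # mirror[i] for cortical i
    n_per_hemisphere = n,
    n_cortical = 2L * n,
    n_vertices = 2L * n + n_sc,
    n_structures = S,
    nodes_per_structure = m,
    seed = as.integer(seed),
    k_neighbors = as.integer(k_neighbors)
  )
  class(out) <- "brain_space"
  out
}

#' @export
print.brain_space <- function(x, ...) {
  cat(sprintf(
    "brain_space: %d cortical vertices (%d per hemisphere), %d subcortical structures (%d nodes)\n",
    x$n_cortical, x$n_per_hemisphere, x$n_structures, x$n_vertices - x$n_cortical))
  invisible(x)
}

# Indices of the vertices in one compartment of the space.
space_indices <- function(space, which = c("L", "R", "cortical", "SC")) {
  which <- match.arg(which)
  switch(which,
         L = seq_len(space$n_per_hemisphere),
         R = space$n_per_hemisphere + seq_len(space$n_per_hemisphere),
         cortical = seq_len(space$n_cortical),
         SC = space$n_cortical + seq_len(space$n_vertices - space$n_cortical))
}

# Binary indicator maps (n_vertices x n_structures) of subcortical membership.
subcortical_indicators <- function(space) {
  S <- space$n_structures
  out <- matrix(0, space$n_vertices, S)
  for (s in seq_len(S)) out[which(space$structure == s), s] <- 1
  colnames(out) <- paste0("SC", seq_len(S))
  out
}

# Symmetric k-NN neighbour lists from a coordinate matrix.
knn_neighbors <- function(coords, k) {
  n <- nrow(coords)
  D <- as.matrix(stats::dist(coords))
  diag(D) <- Inf
  nbr <- lapply(seq_len(n), function(i) order(D[i, ])[seq_len(min(k, n - 1L))])
  # symmetrize
  for (i in seq_len(n)) for (j in nbr[[i]])
    if (!(i %in% nbr[[j]])) nbr[[j]] <- c(nbr[[j]], i)
  lapply(nbr, sort)
}

# Join disconnected k-NN components by adding the shortest bridging edge
# until the graph is a single component.
connect_components <- function(coords, nbr) {
  n <- length(nbr)
  D <- as.matrix(stats::dist(coords))
  repeat {
    g <- igraph::graph_from_adj_list(nbr, mode = "all")
    comp <- igraph::components(g)
    if (comp$no == 1L) break
    main <- which(comp$membership == which.max(comp$csize))
    other <- which(comp$membership != which.max(comp$csize))
    sub <- D[other, main, drop = FALSE]
    idx <- arrayInd(which.min(sub), dim(sub))
    i <- other[idx[1L]]; j <- main[idx[2L]]
    nbr[[i]] <- sort(c(nbr[[i]], j))
    nbr[[j]] <- sort(c(nbr[[j]], i))
  }
  nbr
}

# Row-normalized cortical adjacency operator used for smoothing on the mesh.
smoothing_operator <- function(space) {
  idx <- seq_len(space$n_cortical)
  A <- space$A[idx, idx, drop = FALSE]
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  Matrix::Diagonal(x = 1 / deg) %*% A
}

# Nearest-neighbour diffusion smoothing of cortical maps: `steps` rounds of
# x <- (x + Wx) / 2. `x` has one row per cortical vertex.
smooth_cortical <- function(space, x, steps) {
  W <- smoothing_operator(space)
  x <- as.matrix(x)
  for (i in seq_len(max(0L, round(steps)))) x <- as.matrix((x + W %*% x) / 2)
  x
}
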