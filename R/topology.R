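#' Signed incidence structure of a confluent polygonal monolayer
#'
#' Builds the primal network of a monolayer from a list of cells, each an
#' ordered (clockwise) cycle of vertex indices. Edges are enumerated uniquely
#' and oriented from their lower-indexed to their higher-indexed vertex; the
#' edge--vertex incidence matrix `A` (one row per edge, -1 at the tail, +1 at
#' the head) and the cell--edge incidence matrix `B` (+1 where the cell
#' traverses the edge along its orientation, -1 against) then encode the full
#' topology and satisfy the chain-complex identity `B %*% A == 0`.
#'
#' Edges incident to a single cell are peripheral; this includes both the
#' outer boundary and the boundaries of any internal holes. The number of
#' holes follows from the Euler formula
#' `n_vertices - n_edges + n_cells = 1 - n_holes`.
#'
#' @param cells list of integer vectors, each a simple clockwise cycle of
#'   vertex indices (1-based). Shared borders between adjacent cells must
#'   coincide vertex-by-vertex (confluence).
#' @param n_vertices total number of vertices; defaults to the largest index
#'   appearing in `cells`.
#' @param cell_ids optional stable identifiers for the cells (defaults to
#'   `seq_along(cells)`); preserved across ablation and neighbour exchanges.
#' @return an object of class `mono_topology`: a list with counts
#'   (`n_vertices`, `n_edges`, `n_cells`, `n_holes`), sparse incidence
#'   matrices `A`, `B`, the edge endpoint table `edges`, logical masks
#'   `peripheral_edges`, `peripheral_vertices`, and `boundary_cycles`
#'   (oriented vertex cycles of each boundary component).
#' @export
build_topology <- function(cells, n_vertices = NULL, cell_ids = NULL) {
  if (length(cells) < 1L) stop("need at least one cell")
  cells <- lapply(cells, as.integer)
  bad <- vapply(cells, function(cc) length(cc) < 3L || anyDuplicated(cc) > 0L,
                logical(1))
  if (any(bad)) stop("each cell must be a simple cycle of >= 3 distinct vertices")
  if (is.null(n_vertices)) n_vertices <- max(unlist(cells))
  if (is.null(cell_ids)) cell_ids <- seq_along(cells)
  n_cells <- length(cells)

  ## directed half-edges, one per cell corner
  zl  <- lengths(cells)
  ci  <- rep.int(seq_len(n_cells), zl)
  va  <- unlist(cells, use.names = FALSE)
  vb  <- unlist(lapply(cells, function(cc) c(cc[-1L], cc[1L])), use.names = FALSE)
  if (any(va == vb)) stop("degenerate edge (cell revisits a vertex consecutively)")

  tail <- pmin(va, vb)
  head <- pmax(va, vb)
  key  <- paste(tail, head)
  ue   <- !duplicated(key)
  edge_id <- match(key, key[ue])
  n_edges <- sum(ue)
  edges   <- cbind(tail = tail[ue], head = head[ue])

  mult <- tabulate(edge_id, n_edges)
  if (any(mult > 2L))
    stop("non-manifold edge: more than two cells share an edge")
  ## two cells traversing an edge in the same direction => inconsistent winding
  dirkey <- paste(va, vb)
  if (anyDuplicated(dirkey) > 0L)
    stop("inconsistent winding: two cells traverse an edge in the same direction")

  A <- Matrix::sparseMatrix(
    i = c(seq_len(n_edges), seq_len(n_edges)),
    j = c(edges[, "tail"], edges[, "head"]),
    x = c(rep(-1, n_edges), rep(1, n_edges)),
    dims = c(n_edges, n_vertices))
  B <- Matrix::sparseMatrix(
    i = ci, j = edge_id,
    x = ifelse(va == tail, 1, -1),
    dims = c(n_cells, n_edges))

  BA <- B %*% A
  if (length(BA@x) && max(abs(BA@x)) != 0)
    stop("incidence inconsistency: B %*% A != 0")

  peripheral_edges <- mult == 1L
  peripheral_vertices <- rep(FALSE, n_vertices)
  peripheral_vertices[edges[peripheral_edges, , drop = FALSE]] <- TRUE

  used_vertices <- sort(unique(c(edges)))
  if (length(used_vertices) != n_vertices)
    stop("isolated vertices present: every vertex must belong to an edge")
  ## connectivity of the vertex graph
  comp <- .vertex_components(edges, n_vertices)
  if (max(comp) > 1L) stop("disconnected network")

  chi <- n_vertices - n_edges + n_cells
  n_holes <- 1L - chi
  if (n_holes < 0L) stop("invalid topology: Euler characteristic exceeds 1")

  cycles <- .boundary_cycles(edges, peripheral_edges, n_vertices)
  if (length(cycles) != n_holes + 1L)
    stop(sprintf("boundary cycle count (%d) inconsistent with hole count (%d)",
                 length(cycles), n_holes))

  structure(list(
    n_vertices = n_vertices, n_edges = n_edges, n_cells = n_cells,
    A = A, B = B, edges = edges, cells = cells, cell_ids = cell_ids,
    edge_of_pair = stats::setNames(seq_len(n_edges), paste(edges[, 1], edges[, 2])),
    peripheral_edges = peripheral_edges,
    peripheral_vertices = peripheral_vertices,
    n_holes = n_holes, boundary_cycles = cycles
  ), class = "mono_topology")
}

.vertex_components <- function(edges, n_vertices) {
  comp <- integer(n_vertices)
  adj <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
  labs <- as.integer(names(adj))
  idx <- integer(n_vertices); idx[labs] <- seq_along(adj)
  cur <- 0L
  for (v in seq_len(n_vertices)) {
    if (comp[v] != 0L) next
    cur <- cur + 1L
    queue <- v; comp[v] <- cur
    while (length(queue)) {
      u <- queue[[1L]]; queue <- queue[-1L]
      nb <- adj[[idx[u]]]
      nb <- nb[comp[nb] == 0L]
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

## walk the 1-cell boundary edges into closed vertex cycles
.boundary_cycles <- function(edges, peripheral, n_vertices) {
  be <- which(peripheral)
  if (!length(be)) return(list())
  ends <- edges[be, , drop = FALSE]
  inc <- split(rep(be, 2L), c(ends[, 1], ends[, 2]))
  vids <- as.integer(names(inc))
  if (any(lengths(inc) != 2L))
    stop("boundary is not a disjoint union of simple cycles")
  pos <- integer(n_vertices); pos[vids] <- seq_along(inc)
  seen <- rep(FALSE, length(be))
  names(seen) <- be
  cycles <- list()
  for (s in seq_along(be)) {
    if (seen[s]) next
    e0 <- be[s]
    cyc <- integer(0)
    v <- edges[e0, 1]
    e <- e0
    repeat {
      seen[as.character(e)] <- TRUE
      cyc <- c(cyc, v)
      ends_e <- edges[e, ]
      v_next <- if (ends_e[1] == v) ends_e[2] else ends_e[1]
      cand <- inc[[pos[v_next]]]
      e_next <- cand[cand != e]
      v <- v_next
      e <- e_next
      if (e == e0) { cyc <- c(cyc, v); break }
    }
    ## last vertex closes onto the first edge's start
    cycles[[length(cycles) + 1L]] <- cyc
  }
  cycles
}

#' Euler characteristic of a monolayer network
#'
#' Returns `n_vertices - n_edges + n_cells`, which equals `1 - n_holes` for a
#' planar confluent monolayer with `n_holes` internal holes.
#'
#' @param x a `mono_topology`, `mono_mesh`, or `vm_state`
#' @return integer Euler characteristic
#' @export
euler_characteristic <- function(x) {
  top <- as_topology(x)
  top$n_vertices - top$n_edges + top$n_cells
}

as_topology <- function(x) {
  if (inherits(x, "mono_topology")) return(x)
  if (inherits(x, "mono_mesh")) return(x$topology)
  if (inherits(x, "vm_state")) return(vm_topology(x))
  stop("cannot extract a topology from this object")
}

#' Reduced incidence matrices suppressing the periphery
#'
#' Boundary conditions are implemented on reduced networks: the reduced primal
#' network drops peripheral edges and peripheral vertices, and the reduced
#' dual network drops links to peripheral edge midpoints. Concretely, `A_hat`
#' is `A` with peripheral-edge rows and peripheral-vertex columns zeroed and
#' `B_hat` is `B` with peripheral-edge columns zeroed; the pair still
#' satisfies `B_hat %*% A_hat == 0` exactly. Hole boundaries (after ablation)
#' bound a single cell and are treated exactly like the outer periphery.
#'
#' @param topology a `mono_topology`
#' @return a list of class `mono_reduced` with the zero-padded `A_hat`,
#'   `B_hat` on the full index sets, the restricted matrices `A_int`
#'   (interior edges x interior vertices) and `B_int` (cells x interior
#'   edges), and the retained index vectors `retained_edges`,
#'   `retained_vertices`.
#' @export
reduce_incidence <- function(topology) {
  top <- as_topology(topology)
  ie <- which(!top$peripheral_edges)
  iv <- which(!top$peripheral_vertices)
  A_hat <- top$A
  if (any(top$peripheral_edges)) A_hat[top$peripheral_edges, ] <- 0
  if (any(top$peripheral_vertices)) A_hat[, top$peripheral_vertices] <- 0
  B_hat <- top$B
  if (any(top$peripheral_edges)) B_hat[, top$peripheral_edges] <- 0
  A_hat <- Matrix::drop0(A_hat)
  B_hat <- Matrix::drop0(B_hat)
  BA <- B_hat %*% A_hat
  stopifnot(length(BA@x) == 0 || max(abs(BA@x)) == 0)
  structure(list(
    A_hat = A_hat, B_hat = B_hat,
    A_int = top$A[ie, iv, drop = FALSE],
    B_int = top$B[, ie, drop = FALSE],
    retained_edges = ie, retained_vertices = iv
  ), class = "mono_reduced")
}
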