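## Orientation conventions, fixed once for the whole package:
##  * cells are wound clockwise; eps_i is the clockwise (-pi/2) rotation,
##    eps_k = -eps_i the anticlockwise one;
##  * with these choices all cell areas A_i, triangle areas E_k and interior
##    parallelogram areas F_j = T_j . eps_i t_j come out strictly positive on
##    any valid confluent mesh, with no per-edge sign fixing.
EPS_I <- matrix(c(0, -1, 1, 0), 2, 2)   # rows: (0,1;-1,0): (x,y) -> (y,-x)
EPS_K <- -EPS_I

rot_cw  <- function(v) cbind(v[, 2], -v[, 1])   # eps_i applied to row vectors
rot_ccw <- function(v) cbind(-v[, 2], v[, 1])   # eps_k

#' Metric data of a monolayer mesh
#'
#' Computes every geometric quantity the calculus needs from vertex positions:
#' cell centres `Rc` (vertex centroids), edge vectors `t_vec`, link vectors
#' `T_vec` (between adjacent cell centres, or between a cell centre and the
#' edge centroid on the periphery), edge centroids `c_mid`, edge--link
#' intersection points `b_pt`, cell areas `A_cell`, vertex triangle areas
#' `E_tri` (spanned by the cell centres around each vertex, closed by
#' peripheral edge centroids at the boundary), and the parallelogram areas
#' `F_par` spanned by each edge and its link.
#'
#' @param topology a `mono_topology`
#' @param r numeric matrix (n_vertices x 2) of vertex positions
#' @return a list of class `mono_geometry`
#' @export
compute_geometry <- function(topology, r) {
  top <- as_topology(topology)
  r <- as.matrix(r)
  stopifnot(nrow(r) == top$n_vertices, ncol(r) == 2)

  zl <- lengths(top$cells)
  ci <- rep.int(seq_len(top$n_cells), zl)
  vs <- unlist(top$cells, use.names = FALSE)
  Rc <- cbind(rowsum(r[vs, 1], ci), rowsum(r[vs, 2], ci)) / zl

  ## signed cell areas: clockwise winding => -shoelace > 0
  vn <- unlist(lapply(top$cells, function(cc) c(cc[-1L], cc[1L])), use.names = FALSE)
  cross <- r[vs, 1] * r[vn, 2] - r[vn, 1] * r[vs, 2]
  A_cell <- -0.5 * as.numeric(rowsum(cross, ci))
  if (any(A_cell <= 0))
    stop("orientation error: non-positive cell area (cells must be wound clockwise)")

  t_vec <- cbind(r[top$edges[, "head"], 1] - r[top$edges[, "tail"], 1],
                 r[top$edges[, "head"], 2] - r[top$edges[, "tail"], 2])
  t_len <- sqrt(rowSums(t_vec^2))
  if (any(t_len == 0)) stop("degenerate geometry: zero-length edge")
  c_mid <- 0.5 * (r[top$edges[, "tail"], , drop = FALSE] +
                  r[top$edges[, "head"], , drop = FALSE])

  ## links: T_j = sum_i B_ij (Rc_i - c_j); the centroid term cancels on
  ## interior edges and closes peripheral links at the edge centroid
  Bt <- Matrix::t(top$B)
  T_vec <- cbind(as.numeric(Bt %*% Rc[, 1]), as.numeric(Bt %*% Rc[, 2]))
  csum <- as.numeric(Bt %*% rep(1, top$n_cells))   # +-1 on peripheral edges
  T_vec <- T_vec - csum * c_mid
  T_len <- sqrt(rowSums(T_vec^2))

  F_par <- rowSums(T_vec * rot_cw(t_vec))
  if (any(F_par[!top$peripheral_edges] <= 0))
    stop("orientation error: non-positive parallelogram area on an interior edge")
  if (any(F_par <= 0))
    stop("orientation error: non-positive parallelogram area on a peripheral edge")

  ## edge-line / link-line intersection b_j. Link line passes through b0 with
  ## direction T; edge line through the tail vertex with direction t.
  b0 <- .link_base(top, Rc, c_mid)
  b_pt <- matrix(NA_real_, top$n_edges, 2)
  tl <- r[top$edges[, "tail"], , drop = FALSE]
  dx <- b0 - tl
  den <- t_vec[, 1] * (-T_vec[, 2]) - t_vec[, 2] * (-T_vec[, 1])
  s <- (dx[, 1] * (-T_vec[, 2]) - dx[, 2] * (-T_vec[, 1])) / den
  b_pt <- tl + s * t_vec
  if (any(s < -1e-9 | s > 1 + 1e-9))
    warning("edge-link intersection outside an edge segment (irregular mesh); using it as-is")

  ## cell-vertex adjacency and counts
  C_adj <- Matrix::sparseMatrix(i = ci, j = vs, x = 1,
                                dims = c(top$n_cells, top$n_vertices))
  Z <- zl

  E_tri <- .triangle_areas(top, r, Rc, c_mid)

  structure(list(
    r = r, Rc = Rc, t_vec = t_vec, T_vec = T_vec, t_len = t_len, T_len = T_len,
    c_mid = c_mid, b_pt = b_pt, A_cell = A_cell, E_tri = E_tri, F_par = F_par,
    C_adj = C_adj, Z = Z
  ), class = "mono_geometry")
}

## a point on each link line: interior -> either cell centre; peripheral ->
## the adjacent cell centre
.link_base <- function(top, Rc, c_mid) {
  first_cell <- integer(top$n_edges)
  Bt <- as(Matrix::t(top$B), "TsparseMatrix")
  ## for each edge take one incident cell
  ord <- order(Bt@i)
  first <- !duplicated(Bt@i[ord])
  first_cell[Bt@i[ord][first] + 1L] <- Bt@j[ord][first] + 1L
  Rc[first_cell, , drop = FALSE]
}

## polygon area around each vertex spanned by incident cell centres, plus the
## centroids of incident peripheral edges for boundary vertices; ordered by
## angle around the vertex (triangles for interior 3-valent vertices)
.triangle_areas <- function(top, r, Rc, c_mid) {
  n_v <- top$n_vertices
  zl <- lengths(top$cells)
  ci <- rep.int(seq_len(top$n_cells), zl)
  vs <- unlist(top$cells, use.names = FALSE)
  cells_at <- split(ci, vs)
  vlab <- as.integer(names(cells_at))
  pe <- which(top$peripheral_edges)
  pedges_at <- split(rep(pe, 2L), c(top$edges[pe, 1], top$edges[pe, 2]))
  E <- numeric(n_v)
  for (idx in seq_along(cells_at)) {
    v <- vlab[idx]
    pts <- Rc[cells_at[[idx]], , drop = FALSE]
    pkey <- as.character(v)
    if (!is.null(pedges_at[[pkey]]))
      pts <- rbind(pts, c_mid[pedges_at[[pkey]], , drop = FALSE])
    if (nrow(pts) < 3) { E[v] <- 0; next }
    rel <- sweep(pts, 2, r[v, ])
    o <- order(atan2(rel[, 2], rel[, 1]))
    p <- pts[o, , drop = FALSE]
    pn <- p[c(2:nrow(p), 1), , drop = FALSE]
    E[v] <- abs(0.5 * sum(p[, 1] * pn[, 2] - pn[, 1] * p[, 2]))
  }
  E
}

#' Assemble a monolayer mesh
#'
#' Convenience constructor pairing a topology with its geometry and the
#' reduced (periphery-suppressed) incidence structure.
#'
#' @param cells list of clockwise vertex cycles
#' @param vertices numeric matrix (n x 2) of vertex positions
#' @param cell_ids optional stable cell identifiers
#' @return an object of class `mono_mesh` with elements `topology`,
#'   `geometry`, `reduced`
#' @export
mono_mesh <- function(cells, vertices, cell_ids = NULL) {
  top <- build_topology(cells, n_vertices = nrow(vertices), cell_ids = cell_ids)
  geo <- compute_geometry(top, vertices)
  structure(list(topology = top, geometry = geo,
                 reduced = reduce_incidence(top)),
            class = "mono_mesh")
}

#' @export
print.mono_mesh <- function(x, ...) {
  top <- x$topology
  cat(sprintf("<mono_mesh> %d cells, %d edges, %d vertices, %d hole(s), chi = %d\n",
              top$n_cells, top$n_edges, top$n_vertices, top$n_holes,
              euler_characteristic(top)))
  invisible(x)
}

#' Diagonal metric operators on the reduced networks
#'
#' Gathers the metric weights used by the Hodge stars and Laplacians:
#' `E_hat` (triangle areas over interior vertices), `H` (cell areas),
#' `Te_hat = t_j^2 / F_j` and `Tl_hat = T_j^2 / F_j` over interior edges.
#' `Te_hat` and `Tl_hat` are mutual inverses exactly when every edge is
#' orthogonal to its link.
#'
#' @param geometry a `mono_geometry`
#' @param reduced a `mono_reduced`
#' @return list of class `mono_metric` with numeric weight vectors
#' @export
metric_operators <- function(geometry, reduced) {
  ie <- reduced$retained_edges
  iv <- reduced$retained_vertices
  F_j <- geometry$F_par[ie]
  if (any(F_j == 0)) stop("degenerate geometry: zero parallelogram area")
  out <- list(
    E_hat = geometry$E_tri[iv],
    H = geometry$A_cell,
    Te_hat = geometry$t_len[ie]^2 / F_j,
    Tl_hat = geometry$T_len[ie]^2 / F_j)
  stopifnot(all(out$E_hat > 0), all(out$H > 0),
            all(out$Te_hat > 0), all(out$Tl_hat > 0))
  class(out) <- "mono_metric"
  out
}
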