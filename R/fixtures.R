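#' Regular hexagonal monolayer patch
#'
#' Deterministic fixture: a centred hexagonal tiling with `rings` shells
#' around a central cell (`3 * rings * (rings + 1) + 1` cells in total).
#' Edges and links are exactly orthogonal everywhere in its interior, which
#' makes it the reference mesh for the degeneracies that orthogonality
#' induces among the differential operators.
#'
#' @param rings number of shells (>= 0); `rings = 0` is a single hexagon
#' @param side edge length
#' @return a `mono_mesh`
#' @export
hex_patch <- function(rings = 2, side = 1) {
  stopifnot(rings >= 0)
  centers <- list()
  for (q in -rings:rings) for (rr in -rings:rings) {
    if (abs(q + rr) > rings) next
    centers[[length(centers) + 1L]] <- c(q, rr)
  }
  ang <- (0:5) * pi / 3
  hexoff <- cbind(cos(ang), sin(ang)) * side
  verts <- list(); keys <- character(0); cells <- list()
  for (cc in centers) {
    ctr <- c(1.5 * side * cc[1], sqrt(3) * side * (cc[2] + cc[1] / 2))
    vv <- sweep(hexoff, 2, ctr, "+")
    ids <- integer(6)
    for (m in 1:6) {
      k <- sprintf("%.9f_%.9f", vv[m, 1], vv[m, 2])
      pos <- match(k, keys)
      if (is.na(pos)) {
        keys <- c(keys, k)
        verts[[length(verts) + 1L]] <- vv[m, ]
        pos <- length(verts)
      }
      ids[m] <- pos
    }
    cells[[length(cells) + 1L]] <- rev(ids)  # clockwise winding
  }
  mono_mesh(cells, do.call(rbind, verts))
}

#' Hexagonal patch with interior holes
#'
#' Fixture for multiply-connected monolayers: a `hex_patch` with 1--3
#' pairwise non-adjacent interior cells removed, so that the Euler
#' characteristic is `1 - holes` and the edge Laplacian kernel has dimension
#' `holes`.
#'
#' @param rings number of shells (>= 2)
#' @param holes number of removed cells (1--3)
#' @param side edge length
#' @return a `mono_mesh`
#' @export
hex_annulus <- function(rings = 3, holes = 1, side = 1) {
  stopifnot(rings >= 2, holes >= 1, holes <= 3)
  mesh <- hex_patch(rings, side)
  ## axial coordinates of removed cells: centre, then two opposite cells
  targets <- list(c(0, 0), c(2, -1), c(-2, 1))[seq_len(holes)]
  if (holes > 1 && rings < 3) stop("need rings >= 3 for more than one hole")
  cn <- t(vapply(targets, function(ax)
    c(1.5 * side * ax[1], sqrt(3) * side * (ax[2] + ax[1] / 2)), numeric(2)))
  Rc <- mesh$geometry$Rc
  drop_cells <- vapply(seq_len(nrow(cn)), function(m)
    which.min((Rc[, 1] - cn[m, 1])^2 + (Rc[, 2] - cn[m, 2])^2), integer(1))
  remove_cells_mesh(mesh, drop_cells)
}

## remove cells from a mesh, discarding edges/vertices left without any cell
remove_cells_mesh <- function(mesh, drop_cells) {
  top <- mesh$topology
  pv <- top$peripheral_vertices
  for (i in drop_cells) {
    if (any(pv[top$cells[[i]]]))
      stop("cannot remove a cell touching the periphery")
  }
  keep <- setdiff(seq_len(top$n_cells), drop_cells)
  cells <- top$cells[keep]
  used <- sort(unique(unlist(cells)))
  remap <- integer(top$n_vertices); remap[used] <- seq_along(used)
  cells <- lapply(cells, function(cc) remap[cc])
  mono_mesh(cells, mesh$geometry$r[used, , drop = FALSE],
            cell_ids = top$cell_ids[keep])
}

#' Apply an affine shear to a mesh
#'
#' Maps `(x, y)` to `(x + k * y, y)`; used to break edge--link orthogonality
#' on the regular hexagonal fixture.
#'
#' @param mesh a `mono_mesh`
#' @param k shear coefficient
#' @return a sheared `mono_mesh`
#' @export
shear_mesh <- function(mesh, k = 0.3) {
  r <- mesh$geometry$r
  r[, 1] <- r[, 1] + k * r[, 2]
  mono_mesh(mesh$topology$cells, r, cell_ids = mesh$topology$cell_ids)
}
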