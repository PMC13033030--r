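#' Cochain container
#'
#' A discrete field over one of the carriers of the (possibly reduced) primal
#' or dual network. Scalar-valued cochains (`rank = 0`) carry one value per
#' element; covector-valued cochains (`rank = 1`) carry an ordered pair of
#' components, labelled parallel / perpendicular with respect to the edge (or
#' link) aligned bases.
#'
#' @param values numeric vector (rank 0) or two-column matrix (rank 1)
#' @param network `"primal"` or `"dual"`
#' @param degree 0 (vertices / cell centres), 1 (edges / links) or
#'   2 (cells / triangles)
#' @param rank 0 (scalar) or 1 (P-valued pair)
#' @param reduced logical; whether the carrier is the reduced network
#' @return object of class `mono_cochain`
#' @export
cochain <- function(values, network = c("primal", "dual"), degree, rank = 0,
                    reduced = TRUE) {
  network <- match.arg(network)
  stopifnot(degree %in% 0:2, rank %in% 0:1)
  if (rank == 1) {
    values <- as.matrix(values)
    stopifnot(ncol(values) == 2)
  } else {
    values <- as.numeric(values)
  }
  structure(list(values = values, network = network, degree = degree,
                 rank = rank, reduced = reduced), class = "mono_cochain")
}

#' @export
print.mono_cochain <- function(x, ...) {
  n <- if (x$rank == 1) nrow(x$values) else length(x$values)
  cat(sprintf("<mono_cochain> %s network, degree %d, rank %d, %d element(s)%s\n",
              x$network, x$degree, x$rank, n,
              if (x$reduced) " (reduced)" else ""))
  invisible(x)
}

carrier_length <- function(ops, network, degree, reduced = TRUE) {
  if (network == "primal") {
    switch(as.character(degree),
           "0" = if (reduced) length(ops$idx_v) else ops$mesh$topology$n_vertices,
           "1" = if (reduced) length(ops$idx_e) else ops$mesh$topology$n_edges,
           "2" = ops$mesh$topology$n_cells)
  } else {
    switch(as.character(degree),
           "0" = ops$mesh$topology$n_cells,
           "1" = if (reduced) length(ops$idx_e) else ops$mesh$topology$n_edges,
           "2" = if (reduced) length(ops$idx_v) else ops$mesh$topology$n_vertices)
  }
}

#' Edge- and link-aligned basis vectors
#'
#' Returns, per retained element, the contravariant bases `e_lo_par = t/t^2`,
#' `e_lo_perp = eps t/t^2` and covariant bases `e_up_par = t`,
#' `e_up_perp = eps t` (and the link analogues built from `T` with the
#' opposite rotation), satisfying the duality relations
#' `e_up_par . e_lo_par = 1`, `e_up_par . e_lo_perp = 0`.
#'
#' @param ops a `mono_operators` object (or a `mono_mesh`)
#' @param carrier `"edges"` or `"links"`
#' @return list of four n x 2 matrices over the retained carrier elements
#' @export
basis_vectors <- function(ops, carrier = c("edges", "links")) {
  carrier <- match.arg(carrier)
  ops <- as_operators(ops)
  g <- ops$mesh$geometry
  ie <- ops$idx_e
  if (carrier == "edges") {
    tt <- g$t_vec[ie, , drop = FALSE]
    l2 <- g$t_len[ie]^2
    list(lo_par = tt / l2, lo_perp = rot_cw(tt) / l2,
         up_par = tt, up_perp = rot_cw(tt))
  } else {
    TT <- g$T_vec[ie, , drop = FALSE]
    L2 <- g$T_len[ie]^2
    list(lo_par = TT / L2, lo_perp = rot_ccw(TT) / L2,
         up_par = TT, up_perp = rot_ccw(TT))
  }
}

#' Flat: vector field to covector-valued 1-cochain
#'
#' Projects a discrete vector field (one 2D vector per retained edge or link)
#' onto the covariant bases, giving the component pair
#' `(v . e_up_par, v . e_up_perp)`.
#'
#' @param ops `mono_operators`
#' @param v n x 2 matrix of vectors over retained edges (or links)
#' @param carrier `"edges"` or `"links"`
#' @return n x 2 matrix of (parallel, perpendicular) components
#' @export
flat_field <- function(ops, v, carrier = c("edges", "links")) {
  carrier <- match.arg(carrier)
  b <- basis_vectors(ops, carrier)
  v <- as.matrix(v)
  cbind(rowSums(v * b$up_par), rowSums(v * b$up_perp))
}

#' Sharp: covector-valued 1-cochain to vector field
#'
#' Expands a component pair on the contravariant bases:
#' `psi_par * e_lo_par + psi_perp * e_lo_perp`. Inverse of [flat_field()].
#'
#' @param ops `mono_operators`
#' @param psi n x 2 matrix of components
#' @param carrier `"edges"` or `"links"`
#' @return n x 2 matrix of vectors
#' @export
sharp_field <- function(ops, psi, carrier = c("edges", "links")) {
  carrier <- match.arg(carrier)
  b <- basis_vectors(ops, carrier)
  psi <- as.matrix(psi)
  psi[, 1] * b$lo_par + psi[, 2] * b$lo_perp
}

## rotation in P-space (component pairs), Eq-fixed once:
## eps_P (a_par, a_perp) = (-a_perp, a_par)
rot_P <- function(psi) cbind(-psi[, 2], psi[, 1])

#' Hodge star operators
#'
#' Applies the metric-weighted star connecting the primal and dual cochain
#' sequences. For scalar-valued arguments the action is a diagonal scaling by
#' triangle areas `E_k`, cell areas `A_i`, or the edge/link weights
#' `F_j/t_j^2`, `F_j/T_j^2`; for covector-valued arguments (`rank = 1`) the
#' same scaling is composed with the quarter-turn in component space.
#'
#' @param x a `mono_cochain`
#' @param ops `mono_operators`
#' @param inverse apply the inverse star
#' @return a `mono_cochain` on the opposite network
#' @export
hodge_star <- function(x, ops, inverse = FALSE) {
  ops <- as_operators(ops)
  stopifnot(inherits(x, "mono_cochain"))
  n <- x$rank; m <- x$degree; net <- x$network
  out_net <- if (net == "primal") "dual" else "primal"
  ## forward stars scale by the weight of their source carrier; the inverse
  ## of a star undoes the forward map that produced x, whose weight is keyed
  ## by the *target* carrier (out_net, 2 - m)
  wkey <- if (inverse) paste(out_net, 2L - m) else paste(net, m)
  ## top-degree (m = 2) stars divide by the face areas, so that they are
  ## (up to the quarter-turn sign) the inverses of the m = 0 stars of the
  ## opposite network
  w <- switch(wkey,
    "primal 0" = ops$metric$E_hat,
    "primal 1" = 1 / ops$metric$Te_hat,
    "primal 2" = 1 / ops$metric$H,
    "dual 0"   = ops$metric$H,
    "dual 1"   = 1 / ops$metric$Tl_hat,
    "dual 2"   = 1 / ops$metric$E_hat,
    stop("unsupported star"))
  len <- carrier_length(ops, net, m)
  if ((if (n == 1) nrow(x$values) else length(x$values)) != len)
    stop("cochain length does not match its reduced carrier")
  if (n == 0) {
    vals <- if (inverse) x$values / w else x$values * w
  } else if (n == 1) {
    ## star = w * eps_P; inverse = -eps_P / w
    vals <- if (inverse) -rot_P(x$values) / w else rot_P(x$values) * w
  } else if (n == 2) {
    vals <- if (inverse) x$values / w else x$values * w
  } else stop("unsupported rank")
  cochain(vals, out_net, 2L - m, n, reduced = TRUE)
}

#' Exterior derivative of a (possibly P-valued) cochain
#'
#' Applies the reduced coboundary componentwise: on the primal network the
#' vertex-to-edge difference `A_hat` (degree 0 to 1) or the edge-to-cell
#' circulation `B_hat` (degree 1 to 2); on the dual network their transposes.
#' Nilpotent (`d(d(x)) == 0`) by the incidence identity.
#'
#' @param x `mono_cochain` of degree 0 or 1
#' @param ops `mono_operators`
#' @return `mono_cochain` of degree `x$degree + 1`
#' @export
exterior_derivative <- function(x, ops) {
  ops <- as_operators(ops)
  stopifnot(inherits(x, "mono_cochain"))
  if (x$degree >= 2) stop("d is undefined on top-degree cochains")
  M <- if (x$network == "primal") {
    if (x$degree == 0) ops$red$A_int else ops$red$B_int
  } else {
    if (x$degree == 0) Matrix::t(ops$red$B_int) else Matrix::t(ops$red$A_int)
  }
  v <- if (x$rank == 1) x$values else cbind(x$values)
  out <- as.matrix(M %*% v)
  cochain(if (x$rank == 1) out else drop(out), x$network, x$degree + 1L,
          x$rank, reduced = TRUE)
}

#' Value-leg wedge product of two covector-valued 1-cochains
#'
#' Elementwise `v_par * w_perp - v_perp * w_par` (the quarter-turn pairing in
#' component space), yielding a scalar 2-cochain-valued field on the same
#' carrier. With a scalar first argument the product is `phi * (-eps_P) w`,
#' implementing graded anticommutativity.
#'
#' @param a n x 2 matrix (or numeric vector for the scalar case)
#' @param b n x 2 matrix of components on the same carrier
#' @return numeric vector (both rank 1) or n x 2 matrix (scalar case)
#' @export
wedge_value <- function(a, b) {
  b <- as.matrix(b)
  if (is.matrix(a) && ncol(a) == 2) {
    stopifnot(nrow(a) == nrow(b))
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  } else {
    ## phi wedge v = phi * (-eps_P) v = phi * (v_perp, -v_par)
    as.numeric(a) * cbind(b[, 2], -b[, 1])
  }
}

#' Chain-leg wedge product of two scalar link 1-cochains
#'
#' The quadruple-sum contraction
#' `sum_{i,j,j'} A_jk B_ij' |A_j'k| |B_ij| a_j b_j'` mapping two scalar
#' 1-cochains on links to a scalar 2-cochain on triangles (one value per
#' vertex). Applied to the Cartesian component cochains `T_y`, `T_x` of the
#' link vectors it returns `6 E_k` at every interior vertex, which is the
#' package's primary orientation self-check.
#'
#' @param a,b numeric vectors over all edges/links (full carrier)
#' @param topology a `mono_topology` (or mesh)
#' @param edge_carrier if `TRUE` use the edge-network form (roles of the two
#'   incidence matrices exchanged), returning one value per cell
#' @return numeric vector over vertices (or cells)
#' @export
wedge_tilde <- function(a, b, topology, edge_carrier = FALSE) {
  top <- as_topology(topology)
  stopifnot(length(a) == top$n_edges, length(b) == top$n_edges)
  A <- top$A; B <- top$B
  if (!edge_carrier) {
    P <- abs(B) %*% (a * A)          # P_ik = sum_j |B_ij| a_j A_jk
    Q <- B %*% (b * abs(A))          # Q_ik = sum_j' B_ij' b_j' |A_j'k|
    as.numeric(Matrix::colSums(P * Q))
  } else {
    P <- B %*% (a * abs(A))          # P_ik = sum_j B_ij a_j |A_jk|
    Q <- abs(B) %*% (b * A)          # Q_ik = sum_j' |B_ij'| b_j' A_j'k
    as.numeric(Matrix::rowSums(P * Q))
  }
}

#' Interior product with a uniform component pair
#'
#' Builds the covector-valued 1-cochain `(z_par * w_j, z_perp * w_j)` from a
#' scalar edge (or link) cochain `w` and a uniform amplitude pair `z`; this
#' is the contraction used to turn a harmonic eigenmode into a vector field.
#'
#' @param z numeric length-2 amplitude pair
#' @param w numeric vector over retained edges (or links)
#' @return n x 2 matrix of components
#' @export
interior_product <- function(z, w) {
  stopifnot(length(z) == 2)
  cbind(z[1] * w, z[2] * w)
}

#' Metric inner products
#'
#' The inner products induced by the wedge/star pairing:
#' `sum_j F_j v_j . w_j` for vector fields on retained edges or links;
#' `sum_k E_k (f_par g_par + f_perp g_perp)` for component pairs on interior
#' vertices; `sum_i A_i (u . v)` for pairs on cells.
#'
#' @param a,b matrices over the named carrier (vectors for fields, component
#'   pairs for vertex/cell arguments)
#' @param ops `mono_operators`
#' @param carrier one of `"edges"`, `"links"`, `"vertices"`, `"cells"`
#' @return scalar
#' @export
inner_product <- function(a, b, ops, carrier = c("edges", "links", "vertices", "cells")) {
  carrier <- match.arg(carrier)
  ops <- as_operators(ops)
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("carrier mismatch between arguments")
  w <- switch(carrier,
    edges = ops$mesh$geometry$F_par[ops$idx_e],
    links = ops$mesh$geometry$F_par[ops$idx_e],
    vertices = ops$metric$E_hat,
    cells = ops$metric$H)
  if (nrow(a) != length(w)) stop("argument length does not match carrier")
  sum(w * rowSums(a * b))
}
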