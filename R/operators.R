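#' Assemble the differential-operator set of a mesh
#'
#' Gathers everything needed to differentiate fields on a monolayer: the
#' reduced incidence matrices, the diagonal metric weights, and the six
#' Laplacians
#' \itemize{
#'   \item `L_V = E^-1 A' Te^-1 A` (interior vertices; scalar potentials on
#'     the primal network),
#'   \item `L_C = H^-1 B Tl^-1 B'` (cells; potentials on the dual network),
#'   \item `L_T = E^-1 A' Tl A` and `L_F = H^-1 B Te B'` (the curl--rot
#'     Laplacians),
#'   \item the edge and link Laplace--de Rham operators `L_E`, `L_L`, whose
#'     kernels carry one harmonic mode per hole.
#' }
#' Non-symmetric operators are stored together with their symmetrized forms
#' (`S_E` for `L_E = diag(Te) S_E`), which are what the solvers factorize.
#'
#' @param mesh a `mono_mesh`
#' @return object of class `mono_operators`
#' @export
mesh_operators <- function(mesh) {
  stopifnot(inherits(mesh, "mono_mesh"))
  red <- mesh$reduced
  met <- metric_operators(mesh$geometry, red)
  A <- red$A_int                       # interior edges x interior vertices
  B <- red$B_int                       # cells x interior edges
  Dinv <- function(w) Matrix::Diagonal(x = 1 / w)
  D <- function(w) Matrix::Diagonal(x = w)

  M_V <- Matrix::t(A) %*% Dinv(met$Te_hat) %*% A     # SPD on interior vertices
  M_T <- Matrix::t(A) %*% D(met$Tl_hat) %*% A
  K_C <- B %*% Dinv(met$Tl_hat) %*% Matrix::t(B)     # PSD, kernel = constants
  K_F <- B %*% D(met$Te_hat) %*% Matrix::t(B)

  L_V <- Dinv(met$E_hat) %*% M_V
  L_T <- Dinv(met$E_hat) %*% M_T
  L_C <- Dinv(met$H) %*% K_C
  L_F <- Dinv(met$H) %*% K_F

  S_E <- Dinv(met$Te_hat) %*% A %*% Dinv(met$E_hat) %*% Matrix::t(A) %*%
    Dinv(met$Te_hat) + Matrix::t(B) %*% Dinv(met$H) %*% B
  L_E <- D(met$Te_hat) %*% S_E
  S_L <- Dinv(met$Tl_hat) %*% Matrix::t(B) %*% Dinv(met$H) %*% B %*%
    Dinv(met$Tl_hat) + A %*% Dinv(met$E_hat) %*% Matrix::t(A)
  L_L <- D(met$Tl_hat) %*% S_L

  structure(list(
    mesh = mesh, red = red, metric = met,
    idx_e = red$retained_edges, idx_v = red$retained_vertices,
    M_V = M_V, M_T = M_T, K_C = K_C, K_F = K_F,
    L_V = L_V, L_C = L_C, L_T = L_T, L_F = L_F,
    L_E = L_E, L_L = L_L, S_E = S_E, S_L = S_L
  ), class = "mono_operators")
}

as_operators <- function(x) {
  if (inherits(x, "mono_operators")) return(x)
  if (inherits(x, "mono_mesh")) return(mesh_operators(x))
  stop("expected a mono_operators or mono_mesh object")
}

#' Gradient of a covector-valued 0-cochain
#'
#' Evaluates `(d phi)^sharp`: the coboundary of the potential followed by
#' expansion on the contravariant bases. On the primal network `phi` lives on
#' interior vertices and the result is a vector field on interior edges; on
#' the dual network `phi` lives on cell centres and the result lives on
#' links. The parallel component generates the edge-aligned part
#' (`grad`), the perpendicular component the rotated part (`cograd`).
#'
#' @param phi n x 2 matrix of (parallel, perpendicular) potential components
#' @param ops `mono_operators`
#' @param network `"primal"` or `"dual"`
#' @return n_interior_edges x 2 matrix of vectors
#' @export
grad_field <- function(phi, ops, network = c("primal", "dual")) {
  network <- match.arg(network)
  ops <- as_operators(ops)
  phi <- as.matrix(phi)
  if (network == "primal") {
    psi <- as.matrix(ops$red$A_int %*% phi)
    sharp_field(ops, psi, "edges")
  } else {
    psi <- as.matrix(Matrix::t(ops$red$B_int) %*% phi)
    sharp_field(ops, psi, "links")
  }
}

#' Negative divergence of an edge (or link) vector field
#'
#' Evaluates `star d star v^flat`, the adjoint of the gradient under the
#' metric inner products. The result is a component pair over interior
#' vertices (primal) or cells (dual); the parallel slot is the
#' circulation-type derivative, the perpendicular slot the flux-type
#' (divergence-like) derivative.
#'
#' @param v n x 2 matrix of vectors on retained edges (or links)
#' @param ops `mono_operators`
#' @param network `"primal"` or `"dual"`
#' @return component-pair matrix (`-div` in both slots)
#' @export
neg_div_field <- function(v, ops, network = c("primal", "dual")) {
  network <- match.arg(network)
  ops <- as_operators(ops)
  if (network == "primal") {
    psi <- flat_field(ops, v, "edges")
    as.matrix(Matrix::t(ops$red$A_int) %*% (psi / ops$metric$Te_hat)) /
      ops$metric$E_hat
  } else {
    psi <- flat_field(ops, v, "links")
    as.matrix(ops$red$B_int %*% (psi / ops$metric$Tl_hat)) / ops$metric$H
  }
}

#' Curl of an edge (or link) vector field
#'
#' Evaluates `(star d v^flat)^sharp`. On the primal network the result is a
#' component pair over cells: the perpendicular slot is the circulation per
#' unit area around each cell (`curl`), the parallel slot its rotated
#' companion (`cocurl`, a divergence read off the same field). On the dual
#' network the result lives on interior vertices.
#'
#' @inheritParams neg_div_field
#' @return component-pair matrix (parallel = cocurl, perpendicular = curl)
#' @export
curl_field <- function(v, ops, network = c("primal", "dual")) {
  network <- match.arg(network)
  ops <- as_operators(ops)
  if (network == "primal") {
    psi <- flat_field(ops, v, "edges")
    w <- as.matrix(ops$red$B_int %*% psi)
    rot_P(w) / ops$metric$H
  } else {
    psi <- flat_field(ops, v, "links")
    w <- as.matrix(Matrix::t(ops$red$A_int) %*% psi)
    rot_P(w) / ops$metric$E_hat
  }
}

#' Rotated gradient (adjoint of curl)
#'
#' Evaluates `(star d u^flat)^sharp` for a component pair on cells (primal)
#' or interior vertices (dual), returning a vector field on interior edges
#' (links). The perpendicular potential drives the edge-aligned part
#' (`rot`), the parallel potential the rotated part (`corot`).
#'
#' @param u component-pair matrix on cells (primal) or interior vertices (dual)
#' @inheritParams neg_div_field
#' @return vector-field matrix on retained edges (links)
#' @export
rot_field <- function(u, ops, network = c("primal", "dual")) {
  network <- match.arg(network)
  ops <- as_operators(ops)
  u <- as.matrix(u)
  if (network == "primal") {
    Bu <- as.matrix(Matrix::t(ops$red$B_int) %*% u)
    psi <- ops$metric$Te_hat * cbind(Bu[, 2], -Bu[, 1])
    sharp_field(ops, psi, "edges")
  } else {
    Au <- as.matrix(ops$red$A_int %*% u)
    psi <- ops$metric$Tl_hat * cbind(Au[, 2], -Au[, 1])
    sharp_field(ops, psi, "links")
  }
}
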