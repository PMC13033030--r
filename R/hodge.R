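#' Harmonic basis of a multiply-connected monolayer
#'
#' Computes the kernel of the scalar edge Laplace--de Rham operator. The
#' operator is factorized through its symmetrized form `S_E` (so a symmetric
#' eigensolver applies); eigenvalues below `tol` times the largest eigenvalue
#' count as zero. For a monolayer with `n_holes` holes the kernel dimension
#' must equal `n_holes`; any other count signals a topology/reduction
#' inconsistency and is an error. Modes are orthonormalized under the
#' edge-field inner product (weights `F_j / t_j^2`) and sign-fixed so the
#' largest-magnitude entry is positive.
#'
#' @param ops `mono_operators`
#' @param network `"primal"` (edge modes) or `"dual"` (link modes)
#' @param tol relative null-space tolerance
#' @return object of class `mono_harmonic_basis` with `modes` (one scalar
#'   edge cochain per column), `n_modes`, the eigenvalues retained, and the
#'   weight vector used for normalization
#' @export
harmonic_basis <- function(ops, network = c("primal", "dual"), tol = 1e-10) {
  network <- match.arg(network)
  ops <- as_operators(ops)
  n_holes <- ops$mesh$topology$n_holes
  S <- if (network == "primal") ops$S_E else ops$S_L
  S <- as.matrix(S)
  S <- 0.5 * (S + t(S))
  ee <- eigen(S, symmetric = TRUE)
  thresh <- tol * max(ee$values)
  null_idx <- which(ee$values < thresh)
  if (length(null_idx) != n_holes)
    stop(sprintf(
      "edge-Laplacian kernel dimension (%d) does not match hole count (%d)",
      length(null_idx), n_holes))
  ## weight of the field inner product: F_j (w_j/t_j)^2 => F/t^2 = 1/Te (1/Tl dual)
  wgt <- if (network == "primal") 1 / ops$metric$Te_hat else 1 / ops$metric$Tl_hat
  modes <- ee$vectors[, null_idx, drop = FALSE]
  if (length(null_idx)) {
    ## Gram-Schmidt under the weighted product, then sign fix
    for (m in seq_len(ncol(modes))) {
      v <- modes[, m]
      if (m > 1) for (p in seq_len(m - 1))
        v <- v - sum(wgt * v * modes[, p]) * modes[, p]
      v <- v / sqrt(sum(wgt * v^2))
      if (v[which.max(abs(v))] < 0) v <- -v
      modes[, m] <- v
    }
  }
  structure(list(modes = modes, n_modes = length(null_idx),
                 eigenvalues = ee$values[null_idx], weight = wgt,
                 network = network, ops = ops, tol = tol),
            class = "mono_harmonic_basis")
}

#' @export
print.mono_harmonic_basis <- function(x, ...) {
  cat(sprintf("<mono_harmonic_basis> %d mode(s) on the %s network\n",
              x$n_modes, x$network))
  invisible(x)
}

#' Harmonic vector field of a given mode
#'
#' Reconstructs the divergence- and curl-free field
#' `z_par * sum_j w_j e_par + z_perp * sum_j w_j e_perp` from the `m`-th
#' kernel mode. `(z_par, z_perp) = (1, 0)` and `(0, 1)` give the two
#' orientations (radial / azimuthal around the generating hole) of the same
#' one-parameter family.
#'
#' @param basis `mono_harmonic_basis`
#' @param m mode index
#' @param z amplitude pair `c(z_par, z_perp)`
#' @return vector-field matrix over retained edges (or links)
#' @export
harmonic_field <- function(basis, m = 1, z = c(1, 0)) {
  stopifnot(inherits(basis, "mono_harmonic_basis"))
  if (m < 1 || m > basis$n_modes) stop("mode index out of range")
  psi <- interior_product(z, basis$modes[, m])
  sharp_field(basis$ops, psi,
              if (basis$network == "primal") "edges" else "links")
}

#' Radial profile of the harmonic-mode magnitude
#'
#' Tabulates, per retained edge, the distance of the edge centroid from a
#' reference point (typically the centre of the ablated cell), the mode
#' magnitude `chi_j = |w_j| / t_j`, and the alignment `|cos(theta_j)|`
#' between the edge and the radial direction. Radially oriented edges carry
#' the largest magnitudes; the upper bound of `chi` decays like `1/r`.
#'
#' @param basis `mono_harmonic_basis`
#' @param center length-2 reference point
#' @param m mode index
#' @return a tibble with columns `edge`, `r`, `chi`, `cos_theta`
#' @export
harmonic_profile <- function(basis, center, m = 1) {
  stopifnot(inherits(basis, "mono_harmonic_basis"))
  ops <- basis$ops
  g <- ops$mesh$geometry
  ie <- ops$idx_e
  cj <- sweep(g$c_mid[ie, , drop = FALSE], 2, center)
  rj <- sqrt(rowSums(cj^2))
  tv <- g$t_vec[ie, , drop = FALSE]
  costh <- abs(rowSums(cj * tv)) / (rj * g$t_len[ie])
  tibble::tibble(edge = ie, r = rj,
                 chi = abs(basis$modes[, m]) / g$t_len[ie],
                 cos_theta = costh)
}

## solve the vertex-potential Poisson problem M phi = rhs (SPD)
.solve_spd <- function(M, rhs) {
  as.matrix(Matrix::solve(M, rhs))
}

## solve the cell-potential problem K u = rhs with kernel = constants:
## pin one unknown, then return the solution (gauge fixed by the caller)
.solve_pinned <- function(K, rhs) {
  n <- nrow(K)
  sol <- matrix(0, n, ncol(rhs))
  Kr <- K[-1, -1, drop = FALSE]
  sol[-1, ] <- as.matrix(Matrix::solve(Kr, rhs[-1, , drop = FALSE]))
  sol
}

#' Helmholtz--Hodge decomposition of an edge or link vector field
#'
#' Splits a discrete vector field into a gradient part, a rotational part
#' and a residual: `v = grad(phi) + rot(u) + x`. The scalar potentials solve
#' the Poisson problems driven by the divergence and curl of `v`; the
#' periphery-suppressed incidence matrices impose the effective boundary
#' conditions (Dirichlet on `phi`, natural on `u`). The forcing of the
#' cell-potential problem is first projected onto the operator's range by
#' removing its area-weighted mean (the printed solvability condition); the
#' size of that correction is reported in `diagnostics`. On a
#' multiply-connected monolayer the residual is (up to solver error) the
#' harmonic component; pass a `basis` to also project it onto the kernel
#' modes and obtain amplitude pairs.
#'
#' @param v vector-field matrix over retained edges (primal) or links (dual)
#' @param ops `mono_operators`
#' @param network `"primal"` or `"dual"`
#' @param basis optional `mono_harmonic_basis` for harmonic projection
#' @return object of class `mono_hodge` with `phi`, `u`, `grad_part`,
#'   `rot_part`, `residual`, optional `harmonic` + `amplitudes`, and
#'   `diagnostics`
#' @export
helmholtz_decompose <- function(v, ops, network = c("primal", "dual"),
                                basis = NULL) {
  network <- match.arg(network)
  ops <- as_operators(ops)
  v <- as.matrix(v)
  met <- ops$metric
  g <- ops$mesh$geometry
  primal <- network == "primal"
  carrier <- if (primal) "edges" else "links"
  psi <- flat_field(ops, v, carrier)

  if (primal) {
    ## phi: L_V phi = -div v  <=>  M_V phi = A' Te^-1 psi
    rhs_phi <- as.matrix(Matrix::t(ops$red$A_int) %*% (psi / met$Te_hat))
    phi <- .solve_spd(ops$M_V, rhs_phi)
  } else {
    ## dual: Phi solves the cell problem (kernel = constants), U the vertex one
    f_Phi <- neg_div_field(v, ops, "dual")
    wmean_Phi <- colSums(met$H * f_Phi) / sum(met$H)
    f_Phi_c <- sweep(f_Phi, 2, wmean_Phi)
    Phi <- .solve_pinned(ops$K_C, met$H * f_Phi_c)
    Phi <- sweep(Phi, 2, colSums(met$H * Phi) / sum(met$H))
    ## U: L_T U = curl V  <=>  M_T U = E * curl V (SPD on interior vertices)
    f_U <- curl_field(v, ops, "dual")
    U <- .solve_spd(ops$M_T, met$E_hat * f_U)
    grad_part <- grad_field(Phi, ops, "dual")
    rot_part <- rot_field(U, ops, "dual")
    residual <- v - grad_part - rot_part
    out <- .finish_hodge(v, Phi, U, grad_part, rot_part, residual, ops,
                         network, basis,
                         solvability = wmean_Phi)
    return(out)
  }

  f_u <- curl_field(v, ops, "primal")
  wmean_u <- colSums(met$H * f_u) / sum(met$H)
  f_u_c <- sweep(f_u, 2, wmean_u)
  ## u is defined up to a constant (kernel of K_F); gauge: zero area-weighted
  ## mean. phi carries effective Dirichlet data at the suppressed periphery,
  ## so it is unique and takes no gauge fixing.
  u <- .solve_pinned(ops$K_F, met$H * f_u_c)
  u <- sweep(u, 2, colSums(met$H * u) / sum(met$H))
  grad_part <- grad_field(phi, ops, "primal")
  rot_part <- rot_field(u, ops, "primal")
  residual <- v - grad_part - rot_part
  .finish_hodge(v, phi, u, grad_part, rot_part, residual, ops, network,
                basis, solvability = wmean_u)
}

.finish_hodge <- function(v, phi, u, grad_part, rot_part, residual, ops,
                          network, basis, solvability) {
  carrier <- if (network == "primal") "edges" else "links"
  harmonic <- NULL; amplitudes <- NULL; remainder <- residual
  if (!is.null(basis) && basis$n_modes > 0) {
    stopifnot(basis$network == network)
    bfun <- basis_vectors(ops, carrier)
    amplitudes <- matrix(0, basis$n_modes, 2,
                         dimnames = list(NULL, c("z_par", "z_perp")))
    harmonic <- matrix(0, nrow(v), 2)
    Fw <- ops$mesh$geometry$F_par[ops$idx_e]
    for (m in seq_len(basis$n_modes)) {
      xm_par <- basis$modes[, m] * bfun$lo_par
      xm_perp <- basis$modes[, m] * bfun$lo_perp
      ## modes are unit-norm under the field product, so projection is direct
      amplitudes[m, 1] <- sum(Fw * rowSums(residual * xm_par))
      amplitudes[m, 2] <- sum(Fw * rowSums(residual * xm_perp))
      harmonic <- harmonic + amplitudes[m, 1] * xm_par + amplitudes[m, 2] * xm_perp
    }
    remainder <- residual - harmonic
  }
  nrm <- function(x) sqrt(inner_product(x, x, ops, carrier))
  structure(list(
    phi = phi, u = u, grad_part = grad_part, rot_part = rot_part,
    residual = residual, harmonic = harmonic, amplitudes = amplitudes,
    remainder = remainder, network = network,
    diagnostics = list(
      solvability_correction = solvability,
      norm_v = nrm(v), norm_grad = nrm(grad_part), norm_rot = nrm(rot_part),
      norm_residual = nrm(residual),
      max_residual = max(sqrt(rowSums(residual^2))),
      max_v = max(sqrt(rowSums(v^2))))
  ), class = "mono_hodge")
}

#' @export
print.mono_hodge <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf(
    "<mono_hodge> %s network | ||v|| = %.4g, ||grad|| = %.4g, ||rot|| = %.4g, ||residual|| = %.4g\n",
    x$network, d$norm_v, d$norm_grad, d$norm_rot, d$norm_residual))
  if (!is.null(x$amplitudes)) {
    cat("harmonic amplitudes (z_par, z_perp):\n")
    print(round(x$amplitudes, 6))
  }
  invisible(x)
}

#' Reconstruction residual of a decomposition
#'
#' Returns the per-edge residual `v - grad(phi) - rot(u)` of a decomposition
#' computed without harmonic projection, together with its maximum magnitude
#' and that of the input field. On an ablated monolayer this residual is the
#' numerically excited harmonic component, elevated near the hole.
#'
#' @param v the decomposed field
#' @param decomposition a `mono_hodge`
#' @return list with `residual`, `max_residual`, `max_v`
#' @export
reconstruction_residual <- function(v, decomposition) {
  stopifnot(inherits(decomposition, "mono_hodge"))
  res <- decomposition$residual
  list(residual = res,
       max_residual = max(sqrt(rowSums(res^2))),
       max_v = max(sqrt(rowSums(as.matrix(v)^2))))
}
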