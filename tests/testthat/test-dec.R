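test_that("edge and link bases satisfy the duality relations", {
  ops <- fx_hex3_ops()
  for (carrier in c("edges", "links")) {
    b <- basis_vectors(ops, carrier)
    expect_near(rowSums(b$up_par * b$lo_par), 1, 1e-12)
    expect_near(rowSums(b$up_par * b$lo_perp), 0, 1e-12)
    expect_near(rowSums(b$up_perp * b$lo_perp), 1, 1e-12)
  }
  ## explicit scaling: an edge vector (2, 0) has contravariant basis (0.5, 0)
  b2 <- basis_vectors(mesh_operators(hex_patch(1, side = 2)), "edges")
  expect_near(sqrt(rowSums(b2$lo_par^2)), 0.5, 1e-12)
  expect_near(sqrt(rowSums(b2$up_par^2)), 2, 1e-12)
  ## orthogonal lattice: rotated edge covector parallel to the link
  ops3 <- fx_hex3_ops()
  be <- basis_vectors(ops3, "edges"); bl <- basis_vectors(ops3, "links")
  crossp <- be$up_perp[, 1] * bl$up_par[, 2] - be$up_perp[, 2] * bl$up_par[, 1]
  expect_near(crossp, 0, 1e-10)
})

test_that("sharp and flat are mutually inverse and induce the metric", {
  for (ops in list(fx_hex3_ops(), fx_sheared_ops(),
                   mesh_operators(fx_grown_mesh()))) {
    ne <- length(ops$idx_e)
    v <- rand_pair(ne, seed = 11)
    psi <- rand_pair(ne)
    for (carrier in c("edges", "links")) {
      expect_near(sharp_field(ops, flat_field(ops, v, carrier), carrier), v,
                  1e-11)
      expect_near(flat_field(ops, sharp_field(ops, psi, carrier), carrier),
                  psi, 1e-11)
    }
    ## flat metric: sum_j (v.e_up)(v.e_lo) over both slots = sum_j |v_j|^2
    b <- basis_vectors(ops, "edges")
    lhs <- sum(rowSums(v * b$up_par) * rowSums(v * b$lo_par) +
               rowSums(v * b$up_perp) * rowSums(v * b$lo_perp))
    expect_lt(abs(lhs - sum(rowSums(v^2))) / sum(rowSums(v^2)), 1e-10)
    ## sharp metric: <psi | psi_sharp> = sum_j (psi_par^2 + psi_perp^2)/t_j^2
    vs <- sharp_field(ops, psi, "edges")
    lhs2 <- sum(rowSums(psi * flat_field(ops, vs / ops$mesh$geometry$t_len[
      ops$idx_e]^2, "edges")))
    rhs2 <- sum(rowSums(psi^2) / ops$mesh$geometry$t_len[ops$idx_e]^2)
    expect_lt(abs(lhs2 - rhs2) / abs(rhs2), 1e-10)
  }
})

test_that("flat recovers the stated component identity on random fields", {
  ops <- mesh_operators(fx_grown_mesh())
  ne <- length(ops$idx_e)
  v <- rand_pair(ne, seed = 3)
  psi <- flat_field(ops, v, "edges")
  ## pairing <v_flat | v>_P = sum_j |v_j|^2: components contract through the
  ## contravariant basis
  b <- basis_vectors(ops, "edges")
  recon <- psi[, 1] * b$lo_par + psi[, 2] * b$lo_perp
  expect_near(recon, v, 1e-10)
  expect_lt(abs(sum(rowSums(recon * v)) - sum(rowSums(v^2))) /
              sum(rowSums(v^2)), 1e-10)
})

test_that("exterior derivative is nilpotent and matches incidence rows", {
  for (ops in list(fx_hex3_ops(), fx_annulus_ops())) {
    nv <- length(ops$idx_v)
    phi <- cochain(rand_pair(nv, seed = 5), "primal", 0, rank = 1)
    dphi <- exterior_derivative(phi, ops)
    ddphi <- exterior_derivative(dphi, ops)
    expect_lt(max(abs(ddphi$values)), 1e-12)
    ## constant scalar field: zero derivative on interior edges
    const <- cochain(cbind(rep(1, nv), rep(2, nv)), "primal", 0, rank = 1)
    dconst <- exterior_derivative(const, ops)
    ## edges joining two interior vertices difference to zero; edges with a
    ## suppressed peripheral endpoint keep a single +-1 contribution
    both_int <- Matrix::rowSums(abs(ops$red$A_int)) == 2
    expect_equal(max(abs(dconst$values[both_int, ])), 0)
    ## indicator of one interior vertex: +-1 on its incident edges
    ind <- matrix(0, nv, 2); ind[1, 1] <- 1
    dind <- exterior_derivative(cochain(ind, "primal", 0, 1), ops)
    expect_equal(unname(as.matrix(dind$values[, 1])),
                 unname(as.matrix(ops$red$A_int[, 1])))
    ## dual nilpotency
    nc <- ops$mesh$topology$n_cells
    Phi <- cochain(rand_pair(nc), "dual", 0, rank = 1)
    expect_lt(max(abs(exterior_derivative(
      exterior_derivative(Phi, ops), ops)$values)), 1e-12)
  }
  expect_error(exterior_derivative(
    cochain(rand_pair(fx_hex3_ops()$mesh$topology$n_cells), "primal", 2, 1),
    fx_hex3_ops()), "top-degree")
})

test_that("Hodge stars scale by the tabulated weights and invert correctly", {
  ops <- fx_sheared_ops()
  met <- ops$metric
  nv <- length(ops$idx_v); ne <- length(ops$idx_e)
  nc <- ops$mesh$topology$n_cells
  ## scalar star on vertices: all-ones maps to the triangle areas
  ones <- cochain(rep(1, nv), "primal", 0, rank = 0)
  expect_near(hodge_star(ones, ops)$values, met$E_hat, 1e-12)
  ## P-valued stars compose with the quarter turn; star then inverse = id
  psi <- cochain(rand_pair(ne, seed = 9), "primal", 1, rank = 1)
  round1 <- hodge_star(hodge_star(psi, ops), ops, inverse = TRUE)
  expect_near(round1$values, psi$values, 1e-12)
  phi <- cochain(rand_pair(nv), "primal", 0, rank = 1)
  s10 <- hodge_star(phi, ops)
  expect_near(s10$values, met$E_hat * cbind(-phi$values[, 2], phi$values[, 1]),
              1e-12)
  ## inverse-pairing: star_{1,0}^-1 = -star_{1,2} applied on the dual side
  back <- hodge_star(s10, ops, inverse = TRUE)
  expect_near(back$values, phi$values, 1e-12)
  ## orthogonal lattice: edge star and link star are mutually inverse up to
  ## the sign of the double rotation
  oh <- fx_hex3_ops()
  psi_h <- cochain(rand_pair(length(oh$idx_e)), "primal", 1, rank = 1)
  fwd <- hodge_star(psi_h, oh)          # primal -> dual, weight F/t^2
  fwd2 <- hodge_star(fwd, oh)           # dual -> primal, weight F/T^2
  expect_near(fwd2$values, -psi_h$values, 1e-12)
})

test_that("value-leg wedge product is antisymmetric and determinant-like", {
  ne <- 40
  v <- rand_pair(ne, seed = 13); w <- rand_pair(ne)
  expect_equal(max(abs(wedge_value(v, v))), 0)
  expect_near(wedge_value(v, w), -wedge_value(w, v), 1e-12)
  unit <- cbind(rep(1, ne), 0); perp <- cbind(0, rep(1, ne))
  expect_near(wedge_value(unit, perp), 1, 1e-12)
  ## scalar case implements graded anticommutativity
  phi <- stats::rnorm(ne)
  expect_near(wedge_value(phi, v), phi * cbind(v[, 2], -v[, 1]), 1e-12)
})

test_that("chain-leg wedge of link components reproduces six triangle areas", {
  for (mesh in list(fx_hex3(), fx_grown_mesh())) {
    g <- mesh$geometry; top <- mesh$topology
    wt <- wedge_tilde(g$T_vec[, 2], g$T_vec[, 1], top)
    iv <- which(!top$peripheral_vertices)
    expect_near(wt[iv] / g$E_tri[iv], 6, 1e-10)
  }
  ## brute-force quadruple-sum oracle on the rosette
  ros <- hex_patch(1)
  g <- ros$geometry; top <- ros$topology
  A <- as.matrix(top$A); B <- as.matrix(top$B)
  a <- g$T_vec[, 2]; b <- g$T_vec[, 1]
  brute <- numeric(top$n_vertices)
  for (i in seq_len(top$n_cells)) for (j in seq_len(top$n_edges))
    for (jp in seq_len(top$n_edges)) for (k in seq_len(top$n_vertices))
      brute[k] <- brute[k] + A[j, k] * B[i, jp] * abs(A[jp, k]) *
        abs(B[i, j]) * a[j] * b[jp]
  expect_near(wedge_tilde(a, b, top), brute, 1e-10)
  ## zero argument
  expect_equal(max(abs(wedge_tilde(a * 0, b, top))), 0)
  ## interior vertex of the unit lattice: 6 * 3 sqrt(3) / 4
  iv <- which(!top$peripheral_vertices)
  expect_near(brute[iv], 6 * 3 * sqrt(3) / 4, 1e-10)
})

test_that("interior product and inner products behave as contractions", {
  ops <- fx_annulus_ops()
  ne <- length(ops$idx_e)
  set.seed(21)
  w <- stats::rnorm(ne)
  expect_near(interior_product(c(1, 0), w), cbind(w, 0), 1e-15)
  expect_equal(max(abs(interior_product(c(0, 0), w))), 0)
  ## sharp of the contraction equals the explicit two-sum expansion
  z <- c(0.3, -1.7)
  b <- basis_vectors(ops, "edges")
  expect_near(sharp_field(ops, interior_product(z, w), "edges"),
              z[1] * w * b$lo_par + z[2] * w * b$lo_perp, 1e-12)
  ## inner products: positivity and the closed-form weights
  v <- rand_pair(ne)
  expect_gte(inner_product(v, v, ops, "edges"), 0)
  Fw <- ops$mesh$geometry$F_par[ops$idx_e]
  expect_lt(abs(inner_product(v, v, ops, "edges") - sum(Fw * rowSums(v^2))),
            1e-10)
  ## unit parallel covector on one edge: F_j |e_par|^2 = F_j / t_j^2
  one <- matrix(0, ne, 2); one[5, 1] <- 1
  vf <- sharp_field(ops, one, "edges")
  expect_lt(abs(inner_product(vf, vf, ops, "edges") -
                  Fw[5] / ops$mesh$geometry$t_len[ops$idx_e][5]^2), 1e-12)
  expect_error(inner_product(v, v[-1, ], ops, "edges"), "mismatch")
})
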