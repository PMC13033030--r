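test_that("exact sequences hold to machine precision on both networks", {
  for (ops in list(fx_hex3_ops(), fx_sheared_ops(), fx_annulus_ops())) {
    nv <- length(ops$idx_v); nc <- ops$mesh$topology$n_cells
    phi <- rand_pair(nv, seed = 1); u <- rand_pair(nc)
    expect_near(curl_field(grad_field(phi, ops), ops), 0, 1e-12)
    expect_near(neg_div_field(rot_field(u, ops), ops), 0, 1e-12)
    Phi <- rand_pair(nc); U <- rand_pair(nv)
    expect_near(curl_field(grad_field(Phi, ops, "dual"), ops, "dual"), 0, 1e-12)
    expect_near(neg_div_field(rot_field(U, ops, "dual"), ops, "dual"), 0, 1e-12)
  }
})

test_that("gradient of an interior indicator lives on its incident edges", {
  ops <- fx_hex3_ops()
  nv <- length(ops$idx_v)
  phi <- matrix(0, nv, 2); phi[1, 1] <- 1
  v <- grad_field(phi, ops)
  touched <- which(rowSums(abs(v)) > 0)
  expect_setequal(touched, which(ops$red$A_int[, 1] != 0))
  ## magnitude 1/t_j along the contravariant direction (unit lattice: 1)
  expect_near(sqrt(rowSums(v[touched, , drop = FALSE]^2)), 1, 1e-12)
})

test_that("div and curl are the metric adjoints of grad and rot", {
  for (ops in list(fx_sheared_ops(), mesh_operators(fx_grown_mesh()))) {
    nv <- length(ops$idx_v); nc <- ops$mesh$topology$n_cells
    ne <- length(ops$idx_e)
    set.seed(42)
    for (rep in 1:25) {
      v <- rand_pair(ne); phi <- rand_pair(nv)
      u <- rand_pair(nc); V <- rand_pair(ne)
      Phi <- rand_pair(nc); U <- rand_pair(nv)
      a1 <- inner_product(v, grad_field(phi, ops), ops, "edges")
      a2 <- inner_product(neg_div_field(v, ops), phi, ops, "vertices")
      expect_lt(abs(a1 - a2), 1e-10 * max(1, abs(a1)))
      b1 <- inner_product(u, curl_field(v, ops), ops, "cells")
      b2 <- inner_product(rot_field(u, ops), v, ops, "edges")
      expect_lt(abs(b1 - b2), 1e-10 * max(1, abs(b1)))
      c1 <- inner_product(V, grad_field(Phi, ops, "dual"), ops, "links")
      c2 <- inner_product(neg_div_field(V, ops, "dual"), Phi, ops, "cells")
      expect_lt(abs(c1 - c2), 1e-10 * max(1, abs(c1)))
      d1 <- inner_product(U, curl_field(V, ops, "dual"), ops, "vertices")
      d2 <- inner_product(rot_field(U, ops, "dual"), V, ops, "links")
      expect_lt(abs(d1 - d2), 1e-10 * max(1, abs(d1)))
    }
  }
})

test_that("operator compositions assemble the six Laplacians entrywise", {
  for (ops in list(fx_sheared_ops(), fx_annulus_ops())) {
    nv <- length(ops$idx_v); nc <- ops$mesh$topology$n_cells
    ne <- length(ops$idx_e)
    phi <- rand_pair(nv, seed = 2); u <- rand_pair(nc)
    Phi <- rand_pair(nc); U <- rand_pair(nv)
    expect_near(neg_div_field(grad_field(phi, ops), ops),
                as.matrix(ops$L_V %*% phi), 1e-11)
    expect_near(curl_field(rot_field(u, ops), ops),
                as.matrix(ops$L_F %*% u), 1e-11)
    expect_near(neg_div_field(grad_field(Phi, ops, "dual"), ops, "dual"),
                as.matrix(ops$L_C %*% Phi), 1e-11)
    expect_near(curl_field(rot_field(U, ops, "dual"), ops, "dual"),
                as.matrix(ops$L_T %*% U), 1e-11)
    ## edge Laplacian = -grad div + rot curl through the same compositions
    v <- rand_pair(ne)
    psi <- flat_field(ops, v, "edges")
    lhs <- as.matrix(ops$L_E %*% psi)
    gd <- flat_field(ops, grad_field(neg_div_field(v, ops), ops), "edges")
    rc <- flat_field(ops, rot_field(curl_field(v, ops), ops), "edges")
    expect_near(lhs, gd + rc, 1e-10)
  }
})

test_that("cell-potential Laplacians annihilate constants", {
  for (ops in list(fx_hex3_ops(), mesh_operators(fx_grown_mesh()))) {
    nc <- ops$mesh$topology$n_cells
    expect_near(as.matrix(ops$L_C %*% rep(1, nc)), 0, 1e-12)
    expect_near(as.matrix(ops$L_F %*% rep(1, nc)), 0, 1e-12)
  }
})

test_that("the symmetrized edge Laplacian is symmetric PSD", {
  for (ops in list(fx_sheared_ops(), mesh_operators(fx_grown_mesh()))) {
    S <- as.matrix(ops$S_E)
    expect_lt(max(abs(S - t(S))), 1e-12)
    ev <- eigen(0.5 * (S + t(S)), symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10 * max(ev))
    ## similarity: L_E = diag(Te) S_E
    expect_near(as.matrix(ops$L_E),
                as.matrix(Matrix::Diagonal(x = ops$metric$Te_hat) %*% ops$S_E),
                1e-12)
  }
})

test_that("edge-Laplacian energy splits into divergence and curl parts", {
  ops <- fx_annulus_ops()
  ne <- length(ops$idx_e)
  set.seed(12)
  for (rep in 1:10) {
    v <- rand_pair(ne)
    q <- inner_product(sharp_field(ops, as.matrix(
      ops$L_E %*% flat_field(ops, v, "edges")), "edges"), v, ops, "edges")
    dv <- neg_div_field(v, ops)
    cv <- curl_field(v, ops)
    ## [L_E b, b] = [div b, div b]_V + [curl b, curl b]_C (adjointness)
    split <- inner_product(dv, dv, ops, "vertices") +
      inner_product(cv, cv, ops, "cells")
    expect_lt(abs(q - split) / max(1, abs(q)), 1e-10)
    expect_gte(q, -1e-10)
  }
})

test_that("orthogonal lattice degeneracies hold and shear breaks them", {
  oh <- fx_hex3_ops()
  expect_near(as.matrix(oh$L_V - oh$L_T), 0, 1e-12)
  expect_near(as.matrix(oh$L_C - oh$L_F), 0, 1e-12)
  ## operator-level degeneracy: grad equals the rotated dual rot
  nv <- length(oh$idx_v)
  phi <- rand_pair(nv, seed = 31)
  g1 <- grad_field(cbind(phi[, 1], 0), oh)             # grad of parallel part
  r1 <- rot_field(cbind(phi[, 1], 0), oh, "dual")      # corot on the dual
  expect_near(g1, -r1, 1e-10)
  g2 <- grad_field(cbind(0, phi[, 2]), oh)             # cograd
  r2 <- rot_field(cbind(0, phi[, 2]), oh, "dual")      # rot
  expect_near(g2, r2, 1e-10)
  sh <- fx_sheared_ops()
  expect_gt(max(abs(sh$L_V - sh$L_T)), 1e-3)
  expect_gt(max(abs(sh$L_C - sh$L_F)), 1e-3)
  phs <- rand_pair(length(sh$idx_v), seed = 32)
  expect_gt(max(abs(grad_field(cbind(phs[, 1], 0), sh) +
                    rot_field(cbind(phs[, 1], 0), sh, "dual"))), 1e-3)
})

test_that("operators are exact on affine fields (continuum limit)", {
  mesh <- hex_patch(8)
  ops <- mesh_operators(mesh)
  top <- mesh$topology
  b <- mesh$geometry$b_pt[ops$idx_e, , drop = FALSE]
  ## rigid rotation at rate w: circulation (clockwise convention) = -2w
  w <- 0.7
  v <- w * cbind(-b[, 2], b[, 1])
  cu <- curl_field(v, ops)
  intc <- Matrix::rowSums(abs(top$B[, top$peripheral_edges, drop = FALSE])) == 0
  expect_near(cu[intc, 2], -2 * w, 1e-10)
  expect_near(cu[intc, 1], 0, 1e-10)
  ## pure expansion v(x) = x: divergence 2, so the parallel slot of -div
  ## reads -2 at every interior vertex
  dv <- neg_div_field(b, ops)
  expect_near(dv[, 1], -2, 1e-10)
  expect_near(dv[, 2], 0, 1e-10)
})
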