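test_that("edge-Laplacian kernel dimension equals the hole count", {
  expect_equal(harmonic_basis(fx_hex3_ops())$n_modes, 0)
  expect_equal(harmonic_basis(fx_annulus_ops())$n_modes, 1)
  expect_equal(harmonic_basis(mesh_operators(hex_annulus(4, 2)))$n_modes, 2)
  expect_equal(harmonic_basis(mesh_operators(hex_annulus(4, 3)))$n_modes, 3)
  expect_equal(harmonic_basis(mesh_operators(fx_grown_mesh()))$n_modes, 0)
})

test_that("harmonic fields are divergence- and curl-free with the stated norm", {
  ops <- fx_annulus_ops()
  hb <- harmonic_basis(ops)
  for (z in list(c(1, 0), c(0, 1), c(0.7, -1.3))) {
    x <- harmonic_field(hb, 1, z)
    expect_near(neg_div_field(x, ops), 0, 1e-8)
    expect_near(curl_field(x, ops), 0, 1e-8)
    ## norm identity: [x, x] = (z_par^2 + z_perp^2) sum_j F_j (w_j / t_j)^2
    g <- ops$mesh$geometry; ie <- ops$idx_e
    rhs <- sum(z^2) * sum(g$F_par[ie] * (hb$modes[, 1] / g$t_len[ie])^2)
    expect_lt(abs(inner_product(x, x, ops, "edges") - rhs), 1e-10)
  }
  expect_equal(max(abs(harmonic_field(hb, 1, c(0, 0)))), 0)
  expect_error(harmonic_field(hb, 2), "out of range")
})

test_that("two-hole monolayers carry one localized mode per hole", {
  mesh <- hex_annulus(4, 2)
  ops <- mesh_operators(mesh)
  hb <- harmonic_basis(ops)
  expect_equal(hb$n_modes, 2)
  ## modes orthonormal under the field inner product
  wgt <- 1 / ops$metric$Te_hat
  G <- t(hb$modes) %*% (wgt * hb$modes)
  expect_near(G, diag(2), 1e-8)
  ## each mode's energy concentrates near one hole: share of the weighted
  ## energy within graph distance of each hole boundary differs across modes
  cyc <- mesh$topology$boundary_cycles
  areas <- vapply(cyc, function(cc) {
    p <- mesh$geometry$r[cc, , drop = FALSE]
    abs(0.5 * sum(p[, 1] * p[c(2:nrow(p), 1), 2] -
                  p[c(2:nrow(p), 1), 1] * p[, 2]))
  }, numeric(1))
  holes <- cyc[order(areas)][1:2]
  centers <- lapply(holes, function(cc) colMeans(mesh$geometry$r[cc, ]))
  ie <- ops$idx_e
  e_near <- function(m, ctr) {
    d <- sqrt(rowSums(sweep(mesh$geometry$c_mid[ie, ], 2, ctr)^2))
    sum((wgt * hb$modes[, m]^2)[d < 2])
  }
  ## the dominant hole differs between the two modes
  pref <- vapply(1:2, function(m)
    which.max(c(e_near(m, centers[[1]]), e_near(m, centers[[2]]))), integer(1))
  expect_setequal(pref, 1:2)
})

test_that("forward-then-invert recovery of synthetic decompositions", {
  for (ops in list(fx_annulus_ops(), mesh_operators(fx_grown_mesh()))) {
    n_h <- ops$mesh$topology$n_holes
    hb <- harmonic_basis(ops)
    nv <- length(ops$idx_v); nc <- ops$mesh$topology$n_cells
    set.seed(33)
    phi0 <- rand_pair(nv)
    u0 <- rand_pair(nc)
    u0 <- sweep(u0, 2, colSums(ops$metric$H * u0) / sum(ops$metric$H))
    ## gradient-only input
    hd <- helmholtz_decompose(grad_field(phi0, ops), ops, basis = hb)
    expect_near(hd$phi, phi0, 1e-8)
    expect_near(hd$u, 0, 1e-8)
    expect_lt(hd$diagnostics$max_residual, 1e-8)
    ## rotational-only input
    hd <- helmholtz_decompose(rot_field(u0, ops), ops, basis = hb)
    expect_near(hd$u, u0, 1e-8)
    expect_near(hd$phi, 0, 1e-8)
    ## mixed (plus a harmonic component when the domain has holes)
    v <- grad_field(phi0, ops) + rot_field(u0, ops)
    z_true <- c(0.5, 0.2)
    if (n_h > 0) v <- v + harmonic_field(hb, 1, z_true)
    hd <- helmholtz_decompose(v, ops, basis = hb)
    expect_lt(max(abs(hd$phi - phi0)) / max(abs(phi0)), 1e-6)
    expect_lt(max(abs(hd$u - u0)) / max(abs(u0)), 1e-6)
    if (n_h > 0) {
      expect_near(as.numeric(hd$amplitudes[1, ]), z_true, 1e-8)
      expect_lt(max(abs(hd$remainder)), 1e-8)
    } else {
      expect_lt(hd$diagnostics$max_residual, 1e-8)
    }
    ## the three parts are mutually orthogonal in the edge inner product
    scale <- inner_product(v, v, ops, "edges")
    expect_lt(abs(inner_product(hd$grad_part, hd$rot_part, ops, "edges")),
              1e-8 * scale)
    if (n_h > 0) {
      expect_lt(abs(inner_product(hd$grad_part, hd$harmonic, ops, "edges")),
                1e-8 * scale)
      expect_lt(abs(inner_product(hd$rot_part, hd$harmonic, ops, "edges")),
                1e-8 * scale)
    }
  }
})

test_that("a purely harmonic field projects entirely onto the kernel", {
  ops <- fx_annulus_ops()
  hb <- harmonic_basis(ops)
  v <- harmonic_field(hb, 1, c(1, 0))
  hd <- helmholtz_decompose(v, ops, basis = hb)
  energy <- inner_product(v, v, ops, "edges")
  captured <- inner_product(hd$harmonic, hd$harmonic, ops, "edges")
  expect_gt(captured / energy, 0.99)
  expect_lt(max(abs(hd$phi)), 1e-8)
  expect_lt(max(abs(hd$u)), 1e-8)
})

test_that("reconstruction residual reports the unexplained field", {
  ops <- fx_annulus_ops()
  set.seed(9)
  nv <- length(ops$idx_v); nc <- ops$mesh$topology$n_cells
  u0 <- rand_pair(nc)
  u0 <- sweep(u0, 2, colSums(ops$metric$H * u0) / sum(ops$metric$H))
  v <- grad_field(rand_pair(nv), ops) + rot_field(u0, ops)
  hd <- helmholtz_decompose(v, ops)
  rr <- reconstruction_residual(v, hd)
  expect_lt(rr$max_residual, 1e-8)
  expect_equal(rr$max_v, max(sqrt(rowSums(v^2))))
  ## with a harmonic component the residual carries exactly that part
  hb <- harmonic_basis(ops)
  x <- harmonic_field(hb, 1, c(0.3, 0.1))
  hd2 <- helmholtz_decompose(v + x, ops)
  expect_near(hd2$residual, x, 1e-7)
})

test_that("dual-network decomposition mirrors the primal one", {
  ops <- fx_annulus_ops()
  hbL <- harmonic_basis(ops, "dual")
  expect_equal(hbL$n_modes, 1)
  set.seed(14)
  nc <- ops$mesh$topology$n_cells; nv <- length(ops$idx_v)
  Phi0 <- rand_pair(nc)
  Phi0 <- sweep(Phi0, 2, colSums(ops$metric$H * Phi0) / sum(ops$metric$H))
  U0 <- rand_pair(nv)
  V <- grad_field(Phi0, ops, "dual") + rot_field(U0, ops, "dual")
  hd <- helmholtz_decompose(V, ops, "dual")
  expect_near(hd$phi, Phi0, 1e-8)
  expect_near(hd$u, U0, 1e-8)
  expect_lt(hd$diagnostics$max_residual, 1e-8)
})

test_that("orthogonal-lattice potentials coincide across networks", {
  ops <- fx_hex3_ops()
  set.seed(15)
  vv <- rand_pair(length(ops$idx_e))
  hp <- helmholtz_decompose(vv, ops, "primal")
  hdual <- helmholtz_decompose(vv, ops, "dual")
  expect_near(hp$phi[, 1], -hdual$u[, 1], 1e-10)
  expect_near(hp$phi[, 2], hdual$u[, 2], 1e-10)
  expect_near(hdual$phi[, 1], -hp$u[, 1], 1e-10)
  expect_near(hdual$phi[, 2], hp$u[, 2], 1e-10)
  ## kernel modes agree up to sign and normalization on an orthogonal annulus
  oa <- mesh_operators(hex_annulus(3, 1))
  w <- harmonic_basis(oa, "primal")$modes[, 1]
  W <- harmonic_basis(oa, "dual")$modes[, 1]
  w <- w / sqrt(sum(w^2)); W <- W / sqrt(sum(W^2))
  expect_lt(min(max(abs(w - W)), max(abs(w + W))), 1e-10)
})

test_that("harmonic magnitude profile flags radially oriented edges", {
  mesh <- hex_annulus(4, 1)
  ops <- mesh_operators(mesh)
  hb <- harmonic_basis(ops)
  prof <- harmonic_profile(hb, c(0, 0))
  expect_true(all(prof$chi >= 0))
  expect_true(all(prof$cos_theta >= -1e-12 & prof$cos_theta <= 1 + 1e-12))
  ## the largest magnitudes near the hole sit on radially aligned edges
  near <- prof[prof$r < 2.5, ]
  top_edges <- near[order(-near$chi)[1:5], ]
  expect_gt(mean(top_edges$cos_theta), 0.8)
})
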