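## shared fixtures, built once per test run and memoized

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- suppressWarnings(force(expr))
  .fixture_cache[[key]]
}

fx_hex3 <- function() memo("hex3", hex_patch(3))
fx_hex3_ops <- function() memo("hex3_ops", mesh_operators(fx_hex3()))
fx_annulus <- function() memo("annulus", hex_annulus(4, 1))
fx_annulus_ops <- function() memo("annulus_ops", mesh_operators(fx_annulus()))
fx_sheared_ops <- function() memo("sheared_ops",
                                  mesh_operators(shear_mesh(fx_hex3(), 0.3)))

## small grown monolayer shared across vertex-model / stress tests
fx_grown <- function() memo("grown", grow_monolayer(60, seed = 7))
fx_grown_mesh <- function() memo("grown_mesh", vm_mesh(fx_grown()))

## convenience: random P-valued cochains with a fixed seed
rand_pair <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::rnorm(2 * n), n, 2)
}

expect_near <- function(object, expected, tol = 1e-10) {
  expect_lt(max(abs(object - expected)), tol)
}
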