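#' Write a monolayer mesh to JSON
#'
#' The mesh interchange format is a single JSON object:
#' `{"vertices": [[x, y], ...], "cells": [[v0, v1, ...], ...],
#'   "orientation": "clockwise", "index_base": 0, "metadata": {...}}`.
#' Cells are written 0-indexed; the reader converts back. Writing the same
#' mesh twice produces byte-identical files.
#'
#' @param mesh a `mono_mesh` (or `vm_state`)
#' @param path output file
#' @param metadata optional named list stored verbatim
#' @export
write_mesh_json <- function(mesh, path, metadata = NULL) {
  if (inherits(mesh, "vm_state")) mesh <- vm_mesh(mesh)
  obj <- list(
    vertices = unname(lapply(seq_len(nrow(mesh$geometry$r)),
                             function(i) mesh$geometry$r[i, ])),
    cells = unname(lapply(mesh$topology$cells, function(cc) cc - 1L)),
    cell_ids = mesh$topology$cell_ids,
    orientation = "clockwise",
    index_base = 0L,
    metadata = if (is.null(metadata)) structure(list(), names = character(0)) else metadata)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Read a monolayer mesh from JSON
#'
#' Validates winding and confluence while rebuilding the incidence
#' structure.
#'
#' @param path JSON file written by [write_mesh_json()] (or compatible)
#' @return a `mono_mesh`
#' @export
read_mesh_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- if (is.null(obj$index_base)) 0L else as.integer(obj$index_base)
  r <- .as_coord_matrix(obj$vertices)
  cells <- lapply(.as_cycle_list(obj$cells),
                  function(cc) as.integer(cc) + (1L - base))
  ids <- if (!is.null(obj$cell_ids)) as.integer(obj$cell_ids) else NULL
  if (!is.null(obj$orientation) && !identical(obj$orientation, "clockwise"))
    stop("unsupported orientation: ", obj$orientation)
  mono_mesh(cells, r, cell_ids = ids)
}

#' Write a cochain (or per-element field) to JSON
#'
#' Companion arrays to the mesh format: field name, carrier, components.
#' Round-trips losslessly at double precision.
#'
#' @param x a `mono_cochain` or a plain numeric vector/matrix
#' @param path output file
#' @param name field name
#' @param carrier carrier description string
#' @export
write_field_json <- function(x, path, name = "field", carrier = NULL) {
  if (inherits(x, "mono_cochain")) {
    obj <- list(name = name, network = x$network, degree = x$degree,
                rank = x$rank, reduced = x$reduced,
                values = if (x$rank == 1) unname(asplit(x$values, 1)) else x$values)
  } else {
    x <- as.matrix(x)
    obj <- list(name = name, carrier = carrier,
                values = unname(asplit(x, 1)))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cochain written by [write_field_json()]
#' @param path JSON file
#' @return a `mono_cochain` or numeric matrix
#' @export
read_field_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  vals <- obj$values
  if (is.list(vals)) vals <- do.call(rbind, vals)
  if (!is.null(obj$degree)) {
    cochain(vals, obj$network, obj$degree, obj$rank, obj$reduced)
  } else {
    as.matrix(vals)
  }
}

#' Export the primal (or dual) network to OFF for visualization
#'
#' @param mesh a `mono_mesh`
#' @param path output file
#' @param network `"primal"` writes cell polygons over vertices; `"dual"`
#'   writes triangles of cell centres over interior vertices
#' @export
write_off <- function(mesh, path, network = c("primal", "dual")) {
  network <- match.arg(network)
  if (network == "primal") {
    v <- cbind(mesh$geometry$r, 0)
    faces <- lapply(mesh$topology$cells, function(cc) cc - 1L)
  } else {
    v <- cbind(mesh$geometry$Rc, 0)
    iv <- which(!mesh$topology$peripheral_vertices)
    ca <- as(mesh$geometry$C_adj, "TsparseMatrix")
    faces <- lapply(iv, function(k) (ca@i[ca@j + 1L == k] + 1L) - 1L)
    faces <- Filter(function(f) length(f) >= 3, faces)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(v), length(faces)), con)
  writeLines(apply(v, 1, function(p) paste(p, collapse = " ")), con)
  writeLines(vapply(faces, function(f)
    paste(c(length(f), f), collapse = " "), character(1)), con)
  invisible(path)
}

#' Serialize a simulation state to JSON
#'
#' Mesh plus parameters and the event log, sufficient to resume analysis
#' (not mid-relaxation dynamics).
#'
#' @param state `vm_state`
#' @param path output file
#' @export
write_state_json <- function(state, path) {
  obj <- list(
    vertices = unname(asplit(state$r, 1)),
    cells = unname(lapply(state$cells, function(cc) cc - 1L)),
    cell_ids = state$cell_ids,
    orientation = "clockwise", index_base = 0L,
    params = unclass(state$params),
    time = state$time,
    events = state$events)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a simulation state written by [write_state_json()]
#' @param path JSON file
#' @return `vm_state`
#' @export
read_state_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  r <- .as_coord_matrix(obj$vertices)
  cells <- lapply(.as_cycle_list(obj$cells), function(cc) as.integer(cc) + 1L)
  p <- do.call(vm_params, obj$params[names(obj$params) %in%
                 names(formals(vm_params))])
  st <- vm_state(cells, r, p, cell_ids = as.integer(obj$cell_ids))
  st$time <- obj$time
  st
}

#' Run the full ablation experiment pipeline
#'
#' Grow, relax, ablate, re-relax, then compute the rotated force potential,
#' cell stresses, harmonic mode and the radial scaling fits, returning all
#' intermediates. Deterministic given the seed.
#'
#' @param n_cells target cell count
#' @param seed RNG seed
#' @param params `vm_params` used for growth
#' @param selector which cell to ablate: `"central"`, `"min_peff"`,
#'   `"max_peff"`, or an explicit cell id (integer)
#' @param n_bins bins for the edge-level slope fits (per-edge quantities,
#'   ~1400 samples)
#' @param n_bins_cells bins for the cell-level slope fits (~400 interior
#'   cells; fewer bins keep the per-bin envelope estimates populated)
#' @return list with the pre/post states, stress tables, harmonic basis,
#'   decomposition, response table and a `slopes` list
#' @export
run_ablation_experiment <- function(n_cells = 500, seed = 1,
                                    params = vm_params(peripheral_stress = -0.1),
                                    selector = "central", n_bins = 12,
                                    n_bins_cells = 8) {
  pre <- grow_monolayer(n_cells, params = params, seed = seed)
  mesh_pre <- vm_mesh(pre)
  stress_pre <- cell_stress(pre)
  target_idx <- if (is.numeric(selector)) {
    match(selector, pre$cell_ids)
  } else {
    switch(selector,
      central = which.min(rowSums(sweep(mesh_pre$geometry$Rc, 2,
                                        colMeans(pre$r))^2)),
      min_peff = {
        interior <- !.peripheral_cells(mesh_pre$topology)
        which(interior)[which.min(stress_pre$p_eff[interior])]
      },
      max_peff = {
        interior <- !.peripheral_cells(mesh_pre$topology)
        which(interior)[which.max(stress_pre$p_eff[interior])]
      },
      stop("unknown selector"))
  }
  center <- as.numeric(mesh_pre$geometry$Rc[target_idx, ])
  post <- ablate(pre, pre$cell_ids[target_idx])
  mesh_post <- vm_mesh(post)
  ops <- mesh_operators(mesh_post)
  basis <- harmonic_basis(ops)
  profile <- harmonic_profile(basis, center)
  h <- rotated_force_potential(post)
  decomp <- helmholtz_decompose(h$h[ops$idx_e, ], ops)
  response <- ablation_response(pre, post, center = center)
  int <- response[!response$peripheral, ]
  rj <- sqrt(rowSums(sweep(mesh_post$geometry$c_mid[ops$idx_e, ], 2, center)^2))
  ## every fit drops the outer 20% radius band (boundary effects); the
  ## cell-stress differences additionally exclude peripheral cells, and the
  ## Helmholtz residual uses the inner half, where the harmonic component
  ## stands above the reconstruction error
  slopes <- list(
    chi = upper_bound_slope(profile$chi, profile$r, n_bins = n_bins),
    d_zeta = upper_bound_slope(int$abs_d_zeta, int$r, n_bins = n_bins_cells),
    d_p_eff = upper_bound_slope(int$abs_d_p_eff, int$r,
                                n_bins = n_bins_cells),
    residual = upper_bound_slope(sqrt(rowSums(decomp$residual^2)), rj,
                                 n_bins = n_bins, r_max_frac = 0.5))
  list(pre = pre, post = post, center = center,
       stress_pre = stress_pre, stress_post = cell_stress(post),
       basis = basis, profile = profile, h = h, decomposition = decomp,
       response = response, slopes = slopes, seed = seed)
}

## jsonlite may simplify equal-length lists to matrices; normalize both ways
.as_coord_matrix <- function(v) {
  if (is.matrix(v)) return(v)
  do.call(rbind, lapply(v, as.numeric))
}

.as_cycle_list <- function(cc) {
  if (is.matrix(cc)) return(lapply(seq_len(nrow(cc)), function(i) cc[i, ]))
  cc
}

.peripheral_cells <- function(top) {
  Matrix::rowSums(abs(top$B[, top$peripheral_edges, drop = FALSE])) > 0
}
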