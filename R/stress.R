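#' Rotated force potential of an equilibrated monolayer
#'
#' At equilibrium the three corner forces at each vertex close into a
#' triangle; rotating every corner force by a quarter turn therefore builds a
#' closed network (topologically the network joining adjacent edge
#' centroids) whose nodes define a vector `h_j` per cell edge. `h` is a
#' potential for the force field: differencing it through the incidence
#' matrices, `-sum_j B_ij A_jk h_j`, recovers the rotated corner force of
#' cell `i` at vertex `k`. It is assembled here by integrating the rotated
#' corner forces over the edge graph, starting from `h = 0` on a peripheral
#' edge; path-independence (the equilibrium closure) is verified and the
#' worst loop residual reported. Under zero external load the integrated
#' values on all peripheral edges vanish with the force residual and are
#' snapped to zero.
#'
#' @param state an equilibrated `vm_state`
#' @param tol closure tolerance (defaults to 100x the parameter force
#'   tolerance)
#' @return object of class `mono_force_potential`: `h` (n_edges x 2),
#'   `residual` (worst unused-constraint mismatch), `max_boundary` (largest
#'   integrated peripheral magnitude before snapping), `corner_forces`
#' @export
rotated_force_potential <- function(state, tol = NULL) {
  st <- state
  if (is.null(tol)) tol <- 100 * st$params$force_tol
  top <- vm_topology(st)
  pc <- vm_forces(st, per_corner = TRUE)
  fmax <- sqrt(max(rowSums(cbind(rowsum(pc$fx, st$corners$k),
                                 rowsum(pc$fy, st$corners$k))^2)))
  if (fmax > tol)
    stop(sprintf("state is not equilibrated (max force %.3g > %.3g)", fmax, tol))
  co <- st$corners
  ## rotated corner forces (clockwise quarter turn, matching the cell
  ## orientation convention)
  sx <- pc$fy
  sy <- -pc$fx
  ## edge indices before/after each corner within its cell
  epair <- paste(pmin(co$k, co$kn), pmax(co$k, co$kn))
  j_out <- unname(top$edge_of_pair[epair])
  epair_in <- paste(pmin(co$kp, co$k), pmax(co$kp, co$k))
  j_in <- unname(top$edge_of_pair[epair_in])
  ## h[j_out] = h[j_in] + rotated corner force; integrate by BFS
  ne <- top$n_edges
  h <- matrix(NA_real_, ne, 2)
  start <- which(top$peripheral_edges)[1]
  h[start, ] <- 0
  from <- c(j_in, j_out)
  to <- c(j_out, j_in)
  dx <- c(sx, -sx); dy <- c(sy, -sy)
  ord <- order(from)
  adj_ptr <- split(ord, from[ord])
  queue <- start
  while (length(queue)) {
    jj <- queue[[1L]]; queue <- queue[-1L]
    rows <- adj_ptr[[as.character(jj)]]
    for (rr in rows) {
      tt <- to[rr]
      if (is.na(h[tt, 1])) {
        h[tt, ] <- h[jj, ] + c(dx[rr], dy[rr])
        queue <- c(queue, tt)
      }
    }
  }
  if (anyNA(h)) stop("edge graph not connected while integrating h")
  resid <- max(abs(h[j_out, 1] - h[j_in, 1] - sx),
               abs(h[j_out, 2] - h[j_in, 2] - sy))
  if (resid > tol)
    stop(sprintf("rotated-force integration is path-dependent (residual %.3g)",
                 resid))
  maxb <- max(abs(h[top$peripheral_edges, ]))
  h[top$peripheral_edges, ] <- 0
  structure(list(h = h, residual = resid, max_boundary = maxb,
                 corner_forces = pc, topology = top),
            class = "mono_force_potential")
}

#' @export
print.mono_force_potential <- function(x, ...) {
  cat(sprintf("<mono_force_potential> %d edges | loop residual %.3g | boundary %.3g\n",
              nrow(x$h), x$residual, x$max_boundary))
  invisible(x)
}

#' Cell stress tensors from the rotated force potential
#'
#' Evaluates the per-cell stress
#' `sigma_i = A_i^-1 sum_j B_ij (t_j x h_j) eps_i`, splits off the
#' deviatoric part and its symmetric/antisymmetric components, and derives
#' the shear stress `zeta_i = sqrt(-det(sigma_Ds))` and effective pressure
#' `P_eff = tr(sigma)/2`. At equilibrium the rotated forces close around
#' every cell, so `sigma_i` is symmetric; the antisymmetric part and the
#' cell-wise curl of `h` vanish together. The pressure is also evaluated by
#' its derivative route (`-cocurl(h)/2`) as a consistency check.
#'
#' @param state equilibrated `vm_state`
#' @param h a `mono_force_potential` (computed if missing)
#' @return a tibble with one row per cell: `cell_id`, `area`, the stress
#'   components, `zeta`, `p_eff`, `p_eff_cocurl`, `curl_h`, `asym`
#' @export
cell_stress <- function(state, h = NULL) {
  st <- state
  if (is.null(h)) h <- rotated_force_potential(st)
  top <- h$topology
  mesh <- vm_mesh(st)
  g <- mesh$geometry
  hv <- h$h
  B <- top$B
  tv <- g$t_vec
  ## M_i = sum_j B_ij (t_j outer h_j); then sigma = M eps_i / A_i
  M11 <- as.numeric(B %*% (tv[, 1] * hv[, 1]))
  M12 <- as.numeric(B %*% (tv[, 1] * hv[, 2]))
  M21 <- as.numeric(B %*% (tv[, 2] * hv[, 1]))
  M22 <- as.numeric(B %*% (tv[, 2] * hv[, 2]))
  A <- g$A_cell
  ## right-multiply by eps_i (clockwise): (c1 c2) -> (-c2 c1) on columns
  s11 <- -M12 / A; s12 <- M11 / A
  s21 <- -M22 / A; s22 <- M21 / A
  p_eff <- 0.5 * (s11 + s22)
  d11 <- s11 - p_eff; d22 <- s22 - p_eff
  ds12 <- 0.5 * (s12 + s21)
  da12 <- 0.5 * (s12 - s21)
  det_ds <- d11 * d22 - ds12^2
  zeta <- sqrt(pmax(-det_ds, 0))
  ## derivative route for the pressure: cocurl over interior edges (h = 0 on
  ## peripheral edges so the restriction is exact)
  ie <- !top$peripheral_edges
  et <- rot_cw(tv)
  cocurl <- -as.numeric(B[, ie, drop = FALSE] %*%
                          rowSums(hv[ie, , drop = FALSE] * et[ie, , drop = FALSE])) / A
  tibble::tibble(
    cell_id = top$cell_ids, area = A,
    sxx = s11, sxy = s12, syx = s21, syy = s22,
    zeta = zeta, p_eff = p_eff, p_eff_cocurl = -0.5 * cocurl,
    curl_h = as.numeric(B[, ie, drop = FALSE] %*%
                          rowSums(hv[ie, , drop = FALSE] * tv[ie, , drop = FALSE])) / A,
    asym = da12,
    cx = g$Rc[, 1], cy = g$Rc[, 2])
}

#' Mechanical response to an ablation
#'
#' Differences two equilibrated states sharing cell identities (before and
#' after removing one or more cells): per surviving cell it reports the
#' centre displacement, its radial component relative to the ablation
#' centre, and the changes in shear stress and effective pressure
#' magnitudes.
#'
#' @param pre,post equilibrated `vm_state`s (post typically from [ablate()])
#' @param center reference point; defaults to the pre-ablation centre of the
#'   removed cell(s)
#' @return a tibble with one row per surviving cell
#' @export
ablation_response <- function(pre, post, center = NULL) {
  s_pre <- cell_stress(pre)
  s_post <- cell_stress(post)
  lost <- setdiff(s_pre$cell_id, s_post$cell_id)
  if (is.null(center)) {
    if (!length(lost)) stop("no removed cell and no explicit center")
    center <- c(mean(s_pre$cx[s_pre$cell_id %in% lost]),
                mean(s_pre$cy[s_pre$cell_id %in% lost]))
  }
  common <- intersect(s_pre$cell_id, s_post$cell_id)
  a <- s_pre[match(common, s_pre$cell_id), ]
  b <- s_post[match(common, s_post$cell_id), ]
  dRx <- b$cx - a$cx; dRy <- b$cy - a$cy
  rx <- a$cx - center[1]; ry <- a$cy - center[2]
  rr <- sqrt(rx^2 + ry^2)
  disp <- sqrt(dRx^2 + dRy^2)
  radial <- ifelse(disp > 0, (dRx * rx + dRy * ry) / (rr * disp), 0)
  ## peripheral cells behave differently; flag them
  top <- vm_topology(post)
  periph_ids <- top$cell_ids[Matrix::rowSums(
    abs(top$B[, top$peripheral_edges, drop = FALSE])) > 0]
  tibble::tibble(
    cell_id = common, r = rr,
    dx = dRx, dy = dRy, displacement = disp, radial_component = radial,
    d_zeta = b$zeta - a$zeta, d_p_eff = b$p_eff - a$p_eff,
    abs_d_zeta = abs(b$zeta - a$zeta), abs_d_p_eff = abs(b$p_eff - a$p_eff),
    peripheral = common %in% periph_ids)
}

#' Log-log slope of a radial upper bound
#'
#' Bins the supplied radii into log-spaced bins, records the per-bin maximum
#' of the (non-negative) values, and fits `log10(max)` against `log10(r)` by
#' ordinary least squares over the decaying part of the envelope: the fit
#' window starts at the bin where the per-bin maximum peaks (inside the
#' apex the bound is set by saturation at the hole scale, not by the
#' far-field decay being measured). By default the outer 20% of the radius
#' range is excluded.
#'
#' @param values non-negative values
#' @param radii positive distances, same length
#' @param n_bins number of log-spaced bins
#' @param r_max_frac outer cutoff as a fraction of the maximum radius
#' @return list with `slope`, `stderr`, `n_bins_used`, and the binned table
#' @export
upper_bound_slope <- function(values, radii, n_bins = 12, r_max_frac = 0.8) {
  stopifnot(length(values) == length(radii), all(radii > 0))
  keep <- values > 0 & radii <= r_max_frac * max(radii)
  v <- values[keep]; r <- radii[keep]
  br <- exp(seq(log(min(r)), log(max(r)), length.out = n_bins + 1))
  br[1] <- br[1] * (1 - 1e-12); br[n_bins + 1] <- br[n_bins + 1] * (1 + 1e-12)
  bin <- as.integer(cut(r, br, include.lowest = TRUE))
  cnt <- tabulate(bin, n_bins)
  pop <- which(cnt >= 1)
  vmax_all <- vapply(pop, function(bb) max(v[which(bin == bb)]), numeric(1))
  apex <- pop[which.max(vmax_all)]
  use <- pop[pop >= apex]
  if (length(use) < 5) stop("insufficient populated bins for a slope fit")
  vmax <- vmax_all[match(use, pop)]
  ctr <- sqrt(br[use] * br[use + 1])
  fit <- stats::lm(log10(vmax) ~ log10(ctr))
  sm <- summary(fit)$coefficients
  list(slope = unname(sm[2, 1]), stderr = unname(sm[2, 2]),
       n_bins_used = length(use),
       bins = tibble::tibble(r = ctr, max_value = vmax))
}
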