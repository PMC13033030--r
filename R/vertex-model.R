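#' Vertex-model parameters
#'
#' The monolayer evolves by gradient flow of the quadratic energy
#' `E = 1/2 * sum_i ((A_i - 1)^2 + Gamma * (L_i - L0_tilde)^2)` in units of
#' the preferred cell area; `Gamma` weighs perimeter against bulk
#' elasticity and `L0_tilde` is the dimensionless preferred perimeter. The
#' defaults `Gamma = 0.2`, `L0_tilde = 0.75` keep monolayers rigid
#' (jammed). `peripheral_stress` is an isotropic stress applied at the
#' monolayer boundary through an energy term `-sigma * total area` (negative
#' values compress); it is used while growing and set to zero for analysis.
#'
#' @param Gamma perimeter stiffness (> 0)
#' @param L0_tilde preferred perimeter
#' @param peripheral_stress boundary stress during growth
#' @param force_tol equilibrium criterion: largest vertex force magnitude
#' @param t1_threshold edge length triggering a neighbour exchange
#' @param t1_length length of a freshly created edge after an exchange
#' @param dt_init,dt_max adaptive gradient-flow step bounds
#' @return list of class `vm_params`
#' @export
vm_params <- function(Gamma = 0.2, L0_tilde = 0.75, peripheral_stress = 0,
                      force_tol = 1e-8, t1_threshold = 0.05,
                      t1_length = 1.5 * t1_threshold,
                      dt_init = 0.05, dt_max = 0.4) {
  stopifnot(Gamma > 0, force_tol > 0, t1_threshold >= 0)
  structure(list(Gamma = Gamma, L0_tilde = L0_tilde,
                 peripheral_stress = peripheral_stress,
                 force_tol = force_tol, t1_threshold = t1_threshold,
                 t1_length = t1_length, dt_init = dt_init, dt_max = dt_max),
            class = "vm_params")
}

#' Create a simulation state
#'
#' @param cells list of clockwise vertex cycles
#' @param r vertex position matrix
#' @param params a `vm_params`
#' @param cell_ids stable cell identifiers
#' @return object of class `vm_state`
#' @export
vm_state <- function(cells, r, params = vm_params(), cell_ids = NULL) {
  if (is.null(cell_ids)) cell_ids <- seq_along(cells)
  st <- structure(list(cells = cells, r = as.matrix(r), params = params,
                       cell_ids = cell_ids, time = 0,
                       events = list(), next_cell_id = max(cell_ids) + 1L),
                  class = "vm_state")
  .vm_refresh(st)
}

#' Initial single-hexagon state
#'
#' A regular hexagon of unit area, the seed of the growth algorithm.
#' @param params a `vm_params`
#' @return `vm_state`
#' @export
vm_seed_state <- function(params = vm_params()) {
  s <- sqrt(2 / (3 * sqrt(3)))
  ang <- (0:5) * pi / 3
  r <- cbind(cos(ang), sin(ang)) * s
  vm_state(list(6:1), r, params)
}

## rebuild derived index caches after any topological change
.vm_refresh <- function(st) {
  st$cells <- lapply(st$cells, function(cc) as.integer(unname(cc)))
  zl <- lengths(st$cells)
  ci <- rep.int(seq_along(st$cells), zl)
  k  <- unlist(st$cells, use.names = FALSE)
  kn <- unlist(lapply(st$cells, function(cc) c(cc[-1L], cc[1L])), use.names = FALSE)
  kp <- unlist(lapply(st$cells, function(cc) c(cc[length(cc)], cc[-length(cc)])),
               use.names = FALSE)
  ## interior-edge table for T1 scanning and valences
  tail <- pmin(k, kn); head <- pmax(k, kn)
  key <- paste(tail, head)
  ue <- !duplicated(key)
  mult <- tabulate(match(key, key[ue]), sum(ue))
  st$corners <- list(ci = ci, k = k, kn = kn, kp = kp, zl = zl)
  st$edge_tab <- cbind(tail = tail[ue], head = head[ue])
  st$edge_interior <- mult == 2L
  st$valence <- tabulate(c(st$edge_tab), nrow(st$r))
  st$cache <- new.env(parent = emptyenv())
  st
}

#' @export
print.vm_state <- function(x, ...) {
  cat(sprintf("<vm_state> %d cells, %d vertices, t = %.3g, %d event(s)\n",
              length(x$cells), nrow(x$r), x$time, length(x$events)))
  invisible(x)
}

## energy and forces, vectorized over corners ------------------------------

vm_energy <- function(st, r = st$r) {
  co <- st$corners; p <- st$params
  cross <- r[co$k, 1] * r[co$kn, 2] - r[co$kn, 1] * r[co$k, 2]
  A <- -0.5 * as.numeric(rowsum(cross, co$ci))
  el <- sqrt((r[co$kn, 1] - r[co$k, 1])^2 + (r[co$kn, 2] - r[co$k, 2])^2)
  L <- as.numeric(rowsum(el, co$ci))
  0.5 * sum((A - 1)^2 + p$Gamma * (L - p$L0_tilde)^2) -
    p$peripheral_stress * sum(A)
}

## corner-wise force contributions; rowsum-accumulated per vertex.
## Returns the total force matrix; with `per_corner = TRUE` also the
## per-corner contributions f_ik (force on vertex k from cell i's energy).
vm_forces <- function(st, r = st$r, per_corner = FALSE) {
  co <- st$corners; p <- st$params
  x <- r[, 1]; y <- r[, 2]
  cross <- x[co$k] * y[co$kn] - x[co$kn] * y[co$k]
  A <- -0.5 * as.numeric(rowsum(cross, co$ci))
  dxn <- x[co$kn] - x[co$k]; dyn <- y[co$kn] - y[co$k]
  eln <- sqrt(dxn^2 + dyn^2)
  L <- as.numeric(rowsum(eln, co$ci))
  aco <- (A - 1 - p$peripheral_stress)[co$ci]
  lco <- (p$Gamma * (L - p$L0_tilde))[co$ci]
  ## clockwise shoelace gradient
  dAx <- 0.5 * (y[co$kp] - y[co$kn])
  dAy <- 0.5 * (x[co$kn] - x[co$kp])
  dxp <- x[co$k] - x[co$kp]; dyp <- y[co$k] - y[co$kp]
  elp <- sqrt(dxp^2 + dyp^2)
  dLx <- dxp / elp - dxn / eln
  dLy <- dyp / elp - dyn / eln
  fx <- -(aco * dAx + lco * dLx)
  fy <- -(aco * dAy + lco * dLy)
  F <- cbind(as.numeric(rowsum(fx, co$k)), as.numeric(rowsum(fy, co$k)))
  ## rowsum() orders by sorted unique vertex id == 1..n (all vertices in use)
  if (per_corner) list(F = F, fx = fx, fy = fy, A = A, L = L) else F
}

#' Forces on every vertex
#'
#' Analytic gradient of the vertex-model energy: the force on vertex `k` is
#' `-dE/dr_k`, combining the polygon-area gradient and the perimeter
#' unit-tangent gradient of each incident cell.
#'
#' @param state a `vm_state`
#' @return n_vertices x 2 force matrix
#' @export
vertex_forces <- function(state) vm_forces(state)

max_force <- function(st) {
  F <- vm_forces(st)
  sqrt(max(rowSums(F^2)))
}

## adaptive-step gradient flow with neighbour exchanges ---------------------

#' Relax a monolayer to mechanical equilibrium
#'
#' Explicit adaptive-step gradient flow: a step is accepted only if the
#' energy does not increase (halving the step otherwise, growing it after
#' success). Edges shorter than the exchange threshold trigger T1
#' transitions between steps. When the flow has brought the largest vertex
#' force close to the target, an L-BFGS polish of the same energy finishes
#' the equilibration (the exchange threshold is re-checked afterwards).
#'
#' @param state `vm_state`
#' @param force_tol override of the parameter set's tolerance
#' @param max_steps step budget for the explicit flow
#' @param t1 allow neighbour exchanges
#' @param polish finish with an L-BFGS minimization
#' @param strict error on step underflow (`FALSE` logs a stall event and
#'   returns the current state; used between growth divisions)
#' @return relaxed `vm_state`
#' @export
relax <- function(state, force_tol = NULL, max_steps = 20000, t1 = TRUE,
                  polish = TRUE, strict = TRUE) {
  st <- state
  tol <- if (is.null(force_tol)) st$params$force_tol else force_tol
  dt <- st$params$dt_init
  E <- vm_energy(st)
  stalled <- FALSE
  for (step in seq_len(max_steps)) {
    if (t1) {
      st2 <- .vm_do_t1s(st)
      if (!identical(st2, st)) { st <- st2; E <- vm_energy(st) }
    }
    F <- vm_forces(st)
    fmax <- sqrt(max(rowSums(F^2)))
    if (fmax <= tol) break
    accepted <- FALSE
    while (!accepted) {
      r_new <- st$r + dt * F
      E_new <- vm_energy(st, r_new)
      if (is.finite(E_new) && E_new <= E + 1e-14) {
        st$r <- r_new; E <- E_new
        dt <- min(dt * 1.1, st$params$dt_max)
        accepted <- TRUE
      } else {
        dt <- dt / 2
        if (dt < 1e-12) {
          ## the energy decrement has fallen below double resolution; the
          ## polish stage finishes on the force residual instead
          stalled <- TRUE
          st$events[[length(st$events) + 1L]] <-
            list(type = "relax_stalled", time = st$time)
          break
        }
      }
    }
    if (!accepted) break
    st$time <- st$time + dt
  }
  if (polish) {
    for (round in 1:8) {
      st <- .vm_polish(st, tol)
      if (!t1) break
      st2 <- .vm_do_t1s(st)
      if (identical(st2, st)) break
      st <- st2
    }
  }
  if (strict && max_force(st) > tol * 1.001)
    stop(sprintf("relaxation did not converge (max force %.3g > %.3g)",
                 max_force(st), tol))
  st
}

.vm_polish <- function(st, tol, maxit = 5000) {
  n <- nrow(st$r)
  fn <- function(p) vm_energy(st, matrix(p, n, 2))
  gr <- function(p) -as.vector(vm_forces(st, matrix(p, n, 2)))
  ## near the minimum the energy decrement falls below double resolution
  ## while the force (computed directly) is still informative: alternate
  ## L-BFGS rounds with force-monitored descent whose step adapts both ways
  for (cycle in 1:8) {
    opt <- stats::optim(as.vector(st$r), fn, gr, method = "L-BFGS-B",
                        control = list(maxit = maxit, factr = 10))
    st$r <- matrix(opt$par, n, 2)
    if (max_force(st) <= tol) return(st)
    dt <- st$params$dt_init
    fprev <- Inf
    for (i in seq_len(20000)) {
      F <- vm_forces(st)
      fmax <- sqrt(max(rowSums(F^2)))
      if (fmax <= tol) return(st)
      if (fmax > fprev) dt <- max(dt / 2, 1e-4)
      else dt <- min(dt * 1.02, st$params$dt_max)
      st$r <- st$r + dt * F
      fprev <- fmax
    }
  }
  st
}

## T1 transitions -----------------------------------------------------------

.vm_do_t1s <- function(st) {
  thr <- st$params$t1_threshold
  if (thr <= 0) return(st)
  guard <- 0L
  repeat {
    et <- st$edge_tab
    len <- sqrt((st$r[et[, 1], 1] - st$r[et[, 2], 1])^2 +
                (st$r[et[, 1], 2] - st$r[et[, 2], 2])^2)
    short <- which(len < thr)
    if (!length(short)) return(st)
    done <- FALSE
    E0 <- vm_energy(st)
    for (j in short[order(len[short])]) {
      ab <- st$edge_tab[j, ]
      st2 <- if (st$edge_interior[j]) {
        s <- try(t1_transition(st, ab), silent = TRUE)
        if (inherits(s, "try-error") || is.null(s))
          s <- .vm_t1_boundary_reach(st, ab)
        s
      } else if (min(st$valence[ab]) == 2L) {
        .vm_boundary_collapse(st, ab)
      } else if (all(st$valence[ab] == 3L)) {
        .vm_boundary_t1(st, ab)
      } else NULL
      if (inherits(st2, "try-error") || is.null(st2)) next
      ## the flow is a gradient descent, so a rewiring is only kept if it
      ## dissipates energy; a sub-threshold edge that is *stable* (its
      ## exchange would raise the energy) is a legitimate equilibrium
      ## feature and is left alone. Only near-degenerate edges force the
      ## move regardless.
      if (len[j] >= 0.3 * thr && vm_energy(st2) > E0 - 1e-12) next
      st <- st2; done <- TRUE; break
    }
    if (!done) return(st)
    guard <- guard + 1L
    if (guard > 50L) return(st)   # avoid runaway cascades
  }
}

## merge the two endpoints of a vanishing peripheral edge when one of them
## is 2-valent (the fusion then leaves every vertex at most 3-valent)
.vm_boundary_collapse <- function(st, edge) {
  a <- edge[1]; b <- edge[2]
  if (st$valence[a] != 2L) { tmp <- a; a <- b; b <- tmp }
  if (st$valence[a] != 2L) return(NULL)
  ## merge the 2-valent vertex a into b
  tmp <- a; a <- b; b <- tmp   # code below removes b
  owner <- which(vapply(st$cells, function(cc) a %in% cc && b %in% cc, logical(1)))
  if (length(owner) != 1L) return(NULL)
  if (length(st$cells[[owner]]) <= 3L) return(NULL)
  cells <- lapply(st$cells, function(cc) {
    cc[cc == b] <- a
    ## collapse the (cyclically) consecutive duplicate left by the merge
    prev <- c(cc[length(cc)], cc[-length(cc)])
    cc[cc != prev]
  })
  if (any(lengths(cells) < 3L)) return(NULL)
  r <- st$r
  r[a, ] <- 0.5 * (st$r[a, ] + st$r[b, ])
  st$cells <- cells
  st$r <- r
  st$events[[length(st$events) + 1L]] <-
    list(type = "boundary_collapse", edge = c(a, b), time = st$time)
  .vm_compact(st)
}

## collapse of an interior edge whose boundary endpoint belongs to only the
## two edge cells: the third cell (at the interior endpoint) reaches the
## boundary, acquiring a new peripheral edge between the exchanged vertices.
## With P the edge cell traversing a -> b (a the 2-cell boundary endpoint):
##   P: (..., u, a, b, x, ...) -> (..., u, a, x, ...)
##   Q: (..., y, b, a, w, ...) -> (..., y, b, w, ...)
##   R: (..., x, b, y, ...)    -> (..., x, a, b, y, ...)
.vm_t1_boundary_reach <- function(st, edge) {
  a <- edge[1]; b <- edge[2]
  has_a <- vapply(st$cells, function(cc) a %in% cc, logical(1))
  has_b <- vapply(st$cells, function(cc) b %in% cc, logical(1))
  if (sum(has_a) == 3L && sum(has_b) == 2L) { tmp <- a; a <- b; b <- tmp }
  has_a <- vapply(st$cells, function(cc) a %in% cc, logical(1))
  has_b <- vapply(st$cells, function(cc) b %in% cc, logical(1))
  PQ <- which(has_a & has_b)
  R <- which(has_b & !has_a)
  if (length(PQ) != 2L || sum(has_a) != 2L || length(R) != 1L) return(NULL)
  if (st$valence[a] != 3L || st$valence[b] != 3L) return(NULL)
  traverses_ab <- function(cyc) {
    pos <- which(cyc == a)
    cyc[if (pos == length(cyc)) 1L else pos + 1L] == b
  }
  if (traverses_ab(st$cells[[PQ[1]]])) { P <- PQ[1]; Q <- PQ[2] } else { P <- PQ[2]; Q <- PQ[1] }
  if (length(st$cells[[P]]) <= 3L || length(st$cells[[Q]]) <= 3L) return(NULL)
  cells <- st$cells
  cyc_nbrs <- function(cyc, v) {
    pos <- which(cyc == v)
    c(cyc[if (pos == 1L) length(cyc) else pos - 1L],
      cyc[if (pos == length(cyc)) 1L else pos + 1L])
  }
  x <- setdiff(cyc_nbrs(cells[[P]], b), a)   # P's other neighbour of b
  if (length(x) != 1L) return(NULL)
  cells[[P]] <- cells[[P]][cells[[P]] != b]
  cells[[Q]] <- cells[[Q]][cells[[Q]] != a]
  pos <- which(cells[[R]] == b)
  nxt <- cells[[R]][if (pos == length(cells[[R]])) 1L else pos + 1L]
  cells[[R]] <- if (nxt == x) append(cells[[R]], a, after = pos)
                else append(cells[[R]], a, after = pos - 1L)
  mid <- 0.5 * (st$r[a, ] + st$r[b, ])
  tdir <- st$r[b, ] - st$r[a, ]
  tdir <- tdir / sqrt(sum(tdir^2))
  ndir <- c(-tdir[2], tdir[1])
  ctrP <- colMeans(st$r[st$cells[[P]], , drop = FALSE])
  if (sum((ctrP - mid) * ndir) < 0) ndir <- -ndir
  r <- st$r
  r[a, ] <- mid + 0.5 * st$params$t1_length * ndir   # stays with P
  r[b, ] <- mid - 0.5 * st$params$t1_length * ndir   # stays with Q
  ok <- all(vapply(list(cells[[P]], cells[[Q]], cells[[R]]), function(cc) {
    pp <- r[cc, , drop = FALSE]
    pn <- pp[c(2:nrow(pp), 1), , drop = FALSE]
    -0.5 * sum(pp[, 1] * pn[, 2] - pn[, 1] * pp[, 2]) > 0
  }, logical(1)))
  if (!ok) return(NULL)
  st$cells <- cells
  st$r <- r
  st$events[[length(st$events) + 1L]] <-
    list(type = "t1_boundary_reach", edge = c(a, b), time = st$time)
  .vm_refresh(st)
}

## neighbour exchange at the boundary: the peripheral edge (a, b) of cell P
## collapses, its side cells R (at a) and S (at b) become adjacent through a
## new short interior edge pushed inwards, and P detaches from the boundary
## at that site. Implemented as an atomic merge-and-split so every vertex
## stays 3-valent: a becomes the boundary junction of R and S, b becomes the
## interior junction of P, R and S.
.vm_boundary_t1 <- function(st, edge) {
  a <- edge[1]; b <- edge[2]
  has_a <- vapply(st$cells, function(cc) a %in% cc, logical(1))
  has_b <- vapply(st$cells, function(cc) b %in% cc, logical(1))
  P <- which(has_a & has_b)
  R <- which(has_a & !has_b)
  S <- which(has_b & !has_a)
  if (length(P) != 1L || length(R) != 1L || length(S) != 1L || R == S)
    return(NULL)
  if (length(st$cells[[P]]) <= 3L) return(NULL)
  cyc_nbrs <- function(cyc, v) {
    pos <- which(cyc == v)
    c(cyc[if (pos == 1L) length(cyc) else pos - 1L],
      cyc[if (pos == length(cyc)) 1L else pos + 1L])
  }
  ## X: P's other neighbour of a (shared P-R edge); Y: P's other neighbour of b
  X <- setdiff(cyc_nbrs(st$cells[[P]], a), b)
  Y <- setdiff(cyc_nbrs(st$cells[[P]], b), a)
  qR <- setdiff(cyc_nbrs(st$cells[[R]], a), X)    # R's boundary neighbour of a
  qS <- setdiff(cyc_nbrs(st$cells[[S]], b), Y)
  if (length(X) != 1L || length(Y) != 1L || length(qR) != 1L || length(qS) != 1L)
    return(NULL)
  mid <- 0.5 * (st$r[a, ] + st$r[b, ])
  ctrP <- colMeans(st$r[st$cells[[P]], , drop = FALSE])
  n_in <- ctrP - mid
  n_in <- n_in / sqrt(sum(n_in^2))
  cells <- st$cells
  cells[[P]] <- cells[[P]][cells[[P]] != a]
  insert_next_to <- function(cyc, at, new_v, towards) {
    pos <- which(cyc == at)
    nxt <- cyc[if (pos == length(cyc)) 1L else pos + 1L]
    if (nxt == towards) append(cyc, new_v, after = pos)
    else append(cyc, new_v, after = pos - 1L)
  }
  cells[[R]] <- insert_next_to(cells[[R]], a, b, X)   # b between a and X
  cells[[S]] <- insert_next_to(cells[[S]], b, a, qS)  # a between b and qS
  r <- st$r
  r[a, ] <- mid
  r[b, ] <- mid + st$params$t1_length * n_in
  ok <- all(vapply(list(cells[[P]], cells[[R]], cells[[S]]), function(cc) {
    pp <- r[cc, , drop = FALSE]
    pn <- pp[c(2:nrow(pp), 1), , drop = FALSE]
    -0.5 * sum(pp[, 1] * pn[, 2] - pn[, 1] * pp[, 2]) > 0
  }, logical(1)))
  if (!ok) return(NULL)
  st$cells <- cells
  st$r <- r
  st$events[[length(st$events) + 1L]] <-
    list(type = "boundary_t1", edge = c(a, b), time = st$time)
  .vm_refresh(st)
}

## drop vertices no longer referenced by any cell and renumber
.vm_compact <- function(st) {
  used <- sort(unique(unlist(st$cells)))
  if (length(used) != nrow(st$r)) {
    remap <- integer(nrow(st$r)); remap[used] <- seq_along(used)
    st$cells <- lapply(st$cells, function(cc) remap[cc])
    st$r <- st$r[used, , drop = FALSE]
  }
  .vm_refresh(st)
}

#' Perform a single T1 neighbour exchange
#'
#' Collapses the interior edge joining two 3-valent interior vertices and
#' re-expands it perpendicular to its old direction at the post-exchange
#' length, swapping which pairs of cells are adjacent. The incidence
#' structure is rebuilt and validated.
#'
#' @param state `vm_state`
#' @param edge length-2 vector of vertex indices
#' @return updated `vm_state`, or `NULL` (invisibly, with a logged event) if
#'   the configuration does not admit an exchange
#' @export
t1_transition <- function(state, edge) {
  st <- state
  a <- edge[1]; b <- edge[2]
  has_a <- vapply(st$cells, function(cc) a %in% cc, logical(1))
  has_b <- vapply(st$cells, function(cc) b %in% cc, logical(1))
  PQ <- which(has_a & has_b)
  Ra <- which(has_a & !has_b)
  Sb <- which(has_b & !has_a)
  if (length(PQ) != 2L || length(Ra) != 1L || length(Sb) != 1L ||
      st$valence[a] != 3L || st$valence[b] != 3L) {
    st$events[[length(st$events) + 1L]] <-
      list(type = "t1_skipped", edge = c(a, b), time = st$time)
    return(NULL)
  }
  cells <- st$cells
  ## orient so that P is the edge cell traversing a -> b and Q the one
  ## traversing b -> a; after the exchange (keeping clockwise winding
  ## throughout) the update is purely combinatorial:
  ##   P drops b, Q drops a, R replaces a by (b, a), S replaces b by (a, b)
  traverses_ab <- function(cyc) {
    pos <- which(cyc == a)
    nxt <- cyc[if (pos == length(cyc)) 1L else pos + 1L]
    nxt == b
  }
  if (traverses_ab(cells[[PQ[1]]])) { P <- PQ[1]; Q <- PQ[2] } else { P <- PQ[2]; Q <- PQ[1] }
  mid <- 0.5 * (st$r[a, ] + st$r[b, ])
  tdir <- st$r[b, ] - st$r[a, ]
  tdir <- tdir / sqrt(sum(tdir^2))
  ndir <- c(-tdir[2], tdir[1])
  ctrP <- colMeans(st$r[cells[[P]], , drop = FALSE])
  if (sum((ctrP - mid) * ndir) < 0) ndir <- -ndir
  lnew <- st$params$t1_length
  r <- st$r
  r[a, ] <- mid + 0.5 * lnew * ndir   # a stays with P (and joins R, S)
  r[b, ] <- mid - 0.5 * lnew * ndir   # b stays with Q
  replace_in <- function(cyc, at, repl) {
    pos <- which(cyc == at)
    append(cyc[-pos], repl, after = pos - 1L)
  }
  cells[[P]] <- cells[[P]][cells[[P]] != b]
  cells[[Q]] <- cells[[Q]][cells[[Q]] != a]
  cells[[Ra]] <- replace_in(cells[[Ra]], a, c(b, a))
  cells[[Sb]] <- replace_in(cells[[Sb]], b, c(a, b))
  ok <- all(vapply(list(cells[[P]], cells[[Q]], cells[[Ra]], cells[[Sb]]),
                   function(cc) {
                     pp <- r[cc, , drop = FALSE]
                     pn <- pp[c(2:nrow(pp), 1), , drop = FALSE]
                     -0.5 * sum(pp[, 1] * pn[, 2] - pn[, 1] * pp[, 2]) > 0
                   }, logical(1)))
  if (!ok) {
    st$events[[length(st$events) + 1L]] <-
      list(type = "t1_skipped", edge = c(a, b), time = st$time)
    return(NULL)
  }
  st$cells <- cells
  st$r <- r
  st$events[[length(st$events) + 1L]] <-
    list(type = "t1", edge = c(a, b), time = st$time)
  .vm_refresh(st)
}

.simple_polygon <- function(p) {
  n <- nrow(p)
  if (n < 4) return(TRUE)
  seg <- cbind(p, p[c(2:n, 1), , drop = FALSE])
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (abs(i - j) %in% c(1, n - 1)) next
    if (.segments_cross(seg[i, 1:2], seg[i, 3:4], seg[j, 1:2], seg[j, 3:4]))
      return(FALSE)
  }
  TRUE
}

.segments_cross <- function(p1, p2, q1, q2) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2)
  d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

## cell division ------------------------------------------------------------

.vm_divide <- function(st, cell_idx) {
  cyc <- st$cells[[cell_idx]]
  for (try_n in 1:10) {
    theta <- stats::runif(1, 0, pi)
    dd <- c(cos(theta), sin(theta))
    ctr <- colMeans(st$r[cyc, , drop = FALSE])
    nn <- c(-dd[2], dd[1])
    ## signed distances of vertices to the division line
    sd <- as.numeric((st$r[cyc, , drop = FALSE] -
                        matrix(ctr, length(cyc), 2, byrow = TRUE)) %*% nn)
    nx <- c(2:length(cyc), 1)
    crossing <- which(sd * sd[nx] < 0)
    if (length(crossing) != 2L) next
    frac <- sd[crossing] / (sd[crossing] - sd[nx][crossing])
    if (any(frac < 0.08 | frac > 0.92)) next   # avoid sliver daughters
    p1 <- crossing[1]; p2 <- crossing[2]
    va <- cyc[p1]; vb <- cyc[nx][p1]
    vc <- cyc[p2]; vd <- cyc[nx][p2]
    r1 <- st$r[va, ] + frac[1] * (st$r[vb, ] - st$r[va, ])
    r2 <- st$r[vc, ] + frac[2] * (st$r[vd, ] - st$r[vc, ])
    nv1 <- nrow(st$r) + 1L; nv2 <- nrow(st$r) + 2L
    st$r <- rbind(st$r, r1, r2)
    ## insert the new vertices into every cell sharing the split edges
    insert_on_edge <- function(cells, x, y, newv) {
      lapply(cells, function(cc) {
        m <- length(cc)
        for (q in seq_len(m)) {
          qn <- if (q == m) 1L else q + 1L
          if ((cc[q] == x && cc[qn] == y) || (cc[q] == y && cc[qn] == x))
            return(append(cc, newv, after = q))
        }
        cc
      })
    }
    cells <- insert_on_edge(st$cells, va, vb, nv1)
    cells <- insert_on_edge(cells, vc, vd, nv2)
    cyc2 <- cells[[cell_idx]]
    q1 <- which(cyc2 == nv1); q2 <- which(cyc2 == nv2)
    roll <- function(v, i) if (i == 1) v else c(v[i:length(v)], v[1:(i - 1)])
    cyc2 <- roll(cyc2, q1)
    q2 <- which(cyc2 == nv2)
    d1 <- cyc2[1:q2]                      # nv1 ... nv2
    d2 <- c(cyc2[q2:length(cyc2)], nv1)   # nv2 ... nv1
    if (length(d1) < 3 || length(d2) < 3) next
    cells[[cell_idx]] <- d1
    cells[[length(cells) + 1L]] <- d2
    st$cells <- cells
    st$cell_ids <- c(st$cell_ids, st$next_cell_id)
    st$next_cell_id <- st$next_cell_id + 1L
    st$events[[length(st$events) + 1L]] <-
      list(type = "division", cell = st$cell_ids[cell_idx], theta = theta,
           new_cell = st$cell_ids[length(st$cell_ids)], time = st$time)
    return(.vm_refresh(st))
  }
  st$events[[length(st$events) + 1L]] <-
    list(type = "division_failed", cell = st$cell_ids[cell_idx], time = st$time)
  st
}

#' Grow a disordered monolayer by random cell division
#'
#' Starting from a single hexagon, repeatedly divides a uniformly chosen
#' cell along a uniformly oriented axis through its centroid, relaxing the
#' monolayer (under the prescribed peripheral stress, with neighbour
#' exchanges) after each division. Growth under load locks heterogeneous
#' prestress into the tissue. After the target count is reached the
#' periphery is unloaded and the monolayer relaxed to the analysis
#' tolerance.
#'
#' @param n_cells target cell count
#' @param params `vm_params`; `peripheral_stress` applies during growth only
#' @param seed RNG seed (growth is deterministic given the seed)
#' @param growth_tol force tolerance during growth relaxations
#' @param growth_steps step budget per division
#' @return equilibrated `vm_state` with zero peripheral stress
#' @export
grow_monolayer <- function(n_cells, params = vm_params(peripheral_stress = -0.1),
                           seed = 1, growth_tol = 2e-3, growth_steps = 400) {
  set.seed(seed)
  st <- vm_seed_state(params)
  while (length(st$cells) < n_cells) {
    idx <- sample.int(length(st$cells), 1)
    st <- .vm_divide(st, idx)
    st <- relax(st, force_tol = growth_tol, max_steps = growth_steps,
                polish = FALSE, strict = FALSE)
  }
  st$params$peripheral_stress <- 0
  relax(st)
}

## topology bridge ----------------------------------------------------------

#' Mesh view of a simulation state
#' @param state `vm_state`
#' @return `mono_mesh`
#' @export
vm_mesh <- function(state) {
  mono_mesh(state$cells, state$r, cell_ids = state$cell_ids)
}

vm_topology <- function(state) build_topology(state$cells,
                                              n_vertices = nrow(state$r),
                                              cell_ids = state$cell_ids)

#' Ablate cells from a monolayer
#'
#' Removes the listed interior cells, leaving holes bounded by the former
#' cell outlines, and relaxes the wounded monolayer back to equilibrium.
#' Edges and vertices that end up bounding no cell are discarded. Cell
#' identifiers are preserved, so pre/post states can be differenced.
#'
#' @param state equilibrated `vm_state`
#' @param cell_ids identifiers (from `state$cell_ids`) of cells to remove
#' @param relax_after relax after removal
#' @return post-ablation `vm_state`
#' @export
ablate <- function(state, cell_ids, relax_after = TRUE) {
  st <- state
  idx <- match(cell_ids, st$cell_ids)
  if (anyNA(idx)) stop("unknown cell id")
  top <- vm_topology(st)
  for (i in idx) {
    if (any(top$peripheral_vertices[st$cells[[i]]]))
      stop("can only ablate strictly interior cells")
  }
  keep <- setdiff(seq_along(st$cells), idx)
  cells <- st$cells[keep]
  used <- sort(unique(unlist(cells)))
  remap <- integer(nrow(st$r)); remap[used] <- seq_along(used)
  st$cells <- lapply(cells, function(cc) remap[cc])
  st$r <- st$r[used, , drop = FALSE]
  st$cell_ids <- st$cell_ids[keep]
  st$events[[length(st$events) + 1L]] <-
    list(type = "ablation", cells = cell_ids, time = st$time)
  st <- .vm_refresh(st)
  if (relax_after) st <- relax(st)
  st
}
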