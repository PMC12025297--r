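#' @importFrom Matrix sparseMatrix Diagonal t solve
NULL

# Assemble the P1 stiffness matrix restricted to one element subset, as a
# sparse (n_nodes x n_nodes) matrix with unit conductivity on those elements.
region_stiffness <- function(ph, geom, elements) {
  n <- nrow(ph$nodes)
  if (length(elements) == 0L)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n, n)))
  t3 <- ph$tris[elements, , drop = FALSE]
  bx <- geom$bx[elements, , drop = FALSE]
  by <- geom$by[elements, , drop = FALSE]
  area <- geom$area[elements]
  ii <- jj <- xx <- vector("list", 9L)
  k <- 0L
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1L
    ii[[k]] <- t3[, a]
    jj[[k]] <- t3[, b]
    xx[[k]] <- area * (bx[, a] * bx[, b] + by[, a] * by[, b])
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(n, n))
}

# Complete-electrode-model boundary blocks (independent of conductivity):
# M (node-node electrode mass / z), G (node-electrode coupling / z),
# Dd (electrode self terms |E_l| / z).
cem_boundary_blocks <- function(ph) {
  n <- nrow(ph$nodes)
  z <- ph$contact_impedance
  n_el <- length(ph$electrode_edges)
  mi <- mj <- mx <- list(); gi <- gj <- gx <- list()
  dd <- numeric(n_el)
  for (l in seq_len(n_el)) {
    edges <- ph$electrode_edges[[l]]
    for (r in seq_len(nrow(edges))) {
      a <- edges[r, 1]; b <- edges[r, 2]
      len <- sqrt(sum((ph$nodes[a, ] - ph$nodes[b, ])^2))
      mi <- c(mi, list(c(a, a, b, b)))
      mj <- c(mj, list(c(a, b, a, b)))
      mx <- c(mx, list(len / z * c(1 / 3, 1 / 6, 1 / 6, 1 / 3)))
      gi <- c(gi, list(c(a, b)))
      gj <- c(gj, list(c(l, l)))
      gx <- c(gx, list(len / z * c(1 / 2, 1 / 2)))
      dd[l] <- dd[l] + len / z
    }
  }
  list(
    M = Matrix::sparseMatrix(i = unlist(mi), j = unlist(mj), x = unlist(mx),
                             dims = c(n, n)),
    G = Matrix::sparseMatrix(i = unlist(gi), j = unlist(gj), x = unlist(gx),
                             dims = c(n, n_el)),
    Dd = dd)
}

# Cached per-phantom FEM operator pieces.
cem_operator <- function(ph) {
  geom <- mesh_geometry(ph)
  regions <- sort(unique(ph$region))
  Ks <- lapply(regions, function(r) region_stiffness(ph, geom, which(ph$region == r)))
  names(Ks) <- as.character(regions)
  bb <- cem_boundary_blocks(ph)
  list(geom = geom, regions = regions, Ks = Ks, bb = bb,
       n_nodes = nrow(ph$nodes), n_el = length(ph$electrode_edges))
}

# Solve the CEM for one conductivity state and a matrix of electrode current
# patterns. `sigma_by_region` is a named numeric vector (names = region
# labels). Returns node potentials (n_nodes x P) and electrode potentials
# (n_el x P). Grounded by a Lagrange multiplier enforcing sum(U) = 0.
cem_solve <- function(op, sigma_by_region, currents) {
  K <- NULL
  for (r in names(op$Ks)) {
    s <- sigma_by_region[[r]]
    K <- if (is.null(K)) s * op$Ks[[r]] else K + s * op$Ks[[r]]
  }
  n <- op$n_nodes; ne <- op$n_el
  ones <- Matrix::sparseMatrix(i = seq_len(ne), j = rep(1L, ne), x = 1,
                               dims = c(ne, 1L))
  zn <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                             dims = c(n, 1L))
  A <- rbind(
    cbind(K + op$bb$M, -op$bb$G, zn),
    cbind(-Matrix::t(op$bb$G), Matrix::Diagonal(x = op$bb$Dd), ones),
    cbind(Matrix::t(zn), Matrix::t(ones),
          Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                               dims = c(1L, 1L))))
  currents <- as.matrix(currents)
  rhs <- rbind(matrix(0, n, ncol(currents)), currents,
               matrix(0, 1L, ncol(currents)))
  sol <- as.matrix(Matrix::solve(A, rhs))
  list(u = sol[seq_len(n), , drop = FALSE],
       U = sol[n + seq_len(ne), , drop = FALSE])
}

# 16 opposite-drive current patterns (columns): +I at electrode i, -I at the
# diametrically opposite electrode.
opposite_drive_currents <- function(current = 1e-3, n_el = 16L) {
  I <- matrix(0, n_el, n_el)
  for (i in seq_len(n_el)) {
    I[i, i] <- current
    I[((i + 7L) %% n_el) + 1L, i] <- -current
  }
  I
}

pattern_of <- function(cmap) match(cmap$drive_a, unique(cmap$drive_a))

#' Electrode potentials for arbitrary current injections
#'
#' Low-level access to the complete-electrode-model forward solution: given a
#' phantom, an element-region conductivity assignment, and electrode current
#' patterns, returns the electrode potentials. Mainly useful for physics
#' checks (e.g. reciprocity) and custom protocols.
#'
#' @param phantom an [make_phantom()] object.
#' @param sigma_by_region named numeric vector of conductivities (S/m), one
#'   entry per region label appearing in the phantom (names `"0"`, `"1"`, ...).
#' @param currents numeric matrix (16 x P), each column a current pattern in
#'   amperes summing to zero.
#' @return 16 x P matrix of electrode potentials (grounded to mean zero).
#' @export
electrode_potentials <- function(phantom, sigma_by_region, currents) {
  if (!inherits(phantom, "eit_phantom")) stop("expected an `eit_phantom`")
  currents <- as.matrix(currents)
  if (nrow(currents) != 16L) stop("`currents` must have 16 rows")
  if (any(abs(colSums(currents)) > 1e-12))
    stop("each current pattern must sum to zero")
  op <- cem_operator(phantom)
  need <- as.character(sort(unique(phantom$region)))
  if (!all(need %in% names(sigma_by_region)))
    stop("`sigma_by_region` must name regions: ", paste(need, collapse = ", "))
  cem_solve(op, sigma_by_region, currents)$U
}

#' Simulate breathing EIT boundary voltages
#'
#' Drives the phantom's lung regions with a breathing waveform and solves the
#' complete-electrode-model forward problem frame by frame under the
#' 16-electrode opposite-current-excitation / adjacent-voltage-measurement
#' protocol, producing a 192-channel recording. Channels report demodulated
#' amplitudes (the magnitude of the measured pair's potential difference), the
#' convention of clinical EIT electronics; this is what makes the summed
#' waveform trace the respiratory cycle. At frame `t`, region 1 (left
#' lung; in the heterogeneous phantom its ventral part) has conductivity
#' `w[t]` and region 2 (right lung) has `lung2_scale * w[t]`, where `w` is the
#' normalized waveform; in the heterogeneous phantom the dorsal-left
#' sub-region (region 3) also uses `lung2_scale * w[t]`. Non-lung tissue keeps
#' the phantom's background conductivity.
#'
#' @param phantom an [make_phantom()] object.
#' @param breathing a [synth_breathing()] waveform (values in (0, 1]).
#' @param lung2_scale conductivity scaling of the second lung region
#'   (default 0.15).
#' @param current_mA excitation current amplitude in milliamperes (default 1).
#' @param gain unit conversion applied to the solved potentials (default 1e3:
#'   recorded values are in millivolts; a 1 mA drive on a thorax-sized domain
#'   yields channel amplitudes of a few tenths of a millivolt). The fixed
#'   shrinkage thresholds of the default denoising parameters (`1/rho` on
#'   singular values, `lam/rho` per entry) presuppose data of roughly this
#'   numeric scale; recordings in other units call for re-tuned `rho`.
#' @return An [voltage_matrix()] with 192 rows and `length(breathing$values)`
#'   frames at the waveform's frame rate.
#' @export
forward_voltages <- function(phantom, breathing, lung2_scale = 0.15,
                             current_mA = 1.0, gain = 1e3) {
  if (!inherits(phantom, "eit_phantom")) stop("expected an `eit_phantom`")
  if (!inherits(breathing, "eit_breathing")) stop("expected an `eit_breathing`")
  w <- breathing$values
  if (length(w) < 2L) stop("need at least 2 frames")
  op <- cem_operator(phantom)
  cmap <- channel_map(16L)
  currents <- opposite_drive_currents(current = current_mA * 1e-3)
  pat <- pattern_of(cmap)
  ic <- cbind(cmap$meas_c, pat); id <- cbind(cmap$meas_d, pat)

  out <- matrix(0, nrow(cmap), length(w))
  # solve once per distinct conductivity state (periodic waveforms repeat)
  states <- as.character(signif(w, 12))
  for (s in unique(states)) {
    wv <- w[match(s, states)]
    sig <- c("0" = phantom$background_conductivity, "1" = wv,
             "2" = lung2_scale * wv, "3" = lung2_scale * wv)
    U <- cem_solve(op, sig, currents)$U
    out[, states == s] <- gain * abs(U[ic] - U[id])
  }
  voltage_matrix(out, breathing$frame_rate)
}

# Channel sensitivities to per-element conductivity perturbations on a given
# background state, via the adjoint method: J[ch, e] = -area_e *
# grad(u_drive) . grad(u_meas), with u_meas the CEM solution injecting unit
# current through the channel's measurement pair. Rows are sign-corrected to
# the amplitude convention of forward_voltages (sensitivity of |v_ch| equals
# sign(v_ch) times that of v_ch away from zero). Used for GREIT training.
forward_jacobian <- function(phantom, sigma_by_region, current = 1e-3) {
  op <- cem_operator(phantom)
  cmap <- channel_map(16L)
  sol_d <- cem_solve(op, sigma_by_region,
                     opposite_drive_currents(current = current))
  drive <- sol_d$u
  # unit-current injections through the 16 adjacent pairs (c, c+1)
  Im <- matrix(0, 16L, 16L)
  for (c in seq_len(16L)) {
    Im[c, c] <- 1
    Im[(c %% 16L) + 1L, c] <- -1
  }
  meas <- cem_solve(op, sigma_by_region, Im)$u

  gx <- function(u) {  # per-element gradient components for all solution cols
    ux <- op$geom$bx[, 1] * u[phantom$tris[, 1], ] +
          op$geom$bx[, 2] * u[phantom$tris[, 2], ] +
          op$geom$bx[, 3] * u[phantom$tris[, 3], ]
    uy <- op$geom$by[, 1] * u[phantom$tris[, 1], ] +
          op$geom$by[, 2] * u[phantom$tris[, 2], ] +
          op$geom$by[, 3] * u[phantom$tris[, 3], ]
    list(x = ux, y = uy)
  }
  gd <- gx(drive); gm <- gx(meas)
  pat <- pattern_of(cmap)
  v0 <- sol_d$U[cbind(cmap$meas_c, pat)] - sol_d$U[cbind(cmap$meas_d, pat)]
  sgn <- ifelse(v0 >= 0, 1, -1)
  J <- matrix(0, nrow(cmap), nrow(phantom$tris))
  for (ch in seq_len(nrow(cmap))) {
    p <- pat[ch]; m <- cmap$meas_c[ch]
    J[ch, ] <- -sgn[ch] * op$geom$area *
      (gd$x[, p] * gm$x[, m] + gd$y[, p] * gm$y[, m])
  }
  J
}
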