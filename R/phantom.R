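#' Thorax-like 2-D phantom with lung inclusions
#'
#' Builds a triangulated 2-D domain with 16 equispaced boundary electrodes and
#' two elliptical lung-shaped inclusions, used by the forward simulator. The
#' mesh is a structured polar grid (concentric rings of a fixed angular
#' resolution) over the unit disc, optionally squashed to an ellipse for the
#' `"thorax"` style. Region labels: 0 = background, 1 = left lung, 2 = right
#' lung; with `heterogeneous_left = TRUE` the left lung is split along its
#' minor axis into sub-regions 1 (ventral half) and 3 (dorsal half), which the
#' forward model drives with different conductivity scalings.
#'
#' Orientation convention: the subject's ventral (anterior) side is at +y and
#' the subject's right is at -x (the usual view from the feet). Electrode 1
#' sits on the ventral midline and numbering proceeds clockwise when viewed in
#' standard x-y coordinates (towards the subject's left first).
#'
#' @param style `"circular"` (unit disc) or `"thorax"` (ellipse, y squashed to
#'   0.8).
#' @param heterogeneous_left split the left lung into two sub-regions.
#' @param n_rings,n_theta mesh resolution: number of radial rings and angular
#'   subdivisions. Defaults give 2240 triangles.
#' @param background_conductivity baseline conductivity in S/m (default 1).
#' @return An object of class `eit_phantom`: list with `nodes` (n x 2),
#'   `tris` (m x 3 node indices), `region` (length-m integer labels),
#'   `electrode_edges` (list of 16 edge matrices, each row a boundary node
#'   pair), `electrode_angles`, `style`, `background_conductivity`,
#'   `contact_impedance`, `bounds` (semi-axes).
#' @export
make_phantom <- function(style = c("thorax", "circular"),
                         heterogeneous_left = FALSE,
                         n_rings = 18L, n_theta = 64L,
                         background_conductivity = 1.0) {
  style <- match.arg(style)
  n_rings <- as.integer(n_rings); n_theta <- as.integer(n_theta)
  if (n_theta %% 16L != 0L)
    stop("`n_theta` must be a multiple of 16 so electrodes align with mesh nodes")
  if (n_rings < 4L) stop("`n_rings` must be at least 4")

  ay <- if (style == "thorax") 0.8 else 1.0  # y semi-axis

  # nodes: centre, then rings 1..n_rings each with n_theta nodes;
  # angular slot 1 on the ventral midline (+y), proceeding clockwise so
  # electrode 1 is ventral and numbering runs towards the subject's left
  theta <- pi / 2 - 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  nodes <- matrix(0, 1L + n_rings * n_theta, 2L)
  for (i in seq_len(n_rings)) {
    r <- i / n_rings
    idx <- 1L + (i - 1L) * n_theta + seq_len(n_theta)
    nodes[idx, 1L] <- r * cos(theta)
    nodes[idx, 2L] <- ay * r * sin(theta)
  }

  ring_node <- function(i, j) {  # ring i >= 1, angular slot j (1-based, wraps)
    1L + (i - 1L) * n_theta + ((j - 1L) %% n_theta) + 1L
  }

  tris <- matrix(0L, n_theta + 2L * (n_rings - 1L) * n_theta, 3L)
  k <- 0L
  for (j in seq_len(n_theta)) {           # central fan
    k <- k + 1L
    tris[k, ] <- c(1L, ring_node(1L, j), ring_node(1L, j + 1L))
  }
  for (i in 2L:n_rings) {                 # annuli, two triangles per quad
    for (j in seq_len(n_theta)) {
      a <- ring_node(i - 1L, j); b <- ring_node(i - 1L, j + 1L)
      c <- ring_node(i, j);      d <- ring_node(i, j + 1L)
      k <- k + 1L; tris[k, ] <- c(a, c, d)
      k <- k + 1L; tris[k, ] <- c(a, d, b)
    }
  }

  # region labels from element centroids; lungs are ellipses placed
  # symmetrically about the x (right-left) axis, ventral side at +y
  cx <- (nodes[tris[, 1L], 1L] + nodes[tris[, 2L], 1L] + nodes[tris[, 3L], 1L]) / 3
  cy <- (nodes[tris[, 1L], 2L] + nodes[tris[, 2L], 2L] + nodes[tris[, 3L], 2L]) / 3
  in_ellipse <- function(x, y, x0, y0, rx, ry)
    ((x - x0) / rx)^2 + ((y - y0) / ry)^2 <= 1
  # subject right = -x (image left); subject left = +x
  lung_rx <- 0.30; lung_ry <- 0.42 * ay; lung_cx <- 0.42; lung_cy <- -0.05 * ay
  region <- integer(nrow(tris))
  region[in_ellipse(cx, cy, +lung_cx, lung_cy, lung_rx, lung_ry)] <- 1L # left
  region[in_ellipse(cx, cy, -lung_cx, lung_cy, lung_rx, lung_ry)] <- 2L # right
  if (heterogeneous_left) {
    # split the left lung into ventral (stays region 1) and dorsal (region 3)
    region[region == 1L & cy < lung_cy] <- 3L
  }

  # electrodes: 16 equispaced, each spanning 2 consecutive boundary edges
  per <- n_theta %/% 16L
  boundary <- function(j) ring_node(n_rings, j)
  electrode_edges <- vector("list", 16L)
  electrode_angles <- numeric(16L)
  for (e in seq_len(16L)) {
    centre_slot <- (e - 1L) * per + 1L    # node slot at the electrode centre
    electrode_angles[e] <- theta[centre_slot]
    electrode_edges[[e]] <- rbind(
      c(boundary(centre_slot - 1L), boundary(centre_slot)),
      c(boundary(centre_slot), boundary(centre_slot + 1L)))
  }

  structure(list(
    nodes = nodes, tris = tris, region = region,
    electrode_edges = electrode_edges, electrode_angles = electrode_angles,
    style = style, heterogeneous_left = heterogeneous_left,
    background_conductivity = background_conductivity,
    contact_impedance = 0.01,   # ohm * m^2-equivalent in 2-D units (100 ohm cm^2)
    bounds = c(1.0, ay)),
    class = "eit_phantom")
}

#' @export
print.eit_phantom <- function(x, ...) {
  cat(sprintf("EIT phantom (%s): %d nodes, %d elements, regions {%s}\n",
              x$style, nrow(x$nodes), nrow(x$tris),
              paste(sort(unique(x$region)), collapse = ", ")))
  invisible(x)
}

# element areas and P1 gradient geometry, precomputed once per mesh
mesh_geometry <- function(ph) {
  p <- ph$nodes; t3 <- ph$tris
  x1 <- p[t3[, 1], 1]; y1 <- p[t3[, 1], 2]
  x2 <- p[t3[, 2], 1]; y2 <- p[t3[, 2], 2]
  x3 <- p[t3[, 3], 1]; y3 <- p[t3[, 3], 2]
  det <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  area <- abs(det) / 2
  # gradients of the three barycentric basis functions (constant per element)
  bx <- cbind(y2 - y3, y3 - y1, y1 - y2) / det
  by <- cbind(x3 - x2, x1 - x3, x2 - x1) / det
  list(area = area, bx = bx, by = by)
}
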