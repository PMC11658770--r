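# Tension-isogonal decomposition.
#
# The tension triangulation (rotated 90 degrees into physical
# orientation) provides a force-balance reference geometry; the isogonal
# tensor I is the linear map carrying the l0-scaled reference into the
# observed centroidal geometry, l0 * I * t_ij = c_i - c_j. Deviations of
# I from a rotation measure angle-preserving (isogonal) strain, which
# force balance does not constrain and which therefore reports external
# stresses and cell-shape elasticity.

rot90ccw <- function(v) c(-v[2], v[1])

#' Physical-orientation tension triangle at a mesh vertex
#'
#' Rotates the three balancing tension vectors at a tri-cellular vertex
#' by 90 degrees counter-clockwise and chains them into the dual
#' triangle whose corners correspond to the three incident cells
#' (one triangulation vertex per cell, edges perpendicular to the
#' interfaces they are dual to). Tensions are the vertex-normalized
#' relative tensions (mean 1).
#'
#' @param mesh a \code{cell_mesh}.
#' @param vertex interior tri-cellular vertex id.
#' @return 3 x 2 coordinate matrix with rownames = cell ids (centered on
#'   the triangle centroid).
#' @export
tension_triangle_at_vertex <- function(mesh, vertex) {
  ang <- vertex_angles(mesh, vertex)
  if (length(ang) != 3L) stop("vertex ", vertex, " is not tri-cellular")
  tens <- infer_vertex_tensions(ang)
  dirs <- attr(ang, "directions")
  cells <- attr(ang, "cells")
  g <- t(vapply(1:3, function(i) rot90ccw(tens[i] * dirs[i, ]), numeric(2)))
  # chain: v0 = 0, v1 = g1, v2 = g1 + g2; the cell between interfaces
  # i and i+1 sits at the corner shared by dual edges g_i and g_{i+1}
  v0 <- c(0, 0); v1 <- g[1, ]; v2 <- g[1, ] + g[2, ]
  xy <- rbind(v1, v2, v0)
  rownames(xy) <- c(cells[1], cells[2], cells[3])
  sweep(xy, 2, colMeans(xy))
}

#' Isogonal tensor from matched triangles
#'
#' Solves the exact linear map I (translation discarded) with
#' \code{l0 * I * (tension edge vectors) = centroid edge vectors}, from
#' the two independent edge correspondences of a matched triangle pair.
#'
#' @param tension_xy 3 x 2 matrix: physical-orientation tension triangle,
#'   rows labeled by cell id.
#' @param centroid_xy 3 x 2 matrix: centroids of the same cells, rows in
#'   the same order (or with matching rownames).
#' @param l0 tension-to-length scale, micrometres.
#' @return object of class \code{isogonal_tensor}: the 2 x 2 matrix
#'   \code{I}, \code{l0}, residual 0, plus the polar decomposition
#'   (rotation angle \code{theta}, symmetric stretch \code{U}).
#' @export
vertex_isogonal <- function(tension_xy, centroid_xy, l0 = tigon_constants$l0) {
  tension_xy <- as.matrix(tension_xy); centroid_xy <- as.matrix(centroid_xy)
  if (!is.null(rownames(tension_xy)) && !is.null(rownames(centroid_xy))) {
    centroid_xy <- centroid_xy[rownames(tension_xy), , drop = FALSE]
  }
  Tm <- cbind(tension_xy[1, ] - tension_xy[3, ], tension_xy[2, ] - tension_xy[3, ])
  Cm <- cbind(centroid_xy[1, ] - centroid_xy[3, ], centroid_xy[2, ] - centroid_xy[3, ])
  if (abs(det(Tm)) < 1e-14 * max(abs(Tm))^2) stop("degenerate tension triangle")
  if (abs(det(Cm)) < 1e-300) stop("degenerate centroid triangle")
  I <- Cm %*% solve(l0 * Tm)
  isogonal_tensor(I, l0, residual = 0)
}

isogonal_tensor <- function(I, l0, residual = NA_real_) {
  if (det(I) <= 0) warning("isogonal tensor with non-positive determinant")
  pol <- polar_decompose(I)
  structure(list(I = I, l0 = l0, residual = residual,
                 theta = pol$theta, U = pol$U),
            class = "isogonal_tensor")
}

#' @export
print.isogonal_tensor <- function(x, ...) {
  s <- svd(x$I)$d
  cat("isogonal_tensor: stretches", paste(signif(s, 4), collapse = ", "),
      "| rotation", round(x$theta * 180 / pi, 2), "deg | aspect",
      signif(tensor_aspect(x), 4), "\n")
  invisible(x)
}

polar_decompose <- function(I) {
  s <- svd(I)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {           # keep a proper rotation
    s$v[, 2] <- -s$v[, 2]; s$d[2] <- -s$d[2]
    R <- s$u %*% t(s$v)
  }
  U <- t(R) %*% I             # symmetric stretch, I = R U
  list(theta = atan2(R[2, 1], R[1, 1]), U = (U + t(U)) / 2)
}

#' Aspect ratio of an isogonal tensor
#'
#' \code{sqrt(sigma_max / sigma_min)} of the stretch part's singular
#' values: the square-root convention matches the point-set aspect ratio
#' of \code{\link{quartet_shape_aspect}} (second-moment eigenvalue
#' ratios), so a pure shear \code{diag(s, 1/s)} has aspect \code{s}.
#'
#' @param x an \code{isogonal_tensor} or 2 x 2 matrix.
#' @return aspect ratio >= 1.
#' @export
tensor_aspect <- function(x) {
  I <- if (inherits(x, "isogonal_tensor")) x$I else as.matrix(x)
  s <- svd(I)$d
  sqrt(s[1] / s[2])
}

#' Least-squares isogonal tensor of a cell quartet
#'
#' Fits the single 2 x 2 map I minimizing
#' \code{sum_k | l0 * I * t_k - d_k |^2} over the five kite edge
#' correspondences (tension-triangulation edge vectors t_k vs centroid
#' differences d_k). The system is overdetermined; the residual RMS is
#' reported.
#'
#' @param tension_xy 4 x 2 matrix of tension-triangulation corner
#'   positions, rows labeled by cell id.
#' @param centroid_xy 4 x 2 matrix of the same cells' centroids.
#' @param pairs 2-column matrix of rowname pairs defining the edges
#'   (default: the 5 kite edges in row order shared pair first:
#'   rows 1-2 = the interface-sharing pair, rows 3-4 = the end cells).
#' @param l0 tension-to-length scale.
#' @return an \code{isogonal_tensor} with least-squares residual.
#' @export
quartet_isogonal <- function(tension_xy, centroid_xy, pairs = NULL,
                             l0 = tigon_constants$l0) {
  tension_xy <- as.matrix(tension_xy); centroid_xy <- as.matrix(centroid_xy)
  ids <- rownames(tension_xy)
  if (is.null(ids)) {
    ids <- as.character(seq_len(nrow(tension_xy)))
    rownames(tension_xy) <- ids
    if (is.null(rownames(centroid_xy))) rownames(centroid_xy) <- ids
  }
  centroid_xy <- centroid_xy[ids, , drop = FALSE]
  if (is.null(pairs)) {
    pairs <- rbind(c(ids[1], ids[2]),
                   c(ids[1], ids[3]), c(ids[1], ids[4]),
                   c(ids[2], ids[3]), c(ids[2], ids[4]))
  }
  Tm <- t(tension_xy[pairs[, 1], ] - tension_xy[pairs[, 2], ])   # 2 x k
  Dm <- t(centroid_xy[pairs[, 1], ] - centroid_xy[pairs[, 2], ]) # 2 x k
  G <- Tm %*% t(Tm)
  if (abs(det(G)) < 1e-14 * max(abs(G))^2) stop("rank-deficient quartet system")
  I <- (Dm %*% t(Tm)) %*% solve(G) / l0
  res <- sqrt(mean(colSums((l0 * I %*% Tm - Dm)^2)))
  isogonal_tensor(I, l0, residual = res)
}

#' Aspect ratio of a point configuration
#'
#' \code{sqrt(lambda_max / lambda_min)} of the second-moment (covariance)
#' tensor of the points, so the ratio is in length units: stretching the
#' set by 2 along one axis doubles the aspect ratio.
#'
#' @param pts n x 2 matrix (n >= 3, non-collinear).
#' @return aspect ratio >= 1 (Inf for collinear input, with a warning).
#' @export
quartet_shape_aspect <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 3L) stop("need at least 3 points")
  X <- sweep(pts, 2, colMeans(pts))
  M <- crossprod(X) / nrow(pts)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] <= 1e-14 * ev[1]) {
    warning("collinear points: infinite aspect ratio")
    return(Inf)
  }
  sqrt(ev[1] / ev[2])
}

#' Reference / isogonal decomposition of an interface length
#'
#' Splits the observed interface length into the tension-determined
#' Voronoi reference length and the isogonal remainder,
#' \code{l = l_ref + dl_iso}. The kite is inferred from the edge's end
#' vertex angles (relative tensions, mean flank = 1).
#'
#' @param mesh a \code{cell_mesh}.
#' @param interface interface id.
#' @param l0 tension-to-length scale, micrometres.
#' @return list with \code{l} (observed), \code{l_ref}, \code{dl_iso},
#'   \code{T_rel} and the kite.
#' @export
edge_length_decomposition <- function(mesh, interface, l0 = tigon_constants$l0) {
  inf <- infer_edge_tension(mesh, interface)
  l <- mesh$interfaces$length[match(interface, mesh$interfaces$id)]
  l_ref <- voronoi_reference_length(inf$kite, l0)
  list(l = l, l_ref = l_ref, dl_iso = l - l_ref,
       T_rel = inf$T_rel, kite = inf$kite)
}

#' Per-vertex isogonal tensors over a mesh
#'
#' Computes the isogonal tensor at every interior tri-cellular vertex
#' whose three incident cells are all interior (centroids of boundary
#' cells are biased by the cut).
#'
#' @param mesh a \code{cell_mesh}.
#' @param l0 tension-to-length scale.
#' @return data frame: vertex_id, Ixx, Ixy, Iyx, Iyy, theta (rotation,
#'   radians), s1, s2 (principal stretches), aspect.
#' @export
vertex_isogonal_field <- function(mesh, l0 = tigon_constants$l0) {
  rows <- list()
  for (v in mesh$interior_vertices) {
    if (mesh$vertex_degree[[v]] != 3L) next
    cells <- mesh$vertex_cells[[v]]
    if (any(cells %in% mesh$boundary_cells)) next
    tri <- tryCatch(tension_triangle_at_vertex(mesh, v), error = function(e) NULL)
    if (is.null(tri)) next
    cen <- mesh$centroids[rownames(tri), , drop = FALSE]
    it <- tryCatch(vertex_isogonal(tri, cen, l0), error = function(e) NULL)
    if (is.null(it)) next
    sv <- svd(it$U)$d
    rows[[v]] <- data.frame(vertex_id = v,
                            Ixx = it$I[1, 1], Ixy = it$I[1, 2],
                            Iyx = it$I[2, 1], Iyy = it$I[2, 2],
                            theta = it$theta, s1 = sv[1], s2 = sv[2],
                            aspect = sqrt(sv[1] / sv[2]))
  }
  if (!length(rows)) stop("no valid vertices for isogonal field")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Grid-averaged isogonal strain field
#'
#' Averages the per-vertex isogonal tensors component-wise on a square
#' grid (anchored at the mesh bounding-box origin), then polar-decomposes
#' the averaged tensor. The DV-DV component is measured along the fixed
#' +y axis.
#'
#' @param mesh a \code{cell_mesh}.
#' @param field result of \code{\link{vertex_isogonal_field}}.
#' @param spacing grid spacing, micrometres (default 20).
#' @return data frame: gx, gy, x, y, s1, s2 (principal stretches of the
#'   averaged tensor), theta_deg (principal-axis orientation), dvdv,
#'   count.
#' @export
grid_average_isogonal <- function(mesh, field = vertex_isogonal_field(mesh),
                                  spacing = 20) {
  if (spacing <= 0) stop("spacing must be positive")
  origin <- c(min(mesh$vertices[, 1]), min(mesh$vertices[, 2]))
  p <- mesh$vertices[field$vertex_id, , drop = FALSE]
  gx <- floor((p[, 1] - origin[1]) / spacing)
  gy <- floor((p[, 2] - origin[2]) / spacing)
  tab <- cbind(field, gx = gx, gy = gy, n = 1)
  agg <- stats::aggregate(cbind(Ixx, Ixy, Iyx, Iyy, n) ~ gx + gy,
                          data = tab, FUN = sum)
  agg[, c("Ixx", "Ixy", "Iyx", "Iyy")] <-
    agg[, c("Ixx", "Ixy", "Iyx", "Iyy")] / agg$n
  out <- lapply(seq_len(nrow(agg)), function(k) {
    I <- matrix(c(agg$Ixx[k], agg$Iyx[k], agg$Ixy[k], agg$Iyy[k]), 2, 2)
    pol <- polar_decompose(I)
    ev <- eigen(pol$U, symmetric = TRUE)
    data.frame(gx = agg$gx[k], gy = agg$gy[k],
               x = origin[1] + (agg$gx[k] + 0.5) * spacing,
               y = origin[2] + (agg$gy[k] + 0.5) * spacing,
               s1 = ev$values[1], s2 = ev$values[2],
               theta_deg = (atan2(ev$vectors[2, 1], ev$vectors[1, 1]) * 180 / pi) %% 180,
               dvdv = pol$U[2, 2], count = agg$n[k])
  })
  do.call(rbind, out)
}

#' Isogonal aspect ratio of the symmetric passive collapse
#'
#' Explicit geometric construction of a symmetric passive T1: starting
#' from the hexagonal (Voronoi reference) quartet, all vertex angles are
#' held at 120 degrees while the central interface shrinks to zero at
#' constant cell area. The returned value is the aspect ratio of the
#' least-squares quartet isogonal tensor at the moment of collapse
#' (analytically sqrt(3)).
#'
#' @param l_hex initial hexagon edge length, micrometres.
#' @return list with \code{aspect}, the isogonal tensor \code{I}, and
#'   the start/end centroid configurations.
#' @export
passive_collapse_aspect <- function(l_hex = 1) {
  # equilateral tension kite, central interface vertical: shared dual
  # edge horizontal between the cells L, R; apexes T, B
  tension_xy <- rbind(L = c(-0.5, 0), R = c(0.5, 0),
                      Tc = c(0, sqrt(3) / 2), B = c(0, -sqrt(3) / 2))
  l0 <- sqrt(3) * l_hex   # Voronoi edge of the unit triangulation = l0/sqrt(3)
  cent_ref <- rbind(L = c(-sqrt(3) / 2, 0) * l_hex, R = c(sqrt(3) / 2, 0) * l_hex,
                    Tc = c(0, 1.5) * l_hex, B = c(0, -1.5) * l_hex)
  # collapse at fixed 120-degree angles and fixed cell area:
  # cell area = sqrt(3) * lf * (lc + lf / 2); lc: l_hex -> 0
  lf_end <- sqrt(3) * l_hex
  X <- lf_end * cos(pi / 6); Y <- 0 + lf_end * sin(pi / 6)
  cent_end <- rbind(L = c(-X, 0), R = c(X, 0), Tc = c(0, Y), B = c(0, -Y))
  pairs <- rbind(c("L", "R"), c("L", "Tc"), c("L", "B"), c("R", "Tc"), c("R", "B"))
  it <- quartet_isogonal(tension_xy, cent_end, pairs, l0 = l0)
  list(aspect = tensor_aspect(it), I = it$I,
       centroids_reference = cent_ref, centroids_collapse = cent_end,
       tension_xy = tension_xy, l0 = l0)
}
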