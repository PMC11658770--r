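# Tension-space geometry: triangles, kites, the Voronoi reference length,
# the geometric T1 threshold, and local-tension-configuration (LTC)
# triangle shape coordinates.

#' Tension triangle from three side lengths
#'
#' The three relative tensions balancing at a tri-cellular vertex form a
#' closed triangle with side lengths equal to the tensions. Internal
#' angles come from the law of cosines; each internal angle is the
#' complement (pi minus) of the vertex angle between the corresponding
#' pair of interfaces.
#'
#' @param t0,t1,t2 positive side lengths (relative tensions).
#' @return object of class \code{tension_triangle}: \code{tensions},
#'   \code{angles} (internal, radians; angle k opposite side k),
#'   \code{vertex_angles} (the complementary cell-vertex angles), and
#'   triangle coordinates \code{xy} (side 0 spans vertices 1-2).
#' @export
triangle_from_tensions <- function(t0, t1, t2) {
  tens <- c(t0, t1, t2)
  if (any(tens <= 0)) stop("tensions must be positive")
  s <- sort(tens)
  if (s[3] >= s[1] + s[2] - 1e-14 * s[3]) {
    stop("no force balance: tensions violate the triangle inequality")
  }
  lc <- function(a, b, c) acos(pmin(1, pmax(-1, (b^2 + c^2 - a^2) / (2 * b * c))))
  ang <- c(lc(t0, t1, t2), lc(t1, t2, t0), lc(t2, t0, t1))
  # coordinates: vertex A opposite side 0; side 0 from B to C along x
  B <- c(0, 0); C <- c(t0, 0)
  A <- c(t2 * cos(ang[2]), t2 * sin(ang[2]))
  structure(list(tensions = tens, angles = ang,
                 vertex_angles = pi - ang,
                 xy = rbind(A = A, B = B, C = C)),
            class = "tension_triangle")
}

#' @export
print.tension_triangle <- function(x, ...) {
  cat("tension_triangle: sides", paste(signif(x$tensions, 4), collapse = ", "),
      "| internal angles", paste(round(x$angles * 180 / pi, 2), collapse = ", "),
      "deg\n")
  invisible(x)
}

circumcenter <- function(p1, p2, p3) {
  ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-300) stop("degenerate triangle: no circumcenter")
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
         (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
         (cx^2 + cy^2) * (bx - ax)) / d
  c(ux, uy)
}

#' Tension kite from five tensions
#'
#' Two tension triangles sharing the side dual to a cell-cell interface.
#' The kite is embedded with the shared side along the y axis, the first
#' triangle's apex at x > 0 and the second at x < 0.
#'
#' @param t_central shared-side tension.
#' @param t1a,t1b flank tensions of the first triangle.
#' @param t2a,t2b flank tensions of the second triangle.
#' @return object of class \code{tension_kite}: the five tensions, apex
#'   angles \code{phi} (internal angles opposite the shared side), apex
#'   coordinates and shared-side endpoints.
#' @export
kite_from_tensions <- function(t_central, t1a, t1b, t2a, t2b) {
  tr1 <- triangle_from_tensions(t_central, t1a, t1b)
  tr2 <- triangle_from_tensions(t_central, t2a, t2b)
  # shared side from S1 = (0, -t/2) to S2 = (0, +t/2);
  # triangle 1 apex to the right: apex adjacent to sides t1a (from S1)...
  # place apex using angle at S1 between shared side and side of length t1b
  apex <- function(tr, side) {
    # flank a joins S1 to the apex; the angle at S1 between the shared
    # side (pointing to S2) and flank a is the internal angle opposite
    # flank b, i.e. tr$angles[3]
    gamma <- tr$angles[3]
    ta <- tr$tensions[2]
    c(side * ta * sin(gamma), -t_central / 2 + ta * cos(gamma))
  }
  a1 <- apex(tr1, +1); a2 <- apex(tr2, -1)
  structure(list(tensions = c(central = t_central,
                              t1a = t1a, t1b = t1b, t2a = t2a, t2b = t2b),
                 phi = c(tr1$angles[1], tr2$angles[1]),
                 shared = rbind(S1 = c(0, -t_central / 2),
                                S2 = c(0, t_central / 2)),
                 apex = rbind(A1 = a1, A2 = a2),
                 triangles = list(tr1, tr2)),
            class = "tension_kite")
}

#' @export
print.tension_kite <- function(x, ...) {
  cat("tension_kite: central", signif(x$tensions[1], 4), "| flanks",
      paste(signif(x$tensions[-1], 4), collapse = ", "),
      "| apex angles", paste(round(x$phi * 180 / pi, 2), collapse = ", "),
      "deg\n")
  invisible(x)
}

#' Voronoi reference length of a kite's central interface
#'
#' The reference interface length predicted by force balance alone: the
#' signed distance between the circumcenters of the kite's two tension
#' triangles, scaled by the tension-to-length factor \code{l0}. Positive
#' when the circumcenters lie on opposite sides of the shared side in the
#' valid Voronoi order; zero exactly when the four kite vertices are
#' concyclic; negative past the T1 threshold. For a symmetric kite of
#' isosceles triangles with apex angle phi and central tension
#' T = 2 sin(phi/2) this reduces to \code{l0 * T * cot(phi)}.
#'
#' @param kite a \code{tension_kite}.
#' @param l0 tension-to-length scale in micrometres (default 4.2, the
#'   shipped calibration constant; see \code{\link{tigon_constants}}).
#' @return signed reference length in micrometres.
#' @export
voronoi_reference_length <- function(kite, l0 = tigon_constants$l0) {
  cc1 <- circumcenter(kite$shared[1, ], kite$shared[2, ], kite$apex[1, ])
  cc2 <- circumcenter(kite$shared[1, ], kite$shared[2, ], kite$apex[2, ])
  # both circumcenters lie on the perpendicular bisector of the shared
  # side (the x axis here); valid order: cc1 on the apex-1 side (x > 0)
  l0 * (cc1[1] - cc2[1])
}

#' Geometric T1 threshold tension
#'
#' Solves the symmetric-quartet threshold relation: the interface length
#' \code{l = l_ref(T) + dl_iso} vanishes, with
#' \code{l_ref = l0 * T * cot(phi)} and \code{T = 2 sin(phi / 2)}.
#' The root in phi is found by bisection; at \code{dl_iso = 0} the
#' threshold is exactly \code{sqrt(2)} (the two isosceles tension
#' triangles form a square).
#'
#' @param dl_iso isogonal length contribution in micrometres (may be
#'   negative; a root exists for \code{dl_iso > -l0}).
#' @param l0 tension-to-length scale, micrometres.
#' @param tol bisection tolerance on phi (radians).
#' @return critical relative tension \code{T_crit} in (0, 2).
#' @export
t1_threshold <- function(dl_iso, l0 = tigon_constants$l0, tol = 1e-12) {
  if (length(dl_iso) > 1L) {
    return(vapply(dl_iso, t1_threshold, numeric(1), l0 = l0, tol = tol))
  }
  f <- function(phi) l0 * 2 * sin(phi / 2) / tan(phi) + dl_iso
  lo <- 1e-9; hi <- pi - 1e-9
  if (f(lo) < 0) stop("no T1 threshold root: dl_iso <= -l0")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  phi <- (lo + hi) / 2
  2 * sin(phi / 2)
}

#' Edge flip of a tension kite
#'
#' Executes the tension-space edge flip at a neighbor exchange: the side
#' shared by the two tension triangles collapses in the cell array and
#' the new interface's total tension is the length of the other diagonal
#' of the tension quadrilateral. The four outer sides are unchanged, so
#' flipping twice returns the original shared tension.
#'
#' @param kite a \code{tension_kite} with a convex tension quadrilateral.
#' @return the flipped \code{tension_kite}; its central tension is the
#'   new interface's total tension.
#' @export
flip_kite <- function(kite) {
  S1 <- kite$shared[1, ]; S2 <- kite$shared[2, ]
  A1 <- kite$apex[1, ]; A2 <- kite$apex[2, ]
  # quadrilateral in cyclic order S1, A1, S2, A2; convex iff the
  # diagonals S1-S2 and A1-A2 properly intersect
  if (!segments_intersect(S1, S2, A1, A2)) {
    stop("flip undefined: tension quadrilateral is not convex")
  }
  t_new <- sqrt(sum((A1 - A2)^2))
  # new triangles share side A1-A2; outer sides are preserved:
  # triangle at S1: sides (t_new, |S1-A1|, |S1-A2|), similarly S2
  d <- function(p, q) sqrt(sum((p - q)^2))
  kite_from_tensions(t_new, d(S1, A1), d(S1, A2), d(S2, A1), d(S2, A2))
}

#' LTC shape coordinates of a tension triangle
#'
#' Local-tension-configuration coordinates: elongation \code{a} in
#' [0, 1) from the triangle-vertex gyration tensor,
#' \code{a = (sqrt(l1) - sqrt(l2)) / (sqrt(l1) + sqrt(l2))} with
#' \code{l1 >= l2} its eigenvalues, and the bridge/cable coordinate
#' \code{b = -cos(theta_max)} with \code{theta_max} the largest internal
#' angle. Obtuse triangles (b > 0) are tension-bridge motifs, acute ones
#' (b < 0) tension cables; an equilateral triangle sits at (0, -0.5).
#' Both coordinates are invariant under rotation, translation, uniform
#' scaling, and vertex relabeling.
#'
#' @param triangle a \code{tension_triangle} (or 3 x 2 coordinate matrix).
#' @return list with \code{a}, \code{b}, \code{theta_max} (radians), and
#'   \code{degenerate} flag.
#' @export
ltc_shape <- function(triangle) {
  xy <- if (inherits(triangle, "tension_triangle")) triangle$xy else as.matrix(triangle)
  ctr <- colMeans(xy)
  X <- sweep(xy, 2, ctr)
  G <- crossprod(X) / 3
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  a <- (sqrt(ev[1]) - sqrt(ev[2])) / (sqrt(ev[1]) + sqrt(ev[2]))
  sides <- sqrt(c(sum((xy[2, ] - xy[3, ])^2), sum((xy[1, ] - xy[3, ])^2),
                  sum((xy[1, ] - xy[2, ])^2)))
  degenerate <- min(sides) <= 1e-12 * max(sides) ||
    abs(signed_area(xy)) <= 1e-12 * max(sides)^2
  ang <- tryCatch(triangle_from_tensions(sides[1], sides[2], sides[3])$angles,
                  error = function(e) NULL)
  if (is.null(ang)) {
    return(list(a = 1, b = 1, theta_max = pi, degenerate = TRUE))
  }
  theta_max <- max(ang)
  list(a = a, b = -cos(theta_max), theta_max = theta_max,
       degenerate = degenerate)
}

#' LTC shape statistics over a mesh region
#'
#' Computes the tension triangle at every interior tri-cellular vertex in
#' the region (from the inferred vertex tensions) and summarizes the
#' shape distribution: 2D histogram over (a, b), the bridge fraction
#' (share of obtuse triangles, b > 0) and the median b.
#'
#' @param mesh a \code{cell_mesh}.
#' @param fit a \code{tension_fit} for the mesh.
#' @param region optional region label; only vertices all of whose
#'   incident cells carry this label are used. NULL = whole interior.
#' @param breaks number of histogram bins per axis.
#' @return object of class \code{ltc_stats}: per-vertex table
#'   (vertex_id, a, b, theta_max_deg), \code{bridge_fraction},
#'   \code{median_b}, and the histogram (\code{a_breaks},
#'   \code{b_breaks}, \code{counts}).
#' @export
ltc_statistics <- function(mesh, fit = infer_tensions(mesh), region = NULL,
                           breaks = 24) {
  verts <- unique(fit$vertices$vertex_id)
  if (!is.null(region)) {
    keep <- vapply(verts, function(v)
      all(mesh$labels[mesh$vertex_cells[[v]]] == region), logical(1))
    verts <- verts[keep]
  }
  if (!length(verts)) stop("no valid tension triangles in region")
  rows <- lapply(verts, function(v) {
    tens <- fit$vertices$tension[fit$vertices$vertex_id == v]
    tri <- triangle_from_tensions(tens[1], tens[2], tens[3])
    sh <- ltc_shape(tri)
    data.frame(vertex_id = v, a = sh$a, b = sh$b,
               theta_max_deg = sh$theta_max * 180 / pi)
  })
  tab <- do.call(rbind, rows)
  ltc_stats_from_table(tab, breaks)
}

ltc_stats_from_table <- function(tab, breaks = 24) {
  a_breaks <- seq(0, 1, length.out = breaks + 1)
  b_breaks <- seq(-0.5, 1, length.out = breaks + 1)
  ai <- pmin(breaks, pmax(1, findInterval(tab$a, a_breaks, rightmost.closed = TRUE)))
  bi <- pmin(breaks, pmax(1, findInterval(tab$b, b_breaks, rightmost.closed = TRUE)))
  counts <- matrix(0L, breaks, breaks)
  for (k in seq_len(nrow(tab))) {
    counts[ai[k], bi[k]] <- counts[ai[k], bi[k]] + 1L
  }
  structure(list(table = tab,
                 bridge_fraction = mean(tab$b > 0),
                 median_b = stats::median(tab$b),
                 a_breaks = a_breaks, b_breaks = b_breaks, counts = counts),
            class = "ltc_stats")
}

#' @export
print.ltc_stats <- function(x, ...) {
  cat("ltc_stats over", nrow(x$table), "tension triangles\n")
  cat("  bridge fraction (b > 0):", signif(x$bridge_fraction, 4), "\n")
  cat("  median b:", signif(x$median_b, 4), "\n")
  invisible(x)
}

#' LTC statistics of a random Delaunay triangulation
#'
#' The fully disordered baseline: Delaunay triangulation of n uniform
#' random points in the unit square, boundary (convex-hull-incident)
#' triangles excluded, triangle shapes summarized as in
#' \code{\link{ltc_statistics}}. Seed-reproducible.
#'
#' @param n_points number of points (>= 10).
#' @param seed integer RNG seed.
#' @param breaks histogram bins per axis.
#' @return an \code{ltc_stats} object.
#' @export
random_delaunay_baseline <- function(n_points, seed = 1L, breaks = 24) {
  if (n_points < 10L) stop("need at least 10 points")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pts <- cbind(stats::runif(n_points), stats::runif(n_points))
  dt <- delaunay_triangulation(pts)
  hull_pts <- unique(as.vector(dt$hull))
  interior <- !apply(dt$triangles, 1, function(tr) any(tr %in% hull_pts))
  tri <- dt$triangles[interior, , drop = FALSE]
  rows <- lapply(seq_len(nrow(tri)), function(k) {
    sh <- ltc_shape(pts[tri[k, ], ])
    data.frame(vertex_id = as.character(k), a = sh$a, b = sh$b,
               theta_max_deg = sh$theta_max * 180 / pi)
  })
  ltc_stats_from_table(do.call(rbind, rows), breaks)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Shipped calibration constants
#'
#' \code{l0}: global tension-to-length scale (micrometres) converting
#' relative tensions to reference interface lengths via the
#' Voronoi construction. \code{mean_initial_edge}: mean interface length
#' at the reference (initial) timepoint used for the calibration.
#' Both are overridable arguments wherever they enter.
#' @export
tigon_constants <- list(l0 = 4.2, mean_initial_edge = 3.5)
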