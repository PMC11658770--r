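# Data model for planar, tracked polygonal cell meshes.
#
# A mesh is stored non-redundantly as vertices + per-cell vertex loops
# (counter-clockwise); interfaces are derived from shared loop edges.
# Cells bordering the outside carry the boundary sentinel NA in the
# derived interface table.

BOUNDARY <- NA_integer_

#' Construct a cell mesh
#'
#' Builds a validated planar cell mesh from vertex coordinates and
#' counter-clockwise cell vertex loops. Interfaces (cell-cell edges) are
#' derived from loop edges shared by two cells; loop edges belonging to a
#' single cell are boundary interfaces. All interfaces are straight
#' segments between their end vertices.
#'
#' @param vertices numeric matrix (n x 2) of vertex positions in micrometres;
#'   rownames (or integer row indices) are vertex ids.
#' @param cells named list; each element is an integer vector of vertex ids
#'   forming a simple polygon. Names are cell (tracking) ids.
#' @param time frame time in minutes.
#' @param labels optional named character vector of region labels per cell.
#' @param validate logical; run invariant checks (simple polygons, positive
#'   area, angle sums) and fail with the offending entity named.
#' @return an object of class \code{cell_mesh} with components
#'   \code{vertices}, \code{cells}, \code{labels}, \code{time},
#'   \code{interfaces} (data frame: id, v1, v2, cell_a, cell_b, length,
#'   ex, ey), \code{vertex_cells}, \code{vertex_degree},
#'   \code{fourfold} (ids of vertices with >= 4 interfaces, flagged as
#'   transient), \code{boundary_cells}.
#' @export
cell_mesh <- function(vertices, cells, time = 0, labels = NULL, validate = TRUE) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L) stop("vertices must be an n x 2 matrix")
  if (is.null(rownames(vertices))) rownames(vertices) <- seq_len(nrow(vertices))
  if (anyDuplicated(rownames(vertices))) stop("duplicate vertex ids")
  if (!all(is.finite(vertices))) stop("non-finite vertex coordinates")
  if (is.null(names(cells))) names(cells) <- seq_along(cells)
  if (anyDuplicated(names(cells))) stop("duplicate cell ids")
  if (is.null(labels)) {
    labels <- rep("", length(cells)); names(labels) <- names(cells)
  }

  vid <- rownames(vertices)
  cells <- lapply(cells, function(loop) as.character(loop))
  bad <- vapply(cells, function(loop) !all(loop %in% vid), logical(1))
  if (any(bad)) stop("cell ", names(cells)[bad][1], " references unknown vertex")

  # orient all loops counter-clockwise
  cells <- lapply(cells, function(loop) {
    if (signed_area(vertices[loop, , drop = FALSE]) < 0) rev(loop) else loop
  })

  if (validate) {
    for (cid in names(cells)) {
      loop <- cells[[cid]]
      if (length(loop) < 3L) stop("cell ", cid, ": fewer than 3 vertices")
      if (anyDuplicated(loop)) stop("cell ", cid, ": repeated vertex in loop")
      poly <- vertices[loop, , drop = FALSE]
      if (signed_area(poly) <= 0) stop("cell ", cid, ": non-positive area")
      if (!polygon_is_simple(poly)) stop("cell ", cid, ": self-intersecting vertex loop")
    }
  }

  m <- structure(list(vertices = vertices, cells = cells, labels = labels,
                      time = time), class = "cell_mesh")
  m <- derive_interfaces(m)
  if (validate) validate_mesh(m)
  m
}

signed_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  i2 <- c(seq_len(nrow(poly))[-1], 1L)
  sum(x * y[i2] - x[i2] * y) / 2
}

polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  i2 <- c(seq_len(nrow(poly))[-1], 1L)
  cr <- x * y[i2] - x[i2] * y
  a <- sum(cr) / 2
  c(sum((x + x[i2]) * cr), sum((y + y[i2]) * cr)) / (6 * a)
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) && ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  if (n < 4L) return(TRUE)
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      i2 <- i + 1L; j2 <- if (j == n) 1L else j + 1L
      if (segments_intersect(poly[i, ], poly[i2, ], poly[j, ], poly[j2, ])) return(FALSE)
    }
  }
  TRUE
}

derive_interfaces <- function(m) {
  # collect directed loop edges; cell on the LEFT of v1 -> v2 (CCW loops)
  e_from <- character(0); e_to <- character(0); e_cell <- character(0)
  for (cid in names(m$cells)) {
    loop <- m$cells[[cid]]
    nxt <- c(loop[-1], loop[1])
    e_from <- c(e_from, loop); e_to <- c(e_to, nxt)
    e_cell <- c(e_cell, rep(cid, length(loop)))
  }
  key <- ifelse(e_from < e_to, paste(e_from, e_to), paste(e_to, e_from))
  sp <- split(seq_along(key), key)
  n_if <- length(sp)
  v1 <- character(n_if); v2 <- character(n_if)
  ca <- character(n_if); cb <- character(n_if)
  k <- 0L
  for (idx in sp) {
    k <- k + 1L
    if (length(idx) > 2L) {
      stop("interface ", key[idx[1]], " shared by more than two cells")
    }
    i1 <- idx[1]
    v1[k] <- e_from[i1]; v2[k] <- e_to[i1]; ca[k] <- e_cell[i1]
    cb[k] <- if (length(idx) == 2L) e_cell[idx[2]] else NA_character_
  }
  d <- m$vertices[v2, , drop = FALSE] - m$vertices[v1, , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  ifc <- data.frame(id = seq_len(n_if), v1 = v1, v2 = v2,
                    cell_a = ca, cell_b = cb,
                    length = len, ex = d[, 1], ey = d[, 2],
                    stringsAsFactors = FALSE)
  rownames(ifc) <- NULL
  m$interfaces <- ifc

  vc <- split(c(ifc$id, ifc$id), c(ifc$v1, ifc$v2))
  deg <- integer(nrow(m$vertices)); names(deg) <- rownames(m$vertices)
  deg[names(vc)] <- lengths(vc)
  m$vertex_degree <- deg
  m$vertex_interfaces <- vc

  # cells incident to each vertex
  cv <- list()
  for (cid in names(m$cells)) for (v in m$cells[[cid]]) cv[[v]] <- c(cv[[v]], cid)
  m$vertex_cells <- cv

  m$boundary_cells <- unique(ifc$cell_a[is.na(ifc$cell_b)])
  # interior vertex: all incident interfaces are cell-cell interfaces
  on_boundary <- unique(c(ifc$v1[is.na(ifc$cell_b)], ifc$v2[is.na(ifc$cell_b)]))
  m$interior_vertices <- setdiff(names(vc)[lengths(vc) >= 3L], on_boundary)
  m$fourfold <- m$interior_vertices[deg[m$interior_vertices] >= 4L]
  m$centroids <- t(vapply(m$cells, function(loop)
    polygon_centroid(m$vertices[loop, , drop = FALSE]), numeric(2)))
  m
}

validate_mesh <- function(m) {
  zero <- m$interfaces$length <= 0
  if (any(zero)) {
    stop("interface ", m$interfaces$id[zero][1], " (",
         m$interfaces$v1[zero][1], "-", m$interfaces$v2[zero][1],
         ") has non-positive length")
  }
  for (v in m$interior_vertices) {
    s <- sum(vertex_angles(m, v))
    if (abs(s - 2 * pi) > 1e-6) {
      stop("vertex ", v, ": interface angles sum to ", s, ", not 2*pi")
    }
  }
  invisible(m)
}

#' Angles between cyclically adjacent interfaces at a vertex
#'
#' Returns the angles (radians) between consecutive interfaces around a
#' vertex, ordered counter-clockwise. For an interior tri-cellular vertex
#' the three angles are the vertex angles whose complements are the
#' internal angles of the dual tension triangle. The attribute
#' \code{"interfaces"} gives the interface id preceding each angle and
#' \code{"cells"} the cell lying inside each angular sector.
#'
#' @param mesh a \code{cell_mesh}.
#' @param vertex vertex id.
#' @return numeric vector of angles summing to \code{2*pi}.
#' @export
vertex_angles <- function(mesh, vertex) {
  vertex <- as.character(vertex)
  ids <- mesh$vertex_interfaces[[vertex]]
  if (is.null(ids) || length(ids) < 3L) {
    stop("vertex ", vertex, " has degree < 3")
  }
  ifc <- mesh$interfaces[match(ids, mesh$interfaces$id), ]
  # outgoing direction of each interface
  sgn <- ifelse(ifc$v1 == vertex, 1, -1)
  dx <- sgn * ifc$ex; dy <- sgn * ifc$ey
  th <- atan2(dy, dx)
  o <- order(th)
  th <- th[o]; ids <- ids[o]; ifc <- ifc[o, ]
  ang <- diff(c(th, th[1] + 2 * pi))
  # cell in the sector between interface k and k+1: the cell to the LEFT of
  # the outgoing direction of interface k
  sect <- ifelse(ifc$v1 == vertex, ifc$cell_a, ifc$cell_b)
  attr(ang, "interfaces") <- ids
  attr(ang, "cells") <- sect
  attr(ang, "directions") <- cbind(cos(th), sin(th))
  ang
}

#' Cell quartet and flanking interfaces of an interior edge
#'
#' For an interior interface whose two end vertices are tri-cellular,
#' returns the kite neighborhood: the two cells sharing the edge, the two
#' cells touching exactly one end vertex each, and the four flanking
#' interfaces.
#'
#' @param mesh a \code{cell_mesh}.
#' @param interface interface id (row of \code{mesh$interfaces}).
#' @return list with \code{edge_cells} (the adjacent pair),
#'   \code{end_cells} (cells at vertex \code{v1} and \code{v2}),
#'   \code{flanks} (interface ids at \code{v1} then \code{v2}) and the end
#'   vertex ids.
#' @export
quartet_of_edge <- function(mesh, interface) {
  row <- mesh$interfaces[match(interface, mesh$interfaces$id), ]
  if (is.na(row$cell_b)) stop("interface ", interface, " is a boundary edge")
  for (v in c(row$v1, row$v2)) {
    if (!(v %in% mesh$interior_vertices)) {
      stop("interface ", interface, ": end vertex ", v, " is not interior")
    }
    if (mesh$vertex_degree[[v]] != 3L) {
      stop("interface ", interface, ": end vertex ", v, " has degree ",
           mesh$vertex_degree[[v]])
    }
  }
  end_cell <- function(v) {
    setdiff(mesh$vertex_cells[[v]], c(row$cell_a, row$cell_b))
  }
  c1 <- end_cell(row$v1); c2 <- end_cell(row$v2)
  if (length(c1) != 1L || length(c2) != 1L) {
    stop("interface ", interface, ": end vertices not tri-cellular")
  }
  flanks1 <- setdiff(mesh$vertex_interfaces[[row$v1]], row$id)
  flanks2 <- setdiff(mesh$vertex_interfaces[[row$v2]], row$id)
  list(interface = row$id,
       edge_cells = c(row$cell_a, row$cell_b),
       end_cells = c(c1, c2),
       v1 = row$v1, v2 = row$v2,
       flanks = c(flanks1, flanks2))
}

#' @export
print.cell_mesh <- function(x, ...) {
  ifc <- x$interfaces
  cat("cell_mesh: ", length(x$cells), " cells, ", nrow(x$vertices),
      " vertices, ", nrow(ifc), " interfaces (",
      sum(!is.na(ifc$cell_b)), " interior), t = ", x$time, " min\n", sep = "")
  if (length(x$fourfold)) {
    cat("  flagged fourfold/rosette vertices:", length(x$fourfold), "\n")
  }
  invisible(x)
}

#' @export
summary.cell_mesh <- function(object, ...) {
  ifc <- object$interfaces
  interior <- ifc[!is.na(ifc$cell_b), ]
  out <- list(n_cells = length(object$cells),
              n_vertices = nrow(object$vertices),
              n_interfaces = nrow(ifc),
              n_interior_interfaces = nrow(interior),
              n_boundary_cells = length(object$boundary_cells),
              n_fourfold = length(object$fourfold),
              mean_interface_length = mean(interior$length),
              time = object$time)
  class(out) <- "summary.cell_mesh"
  out
}

#' @export
print.summary.cell_mesh <- function(x, ...) {
  cat("cell_mesh at t =", x$time, "min\n")
  cat("  cells:", x$n_cells, "(", x$n_boundary_cells, "on boundary )\n")
  cat("  vertices:", x$n_vertices, " fourfold:", x$n_fourfold, "\n")
  cat("  interfaces:", x$n_interfaces, "(", x$n_interior_interfaces,
      "interior ), mean length", signif(x$mean_interface_length, 4), "um\n")
  invisible(x)
}

#' @export
plot.cell_mesh <- function(x, col = NA, lwd = 1, ...) {
  plot(NA, xlim = range(x$vertices[, 1]), ylim = range(x$vertices[, 2]),
       asp = 1, xlab = "x (um)", ylab = "y (um)", ...)
  for (loop in x$cells) {
    poly <- x$vertices[loop, , drop = FALSE]
    graphics::polygon(poly[, 1], poly[, 2], border = "grey30", col = col, lwd = lwd)
  }
  invisible(x)
}

#' Construct a tracked sequence of meshes
#'
#' @param frames list of \code{cell_mesh} objects with strictly increasing
#'   frame times; cell ids are persistent tracking ids.
#' @return object of class \code{tracked_sequence}.
#' @export
tracked_sequence <- function(frames) {
  if (!length(frames)) stop("empty frame list")
  ok <- vapply(frames, inherits, logical(1), "cell_mesh")
  if (!all(ok)) stop("all frames must be cell_mesh objects")
  times <- vapply(frames, `[[`, numeric(1), "time")
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  structure(list(frames = frames, times = times), class = "tracked_sequence")
}

#' @export
print.tracked_sequence <- function(x, ...) {
  cat("tracked_sequence:", length(x$frames), "frames, t =",
      x$times[1], "...", x$times[length(x$times)], "min\n")
  invisible(x)
}

#' @export
length.tracked_sequence <- function(x) length(x$frames)

#' Euler characteristic check for a bounded planar mesh
#'
#' V - E + F must equal 2, counting cells plus the outer face.
#' @param mesh a \code{cell_mesh}.
#' @return integer Euler characteristic.
#' @export
euler_characteristic <- function(mesh) {
  nrow(mesh$vertices) - nrow(mesh$interfaces) + (length(mesh$cells) + 1L)
}

#' Interior cell-cell adjacency pairs
#'
#' @param mesh a \code{cell_mesh}.
#' @return two-column character matrix of sorted cell-id pairs, one row per
#'   interior interface.
#' @export
adjacency_pairs <- function(mesh) {
  ifc <- mesh$interfaces[!is.na(mesh$interfaces$cell_b), ]
  a <- pmin(ifc$cell_a, ifc$cell_b); b <- pmax(ifc$cell_a, ifc$cell_b)
  cbind(a, b)
}

#' Per-interface CSV export table
#'
#' @param mesh a \code{cell_mesh}.
#' @param frame frame index recorded in the table.
#' @return data frame with frame, edge id, adjacent cells, length and
#'   orientation angle in degrees.
#' @export
interface_table <- function(mesh, frame = 1L) {
  ifc <- mesh$interfaces
  data.frame(frame = frame, edge_id = ifc$id,
             cell_a = ifc$cell_a, cell_b = ifc$cell_b,
             length_um = ifc$length,
             angle_deg = atan2(ifc$ey, ifc$ex) * 180 / pi,
             stringsAsFactors = FALSE)
}
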