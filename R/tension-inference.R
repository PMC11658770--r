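# Relative cortical tension inference from vertex angles.
#
# At a tri-cellular vertex the three cortical tension vectors balance, so
# they close into a triangle whose internal angles are complementary
# (pi minus) to the vertex angles. The law of sines then gives each
# tension as the sine of the vertex angle between the OTHER two
# interfaces. Per-edge relative tension uses the kite of the two tension
# triangles at the edge's end vertices.

#' Relative tensions at a tri-cellular vertex from its angles
#'
#' Given the three vertex angles (radians, summing to \code{2*pi}),
#' returns the relative tensions on the three incident interfaces,
#' normalized to mean 1. Tension i is proportional to the sine of the
#' angle between the other two interfaces.
#'
#' @param angles numeric length-3, vertex angles in radians in the same
#'   (cyclic) order as the interfaces; angle k lies between interfaces
#'   k and k+1.
#' @return numeric length-3 of tensions, mean 1, ordered like the
#'   interfaces; tension for interface k is driven by the angle opposite
#'   it (the one not adjacent to interface k).
#' @export
infer_vertex_tensions <- function(angles) {
  if (length(angles) != 3L) stop("exactly three vertex angles required")
  if (abs(sum(angles) - 2 * pi) > 1e-6) stop("vertex angles must sum to 2*pi")
  if (any(angles >= pi) || any(angles <= 0)) {
    stop("inference undefined: vertex angle outside (0, 180) degrees")
  }
  # angle k is between interfaces k and k+1 (cyclic); the angle opposite
  # interface i (between the other two interfaces) is angle k with
  # k = i + 1 (cyclic): interface 1 <- angle 2 (between 2, 3), etc.
  opp <- c(2L, 3L, 1L)
  tens <- sin(angles)[opp]
  tens / mean(tens)
}

#' Relative tension of one interface from its kite neighborhood
#'
#' Applies the law of sines to the two tension triangles at the edge's
#' end vertices (the tension kite). Both triangles share the side dual to
#' the central interface; fixing that shared side to 1 expresses the four
#' flanking tensions in units of the central tension, and the relative
#' tension is the central tension with the arithmetic mean of the four
#' flanking tensions normalized to 1.
#'
#' @param mesh a \code{cell_mesh}.
#' @param interface interface id.
#' @return list with \code{T_rel}, \code{consistency} (relative
#'   disagreement of the two per-triangle estimates; zero on integrable
#'   meshes), and the kite geometry used (\code{kite}).
#' @export
infer_edge_tension <- function(mesh, interface) {
  q <- quartet_of_edge(mesh, interface)
  ratios <- function(v) {
    ang <- vertex_angles(mesh, v)
    ids <- attr(ang, "interfaces")
    if (any(ang >= pi) || any(ang <= 0)) {
      stop("inference undefined at vertex ", v)
    }
    tens <- infer_vertex_tensions(ang)
    names(tens) <- ids
    tens / tens[[as.character(q$interface)]]   # central tension = 1
  }
  r1 <- ratios(q$v1); r2 <- ratios(q$v2)
  fl1 <- r1[setdiff(names(r1), as.character(q$interface))]
  fl2 <- r2[setdiff(names(r2), as.character(q$interface))]
  flanks <- c(fl1, fl2)
  T_rel <- 1 / mean(flanks)
  est1 <- 1 / mean(fl1); est2 <- 1 / mean(fl2)
  consistency <- abs(est1 - est2) / mean(c(est1, est2))
  kite <- kite_from_tensions(T_rel * 1, T_rel * fl1[[1]], T_rel * fl1[[2]],
                             T_rel * fl2[[1]], T_rel * fl2[[2]])
  list(T_rel = T_rel, consistency = consistency, kite = kite,
       flank_interfaces = as.integer(names(flanks)))
}

#' Infer relative tensions on a whole mesh
#'
#' Runs the per-vertex and per-edge (kite) tension inference over all
#' interior tri-cellular vertices and all interior edges whose end
#' vertices are valid. Edges touching fourfold vertices, the mesh
#' boundary, or vertices with angles >= 180 degrees are skipped and
#' enumerated in the skip log.
#'
#' @param mesh a \code{cell_mesh}.
#' @return object of class \code{tension_fit} with components
#'   \code{edges} (data frame: edge_id, cell_a, cell_b, length_um, T_rel,
#'   consistency), \code{vertices} (data frame: vertex_id, interface id,
#'   tension), \code{skipped} (data frame: edge_id, reason) and
#'   \code{mesh}.
#' @export
infer_tensions <- function(mesh) {
  ifc <- mesh$interfaces
  interior <- ifc[!is.na(ifc$cell_b), ]
  res <- vector("list", nrow(interior))
  skip <- list()
  for (k in seq_len(nrow(interior))) {
    e <- interior$id[k]
    out <- tryCatch(infer_edge_tension(mesh, e), error = function(err) err)
    if (inherits(out, "error")) {
      skip[[length(skip) + 1L]] <- data.frame(edge_id = e,
                                              reason = conditionMessage(out))
    } else {
      res[[k]] <- data.frame(edge_id = e,
                             cell_a = interior$cell_a[k],
                             cell_b = interior$cell_b[k],
                             length_um = interior$length[k],
                             T_rel = out$T_rel,
                             consistency = out$consistency)
    }
  }
  edges <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(edges)) {
    edges <- data.frame(edge_id = integer(0), cell_a = character(0),
                        cell_b = character(0), length_um = numeric(0),
                        T_rel = numeric(0), consistency = numeric(0))
  }
  vres <- list()
  for (v in mesh$interior_vertices) {
    if (mesh$vertex_degree[[v]] != 3L) next
    ang <- vertex_angles(mesh, v)
    if (any(ang >= pi)) next
    tens <- infer_vertex_tensions(ang)
    vres[[v]] <- data.frame(vertex_id = v,
                            interface = attr(ang, "interfaces"),
                            tension = as.numeric(tens))
  }
  vertices <- if (length(vres)) do.call(rbind, vres) else
    data.frame(vertex_id = character(0), interface = integer(0),
               tension = numeric(0))
  rownames(vertices) <- NULL
  skipped <- if (length(skip)) do.call(rbind, skip) else
    data.frame(edge_id = integer(0), reason = character(0))
  structure(list(edges = edges, vertices = vertices, skipped = skipped,
                 mesh = mesh),
            class = "tension_fit")
}

#' @export
print.tension_fit <- function(x, ...) {
  cat("tension_fit:", nrow(x$edges), "edges inferred,",
      nrow(x$skipped), "skipped\n")
  if (nrow(x$edges)) {
    cat("  T_rel: ", paste(signif(stats::quantile(x$edges$T_rel,
        c(0.05, 0.5, 0.95)), 4), collapse = " / "),
        " (5% / median / 95%)\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.tension_fit <- function(object, ...) {
  out <- list(n_edges = nrow(object$edges),
              n_skipped = nrow(object$skipped),
              T_rel = summary(object$edges$T_rel),
              consistency = summary(object$edges$consistency))
  class(out) <- "summary.tension_fit"
  out
}

#' @export
print.summary.tension_fit <- function(x, ...) {
  cat("tension_fit over", x$n_edges, "interior edges (",
      x$n_skipped, "skipped )\n")
  cat("relative tension:\n"); print(x$T_rel)
  cat("kite consistency score:\n"); print(x$consistency)
  invisible(x)
}

#' @export
plot.tension_fit <- function(x, palette = grDevices::hcl.colors(64, "Viridis"),
                             ...) {
  m <- x$mesh
  plot(NA, xlim = range(m$vertices[, 1]), ylim = range(m$vertices[, 2]),
       asp = 1, xlab = "x (um)", ylab = "y (um)", ...)
  rng <- range(x$edges$T_rel)
  idx <- match(x$edges$edge_id, m$interfaces$id)
  colv <- palette[pmax(1, ceiling((x$edges$T_rel - rng[1]) /
                                  max(rng[2] - rng[1], 1e-12) * length(palette)))]
  for (k in seq_len(nrow(x$edges))) {
    e <- m$interfaces[idx[k], ]
    p1 <- m$vertices[e$v1, ]; p2 <- m$vertices[e$v2, ]
    graphics::segments(p1[1], p1[2], p2[1], p2[2], col = colv[k], lwd = 2)
  }
  invisible(x)
}

#' Nematic tension anisotropy at a vertex
#'
#' Builds the tension-weighted second-moment tensor of the unit interface
#' directions, sigma = sum_i T_i e_i (x) e_i, removes the isotropic part
#' (Q = sigma - Tr(sigma)/2 I) and returns the anisotropy magnitude
#' (the absolute eigenvalue of the traceless part) and the orientation of
#' the positive eigenvector in [0, pi).
#'
#' @param tensions numeric length-3 relative tensions.
#' @param directions 3 x 2 matrix of unit interface directions (outgoing
#'   from the vertex), rows matching \code{tensions}.
#' @return list with \code{m}, \code{theta} (radians in [0, pi)), and the
#'   traceless tensor \code{Q}.
#' @export
vertex_anisotropy <- function(tensions, directions) {
  u <- directions / sqrt(rowSums(directions^2))
  sxx <- sum(tensions * u[, 1]^2)
  syy <- sum(tensions * u[, 2]^2)
  sxy <- sum(tensions * u[, 1] * u[, 2])
  q1 <- (sxx - syy) / 2; q2 <- sxy
  m <- sqrt(q1^2 + q2^2)
  theta <- (atan2(q2, q1) / 2) %% pi
  list(m = m, theta = theta, Q = matrix(c(q1, q2, q2, -q1), 2, 2))
}

#' Grid-averaged tension anisotropy field
#'
#' Averages the per-vertex nematic tensors (not the angles) on a square
#' grid anchored at the mesh bounding-box origin, then re-extracts the
#' magnitude and orientation per grid cell.
#'
#' @param mesh a \code{cell_mesh}.
#' @param fit a \code{tension_fit} (defaults to running
#'   \code{\link{infer_tensions}} on \code{mesh}).
#' @param spacing grid spacing in micrometres (default 20).
#' @return data frame with grid indices \code{gx}, \code{gy}, cell-centre
#'   coordinates, anisotropy magnitude \code{m}, orientation
#'   \code{theta_deg} (NA where \code{m} is numerically zero), and the
#'   contributing vertex \code{count}.
#' @export
grid_average_anisotropy <- function(mesh, fit = infer_tensions(mesh),
                                    spacing = 20) {
  if (spacing <= 0) stop("spacing must be positive")
  verts <- unique(fit$vertices$vertex_id)
  if (!length(verts)) stop("no inferred vertices")
  origin <- c(min(mesh$vertices[, 1]), min(mesh$vertices[, 2]))
  rows <- lapply(verts, function(v) {
    ang <- vertex_angles(mesh, v)
    tens <- fit$vertices$tension[fit$vertices$vertex_id == v]
    an <- vertex_anisotropy(tens, attr(ang, "directions"))
    p <- mesh$vertices[v, ]
    data.frame(gx = floor((p[1] - origin[1]) / spacing),
               gy = floor((p[2] - origin[2]) / spacing),
               q1 = an$Q[1, 1], q2 = an$Q[1, 2])
  })
  tab <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(q1, q2) ~ gx + gy, data = tab, FUN = mean)
  cnt <- stats::aggregate(n ~ gx + gy, data = cbind(tab, n = 1), FUN = sum)
  names(cnt)[3] <- "count"
  out <- merge(agg, cnt, by = c("gx", "gy"))
  out$m <- sqrt(out$q1^2 + out$q2^2)
  theta <- (atan2(out$q2, out$q1) / 2) %% pi
  out$theta_deg <- ifelse(out$m > 1e-12, theta * 180 / pi, NA_real_)
  out$x <- origin[1] + (out$gx + 0.5) * spacing
  out$y <- origin[2] + (out$gy + 0.5) * spacing
  out[, c("gx", "gy", "x", "y", "m", "theta_deg", "count")]
}
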