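# Ground-truth synthetic data: tension patterns, Voronoi realization of
# meshes from tension triangulations, and tracked T1 sequences embedding
# the quartet-model dynamics in a lattice surround.

#' Honeycomb-family mesh with prescribed vertex angles
#'
#' Constructs a periodic (bounded) honeycomb-like cell array with
#' vertical "central-class" edges of length \code{lc} and slanted flank
#' edges of length \code{lf} at angle \code{theta} from the x axis.
#' \code{theta = 30} degrees with \code{lc = lf} gives the regular
#' hexagonal lattice; larger \code{theta} concentrates tension on the
#' vertical (DV-oriented) edges. The implied relative tension on the
#' vertical edges is \code{2 * sin(theta)}.
#'
#' The named patterns map onto this family:
#' \describe{
#'   \item{uniform}{theta = 30 deg: all tensions equal.}
#'   \item{anisotropic}{theta = asin((1 + eps) / 2): vertical (DV) edge
#'     tensions scaled by 1 + eps.}
#'   \item{alternating_bridge}{theta = 45 + 20 * eps deg: obtuse tension
#'     triangles, every vertical edge a tension bridge (b > 0).}
#'   \item{cable}{theta = 30 - 15 * eps deg: acute tension triangles,
#'     flank chains form tension cables (b < 0).}
#' }
#'
#' @param pattern one of "uniform", "anisotropic", "alternating_bridge",
#'   "cable".
#' @param nx,ny cells per row / number of rows.
#' @param eps pattern amplitude in [0, 1].
#' @param l edge length scale, micrometres.
#' @param time frame time.
#' @return a \code{cell_mesh} with ground-truth attributes
#'   \code{"truth"}: per-edge relative tension of vertical
#'   (\code{T_rel_vertical}) and slant edges, and the vertex angles.
#' @export
pattern_mesh <- function(pattern = c("uniform", "anisotropic",
                                     "alternating_bridge", "cable"),
                         nx = 6, ny = 6, eps = 0.3, l = 3.5, time = 0) {
  pattern <- match.arg(pattern)
  theta <- switch(pattern,
    uniform = pi / 6,
    anisotropic = asin(pmin((1 + eps) / 2, 0.99)),
    alternating_bridge = (45 + 20 * pmin(eps, 1)) * pi / 180,
    cable = (30 - 15 * pmin(eps, 1)) * pi / 180)
  honeycomb_mesh(nx, ny, lc = l, lf = l, theta = theta, time = time,
                 pattern = pattern)
}

honeycomb_mesh <- function(nx, ny, lc, lf, theta, time = 0,
                           pattern = "uniform") {
  w <- lf * cos(theta); ls <- lf * sin(theta)
  # corner positions are integer combinations x = kx * w,
  # y = m * lc/2 + n * ls; dedup on the exact integer key
  corner_key <- rbind(c(-1, -1, 0), c(-1, 1, 0), c(0, 1, 1),
                      c(1, 1, 0), c(1, -1, 0), c(0, -1, -1))
  vmap <- new.env(parent = emptyenv())
  vxy <- list(); vcount <- 0L
  cells <- list()
  for (j in seq_len(ny) - 1L) {
    for (i in seq_len(nx) - 1L) {
      base_key <- c(2L * i + j %% 2L, 2L * j, j)
      loop <- character(6)
      for (c6 in 1:6) {
        key <- base_key + corner_key[c6, ]
        kk <- paste(key, collapse = " ")
        id <- vmap[[kk]]
        if (is.null(id)) {
          vcount <- vcount + 1L
          id <- as.character(vcount)
          vmap[[kk]] <- id
          vxy[[vcount]] <- c(key[1] * w, key[2] * lc / 2 + key[3] * ls)
        }
        loop[c6] <- id
      }
      cells[[paste0("c", i, "_", j)]] <- loop
    }
  }
  verts <- do.call(rbind, vxy)
  rownames(verts) <- as.character(seq_len(vcount))
  m <- cell_mesh(verts, cells, time = time)
  attr(m, "truth") <- list(pattern = pattern, theta = theta,
                           T_rel_vertical = 2 * sin(theta),
                           vertex_angles_deg = c(180 - 2 * theta * 180 / pi,
                                                 90 + theta * 180 / pi,
                                                 90 + theta * 180 / pi))
  m
}

#' Generate a tension triangulation with a prescribed pattern
#'
#' Produces a planar triangulation whose edge lengths are the target
#' relative tensions. Lattice patterns are rows of isosceles triangles
#' with base \code{2 * sin(theta)} and legs 1 (the duals of
#' \code{\link{pattern_mesh}} configurations); the random pattern is the
#' Delaunay triangulation of uniformly random points.
#'
#' @param pattern "uniform", "anisotropic", "alternating_bridge",
#'   "cable" or "random".
#' @param nx,ny lattice extent (or \code{nx * ny} random points).
#' @param eps pattern amplitude.
#' @param seed RNG seed (random pattern).
#' @return list with \code{points} (n x 2), \code{triangulation}
#'   (Delaunay structure), and \code{edge_tensions} (data frame i, j,
#'   tension).
#' @export
make_tension_triangulation <- function(pattern = "uniform", nx = 10, ny = 10,
                                       eps = 0.3, seed = 1L) {
  if (pattern == "random") {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    pts <- cbind(stats::runif(nx * ny, 0, nx), stats::runif(nx * ny, 0, ny))
    dt <- delaunay_triangulation(pts)
  } else {
    theta <- switch(pattern,
      uniform = pi / 6,
      anisotropic = asin(pmin((1 + eps) / 2, 0.99)),
      alternating_bridge = (45 + 20 * pmin(eps, 1)) * pi / 180,
      cable = (30 - 15 * pmin(eps, 1)) * pi / 180)
    Tc <- 2 * sin(theta); h <- cos(theta)
    pts <- do.call(rbind, lapply(seq_len(ny) - 1L, function(j) {
      cbind(seq_len(nx) * Tc + (j %% 2) * Tc / 2, j * h)
    }))
    # combinatorial row triangulation (the intended isosceles tiling is
    # non-Delaunay for obtuse patterns, so it is built explicitly)
    idx <- function(i, j) (j - 1L) * nx + i
    tris <- list()
    for (j in seq_len(ny - 1L)) {
      odd <- (j - 1L) %% 2L == 1L    # row j has offset if odd (0-based)
      for (i in seq_len(nx - 1L)) {
        if (!odd) {
          tris[[length(tris) + 1L]] <- c(idx(i, j), idx(i + 1L, j), idx(i, j + 1L))
          tris[[length(tris) + 1L]] <- c(idx(i, j + 1L), idx(i + 1L, j + 1L),
                                         idx(i + 1L, j))
        } else {
          tris[[length(tris) + 1L]] <- c(idx(i, j), idx(i + 1L, j),
                                         idx(i + 1L, j + 1L))
          tris[[length(tris) + 1L]] <- c(idx(i, j + 1L), idx(i + 1L, j + 1L),
                                         idx(i, j))
        }
      }
    }
    T <- do.call(rbind, tris)
    E <- rbind(T[, c(1, 2)], T[, c(2, 3)], T[, c(3, 1)])
    ekey <- paste(pmin(E[, 1], E[, 2]), pmax(E[, 1], E[, 2]))
    dup <- duplicated(ekey) | duplicated(ekey, fromLast = TRUE)
    dt <- list(points = pts, triangles = T,
               edges = E[!duplicated(ekey), , drop = FALSE],
               hull = unique(E[!dup, , drop = FALSE]))
  }
  et <- triangulation_edge_table(dt)
  et$tension <- sqrt(rowSums((pts[et$i, , drop = FALSE] -
                              pts[et$j, , drop = FALSE])^2))
  viol <- vapply(seq_len(nrow(dt$triangles)), function(k) {
    tr <- dt$triangles[k, ]
    d <- c(sqrt(sum((pts[tr[1], ] - pts[tr[2], ])^2)),
           sqrt(sum((pts[tr[2], ] - pts[tr[3], ])^2)),
           sqrt(sum((pts[tr[1], ] - pts[tr[3], ])^2)))
    max(d) >= sum(d) - max(d)
  }, logical(1))
  if (any(viol)) stop("pattern produces degenerate tension triangles")
  list(points = pts, triangulation = dt,
       edge_tensions = et[, c("i", "j", "tension")])
}

matrix_sqrt_spd <- function(U) {
  U <- (U + t(U)) / 2
  e <- eigen(U, symmetric = TRUE)
  if (any(e$values <= 0)) stop("isogonal map must be positive definite")
  e$vectors %*% diag(sqrt(e$values)) %*% t(e$vectors)
}

#' Realize a cell mesh from a tension triangulation
#'
#' Voronoi-from-tension construction: cell vertices are placed at the
#' l0-scaled circumcenters of the tension triangulation, giving the
#' zero-isogonal-strain reference cell array; an isogonal deformation U
#' (symmetric positive definite) is applied exactly angle-preservingly
#' through the sandwich \code{q = l0 * S * circumcenter(S * p)} with
#' \code{S = U^(1/2)} (for symmetric S, \code{S R90 S = det(S) R90}, so
#' every interface direction - hence every vertex angle - is preserved);
#' optional vertex-position noise is added last. Ground truth (per-edge
#' tensions and relative tensions, the applied map, the seed) travels
#' with the mesh.
#'
#' @param pts n x 2 triangulation points (tensions = edge lengths), e.g.
#'   from \code{\link{make_tension_triangulation}}.
#' @param l0 tension-to-length scale, micrometres.
#' @param isogonal 2 x 2 SPD matrix applied as isogonal deformation.
#' @param noise_sd vertex noise SD as a fraction of the mean edge length.
#' @param seed RNG seed for the noise.
#' @param time frame time.
#' @return a \code{cell_mesh} (cells = interior triangulation points)
#'   with attribute \code{"truth"}: data frame of per-interface ground
#'   truth (cell_a, cell_b, tension, T_rel) plus \code{isogonal},
#'   \code{l0}, \code{noise_sd}, \code{seed}.
#' @export
realize_mesh_from_tensions <- function(pts, l0 = tigon_constants$l0,
                                       isogonal = diag(2), noise_sd = 0,
                                       seed = 1L, time = 0) {
  pts <- as.matrix(pts)
  S <- matrix_sqrt_spd(isogonal)
  pm <- pts %*% S                 # mapped generators (S symmetric)
  dt <- delaunay_triangulation(pm)
  ntr <- nrow(dt$triangles)
  # circumcenters of mapped triangles, then second S application
  cc <- t(vapply(seq_len(ntr), function(k) {
    tr <- dt$triangles[k, ]
    circumcenter(pm[tr[1], ], pm[tr[2], ], pm[tr[3], ])
  }, numeric(2)))
  q <- l0 * cc %*% S
  # triangles incident to each point
  inc <- vector("list", nrow(pts))
  for (k in seq_len(ntr)) for (v in dt$triangles[k, ]) {
    inc[[v]] <- c(inc[[v]], k)
  }
  hull_pts <- unique(as.vector(dt$hull))
  interior <- setdiff(seq_len(nrow(pts)), hull_pts)
  rownames(q) <- as.character(seq_len(ntr))
  cells <- list()
  for (v in interior) {
    tris <- inc[[v]]
    ang <- atan2(cc[tris, 2] - pm[v, 2], cc[tris, 1] - pm[v, 1])
    cells[[as.character(v)]] <- as.character(tris[order(ang)])
  }
  verts <- q
  used <- unique(unlist(cells))
  if (noise_sd > 0) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    m0 <- cell_mesh(verts[used, , drop = FALSE], cells, time = time)
    amp <- noise_sd * mean(m0$interfaces$length)
    verts <- verts + matrix(stats::rnorm(length(verts), 0, amp), nrow(verts))
  }
  verts <- verts[used, , drop = FALSE]
  m <- cell_mesh(verts, cells, time = time)

  # ground truth relative tensions on interior edges
  et <- triangulation_edge_table(dt)
  tension_of <- function(i, j) sqrt(sum((pts[i, ] - pts[j, ])^2))
  et$tension <- mapply(tension_of, et$i, et$j)
  tkey <- stats::setNames(et$tension, paste(et$i, et$j))
  truth <- list()
  for (r in seq_len(nrow(et))) {
    if (is.na(et$tri2[r])) next
    a <- et$i[r]; b <- et$j[r]
    if (!(as.character(a) %in% names(cells)) ||
        !(as.character(b) %in% names(cells))) next
    tr1 <- dt$triangles[et$tri1[r], ]; tr2 <- dt$triangles[et$tri2[r], ]
    opp <- c(setdiff(tr1, c(a, b)), setdiff(tr2, c(a, b)))
    flanks <- c(tension_of(a, opp[1]), tension_of(b, opp[1]),
                tension_of(a, opp[2]), tension_of(b, opp[2]))
    truth[[length(truth) + 1L]] <- data.frame(
      cell_a = as.character(a), cell_b = as.character(b),
      tension = et$tension[r], T_rel = et$tension[r] / mean(flanks))
  }
  attr(m, "truth") <- list(edges = do.call(rbind, truth),
                           isogonal = isogonal, l0 = l0,
                           noise_sd = noise_sd, seed = seed,
                           points = pts)
  m
}

# --- tracked T1 sequences -------------------------------------------------

# ideal periodic-quartet cell polygons for a simulator state.
# Returns list of 4 polygons (L, R, T, B) relative to the central-edge
# midpoint, for "v" (pre-flip) or "h" (post-flip) orientation.
quartet_cell_polygons <- function(lc, l1, l2, phi, orientation = "v") {
  dirs <- quartet_directions(phi, "v")
  al <- attr(dirs, "alpha")
  e1 <- c(cos(al[1]), sin(al[1])); e2 <- c(cos(al[2]), sin(al[2]))
  vb <- c(0, -lc / 2); va <- c(0, lc / 2)
  p3 <- va + l1 * e1
  p4 <- p3 - l2 * e2
  p5 <- p4 - c(0, lc)
  p6 <- p5 - l1 * e1
  Rpoly <- rbind(vb, va, p3, p4, p5, p6)
  a1 <- l1 * e1 - l2 * e2            # horizontal period
  t_ur <- c(0, lc) + l1 * e1         # up-right neighbor translation
  Lpoly <- sweep(Rpoly, 2, a1)
  Tpoly <- sweep(Lpoly, 2, -t_ur)
  Bpoly <- sweep(Rpoly, 2, t_ur)
  out <- list(L = Lpoly, R = Rpoly, T = Tpoly, B = Bpoly)
  if (orientation == "h") {
    rot <- function(P) cbind(-P[, 2], P[, 1])   # +90 degrees
    out <- list(L = rot(out$T), R = rot(out$B),
                T = rot(out$R), B = rot(out$L))
  }
  out
}

#' Generate a tracked sequence containing one programmed T1
#'
#' Embeds a quartet-model trajectory in a bounded hexagonal-lattice
#' surround: the four quartet cells follow the simulator's ideal
#' periodic geometry exactly (so tension inference at the central edge
#' reproduces the simulated relative tension), the surrounding ring
#' absorbs the deformation, and the cell topology is rewired at the
#' programmed flip time. With \code{mode = "none"} the sequence is
#' static (no event).
#'
#' @param mode "active", "passive", "mixed" or "none".
#' @param params a \code{\link{quartet_params}} list; \code{l_hex} sets
#'   the lattice edge length.
#' @param T_init initial active tensions for the simulator.
#' @param frame_dt frame interval, minutes (default 0.25 = 15 s).
#' @param n_pre,n_post frames before / after the exchange.
#' @param nx,ny lattice extent (>= 5 each so the quartet is buffered).
#' @param time0 time of the first frame.
#' @param frame_times optional absolute frame times on the simulator's
#'   time axis (overrides \code{frame_dt}/\code{n_pre}/\code{n_post}).
#' @return list with \code{sequence} (a \code{tracked_sequence}),
#'   \code{truth} (programmed event: losing/gaining cells, flip time,
#'   the trajectory), and \code{trajectory}.
#' @export
generate_t1_sequence <- function(mode = "active", params = quartet_params(),
                                 T_init = c(1.05, 0.975, 0.975),
                                 frame_dt = 0.25, n_pre = 12L, n_post = 8L,
                                 nx = 7L, ny = 7L, time0 = 0,
                                 frame_times = NULL) {
  if (nx < 5L || ny < 5L) stop("lattice too small to buffer the quartet")
  base <- honeycomb_mesh(nx, ny, lc = params$l_hex, lf = params$l_hex,
                         theta = pi / 6)
  # central vertical interior edge
  ifc <- base$interfaces
  ok <- !is.na(ifc$cell_b) & abs(ifc$ex) < 1e-9 * params$l_hex
  ctr <- colMeans(base$vertices)
  mid <- cbind((base$vertices[ifc$v1, 1] + base$vertices[ifc$v2, 1]) / 2,
               (base$vertices[ifc$v1, 2] + base$vertices[ifc$v2, 2]) / 2)
  d2 <- (mid[, 1] - ctr[1])^2 + (mid[, 2] - ctr[2])^2
  d2[!ok] <- Inf
  e_star <- ifc$id[which.min(d2)]
  q <- quartet_of_edge(base, e_star)
  quartet_cells <- c(q$edge_cells, q$end_cells)
  if (any(quartet_cells %in% base$boundary_cells)) {
    stop("central quartet touches the boundary; enlarge the lattice")
  }
  # roles: L/R = edge cells by centroid x; T/B = end cells by vertex y
  ecx <- base$centroids[q$edge_cells, 1]
  Lc <- q$edge_cells[which.min(ecx)]; Rc <- q$edge_cells[which.max(ecx)]
  vy <- base$vertices[c(q$v1, q$v2), 2]
  va <- c(q$v1, q$v2)[which.max(vy)]; vb <- c(q$v1, q$v2)[which.min(vy)]
  Tc <- q$end_cells[match(va, c(q$v1, q$v2))]
  Bc <- q$end_cells[match(vb, c(q$v1, q$v2))]
  roles <- c(L = Lc, R = Rc, T = Tc, B = Bc)
  m0 <- colMeans(base$vertices[c(va, vb), , drop = FALSE])

  static <- mode == "none"
  if (!static) {
    traj <- simulate_quartet(mode, params, T_init = T_init)
    if (is.na(traj$flip_time)) stop("no neighbor exchange within horizon")
    s <- traj$states
  } else {
    traj <- NULL
  }

  # vertex correspondence at the regular reference state
  ref_poly <- quartet_cell_polygons(params$l_hex, params$l_hex, params$l_hex,
                                    angles_from_tensions(c(1, 1, 1)), "v")
  corr <- list()
  for (role in names(roles)) {
    loop <- base$cells[[roles[[role]]]]
    P <- sweep(ref_poly[[role]], 2, -m0)
    idx <- vapply(loop, function(v) {
      dd <- colSums((t(P) - base$vertices[v, ])^2)
      which.min(dd)
    }, integer(1))
    if (max(vapply(loop, function(v) {
      min(colSums((t(P) - base$vertices[v, ])^2))
    }, numeric(1))) > (1e-6 * params$l_hex)^2) {
      stop("vertex correspondence failed")
    }
    corr[[role]] <- idx
  }

  state_at <- function(t, topo) {
    rows <- s[s$topology == topo, ]
    cols <- c("l_c", "l_1", "l_2", "phi0_deg", "phi1_deg", "phi2_deg")
    if (nrow(rows) == 1L) return(as.numeric(rows[1, cols]))
    vapply(cols, function(cn)
      stats::approx(rows$time, rows[[cn]], xout = t, rule = 2)$y, numeric(1))
  }
  if (is.null(frame_times)) {
    frame_times <- if (static) time0 + frame_dt * (0:(n_pre + n_post)) else
      c(traj$flip_time - frame_dt * (n_pre:1), traj$flip_time + frame_dt * (1:n_post))
  }

  # flank-corner ids around the central edge
  nbrs <- function(v) {
    ids <- base$vertex_interfaces[[v]]
    e <- base$interfaces[match(ids, base$interfaces$id), ]
    setdiff(unique(c(e$v1, e$v2)), v)
  }
  fa <- setdiff(nbrs(va), vb); fb <- setdiff(nbrs(vb), va)
  x_tl <- fa[which.min(base$vertices[fa, 1])]
  x_tr <- fa[which.max(base$vertices[fa, 1])]
  x_bl <- fb[which.min(base$vertices[fb, 1])]
  x_br <- fb[which.max(base$vertices[fb, 1])]

  set_pre_positions <- function(verts, st) {
    phi <- st[4:6] * pi / 180
    polys <- quartet_cell_polygons(st[1], st[2], st[3], phi, "v")
    for (role in names(roles)) {
      loop <- base$cells[[roles[[role]]]]
      verts[loop, ] <- sweep(polys[[role]][corr[[role]], , drop = FALSE],
                             2, -m0)
    }
    verts
  }
  st_flip <- if (!static) state_at(traj$flip_time, "pre") else NULL

  frames <- list()
  for (fi in seq_along(frame_times)) {
    tt <- frame_times[fi]
    verts <- base$vertices
    cells <- base$cells
    if (!static) {
      post <- tt >= traj$flip_time
      if (!post) {
        verts <- set_pre_positions(verts, state_at(max(tt, 0), "pre"))
      } else {
        # outer quartet corners frozen at the flip-time configuration;
        # the central pair and the four flank corners follow the ideal
        # post-flip geometry exactly (these set the new edge's angles)
        verts <- set_pre_positions(verts, st_flip)
        cells <- rewire_t1(cells, roles, va, vb)
        st <- state_at(tt, "post")
        lc <- st[1]; l1 <- st[2]; l2 <- st[3]
        phi <- st[4:6] * pi / 180
        a1 <- pi + phi[3]; a2 <- pi - phi[2]   # outgoing flanks at wr
        e1 <- c(cos(a1), sin(a1)); e2 <- c(cos(a2), sin(a2))
        wl <- m0 + c(-lc / 2, 0); wr <- m0 + c(lc / 2, 0)
        verts[va, ] <- wl; verts[vb, ] <- wr
        verts[x_br, ] <- wr + l1 * e1
        verts[x_tr, ] <- wr + l2 * e2
        verts[x_tl, ] <- wl - l1 * e1
        verts[x_bl, ] <- wl - l2 * e2
      }
    }
    frames[[fi]] <- cell_mesh(verts, cells, time = tt)
  }
  truth <- list(mode = mode,
                losing = if (static) NULL else sort(c(Lc, Rc)),
                gaining = if (static) NULL else sort(c(Tc, Bc)),
                flip_time = if (static) NA_real_ else traj$flip_time,
                roles = roles)
  list(sequence = tracked_sequence(frames), truth = truth, trajectory = traj)
}

# topology surgery at the flip: losing pair keeps one central vertex
# each, gaining pair takes both (va -> left vertex, vb -> right vertex)
rewire_t1 <- function(cells, roles, va, vb) {
  drop_from <- function(loop, v) loop[loop != v]
  insert_after <- function(loop, after, v) {
    i <- match(after, loop)
    append(loop, v, after = i)
  }
  cells[[roles[["L"]]]] <- drop_from(cells[[roles[["L"]]]], vb)
  cells[[roles[["R"]]]] <- drop_from(cells[[roles[["R"]]]], va)
  cells[[roles[["T"]]]] <- insert_after(cells[[roles[["T"]]]], va, vb)
  cells[[roles[["B"]]]] <- insert_after(cells[[roles[["B"]]]], vb, va)
  cells
}

#' Snail-like and wild-type-like generator presets
#'
#' Two quartet parameter sets differing only in the isogonal
#' pre-stretch: the wild-type-like preset carries a DV isogonal
#' extension (dl_iso = 1.9 um), shifting the collapse threshold above
#' sqrt(2); the snail-like preset carries none, so active T1s collapse
#' at the bare geometric threshold sqrt(2).
#'
#' @param ... overrides passed to \code{\link{quartet_params}}.
#' @return named list with elements \code{snail_like} and \code{wt_like}.
#' @export
snail_like_and_wt_like_presets <- function(...) {
  list(snail_like = quartet_params(dl_iso = 0, ...),
       wt_like = quartet_params(dl_iso = 1.9, ...))
}
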