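# Detection, pooling and classification of neighbor exchanges (T1s) in
# tracked cell-mesh sequences.

#' Detect neighbor exchanges and rosettes in a tracked sequence
#'
#' A T1 event is recorded when a cell-pair adjacency present at frame k
#' is absent at frame k+1 while a new adjacency appears among the same
#' quartet (the common neighbors of the losing pair). Collapse time t*
#' is the midpoint of the two frame times. Configurations with five or
#' more cells sharing a vertex are recorded as rosettes. Reversals
#' (flip followed by the inverse flip) are recorded as two events and
#' flagged.
#'
#' @param seq a \code{tracked_sequence} (>= 2 frames).
#' @return object of class \code{t1_events}: data frame \code{events}
#'   (event_id, type, cells_losing, cells_gaining, t_star_min, frame,
#'   reversed) and data frame \code{rosettes} (frame, time, vertex_id,
#'   n_cells).
#' @export
detect_events <- function(seq) {
  if (length(seq$frames) < 2L) stop("need at least 2 frames")
  events <- list()
  all_ids <- names(seq$frames[[1]]$cells)
  for (k in seq_along(seq$frames)[-1]) {
    newcells <- setdiff(names(seq$frames[[k]]$cells), all_ids)
    if (length(newcells)) {
      warning("untracked cell id(s) appearing at frame ", k, ": ",
              paste(newcells, collapse = ", "), " (excluded)")
    }
    all_ids <- union(all_ids, names(seq$frames[[k]]$cells))
  }
  adj <- lapply(seq$frames, function(m) {
    p <- adjacency_pairs(m)
    paste(p[, 1], p[, 2], sep = "|")
  })
  for (k in seq_len(length(seq$frames) - 1L)) {
    lost <- setdiff(adj[[k]], adj[[k + 1]])
    gained <- setdiff(adj[[k + 1]], adj[[k]])
    if (!length(lost) && !length(gained)) next
    t_star <- (seq$times[k] + seq$times[k + 1]) / 2
    gsplit <- strsplit(gained, "|", fixed = TRUE)
    for (lp in strsplit(lost, "|", fixed = TRUE)) {
      # common neighbors of the losing pair at frame k
      mk <- seq$frames[[k]]
      pk <- adjacency_pairs(mk)
      nb <- function(cid) unique(c(pk[pk[, 1] == cid, 2], pk[pk[, 2] == cid, 1]))
      common <- intersect(nb(lp[1]), nb(lp[2]))
      hit <- which(vapply(gsplit, function(gp) all(gp %in% common), logical(1)))
      if (length(hit)) {
        gp <- gsplit[[hit[1]]]
        events[[length(events) + 1L]] <- data.frame(
          type = "t1",
          cells_losing = paste(lp, collapse = "|"),
          cells_gaining = paste(gp, collapse = "|"),
          t_star_min = t_star, frame = k, reversed = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(type = character(0), cells_losing = character(0),
               cells_gaining = character(0), t_star_min = numeric(0),
               frame = integer(0), reversed = logical(0))
  if (nrow(ev) > 1L) {
    for (i in seq_len(nrow(ev))) {
      rev_idx <- which(ev$cells_losing == ev$cells_gaining[i] &
                       ev$cells_gaining == ev$cells_losing[i] &
                       ev$t_star_min > ev$t_star_min[i])
      if (length(rev_idx)) ev$reversed[c(i, rev_idx)] <- TRUE
    }
  }
  ev <- cbind(event_id = seq_len(nrow(ev)), ev)
  ros <- list()
  for (k in seq_along(seq$frames)) {
    m <- seq$frames[[k]]
    for (v in names(m$vertex_cells)) {
      nc <- length(m$vertex_cells[[v]])
      if (nc >= 5L) {
        ros[[length(ros) + 1L]] <- data.frame(frame = k, time = seq$times[k],
                                              vertex_id = v, n_cells = nc)
      }
    }
  }
  rosettes <- if (length(ros)) do.call(rbind, ros) else
    data.frame(frame = integer(0), time = numeric(0),
               vertex_id = character(0), n_cells = integer(0))
  structure(list(events = ev, rosettes = rosettes, times = seq$times),
            class = "t1_events")
}

#' @export
print.t1_events <- function(x, ...) {
  cat("t1_events:", nrow(x$events), "T1 event(s),",
      nrow(x$rosettes), "rosette record(s)\n")
  if (nrow(x$events)) print(utils::head(x$events, 10))
  invisible(x)
}

# per-frame edge tension lookup: list of tension_fit (one per frame)
fit_sequence <- function(seq) lapply(seq$frames, infer_tensions)

edge_row <- function(fit, pair) {
  a <- pmin(pair[1], pair[2]); b <- pmax(pair[1], pair[2])
  e <- fit$edges
  e[(pmin(e$cell_a, e$cell_b) == a) & (pmax(e$cell_a, e$cell_b) == b), ]
}

#' Align and pool interface trajectories around neighbor exchanges
#'
#' For each event, the collapsing interface contributes length/tension
#' samples at t - t* < 0 and the emerging interface at t - t* > 0 (no
#' interpolation across the exchange). Samples are snapped to a common
#' relative-time grid (spacing = median frame interval) and summarized
#' by mean, SD, SEM and count per offset and phase.
#'
#' @param events a \code{t1_events} object.
#' @param seq the \code{tracked_sequence} the events came from.
#' @param fits list of per-frame \code{tension_fit}s (default: computed).
#' @param window half-width of the relative-time window, minutes.
#' @param min_frames events need at least this many frames on each side
#'   to be pooled (default 2).
#' @return object of class \code{pooled_trajectory}: data frame with
#'   t_rel_min, phase, mean_l, sd_l, sem_l, mean_T, sd_T, sem_T, n.
#' @export
pool_trajectories <- function(events, seq, fits = fit_sequence(seq),
                              window = 15, min_frames = 2L) {
  ev <- events$events
  ev <- ev[ev$type == "t1", ]
  if (!nrow(ev)) stop("no T1 events to pool")
  grid_dt <- stats::median(diff(seq$times))
  series <- list()
  for (i in seq_len(nrow(ev))) {
    lp <- strsplit(ev$cells_losing[i], "|", fixed = TRUE)[[1]]
    gp <- strsplit(ev$cells_gaining[i], "|", fixed = TRUE)[[1]]
    t_star <- ev$t_star_min[i]
    rows <- list()
    for (k in seq_along(seq$frames)) {
      trel <- seq$times[k] - t_star
      if (abs(trel) > window) next
      pair <- if (trel < 0) lp else gp
      r <- edge_row(fits[[k]], pair)
      if (nrow(r) == 1L) {
        rows[[length(rows) + 1L]] <- data.frame(
          t_rel = trel, phase = if (trel < 0) "collapsing" else "emerging",
          l = r$length_um, T_rel = r$T_rel)
      }
    }
    if (!length(rows)) next
    tab <- do.call(rbind, rows)
    if (sum(tab$phase == "collapsing") >= min_frames &&
        sum(tab$phase == "emerging") >= min_frames) {
      series[[length(series) + 1L]] <- tab
    }
  }
  if (!length(series)) stop("no events with enough frames on both sides")
  pool_aligned(series, grid_dt)
}

pool_aligned <- function(series, grid_dt) {
  # one sample per event and grid offset (recorded states denser than the
  # grid are averaged within the bin first)
  series <- lapply(series, function(tab) {
    tab$offset <- round(tab$t_rel / grid_dt) * grid_dt
    k <- interaction(tab$offset, tab$phase, drop = TRUE)
    data.frame(t_rel = as.numeric(tapply(tab$offset, k, `[`, 1)),
               phase = as.character(tapply(as.character(tab$phase), k, `[`, 1)),
               l = as.numeric(tapply(tab$l, k, mean)),
               T_rel = as.numeric(tapply(tab$T_rel, k, mean)))
  })
  tab <- do.call(rbind, series)
  tab$offset <- round(tab$t_rel / grid_dt) * grid_dt
  key <- interaction(tab$offset, tab$phase, drop = TRUE)
  agg <- function(v, f) tapply(v, key, f)
  n <- as.numeric(agg(tab$l, length))
  sdl <- as.numeric(agg(tab$l, stats::sd)); sdl[is.na(sdl)] <- 0
  sdt <- as.numeric(agg(tab$T_rel, stats::sd)); sdt[is.na(sdt)] <- 0
  out <- data.frame(
    t_rel_min = as.numeric(tapply(tab$offset, key, `[`, 1)),
    phase = as.character(tapply(as.character(tab$phase), key, `[`, 1)),
    mean_l = as.numeric(agg(tab$l, mean)), sd_l = sdl, sem_l = sdl / sqrt(n),
    mean_T = as.numeric(agg(tab$T_rel, mean)), sd_T = sdt,
    sem_T = sdt / sqrt(n), n = n)
  out <- out[order(out$t_rel_min), ]
  rownames(out) <- NULL
  structure(list(table = out, grid_dt = grid_dt, n_events = length(series)),
            class = "pooled_trajectory")
}

#' Pool the central-interface trajectories of a quartet ensemble
#'
#' Aligns each simulated run to its neighbor-exchange time and pools
#' length and relative tension exactly as \code{\link{pool_trajectories}}
#' does for detected events (pre-flip samples from the collapsing, post-
#' flip from the emerging interface).
#'
#' @param ensemble a \code{quartet_ensemble}.
#' @param grid_dt relative-time grid spacing, minutes.
#' @param window half-width of the window, minutes.
#' @return a \code{pooled_trajectory}.
#' @export
pool_ensemble <- function(ensemble, grid_dt = 0.25, window = 15) {
  series <- lapply(ensemble$runs, function(run) {
    if (is.na(run$flip_time)) return(NULL)
    s <- run$states
    trel <- s$time - run$flip_time
    keep <- abs(trel) <= window
    data.frame(t_rel = trel[keep],
               phase = ifelse(s$topology[keep] == "pre", "collapsing", "emerging"),
               l = s$l_c[keep], T_rel = s$T_rel[keep])
  })
  series <- series[!vapply(series, is.null, logical(1))]
  if (!length(series)) stop("no runs with a neighbor exchange")
  pool_aligned(series, grid_dt)
}

#' @export
print.pooled_trajectory <- function(x, ...) {
  cat("pooled_trajectory:", x$n_events, "events,",
      nrow(x$table), "grid points (dt =", x$grid_dt, "min)\n")
  invisible(x)
}

#' @export
plot.pooled_trajectory <- function(x, what = c("tension", "length"), ...) {
  what <- match.arg(what)
  tab <- x$table
  ycol <- if (what == "tension") "mean_T" else "mean_l"
  scol <- if (what == "tension") "sd_T" else "sd_l"
  plot(tab$t_rel_min, tab[[ycol]], type = "n",
       xlab = "time from exchange (min)",
       ylab = if (what == "tension") "relative tension" else "length (um)", ...)
  for (ph in unique(tab$phase)) {
    s <- tab[tab$phase == ph, ]
    graphics::polygon(c(s$t_rel_min, rev(s$t_rel_min)),
                      c(s[[ycol]] + s[[scol]], rev(s[[ycol]] - s[[scol]])),
                      col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
    graphics::lines(s$t_rel_min, s[[ycol]], lwd = 2)
  }
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Collapse-threshold tension estimate
#'
#' Mean relative tension on collapsing interfaces at the last frame (or
#' recorded state) before the neighbor exchange, with SD and SEM over
#' events.
#'
#' @param x a \code{t1_events} object or a \code{quartet_ensemble}.
#' @param ... further arguments (for events: \code{seq}, \code{fits},
#'   \code{exclude_reversed = TRUE}).
#' @return list with \code{T_crit} (mean), \code{sd}, \code{sem},
#'   \code{n} and the per-event values.
#' @export
estimate_threshold <- function(x, ...) UseMethod("estimate_threshold")

#' @export
estimate_threshold.quartet_ensemble <- function(x, ...) {
  v <- vapply(x$runs, `[[`, numeric(1), "T_rel_at_flip")
  v <- v[!is.na(v)]
  if (!length(v)) stop("no valid pre-collapse tensions")
  list(T_crit = mean(v), sd = stats::sd(v),
       sem = stats::sd(v) / sqrt(length(v)), n = length(v), values = v)
}

#' @export
estimate_threshold.t1_events <- function(x, seq, fits = fit_sequence(seq),
                                         exclude_reversed = TRUE, ...) {
  ev <- x$events[x$events$type == "t1", ]
  if (exclude_reversed) ev <- ev[!ev$reversed, ]
  vals <- numeric(0)
  for (i in seq_len(nrow(ev))) {
    lp <- strsplit(ev$cells_losing[i], "|", fixed = TRUE)[[1]]
    pre <- which(seq$times < ev$t_star_min[i])
    for (k in rev(pre)) {
      r <- edge_row(fits[[k]], lp)
      if (nrow(r) == 1L) { vals <- c(vals, r$T_rel); break }
    }
  }
  if (!length(vals)) stop("no valid pre-collapse tensions")
  list(T_crit = mean(vals), sd = stats::sd(vals),
       sem = stats::sd(vals) / sqrt(length(vals)), n = length(vals),
       values = vals)
}

#' Does reference-time tension predict collapse?
#'
#' Spearman rank correlation between an interface's relative tension at
#' a reference time and its time-to-collapse, plus the tension
#' distributions of collapsing vs never-collapsing interfaces.
#'
#' @param events a \code{t1_events} object.
#' @param seq the \code{tracked_sequence}.
#' @param fits per-frame tension fits.
#' @param t_ref reference time (minutes); the closest frame is used.
#' @return list with \code{rho} (Spearman), \code{p_value}, \code{n},
#'   the per-interface table, and group summaries
#'   \code{collapsing_tension} / \code{noncollapsing_tension}.
#' @export
time_to_collapse_stats <- function(events, seq, fits = fit_sequence(seq),
                                   t_ref = seq$times[1]) {
  k_ref <- which.min(abs(seq$times - t_ref))
  ref <- fits[[k_ref]]$edges
  ev <- events$events[events$events$type == "t1", ]
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  ev_key <- ev$cells_losing
  tab <- data.frame(pair = key(ref$cell_a, ref$cell_b),
                    T_ref = ref$T_rel, stringsAsFactors = FALSE)
  hit <- match(tab$pair, ev_key)
  tab$collapses <- !is.na(hit)
  tab$time_to_collapse <- ifelse(tab$collapses,
                                 ev$t_star_min[hit] - seq$times[k_ref],
                                 NA_real_)
  coll <- tab[tab$collapses & tab$time_to_collapse > 0, ]
  if (nrow(coll) < 3L) stop("fewer than 3 collapsing interfaces: correlation undefined")
  ct <- stats::cor.test(coll$T_ref, coll$time_to_collapse, method = "spearman",
                        exact = FALSE)
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(coll),
       table = tab,
       collapsing_tension = mean(coll$T_ref),
       noncollapsing_tension = mean(tab$T_ref[!tab$collapses]))
}

#' Tension kite of an edge in physical orientation
#'
#' Assembles the two physical-orientation tension triangles at an
#' interior edge's end vertices into the kite: a 4 x 2 matrix of
#' tension-triangulation corner positions labeled by cell id (the two
#' edge cells plus the two end cells). The second triangle is rigidly
#' aligned to the first along the shared (edge-dual) side.
#'
#' @param mesh a \code{cell_mesh}.
#' @param interface interface id.
#' @return 4 x 2 matrix with cell-id rownames.
#' @export
tension_kite_at_edge <- function(mesh, interface) {
  q <- quartet_of_edge(mesh, interface)
  t1 <- tension_triangle_at_vertex(mesh, q$v1)
  t2 <- tension_triangle_at_vertex(mesh, q$v2)
  ec <- q$edge_cells
  # align triangle 2 onto triangle 1 along the shared dual edge
  s1 <- t1[ec[2], ] - t1[ec[1], ]
  s2 <- t2[ec[2], ] - t2[ec[1], ]
  sc <- sqrt(sum(s1^2) / sum(s2^2))
  t2s <- t2 * sc
  shift <- (t1[ec[1], ] + t1[ec[2], ]) / 2 - (t2s[ec[1], ] + t2s[ec[2], ]) / 2
  t2s <- sweep(t2s, 2, -shift)
  rbind(t1[c(ec[1], ec[2], q$end_cells[1]), ],
        matrix(t2s[q$end_cells[2], ], 1, 2,
               dimnames = list(q$end_cells[2], NULL)))
}

#' Classify an event as active, passive or mixed
#'
#' Scores the pre-collapse change of the tension-kite shape (aspect
#' ratio of the four tension-triangulation corners) against the change
#' of the quartet isogonal aspect ratio; tension-driven (active) T1s
#' deform the former at constant isogonal mode, externally driven
#' (passive) T1s the reverse.
#'
#' @param event one row of a \code{t1_events} events table.
#' @param seq the \code{tracked_sequence}.
#' @param l0 tension-to-length scale.
#' @param margin dominance factor for a pure label (default 2: the
#'   dominant score must be at least twice the other).
#' @param min_frames minimum pre-collapse frames (default 3).
#' @return list with \code{label} ("active", "passive", "mixed" or
#'   "unclassified"), \code{score_tension}, \code{score_isogonal} and
#'   the per-frame aspect table.
#' @export
classify_active_passive <- function(event, seq, l0 = tigon_constants$l0,
                                    margin = 2, min_frames = 3L) {
  lp <- strsplit(event$cells_losing, "|", fixed = TRUE)[[1]]
  pre <- which(seq$times < event$t_star_min)
  rows <- list()
  for (k in pre) {
    m <- seq$frames[[k]]
    ifc <- m$interfaces
    hit <- which((pmin(ifc$cell_a, ifc$cell_b) == min(lp)) &
                 (pmax(ifc$cell_a, ifc$cell_b) == max(lp)))
    if (!length(hit)) next
    kxy <- tryCatch(tension_kite_at_edge(m, ifc$id[hit[1]]),
                    error = function(e) NULL)
    if (is.null(kxy)) next
    cen <- m$centroids[rownames(kxy), , drop = FALSE]
    it <- tryCatch(quartet_isogonal(kxy, cen, l0 = l0), error = function(e) NULL)
    if (is.null(it)) next
    rows[[length(rows) + 1L]] <- data.frame(
      time = seq$times[k],
      aspect_tension = quartet_shape_aspect(kxy),
      aspect_isogonal = tensor_aspect(it))
  }
  if (length(rows) < min_frames) {
    return(list(label = "unclassified", score_tension = NA_real_,
                score_isogonal = NA_real_, table = NULL))
  }
  tab <- do.call(rbind, rows)
  st <- abs(tab$aspect_tension[nrow(tab)] - tab$aspect_tension[1])
  si <- abs(tab$aspect_isogonal[nrow(tab)] - tab$aspect_isogonal[1])
  label <- if (st >= margin * si) "active"
           else if (si >= margin * st) "passive"
           else "mixed"
  list(label = label, score_tension = st, score_isogonal = si, table = tab)
}
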