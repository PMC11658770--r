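# Planar Delaunay triangulation (incremental Bowyer-Watson).
#
# Used by the random-Delaunay LTC baseline and the random synthetic
# tension pattern. Vectorized over the triangle list per insertion, which
# is fast enough for the few-thousand-point problem sizes used here.

#' Delaunay triangulation of a planar point set
#'
#' Incremental Bowyer-Watson construction with a super-triangle; exact
#' within floating-point tolerance (near-degenerate cocircular quadruples
#' are resolved by insertion order).
#'
#' @param pts n x 2 numeric matrix of point coordinates.
#' @return list with \code{points}, \code{triangles} (m x 3 matrix of
#'   point indices, counter-clockwise), \code{edges} (unique undirected
#'   edges, 2-column matrix) and \code{hull} (edges on the convex hull).
#' @export
delaunay_triangulation <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 3L) stop("need at least 3 points")
  ctr <- colMeans(pts)
  rad <- max(sqrt(rowSums(sweep(pts, 2, ctr)^2))) * 3 + 1
  sup <- rbind(ctr + rad * c(0, 2.2),
               ctr + rad * c(-2.0, -1.2),
               ctr + rad * c(2.0, -1.2))
  P <- rbind(pts, sup)
  si <- n + 1:3

  # triangle store (grown geometrically)
  cap <- max(64L, 4L * n)
  tri <- matrix(0L, cap, 3)
  ccx <- numeric(cap); ccy <- numeric(cap); rr <- numeric(cap)
  alive <- logical(cap)
  ntri <- 0L

  add_tri <- function(i, j, k) {
    # ensure CCW
    ax <- P[i, 1]; ay <- P[i, 2]
    if ((P[j, 1] - ax) * (P[k, 2] - ay) - (P[j, 2] - ay) * (P[k, 1] - ax) < 0) {
      tmp <- j; j <- k; k <- tmp
    }
    ntri <<- ntri + 1L
    if (ntri > nrow(tri)) {
      grow <- nrow(tri)
      tri <<- rbind(tri, matrix(0L, grow, 3))
      ccx <<- c(ccx, numeric(grow)); ccy <<- c(ccy, numeric(grow))
      rr <<- c(rr, numeric(grow)); alive <<- c(alive, logical(grow))
    }
    tri[ntri, ] <<- c(i, j, k)
    cc <- circumcenter(P[i, ], P[j, ], P[k, ])
    ccx[ntri] <<- cc[1]; ccy[ntri] <<- cc[2]
    rr[ntri] <<- (cc[1] - P[i, 1])^2 + (cc[2] - P[i, 2])^2
    alive[ntri] <<- TRUE
  }
  add_tri(si[1], si[2], si[3])

  for (p in seq_len(n)) {
    px <- P[p, 1]; py <- P[p, 2]
    act <- which(alive[seq_len(ntri)])
    bad <- act[(ccx[act] - px)^2 + (ccy[act] - py)^2 < rr[act] * (1 + 1e-12)]
    if (!length(bad)) next
    alive[bad] <- FALSE
    # cavity boundary: edges of bad triangles that appear exactly once
    e1 <- tri[bad, c(1, 2), drop = FALSE]
    e2 <- tri[bad, c(2, 3), drop = FALSE]
    e3 <- tri[bad, c(3, 1), drop = FALSE]
    E <- rbind(e1, e2, e3)
    key <- paste(pmin(E[, 1], E[, 2]), pmax(E[, 1], E[, 2]))
    single <- !(key %in% key[duplicated(key)])
    for (r in which(single)) add_tri(E[r, 1], E[r, 2], p)
  }

  keep <- which(alive[seq_len(ntri)])
  T <- tri[keep, , drop = FALSE]
  touches_super <- apply(T, 1, function(t) any(t %in% si))
  T <- T[!touches_super, , drop = FALSE]

  E <- rbind(T[, c(1, 2)], T[, c(2, 3)], T[, c(3, 1)])
  ekey <- paste(pmin(E[, 1], E[, 2]), pmax(E[, 1], E[, 2]))
  dup <- duplicated(ekey) | duplicated(ekey, fromLast = TRUE)
  hull <- unique(E[!dup, , drop = FALSE])
  edges <- E[!duplicated(ekey), , drop = FALSE]
  list(points = pts, triangles = T, edges = edges, hull = hull)
}

#' Adjacent-triangle table of a triangulation
#'
#' For each interior edge, the indices of the two triangles sharing it.
#'
#' @param dt result of \code{\link{delaunay_triangulation}} (or any list
#'   with a \code{triangles} matrix).
#' @return data frame with columns \code{i}, \code{j} (edge endpoints,
#'   i < j), \code{tri1}, \code{tri2} (NA for hull edges).
#' @export
triangulation_edge_table <- function(dt) {
  T <- dt$triangles
  E <- rbind(T[, c(1, 2)], T[, c(2, 3)], T[, c(3, 1)])
  tid <- rep(seq_len(nrow(T)), 3)
  i <- pmin(E[, 1], E[, 2]); j <- pmax(E[, 1], E[, 2])
  key <- paste(i, j)
  sp <- split(seq_along(key), key)
  out <- data.frame(i = integer(length(sp)), j = integer(length(sp)),
                    tri1 = integer(length(sp)), tri2 = NA_integer_)
  k <- 0L
  for (idx in sp) {
    k <- k + 1L
    out$i[k] <- i[idx[1]]; out$j[k] <- j[idx[1]]
    out$tri1[k] <- tid[idx[1]]
    if (length(idx) > 1L) out$tri2[k] <- tid[idx[2]]
  }
  out
}
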