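# JSON mesh I/O ("tigon-mesh-1" schema) and label-image extraction.

MESH_SCHEMA <- "tigon-mesh-1"

#' Write a tracked sequence to JSON
#'
#' Serializes frames as \code{{"schema": "tigon-mesh-1", "frames": [...]}}
#' with per-frame vertex coordinate maps and per-cell vertex loops.
#' Interfaces are derived on read, not stored. Coordinates keep full
#' precision, so \code{read_mesh_json(write_mesh_json(seq))} reproduces the
#' sequence exactly and repeated writes are byte-stable.
#'
#' @param seq a \code{tracked_sequence} (a single \code{cell_mesh} is
#'   wrapped into one frame).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_mesh_json <- function(seq, path) {
  if (inherits(seq, "cell_mesh")) seq <- tracked_sequence(list(seq))
  frames <- lapply(seq$frames, function(m) {
    verts <- lapply(seq_len(nrow(m$vertices)), function(i)
      unname(m$vertices[i, ]))
    names(verts) <- rownames(m$vertices)
    cells <- lapply(names(m$cells), function(cid)
      list(vertex_loop = I(m$cells[[cid]]), label = m$labels[[cid]]))
    names(cells) <- names(m$cells)
    list(time_min = m$time, vertices = verts, cells = cells)
  })
  out <- list(schema = MESH_SCHEMA, frames = frames)
  json <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = I(17), pretty = FALSE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Read a tracked sequence from JSON
#'
#' Parses the \code{tigon-mesh-1} schema and validates every frame's mesh
#' invariants; violations are reported with the frame and entity id.
#'
#' @param path JSON file written by \code{\link{write_mesh_json}} or
#'   conforming to the schema.
#' @return a \code{tracked_sequence}.
#' @export
read_mesh_json <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("malformed JSON in ", path, ": ",
                                           conditionMessage(e)))
  if (is.null(obj$schema) || obj$schema != MESH_SCHEMA) {
    stop("unsupported mesh schema: ", deparse(obj$schema))
  }
  frames <- lapply(seq_along(obj$frames), function(k) {
    fr <- obj$frames[[k]]
    verts <- t(vapply(fr$vertices, function(p) as.numeric(unlist(p)), numeric(2)))
    rownames(verts) <- names(fr$vertices)
    loops <- lapply(fr$cells, function(cl) as.character(unlist(cl$vertex_loop)))
    labels <- vapply(fr$cells, function(cl)
      if (is.null(cl$label)) "" else as.character(cl$label), character(1))
    names(labels) <- names(fr$cells)
    tryCatch(
      cell_mesh(verts, loops, time = as.numeric(fr$time_min), labels = labels),
      error = function(e) stop("frame ", k, ": ", conditionMessage(e)))
  })
  tracked_sequence(frames)
}

#' Extract a cell mesh from an integer label image
#'
#' Cells are contiguous label regions (label 0 = background/outside).
#' Vertices are placed at pixel corners where at least three distinct
#' regions (background included) meet; interfaces are the straight
#' segments between consecutive junction corners along each shared
#' boundary, discarding boundary curvature.
#'
#' @param image integer matrix; \code{image[i, j]} is the label of the
#'   pixel at x = j, y = i (row 1 = bottom after the flip applied here, so
#'   the mesh lives in standard xy orientation).
#' @param pixel_size physical pixel edge in micrometres.
#' @param time frame time in minutes.
#' @return a \code{cell_mesh}; cells touching the image border or the
#'   background are boundary cells.
#' @export
mesh_from_labels <- function(image, pixel_size = 1, time = 0) {
  lab <- as.matrix(image)
  storage.mode(lab) <- "integer"
  check_labels_contiguous(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  # pad with background so every region boundary is closed
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- lab

  # corner (i, j) of the padded grid touches pixels
  # pad[i, j], pad[i+1, j], pad[i, j+1], pad[i+1, j+1]
  corner_labels <- function(i, j) c(pad[i, j], pad[i + 1L, j],
                                    pad[i, j + 1L], pad[i + 1L, j + 1L])
  a <- pad[-nrow(pad), -ncol(pad)]; b <- pad[-1, -ncol(pad)]
  c_ <- pad[-nrow(pad), -1]; d <- pad[-1, -1]
  ndist <- matrix(0L, nrow(a), ncol(a))
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    ndist[i, j] <- length(unique(c(a[i, j], b[i, j], c_[i, j], d[i, j])))
  }
  junction <- which(ndist >= 3L, arr.ind = TRUE)
  jkey <- paste(junction[, 1], junction[, 2])

  corner_xy <- function(i, j) {
    # corner between padded rows i, i+1 and cols j, j+1 -> unpadded corner
    c((j - 1L), (nr + 1L - i))
  }

  # rasterization can split one tri-cellular junction across adjacent pixel
  # corners; cluster junction corners within Chebyshev distance 1 into a
  # single mesh vertex at their mean position
  nj <- nrow(junction)
  cl <- seq_len(nj)
  find <- function(k) { while (cl[k] != k) k <- cl[k]; k }
  if (nj > 1L) {
    for (p in seq_len(nj - 1L)) for (q in (p + 1L):nj) {
      if (max(abs(junction[p, ] - junction[q, ])) <= 1L) {
        cl[find(q)] <- find(p)
      }
    }
  }
  roots <- vapply(seq_len(nj), find, integer(1))
  cluster_id <- match(roots, unique(roots))
  xy_all <- t(apply(junction, 1, function(r) corner_xy(r[1], r[2])))
  vxy <- lapply(seq_len(max(cluster_id)), function(g)
    colMeans(xy_all[cluster_id == g, , drop = FALSE]))
  vert_of_key <- stats::setNames(as.character(cluster_id), jkey)
  vcount <- max(cluster_id)
  extra_map <- new.env(parent = emptyenv())
  get_vertex <- function(i, j, allow_new = FALSE) {
    key <- paste(i, j)
    id <- vert_of_key[key]
    if (!is.na(id)) return(id)
    if (!allow_new) return(NA_character_)
    id <- extra_map[[key]]
    if (is.null(id)) {
      vcount <<- vcount + 1L
      id <- as.character(vcount)
      extra_map[[key]] <- id
      vxy[[vcount]] <<- corner_xy(i, j)
    }
    id
  }
  touches_background <- function(i, j) {
    px <- rbind(c(i, j), c(i + 1L, j), c(i, j + 1L), c(i + 1L, j + 1L))
    any(apply(px, 1, function(p)
      p[1] < 1 || p[1] > nrow(pad) || p[2] < 1 || p[2] > ncol(pad) ||
        pad[p[1], p[2]] == 0L))
  }

  # trace each region's crack boundary; keep junction corners and, for
  # cells on the background boundary, corners where the outline turns
  # (so boundary cells remain simple polygons)
  loops <- list(); labels_out <- character(0)
  region_ids <- sort(setdiff(unique(as.vector(lab)), 0L))

  for (rid in region_ids) {
    path <- trace_region_corners(pad, rid)           # closed corner path
    np <- nrow(path) - 1L                            # last repeats first
    pathc <- path[seq_len(np), , drop = FALSE]
    loop <- character(0)
    for (k in seq_len(np)) {
      prev <- pathc[(k - 2L) %% np + 1L, ]
      cur <- pathc[k, ]; nxt <- pathc[k %% np + 1L, ]
      jid <- get_vertex(cur[1], cur[2])
      if (!is.na(jid)) { loop <- c(loop, jid); next }
      turned <- any((cur - prev) != (nxt - cur))
      if (turned && touches_background(cur[1], cur[2])) {
        loop <- c(loop, get_vertex(cur[1], cur[2], allow_new = TRUE))
      }
    }
    keep <- c(TRUE, loop[-1] != loop[-length(loop)])
    loop <- loop[keep]
    if (loop[1] == loop[length(loop)]) loop <- loop[-length(loop)]
    if (length(loop) < 3L) {
      stop("label ", rid, ": fewer than 3 boundary corners")
    }
    loops[[as.character(rid)]] <- loop
    labels_out <- c(labels_out, "")
  }
  verts <- do.call(rbind, vxy) * pixel_size
  rownames(verts) <- as.character(seq_len(vcount))
  names(labels_out) <- names(loops)
  cell_mesh(verts, loops, time = time, labels = labels_out)
}

check_labels_contiguous <- function(lab) {
  ids <- setdiff(unique(as.vector(lab)), 0L)
  for (rid in ids) {
    mask <- lab == rid
    n <- sum(mask)
    # flood fill from first pixel
    start <- which(mask, arr.ind = TRUE)[1, ]
    seen <- matrix(FALSE, nrow(lab), ncol(lab))
    stack <- list(start)
    seen[start[1], start[2]] <- TRUE
    cnt <- 1L
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= nrow(lab) && q[2] >= 1 && q[2] <= ncol(lab) &&
            mask[q[1], q[2]] && !seen[q[1], q[2]]) {
          seen[q[1], q[2]] <- TRUE
          cnt <- cnt + 1L
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
    if (cnt != n) stop("label ", rid, " is not contiguous")
  }
  invisible(TRUE)
}

# Walk the crack boundary of region `rid` in padded label matrix, keeping the
# region on the LEFT (counter-clockwise in xy coordinates, i.e. clockwise in
# matrix row order since rows are flipped later). Returns the corner path as
# a matrix of (i, j) corner indices.
trace_region_corners <- function(pad, rid) {
  inside <- function(i, j) i >= 1 && i <= nrow(pad) && j >= 1 && j <= ncol(pad) &&
    pad[i, j] == rid
  # find a starting crack: topmost-leftmost pixel of the region
  w <- which(pad == rid, arr.ind = TRUE)
  i0 <- min(w[, 1]); j0 <- min(w[w[, 1] == i0, 2])
  # corners indexed by (ci, cj): corner between rows ci, ci+1 and cols cj, cj+1
  # pixel (i, j) has corners (i-1, j-1), (i-1, j), (i, j-1), (i, j)
  # Start at top-left corner of the start pixel, initial direction = +col
  # (walk along the top edge of the region, region below => region on the
  # right in matrix coords; after the y-flip this is CCW with region left).
  pos <- c(i0 - 1L, j0 - 1L)
  dir <- c(0L, 1L)
  path <- list(pos)
  repeat {
    # at corner pos heading dir, choose next crack keeping region on the
    # matrix-right of dir (matrix-right of (di,dj) is (dj,-di)... careful:
    # in matrix coords, rows grow downward; region must stay on the side
    # that maps to the LEFT after the vertical flip)
    di <- dir[1]; dj <- dir[2]
    # pixels adjacent to the crack ahead: moving from corner (ci,cj) by dir
    # crack from pos to pos+dir separates two pixels:
    # for dir=(0,1): pixels (ci, cj+1) above and (ci+1, cj+1) below
    # for dir=(0,-1): pixels (ci, cj) above, (ci+1, cj) below
    # for dir=(1,0): pixels (ci+1, cj) left, (ci+1, cj+1) right
    # for dir=(-1,0): pixels (ci, cj) left, (ci, cj+1) right
    # We maintain: region on the matrix side such that xy orientation is CCW.
    # Turn preference: right-hand wall-follow with region kept on the
    # "upper/left-in-matrix" side.
    turns <- list(c(dj, -di), dir, c(-dj, di))  # left, straight, right (matrix)
    moved <- FALSE
    for (nd in turns) {
      npos <- pos + nd
      if (crack_has_region(pad, pos, nd, rid)) { pos <- npos; dir <- nd; moved <- TRUE; break }
    }
    if (!moved) stop("boundary trace stuck for label ", rid)
    path[[length(path) + 1L]] <- pos
    if (all(pos == path[[1]]) ) break
  }
  do.call(rbind, path)
}

# crack from corner (ci,cj) in matrix direction nd is on the region boundary
# with the region on the consistent side (region pixel on one side,
# non-region on the other); side chosen to give a consistent orientation.
crack_has_region <- function(pad, pos, nd, rid) {
  ci <- pos[1]; cj <- pos[2]
  if (nd[1] == 0L && nd[2] == 1L) {        # move +col: region below (right)
    p_in <- c(ci + 1L, cj + 1L); p_out <- c(ci, cj + 1L)
  } else if (nd[1] == 0L && nd[2] == -1L) { # move -col: region above
    p_in <- c(ci, cj); p_out <- c(ci + 1L, cj)
  } else if (nd[1] == 1L && nd[2] == 0L) {  # move +row (down): region left
    p_in <- c(ci + 1L, cj); p_out <- c(ci + 1L, cj + 1L)
  } else {                                  # move -row (up): region right
    p_in <- c(ci, cj + 1L); p_out <- c(ci, cj)
  }
  ok <- function(p) p[1] >= 1 && p[1] <= nrow(pad) && p[2] >= 1 && p[2] <= ncol(pad)
  lab_in <- if (ok(p_in)) pad[p_in[1], p_in[2]] else -1L
  lab_out <- if (ok(p_out)) pad[p_out[1], p_out[2]] else -1L
  (lab_in == rid) && (lab_out != rid)
}

#' Read a frame manifest of label images
#'
#' The manifest is a CSV with columns \code{frame}, \code{file},
#' \code{time_min}; each file is a 2D integer label image (PNG or TIFF).
#'
#' @param manifest path to the CSV manifest; image paths are resolved
#'   relative to the manifest's directory.
#' @param pixel_size micrometres per pixel.
#' @return a \code{tracked_sequence}. Requires the \pkg{png} or \pkg{tiff}
#'   package for the respective formats.
#' @export
read_label_sequence <- function(manifest, pixel_size = 1) {
  tab <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  dir <- dirname(manifest)
  frames <- lapply(order(tab$time_min), function(k) {
    f <- file.path(dir, tab$file[k])
    img <- read_label_image(f)
    mesh_from_labels(img, pixel_size = pixel_size, time = tab$time_min[k])
  })
  tracked_sequence(frames)
}

read_label_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) stop("png package required")
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    round(img * 255)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) stop("tiff package required")
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    img
  } else {
    stop("unsupported label image format: ", ext)
  }
}
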