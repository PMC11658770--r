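# Fixtures built in code, shared across test files.

# two squares sharing an edge
two_cell_mesh <- function() {
  v <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(2, 0), c(2, 1))
  rownames(v) <- as.character(1:6)
  cell_mesh(v, list(a = c("1", "2", "3", "4"), b = c("2", "5", "6", "3")))
}

# five wedge cells sharing one central vertex (rosette configuration)
rosette_mesh <- function(n = 5) {
  ang <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  v <- rbind(c(0, 0), cbind(2 * cos(ang), 2 * sin(ang)))
  rownames(v) <- as.character(seq_len(n + 1))
  cells <- lapply(seq_len(n), function(k) {
    c("1", as.character(1 + k), as.character(1 + (k %% n) + 1))
  })
  names(cells) <- paste0("w", seq_len(n))
  cell_mesh(v, cells)
}

# fast quartet parameters for simulation-heavy tests
fast_params <- function(...) {
  args <- utils::modifyList(list(tau_T = 20, t_max = 40), list(...))
  do.call(quartet_params, args)
}

# key for unordered cell pairs
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

# rasterized Voronoi label image of a point set
voronoi_label_image <- function(centers, nx = 120, lim = NULL) {
  if (is.null(lim)) lim <- range(centers) + c(-1, 1) * diff(range(centers)) * 0.3
  xs <- seq(lim[1], lim[2], length.out = nx)
  outer(seq_len(nx), seq_len(nx), Vectorize(function(i, j) {
    which.min((centers[, 1] - xs[j])^2 + (centers[, 2] - xs[i])^2)
  }))
}
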