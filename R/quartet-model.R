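# Minimal periodic cell-quartet model of T1 transitions.
#
# A representative quartet in a periodic cell array is described by three
# interface classes (central + two flanks) with active tensions T_i
# under positive feedback,
#     tau_T dT_i/dt = T_i^n - (1/3) sum_k T_k^n,
# which conserves the total active tension (finite myosin pool). Force
# balance fixes the vertex angles from the tensions (tension triangle
# complementarity); the interface lengths are the remaining, isogonal,
# degrees of freedom and follow from minimizing the cell shape energy
#     E_C = lambda * Tr(S_C - S0)^2 + mu * Tr[(S_C - S0)^2],
#     S_C = sum_i l_i e_i (x) e_i   (e_i unit interface directions)
# at fixed angles. When the central interface length reaches zero the
# kite flips: the new interface's total tension is set by the tension-
# quadrilateral diagonal, the myosin (active) part by the handover rule,
# and the passive remainder decays exponentially with timescale tau_p.

#' Model parameters for the quartet simulator
#'
#' @param tau_T tension-feedback timescale, minutes.
#' @param n feedback exponent (>= 2; default 4).
#' @param lambda,mu elastic coefficients of the shape energy (only their
#'   ratio matters while the target shape is attainable).
#' @param l0 tension-to-length scale, micrometres.
#' @param l_hex resting hexagon edge length; defaults to the
#'   Voronoi-consistent value \code{l0 / sqrt(3)} so that the uniform
#'   hexagonal state carries zero isogonal strain.
#' @param tau_p passive-tension remodeling timescale, minutes.
#' @param dl_iso target isogonal length offset (micrometres) of the run;
#'   sets the anisotropy of the target shape tensor S0 through the
#'   reference-length geometry (0 = isotropic target).
#' @param dt integrator step, minutes (default \code{1e-3 * tau_T}).
#' @param t_max simulation horizon, minutes.
#' @param eps flip threshold on the central length (default
#'   \code{1e-3 * l0}).
#' @param shear_rate prescribed centroid pure-shear rate (1/min): the
#'   driving of the passive mode, and the centroid drift of the mixed
#'   mode.
#' @param record_every record every k-th step (thins the output).
#' @return list of validated parameters with the derived target shape
#'   tensor \code{S0}.
#' @export
quartet_params <- function(tau_T = 40, n = 4, lambda = 1, mu = 1,
                           l0 = tigon_constants$l0, l_hex = l0 / sqrt(3),
                           tau_p = 2, dl_iso = 0, dt = NULL, t_max = 60,
                           eps = NULL, shear_rate = 0.02, record_every = 5L) {
  if (tau_T <= 0 || tau_p <= 0) stop("timescales must be positive")
  if (n < 2) stop("feedback exponent n must be >= 2")
  if (lambda < 0 || mu < 0 || (lambda == 0 && mu == 0)) {
    stop("lambda, mu must be non-negative and not both zero")
  }
  if (is.null(dt)) dt <- 1e-3 * tau_T
  if (is.null(eps)) eps <- 1e-3 * l0
  s_iso <- 1.5 * l_hex
  # anisotropy of S0 targets the requested dl_iso at the collapse point:
  # the S_C = S0 solve gives l_central = 0 at flank angle theta* with
  # tan(theta*)^2 = S0_yy / S0_xx, where dl_iso = -l_ref(theta*)
  #               = -l0 cos(theta*) (1 - tan(theta*)^2)
  g <- function(th) l0 * cos(th) * (1 - tan(th)^2) + dl_iso
  if (g(1e-6) <= 0) stop("dl_iso too negative: no collapse geometry")
  th_star <- stats::uniroot(g, c(1e-6, pi / 2 - 1e-6), tol = 1e-14)$root
  S0 <- diag(c(s_iso, s_iso * tan(th_star)^2))
  list(tau_T = tau_T, n = n, lambda = lambda, mu = mu, l0 = l0,
       l_hex = l_hex, tau_p = tau_p, dl_iso = dl_iso, dt = dt,
       t_max = t_max, eps = eps, shear_rate = shear_rate,
       record_every = as.integer(record_every), S0 = S0,
       theta_star = th_star)
}

#' Tension feedback rate (positive feedback on active tensions)
#'
#' \code{tau_T dT_i/dt = T_i^n - (1/3) sum_k T_k^n}: the time derivative
#' of the three active tensions. The rates sum to zero exactly, so the
#' total active tension is conserved; any tension above the mean of the
#' n-th powers grows.
#'
#' @param T numeric length-3 of positive active tensions.
#' @param params a \code{\link{quartet_params}} list (uses tau_T, n).
#' @return dT/dt, numeric length-3 summing to zero.
#' @export
tension_feedback_step <- function(T, params) {
  if (any(T <= 0)) stop("non-positive tension")
  p <- T^params$n
  (p - mean(p)) / params$tau_T
}

#' Vertex angles from total tensions
#'
#' Law of cosines on the tension triangle, complemented to pi: vertex
#' angle i (between the interfaces other than i) is
#' \code{pi - internal angle opposite tension i}. The three angles sum to
#' \code{2*pi} exactly.
#'
#' @param T numeric length-3 total tensions (central, flank1, flank2).
#' @return vertex angles (radians), \code{phi[1]} between the two flanks.
#' @export
angles_from_tensions <- function(T) {
  tri <- tryCatch(triangle_from_tensions(T[1], T[2], T[3]),
                  error = function(e)
                    stop("force balance lost: ", conditionMessage(e)))
  pi - tri$angles
}

# unit direction lines of the three interface classes.
# orientation "v": central interface vertical; "h": horizontal.
# Returns 3 x 2 matrix (central, flank1, flank2) plus the outgoing flank
# angles at the "positive" central vertex (top for "v", right for "h").
quartet_directions <- function(phi, orientation = c("v", "h")) {
  orientation <- match.arg(orientation)
  base <- if (orientation == "v") -pi / 2 else pi
  a1 <- base + phi[3]   # CCW from outgoing central by angle between c & f1
  a2 <- base - phi[2]   # CW  by angle between c & f2
  dc <- if (orientation == "v") c(0, 1) else c(1, 0)
  m <- rbind(central = dc,
             flank1 = c(cos(a1), sin(a1)),
             flank2 = c(cos(a2), sin(a2)))
  attr(m, "alpha") <- c(a1, a2)
  m
}

#' Interface lengths minimizing the cell shape energy at fixed angles
#'
#' Minimizes \code{E_C = lambda Tr(S_C - S0)^2 + mu Tr[(S_C - S0)^2]}
#' over the three lengths at the angles implied by \code{phi}. The
#' target equation \code{S_C = S0} is three linear equations in three
#' lengths and is generically solvable, so the interior minimizer is the
#' exact solve (independent of lambda, mu) whenever it is non-negative;
#' otherwise the negative length is clamped to zero and the energy is
#' minimized over the rest.
#'
#' @param phi vertex angles (from \code{\link{angles_from_tensions}}).
#' @param params a \code{\link{quartet_params}} list.
#' @param S0 target shape tensor (default \code{params$S0}).
#' @param orientation central-interface orientation, "v" or "h".
#' @return list with \code{l} (central, flank1, flank2; the central entry
#'   may be negative, signalling that the angles are past the collapse
#'   point), \code{EC}, and \code{gradient_norm} at the returned lengths.
#' @export
relax_lengths <- function(phi, params, S0 = params$S0,
                          orientation = "v") {
  dirs <- quartet_directions(phi, orientation)
  A <- vapply(1:3, function(i) {
    u <- dirs[i, ]
    c(u[1]^2, u[2]^2, u[1] * u[2])
  }, numeric(3))                      # 3 x 3, columns per interface
  b <- c(S0[1, 1], S0[2, 2], S0[1, 2])
  l <- tryCatch(as.numeric(solve(A, b)), error = function(e) NULL)
  ec_of <- function(l) {
    S <- matrix(0, 2, 2)
    for (i in 1:3) S <- S + l[i] * tcrossprod(dirs[i, ])
    D <- S - S0
    params$lambda * sum(diag(D))^2 + params$mu * sum(D^2)
  }
  grad_of <- function(l) {
    S <- matrix(0, 2, 2)
    for (i in 1:3) S <- S + l[i] * tcrossprod(dirs[i, ])
    D <- S - S0
    vapply(1:3, function(i) {
      N <- tcrossprod(dirs[i, ])
      2 * params$lambda * sum(diag(D)) * sum(diag(N)) +
        2 * params$mu * sum(D * N)
    }, numeric(1))
  }
  if (!is.null(l) && all(l[2:3] >= 0)) {
    return(list(l = l, EC = ec_of(pmax(l, 0)),
                gradient_norm = sqrt(sum(grad_of(l)^2))))
  }
  # constrained fallback: coordinate-descent quadratic minimization
  l <- c(0, params$l_hex, params$l_hex)
  for (iter in 1:200) {
    for (i in 1:3) {
      N <- tcrossprod(dirs[i, ])
      S <- matrix(0, 2, 2)
      for (j in 1:3) if (j != i) S <- S + l[j] * tcrossprod(dirs[j, ])
      D0 <- S - S0
      num <- params$lambda * sum(diag(D0)) * sum(diag(N)) + params$mu * sum(D0 * N)
      den <- params$lambda * sum(diag(N))^2 + params$mu * sum(N^2)
      l[i] <- max(0, -num / den)
    }
    g <- grad_of(l)
    pg <- ifelse(l > 0, g, pmin(g, 0))
    if (sqrt(sum(pg^2)) < 1e-10) break
  }
  list(l = l, EC = ec_of(l), gradient_norm = sqrt(sum(grad_of(l)^2)))
}

#' Myosin handover at a neighbor exchange
#'
#' Continuity of cortical myosin at vertices within each cell: each
#' interface's tension is carried half per abutting cortex, and the two
#' cortices of the emerging interface inherit the myosin of the gaining
#' cells' flank cortices at the collapsed vertex, so the active tension
#' on the new interface is the mean of the two flank tensions. At
#' collapse configurations this is below the geometrically required
#' total tension, which is what loads the passive element.
#'
#' @param T_flank1,T_flank2 flank active tensions at the flip.
#' @return active tension on the emerging interface.
#' @export
handover <- function(T_flank1, T_flank2) (T_flank1 + T_flank2) / 2

# relative-tension kite of the current state (flank mean normalized to 1)
state_kite <- function(T_total) {
  m <- mean(T_total[2:3])
  kite_from_tensions(T_total[1] / m, T_total[2] / m, T_total[3] / m,
                     T_total[2] / m, T_total[3] / m)
}

#' Simulate a cell quartet T1
#'
#' Integrates the quartet model. In \code{"active"} mode the tension
#' feedback (RK4) drives the central interface to collapse while the
#' lengths track the shape-energy minimum adiabatically. In
#' \code{"passive"} mode feedback is off, tensions stay homeostatic
#' (vertex angles fixed by force balance) and the lengths follow a
#' prescribed pure-shear displacement of the cell centroids at rate
#' \code{params$shear_rate}. \code{"mixed"} combines active feedback with
#' the prescribed centroid drift (time-dependent target shape). In every
#' mode the neighbor exchange executes the tension-kite flip, the
#' handover rule sets the emerging myosin level, and the passive tension
#' decays exponentially afterwards.
#'
#' @param mode "active", "passive" or "mixed".
#' @param params a \code{\link{quartet_params}} list.
#' @param T_init initial active tensions (central first; the central
#'   interface must start with the highest tension for a flip to occur).
#' @return object of class \code{quartet_trajectory}: data frame
#'   \code{states} (time, active tensions, passive tension, totals,
#'   relative central tension, lengths, vertex angles in degrees,
#'   reference/isogonal lengths, shape energy, topology), plus
#'   \code{flip_time}, \code{T_rel_at_flip}, \code{dl_iso_at_flip},
#'   \code{params}, \code{mode}.
#' @export
simulate_quartet <- function(mode = c("active", "passive", "mixed"),
                             params = quartet_params(),
                             T_init = c(1.05, 0.975, 0.975)) {
  mode <- match.arg(mode)
  if (mode == "passive") return(simulate_quartet_passive(params, T_init))

  dt <- params$dt
  nstep <- ceiling(params$t_max / dt)
  S0_at <- function(t) {
    if (mode == "mixed") {
      D <- diag(c(exp(params$shear_rate * t), exp(-params$shear_rate * t)))
      D %*% params$S0 %*% D
    } else params$S0
  }
  deriv <- function(T) tension_feedback_step(T, params)
  rk4 <- function(T, h) {
    k1 <- deriv(T); k2 <- deriv(T + h / 2 * k1)
    k3 <- deriv(T + h / 2 * k2); k4 <- deriv(T + h * k3)
    T + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }

  topo <- "pre"; orient <- "v"
  T <- T_init
  Tp0 <- 0; t_flip <- NA_real_
  rec <- matrix(NA_real_, nstep + 8L, 17)
  nrec <- 0L
  eval_state <- function(T, t) {
    Tp <- if (topo == "post") Tp0 * exp(-(t - t_flip) / params$tau_p) else 0
    tot <- T; tot[1] <- tot[1] + Tp
    phi <- angles_from_tensions(tot)
    rl <- relax_lengths(phi, params, S0 = S0_at(t), orientation = orient)
    kite <- state_kite(tot)
    l_ref <- voronoi_reference_length(kite, params$l0)
    list(T = T, Tp = Tp, tot = tot, phi = phi, l = rl$l, EC = rl$EC,
         T_rel = tot[1] / mean(tot[2:3]), l_ref = l_ref,
         dl_iso = rl$l[1] - l_ref, t = t)
  }
  record <- function(st) {
    nrec <<- nrec + 1L
    rec[nrec, ] <<- c(st$t, st$T, st$Tp, st$tot[1], st$T_rel, st$l,
                      st$phi * 180 / pi, st$l_ref, st$dl_iso, st$EC,
                      if (topo == "pre") 0 else 1)
  }

  st <- eval_state(T, 0)
  if (st$l[1] <= 0) stop("initial state already past collapse")
  record(st)
  t <- 0; krec <- 0L
  flip_state <- NULL
  while (t < params$t_max - 1e-12) {
    T_new <- rk4(T, dt)
    t_new <- t + dt
    st_new <- tryCatch(eval_state(T_new, t_new), error = function(e) e)
    if (inherits(st_new, "error")) {
      if (topo == "post") break   # runaway flank: next T1 is out of scope
      stop("simulation aborted at t = ", t, ": ", conditionMessage(st_new))
    }
    if (topo == "pre" && st_new$l[1] <= params$eps) {
      # refine flip time with fine substeps from the previous state
      h <- dt / 100
      Tf <- T; tf <- t; stf <- st
      while (tf < t_new + 1e-15) {
        T2 <- rk4(Tf, h); t2 <- tf + h
        st2 <- eval_state(T2, t2)
        if (st2$l[1] <= params$eps) {
          w <- (stf$l[1] - params$eps) / max(stf$l[1] - st2$l[1], 1e-300)
          t_flip <- tf + w * h
          Tf <- rk4(Tf, w * h)
          break
        }
        Tf <- T2; tf <- t2; stf <- st2
      }
      if (is.na(t_flip)) t_flip <- t_new
      flip_state <- eval_state(Tf, t_flip)
      record(flip_state)
      # execute the flip
      kite_abs <- kite_from_tensions(Tf[1], Tf[2], Tf[3], Tf[2], Tf[3])
      t_new_total <- flip_kite(kite_abs)$tensions[["central"]]
      Tmyo_new <- handover(Tf[2], Tf[3])
      Tp0 <- max(t_new_total - Tmyo_new, 0)
      T <- c(Tmyo_new, Tf[2], Tf[3])
      topo <- "post"; orient <- "h"
      t <- t_flip
      st <- eval_state(T, t)
      record(st)
      next
    }
    T <- T_new; t <- t_new; st <- st_new
    krec <- krec + 1L
    if (krec %% params$record_every == 0L || t >= params$t_max - 1e-12) record(st)
  }
  finish_trajectory(rec, nrec, t_flip, params, mode)
}

simulate_quartet_passive <- function(params, T_init = c(1, 1, 1)) {
  # constant tensions; prescribed pure-shear centroid displacement
  dt <- params$dt
  nstep <- ceiling(params$t_max / dt)
  T <- c(1, 1, 1) * mean(T_init)
  phi0 <- angles_from_tensions(T)
  th <- pi / 6
  lf0 <- params$l_hex; lc0 <- params$l_hex
  X0 <- lf0 * cos(th); Y0 <- lc0 + lf0 * sin(th)
  g <- params$shear_rate
  rec <- matrix(NA_real_, nstep + 8L, 17)
  nrec <- 0L
  Tp0 <- 0; t_flip <- NA_real_
  topo <- "pre"
  eval_state <- function(t) {
    X <- X0 * exp(g * t); Y <- Y0 * exp(-g * t)
    if (topo == "pre") {
      tot <- T; phi <- phi0
      lf <- X / cos(th); lc <- Y - X * tan(th)
      l <- c(lc, lf, lf)
    } else {
      Tp <- Tp0 * exp(-(t - t_flip) / params$tau_p)
      tot <- c(T[1] + Tp, T[2], T[3])
      phi <- angles_from_tensions(tot)
      psi_f <- acos(pmin(1, pmax(-1, tot[1] / (2 * tot[2]))))
      lf <- Y / sin(psi_f)
      lc <- X - lf * cos(psi_f)
      l <- c(lc, lf, lf)
    }
    kite <- state_kite(tot)
    l_ref <- voronoi_reference_length(kite, params$l0)
    list(T = T, Tp = if (topo == "post") tot[1] - T[1] else 0, tot = tot,
         phi = phi, l = l, EC = NA_real_, T_rel = tot[1] / mean(tot[2:3]),
         l_ref = l_ref, dl_iso = l[1] - l_ref, t = t)
  }
  record <- function(st) {
    nrec <<- nrec + 1L
    rec[nrec, ] <<- c(st$t, st$T, st$Tp, st$tot[1], st$T_rel, st$l,
                      st$phi * 180 / pi, st$l_ref, st$dl_iso, st$EC,
                      if (topo == "pre") 0 else 1)
  }
  # analytic pre-flip collapse time: Y0 e^{-gt} - X0 e^{gt} tan(th) = eps
  f <- function(t) Y0 * exp(-g * t) - X0 * exp(g * t) * tan(th) - params$eps
  if (f(params$t_max) < 0) {
    t_flip <- stats::uniroot(f, c(0, params$t_max), tol = 1e-12)$root
  }
  t <- 0; krec <- 0L
  while (t < params$t_max - 1e-12) {
    st <- eval_state(t)
    krec <- krec + 1L
    if (krec %% params$record_every == 1L) record(st)
    t_next <- t + dt
    if (topo == "pre" && !is.na(t_flip) && t_next >= t_flip) {
      record(eval_state(t_flip))
      # flip: equilateral kite diagonal at constant relative tensions
      kite_abs <- kite_from_tensions(T[1], T[2], T[3], T[2], T[3])
      t_new_total <- flip_kite(kite_abs)$tensions[["central"]]
      Tmyo_new <- handover(T[2], T[3])
      Tp0 <- max(t_new_total - Tmyo_new, 0)
      T <- c(Tmyo_new, T[2], T[3])
      topo <- "post"
      record(eval_state(t_flip + 1e-9))
      t <- t_flip + dt
      next
    }
    t <- t_next
  }
  record(eval_state(params$t_max))
  finish_trajectory(rec, nrec, t_flip, params, "passive")
}

finish_trajectory <- function(rec, nrec, t_flip, params, mode) {
  states <- as.data.frame(rec[seq_len(nrec), , drop = FALSE])
  names(states) <- c("time", "T0", "T1", "T2", "Tp", "T0_total", "T_rel",
                     "l_c", "l_1", "l_2", "phi0_deg", "phi1_deg", "phi2_deg",
                     "l_ref", "dl_iso", "EC", "post")
  states$topology <- ifelse(states$post > 0.5, "post", "pre")
  states$post <- NULL
  pre <- states[states$topology == "pre", ]
  out <- list(states = states, flip_time = t_flip,
              T_rel_at_flip = if (!is.na(t_flip)) pre$T_rel[nrow(pre)] else NA_real_,
              dl_iso_at_flip = if (!is.na(t_flip)) pre$dl_iso[nrow(pre)] else NA_real_,
              params = params, mode = mode)
  class(out) <- "quartet_trajectory"
  out
}

#' @export
print.quartet_trajectory <- function(x, ...) {
  cat("quartet_trajectory (", x$mode, " mode): ", nrow(x$states),
      " recorded states\n", sep = "")
  if (!is.na(x$flip_time)) {
    cat("  neighbor exchange at t =", signif(x$flip_time, 5), "min,",
        "relative tension", signif(x$T_rel_at_flip, 5), "\n")
  } else cat("  no neighbor exchange within horizon\n")
  invisible(x)
}

#' @export
plot.quartet_trajectory <- function(x, what = c("tension", "length"), ...) {
  what <- match.arg(what)
  s <- x$states
  if (what == "tension") {
    plot(s$time, s$T_rel, type = "l", xlab = "time (min)",
         ylab = "relative central tension", ...)
  } else {
    plot(s$time, s$l_c, type = "l", xlab = "time (min)",
         ylab = "central interface length (um)", ...)
  }
  if (!is.na(x$flip_time)) graphics::abline(v = x$flip_time, lty = 3)
  invisible(x)
}

#' Ensemble of quartet simulations
#'
#' Runs \code{n_runs} simulations with initial vertex angles jittered
#' about the symmetric 120-degree configuration (the configurable
#' stand-in for an experimental initial-angle distribution): the two
#' central-flank angles are increased by independent half-normal
#' deviates so the central interface always starts with the highest
#' tension. Fully seed-reproducible.
#'
#' @param n_runs number of runs.
#' @param seed integer seed.
#' @param mode simulation mode (see \code{\link{simulate_quartet}}).
#' @param params a \code{\link{quartet_params}} list.
#' @param angle_sd SD of the angle jitter, degrees.
#' @return object of class \code{quartet_ensemble}: list of
#'   \code{quartet_trajectory} plus the drawn initial angles.
#' @export
quartet_ensemble <- function(n_runs, seed = 1L, mode = "active",
                             params = quartet_params(), angle_sd = 5) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  runs <- vector("list", n_runs)
  angles <- matrix(NA_real_, n_runs, 3)
  for (k in seq_len(n_runs)) {
    d1 <- abs(stats::rnorm(1, 0, angle_sd)) + 0.5
    d2 <- abs(stats::rnorm(1, 0, angle_sd)) + 0.5
    phi <- c(120 - d1 - d2, 120 + d1, 120 + d2) * pi / 180
    angles[k, ] <- phi * 180 / pi
    # tension i faces the angle between the other two interfaces:
    # the central tension corresponds to the flank-flank angle phi[1]
    tens <- c(sin(phi[1]), sin(phi[3]), sin(phi[2]))
    tens <- tens / mean(tens)
    runs[[k]] <- simulate_quartet(mode, params, T_init = tens)
  }
  structure(list(runs = runs, initial_angles = angles, mode = mode,
                 params = params, seed = seed),
            class = "quartet_ensemble")
}

#' @export
print.quartet_ensemble <- function(x, ...) {
  ft <- vapply(x$runs, `[[`, numeric(1), "flip_time")
  cat("quartet_ensemble:", length(x$runs), "runs (", x$mode, "),",
      sum(!is.na(ft)), "with a neighbor exchange\n")
  invisible(x)
}
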