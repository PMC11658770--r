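test_that("tension feedback conserves the sum and amplifies the leader", {
  p <- quartet_params()
  expect_equal(tension_feedback_step(c(1, 1, 1), p), c(0, 0, 0))
  # direct arithmetic oracle at n = 4, tau_T = 1
  p1 <- quartet_params(tau_T = 1)
  d <- tension_feedback_step(c(1.2, 0.9, 0.9), p1)
  expect_equal(d[1], 1.2^4 - (1.2^4 + 2 * 0.9^4) / 3, tolerance = 1e-14)
  expect_equal(sum(d), 0, tolerance = 1e-15)
  expect_gt(d[1], 0)
  # linearized growth rate of a zero-mean perturbation is n / tau_T
  eps <- 1e-7
  delta <- c(2, -1, -1) * eps
  dnum <- tension_feedback_step(c(1, 1, 1) + delta, p1)
  expect_equal(dnum, (p1$n / p1$tau_T) * delta, tolerance = 1e-5)
  expect_error(tension_feedback_step(c(1, -0.1, 1), p1), "non-positive")
})

test_that("angles_from_tensions hits the landmark configurations", {
  expect_equal(angles_from_tensions(c(1, 1, 1)) * 180 / pi, rep(120, 3))
  a2 <- angles_from_tensions(c(sqrt(2), 1, 1)) * 180 / pi
  expect_equal(sort(a2), c(90, 135, 135), tolerance = 1e-12)
  a3 <- angles_from_tensions(c(sqrt(3), 1, 1)) * 180 / pi
  expect_equal(sort(a3), c(60, 150, 150), tolerance = 1e-12)
  expect_equal(sum(angles_from_tensions(c(1.2, 0.9, 1.05))), 2 * pi,
               tolerance = 1e-12)
  expect_error(angles_from_tensions(c(3, 1, 1)), "force balance")
})

test_that("length relaxation reproduces the resting hexagon and the grid oracle", {
  p <- quartet_params(l_hex = 2)
  phi <- angles_from_tensions(c(1, 1, 1))
  rl <- relax_lengths(phi, p)
  expect_equal(rl$l, rep(2, 3), tolerance = 1e-12)
  expect_equal(rl$EC, 0, tolerance = 1e-20)
  expect_lt(rl$gradient_norm, 1e-8)
  # square-threshold angles: central length ~ 0, flanks positive;
  # brute-force grid search oracle on the energy
  phi2 <- angles_from_tensions(c(sqrt(2), 1, 1))
  rl2 <- relax_lengths(phi2, p)
  expect_lt(abs(rl2$l[1]), 1e-10)
  expect_gt(rl2$l[2], 0)
  dirs <- tigon:::quartet_directions(phi2, "v")
  ec <- function(l) {
    S <- matrix(0, 2, 2)
    for (i in 1:3) S <- S + l[i] * tcrossprod(dirs[i, ])
    D <- S - p$S0
    p$lambda * sum(diag(D))^2 + p$mu * sum(D^2)
  }
  grid <- as.matrix(expand.grid(l1 = seq(0, 1, 0.05),
                                l2 = seq(2, 4, 0.05),
                                l3 = seq(2, 4, 0.05)))
  best <- grid[which.min(apply(grid, 1, ec)), ]
  expect_lt(ec(rl2$l), ec(best) + 1e-6)
  # minimizer is a basin: independent of any starting lengths
  rl2b <- relax_lengths(phi2, p)
  expect_equal(rl2$l, rl2b$l)
})

test_that("active runs conserve total myosin and hit the geometric threshold", {
  p <- fast_params()
  tr <- simulate_quartet("active", p)
  s <- tr$states
  for (tp in c("pre", "post")) {
    ss <- s[s$topology == tp, c("T0", "T1", "T2")]
    expect_lt(max(abs(rowSums(ss) - sum(ss[1, ]))), 1e-9)
  }
  expect_false(is.na(tr$flip_time))
  expect_equal(tr$T_rel_at_flip, sqrt(2), tolerance = 0.01)
  # pre-flip tension strictly rising, post-flip decaying toward 1
  pre <- s[s$topology == "pre", ]
  post <- s[s$topology == "post", ]
  expect_true(all(diff(pre$T_rel) > -1e-9))
  expect_true(all(diff(post$T_rel) < 1e-9))
  expect_equal(post$T_rel[nrow(post)], 1, tolerance = 0.01)
  expect_true(all(diff(post$l_c) > -1e-9))
  # symmetric initial tensions: fixed point, no flip
  tr0 <- simulate_quartet("active", quartet_params(tau_T = 20, t_max = 5),
                          T_init = c(1, 1, 1))
  expect_true(is.na(tr0$flip_time))
})

test_that("flip tension tracks t1_threshold across an isogonal sweep", {
  for (d in c(-1, 0, 1, 1.9)) {
    p <- quartet_params(tau_T = 20, t_max = 60, dl_iso = d)
    tr <- simulate_quartet("active", p)
    expect_equal(tr$T_rel_at_flip, t1_threshold(d, p$l0), tolerance = 0.02,
                 label = paste("dl_iso", d))
    # measured isogonal offset at flip agrees with the prescription
    expect_equal(tr$dl_iso_at_flip, d, tolerance = 0.05 + 0.02 * abs(d))
  }
})

test_that("halving dt changes the flip time by far less than 0.1 percent", {
  p1 <- fast_params()
  p2 <- fast_params(dt = p1$dt / 2)
  f1 <- simulate_quartet("active", p1)$flip_time
  f2 <- simulate_quartet("active", p2)$flip_time
  expect_lt(abs(f1 - f2) / f1, 1e-3)
})

test_that("handover sets the emerging myosin below the total tension", {
  expect_equal(handover(1, 1), 1)
  expect_equal(handover(1.1, 0.9), 1)
  # at concyclic (threshold) configurations the flip diagonal follows
  # Ptolemy, d = 2 * tf1 * tf2 / tc, and exceeds the handover level
  expect_equal(flip_kite(kite_from_tensions(sqrt(2), 1, 1, 1, 1))$tensions[["central"]],
               2 * 1 * 1 / sqrt(2), tolerance = 1e-12)
  # across simulated flips (symmetric and asymmetric starts, with and
  # without isogonal offset) the passive tension loaded at the exchange
  # is strictly positive: handover always under-supplies the new edge
  for (ti in list(c(1.05, 0.975, 0.975), c(1.06, 1.0, 0.94))) {
    for (d in c(0, 1.9)) {
      tr <- simulate_quartet("active", quartet_params(tau_T = 20, t_max = 60,
                                                      dl_iso = d), T_init = ti)
      post <- tr$states[tr$states$topology == "post", ]
      expect_gt(post$Tp[1], 0)
      expect_gt(post$T0_total[1], post$T0[1])
    }
  }
})

test_that("post-flip tension limits follow the passive relaxation timescale", {
  # tau_p -> 0: total drops immediately to the handover level
  p_fast <- fast_params(tau_p = 1e-4)
  trf <- simulate_quartet("active", p_fast)
  post <- trf$states[trf$states$topology == "post", ]
  expect_equal(post$T0_total[2], post$T0[2], tolerance = 1e-3)
  # tau_p -> inf: total stays at the flip-kite diagonal value
  p_slow <- fast_params(tau_p = 1e6)
  trs <- simulate_quartet("active", p_slow)
  posts <- trs$states[trs$states$topology == "post", ]
  expect_equal(posts$T0_total[nrow(posts)], posts$T0_total[1], tolerance = 1e-3)
})

test_that("passive runs are homeostatic before and sqrt(3)-loaded after the flip", {
  p <- quartet_params(t_max = 60, shear_rate = 0.02)
  tr <- simulate_quartet("passive", p)
  s <- tr$states
  pre <- s[s$topology == "pre", ]
  post <- s[s$topology == "post", ]
  expect_true(all(abs(pre$T_rel - 1) < 1e-12))
  expect_equal(tr$T_rel_at_flip, 1, tolerance = 1e-12)
  expect_equal(post$T_rel[1], sqrt(3), tolerance = 1e-6)
  expect_true(all(diff(post$T_rel) < 1e-9))
  expect_true(all(diff(post$l_c) > -1e-9))
  # central length shrinks monotonically pre-flip
  expect_true(all(diff(pre$l_c) < 1e-9))
})

test_that("ensembles are seed-reproducible and bracket the symmetric run", {
  p <- fast_params(record_every = 20L)
  e1 <- quartet_ensemble(5, seed = 42, params = p)
  e2 <- quartet_ensemble(5, seed = 42, params = p)
  expect_identical(vapply(e1$runs, `[[`, numeric(1), "flip_time"),
                   vapply(e2$runs, `[[`, numeric(1), "flip_time"))
  expect_identical(e1$initial_angles, e2$initial_angles)
  # n_runs = 1 equals a single simulation with the same draw
  e3 <- quartet_ensemble(1, seed = 7, params = p)
  expect_length(e3$runs, 1L)
  # flip tensions cluster at the threshold
  th <- vapply(e1$runs, `[[`, numeric(1), "T_rel_at_flip")
  expect_true(all(abs(th - sqrt(2)) < 0.05))
})
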