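test_that("programmed neighbor exchanges are detected exactly", {
  p <- fast_params()
  g <- generate_t1_sequence("active", p, n_pre = 6L, n_post = 4L)
  ev <- detect_events(g$sequence)
  expect_equal(nrow(ev$events), 1L)
  expect_equal(ev$events$cells_losing, paste(g$truth$losing, collapse = "|"))
  expect_equal(ev$events$cells_gaining, paste(g$truth$gaining, collapse = "|"))
  # t* = midpoint of bracketing frames = programmed flip time here
  expect_equal(ev$events$t_star_min, g$truth$flip_time, tolerance = 0.25)
  expect_false(ev$events$reversed)
  # no events in a static sequence
  g0 <- generate_t1_sequence("none", p, n_pre = 4L, n_post = 3L)
  expect_equal(nrow(detect_events(g0$sequence)$events), 0L)
})

test_that("rosettes (>= 5 cells at a vertex) are recorded", {
  m5 <- rosette_mesh(5)
  m5b <- rosette_mesh(5)
  m5b$time <- 1
  s <- tracked_sequence(list(m5, m5b))
  ev <- detect_events(s)
  expect_gt(nrow(ev$rosettes), 0L)
  expect_true(all(ev$rosettes$n_cells >= 5L))
  # a plain hexagonal sequence has none
  g0 <- generate_t1_sequence("none", fast_params(), n_pre = 2L, n_post = 1L)
  expect_equal(nrow(detect_events(g0$sequence)$rosettes), 0L)
})

test_that("untracked ids appearing mid-sequence raise a warning", {
  m1 <- pattern_mesh("uniform", 4, 4, time = 0)
  m2 <- pattern_mesh("uniform", 4, 4, time = 1)
  names(m2$cells)[1] <- "intruder"
  m2 <- cell_mesh(m2$vertices, m2$cells, time = 1)
  expect_warning(detect_events(tracked_sequence(list(m1, m2))), "untracked")
})

test_that("pooled trajectories reproduce the simulated tension dynamics", {
  p <- fast_params()
  g <- generate_t1_sequence("active", p, frame_dt = 0.25, n_pre = 12L,
                            n_post = 6L)
  ev <- detect_events(g$sequence)
  fits <- lapply(g$sequence$frames, infer_tensions)
  pool <- pool_trajectories(ev, g$sequence, fits, window = 5)
  tab <- pool$table
  coll <- tab[tab$phase == "collapsing", ]
  emer <- tab[tab$phase == "emerging", ]
  # single event: mean equals the trajectory, SD 0
  expect_true(all(coll$sd_T == 0))
  expect_true(all(tab$n == 1))
  # tension rises toward the exchange, length falls
  expect_true(all(diff(coll$mean_T) > 0))
  expect_true(all(diff(coll$mean_l) < 0))
  # emerging interface relaxes toward 1
  expect_true(all(diff(emer$mean_T) < 1e-9))
  # pooled values match the simulator at the matching offsets
  s <- g$trajectory$states
  pre <- s[s$topology == "pre", ]
  for (k in seq_len(nrow(coll))) {
    T_sim <- stats::approx(pre$time - g$truth$flip_time, pre$T_rel,
                           xout = coll$t_rel_min[k])$y
    expect_equal(coll$mean_T[k], T_sim, tolerance = 1e-4)
  }
})

test_that("pooling algebra: SEM = SD / sqrt(n); merging reproduces moments", {
  p <- fast_params(record_every = 10L)
  ens <- quartet_ensemble(6, seed = 11, params = p)
  pool <- pool_ensemble(ens, grid_dt = 0.5, window = 4)
  tab <- pool$table
  expect_equal(tab$sem_T, tab$sd_T / sqrt(tab$n))
  expect_equal(tab$sem_l, tab$sd_l / sqrt(tab$n))
  # counts do not increase away from the exchange
  coll <- tab[tab$phase == "collapsing", ]
  expect_true(all(diff(coll$n) >= 0))
  # merging two disjoint ensembles = pooling the union
  e1 <- quartet_ensemble(3, seed = 1, params = p)
  e2 <- quartet_ensemble(3, seed = 2, params = p)
  eu <- e1; eu$runs <- c(e1$runs, e2$runs)
  pu <- pool_ensemble(eu, grid_dt = 0.5, window = 4)
  # recompute directly from per-run bin means at one offset
  off <- 0 - 0.5
  vals <- unlist(lapply(eu$runs, function(run) {
    s <- run$states[run$states$topology == "pre", ]
    tr <- s$time - run$flip_time
    sel <- round(tr / 0.5) * 0.5 == off & abs(tr) <= 4
    if (any(sel)) mean(s$T_rel[sel]) else NULL
  }))
  row <- pu$table[pu$table$t_rel_min == off & pu$table$phase == "collapsing", ]
  expect_equal(row$mean_T, mean(vals), tolerance = 1e-12)
  expect_equal(row$n, length(vals))
})

test_that("threshold estimates match the geometric prediction", {
  p <- fast_params(record_every = 10L)
  ens <- quartet_ensemble(8, seed = 5, params = p)
  th <- estimate_threshold(ens)
  expect_equal(th$n, 8L)
  expect_equal(th$T_crit, t1_threshold(0, p$l0), tolerance = 0.02 * sqrt(2))
  # passive ensemble: last pre-collapse tension is 1
  trp <- simulate_quartet("passive", quartet_params(t_max = 60))
  expect_equal(trp$T_rel_at_flip, 1, tolerance = 1e-12)
  # event-based estimate from a fine-grained sequence
  g <- generate_t1_sequence("active", p, frame_dt = 0.1, n_pre = 8L,
                            n_post = 4L)
  ev <- detect_events(g$sequence)
  est <- estimate_threshold(ev, g$sequence)
  expect_equal(est$n, 1L)
  expect_equal(est$T_crit, sqrt(2), tolerance = 0.03)
})

test_that("reference tension predicts time to collapse in active tissue", {
  p <- fast_params()
  # merge several programmed quartets (disjoint lattices on a common
  # absolute time grid) into one tracked sequence
  times <- seq(0.5, 12, by = 0.5)
  d1s <- c(3, 5, 7, 9, 11)
  parts <- lapply(seq_along(d1s), function(k) {
    d <- d1s[k]
    phi <- c(120 - 2 * d, 120 + d, 120 + d) * pi / 180
    tens <- c(sin(phi[1]), sin(phi[3]), sin(phi[2]))
    generate_t1_sequence("active", p, T_init = tens / mean(tens),
                         frame_times = times)
  })
  merged <- lapply(seq_along(times), function(fi) {
    verts <- NULL; cells <- list()
    for (k in seq_along(parts)) {
      m <- parts[[k]]$sequence$frames[[fi]]
      v <- m$vertices
      v[, 1] <- v[, 1] + (k - 1) * 100
      rownames(v) <- paste0("p", k, "_", rownames(m$vertices))
      verts <- rbind(verts, v)
      loops <- lapply(m$cells, function(lp) paste0("p", k, "_", lp))
      names(loops) <- paste0("p", k, "_", names(m$cells))
      cells <- c(cells, loops)
    }
    cell_mesh(verts, cells, time = times[fi])
  })
  seqm <- tracked_sequence(merged)
  ev <- detect_events(seqm)
  expect_equal(nrow(ev$events), length(parts))
  fits <- lapply(seqm$frames, infer_tensions)
  st <- time_to_collapse_stats(ev, seqm, fits, t_ref = times[1])
  # stronger initial tension -> earlier collapse: negative rank correlation
  expect_lt(st$rho, -0.8)
  # collapsing interfaces start at higher tension than the bulk
  expect_gt(st$collapsing_tension, st$noncollapsing_tension)
  # permutation null: shuffled tensions give |rho| near 0
  coll <- st$table[st$table$collapses & !is.na(st$table$time_to_collapse), ]
  set.seed(9)
  null_rho <- replicate(100, stats::cor(sample(coll$T_ref),
                                        coll$time_to_collapse,
                                        method = "spearman"))
  expect_lt(abs(mean(null_rho)), 0.35)
})

test_that("events are classified by which mode carries the deformation", {
  p <- fast_params(shear_rate = 0.03, t_max = 60)
  for (md in c("active", "passive", "mixed")) {
    g <- generate_t1_sequence(md, p, frame_dt = 0.25, n_pre = 10L, n_post = 4L)
    ev <- detect_events(g$sequence)
    cl <- classify_active_passive(ev$events[1, ], g$sequence)
    expect_equal(cl$label, md, label = paste("mode", md))
  }
  # too-short trajectories are unclassified
  gshort <- generate_t1_sequence("active", p, n_pre = 2L, n_post = 2L)
  evs <- detect_events(gshort$sequence)
  cls <- classify_active_passive(evs$events[1, ], gshort$sequence)
  expect_equal(cls$label, "unclassified")
})
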