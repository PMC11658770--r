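test_that("tension triangles encode force balance and complementarity", {
  tri <- triangle_from_tensions(1, 1, 1)
  expect_equal(tri$angles, rep(pi / 3, 3))
  expect_equal(tri$vertex_angles, rep(2 * pi / 3, 3))
  tri3 <- triangle_from_tensions(sqrt(3), 1, 1)
  expect_equal(sort(tri3$angles * 180 / pi), c(30, 30, 120), tolerance = 1e-12)
  expect_equal(sort(tri3$vertex_angles * 180 / pi), c(60, 150, 150),
               tolerance = 1e-12)
  tri2 <- triangle_from_tensions(sqrt(2), 1, 1)
  expect_equal(sort(tri2$vertex_angles * 180 / pi), c(90, 135, 135),
               tolerance = 1e-12)
  expect_equal(sum(tri2$angles), pi)
  # the embedded coordinates close the triangle with the right side lengths
  xy <- tri3$xy
  sides <- c(sqrt(sum((xy[2, ] - xy[3, ])^2)), sqrt(sum((xy[1, ] - xy[3, ])^2)),
             sqrt(sum((xy[1, ] - xy[2, ])^2)))
  expect_equal(sides, tri3$tensions, tolerance = 1e-14)
  expect_error(triangle_from_tensions(3, 1, 1), "triangle inequality")
})

test_that("Voronoi reference length matches the closed form and circumcenters", {
  # two unit equilateral triangles at l0 = 1: cot(60 deg)
  k <- kite_from_tensions(1, 1, 1, 1, 1)
  expect_equal(voronoi_reference_length(k, 1), 1 / tan(pi / 3),
               tolerance = 1e-14)
  # symmetric isosceles family: l0 * T * cot(phi), T = 2 sin(phi/2)
  for (phi_deg in c(40, 60, 80, 90, 110, 130)) {
    phi <- phi_deg * pi / 180
    T <- 2 * sin(phi / 2)
    kk <- kite_from_tensions(T, 1, 1, 1, 1)
    expect_equal(voronoi_reference_length(kk, 2.5), 2.5 * T / tan(phi),
                 tolerance = 1e-12, label = paste("phi", phi_deg))
  }
  # sign: zero at the square configuration, negative past it
  expect_equal(voronoi_reference_length(kite_from_tensions(sqrt(2), 1, 1, 1, 1), 1),
               0, tolerance = 1e-12)
  expect_lt(voronoi_reference_length(kite_from_tensions(2 * sin(pi / 3), 1, 1, 1, 1), 1), 0)
  # zero iff concyclic: direct circumcircle test on an asymmetric kite
  ka <- kite_from_tensions(1.3, 1.0, 1.1, 0.9, 1.2)
  cc <- tigon:::circumcenter(ka$shared[1, ], ka$shared[2, ], ka$apex[1, ])
  r <- sqrt(sum((cc - ka$shared[1, ])^2))
  d4 <- sqrt(sum((cc - ka$apex[2, ])^2))
  concyclic <- abs(d4 - r) < 1e-12
  expect_equal(abs(voronoi_reference_length(ka, 1)) < 1e-12, concyclic)
})

test_that("t1_threshold solves the symmetric relation", {
  expect_equal(t1_threshold(0), sqrt(2), tolerance = 1e-10)
  # isogonal contraction equal to the hexagonal reference length: T = 1
  expect_equal(t1_threshold(-4.2 / tan(pi / 3), l0 = 4.2), 1, tolerance = 1e-9)
  # strictly increasing over a sampled grid
  dl <- seq(-2, 3, by = 0.1)
  tc <- t1_threshold(dl, l0 = 4.2)
  expect_true(all(diff(tc) > 0))
  expect_true(all(tc[dl > 0] > sqrt(2)))
  # out of range
  expect_error(t1_threshold(-5, l0 = 4.2), "no T1 threshold")
})

test_that("kite flip takes the other diagonal and is an involution", {
  expect_equal(flip_kite(kite_from_tensions(1, 1, 1, 1, 1))$tensions[["central"]],
               sqrt(3), tolerance = 1e-14)
  # square kite is self-dual
  expect_equal(flip_kite(kite_from_tensions(sqrt(2), 1, 1, 1, 1))$tensions[["central"]],
               sqrt(2), tolerance = 1e-12)
  # involution and outer-side preservation on random convex kites
  set.seed(7)
  n_ok <- 0L
  while (n_ok < 20L) {
    tens <- exp(stats::rnorm(5, 0, 0.25))
    k <- tryCatch(kite_from_tensions(tens[1], tens[2], tens[3], tens[4], tens[5]),
                  error = function(e) NULL)
    if (is.null(k)) next
    f <- tryCatch(flip_kite(k), error = function(e) NULL)
    if (is.null(f)) next
    n_ok <- n_ok + 1L
    expect_equal(flip_kite(f)$tensions[["central"]], k$tensions[["central"]],
                 tolerance = 1e-10)
    expect_equal(unname(sort(f$tensions[-1])), unname(sort(k$tensions[-1])),
                 tolerance = 1e-10)
  }
})

test_that("LTC shape coordinates hit the landmark triangles", {
  expect_equal(unlist(ltc_shape(triangle_from_tensions(1, 1, 1))[c("a", "b")]),
               c(a = 0, b = -0.5), tolerance = 1e-12)
  # right isosceles: b = 0
  expect_equal(ltc_shape(triangle_from_tensions(sqrt(2), 1, 1))$b, 0,
               tolerance = 1e-12)
  # obtuse isosceles (sqrt(3), 1, 1): theta_max = 120 -> b = 0.5,
  # a against an explicit gyration-tensor oracle
  tri <- triangle_from_tensions(sqrt(3), 1, 1)
  sh <- ltc_shape(tri)
  expect_equal(sh$b, 0.5, tolerance = 1e-12)
  X <- sweep(tri$xy, 2, colMeans(tri$xy))
  ev <- eigen(crossprod(X) / 3, symmetric = TRUE, only.values = TRUE)$values
  a_oracle <- (sqrt(ev[1]) - sqrt(ev[2])) / (sqrt(ev[1]) + sqrt(ev[2]))
  expect_equal(sh$a, a_oracle, tolerance = 1e-12)
})

test_that("LTC shape is invariant under similarity transforms and relabeling", {
  set.seed(12)
  for (rep in 1:25) {
    tens <- sort(exp(stats::rnorm(3, 0, 0.3)), decreasing = TRUE)
    if (tens[1] >= tens[2] + tens[3]) next
    tri <- triangle_from_tensions(tens[1], tens[2], tens[3])
    sh0 <- ltc_shape(tri)
    th <- stats::runif(1, 0, 2 * pi); sc <- exp(stats::runif(1, -1, 1))
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    xy2 <- sc * tri$xy %*% t(R) + matrix(stats::rnorm(2), 3, 2, byrow = TRUE)
    perm <- sample(3)
    sh2 <- ltc_shape(xy2[perm, ])
    expect_equal(sh2$a, sh0$a, tolerance = 1e-10)
    expect_equal(sh2$b, sh0$b, tolerance = 1e-10)
  }
})

test_that("LTC statistics separate ordered and disordered patterns", {
  m <- pattern_mesh("uniform", 5, 5)
  st <- ltc_statistics(m)
  expect_equal(st$bridge_fraction, 0)
  expect_equal(st$median_b, -0.5, tolerance = 1e-10)
  expect_true(all(abs(st$table$a) < 1e-10))

  mb <- pattern_mesh("alternating_bridge", 5, 5, eps = 0.3)
  stb <- ltc_statistics(mb)
  expect_gt(stb$bridge_fraction, 0.5)

  mc <- pattern_mesh("cable", 5, 5, eps = 0.3)
  stc <- ltc_statistics(mc)
  expect_equal(stc$bridge_fraction, 0)
  expect_lt(stc$median_b, 0)
})

test_that("random Delaunay baseline is reproducible and well-separated", {
  b1 <- random_delaunay_baseline(400, seed = 5)
  b2 <- random_delaunay_baseline(400, seed = 5)
  expect_identical(b1$table, b2$table)
  expect_gt(nrow(b1$table), 100L)
  # disorder vs order: KS distance on the b marginal vs uniform lattice
  lat <- ltc_statistics(pattern_mesh("uniform", 6, 6))
  ks <- suppressWarnings(stats::ks.test(b1$table$b, lat$table$b))
  expect_gt(unname(ks$statistic), 0.5)
})
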