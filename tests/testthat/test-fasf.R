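test_that("centre initialisation follows the quantile rule and is seeded", {
  vals <- 0:99
  cen <- init_centers(vals, 2, method = "quantile")
  expect_equal(as.vector(cen),
               as.vector(stats::quantile(vals, c(0.25, 0.75))),
               tolerance = 1e-12)
  # exactly c distinct values: the centres are those values, sorted
  expect_equal(as.vector(init_centers(c(5, 1, 3), 3)), c(1, 3, 5))
  expect_error(init_centers(c(1, 1, 1), 2), "distinct")
  k1 <- init_centers(runif(50), 3, seed = 9, method = "kmeanspp")
  k2 <- init_centers(runif(50), 3, seed = 9, method = "kmeanspp")
  # seeding controls the kmeans++ draw, not the data here
  set.seed(9); v <- runif(50)
  expect_identical(init_centers(v, 3, seed = 4, method = "kmeanspp"),
                   init_centers(v, 3, seed = 4, method = "kmeanspp"))
})

test_that("fuzzy membership update matches hand-evaluated cases", {
  # x = 0.25 between centres {0, 1}, M = 2: U = (0.9, 0.1)
  U <- update_fuzzy_memberships(0.25, c(0, 1), 2)
  expect_equal(as.vector(U), c(0.9, 0.1), tolerance = 1e-9)
  # voxel exactly at a centre
  U0 <- update_fuzzy_memberships(0, c(0, 1), 2)
  expect_equal(as.vector(U0), c(1, 0))
  # symmetric midpoint
  Um <- update_fuzzy_memberships(0.5, c(0, 1), 2)
  expect_equal(as.vector(Um), c(0.5, 0.5))
  expect_error(update_fuzzy_memberships(0.5, c(0, 1), 1), "M")
  # conservation across random cases
  set.seed(3)
  for (i in 1:5) {
    U <- update_fuzzy_memberships(runif(40), sort(runif(3)), 1.5 + runif(1))
    expect_equal(rowSums(U), rep(1, 40), tolerance = 1e-9)
    expect_true(all(U >= 0 & U <= 1))
  }
})

test_that("possibilistic membership matches its closed form", {
  expect_equal(as.vector(update_possibilistic_memberships(0, 0, 2, 1)), 1)
  expect_equal(as.vector(update_possibilistic_memberships(1, 0, 3, 1)), 0.5)
  # D = 2*eta, Q = 2 -> alpha = 1/(1+4) = 0.2
  expect_equal(as.vector(update_possibilistic_memberships(2, 0, 2, 1)), 0.2)
  expect_error(update_possibilistic_memberships(1, 0, 2, 0), "eta")
})

test_that("eta estimation matches the weighted-mean-distance formula", {
  # toy: values {0, 2}, centre 1, U = 1, M = 2 -> eta = (1 + 1)/2 = 1
  U <- matrix(1, 2, 1)
  expect_equal(estimate_eta(U, c(0, 2), 1, 2), 1)
  # homogeneity: scaling intensities by s scales eta by s^2
  set.seed(5)
  v <- runif(30); V <- c(0.2, 0.8)
  U2 <- update_fuzzy_memberships(v, V, 2)
  e1 <- estimate_eta(U2, v, V, 2)
  e2 <- estimate_eta(U2, 3 * v, 3 * V, 2)
  expect_equal(e2, 9 * e1, tolerance = 1e-9)
  # degenerate cluster: all voxels at centres
  Ud <- diag(2)
  expect_error(estimate_eta(Ud, c(0, 1), c(0, 1), 2), "degenerate")
  expect_equal(estimate_eta(Ud, c(0, 1), c(0, 1), 2,
                            floor_degenerate = TRUE), c(1e-6, 1e-6))
})

test_that("objective matches a brute-force term-by-term sum", {
  vals <- c(0.1, 0.9)
  V <- c(0.2, 0.7)
  U <- matrix(c(0.8, 0.3, 0.2, 0.7), 2, 2)
  A <- matrix(c(0.9, 0.4, 0.1, 0.6), 2, 2)
  M <- 2; Q <- 2
  brute <- 0
  for (i in 1:2) for (cc in 1:2) {
    D2 <- (vals[i] - V[cc])^2
    brute <- brute + U[i, cc]^M * D2 + A[i, cc]^Q * D2
  }
  expect_equal(fpcm_objective(U, A, vals, V, M, Q), brute, tolerance = 1e-12)
  # zero at perfect fit
  expect_equal(fpcm_objective(diag(2), diag(2), c(0, 2), c(0, 2), 2, 2), 0)
})

test_that("centre update is the joint-membership-weighted mean", {
  U <- matrix(c(0.8, 0.2), 2, 1)
  A <- matrix(1, 2, 1)
  # exponents M = Q = 1 would give 2.0 for weights {0.8, 0.2} on {0, 10};
  # with the squared exponents used here, weights {0.64, 0.04}
  V <- update_centers(U, A, c(0, 10), 2, 2)
  expect_equal(as.vector(V), 10 * 0.2^2 / (0.8^2 + 0.2^2))
  # equal weights -> arithmetic mean
  Ue <- matrix(0.5, 4, 1); Ae <- matrix(0.5, 4, 1)
  expect_equal(as.vector(update_centers(Ue, Ae, 1:4, 2, 2)), 2.5)
  expect_error(update_centers(matrix(0, 2, 1), matrix(0, 2, 1), c(0, 1),
                              2, 2), "degenerate")
})

test_that("fpcm_segment recovers a separable two-class mixture", {
  ok <- 0
  for (seed in 1:20) {
    set.seed(seed)
    n <- 800
    vals <- c(stats::rnorm(n, 0.25, 0.03), stats::rnorm(n, 0.75, 0.03))
    truth <- rep(1:2, each = n)
    r <- fpcm_segment(vals, params = list(c = 2, seed = seed))
    good <- all(abs(r$state$V[, 1] - c(0.25, 0.75)) < 0.02) &&
      mean(r$label_vector == truth) >= 0.99 &&
      all(diff(r$state$objective_trace) <= 1e-9)
    ok <- ok + good
  }
  expect_gte(ok, 19)
})

test_that("fpcm_segment contracts: c = 1, determinism, state invariants", {
  set.seed(2)
  vals <- runif(200)
  r1 <- fpcm_segment(vals, params = list(c = 1))
  expect_true(all(r1$label_vector == 1))
  r <- fpcm_segment(vals, params = list(c = 3, seed = 5))
  r2 <- fpcm_segment(vals, params = list(c = 3, seed = 5))
  expect_identical(r$state$U, r2$state$U)
  expect_identical(r$state$V, r2$state$V)
  expect_equal(rowSums(r$state$U), rep(1, 200), tolerance = 1e-9)
  expect_true(all(r$state$A > 0 & r$state$A <= 1))
  expect_false(is.unsorted(r$state$V[, 1]))   # ascending-centre labelling
})

test_that("near-crisp memberships emerge as M approaches 1", {
  set.seed(8)
  vals <- c(stats::rnorm(300, 0.2, 0.02), stats::rnorm(300, 0.8, 0.02))
  r <- fpcm_segment(vals, params = list(c = 2, M = 1.05))
  expect_gte(min(apply(r$state$U, 1, max)), 0.99)
})

test_that("volume segmentation labels out-of-mask voxels 0", {
  ph <- make_phantom(shape = c(24, 24, 12), seed = 6)
  ss <- skull_strip(ph$vol)
  seg <- fpcm_segment(ss$vol, mask = ss$mask, params = list(c = 3))
  expect_true(all(seg$labels$labels[!ss$mask$mask] == 0))
  expect_true(all(seg$labels$labels[ss$mask$mask] %in% 1:3))
  # recovered centres close to the three class means
  expect_equal(seg$state$V[, 1], c(0.25, 0.5, 0.75), tolerance = 0.05)
})

test_that("atlas labelling matches a brute-force per-voxel oracle", {
  shape <- c(5, 5, 5)
  set.seed(7)
  atl_lab <- label_volume(array(sample(0:3, prod(shape), TRUE), shape),
                          legend = c(`1` = "r1", `2` = "r2", `3` = "r3"))
  seg <- label_volume(array(1L, shape), legend = c(`1` = "tissue"))
  for (aff in list(diag(4),
                   matrix(c(1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 1, 0, 1, 0, 0, 1),
                          4, 4))) {   # identity and +1 x-translation
    res <- aal_label(seg, atlas_ref(atl_lab, affine_h = aff))
    oracle <- array(0L, shape)
    for (x in 0:(shape[1] - 1)) for (y in 0:(shape[2] - 1)) {
      for (z in 0:(shape[3] - 1)) {
        p <- aff %*% c(x, y, z, 1)
        q <- round(p[1:3])
        oracle[x + 1, y + 1, z + 1] <-
          if (all(q >= 0) && all(q < shape)) {
            atl_lab$labels[q[1] + 1, q[2] + 1, q[3] + 1]
          } else 0L
      }
    }
    expect_identical(res$regions$labels, oracle)
  }
})

test_that("atlas labelling stats count (region x tissue) voxels", {
  atl <- make_toy_atlas(c(16, 16, 8), n_regions = 3)
  ph <- make_phantom(shape = c(16, 16, 8), seed = 1)
  res <- aal_label(ph$truth, atl)
  for (i in seq_len(nrow(res$stats))) {
    expect_equal(res$stats$voxels[i],
                 sum(res$regions$labels == res$stats$region_id[i] &
                       ph$truth$labels == res$stats$tissue[i]))
  }
  # empty segmentation -> all-zero stats
  empty <- label_volume(array(0L, c(16, 16, 8)))
  res0 <- aal_label(empty, atl)
  expect_true(all(res0$stats$voxels == 0))
})

test_that("region masks are disjoint, cover their ids, and reject unknowns", {
  atl <- make_toy_atlas(c(16, 16, 8), n_regions = 4)
  ids <- as.integer(names(atl$legend))
  masks <- region_masks(atl$labels, ids)
  un <- Reduce(`|`, masks)
  expect_equal(un, atl$labels$labels > 0)
  for (i in seq_along(masks)) for (j in seq_along(masks)) {
    if (i < j) expect_false(any(masks[[i]] & masks[[j]]))
  }
  expect_error(region_masks(atl$labels, 99), "known ids")
})
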