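test_that("LBP codes match hand-evaluated patterns", {
  # alternating neighbours {1,9,1,9,...} clockwise from top-left, centre 5
  img <- matrix(0, 3, 3)
  offs <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
                c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  nb <- c(1, 9, 1, 9, 1, 9, 1, 9)
  img[2, 2] <- 5
  for (n in 1:8) img[2 + offs[n, 1], 2 + offs[n, 2]] <- nb[n]
  h <- lbp_histogram(img)
  expect_equal(which(h > 0) - 1, 170)
  # constant image: every comparison >= 0 -> code 255
  hc <- lbp_histogram(matrix(4, 6, 6))
  expect_equal(which(hc > 0) - 1, 255)
  expect_equal(sum(hc), 1)
})

test_that("LBP histogram is invariant under positive affine intensity maps", {
  set.seed(11)
  img <- matrix(runif(400), 20, 20)
  h0 <- lbp_histogram(img)
  expect_equal(lbp_histogram(img + 7), h0)
  expect_equal(lbp_histogram(3 * img + 1), h0)
  expect_equal(sum(h0), 1, tolerance = 1e-9)
  # empty interior
  expect_warning(he <- lbp_histogram(img, matrix(FALSE, 20, 20)), "empty")
  expect_true(all(he == 0))
})

test_that("colour moments match the printed population formulas", {
  expect_equal(unname(color_moments(c(0, 0, 3, 3))), c(1.5, 2.25, 0))
  expect_equal(unname(color_moments(c(0, 0, 0, 4))), c(1, 3, 6))
  expect_equal(unname(color_moments(rep(2.5, 9))), c(2.5, 0, 0))
  expect_error(color_moments(numeric(0)), "empty")
})

test_that("shape features match hand counts on a 4x5 rectangle", {
  m <- matrix(FALSE, 8, 9); m[2:5, 2:6] <- TRUE
  sf <- shape_features(m)
  expect_equal(unname(sf["area"]), 20)
  expect_equal(unname(sf["perimeter"]), 14)
  expect_equal(unname(sf["compactness"]), 196 / 20)
  # single pixel: degenerate conventions
  s1 <- shape_features(matrix(c(FALSE, TRUE, FALSE, FALSE), 2, 2))
  expect_equal(unname(s1), c(1, 1, 0, 1))
  expect_error(shape_features(matrix(FALSE, 3, 3)), "empty")
})

test_that("eccentricity separates round from elongated shapes", {
  sq <- matrix(FALSE, 12, 12); sq[3:10, 3:10] <- TRUE
  line <- matrix(FALSE, 3, 12); line[2, 2:9] <- TRUE
  expect_equal(unname(shape_features(sq)["eccentricity"]), 0)
  expect_gte(unname(shape_features(line)["eccentricity"]), 0.99)
  expect_lt(unname(shape_features(line)["eccentricity"]), 1)
  # disk vs line compactness ordering
  d <- matrix(FALSE, 20, 20)
  ij <- expand.grid(1:20, 1:20)
  d[as.matrix(ij[(ij[, 1] - 10)^2 + (ij[, 2] - 10)^2 <= 64, ])] <- TRUE
  kline <- matrix(FALSE, 3, 14); kline[2, 2:13] <- TRUE
  expect_lt(unname(shape_features(d)["compactness"]),
            unname(shape_features(kline)["compactness"]))
})

test_that("shape features agree with a brute-force counting oracle", {
  set.seed(13)
  for (rep in 1:5) {
    m <- matrix(runif(24 * 24) < 0.4, 24, 24)
    if (!any(m)) next
    sf <- shape_features(m)
    comp <- fasftle:::largest_component(m)
    area <- sum(comp)
    per <- 0
    for (i in 1:24) for (j in 1:24) {
      if (!comp[i, j]) next
      nb <- c(
        if (i > 1) comp[i - 1, j] else FALSE,
        if (i < 24) comp[i + 1, j] else FALSE,
        if (j > 1) comp[i, j - 1] else FALSE,
        if (j < 24) comp[i, j + 1] else FALSE)
      if (!all(nb)) per <- per + 1
    }
    expect_equal(unname(sf["area"]), area)
    expect_equal(unname(sf["perimeter"]), per)
  }
})

test_that("feature extraction flattens regions deterministically", {
  ph <- make_phantom(shape = c(24, 24, 12), seed = 3)
  atl <- make_toy_atlas(c(24, 24, 12), n_regions = 2)
  masks <- region_masks(atl$labels, c(1, 2))
  t1 <- extract_features(ph$vol, masks, sample_id = "a")
  t2 <- extract_features(ph$vol, masks, sample_id = "a")
  expect_identical(t1, t2)
  expect_equal(length(ft_names(t1)), 2 * (256 + 3 + 4))
  expect_true(all(grepl("^r[12]_", ft_names(t1))))
  # planted elongated vs round region ordering of eccentricity
  roundm <- array(FALSE, c(24, 24, 12))
  ij <- expand.grid(1:24, 1:24)
  disk <- matrix(FALSE, 24, 24)
  disk[as.matrix(ij[(ij[, 1] - 12)^2 + (ij[, 2] - 12)^2 <= 25, ])] <- TRUE
  roundm[, , 6] <- disk
  longm <- array(FALSE, c(24, 24, 12))
  bar <- matrix(FALSE, 24, 24); bar[12, 4:20] <- TRUE
  longm[, , 6] <- bar
  te <- extract_features(ph$vol, list(`1` = roundm, `2` = longm))
  expect_gt(te$r2_eccentricity, te$r1_eccentricity)
  # absent region -> NA sentinels with a warning
  expect_warning(
    tm <- extract_features(ph$vol, list(`1` = roundm,
                                        `9` = array(FALSE, c(24, 24, 12)))),
    "empty")
  expect_true(all(is.na(tm$r9_m1)))
  expect_false(anyNA(tm$r1_m1))
})
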