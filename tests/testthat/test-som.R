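sched_fixed <- function(sigma0 = 2, lam = 10, learn0 = 0.5, n_iter = 100,
                        seed = 1) {
  s <- som_schedule(sigma0 = sigma0, lam = lam, learn0 = learn0, seed = seed)
  s$n_iter <- n_iter
  s
}

rand_lattice <- function(rows, cols, nv, seed = 1) {
  set.seed(seed)
  brainlattice:::new_lattice(rows, cols, matrix(rnorm(rows * cols * nv),
                                                rows * cols, nv))
}

test_that("neighborhood width follows the exponential decay", {
  s <- sched_fixed(sigma0 = 11, lam = 10)
  expect_equal(som_sigma(0, s), 11)                  # exp(0) = 1
  expect_equal(som_sigma(10, s), 11 * exp(-1))       # ~ 4.04664
  expect_equal(som_sigma(10, s), 4.04664, tolerance = 1e-5)
  tt <- 0:50
  expect_true(all(diff(som_sigma(tt, s)) < 0))       # strictly decreasing
  expect_true(all(diff(som_learn(tt, s)) < 0))
})

test_that("find_bmu equals an exhaustive scan and breaks ties lexicographically", {
  lat <- rand_lattice(3, 3, 12)
  # exact-match node wins with distance 0
  v <- lat$weights[5, ]
  expect_equal(find_bmu(v, lat), 5L)

  set.seed(2)
  for (i in 1:20) {
    v <- rnorm(12)
    d <- apply(lat$weights, 1, function(w) sqrt(sum((w - v)^2)))
    expect_equal(find_bmu(v, lat), which.min(d))
  }

  # two equidistant nodes: the lower (row, col) index wins
  lat2 <- brainlattice:::new_lattice(2, 2, rbind(c(1, 0), c(0, 1),
                                                 c(1, 0), c(0, 1)))
  expect_equal(find_bmu(c(0.5, 0.5), lat2), 1L)
  expect_error(find_bmu(rnorm(5), lat), "length")
})

test_that("the weight update is the printed convex step", {
  nv <- 4
  lat <- rand_lattice(1, 1, nv)
  v <- rnorm(nv)

  # learning rate 1 jumps straight to the training vector
  s1 <- sched_fixed(sigma0 = 1, lam = 1e9, learn0 = 1)
  lat1 <- update_weights(lat, v, 1, t = 0, s1)
  expect_equal(unname(lat1$weights[1, ]), v)

  # learning rate ~0 leaves weights unchanged
  s0 <- sched_fixed(learn0 = 1e-12)
  lat0 <- update_weights(lat, v, 1, t = 0, s0)
  expect_equal(lat0$weights, lat$weights, tolerance = 1e-9)

  # W = 0, v = 2, L = 0.5 -> W becomes 1
  latz <- brainlattice:::new_lattice(1, 1, matrix(0, 1, nv))
  sh <- sched_fixed(sigma0 = 1, lam = 1e9, learn0 = 0.5)
  latz <- update_weights(latz, rep(2, nv), 1, t = 0, sh)
  expect_equal(unname(latz$weights[1, ]), rep(1, nv))

  # only nodes within sigma of the BMU move; below sigma = 1 only the BMU
  lat3 <- rand_lattice(3, 3, nv, seed = 3)
  s <- sched_fixed(sigma0 = 0.5, lam = 1e9, learn0 = 0.5)
  lat3u <- update_weights(lat3, v, 5, t = 0, s)
  moved <- rowSums(lat3u$weights != lat3$weights) > 0
  expect_equal(which(moved), 5L)

  # sigma = 1 moves the BMU and its 4-neighborhood on the grid
  s2 <- sched_fixed(sigma0 = 1, lam = 1e9, learn0 = 0.5)
  lat3v <- update_weights(lat3, v, 5, t = 0, s2)
  moved2 <- which(rowSums(lat3v$weights != lat3$weights) > 0)
  expect_setequal(moved2, c(2L, 4L, 5L, 6L, 8L))
})

test_that("weights stay inside the data/init bounding box", {
  set.seed(5)
  X <- matrix(rnorm(8 * 6), 8, 6)
  sched <- som_schedule(seed = 9)
  lat <- train_som(X, dims = c(2, 3), sched = sched)
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  # initialization is inside [lo, hi], and every update is a convex
  # combination with a training vector, so the box is invariant
  expect_true(all(sweep(lat$weights, 2, lo, ">=")))
  expect_true(all(sweep(lat$weights, 2, hi, "<=")))
})

test_that("training contracts to the data and is reproducible", {
  # single training vector on a 1x1 grid: geometric contraction to v
  v <- c(2, -1, 3, 0.5)
  X <- matrix(v, 1, byrow = TRUE)
  lat <- train_som(X, dims = c(1, 1),
                   sched = som_schedule(sigma0 = 1.5, learn0 = 0.5, seed = 1))
  expect_lt(max(abs(lat$weights[1, ] - v)), 1e-3)

  # two far-apart clusters, 1x2 grid: nodes specialize to the centroids
  set.seed(6)
  c1 <- matrix(rnorm(5 * 4, mean = 10, sd = 0.2), 5, 4)
  c2 <- matrix(rnorm(5 * 4, mean = -10, sd = 0.2), 5, 4)
  X2 <- rbind(c1, c2)
  lat2 <- train_som(X2, dims = c(1, 2), sched = som_schedule(seed = 2))
  cent <- rbind(colMeans(c1), colMeans(c2))
  d <- as.matrix(stats::dist(rbind(lat2$weights, cent)))[1:2, 3:4]
  assign1 <- unname(which.min(d[1, ])); assign2 <- unname(which.min(d[2, ]))
  expect_equal(sort(c(assign1, assign2)), c(1L, 2L))
  expect_lt(d[1, assign1], d[1, 3 - assign1])
  expect_lt(d[2, assign2], d[2, 3 - assign2])

  # determinism under the seed
  lat3 <- train_som(X2, dims = c(1, 2), sched = som_schedule(seed = 2))
  expect_identical(lat2$weights, lat3$weights)

  # no-resampling constraint: more nodes than maps is refused
  expect_error(train_som(X2, dims = c(4, 4)), "resampl")
  expect_silent(train_som(X2, dims = c(4, 4), allow_resample = TRUE,
                          sched = som_schedule(seed = 1, n_iter = 50L)))

  # every training map is assigned to exactly one node label
  expect_equal(sort(unlist(lat2$labels)),
               sort(sprintf("map_%03d", 1:10)))
})

test_that("node volumes and lattice serialization round-trip", {
  g <- ellipsoid_grid(c(8, 8, 8), 8)
  set.seed(3)
  X <- matrix(rnorm(4 * g$n_voxels), 4, g$n_voxels,
              dimnames = list(sprintf("t%d", 1:4), NULL))
  lat <- train_som(X, dims = c(2, 2), sched = som_schedule(seed = 4))
  vol <- node_volume(lat, 3, g)
  expect_equal(dim(vol), g$dim)
  expect_equal(vectorize(vol, g), unname(lat$weights[3, ]))
  expect_true(all(vol[!g$mask] == 0))

  dir <- withr::local_tempdir()
  write_lattice(lat, dir)
  lat2 <- read_lattice(dir)
  expect_equal(lat2$weights, lat$weights, tolerance = 1e-6)
  expect_equal(lat2$rows, lat$rows)
  expect_equal(lat2$labels[vapply(lat$labels, length, 0L) > 0],
               lat$labels[vapply(lat$labels, length, 0L) > 0])
})
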