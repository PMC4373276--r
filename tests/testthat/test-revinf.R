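test_that("contingency counts the four activity-by-membership cells", {
  expect_equal(contingency(c(1, 1, 1), c(TRUE, TRUE, TRUE)),
               c(a = 3L, b = 0L, c = 0L, d = 0L))
  expect_equal(contingency(c(1, 1, 0, 0), c(TRUE, FALSE, TRUE, FALSE)),
               c(a = 1L, b = 1L, c = 1L, d = 1L))
  set.seed(20)
  v <- sample(0:1, 20, replace = TRUE)
  m <- sample(c(TRUE, FALSE), 20, replace = TRUE)
  oracle <- c(a = sum(v == 1 & m), b = sum(v == 1 & !m),
              c = sum(v == 0 & m), d = sum(v == 0 & !m))
  expect_equal(contingency(v, m), oracle, ignore_attr = TRUE)
  expect_error(contingency(c(1, 0), c(TRUE, TRUE, FALSE)), "length")
})

test_that("chi_square matches the Pearson formula, with declared edge cases", {
  # perfect independence
  r <- chi_square(c(5, 5, 5, 5))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$direction, 0)

  # hand-computed: expected cells all 5, sum (O-E)^2/E = 4 * 9/5 = 7.2
  r2 <- chi_square(c(8, 2, 2, 8))
  expect_equal(r2$statistic, 7.2)
  expect_equal(r2$direction, 1)

  # permuting the diagonal flips direction, not the statistic
  r3 <- chi_square(c(10, 0, 0, 10)); r4 <- chi_square(c(0, 10, 10, 0))
  expect_equal(r3$statistic, r4$statistic)
  expect_equal(r3$direction, 1)
  expect_equal(r4$direction, -1)

  # zero marginal: no test possible
  r5 <- chi_square(c(0, 0, 5, 5))
  expect_true(is.na(r5$statistic))
  expect_equal(r5$p_value, 1)
  expect_equal(r5$direction, 0)
})

test_that("chi_square agrees with stats::chisq.test on random tables", {
  set.seed(99)
  for (i in 1:1000) {
    x <- rpois(4, lambda = sample(3:20, 1)) + c(1, 0, 0, 1)
    if (any(c(x[1] + x[2], x[3] + x[4], x[1] + x[3], x[2] + x[4]) == 0)) next
    ours <- chi_square(x)
    ref <- suppressWarnings(
      stats::chisq.test(matrix(x, 2, 2, byrow = TRUE), correct = FALSE))
    expect_lt(abs(ours$statistic - unname(ref$statistic)), 1e-10)
    expect_lt(abs(ours$p_value - ref$p.value), 1e-10)
  }
})

test_that("fdr_bh reproduces the step-up procedure", {
  # hand BH at q = 0.05: 0.001 <= 0.05 * 1/2 keeps rank 1; 0.9 fails
  expect_equal(fdr_bh(c(0.001, 0.9)), c(TRUE, FALSE))
  expect_true(all(fdr_bh(rep(0, 5))))
  expect_false(any(fdr_bh(rep(1, 5))))
  expect_length(fdr_bh(numeric(0)), 0)

  # oracle: literal step-up on sorted p-values
  hand_bh <- function(p, q) {
    o <- order(p); m <- length(p)
    ok <- which(p[o] <= q * seq_len(m) / m)
    keep <- logical(m)
    if (length(ok)) keep[o[seq_len(max(ok))]] <- TRUE
    keep
  }
  set.seed(4)
  for (i in 1:20) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    q <- sample(c(0.01, 0.05, 0.1), 1)
    expect_equal(fdr_bh(p, q), hand_bh(p, q))
  }

  # survivors are non-decreasing in q
  p <- runif(100)^2
  k <- vapply(c(0.01, 0.05, 0.1, 0.2), function(q) sum(fdr_bh(p, q)), 0)
  expect_true(all(diff(k) >= 0))
})

test_that("reverse-inference maps satisfy the significance biconditional", {
  gen <- default_gen(seed = 2)
  am <- activation_matrix(gen$tables, test_grid(), radius = 10)
  labels <- term_labels(gen$tables, am)
  maps <- suppressMessages(batch_maps(am, labels, q = 0.05))
  expect_gt(length(maps), 0)
  for (m in maps) {
    cs <- lapply(seq_len(ncol(am$values)), function(j)
      chi_square(contingency(am$values[, j],
                             labels[[m$label_id]]$member[am$studies])))
    dir_pos <- vapply(cs, function(x) x$direction > 0, TRUE)
    expect_equal(m$z != 0, m$p <= 0.05 & dir_pos)
    expect_true(all(is.finite(m$z)) && all(is.finite(m$p)))
    expect_true(all(m$z >= 0))
  }
})

test_that("label-independent activity yields an all-zero map", {
  g <- test_grid()
  n <- 30
  am <- structure(list(studies = sprintf("S%02d", 1:n),
                       values = matrix(1L, n, g$n_voxels)),
                  class = "activation_matrix")
  set.seed(8)
  lb <- study_label("coin", sample(c(TRUE, FALSE), n, replace = TRUE),
                    am$studies)
  m <- suppressMessages(reverse_inference_map(am, lb))
  expect_true(all(m$z == 0))
})

test_that("degenerate labels error in single maps and are skipped in batches", {
  gen <- default_gen(seed = 2)
  am <- activation_matrix(gen$tables, test_grid(), radius = 10)
  none <- study_label("nobody", rep(FALSE, length(am$studies)), am$studies)
  all_ <- study_label("everyone", rep(TRUE, length(am$studies)), am$studies)
  expect_error(reverse_inference_map(am, none), "nobody")
  expect_error(reverse_inference_map(am, all_), "everyone")
  ok <- term_labels(gen$tables, am)[1]
  msgs <- capture_messages(maps <- batch_maps(am, c(ok, list(none))))
  expect_true(any(grepl("degenerate", msgs)))
  expect_length(maps, 1)
})

test_that("planted foci localize the term and author maps", {
  gen <- default_gen(seed = 6)
  mf <- gen$manifest
  am <- activation_matrix(gen$tables, test_grid(), radius = 10)
  g <- test_grid()

  # author map: all nonzero voxels within twice the focus radius
  a <- names(mf$pi_condition)[1]
  amap <- suppressMessages(
    reverse_inference_map(am, author_labels(gen$tables, am, a)[[1]]))
  expect_gt(sum(amap$z != 0), 0)
  f <- mf$foci[[mf$pi_condition[[a]]]]
  d <- sqrt(rowSums(sweep(g$centers[amap$z != 0, , drop = FALSE], 2,
                          f$center)^2))
  expect_true(all(d <= 2 * f$radius))

  # two terms planted at far-apart foci have disjoint nonzero support
  tmaps <- suppressMessages(batch_maps(am, term_labels(gen$tables, am)))
  tc <- mf$term_condition
  t_motor <- names(tc)[tc == "motor"][1]
  t_reward <- names(tc)[tc == "reward"][1]
  expect_gt(sum(tmaps[[t_motor]]$z != 0), 0)
  expect_equal(sum(tmaps[[t_motor]]$z != 0 & tmaps[[t_reward]]$z != 0), 0L)

  # determinism: identical maps on a second pass
  tmaps2 <- suppressMessages(batch_maps(am, term_labels(gen$tables, am)))
  expect_identical(tmaps[[t_motor]]$z, tmaps2[[t_motor]]$z)
})

test_that("label maps export to NIfTI with a faithful index", {
  gen <- default_gen(seed = 2)
  g <- test_grid()
  am <- activation_matrix(gen$tables, g, radius = 10)
  maps <- suppressMessages(batch_maps(am, term_labels(gen$tables, am)))
  dir <- withr::local_tempdir()
  idx <- write_label_maps(maps, g, dir)
  expect_true(file.exists(file.path(dir, "index.tsv")))
  for (i in seq_len(nrow(idx))) {
    z <- read_volume(file.path(dir, idx$file[i]), g)
    expect_equal(z, maps[[idx$label_id[i]]]$z, tolerance = 1e-6)
    expect_equal(idx$n_nonzero_voxels[i], sum(z != 0))
  }
})
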