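toy_mm <- function(n_authors = 5, n_nodes = 4, seed = 1) {
  set.seed(seed)
  A <- matrix(abs(rnorm(n_authors * 12)), n_authors, 12,
              dimnames = list(sprintf("a%02d", seq_len(n_authors)), NULL))
  lat <- brainlattice:::new_lattice(1, n_nodes,
                                    matrix(abs(rnorm(n_nodes * 12)), n_nodes, 12))
  list(A = A, lat = lat, mm = match_matrix(A, lat))
}

test_that("cosine similarity follows the angle formula", {
  expect_equal(cosine(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine(c(1, 1), c(1, 0)), 1 / sqrt(2))
  expect_warning(z <- cosine(c(0, 0), c(1, 1)), "zero-norm")
  expect_equal(z, 0)
  expect_error(cosine(1:3, 1:4), "length")
})

test_that("the match matrix is entry-wise cosine with pooled standardization", {
  tm <- toy_mm(3, 4)
  for (i in 1:3) for (j in 1:4)
    expect_equal(tm$mm$C[i, j], cosine(tm$A[i, ], tm$lat$weights[j, ]),
                 ignore_attr = TRUE)
  expect_true(all(tm$mm$C >= -1 & tm$mm$C <= 1))
  expect_equal(mean(tm$mm$Z), 0, tolerance = 1e-12)
  expect_equal(sd(as.vector(tm$mm$Z)), 1, tolerance = 1e-12)

  # a node equal to an author's map scores 1, the row maximum
  A <- tm$A
  lat <- tm$lat
  lat$weights[2, ] <- A[1, ]
  mm2 <- match_matrix(A, lat)
  expect_equal(unname(mm2$C[1, 2]), 1)
  expect_equal(which.max(mm2$C[1, ]), 2L)

  # all-zero author map: zero row, flagged, no NaNs
  A0 <- rbind(A, zero = 0)
  expect_warning(mm0 <- match_matrix(A0, tm$lat), "zero")
  expect_equal(mm0$flagged, "zero")
  expect_true(all(mm0$C["zero", ] == 0))

  # constant C degenerates to Z = 0
  latc <- brainlattice:::new_lattice(1, 2, matrix(1, 2, 12))
  Ac <- matrix(1, 2, 12, dimnames = list(c("u", "v"), NULL))
  expect_true(all(match_matrix(Ac, latc)$Z == 0))
})

test_that("node queries respect the z threshold, ranking and cap", {
  tm <- toy_mm(80, 3, seed = 3)
  mm <- tm$mm
  # impossible threshold: empty result
  expect_equal(nrow(top_authors_for_node(mm, 1, z_cut = 99)), 0L)
  # more eligible authors than the cap: exactly cap returned, best first
  hits <- top_authors_for_node(mm, 2, z_cut = -99, cap = 50)
  expect_equal(nrow(hits), 50L)
  expect_equal(hits$score, sort(mm$C[, 2], decreasing = TRUE)[1:50],
               ignore_attr = TRUE)
  # a planted top scorer leads the list
  A <- tm$A
  A["a05", ] <- tm$lat$weights[2, ] * 7
  mm2 <- match_matrix(A, tm$lat)
  expect_equal(top_authors_for_node(mm2, 2, z_cut = 1.5)$author[1], "a05")
})

test_that("the distance matrix is the metric of C rows", {
  tm <- toy_mm(5, 4)
  M <- distance_matrix(tm$mm)
  # entry-wise brute force
  for (i in 1:5) for (j in 1:5)
    expect_equal(M[i, j], sqrt(sum((tm$mm$C[i, ] - tm$mm$C[j, ])^2)),
                 ignore_attr = TRUE)
  # metric axioms
  expect_equal(unname(diag(M)), rep(0, 5))
  expect_equal(M, t(M), ignore_attr = TRUE)
  expect_true(all(M >= 0))
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    expect_lte(M[i, j], M[i, k] + M[k, j] + 1e-12)

  # identical C rows are at distance zero
  A <- tm$A; A[2, ] <- A[1, ]
  M2 <- distance_matrix(match_matrix(A, tm$lat))
  expect_equal(unname(M2[1, 2]), 0)
})

test_that("ranked lists start with the author and ascend in distance", {
  tm <- toy_mm(6, 4, seed = 5)
  M <- distance_matrix(tm$mm)
  rl <- ranked_list(M, "a03")
  expect_equal(rl$author[1], "a03")
  expect_equal(rl$distance[1], 0)
  expect_true(!is.unsorted(rl$distance[-1]))
  expect_setequal(rl$author, rownames(M))
  expect_error(ranked_list(M, "nobody"), "unknown")
})

test_that("tree cuts give exact group counts and nest by height", {
  tm <- toy_mm(12, 4, seed = 7)
  M <- distance_matrix(tm$mm)
  tree <- hcluster_authors(M)
  cuts <- cut_groups(tree, heights = c(0.5, 1.5), ks = c(1, 4, 12))
  expect_equal(length(unique(cuts[["k:4"]])), 4L)
  expect_equal(length(unique(cuts[["k:12"]])), 12L)  # singletons
  expect_equal(length(unique(cuts[["k:1"]])), 1L)
  expect_error(cut_groups(tree, ks = 13), "larger")

  # higher cut heights coarsen lower ones: groups at the low cut never
  # split across groups at the high cut
  lo <- cuts[["h:0.5"]]; hi <- cuts[["h:1.5"]]
  for (gval in unique(lo))
    expect_equal(length(unique(hi[lo == gval])), 1L)
})

test_that("k = 2 clustering recovers planted author cohorts", {
  gen <- default_gen(seed = 13)
  g <- test_grid()
  am <- activation_matrix(gen$tables, g, radius = 10)
  roster <- extract_pis(gen$tables)
  amaps <- suppressMessages(batch_maps(am, author_labels(gen$tables, am,
                                                         roster$pis)))
  tmaps <- suppressMessages(batch_maps(am, term_labels(gen$tables, am)))
  lat <- train_som(map_matrix(tmaps), dims = c(2, 3),
                   sched = som_schedule(seed = 14))
  M <- distance_matrix(match_matrix(map_matrix(amaps), lat))
  grp <- cut_groups(hcluster_authors(M), heights = numeric(0), ks = 2)[["k:2"]]
  truth <- unlist(gen$manifest$pi_condition)[names(grp)]
  expect_equal(rand_index(grp, as.integer(factor(truth))), 1)
})

test_that("rand_index counts pair agreements", {
  expect_equal(rand_index(c(1, 1, 2, 2), c(5, 5, 9, 9)), 1)
  expect_equal(rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), 1 / 3)
  # brute-force oracle on random partitions
  set.seed(10)
  for (i in 1:10) {
    a <- sample(1:3, 8, replace = TRUE); b <- sample(1:3, 8, replace = TRUE)
    agree <- 0; tot <- 0
    for (p in 1:7) for (q in (p + 1):8) {
      tot <- tot + 1
      agree <- agree + ((a[p] == a[q]) == (b[p] == b[q]))
    }
    expect_equal(rand_index(a, b), agree / tot)
  }
})
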