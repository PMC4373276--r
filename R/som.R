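#' Training schedule for the brain lattice SOM
#'
#' The neighborhood width decays exponentially,
#' `sigma(t) = sigma0 * exp(-t / lambda)`, and the learning rate follows
#' the same decay, `L(t) = learn0 * exp(-t / lambda)`.  Training stops
#' at the first iteration whose neighborhood is smaller than one grid
#' step (the neighborhood is then the best matching unit itself), or at
#' `n_iter`, whichever comes first.
#'
#' Defaults (resolved at training time when left `NULL`):
#' `sigma0 = max(rows, cols) / 2`, `n_iter = min(500 * n_maps, 20000)`,
#' `lambda = n_iter / log(sigma0)` — which makes `sigma(n_iter) = 1`, so
#' the schedule ends exactly when the neighborhood has contracted to the
#' BMU.
#'
#' @param sigma0 initial neighborhood width, in grid units.
#' @param lam time constant lambda of the exponential decay.
#' @param learn0 initial learning rate in (0, 1].
#' @param n_iter maximum number of iterations.
#' @param seed integer seed controlling weight initialization and the
#'   sampling of training vectors.
#' @return object of class `som_schedule`.
#' @export
som_schedule <- function(sigma0 = NULL, lam = NULL, learn0 = 0.05,
                         n_iter = NULL, seed = 1L) {
  stopifnot(is.null(sigma0) || sigma0 > 0, is.null(lam) || lam > 0,
            learn0 > 0, learn0 <= 1)
  structure(list(sigma0 = sigma0, lam = lam, learn0 = learn0,
                 n_iter = n_iter, seed = as.integer(seed)),
            class = "som_schedule")
}

#' @rdname som_schedule
#' @param t iteration number (>= 0).
#' @param sched a `som_schedule` with `sigma0` and `lam` resolved.
#' @export
som_sigma <- function(t, sched) {
  stopifnot(all(t >= 0))
  sched$sigma0 * exp(-t / sched$lam)
}

#' @rdname som_schedule
#' @export
som_learn <- function(t, sched) {
  stopifnot(all(t >= 0))
  sched$learn0 * exp(-t / sched$lam)
}

new_lattice <- function(rows, cols, weights, sched = NULL, labels = NULL) {
  grid_pos <- cbind(row = rep(seq_len(rows), each = cols),
                    col = rep(seq_len(cols), times = rows))
  structure(list(rows = rows, cols = cols, weights = weights,
                 grid_pos = grid_pos, labels = labels, schedule = sched),
            class = "som_lattice")
}

#' @export
print.som_lattice <- function(x, ...) {
  cat(sprintf("<som_lattice> %d x %d nodes, weight length %d%s\n",
              x$rows, x$cols, ncol(x$weights),
              if (is.null(x$labels)) "" else
                sprintf(", %d labels assigned", length(unlist(x$labels)))))
  invisible(x)
}

#' Best matching unit
#'
#' The lattice node whose weight vector is closest to `v` in Euclidean
#' distance.  Ties go to the lowest (row, col) in lexicographic order
#' (nodes are stored row-major, so this is the first minimum).
#'
#' @param v numeric vector of length `n_voxels`.
#' @param lattice a `som_lattice`.
#' @return node index (row-major, 1-based).
#' @export
find_bmu <- function(v, lattice) {
  if (length(v) != ncol(lattice$weights))
    stop("training vector length does not match node weights")
  d2 <- rowSums(sweep(lattice$weights, 2, v)^2)
  which.min(d2)
}

#' One SOM weight update
#'
#' Every node whose grid distance (Euclidean on (row, col)) to the BMU
#' is at most `sigma(t)` moves toward the training vector:
#' `W <- W + L(t) * (v - W)`.  By default the full learning rate applies
#' uniformly inside the neighborhood; `kernel = "gaussian"` instead
#' scales it by `exp(-d^2 / (2 sigma(t)^2))` with grid distance `d`.
#'
#' @param lattice a `som_lattice`.
#' @param v training vector.
#' @param bmu node index of the best matching unit.
#' @param t iteration number.
#' @param sched resolved [som_schedule()].
#' @param kernel `"flat"` (default) or `"gaussian"`.
#' @return the updated lattice.
#' @export
update_weights <- function(lattice, v, bmu, t, sched,
                           kernel = c("flat", "gaussian")) {
  kernel <- match.arg(kernel)
  s <- som_sigma(t, sched)
  L <- som_learn(t, sched)
  gd2 <- (lattice$grid_pos[, 1] - lattice$grid_pos[bmu, 1])^2 +
         (lattice$grid_pos[, 2] - lattice$grid_pos[bmu, 2])^2
  inside <- gd2 <= s^2
  if (any(inside)) {
    rate <- if (kernel == "flat") rep(L, sum(inside))
            else L * exp(-gd2[inside] / (2 * s^2))
    W <- lattice$weights[inside, , drop = FALSE]
    lattice$weights[inside, ] <- W + rate * sweep(-W, 2, v, "+")
  }
  lattice
}

#' Train the brain lattice
#'
#' Kohonen-style online training on flattened label maps: weights start
#' uniform at random inside the per-voxel min/max envelope of the
#' training data; each iteration draws one training vector uniformly at
#' random (with replacement), finds its BMU and pulls the BMU's
#' neighborhood toward it; the neighborhood width and learning rate
#' decay per the schedule and training stops once the neighborhood
#' contracts below one grid step.  Finally each training map is assigned
#' as a label to its BMU on the trained lattice.
#'
#' The grid may not exceed the number of training maps (one node per
#' map at most, so no training image need be resampled onto several
#' nodes) unless `allow_resample = TRUE`.
#'
#' @param maps named list of `label_map`s, or a numeric matrix with one
#'   training vector per row (rownames used as labels).
#' @param dims `c(rows, cols)`; the full-scale default used with a
#'   complete term set is 22 x 23, but any grid no larger than the
#'   training set is valid.
#' @param sched a [som_schedule()]; `NULL` fields get the documented
#'   defaults.
#' @param allow_resample permit `rows * cols` to exceed the number of
#'   training maps.
#' @param kernel neighborhood kernel, see [update_weights()].
#' @return a `som_lattice` with trained `weights`, per-node `labels`
#'   and the resolved schedule.
#' @export
train_som <- function(maps, dims = c(22L, 23L), sched = som_schedule(),
                      allow_resample = FALSE, kernel = c("flat", "gaussian")) {
  kernel <- match.arg(kernel)
  X <- if (is.matrix(maps)) maps else map_matrix(maps)
  n_maps <- nrow(X)
  rows <- as.integer(dims[1]); cols <- as.integer(dims[2])
  stopifnot(rows >= 1, cols >= 1, n_maps >= 1)
  if (rows * cols > n_maps && !allow_resample)
    stop(sprintf(paste("grid of %d nodes exceeds the %d training maps;",
                       "shrink the grid or set allow_resample = TRUE"),
                 rows * cols, n_maps))
  if (is.null(sched$sigma0)) sched$sigma0 <- max(rows, cols) / 2
  if (is.null(sched$n_iter)) sched$n_iter <- min(500L * n_maps, 20000L)
  if (is.null(sched$lam))
    sched$lam <- if (sched$sigma0 > 1) sched$n_iter / log(sched$sigma0)
                 else sched$n_iter

  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  lattice <- with_seed(sched$seed, {
    W <- matrix(runif(rows * cols * ncol(X)), rows * cols, ncol(X))
    W <- sweep(sweep(W, 2, hi - lo, "*"), 2, lo, "+")
    lat <- new_lattice(rows, cols, W, sched)
    for (t in seq_len(sched$n_iter)) {
      if (som_sigma(t, sched) < 1) break
      v <- X[sample.int(n_maps, 1L), ]
      bmu <- find_bmu(v, lat)
      lat <- update_weights(lat, v, bmu, t, sched, kernel)
    }
    lat
  })
  labs <- vector("list", rows * cols)
  ids <- rownames(X) %||% sprintf("map_%03d", seq_len(n_maps))
  for (i in seq_len(n_maps)) {
    b <- find_bmu(X[i, ], lattice)
    labs[[b]] <- c(labs[[b]], ids[i])
  }
  lattice$labels <- labs
  lattice
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reshape a node's weight vector into a brain volume
#' @param lattice a trained `som_lattice`.
#' @param node node index (row-major, 1-based).
#' @param grid the [vol_grid()] the training maps were vectorized on.
#' @return 3D array (out-of-mask voxels 0).
#' @export
node_volume <- function(lattice, node, grid) {
  stopifnot(node >= 1, node <= nrow(lattice$weights))
  unvectorize(lattice$weights[node, ], grid)
}

#' Serialize / restore a trained lattice
#'
#' The weights go to a TSV matrix and everything else (dims, schedule,
#' node labels) to a JSON sidecar, so a lattice round-trips through
#' plain text.
#'
#' @param lattice a `som_lattice`.
#' @param dir output directory.
#' @export
write_lattice <- function(lattice, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(lattice$weights, file.path(dir, "weights.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  meta <- list(rows = lattice$rows, cols = lattice$cols,
               schedule = unclass(lattice$schedule),
               labels = lapply(lattice$labels, function(x) as.list(x %||% character(0))))
  jsonlite::write_json(meta, file.path(dir, "lattice.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_lattice
#' @export
read_lattice <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "lattice.json"))
  W <- as.matrix(read.delim(file.path(dir, "weights.tsv"), header = FALSE))
  dimnames(W) <- NULL
  sched <- meta$schedule
  sc <- som_schedule(sigma0 = sched$sigma0, lam = sched$lam,
                     learn0 = sched$learn0, n_iter = NULL, seed = sched$seed)
  sc$n_iter <- sched$n_iter
  labs <- lapply(meta$labels, function(x) unlist(x) %||% character(0))
  new_lattice(meta$rows, meta$cols, W, sc, labs)
}
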