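#' Pipeline run configuration
#'
#' One flat, JSON-serializable object carrying every knob of the
#' end-to-end pipeline, with the module defaults: 10 mm stamping
#' spheres, term-presence threshold 0.001, FDR q = 0.05, pooled-Z
#' match threshold 1.96 with a 50-match cap, network edge rule of 2
#' joint papers, and the interactive tree-cut grids (heights 1-4,
#' group counts 5-100).  The lattice dimensions default to the largest
#' near-square grid not exceeding the number of training maps (so no
#' training image is resampled); with a full 525-term corpus that rule
#' yields 22 x 23 = 506 nodes.
#'
#' A single global `seed` fans out deterministically to the stages
#' (corpus generation uses `seed`, SOM training `seed + 1`).
#'
#' @param ... overrides of any configuration field.
#' @return object of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    mask_path = NULL,            # NULL -> synthetic ellipsoid grid
    grid_dim = c(14L, 17L, 14L),
    resolution = 8,
    radius = 10,
    freq_threshold = 0.001,
    q = 0.05,
    lattice_dims = NULL,         # NULL -> auto_lattice_dims()
    sigma0 = NULL, lam = NULL, learn0 = 0.05, n_iter = NULL,
    kernel = "flat",
    z_cut = 1.96,
    cap = 50L,
    edge_threshold = 2L,
    cut_heights = c(1, 2, 2.5, 3, 3.5, 4),
    cut_ks = c(5, 10, 15, 20, 25, 30, 50, 60, 70, 80, 90, 100),
    group_cut = NULL,            # NULL -> smallest feasible k cut
    synth = list(n_studies = 40L, n_authors = 40L, n_terms = 6L,
                 peaks_per_study = 5L, focus_fraction = 0.9,
                 studies_per_focus = 10L, pis_per_focus = 2L,
                 foci = NULL, planted_pairs = NULL))
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop(sprintf("unknown config field(s): %s",
                                paste(bad, collapse = ", ")))
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @param path JSON file path.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  do.call(run_config, x)
}

#' Largest near-square lattice not exceeding the training set
#' @param n_maps number of training maps.
#' @return `c(rows, cols)` with `rows * cols <= n_maps`.
#' @export
auto_lattice_dims <- function(n_maps) {
  rows <- max(1L, floor(sqrt(n_maps)))
  c(rows, n_maps %/% rows)
}

pipeline_grid <- function(cfg, out = NULL) {
  mask <- cfg$mask_path
  if (!is.null(out) && file.exists(file.path(out, "corpus", "mask.nii")))
    mask <- file.path(out, "corpus", "mask.nii")
  if (is.null(mask)) ellipsoid_grid(cfg$grid_dim, cfg$resolution)
  else grid_from_nifti(mask)
}

require_artifact <- function(path, stage) {
  if (!file.exists(path))
    stop(sprintf("missing artifact %s: run the '%s' stage first", path, stage),
         call. = FALSE)
  path
}

write_map_tsv <- function(mat, path) {
  df <- data.frame(label_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_map_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$label_id
  colnames(m) <- NULL
  m
}

#' Pipeline stages
#'
#' Each stage reads the previous stage's artifacts from `out` and
#' writes its own there, so the stages compose into the `all` run and
#' can be re-run individually (a missing upstream artifact raises an
#' error naming the stage that produces it).
#'
#' * `stage_synth`: generate the synthetic corpus (tables, ground-truth
#'   manifest, mask volume) under `out/corpus/`.
#' * `stage_maps`: activation matrix, reverse-inference maps for all
#'   terms and all roster PIs; z-matrices and NIfTI maps under
#'   `out/maps/`.
#' * `stage_lattice`: train the SOM on the term maps; `out/lattice/`.
#' * `stage_project`: match matrix C/Z and distance matrix M;
#'   `out/project/`.
#' * `stage_cluster`: dendrogram cuts; `out/cluster/groups.json`.
#' * `stage_network`: PI pair counts, collaboration network with group
#'   colors, d3 JSON, ranked lists with collaboration scores;
#'   `out/network/`.
#'
#' @param cfg a [run_config()].
#' @param out output directory.
#' @return each stage invisibly returns its main artifact(s).
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
stage_synth <- function(cfg, out) {
  dir.create(file.path(out, "corpus"), recursive = TRUE, showWarnings = FALSE)
  grid <- pipeline_grid(cfg)
  sy <- cfg$synth
  args <- list(n_studies = sy$n_studies, n_authors = sy$n_authors,
               n_terms = sy$n_terms, peaks_per_study = sy$peaks_per_study,
               focus_fraction = sy$focus_fraction,
               studies_per_focus = sy$studies_per_focus,
               pis_per_focus = sy$pis_per_focus, seed = cfg$seed)
  if (!is.null(sy$foci)) args$foci <- sy$foci
  if (!is.null(sy$planted_pairs)) args$planted_pairs <- sy$planted_pairs
  spec <- do.call(synth_spec, args)
  gen <- generate_corpus(spec, grid)
  write_corpus(gen$tables, file.path(out, "corpus"))
  write_mask(grid, file.path(out, "corpus", "mask.nii"))
  man <- gen$manifest
  for (f in c("study_condition", "pi_condition", "term_condition"))
    man[[f]] <- as.list(man[[f]])   # keep names as JSON object keys
  jsonlite::write_json(man, file.path(out, "corpus", "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(gen)
}

read_pipeline_corpus <- function(out) {
  cdir <- file.path(out, "corpus")
  require_artifact(file.path(cdir, "coordinates.tsv"), "synth")
  read_corpus(file.path(cdir, "coordinates.tsv"),
              file.path(cdir, "authorship.tsv"),
              file.path(cdir, "term_freq.tsv"))
}

#' @rdname pipeline
#' @export
stage_maps <- function(cfg, out) {
  tables <- read_pipeline_corpus(out)
  grid <- pipeline_grid(cfg, out)
  am <- activation_matrix(tables, grid, radius = cfg$radius)
  roster <- extract_pis(tables)
  tmaps <- batch_maps(am, term_labels(tables, am, cfg$freq_threshold), q = cfg$q)
  amaps <- batch_maps(am, author_labels(tables, am, roster$pis), q = cfg$q)
  mdir <- file.path(out, "maps")
  dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
  write_map_tsv(map_matrix(tmaps), file.path(mdir, "term_z.tsv"))
  write_map_tsv(map_matrix(amaps), file.path(mdir, "author_z.tsv"))
  write_label_maps(tmaps, grid, file.path(mdir, "terms"))
  write_label_maps(amaps, grid, file.path(mdir, "authors"))
  invisible(list(term_maps = tmaps, author_maps = amaps, roster = roster))
}

#' @rdname pipeline
#' @export
stage_lattice <- function(cfg, out) {
  X <- read_map_tsv(require_artifact(file.path(out, "maps", "term_z.tsv"), "maps"))
  dims <- cfg$lattice_dims %||% auto_lattice_dims(nrow(X))
  sched <- som_schedule(sigma0 = cfg$sigma0, lam = cfg$lam,
                        learn0 = cfg$learn0, n_iter = cfg$n_iter,
                        seed = cfg$seed + 1L)
  lat <- train_som(X, dims = dims, sched = sched, kernel = cfg$kernel)
  write_lattice(lat, file.path(out, "lattice"))
  invisible(lat)
}

#' @rdname pipeline
#' @export
stage_project <- function(cfg, out) {
  A <- read_map_tsv(require_artifact(file.path(out, "maps", "author_z.tsv"), "maps"))
  lat <- read_lattice(dirname(require_artifact(
    file.path(out, "lattice", "lattice.json"), "lattice")))
  mm <- match_matrix(A, lat)
  M <- distance_matrix(mm)
  pdir <- file.path(out, "project")
  dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(mm$C, file.path(pdir, "C.csv"))
  utils::write.csv(mm$Z, file.path(pdir, "Z.csv"))
  utils::write.csv(unclass(M), file.path(pdir, "M.csv"))
  invisible(list(mm = mm, M = M))
}

read_csv_matrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}

#' @rdname pipeline
#' @export
stage_cluster <- function(cfg, out) {
  M <- read_csv_matrix(require_artifact(file.path(out, "project", "M.csv"),
                                        "project"))
  class(M) <- c("distance_matrix", class(M))
  tree <- hcluster_authors(M)
  n <- nrow(M)
  ks <- cfg$cut_ks[cfg$cut_ks <= n]
  if (length(ks) < length(cfg$cut_ks))
    message(sprintf("dropping %d cut k value(s) larger than the %d authors",
                    length(cfg$cut_ks) - length(ks), n))
  cuts <- cut_groups(tree, heights = cfg$cut_heights, ks = ks)
  cdir <- file.path(out, "cluster")
  dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(lapply(cuts, as.list), file.path(cdir, "groups.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(cuts)
}

pick_group_cut <- function(cuts, group_cut = NULL) {
  if (!is.null(group_cut)) {
    if (!group_cut %in% names(cuts))
      stop(sprintf("cut '%s' not among computed cuts (%s)", group_cut,
                   paste(names(cuts), collapse = ", ")))
    return(cuts[[group_cut]])
  }
  kc <- grep("^k:", names(cuts), value = TRUE)
  if (!length(kc)) return(cuts[[1]])
  cuts[[kc[which.min(as.integer(sub("^k:", "", kc)))]]]
}

#' @rdname pipeline
#' @export
stage_network <- function(cfg, out) {
  tables <- read_pipeline_corpus(out)
  roster <- extract_pis(tables)
  cuts_raw <- jsonlite::fromJSON(require_artifact(
    file.path(out, "cluster", "groups.json"), "cluster"),
    simplifyVector = TRUE, simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  cuts <- lapply(cuts_raw, unlist)
  groups <- pick_group_cut(cuts, cfg$group_cut)
  counts <- pair_counts(tables, roster)
  net <- build_network(counts, roster, threshold = cfg$edge_threshold,
                       groups = groups)
  ndir <- file.path(out, "network")
  dir.create(ndir, recursive = TRUE, showWarnings = FALSE)
  export_d3(net, file.path(ndir, "network.json"))
  write_edgelist(net, file.path(ndir, "edges.tsv"))

  M <- read_csv_matrix(require_artifact(file.path(out, "project", "M.csv"),
                                        "project"))
  rankings <- lapply(stats::setNames(rownames(M), rownames(M)), function(a) {
    rl <- ranked_list(M, a)
    collab <- collaborators_of(net, a)
    n_other <- nrow(rl) - 1L
    scores <- if (n_other) collaboration_score(rl, collab, seq_len(n_other))
              else numeric(0)
    list(ranked = rl$author[-1], distance = rl$distance[-1],
         is_collaborator = rl$author[-1] %in% collab,
         collaboration_score = scores)
  })
  jsonlite::write_json(rankings, file.path(ndir, "rankings.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(list(network = net, rankings = rankings,
                 same_group_edge_fraction = same_group_edge_fraction(net)))
}

#' Run the whole pipeline
#'
#' `synth -> maps -> lattice -> project -> cluster -> network` in one
#' call; the effective configuration is written to `out/config.json`
#' and a manifest of all produced files (with MD5 checksums) to
#' `out/run_manifest.json`, so a rerun with the same config and seed
#' can be verified bit-for-bit.
#'
#' @param cfg a [run_config()].
#' @param out output directory.
#' @return invisibly, the run manifest (data frame of `file`, `md5`).
#' @export
run_all <- function(cfg, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_config(cfg, file.path(out, "config.json"))
  stage_synth(cfg, out)
  stage_maps(cfg, out)
  stage_lattice(cfg, out)
  stage_project(cfg, out)
  stage_cluster(cfg, out)
  stage_network(cfg, out)
  files <- sort(list.files(out, recursive = TRUE))
  files <- setdiff(files, "run_manifest.json")
  man <- data.frame(file = files,
                    md5 = unname(tools::md5sum(file.path(out, files))),
                    stringsAsFactors = FALSE)
  jsonlite::write_json(man, file.path(out, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(man)
}
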