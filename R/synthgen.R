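#' Specification for a synthetic corpus
#'
#' Describes a corpus with planted structure: each named focus is a
#' spatial "research topic" (an mm center and radius) owning a small
#' cohort of PIs and a set of behavioral terms.  Each focus receives
#' `studies_per_focus` studies whose peaks concentrate near its center
#' (a fraction `focus_fraction` drawn from an isotropic Gaussian with
#' sd = radius / 2 truncated to the mask, the rest uniform over in-mask
#' voxel centers); all remaining studies are background — uniform
#' peaks, one-off last authors — so planted conditions stay rare
#' relative to the corpus, as label-specific activation is in real
#' coordinate databases.
#'
#' Cohort PIs rotate as last author over their focus's studies, so each
#' accrues at least two last-author papers; background studies take a
#' junior as last author at most once each, so the PI roster is exactly
#' the cohorts.  Middle author positions are filled from the junior
#' pool only, which makes PI-PI joint-paper counts zero except through
#' `planted_pairs`: a pair `list(a = i, b = j, n = m)` adds PI `j` (into
#' the sorted PI list) as co-author on `m` of PI `i`'s studies, so the
#' manifest's joint counts are exact by construction.
#'
#' @param n_studies number of studies.
#' @param n_authors total author pool (cohort PIs + juniors); must
#'   cover one distinct junior last author per background study.
#' @param n_terms number of behavioral terms; assigned round-robin over
#'   the foci, every (k+1)-th term a spatially unstructured background
#'   term present in about half of all studies.
#' @param foci named list: focus label -> `list(center = mm triple,
#'   radius = mm)`.  Centers must land on in-mask voxels.
#' @param peaks_per_study peaks reported by every study.
#' @param focus_fraction fraction of a focus study's peaks drawn near
#'   its focus, in \[0, 1\].
#' @param studies_per_focus studies assigned to each focus condition.
#' @param pis_per_focus cohort size per focus.
#' @param planted_pairs list of `list(a = i, b = j, n = m)` entries
#'   (indices into the sorted PI list).
#' @param seed integer; fully determines the generated corpus.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(n_studies = 40L, n_authors = 40L, n_terms = 6L,
                       foci = list(
                         motor  = list(center = c(-32, 0, 24), radius = 12),
                         reward = list(center = c(32, 0, 24), radius = 12)),
                       peaks_per_study = 5L, focus_fraction = 0.9,
                       studies_per_focus = 10L, pis_per_focus = 2L,
                       planted_pairs = list(list(a = 1L, b = 2L, n = 3L),
                                            list(a = 3L, b = 4L, n = 2L)),
                       seed = 1L) {
  stopifnot(n_studies >= 1, n_authors >= 2, n_terms >= 1,
            length(foci) >= 1, !is.null(names(foci)),
            peaks_per_study >= 1,
            focus_fraction >= 0, focus_fraction <= 1,
            studies_per_focus >= 2, pis_per_focus >= 1)
  k <- length(foci)
  if (k * studies_per_focus > n_studies)
    stop("n_studies too small for studies_per_focus x number of foci")
  if (studies_per_focus < 2 * pis_per_focus)
    stop("each cohort PI needs at least two last-author studies")
  structure(list(n_studies = as.integer(n_studies),
                 n_authors = as.integer(n_authors),
                 n_terms = as.integer(n_terms), foci = foci,
                 peaks_per_study = as.integer(peaks_per_study),
                 focus_fraction = focus_fraction,
                 studies_per_focus = as.integer(studies_per_focus),
                 pis_per_focus = as.integer(pis_per_focus),
                 planted_pairs = planted_pairs, seed = as.integer(seed)),
            class = "synth_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# rejection-sample `n` points from N(center, (radius/2)^2 I) truncated to
# the mask (membership = nearest voxel in-mask)
sample_focus_peaks <- function(n, center, radius, grid) {
  out <- matrix(NA_real_, 0, 3)
  while (nrow(out) < n) {
    cand <- matrix(rnorm(3 * 2 * (n - nrow(out) + 4), sd = radius / 2),
                   ncol = 3, byrow = TRUE)
    cand <- sweep(cand, 2, center, "+")
    out <- rbind(out, cand[in_mask(grid, cand), , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' Generate a synthetic corpus with planted structure
#'
#' Produces [corpus_tables()] plus a ground-truth manifest recording
#' each label's focus, each study's condition, the PI cohorts and the
#' planted collaboration pairs — everything downstream recovery tests
#' need as an oracle.
#'
#' @param spec a [synth_spec()].
#' @param grid a [vol_grid()] supplying the mask.
#' @return list with elements `tables` ([corpus_tables()]) and
#'   `manifest` (plain list, JSON-serializable).
#' @export
generate_corpus <- function(spec, grid) {
  stopifnot(inherits(spec, "synth_spec"), inherits(grid, "vol_grid"))
  conds <- names(spec$foci)
  k <- length(conds)
  for (cn in conds) {
    ctr <- spec$foci[[cn]]$center
    if (!in_mask(grid, matrix(ctr, 1)))
      stop(sprintf("focus '%s' center (%s) is outside the mask", cn,
                   paste(ctr, collapse = ", ")))
  }

  n_pis <- k * spec$pis_per_focus
  n_bg <- spec$n_studies - k * spec$studies_per_focus
  if (spec$n_authors < n_pis + n_bg)
    stop(sprintf(paste("n_authors = %d cannot cover %d cohort PIs plus one",
                       "distinct junior last author per %d background studies"),
                 spec$n_authors, n_pis, n_bg))
  pi_cond <- rep(conds, each = spec$pis_per_focus)
  pi_names <- sprintf("PI_%s_%02d", pi_cond,
                      rep(seq_len(spec$pis_per_focus), times = k))
  juniors <- sprintf("AU_%02d", seq_len(spec$n_authors - n_pis))

  term_cond <- rep(c(conds, "background"), length.out = spec$n_terms)
  term_names <- sprintf("term_%s_%02d", term_cond,
                        stats::ave(seq_len(spec$n_terms), term_cond, FUN = seq_along))

  study_ids <- sprintf("S%04d", seq_len(spec$n_studies))
  study_cond <- rep(c(rep(conds, each = spec$studies_per_focus),
                      rep("background", n_bg)))

  with_seed(spec$seed, {
    # shuffle condition over study ids so condition is not confounded
    # with id order
    study_cond <- sample(study_cond)

    # last authors: cohort PIs rotate over their focus's studies;
    # background studies consume distinct juniors (never twice)
    last_author <- character(spec$n_studies)
    for (cn in conds) {
      idx <- which(study_cond == cn)
      cohort <- pi_names[pi_cond == cn]
      last_author[idx] <- cohort[((seq_along(idx) - 1L) %% length(cohort)) + 1L]
    }
    bg_idx <- which(study_cond == "background")
    bg_last <- sample(juniors, length(bg_idx))
    last_author[bg_idx] <- bg_last

    # middle positions from the junior pool only (excluding the study's
    # own last author)
    authors_by_study <- vector("list", spec$n_studies)
    for (i in seq_len(spec$n_studies)) {
      pool <- setdiff(juniors, last_author[i])
      mids <- sample(pool, min(sample(1:3, 1), length(pool)))
      authors_by_study[[i]] <- c(mids, last_author[i])
    }

    # planted pairs: PI b joins n of PI a's studies as penultimate author
    pis_sorted <- sort(pi_names)
    planted <- vector("list", length(spec$planted_pairs))
    for (pi in seq_along(spec$planted_pairs)) {
      pp <- spec$planted_pairs[[pi]]
      a <- pis_sorted[pp$a]; b <- pis_sorted[pp$b]
      if (identical(a, b)) stop("planted pair members must differ")
      host <- which(last_author == a)
      if (length(host) < pp$n)
        stop(sprintf("planted pair (%s, %s): %s has only %d studies, need %d",
                     a, b, a, length(host), pp$n))
      host <- host[seq_len(pp$n)]
      for (h in host) {
        x <- authors_by_study[[h]]
        authors_by_study[[h]] <- c(x[-length(x)], b, x[length(x)])
      }
      planted[[pi]] <- list(a = a, b = b, n = pp$n, studies = study_ids[host])
    }

    authorship <- do.call(rbind, lapply(seq_len(spec$n_studies), function(i) {
      a <- authors_by_study[[i]]
      data.frame(study_id = study_ids[i], position = seq_along(a),
                 author = a, stringsAsFactors = FALSE)
    }))

    # peaks: focus studies put focus_fraction of their peaks near the
    # focus; background studies (and the remainder) are uniform in-mask
    n_foc <- round(spec$focus_fraction * spec$peaks_per_study)
    coords <- do.call(rbind, lapply(seq_len(spec$n_studies), function(i) {
      cn <- study_cond[i]
      if (cn == "background") {
        pk <- grid$centers[sample.int(grid$n_voxels, spec$peaks_per_study,
                                      replace = TRUE), , drop = FALSE]
      } else {
        f <- spec$foci[[cn]]
        pk_f <- sample_focus_peaks(n_foc, f$center, f$radius, grid)
        pk_b <- grid$centers[sample.int(grid$n_voxels,
                                        spec$peaks_per_study - n_foc,
                                        replace = TRUE), , drop = FALSE]
        pk <- rbind(pk_f, pk_b)
      }
      data.frame(study_id = study_ids[i],
                 x = round(pk[, 1], 2), y = round(pk[, 2], 2),
                 z = round(pk[, 3], 2), space = "MNI",
                 stringsAsFactors = FALSE)
    }))

    # term frequencies: a focus study is "about" its condition's terms;
    # background terms appear in ~half of all studies regardless of space
    tf <- do.call(rbind, lapply(seq_len(spec$n_studies), function(i) {
      on_terms <- if (study_cond[i] == "background") character(0)
                  else term_names[term_cond == study_cond[i]]
      bg <- term_names[term_cond == "background"]
      bg <- bg[runif(length(bg)) < 0.5]
      tt <- c(on_terms, bg)
      if (!length(tt)) return(NULL)
      data.frame(study_id = study_ids[i], term = tt,
                 frequency = round(runif(length(tt), 0.005, 0.05), 6),
                 stringsAsFactors = FALSE)
    }))

    tables <- corpus_tables(coords, authorship, tf)
    manifest <- list(
      seed = spec$seed,
      foci = spec$foci,
      study_condition = stats::setNames(study_cond, study_ids),
      pi_condition = stats::setNames(pi_cond, pi_names),
      juniors = juniors,
      term_condition = stats::setNames(term_cond, term_names),
      planted_pairs = planted)
    list(tables = tables, manifest = manifest)
  })
}
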