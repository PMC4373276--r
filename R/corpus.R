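#' Corpus tables: coordinates, authorship, term frequencies
#'
#' The raw material of the pipeline: three long-format tables keyed by
#' an opaque `study_id` (PubMed IDs in real corpora, synthetic ids in
#' generated ones).
#'
#' * `coordinates`: one row per reported activation peak
#'   (`study_id, x, y, z, space`), mm in MNI space;
#' * `authorship`: one row per author slot
#'   (`study_id, position, author`), positions a contiguous 1..k;
#' * `term_freq`: per-study behavioral-term frequencies
#'   (`study_id, term, frequency`), fractions in \[0, 1\].
#'
#' Validation enforces the schema, position contiguity, frequency range
#' and uniqueness of `(study_id, position)`; study ids appearing in
#' `authorship`/`term_freq` but absent from `coordinates` are recorded
#' in the `orphans` attribute rather than rejected.
#'
#' @param coordinates,authorship,term_freq data frames with the columns
#'   above.
#' @return a validated object of class `corpus_tables`.
#' @export
corpus_tables <- function(coordinates, authorship, term_freq) {
  req <- list(coordinates = c("study_id", "x", "y", "z", "space"),
              authorship  = c("study_id", "position", "author"),
              term_freq   = c("study_id", "term", "frequency"))
  tabs <- list(coordinates = coordinates, authorship = authorship,
               term_freq = term_freq)
  for (nm in names(req)) {
    missing <- setdiff(req[[nm]], names(tabs[[nm]]))
    if (length(missing))
      stop(sprintf("%s table is missing column(s): %s", nm,
                   paste(missing, collapse = ", ")))
    tabs[[nm]] <- as.data.frame(tabs[[nm]])[req[[nm]]]
  }
  tabs$coordinates$study_id <- as.character(tabs$coordinates$study_id)
  tabs$authorship$study_id  <- as.character(tabs$authorship$study_id)
  tabs$term_freq$study_id   <- as.character(tabs$term_freq$study_id)
  tabs$authorship$author    <- as.character(tabs$authorship$author)
  tabs$term_freq$term       <- as.character(tabs$term_freq$term)
  tabs$authorship$position  <- as.integer(tabs$authorship$position)

  au <- tabs$authorship
  if (nrow(au)) {
    if (anyDuplicated(au[c("study_id", "position")]))
      stop("duplicate (study_id, position) pairs in authorship table")
    bad <- vapply(split(au$position, au$study_id),
                  function(p) !identical(sort(p), seq_along(p)), logical(1))
    if (any(bad))
      stop(sprintf("non-contiguous author positions for study: %s",
                   paste(names(bad)[bad], collapse = ", ")))
  }
  fr <- tabs$term_freq$frequency
  if (length(fr) && (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1)))
    stop("term frequencies must be finite and in [0, 1]")

  known <- unique(tabs$coordinates$study_id)
  orphans <- sort(setdiff(unique(c(au$study_id, tabs$term_freq$study_id)), known))
  structure(tabs, orphans = orphans, class = "corpus_tables")
}

#' @export
print.corpus_tables <- function(x, ...) {
  cat(sprintf(
    "<corpus_tables> %d studies, %d peaks, %d author rows, %d term rows\n",
    length(unique(x$coordinates$study_id)), nrow(x$coordinates),
    nrow(x$authorship), nrow(x$term_freq)))
  orp <- attr(x, "orphans")
  if (length(orp)) cat(sprintf("  %d study id(s) lack coordinates\n", length(orp)))
  invisible(x)
}

#' Read a corpus from TSV files
#'
#' Reads the three corpus tables from tab-separated files with header
#' rows and validates them.  Rows whose `space` is not `"MNI"` are
#' either converted (`tal_convert = TRUE`, Talairach only, via the
#' ICBM-to-Talairach affine inverse) or dropped with a warning giving
#' the count.  An unparseable coordinate raises an error naming the
#' offending data line.
#'
#' @param coordinates,authorship,term_freq paths to the three TSV files.
#' @param tal_convert convert Talairach rows to MNI instead of dropping
#'   all non-MNI rows.
#' @param normalize_names fold author names with [normalize_author()]
#'   (trim/collapse whitespace, lower-case).  Identity is otherwise
#'   exact string match.
#' @return a [corpus_tables()] object.
#' @export
read_corpus <- function(coordinates, authorship, term_freq,
                        tal_convert = FALSE, normalize_names = FALSE) {
  for (p in c(coordinates, authorship, term_freq))
    if (!file.exists(p)) stop(sprintf("file not found: %s", p))
  rd <- function(p) read.delim(p, sep = "\t", header = TRUE,
                               colClasses = "character",
                               check.names = TRUE, quote = "")
  co <- rd(coordinates); au <- rd(authorship); tf <- rd(term_freq)

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(sprintf("%s is missing required column(s): %s", what,
                   paste(miss, collapse = ", ")))
  }
  need(co, c("study_id", "x", "y", "z", "space"), "coordinates table")
  need(au, c("study_id", "position", "author"), "authorship table")
  need(tf, c("study_id", "term", "frequency"), "term_freq table")

  for (col in c("x", "y", "z")) {
    val <- suppressWarnings(as.numeric(co[[col]]))
    bad <- which(is.na(val))
    if (length(bad))
      stop(sprintf("unparseable coordinate '%s' in column %s, line %d of %s",
                   co[[col]][bad[1]], col, bad[1] + 1L, coordinates))
    co[[col]] <- val
  }

  non_mni <- toupper(trimws(co$space)) != "MNI"
  if (any(non_mni)) {
    tal <- non_mni & toupper(trimws(co$space)) %in% c("TAL", "TALAIRACH")
    if (tal_convert && any(tal)) {
      co[tal, c("x", "y", "z")] <- tal_to_mni(as.matrix(co[tal, c("x", "y", "z")]))
      co$space[tal] <- "MNI"
      non_mni <- non_mni & !tal
    }
    if (any(non_mni)) {
      warning(sprintf("dropped %d coordinate row(s) not in MNI space",
                      sum(non_mni)))
      co <- co[!non_mni, , drop = FALSE]
    }
  }

  au$position <- suppressWarnings(as.integer(au$position))
  if (anyNA(au$position)) stop("unparseable position in authorship table")
  tf$frequency <- suppressWarnings(as.numeric(tf$frequency))
  if (anyNA(tf$frequency)) stop("unparseable frequency in term_freq table")
  if (normalize_names) au$author <- normalize_author(au$author)

  corpus_tables(co, au, tf)
}

#' Write a corpus to TSV files
#'
#' Inverse of [read_corpus()]: writes the three tables as tab-separated
#' UTF-8 files with header rows, deterministic row order preserved.
#'
#' @param tables a [corpus_tables()] object.
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_corpus <- function(tables, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("coordinates.tsv", "authorship.tsv", "term_freq.tsv"))
  wr <- function(df, p) write.table(df, p, sep = "\t", quote = FALSE,
                                    row.names = FALSE, fileEncoding = "UTF-8")
  wr(tables$coordinates, paths[1])
  wr(tables$authorship, paths[2])
  wr(tables$term_freq, paths[3])
  invisible(paths)
}

#' @rdname read_corpus
#' @param x character vector of author names.
#' @export
normalize_author <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

#' Talairach to MNI conversion (single affine)
#'
#' Applies the inverse of the Lancaster `icbm_spm2tal` affine, the
#' common single-matrix bridge between the two stereotaxic spaces.  Only
#' used when [read_corpus()] is asked to convert rather than drop
#' Talairach rows.
#'
#' @param xyz n x 3 matrix of Talairach mm coordinates.
#' @return n x 3 matrix of MNI mm coordinates.
#' @export
tal_to_mni <- function(xyz) {
  icbm_spm2tal <- matrix(c(
    0.9254,  0.0024, -0.0118, -1.0207,
   -0.0048,  0.9316, -0.0871, -1.7667,
    0.0152,  0.0883,  0.8924,  4.0926,
    0,       0,       0,       1), 4, 4, byrow = TRUE)
  xyz <- matrix(xyz, ncol = 3)
  t(solve(icbm_spm2tal) %*% rbind(t(xyz), 1))[, 1:3, drop = FALSE]
}

#' Extract principal investigators from the authorship table
#'
#' A PI is an author appearing in the last (highest) author position on
#' at least `min_papers` studies; single-author papers count their sole
#' author as last.
#'
#' @param tables a [corpus_tables()] object.
#' @param min_papers minimum number of last-author papers (default 2).
#' @return a `pi_roster`: list with `pis` (sorted character vector) and
#'   `papers_per_pi` (named integer vector of last-author counts).
#' @export
extract_pis <- function(tables, min_papers = 2L) {
  au <- tables$authorship
  if (nrow(au) == 0L)
    return(structure(list(pis = character(0),
                          papers_per_pi = integer(0)), class = "pi_roster"))
  last_rows <- unlist(lapply(split(seq_len(nrow(au)), au$study_id),
                             function(i) i[which.max(au$position[i])]),
                      use.names = FALSE)
  counts <- table(au$author[last_rows])
  keep <- counts >= min_papers
  pis <- sort(names(counts)[keep])
  structure(list(pis = pis,
                 papers_per_pi = stats::setNames(as.integer(counts[pis]), pis)),
            class = "pi_roster")
}

#' @export
print.pi_roster <- function(x, ...) {
  cat(sprintf("<pi_roster> %d PIs (last author on >= 2 papers)\n", length(x$pis)))
  invisible(x)
}
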