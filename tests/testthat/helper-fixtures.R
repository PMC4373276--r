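# Shared fixtures: a small ellipsoid grid and corpora built in code.

test_grid <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- ellipsoid_grid()
    g
  }
})

# tiny corpus matching a hand-checkable layout: authorship
# P1 = [X, Y], P2 = [Z, Y], P3 = [Z, X]
toy_tables <- function() {
  corpus_tables(
    coordinates = data.frame(
      study_id = c("P1", "P1", "P2", "P2", "P3"),
      x = c(-32, -30, 32, 30, 0), y = c(0, 2, 0, -2, -52),
      z = c(24, 20, 24, 20, 8), space = "MNI"),
    authorship = data.frame(
      study_id = c("P1", "P1", "P2", "P2", "P3", "P3"),
      position = c(1L, 2L, 1L, 2L, 1L, 2L),
      author = c("X", "Y", "Z", "Y", "Z", "X")),
    term_freq = data.frame(
      study_id = c("P1", "P2", "P3"),
      term = c("motor", "reward", "motor"),
      frequency = c(0.02, 0.01, 0.002)))
}

extdata <- function(f) system.file("extdata", f, package = "brainlattice")

default_gen <- function(seed = 1L, ...) {
  generate_corpus(synth_spec(seed = seed, ...), test_grid())
}

# brute-force joint-paper counts over all author pairs in a table
brute_pair_counts <- function(authorship, pis) {
  counts <- list()
  for (ids in split(authorship$author, authorship$study_id)) {
    ids <- sort(unique(intersect(ids, pis)))
    if (length(ids) < 2) next
    for (i in seq_len(length(ids) - 1)) for (j in (i + 1):length(ids)) {
      key <- paste(ids[i], ids[j], sep = "|")
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
    }
  }
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a
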