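#' Binary study labelings
#'
#' A study label marks, for every study in an activation matrix, whether
#' the label applies: a behavioral term is present in the study's text
#' (frequency at or above a threshold) or an author is on the paper.
#'
#' @param label_id label name.
#' @param member logical vector named by study id, or unnamed and
#'   aligned to `studies`.
#' @param studies optional character vector fixing the study order.
#' @return object of class `study_label` with fields `label_id` and
#'   `member` (named logical).
#' @export
study_label <- function(label_id, member, studies = names(member)) {
  if (is.null(studies)) stop("member must be named or studies supplied")
  member <- stats::setNames(as.logical(member), studies)
  if (anyNA(member)) stop(sprintf("label %s: member must be TRUE/FALSE", label_id))
  structure(list(label_id = label_id, member = member), class = "study_label")
}

label_members <- function(label, studies) {
  m <- label$member[studies]
  if (anyNA(m))
    stop(sprintf("label %s is not defined for all studies", label$label_id))
  unname(m)
}

#' @rdname study_label
#' @param tables a [corpus_tables()] object.
#' @param am an [activation_matrix()].
#' @param threshold term-presence threshold on frequency (default 0.001).
#' @return `term_labels()` / `author_labels()`: named list of
#'   `study_label`s, one per term / author.
#' @export
term_labels <- function(tables, am, threshold = 0.001) {
  tf <- tables$term_freq
  terms <- sort(unique(tf$term))
  present <- tf[tf$frequency >= threshold, , drop = FALSE]
  lapply(stats::setNames(terms, terms), function(t) {
    in_t <- unique(present$study_id[present$term == t])
    study_label(t, am$studies %in% in_t, am$studies)
  })
}

#' @rdname study_label
#' @param authors character vector of author names (e.g. a PI roster's
#'   `pis`).
#' @export
author_labels <- function(tables, am, authors) {
  au <- tables$authorship
  lapply(stats::setNames(authors, authors), function(a) {
    on_a <- unique(au$study_id[au$author == a])
    study_label(a, am$studies %in% on_a, am$studies)
  })
}

#' 2x2 contingency counts for one voxel
#'
#' Cross-tabulates activation (voxel active in a study) against label
#' membership: `a` = active & member, `b` = active & non-member,
#' `c` = inactive & member, `d` = inactive & non-member.
#'
#' @param voxel_column binary vector, one entry per study.
#' @param label a [study_label()] or logical vector of equal length.
#' @return named integer vector `c(a, b, c, d)`.
#' @export
contingency <- function(voxel_column, label) {
  m <- if (inherits(label, "study_label")) unname(label$member) else as.logical(label)
  v <- as.logical(voxel_column)
  if (length(v) != length(m)) stop("voxel column and label differ in length")
  c(a = sum(v & m), b = sum(v & !m), c = sum(!v & m), d = sum(!v & !m))
}

#' Pearson chi-square test of independence for a 2x2 table
#'
#' Plain Pearson statistic (no continuity correction) with 1 df and an
#' upper-tail p-value, plus the direction of association: the sign of
#' `a*d - b*c` (positive means activation is preferentially associated
#' with label presence).  A zero row or column marginal leaves the
#' statistic undefined; such tables return `statistic = NA`, `p = 1`,
#' `direction = 0`.
#'
#' @param counts `c(a, b, c, d)` or a 2x2 matrix (rows = active yes/no,
#'   columns = member yes/no).
#' @return list with `statistic`, `p_value`, `direction`.
#' @export
chi_square <- function(counts) {
  x <- as.numeric(counts)
  if (length(x) != 4L || any(x < 0) || anyNA(x)) stop("counts must be 4 nonnegative values")
  a <- x[1]; b <- x[2]; cc <- x[3]; d <- x[4]
  n <- a + b + cc + d
  if (n <= 0) stop("empty table")
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0)
    return(list(statistic = NA_real_, p_value = 1, direction = 0L))
  stat <- n * (a * d - b * cc)^2 / (r1 * r2 * c1 * c2)
  list(statistic = stat,
       p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       direction = sign(a * d - b * cc))
}

# vectorized chi-square over all voxel columns of an activation matrix
chi_square_cols <- function(values, member) {
  n <- nrow(values)
  nm <- sum(member)
  active <- colSums(values)
  a <- as.numeric(member %*% values)          # active & member
  b <- active - a
  cc <- nm - a
  d <- n - nm - b
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc; c2 <- b + d
  denom <- r1 * r2 * c1 * c2
  det <- a * d - b * cc
  stat <- ifelse(denom > 0, n * det^2 / denom, NA_real_)
  p <- ifelse(denom > 0, pchisq(stat, df = 1, lower.tail = FALSE), 1)
  # minimum expected cell count, for the conservative small-cell guard
  min_exp <- pmin(r1 * c1, r1 * c2, r2 * c1, r2 * c2) / n
  list(statistic = stat, p_value = p, direction = sign(det), min_expected = min_exp)
}

#' Benjamini-Hochberg keep vector
#'
#' Step-up FDR control: keeps all p-values at or below the largest
#' p(k) with p(k) <= q * k / m.  Implemented through the adjusted
#' p-values of [stats::p.adjust()], whose `<= q` rule is equivalent.
#'
#' @param p_values numeric vector of raw p-values in \[0, 1\].
#' @param q false-discovery rate (default 0.05).
#' @return logical keep vector of the same length.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (length(p_values) == 0L) return(logical(0))
  stopifnot(all(p_values >= 0 & p_values <= 1))
  p.adjust(p_values, method = "BH") <= q
}

#' Reverse-inference map for one label
#'
#' Per-voxel 2x2 chi-square of activation against label membership over
#' all studies, BH-corrected across in-mask voxels at rate `q`.
#' Surviving voxels with a *positive* association get
#' `z = qnorm(1 - p_raw / 2)` (two-sided p mapped to a positive normal
#' deviate); all other voxels are zeroed.  Voxels whose 2x2 table has
#' any expected cell count below 1 are conservatively set to p = 1
#' before correction.
#'
#' @param am an [activation_matrix()].
#' @param label a [study_label()]; must have at least one member and one
#'   non-member study.
#' @param q FDR rate (default 0.05).
#' @param signed keep negative associations as negative z instead of
#'   zeroing them.
#' @return a `label_map`: list with `label_id`, `z` and `p` (in-mask
#'   vectors; `p` is the BH-adjusted p-value), `n_studies`, `n_member`.
#' @export
reverse_inference_map <- function(am, label, q = 0.05, signed = FALSE) {
  member <- label_members(label, am$studies)
  if (all(member) || !any(member))
    stop(sprintf("label %s is degenerate: %d of %d studies are members",
                 label$label_id, sum(member), length(member)))
  cs <- chi_square_cols(am$values, member)
  p_raw <- cs$p_value
  small <- cs$min_expected < 1 & is.finite(cs$min_expected)
  if (any(small)) {
    p_raw[small] <- 1
    message(sprintf("label %s: %d voxel(s) with expected count < 1 set to p = 1",
                    label$label_id, sum(small)))
  }
  p_adj <- p.adjust(p_raw, method = "BH")
  keep <- p_adj <= q & if (signed) cs$direction != 0 else cs$direction > 0
  z <- numeric(length(p_raw))
  z[keep] <- qnorm(pmax(p_raw[keep], 1e-300) / 2, lower.tail = FALSE) *
    (if (signed) cs$direction[keep] else 1)
  structure(list(label_id = label$label_id, z = z, p = p_adj,
                 n_studies = length(member), n_member = sum(member)),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %s: %d/%d member studies, %d significant voxel(s)\n",
              x$label_id, x$n_member, x$n_studies, sum(x$z != 0)))
  invisible(x)
}

#' Reverse-inference maps for a batch of labels
#'
#' Applies [reverse_inference_map()] per label, skipping (with a
#' message) labels that are degenerate — applying to all studies or to
#' none.
#'
#' @param am an [activation_matrix()].
#' @param labels named list of [study_label()]s (see [term_labels()],
#'   [author_labels()]).
#' @param q FDR rate.
#' @inheritParams reverse_inference_map
#' @return named list of `label_map`s (degenerate labels absent).
#' @export
batch_maps <- function(am, labels, q = 0.05, signed = FALSE) {
  out <- list()
  for (lb in labels) {
    member <- label_members(lb, am$studies)
    if (all(member) || !any(member)) {
      message(sprintf("skipping degenerate label %s (%d/%d members)",
                      lb$label_id, sum(member), length(member)))
      next
    }
    out[[lb$label_id]] <- reverse_inference_map(am, lb, q = q, signed = signed)
  }
  out
}

#' Stack label maps into a labels-by-voxels matrix
#' @param maps named list of `label_map`s.
#' @return numeric matrix, one row per label (z-vectors).
#' @export
map_matrix <- function(maps) {
  if (!length(maps)) stop("no maps supplied")
  do.call(rbind, lapply(maps, function(m) m$z)) |>
    `rownames<-`(vapply(maps, function(m) m$label_id, character(1)))
}

#' Write a batch of label maps as NIfTI z-maps plus a TSV index
#'
#' @param maps named list of `label_map`s.
#' @param grid the [vol_grid()] the maps live on.
#' @param dir output directory.
#' @return invisibly, the index data frame (`label_id`, `n_member`,
#'   `n_nonzero_voxels`, `file`).
#' @export
write_label_maps <- function(maps, grid, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- do.call(rbind, lapply(maps, function(m) {
    f <- paste0(gsub("[^A-Za-z0-9_.-]", "_", m$label_id), "_z.nii.gz")
    write_volume(m$z, grid, file.path(dir, f))
    data.frame(label_id = m$label_id, n_member = m$n_member,
               n_nonzero_voxels = sum(m$z != 0), file = f,
               stringsAsFactors = FALSE)
  }))
  write.table(idx, file.path(dir, "index.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(idx)
}
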