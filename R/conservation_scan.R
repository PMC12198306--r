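#' Default conservative-substitution groups
#'
#' Residues within one group count as conservative substitutions (1 point) in
#' the column score. The default uses the common strong classes
#' (aliphatic ILMV; aromatic FWY; acid/amide DENQ; basic HKR; small AGPST;
#' cysteine alone). Any scheme can be substituted as a list of character
#' vectors; residues outside every group only ever score as identities.
#'
#' @return Named list of character vectors.
#' @export
default_substitution_groups <- function() {
  list(aliphatic = c("I", "L", "M", "V"),
       aromatic = c("F", "W", "Y"),
       acid_amide = c("D", "E", "N", "Q"),
       basic = c("H", "K", "R"),
       small = c("A", "G", "P", "S", "T"),
       cysteine = "C")
}

as_alignment_matrix <- function(alignment) {
  if (is.matrix(alignment)) {
    m <- toupper(alignment)
  } else {
    if (methods::is(alignment, "AAStringSet") ||
        methods::is(alignment, "XStringSet")) {
      alignment <- as.character(alignment)
    }
    alignment <- toupper(alignment)
    if (length(unique(nchar(alignment))) > 1) {
      abort("alignment rows differ in width")
    }
    m <- do.call(rbind, strsplit(alignment, ""))
    rownames(m) <- names(alignment)
  }
  m
}

## map residues to group index (0 = no group); gaps ('-' or '.') -> NA
group_index <- function(m, groups) {
  key <- setNames(rep(seq_along(groups), lengths(groups)),
                  unlist(groups))
  g <- matrix(key[m], nrow = nrow(m))
  g[is.na(g)] <- 0L
  g[m %in% c("-", ".")] <- NA_integer_
  g
}

net_scores <- function(m, groups) {
  n <- nrow(m)
  if (n < 2) abort("need at least 2 sequences")
  gap <- m == "-" | m == "."
  g <- group_index(m, groups)
  pairs <- utils::combn(n, 2)
  W <- ncol(m)
  vapply(seq_len(W), function(j) {
    col <- m[, j]; cg <- gap[, j]; cgr <- g[, j]
    if (!any(cg) && length(unique(col)) == 1L) return(3)
    sc <- vapply(seq_len(ncol(pairs)), function(p) {
      a <- pairs[1, p]; b <- pairs[2, p]
      if (cg[a] || cg[b]) return(0)          # single or double gap
      if (col[a] == col[b]) return(2)        # identity
      if (!is.na(cgr[a]) && cgr[a] != 0L && cgr[a] == cgr[b]) return(1)
      0
    }, numeric(1))
    mean(sc)
  }, numeric(1))
}

#' Net conservation score of one alignment column
#'
#' Every unordered pair of rows scores 2 for an amino-acid identity, 1 for a
#' conservative substitution, and 0 for nonconservative substitutions and
#' for single or double gaps; an identity is elevated to 3 if, and only if,
#' the column is identical (and gap-free) across all rows. The net score is
#' the average over all pairs, so it lies in [0, 3] and equals 3 exactly for
#' universally identical columns.
#'
#' @param alignment Aligned sequences: character vector, matrix, or
#'   `AAStringSet` (equal widths; `-`/`.` are gaps).
#' @param column Column index.
#' @param substitution_groups List of residue groups
#'   ([default_substitution_groups()]).
#' @return Numeric score in [0, 3].
#' @export
column_net_score <- function(alignment, column,
                             substitution_groups = default_substitution_groups()) {
  m <- as_alignment_matrix(alignment)
  if (column < 1 || column > ncol(m)) abort("column outside alignment width")
  net_scores(m[, column, drop = FALSE], substitution_groups)[[1]]
}

#' Sliding-window local similarity profile of a protein alignment
#'
#' The local similarity of a window is the mean of the column net scores
#' ([column_net_score()]) over its columns; windows advance one column and
#' only fully contained windows are scored. Each window is reported at its
#' center column: for even window length w, center = start + w/2; for odd w,
#' the middle column. Gap columns are included in windows and score 0 in the
#' pairs they gap.
#'
#' @param alignment As in [column_net_score()].
#' @param window_length Columns per window (default 30).
#' @param substitution_groups Residue groups.
#' @param ref_row Optional row index/name: adds `ref_center`, the residue
#'   number in that (ungapped) row at or before each center column, for
#'   plotting against a reference sequence's coordinates.
#' @param alignment_id Label stored on the profile.
#' @return A `similarity_profile`: tibble with `center` and `score` (one row
#'   per window), attributes `window_length` and `alignment_id`.
#' @export
window_scan <- function(alignment, window_length = 30L,
                        substitution_groups = default_substitution_groups(),
                        ref_row = NULL, alignment_id = "alignment") {
  m <- as_alignment_matrix(alignment)
  W <- ncol(m)
  if (W < window_length) abort("alignment narrower than window_length")
  ns <- net_scores(m, substitution_groups)
  cs <- cumsum(c(0, ns))
  starts <- seq_len(W - window_length + 1L)
  score <- (cs[starts + window_length] - cs[starts]) / window_length
  centers <- starts + (if (window_length %% 2L == 0L) window_length %/% 2L
                       else (window_length - 1L) %/% 2L)
  out <- tibble(center = as.integer(centers), score = score)
  if (!is.null(ref_row)) {
    row <- m[ref_row, ]
    respos <- cumsum(row != "-" & row != ".")
    out$ref_center <- respos[out$center]
  }
  structure(out, window_length = as.integer(window_length),
            alignment_id = alignment_id,
            class = c("similarity_profile", class(out)))
}

#' @exportS3Method generics::tidy
tidy.similarity_profile <- function(x, ...) as_tibble(unclass(x))

#' @exportS3Method generics::glance
glance.similarity_profile <- function(x, ...) {
  tibble(alignment_id = attr(x, "alignment_id"),
         window_length = attr(x, "window_length"),
         n_windows = nrow(x),
         peak_center = x$center[which.max(x$score)],
         peak_score = max(x$score))
}

#' Integer percent identity
#'
#' `round(100 * n_identical / n_compared)` with halves rounded away from
#' zero, the convention used when printing identity percentages (e.g.
#' 12/29 -> 41, 6/28 -> 21, 29/29 -> 100).
#'
#' @param n_identical,n_compared Non-negative counts, `n_compared > 0`.
#' @return Integer percent.
#' @export
percent_identity <- function(n_identical, n_compared) {
  if (any(n_compared <= 0)) abort("n_compared must be positive")
  if (any(n_identical < 0) || any(n_identical > n_compared)) {
    abort("need 0 <= n_identical <= n_compared")
  }
  as.integer(round_half_up(100 * n_identical / n_compared))
}
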