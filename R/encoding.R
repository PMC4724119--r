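as_sequences <- function(x) {
  seqs <- if (inherits(x, "splice_windows")) x$seq else as.character(x)
  if (length(seqs) == 0) stop("empty sequence set")
  if (length(unique(nchar(seqs))) != 1) stop("sequences must share one length")
  if (any(grepl("[^ACGT]", seqs))) stop("sequences must contain only A/C/G/T")
  seqs
}

base_matrix <- function(seqs) {
  matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
         nrow = length(seqs), byrow = TRUE)
}

#' Position weight matrix of an aligned window set
#'
#' For N position-aligned sequences of length l, entry `(i, j)` is the
#' fraction of sequences carrying base i at position j. Rows are ordered
#' A, C, G, T; every column sums to 1.
#'
#' @param x A `splice_windows` data frame or character vector of
#'   equal-length A/C/G/T strings.
#' @return A 4 x l numeric matrix of class `pwm` with attribute `N`.
#' @export
compute_pwm <- function(x) {
  seqs <- as_sequences(x)
  m <- base_matrix(seqs)
  probs <- vapply(BASES, function(b) colMeans(m == b), numeric(ncol(m)))
  probs <- t(probs)  # 4 x l
  dimnames(probs) <- list(BASES, seq_len(ncol(m)))
  structure(probs, N = length(seqs), class = c("pwm", class(probs)))
}

#' Adjacent di-nucleotide counts
#'
#' Counts each ordered base pair at every adjacent position pair (j, j+1)
#' over an aligned set. Rows are the 16 pairs AA, AC, ..., TT (lexicographic
#' over A < C < G < T); column j covers positions (j, j+1), so every column
#' sums to N.
#'
#' @inheritParams compute_pwm
#' @return A 16 x (l-1) integer matrix of class `dinuc_counts` with
#'   attribute `N`.
#' @export
count_adjacent_dinucleotides <- function(x) {
  seqs <- as_sequences(x)
  l <- nchar(seqs[1])
  if (l < 2) stop("sequences must be at least 2 bases long")
  m <- base_matrix(seqs)
  pairs <- matrix(paste0(m[, -l, drop = FALSE], m[, -1, drop = FALSE]),
                  nrow = nrow(m))
  counts <- vapply(seq_len(l - 1L), function(j) {
    tabulate(factor(pairs[, j], levels = DINUCS), nbins = 16L)
  }, integer(16L))
  dimnames(counts) <- list(DINUCS, feature_names_for(l))
  structure(counts, N = length(seqs), class = c("dinuc_counts", class(counts)))
}

expected_counts <- function(pwm) {
  l <- ncol(pwm)
  n <- attr(pwm, "N")
  e <- vapply(seq_len(l - 1L), function(j) {
    as.vector(t(outer(pwm[, j], pwm[, j + 1L]))) * n
  }, numeric(16L))
  dimnames(e) <- list(DINUCS, feature_names_for(l))
  e
}

#' Di-nucleotide association score matrix
#'
#' Turns adjacent-pair counts into log2 association scores under one of
#' three procedures. With observed count n, set size N, and PWM marginals
#' p and p' at the two positions:
#' \describe{
#'   \item{P-1}{`log2(n / (N * 0.0625))` — observed over the uniform random
#'     expectation 1/16.}
#'   \item{P-2}{`log2(n / (N * p * p'))` — observed over the expectation
#'     under positional independence.}
#'   \item{P-3}{`log2(|n - N * p * p'| / (N * p * p'))` — absolute relative
#'     deviation from the independence expectation.}
#' }
#' A pseudo count (default 0.001) is added to each log numerator, and to the
#' expected-count denominators of P-2/P-3 (which can be zero when a PWM
#' probability is zero); the P-1 denominator is never zero and takes none.
#'
#' @param counts A `dinuc_counts` matrix.
#' @param pwm The `pwm` computed from the same aligned set.
#' @param procedure `"P-1"`, `"P-2"` or `"P-3"`.
#' @param pseudo Non-negative pseudo count; 0 reproduces the textbook
#'   formulas exactly on sets with no zero cells.
#' @return A 16 x (l-1) matrix of class `assoc_scores` with attributes
#'   `procedure`, `pseudo`, `N`.
#' @export
association_scores <- function(counts, pwm, procedure = c("P-1", "P-2", "P-3"),
                               pseudo = 0.001) {
  procedure <- match.arg(procedure)
  if (pseudo < 0) stop("pseudo count must be non-negative")
  n_set <- attr(counts, "N")
  if (!identical(n_set, attr(pwm, "N")) || ncol(pwm) != ncol(counts) + 1L) {
    stop("counts and pwm must come from the same aligned set")
  }
  n <- unclass(counts)
  scores <- switch(procedure,
    "P-1" = log2((n + pseudo) / (n_set * 0.0625)),
    "P-2" = {
      e <- expected_counts(pwm)
      log2((n + pseudo) / (e + pseudo))
    },
    "P-3" = {
      e <- expected_counts(pwm)
      log2((abs(n - e) + pseudo) / (e + pseudo))
    }
  )
  structure(scores, procedure = procedure, pseudo = pseudo, N = n_set,
            class = c("assoc_scores", "matrix", "array"))
}

#' Difference scoring matrix between false- and true-site scores
#'
#' The encoder of the method: the per-cell difference between the
#' false-site and true-site association score matrices built under the same
#' procedure. The default direction subtracts the true-site matrix from the
#' false-site matrix; `direction = "tss_minus_fss"` flips the sign (tree
#' ensembles are invariant to a per-feature sign flip).
#'
#' @param tss_scores,fss_scores `assoc_scores` matrices of equal shape and
#'   procedure.
#' @param direction `"fss_minus_tss"` (default) or `"tss_minus_fss"`.
#' @return A 16 x (l-1) matrix of class `diff_matrix` with attributes
#'   `procedure` and `direction`.
#' @export
build_difference_matrix <- function(tss_scores, fss_scores,
                                    direction = c("fss_minus_tss", "tss_minus_fss")) {
  direction <- match.arg(direction)
  if (!identical(dim(tss_scores), dim(fss_scores))) stop("shape mismatch")
  if (!identical(attr(tss_scores, "procedure"), attr(fss_scores, "procedure"))) {
    stop("procedure mismatch")
  }
  delta <- if (direction == "fss_minus_tss") {
    unclass(fss_scores) - unclass(tss_scores)
  } else {
    unclass(tss_scores) - unclass(fss_scores)
  }
  structure(delta, procedure = attr(tss_scores, "procedure"),
            direction = direction,
            class = c("diff_matrix", "matrix", "array"))
}

#' Encode one window through a difference matrix
#'
#' A window of length l becomes a vector of l-1 scores: feature j is the
#' difference-matrix cell for the ordered pair at positions (j, j+1).
#'
#' @param window A 1-row `splice_windows`, or a single A/C/G/T string.
#' @param diff A `diff_matrix`.
#' @return Named numeric vector of length l-1 (names `"1_2"`, `"2_3"`, ...).
#' @export
encode_sequence <- function(window, diff) {
  seq <- if (inherits(window, "splice_windows")) window$seq[1] else as.character(window)
  l <- nchar(seq)
  if (l != ncol(diff) + 1L) {
    stop("window length ", l, " incompatible with ", ncol(diff), "-column matrix")
  }
  if (grepl("[^ACGT]", seq)) stop("ambiguous base in window")
  ch <- strsplit(seq, "")[[1]]
  pairs <- paste0(ch[-l], ch[-1])
  v <- unclass(diff)[cbind(match(pairs, DINUCS), seq_len(l - 1L))]
  names(v) <- feature_names_for(l)
  v
}

#' Encode a window set into a feature matrix
#'
#' Row-wise application of [encode_sequence()]; labels, when the windows
#' carry them, are passed through as a factor with levels TSS, FSS.
#'
#' @param windows A `splice_windows` data frame (all windows one length).
#' @param diff A `diff_matrix` whose width is the window length minus 1.
#' @return An `encoded_dataset`: list with `x` (n x (l-1) matrix), `labels`
#'   (factor or NULL) and `feature_names`.
#' @export
encode_dataset <- function(windows, diff) {
  fn <- colnames(unclass(diff)) %||% feature_names_for(ncol(diff) + 1L)
  if (nrow(windows) == 0) {
    x <- matrix(numeric(0), nrow = 0, ncol = ncol(diff),
                dimnames = list(NULL, fn))
    return(structure(list(x = x, labels = NULL, feature_names = fn),
                     class = "encoded_dataset"))
  }
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    tryCatch(encode_sequence(windows$seq[i], diff),
             error = function(e) stop("window ", windows$source_id[i], " (row ",
                                      i, "): ", conditionMessage(e)))
  })
  x <- do.call(rbind, rows)
  colnames(x) <- fn
  labels <- windows$label
  labels <- if (all(labels == "unknown")) NULL else as_class_factor(labels)
  structure(list(x = x, labels = labels, feature_names = fn),
            class = "encoded_dataset")
}

#' Write a scoring or difference matrix as labelled TSV
#'
#' 16 labelled rows (AA..TT) by l-1 labelled columns, plus a JSON sidecar
#' (`<path>.json`) recording procedure, N, pseudo count and direction.
#'
#' @param mat An `assoc_scores` or `diff_matrix`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_score_matrix <- function(mat, path) {
  df <- as.data.frame(unclass(mat))
  utils::write.table(cbind(pair = rownames(unclass(mat)) %||% DINUCS, df),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(procedure = attr(mat, "procedure"), N = attr(mat, "N"),
               pseudo = attr(mat, "pseudo"), direction = attr(mat, "direction"))
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a matrix written by [write_score_matrix()]
#'
#' @param path TSV path.
#' @return The matrix with attributes restored from the JSON sidecar.
#' @export
read_score_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$pair
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    for (nm in names(meta)) attr(mat, nm) <- meta[[nm]]
    cls <- if (!is.null(meta$direction)) "diff_matrix" else "assoc_scores"
    class(mat) <- c(cls, "matrix", "array")
  }
  mat
}
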