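#' @keywords internal
#' @importFrom stats predict
"_PACKAGE"

BASES <- c("A", "C", "G", "T")

# 16 ordered adjacent pairs, lexicographic over A < C < G < T; this row order
# is fixed so serialized matrices round-trip unambiguously.
DINUCS <- as.vector(t(outer(BASES, BASES, paste0)))

CLASS_LEVELS <- c("TSS", "FSS")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Stable sub-seed derivation, kept well below 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(offset) %% 1009L
}

feature_names_for <- function(l) paste(seq_len(l - 1L), seq_len(l - 1L) + 1L, sep = "_")

as_class_factor <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), CLASS_LEVELS)
  if (length(bad) > 0) {
    stop("unknown label(s): ", paste(bad, collapse = ", "))
  }
  factor(x, levels = CLASS_LEVELS)
}
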