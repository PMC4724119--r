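#' Read sequences from a FASTA file
#'
#' Reads every record of a FASTA file into a data frame. Sequences are
#' uppercased and RNA `U` is mapped to `T`, so downstream code only ever sees
#' DNA letters.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id`, `seq` and `length`, one row per
#'   record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("no records in ", path)
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  ids <- names(set)
  ids[is.na(ids) | ids == ""] <- paste0("seq_", which(is.na(ids) | ids == ""))
  # keep only the first whitespace-delimited token, as aligners do
  ids <- sub("\\s.*$", "", ids)
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("record with empty sequence: ", paste(ids[empty], collapse = ", "))
  }
  data.frame(id = ids, seq = unname(seqs), length = nchar(seqs),
             stringsAsFactors = FALSE)
}

#' Read splice-site windows from FASTA or plain text
#'
#' Accepts either FASTA or a plain one-sequence-per-line file (the layout
#' used by the HS3D distribution). All sequences must share one length.
#'
#' @param path Input file.
#' @param label Class label to attach: `"TSS"`, `"FSS"` or `"unknown"`.
#' @param gt_pos 1-based position of the `G` of the GT anchor within each
#'   record. Defaults to the record midpoint left of centre, i.e.
#'   `length/2` for even lengths, which matches windows of the form
#'   flank + GT + flank.
#' @return A `splice_windows` data frame (see [extract_window()]).
#' @export
read_windows <- function(path, label = "unknown", gt_pos = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) > 0 && startsWith(first, ">")) {
    recs <- read_fasta(path)
  } else {
    lines <- toupper(trimws(readLines(path)))
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0) stop("no records in ", path)
    recs <- data.frame(id = paste0("line_", seq_along(lines)), seq = lines,
                       length = nchar(lines), stringsAsFactors = FALSE)
  }
  len <- unique(recs$length)
  if (length(len) != 1) stop("windows must share one length; saw ", paste(len, collapse = ", "))
  if (len %% 2 != 0) stop("window length must be even (flank + GT + flank)")
  gt_pos <- gt_pos %||% (len %/% 2L)
  flank <- gt_pos - 1L
  if (2L * flank + 2L != len) {
    stop("gt_pos = ", gt_pos, " does not centre a GT in windows of length ", len)
  }
  out <- lapply(seq_len(nrow(recs)), function(i) {
    extract_window(recs[i, ], gt_pos = gt_pos, flank = flank, label = label)
  })
  do.call(rbind_windows, out)
}

new_splice_windows <- function(df, flank) {
  stopifnot(all(c("seq", "source_id", "start", "end", "label") %in% names(df)))
  structure(df, flank = as.integer(flank),
            class = c("splice_windows", "data.frame"))
}

rbind_windows <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) && !is.data.frame(parts[[1]])) {
    parts <- parts[[1]]
  }
  flanks <- unique(vapply(parts, function(w) attr(w, "flank"), integer(1)))
  if (length(flanks) != 1) stop("cannot combine windows with different flanks")
  new_splice_windows(do.call(rbind, lapply(parts, as.data.frame)), flanks)
}

#' Extract one GT-anchored window from a sequence record
#'
#' Cuts a window of `flank` bases on each side of a GT di-nucleotide. The
#' paper's benchmark records are 140 bp with GT at positions 71-72 and a
#' 50-base flank, giving 102-bp windows. Coordinates are 1-based inclusive.
#'
#' @param record A single-row data frame (or list) with `id` and `seq`.
#' @param gt_pos 1-based position of the `G` of the anchor.
#' @param flank Number of bases kept on each side of the GT.
#' @param label Optional class label (`"TSS"`, `"FSS"`, `"unknown"`).
#' @return A `splice_windows` data frame with one row: `seq`, `source_id`,
#'   `start`, `end`, `label`.
#' @export
extract_window <- function(record, gt_pos, flank, label = "unknown") {
  seq <- as.character(record$seq)
  id <- as.character(record$id)
  n <- nchar(seq)
  start <- gt_pos - flank
  end <- gt_pos + 1L + flank
  if (start < 1 || end > n) {
    stop("out of bounds: window [", start, ",", end, "] for record '", id,
         "' of length ", n)
  }
  if (substr(seq, gt_pos, gt_pos + 1L) != "GT") {
    stop("anchor mismatch: no GT at position ", gt_pos, " of record '", id, "'")
  }
  win <- substr(seq, start, end)
  if (grepl("[^ACGT]", win)) {
    stop("ambiguous base inside window of record '", id, "'")
  }
  new_splice_windows(
    data.frame(seq = win, source_id = id, start = start, end = end,
               label = label, stringsAsFactors = FALSE),
    flank
  )
}

#' Scan a sequence for all full-flank GT windows
#'
#' Every GT in a sequence is a candidate donor site. Each occurrence with
#' full flanks on both sides and no ambiguous base in the window yields one
#' window; the others are skipped and tallied in the `skips` attribute
#' (a data frame of record id, GT position and reason).
#'
#' @inheritParams extract_window
#' @return A `splice_windows` data frame ordered by start coordinate
#'   (possibly zero rows), with attribute `skips`.
#' @export
scan_gt_sites <- function(record, flank, label = "unknown") {
  seq <- as.character(record$seq)
  id <- as.character(record$id)
  hits <- gregexpr("(?=GT)", seq, perl = TRUE)[[1]]
  hits <- as.integer(hits[hits > 0])
  rows <- list()
  skips <- data.frame(id = character(), gt_pos = integer(), reason = character(),
                      stringsAsFactors = FALSE)
  for (p in hits) {
    if (p - flank < 1 || p + 1L + flank > nchar(seq)) {
      skips <- rbind(skips, data.frame(id = id, gt_pos = p, reason = "short_flank"))
      next
    }
    win <- substr(seq, p - flank, p + 1L + flank)
    if (grepl("[^ACGT]", win)) {
      skips <- rbind(skips, data.frame(id = id, gt_pos = p, reason = "ambiguous_base"))
      next
    }
    rows[[length(rows) + 1L]] <- extract_window(record, p, flank, label)
  }
  out <- if (length(rows) == 0) {
    new_splice_windows(
      data.frame(seq = character(), source_id = character(), start = integer(),
                 end = integer(), label = character(), stringsAsFactors = FALSE),
      flank
    )
  } else {
    rbind_windows(rows)
  }
  attr(out, "skips") <- skips
  out
}

#' Remove duplicate window sequences
#'
#' Keeps the first occurrence of each distinct window sequence, preserving
#' input order. The redundancy check runs on the extracted windows (what the
#' model sees), not on any longer source record.
#'
#' @param windows A `splice_windows` data frame.
#' @return The deduplicated `splice_windows`.
#' @export
deduplicate_windows <- function(windows) {
  if (nrow(windows) == 0) return(windows)
  if (length(unique(nchar(windows$seq))) != 1) {
    stop("mixed window lengths")
  }
  out <- windows[!duplicated(windows$seq), , drop = FALSE]
  rownames(out) <- NULL
  new_splice_windows(out, attr(windows, "flank"))
}

#' Percent identity between two equal-length sequences
#'
#' Scores 1 per matching position and 0 per mismatch, expressed as a
#' percentage of the common length.
#'
#' @param a,b Nucleotide strings of equal positive length.
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_similarity <- function(a, b) {
  if (nchar(a) != nchar(b) || nchar(a) == 0) {
    stop("sequences must have equal positive length")
  }
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  100 * sum(av == bv) / length(av)
}

#' Stratified k-fold assignment
#'
#' Partitions `n_pos` positives and `n_neg` negatives into `k` random
#' non-overlapping folds, stratified so each fold holds `floor(n/k)` or
#' `ceiling(n/k)` items of each class.
#'
#' @param n_pos,n_neg Class sizes.
#' @param k Number of folds (the cross-validation protocol uses 10).
#' @param seed Integer seed; identical seeds give identical assignments.
#' @return A list with `k`, `seed`, and integer fold vectors `pos` and `neg`.
#' @export
make_folds <- function(n_pos, n_neg, k = 10, seed = 1) {
  if (k < 2) stop("k must be at least 2")
  if (n_pos < k || n_neg < k) stop("each class needs at least k members")
  assign_one <- function(n) sample(rep(seq_len(k), length.out = n))
  with_seed(seed, list(
    k = as.integer(k),
    seed = as.integer(seed),
    pos = assign_one(n_pos),
    neg = assign_one(n_neg)
  ))
}

#' Sample windows without replacement
#'
#' Draws `n` distinct windows from a pool, reproducibly for a fixed seed.
#' Used to draw a false-site set matched in size to the unique true sites.
#'
#' @param pool A `splice_windows` data frame.
#' @param n Number of windows to draw.
#' @param seed Integer seed.
#' @return A `splice_windows` data frame with `n` rows.
#' @export
sample_negatives <- function(pool, n, seed = 1) {
  if (n > nrow(pool)) stop("n exceeds pool size")
  idx <- with_seed(seed, sample.int(nrow(pool), n))
  out <- pool[idx, , drop = FALSE]
  rownames(out) <- NULL
  new_splice_windows(out, attr(pool, "flank"))
}

#' Write windows to FASTA
#'
#' @param windows A `splice_windows` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_windows_fasta <- function(windows, path) {
  set <- Biostrings::DNAStringSet(windows$seq)
  names(set) <- sprintf("%s|%s|%d-%d", windows$label, windows$source_id,
                        windows$start, windows$end)
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}
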