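# Shared fixtures built in code at test time.

# Full-pipeline encoded dataset from the synthetic generator: difference
# matrix from all windows (fine for classifier unit tests, where fold
# hygiene is not under test), then row-wise encoding.
make_encoded <- function(n = 200, flank = 10, consensus = 0.8, dependency = 0.5,
                         seed = 7, procedure = "P-1") {
  spec <- synthetic_spec(n_tss = n / 2, n_fss = n / 2, flank = flank,
                         consensus_strength = consensus,
                         dependency_strength = dependency, seed = seed)
  d <- generate_dataset(spec)
  diff <- fold_difference_matrix(d$tss, d$fss, procedure)
  all <- rbind_windows_for_test(d$tss, d$fss)
  list(enc = encode_dataset(all, diff), diff = diff, windows = d)
}

rbind_windows_for_test <- function(a, b) {
  out <- rbind(as.data.frame(a), as.data.frame(b))
  attr(out, "flank") <- attr(a, "flank")
  class(out) <- c("splice_windows", "data.frame")
  out
}

write_temp_fasta <- function(ids, seqs, wrap = NULL) {
  path <- withr::local_tempfile(fileext = ".fasta", .local_envir = parent.frame())
  lines <- unlist(lapply(seq_along(ids), function(i) {
    s <- seqs[i]
    body <- if (is.null(wrap)) s else {
      starts <- seq(1, nchar(s), by = wrap)
      vapply(starts, function(k) substr(s, k, min(k + wrap - 1, nchar(s))),
             character(1))
    }
    c(paste0(">", ids[i]), body)
  }))
  writeLines(lines, path)
  path
}

# A 140-bp record with GT at positions 71-72 (benchmark record layout).
hs3d_like_record <- function(seed = 3) {
  set.seed(seed)
  s <- sample(c("A", "C", "G", "T"), 140, replace = TRUE)
  s[71:72] <- c("G", "T")
  data.frame(id = "rec140", seq = paste(s, collapse = ""), length = 140,
             stringsAsFactors = FALSE)
}
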