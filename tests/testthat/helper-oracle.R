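# Independent naive reference scanner used as the alignment oracle.
# Deliberately written as a plain double loop over character vectors, with no
# shared code with the package implementation.

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  s <- rev(strsplit(x, "", fixed = TRUE)[[1]])
  out <- comp[s]
  out[is.na(out)] <- "N"
  paste(out, collapse = "")
}

oracle_align_one <- function(read, refs, max_mm = 3L) {
  acgt <- c("A", "C", "G", "T")
  rd <- strsplit(read, "", fixed = TRUE)[[1]]
  rc <- strsplit(oracle_revcomp(read), "", fixed = TRUE)[[1]]
  k <- length(rd)
  rows <- list()
  for (j in seq_len(nrow(refs))) {
    rf <- strsplit(refs$seq[j], "", fixed = TRUE)[[1]]
    L <- length(rf)
    if (L < k) next
    for (p in 0:(L - k)) {
      win <- rf[(p + 1):(p + k)]
      mm_s <- sum(rd != win | !(rd %in% acgt))
      if (mm_s <= max_mm) {
        rows[[length(rows) + 1]] <- data.frame(
          ref = refs$name[j], strand = "sense", start = p, end = p + k,
          mismatches = mm_s)
      }
      mm_a <- sum(rc != win | !(rc %in% acgt))
      if (mm_a <= max_mm) {
        rows[[length(rows) + 1]] <- data.frame(
          ref = refs$name[j], strand = "antisense", start = p, end = p + k,
          mismatches = mm_a)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(ref = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      mismatches = integer(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[out$mismatches == min(out$mismatches), , drop = FALSE]
  out[order(out$ref, out$strand, out$start), , drop = FALSE]
}

# canonical string form of an alignment set, for set equality checks
aln_key <- function(df) {
  sort(sprintf("%s:%s:%d:%d:%d", df$ref, df$strand, df$start, df$end,
               df$mismatches))
}

# random read with a planted occurrence carrying exactly n_mm mismatches
plant_read <- function(refs, len, n_mm, antisense = FALSE) {
  j <- sample.int(nrow(refs), 1)
  L <- nchar(refs$seq[j])
  p <- sample.int(L - len + 1L, 1) - 1L
  x <- substr(refs$seq[j], p + 1L, p + len)
  if (antisense) x <- oracle_revcomp(x)
  if (n_mm > 0) {
    s <- strsplit(x, "", fixed = TRUE)[[1]]
    pos <- sample.int(len, n_mm)
    for (i in pos) s[i] <- sample(setdiff(c("A", "C", "G", "T"), s[i]), 1)
    x <- paste(s, collapse = "")
  }
  x
}
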