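#' Read a 4-line FASTQ file into a tibble
#'
#' @param path FASTQ path (gzip accepted).
#' @return Tibble with `read_id` and `seq` (uppercase).
#' @export
read_fastq <- function(path) {
  if (file.size(path) == 0) {
    return(tibble(read_id = character(0), seq = character(0)))
  }
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(read_id = sub("\\s.*$", "", names(x)),
         seq = unname(toupper(as.character(x))))
}

#' Trim the 3' adapter from raw reads
#'
#' Finds the leftmost adapter occurrence in each read: either a full-adapter
#' match anywhere, or an adapter prefix of at least `min_overlap` bases
#' ending at the read's 3' terminus, tolerating up to
#' `floor(max_mismatch_rate * overlap)` mismatches. The prefix preceding the
#' occurrence is the adapter-trimmed read; reads with no occurrence are
#' returned unchanged with `adapter_found = FALSE`.
#'
#' @param reads Tibble with a `seq` column (or a character vector).
#' @param adapter Adapter sequence to trim
#'   (default the Illumina small-RNA adapter).
#' @param min_overlap Minimum terminal adapter-prefix length.
#' @param max_mismatch_rate Mismatch tolerance as a fraction of the overlap.
#' @return The input tibble with `seq` replaced by the trimmed prefix and an
#'   `adapter_found` logical column added.
#' @examples
#' trim_adapter(tibble::tibble(seq = "ACGTACGTAGATCGGAAGAGCACACGTCTGAACTCCAGTCAC"))
#' @export
trim_adapter <- function(reads,
                         adapter = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC",
                         min_overlap = 5L, max_mismatch_rate = 0.1) {
  if (is.character(reads)) reads <- tibble(seq = reads)
  stopifnot(nchar(adapter) >= min_overlap, min_overlap >= 1)
  res <- cpp_trim_adapter(reads$seq, adapter, as.integer(min_overlap),
                          max_mismatch_rate)
  reads$seq <- substr(reads$seq, 1L, res$prefix_len)
  reads$adapter_found <- res$found
  reads
}

#' Strip randomized-end (UMI) bases from adapter-trimmed reads
#'
#' Removes `umi_len` bases from each end of the trimmed prefix, retaining
#' them as `umi5`/`umi3` columns for optional downstream deduplication
#' (deduplication itself is not applied). Reads in which the adapter was not
#' found are discarded, as are prefixes shorter than `2 * umi_len + 1`
#' (no complete insert can be recovered from them).
#'
#' @param reads Tibble from [trim_adapter()] with `seq` and `adapter_found`.
#' @param umi_len Randomized-end length (default 4).
#' @return A list: `reads` (tibble with `seq` = insert, `umi5`, `umi3`),
#'   `n_no_adapter` and `n_too_short` discard counters.
#' @export
strip_umis <- function(reads, umi_len = 4L) {
  n_no_adapter <- sum(!reads$adapter_found)
  kept <- filter(reads, .data$adapter_found)
  len <- nchar(kept$seq)
  too_short <- len < 2L * umi_len + 1L
  n_too_short <- sum(too_short)
  kept <- kept[!too_short, , drop = FALSE]
  len <- len[!too_short]
  kept$umi5 <- substr(kept$seq, 1L, umi_len)
  kept$umi3 <- substr(kept$seq, len - umi_len + 1L, len)
  kept$seq <- substr(kept$seq, umi_len + 1L, len - umi_len)
  list(reads = kept, n_no_adapter = n_no_adapter, n_too_short = n_too_short)
}

#' Size-select inserts
#'
#' Retains inserts with `lo <= length <= hi` (defaults 18-40 nt, the analysis
#' window for small-RNA libraries) and reports a per-length histogram of the
#' input.
#'
#' @param reads Tibble with a `seq` column.
#' @param lo,hi Inclusive length bounds.
#' @return A list: `reads` (retained rows), `histogram` (tibble `length`,
#'   `n`), `n_out_of_range`.
#' @export
size_filter <- function(reads, lo = 18L, hi = 40L) {
  stopifnot(lo <= hi)
  len <- nchar(reads$seq)
  histogram <- count(tibble(length = len), .data$length)
  keep <- len >= lo & len <= hi
  list(reads = reads[keep, , drop = FALSE], histogram = histogram,
       n_out_of_range = sum(!keep))
}

#' Preprocess a raw small-RNA FASTQ to analyzable inserts
#'
#' Runs adapter trimming, randomized-end removal and size selection in order
#' and returns the retained inserts together with the discard accounting
#' (input = retained + no-adapter + too-short + out-of-size-range, always).
#'
#' @param fastq Path to a raw FASTQ, or a tibble with `read_id` and `seq`.
#' @inheritParams trim_adapter
#' @inheritParams strip_umis
#' @inheritParams size_filter
#' @return A list: `reads` (tibble `read_id`, `seq`, `umi5`, `umi3`),
#'   `histogram`, and `counts` (named: `input`, `retained`,
#'   `discarded_no_adapter`, `discarded_too_short`, `discarded_out_of_range`).
#' @export
preprocess_reads <- function(fastq,
                             adapter = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC",
                             umi_len = 4L, lo = 18L, hi = 40L,
                             min_overlap = 5L, max_mismatch_rate = 0.1) {
  raw <- if (is.character(fastq)) read_fastq(fastq) else fastq
  n_in <- nrow(raw)
  trimmed <- trim_adapter(raw, adapter, min_overlap, max_mismatch_rate)
  stripped <- strip_umis(trimmed, umi_len)
  sized <- size_filter(stripped$reads, lo, hi)
  out <- select(sized$reads, "read_id", "seq", "umi5", "umi3")
  counts <- c(input = n_in, retained = nrow(out),
              discarded_no_adapter = stripped$n_no_adapter,
              discarded_too_short = stripped$n_too_short,
              discarded_out_of_range = sized$n_out_of_range)
  stopifnot(counts[["input"]] == sum(counts[-1]))
  list(reads = out, histogram = sized$histogram, counts = counts)
}
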