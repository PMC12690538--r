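#' Map reads to transposon consensus sequences (all best-stratum hits)
#'
#' Exhaustive ungapped full-length comparison of every read against every
#' transposon consensus on both strands: for each read the minimal mismatch
#' count m* over all placements is found and *all* placements with exactly m*
#' mismatches are reported, provided m* does not exceed `max_mm` (bowtie
#' `-v 3 --all --best --strata` semantics). A read is antisense when it
#' equals the reverse complement of the reference window. Non-ACGT symbols in
#' a read count as mismatches at their positions.
#'
#' Duplicate read sequences are collapsed internally and re-expanded, so cost
#' scales with the number of distinct sequences.
#'
#' @param reads Tibble with `read_id` and `seq`, or a character vector of
#'   read sequences.
#' @param refs Transposon reference tibble (`name`, `seq`) or a full
#'   `pirna_refs` set (transposons are selected automatically).
#' @param max_mm Maximum tolerated mismatches (default 3).
#' @param fractional If `TRUE`, each alignment carries weight `1/n` where `n`
#'   is the read's number of best-stratum hits; otherwise every alignment
#'   weighs 1.
#' @return A tibble with columns `read_id`, `ref`, `strand` (`sense` /
#'   `antisense`), `start`, `end` (0-based half-open on the reference),
#'   `mismatches`, `weight`. Reads with no placement within `max_mm` are
#'   absent.
#' @examples
#' refs <- tibble::tibble(name = "TE1", class = "transposon",
#'                        seq = strrep("ACGT", 30))
#' align_reads(tibble::tibble(read_id = "r1", seq = "ACGTACGTACGTACGTACGTACG"),
#'             refs)
#' @export
align_reads <- function(reads, refs, max_mm = 3L, fractional = FALSE) {
  if (is.character(reads)) {
    reads <- tibble(read_id = sprintf("read%06d", seq_along(reads)),
                    seq = reads)
  }
  if (inherits(refs, "pirna_refs") || "class" %in% names(refs)) {
    te <- refs[refs$class == "transposon", , drop = FALSE]
    if (nrow(te) > 0) refs <- te
  }
  useq <- unique(reads$seq)
  hits <- as_tibble(cpp_align_best(useq, refs$seq, as.integer(max_mm)))
  hits <- mutate(hits,
                 seq = useq[.data$read],
                 ref = refs$name[.data$ref],
                 strand = if_else(.data$strand == 0L, "sense", "antisense"),
                 end = .data$start + nchar(.data$seq))
  out <- inner_join(select(reads, "read_id", "seq"), hits,
                    by = "seq", relationship = "many-to-many")
  out <- select(out, "read_id", "ref", "strand", "start", "end",
                "mismatches")
  if (fractional) {
    out <- out |>
      group_by(.data$read_id) |>
      mutate(weight = 1 / n()) |>
      ungroup()
  } else {
    out$weight <- 1
  }
  arrange(out, .data$read_id, .data$ref, .data$start)
}

#' Write alignments as SAM
#'
#' Emits a minimal, standards-conformant SAM file: `@HD`/`@SQ` headers with
#' reference lengths, 1-based `POS`, FLAG 16 for antisense placements, a
#' full-length match CIGAR and an `NM` mismatch tag.
#'
#' @param alignments Tibble from [align_reads()].
#' @param reads Tibble with `read_id` and `seq` supplying sequences.
#' @param refs Reference tibble with `name` and `seq` (for header lengths).
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, reads, refs, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", refs$name, nchar(refs$seq)))
  aln <- left_join(alignments, select(reads, "read_id", "seq"),
                   by = "read_id")
  seq_out <- if_else(aln$strand == "antisense", revcomp_chr(aln$seq), aln$seq)
  body <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                  aln$read_id,
                  if_else(aln$strand == "antisense", 16L, 0L),
                  aln$ref, aln$start + 1L, nchar(aln$seq), seq_out,
                  aln$mismatches)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Import externally produced alignments from SAM
#'
#' Accepts a SAM file as an alternative front door to [align_reads()];
#' mapped records are converted to the same alignment tibble (strand from
#' FLAG bit 16, 0-based coordinates, mismatches from the `NM` tag).
#'
#' @param path SAM path.
#' @return Alignment tibble as from [align_reads()] (weight 1).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0) {
    return(tibble(read_id = character(0), ref = character(0),
                  strand = character(0), start = integer(0),
                  end = integer(0), mismatches = integer(0),
                  weight = numeric(0)))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  flag <- vapply(f, function(x) as.integer(x[2]), integer(1))
  mapped <- bitwAnd(flag, 4L) == 0L
  f <- f[mapped]; flag <- flag[mapped]
  nm <- vapply(f, function(x) {
    tag <- grep("^NM:i:", x[-(1:11)], value = TRUE)
    if (length(tag)) as.integer(sub("^NM:i:", "", tag[1])) else NA_integer_
  }, integer(1))
  start <- vapply(f, function(x) as.integer(x[4]), integer(1)) - 1L
  len <- vapply(f, function(x) nchar(x[10]), integer(1))
  tibble(read_id = vapply(f, `[`, character(1), 1),
         ref = vapply(f, `[`, character(1), 3),
         strand = if_else(bitwAnd(flag, 16L) != 0L, "antisense", "sense"),
         start = start, end = start + len, mismatches = nm, weight = 1)
}
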