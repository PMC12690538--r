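#' Remove infrastructural-RNA reads
#'
#' A read matching any infrastructural reference (rRNA, tRNA, snRNA, snoRNA,
#' miRNA) on either strand, full length, with at most `max_mm` mismatches is
#' removed before any further classification. References shorter than a read
#' are simply never matched by it.
#'
#' @param reads Tibble with `read_id` and `seq`.
#' @param infra Reference tibble (`name`, `class`, `seq`) of infrastructural
#'   RNAs.
#' @param max_mm Mismatch tolerance (default 1).
#' @return A list: `reads` (passing rows), `removed` (removed rows with
#'   `matched_ref` and `matched_class`), `removed_by_class` (count tibble).
#' @export
filter_infrastructural <- function(reads, infra, max_mm = 1L) {
  if (nrow(infra) == 0) {
    abort("Infrastructural reference set is empty.",
          class = "pirnakit_bad_refs")
  }
  hit <- cpp_match_any(reads$seq, infra$seq, as.integer(max_mm))
  removed <- reads[!is.na(hit), , drop = FALSE]
  removed$matched_ref <- infra$name[hit[!is.na(hit)]]
  removed$matched_class <- infra$class[hit[!is.na(hit)]]
  list(reads = reads[is.na(hit), , drop = FALSE],
       removed = removed,
       removed_by_class = count(removed, .data$matched_class,
                                name = "n"))
}

#' Extract endogenous siRNA reads and the normalisation denominator
#'
#' Reads of length within `len_range` matching an hpRNA reference (either
#' strand, full length, at most `max_mm` mismatches) are tagged as endogenous
#' siRNAs; their count `S` is the library's per-million normalisation
#' denominator. A zero count is flagged with a warning here and causes a hard
#' failure at normalisation time.
#'
#' @param reads Tibble with `read_id` and `seq` (already
#'   infrastructural-filtered).
#' @param hp hpRNA reference tibble.
#' @param len_range Inclusive siRNA length window (default 20-22 nt).
#' @param max_mm Mismatch tolerance (default 1).
#' @return A list: `sirna_count`, `sirnas` (tagged rows with `matched_ref`),
#'   `reads` (all remaining rows).
#' @export
extract_sirnas <- function(reads, hp, len_range = c(20L, 22L), max_mm = 1L) {
  if (nrow(hp) == 0) {
    abort("hpRNA reference set is empty.", class = "pirnakit_bad_refs")
  }
  len <- nchar(reads$seq)
  in_window <- len >= len_range[1] & len <= len_range[2]
  hit <- rep(NA_integer_, nrow(reads))
  hit[in_window] <- cpp_match_any(reads$seq[in_window], hp$seq,
                                  as.integer(max_mm))
  is_si <- !is.na(hit)
  sirnas <- reads[is_si, , drop = FALSE]
  sirnas$matched_ref <- hp$name[hit[is_si]]
  S <- nrow(sirnas)
  if (S == 0) {
    warn("No hpRNA-matching reads: siRNA normalisation denominator is 0.")
  }
  list(sirna_count = S, sirnas = sirnas,
       reads = reads[!is_si, , drop = FALSE])
}

#' Define the piRNA candidate set
#'
#' Among infrastructural-filtered, non-siRNA reads, those longer than 22 nt
#' are piRNA candidates; shorter reads are left unassigned.
#'
#' @param reads Tibble with `seq`.
#' @param min_len Minimum piRNA length (default 23, i.e. "> 22 nt").
#' @return A list: `pirna_candidates`, `unassigned` (tibbles).
#' @export
define_pirnas <- function(reads, min_len = 23L) {
  is_pi <- nchar(reads$seq) >= min_len
  list(pirna_candidates = reads[is_pi, , drop = FALSE],
       unassigned = reads[!is_pi, , drop = FALSE])
}

#' Classify processed reads hierarchically
#'
#' Applies the fixed classification order: infrastructural filter first, then
#' endogenous-siRNA extraction (which therefore takes precedence over any
#' transposon match), then piRNA-candidate definition by length. Every read
#' ends in exactly one class.
#'
#' @param reads Tibble with `read_id` and `seq` (processed inserts).
#' @param refs Full `pirna_refs` reference set.
#' @param max_mm Mismatch tolerance for infrastructural and hpRNA matching.
#' @param sirna_range siRNA length window.
#' @param pirna_min_len Minimum piRNA candidate length.
#' @return A list: `reads` (input rows with a `class` column in
#'   `infrastructural`, `sirna`, `pirna_candidate`, `unassigned`, and
#'   `matched_ref` where applicable), `sirna_count`, and `report` (class
#'   count tibble).
#' @examples
#' refs <- make_references(2, 2, 1, seed = 5)
#' lib <- simulate_library(refs, library_spec(genotype_wildtype(),
#'   n_pirna = 200, n_sirna = 100, n_infrastructural = 50, seed = 9))
#' cls <- classify_reads(lib$truth, lib$refs)
#' cls$report
#' @export
classify_reads <- function(reads, refs, max_mm = 1L,
                           sirna_range = c(20L, 22L), pirna_min_len = 23L) {
  fi <- filter_infrastructural(reads, infra_refs(refs), max_mm)
  si <- extract_sirnas(fi$reads, hp_refs(refs), sirna_range, max_mm)
  pi <- define_pirnas(si$reads, pirna_min_len)

  tag <- function(x, cls, ref = NULL) {
    if (nrow(x) == 0) {
      x$class <- character(0)
    } else {
      x$class <- cls
    }
    if (is.null(ref)) x$matched_ref <- rep(NA_character_, nrow(x))
    x
  }
  out <- bind_rows(
    tag(fi$removed, "infrastructural", ref = TRUE),
    tag(si$sirnas, "sirna", ref = TRUE),
    tag(pi$pirna_candidates, "pirna_candidate"),
    tag(pi$unassigned, "unassigned")
  )
  stopifnot(nrow(out) == nrow(reads))
  list(reads = out, sirna_count = si$sirna_count,
       report = count(out, .data$class, name = "n"))
}
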