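#' Count piRNAs per transposon and strand
#'
#' Each best-stratum alignment of a read longer than 22 nt increments its
#' (transposon, strand) cell by the alignment's weight (1 in the default
#' all-hits mode, 1/n in fractional mode). All (reference, strand) cells of
#' the supplied reference universe are reported, zero-filled.
#'
#' @param alignments Alignment tibble from [align_reads()] (piRNA-candidate
#'   reads).
#' @param min_len Minimum read length counted (default 23).
#' @param universe Optional character vector of transposon names defining the
#'   full table; defaults to the references present in `alignments`.
#' @return Tibble `transposon`, `strand`, `count`.
#' @export
count_pirnas <- function(alignments, min_len = 23L, universe = NULL) {
  if (is.null(universe)) universe <- sort(unique(alignments$ref))
  if (!"weight" %in% names(alignments)) alignments$weight <- 1
  kept <- filter(alignments, .data$end - .data$start >= min_len)
  counts <- kept |>
    group_by(transposon = .data$ref, strand = .data$strand) |>
    summarise(count = sum(.data$weight), .groups = "drop")
  grid <- tidyr::expand_grid(transposon = universe,
                             strand = c("sense", "antisense"))
  grid |>
    left_join(counts, by = c("transposon", "strand")) |>
    mutate(count = replace_na(.data$count, 0))
}

#' Normalise piRNA counts to one million endogenous siRNAs
#'
#' Computes `abundance = 1e6 * count / sirna_count` per (transposon, strand)
#' cell. Scaling every raw count (including the siRNA denominator) by a
#' common factor leaves abundances exactly unchanged.
#'
#' @param counts Tibble from [count_pirnas()].
#' @param sirna_count Library siRNA count `S`; must be positive.
#' @param library Library label recorded in the table.
#' @return Tibble of class `abundance_table`: `library`, `transposon`,
#'   `strand`, `count`, `sirna_count`, `abundance`.
#' @export
normalize_abundance <- function(counts, sirna_count, library = "library") {
  if (!is.numeric(sirna_count) || length(sirna_count) != 1 ||
      is.na(sirna_count) || sirna_count <= 0) {
    abort(paste0("siRNA normalisation denominator must be positive (got ",
                 deparse(sirna_count), "); the library has no usable ",
                 "endogenous siRNAs."),
          class = "pirnakit_zero_sirna")
  }
  out <- mutate(counts, library = library, sirna_count = sirna_count,
                abundance = 1e6 * .data$count / sirna_count)
  out <- select(out, "library", "transposon", "strand", "count",
                "sirna_count", "abundance")
  class(out) <- c("abundance_table", class(out))
  out
}

#' Average replicate abundance tables on the normalised scale
#'
#' @param tables A list of `abundance_table` tibbles over the same
#'   transposon universe.
#' @param library Label for the averaged table.
#' @return An `abundance_table` with averaged `abundance` (counts and
#'   denominators are summed for reference).
#' @export
average_abundance <- function(tables, library = "mean") {
  bound <- bind_rows(tables)
  out <- bound |>
    group_by(.data$transposon, .data$strand) |>
    summarise(count = sum(.data$count),
              sirna_count = sum(.data$sirna_count),
              abundance = mean(.data$abundance), .groups = "drop") |>
    mutate(library = library) |>
    select("library", "transposon", "strand", "count", "sirna_count",
           "abundance")
  class(out) <- c("abundance_table", class(out))
  out
}

#' Per-transposon fold changes between two libraries
#'
#' Computes `r = (A_mut + eps) / (A_wt + eps)` and `log2(r)` per
#' (transposon, strand) cell on the siRNA-normalised scale. Cells absent in
#' one table are treated as zero counts; a mismatch in the transposon
#' universes themselves is an error.
#'
#' @param wt,mut `abundance_table` tibbles (wild-type reference and mutant).
#' @param eps Pseudo-count in normalised units (default 1), recorded in the
#'   `eps` attribute of the result.
#' @return Tibble `transposon`, `strand`, `abundance_wt`, `abundance_mut`,
#'   `ratio`, `log2_ratio`.
#' @export
fold_changes <- function(wt, mut, eps = 1) {
  only_wt <- setdiff(unique(wt$transposon), unique(mut$transposon))
  only_mut <- setdiff(unique(mut$transposon), unique(wt$transposon))
  if (length(only_wt) || length(only_mut)) {
    abort(paste0("Transposon universes differ between libraries. ",
                 "Only in wild-type: ",
                 paste(only_wt, collapse = ", "), "; only in mutant: ",
                 paste(only_mut, collapse = ", ")),
          class = "pirnakit_universe_mismatch")
  }
  joined <- full_join(
    select(wt, "transposon", "strand", abundance_wt = "abundance"),
    select(mut, "transposon", "strand", abundance_mut = "abundance"),
    by = c("transposon", "strand"))
  out <- joined |>
    mutate(abundance_wt = replace_na(.data$abundance_wt, 0),
           abundance_mut = replace_na(.data$abundance_mut, 0),
           ratio = (.data$abundance_mut + eps) / (.data$abundance_wt + eps),
           log2_ratio = log2(.data$ratio))
  attr(out, "eps") <- eps
  out
}
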