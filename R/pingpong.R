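#' 5'-5' overlap spectrum between opposite-strand piRNAs
#'
#' For every (sense, antisense) alignment pair on the same transposon, the
#' overlap distance is the number of bases the two 5' ends share:
#' `d = a5 - s5 + 1`, where the sense 5' end is `s5 = start` and the
#' antisense 5' end is `a5 = end - 1` (0-based half-open intervals). Pairs
#' are counted with the product of the two alignments' weights for
#' `1 <= d <= d_max`. Only piRNA-length reads (`> 22` nt) contribute.
#'
#' @param alignments Alignment tibble (columns `ref`, `strand`, `start`,
#'   `end`, optional `weight`); truth tables from [simulate_library()] work
#'   directly.
#' @param d_max Largest overlap distance tabulated (default 20).
#' @param min_len Minimum read length (default 23).
#' @return Tibble `transposon`, `overlap` (1..`d_max`), `count`, zero-filled;
#'   transposons with no opposite-strand pair yield all-zero rows.
#' @examples
#' aln <- tibble::tibble(ref = "TE1", strand = c("sense", "antisense"),
#'                       start = c(100L, 84L), end = c(126L, 110L))
#' overlap_spectrum(aln)  # one pair at overlap 10
#' @export
overlap_spectrum <- function(alignments, d_max = 20L, min_len = 23L) {
  if (!"weight" %in% names(alignments)) alignments$weight <- 1
  aln <- filter(alignments, .data$end - .data$start >= min_len)
  universe <- sort(unique(alignments$ref))
  sense <- aln |>
    filter(.data$strand == "sense") |>
    group_by(.data$ref, pos = .data$start) |>
    summarise(w = sum(.data$weight), .groups = "drop")
  anti <- aln |>
    filter(.data$strand == "antisense") |>
    group_by(.data$ref, pos = .data$end - 1L) |>
    summarise(w = sum(.data$weight), .groups = "drop")
  per_d <- purrr::map(seq_len(d_max), function(d) {
    m <- inner_join(sense, mutate(anti, pos = .data$pos - d + 1L),
                    by = c("ref", "pos"))
    m |>
      group_by(.data$ref) |>
      summarise(count = sum(.data$w.x * .data$w.y), .groups = "drop") |>
      mutate(overlap = d)
  })
  grid <- tidyr::expand_grid(transposon = universe,
                             overlap = seq_len(d_max))
  bind_rows(per_d) |>
    rename(transposon = "ref") |>
    right_join(grid, by = c("transposon", "overlap")) |>
    mutate(count = replace_na(.data$count, 0)) |>
    arrange(.data$transposon, .data$overlap)
}

#' Ping-pong linkage z-score at overlap 10
#'
#' Per transposon, overlap counts are converted to frequencies
#' `f(d) = o(d) / sum(o)` and the linkage score is the z-score of `f(10)`
#' against the background of the other distances:
#' `z10 = (f(10) - mean(f(d != 10))) / sd(f(d != 10))` (sample sd). The score
#' is undefined (`NA`, never 0) when the total pair count is below
#' `min_pairs`, or when the background sd is zero while `f(10)` equals the
#' background mean (a perfectly flat spectrum); a zero-variance background
#' with an excess at 10 yields `Inf`.
#'
#' @param spectrum Tibble from [overlap_spectrum()].
#' @param min_pairs Minimum total pair count (default 100).
#' @param signal_d Overlap distance scored (default 10).
#' @return Tibble `transposon`, `n_pairs`, `z10`.
#' @export
linkage_z <- function(spectrum, min_pairs = 100, signal_d = 10L) {
  spectrum |>
    group_by(.data$transposon) |>
    summarise(n_pairs = sum(.data$count),
              z10 = {
                total <- sum(.data$count)
                if (total < min_pairs) NA_real_ else {
                  f <- .data$count / total
                  bg <- f[.data$overlap != signal_d]
                  fd <- f[.data$overlap == signal_d]
                  s <- sd(bg)
                  if (is.na(s) || (s == 0 && fd == mean(bg))) {
                    NA_real_
                  } else {
                    (fd - mean(bg)) / s
                  }
                }
              },
              .groups = "drop")
}

#' Compare ping-pong linkage between two libraries
#'
#' Student's t-test on per-transposon linkage values shared (and defined) in
#' both libraries; the two-sample equal-variance flavour by default, with a
#' paired variant available.
#'
#' @param lib_a,lib_b Linkage tibbles from [linkage_z()].
#' @param labels Length-2 labels for the two libraries.
#' @param paired Use the paired test variant.
#' @return An object of class `pp_linkage_test` with the `htest` fit, the
#'   per-transposon values and deltas, and n. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
compare_linkage <- function(lib_a, lib_b, labels = c("a", "b"),
                            paired = FALSE) {
  shared <- inner_join(
    filter(lib_a, !is.na(.data$z10)),
    filter(lib_b, !is.na(.data$z10)),
    by = "transposon", suffix = c("_a", "_b"))
  if (nrow(shared) < 3) {
    abort(sprintf(paste0("Only %d transposons have defined linkage in both ",
                         "libraries; at least 3 are required."),
                  nrow(shared)),
          class = "pirnakit_too_few_te")
  }
  fit <- t.test(shared$z10_a, shared$z10_b, var.equal = TRUE,
                paired = paired)
  structure(list(
    test = fit,
    labels = labels,
    per_te = mutate(shared, delta = .data$z10_a - .data$z10_b),
    n = nrow(shared)),
    class = "pp_linkage_test")
}

#' @export
print.pp_linkage_test <- function(x, ...) {
  cat(sprintf("Ping-pong linkage comparison: %s vs %s (%d transposons)\n",
              x$labels[1], x$labels[2], x$n))
  cat(sprintf("  t = %.3f, df = %.1f, p = %.3g\n",
              x$test$statistic, x$test$parameter, x$test$p.value))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname compare_linkage
#' @param x A `pp_linkage_test`.
#' @param ... Unused.
#' @export
tidy.pp_linkage_test <- function(x, ...) {
  select(x$per_te, "transposon", "z10_a", "z10_b", "delta")
}

#' @rdname compare_linkage
#' @export
glance.pp_linkage_test <- function(x, ...) {
  tibble(statistic = unname(x$test$statistic),
         p.value = x$test$p.value,
         parameter = unname(x$test$parameter),
         n = x$n,
         method = x$test$method)
}

#' Read a per-transposon linkage table from TSV
#'
#' Ingests externally produced ping-pong linkage values (one row per
#' transposon) for use with [compare_linkage()], e.g. processed
#' per-library tables distributed alongside a study.
#'
#' @param path TSV path with a transposon identifier column and one numeric
#'   linkage column per library.
#' @return A tibble with `transposon` first.
#' @export
read_linkage_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  names(x)[1] <- "transposon"
  x
}
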