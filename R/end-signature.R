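#' Collect genomic windows around antisense piRNA 3' ends
#'
#' For each antisense piRNA alignment, extracts the window covering the last
#' `window_up` read positions plus `window_down` genomic positions downstream
#' of the 3' end, in the read's 5'->3' orientation (i.e. the reverse
#' complement of the consensus window `[start - window_down, start +
#' window_up)` for an antisense alignment `[start, end)`). The downstream
#' position(s) come last in the returned strings, so with the default 10 + 1
#' split each 11-nt window ends on the +1 base. Windows extending past the
#' reference boundary are skipped and counted.
#'
#' @param alignments Alignment tibble (antisense rows of piRNA length are
#'   selected automatically).
#' @param refs Reference tibble with `name` and `seq`.
#' @param window_up Read-terminal positions included (default 10).
#' @param window_down Downstream genomic positions included (default 1).
#' @param min_len Minimum read length (default 23).
#' @return A list: `windows` (character vector, one weight-replicated entry
#'   per best-stratum alignment), `n_skipped`.
#' @export
collect_windows <- function(alignments, refs, window_up = 10L,
                            window_down = 1L, min_len = 23L) {
  aln <- filter(alignments, .data$strand == "antisense",
                .data$end - .data$start >= min_len)
  lo <- aln$start - window_down          # 0-based inclusive
  hi <- aln$start + window_up - 1L
  reflen <- nchar(refs$seq)[match(aln$ref, refs$name)]
  ok <- !is.na(reflen) & lo >= 0L & hi < reflen
  refseq <- refs$seq[match(aln$ref[ok], refs$name)]
  windows <- revcomp_chr(substring(refseq, lo[ok] + 1L, hi[ok] + 1L))
  list(windows = windows, n_skipped = sum(!ok))
}

#' Nucleotide frequency matrix and +1 z-scores around piRNA 3' ends
#'
#' Column-wise base frequencies over the window positions (labelled `-9`..`0`
#' for the read-terminal positions and `+1`.. for the downstream positions),
#' plus, per base, the z-score of its frequency at the first downstream (+1)
#' position against all window positions:
#' `z_b = (F[+1][b] - mean_p F[p][b]) / sd_p F[p][b]` with the population sd
#' (divide by the number of positions). With one outlying position among 11
#' the score is bounded by `sqrt(10)`; the planted-bias recovery tests pin
#' this convention.
#'
#' @param windows Character vector of equal-length windows from
#'   [collect_windows()].
#' @param min_windows Minimum number of windows (default 100); fewer yields
#'   an undefined signature (`NULL`).
#' @param window_down Number of trailing downstream positions in the windows.
#' @return An object of class `end_signature`: `freq` (tibble `position`,
#'   `A`, `C`, `G`, `T`, weblogo-ready), `z` (tibble `base`, `z`),
#'   `n_windows`. Supports [generics::tidy()] and [generics::glance()].
#' @examples
#' sig <- end_signature(rep("AAAAAAAAAAT", 200))
#' sig$z  # z for T is sqrt(10)
#' @export
end_signature <- function(windows, min_windows = 100L, window_down = 1L) {
  n <- length(windows)
  if (n < min_windows) {
    warn(sprintf("Only %d windows (< %d): signature undefined.",
                 n, min_windows))
    return(NULL)
  }
  width <- unique(nchar(windows))
  if (length(width) != 1) {
    abort("Windows must all have the same length.",
          class = "pirnakit_bad_windows")
  }
  mat <- matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
                nrow = n, byrow = TRUE)
  freq <- vapply(seq_len(width), function(p) {
    tab <- table(factor(mat[, p], levels = DNA_BASES))
    as.numeric(tab) / n
  }, numeric(4))          # 4 x width
  positions <- c(seq.int(-(width - window_down - 1L), 0L),
                 seq_len(window_down))
  pos_label <- if_else(positions > 0, paste0("+", positions),
                       as.character(positions))
  freq_tbl <- as_tibble(t(freq), .name_repair = ~DNA_BASES)
  freq_tbl <- mutate(freq_tbl, position = pos_label, .before = 1)

  plus1 <- width - window_down + 1L
  z <- vapply(seq_len(4), function(b) {
    x <- freq[b, ]
    s <- sqrt(mean((x - mean(x))^2))  # population sd over positions
    if (s == 0) NA_real_ else (x[plus1] - mean(x)) / s
  }, numeric(1))
  structure(list(freq = freq_tbl,
                 z = tibble(base = DNA_BASES, z = z),
                 n_windows = n),
            class = "end_signature")
}

#' @export
print.end_signature <- function(x, ...) {
  cat(sprintf("3'-end nucleotide signature over %d windows\n", x$n_windows))
  zu <- x$z$z[x$z$base == "T"]
  cat(sprintf("  z at +1: U/T %.2f, A %.2f, C %.2f, G %.2f\n",
              zu, x$z$z[x$z$base == "A"], x$z$z[x$z$base == "C"],
              x$z$z[x$z$base == "G"]))
  invisible(x)
}

#' @rdname end_signature
#' @param x An `end_signature`.
#' @param ... Unused.
#' @export
tidy.end_signature <- function(x, ...) {
  pivot_longer(x$freq, -"position", names_to = "base",
               values_to = "frequency")
}

#' @rdname end_signature
#' @export
glance.end_signature <- function(x, ...) {
  z <- setNames(x$z$z, paste0("z_", c("A", "C", "G", "U")))
  bind_rows(c(as.list(z), n_windows = x$n_windows))
}
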