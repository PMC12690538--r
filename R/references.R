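#' Generate a synthetic reference set
#'
#' Builds the three reference universes the small-RNA pipeline maps against:
#' transposon consensus sequences, infrastructural RNAs (rRNA, tRNA, snRNA,
#' snoRNA, miRNA, cycled in that order) and hairpin-RNA (hpRNA) loci whose
#' 20-22 nt Dicer products serve as the endogenous-siRNA normalisation
#' denominator. Sequences are i.i.d. uniform over A/C/G/T; locus-level biases
#' (ping-pong pairs, 1U, +1U phasing) are planted later by
#' [sample_pirnas()], which rewrites individual bases.
#'
#' @param n_te Number of transposon consensus sequences (>= 1).
#' @param n_infra Number of infrastructural RNAs (>= 1).
#' @param n_hp Number of hpRNA loci (>= 1).
#' @param seed Integer seed; fully determines the output.
#' @param te_length,hp_length Lengths (nt) of transposon and hpRNA sequences.
#'
#' @return A tibble of class `pirna_refs` with columns `name`, `class`
#'   (`transposon`, `rRNA`, `tRNA`, `snRNA`, `snoRNA`, `miRNA`, `hpRNA`) and
#'   `seq`. Names are unique across the whole set.
#' @examples
#' refs <- make_references(n_te = 2, n_infra = 2, n_hp = 1, seed = 7)
#' dplyr::count(refs, class)
#' @export
make_references <- function(n_te, n_infra, n_hp, seed,
                            te_length = 2000L, hp_length = 400L) {
  for (arg in c("n_te", "n_infra", "n_hp")) {
    v <- get(arg)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 1) {
      abort(paste0("`", arg, "` must be a positive integer (got ",
                   deparse(v), ")."),
            class = "pirnakit_bad_count")
    }
  }
  infra_classes <- c("rRNA", "tRNA", "snRNA", "snoRNA", "miRNA")
  infra_len <- c(rRNA = 1500L, tRNA = 75L, snRNA = 150L, snoRNA = 120L,
                 miRNA = 80L)
  with_seed(seed, {
    te <- tibble(
      name = sprintf("TE%02d", seq_len(n_te)),
      class = "transposon",
      seq = random_dna(n_te, te_length)
    )
    icls <- rep_len(infra_classes, n_infra)
    infra <- tibble(
      name = sprintf("%s%02d", icls, seq_len(n_infra)),
      class = icls,
      seq = unname(purrr::map_chr(infra_len[icls], ~ random_dna(1, .x)))
    )
    hp <- tibble(
      name = sprintf("hpRNA%02d", seq_len(n_hp)),
      class = "hpRNA",
      seq = random_dna(n_hp, hp_length)
    )
    out <- bind_rows(te, infra, hp)
    stopifnot(!anyDuplicated(out$name))
    class(out) <- c("pirna_refs", class(out))
    out
  })
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Write a reference set (or any named sequence table) to FASTA
#'
#' @param refs A tibble with `name` and `seq` columns.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(refs, path) {
  x <- Biostrings::DNAStringSet(setNames(refs$seq, refs$name))
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read a FASTA file into a reference tibble
#'
#' @param path FASTA path.
#' @param class Class label to attach to every sequence (e.g. `"transposon"`).
#' @return A tibble with `name`, `class`, `seq`.
#' @export
read_fasta <- function(path, class = NA_character_) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(name = names(x), class = class,
         seq = unname(toupper(as.character(x))))
}

ref_subset <- function(refs, classes) {
  filter(refs, .data$class %in% classes)
}

transposon_refs <- function(refs) ref_subset(refs, "transposon")
infra_refs <- function(refs) {
  ref_subset(refs, c("rRNA", "tRNA", "snRNA", "snoRNA", "miRNA"))
}
hp_refs <- function(refs) ref_subset(refs, "hpRNA")
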