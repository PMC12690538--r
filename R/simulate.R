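#' Genotype effect sizes for the library simulator
#'
#' Describes how a genotype perturbs piRNA biogenesis relative to wild type:
#' per-transposon multipliers on antisense and sense piRNA output, the
#' fraction of piRNAs emitted as 10-nt-overlap ping-pong pairs, and the
#' probability that the genomic position immediately downstream (+1) of an
#' antisense piRNA 3' end is uridine (the phasing footprint).
#'
#' `antisense_fold`/`sense_fold` may be scalars or vectors recycled across
#' transposons (1.0 = wild-type output).
#'
#' @param label Genotype label.
#' @param antisense_fold,sense_fold Positive multipliers on per-transposon
#'   antisense / sense piRNA counts.
#' @param pingpong_fraction Fraction in `[0, 1]` of piRNA emission events that
#'   produce a sense/antisense pair with an exact 10-nt 5' overlap.
#' @param phasing_u_bias Probability in `[0, 1]` that the +1 position
#'   downstream of an antisense piRNA 3' end is U; 0.25 is the uniform null.
#' @return A list of class `genotype_effect`.
#' @examples
#' genotype_effect("wt")
#' genotype_null_like()
#' @export
genotype_effect <- function(label,
                            antisense_fold = 1,
                            sense_fold = 1,
                            pingpong_fraction = 0.5,
                            phasing_u_bias = 0.8) {
  if (any(antisense_fold <= 0) || any(sense_fold <= 0)) {
    abort("Fold multipliers must be positive.", class = "pirnakit_bad_genotype")
  }
  if (pingpong_fraction < 0 || pingpong_fraction > 1 ||
      phasing_u_bias < 0 || phasing_u_bias > 1) {
    abort("`pingpong_fraction` and `phasing_u_bias` must lie in [0, 1].",
          class = "pirnakit_bad_genotype")
  }
  structure(list(label = label,
                 antisense_fold = antisense_fold,
                 sense_fold = sense_fold,
                 pingpong_fraction = pingpong_fraction,
                 phasing_u_bias = phasing_u_bias),
            class = "genotype_effect")
}

#' @rdname genotype_effect
#' @export
genotype_wildtype <- function() genotype_effect("wildtype")

#' @rdname genotype_effect
#' @details `genotype_zf_like()` mimics a hypomorphic Zinc-Finger-domain
#'   mutant: modest (<10-fold) abundance changes, ping-pong collapsed to a
#'   residual fraction, phasing untouched. `genotype_null_like()` mimics a
#'   null piRNA-pathway mutant: 30-fold antisense reduction, no ping-pong,
#'   no phasing bias.
#' @export
genotype_zf_like <- function() {
  genotype_effect("zf_like", antisense_fold = 0.4, sense_fold = 0.8,
                  pingpong_fraction = 0.05, phasing_u_bias = 0.8)
}

#' @rdname genotype_effect
#' @export
genotype_null_like <- function() {
  genotype_effect("null_like", antisense_fold = 1 / 30, sense_fold = 1 / 30,
                  pingpong_fraction = 0, phasing_u_bias = 0.25)
}

#' Specification of one simulated small-RNA library
#'
#' Bundles the genotype, the target read counts per class, the read-length
#' distributions (piRNA 23-29 nt, siRNA 20-22 nt), the raw-read architecture
#' (4-nt randomized ends flanking the insert, then the 3' adapter, padded to
#' a fixed machine read length) and the seed that fully determines the
#' library.
#'
#' @param genotype A [genotype_effect()].
#' @param n_pirna Target number of transposon piRNA reads at wild-type folds.
#' @param n_sirna Number of hpRNA-derived endogenous siRNA reads.
#' @param n_infrastructural Number of infrastructural-RNA reads.
#' @param seed Integer seed.
#' @param pirna_len_probs Named probabilities over lengths 23-29 nt.
#' @param sirna_len_probs Named probabilities over lengths 20-22 nt.
#' @param umi_len Randomized-end length on each side of the insert.
#' @param adapter3 3' adapter read-through sequence appended after the insert
#'   and 3' UMI: the ligated adapter followed by the downstream PCR-primer
#'   context the sequencer continues into (default the 34-nt Illumina
#'   small-RNA trim target).
#' @param read_length Machine read length records are padded/truncated to.
#' @param p_antisense Probability that an unpaired piRNA is antisense.
#' @param u1_bias Probability that a pair-member antisense piRNA starts with U.
#' @param error_rate Per-base uniform sequencing error rate (default 0).
#' @return A list of class `library_spec`.
#' @export
library_spec <- function(genotype,
                         n_pirna = 20000L,
                         n_sirna = 10000L,
                         n_infrastructural = 5000L,
                         seed = 1L,
                         pirna_len_probs = c(`23` = 0.05, `24` = 0.12,
                                             `25` = 0.20, `26` = 0.30,
                                             `27` = 0.18, `28` = 0.10,
                                             `29` = 0.05),
                         sirna_len_probs = c(`20` = 0.25, `21` = 0.50,
                                             `22` = 0.25),
                         umi_len = 4L,
                         adapter3 = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC",
                         read_length = 150L,
                         p_antisense = 0.75,
                         u1_bias = 0.9,
                         error_rate = 0) {
  stopifnot(inherits(genotype, "genotype_effect"))
  if (n_pirna < 0 || n_sirna < 0 || n_infrastructural < 0) {
    abort("Read counts must be non-negative.", class = "pirnakit_bad_spec")
  }
  if (!nzchar(adapter3)) {
    abort("`adapter3` must be a non-empty nucleotide string.",
          class = "pirnakit_bad_spec")
  }
  structure(list(genotype = genotype, n_pirna = n_pirna, n_sirna = n_sirna,
                 n_infrastructural = n_infrastructural, seed = seed,
                 pirna_len_probs = pirna_len_probs,
                 sirna_len_probs = sirna_len_probs,
                 umi_len = umi_len, adapter3 = adapter3,
                 read_length = read_length, p_antisense = p_antisense,
                 u1_bias = u1_bias, error_rate = error_rate),
            class = "library_spec")
}

sample_lengths <- function(n, probs) {
  as.integer(sample(names(probs), n, replace = TRUE, prob = probs))
}

#' Plant transposon piRNA reads with ping-pong and phasing structure
#'
#' Emits piRNA truth records on the transposon consensus sequences. Emission
#' events per transposon are Poisson with rates proportional to consensus
#' length and the genotype's fold multipliers: a fraction
#' `pingpong_fraction` of events produce a ping-pong pair -- an antisense
#' read whose 5' end (consensus coordinate `a5`) faces a sense partner with
#' 5' end at `a5 - 9`, so the two 5' ends share exactly 10 bases -- and the
#' remainder produce single reads placed uniformly. Pair-member antisense
#' reads start with U with probability `u1_bias`; the sense partner's 10th
#' base is then A by complementarity. The genomic base immediately downstream
#' (+1, read orientation) of every antisense 3' end is U with probability
#' `phasing_u_bias` (else approximately uniform over A/C/G).
#'
#' Biases are planted by *conditioned placement*: read ends are sampled at
#' consensus positions whose genomic base realises the desired outcome, so
#' the consensus sequences are never modified, every emitted read is an exact
#' substring of the references, and all libraries simulated from one
#' reference set stay mutually consistent.
#'
#' @param refs A `pirna_refs` tibble with at least one transposon.
#' @param spec A [library_spec()].
#' @return A list with `truth` (tibble: `read_id`, `class`, `ref`, `strand`,
#'   `start`, `end` (0-based half-open), `pair_id`, `seq`) and `refs` (the
#'   reference set, unchanged, returned for interface symmetry). Transposons
#'   too short to place a read are skipped with a warning.
#' @export
sample_pirnas <- function(refs, spec) {
  te <- transposon_refs(refs)
  if (nrow(te) == 0) {
    abort("Reference set has no transposons.", class = "pirnakit_bad_refs")
  }
  g <- spec$genotype
  f <- g$pingpong_fraction
  len_max <- max(as.integer(names(spec$pirna_len_probs)))
  anti_fold <- rep_len(g$antisense_fold, nrow(te))
  sense_fold <- rep_len(g$sense_fold, nrow(te))
  w <- nchar(te$seq) / sum(nchar(te$seq))
  n0 <- spec$n_pirna / (1 + f)

  out_truth <- vector("list", nrow(te))
  for (i in seq_len(nrow(te))) {
    L <- nchar(te$seq[i])
    if (L < 2L * len_max + 2L) {
      warn(sprintf("Transposon %s (%d nt) too short for read placement; skipped.",
                   te$name[i], L))
      next
    }
    n_pair <- rpois(1, n0 * w[i] * f * anti_fold[i])
    n_anti <- rpois(1, n0 * w[i] * (1 - f) * spec$p_antisense * anti_fold[i])
    n_sense <- rpois(1, n0 * w[i] * (1 - f) * (1 - spec$p_antisense) *
                       sense_fold[i])
    out_truth[[i]] <- plant_on_te(te$name[i], te$seq[i], n_pair, n_anti,
                                  n_sense, spec, len_max)
  }
  truth <- bind_rows(out_truth)
  if (nrow(truth) > 0) {
    truth$read_id <- sprintf("%s_pi%06d", g$label, seq_len(nrow(truth)))
    truth <- select(truth, "read_id", "class", "ref", "strand", "start",
                    "end", "pair_id", "seq")
  }
  list(truth = truth, refs = refs)
}

# plant pairs and singles on one transposon by conditioned placement: the
# consensus sequence is never modified; instead 5'/3' ends are sampled at
# positions whose genomic base realises the desired 1U / +1U outcome, so the
# planted marginal probabilities are exact and all libraries share one
# consistent reference
plant_on_te <- function(name, seq, n_pair, n_anti, n_sense, spec, len_max) {
  g <- spec$genotype
  L <- nchar(seq)
  is_a <- strsplit(seq, "", fixed = TRUE)[[1]] == "A"  # 1-based

  # Pair geometry: antisense 5' end a5 (0-based), sense 5' end s5 = a5 - 9.
  # Constraints realised by position choice:
  #   1U   <=> consensus base at a5 is A (read starts with its complement U;
  #            the sense partner's 10th base is then A by complementarity)
  #   +1U  <=> consensus base at a5 - len (just before the antisense
  #            alignment start) is A
  la_pair <- sample_lengths(n_pair, spec$pirna_len_probs)
  ls_pair <- sample_lengths(n_pair, spec$pirna_len_probs)
  a5_pair <- integer(n_pair)
  if (n_pair > 0) {
    want_u1 <- runif(n_pair) < spec$u1_bias
    want_ph <- runif(n_pair) < g$phasing_u_bias
    rng <- seq.int(len_max, L - len_max - 1L)   # valid a5, 0-based
    for (l in unique(la_pair)) {
      for (w1 in c(TRUE, FALSE)) for (wp in c(TRUE, FALSE)) {
        sel <- la_pair == l & want_u1 == w1 & want_ph == wp
        if (!any(sel)) next
        cand <- rng[is_a[rng + 1L] == w1 & is_a[rng - l + 1L] == wp]
        if (!length(cand)) cand <- rng[is_a[rng + 1L] == w1]
        if (!length(cand)) cand <- rng
        a5_pair[sel] <- sample(cand, sum(sel), replace = TRUE)
      }
    }
  }

  # unpaired antisense: start st (0-based) with +1 condition on base st - 1
  la_single <- sample_lengths(n_anti, spec$pirna_len_probs)
  start_anti <- integer(n_anti)
  if (n_anti > 0) {
    want_ph <- runif(n_anti) < g$phasing_u_bias
    for (l in unique(la_single)) {
      rng <- seq.int(1L, L - l)                 # keep a +1 base in range
      for (wp in c(TRUE, FALSE)) {
        sel <- la_single == l & want_ph == wp
        if (!any(sel)) next
        cand <- rng[is_a[rng] == wp]
        if (!length(cand)) cand <- c(0L, rng)
        start_anti[sel] <- sample(cand, sum(sel), replace = TRUE)
      }
    }
  }

  # unpaired sense: uniform placement
  ls_single <- sample_lengths(n_sense, spec$pirna_len_probs)
  start_sense <- if (n_sense > 0) {
    vapply(ls_single, function(l) sample.int(L - l + 1L, 1) - 1L, integer(1))
  } else integer(0)

  rows <- list()
  if (n_pair > 0) {
    pair_id <- sprintf("%s_pp%05d", name, seq_len(n_pair))
    rows$pair_anti <- tibble(
      class = "pirna", ref = name, strand = "antisense",
      start = a5_pair - la_pair + 1L, end = a5_pair + 1L, pair_id = pair_id)
    rows$pair_sense <- tibble(
      class = "pirna", ref = name, strand = "sense",
      start = a5_pair - 9L, end = a5_pair - 9L + ls_pair, pair_id = pair_id)
  }
  if (n_anti > 0) {
    rows$anti <- tibble(class = "pirna", ref = name, strand = "antisense",
                        start = start_anti, end = start_anti + la_single,
                        pair_id = NA_character_)
  }
  if (n_sense > 0) {
    rows$sense <- tibble(class = "pirna", ref = name, strand = "sense",
                         start = start_sense, end = start_sense + ls_single,
                         pair_id = NA_character_)
  }
  truth <- bind_rows(rows)
  if (nrow(truth) > 0) {
    truth$seq <- extract_reads(seq, truth$start, truth$end, truth$strand)
  }
  truth
}

# read sequence in 5'->3' orientation from 0-based half-open coordinates
extract_reads <- function(refseq, start, end, strand) {
  x <- substring(refseq, start + 1L, end)
  anti <- strand == "antisense"
  x[anti] <- revcomp_chr(x[anti])
  x
}

sample_background_reads <- function(refs, n, len_probs, class, label, prefix) {
  if (n == 0 || nrow(refs) == 0) {
    return(tibble(read_id = character(0), class = character(0),
                  ref = character(0), strand = character(0),
                  start = integer(0), end = integer(0),
                  pair_id = character(0), seq = character(0)))
  }
  lens <- if (is.null(names(len_probs))) {
    sample(len_probs, n, replace = TRUE)
  } else {
    sample_lengths(n, len_probs)
  }
  idx <- sample.int(nrow(refs), n, replace = TRUE,
                    prob = nchar(refs$seq))
  L <- nchar(refs$seq)[idx]
  lens <- pmin(lens, L)
  start <- vapply(seq_len(n), function(i) {
    sample.int(L[i] - lens[i] + 1L, 1) - 1L
  }, integer(1))
  strand <- sample(c("sense", "antisense"), n, replace = TRUE)
  seqs <- vapply(seq_len(n), function(i) {
    substring(refs$seq[idx[i]], start[i] + 1L, start[i] + lens[i])
  }, character(1))
  anti <- strand == "antisense"
  seqs[anti] <- revcomp_chr(seqs[anti])
  tibble(read_id = sprintf("%s_%s%06d", label, prefix, seq_len(n)),
         class = class, ref = refs$name[idx], strand = strand,
         start = start, end = start + lens, pair_id = NA_character_,
         seq = seqs)
}

#' Simulate one complete small-RNA library
#'
#' Plants piRNA, siRNA and infrastructural reads per the genotype and library
#' specification, optionally applies uniform sequencing errors, and (when
#' `dir` is given) writes the raw FASTQ, the reference FASTAs and the truth
#' table. The seed inside `spec` fully determines every byte of output.
#'
#' @param refs A `pirna_refs` tibble from [make_references()].
#' @param spec A [library_spec()].
#' @param dir Optional output directory; created if missing.
#' @return A list with `truth` (one row per emitted read), `refs` (reference
#'   set with planted bases), and, when `dir` is given, `files` (named paths:
#'   `fastq`, `truth`, plus one FASTA per reference class group).
#' @examples
#' refs <- make_references(n_te = 2, n_infra = 2, n_hp = 1, seed = 7)
#' spec <- library_spec(genotype_wildtype(), n_pirna = 200, n_sirna = 100,
#'                      n_infrastructural = 50, seed = 11)
#' lib <- simulate_library(refs, spec)
#' dplyr::count(lib$truth, class)
#' @export
simulate_library <- function(refs, spec, dir = NULL) {
  stopifnot(inherits(spec, "library_spec"))
  label <- spec$genotype$label
  with_seed(spec$seed, {
    pir <- sample_pirnas(refs, spec)
    sir <- sample_background_reads(hp_refs(pir$refs), spec$n_sirna,
                                   spec$sirna_len_probs, "sirna", label, "si")
    inf <- sample_background_reads(infra_refs(pir$refs),
                                   spec$n_infrastructural,
                                   18:30, "infrastructural", label, "in")
    truth <- bind_rows(pir$truth, sir, inf)
    if (spec$error_rate > 0 && nrow(truth) > 0) {
      truth$seq <- mutate_seqs(truth$seq, spec$error_rate)
    }
    out <- list(truth = truth, refs = pir$refs)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      fq <- file.path(dir, paste0(label, ".fastq"))
      assemble_fastq(truth, fq, umi_len = spec$umi_len,
                     adapter3 = spec$adapter3,
                     read_length = spec$read_length)
      tr <- file.path(dir, paste0(label, "_truth.tsv"))
      readr::write_tsv(truth, tr)
      fa <- c(transposons = file.path(dir, "transposons.fa"),
              infrastructural = file.path(dir, "infrastructural.fa"),
              hpRNA = file.path(dir, "hpRNA.fa"))
      write_fasta(transposon_refs(pir$refs), fa[["transposons"]])
      write_fasta(infra_refs(pir$refs), fa[["infrastructural"]])
      write_fasta(hp_refs(pir$refs), fa[["hpRNA"]])
      out$files <- c(list(fastq = fq, truth = tr), as.list(fa))
    }
    out
  })
}

mutate_seqs <- function(seqs, rate) {
  vapply(seqs, function(x) {
    s <- strsplit(x, "", fixed = TRUE)[[1]]
    hit <- which(runif(length(s)) < rate)
    for (i in hit) {
      s[i] <- sample(setdiff(DNA_BASES, s[i]), 1)
    }
    paste(s, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Assemble raw FASTQ records from inserts
#'
#' Reproduces the sequenced read architecture the preprocessing stage later
#' undoes: 4 random nucleotides, the insert, 4 more random nucleotides, the
#' 3' adapter, padded with G (two-colour chemistry dark cycles) or truncated
#' to the machine read length. Qualities are constant high.
#'
#' @param reads Tibble with `read_id` and `seq` (insert) columns.
#' @param path Output FASTQ path.
#' @param umi_len Randomized-end length.
#' @param adapter3 3' adapter sequence.
#' @param read_length Fixed record length.
#' @return Number of records written, invisibly.
#' @export
assemble_fastq <- function(reads, path, umi_len = 4L,
                           adapter3 = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC",
                           read_length = 150L) {
  n <- nrow(reads)
  if (n == 0) {
    file.create(path)
    return(invisible(0L))
  }
  umi5 <- random_dna_vec(n, umi_len)
  umi3 <- random_dna_vec(n, umi_len)
  rec <- paste0(umi5, reads$seq, umi3, adapter3)
  pad <- pmax(0L, read_length - nchar(rec))
  rec <- substr(paste0(rec, strrep("G", pad)), 1L, read_length)
  qual <- strrep("I", nchar(rec))
  x <- Biostrings::DNAStringSet(setNames(rec, reads$read_id))
  Biostrings::writeXStringSet(x, filepath = path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual))
  invisible(n)
}

random_dna_vec <- function(n, len) {
  if (len == 0) return(rep("", n))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  apply(m, 1, paste, collapse = "")
}
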