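test_that("make_references produces the requested, uniquely named universe", {
  refs <- make_references(n_te = 5, n_infra = 3, n_hp = 2, seed = 7)
  expect_equal(nrow(refs), 10)
  expect_equal(sum(refs$class == "transposon"), 5)
  expect_false(anyDuplicated(refs$name) > 0)
  expect_true(all(grepl("^[ACGT]+$", refs$seq)))
  expect_true(all(c("rRNA", "tRNA", "snRNA") %in% refs$class))

  refs1 <- make_references(n_te = 1, n_infra = 1, n_hp = 1, seed = 7)
  expect_equal(nrow(refs1), 3)
})

test_that("reference generation is deterministic and FASTA round-trips", {
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_fasta(make_references(2, 2, 1, seed = 7), f1)
  write_fasta(make_references(2, 2, 1, seed = 7), f2)
  expect_identical(readLines(f1), readLines(f2))

  back <- read_fasta(f1)
  expect_equal(back$seq, make_references(2, 2, 1, seed = 7)$seq)
})

test_that("non-positive reference counts are rejected distinctly", {
  expect_error(make_references(0, 1, 1, seed = 1), class = "pirnakit_bad_count")
  expect_error(make_references(1, -2, 1, seed = 1), class = "pirnakit_bad_count")
})

test_that("pingpong_fraction = 1 emits only 10-nt-overlap pairs", {
  g <- genotype_effect("pp1", pingpong_fraction = 1)
  lib <- small_library(g, n_pirna = 300, n_sirna = 0, n_infrastructural = 0)
  truth <- lib$truth
  expect_true(all(!is.na(truth$pair_id)))
  pairs <- split(truth, truth$pair_id)
  expect_true(all(vapply(pairs, nrow, integer(1)) == 2))
  d <- vapply(pairs, function(p) {
    a5 <- p$end[p$strand == "antisense"] - 1L
    s5 <- p$start[p$strand == "sense"]
    a5 - s5 + 1L
  }, integer(1))
  expect_true(all(d == 10L))
})

test_that("planted reads are exact substrings of the returned references", {
  lib <- small_library(n_pirna = 500, n_sirna = 200, n_infrastructural = 100)
  truth <- lib$truth
  refseq <- lib$refs$seq[match(truth$ref, lib$refs$name)]
  window <- substring(refseq, truth$start + 1L, truth$end)
  anti <- truth$strand == "antisense"
  recon <- window
  recon[anti] <- vapply(window[anti], oracle_revcomp, character(1),
                        USE.NAMES = FALSE)
  expect_identical(recon, truth$seq)
})

test_that("phasing_u_bias = 1 makes every +1 downstream base U", {
  g <- genotype_effect("ph1", pingpong_fraction = 0.5, phasing_u_bias = 1)
  lib <- small_library(g, n_pirna = 400, n_sirna = 0, n_infrastructural = 0)
  win <- collect_windows(lib$truth, lib$refs)
  expect_gt(length(win$windows), 100)
  expect_true(all(substr(win$windows, 11, 11) == "T"))
})

test_that("library output is seed-deterministic byte for byte", {
  refs <- small_refs()
  spec <- library_spec(genotype_wildtype(), n_pirna = 200, n_sirna = 100,
                       n_infrastructural = 50, seed = 33)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  quiet_simulate(refs, spec, dir = d1)
  quiet_simulate(refs, spec, dir = d2)
  for (f in c("wildtype.fastq", "wildtype_truth.tsv", "transposons.fa")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("truth records, emitted reads and FASTQ records agree in number", {
  lib <- small_library(n_pirna = 300, n_sirna = 150, n_infrastructural = 80)
  fq <- tempfile(fileext = ".fastq")
  n <- assemble_fastq(lib$truth, fq)
  expect_equal(n, nrow(lib$truth))
  expect_equal(length(readLines(fq)), 4 * nrow(lib$truth))
})

test_that("expected antisense count scales linearly with antisense_fold", {
  refs <- small_refs()
  anti_n <- function(fold, seed) {
    g <- genotype_effect("x", antisense_fold = fold, pingpong_fraction = 0.3)
    spec <- library_spec(g, n_pirna = 4000, n_sirna = 0,
                         n_infrastructural = 0, seed = seed)
    lib <- quiet_simulate(refs, spec)
    sum(lib$truth$strand == "antisense")
  }
  seeds <- 1:10
  m_full <- mean(vapply(seeds, function(s) anti_n(1, s), numeric(1)))
  m_half <- mean(vapply(seeds, function(s) anti_n(0.5, s + 100), numeric(1)))
  expect_lt(abs(m_half / m_full - 0.5), 0.05)
})

test_that("assembled records have the UMI-insert-UMI-adapter architecture", {
  reads <- tibble::tibble(read_id = "r1", seq = strrep("ACGT", 6))  # 24 nt
  fq <- tempfile(fileext = ".fastq")
  adapter <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC"
  assemble_fastq(reads, fq, umi_len = 4, adapter3 = adapter,
                 read_length = 150)
  rec <- readLines(fq)[2]
  expect_equal(nchar(rec), 150)
  expect_equal(substr(rec, 5, 28), reads$seq)
  expect_equal(substr(rec, 33, 32 + nchar(adapter)), adapter)

  fq0 <- tempfile(fileext = ".fastq")
  expect_equal(assemble_fastq(reads[0, ], fq0), 0L)
  expect_true(file.exists(fq0) && file.size(fq0) == 0)
})
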