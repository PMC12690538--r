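test_that("a uniquely planted read yields its single sense alignment", {
  withr::local_seed(21)
  refs <- tibble::tibble(name = "TE1", class = "transposon",
                         seq = paste(sample(c("A", "C", "G", "T"), 500,
                                            replace = TRUE), collapse = ""))
  read <- substr(refs$seq, 101, 126)
  aln <- align_reads(read, refs)
  expect_equal(nrow(aln), 1)
  expect_equal(aln$ref, "TE1")
  expect_equal(aln$strand, "sense")
  expect_equal(aln$start, 100)
  expect_equal(aln$end, 126)
  expect_equal(aln$mismatches, 0)
})

test_that("only best-stratum placements are reported", {
  # reference carries the read twice exactly and several 1-mm copies
  withr::local_seed(22)
  core <- paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE),
                collapse = "")
  variant <- core
  substr(variant, 3, 3) <- chartr("ACGT", "CATC", substr(variant, 3, 3))
  spacer <- function() paste(sample(c("A", "C", "G", "T"), 40,
                                    replace = TRUE), collapse = "")
  refseq <- paste0(spacer(), core, spacer(), variant, spacer(), core,
                   spacer(), variant, spacer())
  refs <- tibble::tibble(name = "TE1", class = "transposon", seq = refseq)
  aln <- align_reads(core, refs)
  expect_true(all(aln$mismatches == 0))
  expect_equal(sum(aln$strand == "sense"), 2)

  # removing the exact copies promotes the 1-mm stratum
  refs2 <- refs
  refs2$seq <- paste0(spacer(), variant, spacer(), variant, spacer())
  aln2 <- align_reads(core, refs2)
  expect_true(all(aln2$mismatches == 1))
  expect_equal(nrow(aln2), 2)
})

test_that("antisense placements and strand symmetry behave correctly", {
  withr::local_seed(23)
  refs <- tibble::tibble(name = "TE1", class = "transposon",
                         seq = paste(sample(c("A", "C", "G", "T"), 300,
                                            replace = TRUE), collapse = ""))
  read <- oracle_revcomp(substr(refs$seq, 51, 76))
  aln <- align_reads(read, refs)
  expect_equal(aln$strand, "antisense")
  expect_equal(aln$start, 50)

  # aligning the reverse complement swaps strands, nothing else
  fwd <- align_reads(substr(refs$seq, 51, 76), refs)
  expect_equal(fwd$strand, "sense")
  expect_equal(fwd[c("ref", "start", "end", "mismatches")],
               aln[c("ref", "start", "end", "mismatches")])
})

test_that("palindromic reads align once per strand at the same locus", {
  pal <- "ACGTACGTACGTACGTACGTACGT"  # reverse complement of itself
  expect_equal(pal, oracle_revcomp(pal))
  refs <- tibble::tibble(name = "TE1", class = "transposon",
                         seq = paste0(strrep("C", 60), pal, strrep("C", 60)))
  aln <- align_reads(pal, refs)
  both <- aln[aln$start == 60, ]
  expect_setequal(both$strand, c("sense", "antisense"))
})

test_that("non-ACGT read symbols count as mismatches", {
  refs <- tibble::tibble(name = "TE1", class = "transposon",
                         seq = strrep("ACGTT", 20))
  read <- substr(refs$seq, 1, 24)
  substr(read, 5, 5) <- "N"
  aln <- align_reads(read, refs, max_mm = 1)
  expect_true(all(aln$mismatches >= 1))
  expect_gt(nrow(aln), 0)
})

test_that("raising max_mm never removes alignments and is stable below it", {
  withr::local_seed(24)
  refs <- tibble::tibble(
    name = c("TE1", "TE2"), class = "transposon",
    seq = replicate(2, paste(sample(c("A", "C", "G", "T"), 400,
                                    replace = TRUE), collapse = "")))
  for (i in 1:20) {
    read <- plant_read(refs, 24, sample(0:2, 1), antisense = sample(c(TRUE, FALSE), 1))
    a3 <- align_reads(read, refs, max_mm = 3)
    a4 <- align_reads(read, refs, max_mm = 4)
    if (nrow(a3) > 0 && min(a3$mismatches) < 3) {
      expect_identical(aln_key(a3), aln_key(a4))
    } else {
      expect_true(all(aln_key(a3) %in% aln_key(a4)))
    }
  }
})

test_that("alignments agree with the independent naive scanner", {
  withr::local_seed(25)
  refs <- tibble::tibble(
    name = paste0("TE", 1:3), class = "transposon",
    seq = replicate(3, paste(sample(c("A", "C", "G", "T"), 200,
                                    replace = TRUE), collapse = "")))
  for (i in 1:200) {
    n_mm <- sample(0:4, 1)
    read <- plant_read(refs, sample(20:29, 1), n_mm,
                       antisense = sample(c(TRUE, FALSE), 1))
    mine <- align_reads(read, refs, max_mm = 3)
    oracle <- oracle_align_one(read, refs, max_mm = 3)
    expect_identical(aln_key(mine), aln_key(oracle),
                     label = paste("case", i))
  }
})

test_that("fractional mode distributes one count across best-stratum hits", {
  seg <- strrep("ACCGTTGAACCGGTTAACCGGTAG", 1)
  refs <- tibble::tibble(name = c("TE1", "TE2"), class = "transposon",
                         seq = c(paste0(strrep("T", 50), seg, strrep("G", 50)),
                                 paste0(strrep("A", 30), seg, strrep("C", 30))))
  aln <- align_reads(seg, refs, fractional = TRUE)
  expect_equal(nrow(aln), 2)
  expect_equal(aln$weight, c(0.5, 0.5))
  expect_equal(sum(aln$weight), 1)
})

test_that("SAM export/import round-trips the alignment table", {
  lib <- small_library(n_pirna = 200, n_sirna = 0, n_infrastructural = 0)
  reads <- lib$truth[, c("read_id", "seq")]
  aln <- align_reads(reads, lib$refs)
  sam <- tempfile(fileext = ".sam")
  write_sam(aln, reads, lib$refs[lib$refs$class == "transposon", ], sam)
  back <- read_sam(sam)
  expect_equal(nrow(back), nrow(aln))
  expect_identical(aln_key(back), aln_key(aln))
  expect_true(any(grepl("^@SQ\tSN:TE01\tLN:", readLines(sam))))
})
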