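pair_at <- function(a5, sense_start = 100L, sense_len = 26L,
                    anti_len = 26L, te = "TE1") {
  tibble::tibble(
    ref = te, strand = c("sense", "antisense"),
    start = c(sense_start, a5 - anti_len + 1L),
    end = c(sense_start + sense_len, a5 + 1L), weight = 1)
}

test_that("overlap geometry: facing 5' ends 10 apart give d = 10", {
  sp <- overlap_spectrum(pair_at(a5 = 109L))
  expect_equal(sp$count[sp$overlap == 10], 1)
  expect_equal(sum(sp$count), 1)

  sp6 <- overlap_spectrum(pair_at(a5 = 105L))
  expect_equal(sp6$count[sp6$overlap == 6], 1)
})

test_that("spectra use count-weight products and same-reference pairs only", {
  aln <- dplyr::bind_rows(pair_at(109L), pair_at(109L))  # 2 sense x 2 anti
  sp <- overlap_spectrum(aln)
  expect_equal(sp$count[sp$overlap == 10], 4)

  cross <- dplyr::bind_rows(pair_at(109L, te = "TE1"),
                            pair_at(109L, te = "TE2"))
  spc <- overlap_spectrum(cross)
  expect_equal(spc$count[spc$transposon == "TE1" & spc$overlap == 10], 1)
  expect_equal(sum(spc$count), 2)
})

test_that("spectra are translation-invariant and strand-swap symmetric", {
  lib <- small_library(n_pirna = 800, n_sirna = 0, n_infrastructural = 0)
  aln <- lib$truth[lib$truth$class == "pirna", ]
  sp <- overlap_spectrum(aln)

  shifted <- aln
  shifted$start <- shifted$start + 1000L
  shifted$end <- shifted$end + 1000L
  expect_equal(overlap_spectrum(shifted)$count, sp$count)

  swapped <- aln
  swapped$strand <- ifelse(aln$strand == "sense", "antisense", "sense")
  # re-anchor 5' ends: swap start/end roles by mirroring coordinates
  swapped$start <- -aln$end
  swapped$end <- -aln$start
  expect_equal(overlap_spectrum(swapped)$count, sp$count)
})

test_that("linkage z-score handles flat, spiked and sparse spectra", {
  flat <- tibble::tibble(transposon = "TE1", overlap = 1:20, count = 50)
  expect_true(is.na(linkage_z(flat, min_pairs = 100)$z10))

  spiked <- flat
  spiked$count[spiked$overlap == 10] <- 51
  expect_gt(linkage_z(spiked, min_pairs = 100)$z10, 0)

  sparse <- flat
  sparse$count <- 1
  expect_true(is.na(linkage_z(sparse, min_pairs = 100)$z10))

  # hand-computed oracle: counts 1..20 with 100 at d = 10
  counts <- c(1:9, 100, 11:20)
  f <- counts / sum(counts)
  bg <- f[-10]
  expected <- (f[10] - mean(bg)) / sd(bg)
  sp <- tibble::tibble(transposon = "TE1", overlap = 1:20, count = counts)
  expect_equal(linkage_z(sp, min_pairs = 10)$z10, expected)
})

test_that("planted ping-pong fraction drives the z10 signal", {
  z_at <- function(fraction, seed) {
    g <- genotype_effect("x", pingpong_fraction = fraction)
    lib <- small_library(g, seed = seed, n_pirna = 6000, n_sirna = 0,
                         n_infrastructural = 0)
    lz <- linkage_z(overlap_spectrum(lib$truth[lib$truth$class == "pirna", ]))
    mean(lz$z10, na.rm = TRUE)
  }
  z0 <- z_at(0, 71)
  z5 <- z_at(0.5, 72)
  expect_lt(abs(z0), 3)
  expect_gt(z5, 10)
})

test_that("linkage comparison is identity-safe and needs 3 transposons", {
  lz <- tibble::tibble(transposon = paste0("TE", 1:5), n_pairs = 1000,
                       z10 = c(30, 25, 40, 35, 28))
  cmp <- compare_linkage(lz, lz)
  expect_equal(unname(cmp$test$statistic), 0)
  expect_equal(cmp$test$p.value, 1)
  expect_equal(cmp$n, 5)
  expect_equal(nrow(generics::tidy(cmp)), 5)
  expect_equal(generics::glance(cmp)$p.value, 1)

  too_few <- lz[1:2, ]
  expect_error(compare_linkage(too_few, too_few),
               class = "pirnakit_too_few_te")

  # undefined linkage rows are excluded from the comparison
  lz_na <- lz; lz_na$z10[1] <- NA
  expect_equal(compare_linkage(lz, lz_na)$n, 4)
})

test_that("simulated wild-type vs ping-pong-collapsed libraries separate", {
  refs <- make_references(n_te = 12, n_infra = 1, n_hp = 1, seed = 81)
  lz_for <- function(genotype, seed) {
    spec <- library_spec(genotype, n_pirna = 20000, n_sirna = 0,
                         n_infrastructural = 0, seed = seed)
    lib <- quiet_simulate(refs, spec)
    linkage_z(overlap_spectrum(lib$truth))
  }
  wt <- lz_for(genotype_wildtype(), 91)
  zf <- lz_for(genotype_zf_like(), 92)
  cmp <- compare_linkage(wt, zf, labels = c("wt", "zf"))
  expect_lt(cmp$test$p.value, 1e-6)
  expect_gt(mean(cmp$per_te$delta), 0)
})
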