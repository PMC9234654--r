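# GenePop reader / writer

test_that("parsing handles genotypes, missing sentinels and site prefixes", {
  path <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("toy file", "locA", "locB", "POP",
               "S1_1 ,  0101 0102",
               "S1_2 ,  0000 0201"), path)
  d <- read_genepop(path, allele_digits = 2)
  expect_equal(d$loci, c("locA", "locB"))
  expect_equal(d$site, c("S1", "S1"))
  expect_equal(unname(d$allele1[1, ]), c(1L, 1L))
  expect_equal(unname(d$allele2[1, ]), c(1L, 2L))
  # whole-call missing from "0000"; unordered pair stored sorted
  expect_true(is.na(d$allele1[2, 1]) && is.na(d$allele2[2, 1]))
  expect_equal(unname(c(d$allele1[2, 2], d$allele2[2, 2])), c(1L, 2L))
})

test_that("comma-separated locus line and case-insensitive Pop accepted", {
  path <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("t", "locA, locB", "pop", "X_1 ,  001002 003003"), path)
  d <- read_genepop(path, allele_digits = 3)
  expect_equal(d$loci, c("locA", "locB"))
  expect_equal(unname(d$allele2[1, ]), c(2L, 3L))
})

test_that("malformed files are rejected with location information", {
  bad <- function(lines) {
    p <- tempfile(fileext = ".gen")
    writeLines(lines, p)
    p
  }
  expect_error(read_genepop(bad(c("t", "locA", "Pop", "S_1 , 01010"))),
               "width|genotypes")
  expect_error(read_genepop(bad(c("t", "locA", "locA", "Pop",
                                  "S_1 , 0101"))), "duplicate")
  expect_error(read_genepop(bad(c("t", "locA", "Pop", "Pop",
                                  "S_1 , 0101")), 2), "empty population")
  expect_error(read_genepop(bad(c("t", "locA", "Pop"))), "empty population")
})

test_that("round trip is identity on simulated content and writes are
           byte-identical", {
  d <- random_dataset(1, n_pops = 34, n_per_pop = 4, n_loci = 16,
                      n_alleles = 6, miss_rate = 0.05)
  p1 <- withr::local_tempfile(fileext = ".gen")
  p2 <- withr::local_tempfile(fileext = ".gen")
  write_genepop(d, p1)
  back <- read_genepop(p1, site_to_river = d$site_to_river,
                       river_to_catchment = d$river_to_catchment)
  expect_equal(back$ind_id, d$ind_id)
  expect_equal(back$site, d$site)
  expect_equal(back$loci, d$loci)
  expect_equal(back$allele1, d$allele1)
  expect_equal(back$allele2, d$allele2)
  write_genepop(d, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("missing calls are emitted as zero genotypes and widths guarded", {
  d <- toy_dataset(c("S1", "S1"), list(c("1/2", NA)))
  p <- withr::local_tempfile(fileext = ".gen")
  write_genepop(d, p)
  expect_match(readLines(p)[5], "000000")
  big <- toy_dataset("S1", list("1000/1000"))
  expect_error(write_genepop(big, p, allele_digits = 3), "does not fit")
})

test_that("empty dataset writes title and loci without Pop blocks", {
  d <- microsat_dataset(character(0), character(0), c("locA", "locB"),
                        matrix(integer(0), 0, 2), matrix(integer(0), 0, 2),
                        setNames(character(0), character(0)),
                        setNames(character(0), character(0)))
  p <- withr::local_tempfile(fileext = ".gen")
  write_genepop(d, p)
  lines <- readLines(p)
  expect_length(lines, 3)
  expect_false(any(grepl("^Pop$", lines)))
})

test_that("half-missing genotypes collapse to whole-call missing", {
  path <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("t", "locA", "Pop", "S_1 ,  001000"), path)
  d <- read_genepop(path)
  expect_true(is.na(d$allele1[1, 1]))
})
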