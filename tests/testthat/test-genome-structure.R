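test_that("degenerate length distributions give exact element sizes", {
  st <- generate_random_structure(20000, seed = 1,
                                  exon_sdlog = 0, intron_sdlog = 0)
  el <- st$elements
  # drop the truncated terminal element
  el <- el[-nrow(el), ]
  expect_true(all(el$end[el$kind == "exon"] - el$start[el$kind == "exon"] == 50))
  expect_true(all(el$end[el$kind == "intron"] - el$start[el$kind == "intron"] == 100))
})

test_that("element length distributions match their analytic moments", {
  # median of Lognormal(meanlog, sdlog) is exp(meanlog); mean of
  # Unif(100, 5000) is 2550 -- sample enough elements to see both
  st <- generate_random_structure(3e6, seed = 42)
  el <- st$elements[-nrow(st$elements), ]
  exon_len <- (el$end - el$start)[el$kind == "exon"]
  inter_len <- (el$end - el$start)[el$kind == "intergenic"]
  expect_gt(length(exon_len), 1000)
  expect_lt(abs(median(exon_len) - 50) / 50, 0.05)
  expect_lt(abs(mean(inter_len) - 2550) / 2550,
            3 * sd(inter_len) / sqrt(length(inter_len)) / 2550 + 0.02)
  intron_len <- (el$end - el$start)[el$kind == "intron"]
  expect_lt(abs(median(intron_len) - 100) / 100, 0.05)
})

test_that("structures tile the chromosome and are seed-deterministic", {
  for (L in c(1234L, 50000L)) {
    st <- generate_random_structure(L, seed = 7)
    el <- st$elements
    expect_identical(el$start[1], 0L)
    expect_identical(el$end[nrow(el)], L)
    expect_true(all(el$start[-1] == el$end[-nrow(el)]))
    expect_true(all(el$end > el$start))
  }
  a <- generate_random_structure(50000, seed = 11)
  b <- generate_random_structure(50000, seed = 11)
  expect_identical(a, b)
  # explicit seed leaves the caller's RNG stream untouched
  set.seed(99); x1 <- runif(1)
  set.seed(99); invisible(generate_random_structure(10000, seed = 5)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("invalid generator parameters are rejected", {
  expect_error(generate_random_structure(0), "positive")
  expect_error(generate_random_structure(1000, exon_sdlog = -1), "sdlog")
  expect_error(generate_random_structure(1000, intergenic_min = 10,
                                         intergenic_max = 5), "intergenic")
})

test_that("BED annotations load with merge semantics and line-level errors", {
  bed <- tempfile(fileext = ".bed")
  # empty file -> single intergenic element
  writeLines(character(0), bed)
  st <- read_annotation(bed, 1000)
  expect_identical(nrow(st$elements), 1L)
  expect_identical(st$elements$kind, "intergenic")

  # overlapping records merge into one exon
  writeLines(c("chr1\t100\t200", "chr1\t150\t300"), bed)
  st <- read_annotation(bed, 1000)
  ex <- st$elements[st$elements$kind == "exon", ]
  expect_identical(nrow(ex), 1L)
  expect_identical(c(ex$start, ex$end), c(100L, 300L))

  # record past the chromosome end names its line
  writeLines(c("chr1\t100\t200", "chr1\t900\t1200"), bed)
  expect_error(read_annotation(bed, 1000), "line 2")
  writeLines(c("chr1\t100"), bed)
  expect_error(read_annotation(bed, 1000), "line 1")
})

test_that("recombination maps read with piecewise-constant semantics", {
  f <- tempfile()
  writeLines("0\t1e-8", f)
  map <- read_recomb_map(f, 1e6)
  expect_identical(nrow(map), 1L)
  # total map length of the uniform map: 0.01 Morgans
  expect_equal(sum(map$rate * (map$end - c(0, head(map$end, -1)))), 0.01)

  writeLines(c("0\t1e-8", "600000\t5e-8"), f)
  map <- read_recomb_map(f, 1e6)
  # base-pair-weighted mean rate equals sum(r_i * len_i) / L
  lens <- map$end - c(0, head(map$end, -1))
  expect_equal(sum(map$rate * lens) / 1e6,
               (1e-8 * 6e5 + 5e-8 * 4e5) / 1e6)

  writeLines(c("500\t1e-8", "100\t1e-8"), f)
  expect_error(read_recomb_map(f, 1e6), "increasing")
  writeLines(c("0\t-1e-8"), f)
  expect_error(read_recomb_map(f, 1e6), "negative")
})

test_that("structure round-trips through its TSV serialization", {
  st <- generate_random_structure(30000, seed = 2, recomb_rate = 3e-8)
  ef <- tempfile(); mf <- tempfile()
  write_structure(st, ef, mf)
  st2 <- read_structure(ef, mf, 30000)
  expect_equal(st2$elements, st$elements)
  expect_equal(st2$recomb_map$rate, st$recomb_map$rate)
})

test_that("windows tile, weight by base pairs, and conserve exonic content", {
  # all-exon chromosome: every window has density 1 and the map rate
  st <- genome_structure(250000,
                         tibble::tibble(kind = "exon", start = 0L, end = 250000L),
                         uniform_recomb_map(250000, 1e-8))
  w <- make_windows(st, 1e5)
  expect_identical(nrow(w), 3L)
  expect_true(all(w$exon_density == 1))
  expect_true(all(abs(w$mean_r - 1e-8) < 1e-20))
  expect_identical(w$end[3] - w$start[3], 50000L) # terminal window truncated

  # half-exon window
  st <- genome_structure(100000,
                         tibble::tibble(kind = c("exon", "intergenic"),
                                        start = c(0L, 50000L),
                                        end = c(50000L, 100000L)),
                         uniform_recomb_map(100000, 1e-8))
  expect_equal(make_windows(st, 1e5)$exon_density, 0.5)

  # conservation on a random structure, including a non-uniform map
  st <- generate_random_structure(1e6, seed = 13)
  st$recomb_map <- tibble::tibble(end = c(3e5, 7e5, 1e6),
                                  rate = c(1e-8, 5e-8, 2e-9))
  w <- make_windows(st, 1e5)
  exonic_total <- sum((st$elements$end - st$elements$start)[st$elements$kind == "exon"])
  expect_equal(sum(w$exon_density * (w$end - w$start)), exonic_total)
  map_mean <- sum(c(3e5, 4e5, 3e5) * st$recomb_map$rate) / 1e6
  expect_equal(sum(w$mean_r * (w$end - w$start)) / 1e6, map_mean,
               tolerance = 1e-12)
})
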