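test_that("the packaged island table reproduces the printed annotation", {
  pis <- parse_island_table()
  expect_identical(nrow(pis), 78L)
  expect_identical(sum(pis$length), 33397L)
  expect_identical(pis$start[1], 29150L)
  expect_identical(pis$end[1], 29462L)
  expect_identical(pis$length[1], 313L)
  expect_identical(sum(pis$n_assoc >= 1), 75L)
  expect_false(anyNA(pis$hns_mark))
  expect_true(all(pis$hns_mark %in% c("G", "K", "O", "A")))
  expect_true(all(pis$end - pis$start + 1L == pis$length))
  expect_true(all(pis$length >= 300))
})

test_that("malformed island tables are rejected", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("five_prime_end\tlength\tgenes\tA\tB\tC\tD\tE\tH",
               "100\toops\tx\t\t\t\t\t\tG"), tmp)
  expect_error(parse_island_table(tmp), "malformed")
  writeLines(c("five_prime_end\tlength", "1\t2"), tmp)
  expect_error(parse_island_table(tmp), "columns")
})

test_that("at_content computes percentages with a binomial check", {
  expect_equal(at_content("ATAT"), 100)
  expect_equal(at_content("GCGC"), 0)
  expect_equal(at_content("ACGT"), 50)
  g <- gen_genome(10000, gc = 0.5, seed = 9)
  expect_lt(abs(at_content(g) - 50), 2)
  expect_error(at_content(""), "empty")
})

test_that("promoter search windows follow the +/-150 bp rules", {
  expect_identical(promoter_search_window("single", 1000),
                   data.frame(start = 850, end = 1150))
  expect_identical(promoter_search_window("multiple", c(1000, 1200)),
                   data.frame(start = 850, end = 1350))
  # one TSP degenerates to the single rule
  expect_identical(promoter_search_window("multiple", 1000),
                   promoter_search_window("single", 1000))
  expect_identical(promoter_search_window("island", c(500, 900)),
                   data.frame(start = 500, end = 900))
  expect_identical(promoter_search_window("alien", 100)$start, 1)
  expect_error(promoter_search_window("single", numeric(0)), "anchors")
  expect_error(promoter_search_window("single", c(1, 2)), "exactly one")
})

test_that("is_bound applies the probe-ratio and 20-bp overlap rules", {
  region <- list(start = 1, end = 100)
  probe <- list(mode = "probe", positions = c(10, 50, 200),
                ratios = c(1.2, 1.5, 9))
  expect_true(is_bound(region, probe))
  probe$ratios <- c(1.2, 1.49, 9)   # the only >= 1.5 probe lies outside
  expect_false(is_bound(region, probe))

  iv <- function(s, e) list(mode = "intervals",
                            series = list(data.frame(start = s, end = e)))
  expect_true(is_bound(region, iv(81, 100)))    # exactly 20 bp
  expect_false(is_bound(region, iv(82, 100)))   # 19 bp
  # any single series suffices
  two <- list(mode = "intervals",
              series = list(data.frame(start = 500, end = 600),
                            data.frame(start = 1, end = 50)))
  expect_true(is_bound(region, two))
})

test_that("is_bound agrees with a naive scan and is monotone in min_overlap", {
  set.seed(10)
  for (i in 1:50) {
    region <- list(start = sample(1:500, 1), end = 0)
    region$end <- region$start + sample(50:300, 1)
    sites <- gen_binding_intervals(1000, 5, len = c(10, 120),
                                   seed = sample.int(1e6, 1))
    ev <- list(mode = "intervals", series = list(sites))
    naive <- any(pmin(sites$end, region$end) -
                   pmax(sites$start, region$start) + 1 >= 20)
    expect_identical(is_bound(region, ev), naive)
    if (is_bound(region, ev, min_overlap = 40)) {
      expect_true(is_bound(region, ev, min_overlap = 20))
    }
  }
})

test_that("relative occupancy normalizes to the reference set", {
  sets <- list(
    pi = data.frame(start = c(1, 101), end = c(50, 160)),
    multiple = data.frame(start = c(201, 301), end = c(260, 360)))
  ev <- list(mode = "intervals",
             series = list(data.frame(start = c(1, 101, 201),
                                      end = c(60, 160, 260))))
  res <- relative_occupancy(sets, ev)
  expect_equal(unname(res$fold_ratio["multiple"]), 1)
  expect_equal(unname(res$percent_bound["pi"]), 100)
  expect_equal(unname(res$percent_bound["multiple"]), 50)
  expect_equal(unname(res$fold_ratio["pi"]), 2)

  none <- list(mode = "intervals",
               series = list(data.frame(start = 9000, end = 9100)))
  expect_error(relative_occupancy(sets, none), "undefined")
})

test_that("planted differential binding is recovered across seeds", {
  # regions of set A are made bound 3x as often as the reference
  folds <- vapply(1:10, function(seed) {
    set.seed(seed)
    mk <- function(n, p) {
      start <- seq(1, by = 1000, length.out = n)
      bound <- runif(n) < p
      list(regions = data.frame(start = start, end = start + 199),
           sites = data.frame(start = start[bound], end = start[bound] + 99))
    }
    a <- mk(60, 0.9)
    ref <- mk(60, 0.3)
    ref$sites$start <- ref$sites$start + 60000
    ref$sites$end <- ref$sites$end + 60000
    ref$regions$start <- ref$regions$start + 60000
    ref$regions$end <- ref$regions$end + 60000
    ev <- list(mode = "intervals", series = list(rbind(a$sites, ref$sites)))
    res <- relative_occupancy(list(a = a$regions, multiple = ref$regions), ev)
    unname(res$fold_ratio["a"])
  }, numeric(1))
  expect_lt(abs(mean(folds) - 3), 0.45)
})

test_that("overlap null model honours its closed forms", {
  # features covering the whole genome: expected overlap = total region length
  regions <- data.frame(start = c(11, 501), end = c(110, 700))
  whole <- data.frame(start = 1, end = 1000)
  res <- overlap_null_model(regions, whole, 1000, n_trials = 10, seed = 1)
  expect_equal(res$expected_bp, 300)
  expect_equal(res$observed_bp, 300)

  none <- overlap_null_model(regions, whole[0, ], 1000, n_trials = 5, seed = 1)
  expect_identical(none$observed_bp, 0)

  expect_error(overlap_null_model(regions, data.frame(start = 1, end = 2000),
                                  1000), "longer than the genome")
})

test_that("null expectation converges to f * L for independent features", {
  genome <- 50000
  regions <- gen_binding_intervals(genome, 8, len = 800, seed = 21)
  features <- gen_binding_intervals(genome, 20, len = 300, seed = 22)
  res <- overlap_null_model(regions, features, genome, n_trials = 3000,
                            seed = 23)
  L <- sum(BiocGenerics::width(IRanges::reduce(
    IRanges::IRanges(regions$start, regions$end))))
  # expected covered fraction for independent uniform circular features
  f <- 1 - (1 - 300 / genome)^nrow(features)
  want <- f * L
  se <- stats::sd(res$null_overlaps) / sqrt(length(res$null_overlaps))
  expect_lt(abs(res$expected_bp - want), max(3 * se, 0.02 * want))
})

test_that("substitution classes follow the donor/recipient rules", {
  res <- classify_substitutions("ACGT", "ATGT")
  expect_identical(res$total_substitutions, 1L)
  expect_identical(res$at_increasing, 1L)
  expect_identical(res$deamination_compatible, 1L)

  res <- classify_substitutions("AAAA", "AGAA")
  expect_identical(res$at_decreasing, 1L)
  expect_identical(res$deamination_compatible, 0L)

  # neutral transversions and gap runs
  res <- classify_substitutions("ATG-CA--T", "TTGGCAAAT")
  expect_identical(res$neutral, 1L)        # A->T at column 1
  expect_identical(res$insertions, 2L)     # two donor-gap runs
  expect_identical(res$deletions, 0L)
  res <- classify_substitutions("AACCGG", "A-C-GG")
  expect_identical(res$deletions, 2L)

  expect_error(classify_substitutions("ACG", "AC"), "equal length")
  expect_error(classify_substitutions("AXG", "ACG"), "only A/C/G/T")
})

test_that("planted substitution counts are recovered exactly", {
  base <- gen_genome(1000, 0.5, seed = 30)
  pl <- plant_substitutions(base, n_inc = 12, n_dec = 7, n_neu = 5,
                            n_deam = 8, seed = 31)
  res <- classify_substitutions(pl$donor, pl$recipient)
  expect_identical(res$at_increasing, pl$counts$inc)
  expect_identical(res$at_decreasing, pl$counts$dec)
  expect_identical(res$neutral, pl$counts$neu)
  expect_identical(res$deamination_compatible, pl$counts$deam)
  expect_identical(res$total_substitutions,
                   pl$counts$inc + pl$counts$dec + pl$counts$neu)

  # class counts invariant under reverse complement of both rows
  rc <- classify_substitutions(revcomp(pl$donor), revcomp(pl$recipient))
  for (f in c("total_substitutions", "at_increasing", "at_decreasing",
              "neutral", "deamination_compatible")) {
    expect_identical(rc[[f]], res[[f]])
  }
})

test_that("subregion restriction uses recipient coordinates", {
  # donor:    A C G T A C
  # recipient A T G T A C   (C->T at recipient position 2)
  full <- classify_substitutions("ACGTAC", "ATGTAC")
  expect_identical(full$total_substitutions, 1L)
  inside <- classify_substitutions("ACGTAC", "ATGTAC", subregion = c(1, 3))
  expect_identical(inside$total_substitutions, 1L)
  outside <- classify_substitutions("ACGTAC", "ATGTAC", subregion = c(3, 6))
  expect_identical(outside$total_substitutions, 0L)
})
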