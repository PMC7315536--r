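test_that("site frequencies weight patterns by multiplicity and skip missing calls", {
  rps <- make_rps(c("101" = 3, "001" = 1, ".11" = 4))
  f <- site_frequencies(rps)
  # site 1: calls 1,1,1,0 over counts 3+1 -> 3/4; '.' excluded
  expect_equal(f[1], 3 / 4)
  # site 2: 0 (x3), 0 (x1), 1 (x4) -> 4/8
  expect_equal(f[2], 0.5)
  expect_equal(f[3], 1)
})

test_that("site models recover exact linear frequencies by OLS", {
  ages <- c(20, 35, 50, 65, 80)
  sets <- lapply(seq_along(ages), function(k) {
    freq <- 0.002 * ages[k] + 0.1
    n <- 1000
    n1 <- round(freq * n)
    make_rps(stats::setNames(c(n1, n - n1), c("1", "0")),
             sample_id = paste0("s", k))
  })
  meta <- make_meta(ages)
  models <- fit_site_models(sets, meta, min_count = 1)
  expect_equal(models$slope, 0.002, tolerance = 1e-9)
  expect_equal(models$intercept, 0.1, tolerance = 1e-9)

  # constant frequency -> slope 0
  sets_c <- lapply(seq_along(ages), function(k)
    make_rps(c("1" = 40, "0" = 60), sample_id = paste0("s", k)))
  mc <- fit_site_models(sets_c, meta, min_count = 1)
  expect_equal(mc$slope, 0, tolerance = 1e-12)
  expect_equal(mc$intercept, 0.4, tolerance = 1e-12)

  expect_error(fit_site_models(sets[1:2], meta), "at least 3")
})

test_that("site probabilities are the clipped linear functions", {
  m <- data.frame(amplicon_id = "X", site_index = 1:3,
                  slope = c(0.01, 0.01, 0.005),
                  intercept = c(-0.5, 0.5, 0.1))
  p20 <- site_probability(m, 20)
  expect_equal(as.vector(p20), c(0, 0.7, 0.2))     # lower clip at site 1
  p200 <- site_probability(m, 200)
  expect_equal(as.vector(p200), c(1, 1, 1))        # upper clip (site 3: 1.1 -> 1)
  expect_equal(as.vector(site_probability(m[3, ], 60)), 0.4)
})

test_that("pattern likelihood is the independent-site product", {
  # four sites all at p = 0.5 for every age
  m <- data.frame(amplicon_id = "X", site_index = 1:4,
                  slope = 0, intercept = 0.5)
  expect_equal(pattern_likelihood(m, "1010", 50), 0.0625)
  expect_equal(pattern_likelihood(m, "1111", c(0, 100)), c(0.0625, 0.0625))

  # an impossible site zeroes the whole product
  m0 <- data.frame(amplicon_id = "X", site_index = 1:2,
                   slope = 0, intercept = c(0, 0.5))
  expect_equal(pattern_likelihood(m0, "11", 42), 0)
  expect_equal(pattern_likelihood(m0, "01", 42), 0.5)
})

test_that("likelihoods over all patterns sum to one at every grid age", {
  grid <- age_grid()
  for (s in 1:3) {
    n <- c(3, 6, 9)[s]
    mm <- random_site_models(n, seed = 30 + s)
    tot <- Reduce(`+`, lapply(all_patterns(n), function(p)
      pattern_likelihood(mm, p, grid)))
    expect_lt(max(abs(tot - 1)), 1e-9)
  }
})

test_that("pattern-age assignment maximizes over the grid with tie averaging", {
  # Pr('1', a) = a/200 increases to the grid end
  m <- data.frame(amplicon_id = "X", site_index = 1,
                  slope = 1 / 200, intercept = 0)
  expect_equal(predict_pattern_age(m, "1")$a_P, 200)
  expect_equal(predict_pattern_age(m, "0")$a_P, 0)

  # p clips to 1 for a >= 100: plateau 100..200 averages to 150
  mp <- data.frame(amplicon_id = "X", site_index = 1,
                   slope = 0.01, intercept = 0)
  r <- predict_pattern_age(mp, "1")
  expect_equal(r$a_P, 150)
  expect_equal(r$max_likelihood, 1)
  expect_equal(r$n_tied, 101L)

  # impossible pattern at every age -> undefined
  mz <- data.frame(amplicon_id = "X", site_index = 1, slope = 0, intercept = 0)
  rz <- predict_pattern_age(mz, "1")
  expect_true(is.na(rz$a_P))
  expect_equal(rz$max_likelihood, 0)
})

test_that("argmax agrees with the naive brute-force scan on random instances", {
  set.seed(77)
  for (i in 1:100) {
    n <- sample(1:8, 1)
    mm <- random_site_models(n, slope_range = c(-0.01, 0.01),
                             intercept_range = c(-0.2, 1.2))
    pat <- paste(sample(c("0", "1"), n, TRUE), collapse = "")
    got <- predict_pattern_age(mm, pat)
    ref <- naive_pattern_age(mm, pat)
    if (is.na(ref$a_P)) {
      expect_true(is.na(got$a_P))
    } else {
      expect_equal(got$a_P, ref$a_P)
      expect_equal(got$max_likelihood, ref$max_likelihood, tolerance = 1e-12)
    }
  }
})

test_that("donor age is the multiplicity-weighted mean of pattern ages", {
  # two single-site patterns with known a_P: 200 ('1') and 0 ('0')
  m <- data.frame(amplicon_id = "X", site_index = 1,
                  slope = 1 / 200, intercept = 0)
  rps <- make_rps(c("1" = 3, "0" = 1))
  pred <- predict_sample_age(m, rps)
  expect_equal(pred$predicted_age, (3 * 200 + 0) / 4)
  expect_equal(pred$n_reads_used, 4L)

  single <- predict_sample_age(m, make_rps(c("1" = 5)))
  expect_equal(single$predicted_age, 200)
})

test_that("impossible and missing-call reads are excluded per policy", {
  m <- data.frame(amplicon_id = "X", site_index = 1:2,
                  slope = c(0, 1 / 200), intercept = c(0, 0))
  # site 1 can never be methylated: '10' impossible everywhere
  rps <- make_rps(c("10" = 2, "01" = 2, ".1" = 4))
  pred <- predict_sample_age(m, rps)           # default drops '.' reads
  expect_equal(pred$n_reads_excluded, 6L)
  expect_equal(pred$n_reads_used, 2L)
  expect_equal(pred$predicted_age, 200)        # only '01' usable

  marg <- predict_sample_age(m, rps, missing_policy = "marginalize")
  expect_equal(marg$n_reads_excluded, 2L)      # only the impossible pattern
  expect_equal(marg$predicted_age, 200)        # '.1' marginalizes to a_P = 200

  none <- predict_sample_age(m, make_rps(c("10" = 3)))
  expect_true(is.na(none$predicted_age))
})

test_that("single positive-slope site: assigned age is monotone in methylated calls", {
  mm <- data.frame(amplicon_id = "X", site_index = 1:4,
                   slope = 0.003, intercept = 0.2)
  ages <- vapply(0:4, function(k) {
    pat <- paste(c(rep("1", k), rep("0", 4 - k)), collapse = "")
    predict_pattern_age(mm, pat)$a_P
  }, numeric(1))
  expect_true(all(diff(ages) >= 0))
})

test_that("refining the grid step moves interior unique maxima by at most half a year", {
  set.seed(55)
  checked <- 0
  while (checked < 25) {
    mm <- random_site_models(6)
    pat <- paste(sample(c("0", "1"), 6, TRUE), collapse = "")
    coarse <- predict_pattern_age(mm, pat, age_grid(0, 200, 1))
    if (is.na(coarse$a_P) || coarse$n_tied != 1 ||
        coarse$a_P <= 0 || coarse$a_P >= 200) next
    fine <- predict_pattern_age(mm, pat, age_grid(0, 200, 0.25))
    expect_lte(abs(fine$a_P - coarse$a_P), 0.5)
    checked <- checked + 1
  }
})

test_that("read-age distribution is a normalized multiplicity histogram", {
  df <- data.frame(pattern = c("a", "b"), count = c(1, 3),
                   a_P = c(30.2, 75.5), max_likelihood = c(0.5, 0.5))
  dist <- read_age_distribution(df)
  expect_equal(sum(dist$mass), 1)
  expect_equal(dist$mass[dist$bin_start == 30], 0.25)
  expect_equal(dist$mass[dist$bin_start == 75], 0.75)

  one <- read_age_distribution(data.frame(pattern = "a", count = 10,
                                          a_P = 30, max_likelihood = 1))
  expect_equal(sum(one$mass == 1), 1)
  expect_equal(sum(one$mass), 1)
})

test_that("site models round-trip through TSV", {
  mm <- random_site_models(5, amplicon_id = "PDE4C", seed = 8)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_site_models(mm, path)
  back <- read_site_models(path)
  expect_equal(back$slope, mm$slope)
  expect_equal(back$intercept, mm$intercept)
  expect_equal(back$amplicon_id, mm$amplicon_id)
})

test_that("prediction variance shrinks with more reads per donor", {
  mm <- random_site_models(12, seed = 41)
  spread <- vapply(c(50, 800), function(n_reads) {
    preds <- vapply(1:12, function(rep) {
      sets <- simulate_reads(mm, c(d = 50), reads_per_donor = n_reads,
                             seed = 1000 * rep + n_reads)
      predict_sample_age(mm, sets$d, missing_policy = "marginalize")$predicted_age
    }, numeric(1))
    stats::sd(preds)
  }, numeric(1))
  expect_lt(spread[2], spread[1])
})
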