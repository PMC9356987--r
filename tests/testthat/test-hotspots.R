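# Per-codon missense recurrence tests: tallies, exact binomial tail,
# BLOSUM90 weighting and the continuous-tail extension

test_that("codon tallies count only missense observations with codons", {
  u <- make_units(list("CHB", "CHB", "CHB", "PPGL"),
                  variant_type = c("missense", "missense", "missense",
                                   "frameshift"),
                  codon = c(167L, 167L, 167L, 82L),
                  ref_aa = "R", alt_aa = "W")
  cc <- codonCounts(u)
  expect_equal(unname(cc$counts[167]), 3)
  expect_equal(cc$n_total, 3)
  none <- codonCounts(make_units(list("CHB"), variant_type = "frameshift",
                                 codon = 82L))
  expect_equal(none$n_total, 0)
  expect_true(all(none$counts == 0))
})

test_that("zero counts give p = 1 and an empty test errors", {
  counts <- integer(213); counts[167] <- 5
  res <- binomialHotspotTest(counts, 5)
  expect_equal(res$p_raw[1], 1)
  expect_true(all(res$p_raw[counts == 0] == 1))
  expect_error(binomialHotspotTest(integer(213), 0), "empty")
})

test_that("the exact tail matches log-space pmf summation", {
  set.seed(101)
  for (i in 1:20) {
    n <- sample(10:2000, 1)
    cnt <- sample(0:12, 1)
    counts <- integer(213); counts[50] <- cnt
    res <- binomialHotspotTest(counts, n)
    expect_equal(res$p_raw[50], log_binom_tail(n, cnt, 1 / 213),
                 tolerance = 1e-12)
  }
})

test_that("counts of 21 over 1339 observations are deeply significant", {
  counts <- integer(213); counts[167] <- 21
  res <- binomialHotspotTest(counts, 1339)
  expect_lt(res$p_raw[167], 0.05 / 213)
  expect_true(res$significant[167])
})

test_that("BLOSUM weights: normalization identity, additivity, ordering", {
  bl <- readBlosum()
  expect_true(isSymmetric(bl))
  # mean radicality over the 380 ordered non-identical pairs
  aas <- rownames(bl)
  pairs <- expand.grid(r = aas, a = aas, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$r != pairs$a, ]
  expect_equal(nrow(pairs), 380)
  wbar <- mean(bl[cbind(pairs$r, pairs$r)] - bl[cbind(pairs$r, pairs$a)])
  # a substitution whose radicality equals the mean has weight exactly 1
  rad <- bl["R", "R"] - bl["R", "W"]
  expect_equal(blosumWeight("R", "W"), rad / wbar)
  # two identical observations double the codon score
  obs1 <- data.frame(codon = 167L, ref_aa = "R", alt_aa = "W")
  obs2 <- rbind(obs1, obs1)
  expect_equal(blosumAdjust(obs2)$scores[["167"]],
               2 * blosumAdjust(obs1)$scores[["167"]])
  # conservative substitutions weigh less than radical ones (L->I vs L->D)
  expect_lt(blosumWeight("L", "I"), blosumWeight("L", "D"))
  # stop gains are rejected: not missense
  expect_error(blosumWeight("R", "*"), "not missense")
  expect_error(blosumWeight("R", "R"), "not missense")
})

test_that("the continuous tail is 1 at score 0, decreasing in the score,
          and equals the Poisson tail at integer scores", {
  scores <- numeric(213)
  scores[c(10, 20, 30)] <- c(2, 5, 9)
  s_total <- 40
  res <- blosumHotspotTest(scores, s_total)
  expect_equal(res$p_blosum[1], 1)
  expect_true(all(diff(res$p_blosum[order(res$blosum_score)]) <= 1e-12))
  lambda <- s_total / 213
  for (k in c(2, 5, 9)) {
    poisson_tail <- sum(exp(-lambda) * lambda^(k:60) / factorial(k:60))
    expect_equal(res$p_blosum[res$blosum_score == k][1], poisson_tail,
                 tolerance = 1e-9)
  }
  expect_error(blosumHotspotTest(-scores, 40), "negative")
})

test_that("a planted 10x hotspot is recovered with high power", {
  set.seed(2026)
  w <- rep(1, 213); w[167] <- 10; w <- w / sum(w)
  hits <- 0L
  reps <- 60
  for (r in seq_len(reps)) {
    counts <- tabulate(sample.int(213, 500, replace = TRUE, prob = w),
                       nbins = 213)
    res <- binomialHotspotTest(counts, 500)
    hits <- hits + res$significant[167]
  }
  expect_gte(hits / reps, 0.95)
})

test_that("full hotspot analysis combines raw and adjusted tests", {
  u <- make_units(rep(list("PPGL"), 30),
                  variant_type = "missense", codon = 167L,
                  ref_aa = "R", alt_aa = "W")
  hs <- hotspotAnalysis(u)
  tb <- hs@table
  expect_equal(tb$count[tb$codon == 167], 30)
  expect_true(tb$significant[tb$codon == 167])
  expect_true(tb$significant_blosum[tb$codon == 167])
  expect_equal(sum(tb$count), hs@n_total)
  expect_equal(sum(tb$blosum_score), hs@s_total, tolerance = 1e-9)
  expect_true(all(tb$significant | !tb$highly_significant))
})
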