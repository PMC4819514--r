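test_that("group summaries follow the mean +/- SE convention", {
  s <- summarizeGroups(c(1, 2, 3), rep("a", 3))
  expect_equal(s$mean, 2)
  expect_equal(s$se, 1 / sqrt(3))
  sC <- summarizeGroups(rep(5, 4), rep("a", 4))
  expect_equal(sC$se, 0)
  expect_warning(s1 <- summarizeGroups(c(1, 2, 3), c("a", "a", "b")),
                 "n < 2")
  expect_true(is.na(s1$se[s1$group == "b"]))
  # random tables against the sums-of-squares formulas
  set.seed(21)
  for (i in 1:20) {
    v <- rnorm(30); g <- sample(letters[1:3], 30, TRUE)
    s <- summarizeGroups(v, g)
    for (r in seq_len(nrow(s))) {
      vg <- v[g == s$group[r]]
      expect_equal(s$mean[r], sum(vg) / length(vg))
      expect_equal(s$se[r], sqrt(sum((vg - mean(vg))^2) /
                                 (length(vg) - 1) / length(vg)))
    }
  }
})

test_that("one-way ANOVA agrees with first-principles sums of squares", {
  set.seed(33)
  for (i in 1:100) {
    k <- sample(2:5, 1)
    n <- sample(3:9, k, replace = TRUE)
    g <- rep(letters[1:k], n)
    v <- rnorm(sum(n), mean = rep(runif(k, 0, 3), n))
    got <- oneWayAnova(v, g)
    ref <- handAnova(v, g)
    expect_equal(got$F, ref$F, tolerance = 1e-10)
    expect_equal(got$p, ref$p, tolerance = 1e-10)
  }
})

test_that("ANOVA degenerate and error paths behave", {
  expect_error(oneWayAnova(c(1, 1, 1, 1), c("a", "a", "b", "b")),
               class = "tumorquantUndefined")
  expect_error(oneWayAnova(1:4, rep("a", 4)), "two groups")
  expect_error(oneWayAnova(1:3, c("a", "a", "b")), "n >= 2")
  # hand-worked case: two flat groups, one perturbed value
  v <- c(0, 0, 0, 1, 1, 1.3)
  g <- c("a", "a", "a", "b", "b", "b")
  got <- oneWayAnova(v, g)
  # SSB = 2*3*(0.55^2) = 1.815, SSW = 0.06, F = (1.815/1)/(0.06/4) = 121
  expect_equal(got$F, 121, tolerance = 1e-12)
  expect_equal(got$dfBetween, 1)
  expect_equal(got$dfWithin, 4)
  # F is invariant under adding a constant; p invariant under relabeling
  shifted <- oneWayAnova(v + 100, g)
  expect_equal(shifted$F, got$F)
  relab <- oneWayAnova(v, c("z", "z", "z", "q", "q", "q"))
  expect_equal(relab$p, got$p)
})

test_that("Newman-Keuls at k = 2 collapses to the studentized-range (Tukey) test", {
  set.seed(8)
  v <- c(rnorm(6, 0), rnorm(6, 1.2))
  g <- rep(c("a", "b"), each = 6)
  nk <- newmanKeuls(v, g)
  expect_identical(nrow(nk), 1L)
  tk <- TukeyHSD(aov(v ~ factor(g)))[[1]][, "p adj"]
  expect_equal(nk$pValue, unname(tk), tolerance = 1e-8)
})

test_that("Newman-Keuls reproduces a hand-worked three-group stepwise example", {
  # groups of n = 5 with means 10.0, 10.9, 16.0; hand-working the
  # procedure from the sums of squares: MSE = 0.70667, df = 12,
  # SE = sqrt(MSE/5) = 0.37594;
  # outer span (r = 3): q = (16.0 - 10.0)/0.37594 = 15.9599, p ~ 2.7e-7 (sig)
  # nested r = 2: 10.9 vs 10.0 -> q = 2.3940, p = 0.1163 (not sig);
  #               16.0 vs 10.9 -> q = 13.5659, p ~ 5.6e-7 (sig)
  v <- c(9.1, 10.3, 10.0, 11.2, 9.4,
         10.1, 11.6, 10.4, 11.8, 10.6,
         15.2, 16.8, 15.9, 17.1, 15.0)
  g <- rep(c("ctrl", "low", "high"), each = 5)
  nk <- newmanKeuls(v, g)
  getRow <- function(g1, g2) nk[(nk$group1 == g1 & nk$group2 == g2) |
                                (nk$group1 == g2 & nk$group2 == g1), ]
  expect_true(getRow("ctrl", "high")$significant)
  expect_identical(getRow("ctrl", "high")$stepRange, 3L)
  expect_true(getRow("low", "high")$significant)
  expect_false(getRow("ctrl", "low")$significant)
  expect_identical(getRow("ctrl", "low")$stepRange, 2L)
  # frozen hand-computed q statistics and p-values
  expect_equal(getRow("ctrl", "high")$q, 15.9599, tolerance = 1e-4)
  expect_equal(getRow("ctrl", "low")$q, 2.3940, tolerance = 1e-4)
  expect_equal(getRow("ctrl", "low")$pValue, 0.11627, tolerance = 1e-4)
  # decisions match the independent recursive implementation
  orc <- snkOracle(v, g)
  for (r in seq_len(nrow(orc))) {
    expect_identical(getRow(orc$group1[r], orc$group2[r])$significant,
                     orc$significant[r])
  }
})

test_that("Newman-Keuls containment: pairs inside a non-significant span never flag", {
  set.seed(55)
  for (i in 1:50) {
    k <- sample(3:5, 1)
    v <- rnorm(k * 4, rep(runif(k, 0, 2), each = 4))
    g <- rep(letters[1:k], each = 4)
    nk <- newmanKeuls(v, g)
    expect_false(any(nk$blocked & nk$significant))
    orc <- snkOracle(v, g)
    m <- merge(nk, orc, by = c("group1", "group2"))
    expect_identical(m$significant.x, m$significant.y)
  }
  # all-equal means: nothing significant at any alpha
  v0 <- rep(c(1, 2, 3, 4), 3)
  g0 <- rep(c("a", "b", "c"), each = 4)
  for (alpha in c(0.2, 0.05, 0.01))
    expect_false(any(newmanKeuls(v0, g0, alpha)$significant))
  expect_error(newmanKeuls(c(1, 2, 3), c("a", "a", "b")), "n >= 2")
})

test_that("cohort report flags the treated-arm effects and degrades gracefully", {
  tab <- makeGroupCohort(nPerArm = 8L, sdLog = 0.2, seed = 42)
  rep <- runCohortReport(tab)
  expect_setequal(unique(rep$summaries$metric),
                  c("volume", "ktrans", "ef5Fraction", "vesselDistance"))
  fl <- rep$flags
  volFlag <- fl[fl$metric == "volume" & fl$arm == "Met-Gem", ]
  expect_true(volFlag$significantVsControl)
  # single-arm table: summaries only, no ANOVA
  solo <- tab[tab$arm == "Veh-ctrl", ]
  repSolo <- runCohortReport(solo)
  expect_false(is.null(repSolo$summaries))
  expect_null(repSolo$anova)
  # report files are written and rewritten deterministically
  d1 <- file.path(tempdir(), "tq-report-test")
  writeCohortReport(rep, d1)
  expect_true(file.exists(file.path(d1, "summaries.csv")))
  expect_true(file.exists(file.path(d1, "report.txt")))
})
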