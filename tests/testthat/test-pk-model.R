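acq <- acquisitionParams()
aifDefault <- aifModel(onsetTime = acq@nPre * acq@frameInterval)
tt <- frameTimes(acq)

test_that("Kety forward model honours its degenerate limits", {
  expect_equal(ketyForward(0, 0.3, 0, aifDefault, tt), rep(0, length(tt)))
  # a pure-plasma voxel reproduces the AIF exactly
  expect_equal(ketyForward(0, 0.3, 1, aifDefault, tt),
               aifConcentration(aifDefault, tt))
  expect_error(ketyForward(0.2, 0, 0.05, aifDefault, tt), "efflux")
  # pre-contrast frames carry no tracer
  ct <- ketyForward(0.25, 0.3, 0.05, aifDefault, tt)
  expect_identical(ct[tt < aifDefault@onsetTime], rep(0, acq@nPre))
})

test_that("exact convolution matches a fine-grid trapezoid oracle", {
  set.seed(7)
  n <- 10
  kt <- runif(n, 0.05, 0.5); ve <- runif(n, 0.1, 0.5); vp <- runif(n, 0, 0.1)
  oracle <- trapzKetyOracle(kt, ve, vp, aifDefault, tt)
  for (i in seq_len(n)) {
    ct <- ketyForward(kt[i], ve[i], vp[i], aifDefault, tt)
    expect_lt(max(abs(ct - oracle[i, ])), 1e-4)
  }
})

test_that("tissue concentration is monotone in vp, and in ktrans at fixed efflux rate", {
  # note: at fixed ve, raising ktrans also raises kep = ktrans/ve and so
  # accelerates washout; concentration is NOT globally monotone in ktrans
  # then. The clean statements are: linear (hence increasing) in ktrans at
  # fixed kep, nondecreasing in vp everywhere, and nondecreasing in ktrans
  # at fixed ve during early uptake.
  tAll <- tt[c(10, 40, 90, 170)]
  for (kep in c(0.5, 1, 3)) {
    for (kt in seq(0.05, 0.5, by = 0.15)) {
      lo <- ketyForward(kt, kt / kep, 0.05, aifDefault, tAll)
      hi <- ketyForward(kt + 0.02, (kt + 0.02) / kep, 0.05, aifDefault, tAll)
      expect_true(all(hi >= lo))
    }
  }
  for (vp in seq(0, 0.5, by = 0.1)) {
    lo <- ketyForward(0.2, 0.3, vp, aifDefault, tAll)
    hi <- ketyForward(0.2, 0.3, vp + 0.05, aifDefault, tAll)
    expect_true(all(hi >= lo))
  }
  tEarly <- tt[tt >= aifDefault@onsetTime &
               tt <= aifDefault@onsetTime + 90]
  for (kt in seq(0, 0.45, by = 0.05)) {
    lo <- ketyForward(kt, 0.3, 0.05, aifDefault, tEarly)
    hi <- ketyForward(kt + 0.05, 0.3, 0.05, aifDefault, tEarly)
    expect_true(all(hi >= lo - 1e-12))
  }
})

test_that("signal-to-concentration inverts the SPGR forward chain", {
  ctTrue <- ketyForward(0.25, 0.3, 0.05, aifDefault, tt)
  r1 <- 3.9; t1n <- 1800; m0 <- 1000; kappa <- 0.9
  t1t <- 1000 / (1000 / t1n + r1 * ctTrue)
  sig <- array(0, c(1, 1, 1, length(tt)))
  sig[1, 1, 1, ] <- spgrSignal(m0, t1t, acq@trDyn, kappa * acq@flipDyn)
  dyn <- new("DynamicSeries", signal = sig, frameTimes = tt, acq = acq)
  t1m <- new("T1Map", t1 = array(t1n, c(1, 1, 1)),
             m0 = array(m0, c(1, 1, 1)), fitOk = array(TRUE, c(1, 1, 1)))
  fa <- new("FlipAngleMap", kappa = array(kappa, c(1, 1, 1)),
            fitOk = array(TRUE, c(1, 1, 1)))
  conc <- signalToConcentration(dyn, t1m, fa, relaxivity = r1)
  expect_true(all(conc@valid))
  expect_lt(max(abs(conc@conc[1, 1, 1, ] - ctTrue)), 1e-6)

  # constant signal at baseline means zero concentration everywhere
  sigC <- array(spgrSignal(m0, t1n, acq@trDyn, kappa * acq@flipDyn),
                c(1, 1, 1, length(tt)))
  dynC <- new("DynamicSeries", signal = sigC, frameTimes = tt, acq = acq)
  concC <- signalToConcentration(dynC, t1m, fa, relaxivity = r1)
  expect_equal(max(abs(concC@conc[1, 1, 1, ])), 0, tolerance = 1e-12)

  # doubling the relaxivity halves the recovered concentration
  concHalf <- signalToConcentration(dyn, t1m, fa, relaxivity = 2 * r1)
  expect_equal(concHalf@conc[1, 1, 1, ], ctTrue / 2, tolerance = 1e-6)

  # voxels without a valid T1 fit are excluded entirely
  t1bad <- new("T1Map", t1 = array(NA_real_, c(1, 1, 1)),
               m0 = array(NA_real_, c(1, 1, 1)),
               fitOk = array(FALSE, c(1, 1, 1)))
  concBad <- signalToConcentration(dyn, t1bad, fa, relaxivity = r1)
  expect_false(any(concBad@valid))
})

test_that("voxelwise fit recovers noiseless parameters to 0.1% and flags degenerate voxels", {
  truth <- c(ktrans = 0.25, ve = 0.3, vp = 0.05)
  curves <- rbind(ketyForward(truth[1], truth[2], truth[3], aifDefault, tt),
                  rep(0, length(tt)))     # second voxel: no tracer at all
  conc <- curvesAsConcentration(curves, acq)
  pk <- fitKetyVoxelwise(conc, aifDefault, array(TRUE, c(2, 1, 1)))
  expect_true(fitOk(pk)[1, 1, 1])
  expect_equal(ktransMap(pk)[1, 1, 1], truth[["ktrans"]], tolerance = 1e-3)
  expect_equal(veMap(pk)[1, 1, 1], truth[["ve"]], tolerance = 1e-3)
  expect_equal(vpMap(pk)[1, 1, 1], truth[["vp"]], tolerance = 1e-3)
  # all-zero voxel: ktrans driven to its lower bound and flagged
  expect_equal(ktransMap(pk)[2, 1, 1], 0, tolerance = 1e-9)
  expect_false(fitOk(pk)[2, 1, 1])
  expect_false(pk@enhancing[2, 1, 1])
  expect_error(fitKetyVoxelwise(conc, aifDefault, array(FALSE, c(2, 1, 1))),
               "empty mask")
})

test_that("median viable Ktrans excludes flagged voxels and respects phantom counts", {
  mk <- function(kt, ok, enh = TRUE) {
    n <- length(kt)
    new("PKParameterMap", ktrans = array(kt, c(n, 1, 1)),
        ve = array(0.3, c(n, 1, 1)), vp = array(0.05, c(n, 1, 1)),
        rss = array(0, c(n, 1, 1)), fitOk = array(ok, c(n, 1, 1)),
        enhancing = array(enh, c(n, 1, 1)))
  }
  # rim at 0.3 forming 60% of viable voxels pins the median at 0.3
  kt <- c(rep(0.3, 6), rep(0.1, 4))
  pk <- mk(kt, ok = TRUE)
  expect_equal(medianKtransViable(pk, array(TRUE, c(10, 1, 1))), 0.3)
  # uniform map: median equals the value
  expect_equal(medianKtransViable(mk(rep(0.2, 5), TRUE),
                                  array(TRUE, c(5, 1, 1))), 0.2)
  # flagged voxels with arbitrary values never move the result
  kt2 <- c(kt, 99, -5)
  pk2 <- mk(kt2, ok = c(rep(TRUE, 10), FALSE, FALSE))
  expect_equal(medianKtransViable(pk2, array(TRUE, c(12, 1, 1))), 0.3)
  # no viable voxels is an undefined result, not a number
  expect_error(medianKtransViable(mk(0.3, FALSE), array(TRUE, c(1, 1, 1))),
               class = "tumorquantUndefined")
})
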