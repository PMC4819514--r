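blobChannel <- function(d = c(64, 64), nBlobs = 12, seed = 3) {
  set.seed(seed)
  ch <- matrix(10, d[1], d[2])
  for (i in seq_len(nBlobs)) {
    r <- sample(5:(d[1] - 5), 1); c <- sample(5:(d[2] - 5), 1)
    ch[(r - 1):(r + 1), (c - 1):(c + 1)] <- 200
  }
  ch
}

test_that("channel alignment recovers synthetic shifts up to +/-5 px exactly", {
  ref <- blobChannel()
  for (shift in list(c(3, -2), c(-5, 5), c(0, 4), c(-1, 0))) {
    moved <- tumorquant:::shiftMatrix(ref, shift[1], shift[2], fill = 10)
    set <- new("SectionImageSet",
               channels = list(counterstain = ref, ef5 = moved),
               pixelSizeUm = 1, tumorMask = matrix(TRUE, 64, 64),
               necrosisMask = matrix(FALSE, 64, 64),
               artifactMask = matrix(FALSE, 64, 64))
    aligned <- alignChannels(set, maxShift = 6L)
    expect_equal(attr(aligned, "shifts")$ef5, c(-shift[1], -shift[2]))
  }
  # identical channels need no shift
  set0 <- new("SectionImageSet",
              channels = list(counterstain = ref, ef5 = ref),
              pixelSizeUm = 1, tumorMask = matrix(TRUE, 64, 64),
              necrosisMask = matrix(FALSE, 64, 64),
              artifactMask = matrix(FALSE, 64, 64))
  aligned0 <- alignChannels(set0, maxShift = 6L)
  expect_identical(attr(aligned0, "shifts")$ef5, c(0L, 0L))
})

test_that("a pure-noise channel takes the indistinct-peak path and stays unshifted", {
  set.seed(9)
  ref <- blobChannel()
  noise <- matrix(rnorm(64 * 64, 100, 30), 64)
  set <- new("SectionImageSet",
             channels = list(counterstain = ref, tunel = noise),
             pixelSizeUm = 1, tumorMask = matrix(TRUE, 64, 64),
             necrosisMask = matrix(FALSE, 64, 64),
             artifactMask = matrix(FALSE, 64, 64))
  expect_warning(aligned <- alignChannels(set, maxShift = 6L), "indistinct")
  expect_identical(attr(aligned, "shifts")$tunel, c(0L, 0L))
  expect_identical(aligned@channels$tunel, noise)
})

test_that("viable mask is tumor minus necrosis minus artifact, by pixel count", {
  d <- c(40, 40)
  tumor <- matrix(FALSE, d[1], d[2]); tumor[5:36, 5:36] <- TRUE
  necrosis <- matrix(FALSE, d[1], d[2]); necrosis[10:19, 10:29] <- TRUE
  artifact <- matrix(FALSE, d[1], d[2]); artifact[15:24, 25:34] <- TRUE
  ch <- list(counterstain = matrix(50, d[1], d[2]))
  set <- new("SectionImageSet", channels = ch, pixelSizeUm = 1,
             tumorMask = tumor, necrosisMask = necrosis,
             artifactMask = artifact)
  v <- viableMask(set)
  # inclusion-exclusion on the painted rectangles
  nNec <- sum(necrosis & tumor)
  nArt <- sum(artifact & tumor)
  nBoth <- sum(necrosis & artifact & tumor)
  expect_identical(sum(v), sum(tumor) - nNec - nArt + nBoth)
  # no exclusions: viable = tumor
  setAll <- new("SectionImageSet", channels = ch, pixelSizeUm = 1,
                tumorMask = tumor,
                necrosisMask = matrix(FALSE, d[1], d[2]),
                artifactMask = matrix(FALSE, d[1], d[2]))
  expect_identical(viableMask(setAll), tumor)
  # necrosis covering the whole tumor leaves nothing viable
  setNone <- new("SectionImageSet", channels = ch, pixelSizeUm = 1,
                 tumorMask = tumor, necrosisMask = tumor,
                 artifactMask = matrix(FALSE, d[1], d[2]))
  expect_error(viableMask(setNone), "empty")
})

test_that("positive fraction counts painted pixels exactly", {
  viable <- matrix(TRUE, 50, 40)
  ch <- matrix(10, 50, 40)
  nPos <- round(0.3 * length(ch))
  set.seed(2); ch[sample(length(ch), nPos)] <- 200
  expect_equal(positiveFraction(ch, viable, 100), 100 * nPos / length(ch))
  expect_equal(positiveFraction(matrix(0, 50, 40), viable, 100), 0)
  expect_equal(positiveFraction(matrix(150, 50, 40), viable, 100), 100)
  # Otsu within viable separates a bimodal channel the same way
  expect_equal(positiveFraction(ch, viable, "otsu"),
               100 * nPos / length(ch))
})

test_that("perfused-vessel fraction is double-positive over vessel pixels", {
  d <- c(30, 30)
  cd31 <- matrix(FALSE, d[1], d[2]); cd31[1:10, 1:10] <- TRUE   # 100 vessel px
  hoechst <- matrix(FALSE, d[1], d[2]); hoechst[1:4, 1:10] <- TRUE # 40 of them
  expect_equal(perfusedVesselFraction(cd31, hoechst), 40)
  expect_equal(perfusedVesselFraction(cd31, cd31 | hoechst), 100)
  expect_equal(perfusedVesselFraction(cd31, !cd31 & hoechst), 0)
  expect_error(perfusedVesselFraction(matrix(FALSE, 3, 3),
                                      matrix(TRUE, 3, 3)),
               class = "tumorquantUndefined")
})

test_that("mean vessel distance matches exhaustive nearest-vessel search", {
  # one vessel at the centre of a 21x21 field
  d <- c(21, 21)
  cd31 <- matrix(FALSE, d[1], d[2]); cd31[11, 11] <- TRUE
  viable <- matrix(TRUE, d[1], d[2])
  expect_equal(meanVesselDistance(cd31, viable, 1),
               bruteForceMeanNearest(cd31, viable))
  # random 64x64 pattern, exact agreement
  set.seed(17)
  cd64 <- matrix(runif(64 * 64) < 0.01, 64)
  cd64[1, 1] <- TRUE
  v64 <- matrix(TRUE, 64, 64)
  expect_equal(meanVesselDistance(cd64, v64, 1),
               bruteForceMeanNearest(cd64, v64))
  # every viable pixel a vessel: zero distance; units scale linearly
  expect_equal(meanVesselDistance(v64, v64, 2.5), 0)
  expect_equal(meanVesselDistance(cd64, v64, 2),
               2 * meanVesselDistance(cd64, v64, 1))
  expect_error(meanVesselDistance(matrix(FALSE, 4, 4),
                                  matrix(TRUE, 4, 4), 1),
               class = "tumorquantUndefined")
})

test_that("adding vessels never increases the mean vessel distance", {
  set.seed(31)
  v <- matrix(TRUE, 32, 32)
  cd <- matrix(FALSE, 32, 32); cd[sample(1024, 3)] <- TRUE
  dPrev <- meanVesselDistance(cd, v, 1)
  for (i in 1:8) {
    cd[sample(which(!cd), 2)] <- TRUE
    dNew <- meanVesselDistance(cd, v, 1)
    expect_lte(dNew, dPrev)
    dPrev <- dNew
  }
})

test_that("necrotic fraction is painted-count arithmetic with subset checks", {
  tumor <- matrix(FALSE, 20, 20); tumor[3:18, 3:18] <- TRUE
  none <- matrix(FALSE, 20, 20)
  expect_equal(necroticFraction(none, tumor), 0)
  expect_equal(necroticFraction(tumor, tumor), 100)
  quarter <- matrix(FALSE, 20, 20); quarter[3:18, 3:6] <- TRUE
  expect_equal(necroticFraction(quarter, tumor), 100 * sum(quarter) / sum(tumor))
  expect_error(necroticFraction(tumor, none), "empty|subset")
})

test_that("section metrics are invariant under joint translation", {
  ph <- makeSectionPhantom(sectionPhantomSpec(imageShape = c(80, 80),
                                              nVessels = 12L, seed = 4))
  base <- computeSectionMetrics(ph$set)
  sh <- function(m) tumorquant:::shiftMatrix(m, 2, -3, fill = 0)
  moved <- new("SectionImageSet",
               channels = lapply(ph$set@channels, function(ch)
                 tumorquant:::shiftMatrix(ch, 2, -3, fill = 10)),
               pixelSizeUm = ph$set@pixelSizeUm,
               tumorMask = sh(ph$set@tumorMask) > 0,
               necrosisMask = sh(ph$set@necrosisMask) > 0,
               artifactMask = sh(ph$set@artifactMask) > 0)
  expect_equal(computeSectionMetrics(moved), base)
})
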