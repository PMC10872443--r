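test_that("sphere radius inverts the discrete volume formula", {
  expect_equal(sphereRadiusForVolume(4 / 3 * pi * 27), 3)
  # a radius-4 discrete sphere holds 257 voxels (lattice-point oracle)
  expect_equal(oracleSphereCount(4), 257)
  expect_error(sphereRadiusForVolume(0), class = "boldrel_invalid_parameter")
})

test_that("matchControlSphere returns exact-size contained spheres", {
  lv <- generateLabelVolume(c(24, 24, 24), list(
    list(label = 1L, type = "block", corner = c(2, 2, 2),
         size = c(16, 16, 16))))
  vs <- matchControlSphere(lv, controlLabel = 1L, targetVoxels = 257L,
                           seed = 5)
  expect_s4_class(vs, "VoxelSet")
  expect_equal(nrow(vs@coords), 257L)
  lin <- 1L + vs@coords[, 1] + 24L * vs@coords[, 2] + 576L * vs@coords[, 3]
  expect_true(all(lv@labels[lin] == 1L))
  expect_false(any(duplicated(lin)))
  # determinism
  vs2 <- matchControlSphere(lv, 1L, 257L, seed = 5)
  expect_identical(vs@coords, vs2@coords)
  # the sphere is compact: all voxels within the grown radius of the center
  ctr <- colMeans(vs@coords)
  d <- sqrt(rowSums(sweep(vs@coords, 2, ctr)^2))
  expect_lt(max(d), sphereRadiusForVolume(257) + 1.6)
})

test_that("matchControlSphere raises placement errors honestly", {
  lv <- generateLabelVolume(c(10, 10, 10), list(
    list(label = 1L, type = "block", corner = c(0, 0, 0),
         size = c(3, 3, 3))))
  expect_error(matchControlSphere(lv, 1L, 100L, seed = 1),
               class = "boldrel_placement_failure")
  expect_error(matchControlSphere(lv, 9L, 5L, seed = 1),
               class = "boldrel_invalid_parameter")
  # a thin 1-voxel sheet cannot contain a 3-D sphere of 30 voxels
  sheet <- generateLabelVolume(c(12, 12, 12), list(
    list(label = 2L, type = "block", corner = c(0, 0, 5),
         size = c(12, 12, 1))))
  expect_error(matchControlSphere(sheet, 2L, 30L, seed = 1, maxTries = 25L),
               class = "boldrel_placement_failure")
})

test_that("extractParcelValues uses stable array order and round-trips", {
  lv <- generateLabelVolume(c(8, 8, 8), list(
    list(label = 3L, type = "block", corner = c(1, 2, 3),
         size = c(2, 2, 2))))
  vol <- array(seq_len(512), dim = c(8, 8, 8))
  vals <- extractParcelValues(vol, lv, 3L)
  expect_equal(length(vals), 8)
  # array order oracle: linear indices of the labeled voxels, ascending
  expect_equal(vals, vol[sort(which(lv@labels == 3L))])
  expect_error(extractParcelValues(vol, lv, 5L),
               class = "boldrel_unknown_parcel")
  expect_error(extractParcelValues(array(0, c(4, 4, 4)), lv, 3L),
               class = "boldrel_invalid_parameter")
})

test_that("subsampleVoxels draws without replacement, order-normalized", {
  lv <- generateLabelVolume(c(10, 10, 10), list(
    list(label = 1L, type = "block", corner = c(0, 0, 0),
         size = c(5, 5, 5))))
  vs <- matchControlSphere(lv, 1L, 57L, seed = 2)
  sub <- subsampleVoxels(vs, 15L, seed = 3)
  expect_equal(nrow(sub@coords), 15L)
  key <- function(co) paste(co[, 1], co[, 2], co[, 3])
  expect_true(all(key(sub@coords) %in% key(vs@coords)))
  expect_false(any(duplicated(key(sub@coords))))
  # lexicographic normalization makes output independent of draw order
  expect_true(!is.unsorted(order(sub@coords[, 1], sub@coords[, 2],
                                 sub@coords[, 3])))
  expect_identical(sub@coords, subsampleVoxels(vs, 15L, seed = 3)@coords)
  expect_error(subsampleVoxels(vs, 100L, seed = 1),
               class = "boldrel_invalid_parameter")
  # over many seeds every voxel is drawn with roughly equal frequency
  counts <- table(unlist(lapply(1:400, function(s)
    key(subsampleVoxels(vs, 10L, seed = s)@coords))))
  expect_equal(length(counts), 57L)
  # uniform sampling: each voxel expected 400 * 10/57 ~ 70 times
  expect_gt(min(counts), 35)
  expect_lt(max(counts), 140)
})

test_that("FWHM recovery is monotone and accurate for known kernels", {
  set.seed(7)
  vol <- array(rnorm(32^3), dim = c(32, 32, 32))
  est <- vapply(c(0, 2, 4, 6), function(k) {
    sm <- smoothVolume(vol, fwhmVoxels = k)
    fwhm(estimateFWHM(sm, voxelSize = c(1, 1, 1)))
  }, numeric(1))
  expect_true(all(diff(est) > 0))
  expect_lt(est[1], 0.5)
  expect_equal(est[2:4], c(2, 4, 6), tolerance = 0.10)
})

test_that("estimateFWHM honors masks and flags degenerate input", {
  set.seed(8)
  vol <- array(rnorm(20^3), dim = c(20, 20, 20))
  sm <- smoothVolume(vol, fwhmVoxels = 3)
  mask <- array(FALSE, dim = c(20, 20, 20))
  mask[4:16, 4:16, 4:16] <- TRUE
  fm <- estimateFWHM(sm, mask = mask, voxelSize = c(1, 1, 1))
  expect_equal(fwhm(fm), 3, tolerance = 0.15)
  expect_equal(length(fwhmPerAxis(fm)), 3)
  expect_error(estimateFWHM(array(1, c(5, 5, 5)), voxelSize = c(1, 1, 1)),
               class = "boldrel_degenerate_input")
  one <- array(FALSE, c(5, 5, 5)); one[2, 2, 2] <- TRUE
  expect_error(estimateFWHM(array(rnorm(125), c(5, 5, 5)), mask = one,
                            voxelSize = c(1, 1, 1)),
               class = "boldrel_degenerate_input")
})

test_that("anisotropic voxel sizes scale the per-axis FWHM in mm", {
  set.seed(9)
  vol <- array(rnorm(28^3), dim = c(28, 28, 28))
  sm <- smoothVolume(vol, fwhmVoxels = 3)
  iso <- estimateFWHM(sm, voxelSize = c(1, 1, 1))
  mm <- estimateFWHM(sm, voxelSize = c(3, 3, 3))
  expect_equal(fwhmPerAxis(mm), 3 * fwhmPerAxis(iso))
})

test_that("label volume NIfTI round trip preserves labels and voxel size", {
  lv <- generateLabelVolume(c(9, 10, 11), list(
    list(label = 2L, type = "block", corner = c(1, 1, 1), size = c(3, 3, 3)),
    list(label = 5L, type = "sphere", center = c(6, 6, 6), radius = 2)),
    voxelSize = c(2, 2.5, 3))
  tn <- withr::local_tempfile(fileext = ".nii.gz")
  writeLabelVolume(lv, tn)
  lv2 <- readLabelVolume(tn)
  expect_identical(lv2@labels, lv@labels)
  expect_equal(lv2@voxelSize, lv@voxelSize, tolerance = 1e-6)
})

test_that("panelToVolume / extractParcelValues round-trip panel values", {
  lv <- generateLabelVolume(c(8, 8, 8), list(
    list(label = 1L, type = "block", corner = c(2, 2, 2),
         size = c(2, 3, 2))))
  vc <- varianceComponents()
  p <- generateParcelVoxels(vc, 3, 2, 12, seed = 11)
  vol <- panelToVolume(p, lv, parcelId = 1L, participant = 2, session = 1)
  vals <- extractParcelValues(vol, lv, 1L)
  d <- p@data
  expect_equal(vals, d$value[d$participant == 2 & d$session == 1])
})
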