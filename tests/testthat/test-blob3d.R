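vox_conf <- c(0.06, 0.06, 0.26)

test_that("constant stacks produce no objects; thin stacks error on z", {
  empty <- array(7, c(32, 32, 10))
  lab <- blob_segment(empty, vox_conf, blob_params())
  expect_equal(attr(lab, "n_objects"), 0)
  expect_error(blob_segment(array(1, c(32, 32, 2)), vox_conf, blob_params()),
               "z")
})

test_that("a single bright sphere segments to one object at its centre", {
  obj <- data.frame(x = 1.4, y = 1.4, z = 1.8, rx = 0.175, ry = 0.175,
                    rz = 0.175, peak = 100)
  ph <- simulate_confocal_stack(phantom3d_config(shape = c(48, 48, 14),
                                                 objects_ch1 = obj))
  lab <- blob_segment(ph$ch1, vox_conf, blob_params(preset = "mscarlet"))
  expect_equal(attr(lab, "n_objects"), 1)
  m <- object_metrics(lab, ph$ch1, vox_conf)
  expect_lt(abs(m$x_um - 1.4), vox_conf[1])
  expect_lt(abs(m$y_um - 1.4), vox_conf[2])
  expect_lt(abs(m$z_um - 1.8), vox_conf[3])
})

test_that("split sensitivity controls merging of well-separated spheres", {
  obj <- data.frame(x = c(0.9, 2.9), y = 1.4, z = 1.8, rx = 0.175,
                    ry = 0.175, rz = 0.175, peak = 100)
  ph <- simulate_confocal_stack(phantom3d_config(shape = c(64, 48, 14),
                                                 objects_ch1 = obj))
  lab50 <- blob_segment(ph$ch1, vox_conf, blob_params(split_sensitivity = 50))
  lab0 <- blob_segment(ph$ch1, vox_conf, blob_params(split_sensitivity = 0))
  expect_equal(attr(lab50, "n_objects"), 2)
  expect_equal(attr(lab0, "n_objects"), 1)
})

test_that("segmentation is invariant to intensity scaling", {
  obj <- data.frame(x = c(0.9, 2.3), y = 1.4, z = 1.8, rx = 0.175,
                    ry = 0.175, rz = 0.175, peak = c(100, 60))
  ph <- simulate_confocal_stack(phantom3d_config(shape = c(64, 48, 14),
                                                 objects_ch1 = obj))
  lab1 <- blob_segment(ph$ch1, vox_conf, blob_params())
  lab2 <- blob_segment(ph$ch1 * 7.3, vox_conf, blob_params())
  expect_identical(unclass(lab1), unclass(lab2))
})

test_that("object metrics: single voxel, analytic sphere, linearity", {
  lab <- array(0L, c(9, 9, 9)); lab[5, 5, 5] <- 1L
  stack <- array(0, c(9, 9, 9)); stack[5, 5, 5] <- 7
  m <- object_metrics(lab, stack, c(0.06, 0.06, 0.06))
  expect_equal(m$total_intensity, 7)
  expect_equal(m$mean_intensity, 7)
  expect_equal(m$volume_um3, 0.06^3)
  expect_error(object_metrics(lab, array(0, c(4, 4, 4)), rep(0.06, 3)),
               "shape")
  # digitized ball of radius 5 voxels: volume and area within 5%
  mball <- ball_mask(5, rep(19, 3))
  labb <- array(as.integer(mball), dim(mball))
  mm <- object_metrics(labb, array(1, dim(mball)), c(1, 1, 1))
  expect_equal(mm$volume_um3, 4 / 3 * pi * 125, tolerance = 0.05)
  expect_equal(mm$area_um2, 4 * pi * 25, tolerance = 0.05)
  expect_gt(mm$sphericity, 0.9)
  expect_lt(mm$sphericity, 1.05)
  # doubling intensities doubles intensity metrics, preserves shape metrics
  m2 <- object_metrics(labb, array(2, dim(mball)), c(1, 1, 1))
  expect_equal(m2$total_intensity, 2 * mm$total_intensity)
  expect_equal(m2$volume_um3, mm$volume_um3)
  expect_equal(m2$sphericity, mm$sphericity)
})

test_that("volume and sphericity filters remove the paper-scale rejects", {
  # 10-voxel blob at confocal voxel size: 0.00936 um^3 < 0.03 -> removed
  lab <- array(0L, c(16, 16, 8))
  lab[4:8, 4, 4] <- 1L; lab[4:8, 5, 4] <- 1L
  expect_equal(sum(lab > 0), 10)
  f <- filter_objects(lab, vox_conf, filter_params())
  expect_equal(attr(f, "n_objects"), 0)
  # digitized ball radius 0.3 um: volume ~0.113 um^3, sphericity >= 0.9 -> kept
  mball <- ball_mask(0.3, c(21, 21, 9), vox_conf)
  labb <- array(as.integer(mball), dim(mball))
  mm <- object_metrics(labb, array(1, dim(mball)), vox_conf)
  expect_equal(mm$volume_um3, 4 / 3 * pi * 0.3^3, tolerance = 0.05)
  expect_gte(mm$sphericity, 0.9)
  fb <- filter_objects(labb, vox_conf, filter_params())
  expect_equal(attr(fb, "n_objects"), 1)
  # 1-voxel-wide rod of length ~2 um: sphericity < 0.6 -> removed
  rod <- array(0L, c(40, 7, 7)); rod[4:37, 4, 4] <- 1L
  mr <- object_metrics(rod, array(1, dim(rod)), rep(0.06, 3))
  expect_lt(mr$sphericity, 0.6)
  fr <- filter_objects(rod, rep(0.06, 3),
                       filter_params(min_volume = 0))  # volume not the reason
  expect_equal(attr(fr, "n_objects"), 0)
})

test_that("filtering is monotone in both thresholds", {
  set.seed(1)
  obj <- data.frame(x = runif(6, 0.6, 3.2), y = runif(6, 0.6, 2.4),
                    z = runif(6, 1.0, 2.6), rx = runif(6, 0.1, 0.3),
                    ry = runif(6, 0.1, 0.3), rz = runif(6, 0.15, 0.3),
                    peak = 100)
  ph <- simulate_confocal_stack(phantom3d_config(shape = c(64, 48, 14),
                                                 objects_ch1 = obj))
  lab <- blob_segment(ph$ch1, vox_conf, blob_params())
  counts_v <- sapply(c(0, 0.01, 0.03, 0.1), function(v)
    attr(filter_objects(lab, vox_conf,
                        filter_params(min_volume = v,
                                      min_sphericity = 0.2)), "n_objects"))
  expect_true(all(diff(counts_v) <= 0))
  counts_s <- sapply(c(0.2, 0.5, 0.8, 0.95), function(s)
    attr(filter_objects(lab, vox_conf,
                        filter_params(min_volume = 0,
                                      min_sphericity = s)), "n_objects"))
  expect_true(all(diff(counts_s) <= 0))
})

test_that("channel alignment: identical, integer and sub-voxel shifts", {
  obj <- data.frame(x = c(1, 2), y = c(1, 2), z = c(1.4, 1.8),
                    rx = 0.1, ry = 0.1, rz = 0.2, peak = 100)
  ph <- simulate_confocal_stack(phantom3d_config(shape = c(48, 48, 12),
                                                 objects_ch1 = obj))
  al0 <- align_channels(ph$ch1, ph$ch1)
  expect_equal(al0$shift_vox, c(0, 0, 0), tolerance = 1e-9)
  # exact 2-voxel circular shift in x
  ch2 <- ph$ch1[c(47:48, 1:46), , ]
  al2 <- align_channels(ph$ch1, ch2)
  expect_equal(al2$shift_vox, c(2, 0, 0), tolerance = 0.02)
  # rendered sub-voxel shift of 0.3 px recovered within 0.1 px
  cfgB <- phantom3d_config(shape = c(48, 48, 12), objects_ch1 = obj,
                           objects_ch2 = obj,
                           channel_shift = c(0.3 * 0.06, 0))
  phB <- simulate_confocal_stack(cfgB)
  alB <- align_channels(phB$ch1, phB$ch2)
  expect_lt(abs(alB$shift_vox[1] - 0.3), 0.1)
  expect_lt(abs(alB$shift_vox[2]), 0.1)
  # applying the correction moves channel 2 back onto channel 1
  fixed <- alB$apply(phB$ch2)
  expect_lt(mean(abs(fixed - phB$ch1)), mean(abs(phB$ch2 - phB$ch1)))
  # featureless stacks fall back to zero shift with a warning
  set.seed(2)
  expect_warning(aln <- align_channels(array(rnorm(1000), c(10, 10, 10)),
                                       array(rnorm(1000), c(10, 10, 10)),
                                       min_correlation = 0.9), "confidence")
  expect_equal(aln$shift_vox, c(0, 0, 0))
})

test_that("colocalization: identical, disjoint and 30%-overlap phantoms", {
  la <- array(0L, c(12, 12, 4)); lb <- la
  la[2:4, 2:4, 2] <- 1L; la[8:10, 8:10, 3] <- 2L
  cc_same <- colocalize(la, la)
  expect_true(all(cc_same$a$colocalized))
  expect_identical(cc_same$intersection > 0, la > 0)
  lb[6, 6, 1] <- 1L
  cc_dis <- colocalize(la, lb)
  expect_equal(cc_dis$fraction_a_colocalized, 0)
  expect_equal(sum(cc_dis$intersection), 0)
  expect_error(colocalize(la, array(0L, c(5, 5, 5))), "shape")
  # constructed phantom: exactly 30% of A objects touch a B object
  A <- array(0L, c(40, 10, 4)); B <- array(0L, c(40, 10, 4))
  for (i in 1:10) A[(4 * i - 3):(4 * i - 1), 3:5, 2] <- i
  for (i in 1:3) B[(4 * i - 3), 3, 2] <- i  # overlap first three A objects
  cc <- colocalize(A, B)
  expect_equal(cc$fraction_a_colocalized, 0.3)
})

test_that("colocalization intersection is symmetric at the voxel level", {
  set.seed(3)
  A <- array(sample(0:2, 12 * 12 * 5, TRUE), c(12, 12, 5))
  B <- array(sample(0:2, 12 * 12 * 5, TRUE), c(12, 12, 5))
  ab <- colocalize(A, B)
  ba <- colocalize(B, A)
  expect_identical(ab$intersection > 0, ba$intersection > 0)
})
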