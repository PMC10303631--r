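test_that("discretization follows the fixed-bin-count and bin-width rules", {
  # constant region: single level regardless of scheme
  volc <- volume3d(array(5, c(3, 3, 3)))
  mskc <- voi_mask(array(TRUE, c(3, 3, 3)))
  qv <- discretize(volc, mskc)
  expect_equal(qv$ng, 1L)
  expect_true(all(qv$levels[mskc$data] == 1L))
  # values 0..31 with 32 bins hit every level once
  vol <- volume3d(array(as.numeric(0:31), c(32, 1, 1)))
  msk <- voi_mask(array(TRUE, c(32, 1, 1)))
  qv2 <- discretize(vol, msk, discretization_scheme(n_bins = 32))
  expect_equal(sort(unique(qv2$levels[msk$data])), 1:32)
  # fixed bin width: floor(x/w) - floor(min/w) + 1
  vol3 <- volume3d(array(c(0, 100), c(2, 1, 1)))
  msk3 <- voi_mask(array(TRUE, c(2, 1, 1)))
  qv3 <- discretize(vol3, msk3,
                    discretization_scheme("fixed_bin_width", bin_width = 25))
  expect_equal(as.vector(qv3$levels), c(1L, 5L))
})

test_that("first-order statistics match closed forms and the sort oracle", {
  vol <- volume3d(array(c(1, 2, 3, 4), c(4, 1, 1)))
  msk <- voi_mask(array(TRUE, c(4, 1, 1)))
  fo <- first_order_features(vol, msk)
  expect_equal(fo$`firstorder/Mean`, 2.5)
  expect_equal(fo$`firstorder/RootMeanSquared`, sqrt(30 / 4))
  expect_equal(fo$`firstorder/Energy`, 30)
  # constant region conventions
  volc <- volume3d(array(7, c(3, 3, 2)))
  mskc <- voi_mask(array(TRUE, c(3, 3, 2)))
  fc <- first_order_features(volc, mskc)
  expect_equal(fc$`firstorder/Mean`, 7)
  expect_equal(fc$`firstorder/Variance`, 0)
  expect_equal(fc$`firstorder/Entropy`, 0)
  expect_equal(fc$`firstorder/Uniformity`, 1)
  expect_equal(fc$`firstorder/Skewness`, 0)
  expect_equal(fc$`firstorder/Kurtosis`, 0)
  # percentile rule against the explicit interpolation oracle, 1..10
  vol10 <- volume3d(array(as.numeric(1:10), c(10, 1, 1)))
  msk10 <- voi_mask(array(TRUE, c(10, 1, 1)))
  f10 <- first_order_features(vol10, msk10)
  expect_equal(f10$`firstorder/90Percentile`,
               oracle_percentile(1:10, 0.9))
  expect_equal(f10$`firstorder/10Percentile`,
               oracle_percentile(1:10, 0.1))
  # full random check against the naive oracle
  set.seed(11)
  for (i in 1:10) {
    vol <- volume3d(array(rnorm(60), c(5, 4, 3)))
    msk <- voi_mask(array(runif(60) < 0.8, c(5, 4, 3)))
    qv <- discretize(vol, msk)
    want <- oracle_firstorder(vol$data[msk$data], qv$levels[msk$data], qv$ng)
    got <- unlist(first_order_features(vol, msk))
    names(got) <- sub("^firstorder/", "", names(got))
    expect_lt(max(abs(got[names(want)] - want)), 1e-10)
  }
})

test_that("shape features match geometry on cubes, balls and single voxels", {
  # single 1 mm^3 voxel
  m1 <- array(FALSE, c(3, 3, 3)); m1[2, 2, 2] <- TRUE
  s1 <- shape3d_features(voi_mask(m1))
  expect_equal(s1$`shape/VoxelVolume`, 1)
  expect_true(attr(s1, "mesh_fallback"))
  expect_true(all(vapply(s1, is.finite, logical(1))))
  # 10x10x10 cube at unit spacing
  mc <- array(FALSE, c(14, 14, 14)); mc[3:12, 3:12, 3:12] <- TRUE
  sc <- shape3d_features(voi_mask(mc))
  expect_equal(sc$`shape/VoxelVolume`, 1000)
  expect_equal(sc$`shape/Elongation`, 1, tolerance = 1e-8)
  expect_equal(sc$`shape/Flatness`, 1, tolerance = 1e-8)
  expect_equal(sc$`shape/Maximum3DDiameter`, 9 * sqrt(3), tolerance = 1e-8)
  # digitized ball approaches the analytic sphericity limit
  sb <- shape3d_features(ball_mask(8))
  expect_gte(sb$`shape/Sphericity`, 0.95)
  expect_lte(sb$`shape/Sphericity`, 1.0)
  # anisotropic spacing scales the voxel volume
  sa <- shape3d_features(voi_mask(m1, spacing = c(2, 3, 4)))
  expect_equal(sa$`shape/VoxelVolume`, 24)
})

test_that("hand-enumerated texture cases evaluate as derived", {
  # 1D strip 1,2,1,2: one informative direction, P(1,2) = P(2,1) = 1/2
  qv <- qvoi_from_levels(array(c(1L, 2L, 1L, 2L), c(4, 1, 1)), ng = 2)
  g <- glcm_features(qv)
  expect_equal(g$`glcm/Contrast`, 1)
  expect_equal(g$`glcm/MaximumProbability`, 0.5)
  # constant strip: single run of 6 along the strip (RLN contribution 1),
  # six unit runs in each of the 12 other directions (contribution 6)
  qc <- qvoi_from_levels(array(1L, c(6, 1, 1)), ng = 1)
  r <- glrlm_features(qc)
  expect_equal(r$`glrlm/RunLengthNonUniformity`, (1 + 12 * 6) / 13)
  # strictly alternating strip: all runs length 1, SRE = 1
  qa <- qvoi_from_levels(array(rep(c(1L, 2L), 4), c(8, 1, 1)), ng = 2)
  ra <- glrlm_features(qa)
  expect_equal(ra$`glrlm/ShortRunEmphasis`, 1)
  # constant region of V voxels: single zone, SZN = 1
  qz <- qvoi_from_levels(array(1L, c(3, 3, 2)), ng = 1)
  z <- glszm_features(qz)
  expect_equal(z$`glszm/SizeZoneNonUniformity`, 1)
  expect_equal(z$`glszm/ZonePercentage`, 1 / 18)
  # two disjoint single-voxel zones at the lowest level, Ng = 1
  lev <- array(0L, c(5, 1, 1)); lev[c(1, 5)] <- 1L
  z2 <- glszm_features(qvoi_from_levels(lev, ng = 1))
  expect_equal(z2$`glszm/LowGrayLevelZoneEmphasis`, 1)
  # 2-level checkerboard strip: hand-computed NGTDM contrast
  # levels 1,2,1,2: neighbors of ends differ by 1, middles mean to g
  lev_cb <- array(c(1L, 2L, 1L, 2L), c(4, 1, 1))
  # s_1 = |1-2| + |1-2| = 2 (voxels 1 and 3; voxel 3 sees mean (2+2)/2)
  # s_2 = |2-1| + |2-1| = 2; p_1 = p_2 = 1/2, Ngp = 2, N = 4
  # Contrast = [p1 p2 (1-2)^2 * 2 / (2*1)] * [(s1+s2)/4] = 0.25 * 1 = 0.25
  ncb <- ngtdm_features(qvoi_from_levels(lev_cb, ng = 2))
  expect_equal(ncb$`ngtdm/Contrast`, 0.25)
  # isolated voxels with alpha = 0: all mass in the smallest dependence
  lev_iso <- array(c(1L, 2L, 1L, 2L), c(4, 1, 1))
  gd <- gldm_features(qvoi_from_levels(lev_iso, ng = 2), alpha = 0)
  expect_equal(gd$`gldm/SmallDependenceEmphasis`, 1)
  expect_equal(gd$`gldm/LargeDependenceEmphasis`, 1)
  # constant 2x2x2 cube: every voxel has 7 dependent neighbors
  lev8 <- array(1L, c(2, 2, 2))
  gd8 <- gldm_features(qvoi_from_levels(lev8, ng = 1))
  expect_equal(gd8$`gldm/DependenceNonUniformityNormalized`, 1)
})

test_that("texture families equal brute-force enumeration on random images", {
  set.seed(123)
  for (i in 1:25) {
    qv <- random_qvoi(dim = c(5, 5, 3), ng = sample(2:6, 1),
                      p_mask = runif(1, 0.5, 1))
    errs <- compare_families(qv)
    expect_lt(max(errs), 1e-10)
  }
})

test_that("extract_features returns the canonical 107-entry vector", {
  set.seed(5)
  vol <- volume3d(array(runif(200, 1, 9), c(8, 5, 5)))
  msk <- voi_mask(array(runif(200) < 0.7, c(8, 5, 5)))
  fv <- extract_features(vol, msk)
  expect_equal(ncol(fv), 107)
  expect_identical(names(fv), feature_names())
  expect_true(all(vapply(fv, is.finite, logical(1))))
  expect_equal(length(feature_names()), 107)
  # family sizes: 18 + 14 + 24 + 16 + 16 + 5 + 14
  fam <- table(sub("/.*", "", feature_names()))
  expect_equal(as.integer(fam[c("firstorder", "shape", "glcm", "glrlm",
                                "glszm", "ngtdm", "gldm")]),
               c(18L, 14L, 24L, 16L, 16L, 5L, 14L))
})

test_that("intensity shifts leave discretized features unchanged", {
  set.seed(8)
  vol <- volume3d(array(runif(150, 0, 5), c(6, 5, 5)))
  msk <- voi_mask(array(runif(150) < 0.8, c(6, 5, 5)))
  f0 <- extract_features(vol, msk)
  f1 <- extract_features(volume3d(vol$data + 100, vol$spacing), msk)
  texture <- grep("^(glcm|glrlm|glszm|ngtdm|gldm)/", feature_names(),
                  value = TRUE)
  for (nm in texture) expect_equal(f1[[nm]], f0[[nm]], tolerance = 1e-9)
  expect_equal(f1$`firstorder/Entropy`, f0$`firstorder/Entropy`)
  expect_equal(f1$`firstorder/Uniformity`, f0$`firstorder/Uniformity`)
})

test_that("features are invariant to 90-degree grid rotations", {
  set.seed(21)
  vol <- volume3d(array(runif(4^3, 1, 9), c(4, 4, 4)))
  msk <- voi_mask(array(runif(4^3) < 0.75, c(4, 4, 4)))
  f0 <- extract_features(vol, msk)
  # rotate 90 degrees in the xy-plane: (x, y) -> (y, nx + 1 - x)
  rot <- function(a) aperm(a, c(2, 1, 3))[dim(a)[2]:1, , , drop = FALSE]
  f1 <- extract_features(volume3d(rot(vol$data)), voi_mask(rot(msk$data)))
  skip_cols <- c("shape/Maximum2DDiameterSlice", "shape/Maximum2DDiameterColumn",
                 "shape/Maximum2DDiameterRow") # axis-specific by definition
  # the tetrahedral mesh decomposition has a fixed chirality, so
  # mesh-derived values agree under rotation only to ~1%
  mesh_cols <- c("shape/MeshVolume", "shape/SurfaceArea",
                 "shape/SurfaceVolumeRatio", "shape/Sphericity")
  for (nm in setdiff(feature_names(), c(skip_cols, mesh_cols))) {
    expect_equal(f1[[nm]], f0[[nm]], tolerance = 1e-8, label = nm)
  }
  for (nm in mesh_cols) {
    expect_equal(f1[[nm]], f0[[nm]], tolerance = 0.03, label = nm)
  }
})

test_that("degenerate VOIs stay finite across all families", {
  cases <- list(
    constant = list(vol = array(3, c(4, 4, 3)),
                    msk = array(TRUE, c(4, 4, 3))),
    single_voxel = list(vol = array(2, c(3, 3, 3)),
                        msk = array(c(rep(FALSE, 13), TRUE,
                                      rep(FALSE, 13)), c(3, 3, 3))),
    two_voxels = list(vol = array(seq_len(27), c(3, 3, 3)),
                      msk = array(seq_len(27) %in% c(1, 27), c(3, 3, 3))))
  for (nm in names(cases)) {
    fv <- extract_features(volume3d(cases[[nm]]$vol),
                           voi_mask(cases[[nm]]$msk))
    expect_true(all(vapply(fv, is.finite, logical(1))), label = nm)
    expect_equal(ncol(fv), 107)
  }
})
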