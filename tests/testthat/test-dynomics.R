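# small deterministic dynamic fixture: 6x6x5 grid, short schedule
make_test_series <- function(n_frames = 6, constant = FALSE, seed = 2) {
  set.seed(seed)
  sched <- frame_schedule(seq(0, by = 10, length.out = n_frames),
                          rep(10, n_frames))
  arr <- array(0, c(6, 6, 5, n_frames))
  base <- array(runif(6 * 6 * 5, 1, 5), c(6, 6, 5))
  for (f in seq_len(n_frames)) {
    arr[, , , f] <- if (constant) base else base * f + f
  }
  list(series = dynamic_series(arr, sched),
       mask = voi_mask(array(runif(6 * 6 * 5) < 0.6, c(6, 6, 5))))
}

test_that("per-frame extraction yields a frames x 107 matrix", {
  fx <- make_test_series(6)
  fts <- extract_per_frame(fx$series, fx$mask)
  expect_s3_class(fts, "feature_timeseries")
  expect_equal(nrow(fts), 6)
  expect_identical(setdiff(names(fts), c("frame", "start_s", "duration_s")),
                   feature_names())
  expect_true(all(vapply(fts[feature_names()],
                         function(x) all(is.finite(x)), logical(1))))
  # shape columns constant across rows: the mask does not move
  for (nm in grep("^shape/", feature_names(), value = TRUE)) {
    expect_equal(length(unique(fts[[nm]])), 1, label = nm)
  }
})

test_that("a time-constant series repeats the static extraction per row", {
  fx <- make_test_series(4, constant = TRUE)
  fts <- extract_per_frame(fx$series, fx$mask)
  single <- extract_features(get_frame(fx$series, 1), fx$mask)
  for (f in 1:4) {
    expect_equal(unlist(fts[f, feature_names()]), unlist(single),
                 tolerance = 1e-12)
  }
})

test_that("temporal median and MAD follow their definitions", {
  fx <- make_test_series(3)
  fts <- extract_per_frame(fx$series, fx$mask)
  med <- temporal_median(fts)
  mad_ <- temporal_mad(fts)
  expect_equal(ncol(med), 107)
  expect_equal(ncol(mad_), 107)
  # sort-based oracle on every column
  for (nm in sample(feature_names(), 20)) {
    x <- fts[[nm]]
    expect_equal(med[[nm]], sort(x)[2]) # odd count: middle order statistic
    expect_equal(mad_[[nm]], median(abs(x - median(x))))
  }
  # single frame: identity
  one <- fts[1, ]
  class(one) <- class(fts)
  expect_equal(unlist(temporal_median(one)), unlist(one[feature_names()]))
  expect_equal(unname(unlist(temporal_mad(one))), rep(0, 107))
  # hand cases
  df <- tibble::tibble(frame = 1:3, start_s = 0:2, duration_s = 1,
                       a = c(1, 2, 100), b = c(1, 2, 3))
  expect_equal(temporal_median(df)$a, 2) # robust to the outlier frame
  expect_equal(temporal_mad(df)$b, 1)
  # MAD >= 0 everywhere; exactly 0 for time-constant columns (all shape
  # features, since the mask is fixed); strictly positive when a column
  # genuinely varies in a majority of frames
  expect_true(all(unlist(mad_) >= 0))
  shape_cols <- grep("^shape/", feature_names(), value = TRUE)
  expect_equal(unname(unlist(mad_[shape_cols])), rep(0, length(shape_cols)))
  varying <- tibble::tibble(frame = 1:5, start_s = 0:4, duration_s = 1,
                            v = c(1, 4, 9, 16, 25))
  expect_gt(temporal_mad(varying)$v, 0)
})

test_that("temporal summaries are invariant to frame order", {
  fx <- make_test_series(5)
  fts <- extract_per_frame(fx$series, fx$mask)
  perm <- fts[sample(5), ]
  class(perm) <- class(fts)
  expect_equal(temporal_median(perm), temporal_median(fts))
  expect_equal(temporal_mad(perm), temporal_mad(fts))
})

test_that("design matrices have the mode-dependent shapes", {
  set.seed(9)
  n_sub <- 4; n_frames <- 3; m <- 5
  feats <- paste0("f", seq_len(m))
  long <- tidyr::expand_grid(sample_id = paste0("S", 1:n_sub),
                             frame = seq_len(n_frames))
  long$label <- rep(c("CR", "PR"), each = n_frames * 2)
  for (f in feats) long[[f]] <- rnorm(nrow(long))
  static <- long[long$frame == 1, c("sample_id", "label", feats)]

  ds <- assemble_design_matrix(static, "static")
  expect_equal(dim(ds), c(n_sub, 2 + m))
  dm <- assemble_design_matrix(long, "median")
  expect_equal(dim(dm), c(n_sub, 2 + m))
  dmm <- assemble_design_matrix(long, "median+mad")
  expect_equal(dim(dmm), c(n_sub, 2 + 2 * m)) # n x 2m concatenation
  expect_true(all(paste0(feats, "/median") %in% names(dmm)))
  expect_true(all(paste0(feats, "/mad") %in% names(dmm)))
  # median+mad equals the exact concatenation of the two summaries
  dmad <- assemble_design_matrix(long, "mad")
  expect_equal(unname(as.matrix(dmm[paste0(feats, "/median")])),
               unname(as.matrix(dm[feats])))
  expect_equal(unname(as.matrix(dmm[paste0(feats, "/mad")])),
               unname(as.matrix(dmad[feats])))
  # single-subject median mode reproduces the temporal median row
  one <- long[long$sample_id == "S1", ]
  d1 <- assemble_design_matrix(one, "median")
  expect_equal(unlist(d1[feats]),
               unlist(temporal_median(one)[feats]))
  # errors
  expect_error(assemble_design_matrix(static[-1], "static"),
               class = "dynomics_design_error")
  bad <- static; bad$label[1] <- NA
  expect_error(assemble_design_matrix(bad, "static"),
               class = "dynomics_design_error")
})

test_that("the tumor-vs-reference design holds two rows per subject", {
  feats <- list(static = tibble::tibble(
    subject_id = rep(paste0("S", 1:3), each = 2),
    voi = rep(c("lesion", "reference"), 3),
    class = rep(c("CR", "PR", "PR"), each = 2),
    `firstorder/Mean` = rnorm(6), `glcm/Contrast` = rnorm(6)))
  d <- design_from_features(feats, "tumor-vs-reference", "static")
  expect_equal(nrow(d), 6) # n = 2 x subjects
  expect_equal(sort(unique(d$label)), c("lesion", "reference"))
  d2 <- design_from_features(feats, "cr-vs-pr", "static")
  expect_equal(nrow(d2), 3)
  expect_equal(sort(unique(d2$label)), c("CR", "PR"))
})

test_that("the time-series tensor export is (n x m) x t with labels", {
  set.seed(4)
  long <- tidyr::expand_grid(sample_id = c("A", "B"), frame = 1:4)
  long$label <- rep(c("CR", "PR"), each = 4)
  long$f1 <- rnorm(8); long$f2 <- rnorm(8); long$f3 <- rnorm(8)
  tens <- export_timeseries_tensor(long)
  expect_equal(nrow(tens), 2 * 3) # samples x features
  expect_equal(ncol(tens), 3 + 4) # id, feature, label + t columns
  expect_true(all(paste0("t", 1:4) %in% names(tens)))
  # labels replicate across a sample's feature rows
  expect_equal(unique(tens$label[tens$sample_id == "A"]), "CR")
  # value round-trip for one cell
  expect_equal(tens$t3[tens$sample_id == "B" & tens$feature == "f2"],
               long$f2[long$sample_id == "B" & long$frame == 3])
  # CSV round-trip
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tens, f)
  expect_equal(as.data.frame(readr::read_csv(f, show_col_types = FALSE)),
               as.data.frame(tens))
  # heterogeneous frame counts error
  expect_error(export_timeseries_tensor(long[-1, ]),
               class = "dynomics_design_error")
})
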