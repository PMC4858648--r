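make_patch <- function(values) {
  list(slice_index = 1L, values = values,
       inside = matrix(TRUE, nrow(values), ncol(values)))
}

test_that("quantization maps the pooled range into equal-width bins", {
  # 4 values, 4 levels: one value per bin, top edge in the last bin
  q <- quantize(list(make_patch(matrix(c(0, 10, 20, 40), 2, 2))), 4)
  expect_equal(sort(as.vector(q[[1]]$levels)), 1:4)
  expect_false(attr(q, "degenerate"))

  # integers 0..7 at 8 levels: identity mapping
  q <- quantize(list(make_patch(matrix(0:7, 2, 4))), 8)
  expect_equal(q[[1]]$levels, matrix(0:7, 2, 4) + 1L)

  # constant ROI degenerates to level 1 with a flag
  q <- quantize(list(make_patch(matrix(5, 3, 3))), 8)
  expect_true(all(q[[1]]$levels == 1L))
  expect_true(attr(q, "degenerate"))

  # the range is pooled across slices, not per slice
  q <- quantize(list(make_patch(matrix(c(0, 0, 1, 1), 2, 2)),
                     make_patch(matrix(c(9, 9, 10, 10), 2, 2))), 2)
  expect_true(all(q[[1]]$levels == 1L))
  expect_true(all(q[[2]]$levels == 2L))

  expect_error(quantize(list(), 8), "no patches")
  expect_error(quantize(list(make_patch(matrix(1, 2, 2))), 1), ">= 2")
})

test_that("GLCM counting matches hand-enumerated pairs", {
  # rows (1,2),(1,2): two horizontal (1,2) pairs, symmetrized
  p <- list(levels = matrix(c(1, 1, 2, 2), 2, 2),
            inside = matrix(TRUE, 2, 2), n_levels = 2L)
  g <- compute_glcm(p, 0)
  expect_equal(unclass(g)[1, 2], 2)
  expect_equal(unclass(g)[2, 1], 2)
  expect_equal(sum(g), 4)

  # constant patch: all mass at (1,1) in every direction
  p <- list(levels = matrix(1L, 3, 3), inside = matrix(TRUE, 3, 3),
            n_levels = 2L)
  for (ang in c(0, 45, 90, 135)) {
    g <- compute_glcm(p, ang)
    expect_equal(sum(g) - unclass(g)[1, 1], 0)
    expect_gt(unclass(g)[1, 1], 0)
  }

  # a patch with no valid pair is flagged empty
  p <- list(levels = matrix(1L, 1, 1), inside = matrix(TRUE, 1, 1),
            n_levels = 2L)
  expect_true(attr(compute_glcm(p, 0), "empty"))
})

test_that("GLCM equals the brute-force pair enumeration on random patches", {
  set.seed(101)
  for (i in 1:60) {
    n_lev <- sample(2:8, 1)
    p <- random_patch(sample(2:12, 1), sample(2:12, 1), n_lev,
                      p_inside = runif(1, 0.4, 1))
    for (ang in names(oracle_offsets)) {
      off <- oracle_offsets[[ang]]
      expect_identical(matrix(unclass(compute_glcm(p, ang)), n_lev),
                       oracle_glcm(p$levels, p$inside, off[1], off[2], n_lev))
    }
  }
})

test_that("roi_glcms accumulates slices, then normalizes once", {
  set.seed(7)
  p1 <- random_patch(6, 6, 4); p2 <- random_patch(5, 7, 4)
  g <- roi_glcms(list(p1, p2))
  for (ang in names(g)) {
    expect_equal(sum(g[[ang]]), 1, tolerance = 1e-12)
    expect_equal(unclass(g[[ang]]), t(unclass(g[[ang]])), tolerance = 1e-12)
    # accumulated counts = sum of per-slice oracle counts
    off <- oracle_offsets[[ang]]
    raw <- oracle_glcm(p1$levels, p1$inside, off[1], off[2], 4) +
      oracle_glcm(p2$levels, p2$inside, off[1], off[2], 4)
    expect_equal(matrix(unclass(g[[ang]]), 4), raw / sum(raw), tolerance = 1e-14)
  }

  # duplicating a slice cancels under normalization
  g1 <- roi_glcms(list(p1))
  g2 <- roi_glcms(list(p1, p1))
  expect_equal(lapply(g1, unclass), lapply(g2, unclass), tolerance = 1e-14)

  # a single-pixel ROI has no pairs in any direction
  single <- list(levels = matrix(1L, 1, 1), inside = matrix(TRUE, 1, 1),
                 n_levels = 2L)
  expect_error(roi_glcms(list(single)), "undefined")
})

test_that("features take their closed-form values on toy GLCMs", {
  # point mass on a diagonal cell
  P <- matrix(0, 4, 4); P[2, 2] <- 1
  f <- compute_features(P)
  expect_equal(f[["energy"]], 1)
  expect_equal(f[["entropy"]], 0)
  expect_equal(f[["contrast"]], 0)
  expect_equal(f[["dissimilarity"]], 0)
  expect_equal(f[["homogeneity"]], 1)
  expect_equal(f[["maximum_probability"]], 1)
  expect_equal(f[["correlation"]], 1)  # degenerate convention

  # two off-diagonal cells, n = 2
  P <- matrix(0, 2, 2); P[1, 2] <- P[2, 1] <- 0.5
  f <- compute_features(P)
  expect_equal(f[["energy"]], 0.5)
  expect_equal(f[["entropy"]], log(2))
  expect_equal(f[["contrast"]], 1)
  expect_equal(f[["maximum_probability"]], 0.5)
  expect_equal(f[["sum_average"]], 3)
  expect_equal(f[["autocorrelation"]], 2)

  expect_error(compute_features(matrix(1, 2, 2)), "normalized")
})

test_that("feature invariant ranges hold on random GLCMs (property)", {
  set.seed(202)
  for (i in 1:40) {
    n <- sample(2:8, 1)
    M <- matrix(rexp(n * n), n, n)
    M <- M + t(M)
    P <- M / sum(M)
    f <- compute_features(P)
    expect_true(f[["energy"]] > 0 && f[["energy"]] <= 1)
    expect_gte(f[["entropy"]], 0)
    expect_true(f[["homogeneity"]] > 0 && f[["homogeneity"]] <= 1)
    expect_true(f[["maximum_probability"]] > 0 && f[["maximum_probability"]] <= 1)
    expect_gte(f[["contrast"]], 0)
    expect_gte(f[["dissimilarity"]], 0)
    expect_true(abs(f[["correlation"]]) <= 1 + 1e-12)
    expect_length(f, 20)
    expect_named(f, texture_feature_names)
  }
})

test_that("direction averaging is rotation invariant", {
  set.seed(303)
  # four identical GLCMs average to the single-direction vector
  p <- random_patch(8, 8, 5)
  g <- compute_glcm(p, 0)
  P <- unclass(g) / sum(g); attr(P, "empty") <- FALSE
  four <- list(`0` = P, `45` = P, `90` = P, `135` = P)
  expect_equal(unname(rotation_invariant_features(four)[TRUE]),
               unname(compute_features(P)))

  # rotating the pixel grid by 90 degrees permutes the direction set
  for (i in 1:15) {
    p <- random_patch(sample(3:10, 1), sample(3:10, 1), 8,
                      p_inside = runif(1, 0.5, 1))
    rot <- list(slice_index = 1L,
                levels = t(p$levels)[ncol(p$levels):1, , drop = FALSE],
                inside = t(p$inside)[ncol(p$inside):1, , drop = FALSE],
                n_levels = p$n_levels)
    f1 <- try(rotation_invariant_features(roi_glcms(list(p))), silent = TRUE)
    if (inherits(f1, "try-error")) next
    f2 <- rotation_invariant_features(roi_glcms(list(rot)))
    expect_equal(unname(f1[TRUE]), unname(f2[TRUE]), tolerance = 1e-9)
  }

  # averaged vector is the mean of the four directional vectors
  p <- random_patch(10, 10, 8)
  g <- roi_glcms(list(p))
  expect_equal(unname(rotation_invariant_features(g)[TRUE]),
               unname(rowMeans(vapply(g, compute_features, numeric(20)))))
})

test_that("smoother random fields score higher homogeneity and autocorrelation", {
  set.seed(404)
  n_rep <- 30
  feat_at <- function(sigma) {
    rowMeans(vapply(seq_len(n_rep), function(i) {
      q <- quantize(list(random_field_patch(16, 16, sigma)), 8)
      rotation_invariant_features(roi_glcms(q))[c("homogeneity", "autocorrelation")]
    }, numeric(2)))
  }
  rough <- feat_at(0.5)
  smooth <- feat_at(2.5)
  expect_gt(smooth[["homogeneity"]], rough[["homogeneity"]])
  expect_gt(smooth[["autocorrelation"]], rough[["autocorrelation"]])
})

test_that("extract_roi_features runs the full per-ROI chain", {
  set.seed(9)
  vol <- image_volume(array(rnorm(12 * 12 * 4, 100, 10), c(12, 12, 4)))
  m <- array(FALSE, c(12, 12, 4)); m[3:9, 3:9, 2:3] <- TRUE
  f <- extract_roi_features(vol, roi_mask(m, "s", "r", "E"))
  expect_named(f, texture_feature_names)
  expect_equal(attr(f, "n_voxels"), sum(m))
  expect_false(attr(f, "degenerate"))
})
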