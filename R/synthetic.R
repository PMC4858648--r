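#' Default per-class feature distribution parameters
#'
#' Per-feature mean and standard deviation of the 20 rotation-invariant
#' texture features for the expected (E) and non-expected (NE) ROI
#' populations the table generator emulates. The two inverse-difference
#' features are nearly constant in this population (SD below the 0.05
#' print resolution); their SDs are floored at 0.02 so that generated
#' tables have full-rank designs.
#'
#' @return data.frame: `feature`, `mean_e`, `sd_e`, `mean_ne`, `sd_ne`.
#' @export
default_feature_params <- function() {
  df <- data.frame(
    feature = c("autocorrelation", "contrast", "correlation",
                "cluster_prominence", "cluster_shade", "dissimilarity",
                "energy", "entropy", "homogeneity", "maximum_probability",
                "sum_of_squares_variance", "sum_average", "sum_variance",
                "sum_entropy", "difference_variance", "difference_entropy",
                "imc1", "imc2", "inverse_difference_normalized",
                "inverse_difference_moment_normalized"),
    mean_e = c(27.5, 0.3, 0.6, 8.0, -1.1, 0.3, 0.5, 0.5, 0.9, 0.6,
               27.9, 10.4, 101.5, 0.4, 0.3, 0.2, -0.3, 0.4, 1.0, 1.0),
    sd_e   = c(6.9, 0.2, 0.3, 10.7, 2.0, 0.2, 0.3, 0.3, 0.1, 0.2,
               7.3, 1.3, 25.4, 0.2, 0.2, 0.1, 0.2, 0.2, 0.02, 0.02),
    mean_ne = c(33.4, 0.2, 0.6, 9.1, -0.7, 0.2, 0.5, 0.4, 0.9, 0.6,
                33.4, 11.4, 124.5, 0.4, 0.2, 0.2, -0.4, 0.4, 1.0, 1.0),
    sd_ne  = c(10.8, 0.4, 0.3, 20.8, 2.3, 0.2, 0.3, 0.3, 0.1, 0.2,
               10.8, 1.9, 39.8, 0.2, 0.4, 0.1, 0.2, 0.2, 0.02, 0.02),
    stringsAsFactors = FALSE)
  stopifnot(identical(sort(df$feature), sort(texture_feature_names)))
  df
}

#' Configuration for the feature-table generator
#'
#' @param n_e,n_ne class sizes; defaults 43 expected / 73 non-expected.
#' @param feature_params per-class means/SDs; default
#'   [default_feature_params()].
#' @param cor_features features sharing a common equicorrelation block;
#'   default the four strongly intercorrelated intensity-scale features.
#' @param cor_value common within-block correlation; default 0.99.
#' @param n_subjects subjects to spread rows over (round-robin), so
#'   grouped splitting is exercised; default 15.
#' @param seed RNG seed.
#' @return A `table_gen_config` list.
#' @export
table_gen_config <- function(n_e = 43L, n_ne = 73L,
                             feature_params = default_feature_params(),
                             cor_features = c("autocorrelation",
                                              "sum_of_squares_variance",
                                              "sum_average", "sum_variance"),
                             cor_value = 0.99, n_subjects = 15L, seed = 1L) {
  stopifnot(n_e >= 1L, n_ne >= 1L, all(feature_params$sd_e >= 0),
            all(feature_params$sd_ne >= 0), abs(cor_value) <= 1,
            all(cor_features %in% feature_params$feature))
  structure(list(n_e = as.integer(n_e), n_ne = as.integer(n_ne),
                 feature_params = feature_params, cor_features = cor_features,
                 cor_value = cor_value, n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed)),
            class = "table_gen_config")
}

# Correlation matrix with an equicorrelation block; shrunk toward the
# identity until positive definite if the requested block is infeasible.
block_correlation <- function(features, block, rho) {
  p <- length(features)
  R <- diag(p)
  idx <- match(block, features)
  R[idx, idx] <- rho
  diag(R) <- 1
  shrink <- 0
  while (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < 1e-10) {
    shrink <- shrink + 0.05
    if (shrink >= 1)
      stop("correlation block infeasible even after shrinkage", call. = FALSE)
    R <- (1 - shrink) * R + shrink * diag(p)
  }
  attr(R, "shrinkage") <- shrink
  R
}

#' Generate a labeled synthetic feature table
#'
#' Draws each class's rows from a multivariate Gaussian with the
#' configured per-feature means/SDs and the equicorrelation block among
#' `cor_features`; all other features are independent. Subject ids are
#' assigned round-robin so that patient-grouped splitting can be
#' exercised. Gaussianity is a deliberate modeling simplification.
#'
#' @param config a [table_gen_config()].
#' @return A feature table data.frame (`subject_id`, `roi_id`, `label`,
#'   20 feature columns), deterministic given `config$seed`.
#' @export
generate_feature_table <- function(config = table_gen_config()) {
  stopifnot(inherits(config, "table_gen_config"))
  fp <- config$feature_params
  feats <- fp$feature
  R <- block_correlation(feats, config$cor_features, config$cor_value)
  set.seed(config$seed)
  draw <- function(n, means, sds) {
    Sigma <- diag(sds) %*% R %*% diag(sds)
    X <- MASS::mvrnorm(n, mu = means, Sigma = Sigma)
    # mvrnorm drops the dim for n = 1
    matrix(X, nrow = n, dimnames = list(NULL, feats))
  }
  Xe <- draw(config$n_e, fp$mean_e, fp$sd_e)
  Xn <- draw(config$n_ne, fp$mean_ne, fp$sd_ne)
  X <- rbind(Xe, Xn)
  n <- nrow(X)
  subjects <- sprintf("S%02d", ((seq_len(n) - 1L) %% config$n_subjects) + 1L)
  out <- data.frame(subject_id = subjects,
                    roi_id = sprintf("R%03d", seq_len(n)),
                    label = rep(c("E", "NE"), c(config$n_e, config$n_ne)),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(X))
}

#' Configuration for the textured-volume generator
#'
#' Emulates mean-EPI-like volumes in which the within-ROI spatial
#' heterogeneity differs by class: expected (truly active) ROIs are the
#' heterogeneous class, so their Gaussian-random-field correlation
#' length must be smaller than the non-expected one.
#'
#' @param n_subjects default 15.
#' @param volume_shape acquisition-like grid; default 64 x 64 x 30.
#' @param spacing voxel size in mm; default 3.75 x 3.75 x 4.
#' @param n_e_total,n_ne_active_total activation ROI counts over the
#'   whole cohort; defaults 43 and 43. Together with two fixed control
#'   ROIs per subject (labelled NE) the defaults yield 116 ROIs,
#'   43 E / 73 NE.
#' @param controls_per_subject fixed inactivity ROIs per subject;
#'   default 2.
#' @param roi_extent activation ROI box in voxels; default 9 x 9 x 3.
#' @param e_corlen,ne_corlen Gaussian-field correlation lengths (voxels)
#'   for the two classes; defaults 0.6 (E, heterogeneous) and 2.0 (NE,
#'   homogeneous). Setting them equal removes the class contrast.
#' @param background_corlen correlation length of the background field
#'   (also what the control ROIs sample); default 2.0.
#' @param intensity_mean,intensity_sd volume intensity scale; defaults
#'   500 and 50 (arbitrary MR units).
#' @param skew log-normal shape of the pointwise intensity transform
#'   (right-skewed marginals, as in EPI magnitude data); default 0.75.
#' @param seed RNG seed.
#' @return An `image_gen_config` list.
#' @export
image_gen_config <- function(n_subjects = 15L, volume_shape = c(64L, 64L, 30L),
                             spacing = c(3.75, 3.75, 4),
                             n_e_total = 43L, n_ne_active_total = 43L,
                             controls_per_subject = 2L,
                             roi_extent = c(9L, 9L, 3L),
                             e_corlen = 0.6, ne_corlen = 2.0,
                             background_corlen = 2.0,
                             intensity_mean = 500, intensity_sd = 50,
                             skew = 0.75, seed = 1L) {
  stopifnot(e_corlen > 0, ne_corlen > 0, background_corlen > 0,
            n_subjects >= 1L, all(roi_extent >= 1L))
  if (e_corlen >= ne_corlen)
    stop("the expected class must be the heterogeneous one: ",
         "`e_corlen` must be < `ne_corlen`", call. = FALSE)
  if (any(roi_extent > volume_shape))
    stop("`roi_extent` exceeds the volume shape", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects),
                 volume_shape = as.integer(volume_shape), spacing = spacing,
                 n_e_total = as.integer(n_e_total),
                 n_ne_active_total = as.integer(n_ne_active_total),
                 controls_per_subject = as.integer(controls_per_subject),
                 roi_extent = as.integer(roi_extent),
                 e_corlen = e_corlen, ne_corlen = ne_corlen,
                 background_corlen = background_corlen,
                 intensity_mean = intensity_mean, intensity_sd = intensity_sd,
                 skew = skew, seed = as.integer(seed)),
            class = "image_gen_config")
}

# Separable 3-D Gaussian smoothing (sigma in voxels), edge-replicated.
gaussian_smooth_3d <- function(arr, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(-r:r, sd = sigma)
  kern <- kern / sum(kern)
  smooth_axis <- function(a, axis) {
    perm <- switch(axis, `1` = 1:3, `2` = c(2L, 1L, 3L), `3` = c(3L, 2L, 1L))
    x <- aperm(a, perm)
    d <- dim(x)
    m <- matrix(x, nrow = d[1])
    m <- rbind(m[rep(1L, r), , drop = FALSE], m,
               m[rep(d[1], r), , drop = FALSE])
    f <- stats::filter(m, kern, sides = 2)
    f <- f[(r + 1L):(r + d[1]), , drop = FALSE]
    aperm(array(f, d), order(perm))
  }
  for (ax in 1:3) arr <- smooth_axis(arr, ax)
  arr
}

# Standardized Gaussian random field -> right-skewed intensity field on
# the configured scale. The log-normal marginal gives EPI-like skew;
# a monotone pointwise transform preserves the field's smoothness
# ordering between classes.
textured_field <- function(dims, corlen, mean, sd, skew) {
  z <- gaussian_smooth_3d(array(stats::rnorm(prod(dims)), dims), corlen)
  z <- (z - mean(z)) / max(stats::sd(z), .Machine$double.eps)
  if (skew > 0) {
    w <- exp(skew * z)
    z <- (w - mean(w)) / max(stats::sd(w), .Machine$double.eps)
  }
  mean + sd * z
}

# Spread a cohort total over subjects as evenly as possible,
# deterministically (earlier subjects take the remainder).
allocate_counts <- function(total, n_subjects) {
  base <- total %/% n_subjects
  extra <- total %% n_subjects
  base + as.integer(seq_len(n_subjects) <= extra)
}

#' Generate a synthetic cohort of textured volumes with labelled ROIs
#'
#' Per subject: a background volume of smoothed, right-skewed Gaussian
#' noise; activation ROIs placed at random non-overlapping box positions
#' whose voxels are replaced by a Gaussian random field with the class's
#' correlation length (E rough, NE smooth); plus the fixed control ROIs
#' (labelled NE) sampling the untouched smooth background. Reproducible
#' from `config$seed`.
#'
#' @param config an [image_gen_config()].
#' @return List with `volumes` (named list of [image_volume], one per
#'   subject), `rois` (list of [roi_mask]), and `manifest` (data.frame
#'   `subject_id`, `roi_id`, `label`, `n_voxels`).
#' @export
generate_volume_dataset <- function(config = image_gen_config()) {
  stopifnot(inherits(config, "image_gen_config"))
  dims <- config$volume_shape
  ext <- config$roi_extent
  if (any(ext > dims))
    stop("`roi_extent` exceeds the volume shape", call. = FALSE)
  set.seed(config$seed)

  sids <- sprintf("S%02d", seq_len(config$n_subjects))
  n_e_per <- allocate_counts(config$n_e_total, config$n_subjects)
  n_ne_per <- allocate_counts(config$n_ne_active_total, config$n_subjects)

  # control ROI geometry: fixed across subjects, kept clear of the
  # random activation boxes via the occupancy map below
  ctrl_centers <- list(
    as.integer(round(dims * c(0.25, 0.25, 0.33))),
    as.integer(round(dims * c(0.75, 0.75, 0.33))))
  ctrl_size <- c(5L, 5L, 1L)

  volumes <- list()
  rois <- list()
  for (s in seq_along(sids)) {
    sid <- sids[s]
    vol_data <- textured_field(dims, config$background_corlen,
                               config$intensity_mean, config$intensity_sd,
                               config$skew)

    occupied <- array(FALSE, dims)
    half <- (ctrl_size - 1L) %/% 2L
    for (ctr in ctrl_centers) {
      lo <- pmax(ctr - half - 1L, 1L)
      hi <- pmin(ctr + (ctrl_size - 1L - half) + 1L, dims)
      occupied[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
    }

    labels <- rep(c("E", "NE"), c(n_e_per[s], n_ne_per[s]))
    for (k in seq_along(labels)) {
      lab <- labels[k]
      corlen <- if (lab == "E") config$e_corlen else config$ne_corlen
      # rejection-sample a free box position
      placed <- FALSE
      for (try in seq_len(200L)) {
        lo <- vapply(1:3, function(a) sample.int(dims[a] - ext[a] + 1L, 1L),
                     integer(1))
        hi <- lo + ext - 1L
        if (!any(occupied[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]])) {
          placed <- TRUE; break
        }
      }
      if (!placed)
        stop("could not place ROI ", k, " for subject ", sid,
             ": volume too crowded", call. = FALSE)
      occupied[max(lo[1] - 1L, 1L):min(hi[1] + 1L, dims[1]),
               max(lo[2] - 1L, 1L):min(hi[2] + 1L, dims[2]),
               max(lo[3] - 1L, 1L):min(hi[3] + 1L, dims[3])] <- TRUE
      field <- textured_field(ext, corlen, config$intensity_mean,
                              config$intensity_sd, config$skew)
      vol_data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- field
      m <- array(FALSE, dims)
      m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
      rois[[length(rois) + 1L]] <-
        roi_mask(m, subject_id = sid,
                 roi_id = sprintf("%s_act%02d", sid, k), label = lab)
    }
    volume <- image_volume(vol_data, spacing = config$spacing)
    volumes[[sid]] <- volume
    if (config$controls_per_subject > 0L)
      rois <- c(rois, place_control_rois(
        volume, sid, centers = ctrl_centers[seq_len(config$controls_per_subject)],
        size = ctrl_size))
  }

  manifest <- do.call(rbind, lapply(rois, function(r)
    data.frame(subject_id = r$subject_id, roi_id = r$roi_id, label = r$label,
               n_voxels = sum(r$mask), stringsAsFactors = FALSE)))
  list(volumes = volumes, rois = rois, manifest = manifest)
}
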