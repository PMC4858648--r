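#' The 20 rotation-invariant texture feature names
#'
#' Order matches the feature vector returned by [compute_features()]:
#' the classical Haralick set (contrast, correlation, energy, entropy,
#' sum/difference statistics, the two information measures of
#' correlation), the Soh additions (autocorrelation, cluster prominence
#' and shade, dissimilarity, homogeneity, maximum probability) and the
#' two Clausi normalized inverse-difference features.
#'
#' @export
texture_feature_names <- c(
  "autocorrelation", "contrast", "correlation", "cluster_prominence",
  "cluster_shade", "dissimilarity", "energy", "entropy", "homogeneity",
  "maximum_probability", "sum_of_squares_variance", "sum_average",
  "sum_variance", "sum_entropy", "difference_variance",
  "difference_entropy", "imc1", "imc2", "inverse_difference_normalized",
  "inverse_difference_moment_normalized"
)

#' The four angular GLCM directions
#'
#' Offsets are (row, column) steps in pixel index space for angles
#' 0, 45, 90 and 135 degrees at unit distance; anisotropic voxel spacing
#' is deliberately ignored (unit grid offsets).
#'
#' @keywords internal
glcm_directions <- function(distance = 1L) {
  d <- as.integer(distance)
  list(`0`   = c(0L,  d),
       `45`  = c(-d,  d),
       `90`  = c(-d, 0L),
       `135` = c(-d, -d))
}

#' Quantize ROI patches to a small number of gray levels
#'
#' Intensities are pooled over all inside pixels of the ROI (across its
#' slices); the pooled \[min, max\] range is split into `n_levels`
#' equal-width bins and each inside pixel is mapped to its 1-based bin
#' index, with the top edge belonging to the last bin. Quantizing over
#' the per-ROI range makes the downstream features invariant to affine
#' intensity shifts of the ROI.
#'
#' A constant ROI (max == min) degenerates to all pixels at level 1; the
#' result then carries attribute `degenerate = TRUE`.
#'
#' @param patches list of patches from [extract_patches()].
#' @param n_levels number of gray levels (>= 2); default 8.
#' @return A list of quantized patches (`levels` integer matrix, `inside`
#'   logical matrix, `n_levels`), with attribute `degenerate`.
#' @export
quantize <- function(patches, n_levels = 8L) {
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L) stop("`n_levels` must be >= 2", call. = FALSE)
  if (!length(patches)) stop("no patches to quantize", call. = FALSE)
  vals <- unlist(lapply(patches, function(p) p$values[p$inside]))
  if (!length(vals)) stop("patches contain no inside pixels", call. = FALSE)
  if (any(!is.finite(vals)))
    stop("non-finite intensities at inside pixels", call. = FALSE)
  mn <- min(vals); mx <- max(vals)
  degenerate <- mx == mn
  width <- if (degenerate) 1 else (mx - mn) / n_levels
  out <- lapply(patches, function(p) {
    lev <- matrix(NA_integer_, nrow(p$inside), ncol(p$inside))
    x <- p$values[p$inside]
    l <- pmin.int(as.integer(floor((x - mn) / width)) + 1L, n_levels)
    lev[p$inside] <- l
    list(slice_index = p$slice_index, levels = lev, inside = p$inside,
         n_levels = n_levels)
  })
  attr(out, "degenerate") <- degenerate
  out
}

#' Raw (unnormalized) gray-level co-occurrence matrix of one patch
#'
#' Counts every ordered pixel pair (a, b) with both pixels inside the ROI
#' and b offset from a by the direction/distance vector, symmetrized so
#' each pair contributes to both (i, j) and (j, i). The matrix is
#' returned as raw counts so that counts can be accumulated over the
#' slices of an ROI before a single normalization.
#'
#' @param patch a quantized patch from [quantize()].
#' @param direction one of 0, 45, 90, 135 (degrees).
#' @param distance pixel offset (>= 1); default 1 ("adjacent" pixels).
#' @return n_levels x n_levels count matrix with attribute `empty = TRUE`
#'   when the patch contains no valid pair for this direction.
#' @export
compute_glcm <- function(patch, direction, distance = 1L) {
  direction <- as.character(direction)
  offs <- glcm_directions(distance)
  if (!direction %in% names(offs))
    stop("direction must be one of 0, 45, 90, 135 degrees", call. = FALSE)
  if (as.integer(distance) < 1L) stop("`distance` must be >= 1", call. = FALSE)
  off <- offs[[direction]]
  L <- patch$levels; ins <- patch$inside; n <- patch$n_levels
  nr <- nrow(L); nc <- ncol(L)
  dr <- off[1]; dc <- off[2]
  ra <- seq_len(nr); ca <- seq_len(nc)
  ra <- ra[ra + dr >= 1L & ra + dr <= nr]
  ca <- ca[ca + dc >= 1L & ca + dc <= nc]
  M <- matrix(0, n, n)
  if (length(ra) && length(ca)) {
    A  <- L[ra, ca, drop = FALSE]
    B  <- L[ra + dr, ca + dc, drop = FALSE]
    ok <- ins[ra, ca, drop = FALSE] & ins[ra + dr, ca + dc, drop = FALSE]
    if (any(ok)) {
      idx <- A[ok] + (B[ok] - 1L) * n          # column-major cell index
      M <- matrix(as.numeric(tabulate(idx, nbins = n * n)), n, n)
      M <- M + t(M)                            # symmetric counting
    }
  }
  attr(M, "empty") <- sum(M) == 0
  M
}

#' Per-direction GLCMs of a whole ROI
#'
#' For each of the four directions, raw pair counts are accumulated over
#' all slices of the ROI and then normalized once to sum 1, so large
#' slices contribute proportionally more than tiny ones. A direction with
#' no valid pair anywhere is flagged `empty` and left as a zero matrix;
#' if all four directions are empty (e.g. a single-pixel ROI) the ROI's
#' features are undefined and an error is raised.
#'
#' @param patches list of quantized patches from [quantize()].
#' @param distance pixel offset; default 1.
#' @return Named list (`"0"`, `"45"`, `"90"`, `"135"`) of normalized GLCM
#'   matrices, each with attribute `empty`.
#' @export
roi_glcms <- function(patches, distance = 1L) {
  if (!length(patches)) stop("no quantized patches supplied", call. = FALSE)
  n <- patches[[1]]$n_levels
  dirs <- names(glcm_directions(distance))
  out <- lapply(dirs, function(ang) {
    acc <- matrix(0, n, n)
    for (p in patches) acc <- acc + compute_glcm(p, ang, distance)
    tot <- sum(acc)
    if (tot > 0) acc <- acc / tot
    attr(acc, "empty") <- tot == 0
    acc
  })
  names(out) <- dirs
  if (all(vapply(out, function(m) attr(m, "empty"), logical(1))))
    stop("texture features undefined: no co-occurring pixel pair in any direction",
         call. = FALSE)
  out
}

# Marginal and diagonal distributions derived from a normalized GLCM:
# p_x, p_y, p_{i+j}, p_{|i-j|}, their moments, and the entropies feeding
# the information measures of correlation. All logs are natural; 0*log 0
# terms are dropped.
glcm_derived <- function(P) {
  n <- nrow(P)
  i <- seq_len(n)
  px <- rowSums(P); py <- colSums(P)
  mu_x <- sum(i * px); mu_y <- sum(i * py)
  sigma_x <- sqrt(sum((i - mu_x)^2 * px))
  sigma_y <- sqrt(sum((i - mu_y)^2 * py))
  I <- matrix(i, n, n); J <- t(I)
  p_sum <- vapply(2:(2 * n), function(k) sum(P[(I + J) == k]), numeric(1))
  p_diff <- vapply(0:(n - 1), function(k) sum(P[abs(I - J) == k]), numeric(1))
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  pxy <- outer(px, py)
  HX <- ent(px); HY <- ent(py); HXY <- ent(P)
  pos <- pxy > 0
  HXY1 <- -sum(P[pos] * log(pxy[pos]))
  HXY2 <- ent(pxy)
  list(n = n, i = i, I = I, J = J, px = px, py = py,
       mu_x = mu_x, mu_y = mu_y, sigma_x = sigma_x, sigma_y = sigma_y,
       p_sum = p_sum, p_diff = p_diff,
       HX = HX, HY = HY, HXY = HXY, HXY1 = HXY1, HXY2 = HXY2)
}

#' Compute the 20 texture features of one normalized GLCM
#'
#' Uses the standard Haralick/Soh/Clausi definitions with p = p(i, j),
#' i, j in 1..n. Natural logarithms throughout; 0 log 0 := 0. Degenerate
#' conventions: correlation := 1 when sigma_x * sigma_y = 0 (all mass on
#' the diagonal implies deterministic equality); imc1 := 0 when
#' max(HX, HY) = 0; a small negative under the imc2 square root clamps
#' to 0.
#'
#' @param glcm a normalized (sum-1) GLCM matrix.
#' @return Named numeric vector of length 20 (see [texture_feature_names]).
#' @export
compute_features <- function(glcm) {
  P <- unclass(glcm)
  if (!is.matrix(P) || nrow(P) != ncol(P))
    stop("`glcm` must be a square matrix", call. = FALSE)
  if (abs(sum(P) - 1) > 1e-8)
    stop("`glcm` must be normalized to sum 1 (got sum ", signif(sum(P), 6), ")",
         call. = FALSE)
  d <- glcm_derived(P)
  n <- d$n; I <- d$I; J <- d$J
  ks <- 2:(2 * n)               # support of p_{i+j}
  kd <- 0:(n - 1)               # support of p_{|i-j|}
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }

  autocorrelation <- sum(I * J * P)
  contrast <- sum((I - J)^2 * P)
  ss <- d$sigma_x * d$sigma_y
  correlation <- if (ss == 0) 1 else (autocorrelation - d$mu_x * d$mu_y) / ss
  cluster_prominence <- sum((I + J - d$mu_x - d$mu_y)^4 * P)
  cluster_shade <- sum((I + J - d$mu_x - d$mu_y)^3 * P)
  dissimilarity <- sum(abs(I - J) * P)
  energy <- sum(P^2)
  entropy <- ent(P)
  homogeneity <- sum(P / (1 + (I - J)^2))
  maximum_probability <- max(P)
  sum_of_squares_variance <- sum((I - d$mu_x)^2 * P)
  sum_average <- sum(ks * d$p_sum)
  sum_variance <- sum((ks - sum_average)^2 * d$p_sum)
  sum_entropy <- ent(d$p_sum)
  mu_d <- sum(kd * d$p_diff)
  difference_variance <- sum((kd - mu_d)^2 * d$p_diff)
  difference_entropy <- ent(d$p_diff)
  hmax <- max(d$HX, d$HY)
  imc1 <- if (hmax == 0) 0 else (d$HXY - d$HXY1) / hmax
  imc2 <- sqrt(max(0, 1 - exp(-2 * (d$HXY2 - d$HXY))))
  inverse_difference_normalized <- sum(P / (1 + abs(I - J) / n))
  inverse_difference_moment_normalized <- sum(P / (1 + (I - J)^2 / n^2))

  c(autocorrelation = autocorrelation, contrast = contrast,
    correlation = correlation, cluster_prominence = cluster_prominence,
    cluster_shade = cluster_shade, dissimilarity = dissimilarity,
    energy = energy, entropy = entropy, homogeneity = homogeneity,
    maximum_probability = maximum_probability,
    sum_of_squares_variance = sum_of_squares_variance,
    sum_average = sum_average, sum_variance = sum_variance,
    sum_entropy = sum_entropy, difference_variance = difference_variance,
    difference_entropy = difference_entropy, imc1 = imc1, imc2 = imc2,
    inverse_difference_normalized = inverse_difference_normalized,
    inverse_difference_moment_normalized = inverse_difference_moment_normalized)
}

#' Rotation-invariant feature vector from the four directional GLCMs
#'
#' Per-feature arithmetic mean over the four directional feature vectors.
#' Directions flagged as empty are excluded from the mean and recorded in
#' the `excluded_directions` attribute.
#'
#' @param glcms named list of four normalized GLCMs from [roi_glcms()].
#' @return Named numeric vector of length 20, attribute
#'   `excluded_directions`.
#' @export
rotation_invariant_features <- function(glcms) {
  empty <- vapply(glcms, function(m) isTRUE(attr(m, "empty")), logical(1))
  if (all(empty))
    stop("texture features undefined: all four directions are empty", call. = FALSE)
  mat <- vapply(glcms[!empty], compute_features,
                numeric(length(texture_feature_names)))
  out <- rowMeans(mat)
  attr(out, "excluded_directions") <- names(glcms)[empty]
  out
}

#' Texture features of one ROI on a volume
#'
#' Convenience wrapper: slice patches, per-ROI quantization, per-direction
#' GLCM accumulation, feature computation and direction averaging.
#'
#' @param volume an [image_volume].
#' @param roi an [roi_mask].
#' @param n_levels gray levels; default 8.
#' @param distance pair offset; default 1.
#' @return Named numeric vector of the 20 rotation-invariant features,
#'   with attributes `n_voxels` and `degenerate`.
#' @export
extract_roi_features <- function(volume, roi, n_levels = 8L, distance = 1L) {
  patches <- extract_patches(volume, roi)
  q <- quantize(patches, n_levels)
  feats <- rotation_invariant_features(roi_glcms(q, distance))
  attr(feats, "n_voxels") <- sum(if (inherits(roi, "roi_mask")) roi$mask else roi)
  attr(feats, "degenerate") <- isTRUE(attr(q, "degenerate"))
  feats
}

#' Build the ROI x feature table for a dataset
#'
#' One row per ROI with identity, label, the 20 rotation-invariant
#' features and provenance columns (`n_levels`, `distance`, `n_voxels`).
#'
#' @param volumes named list of [image_volume]s, indexed by subject id.
#' @param rois list of [roi_mask] objects.
#' @param n_levels,distance texture settings; defaults 8 and 1.
#' @return A data.frame feature table.
#' @export
extract_feature_table <- function(volumes, rois, n_levels = 8L, distance = 1L) {
  rows <- lapply(rois, function(roi) {
    vol <- volumes[[roi$subject_id]]
    if (is.null(vol))
      stop("no volume for subject ", roi$subject_id, " (ROI ", roi$roi_id, ")",
           call. = FALSE)
    f <- extract_roi_features(vol, roi, n_levels, distance)
    cbind(data.frame(subject_id = roi$subject_id, roi_id = roi$roi_id,
                     label = roi$label, stringsAsFactors = FALSE),
          as.data.frame(as.list(f)),
          data.frame(n_levels = n_levels, distance = distance,
                     n_voxels = attr(f, "n_voxels")))
  })
  do.call(rbind, rows)
}

#' Write a feature table as CSV
#' @param table feature table from [extract_feature_table()].
#' @param path CSV path.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
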