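# Shared fixtures: brute-force GLCM oracle, random patch generators,
# and small synthetic tables. All fixtures are built in code.

# Exhaustive double loop over all pixel pairs testing the offset; the
# independent oracle for compute_glcm (symmetric counting).
oracle_glcm <- function(levels, inside, dr, dc, n_levels) {
  m <- matrix(0, n_levels, n_levels)
  nr <- nrow(levels); nc <- ncol(levels)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    r2 <- r + dr; c2 <- c + dc
    if (inside[r, c] && r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
        inside[r2, c2]) {
      i <- levels[r, c]; j <- levels[r2, c2]
      m[i, j] <- m[i, j] + 1
      m[j, i] <- m[j, i] + 1
    }
  }
  m
}

oracle_offsets <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L),
                       `90` = c(-1L, 0L), `135` = c(-1L, -1L))

# Random quantized patch with optional holes in the inside mask.
random_patch <- function(nr, nc, n_levels, p_inside = 1) {
  inside <- matrix(runif(nr * nc) < p_inside, nr, nc)
  if (!any(inside)) inside[sample(nr * nc, 1)] <- TRUE
  lev <- matrix(sample.int(n_levels, nr * nc, replace = TRUE), nr, nc)
  lev[!inside] <- NA_integer_
  list(slice_index = 1L, levels = lev, inside = inside, n_levels = n_levels)
}

# Intensity patch (pre-quantization) from a smoothed 2-D Gaussian field.
random_field_patch <- function(nr, nc, sigma) {
  pad <- max(1L, ceiling(3 * sigma))
  z <- matrix(rnorm((nr + 2 * pad) * (nc + 2 * pad)), nr + 2 * pad)
  k <- dnorm(-pad:pad, sd = sigma); k <- k / sum(k)
  z <- apply(z, 2, function(col) stats::filter(col, k, sides = 2))
  z <- t(apply(z, 1, function(row) stats::filter(row, k, sides = 2)))
  z <- z[(pad + 1):(pad + nr), (pad + 1):(pad + nc), drop = FALSE]
  list(slice_index = 1L, values = z, inside = matrix(TRUE, nr, nc))
}

# Feature table with 19 i.i.d. noise features and (optionally) one
# feature separated between classes by `shift` SDs.
planted_table <- function(n_e = 43, n_ne = 73, shift = 2,
                          planted = "sum_variance") {
  n <- n_e + n_ne
  X <- matrix(rnorm(n * 20), n, 20)
  colnames(X) <- fmritex::texture_feature_names
  lab <- rep(c("E", "NE"), c(n_e, n_ne))
  if (!is.null(planted)) X[lab == "E", planted] <- X[lab == "E", planted] + shift
  df <- data.frame(subject_id = sprintf("S%02d", ((seq_len(n) - 1) %% 15) + 1),
                   roi_id = sprintf("R%03d", seq_len(n)), label = lab,
                   stringsAsFactors = FALSE)
  cbind(df, as.data.frame(X))
}
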