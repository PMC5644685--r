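# Independent brute-force reference implementations used to validate the
# vectorised texture code. These are literal transcriptions of the
# co-occurrence / neighbourhood-difference definitions as explicit loops
# over voxels and neighbour offsets, sharing no code with the package.

oracle_offsets26 <- local({
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
})

# Map from "x,y,z" coordinate keys to grey level.
oracle_level_map <- function(levels, coords) {
  stats::setNames(levels, paste(coords[, 1], coords[, 2], coords[, 3],
                                sep = ","))
}

# GLCM features by per-voxel neighbour loops: every ordered pair of
# 26-adjacent VOI voxels contributes one count.
oracle_glcm <- function(levels, coords, ng) {
  lut <- oracle_level_map(levels, coords)
  counts <- matrix(0, ng, ng)
  for (v in seq_len(nrow(coords))) {
    for (o in seq_len(nrow(oracle_offsets26))) {
      nb <- coords[v, ] + oracle_offsets26[o, ]
      l2 <- unname(lut[paste(nb[1], nb[2], nb[3], sep = ",")])
      if (!is.na(l2)) {
        counts[levels[v], l2] <- counts[levels[v], l2] + 1
      }
    }
  }
  tot <- sum(counts)
  if (tot == 0) {
    return(c(contrast = NA_real_, entropy = NA_real_, uniformity = NA_real_,
             homogeneity = NA_real_))
  }
  p <- counts / tot
  contrast <- 0; entropy <- 0; uniformity <- 0; homogeneity <- 0
  for (i in 1:ng) {
    for (j in 1:ng) {
      if (p[i, j] > 0) entropy <- entropy - p[i, j] * log2(p[i, j])
      contrast <- contrast + (i - j)^2 * p[i, j]
      uniformity <- uniformity + p[i, j]^2
      homogeneity <- homogeneity + p[i, j] / (1 + (i - j)^2)
    }
  }
  c(contrast = contrast, entropy = entropy, uniformity = uniformity,
    homogeneity = homogeneity)
}

# NGTDM features by per-voxel loops with the complete-neighbourhood rule.
oracle_ngtdm <- function(levels, coords, ng, eps = 1e-6) {
  lut <- oracle_level_map(levels, coords)
  s <- numeric(ng)
  n <- integer(ng)
  for (v in seq_len(nrow(coords))) {
    nb_levels <- numeric(0)
    complete <- TRUE
    for (o in seq_len(nrow(oracle_offsets26))) {
      nb <- coords[v, ] + oracle_offsets26[o, ]
      l2 <- unname(lut[paste(nb[1], nb[2], nb[3], sep = ",")])
      if (is.na(l2)) {
        complete <- FALSE
        break
      }
      nb_levels <- c(nb_levels, l2)
    }
    if (complete) {
      i <- levels[v]
      n[i] <- n[i] + 1L
      s[i] <- s[i] + abs(i - mean(nb_levels))
    }
  }
  n_tot <- sum(n)
  if (n_tot == 0) {
    return(c(coarseness = NA_real_, contrast = NA_real_, busyness = NA_real_,
             complexity = NA_real_))
  }
  p <- n / n_tot
  pres <- which(p > 0)
  g <- length(pres)
  ps <- sum(p * s)
  coarseness <- 1 / (eps + ps)
  contrast <- 0
  if (g > 1) {
    for (i in pres) for (j in pres) {
      contrast <- contrast + p[i] * p[j] * (i - j)^2
    }
    contrast <- contrast / (g * (g - 1)) * sum(s) / n_tot
  }
  den <- 0
  for (i in pres) for (j in pres) den <- den + abs(i * p[i] - j * p[j])
  busyness <- if (den > 0) ps / den else NA_real_
  complexity <- 0
  for (i in pres) for (j in pres) {
    complexity <- complexity +
      abs(i - j) / (p[i] + p[j]) * (p[i] * s[i] + p[j] * s[j])
  }
  complexity <- complexity / n_tot
  c(coarseness = coarseness, contrast = contrast, busyness = busyness,
    complexity = complexity)
}

# AUC by exhaustive pair counting (ties count one half).
oracle_auc <- function(scores, is_malignant) {
  pos <- scores[is_malignant]
  neg <- scores[!is_malignant]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}

# Voxel offsets inside a sphere of `volume_ml`, by direct enumeration
# over a generous cube of candidate offsets.
oracle_sphere_size <- function(spacing, volume_ml = 1.0) {
  r <- (3 * volume_ml * 1000 / (4 * pi))^(1 / 3)
  cand <- expand.grid(dx = -5:5, dy = -5:5, dz = -5:5)
  sum(sqrt((cand$dx * spacing[1])^2 + (cand$dy * spacing[2])^2 +
             (cand$dz * spacing[3])^2) <= r)
}

# Random VOI fixture: volume + mask (+ the extracted sample/quantization)
# on a small grid, optionally with duplicate values to exercise ties.
random_voi <- function(max_dim = 8, n_bins = 64, p_inside = 0.7,
                       discrete = FALSE) {
  dims <- sample(3:max_dim, 3, replace = TRUE)
  vals <- if (discrete) {
    array(sample(1:5, prod(dims), replace = TRUE), dims)
  } else {
    array(stats::rnorm(prod(dims), mean = 5), dims)
  }
  flags <- array(stats::runif(prod(dims)) < p_inside, dims)
  if (sum(flags) < 2) flags[1:2] <- TRUE
  vol <- image_volume(vals, c(4.7, 4.7, 3.27))
  mask <- voi_mask(flags)
  sample <- extract_voi(vol, mask)
  list(volume = vol, mask = mask, sample = sample,
       quant = quantize_voi(sample, n_bins))
}
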