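#' Voxel grid for coordinate-based meta-analysis
#'
#' A regular isotropic grid with a recorded mm-to-voxel mapping:
#' `voxel = round((mm - origin) / spacing) + 1` (nearest-voxel assignment).
#'
#' @param dim Integer grid dimensions (x, y, z).
#' @param spacing Voxel size in mm (default 2, MKDA convention).
#' @param origin mm coordinate of voxel (1, 1, 1).
#' @export
mkda_grid <- function(dim, spacing = 2, origin = -spacing * (dim - 1) / 2) {
  stopifnot(length(dim) == 3, all(dim >= 1))
  if (length(origin) == 1) origin <- rep(origin, 3)
  structure(list(dim = as.integer(dim), spacing = spacing, origin = origin),
            class = "mkda_grid")
}

mm_to_voxel <- function(grid, mm) {
  mm <- matrix(mm, ncol = 3)
  v <- round(sweep(mm, 2L, grid$origin) / grid$spacing) + 1
  storage.mode(v) <- "integer"
  v
}

voxel_to_mm <- function(grid, vox) {
  vox <- matrix(vox, ncol = 3)
  sweep((vox - 1) * grid$spacing, 2L, grid$origin, "+")
}

#' Synthetic ellipsoid analysis mask
#'
#' A packaged stand-in "brain": voxels inside an axis-aligned ellipsoid.
#' Used for tests and simulations when no anatomical mask is supplied.
#'
#' @param grid An [mkda_grid()].
#' @param center Ellipsoid center in mm (defaults to the grid center).
#' @param radii Semi-axes in mm (defaults to 80% of the grid half-extent).
#' @return Logical 3D array on the grid.
#' @export
ellipsoid_mask <- function(grid, center = NULL, radii = NULL) {
  half <- (grid$dim - 1) * grid$spacing / 2
  if (is.null(center)) center <- grid$origin + half
  if (is.null(radii)) radii <- 0.8 * pmax(half, grid$spacing)
  ax <- lapply(1:3, function(k)
    grid$origin[k] + (seq_len(grid$dim[k]) - 1) * grid$spacing)
  dx <- (ax[[1]] - center[1]) / radii[1]
  dy <- (ax[[2]] - center[2]) / radii[2]
  dz <- (ax[[3]] - center[3]) / radii[3]
  outer(outer(dx^2, dy^2, "+"), dz^2, "+") <= 1
}

#' A study's activation foci
#'
#' @param study_id Study identifier.
#' @param category `"reward_mixed"` or `"reward_only"` (free-form allowed).
#' @param foci n x 3 matrix of MNI mm coordinates.
#' @param n_participants Study sample size (drives the default
#'   square-root-of-n weighting).
#' @export
foci_study <- function(study_id, category, foci, n_participants) {
  foci <- matrix(as.numeric(foci), ncol = 3)
  if (nrow(foci) < 1) stop("study needs at least one focus")
  structure(list(study_id = study_id, category = category, foci = foci,
                 n_participants = n_participants),
            class = "foci_study")
}

#' Read/write foci tables
#'
#' CSV with columns `study_id, category, x, y, z, n`; one row per focus.
#'
#' @param path File path.
#' @param studies List of [foci_study()] objects.
#' @export
read_foci <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  lapply(split(d, d$study_id), function(s)
    foci_study(s$study_id[1], s$category[1],
               cbind(s$x, s$y, s$z), s$n[1]))
}

#' @rdname read_foci
#' @export
write_foci <- function(studies, path) {
  rows <- lapply(studies, function(s)
    data.frame(study_id = s$study_id, category = s$category,
               x = s$foci[, 1], y = s$foci[, 2], z = s$foci[, 3],
               n = s$n_participants))
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
}

# Voxel-offset triples within `radius` mm of a voxel center.
sphere_offsets <- function(grid, radius) {
  r_vox <- floor(radius / grid$spacing)
  g <- expand.grid(x = -r_vox:r_vox, y = -r_vox:r_vox, z = -r_vox:r_vox)
  d2 <- (g$x^2 + g$y^2 + g$z^2) * grid$spacing^2
  as.matrix(g[d2 <= radius^2, , drop = FALSE])
}

#' Binary indicator map of a study's foci
#'
#' Marks every in-mask voxel whose center lies within `radius` mm of any of
#' the study's foci (the union of spheres). Foci falling outside the mask
#' are clipped with a warning.
#'
#' @param study A [foci_study()].
#' @param grid An [mkda_grid()].
#' @param mask Logical 3D array on the grid.
#' @param radius Kernel radius in mm (default 10, MKDA convention).
#' @return Logical 3D array.
#' @export
indicator_map <- function(study, grid, mask, radius = 10) {
  stopifnot(radius > 0, all(dim(mask) == grid$dim))
  off <- sphere_offsets(grid, radius)
  map <- array(FALSE, grid$dim)
  centers <- mm_to_voxel(grid, study$foci)
  inside <- centers[, 1] >= 1 & centers[, 1] <= grid$dim[1] &
    centers[, 2] >= 1 & centers[, 2] <= grid$dim[2] &
    centers[, 3] >= 1 & centers[, 3] <= grid$dim[3]
  inside[inside] <- mask[centers[inside, , drop = FALSE]]
  if (any(!inside))
    warning(sum(!inside), " focus/foci outside the mask were clipped")
  for (i in which(inside)) {
    v <- sweep(off, 2L, centers[i, ], "+")
    ok <- v[, 1] >= 1 & v[, 1] <= grid$dim[1] &
      v[, 2] >= 1 & v[, 2] <= grid$dim[2] &
      v[, 3] >= 1 & v[, 3] <= grid$dim[3]
    map[v[ok, , drop = FALSE]] <- TRUE
  }
  map & mask
}

# Study weights: sqrt(n_participants) normalized to sum 1 (or uniform).
study_weights <- function(studies, weighting = c("sqrt_n", "uniform")) {
  weighting <- match.arg(weighting)
  w <- if (weighting == "sqrt_n")
    sqrt(vapply(studies, `[[`, 0, "n_participants"))
  else rep(1, length(studies))
  if (sum(w) == 0) stop("weight sum is zero")
  w / sum(w)
}

#' Weighted density map over studies
#'
#' Voxelwise weighted proportion of studies whose indicator map is active;
#' weights default to normalized `sqrt(n_participants)` so heavily sampled
#' studies count more without letting focus-rich studies dominate (each
#' study contributes a binary map).
#'
#' @param studies List of [foci_study()].
#' @param grid,mask Grid and mask shared by all studies.
#' @param radius Kernel radius in mm.
#' @param weights Optional explicit weights (normalized internally).
#' @return A list of class `density_map`: `values` (3D array in \[0, 1\]),
#'   `grid`, `radius`, `weights`.
#' @export
density_map <- function(studies, grid, mask, radius = 10, weights = NULL) {
  w <- if (is.null(weights)) study_weights(studies)
       else { if (sum(weights) == 0) stop("weight sum is zero")
              weights / sum(weights) }
  values <- array(0, grid$dim)
  for (i in seq_along(studies))
    values <- values + w[i] * indicator_map(studies[[i]], grid, mask, radius)
  structure(list(values = values, grid = grid, radius = radius, weights = w),
            class = "density_map")
}

#' Permutation FWE threshold for a density map
#'
#' Monte Carlo max-statistic threshold: each permutation relocates every
#' study's foci uniformly at random within the mask (preserving each
#' study's focus count), recomputes the weighted density map, and records
#' its maximum; the critical value is the `(1 - alpha)` quantile of the
#' maxima, giving family-wise error control at `alpha`.
#'
#' @param studies,grid,mask,radius,weights As in [density_map()].
#' @param n_perm Number of permutations (>= 1).
#' @param alpha FWE level.
#' @param seed Integer seed.
#' @return List with `critical`, `maxima`, `alpha`, `n_perm`.
#' @export
permutation_threshold <- function(studies, grid, mask, radius = 10,
                                  weights = NULL, n_perm = 1000,
                                  alpha = 0.05, seed = 1) {
  stopifnot(n_perm >= 1)
  w <- if (is.null(weights)) study_weights(studies) else weights / sum(weights)
  mask_vox <- which(mask, arr.ind = TRUE)
  if (nrow(mask_vox) < 1) stop("empty mask")
  counts <- vapply(studies, function(s) nrow(s$foci), 0L)
  maxima <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      perm <- lapply(seq_along(studies), function(i) {
        idx <- sample.int(nrow(mask_vox), counts[i], replace = TRUE)
        foci_study(studies[[i]]$study_id, studies[[i]]$category,
                   voxel_to_mm(grid, mask_vox[idx, , drop = FALSE]),
                   studies[[i]]$n_participants)
      })
      max(density_map(perm, grid, mask, radius, weights = w)$values)
    }, 0)
  })
  k <- min(max(ceiling((1 - alpha) * n_perm), 1L), n_perm)
  list(critical = sort(maxima)[k], maxima = maxima,
       alpha = alpha, n_perm = n_perm)
}

#' Bootstrap-balanced category contrast map
#'
#' Balances unequal category sizes: each iteration draws a random subset of
#' the larger (mixed) category of size `subset_size`, computes separately
#' FWE-thresholded density maps for the subset and for the fixed
#' reward-only set, and marks voxels significant for mixed but not only.
#' Averaging the per-iteration binary maps gives a significance-frequency
#' map; the final contrast keeps voxels whose frequency reaches the
#' `consistency` threshold.
#'
#' @param mixed_studies,only_studies Lists of [foci_study()].
#' @param grid,mask,radius As in [density_map()].
#' @param n_boot Bootstrap iterations (paper-scale default 500).
#' @param subset_size Mixed-category subset size (default matches the
#'   reward-only count, 9).
#' @param consistency Frequency threshold in (0, 1\] (default 0.05).
#' @param n_perm,alpha Permutation-test settings per iteration.
#' @param seed Integer seed.
#' @return List with `final` (logical array), `frequency` (array in
#'   \[0, 1\]), `only_critical`, `n_boot`, `subset_size`, `consistency`.
#' @export
bootstrap_contrast <- function(mixed_studies, only_studies, grid, mask,
                               radius = 10, n_boot = 500,
                               subset_size = min(9, length(mixed_studies)),
                               consistency = 0.05, n_perm = 1000,
                               alpha = 0.05, seed = 1) {
  if (consistency <= 0 || consistency > 1)
    stop("consistency must be in (0, 1]")
  stopifnot(subset_size <= length(mixed_studies))
  dens_only <- density_map(only_studies, grid, mask, radius)
  thr_only <- permutation_threshold(only_studies, grid, mask, radius,
                                    n_perm = n_perm, alpha = alpha,
                                    seed = seed)
  sig_only <- dens_only$values > thr_only$critical
  freq <- array(0, grid$dim)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      subset <- mixed_studies[sort(sample.int(length(mixed_studies),
                                              subset_size))]
      dens_m <- density_map(subset, grid, mask, radius)
      thr_m <- permutation_threshold(subset, grid, mask, radius,
                                     n_perm = n_perm, alpha = alpha,
                                     seed = seed + b)
      freq <- freq + ((dens_m$values > thr_m$critical) & !sig_only)
    }
  })
  freq <- freq / n_boot
  list(final = freq >= consistency, frequency = freq,
       only_critical = thr_only$critical, n_boot = n_boot,
       subset_size = subset_size, consistency = consistency)
}

#' Spatial overlap between two binary maps
#'
#' Percentage of `map_a`'s active voxels inside `region_mask` that are also
#' active in `map_b`; 0 (flagged) when `map_a` has no active voxels in the
#' region.
#'
#' @param map_a,map_b Logical 3D arrays on the same grid.
#' @param region_mask Logical 3D array restricting the comparison.
#' @return List with `percent` and `flagged`.
#' @export
overlap_fraction <- function(map_a, map_b, region_mask) {
  if (!all(dim(map_a) == dim(map_b)) || !all(dim(map_a) == dim(region_mask)))
    stop("grid mismatch")
  denom <- sum(map_a & region_mask)
  if (denom == 0) return(list(percent = 0, flagged = TRUE))
  list(percent = 100 * sum(map_a & map_b & region_mask) / denom,
       flagged = FALSE)
}

#' Specification for synthetic foci corpora
#'
#' Ground-truth generator settings for meta-analysis tests: per-category
#' study counts (default 16 reward-mixed, 9 reward-only), foci per study,
#' a planted convergence cluster (center, mm spread, and the categories
#' that carry it), and a per-study sample-size range.
#'
#' @param n_studies Named vector of study counts per category.
#' @param foci_per_study Mean focus count (Poisson, floored at 1).
#' @param cluster_center Planted cluster center (MNI mm) or `NULL` for a
#'   background-only corpus.
#' @param cluster_sd Gaussian spread of planted foci in mm.
#' @param cluster_categories Categories whose studies carry a planted
#'   focus.
#' @param n_participants_range Uniform integer range of study sample sizes.
#' @export
foci_spec <- function(n_studies = c(reward_mixed = 16, reward_only = 9),
                      foci_per_study = 8, cluster_center = NULL,
                      cluster_sd = 4,
                      cluster_categories = "reward_mixed",
                      n_participants_range = c(15, 40)) {
  structure(list(n_studies = n_studies, foci_per_study = foci_per_study,
                 cluster_center = cluster_center, cluster_sd = cluster_sd,
                 cluster_categories = cluster_categories,
                 n_participants_range = n_participants_range),
            class = "foci_spec")
}

#' Simulate study foci with known ground truth
#'
#' Draws background foci uniformly over mask voxels; studies in the planted
#' categories additionally place one focus at the cluster center plus
#' Gaussian jitter (resampled into the mask, exact at zero spread).
#'
#' @param spec A [foci_spec()].
#' @param grid,mask Target grid and mask.
#' @param seed Integer seed.
#' @return List of [foci_study()] objects.
#' @export
simulate_foci <- function(spec, grid, mask, seed = 1) {
  mask_vox <- which(mask, arr.ind = TRUE)
  if (nrow(mask_vox) < 1) stop("empty mask")
  if (!is.null(spec$cluster_center)) {
    cv <- mm_to_voxel(grid, spec$cluster_center)
    ok <- all(cv >= 1) && all(cv <= grid$dim) && mask[cv]
    if (!ok) stop("cluster center outside mask")
  }
  with_seed(seed, {
    studies <- list()
    sid <- 0L
    for (cat in names(spec$n_studies)) {
      for (j in seq_len(spec$n_studies[[cat]])) {
        sid <- sid + 1L
        n_foci <- max(1L, stats::rpois(1, spec$foci_per_study))
        idx <- sample.int(nrow(mask_vox), n_foci, replace = TRUE)
        foci <- voxel_to_mm(grid, mask_vox[idx, , drop = FALSE])
        if (!is.null(spec$cluster_center) &&
            cat %in% spec$cluster_categories) {
          f <- draw_cluster_focus(spec, grid, mask)
          foci[1, ] <- f
        }
        studies[[sid]] <- foci_study(
          paste0("study", sid), cat, foci,
          sample(spec$n_participants_range[1]:spec$n_participants_range[2], 1))
      }
    }
    studies
  })
}

draw_cluster_focus <- function(spec, grid, mask) {
  if (spec$cluster_sd == 0) return(spec$cluster_center)
  for (tries in 1:100) {
    f <- spec$cluster_center + rnorm(3, sd = spec$cluster_sd)
    v <- mm_to_voxel(grid, f)
    if (all(v >= 1) && all(v <= grid$dim) && mask[v]) return(f)
  }
  spec$cluster_center
}

#' Write a map or density map as NIfTI
#'
#' Thin convenience wrapper around the RNifti package for interoperability
#' with neuroimaging viewers; the analysis itself runs on plain arrays.
#'
#' @param values 3D array (logical maps are written as 0/1).
#' @param grid An [mkda_grid()] supplying the affine.
#' @param path Output path (`.nii` / `.nii.gz`).
#' @export
write_map_nifti <- function(values, grid, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("the RNifti package is required to write NIfTI files")
  img <- array(as.numeric(values), dim = grid$dim)
  nii <- RNifti::asNifti(img)
  RNifti::pixdim(nii) <- rep(grid$spacing, 3)
  RNifti::writeNifti(nii, path)
  invisible(path)
}
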