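#' Seeded uniform random point sets
#'
#' Generates N points i.i.d. uniform on `[low, high]^d`. This is the input
#' family used for the scalability experiments (N = 400 to 1600 in steps of
#' 400, d = 2); the defaults reflect that setting. Generators are pure
#' functions of their arguments including the seed.
#'
#' @param n Number of points.
#' @param d Dimensionality (default 2).
#' @param seed RNG seed (fixed default: reproducibility by construction).
#' @param low,high Box bounds, `low < high`.
#' @return An `n` x `d` tibble with columns `x1..xd`.
#' @export
#' @examples
#' gen_random_points(5, seed = 42)
gen_random_points <- function(n, d = 2L, seed = 1L, low = 0, high = 100) {
  stopifnot(n >= 1, d >= 1)
  if (!(low < high)) abort("low must be less than high")
  pts <- withr::with_seed(seed, matrix(stats::runif(n * d, low, high), n, d))
  colnames(pts) <- paste0("x", seq_len(d))
  as_tibble(pts)
}

#' Seeded Gaussian cluster mixtures
#'
#' K spherical Gaussian blobs whose centres are mutually at least
#' `separation` apart, with per-cluster sizes `round(n * size_weights)` (any
#' rounding residual goes to cluster 1). Equal weights give the
#' "uniform clusters" condition of the cluster-balance experiments; skewed
#' weights the "non-uniform" one. Points are emitted grouped by cluster
#' (cluster 1 first), emulating the spatially coherent ordering of image
#' pixels, which is what makes cluster balance visible to a contiguous
#' partition.
#'
#' @inheritParams gen_random_points
#' @param k Number of clusters.
#' @param size_weights Length-k positive weights summing to 1.
#' @param separation Minimum distance between cluster centres (> 0).
#' @param spread Within-cluster standard deviation.
#' @return A tibble with coordinate columns `x1..xd` and an integer `.label`
#'   column holding the true cluster of each point.
#' @export
#' @examples
#' gen_gaussian_clusters(40, k = 4, seed = 3)
gen_gaussian_clusters <- function(n, d = 2L, k = 4L,
                                  size_weights = rep(1 / k, k),
                                  separation = 20, spread = 1, seed = 1L) {
  stopifnot(n >= k, d >= 1, length(size_weights) == k,
            all(size_weights > 0))
  if (separation <= 0) abort("separation must be positive")
  if (abs(sum(size_weights) - 1) > 1e-8) abort("size_weights must sum to 1")
  sizes <- round(n * size_weights)
  sizes[1] <- sizes[1] + (n - sum(sizes))
  if (any(sizes < 1)) abort("size_weights give an empty cluster")
  withr::with_seed(seed, {
    # Rejection-sample centres in a box generously scaled to the separation.
    side <- separation * max(4, k)
    centres <- matrix(NA_real_, k, d)
    placed <- 0L
    tries <- 0L
    while (placed < k) {
      cand <- stats::runif(d, 0, side)
      ok <- placed == 0L ||
        all(sqrt(colSums((t(centres[seq_len(placed), , drop = FALSE]) - cand)^2)) >= separation)
      if (ok) { placed <- placed + 1L; centres[placed, ] <- cand }
      tries <- tries + 1L
      if (tries > 10000L) { side <- side * 2; tries <- 0L }
    }
    pts <- do.call(rbind, lapply(seq_len(k), function(j) {
      matrix(stats::rnorm(sizes[j] * d, sd = spread), sizes[j], d) +
        matrix(centres[j, ], sizes[j], d, byrow = TRUE)
    }))
    colnames(pts) <- paste0("x", seq_len(d))
    out <- as_tibble(pts)
    out$.label <- rep(seq_len(k), times = sizes)
    out
  })
}

#' Seeded synthetic multi-region RGB test image
#'
#' An H x W image made of k vertical flat-colour bands drawn from a fixed
#' well-separated palette, with optional bounded integer noise. At
#' `noise = 0` the image has exactly k distinct colours, so segmenting it
#' with a matching k reproduces the input exactly.
#'
#' @inheritParams gen_random_points
#' @param height,width Raster dimensions.
#' @param k Number of regions (at most 8).
#' @param noise Maximum absolute value of the uniform integer noise added to
#'   every channel (clamped to [0, 255]); 0 for flat regions.
#' @param region_weights Optional length-k positive weights for the relative
#'   band widths (default equal).
#' @return An H x W x 3 array of integers in [0, 255].
#' @export
#' @examples
#' img <- gen_synthetic_image(90, 108, k = 4)
#' dim(img)                                  # 90 108 3
#' nrow(unique(image_to_points(img)))        # 4 distinct colours
gen_synthetic_image <- function(height, width, k, noise = 0L, seed = 1L,
                                region_weights = NULL) {
  stopifnot(height >= 1, width >= 1, k >= 1, k <= 8, height * width >= k,
            noise >= 0)
  palette <- matrix(c(
    200,  40,  40,
     40, 200,  40,
     40,  40, 200,
    220, 220,  60,
    220,  60, 220,
     60, 220, 220,
    250, 250, 250,
     30,  30,  30
  ), ncol = 3, byrow = TRUE)[seq_len(k), , drop = FALSE]
  if (is.null(region_weights)) region_weights <- rep(1 / k, k)
  stopifnot(length(region_weights) == k, all(region_weights > 0))
  cuts <- round(cumsum(region_weights / sum(region_weights)) * width)
  cuts[k] <- width
  starts <- c(1L, utils::head(cuts, -1) + 1L)
  if (any(starts > cuts)) abort("region_weights give an empty band")
  img <- array(0, dim = c(height, width, 3))
  for (j in seq_len(k)) {
    for (ch in 1:3) img[, starts[j]:cuts[j], ch] <- palette[j, ch]
  }
  if (noise > 0) {
    img <- withr::with_seed(seed, {
      img + array(sample(seq(-noise, noise), height * width * 3, replace = TRUE),
                  dim = dim(img))
    })
    img <- pmin(pmax(img, 0), 255)
  }
  img
}
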