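#' Distance metrics
#'
#' Three point-to-point metrics are supported: `"euclidean"` (root of the
#' sum of squared attribute differences), `"sqeuclidean"` (the same without
#' the root) and `"cityblock"` (sum of absolute differences). Euclidean is
#' the default everywhere; the others exist to study whether the parallel
#' speedup depends on the metric (it does not: the per-distance unit charge
#' is `d` regardless of metric).
#'
#' @param metric Metric name, one of `"euclidean"`, `"sqeuclidean"`,
#'   `"cityblock"`.
#' @return `metric_code()` returns the internal integer code.
#' @keywords internal
metric_code <- function(metric) {
  metric <- match.arg(metric, c("euclidean", "sqeuclidean", "cityblock"))
  c(euclidean = 0L, sqeuclidean = 1L, cityblock = 2L)[[metric]]
}

#' Distance between two points
#'
#' @param a,b Numeric vectors of identical length (one point each).
#' @inheritParams metric_code
#' @return A single nonnegative number; 0 when `a` and `b` coincide.
#' @export
#' @examples
#' pairwise_distance(c(0, 0), c(3, 4))              # 5
#' pairwise_distance(c(1, 2), c(4, 6), "cityblock") # 7
pairwise_distance <- function(a, b, metric = "euclidean") {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) {
    abort(sprintf("dimensionality mismatch: length(a) = %d, length(b) = %d",
                  length(a), length(b)))
  }
  metric <- match.arg(metric, c("euclidean", "sqeuclidean", "cityblock"))
  switch(metric,
    euclidean   = sqrt(sum((a - b)^2)),
    sqeuclidean = sum((a - b)^2),
    cityblock   = sum(abs(a - b))
  )
}

#' Objective cost of a medoid set
#'
#' The clustering objective: the sum over all active points of the distance
#' to the nearest medoid. Padding (inactive) records contribute nothing.
#'
#' @param data Point set: data frame, matrix or [as_pam_dataset()] object.
#' @param medoids Integer vector of distinct row indices (1-based) of the
#'   medoids.
#' @inheritParams metric_code
#' @return Nonnegative number.
#' @export
#' @examples
#' pts <- data.frame(x = c(0, 1, 2, 10, 11, 12))
#' objective_cost(pts, medoids = c(2, 5)) # 4: (1+0+1) + (1+0+1)
objective_cost <- function(data, medoids, metric = "euclidean") {
  ds <- as_pam_dataset(data)
  medoids <- validate_medoids(ds, medoids)
  cpp_objective(ds$points, ds$active, medoids, metric_code(metric))
}
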