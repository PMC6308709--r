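#' Partitioning Around Medoids clustering
#'
#' Clusters a point set into `k` groups around medoids (cluster centres that
#' are themselves data points). Initial medoids come from the greedy build
#' phase by default; the swap phase then alternates nearest-medoid
#' assignment with replacing each cluster's medoid by its most central
#' member until no medoid changes. With `pes > 1` the run is a deterministic
#' simulation of `pes` homogeneous processing elements executing the same
#' algorithm in synchronous rounds under a master-worker protocol; its
#' medoids, tags, cost and iteration count are identical to the sequential
#' run, only the operation-count ledger differs.
#'
#' @param data Point set: data frame, tibble, numeric matrix, or
#'   [as_pam_dataset()] object. One row per point.
#' @param k Number of clusters (1 <= k <= number of points).
#' @param pes Number of processing elements P (default 1).
#' @param metric Distance metric: `"euclidean"` (default), `"sqeuclidean"`,
#'   or `"cityblock"`.
#' @param init `"build"` (greedy build phase, default) or `"random"` (k
#'   distinct seeded indices).
#' @param medoids Optional integer vector of initial medoid row indices;
#'   overrides `init`.
#' @param seed Seed for random initialization (ignored for `init =
#'   "build"`). Fixed default so runs are reproducible by construction.
#' @param max_iter Swap-iteration cap; a run hitting it is flagged
#'   `converged = FALSE` rather than erroring. The objective is
#'   non-increasing across swap iterations, so the cap is a guard, not a
#'   tuning knob.
#' @param engine `"auto"` (sequential when `pes == 1`, parallel otherwise),
#'   `"sequential"`, or `"parallel"`. `engine = "parallel"` with `pes = 1`
#'   runs the full master-worker protocol on one element, including its
#'   communication charges.
#'
#' @return An object of class `pam_fit` with elements `medoid_ids` (row
#'   indices, one per cluster), `tags` (cluster of each row, `NA` for
#'   padding), `cost` (objective value), `cost_trace` (objective after each
#'   swap iteration), `swap_iterations`, `converged`, and `ledger` (tidy
#'   operation counts, see [ledger_tables()]).
#' @export
#' @examples
#' pts <- data.frame(x = c(0, 1, 2, 10, 11, 12))
#' fit <- pam_cluster(pts, k = 2)
#' fit$cost            # 4
#' tidy(fit)
#' glance(pam_cluster(pts, k = 2, pes = 2))
pam_cluster <- function(data, k, pes = 1L, metric = "euclidean",
                        init = c("build", "random"), medoids = NULL,
                        seed = 1L, max_iter = 100L,
                        engine = c("auto", "sequential", "parallel")) {
  ds <- as_pam_dataset(data)
  k <- as.integer(k)
  pes <- as.integer(pes)
  max_iter <- as.integer(max_iter)
  if (max_iter < 1L) abort("max_iter must be at least 1")
  engine <- match.arg(engine)
  init <- match.arg(init)
  if (engine == "auto") engine <- if (pes == 1L) "sequential" else "parallel"
  if (engine == "sequential" && pes != 1L) {
    abort("sequential engine requires pes = 1")
  }
  mcode <- metric_code(metric)
  if (k < 1L) abort("k must be at least 1")
  if (k > ds$n_active) {
    abort(sprintf("k = %d exceeds the number of active points (%d)", k, ds$n_active))
  }
  init_meds <- init_medoids(ds, k, mcode, init, medoids, seed, NULL)

  ledger <- new_cost_ledger()
  res <- if (engine == "sequential") {
    run_pam_core(ds, k, mcode, init_meds, max_iter, ledger)
  } else {
    run_parallel_core(ds, k, pes, mcode, init_meds, max_iter, ledger)
  }
  if (!res$converged) {
    warn(sprintf("no convergence within %d swap iterations", max_iter))
  }

  structure(
    list(medoid_ids = res$medoids, tags = res$tags, cost = res$cost,
         cost_trace = res$cost_trace, swap_iterations = res$swap_iterations,
         converged = res$converged, k = k, pes = pes, metric = metric,
         init = if (!is.null(medoids)) "given" else init, seed = seed,
         engine = engine, n = ds$n, n_active = ds$n_active, d = ds$d,
         points = ds$points, active = ds$active,
         ledger = ledger_tables(ledger)),
    class = "pam_fit"
  )
}

#' @export
print.pam_fit <- function(x, ...) {
  cat(sprintf("Partitioning Around Medoids (%s engine, P = %d)\n",
              x$engine, x$pes))
  cat(sprintf("  %d points x %d attributes, k = %d, metric = %s, init = %s\n",
              x$n_active, x$d, x$k, x$metric, x$init))
  cat(sprintf("  objective cost %.6g after %d swap iteration(s)%s\n",
              x$cost, x$swap_iterations,
              if (x$converged) "" else " [NOT CONVERGED]"))
  tot <- ledger_totals(x)
  cat(sprintf("  ledger: %s compute units, %s communication units\n",
              format(tot$compute_units, big.mark = ","),
              format(tot$comm_units, big.mark = ",")))
  cat("  medoid rows:", paste(x$medoid_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy per-cluster summary of a PAM fit
#'
#' @param x A `pam_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per cluster: `cluster`, `medoid_id` (row
#'   index of the medoid), `size`, `within_cost` (sum of member distances to
#'   the medoid), and the medoid's coordinates.
#' @method tidy pam_fit
#' @export
tidy.pam_fit <- function(x, ...) {
  coords <- as_tibble(as.data.frame(x$points[x$medoid_ids, , drop = FALSE]))
  mcode <- metric_code(x$metric)
  per <- purrr::map_dfr(seq_len(x$k), function(j) {
    members <- which(!is.na(x$tags) & x$tags == j)
    wc <- if (length(members) > 0L) {
      sum(cpp_cluster_sums(x$points, members, x$medoid_ids[j], mcode))
    } else 0
    tibble(cluster = j, medoid_id = x$medoid_ids[j],
           size = length(members), within_cost = wc)
  })
  dplyr::bind_cols(per, coords)
}

#' One-row summary of a PAM fit
#'
#' @inheritParams tidy.pam_fit
#' @return A tibble with the model dimensions, objective cost, iteration and
#'   convergence status, and ledger totals (`compute_units`, `comm_units`,
#'   `critical_path_units`).
#' @method glance pam_fit
#' @export
glance.pam_fit <- function(x, ...) {
  tot <- ledger_totals(x)
  tibble(
    n = x$n_active, d = x$d, k = x$k, pes = x$pes, metric = x$metric,
    init = x$init, engine = x$engine, cost = x$cost,
    swap_iterations = x$swap_iterations, converged = x$converged,
    compute_units = tot$compute_units, comm_units = tot$comm_units,
    critical_path_units = critical_path_units(x)
  )
}

#' Augment data with cluster assignments
#'
#' @inheritParams tidy.pam_fit
#' @param data Optional data frame to augment; defaults to the fitted
#'   points. Padding records are dropped.
#' @return The data as a tibble with `.cluster` (factor) and `.medoid`
#'   (logical) columns appended.
#' @method augment pam_fit
#' @export
augment.pam_fit <- function(x, data = NULL, ...) {
  if (is.null(data)) data <- as.data.frame(x$points)
  out <- as_tibble(data)
  stopifnot(nrow(out) == x$n)
  out$.cluster <- factor(x$tags, levels = seq_len(x$k))
  out$.medoid <- seq_len(x$n) %in% x$medoid_ids
  out[x$active, , drop = FALSE]
}

#' Scatter plot of a 2-D (or higher) PAM fit
#'
#' Plots two attribute dimensions coloured by cluster, with medoids marked.
#'
#' @param object A `pam_fit`.
#' @param dims Integer pair: which attribute columns to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pam_fit
#' @export
autoplot.pam_fit <- function(object, dims = c(1, 2), ...) {
  if (object$d < 2) dims <- c(1, 1)
  df <- augment.pam_fit(object)
  nm <- colnames(object$points)
  if (is.null(nm)) nm <- paste0("V", seq_len(object$d))
  xv <- nm[dims[1]]; yv <- nm[dims[2]]
  names(df)[seq_len(object$d)] <- nm
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[xv]], y = .data[[yv]],
                                   colour = .data$.cluster)) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::geom_point(data = df[df$.medoid, , drop = FALSE],
                        shape = 4, size = 4, stroke = 1.5, colour = "black") +
    ggplot2::labs(colour = "cluster",
                  title = sprintf("PAM fit: k = %d, cost = %.4g",
                                  object$k, object$cost)) +
    ggplot2::theme_minimal()
}
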