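#' Speedup sweep over processing-element counts
#'
#' Runs the same clustering problem at each requested P and tabulates the
#' operation-count running-time model: `n1` is the sequential running time
#' (total compute units of the single-element reference, which sends no
#' messages), `np` the parallel critical path (per-round maxima plus
#' communication), `overhead` the communication units, and
#' `speedup = n1 / np`. The P = 1 row *is* the sequential reference, so its
#' speedup is exactly 1.
#'
#' @inheritParams pam_cluster
#' @param pes Integer vector of processing-element counts to sweep
#'   (default 1, 2, 4, ..., 64).
#' @param include_build Include the build phase in `n1`/`np` (default). With
#'   `FALSE` only the swap phase (assignment + update rounds) is timed,
#'   which exposes the effect of cluster-size balance much more strongly,
#'   because the build phase's candidate scans dominate total cost and are
#'   balanced by construction.
#' @return A tibble with columns `p`, `n1`, `np`, `overhead`, `speedup`,
#'   plus `cost` and `swap_iterations` as an equivalence cross-check (they
#'   are identical across rows by construction).
#' @export
#' @examples
#' pts <- gen_random_points(120, d = 2, seed = 7)
#' speedup_sweep(pts, k = 3, pes = c(1, 2, 4, 8))
speedup_sweep <- function(data, k, pes = 2^(0:6), metric = "euclidean",
                          init = c("build", "random"), medoids = NULL,
                          seed = 1L, max_iter = 100L, include_build = TRUE) {
  init <- match.arg(init)
  phases <- if (include_build) NULL else c("assign", "update")
  seq_fit <- pam_cluster(data, k, pes = 1L, metric = metric, init = init,
                         medoids = medoids, seed = seed, max_iter = max_iter,
                         engine = "sequential")
  n1 <- ledger_totals(seq_fit, phases = phases)$compute_units
  purrr::map_dfr(sort(unique(as.integer(pes))), function(p) {
    if (p == 1L) {
      return(tibble(p = 1L, n1 = n1, np = n1, overhead = 0,
                    speedup = 1, cost = seq_fit$cost,
                    swap_iterations = seq_fit$swap_iterations))
    }
    fit <- pam_cluster(data, k, pes = p, metric = metric, init = init,
                       medoids = medoids, seed = seed, max_iter = max_iter,
                       engine = "parallel")
    np <- critical_path_units(fit, phases = phases, include_comm = TRUE)
    tibble(p = p, n1 = n1, np = np,
           overhead = ledger_totals(fit, phases = phases)$comm_units,
           speedup = speedup(n1, np), cost = fit$cost,
           swap_iterations = fit$swap_iterations)
  })
}

#' Plot a speedup sweep against the ideal linear speedup
#'
#' @param sweep A tibble from [speedup_sweep()] (optionally several row-bound
#'   sweeps distinguished by a `label` column).
#' @return A ggplot object.
#' @export
plot_speedup <- function(sweep) {
  has_label <- "label" %in% names(sweep)
  aes <- if (has_label) {
    ggplot2::aes(x = .data$p, y = .data$speedup, colour = .data$label)
  } else {
    ggplot2::aes(x = .data$p, y = .data$speedup)
  }
  ggplot2::ggplot(sweep, aes) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(trans = "log2", breaks = unique(sweep$p)) +
    ggplot2::scale_y_continuous(trans = "log2", breaks = unique(sweep$p)) +
    ggplot2::labs(x = "processing elements (P)", y = "speedup  n1 / np",
                  title = "Operation-count speedup vs ideal") +
    ggplot2::theme_minimal()
}

#' Write a speedup sweep as delimited text
#'
#' Columns `p`, `n1`, `np`, `overhead`, `speedup`.
#'
#' @inheritParams plot_speedup
#' @param path Output path (comma-separated).
#' @export
write_sweep <- function(sweep, path) {
  readr::write_csv(sweep[, c("p", "n1", "np", "overhead", "speedup")], path)
  invisible(path)
}
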