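#' Operation-count ledger
#'
#' Every clustering run carries a ledger that models the running time of the
#' *literal* pseudo-code loops, independent of how the implementation
#' vectorises or caches. The unit convention is normative across the
#' package: each pairwise distance evaluation between d-dimensional points
#' charges d scalar units; comparisons, accumulations of already-charged
#' terms, and square roots charge nothing. Communication is charged in
#' scalar units per message on a shared bus: one charge per broadcast
#' regardless of receiver count.
#'
#' @return `new_cost_ledger()` returns an empty ledger (an environment used
#'   as a mutable accumulator during a run). [ledger_tables()] converts a
#'   ledger or fitted object to tidy tibbles.
#' @keywords internal
new_cost_ledger <- function() {
  led <- new.env(parent = emptyenv())
  led$compute <- list()
  led$messages <- list()
  class(led) <- "pam_ledger"
  led
}

ledger_add_compute <- function(led, phase, iteration, pe, units) {
  if (is.null(led)) return(invisible(NULL))
  led$compute[[length(led$compute) + 1L]] <-
    list(phase = phase, iteration = as.integer(iteration),
         pe = as.integer(pe), units = as.numeric(units))
  invisible(NULL)
}

ledger_add_message <- function(led, phase, iteration, sender, kind, units) {
  if (is.null(led)) return(invisible(NULL))
  led$messages[[length(led$messages) + 1L]] <-
    list(phase = phase, iteration = as.integer(iteration),
         sender = as.integer(sender), kind = kind, units = as.numeric(units))
  invisible(NULL)
}

#' Tidy view of a run's operation counts
#'
#' @param x A `pam_fit`, `pam_ledger`, or the `ledger` element of a fit.
#' @return A list with two tibbles: `compute` (one row per processing
#'   element per synchronous round, columns `phase`, `iteration`, `pe`,
#'   `units`) and `messages` (one row per message, columns `phase`,
#'   `iteration`, `sender`, `kind`, `units`).
#' @export
ledger_tables <- function(x) {
  if (inherits(x, "pam_fit")) return(x$ledger)
  if (inherits(x, "pam_ledger")) {
    to_tbl <- function(rows, proto) {
      if (length(rows) == 0L) return(proto)
      dplyr::bind_rows(lapply(rows, as_tibble))
    }
    compute_proto <- tibble(phase = character(), iteration = integer(),
                            pe = integer(), units = numeric())
    msg_proto <- tibble(phase = character(), iteration = integer(),
                        sender = integer(), kind = character(),
                        units = numeric())
    return(list(compute = to_tbl(x$compute, compute_proto),
                messages = to_tbl(x$messages, msg_proto)))
  }
  if (is.list(x) && all(c("compute", "messages") %in% names(x))) return(x)
  abort("cannot extract a ledger from this object")
}

#' Total compute and communication units of a run
#'
#' @inheritParams ledger_tables
#' @param phases Optional character vector restricting the total to a subset
#'   of phases (`"build"`, `"assign"`, `"update"`).
#' @return One-row tibble with `compute_units` (summed over all processing
#'   elements) and `comm_units`.
#' @export
ledger_totals <- function(x, phases = NULL) {
  lt <- ledger_tables(x)
  comp <- lt$compute
  msgs <- lt$messages
  if (!is.null(phases)) {
    comp <- dplyr::filter(comp, .data$phase %in% phases)
    msgs <- dplyr::filter(msgs, .data$phase %in% phases)
  }
  tibble(compute_units = sum(comp$units), comm_units = sum(msgs$units))
}

#' Critical-path running time of a parallel run
#'
#' The model of parallel running time: within each synchronous round the
#' slowest processing element gates progress, so the critical path is the
#' sum over rounds of the per-round maximum compute units, plus (optionally)
#' all communication units on the shared interconnect.
#'
#' @inheritParams ledger_totals
#' @param include_comm Add total communication units (default `TRUE`).
#' @return A single number of scalar units.
#' @export
#' @examples
#' # A balanced 2-PE round of 100 units each contributes 100;
#' # an imbalanced round (70, 30) contributes 70.
critical_path_units <- function(x, phases = NULL, include_comm = TRUE) {
  lt <- ledger_tables(x)
  comp <- lt$compute
  msgs <- lt$messages
  if (nrow(comp) == 0L) abort("ledger has no compute records")
  if (!is.null(phases)) {
    comp <- dplyr::filter(comp, .data$phase %in% phases)
    msgs <- dplyr::filter(msgs, .data$phase %in% phases)
  }
  per_round <- dplyr::summarise(
    dplyr::group_by(comp, .data$phase, .data$iteration),
    round_units = max(.data$units), .groups = "drop"
  )
  np <- sum(per_round$round_units)
  if (include_comm) np <- np + sum(msgs$units)
  np
}

#' Speedup of a parallel run over the sequential reference
#'
#' @param n1 Sequential running time in scalar units.
#' @param np Parallel critical-path running time in scalar units.
#' @return `n1 / np`.
#' @export
#' @examples
#' speedup(100, 50) # 2
speedup <- function(n1, np) {
  stopifnot(is.numeric(n1), is.numeric(np))
  if (any(np <= 0)) abort("np must be positive")
  n1 / np
}

#' Closed-form build-phase compute units
#'
#' The greedy build phase in round k scores each of the N-k+1 remaining
#' candidates against all N points and the k medoids available during the
#' scan, so a literal execution evaluates (N-k+1) * N * k distances in round
#' k, each charging d scalar units.
#'
#' @param n Number of (active) points.
#' @param k Number of medoids to select.
#' @param d Point dimensionality.
#' @return Integer-valued double: `d * sum_k (n-k+1) * n * k`.
#' @export
#' @examples
#' expected_build_units(6, 2, 1)    # 96
#' expected_build_units(800, 4, 2)  # 12768000
expected_build_units <- function(n, k, d) {
  stopifnot(k >= 1, k <= n, d >= 1)
  ks <- seq_len(k)
  d * sum((n - ks + 1) * n * ks)
}

#' Write a run's ledger as delimited text
#'
#' One row per (processing element, phase, iteration) with compute units,
#' plus one row per message; the `record` column distinguishes the two.
#'
#' @inheritParams ledger_tables
#' @param path Output file path (tab-separated).
#' @export
write_ledger <- function(x, path) {
  lt <- ledger_tables(x)
  comp <- dplyr::mutate(lt$compute, record = "compute", sender = NA_integer_,
                        kind = NA_character_)
  msgs <- dplyr::mutate(lt$messages, record = "message", pe = NA_integer_)
  cols <- c("record", "phase", "iteration", "pe", "sender", "kind", "units")
  out <- dplyr::bind_rows(comp[, cols], msgs[, cols])
  readr::write_tsv(out, path)
  invisible(path)
}
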