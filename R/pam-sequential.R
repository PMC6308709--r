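#' Greedy build-phase initialization
#'
#' Selects K initial medoids one at a time. In round k every active
#' non-medoid point is tried as a temporary medoid; its score is the
#' objective cost of the k-1 already-chosen medoids plus the candidate, and
#' the candidate with the minimum score (ties to the lowest row index)
#' becomes medoid k. The first medoid is therefore the most centrally
#' located point of the whole set.
#'
#' @inheritParams objective_cost
#' @param k Number of medoids to select (1 <= k <= number of active points).
#' @param ledger Optional internal cost ledger (used by [pam_cluster()]).
#' @return Integer vector of k medoid row indices, in selection order.
#' @export
#' @examples
#' pts <- data.frame(x = c(0, 1, 2, 10, 11, 12))
#' build_phase(pts, k = 2) # rows 3 and 5 (values 2 and 11)
build_phase <- function(data, k, metric = "euclidean", ledger = NULL) {
  ds <- as_pam_dataset(data)
  build_phase_core(ds, k, metric_code(metric), ledger)
}

build_phase_core <- function(ds, k, mcode, ledger = NULL) {
  k <- as.integer(k)
  if (k < 1L) abort("k must be at least 1")
  if (k > ds$n_active) {
    abort(sprintf("k = %d exceeds the number of active points (%d)", k, ds$n_active))
  }
  act <- which(ds$active)
  chosen <- integer(0)
  dmin <- rep(Inf, ds$n)
  for (ki in seq_len(k)) {
    cand <- setdiff(act, chosen)           # ascending: which.min = lowest index
    scores <- cpp_build_scores(ds$points, ds$active, cand, dmin, mcode)
    best <- cand[which.min(scores)]
    chosen <- c(chosen, best)
    dmin <- pmin(dmin, cpp_dists_to_point(ds$points, best, mcode))
    ledger_add_compute(ledger, "build", ki, 1L,
                       (ds$n_active - ki + 1) * ds$n_active * ki * ds$d)
  }
  chosen
}

#' Nearest-medoid cluster assignment
#'
#' Tags every active point with the 1-based position of its nearest medoid
#' in `medoids`; ties break to the lowest position. Padding records get
#' `NA`.
#'
#' @inheritParams build_phase
#' @param medoids Integer vector of medoid row indices.
#' @return Integer vector of tags in `1..length(medoids)` (NA for padding).
#' @export
#' @examples
#' pts <- data.frame(x = c(0, 1, 2, 10, 11, 12))
#' assign_clusters(pts, medoids = c(3, 5)) # 1 1 1 2 2 2
assign_clusters <- function(data, medoids, metric = "euclidean", ledger = NULL) {
  ds <- as_pam_dataset(data)
  medoids <- validate_medoids(ds, medoids)
  assign_core(ds, medoids, metric_code(metric), ledger, iteration = 1L)
}

assign_core <- function(ds, medoids, mcode, ledger = NULL, iteration = 1L) {
  act <- which(ds$active)
  tags <- rep(NA_integer_, ds$n)
  tags[act] <- cpp_assign(ds$points, act, medoids, mcode)
  ledger_add_compute(ledger, "assign", iteration, 1L,
                     ds$n_active * length(medoids) * ds$d)
  tags
}

#' Swap-phase medoid update
#'
#' For each cluster j, the member minimizing the sum of distances to all
#' members of j (self-distance included, contributing 0) becomes the new
#' medoid of j; ties break to the lowest row index. A cluster with no
#' members keeps its current medoid.
#'
#' @inheritParams assign_clusters
#' @param tags Integer cluster tags as produced by [assign_clusters()].
#' @param current Current medoid row indices (one per cluster).
#' @return Integer vector of updated medoid indices, one per cluster.
#' @export
update_medoids <- function(data, tags, current, metric = "euclidean",
                           ledger = NULL) {
  ds <- as_pam_dataset(data)
  current <- validate_medoids(ds, current)
  stopifnot(length(tags) == ds$n)
  update_core(ds, as.integer(tags), current, metric_code(metric), ledger,
              iteration = 1L)
}

update_core <- function(ds, tags, current, mcode, ledger = NULL,
                        iteration = 1L) {
  k <- length(current)
  new_meds <- current
  units <- 0
  for (j in seq_len(k)) {
    members <- which(!is.na(tags) & tags == j)  # ascending row order
    if (length(members) == 0L) next
    sums <- cpp_cluster_sums(ds$points, members, members, mcode)
    new_meds[j] <- members[which.min(sums)]
    units <- units + length(members)^2 * ds$d
  }
  ledger_add_compute(ledger, "update", iteration, 1L, units)
  new_meds
}

# Shared initialization for the sequential and parallel engines. Random
# initialization draws k distinct active indices with a seeded generator,
# leaving the caller's RNG state untouched.
init_medoids <- function(ds, k, mcode, init, medoids, seed, ledger) {
  if (!is.null(medoids)) return(validate_medoids(ds, medoids))
  init <- match.arg(init, c("build", "random"))
  if (init == "random") {
    k <- as.integer(k)
    if (k < 1L || k > ds$n_active) abort("k out of range for random init")
    act <- which(ds$active)
    return(withr::with_seed(seed, sort(sample(act, k))))
  }
  NULL  # build: engine-specific (ledger differs between engines)
}

run_pam_core <- function(ds, k, mcode, init_meds, max_iter, ledger) {
  meds <- if (is.null(init_meds)) build_phase_core(ds, k, mcode, ledger) else init_meds
  cost_trace <- numeric(0)
  converged <- FALSE
  tags <- NULL
  iter <- 0L
  for (t in seq_len(max_iter)) {
    iter <- t
    tags <- assign_core(ds, meds, mcode, ledger, iteration = t)
    new_meds <- update_core(ds, tags, meds, mcode, ledger, iteration = t)
    cost_trace[t] <- cpp_objective(ds$points, ds$active, new_meds, mcode)
    if (identical(new_meds, meds)) { converged <- TRUE; break }
    meds <- new_meds
  }
  if (!converged) tags <- assign_core(ds, meds, mcode, NULL, iteration = iter)
  list(medoids = meds, tags = tags,
       cost = cpp_objective(ds$points, ds$active, meds, mcode),
       cost_trace = cost_trace, swap_iterations = iter, converged = converged)
}
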