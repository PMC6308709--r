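#' Partition a dataset across processing elements
#'
#' The dataset is padded to the smallest length divisible by the number of
#' processing elements P by appending inactive records, then split into P
#' contiguous equal blocks in input order. Padding records are
#' computationally inert: they are never medoid candidates and contribute
#' nothing to any distance sum.
#'
#' @param n Number of (real) records.
#' @param p Number of processing elements; must not exceed `n`, otherwise
#'   some element would hold only padding.
#' @return An object of class `pam_partition`: list with `p`, `n`,
#'   `padded_n`, `padded_count`, `block_size`, and `blocks` (list of index
#'   vectors into the padded sequence).
#' @export
#' @examples
#' partition_data(10, 4) # blocks of 3, padded_count 2
partition_data <- function(n, p) {
  n <- as.integer(n); p <- as.integer(p)
  if (n < 1L) abort("n must be at least 1")
  if (p < 1L) abort("p must be at least 1")
  if (p > n) abort(sprintf("p = %d exceeds n = %d: a processing element would hold only padding", p, n))
  padded_n <- as.integer(ceiling(n / p) * p)
  block_size <- padded_n %/% p
  blocks <- lapply(seq_len(p), function(i) ((i - 1L) * block_size + 1L):(i * block_size))
  structure(list(p = p, n = n, padded_n = padded_n,
                 padded_count = padded_n - n, block_size = block_size,
                 blocks = blocks),
            class = "pam_partition")
}

#' @export
print.pam_partition <- function(x, ...) {
  cat(sprintf("<pam_partition> %d records across %d PEs (block size %d, %d padding)\n",
              x$n, x$p, x$block_size, x$padded_count))
  invisible(x)
}

# Pad a dataset with inactive zero records so its length matches the plan.
pad_dataset <- function(ds, plan) {
  if (plan$padded_count == 0L) return(ds)
  pad <- matrix(0, plan$padded_count, ds$d)
  as_pam_dataset(rbind(ds$points, pad),
                 active = c(ds$active, rep(FALSE, plan$padded_count)))
}

# One PE's build-phase scan: score the eligible candidates (active,
# non-medoid) of its block against all N active points given the medoids
# chosen so far. Returns the PE-local argmin or an empty marker.
pe_build_scan <- function(pe, plan, ds, chosen, dmin, mcode, round_k, ledger) {
  cand <- plan$blocks[[pe]]
  cand <- cand[ds$active[cand]]
  cand <- setdiff(cand, chosen)            # ascending within the block
  ledger_add_compute(ledger, "build", round_k, pe,
                     length(cand) * ds$n_active * round_k * ds$d)
  ledger_add_message(ledger, "build", round_k, pe, "candidate_score", 2)
  if (length(cand) == 0L) return(list(index = NA_integer_, sum = Inf))
  scores <- cpp_build_scores(ds$points, ds$active, cand, dmin, mcode)
  w <- which.min(scores)
  list(index = cand[w], sum = scores[w])
}

# Master aggregation of per-PE build results: global argmin of the sums,
# ties to the lowest point index. Master comparisons charge nothing.
master_select_medoid <- function(results) {
  sums <- vapply(results, `[[`, numeric(1), "sum")
  idxs <- vapply(results, `[[`, integer(1), "index")
  ok <- !is.na(idxs)
  if (!any(ok)) abort("no processing element produced a candidate")
  sums <- sums[ok]; idxs <- idxs[ok]
  best <- which(sums == min(sums))
  idxs[best[which.min(idxs[best])]]
}

# One swap iteration's assignment + tag exchange: each PE tags its block,
# then broadcasts its block's tags so every PE holds the full clustering.
pe_assign_and_exchange <- function(plan, ds, medoids, mcode, iteration, ledger) {
  tags <- rep(NA_integer_, ds$n)
  for (pe in seq_len(plan$p)) {
    rows <- plan$blocks[[pe]]
    rows_act <- rows[ds$active[rows]]
    if (length(rows_act) > 0L) {
      tags[rows_act] <- cpp_assign(ds$points, rows_act, medoids, mcode)
    }
    ledger_add_compute(ledger, "assign", iteration, pe,
                       length(rows_act) * length(medoids) * ds$d)
    ledger_add_message(ledger, "assign", iteration, pe, "tag_block",
                       plan$block_size)
  }
  tags
}

# One swap iteration's medoid update: each PE scores its block's members of
# every cluster against all of that cluster's members; the master takes the
# global per-cluster argmin (ties to the lowest index) and keeps the old
# medoid for empty clusters, then broadcasts the K updated medoids.
pe_swap_scan_and_update <- function(plan, ds, tags, current, mcode,
                                    iteration, ledger) {
  k <- length(current)
  members_by_cluster <- lapply(seq_len(k), function(j) which(!is.na(tags) & tags == j))
  best_sum <- rep(Inf, k)
  best_idx <- rep(NA_integer_, k)
  for (pe in seq_len(plan$p)) {
    rows <- plan$blocks[[pe]]
    units <- 0
    for (j in seq_len(k)) {
      members <- members_by_cluster[[j]]
      local <- members[members %in% rows]   # ascending global order preserved
      ledger_add_message(ledger, "update", iteration, pe, "medoid_update", 2)
      if (length(local) == 0L) next
      units <- units + length(local) * length(members) * ds$d
      sums <- cpp_cluster_sums(ds$points, members, local, mcode)
      w <- which.min(sums)
      s <- sums[w]; i <- local[w]
      if (s < best_sum[j] || (s == best_sum[j] && i < best_idx[j])) {
        best_sum[j] <- s
        best_idx[j] <- i
      }
    }
    ledger_add_compute(ledger, "update", iteration, pe, units)
  }
  ledger_add_message(ledger, "update", iteration, 1L, "medoid_broadcast",
                     k * (1 + ds$d))
  new_meds <- current
  upd <- !is.na(best_idx)
  new_meds[upd] <- best_idx[upd]
  new_meds
}

run_parallel_core <- function(ds, k, p, mcode, init_meds, max_iter, ledger) {
  plan <- partition_data(ds$n, p)
  ds <- pad_dataset(ds, plan)
  if (is.null(init_meds)) {
    chosen <- integer(0)
    dmin <- rep(Inf, ds$n)
    for (ki in seq_len(k)) {
      results <- lapply(seq_len(plan$p), function(pe) {
        pe_build_scan(pe, plan, ds, chosen, dmin, mcode, ki, ledger)
      })
      best <- master_select_medoid(results)
      chosen <- c(chosen, best)
      dmin <- pmin(dmin, cpp_dists_to_point(ds$points, best, mcode))
      ledger_add_message(ledger, "build", ki, 1L, "medoid_broadcast", 1 + ds$d)
    }
    meds <- chosen
  } else {
    meds <- init_meds
  }
  cost_trace <- numeric(0)
  converged <- FALSE
  tags <- NULL
  iter <- 0L
  for (t in seq_len(max_iter)) {
    iter <- t
    tags <- pe_assign_and_exchange(plan, ds, meds, mcode, t, ledger)
    new_meds <- pe_swap_scan_and_update(plan, ds, tags, meds, mcode, t, ledger)
    cost_trace[t] <- cpp_objective(ds$points, ds$active, new_meds, mcode)
    if (identical(new_meds, meds)) { converged <- TRUE; break }
    meds <- new_meds
  }
  if (!converged) tags <- pe_assign_and_exchange(plan, ds, meds, mcode, iter, NULL)
  list(medoids = meds, tags = tags[seq_len(plan$n)],
       cost = cpp_objective(ds$points, ds$active, meds, mcode),
       cost_trace = cost_trace, swap_iterations = iter, converged = converged,
       partition = plan)
}
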