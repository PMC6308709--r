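# Independent brute-force oracles. These deliberately avoid every code path
# of the package kernels: plain double loops over rows built on
# pairwise_distance() only, so agreement is a genuine cross-check.

oracle_cost <- function(pts, medoids, metric = "euclidean") {
  pts <- as.matrix(pts)
  total <- 0
  for (i in seq_len(nrow(pts))) {
    best <- Inf
    for (m in medoids) {
      dd <- pairwise_distance(pts[i, ], pts[m, ], metric)
      if (dd < best) best <- dd
    }
    total <- total + best
  }
  total
}

# Exhaustive greedy build: at each round score every remaining candidate by
# the objective of chosen + candidate, lowest index on ties.
oracle_build <- function(pts, k, metric = "euclidean") {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  chosen <- integer(0)
  for (round in seq_len(k)) {
    cand <- setdiff(seq_len(n), chosen)
    scores <- vapply(cand, function(a) oracle_cost(pts, c(chosen, a), metric),
                     numeric(1))
    chosen <- c(chosen, cand[which.min(scores)])
  }
  chosen
}

oracle_assign <- function(pts, medoids, metric = "euclidean") {
  pts <- as.matrix(pts)
  vapply(seq_len(nrow(pts)), function(i) {
    dd <- vapply(medoids, function(m) pairwise_distance(pts[i, ], pts[m, ], metric),
                 numeric(1))
    which.min(dd)
  }, integer(1))
}

oracle_update <- function(pts, tags, current, metric = "euclidean") {
  pts <- as.matrix(pts)
  out <- as.integer(current)
  for (j in seq_along(current)) {
    members <- which(tags == j)
    if (length(members) == 0L) next
    sums <- vapply(members, function(a) {
      sum(vapply(members, function(i) pairwise_distance(pts[a, ], pts[i, ], metric),
                 numeric(1)))
    }, numeric(1))
    out[j] <- members[which.min(sums)]
  }
  out
}

# Global optimum over all k-subsets of rows as medoid sets (tiny n only).
oracle_best_cost <- function(pts, k, metric = "euclidean") {
  sets <- utils::combn(nrow(as.matrix(pts)), k)
  min(apply(sets, 2, function(m) oracle_cost(pts, m, metric)))
}

# The six-point 1-D worked example used throughout.
line6 <- function() data.frame(x = c(0, 1, 2, 10, 11, 12))
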