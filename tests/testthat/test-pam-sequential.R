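test_that("build phase reproduces the hand-traced 1-D example", {
  pts <- line6()
  # candidate scores round 1: 36 32 30 30 32 36 -> tie between rows 3 and 4,
  # lowest index wins (value 2)
  expect_identical(build_phase(pts, k = 1), 3L)
  m2 <- build_phase(pts, k = 2)
  expect_identical(m2, c(3L, 5L))  # values 2 and 11; second-round cost 5
  expect_equal(objective_cost(pts, m2), 5)
  # k = n: every point ends up a medoid
  expect_identical(sort(build_phase(pts, k = 6)), 1:6)
  expect_error(build_phase(pts, k = 0), "at least 1")
  expect_error(build_phase(pts, k = 7), "exceeds")
})

test_that("build phase matches the exhaustive greedy oracle on small random sets", {
  set.seed(11)
  for (rep in 1:15) {
    n <- sample(4:12, 1)
    d <- sample(1:3, 1)
    k <- sample.int(min(n, 4), 1)
    metric <- sample(c("euclidean", "cityblock"), 1)
    pts <- matrix(round(rnorm(n * d), 2), n, d)  # rounding provokes ties
    expect_identical(build_phase(pts, k, metric), oracle_build(pts, k, metric))
  }
})

test_that("assignment tags by nearest medoid with lowest-position tie-break", {
  pts <- line6()
  expect_identical(assign_clusters(pts, c(3, 5)), c(1L, 1L, 1L, 2L, 2L, 2L))
  # the value 6 is equidistant to medoids 2 and 10 -> tag 1
  pts2 <- data.frame(x = c(2, 6, 10))
  expect_identical(assign_clusters(pts2, c(1, 3)), c(1L, 1L, 2L))
  expect_identical(assign_clusters(pts, 4), rep(1L, 6))  # k = 1
  set.seed(3)
  pts3 <- matrix(rnorm(60), 30, 2)
  meds <- c(4, 17, 25)
  expect_identical(assign_clusters(pts3, meds), oracle_assign(pts3, meds))
})

test_that("medoid update picks the most central member per cluster", {
  pts <- line6()
  tags <- c(1L, 1L, 1L, 2L, 2L, 2L)
  # cluster {0,1,2}: sums 3,2,3 -> value 1; cluster {10,11,12}: -> value 11
  expect_identical(update_medoids(pts, tags, current = c(3, 5)), c(2L, 5L))
  # singleton cluster keeps its only member
  tags2 <- c(1L, 1L, 1L, 1L, 1L, 2L)
  expect_identical(update_medoids(pts, tags2, current = c(2, 6))[2], 6L)
  # empty cluster keeps the current medoid
  tags3 <- rep(1L, 6)
  expect_identical(update_medoids(pts, tags3, current = c(2, 5))[2], 5L)
  set.seed(5)
  pts4 <- matrix(rnorm(80), 40, 2)
  meds <- c(1, 20)
  tg <- assign_clusters(pts4, meds)
  expect_identical(update_medoids(pts4, tg, meds), oracle_update(pts4, tg, meds))
})

test_that("full PAM run converges to the hand-traced and exhaustive optimum", {
  pts <- line6()
  fit <- pam_cluster(pts, k = 2)
  expect_identical(sort(fit$medoid_ids), c(2L, 5L))  # values 1 and 11
  expect_equal(fit$cost, 4)
  expect_identical(fit$swap_iterations, 2L)
  expect_true(fit$converged)
  # equals the exhaustive minimum over all C(6,2) = 15 medoid pairs
  expect_equal(fit$cost, oracle_best_cost(pts, 2))
  # k = n: zero cost in one confirming iteration
  fit_n <- pam_cluster(pts, k = 6)
  expect_equal(fit_n$cost, 0)
  expect_identical(fit_n$swap_iterations, 1L)
})

test_that("objective cost is non-increasing across swap iterations", {
  for (s in 1:8) {
    pts <- gen_random_points(60, d = 2, seed = s)
    fit <- pam_cluster(pts, k = 4, init = "random", seed = s)
    expect_true(all(diff(fit$cost_trace) <= 1e-12))
    expect_true(fit$converged)
  }
})

test_that("converged medoids are within-cluster optimal by brute force", {
  for (s in 1:5) {
    pts <- as.matrix(gen_random_points(40, d = 2, seed = 100 + s))
    fit <- pam_cluster(pts, k = 3)
    for (j in seq_len(3)) {
      members <- which(fit$tags == j)
      sums <- vapply(members, function(a) {
        sum(vapply(members, function(i) pairwise_distance(pts[a, ], pts[i, ]),
                   numeric(1)))
      }, numeric(1))
      med_sum <- sums[match(fit$medoid_ids[j], members)]
      expect_true(all(sums >= med_sum - 1e-9))
    }
  }
})

test_that("results are invariant to padding records and to metric scaling", {
  pts <- as.matrix(gen_random_points(30, d = 2, seed = 9))
  fit <- pam_cluster(pts, k = 3)
  padded <- as_pam_dataset(rbind(pts, matrix(0, 4, 2)),
                           active = c(rep(TRUE, 30), rep(FALSE, 4)))
  fit_pad <- pam_cluster(padded, k = 3)
  expect_identical(fit_pad$medoid_ids, fit$medoid_ids)
  expect_identical(fit_pad$tags[1:30], fit$tags)
  expect_true(all(is.na(fit_pad$tags[31:34])))
  expect_equal(fit_pad$cost, fit$cost)
  for (m in c("euclidean", "cityblock")) {
    f1 <- pam_cluster(pts, k = 3, metric = m)
    f2 <- pam_cluster(pts * 7.5, k = 3, metric = m)
    expect_identical(f2$medoid_ids, f1$medoid_ids)
    expect_identical(f2$tags, f1$tags)
  }
})

test_that("random initialization is seeded and reproducible", {
  pts <- gen_random_points(50, d = 2, seed = 1)
  f1 <- pam_cluster(pts, k = 3, init = "random", seed = 77)
  f2 <- pam_cluster(pts, k = 3, init = "random", seed = 77)
  expect_identical(f1$medoid_ids, f2$medoid_ids)
  expect_identical(f1$cost, f2$cost)
  # a caller-supplied medoid set is honoured as the starting point
  f3 <- pam_cluster(line6(), k = 2, medoids = c(1, 6))
  expect_identical(sort(f3$medoid_ids), c(2L, 5L))
  expect_identical(f3$init, "given")
})

test_that("broom methods return tidy per-cluster and per-fit summaries", {
  pts <- gen_gaussian_clusters(60, k = 3, seed = 4)
  fit <- pam_cluster(dplyr::select(pts, -".label"), k = 3)
  td <- tidy(fit)
  expect_identical(nrow(td), 3L)
  expect_identical(sum(td$size), 60L)
  expect_equal(sum(td$within_cost), fit$cost)
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$compute_units, ledger_totals(fit)$compute_units)
  ag <- augment(fit)
  expect_identical(nrow(ag), 60L)
  expect_identical(sum(ag$.medoid), 3L)
  expect_s3_class(autoplot(fit), "ggplot")
})
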