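test_that("partition_data pads to equal contiguous blocks", {
  p1 <- partition_data(6, 2)
  expect_identical(p1$blocks, list(1:3, 4:6))
  expect_identical(p1$padded_count, 0L)
  p2 <- partition_data(10, 4)
  expect_identical(p2$padded_n, 12L)
  expect_identical(p2$block_size, 3L)
  expect_identical(p2$padded_count, 2L)
  expect_identical(unlist(p2$blocks), 1:12)
  p3 <- partition_data(5, 1)
  expect_identical(p3$blocks, list(1:5))
  expect_error(partition_data(4, 5), "padding")
})

test_that("per-element build scan reproduces the sequential round argmin", {
  ds <- as_pam_dataset(line6())
  plan <- partition_data(6, 2)
  dmin <- rep(Inf, 6)
  r0 <- parapam:::pe_build_scan(1, plan, ds, integer(0), dmin, 0L, 1L, NULL)
  expect_identical(r0$index, 3L)   # block values 0,1,2: scores 36,32,30
  expect_equal(r0$sum, 30)
  r1 <- parapam:::pe_build_scan(2, plan, ds, integer(0), dmin, 0L, 1L, NULL)
  expect_identical(r1$index, 4L)   # block values 10,11,12: scores 30,32,36
  expect_equal(r1$sum, 30)
  # master: tie on the sums -> lowest point index, as in the sequential build
  expect_identical(parapam:::master_select_medoid(list(r0, r1)), 3L)
  expect_identical(parapam:::master_select_medoid(list(r1)), 4L)
  expect_identical(parapam:::master_select_medoid(
    list(list(index = 6L, sum = 12), list(index = 10L, sum = 11.5))), 10L)
  expect_error(parapam:::master_select_medoid(
    list(list(index = NA_integer_, sum = Inf))), "no processing element")
  # degenerate partition: identical to the sequential argmin
  plan1 <- partition_data(6, 1)
  rs <- parapam:::pe_build_scan(1, plan1, ds, integer(0), dmin, 0L, 1L, NULL)
  expect_identical(rs$index, build_phase(line6(), 1)[1])
})

test_that("parallel output is identical to sequential for every P (equivalence contract)", {
  pts <- line6()
  fit_seq <- pam_cluster(pts, k = 2)
  for (p in c(1, 2, 3, 6)) {
    fp <- pam_cluster(pts, k = 2, pes = p, engine = "parallel")
    expect_identical(fp$medoid_ids, fit_seq$medoid_ids)
    expect_identical(fp$tags, fit_seq$tags)
    expect_identical(fp$cost, fit_seq$cost)
    expect_identical(fp$swap_iterations, fit_seq$swap_iterations)
  }
  # 100+ seeded random instances across metrics, inits, and non-dividing P
  set.seed(202)
  cases <- expand.grid(seed = 1:26, p = c(2, 3, 5, 8), stringsAsFactors = FALSE)
  cases$metric <- rep(c("euclidean", "sqeuclidean", "cityblock"), length.out = nrow(cases))
  cases$init <- rep(c("build", "random"), length.out = nrow(cases))
  for (r in seq_len(nrow(cases))) {
    cs <- cases[r, ]
    pts <- gen_random_points(sample(20:45, 1), d = 2, seed = cs$seed)
    k <- sample(2:4, 1)
    f1 <- pam_cluster(pts, k, metric = cs$metric, init = cs$init, seed = cs$seed)
    f2 <- pam_cluster(pts, k, pes = cs$p, metric = cs$metric, init = cs$init,
                      seed = cs$seed)
    expect_identical(f2$medoid_ids, f1$medoid_ids)
    expect_identical(f2$tags, f1$tags)
    expect_identical(f2$cost, f1$cost)
    expect_identical(f2$swap_iterations, f1$swap_iterations)
  }
})

test_that("results at N = 400 are identical across the full PE range", {
  pts <- gen_random_points(400, d = 2, seed = 7)
  fits <- lapply(c(1, 2, 4, 8, 16, 32, 64), function(p) {
    pam_cluster(pts, k = 4, pes = p, engine = "parallel")
  })
  for (f in fits[-1]) {
    expect_identical(f$medoid_ids, fits[[1]]$medoid_ids)
    expect_identical(f$tags, fits[[1]]$tags)
    expect_identical(f$cost, fits[[1]]$cost)
  }
})

test_that("tag exchange yields sequential tags and charges the protocol's units", {
  pts <- line6()
  for (p in c(1, 2, 3)) {
    fit <- pam_cluster(pts, k = 2, pes = p, engine = "parallel", medoids = c(3, 5))
    msgs <- ledger_tables(fit)$messages
    tag_units <- sum(msgs$units[msgs$kind == "tag_block" & msgs$iteration == 1])
    expect_equal(tag_units, 6)  # N units per swap iteration, any dividing P
  }
})

test_that("build-phase compute units are conserved across processing elements", {
  pts <- gen_random_points(48, d = 3, seed = 13)
  f1 <- pam_cluster(pts, k = 3)
  seq_build <- sum(dplyr::filter(ledger_tables(f1)$compute, phase == "build")$units)
  expect_equal(seq_build, expected_build_units(48, 3, 3))
  for (p in c(2, 4, 6, 8)) {
    fp <- pam_cluster(pts, k = 3, pes = p)
    par_build <- sum(dplyr::filter(ledger_tables(fp)$compute, phase == "build")$units)
    expect_equal(par_build, seq_build)
  }
})

test_that("P = 1 parallel run has sequential compute plus protocol communication", {
  pts <- gen_random_points(40, d = 2, seed = 21)
  fs <- pam_cluster(pts, k = 3)
  fp <- pam_cluster(pts, k = 3, pes = 1, engine = "parallel")
  n1 <- ledger_totals(fs)$compute_units
  expect_equal(ledger_totals(fp)$compute_units, n1)
  comm <- ledger_totals(fp)$comm_units
  expect_gt(comm, 0)
  expect_equal(critical_path_units(fp), n1 + comm)
})

test_that("communication per swap iteration is exactly N + 2KP + K(1+d)", {
  n <- 60; k <- 3; d <- 2
  pts <- gen_random_points(n, d = d, seed = 31)
  for (p in c(2, 4, 6)) {
    fit <- pam_cluster(pts, k = k, pes = p)
    msgs <- ledger_tables(fit)$messages
    for (it in seq_len(fit$swap_iterations)) {
      swap_units <- sum(msgs$units[msgs$phase %in% c("assign", "update") &
                                     msgs$iteration == it])
      expect_equal(swap_units, n + 2 * k * p + k * (1 + d))
    }
  }
})

test_that("per-round build balance: max-PE units equal sequential/P for dividing P", {
  n <- 48; k <- 3; d <- 2
  pts <- gen_random_points(n, d = d, seed = 41)
  for (p in c(2, 4)) {
    fit <- pam_cluster(pts, k = k, pes = p)
    comp <- dplyr::filter(ledger_tables(fit)$compute, phase == "build")
    for (round_k in seq_len(k)) {
      per_pe <- comp$units[comp$iteration == round_k]
      seq_round <- (n - round_k + 1) * n * round_k * d
      # candidate-exclusion asymmetry: at most k-1 medoids missing per block
      expect_lte(max(per_pe), (n / p) * n * round_k * d)
      expect_gte(max(per_pe), seq_round / p - (round_k - 1) * n * round_k * d)
    }
  }
})
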