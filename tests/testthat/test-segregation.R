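test_that("single-molecule occupancy lands in the expected half-open cell", {
  box <- simulation_box(10)
  part <- partition_spec(8, c(2, 2, 2))
  cfg <- molecular_configuration("water", box,
                                 points = matrix(c(0.1, 0.1, 0.1), 1))
  oc <- count_occupancy(cfg, part)
  expect_equal(oc$water, c(1L, rep(0L, 7)))
  expect_equal(sum(oc$alcohol), 0L)
  # a coordinate exactly on the upper face wraps into cell 0
  cfg2 <- molecular_configuration("water", box,
                                  points = matrix(c(10, 5.0, 9.999999), 1))
  oc2 <- count_occupancy(cfg2, part)
  expect_equal(sum(oc2$water), 1L)
})

test_that("an alcohol straddling a cell face is counted once per occupied cell", {
  box <- simulation_box(10)
  part <- partition_spec(8, c(2, 2, 2))
  atoms <- data.frame(
    element = c("C", "C", "C", "O", "H"),
    x = c(4.2, 5.8, 4.5, 4.0, 3.6),  # carbons on both sides of x = 5
    y = c(2, 2, 2.5, 1.5, 1.2),
    z = c(2, 2, 2, 2, 2),
    mol = 1L)
  cfg <- molecular_configuration("alcohol", box, atoms = atoms)
  oc <- count_occupancy(cfg, part)
  expect_equal(sum(oc$alcohol), 2L)
  expect_equal(sum(oc$alcohol > 0), 2L)
})

test_that("per-cell counts match the nested-loop oracle", {
  part <- partition_spec(27, c(3, 3, 3))
  cfg_pt <- gen_random_mixture(mixture_spec(200, 30, box = simulation_box(15),
                                            seed = 8))
  expect_identical(count_occupancy(cfg_pt, part), oracle_occupancy(cfg_pt, part))
  cfg_at <- gen_random_mixture(mixture_spec(60, 40, box = simulation_box(15),
                                            seed = 9), atomistic = TRUE)
  expect_identical(count_occupancy(cfg_at, part), oracle_occupancy(cfg_at, part))
})

test_that("occupancy distributions normalize and match hand-built fractions", {
  counts <- list(water = integer(8), alcohol = c(1L, rep(0L, 7)))
  d <- build_distribution(counts, "alcohol")
  expect_equal(unname(d$fractions), c(0.875, 0.125))
  expect_equal(names(d$fractions), c("0", "1"))
  cfg <- gen_random_mixture(mixture_spec(100, 20, seed = 2))
  d2 <- build_distribution(count_occupancy(cfg, partition_spec(27, c(3, 3, 3))),
                           "alcohol")
  expect_equal(sum(d2$fractions), 1, tolerance = 1e-12)
  expect_error(build_distribution(list(), "alcohol"), "empty")
})

test_that("non-ideality equals the direct two-histogram computation", {
  expect_identical(non_ideality(occ_dist(c(`0` = 0.5, `1` = 0.5)),
                                occ_dist(c(`0` = 0.5, `1` = 0.5)))$value, 0)
  v <- non_ideality(occ_dist(c(`0` = 0.5, `1` = 0.5)),
                    occ_dist(c(`0` = 0.8, `1` = 0.2)))$value
  expect_equal(v, sqrt(0.09 + 0.09), tolerance = 1e-15)
  # mismatched supports are zero-filled over the union
  withr::local_seed(14)
  for (i in 1:20) {
    ks <- sample(0:6, sample(2:5, 1))
    kr <- sample(0:6, sample(2:5, 1))
    fs <- stats::setNames(as.numeric(rmultinom(1, 50, rep(1, length(ks)))) / 50,
                          ks)
    fr <- stats::setNames(as.numeric(rmultinom(1, 50, rep(1, length(kr)))) / 50,
                          kr)
    expect_equal(non_ideality(occ_dist(fs), occ_dist(fr))$value,
                 oracle_non_ideality(as.list(fs), as.list(fr)),
                 tolerance = 1e-12)
  }
})

test_that("two independent null ensembles sit at the sampling-noise floor", {
  # scaled-down: 300 molecules / 100 cells keeps the 3-per-cell mean occupancy
  part <- partition_spec(100, c(5, 5, 4))
  n1 <- sample_null_ensemble(mixture_spec(300, 10, seed = 1), part, 500)
  n2 <- sample_null_ensemble(mixture_spec(300, 10, seed = 2), part, 500)
  expect_lt(non_ideality(n1, n2)$value, 0.02)
})

test_that("a trajectory drawn from the null generator scores near zero", {
  sp <- mixture_spec(300, 25, seed = 50)
  traj <- gen_mixture_trajectory(sp, n_frames = 400)
  r <- trajectory_non_ideality(traj, part = partition_spec(100, c(5, 5, 4)),
                               n_frames = 400, seed = 99)
  expect_lt(r$value, 0.03)
  expect_equal(r$n_null, 400L)
})

test_that("non-ideality responds monotonically to planted clustering", {
  part <- partition_spec(100, c(5, 5, 4))
  vals <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(f) {
    sp <- mixture_spec(300, 25, seed = 60)
    traj <- gen_mixture_trajectory(sp, n_frames = 200,
                                   cluster = cluster_spec(1, 2, f))
    trajectory_non_ideality(traj, part = part, n_frames = 200,
                            seed = 13)$value
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_gt(vals[5], 0.5)
})

test_that("atomistic null ensembles apply the carbon rule on both sides", {
  sp <- mixture_spec(60, 40, box = simulation_box(15), seed = 5)
  part <- partition_spec(27, c(3, 3, 3))
  d_at <- sample_null_ensemble(sp, part, n_configs = 40, atomistic = TRUE)
  d_pt <- sample_null_ensemble(sp, part, n_configs = 40, atomistic = FALSE)
  # multi-cell counting shifts mass upward: atomistic mean occupancy exceeds
  # the point-mode expectation n_alcohol / n_cells
  expect_gt(occupancy_mean(d_at), occupancy_mean(d_pt))
  expect_equal(occupancy_mean(d_pt), 24 / 27, tolerance = 0.15)
})

test_that("auto partitioning preserves the reference mean occupancy", {
  p <- auto_partition(3000)
  expect_equal(p$n_boxes, 1000L)
  expect_equal(sort(p$grid_shape), c(10L, 10L, 10L))
  p2 <- auto_partition(300)
  expect_equal(p2$n_boxes, 100L)
})
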