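test_that("coincidence events record same-site same-step pairs", {
  # hand trace: walkers [1,2,3,3] and [5,2,3,1] meet at t = 1 and t = 2
  tr <- manual_trajectories(rbind(c(1L, 2L, 3L, 3L), c(5L, 2L, 3L, 1L)))
  ev <- coincidence_events(tr)
  expect_equal(ev$t, c(1L, 2L))
  expect_equal(ev$i, c(1L, 1L))
  expect_equal(ev$j, c(2L, 2L))

  same <- manual_trajectories(rbind(c(2L, 4L, 1L), c(2L, 4L, 1L)))
  expect_equal(coincidence_events(same)$t, 0:2)  # t = 0 co-placements count

  disjoint <- manual_trajectories(rbind(c(1L, 1L), c(2L, 2L), c(3L, 3L)))
  expect_equal(nrow(coincidence_events(disjoint)), 0)

  three <- manual_trajectories(rbind(c(7L, 1L), c(7L, 2L), c(7L, 3L)))
  ev3 <- coincidence_events(three)  # triple co-location = 3 pairs
  expect_equal(nrow(ev3), 3)
  expect_true(all(ev3$t == 0L))

  expect_error(coincidence_events(manual_trajectories(matrix(1L, 1, 4))),
               "2 walkers")
})

test_that("the memory window (t - M, t] creates and dissolves links", {
  tr <- manual_trajectories(rbind(c(1L, 2L, 3L, 3L), c(5L, 2L, 3L, 1L)))
  ev <- coincidence_events(tr)

  # M = 2, c = 2: window (0, 2] holds both encounters, (1, 3] only one
  A2 <- encounter_adjacency(ev, t = 2, memory = 2, min_contacts = 2)
  A3 <- encounter_adjacency(ev, t = 3, memory = 2, min_contacts = 2)
  expect_equal(A2[1, 2], 1)
  expect_equal(A3[1, 2], 0)

  # the encounter at exactly t - M is excluded (half-open window)
  A_excl <- encounter_adjacency(ev, t = 3, memory = 2, min_contacts = 1)
  expect_equal(A_excl[1, 2], 1)  # encounter at t = 2 still inside
  A_gone <- encounter_adjacency(ev, t = 4, memory = 2, min_contacts = 2)
  expect_equal(A_gone[1, 2], 0)

  expect_equal(sum(encounter_adjacency(ev, t = -1, memory = 5)), 0)

  # infinite memory = cumulative rule, monotone in t
  prev <- 0
  for (t in 0:3) {
    At <- encounter_adjacency(ev, t = t, memory = Inf, min_contacts = 1)
    expect_gte(sum(At), prev)
    prev <- sum(At)
  }
})

test_that("adjacency slices are symmetric, hollow and binary", {
  k <- random_kernel(20, 2, 0.2, seed = 31)
  tr <- simulate_walk(k, 60, walkers = 15, seed = 77)
  ev <- coincidence_events(tr)
  for (t in c(0, 5, 30, 60)) {
    A <- encounter_adjacency(ev, t = t, memory = 10, min_contacts = 2)
    expect_true(Matrix::isSymmetric(A))
    expect_equal(Matrix::diag(A), rep(0, 15))
    expect_true(all(A@x == 1))
  }
  # before c - 1 steps have elapsed no pair can have c encounters
  A0 <- encounter_adjacency(ev, t = 1, memory = 10, min_contacts = 3)
  expect_equal(sum(A0), 0)
  expect_equal(sum(encounter_adjacency(ev, t = 0, memory = 10, min_contacts = 2)), 0)
})

test_that("average degree equals twice the edge count over n", {
  expect_equal(average_degree(matrix(0, 4, 4)), 0)
  K5 <- 1 - diag(5)
  expect_equal(average_degree(K5), 4)
  set.seed(51)
  A <- random_adjacency(30, 0.2)
  expect_equal(average_degree(A), 2 * sum(A) / 2 / 30)
})

test_that("clustering matches closed cases and the triangle-enumeration oracle", {
  K3 <- 1 - diag(3)
  expect_equal(clustering_coefficient(K3)$local, rep(1, 3))
  expect_equal(clustering_coefficient(K3)$mean, 1)

  P3 <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3)
  expect_equal(clustering_coefficient(P3)$local, rep(0, 3))

  set.seed(61)
  for (trial in 1:8) {
    n <- sample(10:50, 1)
    A <- random_adjacency(n, runif(1, 0.05, 0.5))
    expect_equal(clustering_coefficient(A)$local, clustering_oracle(A),
                 tolerance = 1e-13)
    As <- Matrix::Matrix(A, sparse = TRUE)
    expect_equal(clustering_coefficient(As)$local, clustering_oracle(A),
                 tolerance = 1e-13)
  }
})

test_that("degree distributions are normalized histograms over 0..n-1", {
  K4 <- 1 - diag(4)
  dd <- degree_distribution(K4)
  expect_equal(dd$k, 0:3)
  expect_equal(dd$p, c(0, 0, 0, 1))
  set.seed(71)
  A <- random_adjacency(40, 0.15)
  dd <- degree_distribution(A)
  expect_equal(sum(dd$p), 1)
  expect_equal(sum(dd$k * dd$p), average_degree(A))
})

test_that("ensemble curves start empty, stay zero when c is unreachable, and reproduce", {
  k <- random_kernel(25, 3, 0.2, seed = 81)
  # c > M: the window can never hold c encounters
  cur0 <- encounter_curves(k, walkers = 12, steps = 30, memory = 3,
                           min_contacts = 5, realizations = 2, seed = 5)
  expect_true(all(cur0$mean_k == 0))
  expect_true(all(cur0$mean_C == 0))

  cur <- encounter_curves(k, walkers = 30, steps = 60, memory = 15,
                          min_contacts = 2, realizations = 3, seed = 6)
  expect_equal(cur$mean_k[1], 0)  # a single step cannot hold 2 encounters
  expect_true(any(cur$mean_k > 0))
  expect_true(all(cur$mean_C >= 0 & cur$mean_C <= 1))

  cur2 <- encounter_curves(k, walkers = 30, steps = 60, memory = 15,
                           min_contacts = 2, realizations = 3, seed = 6)
  expect_identical(cur$mean_k, cur2$mean_k)

  # windowed adjacency at the horizon agrees with the event-based path
  one <- encounter_curves(k, walkers = 30, steps = 40, memory = 10,
                          min_contacts = 2, realizations = 1, seed = 11,
                          keep_final = TRUE)
  tr <- simulate_walk(k, 40, walkers = 30, seed = 11)
  ev <- coincidence_events(tr)
  A_ref <- encounter_adjacency(ev, t = 40, memory = 10, min_contacts = 2)
  expect_equal(as.matrix(one$final[[1]] * 1), as.matrix(A_ref * 1))
})
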