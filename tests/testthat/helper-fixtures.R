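# Shared fixtures and independent oracles used across the suite.

# Three collinear sites at x = 0, 0.05, 1.0: small enough to evaluate the
# kernel and its stationary distribution by hand.
collinear3_distances <- function() {
  x <- c(0, 0.05, 1.0)
  as.matrix(dist(cbind(x, 0)))
}

# A kernel on uniform random points in the unit square.
random_kernel <- function(n, alpha, R, seed, allow_self = TRUE) {
  loc <- generate_locations(n, seed = seed)
  levy_kernel(pairwise_distances(loc), alpha, R, allow_self = allow_self)
}

# Wrap a hand-written state matrix as a trajectory ensemble.
manual_trajectories <- function(states) {
  structure(list(states = states, steps = ncol(states) - 1L,
                 walkers = nrow(states), seed = NULL),
            class = "trajectory_ensemble")
}

# O(n^3) triangle-enumeration clustering oracle, independent of the
# matrix-power implementation.
clustering_oracle <- function(A) {
  A <- as.matrix(A) * 1
  n <- nrow(A)
  C <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    links <- 0L
    for (a in seq_len(k - 1L)) for (b in (a + 1L):k)
      if (A[nb[a], nb[b]] > 0) links <- links + 1L
    C[i] <- 2 * links / (k * (k - 1))
  }
  C
}

# Symmetric binary Erdos-Renyi adjacency with zero diagonal.
random_adjacency <- function(n, p) {
  A <- matrix(0L, n, n)
  up <- upper.tri(A)
  A[up] <- as.integer(runif(sum(up)) < p)
  A + t(A)
}

# Build a checkin_table directly from vectors (times given as POSIXct
# or seconds since a fixed UTC origin).
manual_checkins <- function(user, time, lat, lon, tz_offset = 0L,
                            origin = as.POSIXct("2012-04-12 00:00:00", tz = "UTC")) {
  if (!inherits(time, "POSIXct")) time <- origin + time
  tab <- data.table::data.table(
    user_id = as.character(user), venue_id = NA_character_,
    venue_category = NA_character_, lat = lat, lon = lon,
    tz_offset = as.integer(rep_len(tz_offset, length(user))), utc_time = time)
  encounternets:::.as_checkin_table(tab, 0L)
}
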