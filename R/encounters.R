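#' Encounter events of simultaneous random walkers
#'
#' Two walkers have an encounter (a co-coincidence) when they occupy the
#' same site at the same discrete step. Co-placements at t = 0 count:
#' the dynamics starts at t0 = 0 and there are no encounters before it.
#'
#' @param trajectories a `trajectory_ensemble` with at least 2 walkers,
#'   all on the same time grid.
#' @return a data.table with columns `i`, `j` (walker pair, i < j) and
#'   `t` (encounter time), sorted by pair then time. The number of
#'   walkers is kept in attribute `walkers` and the horizon in `steps`.
#' @export
coincidence_events <- function(trajectories) {
  stopifnot(inherits(trajectories, "trajectory_ensemble"))
  st <- trajectories$states
  if (nrow(st) < 2L) stop("need at least 2 walkers", call. = FALSE)
  res <- vector("list", ncol(st))
  for (col in seq_len(ncol(st))) {
    groups <- split(seq_len(nrow(st)), st[, col])
    groups <- groups[lengths(groups) >= 2L]
    if (length(groups) == 0L) next
    pr <- lapply(groups, function(g) {
      cmb <- utils::combn(g, 2L)
      data.table::data.table(i = cmb[1L, ], j = cmb[2L, ], t = col - 1L)
    })
    res[[col]] <- data.table::rbindlist(pr)
  }
  out <- data.table::rbindlist(res[!vapply(res, is.null, logical(1L))])
  if (nrow(out) == 0L)
    out <- data.table::data.table(i = integer(), j = integer(), t = integer())
  data.table::setorder(out, i, j, t)
  data.table::setattr(out, "walkers", trajectories$walkers)
  data.table::setattr(out, "steps", trajectories$steps)
  out[]
}

#' Temporal adjacency from windowed encounter counts
#'
#' A link i ~ j exists at time t when the half-open memory window
#' (t - M, t] contains at least c encounters of the pair: M is how long
#' a walker remembers past encounters, c how many it takes to call the
#' relation a contact. `memory = Inf` gives the cumulative rule
#' (encounters in [0, t]), the construction used for empirical check-in
#' networks. The matrix is symmetric, binary and hollow; for t < 0 it is
#' empty.
#'
#' @param events encounter table from [coincidence_events()] (or any
#'   data.table with columns i, j, t).
#' @param n_walkers number of nodes (defaults to the `walkers`
#'   attribute of `events`).
#' @param t evaluation time.
#' @param memory window length M (>= 1, or Inf).
#' @param min_contacts threshold c (>= 1).
#' @return a sparse symmetric binary `Matrix::sparseMatrix` (ngCMatrix)
#'   of size n_walkers x n_walkers.
#' @export
encounter_adjacency <- function(events, t, memory = Inf, min_contacts = 1L,
                                n_walkers = attr(events, "walkers")) {
  if (is.null(n_walkers)) stop("`n_walkers` is required", call. = FALSE)
  if (memory < 1) stop("`memory` must be >= 1", call. = FALSE)
  if (min_contacts < 1) stop("`min_contacts` must be >= 1", call. = FALSE)
  i <- j <- NULL  # data.table NSE
  if (t < 0 || nrow(events) == 0L) {
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(n_walkers, n_walkers)))
  }
  lo <- if (is.infinite(memory)) -Inf else t - memory
  keep <- which(events$t > lo & events$t <= t)  # outside the frame: the
  win <- events[keep]                           # column `t` must not shadow

  cnt <- win[, list(n = .N), by = list(i, j)]
  cnt <- cnt[cnt$n >= min_contacts]
  Matrix::sparseMatrix(i = c(cnt$i, cnt$j), j = c(cnt$j, cnt$i), x = 1,
                       dims = c(n_walkers, n_walkers))
}

#' Average degree of an adjacency matrix
#'
#' <k> = (1/N) sum_i k_i = 2 E / N for a simple undirected graph.
#'
#' @param A symmetric binary adjacency (dense or sparse), zero diagonal.
#' @return scalar mean degree.
#' @export
average_degree <- function(A) {
  mean(Matrix::rowSums(A))
}

#' Local clustering coefficients
#'
#' C_i = (A^3)_ii / (k_i (k_i - 1)) for k_i >= 2, else C_i = 0: the
#' fraction of a node's neighbour pairs that are themselves linked
#' ((A^3)_ii counts twice the triangles through i). The mean is taken
#' over all nodes, including the degenerate ones.
#'
#' @param A symmetric binary adjacency, zero diagonal.
#' @return list with `local` (C_i vector) and `mean`.
#' @export
clustering_coefficient <- function(A) {
  A <- A * 1  # force numeric (pattern matrices do not multiply)
  k <- Matrix::rowSums(A)
  # (A^3)_ii = sum_j (A^2)_ij A_ij: row sums of the elementwise product
  A2 <- A %*% A
  tri2 <- Matrix::rowSums(A2 * A)  # = 2 * triangles through i
  denom <- k * (k - 1)
  C <- ifelse(denom > 0, as.numeric(tri2) / denom, 0)
  list(local = C, mean = mean(C))
}

#' Degree distribution of an adjacency matrix
#'
#' @param A symmetric binary adjacency.
#' @return data.frame with columns `k` (0..N-1) and `p`; p sums to 1.
#' @export
degree_distribution <- function(A) {
  n <- nrow(A)
  k <- Matrix::rowSums(A)
  p <- tabulate(k + 1L, nbins = n) / n
  data.frame(k = 0:(n - 1L), p = p)
}

#' Ensemble-averaged encounter-network dynamics
#'
#' Simulates `walkers` independent walkers on the kernel for T steps,
#' builds the memory-M, threshold-c adjacency at every step, and
#' averages the mean degree <k(t)> and mean clustering <C(t)> over
#' independent realizations (metrics are averaged across realizations
#' at each t, not computed on an averaged matrix). Both curves start at
#' 0 on an empty network and, for t >> M, fluctuate around a stationary
#' plateau set by the balance between link creation and memory loss.
#' Walkers start at independently uniform random sites.
#'
#' The per-pair encounter counts inside the sliding window are updated
#' incrementally (add events entering at t, drop events leaving at
#' t - M), so the cost per step is proportional to the number of
#' co-locations, not to the number of pairs.
#'
#' @param kernel a `levy_kernel`.
#' @param walkers number of walkers.
#' @param steps time horizon T (curves are reported on t = 0..T).
#' @param memory window M.
#' @param min_contacts threshold c.
#' @param realizations number of independent repetitions.
#' @param seed master seed; realization r simulates its ensemble with
#'   [simulate_walk()] under seed + (r - 1) * walkers, so every walker
#'   in every realization gets its own substream.
#' @param keep_final if TRUE, also return the list of final adjacency
#'   matrices (for degree distributions pooled across realizations).
#' @return list with `t` (0..T), `mean_k`, `mean_C` (ensemble means),
#'   `per_realization` (list of k/C matrices), and optionally `final`
#'   (adjacencies at t = T).
#' @export
encounter_curves <- function(kernel, walkers, steps, memory, min_contacts,
                             realizations = 1L, seed = NULL,
                             keep_final = FALSE) {
  stopifnot(inherits(kernel, "levy_kernel"))
  kmat <- matrix(0, realizations, steps + 1L)
  cmat <- matrix(0, realizations, steps + 1L)
  finals <- if (keep_final) vector("list", realizations) else NULL
  for (r in seq_len(realizations)) {
    traj <- simulate_walk(kernel, steps, walkers = walkers,
                          seed = if (is.null(seed)) NULL else seed + (r - 1L) * walkers)
    counts <- matrix(0L, walkers, walkers)   # windowed encounter counts, i < j
    window_events <- vector("list", steps + 1L)  # events entering at each t
    for (tt in 0:steps) {
      ev <- .colocated_pairs(traj$states[, tt + 1L])
      window_events[[tt + 1L]] <- ev
      if (length(ev)) counts[ev] <- counts[ev] + 1L
      drop_t <- tt - memory  # events at drop_t leave the window (t - M, t]
      if (is.finite(memory) && drop_t >= 0L) {
        old_ev <- window_events[[drop_t + 1L]]
        if (length(old_ev)) counts[old_ev] <- counts[old_ev] - 1L
      }
      hit <- which(counts >= min_contacts, arr.ind = TRUE)
      A <- Matrix::sparseMatrix(i = c(hit[, 1L], hit[, 2L]),
                                j = c(hit[, 2L], hit[, 1L]), x = 1,
                                dims = c(walkers, walkers))
      kmat[r, tt + 1L] <- average_degree(A)
      cmat[r, tt + 1L] <- clustering_coefficient(A)$mean
      if (keep_final && tt == steps) finals[[r]] <- A
    }
  }
  out <- list(t = 0:steps, mean_k = colMeans(kmat), mean_C = colMeans(cmat),
              per_realization = list(k = kmat, C = cmat))
  if (keep_final) out$final <- finals
  out
}

# Index matrix (i < j rows of an N_w x N_w count matrix) of all walker
# pairs sharing a site in the given state vector.
.colocated_pairs <- function(state) {
  groups <- split(seq_along(state), state)
  groups <- groups[lengths(groups) >= 2L]
  if (length(groups) == 0L) return(NULL)
  do.call(rbind, lapply(groups, function(g) t(utils::combn(g, 2L))))
}
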