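#' Configuration for the synthetic check-in generator
#'
#' Describes a synthetic city of users whose check-in streams carry the
#' statistical structure the empirical pipeline assumes: Pareto
#' inter-event times P(tau) ~ tau^-gamma above a floor, displacement
#' lengths from a power law truncated to a finite range (shallow
#' exponents near 1 are only normalizable on such a range), shared
#' hotspot venues that induce proximity co-coincidences, and a cohort
#' of users with fixed daily hotspot routines that plant repeated
#' encounters.
#'
#' Defaults: 200 users over 30 days in a ~20 km box, gamma = 2.5 above
#' a 15-minute floor, displacement exponent 1.5 on [0.001, 10] km (use
#' `delta_true = 1.15` to mirror the shallow empirical regime), 50
#' hotspots, half of all moves snapping to the nearest hotspot, and a
#' 20% routine cohort.
#'
#' @param n_users number of users.
#' @param duration_h observation window in hours.
#' @param gamma_true planted inter-event-time exponent (> 1).
#' @param tau_floor_h lower cutoff of the gaps, hours.
#' @param delta_true planted displacement exponent.
#' @param r_range_km displacement range `c(lo, hi)` in km.
#' @param n_hotspots number of shared hotspot venues.
#' @param p_hotspot probability a move snaps to the nearest hotspot.
#' @param routine_cohort fraction of users with fixed daily routines.
#' @param routine_slots hotspot visits per day for routine users.
#' @param city_km side of the square city box, km.
#' @param center_lat,center_lon city centre, degrees.
#' @param tz_offset timezone offset emitted with every check-in,
#'   minutes.
#' @param t0 UTC start time of the observation window.
#' @param seed integer seed.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_users = 200L, duration_h = 720,
                             gamma_true = 2.5, tau_floor_h = 0.25,
                             delta_true = 1.5, r_range_km = c(0.001, 10),
                             n_hotspots = 50L, p_hotspot = 0.5,
                             routine_cohort = 0.2, routine_slots = 3L,
                             city_km = 20, center_lat = 40.75,
                             center_lon = -74.0, tz_offset = -240L,
                             t0 = as.POSIXct("2012-04-12 00:00:00", tz = "UTC"),
                             seed = 1L) {
  if (gamma_true <= 1) stop("`gamma_true` must exceed 1 for a normalizable tail",
                            call. = FALSE)
  if (r_range_km[2L] <= r_range_km[1L] || r_range_km[1L] <= 0)
    stop("`r_range_km` must satisfy 0 < lo < hi", call. = FALSE)
  if (p_hotspot < 0 || p_hotspot > 1 || routine_cohort < 0 || routine_cohort > 1)
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  structure(list(n_users = as.integer(n_users), duration_h = duration_h,
                 gamma_true = gamma_true, tau_floor_h = tau_floor_h,
                 delta_true = delta_true, r_range_km = r_range_km,
                 n_hotspots = as.integer(n_hotspots), p_hotspot = p_hotspot,
                 routine_cohort = routine_cohort,
                 routine_slots = as.integer(routine_slots),
                 city_km = city_km, center_lat = center_lat,
                 center_lon = center_lon, tz_offset = as.integer(tz_offset),
                 t0 = t0, seed = as.integer(seed)),
            class = "synthetic_config")
}

# One degree of latitude on the 6371 km sphere, in km.
.KM_PER_DEG <- 6371 * pi / 180

.km_to_latlon <- function(x_km, y_km, cfg) {
  cbind(lat = cfg$center_lat + y_km / .KM_PER_DEG,
        lon = cfg$center_lon + x_km / (.KM_PER_DEG * cos(cfg$center_lat * pi / 180)))
}

#' Generate a synthetic check-in table
#'
#' Simulates every user's stream under the planted laws of a
#' [synthetic_config()]. Roaming users start at a uniform home point;
#' each subsequent check-in happens after a Pareto-distributed gap and
#' moves by a truncated-power-law displacement in a uniform direction,
#' snapping to the nearest shared hotspot with probability `p_hotspot`.
#' Routine-cohort users instead repeat a fixed daily schedule of
#' hotspot visits (with small spatial jitter and a random
#' within-the-hour offset), guaranteeing recurrent co-coincidences.
#' Identical config and seed reproduce the identical table.
#'
#' @param config a `synthetic_config`.
#' @return a `checkin_table` (see [read_checkins()]), chronologically
#'   unsorted as raw feeds usually are, with attribute `config`.
#' @export
generate_checkins <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(cfg$seed)

  half <- cfg$city_km / 2
  hot_xy <- cbind(stats::runif(cfg$n_hotspots, -half, half),
                  stats::runif(cfg$n_hotspots, -half, half))
  n_routine <- floor(cfg$routine_cohort * cfg$n_users)
  rows <- vector("list", cfg$n_users)
  cats <- c("Restaurant", "Gym", "Bar", "Office", "Park", "Museum")

  for (u in seq_len(cfg$n_users)) {
    uid <- sprintf("u%04d", u)
    if (u <= n_routine) {
      # fixed daily schedule: routine_slots (hour, hotspot) pairs
      hrs <- sort(sample(8:22, cfg$routine_slots))
      spots <- sample.int(cfg$n_hotspots, cfg$routine_slots, replace = TRUE)
      days <- seq_len(max(1L, floor(cfg$duration_h / 24)))
      slot <- rep(seq_len(cfg$routine_slots), times = length(days))
      day <- rep(days - 1L, each = cfg$routine_slots)
      t_h <- day * 24 + hrs[slot] + stats::runif(length(slot))
      keep <- t_h <= cfg$duration_h
      t_h <- t_h[keep]; slot <- slot[keep]
      jit <- matrix(stats::rnorm(2L * length(slot), sd = 0.02), ncol = 2L)  # ~20 m
      xy <- hot_xy[spots[slot], , drop = FALSE] + jit
      venue <- sprintf("H%03d", spots[slot])
    } else {
      t_h <- stats::runif(1L, 0, 24)
      gaps <- numeric(0)
      while (sum(gaps) < cfg$duration_h) {
        gaps <- c(gaps, rpareto(512L, cfg$gamma_true, cfg$tau_floor_h))
      }
      t_h <- t_h + c(0, cumsum(gaps))
      t_h <- t_h[t_h <= cfg$duration_h]
      if (length(t_h) == 0L) t_h <- stats::runif(1L, 0, cfg$duration_h)
      nstep <- length(t_h)
      xy <- matrix(0, nstep, 2L)
      xy[1L, ] <- stats::runif(2L, -half, half)
      venue <- character(nstep)
      venue[1L] <- sprintf("V%s_%05d", uid, 1L)
      if (nstep >= 2L) {
        r <- rpowerlaw_trunc(nstep - 1L, cfg$delta_true,
                             cfg$r_range_km[1L], cfg$r_range_km[2L])
        theta <- stats::runif(nstep - 1L, 0, 2 * pi)
        snap <- stats::runif(nstep - 1L) < cfg$p_hotspot
        for (s in 2:nstep) {
          prop <- xy[s - 1L, ] + r[s - 1L] * c(cos(theta[s - 1L]), sin(theta[s - 1L]))
          if (snap[s - 1L]) {
            d2 <- (hot_xy[, 1L] - prop[1L])^2 + (hot_xy[, 2L] - prop[2L])^2
            k <- which.min(d2)
            xy[s, ] <- hot_xy[k, ]
            venue[s] <- sprintf("H%03d", k)
          } else {
            xy[s, ] <- prop
            venue[s] <- sprintf("V%s_%05d", uid, s)
          }
        }
      }
    }
    ll <- .km_to_latlon(xy[, 1L], xy[, 2L], cfg)
    rows[[u]] <- data.table::data.table(
      user_id = uid, venue_id = venue,
      venue_category = sample(cats, length(t_h), replace = TRUE),
      lat = ll[, "lat"], lon = ll[, "lon"],
      tz_offset = cfg$tz_offset,
      utc_time = cfg$t0 + round(t_h * 3600))
  }
  tab <- data.table::rbindlist(rows)
  tab <- .as_checkin_table(tab, 0L)
  data.table::setattr(tab, "config", cfg)
  tab
}

#' Brute-force co-coincidence oracle
#'
#' Exhaustive quadratic scan over all pairs of check-in rows, applying
#' the same hour-bin and distance rule as [hourly_cocoincidences()] but
#' through an independent computation path (no per-bin grouping or
#' per-pair minimum): a (pair, hour) co-coincidence is recorded when any
#' two rows of distinct users share the hour bin at haversine distance
#' <= `delta_r`. Intended for validating the pipeline on small tables.
#'
#' @param tab a `checkin_table` with at most `max_rows` rows.
#' @param delta_r threshold in metres.
#' @param local_time hour binning convention, as in
#'   [hourly_cocoincidences()].
#' @param max_rows size guard for the quadratic scan.
#' @return a `coincidence_table`.
#' @export
brute_force_cocoincidences <- function(tab, delta_r, local_time = TRUE,
                                       max_rows = 1e4) {
  if (nrow(tab) > max_rows)
    stop(sprintf("quadratic oracle limited to %g rows (got %d)", max_rows,
                 nrow(tab)), call. = FALSE)
  users <- sort(unique(tab$user_id))
  empty <- data.table::data.table(i = integer(), j = integer(), bin = integer())
  if (nrow(tab) == 0L)
    return(.coincidence_table(empty, users, delta_r, 0L))
  epoch <- as.numeric(tab$utc_time)
  if (local_time) epoch <- epoch + as.numeric(tab$tz_offset) * 60
  bin <- as.integer(floor(epoch / 3600))
  origin <- min(bin)
  u <- match(tab$user_id, users)
  n <- nrow(tab)
  found <- vector("list", n)
  for (a in seq_len(n - 1L)) {
    b <- (a + 1L):n
    b <- b[bin[b] == bin[a] & u[b] != u[a]]
    if (length(b) == 0L) next
    d <- haversine_km(tab$lat[a], tab$lon[a], tab$lat[b], tab$lon[b]) * 1000
    b <- b[d <= delta_r]
    if (length(b) == 0L) next
    found[[a]] <- data.table::data.table(i = pmin(u[a], u[b]),
                                         j = pmax(u[a], u[b]),
                                         bin = bin[a] - origin)
  }
  ev <- data.table::rbindlist(found[!vapply(found, is.null, logical(1L))])
  if (nrow(ev) == 0L) ev <- empty else ev <- unique(ev)
  data.table::setorder(ev, i, j, bin)
  .coincidence_table(ev, users, delta_r, origin)
}
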