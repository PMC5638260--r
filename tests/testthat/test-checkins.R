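test_that("check-in files round-trip through the tab-separated dialect", {
  tab <- generate_checkins(synthetic_config(n_users = 10, duration_h = 48, seed = 2))
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_checkins(tab, path)
  back <- read_checkins(path)
  expect_equal(nrow(back), nrow(tab))
  expect_identical(back$user_id, tab$user_id)
  expect_equal(back$lat, tab$lat, tolerance = 1e-7)
  expect_identical(as.numeric(back$utc_time), as.numeric(tab$utc_time))
  expect_identical(attr(back, "n_malformed"), 0L)
})

test_that("malformed rows are counted and reported, not silently dropped", {
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  good <- "u1\tv1\tc1\tBar\t40.7\t-74.0\t-240\tTue Apr 03 18:00:09 +0000 2012"
  bad_time <- "u2\tv1\tc1\tBar\t40.7\t-74.0\t-240\tnot a time"
  bad_lat <- "u3\tv1\tc1\tBar\t95.0\t-74.0\t-240\tTue Apr 03 19:00:09 +0000 2012"
  writeLines(c(good, bad_time, bad_lat, good), path)
  expect_warning(tab <- read_checkins(path), "2 malformed")
  expect_equal(nrow(tab), 2)
  expect_identical(attr(tab, "n_malformed"), 2L)

  empty <- tempfile(fileext = ".tsv")
  on.exit(unlink(empty), add = TRUE)
  file.create(empty)
  expect_warning(etab <- read_checkins(empty), "empty")
  expect_equal(nrow(etab), 0)

  expect_error(read_checkins(tempfile()), "no such file")
})

test_that("inter-event times are per-user consecutive gaps in hours", {
  tab <- manual_checkins(user = c("a", "a", "b"),
                         time = c(10, 13.5, 2) * 3600,
                         lat = c(40, 40, 41), lon = c(-74, -74, -74))
  expect_equal(interevent_times(tab), 3.5)

  single <- manual_checkins("a", 0, 40, -74)
  expect_length(interevent_times(single), 0)

  # gaps never straddle users
  two <- manual_checkins(c("a", "b"), c(0, 3600), c(40, 40), c(-74, -74))
  expect_length(interevent_times(two), 0)
})

test_that("displacements are per-user consecutive haversine hops in km", {
  tab <- manual_checkins(user = c("a", "a", "a"),
                         time = c(0, 3600, 7200),
                         lat = c(40, 40, 41), lon = c(-74, -74, -74))
  r <- displacements(tab)
  expect_equal(r, c(0, 111.1949), tolerance = 1e-4)
})

test_that("hourly co-coincidences follow the same-hour, within-distance rule", {
  # two users at the same venue at 14:10 and 14:50 -> one shared hour
  tab <- manual_checkins(user = c("a", "b"),
                         time = c(14 * 3600 + 600, 14 * 3600 + 3000),
                         lat = c(40.7, 40.7), lon = c(-74, -74))
  co <- hourly_cocoincidences(tab, delta_r = 100)
  expect_equal(nrow(co$counts), 1)
  expect_equal(co$counts$n, 1L)

  # same clock times on the next day -> a second co-coincident hour
  tab2 <- manual_checkins(user = rep(c("a", "b"), 2),
                          time = c(600, 3000, 86400 + 600, 86400 + 3000) + 14 * 3600,
                          lat = rep(40.7, 4), lon = rep(-74, 4))
  co2 <- hourly_cocoincidences(tab2, delta_r = 100)
  expect_equal(co2$counts$n, 2L)

  # 14:50 and 15:10 are 20 minutes apart but in different hours
  tab3 <- manual_checkins(user = c("a", "b"),
                          time = c(14 * 3600 + 3000, 15 * 3600 + 600),
                          lat = c(40.7, 40.7), lon = c(-74, -74))
  expect_equal(nrow(hourly_cocoincidences(tab3, 100)$counts), 0)

  # beyond delta_r: ~222 m apart at delta_r = 100 m
  tab4 <- manual_checkins(user = c("a", "b"), time = c(0, 60),
                          lat = c(40.7, 40.702), lon = c(-74, -74))
  expect_equal(nrow(hourly_cocoincidences(tab4, 100)$counts), 0)
  expect_equal(nrow(hourly_cocoincidences(tab4, 300)$counts), 1)

  expect_equal(nrow(hourly_cocoincidences(manual_checkins("a", 0, 40, -74), 100)$counts), 0)
  expect_error(hourly_cocoincidences(tab, -5), "positive")
})

test_that("many same-hour proximities still count as one co-coincidence", {
  tab <- manual_checkins(user = c("a", "a", "a", "b", "b"),
                         time = c(0, 600, 1200, 300, 900),
                         lat = rep(40.7, 5), lon = rep(-74, 5))
  co <- hourly_cocoincidences(tab, 100)
  expect_equal(co$counts$n, 1L)
})

test_that("local-time binning responds to the timezone offset", {
  # 03:30 UTC with a -240 min offset is 23:30 local on the previous day;
  # the second user checks in at 03:45 UTC with offset 0 (03:45 local).
  tab <- manual_checkins(user = c("a", "b"),
                         time = c(3.5 * 3600, 3.75 * 3600),
                         lat = c(40.7, 40.7), lon = c(-74, -74),
                         tz_offset = c(-240L, 0L))
  expect_equal(nrow(hourly_cocoincidences(tab, 100, local_time = TRUE)$counts), 0)
  expect_equal(nrow(hourly_cocoincidences(tab, 100, local_time = FALSE)$counts), 1)
})

test_that("the coincidence frequency spectrum counts pairs by n", {
  tab <- manual_checkins(
    user = c("a", "b", "a", "b", "c", "d"),
    time = c(0, 60, 86400, 86460, 120, 180),
    lat = rep(40.7, 6), lon = rep(-74, 6))
  co <- hourly_cocoincidences(tab, 100)
  f <- coincidence_frequency(co)
  # pairs: (a,b) n=2; (a,c),(a,d),(b,c),(b,d),(c,d) n=1 in hour 0
  expect_equal(f$f[f$n == 1], 5)
  expect_equal(f$f[f$n == 2], 1)
  expect_equal(sum(f$f), nrow(co$counts))
  expect_equal(coincidence_frequency(hourly_cocoincidences(
    manual_checkins("a", 0, 40, -74), 100)),
    data.frame(n = integer(), f = integer()))
})

test_that("cumulative networks appear at the c-th encounter and never vanish", {
  # pair co-located in hour bins 5 and 9 -> relative bins 0 and 4
  tab <- manual_checkins(user = c("a", "b", "a", "b", "c"),
                         time = c(5.1, 5.2, 9.1, 9.2, 50.5) * 3600,
                         lat = rep(40.7, 5), lon = rep(-74, 5))
  co <- hourly_cocoincidences(tab, 100)
  expect_equal(sort(unique(co$events$bin)), c(0L, 4L))
  expect_equal(sum(cumulative_network(co, 2, t = -1)), 0)  # before any event
  expect_equal(sum(cumulative_network(co, 2, t = 3)), 0)   # only one event yet
  A4 <- cumulative_network(co, 2, t = 4)
  expect_equal(A4[1, 2], 1)
  expect_equal(A4[1, 2], cumulative_network(co, 2, t = 1e6)[1, 2])

  # threshold nesting: c = 3 edges are a subset of c = 1 edges
  tabr <- generate_checkins(synthetic_config(n_users = 20, duration_h = 96, seed = 9))
  cor_ <- hourly_cocoincidences(tabr, 150)
  A1 <- cumulative_network(cor_, 1)
  A3 <- cumulative_network(cor_, 3)
  expect_true(all((A3 - A1) <= 0))
})

test_that("cumulative mean degree is non-decreasing over the time grid", {
  tab <- generate_checkins(synthetic_config(n_users = 25, duration_h = 96, seed = 14))
  co <- hourly_cocoincidences(tab, 150)
  cur <- temporal_curves(co, min_contacts = c(1L, 2L))
  for (cc in c(1L, 2L)) {
    sub <- cur[cur$c == cc, ]
    expect_true(all(diff(sub$mean_k) >= 0))
    expect_true(all(sub$mean_C >= 0 & sub$mean_C <= 1))
  }
  # an empty event set yields flat-zero curves
  far <- manual_checkins(c("a", "b"), c(0, 60), c(10, 60), c(10, 60))
  cur0 <- temporal_curves(hourly_cocoincidences(far, 100), 1L, grid = c(0, 10))
  expect_true(all(cur0$mean_k == 0) && all(cur0$mean_C == 0))
})

test_that("largest-component summaries match closed-form graphs", {
  K3 <- 1 - diag(3)
  s <- largest_component_summary(K3)
  expect_equal(s[c("size", "edges", "mean_degree", "mean_clustering",
                   "diameter", "mean_distance")],
               list(size = 3, edges = 3, mean_degree = 2, mean_clustering = 1,
                    diameter = 1, mean_distance = 1), tolerance = 1e-12)

  P4 <- matrix(0, 4, 4)
  P4[cbind(1:3, 2:4)] <- 1
  P4 <- P4 + t(P4)
  s4 <- largest_component_summary(P4)
  expect_equal(s4$diameter, 3)
  expect_equal(s4$mean_distance, 10 / 6, tolerance = 1e-12)
  expect_equal(s4$mean_clustering, 0)

  # two components: only the larger is summarized
  A <- as.matrix(Matrix::bdiag(K3, matrix(c(0, 1, 1, 0), 2)))
  expect_equal(largest_component_summary(A)$size, 3)

  empty <- largest_component_summary(matrix(0, 5, 5))
  expect_equal(empty$size, 0)
})

test_that("co-coincidence counts grow with the distance threshold", {
  tab <- generate_checkins(synthetic_config(n_users = 20, duration_h = 72, seed = 21))
  radii <- c(10, 50, 200)
  cos_ <- lapply(radii, function(dr) hourly_cocoincidences(tab, dr))
  merged <- NULL
  for (idx in seq_along(radii)) {
    cnt <- cos_[[idx]]$counts
    expect_true(all(cnt$n >= 1))
    key <- paste(cnt$i, cnt$j)
    if (idx > 1) {
      prev <- cos_[[idx - 1]]$counts
      pkey <- paste(prev$i, prev$j)
      expect_true(all(pkey %in% key))  # pairs never disappear as delta_r grows
      common <- match(pkey, key)
      expect_true(all(cnt$n[common] >= prev$n))  # per-pair n non-decreasing
    }
  }
  # the full c = 1 edge set is nested across radii, so total edges grow
  edges <- vapply(cos_, function(co)
    sum(cumulative_network(co, 1)) / 2, numeric(1))
  expect_true(all(diff(edges) >= 0))
})
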