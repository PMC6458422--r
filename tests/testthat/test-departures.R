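test_that("IDI reproduces the hand-computed two-movement example", {
  ev <- make_events(list(c(A = 0, B = 30, C = 60), c(A = 0, B = 10, C = 50)))
  idi <- compute_idi(ev)[["g"]]
  ## m_1 = mean(30, 60, 30) = 40; m_2 = mean(10, 50, 40) = 100/3
  expect_equal(idi$value["A", "B"], (30 / 40 + 10 / (100 / 3)) / 2)
  expect_equal(idi$value["A", "B"], 0.525)
  expect_equal(idi$support["A", "B"], 2)
  expect_equal(idi$value, t(idi$value))
  ## consecutive-gap normalisation: m_1 = 30, m_2 = 25
  idic <- compute_idi(ev, norm = "consecutive")[["g"]]
  expect_equal(idic$value["A", "B"], (30 / 30 + 10 / 25) / 2)
})

test_that("a dyad departing simultaneously has IDI 0", {
  ev <- make_events(list(c(A = 0, B = 0, C = 60)))
  idi <- compute_idi(ev)[["g"]]
  expect_equal(idi$value["A", "B"], 0)
})

test_that("normalised differences average to 1 over a movement's dyads", {
  set.seed(5)
  for (k in 1:20) {
    lat <- c(0, sort(round(runif(sample(2:8, 1), 1, 590))))
    names(lat) <- paste0("I", seq_along(lat))
    idi <- compute_idi(make_events(list(lat)))[["g"]]
    expect_equal(mean(dyad_values(idi)), 1, tolerance = 1e-12)
  }
})

test_that("IDI is invariant to a common latency shift within a movement", {
  ev <- make_events(list(c(A = 0, B = 30, C = 60), c(A = 0, B = 10, C = 50)))
  shifted <- ev
  shifted$latency_s <- shifted$latency_s + 50  # bypasses validation on purpose
  expect_equal(compute_idi(shifted)[["g"]]$value, compute_idi(ev)[["g"]]$value)
})

test_that("IDI agrees with the brute-force all-pairs oracle on random data", {
  set.seed(7)
  for (k in 1:100) {
    n <- sample(4:7, 1)
    ids <- paste0("I", 1:n)
    n_ev <- sample(3:6, 1)
    evs <- lapply(1:n_ev, function(e) {
      joiners <- sample(ids, sample(2:n, 1))
      lat <- setNames(rep(NA_real_, n), ids)
      lat[joiners] <- c(0, sort(round(runif(length(joiners) - 1, 1, 595), 1)))
      lat
    })
    ev <- make_events(evs)
    got <- dyad_df(compute_idi(ev))
    want <- oracle_idi(ev)
    for (i in seq_len(nrow(want))) {
      row <- got[got$id_x == want$id_x[i] & got$id_y == want$id_y[i], ]
      expect_equal(row$value, unname(want$idi[i]), tolerance = 1e-12)
      expect_equal(row$support, want$support[i])
    }
  }
})

test_that("movements with fewer than two joiners are skipped with a warning", {
  ev <- make_events(list(c(A = 0, B = 30, C = 60)))
  solo <- make_event(c(A = 0, B = NA, C = NA), event_id = "E999")
  solo$rank <- c(1L, NA, NA)
  expect_warning(idi <- compute_idi(rbind(ev, solo)), "fewer than 2 joiners")
  expect_equal(idi[["g"]]$support["A", "B"], 1)
})

test_that("van/centre/rear assignment follows the two-mover rule", {
  ev6 <- validate_events(make_event(setNames(c(0, 10, 20, 30, 40, 50), LETTERS[1:6])))
  p6 <- assign_positions(ev6)
  expect_equal(as.character(p6[LETTERS[1:6]]),
               c("van", "van", "centre", "centre", "rear", "rear"))

  ev11 <- validate_events(make_event(setNames(c(0, 1:10 * 10), paste0("I", 1:11))))
  expect_equal(sum(assign_positions(ev11) == "centre"), 7L)

  ## partial joining: van takes precedence, then rear; centre may be empty
  ev3 <- validate_events(make_event(c(A = 0, B = 10, C = 20,
                                      D = NA, E = NA, F = NA)))
  p3 <- assign_positions(ev3)
  expect_equal(as.character(p3[c("A", "B", "C")]), c("van", "van", "rear"))
  expect_equal(sum(p3 == "centre"), 0L)
  expect_equal(sum(p3 == "not_joined"), 3L)
})

test_that("position assignment partitions every simulated event exactly", {
  sim <- simulate_dataset(scenario_config("study", seed = 13,
                                          n_events_per_group = c(5, 4, 4, 5),
                                          n_scans_per_group = 10))
  for (e in split(sim$events, sim$events$event_id)) {
    p <- assign_positions(e)
    expect_setequal(names(p), e$individual_id)
    expect_false(anyNA(p))
    k <- sum(e$joined)
    expect_equal(sum(p == "van"), min(2L, k))
    expect_equal(sum(p == "rear"), min(2L, max(0L, k - 2L)))
  }
})

test_that("position scores are per-individual proportions that sum to one", {
  lat <- function(b, c_, d) c(A = 0, B = b, C = c_, D = d)
  evs <- make_events(list(lat(10, 20, 30), lat(30, 10, 20), lat(20, 30, 10)))
  grp <- data.frame(group_id = "g", individual_id = c("A", "B", "C", "D"),
                    age_sex_class = c("adult_female", "adult_male",
                                      "juvenile", "juvenile"))
  sc <- position_scores(evs, grp)
  expect_equal(unique(as.numeric(tapply(sc$score, sc$individual_id, sum))), 1)
  a <- sc[sc$individual_id == "A", ]
  expect_equal(a$score[a$position == "van"], 1)  # A initiated every time
})

test_that("follower histograms count recruitment sizes with zero filling", {
  full <- make_events(lapply(1:10, function(i) {
    setNames(c(0, 1:5 * 10 + i), LETTERS[1:6])
  }))
  grp <- data.frame(group_id = "g", individual_id = LETTERS[1:6],
                    age_sex_class = "adult_female")
  fh <- follower_histogram(full, grp)
  expect_equal(fh$histogram$count, c(0, 0, 0, 0, 10))
  expect_equal(unname(fh$full_group_fraction["g"]), 1)

  part <- make_events(c(
    list(setNames(c(0, 10, rep(NA, 4)), LETTERS[1:6])),
    lapply(1:3, function(i) setNames(c(0, 1:5 * 10 + i), LETTERS[1:6]))))
  fh2 <- follower_histogram(part, grp)
  expect_equal(fh2$histogram$count, c(1, 0, 0, 0, 3))
  expect_equal(unname(fh2$full_group_fraction["g"]), 0.75)
})

test_that("chi-squared homogeneity matches the definitional statistic", {
  u <- chi_square_homogeneity(c(4, 4, 4, 4, 4), 6)
  expect_equal(u$statistic, 0)
  expect_equal(u$df, 4L)
  conc <- chi_square_homogeneity(c(10, 0, 0, 0, 0), 6)
  expect_equal(conc$statistic, 40)
  expect_equal(conc$df, 4L)
  expect_error(chi_square_homogeneity(c(1), 2), "at least 3")

  set.seed(19)
  for (k in 1:100) {
    N <- sample(4:12, 1)
    cnt <- rmultinom(1, sample(10:80, 1), prob = runif(N - 1))[, 1]
    got <- chi_square_homogeneity(cnt, N)
    ref <- suppressWarnings(chisq.test(cnt, p = rep(1 / (N - 1), N - 1)))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p_value, unname(ref$p.value), tolerance = 1e-12)
    obs <- chi_square_homogeneity(cnt, N, observed_only = TRUE)
    expect_equal(obs$df, sum(cnt > 0) - 1L)
  }
})

test_that("the homogeneity test holds its nominal type-I error", {
  set.seed(23)
  rej <- replicate(1000, {
    cnt <- tabulate(sample.int(5, 100, replace = TRUE), 5)
    chi_square_homogeneity(cnt, 6)$p_value <= 0.05
  })
  se3 <- 3 * sqrt(0.05 * 0.95 / 1000)
  expect_lt(abs(mean(rej) - 0.05), se3)
})

test_that("cohesion summary reports follower latencies and last joiners", {
  evs <- make_events(list(c(A = 0, B = 10, C = 20, D = NA),
                          c(A = 0, B = 30, C = NA, D = NA)))
  grp <- data.frame(group_id = "g", individual_id = LETTERS[1:4],
                    age_sex_class = "adult_female")
  cs <- cohesion_summary(evs, grp)
  expect_equal(cs$median_join_latency_s, 20)
  expect_equal(cs$n_followers_observed, 3L)
  expect_null(cs$last_follower)  # no full-group departures here

  full <- make_events(list(c(A = 0, B = 5, C = 12, D = 40)))
  cf <- cohesion_summary(full, grp)
  expect_equal(cf$last_follower$last_latency_s, 40)
  expect_equal(cf$last_follower$last_id, "D")
  expect_equal(cf$full_group_fraction_overall, 1)
})

test_that("last-follower latency grows with group size under per-capita rates", {
  set.seed(37)
  cfg <- scenario_config("null", seed = 1, lambda0 = 0.01)
  g6 <- toy_group(2, 2, 2, "g6")
  g11 <- toy_group(4, 3, 4, "g11")
  last_lat <- function(grp) {
    a <- simulate_affiliation(grp, cfg)
    replicate(500, {
      ev <- simulate_departure_event(grp, a, cfg)
      max(ev$latency_s[ev$joined])
    })
  }
  l6 <- last_lat(g6)
  l11 <- last_lat(g11)
  expect_lt(wilcox.test(l6, l11, alternative = "less")$p.value, 0.01)
})

test_that("distance occupancy gives per-individual category proportions", {
  d5 <- c("0-1", "0-1", "0-1", "0-1", ">10")
  evs <- make_events(lapply(seq_along(d5), function(i) {
    setNames(c(0, 10, 20), c("A", "B", "C"))
  }))
  evs$dist_to_initiator[evs$individual_id == "B"] <- as_distance_category(d5)
  grp <- data.frame(group_id = "g", individual_id = c("A", "B", "C"),
                    age_sex_class = c("adult_female", "adult_male", "juvenile"))
  occ <- distance_occupancy(evs, grp)
  b <- occ[occ$individual_id == "B", ]
  expect_equal(b$proportion, c(0.8, 0, 0, 0, 0.2))
  expect_equal(unique(as.numeric(tapply(occ$proportion, occ$individual_id, sum))), 1)
  expect_false("C" %in% occ$individual_id)  # no distance data -> absent
})

test_that("peripheral males occupy the far distance category more than females", {
  set.seed(41)
  cfg <- scenario_config("null", seed = 1, groups = list(c(3, 3, 2)),
                         male_peripherality = 2, n_events_per_group = 200)
  sim <- simulate_dataset(cfg)
  occ <- distance_occupancy(sim$events, sim$groups)
  far <- occ[occ$distance == ">10", ]
  m <- mean(far$proportion[far$age_sex_class == "adult_male"])
  f <- mean(far$proportion[far$age_sex_class == "adult_female"])
  expect_gt(m, f)
})
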