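test_that("Holm adjustment matches the definitional step-down procedure", {
  h <- holm_adjust(c(a = 0.01, b = 0.04))
  expect_equal(unname(h$adjusted), c(0.02, 0.04))
  expect_equal(unname(holm_adjust(0.03)$adjusted), 0.03)
  expect_equal(unname(holm_adjust(rep(1, 4))$adjusted), rep(1, 4))
  expect_error(holm_adjust(c(0.1, 1.2)), "0, 1")

  set.seed(43)
  for (k in 1:1000) {
    p <- runif(sample(1:8, 1))
    got <- unname(holm_adjust(p)$adjusted)
    expect_equal(got, oracle_holm(p), tolerance = 1e-15)
    expect_true(all(got >= p))
    expect_equal(order(got[order(p)]), seq_along(p))  # monotone step-down
  }
})

make_collinear_dyads <- function() {
  ids <- paste0("I", 1:6)
  pairs <- apply(combn(ids, 2), 2, paste, collapse = "-")
  dsi_vals <- setNames(as.list(seq(0.2, 3, length.out = 15)), pairs)
  idi_vals <- lapply(dsi_vals, function(d) 2 - 0.5 * d)
  sup <- setNames(as.list(rep(10L, 15)), pairs)
  list(dsi = list(g = make_dm(ids, dsi_vals, sup, label = "dsi")),
       idi = list(g = make_dm(ids, idi_vals, sup, label = "idi")))
}

test_that("an exact linear relation is recovered with a floor permutation p", {
  toy <- make_collinear_dyads()
  set.seed(47)
  m <- suppressWarnings(fit_idi_on_dsi(toy$idi, toy$dsi, n_perm = 500))
  expect_equal(m$coefficients$estimate[m$coefficients$term == "dsi"], -0.5,
               tolerance = 1e-10)
  expect_lte(m$permutation_p$dsi, 3 / 501)
  ## too few usable dyads errors
  expect_error(fit_idi_on_dsi(toy$idi, toy$dsi, min_support = 100),
               "fewer than 10")
})

test_that("the IDI~DSI fit is invariant to dyad row order", {
  sim <- simulate_dataset(scenario_config("affiliative", seed = 53))
  g <- dyadic_rate(sim$scans, "grooming", sim$groups)
  h <- dyadic_rate(sim$scans, "huddling", sim$groups)
  dsi <- compute_dsi(g, h)
  idi <- compute_idi(sim$events, sim$groups)
  m1 <- fit_idi_on_dsi(idi, dsi, n_perm = 0)
  m2 <- fit_idi_on_dsi(rev(idi), rev(dsi), n_perm = 0)
  expect_equal(m1$coefficients$estimate[m1$coefficients$term == "dsi"],
               m2$coefficients$estimate[m2$coefficients$term == "dsi"])
})

test_that("strong affiliative mimetism yields a significant negative DSI effect", {
  sim <- simulate_dataset(scenario_config("affiliative", seed = 59))
  g <- dyadic_rate(sim$scans, "grooming", sim$groups)
  h <- dyadic_rate(sim$scans, "huddling", sim$groups)
  set.seed(59)
  m <- fit_idi_on_dsi(compute_idi(sim$events, sim$groups), compute_dsi(g, h),
                      n_perm = 500)
  b <- m$coefficients$estimate[m$coefficients$term == "dsi"]
  expect_lt(b, 0)
  expect_lt(m$permutation_p$dsi, 0.05)
})

test_that("normalised following latencies have event mean 1 before transform", {
  sim <- simulate_dataset(scenario_config("spatial", seed = 61,
                                          groups = list(c(3, 3, 2))))
  for (ref in c("predecessor", "initiator")) {
    m <- fit_latency_on_distance(sim$events, sim$groups, ref, method = "lm")
    mu <- as.numeric(tapply(m$data$y_norm, m$data$event_id, mean))
    expect_equal(mu, rep(1, length(mu)), tolerance = 1e-12)
    expect_equal(m$transform, if (ref == "predecessor") "sqrt" else "log")
  }
})

test_that("distance to the initiator increases following latency under spatial mimetism", {
  cfg <- scenario_config("spatial", seed = 67, groups = list(c(3, 3, 2)),
                         n_events_per_group = 200)
  sim <- simulate_dataset(cfg)
  m <- fit_latency_on_distance(sim$events, sim$groups, "initiator",
                               method = "lm")
  cf <- m$coefficients
  d <- cf[grepl("^dist", cf$term), ]
  expect_false(is.unsorted(c(0, d$estimate)))  # monotone in category order
  far <- d[d$term == "dist>10", ]
  expect_gt(far$estimate, 0)
  expect_lt(far$p_holm, 0.05)
})

test_that("the completeness filter keeps only fully distance-recorded departures", {
  cfg <- scenario_config("spatial", seed = 71, groups = list(c(3, 3, 2)),
                         n_events_per_group = 100, p_distance_missing = 0.15)
  sim <- simulate_dataset(cfg)
  m <- fit_latency_on_distance(sim$events, sim$groups, "initiator",
                               method = "lm")
  fr <- follower_rows(sim$events, sim$groups)
  complete <- tapply(!is.na(fr$dist_to_initiator), fr$event_id, all)
  expect_equal(m$n_events, sum(complete))
  expect_true(all(!is.na(m$data$dist)))
})

test_that("the mixed latency model runs and reports its fit path", {
  sim <- simulate_dataset(scenario_config("spatial", seed = 73))
  m <- fit_latency_on_distance(sim$events, sim$groups, "predecessor",
                               method = "auto")
  expect_true(m$fit_method %in% c("lmer", "lm"))
  expect_true(all(c("estimate", "se", "p_value", "p_holm") %in%
                    names(m$coefficients)))
})

test_that("two shifted event sets give the exact two-point group-size slope", {
  lat4 <- c(A = 0, B = 10, C = 20, D = 30)
  lat6 <- c(E = 0, F = 10, G = 20, H = 30, I = 40, J = 90)
  ev4 <- make_events(list(lat4, lat4 + c(0, 1, 1, 1)), group_id = "g4")
  ev6 <- make_events(list(lat6, lat6 + c(0, rep(1, 5))), group_id = "g6")
  ev6$event_id <- sub("^E", "F", ev6$event_id)
  events <- validate_events(rbind(ev4, ev6))
  grp <- rbind(data.frame(group_id = "g4", individual_id = names(lat4),
                          age_sex_class = "adult_female"),
               data.frame(group_id = "g6", individual_id = names(lat6),
                          age_sex_class = "adult_male"))
  m <- fit_last_latency_on_group_size(events, grp, method = "lm")
  b <- m$coefficients
  ## mean last latencies: g4 (30, 31) -> 30.5; g6 (90, 91) -> 90.5
  expect_equal(b$estimate[b$term == "group_size"], (90.5 - 30.5) / (6 - 4))
  expect_error(fit_last_latency_on_group_size(ev4, grp[grp$group_id == "g4", ]),
               "variation")
})

test_that("per-capita rates recover a positive group-size slope; matched means cover zero", {
  set.seed(79)
  cfg <- scenario_config("null", seed = 1, lambda0 = 0.01,
                         groups = list(c(2, 2, 2), c(4, 3, 4)),
                         n_events_per_group = 30)
  pos_slope <- replicate(50, {
    sim <- simulate_dataset(scenario_config("null", seed = sample.int(1e6, 1),
                                            lambda0 = 0.01,
                                            groups = list(c(2, 2, 2), c(4, 3, 4)),
                                            n_events_per_group = 30))
    m <- fit_last_latency_on_group_size(sim$events, sim$groups, method = "lm")
    m$coefficients$estimate[2] > 0
  })
  expect_gte(mean(pos_slope), 0.9)

  ## rate-compensated sizes: expected last latency matched, CI covers 0 ~95%
  h <- function(n) sum(1 / (1:n))
  covered <- replicate(100, {
    g6 <- toy_group(2, 2, 2, "g6"); g11 <- toy_group(4, 3, 4, "g11")
    c6 <- scenario_config("null", seed = 1, lambda0 = 0.01)
    c11 <- scenario_config("null", seed = 1, lambda0 = 0.01 * h(10) / h(5))
    a6 <- simulate_affiliation(g6, c6); a11 <- simulate_affiliation(g11, c11)
    evs <- c(lapply(1:12, function(k) {
      simulate_departure_event(g6, a6, c6, event_id = paste0("A", k))
    }), lapply(1:12, function(k) {
      simulate_departure_event(g11, a11, c11, event_id = paste0("B", k))
    }))
    events <- do.call(rbind, evs)
    m <- fit_last_latency_on_group_size(events, rbind(g6, g11), method = "lm")
    b <- m$coefficients[m$coefficients$term == "group_size", ]
    b$ci_lower <= 0 && b$ci_upper >= 0
  })
  expect_gte(mean(covered), 0.885)
})

test_that("position contrasts equal raw score differences in the one-each case", {
  scores <- do.call(rbind, lapply(list(
    list(id = "F1", cls = "adult_female", s = c(0.6, 0.2, 0.1, 0.1)),
    list(id = "M1", cls = "adult_male", s = c(0.1, 0.2, 0.6, 0.1)),
    list(id = "J1", cls = "juvenile", s = c(0.1, 0.6, 0.2, 0.1))), function(x) {
      data.frame(individual_id = x$id, group_id = "g", age_sex_class = x$cls,
                 n_events_observed = 10, position = position_levels(),
                 score = x$s)
  }))
  m <- fit_position_by_class(scores)
  ct <- m$contrasts
  van_fm <- ct$estimate[ct$contrast == "van: adult_female - adult_male"]
  expect_equal(van_fm, 0.6 - 0.1, tolerance = 1e-10)
  cen_mj <- ct$estimate[ct$contrast == "centre: adult_male - juvenile"]
  expect_equal(cen_mj, 0.2 - 0.6, tolerance = 1e-10)
})

test_that("female-led departures put females in the van significantly", {
  cfg <- scenario_config("study", seed = 83,
                         female_initiator_weight = 10)
  sim <- simulate_dataset(cfg)
  sc <- position_scores(sim$events, sim$groups)
  set.seed(83)
  m <- fit_position_by_class(sc)
  ct <- m$contrasts
  fm <- ct[ct$contrast == "van: adult_female - adult_male", ]
  fj <- ct[ct$contrast == "van: adult_female - juvenile", ]
  expect_gt(fm$estimate, 0)
  expect_gt(fj$estimate, 0)
  expect_lt(fm$p_adjusted, 0.05)
  expect_lt(fj$p_adjusted, 0.05)
})

test_that("coupled affiliation and space give a negative DSI effect on proximity", {
  cfg <- scenario_config("affiliative", seed = 89,
                         beta_affiliative = 0,
                         affiliation_distance_coupling = 1,
                         n_events_per_group = 60)
  sim <- simulate_dataset(cfg)
  g <- dyadic_rate(sim$scans, "grooming", sim$groups)
  h <- dyadic_rate(sim$scans, "huddling", sim$groups)
  dsi <- compute_dsi(g, h)
  set.seed(89)
  m <- fit_proximity_on_dsi(sim$events, dsi, sim$groups, n_perm = 500)
  b <- m$coefficients$estimate[m$coefficients$term == "dsi"]
  expect_lt(b, 0)
  expect_lt(m$permutation_p$dsi, 0.05)
  expect_gte(m$n_obs, 300)
})

test_that("a single occupied distance category is rejected as degenerate", {
  ev <- make_event(c(A = 0, B = 10, C = 20),
                   d_init = c(NA, "1-3", "1-3"),
                   d_pred = c(NA, "1-3", "1-3"))
  ev <- validate_events(ev)
  grp <- data.frame(group_id = "g", individual_id = c("A", "B", "C"),
                    age_sex_class = c("adult_female", "adult_male", "juvenile"))
  dsi <- list(g = make_dm(c("A", "B", "C"),
                          list("A-B" = 1, "A-C" = 1, "B-C" = 1), label = "dsi"))
  expect_error(fit_proximity_on_dsi(ev, dsi, grp, n_perm = 0),
               "zero-variance")
})
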