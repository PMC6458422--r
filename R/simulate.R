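## Agent-based generator of group compositions, latent affiliation networks,
## scan datasets and departure events under anonymous, affiliative and
## spatial mimetism. Joining is modelled as competing risks with log-linear
## hazards and sampled Gillespie-style; the generator exists so that every
## downstream statistic can be validated by parameter recovery.

#' Simulation configuration
#'
#' Study conditions for the synthetic generator. The defaults reproduce the
#' observed study design: four groups with age-sex compositions
#' (3f,3m,2j), (2,2,2), (2,2,2), (4f,3m,4j) (31 individuals, 113 dyads),
#' 49/37/35/46 departures and 199/200/181/279 scans per group, a 600 s
#' joining window, and moderately strong mimetism of all three kinds.
#'
#' @param seed Integer RNG seed.
#' @param groups List of class-count triples `c(n_females, n_males,
#'   n_juveniles)`, one per group.
#' @param n_events_per_group Integer (scalar or per-group) number of
#'   departures to simulate.
#' @param n_scans_per_group Integer (scalar or per-group) number of scans.
#' @param window_s Joining window in seconds (600).
#' @param lambda0 Baseline per-second joining hazard (> 0).
#' @param beta_anonymous Log-hazard increment per individual already departed.
#' @param beta_affiliative Log-hazard coefficient on summed affiliation weight
#'   to already-departed members.
#' @param beta_spatial Log-hazard penalty scaling the (0..1-scaled) rank of an
#'   individual's distance to the most recent departer.
#' @param female_initiator_weight Sampling weight of adult females when
#'   drawing the initiator (males/juveniles weight 1); >= 1.
#' @param juvenile_centrality Spatial pull of juveniles toward the group
#'   centroid: their offset is shrunk by `1 / (1 + kappa)`.
#' @param male_peripherality Outward push of adult males: their offset is
#'   stretched by `1 + this`.
#' @param affiliation_shape Gamma shape of the latent dyadic weight
#'   distribution (scaled to group mean 1); shapes below 1 give the
#'   right-skewed bond structure seen in the field. `Inf` gives equal weights.
#' @param scan_visibility_p Per-scan, per-individual visibility probability.
#' @param interaction_scale Maps latent weight to the per-scan probability of
#'   grooming (and, independently, huddling): `min(scale * w, 1)`.
#' @param affiliation_distance_coupling rho in `[0, 1]`: 0 = spatial positions
#'   independent of affiliation; 1 = inter-individual distance ranks are the
#'   reverse of affiliation ranks.
#' @param spatial_sd Standard deviation (m) of the planar Gaussian scatter of
#'   individuals at a departure.
#' @param p_distance_missing Probability that any one recorded distance
#'   (to initiator or predecessor) is missing, emulating field observation
#'   loss.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       groups = list(c(3, 3, 2), c(2, 2, 2), c(2, 2, 2), c(4, 3, 4)),
                       n_events_per_group = c(49, 37, 35, 46),
                       n_scans_per_group = c(199, 200, 181, 279),
                       window_s = 600,
                       lambda0 = 0.012,
                       beta_anonymous = 0.02,
                       beta_affiliative = 0.1,
                       beta_spatial = 2,
                       female_initiator_weight = 4,
                       juvenile_centrality = 1,
                       male_peripherality = 0.5,
                       affiliation_shape = 0.5,
                       scan_visibility_p = 0.85,
                       interaction_scale = 0.08,
                       affiliation_distance_coupling = 0.5,
                       spatial_sd = 4,
                       p_distance_missing = 0.25) {
  cfg <- list(seed = as.integer(seed), groups = groups,
              n_events_per_group = rep_len(n_events_per_group, length(groups)),
              n_scans_per_group = rep_len(n_scans_per_group, length(groups)),
              window_s = window_s, lambda0 = lambda0,
              beta_anonymous = beta_anonymous,
              beta_affiliative = beta_affiliative,
              beta_spatial = beta_spatial,
              female_initiator_weight = female_initiator_weight,
              juvenile_centrality = juvenile_centrality,
              male_peripherality = male_peripherality,
              affiliation_shape = affiliation_shape,
              scan_visibility_p = scan_visibility_p,
              interaction_scale = interaction_scale,
              affiliation_distance_coupling = affiliation_distance_coupling,
              spatial_sd = spatial_sd,
              p_distance_missing = p_distance_missing)
  with(cfg, {
    stopifnot(length(groups) >= 1, all(vapply(groups, length, 1L) == 3),
              all(vapply(groups, sum, 1) >= 3),
              window_s > 0, lambda0 > 0,
              beta_anonymous >= 0, beta_affiliative >= 0, beta_spatial >= 0,
              female_initiator_weight >= 1,
              juvenile_centrality >= 0, male_peripherality >= 0,
              affiliation_shape > 0,
              scan_visibility_p > 0, scan_visibility_p <= 1,
              interaction_scale >= 0,
              affiliation_distance_coupling >= 0,
              affiliation_distance_coupling <= 1,
              spatial_sd > 0, p_distance_missing >= 0, p_distance_missing <= 1)
  })
  structure(cfg, class = "sim_config")
}

#' Build a composition table from a configuration
#'
#' Groups are labelled `G1, G2, ...`; ids encode group, class and index
#' (`G1_f1`, `G1_m2`, `G1_j1`, ...).
#'
#' @param config A `sim_config`.
#' @return Composition data frame (`group_id, individual_id, age_sex_class`).
#' @export
sim_groups <- function(config) {
  rows <- lapply(seq_along(config$groups), function(gi) {
    cc <- config$groups[[gi]]
    g <- paste0("G", gi)
    cls <- rep(AGE_SEX_LEVELS, times = cc)
    tag <- c(if (cc[1]) paste0("f", seq_len(cc[1])),
             if (cc[2]) paste0("m", seq_len(cc[2])),
             if (cc[3]) paste0("j", seq_len(cc[3])))
    data.frame(group_id = g, individual_id = paste0(g, "_", tag),
               age_sex_class = cls)
  })
  validate_groups(do.call(rbind, rows))
}

#' Simulate a latent affiliation network
#'
#' Dyadic weights are drawn i.i.d. from a gamma distribution with the
#' configured shape and then rescaled so the group mean is exactly 1; shapes
#' below 1 produce a strongly right-skewed bond distribution (median below
#' mean). Weights are class-blind: the generator builds no assortment by
#' age-sex class. Consumes the current RNG stream; seed it (or call through
#' [simulate_dataset()]) for reproducibility.
#'
#' @param group One group's rows of a composition table.
#' @param config A `sim_config`.
#' @return `dyad_matrix` labelled `"latent_weight"`, group mean exactly 1.
#' @export
simulate_affiliation <- function(group, config) {
  ids <- sort(group$individual_id)
  n <- length(ids)
  if (n < 3) stop("group must have at least 3 members")
  m <- choose(n, 2)
  w <- if (is.finite(config$affiliation_shape)) {
    rgamma(m, shape = config$affiliation_shape, rate = config$affiliation_shape)
  } else {
    rep(1, m)
  }
  w <- w / mean(w)
  V <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  V[upper.tri(V)] <- w
  V[lower.tri(V)] <- t(V)[lower.tri(V)]
  S <- matrix(1L, n, n, dimnames = list(ids, ids))
  dyad_matrix(V, S, group_id = group$group_id[1], label = "latent_weight")
}

#' Simulate group scans
#'
#' Each individual is visible in a scan independently with probability
#' `scan_visibility_p`; each co-visible dyad grooms (and, independently,
#' huddles) with probability `min(interaction_scale * w, 1)`. Grooming and
#' huddling are two independent read-outs of the same latent weight.
#'
#' @param group One group's composition rows.
#' @param affiliation `dyad_matrix` of latent weights for that group.
#' @param config A `sim_config`.
#' @param n_scans Number of scans (defaults to the group's configured count).
#' @param scan_prefix Prefix for scan ids.
#' @return A `scan_dataset`.
#' @export
simulate_scans <- function(group, affiliation, config, n_scans = NULL,
                           scan_prefix = NULL) {
  g <- group$group_id[1]
  if (is.null(n_scans)) {
    gi <- as.integer(sub("^G", "", g))
    n_scans <- config$n_scans_per_group[min(gi, length(config$n_scans_per_group))]
  }
  if (is.null(scan_prefix)) scan_prefix <- paste0(g, "_S")
  ids <- affiliation$ids
  n <- length(ids)
  pr <- pmin(config$interaction_scale * affiliation$value, 1)
  scan_rows <- vector("list", n_scans)
  int_rows <- list()
  ut <- which(upper.tri(pr), arr.ind = TRUE)
  for (s in seq_len(n_scans)) {
    sid <- sprintf("%s%04d", scan_prefix, s)
    vis <- ids[runif(n) < config$scan_visibility_p]
    scan_rows[[s]] <- data.frame(scan_id = sid, group_id = g,
                                 visible_ids = join_ids(vis))
    if (length(vis) >= 2) {
      both <- matrix(FALSE, n, n)
      vi <- match(vis, ids)
      both[vi, vi] <- TRUE
      for (b in c("grooming", "huddling")) {
        p <- pr[ut]
        hit <- both[ut] & runif(nrow(ut)) < p
        if (any(hit)) {
          hx <- ids[ut[hit, 1]]; hy <- ids[ut[hit, 2]]
          lo <- pmin(hx, hy); hi <- pmax(hx, hy)
          int_rows[[length(int_rows) + 1L]] <-
            data.frame(scan_id = sid, group_id = g, behaviour = b,
                       id_x = lo, id_y = hi)
        }
      }
    }
  }
  interactions <- if (length(int_rows)) do.call(rbind, int_rows) else
    data.frame(scan_id = character(), group_id = character(),
               behaviour = character(), id_x = character(), id_y = character())
  scan_dataset(do.call(rbind, scan_rows), interactions)
}

#' Simulate spatial positions for one departure
#'
#' Individuals are scattered in the plane (Gaussian, sd `spatial_sd` m);
#' juveniles are shrunk toward the group centroid by `1/(1+kappa)` and adult
#' males stretched outward by `1 + male_peripherality`. With coupling `rho`
#' between affiliation and proximity, the Euclidean dyadic distances are
#' re-assigned across dyads by blending the spatial ranking with the reverse
#' affiliation ranking: at `rho = 0` distances are the raw Euclidean ones
#' (independent of affiliation); at `rho = 1` the most affiliated dyad is
#' the closest. Positions are regenerated per event (distances are measured
#' per departure, not persistent).
#'
#' @param group One group's composition rows.
#' @param affiliation `dyad_matrix` of latent weights.
#' @param config A `sim_config`.
#' @return List with `coords` (n x 2 matrix), `dist` (dyadic distance matrix,
#'   metres) and `category` (matrix of distance-category labels).
#' @export
simulate_positions <- function(group, affiliation, config) {
  ids <- affiliation$ids
  n <- length(ids)
  cls <- as.character(group$age_sex_class)[match(ids, group$individual_id)]
  xy <- matrix(rnorm(2 * n, sd = config$spatial_sd), n, 2,
               dimnames = list(ids, c("x", "y")))
  ctr <- colMeans(xy)
  off <- sweep(xy, 2, ctr)
  shrink <- rep(1, n)
  shrink[cls == "juvenile"] <- 1 / (1 + config$juvenile_centrality)
  shrink[cls == "adult_male"] <- 1 + config$male_peripherality
  xy <- sweep(off * shrink, 2, ctr, "+")
  D <- as.matrix(dist(xy))
  rho <- config$affiliation_distance_coupling
  if (rho > 0) {
    ut <- upper.tri(D)
    dvals <- D[ut]
    wvals <- affiliation$value[ut]
    r_d <- rank(dvals, ties.method = "first")
    r_w <- rank(-wvals, ties.method = "first")
    blend <- (1 - rho) * r_d + rho * r_w
    d_new <- sort(dvals)[rank(blend, ties.method = "first")]
    D[ut] <- d_new
    D[lower.tri(D)] <- t(D)[lower.tri(D)]
  }
  cat_lab <- distance_from_metres(D[upper.tri(D)])
  Cm <- matrix(NA_character_, n, n, dimnames = dimnames(D))
  Cm[upper.tri(Cm)] <- as.character(cat_lab)
  Cm[lower.tri(Cm)] <- t(Cm)[lower.tri(Cm)]
  list(coords = xy, dist = D, category = Cm)
}

#' Simulate one departure event
#'
#' The initiator is drawn with class weights (adult females get
#' `female_initiator_weight`, others 1). Joining then unfolds in continuous
#' time as competing risks: an undeparted individual `j` has hazard
#' `lambda0 * exp(bN * D + bA * sum_k w_jk + bS * (-s_j))`, where `D` is the
#' number already departed, the sum runs over departed members `k`, and `s_j`
#' is the rank of `j`'s distance to the most recent departer among undeparted
#' individuals, scaled to `[0, 1]` (closest = 0). Waiting times and joiner
#' identities are sampled Gillespie-style (exponential competing risks);
#' individuals not departed when the window closes do not join. With all
#' mimetism coefficients zero, joiner identities are exchangeable and the
#' wait for the k-th follower is `Exp((N - k) * lambda0)`.
#'
#' Distances to the initiator (all non-initiators) and to the departure
#' predecessor (joiners) are recorded from the event's positions, each lost
#' with probability `p_distance_missing`.
#'
#' @param group One group's composition rows.
#' @param affiliation `dyad_matrix` of latent weights.
#' @param config A `sim_config`.
#' @param positions Optional output of [simulate_positions()]; regenerated if
#'   omitted.
#' @param event_id Event identifier.
#' @param require_success Redraw (up to 100 times) if no follower joins
#'   within the window, mirroring the rarity of failed initiations in
#'   cohesive groups.
#' @return One event's rows of an events table (covering every member).
#' @export
simulate_departure_event <- function(group, affiliation, config,
                                     positions = NULL, event_id = "E1",
                                     require_success = TRUE) {
  if (config$lambda0 <= 0) stop("degenerate config: lambda0 must be positive")
  ids <- affiliation$ids
  n <- length(ids)
  cls <- as.character(group$age_sex_class)[match(ids, group$individual_id)]
  W <- affiliation$value
  W[is.na(W)] <- 0
  for (try in seq_len(if (require_success) 100L else 1L)) {
    pos <- if (is.null(positions)) simulate_positions(group, affiliation, config)
           else positions
    iw <- ifelse(cls == "adult_female", config$female_initiator_weight, 1)
    initiator <- ids[sample.int(n, 1L, prob = iw)]
    departed <- initiator
    times <- c(0)
    und <- setdiff(ids, initiator)
    t_now <- 0
    while (length(und) > 0) {
      last <- departed[length(departed)]
      M <- length(und)
      dvec <- pos$dist[und, last]
      s <- if (M > 1) (rank(dvec, ties.method = "first") - 1) / (M - 1) else 0
      wsum <- rowSums(W[und, departed, drop = FALSE])
      loghz <- config$beta_anonymous * length(departed) +
        config$beta_affiliative * wsum - config$beta_spatial * s
      hz <- config$lambda0 * exp(loghz)
      t_now <- t_now + rexp(1, sum(hz))
      if (t_now > config$window_s) break
      j <- und[sample.int(M, 1L, prob = hz)]
      departed <- c(departed, j)
      times <- c(times, t_now)
      und <- setdiff(und, j)
    }
    if (length(departed) >= 2 || !require_success) break
    if (!is.null(positions)) positions <- NULL  # redraw layout too
  }
  if (require_success && length(departed) < 2) {
    stop("no follower recruited in 100 attempts; hazards too low for window")
  }
  joined <- ids %in% departed
  lat <- rep(NA_real_, n)
  lat[match(departed, ids)] <- times
  miss <- function(k) runif(k) < config$p_distance_missing
  d_init <- rep(NA_character_, n)
  nonini <- ids != initiator
  d_init[nonini] <- pos$category[cbind(ids[nonini], initiator)]
  d_init[nonini][miss(sum(nonini))] <- NA_character_
  d_pred <- rep(NA_character_, n)
  if (length(departed) >= 2) {
    fol <- departed[-1]
    pred <- departed[-length(departed)]
    di <- match(fol, ids)
    d_pred[di] <- pos$category[cbind(fol, pred)]
    d_pred[di][miss(length(di))] <- NA_character_
  }
  ev <- data.frame(event_id = event_id, group_id = group$group_id[1],
                   individual_id = ids,
                   is_initiator = ids == initiator,
                   joined = joined, latency_s = lat,
                   dist_to_initiator = d_init,
                   dist_to_predecessor = d_pred)
  validate_events(ev)
}

#' Simulate a full dataset
#'
#' Seeds the RNG from the configuration and generates, group by group, the
#' latent affiliation network, the scan dataset and the departure events,
#' together with a truth bundle (latent weights, mimetism coefficients, seed)
#' for parameter-recovery experiments. Identical configuration and seed give
#' identical output.
#'
#' @param config A `sim_config`.
#' @param out_dir Optional directory: writes `groups.csv`, `events.csv`,
#'   `scans.csv` and `truth.json` there.
#' @return List `groups, events, scans, affiliation` (named list of latent
#'   `dyad_matrix`), `truth` (list), `config`.
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  groups <- sim_groups(config)
  aff <- list()
  scan_parts <- list()
  event_parts <- list()
  for (gi in seq_along(config$groups)) {
    g <- paste0("G", gi)
    grp <- groups[groups$group_id == g, , drop = FALSE]
    A <- simulate_affiliation(grp, config)
    aff[[g]] <- A
    scan_parts[[g]] <- simulate_scans(grp, A, config,
                                      n_scans = config$n_scans_per_group[gi])
    n_ev <- config$n_events_per_group[gi]
    if (n_ev > 0) {
      evs <- lapply(seq_len(n_ev), function(k) {
        simulate_departure_event(grp, A, config,
                                 event_id = sprintf("%s_E%03d", g, k))
      })
      event_parts[[g]] <- do.call(rbind, evs)
    }
  }
  scans <- scan_dataset(
    do.call(rbind, lapply(scan_parts, `[[`, "scans")),
    do.call(rbind, lapply(scan_parts, `[[`, "interactions")))
  events <- if (length(event_parts)) do.call(rbind, event_parts) else
    data.frame(event_id = character(), group_id = character(),
               individual_id = character(), is_initiator = logical(),
               joined = logical(), latency_s = numeric(),
               dist_to_initiator = character(),
               dist_to_predecessor = character(), rank = integer())
  rownames(events) <- NULL
  truth <- list(seed = config$seed,
                beta_anonymous = config$beta_anonymous,
                beta_affiliative = config$beta_affiliative,
                beta_spatial = config$beta_spatial,
                affiliation_distance_coupling = config$affiliation_distance_coupling,
                latent_weights = lapply(aff, function(a) {
                  d <- dyad_df(a)
                  d[c("group_id", "id_x", "id_y", "value")]
                }))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_groups(groups, file.path(out_dir, "groups.csv"))
    if (nrow(events)) {
      write_events(events, file.path(out_dir, "events.csv"))
    } else {
      writeLines(paste("event_id,group_id,individual_id,is_initiator,joined,",
                       "latency_s,dist_to_initiator,dist_to_predecessor", sep = ""),
                 file.path(out_dir, "events.csv"))
    }
    write_scans(scans, file.path(out_dir, "scans.csv"))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  list(groups = groups, events = events, scans = scans,
       affiliation = aff, truth = truth, config = config)
}
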