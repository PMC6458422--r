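## Departure metrics: travel association (inter-departure intervals),
## van/centre/rear position scoring, cohesion statistics, follower-count
## homogeneity, and distance-category occupancy.

POSITION_LEVELS <- c("van", "centre", "rear", "not_joined")

#' Departure position categories
#'
#' @return Character vector `van, centre, rear, not_joined`.
#' @export
position_levels <- function() POSITION_LEVELS

#' Inter-departure interval (IDI) per dyad
#'
#' The IDI of a dyad is its mean normalised departure-time difference across
#' the movements both members joined:
#' `IDI_xy = (1/n) * sum_i |t_xi - t_yi| / m_i`, where `m_i` normalises for
#' movement `i`'s overall pace. Dyads that habitually depart in close
#' succession have a small IDI; within any single movement the average of the
#' normalised differences over all joiner dyads is exactly 1 (with the default
#' normalisation), so the all-dyad IDI average over any event set is 1.
#'
#' @param events Validated events table.
#' @param groups Optional composition table (fixes each group's roster; else
#'   the roster is the union of ids seen in that group's events).
#' @param norm Per-movement normaliser `m_i`: `"dyadic"` (default) is the mean
#'   absolute departure-time difference over all joiner dyads of the movement;
#'   `"consecutive"` is the mean gap between consecutive departures.
#' @return Named list of `dyad_matrix` objects labelled `"idi"`; support is
#'   the number of shared movements, value missing when it is 0. Movements
#'   with fewer than 2 joiners, or all simultaneous departures, contribute
#'   nothing (skipped with a warning).
#' @export
compute_idi <- function(events, groups = NULL, norm = c("dyadic", "consecutive")) {
  norm <- match.arg(norm)
  gids <- sort(unique(events$group_id))
  out <- list()
  for (g in gids) {
    eg <- events[events$group_id == g, , drop = FALSE]
    ids <- if (!is.null(groups)) {
      sort(groups$individual_id[groups$group_id == g])
    } else {
      sort(unique(eg$individual_id))
    }
    n <- length(ids)
    num <- matrix(0, n, n, dimnames = list(ids, ids))
    cnt <- matrix(0L, n, n, dimnames = list(ids, ids))
    for (ev in unique(eg$event_id)) {
      e <- eg[eg$event_id == ev, ]
      j <- e[e$joined, ]
      if (nrow(j) < 2) {
        warning("movement ", ev, " has fewer than 2 joiners; skipped")
        next
      }
      t <- j$latency_s
      m_i <- if (norm == "dyadic") {
        mean(as.numeric(dist(t)))
      } else {
        mean(diff(sort(t)))
      }
      if (m_i == 0) {
        warning("movement ", ev, " has all departures simultaneous; skipped")
        next
      }
      idx <- match(j$individual_id, ids)
      D <- abs(outer(t, t, "-")) / m_i
      num[idx, idx] <- num[idx, idx] + D
      cnt[idx, idx] <- cnt[idx, idx] + 1L
    }
    diag(cnt) <- 0L
    V <- ifelse(cnt > 0, num / cnt, NA_real_)
    dimnames(V) <- list(ids, ids)
    out[[g]] <- dyad_matrix(V, cnt, group_id = g, label = "idi")
  }
  out
}

#' Assign van/centre/rear positions for one departure
#'
#' Joiners ordered by departure rank are grouped into position categories: the
#' two first movers form the van, the two last joiners the rear, remaining
#' joiners the centre; non-joiners get `not_joined`. When four or fewer
#' individuals join, the van (first two) takes precedence, the rear takes the
#' remaining last joiners and the centre may be empty. Latency ties share the
#' minimum rank (competition ranking); the residual order among tied joiners
#' is broken by id so the partition is deterministic.
#'
#' @param event Rows of a validated events table for a single event.
#' @return Named factor id -> position category, covering every member of the
#'   event exactly once.
#' @export
assign_positions <- function(event) {
  ev <- unique(event$event_id)
  if (length(ev) != 1) stop("assign_positions expects a single event")
  j <- event[event$joined, , drop = FALSE]
  j <- j[order(j$rank, j$individual_id), , drop = FALSE]
  k <- nrow(j)
  if (k < 2) stop("event ", ev, " is not a successful departure")
  pos <- setNames(rep("not_joined", nrow(event)), event$individual_id)
  n_van <- min(2L, k)
  n_rear <- min(2L, k - n_van)
  jo <- j$individual_id
  pos[jo[seq_len(n_van)]] <- "van"
  if (n_rear > 0) pos[jo[(k - n_rear + 1L):k]] <- "rear"
  mid <- setdiff(jo, c(jo[seq_len(n_van)], if (n_rear > 0) jo[(k - n_rear + 1L):k]))
  pos[mid] <- "centre"
  factor(pos, levels = POSITION_LEVELS)
}

#' Long-form position table over all events
#'
#' @param events Validated events table.
#' @return Data frame `event_id, group_id, individual_id, position`.
#' @export
position_table <- function(events) {
  rows <- lapply(unique(events$event_id), function(ev) {
    e <- events[events$event_id == ev, ]
    p <- assign_positions(e)
    data.frame(event_id = ev, group_id = e$group_id[1],
               individual_id = names(p), position = as.character(p))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-individual position scores
#'
#' For each individual, the proportion of its group's departures in which it
#' was observed in each position category (van, centre, rear, not joined);
#' the four proportions sum to 1.
#'
#' @param events Validated events table.
#' @param groups Composition table (provides age-sex classes).
#' @return Data frame `individual_id, group_id, age_sex_class,
#'   n_events_observed, position, score` in long form (4 rows per individual).
#' @export
position_scores <- function(events, groups) {
  groups <- validate_groups(groups)
  pt <- position_table(events)
  rows <- list()
  for (i in seq_len(nrow(groups))) {
    id <- groups$individual_id[i]
    g <- groups$group_id[i]
    p <- pt[pt$individual_id == id & pt$group_id == g, ]
    n <- nrow(p)
    if (n == 0) next
    cnt <- table(factor(p$position, levels = POSITION_LEVELS))
    rows[[length(rows) + 1L]] <- data.frame(
      individual_id = id, group_id = g,
      age_sex_class = as.character(groups$age_sex_class[i]),
      n_events_observed = n,
      position = POSITION_LEVELS,
      score = as.numeric(cnt) / n)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Follower-count histogram per group
#'
#' How often how many individuals followed the initiator: counts over the
#' possible follower numbers `1 .. N-1` for each group (zero-filled), plus the
#' fraction of departures that recruited the entire group.
#'
#' @param events Validated events table.
#' @param groups Composition table (fixes `N` per group).
#' @return List with `histogram` (data frame `group_id, n_followers, count`)
#'   and `full_group_fraction` (named vector per group).
#' @export
follower_histogram <- function(events, groups) {
  sizes <- group_sizes(groups)
  et <- event_table(events)
  hist_rows <- list()
  fgf <- c()
  for (g in names(sizes)) {
    k <- et$n_followers[et$group_id == g]
    if (!length(k)) next
    N <- sizes[[g]]
    cnt <- table(factor(k, levels = 1:(N - 1)))
    hist_rows[[g]] <- data.frame(group_id = g, n_followers = 1:(N - 1),
                                 count = as.integer(cnt))
    fgf[g] <- mean(k == N - 1)
  }
  out <- do.call(rbind, hist_rows)
  rownames(out) <- NULL
  list(histogram = out, full_group_fraction = fgf)
}

#' Chi-squared test of follower-count homogeneity
#'
#' Tests whether the follower-count distribution is homogeneous (uniform over
#' the possible counts `1 .. N-1`). A strongly non-uniform, full-group-heavy
#' distribution indicates an all-or-nothing joining process and a cohesive
#' group. Pearson statistic `sum((O-E)^2 / E)` with `E = total / (N-1)` and
#' `df = N - 2`; with `observed_only = TRUE` the expectation runs over the
#' observed counts only (`df` = observed categories - 1), a data-defined
#' convention some field studies use.
#'
#' @param counts Integer vector of counts over follower numbers `1..N-1`
#'   (length `N-1`, zeros included), e.g. one group's rows of
#'   [follower_histogram()].
#' @param group_size Group size `N` (>= 3).
#' @param observed_only Use only categories with at least one observation.
#' @return List `statistic, df, p_value, expected`.
#' @export
chi_square_homogeneity <- function(counts, group_size, observed_only = FALSE) {
  group_size <- as.integer(group_size)
  if (group_size < 3) stop("group_size must be at least 3")
  counts <- as.numeric(counts)
  if (length(counts) != group_size - 1) {
    stop("counts must have one entry per follower number 1..N-1")
  }
  if (sum(counts) < 1) stop("at least one observed departure required")
  if (observed_only) counts <- counts[counts > 0]
  E <- sum(counts) / length(counts)
  stat <- sum((counts - E)^2 / E)
  df <- length(counts) - 1L
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE),
       expected = E)
}

#' Group-cohesion summary
#'
#' Median and interquartile range of follower joining latencies (initiators
#' excluded), per-event last-follower latencies restricted to departures in
#' which the entire group followed, the follower-count histogram and the
#' full-group fraction.
#'
#' @param events Validated events table.
#' @param groups Composition table.
#' @return List: `median_join_latency_s`, `iqr_join_latency_s` (q1, q3),
#'   `n_followers_observed`, `last_follower` (data frame over full-group
#'   events: `event_id, group_id, group_size, initiator_id, last_id,
#'   last_latency_s`), `follower_histogram`, `full_group_fraction` (per group)
#'   and `full_group_fraction_overall`.
#' @export
cohesion_summary <- function(events, groups) {
  lat <- events$latency_s[events$joined & !events$is_initiator]
  et <- event_table(events)
  sizes <- group_sizes(groups)
  full <- et[et$full_group, , drop = FALSE]
  last_rows <- lapply(seq_len(nrow(full)), function(i) {
    e <- events[events$event_id == full$event_id[i], ]
    j <- e[e$joined, ]
    last_id <- j$individual_id[which.max(j$latency_s)]
    data.frame(event_id = full$event_id[i], group_id = full$group_id[i],
               group_size = sizes[[full$group_id[i]]],
               initiator_id = full$initiator_id[i], last_id = last_id,
               last_latency_s = full$last_latency_s[i])
  })
  fh <- follower_histogram(events, groups)
  list(median_join_latency_s = median(lat),
       iqr_join_latency_s = unname(quantile(lat, c(0.25, 0.75))),
       n_followers_observed = length(lat),
       last_follower = do.call(rbind, last_rows),
       follower_histogram = fh$histogram,
       full_group_fraction = fh$full_group_fraction,
       full_group_fraction_overall = mean(et$full_group))
}

#' Distance-category occupancy per individual
#'
#' For each non-initiating individual, the proportion of its observations (its
#' recorded distances to the initiator across events) falling in each of the
#' five distance categories; proportions sum to 1 per individual. Individuals
#' never observed with distance data are absent from the result, not reported
#' as zeros.
#'
#' @param events Validated events table.
#' @param groups Composition table.
#' @return Data frame `individual_id, group_id, age_sex_class, n_obs,
#'   distance, proportion` in long form (5 rows per observed individual).
#' @export
distance_occupancy <- function(events, groups) {
  groups <- validate_groups(groups)
  obs <- events[!events$is_initiator & !is.na(events$dist_to_initiator), ,
                drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(groups))) {
    id <- groups$individual_id[i]
    g <- groups$group_id[i]
    o <- obs[obs$individual_id == id & obs$group_id == g, ]
    if (!nrow(o)) next
    cnt <- table(factor(o$dist_to_initiator, levels = DIST_LEVELS))
    rows[[length(rows) + 1L]] <- data.frame(
      individual_id = id, group_id = g,
      age_sex_class = as.character(groups$age_sex_class[i]),
      n_obs = nrow(o), distance = DIST_LEVELS,
      proportion = as.numeric(cnt) / nrow(o))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
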