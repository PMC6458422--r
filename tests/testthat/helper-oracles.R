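# Independent oracle implementations and small fixture builders.
# Oracles are deliberately naive (loops, definitional formulas) and share no
# code with the package internals they check.

# Build a dyad_matrix from named dyadic values ("A-B" = 0.2, ...)
make_dm <- function(ids, values, support = NULL, group_id = "g", label = "value") {
  n <- length(ids)
  V <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  S <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (nm in names(values)) {
    p <- strsplit(nm, "-", fixed = TRUE)[[1]]
    V[p[1], p[2]] <- V[p[2], p[1]] <- values[[nm]]
    s <- if (is.null(support)) 1L else support[[nm]]
    S[p[1], p[2]] <- S[p[2], p[1]] <- s
  }
  dyad_matrix(V, S, group_id = group_id, label = label)
}

# One event's rows from a named latency vector (NA = did not join).
make_event <- function(latencies, event_id = "E1", group_id = "g",
                       d_init = NULL, d_pred = NULL) {
  ids <- names(latencies)
  df <- data.frame(event_id = event_id, group_id = group_id,
                   individual_id = ids,
                   is_initiator = !is.na(latencies) & latencies == 0,
                   joined = !is.na(latencies),
                   latency_s = unname(latencies),
                   dist_to_initiator = if (is.null(d_init)) NA_character_ else d_init,
                   dist_to_predecessor = if (is.null(d_pred)) NA_character_ else d_pred)
  if (sum(df$is_initiator) > 1) {  # ties at 0: first id is the initiator
    first <- which(df$is_initiator)[1]
    df$is_initiator[-first] <- FALSE & df$is_initiator[-first]
  }
  df
}

make_events <- function(latency_list, group_id = "g") {
  validate_events(do.call(rbind, lapply(seq_along(latency_list), function(i) {
    make_event(latency_list[[i]], event_id = sprintf("E%03d", i),
               group_id = group_id)
  })))
}

# Brute-force IDI: loop over dyads, then over movements both joined.
oracle_idi <- function(events, norm = "dyadic") {
  out <- list()
  for (g in unique(events$group_id)) {
    eg <- events[events$group_id == g, ]
    ids <- sort(unique(eg$individual_id))
    for (a in ids) for (b in ids) {
      if (a >= b) next
      vals <- c()
      for (ev in unique(eg$event_id)) {
        e <- eg[eg$event_id == ev, ]
        j <- e[e$joined, ]
        if (nrow(j) < 2) next
        times <- setNames(j$latency_s, j$individual_id)
        if (norm == "dyadic") {
          difs <- c()
          nm <- names(times)
          for (x in nm) for (y in nm) {
            if (x < y) difs <- c(difs, abs(times[x] - times[y]))
          }
          m <- mean(difs)
        } else {
          m <- mean(diff(sort(times)))
        }
        if (m == 0) next
        if (a %in% names(times) && b %in% names(times)) {
          vals <- c(vals, abs(times[a] - times[b]) / m)
        }
      }
      if (length(vals)) {
        out[[paste(g, a, b)]] <- data.frame(group_id = g, id_x = a, id_y = b,
                                            idi = mean(vals),
                                            support = length(vals))
      }
    }
  }
  do.call(rbind, out)
}

# Definitional step-down Holm adjustment.
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- numeric(m)
  running <- 0
  for (j in seq_len(m)) {
    running <- max(running, min(1, (m - j + 1) * p[o[j]]))
    adj_sorted[j] <- running
  }
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

# Brute-force Newman weighted categorical assortativity over ordered pairs:
# e_ij = sum over ordered pairs (x, y), x != y, of w_xy / (2 * total weight).
oracle_assort <- function(W, classes) {
  ids <- rownames(W)
  lev <- sort(unique(classes[ids]))
  e <- matrix(0, length(lev), length(lev), dimnames = list(lev, lev))
  for (x in ids) for (y in ids) {
    if (x == y) next
    w <- W[x, y]
    if (is.na(w) || w == 0) next
    e[classes[x], classes[y]] <- e[classes[x], classes[y]] + w
  }
  e <- e / sum(e)
  ab <- sum(rowSums(e) * colSums(e))
  (sum(diag(e)) - ab) / (1 - ab)
}

# Small composition builders
toy_group <- function(n_f = 3, n_m = 3, n_j = 2, group_id = "g") {
  data.frame(group_id = group_id,
             individual_id = paste0(group_id, "_", seq_len(n_f + n_m + n_j)),
             age_sex_class = rep(c("adult_female", "adult_male", "juvenile"),
                                 times = c(n_f, n_m, n_j)))
}
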