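## Domain vocabulary: age-sex classes and the five ordinal distance bins
## used for proximity at departure.

AGE_SEX_LEVELS <- c("adult_female", "adult_male", "juvenile")
DIST_LEVELS <- c("0-1", "1-3", "3-5", "5-10", ">10")
DIST_EDGES <- c(0, 1, 3, 5, 10, Inf)
DIST_MIDPOINTS <- c(`0-1` = 0.5, `1-3` = 2, `3-5` = 4, `5-10` = 7.5, `>10` = 15)

#' Age-sex class levels
#'
#' The three age-sex classes used throughout: adult females, adult males and
#' juveniles (individuals under about 2.5 years).
#'
#' @return Character vector of the three class labels.
#' @export
age_sex_levels <- function() AGE_SEX_LEVELS

#' Ordinal distance categories
#'
#' Inter-individual distances at departure are field-estimated in five ordinal
#' bins: 0-1 m, 1-3 m, 3-5 m, 5-10 m and more than 10 m (half-open
#' \code{[lo, hi)} bins, last bin unbounded).
#'
#' @return Character vector of the five bin labels, in increasing order.
#' @export
distance_levels <- function() DIST_LEVELS

#' Numeric midpoints of the distance categories
#'
#' Midpoints in metres used when the ordinal bins enter a model numerically;
#' the unbounded \code{>10} bin is assigned 15 m.
#'
#' @return Named numeric vector (metres), one entry per bin.
#' @export
distance_midpoints <- function() DIST_MIDPOINTS

#' Coerce to a distance-category factor
#'
#' @param x Character vector of bin labels (or an existing factor). Empty
#'   strings and `NA` become missing.
#' @return Ordered factor with the five canonical levels.
#' @export
as_distance_category <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & x == ""] <- NA_character_
  bad <- !is.na(x) & !(x %in% DIST_LEVELS)
  if (any(bad)) {
    stop("unknown distance category: ", paste(unique(x[bad]), collapse = ", "))
  }
  factor(x, levels = DIST_LEVELS, ordered = TRUE)
}

#' Bin metric distances into the five ordinal categories
#'
#' @param d Numeric distances in metres (non-negative).
#' @return Ordered factor over the five bins; edges 0,1,3,5,10 m, half-open.
#' @export
distance_from_metres <- function(d) {
  stopifnot(all(is.na(d) | d >= 0))
  cut(d, breaks = DIST_EDGES, labels = DIST_LEVELS,
      right = FALSE, include.lowest = TRUE, ordered_result = TRUE)
}

## ---------------------------------------------------------------- groups ----

#' Validate a group-composition table
#'
#' A composition table has one row per individual with columns `group_id`,
#' `individual_id` and `age_sex_class`. Individuals must be unique within
#' group, classes must be one of the three canonical levels, and every group
#' must have at least 3 members (an initiator, a follower and some positional
#' structure).
#'
#' @param groups Data frame as described.
#' @param min_size Minimum group size (default 3).
#' @return The validated data frame (invisibly classed columns normalised).
#' @export
validate_groups <- function(groups, min_size = 3L) {
  need <- c("group_id", "individual_id", "age_sex_class")
  miss <- setdiff(need, names(groups))
  if (length(miss)) stop("groups table missing columns: ", paste(miss, collapse = ", "))
  groups$group_id <- as.character(groups$group_id)
  groups$individual_id <- as.character(groups$individual_id)
  cls <- as.character(groups$age_sex_class)
  bad <- !(cls %in% AGE_SEX_LEVELS)
  if (any(bad)) stop("unknown age_sex_class: ", paste(unique(cls[bad]), collapse = ", "))
  groups$age_sex_class <- factor(cls, levels = AGE_SEX_LEVELS)
  dup <- duplicated(groups[c("group_id", "individual_id")])
  if (any(dup)) stop("duplicate individual within group: ",
                     paste(groups$individual_id[dup], collapse = ", "))
  sz <- table(groups$group_id)
  if (any(sz < min_size)) {
    stop("group(s) smaller than ", min_size, ": ",
         paste(names(sz)[sz < min_size], collapse = ", "))
  }
  groups
}

#' Sizes of each group
#'
#' @param groups Validated composition table.
#' @return Named integer vector of group sizes.
#' @export
group_sizes <- function(groups) {
  tab <- table(as.character(groups$group_id))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Number of within-group dyads
#'
#' Total count of unordered same-group pairs, `sum(choose(n_g, 2))`. The study
#' design of four groups sized 8/6/6/11 yields 113 dyads.
#'
#' @param groups Composition table, or a numeric vector of group sizes.
#' @return Integer dyad count.
#' @export
count_dyads <- function(groups) {
  sizes <- if (is.data.frame(groups)) group_sizes(groups) else as.integer(groups)
  if (any(sizes < 2)) stop("all group sizes must be >= 2")
  as.integer(sum(choose(sizes, 2)))
}

#' Read / write group compositions
#'
#' CSV columns: `group_id, individual_id, age_sex_class`.
#'
#' @param path File path.
#' @param groups Composition table.
#' @param min_size Passed to [validate_groups()].
#' @return `read_groups` returns the validated table; `write_groups` returns
#'   `path` invisibly.
#' @export
read_groups <- function(path, min_size = 3L) {
  validate_groups(read.csv(path, colClasses = "character"), min_size = min_size)
}

#' @rdname read_groups
#' @export
write_groups <- function(groups, path) {
  groups <- validate_groups(groups)
  out <- data.frame(group_id = groups$group_id,
                    individual_id = groups$individual_id,
                    age_sex_class = as.character(groups$age_sex_class))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------- events ----

JOIN_WINDOW_S <- 600

#' Joining window
#'
#' A group member counts as a follower only if it departs within 10 minutes
#' (600 s) of the initiator.
#'
#' @return 600 (seconds).
#' @export
join_window_s <- function() JOIN_WINDOW_S

#' Validate a departure-event table
#'
#' One row per (event, individual). Enforced invariants: exactly one initiator
#' per event with latency 0; joined rows carry a latency in `[0, 600]` s;
#' non-joined rows carry no latency; no duplicate (event, individual) rows;
#' at least one follower per event (a successful initiation recruits at least
#' one follower); if a composition table is supplied, each event's rows cover
#' that group's members exactly. Departure ranks are recomputed from latencies
#' with competition ranking (ties share the minimum rank); a `rank` column in
#' the input, if present, must agree.
#'
#' @param events Data frame with columns `event_id, group_id, individual_id,
#'   is_initiator, joined, latency_s, dist_to_initiator, dist_to_predecessor`.
#' @param groups Optional composition table for coverage checks.
#' @return Validated events table with recomputed integer `rank` column
#'   (`NA` for non-joiners).
#' @export
validate_events <- function(events, groups = NULL) {
  need <- c("event_id", "group_id", "individual_id", "is_initiator", "joined",
            "latency_s")
  miss <- setdiff(need, names(events))
  if (length(miss)) stop("events table missing columns: ", paste(miss, collapse = ", "))
  events$event_id <- as.character(events$event_id)
  events$group_id <- as.character(events$group_id)
  events$individual_id <- as.character(events$individual_id)
  events$is_initiator <- as.logical(events$is_initiator)
  events$joined <- as.logical(events$joined)
  events$latency_s <- as.numeric(events$latency_s)
  if (!"dist_to_initiator" %in% names(events)) events$dist_to_initiator <- NA_character_
  if (!"dist_to_predecessor" %in% names(events)) events$dist_to_predecessor <- NA_character_
  events$dist_to_initiator <- as_distance_category(events$dist_to_initiator)
  events$dist_to_predecessor <- as_distance_category(events$dist_to_predecessor)

  dup <- duplicated(events[c("event_id", "individual_id")])
  if (any(dup)) {
    stop("duplicate (event, individual) rows: ",
         paste(unique(events$event_id[dup]), collapse = ", "))
  }
  if (anyNA(events$is_initiator) || anyNA(events$joined)) {
    stop("is_initiator/joined must be TRUE or FALSE")
  }
  bad_init <- events$is_initiator &
    (!events$joined | is.na(events$latency_s) | events$latency_s != 0)
  if (any(bad_init)) stop("initiator latency must be 0 (and joined): event ",
                          paste(unique(events$event_id[bad_init]), collapse = ", "))
  bad_lat <- events$joined & is.na(events$latency_s)
  if (any(bad_lat)) stop("joined row with missing latency: event ",
                         paste(unique(events$event_id[bad_lat]), collapse = ", "))
  bad_win <- events$joined & !is.na(events$latency_s) &
    (events$latency_s < 0 | events$latency_s > JOIN_WINDOW_S)
  if (any(bad_win)) {
    stop("ambiguous record: joined=TRUE with latency outside [0, ",
         JOIN_WINDOW_S, "] s: event ",
         paste(unique(events$event_id[bad_win]), collapse = ", "))
  }
  bad_nj <- !events$joined & !is.na(events$latency_s)
  if (any(bad_nj)) stop("non-joined row carries a latency: event ",
                        paste(unique(events$event_id[bad_nj]), collapse = ", "))

  given_rank <- if ("rank" %in% names(events)) as.integer(events$rank) else NULL
  events$rank <- NA_integer_
  for (ev in unique(events$event_id)) {
    idx <- which(events$event_id == ev)
    if (sum(events$is_initiator[idx]) != 1L) {
      stop("event ", ev, " must have exactly one initiator")
    }
    j <- idx[events$joined[idx]]
    if (length(j) < 2L) stop("event ", ev, " has no followers (failed initiation)")
    events$rank[j] <- as.integer(rank(events$latency_s[j], ties.method = "min"))
    gid <- unique(events$group_id[idx])
    if (length(gid) != 1L) stop("event ", ev, " spans multiple groups")
    if (!is.null(groups)) {
      members <- groups$individual_id[groups$group_id == gid]
      if (!setequal(events$individual_id[idx], members) ||
          length(idx) != length(members)) {
        stop("event ", ev, " rows do not cover group ", gid, " exactly")
      }
    }
  }
  if (!is.null(given_rank)) {
    chk <- !is.na(given_rank) & !is.na(events$rank) & given_rank != events$rank
    if (any(chk)) stop("rank column disagrees with ranks recomputed from latencies: event ",
                       paste(unique(events$event_id[chk]), collapse = ", "))
  }
  events
}

#' Read / write departure-event tables
#'
#' CSV columns: `event_id, group_id, individual_id, is_initiator, joined,
#' latency_s, dist_to_initiator, dist_to_predecessor`. Logicals are written as
#' `true`/`false`, missing values as empty fields; latencies are numeric
#' seconds written at full precision so a write/read cycle is lossless.
#'
#' @param path File path.
#' @param events Events table.
#' @param groups Optional composition table for coverage validation.
#' @return `read_events` returns a validated events table (with recomputed
#'   ranks); `write_events` returns `path` invisibly.
#' @export
read_events <- function(path, groups = NULL) {
  raw <- read.csv(path, colClasses = "character")
  raw$is_initiator <- raw$is_initiator == "true"
  raw$joined <- raw$joined == "true"
  raw$latency_s <- suppressWarnings(as.numeric(ifelse(raw$latency_s == "",
                                                      NA, raw$latency_s)))
  validate_events(raw, groups = groups)
}

#' @rdname read_events
#' @export
write_events <- function(events, path) {
  events <- validate_events(events)
  fmt_num <- function(x) ifelse(is.na(x), "", format(x, digits = 17, trim = TRUE,
                                                     scientific = FALSE))
  out <- data.frame(
    event_id = events$event_id,
    group_id = events$group_id,
    individual_id = events$individual_id,
    is_initiator = ifelse(events$is_initiator, "true", "false"),
    joined = ifelse(events$joined, "true", "false"),
    latency_s = fmt_num(events$latency_s),
    dist_to_initiator = ifelse(is.na(events$dist_to_initiator), "",
                               as.character(events$dist_to_initiator)),
    dist_to_predecessor = ifelse(is.na(events$dist_to_predecessor), "",
                                 as.character(events$dist_to_predecessor)))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-event summary
#'
#' @param events Validated events table.
#' @return Data frame with one row per event: `event_id, group_id, n_members,
#'   n_joined, n_followers, initiator_id, last_latency_s, full_group`.
#' @export
event_table <- function(events) {
  evs <- unique(events$event_id)
  rows <- lapply(evs, function(ev) {
    e <- events[events$event_id == ev, ]
    j <- e[e$joined, ]
    data.frame(event_id = ev,
               group_id = e$group_id[1],
               n_members = nrow(e),
               n_joined = nrow(j),
               n_followers = nrow(j) - 1L,
               initiator_id = e$individual_id[e$is_initiator],
               last_latency_s = max(j$latency_s),
               full_group = nrow(j) == nrow(e))
  })
  do.call(rbind, rows)
}

## ----------------------------------------------------------------- scans ----

#' Construct a scan dataset
#'
#' A scan dataset holds instantaneous group scans: per scan the set of visible
#' individuals, plus long-form grooming/huddling interaction records. Each
#' interacting dyad must be within the scan's visible set, and a dyad appears
#' at most once per behaviour per scan.
#'
#' @param scans Data frame `scan_id, group_id, visible_ids` (`visible_ids` a
#'   semicolon-joined id string).
#' @param interactions Data frame `scan_id, group_id, behaviour, id_x, id_y`
#'   with behaviour in `grooming`/`huddling`.
#' @return Object of class `scan_dataset`.
#' @export
scan_dataset <- function(scans, interactions) {
  obj <- structure(list(scans = scans, interactions = interactions),
                   class = "scan_dataset")
  validate_scans(obj)
}

#' Validate a scan dataset
#'
#' @param x A `scan_dataset`.
#' @return The validated object.
#' @export
validate_scans <- function(x) {
  stopifnot(inherits(x, "scan_dataset"))
  sc <- x$scans
  need <- c("scan_id", "group_id", "visible_ids")
  miss <- setdiff(need, names(sc))
  if (length(miss)) stop("scans table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(sc$scan_id)) stop("duplicate scan_id")
  it <- x$interactions
  needi <- c("scan_id", "behaviour", "id_x", "id_y")
  missi <- setdiff(needi, names(it))
  if (length(missi)) stop("interactions table missing columns: ",
                          paste(missi, collapse = ", "))
  if (nrow(it)) {
    bad_b <- !(it$behaviour %in% c("grooming", "huddling"))
    if (any(bad_b)) stop("unknown behaviour: ", paste(unique(it$behaviour[bad_b]),
                                                      collapse = ", "))
    if (any(it$id_x == it$id_y)) stop("self-dyad in interactions")
    ## canonical unordered pairs
    swap <- it$id_x > it$id_y
    tmp <- it$id_x[swap]; it$id_x[swap] <- it$id_y[swap]; it$id_y[swap] <- tmp
    key <- paste(it$scan_id, it$behaviour, it$id_x, it$id_y)
    if (anyDuplicated(key)) stop("dyad recorded twice for one behaviour in one scan")
    vis <- split_ids(sc$visible_ids)
    names(vis) <- sc$scan_id
    for (i in seq_len(nrow(it))) {
      v <- vis[[it$scan_id[i]]]
      if (is.null(v)) stop("interaction references unknown scan ", it$scan_id[i])
      if (!(it$id_x[i] %in% v) || !(it$id_y[i] %in% v)) {
        stop("interacting dyad not within visible set in scan ", it$scan_id[i])
      }
    }
    x$interactions <- it
  }
  x
}

split_ids <- function(s) strsplit(as.character(s), ";", fixed = TRUE)

join_ids <- function(ids) paste(sort(ids), collapse = ";")

#' @export
print.scan_dataset <- function(x, ...) {
  cat("<scan_dataset> ", nrow(x$scans), " scans, ",
      nrow(x$interactions), " interaction records, groups: ",
      paste(unique(x$scans$group_id), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read / write scan datasets
#'
#' CSV columns: `scan_id, group_id, visible_ids, behaviour, id_x, id_y`; one
#' row per interaction, and a single row with behaviour `none` for scans
#' without interactions.
#'
#' @param path File path.
#' @param x A `scan_dataset`.
#' @return `read_scans` returns a validated `scan_dataset`; `write_scans`
#'   returns `path` invisibly.
#' @export
read_scans <- function(path) {
  raw <- read.csv(path, colClasses = "character")
  key <- !duplicated(raw$scan_id)
  scans <- data.frame(scan_id = raw$scan_id[key],
                      group_id = raw$group_id[key],
                      visible_ids = raw$visible_ids[key])
  it <- raw[raw$behaviour %in% c("grooming", "huddling"), ]
  interactions <- data.frame(scan_id = it$scan_id, group_id = it$group_id,
                             behaviour = it$behaviour,
                             id_x = it$id_x, id_y = it$id_y)
  scan_dataset(scans, interactions)
}

#' @rdname read_scans
#' @export
write_scans <- function(x, path) {
  x <- validate_scans(x)
  sc <- x$scans
  it <- x$interactions
  base <- sc[!(sc$scan_id %in% it$scan_id), , drop = FALSE]
  rows <- list()
  if (nrow(base)) {
    rows[[1]] <- data.frame(scan_id = base$scan_id, group_id = base$group_id,
                            visible_ids = base$visible_ids,
                            behaviour = "none", id_x = "", id_y = "")
  }
  if (nrow(it)) {
    vis <- sc$visible_ids[match(it$scan_id, sc$scan_id)]
    rows[[length(rows) + 1L]] <- data.frame(scan_id = it$scan_id,
                                            group_id = it$group_id,
                                            visible_ids = vis,
                                            behaviour = it$behaviour,
                                            id_x = it$id_x, id_y = it$id_y)
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(out$scan_id, sc$scan_id), out$behaviour, out$id_x), ]
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
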