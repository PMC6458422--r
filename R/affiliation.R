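## Affiliation metrics: dyadic interaction rates from group scans, the
## composite sociability index (DSI), its distribution summary, and weighted
## categorical assortativity of the affiliation network.

#' Dyadic interaction rate from group scans
#'
#' For each dyad, the proportion of scans in which the pair was engaged in the
#' behaviour, corrected for observation effort: the denominator is the number
#' of scans in which both individuals were visible (the dyad's support). Dyads
#' never co-visible get a missing rate, not zero.
#'
#' @param scans A `scan_dataset` (may span several groups).
#' @param behaviour `"grooming"` or `"huddling"`.
#' @param groups Optional composition table supplying each group's full
#'   roster; if omitted the roster is the union of ids ever visible.
#' @return Named list of `dyad_matrix` objects (one per group), labelled
#'   `<behaviour>_rate`.
#' @export
dyadic_rate <- function(scans, behaviour = c("grooming", "huddling"),
                        groups = NULL) {
  behaviour <- match.arg(behaviour)
  scans <- validate_scans(scans)
  sc <- scans$scans
  it <- scans$interactions
  it <- it[it$behaviour == behaviour, , drop = FALSE]
  gids <- sort(unique(sc$group_id))
  vis_list <- split_ids(sc$visible_ids)
  out <- list()
  for (g in gids) {
    in_g <- sc$group_id == g
    ids <- if (!is.null(groups)) {
      sort(groups$individual_id[groups$group_id == g])
    } else {
      sort(unique(unlist(vis_list[in_g])))
    }
    n <- length(ids)
    S <- matrix(0L, n, n, dimnames = list(ids, ids))
    for (v in vis_list[in_g]) {
      v <- intersect(v, ids)
      if (length(v) >= 2) S[v, v] <- S[v, v] + 1L
    }
    diag(S) <- 0L
    C <- matrix(0L, n, n, dimnames = list(ids, ids))
    itg <- it[it$scan_id %in% sc$scan_id[in_g], , drop = FALSE]
    if (nrow(itg)) {
      for (i in seq_len(nrow(itg))) {
        x <- itg$id_x[i]; y <- itg$id_y[i]
        C[x, y] <- C[x, y] + 1L; C[y, x] <- C[y, x] + 1L
      }
    }
    V <- ifelse(S > 0, C / S, NA_real_)
    dimnames(V) <- dimnames(S)
    out[[g]] <- dyad_matrix(V, S, group_id = g,
                            label = paste0(behaviour, "_rate"))
  }
  out
}

#' Dyadic composite sociability index
#'
#' The DSI of a dyad is the mean of its normalised grooming and huddling
#' rates, each divided by the group mean of that rate over dyads with a
#' defined rate: `DSI_xy = ((g_xy / g_bar) + (h_xy / h_bar)) / 2`. By
#' construction the group mean DSI is 1 whenever all dyads have defined rates.
#' If one behaviour was never observed in a group (group mean 0) that
#' component is dropped with a warning and the DSI is the remaining normalised
#' rate; if neither behaviour was observed the index is undefined.
#'
#' @param grooming,huddling `dyad_matrix` objects (or parallel named lists) on
#'   the same dyad set.
#' @return `dyad_matrix` labelled `"dsi"` (or a named list of them); support
#'   is the elementwise minimum of the two rates' supports.
#' @export
compute_dsi <- function(grooming, huddling) {
  if (!is_dyad_matrix(grooming)) {
    stopifnot(identical(names(grooming), names(huddling)))
    return(Map(compute_dsi, grooming, huddling))
  }
  stopifnot(is_dyad_matrix(huddling), identical(grooming$ids, huddling$ids))
  g <- grooming$value; h <- huddling$value
  gbar <- mean(g[upper.tri(g)], na.rm = TRUE)
  hbar <- mean(h[upper.tri(h)], na.rm = TRUE)
  if (is.nan(gbar)) gbar <- 0
  if (is.nan(hbar)) hbar <- 0
  if (gbar == 0 && hbar == 0) {
    stop("no affiliative interactions observed in group ", grooming$group_id)
  }
  if (gbar == 0 || hbar == 0) {
    dropped <- if (gbar == 0) "grooming" else "huddling"
    warning("group ", grooming$group_id, ": ", dropped,
            " never observed; DSI uses the remaining behaviour only")
    V <- if (gbar == 0) h / hbar else g / gbar
  } else {
    V <- (g / gbar + h / hbar) / 2
  }
  S <- pmin(grooming$support, huddling$support)
  V[S == 0] <- NA_real_
  dimnames(V) <- list(grooming$ids, grooming$ids)
  dimnames(S) <- dimnames(V)
  dyad_matrix(V, S, group_id = grooming$group_id, label = "dsi")
}

#' Summary of the DSI distribution across dyads
#'
#' Affiliation in wild groups is typically concentrated in few dyads, giving a
#' right-skewed DSI distribution: the median falls below the construction
#' mean of 1 and only a minority of dyads exceed the mean. The summary reports
#' mean, median, the fraction of dyads strictly above the mean, and adjusted
#' Fisher-Pearson skewness.
#'
#' @param dsi A `dyad_matrix` (label `dsi`) or named list of them.
#' @return Data frame with one row per group: `group_id, n_dyads, mean,
#'   median, fraction_above_mean, skewness` (skewness `NA` with fewer than 3
#'   dyads).
#' @export
dsi_summary <- function(dsi) {
  if (is_dyad_matrix(dsi)) dsi <- list(dsi)
  rows <- lapply(dsi, function(dm) {
    v <- dyad_values(dm, na.rm = TRUE)
    if (length(v) < 2) stop("dsi_summary needs at least 2 defined dyads (group ",
                            dm$group_id, ")")
    m <- mean(v)
    data.frame(group_id = dm$group_id,
               n_dyads = length(v),
               mean = m,
               median = median(v),
               fraction_above_mean = mean(v > m),
               skewness = if (length(v) >= 3) e1071::skewness(v, type = 2) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Weighted assortativity by a categorical node attribute
#'
#' Newman's weighted assortativity coefficient for categorical attributes on
#' a weighted undirected network. The class mixing matrix `e` allocates each
#' unordered dyad's weight once: within-class weight to the diagonal cell,
#' between-class weight split 50/50 across the two symmetric off-diagonal
#' cells; `e` is then normalised to sum 1 and
#' `r = (sum_i e_ii - sum_i a_i b_i) / (1 - sum_i a_i b_i)` with
#' `a = rowSums(e)`, `b = colSums(e)`. `r = 1` iff all weight is within-class;
#' disassortative networks give `r < 0`.
#'
#' @param weights A `dyad_matrix` of non-negative edge weights (missing dyads
#'   contribute nothing).
#' @param classes Named character vector or factor mapping individual id to
#'   class; must cover the matrix's ids and contain at least 2 distinct
#'   classes among them.
#' @return List with `group_id`, `attribute`, `r_weighted`, and the normalised
#'   `mixing_matrix`.
#' @export
weighted_assortativity <- function(weights, classes) {
  stopifnot(is_dyad_matrix(weights))
  cls <- as.character(classes)[match(weights$ids, names(classes))]
  if (anyNA(cls)) stop("classes must be a named vector covering all individuals")
  lev <- sort(unique(cls))
  if (length(lev) < 2) stop("assortativity undefined with a single class")
  e <- matrix(0, length(lev), length(lev), dimnames = list(lev, lev))
  ut <- which(upper.tri(weights$value), arr.ind = TRUE)
  for (k in seq_len(nrow(ut))) {
    w <- weights$value[ut[k, 1], ut[k, 2]]
    if (is.na(w) || w == 0) next
    if (w < 0) stop("assortativity requires non-negative weights")
    ci <- cls[ut[k, 1]]; cj <- cls[ut[k, 2]]
    if (ci == cj) {
      e[ci, ci] <- e[ci, ci] + w
    } else {
      e[ci, cj] <- e[ci, cj] + w / 2
      e[cj, ci] <- e[cj, ci] + w / 2
    }
  }
  tot <- sum(e)
  if (tot <= 0) stop("total edge weight must be positive")
  e <- e / tot
  ab <- sum(rowSums(e) * colSums(e))
  r <- (sum(diag(e)) - ab) / (1 - ab)
  list(group_id = weights$group_id, attribute = "age_sex_class",
       r_weighted = r, mixing_matrix = e)
}
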