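## Statistical models for the departure analyses, with node-permutation
## inference for dyadic regressions (individual labels shuffled within group,
## dyadic structure preserved) and Holm correction across each model family.
## Mixed-effect structures are fit with lmerTest when the data support them;
## otherwise a fixed-effects fit is used and reported as such.

new_dep_model <- function(model_name, coefficients, n_obs,
                          transform = "none", fit_method = "lm",
                          permutation_p = NULL, n_permutations = 0L,
                          extra = list()) {
  structure(c(list(model_name = model_name, coefficients = coefficients,
                   n_obs = n_obs, transform = transform,
                   fit_method = fit_method, permutation_p = permutation_p,
                   n_permutations = n_permutations), extra),
            class = "dep_model")
}

#' @export
print.dep_model <- function(x, ...) {
  cat("<dep_model> ", x$model_name, " (", x$fit_method, ", n = ", x$n_obs,
      if (x$transform != "none") paste0(", transform = ", x$transform), ")\n",
      sep = "")
  print(x$coefficients, digits = 4)
  if (!is.null(x$permutation_p)) {
    cat("permutation p (", x$n_permutations, " node permutations): ",
        paste(names(x$permutation_p), signif(unlist(x$permutation_p), 3),
              sep = " = ", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Holm step-down multiple-testing correction
#'
#' Familywise step-down adjustment: with the raw p-values sorted ascending,
#' `adjusted_i = max_{j <= i} min(1, (m - j + 1) * p_(j))`. Adjusted values
#' are never below the raw ones and preserve the step-down ordering.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`, optionally named.
#' @return List with `family` (data frame `id, p_raw, p_adjusted`) and
#'   `adjusted` (named vector in input order).
#' @export
holm_adjust <- function(p) {
  p <- unlist(p)
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  ids <- if (is.null(names(p))) paste0("test", seq_along(p)) else names(p)
  adj <- p.adjust(p, method = "holm")
  names(adj) <- ids
  list(family = data.frame(id = ids, p_raw = unname(p), p_adjusted = unname(adj)),
       adjusted = adj)
}

## --- node-permutation machinery -------------------------------------------

## Permute individual labels within each group and re-read dyadic values:
## value*(x, y) = value(sigma(x), sigma(y)). Missing dyads in the source
## matrix are imputed at the group mean for permuted draws only (they are
## excluded from the observed fit).
make_perm_reader <- function(dyad_mats, group_of_obs, id_x, id_y) {
  groups <- unique(group_of_obs)
  per_group <- lapply(groups, function(g) {
    dm <- dyad_mats[[g]]
    if (is.null(dm)) stop("no dyadic matrix for group ", g)
    V <- dm$value
    mu <- mean(V[upper.tri(V)], na.rm = TRUE)
    V[is.na(V)] <- mu
    rows <- which(group_of_obs == g)
    list(V = V, rows = rows,
         ix = match(id_x[rows], dm$ids), iy = match(id_y[rows], dm$ids),
         n = length(dm$ids))
  })
  names(per_group) <- groups
  function() {
    out <- numeric(length(group_of_obs))
    for (pg in per_group) {
      sg <- sample.int(pg$n)
      out[pg$rows] <- pg$V[cbind(sg[pg$ix], sg[pg$iy])]
    }
    out
  }
}

## Two-sided permutation p for the coefficient of `d` in lm(y ~ d + X_other),
## via Frisch-Waugh residualisation on the fixed covariates.
perm_coef_p <- function(y, d, X_other, reader, n_perm) {
  qrX <- qr(X_other)
  ry <- qr.resid(qrX, y)
  rd <- qr.resid(qrX, d)
  b_obs <- sum(ry * rd) / sum(rd^2)
  if (n_perm < 1) return(list(b = b_obs, p = NULL))
  hits <- 0L
  for (k in seq_len(n_perm)) {
    dstar <- reader()
    rds <- qr.resid(qrX, dstar)
    den <- sum(rds^2)
    bstar <- if (den > 0) sum(ry * rds) / den else 0
    if (abs(bstar) >= abs(b_obs) - 1e-12) hits <- hits + 1L
  }
  list(b = b_obs, p = (hits + 1) / (n_perm + 1))
}

lm_coef_table <- function(fit, conf_level = 0.95) {
  s <- suppressWarnings(summary(fit))$coefficients
  ci <- suppressMessages(suppressWarnings(confint(fit, level = conf_level)))
  ci <- ci[rownames(s), , drop = FALSE]
  data.frame(term = rownames(s), estimate = s[, 1], se = s[, 2],
             ci_lower = ci[, 1], ci_upper = ci[, 2],
             p_value = s[, ncol(s)], row.names = NULL)
}

lmer_coef_table <- function(fit, conf_level = 0.95) {
  s <- coef(summary(fit))
  z <- qnorm(1 - (1 - conf_level) / 2)
  data.frame(term = rownames(s), estimate = s[, "Estimate"],
             se = s[, "Std. Error"],
             ci_lower = s[, "Estimate"] - z * s[, "Std. Error"],
             ci_upper = s[, "Estimate"] + z * s[, "Std. Error"],
             p_value = s[, "Pr(>|t|)"], row.names = NULL)
}

try_lmer <- function(formula, data) {
  tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(formula, data = data,
                     control = lme4::lmerControl(check.conv.singular = "ignore",
                                                 calc.derivs = FALSE)))),
    error = function(e) NULL)
}

## --- the model contracts ---------------------------------------------------

#' Regress travel association (IDI) on affiliation (DSI)
#'
#' Linear fit of dyadic IDI on dyadic DSI with group as a fixed factor, over
#' dyads with a defined DSI and an IDI supported by at least `min_support`
#' shared movements. Because dyadic observations are non-independent, the
#' DSI coefficient's p-value comes from node-label permutations within group
#' (two-sided). Affiliative mimetism predicts a negative coefficient: closely
#' bonded dyads depart in closer succession.
#'
#' @param idi,dsi Named lists of `dyad_matrix` objects per group, as returned
#'   by [compute_idi()] and [compute_dsi()].
#' @param min_support Minimum number of shared movements for a dyad's IDI.
#' @param n_perm Number of node permutations (0 disables).
#' @param conf_level Confidence level for the Wald interval.
#' @return A `dep_model`; `permutation_p["dsi"]` carries the permutation
#'   p-value.
#' @export
fit_idi_on_dsi <- function(idi, dsi, min_support = 5, n_perm = 2000,
                           conf_level = 0.95) {
  stopifnot(identical(sort(names(idi)), sort(names(dsi))))
  di <- dyad_df(idi)
  names(di)[names(di) == "value"] <- "idi"
  dd <- dyad_df(dsi)
  names(dd)[names(dd) == "value"] <- "dsi"
  tab <- merge(di, dd[c("group_id", "id_x", "id_y", "dsi")],
               by = c("group_id", "id_x", "id_y"))
  tab <- tab[!is.na(tab$idi) & !is.na(tab$dsi) & tab$support >= min_support, ]
  if (nrow(tab) < 10) stop("fewer than 10 usable dyads")
  tab$group_id <- factor(tab$group_id)
  multi <- nlevels(tab$group_id) > 1
  fit <- if (multi) lm(idi ~ dsi + group_id, data = tab) else
    lm(idi ~ dsi, data = tab)
  X_other <- model.matrix(if (multi) ~group_id else ~1, data = tab)
  reader <- make_perm_reader(dsi, as.character(tab$group_id), tab$id_x, tab$id_y)
  pr <- perm_coef_p(tab$idi, tab$dsi, X_other, reader, n_perm)
  new_dep_model("idi_on_dsi", lm_coef_table(fit, conf_level), nrow(tab),
                fit_method = "lm",
                permutation_p = if (n_perm >= 1) list(dsi = pr$p) else NULL,
                n_permutations = n_perm,
                extra = list(data = tab))
}

#' Follower-level observation table
#'
#' One row per follower per movement with departure rank, latency, initiator,
#' predecessor (the previous departer, including the initiator), the recorded
#' distance categories, and the follower's age-sex class.
#'
#' @param events Validated events table.
#' @param groups Composition table.
#' @return Data frame `event_id, group_id, group_size, individual_id,
#'   age_sex_class, rank, n_predecessors, latency_s, initiator_id,
#'   predecessor_id, predecessor_latency_s, dist_to_initiator,
#'   dist_to_predecessor`.
#' @export
follower_rows <- function(events, groups) {
  groups <- validate_groups(groups)
  sizes <- group_sizes(groups)
  cls <- setNames(as.character(groups$age_sex_class), groups$individual_id)
  rows <- lapply(unique(events$event_id), function(ev) {
    e <- events[events$event_id == ev, ]
    j <- e[e$joined, ]
    j <- j[order(j$rank, j$individual_id), ]
    ini <- e$individual_id[e$is_initiator]
    k <- nrow(j)
    data.frame(event_id = ev, group_id = e$group_id[1],
               group_size = sizes[[e$group_id[1]]],
               individual_id = j$individual_id[-1],
               age_sex_class = cls[j$individual_id[-1]],
               rank = j$rank[-1],
               n_predecessors = seq_len(k - 1L),
               latency_s = j$latency_s[-1],
               initiator_id = ini,
               predecessor_id = j$individual_id[-k],
               predecessor_latency_s = j$latency_s[-k],
               dist_to_initiator = as.character(j$dist_to_initiator[-1]),
               dist_to_predecessor = as.character(j$dist_to_predecessor[-1]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Regress normalised following latency on proximity
#'
#' Spatial mimetism predicts that individuals follow more quickly those in
#' closer proximity. The following latency is the time since the reference
#' individual departed: the latency from initiation for the initiator model,
#' and the gap since the predecessor's departure for the predecessor model.
#' It is divided by the mean following latency of its departure event (so
#' every event has pre-transform mean 1), square-root transformed for the
#' predecessor model and log-transformed for the initiator model. Fixed effects are the distance
#' category (reference 0-1 m) and the follower's age-sex class (reference
#' juvenile). Only departures with complete distance data for all followers
#' enter, to avoid a biased sample. Random intercepts (predecessor/initiator,
#' follower, event, and number-of-predecessors-in-group-size or group size)
#' are used when the mixed solver succeeds; otherwise the fixed-effects fit
#' is reported, flagged by `fit_method`. Per-model p-values are
#' Holm-adjusted over the non-intercept terms.
#'
#' @param events Validated events table.
#' @param groups Composition table.
#' @param reference `"predecessor"` or `"initiator"`.
#' @param method `"auto"` (try mixed, fall back), `"lmer"`, or `"lm"`.
#' @param conf_level Confidence level.
#' @return A `dep_model` with an extra `p_holm` column in `coefficients` and
#'   the number of retained events in `n_events`.
#' @export
fit_latency_on_distance <- function(events, groups,
                                    reference = c("predecessor", "initiator"),
                                    method = c("auto", "lmer", "lm"),
                                    conf_level = 0.95) {
  reference <- match.arg(reference)
  method <- match.arg(method)
  fr <- follower_rows(events, groups)
  dist_col <- if (reference == "predecessor") "dist_to_predecessor" else
    "dist_to_initiator"
  ## completeness filter: keep events where every follower has the distance
  ok_ev <- tapply(!is.na(fr[[dist_col]]), fr$event_id, all)
  fr <- fr[fr$event_id %in% names(ok_ev)[ok_ev], , drop = FALSE]
  if (!nrow(fr)) stop("no departures with complete ", reference, " distance data")
  fr$follow_latency_s <- if (reference == "predecessor") {
    fr$latency_s - fr$predecessor_latency_s
  } else {
    fr$latency_s
  }
  mu <- tapply(fr$follow_latency_s, fr$event_id, mean)
  fr$y_norm <- fr$follow_latency_s / mu[fr$event_id]
  if (any(fr$y_norm <= 0)) stop("follower latencies must be positive")
  transform <- if (reference == "predecessor") "sqrt" else "log"
  fr$y_t <- if (transform == "sqrt") sqrt(fr$y_norm) else log(fr$y_norm)
  fr$dist <- factor(fr[[dist_col]], levels = DIST_LEVELS)
  fr$dist <- droplevels(fr$dist)
  fr$cls <- factor(fr$age_sex_class,
                   levels = c("juvenile", "adult_female", "adult_male"))
  fr$cls <- droplevels(fr$cls)
  fr <- fr[order(fr$event_id, fr$rank, fr$individual_id), ]

  fe <- y_t ~ dist + cls
  fit <- NULL
  fit_method <- "lm"
  if (method %in% c("auto", "lmer")) {
    fr$size_stratum <- if (reference == "predecessor") {
      interaction(fr$group_size, fr$n_predecessors, drop = TRUE)
    } else {
      factor(fr$group_size)
    }
    ref_id <- if (reference == "predecessor") "predecessor_id" else "initiator_id"
    fml <- as.formula(paste(
      "y_t ~ dist + cls + (1|", ref_id,
      ") + (1|individual_id) + (1|event_id) + (1|size_stratum)"))
    fit <- try_lmer(fml, fr)
    if (!is.null(fit)) fit_method <- "lmer"
    if (is.null(fit) && method == "lmer") stop("mixed model failed to fit")
  }
  if (is.null(fit)) fit <- lm(fe, data = fr)
  tab <- if (fit_method == "lmer") lmer_coef_table(fit, conf_level) else
    lm_coef_table(fit, conf_level)
  nonint <- tab$term != "(Intercept)"
  tab$p_holm <- NA_real_
  if (any(nonint)) {
    tab$p_holm[nonint] <- holm_adjust(setNames(tab$p_value[nonint],
                                               tab$term[nonint]))$adjusted
  }
  new_dep_model(paste0("latency_on_distance_", reference), tab, nrow(fr),
                transform = transform, fit_method = fit_method,
                extra = list(n_events = length(unique(fr$event_id)), data = fr))
}

#' Regress last-follower latency on group size
#'
#' Over departures in which the entire group followed, the time from
#' initiation to the last joiner is modelled as a function of group size
#' (random intercepts for initiator and last-follower identity when the mixed
#' solver succeeds). A positive slope means larger groups take longer to
#' complete a departure. A likelihood-ratio test against the null (intercept
#' only) model is reported.
#'
#' @param events Validated events table.
#' @param groups Composition table (at least two distinct group sizes).
#' @param method `"auto"`, `"lmer"` or `"lm"`.
#' @param conf_level Confidence level.
#' @return A `dep_model`; extras `lrt_statistic`, `lrt_df`, `lrt_p`.
#' @export
fit_last_latency_on_group_size <- function(events, groups,
                                           method = c("auto", "lmer", "lm"),
                                           conf_level = 0.95) {
  method <- match.arg(method)
  cs <- cohesion_summary(events, groups)
  lf <- cs$last_follower
  if (is.null(lf) || !nrow(lf)) stop("no full-group departures")
  if (length(unique(lf$group_size)) < 2) {
    stop("group size has no variation across full-group departures")
  }
  fit <- NULL
  fit_method <- "lm"
  lrt <- c(NA_real_, NA_real_, NA_real_)
  if (method %in% c("auto", "lmer")) {
    fit <- try_lmer(last_latency_s ~ group_size + (1 | initiator_id) +
                      (1 | last_id), lf)
    if (!is.null(fit)) {
      fit_method <- "lmer"
      m1 <- suppressMessages(suppressWarnings(
        lme4::refitML(fit)))
      m0 <- try_lmer(last_latency_s ~ 1 + (1 | initiator_id) + (1 | last_id), lf)
      if (!is.null(m0)) {
        a <- suppressMessages(suppressWarnings(
          anova(lme4::refitML(m0), m1)))
        lrt <- c(a$Chisq[2], a$Df[2], a$`Pr(>Chisq)`[2])
      }
    } else if (method == "lmer") {
      stop("mixed model failed to fit")
    }
  }
  if (is.null(fit)) {
    fit <- lm(last_latency_s ~ group_size, data = lf)
    m0 <- lm(last_latency_s ~ 1, data = lf)
    a <- anova(m0, fit)
    lrt <- c(a$F[2], a$Df[2], a$`Pr(>F)`[2])
  }
  tab <- if (fit_method == "lmer") lmer_coef_table(fit, conf_level) else
    lm_coef_table(fit, conf_level)
  new_dep_model("last_latency_on_group_size", tab, nrow(lf),
                fit_method = fit_method,
                extra = list(lrt_statistic = lrt[1], lrt_df = lrt[2],
                             lrt_p = lrt[3], data = lf))
}

#' Departure-position scores by age-sex class
#'
#' No-intercept linear model of the per-individual position scores on the
#' combined class-by-position factor plus group, followed by pairwise
#' within-position contrasts between the three age-sex classes
#' (familywise-adjusted via the multivariate-t single-step method). A
#' protective travel order shows up as juveniles scoring high in the centre,
#' females in the van and males in the rear.
#'
#' @param scores Long-form score table from [position_scores()].
#' @param conf_level Confidence level for contrast intervals.
#' @return A `dep_model`; `contrasts` holds the pairwise class contrasts per
#'   position with adjusted p-values.
#' @export
fit_position_by_class <- function(scores, conf_level = 0.95) {
  cls_tab <- table(unique(scores[c("individual_id", "age_sex_class")])$age_sex_class)
  need_cls <- setNames(as.integer(cls_tab), names(cls_tab))
  scores$cc <- factor(paste(scores$age_sex_class, scores$position, sep = ":"))
  scores$group_id <- factor(scores$group_id)
  multi <- nlevels(scores$group_id) > 1
  fit <- if (multi) lm(score ~ 0 + cc + group_id, data = scores) else
    lm(score ~ 0 + cc, data = scores)
  cn <- names(coef(fit))
  pairs <- list(c("adult_female", "adult_male"),
                c("adult_female", "juvenile"),
                c("adult_male", "juvenile"))
  K <- list()
  for (pos in POSITION_LEVELS) {
    for (p in pairs) {
      t1 <- paste0("cc", p[1], ":", pos)
      t2 <- paste0("cc", p[2], ":", pos)
      if (!(t1 %in% cn) || !(t2 %in% cn)) {
        warning("class missing for position ", pos, "; contrast ",
                p[1], "-", p[2], " skipped")
        next
      }
      v <- setNames(numeric(length(cn)), cn)
      v[t1] <- 1; v[t2] <- -1
      K[[paste0(pos, ": ", p[1], " - ", p[2])]] <- v
    }
  }
  Km <- do.call(rbind, K)
  if (df.residual(fit) > 0) {
    gl <- multcomp::glht(fit, linfct = Km)
    sg <- summary(gl)
    ci <- confint(gl, level = conf_level)$confint
    contrasts <- data.frame(contrast = rownames(Km),
                            estimate = as.numeric(sg$test$coefficients),
                            se = as.numeric(sg$test$sigma),
                            ci_lower = ci[, "lwr"], ci_upper = ci[, "upr"],
                            p_adjusted = as.numeric(sg$test$pvalues),
                            row.names = NULL)
  } else {
    ## saturated fit: estimates are exact score differences, no inference
    contrasts <- data.frame(contrast = rownames(Km),
                            estimate = as.numeric(Km %*% coef(fit)),
                            se = NA_real_, ci_lower = NA_real_,
                            ci_upper = NA_real_, p_adjusted = NA_real_,
                            row.names = NULL)
  }
  new_dep_model("position_by_class", lm_coef_table(fit, conf_level),
                nrow(scores), fit_method = "lm",
                extra = list(contrasts = contrasts, class_counts = need_cls))
}

#' Regress proximity at departure on affiliation
#'
#' Each follower contributes up to two dyadic observations per departure: its
#' distance category to the initiator and to its predecessor. Distances enter
#' as log bin midpoints (0.5, 2, 4, 7.5, 15 m) regressed on the dyad's DSI,
#' the dyad's age-sex class combination, group, and the observation type
#' (initiator vs predecessor pairing). The DSI term's p-value comes from
#' node-label permutations within group. When affiliation and spatial
#' structure are coupled, closely bonded dyads sit nearer: a negative DSI
#' coefficient.
#'
#' @param events Validated events table.
#' @param dsi Named list of DSI `dyad_matrix` objects per group.
#' @param groups Composition table.
#' @param n_perm Number of node permutations (0 disables).
#' @param conf_level Confidence level.
#' @return A `dep_model`; `permutation_p["dsi"]` carries the permutation p.
#' @export
fit_proximity_on_dsi <- function(events, dsi, groups, n_perm = 2000,
                                 conf_level = 0.95) {
  fr <- follower_rows(events, groups)
  cls <- setNames(as.character(validate_groups(groups)$age_sex_class),
                  groups$individual_id)
  mk <- function(partner, dcol, type) {
    keep <- !is.na(fr[[dcol]])
    if (!any(keep)) return(NULL)
    f <- fr[keep, ]
    data.frame(event_id = f$event_id, group_id = f$group_id,
               id_a = f$individual_id, id_b = f[[partner]],
               distance = f[[dcol]], obs_type = type)
  }
  obs <- rbind(mk("initiator_id", "dist_to_initiator", "initiator"),
               mk("predecessor_id", "dist_to_predecessor", "predecessor"))
  if (is.null(obs) || !nrow(obs)) stop("no distance data recorded")
  obs$log_dist <- log(DIST_MIDPOINTS[obs$distance])
  if (length(unique(obs$distance)) < 2) {
    stop("zero-variance response: all observations in one distance category")
  }
  ## dyadic DSI for each observation
  obs$dsi <- vapply(seq_len(nrow(obs)), function(i) {
    dm <- dsi[[obs$group_id[i]]]
    dm$value[obs$id_a[i], obs$id_b[i]]
  }, numeric(1))
  obs <- obs[!is.na(obs$dsi), , drop = FALSE]
  if (nrow(obs) < 10) stop("fewer than 10 usable observations")
  abbr <- c(adult_female = "f", adult_male = "m", juvenile = "j")
  ca <- abbr[cls[obs$id_a]]; cb <- abbr[cls[obs$id_b]]
  obs$class_combo <- factor(paste0(pmin(ca, cb), pmax(ca, cb)))
  obs$group_id <- factor(obs$group_id)
  obs$obs_type <- factor(obs$obs_type)
  rhs <- c("dsi", "class_combo",
           if (nlevels(obs$group_id) > 1) "group_id",
           if (nlevels(obs$obs_type) > 1) "obs_type")
  fit <- lm(reformulate(rhs, response = "log_dist"), data = obs)
  X_other <- model.matrix(reformulate(setdiff(rhs, "dsi"), intercept = TRUE),
                          data = obs)
  reader <- make_perm_reader(dsi, as.character(obs$group_id), obs$id_a, obs$id_b)
  pr <- perm_coef_p(obs$log_dist, obs$dsi, X_other, reader, n_perm)
  new_dep_model("proximity_on_dsi", lm_coef_table(fit, conf_level), nrow(obs),
                fit_method = "lm",
                permutation_p = if (n_perm >= 1) list(dsi = pr$p) else NULL,
                n_permutations = n_perm,
                extra = list(data = obs))
}
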