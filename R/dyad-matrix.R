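#' Symmetric dyadic value matrix
#'
#' Container for per-group dyadic quantities (affiliation weights, interaction
#' rates, DSI, IDI, ...): a symmetric value matrix over the group's members
#' with a parallel support-count matrix (co-observation scans or shared
#' movements). A dyad with zero support has a missing value, never an imputed
#' zero. Self-dyads are undefined (`NA` diagonal).
#'
#' @param value Symmetric numeric matrix with dimnames = individual ids.
#' @param support Symmetric non-negative integer matrix, same shape; defaults
#'   to 1 wherever `value` is defined.
#' @param group_id Group identifier.
#' @param label Semantic tag, e.g. `"dsi"`, `"idi"`, `"grooming_rate"`.
#' @return Object of class `dyad_matrix`.
#' @export
dyad_matrix <- function(value, support = NULL, group_id = "g", label = "value") {
  stopifnot(is.matrix(value), nrow(value) == ncol(value))
  ids <- rownames(value)
  if (is.null(ids) || is.null(colnames(value)) || !identical(ids, colnames(value))) {
    stop("value must have identical row/col dimnames (individual ids)")
  }
  if (anyDuplicated(ids)) stop("duplicate individual ids")
  diag(value) <- NA_real_
  if (!isTRUE(all.equal(value, t(value)))) stop("value matrix must be symmetric")
  if (is.null(support)) {
    support <- ifelse(is.na(value), 0L, 1L)
    dimnames(support) <- dimnames(value)
  }
  stopifnot(identical(dim(support), dim(value)))
  if (any(support < 0, na.rm = TRUE)) stop("support counts must be non-negative")
  diag(support) <- 0L
  bad <- support == 0 & !is.na(value)
  if (any(bad)) stop("dyads with zero support must have missing value")
  structure(list(group_id = as.character(group_id), ids = ids,
                 value = value, support = support, label = label),
            class = "dyad_matrix")
}

#' @export
print.dyad_matrix <- function(x, ...) {
  n <- length(x$ids)
  vals <- dyad_values(x)
  cat("<dyad_matrix '", x$label, "'> group ", x$group_id, ": ", n,
      " individuals, ", choose(n, 2), " dyads (", sum(!is.na(vals)),
      " defined)\n", sep = "")
  invisible(x)
}

is_dyad_matrix <- function(x) inherits(x, "dyad_matrix")

#' Long-form dyad table
#'
#' @param x A `dyad_matrix` or named list of them.
#' @return Data frame `group_id, id_x, id_y, value, support` with `id_x <
#'   id_y`, one row per unordered dyad.
#' @export
dyad_df <- function(x) {
  if (is_dyad_matrix(x)) x <- list(x)
  out <- lapply(x, function(dm) {
    n <- length(dm$ids)
    ut <- which(upper.tri(dm$value), arr.ind = TRUE)
    data.frame(group_id = dm$group_id,
               id_x = dm$ids[ut[, 1]], id_y = dm$ids[ut[, 2]],
               value = dm$value[ut], support = dm$support[ut])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Vector of dyadic values
#'
#' @param x A `dyad_matrix`.
#' @param na.rm Drop missing dyads?
#' @return Numeric vector, one entry per unordered dyad (upper triangle).
#' @export
dyad_values <- function(x, na.rm = FALSE) {
  v <- x$value[upper.tri(x$value)]
  if (na.rm) v <- v[!is.na(v)]
  v
}

## internal: build a dyad_matrix from a long dyad table
dyads_to_matrix <- function(ids, id_x, id_y, value, support = NULL,
                            group_id = "g", label = "value") {
  n <- length(ids)
  V <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  S <- matrix(0L, n, n, dimnames = list(ids, ids))
  ix <- match(id_x, ids); iy <- match(id_y, ids)
  if (anyNA(ix) || anyNA(iy)) stop("dyad references unknown individual")
  V[cbind(ix, iy)] <- value; V[cbind(iy, ix)] <- value
  if (is.null(support)) support <- ifelse(is.na(value), 0L, 1L)
  S[cbind(ix, iy)] <- support; S[cbind(iy, ix)] <- support
  dyad_matrix(V, S, group_id = group_id, label = label)
}
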