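#' Steady-state promoter x condition activity table
#'
#' @param pa numeric matrix of steady-state promoter activities (fluorescence
#'   units/h), rows = promoters, columns = conditions, with dimnames.
#' @param growth_rates named per-condition growth rates (1/h).
#' @param condition_meta optional data frame of per-condition annotations
#'   (carbon source, chloramphenicol dose, ...), rownames = condition ids.
#' @return An object of class `"activity_table"`.
#' @export
activity_table <- function(pa, growth_rates, condition_meta = NULL) {
  stopifnot(is.matrix(pa), !is.null(rownames(pa)), !is.null(colnames(pa)))
  if (anyDuplicated(rownames(pa)) || anyDuplicated(colnames(pa))) {
    stop("promoter/condition ids must be unique", call. = FALSE)
  }
  if (!all(is.finite(pa))) stop("non-finite promoter activities", call. = FALSE)
  if (is.null(names(growth_rates))) names(growth_rates) <- colnames(pa)
  if (!all(colnames(pa) %in% names(growth_rates)) ||
      any(!is.finite(growth_rates[colnames(pa)]))) {
    stop("missing growth rate for some condition", call. = FALSE)
  }
  structure(list(pa = pa,
                 promoters = rownames(pa),
                 conditions = colnames(pa),
                 growth_rates = growth_rates[colnames(pa)],
                 condition_meta = condition_meta),
            class = "activity_table")
}

#' @export
print.activity_table <- function(x, ...) {
  cat(sprintf("Activity table: %d promoters x %d conditions, growth %.2f-%.2f/h\n",
              nrow(x$pa), ncol(x$pa), min(x$growth_rates), max(x$growth_rates)))
  invisible(x)
}

#' Assemble steady-state records into an activity table
#'
#' @param records data frame with columns `promoter_id`, `condition_id`, `pa`,
#'   `mu` (one row per pair after replicate averaging).
#' @param missing how to handle missing (promoter, condition) cells:
#'   `"error"` (default) or `"drop_condition"` (remove conditions with any
#'   missing cell, with a message).
#' @param condition_meta optional per-condition annotation data frame.
#' @return An [activity_table()]; per-condition growth rate is the mean of the
#'   records' `mu` in that condition.
#' @export
assemble <- function(records, missing = c("error", "drop_condition"),
                     condition_meta = NULL) {
  missing <- match.arg(missing)
  key <- paste(records$promoter_id, records$condition_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- records[duplicated(key), c("promoter_id", "condition_id")][1, ]
    stop(sprintf("duplicate record for (%s, %s)",
                 dup$promoter_id, dup$condition_id), call. = FALSE)
  }
  proms <- unique(records$promoter_id)
  conds <- unique(records$condition_id)
  pa <- matrix(NA_real_, length(proms), length(conds),
               dimnames = list(proms, conds))
  pa[cbind(match(records$promoter_id, proms),
           match(records$condition_id, conds))] <- records$pa
  if (anyNA(pa)) {
    bad <- colnames(pa)[colSums(is.na(pa)) > 0]
    if (missing == "error") {
      stop("missing cells in condition(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    message("dropping condition(s) with missing cells: ",
            paste(bad, collapse = ", "))
    pa <- pa[, !colnames(pa) %in% bad, drop = FALSE]
    conds <- colnames(pa)
  }
  mu <- tapply(records$mu, records$condition_id, mean)[conds]
  activity_table(pa, stats::setNames(as.numeric(mu), names(mu)),
                 condition_meta)
}

#' ln-transform and z-score the activity matrix
#'
#' Row-wise: `X_ij = (ln pa_ij - mean_i) / sd_i` with the sample standard
#' deviation (denominator n-1). Row means and sds are stored so the transform
#' is invertible via [invert_log_zscore()].
#'
#' @param table an [activity_table()] with strictly positive activities.
#' @return An object of class `"normalized_matrix"`: `X`, `row_means`,
#'   `row_sds`, plus the promoter/condition ids and growth rates.
#' @export
log_zscore <- function(table) {
  stopifnot(inherits(table, "activity_table"))
  if (any(table$pa <= 0)) {
    stop("non-positive promoter activity; cannot take logarithms",
         call. = FALSE)
  }
  L <- log(table$pa)
  m <- rowMeans(L)
  s <- apply(L, 1, stats::sd)
  if (any(s == 0)) {
    stop("promoter(s) constant across conditions: ",
         paste(rownames(L)[s == 0], collapse = ", "), call. = FALSE)
  }
  structure(list(X = (L - m) / s, row_means = m, row_sds = s,
                 promoters = table$promoters, conditions = table$conditions,
                 growth_rates = table$growth_rates),
            class = "normalized_matrix")
}

#' Invert [log_zscore()] back to linear-scale activities
#'
#' @param norm a `"normalized_matrix"`; alternatively supply a z-matrix `X`
#'   with the stats of `norm`.
#' @param X optional replacement z-matrix (e.g. model predictions).
#' @return Matrix of activities `exp(mean + sd * X)`.
#' @export
invert_log_zscore <- function(norm, X = norm$X) {
  stopifnot(inherits(norm, "normalized_matrix"))
  exp(norm$row_means + norm$row_sds * X)
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("Normalized ln-activity matrix: %d promoters x %d conditions\n",
              nrow(x$X), ncol(x$X)))
  invisible(x)
}

#' Hierarchically cluster promoters by response shape
#'
#' One-dimensional agglomerative clustering of z-scored (but deliberately not
#' log-transformed) promoter activities, with distance `1 - Pearson r`
#' between promoter profiles, cut at the given height.
#'
#' @param table an [activity_table()].
#' @param cutoff dendrogram cut height on the `1 - r` scale, default 0.225.
#' @param method linkage, default `"average"`.
#' @return Named integer vector of cluster labels; the dendrogram is attached
#'   as attribute `"hclust"`.
#' @export
cluster_promoters <- function(table, cutoff = 0.225, method = "average") {
  stopifnot(inherits(table, "activity_table"))
  if (nrow(table$pa) < 2L) stop("need at least 2 promoters", call. = FALSE)
  s <- apply(table$pa, 1, stats::sd)
  if (any(s == 0)) {
    stop("promoter(s) constant across conditions: ",
         paste(rownames(table$pa)[s == 0], collapse = ", "), call. = FALSE)
  }
  Z <- (table$pa - rowMeans(table$pa)) / s
  d <- stats::as.dist(1 - stats::cor(t(Z)))
  hc <- stats::hclust(d, method = method)
  labels <- stats::cutree(hc, h = cutoff)
  attr(labels, "hclust") <- hc
  labels
}

#' Write / read the activity matrix and condition table as CSV
#'
#' The matrix CSV has promoter ids in the first column and condition ids as
#' header; the companion conditions CSV carries per-condition growth rates
#' and any metadata columns.
#'
#' @param table an [activity_table()].
#' @param path,conditions_path output CSV paths.
#' @return `write_activity_csv` invisibly returns the paths;
#'   `read_activity_csv` returns an [activity_table()].
#' @export
write_activity_csv <- function(table, path, conditions_path) {
  stopifnot(inherits(table, "activity_table"))
  df <- data.frame(promoter_id = rownames(table$pa), table$pa,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  cond <- data.frame(condition_id = table$conditions,
                     growth_rate = unname(table$growth_rates))
  if (!is.null(table$condition_meta)) {
    cond <- cbind(cond, table$condition_meta[table$conditions, , drop = FALSE])
  }
  utils::write.csv(cond, conditions_path, row.names = FALSE)
  invisible(c(path, conditions_path))
}

#' @rdname write_activity_csv
#' @export
read_activity_csv <- function(path, conditions_path) {
  df <- utils::read.csv(path, check.names = FALSE)
  pa <- as.matrix(df[, -1, drop = FALSE])
  rownames(pa) <- df[[1]]
  cond <- utils::read.csv(conditions_path)
  mu <- stats::setNames(cond$growth_rate, cond$condition_id)
  meta <- cond[, setdiff(names(cond), c("condition_id", "growth_rate")),
               drop = FALSE]
  rownames(meta) <- cond$condition_id
  activity_table(pa, mu, if (ncol(meta)) meta else NULL)
}
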