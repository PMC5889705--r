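#' Error matrix with mapped areas
#'
#' The design-based accuracy container: a q x q cross-tabulation of sample
#' counts `n_ij` with map classes as rows and reference classes as columns,
#' plus the mapped area `A_i` (hectares) of each map class. Area weights
#' `W_i = A_i / A` drive the poststratified estimators.
#'
#' @param counts q x q numeric matrix of nonnegative integer counts, map
#'   classes in rows, reference classes in columns.
#' @param mapped_areas Mapped area per map class (hectares), length q.
#' @param class_names Class names; defaults to `rownames(counts)`.
#' @return An object of class `error_matrix`.
#' @export
error_matrix <- function(counts, mapped_areas, class_names = NULL) {
  counts <- as.matrix(counts)
  q <- nrow(counts)
  if (ncol(counts) != q) stop("`counts` must be square", call. = FALSE)
  if (is.null(class_names)) class_names <- rownames(counts)
  if (is.null(class_names)) class_names <- paste0("class", seq_len(q))
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (length(mapped_areas) != q || any(!is.finite(mapped_areas)) ||
      any(mapped_areas < 0)) {
    stop("`mapped_areas` must be length-", q, " nonnegative", call. = FALSE)
  }
  if (sum(counts) == 0) stop("consistency error: empty error matrix",
                             call. = FALSE)
  row_totals <- rowSums(counts)
  zero_area <- mapped_areas == 0 & row_totals > 0
  if (any(zero_area)) {
    stop("consistency error: class(es) with zero mapped area but sampled ",
         "rows: ", paste(class_names[zero_area], collapse = ", "),
         call. = FALSE)
  }
  total_area <- sum(mapped_areas)
  if (total_area <= 0) stop("total mapped area must be positive",
                            call. = FALSE)
  dimnames(counts) <- list(class_names, class_names)
  row_totals <- stats::setNames(as.numeric(row_totals), class_names)
  structure(list(class_names = class_names, counts = counts,
                 row_totals = row_totals,
                 mapped_areas = stats::setNames(mapped_areas, class_names),
                 total_area = total_area,
                 weights = stats::setNames(mapped_areas / total_area,
                                           class_names)),
            class = "error_matrix")
}

#' @export
print.error_matrix <- function(x, ...) {
  cat(sprintf("<error_matrix> %d classes, n = %d, A = %.6g ha\n",
              length(x$class_names), sum(x$counts), x$total_area))
  m <- cbind(x$counts, Total = x$row_totals,
             `Area (ha)` = x$mapped_areas, W = round(x$weights, 4))
  print(m)
  invisible(x)
}

#' Cross-tabulate a labelled reference sample into an error matrix
#'
#' @param samples Data frame with `mapped_class` and `true_class` columns
#'   (map and reference label of each sampled cell).
#' @param mapped_areas Named vector of mapped areas (hectares) per map
#'   class; its names fix the class order.
#' @return An `error_matrix`.
#' @export
build_error_matrix <- function(samples, mapped_areas) {
  if (is.null(names(mapped_areas))) {
    stop("`mapped_areas` must be named by class", call. = FALSE)
  }
  if (nrow(samples) == 0L) {
    stop("consistency error: empty sample table", call. = FALSE)
  }
  cls <- names(mapped_areas)
  if (!all(samples$mapped_class %in% cls) ||
      !all(samples$true_class %in% cls)) {
    stop("sample classes outside `mapped_areas` names", call. = FALSE)
  }
  counts <- table(factor(samples$mapped_class, levels = cls),
                  factor(samples$true_class, levels = cls))
  error_matrix(unclass(counts), mapped_areas[cls], class_names = cls)
}

#' Poststratified proportion-of-area matrix
#'
#' The poststratified estimator of the proportion of total map area in
#' error-matrix cell (i, j): `p_ij = W_i * n_ij / n_i.`, with column
#' totals `p_.j = sum_i p_ij` estimating the proportion of area in each
#' reference class. Rows sum to the area weights `W_i` and the whole
#' matrix sums to one.
#'
#' @param em An `error_matrix`.
#' @return List with `p` (q x q proportion matrix) and `col_totals`.
#' @export
poststratified_proportions <- function(em) {
  stopifnot(inherits(em, "error_matrix"))
  zero <- em$row_totals == 0
  if (any(zero)) {
    stop("estimation error: zero sample count in map stratum ",
         paste(em$class_names[zero], collapse = ", "), call. = FALSE)
  }
  p <- em$weights * sweep(em$counts, 1, em$row_totals, "/")
  list(p = p, col_totals = colSums(p))
}

#' Error-adjusted class areas with standard errors
#'
#' The unbiased estimator of the total area of reference class j is
#' `A_j = A * p_.j`. Its standard error follows from the stratified
#' variance of `p_.j`:
#' `S(p_.j) = sqrt(sum_i W_i^2 * r_ij (1 - r_ij) / (n_i. - 1))` with
#' `r_ij = n_ij / n_i.`, and `S(A_j) = A * S(p_.j)`. The report carries
#' both the `ci_multiplier * SE` interval half-width (1.96 by default, an
#' approximate 95% interval) and the `2 * SE` margin, a common rounding of
#' the same interval.
#'
#' @param em An `error_matrix`.
#' @param ci_multiplier Interval half-width multiplier (default 1.96).
#' @return Data frame, one row per reference class: `class`, `proportion`,
#'   `area_ha`, `se_proportion`, `se_ha`, `margin_ha`
#'   (`ci_multiplier * se_ha`), `margin_2se_ha`, `lower_ha`, `upper_ha`.
#' @export
estimate_areas <- function(em, ci_multiplier = 1.96) {
  stopifnot(inherits(em, "error_matrix"))
  pp <- poststratified_proportions(em)
  r <- sweep(em$counts, 1, em$row_totals, "/")
  undefined <- em$row_totals == 1 &
    (rowSums(em$counts) - diag(em$counts)) > 0
  if (any(undefined)) {
    stop("estimation error: variance undefined for single-sample ",
         "stratum with off-diagonal counts: ",
         paste(em$class_names[undefined], collapse = ", "), call. = FALSE)
  }
  denom <- pmax(em$row_totals - 1, 1)
  var_terms <- (em$weights^2) * r * (1 - r) / denom
  se_p <- sqrt(colSums(var_terms))
  A <- em$total_area
  data.frame(class = em$class_names,
             proportion = as.numeric(pp$col_totals),
             area_ha = A * as.numeric(pp$col_totals),
             se_proportion = as.numeric(se_p),
             se_ha = A * as.numeric(se_p),
             margin_ha = ci_multiplier * A * as.numeric(se_p),
             margin_2se_ha = 2 * A * as.numeric(se_p),
             lower_ha = A * (as.numeric(pp$col_totals) -
                               ci_multiplier * as.numeric(se_p)),
             upper_ha = A * (as.numeric(pp$col_totals) +
                               ci_multiplier * as.numeric(se_p)),
             row.names = NULL)
}

#' Overall, user's and producer's accuracy
#'
#' Computed on the proportion-of-area matrix: overall accuracy is the sum
#' of its diagonal; user's accuracy of map class i is `p_ii / p_i.` (the
#' proportion of area mapped as i that truly is i); producer's accuracy of
#' reference class j is `p_jj / p_.j`. A reference class with zero
#' estimated proportion gets `NA` producer's accuracy rather than an error.
#'
#' @param em An `error_matrix`.
#' @return List with `overall`, `users` (named vector), `producers`.
#' @export
accuracies <- function(em) {
  stopifnot(inherits(em, "error_matrix"))
  pp <- poststratified_proportions(em)
  p <- pp$p
  users <- diag(p) / rowSums(p)
  producers <- diag(p) / pp$col_totals
  producers[pp$col_totals == 0] <- NA_real_
  list(overall = sum(diag(p)),
       users = stats::setNames(as.numeric(users), em$class_names),
       producers = stats::setNames(as.numeric(producers), em$class_names))
}

#' Kappa coefficient of an error matrix
#'
#' Chance-corrected agreement `K = (p_o - p_e) / (1 - p_e)`, with observed
#' and expected agreement computed either on the raw sample counts or on
#' the poststratified proportion-of-area matrix.
#'
#' @param em An `error_matrix`.
#' @param basis `"counts"` (default) or `"area_proportions"`.
#' @return Kappa, or `NA` when expected agreement is 1 (degenerate
#'   single-class table).
#' @export
kappa_coefficient <- function(em, basis = c("counts", "area_proportions")) {
  stopifnot(inherits(em, "error_matrix"))
  basis <- match.arg(basis)
  if (basis == "counts") {
    n <- sum(em$counts)
    po <- sum(diag(em$counts)) / n
    pe <- sum(rowSums(em$counts) * colSums(em$counts)) / n^2
  } else {
    pp <- poststratified_proportions(em)
    po <- sum(diag(pp$p))
    pe <- sum(rowSums(pp$p) * pp$col_totals)
  }
  if (1 - pe <= .Machine$double.eps) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Full design-based accuracy and area report
#'
#' Bundles the proportion matrix, error-adjusted areas with uncertainty,
#' overall/user's/producer's accuracies and kappa into one classed object
#' with a formatted print method.
#'
#' @param em An `error_matrix`.
#' @param ci_multiplier Passed to [estimate_areas()].
#' @param kappa_basis Passed to [kappa_coefficient()].
#' @return An object of class `area_report`.
#' @export
area_report <- function(em, ci_multiplier = 1.96, kappa_basis = "counts") {
  pp <- poststratified_proportions(em)
  acc <- accuracies(em)
  areas <- estimate_areas(em, ci_multiplier = ci_multiplier)
  structure(list(error_matrix = em,
                 proportions = pp$p, column_totals = pp$col_totals,
                 areas = areas, overall = acc$overall, users = acc$users,
                 producers = acc$producers,
                 kappa = kappa_coefficient(em, basis = kappa_basis),
                 kappa_basis = kappa_basis,
                 ci_multiplier = ci_multiplier),
            class = "area_report")
}

#' @export
print.area_report <- function(x, digits = 4, ...) {
  cat("Design-based accuracy and area report\n")
  cat(sprintf("  total area %.6g ha, n = %d, %d classes\n",
              x$error_matrix$total_area, sum(x$error_matrix$counts),
              length(x$error_matrix$class_names)))
  cat("\nProportion-of-area matrix (map rows x reference columns):\n")
  m <- rbind(round(x$proportions, digits),
             Total = round(x$column_totals, digits))
  print(m)
  cat("\nAccuracies:\n")
  acc <- data.frame(class = x$error_matrix$class_names,
                    users = round(x$users, 3),
                    producers = round(x$producers, 3), row.names = NULL)
  print(acc)
  cat(sprintf("  overall = %.4f   kappa (%s basis) = %.4f\n",
              x$overall, x$kappa_basis, x$kappa))
  cat("\nError-adjusted areas:\n")
  a <- x$areas
  print(data.frame(class = a$class, area_ha = round(a$area_ha, 1),
                   se_ha = round(a$se_ha, 1),
                   margin = round(a$margin_ha, 1),
                   margin_2se = round(a$margin_2se_ha, 1), row.names = NULL))
  cat(sprintf("  (margin = %.3g * SE; margin_2se = 2 * SE)\n",
              x$ci_multiplier))
  invisible(x)
}

#' @export
summary.area_report <- function(object, ...) {
  print(object, ...)
}

#' Read an error-matrix CSV
#'
#' Expected layout: a header of reference-class names plus a trailing
#' `mapped_area` column, then one row per map class whose first field is
#' the map-class name. Class order is taken from the rows.
#'
#' @param path CSV file path.
#' @return An `error_matrix`.
#' @export
read_error_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"mapped_area" %in% names(df)) {
    stop("parse error: missing `mapped_area` column in ", path,
         call. = FALSE)
  }
  cls <- as.character(df[[1]])
  ref_cols <- setdiff(names(df)[-1], "mapped_area")
  if (!setequal(ref_cols, cls)) {
    stop("parse error: reference columns must match map-class rows",
         call. = FALSE)
  }
  counts <- as.matrix(df[, cls, drop = FALSE])
  rownames(counts) <- cls
  bad <- which(counts < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("parse error: negative count at line ", bad[1, 1] + 1L,
         " of ", path, call. = FALSE)
  }
  error_matrix(counts, df$mapped_area, class_names = cls)
}

#' Accuracy and area report straight from an error-matrix CSV
#'
#' The desk entry point: reads a CSV error matrix (see
#' [read_error_matrix_csv()]) and returns the full [area_report()].
#'
#' @param path CSV file path.
#' @param ci_multiplier Passed to [estimate_areas()].
#' @param kappa_basis Passed to [kappa_coefficient()].
#' @return An `area_report`.
#' @examples
#' f <- system.file("extdata", "table3_error_matrix.csv", package = "pinyon")
#' rep <- assess_from_csv(f)
#' round(rep$overall, 4)
#' @export
assess_from_csv <- function(path, ci_multiplier = 1.96,
                            kappa_basis = "counts") {
  area_report(read_error_matrix_csv(path), ci_multiplier = ci_multiplier,
              kappa_basis = kappa_basis)
}
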