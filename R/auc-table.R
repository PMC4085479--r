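#' Published risk-factor x task AUC table
#'
#' The 6 x 7 matrix of published leave-one-subject-out AUC values for
#' the six risk factors (DM, HT, HC, CS, CD, OB) across the seven test
#' columns of the battery (tasks #2, #3, #4, #5, #6, #7 and the pooled
#' signature tasks #1&9), shipped as a package fixture.  Only the 42
#' cells are stored; every median or fraction is recomputed from them
#' by [summarize_auc_matrix()], never read off the printed summary.
#'
#' @return numeric matrix with risk-factor rows and task columns.
#' @export
auc_table_fixture <- function() {
  path <- system.file("extdata", "table1_auc.csv", package = "kinestroke",
                      mustWork = TRUE)
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$risk_factor
  if (!all(dim(m) == c(6L, 7L))) stopf("corrupt fixture: expected 6 x 7 cells")
  if (any(m < 0 | m > 1)) stopf("corrupt fixture: AUC outside [0, 1]")
  m
}

#' Summarize an AUC matrix
#'
#' Row medians (per risk factor), column medians (per task), the grand
#' median over all cells, and the fractions of cells strictly above a
#' set of cutoffs.  Medians use the midpoint convention for even counts
#' and are reported rounded half-away-from-zero to 2 decimals, matching
#' the printed precision of the published table; threshold fractions
#' are the count of cells strictly above the cutoff divided by the
#' number of cells, reported as the floor of the percentage (the only
#' rounding rule consistent with the published 83% / 35% figures).
#'
#' @param m an [build_auc_matrix()] result, the [auc_table_fixture()],
#'   or any numeric matrix of AUC cells (NA cells are excluded).
#' @param cutoffs numeric cutoffs for the strictly-above fractions.
#' @return list of class `auc_summary` with `row_medians`,
#'   `col_medians`, `grand_median`, `frac_above` (percent, floored),
#'   `n_cells`.
#' @export
summarize_auc_matrix <- function(m, cutoffs = c(0.7, 0.8)) {
  m <- unclass(m)
  if (!is.matrix(m) || !is.numeric(m)) stopf("m must be a numeric matrix")
  cells <- m[!is.na(m)]
  if (!length(cells)) stopf("empty matrix: no AUC cells to summarize")
  med <- function(x) round_half_away(median(x[!is.na(x)]), 2L)
  out <- list(
    row_medians = apply(m, 1, med),
    col_medians = apply(m, 2, med),
    grand_median = med(cells),
    frac_above = setNames(
      floor(vapply(cutoffs, function(ct) 100 * sum(cells > ct) / length(cells), 0)),
      paste0(">", cutoffs)),
    n_cells = length(cells))
  structure(out, class = "auc_summary")
}

#' @export
print.auc_summary <- function(x, ...) {
  cat("AUC summary over", x$n_cells, "cells\n")
  cat("  row medians:   ",
      paste(sprintf("%s=%.2f", names(x$row_medians), x$row_medians),
            collapse = " "), "\n")
  cat("  column medians:",
      paste(sprintf("%s=%.2f", names(x$col_medians), x$col_medians),
            collapse = " "), "\n")
  cat(sprintf("  grand median:   %.2f\n", x$grand_median))
  for (nm in names(x$frac_above))
    cat(sprintf("  cells %s:     %d%%\n", nm, x$frac_above[[nm]]))
  invisible(x)
}

#' Write an AUC matrix as CSV in the published-table layout
#'
#' Risk-factor rows and task columns with the recomputed `Median` row
#' and column appended.
#'
#' @param m AUC matrix.
#' @param path CSV path.
#' @export
write_auc_matrix <- function(m, path) {
  s <- summarize_auc_matrix(m)
  mm <- cbind(unclass(m), Median = s$row_medians)
  mm <- rbind(mm, Median = c(s$col_medians, s$grand_median))
  df <- data.frame(risk_factor = rownames(mm), round_half_away(mm, 2L),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
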