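#' Rating table for a thrombus reader study
#'
#' Holds the categorical calls of `k` raters over `n` patients. Each cell is
#' one of `"positive"` (thrombus present), `"negative"` (absent) or
#' `"nondiagnostic"`.
#'
#' @param values An `n x k` character matrix (or data frame) of calls.
#' @param patient_ids Optional row labels (default `P1..Pn`).
#' @param rater_names Optional column labels (taken from `values` when
#'   available).
#' @return An object of class `rating_table`.
#' @export
rating_table <- function(values, patient_ids = NULL, rater_names = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 1L || ncol(values) < 2L)
    stop("a rating table needs at least 1 patient and 2 raters")
  mode(values) <- "character"
  bad <- matrix(!values %in% c("positive", "negative", "nondiagnostic"),
                nrow(values))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "unknown rating '%s' at row %d, column %d (expected positive, negative or nondiagnostic)",
      values[idx[1L], idx[2L]], idx[1L], idx[2L]))
  }
  rater_names <- rater_names %||% colnames(values) %||%
    paste0("rater", seq_len(ncol(values)))
  patient_ids <- patient_ids %||% rownames(values) %||%
    paste0("P", seq_len(nrow(values)))
  dimnames(values) <- list(patient_ids, rater_names)
  structure(list(values = values, patient_ids = patient_ids,
                 rater_names = rater_names),
            class = "rating_table")
}

#' Read a rating table from CSV
#'
#' One row per patient; one column per rater plus the reference column;
#' an optional first column named `patient_id` supplies row labels. Cells
#' must be `positive`, `negative` or `nondiagnostic`.
#'
#' @param path CSV file path.
#' @return A [rating_table()].
#' @export
read_rating_table <- function(path) {
  if (!file.exists(path)) stop("ratings file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE, strip.white = TRUE)
  ids <- NULL
  if (tolower(names(df)[1L]) %in% c("patient_id", "patient", "id")) {
    ids <- as.character(df[[1L]])
    df <- df[-1L]
  }
  rating_table(df, patient_ids = ids)
}

#' Confusion counts of one rater against the reference
#'
#' Cross-tabulates a rater's calls against the reference standard. Patient
#' pairs in which either call is `"nondiagnostic"` are excluded pairwise
#' (the default policy) before counting.
#'
#' @param ratings Character vector of one rater's calls.
#' @param reference Character vector of reference calls, same length.
#' @param nondiagnostic Handling of nondiagnostic calls: only
#'   `"exclude"` (pairwise deletion) is offered.
#' @return An object of class `confusion_counts` with fields `TP`, `FP`,
#'   `FN`, `TN` and `n_excluded`.
#' @examples
#' confusion(c("positive", "negative"), c("positive", "negative"))
#' @export
confusion <- function(ratings, reference, nondiagnostic = "exclude") {
  nondiagnostic <- match.arg(nondiagnostic)
  if (length(ratings) != length(reference))
    stop("'ratings' and 'reference' must have equal length")
  ok <- c("positive", "negative", "nondiagnostic")
  if (!all(ratings %in% ok) || !all(reference %in% ok))
    stop("ratings must be 'positive', 'negative' or 'nondiagnostic'")
  keep <- ratings != "nondiagnostic" & reference != "nondiagnostic"
  r <- ratings[keep]; s <- reference[keep]
  structure(list(
    TP = sum(r == "positive" & s == "positive"),
    FP = sum(r == "positive" & s == "negative"),
    FN = sum(r == "negative" & s == "positive"),
    TN = sum(r == "negative" & s == "negative"),
    n_excluded = sum(!keep)), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion counts: TP %d, FP %d, FN %d, TN %d (%d excluded)\n",
              x$TP, x$FP, x$FN, x$TN, x$n_excluded))
  invisible(x)
}

confusion_counts <- function(TP, FP, FN, TN) {
  v <- c(TP, FP, FN, TN)
  if (any(v < 0) || any(v != floor(v)))
    stop("confusion counts must be non-negative integers")
  structure(list(TP = TP, FP = FP, FN = FN, TN = TN, n_excluded = 0L),
            class = "confusion_counts")
}

#' Diagnostic performance metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, positive predictive
#' value `TP/(TP+FP)`, negative predictive value `TN/(TN+FN)` and accuracy
#' `(TP+TN)/n`, kept as exact fractions alongside whole-number percentages.
#' A metric with a zero denominator is reported as `NA` and flagged in
#' `undefined`, never silently zeroed.
#'
#' @param counts A `confusion_counts` object (from [confusion()]).
#' @return An object of class `diagnostic_metrics` with fields `value`
#'   (named numeric proportions), `percent` (rounded whole percentages),
#'   `numerator`, `denominator` and `undefined`.
#' @examples
#' diagnostic_metrics(confusion(
#'   rep(c("positive", "negative"), c(3, 7)),
#'   rep(c("positive", "negative"), c(2, 8))))
#' @export
diagnostic_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  n <- counts$TP + counts$FP + counts$FN + counts$TN
  num <- c(sensitivity = counts$TP, specificity = counts$TN,
           ppv = counts$TP, npv = counts$TN, accuracy = counts$TP + counts$TN)
  den <- c(sensitivity = counts$TP + counts$FN,
           specificity = counts$TN + counts$FP,
           ppv = counts$TP + counts$FP,
           npv = counts$TN + counts$FN,
           accuracy = n)
  value <- ifelse(den > 0, num / den, NA_real_)
  names(value) <- names(num)
  structure(list(value = value,
                 percent = round(100 * value),
                 numerator = num, denominator = den,
                 undefined = names(num)[den == 0],
                 counts = counts),
            class = "diagnostic_metrics")
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  cat("Diagnostic metrics (percent):\n")
  for (m in names(x$value))
    cat(sprintf("  %-12s %s  (%d/%d)\n", m,
                if (is.na(x$value[m])) "undefined"
                else paste0(x$percent[m], "%"),
                x$numerator[m], x$denominator[m]))
  invisible(x)
}

#' Area under the single-operating-point ROC curve
#'
#' A binary rater defines one operating point; the ROC curve through
#' `(0, 0)`, `(1 - Sp, Se)` and `(1, 1)` has trapezoidal area
#' `(Se + Sp) / 2`.
#'
#' @param counts A `confusion_counts` object.
#' @return The AUC in \[0, 1\], or `NA` if sensitivity or specificity is
#'   undefined.
#' @examples
#' binary_auc(confusion(c("positive", "negative"), c("positive", "negative")))
#' @export
binary_auc <- function(counts) {
  m <- diagnostic_metrics(counts)
  se <- m$value["sensitivity"]; sp <- m$value["specificity"]
  if (is.na(se) || is.na(sp)) return(NA_real_)
  unname((se + sp) / 2)
}

#' Upper-tail probability of the chi-square distribution
#'
#' The asymptotic significance of a Friedman statistic with `df = k - 1`
#' degrees of freedom. For `df = 2` this equals `exp(-x / 2)` in closed
#' form.
#'
#' @param x Non-negative statistic value.
#' @param df Positive integer degrees of freedom.
#' @return `P(X >= x)` for `X ~ chi-square(df)`.
#' @examples
#' chi2_upper_tail(4.333, 2)
#' @export
chi2_upper_tail <- function(x, df) {
  if (any(x < 0)) stop("'x' must be non-negative")
  if (any(df < 1) || any(df != floor(df)))
    stop("'df' must be a positive integer")
  stats::pchisq(x, df = df, lower.tail = FALSE)
}

#' Tie-corrected Friedman test
#'
#' Rank test for `k` related samples over `n` blocks (patients). Within each
#' block the `k` values receive mid-ranks (tied values share the average of
#' the ranks they span); with `Rj` the column rank sums, the uncorrected
#' statistic is
#' \deqn{\chi^2_u = \frac{12 \sum_j R_j^2}{n k (k+1)} - 3 n (k + 1),}
#' and the tie correction divides it by
#' \deqn{C = 1 - \frac{\sum_{\mathrm{blocks}} \sum_{\mathrm{groups}} (t^3 - t)}{n k (k^2 - 1)},}
#' where `t` runs over the sizes of tied groups within each block. This is
#' the convention used by the major statistical packages for heavily tied
#' (e.g. binary) data; with no ties `C = 1` and the classic statistic is
#' recovered. The p-value is the chi-square upper tail at `k - 1` degrees of
#' freedom.
#'
#' When every block is fully tied the correction `C` is zero and the data
#' carry no rank information; the test returns a zero statistic with
#' `p = 1` and `degenerate = TRUE`.
#'
#' @param table An `n x k` numeric matrix of orderable scores (binary
#'   ratings coded 0/1), or a [rating_table()] whose calls are coded
#'   negative = 0, positive = 1 with nondiagnostic rows dropped listwise.
#' @return An object of class `friedman_result` with fields `rank_sums`,
#'   `mean_ranks`, `chi_square`, `df`, `p_value`, `tie_correction`,
#'   `n`, `k` and `degenerate`.
#' @examples
#' friedman_test(cbind(a = c(1, 1, 0), b = c(1, 0, 0), c = c(0, 0, 0)))
#' @export
friedman_test <- function(table) {
  if (inherits(table, "rating_table")) {
    keep <- rowSums(table$values == "nondiagnostic") == 0L
    table <- matrix((table$values[keep, , drop = FALSE] == "positive") + 0,
                    nrow = sum(keep),
                    dimnames = list(NULL, table$rater_names))
  }
  table <- as.matrix(table)
  if (!is.numeric(table)) stop("'table' must be numeric")
  n <- nrow(table); k <- ncol(table)
  if (n < 2L || k < 2L)
    stop("the Friedman test needs at least 2 blocks and 2 treatments")
  if (anyNA(table)) stop("'table' must not contain missing values")

  ranks <- t(apply(table, 1L, rank))  # mid-ranks within each block
  rank_sums <- colSums(ranks)
  chi_u <- 12 * sum(rank_sums^2) / (n * k * (k + 1)) - 3 * n * (k + 1)
  tie_sum <- sum(apply(table, 1L, function(row) {
    t <- table(row)
    sum(t^3 - t)
  }))
  C <- 1 - tie_sum / (n * k * (k^2 - 1))
  degenerate <- C <= 0
  chi <- if (degenerate) 0 else chi_u / C
  structure(list(rank_sums = rank_sums,
                 mean_ranks = rank_sums / n,
                 chi_square = chi,
                 df = k - 1L,
                 p_value = if (degenerate) 1 else chi2_upper_tail(chi, k - 1L),
                 tie_correction = C,
                 n = n, k = k,
                 degenerate = degenerate),
            class = "friedman_result")
}

#' @export
print.friedman_result <- function(x, ...) {
  cat(sprintf(
    "Friedman test (tie-corrected): chi-square = %.3f, df = %d, p = %.3f\n",
    x$chi_square, x$df, x$p_value))
  cat("  mean ranks:",
      paste(sprintf("%s %.2f", names(x$rank_sums) %||%
                      paste0("col", seq_along(x$rank_sums)),
                    x$mean_ranks), collapse = ", "), "\n")
  if (x$degenerate)
    cat("  note: all blocks fully tied; the data carry no rank information\n")
  invisible(x)
}

#' Reconstruct a reader-study rating table from its margins
#'
#' Builds an `n x (k+1)` binary rating table (raters plus reference) from
#' per-rater positive counts under two structural constraints observed in
#' apical-thrombus reader studies: no rater misses a reference-positive
#' patient (every reference positive is called positive by every rater),
#' and each rater's excess positives are false positives. With two raters
#' the joint distribution of false positives is not fixed by the margins;
#' `overlap` gives the number of reference-negative patients overcalled by
#' *both* raters. Column rank sums of the Friedman ranking depend only on
#' the margins, not on `overlap`; the tie-corrected statistic does depend
#' on it.
#'
#' @param n_patients Total number of patients.
#' @param rater_pos Named or unnamed vector of positive counts, one per
#'   rater.
#' @param ref_pos Number of reference-standard positives.
#' @param overlap For two raters: reference-negative patients called
#'   positive by both. Default 1.
#' @param rater_names,reference_name Column labels.
#' @return A [rating_table()] whose last column is the reference.
#' @examples
#' tab <- reconstruct_study_table(29, c(observer1 = 14, observer2 = 15), 11)
#' friedman_test(tab)
#' @export
reconstruct_study_table <- function(n_patients, rater_pos, ref_pos,
                                    overlap = 1,
                                    rater_names = names(rater_pos),
                                    reference_name = "contrast") {
  if (length(rater_pos) != 2L)
    stop("the margin reconstruction is defined for exactly 2 raters")
  if (ref_pos > n_patients || any(rater_pos > n_patients))
    stop("positive counts cannot exceed the number of patients")
  if (any(rater_pos < ref_pos))
    stop("a rater with fewer positives than the reference must have missed ",
         "a reference-positive patient, violating the no-false-negative ",
         "constraint")
  fp <- rater_pos - ref_pos
  if (overlap < 0 || overlap > min(fp) || overlap != floor(overlap))
    stop("'overlap' must be an integer in [0, ", min(fp), "]")
  n_neg <- n_patients - ref_pos
  only1 <- fp[1L] - overlap
  only2 <- fp[2L] - overlap
  n_allneg <- n_neg - overlap - only1 - only2
  if (n_allneg < 0)
    stop("margins are inconsistent: more false positives than ",
         "reference-negative patients")
  rows <- rbind(
    matrix(rep(c(1, 1, 1), ref_pos), ncol = 3L, byrow = TRUE),
    matrix(rep(c(1, 1, 0), overlap), ncol = 3L, byrow = TRUE),
    matrix(rep(c(1, 0, 0), only1), ncol = 3L, byrow = TRUE),
    matrix(rep(c(0, 1, 0), only2), ncol = 3L, byrow = TRUE),
    matrix(rep(c(0, 0, 0), n_allneg), ncol = 3L, byrow = TRUE))
  vals <- matrix(ifelse(rows == 1, "positive", "negative"), ncol = 3L)
  colnames(vals) <- c(rater_names %||% c("rater1", "rater2"), reference_name)
  rating_table(vals)
}

#' Full rater-study evaluation
#'
#' For every rater column: confusion counts against the reference,
#' diagnostic metrics and the single-operating-point AUC; plus the
#' tie-corrected Friedman test across all raters and the reference.
#'
#' @param table A [rating_table()] whose columns include `reference`.
#' @param reference Name of the reference-standard column.
#' @return An object of class `rater_evaluation`: a list with `per_rater`
#'   (one entry per non-reference column holding `counts`, `metrics`,
#'   `auc`) and `friedman`.
#' @examples
#' tab <- reconstruct_study_table(29, c(observer1 = 14, observer2 = 15), 11)
#' evaluate_ratings(tab)
#' @export
evaluate_ratings <- function(table, reference = "contrast") {
  stopifnot(inherits(table, "rating_table"))
  if (!reference %in% table$rater_names)
    stop("reference column '", reference, "' not found; columns are: ",
         paste(table$rater_names, collapse = ", "))
  ref <- table$values[, reference]
  raters <- setdiff(table$rater_names, reference)
  per_rater <- lapply(raters, function(rn) {
    cc <- confusion(table$values[, rn], ref)
    list(counts = cc, metrics = diagnostic_metrics(cc), auc = binary_auc(cc))
  })
  names(per_rater) <- raters
  structure(list(per_rater = per_rater,
                 friedman = friedman_test(table),
                 reference = reference),
            class = "rater_evaluation")
}

#' @export
print.rater_evaluation <- function(x, ...) {
  for (rn in names(x$per_rater)) {
    cat("==", rn, "vs", x$reference, "==\n")
    print(x$per_rater[[rn]]$counts)
    print(x$per_rater[[rn]]$metrics)
    cat(sprintf("  AUC          %.3f\n", x$per_rater[[rn]]$auc))
  }
  print(x$friedman)
  invisible(x)
}

#' Path of the packaged 29-patient study fixture
#'
#' A 29-patient, two-observer rating table consistent with the published
#' margins of the reader study the package reproduces (14 and 15 positive
#' calls against 11 reference positives, no false negatives, one shared
#' false positive), stored as CSV under `extdata`.
#'
#' @return File path of the CSV fixture.
#' @export
study_fixture_path <- function() {
  system.file("extdata", "study_ratings.csv", package = "lvtdm",
              mustWork = TRUE)
}
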