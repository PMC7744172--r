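#' @title Diagnostic accuracy and inter-rater agreement
#' @description Statistics for binary (cancer/benign) biopsy calls by several
#'   raters against a slide-histology ground truth: per-rater and
#'   majority-vote confusion counts and diagnostic metrics, Randolph's
#'   free-marginal multirater kappa with a case-resampled bootstrap CI, and a
#'   canonical 44-case, 3-rater fixture reproducing the published evaluation.
#' @name raterstats
NULL

.LEVELS <- c("benign", "cancer")

#' Construct a rating table
#'
#' @param calls Character matrix, cases x raters, entries `"cancer"` or
#'   `"benign"`; no missing values.
#' @param case_ids,rater_ids Optional identifiers; default from dimnames or
#'   generated.
#' @return An object of class `rating_table`.
#' @export
rating_table <- function(calls, case_ids = NULL, rater_ids = NULL) {
  calls <- as.matrix(calls)
  if (anyNA(calls)) stop("rating table has missing entries")
  if (!all(calls %in% .LEVELS))
    stop("ratings must be 'cancer' or 'benign'")
  if (nrow(calls) < 1L || ncol(calls) < 1L)
    stop("need at least one case and one rater")
  if (is.null(case_ids))
    case_ids <- rownames(calls) %||% paste0("case", seq_len(nrow(calls)))
  if (is.null(rater_ids))
    rater_ids <- colnames(calls) %||% paste0("rater", seq_len(ncol(calls)))
  stopifnot(length(case_ids) == nrow(calls),
            length(rater_ids) == ncol(calls))
  dimnames(calls) <- list(case_ids, rater_ids)
  structure(list(calls = calls, case_ids = as.character(case_ids),
                 rater_ids = as.character(rater_ids)),
            class = "rating_table")
}

#' @export
print.rating_table <- function(x, ...) {
  cat(sprintf("Rating table: %d cases x %d raters (%d cancer calls)\n",
              nrow(x$calls), ncol(x$calls), sum(x$calls == "cancer")))
  invisible(x)
}

#' Confusion counts of binary calls against ground truth
#'
#' Cancer is the positive class. Calls and truth must carry identical case
#' ids in the same order.
#'
#' @param calls Named character vector of `"cancer"`/`"benign"` calls (one
#'   rater's column, or a majority vote).
#' @param truth Named character vector of ground-truth labels with the same
#'   case ids.
#' @return A list of class `confusion_counts` with integer fields `tp`, `fn`,
#'   `fp`, `tn`.
#' @export
confusion_counts <- function(calls, truth) {
  if (!is.null(names(calls)) && !is.null(names(truth)) &&
      !identical(names(calls), names(truth)))
    stop("case ids of calls and truth do not match")
  if (length(calls) != length(truth)) stop("length mismatch")
  stopifnot(all(calls %in% .LEVELS), all(truth %in% .LEVELS))
  structure(list(tp = sum(calls == "cancer" & truth == "cancer"),
                 fn = sum(calls == "benign" & truth == "cancer"),
                 fp = sum(calls == "cancer" & truth == "benign"),
                 tn = sum(calls == "benign" & truth == "benign")),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("tp=%d fn=%d fp=%d tn=%d (n=%d)\n",
              x$tp, x$fn, x$fp, x$tn, x$tp + x$fn + x$fp + x$tn))
  invisible(x)
}

#' Diagnostic accuracy metrics from confusion counts
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, accuracy
#' `(tp+tn)/n`, positive predictive value `tp/(tp+fp)` and negative
#' predictive value `tn/(tn+fn)`. A metric whose denominator is zero is
#' reported as `NA` (absent), never as 0. Values are returned raw and
#' rounded half-up to 2 decimals, matching clinical table formatting.
#'
#' @param counts A [confusion_counts()].
#' @return A list of class `diagnostic_metrics` with `raw` and `rounded`
#'   named numeric vectors (`sensitivity`, `specificity`, `accuracy`, `ppv`,
#'   `npv`).
#' @export
diagnostic_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  n <- counts$tp + counts$fn + counts$fp + counts$tn
  if (n == 0) stop("empty confusion counts")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  raw <- c(sensitivity = ratio(counts$tp, counts$tp + counts$fn),
           specificity = ratio(counts$tn, counts$tn + counts$fp),
           accuracy = (counts$tp + counts$tn) / n,
           ppv = ratio(counts$tp, counts$tp + counts$fp),
           npv = ratio(counts$tn, counts$tn + counts$fn))
  structure(list(raw = raw, rounded = round_half_up(raw, 2)),
            class = "diagnostic_metrics")
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  v <- x$rounded
  cat(paste(sprintf("%s=%.2f", names(v), v), collapse = "  "), "\n")
  invisible(x)
}

#' Round half away from zero (table-style rounding)
#'
#' `round()` in R rounds half to even; printed clinical tables round half up.
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector (NAs preserved).
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Majority vote across raters
#'
#' Per case, the label chosen by more than half of the raters. With an even
#' rater count a tie is possible; `tie` selects the label assigned then
#' (default `"benign"`, the conservative call — a package convention, not a
#' published rule).
#'
#' @param table A [rating_table()].
#' @param tie Label used for exact ties (even rater counts only).
#' @return Named character vector of majority calls.
#' @export
majority_vote <- function(table, tie = c("benign", "cancer")) {
  stopifnot(inherits(table, "rating_table"))
  tie <- match.arg(tie)
  r <- ncol(table$calls)
  n_cancer <- rowSums(table$calls == "cancer")
  out <- ifelse(n_cancer > r / 2, "cancer",
                ifelse(n_cancer < r / 2, "benign", tie))
  stats::setNames(out, table$case_ids)
}

#' Randolph's observed overall agreement
#'
#' The proportion of agreeing rater pairs,
#' \deqn{P_o = \frac{1}{N R (R-1)} \sum_i \sum_j n_{ij} (n_{ij} - 1)}
#' where `n_ij` is the number of raters assigning case `i` to category `j`.
#' For 3 raters a unanimous case contributes 1 and a 2-1 split 1/3.
#'
#' @param table A [rating_table()] with at least 2 raters.
#' @return The agreement proportion in `[0, 1]`.
#' @export
overall_agreement <- function(table) {
  stopifnot(inherits(table, "rating_table"))
  r <- ncol(table$calls)
  if (r < 2L) stop("agreement needs at least 2 raters")
  n <- nrow(table$calls)
  n_cancer <- rowSums(table$calls == "cancer")
  n_benign <- r - n_cancer
  sum(n_cancer * (n_cancer - 1) + n_benign * (n_benign - 1)) /
    (n * r * (r - 1))
}

#' Randolph's free-marginal multirater kappa
#'
#' Chance-corrected agreement under free margins (raters are not constrained
#' to fixed category frequencies): `kappa = (P_o - 1/k) / (1 - 1/k)` with `k`
#' categories; for `k = 2`, `kappa = 2 P_o - 1`.
#'
#' @param table A [rating_table()].
#' @param k_categories Number of rating categories (>= 2); default 2.
#' @return A list of class `agreement_result`: `p_overall`, `kappa_free`,
#'   `k_categories`, `ci95` (`NULL` unless filled by
#'   [kappa_bootstrap_ci()]).
#' @export
free_marginal_kappa <- function(table, k_categories = 2L) {
  if (k_categories < 2L) stop("k_categories must be >= 2")
  p <- overall_agreement(table)
  structure(list(p_overall = p,
                 kappa_free = (p - 1 / k_categories) / (1 - 1 / k_categories),
                 k_categories = as.integer(k_categories),
                 ci95 = NULL),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("P_o = %.4f (%.2f%%), free-marginal kappa (k=%d) = %.4f\n",
              x$p_overall, 100 * x$p_overall, x$k_categories, x$kappa_free))
  if (!is.null(x$ci95))
    cat(sprintf("  95%% bootstrap CI: [%.3f, %.3f]\n", x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Percentile bootstrap CI for the free-marginal kappa
#'
#' Resamples cases (rows) with replacement, recomputes the kappa on each
#' replicate, and returns the percentile interval. The published table's CI
#' method is not specified, so this is the package's own CI and is compared
#' to the printed interval only as a sanity bracket.
#'
#' @param table A [rating_table()] with at least 2 cases.
#' @param k_categories Category count.
#' @param n_boot Number of replicates (>= 100).
#' @param seed Integer seed; same seed gives an identical interval.
#' @param level Confidence level, default 0.95.
#' @return Length-2 numeric interval.
#' @export
kappa_bootstrap_ci <- function(table, k_categories = 2L, n_boot = 2000L,
                               seed = 1L, level = 0.95) {
  stopifnot(inherits(table, "rating_table"))
  n <- nrow(table$calls)
  if (n < 2L) stop("bootstrap needs at least 2 cases")
  if (n_boot < 100L) stop("n_boot must be >= 100")
  r <- ncol(table$calls)
  n_cancer <- rowSums(table$calls == "cancer")
  pair_sum <- n_cancer * (n_cancer - 1) + (r - n_cancer) * (r - n_cancer - 1)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  kap <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    p <- sum(pair_sum[idx]) / (n * r * (r - 1))
    (p - 1 / k_categories) / (1 - 1 / k_categories)
  }, numeric(1))
  a <- (1 - level) / 2
  unname(stats::quantile(kap, c(a, 1 - a), type = 7))
}

#' Canonical 44-case, 3-rater fixture
#'
#' The published evaluation rated 44 needle cores (10 containing cancer by
#' slide histology) with three pathologists, but released only the marginal
#' statistics: per-rater diagnostic metrics, majority-vote metrics and the
#' multirater agreement. Those marginals admit an (essentially unique, up to
#' case permutation) integer solution for the underlying table, which this
#' function returns:
#' cases 1-6 rated (C,C,C); 7-9 (C,B,C); 10 (B,B,B); 11-12 (C,B,C);
#' 13-19 (B,B,C); 20-44 (B,B,B); truth = cancer for cases 1-10.
#' Per-rater confusions are (9,1,2,32), (6,4,0,34), (9,1,9,25); the majority
#' vote gives (9,1,2,32); 32 cases are unanimous and 12 split 2-1.
#'
#' @return A list with `table` (a [rating_table()]) and `truth` (named
#'   character vector).
#' @export
fixture_table <- function() {
  pat <- function(p1, p2, p3, times)
    matrix(rep(c(p1, p2, p3), times), ncol = 3, byrow = TRUE)
  C <- "cancer"; B <- "benign"
  calls <- rbind(pat(C, C, C, 6),    # cases 1-6: unanimous cancer
                 pat(C, B, C, 3),    # 7-9: split, truth cancer
                 pat(B, B, B, 1),    # 10: unanimous benign, truth cancer
                 pat(C, B, C, 2),    # 11-12: split, truth benign
                 pat(B, B, C, 7),    # 13-19: split, truth benign
                 pat(B, B, B, 25))   # 20-44: unanimous benign
  ids <- sprintf("case%02d", 1:44)
  truth <- stats::setNames(c(rep(C, 10), rep(B, 34)), ids)
  list(table = rating_table(calls, case_ids = ids,
                            rater_ids = paste0("pathologist", 1:3)),
       truth = truth)
}

#' Read / write rating tables as CSV
#'
#' Layout: one row per case with columns `case_id`, `truth`, then one column
#' per rater; all values `"cancer"` or `"benign"`.
#' @param path CSV file path.
#' @return For the reader, a list with `table` and `truth` (as
#'   [fixture_table()]); the writer returns `path` invisibly.
#' @export
read_ratings_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "truth")
  if (!all(need %in% names(df)))
    stop("ratings CSV needs columns: ", paste(need, collapse = ", "))
  raters <- setdiff(names(df), need)
  if (length(raters) == 0L) stop("ratings CSV has no rater columns")
  calls <- as.matrix(df[, raters, drop = FALSE])
  list(table = rating_table(calls, case_ids = df$case_id,
                            rater_ids = raters),
       truth = stats::setNames(df$truth, df$case_id))
}

#' @rdname read_ratings_csv
#' @param table A [rating_table()].
#' @param truth Named ground-truth vector aligned with the table.
#' @export
write_ratings_csv <- function(table, truth, path) {
  stopifnot(inherits(table, "rating_table"),
            identical(names(truth), table$case_ids))
  df <- data.frame(case_id = table$case_ids, truth = unname(truth),
                   table$calls, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Full evaluation report (Table-1/Table-2 shaped)
#'
#' Computes per-rater and majority-vote diagnostic metrics plus the
#' multirater agreement for a rating table against ground truth.
#'
#' @param table A [rating_table()].
#' @param truth Named ground-truth vector.
#' @param k_categories Category count for the kappa.
#' @param ci If `TRUE`, attach a bootstrap CI (seeded by `seed`).
#' @param n_boot,seed Bootstrap parameters, see [kappa_bootstrap_ci()].
#' @return A list of class `rater_report`: `metrics` (data.frame, one row per
#'   metric, one column per rater plus `majority`), `agreement` (an
#'   `agreement_result`), `confusions` (list of [confusion_counts()]).
#' @export
evaluate_ratings <- function(table, truth, k_categories = 2L, ci = FALSE,
                             n_boot = 2000L, seed = 1L) {
  stopifnot(inherits(table, "rating_table"))
  cols <- c(table$rater_ids, "majority")
  conf <- lapply(seq_along(cols), function(i) {
    calls <- if (i <= ncol(table$calls))
      stats::setNames(table$calls[, i], table$case_ids)
    else majority_vote(table)
    confusion_counts(calls, truth)
  })
  names(conf) <- cols
  met <- vapply(conf, function(cc) diagnostic_metrics(cc)$rounded,
                numeric(5))
  agreement <- free_marginal_kappa(table, k_categories)
  if (ci)
    agreement$ci95 <- kappa_bootstrap_ci(table, k_categories, n_boot, seed)
  structure(list(metrics = as.data.frame(met),
                 agreement = agreement, confusions = conf),
            class = "rater_report")
}

#' @export
print.rater_report <- function(x, ...) {
  cat("Diagnostic performance (rounded to 2 decimals)\n")
  print(x$metrics)
  print(x$agreement)
  invisible(x)
}
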