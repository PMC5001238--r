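# Rank-based evaluation: median percentile ranks, paired t-tests between two
# methods, precision-recall curves and average precision.

#' Median percentile of a drug set in a ranked list
#'
#' The median (midpoint mean for even counts) of the percentiles of the
#' evaluation drugs found in the list. The median is preferred to the mean
#' because a single drug ranked near the bottom cannot drag it. Drugs absent
#' from the list are excluded from the median; their count is available via
#' the `"n_missing"` attribute.
#'
#' @param ranked a [rank_drugs()] result.
#' @param drugs character vector of evaluation drug ids.
#' @return the median percentile (`NA_real_` if no evaluation drug is in the
#'   list), with attributes `n_found` and `n_missing`.
#' @export
median_percentile <- function(ranked, drugs) {
  pct <- rank_percentiles(ranked)
  found <- intersect(unique(drugs), names(pct))
  n_missing <- length(unique(drugs)) - length(found)
  if (!length(found)) {
    message("no evaluation drug present in the ranked list")
    return(structure(NA_real_, n_found = 0L, n_missing = n_missing))
  }
  structure(stats::median(pct[found]),
            n_found = length(found), n_missing = n_missing)
}

#' Paired t-test on two methods' percentile ranks
#'
#' Two-sided paired Student's t-test on the percentile differences over the
#' drugs present in both lists. Degenerate cases follow the usual
#' conventions: all-zero differences give t = 0, p = 1; non-zero constant
#' differences (zero variance) give t = +/-Inf, p = 0.
#'
#' @param ranks_a,ranks_b named numeric vectors, drug id -> percentile.
#' @return list with `t`, `p`, `n` (overlap size); `t` and `p` are `NA` when
#'   the overlap has fewer than two drugs.
#' @export
paired_rank_test <- function(ranks_a, ranks_b) {
  common <- intersect(names(ranks_a), names(ranks_b))
  n <- length(common)
  if (n < 2L) {
    message("fewer than 2 overlapping drugs; paired test undefined")
    return(list(t = NA_real_, p = NA_real_, n = n))
  }
  d <- ranks_a[common] - ranks_b[common]
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, p = 1, n = n))
    return(list(t = sign(mean(d)) * Inf, p = 0, n = n))
  }
  ht <- stats::t.test(ranks_a[common], ranks_b[common], paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, n = n)
}

#' Precision-recall curve and average precision
#'
#' Walks the ranked list from the top; at each rank holding a positive drug it
#' records a (recall, precision) point. The average precision is the mean of
#' the recorded precisions — the standard single-query definition, so with one
#' disease the mean average precision equals the average precision. The curve
#' is the raw step curve at the hits; no interpolation. Positives absent from
#' the list are excluded (their count is reported).
#'
#' @param ranked a [rank_drugs()] result.
#' @param positives character vector of positive drug ids.
#' @return list with `curve` (data.frame `recall`, `precision`),
#'   `average_precision`, `n_positives_found`, `n_positives_missing`.
#' @export
precision_recall <- function(ranked, positives) {
  ids <- ranked$entries$drug_id
  pos <- unique(positives)
  found <- intersect(pos, ids)
  n_missing <- length(pos) - length(found)
  if (!length(found)) {
    message("no positive drug present in the ranked list")
    return(list(curve = data.frame(recall = numeric(), precision = numeric()),
                average_precision = NA_real_,
                n_positives_found = 0L, n_positives_missing = n_missing))
  }
  is_pos <- ids %in% found
  hits <- which(is_pos)
  prec <- cumsum(is_pos)[hits] / hits
  rec <- seq_along(hits) / length(found)
  list(curve = data.frame(recall = rec, precision = prec),
       average_precision = mean(prec),
       n_positives_found = length(found), n_positives_missing = n_missing)
}

test_or_na <- function(pct_a, pct_b, drugs) {
  paired_rank_test(pct_a[intersect(drugs, names(pct_a))],
                   pct_b[intersect(drugs, names(pct_b))])
}

#' Evaluate a ranked drug list against labeled drug sets
#'
#' Produces the full evaluation report: each approved drug's individual
#' percentile, median percentiles per evaluation set and per drug type, the
#' combined-set median, the precision-recall curve and average precision over
#' the union of all evaluation drugs, and — when a comparator ranked list is
#' supplied — two-sided paired t-tests (on percentiles, over the drugs both
#' lists rank) per set, per type and combined. Undefined metrics are reported
#' as `NA`.
#'
#' @param ranked a [rank_drugs()] result.
#' @param sets an [evaluation_sets()] object.
#' @param comparator optional second `"ranked_drugs"` list (e.g. another
#'   method's output read with [read_ranked_drugs()]).
#' @return object of class `"evaluation_report"`.
#' @export
evaluate <- function(ranked, sets, comparator = NULL) {
  pct <- rank_percentiles(ranked)
  all_drugs <- names(sets$membership)
  by_set <- split(all_drugs, sets$membership[all_drugs])
  by_type <- split(all_drugs, sets$drug_type[all_drugs])

  approved <- by_set[["approved"]]
  approved_ranks <- if (length(approved)) {
    fa <- intersect(approved, names(pct))
    data.frame(drug_id = fa, percentile = unname(pct[fa]),
               stringsAsFactors = FALSE)
  } else data.frame(drug_id = character(), percentile = numeric())

  med_of <- function(groups) {
    vapply(groups, function(d) as.numeric(median_percentile(ranked, d)),
           0, USE.NAMES = TRUE)
  }
  per_set_median <- med_of(by_set)
  per_type_median <- med_of(by_type)
  combined_median <- as.numeric(median_percentile(ranked, all_drugs))

  pr <- precision_recall(ranked, all_drugs)

  paired <- NULL
  if (!is.null(comparator)) {
    pct_b <- rank_percentiles(comparator)
    paired <- list(
      per_set = lapply(by_set, function(d) test_or_na(pct, pct_b, d)),
      per_type = lapply(by_type, function(d) test_or_na(pct, pct_b, d)),
      combined = test_or_na(pct, pct_b, all_drugs))
  }

  structure(list(approved_ranks = approved_ranks,
                 per_set_median = per_set_median,
                 per_type_median = per_type_median,
                 combined_median = combined_median,
                 pr_curve = pr$curve,
                 average_precision = pr$average_precision,
                 n_eval_drugs = length(all_drugs),
                 n_eval_missing = length(all_drugs) -
                   sum(all_drugs %in% names(pct)),
                 paired = paired,
                 paired_scale = "percentile"),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report over", x$n_eval_drugs, "labeled drugs",
      sprintf("(%d not in the ranked list)\n", x$n_eval_missing))
  if (nrow(x$approved_ranks)) {
    cat("approved drugs (individual percentiles):\n")
    print(x$approved_ranks, row.names = FALSE)
  }
  fmt <- function(v) paste(sprintf("%s %.1f%%", names(v), v), collapse = ", ")
  if (length(x$per_set_median)) cat("set medians:", fmt(x$per_set_median), "\n")
  if (length(x$per_type_median)) cat("type medians:", fmt(x$per_type_median), "\n")
  cat(sprintf("combined median %.1f%%; average precision %.3f\n",
              x$combined_median, x$average_precision))
  if (!is.null(x$paired))
    cat(sprintf("paired t-test (combined): t = %.3f, p = %.3g, n = %d\n",
                x$paired$combined$t, x$paired$combined$p, x$paired$combined$n))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#' @param report an [evaluate()] result.
#' @param path output file path.
#' @export
write_evaluation_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
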