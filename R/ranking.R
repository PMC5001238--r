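# Score every candidate drug against the disease profile and rank.

#' Rank candidate drugs by phenotype similarity to the disease
#'
#' Computes the symmetric best-match-average similarity between the disease
#' profile and each drug profile and sorts drugs by descending score. Tied
#' scores share the average of their positional ranks, and each drug's
#' percentile is `rank / n_candidates * 100` (so "top 6.7%" reads directly
#' off the list). Drugs whose similarity is undefined (no IC-covered
#' phenotype terms) are excluded from the ranking and reported.
#'
#' @param disease_profile the disease [phenotype_profile()].
#' @param drug_profiles named list of drug [phenotype_profile()]s.
#' @param ic an [compute_ic()] table.
#' @param ont an [ontology()].
#' @param weighted use weighted best-match averages? Default `FALSE`.
#' @return object of class `"ranked_drugs"`: list with `entries` (data.frame
#'   `rank`, `drug_id`, `score`, `percentile`, sorted by descending score,
#'   ties broken by drug id for a deterministic row order), `n_candidates`
#'   and `excluded` (character vector of unscorable drugs; by convention such
#'   drugs sit below every scored drug).
#' @export
rank_drugs <- function(disease_profile, drug_profiles, ic, ont,
                       weighted = FALSE) {
  if (!length(disease_profile$weights)) stop("disease profile is empty")
  if (!length(drug_profiles)) stop("no drug profiles supplied")
  cache <- new.env(parent = emptyenv())
  scores <- vapply(drug_profiles, function(p)
    profile_similarity(disease_profile, p, ic, ont, weighted, cache),
    0, USE.NAMES = TRUE)
  excluded <- names(scores)[is.na(scores)]
  scores <- scores[!is.na(scores)]
  if (!length(scores)) stop("no drug could be scored against the disease profile")
  ranks <- rank(-scores, ties.method = "average")
  ord <- order(-scores, names(scores))
  n <- length(scores)
  entries <- data.frame(rank = unname(ranks[ord]),
                        drug_id = names(scores)[ord],
                        score = unname(scores[ord]),
                        percentile = unname(ranks[ord]) / n * 100,
                        stringsAsFactors = FALSE)
  structure(list(entries = entries, n_candidates = n,
                 excluded = sort(excluded)),
            class = "ranked_drugs")
}

#' @export
print.ranked_drugs <- function(x, n = 10L, ...) {
  cat("ranked_drugs:", x$n_candidates, "candidates ranked,",
      length(x$excluded), "excluded\n")
  print(utils::head(x$entries, n))
  invisible(x)
}

#' Percentiles of a ranked list as a named vector
#' @param ranked a [rank_drugs()] result.
#' @return named numeric vector, drug id -> percentile.
#' @export
rank_percentiles <- function(ranked) {
  stats::setNames(ranked$entries$percentile, ranked$entries$drug_id)
}

#' Write a ranked list to TSV (rank, drug_id, score, percentile)
#' @param ranked a [rank_drugs()] result.
#' @param path output file path.
#' @export
write_ranked_drugs <- function(ranked, path) {
  utils::write.table(ranked$entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a ranked list written by [write_ranked_drugs()]
#'
#' Also accepts any TSV with columns `drug_id` and either `percentile` or
#' both `rank` and a list length to derive it — e.g. a comparator method's
#' ranked list used for paired evaluation.
#'
#' @param path TSV file path.
#' @return a `"ranked_drugs"` object.
#' @export
read_ranked_drugs <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          stringsAsFactors = FALSE)
  if (!"drug_id" %in% names(df)) stop("ranked list needs a drug_id column")
  if (!"percentile" %in% names(df)) {
    if (!"rank" %in% names(df))
      stop("ranked list needs percentile or rank columns")
    df$percentile <- df$rank / nrow(df) * 100
  }
  if (!"rank" %in% names(df)) df$rank <- rank(df$percentile, ties.method = "average")
  if (!"score" %in% names(df)) df$score <- -df$rank
  df <- df[order(df$rank, df$drug_id), c("rank", "drug_id", "score", "percentile")]
  structure(list(entries = df, n_candidates = nrow(df), excluded = character()),
            class = "ranked_drugs")
}
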