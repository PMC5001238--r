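# Information content from propagated annotations and Resnik-style
# best-match-average semantic similarity between phenotype profiles.

#' Compute information content from propagated annotations
#'
#' A term's annotation frequency p(t) is the fraction of annotated genes whose
#' ancestor-closed (propagated) annotation set contains t; its information
#' content is -log p(t) in natural-log units. Because every gene's closure
#' reaches the root, the root has p = 1 and IC 0, and IC never decreases when
#' moving from a parent to a child.
#'
#' @param ont an [ontology()].
#' @param ann a [gene_annotations()] object.
#' @param base logarithm base; default `exp(1)`. Changing the base rescales
#'   all IC values by a constant factor and leaves every ranking unchanged.
#' @return object of class `"ic_table"`: list with named numeric `ic`, named
#'   integer `frequency` (annotated-gene count under closure; only terms with
#'   frequency > 0 appear) and `universe` (the p(t) denominator).
#' @export
compute_ic <- function(ont, ann, base = exp(1)) {
  if (ann$universe == 0) stop("annotation universe is empty")
  counts <- table(unlist(ann$propagated, use.names = FALSE))
  freq <- stats::setNames(as.integer(counts), names(counts))
  ic <- -log(freq / ann$universe, base = base)
  ic[ic < 0] <- 0   # guard against -0
  structure(list(ic = ic, frequency = freq, universe = ann$universe,
                 base = base),
            class = "ic_table")
}

#' @export
print.ic_table <- function(x, ...) {
  cat("ic_table:", length(x$ic), "terms over", x$universe,
      "genes; max IC", format(max(x$ic), digits = 4), "\n")
  invisible(x)
}

#' Resnik similarity between two terms
#'
#' The maximum information content over the common ancestors of the two terms
#' (their reflexive ancestor sets always share at least the root, whose IC is
#' 0 after propagation). A term's similarity to itself is its own IC.
#'
#' @param t1,t2 term ids.
#' @param ic an [compute_ic()] table.
#' @param ont an [ontology()].
#' @return non-negative similarity score.
#' @export
term_similarity <- function(t1, t2, ic, ont) {
  ca <- common_ancestors(ont, t1, t2)
  vals <- ic$ic[intersect(ca, names(ic$ic))]
  if (!length(vals)) {
    warning("no common ancestor of ", t1, " and ", t2,
            " carries an IC entry; similarity 0")
    return(0)
  }
  max(vals)
}

# Best-match table: for each term in `terms1`, the max term similarity
# against `terms2`. `cache` is an environment memoizing pairwise scores
# across calls (purely a speed-up; results identical without it).
best_matches <- function(terms1, terms2, ic, ont, cache = NULL) {
  vapply(terms1, function(t1) {
    best <- 0
    for (t2 in terms2) {
      if (!is.null(cache)) {
        key <- if (t1 <= t2) paste0(t1, "\r", t2) else paste0(t2, "\r", t1)
        s <- cache[[key]]
        if (is.null(s)) {
          s <- term_similarity(t1, t2, ic, ont)
          assign(key, s, envir = cache)
        }
      } else s <- term_similarity(t1, t2, ic, ont)
      if (s > best) best <- s
    }
    best
  }, 0)
}

# Profile terms that carry an IC entry; attribute "skipped" counts the rest.
ic_terms <- function(profile, ic) {
  ts <- profile_terms(profile)
  keep <- ts[ts %in% names(ic$ic)]
  structure(keep, skipped = length(ts) - length(keep))
}

#' Directed best-match-average similarity between profiles
#'
#' Matches each phenotype term of `p1` to its most similar term in `p2`
#' (Resnik term similarity) and averages the best-match scores over the terms
#' of `p1`. By default the average is unweighted; with `weighted = TRUE` the
#' profile weights of `p1` (normalized to sum to one) weight the average.
#' Terms without an IC entry are skipped; if nothing remains on either side
#' the similarity is undefined and `NA` is returned.
#'
#' @param p1,p2 [phenotype_profile()] objects.
#' @param ic an [compute_ic()] table.
#' @param ont an [ontology()].
#' @param weighted weight the average by `p1`'s profile weights? Default
#'   `FALSE` (the plain best-match average).
#' @param cache optional environment memoizing term-pair similarities.
#' @return similarity score, or `NA_real_` when undefined.
#' @export
directed_similarity <- function(p1, p2, ic, ont, weighted = FALSE,
                                cache = NULL) {
  t1 <- ic_terms(p1, ic)
  t2 <- ic_terms(p2, ic)
  if (!length(t1) || !length(t2)) return(NA_real_)
  bm <- best_matches(t1, t2, ic, ont, cache)
  if (!weighted) return(mean(bm))
  w <- p1$weights[t1]
  sum(bm * w / sum(w))
}

#' Symmetric profile similarity
#'
#' The arithmetic mean of the two directed best-match averages:
#' `sim(p1, p2) = (sim(p1 -> p2) + sim(p2 -> p1)) / 2`. Symmetric and
#' non-negative; `NA` when either direction is undefined.
#'
#' @inheritParams directed_similarity
#' @return similarity score, or `NA_real_` when undefined.
#' @export
profile_similarity <- function(p1, p2, ic, ont, weighted = FALSE,
                               cache = NULL) {
  d12 <- directed_similarity(p1, p2, ic, ont, weighted, cache)
  d21 <- directed_similarity(p2, p1, ic, ont, weighted, cache)
  if (is.na(d12) || is.na(d21)) return(NA_real_)
  (d12 + d21) / 2
}

#' Write an IC table to TSV (term_id, gene_count, ic)
#' @param ic an [compute_ic()] table.
#' @param path output file path.
#' @export
write_ic_table <- function(ic, path) {
  ids <- sort(names(ic$ic))
  df <- data.frame(term_id = ids, gene_count = unname(ic$frequency[ids]),
                   ic = unname(ic$ic[ids]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
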