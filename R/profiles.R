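# Weighted phenotype profiles for a disease (gene-count weights) and for
# drugs (confidence-sum weights), the median filter, and category scoring.

#' Construct a phenotype profile
#'
#' A profile is a sparse weighted set of phenotype terms attached to a disease
#' (via its associated genes) or a drug (via its target genes). Zero-weight
#' terms are absent by construction.
#'
#' @param owner_id disease or drug identifier.
#' @param weights named numeric vector, term id -> strictly positive weight.
#' @param source `"disease"` or `"drug"`.
#' @return object of class `"phenotype_profile"`.
#' @export
phenotype_profile <- function(owner_id, weights, source = c("disease", "drug")) {
  source <- match.arg(source)
  weights <- weights[weights > 0]
  if (length(weights)) weights <- weights[order(names(weights))]
  else weights <- stats::setNames(numeric(0), character(0))
  structure(list(owner_id = owner_id, weights = weights, source = source),
            class = "phenotype_profile")
}

#' @export
print.phenotype_profile <- function(x, ...) {
  cat("phenotype_profile [", x$source, "] ", x$owner_id, ": ",
      length(x$weights), " terms\n", sep = "")
  invisible(x)
}

profile_terms <- function(p) names(p$weights)

#' Build the disease phenotype profile
#'
#' Each phenotype term directly annotated to at least one disease gene enters
#' the profile with weight equal to the number of distinct disease genes
#' carrying that annotation. Profile membership uses direct annotations only;
#' ancestor closure enters later through the information content, so the
#' profile is not flooded with generic ancestor terms.
#'
#' @param genes character vector of disease gene ids.
#' @param ann a [gene_annotations()] object.
#' @param owner_id label for the profile (default `"disease"`).
#' @return a [phenotype_profile()] with integer weights.
#' @export
build_disease_profile <- function(genes, ann, owner_id = "disease") {
  if (!length(genes)) stop("empty disease gene set")
  genes <- unique(as.character(genes))
  have <- intersect(genes, names(ann$direct))
  missing <- length(genes) - length(have)
  if (missing)
    message(missing, " disease gene(s) have no phenotype annotations")
  if (!length(have))
    stop("no disease gene has any phenotype annotation; profile would be empty")
  counts <- table(unlist(ann$direct[have], use.names = FALSE))
  phenotype_profile(owner_id,
                    stats::setNames(as.numeric(counts), names(counts)),
                    source = "disease")
}

#' Remove below-median terms from a profile
#'
#' Terms whose weight is strictly smaller than the median of all the profile's
#' weights are removed; terms exactly at the median are kept. The median is
#' computed once, on the unfiltered weights (even counts use the midpoint
#' mean), so at most half of the terms (rounded down) can be removed.
#'
#' @param profile a [phenotype_profile()].
#' @return the filtered [phenotype_profile()].
#' @export
filter_by_median <- function(profile) {
  w <- profile$weights
  if (!length(w)) stop("cannot median-filter an empty profile")
  m <- stats::median(w)
  phenotype_profile(profile$owner_id, w[w >= m], source = profile$source)
}

#' Build one drug's phenotype profile
#'
#' Each phenotype term directly annotated to at least one of the drug's target
#' genes enters the profile with weight equal to the sum of the confidence
#' scores of the target genes carrying that annotation.
#'
#' @param drug drug id, present in `targets`.
#' @param targets a [drug_targets()] object.
#' @param ann a [gene_annotations()] object.
#' @return a [phenotype_profile()]; empty (zero terms) when none of the
#'   drug's targets has any phenotype annotation — such drugs cannot be
#'   scored and are reported as excluded by [rank_drugs()].
#' @export
build_drug_profile <- function(drug, targets, ann) {
  if (!drug %in% names(targets)) stop("drug not in target table: ", drug)
  links <- targets[[drug]]
  w <- numeric(0)
  for (g in names(links)) {
    ts <- ann$direct[[g]]
    if (is.null(ts)) next
    add <- stats::setNames(rep.int(links[[g]], length(ts)), ts)
    w <- c(w, add)
  }
  if (!length(w)) return(phenotype_profile(drug, numeric(0), source = "drug"))
  agg <- tapply(w, names(w), sum)
  phenotype_profile(drug, stats::setNames(as.numeric(agg), names(agg)),
                    source = "drug")
}

#' Build profiles for every drug in a target table
#'
#' @inheritParams build_drug_profile
#' @return named list of [phenotype_profile()] objects, one per drug.
#' @export
build_drug_profiles <- function(targets, ann) {
  drugs <- names(targets)
  stats::setNames(lapply(drugs, build_drug_profile, targets = targets,
                         ann = ann), drugs)
}

#' Score phenotype categories for a profile
#'
#' Adds each profile term's weight to every top-level category (root child)
#' the term maps to via [term_categories()]; a term under several categories
#' counts fully toward each. Categories with no mapped weight are omitted.
#'
#' @param profile a non-empty [phenotype_profile()].
#' @param ont an [ontology()].
#' @return object of class `"category_scores"`: a data.frame with columns
#'   `rank`, `category_id`, `category_name`, `score`, ordered by descending
#'   score with lexicographic tie-break on category id.
#' @export
score_categories <- function(profile, ont) {
  if (!length(profile$weights)) stop("cannot score categories of an empty profile")
  acc <- stats::setNames(numeric(length(root_categories(ont))),
                         root_categories(ont))
  for (t in profile_terms(profile)) {
    for (cat in term_categories(ont, t))
      acc[[cat]] <- acc[[cat]] + profile$weights[[t]]
  }
  acc <- acc[acc > 0]
  ord <- order(-acc, names(acc))
  df <- data.frame(rank = seq_along(ord),
                   category_id = names(acc)[ord],
                   category_name = unname(ont$names[names(acc)[ord]]),
                   score = unname(acc[ord]),
                   stringsAsFactors = FALSE)
  class(df) <- c("category_scores", "data.frame")
  df
}

#' Write a profile to TSV (owner_id, term_id, weight)
#' @param profile a [phenotype_profile()].
#' @param path output file path.
#' @export
write_profile <- function(profile, path) {
  df <- data.frame(owner_id = profile$owner_id,
                   term_id = profile_terms(profile),
                   weight = unname(profile$weights))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
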