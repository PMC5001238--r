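# End-to-end screen: from loaded objects (or input files) to a ranked list
# and evaluation report.

#' Run the phenotype-profile drug screen on loaded objects
#'
#' Builds the disease profile (gene-count weights, median filter by default),
#' one profile per drug (confidence-sum weights), the IC table from the
#' propagated annotation corpus, and ranks every drug by symmetric best-match
#' average similarity to the disease.
#'
#' @param ont an [ontology()].
#' @param ann a [gene_annotations()] object.
#' @param disease_genes character vector of disease gene ids.
#' @param targets a [drug_targets()] object.
#' @param median_filter apply [filter_by_median()] to the disease profile?
#'   Default `TRUE`.
#' @param drug_median_filter also median-filter each drug profile? Default
#'   `FALSE` (experimental).
#' @param weighted weight the best-match averages by profile weights?
#'   Default `FALSE`.
#' @return list with `ranked` ([rank_drugs()] result), `disease_profile`
#'   (after filtering), `drug_profiles`, and `ic`.
#' @export
run_screen <- function(ont, ann, disease_genes, targets,
                       median_filter = TRUE, drug_median_filter = FALSE,
                       weighted = FALSE) {
  disease <- build_disease_profile(disease_genes, ann)
  if (median_filter) disease <- filter_by_median(disease)
  drugs <- build_drug_profiles(targets, ann)
  if (drug_median_filter)
    drugs <- lapply(drugs, function(p)
      if (length(p$weights)) filter_by_median(p) else p)
  ic <- compute_ic(ont, ann)
  ranked <- rank_drugs(disease, drugs, ic, ont, weighted = weighted)
  list(ranked = ranked, disease_profile = disease, drug_profiles = drugs,
       ic = ic)
}

#' Run the full pipeline from input files
#'
#' Loads the five input files, runs [run_screen()], and (if evaluation sets
#' are given) [evaluate()]s the ranking, optionally against a comparator
#' ranked list.
#'
#' @param ontology_path OBO file.
#' @param annotations_path gene-phenotype TSV.
#' @param targets_path drug-target TSV.
#' @param genes_path disease gene list.
#' @param eval_sets_path optional evaluation-set TSV.
#' @param comparator_path optional comparator ranked-list TSV.
#' @param score_scale,min_confidence see [load_drug_targets()].
#' @param virtual_root see [parse_obo()].
#' @inheritParams run_screen
#' @return the [run_screen()] list, plus `report` (an [evaluate()] result or
#'   `NULL`) and `sets`.
#' @export
run_pipeline <- function(ontology_path, annotations_path, targets_path,
                         genes_path, eval_sets_path = NULL,
                         comparator_path = NULL, score_scale = 1000,
                         min_confidence = 0, median_filter = TRUE,
                         weighted = FALSE, virtual_root = FALSE) {
  ont <- parse_obo(ontology_path, virtual_root = virtual_root)
  ann <- load_gene_phenotypes(annotations_path, ont)
  targets <- load_drug_targets(targets_path, score_scale = score_scale,
                               min_confidence = min_confidence)
  genes <- load_gene_list(genes_path)
  res <- run_screen(ont, ann, genes, targets, median_filter = median_filter,
                    weighted = weighted)
  res$ontology <- ont
  res$annotations <- ann
  res$sets <- NULL
  res$report <- NULL
  if (!is.null(eval_sets_path)) {
    res$sets <- load_evaluation_sets(eval_sets_path)
    comp <- if (!is.null(comparator_path)) read_ranked_drugs(comparator_path)
    res$report <- evaluate(res$ranked, res$sets, comparator = comp)
  }
  res
}
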