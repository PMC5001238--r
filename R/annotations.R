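# Readers for gene-phenotype annotations, drug-target tables, disease gene
# lists and evaluation sets, plus annotation propagation (true-path rule).

read_tsv_cols <- function(path, cols, header) {
  df <- utils::read.table(path, sep = "\t", header = header,
                          colClasses = "character", quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  if (header) {
    missing <- setdiff(cols, names(df))
    if (length(missing))
      stop("missing required column(s) in ", path, ": ",
           paste(missing, collapse = ", "))
    df <- df[cols]
  } else {
    if (ncol(df) < length(cols))
      stop("expected ", length(cols), " columns in ", path,
           ", found ", ncol(df))
    df <- df[seq_along(cols)]
    names(df) <- cols
  }
  df
}

#' Build a gene-phenotype annotation object
#'
#' @param direct named list: gene id -> character vector of directly annotated
#'   phenotype term ids.
#' @param ont the [ontology()] the terms live in.
#' @return object of class `"gene_annotations"` with elements `direct`,
#'   `propagated` (reflexive ancestor closure of each gene's set) and
#'   `universe` (number of genes with at least one annotation) — the
#'   denominator of the annotation frequency p(t).
#' @export
gene_annotations <- function(direct, ont) {
  direct <- direct[vapply(direct, length, 0L) > 0L]
  direct <- lapply(direct, function(ts) sort(unique(as.character(ts))))
  bad <- setdiff(unlist(direct, use.names = FALSE), ont$ids)
  if (length(bad))
    stop("annotation terms not in ontology: ", paste(bad, collapse = ", "))
  propagated <- lapply(direct, function(ts)
    sort(unique(unlist(ont$ancestors[ts], use.names = FALSE))))
  structure(list(direct = direct, propagated = propagated,
                 universe = length(direct)),
            class = "gene_annotations")
}

#' @export
print.gene_annotations <- function(x, ...) {
  cat("gene_annotations:", x$universe, "annotated genes,",
      length(unique(unlist(x$direct, use.names = FALSE))),
      "distinct direct terms\n")
  invisible(x)
}

#' Load a gene-phenotype annotation TSV
#'
#' Expects tab-separated columns `gene_id`, `phenotype_id` (MGI-report style
#' two-column projection). Rows citing terms unknown to the ontology (after
#' alt-id resolution) or obsolete terms are dropped with a warning giving the
#' count. Annotations are propagated to all ancestors of each term.
#'
#' @param path TSV file path.
#' @param ont an [ontology()].
#' @param header does the file carry a header row? Default `TRUE`.
#' @return a [gene_annotations()] object.
#' @export
load_gene_phenotypes <- function(path, ont, header = TRUE) {
  df <- read_tsv_cols(path, c("gene_id", "phenotype_id"), header)
  if (!nrow(df)) stop("no annotation rows in ", path)
  res <- vapply(df$phenotype_id, function(t) {
    r <- resolve_term(ont, t)
    if (is.na(r)) "" else r
  }, "", USE.NAMES = FALSE)
  dropped <- sum(res == "")
  if (dropped)
    warning(dropped, " annotation row(s) cite unknown/obsolete terms; dropped")
  keep <- res != ""
  if (!any(keep)) stop("no annotation rows survive term resolution in ", path)
  direct <- split(res[keep], df$gene_id[keep])
  gene_annotations(direct, ont)
}

#' Build a drug-target table
#'
#' @param drug_id,gene_id,confidence parallel vectors of drug-target links
#'   with confidences in `[0, 1]`. Duplicate (drug, gene) pairs collapse to
#'   the maximum confidence.
#' @return object of class `"drug_targets"`: a named list mapping drug id to a
#'   named numeric vector of per-gene confidences.
#' @export
drug_targets <- function(drug_id, gene_id, confidence) {
  confidence <- as.numeric(confidence)
  if (any(confidence < 0 | confidence > 1))
    stop("confidence outside [0, 1] for row(s): ",
         paste(which(confidence < 0 | confidence > 1), collapse = ", "))
  key <- paste(drug_id, gene_id, sep = "\r")
  best <- tapply(confidence, key, max)
  parts <- strsplit(names(best), "\r", fixed = TRUE)
  d <- vapply(parts, `[[`, "", 1L)
  g <- vapply(parts, `[[`, "", 2L)
  links <- lapply(split(seq_along(d), d), function(i)
    stats::setNames(as.numeric(best[i]), g[i])[order(g[i])])
  structure(links, class = "drug_targets")
}

#' Load a drug-target TSV
#'
#' Expects columns `drug_id`, `gene_id`, `score`. Raw scores are divided by
#' `score_scale` (1000 for STITCH-dialect integer scores, 1 for unit-scale
#' reals); links whose scaled confidence falls below `min_confidence` are
#' removed, and duplicate (drug, gene) links collapse to the maximum.
#'
#' @param path TSV file path.
#' @param score_scale positive divisor applied to the raw score column.
#' @param min_confidence drop links with scaled confidence strictly below
#'   this value; default 0 keeps all links.
#' @param header does the file carry a header row? Default `TRUE`.
#' @return a [drug_targets()] object.
#' @export
load_drug_targets <- function(path, score_scale = 1000, min_confidence = 0,
                              header = TRUE) {
  df <- read_tsv_cols(path, c("drug_id", "gene_id", "score"), header)
  if (!nrow(df)) stop("no drug-target rows in ", path)
  conf <- as.numeric(df$score) / score_scale
  bad <- which(is.na(conf) | conf < 0 | conf > 1)
  if (length(bad))
    stop("scaled score outside [0, 1] at data row(s): ",
         paste(bad, collapse = ", "))
  keep <- conf >= min_confidence
  if (!any(keep)) stop("no links survive min_confidence = ", min_confidence)
  drug_targets(df$drug_id[keep], df$gene_id[keep], conf[keep])
}

#' Load a disease gene list
#'
#' One gene id per line; blank lines and lines starting with `#` are ignored;
#' duplicates are removed.
#'
#' @param path file path.
#' @return character vector of gene ids.
#' @export
load_gene_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  genes <- unique(lines)
  if (!length(genes)) stop("no gene ids found in ", path)
  genes
}

eval_set_labels <- c("approved", "potential", "off_label")
eval_type_labels <- c("non_targeted_cancer", "targeted_cancer", "non_cancer")

#' Build evaluation drug sets
#'
#' Holds the labeled drug sets a ranked list is scored against. A drug listed
#' as `approved` is removed from the `potential` and `off_label` sets (the
#' novel-drug sets must not contain already-approved therapies).
#'
#' @param drug_id,set_label,drug_type parallel vectors; `set_label` in
#'   `approved | potential | off_label`, `drug_type` in
#'   `non_targeted_cancer | targeted_cancer | non_cancer`.
#' @return object of class `"evaluation_sets"` with named character vectors
#'   `membership` (drug -> set label) and `drug_type` (drug -> type label).
#' @export
evaluation_sets <- function(drug_id, set_label, drug_type) {
  bad <- setdiff(unique(set_label), eval_set_labels)
  if (length(bad)) stop("unknown set label(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(drug_type), eval_type_labels)
  if (length(bad)) stop("unknown drug type(s): ", paste(bad, collapse = ", "))
  approved <- unique(drug_id[set_label == "approved"])
  demoted <- unique(drug_id[set_label != "approved" & drug_id %in% approved])
  if (length(demoted))
    message(length(demoted),
            " approved drug(s) removed from potential/off_label sets")
  keep <- set_label == "approved" | !(drug_id %in% approved)
  drug_id <- drug_id[keep]; set_label <- set_label[keep]
  drug_type <- drug_type[keep]
  first <- !duplicated(drug_id)
  structure(list(
    membership = stats::setNames(set_label[first], drug_id[first]),
    drug_type = stats::setNames(drug_type[first], drug_id[first])),
    class = "evaluation_sets")
}

#' Load an evaluation-set TSV
#'
#' Expects columns `drug_id`, `set_label`, `drug_type`; see
#' [evaluation_sets()] for label vocabularies and the approved-drug removal
#' rule.
#'
#' @inheritParams load_gene_phenotypes
#' @return an [evaluation_sets()] object.
#' @export
load_evaluation_sets <- function(path, header = TRUE) {
  df <- read_tsv_cols(path, c("drug_id", "set_label", "drug_type"), header)
  if (!nrow(df)) stop("no evaluation rows in ", path)
  evaluation_sets(df$drug_id, df$set_label, df$drug_type)
}
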