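# Seeded synthetic study generator: layered is-a ontology, depth-biased
# gene-phenotype annotations, a disease gene set, and drug-target tables with
# planted positive drugs; plus writers for every input file dialect the
# loaders read.

#' Configuration for the synthetic study generator
#'
#' Defaults define the package's standard benchmark: a 200-term, 6-layer
#' ontology, 500 annotated genes averaging 8 direct annotations, 25 disease
#' genes, and 100 drugs averaging 5 targets each of which 10 are planted
#' positives drawing 80% of their targets from the disease gene set, with
#' STITCH-style confidences in [0.4, 0.9].
#'
#' @param seed integer seed; all generator randomness derives from it.
#' @param n_terms,n_layers,max_parents ontology shape: term count, number of
#'   layers (root layer included), and the maximum parents a term draws from
#'   the layer above.
#' @param n_genes number of annotated genes.
#' @param annotations_per_gene mean of the (min-1 Poisson) count of direct
#'   annotations per gene.
#' @param n_disease_genes size of the disease gene set.
#' @param n_drugs,n_positive_drugs total drugs and planted positives.
#' @param targets_per_drug mean of the (min-1 Poisson) target count per drug.
#' @param positive_overlap_fraction fraction of a positive drug's targets
#'   drawn from the disease gene set (0 = null condition).
#' @param confidence_range length-2 numeric in [0, 1]; confidences are drawn
#'   uniformly on the thousandths grid inside this range, so integer-score
#'   files round-trip exactly.
#' @return a `"synthetic_config"` list.
#' @export
synthetic_config <- function(seed = 42L, n_terms = 200L, n_layers = 6L,
                             max_parents = 3L, n_genes = 500L,
                             annotations_per_gene = 8,
                             n_disease_genes = 25L, n_drugs = 100L,
                             n_positive_drugs = 10L, targets_per_drug = 5,
                             positive_overlap_fraction = 0.8,
                             confidence_range = c(0.4, 0.9)) {
  cfg <- list(seed = as.integer(seed), n_terms = as.integer(n_terms),
              n_layers = as.integer(n_layers),
              max_parents = as.integer(max_parents),
              n_genes = as.integer(n_genes),
              annotations_per_gene = annotations_per_gene,
              n_disease_genes = as.integer(n_disease_genes),
              n_drugs = as.integer(n_drugs),
              n_positive_drugs = as.integer(n_positive_drugs),
              targets_per_drug = targets_per_drug,
              positive_overlap_fraction = positive_overlap_fraction,
              confidence_range = as.numeric(confidence_range))
  stopifnot(cfg$n_terms >= 1, cfg$n_layers >= 2, cfg$max_parents >= 1,
            cfg$n_genes >= 1, cfg$annotations_per_gene > 0,
            cfg$n_disease_genes >= 1, cfg$n_drugs >= 1,
            cfg$n_positive_drugs >= 0, cfg$targets_per_drug > 0,
            cfg$positive_overlap_fraction >= 0,
            cfg$positive_overlap_fraction <= 1,
            cfg$n_positive_drugs <= cfg$n_drugs,
            length(cfg$confidence_range) == 2,
            cfg$confidence_range[1] >= 0, cfg$confidence_range[2] <= 1,
            cfg$confidence_range[1] <= cfg$confidence_range[2])
  if (cfg$n_disease_genes > cfg$n_genes)
    stop("n_disease_genes exceeds n_genes")
  structure(cfg, class = "synthetic_config")
}

# Run fn with a deterministic sub-seed without disturbing the caller's RNG.
with_subseed <- function(seed, offset, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed((seed + offset) %% .Machine$integer.max)
  fn()
}

syn_term_id <- function(i) sprintf("SP:%07d", i)
syn_gene_id <- function(i) sprintf("gene%04d", i)
syn_drug_id <- function(i) sprintf("drug%04d", i)

#' Generate a layered single-root ontology
#'
#' Terms are arranged in layers with sizes growing geometrically from the
#' single root; each non-root term draws 1..`max_parents` parents uniformly
#' from the layer above, so the graph is acyclic by construction and every
#' term reaches the root. Deterministic for a fixed seed.
#'
#' @param config a [synthetic_config()].
#' @return an [ontology()] that passes full validation.
#' @export
generate_ontology <- function(config) {
  n <- config$n_terms
  if (n == 1L)
    return(ontology(syn_term_id(1L), "synthetic root",
                    stats::setNames(list(character()), syn_term_id(1L))))
  L <- config$n_layers
  if (n < L) stop("infeasible shape: n_terms must be >= n_layers")
  # geometric layer sizes: 1, ~2x, ~4x, ... rescaled to sum to n
  raw <- 2^(seq_len(L - 1L))
  sizes <- pmax(1L, as.integer(round(raw / sum(raw) * (n - 1L))))
  while (sum(sizes) > n - 1L) sizes[which.max(sizes)] <- sizes[which.max(sizes)] - 1L
  while (sum(sizes) < n - 1L) sizes[L - 1L] <- sizes[L - 1L] + 1L
  layer_of <- rep(seq_len(L - 1L), sizes)          # layer per non-root term

  ids <- syn_term_id(seq_len(n))
  root <- ids[[1L]]
  with_subseed(config$seed, 0L, function() {
    parents <- stats::setNames(vector("list", n), ids)
    parents[[root]] <- character()
    above <- list(root)
    start <- 2L
    for (l in seq_len(L - 1L)) {
      members <- ids[seq.int(start, length.out = sizes[[l]])]
      pool <- if (l == 1L) root else
        ids[seq.int(start - sizes[[l - 1L]], length.out = sizes[[l - 1L]])]
      for (t in members) {
        k <- sample.int(min(config$max_parents, length(pool)), 1L)
        parents[[t]] <- sample(pool, k)
      }
      start <- start + sizes[[l]]
    }
    ontology(ids, paste("synthetic term", seq_len(n)), parents)
  })
}

#' Generate a depth-biased gene-phenotype annotation corpus
#'
#' Each gene draws a direct-annotation count from a Poisson distribution
#' (minimum 1) and samples non-root terms without replacement with probability
#' proportional to a geometric decay in term depth (`0.5^depth`), so deeper,
#' more specific terms are rarer and information content grows with depth on
#' average — the property of real annotation corpora that gives Resnik scores
#' their signal.
#'
#' @param ont an [ontology()], typically from [generate_ontology()].
#' @param config a [synthetic_config()].
#' @return a [gene_annotations()] object with `universe == n_genes`.
#' @export
generate_annotations <- function(ont, config) {
  candidates <- setdiff(ont$ids, ont$root)
  if (!length(candidates)) candidates <- ont$root
  w <- 0.5^ont$depth[candidates]
  with_subseed(config$seed, 1L, function() {
    direct <- lapply(seq_len(config$n_genes), function(i) {
      k <- max(1L, stats::rpois(1L, config$annotations_per_gene))
      k <- min(k, length(candidates))
      sample(candidates, k, prob = w)
    })
    names(direct) <- syn_gene_id(seq_len(config$n_genes))
    gene_annotations(direct, ont)
  })
}

#' Generate the disease gene set and drug-target table with planted positives
#'
#' Disease genes are sampled uniformly from the annotated genes. Each drug
#' draws a Poisson (min 1) number of target genes; planted positive drugs
#' take `positive_overlap_fraction` of their targets (rounded) from the
#' disease gene set and the rest from non-disease genes, while negatives
#' target non-disease genes only. Confidences are uniform on the thousandths
#' grid within `confidence_range`.
#'
#' @param ann a [gene_annotations()] object (defines the gene pool).
#' @param config a [synthetic_config()].
#' @return list with `disease_genes` (character), `targets`
#'   ([drug_targets()]), and `truth` — a list with `positive_drug_ids`,
#'   `overlap_counts` (planted disease-gene targets per positive drug) and a
#'   `config` echo.
#' @export
generate_disease_and_drugs <- function(ann, config) {
  genes <- names(ann$direct)
  if (config$n_disease_genes >= length(genes))
    stop("need more genes than disease genes")
  lo <- round(config$confidence_range[1] * 1000)
  hi <- round(config$confidence_range[2] * 1000)
  with_subseed(config$seed, 2L, function() {
    disease_genes <- sort(sample(genes, config$n_disease_genes))
    other <- setdiff(genes, disease_genes)
    d_ids <- g_ids <- character(0); confs <- numeric(0)
    overlap_counts <- integer(0)
    for (i in seq_len(config$n_drugs)) {
      drug <- syn_drug_id(i)
      k <- max(1L, stats::rpois(1L, config$targets_per_drug))
      positive <- i <= config$n_positive_drugs
      if (positive) {
        k_pos <- min(round(config$positive_overlap_fraction * k),
                     length(disease_genes))
        k_neg <- min(k - k_pos, length(other))
        tg <- c(sample(disease_genes, k_pos), sample(other, k_neg))
        overlap_counts[[drug]] <- as.integer(k_pos)
      } else {
        tg <- sample(other, min(k, length(other)))
      }
      d_ids <- c(d_ids, rep.int(drug, length(tg)))
      g_ids <- c(g_ids, tg)
      confs <- c(confs, sample(seq.int(lo, hi), length(tg),
                               replace = TRUE) / 1000)
    }
    list(disease_genes = disease_genes,
         targets = drug_targets(d_ids, g_ids, confs),
         truth = list(positive_drug_ids = syn_drug_id(
                        seq_len(config$n_positive_drugs)),
                      overlap_counts = overlap_counts,
                      config = unclass(config)))
  })
}

# ---- writers for the input file dialects ----------------------------------

#' Write an ontology as an OBO flat file
#' @param ont an [ontology()].
#' @param path output file path.
#' @export
write_obo <- function(ont, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (t in ont$ids) {
    writeLines("[Term]", con)
    writeLines(paste0("id: ", t), con)
    writeLines(paste0("name: ", ont$names[[t]]), con)
    for (p in sort(ont$parents[[t]]))
      writeLines(paste0("is_a: ", p, " ! ", ont$names[[p]]), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Write a gene-phenotype annotation TSV
#' @param ann a [gene_annotations()] object (direct annotations are written).
#' @param path output file path.
#' @export
write_gene_phenotypes <- function(ann, path) {
  genes <- names(ann$direct)
  df <- data.frame(
    gene_id = rep(genes, vapply(ann$direct, length, 0L)),
    phenotype_id = unlist(ann$direct, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a drug-target TSV with STITCH-style integer scores
#' @param targets a [drug_targets()] object; confidences are written as
#'   integer scores (confidence x 1000), the dialect [load_drug_targets()]
#'   reads with `score_scale = 1000`.
#' @param path output file path.
#' @export
write_drug_targets <- function(targets, path) {
  drugs <- names(targets)
  df <- data.frame(
    drug_id = rep(drugs, vapply(targets, length, 0L)),
    gene_id = unlist(lapply(targets, names), use.names = FALSE),
    score = as.integer(round(unlist(targets, use.names = FALSE) * 1000)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a disease gene list (one id per line)
#' @param genes character vector of gene ids.
#' @param path output file path.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(c("# disease gene list", sort(unique(genes))), path)
  invisible(path)
}

#' Write an evaluation-set TSV from the planted truth
#'
#' Planted positive drugs are rendered with set label `"potential"` and a
#' drug type cycling deterministically through the three type labels, so the
#' per-type report paths are exercised.
#'
#' @param truth the `truth` element of [generate_disease_and_drugs()].
#' @param path output file path.
#' @export
write_evaluation_sets_tsv <- function(truth, path) {
  pos <- truth$positive_drug_ids
  types <- eval_type_labels[(seq_along(pos) - 1L) %% 3L + 1L]
  df <- data.frame(drug_id = pos, set_label = "potential", drug_type = types)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the planted truth as JSON
#' @param truth the `truth` element of [generate_disease_and_drugs()].
#' @param path output file path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Generate a full synthetic study and write all input files
#'
#' Runs the three generators and writes `ontology.obo`,
#' `gene_phenotypes.tsv`, `drug_targets.tsv`, `disease_genes.txt`,
#' `evaluation_sets.tsv` and `truth.json` into `dir` — the same dialects the
#' package's loaders read, so loader tests and end-to-end runs share one
#' fixture path. Byte-identical output for a fixed config.
#'
#' @param dir output directory (created if absent).
#' @param config a [synthetic_config()].
#' @return invisibly, a named list of the written file paths plus the
#'   in-memory objects (`ontology`, `annotations`, `disease_genes`,
#'   `targets`, `truth`).
#' @export
simulate_study <- function(dir, config = synthetic_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ont <- generate_ontology(config)
  ann <- generate_annotations(ont, config)
  dd <- generate_disease_and_drugs(ann, config)
  paths <- list(ontology = file.path(dir, "ontology.obo"),
                annotations = file.path(dir, "gene_phenotypes.tsv"),
                targets = file.path(dir, "drug_targets.tsv"),
                genes = file.path(dir, "disease_genes.txt"),
                eval_sets = file.path(dir, "evaluation_sets.tsv"),
                truth = file.path(dir, "truth.json"))
  write_obo(ont, paths$ontology)
  write_gene_phenotypes(ann, paths$annotations)
  write_drug_targets(dd$targets, paths$targets)
  write_gene_list(dd$disease_genes, paths$genes)
  write_evaluation_sets_tsv(dd$truth, paths$eval_sets)
  write_truth(dd$truth, paths$truth)
  invisible(c(paths, list(ontology_obj = ont, annotations_obj = ann,
                          disease_genes = dd$disease_genes,
                          targets_obj = dd$targets, truth = dd$truth)))
}
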