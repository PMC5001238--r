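# In-code fixtures shared across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# root R; categories C1, C2 under R; leaves under the categories, X under both
tiny_ontology <- function() {
  ontology(
    ids = c("R", "C1", "C2", "A", "B", "X"),
    names = c("root", "cat one", "cat two", "leaf a", "leaf b", "shared leaf"),
    parents = list(R = character(), C1 = "R", C2 = "R",
                   A = "C1", B = "C2", X = c("C1", "C2")))
}

# 4 genes over the tiny ontology; term X annotated to 2 of the 4 genes
tiny_annotations <- function(ont = tiny_ontology()) {
  gene_annotations(list(g1 = c("A", "X"), g2 = "X", g3 = "B", g4 = "A"), ont)
}

# a small random study in one call; sizes chosen so brute force stays instant
small_study <- function(seed, n_terms = 40, n_genes = 15, ...) {
  cfg <- synthetic_config(seed = seed, n_terms = n_terms, n_layers = 4,
                          n_genes = n_genes, annotations_per_gene = 4,
                          n_disease_genes = 5, n_drugs = 12,
                          n_positive_drugs = 3, targets_per_drug = 3, ...)
  ont <- generate_ontology(cfg)
  ann <- generate_annotations(ont, cfg)
  dd <- generate_disease_and_drugs(ann, cfg)
  list(cfg = cfg, ont = ont, ann = ann, dd = dd)
}

obo_text <- function(...) {
  f <- withr::local_tempfile(fileext = ".obo",
                             .local_envir = parent.frame())
  writeLines(c(...), f)
  f
}

write_tsv_fixture <- function(df, dir = NULL) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}
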