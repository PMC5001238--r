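test_that("IC from a hand-counted closure: 2 of 4 genes -> -ln(0.5)", {
  # chain root <- mid <- leaf; sib under root
  ont <- ontology(c("root", "mid", "leaf", "sib"),
                  parents = list(root = character(), mid = "root",
                                 leaf = "mid", sib = "root"))
  ann <- gene_annotations(list(g1 = "leaf", g2 = "mid", g3 = "sib",
                               g4 = "sib"), ont)
  ic <- compute_ic(ont, ann)
  expect_equal(ic$ic[["root"]], 0)              # closure forces p(root) = 1
  expect_equal(ic$frequency[["mid"]], 2L)       # g1 (via leaf) and g2
  expect_equal(ic$ic[["mid"]], -log(0.5))
  expect_equal(ic$ic[["leaf"]], -log(0.25))
  expect_false("unseen" %in% names(ic$ic))
})

test_that("IC frequencies match brute-force membership counting", {
  s <- small_study(seed = 43, n_terms = 50, n_genes = 20)
  ic <- compute_ic(s$ont, s$ann)
  oracle <- bf_ic(s$ont$parents, s$ann$direct)
  expect_setequal(names(ic$ic), names(oracle))
  expect_equal(ic$ic[names(oracle)], oracle, tolerance = 1e-12)
})

test_that("IC never decreases from parent to child", {
  s <- small_study(seed = 47)
  ic <- compute_ic(s$ont, s$ann)
  for (t in s$ont$ids) for (p in s$ont$parents[[t]])
    if (t %in% names(ic$ic) && p %in% names(ic$ic))
      expect_gte(ic$ic[[t]], ic$ic[[p]])
})

test_that("log base rescales IC globally and preserves order", {
  s <- small_study(seed = 53)
  ic_e <- compute_ic(s$ont, s$ann)
  ic_2 <- compute_ic(s$ont, s$ann, base = 2)
  nz <- names(ic_e$ic)[ic_e$ic > 0]
  expect_equal(ic_2$ic[nz] / ic_e$ic[nz],
               rep(1 / log(2), length(nz)), ignore_attr = TRUE)
})

test_that("term similarity: self gives own IC, root-only siblings give 0", {
  ont <- tiny_ontology()
  ann <- tiny_annotations(ont)
  ic <- compute_ic(ont, ann)
  for (t in names(ic$ic))
    expect_equal(term_similarity(t, t, ic, ont), ic$ic[[t]])
  expect_equal(term_similarity("A", "B", ic, ont), 0)  # only share the root
})

test_that("similarities match the exhaustive triple-loop reference", {
  for (seed in c(61, 67, 71)) {
    s <- small_study(seed = seed, n_terms = 50, n_genes = 20)
    ic <- compute_ic(s$ont, s$ann)
    ic_map <- ic$ic
    terms <- names(ic_map)
    for (i in 1:10) {
      t1 <- sample(terms, 1); t2 <- sample(terms, 1)
      expect_equal(term_similarity(t1, t2, ic, s$ont),
                   bf_term_sim(s$ont$parents, ic_map, t1, t2),
                   tolerance = 1e-12)
    }
    p1 <- phenotype_profile("a", stats::setNames(runif(10, 0.5, 3),
                                                 sample(terms, 10)))
    p2 <- phenotype_profile("b", stats::setNames(runif(8, 0.5, 3),
                                                 sample(terms, 8)))
    expect_equal(directed_similarity(p1, p2, ic, s$ont),
                 bf_directed_sim(s$ont$parents, ic_map,
                                 names(p1$weights), names(p2$weights)),
                 tolerance = 1e-12)
    expect_equal(profile_similarity(p1, p2, ic, s$ont),
                 bf_profile_sim(s$ont$parents, ic_map,
                                names(p1$weights), names(p2$weights)),
                 tolerance = 1e-12)
  }
})

test_that("profile similarity identities: self, symmetry, bounds, two-direction mean", {
  s <- small_study(seed = 73)
  ic <- compute_ic(s$ont, s$ann)
  terms <- names(ic$ic)
  set.seed(73)
  for (i in 1:10) {
    p1 <- phenotype_profile("a", stats::setNames(rep(1, 6), sample(terms, 6)))
    p2 <- phenotype_profile("b", stats::setNames(rep(1, 5), sample(terms, 5)))
    # self-similarity is the mean IC of the profile's terms
    expect_equal(profile_similarity(p1, p1, ic, s$ont),
                 mean(ic$ic[names(p1$weights)]))
    s12 <- profile_similarity(p1, p2, ic, s$ont)
    expect_identical(s12, profile_similarity(p2, p1, ic, s$ont))
    expect_gte(s12, 0)
    expect_lte(s12, max(ic$ic))
    d12 <- directed_similarity(p1, p2, ic, s$ont)
    d21 <- directed_similarity(p2, p1, ic, s$ont)
    expect_equal(s12, (d12 + d21) / 2)
  }
})

test_that("profiles with no IC-covered terms give NA, not zero", {
  ont <- tiny_ontology()
  ann <- gene_annotations(list(g1 = "A", g2 = "A"), ont)
  ic <- compute_ic(ont, ann)
  covered <- phenotype_profile("a", c(A = 1))
  uncovered <- phenotype_profile("b", c(B = 1))  # B never annotated
  expect_true(is.na(directed_similarity(uncovered, covered, ic, ont)))
  expect_true(is.na(profile_similarity(uncovered, covered, ic, ont)))
  expect_false(is.na(profile_similarity(covered, covered, ic, ont)))
})

test_that("pair cache does not change results", {
  s <- small_study(seed = 79)
  ic <- compute_ic(s$ont, s$ann)
  terms <- names(ic$ic)
  p1 <- phenotype_profile("a", stats::setNames(rep(1, 7), terms[1:7]))
  p2 <- phenotype_profile("b", stats::setNames(rep(1, 7), terms[8:14]))
  cache <- new.env(parent = emptyenv())
  a <- profile_similarity(p1, p2, ic, s$ont, cache = cache)
  b <- profile_similarity(p1, p2, ic, s$ont, cache = cache)  # cache warm
  c0 <- profile_similarity(p1, p2, ic, s$ont)
  expect_identical(a, b)
  expect_identical(a, c0)
})

test_that("weighted mode reweights the best-match average by profile weights", {
  s <- small_study(seed = 83)
  ic <- compute_ic(s$ont, s$ann)
  terms <- names(ic$ic)[ic$ic > 0][1:4]
  w <- stats::setNames(c(4, 1, 1, 1), terms)
  p1 <- phenotype_profile("a", w)
  p2 <- phenotype_profile("b", stats::setNames(1, terms[1]))
  bm <- vapply(terms, function(t1)
    max(vapply(terms[1], function(t2)
      term_similarity(t1, t2, ic, s$ont), 0)), 0)
  expect_equal(directed_similarity(p1, p2, ic, s$ont, weighted = TRUE),
               sum(bm * w / sum(w)))
  expect_equal(directed_similarity(p1, p2, ic, s$ont), mean(bm))
})
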