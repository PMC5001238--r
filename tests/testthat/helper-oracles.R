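# Brute-force reference implementations, kept independent of the package's
# precomputed-closure code path: ancestors by exhaustive path enumeration,
# similarities by literal triple loops over term pairs and common ancestors.

# reflexive ancestor set by following every parent path (no memoization)
bf_ancestors <- function(parents, term) {
  out <- term
  for (p in parents[[term]]) out <- c(out, bf_ancestors(parents, p))
  unique(out)
}

bf_common_ancestors <- function(parents, t1, t2) {
  intersect(bf_ancestors(parents, t1), bf_ancestors(parents, t2))
}

# IC by direct membership counting over propagated-by-brute-force gene sets
bf_ic <- function(parents, direct) {
  prop <- lapply(direct, function(ts)
    unique(unlist(lapply(ts, bf_ancestors, parents = parents))))
  all_terms <- unique(unlist(prop))
  freq <- vapply(all_terms, function(t)
    sum(vapply(prop, function(s) t %in% s, TRUE)), 0L)
  names(freq) <- all_terms
  -log(freq / length(direct))
}

bf_term_sim <- function(parents, ic_map, t1, t2) {
  ca <- bf_common_ancestors(parents, t1, t2)
  vals <- ic_map[intersect(ca, names(ic_map))]
  if (!length(vals)) 0 else max(vals)
}

bf_directed_sim <- function(parents, ic_map, terms1, terms2) {
  terms1 <- terms1[terms1 %in% names(ic_map)]
  terms2 <- terms2[terms2 %in% names(ic_map)]
  if (!length(terms1) || !length(terms2)) return(NA_real_)
  mean(vapply(terms1, function(t1)
    max(vapply(terms2, function(t2)
      bf_term_sim(parents, ic_map, t1, t2), 0)), 0))
}

bf_profile_sim <- function(parents, ic_map, terms1, terms2) {
  d12 <- bf_directed_sim(parents, ic_map, terms1, terms2)
  d21 <- bf_directed_sim(parents, ic_map, terms2, terms1)
  if (is.na(d12) || is.na(d21)) NA_real_ else (d12 + d21) / 2
}

# AP by the literal definition: sum over positives of precision at their
# rank, divided by the number of positives in the list
bf_average_precision <- function(ids_in_order, positives) {
  pos <- intersect(positives, ids_in_order)
  s <- 0
  for (p in pos) {
    r <- match(p, ids_in_order)
    s <- s + sum(ids_in_order[seq_len(r)] %in% pos) / r
  }
  s / length(pos)
}
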