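# Ontology: rooted is-a DAG over phenotype terms, with ancestor queries.

#' Construct a phenotype ontology from parent lists
#'
#' Builds and validates a rooted directed acyclic graph of phenotype terms
#' connected by is-a edges. Ancestor closures are precomputed so that
#' [ancestors()], [common_ancestors()] and [term_categories()] are cheap
#' lookups.
#'
#' @param ids character vector of unique term identifiers.
#' @param names character vector of term labels, parallel to `ids`.
#' @param parents named list: for each term id, the character vector of its
#'   is-a parents (empty for the root).
#' @param alt_ids named character vector mapping alternate ids to primary ids
#'   (may be empty).
#' @param virtual_root if `TRUE` and the graph has several parentless terms,
#'   a synthetic root (`"VROOT"`) is inserted above them; if `FALSE` (default)
#'   anything other than exactly one root is an error.
#' @return An object of class `"ontology"`: a list with elements `ids`,
#'   `names`, `parents`, `children`, `ancestors` (reflexive closure per term),
#'   `depth` (shortest is-a distance to the root), `root`, `alt_ids`.
#' @export
ontology <- function(ids, names = ids, parents, alt_ids = character(),
                     virtual_root = FALSE) {
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop("duplicate term ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (length(names) != length(ids)) stop("`names` must be parallel to `ids`")
  parents <- parents[ids]
  names(parents) <- ids
  parents <- lapply(parents, function(p) unique(as.character(p)))

  unknown <- setdiff(unlist(parents, use.names = FALSE), ids)
  if (length(unknown))
    stop("is_a target(s) not defined in the ontology: ",
         paste(unknown, collapse = ", "))

  topo_sort_terms(ids, parents)   # cycle check before root diagnosis

  roots <- ids[vapply(parents, length, 0L) == 0L]
  if (length(roots) != 1L) {
    if (virtual_root && length(roots) > 1L) {
      vr <- "VROOT"
      if (vr %in% ids) stop("cannot insert virtual root: id 'VROOT' in use")
      ids <- c(vr, ids)
      names <- c("virtual root", names)
      parents <- c(stats::setNames(list(character()), vr), parents)
      for (r in roots) parents[[r]] <- vr
      roots <- vr
    } else {
      stop("ontology must have exactly one root; found ", length(roots),
           if (length(roots)) paste0(" (", paste(roots, collapse = ", "), ")"))
    }
  }
  root <- roots[[1L]]

  ord <- topo_sort_terms(ids, parents)

  # reflexive ancestor closure and depth, in topological (root-first) order
  anc <- vector("list", length(ids)); names(anc) <- ids
  depth <- stats::setNames(rep.int(NA_integer_, length(ids)), ids)
  for (t in ord) {
    ps <- parents[[t]]
    anc[[t]] <- unique(c(t, unlist(anc[ps], use.names = FALSE)))
    depth[[t]] <- if (length(ps)) min(depth[ps]) + 1L else 0L
  }

  children <- lapply(stats::setNames(ids, ids), function(x) character())
  for (t in ids) for (p in parents[[t]])
    children[[p]] <- c(children[[p]], t)

  structure(
    list(ids = ids, names = stats::setNames(as.character(names), ids),
         parents = parents, children = children, ancestors = anc,
         depth = depth, root = root, alt_ids = alt_ids),
    class = "ontology")
}

#' @export
print.ontology <- function(x, ...) {
  cat("ontology: ", length(x$ids), " terms, root ", x$root,
      " (", x$names[[x$root]], "), max depth ", max(x$depth), "\n", sep = "")
  invisible(x)
}

# Kahn topological sort from the root downward; errors on cycles.
topo_sort_terms <- function(ids, parents) {
  n_par <- vapply(parents, length, 0L)
  kids <- lapply(stats::setNames(ids, ids), function(x) character())
  for (t in ids) for (p in parents[[t]]) kids[[p]] <- c(kids[[p]], t)
  queue <- ids[n_par == 0L]
  out <- character(0)
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]
    out <- c(out, t)
    for (k in kids[[t]]) {
      n_par[[k]] <- n_par[[k]] - 1L
      if (n_par[[k]] == 0L) queue <- c(queue, k)
    }
  }
  if (length(out) != length(ids))
    stop("cycle detected in is-a graph involving: ",
         paste(setdiff(ids, out), collapse = ", "))
  out
}

#' Parse an OBO flat file into an ontology
#'
#' Reads `[Term]` stanzas and honors the tags `id`, `name`, `is_a`,
#' `is_obsolete` and `alt_id`; all other stanza types and tag lines are
#' ignored. Obsolete terms are dropped (with their edges). Term ids are
#' opaque strings.
#'
#' @param path path to an OBO 1.2/1.4 flat file.
#' @param virtual_root see [ontology()].
#' @return an [ontology()] object.
#' @export
parse_obo <- function(path, virtual_root = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s*!.*$", "", lines)        # trailing comments
  lines <- trimws(lines)

  in_term <- FALSE
  cur <- NULL
  terms <- list()
  flush <- function(cur) {
    if (is.null(cur)) return(invisible())
    if (is.null(cur$id))
      stop("malformed [Term] stanza ending near line ", cur$line, ": no id")
    terms[[length(terms) + 1L]] <<- cur
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (ln == "") next
    if (grepl("^\\[", ln)) {
      flush(cur); cur <- NULL
      in_term <- identical(ln, "[Term]")
      if (in_term) cur <- list(line = i, parents = character(),
                               alt = character(), obsolete = FALSE)
      next
    }
    if (!in_term) next
    m <- regmatches(ln, regexec("^([A-Za-z_]+):\\s*(.*)$", ln))[[1L]]
    if (length(m) != 3L)
      stop("malformed tag line ", i, ": ", ln)
    tag <- m[[2L]]; val <- trimws(m[[3L]])
    if (tag == "id") {
      if (!is.null(cur$id)) stop("duplicate id tag at line ", i)
      cur$id <- val
    } else if (tag == "name") cur$name <- val
    else if (tag == "is_a") cur$parents <- c(cur$parents, val)
    else if (tag == "alt_id") cur$alt <- c(cur$alt, val)
    else if (tag == "is_obsolete") cur$obsolete <- identical(tolower(val), "true")
    # other tags ignored
  }
  flush(cur)
  if (!length(terms)) stop("no [Term] stanzas found in ", path)

  obs <- vapply(terms, function(t) isTRUE(t$obsolete), TRUE)
  live <- terms[!obs]
  if (!length(live)) stop("all terms obsolete in ", path)
  ids <- vapply(live, function(t) t$id, "")
  nms <- vapply(live, function(t) if (is.null(t$name)) t$id else t$name, "")
  parents <- stats::setNames(lapply(live, function(t) t$parents), ids)

  alt <- character()
  for (t in live) if (length(t$alt))
    alt[t$alt] <- t$id

  ontology(ids, nms, parents, alt_ids = alt, virtual_root = virtual_root)
}

# Resolve a possibly-alternate id to its primary id; NA if unknown.
resolve_term <- function(ont, id) {
  if (id %in% ont$ids) return(id)
  if (id %in% names(ont$alt_ids)) return(unname(ont$alt_ids[[id]]))
  NA_character_
}

check_term <- function(ont, term) {
  t <- resolve_term(ont, term)
  if (is.na(t)) stop("unknown term id: ", term)
  t
}

#' Ancestors of a term
#'
#' Transitive closure over is-a parent edges. With `reflexive = TRUE` the
#' term itself is included, so that every term is its own ancestor (this
#' reflexive convention is what makes a term's self-similarity equal its own
#' information content downstream).
#'
#' @param ont an [ontology()].
#' @param term a term id (alternate ids are resolved).
#' @param reflexive include `term` itself? Default `TRUE`.
#' @return character vector of term ids.
#' @export
ancestors <- function(ont, term, reflexive = TRUE) {
  t <- check_term(ont, term)
  a <- ont$ancestors[[t]]
  if (reflexive) a else setdiff(a, t)
}

#' Common ancestors of two terms
#'
#' Intersection of the two reflexive ancestor sets; never empty because the
#' root is shared by every pair, and contains the term itself when the two
#' arguments coincide.
#'
#' @inheritParams ancestors
#' @param t1,t2 term ids.
#' @return character vector of term ids.
#' @export
common_ancestors <- function(ont, t1, t2) {
  a1 <- ancestors(ont, t1, reflexive = TRUE)
  a2 <- ancestors(ont, t2, reflexive = TRUE)
  intersect(a1, a2)
}

#' Top-level categories of a term
#'
#' The phenotype categories are the root's direct children; a term belongs to
#' every category it can reach by is-a edges (multiple inheritance gives
#' multiple categories). The root itself has no category.
#'
#' @inheritParams ancestors
#' @return character vector of category term ids (root children).
#' @export
term_categories <- function(ont, term) {
  t <- check_term(ont, term)
  intersect(ont$ancestors[[t]], ont$children[[ont$root]])
}

#' @rdname term_categories
#' @export
root_categories <- function(ont) ont$children[[ont$root]]
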