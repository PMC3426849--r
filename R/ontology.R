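#' Ontology DAG of functional terms
#'
#' A rooted directed acyclic graph of terms with child-to-parent edges,
#' as used for upward propagation of gene annotations.
#'
#' @param terms Character vector of term IDs.
#' @param edges Two-column data frame or matrix (`child`, `parent`).
#' @param root Root term ID; inferred as the unique term without parents
#'   when omitted.
#' @return An `OntologyDAG` object with a precomputed parent list.
#' @export
ontology_dag <- function(terms, edges, root = NULL) {
  terms <- unique(as.character(terms))
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  names(edges)[1:2] <- c("child", "parent")
  bad <- setdiff(unique(c(edges$child, edges$parent)), terms)
  if (length(bad)) stop("edges reference unknown terms: ",
                        paste(bad, collapse = ", "))
  parents <- split(edges$parent, factor(edges$child, levels = terms))
  if (is.null(root)) {
    no_parent <- terms[vapply(parents, length, 0L) == 0L]
    if (length(no_parent) != 1L)
      stop("cannot infer a unique root (parentless terms: ",
           paste(no_parent, collapse = ", "), ")")
    root <- no_parent
  }
  dag <- structure(list(terms = terms, edges = edges, root = root,
                        parents = parents),
                   class = "OntologyDAG")
  # acyclicity + reachability check via full ancestor closure
  anc <- term_ancestors(dag)
  non_root <- setdiff(terms, root)
  unreachable <- non_root[!vapply(anc[non_root], function(a) root %in% a,
                                  TRUE)]
  if (length(unreachable))
    stop("terms cannot reach root: ", paste(unreachable, collapse = ", "))
  dag$ancestors <- anc
  dag
}

#' @export
print.OntologyDAG <- function(x, ...) {
  cat(sprintf("OntologyDAG: %d terms, %d edges, root %s\n",
              length(x$terms), nrow(x$edges), x$root))
  invisible(x)
}

# Ancestor sets (excluding the term itself) for every term; errors on a
# cycle, which would make the memoized recursion re-enter a term.
term_ancestors <- function(dag) {
  anc <- stats::setNames(vector("list", length(dag$terms)), dag$terms)
  state <- stats::setNames(integer(length(dag$terms)), dag$terms)
  visit <- function(t) {
    if (state[[t]] == 2L) return(anc[[t]])
    if (state[[t]] == 1L) stop("ontology contains a cycle through ", t)
    state[[t]] <<- 1L
    ps <- dag$parents[[t]]
    res <- character()
    for (p in ps) res <- union(res, c(p, visit(p)))
    anc[[t]] <<- res
    state[[t]] <<- 2L
    res
  }
  for (t in dag$terms) visit(t)
  anc
}

#' Direct gene annotations with evidence codes
#'
#' @param df Data frame with columns `gene_id`, `term_id`, `evidence`
#'   (evidence missing entries are treated as empty strings).
#' @return An `AnnotationSet` (propagation is filled by [propagate()]).
#' @export
annotation_set <- function(df) {
  stopifnot(all(c("gene_id", "term_id") %in% names(df)))
  if (is.null(df$evidence)) df$evidence <- ""
  df <- unique(df[, c("gene_id", "term_id", "evidence")])
  structure(list(records = df, propagated = NULL),
            class = "AnnotationSet")
}

#' Propagate annotations upward through the DAG
#'
#' Every gene inherits, in addition to its direct terms, all their
#' ancestors. Propagation is idempotent.
#'
#' @param dag An [ontology_dag()].
#' @param annotations An [annotation_set()].
#' @param lenient If `TRUE`, annotations to unknown terms are dropped with
#'   a warning instead of raising an error.
#' @return The `AnnotationSet` with `propagated` filled (a named list of
#'   term-ID character vectors per gene).
#' @export
propagate <- function(dag, annotations, lenient = FALSE) {
  rec <- annotations$records
  unknown <- setdiff(unique(rec$term_id), dag$terms)
  if (length(unknown)) {
    msg <- paste("annotations to unknown terms:",
                 paste(unknown, collapse = ", "))
    if (!lenient) stop(msg)
    warning(msg, "; dropped")
    rec <- rec[!rec$term_id %in% unknown, ]
  }
  direct <- split(rec$term_id, rec$gene_id)
  prop <- lapply(direct, function(ts) {
    ts <- unique(ts)
    unique(c(ts, unlist(dag$ancestors[ts], use.names = FALSE)))
  })
  annotations$records <- rec
  annotations$direct <- lapply(direct, unique)
  annotations$propagated <- prop
  annotations
}

#' Positive training genes for a term
#'
#' Genes annotated to `term` directly or by inheritance, after removing
#' direct annotations whose evidence code is blacklisted (before
#' propagation, so a gene reachable only via a blacklisted record is
#' excluded).
#'
#' @param dag An [ontology_dag()].
#' @param annotations An [annotation_set()].
#' @param term Target term ID.
#' @param evidence_blacklist Character vector of excluded evidence codes
#'   (e.g. `"IEA"`).
#' @return Character vector of gene IDs (possibly empty, with a warning).
#' @export
derive_positive_set <- function(dag, annotations, term,
                                evidence_blacklist = character()) {
  if (!term %in% dag$terms) stop("unknown term: ", term)
  rec <- annotations$records
  rec <- rec[!rec$evidence %in% evidence_blacklist, ]
  ann <- propagate(dag, annotation_set(rec))
  pos <- names(ann$propagated)[vapply(ann$propagated,
                                      function(ts) term %in% ts, TRUE)]
  if (!length(pos)) warning("no genes annotated to ", term)
  sort(pos)
}

#' Negative training genes and the terms defining them
#'
#' A term is "negative" when at most a fraction `p_threshold` of its
#' (propagated) annotated genes are positives; terms with no annotated
#' genes are ignored, and the root is excluded from the non-negative test
#' (every gene trivially reaches it). Negatives are genes with at least
#' one direct annotation in a negative term and no annotation, direct or
#' propagated, in any non-root non-negative term.
#'
#' @param dag An [ontology_dag()].
#' @param annotations A propagated [annotation_set()] (propagation is run
#'   if missing).
#' @param positives Character vector, the positive class.
#' @param p_threshold Fraction in [0, 1]; default 0.05.
#' @return List with `negatives` and `negative_terms`.
#' @export
derive_negative_set <- function(dag, annotations, positives,
                                p_threshold = 0.05) {
  stopifnot(p_threshold >= 0, p_threshold <= 1)
  if (is.null(annotations$propagated))
    annotations <- propagate(dag, annotations)
  prop <- annotations$propagated
  genes_by_term <- stats::setNames(
    lapply(dag$terms, function(t)
      names(prop)[vapply(prop, function(ts) t %in% ts, TRUE)]),
    dag$terms)
  n_ann <- vapply(genes_by_term, length, 0L)
  frac_pos <- vapply(genes_by_term, function(g)
    if (length(g)) mean(g %in% positives) else NA_real_, 0)
  negative_terms <- dag$terms[!is.na(frac_pos) & frac_pos <= p_threshold]
  non_negative <- setdiff(dag$terms[n_ann > 0], c(negative_terms, dag$root))

  direct <- annotations$direct
  negatives <- names(direct)[vapply(names(direct), function(g) {
    any(direct[[g]] %in% negative_terms) &&
      !any(prop[[g]] %in% non_negative)
  }, TRUE)]
  negatives <- setdiff(negatives, positives)
  if (!length(negatives)) warning("negative set is empty")
  list(negatives = sort(negatives), negative_terms = sort(negative_terms))
}

#' Derive a full training set from ontology + annotations
#'
#' Convenience wrapper: positive class from [derive_positive_set()],
#' negative class from [derive_negative_set()].
#'
#' @inheritParams derive_positive_set
#' @inheritParams derive_negative_set
#' @return A [training_set()].
#' @export
derive_training_set <- function(dag, annotations, term,
                                p_threshold = 0.05,
                                evidence_blacklist = character()) {
  pos <- derive_positive_set(dag, annotations, term, evidence_blacklist)
  rec <- annotations$records
  rec <- rec[!rec$evidence %in% evidence_blacklist, ]
  ann <- propagate(dag, annotation_set(rec))
  neg <- derive_negative_set(dag, ann, pos, p_threshold)
  training_set(pos, neg$negatives, process_term = term,
               negative_terms = neg$negative_terms)
}

#' Minimal OBO-format ontology reader
#'
#' Parses `[Term]` stanzas for `id:`, `is_a:` and
#' `relationship: part_of` lines; obsolete terms are skipped. Both
#' `is_a` and (optionally) `part_of` edges propagate.
#'
#' @param path Path to an OBO file.
#' @param use_part_of Include `part_of` relationships as edges.
#' @return An [ontology_dag()].
#' @export
read_obo <- function(path, use_part_of = TRUE) {
  lines <- readLines(path)
  terms <- character(); edges <- list()
  cur <- NULL; obsolete <- FALSE
  flush <- function() {
    if (!is.null(cur) && !obsolete) terms <<- c(terms, cur)
  }
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "[Term]") { flush(); cur <- NULL; obsolete <- FALSE }
    else if (startsWith(ln, "id:") && is.null(cur))
      cur <- trimws(sub("^id:", "", ln))
    else if (startsWith(ln, "is_obsolete: true")) obsolete <- TRUE
    else if (startsWith(ln, "is_a:") && !is.null(cur))
      edges[[length(edges) + 1L]] <-
        c(cur, trimws(sub("^is_a:", "", ln)))
    else if (use_part_of && startsWith(ln, "relationship: part_of") &&
             !is.null(cur))
      edges[[length(edges) + 1L]] <-
        c(cur, trimws(sub("^relationship: part_of", "", ln)))
  }
  flush()
  e <- if (length(edges)) do.call(rbind, edges) else
    matrix(character(), 0, 2)
  e <- e[e[, 1] %in% terms & e[, 2] %in% terms, , drop = FALSE]
  ontology_dag(terms, data.frame(child = e[, 1], parent = e[, 2],
                                 stringsAsFactors = FALSE))
}

#' GAF-like annotation reader
#'
#' Reads a tab-delimited file with (at least) gene, term and evidence
#' columns; comment lines starting with `!` are skipped.
#'
#' @param path File path.
#' @param columns Integer positions of the gene, term and evidence
#'   columns (default 1:3, suiting the simplified 3-column format this
#'   package writes; full GAF users can pass `c(2, 5, 7)`).
#' @return An [annotation_set()].
#' @export
read_gaf <- function(path, columns = c(1L, 2L, 3L)) {
  lines <- grep("^!", readLines(path), value = TRUE, invert = TRUE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  first <- parts[[1]]
  if (any(c("gene_id", "term_id") %in% first)) parts <- parts[-1]
  df <- data.frame(
    gene_id = vapply(parts, `[`, "", columns[1]),
    term_id = vapply(parts, `[`, "", columns[2]),
    evidence = vapply(parts, function(p)
      if (length(p) >= columns[3]) p[columns[3]] else "", ""),
    stringsAsFactors = FALSE)
  annotation_set(df)
}
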