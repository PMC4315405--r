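#' Parse an OBO ontology file
#'
#' Minimal reader for OBO 1.2/1.4 `[Term]` stanzas sufficient for
#' ancestor expansion of GO annotations.  Edges followed are `is_a` and,
#' optionally, `relationship: part_of`; other relationship types are
#' ignored.  Obsolete terms are dropped.  The resulting graph must be
#' acyclic.
#'
#' @param path Path to an OBO file.
#' @param edges Either `"is_a+part_of"` (default) or `"is_a"`.
#' @return A `tricall_ontology` object: list with `terms` (character
#'   vector of term ids), `parents` (named list, term -> character vector
#'   of direct parents), `names` (term -> name).
#' @export
read_obo <- function(path, edges = c("is_a+part_of", "is_a")) {
  edges <- arg_match(edges)
  lines <- readLines(path, warn = FALSE)
  parse_obo_lines(lines, use_part_of = edges == "is_a+part_of")
}

#' @rdname read_obo
#' @param text OBO content as a single string or character vector of
#'   lines (alternative to reading from a file).
#' @export
obo_from_text <- function(text, edges = c("is_a+part_of", "is_a")) {
  edges <- arg_match(edges)
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  parse_obo_lines(lines, use_part_of = edges == "is_a+part_of")
}

parse_obo_lines <- function(lines, use_part_of = TRUE) {
  lines <- sub("\\s*!.*$", "", trimws(lines))
  stanza_starts <- grep("^\\[", lines)
  term_starts <- which(lines == "[Term]")
  parents <- list()
  term_names <- character(0)
  for (s in term_starts) {
    nxt <- stanza_starts[stanza_starts > s]
    e <- if (length(nxt)) nxt[1] - 1L else length(lines)
    block <- lines[s:e]
    id <- sub("^id:\\s*", "", grep("^id:", block, value = TRUE))[1]
    if (is.na(id) || !nzchar(id)) next
    if (any(grepl("^is_obsolete:\\s*true", block))) next
    nm <- sub("^name:\\s*", "", grep("^name:", block, value = TRUE))[1]
    isa <- sub("^is_a:\\s*", "", grep("^is_a:", block, value = TRUE))
    isa <- sub("\\s.*$", "", isa)
    po <- character(0)
    if (use_part_of) {
      po <- grep("^relationship:\\s*part_of\\s", block, value = TRUE)
      po <- sub("^relationship:\\s*part_of\\s+", "", po)
      po <- sub("\\s.*$", "", po)
    }
    parents[[id]] <- unique(c(isa, po))
    term_names[id] <- if (is.na(nm)) id else nm
  }
  onto <- structure(list(terms = names(parents), parents = parents,
                         names = term_names),
                    class = "tricall_ontology")
  check_acyclic(onto)
  onto
}

check_acyclic <- function(onto) {
  state <- setNames(integer(length(onto$terms)), onto$terms)  # 0 new 1 open 2 done
  visit <- function(t) {
    if (!t %in% names(state)) return(invisible())
    if (state[[t]] == 1L) abort(paste0("ontology contains a cycle through ", t))
    if (state[[t]] == 2L) return(invisible())
    state[[t]] <<- 1L
    for (p in onto$parents[[t]]) visit(p)
    state[[t]] <<- 2L
    invisible()
  }
  for (t in onto$terms) visit(t)
  invisible(onto)
}

#' @export
print.tricall_ontology <- function(x, ...) {
  cat("<tricall_ontology> ", length(x$terms), " terms, ",
      sum(lengths(x$parents)), " edges\n", sep = "")
  invisible(x)
}

#' Ancestors of an ontology term
#'
#' All terms reachable from `term` by following parent edges; the term
#' itself is not included.  Querying an unknown term returns an empty set
#' with a warning.
#'
#' @param onto A `tricall_ontology` from [read_obo()].
#' @param term A term id.
#' @return Character vector of ancestor term ids.
#' @export
ontology_ancestors <- function(onto, term) {
  stopifnot(inherits(onto, "tricall_ontology"))
  if (!term %in% names(onto$parents)) {
    warn(paste0("unknown ontology term: ", term))
    return(character(0))
  }
  seen <- character(0)
  frontier <- onto$parents[[term]]
  while (length(frontier) > 0) {
    frontier <- setdiff(frontier, seen)
    seen <- c(seen, frontier)
    frontier <- unique(unlist(onto$parents[intersect(frontier,
                                                     names(onto$parents))]))
  }
  seen
}

#' Ancestor-expanded, deduplicated term set
#'
#' Expands a protein's annotated GO terms with all their ancestors and
#' deduplicates, so each protein carries each term at most once.
#'
#' @param terms Character vector of annotated term ids.
#' @param onto A `tricall_ontology`.
#' @return Character vector of the expanded unique term set.
#' @export
expand_terms <- function(terms, onto) {
  if (length(terms) == 0) return(character(0))
  unique(c(terms, unlist(lapply(unique(terms), ontology_ancestors,
                                onto = onto))))
}
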