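# Pathway rule parsing and completeness scoring.
#
# A rule file defines, per pathway, an ordered list of steps; each step is a
# boolean expression over KO identifiers with infix operators AND / OR and
# parentheses. AND binds tighter than OR, so
#   K00001 AND K00002 OR K00003
# reads as (K00001 AND K00002) OR K00003. Internally OR maps to an ANY node
# (alternative enzymes) and AND to an ALL node (complex subunits).

.tokenizeStep <- function(text) {
  # split on parentheses and whitespace, keeping the parentheses
  padded <- gsub("([()])", " \\1 ", text)
  toks <- strsplit(trimws(padded), "[[:space:]]+")[[1L]]
  toks[nzchar(toks)]
}

# recursive-descent parser over a token stream held in an environment
.parseOr <- function(st) {
  children <- list(.parseAnd(st))
  while (!is.na(.peek(st)) && toupper(.peek(st)) == "OR") {
    .advance(st)
    children <- c(children, list(.parseAnd(st)))
  }
  if (length(children) == 1L) children[[1L]]
  else list(op = "ANY", children = children)
}

.parseAnd <- function(st) {
  children <- list(.parseAtom(st))
  while (!is.na(.peek(st)) && toupper(.peek(st)) == "AND") {
    .advance(st)
    children <- c(children, list(.parseAtom(st)))
  }
  if (length(children) == 1L) children[[1L]]
  else list(op = "ALL", children = children)
}

.parseAtom <- function(st) {
  tok <- .peek(st)
  if (is.na(tok)) stop("unexpected end of expression", call. = FALSE)
  if (tok == "(") {
    .advance(st)
    node <- .parseOr(st)
    if (is.na(.peek(st)) || .peek(st) != ")")
      stop("unbalanced parentheses", call. = FALSE)
    .advance(st)
    return(node)
  }
  if (tok == ")") stop("unbalanced parentheses", call. = FALSE)
  if (toupper(tok) %in% c("AND", "OR", "ANY", "ALL"))
    stop(sprintf("operator '%s' where a KO identifier was expected", tok),
         call. = FALSE)
  if (!grepl(KO_PATTERN, tok))
    stop(sprintf("invalid KO identifier '%s' (expected K followed by 5 digits)",
                 tok), call. = FALSE)
  .advance(st)
  list(op = "KO", ko = tok)
}

.peek    <- function(st) if (st$i > length(st$toks)) NA_character_ else st$toks[st$i]
.advance <- function(st) st$i <- st$i + 1L

#' Parse a single step expression string into an expression tree
#'
#' @param text an expression string such as
#'   \code{"(K00001 AND K00002) OR K00003"}.
#' @return a nested-list expression tree with nodes of `op` \code{"KO"}
#'   (leaf, field `ko`), \code{"ANY"} (OR) or \code{"ALL"} (AND), each
#'   operator holding a `children` list.
#' @examples
#' parseStepExpression("K00844 OR K00886")
#' @export
parseStepExpression <- function(text) {
  st <- new.env(parent = emptyenv())
  st$toks <- .tokenizeStep(text)
  st$i <- 1L
  if (!length(st$toks)) stop("empty step expression", call. = FALSE)
  node <- .parseOr(st)
  if (!is.na(.peek(st)))
    stop(sprintf("trailing token '%s' after expression", .peek(st)),
         call. = FALSE)
  node
}

#' Parse a pathway rule file
#'
#' The rule file is YAML: a list of records, each with fields `pathway`
#' (short unique id), `category` and `steps` (a list of step expression
#' strings). See `system.file("extdata", "example_pathway_rules.yaml",
#' package = "beeprofiler")` for a curated example covering central carbon
#' and energy metabolism. That file is a reconstruction of typical
#' bee-gut-symbiont pathway definitions, shipped so the profiler runs out of
#' the box; the engine accepts any rule file in this format.
#'
#' @param path path to a YAML rule file.
#' @return a named list of [PathwayRule-class] objects, in file order.
#' @examples
#' rules <- parseRules(system.file("extdata", "example_pathway_rules.yaml",
#'                                 package = "beeprofiler"))
#' rules[[1]]
#' @export
parseRules <- function(path) {
  if (!file.exists(path))
    stop(sprintf("rule file '%s' not found", path), call. = FALSE)
  records <- yaml::read_yaml(path)
  if (!is.list(records) || !length(records))
    stop("rule file contains no pathway records", call. = FALSE)
  rules <- vector("list", length(records))
  ids <- character(length(records))
  for (r in seq_along(records)) {
    rec <- records[[r]]
    for (f in c("pathway", "category", "steps"))
      if (is.null(rec[[f]]))
        stop(sprintf("record %d: missing field '%s'", r, f), call. = FALSE)
    stepText <- as.character(unlist(rec$steps, use.names = FALSE))
    if (!length(stepText))
      stop(sprintf("pathway '%s': empty step list", rec$pathway),
           call. = FALSE)
    steps <- vector("list", length(stepText))
    for (i in seq_along(stepText)) {
      steps[[i]] <- tryCatch(parseStepExpression(stepText[i]),
        error = function(e) stop(sprintf("pathway '%s', step %d: %s",
                                         rec$pathway, i, conditionMessage(e)),
                                 call. = FALSE))
    }
    rules[[r]] <- new("PathwayRule", pathwayId = as.character(rec$pathway),
                      category = as.character(rec$category),
                      steps = steps, stepText = stepText)
    ids[r] <- rec$pathway
  }
  if (anyDuplicated(ids))
    stop(sprintf("duplicate pathway id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  names(rules) <- ids
  rules
}

#' Evaluate a step expression against a KO set
#'
#' Standard boolean semantics: an \code{ANY} node is TRUE if any child is,
#' an \code{ALL} node if all children are, a leaf if its KO identifier is in
#' `kos`.
#'
#' @param expr an expression tree from [parseStepExpression()].
#' @param kos character vector of KO identifiers present in a genome.
#' @return logical scalar.
#' @export
evaluateStep <- function(expr, kos) {
  switch(expr$op,
    KO  = expr$ko %in% kos,
    ANY = any(vapply(expr$children, evaluateStep, logical(1L), kos = kos)),
    ALL = all(vapply(expr$children, evaluateStep, logical(1L), kos = kos)),
    stop(sprintf("unknown operator '%s'", expr$op)))
}

#' Pathway completeness of one genome for one rule
#'
#' Completeness is the number of steps whose expression evaluates TRUE on the
#' union of the genome's KO assignments, divided by the total number of
#' steps — an exact rational reported alongside its float value.
#'
#' @param rule a [PathwayRule-class].
#' @param genome a [GenomeAnnotation-class], or a character vector taken
#'   directly as a KO set.
#' @return a list with elements `completeness` (numeric fraction),
#'   `nPresent` and `nTotal` (integers).
#' @export
pathwayCompleteness <- function(rule, genome) {
  kos <- if (is(genome, "GenomeAnnotation")) koSet(genome)
         else as.character(genome)
  sat <- vapply(rule@steps, evaluateStep, logical(1L), kos = kos)
  list(completeness = sum(sat) / length(sat),
       nPresent = as.integer(sum(sat)), nTotal = length(sat))
}

#' Completeness matrix over genomes and pathway rules
#'
#' @param rules list of [PathwayRule-class] objects (e.g. from
#'   [parseRules()]).
#' @param genomes list of [GenomeAnnotation-class] objects.
#' @return a [CompletenessMatrix-class]; rows follow the input genome order,
#'   columns the input rule order.
#' @export
completenessMatrix <- function(rules, genomes) {
  if (!length(rules) || !length(genomes))
    stop("need at least one rule and one genome", call. = FALSE)
  gids <- vapply(genomes, genomeId, character(1L))
  pids <- vapply(rules, function(r) r@pathwayId, character(1L))
  nTotal <- vapply(rules, function(r) length(r@steps), integer(1L))
  sp <- matrix(0L, nrow = length(genomes), ncol = length(rules),
               dimnames = list(unname(gids), unname(pids)))
  for (g in seq_along(genomes)) {
    kos <- koSet(genomes[[g]])
    for (p in seq_along(rules)) {
      sat <- vapply(rules[[p]]@steps, evaluateStep, logical(1L), kos = kos)
      sp[g, p] <- sum(sat)
    }
  }
  cm <- sweep(sp, 2L, nTotal, "/")
  new("CompletenessMatrix", completeness = cm, stepsPresent = sp,
      stepsTotal = stats::setNames(nTotal, pids))
}

#' Map a categorical completeness table to fractions
#'
#' Amino-acid biosynthesis (and similar externally scored) pathway calls are
#' consumed as a per-genome pathway -> {complete, partial, absent} table and
#' mapped to numeric completeness {1, 0.5, 0} for joint display with
#' rule-based scores.
#'
#' @param path TSV with columns `genome_id`, `pathway`, `call` where `call`
#'   is one of complete / partial / absent (case-insensitive).
#' @return numeric genomes x pathways matrix with values in {0, 0.5, 1}.
#' @export
readCategoricalCompleteness <- function(path) {
  df <- readTsv(path)
  need <- c("genome_id", "pathway", "call")
  if (!all(need %in% colnames(df)))
    stop(sprintf("expected columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  map <- c(complete = 1, partial = 0.5, absent = 0)
  val <- map[tolower(df$call)]
  if (anyNA(val))
    stop(sprintf("unknown call value(s): %s",
                 paste(unique(df$call[is.na(val)]), collapse = ", ")),
         call. = FALSE)
  gids <- unique(df$genome_id); pids <- unique(df$pathway)
  m <- matrix(0, length(gids), length(pids), dimnames = list(gids, pids))
  m[cbind(match(df$genome_id, gids), match(df$pathway, pids))] <- val
  m
}
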