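# Level ordering shared by the rule engine: higher = more complete.
PATHWAY_LEVELS <- c(none = 0, partial = 1, uncomplete = 2, complete = 3)

#' Read a pathway rule set from its text serialization
#'
#' The format is block-structured plain text (see the packaged
#' `pathway_rules.txt`): a `pathway:` line opens a block; indented
#' `complete:` / `uncomplete:` / `partial:` lines give boolean rules over
#' gene-symbol presence, or a single `present:` line for a binary trait.
#' Rules use `&`, `|`, parentheses, and `n_true(e1, e2, ...) >= k`.
#'
#' @param path File to read.
#' @return A `pathway_ruleset`: named list of pathways, each with `name`,
#'   `binary`, and `rules` (named character vector of rule expressions in
#'   precedence order); attribute `vocabulary` holds every referenced
#'   symbol.
#' @export
read_ruleset <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  rules <- list()
  current <- NULL
  for (ln in lines) {
    if (startsWith(ln, "pathway:")) {
      if (!is.null(current)) rules[[current$name]] <- current
      current <- list(name = trimws(sub("^pathway:", "", ln)),
                      binary = FALSE, rules = character(0))
    } else {
      m <- regmatches(ln, regexec("^(complete|uncomplete|partial|present):(.*)$",
                                  ln))[[1]]
      if (length(m) != 3)
        stop("read_ruleset: cannot parse line: ", ln)
      if (is.null(current)) stop("read_ruleset: rule before any pathway")
      lvl <- m[2]
      if (lvl == "present") current$binary <- TRUE
      current$rules[lvl] <- trimws(m[3])
    }
  }
  if (!is.null(current)) rules[[current$name]] <- current
  rs <- structure(rules, class = "pathway_ruleset")
  validate_ruleset(rs)
}

#' Write a pathway rule set to its text serialization
#'
#' Inverse of [read_ruleset()]; `read_ruleset(write_ruleset(rs, f))`
#' reproduces `rs` exactly.
#'
#' @param rules A `pathway_ruleset`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_ruleset <- function(rules, path) {
  out <- c("# Metabolic pathway completeness rules.")
  for (pw in rules) {
    out <- c(out, "", paste0("pathway: ", pw$name),
             paste0("  ", names(pw$rules), ": ", pw$rules))
  }
  writeLines(out, path)
  invisible(path)
}

validate_ruleset <- function(rules) {
  allowed_funs <- c("&", "|", "(", ">=", "==", "n_true")
  vocab <- character(0)
  for (pw in rules) {
    if (pw$binary && !identical(names(pw$rules), "present"))
      stop("validate_ruleset: binary pathway '", pw$name,
           "' must have exactly a 'present' rule")
    if (!pw$binary) {
      ord <- intersect(c("complete", "uncomplete", "partial"),
                       names(pw$rules))
      if (!identical(names(pw$rules), ord) || !length(ord))
        stop("validate_ruleset: pathway '", pw$name,
             "' levels out of precedence order")
    }
    for (r in pw$rules) {
      expr <- tryCatch(parse(text = r)[[1]],
                       error = function(e)
                         stop("validate_ruleset: bad rule in '", pw$name,
                              "': ", r))
      nm <- all.names(expr)
      funs <- setdiff(nm, all.vars(expr))
      bad <- setdiff(funs, allowed_funs)
      if (length(bad))
        stop("validate_ruleset: disallowed operator(s) in '", pw$name,
             "': ", paste(bad, collapse = ", "))
      vocab <- union(vocab, all.vars(expr))
    }
  }
  attr(rules, "vocabulary") <- sort(vocab)
  invisible(rules)
}

#' The packaged pathway completeness rule set
#'
#' Loads the rule grammar shipped with the package: sulfide oxidation, the
#' Sox thiosulfate-oxidation system, dissimilatory sulfite/sulfate
#' reduction (DSR), DNRA and denitrification downstream steps, nitrogen
#' fixation, the Wood-Ljungdahl pathway, CO oxidation, acetate metabolism,
#' rTCA, CBB, methanogenesis, cytochrome c oxidases, and the binary cyc2
#' and fermentation traits. Slash-joined genes (dsrAB, aprAB, nrfA/H) are
#' groups requiring all members.
#'
#' @return A `pathway_ruleset` (see [read_ruleset()]).
#' @export
builtin_ruleset <- function() {
  read_ruleset(system.file("extdata", "pathway_rules.txt",
                           package = "hydrovent", mustWork = TRUE))
}

ruleset_vocabulary <- function(rules) {
  attr(validate_ruleset(rules), "vocabulary")
}

eval_rule <- function(rule, present, vocab) {
  env <- new.env(parent = baseenv())
  for (s in vocab) assign(s, s %in% present, envir = env)
  assign("n_true", function(...) sum(vapply(list(...), isTRUE, TRUE)),
         envir = env)
  isTRUE(eval(parse(text = rule)[[1]], envir = env))
}

#' Completeness level of one pathway for one gene set
#'
#' Evaluates the pathway's rules in precedence order (complete,
#' uncomplete, partial) against the set of present gene symbols; the first
#' matching level wins, and no match yields `"none"` (binary traits:
#' `"present"` / `"absent"`).
#'
#' @param present Character vector of present gene symbols.
#' @param pathway Pathway name (must be in `rules`).
#' @param rules A `pathway_ruleset` (default [builtin_ruleset()]).
#' @return A level string.
#' @export
classify_pathway <- function(present, pathway, rules = builtin_ruleset()) {
  pw <- rules[[pathway]]
  if (is.null(pw)) stop("classify_pathway: unknown pathway '", pathway, "'")
  vocab <- attr(rules, "vocabulary") %||% ruleset_vocabulary(rules)
  for (lvl in names(pw$rules)) {
    if (eval_rule(pw$rules[[lvl]], present, vocab))
      return(if (pw$binary) "present" else lvl)
  }
  if (pw$binary) "absent" else "none"
}

#' Annotation bundle for one MAG
#'
#' @param bin_id Bin identifier.
#' @param symbols Present gene symbols.
#' @param cazyme_count Number of CAZyme-annotated genes.
#' @param hydrogenase_groups Hydrogenase group labels (consumed as input
#'   from an upstream classifier, e.g. "Group 1b").
#' @return A `mag_annotation` list.
#' @export
mag_annotation <- function(bin_id, symbols = character(0), cazyme_count = 0L,
                           hydrogenase_groups = character(0)) {
  structure(list(bin_id = bin_id, symbols = unique(as.character(symbols)),
                 cazyme_count = as.integer(cazyme_count),
                 hydrogenase_groups = hydrogenase_groups),
            class = "mag_annotation")
}

#' Pathway completeness matrix over MAGs
#'
#' Classifies every pathway of the rule set for every annotated MAG —
#' the bin-by-pathway metabolic-potential matrix. Symbols outside the rule
#' vocabulary are reported once via a message and ignored.
#'
#' @param annotations List of [mag_annotation()] objects.
#' @param rules A `pathway_ruleset`.
#' @return Character matrix (bins x pathways) of levels, with attribute
#'   `codes` giving the numeric encoding (none 0, partial 1, uncomplete 2,
#'   complete 3; absent 0 / present 3 for binary traits).
#' @export
classify_all <- function(annotations, rules = builtin_ruleset()) {
  stopifnot(all(vapply(annotations, inherits, TRUE, "mag_annotation")))
  vocab <- attr(rules, "vocabulary") %||% ruleset_vocabulary(rules)
  unknown <- sort(unique(unlist(lapply(annotations, function(a)
    setdiff(a$symbols, vocab)))))
  if (length(unknown))
    message("classify_all: ignoring symbols outside the rule vocabulary: ",
            paste(unknown, collapse = ", "))
  bins <- vapply(annotations, `[[`, "", "bin_id")
  mat <- matrix("", length(annotations), length(rules),
                dimnames = list(bins, names(rules)))
  for (i in seq_along(annotations)) {
    for (pw in names(rules)) {
      mat[i, pw] <- classify_pathway(annotations[[i]]$symbols, pw, rules)
    }
  }
  codes <- c(PATHWAY_LEVELS, absent = 0, present = 3)
  structure(mat, codes = codes)
}

#' Count CAZyme-annotated genes
#'
#' @param labels Character vector of per-gene annotation labels.
#' @param pattern Regular expression identifying carbohydrate-active-enzyme
#'   annotations (default matches "CAZy"/"CAZyme", case-insensitive).
#' @return Integer count. Group averages over a set of MAGs are plain
#'   arithmetic means of the per-MAG counts.
#' @export
count_cazymes <- function(labels, pattern = "CAZy") {
  sum(grepl(pattern, labels, ignore.case = TRUE))
}
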