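# In-memory RDF triple graph with set semantics, conjunctive count-query
# evaluation (the basic-graph-pattern subset the hypothesis engine emits),
# and deterministic N-Triples / Turtle serialization.

#' Construct a triple graph
#'
#' A triple graph is a duplicate-free tibble of subject--predicate--object
#' statements. Subjects and predicates are absolute URIs; objects are either
#' URIs (e.g. foreign-key links between rows) or plain string literals.
#'
#' @param subject,predicate Character vectors of absolute URIs.
#' @param object Character vector of URIs or literals.
#' @param object_is_uri Logical vector saying which objects are URIs.
#' @return A tibble of class `triple_graph` with those four columns,
#'   deduplicated.
#' @seealso [add_triples()], [evaluate_count_query()], [serialize_graph()]
#' @export
triple_graph <- function(subject = character(), predicate = character(),
                         object = character(), object_is_uri = logical()) {
  out <- tibble::tibble(
    subject = subject, predicate = predicate,
    object = object, object_is_uri = object_is_uri
  )
  if (nrow(out) > 0 &&
    (any(is.na(out$subject) | is.na(out$predicate) | is.na(out$object)) ||
      any(!nzchar(out$subject) | !nzchar(out$predicate) | !nzchar(out$object)))) {
    rlang::abort("triples must have non-empty subject, predicate and object",
      class = "tmatriad_validation_error"
    )
  }
  out <- dplyr::distinct(out)
  class(out) <- c("triple_graph", class(out))
  out
}

#' Add triples to a graph (set semantics)
#'
#' Inserting a triple already present leaves the graph unchanged.
#'
#' @param graph A [triple_graph()].
#' @param triples A tibble with columns `subject`, `predicate`, `object`,
#'   `object_is_uri`.
#' @return The enlarged `triple_graph`.
#' @export
add_triples <- function(graph, triples) {
  stopifnot(inherits(graph, "triple_graph"))
  out <- dplyr::distinct(dplyr::bind_rows(graph, triples))
  class(out) <- c("triple_graph", setdiff(class(out), "triple_graph"))
  out
}

#' @export
print.triple_graph <- function(x, ...) {
  cat(sprintf("<triple_graph: %d triple(s)>\n", nrow(x)))
  NextMethod()
}

# --- terms and patterns ------------------------------------------------------

# Pattern term encoding (strings): "?name" is a variable, "<uri>" a URI
# constant, anything else a literal constant.
term_kind <- function(x) {
  if (startsWith(x, "?")) {
    "var"
  } else if (startsWith(x, "<") && endsWith(x, ">")) {
    "uri"
  } else {
    "lit"
  }
}

term_value <- function(x) {
  if (term_kind(x) == "uri") substr(x, 2, nchar(x) - 1) else x
}

#' Construct a triple pattern
#'
#' Each position is a constant or a named variable. Variables are written
#' `"?name"`; URI constants are wrapped in angle brackets (`"<http://...>"`);
#' any other string is a literal constant. Predicates may be written bare
#' (they are always URIs).
#'
#' @param subject,predicate,object Pattern terms as described above.
#' @return A list of class `triple_pattern`.
#' @export
triple_pattern <- function(subject, predicate, object) {
  if (term_kind(predicate) == "lit") predicate <- paste0("<", predicate, ">")
  if (term_kind(subject) == "lit") {
    rlang::abort("pattern subject must be a variable or a URI",
      class = "tmatriad_validation_error"
    )
  }
  structure(list(subject = subject, predicate = predicate, object = object),
    class = "triple_pattern"
  )
}

pattern_vars <- function(pattern) {
  terms <- unlist(pattern, use.names = FALSE)
  unique(terms[vapply(terms, term_kind, "") == "var"])
}

#' Construct a conjunctive count query
#'
#' The SPARQL fragment the hypothesis engine emits: a basic graph pattern (a
#' conjunction of triple patterns joined on shared variables) and a count
#' variable, evaluated as `count(distinct <count_var>)`.
#'
#' @param patterns Non-empty list of [triple_pattern()]s.
#' @param count_var The variable to count distinct bindings of (default
#'   `"?cr"`, the core variable); must occur in at least one pattern.
#' @return A list of class `count_query`.
#' @export
count_query <- function(patterns, count_var = "?cr") {
  if (length(patterns) == 0) {
    rlang::abort("count query needs at least one triple pattern",
      class = "tmatriad_validation_error"
    )
  }
  all_vars <- unique(unlist(lapply(patterns, pattern_vars)))
  if (!count_var %in% all_vars) {
    rlang::abort(sprintf("count variable %s appears in no pattern", count_var),
      class = "tmatriad_validation_error"
    )
  }
  structure(list(patterns = patterns, count_var = count_var),
    class = "count_query"
  )
}

# --- evaluation --------------------------------------------------------------

# Bindings encode URIs as "<uri>" and literals bare, so a URI and a literal
# with the same spelling never join.
binding_term <- function(value, is_uri) {
  is_uri <- rep_len(is_uri, length(value))
  ifelse(is_uri, paste0("<", value, ">"), value)
}

# Rows of `graph` matching the constants of one pattern, projected to the
# pattern's variables. Repeated variables within a pattern are enforced.
match_pattern <- function(graph, pattern) {
  keep <- rep(TRUE, nrow(graph))
  for (pos in c("subject", "predicate", "object")) {
    term <- pattern[[pos]]
    kind <- term_kind(term)
    if (kind == "var") next
    if (pos == "object") {
      keep <- keep & graph$object == term_value(term) &
        graph$object_is_uri == (kind == "uri")
    } else {
      keep <- keep & graph[[pos]] == term_value(term)
    }
  }
  rows <- graph[keep, , drop = FALSE]
  # per-position binding values for variable positions
  pos_vals <- list()
  for (pos in c("subject", "predicate", "object")) {
    term <- pattern[[pos]]
    if (term_kind(term) != "var") next
    pos_vals[[pos]] <- list(term = term, val = switch(pos,
      subject = binding_term(rows$subject, TRUE),
      predicate = binding_term(rows$predicate, TRUE),
      object = binding_term(rows$object, rows$object_is_uri)
    ))
  }
  if (length(pos_vals) == 0) {
    return(tibble::tibble(.matches = sum(keep)))
  }
  # a variable repeated within the pattern must bind identically
  mask <- rep(TRUE, nrow(rows))
  cols <- list()
  for (pv in pos_vals) {
    if (pv$term %in% names(cols)) {
      mask <- mask & cols[[pv$term]] == pv$val
    } else {
      cols[[pv$term]] <- pv$val
    }
  }
  cols <- lapply(cols, function(x) x[mask])
  dplyr::distinct(tibble::as_tibble(cols))
}

# Greedy join order: most selective pattern first, then prefer patterns
# sharing a variable with those already joined (avoids cross products).
order_patterns <- function(graph, patterns) {
  sizes <- vapply(patterns, function(p) nrow(match_pattern(graph, p)), 0L)
  remaining <- seq_along(patterns)
  bound <- character()
  out <- integer()
  while (length(remaining) > 0) {
    shares <- vapply(
      remaining,
      function(i) length(intersect(pattern_vars(patterns[[i]]), bound)) > 0,
      TRUE
    )
    cand <- if (any(shares) && length(bound) > 0) remaining[shares] else remaining
    pick <- cand[which.min(sizes[cand])]
    out <- c(out, pick)
    bound <- union(bound, pattern_vars(patterns[[pick]]))
    remaining <- setdiff(remaining, pick)
  }
  patterns[out]
}

#' Solve a basic graph pattern against a triple graph
#'
#' Returns the distinct variable bindings satisfying every pattern (the
#' natural join of per-pattern matches on shared variables). URI bindings are
#' returned wrapped in angle brackets, literals bare.
#'
#' @param graph A [triple_graph()].
#' @param patterns List of [triple_pattern()]s.
#' @return Tibble with one column per variable (names without the `?`).
#' @export
evaluate_bgp <- function(graph, patterns) {
  patterns <- order_patterns(graph, patterns)
  bindings <- NULL
  for (p in patterns) {
    m <- match_pattern(graph, p)
    if (".matches" %in% names(m)) {
      # fully ground pattern: acts as a boolean guard
      if (m$.matches[1] == 0) {
        bindings <- tibble::tibble()[0, ]
        break
      }
      next
    }
    names(m) <- sub("^\\?", "", names(m))
    if (is.null(bindings)) {
      bindings <- m
    } else {
      shared <- intersect(names(bindings), names(m))
      bindings <- if (length(shared) > 0) {
        dplyr::inner_join(bindings, m,
          by = shared,
          relationship = "many-to-many"
        )
      } else {
        dplyr::cross_join(bindings, m)
      }
    }
    if (nrow(bindings) == 0) break
  }
  if (is.null(bindings)) bindings <- tibble::tibble(.rows = 1)[, 0]
  dplyr::distinct(bindings)
}

#' Evaluate a conjunctive count query
#'
#' Counts the distinct bindings of the query's count variable over all
#' solutions of its basic graph pattern. An unmatched pattern yields 0.
#'
#' @param graph A [triple_graph()].
#' @param query A [count_query()].
#' @return A non-negative integer.
#' @export
evaluate_count_query <- function(graph, query) {
  stopifnot(inherits(query, "count_query"))
  bindings <- evaluate_bgp(graph, query$patterns)
  var <- sub("^\\?", "", query$count_var)
  if (!var %in% names(bindings)) {
    return(0L)
  }
  length(unique(bindings[[var]]))
}

# Distinct values of one variable over the BGP solutions (used to union
# distinct cores across the per-value queries of a plan).
bgp_var_values <- function(graph, patterns, var) {
  bindings <- evaluate_bgp(graph, patterns)
  v <- sub("^\\?", "", var)
  if (!v %in% names(bindings)) {
    return(character())
  }
  unique(bindings[[v]])
}

# --- serialization -----------------------------------------------------------

escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_literal <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    chars <- strsplit(x[i], "", fixed = TRUE)[[1]]
    buf <- character(0)
    j <- 1
    while (j <= length(chars)) {
      if (chars[j] == "\\" && j < length(chars)) {
        nxt <- chars[j + 1]
        buf <- c(buf, switch(nxt,
          "n" = "\n", "r" = "\r", "t" = "\t", "\\" = "\\", "\"" = "\"",
          nxt
        ))
        j <- j + 2
      } else {
        buf <- c(buf, chars[j])
        j <- j + 1
      }
    }
    out[i] <- paste(buf, collapse = "")
  }
  out
}

render_object <- function(object, is_uri) {
  ifelse(is_uri, paste0("<", object, ">"),
    paste0("\"", escape_literal(object), "\"")
  )
}

sorted_graph <- function(graph) {
  ord <- order(graph$subject, graph$predicate, graph$object,
    graph$object_is_uri,
    method = "radix"
  )
  graph[ord, , drop = FALSE]
}

#' Serialize / parse a triple graph
#'
#' N-Triples output is one sorted line per triple and therefore
#' byte-deterministic; Turtle output groups triples by subject with `;`
#' continuations (full URIs, no prefixes). `parse_graph()` reads back the
#' subset `serialize_graph()` emits and raises a parse error naming the line
#' on malformed input.
#'
#' @param graph A [triple_graph()].
#' @param format `"ntriples"` or `"turtle"`.
#' @return `serialize_graph()`: a single string. `parse_graph()`: a
#'   [triple_graph()].
#' @export
serialize_graph <- function(graph, format = c("ntriples", "turtle")) {
  format <- match.arg(format)
  g <- sorted_graph(graph)
  if (nrow(g) == 0) {
    return("")
  }
  obj <- render_object(g$object, g$object_is_uri)
  if (format == "ntriples") {
    lines <- paste0("<", g$subject, "> <", g$predicate, "> ", obj, " .")
  } else {
    lines <- character(0)
    for (s in unique(g$subject)) {
      rows <- which(g$subject == s)
      po <- paste0("    <", g$predicate[rows], "> ", obj[rows])
      lines <- c(
        lines,
        paste0("<", s, ">"),
        paste0(po, c(rep(" ;", length(rows) - 1), " ."))
      )
    }
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' @rdname serialize_graph
#' @param text Serialized graph text.
#' @export
parse_graph <- function(text, format = c("ntriples", "turtle")) {
  format <- match.arg(format)
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  s <- p <- o <- character(0)
  is_uri <- logical(0)
  bad <- function(i) {
    rlang::abort(sprintf("parse error at line %d: %s", i, lines[i]),
      class = "tmatriad_parse_error"
    )
  }
  uri_re <- "<([^<>]*)>"
  obj_re <- "(<[^<>]*>|\"(?:[^\"\\\\]|\\\\.)*\")"
  if (format == "ntriples") {
    re <- paste0("^", uri_re, " ", uri_re, " ", obj_re, " \\.$")
    for (i in seq_along(lines)) {
      if (!nzchar(trimws(lines[i]))) next
      m <- regmatches(lines[i], regexec(re, lines[i]))[[1]]
      if (length(m) != 4) bad(i)
      s <- c(s, m[2])
      p <- c(p, m[3])
      o <- c(o, m[4])
    }
  } else {
    subj_re <- paste0("^", uri_re, "$")
    po_re <- paste0("^\\s+", uri_re, " ", obj_re, " (;|\\.)$")
    cur <- NA_character_
    for (i in seq_along(lines)) {
      if (!nzchar(trimws(lines[i]))) next
      if (grepl(subj_re, lines[i])) {
        cur <- sub(subj_re, "\\1", lines[i])
        next
      }
      m <- regmatches(lines[i], regexec(po_re, lines[i]))[[1]]
      if (length(m) != 4 || is.na(cur)) bad(i)
      s <- c(s, cur)
      p <- c(p, m[2])
      o <- c(o, m[3])
      if (m[4] == ".") cur <- NA_character_
    }
  }
  o_is_uri <- startsWith(o, "<")
  o_val <- ifelse(o_is_uri, substr(o, 2, nchar(o) - 1),
    unescape_literal(substr(o, 2, nchar(o) - 1))
  )
  triple_graph(s, p, o_val, o_is_uri)
}
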