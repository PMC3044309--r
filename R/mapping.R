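# Declarative relational-to-RDF mapping: one subject URI per row (built from
# table name + primary key), one triple per non-missing non-key column.
# Foreign-key columns become object-URI triples linking rows; other columns
# become string literals.

#' Mapping rules from relational columns to RDF predicates
#'
#' One entry per non-primary-key column of each mapped table. `kind`
#' `"literal"` emits a literal-valued triple with predicate
#' `<base>/vocab#<predicate>`; kind `"ref"` emits an object-URI triple whose
#' object is the subject URI of the referenced row
#' (`<base>/<ref_table>/<value>`). Predicate names are taken verbatim from
#' the rule (no automatic "has" prefixing), so a table may mix styles, e.g.
#' the experiment `Name` column maps to `hasName` while `ExpType` maps to
#' itself.
#'
#' @param table,column Character vectors naming the mapped columns.
#' @param kind `"literal"` or `"ref"` per entry.
#' @param predicate Predicate local name per entry.
#' @param ref_table Referenced table for `"ref"` entries, `NA` otherwise.
#'   `"Sample"` is a virtual table: samples have URIs but no rows of their
#'   own, which is how cores join to clinical sample attributes.
#' @return A tibble of class `mapping_rules`.
#' @export
mapping_rules <- function(table, column, kind, predicate, ref_table = NA) {
  stopifnot(all(kind %in% c("literal", "ref")))
  out <- tibble::tibble(
    table = table, column = column, kind = kind,
    predicate = predicate, ref_table = as.character(ref_table)
  )
  if (anyDuplicated(out[c("table", "column")])) {
    rlang::abort("duplicate mapping entry for a (table, column) pair",
      class = "tmatriad_mapping_error"
    )
  }
  class(out) <- c("mapping_rules", class(out))
  out
}

#' Default mapping rules for the TMA schema
#'
#' @return A [mapping_rules()] tibble covering every non-key column of the
#'   six tables.
#' @export
default_mapping_rules <- function() {
  mapping_rules(
    table = c(
      "Experiment", "Experiment",
      "Slide", "Slide", "Slide",
      "Core", "Core",
      "SampleAttribute", "SampleAttribute", "SampleAttribute",
      "StainingResult", "StainingResult", "StainingResult", "StainingResult"
    ),
    column = c(
      "Name", "ExpType",
      "ExperimentId", "BlockId", "MarkerName",
      "SlideId", "SampleId",
      "SampleId", "AttributeName", "Value",
      "CoreId", "MarkerName", "Intensity", "Range"
    ),
    kind = c(
      "literal", "literal",
      "ref", "ref", "literal",
      "ref", "ref",
      "ref", "literal", "literal",
      "ref", "literal", "literal", "literal"
    ),
    predicate = c(
      "hasName", "ExpType",
      "ExperimentId", "BlockId", "MarkerName",
      "SlideId", "SampleId",
      "SampleId", "AttributeName", "Value",
      "CoreId", "MarkerName", "Intensity", "Range"
    ),
    ref_table = c(
      NA, NA,
      "Experiment", "Block", NA,
      "Slide", "Sample",
      "Sample", NA, NA,
      "Core", NA, NA, NA
    )
  )
}

default_base_uri <- "http://example.org/xtma"

#' Subject and predicate URI construction
#'
#' Subjects follow `<base>/<table>/<pk>`, predicates `<base>/vocab#<name>`.
#' Primary-key values are percent-encoded so distinct keys always yield
#' distinct URIs.
#'
#' @param table Table name.
#' @param pk Primary-key value.
#' @param base Base URI.
#' @return A URI string.
#' @export
subject_uri <- function(table, pk, base = default_base_uri) {
  enc <- vapply(as.character(pk), utils::URLencode, "", reserved = TRUE)
  paste0(base, "/", table, "/", unname(enc))
}

#' @rdname subject_uri
#' @param name Predicate local name.
#' @export
predicate_uri <- function(name, base = default_base_uri) {
  paste0(base, "/vocab#", name)
}

#' Map one relational row to RDF triples
#'
#' The subject URI is generated from the table name and the row's
#' primary-key value. Each non-key column with a non-missing value yields
#' exactly one triple: a literal triple for `"literal"` rules, an object-URI
#' triple (pointing at the referenced row's subject URI) for `"ref"` rules.
#' Missing values emit no triple.
#'
#' @param table Table name.
#' @param row Named character vector or one-row data frame of column values.
#' @param rules A [mapping_rules()].
#' @param base Base URI.
#' @return A [triple_graph()] (possibly empty).
#' @export
row_to_triples <- function(table, row, rules, base = default_base_uri) {
  if (is.data.frame(row)) row <- unlist(row[1, , drop = TRUE])
  row <- setNames(as.character(row), names(row))
  pk_col <- tma_schema()[[table]]$pk %||% names(row)[1]
  subj <- subject_uri(table, row[[pk_col]], base)
  cols <- setdiff(names(row), pk_col)
  tab_rules <- rules[rules$table == table, ]
  missing_rule <- setdiff(cols, tab_rules$column)
  if (length(missing_rule) > 0) {
    rlang::abort(
      sprintf(
        "no mapping rule for column(s) %s of table %s",
        paste(missing_rule, collapse = ", "), table
      ),
      class = "tmatriad_mapping_error"
    )
  }
  s <- p <- o <- character(0)
  is_uri <- logical(0)
  for (col in cols) {
    val <- row[[col]]
    if (is.na(val)) next
    r <- tab_rules[tab_rules$column == col, ]
    s <- c(s, subj)
    p <- c(p, predicate_uri(r$predicate, base))
    if (r$kind == "ref") {
      o <- c(o, subject_uri(r$ref_table, val, base))
      is_uri <- c(is_uri, TRUE)
    } else {
      o <- c(o, val)
      is_uri <- c(is_uri, FALSE)
    }
  }
  triple_graph(s, p, o, is_uri)
}

#' Map a whole TMA dataset to a triple graph
#'
#' Deterministic: the same dataset always yields the identical graph. The
#' graph size equals the sum over rows of the per-row triple counts (set
#' semantics; the mapping is injective on rows because the primary key is
#' embedded in the subject URI).
#'
#' @param dataset A [tma_dataset()].
#' @param rules A [mapping_rules()] covering every non-key column.
#' @param base Base URI.
#' @return A [triple_graph()].
#' @export
dataset_to_graph <- function(dataset, rules = default_mapping_rules(),
                             base = default_base_uri) {
  stopifnot(inherits(dataset, "tma_dataset"))
  schema <- tma_schema()
  parts <- list()
  for (tab in names(dataset)) {
    df <- dataset[[tab]]
    if (nrow(df) == 0) next
    pk_col <- schema[[tab]]$pk
    subj <- subject_uri(tab, df[[pk_col]], base)
    cols <- setdiff(names(df), pk_col)
    tab_rules <- rules[rules$table == tab, ]
    missing_rule <- setdiff(cols, tab_rules$column)
    if (length(missing_rule) > 0) {
      rlang::abort(
        sprintf(
          "no mapping rule for column(s) %s of table %s",
          paste(missing_rule, collapse = ", "), tab
        ),
        class = "tmatriad_mapping_error"
      )
    }
    for (col in cols) {
      r <- tab_rules[tab_rules$column == col, ]
      ok <- !is.na(df[[col]])
      if (!any(ok)) next
      obj <- if (r$kind == "ref") {
        vapply(df[[col]][ok], function(v) subject_uri(r$ref_table, v, base), "")
      } else {
        df[[col]][ok]
      }
      parts[[length(parts) + 1]] <- tibble::tibble(
        subject = subj[ok],
        predicate = predicate_uri(r$predicate, base),
        object = unname(obj),
        object_is_uri = r$kind == "ref"
      )
    }
  }
  if (length(parts) == 0) {
    return(triple_graph())
  }
  all <- dplyr::bind_rows(parts)
  triple_graph(all$subject, all$predicate, all$object, all$object_is_uri)
}
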