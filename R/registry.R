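#' Create an empty attribute registry
#'
#' The registry holds the context-dependent controlled vocabulary of every
#' categorical attribute used in a TMA database: for each (attribute, context)
#' pair, the ordered list of permissible values and whether that order is
#' meaningful (ordinal scales such as staining intensity 0--3). Complementary
#' value sets for hypothesis models are always taken against the permissible
#' set registered here.
#'
#' A context of `"*"` is a wildcard: it applies to every context that has no
#' context-specific definition of the same attribute (context-specific entries
#' shadow the wildcard).
#'
#' @return A tibble of class `tma_registry` with columns `attribute`,
#'   `context`, `values` (list-column of character vectors) and `is_ordinal`.
#' @seealso [register_attribute()], [lookup_attribute()]
#' @export
#' @examples
#' reg <- attribute_registry() |>
#'   register_attribute("HistologicGrade", "Colon cancer",
#'     c("Low-grade", "Intermediate-grade", "High-grade"),
#'     is_ordinal = TRUE
#'   )
attribute_registry <- function() {
  out <- tibble::tibble(
    attribute = character(),
    context = character(),
    values = list(),
    is_ordinal = logical()
  )
  class(out) <- c("tma_registry", class(out))
  out
}

#' Register a categorical attribute and its permissible value set
#'
#' @param registry A registry created by [attribute_registry()].
#' @param attribute Attribute name, e.g. `"HistologicGrade"` or
#'   `"Apaf-1 Intensity"`.
#' @param context Context in which this value set applies (e.g.
#'   `"Colon cancer"`), or `"*"` for a wildcard definition.
#' @param values Ordered character vector of permissible values; must be
#'   non-empty and duplicate-free. For ordinal attributes the vector order
#'   defines the total order used by threshold expansion.
#' @param is_ordinal Whether the value order is meaningful.
#' @return The registry with the new definition appended.
#' @export
register_attribute <- function(registry, attribute, context, values,
                               is_ordinal = FALSE) {
  stopifnot(inherits(registry, "tma_registry"))
  if (length(values) == 0) {
    rlang::abort("permissible value set must be non-empty",
      class = "tmatriad_validation_error"
    )
  }
  values <- as.character(values)
  if (anyDuplicated(values)) {
    rlang::abort("permissible value set must be duplicate-free",
      class = "tmatriad_validation_error"
    )
  }
  if (any(registry$attribute == attribute & registry$context == context)) {
    rlang::abort(
      sprintf("attribute '%s' already registered for context '%s'", attribute, context),
      class = "tmatriad_conflict_error"
    )
  }
  out <- dplyr::bind_rows(
    registry,
    tibble::tibble(
      attribute = attribute, context = context,
      values = list(values), is_ordinal = is_ordinal
    )
  )
  class(out) <- c("tma_registry", setdiff(class(out), "tma_registry"))
  out
}

#' Look up an attribute definition, honouring context shadowing
#'
#' A context-specific definition is returned in preference to a wildcard
#' (`"*"`) one; with no context-specific entry the wildcard is returned.
#'
#' @inheritParams register_attribute
#' @return A one-row tibble (attribute, context, values, is_ordinal).
#' @export
lookup_attribute <- function(registry, attribute, context) {
  hit <- registry[registry$attribute == attribute & registry$context == context, ]
  if (nrow(hit) == 0) {
    hit <- registry[registry$attribute == attribute & registry$context == "*", ]
  }
  if (nrow(hit) == 0) {
    rlang::abort(
      sprintf("attribute '%s' not registered for context '%s'", attribute, context),
      class = "tmatriad_lookup_error"
    )
  }
  hit[1, ]
}

#' Permissible values of an attribute in a context
#'
#' @inheritParams lookup_attribute
#' @return Character vector in registered order.
#' @export
permissible_values <- function(registry, attribute, context) {
  lookup_attribute(registry, attribute, context)$values[[1]]
}

#' Read / write an attribute registry as YAML
#'
#' The on-disk format is a list of entries with fields `attribute`,
#' `context`, `values` and `ordinal`.
#'
#' @param path File path.
#' @return `read_registry()` returns a `tma_registry`; `write_registry()`
#'   returns `path` invisibly.
#' @export
read_registry <- function(path) {
  entries <- yaml::read_yaml(path)
  reg <- attribute_registry()
  for (e in entries) {
    reg <- register_attribute(
      reg, e$attribute, e$context %||% "*",
      as.character(unlist(e$values)), isTRUE(e$ordinal)
    )
  }
  reg
}

#' @rdname read_registry
#' @param registry Registry to serialize.
#' @export
write_registry <- function(registry, path) {
  entries <- purrr::pmap(registry, function(attribute, context, values, is_ordinal) {
    list(
      attribute = attribute, context = context,
      values = as.list(values), ordinal = is_ordinal
    )
  })
  yaml::write_yaml(entries, path)
  invisible(path)
}

#' Demo attribute registry used by the worked examples
#'
#' Registers the colon-cancer vocabulary (Apaf-1 staining intensity 0--3,
#' three-level histologic grade, diagnosis), the gastric/nodal vocabulary
#' and the glioma histology vocabulary used by the integration use case.
#'
#' @return A `tma_registry`.
#' @export
demo_registry <- function() {
  attribute_registry() |>
    register_attribute("Diagnosis", "*",
      c("Colon cancer", "Stomach cancer", "Glioma"),
      is_ordinal = FALSE
    ) |>
    register_attribute("HistologicGrade", "Colon cancer",
      c("Low-grade", "Intermediate-grade", "High-grade"),
      is_ordinal = TRUE
    ) |>
    register_attribute("Apaf-1 Intensity", "Colon cancer",
      c("0", "1", "2", "3"),
      is_ordinal = TRUE
    ) |>
    register_attribute("Intensity", "*", c("0", "1", "2", "3"),
      is_ordinal = TRUE
    ) |>
    register_attribute("NodalStatus", "*", c("N0", "N1", "N2", "N3"),
      is_ordinal = TRUE
    ) |>
    register_attribute("Histology", "*",
      c("Glioblastoma", "Astrocytoma", "Oligodendroglioma", "Ependymoma"),
      is_ordinal = FALSE
    )
}
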