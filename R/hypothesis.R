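# Triadic hypothesis model: "in condition A, entity B correlates with
# entity C". Factor A is a shared property of the samples (e.g. a diagnosis),
# factor B the classifier (an attribute plus a hypothesis-describing value
# set splitting cores into Core Collections A and B), factor C the dependent
# property whose value distributions D1/D2 are compared across the two
# collections. Four count queries — one per (hypothesis, complement) cell —
# feed Fisher's exact test.

#' Complementary value set of a hypothesis-describing value set
#'
#' The complement is taken against the attribute's permissible value set:
#' e.g. with permissible grades (Low, Intermediate, High), the hypothesis set
#' \{High\} has complement \{Low, Intermediate\}; with intensities 0--3, \{0\}
#' has complement \{1, 2, 3\}. Order of the permissible set is preserved.
#'
#' @param attribute An attribute definition (one-row tibble from
#'   [lookup_attribute()]) or a character vector of permissible values.
#' @param hypothesis_values Non-empty proper subset of the permissible set.
#' @return Character vector: permissible set minus `hypothesis_values`.
#' @export
complement_value_set <- function(attribute, hypothesis_values) {
  permissible <- if (is.character(attribute)) {
    attribute
  } else {
    attribute$values[[1]]
  }
  hypothesis_values <- as.character(hypothesis_values)
  if (!all(hypothesis_values %in% permissible)) {
    rlang::abort("hypothesis values must be a subset of the permissible set",
      class = "tmatriad_domain_error"
    )
  }
  if (length(hypothesis_values) == 0 ||
    length(unique(hypothesis_values)) == length(permissible)) {
    rlang::abort(
      "degenerate hypothesis: value set must be a non-empty proper subset of the permissible set",
      class = "tmatriad_degenerate_error"
    )
  }
  setdiff(permissible, hypothesis_values)
}

#' Build a triadic hypothesis model
#'
#' Complementary value sets are filled in automatically from the registry, so
#' the classifier and dependent value sets each partition their attribute's
#' permissible set. A factor whose attribute is named `"<Marker> Intensity"`
#' (or whose marker is given explicitly) is compiled against staining
#' results for that marker; any other attribute is matched as a clinical
#' sample attribute.
#'
#' @param registry A [attribute_registry()].
#' @param shared_value Value of the shared property (the context, e.g.
#'   `"Colon cancer"`).
#' @param classifier_attribute,classifier_values Attribute name and
#'   hypothesis-describing value set of the classifier (factor B).
#' @param dependent_attribute,dependent_values Same for the dependent
#'   property (factor C).
#' @param shared_attribute Sample attribute carrying the shared property
#'   (default `"Diagnosis"`).
#' @param classifier_marker,dependent_marker Marker (antibody) name when the
#'   factor is a staining intensity; by default inferred from an attribute
#'   name of the form `"<Marker> Intensity"`.
#' @param direction Descriptive metadata: the correlation direction stated in
#'   the hypothesis. The test itself is two-sided.
#' @return A list of class `hypothesis_model`.
#' @export
#' @examples
#' model <- hypothesis_model(
#'   demo_registry(),
#'   shared_value = "Colon cancer",
#'   classifier_attribute = "Apaf-1 Intensity", classifier_values = "0",
#'   dependent_attribute = "HistologicGrade", dependent_values = "High-grade"
#' )
hypothesis_model <- function(registry, shared_value,
                             classifier_attribute, classifier_values,
                             dependent_attribute, dependent_values,
                             shared_attribute = "Diagnosis",
                             classifier_marker = NULL,
                             dependent_marker = NULL,
                             direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  context <- shared_value
  factor_spec <- function(attribute, values, marker) {
    def <- lookup_attribute(registry, attribute, context)
    values <- unique(as.character(values))
    comp <- complement_value_set(def, values)
    if (is.null(marker) && grepl(" Intensity$", attribute)) {
      marker <- sub(" Intensity$", "", attribute)
    }
    list(
      attribute = attribute,
      marker = marker,
      kind = if (is.null(marker)) "sample" else "staining",
      hypothesis_values = values,
      complement_values = comp,
      permissible_values = def$values[[1]]
    )
  }
  structure(
    list(
      shared = list(attribute = shared_attribute, value = shared_value),
      classifier = factor_spec(
        classifier_attribute, classifier_values, classifier_marker
      ),
      dependent = factor_spec(
        dependent_attribute, dependent_values, dependent_marker
      ),
      direction = direction
    ),
    class = "hypothesis_model"
  )
}

#' @export
print.hypothesis_model <- function(x, ...) {
  fmt_set <- function(v) paste0("{", paste(v, collapse = ", "), "}")
  cat("<hypothesis_model>\n")
  cat(sprintf("  shared:     %s = %s\n", x$shared$attribute, x$shared$value))
  cat(sprintf(
    "  classifier: %s in %s (vs %s)\n", x$classifier$attribute,
    fmt_set(x$classifier$hypothesis_values),
    fmt_set(x$classifier$complement_values)
  ))
  cat(sprintf(
    "  dependent:  %s in %s (vs %s)\n", x$dependent$attribute,
    fmt_set(x$dependent$hypothesis_values),
    fmt_set(x$dependent$complement_values)
  ))
  cat(sprintf("  direction:  %s correlation\n", x$direction))
  invisible(x)
}

# Pattern groups of the canonical skeleton. Variables: ?cr core, ?sl slide,
# ?ex experiment, ?s sample; ?sa0 the shared-property attribute row; ?sr1/?sa1
# the classifier row; ?sr2/?sa2 the dependent row.
shared_patterns <- function(model, base) {
  P <- function(name) paste0("<", predicate_uri(name, base), ">")
  list(
    triple_pattern("?cr", P("SlideId"), "?sl"),
    triple_pattern("?sl", P("ExperimentId"), "?ex"),
    triple_pattern("?cr", P("SampleId"), "?s"),
    triple_pattern("?sa0", P("SampleId"), "?s"),
    triple_pattern("?sa0", P("AttributeName"), model$shared$attribute),
    triple_pattern("?sa0", P("Value"), model$shared$value)
  )
}

factor_patterns <- function(factor, value, slot, base) {
  P <- function(name) paste0("<", predicate_uri(name, base), ">")
  if (factor$kind == "staining") {
    v <- paste0("?sr", slot)
    list(
      triple_pattern(v, P("CoreId"), "?cr"),
      triple_pattern(v, P("MarkerName"), factor$marker),
      triple_pattern(v, P("Intensity"), value)
    )
  } else {
    v <- paste0("?sa", slot)
    list(
      triple_pattern(v, P("SampleId"), "?s"),
      triple_pattern(v, P("AttributeName"), factor$attribute),
      triple_pattern(v, P("Value"), value)
    )
  }
}

#' Generate the four count-query plans of a hypothesis model
#'
#' Plan `i` assigns value sets by the fixed rule: the classifier (factor 2)
#' uses its hypothesis-describing set for plans 1 and 3 and its complementary
#' set for plans 2 and 4; the dependent property (factor 3) uses its
#' hypothesis set for plans 1 and 2 and its complement for plans 3 and 4; the
#' shared property (factor 1) is a constant in every plan. The four
#' assignments thus cover the 2x2 of \{hypothesis, complement\} x
#' \{hypothesis, complement\}, and every (classifier value, dependent value)
#' pair of the permissible product is matched by exactly one plan.
#'
#' Each plan counts `count(distinct ?cr)` over the canonical pattern skeleton
#' (core-slide-experiment linkage, core-sample shared-property match,
#' classifier match, dependent match). Value-set membership is a disjunction,
#' realized as one conjunctive query per member-value pair with distinct
#' cores unioned across them.
#'
#' @param model A [hypothesis_model()].
#' @param base Base URI the target graph was built with.
#' @return List of 4 `query_plan` objects (fields `index`, `valuesets`,
#'   `queries`).
#' @export
generate_query_plans <- function(model, base = default_base_uri) {
  stopifnot(inherits(model, "hypothesis_model"))
  plans <- vector("list", 4)
  for (i in 1:4) {
    cls_set <- if (i %in% c(1, 3)) {
      model$classifier$hypothesis_values
    } else {
      model$classifier$complement_values
    }
    dep_set <- if (i %in% c(1, 2)) {
      model$dependent$hypothesis_values
    } else {
      model$dependent$complement_values
    }
    combos <- expand.grid(
      cls = cls_set, dep = dep_set,
      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
    )
    queries <- purrr::pmap(combos, function(cls, dep) {
      count_query(
        c(
          shared_patterns(model, base),
          factor_patterns(model$classifier, cls, 1, base),
          factor_patterns(model$dependent, dep, 2, base)
        ),
        count_var = "?cr"
      )
    })
    plans[[i]] <- structure(
      list(
        index = i,
        valuesets = list(
          shared = model$shared$value,
          classifier = cls_set,
          dependent = dep_set
        ),
        queries = queries
      ),
      class = "query_plan"
    )
  }
  plans
}

# Distinct (core, slide, experiment) bindings matched by a plan: union over
# its per-value-pair conjunctive queries, each core counted once.
plan_bindings <- function(graph, plan) {
  parts <- purrr::map(plan$queries, function(q) {
    b <- evaluate_bgp(graph, q$patterns)
    if (!all(c("cr", "sl", "ex") %in% names(b))) {
      return(tibble::tibble(cr = character(), sl = character(), ex = character()))
    }
    dplyr::distinct(b[, c("cr", "sl", "ex")])
  })
  dplyr::distinct(dplyr::bind_rows(parts))
}

#' Test a triadic hypothesis against a triple graph
#'
#' Generates the four count queries, evaluates them against the graph, fills
#' the 2x2 contingency table (n11 from plan 1, n12 from plan 2, n21 from
#' plan 3, n22 from plan 4, i.e. columns = classifier, rows = dependent) and
#' applies Fisher's exact test. The hypothesis is supported when the
#' two-sided p-value is below `alpha`.
#'
#' @param model A [hypothesis_model()].
#' @param graph A [triple_graph()] built by [dataset_to_graph()].
#' @param alpha Significance threshold (default 0.01).
#' @param base Base URI the graph was built with.
#' @return A list of class `tma_hypothesis_result` with fields `model`,
#'   `table` ([contingency_2x2()]), `test`, `p_value`, `alpha`, `decision`
#'   (`"supported"` or `"rejected"`) and `provenance` (distinct cores /
#'   slides / experiments contributing to any cell).
#' @export
test_hypothesis <- function(model, graph, alpha = 0.01,
                            base = default_base_uri) {
  stopifnot(inherits(model, "hypothesis_model"), inherits(graph, "triple_graph"))
  if (!(alpha > 0 && alpha < 1)) {
    rlang::abort("alpha must lie in (0, 1)", class = "tmatriad_domain_error")
  }
  plans <- generate_query_plans(model, base)
  bindings <- purrr::map(plans, plan_bindings, graph = graph)
  counts <- vapply(bindings, function(b) length(unique(b$cr)), 0L)
  if (sum(counts) == 0) {
    rlang::abort("no data: all four cell counts are zero on this graph",
      class = "tmatriad_nodata_error"
    )
  }
  table <- contingency_2x2(counts[1], counts[2], counts[3], counts[4])
  test <- fisher_exact(table)
  all_b <- dplyr::bind_rows(bindings)
  result <- list(
    model = model,
    table = table,
    test = test,
    p_value = test$p_value,
    alpha = alpha,
    decision = if (test$p_value < alpha) "supported" else "rejected",
    provenance = list(
      n_cores = length(unique(all_b$cr)),
      n_slides = length(unique(all_b$sl)),
      n_experiments = length(unique(all_b$ex))
    )
  )
  class(result) <- "tma_hypothesis_result"
  result
}

#' @export
print.tma_hypothesis_result <- function(x, ...) {
  cat("<tma_hypothesis_result>\n")
  print(x$model)
  cat("  contingency table (rows = dependent, cols = classifier):\n")
  m <- unclass(x$table)
  cat(sprintf(
    "    %6d %6d\n    %6d %6d\n",
    m[1, 1], m[1, 2], m[2, 1], m[2, 2]
  ))
  cat(sprintf("  %s: p = %.4g\n", x$test$method, x$p_value))
  cat(sprintf("  decision at alpha = %g: %s\n", x$alpha, x$decision))
  cat(sprintf(
    "  provenance: %d cores / %d slides / %d experiments\n",
    x$provenance$n_cores, x$provenance$n_slides, x$provenance$n_experiments
  ))
  invisible(x)
}

#' Tidy / summarize a hypothesis-test result
#'
#' `tidy()` returns one row per contingency cell; `glance()` returns a
#' one-row summary (cells, p-value, decision, provenance).
#'
#' @param x A `tma_hypothesis_result`.
#' @param ... Unused.
#' @export
tidy.tma_hypothesis_result <- function(x, ...) {
  m <- unclass(x$table)
  tibble::tibble(
    classifier = rep(c("hypothesis", "complement"), each = 2),
    dependent = rep(c("hypothesis", "complement"), 2),
    count = as.integer(c(m[1, 1], m[2, 1], m[1, 2], m[2, 2]))
  )
}

#' @rdname tidy.tma_hypothesis_result
#' @export
glance.tma_hypothesis_result <- function(x, ...) {
  m <- unclass(x$table)
  tibble::tibble(
    n11 = m[1, 1], n12 = m[1, 2], n21 = m[2, 1], n22 = m[2, 2],
    p.value = x$p_value, alpha = x$alpha, decision = x$decision,
    n_cores = x$provenance$n_cores,
    n_slides = x$provenance$n_slides,
    n_experiments = x$provenance$n_experiments
  )
}

#' Plot the dependent-value distributions D1 and D2
#'
#' Stacked proportion bars of the dependent property within Core Collection A
#' (classifier = hypothesis values) and Core Collection B (complement) — the
#' two distributions Fisher's exact test compares.
#'
#' @param object A `tma_hypothesis_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tma_hypothesis_result <- function(object, ...) {
  d <- tidy(object)
  d$collection <- ifelse(d$classifier == "hypothesis",
    "Core Collection A", "Core Collection B"
  )
  ggplot2::ggplot(
    d,
    ggplot2::aes(
      x = .data$collection, y = .data$count, fill = .data$dependent
    )
  ) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::labs(
      x = NULL, y = "proportion of cores",
      fill = "dependent property",
      title = sprintf(
        "%s | %s vs %s", object$model$shared$value,
        object$model$classifier$attribute, object$model$dependent$attribute
      ),
      subtitle = sprintf(
        "Fisher's exact p = %.3g (%s at alpha = %g)",
        object$p_value, object$decision, object$alpha
      )
    ) +
    ggplot2::theme_minimal()
}

#' Contingency table by direct tabular filtering
#'
#' Computes the same 2x2 table as [test_hypothesis()] without the RDF hop:
#' cores are restricted to samples carrying the shared property, classifier
#' and dependent values are read straight from the staining-result /
#' sample-attribute tables, and cores missing either value are excluded
#' (complete-case analysis). Used as the fast path for simulation studies;
#' equality with the triple-graph path is a package invariant.
#'
#' @param dataset A [tma_dataset()].
#' @param model A [hypothesis_model()].
#' @return A [contingency_2x2()].
#' @export
contingency_from_dataset <- function(dataset, model) {
  stopifnot(inherits(dataset, "tma_dataset"), inherits(model, "hypothesis_model"))
  sa <- dataset$SampleAttribute
  shared_samples <- unique(sa$SampleId[
    !is.na(sa$AttributeName) & sa$AttributeName == model$shared$attribute &
      !is.na(sa$Value) & sa$Value == model$shared$value
  ])
  cores <- dataset$Core[dataset$Core$SampleId %in% shared_samples, ]

  membership <- function(factor) {
    if (factor$kind == "staining") {
      sr <- dataset$StainingResult
      sr <- sr[!is.na(sr$MarkerName) & sr$MarkerName == factor$marker &
        !is.na(sr$Intensity), ]
      key <- sr$CoreId
      val <- sr$Intensity
    } else {
      rows <- sa[!is.na(sa$AttributeName) &
        sa$AttributeName == factor$attribute & !is.na(sa$Value), ]
      # a sample may carry several rows of the same attribute; keep them all
      m <- merge(cores[, c("Id", "SampleId")], rows[, c("SampleId", "Value")],
        by = "SampleId"
      )
      key <- m$Id
      val <- m$Value
    }
    list(
      hyp = unique(key[val %in% factor$hypothesis_values]),
      comp = unique(key[val %in% factor$complement_values])
    )
  }
  b <- membership(model$classifier)
  c_ <- membership(model$dependent)
  ids <- cores$Id
  n <- function(cls, dep) length(intersect(ids, intersect(cls, dep)))
  contingency_2x2(
    n(b$hyp, c_$hyp), n(b$comp, c_$hyp),
    n(b$hyp, c_$comp), n(b$comp, c_$comp)
  )
}
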