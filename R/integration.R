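# Marker-mediated integration of DNA-microarray and TMA data: an array probe
# is mapped to the antibody used in TMA staining, and the cross-platform
# query asks how histologies distribute among the cores where that antibody
# stained above an intensity threshold.

#' Read a probe-to-antibody map
#'
#' Two-column TSV (`probe_id`, `antibody`). Probe identifiers must be unique;
#' a duplicated probe is a load-time validation error.
#'
#' @param path TSV file path.
#' @return A tibble of class `probe_antibody_map`.
#' @export
read_probe_map <- function(path) {
  df <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    na = "", progress = FALSE
  )
  if (!identical(names(df), c("probe_id", "antibody"))) {
    rlang::abort(sprintf("%s: expected columns probe_id, antibody", path),
      class = "tmatriad_parse_error"
    )
  }
  probe_antibody_map(df$probe_id, df$antibody)
}

#' @rdname read_probe_map
#' @param probe_id,antibody Character vectors of equal length.
#' @export
probe_antibody_map <- function(probe_id, antibody) {
  dup <- probe_id[duplicated(probe_id)]
  if (length(dup) > 0) {
    rlang::abort(
      sprintf("duplicate probe id(s): %s", paste(unique(dup), collapse = ", ")),
      class = "tmatriad_validation_error"
    )
  }
  out <- tibble::tibble(probe_id = probe_id, antibody = antibody)
  class(out) <- c("probe_antibody_map", class(out))
  out
}

#' Map an array probe to its TMA antibody
#'
#' Exact string match on the probe identifier.
#'
#' @param probe Probe identifier, e.g. `"201983_s_at"`.
#' @param map A [probe_antibody_map()].
#' @return The antibody (marker) name.
#' @export
map_probe_to_antibody <- function(probe, map) {
  stopifnot(inherits(map, "probe_antibody_map"))
  hit <- map$antibody[map$probe_id == probe]
  if (length(hit) == 0) {
    rlang::abort(sprintf("probe '%s' is not in the probe-antibody map", probe),
      class = "tmatriad_notfound_error"
    )
  }
  hit[1]
}

# Permissible intensity values strictly above `threshold` in registry order.
intensities_above <- function(registry, attribute, context, threshold) {
  def <- lookup_attribute(registry, attribute, context)
  if (!def$is_ordinal) {
    rlang::abort(
      sprintf("attribute '%s' is not ordinal; '>' has no meaning", attribute),
      class = "tmatriad_domain_error"
    )
  }
  values <- def$values[[1]]
  pos <- match(threshold, values)
  if (is.na(pos)) {
    rlang::abort(
      sprintf("threshold '%s' is not a permissible value of '%s'", threshold, attribute),
      class = "tmatriad_domain_error"
    )
  }
  if (pos == length(values)) character(0) else values[(pos + 1):length(values)]
}

#' Histology distribution of cores with strong staining of an antibody
#'
#' Answers the cross-platform use-case query: among cores whose staining
#' intensity for `antibody` is strictly above `intensity_threshold`, how are
#' the histologies distributed? The ordinal comparison is done by expanding
#' the threshold into the explicit set of permissible intensities above it
#' (registry order), then evaluating one count query per histology value.
#' Histologies with no matching core are omitted.
#'
#' @param graph A [triple_graph()] built by [dataset_to_graph()].
#' @param antibody Marker name, e.g. `"EGFR"`.
#' @param intensity_threshold A member of the ordinal intensity scale
#'   (e.g. `"1"` for "intensity > 1").
#' @param registry A [attribute_registry()] with the intensity and
#'   `Histology` vocabularies.
#' @param context Context for vocabulary lookups (default wildcard).
#' @param histology_attribute Sample attribute carrying the histology.
#' @param base Base URI the graph was built with.
#' @return A tibble of class `histology_distribution` with columns
#'   `histology` and `count`, plus a `total` attribute (distinct cores above
#'   threshold).
#' @export
histology_distribution <- function(graph, antibody, intensity_threshold,
                                   registry, context = "*",
                                   histology_attribute = "Histology",
                                   base = default_base_uri) {
  int_attr_name <- intensity_attribute_name(registry, antibody, context)
  above <- intensities_above(registry, int_attr_name, context, intensity_threshold)
  P <- function(name) paste0("<", predicate_uri(name, base), ">")
  core_patterns <- function(intensity) {
    list(
      triple_pattern("?sr", P("CoreId"), "?cr"),
      triple_pattern("?sr", P("MarkerName"), antibody),
      triple_pattern("?sr", P("Intensity"), intensity)
    )
  }
  hist_patterns <- function(histology) {
    list(
      triple_pattern("?cr", P("SampleId"), "?s"),
      triple_pattern("?sa", P("SampleId"), "?s"),
      triple_pattern("?sa", P("AttributeName"), histology_attribute),
      triple_pattern("?sa", P("Value"), histology)
    )
  }
  histologies <- permissible_values(registry, histology_attribute, context)
  counts <- integer(length(histologies))
  all_cores <- character(0)
  for (h in seq_along(histologies)) {
    cores <- character(0)
    for (v in above) {
      cores <- union(cores, bgp_var_values(
        graph, c(core_patterns(v), hist_patterns(histologies[h])), "?cr"
      ))
    }
    counts[h] <- length(cores)
    all_cores <- union(all_cores, cores)
  }
  out <- tibble::tibble(histology = histologies, count = counts)
  out <- out[out$count > 0, ]
  attr(out, "total") <- length(all_cores)
  attr(out, "antibody") <- antibody
  class(out) <- c("histology_distribution", class(out))
  out
}

#' Integrated probe-to-histology query
#'
#' Composition of [map_probe_to_antibody()] and [histology_distribution()]:
#' the DNA-microarray probe is mapped to its TMA antibody, then the histology
#' distribution of strongly stained cores is returned.
#'
#' @inheritParams histology_distribution
#' @param probe Probe identifier.
#' @param map A [probe_antibody_map()].
#' @return A list with elements `antibody` and `distribution`.
#' @export
integrated_query <- function(probe, map, graph, intensity_threshold, registry,
                             context = "*", base = default_base_uri) {
  antibody <- map_probe_to_antibody(probe, map)
  dist <- histology_distribution(
    graph, antibody, intensity_threshold, registry,
    context = context, base = base
  )
  list(antibody = antibody, distribution = dist)
}

#' Plot a histology distribution
#'
#' @param object A `histology_distribution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.histology_distribution <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$histology, -.data$count), y = .data$count
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "histology", y = "cores above threshold",
      title = sprintf(
        "Histologies of cores strongly stained for %s",
        attr(object, "antibody") %||% "marker"
      )
    ) +
    ggplot2::theme_minimal()
}
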