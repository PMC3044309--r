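# Relational TMA data model: a minimal concrete schema sufficient for the
# joins the hypothesis engine needs (core -> slide -> experiment,
# core -> sample attribute, core -> staining result).

tma_schema <- function() {
  list(
    Experiment = list(
      columns = c("Id", "Name", "ExpType"),
      pk = "Id", fk = list()
    ),
    Block = list(columns = "Id", pk = "Id", fk = list()),
    Slide = list(
      columns = c("Id", "ExperimentId", "BlockId", "MarkerName"),
      pk = "Id",
      fk = list(ExperimentId = "Experiment", BlockId = "Block")
    ),
    Core = list(
      columns = c("Id", "SlideId", "SampleId"),
      pk = "Id", fk = list(SlideId = "Slide")
    ),
    SampleAttribute = list(
      columns = c("Id", "SampleId", "AttributeName", "Value"),
      pk = "Id", fk = list()
    ),
    StainingResult = list(
      columns = c("Id", "CoreId", "MarkerName", "Intensity", "Range"),
      pk = "Id", fk = list(CoreId = "Core")
    )
  )
}

#' Construct a TMA dataset from relational tables
#'
#' A TMA dataset is a set of six relational tables mirroring how TMA
#' databases store experiments: `Experiment(Id, Name, ExpType)`,
#' `Block(Id)`, `Slide(Id, ExperimentId, BlockId, MarkerName)`,
#' `Core(Id, SlideId, SampleId)`,
#' `SampleAttribute(Id, SampleId, AttributeName, Value)` and
#' `StainingResult(Id, CoreId, MarkerName, Intensity, Range)`. The first
#' column of each table is its primary key; `SampleId` identifies the
#' biological sample (patient tissue) a core was taken from and links cores
#' to clinical attributes. All cells are stored as character; `NA` encodes a
#' missing value.
#'
#' @param ... Named tibbles/data frames, one per table. Omitted tables are
#'   created empty. Unknown table names are an error.
#' @return A list of tibbles of class `tma_dataset`.
#' @seealso [validate_dataset()], [read_tma_dataset()], [write_tma_dataset()]
#' @export
tma_dataset <- function(...) {
  schema <- tma_schema()
  supplied <- list(...)
  if (length(supplied) > 0 && (is.null(names(supplied)) || any(names(supplied) == ""))) {
    rlang::abort("all tables must be named", class = "tmatriad_validation_error")
  }
  unknown <- setdiff(names(supplied), names(schema))
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown table name(s): ", paste(unknown, collapse = ", ")),
      class = "tmatriad_parse_error"
    )
  }
  tables <- purrr::imap(schema, function(sch, tab) {
    if (tab %in% names(supplied)) {
      df <- tibble::as_tibble(supplied[[tab]])
      missing_cols <- setdiff(sch$columns, names(df))
      if (length(missing_cols) > 0) {
        rlang::abort(
          sprintf(
            "table %s is missing column(s): %s", tab,
            paste(missing_cols, collapse = ", ")
          ),
          class = "tmatriad_parse_error"
        )
      }
      df <- df[sch$columns]
      df[] <- lapply(df, as.character)
      df
    } else {
      as_empty_table(sch$columns)
    }
  })
  structure(tables, class = "tma_dataset")
}

as_empty_table <- function(columns) {
  out <- tibble::as_tibble(setNames(
    rep(list(character()), length(columns)), columns
  ))
  out
}

#' @export
print.tma_dataset <- function(x, ...) {
  cat("<tma_dataset>\n")
  for (tab in names(x)) {
    cat(sprintf("  %-16s %d row(s)\n", tab, nrow(x[[tab]])))
  }
  invisible(x)
}

#' Validate a TMA dataset against its schema and an attribute registry
#'
#' Checks referential integrity (every foreign-key value resolves to an
#' existing primary key), primary-key uniqueness, and that every categorical
#' value lies in the permissible value set registered for its attribute in
#' the sample's context. A sample's context is its `Diagnosis` attribute
#' value; staining intensities are checked against the marker-specific
#' `"<Marker> Intensity"` definition when one is registered, otherwise the
#' generic `"Intensity"` definition. Violations are returned as data, not
#' raised: the dataset is accepted downstream only if the report is empty.
#'
#' @param dataset A [tma_dataset()].
#' @param registry A [attribute_registry()]; if `NULL`, only structural
#'   checks are performed.
#' @return A tibble with columns `table`, `row`, `column`, `kind`
#'   (`"duplicate_pk"`, `"dangling_fk"` or `"value"`) and `message`;
#'   zero rows means valid.
#' @export
validate_dataset <- function(dataset, registry = NULL) {
  stopifnot(inherits(dataset, "tma_dataset"))
  schema <- tma_schema()
  viol <- list()
  add <- function(table, row, column, kind, message) {
    viol[[length(viol) + 1]] <<- tibble::tibble(
      table = table, row = as.integer(row), column = column,
      kind = kind, message = message
    )
  }

  for (tab in names(schema)) {
    df <- dataset[[tab]]
    pk <- schema[[tab]]$pk
    dup <- which(duplicated(df[[pk]]) & !is.na(df[[pk]]))
    for (i in dup) {
      add(tab, i, pk, "duplicate_pk", sprintf(
        "duplicate primary key '%s' in table %s", df[[pk]][i], tab
      ))
    }
    for (col in names(schema[[tab]]$fk)) {
      ref <- schema[[tab]]$fk[[col]]
      ref_keys <- dataset[[ref]][[schema[[ref]]$pk]]
      bad <- which(!is.na(df[[col]]) & !(df[[col]] %in% ref_keys))
      for (i in bad) {
        add(tab, i, col, "dangling_fk", sprintf(
          "%s.%s = '%s' matches no %s.%s",
          tab, col, df[[col]][i], ref, schema[[ref]]$pk
        ))
      }
    }
  }

  if (!is.null(registry)) {
    ctx <- sample_contexts(dataset)
    sa <- dataset$SampleAttribute
    for (i in seq_len(nrow(sa))) {
      if (is.na(sa$Value[i]) || is.na(sa$AttributeName[i])) next
      context <- ctx[sa$SampleId[i]]
      if (is.na(context)) context <- "*"
      ok <- value_is_permissible(registry, sa$AttributeName[i], context, sa$Value[i])
      if (!isTRUE(ok)) {
        add("SampleAttribute", i, "Value", "value", sprintf(
          "value '%s' not permissible for attribute '%s' in context '%s'",
          sa$Value[i], sa$AttributeName[i], context
        ))
      }
    }
    sr <- dataset$StainingResult
    core_sample <- setNames(dataset$Core$SampleId, dataset$Core$Id)
    for (i in seq_len(nrow(sr))) {
      if (is.na(sr$Intensity[i])) next
      context <- ctx[core_sample[sr$CoreId[i]]]
      if (length(context) == 0 || is.na(context)) context <- "*"
      attr_name <- intensity_attribute_name(registry, sr$MarkerName[i], context)
      ok <- value_is_permissible(registry, attr_name, context, sr$Intensity[i])
      if (!isTRUE(ok)) {
        add("StainingResult", i, "Intensity", "value", sprintf(
          "intensity '%s' not permissible for '%s' in context '%s'",
          sr$Intensity[i], attr_name, context
        ))
      }
    }
  }

  if (length(viol) == 0) {
    return(tibble::tibble(
      table = character(), row = integer(), column = character(),
      kind = character(), message = character()
    ))
  }
  dplyr::bind_rows(viol)
}

# Diagnosis value per sample id (named character vector); the shared
# condition of a hypothesis ("Colon cancer") is matched against this.
sample_contexts <- function(dataset) {
  sa <- dataset$SampleAttribute
  diag <- sa[!is.na(sa$AttributeName) & sa$AttributeName == "Diagnosis", ]
  setNames(diag$Value, diag$SampleId)
}

# Marker-specific intensity attribute if registered, else generic Intensity.
intensity_attribute_name <- function(registry, marker, context) {
  specific <- paste(marker, "Intensity")
  hit <- registry$attribute == specific &
    (registry$context == context | registry$context == "*")
  if (any(hit)) specific else "Intensity"
}

value_is_permissible <- function(registry, attribute, context, value) {
  def <- tryCatch(lookup_attribute(registry, attribute, context),
    tmatriad_lookup_error = function(e) NULL
  )
  if (is.null(def)) {
    return(FALSE)
  }
  trimws(value) %in% def$values[[1]]
}

#' Read / write a TMA dataset as per-table TSV files
#'
#' One file per table (`Experiment.tsv`, `Slide.tsv`, ...), UTF-8, header row
#' of column names, first column the primary key, empty cell = missing value.
#' Reading a file with a duplicated primary key is a parse error naming the
#' file and line; unknown file names in `dir` are ignored unless listed in
#' the schema.
#'
#' @param dir Directory holding (or to receive) the TSV files.
#' @return `read_tma_dataset()` returns a [tma_dataset()];
#'   `write_tma_dataset()` returns `dir` invisibly.
#' @export
read_tma_dataset <- function(dir) {
  schema <- tma_schema()
  tables <- list()
  for (tab in names(schema)) {
    path <- file.path(dir, paste0(tab, ".tsv"))
    if (!file.exists(path)) next
    df <- readr::read_tsv(path,
      col_types = readr::cols(.default = readr::col_character()),
      na = "", progress = FALSE
    )
    if (!identical(names(df), schema[[tab]]$columns)) {
      rlang::abort(
        sprintf(
          "%s: malformed header (expected %s)", path,
          paste(schema[[tab]]$columns, collapse = ", ")
        ),
        class = "tmatriad_parse_error"
      )
    }
    pk <- df[[schema[[tab]]$pk]]
    dup <- which(duplicated(pk))
    if (length(dup) > 0) {
      rlang::abort(
        sprintf(
          "%s: duplicate primary key '%s' at line %d",
          path, pk[dup[1]], dup[1] + 1L
        ),
        class = "tmatriad_parse_error"
      )
    }
    tables[[tab]] <- df
  }
  do.call(tma_dataset, tables)
}

#' @rdname read_tma_dataset
#' @param dataset Dataset to write.
#' @export
write_tma_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "tma_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tab in names(dataset)) {
    readr::write_tsv(dataset[[tab]], file.path(dir, paste0(tab, ".tsv")),
      na = "", progress = FALSE
    )
  }
  invisible(dir)
}

#' Marker names present in a dataset
#'
#' @param dataset A [tma_dataset()].
#' @return Sorted character vector of distinct marker (antibody) names from
#'   the slide and staining-result tables.
#' @export
dataset_markers <- function(dataset) {
  sort(unique(stats::na.omit(c(
    dataset$Slide$MarkerName, dataset$StainingResult$MarkerName
  ))))
}
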