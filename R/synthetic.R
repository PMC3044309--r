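# Synthetic multi-experiment TMA datasets with a controlled association
# (odds ratio) between a binarized marker factor and a binarized clinical
# factor, plus the deterministic worked-example fixture.

#' Configuration for the synthetic TMA data generator
#'
#' Defaults mirror the worked colon-cancer example: three experiments, an
#' Apaf-1 staining classifier with marginal probability 0.58 of falling in
#' the hypothesis-describing set \{0\}, a histologic-grade dependent factor
#' with marginal probability 0.55 of High-grade, and an odds ratio of 20
#' between the two binarized factors (the empirical margins and odds ratio of
#' the 26/4/6/19 table).
#'
#' @param n_experiments,slides_per_experiment,cores_per_slide Structure of
#'   the generated data; total cores = product of the three.
#' @param shared_value Diagnosis shared by all samples (the context).
#' @param classifier_attribute,classifier_values Classifier attribute and its
#'   hypothesis-describing value set.
#' @param p_classifier Marginal probability a core's classifier value falls
#'   in the hypothesis set.
#' @param dependent_attribute,dependent_values,p_dependent Same for the
#'   dependent factor.
#' @param odds_ratio Target odds ratio between the binarized factors (> 0).
#' @param missing_rate Probability, independently per factor and core, that
#'   the value is missing.
#' @param seed Integer seed; identical seeds yield byte-identical datasets.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_experiments = 3,
                             slides_per_experiment = 2,
                             cores_per_slide = 10,
                             shared_value = "Colon cancer",
                             classifier_attribute = "Apaf-1 Intensity",
                             classifier_values = "0",
                             p_classifier = 0.58,
                             dependent_attribute = "HistologicGrade",
                             dependent_values = "High-grade",
                             p_dependent = 0.55,
                             odds_ratio = 20,
                             missing_rate = 0,
                             seed = 1L) {
  if (!(p_classifier > 0 && p_classifier < 1 && p_dependent > 0 && p_dependent < 1)) {
    rlang::abort("marginal probabilities must lie in (0, 1)",
      class = "tmatriad_domain_error"
    )
  }
  if (!(odds_ratio > 0)) {
    rlang::abort("odds_ratio must be > 0", class = "tmatriad_domain_error")
  }
  if (!(missing_rate >= 0 && missing_rate < 1)) {
    rlang::abort("missing_rate must lie in [0, 1)",
      class = "tmatriad_domain_error"
    )
  }
  if (n_experiments < 1 || slides_per_experiment < 1 || cores_per_slide < 1) {
    rlang::abort("structure counts must be >= 1", class = "tmatriad_domain_error")
  }
  structure(
    list(
      n_experiments = as.integer(n_experiments),
      slides_per_experiment = as.integer(slides_per_experiment),
      cores_per_slide = as.integer(cores_per_slide),
      shared_value = shared_value,
      classifier_attribute = classifier_attribute,
      classifier_values = as.character(classifier_values),
      p_classifier = p_classifier,
      dependent_attribute = dependent_attribute,
      dependent_values = as.character(dependent_values),
      p_dependent = p_dependent,
      odds_ratio = odds_ratio,
      missing_rate = missing_rate,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

#' Joint cell probabilities of a 2x2 distribution with given margins and
#' odds ratio
#'
#' Solves the quadratic for the (1,1) cell: the unique joint distribution of
#' two binary variables with marginals `p_b`, `p_c` and odds ratio
#' `odds_ratio` (Plackett construction).
#'
#' @param p_b,p_c Marginal probabilities in (0, 1).
#' @param odds_ratio Target odds ratio (> 0).
#' @return Numeric length-4 vector `(p11, p01, p10, p00)` where the first
#'   index is the classifier and the second the dependent factor.
#' @export
joint_cell_probabilities <- function(p_b, p_c, odds_ratio) {
  if (abs(odds_ratio - 1) < 1e-12) {
    p11 <- p_b * p_c
  } else {
    s <- 1 + (odds_ratio - 1) * (p_b + p_c)
    disc <- s^2 - 4 * odds_ratio * (odds_ratio - 1) * p_b * p_c
    if (disc < 0) {
      rlang::abort("no joint distribution with these margins and odds ratio",
        class = "tmatriad_domain_error"
      )
    }
    p11 <- (s - sqrt(disc)) / (2 * (odds_ratio - 1))
  }
  p <- c(
    p11 = p11, p01 = p_c - p11, p10 = p_b - p11,
    p00 = 1 - p_b - p_c + p11
  )
  if (any(p < -1e-12)) {
    rlang::abort("margins and odds ratio are jointly unsatisfiable",
      class = "tmatriad_domain_error"
    )
  }
  pmax(p, 0)
}

#' Generate a synthetic TMA dataset
#'
#' Per core, the joint (classifier in hypothesis set, dependent in hypothesis
#' set) indicator pair is drawn from the unique 2x2 distribution with the
#' configured margins and odds ratio; the concrete categorical value is then
#' drawn uniformly from the chosen side's value set. Cores are assigned
#' round-robin to slides (no slide-level random effects: the hypothesis test
#' pools cores). Each core comes from its own sample carrying the shared
#' diagnosis. Missing values are injected independently per factor at
#' `missing_rate` (a missing staining value drops the staining row; a missing
#' clinical value drops the attribute row).
#'
#' @param config A [synthetic_config()].
#' @param registry Attribute registry supplying the permissible value sets
#'   (default [demo_registry()]).
#' @return A [tma_dataset()] that passes [validate_dataset()].
#' @export
generate_tma_dataset <- function(config, registry = demo_registry()) {
  stopifnot(inherits(config, "synthetic_config"))
  model <- hypothesis_model(
    registry,
    shared_value = config$shared_value,
    classifier_attribute = config$classifier_attribute,
    classifier_values = config$classifier_values,
    dependent_attribute = config$dependent_attribute,
    dependent_values = config$dependent_values
  )
  n_slides <- config$n_experiments * config$slides_per_experiment
  n_cores <- n_slides * config$cores_per_slide
  p <- joint_cell_probabilities(
    config$p_classifier, config$p_dependent, config$odds_ratio
  )

  withr::with_seed(config$seed, {
    cell <- sample.int(4, n_cores, replace = TRUE, prob = p)
    in_b <- cell %in% c(1, 3) # classifier in hypothesis set
    in_c <- cell %in% c(1, 2) # dependent in hypothesis set
    pick <- function(in_hyp, factor) {
      vals <- character(length(in_hyp))
      hyp <- factor$hypothesis_values
      comp <- factor$complement_values
      vals[in_hyp] <- hyp[sample.int(length(hyp), sum(in_hyp), replace = TRUE)]
      vals[!in_hyp] <- comp[sample.int(length(comp), sum(!in_hyp), replace = TRUE)]
      vals
    }
    b_val <- pick(in_b, model$classifier)
    c_val <- pick(in_c, model$dependent)
    b_missing <- stats::runif(n_cores) < config$missing_rate
    c_missing <- stats::runif(n_cores) < config$missing_rate
  })

  experiment <- tibble::tibble(
    Id = paste0("E", seq_len(config$n_experiments)),
    Name = paste0("synthTMA", seq_len(config$n_experiments)),
    ExpType = "TMA"
  )
  slide_exp <- rep(experiment$Id, each = config$slides_per_experiment)
  block <- tibble::tibble(Id = paste0("B", seq_len(n_slides)))
  marker <- model$classifier$marker %||% NA_character_
  slide <- tibble::tibble(
    Id = paste0("SL", seq_len(n_slides)),
    ExperimentId = slide_exp,
    BlockId = block$Id,
    MarkerName = marker
  )
  core_slide <- rep(slide$Id, times = config$cores_per_slide)[seq_len(n_cores)]
  core <- tibble::tibble(
    Id = paste0("CR", seq_len(n_cores)),
    SlideId = core_slide,
    SampleId = paste0("P", seq_len(n_cores))
  )

  sa_rows <- list(tibble::tibble(
    SampleId = core$SampleId,
    AttributeName = "Diagnosis",
    Value = config$shared_value
  ))
  sr_rows <- list()
  emit_factor <- function(factor, values, missing) {
    keep <- !missing
    if (factor$kind == "staining") {
      sr_rows[[length(sr_rows) + 1]] <<- tibble::tibble(
        CoreId = core$Id[keep],
        MarkerName = factor$marker,
        Intensity = values[keep],
        Range = NA_character_
      )
    } else {
      sa_rows[[length(sa_rows) + 1]] <<- tibble::tibble(
        SampleId = core$SampleId[keep],
        AttributeName = factor$attribute,
        Value = values[keep]
      )
    }
  }
  emit_factor(model$classifier, b_val, b_missing)
  emit_factor(model$dependent, c_val, c_missing)

  sample_attribute <- dplyr::bind_rows(sa_rows)
  sample_attribute <- dplyr::bind_cols(
    tibble::tibble(Id = paste0("SA", seq_len(nrow(sample_attribute)))),
    sample_attribute
  )
  staining_result <- dplyr::bind_rows(sr_rows)
  if (nrow(staining_result) > 0) {
    staining_result <- dplyr::bind_cols(
      tibble::tibble(Id = paste0("SR", seq_len(nrow(staining_result)))),
      staining_result
    )
  } else {
    staining_result <- as_empty_table(tma_schema()$StainingResult$columns)
  }

  tma_dataset(
    Experiment = experiment, Block = block, Slide = slide, Core = core,
    SampleAttribute = sample_attribute, StainingResult = staining_result
  )
}

#' Deterministic worked-example fixture
#'
#' A colon-cancer TMA dataset of 55 cores across 5 slides and 3 experiments
#' whose Apaf-1/grade contingency table is exactly (26, 4, 6, 19): 26 cores
#' with Apaf-1 intensity 0 and high-grade phenotype, 4 with intensity 1--3
#' and high grade, 6 with intensity 0 and low grade, 19 with intensity 1--3
#' and low grade. Non-zero intensities cycle 1, 2, 3 deterministically; only
#' High-grade and Low-grade values occur.
#'
#' @return A [tma_dataset()].
#' @export
make_worked_example_fixture <- function() {
  cells_fixture(
    cells = c(26L, 4L, 6L, 19L),
    slide_experiments = c("E1", "E1", "E2", "E2", "E3")
  )
}

# Deterministic colon-cancer fixture with prescribed 2x2 cells
# (n11, n12, n21, n22) for the Apaf-1/grade hypothesis; cores are spread
# round-robin over the slides, one sample per core.
cells_fixture <- function(cells, slide_experiments = c("E1", "E1", "E2", "E2", "E3")) {
  n_cores <- sum(cells)
  n_slides <- length(slide_experiments)
  in_b <- rep(c(TRUE, FALSE, TRUE, FALSE), cells) # Apaf-1 = 0
  in_c <- rep(c(TRUE, TRUE, FALSE, FALSE), cells) # High-grade
  intensity <- character(n_cores)
  intensity[in_b] <- "0"
  intensity[!in_b] <- as.character(rep_len(1:3, sum(!in_b)))
  grade <- ifelse(in_c, "High-grade", "Low-grade")

  exp_ids <- unique(slide_experiments)
  experiment <- tibble::tibble(
    Id = exp_ids,
    Name = paste0("colonTMA", seq_along(exp_ids)),
    ExpType = "TMA"
  )
  slide <- tibble::tibble(
    Id = paste0("SL", seq_len(n_slides)),
    ExperimentId = slide_experiments,
    BlockId = paste0("B", seq_len(n_slides)),
    MarkerName = "Apaf-1"
  )
  block <- tibble::tibble(Id = paste0("B", seq_len(n_slides)))
  core <- tibble::tibble(
    Id = paste0("CR", seq_len(n_cores)),
    SlideId = slide$Id[((seq_len(n_cores) - 1) %% n_slides) + 1],
    SampleId = paste0("P", seq_len(n_cores))
  )
  sample_attribute <- tibble::tibble(
    Id = paste0("SA", seq_len(2 * n_cores)),
    SampleId = rep(core$SampleId, 2),
    AttributeName = rep(c("Diagnosis", "HistologicGrade"), each = n_cores),
    Value = c(rep("Colon cancer", n_cores), grade)
  )
  staining_result <- tibble::tibble(
    Id = paste0("SR", seq_len(n_cores)),
    CoreId = core$Id,
    MarkerName = "Apaf-1",
    Intensity = intensity,
    Range = NA_character_
  )
  tma_dataset(
    Experiment = experiment, Block = block, Slide = slide, Core = core,
    SampleAttribute = sample_attribute, StainingResult = staining_result
  )
}

#' Synthetic glioma fixture for the integration use case
#'
#' A deterministic glioma TMA (one experiment, two slides, 36 cores) stained
#' for EGFR, constructed so that strong EGFR staining (intensity > 1) is
#' predominantly found in glioblastoma cores. Labelled synthetic: it stands
#' in for the unpublished TMA data behind the cross-platform use case.
#'
#' @return A [tma_dataset()].
#' @export
make_glioma_fixture <- function() {
  histology <- rep(
    c("Glioblastoma", "Astrocytoma", "Oligodendroglioma"),
    times = c(16, 12, 8)
  )
  # glioblastoma: mostly strong staining; others: mostly weak
  intensity <- c(
    rep(c("3", "2", "2", "1"), 4), # 12/16 glioblastoma above 1
    rep(c("0", "1", "2"), 4), # 4/12 astrocytoma above 1
    rep(c("0", "1"), 4) # 0/8 oligodendroglioma above 1
  )
  n <- length(histology)
  experiment <- tibble::tibble(Id = "E1", Name = "gliomaTMA1", ExpType = "TMA")
  block <- tibble::tibble(Id = c("B1", "B2"))
  slide <- tibble::tibble(
    Id = c("SL1", "SL2"), ExperimentId = "E1",
    BlockId = c("B1", "B2"), MarkerName = "EGFR"
  )
  core <- tibble::tibble(
    Id = paste0("CR", seq_len(n)),
    SlideId = rep(c("SL1", "SL2"), length.out = n),
    SampleId = paste0("G", seq_len(n))
  )
  sample_attribute <- tibble::tibble(
    Id = paste0("SA", seq_len(2 * n)),
    SampleId = rep(core$SampleId, 2),
    AttributeName = rep(c("Diagnosis", "Histology"), each = n),
    Value = c(rep("Glioma", n), histology)
  )
  staining_result <- tibble::tibble(
    Id = paste0("SR", seq_len(n)),
    CoreId = core$Id,
    MarkerName = "EGFR",
    Intensity = intensity,
    Range = NA_character_
  )
  tma_dataset(
    Experiment = experiment, Block = block, Slide = slide, Core = core,
    SampleAttribute = sample_attribute, StainingResult = staining_result
  )
}

#' Demo probe-to-antibody map
#'
#' Includes the use-case probe `201983_s_at -> EGFR`.
#'
#' @return A [probe_antibody_map()].
#' @export
demo_probe_map <- function() {
  probe_antibody_map(
    probe_id = c("201983_s_at", "204686_at", "211300_s_at"),
    antibody = c("EGFR", "Apaf-1", "Leptin")
  )
}
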