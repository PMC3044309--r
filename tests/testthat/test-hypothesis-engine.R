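test_that("complementary value sets partition the permissible set", {
  reg <- demo_registry()
  grade <- lookup_attribute(reg, "HistologicGrade", "Colon cancer")
  expect_equal(
    complement_value_set(grade, "High-grade"),
    c("Low-grade", "Intermediate-grade")
  )
  intensity <- lookup_attribute(reg, "Apaf-1 Intensity", "Colon cancer")
  expect_equal(complement_value_set(intensity, "0"), c("1", "2", "3"))

  expect_error(
    complement_value_set(intensity, c("0", "1", "2", "3")),
    class = "tmatriad_degenerate_error"
  )
  expect_error(
    complement_value_set(intensity, character(0)),
    class = "tmatriad_degenerate_error"
  )
  expect_error(
    complement_value_set(intensity, "7"),
    class = "tmatriad_domain_error"
  )
})

test_that("hypothesis models fill in complements and classify factor kinds", {
  model <- demo_model()
  expect_equal(model$classifier$complement_values, c("1", "2", "3"))
  expect_equal(
    model$dependent$complement_values,
    c("Low-grade", "Intermediate-grade")
  )
  expect_equal(model$classifier$kind, "staining")
  expect_equal(model$classifier$marker, "Apaf-1")
  expect_equal(model$dependent$kind, "sample")

  reg <- demo_registry() |>
    register_attribute("Leptin", "Colon cancer", c("positive", "negative"))
  leptin <- hypothesis_model(
    reg,
    shared_value = "Colon cancer",
    classifier_attribute = "Leptin", classifier_values = "positive",
    dependent_attribute = "NodalStatus", dependent_values = "N0",
    classifier_marker = "Leptin"
  )
  expect_equal(leptin$classifier$complement_values, "negative")
  expect_equal(leptin$dependent$complement_values, c("N1", "N2", "N3"))
  expect_equal(leptin$classifier$kind, "staining")

  expect_error(
    hypothesis_model(
      reg, "Colon cancer",
      "Apaf-1 Intensity", c("0", "1", "2", "3"),
      "HistologicGrade", "High-grade"
    ),
    class = "tmatriad_degenerate_error"
  )
  expect_error(
    hypothesis_model(
      reg, "Colon cancer",
      "NotRegistered", "x", "HistologicGrade", "High-grade"
    ),
    class = "tmatriad_lookup_error"
  )
})

test_that("exactly four query plans are generated with the fixed value-set rule", {
  model <- demo_model()
  plans <- generate_query_plans(model)
  expect_length(plans, 4)
  hyp_b <- model$classifier$hypothesis_values
  comp_b <- model$classifier$complement_values
  hyp_c <- model$dependent$hypothesis_values
  comp_c <- model$dependent$complement_values
  # classifier: hypothesis set for plans 1 and 3, complement for 2 and 4;
  # dependent: hypothesis set for plans 1 and 2, complement for 3 and 4
  expected <- list(
    list(cls = hyp_b, dep = hyp_c),
    list(cls = comp_b, dep = hyp_c),
    list(cls = hyp_b, dep = comp_c),
    list(cls = comp_b, dep = comp_c)
  )
  for (i in 1:4) {
    expect_equal(plans[[i]]$valuesets$classifier, expected[[i]]$cls, info = i)
    expect_equal(plans[[i]]$valuesets$dependent, expected[[i]]$dep, info = i)
    expect_equal(plans[[i]]$valuesets$shared, "Colon cancer", info = i)
    expect_length(
      plans[[i]]$queries,
      length(expected[[i]]$cls) * length(expected[[i]]$dep)
    )
  }
})

test_that("the four plans partition the permissible value product", {
  model <- demo_model()
  plans <- generate_query_plans(model)
  product <- expand.grid(
    cls = model$classifier$permissible_values,
    dep = model$dependent$permissible_values,
    stringsAsFactors = FALSE
  )
  for (k in seq_len(nrow(product))) {
    matched <- vapply(plans, function(pl) {
      product$cls[k] %in% pl$valuesets$classifier &&
        product$dep[k] %in% pl$valuesets$dependent
    }, TRUE)
    expect_equal(sum(matched), 1, info = paste(product[k, ], collapse = "/"))
  }
})

test_that("the worked example yields the 26/4/6/19 table and is supported", {
  ds <- make_worked_example_fixture()
  graph <- dataset_to_graph(ds)
  res <- test_hypothesis(demo_model(), graph, alpha = 0.01)
  expect_equal(as.vector(t(unclass(res$table))), c(26, 4, 6, 19))
  expect_lt(res$p_value, 0.0001)
  expect_equal(res$decision, "supported")
  expect_equal(res$provenance$n_cores, 55)
  expect_equal(res$provenance$n_slides, 5)
  expect_equal(res$provenance$n_experiments, 3)
})

test_that("identical D1 and D2 distributions give p = 1 and rejection", {
  ds <- tmatriad:::cells_fixture(c(5L, 5L, 5L, 5L))
  res <- test_hypothesis(demo_model(), dataset_to_graph(ds))
  expect_equal(as.vector(unclass(res$table)), rep(5, 4))
  expect_equal(res$p_value, 1.0)
  expect_equal(res$decision, "rejected")
})

test_that("a graph with no matching cores raises a no-data error", {
  model <- hypothesis_model(
    demo_registry(),
    shared_value = "Stomach cancer",
    classifier_attribute = "Intensity", classifier_values = "0",
    dependent_attribute = "NodalStatus", dependent_values = "N0",
    classifier_marker = "Apaf-1"
  )
  graph <- dataset_to_graph(make_worked_example_fixture())
  expect_error(
    test_hypothesis(model, graph),
    class = "tmatriad_nodata_error"
  )
})

test_that("cell counts are conserved and swap symmetry holds", {
  reg <- demo_registry()
  cfg <- synthetic_config(cores_per_slide = 8, odds_ratio = 4, seed = 99, missing_rate = 0.15)
  ds <- generate_tma_dataset(cfg)
  graph <- dataset_to_graph(ds)
  model <- demo_model()
  res <- test_hypothesis(model, graph)

  # conservation: cells sum to distinct cores with the shared property and
  # both factor values present
  tab <- contingency_from_dataset(ds, model)
  complete <- sum(tab)
  expect_equal(sum(unclass(res$table)), complete)
  expect_equal(res$provenance$n_cores, complete)

  # exchanging hypothesis and complement of the classifier permutes columns
  # and leaves the two-sided p unchanged
  swapped <- hypothesis_model(
    reg,
    shared_value = "Colon cancer",
    classifier_attribute = "Apaf-1 Intensity",
    classifier_values = c("1", "2", "3"),
    dependent_attribute = "HistologicGrade", dependent_values = "High-grade"
  )
  res2 <- test_hypothesis(swapped, graph)
  m1 <- unclass(res$table)
  m2 <- unclass(res2$table)
  expect_equal(m2, m1[, 2:1], ignore_attr = TRUE)
  expect_equal(res2$p_value, res$p_value, tolerance = 1e-12)
})

test_that("triple-graph cell counts equal direct tabular filtering", {
  set.seed(21)
  model <- demo_model()
  for (i in 1:10) {
    cfg <- synthetic_config(
      n_experiments = sample(1:3, 1),
      slides_per_experiment = sample(1:2, 1),
      cores_per_slide = sample(4:9, 1),
      odds_ratio = sample(c(0.5, 1, 5, 20), 1),
      p_classifier = runif(1, 0.3, 0.7),
      p_dependent = runif(1, 0.3, 0.7),
      missing_rate = sample(c(0, 0.2), 1),
      seed = sample.int(1e6, 1)
    )
    ds <- generate_tma_dataset(cfg)
    tab <- contingency_from_dataset(ds, model)
    if (sum(tab) == 0) next
    res <- test_hypothesis(model, dataset_to_graph(ds))
    expect_equal(unclass(res$table), unclass(tab), info = i)
  }
})

test_that("results tidy, glance and autoplot", {
  res <- test_hypothesis(demo_model(), dataset_to_graph(make_worked_example_fixture()))
  td <- generics::tidy(res)
  expect_equal(sum(td$count), 55)
  gl <- generics::glance(res)
  expect_equal(gl$n11, 26)
  expect_equal(gl$decision, "supported")
  p <- ggplot2::autoplot(res)
  expect_s3_class(p, "ggplot")
})
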