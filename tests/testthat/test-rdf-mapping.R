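test_that("a three-column experiment row maps to two triples with the declared predicates", {
  row <- c(Id = "1", Name = "colonTMA1", ExpType = "TMA")
  triples <- row_to_triples("Experiment", row, default_mapping_rules())
  expect_equal(nrow(triples), 2)
  expect_setequal(
    triples$predicate,
    c(predicate_uri("hasName"), predicate_uri("ExpType"))
  )
  expect_equal(unique(triples$subject), subject_uri("Experiment", "1"))
  expect_false(any(triples$object_is_uri))
  expect_setequal(triples$object, c("colonTMA1", "TMA"))
})

test_that("foreign-key columns become object-URI triples linking rows", {
  row <- c(Id = "SL1", ExperimentId = "1", BlockId = "B1", MarkerName = "Apaf-1")
  triples <- row_to_triples("Slide", row, default_mapping_rules())
  expect_equal(nrow(triples), 3)
  fk <- triples[triples$predicate == predicate_uri("ExperimentId"), ]
  expect_true(fk$object_is_uri)
  expect_equal(fk$object, subject_uri("Experiment", "1"))
})

test_that("missing values emit no triple and uncovered columns are mapping errors", {
  row <- c(Id = "1", Name = NA, ExpType = NA)
  expect_equal(nrow(row_to_triples("Experiment", row, default_mapping_rules())), 0)

  rules <- mapping_rules("Experiment", "Name", "literal", "hasName")
  expect_error(
    row_to_triples("Experiment", c(Id = "1", Name = "x", ExpType = "TMA"), rules),
    class = "tmatriad_mapping_error"
  )
})

test_that("dataset_to_graph emits one triple per non-missing non-key column", {
  g <- dataset_to_graph(mini_dataset())
  # Experiment row: 2 literal triples; Slide row: 2 FK + 1 literal
  expect_equal(nrow(g), 5)

  expect_equal(nrow(dataset_to_graph(tma_dataset())), 0)

  # injective on rows: distinct PKs never share a subject URI
  ds <- make_worked_example_fixture()
  g2 <- dataset_to_graph(ds)
  core_subjects <- unique(g2$subject[startsWith(
    g2$subject, paste0(tmatriad:::default_base_uri, "/Core/")
  )])
  expect_equal(length(core_subjects), nrow(ds$Core))
  # deterministic
  expect_identical(g2, dataset_to_graph(ds))
})

test_that("triple graphs have set semantics", {
  g <- dataset_to_graph(mini_dataset())
  g2 <- add_triples(g, tibble::as_tibble(g))
  expect_equal(nrow(g2), nrow(g))
  q <- count_query(list(triple_pattern("?cr", predicate_uri("hasName"), "?n")))
  expect_equal(evaluate_count_query(g, q), evaluate_count_query(g2, q))
})

test_that("count queries return distinct bindings of the count variable", {
  expect_equal(
    evaluate_count_query(
      triple_graph(),
      count_query(list(triple_pattern("?cr", "http://p/x", "?v")))
    ),
    0
  )
  # 7 distinct core subjects under one predicate
  g <- triple_graph(
    subject = paste0("http://t/Core/", c(1:7, 1:3)),
    predicate = "http://t/vocab#SlideId",
    object = paste0("http://t/Slide/", c(rep("a", 7), "b", "b", "b")),
    object_is_uri = TRUE
  )
  q <- count_query(list(triple_pattern("?cr", "http://t/vocab#SlideId", "?sl")))
  expect_equal(evaluate_count_query(g, q), 7)
  # constrained to one slide
  q2 <- count_query(list(triple_pattern("?cr", "http://t/vocab#SlideId", "<http://t/Slide/b>")))
  expect_equal(evaluate_count_query(g, q2), 3)
})

test_that("count-query construction rejects malformed queries", {
  expect_error(count_query(list()), class = "tmatriad_validation_error")
  expect_error(
    count_query(list(triple_pattern("?x", "http://p", "?y")), count_var = "?cr"),
    class = "tmatriad_validation_error"
  )
  expect_error(
    triple_pattern("literal-subject", "http://p", "?y"),
    class = "tmatriad_validation_error"
  )
})

test_that("query evaluation matches brute-force enumeration on random graphs", {
  set.seed(42)
  for (rep in 1:40) {
    g <- random_small_graph(
      n_triples = sample(5:25, 1),
      n_terms = sample(4:8, 1)
    )
    pats <- random_small_pattern_set(g, n_patterns = sample(1:3, 1))
    q <- count_query(pats, count_var = "?cr")
    expect_equal(
      evaluate_count_query(g, q),
      bgp_count_oracle(g, pats, "?cr"),
      info = sprintf("replicate %d", rep)
    )
  }
})

test_that("tabular column counts commute with one-pattern graph queries", {
  ds <- make_worked_example_fixture()
  g <- dataset_to_graph(ds)
  # count staining rows (by subject) with Intensity "0" both ways
  q <- count_query(
    list(triple_pattern("?sr", predicate_uri("Intensity"), "0")),
    count_var = "?sr"
  )
  expect_equal(
    evaluate_count_query(g, q),
    sum(ds$StainingResult$Intensity == "0", na.rm = TRUE)
  )
  q2 <- count_query(
    list(triple_pattern("?sa", predicate_uri("Value"), "High-grade")),
    count_var = "?sa"
  )
  expect_equal(
    evaluate_count_query(g, q2),
    sum(ds$SampleAttribute$Value == "High-grade", na.rm = TRUE)
  )
})

test_that("N-Triples serialization is sorted, byte-stable and round-trips", {
  g <- dataset_to_graph(make_worked_example_fixture())
  txt <- serialize_graph(g, "ntriples")
  expect_identical(txt, serialize_graph(g, "ntriples"))
  g2 <- parse_graph(txt, "ntriples")
  expect_equal(nrow(g2), nrow(g))
  expect_equal(nrow(dplyr::anti_join(tibble::as_tibble(g), tibble::as_tibble(g2),
    by = names(g)
  )), 0)
  expect_identical(serialize_graph(g2, "ntriples"), txt)

  expect_equal(serialize_graph(triple_graph(), "ntriples"), "")
  expect_equal(nrow(parse_graph("", "ntriples")), 0)
})

test_that("Turtle serialization round-trips, including escaped literals", {
  g <- triple_graph(
    subject = c("http://t/a", "http://t/a", "http://t/b"),
    predicate = c("http://t/p1", "http://t/p2", "http://t/p1"),
    object = c("plain", "with \"quotes\"\nand newline\tand tab \\ backslash", "http://t/a"),
    object_is_uri = c(FALSE, FALSE, TRUE)
  )
  for (fmt in c("ntriples", "turtle")) {
    g2 <- parse_graph(serialize_graph(g, fmt), fmt)
    expect_equal(nrow(g2), nrow(g), info = fmt)
    expect_equal(
      nrow(dplyr::anti_join(tibble::as_tibble(g), tibble::as_tibble(g2), by = names(g))),
      0,
      info = fmt
    )
  }
})

test_that("malformed serializations raise parse errors naming the line", {
  expect_error(
    parse_graph("<http://a> nonsense .", "ntriples"),
    regexp = "line 1",
    class = "tmatriad_parse_error"
  )
  expect_error(
    parse_graph("<http://a> <http://p> \"x\" .\ngarbage", "ntriples"),
    regexp = "line 2",
    class = "tmatriad_parse_error"
  )
})
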