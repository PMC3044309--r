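# Independent oracles and small fixture builders used across the suite.

# Brute-force Fisher two-sided p: enumerate every table with the observed
# margins, with probabilities from direct binomial-coefficient arithmetic
# (choose(), no logs), and sum those no more probable than the observed one.
fisher_oracle <- function(n11, n12, n21, n22) {
  r1 <- n11 + n12
  c1 <- n11 + n21
  n <- n11 + n12 + n21 + n22
  a <- max(0, r1 + c1 - n):min(r1, c1)
  pmf <- choose(c1, a) * choose(n - c1, r1 - a) / choose(n, r1)
  p_obs <- pmf[a == n11]
  min(1, sum(pmf[pmf <= p_obs * (1 + 1e-7)]))
}

# Brute-force basic-graph-pattern count: enumerate every assignment of the
# query variables over all graph terms and count distinct bindings of the
# count variable among assignments satisfying all patterns. Exponential in
# the number of variables; only for tiny graphs.
bgp_count_oracle <- function(graph, patterns, count_var = "?cr") {
  enc <- function(value, is_uri) {
    is_uri <- rep_len(is_uri, length(value))
    ifelse(is_uri, paste0("<", value, ">"), value)
  }
  facts <- paste(
    enc(graph$subject, TRUE), enc(graph$predicate, TRUE),
    enc(graph$object, graph$object_is_uri),
    sep = "\r"
  )
  terms <- unique(c(
    enc(graph$subject, TRUE), enc(graph$predicate, TRUE),
    enc(graph$object, graph$object_is_uri)
  ))
  vars <- unique(unlist(lapply(patterns, function(p) {
    t <- unlist(p, use.names = FALSE)
    t[startsWith(t, "?")]
  })))
  ground <- function(term, assignment) {
    if (startsWith(term, "?")) {
      assignment[[term]]
    } else if (startsWith(term, "<")) {
      term
    } else {
      term
    }
  }
  grid <- do.call(expand.grid, c(
    setNames(rep(list(terms), length(vars)), vars),
    stringsAsFactors = FALSE
  ))
  hits <- character(0)
  for (i in seq_len(nrow(grid))) {
    assignment <- as.list(grid[i, , drop = FALSE])
    ok <- all(vapply(patterns, function(p) {
      s <- ground(p$subject, assignment)
      pr <- ground(p$predicate, assignment)
      o <- ground(p$object, assignment)
      # subjects and predicates in facts are URI-encoded
      paste(s, pr, o, sep = "\r") %in% facts
    }, TRUE))
    if (ok) hits <- c(hits, assignment[[count_var]])
  }
  length(unique(hits))
}

# Random small triple graph over a compact term vocabulary (so the
# brute-force oracle stays cheap).
random_small_graph <- function(n_triples = 20, n_terms = 8) {
  subs <- paste0("http://t/s", seq_len(n_terms))
  preds <- paste0("http://t/p", seq_len(3))
  lits <- paste0("v", seq_len(4))
  s <- sample(subs, n_triples, replace = TRUE)
  p <- sample(preds, n_triples, replace = TRUE)
  is_uri <- sample(c(TRUE, FALSE), n_triples, replace = TRUE)
  o <- ifelse(is_uri,
    sample(subs, n_triples, replace = TRUE),
    sample(lits, n_triples, replace = TRUE)
  )
  triple_graph(s, p, o, is_uri)
}

random_small_pattern_set <- function(graph, n_patterns = 3, count_var = "?cr") {
  vars <- c(count_var, "?x", "?y")
  rand_term <- function(pos) {
    if (stats::runif(1) < 0.5) {
      sample(vars, 1)
    } else if (pos == "p") {
      paste0("<", sample(unique(graph$predicate), 1), ">")
    } else if (pos == "s") {
      paste0("<", sample(unique(graph$subject), 1), ">")
    } else {
      i <- sample(nrow(graph), 1)
      if (graph$object_is_uri[i]) paste0("<", graph$object[i], ">") else graph$object[i]
    }
  }
  repeat {
    pats <- lapply(seq_len(n_patterns), function(i) {
      triple_pattern(rand_term("s"), rand_term("p"), rand_term("o"))
    })
    all_vars <- unlist(lapply(pats, function(p) {
      t <- unlist(p, use.names = FALSE)
      t[startsWith(t, "?")]
    }))
    if (count_var %in% all_vars) {
      return(pats)
    }
  }
}

demo_model <- function(registry = demo_registry()) {
  hypothesis_model(
    registry,
    shared_value = "Colon cancer",
    classifier_attribute = "Apaf-1 Intensity", classifier_values = "0",
    dependent_attribute = "HistologicGrade", dependent_values = "High-grade",
    direction = "negative"
  )
}

# Tiny two-table dataset used by mapping tests.
mini_dataset <- function() {
  tma_dataset(
    Experiment = tibble::tibble(Id = "1", Name = "colonTMA1", ExpType = "TMA"),
    Block = tibble::tibble(Id = "B1"),
    Slide = tibble::tibble(
      Id = "SL1", ExperimentId = "1", BlockId = "B1", MarkerName = "Apaf-1"
    )
  )
}
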