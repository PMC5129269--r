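test_that("dependency graph reflects declared dependencies and roles", {
  m1 <- sd_model(sd_variable("k", "constant", value = 2), name = "const_only")
  g1 <- build_dependency_graph(m1)
  expect_equal(g1$nodes, "k")
  expect_equal(nrow(g1$instantaneous_edges) + nrow(g1$integration_edges), 0)

  model <- build_wfc_model()
  g <- build_dependency_graph(model)
  expect_length(g$nodes, 20)
  expect_equal(sum(variable_roles(model) != "delay"), 18L)
  # the satisfaction increments integrate into their stocks
  expect_true(any(g$integration_edges$from == "job_satisfaction_increment" &
                    g$integration_edges$to == "job_satisfaction"))
  expect_true(any(g$integration_edges$from == "family_satisfaction_increment" &
                    g$integration_edges$to == "family_satisfaction"))
  # stock-to-delay feeds are integration, not instantaneous, edges
  expect_true(any(g$integration_edges$from == "job_satisfaction" &
                    g$integration_edges$to == "delayed_job_satisfaction"))
  expect_false(any(g$instantaneous_edges$to == "delayed_job_satisfaction"))

  expect_error(
    sd_model(list(sd_variable("a", "auxiliary", equation = quote(b + 1))),
             name = "dangling"),
    "'a'.*undeclared.*b")
})

test_that("instantaneous order is a deterministic topological sort", {
  g <- build_dependency_graph(build_wfc_model())
  ord <- instantaneous_order(g)
  expect_setequal(ord, g$nodes)
  pos <- match(g$nodes, ord)
  names(pos) <- g$nodes
  # every instantaneous edge points forward in the order -- exhaustively
  e <- g$instantaneous_edges
  expect_true(all(pos[e$from] < pos[e$to]))
  # sources (stocks, constants, delays) precede everything depending on them
  expect_lt(pos[["job_performance"]], pos[["job_pressure"]])
  expect_lt(pos[["organizational_support"]], pos[["job_pressure"]])
  # repeated calls are identical (alphabetical tie-breaking)
  expect_identical(ord, instantaneous_order(g))

  cyc <- raw_graph(c("a", "b"), from = c("a", "b"), to = c("b", "a"))
  expect_error(instantaneous_order(cyc), "cycle.*a.*b|cycle.*b.*a")
})

test_that("feedback-loop enumeration matches a brute-force search on small graphs", {
  # acyclic chain has no loops
  chain <- raw_graph(c("a", "b", "c"), from = c("a", "b"), to = c("b", "c"))
  expect_length(enumerate_feedback_loops(chain), 0)

  set.seed(7)
  for (rep in 1:20) {
    n <- sample(3:6, 1)
    nodes <- letters[1:n]
    all_pairs <- expand.grid(from = nodes, to = nodes,
                             stringsAsFactors = FALSE)
    all_pairs <- all_pairs[all_pairs$from != all_pairs$to, ]
    keep <- runif(nrow(all_pairs)) < 0.35
    edges <- all_pairs[keep, ]
    # split arbitrarily into instantaneous and integration edges: the
    # enumeration works on the union
    split <- runif(nrow(edges)) < 0.5
    g <- raw_graph(nodes,
                   from = edges$from[split], to = edges$to[split],
                   integ_from = edges$from[!split], integ_to = edges$to[!split])
    got <- canon_cycles(enumerate_feedback_loops(g))
    want <- brute_force_cycles(nodes, edges)
    expect_identical(got, want)
  }
})

test_that("every cycle is reported once, in causal order, up to rotation", {
  g <- raw_graph(c("x", "y", "z"),
                 from = c("x", "y", "z", "y"),
                 to = c("y", "z", "x", "x"))
  loops <- enumerate_feedback_loops(g)
  expect_length(loops, 2)
  expect_true(has_loop(loops, c("x", "y", "z")))
  expect_true(has_loop(loops, c("y", "x")))       # rotation of c("x", "y")
  expect_false(has_loop(loops, c("x", "z", "y"))) # reversed orientation absent
})
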