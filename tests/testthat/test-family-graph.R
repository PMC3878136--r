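# Family-level SC detection and the structure-relationship graph.

fam <- build_family_set(noise = 0.02, seed = 11)
scs <- compare_family(fam)
truth <- attr(fam, "truth")

test_that("the engineered family reproduces the canonical SC census", {
  expect_setequal(scs$sc_id, c("A01", "A11", "A12", "A13", "A31", "B11"))
  dims <- stats::setNames(scs$dimensionality, scs$sc_id)
  expect_equal(dims[["A01"]], 0L)
  expect_equal(dims[["A11"]], 1L)
  expect_equal(dims[["A31"]], 3L)
  expect_equal(dims[["B11"]], 1L)
  for (id in names(truth$members)) {
    expect_setequal(scs$members[[which(scs$sc_id == id)]],
                    truth$members[[id]])
  }
  base <- function(id) sort(scs$base_magnitudes[[which(scs$sc_id == id)]])
  expect_equal(base("A11"), truth$stack, tolerance = 1e-6)
  expect_equal(base("A12"), truth$tape2, tolerance = 1e-6)
  expect_equal(base("A13"), truth$tape3, tolerance = 1e-6)
  expect_equal(base("B11"), truth$tape_b, tolerance = 1e-6)
  expect_equal(base("A31"), sort(c(truth$stack, truth$tape2, truth$tape3)),
               tolerance = 1e-6)
})

test_that("single or unrelated inputs give empty or dimer-only censuses", {
  expect_equal(nrow(compare_family(fam["P"])), 0L)
  # dimer-only family of 3: independent dimers share exactly the 0D SC
  trio <- lapply(1:3, function(k) {
    crystal_structure(build_crystal(motif_spec("inversion_dimer",
                                               seed = 70 + k, noise = 0.02),
                                    structure_id = paste0("d", k))$contents)
  })
  sc3 <- compare_family(trio)
  expect_equal(nrow(sc3), 1L)
  expect_equal(sc3$dimensionality, 0L)
  expect_equal(sc3$n_members, 3L)
})

test_that("the relationship graph obeys the strict vertical hierarchy", {
  g <- build_graph(scs)
  expect_true(igraph::is_dag(g$graph))
  lev <- stats::setNames(g$nodes$level, g$nodes$id)
  expect_true(all(lev[g$edges$from] < lev[g$edges$to]))
  # every SC reaches at least two structure nodes
  for (id in scs$sc_id) {
    anc <- ancestors_of(g, id)
    expect_gte(sum(anc %in% names(fam)), 2)
  }
  # the canonical dependency pattern, as covering edges
  for (dep in truth$dependencies) {
    p <- strsplit(dep, "->", fixed = TRUE)[[1]]
    expect_true(any(g$edges$from == p[2] & g$edges$to == p[1]),
                label = dep)
  }
  # covering reduction: no transitive A31 -> A01 edge
  expect_false(any(g$edges$from == "A01" & g$edges$to == "A31"))
})

test_that("graph laws hold on randomized SC families", {
  for (seed in 1:20) {
    set.seed(seed)
    n_sc <- sample(2:6, 1)
    dims <- sort(sample(0:3, n_sc, replace = TRUE))
    ids <- paste0("S", seq_len(n_sc), "D", dims)
    pool <- paste0("X", 1:6)
    members <- lapply(seq_len(n_sc), function(i) {
      sort(sample(pool, sample(2:4, 1)))
    })
    depends <- lapply(seq_len(n_sc), function(i) {
      lower <- which(dims < dims[i] &
                       vapply(members, function(m) all(members[[i]] %in% m) ||
                                TRUE, logical(1)))
      lower <- lower[lower < i]
      if (length(lower)) sort(ids[sample(lower, sample(0:length(lower), 1))])
      else character(0)
    })
    sc <- tibble::tibble(sc_id = ids, dimensionality = dims,
                         description = "synthetic",
                         n_members = lengths(members),
                         members = members,
                         base_magnitudes = rep(list(numeric(0)), n_sc),
                         base_labels = rep(list(character(0)), n_sc),
                         depends_on = depends)
    g <- build_graph(sc)
    expect_true(igraph::is_dag(g$graph))
    lev <- stats::setNames(g$nodes$level, g$nodes$id)
    if (nrow(g$edges)) {
      expect_true(all(lev[g$edges$from] < lev[g$edges$to]))
    }
  }
  # SCs with fewer than two members are rejected
  bad <- tibble::tibble(sc_id = "A01", dimensionality = 0L,
                        description = "d", n_members = 1L,
                        members = list("X1"),
                        base_magnitudes = list(numeric(0)),
                        base_labels = list(character(0)),
                        depends_on = list(character(0)))
  expect_error(build_graph(bad), "fewer than 2")
})

test_that("ancestor closure and structure meets follow the branches", {
  g <- build_graph(scs)
  expect_true(all(c("A11", "A31", "P", "Q", "R", "S", "T") %in%
                    ancestors_of(g, "A01")))
  expect_equal(common_constructs(g, "P", "Q"), "A31")
  expect_equal(common_constructs(g, "P", "T"), "A01")
  expect_equal(common_constructs(g, "R", "S"), "A12")
  expect_equal(common_constructs(g, "U", "V"), "B11")
  expect_equal(common_constructs(g, "P", "U"), character(0))
  expect_error(ancestors_of(g, "nope"), "unknown node")
})

test_that("DOT output is deterministic and structurally correct", {
  g <- build_graph(scs)
  d1 <- to_dot(g)
  d2 <- to_dot(build_graph(compare_family(build_family_set(noise = 0.02,
                                                           seed = 11))))
  expect_identical(d1, d2)
  expect_equal(sum(grepl(" -> ", d1)), nrow(g$edges))
  # three-node example: exactly 2 edge statements
  mini <- tibble::tibble(sc_id = "A01", dimensionality = 0L,
                         description = "dimer", n_members = 2L,
                         members = list(c("X1", "X2")),
                         base_magnitudes = list(numeric(0)),
                         base_labels = list(character(0)),
                         depends_on = list(character(0)))
  gm <- build_graph(mini)
  expect_equal(nrow(gm$nodes), 3L)
  expect_equal(sum(grepl(" -> ", to_dot(gm))), 2L)
  # empty graph serializes to a valid document
  g0 <- build_graph(compare_family(fam["P"]), structures = character(0))
  expect_true(any(grepl("digraph", to_dot(g0))))
  # JSON adjacency parses back
  j <- jsonlite::fromJSON(graph_to_json(g))
  expect_setequal(j$nodes$id, g$nodes$id)
})

test_that("SC detection order does not depend on structure input order", {
  scs_rev <- compare_family(rev(fam))
  # same motifs with the same dimensionality/member sets (ids may differ
  # with discovery order; compare the partition)
  key <- function(x) {
    sort(vapply(seq_len(nrow(x)), function(i) {
      paste(x$dimensionality[i], paste(sort(x$members[[i]]), collapse = ","))
    }, character(1)))
  }
  expect_identical(key(scs_rev), key(scs))
})
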