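test_that("quantify_interaction maps mechanisms to signed values", {
  expect_identical(quantify_interaction("activation", 900, 500), 1)
  expect_identical(quantify_interaction("catalysis", 900, 500), 0)
  expect_identical(quantify_interaction("inhibition", 400, 500), NA_real_)
  # case-insensitive, whitespace-tolerant; scoreless rows always pass
  expect_identical(quantify_interaction(" Inhibition "), -1)
  expect_identical(
    quantify_interaction(c("activation", "binding", "inhibition"),
                         c(NA, 700, 501)),
    c(1, 0, -1))
  expect_warning(v <- quantify_interaction("phosphorylation", 900),
                 "unknown mechanism")
  expect_identical(v, 0)
  # purity: same inputs, same output
  expect_identical(quantify_interaction("activation", 700, 500),
                   quantify_interaction("activation", 700, 500))
})

test_that("build_adjacency places, sums, clips, and filters edges", {
  # single activation edge: incoming layout puts effect of a on b at (b, a)
  m <- build_adjacency(interactions_df("A", "B", "activation"))
  expect_identical(m$genes, c("a", "b"))
  expect_identical(m$raw_adjacency["b", "a"], 1)
  expect_identical(sum(m$raw_adjacency != 0), 1L)

  # paper-literal layout is the transpose
  ml <- build_adjacency(interactions_df("A", "B", "activation"),
                        layout = "paper-literal")
  expect_identical(ml$raw_adjacency, t(m$raw_adjacency))

  # parallel opposing edges cancel
  m2 <- build_adjacency(interactions_df(c("A", "A"), c("B", "B"),
                                        c("activation", "inhibition")))
  expect_identical(m2$raw_adjacency["b", "a"], 0)

  # filter happens before summation; clip caps at 1 regardless
  m3 <- build_adjacency(interactions_df(c("A", "A"), c("B", "B"),
                                        c("activation", "activation"),
                                        c(900, 100)))
  expect_identical(m3$raw_adjacency["b", "a"], 1)

  # parallel same-sign edges clip to the discretized bound
  m4 <- build_adjacency(interactions_df(c("A", "A"), c("B", "B"),
                                        c("inhibition", "inhibition")))
  expect_identical(m4$raw_adjacency["b", "a"], -1)

  expect_error(
    build_adjacency(interactions_df("A", "B", "inhibition", 100)),
    "empty model")
  expect_error(build_adjacency(data.frame(source = "A", target = "B")),
               "mechanism")
})

test_that("build_adjacency is permutation-equivariant with bounded entries", {
  set.seed(7)
  for (rep in 1:10) {
    n_edge <- 30L
    rec <- interactions_df(
      sample(LETTERS[1:8], n_edge, TRUE), sample(LETTERS[1:8], n_edge, TRUE),
      sample(c("activation", "inhibition", "binding"), n_edge, TRUE))
    a <- build_adjacency(rec)
    b <- build_adjacency(rec[sample(n_edge), , drop = FALSE])
    expect_identical(a$raw_adjacency, b$raw_adjacency)
    expect_true(all(a$raw_adjacency >= -1 & a$raw_adjacency <= 1))
  }
})

test_that("normalize_dynamics divides by the largest eigenvalue magnitude", {
  mk <- function(raw) {
    genes <- letters[seq_len(nrow(raw))]
    dimnames(raw) <- list(genes, genes)
    structure(list(genes = genes, raw_adjacency = raw, dynamics = NULL,
                   normalization = NA_real_, layout = "incoming"),
              class = "system_model")
  }
  # nilpotent: all eigenvalues 0, matrix untouched
  m <- normalize_dynamics(mk(matrix(c(0, 0, 1, 0), 2)))
  expect_identical(m$normalization, 0)
  expect_identical(m$dynamics, m$raw_adjacency)

  # real eigenvalues +-1
  m <- normalize_dynamics(mk(matrix(c(0, 1, 1, 0), 2)))
  expect_equal(m$normalization, 1)
  expect_equal(m$dynamics, m$raw_adjacency)

  # complex eigenvalues +-i still have magnitude 1
  m <- normalize_dynamics(mk(matrix(c(0, -1, 1, 0), 2)))
  expect_equal(m$normalization, 1)
  expect_equal(m$dynamics, m$raw_adjacency)

  expect_error(normalize_dynamics(mk(matrix(c(0, NA, 1, 0), 2))),
               "non-finite")

  # a positive stability margin shrinks strictly inside the unit circle
  m <- normalize_dynamics(mk(matrix(c(0, 1, 1, 0), 2)),
                          stability_margin = 0.05)
  expect_lt(spectral_radius(m$dynamics), 1)
  expect_equal(m$dynamics * m$normalization, m$raw_adjacency)
})

test_that("normalized dynamics has spectral radius <= 1 for random inputs", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(2:12, 1)
    raw <- matrix(sample(c(-1, 0, 1), n * n, TRUE, c(0.2, 0.6, 0.2)), n)
    genes <- sprintf("g%02d", seq_len(n))
    dimnames(raw) <- list(genes, genes)
    m <- normalize_dynamics(structure(
      list(genes = genes, raw_adjacency = raw, dynamics = NULL,
           normalization = NA_real_, layout = "incoming"),
      class = "system_model"))
    expect_lte(spectral_radius(m$dynamics), 1 + 1e-9)
    if (m$normalization > 0)
      expect_equal(m$dynamics * m$normalization, raw, tolerance = 1e-12)
  }
})

test_that("model round-trips through its on-disk directory format", {
  model <- build_model(interactions_df(
    c("TP53", "EGFR", "BRCA1"), c("EGFR", "BRCA1", "TP53"),
    c("activation", "inhibition", "activation")))
  dir <- withr::local_tempdir()
  write_model(model, dir)
  back <- read_model(dir)
  expect_identical(back$genes, model$genes)
  expect_equal(back$raw_adjacency, model$raw_adjacency)
  expect_equal(back$dynamics, model$dynamics)
  expect_equal(back$normalization, model$normalization)
  expect_identical(back$layout, model$layout)
})
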