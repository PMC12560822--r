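test_that("zero branch lengths copy the root draw to every leaf", {
  tr <- fixture_tree()
  tr$edge.length[] <- 0
  model <- build_model(jtt_exchangeabilities()$freq)
  set.seed(3)
  sim <- simulate_gene(tr, model, 30)
  m <- unclass(sim$alignment)
  for (i in 2:nrow(m)) expect_equal(unname(m[i, ]), unname(m[1, ]))
  expect_equal(unname(m[1, ]), unname(sim$truth[ape::Ntip(tr) + 1L, ]))
})

test_that("simulated leaf residue frequencies match the model equilibrium", {
  tr <- parse_tree("(A:0.2,B:0.1);")
  model <- build_model(jtt_exchangeabilities()$freq)
  set.seed(12)
  sim <- simulate_gene(tr, model, 10000)
  obs <- table(factor(unclass(sim$alignment)["A", ], levels = AA))
  n <- sum(obs)
  for (a in AA) {
    p <- model$freq[a]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(obs[a] / n - p), 3 * se + 1e-9)
  }
})

test_that("single-branch transition frequencies match P(t) rows", {
  # one long branch, conditioning on the root state
  tr <- parse_tree("(A:0.3,B:0.0);")  # B pins the root draw (t = 0)
  model <- build_model(jtt_exchangeabilities()$freq)
  set.seed(21)
  sim <- simulate_gene(tr, model, 20000)
  m <- unclass(sim$alignment)
  P <- transition_probabilities(model, 0.3)
  x <- "L"   # common residue: enough conditioning draws
  idx <- m["B", ] == x
  n <- sum(idx)
  obs <- table(factor(m["A", idx], levels = AA)) / n
  for (a in c("L", "I", "V", "S")) {
    se <- sqrt(P[x, a] * (1 - P[x, a]) / n)
    expect_lt(abs(obs[a] - P[x, a]), 3 * se + 1e-9)
  }
})

test_that("simulation is deterministic under a fixed seed", {
  tr <- fixture_tree()
  model <- build_model(jtt_exchangeabilities()$freq)
  set.seed(99); s1 <- simulate_gene(tr, model, 40)
  set.seed(99); s2 <- simulate_gene(tr, model, 40)
  expect_identical(unclass(s1$alignment), unclass(s2$alignment))
  expect_identical(s1$truth, s2$truth)
})

test_that("injection touches only foreground leaves at chosen sites", {
  tr <- fixture_tree()
  fg <- resolve_foreground(tr, fixture_foreground())
  model <- build_model(jtt_exchangeabilities()$freq)
  set.seed(31)
  sim <- simulate_gene(tr, model, 100)
  inj <- inject_convergence(sim, tr, fg, sites = c(7, 50))
  m0 <- unclass(sim$alignment)
  m1 <- unclass(inj$alignment)
  fg_leaves <- tr$tip.label[unlist(lapply(fg, convsites:::descendant_tips,
                                          tree = tr))]
  bg_leaves <- setdiff(rownames(m0), fg_leaves)
  expect_identical(m1[bg_leaves, ], m0[bg_leaves, ])
  expect_identical(m1[, -c(7, 50)], m0[, -c(7, 50)])
  expect_equal(nrow(inj$manifest), 2L)
  parent <- convsites:::tree_parent(tr)
  for (j in 1:2) {
    s <- inj$manifest$site[j]
    der <- inj$manifest$derived_state[j]
    expect_true(all(m1[fg_leaves, s] == der))
    # derived differs from every true foreground parent state
    expect_false(der %in% sim$truth[parent[fg], s])
  }
})

test_that("fixed derived residues are validated against parent states", {
  tr <- fixture_tree()
  fg <- resolve_foreground(tr, fixture_foreground())
  model <- build_model(jtt_exchangeabilities()$freq)
  set.seed(41)
  sim <- simulate_gene(tr, model, 20)
  parent <- convsites:::tree_parent(tr)
  clash <- sim$truth[parent[fg[1]], 5]
  expect_error(inject_convergence(sim, tr, fg, sites = 5, derived = clash),
               "equals a foreground parent")
  expect_error(inject_convergence(sim, tr, fg, sites = 25), "out of range")
})

test_that("end-to-end: an injected site is recovered on one gene", {
  tr <- fixture_tree()
  fg <- resolve_foreground(tr, fixture_foreground())
  model <- build_model(jtt_exchangeabilities()$freq)
  set.seed(55)
  sim <- simulate_gene(tr, model, 300)
  sim <- inject_convergence(sim, tr, fg, sites = 123)
  rec <- marginal_posteriors(sim$alignment, tr, model)
  calls <- enumerate_substitutions(rec, sim$alignment, tr, fg)
  cs <- call_convergent_sites(calls, rec, sim$alignment, tr, fg)
  expect_true(123L %in% cs$site)
})

test_that("manifests round-trip through TSV", {
  tr <- fixture_tree()
  fg <- resolve_foreground(tr, fixture_foreground())
  model <- build_model(jtt_exchangeabilities()$freq)
  set.seed(66)
  sim <- simulate_gene(tr, model, 50)
  inj <- inject_convergence(sim, tr, fg, sites = c(2, 30))
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(inj$manifest, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  back <- utils::read.delim(f, colClasses = c("character", "integer",
                                              "character", "character"))
  expect_equal(back, inj$manifest)
})

test_that("benchmark directories are reproducible and protected", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- simulation_config(n_genes = 4, sites_per_gene = 40,
                           n_injected_genes = 1, seed = 7)
  make_benchmark(cfg, d1, force = TRUE)
  make_benchmark(cfg, d2, force = TRUE)
  files <- c(file.path("alignments", sprintf("gene%04d.fasta", 1:4)),
             "tree.nwk", "manifest.tsv", "config.json")
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  expect_error(make_benchmark(cfg, d1), "not empty")

  # no injection -> empty manifest (header only)
  d3 <- withr::local_tempdir()
  cfg0 <- simulation_config(n_genes = 2, sites_per_gene = 20,
                            n_injected_genes = 0, seed = 5)
  make_benchmark(cfg0, d3, force = TRUE)
  man <- utils::read.delim(file.path(d3, "manifest.tsv"))
  expect_equal(nrow(man), 0L)
})

test_that("simulation config validates its invariants", {
  expect_error(simulation_config(n_genes = 2, n_injected_genes = 3, seed = 1),
               "exceeds")
  expect_error(simulation_config(sites_per_gene = 0, seed = 1), ">= 1")
  expect_error(simulation_config(n_genes = 2), "seed")
})
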