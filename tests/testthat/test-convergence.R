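# Small deterministic setting used across several blocks: the fixture tree
# with states planted directly on the leaves so reconstruction is sharp.
planted_case <- function(derived = "S", background = "A", n_pad = 40) {
  tr <- fixture_tree()
  fg <- resolve_foreground(tr, fixture_foreground())
  base <- setNames(rep(background, 9), tr$tip.label)
  pad <- vapply(seq_len(9), function(i) paste(rep("G", n_pad), collapse = ""),
                "")
  site <- base
  site[c("FG_A1", "FG_A2")] <- derived
  site[c("FG_B", "FG_C")] <- derived
  seqs <- paste0(site, pad)[match(tr$tip.label, names(base))]
  aln <- aa_alignment(setNames(seqs, tr$tip.label), gene_id = "planted")
  list(tree = tr, fg = fg, aln = aln)
}

test_that("substitutions on foreground branches are enumerated correctly", {
  pc <- planted_case()
  model <- build_model(estimate_f_gene(pc$aln))
  rec <- marginal_posteriors(pc$aln, pc$tree, model)
  calls <- enumerate_substitutions(rec, pc$aln, pc$tree, pc$fg)
  s1 <- calls[calls$site == 1, ]
  expect_equal(nrow(s1), 3L)
  expect_setequal(s1$branch, pc$fg)
  expect_true(all(s1$child_state == "S"))
  expect_true(all(s1$parent_state != "S"))
  # leaf children carry posterior exactly 1
  ntip <- ape::Ntip(pc$tree)
  expect_true(all(s1$child_posterior[s1$branch <= ntip] == 1))
  # no call where parent equals child: padding sites are all G
  expect_false(any(calls$site > 1))
})

test_that("gap and unknown children suppress calls at that branch/site", {
  pc <- planted_case()
  m <- unclass(pc$aln)
  m["FG_B", 1] <- "-"
  aln <- aa_alignment(m, gene_id = "gapped")
  model <- build_model(estimate_f_gene(aln))
  rec <- marginal_posteriors(aln, pc$tree, model)
  calls <- enumerate_substitutions(rec, aln, pc$tree, pc$fg)
  fgb <- match("FG_B", pc$tree$tip.label)
  expect_false(any(calls$site == 1 & calls$branch == fgb))
})

test_that("convergent sites classify as parallel/mixed and respect leaf identity", {
  # all ancestral contexts equal -> parallel
  pc <- planted_case()
  model <- build_model(estimate_f_gene(pc$aln))
  rec <- marginal_posteriors(pc$aln, pc$tree, model)
  calls <- enumerate_substitutions(rec, pc$aln, pc$tree, pc$fg)
  cs <- call_convergent_sites(calls, rec, pc$aln, pc$tree, pc$fg)
  expect_equal(nrow(cs), 1L)
  expect_equal(cs$site, 1L)
  expect_equal(cs$derived_state, "S")
  expect_equal(cs$class, "parallel")
  expect_equal(cs$n_branches_substituting, 3L)

  # a foreground leaf deviating from the derived residue disqualifies the site
  m <- unclass(pc$aln)
  m["FG_A2", 1] <- "T"
  aln2 <- aa_alignment(m)
  model2 <- build_model(estimate_f_gene(aln2))
  rec2 <- marginal_posteriors(aln2, pc$tree, model2)
  calls2 <- enumerate_substitutions(rec2, aln2, pc$tree, pc$fg)
  cs2 <- call_convergent_sites(calls2, rec2, aln2, pc$tree, pc$fg)
  expect_false(1L %in% cs2$site)

  expect_error(call_convergent_sites(calls, rec, pc$aln, pc$tree,
                                     pc$fg[1]), "at least 2")
})

test_that("mixed ancestral contexts converging on one residue are labelled", {
  # two branches in an A context, the third in an E context -> mixed
  pc <- planted_case()
  m <- unclass(pc$aln)
  # plant E context around FG_C: its sister and local background
  m[c("BG4"), 1] <- "E"
  aln <- aa_alignment(m)
  model <- build_model(estimate_f_gene(aln))
  rec <- marginal_posteriors(aln, pc$tree, model)
  calls <- enumerate_substitutions(rec, aln, pc$tree, pc$fg)
  cs <- call_convergent_sites(calls, rec, aln, pc$tree, pc$fg)
  if (nrow(cs) == 1L && cs$class == "mixed") {
    expect_match(cs$ancestral_states, "E")
    expect_match(cs$label, "^A1S,E1S$|^E1S,A1S$")
  }
  # the derived state is shared in every qualifying pattern
  expect_true(all(cs$derived_state == "S"))
})

test_that("site calls agree with a brute-force scan on simulated genes", {
  tr <- fixture_tree()
  fg <- resolve_foreground(tr, fixture_foreground())
  set.seed(61)
  for (rep in 1:3) {
    model <- build_model(random_freq(60 + rep))
    sim <- simulate_gene(tr, model, 200)
    sim <- inject_convergence(sim, tr, fg, sites = c(10, 110))
    rec <- marginal_posteriors(sim$alignment, tr, model)
    calls <- enumerate_substitutions(rec, sim$alignment, tr, fg)
    cs <- call_convergent_sites(calls, rec, sim$alignment, tr, fg)
    oracle <- oracle_convergent_scan(rec, sim$alignment, tr, fg)
    expect_equal(cs$site, oracle$site)
    expect_equal(cs$derived_state, oracle$derived)
    expect_equal(cs$class, oracle$class)
  }
})

test_that("expected convergent count follows the analytic per-site formula", {
  pc <- planted_case()
  model <- build_model(estimate_f_gene(pc$aln))
  rec <- marginal_posteriors(pc$aln, pc$tree, model)

  # zero-length foreground branches make substitution impossible
  tr0 <- pc$tree
  tr0$edge.length[] <- 0
  rec0 <- marginal_posteriors(pc$aln, tr0, model)
  lam0 <- expected_convergent_count(rec0, pc$aln, tr0, model, pc$fg)
  expect_equal(as.numeric(lam0), 0, tolerance = 1e-12)

  # hand formula at one site for concentrated parent posteriors
  lam <- expected_convergent_count(rec, pc$aln, pc$tree, model, pc$fg)
  per_site <- attr(lam, "per_site")
  parent <- convsites:::tree_parent(pc$tree)
  hand <- 1
  ms <- list()
  for (b in pc$fg) {
    post <- rec$posterior[[parent[b]]][, 1]
    P <- transition_probabilities(model, rec$blen[b])
    ms[[length(ms) + 1]] <- colSums(post * P) - post * diag(P)
  }
  expect_equal(per_site[1], sum(ms[[1]] * ms[[2]] * ms[[3]]),
               tolerance = 1e-12)
  expect_equal(as.numeric(lam), sum(per_site), tolerance = 1e-12)
})

test_that("analytic per-site convergence probability matches simulation", {
  pc <- planted_case()
  model <- build_model(estimate_f_gene(pc$aln))
  rec <- marginal_posteriors(pc$aln, pc$tree, model)
  lam <- expected_convergent_count(rec, pc$aln, pc$tree, model, pc$fg)
  p_site <- attr(lam, "per_site")[1]
  parent <- convsites:::tree_parent(pc$tree)
  set.seed(505)
  n_rep <- 10000
  hits <- 0L
  Ps <- lapply(pc$fg, function(b)
    transition_probabilities(model, rec$blen[b]))
  posts <- lapply(pc$fg, function(b) rec$posterior[[parent[b]]][, 1])
  for (r in seq_len(n_rep)) {
    anc <- vapply(posts, function(p) sample.int(20, 1, prob = p), 1L)
    der <- vapply(seq_along(anc), function(i)
      sample.int(20, 1, prob = Ps[[i]][anc[i], ]), 1L)
    if (length(unique(der)) == 1L && all(der != anc)) hits <- hits + 1L
  }
  se <- sqrt(p_site * (1 - p_site) / n_rep)
  expect_lt(abs(hits / n_rep - p_site), 3 * se + 1e-12)
})

test_that("lambda is additive over sites and invariant to row order", {
  tr <- fixture_tree()
  fg <- resolve_foreground(tr, fixture_foreground())
  set.seed(77)
  model <- build_model(random_freq(77))
  sim <- simulate_gene(tr, model, 60)
  rec <- marginal_posteriors(sim$alignment, tr, model)
  lam <- expected_convergent_count(rec, sim$alignment, tr, model, fg)
  expect_equal(as.numeric(lam), sum(attr(lam, "per_site")), tolerance = 1e-12)
  m <- unclass(sim$alignment)
  rec2 <- marginal_posteriors(aa_alignment(m[sample(nrow(m)), ]), tr, model)
  lam2 <- expected_convergent_count(rec2, sim$alignment, tr, model, fg)
  expect_equal(as.numeric(lam), as.numeric(lam2), tolerance = 1e-10)
})

test_that("Poisson exceedance matches closed forms and limits", {
  expect_equal(poisson_test(0, 0.5), 1)
  expect_equal(poisson_test(2, 0.1), 1 - exp(-0.1) * 1.1, tolerance = 1e-12)
  expect_warning(p0 <- poisson_test(3, 0), "degenerate")
  expect_equal(p0, 0)
  lams <- 10^seq(-1, -6)
  ps <- vapply(lams, function(l) poisson_test(1, l), 0)
  expect_true(all(diff(ps) < 0))
  expect_lt(ps[length(ps)], 1e-5)
  expect_error(poisson_test(-1, 1), "nonnegative")
  expect_error(poisson_test(1, -1), ">= 0")
})

test_that("BH adjustment reproduces the step-up arithmetic", {
  p <- c(0.001, 0.02, 0.04, 0.5)
  # direct step-up, written out
  expect_equal(bh_adjust(p), c(0.004, 0.04, 0.04 * 4 / 3, 0.5),
               tolerance = 1e-14)
  expect_equal(bh_adjust(rep(0.03, 5)), rep(0.03, 5))
  set.seed(8)
  x <- runif(30)
  q <- bh_adjust(x)
  expect_true(all(diff(q[order(x)]) >= -1e-15))
  expect_true(all(q >= x))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("scan_genes ranks injected genes first and handles edge cases", {
  cfg <- simulation_config(n_genes = 30, sites_per_gene = 150,
                           n_injected_genes = 2, seed = 19)
  bench <- simulate_benchmark(cfg)
  res <- scan_genes(bench$alignments, bench$tree, bench$foreground)
  inj <- unique(bench$manifest$gene_id)
  expect_setequal(res$gene_id[seq_along(inj)], inj)
  expect_true(all(res$q[res$gene_id %in% inj] <
                    min(res$q[!res$gene_id %in% inj])))
  # reported sites include the injected ones
  st <- attr(res, "site_table")
  for (g in inj)
    expect_true(all(bench$manifest$site[bench$manifest$gene_id == g] %in%
                      st$site[st$gene_id == g]))

  # empty collection
  empty <- scan_genes(list(), bench$tree, bench$foreground)
  expect_equal(nrow(empty), 0L)

  # gene not covering the tree is skipped with a warning
  short <- aa_alignment(c(FG_A1 = "MST"), gene_id = "bad")
  expect_warning(one <- scan_genes(list(short, bench$alignments[[3]]),
                                   bench$tree, bench$foreground),
                 "skipped")
  expect_equal(nrow(one), 1L)
  expect_equal(attr(one, "summary")$n_genes_skipped, 1L)
})

test_that("pairwise mode counts sites shared by any branch pair once", {
  pc <- planted_case()
  m <- unclass(pc$aln)
  # remove the derived residue from FG_C so only the cherry+FG_B pair holds
  m["FG_C", 1] <- "A"
  aln <- aa_alignment(m)
  model <- build_model(estimate_f_gene(aln))
  rec <- marginal_posteriors(aln, pc$tree, model)
  calls <- enumerate_substitutions(rec, aln, pc$tree, pc$fg)
  cs_all <- call_convergent_sites(calls, rec, aln, pc$tree, pc$fg,
                                  mode = "all_foreground")
  cs_pw <- call_convergent_sites(calls, rec, aln, pc$tree, pc$fg,
                                 mode = "pairwise")
  expect_false(1L %in% cs_all$site)
  expect_true(1L %in% cs_pw$site)
  expect_equal(sum(cs_pw$site == 1L), 1L)
  expect_equal(cs_pw$n_branches_substituting[cs_pw$site == 1L], 2L)
})
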