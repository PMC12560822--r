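#' Default benchmark tree: two clades plus an outgroup
#'
#' A fixed 9-leaf rooted tree emulating the layout of a two-class species
#' set with an outgroup: one clade holding a cherry of two related
#' foreground taxa (`FG_A1`, `FG_A2`) beside two background taxa, a second
#' clade holding the two independent terminal foreground taxa (`FG_B`,
#' `FG_C`) each paired with a background taxon, and the outgroup `OUT`.
#' Branch lengths sit in 0.05-0.3 expected substitutions per site, with
#' the foreground branches at the long end (fast-evolving stress lineages
#' accumulate substitutions) and background and internal branches at the
#' short end, which keeps ancestral reconstruction informative: a residue
#' shared by the foreground lineages is explained far more cheaply by
#' independent gains on the longer foreground branches than by a deep
#' origin followed by reversals on several short background branches.
#' Keeping the foreground branches moderate (0.15 rather than the top of
#' the range) also keeps the null expectation of convergent sites per gene
#' small, so genuine repeated substitutions stand out against it.
#'
#' @return A rooted `phylo` with 9 tips.
#' @export
fixture_tree <- function() {
  parse_tree(paste0(
    "((((FG_A1:0.15,FG_A2:0.15):0.08,(BG1:0.05,BG2:0.05):0.05):0.05,",
    "((FG_B:0.15,BG3:0.05):0.05,(FG_C:0.15,BG4:0.05):0.05):0.05):0.05,",
    "OUT:0.1);"))
}

#' Default foreground designators for [fixture_tree()]
#'
#' Three independent targets: the branch above the MRCA of the `FG_A1` /
#' `FG_A2` cherry and the terminal branches of `FG_B` and `FG_C`.
#'
#' @return List of taxon-label designators for [resolve_foreground()].
#' @export
fixture_foreground <- function() {
  list(c("FG_A1", "FG_A2"), "FG_B", "FG_C")
}

#' Simulate one gene's alignment on a tree
#'
#' Draws the root state from the model's equilibrium frequencies and
#' propagates it down every branch with the model's transition matrices;
#' leaf rows are assembled into an alignment and the full internal-node
#' history is retained for truth-aware tests. Uses the session RNG: set a
#' seed upstream for reproducibility.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param model A [build_model()] object.
#' @param n_sites Number of independent sites.
#' @param gene_id Identifier for the resulting alignment.
#' @return List with `alignment` (an [aa_alignment()]) and `truth`
#'   (character matrix, all nodes x sites, of true states; rows named by
#'   node ID).
#' @export
simulate_gene <- function(tree, model, n_sites, gene_id = "gene") {
  stopifnot(inherits(tree, "phylo"), inherits(model, "subst_model"),
            n_sites >= 1)
  ntip <- ape::Ntip(tree)
  n_nodes <- ntip + tree$Nnode
  root <- ntip + 1L
  states <- matrix(NA_integer_, n_nodes, n_sites)
  states[root, ] <- sample.int(20L, n_sites, replace = TRUE,
                               prob = model$freq)
  edge <- ape::reorder.phylo(tree, "cladewise")$edge
  elen <- ape::reorder.phylo(tree, "cladewise")$edge.length
  for (e in seq_len(nrow(edge))) {
    u <- edge[e, 1]; v <- edge[e, 2]
    P <- transition_probabilities(model, elen[e])
    ps <- states[u, ]
    cs <- integer(n_sites)
    for (x in unique(ps)) {
      idx <- which(ps == x)
      cs[idx] <- sample.int(20L, length(idx), replace = TRUE, prob = P[x, ])
    }
    states[v, ] <- cs
  }
  truth <- matrix(AA20[states], n_nodes, n_sites,
                  dimnames = list(seq_len(n_nodes), NULL))
  m <- truth[seq_len(ntip), , drop = FALSE]
  rownames(m) <- tree$tip.label
  list(alignment = aa_alignment(m, gene_id = gene_id), truth = truth)
}

#' Inject convergent substitutions into a simulated gene
#'
#' At each chosen site a derived residue is planted on every foreground
#' branch: the leaves of each foreground subtree (and the foreground child
#' node's truth row) are set to the derived residue, which is required to
#' differ from the true state of every foreground branch's parent, so each
#' branch carries a genuine substitution. Non-foreground leaves and
#' non-chosen sites are untouched. Uses the session RNG when drawing random
#' derived residues.
#'
#' @param sim Result of [simulate_gene()].
#' @param tree The tree the gene was simulated on.
#' @param foreground Integer foreground node IDs.
#' @param sites Integer vector of 1-based alignment columns to inject at.
#' @param derived Either `"random"` (draw a residue differing from every
#'   foreground parent's true state, weighted by the JTT reference
#'   frequencies so that planted convergence lands on common residues, as
#'   observed convergent substitutions do) or a fixed single residue, which
#'   is rejected if it matches any foreground parent's true state.
#' @return List with the modified `alignment` and `truth` plus `manifest`,
#'   a data frame of (gene_id, site, derived_state, ancestral_states).
#' @export
inject_convergence <- function(sim, tree, foreground, sites,
                               derived = "random") {
  fg <- foreground_nodes(tree, foreground)
  parent <- tree_parent(tree)
  aln <- unclass(sim$alignment)
  truth <- sim$truth
  n_sites <- ncol(aln)
  if (any(sites < 1 | sites > n_sites))
    stop("injection site out of range 1..", n_sites)
  fg_tips <- lapply(fg, descendant_tips, tree = tree)
  manifest <- vector("list", length(sites))
  for (j in seq_along(sites)) {
    s <- sites[j]
    parents <- truth[parent[fg], s]
    candidates <- setdiff(AA20, parents)
    if (length(candidates) == 0L)
      stop("no residue differs from all foreground parent states at site ", s)
    der <- if (identical(derived, "random")) {
      w <- jtt_exchangeabilities()$freq[candidates]
      candidates[sample.int(length(candidates), 1L, prob = w)]
    } else {
      if (!derived %in% AA20) stop("invalid derived residue: ", derived)
      if (derived %in% parents)
        stop("derived residue '", derived, "' equals a foreground parent ",
             "state at site ", s)
      derived
    }
    for (i in seq_along(fg)) {
      tips <- fg_tips[[i]]
      aln[tree$tip.label[tips], s] <- der
      truth[c(fg[i], tips), s] <- der
    }
    manifest[[j]] <- data.frame(
      gene_id = attr(sim$alignment, "gene_id"), site = s,
      derived_state = der,
      ancestral_states = paste(parents, collapse = ","))
  }
  list(alignment = aa_alignment(aln, gene_id = attr(sim$alignment, "gene_id")),
       truth = truth, manifest = do.call(rbind, manifest))
}

#' Simulation configuration for a synthetic ortholog benchmark
#'
#' @param tree Rooted `phylo`; defaults to [fixture_tree()].
#' @param foreground Foreground designators (taxon-label lists) resolved on
#'   `tree`; defaults to [fixture_foreground()] when using the default tree.
#' @param n_genes Number of genes to simulate.
#' @param sites_per_gene Sites per gene (single value or range `c(lo, hi)`
#'   sampled uniformly per gene).
#' @param f_gene_source One of `"dirichlet"` (per-gene frequencies drawn
#'   from Dirichlet(`dirichlet_alpha`), default), `"uniform"` (all 1/20), or
#'   a fixed 20-vector.
#' @param dirichlet_alpha Dirichlet concentration vector; default `50 *`
#'   the JTT reference frequencies (moderate among-gene compositional
#'   variation around realistic protein composition).
#' @param n_injected_genes Number of genes receiving injected convergence.
#' @param sites_per_injected_gene Number of injected sites in each such gene.
#' @param derived `"random"` or a fixed residue (see [inject_convergence()]).
#' @param seed Mandatory integer seed.
#' @return A `sim_config` list, validated.
#' @export
simulation_config <- function(tree = fixture_tree(),
                              foreground = fixture_foreground(),
                              n_genes = 200, sites_per_gene = 300,
                              f_gene_source = "dirichlet",
                              dirichlet_alpha = NULL,
                              n_injected_genes = 0,
                              sites_per_injected_gene = 3,
                              derived = "random", seed) {
  if (missing(seed) || !is.finite(seed)) stop("seed is mandatory")
  if (n_injected_genes > n_genes)
    stop("n_injected_genes exceeds n_genes")
  if (any(sites_per_gene < 1)) stop("sites_per_gene must be >= 1")
  if (is.null(dirichlet_alpha))
    dirichlet_alpha <- 50 * jtt_exchangeabilities()$freq
  structure(list(tree = tree,
                 foreground = resolve_foreground(tree, foreground),
                 foreground_specs = foreground,
                 n_genes = as.integer(n_genes),
                 sites_per_gene = as.integer(sites_per_gene),
                 f_gene_source = f_gene_source,
                 dirichlet_alpha = dirichlet_alpha,
                 n_injected_genes = as.integer(n_injected_genes),
                 sites_per_injected_gene = as.integer(sites_per_injected_gene),
                 derived = derived, seed = as.integer(seed)),
            class = "sim_config")
}

draw_frequencies <- function(config) {
  src <- config$f_gene_source
  if (is.numeric(src)) return(src / sum(src))
  if (identical(src, "uniform")) return(rep(1 / 20, 20))
  if (identical(src, "dirichlet")) {
    g <- stats::rgamma(20L, shape = config$dirichlet_alpha)
    return(g / sum(g))
  }
  stop("unknown f_gene_source")
}

#' Simulate a full benchmark in memory
#'
#' Runs the generator for every gene of a [simulation_config()]: per-gene
#' frequencies, simulation under the gene's model, and convergence
#' injection into the first `n_injected_genes` genes. Deterministic given
#' the config's seed.
#'
#' @param config A [simulation_config()].
#' @return List with `alignments` (list of [aa_alignment()]), `truths`,
#'   `manifest` (data frame, empty when nothing injected), `tree`,
#'   `foreground`, `config`.
#' @export
simulate_benchmark <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tree <- config$tree
  fg <- config$foreground
  alignments <- vector("list", config$n_genes)
  truths <- vector("list", config$n_genes)
  manifests <- list()
  for (g in seq_len(config$n_genes)) {
    n_sites <- if (length(config$sites_per_gene) > 1L) {
      sample(seq(config$sites_per_gene[1], config$sites_per_gene[2]), 1L)
    } else config$sites_per_gene
    gid <- sprintf("gene%04d", g)
    model <- build_model(draw_frequencies(config))
    sim <- simulate_gene(tree, model, n_sites, gene_id = gid)
    if (g <= config$n_injected_genes) {
      inj_sites <- sort(sample.int(n_sites, config$sites_per_injected_gene))
      sim <- inject_convergence(sim, tree, fg, inj_sites,
                                derived = config$derived)
      manifests[[length(manifests) + 1L]] <- sim$manifest
    }
    alignments[[g]] <- sim$alignment
    truths[[g]] <- sim$truth
  }
  manifest <- do.call(rbind, manifests)
  if (is.null(manifest))
    manifest <- data.frame(gene_id = character(0), site = integer(0),
                           derived_state = character(0),
                           ancestral_states = character(0))
  list(alignments = alignments, truths = truths, manifest = manifest,
       tree = tree, foreground = fg, config = config)
}

#' Write a benchmark directory
#'
#' Materialises [simulate_benchmark()] as files: one FASTA per gene under
#' `alignments/`, the tree as `tree.nwk`, the injection manifest as
#' `manifest.tsv`, and a JSON echo of the configuration as `config.json`.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory.
#' @param force Overwrite an existing non-empty directory.
#' @return `out_dir`, invisibly; the simulated benchmark as attribute
#'   `benchmark`.
#' @export
make_benchmark <- function(config, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir, all.files = FALSE)) && !force)
    stop("output directory ", out_dir, " is not empty; use force = TRUE")
  bench <- simulate_benchmark(config)
  dir.create(file.path(out_dir, "alignments"), recursive = TRUE,
             showWarnings = FALSE)
  for (aln in bench$alignments)
    write_alignment(aln, file.path(out_dir, "alignments",
                                   paste0(attr(aln, "gene_id"), ".fasta")))
  write_tree(bench$tree, file.path(out_dir, "tree.nwk"))
  utils::write.table(bench$manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- bench$config
  echo <- list(n_genes = cfg$n_genes, sites_per_gene = cfg$sites_per_gene,
               f_gene_source = if (is.numeric(cfg$f_gene_source)) "fixed"
                               else cfg$f_gene_source,
               dirichlet_alpha = unname(cfg$dirichlet_alpha),
               n_injected_genes = cfg$n_injected_genes,
               sites_per_injected_gene = cfg$sites_per_injected_gene,
               derived = cfg$derived, seed = cfg$seed,
               foreground = lapply(cfg$foreground_specs, as.character),
               newick = ape::write.tree(cfg$tree))
  jsonlite::write_json(echo, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(structure(out_dir, benchmark = bench))
}
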