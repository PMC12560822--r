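#' Enumerate substitutions on foreground branches
#'
#' For every designated foreground branch (child node `c` with parent `u`)
#' and every alignment site, a substitution is called when both endpoint
#' states are non-missing and differ. The child state is the observed leaf
#' residue when `c` is a tip (posterior 1), otherwise the assigned marginal
#' state at `c`; the parent state is always the assigned state at `u`.
#'
#' @param rec An [marginal_posteriors()] reconstruction.
#' @param aln The [aa_alignment()] the reconstruction was computed from.
#' @param tree The rooted `phylo` used for the reconstruction.
#' @param foreground Integer node IDs of the foreground branches; defaults
#'   to `attr(tree, "foreground")` (see [set_foreground()]).
#' @return Data frame with columns `gene_id`, `site` (1-based alignment
#'   column), `branch` (child node ID), `parent_state`, `child_state`,
#'   `parent_posterior`, `child_posterior`.
#' @export
enumerate_substitutions <- function(rec, aln, tree, foreground = NULL) {
  fg <- foreground_nodes(tree, foreground)
  parent <- tree_parent(tree)
  ntip <- rec$ntip
  out <- vector("list", length(fg))
  for (i in seq_along(fg)) {
    child <- fg[i]
    u <- parent[child]
    if (u == 0L) stop("foreground node ", child, " has no parent branch")
    pstate <- rec$state[as.character(u), ]
    ppost <- rec$state_posterior[as.character(u), ]
    pmiss <- rec$missing[u, ]
    if (child <= ntip) {
      cstate <- unclass(aln)[tree$tip.label[child], ]
      cpost <- rep(1, rec$n_sites)
      cmiss <- is_missing_symbol(cstate)
    } else {
      cstate <- rec$state[as.character(child), ]
      cpost <- rec$state_posterior[as.character(child), ]
      cmiss <- rec$missing[child, ]
    }
    keep <- !pmiss & !cmiss & pstate != cstate
    if (!any(keep)) next
    out[[i]] <- data.frame(
      gene_id = rec$gene_id, site = which(keep), branch = child,
      parent_state = pstate[keep], child_state = cstate[keep],
      parent_posterior = ppost[keep], child_posterior = cpost[keep],
      row.names = NULL)
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), site = integer(0),
                      branch = integer(0), parent_state = character(0),
                      child_state = character(0),
                      parent_posterior = numeric(0),
                      child_posterior = numeric(0))
  out[order(out$site, out$branch), , drop = FALSE]
}

# leaves descending from (and including) a node
descendant_tips <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, descendant_tips, tree = tree))
}

classify_pattern <- function(anc_states) {
  u <- unique(anc_states)
  if (length(u) == 1L) "parallel"
  else if (length(u) == length(anc_states)) "convergent"
  else "mixed"
}

#' Call convergent sites among foreground branches
#'
#' A site is convergent when independent foreground lineages substituted to
#' one identical derived residue. In mode `all_foreground` (the default) a
#' site qualifies if and only if every foreground branch carries a
#' substitution at that site, all derived states are identical, and every
#' extant foreground leaf descendant carries that residue (gaps fail the
#' identity requirement). Mode `pairwise` applies the same rules to each
#' pair of foreground branches and deduplicates sites for counting. Sites
#' are classified `parallel` (all ancestral states equal), `convergent`
#' (all distinct) or `mixed`.
#'
#' @param calls Data frame from [enumerate_substitutions()].
#' @inheritParams enumerate_substitutions
#' @param mode `"all_foreground"` or `"pairwise"`.
#' @return Data frame with columns `gene_id`, `site`, `derived_state`,
#'   `ancestral_states` (comma-joined, branch order), `class`,
#'   `n_branches_substituting`, and `label` in the conventional
#'   `"<ANC><site><DER>"` notation (multiple ancestors comma-separated,
#'   e.g. `"A162S,E162S"`).
#' @export
call_convergent_sites <- function(calls, rec, aln, tree, foreground = NULL,
                                  mode = c("all_foreground", "pairwise")) {
  mode <- match.arg(mode)
  fg <- foreground_nodes(tree, foreground)
  if (length(fg) < 2L)
    stop("convergence needs at least 2 foreground branches; got ", length(fg))
  fg_tips <- lapply(fg, descendant_tips, tree = tree)
  empty <- data.frame(gene_id = character(0), site = integer(0),
                      derived_state = character(0),
                      ancestral_states = character(0), class = character(0),
                      n_branches_substituting = integer(0),
                      label = character(0))
  if (nrow(calls) == 0L) return(empty)

  qualifies <- function(site_calls, branches, tips) {
    # site_calls: calls at one site restricted to `branches`
    if (nrow(site_calls) != length(branches)) return(NULL)
    der <- unique(site_calls$child_state)
    if (length(der) != 1L) return(NULL)
    leaf_res <- unclass(aln)[tree$tip.label[tips], site_calls$site[1]]
    if (!all(leaf_res == der)) return(NULL)
    ord <- match(branches, site_calls$branch)
    anc <- site_calls$parent_state[ord]
    data.frame(gene_id = site_calls$gene_id[1], site = site_calls$site[1],
               derived_state = der,
               ancestral_states = paste(anc, collapse = ","),
               class = classify_pattern(anc),
               n_branches_substituting = length(branches),
               label = paste0(unique(anc), site_calls$site[1], der,
                              collapse = ","))
  }

  res <- list()
  if (mode == "all_foreground") {
    all_tips <- unlist(fg_tips)
    for (s in unique(calls$site)) {
      sc <- calls[calls$site == s & calls$branch %in% fg, , drop = FALSE]
      res[[length(res) + 1L]] <- qualifies(sc, fg, all_tips)
    }
  } else {
    pairs <- utils::combn(seq_along(fg), 2L, simplify = FALSE)
    seen <- character(0)
    for (s in unique(calls$site)) {
      for (pr in pairs) {
        b <- fg[pr]
        sc <- calls[calls$site == s & calls$branch %in% b, , drop = FALSE]
        hit <- qualifies(sc, b, unlist(fg_tips[pr]))
        if (!is.null(hit)) {
          key <- paste(hit$gene_id, hit$site, hit$derived_state)
          if (!(key %in% seen)) {
            seen <- c(seen, key)
            res[[length(res) + 1L]] <- hit
          }
        }
      }
    }
  }
  res <- do.call(rbind, res)
  if (is.null(res)) return(empty)
  res[order(res$site), , drop = FALSE]
}

#' Expected number of convergent sites under the null model
#'
#' Analytic expectation of the convergent-site count for one gene under the
#' fitted gene-specific substitution process, on the same reconstruction
#' used for the observed count. For each site `s` and foreground branch
#' `b = (u -> c)` of length `t_b`, the probability of substituting to
#' residue `a` is `m_b(a|s) = sum_{x != a} post_u(x|s) P[x,a](t_b)`, with
#' `post_u` the marginal posterior at the parent. The per-site convergence
#' probability is `sum_a prod_b m_b(a|s)` over all foreground branches
#' (mode `all_foreground`) or summed over branch pairs (mode `pairwise`);
#' `lambda_g` adds these over sites. Sites where any foreground parent is
#' entirely missing contribute 0.
#'
#' @inheritParams enumerate_substitutions
#' @param model The gene's [build_model()] object.
#' @param mode `"all_foreground"` or `"pairwise"`.
#' @return `lambda_g` (numeric scalar) with attribute `per_site`, the
#'   length-S vector of per-site convergence probabilities.
#' @export
expected_convergent_count <- function(rec, aln, tree, model,
                                      foreground = NULL,
                                      mode = c("all_foreground", "pairwise")) {
  mode <- match.arg(mode)
  fg <- foreground_nodes(tree, foreground)
  parent <- tree_parent(tree)
  S <- rec$n_sites

  # m[[i]]: 20 x S matrix of substitute-to-a probabilities for branch i
  m <- vector("list", length(fg))
  any_parent_missing <- rep(FALSE, S)
  for (i in seq_along(fg)) {
    child <- fg[i]
    u <- parent[child]
    post <- rec$posterior[[u]]
    P <- transition_probabilities(model, rec$blen[child])
    m[[i]] <- crossprod(P, post) - post * diag(P)
    any_parent_missing <- any_parent_missing | rec$missing[u, ]
  }

  per_site <- if (mode == "all_foreground") {
    prod_m <- Reduce(`*`, m)
    colSums(prod_m)
  } else {
    pairs <- utils::combn(seq_along(m), 2L, simplify = FALSE)
    Reduce(`+`, lapply(pairs, function(pr) colSums(m[[pr[1]]] * m[[pr[2]]])))
  }
  per_site[any_parent_missing] <- 0
  lambda <- sum(per_site)
  attr(lambda, "per_site") <- per_site
  lambda
}

#' Poisson exceedance test
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Poisson(lambda)`: the chance
#' of observing at least the seen number of convergent sites if they arose
#' from the null substitution process alone. `k = 0` gives `p = 1`; a
#' degenerate null (`lambda = 0`) with `k > 0` gives `p = 0` with a warning.
#'
#' @param k Observed count (nonnegative integer).
#' @param lambda Expected count under the null (nonnegative).
#' @return The exceedance probability.
#' @export
#' @examples
#' poisson_test(2, 0.1)  # 1 - exp(-0.1) * 1.1
poisson_test <- function(k, lambda) {
  if (!is.finite(k) || k < 0 || k != round(k))
    stop("k must be a nonnegative integer")
  if (!is.finite(lambda) || lambda < 0) stop("lambda must be >= 0")
  if (k == 0) return(1)
  if (lambda == 0) {
    warning("degenerate null: lambda = 0 with observed count ", k)
    return(0)
  }
  stats::ppois(k - 1, lambda, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control: with `m` p-values sorted ascending,
#' `q_(i) = min_{j >= i} m p_(j) / j`, capped at 1 and returned in the input
#' order (delegates to [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  p <- as.numeric(p)
  if (length(p) && (anyNA(p) || any(p < 0) || any(p > 1)))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Scan a collection of genes for convergent substitutions
#'
#' Runs the full per-gene pipeline — gene-specific frequency estimation,
#' model construction, marginal ancestral reconstruction, foreground
#' substitution enumeration, convergent-site calling, analytic expected
#' count and Poisson exceedance test — then adjusts across genes with
#' Benjamini-Hochberg. Genes whose taxa do not cover the tree's tips are
#' skipped with a warning and counted in the run summary.
#'
#' @param alignments List of [aa_alignment()] objects (or a named list of
#'   FASTA paths, which are read on the fly).
#' @param tree Rooted `phylo`.
#' @param foreground Integer node IDs, or a list of taxon-label designators
#'   passed to [resolve_foreground()]; defaults to `attr(tree,
#'   "foreground")`.
#' @param mode `"all_foreground"` (default) or `"pairwise"`.
#' @param pseudocount Pseudocount for [estimate_f_gene()].
#' @return Data frame of per-gene results sorted by `q` then `p`: `gene_id`,
#'   `k` (observed convergent sites), `lambda`, `p`, `q`, `mode`, `sites`
#'   (semicolon-joined substitution labels). Attributes: `summary` (list
#'   with gene/skip tallies, total convergent sites and per-branch
#'   substitution events on qualifying sites) and `site_table` (row-level
#'   detail of every convergent site).
#' @export
scan_genes <- function(alignments, tree, foreground = NULL,
                       mode = c("all_foreground", "pairwise"),
                       pseudocount = 1) {
  mode <- match.arg(mode)
  if (is.list(foreground) || (is.character(foreground)))
    foreground <- resolve_foreground(tree, foreground)
  fg <- foreground_nodes(tree, foreground)

  rows <- list()
  site_tables <- list()
  skipped <- character(0)
  for (i in seq_along(alignments)) {
    aln <- alignments[[i]]
    if (!inherits(aln, "aa_alignment")) aln <- read_alignment(aln)
    gid <- attr(aln, "gene_id")
    if (length(setdiff(tree$tip.label, rownames(aln)))) {
      warning("gene '", gid, "' skipped: does not cover all tree taxa")
      skipped <- c(skipped, gid)
      next
    }
    f <- estimate_f_gene(aln, pseudocount = pseudocount)
    model <- build_model(f)
    rec <- marginal_posteriors(aln, tree, model)
    calls <- enumerate_substitutions(rec, aln, tree, fg)
    sites <- call_convergent_sites(calls, rec, aln, tree, fg, mode = mode)
    lambda <- expected_convergent_count(rec, aln, tree, model, fg, mode = mode)
    k <- nrow(sites)
    p <- poisson_test(k, as.numeric(lambda))
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = gid, k = k, lambda = as.numeric(lambda), p = p,
      mode = mode,
      sites = paste(sites$label, collapse = ";"),
      stringsAsFactors = FALSE)
    if (k > 0) site_tables[[length(site_tables) + 1L]] <- sites
  }
  res <- do.call(rbind, rows)
  if (is.null(res))
    res <- data.frame(gene_id = character(0), k = integer(0),
                      lambda = numeric(0), p = numeric(0),
                      mode = character(0), sites = character(0))
  res$q <- bh_adjust(res$p)
  res <- res[order(res$q, res$p, res$gene_id),
             c("gene_id", "k", "lambda", "p", "q", "mode", "sites")]
  rownames(res) <- NULL
  site_table <- do.call(rbind, site_tables)
  attr(res, "site_table") <- site_table
  attr(res, "summary") <- list(
    n_genes_scanned = nrow(res), n_genes_skipped = length(skipped),
    skipped = skipped, mode = mode,
    n_convergent_sites = sum(res$k),
    n_branch_substitution_events =
      if (is.null(site_table)) 0L else sum(site_table$n_branches_substituting),
    n_foreground_branches = length(fg))
  res
}
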