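# Internal: 20 x S indicator matrix for the observed residues of one taxon.
# Missing symbols (gap, X) give an all-ones column (no information).
leaf_partials <- function(residues) {
  S <- length(residues)
  L <- matrix(0, 20L, S)
  idx <- match(residues, AA20)
  obs <- !is.na(idx)
  L[cbind(idx[obs], which(obs))] <- 1
  L[, !obs] <- 1
  L
}

#' Conditional (partial) likelihoods by the pruning algorithm
#'
#' One post-order pass of Felsenstein's pruning algorithm over all alignment
#' sites at once. Leaf vectors are indicators of the observed residue
#' (all-ones for missing data); each internal node's vector is the product
#' over children `v` of `P(t_v) %*% L_v`. Columns are rescaled by their
#' maximum as the pass ascends and the log scalings accumulated per site, so
#' deep trees do not underflow.
#'
#' @param aln An [aa_alignment()] containing every tip of `tree`.
#' @param tree A rooted `phylo` with branch lengths.
#' @param model A [build_model()] object.
#' @return List with `partials` (per node, 20 x S scaled arrays), `log_scale`
#'   (per node, length-S accumulated log scalings of the subtree),
#'   `site_loglik` (length S), `P` (per node, transition matrix of the branch
#'   above), and bookkeeping (`order`, `children`, `missing` flags: TRUE
#'   where all descendant leaves of a node are missing at a site).
#' @export
conditional_likelihoods <- function(aln, tree, model) {
  stopifnot(inherits(aln, "aa_alignment"), inherits(tree, "phylo"),
            inherits(model, "subst_model"))
  absent <- setdiff(tree$tip.label, rownames(aln))
  if (length(absent))
    stop("taxon in tree absent from alignment '", attr(aln, "gene_id"),
         "': ", paste(absent, collapse = ", "))
  ntip <- ape::Ntip(tree)
  n_nodes <- ntip + tree$Nnode
  S <- ncol(aln)
  root <- ntip + 1L

  edge <- tree$edge
  children <- split(edge[, 2], factor(edge[, 1], levels = seq_len(n_nodes)))
  blen <- numeric(n_nodes)
  blen[edge[, 2]] <- tree$edge.length
  P <- vector("list", n_nodes)
  for (v in edge[, 2]) P[[v]] <- transition_probabilities(model, blen[v])

  # postorder sequence of internal nodes (children always precede parents)
  po <- unique(ape::reorder.phylo(tree, "postorder")$edge[, 1])

  partials <- vector("list", n_nodes)
  log_scale <- vector("list", n_nodes)
  missing <- matrix(FALSE, n_nodes, S)
  for (v in seq_len(ntip)) {
    res <- unclass(aln)[tree$tip.label[v], ]
    partials[[v]] <- leaf_partials(res)
    log_scale[[v]] <- numeric(S)
    missing[v, ] <- is_missing_symbol(res)
  }
  for (u in po) {
    kids <- children[[u]]
    L <- 1
    ls <- numeric(S)
    miss <- rep(TRUE, S)
    for (v in kids) {
      L <- L * (P[[v]] %*% partials[[v]])
      ls <- ls + log_scale[[v]]
      miss <- miss & missing[v, ]
    }
    cmax <- apply(L, 2L, max)
    cmax[cmax == 0] <- 1   # impossible column; keep zeros, loglik -> -Inf
    L <- sweep(L, 2L, cmax, "/")
    partials[[u]] <- L
    log_scale[[u]] <- ls + log(cmax)
    missing[u, ] <- miss
  }
  site_loglik <- log(colSums(model$freq * partials[[root]])) +
    log_scale[[root]]
  list(partials = partials, log_scale = log_scale,
       site_loglik = site_loglik, P = P, children = children,
       postorder = po, missing = missing, root = root, ntip = ntip,
       blen = blen)
}

#' Marginal ancestral state reconstruction
#'
#' Completes the reconstruction with a pre-order (outside) pass: for each
#' internal node the marginal posterior over the 20 states is proportional to
#' the product of the likelihood of the data below the node and the
#' likelihood of the data outside it, rooted with the model's equilibrium
#' frequencies. Each node and site gets an assigned state (the posterior
#' argmax, ties broken by lowest alphabet index) and a missing flag that
#' propagates from the leaves (TRUE when every descendant leaf is missing;
#' there the posterior falls back toward the prior).
#'
#' @inheritParams conditional_likelihoods
#' @param cond Optionally, the result of [conditional_likelihoods()] for the
#'   same inputs (recomputed if omitted).
#' @return An object of class `ancestral_recon`: list with `gene_id`,
#'   `posterior` (list over internal node IDs of 20 x S matrices),
#'   `state` (internal nodes x S character matrix of assigned states),
#'   `state_posterior` (matching matrix of posterior probabilities),
#'   `missing` (all-nodes x S logical), `site_loglik`, and the tree/model
#'   bookkeeping needed by the convergence scan.
#' @export
marginal_posteriors <- function(aln, tree, model, cond = NULL) {
  if (is.null(cond)) cond <- conditional_likelihoods(aln, tree, model)
  ntip <- cond$ntip
  root <- cond$root
  n_nodes <- ntip + tree$Nnode
  S <- ncol(aln)
  internal <- root:n_nodes

  outside <- vector("list", n_nodes)
  outside[[root]] <- matrix(model$freq, 20L, S)
  preorder <- rev(cond$postorder)
  for (u in preorder) {
    kids <- cond$children[[u]]
    M <- lapply(kids, function(v) cond$P[[v]] %*% cond$partials[[v]])
    names(M) <- as.character(kids)
    for (i in seq_along(kids)) {
      v <- kids[i]
      if (v <= ntip) next
      sib <- 1
      for (j in seq_along(kids)) if (j != i) sib <- sib * M[[j]]
      A <- outside[[u]] * sib
      A <- crossprod(cond$P[[v]], A)      # t(P) %*% A
      cmax <- apply(A, 2L, max)
      cmax[cmax == 0] <- 1
      outside[[v]] <- sweep(A, 2L, cmax, "/")
    }
  }

  posterior <- vector("list", n_nodes)
  state <- matrix(NA_character_, length(internal), S,
                  dimnames = list(as.character(internal), NULL))
  state_post <- matrix(NA_real_, length(internal), S,
                       dimnames = list(as.character(internal), NULL))
  for (u in internal) {
    post <- outside[[u]] * cond$partials[[u]]
    tot <- colSums(post)
    tot[tot == 0] <- 1
    post <- sweep(post, 2L, tot, "/")
    rownames(post) <- AA20
    posterior[[u]] <- post
    amax <- apply(post, 2L, which.max)    # ties -> lowest alphabet index
    state[as.character(u), ] <- AA20[amax]
    state_post[as.character(u), ] <- post[cbind(amax, seq_len(S))]
  }

  structure(list(gene_id = attr(aln, "gene_id"), posterior = posterior,
                 state = state, state_posterior = state_post,
                 missing = cond$missing, site_loglik = cond$site_loglik,
                 root = root, ntip = ntip, n_sites = S, blen = cond$blen),
            class = "ancestral_recon")
}

#' @export
print.ancestral_recon <- function(x, ...) {
  cat(sprintf("ancestral_recon '%s': %d internal nodes x %d sites\n",
              x$gene_id, nrow(x$state), x$n_sites))
  invisible(x)
}

#' Export assigned ancestral states to TSV
#'
#' @param rec An [marginal_posteriors()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ancestral_states <- function(rec, path) {
  df <- data.frame(
    node = rep(rownames(rec$state), rec$n_sites),
    site = rep(seq_len(rec$n_sites), each = nrow(rec$state)),
    state = as.vector(rec$state),
    posterior = as.vector(rec$state_posterior))
  utils::write.table(df[order(df$node, df$site), ], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
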