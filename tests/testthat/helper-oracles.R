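# Independent oracles and small fixtures shared across test files.
# Everything here is deliberately written from first principles (explicit
# enumeration, Matrix::expm, direct arithmetic) and never calls the code
# paths it is used to check.

AA <- aa_alphabet()

# Transition matrix by an independent route: dense matrix exponential
# (Higham scaling-and-squaring, as implemented in Matrix::expm).
oracle_P <- function(model, t) {
  P <- as.matrix(Matrix::expm(model$Q * t))
  dimnames(P) <- list(AA, AA)
  P
}

# Tree bookkeeping written independently of the package internals.
oracle_parent_map <- function(tree) {
  parent <- integer(ape::Ntip(tree) + tree$Nnode)
  for (e in seq_len(nrow(tree$edge)))
    parent[tree$edge[e, 2]] <- tree$edge[e, 1]
  parent
}

oracle_tips_below <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  sort(unlist(lapply(kids, oracle_tips_below, tree = tree)))
}

# Joint enumeration over all internal-node state assignments of one site.
# Returns the site likelihood and the marginal posterior matrix
# (20 x n_internal). Leaves must carry observed (non-missing) residues;
# missing leaves are marginalised by an all-ones emission.
oracle_site_enumeration <- function(tree, model, residues) {
  ntip <- ape::Ntip(tree)
  n_int <- tree$Nnode
  root <- ntip + 1L
  internal <- root:(ntip + n_int)
  blen <- numeric(ntip + n_int)
  blen[tree$edge[, 2]] <- tree$edge.length
  Pm <- lapply(seq_len(ntip + n_int), function(v)
    if (v == root) NULL else oracle_P(model, blen[v]))
  parent <- oracle_parent_map(tree)

  grid <- as.matrix(expand.grid(rep(list(1:20), n_int)))
  joint <- model$freq[grid[, 1]]           # root prior; root is internal[1]
  for (j in seq_len(n_int)[-1]) {          # internal-node edges
    v <- internal[j]
    pu <- match(parent[v], internal)
    joint <- joint * Pm[[v]][cbind(grid[, pu], grid[, j])]
  }
  for (v in seq_len(ntip)) {               # leaf edges
    pu <- match(parent[v], internal)
    obs <- match(residues[v], AA)
    if (is.na(obs)) {
      joint <- joint * rowSums(Pm[[v]][grid[, pu], , drop = FALSE])
    } else {
      joint <- joint * Pm[[v]][cbind(grid[, pu], obs)]
    }
  }
  lik <- sum(joint)
  post <- vapply(seq_len(n_int), function(j)
    vapply(1:20, function(a) sum(joint[grid[, j] == a]), 0) / lik,
    numeric(20))
  rownames(post) <- AA
  colnames(post) <- as.character(internal)
  list(likelihood = lik, posterior = post)
}

# Brute-force re-implementation of the convergent-site rules, scanning
# every site directly against the written definition (all-foreground mode).
oracle_convergent_scan <- function(rec, aln, tree, fg) {
  parent <- oracle_parent_map(tree)
  ntip <- ape::Ntip(tree)
  m <- unclass(aln)
  hits <- list()
  for (s in seq_len(ncol(m))) {
    der <- character(0); anc <- character(0); ok <- TRUE
    for (b in fg) {
      u <- parent[b]
      pstate <- rec$state[as.character(u), s]
      if (rec$missing[u, s]) { ok <- FALSE; break }
      if (b <= ntip) {
        cstate <- m[tree$tip.label[b], s]
        if (cstate %in% c("-", "X")) { ok <- FALSE; break }
      } else {
        if (rec$missing[b, s]) { ok <- FALSE; break }
        cstate <- rec$state[as.character(b), s]
      }
      if (pstate == cstate) { ok <- FALSE; break }
      der <- c(der, cstate); anc <- c(anc, pstate)
    }
    if (!ok || length(unique(der)) != 1L) next
    fg_leaves <- unlist(lapply(fg, oracle_tips_below, tree = tree))
    if (!all(m[tree$tip.label[fg_leaves], s] == der[1])) next
    cls <- if (length(unique(anc)) == 1L) "parallel"
           else if (length(unique(anc)) == length(anc)) "convergent"
           else "mixed"
    hits[[length(hits) + 1L]] <- data.frame(site = s, derived = der[1],
                                            class = cls)
  }
  if (!length(hits)) return(data.frame(site = integer(0),
                                       derived = character(0),
                                       class = character(0)))
  do.call(rbind, hits)
}

# 4-taxon workhorse tree for enumeration checks (3 internal nodes).
quartet_tree <- function() {
  parse_tree("((A:0.12,B:0.08):0.1,(C:0.15,D:0.05):0.07);")
}

# A frequency vector with a fixed seed, for model property tests.
random_freq <- function(seed) {
  set.seed(seed)
  f <- stats::rgamma(20, shape = 2)
  f / sum(f)
}

quartet_alignment <- function(residues, gene_id = "q") {
  aa_alignment(setNames(residues, c("A", "B", "C", "D")), gene_id = gene_id)
}
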