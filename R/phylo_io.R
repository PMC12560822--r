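#' Construct a protein alignment object
#'
#' An `aa_alignment` stores an aligned set of protein sequences as a character
#' matrix (rows = taxa, columns = alignment sites) over the alphabet of
#' [aa_alphabet()] plus the gap `-` and unknown `X`. Symbols are upper-cased;
#' any symbol outside the alphabet (ambiguity codes such as `B` or `Z`, `*`,
#' `?`, `.`) is mapped to `X` with a warning.
#'
#' @param seqs Named character vector of equal-length sequences, or a
#'   character matrix with rownames (one residue per cell).
#' @param gene_id Identifier attached to the alignment (used in reports).
#' @return An object of class `aa_alignment`: a character matrix with
#'   attributes `gene_id` and `taxa`.
#' @export
#' @examples
#' aln <- aa_alignment(c(A = "STR", B = "SAR"), gene_id = "g1")
#' dim(aln)
aa_alignment <- function(seqs, gene_id = "gene") {
  if (is.matrix(seqs)) {
    m <- seqs
    if (is.null(rownames(m))) stop("alignment matrix must have taxon rownames")
  } else {
    if (length(seqs) == 0L) stop("empty alignment: no sequences")
    if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
      stop("all sequences must be named by taxon")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L)
      stop("alignment shape error: sequences have unequal lengths (",
           paste(unique(lens), collapse = ", "), ")")
    if (lens[1] == 0L) stop("empty alignment: zero-length sequences")
    m <- do.call(rbind, strsplit(as.character(seqs), "", fixed = TRUE))
    rownames(m) <- names(seqs)
  }
  if (anyDuplicated(rownames(m)))
    stop("duplicate taxon labels: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  m[] <- toupper(m)
  legal <- c(AA20, MISSING_SYMBOLS)
  bad <- !(m %in% legal)
  if (any(bad)) {
    warning(sprintf(
      "%d symbol(s) outside the amino acid alphabet mapped to 'X' (e.g. '%s')",
      sum(bad), m[bad][1]))
    m[bad] <- "X"
  }
  structure(m, gene_id = gene_id, taxa = rownames(m), class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("aa_alignment '%s': %d taxa x %d sites\n",
              attr(x, "gene_id"), nrow(x), ncol(x)))
  invisible(x)
}

#' Read an aligned protein FASTA file
#'
#' @param path Path to a FASTA file of equal-length amino acid sequences.
#' @param gene_id Gene identifier; defaults to the file name without
#'   extension.
#' @return An [aa_alignment()].
#' @export
read_alignment <- function(path, gene_id = NULL) {
  if (is.null(gene_id))
    gene_id <- sub("\\.[^.]*$", "", basename(path))
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) stop("empty input: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty input: no FASTA records in ", path)
  w <- Biostrings::width(ss)
  if (length(unique(w)) != 1L)
    stop("alignment shape error in ", path,
         ": sequence lengths ", paste(unique(w), collapse = ", "))
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  aa_alignment(seqs, gene_id = gene_id)
}

#' Write an alignment to FASTA
#'
#' @param aln An [aa_alignment()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  seqs <- apply(unclass(aln), 1L, paste, collapse = "")
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  invisible(path)
}

#' Read a rooted phylogeny with branch lengths
#'
#' Parses a newick file into an ape `phylo` object and validates the contract
#' required downstream: the tree is rooted (the root has exactly two
#' children), and every edge carries a nonnegative branch length in expected
#' substitutions per site. Node identifiers are ape's deterministic integer
#' indexing (leaves `1..n` in file order, internal nodes `n+1..`).
#'
#' @param path Path to a newick file.
#' @return A `phylo` object.
#' @export
read_tree <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("malformed newick in ", path)
  validate_tree(tr, where = path)
}

#' @rdname read_tree
#' @param text A newick string (alternative to a file).
#' @export
parse_tree <- function(text) {
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("malformed newick string")
  validate_tree(tr, where = "newick string")
}

validate_tree <- function(tr, where = "tree") {
  if (!inherits(tr, "phylo")) stop("not a phylogeny: ", where)
  root <- ape::Ntip(tr) + 1L
  n_root_children <- sum(tr$edge[, 1] == root)
  if (n_root_children != 2L)
    stop("tree in ", where, " is unrooted (root has ", n_root_children,
         " children); root it before analysis")
  if (is.null(tr$edge.length) || length(tr$edge.length) != nrow(tr$edge) ||
      anyNA(tr$edge.length))
    stop("tree in ", where, " is missing branch lengths")
  if (any(tr$edge.length < 0))
    stop("tree in ", where, " has negative branch lengths")
  if (anyDuplicated(tr$tip.label))
    stop("tree in ", where, " has duplicate tip labels")
  tr
}

#' Write a phylogeny to newick
#'
#' @param tree A `phylo` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

tree_parent <- function(tree) {
  # parent[i] = parent node of node i; 0 at the root
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  parent <- integer(n_nodes)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  parent
}

node_ancestors <- function(tree, node) {
  parent <- tree_parent(tree)
  anc <- integer(0)
  while (parent[node] != 0L) {
    node <- parent[node]
    anc <- c(anc, node)
  }
  anc
}

#' Resolve foreground branch designators
#'
#' Each designator is a character vector of taxon labels. A single label
#' designates that terminal branch; two or more labels designate the branch
#' above the most recent common ancestor (MRCA) of the set. Because
#' convergence requires independent lineages, nested designations (one
#' foreground branch ancestral to another) are rejected, as is a designation
#' whose MRCA is the root (which has no parent branch).
#'
#' @param tree A `phylo` object from [read_tree()].
#' @param specs List of character vectors of taxon labels.
#' @return Sorted integer vector of foreground node IDs, each standing for
#'   the branch from that node to its parent.
#' @export
#' @examples
#' tr <- parse_tree("((A:0.1,B:0.1):0.2,C:0.3);")
#' resolve_foreground(tr, list(c("A", "B")))
resolve_foreground <- function(tree, specs) {
  if (!is.list(specs)) specs <- list(specs)
  root <- ape::Ntip(tree) + 1L
  nodes <- vapply(specs, function(sp) {
    sp <- as.character(sp)
    missing <- setdiff(sp, tree$tip.label)
    if (length(missing))
      stop("foreground taxon not in tree: ", paste(missing, collapse = ", "))
    if (length(sp) == 1L) {
      match(sp, tree$tip.label)
    } else {
      as.integer(ape::getMRCA(tree, sp))
    }
  }, integer(1))
  bad_root <- nodes == root
  if (any(bad_root))
    stop("foreground designation resolves to the root, which has no parent ",
         "branch: ", paste(vapply(specs[bad_root], paste, "", collapse = ","),
                           collapse = "; "))
  nodes <- sort(unique(nodes))
  for (i in seq_along(nodes)) {
    anc <- node_ancestors(tree, nodes[i])
    nested <- intersect(anc, nodes)
    if (length(nested))
      stop("nested foreground branches (node ", nodes[i],
           " is a descendant of node ", nested[1],
           "); convergence requires independent lineages")
  }
  nodes
}

#' Attach foreground branches to a tree
#'
#' Convenience wrapper storing the result of [resolve_foreground()] in the
#' tree's `foreground` attribute, where the scan functions look it up.
#'
#' @inheritParams resolve_foreground
#' @return The tree with attribute `foreground` set.
#' @export
set_foreground <- function(tree, specs) {
  attr(tree, "foreground") <- resolve_foreground(tree, specs)
  tree
}

foreground_nodes <- function(tree, foreground = NULL) {
  fg <- if (is.null(foreground)) attr(tree, "foreground") else foreground
  if (is.null(fg)) stop("no foreground branches designated; call ",
                        "set_foreground() or pass `foreground`")
  as.integer(fg)
}

#' Read a genome features table
#'
#' Tab-delimited table with columns `species`, `group` (RIF / non-RIF),
#' `scaffolds`, `n50_bp`, `genome_size_bp`, `protein_count`, `busco_pct`,
#' `gc_pct`. Thousands separators (commas) inside numbers are accepted and
#' stripped.
#'
#' @param path Path to a TSV file. An empty file yields an empty table.
#' @return A data.frame with typed columns.
#' @export
read_genome_table <- function(path) {
  cols <- c("species", "group", "scaffolds", "n50_bp", "genome_size_bp",
            "protein_count", "busco_pct", "gc_pct")
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) {
    df <- as.data.frame(setNames(rep(list(character(0)), 2), cols[1:2]))
    for (nm in cols[3:8]) df[[nm]] <- numeric(0)
    return(df)
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           strip.white = TRUE)
  missing_cols <- setdiff(cols, names(raw))
  if (length(missing_cols))
    stop("genome table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- raw[cols]
  num <- function(col, integerish) {
    x <- gsub(",", "", df[[col]], fixed = TRUE)
    v <- suppressWarnings(as.numeric(x))
    bad <- is.na(v) & nzchar(x)
    if (any(bad))
      stop("non-numeric ", col, " for species: ",
           paste(df$species[bad], collapse = ", "))
    if (integerish) as.integer(round(v)) else v
  }
  df$scaffolds <- num("scaffolds", TRUE)
  df$n50_bp <- num("n50_bp", TRUE)
  df$genome_size_bp <- num("genome_size_bp", TRUE)
  df$protein_count <- num("protein_count", TRUE)
  df$busco_pct <- num("busco_pct", FALSE)
  df$gc_pct <- num("gc_pct", FALSE)
  if (any(df$genome_size_bp <= 0))
    stop("genome_size_bp must be positive; offending species: ",
         paste(df$species[df$genome_size_bp <= 0], collapse = ", "))
  if (any(df$protein_count < 0)) stop("protein_count must be nonnegative")
  df
}

#' Write a genome features table
#'
#' @param table Data frame as returned by [read_genome_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_genome_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
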