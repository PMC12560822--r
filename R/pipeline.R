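ensure_outdir <- function(out_dir, force) {
  if (dir.exists(out_dir) && length(dir(out_dir)) && !force)
    stop("output directory ", out_dir, " is not empty; use force = TRUE")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out_dir
}

echo_config <- function(out_dir, config) {
  jsonlite::write_json(config, file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run a convergence scan end to end
#'
#' Reads the tree and every alignment, resolves the foreground designators,
#' runs [scan_genes()], and writes `results.tsv` (all genes, sorted by q
#' then p), `significant.tsv` (genes with `q < q_threshold`),
#' `convergent_sites.tsv` (site-level detail), `run_summary.json`, and a
#' `run_config.json` echo.
#'
#' @param tree_path Newick file of the rooted species tree.
#' @param alignment_paths Character vector of FASTA paths, or a single
#'   directory containing them.
#' @param foreground List of designators: each a character vector of taxon
#'   labels (length 1 = terminal branch, length > 1 = branch above the MRCA).
#' @param out_dir Output directory.
#' @param mode `"all_foreground"` or `"pairwise"`.
#' @param pseudocount Pseudocount for gene frequency estimation.
#' @param q_threshold FDR significance bound (in (0,1); default 0.05).
#' @param force Overwrite a non-empty output directory.
#' @return The scan result data frame, invisibly.
#' @export
run_scan <- function(tree_path, alignment_paths, foreground, out_dir,
                     mode = "all_foreground", pseudocount = 1,
                     q_threshold = 0.05, force = FALSE) {
  if (q_threshold <= 0 || q_threshold >= 1)
    stop("q_threshold must be in (0, 1)")
  ensure_outdir(out_dir, force)
  if (length(alignment_paths) == 1L && dir.exists(alignment_paths))
    alignment_paths <- list.files(alignment_paths, full.names = TRUE,
                                  pattern = "\\.(fa|fasta|faa)$")
  tree <- read_tree(tree_path)
  fg <- resolve_foreground(tree, foreground)
  alns <- lapply(alignment_paths, read_alignment)
  res <- scan_genes(alns, tree, fg, mode = mode, pseudocount = pseudocount)
  utils::write.table(res, file.path(out_dir, "results.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res[res$q < q_threshold, , drop = FALSE],
                     file.path(out_dir, "significant.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  site_table <- attr(res, "site_table")
  if (is.null(site_table))
    site_table <- data.frame(gene_id = character(0), site = integer(0),
                             derived_state = character(0),
                             ancestral_states = character(0),
                             class = character(0),
                             n_branches_substituting = integer(0),
                             label = character(0))
  utils::write.table(site_table, file.path(out_dir, "convergent_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- attr(res, "summary")
  summ$q_threshold <- q_threshold
  summ$n_significant <- sum(res$q < q_threshold)
  jsonlite::write_json(summ, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  echo_config(out_dir, list(
    subcommand = "scan", tree = tree_path,
    alignments = as.character(alignment_paths),
    foreground = lapply(foreground, as.character), mode = mode,
    pseudocount = pseudocount, q_threshold = q_threshold))
  invisible(res)
}

#' Run the simulator subcommand
#'
#' Thin wrapper over [simulation_config()] + [make_benchmark()].
#'
#' @param out_dir Output directory for the benchmark files.
#' @param seed Mandatory integer seed.
#' @param force Overwrite a non-empty output directory.
#' @param ... Passed to [simulation_config()].
#' @return The benchmark directory path, invisibly.
#' @export
run_simulate <- function(out_dir, seed, force = FALSE, ...) {
  config <- simulation_config(seed = seed, ...)
  make_benchmark(config, out_dir, force = force)
}

#' Run the genome-features subcommand
#'
#' Computes per-species gene densities, per-group summaries of genome size
#' and protein count, optional shared-PSG overlap, and writes
#' `gene_density.tsv`, `group_summaries.tsv`, `features_report.txt` (and
#' `psg_overlap.json` when PSG lists are given).
#'
#' @param genome_table_path TSV read by [read_genome_table()].
#' @param out_dir Output directory.
#' @param psg_paths Optional character vector of files, one gene ID per
#'   line, one file per lineage.
#' @param universe_size Ortholog universe for the PSG overlap (required
#'   with `psg_paths`).
#' @param force Overwrite a non-empty output directory.
#' @return List of computed tables, invisibly.
#' @export
run_features <- function(genome_table_path, out_dir, psg_paths = NULL,
                         universe_size = NULL, force = FALSE) {
  ensure_outdir(out_dir, force)
  tab <- read_genome_table(genome_table_path)
  dens <- data.frame(species = tab$species,
                     density_genes_per_mb = gene_density(tab$protein_count,
                                                         tab$genome_size_bp))
  utils::write.table(dens, file.path(out_dir, "gene_density.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  parts <- lapply(c("genome_size_bp", "protein_count"),
                  function(f) cbind(field = f, group_summary(tab, f)))
  all_cols <- Reduce(union, lapply(parts, names))
  summaries <- do.call(rbind, lapply(parts, function(p) {
    p[setdiff(all_cols, names(p))] <- NA
    p[all_cols]
  }))
  utils::write.table(summaries, file.path(out_dir, "group_summaries.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  overlap <- NULL
  if (!is.null(psg_paths)) {
    if (is.null(universe_size))
      stop("universe_size is required with psg_paths")
    sets <- lapply(psg_paths, function(p) readLines(p, warn = FALSE))
    overlap <- shared_psg_summary(sets, universe_size)
    jsonlite::write_json(overlap, file.path(out_dir, "psg_overlap.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report <- c(
    "Genome feature summary",
    sprintf("  species: %d", nrow(tab)),
    sprintf("  highest gene density: %s at %d genes/Mb",
            dens$species[which.max(dens$density_genes_per_mb)],
            max(dens$density_genes_per_mb)),
    sprintf("  assembly length range: %.1f - %.1f Mb",
            trunc_to(min(tab$genome_size_bp) / 1e6, 1),
            trunc_to(max(tab$genome_size_bp) / 1e6, 1)),
    if (!is.null(overlap))
      sprintf("  shared PSGs: %d of %d (%.2f%%)", overlap$n_shared,
              overlap$universe_size, overlap$shared_pct),
    "  rounding: densities to integers (half-up), percentages to 2",
    "  decimals, Mb ranges to 1 decimal, Mb means to 2 decimals")
  writeLines(report, file.path(out_dir, "features_report.txt"))
  echo_config(out_dir, list(subcommand = "features",
                            genome_table = genome_table_path,
                            psg_paths = as.character(psg_paths),
                            universe_size = universe_size))
  invisible(list(densities = dens, summaries = summaries, overlap = overlap))
}
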