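# round-half-up (R's round() is round-half-even); digits >= 0
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# truncate toward zero at a given number of decimals; assembly-size ranges
# are conventionally printed truncated (29,490,499 bp appears as 29.4 Mb)
trunc_to <- function(x, digits) {
  p <- 10^digits
  trunc(x * p) / p
}

#' Gene density in genes per megabase
#'
#' `round(protein_count / (genome_size_bp / 1e6))` with half-up rounding to
#' an integer, the convention used for printed per-genome densities.
#'
#' @param protein_count Number of predicted protein-coding gene models.
#' @param genome_size_bp Assembly length in base pairs (positive).
#' @return Integer genes/Mb (vectorised).
#' @export
#' @examples
#' gene_density(10933, 24600606)  # 444
gene_density <- function(protein_count, genome_size_bp) {
  if (any(genome_size_bp <= 0)) stop("genome_size_bp must be positive")
  if (any(protein_count < 0)) stop("protein_count must be nonnegative")
  as.integer(round_half_up(protein_count / (genome_size_bp / 1e6)))
}

#' Per-group summary of a genome feature
#'
#' Mean, sample standard deviation (n - 1 denominator; `NA` for a single
#' record), minimum and maximum of one numeric field per `group` level.
#' Fields in base pairs are also reported in Mb: means and SDs rounded
#' half-up to 2 decimals, range endpoints truncated to 1 decimal, matching
#' the precision and convention such tables are printed at.
#'
#' @param table Data frame from [read_genome_table()].
#' @param field Name of a numeric column.
#' @return Data frame with one row per group: `group`, `n`, `mean`, `sd`,
#'   `min`, `max`, and for bp fields `mean_mb`, `sd_mb`, `min_mb`, `max_mb`.
#' @export
group_summary <- function(table, field) {
  if (!field %in% names(table)) stop("no such field: ", field)
  groups <- unique(table$group)
  empty <- groups[!groups %in% table$group[!is.na(table[[field]])]]
  if (length(empty)) stop("empty group for ", field, ": ",
                          paste(empty, collapse = ", "))
  out <- do.call(rbind, lapply(groups, function(g) {
    x <- table[[field]][table$group == g]
    data.frame(group = g, n = length(x), mean = mean(x),
               sd = if (length(x) > 1L) stats::sd(x) else NA_real_,
               min = min(x), max = max(x))
  }))
  if (grepl("_bp$", field)) {
    out$mean_mb <- round_half_up(out$mean / 1e6, 2)
    out$sd_mb <- round_half_up(out$sd / 1e6, 2)
    out$min_mb <- trunc_to(out$min / 1e6, 1)
    out$max_mb <- trunc_to(out$max / 1e6, 1)
  }
  out
}

#' Shared positively-selected-gene summary
#'
#' Intersection of per-lineage gene-ID sets and its percentage of the
#' tested ortholog universe, rounded half-up to 2 decimals (`36 / 3290`
#' genes gives `1.09`).
#'
#' @param sets List of character vectors of gene IDs (one per lineage).
#' @param universe_size Number of orthologs tested; must be at least the
#'   size of the union of the sets.
#' @return List with `universe_size`, `set_sizes`, `intersection` (sorted
#'   IDs), `n_shared`, `shared_pct`.
#' @export
shared_psg_summary <- function(sets, universe_size) {
  stopifnot(length(sets) >= 1L)
  sets <- lapply(sets, function(s) unique(as.character(s)))
  union_size <- length(unique(unlist(sets)))
  if (universe_size < union_size)
    stop("universe_size (", universe_size, ") smaller than the union of the ",
         "sets (", union_size, ")")
  inter <- Reduce(intersect, sets)
  list(universe_size = as.integer(universe_size),
       set_sizes = lengths(sets),
       intersection = sort(inter),
       n_shared = length(inter),
       shared_pct = round_half_up(100 * length(inter) / universe_size, 2))
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Exact p-value (full enumeration of rank assignments) when both samples
#' have at most 10 observations and there are no ties; otherwise the normal
#' approximation with continuity and tie correction. The method actually
#' used is recorded in the result. Two identical groups yield `p = 1` with
#' a degenerate-data warning.
#'
#' @param group_a,group_b Numeric vectors, non-empty.
#' @param alternative `"two.sided"` (default), `"less"`, or `"greater"`.
#' @return List with `p`, `statistic` (rank-sum W of `group_a`), `method`
#'   (`"exact"` or `"normal_approx"`), `alternative`.
#' @export
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p  # 0.1
rank_sum_test <- function(group_a, group_b,
                          alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (!length(group_a) || !length(group_b)) stop("both groups must be non-empty")
  ties <- any(duplicated(c(group_a, group_b)))
  if (length(unique(c(group_a, group_b))) == 1L) {
    warning("degenerate data: all values identical across both groups")
    return(list(p = 1, statistic = NA_real_, method = "degenerate",
                alternative = alternative))
  }
  exact <- !ties && length(group_a) <= 10L && length(group_b) <= 10L
  wt <- suppressWarnings(stats::wilcox.test(
    group_a, group_b, alternative = alternative, exact = exact,
    correct = TRUE))
  list(p = unname(wt$p.value), statistic = unname(wt$statistic),
       method = if (exact) "exact" else "normal_approx",
       alternative = alternative)
}
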