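#' Per-site correlation of methylation with age along an amplicon
#'
#' Computes the Pearson correlation of each CpG site's methylation
#' level with chronological age across samples, ordered by position
#' within the amplicon.  Plotted against genomic position this profile
#' shows which stretch of an amplicon carries the age signal.  Input is
#' either a list of [ReadPatternSet] (one per sample; per-sample site
#' frequencies are computed as in [fit_site_models()]) or a
#' [MethylationMatrix] of site betas.
#'
#' @param x List of [ReadPatternSet] or a [MethylationMatrix] whose
#'   rows are ordered amplicon sites.
#' @param meta Sample metadata with `sample_id` and `age`.
#' @param positions Optional genomic coordinates, one per site.
#' @param min_count Rare-pattern filter for the pattern-set input
#'   (default 10).
#' @return An `AmpliconProfile`: data frame with `site_index`,
#'   `position` (NA when not given), `r` (NA for zero-variance sites).
#' @export
site_age_correlation_profile <- function(x, meta, positions = NULL,
                                         min_count = 10) {
  meta <- validate_sample_metadata(meta)
  if (is.list(x) && all(vapply(x, inherits, logical(1), "ReadPatternSet"))) {
    amp <- unique(vapply(x, `[[`, character(1), "amplicon_id"))
    if (length(amp) != 1)
      stop("pattern sets span multiple amplicons: ", paste(amp, collapse = ", "))
    n_sites <- max(vapply(x, `[[`, integer(1), "n_sites"))
    freqs <- vapply(x, function(r)
      site_frequencies(filter_rare_patterns(r, min_count)),
      numeric(n_sites))
    freqs <- if (is.matrix(freqs)) t(freqs) else matrix(freqs, ncol = 1)
    sample_ids <- vapply(x, `[[`, character(1), "sample_id")
  } else {
    m <- as_beta_matrix(x)
    amp <- "amplicon"
    n_sites <- nrow(m)
    freqs <- t(m)
    sample_ids <- colnames(m)
  }
  age <- meta$age[match(sample_ids, meta$sample_id)]
  if (anyNA(age)) stop("samples without age: ",
                       paste(sample_ids[is.na(age)], collapse = ", "))
  r <- suppressWarnings(as.vector(
    stats::cor(freqs, age, use = "pairwise.complete.obs")))
  if (is.null(positions)) positions <- rep(NA_real_, n_sites)
  stopifnot(length(positions) == n_sites)
  structure(data.frame(amplicon_id = amp, site_index = seq_len(n_sites),
                       position = positions, r = r),
            class = c("AmpliconProfile", "data.frame"))
}

#' Between-site correlation of methylation levels
#'
#' Pearson correlation matrix of per-sample site frequencies between
#' all pairs of CpG sites of an amplicon.  Under purely stochastic,
#' uncoordinated drift the off-diagonal correlations of read-level
#' calls vanish, whereas site frequencies of neighboring CpGs in real
#' amplicons are often strongly coupled through their shared age
#' dependence.
#'
#' @param pattern_sets List of [ReadPatternSet], one per sample
#'   (>= 3 samples).
#' @param min_count Rare-pattern filter (default 10).
#' @return Symmetric numeric matrix (sites x sites) with unit diagonal
#'   where defined and `NA` rows/columns for zero-variance sites.
#' @export
pairwise_site_correlation <- function(pattern_sets, min_count = 10) {
  stopifnot(length(pattern_sets) >= 3)
  n_sites <- max(vapply(pattern_sets, `[[`, integer(1), "n_sites"))
  freqs <- vapply(pattern_sets, function(r)
    site_frequencies(filter_rare_patterns(r, min_count)),
    numeric(n_sites))
  freqs <- if (is.matrix(freqs)) t(freqs) else matrix(freqs, ncol = 1)
  r <- suppressWarnings(stats::cor(freqs, use = "pairwise.complete.obs"))
  dimnames(r) <- list(seq_len(n_sites), seq_len(n_sites))
  r
}

#' Pattern frequency table
#'
#' Relative frequencies of the distinct read patterns of one sample,
#' sorted by count (descending) with lexicographic tie-break, so the
#' output order is deterministic.
#'
#' @param rps A [ReadPatternSet] with at least one pattern.
#' @return Data frame with `pattern`, `count`, `frequency` (summing
#'   to 1).
#' @export
pattern_frequency_table <- function(rps) {
  stopifnot(inherits(rps, "ReadPatternSet"))
  if (length(rps$patterns) == 0) stop("empty pattern set")
  ord <- order(-as.integer(rps$patterns), names(rps$patterns))
  counts <- as.integer(rps$patterns)[ord]
  data.frame(pattern = names(rps$patterns)[ord], count = counts,
             frequency = counts / sum(counts), stringsAsFactors = FALSE)
}

#' Windows around CpG sites
#'
#' Extends each CpG position by `half_width` bases in both directions.
#' Coordinates are 0-based half-open and strand-ignorant: a site at
#' position p yields \[p - 250, p + 251), a 501-base window that covers
#' 250 bp on each side of the site base itself.
#'
#' @param chrom Chromosome names (recycled if length 1).
#' @param pos 0-based site positions.
#' @param ids Window names (default `cpg<k>`).
#' @param half_width Extension in bases (default 250).
#' @return BED-like data frame with `chrom`, `start`, `end`, `name`.
#' @export
cpg_windows <- function(chrom, pos, ids = NULL, half_width = 250) {
  stopifnot(half_width > 0)
  if (is.null(ids)) ids <- paste0("cpg", seq_along(pos))
  data.frame(chrom = rep_len(as.character(chrom), length(pos)),
             start = pmax(pos - half_width, 0),
             end = pos + half_width + 1,
             name = ids, stringsAsFactors = FALSE)
}

#' Quantile-normalize coverage vectors
#'
#' Replaces each sample's values by the mean of the sorted values
#' across samples at the same rank, so every sample ends up with an
#' identical marginal distribution while within-sample ranks are
#' preserved.  Delegates to `limma::normalizeQuantiles` (ties averaged).
#'
#' @param mat Numeric matrix, rows = CpG windows, columns = samples.
#' @return Matrix of the same shape.
#' @export
quantile_normalize <- function(mat) {
  out <- limma::normalizeQuantiles(as.matrix(mat), ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Windowed coverage enrichment at target CpGs
#'
#' Tests whether read coverage (for example ChIP-seq signal summarized
#' over windows of [cpg_windows()]) is higher at a target set of CpGs
#' than at a background set.  Coverage columns are quantile normalized
#' across samples, then target and background values are compared by
#' the Mann-Whitney (Wilcoxon rank-sum) test per sample and on the
#' pooled normalized values.
#'
#' @param coverage Numeric matrix of coverage values, rows named by CpG
#'   id, columns by sample.
#' @param target_ids,background_ids Disjoint character vectors of CpG
#'   ids present in `coverage`.
#' @param alternative Test sidedness passed to [stats::wilcox.test()]
#'   (default `"two.sided"`).
#' @return A `WindowEnrichmentResult`: list with `per_sample` (data
#'   frame: `sample`, `statistic`, `p_value`), `pooled_statistic`,
#'   `pooled_p_value`, `normalized` (the normalized matrix),
#'   `alternative`.
#' @export
window_enrichment <- function(coverage, target_ids, background_ids,
                              alternative = "two.sided") {
  coverage <- as.matrix(coverage)
  if (length(intersect(target_ids, background_ids)) > 0)
    stop("target and background CpG sets overlap")
  missing_ids <- setdiff(c(target_ids, background_ids), rownames(coverage))
  if (length(missing_ids) > 0)
    stop("ids absent from coverage matrix: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  norm <- quantile_normalize(coverage)
  per_sample <- do.call(rbind, lapply(colnames(norm), function(s) {
    w <- suppressWarnings(
      stats::wilcox.test(norm[target_ids, s], norm[background_ids, s],
                         alternative = alternative))
    data.frame(sample = s, statistic = unname(w$statistic),
               p_value = w$p.value, stringsAsFactors = FALSE)
  }))
  pooled <- suppressWarnings(
    stats::wilcox.test(as.vector(norm[target_ids, , drop = FALSE]),
                       as.vector(norm[background_ids, , drop = FALSE]),
                       alternative = alternative))
  structure(list(per_sample = per_sample,
                 pooled_statistic = unname(pooled$statistic),
                 pooled_p_value = pooled$p.value,
                 normalized = norm,
                 alternative = alternative),
            class = "WindowEnrichmentResult")
}

#' Draw a random background CpG set
#'
#' Seeded sampling without replacement from a CpG universe, excluding
#' the target ids, for use as the background of
#' [window_enrichment()].
#'
#' @param universe Character vector of candidate ids.
#' @param n Background size (default 1000).
#' @param exclude Ids never to sample (typically the targets).
#' @param seed Optional integer seed.
#' @return Character vector of `n` ids.
#' @export
sample_background_cpgs <- function(universe, n = 1000,
                                   exclude = character(), seed = NULL) {
  pool <- setdiff(universe, exclude)
  if (length(pool) < n)
    stop(sprintf("universe has only %d eligible CpGs, need %d",
                 length(pool), n))
  if (!is.null(seed)) set.seed(seed)
  sample(pool, n)
}
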