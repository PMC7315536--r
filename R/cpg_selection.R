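#' Bundle methylation studies into a collection
#'
#' A `StudyCollection` pairs each beta-value matrix with its sample
#' metadata.  Candidate screening requires each selection criterion to
#' hold in every study of the collection individually, which is robust
#' to between-study shifts in beta values.
#'
#' @param studies List of `list(matrix = , meta = )` pairs; `matrix` a
#'   [MethylationMatrix], `meta` a metadata data frame (see
#'   [read_sample_metadata()]).  List names are used as study labels
#'   when present.
#' @return An object of class `StudyCollection`.
#' @export
StudyCollection <- function(studies) {
  if (length(studies) < 1) stop("a StudyCollection needs at least one study")
  if (is.null(names(studies)) || any(names(studies) == ""))
    names(studies) <- paste0("study", seq_along(studies))
  studies <- lapply(studies, function(s) {
    m <- as_beta_matrix(s$matrix)
    meta <- validate_sample_metadata(s$meta)
    common <- intersect(colnames(m), meta$sample_id)
    if (sum(!is.na(meta$age[match(common, meta$sample_id)])) < 3)
      stop("each study needs >= 3 samples with known age")
    list(matrix = m, meta = meta)
  })
  structure(studies, class = "StudyCollection")
}

#' Selection criteria for age-associated CpG screening
#'
#' @param r_cutoff Absolute correlation threshold (default 0.5).
#' @param methods Correlation criteria to evaluate; any subset of
#'   `"pearson_age"` (Pearson vs age), `"spearman_age"` (Spearman vs
#'   age), `"pearson_log_age"` (Pearson vs ln(age + offset)).
#' @param subset_variance_cutoff Across-cell-subset variance above which
#'   a CpG is flagged by [subset_variance_filter()] (default 0.02).
#' @param log_offset Years added to age before taking the logarithm
#'   (default 1).
#' @param strict If `TRUE` use `|r| > cutoff`; default is the inclusive
#'   `|r| >= cutoff`.
#' @return An object of class `SelectionCriteria`.
#' @export
SelectionCriteria <- function(r_cutoff = 0.5,
                              methods = c("pearson_age", "spearman_age",
                                          "pearson_log_age"),
                              subset_variance_cutoff = 0.02,
                              log_offset = 1, strict = FALSE) {
  methods <- match.arg(methods, c("pearson_age", "spearman_age",
                                  "pearson_log_age"), several.ok = TRUE)
  if (!(r_cutoff > 0 && r_cutoff < 1)) stop("r_cutoff must be in (0, 1)")
  structure(list(r_cutoff = r_cutoff, methods = methods,
                 subset_variance_cutoff = subset_variance_cutoff,
                 log_offset = log_offset, strict = strict),
            class = "SelectionCriteria")
}

#' Exclusion masks for CpG screening
#'
#' Named lists of CpG ids to remove from the candidate universe before
#' correlation screening: SNP-associated probes, cross-reactive probes,
#' probes variable across hematopoietic cell subsets, smoking-associated
#' probes, sex-chromosome probes, and probes absent from the EPIC
#' platform.  Any list may be empty; the masks themselves are
#' user-supplied.
#'
#' @param snp_associated,cross_reactive,subset_variable,smoking,sex_chromosome,not_on_epic
#'   Character vectors of CpG ids.
#' @return An object of class `ExclusionMasks`.
#' @export
ExclusionMasks <- function(snp_associated = character(),
                           cross_reactive = character(),
                           subset_variable = character(),
                           smoking = character(),
                           sex_chromosome = character(),
                           not_on_epic = character()) {
  structure(list(snp_associated = as.character(snp_associated),
                 cross_reactive = as.character(cross_reactive),
                 subset_variable = as.character(subset_variable),
                 smoking = as.character(smoking),
                 sex_chromosome = as.character(sex_chromosome),
                 not_on_epic = as.character(not_on_epic)),
            class = "ExclusionMasks")
}

#' Remove masked CpGs from a candidate universe
#'
#' Returns the universe minus the union of all mask lists, preserving
#' order.  Per-mask removal counts (within the universe; each id counted
#' once in the union for the total) are attached as attributes.
#'
#' @param universe Character vector of CpG ids.
#' @param masks An [ExclusionMasks] object.
#' @return Character vector of retained ids, with attributes
#'   `removed_per_mask` (named counts of universe ids hit by each mask)
#'   and `removed_total` (size of the union actually removed).
#' @export
apply_exclusion_masks <- function(universe, masks) {
  stopifnot(inherits(masks, "ExclusionMasks"))
  per_mask <- vapply(masks, function(ids) sum(universe %in% ids), integer(1))
  all_masked <- unique(unlist(masks, use.names = FALSE))
  kept <- universe[!(universe %in% all_masked)]
  attr(kept, "removed_per_mask") <- per_mask
  attr(kept, "removed_total") <- length(universe) - length(kept)
  kept
}

#' Flag CpGs variable across cell subsets
#'
#' Computes the population variance (divisor n) of each CpG across the
#' columns of a reference matrix of purified cell subsets and returns
#' the CpGs exceeding the cutoff, to be used as the `subset_variable`
#' exclusion mask.
#'
#' @param subset_matrix [MethylationMatrix] with one column per cell
#'   subset.
#' @param cutoff Variance threshold (default 0.02); strictly greater
#'   values are flagged.
#' @return List with `exclude` (ids with variance > cutoff, computed on
#'   complete rows) and `incomplete` (ids with any missing subset value,
#'   reported separately and not flagged).
#' @export
subset_variance_filter <- function(subset_matrix, cutoff = 0.02) {
  m <- as_beta_matrix(subset_matrix)
  incomplete <- rownames(m)[rowSums(is.na(m)) > 0]
  complete <- m[rowSums(is.na(m)) == 0, , drop = FALSE]
  n <- ncol(complete)
  pop_var <- rowMeans(complete^2) - rowMeans(complete)^2
  list(exclude = rownames(complete)[pop_var > cutoff],
       incomplete = incomplete)
}

# Age vector on the correlation scale for one criterion.
criterion_age <- function(age, method, log_offset = 1) {
  switch(method,
         pearson_age = age,
         spearman_age = age,
         pearson_log_age = log(age + log_offset),
         stop("unknown correlation method: ", method))
}

#' Per-study correlation of CpG methylation with age
#'
#' Computes, for each CpG in one study, the correlation of its beta
#' values with chronological age under one criterion: Pearson vs age,
#' Spearman vs age, or Pearson vs ln(age + offset).  Missing betas are
#' dropped pairwise; a CpG with fewer than 3 remaining pairs, or zero
#' variance in either vector, gets `NA` rather than a number.
#'
#' @param matrix [MethylationMatrix] for the study.
#' @param meta Sample metadata data frame with `sample_id` and `age`.
#' @param method One of `"pearson_age"`, `"spearman_age"`,
#'   `"pearson_log_age"`.
#' @param log_offset Offset for the log-age criterion (default 1).
#' @param cpgs Optional subset of CpG ids (default: all rows).
#' @return Named numeric vector of correlations in \[-1, 1\] (or `NA`).
#' @export
per_study_correlation <- function(matrix, meta, method = "pearson_age",
                                  log_offset = 1, cpgs = NULL) {
  m <- as_beta_matrix(matrix)
  meta <- validate_sample_metadata(meta)
  if (!is.null(cpgs)) {
    missing_cpgs <- setdiff(cpgs, rownames(m))
    if (length(missing_cpgs) > 0)
      stop("CpGs absent from matrix: ", paste(missing_cpgs, collapse = ", "))
    m <- m[cpgs, , drop = FALSE]
  }
  idx <- match(colnames(m), meta$sample_id)
  if (anyNA(idx)) stop("samples without metadata: ",
                       paste(colnames(m)[is.na(idx)], collapse = ", "))
  age <- meta$age[idx]
  ok <- !is.na(age)
  m <- m[, ok, drop = FALSE]
  y <- criterion_age(age[ok], method, log_offset)
  cor_method <- if (method == "spearman_age") "spearman" else "pearson"
  r <- suppressWarnings(
    as.vector(stats::cor(t(m), y, use = "pairwise.complete.obs",
                         method = cor_method)))
  names(r) <- rownames(m)
  # a correlation needs >= 3 complete pairs to be meaningful
  n_pairs <- rowSums(!is.na(m))
  r[n_pairs < 3] <- NA_real_
  # zero variance in the beta vector -> undefined, never a number
  zero_var <- apply(m, 1, function(v) {
    v <- v[!is.na(v)]
    length(v) >= 3 && stats::var(v) == 0
  })
  r[zero_var] <- NA_real_
  if (stats::var(y) == 0) r[] <- NA_real_
  r
}

#' Screen for age-associated CpGs across a study collection
#'
#' For each correlation criterion, selects the CpGs whose correlation
#' with age satisfies `|r| >= r_cutoff` (or `>` when `strict`) with a
#' consistent sign in every study of the collection.  CpGs missing from
#' any study cannot fulfil the criterion there and are ineligible.
#' Exclusion masks, when given, are applied to the common universe
#' first.
#'
#' @param collection A [StudyCollection].
#' @param criteria A [SelectionCriteria] object.
#' @param masks Optional [ExclusionMasks].
#' @return List of class `CpgSelection` with elements `selected` (named
#'   list: per-method character vectors), `union` (CpGs passing at least
#'   one method), `venn` (named counts over method-membership patterns),
#'   `per_study_r` (per-method matrices of CpG x study correlations),
#'   `universe` (ids screened after masking), and `ineligible` (ids
#'   dropped for missing from some study).
#' @export
select_candidates <- function(collection, criteria = SelectionCriteria(),
                              masks = NULL) {
  stopifnot(inherits(collection, "StudyCollection"),
            inherits(criteria, "SelectionCriteria"))
  ids_per_study <- lapply(collection, function(s) rownames(s$matrix))
  universe <- ids_per_study[[1]]
  common <- Reduce(intersect, ids_per_study)
  ineligible <- setdiff(unique(unlist(ids_per_study)), common)
  universe <- common
  if (!is.null(masks)) universe <- apply_exclusion_masks(universe, masks)
  universe <- as.vector(universe)

  passes <- function(r_row) {
    if (anyNA(r_row)) return(FALSE)
    thr <- if (criteria$strict) all(abs(r_row) > criteria$r_cutoff)
           else all(abs(r_row) >= criteria$r_cutoff)
    thr && (all(r_row > 0) || all(r_row < 0))
  }

  per_study_r <- list()
  selected <- list()
  for (method in criteria$methods) {
    rmat <- vapply(collection, function(s)
      per_study_correlation(s$matrix, s$meta, method,
                            criteria$log_offset, cpgs = universe),
      numeric(length(universe)))
    if (length(universe) == 1)
      rmat <- matrix(rmat, nrow = 1, dimnames = list(universe, names(collection)))
    per_study_r[[method]] <- rmat
    selected[[method]] <- universe[apply(rmat, 1, passes)]
  }

  union_set <- unique(unlist(selected, use.names = FALSE))
  membership <- vapply(selected, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1)
    membership <- matrix(membership, nrow = 1,
                         dimnames = list(universe, names(selected)))
  in_any <- rowSums(membership) > 0
  venn_key <- apply(membership[in_any, , drop = FALSE], 1, function(b)
    paste(colnames(membership)[b], collapse = "&"))
  venn <- if (length(venn_key) > 0) table(venn_key) else table(character())

  structure(list(selected = selected, union = union_set,
                 venn = venn, per_study_r = per_study_r,
                 universe = universe, ineligible = ineligible),
            class = "CpgSelection")
}

#' @export
print.CpgSelection <- function(x, ...) {
  cat(sprintf("CpG selection over %d candidates (%d ineligible):\n",
              length(x$universe), length(x$ineligible)))
  for (m in names(x$selected))
    cat(sprintf("  %-16s %d CpGs\n", m, length(x$selected[[m]])))
  cat(sprintf("  union            %d CpGs\n", length(x$union)))
  invisible(x)
}

#' Read a plain-text CpG id list
#'
#' One id per line; blank lines ignored.
#'
#' @param path File path.
#' @return Character vector of ids.
#' @export
read_cpg_list <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ids <- readLines(path)
  ids[nzchar(trimws(ids))]
}
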