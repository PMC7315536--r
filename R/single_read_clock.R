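#' Per-sample methylation frequency at each CpG site
#'
#' The multiplicity-weighted mean of the binary calls at each site
#' across all reads of one sample.  Missing calls (`.`) are excluded
#' from that site's numerator and denominator only.
#'
#' @param rps A [ReadPatternSet].
#' @return Numeric vector of length `n_sites` with site frequencies in
#'   \[0, 1\] (`NaN` where a site has no called read).
#' @export
site_frequencies <- function(rps) {
  stopifnot(inherits(rps, "ReadPatternSet"))
  if (length(rps$patterns) == 0) return(rep(NaN, rps$n_sites))
  calls <- pattern_call_matrix(names(rps$patterns), rps$n_sites)
  counts <- as.numeric(rps$patterns)
  called <- !is.na(calls)
  num <- colSums(counts * ifelse(called & calls == 1, 1, 0))
  den <- colSums(counts * called)
  num / den
}

# Patterns -> reads x sites matrix of 0/1 calls, NA for '.'.
pattern_call_matrix <- function(patterns, n_sites) {
  chars <- matrix(unlist(strsplit(patterns, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(patterns), ncol = n_sites, byrow = TRUE)
  out <- matrix(NA_real_, nrow = length(patterns), ncol = n_sites)
  out[chars == "1"] <- 1
  out[chars == "0"] <- 0
  out
}

#' Fit per-site linear age models for an amplicon
#'
#' For each CpG site of the amplicon, fits one unweighted ordinary
#' least squares regression of the per-sample site methylation
#' frequency on chronological age across the training samples.  The
#' fitted line F_i(a) = intercept + slope * a, clipped to \[0, 1\] by
#' [site_probability()], is interpreted as the probability that site i
#' is methylated on a strand from a donor of age a.
#'
#' @param pattern_sets List of [ReadPatternSet] objects for one
#'   amplicon, one per training sample.
#' @param meta Sample metadata with `sample_id` and `age`.
#' @param min_count Rare-pattern filter applied to each sample before
#'   computing frequencies (default 10; set 1 to disable).
#' @return A `SiteModelSet`: data frame with columns `amplicon_id`,
#'   `site_index`, `slope` (frequency per year), `intercept`
#'   (frequency at age 0).
#' @export
fit_site_models <- function(pattern_sets, meta, min_count = 10) {
  if (inherits(pattern_sets, "ReadPatternSet")) pattern_sets <- list(pattern_sets)
  if (length(pattern_sets) < 3)
    stop("need at least 3 training samples to fit site models")
  meta <- validate_sample_metadata(meta)
  amp <- unique(vapply(pattern_sets, `[[`, character(1), "amplicon_id"))
  if (length(amp) != 1)
    stop("pattern sets span multiple amplicons: ", paste(amp, collapse = ", "))
  n_sites <- unique(vapply(pattern_sets, `[[`, integer(1), "n_sites"))
  n_sites <- n_sites[n_sites > 0]
  if (length(n_sites) != 1)
    stop("inconsistent site counts across samples for amplicon ", amp)
  freqs <- vapply(pattern_sets, function(r)
    site_frequencies(filter_rare_patterns(r, min_count)),
    numeric(n_sites))
  freqs <- if (is.matrix(freqs)) t(freqs) else matrix(freqs, ncol = 1)
  sample_ids <- vapply(pattern_sets, `[[`, character(1), "sample_id")
  age <- meta$age[match(sample_ids, meta$sample_id)]
  if (anyNA(age)) stop("samples without age: ",
                       paste(sample_ids[is.na(age)], collapse = ", "))
  ok <- rowSums(!is.finite(freqs)) == 0
  if (sum(ok) < 3)
    stop("fewer than 3 samples with complete site frequencies")
  cf <- stats::coef(stats::lm(freqs[ok, , drop = FALSE] ~ age[ok]))
  if (is.null(dim(cf))) cf <- matrix(cf, ncol = 1)
  structure(data.frame(amplicon_id = amp,
                       site_index = seq_len(n_sites),
                       slope = unname(cf[2, ]),
                       intercept = unname(cf[1, ])),
            class = c("SiteModelSet", "data.frame"))
}

#' Site methylation probability at a given age
#'
#' Evaluates the fitted linear frequency functions and clips them to
#' \[0, 1\]: a linear function eventually leaves the unit interval, but
#' a methylation frequency cannot.
#'
#' @param models A `SiteModelSet` (or data frame with `slope`,
#'   `intercept`).
#' @param age Ages in years (vectorized).
#' @return Matrix of probabilities, sites x ages.
#' @export
site_probability <- function(models, age) {
  p <- outer(models$slope, age) + models$intercept
  p <- pmin(pmax(p, 0), 1)
  dimnames(p) <- list(NULL, NULL)
  p
}

#' Construct an age grid
#'
#' The likelihood of a read pattern is maximized over a discrete grid of
#' candidate ages, by default 0 to 200 years in steps of 1 year.  The
#' upper endpoint is appended when the step does not land on it.
#'
#' @param min_age,max_age Grid bounds in years (default 0 and 200).
#' @param step Grid step in years (default 1).
#' @return Numeric vector of grid ages including both endpoints.
#' @export
age_grid <- function(min_age = 0, max_age = 200, step = 1) {
  stopifnot(min_age < max_age, step > 0)
  g <- seq(min_age, max_age, by = step)
  if (g[length(g)] < max_age) g <- c(g, max_age)
  g
}

# Log-probability matrices over a grid; the building block of the
# likelihood.  Returns list(lp1, lp0): sites x ages log p and log(1-p).
site_log_probs <- function(models, grid) {
  p <- site_probability(models, grid)
  list(lp1 = log(p), lp0 = log1p(-p))
}

#' Likelihood of a read pattern at given ages
#'
#' Under the independence assumption (methylation at different sites of
#' a strand occurs independently), the probability of observing pattern
#' P at age a is the product over sites of p_i(a) where P has a
#' methylated call and 1 - p_i(a) where it has an unmethylated call.
#' Computed in log space; a clipped probability of exactly 0 or 1 makes
#' the corresponding mismatching pattern impossible (likelihood 0).
#'
#' @param models A `SiteModelSet` with one row per pattern position.
#' @param pattern Pattern string over `{0, 1, .}` of length
#'   `nrow(models)`.
#' @param age Ages in years (vectorized).
#' @param missing_policy How to treat `.` calls: `"drop"` declares the
#'   whole read unusable (likelihood `NA`); `"marginalize"` skips the
#'   factor for that site.
#' @return Numeric vector of Pr(P, a), one per age, each in \[0, 1\].
#' @export
pattern_likelihood <- function(models, pattern, age,
                               missing_policy = c("drop", "marginalize")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(nchar(pattern) == nrow(models))
  lp <- site_log_probs(models, age)
  calls <- pattern_call_matrix(pattern, nrow(models))[1, ]
  if (anyNA(calls) && missing_policy == "drop")
    return(rep(NA_real_, length(age)))
  exp(pattern_loglik(calls, lp))
}

# calls: vector of 0/1/NA per site; lp: site_log_probs() output.
# Returns log Pr over the grid (-Inf where impossible); NA calls skipped.
pattern_loglik <- function(calls, lp) {
  i1 <- which(!is.na(calls) & calls == 1)
  i0 <- which(!is.na(calls) & calls == 0)
  ll <- rep(0, ncol(lp$lp1))
  if (length(i1) > 0) ll <- ll + colSums(lp$lp1[i1, , drop = FALSE])
  if (length(i0) > 0) ll <- ll + colSums(lp$lp0[i0, , drop = FALSE])
  ll
}

# Shared maximizer: log-likelihood vector over grid -> a_P and maximum.
argmax_grid_age <- function(ll, grid, tie_tol = 1e-12) {
  llmax <- max(ll)
  if (!is.finite(llmax) || anyNA(ll))
    return(list(a_P = NA_real_, max_likelihood = 0, n_tied = 0L))
  # ties within relative tolerance on the likelihood scale
  tied <- exp(ll - llmax) >= 1 - tie_tol
  list(a_P = mean(grid[tied]), max_likelihood = exp(llmax),
       n_tied = sum(tied))
}

#' Most likely age for one read pattern
#'
#' Evaluates Pr(P, a) on the age grid and assigns the pattern the age
#' that maximizes it.  When the maximum is attained at several grid
#' ages (within relative tolerance `tie_tol`), the assigned age is
#' their average, so a plateau of clipped probabilities yields its
#' midpoint.  A pattern impossible at every grid age (maximum
#' likelihood 0) gets an undefined (`NA`) age.
#'
#' @param models A `SiteModelSet`.
#' @param pattern Pattern string over `{0, 1, .}`.
#' @param grid Age grid from [age_grid()].
#' @param missing_policy See [pattern_likelihood()].
#' @param tie_tol Relative tolerance for detecting tied maxima
#'   (default 1e-12).
#' @return A `PatternAgeResult`: list with `pattern`, `a_P` (years,
#'   possibly non-integer after tie averaging, `NA` when undefined),
#'   `max_likelihood`, `n_tied`.
#' @export
predict_pattern_age <- function(models, pattern, grid = age_grid(),
                                missing_policy = c("drop", "marginalize"),
                                tie_tol = 1e-12) {
  missing_policy <- match.arg(missing_policy)
  lp <- site_log_probs(models, grid)
  calls <- pattern_call_matrix(pattern, nrow(models))[1, ]
  if (anyNA(calls) && missing_policy == "drop") {
    res <- list(a_P = NA_real_, max_likelihood = NA_real_, n_tied = 0L)
  } else {
    res <- argmax_grid_age(pattern_loglik(calls, lp), grid, tie_tol)
  }
  structure(c(list(pattern = pattern), res), class = "PatternAgeResult")
}

#' Predict donor age from a set of read patterns
#'
#' Assigns every distinct pattern its most likely age a_P and estimates
#' the donor's age as the mean of the a_P over reads, counting a
#' pattern's a_P once per occurrence.  Reads whose pattern is
#' impossible at every grid age (and, under the default missing-call
#' policy, reads with missing calls) are excluded from the mean and
#' counted.
#'
#' @param models A `SiteModelSet`.
#' @param rps A [ReadPatternSet], already filtered with
#'   [filter_rare_patterns()].
#' @param grid Age grid from [age_grid()].
#' @param missing_policy See [pattern_likelihood()].
#' @param tie_tol Tie tolerance, see [predict_pattern_age()].
#' @return List of class `SampleAgePrediction` with `sample_id`,
#'   `amplicon_id`, `predicted_age` (years; `NA` when no read has a
#'   defined age), `n_reads_used`, `n_reads_excluded`, and
#'   `patterns` — a data frame of per-pattern results (`pattern`,
#'   `count`, `a_P`, `max_likelihood`).
#' @export
predict_sample_age <- function(models, rps, grid = age_grid(),
                               missing_policy = c("drop", "marginalize"),
                               tie_tol = 1e-12) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(rps, "ReadPatternSet"))
  if (rps$n_sites != nrow(models) && length(rps$patterns) > 0)
    stop(sprintf("pattern length %d does not match %d site models",
                 rps$n_sites, nrow(models)))
  pats <- names(rps$patterns)
  counts <- as.numeric(rps$patterns)
  if (length(pats) == 0) {
    return(structure(list(sample_id = rps$sample_id,
                          amplicon_id = rps$amplicon_id,
                          predicted_age = NA_real_,
                          n_reads_used = 0L, n_reads_excluded = 0L,
                          patterns = data.frame(pattern = character(),
                                                count = integer(),
                                                a_P = numeric(),
                                                max_likelihood = numeric())),
                     class = "SampleAgePrediction"))
  }
  lp <- site_log_probs(models, grid)
  calls <- pattern_call_matrix(pats, rps$n_sites)
  a_P <- numeric(length(pats))
  maxlik <- numeric(length(pats))
  for (k in seq_along(pats)) {
    ck <- calls[k, ]
    if (anyNA(ck) && missing_policy == "drop") {
      a_P[k] <- NA_real_; maxlik[k] <- NA_real_
    } else {
      r <- argmax_grid_age(pattern_loglik(ck, lp), grid, tie_tol)
      a_P[k] <- r$a_P; maxlik[k] <- r$max_likelihood
    }
  }
  usable <- !is.na(a_P)
  pred <- if (any(usable))
    sum(a_P[usable] * counts[usable]) / sum(counts[usable]) else NA_real_
  structure(list(sample_id = rps$sample_id, amplicon_id = rps$amplicon_id,
                 predicted_age = pred,
                 n_reads_used = as.integer(sum(counts[usable])),
                 n_reads_excluded = as.integer(sum(counts[!usable])),
                 patterns = data.frame(pattern = pats, count = counts,
                                       a_P = a_P, max_likelihood = maxlik,
                                       stringsAsFactors = FALSE)),
            class = "SampleAgePrediction")
}

#' @export
print.SampleAgePrediction <- function(x, ...) {
  cat(sprintf("sample '%s', amplicon '%s': predicted age %.1f years (%d reads used, %d excluded)\n",
              x$sample_id, x$amplicon_id, x$predicted_age,
              x$n_reads_used, x$n_reads_excluded))
  invisible(x)
}

#' Distribution of per-read age predictions
#'
#' Histogram of the per-pattern ages a_P, weighted by pattern
#' multiplicity and normalized to total mass 1 per sample, over bins of
#' the age grid range.
#'
#' @param prediction A `SampleAgePrediction` (or its `patterns` data
#'   frame).
#' @param bin_width Bin width in years (default 1).
#' @param min_age,max_age Histogram range (default 0 and 200 years).
#' @return Data frame with `bin_start`, `bin_end` (half-open
#'   \[start, end), last bin closed) and `mass` summing to 1.
#' @export
read_age_distribution <- function(prediction, bin_width = 1,
                                  min_age = 0, max_age = 200) {
  df <- if (inherits(prediction, "SampleAgePrediction"))
    prediction$patterns else prediction
  ok <- !is.na(df$a_P)
  if (!any(ok)) stop("no reads with a defined age")
  breaks <- seq(min_age, max_age + bin_width, by = bin_width)
  idx <- findInterval(df$a_P[ok], breaks, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(breaks) - 1L)
  mass <- rep(0, length(breaks) - 1L)
  for (k in seq_along(idx)) mass[idx[k]] <- mass[idx[k]] + df$count[ok][k]
  mass <- mass / sum(mass)
  data.frame(bin_start = breaks[-length(breaks)],
             bin_end = breaks[-1], mass = mass)
}

#' Write site models to TSV
#'
#' @param models A `SiteModelSet`.
#' @param path Output path.
#' @export
write_site_models <- function(models, path) {
  utils::write.table(as.data.frame(models)[, c("amplicon_id", "site_index",
                                               "slope", "intercept")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read site models from TSV
#'
#' @param path Path with columns `amplicon_id`, `site_index`, `slope`,
#'   `intercept`.
#' @return A `SiteModelSet` (rows ordered by `site_index`).
#' @export
read_site_models <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("amplicon_id", "site_index", "slope", "intercept")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("site-model file is missing column(s): ", paste(miss, collapse = ", "))
  df <- df[order(df$amplicon_id, df$site_index), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("SiteModelSet", "data.frame"))
}
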