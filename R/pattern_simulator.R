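#' Derive a reproducible substream seed
#'
#' Combines a root seed with a string key (sample or study id) by a
#' stable polynomial hash, so that per-donor and per-study random
#' substreams are reproducible independent of iteration order and of
#' which subset of donors is simulated.
#'
#' @param root Integer root seed.
#' @param key Character key.
#' @return Integer seed in \[0, 2^31 - 2\].
#' @export
derive_seed <- function(root, key) {
  h <- as.double(root %% 2147483647)
  for (v in utf8ToInt(as.character(key)))
    h <- (h * 131 + v) %% 2147483647
  as.integer(h)
}

#' Simulate read patterns under independent stochastic drift
#'
#' Generates binary methylation patterns for each donor under the model
#' that each CpG site i of the amplicon is methylated independently
#' with probability clip(intercept_i + slope_i * age, 0, 1) — i.e., no
#' coordination between neighboring sites on a strand, only an
#' age-dependent marginal frequency.  Reads are aggregated into counted
#' patterns.  Fully reproducible: each donor draws from a substream
#' derived from the root seed and the donor id.
#'
#' @param models A `SiteModelSet` defining the per-site linear
#'   frequency functions.
#' @param ages Named numeric vector of donor ages (names are sample
#'   ids), all >= 0.
#' @param reads_per_donor Number of strands to simulate per donor
#'   (>= 1).
#' @param seed Integer root seed.
#' @return Named list of [ReadPatternSet], one per donor.
#' @export
simulate_reads <- function(models, ages, reads_per_donor = 1000, seed = 1) {
  stopifnot(reads_per_donor >= 1, all(ages >= 0))
  if (is.null(names(ages)))
    names(ages) <- paste0("donor", seq_along(ages))
  amp <- unique(as.character(models$amplicon_id))
  if (length(amp) != 1)
    stop("simulate_reads expects site models for a single amplicon")
  n_sites <- nrow(models)
  out <- lapply(names(ages), function(id) {
    set.seed(derive_seed(seed, paste0(amp, "|", id)))
    p <- as.vector(site_probability(models, ages[[id]]))
    draws <- matrix(stats::runif(reads_per_donor * n_sites) < rep(p, each = reads_per_donor),
                    nrow = reads_per_donor, ncol = n_sites)
    pats <- apply(draws, 1, function(b) paste(as.integer(b), collapse = ""))
    tab <- table(pats)
    ReadPatternSet(id, amp, stats::setNames(as.integer(tab), names(tab)))
  })
  stats::setNames(out, names(ages))
}

#' Simulate a multi-study beta-value collection
#'
#' Generates a [StudyCollection] for exercising the screening and clock
#' pipelines: a few planted CpGs whose beta values are linear in age,
#' the rest age-independent noise; every (study, CpG) pair receives a
#' fixed offset emulating between-dataset shifts in beta values; betas
#' are clipped to \[0, 1\] after adding Gaussian noise.
#'
#' @param n_studies Number of studies (default 7).
#' @param n_samples Samples per study (default 100).
#' @param n_cpgs Total CpGs (default 2000).
#' @param planted Data frame with one row per planted age-associated
#'   CpG: columns `slope` (beta per year), `intercept` (beta at age 0),
#'   `noise_sd`.  Default: 20 CpGs, slope 0.005, intercepts spread over
#'   \[0.1, 0.5\], noise sd 0.02.
#' @param decoy_noise_sd Noise sd of the age-independent CpGs
#'   (default 0.02).
#' @param study_offset_sd Sd of the per-(study, CpG) offset
#'   (default 0.05).
#' @param age_range Age range in years, sampled uniformly
#'   (default c(20, 80)).
#' @param age_dist `"uniform"` or `"log_uniform"` (pediatric-skewed,
#'   for exercising the age transformation).
#' @param seed Integer root seed.
#' @return A [StudyCollection]; planted CpG ids are
#'   `"cg_planted_<k>"`, decoys `"cg_decoy_<k>"`.
#' @export
simulate_study_collection <- function(n_studies = 7, n_samples = 100,
                                      n_cpgs = 2000,
                                      planted = default_planted_cpgs(),
                                      decoy_noise_sd = 0.02,
                                      study_offset_sd = 0.05,
                                      age_range = c(20, 80),
                                      age_dist = c("uniform", "log_uniform"),
                                      seed = 1) {
  age_dist <- match.arg(age_dist)
  n_planted <- nrow(planted)
  stopifnot(n_planted <= n_cpgs)
  cpg_ids <- c(sprintf("cg_planted_%03d", seq_len(n_planted)),
               sprintf("cg_decoy_%04d", seq_len(n_cpgs - n_planted)))
  set.seed(derive_seed(seed, "decoy_levels"))
  decoy_level <- stats::runif(n_cpgs - n_planted, 0.1, 0.9)

  studies <- lapply(seq_len(n_studies), function(s) {
    study_id <- sprintf("study%02d", s)
    set.seed(derive_seed(seed, study_id))
    age <- switch(age_dist,
                  uniform = stats::runif(n_samples, age_range[1], age_range[2]),
                  log_uniform = exp(stats::runif(n_samples,
                                                 log(age_range[1] + 1),
                                                 log(age_range[2] + 1))) - 1)
    offsets <- stats::rnorm(n_cpgs, 0, study_offset_sd)
    mu <- matrix(NA_real_, nrow = n_cpgs, ncol = n_samples)
    for (k in seq_len(n_planted))
      mu[k, ] <- planted$intercept[k] + planted$slope[k] * age
    if (n_cpgs > n_planted)
      mu[(n_planted + 1):n_cpgs, ] <- decoy_level
    noise_sd <- c(planted$noise_sd, rep(decoy_noise_sd, n_cpgs - n_planted))
    betas <- mu + offsets +
      matrix(stats::rnorm(n_cpgs * n_samples, 0, noise_sd),
             nrow = n_cpgs, ncol = n_samples)
    betas <- pmin(pmax(betas, 0), 1)
    sample_ids <- sprintf("%s_s%03d", study_id, seq_len(n_samples))
    dimnames(betas) <- list(cpg_ids, sample_ids)
    list(matrix = MethylationMatrix(betas),
         meta = data.frame(sample_id = sample_ids, age = age,
                           study = study_id, stringsAsFactors = FALSE))
  })
  names(studies) <- sprintf("study%02d", seq_len(n_studies))
  StudyCollection(studies)
}

#' Default planted age-associated CpGs for the study simulator
#'
#' Twenty CpGs gaining about 0.5 percentage points of methylation per
#' year (a typical effect size for strong age-associated sites in
#' blood), baseline levels spread over \[0.1, 0.5\], and measurement
#' noise of 0.02 beta units.
#'
#' @param n Number of planted CpGs (default 20).
#' @return Data frame with `slope`, `intercept`, `noise_sd`.
#' @export
default_planted_cpgs <- function(n = 20) {
  data.frame(slope = rep(0.005, n),
             intercept = seq(0.1, 0.5, length.out = n),
             noise_sd = rep(0.02, n))
}

#' Random site models for simulation studies
#'
#' Draws per-site slopes and intercepts uniformly from the given
#' ranges; used to set up amplicons for round-trip simulations.
#'
#' @param n_sites Number of CpG sites.
#' @param amplicon_id Amplicon label.
#' @param slope_range,intercept_range Sampling ranges.
#' @param seed Optional integer seed.
#' @return A `SiteModelSet`.
#' @export
random_site_models <- function(n_sites, amplicon_id = "simulated",
                               slope_range = c(0.002, 0.008),
                               intercept_range = c(0.05, 0.45),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  structure(data.frame(amplicon_id = amplicon_id,
                       site_index = seq_len(n_sites),
                       slope = stats::runif(n_sites, slope_range[1], slope_range[2]),
                       intercept = stats::runif(n_sites, intercept_range[1],
                                                intercept_range[2])),
            class = c("SiteModelSet", "data.frame"))
}
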