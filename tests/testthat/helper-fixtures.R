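# Shared fixture builders; everything is generated in code at test time.

make_rps <- function(patterns, sample_id = "S1", amplicon_id = "ELOVL2") {
  ReadPatternSet(sample_id, amplicon_id, patterns)
}

# Beta matrix where each listed CpG is an exact linear function of age.
make_linear_beta <- function(ages, slopes, intercepts,
                             cpg_prefix = "cg", sample_prefix = "s") {
  betas <- t(vapply(seq_along(slopes),
                    function(k) intercepts[k] + slopes[k] * ages,
                    numeric(length(ages))))
  stopifnot(all(betas >= 0 & betas <= 1))
  dimnames(betas) <- list(paste0(cpg_prefix, seq_along(slopes)),
                          paste0(sample_prefix, seq_along(ages)))
  MethylationMatrix(betas)
}

make_meta <- function(ages, sample_prefix = "s", study = "study1") {
  data.frame(sample_id = paste0(sample_prefix, seq_along(ages)),
             age = ages, study = study, stringsAsFactors = FALSE)
}

# Naive likelihood oracle: direct product at one age, no log space,
# independent of the package's internal likelihood path.
naive_pattern_prob <- function(models, pattern, age) {
  p <- pmin(pmax(models$intercept + models$slope * age, 0), 1)
  bits <- as.integer(strsplit(pattern, "")[[1]])
  prod(ifelse(bits == 1, p, 1 - p))
}

# Naive grid-scan age assignment with tie averaging (the brute-force
# reference for the argmax).
naive_pattern_age <- function(models, pattern, grid = 0:200,
                              tie_tol = 1e-12) {
  pr <- vapply(grid, function(a) naive_pattern_prob(models, pattern, a),
               numeric(1))
  mx <- max(pr)
  if (mx == 0) return(list(a_P = NA_real_, max_likelihood = 0))
  tied <- pr >= mx * (1 - tie_tol)
  list(a_P = mean(grid[tied]), max_likelihood = mx)
}

all_patterns <- function(n) {
  apply(expand.grid(rep(list(c("0", "1")), n))[, n:1, drop = FALSE],
        1, paste, collapse = "")
}
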