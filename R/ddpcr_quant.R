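#' Poisson channel concentrations from droplet counts
#'
#' In droplet digital PCR the template is partitioned over droplets at
#' random, so the number of target copies per droplet is Poisson
#' distributed.  A droplet is read only as positive or negative per
#' channel; the mean copies per droplet is recovered from the fraction
#' of positive droplets by the Poisson occupancy correction
#' \deqn{\lambda = -\ln(1 - p_{pos}).}
#' In the duplex assay a double-positive droplet counts as positive in
#' both channels.
#'
#' @param d A [DropletCounts] object.
#' @return A `ChannelConcentration`: list with `lambda_meth`,
#'   `lambda_unmeth` (mean copies per droplet) and `n_total`.
#' @export
channel_rates <- function(d) {
  stopifnot(inherits(d, "DropletCounts"))
  pos_meth <- d$n_meth_only + d$n_double
  pos_unmeth <- d$n_unmeth_only + d$n_double
  if (pos_meth >= d$n_total || pos_unmeth >= d$n_total)
    stop(sprintf(paste0("assay '%s': a channel has no negative droplets ",
                        "(saturated assay); dilute the sample and repeat"),
                 d$assay_id))
  structure(list(lambda_meth = -log(1 - pos_meth / d$n_total),
                 lambda_unmeth = -log(1 - pos_unmeth / d$n_total),
                 n_total = d$n_total),
            class = "ChannelConcentration")
}

#' Methylation fraction from channel concentrations
#'
#' The methylated fraction is the ratio of Poisson rates,
#' \eqn{\lambda_m / (\lambda_m + \lambda_u)}; any per-droplet volume
#' factor cancels.  Using rates rather than raw positive-droplet
#' fractions removes the bias toward 0.5 that multiple occupancy causes
#' at high template load.
#'
#' @param conc A `ChannelConcentration` from [channel_rates()].
#' @return Methylation fraction in \[0, 1\].
#' @export
methylation_fraction <- function(conc) {
  stopifnot(inherits(conc, "ChannelConcentration"))
  tot <- conc$lambda_meth + conc$lambda_unmeth
  if (tot <= 0) stop("no template detected in either channel")
  conc$lambda_meth / tot
}

#' Quantify a set of droplet assays
#'
#' Convenience wrapper running [channel_rates()] and
#' [methylation_fraction()] over a list of [DropletCounts].
#'
#' @param counts A [DropletCounts] or list of them.
#' @return Data frame with `assay_id`, `lambda_meth`, `lambda_unmeth`,
#'   `methylation_fraction`.
#' @export
quantify_droplets <- function(counts) {
  if (inherits(counts, "DropletCounts")) counts <- list(counts)
  do.call(rbind, lapply(counts, function(d) {
    conc <- channel_rates(d)
    data.frame(assay_id = d$assay_id,
               lambda_meth = conc$lambda_meth,
               lambda_unmeth = conc$lambda_unmeth,
               methylation_fraction = methylation_fraction(conc),
               stringsAsFactors = FALSE)
  }))
}

#' Simulate a duplex droplet digital PCR experiment
#'
#' Splits `total_copies` template molecules into methylated and
#' unmethylated copies at the given true fraction (deterministic split,
#' rounded), scatters every copy over the droplets uniformly at random,
#' and classifies droplets into the four duplex categories.  Serves as
#' the Monte-Carlo oracle for the Poisson occupancy correction.
#'
#' @param true_fraction Methylated fraction of template in \[0, 1\].
#' @param total_copies Total template molecules (> 0).
#' @param n_droplets Number of droplets (> 0).
#' @param seed Optional integer seed for reproducibility.
#' @param assay_id Identifier for the simulated assay.
#' @return A [DropletCounts].
#' @export
simulate_droplets <- function(true_fraction, total_copies, n_droplets,
                              seed = NULL, assay_id = "sim") {
  stopifnot(true_fraction >= 0, true_fraction <= 1,
            total_copies > 0, n_droplets > 0)
  if (!is.null(seed)) set.seed(seed)
  n_meth <- round(true_fraction * total_copies)
  n_unmeth <- total_copies - n_meth
  hit_meth <- tabulate(sample.int(n_droplets, n_meth, replace = TRUE),
                       nbins = n_droplets) > 0
  hit_unmeth <- tabulate(sample.int(n_droplets, n_unmeth, replace = TRUE),
                         nbins = n_droplets) > 0
  DropletCounts(assay_id,
                n_total = n_droplets,
                n_meth_only = sum(hit_meth & !hit_unmeth),
                n_unmeth_only = sum(!hit_meth & hit_unmeth),
                n_double = sum(hit_meth & hit_unmeth))
}

#' Bootstrap interval for the methylation fraction
#'
#' Seeded nonparametric bootstrap over droplets: resamples the four
#' classification counts from their multinomial proportions and
#' recomputes the corrected fraction.  Off by default in the
#' command-line tool; vendor confidence models are proprietary and are
#' not reproduced here.
#'
#' @param d A [DropletCounts].
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param level Interval coverage (default 0.95).
#' @param seed Optional integer seed.
#' @return List with `estimate`, `lower`, `upper`, `n_boot`.
#' @export
methylation_fraction_ci <- function(d, n_boot = 1000, level = 0.95,
                                    seed = NULL) {
  stopifnot(inherits(d, "DropletCounts"))
  if (!is.null(seed)) set.seed(seed)
  probs <- c(d$n_meth_only, d$n_unmeth_only, d$n_double, d$n_negative) /
    d$n_total
  est <- methylation_fraction(channel_rates(d))
  reps <- vapply(seq_len(n_boot), function(i) {
    k <- as.vector(stats::rmultinom(1, d$n_total, probs))
    db <- DropletCounts(d$assay_id, d$n_total, k[1], k[2], k[3], k[4])
    tryCatch(methylation_fraction(channel_rates(db)), error = function(e) NA_real_)
  }, numeric(1))
  alpha <- (1 - level) / 2
  qs <- stats::quantile(reps, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  list(estimate = est, lower = qs[1], upper = qs[2], n_boot = n_boot)
}
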