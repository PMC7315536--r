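#' Logarithmic age transformation
#'
#' Chronological age is transformed before clock fitting so that the
#' rapid methylation changes of childhood are modelled on a log scale
#' while adult ages remain linear.  With adult age A (20 years by
#' default):
#' \deqn{F(age) = \ln(age + 1) - \ln(A + 1), \quad age \le A}
#' \deqn{F(age) = (age - A) / (A + 1), \quad age > A}
#' The two branches meet at `age = A` where both give 0; the function is
#' continuous and strictly increasing.
#'
#' @param age Ages in years (vectorized); must be non-negative.
#' @param adult_age Branch point in years (default 20).
#' @return Transformed ages (dimensionless).
#' @seealso [inverse_transform_age()]
#' @export
transform_age <- function(age, adult_age = 20) {
  stopifnot(adult_age > 0)
  if (any(is.na(age))) stop("age must not be missing")
  if (any(age < 0)) stop("age must be non-negative")
  ifelse(age <= adult_age,
         log(age + 1) - log(adult_age + 1),
         (age - adult_age) / (adult_age + 1))
}

#' Invert the age transformation
#'
#' Maps a transformed age back to years:
#' \deqn{age = (1 + A)\,e^{y} - 1, \quad y < 0}
#' \deqn{age = (1 + A)\,y + A, \quad y \ge 0}
#' Exact inverse of [transform_age()] on the whole non-negative age
#' range.
#'
#' @param y Transformed ages (vectorized, finite).
#' @param adult_age Branch point in years (default 20).
#' @return Ages in years.
#' @export
inverse_transform_age <- function(y, adult_age = 20) {
  stopifnot(adult_age > 0)
  ifelse(y < 0,
         (1 + adult_age) * exp(y) - 1,
         (1 + adult_age) * y + adult_age)
}

#' Fit a multivariable linear epigenetic clock
#'
#' Ordinary least squares of (optionally transformed) chronological age
#' on the beta values of the listed CpGs.  Samples missing any of the
#' CpG betas or age are dropped and counted; a rank-deficient design is
#' an error naming the collinear CpGs.
#'
#' @param matrix [MethylationMatrix] (CpGs x samples).
#' @param meta Sample metadata with `sample_id` and `age`.
#' @param cpgs CpG ids to use as predictors (all must be present).
#' @param uses_transform Fit on `transform_age(age)` and invert at
#'   prediction time (default `TRUE`).
#' @param adult_age Branch point of the transformation (default 20).
#' @return A `LinearClock`: list with `intercept`, `coefficients`
#'   (named), `uses_transform`, `adult_age`, `n_used`, `n_dropped`.
#' @export
fit_linear_clock <- function(matrix, meta, cpgs, uses_transform = TRUE,
                             adult_age = 20) {
  m <- as_beta_matrix(matrix)
  meta <- validate_sample_metadata(meta)
  missing_cpgs <- setdiff(cpgs, rownames(m))
  if (length(missing_cpgs) > 0)
    stop("CpGs absent from matrix: ", paste(missing_cpgs, collapse = ", "))
  idx <- match(colnames(m), meta$sample_id)
  if (anyNA(idx)) stop("samples without metadata: ",
                       paste(colnames(m)[is.na(idx)], collapse = ", "))
  age <- meta$age[idx]
  X <- t(m[cpgs, , drop = FALSE])
  complete <- !is.na(age) & rowSums(is.na(X)) == 0
  n_used <- sum(complete)
  if (n_used < length(cpgs) + 1)
    stop(sprintf("need more complete samples (%d) than coefficients (%d)",
                 n_used, length(cpgs) + 1))
  if (n_used <= 2 * length(cpgs))
    warning("fewer than twice as many samples as CpGs; fit may be unstable")
  X <- X[complete, , drop = FALSE]
  y <- if (uses_transform) transform_age(age[complete], adult_age)
       else age[complete]
  fit <- stats::lm(y ~ X)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    bad <- sub("^X", "", names(cf)[is.na(cf)])
    stop("singular design; collinear CpGs: ", paste(bad, collapse = ", "))
  }
  structure(list(intercept = unname(cf[1]),
                 coefficients = stats::setNames(unname(cf[-1]), cpgs),
                 uses_transform = uses_transform,
                 adult_age = adult_age,
                 n_used = n_used,
                 n_dropped = length(age) - n_used),
            class = "LinearClock")
}

#' @export
print.LinearClock <- function(x, ...) {
  cat(sprintf("LinearClock: %d CpGs, intercept %.4g, %s age scale\n",
              length(x$coefficients), x$intercept,
              if (x$uses_transform) "transformed" else "raw"))
  invisible(x)
}

#' Predict epigenetic age from beta values
#'
#' Applies the linear combination of the clock and, when the clock was
#' fit on transformed age, inverts the transformation.  Predictions are
#' not clipped by default: a clock may legitimately return slightly
#' negative ages for very young profiles.  Samples missing any clock
#' CpG get `NA` and are counted in the `n_incomplete` attribute.
#'
#' @param clock A `LinearClock`.
#' @param matrix [MethylationMatrix] with the clock CpGs in its rows.
#' @param clip_negative If `TRUE`, clip predictions at 0 years.
#' @return Named numeric vector of predicted ages (years), one per
#'   sample, with attribute `n_incomplete`.
#' @export
predict_age <- function(clock, matrix, clip_negative = FALSE) {
  stopifnot(inherits(clock, "LinearClock"))
  m <- as_beta_matrix(matrix)
  cpgs <- names(clock$coefficients)
  missing_cpgs <- setdiff(cpgs, rownames(m))
  if (length(missing_cpgs) > 0)
    stop("clock CpGs absent from matrix: ",
         paste(missing_cpgs, collapse = ", "))
  B <- m[cpgs, , drop = FALSE]
  lin <- clock$intercept + as.vector(crossprod(B, clock$coefficients))
  incomplete <- colSums(is.na(B)) > 0
  lin[incomplete] <- NA_real_
  pred <- if (clock$uses_transform)
    inverse_transform_age(lin, clock$adult_age) else lin
  if (clip_negative) pred <- pmax(pred, 0)
  names(pred) <- colnames(m)
  attr(pred, "n_incomplete") <- sum(incomplete)
  pred
}

#' Evaluate age predictions against chronological age
#'
#' The two reported metrics of this literature: the squared Pearson
#' correlation of predicted vs chronological age (as annotated on
#' scatterplots, not a refit regression R-squared) and the median
#' absolute error in years.  Pairs with a missing value are dropped.
#'
#' @param predicted,actual Paired numeric vectors (>= 2 complete pairs).
#' @return A `ClockEvaluation`: list with `r_squared`,
#'   `median_abs_error`, `n`.
#' @export
evaluate_predictions <- function(predicted, actual) {
  if (length(predicted) != length(actual))
    stop("predicted and actual must have equal length")
  ok <- !is.na(predicted) & !is.na(actual)
  if (sum(ok) < 2) stop("need at least 2 complete prediction pairs")
  p <- predicted[ok]; a <- actual[ok]
  r2 <- if (stats::var(p) == 0 || stats::var(a) == 0) NA_real_
        else stats::cor(p, a)^2
  structure(list(r_squared = r2,
                 median_abs_error = stats::median(abs(p - a)),
                 n = sum(ok)),
            class = "ClockEvaluation")
}

#' @export
print.ClockEvaluation <- function(x, ...) {
  cat(sprintf("n = %d, r^2 = %.3f, median error = %.2f years\n",
              x$n, x$r_squared, x$median_abs_error))
  invisible(x)
}

#' Write a clock model to TSV
#'
#' Layout mirrors published coefficient tables: header comment lines
#' carry the transformation settings, then rows of `term` and `weight`
#' with the reserved term `(Intercept)`.
#'
#' @param clock A `LinearClock`.
#' @param path Output path.
#' @export
write_clock <- function(clock, path) {
  stopifnot(inherits(clock, "LinearClock"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# uses_transform=%s", clock$uses_transform),
               sprintf("# adult_age=%g", clock$adult_age),
               "term\tweight"), con)
  df <- data.frame(term = c("(Intercept)", names(clock$coefficients)),
                   weight = c(clock$intercept, unname(clock$coefficients)))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a clock model from TSV
#'
#' @param path Path written by [write_clock()] or a transcribed
#'   coefficient table in the same layout.
#' @return A `LinearClock`.
#' @export
read_clock <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get_hdr <- function(key, default) {
    hit <- grep(paste0("^#\\s*", key, "="), hdr, value = TRUE)
    if (length(hit) == 0) return(default)
    sub(paste0("^#\\s*", key, "="), "", hit[1])
  }
  uses_transform <- as.logical(get_hdr("uses_transform", "TRUE"))
  adult_age <- as.numeric(get_hdr("adult_age", "20"))
  df <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                          sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("term", "weight") %in% names(df)))
    stop("clock file needs columns term, weight: ", path)
  ic <- df$term == "(Intercept)"
  if (sum(ic) != 1) stop("clock file needs exactly one (Intercept) row")
  structure(list(intercept = df$weight[ic],
                 coefficients = stats::setNames(df$weight[!ic], df$term[!ic]),
                 uses_transform = uses_transform,
                 adult_age = adult_age,
                 n_used = NA_integer_, n_dropped = NA_integer_),
            class = "LinearClock")
}
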