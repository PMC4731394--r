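#' Run an evaluation suite over synthetic configurations
#'
#' For each configuration x replicate: generate a planted-partition network,
#' compute the VA-index alpha and the per-dimension baseline r_base, and
#' record the absolute-error difference
#' \code{delta_e = |r_true - alpha| - |r_true - r_base|} (negative values
#' mean the VA-index recovered the ground truth better). Per-network failures
#' are recorded in the \code{error} column, not fatal.
#'
#' @param configs a [SyntheticConfig] or list of them; names (or list
#'   indices) become the \code{config} column.
#' @param replicates replicates per configuration; default 1.
#' @param similarity,scheme,B,epsilon,sigLevel passed to [computeVAIndex()];
#'   \code{scheme} may be a [RandomizationScheme] or one of \code{"gnm"},
#'   \code{"degree"}.
#' @param seed master seed; per-run seeds are derived from it, so the whole
#'   suite is reproducible.
#' @return a data.frame with one row per run: \code{config, replicate, seed,
#'   r_true, alpha, r_base, delta_e, p_value, verdict, error}.
#' @examples
#' cfg <- syntheticConfig(n = 40, targetM = 80, q = 3, pIn = 0.9, pOut = 0.1)
#' runSuite(cfg, replicates = 2, B = 50, seed = 1)
#' @export
runSuite <- function(configs, replicates = 1, similarity = "cosine",
                     scheme = "gnm", B = 1000, epsilon = 1, sigLevel = 0.05,
                     seed = NULL) {
  if (is(configs, "SyntheticConfig")) configs <- list(configs)
  stopifnot(length(configs) >= 1, replicates >= 1)
  seed <- .resolveSeed(seed)
  ids <- names(configs)
  if (is.null(ids)) ids <- as.character(seq_along(configs))
  nRuns <- length(configs) * replicates
  runSeeds <- withr::with_seed(seed,
    matrix(sample.int(.Machine$integer.max - 1L, 2L * nRuns), ncol = 2L))
  rows <- vector("list", nRuns)
  run <- 0L
  for (ci in seq_along(configs)) {
    for (rep in seq_len(replicates)) {
      run <- run + 1L
      genSeed <- runSeeds[run, 1L]
      vaSeed <- runSeeds[run, 2L]
      rec <- data.frame(config = ids[ci], replicate = rep, seed = genSeed,
                        r_true = NA_real_, alpha = NA_real_,
                        r_base = NA_real_, delta_e = NA_real_,
                        p_value = NA_real_, verdict = NA_character_,
                        error = NA_character_, stringsAsFactors = FALSE)
      res <- tryCatch({
        net <- generateNetwork(configs[[ci]], seed = genSeed)
        sch <- .resolveScheme(scheme, net@graph)
        va <- computeVAIndex(net@graph, similarity = similarity, scheme = sch,
                             B = B, epsilon = epsilon, sigLevel = sigLevel,
                             seed = vaSeed)
        rb <- suppressWarnings(baselineVectorAssortativity(net@graph))
        rec$r_true <- net@rTrue
        rec$alpha <- va@alpha
        rec$r_base <- rb
        rec$delta_e <- abs(net@rTrue - va@alpha) - abs(net@rTrue - rb)
        rec$p_value <- va@pValue
        rec$verdict <- va@verdict
        rec
      }, error = function(e) {
        rec$error <- conditionMessage(e)
        rec
      })
      rows[[run]] <- res
    }
  }
  do.call(rbind, rows)
}

.resolveScheme <- function(scheme, graph) {
  if (is(scheme, "RandomizationScheme")) return(scheme)
  switch(match.arg(scheme, c("gnm", "degree")),
         gnm = gnmScheme(),
         degree = degreeSwapScheme())
}

#' Root mean square error of an estimator against the ground truth
#'
#' \code{sqrt(mean((r_true - estimate)^2))} over the suite records. Rows with
#' a recorded error (NA estimates) are dropped with a warning.
#'
#' @param records data.frame from [runSuite()].
#' @param estimator \code{"alpha"} (the VA-index) or \code{"r_base"} (the
#'   per-dimension baseline).
#' @return the RMSE.
#' @export
rmse <- function(records, estimator = c("alpha", "r_base")) {
  estimator <- match.arg(estimator)
  if (NROW(records) < 1L) stop("no records", call. = FALSE)
  est <- records[[estimator]]
  ok <- !is.na(est) & !is.na(records$r_true)
  if (!any(ok)) stop("no usable records", call. = FALSE)
  if (!all(ok)) warning(sum(!ok), " failed record(s) dropped from the RMSE")
  sqrt(mean((records$r_true[ok] - est[ok])^2))
}

#' Two-sided t-test of the mean absolute-error difference
#'
#' One-sample two-sided t-test of \code{delta_e} against 0. Rejection with a
#' negative mean indicates the VA-index recovers the ground-truth
#' assortativity with smaller absolute error than the baseline, on average.
#'
#' @param records data.frame from [runSuite()] (or a numeric vector of
#'   delta_e values).
#' @return list with \code{meanDeltaE}, \code{tStatistic}, \code{pValue} and
#'   a \code{degenerate} flag (TRUE when delta_e has zero variance, in which
#'   case the t-statistic and p-value are NA).
#' @export
deltaETest <- function(records) {
  de <- if (is.data.frame(records)) records$delta_e else as.numeric(records)
  de <- de[!is.na(de)]
  if (length(de) < 2L) stop("need at least 2 delta_e values", call. = FALSE)
  if (stats::var(de) == 0)
    return(list(meanDeltaE = mean(de), tStatistic = NA_real_,
                pValue = NA_real_, degenerate = TRUE))
  tt <- stats::t.test(de, mu = 0, alternative = "two.sided")
  list(meanDeltaE = unname(tt$estimate), tStatistic = unname(tt$statistic),
       pValue = tt$p.value, degenerate = FALSE)
}

#' Bias, variance and mean square error of an estimator
#'
#' \code{bias = mean(estimates) - theta}; \code{variance} is the sample
#' variance (denominator count - 1); \code{mse = variance + bias^2}, i.e. the
#' decomposition identity is enforced rather than recomputed from squared
#' errors (the direct mean of squared errors differs by the (n-1)/n variance
#' scaling).
#'
#' @param estimates numeric vector of repeated estimates (length >= 2).
#' @param theta the true value being estimated.
#' @return list with \code{bias}, \code{variance}, \code{mse}.
#' @examples
#' biasVariance(c(0.5, 1.5), theta = 1)  # bias 0, variance 0.5, mse 0.5
#' @export
biasVariance <- function(estimates, theta) {
  estimates <- as.numeric(estimates)
  if (length(estimates) < 2L) stop("need at least 2 estimates", call. = FALSE)
  if (!all(is.finite(estimates)) || !is.finite(theta))
    stop("estimates and theta must be finite", call. = FALSE)
  bias <- mean(estimates) - theta
  v <- stats::var(estimates)
  list(bias = bias, variance = v, mse = v + bias^2)
}
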