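# Physiological traits: germination summaries, longevity (P50) from storage
# viability curves, and the RFO/Suc sugar ratio.

#' Estimate P50 from a storage loss-of-viability curve
#'
#' Fits G(t) = G0 / (1 + exp((t - m) / s)) by binomial maximum likelihood on
#' the pooled replicate counts (a logistic GLM of germination on storage
#' time). P50 is the time at which the fitted curve crosses half of the
#' fitted initial viability (viability at the earliest observed time); this
#' anchoring makes the estimator exactly equivariant to time shifts. If the
#' GLM fails to converge, the estimate falls back to linear interpolation of
#' the pooled observed proportions at half the initial observed proportion,
#' taking the earliest crossing. If germination never falls below half its
#' initial value within the observed range, the estimate is censored and
#' reported as a lower bound at max(t).
#'
#' @param curve data.frame with columns `time_d`, `n_seeds`, `n_germinated`
#'   (replicate rows allowed); a `stage` column, if present, labels the
#'   output.
#' @return data.frame (one row): stage, p50, scale, censored, method,
#'   deviance. For censored fits `p50` is max(t) and `method` is "censored".
#' @export
estimate_p50 <- function(curve) {
  stopifnot(all(c("time_d", "n_seeds", "n_germinated") %in% names(curve)))
  if (any(curve$time_d < 0)) stop("storage times must be non-negative")
  if (any(curve$n_germinated > curve$n_seeds) || any(curve$n_germinated < 0)) {
    stop("germinated counts must lie in [0, n_seeds]")
  }
  times <- sort(unique(curve$time_d))
  if (length(times) < 2) stop("need at least 2 distinct storage times")
  stage <- if ("stage" %in% names(curve)) as.character(curve$stage[1]) else NA

  # pooled proportions per time
  g <- tapply(curve$n_germinated, curve$time_d, sum)[as.character(times)]
  n <- tapply(curve$n_seeds, curve$time_d, sum)[as.character(times)]
  prop <- as.numeric(g / n)
  t0 <- times[1]
  if (prop[1] == 0) stop("no germination at the initial time: non-viable lot")

  fit <- suppressWarnings(try(stats::glm(
    cbind(n_germinated, n_seeds - n_germinated) ~ time_d,
    family = stats::binomial(), data = curve), silent = TRUE))

  res <- function(p50, scale, censored, method, deviance) {
    data.frame(stage = stage, p50 = p50, scale = scale, censored = censored,
               method = method, deviance = deviance,
               stringsAsFactors = FALSE)
  }

  if (!inherits(fit, "try-error") && fit$converged &&
      is.finite(stats::coef(fit)[2]) && stats::coef(fit)[2] < 0) {
    b0 <- stats::coef(fit)[1]; b1 <- stats::coef(fit)[2]
    m <- -b0 / b1        # absolute 50% midpoint of the logistic
    s <- -1 / b1         # logistic scale (days)
    # time where fitted q(t) = q(t0) / 2:
    # q(t) = 1/(1+e^{(t-m)/s}); solving gives t = m + s*log(1 + 2 e^{(t0-m)/s})
    p50 <- m + s * log1p(2 * exp((t0 - m) / s))
    if (p50 > max(times)) {
      return(res(max(times), s, TRUE, "censored", stats::deviance(fit)))
    }
    return(res(unname(p50), unname(s), FALSE, "logistic-mle",
               stats::deviance(fit)))
  }

  # interpolation fallback on pooled observed proportions
  half <- prop[1] / 2
  below <- which(prop <= half)
  if (!length(below)) {
    return(res(max(times), NA_real_, TRUE, "censored", NA_real_))
  }
  i <- below[1]
  if (i == 1) {
    p50 <- times[1]
  } else {
    p50 <- times[i - 1] + (prop[i - 1] - half) /
      (prop[i - 1] - prop[i]) * (times[i] - times[i - 1])
  }
  res(p50, NA_real_, FALSE, "interpolation", NA_real_)
}

#' Per-stage P50 table from a germination assay table
#'
#' Applies [estimate_p50()] to every stage of a long-format germination
#' table (as produced by [generate_viability_curves()] or read from
#' germination.csv).
#'
#' @param germination data.frame with columns stage, time_d, replicate,
#'   n_seeds, n_germinated.
#' @return data.frame with one row per stage (stage, p50, scale, censored,
#'   method, deviance).
#' @export
p50_table <- function(germination) {
  out <- do.call(rbind, lapply(split(germination, germination$stage),
                               estimate_p50))
  out <- out[order(match(out$stage, unique(germination$stage))), ]
  rownames(out) <- NULL
  out
}

#' Germination summary: mean percentage and standard error over replicates
#'
#' Each replicate contributes 100 * n_germinated / n_seeds; the summary is
#' the mean and SE over replicates. Also services the desiccation-tolerance
#' readout (germination after fast drying to 10\% moisture).
#'
#' @param n_germinated Integer vector of germinated counts per replicate.
#' @param n_seeds Seeds per replicate (scalar or vector).
#' @return List with `mean_pct` and `se_pct` (NA when a single replicate).
#' @export
germination_summary <- function(n_germinated, n_seeds) {
  if (length(n_germinated) == 0) stop("no replicates")
  pct <- 100 * n_germinated / n_seeds
  se <- if (length(pct) > 1) stats::sd(pct) / sqrt(length(pct)) else NA_real_
  list(mean_pct = mean(pct), se_pct = se)
}

#' RFO/Suc ratio
#'
#' Ratio of raffinose family oligosaccharides (raffinose + stachyose +
#' verbascose) to sucrose; the sugar-based indicator of longevity
#' acquisition. Undefined (NA with a warning) when sucrose is zero.
#'
#' @param raf,sta,ver,suc Concentrations (mg per g DW); vectorized.
#' @return Numeric ratio vector.
#' @export
rfo_suc_ratio <- function(raf, sta, ver, suc) {
  out <- (raf + sta + ver) / suc
  bad <- suc == 0
  if (any(bad)) {
    warning("RFO/Suc undefined where sucrose is zero")
    out[bad] <- NA_real_
  }
  out
}
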