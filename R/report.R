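# Comparison and descriptive-statistics utilities.

#' Relative error between the full and a variant CSM
#'
#' `100 * |s_full - s_variant| / s_full`, the percentage by which a
#' baseline strategy (sequence-ordered or greedy) misses the optimal
#' (Hungarian, many-chains) value.
#'
#' @param sFull CSM from the full algorithm (must be > 0 for a defined
#'   value).
#' @param sVariant CSM from the variant.
#' @return percentage >= 0; NaN with a warning when `sFull` is 0 (such
#'   records are excluded from aggregate statistics).
#' @examples
#' relativeError(0.0001, 0.0004)  # 300
#' @export
relativeError <- function(sFull, sVariant) {
  if (sFull == 0) {
    warning("relative error undefined for sFull = 0; returning NaN")
    return(NaN)
  }
  100 * abs(sFull - sVariant) / sFull
}

#' Descriptive statistics of a set of CSM values
#'
#' The summary layout used for sets of homomers: N, mean, sample
#' standard deviation, standard error of the mean, minimum, median,
#' maximum.
#'
#' @param values non-empty numeric vector of CSM values.
#' @return data.frame with one row.
#' @examples
#' batchStats(c(1, 2, 3))
#' @export
batchStats <- function(values) {
  if (!length(values)) stop("empty value list")
  n <- length(values)
  s <- if (n > 1L) stats::sd(values) else NA_real_
  data.frame(n = n, mean = mean(values), sd = s,
             se = if (n > 1L) s / sqrt(n) else NA_real_,
             min = min(values), median = stats::median(values),
             max = max(values))
}

#' Compare assignment strategies on one structure
#'
#' Solves the CSM with the full algorithm (Hungarian, many chains) and
#' with the requested variant(s), and reports the relative error of each
#' variant.
#'
#' @param structure a prepared [ProteinStructure-class].
#' @param group a [PointGroup-class] or label.
#' @param variants character subset of c("sequence", "greedy").
#' @param config base [csmConfig()]; its `strategy` field is overridden.
#' @return data.frame with columns `strategy`, `s`,
#'   `relative_error_percent` (NA for the full run).
#' @export
compareStrategies <- function(structure, group,
                              variants = c("sequence", "greedy"),
                              config = csmConfig()) {
  variants <- match.arg(variants, several.ok = TRUE)
  partition <- buildPartition(structure)
  cfg <- config
  cfg$strategy <- "hungarian"
  cfg$manyChains <- TRUE
  full <- solveCSM(structure, group, cfg, partition)
  rows <- data.frame(strategy = "hungarian", s = full@sValue,
                     relative_error_percent = NA_real_,
                     stringsAsFactors = FALSE)
  for (v in variants) {
    cfg$strategy <- v
    res <- solveCSM(structure, group, cfg, partition)
    err <- if (full@sValue > 0)
      relativeError(full@sValue, res@sValue) else NaN
    rows <- rbind(rows, data.frame(strategy = v, s = res@sValue,
                                   relative_error_percent = err,
                                   stringsAsFactors = FALSE))
  }
  rows
}
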