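#' Co-occurrence-aware enrichment analysis
#'
#' Tests whether annotations are over-represented in a selected cohort
#' relative to a background. For each tested ID y with background frequency
#' f(y) over a universe of size N, the unadjusted expected count in a cohort
#' of size n is n * f(y)/N and the p-value is the upper hypergeometric tail
#' P(observed >= k) of drawing the cohort from the background.
#'
#' When the cohort was itself selected on an annotation x, annotations that
#' co-occur with x are expected more often than their background rate. Given
#' the co-frequency matrix and the conditioning ID, the expected count is
#' raised to the conditional rate n * f(x,y)/f(x) and the p-value is
#' recomputed as the upper binomial tail at that rate, increasing the
#' expectedness of dependent annotations and making their enrichment less
#' significant. P-values are corrected for multiple testing across the
#' tested IDs by Benjamini-Hochberg.
#'
#' @param observed named integer vector: tested ID (as name) -> observed
#'   count of cohort members carrying the annotation.
#' @param selectedSize cohort size n (must be <= background N).
#' @param background a \code{\linkS4class{SingletonCounts}} over the
#'   reference universe.
#' @param adjustWith optional \code{\linkS4class{CoFrequencyMatrix}} sharing
#'   the background's mode/width/level/N, used for the dependency
#'   adjustment.
#' @param conditioningId the ID x the cohort was selected on (required with
#'   \code{adjustWith}).
#' @return data.frame with one row per tested ID: \code{id},
#'   \code{observed}, \code{expected}, \code{fold}, \code{p_value} (upper
#'   tail), \code{adjusted_expected}, \code{adjusted_p} (NA when no
#'   adjustment was requested), and BH-corrected \code{q_value} /
#'   \code{adjusted_q}.
#' @export
enrichment <- function(observed, selectedSize, background,
                       adjustWith = NULL, conditioningId = NULL) {
  stopifnot(is(background, "SingletonCounts"), length(selectedSize) == 1L)
  N <- background@N
  if (selectedSize > N)
    stop("selectedSize exceeds the background universe size N")
  ids <- as.integer(names(observed))
  if (anyNA(ids)) stop("observed must be named by integer IDs")
  bg <- background@counts
  fy <- bg$count[match(ids, bg$id)]
  if (anyNA(fy))
    stop("tested ID absent from background counts: ", ids[is.na(fy)][1])
  k <- as.integer(observed)
  if (any(k > fy) || any(k > selectedSize))
    stop("observed count exceeds its background frequency or the cohort size")
  expected <- selectedSize * fy / N
  fold <- ifelse(expected > 0, k / expected, NA_real_)
  p <- stats::phyper(k - 1L, fy, N - fy, selectedSize, lower.tail = FALSE)
  adjExpected <- rep(NA_real_, length(ids))
  adjP <- rep(NA_real_, length(ids))
  if (!is.null(adjustWith)) {
    if (is.null(conditioningId))
      stop("conditioningId is required together with adjustWith")
    checkCompatible(adjustWith, background)
    x <- as.integer(conditioningId)
    prs <- adjustWith@pairs
    hit <- prs$id_x == x | prs$id_y == x
    if (!any(hit))
      stop("conditioning ID ", x, " absent from the co-frequency matrix")
    fx <- bg$count[match(x, bg$id)]
    if (is.na(fx) || fx == 0)
      stop("conditioning ID ", x, " absent from background counts")
    other <- ifelse(prs$id_x[hit] == x, prs$id_y[hit], prs$id_x[hit])
    fxy <- stats::setNames(prs$count[hit], other)
    rate <- unname(fxy[as.character(ids)]) / fx
    rate[is.na(rate)] <- 0
    rate <- pmin(rate, 1)
    adjExpected <- selectedSize * rate
    adjP <- stats::pbinom(k - 1L, selectedSize, rate, lower.tail = FALSE)
  }
  out <- data.frame(id = ids, observed = k, expected = expected, fold = fold,
                    p_value = p, adjusted_expected = adjExpected,
                    adjusted_p = adjP)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$adjusted_q <- if (all(is.na(adjP))) NA_real_ else
    stats::p.adjust(out$adjusted_p, method = "BH")
  out
}
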