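#' Build a 2-by-2 contingency table from frequency counts
#'
#' Given the frequencies f(X), f(Y), the co-frequency f(X,Y) and the
#' universe size N (number of bins at the relevant width, or number of
#' patients for per-patient counts — in which case N is the patient count,
#' i.e. the infinite-width bin count), fills the table as A = f(X,Y),
#' B = f(X) - f(X,Y), C = f(Y) - f(X,Y), D = N - [f(X) + f(Y)] + f(X,Y).
#'
#' @param fX,fY,fXY non-negative counts with fXY <= min(fX, fY) <= N.
#' @param N universe size.
#' @return a \code{\linkS4class{ContingencyTable}}.
#' @examples
#' tableCells(contingencyTable(30, 40, 10, 100))   # A=10 B=20 C=30 D=40
#' @export
contingencyTable <- function(fX, fY, fXY, N) {
  vals <- c(fX = fX, fY = fY, fXY = fXY, N = N)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("counts must be finite and non-negative")
  if (fXY > min(fX, fY) || max(fX, fY) > N || fX + fY - fXY > N)
    stop(sprintf(
      "inconsistent counts: f(X)=%g, f(Y)=%g, f(X,Y)=%g, N=%g violate f(X,Y) <= min(f(X), f(Y)) and f(X)+f(Y)-f(X,Y) <= N",
      fX, fY, fXY, N))
  # do.call so the C slot cannot partially match new()'s Class argument
  do.call(methods::new, list(Class = "ContingencyTable",
                             A = fXY, B = fX - fXY, C = fY - fXY,
                             D = N - (fX + fY) + fXY, N = N))
}

#' Association statistics from a 2-by-2 table
#'
#' Computes the classical association measures over the table: odds ratio
#' OR = AD/BC, relative risk RR = [A/(A+B)] / [C/(C+D)], the chi-squared
#' statistic sum (O-E)^2/E with expected cells derived from the margins, the
#' G statistic 2 * sum O log(O/E) (taking 0 log 0 = 0), and the Bayesian
#' quantities P(X) = f(X)/N, P(Y) = f(Y)/N, P(X,Y) = f(X,Y)/N,
#' P(Y|X) = P(X,Y)/P(X) and Lift(X->Y) = P(Y|X)/P(Y).
#'
#' A statistic whose denominator is zero is reported as NA with a reason
#' code rather than as infinity, unless \code{continuityCorrection = TRUE},
#' in which case the Haldane correction (+0.5 on every cell) is applied
#' before OR/RR/chi-squared/G are computed (probabilities and lift always
#' use the uncorrected cells).
#'
#' @param table a \code{\linkS4class{ContingencyTable}}.
#' @param continuityCorrection logical (default FALSE).
#' @return named list with elements \code{odds_ratio}, \code{relative_risk},
#'   \code{chi_squared}, \code{g_statistic}, \code{p_marginal_x},
#'   \code{p_marginal_y}, \code{p_joint}, \code{p_y_given_x}, \code{lift}
#'   and a character vector \code{undefined} of reason codes for statistics
#'   reported as NA.
#' @examples
#' associationStats(contingencyTable(30, 40, 10, 100))$odds_ratio  # 10*40/(20*30)
#' @export
associationStats <- function(table, continuityCorrection = FALSE) {
  stopifnot(is(table, "ContingencyTable"))
  A <- table@A; B <- table@B; C <- table@C; D <- table@D; N <- table@N
  undefined <- character()
  a <- A; b <- B; c_ <- C; d <- D
  if (continuityCorrection) {
    a <- A + 0.5; b <- B + 0.5; c_ <- C + 0.5; d <- D + 0.5
  }
  oddsRatio <- if (b * c_ == 0) {
    undefined <- c(undefined, "odds_ratio: zero B*C denominator")
    NA_real_
  } else (a * d) / (b * c_)
  rr <- if ((a + b) == 0 || (c_ + d) == 0 || c_ == 0) {
    undefined <- c(undefined, "relative_risk: zero denominator")
    NA_real_
  } else (a / (a + b)) / (c_ / (c_ + d))
  O <- c(a, b, c_, d)
  n2 <- sum(O)
  E <- c((a + b) * (a + c_), (a + b) * (b + d),
         (c_ + d) * (a + c_), (c_ + d) * (b + d)) / n2
  if (any(E == 0)) {
    undefined <- c(undefined, "chi_squared: zero expected cell")
    chi2 <- NA_real_
    g <- NA_real_
  } else {
    chi2 <- sum((O - E)^2 / E)
    terms <- ifelse(O == 0, 0, O * log(O / E))
    g <- 2 * sum(terms)
  }
  pX <- (A + B) / N
  pY <- (A + C) / N
  pJoint <- A / N
  pYgivenX <- if (pX == 0) {
    undefined <- c(undefined, "p_y_given_x: P(X) = 0")
    NA_real_
  } else pJoint / pX
  lift <- if (pX == 0 || pY == 0) {
    undefined <- c(undefined, "lift: zero marginal")
    NA_real_
  } else pYgivenX / pY
  list(odds_ratio = oddsRatio, relative_risk = rr, chi_squared = chi2,
       g_statistic = g, p_marginal_x = pX, p_marginal_y = pY,
       p_joint = pJoint, p_y_given_x = pYgivenX, lift = lift,
       undefined = undefined)
}

#' Lift of every pair in a co-frequency matrix
#'
#' Lift(X,Y) = P(X,Y) / (P(X) P(Y)) = N f(X,Y) / (f(X) f(Y)), computed with
#' the shared universe size of the matrix and singletons; equals 1 under
#' independence and is symmetric in X and Y.
#'
#' @param matrix a \code{\linkS4class{CoFrequencyMatrix}}.
#' @param singletons a \code{\linkS4class{SingletonCounts}} with matching
#'   mode, width, level and N.
#' @return data.frame (id_x, id_y, count, lift).
#' @export
pairLift <- function(matrix, singletons) {
  checkCompatible(matrix, singletons)
  p <- matrix@pairs
  s <- singletons@counts
  fx <- s$count[match(p$id_x, s$id)]
  fy <- s$count[match(p$id_y, s$id)]
  if (anyNA(fx) || anyNA(fy))
    stop("pair references an ID absent from the singleton counts")
  p$lift <- as.numeric(matrix@N) * p$count / (as.numeric(fx) * fy)
  p
}

checkCompatible <- function(matrix, singletons) {
  if (matrix@N != singletons@N)
    stop(sprintf("universe size mismatch: matrix N=%d, singletons N=%d",
                 matrix@N, singletons@N))
  if (matrix@mode != singletons@mode || matrix@level != singletons@level)
    stop("matrix and singletons must share aggregation mode and ID level")
  invisible(TRUE)
}

#' Groups of highly correlated features
#'
#' Builds an undirected graph with an edge between two IDs whenever their
#' pair count is at least \code{minCount} and their lift is at least
#' \code{liftThreshold}; the groups are the connected components. Such
#' groups can serve as the variable groups of a group-penalized model over
#' collinear clinical features.
#'
#' @param matrix a \code{\linkS4class{CoFrequencyMatrix}}.
#' @param singletons a matching \code{\linkS4class{SingletonCounts}}.
#' @param liftThreshold minimum lift for an edge (default 2).
#' @param minCount minimum pair count for an edge (default 1).
#' @return list of sorted integer vectors (the groups, every singleton ID
#'   included as its own group), ordered by smallest member.
#' @export
featureGroups <- function(matrix, singletons, liftThreshold = 2, minCount = 1L) {
  lifted <- pairLift(matrix, singletons)
  edges <- lifted[lifted$count >= minCount & lifted$lift >= liftThreshold, ,
                  drop = FALSE]
  ids <- sort(unique(singletons@counts$id))
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(edges$id_x),
                   to = as.character(edges$id_y)),
    directed = FALSE,
    vertices = data.frame(name = as.character(ids)))
  comp <- igraph::components(g)
  groups <- split(ids, comp$membership[as.character(ids)])
  groups <- lapply(groups, function(x) sort(as.integer(x)))
  unname(groups[order(vapply(groups, min, integer(1)))])
}
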