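#' Remove genetic trend from EBVs before computing selection intensity
#'
#' Fits an ordinary least-squares model of the EBVs on the herd-year-season
#' factor (intercept included) and returns the residuals, which are mean
#' zero. Levels with a single animal get residual 0 and trigger a warning.
#'
#' @param ebv numeric EBVs.
#' @param hys herd-year-season (of scoring) level per animal.
#' @return numeric vector of detrended EBVs.
#' @export
detrend_ebv <- function(ebv, hys) {
  stopifnot(length(ebv) == length(hys))
  f <- factor(hys)
  singles <- sum(table(f) == 1L)
  if (singles > 0L)
    warning(singles, " herd-year-season level(s) contain a single animal; ",
            "their residuals are 0")
  if (nlevels(f) == 1L) return(ebv - mean(ebv))
  unname(stats::resid(stats::lm(ebv ~ f)))
}

#' Realized selection intensity from an EBV distribution
#'
#' Standardized selection differential when the best `round(p * n)` animals
#' are selected: `|mean(selected) - mean(all)| / sd(all)`. Selecting against
#' damage uses the lower tail. Ties are broken by a stable sort on animal id,
#' so the result is deterministic. With discrete (heavily tied) EBVs the
#' realized intensity falls below the normal-theory value.
#'
#' @param ebv numeric EBVs.
#' @param p selected proportion in (0, 1).
#' @param tail `"lower"` (select smallest EBVs) or `"upper"`.
#' @param ids optional animal ids used for tie-breaking (defaults to input
#'   order).
#' @return non-negative scalar intensity in SD units, with the tail recorded
#'   in attribute `tail`.
#' @export
realized_intensity <- function(ebv, p, tail = c("lower", "upper"), ids = NULL) {
  tail <- match.arg(tail)
  n <- length(ebv)
  stopifnot(p > 0, p < 1)
  nsel <- round(p * n)
  if (nsel < 1L) stop("round(p * n) must be at least 1")
  s <- stats::sd(ebv)
  if (s == 0) stop("EBV standard deviation is zero; intensity undefined")
  if (is.null(ids)) ids <- seq_len(n)
  ord <- order(if (tail == "lower") ebv else -ebv, ids)
  sel <- ord[seq_len(nsel)]
  structure(abs(mean(ebv[sel]) - mean(ebv)) / s, tail = tail)
}

#' Selection intensity under the standard normal distribution
#'
#' Mean of the selected tail of a standard normal at selected proportion
#' `p`: `i = phi(z_{1-p}) / p`. For `p = 0.05` this is 2.063.
#'
#' @param p selected proportion in (0, 1).
#' @export
normal_intensity <- function(p) {
  stopifnot(all(p > 0), all(p < 1))
  stats::dnorm(stats::qnorm(1 - p)) / p
}

#' Predicted direct and correlated responses to selection
#'
#' In genetic-standard-deviation units, the direct response to selection on
#' trait `s` is `R[s, s] = i_s * r_s` (intensity times accuracy) and the
#' correlated response in trait `t` is `R[t, s] = R[s, s] * rg[t, s]`.
#'
#' @param intensities named per-trait selection intensities.
#' @param accuracies named per-trait EBV accuracies (typically from forward
#'   validation).
#' @param rg genetic-correlation matrix (symmetric, unit diagonal) with
#'   matching dimnames.
#' @return a `selection_report`: list with `R` (rows = response trait,
#'   columns = selection trait), `best` (per response trait, the selection
#'   trait with the largest response) and the inputs.
#' @export
response_table <- function(intensities, accuracies, rg) {
  traits <- names(intensities)
  stopifnot(!is.null(traits), setequal(traits, names(accuracies)),
            all(traits %in% rownames(rg)), all(traits %in% colnames(rg)))
  rg <- rg[traits, traits]
  if (any(abs(rg) > 1)) stop("genetic correlations must lie in [-1, 1]")
  if (max(abs(rg - t(rg))) > 1e-8) stop("rg must be symmetric")
  if (max(abs(diag(rg) - 1)) > 1e-8) stop("rg must have unit diagonal")
  direct <- intensities[traits] * accuracies[traits]
  R <- rg * rep(direct, each = length(traits))
  dimnames(R) <- list(response = traits, selection = traits)
  structure(list(R = R,
                 best = stats::setNames(traits[apply(R, 1L, which.max)], traits),
                 intensities = intensities, accuracies = accuracies,
                 rg = rg), class = "selection_report")
}

#' @method print selection_report
#' @export
print.selection_report <- function(x, ...) {
  cat("Predicted response to selection (genetic-SD units);",
      "rows = response trait, columns = selection trait\n")
  print(round(x$R, 3))
  cat("Best selection trait per response trait:\n")
  print(x$best)
  invisible(x)
}

#' Reference estimates from a large multi-line pig breeding study
#'
#' Published across-line estimates from a six-line commercial pig population
#' (about 33,000 scored animals): genetic correlations among the seven damage
#' trait definitions, forward-validation (LR) accuracies, and realized
#' selection intensities at 5 percent selected. These serve as worked-example
#' inputs for [response_table()]; they are shipped values, not computed by
#' this package.
#'
#' @return list with `rg` (7 x 7 matrix), `lr_accuracy` and `intensity`
#'   (named vectors).
#' @export
reference_estimates <- function() {
  dir <- system.file("extdata", "reference_estimates", package = "pigdamage")
  rg <- as.matrix(utils::read.csv(file.path(dir, "genetic_correlations.csv"),
                                  row.names = 1L, check.names = FALSE))
  acc <- utils::read.csv(file.path(dir, "lr_accuracy.csv"))
  int <- utils::read.csv(file.path(dir, "realized_intensity.csv"))
  list(rg = rg,
       lr_accuracy = stats::setNames(acc$accuracy, acc$trait),
       intensity = stats::setNames(int$intensity, int$trait))
}
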