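#' Cross-validation scheme
#'
#' @param k number of folds (>= 2).
#' @param replicates number of replicated fold allocations.
#' @param grouping `"random"` assigns records to folds uniformly;
#'   `"full-sib"` keeps full-sibs (same sire and dam) in the same fold;
#'   `"half-sib"` keeps animals sharing a sire or a dam together (connected
#'   components of the sib graph move as blocks).
#' @param seed RNG seed for the allocations.
#' @return a `cv_scheme` object.
#' @export
cv_scheme <- function(k = 5L, replicates = 100L,
                      grouping = c("random", "full-sib", "half-sib"),
                      seed = 1L) {
  stopifnot(k >= 2L, replicates >= 1L)
  structure(list(k = as.integer(k), replicates = as.integer(replicates),
                 grouping = match.arg(grouping), seed = as.integer(seed)),
            class = "cv_scheme")
}

# sib blocks: indices into rows of `table`
.sib_blocks <- function(table, ped, grouping) {
  ix <- match(as.character(table$animal), ped$id)
  sire <- ped$sire[ix]; dam <- ped$dam[ix]
  n <- length(ix)
  if (grouping == "full-sib") {
    key <- ifelse(sire > 0L & dam > 0L,
                  paste(sire, dam, sep = "|"),
                  paste0("solo", seq_len(n)))
    return(split(seq_len(n), key))
  }
  # half-sib: connected components via shared sire OR dam
  keys <- unique(c(paste0("s", sire[sire > 0L]), paste0("d", dam[dam > 0L])))
  nk <- length(keys)
  parent <- seq_len(n + nk)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) { nxt <- parent[i]; parent[i] <<- root; i <- nxt }
    root
  }
  unite <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[ra] <<- rb }
  skey <- match(paste0("s", sire), keys)
  dkey <- match(paste0("d", dam), keys)
  for (i in seq_len(n)) {
    if (sire[i] > 0L) unite(i, n + skey[i])
    if (dam[i] > 0L) unite(i, n + dkey[i])
  }
  comp <- vapply(seq_len(n), find, 0L)
  split(seq_len(n), comp)
}

#' Allocate records to cross-validation folds
#'
#' Random grouping assigns records to folds uniformly. Sib-based groupings
#' move whole sib blocks: blocks are shuffled each replicate and placed in
#' the currently least-filled fold, so folds are balanced to within one
#' block. A block larger than `n/k` triggers a warning and is placed in the
#' fold with the largest deficit.
#'
#' @param table phenotype data frame.
#' @param ped pedigree (parent information for sib groupings).
#' @param scheme a [cv_scheme()].
#' @return integer matrix `n x replicates` of fold labels in `1..k`.
#' @export
make_folds <- function(table, ped, scheme) {
  n <- nrow(table)
  k <- scheme$k
  set.seed(scheme$seed)
  out <- matrix(0L, n, scheme$replicates)
  blocks <- if (scheme$grouping == "random") NULL
            else .sib_blocks(table, ped, scheme$grouping)
  if (!is.null(blocks) && any(lengths(blocks) > n / k))
    warning(sum(lengths(blocks) > n / k), " sib block(s) larger than n/k; ",
            "placed in the fold with the largest deficit")
  for (r in seq_len(scheme$replicates)) {
    if (is.null(blocks)) {
      out[, r] <- sample(rep_len(seq_len(k), n))
    } else {
      sizes <- numeric(k)
      fold <- integer(n)
      for (b in sample(length(blocks))) {
        f <- which.min(sizes)
        fold[blocks[[b]]] <- f
        sizes[f] <- sizes[f] + length(blocks[[b]])
      }
      out[, r] <- fold
    }
  }
  out
}

#' Adjust phenotypes for all effects except the animal effect
#'
#' Subtracts the full-model fixed-effect solutions and all non-animal random
#' effect solutions from the raw phenotype, leaving the animal effect and
#' residual: `y_adj = y - X b - l - g - hys`. Estimates come from the
#' full-data fit (which includes the animal effect), so the genetic signal is
#' not absorbed into the adjustments.
#'
#' @param fit a univariate `pd_fit` on the full data.
#' @param table optional phenotype table to adjust (defaults to the fitted
#'   one); every factor level must have an estimate in the fit.
#' @return numeric vector of adjusted phenotypes.
#' @export
adjust_phenotypes <- function(fit, table = NULL) {
  design <- fit$design
  if (!is.null(table)) {
    design <- build_design(table, fit$design$spec, fit$design$ped)
    if (!identical(colnames(design$X), names(fit$b)))
      stop("fixed-effect columns of the new table do not match the fit")
  }
  y <- design$Y[, match(fit$trait, design$spec$traits)]
  adj <- as.numeric(design$X %*% fit$b)
  for (term in setdiff(names(design$Zlist), "animal")) {
    est <- fit$u[[term]]
    lev <- design$levels[[term]]
    if (anyNA(match(lev, names(est))))
      stop("no estimate for level(s) of '", term, "': ",
           paste(utils::head(setdiff(lev, names(est)), 5L), collapse = ", "))
    adj <- adj + as.numeric(design$Zlist[[term]] %*% est[lev])
  }
  y - adj
}

#' Replicated k-fold cross-validation of EBVs
#'
#' For every replicate and fold, breeding values are re-predicted by BLUP
#' from the prediction set only (variance components held at the full-data
#' REML estimates), and compared with validation phenotypes adjusted for all
#' non-animal effects estimated on the full data. Accuracy is
#' `cor(y_adj, ebv) / h` with `h` the square root of the full-model
#' heritability; dispersion is the regression slope of adjusted phenotypes
#' on the predicted EBVs (1 = correctly dispersed).
#'
#' Because the adjusted phenotype no longer carries the litter, pen and
#' herd-year-season variance while `h` is defined against the full
#' phenotypic variance, this published form of the accuracy overstates the
#' correlation with the true breeding value by roughly
#' `sqrt(sigma2_P / (sigma2_a + sigma2_e))`. The report therefore also
#' carries `accuracy_cov = cov(y_adj, ebv) / (sigma_a * sd(ebv))`, a
#' variance-consistent estimator of that correlation, for calibration
#' checks against simulated truth.
#'
#' @param table phenotype data frame.
#' @param ped pedigree.
#' @param spec univariate [model_spec()].
#' @param scheme a [cv_scheme()].
#' @param fit optional full-data `pd_fit` (computed when absent).
#' @param keep_ebv also return the predicted EBVs of every validation fold.
#' @return a `cv_report`: list with `summary` (mean accuracy and dispersion
#'   with SEs over replicate-folds), `folds` (per-fold values) and, when
#'   requested, `ebv` (per replicate-fold, the validation animals and their
#'   prediction-set EBVs).
#' @export
run_cv <- function(table, ped, spec, scheme, fit = NULL, keep_ebv = FALSE) {
  if (is.null(fit)) fit <- reml_fit(table, spec, ped)
  h2 <- heritability(fit)$h2
  if (h2 <= 0) stop("full-model heritability is zero; accuracy undefined")
  h <- sqrt(h2)
  sig_a <- sqrt(fit$vc$variance[fit$vc$term == "animal"])
  y_adj <- adjust_phenotypes(fit)
  folds <- make_folds(table, ped, scheme)
  animals <- fit$design$animal
  res <- list()
  kept <- list()
  for (r in seq_len(ncol(folds))) {
    for (f in sort(unique(folds[, r]))) {
      vrows <- which(folds[, r] == f)
      trows <- which(folds[, r] != f)
      bl <- blup_solve(fit, rows = trows)
      av <- bl$ebv[animals[vrows]]
      if (stats::sd(av) == 0) {
        warning("fold ", f, " replicate ", r,
                " skipped: predicted EBVs have zero variance")
        next
      }
      res[[length(res) + 1L]] <- data.frame(
        replicate = r, fold = f,
        accuracy = stats::cor(y_adj[vrows], av) / h,
        accuracy_cov = stats::cov(y_adj[vrows], av) / (sig_a * stats::sd(av)),
        dispersion = unname(stats::coef(stats::lm(y_adj[vrows] ~ av))[2L]))
      if (keep_ebv)
        kept[[length(kept) + 1L]] <- data.frame(
          replicate = r, fold = f, animal = animals[vrows],
          ebv = unname(av), y_adj = y_adj[vrows])
    }
  }
  res <- do.call(rbind, res)
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  structure(list(
    summary = data.frame(trait = fit$trait, scheme = scheme$grouping,
                         accuracy = mean(res$accuracy),
                         accuracy_se = sem(res$accuracy),
                         accuracy_cov = mean(res$accuracy_cov),
                         dispersion = mean(res$dispersion),
                         dispersion_se = sem(res$dispersion)),
    folds = res, h = h,
    ebv = if (keep_ebv) do.call(rbind, kept)), class = "cv_report")
}

#' Split records at a birth-date cutoff for forward validation
#'
#' @param table phenotype data frame with a `birth_date` column.
#' @param cutoff a `Date` (or string); training = born on or before,
#'   validation = born after.
#' @return list with `training` and `validation` row indices.
#' @export
lr_split <- function(table, cutoff) {
  if (!"birth_date" %in% names(table)) stop("birth_date column required")
  bd <- as.Date(table$birth_date)
  cutoff <- as.Date(cutoff)
  val <- which(bd > cutoff)
  trn <- which(bd <= cutoff)
  if (!length(trn)) stop("empty training set: cutoff precedes all births")
  if (!length(val)) stop("empty validation set: cutoff after all births")
  list(training = trn, validation = val)
}

#' Accuracy, bias and dispersion by the linear-regression (LR) method
#'
#' Compares EBVs of validation animals predicted without their own phenotypes
#' (partial, `ebv_p`) against EBVs from the complete data (`ebv_c`):
#' `accuracy = sqrt(cov(p, c) / ((1 - Fbar) sigma2_a))`, `bias =
#' (mean(p) - mean(c)) / sigma_a` (genetic-SD units), `dispersion =
#' cov(p, c) / var(p)` (the regression slope of `ebv_c` on `ebv_p`).
#'
#' @param ebv_p,ebv_c partial and complete EBVs of the same validation
#'   animals.
#' @param var_a estimated additive genetic variance (full univariate model).
#' @param fbar mean inbreeding coefficient of the validation animals.
#' @return list with `accuracy` (NaN with a warning if the covariance is
#'   negative), `bias`, `dispersion`, and `cov_negative` flag.
#' @export
lr_metrics <- function(ebv_p, ebv_c, var_a, fbar = 0) {
  stopifnot(length(ebv_p) == length(ebv_c), var_a > 0)
  cv <- stats::cov(ebv_p, ebv_c)
  neg <- cv < 0
  if (neg) warning("negative covariance between partial and complete EBVs; ",
                   "accuracy undefined")
  list(accuracy = if (neg) NaN else sqrt(cv / ((1 - fbar) * var_a)),
       bias = (mean(ebv_p) - mean(ebv_c)) / sqrt(var_a),
       dispersion = cv / stats::var(ebv_p),
       cov_negative = neg)
}

#' Forward (LR) validation of a trait
#'
#' Splits the data at a birth-date cutoff, computes complete-data EBVs from
#' the full fit and partial EBVs by BLUP with the validation animals'
#' phenotypes removed (their pedigree links retained), and returns the LR
#' metrics.
#'
#' @param table phenotype data frame.
#' @param ped pedigree.
#' @param spec univariate [model_spec()].
#' @param cutoff birth-date cutoff.
#' @param fit optional full-data `pd_fit`.
#' @return list with the metrics of [lr_metrics()] plus `fbar`, the split
#'   sizes and the per-animal EBV pairs.
#' @export
lr_validate <- function(table, ped, spec, cutoff, fit = NULL) {
  if (is.null(fit)) fit <- reml_fit(table, spec, ped)
  sp <- lr_split(table, cutoff)
  animals <- fit$design$animal
  vids <- unique(animals[sp$validation])
  ebv_c <- fit$ebv[vids]
  part <- blup_solve(fit, rows = sp$training)
  ebv_p <- part$ebv[vids]
  va <- fit$vc$variance[fit$vc$term == "animal"]
  fbar <- mean_inbreeding(ped, vids)
  met <- lr_metrics(ebv_p, ebv_c, va, fbar)
  c(met, list(fbar = fbar, n_training = length(sp$training),
              n_validation = length(vids),
              ebv = data.frame(animal = vids, ebv_p = unname(ebv_p),
                               ebv_c = unname(ebv_c))))
}
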