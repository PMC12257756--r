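#' Specify the damage-trait animal model
#'
#' The analysis model for a scored trait `y` is the linear animal model
#' `y = Xb + Z_a a + Z_l l + Z_g g + Z_hys hys + e` with fixed sex, line,
#' sex-by-line, scorer and a linear age-at-scoring covariate, a pedigree-
#' structured additive animal effect (`var(a) = A sigma2_a`) and i.i.d.
#' litter, pen-group and herd-year-season-of-scoring effects.
#'
#' @param traits character vector (length 1 or 2) of response column names.
#' @param fixed fixed-effects formula (right-hand side) evaluated in the
#'   phenotype table; character columns are treated as factors with
#'   treatment contrasts.
#' @param random random terms: `"animal"` (pedigree-structured) plus names of
#'   i.i.d. grouping columns.
#' @param floor_frac variance-component lower bound as a fraction of the
#'   phenotypic variance.
#' @return a `model_spec` object.
#' @export
model_spec <- function(traits,
                       fixed = ~ sex * line + scorer + age_days,
                       random = c("animal", "litter", "pen", "hys_scoring"),
                       floor_frac = 1e-8) {
  stopifnot(length(traits) %in% 1:2, inherits(fixed, "formula"))
  structure(list(traits = traits, fixed = fixed, random = random,
                 floor_frac = floor_frac),
            class = "model_spec")
}

#' Build design matrices for the animal model
#'
#' Constructs the fixed-effects matrix (treatment contrasts, checked for full
#' column rank) and sparse incidence matrices for each random term. The
#' animal term is indexed against the full pedigree, so ancestors without
#' phenotypes receive breeding values through their relationships.
#'
#' @param table phenotype data frame (one row per scored animal, `animal`
#'   column present).
#' @param spec a [model_spec()].
#' @param ped a pedigree covering all phenotyped animals.
#' @return an object of class `mm_design`.
#' @export
build_design <- function(table, spec, ped) {
  iid <- setdiff(spec$random, "animal")
  need <- unique(c(spec$traits, all.vars(spec$fixed), iid, "animal"))
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols))
    stop("phenotype table lacks column(s): ", paste(missing_cols, collapse = ", "))
  for (v in need) if (anyNA(table[[v]]))
    stop("missing values in column '", v, "'")
  df <- table
  for (v in all.vars(spec$fixed))
    if (is.character(df[[v]])) df[[v]] <- factor(df[[v]])
  X <- stats::model.matrix(spec$fixed, df)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("fixed design is rank deficient; confounded columns: ",
         paste(colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]], collapse = ", "))
  Y <- as.matrix(df[spec$traits])
  storage.mode(Y) <- "double"
  n <- nrow(df)
  Zlist <- list()
  levels_ <- list()
  for (term in spec$random) {
    if (term == "animal") {
      j <- match(as.character(df$animal), ped$id)
      if (anyNA(j))
        stop("animal(s) not in pedigree: ",
             paste(utils::head(df$animal[is.na(j)], 5L), collapse = ", "))
      Zlist[[term]] <- Matrix::sparseMatrix(i = seq_len(n), j = j, x = 1,
                                            dims = c(n, length(ped$id)))
      levels_[[term]] <- ped$id
    } else {
      f <- factor(df[[term]])
      Zlist[[term]] <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(f),
                                            x = 1, dims = c(n, nlevels(f)))
      levels_[[term]] <- levels(f)
    }
  }
  structure(list(Y = Y, X = X, Zlist = Zlist, levels = levels_,
                 spec = spec, ped = ped, n = n,
                 animal = as.character(df$animal)),
            class = "mm_design")
}

# embed a square sparse block at `offset` on the diagonal of an m x m matrix
.embed_block <- function(K, offset, m) {
  Kt <- as(as(as(K, "CsparseMatrix"), "generalMatrix"), "TsparseMatrix")
  Matrix::sparseMatrix(i = Kt@i + 1L + offset, j = Kt@j + 1L + offset,
                       x = Kt@x, dims = c(m, m))
}

# precompute everything reusable across REML likelihood evaluations
.mme_prep <- function(design) {
  X <- Matrix::Matrix(design$X, sparse = TRUE)
  T <- do.call(cbind, c(list(X), unname(design$Zlist)))
  p <- ncol(X)
  m <- ncol(T)
  terms <- names(design$Zlist)
  q <- vapply(design$Zlist, ncol, 0L)
  offsets <- p + c(0L, cumsum(q))[seq_along(q)]
  names(offsets) <- terms
  Ainv <- NULL
  logdetA <- 0
  D <- vector("list", length(terms))
  names(D) <- terms
  for (k in seq_along(terms)) {
    if (terms[k] == "animal") {
      Ainv <- a_inverse(design$ped)
      logdetA <- -as.numeric(determinant(Ainv, logarithm = TRUE)$modulus)
      D[[k]] <- .embed_block(Ainv, offsets[k], m)
    } else {
      ix <- offsets[k] + seq_len(q[k])
      D[[k]] <- Matrix::sparseMatrix(i = ix, j = ix, x = 1, dims = c(m, m))
    }
  }
  TtT <- Matrix::forceSymmetric(crossprod(T))
  prep <- list(T = T, TtT = TtT,
       TtY = as.matrix(crossprod(T, design$Y)),
       YtY = crossprod(design$Y),
       Y = design$Y, n = design$n, p = p, m = m,
       terms = terms, q = q, offsets = offsets,
       D = D, Ainv = Ainv, logdetA = logdetA)
  c(prep, .uni_assembler(TtT, D, m))
}

# Precompute the union sparsity pattern of the MME coefficient matrix and the
# position of every component's nonzeros inside it, so that each REML
# likelihood evaluation only fills a numeric vector instead of re-adding
# sparse matrices.
.uni_assembler <- function(TtT, D, m) {
  tsp <- function(M)
    as(as(Matrix::forceSymmetric(M), "CsparseMatrix"), "TsparseMatrix")
  comps <- lapply(c(list(TtT), D), tsp)
  keyof <- function(i, j) i + m * as.double(j)
  ii <- unlist(lapply(comps, slot, "i"))
  jj <- unlist(lapply(comps, slot, "j"))
  tmpl <- tsp(Matrix::sparseMatrix(i = ii + 1L, j = jj + 1L,
                                   x = 1, dims = c(m, m), symmetric = TRUE))
  tkey <- keyof(tmpl@i, tmpl@j)
  maps <- lapply(comps, function(M) match(keyof(M@i, M@j), tkey))
  compx <- lapply(comps, slot, "x")
  list(Ctmpl = as(tmpl, "CsparseMatrix"), maps = maps, compx = compx)
}

# C = coef[1] * TtT + sum_k coef[k+1] * D_k with a constant pattern
.assemble_uni_x <- function(prep, coef) {
  xx <- numeric(length(prep$Ctmpl@x))
  for (k in seq_along(prep$maps)) {
    mk <- prep$maps[[k]]
    xx[mk] <- xx[mk] + prep$compx[[k]] * coef[k]
  }
  xx
}

.assemble_uni <- function(prep, coef) {
  C <- prep$Ctmpl
  C@x <- .assemble_uni_x(prep, coef)
  C
}

# Cholesky with cached symbolic analysis; NULL if the matrix is not PD
.chol_cached <- function(cache, C) {
  if (!is.null(cache$ch)) {
    ch <- tryCatch(update(cache$ch, C), error = function(e) NULL)
    if (!is.null(ch)) { cache$ch <- ch; return(ch) }
  }
  ch <- tryCatch(Matrix::Cholesky(C, LDL = FALSE, super = TRUE),
                 error = function(e) NULL)
  if (!is.null(ch)) cache$ch <- ch
  ch
}

.logdet_chm <- function(ch) 2 * as.numeric(determinant(ch, logarithm = TRUE, sqrt = TRUE)$modulus)

# -2 * restricted log-likelihood, univariate, from the sparse MME
.n2ll_uni <- function(v, prep, t_idx, cache) {
  nk <- length(prep$D)
  ve <- v[nk + 1L]
  C <- .assemble_uni(prep, c(1 / ve, 1 / v[seq_len(nk)]))
  ch <- .chol_cached(cache, C)
  if (is.null(ch)) return(list(value = 1e10))
  r <- prep$TtY[, t_idx] / ve
  s <- as.numeric(solve(ch, r))
  yPy <- prep$YtY[t_idx, t_idx] / ve - sum(s * r)
  val <- (prep$n - prep$p) * log(2 * pi) + prep$n * log(ve) +
    sum(prep$q * log(v[seq_len(nk)])) +
    ("animal" %in% prep$terms) * prep$logdetA +
    .logdet_chm(ch) + yPy
  list(value = val, ch = ch, s = s)
}

# average-information matrix for (variance components..., residual), univariate
.ai_uni <- function(prep, design, t_idx, v, ch, s) {
  nk <- length(prep$D)
  ve <- v[nk + 1L]
  y <- prep$Y[, t_idx]
  Py <- (y - as.numeric(prep$T %*% s)) / ve
  W <- matrix(0, prep$n, nk + 1L)
  for (k in seq_len(nk)) {
    Z <- design$Zlist[[k]]
    t <- as.numeric(crossprod(Z, Py))
    if (prep$terms[k] == "animal") t <- as.numeric(solve(prep$Ainv, t))
    W[, k] <- as.numeric(Z %*% t)
  }
  W[, nk + 1L] <- Py
  PW <- matrix(0, prep$n, nk + 1L)
  for (k in seq_len(nk + 1L)) {
    rw <- as.numeric(crossprod(prep$T, W[, k])) / ve
    sw <- as.numeric(solve(ch, rw))
    PW[, k] <- (W[, k] - as.numeric(prep$T %*% sw)) / ve
  }
  0.5 * crossprod(W, PW)
}

.safe_inv <- function(M) {
  out <- tryCatch(solve(M), error = function(e) NULL)
  if (is.null(out)) {
    sv <- svd(M)
    pos <- sv$d > max(sv$d) * 1e-10
    out <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  }
  (out + t(out)) / 2
}

#' Fit the univariate animal model by REML
#'
#' Maximizes the restricted log-likelihood of the Gaussian animal model over
#' the variance components (animal, i.i.d. terms, residual). The likelihood
#' is evaluated through the sparse mixed-model equations (Cholesky
#' factorization with reused symbolic analysis) and maximized by quasi-Newton
#' iterations on the log-variance scale; components are bounded below at
#' `floor_frac` times the phenotypic variance. Asymptotic standard errors
#' come from the inverse average-information matrix at the optimum.
#'
#' @param table phenotype data frame.
#' @param spec a [model_spec()]; the first (or `trait`) response is fitted.
#' @param ped pedigree covering all phenotyped animals.
#' @param start optional numeric vector of starting values, one variance per
#'   random term plus the residual, in `spec$random` order.
#' @param trait which of `spec$traits` to fit.
#' @param method `"ai"` (default): average-information REML with exact
#'   first derivatives from a sparse selected inverse, step halving and
#'   variance floors; `"lbfgs"`: derivative-free quasi-Newton maximization of
#'   the same restricted likelihood (slower; retained as a cross-check).
#' @param maxit maximum iterations.
#' @return an object of class `pd_fit` with elements `vc` (component table
#'   with SEs), `varcov` (asymptotic covariance of the components), `b`
#'   (fixed-effect solutions), `u` (random-effect solutions per term), `ebv`
#'   (named animal solutions), `logLik`, `converged`, `mme_residual` and the
#'   design/prep needed by downstream validation functions.
#' @export
reml_fit <- function(table, spec, ped, start = NULL, trait = spec$traits[1L],
                     method = c("ai", "lbfgs"), maxit = 100L) {
  method <- match.arg(method)
  design <- build_design(table, spec, ped)
  prep <- .mme_prep(design)
  t_idx <- match(trait, spec$traits)
  if (is.na(t_idx)) stop("trait '", trait, "' not in the model spec")
  varp <- stats::var(prep$Y[, t_idx])
  floor_ <- spec$floor_frac * varp
  nk <- length(prep$D)
  if (is.null(start)) start <- c(rep(varp / (2 * nk), nk), varp / 2)
  stopifnot(length(start) == nk + 1L)
  start <- pmax(start, floor_)
  pev_all <- NULL

  if (method == "ai") {
    res <- .reml_ai(prep, design, d = 1L, t_idx = t_idx,
                    start_blocks = lapply(start, matrix, 1L, 1L),
                    floor_ = floor_, maxit = maxit)
    v <- vapply(res$blocks, function(b) b[1, 1], 0)
    logl <- res$logLik
    converged <- res$converged
    counts <- c(iterations = res$iterations)
    varcov <- res$varcov
    pev_all <- stats::setNames(res$pev[, 1L], rownames(res$pev))
  } else {
    cache <- new.env(parent = emptyenv())
    obj <- function(logv) .n2ll_uni(exp(logv), prep, t_idx, cache)$value
    opt <- stats::optim(log(start), obj, method = "L-BFGS-B",
                        lower = log(floor_), upper = log(varp * 100),
                        control = list(maxit = maxit, factr = 1e6,
                                       ndeps = rep(1e-4, nk + 1L)))
    v <- exp(opt$par)
    logl <- -opt$value / 2
    converged <- opt$convergence == 0L
    counts <- opt$counts
    varcov <- NULL
  }

  # final solve through the cached-symbolic path; also checks the MME
  # residual at the returned components
  cache <- new.env(parent = emptyenv())
  fin <- .n2ll_uni(v, prep, t_idx, cache)
  ch <- fin$ch; s <- fin$s
  C <- .assemble_uni(prep, c(1 / v[nk + 1L], 1 / v[seq_len(nk)]))
  r <- prep$TtY[, t_idx] / v[nk + 1L]
  mme_res <- sqrt(sum((as.numeric(C %*% s) - r)^2)) / sqrt(sum(r^2))
  if (mme_res > 1e-6)
    warning("MME residual ", format(mme_res), " exceeds 1e-6")
  if (is.null(varcov)) varcov <- .safe_inv(.ai_uni(prep, design, t_idx, v, ch, s))
  se <- sqrt(pmax(diag(varcov), 0))
  comp_names <- c(prep$terms, "residual")
  u <- list()
  for (k in seq_len(nk)) {
    ix <- prep$offsets[k] + seq_len(prep$q[k])
    u[[prep$terms[k]]] <- stats::setNames(s[ix], design$levels[[k]])
  }
  structure(list(
    vc = data.frame(term = comp_names, variance = unname(v), se = se,
                    stringsAsFactors = FALSE),
    varcov = structure(varcov, dimnames = list(comp_names, comp_names)),
    trait = trait,
    b = stats::setNames(s[seq_len(prep$p)], colnames(design$X)),
    u = u,
    ebv = u[["animal"]],
    logLik = logl,
    converged = converged,
    counts = counts,
    method = method,
    mme_residual = mme_res,
    at_floor = unname(v) <= floor_ * (1 + 1e-6),
    pev_all = pev_all,
    design = design, prep = prep, chol = ch, solution = s,
    floor = floor_), class = "pd_fit")
}

#' @method print pd_fit
#' @export
print.pd_fit <- function(x, ...) {
  cat("Univariate animal-model REML fit, trait:", x$trait, "\n")
  cat("  logL =", format(x$logLik, digits = 8),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(x$vc, row.names = FALSE)
  h <- heritability(x)
  cat("  h2 =", format(h$h2, digits = 3), "(se", format(h$se, digits = 2), ")\n")
  invisible(x)
}

#' Heritability from univariate variance components
#'
#' `h2 = sigma2_a / sigma2_p` where the phenotypic variance sums all
#' components; the herd-year-season-of-scoring component can be excluded from
#' the denominator (the alternative convention in which that term is treated
#' as fixed). The SE is obtained by the delta method from the asymptotic
#' component covariance.
#'
#' @param fit a `pd_fit`, or a numeric vector of components named as in
#'   `fit$vc$term`.
#' @param include_hys include the herd-year-season variance in the
#'   denominator (default) or not.
#' @param varcov optional component covariance when `fit` is a plain vector.
#' @param hys_term name of the herd-year-season term.
#' @return list with `h2` and `se` (`NA` when no covariance is available).
#' @export
heritability <- function(fit, include_hys = TRUE, varcov = NULL,
                         hys_term = "hys_scoring") {
  if (inherits(fit, "pd_fit")) {
    v <- stats::setNames(fit$vc$variance, fit$vc$term)
    varcov <- fit$varcov
  } else v <- fit
  if (!"animal" %in% names(v)) stop("components must include an 'animal' term")
  use <- if (include_hys) names(v) else setdiff(names(v), hys_term)
  denom <- sum(v[use])
  if (denom <= 0) stop("phenotypic variance is zero")
  h2 <- unname(v[["animal"]] / denom)
  se <- NA_real_
  if (!is.null(varcov)) {
    g <- stats::setNames(rep(0, length(v)), names(v))
    g[use] <- -v[["animal"]] / denom^2
    g["animal"] <- g["animal"] + 1 / denom
    se <- sqrt(max(0, as.numeric(t(g) %*% varcov[names(v), names(v)] %*% g)))
  }
  list(h2 = h2, se = se)
}

#' Prediction error variance of breeding values
#'
#' Diagonal entries of the animal block of the inverse mixed-model-equation
#' coefficient matrix at the fitted components.
#'
#' @param fit a `pd_fit`.
#' @param ids animals to compute PEV for (default: all phenotyped animals).
#' @param chunk columns solved per block.
#' @return named numeric vector of PEVs.
#' @export
pev <- function(fit, ids = NULL, chunk = 512L) {
  prep <- fit$prep
  if (is.null(ids)) ids <- unique(fit$design$animal)
  ix <- match(as.character(ids), fit$design$levels[["animal"]])
  if (anyNA(ix)) stop("unknown animal id(s) in 'ids'")
  cols <- prep$offsets[["animal"]] + ix
  out <- numeric(length(cols))
  for (beg in seq(1L, length(cols), by = chunk)) {
    sel <- beg:min(beg + chunk - 1L, length(cols))
    E <- Matrix::sparseMatrix(i = cols[sel], j = seq_along(sel), x = 1,
                              dims = c(prep$m, length(sel)))
    S <- solve(fit$chol, E)
    out[sel] <- diag(t(E) %*% S)
  }
  stats::setNames(out, ids)
}

#' Model-derived accuracy of breeding values
#'
#' `r_i = sqrt(1 - PEV_i / sigma2_a)`. PEVs are clamped into
#' `[0, sigma2_a]` before the square root; the number of clamped animals is
#' reported as an attribute and in a message.
#'
#' @param fit a `pd_fit`.
#' @param ids animals (default: all phenotyped).
#' @param pev_values optional precomputed PEVs (named).
#' @return named vector of accuracies with attribute `n_clamped`.
#' @export
model_accuracy <- function(fit, ids = NULL, pev_values = NULL) {
  va <- fit$vc$variance[fit$vc$term == "animal"]
  if (va <= 0) stop("additive genetic variance is zero")
  if (is.null(pev_values)) pev_values <- pev(fit, ids)
  clamped <- sum(pev_values < 0 | pev_values > va)
  if (clamped > 0)
    message(clamped, " PEV value(s) clamped into [0, sigma2_a]")
  p <- pmin(pmax(pev_values, 0), va)
  out <- sqrt(1 - p / va)
  attr(out, "n_clamped") <- clamped
  out
}

#' BLUP solutions at fixed variance components
#'
#' Solves the mixed-model equations for fixed and random effects with the
#' variance components held fixed, optionally on a subset of records (the
#' full pedigree stays in the animal term, so animals without records in the
#' subset still receive breeding values through their relatives).
#'
#' @param fit a `pd_fit` whose design and components are reused, or an
#'   `mm_design` (then `v` is required).
#' @param rows integer/logical subset of phenotype rows (default all).
#' @param v variance components (random terms then residual); defaults to the
#'   fitted ones.
#' @param trait response column (index into the design's traits).
#' @return list with `b`, `u`, `ebv`.
#' @export
blup_solve <- function(fit, rows = NULL, v = NULL, trait = NULL) {
  if (inherits(fit, "pd_fit")) {
    prep <- fit$prep; design <- fit$design
    if (is.null(v)) v <- fit$vc$variance
    if (is.null(trait)) trait <- fit$trait
  } else if (inherits(fit, "mm_design")) {
    design <- fit
    prep <- .mme_prep(design)
    if (is.null(v)) stop("variance components 'v' required")
    if (is.null(trait)) trait <- design$spec$traits[1L]
  } else stop("fit must be a pd_fit or mm_design")
  t_idx <- if (is.character(trait)) match(trait, design$spec$traits) else trait
  nk <- length(prep$D)
  ve <- v[nk + 1L]
  if (is.null(rows)) {
    C <- .assemble_uni(prep, c(1 / ve, 1 / v[seq_len(nk)]))
    Tty <- prep$TtY[, t_idx]
  } else {
    Tr <- prep$T[rows, , drop = FALSE]
    C <- crossprod(Tr) / ve
    for (k in seq_len(nk)) C <- C + prep$D[[k]] / v[k]
    C <- Matrix::forceSymmetric(C)
    # fixed-effect levels without records in the subset have empty MME rows;
    # pin their solutions to zero (a generalized-inverse convention) so the
    # system stays positive definite
    empty_fix <- which(diag(C)[seq_len(prep$p)] == 0)
    if (length(empty_fix))
      C <- C + Matrix::sparseMatrix(i = empty_fix, j = empty_fix,
                                    x = 1, dims = dim(C), symmetric = TRUE)
    Tty <- as.numeric(crossprod(Tr, prep$Y[rows, t_idx]))
  }
  ch <- tryCatch(Matrix::Cholesky(C, LDL = FALSE, super = TRUE),
                 error = function(e) NULL)
  if (is.null(ch)) {
    # residual confounding in the subset: regularize the fixed block weakly
    warning("subset mixed-model equations are singular; ",
            "adding a weak ridge to the fixed-effect block")
    ridge <- 1e-6 * max(diag(C))
    C <- C + Matrix::sparseMatrix(i = seq_len(prep$p), j = seq_len(prep$p),
                                  x = ridge, dims = dim(C), symmetric = TRUE)
    ch <- Matrix::Cholesky(C, LDL = FALSE, super = TRUE)
  }
  s <- as.numeric(solve(ch, Tty / ve))
  u <- list()
  for (k in seq_len(nk)) {
    ix <- prep$offsets[k] + seq_len(prep$q[k])
    u[[prep$terms[k]]] <- stats::setNames(s[ix], design$levels[[k]])
  }
  list(b = stats::setNames(s[seq_len(prep$p)], colnames(design$X)),
       u = u, ebv = u[["animal"]])
}
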