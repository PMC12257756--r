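#' Fit the bivariate animal model by REML
#'
#' Joint analysis of two traits measured on the same animals, with an
#' unstructured 2 x 2 covariance block for every random term (animal, litter,
#' pen group, herd-year-season of scoring) and for the residual. Blocks are
#' parameterized as two log variances plus the hyperbolic arctangent of the
#' correlation, so every update is positive semi-definite by construction.
#' Starting variances are taken from the univariate fits of the two traits
#' (run internally when not supplied); correlations start at the phenotypic
#' correlation of the two responses. One block's correlation
#' can be frozen, e.g. the litter correlation at 0.99 when two near-duplicate
#' trait definitions make it inestimable; only that block's variances then
#' update.
#'
#' @param table phenotype data frame.
#' @param spec a [model_spec()] with two traits.
#' @param ped pedigree covering all phenotyped animals.
#' @param fix optional `list(term =, value =)` freezing one block's
#'   correlation (`term` may be a random term name or `"residual"`).
#' @param start_uni optional list of two `pd_fit` objects supplying starting
#'   variances.
#' @param method `"ai"` (default, average-information REML with exact
#'   derivatives) or `"lbfgs"` (derivative-free cross-check path).
#' @param maxit maximum iterations.
#' @return an object of class `pd_bifit`: `vc` (per-term 2 x 2 covariance
#'   summaries with SEs), `rg` and `rg_se` (genetic correlation), per-trait
#'   fixed solutions and EBVs, `logLik`, `converged`.
#' @export
reml_bivariate <- function(table, spec, ped, fix = NULL, start_uni = NULL,
                           method = c("ai", "lbfgs"), maxit = 60L) {
  method <- match.arg(method)
  stopifnot(length(spec$traits) == 2L)
  design <- build_design(table, spec, ped)
  prep <- .mme_prep(design)
  terms_all <- c(prep$terms, "residual")
  nt <- length(terms_all)
  fix_term <- if (!is.null(fix)) fix$term else ""
  if (nzchar(fix_term) && !fix_term %in% terms_all)
    stop("fix$term must be one of: ", paste(terms_all, collapse = ", "))
  fixed_r <- if (nzchar(fix_term)) fix$value else NA_real_

  if (is.null(start_uni)) {
    start_uni <- list(
      reml_fit(table, spec, ped, trait = spec$traits[1L]),
      reml_fit(table, spec, ped, trait = spec$traits[2L]))
  }
  v1_start <- pmax(start_uni[[1L]]$vc$variance, 1e-8)
  v2_start <- pmax(start_uni[[2L]]$vc$variance, 1e-8)
  r_start <- min(max(stats::cor(prep$Y[, 1L], prep$Y[, 2L]), -0.8), 0.8)
  varp <- mean(diag(prep$YtY) / prep$n)
  floor_ <- spec$floor_frac *
    max(stats::var(prep$Y[, 1L]), stats::var(prep$Y[, 2L]))

  mkblock <- function(k, r) {
    rr <- if (identical(terms_all[k], fix_term)) fixed_r else r
    .cov2(c(v1_start[k], v2_start[k]), rr)
  }

  if (method == "ai") {
    start_blocks <- lapply(seq_len(nt), mkblock, r = r_start)
    res <- .reml_ai(prep, design, d = 2L, start_blocks = start_blocks,
                    fix_term = if (nzchar(fix_term)) fix_term else NA,
                    fixed_r = fixed_r, floor_ = floor_, maxit = maxit)
    K0 <- res$blocks
    s <- res$s
    logl <- res$logLik
    converged <- res$converged
    counts <- c(iterations = res$iterations)
    varcov <- res$varcov
    pidx <- res$par_index
    projected <- res$projected
    pev_all <- res$pev
  } else {
    out <- .reml_biv_lbfgs(prep, design, terms_all, fix_term, fixed_r,
                           v1_start, v2_start, r_start, varp, floor_, maxit)
    K0 <- out$K0; s <- out$s; logl <- out$logl
    converged <- out$converged; counts <- out$counts
    ai <- .ai_biv(prep, design, K0, out$R0i, out$ch, s,
                  if (nzchar(fix_term)) fix_term else NA_character_)
    varcov <- .safe_inv(ai$AI)
    pidx <- ai$par_index
    projected <- FALSE
    pev_all <- NULL
  }
  names(K0) <- terms_all
  m <- prep$m
  se <- sqrt(pmax(diag(varcov), 0))

  summ <- data.frame(term = terms_all,
                     var1 = vapply(K0, function(b) b[1, 1], 0),
                     cov12 = vapply(K0, function(b) b[1, 2], 0),
                     var2 = vapply(K0, function(b) b[2, 2], 0))
  summ$r <- summ$cov12 / sqrt(summ$var1 * summ$var2)
  summ$se_var1 <- summ$se_cov12 <- summ$se_var2 <- summ$se_r <- NA_real_
  for (k in seq_len(nt)) {
    ixp <- pidx[[k]]
    if (length(ixp) == 3L) {
      summ$se_var1[k] <- se[ixp[1L]]
      summ$se_cov12[k] <- se[ixp[2L]]
      summ$se_var2[k] <- se[ixp[3L]]
      b <- K0[[k]]
      g <- c(-b[1, 2] / (2 * b[1, 1]^1.5 * sqrt(b[2, 2])),
             1 / sqrt(b[1, 1] * b[2, 2]),
             -b[1, 2] / (2 * b[2, 2]^1.5 * sqrt(b[1, 1])))
      summ$se_r[k] <- sqrt(max(0, as.numeric(
        t(g) %*% varcov[ixp, ixp] %*% g)))
    } else {
      summ$se_var1[k] <- se[ixp[1L]]
      summ$se_var2[k] <- se[ixp[2L]]
    }
  }

  u <- list()
  for (k in seq_len(nt - 1L)) {
    ix <- prep$offsets[k] + seq_len(prep$q[k])
    u[[prep$terms[k]]] <- cbind(s[ix], s[m + ix])
    rownames(u[[prep$terms[k]]]) <- design$levels[[k]]
    colnames(u[[prep$terms[k]]]) <- spec$traits
  }

  ia <- match("animal", terms_all)
  structure(list(
    vc = summ, blocks = K0,
    rg = summ$r[ia], rg_se = summ$se_r[ia],
    varcov = varcov, par_index = pidx,
    b = cbind(stats::setNames(s[seq_len(prep$p)], colnames(design$X)),
              s[m + seq_len(prep$p)]),
    u = u, ebv = u[["animal"]],
    logLik = logl,
    converged = converged,
    counts = counts,
    method = method,
    projected = projected,
    fix = fix,
    pev_all = pev_all,
    design = design, prep = prep, solution = s),
    class = "pd_bifit")
}

# quasi-Newton fallback on the log-variance / atanh-correlation scale
.reml_biv_lbfgs <- function(prep, design, terms_all, fix_term, fixed_r,
                            v1_start, v2_start, r_start, varp, floor_, maxit) {
  nt <- length(terms_all)
  zmax <- atanh(0.999)
  par_index <- list(); pos <- 0L
  for (k in seq_len(nt)) {
    npar <- if (identical(terms_all[k], fix_term)) 2L else 3L
    par_index[[k]] <- pos + seq_len(npar)
    pos <- pos + npar
  }
  unpack <- function(par) {
    lapply(seq_len(nt), function(k) {
      pk <- par[par_index[[k]]]
      v <- exp(pk[1:2])
      r <- if (identical(terms_all[k], fix_term)) fixed_r else tanh(pk[3L])
      .cov2(v, r)
    })
  }
  pack <- function(r) {
    out <- numeric(0)
    for (k in seq_len(nt)) {
      out <- c(out, log(max(v1_start[k], floor_)), log(max(v2_start[k], floor_)))
      if (!identical(terms_all[k], fix_term))
        out <- c(out, atanh(min(max(r, -0.98), 0.98)))
    }
    out
  }
  cache <- new.env(parent = emptyenv())
  asmb <- .biv_assembler(prep)
  n2ll <- function(par) {
    K0 <- tryCatch(unpack(par), error = function(e) NULL)
    if (is.null(K0)) return(list(value = 1e10))
    R0 <- K0[[nt]]
    R0i <- solve(R0)
    C <- .assemble_biv(asmb, c(list(R0i), lapply(K0[seq_len(nt - 1L)], solve)))
    ch <- .chol_cached(cache, C)
    if (is.null(ch)) return(list(value = 1e10))
    rhs <- c(R0i[1, 1] * prep$TtY[, 1L] + R0i[1, 2] * prep$TtY[, 2L],
             R0i[2, 1] * prep$TtY[, 1L] + R0i[2, 2] * prep$TtY[, 2L])
    s <- as.numeric(solve(ch, rhs))
    yPy <- sum(R0i * prep$YtY) - sum(s * rhs)
    ldG <- 0
    for (k in seq_len(nt - 1L)) {
      ldG <- ldG + prep$q[k] * as.numeric(determinant(K0[[k]])$modulus)
      if (prep$terms[k] == "animal") ldG <- ldG + 2 * prep$logdetA
    }
    val <- 2 * (prep$n - prep$p) * log(2 * pi) +
      prep$n * as.numeric(determinant(R0)$modulus) + ldG +
      .logdet_chm(ch) + yPy
    list(value = val, ch = ch, s = s, K0 = K0, R0i = R0i)
  }
  invisible(n2ll(pack(0.2)))  # symbolic pattern with non-zero correlations
  par0 <- pack(r_start)
  zpos <- setdiff(seq_len(pos), unlist(lapply(par_index, `[`, 1:2)))
  lower <- rep(log(floor_), pos); lower[zpos] <- -zmax
  upper <- rep(log(varp * 100), pos); upper[zpos] <- zmax
  if (length(zpos)) {
    obj_z <- function(z) { p <- par0; p[zpos] <- z; n2ll(p)$value }
    o1 <- stats::optim(par0[zpos], obj_z, method = "L-BFGS-B",
                       lower = -zmax, upper = zmax,
                       control = list(maxit = 25L, factr = 1e9,
                                      ndeps = rep(1e-4, length(zpos))))
    par0[zpos] <- o1$par
  }
  opt <- stats::optim(par0, function(p) n2ll(p)$value, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = 150L, factr = 1e7,
                                     ndeps = rep(1e-4, pos)))
  fin <- n2ll(opt$par)
  list(K0 = fin$K0, s = fin$s, logl = -opt$value / 2,
       converged = opt$convergence == 0L, counts = opt$counts,
       R0i = fin$R0i, ch = fin$ch)
}

# average information over the free covariance parameters of a bivariate fit
.ai_biv <- function(prep, design, K0, R0i, ch, s, fix_term) {
  m <- prep$m
  n <- prep$n
  terms_all <- names(K0)
  nt <- length(terms_all)
  e1 <- prep$Y[, 1L] - as.numeric(prep$T %*% s[seq_len(m)])
  e2 <- prep$Y[, 2L] - as.numeric(prep$T %*% s[m + seq_len(m)])
  Py1 <- R0i[1, 1] * e1 + R0i[1, 2] * e2
  Py2 <- R0i[2, 1] * e1 + R0i[2, 2] * e2

  base_w <- function(k) {
    if (terms_all[k] == "residual") {
      t1 <- Py1; t2 <- Py2
      Z <- NULL
    } else {
      Z <- design$Zlist[[k]]
      t1 <- as.numeric(crossprod(Z, Py1))
      t2 <- as.numeric(crossprod(Z, Py2))
      if (terms_all[k] == "animal") {
        t1 <- as.numeric(solve(prep$Ainv, t1))
        t2 <- as.numeric(solve(prep$Ainv, t2))
      }
      t1 <- as.numeric(Z %*% t1)
      t2 <- as.numeric(Z %*% t2)
    }
    list(v1 = cbind(t1, 0), c = cbind(t2, t1), v2 = cbind(0, t2))
  }

  W <- list()
  par_index <- list()
  pos <- 0L
  for (k in seq_len(nt)) {
    bw <- base_w(k)
    if (!is.na(fix_term) && terms_all[k] == fix_term) {
      b <- K0[[k]]
      r <- b[1, 2] / sqrt(b[1, 1] * b[2, 2])
      w1 <- bw$v1 + 0.5 * r * sqrt(b[2, 2] / b[1, 1]) * bw$c
      w2 <- bw$v2 + 0.5 * r * sqrt(b[1, 1] / b[2, 2]) * bw$c
      W <- c(W, list(w1, w2))
      par_index[[k]] <- pos + 1:2
      pos <- pos + 2L
    } else {
      W <- c(W, list(bw$v1, bw$c, bw$v2))
      par_index[[k]] <- pos + 1:3
      pos <- pos + 3L
    }
  }

  Pw <- function(w) {
    rw <- c(R0i[1, 1] * as.numeric(crossprod(prep$T, w[, 1L])) +
              R0i[1, 2] * as.numeric(crossprod(prep$T, w[, 2L])),
            R0i[2, 1] * as.numeric(crossprod(prep$T, w[, 1L])) +
              R0i[2, 2] * as.numeric(crossprod(prep$T, w[, 2L])))
    sw <- as.numeric(solve(ch, rw))
    d1 <- w[, 1L] - as.numeric(prep$T %*% sw[seq_len(m)])
    d2 <- w[, 2L] - as.numeric(prep$T %*% sw[m + seq_len(m)])
    cbind(R0i[1, 1] * d1 + R0i[1, 2] * d2,
          R0i[2, 1] * d1 + R0i[2, 2] * d2)
  }
  PWs <- lapply(W, Pw)
  np <- length(W)
  AI <- matrix(0, np, np)
  for (i in seq_len(np)) for (j in i:np) {
    AI[i, j] <- AI[j, i] <- 0.5 * sum(W[[i]] * PWs[[j]])
  }
  list(AI = AI, par_index = par_index)
}

#' @method print pd_bifit
#' @export
print.pd_bifit <- function(x, ...) {
  cat("Bivariate animal-model REML fit, traits:",
      paste(colnames(x$ebv), collapse = " / "), "\n")
  cat("  logL =", format(x$logLik, digits = 8),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat("  genetic correlation =", format(x$rg, digits = 3),
      "(se", format(x$rg_se, digits = 2), ")\n")
  print(x$vc, row.names = FALSE, digits = 3)
  invisible(x)
}

# Union sparsity pattern of the stacked two-trait MME coefficient matrix and
# per-component position maps; the three distinct entries of each 2 x 2
# inverse covariance block scale the same within-trait pattern, so assembly
# is pure vector arithmetic.
.biv_assembler <- function(prep) {
  m <- prep$m
  tsp <- function(M)
    as(as(Matrix::forceSymmetric(M), "CsparseMatrix"), "TsparseMatrix")
  comps <- lapply(c(list(prep$TtT), prep$D), tsp)
  m2 <- 2L * m
  ii <- list(); jj <- list()
  for (M in comps) {
    off <- M@i != M@j
    ii[[length(ii) + 1L]] <- c(M@i, M@i + m, M@i, M@j[off])
    jj[[length(jj) + 1L]] <- c(M@j, M@j + m, M@j + m, M@i[off] + m)
  }
  tmpl <- tsp(Matrix::sparseMatrix(i = unlist(ii) + 1L, j = unlist(jj) + 1L,
                                   x = 1, dims = c(m2, m2), symmetric = TRUE))
  keyof <- function(i, j) i + m2 * as.double(j)
  tkey <- keyof(tmpl@i, tmpl@j)
  maps <- lapply(comps, function(M) {
    off <- M@i != M@j
    list(m11 = match(keyof(M@i, M@j), tkey),
         m22 = match(keyof(M@i + m, M@j + m), tkey),
         m12a = match(keyof(M@i, M@j + m), tkey),
         m12b = match(keyof(M@j[off], M@i[off] + m), tkey),
         x = M@x, xoff = M@x[off])
  })
  list(tmpl = as(tmpl, "CsparseMatrix"), maps = maps)
}

.assemble_biv_x <- function(asmb, coefs) {
  xx <- numeric(length(asmb$tmpl@x))
  for (k in seq_along(asmb$maps)) {
    mp <- asmb$maps[[k]]
    cc <- coefs[[k]]
    xx[mp$m11] <- xx[mp$m11] + mp$x * cc[1, 1]
    xx[mp$m22] <- xx[mp$m22] + mp$x * cc[2, 2]
    xx[mp$m12a] <- xx[mp$m12a] + mp$x * cc[1, 2]
    xx[mp$m12b] <- xx[mp$m12b] + mp$xoff * cc[1, 2]
  }
  xx
}

.assemble_biv <- function(asmb, coefs) {
  C <- asmb$tmpl
  C@x <- .assemble_biv_x(asmb, coefs)
  C
}
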