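#' Pedigree objects
#'
#' A `pedigree` is a topologically ordered table of animal/sire/dam triples
#' together with per-animal inbreeding coefficients. Parents always precede
#' their offspring, every named parent is present as an animal record (parents
#' that never appear as animals are auto-added as founders), and unknown
#' parents are stored as `NA`. The additive relationship matrix **A** and its
#' sparse inverse are derived from this object.
#'
#' @param animal,sire,dam character vectors of equal length; `sire`/`dam` may
#'   contain `NA` for unknown parents.
#' @return An object of class `pedigree`: a list with
#'   \describe{
#'     \item{id}{character vector of animal ids in topological order}
#'     \item{sire,dam}{integer indices into `id` (0 = unknown parent)}
#'     \item{F}{inbreeding coefficient per animal}
#'     \item{d}{Mendelian-sampling variance ratios used by [a_inverse()]}
#'   }
#' @seealso [read_pedigree()], [relationship_matrix()], [a_inverse()]
#' @export
new_pedigree <- function(animal, sire, dam) {
  animal <- as.character(animal)
  sire <- as.character(sire)
  dam <- as.character(dam)
  if (anyNA(animal) || any(!nzchar(animal)))
    stop("animal ids must be non-empty strings")
  if (anyDuplicated(animal))
    stop("duplicate animal id(s): ",
         paste(unique(animal[duplicated(animal)]), collapse = ", "))
  if (any(!is.na(sire) & sire == animal) || any(!is.na(dam) & dam == animal))
    stop("animal listed as its own parent: ",
         paste(animal[(!is.na(sire) & sire == animal) |
                        (!is.na(dam) & dam == animal)], collapse = ", "))

  # auto-add parents that never occur as animal records, as founders
  parents <- setdiff(stats::na.omit(c(sire, dam)), animal)
  if (length(parents)) {
    animal <- c(parents, animal)
    sire <- c(rep(NA_character_, length(parents)), sire)
    dam <- c(rep(NA_character_, length(parents)), dam)
  }

  n <- length(animal)
  si <- match(sire, animal)
  di <- match(dam, animal)
  si[is.na(si)] <- 0L
  di[is.na(di)] <- 0L

  ord <- .topo_order(animal, si, di)
  rnk <- integer(n)
  rnk[ord] <- seq_len(n)
  id <- animal[ord]
  si2 <- ifelse(si[ord] > 0L, rnk[pmax(si[ord], 1L)], 0L)
  di2 <- ifelse(di[ord] > 0L, rnk[pmax(di[ord], 1L)], 0L)

  ped <- structure(list(id = id, sire = as.integer(si2), dam = as.integer(di2)),
                   class = "pedigree")
  fd <- .ml_inbreeding(ped)
  ped$F <- fd$F
  ped$d <- fd$d
  ped
}

# Kahn topological sort, parents before offspring; names a cycle member on failure.
.topo_order <- function(id, si, di) {
  n <- length(id)
  nchild <- integer(n)
  indeg <- (si > 0L) + (di > 0L)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) if (p > 0L) children[[p]] <- c(children[[p]], i)
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    ord <- c(ord, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n) {
    left <- setdiff(seq_len(n), ord)
    stop("pedigree contains a cycle involving animal '", id[left[1L]], "'")
  }
  ord
}

# Meuwissen & Luo inbreeding: F[i] = sum_j L[i,j]^2 d[j] - 1 over ancestors j,
# accumulating gene-flow coefficients from animal i back through the pedigree.
.ml_inbreeding <- function(ped) {
  n <- length(ped$id)
  si <- ped$sire; di <- ped$dam
  f <- numeric(n)
  dv <- numeric(n)
  coef <- numeric(n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    dv[i] <- if (s > 0L && d > 0L) 0.5 - 0.25 * (f[s] + f[d])
             else if (s > 0L) 0.75 - 0.25 * f[s]
             else if (d > 0L) 0.75 - 0.25 * f[d]
             else 1
    if (s == 0L || d == 0L) { f[i] <- 0; next }
    # collect ancestors of i (including i)
    anc <- i
    frontier <- i
    while (length(frontier)) {
      ps <- c(si[frontier], di[frontier])
      ps <- ps[ps > 0L]
      ps <- setdiff(unique(ps), anc)
      anc <- c(anc, ps)
      frontier <- ps
    }
    anc <- sort(unique(anc), decreasing = TRUE)
    coef[i] <- 1
    aii <- 0
    for (j in anc) {
      cj <- coef[j]
      if (cj == 0) next
      aii <- aii + cj * cj * dv[j]
      if (si[j] > 0L) coef[si[j]] <- coef[si[j]] + cj / 2
      if (di[j] > 0L) coef[di[j]] <- coef[di[j]] + cj / 2
    }
    coef[anc] <- 0
    f[i] <- aii - 1
  }
  list(F = f, d = dv)
}

#' Read a pedigree from CSV
#'
#' Expects a header `animal,sire,dam` (extra columns are ignored). Unknown
#' parents may be coded by any of the `unknown_codes` tokens. Records are
#' topologically sorted on read; missing parent records are added as founders.
#'
#' @param path path to a CSV file.
#' @param unknown_codes tokens treated as "parent unknown".
#' @return a [new_pedigree()] object.
#' @export
read_pedigree <- function(path, unknown_codes = c("0", "", "NA")) {
  df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  if (ncol(df) < 3L)
    stop("pedigree CSV needs at least 3 columns (animal, sire, dam)")
  names(df)[1:3] <- c("animal", "sire", "dam")
  norm <- function(x) {
    x[is.na(x) | x %in% unknown_codes] <- NA_character_
    x
  }
  new_pedigree(df$animal, norm(df$sire), norm(df$dam))
}

#' Write a pedigree to CSV (topologically sorted, unknown parents as 0)
#'
#' @param ped a pedigree.
#' @param path output path.
#' @export
write_pedigree <- function(ped, path) {
  df <- as.data.frame(ped)
  df$sire[is.na(df$sire)] <- "0"
  df$dam[is.na(df$dam)] <- "0"
  utils::write.csv(df[, c("animal", "sire", "dam")], path,
                   row.names = FALSE, quote = FALSE)
}

#' @export
as.data.frame.pedigree <- function(x, ...) {
  data.frame(animal = x$id,
             sire = ifelse(x$sire > 0L, x$id[pmax(x$sire, 1L)], NA_character_),
             dam = ifelse(x$dam > 0L, x$id[pmax(x$dam, 1L)], NA_character_),
             F = x$F,
             stringsAsFactors = FALSE)
}

#' @method print pedigree
#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree with", length(x$id), "animals (",
      sum(x$sire == 0L & x$dam == 0L), "founders ), mean F =",
      format(mean(x$F), digits = 4), "\n")
  invisible(x)
}

#' Additive (numerator) relationship matrix
#'
#' Dense **A** by the tabular (recursive) method:
#' `a_ij = 0.5 (a_{i,s(j)} + a_{i,d(j)})` for `i < j` and
#' `a_ii = 1 + 0.5 a_{s(i),d(i)}`. Unknown parents contribute 0.
#'
#' @param ped a pedigree (at most 5000 animals; **A** is dense).
#' @return symmetric matrix with `dimnames` the animal ids; the diagonal is
#'   `1 + F`.
#' @export
relationship_matrix <- function(ped) {
  n <- length(ped$id)
  if (n > 5000L)
    stop("dense A limited to 5000 animals; use a_inverse() for larger pedigrees")
  si <- ped$sire; di <- ped$dam
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      prev <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (s > 0L) row <- row + 0.5 * A[prev, s]
      if (d > 0L) row <- row + 0.5 * A[prev, d]
      A[prev, i] <- row
      A[i, prev] <- row
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  A
}

#' Sparse inverse of the additive relationship matrix
#'
#' Henderson's rules with inbreeding accounted for through the
#' Meuwissen-Luo Mendelian-sampling variances stored on the pedigree.
#'
#' @param ped a pedigree.
#' @return a sparse symmetric matrix (`Matrix::dsCMatrix`) with animal ids as
#'   dimnames.
#' @export
a_inverse <- function(ped) {
  n <- length(ped$id)
  si <- ped$sire; di <- ped$dam
  alpha <- 1 / ped$d
  ii <- list(); jj <- list(); xx <- list()
  push <- function(i, j, x) {
    k <- length(ii) + 1L
    ii[[k]] <<- i; jj[[k]] <<- j; xx[[k]] <<- x
  }
  idx <- seq_len(n)
  push(idx, idx, alpha)
  hs <- si > 0L
  hd <- di > 0L
  if (any(hs)) {
    push(idx[hs], si[hs], -alpha[hs] / 2)
    push(si[hs], idx[hs], -alpha[hs] / 2)
    push(si[hs], si[hs], alpha[hs] / 4)
  }
  if (any(hd)) {
    push(idx[hd], di[hd], -alpha[hd] / 2)
    push(di[hd], idx[hd], -alpha[hd] / 2)
    push(di[hd], di[hd], alpha[hd] / 4)
  }
  hb <- hs & hd
  if (any(hb)) {
    push(si[hb], di[hb], alpha[hb] / 4)
    push(di[hb], si[hb], alpha[hb] / 4)
  }
  M <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n, n), dimnames = list(ped$id, ped$id))
  Matrix::forceSymmetric(M)
}

#' Mean inbreeding of a subset of animals
#'
#' Average of the diagonal elements of **A** minus one, i.e. mean F, over the
#' given animals.
#'
#' @param ped a pedigree.
#' @param subset character vector of animal ids.
#' @export
mean_inbreeding <- function(ped, subset) {
  if (!length(subset)) stop("subset is empty")
  ix <- match(as.character(subset), ped$id)
  if (anyNA(ix))
    stop("unknown animal id(s): ",
         paste(utils::head(subset[is.na(ix)], 5L), collapse = ", "))
  mean(ped$F[ix])
}

#' Restrict a pedigree to anchors plus recent ancestors
#'
#' Keeps the anchor animals and all ancestors within `depth` meioses; parents
#' of retained animals that fall outside the cut become unknown.
#'
#' @param ped a pedigree.
#' @param anchors ids whose ancestry should be retained.
#' @param depth maximum number of meioses (generations) to walk back;
#'   `depth = 0` keeps the anchors only.
#' @export
prune_to_generations <- function(ped, anchors, depth) {
  stopifnot(depth >= 0)
  ix <- match(as.character(anchors), ped$id)
  if (anyNA(ix))
    stop("unknown anchor id(s): ",
         paste(utils::head(anchors[is.na(ix)], 5L), collapse = ", "))
  dist <- rep(Inf, length(ped$id))
  dist[ix] <- 0
  frontier <- ix
  while (length(frontier)) {
    nxt <- integer(0)
    for (p in list(ped$sire[frontier], ped$dam[frontier])) {
      ok <- p > 0L
      cand <- p[ok]
      better <- dist[frontier[ok]] + 1 < dist[cand]
      upd <- cand[better]
      dist[upd] <- dist[frontier[ok]][better] + 1
      nxt <- c(nxt, upd)
    }
    frontier <- unique(nxt)
  }
  keep <- which(dist <= depth)
  id <- ped$id[keep]
  inset <- function(p) ifelse(p %in% keep, ped$id[pmax(p, 1L)], NA_character_)
  new_pedigree(id, inset(ped$sire[keep]), inset(ped$dam[keep]))
}
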