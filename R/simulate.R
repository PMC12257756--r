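#' Simulation configuration for pedigree and damage-phenotype data
#'
#' Defines the population and variance structure used by [simulate_pedigree()]
#' and [simulate_phenotypes()]. The defaults emulate a multi-line pig nucleus
#' population: several purebred lines with discrete generations, litters nested
#' in dams, a tested (scored) subset of each litter housed in pens of 6-16
#' animals that mix litters, herd-year-season groups, 23 scorers, and scoring
#' ages around 154 days. Bivariate ear/tail liabilities are generated from
#' additive-genetic, litter, pen-group, herd-year-season and residual
#' components with heritability 0.05 per trait and a genetic correlation of
#' 0.45.
#'
#' @param n_lines number of closed lines (no across-line relationships).
#' @param generations number of discrete generations including the founder
#'   generation; generations after the first are phenotyped.
#' @param sires_per_gen,dams_per_gen breeding males/females per line and
#'   generation; each dam produces one litter.
#' @param litter_size list with `mean`, `min`, `max` of the (truncated
#'   Poisson) litter-size distribution at birth.
#' @param phenotyped_fraction probability that a born piglet enters the scored
#'   test group; only tested animals are instantiated and phenotyped.
#' @param pen_size integer range (min, max) of pen-group sizes.
#' @param n_hys_scoring,n_hys_birth herd-year-season levels per line-generation
#'   cohort for scoring (pens) and birth (litters).
#' @param n_scorers number of scoring technicians (global pool).
#' @param age_days list with `mean`, `sd`, `min`, `max` of age at scoring.
#' @param var_a,var_l,var_g,var_hys,var_e variance components per trait
#'   (length 1 or 2: ear, tail) on the liability scale.
#' @param r_g,r_l,r_pen,r_hys,r_e ear-tail correlations of the additive,
#'   litter, pen, herd-year-season and residual effects.
#' @param mode `"gaussian"` returns the liabilities as phenotypes;
#'   `"ordinal"` thresholds them into 0-3 scores.
#' @param threshold_probs cumulative probabilities defining the three ordinal
#'   cutpoints when `thresholds` is `NULL`; the defaults give score
#'   prevalences of roughly 75/15/7/3 percent.
#' @param thresholds optional 2 x 3 matrix of explicit liability cutpoints
#'   (rows = ear, tail); strictly increasing per row.
#' @param sex_effect,line_effect_sd,sexline_sd,scorer_sd,age_slope fixed-effect
#'   generating values on the liability scale (age slope per day, age centered
#'   at its mean).
#' @param seed integer seed; all stochastic steps are replayable from it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_lines = 6L,
                       generations = 3L,
                       sires_per_gen = 7L,
                       dams_per_gen = 108L,
                       litter_size = list(mean = 12.5, min = 1L, max = 30L),
                       phenotyped_fraction = 0.31,
                       pen_size = c(6L, 16L),
                       n_hys_scoring = 3L,
                       n_hys_birth = 4L,
                       n_scorers = 23L,
                       age_days = list(mean = 153.5, sd = 15, min = 119L, max = 221L),
                       var_a = 0.05, var_l = 0.10, var_g = 0.20,
                       var_hys = 0.10, var_e = 0.55,
                       r_g = 0.45, r_l = 0.20, r_pen = 0.10,
                       r_hys = 0.10, r_e = 0.05,
                       mode = c("gaussian", "ordinal"),
                       threshold_probs = c(0.75, 0.90, 0.97),
                       thresholds = NULL,
                       sex_effect = 0.05,
                       line_effect_sd = 0.15,
                       sexline_sd = 0.03,
                       scorer_sd = 0.05,
                       age_slope = 0.0015,
                       seed = 1L) {
  cfg <- list(n_lines = as.integer(n_lines), generations = as.integer(generations),
              sires_per_gen = as.integer(sires_per_gen),
              dams_per_gen = as.integer(dams_per_gen),
              litter_size = litter_size,
              phenotyped_fraction = phenotyped_fraction,
              pen_size = as.integer(pen_size),
              n_hys_scoring = as.integer(n_hys_scoring),
              n_hys_birth = as.integer(n_hys_birth),
              n_scorers = as.integer(n_scorers),
              age_days = age_days,
              var_a = rep_len(var_a, 2L), var_l = rep_len(var_l, 2L),
              var_g = rep_len(var_g, 2L), var_hys = rep_len(var_hys, 2L),
              var_e = rep_len(var_e, 2L),
              r_g = r_g, r_l = r_l, r_pen = r_pen, r_hys = r_hys, r_e = r_e,
              mode = match.arg(mode),
              threshold_probs = threshold_probs,
              thresholds = thresholds,
              sex_effect = sex_effect, line_effect_sd = line_effect_sd,
              sexline_sd = sexline_sd, scorer_sd = scorer_sd,
              age_slope = age_slope,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  vars <- c(cfg$var_a, cfg$var_l, cfg$var_g, cfg$var_hys, cfg$var_e)
  if (any(vars < 0)) stop("variance components must be >= 0")
  cors <- c(cfg$r_g, cfg$r_l, cfg$r_pen, cfg$r_hys, cfg$r_e)
  if (any(abs(cors) > 1)) stop("correlations must lie in [-1, 1]")
  if (cfg$pen_size[1L] > cfg$pen_size[2L] || cfg$pen_size[1L] < 1L)
    stop("invalid pen size range")
  if (!is.null(cfg$thresholds)) {
    th <- cfg$thresholds
    if (!is.matrix(th) || !all(dim(th) == c(2L, 3L)))
      stop("thresholds must be a 2 x 3 matrix (rows: ear, tail)")
    if (any(apply(th, 1L, function(z) any(diff(z) <= 0))))
      stop("thresholds must be strictly increasing")
  } else if (any(diff(cfg$threshold_probs) <= 0) ||
             any(cfg$threshold_probs <= 0 | cfg$threshold_probs >= 1)) {
    stop("threshold_probs must be strictly increasing in (0, 1)")
  }
  if (cfg$phenotyped_fraction <= 0 || cfg$phenotyped_fraction > 1)
    stop("phenotyped_fraction must be in (0, 1]")
  if (cfg$generations < 1L) stop("need at least one generation")
  invisible(cfg)
}

#' Read / write a simulation configuration as YAML
#' @param path YAML file path.
#' @rdname sim_config_io
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$thresholds)) raw$thresholds <- matrix(unlist(raw$thresholds), 2L, 3L, byrow = TRUE)
  do.call(sim_config, raw)
}

#' @param cfg a `sim_config`.
#' @rdname sim_config_io
#' @export
write_sim_config <- function(cfg, path) {
  out <- unclass(cfg)
  if (!is.null(out$thresholds)) out$thresholds <- apply(out$thresholds, 1L, c, simplify = FALSE)
  yaml::write_yaml(out, path)
  invisible(path)
}

# truncated-Poisson litter sizes (mean before truncation, clamped to [min,max])
.draw_litter_sizes <- function(n, ls) {
  pmin(pmax(stats::rpois(n, ls$mean), ls$min), ls$max)
}

#' Simulate a multi-line pedigree with housing-group assignments
#'
#' Generates discrete generations of closed lines with random mating, litters
#' nested in dams (one litter per dam and generation), a random tested subset
#' of each litter, and pens that interleave litters within a line-generation
#' cohort so that nearly all pens house more than one litter. Sexes are
#' assigned 1:1 at random. Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return a list of class `sim_pedigree` with elements `pedigree` (a
#'   [new_pedigree()] object over all instantiated animals) and `groups`, a
#'   data frame with one row per phenotyped animal: line, generation, sex,
#'   litter, pen, herd-year-season of birth and scoring, scorer, age at
#'   scoring and birth date.
#' @export
simulate_pedigree <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  an <- character(0); si <- character(0); da <- character(0)
  rows <- list()
  for (l in seq_len(cfg$n_lines)) {
    males <- sprintf("L%d-G0-M%03d", l, seq_len(cfg$sires_per_gen))
    females <- sprintf("L%d-G0-F%03d", l, seq_len(cfg$dams_per_gen))
    an <- c(an, males, females)
    si <- c(si, rep(NA_character_, length(males) + length(females)))
    da <- c(da, rep(NA_character_, length(males) + length(females)))
    for (g in seq_len(cfg$generations - 1L)) {
      sires <- males
      dams <- females
      litter_sizes <- .draw_litter_sizes(length(dams), cfg$litter_size)
      tested <- stats::rbinom(length(dams), litter_sizes, cfg$phenotyped_fraction)
      mate <- sample(sires, length(dams), replace = TRUE)
      cohort <- list()
      for (k in seq_along(dams)) {
        nt <- tested[k]
        if (nt == 0L) next
        ids <- sprintf("L%d-G%d-D%03d-%02d", l, g, k, seq_len(nt))
        litter <- sprintf("LIT-L%d-G%d-%03d", l, g, k)
        sex <- sample(rep_len(c("M", "F"), nt))
        bd <- as.Date("2021-01-01") + (g - 1L) * 240L + sample(0:119, 1L)
        an <- c(an, ids)
        si <- c(si, rep(mate[k], nt))
        da <- c(da, rep(dams[k], nt))
        cohort[[length(cohort) + 1L]] <-
          data.frame(animal = ids, line = sprintf("line%d", l), generation = g,
                     sex = sex, litter = litter,
                     hys_birth = sprintf("HB-L%d-G%d-%d", l, g,
                                         sample.int(cfg$n_hys_birth, 1L)),
                     birth_date = bd, stringsAsFactors = FALSE)
      }
      cohort <- do.call(rbind, cohort)
      if (is.null(cohort) || nrow(cohort) < cfg$pen_size[1L])
        stop("line ", l, " generation ", g, ": cohort of ",
             if (is.null(cohort)) 0L else nrow(cohort),
             " animals cannot fill a pen of at least ", cfg$pen_size[1L])
      # interleave litters so pens mix litters
      by_lit <- split(seq_len(nrow(cohort)), cohort$litter)
      by_lit <- lapply(by_lit[sample.int(length(by_lit))],
                       function(v) v[sample.int(length(v))])
      maxlen <- max(lengths(by_lit))
      ordidx <- unlist(lapply(seq_len(maxlen), function(r)
        unlist(lapply(by_lit, function(v) if (length(v) >= r) v[r] else NULL))),
        use.names = FALSE)
      cohort <- cohort[ordidx, , drop = FALSE]
      n <- nrow(cohort)
      sizes <- integer(0)
      while (sum(sizes) < n)
        sizes <- c(sizes, sample(cfg$pen_size[1L]:cfg$pen_size[2L], 1L))
      sizes[length(sizes)] <- n - sum(sizes[-length(sizes)])
      if (sizes[length(sizes)] < cfg$pen_size[1L] && length(sizes) > 1L) {
        sizes[length(sizes) - 1L] <- sizes[length(sizes) - 1L] + sizes[length(sizes)]
        sizes <- sizes[-length(sizes)]
      }
      pen_of <- rep(seq_along(sizes), sizes)
      cohort$pen <- sprintf("PEN-L%d-G%d-%03d", l, g, pen_of)
      pen_hys <- sample.int(cfg$n_hys_scoring, length(sizes), replace = TRUE)
      pen_scorer <- sample.int(cfg$n_scorers, length(sizes), replace = TRUE)
      cohort$hys_scoring <- sprintf("HS-L%d-G%d-%d", l, g, pen_hys[pen_of])
      cohort$scorer <- sprintf("scorer%02d", pen_scorer[pen_of])
      age <- round(stats::rnorm(n, cfg$age_days$mean, cfg$age_days$sd))
      cohort$age_days <- pmin(pmax(age, cfg$age_days$min), cfg$age_days$max)
      rows[[length(rows) + 1L]] <- cohort
      # next generation's parents drawn from this cohort
      if (g < cfg$generations - 1L) {
        mcand <- cohort$animal[cohort$sex == "M"]
        fcand <- cohort$animal[cohort$sex == "F"]
        if (length(mcand) < cfg$sires_per_gen || length(fcand) < cfg$dams_per_gen)
          stop("line ", l, " generation ", g,
               ": not enough candidates to supply the next generation's parents")
        males <- sample(mcand, cfg$sires_per_gen)
        females <- sample(fcand, cfg$dams_per_gen)
      }
    }
  }
  groups <- if (length(rows)) do.call(rbind, rows) else
    data.frame(animal = character(0))
  rownames(groups) <- NULL
  ped <- new_pedigree(an, si, da)
  if (nrow(groups)) groups <- groups[order(match(groups$animal, ped$id)), , drop = FALSE]
  rownames(groups) <- NULL
  structure(list(pedigree = ped, groups = groups), class = "sim_pedigree")
}

.cov2 <- function(v, r) {
  s <- sqrt(v)
  m <- matrix(c(v[1L], r * s[1L] * s[2L], r * s[1L] * s[2L], v[2L]), 2L, 2L)
  if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) < -1e-12)
    stop("2x2 covariance block is not positive semi-definite")
  m
}

.rmvn2 <- function(n, sigma) {
  # n draws from N(0, sigma), sigma 2x2 PSD
  ev <- eigen(sigma, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2L)
  matrix(stats::rnorm(2L * n), n, 2L) %*% t(L)
}

#' Simulate bivariate ear/tail damage phenotypes on a pedigree
#'
#' Breeding values follow the pedigree: founders are drawn from
#' `N(0, Sigma_a)` and non-founders as the parent average plus a
#' Mendelian-sampling deviation with variance `0.5 Sigma_a (1 - 0.5(F_s+F_d))`
#' (reduced accordingly when a parent is unknown), so simulated breeding
#' values are consistent with the additive relationship matrix. Litter, pen
#' and herd-year-season effects are i.i.d. draws from their 2 x 2
#' covariances. The liability is the fixed part plus all random effects; in
#' gaussian mode it is returned as the phenotype (columns `ED03`/`TD03` hold
#' the continuous liabilities), in ordinal mode it is cut at three thresholds
#' into scores 0-3 and the seven trait definitions are derived.
#'
#' @param sp a `sim_pedigree` from [simulate_pedigree()].
#' @param cfg the same [sim_config()].
#' @return a list of class `sim_dataset`: `pedigree`, `phenotypes` (one row
#'   per phenotyped animal), and `truth` (true breeding values for every
#'   pedigree animal, true litter/pen/hys effect realizations, liabilities,
#'   thresholds used, generating config).
#' @export
simulate_phenotypes <- function(sp, cfg) {
  stopifnot(inherits(sp, "sim_pedigree"))
  validate_sim_config(cfg)
  set.seed(cfg$seed + 1L)
  ped <- sp$pedigree
  g <- sp$groups
  n <- length(ped$id)

  sig_a <- .cov2(cfg$var_a, cfg$r_g)
  sig_l <- .cov2(cfg$var_l, cfg$r_l)
  sig_p <- .cov2(cfg$var_g, cfg$r_pen)
  sig_h <- .cov2(cfg$var_hys, cfg$r_hys)
  sig_e <- .cov2(cfg$var_e, cfg$r_e)

  # breeding values down the pedigree (PSD-safe square root of Sigma_a)
  ev <- eigen(sig_a, symmetric = TRUE)
  La <- diag(sqrt(pmax(ev$values, 0)), 2L) %*% t(ev$vectors)
  z <- matrix(stats::rnorm(2L * n), n, 2L) %*% La
  bv <- matrix(0, n, 2L, dimnames = list(ped$id, c("ear", "tail")))
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    pa <- numeric(2L)
    if (s > 0L) pa <- pa + 0.5 * bv[s, ]
    if (d > 0L) pa <- pa + 0.5 * bv[d, ]
    bv[i, ] <- pa + sqrt(ped$d[i]) * z[i, ]
  }

  if (!nrow(g)) {
    return(structure(list(pedigree = ped,
                          phenotypes = g,
                          truth = list(bv = bv, config = cfg)),
                     class = "sim_dataset"))
  }

  lev <- function(x) sort(unique(x))
  lit_lev <- lev(g$litter); pen_lev <- lev(g$pen); hys_lev <- lev(g$hys_scoring)
  eff_l <- .rmvn2(length(lit_lev), sig_l); rownames(eff_l) <- lit_lev
  eff_p <- .rmvn2(length(pen_lev), sig_p); rownames(eff_p) <- pen_lev
  eff_h <- .rmvn2(length(hys_lev), sig_h); rownames(eff_h) <- hys_lev
  res <- .rmvn2(nrow(g), sig_e)

  # fixed-effect generating values
  lines <- lev(g$line); scorers <- lev(g$scorer)
  line_eff <- stats::rnorm(length(lines), 0, cfg$line_effect_sd)
  names(line_eff) <- lines
  scorer_eff <- stats::rnorm(length(scorers), 0, cfg$scorer_sd)
  names(scorer_eff) <- scorers
  sexline <- matrix(stats::rnorm(2L * length(lines), 0, cfg$sexline_sd),
                    length(lines), 2L, dimnames = list(lines, c("M", "F")))
  fixed <- line_eff[g$line] +
    ifelse(g$sex == "M", cfg$sex_effect, 0) +
    sexline[cbind(g$line, g$sex)] +
    scorer_eff[g$scorer] +
    cfg$age_slope * (g$age_days - cfg$age_days$mean)

  ia <- match(g$animal, ped$id)
  liab <- fixed + bv[ia, ] + eff_l[g$litter, ] + eff_p[g$pen, ] +
    eff_h[g$hys_scoring, ] + res
  colnames(liab) <- c("ear", "tail")

  phen <- g
  if (cfg$mode == "gaussian") {
    phen$ED03 <- liab[, "ear"]
    phen$TD03 <- liab[, "tail"]
    thr <- NULL
  } else {
    thr <- cfg$thresholds
    if (is.null(thr)) {
      thr <- rbind(stats::quantile(liab[, "ear"], cfg$threshold_probs),
                   stats::quantile(liab[, "tail"], cfg$threshold_probs))
    }
    rownames(thr) <- c("ear", "tail")
    cut03 <- function(x, tau) findInterval(x, tau)
    phen$ED03 <- cut03(liab[, "ear"], thr[1L, ])
    phen$TD03 <- cut03(liab[, "tail"], thr[2L, ])
    phen <- derive_traits(phen)
  }

  structure(list(pedigree = ped,
                 phenotypes = phen,
                 truth = list(bv = bv,
                              litter_effects = eff_l, pen_effects = eff_p,
                              hys_effects = eff_h, residuals = res,
                              liabilities = liab, fixed_part = fixed,
                              line_effects = line_eff, scorer_effects = scorer_eff,
                              thresholds = thr, config = cfg)),
            class = "sim_dataset")
}

#' Simulate a full dataset (pedigree + phenotypes) from a configuration
#' @param cfg a [sim_config()].
#' @return a `sim_dataset`; see [simulate_phenotypes()].
#' @export
simulate_dataset <- function(cfg) {
  simulate_phenotypes(simulate_pedigree(cfg), cfg)
}

#' Write a simulated dataset to plain-text files
#'
#' Writes `pedigree.csv`, `phenotypes.csv`, `truth.csv` (one row per
#' phenotyped animal with the true breeding values) and `config.yaml` into
#' `dir`. Round-trips losslessly via [read_dataset()]; identical seeds give
#' byte-identical files.
#'
#' @param ds a `sim_dataset`.
#' @param dir output directory (created if needed).
#' @export
write_dataset <- function(ds, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory ", dir)
  write_pedigree(ds$pedigree, file.path(dir, "pedigree.csv"))
  phen <- ds$phenotypes
  phen$birth_date <- format(phen$birth_date, "%Y-%m-%d")
  utils::write.csv(phen, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE, quote = FALSE)
  ia <- match(ds$phenotypes$animal, rownames(ds$truth$bv))
  truth <- data.frame(animal = ds$phenotypes$animal,
                      true_bv_ear = ds$truth$bv[ia, "ear"],
                      true_bv_tail = ds$truth$bv[ia, "tail"])
  utils::write.csv(truth, file.path(dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  write_sim_config(ds$truth$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read back a dataset written by [write_dataset()]
#' @param dir directory containing `pedigree.csv` and `phenotypes.csv`.
#' @return list with `pedigree`, `phenotypes`, `truth` (or `NULL`), `config`
#'   (or `NULL`).
#' @export
read_dataset <- function(dir) {
  ped <- read_pedigree(file.path(dir, "pedigree.csv"))
  phen <- utils::read.csv(file.path(dir, "phenotypes.csv"),
                          stringsAsFactors = FALSE)
  if ("birth_date" %in% names(phen)) phen$birth_date <- as.Date(phen$birth_date)
  tpath <- file.path(dir, "truth.csv")
  cpath <- file.path(dir, "config.yaml")
  list(pedigree = ped, phenotypes = phen,
       truth = if (file.exists(tpath)) utils::read.csv(tpath) else NULL,
       config = if (file.exists(cpath)) read_sim_config(cpath) else NULL)
}
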