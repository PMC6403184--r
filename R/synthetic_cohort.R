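#' The 48 ICBM "Mori" white-matter atlas region names
#'
#' Reads the packaged region-name list (standard label order 1-48). The
#' list is a configuration file, not hard-coded truth: a different
#' atlas-version mapping can be supplied to the cohort generator and the
#' feature-table builder.
#'
#' @param path optional path to an alternative two-column (label, region)
#'   TSV.
#' @return character vector of 48 region names, names attribute = label.
#' @export
mori_regions <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "icbm_mori_regions.tsv", package = "minfa")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(tab$region, tab$label)
}

#' Configuration for the synthetic FA cohort generator
#'
#' Describes a cohort of subjects with per-region mean fractional
#' anisotropy, demographic/cognitive covariates, a latent neurofeedback
#' aptitude score and a high/low label from its median split. Defaults
#' mirror an older-adult cohort: n = 21, age 48-77 years, and a negative
#' age-fornix FA correlation of -0.49.
#'
#' Each informative region correlates with the latent aptitude score by
#' the amount that makes its realized between-group (high vs low) Cohen's
#' d converge to the configured `d_r` as n grows. Because the split is at
#' the median of a Gaussian score, the achievable per-region |d| is
#' bounded near 2.6; larger requests are rejected. When several regions
#' are informative their residuals are anti-correlated near the
#' feasibility bound, keeping the regions' mutual correlation as small as
#' the configured effect sizes permit.
#'
#' @param n_subjects cohort size (default 21).
#' @param region_names the 48 region names (default [mori_regions()]).
#' @param informative_regions named numeric vector of signed Cohen's d
#'   values, names in `region_names`; empty (default) for a null cohort.
#' @param age_range length-2 years (default `c(48, 77)`, uniform).
#' @param age_fa_corr list with `region` and `r`: the target correlation
#'   between age and that region's FA (default fornix, -0.49). `NULL`
#'   disables the coupling.
#' @param covariate_spec named list of `function(n)` generators for the
#'   covariate columns; `NULL` uses built-in defaults (education, gender,
#'   handedness, verbal fluency VF-A/VF-S, trail-making TMT-A/TMT-B).
#' @param noise_sd FA-unit SD of per-region variation (default 0.04).
#' @param seed integer RNG seed.
#' @return a `"cohort_sim_config"` list.
#' @export
cohort_sim_config <- function(n_subjects = 21, region_names = mori_regions(),
                              informative_regions = numeric(0),
                              age_range = c(48, 77),
                              age_fa_corr = list(region = "Column and body of fornix",
                                                 r = -0.49),
                              covariate_spec = NULL, noise_sd = 0.04,
                              seed = 1) {
  if (length(informative_regions) > 0) {
    if (is.null(names(informative_regions)) ||
        !all(names(informative_regions) %in% region_names)) {
      stop("informative region name not in region_names")
    }
    if (any(!is.finite(informative_regions))) stop("effect sizes must be finite")
  }
  if (!is.null(age_fa_corr)) {
    if (abs(age_fa_corr$r) >= 1) stop("|age_fa_corr$r| must be < 1")
    if (!(age_fa_corr$region %in% region_names)) {
      stop("age_fa_corr region not in region_names")
    }
  }
  structure(list(n_subjects = n_subjects, region_names = region_names,
                 informative_regions = informative_regions,
                 age_range = age_range, age_fa_corr = age_fa_corr,
                 covariate_spec = covariate_spec, noise_sd = noise_sd,
                 seed = seed),
            class = "cohort_sim_config")
}

# Map a between-group Cohen's d (under a median split of a standard
# normal score) to the required score-region correlation rho:
#   mean gap = 2 rho E[|Z|]/... = rho * 2 sqrt(2/pi) * (1/2) ... for a
# median split of a standard normal s, E[z|s>0] - E[z|s<=0] = rho*2*sqrt(2/pi)
# and the within-group variance is 1 - (gap/2)^2, giving
#   d = c rho / sqrt(1 - (c rho / 2)^2),  c = 2 sqrt(2/pi).
rho_from_d <- function(d) {
  cc <- 2 * sqrt(2 / pi)
  rho <- d / sqrt(cc^2 + d^2 * cc^2 / 4)
  rho
}

#' Generate a synthetic FA cohort
#'
#' One row per subject with the 48 region FA means, covariates, a latent
#' continuous aptitude score and its median-split `"low"`/`"high"` label.
#' Informative regions acquire their configured between-group effect size
#' through loadings on the latent factor; the age-FA coupling for the
#' target region is imposed by Cholesky-style mixing of the standardized
#' age into that region's noise, giving exact control of the target
#' correlation in expectation.
#'
#' @param cfg a [cohort_sim_config()].
#' @return a `data.frame` (class `"minfa_cohort"`) with columns `subject`,
#'   one column per region (verbatim names), the covariates, `age`,
#'   `latent_score` and `label`.
#' @export
generate_fa_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_subjects
  regions <- cfg$region_names
  p <- length(regions)

  score <- stats::rnorm(n)                   # latent aptitude score, N(0,1)

  rho <- stats::setNames(numeric(p), regions)
  if (length(cfg$informative_regions) > 0) {
    r <- rho_from_d(cfg$informative_regions)
    if (any(abs(r) >= 1)) {
      stop(sprintf("effect size(s) too large; max |d| is about %.2f",
                   max_cohort_d()))
    }
    rho[names(cfg$informative_regions)] <- r
  }

  z <- matrix(stats::rnorm(n * p), n, p, dimnames = list(NULL, regions))
  # Informative regions: z_r = rho_r * score + residual. Residuals of the
  # informative set are mutually anti-correlated (near the feasibility
  # bound -1/(k-1)) so the regions stay as close to mutually independent
  # as the configured per-region effect sizes allow; a score built from
  # independent regions cannot carry several large d values at once.
  info <- names(cfg$informative_regions)
  k <- length(info)
  if (k >= 2) {
    e <- z[, info, drop = FALSE]
    kappa <- 0.9
    v <- e - kappa * rowMeans(e)
    v <- v / sqrt(1 - 2 * kappa / k + kappa^2 / k)
    z[, info] <- v
  }
  z <- sweep(z, 2, sqrt(1 - rho^2), `*`) + outer(score, rho)

  age <- stats::runif(n, cfg$age_range[1], cfg$age_range[2])
  if (!is.null(cfg$age_fa_corr)) {
    reg <- cfg$age_fa_corr$region
    r_r <- rho[reg]
    rho_res <- cfg$age_fa_corr$r / sqrt(1 - r_r^2)
    if (abs(rho_res) >= 1) {
      stop("age-FA target correlation incompatible with the region's effect size")
    }
    z_age <- as.numeric(scale(age))
    resid <- stats::rnorm(n)
    z[, reg] <- r_r * score +
      sqrt(1 - r_r^2) * (rho_res * z_age + sqrt(1 - rho_res^2) * resid)
  }

  base <- region_base_fa(p)
  fa <- sweep(sweep(z, 2, cfg$noise_sd, `*`), 2, base, `+`)
  fa <- pmin(pmax(fa, 0.02), 0.98)           # keep FA inside (0, 1)

  cov_spec <- cfg$covariate_spec %||% default_covariate_spec()
  covars <- as.data.frame(lapply(cov_spec, function(f) f(n)),
                          check.names = FALSE)

  out <- data.frame(subject = sprintf("S%02d", seq_len(n)),
                    check.names = FALSE)
  out <- cbind(out, as.data.frame(fa, check.names = FALSE), covars)
  out$age <- age
  out$latent_score <- score
  out$label <- median_split(score)
  class(out) <- c("minfa_cohort", "data.frame")
  attr(out, "region_names") <- unname(regions)
  out
}

# Upper bound on achievable per-region |d| (score-region correlation < 1).
max_cohort_d <- function() {
  cc <- 2 * sqrt(2 / pi)
  rho_max <- 0.999
  cc * rho_max / sqrt(1 - (cc * rho_max / 2)^2)
}

# Deterministic per-region baseline FA means in (0.3, 0.6), fixed across
# seeds so region identity is stable.
region_base_fa <- function(p) {
  0.30 + 0.28 * (((seq_len(p) * 17) %% p) / max(1, p - 1))
}

default_covariate_spec <- function() {
  list(
    education = function(n) pmin(18, pmax(9, round(stats::rnorm(n, 11.8, 2.2)))),
    gender = function(n) sample(c("f", "m"), n, replace = TRUE,
                                prob = c(10 / 21, 11 / 21)),
    handedness = function(n) sample(c("right", "left", "ambidextrous"), n,
                                    replace = TRUE, prob = c(16, 3, 2) / 21),
    vf_a = function(n) round(stats::rnorm(n, 25, 6)),
    vf_s = function(n) round(stats::rnorm(n, 20, 5)),
    tmt_a = function(n) round(pmax(15, stats::rnorm(n, 42, 13))),
    tmt_b = function(n) round(pmax(30, stats::rnorm(n, 95, 35))))
}

#' Write a cohort to CSV
#'
#' Plain CSV with one header row naming the 48 regions verbatim.
#'
#' @param cohort a `"minfa_cohort"` data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort CSV
#' @param path CSV path written by [write_cohort_csv()].
#' @return a `"minfa_cohort"` data.frame (label re-levelled low/high).
#' @export
read_cohort_csv <- function(path) {
  out <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if ("label" %in% names(out)) {
    out$label <- factor(out$label, levels = c("low", "high"))
  }
  class(out) <- c("minfa_cohort", "data.frame")
  out
}

#' Generate a paired FA / atlas-label volume fixture
#'
#' Small pre-aligned FA and integer label volumes for exercising the
#' region-extraction path. Regions are axis-aligned blocks; overlapping
#' blocks are rejected. Background and a deliberate fraction of region
#' voxels fall below the 0.25 FA floor so the masking rule is exercised.
#'
#' @param shape integer length-3 volume extents (each <= 32).
#' @param regions list of region specs: each a list with `label` (positive
#'   integer), `from`/`to` (inclusive 1-based voxel corners) and optional
#'   `fa` (values recycled over the block; default random in (0.1, 0.9)).
#' @param seed integer RNG seed.
#' @return list with `fa` (numeric array in \[0, 1\]) and `labels`
#'   (integer array, 0 = background).
#' @export
generate_fa_volume_fixture <- function(shape = c(16, 16, 8), regions, seed = 1) {
  if (any(shape > 32)) stop("fixture volumes are capped at 32 per axis")
  set.seed(seed)
  fa <- array(stats::runif(prod(shape), 0, 0.2), dim = shape)
  labels <- array(0L, dim = shape)
  for (rg in regions) {
    if (rg$label <= 0 || rg$label != round(rg$label)) {
      stop("region labels must be positive integers")
    }
    ii <- rg$from[1]:rg$to[1]; jj <- rg$from[2]:rg$to[2]; kk <- rg$from[3]:rg$to[3]
    if (any(labels[ii, jj, kk] != 0)) stop("overlapping label definitions")
    block_n <- length(ii) * length(jj) * length(kk)
    vals <- if (!is.null(rg$fa)) rep_len(rg$fa, block_n) else
      stats::runif(block_n, 0.1, 0.9)
    fa[ii, jj, kk] <- vals
    labels[ii, jj, kk] <- rg$label
  }
  list(fa = fa, labels = labels)
}
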