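#' Population specification for the profile simulator
#'
#' Describes one population's compositional distribution: per-component
#' mean percentage and standard error of that mean, the number of
#' individuals to draw, a sex ratio, and the detection threshold below
#' which a simulated component is censored to "nd". Defaults transcribe
#' the bundled six-population reference means.
#'
#' @param label population name.
#' @param mean named numeric vector of mean percentages (components with
#'   mean 0 are structural absences and are never generated).
#' @param se named numeric vector of standard errors (same components).
#' @param n number of individuals (>= 1).
#' @param sex_ratio proportion of males (default 0.5).
#' @param detection_threshold percentage below which a simulated component
#'   is recorded as not detected (default 0.01, mirroring trace "nd"
#'   entries).
#' @return List of class `"population_spec"`.
#' @export
#' @examples
#' population_spec("WDLN")
population_spec <- function(label, mean = NULL, se = NULL, n = NULL,
                            sex_ratio = 0.5, detection_threshold = 0.01) {
  if (is.null(mean) || is.null(se) || is.null(n)) {
    pm <- population_means()
    sub <- pm[pm$population == label, ]
    if (!nrow(sub))
      stop(sprintf("'%s' is not a bundled population; %s", label,
                   "supply mean, se and n explicitly"), call. = FALSE)
    if (is.null(mean)) mean <- setNames(sub$mean, sub$label)
    if (is.null(se)) se <- setNames(sub$se, sub$label)
    if (is.null(n)) n <- sub$n[1]
  }
  if (is.null(names(mean)) || is.null(names(se)) ||
      !identical(names(mean), names(se)))
    stop("'mean' and 'se' must share component names", call. = FALSE)
  if (any(mean < 0)) stop("means must be >= 0", call. = FALSE)
  if (any(se < 0))
    stop("negative SE: dispersion would be negative (infeasible config)",
         call. = FALSE)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  mean <- 100 * mean / sum(mean)  # renormalize to a composition
  structure(list(label = label, mean = mean, se = se, n = as.integer(n),
                 sex_ratio = sex_ratio,
                 detection_threshold = detection_threshold),
            class = "population_spec")
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf("<population_spec> %s: n = %d, %d components (%d structural zeros), detection threshold %g%%\n",
              x$label, x$n, length(x$mean), sum(x$mean == 0),
              x$detection_threshold))
  invisible(x)
}

#' Simulation configuration
#'
#' @param populations list of [population_spec] objects (default: the six
#'   bundled reference populations).
#' @param seed integer seed; a fixed seed makes [simulate_individuals()]
#'   byte-identical across runs.
#' @param sex_effect optional named numeric vector of per-component
#'   multiplicative shifts applied to male means (females use the spec
#'   means unchanged).
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(populations = NULL, seed = 1, sex_effect = NULL) {
  if (is.null(populations)) {
    pm <- population_means()
    populations <- lapply(unique(pm$population), population_spec)
  }
  stopifnot(all(vapply(populations, inherits, logical(1), "population_spec")))
  structure(list(populations = populations, seed = as.integer(seed),
                 sex_effect = sex_effect),
            class = "sim_config")
}

#' Calibrate logistic-normal dispersion to target standard errors
#'
#' Finds per-component Gaussian perturbation scales sigma such that
#' compositions drawn as `softmax(log(mean) + sigma * eps)` reproduce the
#' target per-component SE of the mean at the configured n, i.e. an
#' individual-level sd of `se * sqrt(n)`. Each component's sigma is
#' bracketed and bisected against a common-random-number Monte Carlo
#' estimate of the realized sd (two sweeps; the delta-method value
#' `sd / (p (1 - p))` seeds the bracket), so the procedure is
#' deterministic. Components with target 0 get sigma 0: under
#' compositional renormalization a strictly zero sd is unattainable while
#' any other component varies, so zero targets clamp at the lower bound.
#'
#' @param spec a [population_spec].
#' @param mc_draws Monte Carlo draws per bisection evaluation
#'   (default 400).
#' @param sweeps coordinate sweeps over the components (default 2).
#' @param seed seed for the calibration draws (default 20240384).
#' @return Named numeric vector of sigma values (0 for structural zeros
#'   and zero-SE components).
#' @export
calibrate_dispersion <- function(spec, mc_draws = 400, sweeps = 2,
                                 seed = 20240384) {
  stopifnot(inherits(spec, "population_spec"))
  p <- spec$mean / 100
  pos <- which(p > 0)
  target_sd <- spec$se * sqrt(spec$n) / 100     # proportion scale
  sigma <- setNames(numeric(length(p)), names(p))
  if (length(pos) < 2L) return(sigma)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  eps <- matrix(rnorm(mc_draws * length(pos)), mc_draws, length(pos))
  mu <- log(p[pos])
  realized_sd <- function(sig, j) {
    z <- sweep(eps, 2, sig, `*`)
    z <- sweep(z, 2, mu, `+`)
    w <- exp(z - apply(z, 1, max))
    comp <- w / rowSums(w)
    sd(comp[, j])
  }
  sig <- target_sd[pos] / (p[pos] * (1 - p[pos]))  # delta-method start
  sig[target_sd[pos] == 0] <- 0
  for (sweep_i in seq_len(sweeps)) {
    for (j in seq_along(pos)) {
      tgt <- target_sd[pos][j]
      if (tgt == 0) { sig[j] <- 0; next }
      lo <- 0; hi <- max(sig[j] * 2, 1e-3)
      while (realized_sd(replace(sig, j, hi), j) < tgt && hi < 50) hi <- hi * 2
      for (it in 1:30) {
        mid <- (lo + hi) / 2
        if (realized_sd(replace(sig, j, mid), j) < tgt) lo <- mid else hi <- mid
      }
      sig[j] <- (lo + hi) / 2
    }
  }
  sigma[pos] <- sig
  sigma
}

#' Simulate individual-level CHC peak tables
#'
#' Draws per-individual compositions around each population's mean by
#' logistic-normal perturbation -- `softmax(log(mean) + sigma * eps)` with
#' sigma from [calibrate_dispersion()] -- so that the empirical SE of
#' per-component means at the configured n matches the configured SE
#' within sampling error. Components falling below the detection
#' threshold are censored to "nd" (area 0) and the composition is
#' renormalized to 100. Raw areas are the composition times a random
#' total-area scalar (log-normal), so downstream area normalization is
#' exercised. Output is byte-identical for a fixed config seed.
#'
#' @param cfg a [sim_config].
#' @param calibration optional pre-computed list of sigma vectors, named
#'   by population label (see [calibrate_dispersion()]); computed on the
#'   fly when missing.
#' @return A long peak-table data.frame with columns
#'   `individual, population, sex, component, rt_min, area` (the dialect
#'   [profile_matrix()] reads). Undetected components are omitted, as in
#'   real integrations. Retention times are the catalog values when the
#'   components are catalog labels, `NA` otherwise.
#' @export
#' @examples
#' cfg <- sim_config(list(population_spec("WDLN")), seed = 7)
#' head(simulate_individuals(cfg))
simulate_individuals <- function(cfg, calibration = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(calibration))
    calibration <- lapply(setNames(cfg$populations,
                                   vapply(cfg$populations, `[[`, "", "label")),
                          calibrate_dispersion)
  rt_lookup <- tryCatch({
    cat30 <- chc_catalog()
    setNames(cat30$rt_min, cat30$label)
  }, error = function(e) numeric(0))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  rows <- list()
  for (spec in cfg$populations) {
    sigma <- calibration[[spec$label]]
    if (is.null(sigma)) sigma <- calibrate_dispersion(spec)
    p <- spec$mean / 100
    pos <- which(p > 0)
    n_male <- rbinom(1, spec$n, spec$sex_ratio)
    sexes <- sample(c(rep("male", n_male), rep("female", spec$n - n_male)))
    for (i in seq_len(spec$n)) {
      mu <- p[pos]
      if (!is.null(cfg$sex_effect) && sexes[i] == "male") {
        eff <- cfg$sex_effect[names(mu)]
        eff[is.na(eff)] <- 1
        mu <- mu * eff
      }
      z <- log(mu / sum(mu)) + sigma[pos] * rnorm(length(pos))
      w <- exp(z - max(z))
      comp <- 100 * w / sum(w)
      comp[comp < spec$detection_threshold] <- 0
      if (all(comp == 0)) comp[which.max(w)] <- 100
      comp <- 100 * comp / sum(comp)
      total_area <- exp(rnorm(1, log(1e6), 0.2))
      keep <- which(comp > 0)
      rows[[length(rows) + 1L]] <- data.frame(
        individual = sprintf("%s_%02d", spec$label, i),
        population = spec$label,
        sex = sexes[i],
        component = names(p)[pos][keep],
        rt_min = if (length(rt_lookup))
          unname(rt_lookup[names(p)[pos][keep]]) else NA_real_,
        area = comp[keep] / 100 * total_area,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate an alkane ladder and jittered peak retention times
#'
#' Places synthetic peaks so that their true retention indices equal the
#' catalog indices, then adds Gaussian retention-time jitter. With zero
#' jitter, [retention_index()] recovers the catalog indices exactly by
#' construction (the placement inverts the same interpolation).
#'
#' @param jitter_sd retention-time jitter in minutes (default 0).
#' @param seed integer seed.
#' @param catalog catalog data.frame (default [chc_catalog()]).
#' @return List with `ladder` (an [alkane_ladder]) and `peaks`
#'   (data.frame `label, ki_true, rt_min`).
#' @export
simulate_ladder <- function(jitter_sd = 0, seed = 1, catalog = chc_catalog()) {
  ladder <- build_ladder(catalog)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rt <- invert_retention_index(catalog$ki, ladder) +
    rnorm(nrow(catalog), 0, jitter_sd)
  list(ladder = ladder,
       peaks = data.frame(label = catalog$label, ki_true = catalog$ki,
                          rt_min = rt, stringsAsFactors = FALSE))
}
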