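#' Relative percentages from raw peak areas (area normalization)
#'
#' `percentage_i = 100 * area_i / sum(area)`. Scale-invariant; errors if
#' areas are all zero or any is negative.
#'
#' @param areas numeric vector of raw peak areas.
#' @return Numeric vector summing to 100.
#' @export
#' @examples
#' normalize_areas(c(1, 1, 2)) # 25 25 50
normalize_areas <- function(areas) {
  areas <- as.numeric(areas)
  if (any(is.na(areas)) || any(areas < 0))
    stop("areas must be non-negative and non-missing", call. = FALSE)
  tot <- sum(areas)
  if (tot <= 0) stop("all peak areas are zero", call. = FALSE)
  100 * areas / tot
}

#' Individuals x components profile matrix
#'
#' Builds the central container of the pipeline from a long peak table
#' (one row per individual x component): a matrix of relative percentages
#' with population and sex metadata per row. Input may carry raw areas
#' (renormalized per individual) or percentages (accepted and renormalized
#' to sum to 100). Components absent for an individual are stored as exact
#' zeros with `detected = FALSE` ("nd"): absence is information, not
#' missingness, and propagates as 0 into distances and ordinal coding.
#'
#' @param x data.frame with columns `individual`, `component`, and `area`
#'   (or `percent`), optionally `population` and `sex`.
#' @param components component ordering for the columns; defaults to the
#'   components present, in first-appearance order. Pass
#'   `chc_catalog()$label` to force the catalog order.
#' @return An object of class `"chc_profile"`: list with `percent`
#'   (matrix, rows sum to 100), `detected` (logical matrix), `population`,
#'   `sex` (named character vectors).
#' @export
profile_matrix <- function(x, components = NULL) {
  stopifnot(is.data.frame(x))
  val_col <- intersect(c("area", "percent"), names(x))[1]
  if (is.na(val_col) || !all(c("individual", "component") %in% names(x)))
    stop("need columns 'individual', 'component' and 'area' (or 'percent')",
         call. = FALSE)
  if (is.null(components)) components <- unique(x$component)
  if (!all(x$component %in% components))
    stop("components not in the requested column set: ",
         paste(head(setdiff(x$component, components)), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(paste(x$individual, x$component)))
    stop("duplicated individual x component rows", call. = FALSE)
  ids <- unique(x$individual)
  pc <- matrix(0, length(ids), length(components),
               dimnames = list(ids, components))
  pc[cbind(match(x$individual, ids), match(x$component, components))] <-
    x[[val_col]]
  pc <- t(apply(pc, 1, normalize_areas))
  dimnames(pc) <- list(ids, components)
  meta <- x[!duplicated(x$individual), , drop = FALSE]
  pop <- if ("population" %in% names(x))
    setNames(as.character(meta$population), meta$individual)[ids]
  else setNames(rep("all", length(ids)), ids)
  sex <- if ("sex" %in% names(x))
    setNames(as.character(meta$sex), meta$individual)[ids]
  else setNames(rep("unknown", length(ids)), ids)
  structure(list(percent = pc, detected = pc > 0,
                 population = pop, sex = sex),
            class = "chc_profile")
}

#' Read a peak-table CSV
#'
#' Expects the long dialect
#' `individual,population,sex,component,rt_min,area`.
#'
#' @param path CSV file path.
#' @param ... passed to [profile_matrix()].
#' @return A `"chc_profile"`.
#' @export
read_peak_table <- function(path, ...) {
  profile_matrix(read.csv(path, stringsAsFactors = FALSE), ...)
}

#' @export
print.chc_profile <- function(x, ...) {
  cat(sprintf("<chc_profile> %d individuals x %d components; populations: %s\n",
              nrow(x$percent), ncol(x$percent),
              paste(unique(x$population), collapse = ", ")))
  invisible(x)
}

#' Per-group component summaries (mean, SE, n)
#'
#' @param profile a `"chc_profile"`.
#' @param by grouping metadata: `"population"`, `"sex"`, or a vector with
#'   one label per individual.
#' @return data.frame with columns `group, component, mean, se, n`.
#' @export
group_summary <- function(profile, by = "population") {
  stopifnot(inherits(profile, "chc_profile"))
  g <- resolve_groups(profile, by)
  out <- do.call(rbind, lapply(unique(g), function(lev) {
    sub <- profile$percent[g == lev, , drop = FALSE]
    data.frame(group = lev, component = colnames(sub),
               mean = colMeans(sub),
               se = apply(sub, 2, sd) / sqrt(nrow(sub)),
               n = nrow(sub), row.names = NULL,
               stringsAsFactors = FALSE)
  }))
  out
}

resolve_groups <- function(profile, by) {
  if (length(by) == 1L && by %in% c("population", "sex"))
    return(profile[[by]])
  if (length(by) != nrow(profile$percent))
    stop("'by' must name metadata or give one label per individual",
         call. = FALSE)
  as.character(by)
}

#' Class composition of a group's mean profile
#'
#' Sums a group's mean component percentages by hydrocarbon class
#' (n-alkane, alkene, monomethyl, dimethyl). Component classes are derived
#' by parsing the component labels. Accepts either a `"chc_profile"` (the
#' group mean is computed from individuals) or a taxa x components mean
#' matrix such as [population_mean_matrix()] (printed means are used
#' as-is, so classes sum to 100 only up to their rounding).
#'
#' @param x a `"chc_profile"` or a numeric matrix with taxa in rows.
#' @param group group label (matched against `population` metadata or
#'   rownames). Omit for single-group input.
#' @return Named numeric vector of class percentages.
#' @export
#' @examples
#' class_composition(population_mean_matrix(), "ARIM")
class_composition <- function(x, group = NULL) {
  if (inherits(x, "chc_profile")) {
    g <- x$population
    if (is.null(group)) {
      if (length(unique(g)) != 1L) stop("specify 'group'", call. = FALSE)
      group <- unique(g)
    }
    if (!group %in% g) stop(sprintf("unknown group '%s'", group), call. = FALSE)
    means <- colMeans(x$percent[g == group, , drop = FALSE])
  } else {
    x <- as.matrix(x)
    if (is.null(group)) {
      if (nrow(x) != 1L) stop("specify 'group'", call. = FALSE)
      means <- x[1, ]
    } else {
      if (!group %in% rownames(x))
        stop(sprintf("unknown group '%s'", group), call. = FALSE)
      means <- x[group, ]
    }
  }
  cls <- vapply(lapply(names(means), parse_component_name),
                `[[`, "", "chc_class")
  lev <- c("n_alkane", "alkene", "monomethyl", "dimethyl")
  out <- tapply(means, factor(cls, lev), sum, default = 0)
  setNames(round(as.vector(out), 10), lev)
}

#' Two-sample sex contrast for one component
#'
#' Student's two-sample t test (equal variances by default, mirroring
#' routine CHC practice; set `var_equal = FALSE` for Welch) on the
#' per-individual relative percentages of one component.
#'
#' @param profile a `"chc_profile"` with both sexes present (n >= 2 each).
#' @param component component label.
#' @param var_equal pool variances (classic Student) or not (Welch).
#' @return List with `statistic`, `p_value`, `direction`
#'   (`"male"`/`"female"`/`"none"`, the sex with the larger mean),
#'   `significant_05`, `significant_01`, and the underlying `htest`.
#' @export
sex_contrast <- function(profile, component, var_equal = TRUE) {
  stopifnot(inherits(profile, "chc_profile"))
  if (!component %in% colnames(profile$percent))
    stop(sprintf("unknown component '%s'", component), call. = FALSE)
  v <- profile$percent[, component]
  m <- v[profile$sex == "male"]; f <- v[profile$sex == "female"]
  if (length(m) < 2L || length(f) < 2L)
    stop("need at least two individuals of each sex", call. = FALSE)
  ht <- t.test(m, f, var.equal = var_equal)
  dm <- mean(m) - mean(f)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       direction = if (dm > 0) "male" else if (dm < 0) "female" else "none",
       significant_05 = ht$p.value < 0.05,
       significant_01 = ht$p.value < 0.01,
       test = ht)
}

#' Multi-group contrast: one-way ANOVA with SNK letters
#'
#' One-way ANOVA on one component's percentages across groups, followed by
#' the Student-Newman-Keuls stepwise range procedure on the ordered group
#' means at alpha = 0.05. Groups sharing a letter are not separated.
#' Unequal group sizes are handled with the Tukey-Kramer standard error
#' for each pair. Letters are invariant under group relabeling (the
#' procedure works on means ordered by value).
#'
#' @param profile a `"chc_profile"` (>= 2 groups, each n >= 2).
#' @param component component label.
#' @param by grouping metadata (see [group_summary()]).
#' @param alpha significance level of the range tests (fixed at 0.05 in
#'   routine use).
#' @return List with `f_value`, `p_value`, `df`, `letters` (named by
#'   group), `means` (named, sorted decreasing).
#' @export
population_contrast <- function(profile, component, by = "population",
                                alpha = 0.05) {
  stopifnot(inherits(profile, "chc_profile"))
  if (!component %in% colnames(profile$percent))
    stop(sprintf("unknown component '%s'", component), call. = FALSE)
  g <- factor(resolve_groups(profile, by))
  if (nlevels(g) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(table(g) < 2L)) stop("every group needs n >= 2", call. = FALSE)
  v <- profile$percent[, component]
  fit <- aov(v ~ g)
  an <- anova(fit)
  mse <- an[["Mean Sq"]][2]
  dfe <- an[["Df"]][2]
  means <- tapply(v, g, mean)
  ns <- tapply(v, g, length)
  if (mse <= 0 || !is.finite(mse)) {
    if (max(means) - min(means) < 1e-12) {
      letters <- setNames(rep("a", nlevels(g)), levels(g))
      return(list(f_value = NA_real_, p_value = NA_real_,
                  df = c(an[["Df"]][1], dfe), letters = letters,
                  means = sort(means, decreasing = TRUE)))
    }
    stop("degenerate within-group variance: range tests are undefined",
         call. = FALSE)
  }
  letters <- snk_letters(means, ns, mse, dfe, alpha)
  list(f_value = an[["F value"]][1], p_value = an[["Pr(>F)"]][1],
       df = c(an[["Df"]][1], dfe),
       letters = letters[levels(g)],
       means = sort(means, decreasing = TRUE))
}

## SNK stepwise range procedure with containment: a non-significant range
## closes every sub-range inside it.
snk_letters <- function(means, ns, mse, dfe, alpha = 0.05) {
  o <- order(means, decreasing = TRUE)
  m <- means[o]; n <- ns[o]; k <- length(m)
  homog <- diag(TRUE, k)
  test_range <- function(i, j) {
    if (j <= i) return(invisible())
    p <- j - i + 1L
    se <- sqrt(mse / 2 * (1 / n[i] + 1 / n[j]))
    qobs <- (m[i] - m[j]) / se
    if (qobs < qtukey(1 - alpha, p, dfe)) {
      homog[i:j, i:j] <<- TRUE
    } else {
      test_range(i + 1L, j)
      test_range(i, j - 1L)
    }
  }
  test_range(1L, k)
  ## maximal homogeneous stretches (interval structure holds on sorted means)
  reach <- vapply(seq_len(k), function(i) max(which(homog[i, ])), integer(1))
  intervals <- list()
  for (i in seq_len(k)) {
    iv <- c(i, reach[i])
    if (!length(intervals) || intervals[[length(intervals)]][2] < iv[2])
      intervals[[length(intervals) + 1L]] <- iv
  }
  lab <- rep("", k)
  for (t in seq_along(intervals)) {
    iv <- intervals[[t]]
    lab[iv[1]:iv[2]] <- paste0(lab[iv[1]:iv[2]], letters[t])
  }
  setNames(lab, names(m))[names(means)]
}
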