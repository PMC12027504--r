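#' Bray-Curtis dissimilarity matrix
#'
#' `d(a, b) = sum |a_i - b_i| / sum (a_i + b_i)` over components, computed
#' with [vegan::vegdist()]. Applied to relative percentages for
#' individual-level analyses and to ordinal codes for taxon-level trees.
#'
#' @param x a `"chc_profile"` (its percentage matrix is used) or a
#'   non-negative numeric matrix with items in rows.
#' @return A `dist` object with item labels; entries in `[0, 1]`.
#' @export
bray_curtis <- function(x) {
  m <- if (inherits(x, "chc_profile")) x$percent else as.matrix(x)
  if (any(m < 0)) stop("entries must be non-negative", call. = FALSE)
  rs <- rowSums(m)
  if (any(rs <= 0))
    stop("zero-sum rows: ", paste(head(rownames(m)[rs <= 0]), collapse = ", "),
         call. = FALSE)
  vegan::vegdist(m, method = "bray")
}

#' Non-metric multidimensional scaling (NMDS)
#'
#' Kruskal-style NMDS of a dissimilarity matrix via [vegan::monoMDS()]
#' (global model, stress-1 in `[0, 1]`), taking the best of `restarts`
#' random starts plus one metric-scaling start. Fully deterministic given
#' `seed`.
#'
#' @param d a `dist` object.
#' @param k embedding dimension (default 2).
#' @param restarts number of random starts (default 20).
#' @param seed integer seed recorded in the result.
#' @return List of class `"chc_nmds"`: `points` (n x k), `stress`
#'   (Kruskal stress-1), `k`, `restarts`, `seed`, `converged`.
#' @export
nmds_ordination <- function(d, k = 2, restarts = 20, seed = 1) {
  stopifnot(inherits(d, "dist"), k >= 1)
  n <- attr(d, "Size")
  best <- NULL
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  inits <- c(list(cmdscale(d, k = k, add = TRUE)$points),
             replicate(restarts,
                       matrix(rnorm(n * k), n, k), simplify = FALSE))
  for (y0 in inits) {
    fit <- vegan::monoMDS(d, y = y0, k = k, model = "global")
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  pts <- best$points
  rownames(pts) <- attr(d, "Labels")
  structure(list(points = pts, stress = best$stress, k = k,
                 restarts = restarts, seed = seed,
                 converged = best$iters < best$maxits || best$stress < 1e-6),
            class = "chc_nmds")
}

#' @export
print.chc_nmds <- function(x, ...) {
  cat(sprintf("<chc_nmds> k = %d, stress-1 = %.4f (%d restarts, seed %d)%s\n",
              x$k, x$stress, x$restarts, x$seed,
              if (!x$converged) " [not converged]" else ""))
  invisible(x)
}

#' One-way PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance in Anderson's
#' formulation, computed directly from the distance matrix: with squared
#' dissimilarities, `SS_total = sum_{i<j} d_ij^2 / n` and
#' `SS_within = sum_g sum_{i<j in g} d_ij^2 / n_g` (equivalently, traces
#' of the Gower-centered matrix projected on the design), giving
#' `pseudo-F = (SS_among / (a-1)) / (SS_within / (n-a))` and
#' `R^2 = SS_among / SS_total`. The p value permutes raw group labels
#' freely (one-way design), `p = (b + 1) / (n_permutations + 1)` where b
#' counts permuted F >= observed. Bit-reproducible given `seed`.
#'
#' @param d a `dist` object.
#' @param groups group label per item (>= 2 groups, each n >= 2).
#' @param n_permutations number of label permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @return List of class `"chc_permanova"`: `f_value`, `r_squared`,
#'   `p_value`, `df`, `n_permutations`, `seed`.
#' @export
permanova <- function(d, groups, n_permutations = 999, seed = 1) {
  stopifnot(inherits(d, "dist"))
  n <- attr(d, "Size")
  g <- factor(groups)
  if (length(g) != n) stop("one group label per item", call. = FALSE)
  a <- nlevels(g)
  if (a < 2L) stop("need at least two groups", call. = FALSE)
  if (any(table(g) < 2L)) stop("every group needs n >= 2", call. = FALSE)
  D2 <- as.matrix(d)^2
  ss_total <- sum(D2) / (2 * n)
  ss_within <- function(gi) {
    G <- model_matrix_groups(gi)
    sum(diag(crossprod(G, D2 %*% G)) / (2 * colSums(G)))
  }
  f_of_ssw <- function(ssw) ((ss_total - ssw) / (a - 1)) / (ssw / (n - a))
  ssw_obs <- ss_within(g)
  f_obs <- f_of_ssw(ssw_obs)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  f_perm <- vapply(seq_len(n_permutations),
                   function(i) f_of_ssw(ss_within(g[sample.int(n)])),
                   numeric(1))
  p <- (sum(f_perm >= f_obs) + 1) / (n_permutations + 1)
  structure(list(f_value = f_obs,
                 r_squared = 1 - ssw_obs / ss_total,
                 p_value = p, df = c(a - 1L, n - a),
                 n_permutations = n_permutations, seed = seed),
            class = "chc_permanova")
}

model_matrix_groups <- function(g) {
  G <- matrix(0, length(g), nlevels(g))
  G[cbind(seq_along(g), as.integer(g))] <- 1
  G
}

#' @export
print.chc_permanova <- function(x, ...) {
  cat(sprintf("<chc_permanova> pseudo-F(%d, %d) = %.3f, R2 = %.3f, p = %.4g (%d permutations, seed %d)\n",
              x$df[1], x$df[2], x$f_value, x$r_squared, x$p_value,
              x$n_permutations, x$seed))
  invisible(x)
}

## Save/restore the global RNG state so seeded helpers do not disturb the
## caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}
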