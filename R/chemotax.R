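#' Ordinal coding of mean relative percentages
#'
#' Maps mean percentages to the chemotaxonomic character states
#' {0, 1, 2, 3, 4}: 0 = not detected; then, by relative quantity,
#' `(0, 0.5) -> 1`, `[0.5, 1) -> 2`, `[1, 5] -> 3`, `(5, Inf) -> 4`.
#' The boundary convention (0.5 and 1 open below, 5 closed above in bin 3)
#' keeps every printed mean unambiguous under its displayed rounding; pass
#' custom `bounds` to change it. `NA` is treated as not detected.
#'
#' @param p numeric vector of mean percentages (>= 0).
#' @param bounds numeric length-3 vector of bin edges, default
#'   `c(0.5, 1, 5)`.
#' @return Integer vector of codes in 0..4.
#' @export
#' @examples
#' code_profile(c(0, 0.02, 0.7, 3, 39.4)) # 0 1 2 3 4
code_profile <- function(p, bounds = c(0.5, 1, 5)) {
  p <- as.numeric(p)
  p[is.na(p)] <- 0
  if (any(p < 0)) stop("percentages must be >= 0", call. = FALSE)
  stopifnot(length(bounds) == 3L, !is.unsorted(bounds, strictly = TRUE))
  ifelse(p == 0, 0L,
  ifelse(p < bounds[1], 1L,
  ifelse(p < bounds[2], 2L,
  ifelse(p <= bounds[3], 3L, 4L))))
}

#' Taxa x components coded character matrix
#'
#' Builds the chemotaxonomic data matrix: one row per taxon (species or
#' population), one column per catalog component, entries the ordinal
#' codes of [code_profile()]. Components a taxon lacks are coded 0.
#'
#' @param summaries either a long data.frame with columns
#'   `population` (or `group`/`taxon`), `label` (or `component`) and
#'   `mean` -- e.g. [population_means()] or [group_summary()] output -- or
#'   a numeric taxa x components mean matrix.
#' @param catalog optional catalog ([chc_catalog()]); when given, columns
#'   are laid out in catalog order and unknown components are an error.
#' @param bounds passed to [code_profile()].
#' @return Integer matrix of codes with taxa rownames. Coding is
#'   idempotent on already-coded 0-4 matrices in the sense that
#'   recoding the codes maps 0->0 and positive codes into bin 3 of their
#'   magnitude; use the mean matrix as input, not the codes.
#' @export
#' @examples
#' coded_matrix(population_means(), chc_catalog())
coded_matrix <- function(summaries, catalog = NULL, bounds = c(0.5, 1, 5)) {
  if (is.matrix(summaries) || is.data.frame(summaries) &&
      all(vapply(summaries, is.numeric, logical(1))) &&
      !is.null(rownames(summaries)) && !"mean" %in% names(summaries)) {
    m <- as.matrix(summaries)
  } else {
    df <- as.data.frame(summaries)
    tax_col <- intersect(c("population", "group", "taxon"), names(df))[1]
    lab_col <- intersect(c("label", "component"), names(df))[1]
    if (is.na(tax_col) || is.na(lab_col) || !"mean" %in% names(df))
      stop("need taxon, component and 'mean' columns", call. = FALSE)
    taxa <- unique(df[[tax_col]])
    labs <- unique(df[[lab_col]])
    m <- matrix(0, length(taxa), length(labs), dimnames = list(taxa, labs))
    m[cbind(match(df[[tax_col]], taxa), match(df[[lab_col]], labs))] <-
      ifelse(is.na(df$mean), 0, df$mean)
  }
  if (!is.null(catalog)) {
    extra <- setdiff(colnames(m), catalog$label)
    if (length(extra))
      stop("components not in the catalog: ", paste(extra, collapse = ", "),
           call. = FALSE)
    full <- matrix(0, nrow(m), nrow(catalog),
                   dimnames = list(rownames(m), catalog$label))
    full[, colnames(m)] <- m
    m <- full
  }
  coded <- apply(m, c(1, 2), code_profile, bounds = bounds)
  storage.mode(coded) <- "integer"
  zero_rows <- rownames(coded)[rowSums(coded) == 0]
  if (length(zero_rows))
    warning("all components coded absent for: ",
            paste(zero_rows, collapse = ", "), call. = FALSE)
  coded
}

#' UPGMA clustering
#'
#' Classic unweighted pair-group average-linkage agglomeration: repeatedly
#' merge the closest pair of clusters; the distance from the merged
#' cluster to any other is the size-weighted mean of its members'
#' distances, and the new node sits at half the merge distance, so the
#' result is ultrametric by construction. When several pairs tie at the
#' minimum distance the lexicographically smallest label pair merges
#' first, making the tree deterministic.
#'
#' @param d a `dist` object with item labels (n >= 2).
#' @return An object of class `c("chc_dendrogram", "hclust")`: standard
#'   `hclust` fields (`merge`, `height` = merge distances, `order`,
#'   `labels`) so that [stats::cutree()], plotting and
#'   [ape::as.phylo()] (which halves the heights into ultrametric branch
#'   lengths) all apply.
#' @seealso [write_newick()], [compare_trees()]
#' @export
#' @examples
#' d <- as.dist(matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3,
#'                     dimnames = list(LETTERS[1:3], LETTERS[1:3])))
#' upgma(d)$height # 2 then 8 (nodes at 1 and 4)
upgma <- function(d) {
  stopifnot(inherits(d, "dist"))
  n <- attr(d, "Size")
  if (n < 2L) stop("need at least two items", call. = FALSE)
  labels <- attr(d, "Labels")
  if (is.null(labels)) labels <- as.character(seq_len(n))
  D <- as.matrix(d)
  dimnames(D) <- NULL
  active <- seq_len(n)
  id <- -seq_len(n)             # hclust convention: negatives = singletons
  size <- rep(1L, n)
  ## lexicographic tie-break key: sorted pair of smallest member labels
  minlab <- labels
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (s in seq_len(n - 1L)) {
    best <- NULL
    for (ii in seq_along(active)[-length(active)]) {
      for (jj in (ii + 1L):length(active)) {
        i <- active[ii]; j <- active[jj]
        key <- sort(c(minlab[i], minlab[j]))
        cand <- list(dist = D[i, j], i = i, j = j, key = key)
        if (is.null(best) || cand$dist < best$dist ||
            (cand$dist == best$dist &&
             (cand$key[1] < best$key[1] ||
              (cand$key[1] == best$key[1] && cand$key[2] < best$key[2]))))
          best <- cand
      }
    }
    i <- best$i; j <- best$j
    height[s] <- best$dist
    merge[s, ] <- sort(c(id[i], id[j]))
    ## size-weighted (arithmetic-mean over original members) update into i
    for (k in active) if (k != i && k != j)
      D[i, k] <- D[k, i] <-
        (size[i] * D[i, k] + size[j] * D[j, k]) / (size[i] + size[j])
    size[i] <- size[i] + size[j]
    minlab[i] <- min(minlab[i], minlab[j])
    id[i] <- s
    active <- setdiff(active, j)
  }
  out <- structure(list(merge = merge, height = height,
                        order = hclust_order(merge),
                        labels = labels, method = "upgma",
                        call = match.call(),
                        dist.method = attr(d, "method")),
                   class = c("chc_dendrogram", "hclust"))
  out
}

## leaf order by left-to-right traversal of the merge tree
hclust_order <- function(merge) {
  walk <- function(node) {
    if (node < 0L) return(-node)
    c(walk(merge[node, 1L]), walk(merge[node, 2L]))
  }
  walk(nrow(merge))
}

#' @export
print.chc_dendrogram <- function(x, ...) {
  cat(sprintf("<chc_dendrogram> UPGMA over %d items; root height %.4g (ultrametric depth %.4g)\n",
              length(x$labels), max(x$height), max(x$height) / 2))
  invisible(x)
}

#' Canonical newick serialization
#'
#' Writes a tree to newick with deterministic child ordering (children
#' sorted by their smallest descendant label) and `%.12g`-formatted branch
#' lengths, so `write -> read -> write` round-trips byte-identically.
#' Dendrograms serialize their ultrametric form: leaves at depth 0, each
#' internal node at half its merge distance.
#'
#' @param tree a `chc_dendrogram`, an [ape::phylo] tree, or an `hclust`.
#' @param file optional path; when given the string is also written there.
#' @param digits significant digits for branch lengths (default 12).
#' @return The newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL, digits = 12) {
  phy <- as_phylo_tree(tree)
  ntip <- length(phy$tip.label)
  children <- split(phy$edge[, 2], phy$edge[, 1])
  elen <- if (is.null(phy$edge.length)) NULL else
    setNames(phy$edge.length, phy$edge[, 2])
  fmt <- function(x) sprintf(paste0("%.", digits, "g"), x)
  minlab <- character(ntip + phy$Nnode)
  fill_minlab <- function(node) {
    if (node <= ntip) return(minlab[node] <<- phy$tip.label[node])
    kids <- children[[as.character(node)]]
    for (k in kids) fill_minlab(k)
    minlab[node] <<- min(minlab[kids])
  }
  root <- ntip + 1L
  fill_minlab(root)
  ser <- function(node) {
    if (node <= ntip) return(phy$tip.label[node])
    kids <- children[[as.character(node)]]
    kids <- kids[order(minlab[kids])]
    inner <- paste(vapply(kids, function(k) {
      paste0(ser(k), if (!is.null(elen)) paste0(":", fmt(elen[[as.character(k)]])))
    }, character(1)), collapse = ",")
    paste0("(", inner, ")")
  }
  s <- paste0(ser(root), ";")
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

as_phylo_tree <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (inherits(tree, "hclust")) return(ape::as.phylo(tree))
  if (is.character(tree) && length(tree) == 1L) {
    if (file.exists(tree)) return(ape::read.tree(tree))
    return(ape::read.tree(text = tree))
  }
  stop("cannot interpret 'tree' as a phylogeny", call. = FALSE)
}

#' Robinson-Foulds comparison of two trees
#'
#' Counts the bipartitions (non-trivial splits of the shared leaf set,
#' read off the trees as unrooted) present in exactly one of the two
#' trees. Also reports the normalized distance
#' `RF / (splits(t1) + splits(t2))` in `[0, 1]` (0 = identical topology).
#' Branch lengths are ignored.
#'
#' @param t1,t2 trees: `chc_dendrogram`, `phylo`, newick string or file.
#' @return List with `rf`, `normalized`, `n_splits` (per tree),
#'   `shared_splits`.
#' @export
#' @examples
#' compare_trees("((A,B),(C,D));", "((A,C),(B,D));")$rf # 2
compare_trees <- function(t1, t2) {
  p1 <- as_phylo_tree(t1); p2 <- as_phylo_tree(t2)
  l1 <- sort(p1$tip.label); l2 <- sort(p2$tip.label)
  if (!identical(l1, l2))
    stop("leaf sets differ; only in tree 1: {",
         paste(setdiff(l1, l2), collapse = ", "), "}; only in tree 2: {",
         paste(setdiff(l2, l1), collapse = ", "), "}", call. = FALSE)
  b1 <- tree_bipartitions(p1)
  b2 <- tree_bipartitions(p2)
  shared <- sum(b1 %in% b2)
  rf <- (length(b1) - shared) + (length(b2) - shared)
  denom <- length(b1) + length(b2)
  list(rf = rf, normalized = if (denom > 0) rf / denom else 0,
       n_splits = c(length(b1), length(b2)), shared_splits = shared)
}

## Non-trivial splits as canonical strings: the side NOT containing the
## alphabetically first leaf, members sorted and joined.
tree_bipartitions <- function(phy) {
  ntip <- length(phy$tip.label)
  if (ntip < 4L) return(character(0))
  children <- split(phy$edge[, 2], phy$edge[, 1])
  ref <- sort(phy$tip.label)[1]
  tips_below <- vector("list", ntip + phy$Nnode)
  fill <- function(node) {
    if (node <= ntip) return(tips_below[[node]] <<- phy$tip.label[node])
    kids <- children[[as.character(node)]]
    for (k in kids) fill(k)
    tips_below[[node]] <<- unlist(tips_below[kids], use.names = FALSE)
  }
  root <- ntip + 1L
  fill(root)
  splits <- character(0)
  for (node in setdiff(seq_len(ntip + phy$Nnode), c(seq_len(ntip), root))) {
    side <- tips_below[[node]]
    if (ref %in% side) side <- setdiff(phy$tip.label, side)
    if (length(side) >= 2L && length(side) <= ntip - 2L)
      splits <- c(splits, paste(sort(side), collapse = "|"))
  }
  unique(splits)
}
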