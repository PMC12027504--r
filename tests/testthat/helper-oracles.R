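## Independent oracles used across tests. Each one recomputes a quantity by
## brute force from first principles (explicit atoms, double loops, quartet
## tests) and stays independent of the package code paths it checks.

## Explicit-skeleton fragment oracle: build the carbon graph of an alkane
## (chain plus branch methyl carbons), enumerate every C-C bond cleavage and
## sum atomic nominal masses (C = 12, H = 1). Hydrogens are counted per
## carbon as 4 minus its bond degree. Each homolytic fragment gives the
## radical mass (14m + 1 for an acyclic saturated fragment) and its
## H-rearrangement companion one mass unit below.
oracle_skeleton <- function(chain, methyls = integer()) {
  nodes <- seq_len(chain + length(methyls))
  edges <- cbind(seq_len(chain - 1L), 2:chain)
  for (i in seq_along(methyls))
    edges <- rbind(edges, c(methyls[i], chain + i))
  list(nodes = nodes, edges = edges)
}

oracle_cleavage_masses <- function(chain, methyls = integer(),
                                   bonds = NULL) {
  sk <- oracle_skeleton(chain, methyls)
  deg <- tabulate(c(sk$edges), nbins = length(sk$nodes))
  h_per_c <- 4L - deg
  reachable <- function(start, blocked_edge) {
    seen <- start
    repeat {
      grow <- unique(c(
        sk$edges[sk$edges[, 1] %in% seen &
                 !(sk$edges[, 1] == blocked_edge[1] &
                   sk$edges[, 2] == blocked_edge[2]), 2],
        sk$edges[sk$edges[, 2] %in% seen &
                 !(sk$edges[, 1] == blocked_edge[1] &
                   sk$edges[, 2] == blocked_edge[2]), 1]))
      grow <- setdiff(grow, seen)
      if (!length(grow)) return(seen)
      seen <- c(seen, grow)
    }
  }
  if (is.null(bonds)) bonds <- seq_len(nrow(sk$edges))
  out <- integer(0)
  for (b in bonds) {
    e <- sk$edges[b, ]
    for (side in e) {
      frag <- reachable(side, e)
      # radical keeps the hydrogens it had in the intact molecule
      mass <- 12L * length(frag) + sum(h_per_c[frag])
      out <- c(out, mass, mass - 1L)
    }
  }
  sort(unique(out))
}

## Chain-bond indices flanking the branch carbons (bond i joins carbons
## i and i+1): used to restrict the oracle to the cleavages the
## closed-form rule predicts.
oracle_flanking_bonds <- function(methyls) {
  sort(unique(c(methyls - 1L, methyls)))
}

## DMDS adduct oracle: monoene with SCH3 on carbons d and d+1; cleave the
## derivatized C-C bond and sum atomic masses (C = 12, H = 1, S = 32).
oracle_dmds <- function(chain, d) {
  h_chain <- function(carbons, substituted) {
    # interior carbons bear 2 H, termini 3, minus 1 per substituent
    h <- ifelse(carbons %in% c(1L, chain), 3L, 2L)
    h - as.integer(carbons %in% substituted)
  }
  scme <- 32L + 12L + 3L                      # S + CH3
  low_c <- seq_len(d)
  high_c <- (d + 1L):chain
  low <- 12L * d + sum(h_chain(low_c, c(d, d + 1L))) + scme
  high <- 12L * (chain - d) + sum(h_chain(high_c, c(d, d + 1L))) + scme
  list(fragment_low = low, fragment_high = high, adduct_ion = low + high)
}

## Naive double-loop Bray-Curtis.
oracle_bray <- function(m) {
  n <- nrow(m)
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n))
    out[i, j] <- sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ])
  as.dist(out)
}

## Brute-force bipartition oracle: a canonical leaf subset is a split of a
## tree iff every quartet (a, b | c, d) with a,b inside and c,d outside
## resolves that way under the four-point condition on unit-branch-length
## path distances.
oracle_splits <- function(phy) {
  tips <- sort(phy$tip.label)
  n <- length(tips)
  if (n < 4L) return(character(0))
  phy$edge.length <- rep(1, nrow(phy$edge))
  dm <- ape::cophenetic.phylo(phy)[tips, tips]
  ref <- tips[1]
  subsets <- list()
  idx <- setdiff(seq_len(n), 1L)   # canonical side excludes the ref leaf
  for (size in 2:(n - 2L)) {
    for (comb in utils::combn(idx, size, simplify = FALSE)) {
      s <- tips[comb]
      rest <- setdiff(tips, s)
      ok <- TRUE
      for (ab in utils::combn(s, 2, simplify = FALSE)) {
        for (cd in utils::combn(rest, 2, simplify = FALSE)) {
          same <- dm[ab[1], ab[2]] + dm[cd[1], cd[2]]
          x1 <- dm[ab[1], cd[1]] + dm[ab[2], cd[2]]
          x2 <- dm[ab[1], cd[2]] + dm[ab[2], cd[1]]
          if (!(same < x1 && same < x2)) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (ok) subsets[[length(subsets) + 1L]] <- paste(sort(s), collapse = "|")
    }
  }
  unique(unlist(subsets))
}

oracle_rf <- function(t1, t2) {
  s1 <- oracle_splits(t1); s2 <- oracle_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

## Random leaf-labelled topology with fixed labels.
random_labelled_tree <- function(n) {
  tr <- ape::rtree(n, tip.label = LETTERS[seq_len(n)])
  tr$edge.length <- NULL
  tr
}
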