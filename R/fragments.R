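## Nominal-mass EI and DMDS-adduct fragment arithmetic.
## All masses are nominal integers (CH2 = 14, H = 1, SCH3 = 47); this matches
## every printed diagnostic m/z in routine CHC work, where isotopes and mass
## defects are ignored.

#' Low-mass EI signature of monoenes
#'
#' The homologous CnH2n-1 series (83, 97, 111) printed for alkene peaks.
#' These ions are class evidence only -- they carry no information about the
#' double-bond position -- so they are matched as a fixed signature rather
#' than predicted per compound.
#' @export
ALKENE_SIGNATURE_IONS <- c(83L, 97L, 111L)

#' Nominal molecular ion
#'
#' `14 * total_carbons + 2` for saturated compounds, `14 * total_carbons`
#' for monoenes.
#'
#' @param x a [chc_compound] (saturated or monoene) with all branch
#'   positions known.
#' @return Integer m/z.
#' @export
#' @examples
#' molecular_ion(parse_component_name("n-C25"))   # 352
#' molecular_ion(parse_component_name("9-C27:1")) # 378
molecular_ion <- function(x) {
  stopifnot(inherits(x, "chc_compound"))
  if (anyNA(x$methyl_positions))
    stop(sprintf("'%s' has an unknown branch position; mass rules need %s",
                 x$label, "fully specified structures"), call. = FALSE)
  tc <- total_carbons(x)
  if (x$chc_class == "alkene") 14L * tc else 14L * tc + 2L
}

#' Diagnostic EI ions of methyl-branched alkanes
#'
#' Electron impact preferentially cleaves the C-C bonds flanking a methyl
#' branch (secondary carbenium sites). For each such bond both charged
#' fragments are emitted, in even (`14 m`) and odd (`14 m + 1`) mass
#' variants, where `m` counts the carbons in the fragment including any
#' branch methyls it retains; published tables mix the two variants.
#' Methyl loss (M-15) is always emitted, and ethyl loss (M-29) additionally
#' for 3-methyl compounds.
#'
#' @param x a [chc_compound] of class monomethyl or dimethyl with all
#'   branch positions known.
#' @return An object of class `"ion_set"`: list with `compound`,
#'   sorted integer `mz`, and `molecular_ion` (always a member of `mz`).
#' @export
#' @examples
#' diagnostic_ions(parse_component_name("7-meC27"))$mz # contains 112, 309
diagnostic_ions <- function(x) {
  stopifnot(inherits(x, "chc_compound"))
  if (!x$chc_class %in% c("monomethyl", "dimethyl"))
    stop("diagnostic branch ions are defined for methyl-branched alkanes",
         call. = FALSE)
  if (anyNA(x$methyl_positions))
    stop(sprintf("'%s' has an unknown branch position ('X'); %s", x$label,
                 "fragment prediction requires known positions"),
         call. = FALSE)
  n <- x$chain_length
  me <- sort(x$methyl_positions)
  m_counts <- integer(0)
  for (xx in me) {
    # cleave bond (x-1, x): fragment C1..C(x-1) / fragment Cx..Cn (+ methyls)
    m_counts <- c(m_counts,
                  (xx - 1L) + sum(me < xx),
                  (n - xx + 1L) + 1L + sum(me > xx),
                  # cleave bond (x, x+1)
                  xx + 1L + sum(me < xx),
                  (n - xx) + sum(me > xx))
  }
  m_counts <- m_counts[m_counts > 0L]
  mion <- molecular_ion(x)
  mz <- c(14L * m_counts, 14L * m_counts + 1L, mion, mion - 15L,
          if (3L %in% me) mion - 29L)
  structure(list(compound = x, mz = sort(unique(mz)), molecular_ion = mion),
            class = "ion_set")
}

#' @export
print.ion_set <- function(x, ...) {
  cat(sprintf("<ion_set> %s: M+ = %d; predicted m/z: %s\n",
              x$compound$label, x$molecular_ion,
              paste(x$mz, collapse = ", ")))
  invisible(x)
}

#' Predicted ion set for any catalog compound
#'
#' Branched alkanes get their branch-cleavage ions via
#' [diagnostic_ions()]; n-alkanes are predicted by their molecular ion
#' alone; monoenes by the molecular ion plus the fixed low-mass alkene
#' signature ([ALKENE_SIGNATURE_IONS]).
#'
#' @inheritParams molecular_ion
#' @return An `"ion_set"`.
#' @export
predict_ions <- function(x) {
  stopifnot(inherits(x, "chc_compound"))
  if (x$chc_class %in% c("monomethyl", "dimethyl")) return(diagnostic_ions(x))
  mion <- molecular_ion(x)
  mz <- if (x$chc_class == "alkene") c(ALKENE_SIGNATURE_IONS, mion) else mion
  structure(list(compound = x, mz = sort(unique(mz)), molecular_ion = mion),
            class = "ion_set")
}

#' DMDS adduct and cleavage fragments of a monoene
#'
#' Dimethyl disulfide derivatization adds two thiomethyl (SCH3, nominal 47)
#' groups across the double bond (+94 over the monoene molecular ion).
#' EI cleavage between the two derivatized carbons yields a complementary
#' fragment pair: the fragment holding carbons 1..d plus one thiomethyl
#' (`14 d + 47`) and its complement. Their masses pinpoint the original
#' double-bond position d.
#'
#' @param chain integer main-chain length.
#' @param d integer double-bond position, `2 <= d <= chain - 2`.
#' @return List of class `"dmds_adduct"` with integer `adduct_ion`,
#'   `fragment_low`, `fragment_high` (low + high = adduct).
#' @export
#' @examples
#' dmds_fragments(25, 7) # adduct 444, fragments 145 / 299
dmds_fragments <- function(chain, d) {
  chain <- as.integer(chain); d <- as.integer(d)
  stopifnot(length(chain) == 1L, length(d) == 1L)
  if (is.na(d) || d < 2L || d > chain - 2L)
    stop(sprintf("double-bond position d = %d out of range 2..%d for a C%d chain",
                 d, chain - 2L, chain), call. = FALSE)
  adduct <- 14L * chain + 94L
  low <- 14L * d + 47L
  structure(list(chain = chain, d = d, adduct_ion = adduct,
                 fragment_low = low, fragment_high = adduct - low),
            class = "dmds_adduct")
}

#' @export
print.dmds_adduct <- function(x, ...) {
  cat(sprintf("<dmds_adduct> C%d:1, db at %d: M+94 = %d, fragments %d / %d\n",
              x$chain, x$d, x$adduct_ion, x$fragment_low, x$fragment_high))
  invisible(x)
}

#' Locate a double bond from observed DMDS fragments
#'
#' Inverts [dmds_fragments()]: scans candidate positions d = 2 ..
#' floor(chain/2) (positions are named from the nearer terminus) and keeps
#' those whose predicted fragment pair is consistent with the observed m/z
#' set. Candidates matching both fragments outrank candidates matching one;
#' any remaining tie, or no match at all, is an ambiguity error that lists
#' the candidates.
#'
#' @param chain integer main-chain length of the monoene.
#' @param observed_fragments integer vector of observed m/z.
#' @return The inferred double-bond position (integer scalar).
#' @export
#' @examples
#' locate_double_bond(27, c(173, 299, 472)) # 9
locate_double_bond <- function(chain, observed_fragments) {
  chain <- as.integer(chain)
  obs <- as.integer(observed_fragments)
  if (length(obs) < 1L)
    stop("need at least one observed fragment", call. = FALSE)
  cand <- 2:(chain %/% 2L)
  score <- vapply(cand, function(d) {
    fr <- dmds_fragments(chain, d)
    sum(c(fr$fragment_low, fr$fragment_high) %in% obs)
  }, integer(1))
  best <- max(score)
  hits <- cand[score == best]
  if (best == 0L)
    stop(sprintf("no double-bond position in 2..%d is consistent with m/z {%s} on a C%d chain",
                 chain %/% 2L, paste(obs, collapse = ", "), chain),
         call. = FALSE)
  if (length(hits) > 1L)
    stop(sprintf("ambiguous double-bond position: candidates %s are equally consistent",
                 paste(hits, collapse = ", ")), call. = FALSE)
  hits
}

#' Annotate a peak against the component catalog
#'
#' Ranks catalog components as candidate identities for an observed peak:
#' keep components whose retention index lies within `ki_tolerance` of the
#' observed index, rank by the fraction of observed ions found in the
#' component's predicted ion set (subset matching, never exact-set), and
#' break ties by smaller index difference, then lower peak number. For
#' components whose branch positions are unknown the recorded catalog ions
#' stand in for a prediction.
#'
#' @param ki observed retention index.
#' @param observed_ions integer vector of observed m/z (may be empty).
#' @param catalog a catalog data.frame from [chc_catalog()].
#' @param ki_tolerance half-width of the retention-index window (default 5).
#' @return data.frame of candidates, best first, with columns
#'   `label, peak_no, ki, ki_diff, ion_match`; zero rows if nothing falls
#'   in the window.
#' @export
#' @examples
#' annotate_peak(2741, c(112, 309), chc_catalog())
annotate_peak <- function(ki, observed_ions, catalog, ki_tolerance = 5) {
  stopifnot(is.data.frame(catalog), nrow(catalog) > 0)
  obs <- as.integer(observed_ions)
  dki <- abs(catalog$ki - as.numeric(ki))
  keep <- which(dki <= ki_tolerance)
  if (!length(keep))
    return(data.frame(label = character(), peak_no = integer(),
                      ki = integer(), ki_diff = numeric(),
                      ion_match = numeric()))
  frac <- vapply(keep, function(i) {
    pred <- tryCatch(predict_ions(catalog$compound[[i]])$mz,
                     error = function(e) catalog$diagnostic_ions[[i]])
    if (!length(obs)) 0 else mean(obs %in% pred)
  }, numeric(1))
  out <- data.frame(label = catalog$label[keep],
                    peak_no = catalog$peak_no[keep],
                    ki = catalog$ki[keep],
                    ki_diff = dki[keep],
                    ion_match = frac,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$ion_match, out$ki_diff, out$peak_no), , drop = FALSE]
  rownames(out) <- NULL
  out
}
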