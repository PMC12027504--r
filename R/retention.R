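#' n-Alkane retention ladder
#'
#' A ladder maps n-alkane carbon numbers to their retention times under the
#' chromatographic program and anchors the retention-index scale (each
#' n-alkane CnH2n+2 defines index 100 n). Entries need not be consecutive
#' carbons: gaps (e.g. a C20/C25/C30/C35 standard mix) are interpolated
#' across with the spanning interval.
#'
#' @param carbon integer vector of carbon numbers.
#' @param rt_min numeric vector of retention times (minutes).
#' @return An `alkane_ladder` object (sorted, validated).
#' @export
#' @examples
#' alkane_ladder(c(25, 26, 27), c(34.29, 35.56, 36.8))
alkane_ladder <- function(carbon, rt_min) {
  carbon <- as.integer(carbon)
  rt_min <- as.numeric(rt_min)
  if (length(carbon) != length(rt_min))
    stop("'carbon' and 'rt_min' lengths differ", call. = FALSE)
  if (length(carbon) < 2L)
    stop("a ladder needs at least two n-alkanes", call. = FALSE)
  if (anyDuplicated(carbon))
    stop("duplicate carbon numbers in ladder", call. = FALSE)
  o <- order(carbon)
  carbon <- carbon[o]; rt_min <- rt_min[o]
  if (is.unsorted(rt_min, strictly = TRUE))
    stop("retention times must increase strictly with carbon number",
         call. = FALSE)
  structure(list(carbon = carbon, rt_min = rt_min), class = "alkane_ladder")
}

#' @export
print.alkane_ladder <- function(x, ...) {
  cat("<alkane_ladder> C", min(x$carbon), "..C", max(x$carbon), " (",
      length(x$carbon), " alkanes, ", min(x$rt_min), "-", max(x$rt_min),
      " min)\n", sep = "")
  invisible(x)
}

#' Build a ladder from the n-alkane rows of a peak table
#'
#' Extracts rows whose component parses as an n-alkane and uses their
#' retention times as ladder anchors. Row order is irrelevant.
#'
#' @param x a data.frame with `label` (or `component`) and `rt_min`
#'   columns -- a catalog, a peak table, or any table containing identified
#'   n-alkanes.
#' @return An [alkane_ladder].
#' @export
#' @examples
#' build_ladder(chc_catalog())
build_ladder <- function(x) {
  lab_col <- intersect(c("label", "component"), names(x))[1]
  if (is.na(lab_col) || !"rt_min" %in% names(x))
    stop("need columns 'label' (or 'component') and 'rt_min'", call. = FALSE)
  cmp <- lapply(x[[lab_col]], parse_component_name)
  is_alk <- vapply(cmp, function(c) c$chc_class == "n_alkane", logical(1))
  if (sum(is_alk) < 2L)
    stop("fewer than two identified n-alkanes; cannot anchor a ladder",
         call. = FALSE)
  carbons <- vapply(cmp[is_alk], `[[`, integer(1), "chain_length")
  rts <- tapply(x$rt_min[is_alk], carbons, mean)
  alkane_ladder(as.integer(names(rts)), as.numeric(rts))
}

#' Temperature-programmed (linear) retention index
#'
#' Computes the retention index of a peak by linear interpolation between
#' the bracketing ladder alkanes (van den Dool-Kratz convention for
#' temperature-programmed runs): with bracketing carbons n and n+k,
#' `KI = 100 n + 100 k (t - t_n) / (t_{n+k} - t_n)`, rounded half-up to an
#' integer. Times outside the ladder range raise an error unless
#' `extrapolate = TRUE`, in which case the terminal ladder interval's slope
#' is extended (useful when late-eluting peaks outrun the heaviest bundled
#' alkane standard).
#'
#' @param t numeric vector of retention times (minutes).
#' @param ladder an [alkane_ladder].
#' @param extrapolate extend the first/last ladder interval beyond the
#'   ladder range instead of erroring. Default `FALSE`.
#' @return Integer vector of retention indices.
#' @export
#' @examples
#' lad <- build_ladder(chc_catalog())
#' retention_index(35.21, lad) # 2572
retention_index <- function(t, ladder, extrapolate = FALSE) {
  stopifnot(inherits(ladder, "alkane_ladder"))
  tc <- ladder$carbon; tt <- ladder$rt_min
  m <- length(tt)
  out <- vapply(as.numeric(t), function(ti) {
    if (is.na(ti)) return(NA_real_)
    if (!extrapolate && (ti < tt[1] || ti > tt[m]))
      stop(sprintf(paste0("retention time %.4g min lies outside the ladder ",
                          "range [%.4g, %.4g]; refusing to extrapolate ",
                          "(set extrapolate = TRUE to extend the terminal ",
                          "interval)"), ti, tt[1], tt[m]), call. = FALSE)
    i <- if (ti < tt[1]) 1L else if (ti >= tt[m]) m - 1L
         else max(which(tt <= ti))
    k <- tc[i + 1L] - tc[i]
    100 * tc[i] + 100 * k * (ti - tt[i]) / (tt[i + 1L] - tt[i])
  }, numeric(1))
  as.integer(floor(out + 0.5)) # half-up: printed indices are integers
}

#' Invert a retention index back to a retention time
#'
#' Exact inverse of [retention_index()] (before rounding) on the same
#' ladder, including the terminal-slope extension. Used by the simulator to
#' place synthetic peaks at positions with known true indices.
#'
#' @param ki numeric vector of retention indices.
#' @param ladder an [alkane_ladder].
#' @return Numeric vector of retention times (minutes).
#' @export
invert_retention_index <- function(ki, ladder) {
  stopifnot(inherits(ladder, "alkane_ladder"))
  tc <- ladder$carbon; tt <- ladder$rt_min
  anchors <- 100 * tc
  m <- length(tt)
  vapply(as.numeric(ki), function(k) {
    i <- if (k < anchors[1]) 1L else if (k >= anchors[m]) m - 1L
         else max(which(anchors <= k))
    tt[i] + (k - anchors[i]) / (anchors[i + 1L] - anchors[i]) *
      (tt[i + 1L] - tt[i])
  }, numeric(1))
}
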