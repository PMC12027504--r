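#' Acyclic cuticular hydrocarbon representation
#'
#' `chc_compound()` builds the canonical in-memory representation of one
#' cuticular hydrocarbon: its class (n-alkane, alkene, monomethyl- or
#' dimethyl-branched alkane), main-chain length, methyl branch positions and
#' double-bond position. Positions are stored exactly as named in the
#' field's shorthand, i.e. double bonds are numbered from the nearer chain
#' terminus ("7-pentacosene" has `double_bond_positions = 7`), and unknown
#' branch positions (the "X" of labels such as `5,X-dimeC29`) are kept as
#' `NA` rather than guessed.
#'
#' @param chc_class one of `"n_alkane"`, `"alkene"`, `"monomethyl"`,
#'   `"dimethyl"`.
#' @param chain_length integer number of carbons in the main chain.
#' @param methyl_positions integer vector of branch carbons; `NA` marks an
#'   unknown position. Length must match the class (0, 0, 1, 2).
#' @param double_bond_positions integer vector of double-bond positions,
#'   numbered from the nearer terminus. Alkenes carry exactly one.
#' @param label optional display label; defaults to the canonical shorthand
#'   produced by [format_component_name()].
#'
#' @return An object of class `"chc_compound"`.
#' @seealso [parse_component_name()], [total_carbons()], [molecular_ion()]
#' @export
#' @examples
#' chc_compound("monomethyl", 25, methyl_positions = 3)
chc_compound <- function(chc_class, chain_length,
                         methyl_positions = integer(),
                         double_bond_positions = integer(),
                         label = NULL) {
  chc_class <- match.arg(chc_class,
                         c("n_alkane", "alkene", "monomethyl", "dimethyl"))
  chain_length <- as.integer(chain_length)
  if (length(chain_length) != 1L || is.na(chain_length) || chain_length < 1L)
    stop("'chain_length' must be a single integer >= 1", call. = FALSE)
  methyl_positions <- as.integer(methyl_positions)
  double_bond_positions <- as.integer(double_bond_positions)
  n_me <- c(n_alkane = 0L, alkene = 0L, monomethyl = 1L, dimethyl = 2L)[[chc_class]]
  if (length(methyl_positions) != n_me)
    stop(sprintf("class '%s' requires %d methyl position(s), got %d",
                 chc_class, n_me, length(methyl_positions)), call. = FALSE)
  known <- methyl_positions[!is.na(methyl_positions)]
  if (any(known < 2L | known > chain_length - 1L))
    stop("methyl positions must satisfy 2 <= x <= chain_length - 1",
         call. = FALSE)
  if (chc_class == "alkene") {
    if (length(double_bond_positions) != 1L)
      stop("alkenes carry exactly one double bond", call. = FALSE)
    d <- double_bond_positions
    if (is.na(d) || d < 2L || d > chain_length - 2L)
      stop("double-bond position must satisfy 2 <= d <= chain_length - 2",
           call. = FALSE)
  } else if (length(double_bond_positions) != 0L) {
    stop("only alkenes carry a double bond here", call. = FALSE)
  }
  x <- structure(
    list(label = label, chc_class = chc_class, chain_length = chain_length,
         methyl_positions = methyl_positions,
         double_bond_positions = double_bond_positions),
    class = "chc_compound")
  if (is.null(label)) x$label <- format_component_name(x)
  x
}

#' Parse a shorthand hydrocarbon label
#'
#' Parses the abbreviation grammar used in CHC peak tables:
#' `n-C{n}` (n-alkane), `{d}-C{n}:1` (monoene), `{x}-meC{n}`
#' (monomethylalkane) and `{x},{y}-dimeC{n}` (dimethylalkane), with `X`
#' allowed for an unknown branch position. Underscore/markdown decorations
#' (as in `n-C_25_` or `*n*-C25`) are tolerated, as is the `{x},{y}-meC{n}`
#' contraction sometimes used for dimethylalkanes.
#'
#' @param label character vector of labels.
#' @return A `chc_compound` for a single label, otherwise a list of them.
#' @export
#' @examples
#' parse_component_name("n-C25")
#' parse_component_name("9-C27:1")
#' parse_component_name("5,X-dimeC29")
parse_component_name <- function(label) {
  if (length(label) != 1L) return(lapply(label, parse_component_name))
  raw <- label
  s <- gsub("[*_※#[:space:]]", "", as.character(label))
  if (grepl("^n-?C([0-9]+)$", s)) {
    n <- as.integer(sub("^n-?C([0-9]+)$", "\\1", s))
    return(chc_compound("n_alkane", n, label = canonical_label(raw)))
  }
  if (grepl("^([0-9]+)-C([0-9]+):1$", s)) {
    m <- regmatches(s, regexec("^([0-9]+)-C([0-9]+):1$", s))[[1]]
    return(chc_compound("alkene", as.integer(m[3]),
                        double_bond_positions = as.integer(m[2]),
                        label = canonical_label(raw)))
  }
  if (grepl("^([0-9]+|X)-meC([0-9]+)$", s)) {
    m <- regmatches(s, regexec("^([0-9]+|X)-meC([0-9]+)$", s))[[1]]
    x <- if (m[2] == "X") NA_integer_ else as.integer(m[2])
    return(chc_compound("monomethyl", as.integer(m[3]),
                        methyl_positions = x, label = canonical_label(raw)))
  }
  if (grepl("^([0-9]+|X),([0-9]+|X)-(di)?meC([0-9]+)$", s)) {
    m <- regmatches(s, regexec("^([0-9]+|X),([0-9]+|X)-(di)?meC([0-9]+)$", s))[[1]]
    xs <- ifelse(c(m[2], m[3]) == "X", NA_integer_,
                 suppressWarnings(as.integer(c(m[2], m[3]))))
    return(chc_compound("dimethyl", as.integer(m[5]),
                        methyl_positions = as.integer(xs),
                        label = canonical_label(raw)))
  }
  stop(sprintf("cannot parse hydrocarbon label '%s': token '%s' %s", raw, s,
               "does not match n-C{n}, {d}-C{n}:1, {x}-meC{n} or {x},{y}-dimeC{n}"),
       call. = FALSE)
}

canonical_label <- function(label) {
  gsub("[*_※#[:space:]]", "", as.character(label))
}

#' Format a compound back to its canonical shorthand
#'
#' Inverse of [parse_component_name()]: `parse -> format -> parse`
#' round-trips to an identical structure.
#'
#' @param x a `chc_compound`.
#' @return Character scalar, e.g. `"9,13-dimeC29"`.
#' @export
format_component_name <- function(x) {
  stopifnot(inherits(x, "chc_compound"))
  n <- x$chain_length
  pos <- function(p) ifelse(is.na(p), "X", as.character(p))
  switch(x$chc_class,
    n_alkane   = sprintf("n-C%d", n),
    alkene     = sprintf("%d-C%d:1", x$double_bond_positions, n),
    monomethyl = sprintf("%s-meC%d", pos(x$methyl_positions), n),
    dimethyl   = sprintf("%s,%s-dimeC%d", pos(x$methyl_positions[1]),
                         pos(x$methyl_positions[2]), n))
}

#' Total carbon count of a compound
#'
#' Main-chain carbons plus one per methyl branch (known or unknown);
#' this is the carbon count entering nominal-mass rules.
#'
#' @param x a `chc_compound`.
#' @return Integer.
#' @export
#' @examples
#' total_carbons(parse_component_name("3-meC25")) # 26
total_carbons <- function(x) {
  stopifnot(inherits(x, "chc_compound"))
  x$chain_length + length(x$methyl_positions)
}

#' @export
print.chc_compound <- function(x, ...) {
  cls <- c(n_alkane = "n-alkane", alkene = "alkene",
           monomethyl = "monomethyl alkane", dimethyl = "dimethyl alkane")
  cat(sprintf("<chc_compound> %s (%s, C%d main chain, %d carbons total)\n",
              x$label, cls[[x$chc_class]], x$chain_length, total_carbons(x)))
  invisible(x)
}
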