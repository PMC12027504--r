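#' Reference CHC component catalog for Ips subelongatus
#'
#' Returns the ordered 30-component catalog of elytral cuticular
#' hydrocarbons identified in adult *Ips subelongatus* (chain lengths
#' C24-C31), with retention times, retention indices and the diagnostic
#' electron-impact ions recorded for each GC peak. The catalog partitions
#' into 6 n-alkanes, 6 alkenes, 13 monomethyl- and 5 dimethyl-branched
#' alkanes. Peak 25 carries an `alt_label` ("9-C31:1"): the component was
#' reported under two different double-bond positions in different
#' summaries, and the catalog defaults to the identification backed by the
#' retention-time listing while flagging the alternative.
#'
#' @param path optional path to a catalog CSV with columns
#'   `peak_no,label,chc_class,chain,methyls,double_bonds,rt_min,ki,
#'   diagnostic_ions[,alt_label]`; defaults to the bundled fixture.
#' @return A data.frame with one row per GC peak, plus a `compound`
#'   list-column of parsed [chc_compound] objects.
#' @export
#' @examples
#' cat30 <- chc_catalog()
#' table(cat30$chc_class)
chc_catalog <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "ips_subelongatus_catalog.csv",
                        package = "chctax", mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("peak_no", "label", "chc_class", "chain", "rt_min", "ki",
            "diagnostic_ions")
  if (!all(need %in% names(df)))
    stop("catalog is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  df <- df[order(df$peak_no), , drop = FALSE]
  if (anyDuplicated(df$peak_no) ||
      !identical(as.integer(df$peak_no), seq_len(nrow(df))))
    stop("peak numbers must be unique and contiguous from 1", call. = FALSE)
  if (is.unsorted(df$rt_min, strictly = TRUE))
    stop("catalog rows must be in retention order", call. = FALSE)
  df$diagnostic_ions <- lapply(strsplit(as.character(df$diagnostic_ions), ";"),
                               as.integer)
  df$compound <- lapply(df$label, parse_component_name)
  parsed_class <- vapply(df$compound, `[[`, "", "chc_class")
  if (!identical(parsed_class, df$chc_class))
    stop("catalog 'chc_class' disagrees with the parsed labels", call. = FALSE)
  rownames(df) <- df$label
  df
}

#' Sex-specific mean CHC profiles
#'
#' Mean relative percentage (and standard error) of each catalog component
#' in male (n = 30) and female (n = 28) *I. subelongatus*, from the bundled
#' reference peak table.
#'
#' @param path optional CSV path; defaults to the bundled fixture.
#' @return data.frame with columns `peak_no, label, male_mean, male_se,
#'   female_mean, female_se`.
#' @export
sex_means <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "ips_subelongatus_sex_means.csv",
                        package = "chctax", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Six-population mean CHC profiles
#'
#' Mean relative percentage (+- SE) of each catalog component in the six
#' geographic populations (MJHL, WDLN, GHIM, YCHL, EDJL, ARIM). Components
#' below detection in a population ("nd") are stored as exact zeros with
#' `detected = FALSE`.
#'
#' @param path optional CSV path; defaults to the bundled fixture. Missing
#'   `mean`/`se` cells are read as nd.
#' @return data.frame in long format with columns
#'   `population, n, peak_no, label, mean, se, detected`.
#' @seealso [population_mean_matrix()] for the wide taxa x components form.
#' @export
population_means <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "ips_subelongatus_population_means.csv",
                        package = "chctax", mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$detected <- !is.na(df$mean)
  df$mean[!df$detected] <- 0
  df$se[is.na(df$se)] <- 0
  df
}

#' Population means as a taxa x components matrix
#'
#' @param pm long-format population means, as returned by
#'   [population_means()].
#' @param value which value to spread, `"mean"` or `"se"`.
#' @return Numeric matrix, populations in rows, catalog components in
#'   columns (nd entries are 0).
#' @export
population_mean_matrix <- function(pm = population_means(), value = "mean") {
  value <- match.arg(value, c("mean", "se"))
  pops <- unique(pm$population)
  labs <- pm$label[pm$population == pops[1]]
  m <- matrix(0, length(pops), length(labs), dimnames = list(pops, labs))
  for (p in pops) {
    sub <- pm[pm$population == p, ]
    m[p, sub$label] <- sub[[value]]
  }
  m
}
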