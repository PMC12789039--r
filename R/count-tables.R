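#' Construct a genotype-by-outcome count table
#'
#' The basic tabular input for crude risk- and odds-ratio estimation: one row
#' per exposure level (usually the six APOE genotypes, but any level set is
#' accepted, e.g. a two-level carrier vs non-carrier split), with either
#' case/control counts (`design = "case-control"`) or case counts and
#' stratum totals (`design = "cohort"`).
#'
#' @param genotype Character vector of exposure levels.
#' @param cases Non-negative integer case counts per level.
#' @param controls Control counts (case-control design).
#' @param totals Stratum totals (cohort design); must satisfy
#'   `totals >= cases`.
#' @param design `"case-control"` or `"cohort"`; inferred from which of
#'   `controls`/`totals` is supplied when omitted.
#' @return A tibble of class `genotype_counts` with a `design` attribute.
#' @examples
#' genotype_counts(c("e2/e2", "carrier"), cases = c(1, 1202),
#'                 totals = c(25, 4390))
#' @export
genotype_counts <- function(genotype, cases, controls = NULL, totals = NULL,
                            design = NULL) {
  genotype <- as.character(genotype)
  if (anyDuplicated(genotype)) {
    stop("duplicated exposure levels in count table", call. = FALSE)
  }
  if (is.null(design)) {
    design <- if (!is.null(controls)) "case-control" else "cohort"
  }
  design <- match.arg(design, c("case-control", "cohort"))
  if (any(cases < 0)) stop("case counts must be non-negative", call. = FALSE)

  if (design == "case-control") {
    if (is.null(controls)) stop("case-control design needs `controls`",
                                call. = FALSE)
    if (any(controls < 0)) stop("control counts must be non-negative",
                                call. = FALSE)
    out <- tibble::tibble(genotype = genotype, cases = as.numeric(cases),
                          controls = as.numeric(controls))
  } else {
    if (is.null(totals)) stop("cohort design needs `totals`", call. = FALSE)
    if (any(totals < cases)) {
      stop("stratum totals must be at least the case counts", call. = FALSE)
    }
    out <- tibble::tibble(genotype = genotype, cases = as.numeric(cases),
                          totals = as.numeric(totals))
  }
  structure(out, design = design,
            class = c("genotype_counts", class(out)))
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat("Genotype count table (", attr(x, "design"), " design)\n", sep = "")
  NextMethod()
  invisible(x)
}

#' Tabulate APOE genotypes from an individual-level cohort table
#'
#' Counts cases and stratum totals per genotype from a table with `genotype`
#' and `outcome` columns (as produced by [generate_cohort()] or read with
#' [read_cohort()]); rows with missing genotype are dropped.
#'
#' @param cohort Data frame with columns `genotype` and `outcome` (0/1).
#' @param design `"cohort"` (cases + totals) or `"case-control"`
#'   (cases + controls).
#' @return A [genotype_counts()] table over the genotype levels present.
#' @export
tabulate_genotypes <- function(cohort, design = c("cohort", "case-control")) {
  design <- match.arg(design)
  stopifnot(all(c("genotype", "outcome") %in% names(cohort)))
  g <- cohort$genotype
  if (!is.factor(g)) g <- factor(g, levels = apoe_genotypes())
  keep <- !is.na(g)
  g <- droplevels(g[keep])
  y <- cohort$outcome[keep]
  cases <- as.numeric(tapply(y, g, sum, default = 0))
  n <- as.numeric(table(g))
  if (design == "cohort") {
    genotype_counts(levels(g), cases = cases, totals = n)
  } else {
    genotype_counts(levels(g), cases = cases, controls = n - cases)
  }
}

#' Read / write genotype count tables as TSV
#'
#' Plain-TSV serialisation with columns `genotype`, `cases` and either
#' `controls` or `totals`; the design is inferred from the columns present.
#'
#' @param path File path.
#' @param x A `genotype_counts` table.
#' @return `read_genotype_counts()` returns a `genotype_counts` table;
#'   `write_genotype_counts()` returns `path` invisibly.
#' @export
read_genotype_counts <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if ("controls" %in% names(df)) {
    genotype_counts(df$genotype, df$cases, controls = df$controls)
  } else if ("totals" %in% names(df)) {
    genotype_counts(df$genotype, df$cases, totals = df$totals)
  } else {
    stop("count table TSV needs a `controls` or `totals` column",
         call. = FALSE)
  }
}

#' @rdname read_genotype_counts
#' @export
write_genotype_counts <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
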