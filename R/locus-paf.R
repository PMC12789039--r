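#' Attributable fraction for a biallelic GWAS locus
#'
#' From a risk-allele frequency and per-allele odds ratio — the two numbers
#' a GWAS summary row provides — builds the three-genotype exposure implied
#' under Hardy-Weinberg proportions and computes its multi-level
#' attributable fraction. Genotype frequencies are \eqn{(1-f)^2, 2f(1-f),
#' f^2} for 0/1/2 copies of the risk allele; genotype odds ratios are
#' \eqn{(1, OR, OR^2)} under the multiplicative model or \eqn{(1, OR, OR)}
#' under the dominant (carrier) model; each is converted to a risk ratio at
#' the assumed baseline probability `p0` in zero-copy homozygotes, case
#' fractions are implied as \eqn{q_i RR_i / \sum_j q_j RR_j}, and the
#' per-genotype fractions \eqn{p_{ci}(RR_i - 1)/RR_i} are summed.
#'
#' Because no individual-level case data enter, the case fractions are the
#' Hardy-Weinberg-implied ones; this is recorded in the output.
#'
#' @param eaf Risk-allele frequency in \[0, 1\].
#' @param or Per-allele odds ratio (> 0).
#' @param model `"multiplicative"` (default) or `"dominant"`.
#' @param p0 Baseline outcome probability in zero-risk-allele homozygotes.
#' @param locus_id Optional identifier carried into the output.
#' @return List of class `locus_paf` with elements `paf` (total, a
#'   proportion), `breakdown` (tibble per genotype: copies, frequency, OR,
#'   RR, implied case fraction, per-genotype PAF), `model`, `p0`,
#'   `case_fraction_source = "hwe-implied"` and `locus_id`.
#' @examples
#' locus_paf(eaf = 0.5, or = 2, p0 = 0.01)
#' @export
locus_paf <- function(eaf, or, model = c("multiplicative", "dominant"),
                      p0 = 0.01, locus_id = NA_character_) {
  model <- match.arg(model)
  if (is.na(eaf) || eaf < 0 || eaf > 1) {
    stop("risk-allele frequency must lie in [0, 1]", call. = FALSE)
  }
  if (is.na(or) || or <= 0) stop("odds ratio must be positive",
                                 call. = FALSE)
  q <- c((1 - eaf)^2, 2 * eaf * (1 - eaf), eaf^2)
  or_g <- switch(model,
                 multiplicative = c(1, or, or^2),
                 dominant = c(1, or, or))
  rr <- or_to_rr(or_g, p0)
  p_ci <- q * rr / sum(q * rr)
  paf_i <- genotype_paf(p_ci, rr)
  breakdown <- tibble::tibble(
    copies = 0:2, frequency = q, or = or_g, rr = rr,
    case_fraction = p_ci, paf = paf_i
  )
  structure(list(paf = sum(paf_i[2:3]), breakdown = breakdown,
                 model = model, p0 = p0,
                 case_fraction_source = "hwe-implied",
                 locus_id = locus_id),
            class = "locus_paf")
}

#' @export
print.locus_paf <- function(x, ...) {
  cat(sprintf("Locus %s: PAF = %.1f%% (%s model, p0 = %s, %s case fractions)\n",
              ifelse(is.na(x$locus_id), "<unnamed>", x$locus_id),
              100 * x$paf, x$model, format(x$p0), x$case_fraction_source))
  invisible(x)
}

#' Rank GWAS loci by attributable fraction
#'
#' Computes [locus_paf()] for every row of a locus summary table and returns
#' the table ordered by descending attributable fraction, ties broken by
#' locus id, optionally truncated to the top k.
#'
#' @param loci Data frame with columns `locus_id`, `eaf`, `or` and
#'   optionally `model` (defaults to multiplicative) and `p0`.
#' @param top_k Keep only the k largest; `Inf` keeps all.
#' @param p0 Default baseline probability for rows without their own `p0`.
#' @return Tibble with the input columns plus `paf` (as a proportion),
#'   ordered by descending `paf`.
#' @export
rank_loci <- function(loci, top_k = Inf, p0 = 0.01) {
  stopifnot(all(c("locus_id", "eaf", "or") %in% names(loci)))
  if (nrow(loci) == 0) stop("empty locus table", call. = FALSE)
  model <- if ("model" %in% names(loci)) loci$model else
    rep("multiplicative", nrow(loci))
  p0s <- if ("p0" %in% names(loci)) loci$p0 else rep(p0, nrow(loci))
  paf <- vapply(seq_len(nrow(loci)), function(i) {
    locus_paf(loci$eaf[i], loci$or[i], model = model[i], p0 = p0s[i])$paf
  }, numeric(1))
  out <- tibble::as_tibble(loci)
  out$paf <- paf
  out <- out[order(-out$paf, out$locus_id), , drop = FALSE]
  utils::head(out, n = top_k)
}

#' Read a GWAS locus summary table from TSV
#'
#' Expects columns `locus_id`, `eaf`, `or` and optionally `model`, `p0`.
#'
#' @param path File path.
#' @return Tibble suitable for [rank_loci()].
#' @export
read_loci <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("locus_id", "eaf", "or") %in% names(df))) {
    stop("locus TSV must contain columns locus_id, eaf, or", call. = FALSE)
  }
  tibble::as_tibble(df)
}
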