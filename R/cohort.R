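#' Cohort summary rates from a count table
#'
#' Computes the headline cohort fractions from a two-column `metric`/`count`
#' table: the metastasis rate among all ChRCC patients, the dedifferentiation
#' rate among reviewed aggressive cases, and the fraction of WES patients with
#' a TP53 mutation. The packaged table (`inst/extdata/cohort_counts.tsv`)
#' holds the published institutional cohort counts.
#'
#' @param path count table; defaults to the packaged cohort counts
#' @return list with `metastasis_pct`, `dediff_pct`, `tp53_pct` and the raw
#'   `counts`
#' @export
cohort_rates <- function(path = system.file("extdata", "cohort_counts.tsv",
                                            package = "chromoevo")) {
  x <- read_tsv(path)
  counts <- stats::setNames(x$count, x$metric)
  need <- c("patients_total", "patients_metastatic", "aggressive_reviewed",
            "dediff_patients", "wes_patients", "tp53_mutant_patients")
  miss <- setdiff(need, names(counts))
  if (length(miss)) stop("cohort table missing metric: ", miss[1])
  list(
    metastasis_pct = 100 * counts[["patients_metastatic"]] /
      counts[["patients_total"]],
    dediff_pct = 100 * counts[["dediff_patients"]] /
      counts[["aggressive_reviewed"]],
    tp53_pct = 100 * counts[["tp53_mutant_patients"]] /
      counts[["wes_patients"]],
    counts = counts)
}
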