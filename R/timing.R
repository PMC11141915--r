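## Mutation multiplicity, zygosity and timing relative to genome doubling
##
## The ordering logic rests on a simple observation: a mutation that predates
## a duplication of its chromosome is carried by the duplicated copies, so in
## a doubled genome it sits at multiplicity equal to the total copy number
## (homozygous when the minor allele is absent), whereas a mutation acquired
## after the doubling sits on a single copy.

#' Filter raw somatic variants to callable nonsynonymous mutations
#'
#' Retains variants with VAF >= `vaf_min` (boundary retained) and annotation
#' class `nonsynonymous`. Variants lacking an annotation class are excluded
#' and counted in the attached filter log.
#'
#' @param variants data.frame with columns `alt`, `ref`, `class` (and
#'   whatever identifying columns the caller carries along)
#' @param vaf_min minimum VAF to call a somatic variant (default 0.15)
#' @return the retained rows with an added `vaf` column; attribute
#'   `filter_log` records counts in/out and the unannotated count
#' @export
filter_variants <- function(variants, vaf_min = 0.15) {
  stopifnot(is.data.frame(variants), all(c("alt", "ref", "class") %in% names(variants)))
  depth <- variants$alt + variants$ref
  vaf <- ifelse(depth > 0, variants$alt / depth, 0)
  unannotated <- is.na(variants$class)
  keep <- !unannotated & vaf >= vaf_min & variants$class == "nonsynonymous"
  out <- variants[keep, , drop = FALSE]
  out$vaf <- vaf[keep]
  attr(out, "filter_log") <- list(n_in = nrow(variants), n_out = nrow(out),
                                  n_unannotated = sum(unannotated),
                                  vaf_min = vaf_min)
  out
}

#' Total mutation burden of a filtered sample
#'
#' The count of retained nonsynonymous somatic mutations.
#'
#' @param variants filtered variant table (one sample)
#' @return integer count
#' @export
tmb <- function(variants) nrow(variants)

#' Log odds ratio of a somatic mutation
#'
#' `ln((alt + 0.5) / (ref + 0.5))` with Haldane correction; under the
#' assumption that the mutation occupies every major-allele copy, this is
#' directly comparable with the segment-level germline-het |logOR|, which is
#' how driver mutations are overlaid on B-allele plots.
#'
#' @param alt,ref read depths supporting the mutation and the reference
#' @return natural-log odds, finite for all non-negative depths
#' @export
mutation_logor <- function(alt, ref) {
  stopifnot(all(alt + ref > 0))
  log((alt + 0.5) / (ref + 0.5))
}

#' Mutation multiplicity from VAF, purity and local copy number
#'
#' Inverts the expected-VAF model:
#' `m = vaf * (purity * cn_total + (1 - purity) * 2) / purity`.
#'
#' @param vaf observed variant allele fraction
#' @param purity sample purity in (0, 1]
#' @param cn_total integer total copy number at the locus (>= 1)
#' @param subclonal_below raw multiplicities below this mark the mutation
#'   subclonal (default 0.75)
#' @return data.frame `m_raw` (continuous), `m` (rounded, clamped to
#'   `[1, cn_total]`), `subclonal`
#' @export
estimate_multiplicity <- function(vaf, purity, cn_total, subclonal_below = 0.75) {
  if (any(purity <= 0)) stop("purity must be positive")
  stopifnot(all(cn_total >= 1), all(vaf >= 0 & vaf <= 1))
  m_raw <- vaf * (purity * cn_total + (1 - purity) * 2) / purity
  m <- pmin(pmax(round(m_raw), 1L), cn_total)
  data.frame(m_raw = m_raw, m = as.integer(m), subclonal = m_raw < subclonal_below)
}

#' Zygosity classification of a somatic mutation
#'
#' @param m rounded multiplicity (1..cn_total)
#' @param cn_total,cn_minor integer segment copy numbers at the locus
#' @param subclonal logical; overrides the copy-number classification
#' @return one of `hemizygous_loh`, `homozygous`, `heterozygous`,
#'   `subclonal`, `indeterminate`
#' @export
classify_zygosity <- function(m, cn_total, cn_minor, subclonal = FALSE) {
  n <- max(length(m), length(cn_total), length(cn_minor), length(subclonal))
  m <- rep_len(m, n); cn_total <- rep_len(cn_total, n)
  cn_minor <- rep_len(cn_minor, n); subclonal <- rep_len(subclonal, n)
  out <- character(n)
  for (i in seq_len(n)) {
    out[i] <- if (is.na(cn_total[i]) || is.na(m[i])) "indeterminate"
    else if (m[i] > cn_total[i]) stop("multiplicity exceeds total copy number")
    else if (subclonal[i]) "subclonal"
    else if (cn_total[i] == 1) "hemizygous_loh"
    else if (cn_minor[i] == 0 && m[i] == cn_total[i] && cn_total[i] >= 2) "homozygous"
    else "heterozygous"
  }
  out
}

#' Annotate filtered variants of one sample with multiplicity and zygosity
#'
#' Looks up the fitted segment containing each variant, estimates
#' multiplicity from the sample purity and classifies zygosity; the mutation
#' logOR is attached for overlay on B-allele plots.
#'
#' @param variants filtered variant table for one sample (`chrom`, `pos`,
#'   `alt`, `ref`, `vaf`)
#' @param fit `ascn_fit` of the same sample
#' @return variants with added `cn_total`, `cn_minor`, `m_raw`, `m`,
#'   `zygosity`, `logor`
#' @export
annotate_zygosity <- function(variants, fit) {
  segs <- fit$segments
  v <- variants
  v$cn_total <- NA_integer_; v$cn_minor <- NA_integer_
  for (i in seq_len(nrow(v))) {
    j <- which(segs$chrom == v$chrom[i] & segs$start <= v$pos[i] &
                 segs$end > v$pos[i])
    if (length(j)) {
      v$cn_total[i] <- segs$total[j[1]]
      v$cn_minor[i] <- segs$minor[j[1]]
    }
  }
  ok <- !is.na(v$cn_total) & v$cn_total >= 1
  v$m_raw <- NA_real_; v$m <- NA_integer_; v$subclonal <- NA
  if (any(ok)) {
    est <- estimate_multiplicity(v$vaf[ok], fit$purity, v$cn_total[ok])
    v$m_raw[ok] <- est$m_raw; v$m[ok] <- est$m; v$subclonal[ok] <- est$subclonal
  }
  v$zygosity <- "indeterminate"
  v$zygosity[ok] <- classify_zygosity(v$m[ok], v$cn_total[ok], v$cn_minor[ok],
                                      v$subclonal[ok])
  v$logor <- mutation_logor(v$alt, v$ref)
  v
}

#' Order driver mutations relative to genome doubling
#'
#' Per patient and per mutation (matched across samples by chromosome and
#' position), issues one of three verdicts:
#' \itemize{
#'   \item `mutation_before_duplication` — hemizygous in a non-WGD sample and
#'     homozygous in a WGD sample, or homozygous (multiplicity = total CN >= 2
#'     with minor CN 0) in a WGD sample even if absent before doubling;
#'   \item `mutation_after_duplication` — multiplicity 1 on a segment with
#'     total CN >= 2 in a WGD sample;
#'   \item `unordered` — anything else, including contradictory evidence
#'     across samples (a conflict note is attached).
#' }
#' Samples whose fits are flagged excluded (purity < 0.3) are dropped first
#' unless `include_excluded` is set.
#'
#' @param annotated named list (by sample/region id) of variant tables from
#'   [annotate_zygosity()]
#' @param wgd named list or logical vector of WGD flags per sample
#' @param excluded optional named logical vector of excluded-sample flags
#' @param include_excluded keep excluded samples (default FALSE)
#' @param drivers_only restrict to variants with a driver label (default TRUE)
#' @return data.frame `gene`, `chrom`, `pos`, `verdict`, `evidence` (JSON of
#'   per-sample zygosity/CN/WGD), `conflict`, `extrapolated` (homozygosity
#'   used at total CN > 2)
#' @export
order_events <- function(annotated, wgd, excluded = NULL,
                         include_excluded = FALSE, drivers_only = TRUE) {
  stopifnot(is.list(annotated), length(annotated) >= 1)
  samples <- names(annotated)
  wgd <- unlist(wgd)[samples]
  if (!is.null(excluded) && !include_excluded) {
    drop <- samples[excluded[samples] %in% TRUE]
    samples <- setdiff(samples, drop)
    if (!length(samples)) stop("all samples excluded by the purity filter")
  }
  pool <- do.call(rbind, lapply(samples, function(s) {
    v <- annotated[[s]]
    if (!nrow(v)) return(NULL)
    v$sample <- s
    v
  }))
  if (is.null(pool) || !nrow(pool))
    return(data.frame(gene = character(0), chrom = character(0),
                      pos = numeric(0), verdict = character(0),
                      evidence = character(0), conflict = logical(0),
                      extrapolated = logical(0), stringsAsFactors = FALSE))
  if (drivers_only && "driver" %in% names(pool))
    pool <- pool[!is.na(pool$driver), , drop = FALSE]
  key <- paste(pool$chrom, pool$pos, sep = ":")
  out <- lapply(unique(key), function(k) {
    v <- pool[key == k, , drop = FALSE]
    w <- wgd[v$sample]
    before_a <- any(v$zygosity == "hemizygous_loh" & !w, na.rm = TRUE) &&
      any(v$zygosity == "homozygous" & w, na.rm = TRUE)
    before_b <- any(v$zygosity == "homozygous" & w &
                      v$m == v$cn_total & v$cn_total >= 2 & v$cn_minor == 0,
                    na.rm = TRUE)
    after <- any(v$m == 1 & v$cn_total >= 2 & w & v$zygosity != "subclonal",
                 na.rm = TRUE)
    verdict <- if ((before_a || before_b) && after) "unordered"
    else if (before_a || before_b) "mutation_before_duplication"
    else if (after) "mutation_after_duplication"
    else "unordered"
    conflict <- (before_a || before_b) && after
    data.frame(
      gene = if ("gene" %in% names(v)) v$gene[1] else NA_character_,
      chrom = v$chrom[1], pos = v$pos[1], verdict = verdict,
      evidence = as.character(jsonlite::toJSON(
        data.frame(sample = v$sample, zygosity = v$zygosity,
                   cn_total = v$cn_total, cn_minor = v$cn_minor,
                   m = v$m, wgd = unname(w)))),
      conflict = conflict,
      extrapolated = before_b && any(v$cn_total > 2 & v$zygosity == "homozygous",
                                     na.rm = TRUE),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
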