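## Closed-form scores: IHC H-score and the T effector expression score

#' IHC H-score
#'
#' Staining intensity (integer 0-3) times percent positive cells (0-100);
#' range 0-300.
#'
#' @param intensity integer staining intensity in 0..3 (fractional values are
#'   rejected)
#' @param percent percent of tumor cells staining positive, 0-100
#' @return H-score
#' @export
h_score <- function(intensity, percent) {
  if (any(intensity != round(intensity))) stop("intensity must be integer 0..3")
  if (any(intensity < 0 | intensity > 3)) stop("intensity out of range 0..3")
  if (any(percent < 0 | percent > 100)) stop("percent out of range 0..100")
  intensity * percent
}

#' p53 IHC positivity
#'
#' High nuclear p53 expression is called at H-score strictly greater than 10.
#'
#' @param h H-score in 0..300
#' @return logical
#' @export
p53_positive <- function(h) {
  if (any(h < 0 | h > 300)) stop("H-score out of range 0..300")
  h > 10
}

#' log counts per million (voom convention)
#'
#' `log2((count + 0.5) / (lib_size + 1) * 1e6)` per cell.
#'
#' @param counts non-negative gene x sample count matrix
#' @param lib_size library sizes per sample; defaults to column sums
#' @return logCPM matrix of the same shape
#' @export
logcpm <- function(counts, lib_size = colSums(counts)) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(lib_size <= 0)) stop("library sizes must be positive")
  t(log2(t(counts + 0.5) / (lib_size + 1) * 1e6))
}

#' T effector expression score
#'
#' The mean logCPM of the signature genes present in the matrix, per sample.
#'
#' @param logcpm_matrix gene x sample logCPM matrix with gene rownames
#' @param signature character vector of signature gene names
#' @return list with `scores` (named per-sample means) and `missing`
#'   (signature genes absent from the matrix)
#' @export
t_effector_score <- function(logcpm_matrix, signature) {
  logcpm_matrix <- as.matrix(logcpm_matrix)
  present <- intersect(signature, rownames(logcpm_matrix))
  if (!length(present))
    stop("no signature genes present in the expression matrix (",
         length(signature), " requested)")
  sub <- logcpm_matrix[present, , drop = FALSE]
  list(scores = colMeans(sub), missing = setdiff(signature, present))
}
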