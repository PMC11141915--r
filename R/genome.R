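## Genome abstraction
##
## The inference logic never needs base-pair resolution, so the genome is a
## compact abstract model: 22 autosomes with lengths in 0.01-Mb units, a p-arm
## fraction per chromosome, a fixed number of germline-heterozygous SNP sites,
## and a small gene catalog. Coordinates are 0-based half-open throughout the
## package; VCF positions are converted at the I/O boundary.

#' Construct a genome model
#'
#' @param chromosomes data.frame with columns `chrom` (character), `length`
#'   (positive, abstract units), `p_frac` (p-arm fraction, strictly in (0,1)),
#'   `n_snps` (non-negative integer count of germline-het SNP sites).
#' @param genes data.frame with columns `gene`, `chrom`, `start`, `end`
#'   (0-based half-open, inside the chromosome) and logical `driver`.
#' @return object of class `genome_model`
#' @export
genome_model <- function(chromosomes, genes) {
  stopifnot(is.data.frame(chromosomes),
            all(c("chrom", "length", "p_frac", "n_snps") %in% names(chromosomes)))
  if (any(chromosomes$length <= 0)) stop("chromosome lengths must be > 0")
  if (any(chromosomes$p_frac <= 0 | chromosomes$p_frac >= 1))
    stop("p-arm fractions must lie strictly between 0 and 1")
  if (any(chromosomes$n_snps < 0)) stop("SNP counts must be >= 0")
  if (anyDuplicated(chromosomes$chrom)) stop("duplicated chromosome names")
  stopifnot(is.data.frame(genes),
            all(c("gene", "chrom", "start", "end", "driver") %in% names(genes)))
  idx <- match(genes$chrom, chromosomes$chrom)
  if (anyNA(idx)) stop("gene on unknown chromosome: ", genes$gene[which(is.na(idx))[1]])
  bad <- genes$start < 0 | genes$end > chromosomes$length[idx] | genes$start >= genes$end
  if (any(bad)) stop("gene interval outside its chromosome: ", genes$gene[which(bad)[1]])
  structure(list(chromosomes = chromosomes, genes = genes), class = "genome_model")
}

#' Default compact ChRCC genome
#'
#' Lengths are scaled hg38 autosome sizes (0.01-Mb units) with approximate
#' centromere positions; each chromosome carries `n_snps` germline-het SNP
#' sites. The catalog holds driver loci modelled on the recurrently mutated
#' ChRCC genes (a TP53-like gene on 17p, a PTEN-like gene on 10q, a TSC1-like
#' gene on 9q, an MSH6-like gene on 2p) plus neutral passenger genes; names
#' carry an L suffix to mark them as synthetic stand-ins.
#'
#' @param n_snps SNP sites per chromosome (default 500)
#' @return `genome_model`
#' @export
default_genome <- function(n_snps = 500) {
  len <- c(24900, 24200, 19800, 19000, 18200, 17100, 15900, 14500, 13800,
           13400, 13500, 13300, 11400, 10700, 10200,  9000,  8300,  8000,
            5900,  6400,  4700,  5100)
  pf  <- c(0.50, 0.38, 0.46, 0.26, 0.27, 0.35, 0.38, 0.31, 0.31, 0.30,
           0.40, 0.28, 0.16, 0.16, 0.19, 0.41, 0.30, 0.23, 0.44, 0.44,
           0.28, 0.29)
  chroms <- data.frame(chrom = as.character(1:22), length = len,
                       p_frac = pf, n_snps = as.integer(n_snps),
                       stringsAsFactors = FALSE)
  genes <- data.frame(
    gene   = c("TP53L", "PTENL", "TSC1L", "MSH6L", "KITL", "FOXI1L",
               "PASS3L", "PASS7L", "PASS12L", "PASS19L"),
    chrom  = c("17", "10", "9", "2", "4", "5", "3", "7", "12", "19"),
    start  = c(760, 8970, 13200, 4780, 5460, 17000, 9000, 8000, 6000, 3000),
    end    = c(780, 8990, 13220, 4800, 5480, 17020, 9020, 8020, 6020, 3020),
    driver = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  genome_model(chroms, genes)
}

#' Chromosome-arm table for a genome
#'
#' @param genome `genome_model`
#' @return data.frame with `arm` (e.g. "17p"), `chrom`, `start`, `end`
#'   (0-based half-open) tiling each chromosome into its p and q arm.
#' @export
arm_table <- function(genome) {
  ch <- genome$chromosomes
  cen <- round(ch$length * ch$p_frac)
  data.frame(
    arm    = c(paste0(ch$chrom, "p"), paste0(ch$chrom, "q")),
    chrom  = rep(ch$chrom, 2),
    start  = c(rep(0, nrow(ch)), cen),
    end    = c(cen, ch$length),
    stringsAsFactors = FALSE)[order(rep(seq_len(nrow(ch)), 2)), ]
}

# arm ("p"/"q") of a position on a chromosome
arm_of <- function(genome, chrom, pos) {
  i <- match(chrom, genome$chromosomes$chrom)
  cen <- round(genome$chromosomes$length[i] * genome$chromosomes$p_frac[i])
  ifelse(pos < cen, "p", "q")
}

# deterministic SNP site positions: evenly spread, fixed for a genome
snp_positions <- function(genome, chrom) {
  i <- match(chrom, genome$chromosomes$chrom)
  n <- genome$chromosomes$n_snps[i]
  L <- genome$chromosomes$length[i]
  if (n == 0) return(numeric(0))
  floor((seq_len(n) - 0.5) / n * L)
}
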