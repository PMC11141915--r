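## Forward simulation of multiregion read-count observations
##
## Emission model: at a germline-heterozygous SNP the tumor B-allele fraction
## is the purity-weighted mixture of clone copy numbers; at a somatic variant
## the expected VAF follows the standard purity/multiplicity model. Depths are
## Poisson (tumor depth proportional to local mixed copy number, normalised to
## the sample mean so library sizes are comparable), allele counts Binomial.

#' Expected somatic variant allele fraction
#'
#' `(purity * clone_fraction * multiplicity) /
#'  (purity * tumor_total_cn + (1 - purity) * 2)`
#'
#' @param purity tumor purity in (0, 1]
#' @param tumor_total_cn integer total copy number at the locus in tumor cells
#' @param multiplicity copies carrying the mutation (0..tumor_total_cn)
#' @param clone_fraction fraction of tumor cells in the carrying clone
#' @return expected VAF in `[0, 1]`
#' @export
expected_vaf <- function(purity, tumor_total_cn, multiplicity, clone_fraction = 1) {
  stopifnot(all(purity > 0 & purity <= 1),
            all(multiplicity >= 0), all(multiplicity <= tumor_total_cn),
            all(clone_fraction >= 0 & clone_fraction <= 1))
  den <- purity * tumor_total_cn + (1 - purity) * 2
  if (any(den <= 0))
    stop("homozygous-deletion site: no sequenceable copies (purity 1, CN 0)")
  purity * clone_fraction * multiplicity / den
}

#' Expected major-allele fraction (BAF) at a germline-heterozygous site
#'
#' `(purity * cn_major + (1 - purity)) / (purity * (cn_major + cn_minor) +
#'  (1 - purity) * 2)`
#'
#' @param purity tumor purity in (0, 1]
#' @param cn_major,cn_minor integer allele-specific copy numbers,
#'   `cn_major >= cn_minor >= 0`
#' @return expected fraction of reads carrying the major allele
#' @export
expected_baf <- function(purity, cn_major, cn_minor) {
  stopifnot(all(purity > 0 & purity <= 1),
            all(cn_major >= cn_minor), all(cn_minor >= 0))
  den <- purity * (cn_major + cn_minor) + (1 - purity) * 2
  if (any(den <= 0))
    stop("homozygous-deletion site: no sequenceable copies (purity 1, CN 0)")
  (purity * cn_major + (1 - purity)) / den
}

#' Expected copy-number log ratio of a segment
#'
#' `log2((purity * tumor_total_cn + (1 - purity) * 2) /
#'       (purity * sample_ploidy + (1 - purity) * 2))`
#'
#' @param purity tumor purity in (0, 1]
#' @param tumor_total_cn integer total copy number of the segment
#' @param sample_ploidy average tumor copy number of the sample (> 0)
#' @return expected log2 depth ratio after library-size normalisation
#' @export
expected_logr <- function(purity, tumor_total_cn, sample_ploidy) {
  stopifnot(all(purity > 0 & purity <= 1), all(sample_ploidy > 0))
  log2((purity * tumor_total_cn + (1 - purity) * 2) /
         (purity * sample_ploidy + (1 - purity) * 2))
}

## passenger/driver mutation generation --------------------------------------

empty_mutations <- function() {
  data.frame(id = character(0), gene = character(0),
             chrom = character(0), pos = numeric(0), m = integer(0),
             class = character(0), driver = character(0),
             clone = character(0), stringsAsFactors = FALSE)
}

# Draw passenger mutations for one clone edge. Chromosome choice is weighted
# by length x copy number after the edge's monosomies; mutations landing
# before a WGD on the same edge get doubled multiplicity.
draw_passengers <- function(clone, e, arm_cn_pre_wgd, genome, seed) {
  ch <- genome$chromosomes
  cn_chrom <- vapply(ch$chrom, function(cc) {
    g <- arm_cn_pre_wgd[arm_cn_pre_wgd$chrom == cc, ]
    wmean(g$mat + g$pat, g$end_len)
  }, numeric(1))
  w <- ch$length * cn_chrom
  res <- with_seed(seed, {
    n_ns <- stats::rpois(1, e$rate_nonsyn)
    n_sy <- stats::rpois(1, e$rate_syn)
    n <- n_ns + n_sy
    if (n == 0 || sum(w) == 0) NULL else {
      chrom <- sample(ch$chrom, n, replace = TRUE, prob = w)
      pos <- floor(stats::runif(n) * ch$length[match(chrom, ch$chrom)])
      u <- stats::runif(n)                      # time along the branch
      m <- rep(1L, n)
      if (e$wgd) m[u < e$wgd_time] <- 2L
      data.frame(
        id = sprintf("%s_p%03d", clone, seq_len(n)),
        gene = NA_character_,
        chrom = chrom, pos = pos, m = m,
        class = c(rep("nonsynonymous", n_ns), rep("synonymous", n_sy)),
        driver = NA_character_, clone = clone, stringsAsFactors = FALSE)
    }
  })
  if (is.null(res)) empty_mutations() else res
}

driver_mutations <- function(clone, e, genome) {
  if (!nrow(e$drivers)) {
    return(data.frame(id = character(0), gene = character(0),
                      chrom = character(0), pos = numeric(0), m = integer(0),
                      class = character(0), driver = character(0),
                      clone = character(0), stringsAsFactors = FALSE))
  }
  gi <- match(e$drivers$gene, genome$genes$gene)
  if (anyNA(gi)) stop("driver gene not in genome catalog: ",
                      e$drivers$gene[which(is.na(gi))[1]])
  m <- ifelse(e$wgd & e$drivers$timing == "pre_wgd", 2L, 1L)
  data.frame(
    id = paste0(clone, "_", e$drivers$gene),
    gene = e$drivers$gene,
    chrom = genome$genes$chrom[gi],
    pos = floor((genome$genes$start[gi] + genome$genes$end[gi]) / 2),
    m = m, class = "nonsynonymous", driver = e$drivers$gene,
    clone = clone, stringsAsFactors = FALSE)
}

## main entry ----------------------------------------------------------------

#' Simulate a multiregion dataset from a scenario
#'
#' Generates clone genotypes, passenger and driver mutations, and per-region
#' read-count observations (SNP allelic depths for tumor and matched normal,
#' somatic variant depths) together with the full generating truth. The run is
#' deterministic given `seed`: per-region and per-stage RNG streams are derived
#' from it by [derive_seed()], so adding a region leaves others unchanged.
#'
#' @param scenario `evolution_scenario`
#' @param genome `genome_model`
#' @param seed master integer seed
#' @param error_rate symmetric per-read sequencing error added to every
#'   expected allele fraction (default 0)
#' @return object of class `sim_dataset`: list with `snps`, `variants`,
#'   `truth`, `seed`, `genome`, `scenario`
#' @export
simulate_scenario <- function(scenario, genome, seed, error_rate = 0) {
  stopifnot(inherits(scenario, "evolution_scenario"),
            inherits(genome, "genome_model"))
  arms <- arm_table(genome)
  arms$end_len <- arms$end - arms$start

  ## resolve the chromosome-21 coin
  trunk <- scenario$clones$clone[is.na(scenario$clones$parent)]
  mono_trunk <- scenario$events[[trunk]]$monosomies
  lost21 <- switch(scenario$chr21,
    yes = TRUE, no = FALSE,
    coin = with_seed(derive_seed(seed, "chr21"),
                     stats::runif(1) < scenario$p_chr21))
  if (lost21) mono_trunk <- union(mono_trunk, "21") else
    mono_trunk <- setdiff(mono_trunk, "21")

  cn <- clone_arm_cn(scenario, genome, monosomies_trunk = mono_trunk)
  for (cl in names(cn)) cn[[cl]]$end_len <- arms$end_len
  base_diploid <- data.frame(chrom = arms$chrom, arm = arms$arm,
                             mat = 1L, pat = 1L, end_len = arms$end_len,
                             stringsAsFactors = FALSE)

  ## mutations per edge (drivers deterministic, passengers seeded per clone)
  muts <- do.call(rbind, lapply(clone_order(scenario$clones), function(cl) {
    e <- scenario$events[[cl]]
    parent <- scenario$clones$parent[match(cl, scenario$clones$clone)]
    pre <- if (is.na(parent)) base_diploid else cn[[parent]]
    mono <- if (is.na(parent)) mono_trunk else e$monosomies
    if (length(mono)) {                       # mutations follow the losses
      hit <- pre$chrom %in% mono
      pre$pat[hit] <- pmax(pre$pat[hit] - 1L, 0L)
    }
    rbind(driver_mutations(cl, e, genome),
          draw_passengers(cl, e, pre, genome,
                          derive_seed(seed, paste0("muts:", cl))))
  }))
  if (anyDuplicated(muts$id)) stop("internal: duplicated mutation id")

  ## per-clone multiplicity: present in the originating clone and all
  ## descendants; a WGD on a descendant edge doubles inherited multiplicities
  clones_all <- scenario$clones$clone
  mult <- matrix(0L, nrow(muts), length(clones_all),
                 dimnames = list(muts$id, clones_all))
  for (k in seq_len(nrow(muts))) {
    origin <- muts$clone[k]
    for (cl in clone_descendants(scenario$clones, origin)) {
      m <- muts$m[k]
      path <- cl
      while (path != origin) {                # WGDs strictly below the origin
        if (scenario$events[[path]]$wgd) m <- 2L * m
        path <- scenario$clones$parent[match(path, scenario$clones$clone)]
      }
      mult[k, cl] <- m
    }
  }

  ## germline phase of the B allele, shared across regions
  sites <- do.call(rbind, lapply(genome$chromosomes$chrom, function(cc) {
    pos <- snp_positions(genome, cc)
    data.frame(chrom = cc, pos = pos, stringsAsFactors = FALSE)
  }))
  sites$arm <- arm_of(genome, sites$chrom, sites$pos)
  sites$armid <- paste0(sites$chrom, sites$arm)
  sites$b_on_mat <- with_seed(derive_seed(seed, "phase"),
                              stats::runif(nrow(sites)) < 0.5)
  sites$site <- sprintf("S%05d", seq_len(nrow(sites)))

  mix_err <- function(f, eps) f * (1 - eps) + (1 - f) * eps

  regions <- scenario$regions
  snp_out <- vector("list", nrow(regions))
  var_out <- vector("list", nrow(regions))
  truth_regions <- vector("list", nrow(regions))
  muts$armid <- paste0(muts$chrom, arm_of(genome, muts$chrom, muts$pos))

  for (ri in seq_len(nrow(regions))) {
    rg <- regions[ri, ]
    f <- scenario$fractions[[rg$region]]
    p <- rg$purity
    ## mixed copy numbers per arm
    mixT <- Reduce(`+`, lapply(names(f), function(cl)
      f[[cl]] * (cn[[cl]]$mat + cn[[cl]]$pat)))
    mixMat <- Reduce(`+`, lapply(names(f), function(cl)
      f[[cl]] * cn[[cl]]$mat))
    mixPat <- mixT - mixMat
    ploidy_true <- wmean(mixT, arms$end_len)
    depth_norm <- p * ploidy_true + (1 - p) * 2

    ai <- match(sites$armid, arms$arm)
    cnT <- mixT[ai]
    cnB <- ifelse(sites$b_on_mat, mixMat[ai], mixPat[ai])
    ebaf <- (p * cnB + (1 - p)) / (p * cnT + (1 - p) * 2)
    ebaf <- mix_err(ebaf, error_rate)
    lambda_t <- rg$coverage * (p * cnT + (1 - p) * 2) / depth_norm

    snp_out[[ri]] <- with_seed(derive_seed(seed, paste0("region:", rg$region, ":snp")), {
      tdep <- stats::rpois(nrow(sites), lambda_t)
      talt <- stats::rbinom(nrow(sites), tdep, ebaf)
      ndep <- stats::rpois(nrow(sites), rg$coverage)
      nalt <- stats::rbinom(nrow(sites), ndep, mix_err(0.5, error_rate))
      data.frame(site = sites$site, chrom = sites$chrom, pos = sites$pos,
                 region = rg$region, t_alt = talt, t_ref = tdep - talt,
                 n_alt = nalt, n_ref = ndep - nalt, stringsAsFactors = FALSE)
    })

    vai <- match(muts$armid, arms$arm)
    vT <- mixT[vai]
    vm <- Reduce(`+`, lapply(names(f), function(cl) f[[cl]] * mult[, cl]))
    evaf <- p * vm / (p * vT + (1 - p) * 2)
    evaf <- mix_err(evaf, error_rate)
    lam_v <- rg$coverage * (p * vT + (1 - p) * 2) / depth_norm

    var_out[[ri]] <- with_seed(derive_seed(seed, paste0("region:", rg$region, ":var")), {
      vdep <- stats::rpois(nrow(muts), lam_v)
      valt <- stats::rbinom(nrow(muts), vdep, evaf)
      data.frame(id = muts$id, gene = muts$gene, chrom = muts$chrom,
                 pos = muts$pos, region = rep(rg$region, nrow(muts)),
                 alt = valt, ref = vdep - valt, class = muts$class,
                 driver = muts$driver, stringsAsFactors = FALSE)
    })

    seg <- data.frame(region = rg$region, chrom = arms$chrom, arm = arms$arm,
                      start = arms$start, end = arms$end,
                      total = mixT, major = pmax(mixMat, mixPat),
                      minor = pmin(mixMat, mixPat), stringsAsFactors = FALSE)
    seg$exp_baf <- (p * seg$major + (1 - p)) / (p * seg$total + (1 - p) * 2)
    seg$exp_logr <- log2((p * seg$total + (1 - p) * 2) / depth_norm)
    truth_regions[[ri]] <- list(
      region = rg$region, purity = p, ploidy = ploidy_true,
      wgd = any(vapply(names(f), function(cl) {
        e <- scenario$events[[cl]]
        any(vapply(clone_ancestry(scenario$clones, cl), function(a)
          scenario$events[[a]]$wgd, logical(1)))
      }, logical(1)) & unlist(f) > 0.5),
      segments = seg)
  }
  names(truth_regions) <- regions$region

  truth <- list(
    monosomies_trunk = mono_trunk,
    clone_arm_cn = lapply(cn, function(g) g[c("chrom", "arm", "mat", "pat")]),
    mutations = cbind(muts[c("id", "gene", "chrom", "pos", "class",
                             "driver", "clone")],
                      as.data.frame(mult)),
    regions = truth_regions,
    scenario = scenario)

  structure(list(snps = do.call(rbind, snp_out),
                 variants = do.call(rbind, var_out),
                 truth = truth, seed = seed, genome = genome,
                 scenario = scenario),
            class = "sim_dataset")
}

# ancestors of a clone, including itself, up to the trunk
clone_ancestry <- function(clones, clone) {
  out <- clone
  repeat {
    p <- clones$parent[match(out[length(out)], clones$clone)]
    if (is.na(p)) return(out)
    out <- c(out, p)
  }
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Simulated multiregion dataset\n")
  cat("  regions:  ", paste(x$scenario$regions$region, collapse = ", "), "\n")
  cat("  SNP rows: ", nrow(x$snps), "\n")
  cat("  variants: ", length(unique(x$variants$id)), "distinct,",
      nrow(x$variants), "region rows\n")
  cat("  seed:     ", x$seed, "\n")
  invisible(x)
}
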