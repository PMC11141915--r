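## Simulation-study benchmarks
##
## Reusable recovery studies run against the simulator's generating truth.
## They drive both the package's validation suite and the reproduction
## script; sizes default to the study conditions used throughout
## (coverage 100x, purities 0.4-0.8, ~500 SNP sites per chromosome).

#' Allele-specific CN accuracy of a fit against simulation truth
#'
#' Length-weighted fraction of the genome where the fitted (major, minor)
#' pair equals the generating truth.
#'
#' @param fit `ascn_fit`
#' @param truth_region one element of a dataset's `truth$regions`
#' @return fraction in `[0, 1]`
#' @export
cn_accuracy <- function(fit, truth_region) {
  ts <- truth_region$segments
  correct <- 0; totlen <- 0
  for (i in seq_len(nrow(ts))) {
    s <- fit$segments[fit$segments$chrom == ts$chrom[i], , drop = FALSE]
    ov <- pmin(s$end, ts$end[i]) - pmax(s$start, ts$start[i])
    ov[ov < 0] <- 0
    ok <- s$major == ts$major[i] & s$minor == ts$minor[i]
    correct <- correct + sum(ov[ok]); totlen <- totlen + sum(ov)
  }
  correct / totlen
}

#' Driver zygosity and event-order recovery study
#'
#' Simulates paired classic/dedifferentiated patients across a purity grid,
#' runs the full inference chain (site stats, two-pass segmentation,
#' purity/ploidy fit, variant filtering, multiplicity, zygosity, event
#' ordering) and scores driver zygosity calls and before/after-WGD verdicts
#' against the generating truth: the TP53-like driver is hemizygous in the
#' classic sample, homozygous in the doubled sample; the PTEN-like driver is
#' homozygous in the doubled sample; both precede the WGD.
#'
#' @param n_patients number of simulated patients (default 50)
#' @param purities purity grid cycled over patients
#' @param coverage mean depth
#' @param seed master seed
#' @return list with `zygosity_accuracy`, `verdict_accuracy`, counts, and
#'   per-patient purity errors
#' @export
benchmark_timing <- function(n_patients = 50, purities = c(0.4, 0.6, 0.8),
                             coverage = 100, seed = 1) {
  genome <- default_genome()
  zyg_ok <- 0L; zyg_n <- 0L; ver_ok <- 0L; ver_n <- 0L
  purity_err <- numeric(0)
  for (i in seq_len(n_patients)) {
    p <- purities[(i - 1L) %% length(purities) + 1L]
    sc <- chrcc_scenario(purity = p, coverage = coverage)
    d <- simulate_scenario(sc, genome, seed = derive_seed(seed, paste0("pat", i)))
    fits <- lapply(c("R1", "R2"), function(rg)
      fit_ascn(d$snps[d$snps$region == rg, , drop = FALSE], genome = genome))
    names(fits) <- c("R1", "R2")
    purity_err <- c(purity_err,
                    abs(vapply(fits, `[[`, numeric(1), "purity") - p))
    ann <- lapply(c("R1", "R2"), function(rg)
      annotate_zygosity(
        filter_variants(d$variants[d$variants$region == rg, , drop = FALSE]),
        fits[[rg]]))
    names(ann) <- c("R1", "R2")
    expect_zyg <- list(
      c(driver = "TP53L", region = "R1", zyg = "hemizygous_loh"),
      c(driver = "TP53L", region = "R2", zyg = "homozygous"),
      c(driver = "PTENL", region = "R2", zyg = "homozygous"))
    for (e in expect_zyg) {
      v <- ann[[e[["region"]]]]
      row <- v[!is.na(v$driver) & v$driver == e[["driver"]], , drop = FALSE]
      zyg_n <- zyg_n + 1L
      if (nrow(row) == 1 && row$zygosity == e[["zyg"]]) zyg_ok <- zyg_ok + 1L
    }
    wgd <- vapply(fits, function(f) f$wgd$wgd, logical(1))
    ord <- order_events(ann, wgd)
    for (g in c("TP53L", "PTENL")) {
      ver_n <- ver_n + 1L
      v <- ord$verdict[!is.na(ord$gene) & ord$gene == g]
      if (length(v) == 1 && v == "mutation_before_duplication")
        ver_ok <- ver_ok + 1L
    }
  }
  list(zygosity_accuracy = zyg_ok / zyg_n, zygosity_n = zyg_n,
       verdict_accuracy = ver_ok / ver_n, verdict_n = ver_n,
       purity_err = purity_err)
}

#' Purity, ploidy, copy-number and WGD recovery study
#'
#' @param n_seeds simulated patients per purity (default 10)
#' @param purities purity grid (default 0.4, 0.6, 0.8)
#' @param coverage mean depth
#' @param seed master seed
#' @return data.frame, one row per (seed, purity, genotype in
#'   classic/dediff): `purity`, `purity_est`, `purity_err`, `ploidy_est`,
#'   `ploidy_true`, `cn_acc`, `wgd_est`, `wgd_true`
#' @export
benchmark_ascn <- function(n_seeds = 10, purities = c(0.4, 0.6, 0.8),
                           coverage = 100, seed = 1) {
  genome <- default_genome()
  rows <- list()
  for (s in seq_len(n_seeds)) {
    for (p in purities) {
      sc <- chrcc_scenario(purity = p, coverage = coverage)
      d <- simulate_scenario(sc, genome,
                             seed = derive_seed(seed, paste0("ascn", s, "_", p)))
      for (rg in c("R1", "R2")) {
        fit <- fit_ascn(d$snps[d$snps$region == rg, , drop = FALSE],
                        genome = genome)
        tr <- d$truth$regions[[rg]]
        rows[[length(rows) + 1L]] <- data.frame(
          purity = p, genotype = if (rg == "R1") "classic" else "dediff",
          purity_est = fit$purity, purity_err = abs(fit$purity - p),
          ploidy_est = fit$ploidy, ploidy_true = tr$ploidy,
          cn_acc = cn_accuracy(fit, tr),
          wgd_est = fit$wgd$wgd, wgd_true = tr$wgd,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Segmentation false-split and localization study
#'
#' Null runs: flat bivariate noise (500 sites, sd 0.05) — any split is a
#' false positive. Step runs: a single logR step of -1 at site 250 — the
#' detected breakpoint should sit within a few sites of the change.
#'
#' @param n_null,n_step run counts
#' @param critical split critical value (the fine-pass default)
#' @param seed master seed
#' @return list with `false_split_rate`, `step_detected` (fraction with
#'   exactly one breakpoint), `max_offset`, `offsets`
#' @export
benchmark_segmentation <- function(n_null = 100, n_step = 50, critical = 20,
                                   seed = 1) {
  splits <- with_seed(derive_seed(seed, "segnull"), {
    vapply(seq_len(n_null), function(r) {
      s <- data.frame(chrom = "1", pos = seq_len(500) * 10,
                      logr = stats::rnorm(500, 0, 0.05),
                      logor = stats::rnorm(500, 0, 0.05),
                      t_depth = 100L, n_depth = 100L, var_logor = 0.04)
      nrow(segment_genome(s, critical = critical)) - 1L
    }, integer(1))
  })
  step <- with_seed(derive_seed(seed, "segstep"), {
    vapply(seq_len(n_step), function(r) {
      s <- data.frame(chrom = "1", pos = seq_len(500) * 10,
                      logr = c(stats::rnorm(250, 0, 0.05),
                               stats::rnorm(250, -1, 0.05)),
                      logor = stats::rnorm(500, 0, 0.05),
                      t_depth = 100L, n_depth = 100L, var_logor = 0.04)
      segs <- segment_genome(s, critical = critical)
      if (nrow(segs) != 2) NA_integer_ else abs(segs$last_site[1] - 250L)
    }, integer(1))
  })
  list(false_split_rate = mean(splits > 0),
       step_detected = mean(!is.na(step)),
       max_offset = if (all(is.na(step))) NA_integer_ else max(step, na.rm = TRUE),
       offsets = step)
}

#' Multiregion phylogeny recovery study
#'
#' Four-region patients (two classic, one atypical, one dedifferentiated
#' region); the mutation-pattern containment tree is compared with the
#' generating clone topology by rooted Robinson-Foulds distance, and
#' branch-length conservation (sum of branch lengths = distinct filtered
#' mutations minus conflict-dropped ones) is checked exactly.
#'
#' @param n_seeds number of simulated patients
#' @param purity sample purity
#' @param seed master seed
#' @param min_branch branch-size eligibility threshold for the topology
#'   check (default 20 mutations on every true branch); branch rates are set
#'   to 30 so nearly all runs satisfy it
#' @return data.frame per run: `rf`, `eligible`, `conflicts`, `conserved`
#' @export
benchmark_phylo <- function(n_seeds = 10, purity = 0.7, seed = 1,
                            min_branch = 20) {
  genome <- default_genome(n_snps = 50)   # trees use only the variant table
  truth_clades <- list(c("R1", "R2", "R3", "R4"), c("R3", "R4"))
  rows <- list()
  for (s in seq_len(n_seeds)) {
    sc <- chrcc_scenario(purity = purity, layout = "quad",
                         rate_trunk = 30, rate_classic = 30,
                         rate_atyp = 30, rate_dediff = 30)
    d <- simulate_scenario(sc, genome, seed = derive_seed(seed, paste0("phy", s)))
    filt <- lapply(split(d$variants, d$variants$region), filter_variants)
    pats <- build_pattern_matrix(filt)
    conflicts <- nrow(check_compatibility(pats))
    tree <- build_tree(pats)
    n_mut <- length(unique(unlist(lapply(filt, function(v) v$id))))
    conserved <- sum(tree$nodes$length) ==
      n_mut - sum(tree$dropped$count)
    # eligibility: every true branch carries at least min_branch mutations
    branch_pats <- c("R1,R2,R3,R4", "R1", "R2", "R3,R4", "R4")
    counts <- pats$count[match(branch_pats, pats$pattern)]
    eligible <- conflicts == 0 && !anyNA(counts) && all(counts >= min_branch)
    rows[[length(rows) + 1L]] <- data.frame(
      rf = rf_rooted(tree, truth_clades), eligible = eligible,
      conflicts = conflicts, conserved = conserved)
  }
  do.call(rbind, rows)
}

#' Differential gene copy-number error study
#'
#' Null runs draw paired integer copy numbers from the same distribution for
#' every gene and record the flagged fraction; planted runs add one gene at
#' copy number 4 in every dedifferentiated sample versus 2 in every classic
#' sample and record its detection.
#'
#' @param n_runs runs per condition (default 20)
#' @param n_genes genes per run (default 1000)
#' @param n_pairs patient pairs (default 6)
#' @param seed master seed
#' @return list with `null_flagged_rate`, `planted_detection_rate`,
#'   per-run fractions
#' @export
benchmark_diffcn <- function(n_runs = 20, n_genes = 1000, n_pairs = 6,
                             seed = 1) {
  null_frac <- numeric(n_runs); hit <- logical(n_runs)
  for (r in seq_len(n_runs)) {
    draws <- with_seed(derive_seed(seed, paste0("dcn", r)), {
      list(cl = matrix(sample(1:3, n_genes * n_pairs, TRUE), n_genes, n_pairs),
           dd = matrix(sample(1:3, n_genes * n_pairs, TRUE), n_genes, n_pairs))
    })
    cl <- draws$cl; dd <- draws$dd
    rownames(cl) <- rownames(dd) <- paste0("g", seq_len(n_genes))
    res <- differential_gene_cn(dd, cl)
    null_frac[r] <- mean(res$significant)
    dd["g1", ] <- 4; cl["g1", ] <- 2
    res2 <- differential_gene_cn(dd, cl)
    hit[r] <- res2$significant[res2$gene == "g1"]
  }
  list(null_flagged_rate = mean(null_frac),
       planted_detection_rate = mean(hit),
       null_frac = null_frac)
}

#' Mutation-burden study under the default rates
#'
#' Simulates a cohort of paired patients and reports the median
#' nonsynonymous burden by subcategory and the paired t-test p-value. The
#' default cohort of 25 pairs pins the medians to within about one mutation.
#'
#' @param n_patients cohort size (default 25 pairs)
#' @param seed master seed
#' @return list with `median_classic`, `median_dediff`, `p_value`, burdens
#' @export
benchmark_tmb <- function(n_patients = 25, seed = 1) {
  genome <- default_genome(n_snps = 10)
  t_cl <- t_dd <- numeric(n_patients)
  for (k in seq_len(n_patients)) {
    sc <- chrcc_scenario()
    d <- simulate_scenario(sc, genome, seed = derive_seed(seed, paste0("tmb", k)))
    t_cl[k] <- tmb(filter_variants(d$variants[d$variants$region == "R1", ]))
    t_dd[k] <- tmb(filter_variants(d$variants[d$variants$region == "R2", ]))
  }
  list(median_classic = stats::median(t_cl),
       median_dediff = stats::median(t_dd),
       p_value = stats::t.test(t_dd, t_cl, paired = TRUE)$p.value,
       classic = t_cl, dediff = t_dd)
}
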