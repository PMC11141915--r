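## Configuration and the end-to-end report pipeline

#' Default run configuration
#'
#' Thresholds default to the conventions used throughout the package: somatic
#' VAF cutoff 0.15, WGD genome fraction 0.5, arm-call fraction 0.5, purity
#' exclusion 0.3, BH alpha 0.05, copy-number fold-change 2, segmentation
#' criticals 35 (coarse) / 20 (fine).
#'
#' @param ... overrides of the default fields
#' @return named list of class `run_config`
#' @export
run_config <- function(...) {
  cfg <- list(
    purity = 0.7, coverage = 100, layout = "pair", chr21 = "coin",
    seed = 1L, out = NULL,
    vaf_min = 0.15, wgd_fraction = 0.5, arm_fraction = 0.5,
    purity_exclude = 0.3, bh_alpha = 0.05, cn_fc = 2,
    critical_coarse = 35, critical_fine = 20, error_rate = 0)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field: ", unknown[1])
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$vaf_min >= 0, cfg$vaf_min <= 1,
            cfg$wgd_fraction > 0, cfg$wgd_fraction <= 1,
            cfg$arm_fraction > 0, cfg$arm_fraction <= 1,
            cfg$purity_exclude >= 0, cfg$purity_exclude <= 1,
            cfg$bh_alpha > 0, cfg$bh_alpha < 1,
            cfg$cn_fc >= 1,
            cfg$critical_coarse > 0, cfg$critical_fine > 0,
            cfg$purity > 0, cfg$purity <= 1, cfg$coverage > 0,
            cfg$error_rate >= 0, cfg$error_rate < 0.5)
  invisible(cfg)
}

#' Read a YAML run configuration
#' @param path YAML file with any subset of [run_config()] fields
#' @return `run_config`
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full simulate / fit / time / tree / score pipeline
#'
#' Simulates a multiregion patient (or consumes a supplied dataset), fits
#' allele-specific copy number per region, filters variants, computes burden,
#' orders driver events against WGD, builds the annotated driver phylogeny,
#' and writes a report bundle: `segments.seg` (SEG-like), `arm_calls.tsv`
#' (arm x sample call matrix), `timing.tsv`, `tree.nwk` (+ JSON sidecar) and
#' `summary.json`.
#'
#' @param config from [run_config()]
#' @param dataset optional pre-built `sim_dataset` (otherwise simulated from
#'   the config)
#' @return invisibly, the report bundle (list); files are written when
#'   `config$out` is set
#' @export
run_report <- function(config = run_config(), dataset = NULL) {
  validate_config(config)
  genome <- default_genome()
  if (is.null(dataset)) {
    scen <- chrcc_scenario(purity = config$purity, coverage = config$coverage,
                           layout = config$layout, chr21 = config$chr21)
    dataset <- simulate_scenario(scen, genome, seed = config$seed,
                                 error_rate = config$error_rate)
  }
  genome <- dataset$genome
  arms <- arm_table(genome)
  regions <- dataset$scenario$regions

  fits <- list(); seg_rows <- list(); armcalls <- list()
  for (i in seq_len(nrow(regions))) {
    rg <- regions$region[i]
    fit <- fit_ascn(dataset$snps[dataset$snps$region == rg, , drop = FALSE],
                    genome = genome,
                    critical_coarse = config$critical_coarse,
                    critical_fine = config$critical_fine,
                    low_purity_cutoff = config$purity_exclude)
    fits[[rg]] <- fit
    s <- fit$segments
    seg_rows[[rg]] <- data.frame(sample = rg, chrom = s$chrom,
                                 start = s$start, end = s$end,
                                 n_sites = s$n_sites,
                                 logr = round(s$mean_logr, 4),
                                 logor = round(s$mean_fold, 4),
                                 total = s$total, major = s$major,
                                 minor = s$minor, stringsAsFactors = FALSE)
    armcalls[[rg]] <- call_arms(s, arms)
  }
  excluded <- vapply(fits, `[[`, logical(1), "excluded")
  wgd_flags <- vapply(fits, function(f) f$wgd$wgd, logical(1))

  filt <- list(); burdens <- integer(0)
  for (rg in regions$region) {
    fv <- filter_variants(
      dataset$variants[dataset$variants$region == rg, , drop = FALSE],
      vaf_min = config$vaf_min)
    filt[[rg]] <- fv
    burdens[rg] <- tmb(fv)
  }
  usable <- regions$region[!excluded[regions$region]]
  annotated <- lapply(usable, function(rg) annotate_zygosity(filt[[rg]], fits[[rg]]))
  names(annotated) <- usable
  timing <- if (length(usable)) {
    order_events(annotated, wgd_flags[usable])
  } else NULL

  tree <- NULL
  if (length(usable) >= 2) {
    pats <- build_pattern_matrix(filt[usable])
    meta <- data.frame(sample = regions$region,
                       subcategory = regions$subcategory,
                       metastasis = regions$metastasis,
                       ploidy = round(vapply(fits, `[[`, numeric(1), "ploidy")[regions$region], 2),
                       stringsAsFactors = FALSE)
    tree <- build_tree(pats, metadata = meta[meta$sample %in% usable, ])
    events <- list()
    if (any(wgd_flags[usable])) events$WGD <- usable[wgd_flags[usable]]
    losses <- Reduce(intersect, lapply(usable, function(rg) {
      ac <- armcalls[[rg]]; ac$arm[ac$call == "loss"]
    }))
    if (length(losses)) {
      chroms_lost <- unique(sub("[pq]$", "", losses))
      for (cc in chroms_lost) {
        if (all(paste0(cc, c("p", "q")) %in% losses))
          events[[paste0("loss_chr", cc)]] <- usable
      }
    }
    if (length(events)) tree <- suppressWarnings(annotate_tree(tree, events))
  }

  med_by <- function(sub) {
    r <- regions$region[regions$subcategory == sub & !excluded[regions$region]]
    if (!length(r)) NA_real_ else stats::median(burdens[r])
  }
  summary <- list(
    schema_version = "1.0",
    seed = dataset$seed,
    samples = data.frame(
      sample = regions$region, subcategory = regions$subcategory,
      purity = vapply(fits, `[[`, numeric(1), "purity")[regions$region],
      ploidy = round(vapply(fits, `[[`, numeric(1), "ploidy")[regions$region], 3),
      wgd = wgd_flags[regions$region],
      tmb = unname(burdens[regions$region]),
      excluded = excluded[regions$region],
      low_confidence = vapply(fits, `[[`, logical(1), "low_confidence")[regions$region],
      stringsAsFactors = FALSE),
    exclusions = regions$region[excluded[regions$region]],
    tmb_median = list(classic = med_by("classic"), atyp = med_by("atyp"),
                      dediff = med_by("dediff")),
    timing = if (!is.null(timing)) timing[c("gene", "chrom", "pos", "verdict",
                                            "conflict")] else NULL)
  validate_summary(summary)

  bundle <- list(config = config, dataset = dataset, fits = fits,
                 segments = do.call(rbind, seg_rows),
                 arm_calls = armcalls, timing = timing, tree = tree,
                 summary = summary)

  if (!is.null(config$out)) {
    dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
    write_tsv(bundle$segments, file.path(config$out, "segments.seg"))
    armmat <- data.frame(arm = arms$arm, stringsAsFactors = FALSE)
    for (rg in regions$region) armmat[[rg]] <- armcalls[[rg]]$call
    write_tsv(armmat, file.path(config$out, "arm_calls.tsv"))
    if (!is.null(timing))
      write_tsv(timing, file.path(config$out, "timing.tsv"))
    if (!is.null(tree)) write_tree(tree, file.path(config$out, "tree.nwk"))
    jsonlite::write_json(summary, file.path(config$out, "summary.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(bundle)
}

# minimal structural validation of the report summary before write
validate_summary <- function(s) {
  stopifnot(identical(s$schema_version, "1.0"),
            is.data.frame(s$samples),
            all(c("sample", "purity", "ploidy", "wgd", "tmb", "excluded") %in%
                  names(s$samples)))
  invisible(s)
}
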