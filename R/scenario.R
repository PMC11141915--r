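## Clonal-evolution scenarios
##
## A scenario is the generating truth of a simulated multiregion ChRCC patient:
## a rooted clone tree whose edges carry ordered events (monosomies, driver
## mutations, whole-genome doubling, arm gains, passenger mutation rates) and a
## set of sequenced regions, each dominated by one clone (or a clone mixture)
## at a given purity and coverage.

#' Construct an evolution scenario
#'
#' @param clones data.frame with columns `clone`, `parent` (`NA` for the trunk
#'   clone, whose parent is the germline).
#' @param events named list (one entry per clone) of lists with elements
#'   `monosomies` (character vector of chromosomes losing one copy),
#'   `wgd` (logical), `wgd_time` (fraction of the branch at which the doubling
#'   occurs), `drivers` (data.frame `gene`, `timing` in `pre_wgd`/`post_wgd`),
#'   `gains` (data.frame `arm`, `copies`; extra major-allele copies applied
#'   after any WGD on the edge), `rate_nonsyn`, `rate_syn` (Poisson means of
#'   passenger mutation counts on the edge).
#' @param regions data.frame with columns `region`, `clone`, `purity`,
#'   `coverage`, `metastasis`, `subcategory` (one of classic/atyp/dediff).
#' @param fractions optional named list mapping region id to a named
#'   clone-fraction vector summing to 1; defaults to a pure dominant clone.
#' @param chr21 "coin" (lost with probability `p_chr21` per simulation),
#'   "yes", or "no" — whether the trunk monosomy set includes chromosome 21.
#' @param p_chr21 probability of chromosome 21 loss under `chr21 = "coin"`.
#' @return object of class `evolution_scenario`
#' @export
evolution_scenario <- function(clones, events, regions, fractions = NULL,
                               chr21 = c("coin", "yes", "no"), p_chr21 = 0.5) {
  chr21 <- match.arg(chr21)
  stopifnot(is.data.frame(clones), all(c("clone", "parent") %in% names(clones)))
  if (anyDuplicated(clones$clone)) stop("duplicated clone ids")
  ok_parent <- is.na(clones$parent) | clones$parent %in% clones$clone
  if (!all(ok_parent)) stop("clone with undefined parent: ",
                            clones$clone[which(!ok_parent)[1]])
  if (sum(is.na(clones$parent)) != 1L) stop("exactly one trunk clone required")
  miss <- setdiff(clones$clone, names(events))
  if (length(miss)) stop("missing events for clone: ", miss[1])
  stopifnot(is.data.frame(regions),
            all(c("region", "clone", "purity", "coverage",
                  "metastasis", "subcategory") %in% names(regions)))
  if (any(regions$purity <= 0 | regions$purity > 1))
    stop("region purity must lie in (0, 1]")
  bad <- !regions$clone %in% clones$clone
  if (any(bad)) stop("region references undefined clone: ",
                     regions$clone[which(bad)[1]])
  if (!all(regions$subcategory %in% c("classic", "atyp", "dediff")))
    stop("subcategory must be classic, atyp or dediff")
  if (is.null(fractions)) {
    fractions <- lapply(seq_len(nrow(regions)), function(i) {
      stats::setNames(1, regions$clone[i])
    })
    names(fractions) <- regions$region
  }
  for (r in regions$region) {
    f <- fractions[[r]]
    if (is.null(f) || abs(sum(f) - 1) > 1e-8)
      stop("clone fractions for region ", r, " must sum to 1")
    if (!all(names(f) %in% clones$clone))
      stop("region ", r, " references undefined clone in fractions")
  }
  events <- lapply(events, function(e) {
    list(monosomies = e$monosomies %||% character(0),
         wgd        = isTRUE(e$wgd),
         wgd_time   = e$wgd_time %||% 0.5,
         drivers    = e$drivers %||%
           data.frame(gene = character(0), timing = character(0)),
         gains      = e$gains %||%
           data.frame(arm = character(0), copies = integer(0)),
         rate_nonsyn = e$rate_nonsyn %||% 0,
         rate_syn    = e$rate_syn %||% 0)
  })
  structure(list(clones = clones, events = events, regions = regions,
                 fractions = fractions, chr21 = chr21, p_chr21 = p_chr21),
            class = "evolution_scenario")
}

#' Default ChRCC-like scenario
#'
#' Encodes the canonical dedifferentiation trajectory: a hypodiploid trunk
#' clone with monosomies of chromosomes 1, 2, 6, 10, 13, 17 (and 21 with
#' probability 1/2) and a hemizygous TP53-like driver on the remaining copy of
#' chromosome 17; a classic daughter clone; and a dedifferentiated clone that
#' acquires a PTEN-like driver, then whole-genome doubling, then an extra copy
#' of chromosome arm 1q. Passenger rates are set so nonsynonymous burdens
#' average 28 (classic) and 40 (dedifferentiated) mutations per sample.
#'
#' @param purity tumor purity, recycled over regions
#' @param coverage mean sequencing depth
#' @param layout `"pair"` (one classic + one dedifferentiated region) or
#'   `"quad"` (two classic regions, one atypical, one dedifferentiated — the
#'   multiregion layout used for phylogeny recovery).
#' @param rate_trunk,rate_classic,rate_atyp,rate_dediff nonsynonymous
#'   passenger Poisson means per branch; with the driver mutations the
#'   defaults give expected burdens of 28 (classic: 23 trunk + TP53-like +
#'   4 private) and 40 (dedifferentiated: 23 + 1 + 15 + PTEN-like)
#'   nonsynonymous mutations per sample
#' @param syn_frac synonymous rate as a fraction of the nonsynonymous rate
#' @param chr21 see [evolution_scenario()]
#' @return `evolution_scenario`
#' @export
chrcc_scenario <- function(purity = 0.7, coverage = 100,
                           layout = c("pair", "quad"),
                           rate_trunk = 23, rate_classic = 4,
                           rate_atyp = 30, rate_dediff = 15,
                           syn_frac = 0.4, chr21 = "coin") {
  layout <- match.arg(layout)
  mono <- c("1", "2", "6", "10", "13", "17")   # chr21 handled by the coin
  trunk <- list(
    monosomies = mono,
    drivers = data.frame(gene = "TP53L", timing = "pre_wgd",
                         stringsAsFactors = FALSE),
    rate_nonsyn = rate_trunk, rate_syn = syn_frac * rate_trunk)
  dediff <- list(
    wgd = TRUE, wgd_time = 0.5,
    drivers = data.frame(gene = "PTENL", timing = "pre_wgd",
                         stringsAsFactors = FALSE),
    gains = data.frame(arm = "1q", copies = 1L, stringsAsFactors = FALSE),
    rate_nonsyn = rate_dediff, rate_syn = syn_frac * rate_dediff)
  if (layout == "pair") {
    clones <- data.frame(clone = c("C", "C1", "D"),
                         parent = c(NA, "C", "C"), stringsAsFactors = FALSE)
    events <- list(
      C  = trunk,
      C1 = list(rate_nonsyn = rate_classic, rate_syn = syn_frac * rate_classic),
      D  = dediff)
    regions <- data.frame(
      region = c("R1", "R2"), clone = c("C1", "D"),
      purity = rep_len(purity, 2), coverage = coverage,
      metastasis = c(FALSE, TRUE),
      subcategory = c("classic", "dediff"), stringsAsFactors = FALSE)
  } else {
    clones <- data.frame(clone = c("C", "C1", "C2", "A", "D"),
                         parent = c(NA, "C", "C", "C", "A"),
                         stringsAsFactors = FALSE)
    events <- list(
      C  = trunk,
      C1 = list(rate_nonsyn = rate_atyp, rate_syn = syn_frac * rate_atyp),
      C2 = list(rate_nonsyn = rate_atyp, rate_syn = syn_frac * rate_atyp),
      A  = list(rate_nonsyn = rate_atyp, rate_syn = syn_frac * rate_atyp),
      D  = dediff)
    regions <- data.frame(
      region = c("R1", "R2", "R3", "R4"), clone = c("C1", "C2", "A", "D"),
      purity = rep_len(purity, 4), coverage = coverage,
      metastasis = c(FALSE, FALSE, FALSE, TRUE),
      subcategory = c("classic", "classic", "atyp", "dediff"),
      stringsAsFactors = FALSE)
  }
  evolution_scenario(clones, events, regions, chr21 = chr21)
}

## clone-tree helpers --------------------------------------------------------

# clones ordered so parents precede children
clone_order <- function(clones) {
  ord <- character(0)
  left <- clones$clone
  while (length(left)) {
    ready <- left[is.na(clones$parent[match(left, clones$clone)]) |
                    clones$parent[match(left, clones$clone)] %in% ord]
    if (!length(ready)) stop("clone tree contains a cycle")
    ord <- c(ord, ready)
    left <- setdiff(left, ready)
  }
  ord
}

# all descendants of a clone (including itself)
clone_descendants <- function(clones, clone) {
  out <- clone
  repeat {
    kids <- clones$clone[clones$parent %in% out & !clones$clone %in% out]
    if (!length(kids)) return(out)
    out <- c(out, kids)
  }
}

#' Per-clone arm-level allele-specific copy numbers
#'
#' Walks the clone tree applying each edge's events in order: monosomies
#' (loss of the paternal copy by convention), whole-genome doubling (doubling
#' both parental copies of every arm), then arm gains (extra copies of the
#' current major allele).
#'
#' @param scenario `evolution_scenario`
#' @param genome `genome_model`
#' @param monosomies_trunk optional resolved trunk monosomy set (overrides the
#'   trunk event list; used once the chromosome-21 coin has been tossed)
#' @return named list per clone of data.frames `chrom`, `arm`, `mat`, `pat`
#' @export
clone_arm_cn <- function(scenario, genome, monosomies_trunk = NULL) {
  arms <- arm_table(genome)
  base <- data.frame(chrom = arms$chrom, arm = arms$arm,
                     mat = 1L, pat = 1L, stringsAsFactors = FALSE)
  out <- list()
  for (cl in clone_order(scenario$clones)) {
    parent <- scenario$clones$parent[match(cl, scenario$clones$clone)]
    g <- if (is.na(parent)) base else out[[parent]]
    e <- scenario$events[[cl]]
    mono <- e$monosomies
    if (is.na(parent) && !is.null(monosomies_trunk)) mono <- monosomies_trunk
    if (length(mono)) {
      hit <- g$chrom %in% mono
      g$pat[hit] <- pmax(g$pat[hit] - 1L, 0L)
    }
    if (e$wgd) { g$mat <- 2L * g$mat; g$pat <- 2L * g$pat }
    if (nrow(e$gains)) {
      for (i in seq_len(nrow(e$gains))) {
        j <- match(e$gains$arm[i], g$arm)
        if (is.na(j)) stop("gain on unknown arm: ", e$gains$arm[i])
        if (g$mat[j] >= g$pat[j]) g$mat[j] <- g$mat[j] + e$gains$copies[i]
        else g$pat[j] <- g$pat[j] + e$gains$copies[i]
      }
    }
    out[[cl]] <- g
  }
  out
}
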