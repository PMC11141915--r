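# Shared fixtures: all synthetic data is generated in code at test time.

# simulate one patient under the default study conditions
sim_patient <- function(purity = 0.7, seed = 1, layout = "pair",
                        coverage = 100, chr21 = "coin", n_snps = 500) {
  g <- default_genome(n_snps = n_snps)
  sc <- chrcc_scenario(purity = purity, coverage = coverage, layout = layout,
                       chr21 = chr21)
  list(genome = g, scenario = sc,
       dataset = simulate_scenario(sc, g, seed = seed))
}

fit_region <- function(pat, region, ...) {
  fit_ascn(pat$dataset$snps[pat$dataset$snps$region == region, , drop = FALSE],
           genome = pat$genome, ...)
}

# noise-free site statistics generated from a known allele-specific profile:
# each chromosome one state; logR/logOR set to their exact expected values
noise_free_sites <- function(states, purity, n_per_chrom = 40) {
  ploidy <- mean(states$total)
  do.call(rbind, lapply(seq_len(nrow(states)), function(i) {
    b <- expected_baf(purity, states$major[i], states$minor[i])
    mu <- abs(log(b / (1 - b)))
    data.frame(chrom = as.character(i),
               pos = seq_len(n_per_chrom) * 10,
               logr = expected_logr(purity, states$total[i], ploidy),
               logor = mu,
               t_depth = 1e6, n_depth = 1e6, var_logor = 1e-10)
  }))
}
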