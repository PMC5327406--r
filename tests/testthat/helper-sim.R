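# Shared simulation configurations for the recovery experiments. The
# "study conditions" configuration (6 ingroup species, 20-gene locus, 5-kb
# genes, one forced disruption on the galliform stem, rho = 3) is used by
# the acceptance experiments; the small configuration keeps module tests
# fast.

study_config <- function(seed, rho = 3, p_loss = 0.5) {
  sim_config(
    locus = default_locus(n_genes = 20, length_nt = 5001),
    flank_genes = 4,
    disruption_branches = "galliformes",
    inversion_interval = c(5, 16),
    p_loss = p_loss, p_salvage = 1, rho = rho,
    coverage = 5, err_rate = 0.005,
    seed = seed
  )
}

small_config <- function(seed, n_genes = 12, length_nt = 900, rho = 3,
                         p_loss = 0.5, p_salvage = 1, coverage = 3,
                         interval = c(4, 9),
                         branches = "galliformes") {
  sim_config(
    locus = default_locus(n_genes = n_genes, length_nt = length_nt),
    flank_genes = 3,
    disruption_branches = branches,
    inversion_interval = interval,
    p_loss = p_loss, p_salvage = p_salvage, rho = rho,
    coverage = coverage, seed = seed
  )
}

# rates-only null configuration used for type-I-error calibration: a forced
# disruption whose salvaged genes evolve at the base rate (rho = 1)
null_config <- function(seed) {
  sim_config(
    locus = default_locus(n_genes = 12, length_nt = 300),
    flank_genes = 3,
    disruption_branches = "galliformes",
    inversion_interval = c(4, 9),
    p_loss = 0, p_salvage = 1, rho = 1,
    coverage = 1, seed = seed
  )
}
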