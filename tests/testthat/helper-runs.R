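# Heavy shared runs for the end-to-end checks (built once, cached).

# Scaled-down replication of the full study conditions: 200 kb random
# pseudo-diploid (1% divergence), fragments 7-13 kb, p = 0.15, 150 bp
# pairs at 1% error, coverage 50, 4 fragments/barcode; deconvolution at
# k = 20, d = 1/8, w = 50, min_shared = 3, repeat_factor = 2.
t2_run <- function() fixture("t2_run", function() {
  g <- random_genome(200000, seed = 21)
  dip <- make_pseudo_diploid(g, divergence = 0.01, seed = 22)
  sp <- sim_params(frag_len_min = 7000, frag_len_max = 13000, p = 0.15,
                   read_len = 150, error_rate = 0.01, read_coverage = 50,
                   fragments_per_barcode = 4)
  sim <- simulate_linked_reads(dip, sp, seed = 23)
  idx <- prune_repeats(build_index(sim$pairs, index_params()))
  dec <- deconvolve_all(sim$pairs, idx, seed = 7)
  list(sim = sim, idx = idx, dec = dec)
})

# Planted-partition benchmark: haploid 400 kb, fragments 2-3 kb, p = 0.75,
# coverage 50, error-free. This geometry sits in the method's intended
# operating regime (same-fragment / far-fragment expected shared-barcode
# ratio ~ 35) while keeping ~6 pairs per fragment.
planted_sim <- function() fixture("planted_sim", function() {
  g <- random_genome(400000, seed = 31)
  sp <- sim_params(frag_len_min = 2000, frag_len_max = 3000, p = 0.75,
                   error_rate = 0, read_coverage = 50)
  sim <- simulate_linked_reads(g, sp, seed = 32)
  idx <- prune_repeats(build_index(sim$pairs, index_params()))
  list(sim = sim, idx = idx)
})

# Per-barcode cloud composition: number of fragments, whether any two
# fragments of the cloud overlap when projected onto the haploid genome
# (such clouds are not separable from overlap information), and the
# smallest per-fragment pair count.
cloud_fragment_info <- function(sim) {
  fr <- data.table::as.data.table(sim$fragments)
  fr[, base_seq := sub("_hap2$", "", sequence)]
  data.table::setkey(fr, barcode)
  fr[, {
    n <- .N
    bad <- FALSE
    if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (base_seq[i] == base_seq[j] &&
            start[i] < end[j] && start[j] < end[i]) bad <- TRUE
    .(nfrag = n, collided = bad, minpairs = min(n_pairs))
  }, by = barcode]
}
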