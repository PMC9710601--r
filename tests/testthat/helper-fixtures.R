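# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Small error-free haploid simulation, full indexing (d = 1).
# ~8 kb genome, 2-3 kb fragments, coverage 20 -> ~500 pairs.
tiny_exact_sim <- function() fixture("tiny_exact", function() {
  g <- random_genome(8000, seed = 101)
  sp <- sim_params(frag_len_min = 2000, frag_len_max = 3000,
                   error_rate = 0, read_coverage = 20)
  sim <- simulate_linked_reads(g, sp, seed = 102)
  idx <- build_index(sim$pairs, index_params(d = 1))
  list(sim = sim, idx = idx)
})

# Brute-force per-pair canonical k-mer sets (all k-mers, k = 20).
bf_kmer_sets <- function(lp) {
  km <- function(s) {
    n <- nchar(s)
    if (n < 20L) return(character(0))
    canonical_kmer(substring(s, 1:(n - 19L), 20:n))
  }
  lapply(seq_len(nrow(lp$pairs)), function(i) {
    ks <- c(km(lp$pairs$seq1[i]),
            if (!is.null(lp$pairs$seq2)) km(lp$pairs$seq2[i]))
    unique(ks[!is.na(ks)])
  })
}

# Genomic interval of each pair (haploid single-sequence sims): derived
# from the error-free read sequences by exact matching is fragile; instead
# reconstruct from the simulator internals via truth + exact substring
# search within the fragment.
pair_intervals <- function(sim, genome) {
  tr <- sim$truth
  chrom <- genome[tr$sequence]
  frag <- substring(chrom, tr$start + 1L, tr$end)
  off <- vapply(seq_len(nrow(tr)), function(i) {
    as.integer(regexpr(sim$pairs$pairs$seq1[i], frag[i], fixed = TRUE))
  }, integer(1))
  data.frame(pair = seq_len(nrow(tr)),
             start = tr$start + off,                       # 1-based
             end = tr$start + off + 2L * sim$params$read_len - 1L,
             sequence = tr$sequence)
}

# toy taxonomy: root -> g1 -> (s1, s2); root -> g2 -> s3; s1 -> st1
toy_tax <- function() fixture("toy_tax", function() {
  taxonomy(data.frame(
    taxon = c("root", "g1", "s1", "s2", "g2", "s3", "st1"),
    parent = c(NA, "root", "g1", "g1", "root", "g2", "s1"),
    rank = c("root", "genus", "species", "species", "genus", "species",
             "strain")))
})
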