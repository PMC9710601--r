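# Sparse k-mer indexing: rank selection, window escalation, index CSR
# structure, repeat de-indexing.

test_that("kmer_rank_fraction is the lexicographic base-4 fraction", {
  expect_equal(kmer_rank_fraction(strrep("A", 20)), 0)
  # enumerate all 16 2-mers: CG sits at position 6 (0-based) of 16
  mers <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T")),
                1, function(r) paste0(r[2], r[1]))
  expect_equal(sort(kmer_rank_fraction(mers)), (0:15) / 16)
  expect_equal(kmer_rank_fraction("CG"), 0.375)
  # every k-mer starting with A ranks below 0.25
  set.seed(1)
  amers <- replicate(20, paste0("A", paste(sample(c("A", "C", "G", "T"), 7,
                                                  replace = TRUE),
                                           collapse = "")))
  expect_true(all(kmer_rank_fraction(amers) < 0.25))
  expect_true(is.na(kmer_rank_fraction("ACGTN")))
})

test_that("sparse selection obeys rank fractions and escalation levels", {
  ip <- index_params(k = 20, d = 1 / 8, w = 50)
  # minimum-rank k-mers: everything selected at level 1
  spA <- sparse_positions(strrep("A", 120), ip)
  expect_equal(nrow(spA), 101L)
  expect_true(all(spA$level == 1L))
  # d = 1: every N-free k-mer selected
  set.seed(2)
  s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
  expect_equal(nrow(sparse_positions(s, index_params(d = 1))), 181L)
  # sequences shorter than k give an empty result
  expect_equal(nrow(sparse_positions("ACGT", ip)), 0L)
  # a G-homopolymer canonicalizes to C-run (rank 1/3): escalates to level 3
  spG <- sparse_positions(strrep("G", 60), ip)
  expect_true(all(spG$level == 3L))
  expect_gt(nrow(spG), 0L)
  # N-containing k-mers are never selected
  spN <- sparse_positions(paste0(strrep("A", 30), "N", strrep("A", 30)), ip)
  expect_true(all(spN$pos <= 11L | spN$pos >= 32L))
})

test_that("every w-base stretch holds a selected k-mer (brute force)", {
  ip <- index_params(k = 20, d = 1 / 8, w = 30)
  for (seed in 1:5) {
    set.seed(seed)
    s <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
               collapse = "")
    sp <- sparse_positions(s, ip)
    for (st in 1:(150 - 30 + 1)) {
      starts_in <- st:(st + 30 - 20)
      expect_true(any(sp$pos %in% starts_in),
                  info = sprintf("seed %d stretch %d", seed, st))
    }
  }
})

test_that("selection is orientation-invariant", {
  ip <- index_params(k = 20, d = 1 / 8, w = 30)
  for (seed in 1:8) {
    set.seed(seed)
    s <- paste(sample(c("A", "C", "G", "T"), 163, replace = TRUE),
               collapse = "")
    expect_equal(sort(sparse_positions(s, ip)$kmer),
                 sort(sparse_positions(revcomp(s), ip)$kmer))
  }
})

test_that("build_index pools mates per pair and is order/chunk invariant", {
  set.seed(3)
  s1 <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE), collapse = "")
  s2 <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE), collapse = "")
  pairs <- data.frame(pair_id = c("a", "b"), barcode = "X",
                      seq1 = s1, qual1 = strrep("I", 150),
                      seq2 = s2, qual2 = strrep("I", 150))
  ip <- index_params(d = 1)
  idx <- build_index(pairs, ip)
  # identical pairs: identical k-mer sets, every occurrence list has both
  expect_equal(indexed_kmers(idx, "a"), indexed_kmers(idx, "b"))
  expect_true(all(idx$counts == 2L))
  expect_equal(idx$mean_occurrence, 2)
  # pooled set = union of both mates' selections
  union_km <- sort(unique(c(sparse_positions(s1, ip)$kmer,
                            sparse_positions(s2, ip)$kmer)))
  expect_equal(sort(indexed_kmers(idx, "a")), union_km)
  # single pair: mean occurrence 1
  idx1 <- build_index(pairs[1, ], ip)
  expect_equal(idx1$mean_occurrence, 1)
  # chunking must not change the result
  idx_c <- build_index(pairs, ip, chunk_reads = 1L)
  expect_equal(idx_c[names(idx_c) != "params"], idx[names(idx) != "params"])
  # CSR consistency: pair -> kmer and kmer -> pair agree
  for (i in 1:2) {
    kids <- idx$pair_kids[idx$pair_ptr[i]:(idx$pair_ptr[i + 1] - 1)]
    for (kk in kids) {
      occ <- idx$occ_pairs[idx$occ_ptr[kk]:(idx$occ_ptr[kk + 1] - 1)]
      expect_true(i %in% occ)
    }
  }
})

test_that("d = 1 index contains every k-mer of a tiled region", {
  set.seed(4)
  ref <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
               collapse = "")
  # 10 single-end reads tiling the sequence at 50 bp steps
  starts <- seq(1, 451, by = 50)
  pairs <- data.frame(pair_id = paste0("t", seq_along(starts)),
                      barcode = "X",
                      seq1 = substring(ref, starts, starts + 49),
                      qual1 = strrep("I", 50))
  idx <- build_index(pairs, index_params(d = 1, w = 30))
  have <- unlist(lapply(seq_along(starts), function(i) indexed_kmers(idx, i)))
  want <- canonical_kmer(substring(ref, 1:(500 - 19), 20:500))
  # every 20-mer fully inside one read must be indexed
  inside <- unlist(lapply(starts, function(s) s:(s + 50 - 20)))
  expect_true(all(want[inside] %in% have))
})

test_that("repeat de-indexing arithmetic matches hand oracles", {
  # 9 k-mers occurring once + 1 occurring 11 times
  e <- data.table::data.table(
    pair = c(1:9, 1:11),
    canon = c(as.numeric(1:9), rep(100, 11)))
  data.table::setorder(e, canon, pair)
  cnt <- e[, .N, by = canon]
  idx <- linkdecon:::.build_csr(index_params(), paste0("p", 1:11), 11L,
                                e, cnt$canon, cnt$N,
                                mean_occurrence = mean(cnt$N),
                                occ_mean = sum(cnt$N^2) / sum(cnt$N),
                                pruned = numeric(0))
  expect_equal(idx$mean_occurrence, 2)            # (9 + 11) / 10
  # per-kmer mean: threshold 4, the 11x k-mer goes, the others stay
  pk <- prune_repeats(idx, average = "kmer")
  expect_equal(pk$pruned, 100)
  expect_equal(length(pk$kmer), 9L)
  expect_equal(pk$mean_occurrence, 2)             # retained, not recomputed
  # occurrence-weighted mean: (9 + 121)/20 = 6.5, threshold 13 -> nothing
  expect_equal(idx$occ_mean, 6.5)
  expect_equal(length(prune_repeats(idx, average = "occurrence")$pruned), 0L)
  # huge factor: unchanged either way
  expect_equal(length(prune_repeats(idx, repeat_factor = 1e9)$pruned), 0L)
  # all-singleton index: nothing pruned (count == mean < 2 * mean)
  e1 <- data.table::data.table(pair = 1:5, canon = as.numeric(1:5))
  c1 <- e1[, .N, by = canon]
  i1 <- linkdecon:::.build_csr(index_params(), paste0("p", 1:5), 5L, e1,
                               c1$canon, c1$N, 1, 1, numeric(0))
  expect_equal(length(prune_repeats(i1, average = "kmer")$pruned), 0L)
})

test_that("pruning removes k-mers from occurrences and per-pair sets", {
  tx <- tiny_exact_sim()
  idx <- tx$idx
  p <- prune_repeats(idx, repeat_factor = 1.2, average = "occurrence")
  expect_gt(length(p$pruned), 0L)
  expect_true(!any(p$pruned %in% p$kmer))
  # per-pair sets no longer reference pruned k-mers
  km1 <- indexed_kmers(p, 1L)
  pruned_str <- linkdecon:::.decode_kmer(p$pruned, 20L)
  expect_false(any(km1 %in% pruned_str))
  # counts conserved for survivors
  keep <- match(p$kmer, idx$kmer)
  expect_equal(p$counts, idx$counts[keep])
})

test_that("error-free reads overlapping by >= w share an indexed k-mer", {
  tx <- tiny_exact_sim()
  # recompute with the default sparse density (d = 1/8)
  idx <- build_index(tx$sim$pairs, index_params(d = 1 / 8, w = 50))
  g <- random_genome(8000, seed = 101)
  iv <- pair_intervals(tx$sim, g)
  # per-read intervals: mate 1 then mate 2 (contiguous 150 bp each)
  rd <- data.frame(pair = rep(iv$pair, 2),
                   start = c(iv$start, iv$start + 150L),
                   end = c(iv$start + 149L, iv$end))
  rd <- rd[iv$start[rd$pair] > 0, ]
  # sample read pairs whose *reads* share an exact overlap >= w
  set.seed(9)
  found <- 0L
  for (a in sample(seq_len(nrow(rd)), 60)) {
    ov <- which(pmin(rd$end, rd$end[a]) - pmax(rd$start, rd$start[a]) + 1 >= 50 &
                  rd$pair != rd$pair[a])
    for (b in head(ov, 3)) {
      shared <- intersect(indexed_kmers(idx, rd$pair[a]),
                          indexed_kmers(idx, rd$pair[b]))
      expect_gt(length(shared), 0)
      found <- found + 1L
    }
  }
  expect_gt(found, 50L)  # the check actually exercised many read pairs
})
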