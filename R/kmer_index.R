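# Sparse k-mer occurrence index with lexicographic-fraction selection,
# per-window escalation, and repeat de-indexing.
#
# k-mers are encoded as base-4 integers held in doubles (k <= 26 keeps
# 4^k < 2^53, so all arithmetic is exact). The canonical form is the
# lexicographic minimum of a k-mer and its reverse complement, which in
# code space is simply the smaller of the two codes.

#' Indexing parameters
#'
#' @param k k-mer length (default 20).
#' @param d base indexed fraction: a k-mer is indexed at level `m` when its
#'   lexicographic rank fraction is below `m * d` (default 1/8).
#' @param w window length in bases: every stretch of `w` bases of a read is
#'   guaranteed to contain an indexed k-mer, by escalating the indexed
#'   fraction inside windows that would otherwise be empty (default 50).
#' @param repeat_factor k-mers occurring at least `repeat_factor` times the
#'   mean occurrence count are de-indexed by [prune_repeats()] (default 2).
#' @param min_shared number of shared indexed k-mers at which two read pairs
#'   are flagged as similar (default 3).
#' @return a list of class `index_params`.
#' @export
index_params <- function(k = 20L, d = 1 / 8, w = 50L, repeat_factor = 2,
                         min_shared = 3L) {
  .check(k >= 1 && k <= 26, "k must be in [1, 26]")
  .check(d > 0 && d <= 1, "d must be in (0, 1]")
  .check(w >= k, "window w must be >= k")
  .check(repeat_factor > 1, "repeat_factor must be > 1")
  .check(min_shared >= 1, "min_shared must be >= 1")
  structure(list(k = as.integer(k), d = d, w = as.integer(w),
                 repeat_factor = repeat_factor,
                 min_shared = as.integer(min_shared)),
            class = "index_params")
}

# Dense canonical k-mer codes over `seqs` glued with an "N" separator
# (which poisons boundary-crossing k-mers to NA). Returns the code vector
# aligned to concatenated start coordinates, plus the read offsets.
.encode_concat <- function(seqs, k) {
  lens <- nchar(seqs)
  glued <- paste(seqs, collapse = "N")
  x <- base_codes(utf8ToInt(glued))
  ng <- length(x)
  if (ng < k)
    return(list(canon = numeric(0), lens = lens, off = 0L, ng = ng))
  f <- 4^(0:(k - 1L))
  fwd <- as.numeric(stats::filter(x, f, sides = 1))
  rc <- as.numeric(stats::filter(3 - x, rev(f), sides = 1))
  canon <- pmin(fwd, rc)[k:ng]          # canon[s]: k-mer starting at base s
  off <- cumsum(c(0L, head(lens, -1L) + 1L))
  list(canon = canon, lens = lens, off = off, ng = ng)
}

# rolling min/max over a fixed window of width m (vectorized shift passes)
.roll <- function(v, m, fun) {
  nout <- length(v) - m + 1L
  acc <- v[seq_len(nout)]
  for (j in seq_len(m - 1L)) acc <- fun(acc, v[seq_len(nout) + j])
  acc
}

# Sparse k-mer selection with sliding-stretch escalation.
#
# Every stretch of w consecutive bases of a read escalates its indexed
# fraction (d, 2d, 3d, ...) until it holds at least one selected k-mer;
# a k-mer is selected iff its canonical rank fraction is below the highest
# escalation level among the stretches covering it. This guarantees that
# every w-base stretch of every read contains an indexed k-mer, that the
# minimum-rank k-mer of any w-base stretch is selected (so two error-free
# reads overlapping by >= w bases share an indexed k-mer), and that the
# selection is orientation-invariant. Reads shorter than w escalate over
# the whole read as a single stretch.
#
# Returns data.table(read_i, pos, canon, level), pos 1-based within read.
.select_batch <- function(seqs, params) {
  k <- params$k; w <- params$w
  scale <- params$d * 4^k
  empty <- data.table(read_i = integer(0), pos = integer(0),
                      canon = numeric(0), level = integer(0))
  lens <- nchar(seqs)
  out <- list(empty)
  long <- which(lens >= w)
  short <- which(lens >= k & lens < w)
  if (length(long)) {
    enc <- .encode_concat(seqs[long], k)
    canon <- enc$canon
    S <- length(canon)
    v <- canon
    v[is.na(v)] <- Inf                      # N-poisoned: never a stretch min
    wk1 <- w - k + 1L
    # per-stretch escalation level; stretches crossing a read boundary
    # (i.e. containing a separator base) are voided with -Inf
    rmin <- .roll(v, wk1, pmin)             # min rank over stretch s
    m_s <- floor(rmin / scale) + 1
    m_s[!is.finite(rmin)] <- -Inf
    if (length(enc$off) > 1L) {
      sep <- enc$off[-1L]                   # separator base positions
      nxt <- rep(enc$ng + 1L, enc$ng)
      nxt[sep] <- sep
      nxt <- rev(cummin(rev(nxt)))
      ns <- enc$ng - w + 1L
      m_s[nxt[seq_len(ns)] <= seq_len(ns) + w - 1L] <- -Inf
    }
    # highest stretch level covering each k-mer start
    mp <- c(rep(-Inf, wk1 - 1L), m_s, rep(-Inf, wk1 - 1L))
    M <- .roll(mp, wk1, pmax)
    # +0.5 in integer code space guards the floating-point boundary where
    # a stretch minimum sits exactly on a level threshold
    sel <- which(!is.na(canon) & canon < M * scale + 0.5)
    read_i <- findInterval(sel, enc$off + 1L)
    out[[2L]] <- data.table(read_i = long[read_i],
                            pos = as.integer(sel - enc$off[read_i]),
                            canon = canon[sel],
                            level = as.integer(floor(canon[sel] / scale) + 1))
  }
  if (length(short)) {
    enc <- .encode_concat(seqs[short], k)
    canon <- enc$canon
    s <- seq_along(canon)
    read_i <- findInterval(s, enc$off + 1L)
    pos <- s - enc$off[read_i]
    ok <- !is.na(canon) & pos <= enc$lens[read_i] - k + 1L
    dt <- data.table(read_i = read_i[ok], pos = as.integer(pos[ok]),
                     canon = canon[ok])
    dt[, minrank := min(canon), by = read_i]
    dt <- dt[canon < (floor(minrank / scale) + 1) * scale + 0.5]
    dt[, `:=`(read_i = short[read_i],
              level = as.integer(floor(canon / scale) + 1),
              minrank = NULL)]
    out[[3L]] <- dt
  }
  res <- rbindlist(out, use.names = TRUE)
  setorder(res, read_i, pos)
  res
}

#' Lexicographic rank fraction of k-mers
#'
#' Position of each k-mer in the lexicographic order of all `4^k` k-mers,
#' divided by `4^k` (i.e. its base-4 value as a fraction). A k-mer is
#' indexed at escalation level `m` iff its canonical form's rank fraction
#' is below `m * d`.
#'
#' @param kmer character vector of k-mers over `{A,C,G,T}` (equal lengths).
#' @return numeric vector in `[0, 1)`; `NA` for k-mers containing `N`
#'   (never selected).
#' @examples
#' kmer_rank_fraction(c("AA", "CG", "TT"))  # 0, 0.375, 0.9375
#' @export
kmer_rank_fraction <- function(kmer) {
  if (length(kmer) == 0L) return(numeric(0))
  k <- unique(nchar(kmer))
  .check(length(k) == 1L, "k-mers must have equal length")
  .check(k <= 26, "k must be <= 26")
  codes <- vapply(kmer, function(s) {
    b <- base_codes(utf8ToInt(s))
    if (anyNA(b)) NA_real_ else sum(b * 4^((k - 1L):0))
  }, numeric(1), USE.NAMES = FALSE)
  codes / 4^k
}

#' Canonical form of k-mers
#'
#' The lexicographically smaller of each k-mer and its reverse complement.
#'
#' @param kmer character vector of k-mers over `{A,C,G,T,N}`.
#' @return character vector of canonical k-mers (`NA` for k-mers with `N`).
#' @export
canonical_kmer <- function(kmer) {
  rc <- revcomp(kmer)
  out <- ifelse(kmer <= rc, kmer, rc)
  out[grepl("N", kmer, fixed = TRUE)] <- NA_character_
  out
}

# Decode numeric k-mer codes back to strings.
.decode_kmer <- function(code, k) {
  if (length(code) == 0L) return(character(0))
  m <- matrix("", nrow = length(code), ncol = k)
  rest <- code
  for (j in k:1) {
    m[, j] <- .CODE_BASE[rest %% 4 + 1]
    rest <- rest %/% 4
  }
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Sparse k-mer selection along one sequence
#'
#' Applies the lexicographic-fraction selection with window escalation to a
#' single sequence: the indexed fraction starts at `d` and every stretch of
#' `w` consecutive bases escalates it (`2d`, `3d`, ...) until the stretch
#' holds at least one selected k-mer, so that every `w`-base stretch of the
#' sequence is guaranteed to contain an indexed k-mer. Selection is
#' evaluated on the canonical k-mer, making it orientation-invariant; in
#' particular the minimum-rank k-mer of any `w`-base stretch is always
#' selected, so two error-free reads overlapping by `>= w` bases share an
#' indexed k-mer. k-mers containing `N` are never selected. The reported
#' `level` of a k-mer is the smallest escalation level at which it
#' qualifies (`floor(rank / d) + 1`).
#'
#' @param seq a single DNA string.
#' @param params an [index_params()] object.
#' @return `data.table` with columns `pos` (1-based start), `kmer`
#'   (canonical form), `level` (escalation level of the window). Empty when
#'   the sequence is shorter than `k`.
#' @export
sparse_positions <- function(seq, params = index_params()) {
  stopifnot(length(seq) == 1L)
  sel <- .select_batch(toupper(seq), params)
  data.table(pos = sel$pos, kmer = .decode_kmer(sel$canon, params$k),
             level = sel$level)
}

#' Build the sparse k-mer occurrence index over all read pairs
#'
#' For every pair, the sparse k-mer selections of both mates are pooled
#' into one per-pair set of indexed canonical k-mers (indexing is at pair
#' granularity: one indexed mate is enough to place the pair). The index
#' maps every indexed k-mer to the list of pairs carrying it.
#'
#' @param lp a `linked_pairs` object, or a `data.frame` with columns
#'   `pair_id`, `seq1` and optionally `seq2`.
#' @param params an [index_params()] object.
#' @param chunk_reads internal batching granularity (reads per encoding
#'   chunk); results are independent of it.
#' @return an object of class `kmer_index` with fields `params`, `pair_ids`,
#'   `kmer` (sorted canonical codes), `counts`, `mean_occurrence`
#'   (mean occurrence-list length over k-mers), `occ_mean`
#'   (occurrence-weighted mean count; both fixed at build time), `pruned`
#'   (codes removed by [prune_repeats()]), and the CSR occurrence arrays.
#' @export
build_index <- function(lp, params = index_params(), chunk_reads = 20000L) {
  pairs <- if (inherits(lp, "linked_pairs")) lp$pairs else as.data.table(lp)
  .check(nrow(pairs) > 0, "no read pairs to index")
  np <- nrow(pairs)
  seqs <- c(pairs$seq1, if (!is.null(pairs$seq2)) pairs$seq2)
  pair_of_read <- rep(seq_len(np), length.out = length(seqs))
  entries <- vector("list", ceiling(length(seqs) / chunk_reads))
  for (ci in seq_along(entries)) {
    rows <- ((ci - 1L) * chunk_reads + 1L):min(ci * chunk_reads, length(seqs))
    sel <- .select_batch(seqs[rows], params)
    entries[[ci]] <- unique(data.table(pair = pair_of_read[rows][sel$read_i],
                                       canon = sel$canon))
  }
  e <- unique(rbindlist(entries))
  setorder(e, canon, pair)
  cnt <- e[, .N, by = canon]
  .build_csr(params, pairs$pair_id, np, e, cnt$canon, cnt$N,
             mean_occurrence = mean(cnt$N),
             occ_mean = sum(cnt$N^2) / sum(cnt$N), pruned = numeric(0))
}

# Assemble the kmer_index object from canon-sorted entries.
.build_csr <- function(params, pair_ids, np, e, kmers, counts,
                       mean_occurrence, occ_mean, pruned) {
  nk <- length(kmers)
  kid <- rep(seq_len(nk), counts)        # e is sorted by canon
  occ_pairs <- e$pair
  occ_ptr <- c(1L, 1L + cumsum(counts))
  ord <- order(e$pair, kid)
  pair_kids <- kid[ord]
  plens <- tabulate(e$pair, np)
  pair_ptr <- c(1L, 1L + cumsum(plens))
  structure(list(params = params, pair_ids = pair_ids, n_pairs = np,
                 kmer = kmers, counts = counts,
                 occ_ptr = as.integer(occ_ptr), occ_pairs = occ_pairs,
                 pair_ptr = as.integer(pair_ptr), pair_kids = pair_kids,
                 mean_occurrence = mean_occurrence, occ_mean = occ_mean,
                 pruned = pruned),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf(paste0("kmer_index: %d pairs, %d indexed k-mers (k=%d, d=%.4g, w=%d)\n",
                     "  mean occurrence %.2f; %d k-mers de-indexed as repeats\n"),
              x$n_pairs, length(x$kmer), x$params$k, x$params$d, x$params$w,
              x$mean_occurrence, length(x$pruned)))
  invisible(x)
}

#' Indexed k-mer set of one pair
#'
#' @param index a `kmer_index`.
#' @param pair pair_id (character) or pair row index (integer).
#' @return character vector of canonical k-mers indexed for that pair.
#' @export
indexed_kmers <- function(index, pair) {
  i <- .pair_index(index, pair)
  kids <- index$pair_kids[seq2(index$pair_ptr[i], index$pair_ptr[i + 1L] - 1L)]
  .decode_kmer(index$kmer[kids], index$params$k)
}

# tolerant seq: empty when to < from
seq2 <- function(from, to) if (to < from) integer(0) else from:to

.pair_index <- function(index, pair) {
  if (is.character(pair)) {
    i <- match(pair, index$pair_ids)
    .check(!anyNA(i), "pair '%s' not in index", pair[which(is.na(i))[1L]])
    i
  } else as.integer(pair)
}

#' De-index repeat k-mers
#'
#' Removes every k-mer whose occurrence count is at least `repeat_factor`
#' times the average occurrence count of the index (both averages are the
#' ones fixed at build time and are not recomputed after pruning). Repeat
#' k-mers sit in many reads that are far apart on the genome and would
#' create hubs of false links in the read graphs; de-indexing them may
#' leave some pairs with no indexed k-mer at all, which is accepted.
#'
#' Two notions of "average" are offered. The default, `"occurrence"`, is
#' the occurrence-weighted mean count (`sum(c^2) / sum(c)`): the average
#' occurrence count of the k-mers a read actually carries. It tracks the
#' sequencing coverage, so at `repeat_factor = 2` only k-mers seen at
#' twice the typical coverage or more — repeats — are removed. The plain
#' per-k-mer mean list length (`"kmer"`) is also available; note that on
#' realistic data it is dominated by the vast population of singleton
#' k-mers created by sequencing errors, which pushes the threshold below
#' the counts of ordinary single-copy k-mers and de-indexes essentially
#' everything informative.
#'
#' @param index a `kmer_index`.
#' @param repeat_factor threshold multiplier; defaults to the value in the
#'   index's params.
#' @param average threshold base: `"occurrence"` (occurrence-weighted mean
#'   count, default) or `"kmer"` (mean occurrence-list length over k-mers).
#' @return a new `kmer_index` with the repeat k-mers moved to `pruned`.
#' @export
prune_repeats <- function(index, repeat_factor = NULL,
                          average = c("occurrence", "kmer")) {
  average <- match.arg(average)
  rf <- if (is.null(repeat_factor)) index$params$repeat_factor else repeat_factor
  base <- switch(average, occurrence = index$occ_mean, kmer = index$mean_occurrence)
  thr <- rf * base
  drop <- index$counts >= thr
  if (!any(drop)) {
    index$pruned <- c(index$pruned, numeric(0))
    return(index)
  }
  keep_entry <- !rep(drop, index$counts)         # occ arrays are canon-sorted
  e <- data.table(pair = index$occ_pairs[keep_entry],
                  canon = rep(index$kmer, index$counts)[keep_entry])
  .build_csr(index$params, index$pair_ids, index$n_pairs, e,
             index$kmer[!drop], index$counts[!drop],
             mean_occurrence = index$mean_occurrence,
             occ_mean = index$occ_mean,
             pruned = c(index$pruned, index$kmer[drop]))
}
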