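# Linked-read simulator with ground truth: pseudo-diploid genome, uniform
# long fragments, partial fragment coverage by paired-end reads with
# substitution errors, and random barcode assignment.

#' Simulation parameters
#'
#' Defaults reproduce the study conditions of the E. coli-style protocol:
#' fragments of 70-130 kb drawn uniformly along the genome, 15% of each
#' fragment covered by 150 bp paired-end reads with 1% substitution error,
#' total read coverage 50, and one barcode for every 4 fragments.
#'
#' @param divergence haplotype divergence used by [make_pseudo_diploid()].
#' @param frag_len_min,frag_len_max fragment length bounds (bp).
#' @param p fraction of each fragment's length covered by reads.
#' @param read_len read length (bp); mate 2 is the reverse complement of
#'   the `read_len` bases immediately following mate 1 (fixed insert of
#'   `2 * read_len`).
#' @param error_rate per-base substitution probability.
#' @param read_coverage target total read coverage (fold).
#' @param fragments_per_barcode mean number of fragments per barcode; the
#'   barcode count is the fragment count divided by this.
#' @param barcode_len length of the generated barcode sequences.
#' @return a list of class `sim_params`.
#' @export
sim_params <- function(divergence = 0.01, frag_len_min = 70000L,
                       frag_len_max = 130000L, p = 0.15, read_len = 150L,
                       error_rate = 0.01, read_coverage = 50,
                       fragments_per_barcode = 4L, barcode_len = 16L) {
  .check(p > 0 && p <= 1, "p must be in (0, 1]")
  .check(error_rate >= 0 && error_rate < 1, "error_rate must be in [0, 1)")
  .check(frag_len_min <= frag_len_max, "frag_len_min must be <= frag_len_max")
  .check(divergence >= 0 && divergence < 1, "divergence must be in [0, 1)")
  .check(fragments_per_barcode >= 1, "fragments_per_barcode must be >= 1")
  structure(list(divergence = divergence,
                 frag_len_min = as.integer(frag_len_min),
                 frag_len_max = as.integer(frag_len_max), p = p,
                 read_len = as.integer(read_len), error_rate = error_rate,
                 read_coverage = read_coverage,
                 fragments_per_barcode = fragments_per_barcode,
                 barcode_len = as.integer(barcode_len)),
            class = "sim_params")
}

#' Generate a random genome sequence
#'
#' I.i.d. bases with `P(G or C) = gc`. Deterministic under `seed`.
#'
#' @param length sequence length (bp).
#' @param gc GC content.
#' @param seed integer seed.
#' @param name sequence name.
#' @return named character vector of length 1 (a genome usable by the
#'   other simulator functions).
#' @export
random_genome <- function(length, gc = 0.5, seed = 1L, name = "chr1") {
  .check(length > 0, "length must be > 0")
  .check(gc >= 0 && gc <= 1, "gc must be in [0, 1]")
  with_seed(seed, {
    b <- sample.int(4L, length, replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    setNames(intToUtf8(utf8ToInt("ACGT")[b]), name)
  })
}

#' Duplicate a genome into a pseudo-diploid
#'
#' Adds to each input sequence a copy in which every base is independently
#' substituted (to a uniformly chosen different base) with probability
#' `divergence`; copies are named `<name>_hap2`. This emulates a diploid
#' with divergent haplotypes, a standard stress case for barcode
#' deconvolution since most k-mers are shared between the haplotypes.
#'
#' @param genome named character vector of sequences.
#' @param divergence per-base substitution probability.
#' @param seed integer seed.
#' @return named character vector with the originals followed by the
#'   `_hap2` copies.
#' @export
make_pseudo_diploid <- function(genome, divergence = 0.01, seed = 1L) {
  genome <- .as_genome(genome)
  .check(length(genome) > 0 && all(nchar(genome) > 0), "empty genome")
  .check(divergence >= 0 && divergence < 1, "divergence must be in [0, 1)")
  hap2 <- with_seed(seed, vapply(genome, function(s) {
    x <- utf8ToInt(s)
    b <- base_codes(x)
    hit <- which(!is.na(b) & runif(length(b)) < divergence)
    if (length(hit)) {
      b[hit] <- (b[hit] + sample.int(3L, length(hit), replace = TRUE)) %% 4
      x[hit] <- utf8ToInt("ACGT")[b[hit] + 1L]
    }
    intToUtf8(x)
  }, character(1)))
  c(genome, setNames(hap2, paste0(names(genome), "_hap2")))
}

.as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet"))
    genome <- setNames(as.character(genome), names(genome))
  .check(is.character(genome), "genome must be a named character vector")
  .check(length(genome) > 0, "empty genome")
  if (is.null(names(genome)))
    names(genome) <- paste0("seq", seq_along(genome))
  toupper(genome)
}

# Vectorized substitution errors over a character vector of reads.
.inject_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  lens <- nchar(seqs)
  glued <- paste(seqs, collapse = "")
  x <- utf8ToInt(glued)
  b <- base_codes(x)
  hit <- which(!is.na(b) & runif(length(b)) < rate)
  if (length(hit)) {
    nb <- (b[hit] + sample.int(3L, length(hit), replace = TRUE)) %% 4
    x[hit] <- utf8ToInt("ACGT")[nb + 1L]
  }
  ends <- cumsum(lens)
  substring(intToUtf8(x), ends - lens + 1L, ends)
}

# Distinct random barcode sequences.
.random_barcodes <- function(n, len) {
  bc <- character(0)
  while (length(bc) < n) {
    more <- vapply(seq_len(n - length(bc)), function(i)
      intToUtf8(utf8ToInt("ACGT")[sample.int(4L, len, replace = TRUE)]),
      character(1))
    bc <- unique(c(bc, more))
  }
  bc
}

#' Simulate a linked-read dataset with ground truth
#'
#' Follows the fragment-based linked-read protocol: enough fragments of
#' uniform length in `[frag_len_min, frag_len_max]` are drawn (start
#' uniform along the genome) to reach `read_coverage`; a fraction `p` of
#' each fragment's length is covered by paired-end reads of `read_len`
#' bases (fixed insert, mate 2 reverse-complemented) with substitution
#' errors at `error_rate`; barcodes (count = fragments /
#' `fragments_per_barcode`) are assigned to fragments uniformly at random.
#' Fragments running over a sequence end are clipped and flagged rather
#' than redrawn, preserving the uniformity of start positions.
#'
#' @param genome named character vector of sequences (e.g. from
#'   [random_genome()] + [make_pseudo_diploid()]), or a `DNAStringSet`.
#' @param params a [sim_params()] object.
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @return a list of class `linked_sim`:
#'   \describe{
#'     \item{pairs}{a `linked_pairs` object with `BX:Z:`-style barcodes.}
#'     \item{truth}{`data.table(pair_id, fragment_id, sequence, start, end,
#'       barcode)` mapping every pair to its fragment of origin (fragment
#'       coordinates, 0-based half-open).}
#'     \item{fragments}{per-fragment table incl. a `clipped` flag and
#'       `n_pairs`.}
#'     \item{barcodes}{the full barcode pool (count = fragments /
#'       `fragments_per_barcode`; some barcodes may end up unused).}
#'     \item{params, seed}{the inputs.}
#'   }
#' @export
simulate_linked_reads <- function(genome, params = sim_params(), seed = 1L) {
  genome <- .as_genome(genome)
  .check(length(genome) > 0 && all(nchar(genome) > 0), "empty genome")
  lens <- nchar(genome)
  total <- sum(as.numeric(lens))
  mean_frag <- (params$frag_len_min + params$frag_len_max) / 2
  if (max(lens) < params$frag_len_max)
    warning("genome sequences shorter than frag_len_max; fragments will be clipped")
  n_frag <- as.integer(ceiling(params$read_coverage * total /
                                 (params$p * mean_frag)))
  insert <- 2L * params$read_len
  with_seed(seed, {
    # fragments: sequence weighted by length, start uniform, length uniform
    seq_i <- sample.int(length(genome), n_frag, replace = TRUE,
                        prob = lens / total)
    start <- floor(runif(n_frag) * lens[seq_i])          # 0-based
    flen <- params$frag_len_min +
      floor(runif(n_frag) * (params$frag_len_max - params$frag_len_min + 1L))
    end <- pmin(start + flen, lens[seq_i])
    clipped <- (start + flen) > lens[seq_i]
    # barcodes
    n_bc <- max(1L, as.integer(round(n_frag / params$fragments_per_barcode)))
    bc <- .random_barcodes(n_bc, params$barcode_len)
    bc_of_frag <- bc[sample.int(n_bc, n_frag, replace = TRUE)]
    frags <- data.table(fragment_id = seq_len(n_frag),
                        sequence = names(genome)[seq_i],
                        start = as.integer(start), end = as.integer(end),
                        clipped = clipped, barcode = bc_of_frag)
    # reads: round(p * len / insert) pairs per fragment, starts uniform
    real_len <- frags$end - frags$start
    m <- as.integer(round(params$p * real_len / insert))
    m[real_len < insert] <- 0L
    frag_of_pair <- rep(seq_len(n_frag), m)
    offs <- floor(runif(length(frag_of_pair)) *
                    (real_len[frag_of_pair] - insert + 1L))
    gstart <- frags$start[frag_of_pair] + offs            # 0-based
    chrom <- genome[match(frags$sequence[frag_of_pair], names(genome))]
    seq1 <- substring(chrom, gstart + 1L, gstart + params$read_len)
    seq2 <- revcomp(substring(chrom, gstart + params$read_len + 1L,
                              gstart + insert))
    seq1 <- .inject_errors(seq1, params$error_rate)
    seq2 <- .inject_errors(seq2, params$error_rate)
    qual <- strrep("I", params$read_len)
    pair_id <- sprintf("p%07d", seq_along(frag_of_pair))
    pairs <- data.table(pair_id = pair_id,
                        barcode = frags$barcode[frag_of_pair],
                        suffix = NA_integer_,
                        seq1 = seq1, qual1 = qual,
                        comment1 = paste0("BX:Z:", frags$barcode[frag_of_pair]),
                        seq2 = seq2, qual2 = qual,
                        comment2 = paste0("BX:Z:", frags$barcode[frag_of_pair]))
    truth <- data.table(pair_id = pair_id,
                        fragment_id = frag_of_pair,
                        sequence = frags$sequence[frag_of_pair],
                        start = frags$start[frag_of_pair],
                        end = frags$end[frag_of_pair],
                        barcode = frags$barcode[frag_of_pair])
    frags[, n_pairs := m]
    structure(list(pairs = as_linked_pairs(pairs), truth = truth,
                   fragments = frags, barcodes = bc,
                   params = params, seed = seed),
              class = "linked_sim")
  })
}

#' @export
print.linked_sim <- function(x, ...) {
  cat(sprintf(paste0("linked_sim: %d read pairs from %d fragments, ",
                     "%d barcodes (seed %d)\n"),
              nrow(x$pairs$pairs), nrow(x$fragments),
              length(unique(x$fragments$barcode)), x$seed))
  invisible(x)
}

#' Read / write FASTA genomes
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] and
#' [Biostrings::writeXStringSet()] returning/accepting the named character
#' vectors used by the simulator.
#'
#' @param path FASTA file (optionally gzip-compressed).
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta
#' @param genome named character vector of sequences.
#' @export
write_fasta <- function(genome, path) {
  genome <- .as_genome(genome)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome), path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read / write the simulator ground-truth table
#'
#' TSV with header `pair_id fragment_id sequence start end barcode`
#' (0-based half-open fragment coordinates).
#'
#' @param truth the `truth` table of a `linked_sim`.
#' @param path output TSV path.
#' @export
write_truth <- function(truth, path) {
  fwrite(as.data.table(truth)[, .(pair_id, fragment_id, sequence,
                                  start, end, barcode)],
         path, sep = "\t")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  fread(path, sep = "\t",
        colClasses = list(character = c("pair_id", "sequence", "barcode")))
}
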