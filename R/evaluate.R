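# Entropy-based evaluation of a deconvolution against a reference solution.
#
# A "reference cloud" is the set of reads coming from one true fragment; a
# "deconvolved cloud" is the set of reads a method proposes as one fragment
# (identified by (barcode, group)). Over-deconvolution entropy measures the
# scattering of one reference cloud over deconvolved clouds; under-
# deconvolution entropy measures the mixing of reference clouds inside one
# deconvolved cloud. Both are zero for a perfect deconvolution.

#' Reference solution from simulator ground truth
#'
#' @param truth a ground-truth table (see [simulate_linked_reads()]): one
#'   row per pair with `pair_id` and `fragment_id`.
#' @return a `data.table(pair_id, ref_cloud)` where `ref_cloud` is the
#'   fragment of origin.
#' @export
reference_from_truth <- function(truth) {
  truth <- as.data.table(truth)
  data.table(pair_id = truth$pair_id,
             ref_cloud = as.character(truth$fragment_id))
}

.entropy <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p)) + 0      # + 0 normalizes the pure-cloud case to +0
}

#' Over-deconvolution entropy of one reference cloud
#'
#' Natural-log entropy of the distribution of the reference cloud's reads
#' over the deconvolved clouds containing them: `-sum(p_i * ln p_i)` with
#' `p_i` the proportion of the reference cloud's reads in deconvolved cloud
#' `i`. Zero iff the reference cloud was kept together; an even two-way
#' split gives `ln 2 ~ 0.693`.
#'
#' @param ref_pairs character vector of the reference cloud's pair_ids.
#' @param labels a `deconvolution` table labeling (at least) these pairs.
#' @return entropy in nats.
#' @export
over_entropy <- function(ref_pairs, labels) {
  .check(length(ref_pairs) > 0, "empty reference cloud")
  lab <- as.data.table(labels)[match(ref_pairs, pair_id)]
  .check(!anyNA(lab$group), "unlabeled pairs in reference cloud")
  .entropy(lab[, .N, by = .(barcode, group)]$N)
}

#' Under-deconvolution entropy of one deconvolved cloud
#'
#' Natural-log entropy of the composition of the deconvolved cloud over
#' reference clouds: `-sum(p_j * ln p_j)` with `p_j` the proportion of the
#' cloud's reads coming from reference cloud `j`. Zero iff the cloud is
#' pure (a single true fragment).
#'
#' @param cloud_pairs character vector of the deconvolved cloud's pair_ids.
#' @param reference a [reference_from_truth()] table.
#' @return entropy in nats.
#' @export
under_entropy <- function(cloud_pairs, reference) {
  .check(length(cloud_pairs) > 0, "empty deconvolved cloud")
  ref <- as.data.table(reference)[match(cloud_pairs, pair_id)]
  .check(!anyNA(ref$ref_cloud), "pairs without reference cloud")
  .entropy(ref[, .N, by = ref_cloud]$N)
}

#' Entropy report of a deconvolution against a reference
#'
#' Computes the over-deconvolution entropy of every reference cloud and the
#' under-deconvolution entropy of every deconvolved cloud, with summary
#' statistics and fixed-width histogram counts. Group-0 pairs (clustering
#' ineffective) are excluded by default, matching the evaluation protocol
#' in which only deconvolved reads are scored; raw barcodes can be
#' evaluated by passing [raw_deconvolution()] labels, in which case each
#' original barcode is one deconvolved cloud.
#'
#' @param labels a `deconvolution` table.
#' @param reference a [reference_from_truth()] table.
#' @param include_group0 keep group-0 pairs in the evaluation.
#' @param bin_width histogram bin width (entropy units).
#' @return a list of class `entropy_report`: `over` and `under`
#'   (`data.table(cloud, size, entropy)`), `summary` (mean/median of each
#'   direction), and `histogram` (per-direction bin counts).
#' @export
entropy_report <- function(labels, reference, include_group0 = FALSE,
                           bin_width = 0.1) {
  lab <- as.data.table(labels)[!is.na(group)]
  if (!include_group0) lab <- lab[group > 0L]
  ref <- as.data.table(reference)
  dt <- merge(lab, ref, by = "pair_id")
  dt[, cloud := paste0(barcode, "-", group)]
  over <- dt[, .(size = .N, entropy = .entropy(table(cloud))), by = ref_cloud]
  setnames(over, "ref_cloud", "cloud")
  under <- dt[, .(size = .N, entropy = .entropy(table(ref_cloud))), by = cloud]
  setorder(over, cloud); setorder(under, cloud)
  summary <- data.table(
    direction = c("over", "under"),
    n_clouds = c(nrow(over), nrow(under)),
    mean = c(mean(over$entropy), mean(under$entropy)),
    median = c(median(over$entropy), median(under$entropy)))
  hist_of <- function(e) {
    if (!length(e)) return(data.table(bin_lo = numeric(0), count = integer(0)))
    b <- floor(e / bin_width + 1e-9)
    tb <- table(b)
    data.table(bin_lo = as.numeric(names(tb)) * bin_width,
               count = as.integer(tb))
  }
  structure(list(over = over, under = under, summary = summary,
                 histogram = list(over = hist_of(over$entropy),
                                  under = hist_of(under$entropy)),
                 include_group0 = include_group0, bin_width = bin_width),
            class = "entropy_report")
}

#' @export
print.entropy_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("entropy_report: %d reference clouds ",
                     "(over: mean %.4f, median %.4f)\n",
                     "                %d deconvolved clouds ",
                     "(under: mean %.4f, median %.4f)\n"),
              s$n_clouds[1], s$mean[1], s$median[1],
              s$n_clouds[2], s$mean[2], s$median[2]))
  invisible(x)
}

#' Write an entropy report as TSV
#'
#' One row per cloud: `direction cloud size entropy`.
#'
#' @param report an `entropy_report`.
#' @param path output TSV path.
#' @export
write_entropy_report <- function(report, path) {
  out <- rbind(data.table(direction = "over", report$over),
               data.table(direction = "under", report$under))
  fwrite(out, path, sep = "\t")
  invisible(path)
}
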