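# Expected-shared-barcode model: why two reads of the same fragment share
# many more overlapped barcodes than two reads of different fragments.

#' Theory model parameters
#'
#' @param L fragment length (bp).
#' @param l distance between the two reads on the fragment (bp, `l <= L`).
#' @param c read coverage (fold); fragment coverage is `c / p`.
#' @param p fraction of each fragment covered by reads.
#' @param n mean number of fragments per barcode.
#' @param n_tot total number of distinct barcodes.
#' @param P probability that a read of a common overlapping fragment
#'   overlaps a given read. Both expectations scale by `P^2`, so ratios are
#'   `P`-free; it defaults to 1.
#' @return a list of class `theory_params`.
#' @export
theory_params <- function(L, l = 0, c = 50, p = 0.15, n = 4,
                          n_tot = 1e6, P = 1) {
  .check(l >= 0 && l <= L, "need 0 <= l <= L")
  .check(c > 0 && p > 0 && p <= 1, "need c > 0 and p in (0, 1]")
  .check(n >= 1 && n_tot >= 1, "need n >= 1 and n_tot >= 1")
  structure(list(L = L, l = l, c = c, p = p, n = n, n_tot = n_tot, P = P),
            class = "theory_params")
}

#' Expected common fragments for two reads of the same fragment
#'
#' Two reads of one fragment, `l` apart on the strand, are both covered by
#' the overlapping portion of on average
#' `((L - l) / L) * (c/p - 1)` other fragments. Multiplying by `P^2` gives
#' the expected number of shared overlapped barcodes.
#'
#' @param params a [theory_params()] object.
#' @param scale_P multiply by `P^2` (default `FALSE`: return the raw
#'   common-fragment count).
#' @return expected count (non-negative; 0 when `l = L`).
#' @export
expected_common_same_fragment <- function(params, scale_P = FALSE) {
  stopifnot(inherits(params, "theory_params"))
  .check(params$l <= params$L, "l must be <= L")
  p1 <- (params$L - params$l) / params$L * (params$c / params$p - 1)
  if (scale_P) p1 * params$P^2 else p1
}

#' Expected common fragments for two far-away fragments sharing a barcode
#'
#' Each read overlaps about `c/p` fragments, hence about `c/p` distinct
#' barcodes; a barcode seen by the first read is attached to `n - 1` other,
#' far-away fragments out of `n * n_tot - c/p`, so the expected number of
#' common fragments is `(c/p)^2 * (n - 1) / (n * n_tot - c/p)`. In real
#' linked-read regimes (`n_tot >= 1e6`, `c/p <= 1e3`) this is orders of
#' magnitude below [expected_common_same_fragment()], which is what makes
#' shared-barcode counts discriminating.
#'
#' @inheritParams expected_common_same_fragment
#' @return expected count (0 when `n = 1`: barcodes are never reused).
#' @export
expected_common_far_fragments <- function(params, scale_P = FALSE) {
  stopifnot(inherits(params, "theory_params"))
  cp <- params$c / params$p
  denom <- params$n * params$n_tot - cp
  .check(denom > 0, "need n * n_tot > c/p")
  p2 <- cp * cp * (params$n - 1) / denom
  if (scale_P) p2 * params$P^2 else p2
}

#' Same-fragment vs far-fragment expected overlap ratio
#'
#' @inheritParams expected_common_same_fragment
#' @return `expected_common_same_fragment / expected_common_far_fragments`
#'   (`Inf` when `n = 1`). Independent of `P`.
#' @export
theory_ratio <- function(params) {
  expected_common_same_fragment(params) / expected_common_far_fragments(params)
}
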