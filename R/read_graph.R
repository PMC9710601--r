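# Per-barcode read graph: similar reads dataset-wide, read <-> barcode
# bipartite links, and the collapsed weighted read graph.

# Batched similarity: for every query pair index, count shared indexed
# k-mer types with every other pair. Returns data.table(query, other, shared)
# restricted to shared >= min_shared, self excluded.
.similar_table <- function(index, query, min_shared = index$params$min_shared) {
  query <- .pair_index(index, query)
  qlens <- index$pair_ptr[query + 1L] - index$pair_ptr[query]
  if (sum(qlens) == 0L)
    return(data.table(query = integer(0), other = integer(0), shared = integer(0)))
  kids <- index$pair_kids[sequence(qlens, from = index$pair_ptr[query])]
  qrep <- rep(query, qlens)
  olens <- index$counts[kids]
  others <- index$occ_pairs[sequence(olens, from = index$occ_ptr[kids])]
  dt <- data.table(query = rep(qrep, olens), other = others)
  dt <- dt[query != other][, .(shared = .N), by = .(query, other)]
  dt[shared >= min_shared]
}

#' Find the reads similar to one read pair
#'
#' Two pairs are *similar* when their indexed k-mer sets share at least
#' `min_shared` distinct canonical k-mers (no alignment is ever performed;
#' after [prune_repeats()], de-indexed k-mers contribute nothing). The
#' search covers the whole dataset, not just the pair's own cloud.
#'
#' @param index a `kmer_index` (typically pruned).
#' @param pair pair_id (character) or pair row index.
#' @param min_shared override of the similarity threshold.
#' @return character vector of pair_ids similar to `pair` (excluding
#'   `pair` itself); empty if the pair has no indexed k-mers.
#' @export
find_similar <- function(index, pair, min_shared = index$params$min_shared) {
  st <- .similar_table(index, .pair_index(index, pair), min_shared)
  index$pair_ids[sort(st$other)]
}

#' Build the read-to-barcode bipartite links of one cloud
#'
#' For each pair of the anchor cloud, the set of barcodes whose reads are
#' similar to it, the anchor barcode itself excluded (it carries no
#' discriminating signal between the anchor's fragments; set
#' `self_barcode = "include"` to keep it).
#'
#' @param cloud integer row indices (into the pair table) of the anchor
#'   cloud's pairs, e.g. one element of `linked_pairs$clouds`.
#' @param index a `kmer_index` over the whole dataset.
#' @param barcode_of character vector mapping every pair row index to its
#'   barcode (`NA` allowed for unbarcoded pairs).
#' @param anchor_barcode the cloud's barcode; defaults to the barcode of
#'   the cloud's first pair.
#' @param self_barcode whether links to the anchor's own barcode are kept.
#' @return an object of class `bipartite_links`: list with
#'   `anchor_barcode`, `pairs` (row indices), and `links`, a named list
#'   mapping each anchor pair_id to its barcode set.
#' @export
build_bipartite <- function(cloud, index, barcode_of,
                            anchor_barcode = barcode_of[cloud[1L]],
                            self_barcode = c("exclude", "include")) {
  self_barcode <- match.arg(self_barcode)
  st <- .similar_table(index, cloud)
  st[, barcode := barcode_of[other]]
  st <- st[!is.na(barcode)]
  if (self_barcode == "exclude") st <- st[barcode != anchor_barcode]
  lk <- st[, .(bcs = list(unique(barcode))), by = query]
  links <- setNames(rep(list(character(0)), length(cloud)),
                    index$pair_ids[cloud])
  links[match(lk$query, cloud)] <- lk$bcs
  structure(list(anchor_barcode = anchor_barcode, pairs = cloud,
                 links = links),
            class = "bipartite_links")
}

#' Collapse bipartite links into the weighted read graph
#'
#' Two anchor pairs are joined by an edge of weight `n` when they overlap
#' reads of `n` shared barcodes, i.e. the weight is the size of the
#' intersection of their barcode link sets; pairs with no shared barcode
#' get no edge.
#'
#' @param bipartite a `bipartite_links` object.
#' @return an object of class `read_graph`: list with `anchor_barcode`,
#'   `nodes` (pair_ids of the whole cloud, including isolated ones) and
#'   `edges`, a `data.table(p, q, weight)` of unordered node index pairs
#'   (`p < q`, indices into `nodes`).
#' @export
collapse_bipartite <- function(bipartite) {
  stopifnot(inherits(bipartite, "bipartite_links"))
  nodes <- names(bipartite$links)
  n <- length(nodes)
  lk <- bipartite$links
  sizes <- lengths(lk)
  if (sum(sizes) == 0L) {
    edges <- data.table(p = integer(0), q = integer(0), weight = integer(0))
  } else {
    inc <- data.table(node = rep(seq_len(n), sizes), barcode = unlist(lk))
    both <- merge(inc, inc, by = "barcode", allow.cartesian = TRUE,
                  suffixes = c(".p", ".q"))
    edges <- both[node.p < node.q,
                  .(weight = .N), by = .(p = node.p, q = node.q)]
    setorder(edges, p, q)
  }
  structure(list(anchor_barcode = bipartite$anchor_barcode,
                 nodes = nodes, edges = edges),
            class = "read_graph")
}

#' @export
print.read_graph <- function(x, ...) {
  cat(sprintf("read_graph (barcode %s): %d reads, %d edges\n",
              x$anchor_barcode, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Write a read graph as a TSV edge list
#'
#' Debug output: `node1 node2 weight`, one line per edge.
#'
#' @param graph a `read_graph`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_read_graph <- function(graph, path) {
  out <- data.table(node1 = graph$nodes[graph$edges$p],
                    node2 = graph$nodes[graph$edges$q],
                    weight = graph$edges$weight)
  fwrite(out, path, sep = "\t")
  invisible(path)
}
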