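# Weighted Chinese-whispers clustering of read graphs and the per-cloud /
# whole-dataset deconvolution drivers.

#' Weighted Chinese-whispers graph clustering
#'
#' Every node starts in its own cluster. Nodes are then visited in a fresh
#' seeded-random order each pass; a visited node adopts the label with the
#' largest total incident edge weight among its neighbours (its own current
#' label does not vote), ties broken uniformly at random. The algorithm
#' stops when a full pass changes no label, or after `max_iter` passes
#' (the clustering can oscillate, but this is marginal in practice).
#' It is parameter-free and agnostic about the number of clusters.
#'
#' @param graph a `read_graph` (see [collapse_bipartite()]).
#' @param seed integer seed for the visit orders and tie-breaks.
#' @param max_iter maximum number of passes.
#' @return integer vector of cluster labels named by node (pair_id).
#'   Isolated nodes keep their own singleton label.
#' @export
chinese_whispers <- function(graph, seed = 1L, max_iter = 100L) {
  stopifnot(inherits(graph, "read_graph"), max_iter >= 1)
  n <- length(graph$nodes)
  labels <- seq_len(n)
  ed <- graph$edges
  if (n == 0L || nrow(ed) == 0L)
    return(setNames(labels, graph$nodes))
  # symmetric adjacency, grouped by node
  half <- data.table(v = c(ed$p, ed$q), u = c(ed$q, ed$p),
                     weight = rep(ed$weight, 2L))
  setorder(half, v, u)
  nb <- split(half$u, half$v)
  wt <- split(half$weight, half$v)
  deg_nodes <- as.integer(names(nb))
  nbs <- rep(list(integer(0)), n); nbs[deg_nodes] <- nb
  wts <- rep(list(numeric(0)), n); wts[deg_nodes] <- wt
  with_seed(seed, {
    for (it in seq_len(max_iter)) {
      changed <- FALSE
      for (v in sample.int(n)) {
        nbv <- nbs[[v]]
        if (length(nbv) == 0L) next
        votes <- rowsum(wts[[v]], labels[nbv])
        best <- as.integer(rownames(votes)[votes == max(votes)])
        newl <- if (length(best) == 1L) best else sample(best, 1L)
        if (newl != labels[v]) {
          labels[v] <- newl
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  })
  setNames(labels, graph$nodes)
}

# Renumber raw cluster labels to groups: isolated nodes (degree 0) get
# group 0; remaining clusters are numbered 1..G by first appearance in
# node (= pair input) order.
.number_groups <- function(graph, labels) {
  n <- length(graph$nodes)
  isolated <- !(seq_len(n) %in% c(graph$edges$p, graph$edges$q))
  group <- integer(n)
  if (any(!isolated)) {
    first <- unique(labels[!isolated])   # labels in node order
    group[!isolated] <- match(labels[!isolated], first)
  }
  setNames(group, graph$nodes)
}

# Shared worker: cluster one cloud given its precomputed link table
# (data.table(query = pair row index, barcode)).
.cluster_cloud <- function(cloud, links_dt, pair_ids, anchor_barcode, seed,
                           max_iter = 100L) {
  links <- setNames(rep(list(character(0)), length(cloud)), pair_ids[cloud])
  if (nrow(links_dt)) {
    lk <- links_dt[, .(bcs = list(unique(barcode))), by = query]
    links[match(lk$query, cloud)] <- lk$bcs
  }
  bip <- structure(list(anchor_barcode = anchor_barcode, pairs = cloud,
                        links = links),
                   class = "bipartite_links")
  g <- collapse_bipartite(bip)
  labels <- chinese_whispers(g, seed = derive_seed(seed, anchor_barcode),
                             max_iter = max_iter)
  .number_groups(g, labels)
}

#' Deconvolve a single read cloud
#'
#' Runs the whole per-barcode pipeline: bipartite link construction against
#' the dataset-wide index, collapse to the weighted read graph, Chinese
#' whispers, and group numbering. The clustering seed is derived
#' deterministically from `(seed, barcode)`, so the result does not depend
#' on when or where the cloud is processed.
#'
#' @param cloud integer row indices of the cloud's pairs.
#' @param index a (pruned) `kmer_index` over the whole dataset.
#' @param barcode_of character vector mapping pair row index to barcode.
#' @param seed global integer seed.
#' @param max_iter Chinese-whispers pass cap.
#' @param self_barcode see [build_bipartite()].
#' @return `data.table(pair_id, barcode, group)`; group 0 marks pairs with
#'   no edge in the cloud's graph (clustering was ineffective there).
#' @export
deconvolve_cloud <- function(cloud, index, barcode_of, seed = 1L,
                             max_iter = 100L,
                             self_barcode = c("exclude", "include")) {
  self_barcode <- match.arg(self_barcode)
  anchor <- barcode_of[cloud[1L]]
  st <- .similar_table(index, cloud)
  st[, barcode := barcode_of[other]]
  st <- st[!is.na(barcode)]
  if (self_barcode == "exclude") st <- st[barcode != anchor]
  grp <- .cluster_cloud(cloud, st[, .(query, barcode)], index$pair_ids,
                        anchor, seed, max_iter)
  data.table(pair_id = names(grp), barcode = anchor,
             group = as.integer(grp))
}

#' Deconvolve every read cloud of a dataset
#'
#' Processes all clouds independently and returns the union of their
#' labels. The `workers` argument fixes how clouds are partitioned into
#' batches; because every cloud's clustering seed is derived from
#' `(seed, barcode)`, the output is identical for any `workers` value and
#' any processing order. Unbarcoded pairs are passed through with `NA`
#' group.
#'
#' @param lp a `linked_pairs` object.
#' @param index a `kmer_index` built over `lp` (pruned or not).
#' @param seed global integer seed.
#' @param workers number of independent cloud partitions (round-robin).
#' @param max_iter Chinese-whispers pass cap.
#' @param self_barcode see [build_bipartite()].
#' @param chunk_pairs internal batching of the similarity joins (query
#'   pairs per batch); results are independent of it.
#' @param verbose print progress per processed batch.
#' @return a `data.table` of class `deconvolution` with one row per pair:
#'   `pair_id`, `barcode`, `group` (integer >= 0, or `NA` for unbarcoded
#'   pairs), in the input pair order.
#' @export
deconvolve_all <- function(lp, index, seed = 1L, workers = 1L,
                           max_iter = 100L,
                           self_barcode = c("exclude", "include"),
                           chunk_pairs = 4000L, verbose = FALSE) {
  stopifnot(inherits(lp, "linked_pairs"))
  self_barcode <- match.arg(self_barcode)
  barcode_of <- lp$pairs$barcode
  clouds <- lp$clouds
  out <- vector("list", length(clouds) + 1L)
  if (length(clouds)) {
    worker_of <- rep_len(seq_len(max(1L, workers)), length(clouds))
    ci <- 0L
    for (wk in sort(unique(worker_of))) {
      wclouds <- clouds[worker_of == wk]
      # batch clouds so each similarity join covers ~chunk_pairs queries
      sizes <- lengths(wclouds)
      batch <- cumsum(sizes) %/% chunk_pairs
      for (b in unique(batch)) {
        bclouds <- wclouds[batch == b]
        q <- unlist(bclouds, use.names = FALSE)
        cloud_of <- rep(seq_along(bclouds), lengths(bclouds))
        st <- .similar_table(index, q)
        st[, cloud := cloud_of[match(query, q)]]
        st[, barcode := barcode_of[other]]
        st <- st[!is.na(barcode)]
        anchors <- names(bclouds)
        if (self_barcode == "exclude") st <- st[barcode != anchors[cloud]]
        parts <- split(st[, .(cloud, query, barcode)], by = "cloud")
        for (j in seq_along(bclouds)) {
          lt <- parts[[as.character(j)]]
          if (is.null(lt)) lt <- data.table(query = integer(0),
                                            barcode = character(0))
          grp <- .cluster_cloud(bclouds[[j]], lt, index$pair_ids,
                                anchors[j], seed, max_iter)
          ci <- ci + 1L
          out[[ci]] <- data.table(pair_id = names(grp),
                                  barcode = anchors[j],
                                  group = as.integer(grp))
        }
        if (verbose)
          message(sprintf("worker %d: deconvolved %d/%d clouds",
                          wk, ci, length(clouds)))
      }
    }
  }
  if (length(lp$unbarcoded))
    out[[length(clouds) + 1L]] <-
      data.table(pair_id = lp$pairs$pair_id[lp$unbarcoded],
                 barcode = NA_character_, group = NA_integer_)
  res <- rbindlist(out[!vapply(out, is.null, logical(1))])
  res <- res[match(lp$pairs$pair_id, pair_id)][!is.na(pair_id)]
  setattr(res, "class", c("deconvolution", class(res)))
  res
}

#' Treat raw barcodes as a (non-)deconvolution
#'
#' Returns labels where every barcoded pair is in group 1 of its original
#' barcode, i.e. each original read cloud is one deconvolved cloud. Useful
#' as the baseline for [entropy_report()].
#'
#' @param lp a `linked_pairs` object.
#' @return a `deconvolution` table.
#' @export
raw_deconvolution <- function(lp) {
  stopifnot(inherits(lp, "linked_pairs"))
  res <- data.table(pair_id = lp$pairs$pair_id, barcode = lp$pairs$barcode,
                    group = ifelse(is.na(lp$pairs$barcode), NA_integer_, 1L))
  setattr(res, "class", c("deconvolution", class(res)))
  res
}

#' @export
print.deconvolution <- function(x, ...) {
  lab <- x[!is.na(group)]
  cat(sprintf(paste0("deconvolution: %d labeled pairs, %d enhanced clouds, ",
                     "%.2f%% in groups >= 1\n"),
              nrow(lab), nrow(unique(lab[group > 0L, .(barcode, group)])),
              if (nrow(lab)) 100 * mean(lab$group > 0L) else 0))
  invisible(x)
}
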