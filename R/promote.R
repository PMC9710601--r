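# Barcode-aware taxonomic rank promotion: a read classified at a high rank
# can be promoted to a lower rank supported by its cloud-mates, provided
# the mates' lower-rank taxa do not conflict (lie on divergent branches).
# Deconvolved clouds have fewer conflicts than raw barcodes, so they
# promote more reads.

#' Build a taxonomy from a node table
#'
#' @param nodes `data.frame` with columns `taxon`, `parent`, `rank`
#'   (NCBI `nodes.dmp`-like: the root's parent is itself or `NA`).
#' @return an object of class `taxonomy` with precomputed depths and
#'   ancestor paths.
#' @export
taxonomy <- function(nodes) {
  nodes <- as.data.table(nodes)[, .(taxon = as.character(taxon),
                                    parent = as.character(parent), rank)]
  .check(!anyDuplicated(nodes$taxon), "duplicated taxon ids")
  root <- nodes$taxon[is.na(nodes$parent) | nodes$parent == nodes$taxon]
  .check(length(root) == 1L, "taxonomy must have exactly one root")
  idx <- setNames(seq_len(nrow(nodes)), nodes$taxon)
  parent_i <- idx[nodes$parent]
  # ancestor path (root..self) per taxon; also detects cycles/orphans
  paths <- vector("list", nrow(nodes))
  for (i in seq_len(nrow(nodes))) {
    path <- i
    j <- i
    while (nodes$taxon[j] != root) {
      j <- parent_i[j]
      .check(!is.na(j), "taxon '%s' has a parent outside the taxonomy",
             nodes$taxon[path[length(path)]])
      .check(!(j %in% path), "cycle in taxonomy at taxon '%s'", nodes$taxon[i])
      path <- c(path, j)
    }
    paths[[i]] <- rev(nodes$taxon[path])
  }
  structure(list(nodes = nodes, root = root,
                 depth = setNames(lengths(paths), nodes$taxon),
                 paths = setNames(paths, nodes$taxon)),
            class = "taxonomy")
}

#' Read a taxonomy from a TSV file
#'
#' Expects three columns `taxon`, `parent`, `rank` (header optional if in
#' that order).
#'
#' @param path TSV path.
#' @return a [taxonomy()] object.
#' @export
read_taxonomy <- function(path) {
  dt <- fread(path, sep = "\t", colClasses = "character")
  if (!all(c("taxon", "parent", "rank") %in% names(dt)))
    setnames(dt, seq_len(3L), c("taxon", "parent", "rank"))
  taxonomy(dt)
}

# is `a` an ancestor-or-self of `b`?
.is_anc <- function(tax, a, b) a %in% tax$paths[[b]]

#' Promote the assignments of one read cloud
#'
#' For each read, the set `D` of its cloud-mates' taxa strictly below the
#' read's own taxon is examined. If every taxon in `D` lies on a single
#' root-to-leaf chain (all pairwise ancestor-comparable), the read is
#' promoted to the deepest taxon of the chain (or to the mates' lowest
#' common ancestor with `target = "lca"`). If `D` holds taxa on divergent
#' branches -- a conflict, typically caused by fragments of closely related
#' organisms sharing the barcode -- the read keeps its taxon. Unassigned
#' reads (`NA` taxon) are promoted to the cloud consensus under the same
#' no-conflict rule when `promote_unassigned` is `TRUE`.
#'
#' @param assignments `data.frame(pair_id, taxon)` for the reads of one
#'   cloud (`taxon` `NA` when unassigned).
#' @param tax a [taxonomy()] object.
#' @param promote_unassigned also promote unassigned reads.
#' @param target `"deepest"` (deepest mate taxon on the chain) or `"lca"`.
#' @return the assignments table with a `promoted` taxon column.
#' @export
promote_cloud <- function(assignments, tax, promote_unassigned = TRUE,
                          target = c("deepest", "lca")) {
  target <- match.arg(target)
  a <- as.data.table(assignments)[, .(pair_id, taxon = as.character(taxon))]
  known <- !is.na(a$taxon)
  bad <- !(a$taxon[known] %in% tax$nodes$taxon)
  if (any(bad))
    stop(sprintf("taxon '%s' of pair '%s' absent from taxonomy",
                 a$taxon[known][bad][1L], a$pair_id[known][bad][1L]),
         call. = FALSE)
  promoted <- a$taxon
  for (i in seq_len(nrow(a))) {
    t0 <- a$taxon[i]
    mates <- a$taxon[-i]
    mates <- unique(mates[!is.na(mates)])
    if (is.na(t0)) {
      if (!promote_unassigned) next
      D <- mates
    } else {
      D <- mates[vapply(mates, function(m)
        m != t0 && .is_anc(tax, t0, m), logical(1))]
    }
    if (length(D) == 0L) next
    # single chain <=> every taxon is an ancestor-or-self of the deepest
    deepest <- D[which.max(tax$depth[D])]
    if (!all(vapply(D, function(m) .is_anc(tax, m, deepest), logical(1))))
      next  # conflict: divergent branches
    promoted[i] <- if (target == "deepest") deepest else {
      # LCA of D = deepest common prefix of the ancestor paths
      paths <- tax$paths[D]
      common <- Reduce(function(x, y) x[seq_len(min(length(x), length(y)))][
        x[seq_len(min(length(x), length(y)))] ==
          y[seq_len(min(length(x), length(y)))]], paths)
      common[length(common)]
    }
  }
  a[, promoted := promoted]
  a
}

#' Promote assignments cloud by cloud
#'
#' Applies [promote_cloud()] within each cloud of a cloud mapping (raw
#' barcodes or enhanced barcodes). Reads whose cloud id is `NA` (e.g.
#' unbarcoded, or group-0 pairs if so encoded) are left unchanged.
#'
#' @param assignments `data.frame(pair_id, taxon)` for all reads.
#' @param cloud_of character vector of cloud ids, parallel to
#'   `assignments` rows (e.g. `barcode` for raw clouds or
#'   `paste0(barcode, "-", group)` for deconvolved clouds).
#' @inheritParams promote_cloud
#' @return assignments table with a `promoted` column, in input order.
#' @export
promote_by_cloud <- function(assignments, cloud_of, tax,
                             promote_unassigned = TRUE,
                             target = c("deepest", "lca")) {
  target <- match.arg(target)
  a <- as.data.table(assignments)[, .(pair_id, taxon = as.character(taxon))]
  .check(length(cloud_of) == nrow(a),
         "cloud_of must be parallel to assignments")
  a[, promoted := taxon]
  ok <- !is.na(cloud_of)
  for (cl in unique(cloud_of[ok])) {
    rows <- which(ok & cloud_of == cl)
    if (length(rows) < 2L) next
    a$promoted[rows] <- promote_cloud(a[rows, .(pair_id, taxon)], tax,
                                      promote_unassigned, target)$promoted
  }
  a
}

#' Per-rank assignment counts before and after promotion
#'
#' @param before,after `data.frame(pair_id, taxon)` (the `promoted` column
#'   of a promotion result can be renamed/used as `taxon`); must cover the
#'   same reads.
#' @param tax a [taxonomy()] object.
#' @return `data.table(rank, before, after)` of read counts per rank, plus
#'   an `unassigned` row.
#' @export
promotion_summary <- function(before, after, tax) {
  b <- as.data.table(before); a <- as.data.table(after)
  .check(setequal(b$pair_id, a$pair_id),
         "before/after must cover the same reads")
  rank_of <- setNames(tax$nodes$rank, tax$nodes$taxon)
  cnt <- function(x) {
    r <- ifelse(is.na(x$taxon), "unassigned", rank_of[as.character(x$taxon)])
    table(factor(r, levels = c(unique(tax$nodes$rank), "unassigned")))
  }
  cb <- cnt(b); ca <- cnt(a)
  data.table(rank = names(cb), before = as.integer(cb), after = as.integer(ca))
}
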