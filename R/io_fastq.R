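# Barcoded paired-end FASTQ input/output, including the enhanced-barcode
# output dialect (BX:Z:<barcode>-<group>).

#' Extract the barcode from a FASTQ header comment
#'
#' Scans the whitespace-separated tags of a FASTQ comment field (the text
#' after the first whitespace of the header line) and returns the value of
#' the first `BX:Z:` tag. A trailing `-<integer>` group suffix (the 10x
#' gem-group / enhanced-barcode convention) is split off and reported
#' separately.
#'
#' @param comment character vector of header comment fields (may be `""`).
#' @param keep_suffix if `TRUE`, return a `data.frame` with columns
#'   `barcode` and `suffix` (integer, `NA` when absent) instead of the bare
#'   barcode vector.
#' @return character vector of barcodes (`NA` where no well-formed tag is
#'   present), or a two-column `data.frame` when `keep_suffix = TRUE`.
#' @examples
#' extract_barcode("BX:Z:ACGTACGT")
#' extract_barcode("RG:Z:x BX:Z:AAAACCCC-1", keep_suffix = TRUE)
#' @export
extract_barcode <- function(comment, keep_suffix = FALSE) {
  m <- regexpr("(?:^|\\s)BX:Z:\\S+", comment)
  val <- rep(NA_character_, length(comment))
  hit <- !is.na(m) & m > 0L
  val[hit] <- sub("^\\s*BX:Z:", "", regmatches(comment, m))
  sfx <- rep(NA_integer_, length(val))
  has_sfx <- !is.na(val) & grepl("-[0-9]+$", val)
  sfx[has_sfx] <- as.integer(sub("^.*-([0-9]+)$", "\\1", val[has_sfx]))
  val[has_sfx] <- sub("-[0-9]+$", "", val[has_sfx])
  if (keep_suffix) data.frame(barcode = val, suffix = sfx) else val
}

# Read one FASTQ file into a data.table(id, comment, seq, qual).
# Light structural validation; errors name the offending record.
.read_fastq <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  n <- length(lines)
  if (n %% 4L != 0L)
    stop(sprintf("truncated FASTQ record at record %d in %s", n %/% 4L + 1L, path),
         call. = FALSE)
  if (n == 0L)
    return(data.table(id = character(0), comment = character(0),
                      seq = character(0), qual = character(0)))
  hd <- lines[seq(1L, n, 4L)]
  sq <- lines[seq(2L, n, 4L)]
  pl <- lines[seq(3L, n, 4L)]
  ql <- lines[seq(4L, n, 4L)]
  bad <- which(!startsWith(hd, "@") | !startsWith(pl, "+"))
  if (length(bad))
    stop(sprintf("malformed FASTQ record %d in %s", bad[1L], path), call. = FALSE)
  bad <- which(nchar(sq) != nchar(ql))
  if (length(bad))
    stop(sprintf("sequence/quality length mismatch at record %d in %s", bad[1L], path),
         call. = FALSE)
  hd <- substring(hd, 2L)
  sp <- regexpr("\\s", hd)
  id <- ifelse(sp > 0L, substr(hd, 1L, sp - 1L), hd)
  comment <- ifelse(sp > 0L, substring(hd, sp + 1L), "")
  data.table(id = id, comment = comment, seq = toupper(sq), qual = ql)
}

#' Read barcoded paired-end FASTQ into read pairs and read clouds
#'
#' R1 and R2 records are paired positionally (record i of R1 with record i
#' of R2). Pairs are grouped into read clouds by barcode; pairs without a
#' barcode go into a separate unbarcoded bucket and belong to no cloud.
#'
#' Two barcode dialects are supported: `"bx-tag"` (a `BX:Z:` tag in the
#' header comment, 10x convention; any trailing `-<n>` group suffix is
#' recorded separately) and `"name-suffix"` (barcode embedded in the read
#' name after the last underscore, as some simulators and TELL-Seq data do).
#'
#' @param path_r1 FASTQ file (optionally gzip-compressed) with mate-1 reads.
#' @param path_r2 optional FASTQ file with mate-2 reads; `NULL` for
#'   single-end data.
#' @param dialect barcode encoding, see Details.
#' @return an object of class `linked_pairs`: a list with
#'   \describe{
#'     \item{pairs}{`data.table` with one row per pair: `pair_id`, `barcode`
#'       (`NA` if absent), `suffix` (pre-existing group suffix or `NA`),
#'       `seq1`, `qual1`, `comment1`, and (paired input) `seq2`, `qual2`,
#'       `comment2`.}
#'     \item{clouds}{named list mapping each barcode to the integer row
#'       indices of its pairs (the read clouds).}
#'     \item{unbarcoded}{integer row indices of pairs without a barcode.}
#'   }
#' @export
read_linked_fastq <- function(path_r1, path_r2 = NULL,
                              dialect = c("bx-tag", "name-suffix")) {
  dialect <- match.arg(dialect)
  r1 <- .read_fastq(path_r1)
  paired <- !is.null(path_r2)
  if (paired) {
    r2 <- .read_fastq(path_r2)
    if (nrow(r1) != nrow(r2))
      stop(sprintf("mismatched R1/R2 record counts (%d vs %d)", nrow(r1), nrow(r2)),
           call. = FALSE)
  }
  if (dialect == "bx-tag") {
    bc <- extract_barcode(r1$comment, keep_suffix = TRUE)
    if (paired) {
      bc2 <- extract_barcode(r2$comment)
      # mate barcodes must agree when both present
      both <- !is.na(bc$barcode) & !is.na(bc2)
      if (any(both & bc$barcode != bc2))
        stop("mate barcodes disagree within a pair", call. = FALSE)
      miss1 <- is.na(bc$barcode) & !is.na(bc2)
      bc$barcode[miss1] <- bc2[miss1]
    }
    barcode <- bc$barcode
    suffix <- bc$suffix
  } else {
    nm <- sub("/[12]$", "", r1$id)
    has <- grepl("_[^_]+$", nm)
    barcode <- ifelse(has, sub("^.*_", "", nm), NA_character_)
    suffix <- rep(NA_integer_, nrow(r1))
  }
  pair_id <- sub("/[12]$", "", r1$id)
  pairs <- data.table(pair_id = pair_id, barcode = barcode, suffix = suffix,
                      seq1 = r1$seq, qual1 = r1$qual, comment1 = r1$comment)
  if (paired) {
    pairs[, `:=`(seq2 = r2$seq, qual2 = r2$qual, comment2 = r2$comment)]
  }
  as_linked_pairs(pairs)
}

#' Assemble a `linked_pairs` object from a pair table
#'
#' Groups pairs into read clouds by barcode and collects unbarcoded pairs.
#' Used by [read_linked_fastq()] and [simulate_linked_reads()]; exported so
#' pair tables built in code can enter the pipeline.
#'
#' @param pairs `data.frame`/`data.table` with at least `pair_id`, `barcode`,
#'   `seq1`, `qual1` (and optionally `seq2`, `qual2`, comments).
#' @return a `linked_pairs` object (see [read_linked_fastq()]).
#' @export
as_linked_pairs <- function(pairs) {
  pairs <- as.data.table(pairs)
  .check(!anyDuplicated(pairs$pair_id), "duplicated pair_id in input")
  idx <- seq_len(nrow(pairs))
  unbarcoded <- idx[is.na(pairs$barcode)]
  keep <- idx[!is.na(pairs$barcode)]
  clouds <- split(keep, pairs$barcode[keep])
  structure(list(pairs = pairs, clouds = clouds, unbarcoded = unbarcoded),
            class = "linked_pairs")
}

#' @export
print.linked_pairs <- function(x, ...) {
  cat(sprintf("linked_pairs: %d read pairs, %d read clouds, %d unbarcoded\n",
              nrow(x$pairs), length(x$clouds), length(x$unbarcoded)))
  invisible(x)
}

# Replace (or append) the BX tag in a comment field (vectorized).
.set_bx <- function(comment, tag) {
  m <- regexpr("BX:Z:\\S+", comment)
  has <- !is.na(m) & m > 0L
  out <- comment
  out[has] <- paste0(substr(comment[has], 1L, m[has] - 1L), tag[has],
                     substring(comment[has],
                               m[has] + attr(m, "match.length")[has]))
  out[!has] <- ifelse(comment[!has] == "", tag[!has],
                      paste(comment[!has], tag[!has]))
  out
}

.fastq_block <- function(id, comment, seq, qual) {
  hd <- ifelse(comment == "", paste0("@", id), paste0("@", id, " ", comment))
  as.vector(rbind(hd, seq, "+", qual))
}

.write_lines <- function(lines, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
}

#' Write read pairs as barcoded FASTQ
#'
#' Writes mate-1 and mate-2 FASTQ files with `BX:Z:<barcode>` tags in the
#' header comments (pairs with `NA` barcode get no tag). Paths ending in
#' `.gz` are gzip-compressed.
#'
#' @param lp a `linked_pairs` object (or bare pair table).
#' @param path_r1,path_r2 output paths; `path_r2` ignored for single-end data.
#' @return invisibly, the output paths.
#' @export
write_linked_fastq <- function(lp, path_r1, path_r2 = NULL) {
  pairs <- if (inherits(lp, "linked_pairs")) lp$pairs else as.data.table(lp)
  tag <- ifelse(is.na(pairs$barcode), "", paste0("BX:Z:", pairs$barcode))
  .write_lines(.fastq_block(pairs$pair_id, tag, pairs$seq1, pairs$qual1), path_r1)
  if (!is.null(pairs$seq2)) {
    .check(!is.null(path_r2), "paired data but no path_r2 given")
    .write_lines(.fastq_block(pairs$pair_id, tag, pairs$seq2, pairs$qual2), path_r2)
  }
  invisible(c(path_r1, if (!is.null(pairs$seq2)) path_r2))
}

#' Write an enhanced-barcode FASTQ
#'
#' Writes the input pairs unchanged except that the barcode tag is rewritten
#' `BX:Z:<barcode>-<group>` with the group label of each pair's deconvolution
#' (group 0, "not deconvolved", is written literally). Any pre-existing
#' `-<n>` suffix is overwritten. Record order is preserved; sequences and
#' qualities are untouched.
#'
#' @param lp a `linked_pairs` object.
#' @param labels a [deconvolve_all()] result (or any `data.frame` with
#'   columns `pair_id`, `barcode`, `group`). Every barcoded pair must be
#'   labeled; unbarcoded pairs are passed through unchanged.
#' @param path_r1,path_r2 output FASTQ paths (`.gz` for gzip).
#' @return invisibly, the output paths.
#' @export
write_enhanced_fastq <- function(lp, labels, path_r1, path_r2 = NULL) {
  stopifnot(inherits(lp, "linked_pairs"))
  pairs <- lp$pairs
  lab <- as.data.table(labels)[, .(pair_id, barcode, group)]
  i <- match(pairs$pair_id, lab$pair_id)
  need <- !is.na(pairs$barcode)
  if (any(need & is.na(i)))
    stop(sprintf("pair '%s' has no deconvolution label",
                 pairs$pair_id[which(need & is.na(i))[1L]]), call. = FALSE)
  tag <- rep("", nrow(pairs))
  tag[need] <- paste0("BX:Z:", lab$barcode[i[need]], "-", lab$group[i[need]])
  cm1 <- if (!is.null(pairs$comment1)) pairs$comment1 else rep("", nrow(pairs))
  cm1[need] <- .set_bx(cm1[need], tag[need])
  .write_lines(.fastq_block(pairs$pair_id, cm1, pairs$seq1, pairs$qual1), path_r1)
  if (!is.null(pairs$seq2)) {
    .check(!is.null(path_r2), "paired data but no path_r2 given")
    cm2 <- if (!is.null(pairs$comment2)) pairs$comment2 else rep("", nrow(pairs))
    cm2[need] <- .set_bx(cm2[need], tag[need])
    .write_lines(.fastq_block(pairs$pair_id, cm2, pairs$seq2, pairs$qual2), path_r2)
  }
  invisible(c(path_r1, if (!is.null(pairs$seq2)) path_r2))
}
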