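## Fragment I/O and the post-alignment retention filters.
##
## Internal coordinates are 0-based half-open (BED convention); the alignment
## dialect's 1-based positions are converted at the boundary. The retained
## set reproduces the study's post-alignment rules: proper pairs only, mapq
## >= 30, at most five mismatches, no duplicates or multi-mapped templates,
## and an insert size strictly below 600 bp.

FRAGMENT_COLUMNS <- c("chrom", "start", "end", "strand", "mapq",
                      "mismatches", "proper_pair", "duplicate", "multimapped")

#' Construct / validate a fragment table
#'
#' A fragment table is a data.frame with one row per sequenced cfDNA
#' template: `chrom` (character), `start` < `end` (0-based half-open
#' integers), `strand` of read 1 (`+`/`-`), `mapq` (0..255), `mismatches`
#' (>= 0), and logical `proper_pair`, `duplicate`, `multimapped`.
#'
#' @param df data.frame with the nine fragment columns.
#' @return the validated data.frame (class `fragment_table` prepended).
#' @export
fragment_table <- function(df) {
  missing_cols <- setdiff(FRAGMENT_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("fragment table missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df <- as.data.frame(df)[FRAGMENT_COLUMNS]
  df$chrom <- as.character(df$chrom)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$strand <- as.character(df$strand)
  df$mapq <- as.integer(df$mapq)
  df$mismatches <- as.integer(df$mismatches)
  for (col in c("proper_pair", "duplicate", "multimapped")) {
    df[[col]] <- as.logical(df[[col]])
  }
  bad <- which(!(df$start < df$end))
  if (length(bad) > 0L) {
    stop(sprintf("fragment record %d: start (%d) must be < end (%d)",
                 bad[1], df$start[bad[1]], df$end[bad[1]]), call. = FALSE)
  }
  bad <- which(df$start < 0L)
  if (length(bad) > 0L) {
    stop(sprintf("fragment record %d: negative start", bad[1]), call. = FALSE)
  }
  bad <- which(df$mapq < 0L | df$mapq > 255L)
  if (length(bad) > 0L) {
    stop(sprintf("fragment record %d: mapq out of [0, 255]", bad[1]),
         call. = FALSE)
  }
  bad <- which(df$mismatches < 0L)
  if (length(bad) > 0L) {
    stop(sprintf("fragment record %d: negative mismatch count", bad[1]),
         call. = FALSE)
  }
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad) > 0L) {
    stop(sprintf("fragment record %d: strand must be + or -", bad[1]),
         call. = FALSE)
  }
  class(df) <- c("fragment_table", class(df))
  df
}

#' Read aligned cfDNA fragments
#'
#' Two dialects are supported. `"fragment-table"` is the package's 9-column
#' tab-separated serialisation of fragment records (`#`-prefixed header,
#' 0-based half-open coordinates, 0/1 logical columns). `"alignment"` reads
#' coordinate-sorted SAM/BAM via Rsamtools and collapses each properly
#' book-kept read pair to one fragment: start is the leftmost 1-based
#' position minus one, the insert size is taken from the template length
#' field, mapq is the pair minimum, the mismatch count is the maximum of the
#' two reads' NM tags (per-fragment reading of the mismatch filter), and a
#' template is flagged multimapped when any secondary/supplementary record
#' shares its name. Unpaired (orphan) primary reads are skipped and counted.
#'
#' @param path input file.
#' @param dialect `"fragment-table"` or `"alignment"`.
#' @return a `fragment_table`; for the alignment dialect the attribute
#'   `orphan_count` carries the number of skipped orphan reads.
#' @export
read_fragments <- function(path, dialect = c("fragment-table", "alignment")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  if (dialect == "fragment-table") {
    read_fragment_table(path)
  } else {
    read_fragments_alignment(path)
  }
}

read_fragment_table <- function(path) {
  lines <- readLines(path)
  header <- startsWith(lines, "#")
  body_idx <- which(!header)
  if (length(body_idx) == 0L) {
    return(fragment_table(data.frame(
      chrom = character(0), start = integer(0), end = integer(0),
      strand = character(0), mapq = integer(0), mismatches = integer(0),
      proper_pair = logical(0), duplicate = logical(0),
      multimapped = logical(0))))
  }
  parts <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 9L)) {
    bad <- body_idx[which(nf != 9L)[1]]
    stop(sprintf("parse error at line %d of %s: expected 9 tab-separated fields, got %d",
                 bad, path, nf[which(nf != 9L)[1]]), call. = FALSE)
  }
  m <- matrix(unlist(parts), ncol = 9L, byrow = TRUE)
  to_int <- function(j, what) {
    v <- suppressWarnings(as.integer(m[, j]))
    if (anyNA(v)) {
      bad <- body_idx[which(is.na(v))[1]]
      stop(sprintf("parse error at line %d of %s: non-integer %s",
                   bad, path, what), call. = FALSE)
    }
    v
  }
  df <- data.frame(
    chrom = m[, 1], start = to_int(2L, "start"), end = to_int(3L, "end"),
    strand = m[, 4], mapq = to_int(5L, "mapq"),
    mismatches = to_int(6L, "mismatches"),
    proper_pair = to_int(7L, "proper_pair") != 0L,
    duplicate = to_int(8L, "duplicate") != 0L,
    multimapped = to_int(9L, "multimapped") != 0L,
    stringsAsFactors = FALSE)
  bad <- which(!(df$start < df$end))
  if (length(bad) > 0L) {
    stop(sprintf("parse error at line %d of %s: start >= end",
                 body_idx[bad[1]], path), call. = FALSE)
  }
  fragment_table(df)
}

read_fragments_alignment <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path,
                            destination = tempfile(fileext = ""),
                            overwrite = TRUE, indexDestination = FALSE)
  }
  what <- c("qname", "flag", "rname", "pos", "mapq", "isize")
  res <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(what = what, tag = "NM"))[[1]]
  qname <- res$qname
  flag <- res$flag
  secondary <- bitwAnd(flag, 0x100L) != 0L | bitwAnd(flag, 0x800L) != 0L
  multi_names <- unique(qname[secondary])
  keep <- !secondary & bitwAnd(flag, 0x4L) == 0L
  qname <- qname[keep]
  flag <- flag[keep]
  rname <- as.character(res$rname)[keep]
  pos <- res$pos[keep]
  mapq <- res$mapq[keep]
  isize <- res$isize[keep]
  nm <- res$tag$NM[keep]
  if (is.null(nm)) nm <- rep(0L, length(qname))
  nm[is.na(nm)] <- 0L
  ord <- order(qname)
  qname <- qname[ord]; flag <- flag[ord]; rname <- rname[ord]
  pos <- pos[ord]; mapq <- mapq[ord]; isize <- isize[ord]; nm <- nm[ord]
  first_of_pair <- !duplicated(qname)
  counts <- table(qname)
  paired_names <- names(counts)[counts == 2L]
  orphan_count <- sum(counts != 2L)
  sel1 <- first_of_pair & qname %in% paired_names
  sel2 <- !first_of_pair & qname %in% paired_names
  i1 <- which(sel1); i2 <- which(sel2)
  ## which of the two primary records is read 1 (flag 0x40)
  r1_is_first <- bitwAnd(flag[i1], 0x40L) != 0L
  strand_src_flag <- ifelse(r1_is_first, flag[i1], flag[i2])
  strand <- ifelse(bitwAnd(strand_src_flag, 0x10L) != 0L, "-", "+")
  start0 <- pmin(pos[i1], pos[i2]) - 1L
  span <- pmax(abs(isize[i1]), abs(isize[i2]))
  span[is.na(span) | span == 0L] <- (abs(pos[i1] - pos[i2]) + 1L)[is.na(span) | span == 0L]
  df <- data.frame(
    chrom = rname[i1], start = start0, end = start0 + span,
    strand = strand,
    mapq = pmin(mapq[i1], mapq[i2]),
    mismatches = pmax(nm[i1], nm[i2]),
    proper_pair = bitwAnd(flag[i1], 0x2L) != 0L,
    duplicate = bitwAnd(flag[i1], 0x400L) != 0L |
      bitwAnd(flag[i2], 0x400L) != 0L,
    multimapped = qname[i1] %in% multi_names,
    stringsAsFactors = FALSE)
  ## restore coordinate order
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  out <- fragment_table(df)
  attr(out, "orphan_count") <- orphan_count
  out
}

#' Write a fragment table
#'
#' Serialises to the 9-column tab-separated fragment-table dialect. The
#' round trip `read_fragments(write_fragments(x))` is the identity.
#'
#' @param fragments a `fragment_table` (or coercible data.frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fragments, path) {
  fragments <- fragment_table(fragments)
  if (any(grepl("\t", fragments$chrom, fixed = TRUE))) {
    stop("write_fragments: chromosome names must not contain tabs",
         call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(FRAGMENT_COLUMNS, collapse = "\t")), con)
  if (nrow(fragments) > 0L) {
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%d\t%d\t%d",
                       fragments$chrom, fragments$start, fragments$end,
                       fragments$strand, fragments$mapq, fragments$mismatches,
                       as.integer(fragments$proper_pair),
                       as.integer(fragments$duplicate),
                       as.integer(fragments$multimapped)), con)
  }
  invisible(path)
}

#' Retention-filter configuration
#'
#' Defaults reproduce the study's post-alignment rules: mapping quality at
#' least 30, at most five mismatches, insert size strictly below 600 bp,
#' proper pairs only, duplicates and multi-mapped templates dropped.
#'
#' @param min_mapq minimum mapping quality retained (default 30).
#' @param max_mismatches maximum mismatch count retained (default 5).
#' @param max_insert exclusive insert-size bound in bp (default 600).
#' @param require_proper_pair,drop_duplicates,drop_multimapped logical rule
#'   switches (all default TRUE).
#' @return list of class `filter_config`.
#' @export
filter_config <- function(min_mapq = 30L, max_mismatches = 5L,
                          max_insert = 600L, require_proper_pair = TRUE,
                          drop_duplicates = TRUE, drop_multimapped = TRUE) {
  stopifnot_scalar_number(min_mapq, "min_mapq", lower = 0, integerish = TRUE)
  stopifnot_scalar_number(max_mismatches, "max_mismatches", lower = 0,
                          integerish = TRUE)
  stopifnot_scalar_number(max_insert, "max_insert", lower = 1,
                          integerish = TRUE)
  structure(list(min_mapq = as.integer(min_mapq),
                 max_mismatches = as.integer(max_mismatches),
                 max_insert = as.integer(max_insert),
                 require_proper_pair = isTRUE(require_proper_pair),
                 drop_duplicates = isTRUE(drop_duplicates),
                 drop_multimapped = isTRUE(drop_multimapped)),
            class = "filter_config")
}

## Fixed rule-charging order: a removed fragment is charged to the first
## failing rule in this order.
FILTER_RULES <- c("duplicate", "multimapped", "mapq", "mismatches",
                  "proper_pair", "insert")

#' Apply the post-alignment retention filters
#'
#' Retains fragments that pass every enabled rule; each removed fragment is
#' charged to the first failing rule in the fixed order duplicate ->
#' multimapped -> mapq -> mismatches -> proper_pair -> insert, so the
#' accounting always sums exactly to the input count.
#'
#' @param fragments a `fragment_table`.
#' @param cfg a [filter_config()].
#' @return list with `retained` (fragment table) and `stats` (list with
#'   `input_count`, `retained_count`, `removed_by_rule`).
#' @export
filter_fragments <- function(fragments, cfg = filter_config()) {
  fragments <- fragment_table(fragments)
  n <- nrow(fragments)
  fail <- list(
    duplicate   = cfg$drop_duplicates & fragments$duplicate,
    multimapped = cfg$drop_multimapped & fragments$multimapped,
    mapq        = fragments$mapq < cfg$min_mapq,
    mismatches  = fragments$mismatches > cfg$max_mismatches,
    proper_pair = cfg$require_proper_pair & !fragments$proper_pair,
    insert      = (fragments$end - fragments$start) >= cfg$max_insert
  )
  charged <- rep(NA_character_, n)
  for (rule in FILTER_RULES) {
    hit <- is.na(charged) & fail[[rule]]
    charged[hit] <- rule
  }
  retained <- fragments[is.na(charged), , drop = FALSE]
  rownames(retained) <- NULL
  removed <- vapply(FILTER_RULES, function(r) sum(charged == r, na.rm = TRUE),
                    integer(1))
  stats <- list(input_count = n,
                retained_count = nrow(retained),
                removed_by_rule = as.list(removed))
  stopifnot(stats$input_count ==
              stats$retained_count + sum(unlist(stats$removed_by_rule)))
  list(retained = retained, stats = stats)
}
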