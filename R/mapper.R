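# Built-in read mapper: seed-and-extend against a k-mer index of the
# target, ungapped X-drop extension with clipping, and a one-sided tail
# rescue that re-anchors a clipped 3' tail at a small shift to recover
# short InDels. Alignments read from external SAM files are accepted by the
# downstream modules in the same tabular form.

#' Map reads to a set of target sequences
#'
#' @param targets sequence record table (or named character vector).
#' @param reads character vector of read sequences, or a read table from
#'   [as_read_table()].
#' @param k seed k-mer length (default 25).
#' @param nseeds number of seed offsets tried per orientation.
#' @param max_occ seeds occurring more often than this in the target are
#'   skipped.
#' @param ambig_margin reads whose best placement beats the runner-up (for
#'   the same part of the read) by less than this score margin are dropped
#'   as ambiguous.
#' @param tail_rescue re-anchor clipped 3' tails across small shifts,
#'   producing InDel observations (default TRUE).
#' @return data.frame with read (index into `reads`), read_id, target_id,
#'   tstart/tend (target window), qstart/qend (window on the oriented
#'   read), strand, nmis, max_exact (longest exact stretch), score and tail
#'   rescue columns (tail_len, tail_shift, tail_mis; tail_shift > 0 is a
#'   deletion of that many target bases at the junction, < 0 an insertion).
#' @export
map_reads <- function(targets, reads, k = 25, nseeds = 5, max_occ = 200,
                      ambig_margin = 5, tail_rescue = TRUE) {
  tg <- as_target_vec(targets)
  read_ids <- NULL
  if (is.data.frame(reads)) {
    read_ids <- reads$id
    reads <- reads$seq
  }
  stopifnot(k >= 8, k <= 32)
  aln <- cg_map_reads(unname(tg), reads, k = k, nseeds = nseeds,
                      max_occ = max_occ, ambig_margin = ambig_margin,
                      tail_rescue = tail_rescue)
  aln$target_id <- names(tg)[aln$target]
  if (!is.null(read_ids)) aln$read_id <- read_ids[aln$read]
  aln
}

as_target_vec <- function(targets) {
  if (is.data.frame(targets)) {
    validate_seq_records(targets)
    stats::setNames(targets$sequence, targets$id)
  } else {
    stopifnot(is.character(targets), !is.null(names(targets)))
    targets
  }
}

#' Pair up mate alignments and classify orientation
#'
#' Joins the alignments of the two mates of each pair and classifies the
#' pair's orientation on the target: FR when the leftmost mate is on the
#' plus strand and the mates converge (short-insert fragments), RF when the
#' leftmost mate is on the minus strand (outward-facing mate pairs). The
#' observed insert is the outer distance, rightmost end minus leftmost
#' start.
#'
#' @param aln alignment table from [map_reads()] run on a read table.
#' @param read_table the read table ([as_read_table()]).
#' @return data.frame, one row per pair with both mates mapped to the same
#'   target: pair, lib, target_id, left_start, left_end, left_strand,
#'   right_start, right_end, right_strand, left_max_exact, right_max_exact,
#'   orientation ("FR", "RF" or "tandem"), insert.
#' @export
pair_alignments <- function(aln, read_table) {
  a <- aln
  a$pair <- read_table$pair[a$read]
  a$is_first <- grepl("/1$", read_table$id[a$read])
  a$lib <- read_table$lib[a$read]
  # keep pairs with exactly one alignment per mate
  first <- a[a$is_first, ]
  second <- a[!a$is_first, ]
  first <- first[!duplicated(first$pair), ]
  second <- second[!duplicated(second$pair), ]
  m <- merge(first, second, by = "pair", suffixes = c(".1", ".2"))
  m <- m[m$target_id.1 == m$target_id.2, , drop = FALSE]
  if (!nrow(m))
    return(data.frame(pair = integer(0), lib = character(0),
                      target_id = character(0), left_start = numeric(0),
                      left_end = numeric(0), left_strand = character(0),
                      right_start = numeric(0), right_end = numeric(0),
                      right_strand = character(0), left_max_exact = integer(0),
                      right_max_exact = integer(0), orientation = character(0),
                      insert = numeric(0), stringsAsFactors = FALSE))
  first_left <- m$tstart.1 <= m$tstart.2
  pick <- function(col1, col2) ifelse(first_left, m[[col1]], m[[col2]])
  out <- data.frame(
    pair = m$pair, lib = m$lib.1, target_id = m$target_id.1,
    left_start = pick("tstart.1", "tstart.2"),
    left_end = pick("tend.1", "tend.2"),
    left_strand = pick("strand.1", "strand.2"),
    right_start = pick("tstart.2", "tstart.1"),
    right_end = pick("tend.2", "tend.1"),
    right_strand = pick("strand.2", "strand.1"),
    left_max_exact = pick("max_exact.1", "max_exact.2"),
    right_max_exact = pick("max_exact.2", "max_exact.1"),
    stringsAsFactors = FALSE)
  out$orientation <- ifelse(out$left_strand == out$right_strand, "tandem",
                            ifelse(out$left_strand == "+", "FR", "RF"))
  out$insert <- out$right_end - out$left_start
  out
}

#' Build a pileup from alignments
#'
#' Accumulates per-position base counts over the targets from the aligned
#' (unclipped) windows of each read, including rescued tail segments, and
#' collects InDel observations from tail rescues.
#'
#' @param targets sequence record table (or named character vector).
#' @param reads character vector of read sequences or a read table.
#' @param aln alignment table from [map_reads()].
#' @return classed list `congener_pileup`: ids, ref (target sequences),
#'   counts (per target a 4 x length integer matrix, rows A/C/G/T) and
#'   indels (data.frame chrom, pos, type, len, seq, count; pos is the
#'   0-based anchor base before the event, VCF-style).
#' @export
build_pileup <- function(targets, reads, aln) {
  tg <- as_target_vec(targets)
  if (is.data.frame(reads)) reads <- reads$seq
  counts <- cg_pileup(unname(tg), reads, aln$read, aln$target, aln$tstart,
                      aln$qstart, aln$qend, aln$strand, aln$tail_len,
                      aln$tail_shift, aln$tail_trim)
  names(counts) <- names(tg)
  # indel observations from rescued tails
  k <- which(aln$tail_shift != 0L)
  indels <- data.frame(chrom = character(0), pos = numeric(0),
                       type = character(0), len = integer(0),
                       seq = character(0), count = integer(0),
                       stringsAsFactors = FALSE)
  if (length(k)) {
    tend_main <- aln$tstart[k] + (aln$qend[k] - aln$qstart[k])
    type <- ifelse(aln$tail_shift[k] > 0, "DEL", "INS")
    len <- abs(aln$tail_shift[k])
    oriented <- reads[aln$read[k]]
    neg <- aln$strand[k] == "-"
    oriented[neg] <- revcomp(oriented[neg])
    ins_seq <- ifelse(type == "INS",
                      substr(oriented, aln$qend[k] + 1L, aln$qend[k] + len),
                      "")
    obs <- data.frame(chrom = aln$target_id[k], pos = tend_main - 1,
                      type = type, len = len, seq = ins_seq,
                      stringsAsFactors = FALSE)
    agg <- stats::aggregate(list(count = rep(1L, nrow(obs))),
                            obs[c("chrom", "pos", "type", "len", "seq")],
                            FUN = sum)
    indels <- agg[order(agg$chrom, agg$pos), , drop = FALSE]
    rownames(indels) <- NULL
  }
  structure(list(ids = names(tg), ref = tg, counts = counts, indels = indels),
            class = "congener_pileup")
}

#' @export
print.congener_pileup <- function(x, ...) {
  cat("pileup over", length(x$ids), "targets,",
      sum(vapply(x$counts, function(m) sum(m > 0), numeric(1))),
      "nonzero count cells,", nrow(x$indels), "distinct indel observations\n")
  invisible(x)
}

#' Extract pileup columns as a data.frame
#'
#' Mostly for inspection and small tests; the caller can restrict to a
#' window to keep the result small.
#'
#' @param pileup a `congener_pileup`.
#' @param chrom target id.
#' @param start,end 0-based half-open window (defaults to whole target).
#' @return data.frame with chrom, pos, ref, depth, A, C, G, T.
#' @export
pileup_columns <- function(pileup, chrom, start = 0, end = NULL) {
  stopifnot(inherits(pileup, "congener_pileup"), chrom %in% pileup$ids)
  m <- pileup$counts[[chrom]]
  end <- end %||% ncol(m)
  idx <- (start + 1L):end
  refb <- strsplit(substr(pileup$ref[[chrom]], start + 1L, end), "")[[1]]
  data.frame(chrom = chrom, pos = idx - 1L, ref = refb,
             depth = colSums(m[, idx, drop = FALSE]),
             A = m[1, idx], C = m[2, idx], G = m[3, idx], T = m[4, idx],
             stringsAsFactors = FALSE)
}
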