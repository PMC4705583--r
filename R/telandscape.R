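# Transposable-element comparative statistics: hit filtering, per-family
# genome coverage, Kimura two-parameter age landscapes, and genome vs
# transcriptome representation tables.
#
# Transitions (p) are purine<->purine or pyrimidine<->pyrimidine changes
# (A<->G, C<->T); transversions (q) are purine<->pyrimidine changes. The
# two-parameter distance K = -1/2 ln(1 - 2p - q) - 1/4 ln(1 - 2q) serves as
# an age proxy for each inserted copy under the assumption that copies
# accumulate neutral mutations after insertion.

#' Filter TE hits by length and identity
#'
#' Hits shorter than `min_length` bases or sharing less than `min_identity`
#' percent identity with their library consensus (identity = 100 - percent
#' divergence) are discarded; both boundaries are inclusive for retention.
#'
#' @param hits repeat hit table ([read_repeat_out()]).
#' @param min_length bp (default 80).
#' @param min_identity percent (default 80).
#' @return the retained hit rows.
#' @export
filter_te_hits <- function(hits, min_length = 80, min_identity = 80) {
  stopifnot(min_length >= 0, min_identity >= 0)
  len <- hits$end - hits$start
  identity <- 100 - hits$percent_divergence
  hits[len >= min_length & identity >= min_identity, , drop = FALSE]
}

#' Per-superfamily genome coverage table
#'
#' Covered bases are per-position unions. Within a superfamily class,
#' overlapping hits count once; where hits of different classes overlap,
#' the position is assigned to the longer hit (ties broken by earlier
#' start, then class name), and the Total row counts every covered
#' position exactly once.
#'
#' @param hits repeat hit table with chrom, start, end, superfamily_class.
#' @param genome_length total genome size for percentages.
#' @return data.frame: superfamily_class, covered_bp, percent_of_genome,
#'   copy_count; final row "Total".
#' @export
coverage_table <- function(hits, genome_length) {
  classes <- sort(unique(hits$superfamily_class))
  covered <- setNames(numeric(length(classes)), classes)
  copies <- setNames(as.integer(table(hits$superfamily_class)[classes]),
                     classes)
  total_covered <- 0
  for (chrom in unique(hits$chrom)) {
    h <- hits[hits$chrom == chrom, , drop = FALSE]
    o <- order(-(h$end - h$start), h$start, h$superfamily_class)
    occupied <- IRanges::IRanges()
    for (i in o) {
      r <- IRanges::IRanges(h$start[i] + 1L, h$end[i])
      free <- IRanges::setdiff(r, occupied)
      w <- sum(IRanges::width(free))
      covered[h$superfamily_class[i]] <- covered[h$superfamily_class[i]] + w
      occupied <- IRanges::reduce(c(occupied, free))
    }
    total_covered <- total_covered + sum(IRanges::width(occupied))
  }
  out <- data.frame(superfamily_class = c(classes, "Total"),
                    covered_bp = c(unname(covered), total_covered),
                    percent_of_genome = 100 *
                      c(unname(covered), total_covered) / genome_length,
                    copy_count = c(unname(copies), nrow(hits)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Kimura two-parameter distance
#'
#' K = -1/2 ln(1 - 2p - q) - 1/4 ln(1 - 2q), where p is the transition and
#' q the transversion proportion. Outside the domain (2p + q >= 1 or
#' 2q >= 1) the distance is undefined and NA is returned with a warning.
#'
#' @param p transition proportion(s).
#' @param q transversion proportion(s).
#' @return numeric vector of distances.
#' @export
kimura_distance <- function(p, q) {
  stopifnot(length(p) == length(q) || length(p) == 1 || length(q) == 1)
  n <- max(length(p), length(q))
  p <- rep_len(p, n); q <- rep_len(q, n)
  bad <- p < 0 | q < 0 | (1 - 2 * p - q) <= 0 | (1 - 2 * q) <= 0
  k <- rep(NA_real_, n)
  k[!bad] <- -0.5 * log(1 - 2 * p[!bad] - q[!bad]) -
    0.25 * log(1 - 2 * q[!bad])
  if (any(bad))
    warning(sum(bad), " (p, q) pair(s) outside the K2P domain; NA returned")
  k
}

PURINES <- c("A", "G")

#' Transition/transversion proportions from a pairwise alignment
#'
#' Columns containing gaps ("-") or N are excluded from the aligned-site
#' count. p counts purine<->purine and pyrimidine<->pyrimidine mismatches,
#' q purine<->pyrimidine mismatches.
#'
#' @param copy aligned genome copy sequence (string, may contain "-").
#' @param consensus aligned library consensus of equal length.
#' @return list(p, q, aligned_sites).
#' @export
pq_from_alignment <- function(copy, consensus) {
  stopifnot(nchar(copy) == nchar(consensus))
  a <- strsplit(toupper(copy), "")[[1]]
  b <- strsplit(toupper(consensus), "")[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n == 0) stop("no aligned sites after excluding gaps and N")
  mism <- a != b
  same_type <- (a %in% PURINES) == (b %in% PURINES)
  list(p = sum(mism & same_type) / n,
       q = sum(mism & !same_type) / n,
       aligned_sites = n)
}

#' TE age landscape over Kimura-distance bins
#'
#' Accumulates covered bases per superfamily into integer-width K bins on
#' the 0-50 axis (K expressed as a percentage, i.e. distance x 100).
#' Records with K above 50 go to an overflow bin.
#'
#' @param hits data.frame with superfamily_class, K (0-100 percent scale)
#'   and covered bp per hit (column `bp`, or end - start when absent).
#' @param genome_length optional; adds a percent-of-genome column.
#' @return data.frame: bin_low, bin_high (NA for overflow),
#'   superfamily_class, bp, and percent if genome_length is given.
#' @export
te_landscape <- function(hits, genome_length = NULL) {
  bp <- hits$bp %||% (hits$end - hits$start)
  stopifnot(!is.null(hits$K), all(hits$K >= 0, na.rm = TRUE))
  bin <- ifelse(hits$K > 50, NA_integer_, pmin(floor(hits$K), 49L))
  classes <- sort(unique(hits$superfamily_class))
  grid <- expand.grid(bin_low = 0:49, superfamily_class = classes,
                      stringsAsFactors = FALSE)
  key <- paste(grid$bin_low, grid$superfamily_class)
  acc <- setNames(numeric(nrow(grid)), key)
  ok <- !is.na(bin) & !is.na(hits$K)
  if (any(ok)) {
    add <- tapply(bp[ok], paste(bin[ok], hits$superfamily_class[ok]), sum)
    acc[names(add)] <- acc[names(add)] + add
  }
  out <- data.frame(bin_low = grid$bin_low, bin_high = grid$bin_low + 1,
                    superfamily_class = grid$superfamily_class,
                    bp = unname(acc), stringsAsFactors = FALSE)
  over <- !is.na(hits$K) & hits$K > 50
  if (any(over)) {
    ov <- tapply(bp[over], hits$superfamily_class[over], sum)
    out <- rbind(out, data.frame(bin_low = NA_real_, bin_high = NA_real_,
                                 superfamily_class = names(ov),
                                 bp = unname(ov), stringsAsFactors = FALSE))
  }
  if (!is.null(genome_length))
    out$percent <- 100 * out$bp / genome_length
  out
}

#' Genome vs transcriptome TE representation (spider) table
#'
#' Log10 percentages of each superfamily in the genome and the
#' transcriptome, with a representation flag: "over" when the
#' transcriptome share exceeds the genome share by at least
#' `ratio_threshold`-fold, "under" for the reverse, "proportional"
#' otherwise and "absent" when either percentage is zero.
#'
#' @param genome_cov coverage table for the genome ([coverage_table()]).
#' @param tx_cov coverage table for the transcriptome.
#' @param ratio_threshold fold-change needed to flag (default 2).
#' @return data.frame: superfamily_class, genome_log10_percent,
#'   tx_log10_percent, flag.
#' @export
spider_table <- function(genome_cov, tx_cov, ratio_threshold = 2) {
  g <- genome_cov[genome_cov$superfamily_class != "Total", , drop = FALSE]
  t <- tx_cov[tx_cov$superfamily_class != "Total", , drop = FALSE]
  m <- merge(g[c("superfamily_class", "percent_of_genome")],
             t[c("superfamily_class", "percent_of_genome")],
             by = "superfamily_class", suffixes = c(".g", ".t"), all = TRUE)
  pg <- ifelse(is.na(m$percent_of_genome.g), 0, m$percent_of_genome.g)
  pt <- ifelse(is.na(m$percent_of_genome.t), 0, m$percent_of_genome.t)
  flag <- ifelse(pg == 0 | pt == 0, "absent",
          ifelse(pt / pg >= ratio_threshold, "over",
          ifelse(pg / pt >= ratio_threshold, "under", "proportional")))
  data.frame(superfamily_class = m$superfamily_class,
             genome_log10_percent = ifelse(pg > 0, log10(pg), NA_real_),
             tx_log10_percent = ifelse(pt > 0, log10(pt), NA_real_),
             flag = flag, stringsAsFactors = FALSE)
}
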