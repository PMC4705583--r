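# Scaffold-to-chromosome placement and comparative chromosome analyses:
# anchor-based alignment (MUM-style unique-k-mer seeding, colinear
# chaining), AGP chromosome construction, assembly statistics, the 20 kb
# inter-chromosomal rearrangement rule, and reciprocal-best ortholog
# dot-plot tables.

#' Anchor-based alignment of query sequences to a reference
#'
#' Finds exact unique-k-mer matches, merges same-diagonal runs, and chains
#' colinear anchors into clusters where consecutive anchors are at most
#' `max_gap` apart on both sequences. Clusters with fewer than
#' `min_cluster` matched bases are discarded. Cluster identity is computed
#' over the chained segments: matched anchor bases count as identical, and
#' equal-length inter-anchor gaps are compared base by base (unequal gaps
#' are excluded).
#'
#' @param query sequence record table (scaffolds or contigs).
#' @param reference sequence record table (chromosomes).
#' @param seed_len anchor seed k-mer length (default 20).
#' @param min_cluster minimum total matched bases per retained cluster
#'   (default 400).
#' @param max_gap maximum gap between chained anchors on either sequence
#'   (default 500).
#' @return data.frame of clusters: query_id, target_id, qstart, qend (on
#'   the original query strand), tstart, tend, strand, total_match,
#'   mean_identity, n_anchors.
#' @export
anchor_map <- function(query, reference, seed_len = 20, min_cluster = 400,
                       max_gap = 500) {
  qv <- as_target_vec(query)
  rv <- as_target_vec(reference)
  stopifnot(length(qv) > 0, length(rv) > 0, seed_len >= 12, seed_len <= 32)
  anch <- cg_anchor_seeds(unname(rv), unname(qv), seed_len)
  if (!nrow(anch))
    return(empty_clusters())
  qlen <- nchar(qv)
  out <- list()
  grp <- paste(anch$query, anch$target, anch$strand)
  grp_idx <- split(seq_len(nrow(anch)), grp)
  for (g in names(grp_idx)) {
    a <- anch[grp_idx[[g]], , drop = FALSE]
    a <- a[order(a$qstart), , drop = FALSE]
    qi <- a$query[1]; ti <- a$target[1]; str <- a$strand[1]
    qend <- a$qstart + a$len
    tend <- a$tstart + a$len
    # chain: break when gaps exceed max_gap or colinearity is violated
    newc <- c(TRUE, (a$qstart[-1] - qend[-nrow(a)] > max_gap) |
                    (a$tstart[-1] - tend[-nrow(a)] > max_gap) |
                    (a$tstart[-1] < a$tstart[-nrow(a)]))
    cid <- cumsum(newc)
    for (cc in unique(cid)) {
      k <- cid == cc
      ca <- a[k, , drop = FALSE]
      ir <- IRanges::reduce(IRanges::IRanges(ca$qstart + 1L,
                                             ca$qstart + ca$len))
      total_match <- sum(IRanges::width(ir))
      if (total_match < min_cluster) next
      # identity over equal-length chain gaps
      gm <- 0L; gc <- 0L
      if (nrow(ca) > 1) {
        qg_s <- (ca$qstart + ca$len)[-nrow(ca)]
        qg_e <- ca$qstart[-1]
        tg_s <- (ca$tstart + ca$len)[-nrow(ca)]
        tg_e <- ca$tstart[-1]
        eq <- (qg_e - qg_s) == (tg_e - tg_s) & (qg_e - qg_s) > 0
        if (any(eq)) {
          qseq <- if (str == "+") qv[[qi]] else revcomp(qv[[qi]])
          for (j in which(eq)) {
            s1 <- substr(qseq, qg_s[j] + 1L, qg_e[j])
            s2 <- substr(rv[[ti]], tg_s[j] + 1L, tg_e[j])
            v1 <- charToRaw(s1); v2 <- charToRaw(s2)
            gm <- gm + sum(v1 == v2)
            gc <- gc + length(v1)
          }
        }
      }
      ident <- (total_match + gm) / (total_match + gc)
      qs <- min(ca$qstart); qe <- max(ca$qstart + ca$len)
      if (str == "-") {  # convert rc coordinates back to the original strand
        L <- qlen[qi]
        tmp <- qs
        qs <- L - qe
        qe <- L - tmp
      }
      out[[length(out) + 1L]] <- data.frame(
        query_id = names(qv)[qi], target_id = names(rv)[ti],
        qstart = qs, qend = qe,
        tstart = min(ca$tstart), tend = max(ca$tstart + ca$len),
        strand = str, total_match = total_match, mean_identity = ident,
        n_anchors = nrow(ca), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_clusters())
  res <- do.call(rbind, out)
  res[order(res$query_id, res$target_id, res$qstart), , drop = FALSE]
}

empty_clusters <- function() {
  data.frame(query_id = character(0), target_id = character(0),
             qstart = numeric(0), qend = numeric(0), tstart = numeric(0),
             tend = numeric(0), strand = character(0),
             total_match = numeric(0), mean_identity = numeric(0),
             n_anchors = integer(0), stringsAsFactors = FALSE)
}

#' Place scaffolds onto reference chromosomes
#'
#' Each scaffold is assigned to the chromosome carrying the greatest summed
#' cluster match; if the runner-up chromosome is within 10 % of the winner
#' the assignment is ambiguous and the scaffold goes to "unplaced".
#' Orientation is the strand carrying the majority of matched bases;
#' placed scaffolds are ordered along each chromosome by the median target
#' coordinate of their clusters. The AGP places 100 bp N gaps between
#' consecutive scaffolds.
#'
#' @param clusters cluster table from [anchor_map()].
#' @param scaffolds scaffold sequence table (for lengths).
#' @param tie_fraction runner-up-within-this-fraction rule (default 0.1).
#' @param gap_len inter-scaffold AGP gap (default 100).
#' @return list(placements = data.frame(scaffold, chromosome, orientation,
#'   order_key, matched_bp, status), agp = AGP row data.frame).
#' @export
place_scaffolds <- function(clusters, scaffolds, tie_fraction = 0.1,
                            gap_len = 100) {
  validate_seq_records(scaffolds)
  plc <- list()
  for (sid in scaffolds$id) {
    cc <- clusters[clusters$query_id == sid, , drop = FALSE]
    if (!nrow(cc)) {
      plc[[sid]] <- data.frame(scaffold = sid, chromosome = NA_character_,
                               orientation = NA_character_,
                               order_key = NA_real_, matched_bp = 0,
                               status = "unplaced", stringsAsFactors = FALSE)
      next
    }
    bp <- tapply(cc$total_match, cc$target_id, sum)
    bp <- sort(bp, decreasing = TRUE)
    if (length(bp) > 1 && bp[2] >= (1 - tie_fraction) * bp[1]) {
      plc[[sid]] <- data.frame(scaffold = sid, chromosome = NA_character_,
                               orientation = NA_character_,
                               order_key = NA_real_, matched_bp = bp[[1]],
                               status = "unplaced", stringsAsFactors = FALSE)
      next
    }
    best <- names(bp)[1]
    cb <- cc[cc$target_id == best, , drop = FALSE]
    plus_bp <- sum(cb$total_match[cb$strand == "+"])
    orientation <- if (plus_bp >= sum(cb$total_match) / 2) "+" else "-"
    plc[[sid]] <- data.frame(
      scaffold = sid, chromosome = best, orientation = orientation,
      order_key = median((cb$tstart + cb$tend) / 2), matched_bp = bp[[1]],
      status = "placed", stringsAsFactors = FALSE)
  }
  placements <- do.call(rbind, plc)
  rownames(placements) <- NULL
  # AGP per chromosome
  slen <- setNames(nchar(scaffolds$sequence), scaffolds$id)
  agp_rows <- list()
  for (chrom in sort(unique(placements$chromosome[placements$status == "placed"]))) {
    p <- placements[placements$status == "placed" &
                    placements$chromosome == chrom, , drop = FALSE]
    p <- p[order(p$order_key), , drop = FALSE]
    at <- 0L; part <- 0L
    for (i in seq_len(nrow(p))) {
      if (i > 1) {
        part <- part + 1L
        agp_rows[[length(agp_rows) + 1L]] <- data.frame(
          object = chrom, object_beg = at + 1L, object_end = at + gap_len,
          part_number = part, component_type = "N",
          component_id = as.character(gap_len), component_beg = "scaffold",
          component_end = "yes", orientation = "align_genus",
          stringsAsFactors = FALSE)
        at <- at + gap_len
      }
      part <- part + 1L
      L <- slen[[p$scaffold[i]]]
      agp_rows[[length(agp_rows) + 1L]] <- data.frame(
        object = chrom, object_beg = at + 1L, object_end = at + L,
        part_number = part, component_type = "W",
        component_id = p$scaffold[i], component_beg = "1",
        component_end = as.character(L), orientation = p$orientation[i],
        stringsAsFactors = FALSE)
      at <- at + L
    }
  }
  agp <- if (length(agp_rows)) do.call(rbind, agp_rows) else
    data.frame(object = character(0), object_beg = integer(0),
               object_end = integer(0), part_number = integer(0),
               component_type = character(0), component_id = character(0),
               component_beg = character(0), component_end = character(0),
               orientation = character(0), stringsAsFactors = FALSE)
  list(placements = placements, agp = agp)
}

#' Assemble chromosome sequences from placements
#'
#' Concatenates placed scaffolds (reverse-complementing minus-orientation
#' ones) in placement order with N gaps; unplaced scaffolds are returned
#' separately, never dropped.
#'
#' @param scaffolds scaffold sequence table.
#' @param placements placement table from [place_scaffolds()].
#' @param gap_len gap between scaffolds (default 100).
#' @return list(chromosomes = sequence table (tier "chromosome"),
#'   unplaced = sequence table of unplaced scaffolds).
#' @export
build_chromosomes <- function(scaffolds, placements, gap_len = 100) {
  validate_seq_records(scaffolds)
  chroms <- list()
  for (chrom in sort(unique(placements$chromosome[placements$status == "placed"]))) {
    p <- placements[placements$status == "placed" &
                    placements$chromosome == chrom, , drop = FALSE]
    p <- p[order(p$order_key), , drop = FALSE]
    seqs <- vapply(seq_len(nrow(p)), function(i) {
      sq <- scaffolds$sequence[match(p$scaffold[i], scaffolds$id)]
      if (p$orientation[i] == "-") revcomp(sq) else sq
    }, character(1))
    chroms[[chrom]] <- paste(seqs, collapse = strrep("N", gap_len))
  }
  unplaced_ids <- placements$scaffold[placements$status == "unplaced"]
  list(
    chromosomes = if (length(chroms))
      seq_records(names(chroms), unlist(chroms), "chromosome")
      else seq_records(character(0), character(0))[0, ],
    unplaced = scaffolds[scaffolds$id %in% unplaced_ids, , drop = FALSE])
}

#' Assembly statistics
#'
#' N50 is the length of the smallest sequence in the minimal set of longest
#' sequences whose combined length reaches half the assembly total. GC is
#' computed over A/C/G/T bases only (N excluded).
#'
#' @param assembly sequence record table.
#' @param tier label for the output row (defaults to the records' tier).
#' @return one-row data.frame: tier, count, n50, shortest, gc_percent,
#'   total_size.
#' @export
assembly_stats <- function(assembly, tier = NULL) {
  if (!is.data.frame(assembly) || nrow(assembly) == 0)
    stop("empty assembly")
  validate_seq_records(assembly)
  lens <- nchar(assembly$sequence)
  o <- order(lens, decreasing = TRUE)
  cum <- cumsum(lens[o])
  n50 <- lens[o][which(cum >= sum(lens) / 2)[1]]
  base_counts <- rowSums(vapply(assembly$sequence, function(s) {
    v <- charToRaw(s)
    c(sum(v == charToRaw("G") | v == charToRaw("C")),
      sum(v != charToRaw("N")))
  }, numeric(2)))
  data.frame(tier = tier %||% assembly$tier[1], count = nrow(assembly),
             n50 = n50, shortest = min(lens),
             gc_percent = 100 * base_counts[1] / base_counts[2],
             total_size = sum(lens), stringsAsFactors = FALSE)
}

#' Detect inter-chromosomal rearrangements
#'
#' A single de novo contig whose clusters place at least `min_span` aligned
#' bases on each of two different reference chromosomes is evidence of an
#' inter-chromosomal rearrangement. One event is emitted per (contig,
#' secondary chromosome) against the contig's primary (largest-span)
#' chromosome, with a breakpoint estimate at the boundary between the two
#' chromosomes' query intervals.
#'
#' @param clusters cluster table from [anchor_map()] of de novo contigs vs
#'   reference chromosomes.
#' @param min_span minimum aligned bases on each chromosome (default
#'   20000).
#' @return data.frame: contig, chrom_a, bp_a, chrom_b, bp_b, breakpoint.
#' @export
detect_interchromosomal <- function(clusters, min_span = 20000) {
  out <- list()
  for (ctg in unique(clusters$query_id)) {
    cc <- clusters[clusters$query_id == ctg, , drop = FALSE]
    bp <- tapply(cc$total_match, cc$target_id, sum)
    big <- bp[bp >= min_span]
    if (length(big) < 2) next
    big <- sort(big, decreasing = TRUE)
    primary <- names(big)[1]
    qa <- cc[cc$target_id == primary, , drop = FALSE]
    for (secondary in names(big)[-1]) {
      qb <- cc[cc$target_id == secondary, , drop = FALSE]
      # boundary between the two chromosomes' query footprints
      if (min(qb$qstart) >= max(qa$qend))
        brk <- (max(qa$qend) + min(qb$qstart)) / 2
      else if (min(qa$qstart) >= max(qb$qend))
        brk <- (max(qb$qend) + min(qa$qstart)) / 2
      else  # interleaved footprints (segment inside): nearest edge midpoint
        brk <- (max(qa$qstart, qb$qstart) + min(qa$qend, qb$qend)) / 2
      out[[length(out) + 1L]] <- data.frame(
        contig = ctg, chrom_a = primary, bp_a = as.numeric(big[1]),
        chrom_b = secondary, bp_b = as.numeric(big[[secondary]]),
        breakpoint = brk, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(contig = character(0), chrom_a = character(0),
                      bp_a = numeric(0), chrom_b = character(0),
                      bp_b = numeric(0), breakpoint = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Reciprocal-best-hit ortholog pairs
#'
#' A pair (a, b) is kept iff b is a's unique top-scoring subject and a is
#' b's unique top-scoring subject in the opposite direction. Ties for the
#' top score disqualify the gene.
#'
#' @param hits_ab data.frame(query, subject, score): species A vs B.
#' @param hits_ba data.frame(query, subject, score): species B vs A.
#' @return data.frame: query_gene, ref_gene, score_ab, score_ba. One-to-one
#'   by construction.
#' @export
reciprocal_best <- function(hits_ab, hits_ba) {
  best_unique <- function(h) {
    out <- list()
    for (q in unique(h$query)) {
      hh <- h[h$query == q, , drop = FALSE]
      top <- max(hh$score)
      winners <- hh$subject[hh$score == top]
      if (length(winners) == 1)
        out[[q]] <- list(subject = winners, score = top)
    }
    out
  }
  ab <- best_unique(hits_ab)
  ba <- best_unique(hits_ba)
  rows <- list()
  for (a in names(ab)) {
    b <- ab[[a]]$subject
    if (!is.null(ba[[b]]) && ba[[b]]$subject == a)
      rows[[length(rows) + 1L]] <- data.frame(
        query_gene = a, ref_gene = b, score_ab = ab[[a]]$score,
        score_ba = ba[[b]]$score, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(query_gene = character(0), ref_gene = character(0),
                      score_ab = numeric(0), score_ba = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Ortholog dot-plot table
#'
#' One row per ortholog pair with gene midpoints on both genomes, sorted by
#' query chromosome then position; pairs with unknown coordinates are
#' skipped and counted in the `skipped` attribute.
#'
#' @param pairs ortholog pairs from [reciprocal_best()].
#' @param query_coords data.frame(gene_id, chrom, start, end) for the query
#'   species.
#' @param ref_coords likewise for the reference species.
#' @return data.frame: query_chr, query_pos, ref_chr, ref_pos.
#' @export
dotplot_table <- function(pairs, query_coords, ref_coords) {
  qi <- match(pairs$query_gene, query_coords$gene_id)
  ri <- match(pairs$ref_gene, ref_coords$gene_id)
  known <- !is.na(qi) & !is.na(ri)
  skipped <- sum(!known)
  if (skipped)
    warning(skipped, " ortholog pair(s) skipped: unknown gene coordinates")
  out <- data.frame(
    query_chr = query_coords$chrom[qi[known]],
    query_pos = (query_coords$start[qi[known]] + query_coords$end[qi[known]]) / 2,
    ref_chr = ref_coords$chrom[ri[known]],
    ref_pos = (ref_coords$start[ri[known]] + ref_coords$end[ri[known]]) / 2,
    stringsAsFactors = FALSE)
  out <- out[order(out$query_chr, out$query_pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
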