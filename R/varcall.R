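# Pileup-based SNC/InDel calling, effect classification against gene
# models, effect summarisation, per-bin density tracks, species
# partitioning and rate reporting.
#
# The call test is a one-sided binomial tail against a sequencing error
# rate: a site is called iff depth >= min_coverage, the alternate fraction
# reaches min_alt_fraction, and P(X >= alt_depth | n = depth, error_rate)
# is below the p-value cutoff.

EFFECT_CATEGORIES <- c("downstream", "codon_indel", "exon", "intergenic",
                       "intron", "non_synonymous_coding", "splice_site",
                       "start_lost", "stop_gained", "stop_lost",
                       "synonymous_coding", "upstream", "utr3", "utr5",
                       "frame_shift", "exon_deleted",
                       "chromosome_large_deletion")

HIGH_IMPACT <- c("splice_site", "start_lost", "stop_gained", "stop_lost",
                 "frame_shift", "exon_deleted", "chromosome_large_deletion")

impact_of <- function(category) {
  ifelse(category %in% HIGH_IMPACT, "high",
  ifelse(category %in% c("non_synonymous_coding", "codon_indel"), "moderate",
  ifelse(category == "synonymous_coding", "low", "modifier")))
}

#' Call variants from a pileup
#'
#' @param x a `congener_pileup` from [build_pileup()], or a data.frame of
#'   pileup columns with chrom, pos, ref, depth, A, C, G, T (SNC calling
#'   only).
#' @param min_coverage minimum read depth (default 3).
#' @param p_cutoff binomial tail p-value cutoff (default 0.1).
#' @param error_rate assumed per-base error rate under the null (default
#'   0.01).
#' @param min_alt_fraction minimum alternate allele fraction (default 0.2).
#' @param ... passed between methods.
#' @return data.frame of calls: chrom, pos (0-based), ref, alt, type
#'   ("SNC", "INS", "DEL"), depth, alt_depth, alt_fraction, p_value.
#' @export
call_variants <- function(x, ...) UseMethod("call_variants")

snc_calls_from_counts <- function(chrom, counts, refb, pos0, min_coverage,
                                  p_cutoff, error_rate, min_alt_fraction) {
  depth <- colSums(counts)
  ref_idx <- match(refb, c("A", "C", "G", "T"))
  nonref <- counts
  valid <- !is.na(ref_idx)
  nonref[cbind(ref_idx[valid], which(valid))] <- -1L
  alt_idx <- max.col(t(nonref), ties.method = "first")
  alt_depth <- nonref[cbind(alt_idx, seq_along(depth))]
  keep <- valid & depth >= min_coverage & alt_depth >= 1 &
          alt_depth / depth >= min_alt_fraction
  p <- rep(NA_real_, length(depth))
  p[keep] <- pbinom(alt_depth[keep] - 1L, depth[keep], error_rate,
                    lower.tail = FALSE)
  keep <- keep & !is.na(p) & p < p_cutoff
  if (!any(keep)) return(NULL)
  chrom <- rep_len(chrom, length(depth))
  data.frame(chrom = chrom[keep], pos = pos0[keep], ref = refb[keep],
             alt = c("A", "C", "G", "T")[alt_idx[keep]], type = "SNC",
             depth = depth[keep], alt_depth = alt_depth[keep],
             alt_fraction = alt_depth[keep] / depth[keep],
             p_value = p[keep], stringsAsFactors = FALSE)
}

#' @rdname call_variants
#' @export
call_variants.congener_pileup <- function(x, min_coverage = 3,
                                          p_cutoff = 0.1, error_rate = 0.01,
                                          min_alt_fraction = 0.2, ...) {
  rows <- list()
  for (chrom in x$ids) {
    m <- x$counts[[chrom]]
    refb <- strsplit(x$ref[[chrom]], "")[[1]]
    snc <- snc_calls_from_counts(
      chrom, m, refb, seq_len(ncol(m)) - 1L, min_coverage, p_cutoff,
      error_rate, min_alt_fraction)
    # the genomes compared are effectively haploid (inbred lines): a
    # position cannot be substituted and deleted at once, so SNC evidence
    # inside indel-supported spans is junction artefact and is masked
    ind_all <- x$indels[x$indels$chrom == chrom & x$indels$count >= 2, ,
                        drop = FALSE]
    if (!is.null(snc) && nrow(ind_all)) {
      lo <- ifelse(ind_all$type == "DEL", ind_all$pos + 1, ind_all$pos - 1)
      hi <- ifelse(ind_all$type == "DEL", ind_all$pos + ind_all$len,
                   ind_all$pos + 1)
      masked <- vapply(snc$pos, function(p) any(p >= lo & p <= hi),
                       logical(1))
      snc <- snc[!masked, , drop = FALSE]
    }
    rows[[length(rows) + 1L]] <- snc
    # InDels: cluster observations of the same type/length within 3 bp
    ind <- x$indels[x$indels$chrom == chrom, , drop = FALSE]
    if (nrow(ind)) {
      ind <- ind[order(ind$type, ind$len, ind$pos), , drop = FALSE]
      brk <- c(TRUE, ind$type[-1] != ind$type[-nrow(ind)] |
                     ind$len[-1] != ind$len[-nrow(ind)] |
                     ind$pos[-1] - ind$pos[-nrow(ind)] > 3)
      gid <- cumsum(brk)
      for (g in unique(gid)) {
        obs <- ind[gid == g, , drop = FALSE]
        alt_depth <- sum(obs$count)
        at <- obs$pos[which.max(obs$count)]
        depth <- sum(m[, at + 1L])
        if (depth < min_coverage || alt_depth < 1 ||
            alt_depth / max(depth, alt_depth) < min_alt_fraction) next
        depth <- max(depth, alt_depth)
        p <- pbinom(alt_depth - 1L, depth, error_rate, lower.tail = FALSE)
        if (p >= p_cutoff) next
        anchor <- substr(x$ref[[chrom]], at + 1L, at + 1L)
        if (obs$type[1] == "DEL") {
          ref <- substr(x$ref[[chrom]], at + 1L, at + 1L + obs$len[1])
          alt <- anchor
        } else {
          ins <- obs$seq[which.max(obs$count)]
          ref <- anchor
          alt <- paste0(anchor, ins)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, pos = at, ref = ref, alt = alt,
          type = obs$type[1], depth = depth, alt_depth = alt_depth,
          alt_fraction = alt_depth / depth, p_value = p,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      type = character(0), depth = integer(0),
                      alt_depth = integer(0), alt_fraction = numeric(0),
                      p_value = numeric(0), stringsAsFactors = FALSE)
  out <- out[order(match(out$chrom, x$ids), out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname call_variants
#' @export
call_variants.data.frame <- function(x, min_coverage = 3, p_cutoff = 0.1,
                                     error_rate = 0.01,
                                     min_alt_fraction = 0.2, ...) {
  stopifnot(all(c("chrom", "pos", "ref", "A", "C", "G", "T") %in% names(x)))
  counts <- t(as.matrix(x[, c("A", "C", "G", "T")]))
  out <- snc_calls_from_counts(x$chrom, counts, x$ref, x$pos, min_coverage,
                               p_cutoff, error_rate, min_alt_fraction)
  if (is.null(out))
    out <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      type = character(0), depth = integer(0),
                      alt_depth = integer(0), alt_fraction = numeric(0),
                      p_value = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# Effect classification
# ---------------------------------------------------------------------------

# 5'->3' CDS description of a transcript: genomic positions in reading
# order, plus the spliced CDS sequence
cds_layout <- function(genes, tx_id, genome_seq) {
  cc <- genes$cds[genes$cds$tx_id == tx_id, , drop = FALSE]
  if (!nrow(cc)) return(NULL)
  tx <- genes$transcripts[genes$transcripts$tx_id == tx_id, ]
  pos <- unlist(lapply(seq_len(nrow(cc)), function(i)
    seq(cc$start[i], cc$end[i] - 1L)))
  seq_fwd <- strsplit(paste(substring(genome_seq, cc$start + 1L, cc$end),
                            collapse = ""), "")[[1]]
  if (tx$strand == "-") {
    pos <- rev(pos)
    seq_fwd <- rev(unname(c(A = "T", C = "G", G = "C", T = "A",
                            N = "N")[seq_fwd]))
  }
  list(pos = pos, seq = seq_fwd, strand = tx$strand,
       cds_lo = min(cc$start), cds_hi = max(cc$end))
}

translate_codon <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[[paste(codon, collapse = "")]]
  if (is.null(aa)) "X" else aa
}

classify_snc_in_cds <- function(layout, pos, alt) {
  i <- match(pos, layout$pos)
  base <- alt
  if (layout$strand == "-")
    base <- c(A = "T", C = "G", G = "C", T = "A")[alt]
  codon_i <- (i - 1) %/% 3
  lo <- codon_i * 3 + 1
  if (lo + 2 > length(layout$seq)) return("exon")  # trailing partial codon
  ref_codon <- layout$seq[lo:(lo + 2)]
  alt_codon <- ref_codon
  alt_codon[i - lo + 1] <- base
  aa_ref <- translate_codon(ref_codon)
  aa_alt <- translate_codon(alt_codon)
  if (codon_i == 0 && aa_ref == "M" && aa_alt != "M") return("start_lost")
  if (aa_ref != "*" && aa_alt == "*") return("stop_gained")
  if (aa_ref == "*" && aa_alt != "*") return("stop_lost")
  if (aa_ref == aa_alt) return("synonymous_coding")
  "non_synonymous_coding"
}

#' Classify variant effects against gene models
#'
#' Every (variant, nearby transcript) combination is annotated; one variant
#' can therefore yield several effects in neighbouring genes, and each
#' effect counts separately in downstream summaries. Coding SNCs are
#' translated with the standard genetic code; coding InDels are frame
#' shifts (high impact) unless their length is a multiple of three (codon
#' InDel); intronic positions within `splice_window` of an exon boundary
#' are splice sites (high impact); deletions removing a whole exon are
#' exon_deleted and deletions longer than 1 % of their chromosome are
#' chromosome_large_deletion (both high impact). Positions within
#' `updown_window` of a transcript are upstream/downstream; everything else
#' is intergenic.
#'
#' @param variants variant table (chrom, pos, ref, alt, type).
#' @param genes a `congener_genes` container.
#' @param genome sequence record table of the genome the variants refer to
#'   (used for codon context and ref-allele integrity checks).
#' @param updown_window bp (default 5000).
#' @param splice_window bp into the intron (default 2).
#' @return data.frame: chrom, pos, ref, alt, gene_id, transcript_id,
#'   category, impact.
#' @export
classify_effects <- function(variants, genes, genome, updown_window = 5000,
                             splice_window = 2) {
  stopifnot(inherits(genes, "congener_genes"))
  gseq <- as_target_vec(genome)
  tx <- genes$transcripts
  layouts <- new.env(parent = emptyenv())
  rows <- list()
  for (vi in seq_len(nrow(variants))) {
    v <- variants[vi, ]
    if (!v$chrom %in% names(gseq))
      stop("variant chromosome ", v$chrom, " not in genome")
    gref <- substr(gseq[[v$chrom]], v$pos + 1L, v$pos + nchar(v$ref))
    if (gref != v$ref)
      stop("reference allele mismatch at ", v$chrom, ":", v$pos,
           " (variant says ", v$ref, ", genome has ", gref, ")")
    vtype <- v$type %||% if (nchar(v$ref) == nchar(v$alt)) "SNC" else
      if (nchar(v$ref) > nchar(v$alt)) "DEL" else "INS"
    # deleted interval for DEL (bases after the anchor)
    del_span <- if (vtype == "DEL")
      c(v$pos + 1L, v$pos + nchar(v$ref) - 1L + 1L) else NULL
    indel_len <- abs(nchar(v$ref) - nchar(v$alt))
    near <- tx[tx$chrom == v$chrom &
               tx$start - updown_window <= v$pos &
               tx$end + updown_window > v$pos, , drop = FALSE]
    if (!nrow(near)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
        gene_id = NA_character_, transcript_id = NA_character_,
        category = "intergenic", stringsAsFactors = FALSE)
      next
    }
    for (ti in seq_len(nrow(near))) {
      t1 <- near[ti, ]
      category <- NULL
      # chromosome-scale deletion trumps everything
      if (vtype == "DEL" &&
          indel_len > 0.01 * nchar(gseq[[v$chrom]])) {
        category <- "chromosome_large_deletion"
      } else if (v$pos < t1$start || v$pos >= t1$end) {
        before <- v$pos < t1$start
        category <- if ((before && t1$strand == "+") ||
                        (!before && t1$strand == "-")) "upstream"
                    else "downstream"
      } else {
        ex <- genes$exons[genes$exons$tx_id == t1$tx_id, , drop = FALSE]
        cc <- genes$cds[genes$cds$tx_id == t1$tx_id, , drop = FALSE]
        in_exon <- any(ex$start <= v$pos & v$pos < ex$end)
        if (vtype == "DEL" && nrow(ex) &&
            any(del_span[1] <= ex$start & ex$end <= del_span[2])) {
          category <- "exon_deleted"
        } else if (vtype != "SNC") {
          touches_cds <- nrow(cc) > 0 &&
            any(cc$start <= v$pos + nchar(v$ref) - 1L & v$pos < cc$end)
          if (touches_cds) {
            category <- if (indel_len %% 3 == 0) "codon_indel" else
              "frame_shift"
          }
        }
        if (is.null(category)) {
          if (in_exon) {
            in_cds <- nrow(cc) > 0 && any(cc$start <= v$pos & v$pos < cc$end)
            if (vtype == "SNC" && in_cds) {
              key <- t1$tx_id
              if (!exists(key, envir = layouts))
                assign(key, cds_layout(genes, key, gseq[[v$chrom]]),
                       envir = layouts)
              category <- classify_snc_in_cds(get(key, envir = layouts),
                                              v$pos, v$alt)
            } else if (nrow(cc) == 0) {
              category <- "exon"
            } else {
              cds_lo <- min(cc$start); cds_hi <- max(cc$end)
              five <- if (t1$strand == "+") v$pos < cds_lo else v$pos >= cds_hi
              category <- if (five) "utr5" else "utr3"
            }
          } else {
            # intronic: splice site if within splice_window of a boundary
            near_splice <- any(v$pos >= ex$end & v$pos < ex$end + splice_window) ||
                           any(v$pos < ex$start & v$pos >= ex$start - splice_window)
            category <- if (near_splice) "splice_site" else "intron"
          }
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
        gene_id = t1$gene_id, transcript_id = t1$tx_id,
        category = category, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      gene_id = character(0), transcript_id = character(0),
                      category = character(0), stringsAsFactors = FALSE)
  out$impact <- impact_of(out$category)
  out
}

#' Summarise effect annotations
#'
#' Effects (not variants) are the counting unit: a variant annotated
#' against several transcripts contributes one count per annotation.
#' Percentages are of total effects, rounded to two decimals.
#'
#' @param x annotation data.frame from [classify_effects()] (column
#'   `category`), or a named numeric vector of pre-tabulated category
#'   counts.
#' @return data.frame: category, count, percentage; total count in the
#'   `total` attribute.
#' @export
summarize_effects <- function(x) {
  counts <- if (is.data.frame(x)) {
    tab <- table(x$category)
    setNames(as.numeric(tab), names(tab))
  } else {
    stopifnot(is.numeric(x), !is.null(names(x)))
    x
  }
  total <- sum(counts)
  out <- data.frame(category = names(counts), count = as.numeric(counts),
                    percentage = round(100 * as.numeric(counts) / total, 2),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "total") <- total
  out
}

#' Per-bin variant density track
#'
#' Counts variants in fixed-width bins along each chromosome (the last,
#' partial bin is kept) and divides by a fixed normaliser for plot-ready
#' values.
#'
#' @param variants variant table (chrom, pos).
#' @param chrom_lengths named vector of chromosome lengths.
#' @param bin bin width, bp (default 100000).
#' @param normalizer divisor for the normalised column (default 3000).
#' @return data.frame: chrom, bin_start, bin_end, count, normalized.
#' @export
density_track <- function(variants, chrom_lengths, bin = 100000,
                          normalizer = 3000) {
  rows <- list()
  for (chrom in names(chrom_lengths)) {
    L <- chrom_lengths[[chrom]]
    nb <- max(1L, as.integer(ceiling(L / bin)))
    starts <- (seq_len(nb) - 1L) * bin
    pos <- variants$pos[variants$chrom == chrom]
    counts <- tabulate(pmin(floor(pos / bin), nb - 1L) + 1L, nbins = nb)
    rows[[chrom]] <- data.frame(
      chrom = chrom, bin_start = starts,
      bin_end = pmin(starts + bin, L), count = counts,
      normalized = counts / normalizer, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Partition variants into shared and species-specific sets
#'
#' Both sets must be called against the same reference genome. Matching is
#' exact on (chrom, pos, ref, alt): the same site with different alternate
#' alleles is species-specific in both species, not shared.
#'
#' @param variants_b,variants_c variant tables for the two query species.
#' @return list(shared, only_b, only_c) of variant tables (rows taken from
#'   variants_b for `shared`).
#' @export
partition_species <- function(variants_b, variants_c) {
  key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
  kb <- key(variants_b); kc <- key(variants_c)
  list(shared = variants_b[kb %in% kc, , drop = FALSE],
       only_b = variants_b[!kb %in% kc, , drop = FALSE],
       only_c = variants_c[!kc %in% kb, , drop = FALSE])
}

#' Overall polymorphism rate as "1 per N bp"
#'
#' @param n_variants number of variants.
#' @param denominator_bp the base count the rate refers to (the caller
#'   chooses aligned vs assembled bases explicitly).
#' @return list(n, denominator, per_bp = round(denominator / n), rate,
#'   label).
#' @export
polymorphism_rate <- function(n_variants, denominator_bp) {
  if (n_variants <= 0) stop("polymorphism rate undefined for 0 variants")
  per <- round(denominator_bp / n_variants)
  list(n = n_variants, denominator = denominator_bp, per_bp = per,
       rate = n_variants / denominator_bp,
       label = sprintf("1 per %d bp", per))
}
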