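# Variant calling thresholds, effect classification, summaries, density
# tracks, species partitioning and rate reporting.

pileup_col <- function(pos, ref, A = 0, C = 0, G = 0, T = 0) {
  data.frame(chrom = "chr1", pos = pos, ref = ref, A = A, C = C, G = G,
             T = T, depth = A + C + G + T, stringsAsFactors = FALSE)
}

test_that("the calling thresholds act independently", {
  # depth 2 is below minimum coverage regardless of evidence
  expect_equal(nrow(call_variants(pileup_col(10, "A", A = 0, G = 2))), 0)
  # depth 10, alt 10: binomial tail 0.01^10 = 1e-20, called
  v <- call_variants(pileup_col(10, "A", G = 10))
  expect_equal(nrow(v), 1)
  expect_equal(v$alt, "G")
  expect_equal(v$p_value, 0.01^10)
  # depth 10, alt 1: tail 1 - 0.99^10 < 0.1 but alt fraction 0.1 < 0.2
  expect_lt(1 - 0.99^10, 0.1)
  expect_equal(nrow(call_variants(pileup_col(10, "A", A = 9, G = 1))), 0)
  # most frequent non-reference allele is reported
  v2 <- call_variants(pileup_col(5, "A", A = 2, C = 5, G = 3))
  expect_equal(v2$alt, "C")
})

test_that("the call p-value is non-increasing in alt depth at fixed depth", {
  p <- vapply(1:30, function(ad)
    pbinom(ad - 1, 30, 0.01, lower.tail = FALSE), numeric(1))
  expect_true(all(diff(p) <= 0))
  # and the caller reports exactly that tail
  for (ad in c(10, 20, 30)) {
    v <- call_variants(pileup_col(1, "A", A = 30 - ad, G = ad),
                       min_alt_fraction = 0)
    expect_equal(v$p_value, pbinom(ad - 1, 30, 0.01, lower.tail = FALSE))
  }
})

test_that("InDels are called from clustered observations", {
  ref <- paste0(strrep("A", 50), "CGTAC", strrep("T", 45))
  counts <- matrix(2L, nrow = 4, ncol = 100)
  pl <- structure(list(ids = "c1", ref = c(c1 = ref),
                       counts = list(c1 = counts),
                       indels = data.frame(chrom = "c1",
                                           pos = c(52, 53, 70),
                                           type = c("DEL", "DEL", "INS"),
                                           len = c(3L, 3L, 2L),
                                           seq = c("", "", "GG"),
                                           count = c(6L, 2L, 1L),
                                           stringsAsFactors = FALSE)),
                  class = "congener_pileup")
  v <- call_variants(pl, min_alt_fraction = 0.2)
  del <- v[v$type == "DEL", ]
  expect_equal(nrow(del), 1)          # the two DEL observations cluster
  expect_equal(del$pos, 52)           # modal position
  expect_equal(del$alt_depth, 8)
  expect_equal(nchar(del$ref), 4)     # anchor + 3 deleted bases
  expect_equal(nrow(v[v$type == "INS", ]), 0)  # single observation too weak
})

test_that("coding SNCs agree with an exhaustive translation oracle", {
  # two-exon gene, CDS split across the intron, both strands
  utr5 <- 10L
  cds1 <- "ATGGCATTAGGC"   # 12 bp in exon 1
  cds2 <- "TGCCGATGTTGA"   # 12 bp in exon 2 (ends with stop TGA)
  intron <- random_seq(60, seed = 81)
  g_plus <- paste0(random_seq(100, 82),
                   strrep("C", utr5), cds1, intron, cds2, strrep("G", 8),
                   random_seq(100, 83))
  e1s <- 100L; e1e <- e1s + utr5 + 12L
  e2s <- e1e + 60L; e2e <- e2s + 12L + 8L
  for (strand in c("+", "-")) {
    if (strand == "+") {
      genome <- seq_records("chr1", g_plus, "chromosome")
      cds_int <- data.frame(tx_id = "t1", start = c(e1s + utr5, e2s),
                            end = c(e1e, e2s + 12L), phase = 0L)
    } else {
      genome <- seq_records("chr1", rc_oracle(g_plus), "chromosome")
      L <- nchar(g_plus)
      flip <- function(s, e) c(L - e, L - s)
      i1 <- flip(e1s + utr5, e1e); i2 <- flip(e2s, e2s + 12L)
      cds_int <- data.frame(tx_id = "t1",
                            start = c(i2[1], i1[1]), end = c(i2[2], i1[2]),
                            phase = 0L)
    }
    exon_int <- if (strand == "+")
      data.frame(tx_id = "t1", start = c(e1s, e2s), end = c(e1e, e2e))
    else {
      L <- nchar(g_plus)
      data.frame(tx_id = "t1", start = c(L - e2e, L - e1e),
                 end = c(L - e2s, L - e1s))
    }
    tx <- data.frame(tx_id = "t1", gene_id = "g1", chrom = "chr1",
                     strand = strand,
                     start = min(exon_int$start), end = max(exon_int$end))
    gm <- gene_models(tx, exon_int, cds_int)
    cds_seq <- paste0(cds1, cds2)
    # genomic positions of CDS bases in reading order
    pos_list <- unlist(lapply(seq_len(nrow(cds_int[order(cds_int$start), ])),
      function(i) {
        ci <- cds_int[order(cds_int$start), ][i, ]
        seq(ci$start, ci$end - 1L)
      }))
    if (strand == "-") pos_list <- rev(pos_list)
    gseq <- genome$sequence[1]
    for (ci in seq_len(nchar(cds_seq))) {
      gpos <- pos_list[ci]
      gref <- substr(gseq, gpos + 1L, gpos + 1L)
      for (alt_g in setdiff(c("A", "C", "G", "T"), gref)) {
        v <- data.frame(chrom = "chr1", pos = gpos, ref = gref, alt = alt_g,
                        type = "SNC", stringsAsFactors = FALSE)
        ann <- classify_effects(v, gm, genome)
        got <- ann$category[ann$transcript_id == "t1"]
        # oracle: mutate the spliced CDS and translate both versions
        alt_c <- if (strand == "+") alt_g else chartr("ACGT", "TGCA", alt_g)
        mut <- cds_seq
        substr(mut, ci, ci) <- alt_c
        aa_ref <- as.character(Biostrings::translate(Biostrings::DNAString(cds_seq),
                                                     no.init.codon = TRUE))
        aa_alt <- as.character(Biostrings::translate(Biostrings::DNAString(mut),
                                                     no.init.codon = TRUE))
        d <- which(strsplit(aa_ref, "")[[1]] != strsplit(aa_alt, "")[[1]])
        expected <- if (!length(d)) "synonymous_coding"
          else if (d[1] == 1 && substr(aa_alt, 1, 1) != "M") "start_lost"
          else if (substr(aa_alt, d[1], d[1]) == "*") "stop_gained"
          else if (substr(aa_ref, d[1], d[1]) == "*") "stop_lost"
          else "non_synonymous_coding"
        expect_equal(got, expected,
                     info = sprintf("strand %s cds pos %d alt %s",
                                    strand, ci, alt_g))
      }
    }
  }
})

test_that("non-coding placements follow the window rules", {
  g <- seq_records("chr1", random_seq(100000, 84), "chromosome")
  gs <- g$sequence[1]
  at <- function(p) substr(gs, p + 1, p + 1)
  tx <- data.frame(tx_id = "t1", gene_id = "g1", chrom = "chr1",
                   strand = "+", start = 8000L, end = 10000L)
  ex <- data.frame(tx_id = "t1", start = c(8000L, 9500L),
                   end = c(8600L, 10000L))
  cds <- data.frame(tx_id = "t1", start = c(8100L, 9500L),
                    end = c(8600L, 9800L), phase = 0L)
  gm <- gene_models(tx, ex, cds)
  check <- function(pos, expected, impact = NULL) {
    v <- data.frame(chrom = "chr1", pos = pos, ref = at(pos),
                    alt = setdiff(c("A", "C", "G", "T"), at(pos))[1],
                    type = "SNC", stringsAsFactors = FALSE)
    ann <- classify_effects(v, gm, g)
    expect_equal(ann$category[1], expected, info = paste("pos", pos))
    if (!is.null(impact)) expect_equal(ann$impact[1], impact)
  }
  check(5000, "upstream", "modifier")     # 3 kb before tx start
  check(13000, "downstream", "modifier")  # 3 kb past tx end
  check(1000, "intergenic")               # beyond the 5 kb window
  check(8050, "utr5", "modifier")         # exonic, before CDS start
  check(9900, "utr3", "modifier")         # exonic, after CDS end
  check(9000, "intron")                   # deep intron
  check(8600, "splice_site", "high")      # first intron base (donor side)
  check(8601, "splice_site", "high")
  check(8602, "intron")                   # third intron base
  check(9498, "splice_site", "high")      # acceptor side

  # InDels: frame shift vs codon indel, exon deletion, large deletion
  mk_indel <- function(pos, del_len = 0, ins = "") {
    if (del_len > 0)
      data.frame(chrom = "chr1", pos = pos,
                 ref = substr(gs, pos + 1, pos + 1 + del_len),
                 alt = at(pos), type = "DEL", stringsAsFactors = FALSE)
    else
      data.frame(chrom = "chr1", pos = pos, ref = at(pos),
                 alt = paste0(at(pos), ins), type = "INS",
                 stringsAsFactors = FALSE)
  }
  a1 <- classify_effects(mk_indel(8200, del_len = 4), gm, g)
  expect_equal(a1$category, "frame_shift")
  expect_equal(a1$impact, "high")
  a2 <- classify_effects(mk_indel(8200, del_len = 3), gm, g)
  expect_equal(a2$category, "codon_indel")
  expect_equal(a2$impact, "moderate")
  a3 <- classify_effects(mk_indel(8200, ins = "TT"), gm, g)
  expect_equal(a3$category, "frame_shift")
  # deletion spanning the whole second exon
  a4 <- classify_effects(
    data.frame(chrom = "chr1", pos = 9400,
               ref = substr(gs, 9401, 10100), alt = at(9400), type = "DEL",
               stringsAsFactors = FALSE), gm, g)
  expect_equal(a4$category, "exon_deleted")
  expect_equal(a4$impact, "high")
  # deletion over 1% of the chromosome
  a5 <- classify_effects(
    data.frame(chrom = "chr1", pos = 8200,
               ref = substr(gs, 8201, 9401), alt = at(8200), type = "DEL",
               stringsAsFactors = FALSE), gm, g)
  expect_equal(a5$category, "chromosome_large_deletion")
  expect_equal(a5$impact, "high")

  # integrity: a wrong reference allele is an error, not a silent skip
  expect_error(classify_effects(
    data.frame(chrom = "chr1", pos = 5000,
               ref = setdiff(c("A", "C", "G", "T"), at(5000))[1],
               alt = at(5000), type = "SNC", stringsAsFactors = FALSE),
    gm, g), "mismatch")
})

test_that("one variant near two genes yields one effect per transcript", {
  g <- seq_records("chr1", random_seq(12000, 85), "chromosome")
  tx <- data.frame(tx_id = c("t1", "t2"), gene_id = c("g1", "g2"),
                   chrom = "chr1", strand = c("+", "-"),
                   start = c(2000L, 7000L), end = c(4000L, 9000L))
  ex <- data.frame(tx_id = c("t1", "t2"), start = c(2000L, 7000L),
                   end = c(4000L, 9000L))
  gm <- gene_models(tx, ex)
  p <- 5500L
  b <- substr(g$sequence, p + 1, p + 1)
  v <- data.frame(chrom = "chr1", pos = p, ref = b,
                  alt = setdiff(c("A", "C", "G", "T"), b)[1], type = "SNC",
                  stringsAsFactors = FALSE)
  ann <- classify_effects(v, gm, g)
  expect_equal(nrow(ann), 2)
  expect_setequal(ann$category, c("downstream", "downstream"))
})

test_that("effect summaries count effects and percentages sum to 100", {
  ann <- data.frame(category = c(rep("intron", 6), rep("intergenic", 3),
                                 "stop_gained"))
  s <- summarize_effects(ann)
  expect_equal(sum(s$count), 10)
  expect_equal(attr(s, "total"), 10)
  expect_equal(s$percentage[s$category == "intron"], 60)
  expect_lt(abs(sum(s$percentage) - 100), 0.05)
  s1 <- summarize_effects(data.frame(category = "exon"))
  expect_equal(s1$percentage, 100)
  # property: counts conserved, percentages ~100 for random inputs
  set.seed(86)
  for (i in 1:5) {
    x <- setNames(sample(1:5000, 8), paste0("cat", 1:8))
    ss <- summarize_effects(x)
    expect_equal(sum(ss$count), sum(x))
    expect_lt(abs(sum(ss$percentage) - 100), 0.05)
  }
})

test_that("density tracks bin and normalise as specified", {
  v <- data.frame(chrom = "chr1",
                  pos = c(rep(50, 3000), rep(150000, 1500)))
  d <- density_track(v, c(chr1 = 250000), bin = 100000, normalizer = 3000)
  expect_equal(nrow(d), 3)             # last partial bin kept
  expect_equal(d$normalized, c(1, 0.5, 0))
  expect_equal(d$bin_end[3], 250000)
})

test_that("species partitioning matches on exact alleles", {
  b <- data.frame(chrom = "chr1", pos = c(10, 20, 30), ref = "A",
                  alt = c("G", "C", "T"), stringsAsFactors = FALSE)
  c_ <- data.frame(chrom = "chr1", pos = c(10, 20, 40), ref = "A",
                   alt = c("G", "T", "T"), stringsAsFactors = FALSE)
  p <- partition_species(b, c_)
  expect_equal(p$shared$pos, 10)
  expect_setequal(p$only_b$pos, c(20, 30))   # same site, different alt
  expect_setequal(p$only_c$pos, c(20, 40))
})

test_that("polymorphism rate reports 1 per N bp", {
  r <- polymorphism_rate(100, 6900)
  expect_equal(r$per_bp, 69)
  expect_equal(r$label, "1 per 69 bp")
  expect_error(polymorphism_rate(0, 100), "undefined")
})
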