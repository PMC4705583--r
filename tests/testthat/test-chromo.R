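# Anchor mapping, placement, assembly statistics, the inter-chromosomal
# rearrangement rule, and ortholog dot-plot tables.

test_that("anchor mapping recovers exact and chained matches", {
  ref <- seq_records("chrA", random_seq(30000, 61), "chromosome")
  # query identical to a 10 kb window: one cluster at identity 1
  q1 <- seq_records("q1", substr(ref$sequence, 5001, 15000))
  cl1 <- anchor_map(q1, ref)
  expect_equal(nrow(cl1), 1)
  expect_equal(cl1$tstart, 5000)
  expect_equal(cl1$tend, 15000)
  expect_gte(cl1$total_match / 10000, 0.99)
  expect_equal(cl1$mean_identity, 1)

  # a single 300 bp match is below the 400 bp cluster threshold
  q2 <- seq_records("q2", paste0(random_seq(500, 62),
                                 substr(ref$sequence, 20001, 20300),
                                 random_seq(500, 63)))
  expect_equal(nrow(anchor_map(q2, ref)), 0)

  # two 300 bp matches separated by 450 bp on both sequences chain to 600
  # (the query gap is 450 bp of unrelated sequence)
  q3 <- seq_records("q3", paste0(substr(ref$sequence, 1001, 1300),
                                 random_seq(450, 64),
                                 substr(ref$sequence, 1751, 2050)))
  cl3 <- anchor_map(q3, ref)
  expect_equal(nrow(cl3), 1)
  expect_gte(cl3$total_match, 550)  # two ~300 bp anchor runs chained
  expect_lte(cl3$total_match, 650)

  # reverse-complement query maps on the minus strand in original coords
  q4 <- seq_records("q4", rc_oracle(substr(ref$sequence, 8001, 12000)))
  cl4 <- anchor_map(q4, ref)
  expect_equal(cl4$strand, "-")
  expect_equal(cl4$tstart, 8000)
  expect_equal(cl4$qstart, 0)
})

test_that("self-alignment covers nearly all of each chromosome in one cluster", {
  cfg <- sim_config(genome_length = 2e5, n_chromosomes = 2, seed = 65)
  ref <- simulate_reference(cfg)
  cl <- anchor_map(ref, ref)
  own <- cl[cl$query_id == cl$target_id & cl$strand == "+", ]
  for (i in seq_len(nrow(ref))) {
    cc <- own[own$query_id == ref$id[i], ]
    expect_gte(max(cc$total_match) / nchar(ref$sequence[i]), 0.99)
  }
})

test_that("placement follows majority match, tie rule and orientation rule", {
  sc <- seq_records(c("s1", "s2", "s3"),
                    c(random_seq(1000, 66), random_seq(1000, 67),
                      random_seq(1000, 68)))
  cl <- data.frame(
    query_id = c("s1", "s1", "s2", "s2", "s3"),
    target_id = c("chr2", "chr7", "chr1", "chr1", "chr5"),
    qstart = 0, qend = 1000, tstart = c(0, 5e4, 0, 0, 0),
    tend = c(3e4, 52e3, 600, 500, 1000),
    strand = c("+", "+", "-", "+", "+"),
    total_match = c(30000, 2000, 600, 400, 1000),
    mean_identity = 1, n_anchors = 1, stringsAsFactors = FALSE)
  out <- place_scaffolds(cl, sc)
  p <- out$placements
  expect_equal(p$chromosome[p$scaffold == "s1"], "chr2")   # 30 kb beats 2 kb
  expect_equal(p$status[p$scaffold == "s1"], "placed")
  # 60% of matched bp on the minus strand -> orientation "-"
  expect_equal(p$orientation[p$scaffold == "s2"], "-")
  expect_equal(p$status[p$scaffold == "s3"], "placed")
  # no clusters -> unplaced
  out2 <- place_scaffolds(cl[cl$query_id != "s3", ], sc)
  expect_equal(out2$placements$status[out2$placements$scaffold == "s3"],
               "unplaced")
  # runner-up within 10% of the winner -> ambiguous, unplaced
  cl_tie <- cl[1:2, ]
  cl_tie$total_match <- c(10000, 9500)
  out3 <- place_scaffolds(cl_tie, sc[1, , drop = FALSE])
  expect_equal(out3$placements$status, "unplaced")
})

test_that("chromosome AGP uses 100 bp gaps and placement order", {
  sc <- seq_records(c("s1", "s2"), c(random_seq(400, 69), random_seq(600, 70)))
  cl <- data.frame(query_id = c("s1", "s2"), target_id = "chr1",
                   qstart = 0, qend = c(400, 600),
                   tstart = c(5000, 0), tend = c(5400, 600),
                   strand = "+", total_match = c(400, 600),
                   mean_identity = 1, n_anchors = 1, stringsAsFactors = FALSE)
  out <- place_scaffolds(cl, sc)
  agp <- out$agp
  # s2 (earlier median target coordinate) first, then gap, then s1
  expect_equal(agp$component_type, c("W", "N", "W"))
  expect_equal(agp$component_id, c("s2", "100", "s1"))
  expect_equal(agp$object_beg, c(1, 601, 701))
  expect_equal(agp$object_end, c(600, 700, 1100))
  built <- build_chromosomes(sc, out$placements)
  expect_equal(nchar(built$chromosomes$sequence), 400 + 100 + 600)
})

test_that("assembly statistics match brute-force oracles", {
  a1 <- seq_records(c("a", "b", "c"),
                    c(random_seq(300, 71), random_seq(200, 72),
                      random_seq(100, 73)), "contig")
  expect_equal(assembly_stats(a1)$n50, n50_oracle(c(300, 200, 100)))
  expect_equal(assembly_stats(a1)$n50, 300)

  lens <- c(5, 4, 3, 2, 1) * 10  # short sequences scaled to valid records
  a2 <- seq_records(paste0("s", 1:5),
                    vapply(seq_along(lens), function(i)
                      random_seq(lens[i], 73 + i), character(1)), "contig")
  expect_equal(assembly_stats(a2)$n50, n50_oracle(lens))
  expect_equal(assembly_stats(a2)$n50, 40)

  a3 <- seq_records("x", "ATGC", "contig")
  expect_equal(assembly_stats(a3)$gc_percent, 50)
  expect_equal(assembly_stats(a3)$shortest, 4)
  expect_equal(assembly_stats(a3)$total_size, 4)
  expect_error(assembly_stats(a1[0, ]), "empty")

  # randomised agreement with the oracle, N excluded from GC
  set.seed(75)
  for (rep in 1:5) {
    lens <- sample(50:500, 8)
    seqs <- vapply(lens, function(L) random_seq(L, sample.int(1e6, 1)),
                   character(1))
    st <- assembly_stats(seq_records(paste0("r", 1:8), seqs, "contig"))
    expect_equal(st$n50, n50_oracle(lens))
    expect_equal(st$total_size, sum(lens))
  }
})

test_that("the 20 kb rule requires that span on each of two chromosomes", {
  mk <- function(bp1, bp2, chrom2 = "chr2") data.frame(
    query_id = "ctg1", target_id = c("chr1", chrom2),
    qstart = c(0, 30000), qend = c(bp1, 30000 + bp2),
    tstart = 0, tend = c(bp1, bp2), strand = "+",
    total_match = c(bp1, bp2), mean_identity = 1, n_anchors = 1,
    stringsAsFactors = FALSE)
  expect_equal(nrow(detect_interchromosomal(mk(25000, 22000))), 1)
  expect_equal(nrow(detect_interchromosomal(mk(25000, 5000))), 0)
  expect_equal(nrow(detect_interchromosomal(mk(25000, 22000, "chr1"))), 0)
  ev <- detect_interchromosomal(mk(25000, 22000))
  expect_equal(ev$chrom_a, "chr1")  # primary = larger span
  expect_gte(ev$breakpoint, 25000)
  expect_lte(ev$breakpoint, 30000)
})

test_that("reciprocal best hits are one-to-one and reject ties", {
  ab <- data.frame(query = c("g1", "g1", "g2"), subject = c("h1", "h2", "h1"),
                   score = c(100, 50, 80), stringsAsFactors = FALSE)
  ba <- data.frame(query = c("h1", "h2"), subject = c("g1", "g1"),
                   score = c(95, 40), stringsAsFactors = FALSE)
  rb <- reciprocal_best(ab, ba)
  expect_equal(nrow(rb), 1)
  expect_equal(rb$query_gene, "g1")
  expect_equal(rb$ref_gene, "h1")

  # g1's best is h1 but h1's best is g2: no pair involving g1
  ba2 <- data.frame(query = "h1", subject = "g2", score = 95)
  expect_false("g1" %in% reciprocal_best(ab, ba2)$query_gene)

  # exhaustive check on a 3x3 toy table with a top-score tie
  ab3 <- expand.grid(query = paste0("g", 1:3), subject = paste0("h", 1:3),
                     stringsAsFactors = FALSE)
  ab3$score <- c(9, 1, 2, 9, 3, 4, 1, 2, 8)   # g1 ties h1/h2 at 9
  ba3 <- data.frame(query = ab3$subject, subject = ab3$query,
                    score = ab3$score, stringsAsFactors = FALSE)
  rb3 <- reciprocal_best(ab3, ba3)
  expect_false("g1" %in% rb3$query_gene)
  expect_true("g3" %in% rb3$query_gene)       # unique best h3 both ways
  expect_lte(max(table(rb3$query_gene)), 1)
  expect_lte(max(table(rb3$ref_gene)), 1)
})

test_that("dot-plot tables report sorted midpoints and skip unknown genes", {
  pairs <- data.frame(query_gene = c("g1", "g2", "g3"),
                      ref_gene = c("h1", "h2", "h3"),
                      score_ab = 1, score_ba = 1, stringsAsFactors = FALSE)
  qc <- data.frame(gene_id = c("g1", "g2"), chrom = c("13", "2"),
                   start = c(100, 500), end = c(200, 700),
                   stringsAsFactors = FALSE)
  rc <- data.frame(gene_id = c("h1", "h2"), chrom = c("13", "2"),
                   start = c(1000, 300), end = c(1100, 500),
                   stringsAsFactors = FALSE)
  expect_warning(tab <- dotplot_table(pairs, qc, rc), "skipped")
  expect_equal(nrow(tab), 2)
  expect_equal(tab$query_chr, c("13", "2")[order(c("13", "2"))])
  expect_equal(tab$query_pos[tab$query_chr == "13"], 150)
  expect_equal(tab$ref_pos[tab$query_chr == "13"], 1050)
  # empty input -> empty table
  expect_equal(nrow(dotplot_table(pairs[0, ], qc, rc)), 0)
})

test_that("a translocated block shows up off the dot-plot diagonal", {
  # genes 1..10 colinear on chr1 of both species except a planted block
  # moved to chr2 of the query species
  qc <- data.frame(gene_id = paste0("g", 1:10),
                   chrom = c(rep("q1", 7), rep("q2", 3)),
                   start = c(seq(0, 6000, by = 1000), seq(0, 2000, by = 1000)),
                   end = c(seq(500, 6500, by = 1000), seq(500, 2500, by = 1000)),
                   stringsAsFactors = FALSE)
  rc <- data.frame(gene_id = paste0("h", 1:10), chrom = "r1",
                   start = seq(0, 9000, by = 1000),
                   end = seq(500, 9500, by = 1000), stringsAsFactors = FALSE)
  pairs <- data.frame(query_gene = paste0("g", 1:10),
                      ref_gene = paste0("h", 1:10),
                      score_ab = 1, score_ba = 1, stringsAsFactors = FALSE)
  tab <- dotplot_table(pairs, qc, rc)
  off <- tab[tab$query_chr == "q2", ]
  expect_equal(nrow(off), 3)
  expect_true(all(off$ref_chr == "r1"))
})
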