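# Assisted-assembly core: insert models, pair filtering, bridges, gap
# filling, scaffold reordering and assembly merging.

test_that("insert model selects the central 99% of the dominant mode", {
  # degenerate histogram: all inserts identical
  p1 <- do.call(rbind, replicate(200, pair_row(ls = 0, le = 100, rs = 200,
                                               re = 300), simplify = FALSE))
  m1 <- build_insert_model(p1, library_spec("L", 300, 30, "FR", 1))
  expect_equal(m1$selected_range, c(300, 300))

  # normal inserts: range tracks the empirical 0.5/99.5 percentiles
  set.seed(41)
  ins <- round(rnorm(1e4, 300, 30))
  p2 <- do.call(rbind, lapply(ins, function(L)
    pair_row(ls = 0, le = 100, rs = L - 100, re = L)))
  m2 <- build_insert_model(p2, library_spec("L", 300, 30, "FR", 1))
  q <- quantile(ins, c(0.005, 0.995), type = 1, names = FALSE)
  expect_lt(abs(m2$selected_range[1] - q[1]), 6)
  expect_lt(abs(m2$selected_range[2] - q[2]), 6)

  # 95% mass at 300, 5% at 4000: range confined to the dominant mode
  ins3 <- c(round(rnorm(9500, 300, 10)), round(rnorm(500, 4000, 10)))
  p3 <- do.call(rbind, lapply(ins3, function(L)
    pair_row(ls = 0, le = 100, rs = L - 100, re = L)))
  m3 <- build_insert_model(p3, library_spec("L", 300, 30, "FR", 1))
  expect_lt(m3$selected_range[2], 500)

  # underpowered library errors
  expect_error(build_insert_model(p1[1:50, ],
                                  library_spec("L", 300, 30, "FR", 1)),
               "underpowered")
})

test_that("pair filtering requires both correct orientation and insert range", {
  m <- fake_model(range = c(240, 360), center = 300)
  pairs <- rbind(
    pair_row(ls = 0, le = 100, rs = 210, re = 310),                  # kept
    pair_row(ls = 0, le = 100, rs = 210, re = 310, orientation = "RF"),
    pair_row(ls = 0, le = 100, rs = 4900, re = 5000))                # range
  out <- filter_pairs(pairs, m)
  expect_equal(nrow(out), 1)
  expect_equal(out$insert, 310)
  expect_equal(attr(out, "n_orientation_fail"), 1)
  expect_equal(attr(out, "n_range_fail"), 1)
})

test_that("bridges require spanning support in consecutive contigs", {
  sc <- seq_records("s1", paste0(random_seq(1000, 42), strrep("N", 100),
                                 random_seq(1000, 43)))
  spanning <- do.call(rbind, lapply(1:10, function(i)
    pair_row(target = "s1", ls = 840 + i, le = 940 + i,
             rs = 1150 + i, re = 1250 + i)))
  models <- list(fake_model(center = 400))
  b <- find_bridges(sc, spanning, models, min_support = 3)
  expect_equal(nrow(b), 1)
  expect_equal(b$supporting_pairs, 10)
  # (center 400) - flankL - flankR estimates the 100 bp gap
  expect_lt(abs(b$gap_estimate - 100), 20)
  expect_equal(b$left_contig, "s1_ctg1")
  expect_equal(b$right_contig, "s1_ctg2")

  # non-spanning pairs provide no bridge
  rand <- do.call(rbind, lapply(1:10, function(i)
    pair_row(target = "s1", ls = 100 + i, le = 200 + i,
             rs = 500 + i, re = 600 + i)))
  expect_equal(nrow(find_bridges(sc, rand, models)), 0)

  # below min_support
  expect_equal(nrow(find_bridges(sc, spanning[1:2, ], models,
                                 min_support = 3)), 0)
})

test_that("gap filling recovers the exact planted fill and reports failures", {
  g <- random_seq(6000, seed = 44)
  left <- substr(g, 1, 2000)
  fill <- substr(g, 2001, 2050)
  right <- substr(g, 2051, 6000)
  reads <- substring(g, seq(1, 5900, by = 3), seq(1, 5900, by = 3) + 99)
  w <- cg_kmer_walk(left, right, reads, 30, 5000, 10)
  expect_equal(w$status, "filled")
  expect_identical(w$fill, fill)

  # true fill longer than max_gap -> explicit too-long status
  g2 <- random_seq(14000, seed = 45)
  w2 <- cg_kmer_walk(substr(g2, 1, 2000), substr(g2, 10001, 14000),
                     substring(g2, seq(1, 13900, by = 3),
                               seq(1, 13900, by = 3) + 99),
                     30, 5000, 10)
  expect_equal(w2$status, "unfilled_too_long")

  # two divergent extensions -> explicit ambiguity status
  stem <- random_seq(2000, seed = 46)
  branch_point <- random_seq(40, seed = 47)
  arm1 <- paste0(stem, branch_point, "A", random_seq(200, 48))
  arm2 <- paste0(stem, branch_point, "C", random_seq(200, 49))
  reads3 <- c(substring(arm1, seq(1, 2140, by = 5), seq(1, 2140, by = 5) + 99),
              substring(arm2, seq(1, 2140, by = 5), seq(1, 2140, by = 5) + 99))
  w3 <- cg_kmer_walk(stem, random_seq(2000, seed = 50), reads3, 30, 5000, 10)
  expect_equal(w3$status, "unfilled_ambiguous")
})

test_that("gap-fill count is monotone in max_gap and bridges in min_support", {
  cfg <- sim_config(genome_length = 3e5, n_chromosomes = 1, seed = 51)
  ref <- simulate_reference(cfg)
  fs <- fragment_scaffolds(ref, gap_count = 10, gap_len_range = c(20, 120), seed = 51)
  prs <- simulate_pairs(ref, libraries = list(library_spec("frag", 300, 30, "FR", 30)),
                        read_length = 100, per_base_error = 0, seed = 51)
  rt <- as_read_table(prs)
  aln <- map_reads(fs$scaffolds, rt)
  pa <- pair_alignments(aln, rt)
  mod <- build_insert_model(pa, library_spec("frag", 300, 30, "FR", 30))
  filt <- filter_pairs(pa, mod)
  counts <- vapply(c(1, 3, 10, 50), function(ms)
    nrow(find_bridges(fs$scaffolds, filt, list(mod), min_support = ms)),
    numeric(1))
  expect_true(all(diff(counts) <= 0))

  br <- find_bridges(fs$scaffolds, filt, list(mod))
  filled <- vapply(c(30, 200, 5000), function(mg) {
    f <- fill_gaps(br, fs$scaffolds, rt, aln, max_gap = mg, end_window = 400)
    sum(f$status == "filled")
  }, numeric(1))
  expect_true(all(diff(filled) >= 0))
})

test_that("applying fills restores the true sequence", {
  cfg <- sim_config(genome_length = 3e5, n_chromosomes = 1, seed = 52)
  ref <- simulate_reference(cfg)
  fs <- fragment_scaffolds(ref, gap_count = 8, gap_len_range = c(20, 120), seed = 52)
  prs <- simulate_pairs(ref, libraries = list(library_spec("frag", 300, 30, "FR", 30)),
                        read_length = 100, per_base_error = 0, seed = 52)
  rt <- as_read_table(prs)
  aln <- map_reads(fs$scaffolds, rt)
  pa <- pair_alignments(aln, rt)
  mod <- build_insert_model(pa, library_spec("frag", 300, 30, "FR", 30))
  br <- find_bridges(fs$scaffolds, filter_pairs(pa, mod), list(mod))
  fills <- fill_gaps(br, fs$scaffolds, rt, aln, end_window = 400)
  done <- apply_fills(fs$scaffolds, br, fills)
  # every filled gap region now equals the reference
  expect_true(all(fills$status == "filled"))
  expect_identical(done$sequence, ref$sequence)
})

test_that("cross-scaffold links join mutually best ends and flag conflicts", {
  s <- seq_records(c("s1", "s2", "s3"),
                   c(random_seq(5000, 53), random_seq(5000, 54),
                     random_seq(5000, 55)))
  mk_links <- function(a, enda, b, endb, n, start_read = 1) {
    # one aligned row per mate nominating the given scaffold end
    rows1 <- data.frame(read = seq(start_read, by = 2, length.out = n),
                        target_id = a,
                        tstart = if (enda == "R") 4500 else 100,
                        tend = if (enda == "R") 4600 else 200,
                        strand = if (enda == "R") "+" else "-",
                        stringsAsFactors = FALSE)
    rows2 <- data.frame(read = seq(start_read + 1, by = 2, length.out = n),
                        target_id = b,
                        tstart = if (endb == "R") 4500 else 100,
                        tend = if (endb == "R") 4600 else 200,
                        strand = if (endb == "R") "+" else "-",
                        stringsAsFactors = FALSE)
    rbind(rows1, rows2)
  }
  rt <- function(n) data.frame(
    id = paste0("p", rep(seq_len(n), each = 2), c("/1", "/2")),
    seq = "ACGT", lib = "L", pair = rep(seq_len(n), each = 2),
    mate = as.integer(seq_len(2 * n) + c(1, -1)), stringsAsFactors = FALSE)

  a1 <- mk_links("s1", "R", "s2", "L", 20)
  out <- reorder_scaffolds(s, a1, rt(20), window = 1000, min_links = 5)
  expect_equal(out$events$type, "join")
  expect_equal(nrow(out$scaffolds), 2)
  joined <- out$scaffolds[grepl("\\+", out$scaffolds$id), ]
  expect_equal(joined$id, "s1+s2")
  expect_equal(nchar(joined$sequence), 10100)  # two scaffolds + 100 N gap

  # no cross links: nothing changes
  out0 <- reorder_scaffolds(s, a1[0, ], rt(1), window = 1000)
  expect_equal(nrow(out0$events), 0)
  expect_identical(out0$scaffolds, s)

  # the same end linked to two partners: conflict, no join
  a2 <- rbind(mk_links("s1", "R", "s2", "L", 20),
              mk_links("s1", "R", "s3", "L", 20, start_read = 41))
  out2 <- reorder_scaffolds(s, a2, rt(40), window = 1000, min_links = 5)
  expect_true(all(out2$events$type == "conflict"))
  expect_identical(out2$scaffolds, s)
})

test_that("assembly merging drops covered de novo contigs and keeps novel ones", {
  assisted <- seq_records("a1", random_seq(20000, 56), "scaffold")
  covered <- seq_records("d1", substr(assisted$sequence, 3001, 8000), "contig")
  novel <- seq_records("d2", random_seq(3000, 57), "contig")
  partial <- seq_records("d3",
                         paste0(substr(assisted$sequence, 12001, 14000),
                                random_seq(3500, 58)), "contig")
  denovo <- rbind(covered, novel, partial)
  out <- merge_assemblies(assisted, denovo)
  expect_equal(out$report$action[out$report$contig == "d1"], "dropped")
  expect_equal(out$report$action[out$report$contig == "d2"], "added")
  # 2000 of 5500 covered (36%) is below the 50% threshold
  expect_equal(out$report$action[out$report$contig == "d3"], "added")
  expect_setequal(out$assembly$id, c("a1", "d2", "d3"))
  # every de novo contig appears exactly once in the report
  expect_setequal(out$report$contig, denovo$id)
})
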