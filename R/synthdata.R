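# Synthetic congener genomes with planted truth.
#
# The generator emulates the sequencing design the toolkit targets: a
# reference genome plus a diverged genome of a sister species (point
# mutations around 1 per 100 bp, short InDels, large cut-and-paste
# translocations, TE insertions with an age distribution), and tiered
# paired-end libraries (short-insert fragments read inward, long-insert
# mate pairs read outward). Every planted event is recorded in a truth set,
# and applying the truth set to the reference reproduces the derived genome
# byte for byte.
#
# Determinism: all draws go through R's Mersenne-Twister stream seeded from
# `seed` plus a fixed per-operation offset, so results are reproducible
# across platforms and independent of call order.

BASES <- c("A", "C", "G", "T")
TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

#' Tiered sequencing library specification
#'
#' @param name library name.
#' @param insert_mean mean insert (fragment) size, bp.
#' @param insert_sd insert size standard deviation, bp.
#' @param orientation "FR" (short-insert fragments, reads point inward) or
#'   "RF" (long-insert mate pairs, reads point outward).
#' @param coverage fold sequence coverage contributed by the library.
#' @return classed list `congener_library`.
#' @export
library_spec <- function(name, insert_mean, insert_sd, orientation = c("FR", "RF"),
                         coverage) {
  orientation <- match.arg(orientation)
  stopifnot(insert_mean > 0, insert_sd >= 0, coverage > 0)
  structure(list(name = name, insert_mean = insert_mean, insert_sd = insert_sd,
                 orientation = orientation, coverage = coverage),
            class = "congener_library")
}

#' Default tiered library design
#'
#' A 30x short-insert fragment library (300 bp, FR) plus 17x 3 kb and 5x 8 kb
#' mate-pair libraries (RF) -- the tiered 300 bp-to-8 kb design the assisted
#' assembly procedure expects.
#'
#' @return list of [library_spec()] objects.
#' @export
tiered_libraries <- function() {
  list(library_spec("frag300", 300, 30, "FR", 30),
       library_spec("mp3k", 3000, 300, "RF", 17),
       library_spec("mp8k", 8000, 800, "RF", 5))
}

#' Transposable-element family specification for planting
#'
#' @param name family name (used as superfamily_class in downstream tables).
#' @param consensus consensus sequence string.
#' @param count number of copies to plant.
#' @param divergence per-copy divergence (proportion of mutated sites):
#'   numeric vector recycled to `count`, or a function(n) returning n draws.
#' @return classed list `congener_te_family`.
#' @export
te_family <- function(name, consensus, count, divergence) {
  stopifnot(nchar(consensus) > 0, count >= 0)
  structure(list(name = name, consensus = toupper(consensus), count = count,
                 divergence = divergence),
            class = "congener_te_family")
}

#' Simulation configuration
#'
#' Defaults are the desk-scale study conditions used throughout the test
#' suite: a 2 Mb genome in 8 chromosomes at 35 % GC, congener divergence of
#' 1 SNC per 100 bp and 1 InDel per 1000 bp (lengths uniform on 1..10), and
#' the tiered 30x/17x/5x library design with 100 bp reads.
#'
#' @param genome_length total genome size, bp.
#' @param n_chromosomes number of chromosomes.
#' @param gc_fraction expected GC content of the reference.
#' @param snp_rate per-bp point-mutation rate between the species.
#' @param indel_rate per-bp InDel rate.
#' @param indel_max_len maximum InDel length (lengths uniform on 1..max).
#' @param n_translocations number of >= `translocation_min_len` cut-and-paste
#'   inter-chromosomal segments.
#' @param translocation_min_len minimum translocated segment length, bp.
#' @param te_families list of [te_family()] objects.
#' @param libraries list of [library_spec()] objects.
#' @param read_length read length, bp.
#' @param per_base_error per-base substitution error rate of simulated reads.
#' @param seed integer seed governing all draws.
#' @return classed list `congener_config`.
#' @export
sim_config <- function(genome_length = 2e6, n_chromosomes = 8,
                       gc_fraction = 0.35, snp_rate = 0.01,
                       indel_rate = 0.001, indel_max_len = 10,
                       n_translocations = 0, translocation_min_len = 25000,
                       te_families = list(), libraries = tiered_libraries(),
                       read_length = 100, per_base_error = 0, seed = 1) {
  stopifnot(snp_rate >= 0, snp_rate <= 1, indel_rate >= 0, indel_rate <= 1,
            gc_fraction >= 0, gc_fraction <= 1,
            per_base_error >= 0, per_base_error <= 1,
            n_chromosomes >= 1, genome_length >= n_chromosomes)
  if (n_translocations > 0 && genome_length < 10 * translocation_min_len)
    stop("genome_length must be >= 10 x translocation_min_len when ",
         "translocations are requested")
  for (lib in libraries)
    if (lib$orientation == "FR" && lib$insert_mean <= 2 * read_length)
      stop("FR library ", lib$name, ": insert_mean must exceed 2 x read_length")
  structure(list(genome_length = genome_length, n_chromosomes = n_chromosomes,
                 gc_fraction = gc_fraction, snp_rate = snp_rate,
                 indel_rate = indel_rate, indel_max_len = indel_max_len,
                 n_translocations = n_translocations,
                 translocation_min_len = translocation_min_len,
                 te_families = te_families, libraries = libraries,
                 read_length = read_length, per_base_error = per_base_error,
                 seed = seed),
            class = "congener_config")
}

#' Simulate a reference genome
#'
#' Bases are i.i.d. with expected GC equal to `gc_fraction`; chromosomes are
#' named chr1..chrN and sized as equal shares of `genome_length`.
#'
#' @param config a [sim_config()].
#' @return sequence record table, tier "chromosome".
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "congener_config"))
  with_seed(config$seed, {
    n <- config$n_chromosomes
    lens <- rep(config$genome_length %/% n, n)
    lens[1] <- lens[1] + config$genome_length %% n
    p <- c((1 - config$gc_fraction) / 2, config$gc_fraction / 2,
           config$gc_fraction / 2, (1 - config$gc_fraction) / 2)
    seqs <- vapply(lens, function(L)
      paste(sample(BASES, L, replace = TRUE, prob = p), collapse = ""),
      character(1))
    seq_records(paste0("chr", seq_len(n)), seqs, "chromosome")
  })
}

# mutate one base vector: transitions twice as likely as either transversion
mutate_bases <- function(ref_bases) {
  n <- length(ref_bases)
  is_ti <- runif(n) < 2 / 3
  alt <- character(n)
  alt[is_ti] <- TRANSITION[ref_bases[is_ti]]
  if (any(!is_ti)) {
    tv1 <- c(A = "C", G = "C", C = "A", T = "A")
    tv2 <- c(A = "T", G = "T", C = "G", T = "G")
    pick <- runif(sum(!is_ti)) < 0.5
    alt[!is_ti] <- ifelse(pick, tv1[ref_bases[!is_ti]], tv2[ref_bases[!is_ti]])
  }
  unname(alt)
}

#' Derive a congener genome from a reference
#'
#' Plants point mutations at `snp_rate` (transition:transversion 2:1), InDels
#' at `indel_rate` with lengths uniform on 1..`indel_max_len`, and
#' `n_translocations` cut-and-paste inter-chromosomal segments of at least
#' `translocation_min_len` bp. Overlapping events are re-drawn, never
#' stacked. Every event is recorded in the returned truth set; applying the
#' truth set to the reference ([apply_truth()]) reproduces the derived
#' genome exactly.
#'
#' Variant truth records use VCF-style anchoring in reference coordinates
#' (0-based): SNC rows have single-base ref/alt; INS rows anchor on the base
#' before the insertion; DEL rows carry the anchor base plus deleted bases.
#'
#' @param reference output of [simulate_reference()].
#' @param config the same [sim_config()].
#' @return list(genome = derived sequence table, truth = list(variants,
#'   rearrangements)).
#' @export
diverge_genome <- function(reference, config) {
  stopifnot(inherits(config, "congener_config"))
  validate_seq_records(reference)
  with_seed(config$seed + 1L, {
    derived <- character(nrow(reference))
    var_rows <- vector("list", nrow(reference))
    for (ci in seq_len(nrow(reference))) {
      s <- strsplit(reference$sequence[ci], "")[[1]]
      L <- length(s)
      # --- InDels: draw, then greedily accept non-overlapping, re-draw rest
      ind_pos <- which(runif(L) < config$indel_rate)
      ind_pos <- ind_pos[ind_pos > 1 & ind_pos < L - config$indel_max_len - 1]
      n_ind <- length(ind_pos)
      ind <- NULL
      if (n_ind > 0) {
        lens <- sample.int(config$indel_max_len, n_ind, replace = TRUE)
        is_del <- runif(n_ind) < 0.5
        o <- order(ind_pos)
        ind <- data.frame(pos = ind_pos[o], len = lens[o], del = is_del[o])
        # accept while keeping >= 1 bp clearance between affected spans
        keep <- logical(nrow(ind))
        last_end <- -1L
        for (i in seq_len(nrow(ind))) {
          span_end <- ind$pos[i] + ifelse(ind$del[i], ind$len[i], 0L)
          if (ind$pos[i] > last_end + 1L) {
            keep[i] <- TRUE
            last_end <- span_end
          }
        }
        ind <- ind[keep, , drop = FALSE]
      }
      # --- SNCs outside InDel-affected spans
      snp_pos <- which(runif(L) < config$snp_rate)
      if (!is.null(ind) && nrow(ind)) {
        blocked <- unlist(lapply(seq_len(nrow(ind)), function(i)
          ind$pos[i]:(ind$pos[i] + ifelse(ind$del[i], ind$len[i], 0L))))
        snp_pos <- setdiff(snp_pos, blocked)
      }
      snc <- NULL
      if (length(snp_pos)) {
        ref_b <- s[snp_pos]
        alt_b <- mutate_bases(ref_b)
        snc <- data.frame(chrom = reference$id[ci], pos = snp_pos - 1L,
                          ref = ref_b, alt = alt_b, type = "SNC",
                          stringsAsFactors = FALSE)
      }
      # --- build derived chromosome
      d <- s
      if (!is.null(snc) && nrow(snc)) d[snc$pos + 1L] <- snc$alt
      ind_rows <- NULL
      if (!is.null(ind) && nrow(ind)) {
        recs <- vector("list", nrow(ind))
        for (i in rev(seq_len(nrow(ind)))) {
          p <- ind$pos[i]; l <- ind$len[i]
          if (ind$del[i]) {
            recs[[i]] <- data.frame(
              chrom = reference$id[ci], pos = p - 1L,
              ref = paste(s[p:(p + l)], collapse = ""),
              alt = s[p], type = "DEL", stringsAsFactors = FALSE)
            d <- d[-((p + 1L):(p + l))]
          } else {
            insert <- sample(BASES, l, replace = TRUE)
            recs[[i]] <- data.frame(
              chrom = reference$id[ci], pos = p - 1L,
              ref = s[p],
              alt = paste(c(s[p], insert), collapse = ""),
              type = "INS", stringsAsFactors = FALSE)
            d <- append(d, insert, after = p)
          }
        }
        ind_rows <- do.call(rbind, recs)
      }
      derived[ci] <- paste(d, collapse = "")
      var_rows[[ci]] <- rbind(snc, ind_rows)
    }
    variants <- do.call(rbind, var_rows)
    if (is.null(variants))
      variants <- data.frame(chrom = character(0), pos = integer(0),
                             ref = character(0), alt = character(0),
                             type = character(0), stringsAsFactors = FALSE)
    variants <- variants[order(match(variants$chrom, reference$id),
                               variants$pos), , drop = FALSE]
    rownames(variants) <- NULL
    genome <- seq_records(reference$id, derived, "chromosome")
    # --- translocations: sequential cut-and-paste, distinct (src, dst) pairs
    re_rows <- list()
    if (config$n_translocations > 0) {
      if (nrow(genome) < 2) stop("translocations need >= 2 chromosomes")
      pairs_all <- expand.grid(src = seq_len(nrow(genome)),
                               dst = seq_len(nrow(genome)))
      pairs_all <- pairs_all[pairs_all$src != pairs_all$dst, ]
      if (config$n_translocations > nrow(pairs_all))
        stop("too many translocations for the chromosome count")
      pick <- pairs_all[sample.int(nrow(pairs_all), config$n_translocations), ]
      margin <- 2000L
      # planted segments are protected (current coordinates, per
      # chromosome): a later event may neither cut into nor split one
      protected <- rep(list(cbind(start = numeric(0), end = numeric(0))),
                       nrow(genome))
      hits_protected <- function(iv, lo, hi) {
        nrow(iv) > 0 && any(iv[, "end"] + margin > lo &
                            iv[, "start"] - margin < hi)
      }
      for (i in seq_len(config$n_translocations)) {
        src <- pick$src[i]; dst <- pick$dst[i]
        src_len <- nchar(genome$sequence[src])
        seg_len <- round(runif(1, config$translocation_min_len,
                               1.6 * config$translocation_min_len))
        if (src_len < seg_len + 2 * margin)
          stop("chromosome ", genome$id[src], " too short for a ",
               seg_len, " bp translocation")
        start <- at <- NA_real_
        for (attempt in 1:200) {
          start <- floor(runif(1, margin, src_len - seg_len - margin))
          dst_len <- nchar(genome$sequence[dst])
          at <- floor(runif(1, margin, dst_len - margin))
          if (!hits_protected(protected[[src]], start, start + seg_len) &&
              !hits_protected(protected[[dst]], at, at))
            break
          if (attempt == 200)
            stop("could not place translocation ", i,
                 " without stacking on an earlier event")
        }
        dst_len <- nchar(genome$sequence[dst])
        seg <- substr(genome$sequence[src], start + 1L, start + seg_len)
        genome$sequence[src] <- paste0(
          substr(genome$sequence[src], 1L, start),
          substr(genome$sequence[src], start + seg_len + 1L, src_len))
        genome$sequence[dst] <- paste0(
          substr(genome$sequence[dst], 1L, at), seg,
          substr(genome$sequence[dst], at + 1L, dst_len))
        # shift protected intervals for the coordinate changes, then
        # protect the newly planted segment
        ps <- protected[[src]]
        if (nrow(ps)) {
          after <- ps[, "start"] >= start + seg_len
          ps[after, ] <- ps[after, , drop = FALSE] - seg_len
          protected[[src]] <- ps
        }
        pd <- protected[[dst]]
        if (nrow(pd)) {
          after <- pd[, "start"] >= at
          pd[after, ] <- pd[after, , drop = FALSE] + seg_len
          protected[[dst]] <- pd
        }
        protected[[dst]] <- rbind(protected[[dst]],
                                  cbind(start = at, end = at + seg_len))
        re_rows[[i]] <- data.frame(
          src_chrom = genome$id[src], src_start = start, length = seg_len,
          dst_chrom = genome$id[dst], dst_pos = at, stringsAsFactors = FALSE)
      }
    }
    rearrangements <- if (length(re_rows)) do.call(rbind, re_rows) else
      data.frame(src_chrom = character(0), src_start = integer(0),
                 length = integer(0), dst_chrom = character(0),
                 dst_pos = integer(0), stringsAsFactors = FALSE)
    list(genome = genome,
         truth = list(variants = variants, rearrangements = rearrangements))
  })
}

#' Reconstruct a derived genome from the reference and a truth set
#'
#' Applies recorded variants (per chromosome, InDels right to left), then
#' rearrangements in recorded order. Used to verify truth-set closure.
#'
#' @param reference reference sequence table.
#' @param truth truth list from [diverge_genome()].
#' @return sequence record table that should equal the derived genome.
#' @export
apply_truth <- function(reference, truth) {
  genome <- reference
  v <- truth$variants
  for (ci in seq_len(nrow(genome))) {
    vv <- v[v$chrom == genome$id[ci], , drop = FALSE]
    if (!nrow(vv)) next
    s <- strsplit(genome$sequence[ci], "")[[1]]
    snc <- vv[vv$type == "SNC", , drop = FALSE]
    if (nrow(snc)) s[snc$pos + 1L] <- snc$alt
    ind <- vv[vv$type != "SNC", , drop = FALSE]
    if (nrow(ind)) {
      ind <- ind[order(-ind$pos), , drop = FALSE]
      for (i in seq_len(nrow(ind))) {
        p <- ind$pos[i] + 1L
        if (ind$type[i] == "DEL") {
          l <- nchar(ind$ref[i]) - 1L
          s <- s[-((p + 1L):(p + l))]
        } else {
          insert <- strsplit(substr(ind$alt[i], 2L, nchar(ind$alt[i])), "")[[1]]
          s <- append(s, insert, after = p)
        }
      }
    }
    genome$sequence[ci] <- paste(s, collapse = "")
  }
  r <- truth$rearrangements
  for (i in seq_len(nrow(r))) {
    src <- match(r$src_chrom[i], genome$id)
    dst <- match(r$dst_chrom[i], genome$id)
    start <- r$src_start[i]; seg_len <- r$length[i]; at <- r$dst_pos[i]
    src_len <- nchar(genome$sequence[src])
    seg <- substr(genome$sequence[src], start + 1L, start + seg_len)
    genome$sequence[src] <- paste0(
      substr(genome$sequence[src], 1L, start),
      substr(genome$sequence[src], start + seg_len + 1L, src_len))
    dst_len <- nchar(genome$sequence[dst])
    genome$sequence[dst] <- paste0(
      substr(genome$sequence[dst], 1L, at), seg,
      substr(genome$sequence[dst], at + 1L, dst_len))
  }
  genome
}

#' Plant transposable-element copies into a genome
#'
#' Each copy is the family consensus mutated to its drawn divergence d
#' (a fraction d of sites changed; transitions twice as likely as
#' transversions), inserted at a random position on either strand. Planted
#' intervals and true divergences are recorded.
#'
#' @param genome sequence record table.
#' @param config a [sim_config()] with non-empty `te_families`.
#' @return list(genome = genome with insertions, te_copies = truth
#'   data.frame with chrom, start, end (final coordinates), family,
#'   divergence, strand).
#' @export
plant_tes <- function(genome, config) {
  stopifnot(inherits(config, "congener_config"))
  if (!length(config$te_families)) stop("config$te_families is empty")
  validate_seq_records(genome)
  with_seed(config$seed + 2L, {
    # draw all copies first
    copies <- list()
    for (fam in config$te_families) {
      if (fam$count == 0) next
      d <- if (is.function(fam$divergence)) fam$divergence(fam$count)
           else rep_len(fam$divergence, fam$count)
      cons <- strsplit(fam$consensus, "")[[1]]
      for (j in seq_len(fam$count)) {
        s <- cons
        m <- round(d[j] * length(s))
        if (m > 0) {
          sites <- sample.int(length(s), m)
          s[sites] <- mutate_bases(s[sites])
        }
        strand <- if (runif(1) < 0.5) "+" else "-"
        seqc <- paste(s, collapse = "")
        if (strand == "-") seqc <- revcomp(seqc)
        copies[[length(copies) + 1L]] <- list(family = fam$name,
                                              divergence = d[j],
                                              strand = strand, seq = seqc)
      }
    }
    if (!length(copies))
      return(list(genome = genome,
                  te_copies = data.frame(chrom = character(0),
                                         start = integer(0), end = integer(0),
                                         family = character(0),
                                         divergence = numeric(0),
                                         strand = character(0),
                                         stringsAsFactors = FALSE)))
    lens <- nchar(genome$sequence)
    chrom_i <- sample.int(nrow(genome), length(copies), replace = TRUE,
                          prob = lens)
    at <- floor(runif(length(copies), 1000, lens[chrom_i] - 1000))
    # distinct insertion points (re-draw collisions)
    while (anyDuplicated(paste(chrom_i, at))) {
      dup <- duplicated(paste(chrom_i, at))
      at[dup] <- floor(runif(sum(dup), 1000, lens[chrom_i[dup]] - 1000))
    }
    rows <- vector("list", length(copies))
    for (ci in seq_len(nrow(genome))) {
      k <- which(chrom_i == ci)
      if (!length(k)) next
      k <- k[order(at[k])]
      offs <- cumsum(c(0, vapply(copies[k], function(x) nchar(x$seq),
                                 numeric(1))))[seq_along(k)]
      # apply right to left so earlier positions stay valid
      for (j in rev(seq_along(k))) {
        idx <- k[j]
        p <- at[idx]
        genome$sequence[ci] <- paste0(
          substr(genome$sequence[ci], 1L, p),
          copies[[idx]]$seq,
          substr(genome$sequence[ci], p + 1L, nchar(genome$sequence[ci])))
      }
      for (j in seq_along(k)) {
        idx <- k[j]
        st <- at[idx] + offs[j]
        rows[[idx]] <- data.frame(
          chrom = genome$id[ci], start = st,
          end = st + nchar(copies[[idx]]$seq),
          family = copies[[idx]]$family,
          divergence = copies[[idx]]$divergence,
          strand = copies[[idx]]$strand, stringsAsFactors = FALSE)
      }
    }
    list(genome = genome, te_copies = do.call(rbind, rows))
  })
}

#' Simulate tiered paired-end reads
#'
#' Pair count per library is round(coverage x genome_length / (2 x
#' read_length)); insert sizes are normal(mean, sd); FR pairs read inward
#' from the fragment ends, RF pairs outward. Per-base substitution errors
#' are applied at `per_base_error`.
#'
#' @param genome sequence record table.
#' @param config a [sim_config()] (libraries, read_length, error, seed), or
#'   NULL to pass the pieces individually.
#' @param libraries,read_length,per_base_error,seed overrides of the
#'   corresponding config fields.
#' @return classed list `congener_pairs`: per library a data.frame with
#'   read1, read2, chrom, frag_start, insert.
#' @export
simulate_pairs <- function(genome, config = NULL, libraries = NULL,
                           read_length = NULL, per_base_error = NULL,
                           seed = NULL) {
  validate_seq_records(genome)
  libraries <- libraries %||% config$libraries
  read_length <- read_length %||% config$read_length
  per_base_error <- per_base_error %||% config$per_base_error
  seed <- seed %||% config$seed
  stopifnot(!is.null(libraries), !is.null(read_length), !is.null(seed))
  per_base_error <- per_base_error %||% 0
  G <- sum(nchar(genome$sequence))
  lens <- nchar(genome$sequence)
  if (any(vapply(libraries, function(l) l$insert_mean, numeric(1)) >= min(lens)))
    stop("library insert_mean must be below the shortest chromosome length")
  out <- list()
  for (li in seq_along(libraries)) {
    lib <- libraries[[li]]
    out[[lib$name]] <- with_seed(seed + 3L + li, {
      n <- round(lib$coverage * G / (2 * read_length))
      ci <- sample.int(nrow(genome), n, replace = TRUE, prob = lens)
      L <- pmin(pmax(round(rnorm(n, lib$insert_mean, lib$insert_sd)),
                     read_length), lens[ci])
      s <- floor(runif(n) * (lens[ci] - L + 1))
      r1 <- character(n); r2 <- character(n)
      for (cc in seq_len(nrow(genome))) {
        k <- which(ci == cc)
        if (!length(k)) next
        sq <- genome$sequence[cc]
        r1[k] <- substring(sq, s[k] + 1L, s[k] + read_length)
        r2[k] <- revcomp(substring(sq, s[k] + L[k] - read_length + 1L,
                                   s[k] + L[k]))
      }
      if (lib$orientation == "RF") {
        r1 <- revcomp(r1)
        r2 <- revcomp(r2)
      }
      if (per_base_error > 0) {
        r1 <- add_read_errors(r1, per_base_error)
        r2 <- add_read_errors(r2, per_base_error)
      }
      data.frame(read1 = r1, read2 = r2, chrom = genome$id[ci],
                 frag_start = s, insert = L, stringsAsFactors = FALSE)
    })
  }
  structure(out, class = "congener_pairs", read_length = read_length)
}

add_read_errors <- function(reads, rate) {
  nerr <- rbinom(length(reads), nchar(reads), rate)
  hit <- which(nerr > 0)
  for (i in hit) {
    s <- strsplit(reads[i], "")[[1]]
    pos <- sample.int(length(s), nerr[i])
    s[pos] <- vapply(s[pos], function(b) sample(setdiff(BASES, b), 1),
                     character(1))
    reads[i] <- paste(s, collapse = "")
  }
  reads
}

#' Flatten simulated pairs into a read table
#'
#' @param pairs a `congener_pairs` object.
#' @return data.frame with id, seq, lib, pair (pair index within the table)
#'   and mate (row index of the mate), ready for [map_reads()].
#' @export
as_read_table <- function(pairs) {
  stopifnot(inherits(pairs, "congener_pairs"))
  tabs <- list()
  pair_off <- 0L
  row_off <- 0L
  for (nm in names(pairs)) {
    p <- pairs[[nm]]
    n <- nrow(p)
    tabs[[nm]] <- data.frame(
      id = c(paste0(nm, "_", seq_len(n), "/1"),
             paste0(nm, "_", seq_len(n), "/2")),
      seq = c(p$read1, p$read2),
      lib = nm,
      pair = pair_off + c(seq_len(n), seq_len(n)),
      mate = row_off + c(n + seq_len(n), seq_len(n)),
      stringsAsFactors = FALSE)
    pair_off <- pair_off + n
    row_off <- row_off + 2L * n
  }
  tab <- do.call(rbind, tabs)
  rownames(tab) <- NULL
  tab
}

#' Write simulated pairs as FASTQ files
#'
#' @param pairs a `congener_pairs` object.
#' @param dir output directory.
#' @return character vector of written paths.
#' @export
write_pairs_fastq <- function(pairs, dir) {
  stopifnot(inherits(pairs, "congener_pairs"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(pairs)) {
    p <- pairs[[nm]]
    for (mate in 1:2) {
      path <- file.path(dir, sprintf("%s_%d.fastq", nm, mate))
      reads <- if (mate == 1) p$read1 else p$read2
      write_fastq(data.frame(id = paste0(nm, "_", seq_len(nrow(p)), "/", mate),
                             sequence = reads, stringsAsFactors = FALSE),
                  path)
      paths <- c(paths, path)
    }
  }
  paths
}

#' Cut a genome into gapped scaffolds with known fills
#'
#' Replaces `gap_count` stretches of true sequence with equal-length N-runs,
#' at least 2 kb apart and 2 kb from chromosome ends, recording every
#' removed fill. Because the N-run has the same length as the removed
#' sequence, all other coordinates are unchanged.
#'
#' @param genome sequence record table.
#' @param gap_count number of gaps to plant.
#' @param gap_len_range inclusive range of gap lengths, bp.
#' @param seed integer seed.
#' @param min_spacing minimum distance between gaps and from ends (default
#'   2000).
#' @return list(scaffolds = gapped sequence table (tier "scaffold"),
#'   gap_fills = truth data.frame with scaffold, gap_index, start, end,
#'   fill).
#' @export
fragment_scaffolds <- function(genome, gap_count, gap_len_range = c(20, 500),
                               seed = 1, min_spacing = 2000) {
  validate_seq_records(genome)
  with_seed(seed + 4L, {
    lens <- nchar(genome$sequence)
    if (gap_count == 0)
      return(list(scaffolds = transform(genome, tier = "scaffold"),
                  gap_fills = data.frame(scaffold = character(0),
                                         gap_index = integer(0),
                                         start = integer(0), end = integer(0),
                                         fill = character(0),
                                         stringsAsFactors = FALSE)))
    ci <- sample.int(nrow(genome), gap_count, replace = TRUE, prob = lens)
    glen <- sample(gap_len_range[1]:gap_len_range[2], gap_count, replace = TRUE)
    # exact uniform placement with guaranteed spacing: draw sorted offsets
    # into the free space left after reserving gap lengths and spacers
    pos <- integer(gap_count)
    for (cc in unique(ci)) {
      k <- which(ci == cc)
      n_cc <- length(k)
      lens_cc <- glen[k]
      free <- lens[cc] - 2 * min_spacing - sum(lens_cc) -
        (n_cc - 1) * min_spacing
      if (free < 0)
        stop("could not place ", n_cc, " gaps with ", min_spacing,
             " bp spacing on ", genome$id[cc], "; sequence too small")
      u <- sort(floor(runif(n_cc, 0, free + 1)))
      offsets <- min_spacing +
        cumsum(c(0, lens_cc[-n_cc] + min_spacing))
      pos[k] <- u + offsets
    }
    scaffolds <- genome
    fills <- vector("list", gap_count)
    ord <- order(ci, pos)
    gi_counter <- stats::ave(seq_along(ord), ci[ord], FUN = seq_along)
    for (j in seq_along(ord)) {
      i <- ord[j]
      cc <- ci[i]
      fills[[j]] <- data.frame(
        scaffold = genome$id[cc], gap_index = gi_counter[j],
        start = pos[i], end = pos[i] + glen[i],
        fill = substr(genome$sequence[cc], pos[i] + 1L, pos[i] + glen[i]),
        stringsAsFactors = FALSE)
      scaffolds$sequence[cc] <- paste0(
        substr(scaffolds$sequence[cc], 1L, pos[i]),
        strrep("N", glen[i]),
        substr(scaffolds$sequence[cc], pos[i] + glen[i] + 1L,
               nchar(scaffolds$sequence[cc])))
    }
    scaffolds$tier <- "scaffold"
    list(scaffolds = scaffolds, gap_fills = do.call(rbind, fills))
  })
}

#' Split sequences into pieces with recorded origin
#'
#' Utility for building synthetic scaffolds or de novo contigs whose true
#' placement is known: cuts each sequence into consecutive pieces of roughly
#' `piece_length` bp and reverse-complements a random half.
#'
#' @param seqs sequence record table.
#' @param piece_length target piece length, bp.
#' @param seed integer seed.
#' @param tier tier for the pieces (default "scaffold").
#' @return list(pieces = sequence table, origin = data.frame with piece,
#'   chrom, start, end, strand).
#' @export
split_sequences <- function(seqs, piece_length, seed = 1, tier = "scaffold") {
  validate_seq_records(seqs)
  with_seed(seed + 5L, {
    pieces <- list(); origin <- list()
    n <- 0L
    for (ci in seq_len(nrow(seqs))) {
      L <- nchar(seqs$sequence[ci])
      bounds <- unique(c(seq(0L, L, by = piece_length), L))
      for (j in seq_len(length(bounds) - 1L)) {
        n <- n + 1L
        st <- bounds[j]; en <- bounds[j + 1L]
        if (en - st < 1) next
        s <- substr(seqs$sequence[ci], st + 1L, en)
        strand <- if (runif(1) < 0.5) "+" else "-"
        if (strand == "-") s <- revcomp(s)
        pieces[[n]] <- data.frame(id = sprintf("piece%04d", n), sequence = s,
                                  tier = tier, stringsAsFactors = FALSE)
        origin[[n]] <- data.frame(piece = sprintf("piece%04d", n),
                                  chrom = seqs$id[ci], start = st, end = en,
                                  strand = strand, stringsAsFactors = FALSE)
      }
    }
    list(pieces = do.call(rbind, pieces), origin = do.call(rbind, origin))
  })
}
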