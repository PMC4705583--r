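# Assisted-assembly core: insert-size models, pair filtering, 30-mer contig
# bridging across scaffold gaps, bounded k-mer gap filling, cross-scaffold
# reordering, and merging an assisted assembly with an independent de novo
# assembly.

#' Model a library's insert-size distribution from alignments
#'
#' Builds the histogram of observed inserts of properly oriented pairs,
#' finds the dominant mode (largest 10 bp-smoothed peak), and selects the
#' central 99 % interval of the mass within that mode as the usable insert
#' range.
#'
#' @param pairs pair table from [pair_alignments()].
#' @param library a [library_spec()] (name and expected orientation).
#' @param min_pairs minimum usable pairs (default 100).
#' @return classed list `congener_insert_model`: library, histogram
#'   (named counts), selected_range (low, high), expected_orientation,
#'   center (median insert within the mode), n_pairs.
#' @export
build_insert_model <- function(pairs, library, min_pairs = 100) {
  stopifnot(inherits(library, "congener_library"))
  p <- pairs[pairs$lib == library$name &
             pairs$orientation == library$orientation, , drop = FALSE]
  if (nrow(p) < min_pairs)
    stop("library underpowered: ", nrow(p), " properly oriented pairs for ",
         library$name, " (need >= ", min_pairs, ")")
  ins <- as.integer(round(p$insert))
  lo <- min(ins); hi <- max(ins)
  counts <- tabulate(ins - lo + 1L, nbins = hi - lo + 1L)
  # 10 bp moving-sum smoothing (degenerate histograms are left as is)
  sm <- if (length(counts) >= 10) {
    s <- as.numeric(stats::filter(counts, rep(1, 10), sides = 2))
    s[is.na(s)] <- 0
    s
  } else as.numeric(counts)
  peak <- which.max(sm)
  # dominant mode: contiguous nonzero smoothed region containing the peak
  nz <- sm > 0
  left <- peak
  while (left > 1 && nz[left - 1]) left <- left - 1
  right <- peak
  while (right < length(nz) && nz[right + 1]) right <- right + 1
  in_mode <- ins >= (lo + left - 1L) & ins <= (lo + right - 1L)
  q <- quantile(ins[in_mode], c(0.005, 0.995), type = 1, names = FALSE)
  structure(list(library = library$name,
                 histogram = table(ins),
                 selected_range = as.numeric(q),
                 expected_orientation = library$orientation,
                 center = median(ins[in_mode]),
                 n_pairs = nrow(p)),
            class = "congener_insert_model")
}

#' @export
print.congener_insert_model <- function(x, ...) {
  cat(sprintf("insert model '%s' (%s): range [%d, %d], center %d, %d pairs\n",
              x$library, x$expected_orientation, x$selected_range[1],
              x$selected_range[2], x$center, x$n_pairs))
  invisible(x)
}

#' Filter pairs by orientation and insert range
#'
#' A pair is retained iff its orientation matches the library's expected
#' orientation and its observed insert lies in the model's selected range.
#' The two rejection counts are recorded as attributes.
#'
#' @param pairs pair table from [pair_alignments()] (any library mix; only
#'   rows of the model's library are considered).
#' @param model a `congener_insert_model`.
#' @return the retained pair rows, with attributes `n_orientation_fail` and
#'   `n_range_fail`.
#' @export
filter_pairs <- function(pairs, model) {
  stopifnot(inherits(model, "congener_insert_model"))
  p <- pairs[pairs$lib == model$library, , drop = FALSE]
  ok_orient <- p$orientation == model$expected_orientation
  ok_range <- p$insert >= model$selected_range[1] &
              p$insert <= model$selected_range[2]
  out <- p[ok_orient & ok_range, , drop = FALSE]
  attr(out, "n_orientation_fail") <- sum(!ok_orient)
  attr(out, "n_range_fail") <- sum(ok_orient & !ok_range)
  out
}

#' Find contig bridges across scaffold gaps
#'
#' A filtered pair supports the bridge across a gap iff one mate lies
#' entirely in the contig left of the gap and the other entirely in the
#' contig right of it (consecutive contigs), each mate carries an exact
#' match of at least `k` bases, and the pair's fragment spans the gap. The
#' gap size is estimated as the median of (library insert center minus the
#' two flank distances) over supporting pairs.
#'
#' @param scaffolds sequence record table with N-run gaps.
#' @param filtered_pairs retained pairs from [filter_pairs()] (one or more
#'   libraries concatenated with rbind).
#' @param models named list of insert models keyed by library (for the
#'   insert center used in the gap estimate).
#' @param k required exact match length per mate (default 30).
#' @param min_support minimum supporting pairs per bridge (default 3).
#' @return data.frame of bridges: scaffold, gap_index, gap_start, gap_end,
#'   left_contig, right_contig, supporting_pairs, gap_estimate.
#' @export
find_bridges <- function(scaffolds, filtered_pairs, models, k = 30,
                         min_support = 3) {
  validate_seq_records(scaffolds)
  centers <- vapply(models, function(m) as.numeric(m$center), numeric(1))
  names(centers) <- vapply(models, function(m) m$library, character(1))
  out <- list()
  for (si in seq_len(nrow(scaffolds))) {
    sid <- scaffolds$id[si]
    gaps <- find_gaps(scaffolds$sequence[si])
    if (!nrow(gaps)) next
    ctg <- contig_intervals(nchar(scaffolds$sequence[si]), gaps)
    p <- filtered_pairs[filtered_pairs$target_id == sid, , drop = FALSE]
    if (!nrow(p)) next
    exact_ok <- p$left_max_exact >= k & p$right_max_exact >= k
    p <- p[exact_ok, , drop = FALSE]
    if (!nrow(p)) next
    # contig index of each mate; mate must lie entirely inside its contig
    left_ctg <- findInterval(p$left_start, ctg$start)
    right_ctg <- findInterval(p$right_start, ctg$start)
    in_left <- left_ctg >= 1 & p$left_end <= ctg$end[pmax(left_ctg, 1)]
    in_right <- right_ctg >= 1 & p$right_end <= ctg$end[pmax(right_ctg, 1)]
    spans <- in_left & in_right & (right_ctg == left_ctg + 1L)
    p <- p[spans, , drop = FALSE]
    gi <- left_ctg[spans]  # gap index == index of contig left of the gap
    if (!nrow(p)) next
    for (g in sort(unique(gi))) {
      sel <- gi == g
      if (sum(sel) < min_support) next
      flankL <- gaps$start[g] - p$left_start[sel]
      flankR <- p$right_end[sel] - gaps$end[g]
      est <- median(centers[p$lib[sel]] - flankL - flankR)
      out[[length(out) + 1L]] <- data.frame(
        scaffold = sid, gap_index = g,
        gap_start = gaps$start[g], gap_end = gaps$end[g],
        left_contig = paste0(sid, "_ctg", g),
        right_contig = paste0(sid, "_ctg", g + 1L),
        supporting_pairs = sum(sel), gap_estimate = est,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(scaffold = character(0), gap_index = integer(0),
                      gap_start = integer(0), gap_end = integer(0),
                      left_contig = character(0), right_contig = character(0),
                      supporting_pairs = integer(0), gap_estimate = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Fill bridged gaps by bounded local k-mer assembly
#'
#' For each bridge, builds a 30-mer index from reads mapped near the gap
#' (within `end_window` of either flank) plus the unmapped mates of those
#' reads, and walks the k-mer graph from the left flank's terminal k-mer
#' toward the right flank's initial k-mer. Every step must have a unique
#' successor; a branch is an explicit `unfilled_ambiguous` failure, a dead
#' end after progress is `partial`, and exceeding `max_gap` total extension
#' is `unfilled_too_long`.
#'
#' @param bridges bridge table from [find_bridges()].
#' @param scaffolds the scaffold sequence table.
#' @param read_table read table ([as_read_table()]).
#' @param aln alignment table of those reads against the scaffolds.
#' @param k k-mer size (default 30).
#' @param max_gap maximum fill length, bp (default 5000).
#' @param max_iterations extension budget per gap; one iteration is a
#'   max_gap/max_iterations-bp extension chunk (default 10).
#' @param end_window window around the gap from which reads are admitted to
#'   the index; conventionally the insert mean of the largest library.
#' @return data.frame: scaffold, gap_index, status (filled, partial,
#'   unfilled_ambiguous, unfilled_too_long, unfilled_no_path), fill,
#'   fill_len, iterations_used.
#' @export
fill_gaps <- function(bridges, scaffolds, read_table, aln, k = 30,
                      max_gap = 5000, max_iterations = 10, end_window = 8000) {
  validate_seq_records(scaffolds)
  res <- vector("list", nrow(bridges))
  mapped_of <- split(seq_len(nrow(aln)), aln$target_id)
  for (bi in seq_len(nrow(bridges))) {
    b <- bridges[bi, ]
    si <- match(b$scaffold, scaffolds$id)
    sq <- scaffolds$sequence[si]
    flank_lo <- max(0, b$gap_start - 2000)
    left_flank <- substr(sq, flank_lo + 1L, b$gap_start)
    right_flank <- substr(sq, b$gap_end + 1L,
                          min(nchar(sq), b$gap_end + 2000))
    rows <- mapped_of[[b$scaffold]] %||% integer(0)
    near <- rows[aln$tend[rows] >= b$gap_start - end_window &
                 aln$tstart[rows] <= b$gap_end + end_window]
    ridx <- unique(aln$read[near])
    mates <- read_table$mate[ridx]
    cand <- unique(c(ridx, mates))
    w <- cg_kmer_walk(left_flank, right_flank, read_table$seq[cand], k,
                      max_gap, max_iterations)
    res[[bi]] <- data.frame(
      scaffold = b$scaffold, gap_index = b$gap_index, status = w$status,
      fill = if (w$status == "filled") w$fill else "",
      fill_len = if (w$status == "filled") nchar(w$fill) else NA_integer_,
      iterations_used = w$iterations_used, stringsAsFactors = FALSE)
  }
  if (!length(res))
    return(data.frame(scaffold = character(0), gap_index = integer(0),
                      status = character(0), fill = character(0),
                      fill_len = integer(0), iterations_used = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, res)
}

#' Apply successful gap fills to scaffolds
#'
#' Replaces the N-run of every gap with status "filled" by its fill
#' sequence (right to left within each scaffold, so gap coordinates stay
#' valid during substitution).
#'
#' @param scaffolds scaffold sequence table.
#' @param bridges bridge table (provides gap coordinates).
#' @param fills fill table from [fill_gaps()].
#' @return the scaffold table with filled sequences.
#' @export
apply_fills <- function(scaffolds, bridges, fills) {
  f <- merge(fills[fills$status == "filled", , drop = FALSE],
             bridges[c("scaffold", "gap_index", "gap_start", "gap_end")],
             by = c("scaffold", "gap_index"))
  f <- f[order(f$scaffold, -f$gap_start), , drop = FALSE]
  for (i in seq_len(nrow(f))) {
    si <- match(f$scaffold[i], scaffolds$id)
    sq <- scaffolds$sequence[si]
    scaffolds$sequence[si] <- paste0(
      substr(sq, 1L, f$gap_start[i]), f$fill[i],
      substr(sq, f$gap_end[i] + 1L, nchar(sq)))
  }
  scaffolds
}

#' Reorder scaffolds using cross-scaffold pairs
#'
#' Pairs whose mates align near the ends of two different scaffolds vote
#' for an adjacency between those scaffold ends. Adjacencies supported by
#' at least `min_links` pairs and mutually best for both ends are joined
#' with an N gap; an end with two or more well-supported candidate partners
#' is a conflict and is left unjoined, as is any adjacency that would close
#' a circular chain.
#'
#' @param scaffolds scaffold sequence table.
#' @param aln alignment table of reads against the scaffolds.
#' @param read_table the read table.
#' @param window distance from a scaffold end within which a mate can
#'   nominate that end (use the largest library insert).
#' @param min_links minimum supporting pairs per join (default 5).
#' @param gap_len N-gap placed between joined scaffolds (default 100).
#' @return list(events = data.frame(type, s1, end1, s2, end2, links),
#'   scaffolds = revised sequence table).
#' @export
reorder_scaffolds <- function(scaffolds, aln, read_table, window = 8000,
                              min_links = 5, gap_len = 100) {
  validate_seq_records(scaffolds)
  slen <- setNames(nchar(scaffolds$sequence), scaffolds$id)
  # one alignment per read
  a <- aln[!duplicated(aln$read), , drop = FALSE]
  by_read <- setNames(seq_len(nrow(a)), a$read)
  p1 <- which(grepl("/1$", read_table$id))
  rows1 <- by_read[as.character(p1)]
  rows2 <- by_read[as.character(read_table$mate[p1])]
  ok <- !is.na(rows1) & !is.na(rows2)
  rows1 <- rows1[ok]; rows2 <- rows2[ok]
  cross <- a$target_id[rows1] != a$target_id[rows2]
  rows1 <- rows1[cross]; rows2 <- rows2[cross]
  end_of <- function(rows) {
    # which end of its scaffold does this mate point past?
    tid <- a$target_id[rows]
    plus <- a$strand[rows] == "+"
    near_r <- slen[tid] - a$tend[rows] < window
    near_l <- a$tstart[rows] < window
    ifelse(plus & near_r, "R", ifelse(!plus & near_l, "L", NA_character_))
  }
  e1 <- end_of(rows1); e2 <- end_of(rows2)
  ok <- !is.na(e1) & !is.na(e2)
  links <- data.frame(s1 = a$target_id[rows1][ok], e1 = e1[ok],
                      s2 = a$target_id[rows2][ok], e2 = e2[ok],
                      stringsAsFactors = FALSE)
  empty_events <- data.frame(type = character(0), s1 = character(0),
                             end1 = character(0), s2 = character(0),
                             end2 = character(0), links = integer(0),
                             stringsAsFactors = FALSE)
  if (!nrow(links))
    return(list(events = empty_events, scaffolds = scaffolds))
  # canonical adjacency key
  k1 <- paste(links$s1, links$e1); k2 <- paste(links$s2, links$e2)
  swap <- k1 > k2
  key <- ifelse(swap, paste(k2, k1, sep = "|"), paste(k1, k2, sep = "|"))
  tab <- table(key)
  cand <- names(tab)[tab >= min_links]
  events <- list()
  adj <- list()
  if (length(cand)) {
    parts <- do.call(rbind, strsplit(cand, "[| ]"))
    cdf <- data.frame(s1 = parts[, 1], e1 = parts[, 2], s2 = parts[, 3],
                      e2 = parts[, 4], links = as.integer(tab[cand]),
                      stringsAsFactors = FALSE)
    endkey <- c(paste(cdf$s1, cdf$e1), paste(cdf$s2, cdf$e2))
    dup_ends <- unique(endkey[duplicated(endkey)])
    conflicted <- paste(cdf$s1, cdf$e1) %in% dup_ends |
                  paste(cdf$s2, cdf$e2) %in% dup_ends
    for (i in which(conflicted))
      events[[length(events) + 1L]] <- data.frame(
        type = "conflict", s1 = cdf$s1[i], end1 = cdf$e1[i], s2 = cdf$s2[i],
        end2 = cdf$e2[i], links = cdf$links[i], stringsAsFactors = FALSE)
    cdf <- cdf[!conflicted, , drop = FALSE]
    # reject adjacencies that would close a cycle (union-find)
    parent <- setNames(scaffolds$id, scaffolds$id)
    find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
    for (i in seq_len(nrow(cdf))) {
      r1 <- find(cdf$s1[i]); r2 <- find(cdf$s2[i])
      if (r1 == r2) {
        events[[length(events) + 1L]] <- data.frame(
          type = "conflict", s1 = cdf$s1[i], end1 = cdf$e1[i],
          s2 = cdf$s2[i], end2 = cdf$e2[i], links = cdf$links[i],
          stringsAsFactors = FALSE)
        next
      }
      parent[[r1]] <- r2
      events[[length(events) + 1L]] <- data.frame(
        type = "join", s1 = cdf$s1[i], end1 = cdf$e1[i], s2 = cdf$s2[i],
        end2 = cdf$e2[i], links = cdf$links[i], stringsAsFactors = FALSE)
      adj[[length(adj) + 1L]] <- cdf[i, ]
    }
  }
  events <- if (length(events)) do.call(rbind, events) else empty_events
  # assemble join chains
  revised <- scaffolds
  if (length(adj)) {
    joins <- do.call(rbind, adj)
    used <- character(0)
    pieces <- list()
    # adjacency lookup per scaffold end
    endmap <- list()
    for (i in seq_len(nrow(joins))) {
      endmap[[paste(joins$s1[i], joins$e1[i])]] <- list(s = joins$s2[i], e = joins$e2[i])
      endmap[[paste(joins$s2[i], joins$e2[i])]] <- list(s = joins$s1[i], e = joins$e1[i])
    }
    involved <- unique(c(joins$s1, joins$s2))
    for (s0 in involved) {
      if (s0 %in% used) next
      # walk to the chain's left terminus
      cur <- s0; came_from <- "L"
      repeat {
        nxt <- endmap[[paste(cur, came_from)]]
        if (is.null(nxt)) break
        cur <- nxt$s
        came_from <- if (nxt$e == "L") "R" else "L"
        if (cur == s0) break  # safety; cycles were rejected
      }
      # walk right collecting oriented pieces
      chain <- list()
      prev_exit <- "R"
      node <- cur
      enter <- if (came_from == "L") "L" else "R"
      orient <- if (enter == "L") "+" else "-"
      repeat {
        chain[[length(chain) + 1L]] <- list(s = node, o = orient)
        used <- c(used, node)
        exit_end <- if (orient == "+") "R" else "L"
        nxt <- endmap[[paste(node, exit_end)]]
        if (is.null(nxt) || nxt$s %in% used) break
        node <- nxt$s
        orient <- if (nxt$e == "L") "+" else "-"
      }
      seqs <- vapply(chain, function(x) {
        sq <- scaffolds$sequence[match(x$s, scaffolds$id)]
        if (x$o == "-") revcomp(sq) else sq
      }, character(1))
      pieces[[length(pieces) + 1L]] <- data.frame(
        id = paste(vapply(chain, `[[`, character(1), "s"), collapse = "+"),
        sequence = paste(seqs, collapse = strrep("N", gap_len)),
        tier = "scaffold", stringsAsFactors = FALSE)
    }
    keep <- revised[!(revised$id %in% used), , drop = FALSE]
    revised <- rbind(keep, do.call(rbind, pieces))
    rownames(revised) <- NULL
  }
  list(events = events, scaffolds = revised)
}

#' Merge an assisted assembly with a de novo assembly
#'
#' A de novo contig is dropped iff at least `min_coverage` of its length is
#' covered by anchor clusters against the assisted assembly at identity
#' `min_identity` or better; otherwise it is appended as an unplaced
#' component. This keeps sequence that exists in the species but could not
#' be aligned to the guiding reference.
#'
#' @param assisted assisted assembly sequence table.
#' @param denovo de novo assembly sequence table.
#' @param min_identity cluster identity threshold (default 0.95).
#' @param min_coverage covered-length fraction above which a de novo contig
#'   is redundant (default 0.5).
#' @param seed_len anchor seed length (default 20).
#' @return list(assembly = merged sequence table, report = data.frame with
#'   contig, length, covered_frac, action, reason).
#' @export
merge_assemblies <- function(assisted, denovo, min_identity = 0.95,
                             min_coverage = 0.5, seed_len = 20) {
  validate_seq_records(assisted)
  validate_seq_records(denovo)
  cl <- anchor_map(denovo, assisted, seed_len = seed_len)
  rows <- vector("list", nrow(denovo))
  add <- logical(nrow(denovo))
  for (i in seq_len(nrow(denovo))) {
    id <- denovo$id[i]
    L <- nchar(denovo$sequence[i])
    cc <- cl[cl$query_id == id & cl$mean_identity >= min_identity, ,
             drop = FALSE]
    cov <- if (nrow(cc))
      sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(cc$qstart + 1L, cc$qend)))) else 0L
    frac <- cov / L
    drop <- frac >= min_coverage
    add[i] <- !drop
    rows[[i]] <- data.frame(
      contig = id, length = L, covered_frac = frac,
      action = if (drop) "dropped" else "added",
      reason = if (drop) sprintf("covered %.1f%% at >= %.0f%% identity",
                                 100 * frac, 100 * min_identity)
               else "insufficient alignment to assisted assembly",
      stringsAsFactors = FALSE)
  }
  assembly <- rbind(assisted, denovo[add, , drop = FALSE])
  rownames(assembly) <- NULL
  list(assembly = assembly, report = do.call(rbind, rows))
}
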