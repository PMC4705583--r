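# Readers and writers for the standard formats the toolkit touches.
# Internal convention everywhere: 0-based half-open coordinates; conversion
# to each format's native convention happens here and nowhere else.

#' Read sequences from FASTA
#'
#' @param path FASTA file.
#' @param tier tier to assign ("contig", "scaffold", "chromosome"), or NULL
#'   to classify by gap content (N-run >= 10 makes a scaffold).
#' @return sequence record table (see [seq_records()]); order preserved,
#'   sequences uppercased.
#' @export
read_fasta <- function(path, tier = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                error = function(e) stop("FASTA parse error in ", path, ": ",
                                         conditionMessage(e), call. = FALSE))
  seqs <- toupper(as.character(x))
  ids <- sub("\\s.*$", "", names(x))
  if (is.null(tier))
    tier <- ifelse(grepl("N{10,}", seqs), "scaffold", "contig")
  seq_records(ids, seqs, tier)
}

#' Write sequences to FASTA
#'
#' @param x sequence record table.
#' @param path output file.
#' @param width line width (default 70).
#' @return path, invisibly.
#' @export
write_fasta <- function(x, path, width = 70) {
  validate_seq_records(x)
  s <- Biostrings::DNAStringSet(x$sequence)
  names(s) <- x$id
  Biostrings::writeXStringSet(s, path, width = width)
  invisible(path)
}

#' Read reads and qualities from FASTQ
#'
#' @param path FASTQ file.
#' @return data.frame with columns id, sequence, quality.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 4 != 0)
    stop("FASTQ parse error in ", path, ": record count not a multiple of 4",
         " (near line ", length(lines), ")")
  i <- seq(1, length(lines), by = 4)
  if (any(substr(lines[i], 1, 1) != "@"))
    stop("FASTQ parse error in ", path, ": header line ",
         i[which(substr(lines[i], 1, 1) != "@")[1]], " does not start with @")
  if (any(substr(lines[i + 2], 1, 1) != "+"))
    stop("FASTQ parse error in ", path, ": separator line ",
         i[which(substr(lines[i + 2], 1, 1) != "+")[1]] + 2,
         " does not start with +")
  seqs <- toupper(lines[i + 1])
  quals <- lines[i + 3]
  bad <- nchar(seqs) != nchar(quals)
  if (any(bad))
    stop("FASTQ parse error in ", path, ": quality length differs from ",
         "sequence length at line ", i[which(bad)[1]] + 3)
  data.frame(id = sub("^@", "", sub("\\s.*$", "", lines[i])),
             sequence = seqs, quality = quals, stringsAsFactors = FALSE)
}

#' Write paired or single reads to FASTQ
#'
#' @param x data.frame with id, sequence and optionally quality (defaults to
#'   a constant high quality).
#' @param path output file.
#' @return path, invisibly.
#' @export
write_fastq <- function(x, path) {
  qual <- x$quality %||% strrep("I", nchar(x$sequence))
  writeLines(paste0("@", x$id, "\n", x$sequence, "\n+\n", qual), path)
  invisible(path)
}

# SAM flag bits
FLAG_PAIRED <- 1L
FLAG_UNMAPPED <- 4L
FLAG_MATE_UNMAPPED <- 8L
FLAG_REVERSE <- 16L
FLAG_MATE_REVERSE <- 32L
FLAG_FIRST <- 64L

#' Read mapped alignments from a SAM file (subset)
#'
#' Parses the plain-text SAM subset the toolkit exchanges: header lines,
#' mapped records, flags, and CIGAR operations M/I/D/S/=/X. Unmapped records
#' are skipped. SAM's 1-based positions are converted to the internal
#' 0-based half-open convention.
#'
#' @param path SAM file.
#' @return data.frame with columns query_id, target_id, qstart, qend
#'   (aligned query window after clipping), tstart, tend, strand, paired,
#'   first_of_pair, mate_reverse, mate_target_id, mate_target_start, flag,
#'   cigar.
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  body <- body[nzchar(body)]
  out <- vector("list", length(body))
  n <- 0L
  for (li in seq_along(body)) {
    f <- strsplit(body[li], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11)
      stop("SAM parse error at record ", li, ": fewer than 11 fields")
    flag <- as.integer(f[2])
    if (bitwAnd(flag, FLAG_UNMAPPED) != 0L) next
    cigar <- f[6]
    ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
    if (cigar == "*" || ops[1] == -1)
      stop("SAM parse error at record ", li, ": missing CIGAR")
    toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
    lens <- as.integer(sub("[MIDNSHP=X]$", "", toks))
    op <- sub("^\\d+", "", toks)
    if (!all(op %in% c("M", "I", "D", "S", "=", "X")))
      stop("SAM parse error at record ", li, ": unsupported CIGAR op ",
           paste(setdiff(op, c("M", "I", "D", "S", "=", "X")), collapse = ""))
    qspan <- sum(lens[op %in% c("M", "I", "S", "=", "X")])
    seq <- f[10]
    if (seq != "*" && nchar(seq) != qspan)
      stop("SAM record ", li, ": CIGAR consumes ", qspan,
           " query bases but sequence has ", nchar(seq))
    tspan <- sum(lens[op %in% c("M", "D", "=", "X")])
    lclip <- if (op[1] == "S") lens[1] else 0L
    rclip <- if (op[length(op)] == "S") lens[length(op)] else 0L
    tstart <- as.integer(f[4]) - 1L
    n <- n + 1L
    out[[n]] <- data.frame(
      query_id = f[1],
      target_id = f[3],
      qstart = lclip,
      qend = qspan - rclip,
      tstart = tstart,
      tend = tstart + tspan,
      strand = if (bitwAnd(flag, FLAG_REVERSE) != 0L) "-" else "+",
      paired = bitwAnd(flag, FLAG_PAIRED) != 0L,
      first_of_pair = bitwAnd(flag, FLAG_FIRST) != 0L,
      mate_reverse = bitwAnd(flag, FLAG_MATE_REVERSE) != 0L,
      mate_target_id = if (f[7] == "=") f[3] else f[7],
      mate_target_start = if (f[8] == "0") NA_integer_ else as.integer(f[8]) - 1L,
      flag = flag,
      cigar = cigar,
      stringsAsFactors = FALSE)
  }
  if (n == 0L)
    return(data.frame(query_id = character(0), target_id = character(0),
                      qstart = integer(0), qend = integer(0),
                      tstart = integer(0), tend = integer(0),
                      strand = character(0), paired = logical(0),
                      first_of_pair = logical(0), mate_reverse = logical(0),
                      mate_target_id = character(0),
                      mate_target_start = integer(0), flag = integer(0),
                      cigar = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out[seq_len(n)])
}

#' Read RepeatMasker .out repeat hits
#'
#' Parses the standard .out layout (two header lines, a blank line, then
#' whitespace-delimited columns). Begin/end coordinates are converted to
#' 0-based half-open; the class/family column is split on "/".
#'
#' @param path RepeatMasker .out file.
#' @return data.frame with columns chrom, start, end, strand, repeat_name,
#'   class, family, superfamily_class (full "class/family" string) and
#'   percent_divergence.
#' @export
read_repeat_out <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  body_idx <- which(!grepl("^\\s*$", lines) &
                    !grepl("^\\s*(SW|score)", lines, ignore.case = TRUE))
  rows <- lapply(body_idx, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 11)
      stop("repeat .out parse error at line ", i, ": fewer than 11 columns")
    b <- suppressWarnings(as.integer(f[6])); e <- suppressWarnings(as.integer(f[7]))
    if (is.na(b) || is.na(e))
      stop("repeat .out parse error at line ", i,
           ": non-numeric coordinate '", f[6], "'/'", f[7], "'")
    pd <- suppressWarnings(as.numeric(f[2]))
    if (is.na(pd))
      stop("repeat .out parse error at line ", i, ": non-numeric % divergence")
    cf <- strsplit(f[11], "/", fixed = TRUE)[[1]]
    data.frame(chrom = f[5], start = b - 1L, end = e,
               strand = if (f[9] %in% c("C", "-")) "-" else "+",
               repeat_name = f[10],
               class = cf[1],
               family = if (length(cf) > 1) cf[2] else f[10],
               superfamily_class = f[11],
               percent_divergence = pd,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(out$end <= out$start))
    stop("repeat .out parse error: end <= begin")
  if (any(out$percent_divergence < 0 | out$percent_divergence > 100))
    stop("repeat .out parse error: % divergence outside [0, 100]")
  out
}

#' Read gene models from GFF3
#'
#' Builds the package's gene-model container from a GFF3 file (types gene,
#' mRNA/transcript, exon, CDS). Coordinates become 0-based half-open.
#'
#' @param path GFF3 file.
#' @return object of class `congener_genes`; see [gene_models()].
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  g <- rtracklayer::import(path, format = "gff3")
  type <- as.character(g$type)
  id <- as.character(g$ID)
  parent <- vapply(g$Parent, function(p) if (length(p)) as.character(p[1]) else NA_character_,
                   character(1))
  is_tx <- type %in% c("mRNA", "transcript")
  tx <- data.frame(
    tx_id = id[is_tx],
    gene_id = ifelse(is.na(parent[is_tx]), id[is_tx], parent[is_tx]),
    chrom = as.character(GenomicRanges::seqnames(g))[is_tx],
    strand = as.character(BiocGenerics::strand(g))[is_tx],
    start = BiocGenerics::start(g)[is_tx] - 1L,
    end = BiocGenerics::end(g)[is_tx],
    stringsAsFactors = FALSE)
  sub_tab <- function(what) {
    k <- type == what
    data.frame(tx_id = parent[k],
               start = BiocGenerics::start(g)[k] - 1L,
               end = BiocGenerics::end(g)[k],
               phase = if (what == "CDS") {
                 ph <- g$phase[k]
                 as.integer(ifelse(is.na(ph), 0L, ph))
               } else 0L,
               stringsAsFactors = FALSE)
  }
  gene_models(tx, sub_tab("exon"), sub_tab("CDS"))
}

#' Construct a gene-model container
#'
#' @param transcripts data.frame: tx_id, gene_id, chrom, strand, start, end
#'   (0-based half-open).
#' @param exons data.frame: tx_id, start, end.
#' @param cds data.frame: tx_id, start, end, phase (phase of first interval).
#' @return classed list `congener_genes` with sorted, validated components.
#'   Transcripts whose total CDS length is not a multiple of 3 are flagged in
#'   `$incomplete`.
#' @export
gene_models <- function(transcripts, exons, cds = NULL) {
  stopifnot(all(c("tx_id", "gene_id", "chrom", "strand", "start", "end") %in%
                names(transcripts)))
  if (is.null(cds))
    cds <- data.frame(tx_id = character(0), start = integer(0),
                      end = integer(0), phase = integer(0))
  exons <- exons[order(exons$tx_id, exons$start), , drop = FALSE]
  cds <- cds[order(cds$tx_id, cds$start), , drop = FALSE]
  # exons sorted and non-overlapping within transcript
  for (t in unique(exons$tx_id)) {
    e <- exons[exons$tx_id == t, ]
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)]))
      stop("overlapping exons in transcript ", t)
    cc <- cds[cds$tx_id == t, ]
    if (nrow(cc)) {
      inside <- vapply(seq_len(nrow(cc)), function(i)
        any(e$start <= cc$start[i] & e$end >= cc$end[i]), logical(1))
      if (!all(inside)) stop("CDS outside exons in transcript ", t)
    }
  }
  cds_len <- tapply(cds$end - cds$start, cds$tx_id, sum)
  incomplete <- names(cds_len)[cds_len %% 3 != 0]
  structure(list(transcripts = transcripts, exons = exons, cds = cds,
                 incomplete = incomplete),
            class = "congener_genes")
}

#' @export
print.congener_genes <- function(x, ...) {
  cat("gene models:", nrow(x$transcripts), "transcripts,",
      nrow(x$exons), "exons,", nrow(x$cds), "CDS intervals\n")
  if (length(x$incomplete))
    cat("  incomplete CDS (length % 3 != 0):",
        length(x$incomplete), "transcripts\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# AGP
# ---------------------------------------------------------------------------

#' Build AGP 2.0 rows describing a gapped scaffold
#'
#' Each scaffold is decomposed into W (contig) and N (gap) components; AGP
#' coordinates are emitted 1-based inclusive.
#'
#' @param x sequence record table of scaffolds.
#' @param min_gap minimum N-run length that counts as a gap (default 10).
#' @return data.frame of AGP 2.0 rows.
#' @export
scaffold_agp <- function(x, min_gap = 10) {
  validate_seq_records(x)
  rows <- list()
  for (i in seq_len(nrow(x))) {
    gaps <- find_gaps(x$sequence[i], min_gap)
    L <- nchar(x$sequence[i])
    parts <- rbind(
      cbind(contig_intervals(L, gaps), type = "W"),
      if (nrow(gaps)) cbind(gaps, type = "N") else NULL)
    parts <- parts[order(parts$start), , drop = FALSE]
    nc <- 0L
    for (j in seq_len(nrow(parts))) {
      w <- parts$type[j] == "W"
      if (w) nc <- nc + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        object = x$id[i],
        object_beg = parts$start[j] + 1L,
        object_end = parts$end[j],
        part_number = j,
        component_type = parts$type[j],
        component_id = if (w) paste0(x$id[i], "_ctg", nc)
                       else as.character(parts$end[j] - parts$start[j]),
        component_beg = if (w) "1" else "scaffold",
        component_end = if (w) as.character(parts$end[j] - parts$start[j])
                        else "yes",
        orientation = if (w) "+" else "paired-ends",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write AGP 2.0
#'
#' @param agp data.frame of AGP rows ([scaffold_agp()] or [place_scaffolds()]).
#' @param path output file.
#' @return path, invisibly.
#' @export
write_agp <- function(agp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.0", con)
  write.table(agp, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read AGP 2.0
#'
#' @param path AGP file.
#' @return data.frame with the same columns [write_agp()] emits.
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  data.frame(object = f[, 1], object_beg = as.integer(f[, 2]),
             object_end = as.integer(f[, 3]), part_number = as.integer(f[, 4]),
             component_type = f[, 5], component_id = f[, 6],
             component_beg = f[, 7], component_end = f[, 8],
             orientation = f[, 9], stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# VCF
# ---------------------------------------------------------------------------

#' Write variants to a minimal VCF 4.2 file
#'
#' Internal 0-based positions are emitted 1-based. Depth, alt depth and the
#' call p-value go into INFO (DP, AD, PV) together with the variant type.
#'
#' @param variants data.frame with chrom, pos (0-based), ref, alt, and
#'   optionally type, depth, alt_depth, p_value.
#' @param path output file.
#' @return path, invisibly.
#' @export
write_vcf <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=congener",
               "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
               "##INFO=<ID=AD,Number=1,Type=Integer,Description=\"Alt depth\">",
               "##INFO=<ID=PV,Number=1,Type=Float,Description=\"Call p-value\">",
               "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"SNC/INS/DEL\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(variants)) {
    info <- paste0(
      "DP=", variants$depth %||% rep(".", nrow(variants)),
      ";AD=", variants$alt_depth %||% rep(".", nrow(variants)),
      ";PV=", signif(variants$p_value %||% rep(NA_real_, nrow(variants)), 6),
      ";TYPE=", variants$type %||% rep("SNC", nrow(variants)))
    writeLines(paste(variants$chrom, variants$pos + 1L, ".", variants$ref,
                     variants$alt, ".", "PASS", info, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a minimal VCF back into a variant table
#'
#' Counterpart of [write_vcf()]; positions return to 0-based.
#'
#' @param path VCF file.
#' @return data.frame with chrom, pos, ref, alt, type, depth, alt_depth,
#'   p_value.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      type = character(0), depth = integer(0),
                      alt_depth = integer(0), p_value = numeric(0),
                      stringsAsFactors = FALSE)
  if (!length(body)) return(empty)
  f <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  get_info <- function(info, key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
    ifelse(lengths(regmatches(info, gregexpr(paste0(key, "="), info))) > 0,
           sub(paste0(".*", key, "="), "", m), NA_character_)
  }
  info <- f[, 8]
  data.frame(chrom = f[, 1], pos = as.integer(f[, 2]) - 1L,
             ref = f[, 4], alt = f[, 5],
             type = get_info(info, "TYPE"),
             depth = suppressWarnings(as.integer(get_info(info, "DP"))),
             alt_depth = suppressWarnings(as.integer(get_info(info, "AD"))),
             p_value = suppressWarnings(as.numeric(get_info(info, "PV"))),
             stringsAsFactors = FALSE)
}

#' Write a table as TSV with a header row
#'
#' @param x data.frame.
#' @param path output file.
#' @return path, invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
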