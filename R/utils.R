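# shared helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement
#'
#' @param x character vector of A/C/G/T/N sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  cg_revcomp(x)
}

# run code under a fixed RNG state without disturbing the caller's stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(as.integer(seed %% .Machine$integer.max), kind = "Mersenne-Twister")
  force(code)
}

#' Construct a sequence record table
#'
#' The package's container for sequence collections: a data.frame with one
#' row per sequence and columns `id`, `sequence` (uppercase A/C/G/T/N) and
#' `tier` (one of contig, scaffold, chromosome).
#'
#' @param id character vector of unique identifiers.
#' @param sequence character vector of sequences (uppercased on input).
#' @param tier sequence tier, recycled: "contig", "scaffold" or "chromosome".
#' @return data.frame with columns id, sequence, tier.
#' @export
seq_records <- function(id, sequence, tier = "scaffold") {
  x <- data.frame(id = as.character(id),
                  sequence = toupper(as.character(sequence)),
                  tier = rep_len(as.character(tier), length(id)),
                  stringsAsFactors = FALSE)
  validate_seq_records(x)
  x
}

#' Validate a sequence record table
#'
#' Checks id uniqueness, non-empty uppercase A/C/G/T/N sequences, and the
#' tier rule that contigs must not contain N-runs of 10 or more (an N-run of
#' that length defines a gap, hence a scaffold).
#'
#' @param x data.frame as returned by [seq_records()].
#' @return x, invisibly; errors on violation.
#' @export
validate_seq_records <- function(x) {
  stopifnot(is.data.frame(x), all(c("id", "sequence", "tier") %in% names(x)))
  if (anyDuplicated(x$id)) stop("sequence ids must be unique")
  if (any(!nzchar(x$sequence))) stop("sequences must be non-empty")
  if (any(grepl("[^ACGTN]", x$sequence)))
    stop("sequences must contain only A/C/G/T/N")
  if (!all(x$tier %in% c("contig", "scaffold", "chromosome")))
    stop("tier must be contig, scaffold or chromosome")
  bad <- x$tier == "contig" & grepl("N{10,}", x$sequence)
  if (any(bad))
    stop("contig records must not contain N-runs of >= 10: ",
         paste(x$id[bad], collapse = ", "))
  invisible(x)
}

#' Locate assembly gaps (N-runs) in a sequence
#'
#' A run of at least `min_run` N characters defines a gap separating two
#' contigs within a scaffold; shorter N-runs are treated as sequence.
#'
#' @param sequence a single sequence string.
#' @param min_run minimum N-run length that counts as a gap (default 10).
#' @return data.frame with 0-based half-open `start`, `end` per gap.
#' @export
find_gaps <- function(sequence, min_run = 10) {
  stopifnot(length(sequence) == 1)
  m <- gregexpr(sprintf("N{%d,}", min_run), sequence)[[1]]
  if (m[1] == -1)
    return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = as.integer(m) - 1L,
             end = as.integer(m) - 1L + attr(m, "match.length"))
}

# contig intervals of a scaffold: complement of its gaps
contig_intervals <- function(seq_len, gaps) {
  if (nrow(gaps) == 0)
    return(data.frame(start = 0L, end = as.integer(seq_len)))
  starts <- c(0L, gaps$end)
  ends <- c(gaps$start, as.integer(seq_len))
  keep <- ends > starts
  data.frame(start = starts[keep], end = ends[keep])
}
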