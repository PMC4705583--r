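# shared fixture builders; everything is generated in code

random_seq <- function(n, seed = 1, gc = 0.5) {
  set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# base-R reverse complement, independent of the package kernel
rc_oracle <- function(s) {
  chartr("ACGTN", "TGCAN",
         vapply(strsplit(s, ""), function(x) paste(rev(x), collapse = ""),
                character(1)))
}

# brute-force N50: smallest member of the minimal set of longest sequences
# reaching half the total
n50_oracle <- function(lens) {
  lens <- sort(lens, decreasing = TRUE)
  half <- sum(lens) / 2
  acc <- 0
  for (l in lens) {
    acc <- acc + l
    if (acc >= half) return(l)
  }
}

# per-position bitmap union of intervals (0-based half-open)
union_oracle <- function(starts, ends, len) {
  hit <- logical(len)
  for (i in seq_along(starts)) hit[(starts[i] + 1):ends[i]] <- TRUE
  sum(hit)
}

# a fake insert model for constructed-pair tests
fake_model <- function(lib = "L", orientation = "FR", range = c(300, 500),
                       center = 400) {
  structure(list(library = lib, histogram = NULL,
                 selected_range = range,
                 expected_orientation = orientation,
                 center = center, n_pairs = 1000L),
            class = "congener_insert_model")
}

# a pair-table row in the pair_alignments() layout
pair_row <- function(lib = "L", target = "s1", ls, le, rs, re,
                     orientation = "FR", exact = 100L) {
  data.frame(pair = NA_integer_, lib = lib, target_id = target,
             left_start = ls, left_end = le, left_strand = "+",
             right_start = rs, right_end = re, right_strand = "-",
             left_max_exact = exact, right_max_exact = exact,
             orientation = orientation, insert = re - ls,
             stringsAsFactors = FALSE)
}
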