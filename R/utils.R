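# Internal helpers shared across modules. All genomic coordinates in this
# package are 0-based half-open (BED convention) unless a function converts
# explicitly to 1-based for Biostrings/IRanges calls.

`%||%` <- function(a, b) if (is.null(a)) b else a

.set_seed <- function(seed) {
  if (!is.null(seed)) {
    set.seed(as.integer(seed), kind = "Mersenne-Twister", sample.kind = "Rejection")
  }
  invisible(NULL)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)

.BASES <- c("A", "C", "G", "T")

# Random DNA as a plain character string.
random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(.BASES, n, replace = TRUE), collapse = "")
}

# Point substitutions at per-site probability `rate`; each hit site is replaced
# by one of the three other bases uniformly (Jukes-Cantor-style, no indels).
mutate_dna <- function(seq, rate) {
  if (rate <= 0 || nchar(seq) == 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(b) sample(setdiff(.BASES, b), 1L), "")
  }
  paste(chars, collapse = "")
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Extract [start, end) (0-based half-open) from a character/XString scaffold.
subseq0 <- function(seq, start, end) {
  substr(as.character(seq), start + 1L, end)
}

.as_character_genome <- function(genome) {
  if (inherits(genome, "sim_genome")) genome <- genome$genome
  if (inherits(genome, "DNAStringSet")) {
    out <- as.character(genome)
    names(out) <- names(genome)
    return(out)
  }
  if (is.character(genome)) {
    if (is.null(names(genome))) .stopf("genome sequences must be named by scaffold")
    return(genome)
  }
  .stopf("unsupported genome representation: %s", class(genome)[1])
}

.check_intervals <- function(df, what = "interval set") {
  need <- c("scaffold", "start", "end")
  if (!all(need %in% names(df))) {
    .stopf("%s must have columns scaffold/start/end", what)
  }
  bad <- which(!(df$start < df$end) | df$start < 0)
  if (length(bad)) {
    .stopf("%s contains malformed intervals (start >= end or negative) at row %d",
           what, bad[1])
  }
  invisible(df)
}

.sort_intervals <- function(df) {
  df[order(df$scaffold, df$start, df$end), , drop = FALSE]
}

# Pairwise alignment wrapper over the compiled Gotoh kernel. Identity is
# matches / alignment columns with internal gaps counted as columns and
# terminal gap columns excluded from the denominator. Spans are 1-based.
align_pair <- function(a, b, type = c("global", "local")) {
  type <- match.arg(type)
  .align_dp(a, b, local = (type == "local"),
            match = .SCORE_MATCH, mismatch = .SCORE_MISMATCH,
            gap_open = .GAP_OPEN, gap_ext = .GAP_EXT)
}

# Percent identity of two sequences under global alignment (pair identity of
# the two LTR copies of a provirus, library clustering identity).
global_identity <- function(a, b) align_pair(a, b, "global")$identity

.empty_hits <- function() {
  data.frame(
    hit_id = character(0), scaffold = character(0), start = integer(0),
    end = integer(0), strand = character(0), library_id = character(0),
    family = character(0), identity = numeric(0), query_coverage = numeric(0),
    score = numeric(0), stringsAsFactors = FALSE)
}

.check_hits <- function(hits) {
  need <- c("scaffold", "start", "end", "strand", "library_id", "family",
            "identity", "query_coverage", "score")
  miss <- setdiff(need, names(hits))
  if (length(miss)) .stopf("hit table is missing columns: %s", paste(miss, collapse = ", "))
  if (is.null(hits$hit_id)) hits$hit_id <- sprintf("hit_%05d", seq_len(nrow(hits)))
  hits
}
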