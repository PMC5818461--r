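# Internal helpers shared across modules: seeded RNG, sequence primitives and
# pairwise-alignment wrappers. All genomic coordinates inside the package are
# 0-based half-open; conversion to 1-based happens only in the file writers.

.datatable.aware <- TRUE

.BASES <- c("A", "C", "G", "T")
.TS  <- c(A = "G", G = "A", C = "T", T = "C")          # transitions
.TV1 <- c(A = "C", G = "C", C = "A", T = "A")          # transversion choice 1
.TV2 <- c(A = "T", G = "T", C = "G", T = "G")          # transversion choice 2
.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Derive a reproducible sub-seed from a master seed and a tag
#'
#' Used so that every stage and every simulated object draws from its own
#' stream: adding a stage or an event never perturbs the randomness of the
#' others. The result is always a valid 32-bit R integer.
#'
#' @param seed master integer seed.
#' @param tag character tag (stage or object name).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483629)
}

# Run code under a temporary RNG seed without clobbering the caller's stream.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# ---- sequence primitives -------------------------------------------------

seq_chars <- function(s) strsplit(toupper(as.character(s)), "", fixed = TRUE)[[1]]

chars_seq <- function(x) paste(x, collapse = "")

seq_len_bp <- function(s) nchar(as.character(s))

#' Reverse complement of a nucleotide string
#' @param s nucleotide string.
#' @return reverse-complemented string.
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(as.character(s))))
}

# Extract [start, end) (0-based half-open) from a character sequence.
subseq0 <- function(s, start, end) {
  substr(as.character(s), start + 1L, end)
}

# Mirror a 0-based half-open interval on a sequence of length n.
mirror_interval <- function(start, end, n) {
  c(n - end, n - start)
}

# ---- pairwise alignment wrappers ----------------------------------------

.nt_submat <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                         baseOnly = FALSE)
    }
    cache
  }
})

.aa_submat <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# Global or local nucleotide alignment; returns aligned strings and, for local
# alignments, the 1-based ranges on pattern and subject.
nt_align <- function(a, b, type = "global", gap_open = 5, gap_ext = 2) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(as.character(a)), Biostrings::DNAString(as.character(b)),
    type = type, substitutionMatrix = .nt_submat(),
    gapOpening = gap_open, gapExtension = gap_ext
  )
  list(
    p = as.character(Biostrings::pattern(aln)),
    s = as.character(Biostrings::subject(aln)),
    p_range = c(IRanges::start(Biostrings::pattern(aln)), IRanges::end(Biostrings::pattern(aln))),
    s_range = c(IRanges::start(Biostrings::subject(aln)), IRanges::end(Biostrings::subject(aln))),
    score = Biostrings::score(aln)
  )
}

aa_align_local <- function(a, b, gap_open = 10, gap_ext = 0.5) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(as.character(a)), Biostrings::AAString(as.character(b)),
    type = "local", substitutionMatrix = .aa_submat(),
    gapOpening = gap_open, gapExtension = gap_ext
  )
  list(
    p = as.character(Biostrings::pattern(aln)),
    s = as.character(Biostrings::subject(aln)),
    p_range = c(IRanges::start(Biostrings::pattern(aln)), IRanges::end(Biostrings::pattern(aln))),
    s_range = c(IRanges::start(Biostrings::subject(aln)), IRanges::end(Biostrings::subject(aln))),
    score = Biostrings::score(aln)
  )
}

# Percent identity of two aligned (gapped) strings of equal length.
#   count_gaps = TRUE : gap columns count as mismatching columns
#   count_gaps = FALSE: gap columns are excluded from the denominator
aligned_identity <- function(pa, sa, count_gaps = TRUE) {
  x <- seq_chars(pa); y <- seq_chars(sa)
  stopifnot(length(x) == length(y))
  gap <- x == "-" | y == "-"
  m <- sum(x == y & !gap)
  denom <- if (count_gaps) length(x) else sum(!gap)
  if (denom == 0) return(NA_real_)
  100 * m / denom
}

# ---- k-mer indexing ------------------------------------------------------

# Positions (1-based) of every ACGT-only k-mer in a sequence, as a data.table
# keyed by k-mer. Shared by the structural detector, the census scanner and
# the tandem-array scanner.
kmer_table <- function(s, k) {
  s <- toupper(as.character(s))
  np <- nchar(s) - k + 1L
  if (np < 1L) {
    return(data.table::data.table(kmer = character(), pos = integer()))
  }
  dt <- data.table::data.table(kmer = substring(s, 1:np, k:(np + k - 1L)),
                               pos = seq_len(np))
  dt <- dt[!grepl("[^ACGT]", dt$kmer)]
  data.table::setkey(dt, "kmer")
  dt
}
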