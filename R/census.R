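# Genome-wide copy census of family representatives, Kimura two-parameter
# insertion dating, repeat density tracks, tandem satellite-array detection
# and region composition reports.

#' Census configuration
#'
#' Thresholds follow the masking-tool conventions of the study design:
#' complete copies require more than 80% of both coverage and identity,
#' fragments more than 10% coverage at more than 80% identity (strict
#' inequalities, as printed). The 20% divergence cap mirrors a
#' `-div 20`-style masking limit and applies to the RT-domain density scan.
#'
#' @param complete_min_coverage,complete_min_identity complete-copy floors.
#' @param fragment_min_coverage fragment coverage floor.
#' @param max_divergence_for_masking divergence cap for density masking.
#' @param merge_gap_bp same-strand alignments separated by at most this many
#'   bp are merged before coverage is computed.
#' @param seed_kmer exact seed size of the census scanner.
#' @return a list of class `census_config`.
#' @export
census_config <- function(complete_min_coverage = 0.80,
                          complete_min_identity = 0.80,
                          fragment_min_coverage = 0.10,
                          max_divergence_for_masking = 0.20,
                          merge_gap_bp = 50L, seed_kmer = 12L) {
  stopifnot(fragment_min_coverage < complete_min_coverage,
            complete_min_coverage > 0, complete_min_coverage <= 1,
            complete_min_identity > 0, complete_min_identity <= 1,
            fragment_min_coverage > 0)
  structure(list(complete_min_coverage = complete_min_coverage,
                 complete_min_identity = complete_min_identity,
                 fragment_min_coverage = fragment_min_coverage,
                 max_divergence_for_masking = max_divergence_for_masking,
                 merge_gap_bp = as.integer(merge_gap_bp),
                 seed_kmer = as.integer(seed_kmer)),
            class = "census_config")
}

# Seed-cluster candidate regions of `rep_seq` occurrences on one strand.
.census_strand <- function(rep_seq, genome, cfg, strand, family, gdt = NULL) {
  k <- cfg$seed_kmer
  probe <- if (strand == "+") rep_seq else revcomp(rep_seq)
  rdt <- kmer_table(probe, k)
  data.table::setnames(rdt, "pos", "qpos")
  if (is.null(gdt)) gdt <- kmer_table(genome, k)
  hits <- gdt[rdt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0) return(NULL)
  hits[, `:=`(diag = pos - qpos)]
  data.table::setorder(hits, diag, pos)
  band <- 60L
  brk <- c(TRUE, diff(hits$diag) > band | diff(hits$pos) > 2000L)
  hits[, `:=`(cl = cumsum(brk))]
  regs <- hits[, list(g1 = min(pos), g2 = max(pos) + k, n_seeds = .N), by = "cl"]
  regs <- regs[regs$n_seeds >= 3]
  if (nrow(regs) == 0) return(NULL)
  # merge candidate regions separated by <= merge_gap_bp on the genome
  data.table::setorder(regs, g1)
  grp <- cumsum(c(TRUE, regs$g1[-1] > cummax(regs$g2[-nrow(regs)]) + cfg$merge_gap_bp))
  regs[, `:=`(mrg = grp)]
  regions <- regs[, list(g1 = min(g1), g2 = max(g2)), by = "mrg"]
  L <- nchar(rep_seq)
  out <- list()
  for (i in seq_len(nrow(regions))) {
    gs <- max(1L, regions$g1[i] - 100L)
    ge <- min(nchar(genome), regions$g2[i] + 100L)
    aln <- nt_align(probe, substr(genome, gs, ge), type = "local")
    idv <- aligned_identity(aln$p, aln$s, count_gaps = TRUE) / 100
    qcov <- (aln$p_range[2] - aln$p_range[1] + 1L) / L
    if (is.na(idv) || qcov <= cfg$fragment_min_coverage) next
    out[[length(out) + 1L]] <- data.frame(
      family = family,
      start = gs + aln$s_range[1] - 2L, end = gs + aln$s_range[2] - 1L,
      strand = strand, identity = idv, coverage = qcov,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Census scan of a family representative against a genome
#'
#' Seeded local alignment of the representative against both genome strands.
#' Same-strand seed clusters separated by at most `merge_gap_bp` are merged
#' before alignment; coverage is the aligned fraction of the representative,
#' identity is matches over aligned columns including gap columns (the
#' masking-tool convention; note this differs from the LTR-pair identity
#' convention). Alignments below the fragment coverage floor are dropped.
#'
#' @param representative representative nucleotide string.
#' @param genome genome nucleotide string.
#' @param cfg a [census_config()].
#' @param family label recorded on each hit.
#' @param genome_index optional prebuilt k-mer index of the genome
#'   ([kmer_table()] at `cfg$seed_kmer`), reused across families.
#' @return data.frame of raw hits: `family`, `start`, `end` (0-based
#'   half-open), `strand`, `identity`, `coverage` (fractions).
#' @export
census_scan <- function(representative, genome, cfg = census_config(),
                        family = "rep", genome_index = NULL) {
  representative <- toupper(as.character(representative))
  genome <- toupper(as.character(genome))
  if (!nzchar(representative) || !nzchar(genome)) stop("empty input sequence")
  res <- rbind(
    .census_strand(representative, genome, cfg, "+", family, genome_index),
    .census_strand(representative, genome, cfg, "-", family, genome_index))
  if (is.null(res)) {
    return(data.frame(family = character(), start = integer(), end = integer(),
                      strand = character(), identity = numeric(),
                      coverage = numeric()))
  }
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Call complete and fragment copies from census hits
#'
#' Strict-threshold decision table: complete iff coverage and identity both
#' exceed the complete floors; fragment iff identity exceeds the identity
#' floor and coverage lies in (fragment floor, complete floor]. Everything
#' else is dropped. The classes are disjoint by construction.
#'
#' @param hits data.frame from [census_scan()].
#' @param cfg a [census_config()].
#' @return the hits that pass, with a `completeness` column
#'   (`"complete"`/`"fragment"`).
#' @export
call_copies <- function(hits, cfg = census_config()) {
  cov <- hits$coverage; idv <- hits$identity
  complete <- cov > cfg$complete_min_coverage & idv > cfg$complete_min_identity
  fragment <- idv > cfg$complete_min_identity &
    cov > cfg$fragment_min_coverage & cov <= cfg$complete_min_coverage
  out <- hits[complete | fragment, , drop = FALSE]
  out$completeness <- ifelse(out$coverage > cfg$complete_min_coverage,
                             "complete", "fragment")
  rownames(out) <- NULL
  out
}

#' Kimura two-parameter distance between two sequences
#'
#' Globally aligns the sequences (unless `already_aligned`), computes the
#' transition fraction P and transversion fraction Q over ungapped columns,
#' and the K2P distance `K = -1/2 ln((1-2P-Q) sqrt(1-2Q))`. Saturation
#' (non-positive log argument) is flagged, not silently clipped.
#'
#' @param ltr_a,ltr_b nucleotide strings (typically the two LTRs of one
#'   element).
#' @param already_aligned set TRUE when the inputs are already gapped
#'   aligned strings of equal length.
#' @return list with `P`, `Q`, `K`, `n_sites` (ungapped columns) and
#'   `saturated`.
#' @export
k2p_distance <- function(ltr_a, ltr_b, already_aligned = FALSE) {
  if (already_aligned) {
    pa <- toupper(ltr_a); sa <- toupper(ltr_b)
  } else {
    aln <- nt_align(ltr_a, ltr_b, type = "global")
    pa <- aln$p; sa <- aln$s
  }
  x <- seq_chars(pa); y <- seq_chars(sa)
  keep <- x %in% .BASES & y %in% .BASES
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n == 0) stop("no ungapped aligned columns")
  diff <- x != y
  ts <- diff & ((x == "A" & y == "G") | (x == "G" & y == "A") |
                  (x == "C" & y == "T") | (x == "T" & y == "C"))
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) {
    return(list(P = P, Q = Q, K = NA_real_, n_sites = n, saturated = TRUE))
  }
  K <- -0.5 * log(arg1 * sqrt(arg2))
  list(P = P, Q = Q, K = K, n_sites = n, saturated = FALSE)
}

#' Insertion time from LTR-pair divergence
#'
#' The two LTRs are identical at insertion; divergence K accumulated between
#' them converts to time as `T = K / (2r)` with `r` the substitution rate
#' per site per year (default 1.3e-8).
#'
#' @param K K2P distance (substitutions/site, >= 0); vectorised.
#' @param r substitution rate per site per year (> 0).
#' @return age in years.
#' @export
insertion_time <- function(K, r = 1.3e-8) {
  if (r <= 0) stop("substitution rate must be positive")
  if (any(K < 0, na.rm = TRUE)) stop("K must be non-negative")
  K / (2 * r)
}

#' Date detected elements from their LTR pairs
#'
#' @param elements list of `ltr_element` objects with both LTRs.
#' @param seq genome nucleotide string.
#' @param r substitution rate per site per year.
#' @return data.frame `id`, `P`, `Q`, `K`, `T_years`, `saturated`.
#' @export
date_elements <- function(elements, seq, r = 1.3e-8) {
  n <- nchar(seq)
  rows <- lapply(elements, function(e) {
    if (is.null(e$ltr5) || is.null(e$ltr3)) return(NULL)
    # re-align the two LTRs locally with a little flanking context: boundary
    # slop from detection would otherwise inflate the divergence estimate
    w5 <- subseq0(seq, max(0L, e$ltr5[1] - 6L), min(n, e$ltr5[2] + 6L))
    w3 <- subseq0(seq, max(0L, e$ltr3[1] - 6L), min(n, e$ltr3[2] + 6L))
    aln <- nt_align(w5, w3, type = "local")
    kd <- k2p_distance(aln$p, aln$s, already_aligned = TRUE)
    data.frame(id = e$id, P = kd$P, Q = kd$Q, K = kd$K,
               T_years = if (kd$saturated) NA_real_ else insertion_time(kd$K, r),
               saturated = kd$saturated, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(id = character(), P = numeric(), Q = numeric(),
                      K = numeric(), T_years = numeric(), saturated = logical())
  }
  out
}

#' Density track of annotations along a genome
#'
#' Coverage mode reports the fraction of each window covered by the
#' (flattened) annotation set; count mode reports the number of annotation
#' midpoints per window. Windows advance by `step_bp`.
#'
#' @param annotations data.frame with `start`, `end` (0-based half-open).
#' @param genome_length sequence length in bp.
#' @param window_bp,step_bp window and step sizes (`window_bp >= step_bp >= 1`).
#' @param mode `"coverage"` or `"count"`.
#' @return data.frame `start`, `end`, `value`, one row per window.
#' @export
density_profile <- function(annotations, genome_length, window_bp = 100000L,
                            step_bp = 20000L, mode = c("coverage", "count")) {
  mode <- match.arg(mode)
  stopifnot(step_bp >= 1, window_bp >= step_bp)
  if (window_bp > genome_length) {
    warning("window larger than genome; using a single whole-genome window")
    window_bp <- genome_length
    step_bp <- genome_length
  }
  n_win <- floor((genome_length - window_bp) / step_bp) + 1
  starts <- (seq_len(n_win) - 1L) * step_bp
  ir <- IRanges::reduce(IRanges::IRanges(start = annotations$start + 1L,
                                         end = annotations$end))
  if (mode == "coverage") {
    cov <- IRanges::coverage(ir, width = genome_length)
    v <- IRanges::Views(cov, start = starts + 1L, width = window_bp)
    vals <- IRanges::viewSums(v) / window_bp
  } else {
    mid <- floor((annotations$start + annotations$end) / 2)
    vals <- vapply(starts, function(s0)
      sum(mid >= s0 & mid < s0 + window_bp), numeric(1))
  }
  data.frame(start = starts, end = starts + window_bp, value = as.numeric(vals))
}

#' Detect tandem satellite arrays by k-mer periodicity
#'
#' Positions whose k-mer recurs at a spacing within `[min_period,
#' max_period]` are clustered; a maximal region is an array when a dominant
#' period explains at least `min_copies` consecutive repeats, the supporting
#' positions are dense, and adjacent monomers align at >= 80% identity.
#'
#' @param seq nucleotide string.
#' @param min_period,max_period monomer length range (`min_period >= 2`).
#' @param min_copies minimal copy number (>= 2).
#' @return data.frame `start`, `end` (0-based half-open), `period`,
#'   `copies`, `monomer_identity`.
#' @export
detect_tandem_arrays <- function(seq, min_period = 50L, max_period = 1000L,
                                 min_copies = 5L) {
  stopifnot(min_period >= 2, min_copies >= 2)
  empty <- data.frame(start = integer(), end = integer(), period = integer(),
                      copies = numeric(), monomer_identity = numeric())
  s <- toupper(as.character(seq))
  k <- 12L
  dt <- kmer_table(s, k)
  data.table::setorder(dt, kmer, pos)
  gaps <- dt[, list(pos = pos[-.N], spacing = diff(pos)), by = "kmer"]
  gaps <- gaps[gaps$spacing >= min_period & gaps$spacing <= max_period]
  if (nrow(gaps) == 0) return(empty)
  data.table::setorder(gaps, pos)
  # cluster supporting positions along the sequence
  brk <- c(TRUE, diff(gaps$pos) > max_period)
  gaps[, `:=`(clust = cumsum(brk))]
  out <- list()
  for (cid in unique(gaps$clust)) {
    gg <- gaps[gaps$clust == cid]
    p <- as.integer(round(stats::median(gg$spacing)))
    gg <- gg[abs(gg$spacing - p) <= max(2L, as.integer(0.1 * p))]
    if (nrow(gg) < 3) next
    a_start <- min(gg$pos) - 1L                  # 0-based
    a_end <- max(gg$pos) + p + k - 1L
    len <- a_end - a_start
    copies <- len / p
    if (copies < min_copies) next
    support <- nrow(gg) / max(1, len - p)
    if (support < 0.25) next
    m1 <- subseq0(s, a_start, a_start + p)
    m2 <- subseq0(s, a_start + p, min(a_start + 2L * p, nchar(s)))
    aln <- nt_align(m1, m2, type = "global")
    idv <- aligned_identity(aln$p, aln$s, count_gaps = TRUE)
    if (is.na(idv) || idv < 80) next
    out[[length(out) + 1L]] <- data.frame(start = a_start, end = min(a_end, nchar(s)),
                                          period = p, copies = copies,
                                          monomer_identity = idv)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}

#' Composition report of an annotated region
#'
#' Percent of the region covered per category, each category flattened
#' (covered bases are not double-counted within a category). Categories may
#' overlap hierarchically (e.g. "TE" > "LTR_RT" > one family), so
#' subcategory rows are bounded by their parents but rows do not sum to 100.
#'
#' @param annotations data.frame with `category`, `start`, `end` (0-based
#'   half-open), all within the region.
#' @param region length-2 numeric, 0-based half-open region interval.
#' @return data.frame `category`, `bp`, `percent`.
#' @export
region_composition <- function(annotations, region) {
  stopifnot(length(region) == 2, region[2] > region[1])
  if (nrow(annotations) &&
      any(annotations$start < region[1] | annotations$end > region[2])) {
    stop("annotations outside the region are rejected")
  }
  reg_len <- region[2] - region[1]
  cats <- unique(annotations$category)
  rows <- lapply(cats, function(cat) {
    a <- annotations[annotations$category == cat, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(start = a$start + 1L, end = a$end))
    bp <- sum(IRanges::width(ir))
    data.frame(category = cat, bp = bp, percent = 100 * bp / reg_len,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(category = character(), bp = integer(),
                                      percent = numeric())
  out[order(-out$percent), , drop = FALSE]
}

#' Histogram of insertion ages with peak detection
#'
#' Bins insertion times and reports local maxima: bins exceeding both
#' neighbours and at least `prominence` times the median bin count (with a
#' floor of 2 counts).
#'
#' @param ages numeric vector of insertion times (years), or the
#'   `T_years` column of [date_elements()] output.
#' @param bin_width_years bin width (> 0).
#' @param prominence peak floor as a multiple of the median non-zero bin.
#' @return list with `breaks`, `counts`, `mids` and `peaks` (bin midpoints).
#' @export
age_histogram <- function(ages, bin_width_years, prominence = 2) {
  stopifnot(bin_width_years > 0)
  ages <- ages[!is.na(ages)]
  if (!length(ages)) {
    return(list(breaks = numeric(), counts = integer(), mids = numeric(),
                peaks = numeric()))
  }
  breaks <- seq(0, max(ages) + bin_width_years, by = bin_width_years)
  h <- hist(ages, breaks = breaks, plot = FALSE)
  cnt <- h$counts
  # prominence is referenced to the median over all bins (at least 2): with
  # tightly clustered ages most non-zero bins *are* peak bins, and a
  # non-zero-bin reference would veto every real peak
  floor_ct <- max(2, prominence * stats::median(cnt))
  padded <- c(-Inf, cnt, -Inf)
  is_peak <- vapply(seq_along(cnt), function(i) {
    padded[i + 1] > padded[i] && padded[i + 1] > padded[i + 2] &&
      padded[i + 1] >= floor_ct
  }, logical(1))
  # flat-topped runs: a strictly-greater neighbour rule misses them; accept
  # the first bin of a maximal flat run exceeding both run-flanks
  run <- rle(cnt)
  pos <- cumsum(c(1, run$lengths))
  for (ri in seq_along(run$values)) {
    i0 <- pos[ri]; i1 <- pos[ri] + run$lengths[ri] - 1L
    left <- if (i0 == 1) -Inf else cnt[i0 - 1]
    right <- if (i1 == length(cnt)) -Inf else cnt[i1 + 1]
    if (run$values[ri] > left && run$values[ri] > right &&
        run$values[ri] >= floor_ct) {
      is_peak[i0] <- TRUE
    }
  }
  list(breaks = h$breaks, counts = cnt, mids = h$mids,
       peaks = h$mids[is_peak])
}
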