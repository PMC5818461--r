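# De novo structural discovery of LTR retrotransposons: exact k-mer seeds
# shared by two loci at an element-compatible spacing are chained on a common
# diagonal, extended into a maximal similar direct repeat by local alignment,
# and refined to TG...CA termini with a flanking target-site duplication.

#' Detection configuration
#'
#' Default ranges bracket the LTR (661-781 bp) and element (5,971-8,088 bp)
#' sizes observed for centromeric retrotransposon families in *Coffea*, with
#' generous headroom. The 80% LTR-pair identity floor is a *detection*
#' threshold; the stricter 99% cutoff used to select elements for careful
#' annotation is applied downstream, not here.
#'
#' @param ltr_len_range LTR length range in bp.
#' @param element_len_range element length range in bp.
#' @param seed_kmer exact seed k-mer size.
#' @param min_ltr_pair_identity minimal LTR-pair percent identity (0-100].
#' @param tsd_len_range target-site duplication length range searched.
#' @param require_tg_ca adjust boundaries (<= 20 bp) to 5'-TG...CA-3' termini.
#' @param max_candidates_per_window cap on occurrences per seed k-mer.
#' @param min_seeds minimal chained seeds per candidate.
#' @param extend_pad bp of context added around the seed chain before the
#'   banded extension alignment.
#' @return a list of class `detection_config`.
#' @export
detection_config <- function(ltr_len_range = c(100, 2500),
                             element_len_range = c(1000, 18000),
                             seed_kmer = 20L,
                             min_ltr_pair_identity = 80,
                             tsd_len_range = c(4, 6),
                             require_tg_ca = TRUE,
                             max_candidates_per_window = 50L,
                             min_seeds = 3L,
                             extend_pad = 200L) {
  stopifnot(ltr_len_range[1] < ltr_len_range[2],
            element_len_range[1] < element_len_range[2],
            tsd_len_range[1] <= tsd_len_range[2],
            min_ltr_pair_identity > 0, min_ltr_pair_identity <= 100)
  structure(list(ltr_len_range = ltr_len_range,
                 element_len_range = element_len_range,
                 seed_kmer = as.integer(seed_kmer),
                 min_ltr_pair_identity = min_ltr_pair_identity,
                 tsd_len_range = as.integer(tsd_len_range),
                 require_tg_ca = isTRUE(require_tg_ca),
                 max_candidates_per_window = as.integer(max_candidates_per_window),
                 min_seeds = as.integer(min_seeds),
                 extend_pad = as.integer(extend_pad)),
            class = "detection_config")
}

#' Find candidate LTR pairs by seed-and-chain direct-repeat search
#'
#' Exact `seed_kmer` matches on the same strand, separated by a distance
#' compatible with the element length range, are chained on a shared diagonal
#' and extended by local alignment into a maximal similar direct repeat.
#'
#' @param seq genome nucleotide string.
#' @param cfg a [detection_config()].
#' @return data.frame of candidate pairs, columns `ltr5_start`, `ltr5_end`,
#'   `ltr3_start`, `ltr3_end` (0-based half-open), `identity` (percent,
#'   gap columns excluded), sorted by start. Empty when the sequence is
#'   shorter than the minimal element length.
#' @export
find_ltr_pairs <- function(seq, cfg = detection_config()) {
  empty <- data.frame(ltr5_start = integer(), ltr5_end = integer(),
                      ltr3_start = integer(), ltr3_end = integer(),
                      identity = numeric())
  s <- toupper(as.character(seq))
  n <- nchar(s)
  if (n < cfg$element_len_range[1]) return(empty)
  k <- cfg$seed_kmer
  dt <- kmer_table(s, k)
  cnt <- dt[, list(N = .N), by = "kmer"]
  cnt <- cnt[cnt$N >= 2 & cnt$N <= cfg$max_candidates_per_window]
  dt <- dt[dt$kmer %in% cnt$kmer]
  if (nrow(dt) == 0) return(empty)
  d_min <- max(cfg$ltr_len_range[1],
               cfg$element_len_range[1] - cfg$ltr_len_range[2])
  d_max <- cfg$element_len_range[2] - cfg$ltr_len_range[1]
  P <- dt[, {
    p <- sort(pos)
    cmb <- utils::combn(p, 2L)
    list(p1 = cmb[1L, ], p2 = cmb[2L, ])
  }, by = "kmer"]
  P[, `:=`(d = p2 - p1)]
  P <- P[P$d >= d_min & P$d <= d_max]
  if (nrow(P) == 0) return(empty)
  # chain seeds sharing a diagonal: within one undisturbed LTR pair the
  # spacing d is constant (no indels between seeds), so a tight band suffices
  band <- 30L
  data.table::setorder(P, d, p1)
  new_cluster <- c(TRUE, diff(P$d) > band | diff(P$p1) > cfg$ltr_len_range[2])
  P[, `:=`(cl = cumsum(new_cluster))]
  chains <- P[, list(n_seeds = .N, s1 = min(p1), e1 = max(p1) + k,
                     d_med = as.integer(stats::median(d))), by = "cl"]
  chains <- chains[chains$n_seeds >= cfg$min_seeds]
  if (nrow(chains) == 0) return(empty)

  cand <- list()
  for (i in seq_len(nrow(chains))) {
    ch <- chains[i]
    pad <- cfg$extend_pad
    w5s <- max(1L, ch$s1 - pad)
    w5e <- min(n, ch$e1 + pad, ch$s1 + cfg$ltr_len_range[2] + pad)
    w3s <- max(1L, ch$s1 + ch$d_med - pad)
    w3e <- min(n, ch$e1 + ch$d_med + pad, w3s + (w5e - w5s) + 2L * pad)
    if (w3s <= w5e) w3s <- w5e + 1L           # never extend across the midline
    if (w3e <= w3s) next
    aln <- nt_align(substr(s, w5s, w5e), substr(s, w3s, w3e), type = "local")
    l5 <- c(w5s + aln$p_range[1] - 2L, w5s + aln$p_range[2] - 1L)  # 0-based
    l3 <- c(w3s + aln$s_range[1] - 2L, w3s + aln$s_range[2] - 1L)
    len5 <- l5[2] - l5[1]; len3 <- l3[2] - l3[1]
    el_len <- l3[2] - l5[1]
    idv <- aligned_identity(aln$p, aln$s, count_gaps = FALSE)
    if (len5 < cfg$ltr_len_range[1] || len5 > cfg$ltr_len_range[2]) next
    if (len3 < cfg$ltr_len_range[1] || len3 > cfg$ltr_len_range[2]) next
    if (el_len < cfg$element_len_range[1] || el_len > cfg$element_len_range[2]) next
    if (is.na(idv) || idv < cfg$min_ltr_pair_identity) next
    cand[[length(cand) + 1L]] <- data.frame(
      ltr5_start = l5[1], ltr5_end = l5[2],
      ltr3_start = l3[1], ltr3_end = l3[2], identity = idv)
  }
  if (!length(cand)) return(empty)
  out <- do.call(rbind, cand)
  # tie-break overlapping candidates: keep highest identity x min LTR length
  score <- out$identity * pmin(out$ltr5_end - out$ltr5_start,
                               out$ltr3_end - out$ltr3_start)
  keep <- rep(TRUE, nrow(out))
  ord <- order(-score)
  for (i in seq_along(ord)) {
    a <- ord[i]
    if (!keep[a]) next
    for (b in ord[-seq_len(i)]) {
      if (!keep[b]) next
      if (out$ltr5_start[b] < out$ltr3_end[a] && out$ltr5_start[a] < out$ltr3_end[b]) {
        keep[b] <- FALSE
      }
    }
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$ltr5_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Search candidate terminus positions: returns 0-based positions within
# +/- win of pos0 where the 2-mer `motif` starts, ordered by |shift|.
.motif_positions <- function(s, pos0, motif, win = 20L) {
  n <- nchar(s)
  shifts <- order(abs(seq(-win, win)))
  res <- integer(0)
  for (sh in seq(-win, win)[shifts]) {
    p <- pos0 + sh
    if (p < 0 || p + 2 > n) next
    if (subseq0(s, p, p + 2L) == motif) res <- c(res, p)
  }
  res
}

#' Refine candidate boundaries to canonical termini and locate the TSD
#'
#' Adjusts element boundaries by up to 20 bp to place 5'-TG ... CA-3' LTR
#' termini when they exist, and reports an exact 4-6 bp target-site
#' duplication when one flanks the refined element. Absence of a TSD is
#' recorded, not fatal.
#'
#' @param seq genome nucleotide string.
#' @param pair one row of [find_ltr_pairs()] output (data.frame or list).
#' @param cfg a [detection_config()].
#' @return list with refined `ltr5`, `ltr3` (0-based half-open integer
#'   vectors), `tsd` (duplicated string or `NA`), and `strand` (provisional,
#'   `"+"`; orientation is resolved by domain annotation).
#' @export
refine_boundaries <- function(seq, pair, cfg = detection_config()) {
  s <- toupper(as.character(seq))
  n <- nchar(s)
  l5 <- c(pair$ltr5_start, pair$ltr5_end)
  l3 <- c(pair$ltr3_start, pair$ltr3_end)
  tsd <- NA_character_
  if (cfg$require_tg_ca) {
    # The two LTRs are copies of one sequence: along the pair diagonal they
    # match at ~(pair identity) inside the element and at ~25% beyond it.
    # Each boundary is therefore localised first as the change point of
    # that match profile (accurate to a couple of bp), and only then are
    # TG / CA termini and an exact flanking TSD scored within +/- 4 bp.
    delta_s <- l3[1] - l5[1]
    delta_e <- l3[2] - l5[2]
    win <- 25L
    match_at <- function(q, delta) {
      # q and partner q + delta, both 0-based single positions
      ok <- q >= 0 & q < n & q + delta >= 0 & q + delta < n
      out <- rep(FALSE, length(q))
      out[ok] <- substring(s, q[ok] + 1L, q[ok] + 1L) ==
        substring(s, q[ok] + delta + 1L, q[ok] + delta + 1L)
      out
    }
    # the pair alignment can carry a small spurious gap, shifting the
    # diagonal by a base or two; recalibrate it on the inside of each
    # boundary before reading the match profile
    best_delta <- function(centre, delta0, side) {
      q_in <- if (side == "start") centre:(centre + win) else (centre - win):centre
      cand <- delta0 + (-6:6)
      cand[which.max(vapply(cand, function(d) sum(match_at(q_in, d)), numeric(1)))]
    }
    change_scores <- function(centre, delta, side) {
      q <- (centre - win):(centre + win)
      M <- match_at(q, delta)
      # side "start": mismatches before the boundary, matches from it on;
      # side "end": matches before the boundary, mismatches from it on
      pre <- c(0, cumsum(M))
      tot <- sum(M)
      k <- seq_along(q)              # boundary placed before q[k]
      sc <- if (side == "start") {
        ((k - 1) - pre[k]) + (tot - pre[k])
      } else {
        pre[k] + ((length(q) - (k - 1)) - (tot - pre[k]))
      }
      list(q = q, rel = sc - max(sc))
    }
    d_s <- best_delta(l5[1], delta_s, "start")
    d_e <- best_delta(l3[2], -delta_e, "end")       # partner is on the 5' LTR
    a_ch <- change_scores(l5[1], d_s, "start")
    b_ch <- change_scores(l3[2], d_e, "end")
    has2 <- function(p, motif) {
      p >= 0 && p + 2L <= n && subseq0(s, p, p + 2L) == motif
    }
    a_score <- vapply(a_ch$q, function(a)
      has2(a, "TG") + has2(a + d_s, "TG"), numeric(1))
    b_score <- vapply(b_ch$q, function(b)
      has2(b - 2L, "CA") + has2(b + d_e - 2L, "CA"), numeric(1))
    t_rng <- rev(seq(cfg$tsd_len_range[1], cfg$tsd_len_range[2]))
    best <- list(a = l5[1], b = l3[2], tsd = NA_character_, score = -Inf)
    # candidates worth considering: near-optimal change points, or motif hits
    a_idx <- which(a_ch$rel >= -12 | a_score > 0)
    b_idx <- which(b_ch$rel >= -12 | b_score > 0)
    for (ai in a_idx) {
      for (bi in b_idx) {
        a <- a_ch$q[ai]; b <- b_ch$q[bi]
        tsd_here <- NA_character_
        for (t in t_rng) {
          if (a - t < 0 || b + t > n) next
          up <- subseq0(s, a - t, a)
          dn <- subseq0(s, b, b + t)
          if (up == dn && !grepl("[^ACGT]", up)) { tsd_here <- up; break }
        }
        # graded TSD evidence: a 4-mer duplication arises by chance far more
        # often than a 6-mer
        tsd_bonus <- if (is.na(tsd_here)) 0 else nchar(tsd_here) - 3L
        sc <- 0.4 * (a_ch$rel[ai] + b_ch$rel[bi]) +
          a_score[ai] + b_score[bi] + tsd_bonus
        if (sc > best$score) best <- list(a = a, b = b, tsd = tsd_here, score = sc)
      }
    }
    # outer termini from the joint search; inner termini follow through the
    # recalibrated alignment diagonals
    l5 <- c(best$a, best$b + d_e)
    l3 <- c(best$a + d_s, best$b)
    tsd <- best$tsd
  } else {
    t_rng <- seq(cfg$tsd_len_range[2], cfg$tsd_len_range[1])
    for (t in t_rng) {
      if (l5[1] - t < 0 || l3[2] + t > nchar(s)) next
      up <- subseq0(s, l5[1] - t, l5[1])
      dn <- subseq0(s, l3[2], l3[2] + t)
      if (up == dn && !grepl("[^ACGT]", up)) { tsd <- up; break }
    }
  }
  list(ltr5 = as.integer(l5), ltr3 = as.integer(l3), tsd = tsd, strand = "+")
}

#' Percent identity of an element's two LTRs
#'
#' Global alignment of the two LTR sequences; identity is matches over
#' aligned columns with gap columns excluded (the convention used for the
#' ">= 99% identity" careful-annotation filter).
#'
#' @param element an `ltr_element` (or list with `ltr5`, `ltr3` intervals).
#' @param seq genome nucleotide string.
#' @return percent identity.
#' @export
ltr_pair_identity <- function(element, seq) {
  if (is.null(element$ltr5) || is.null(element$ltr3) ||
      any(is.na(element$ltr5)) || any(is.na(element$ltr3))) {
    stop("element lacks an LTR pair (non-autonomous or fragment input)")
  }
  a <- subseq0(seq, element$ltr5[1], element$ltr5[2])
  b <- subseq0(seq, element$ltr3[1], element$ltr3[2])
  aln <- nt_align(a, b, type = "global")
  aligned_identity(aln$p, aln$s, count_gaps = FALSE)
}

#' Detect PBS and PPT replication signals
#'
#' The primer binding site is the best match of at least 11 bp (at most one
#' mismatch) against the reverse complement of a bundled tRNA 3'-end set,
#' within 20 bp downstream of the 5' LTR. The polypurine tract is a purine
#' run (>= 10 bp, >= 80% purines) within 30 bp upstream of the 3' LTR.
#' Either signal may be absent. Minus-strand elements are analysed in
#' element orientation and results are mapped back to genome coordinates.
#'
#' @param seq genome nucleotide string.
#' @param element `ltr_element` with both LTR intervals and a `strand`.
#' @param cfg a [detection_config()].
#' @return the element with `pbs` and `ppt` intervals (0-based half-open on
#'   the genome) or `NULL` when absent.
#' @export
detect_pbs_ppt <- function(seq, element, cfg = detection_config()) {
  if (is.null(element$ltr5) || is.null(element$ltr3)) {
    stop("element must have both LTRs")
  }
  s <- toupper(as.character(seq))
  n <- nchar(s)
  minus <- identical(element$strand, "-")
  if (minus) {
    s_or <- revcomp(s)
    l5 <- rev(mirror_interval(element$ltr3[1], element$ltr3[2], n))
    l3 <- rev(mirror_interval(element$ltr5[1], element$ltr5[2], n))
    l5 <- sort(mirror_interval(element$ltr3[1], element$ltr3[2], n))
    l3 <- sort(mirror_interval(element$ltr5[1], element$ltr5[2], n))
  } else {
    s_or <- s
    l5 <- element$ltr5
    l3 <- element$ltr3
  }
  # PBS: scan 20 bp downstream of the 5' LTR
  pbs <- NULL
  win_s <- l5[2]
  win_e <- min(nchar(s_or), l5[2] + 20L + 25L)
  window <- subseq0(s_or, win_s, win_e)
  for (trna in trna_3prime_set()) {
    probe <- revcomp(trna)
    for (len in seq(nchar(probe), 11L)) {
      sub <- substr(probe, 1, len)
      m <- .best_ungapped_match(window, sub, max_mismatch = 1L)
      if (!is.null(m) && m$start0 <= 20L) {
        cand <- c(win_s + m$start0, win_s + m$start0 + len)
        if (is.null(pbs) || len > (pbs[2] - pbs[1])) pbs <- cand
        break
      }
    }
  }
  # PPT: purine run within 30 bp upstream of the 3' LTR
  ppt <- NULL
  win_s <- max(0L, l3[1] - 30L)
  window <- seq_chars(subseq0(s_or, win_s, l3[1]))
  if (length(window) >= 10) {
    pur <- window %in% c("A", "G")
    best_len <- 0L
    for (i in seq_len(length(window) - 9L)) {
      for (j in seq(length(window), i + 9L)) {
        if (mean(pur[i:j]) >= 0.8) {
          if (j - i + 1L > best_len) {
            best_len <- j - i + 1L
            ppt <- c(win_s + i - 1L, win_s + j)
          }
          break
        }
      }
    }
  }
  if (minus) {
    if (!is.null(pbs)) pbs <- sort(mirror_interval(pbs[1], pbs[2], n))
    if (!is.null(ppt)) ppt <- sort(mirror_interval(ppt[1], ppt[2], n))
  }
  element$pbs <- if (is.null(pbs)) NULL else as.integer(pbs)
  element$ppt <- if (is.null(ppt)) NULL else as.integer(ppt)
  element
}

# Best ungapped occurrence of `probe` in `window` with at most max_mismatch
# mismatches; returns 0-based start or NULL.
.best_ungapped_match <- function(window, probe, max_mismatch = 1L) {
  wn <- nchar(window); pn <- nchar(probe)
  if (pn > wn) return(NULL)
  pch <- seq_chars(probe)
  best <- NULL
  for (i in 0:(wn - pn)) {
    mm <- sum(seq_chars(substr(window, i + 1, i + pn)) != pch)
    if (mm <= max_mismatch && (is.null(best) || mm < best$mm)) {
      best <- list(start0 = i, mm = mm)
      if (mm == 0) break
    }
  }
  best
}

# ---- element container ---------------------------------------------------

new_ltr_element <- function(id, genome_id, start, end, ltr5, ltr3, strand = "+",
                            tsd = NA_character_, identity = NA_real_) {
  structure(list(id = id, genome_id = genome_id,
                 start = as.integer(start), end = as.integer(end),
                 ltr5 = if (is.null(ltr5)) NULL else as.integer(ltr5),
                 ltr3 = if (is.null(ltr3)) NULL else as.integer(ltr3),
                 strand = strand, tsd = tsd, pbs = NULL, ppt = NULL,
                 ltr_pair_identity = identity, domains = NULL, labels = list()),
            class = "ltr_element")
}

#' @export
print.ltr_element <- function(x, ...) {
  cat(sprintf("<ltr_element %s> [%d, %d) %s  LTR pair id %.1f%%  tsd=%s\n",
              x$id, x$start, x$end, x$strand,
              x$ltr_pair_identity, ifelse(is.na(x$tsd), "absent", x$tsd)))
  invisible(x)
}

#' Convert a list of elements to a data.frame
#' @param elements list of `ltr_element` objects.
#' @return data.frame, one row per element, 0-based half-open coordinates.
#' @export
elements_table <- function(elements) {
  if (!length(elements)) {
    return(data.frame(id = character(), start = integer(), end = integer(),
                      strand = character(), ltr5_start = integer(),
                      ltr5_end = integer(), ltr3_start = integer(),
                      ltr3_end = integer(), tsd = character(),
                      ltr_pair_identity = numeric(),
                      superfamily = character(), motif = character()))
  }
  do.call(rbind, lapply(elements, function(e) {
    data.frame(id = e$id, start = e$start, end = e$end, strand = e$strand,
               ltr5_start = if (is.null(e$ltr5)) NA_integer_ else e$ltr5[1],
               ltr5_end = if (is.null(e$ltr5)) NA_integer_ else e$ltr5[2],
               ltr3_start = if (is.null(e$ltr3)) NA_integer_ else e$ltr3[1],
               ltr3_end = if (is.null(e$ltr3)) NA_integer_ else e$ltr3[2],
               tsd = e$tsd, ltr_pair_identity = e$ltr_pair_identity,
               superfamily = e$labels$superfamily %||% NA_character_,
               motif = e$labels$motif %||% NA_character_,
               stringsAsFactors = FALSE)
  }))
}

#' Full structural detection on a genome
#'
#' Runs [find_ltr_pairs()] and [refine_boundaries()], then performs a second
#' pass with first-pass elements masked so that elements nested inside other
#' insertions can be recovered.
#'
#' @param seq genome nucleotide string.
#' @param cfg a [detection_config()].
#' @param genome_id label recorded on each element.
#' @param two_pass run the masked second pass (default TRUE).
#' @return list of `ltr_element` objects sorted by start.
#' @export
detect_elements <- function(seq, cfg = detection_config(), genome_id = "genome",
                            two_pass = TRUE) {
  s <- toupper(as.character(seq))
  build <- function(pairs, offset_ids) {
    out <- list()
    for (i in seq_len(nrow(pairs))) {
      ref <- refine_boundaries(s, pairs[i, ], cfg)
      el <- new_ltr_element(sprintf("el%03d", offset_ids + i), genome_id,
                            ref$ltr5[1], ref$ltr3[2], ref$ltr5, ref$ltr3,
                            strand = ref$strand, tsd = ref$tsd)
      el$ltr_pair_identity <- ltr_pair_identity(el, s)
      if (el$ltr_pair_identity < cfg$min_ltr_pair_identity) next
      el <- detect_pbs_ppt(s, el, cfg)
      out[[length(out) + 1L]] <- el
    }
    out
  }
  pairs1 <- find_ltr_pairs(s, cfg)
  els <- build(pairs1, 0L)
  if (two_pass && length(els)) {
    # mask first-pass elements and rescan: a host masked away exposes nothing
    # new, but elements nested inside a host become visible only this way
    ch <- seq_chars(s)
    for (e in els) ch[(e$start + 1L):e$end] <- "N"
    pairs2 <- find_ltr_pairs(chars_seq(ch), cfg)
    els2 <- build(pairs2, length(els))
    els <- c(els, els2)
  }
  els[order(vapply(els, function(e) e$start, integer(1)))]
}
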