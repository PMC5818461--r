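# Translated similarity search of retroelement protein domains on candidate
# elements: all six reading frames are aligned locally against a bundled
# exemplar set (GAG, PR, RT, RH, INT, chromodomain), adjacent-frame hits to
# the same domain are joined by a simple frameshift repair, and the RT domain
# is extracted for phylogeny when long enough.

.POL_DOMAINS <- c("PR", "RT", "RH", "INT")
.CODING_DOMAINS <- c("GAG", "PR", "RT", "RH", "INT")

#' Domain-annotation configuration
#'
#' @param min_rt_aa minimal RT length (residues) for phylogeny (default 150).
#' @param min_aa_identity minimal protein percent identity for a hit.
#' @param min_hit_aa minimal aligned length in residues; below this, chance
#'   local alignments dominate.
#' @param min_score minimal BLOSUM62 local-alignment score; short
#'   moderate-identity chance alignments pass percent-identity floors but
#'   not a score floor.
#' @param cr_motif_window_bp window upstream of the 3' LTR searched for the
#'   CR targeting motif.
#' @param cr_min_identity minimal nucleotide percent identity for a CR hit.
#' @param reference_set path to the reference protein domain FASTA; record
#'   names are `DOMAIN|id`. The bundled set is a synthetic, swappable
#'   fixture with one or two exemplars per domain.
#' @param max_hits_per_ref hits retained per reference per frame (iterative
#'   masking recovers secondary copies, e.g. from nested insertions).
#' @return a list of class `domain_config`.
#' @export
domain_config <- function(min_rt_aa = 150L, min_aa_identity = 40,
                          min_hit_aa = 50L, min_score = 100,
                          cr_motif_window_bp = 1000L,
                          cr_min_identity = 65,
                          reference_set = NULL, max_hits_per_ref = 3L) {
  stopifnot(min_rt_aa >= 1)
  structure(list(min_rt_aa = as.integer(min_rt_aa),
                 min_aa_identity = min_aa_identity,
                 min_hit_aa = as.integer(min_hit_aa),
                 min_score = min_score,
                 cr_motif_window_bp = as.integer(cr_motif_window_bp),
                 cr_min_identity = cr_min_identity,
                 reference_set = reference_set,
                 max_hits_per_ref = as.integer(max_hits_per_ref)),
            class = "domain_config")
}

#' Load the reference protein-domain set
#'
#' @param path FASTA path; defaults to the bundled synthetic exemplar set.
#' @return an `AAStringSet` named `DOMAIN|id`.
#' @export
domain_reference_set <- function(path = NULL) {
  if (is.null(path)) path <- .extdata("domain_refs_synthetic.faa")
  if (!file.exists(path)) stop("reference domain set not readable: ", path)
  refs <- Biostrings::readAAStringSet(path)
  if (!length(refs)) stop("reference domain set is empty: ", path)
  refs
}

# Translate one frame; frame in 1..3 on the given strand's sequence.
.translate_frame <- function(s, frame) {
  n <- nchar(s)
  len <- 3L * ((n - frame + 1L) %/% 3L)
  if (len < 3L) return("")
  sub <- substr(s, frame, frame + len - 1L)
  sub <- chartr("N", "A", sub)  # rare ambiguity: translate through
  as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                     if.fuzzy.codon = "solve"))
}

# Map an aa interval [i, j] (1-based, on the frame translation) to genomic
# 0-based half-open coordinates. strand "+": frame on forward; "-": frame on
# the reverse complement of the full element.
.aa_to_genomic <- function(i, j, frame, strand, n) {
  s0 <- (frame - 1L) + 3L * (i - 1L)
  e0 <- (frame - 1L) + 3L * j
  if (strand == "+") c(s0, e0) else c(n - e0, n - s0)
}

#' Scan an element for protein domains in all six frames
#'
#' Every reading frame is translated and locally aligned (BLOSUM62-scored)
#' against every reference domain. Hits below the identity or length floor
#' are discarded; hits to the same domain separated by at most two codons
#' are merged across frames (frameshift repair). Hits are sorted by genomic
#' position.
#'
#' @param seq element nucleotide string (element orientation or genome
#'   forward strand; both strands are scanned).
#' @param cfg a [domain_config()].
#' @return data.frame of domain hits: `domain`, `start`, `end` (0-based
#'   half-open on `seq`), `frame` (-3..-1, +1..+3), `aa_identity`,
#'   `aa_length`, `reference_id`, `translated_seq`.
#' @export
scan_domains <- function(seq, cfg = domain_config()) {
  s <- toupper(as.character(seq))
  if (!nzchar(s)) stop("empty sequence")
  refs <- domain_reference_set(cfg$reference_set)
  n <- nchar(s)
  frames <- list()
  for (f in 1:3) {
    frames[[paste0("+", f)]] <- .translate_frame(s, f)
    frames[[paste0("-", f)]] <- .translate_frame(revcomp(s), f)
  }
  hits <- list()
  for (ref_nm in names(refs)) {
    domain <- sub("\\|.*$", "", ref_nm)
    ref_aa <- as.character(refs[[ref_nm]])
    for (fr_nm in names(frames)) {
      fr_aa <- frames[[fr_nm]]
      if (nchar(fr_aa) < cfg$min_hit_aa) next
      strand <- substr(fr_nm, 1, 1)
      frame <- as.integer(substr(fr_nm, 2, 2))
      masked <- fr_aa
      for (iter in seq_len(cfg$max_hits_per_ref)) {
        aln <- aa_align_local(ref_aa, masked)
        if (aln$s_range[2] < aln$s_range[1]) break
        idv <- aligned_identity(aln$p, aln$s, count_gaps = FALSE)
        sub_aln <- gsub("-", "", aln$s, fixed = TRUE)
        aa_len <- nchar(sub_aln)
        if (is.na(idv) || aa_len < cfg$min_hit_aa ||
            idv < cfg$min_aa_identity || aln$score < cfg$min_score) break
        gi <- .aa_to_genomic(aln$s_range[1], aln$s_range[2], frame, strand, n)
        hits[[length(hits) + 1L]] <- data.frame(
          domain = domain, start = gi[1], end = gi[2],
          frame = if (strand == "+") frame else -frame,
          aa_identity = idv, aa_length = aa_len,
          reference_id = ref_nm, translated_seq = sub_aln,
          stringsAsFactors = FALSE)
        # mask the found region and retry for a secondary copy
        substr(masked, aln$s_range[1], aln$s_range[2]) <-
          paste(rep("X", aln$s_range[2] - aln$s_range[1] + 1L), collapse = "")
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(domain = character(), start = integer(), end = integer(),
                      frame = integer(), aa_identity = numeric(),
                      aa_length = integer(), reference_id = character(),
                      translated_seq = character()))
  }
  out <- do.call(rbind, hits)
  out <- .merge_frameshift(out, max_gap_nt = 6L)
  # one hit per domain locus: drop hits fully inside a better hit to the
  # same domain (multiple exemplars can report the same region)
  out <- out[order(out$domain, -out$aa_length * out$aa_identity), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    j <- which(keep & seq_len(nrow(out)) > i & out$domain == out$domain[i] &
                 out$start < out$end[i] & out$start[i] < out$end)
    keep[j] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Join hits to the same domain on the same strand separated by <= max_gap_nt
# (simple frameshift/stop repair). Never merges different domains.
.merge_frameshift <- function(h, max_gap_nt = 6L) {
  h <- h[order(h$domain, sign(h$frame), h$start), , drop = FALSE]
  out <- list()
  cur <- NULL
  flush <- function(cur, out) { out[[length(out) + 1L]] <- cur; out }
  for (i in seq_len(nrow(h))) {
    r <- h[i, ]
    gap <- if (is.null(cur)) NA_integer_ else r$start - cur$end
    if (!is.null(cur) && r$domain == cur$domain &&
        sign(r$frame) == sign(cur$frame) &&
        !is.na(gap) && gap <= max_gap_nt && gap >= -9L) {
      w <- c(cur$aa_length, r$aa_length)
      cur$aa_identity <- sum(c(cur$aa_identity, r$aa_identity) * w) / sum(w)
      if (sign(r$frame) > 0) {
        cur$translated_seq <- paste0(cur$translated_seq, r$translated_seq)
      } else {
        cur$translated_seq <- paste0(r$translated_seq, cur$translated_seq)
      }
      cur$aa_length <- cur$aa_length + r$aa_length
      if (r$aa_length > w[1]) cur$frame <- r$frame
      cur$end <- max(cur$end, r$end)
    } else {
      if (!is.null(cur)) out <- flush(cur, out)
      cur <- r
    }
  }
  if (!is.null(cur)) out <- flush(cur, out)
  do.call(rbind, out)
}

#' Extract the reverse-transcriptase domain for phylogeny
#'
#' Returns the RT hit when its aligned length reaches `min_rt_aa` residues;
#' otherwise absent. With several RT hits (e.g. a nested insertion), the
#' longest wins, ties broken by identity then leftmost position.
#'
#' @param seq element nucleotide string (same one given to [scan_domains()]).
#' @param hits data.frame from [scan_domains()].
#' @param cfg a [domain_config()].
#' @return list with `aa` (protein string), `nt` (genomic nucleotide string,
#'   element orientation), `start`, `end`, or `NULL` when no qualifying RT.
#' @export
extract_rt <- function(seq, hits, cfg = domain_config()) {
  rt <- hits[hits$domain == "RT" & hits$aa_length >= cfg$min_rt_aa, , drop = FALSE]
  if (!nrow(rt)) return(NULL)
  rt <- rt[order(-rt$aa_length, -rt$aa_identity, rt$start), , drop = FALSE]
  top <- rt[1, ]
  nt <- subseq0(seq, top$start, top$end)
  if (top$frame < 0) nt <- revcomp(nt)
  list(aa = top$translated_seq, nt = nt, start = top$start, end = top$end)
}

#' Detect the targeting motif of a centromeric element
#'
#' A chromodomain is a CHROMO protein hit downstream of the integrase and
#' upstream of the 3' LTR; the CR motif is a nucleotide-level hit of the
#' bundled CR consensus within `cr_motif_window_bp` upstream of (or extending
#' into) the 3' LTR. When both occur, the chromodomain wins as the more
#' specific protein evidence.
#'
#' @param seq element nucleotide string in element orientation (5' LTR
#'   first).
#' @param hits domain hits from [scan_domains()] on the same sequence.
#' @param cfg a [domain_config()].
#' @param ltr3_start 0-based start of the 3' LTR on `seq`; defaults to the
#'   end of the sequence minus 700 bp when unknown.
#' @return one of `"chromodomain"`, `"CR_motif"`, `"none"`.
#' @export
detect_targeting_motif <- function(seq, hits, cfg = domain_config(),
                                   ltr3_start = NULL) {
  n <- nchar(seq)
  if (is.null(ltr3_start)) ltr3_start <- max(0L, n - 700L)
  int_hit <- hits[hits$domain == "INT", , drop = FALSE]
  chromo <- hits[hits$domain == "CHROMO", , drop = FALSE]
  if (nrow(chromo)) {
    ok <- chromo$end <= n &
      (if (nrow(int_hit)) chromo$start >= min(int_hit$start) else TRUE)
    if (any(ok)) return("chromodomain")
  }
  win_s <- max(0L, ltr3_start - cfg$cr_motif_window_bp)
  win_e <- min(n, ltr3_start + 200L)
  if (win_e - win_s >= 40) {
    window <- subseq0(seq, win_s, win_e)
    aln <- nt_align(cr_motif_consensus(), window, type = "local")
    idv <- aligned_identity(aln$p, aln$s, count_gaps = FALSE)
    alen <- nchar(gsub("-", "", aln$p, fixed = TRUE))
    if (!is.na(idv) && idv >= cfg$cr_min_identity && alen >= 40) {
      return("CR_motif")
    }
  }
  "none"
}

#' Annotate detected elements with domains, orientation and motif
#'
#' Runs [scan_domains()] on each element's genomic sequence, resolves the
#' element strand from the majority frame sign of its coding-domain hits,
#' and records the targeting motif and superfamily labels.
#'
#' @param seq genome nucleotide string.
#' @param elements list of `ltr_element` objects from [detect_elements()].
#' @param cfg a [domain_config()].
#' @return the elements, each with `domains` (hits in element orientation,
#'   coordinates on the element), `strand`, and `labels$motif` /
#'   `labels$superfamily` filled in.
#' @export
annotate_elements <- function(seq, elements, cfg = domain_config()) {
  lapply(elements, function(e) {
    el_seq <- subseq0(seq, e$start, e$end)
    hits <- scan_domains(el_seq, cfg)
    coding <- hits[hits$domain %in% .CODING_DOMAINS, , drop = FALSE]
    if (nrow(coding) && sum(sign(coding$frame)) < 0) {
      e$strand <- "-"
      # re-express everything in element orientation
      el_seq <- revcomp(el_seq)
      hits <- scan_domains(el_seq, cfg)
    }
    e$domains <- hits
    lw5 <- if (is.null(e$ltr5)) 0L else e$ltr5[2] - e$ltr5[1]
    lw3 <- if (is.null(e$ltr3)) 0L else e$ltr3[2] - e$ltr3[1]
    ltr3_start_local <- nchar(el_seq) - (if (e$strand == "+") lw3 else lw5)
    e$labels$motif <- detect_targeting_motif(el_seq, hits, cfg,
                                             ltr3_start = ltr3_start_local)
    e$labels$superfamily <- assign_superfamily(hits)
    e
  })
}
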