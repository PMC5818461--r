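# Synthetic genomes with planted LTR retrotransposons of known family, age,
# completeness and nesting. The generator is the ground-truth source for every
# downstream validation: detection recall, dating recovery, family definition
# and census counts are all measured against what was planted here.

# fraction of the template kept by one-sided truncation events
.TRUNC_KEEP <- 0.6

#' Generate a random genomic background
#'
#' Background sequence is i.i.d. nucleotide sampling at a target GC content.
#' There is deliberately no isochore or repeat structure: the background is
#' the null against which planted elements are detected.
#'
#' @param length_bp background length in bp (> 0).
#' @param gc_fraction target GC content in `[0, 1]`.
#' @param seed integer seed; the same seed reproduces the sequence exactly.
#' @return a nucleotide string of exactly `length_bp` bases over A/C/G/T.
#' @export
make_background <- function(length_bp, gc_fraction = 0.38, seed = 1L) {
  if (!is.numeric(length_bp) || length(length_bp) != 1L || length_bp < 1) {
    stop("length_bp must be a positive integer")
  }
  if (gc_fraction < 0 || gc_fraction > 1) stop("gc_fraction must be in [0, 1]")
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2, (1 - gc_fraction) / 2)
  with_seed(seed, chars_seq(sample(.BASES, as.integer(length_bp), replace = TRUE, prob = p)))
}

# Apply K2P substitution events to a character vector of bases.
# n_events: per-site Poisson event counts; p_ts: per-event transition prob.
.k2p_sub <- function(chars, n_events, p_ts) {
  n_events[!(chars %in% .BASES)] <- 0L
  rem <- n_events
  while (any(rem > 0L)) {
    i <- which(rem > 0L)
    is_ts <- stats::runif(length(i)) < p_ts
    pick1 <- stats::runif(length(i)) < 0.5
    b <- chars[i]
    chars[i] <- ifelse(is_ts, .TS[b], ifelse(pick1, .TV1[b], .TV2[b]))
    rem[i] <- rem[i] - 1L
  }
  chars
}

# Mutate with an expected number of substitution events per site d (may exceed
# the observed substitution fraction once multiple hits occur).
mutate_seq <- function(s, d, kappa = 2, seed = 1L) {
  if (d < 0) stop("expected substitutions per site must be non-negative")
  if (kappa <= 0) stop("kappa must be positive")
  if (d == 0) return(toupper(as.character(s)))
  chars <- seq_chars(s)
  p_ts <- kappa / (kappa + 2)
  with_seed(seed, {
    n_events <- stats::rpois(length(chars), d)
    chars_seq(.k2p_sub(chars, n_events, p_ts))
  })
}

#' Age a sequence under a Kimura two-parameter substitution process
#'
#' Each site receives a Poisson number of substitution events with mean
#' `age_years * rate_per_site_per_year`; each event is a transition with
#' probability `kappa / (kappa + 2)` and otherwise one of the two
#' transversions. Multiple hits per site are modelled, so K2P dating of the
#' output is unbiased. No indels are introduced.
#'
#' @param seq nucleotide string.
#' @param age_years non-negative age in years.
#' @param rate_per_site_per_year substitution rate (default `1.3e-8`).
#' @param kappa transition/transversion rate ratio (> 0, default 2).
#' @param seed integer seed.
#' @return mutated nucleotide string of identical length.
#' @export
mutate_by_age <- function(seq, age_years, rate_per_site_per_year = 1.3e-8,
                          kappa = 2, seed = 1L) {
  if (age_years < 0) stop("age_years must be non-negative")
  if (rate_per_site_per_year < 0) stop("substitution rate must be non-negative")
  mutate_seq(seq, age_years * rate_per_site_per_year, kappa = kappa, seed = seed)
}

# ---- element templates ---------------------------------------------------

#' Construct an element template
#'
#' A template is the age-0 model of one retrotransposon family: a single LTR
#' (used for both ends at insertion), an internal region, the ordered layout
#' of coding domains on the internal region, and the targeting motif carried
#' near the integrase C-terminus / 3' LTR.
#'
#' @param name family label.
#' @param ltr_seq nucleotide string for one LTR (100-2500 bp).
#' @param internal_seq nucleotide string for the internal region.
#' @param domain_layout data.frame with columns `domain`, `start`, `end`
#'   (0-based half-open on `internal_seq`), ordered and non-overlapping.
#' @param targeting_motif one of `"chromodomain"`, `"CR_motif"`, `"none"`.
#' @param tsd_len target-site duplication length (4-6 bp, default 5).
#' @return an object of class `element_template`.
#' @export
element_template <- function(name, ltr_seq, internal_seq, domain_layout,
                             targeting_motif = c("CR_motif", "chromodomain", "none"),
                             tsd_len = 5L) {
  targeting_motif <- match.arg(targeting_motif)
  ltr_seq <- toupper(as.character(ltr_seq))
  internal_seq <- toupper(as.character(internal_seq))
  lw <- nchar(ltr_seq)
  if (lw < 100 || lw > 2500) stop("LTR length must be within [100, 2500] bp")
  if (tsd_len < 4 || tsd_len > 6) stop("tsd_len must be within [4, 6] bp")
  dl <- as.data.frame(domain_layout)
  if (nrow(dl)) {
    stopifnot(all(c("domain", "start", "end") %in% names(dl)))
    dl <- dl[order(dl$start), , drop = FALSE]
    if (any(dl$start < 0 | dl$end > nchar(internal_seq) | dl$start >= dl$end)) {
      stop("domain intervals must lie on the internal sequence")
    }
    if (nrow(dl) > 1 && any(dl$start[-1] < dl$end[-nrow(dl)])) {
      stop("domain intervals must be non-overlapping")
    }
  }
  structure(list(name = name, ltr_seq = ltr_seq, internal_seq = internal_seq,
                 domain_layout = dl, targeting_motif = targeting_motif,
                 tsd_len = as.integer(tsd_len)),
            class = "element_template")
}

#' @export
print.element_template <- function(x, ...) {
  cat(sprintf("<element_template %s>  LTR %d bp, internal %d bp, total %d bp, motif %s\n",
              x$name, nchar(x$ltr_seq), nchar(x$internal_seq),
              2L * nchar(x$ltr_seq) + nchar(x$internal_seq), x$targeting_motif))
  invisible(x)
}

template_length <- function(tmpl) 2L * nchar(tmpl$ltr_seq) + nchar(tmpl$internal_seq)

# Minimal codon table used to reverse-translate reference protein domains
# into template coding regions (one codon per residue; arbitrary but fixed).
.CODON <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT", Q = "CAA",
            E = "GAA", G = "GGT", H = "CAT", I = "ATT", L = "CTT", K = "AAA",
            M = "ATG", F = "TTT", P = "CCT", S = "TCT", T = "ACT", W = "TGG",
            Y = "TAT", V = "GTT", `*` = "TAA", X = "AAC")

reverse_translate <- function(aa) {
  ch <- seq_chars(aa)
  codons <- .CODON[ch]
  codons[is.na(codons)] <- "AAC"
  paste(codons, collapse = "")
}

# Replace in-frame stop codons by TGG over [start, end) of a nucleotide
# string (frame anchored at `start`). Emulates purifying selection keeping
# coding domains open after template divergence.
recode_stops <- function(s, start, end) {
  ch <- seq_chars(s)
  for (i in seq(start, end - 3L, by = 3L)) {
    cod <- paste(ch[(i + 1L):(i + 3L)], collapse = "")
    if (cod %in% c("TAA", "TAG", "TGA")) ch[(i + 1L):(i + 3L)] <- c("T", "G", "G")
  }
  chars_seq(ch)
}

.extdata <- function(file) {
  p <- system.file("extdata", file, package = "crckit")
  if (!nzchar(p)) stop("bundled fixture not found: ", file)
  p
}

# Synthetic CR-motif consensus (nucleotide) and PBS donor (tRNA 3' end).
cr_motif_consensus <- function() {
  x <- Biostrings::readDNAStringSet(.extdata("cr_motif_synthetic.fa"))
  as.character(x[[1]])
}

trna_3prime_set <- function() {
  x <- Biostrings::readDNAStringSet(.extdata("trna_3prime_synthetic.fa"))
  stats::setNames(as.character(x), names(x))
}

#' Default family templates
#'
#' Builds ten centromeric-retrotransposon family templates (A-H, X, Y) from
#' the bundled synthetic domain exemplars. Family A carries a chromodomain
#' downstream of the integrase; all other families carry a CR motif adjacent
#' to the 3' LTR, mirroring the structural dichotomy of chromovirus
#' centromeric lineages. Elements span roughly 6-8 kb with 700-bp LTRs.
#' Founders diverge from a common ancestor so that between-family RT identity
#' falls in the distant (~55-60%) band while the targeting motif, PBS and PPT
#' stay conserved.
#'
#' @param n_families number of families (max 10).
#' @param founder_divergence expected substitutions per site separating each
#'   family founder from the common ancestor (default 0.32).
#' @param kappa transition/transversion ratio used for founder divergence.
#' @param seed fixed fixture seed; the default defines the canonical template
#'   set used throughout the package tests.
#' @return named list of `element_template` objects.
#' @export
crc_templates <- function(n_families = 10, founder_divergence = 0.32,
                          kappa = 2, seed = 1803L) {
  stopifnot(n_families >= 1, n_families <= 10)
  fam_names <- c("A", "B", "C", "D", "E", "F", "G", "H", "X", "Y")[seq_len(n_families)]
  refs <- domain_reference_set()
  pick <- function(domain) {
    nm <- names(refs)[startsWith(names(refs), paste0(domain, "|"))][1]
    as.character(refs[[nm]])
  }
  dom_nt <- lapply(c(GAG = "GAG", PR = "PR", RT = "RT", RH = "RH",
                     INT = "INT", CHROMO = "CHROMO"), function(d) reverse_translate(pick(d)))
  cr_nt <- cr_motif_consensus()
  trna1 <- trna_3prime_set()[[1]]
  # the PBS complements the 3'-terminal bases of the primer tRNA
  pbs_nt <- revcomp(substr(trna1, nchar(trna1) - 13L, nchar(trna1)))
  ppt_nt <- "AGGGAGGGAAAGGGA"

  base_parts <- function(extra_spacer) {
    rnd <- function(n) chars_seq(sample(.BASES, n, replace = TRUE))
    sp <- function(n) rnd(n)
    parts <- list(pbs = pbs_nt, s0 = sp(60), GAG = dom_nt$GAG, s1 = sp(48),
                  PR = dom_nt$PR, s2 = sp(33), RT = dom_nt$RT, s3 = sp(33),
                  RH = dom_nt$RH, s4 = sp(33), INT = dom_nt$INT,
                  s5 = sp(extra_spacer), motif = "", s6 = sp(120), ppt = ppt_nt)
    parts
  }

  with_seed(seed, {
    templates <- list()
    for (i in seq_along(fam_names)) {
      fam <- fam_names[i]
      ltr <- paste0("TG", chars_seq(sample(.BASES, 696, replace = TRUE)), "CA")
      extra <- 650L + 220L * ((i - 1L) %% 10L)
      parts <- base_parts(extra)
      if (fam == "A") parts$motif <- dom_nt$CHROMO else parts$motif <- cr_nt
      internal <- paste(unlist(parts), collapse = "")
      # founder divergence from the common ancestor
      fam_seed <- derive_seed(seed, paste0("founder_", fam))
      ltr_f <- mutate_seq(ltr, founder_divergence, kappa, fam_seed)
      internal_f <- mutate_seq(internal, founder_divergence, kappa, fam_seed + 1L)
      # restore conserved features: LTR termini, PBS, PPT, targeting motif
      substr(ltr_f, 1, 2) <- "TG"
      substr(ltr_f, nchar(ltr_f) - 1, nchar(ltr_f)) <- "CA"
      off <- 0L
      iv <- list()
      for (nm in names(parts)) {
        iv[[nm]] <- c(off, off + nchar(parts[[nm]]))
        off <- off + nchar(parts[[nm]])
      }
      substr(internal_f, iv$pbs[1] + 1, iv$pbs[2]) <- pbs_nt
      substr(internal_f, iv$ppt[1] + 1, iv$ppt[2]) <- ppt_nt
      if (fam != "A") {
        cr_f <- mutate_seq(cr_nt, 0.08, kappa, fam_seed + 2L)
        substr(internal_f, iv$motif[1] + 1, iv$motif[2]) <- cr_f
      }
      # keep coding domains open
      dom_rows <- c("GAG", "PR", "RT", "RH", "INT")
      if (fam == "A") dom_rows <- c(dom_rows, "motif")
      for (nm in dom_rows) internal_f <- recode_stops(internal_f, iv[[nm]][1], iv[[nm]][2])
      layout <- data.frame(
        domain = c("GAG", "PR", "RT", "RH", "INT"),
        start = c(iv$GAG[1], iv$PR[1], iv$RT[1], iv$RH[1], iv$INT[1]),
        end = c(iv$GAG[2], iv$PR[2], iv$RT[2], iv$RH[2], iv$INT[2])
      )
      if (fam == "A") {
        layout <- rbind(layout, data.frame(domain = "CHROMO",
                                           start = iv$motif[1], end = iv$motif[2]))
      }
      tmpl <- element_template(fam, ltr_f, internal_f, layout,
                               targeting_motif = if (fam == "A") "chromodomain" else "CR_motif",
                               tsd_len = 5L)
      attr(tmpl, "pbs") <- iv$pbs
      attr(tmpl, "ppt") <- iv$ppt
      attr(tmpl, "cr") <- if (fam == "A") NULL else iv$motif
      templates[[fam]] <- tmpl
    }
    templates
  })
}

# ---- planting ------------------------------------------------------------

# Build the insert sequence realised by one event (after ageing and decay).
build_insert <- function(tmpl, age_years, decay, fragment_fraction,
                         rate, kappa, seed) {
  lw <- nchar(tmpl$ltr_seq)
  d <- age_years * rate
  ltr5 <- mutate_seq(tmpl$ltr_seq, d, kappa, seed)
  ltr3 <- mutate_seq(tmpl$ltr_seq, d, kappa, seed + 1L)
  internal <- mutate_seq(tmpl$internal_seq, d, kappa, seed + 2L)
  full <- paste0(ltr5, internal, ltr3)
  L <- nchar(full)
  li <- nchar(internal)
  out <- switch(decay,
    complete = list(seq = full, ltr5 = c(0L, lw), ltr3 = c(L - lw, L), tsd = TRUE),
    truncated_5p = {
      keep_from <- L - as.integer(round(.TRUNC_KEEP * L))
      s <- subseq0(full, keep_from, L)
      list(seq = s, ltr5 = NULL, ltr3 = c(nchar(s) - lw, nchar(s)), tsd = FALSE)
    },
    truncated_3p = {
      keep_to <- as.integer(round(.TRUNC_KEEP * L))
      s <- subseq0(full, 0L, keep_to)
      list(seq = s, ltr5 = c(0L, lw), ltr3 = NULL, tsd = FALSE)
    },
    internal_deleted = {
      k <- as.integer(round(0.1 * li))
      s <- paste0(ltr5, subseq0(internal, 0L, k), subseq0(internal, li - k, li), ltr3)
      list(seq = s, ltr5 = c(0L, lw), ltr3 = c(nchar(s) - lw, nchar(s)), tsd = TRUE)
    },
    fragment = {
      fl <- max(1L, as.integer(round(fragment_fraction * L)))
      off <- as.integer(floor((L - fl) / 2))
      list(seq = subseq0(full, off, off + fl), ltr5 = NULL, ltr3 = NULL, tsd = FALSE)
    },
    stop("unknown decay class: ", decay)
  )
  out
}

#' Plant retroelements into a background sequence
#'
#' Each event inserts one (possibly decayed) copy of a template at a 0-based
#' locus on the *original* background. Complete and internal-deleted
#' insertions are flanked by an exact target-site duplication; the two LTRs
#' of one element are aged independently, so their expected divergence is
#' `2 * age * rate`. Nested events are inserted at the midpoint of their
#' host's realised interval.
#'
#' @param background background nucleotide string.
#' @param templates named list of `element_template` objects.
#' @param events data.frame with columns `template`, `locus`, `age_years`,
#'   `decay`, and optionally `nest_into` (id of an earlier event), `id`, and
#'   `fragment_fraction`.
#' @param rate substitution rate per site per year.
#' @param kappa transition/transversion ratio.
#' @param seed integer seed.
#' @return list with `genome` (nucleotide string) and `truth` (data.frame of
#'   realised 0-based half-open intervals, one row per event).
#' @export
plant_elements <- function(background, templates, events, rate = 1.3e-8,
                           kappa = 2, seed = 1L) {
  ev <- as.data.frame(events)
  stopifnot(all(c("template", "locus", "age_years", "decay") %in% names(ev)))
  if (!"nest_into" %in% names(ev)) ev$nest_into <- NA_character_
  if (!"fragment_fraction" %in% names(ev)) ev$fragment_fraction <- 1
  if (!"id" %in% names(ev)) ev$id <- sprintf("ev%03d", seq_len(nrow(ev)))
  ev$fragment_fraction[is.na(ev$fragment_fraction)] <- 1
  if (any(!ev$template %in% names(templates))) {
    stop("unknown template name(s): ",
         paste(setdiff(ev$template, names(templates)), collapse = ", "))
  }
  if (any(ev$age_years < 0)) stop("age_years must be non-negative")
  bad_frac <- ev$decay == "fragment" &
    (ev$fragment_fraction <= 0 | ev$fragment_fraction > 1)
  if (any(bad_frac)) stop("fragment_fraction must be in (0, 1]")
  n_bg <- nchar(background)
  top <- is.na(ev$nest_into)
  loci <- ev$locus[top]
  if (any(loci < 0 | loci > n_bg - 6)) stop("event loci must lie within the background")
  if (length(loci) > 1 && min(diff(sort(loci))) < 8) {
    stop("overlapping non-nested loci rejected: insertion points closer than 8 bp")
  }
  nested_refs <- ev$nest_into[!top]
  if (length(nested_refs)) {
    ord_ok <- match(nested_refs, ev$id) < which(!top)
    if (any(is.na(match(nested_refs, ev$id))) || any(!ord_ok)) {
      stop("nest_into must reference a previously planted event")
    }
  }

  genome <- toupper(as.character(background))
  recs <- list()
  for (r in seq_len(nrow(ev))) {
    e <- ev[r, ]
    tmpl <- templates[[e$template]]
    ins <- build_insert(tmpl, e$age_years, e$decay, e$fragment_fraction,
                        rate, kappa, derive_seed(seed, paste0("event_", e$id)))
    t_len <- if (isTRUE(ins$tsd)) tmpl$tsd_len else 0L
    if (is.na(e$nest_into)) {
      shift <- 0L
      for (rc in recs) if (is.na(rc$parent) && rc$orig_locus < e$locus) shift <- shift + rc$added
      p0 <- as.integer(e$locus) + shift
    } else {
      host <- recs[[e$nest_into]]
      p0 <- as.integer(floor((host$cur_start + host$cur_end) / 2))
    }
    if (p0 + t_len > nchar(genome)) stop("insertion point beyond genome end")
    tsd_seq <- if (t_len > 0) subseq0(genome, p0, p0 + t_len) else NA_character_
    m <- nchar(ins$seq)
    genome <- paste0(substr(genome, 1, p0 + t_len), ins$seq,
                     substr(genome, p0 + 1, nchar(genome)))
    el_start <- p0 + t_len
    el_end <- el_start + m
    added <- m + t_len
    # shift / grow previously realised intervals
    for (id in names(recs)) {
      rc <- recs[[id]]
      if (rc$cur_start >= p0) {
        rc$cur_start <- rc$cur_start + added
        rc$cur_end <- rc$cur_end + added
      } else if (rc$cur_end > p0) {
        rc$cur_end <- rc$cur_end + added
      }
      recs[[id]] <- rc
    }
    if (!is.na(e$nest_into)) {
      anc <- e$nest_into
      while (!is.na(anc)) {
        recs[[anc]]$added <- recs[[anc]]$added + added
        anc <- recs[[anc]]$parent
      }
    }
    recs[[e$id]] <- list(id = e$id, parent = if (is.na(e$nest_into)) NA_character_ else e$nest_into,
                         orig_locus = if (is.na(e$nest_into)) as.integer(e$locus) else NA_integer_,
                         cur_start = el_start, cur_end = el_end, added = added,
                         ltr5 = ins$ltr5, ltr3 = ins$ltr3, tsd = tsd_seq)
  }

  truth <- do.call(rbind, lapply(seq_len(nrow(ev)), function(r) {
    e <- ev[r, ]
    rc <- recs[[e$id]]
    data.frame(id = e$id, template = e$template, decay = e$decay,
               age_years = e$age_years, nest_into = e$nest_into,
               locus = e$locus, start = rc$cur_start, end = rc$cur_end,
               ltr5_start = if (is.null(rc$ltr5)) NA_integer_ else rc$cur_start + rc$ltr5[1],
               ltr5_end = if (is.null(rc$ltr5)) NA_integer_ else rc$cur_start + rc$ltr5[2],
               ltr3_start = if (is.null(rc$ltr3)) NA_integer_ else rc$cur_end - (rc$ltr3[2] - rc$ltr3[1]),
               ltr3_end = if (is.null(rc$ltr3)) NA_integer_ else rc$cur_end,
               tsd = rc$tsd, fragment_fraction = e$fragment_fraction,
               stringsAsFactors = FALSE)
  }))
  # final realised coordinates: ltr intervals recorded relative to element
  # ends, which is exact because nesting inserts strictly inside the host
  attr(truth, "genome_length") <- nchar(genome)
  attr(truth, "seed") <- seed
  list(genome = genome, truth = truth)
}

#' Plant a tandem satellite array
#'
#' Inserts `n_copies` head-to-tail copies of a monomer at a locus, each copy
#' independently mutated at the stated per-site divergence. Used to verify
#' that the satellite-array detector finds arrays when they exist (and stays
#' silent when they do not).
#'
#' @param background background nucleotide string.
#' @param monomer monomer nucleotide string.
#' @param n_copies number of copies (>= 2).
#' @param locus 0-based insertion point.
#' @param monomer_divergence expected substitutions per site per copy.
#' @param seed integer seed.
#' @return list with `genome` and `truth` (`start`, `end`, `period`,
#'   `n_copies`).
#' @export
plant_tandem_array <- function(background, monomer, n_copies, locus,
                               monomer_divergence = 0.02, seed = 1L) {
  if (n_copies < 2) stop("n_copies must be at least 2")
  if (locus < 0 || locus > nchar(background)) stop("locus outside background")
  copies <- vapply(seq_len(n_copies), function(i) {
    mutate_seq(monomer, monomer_divergence, 2, derive_seed(seed, paste0("sat_", i)))
  }, character(1))
  arr <- paste(copies, collapse = "")
  genome <- paste0(substr(background, 1, locus), arr,
                   substr(background, locus + 1, nchar(background)))
  list(genome = genome,
       truth = list(start = locus, end = locus + nchar(arr),
                    period = nchar(monomer), n_copies = n_copies))
}

#' Simulate family-structured reverse-transcriptase sequences
#'
#' Generates RT nucleotide sequences for several genomes sharing the same
#' family structure: family founders diverge from a common ancestral RT, and
#' each genome carries several members per family mutated from the founder.
#' Defaults give within-family identity near 90% and between-family identity
#' near 55-60%, the bands observed for centromeric retrotransposon families.
#'
#' @param n_genomes number of genomes.
#' @param n_families number of families.
#' @param members_per_genome members per family per genome.
#' @param within_each expected substitutions per site from founder to member.
#' @param between_each expected substitutions per site from ancestor to founder.
#' @param kappa transition/transversion ratio.
#' @param seed integer seed.
#' @return list with `rts` (named character vector) and `truth`
#'   (data.frame `id`, `genome`, `family`).
#' @export
simulate_family_rts <- function(n_genomes = 3, n_families = 10,
                                members_per_genome = 3, within_each = 0.053,
                                between_each = 0.32, kappa = 2, seed = 1L) {
  refs <- domain_reference_set()
  rt_ref <- names(refs)[startsWith(names(refs), "RT|")][1]
  base <- reverse_translate(as.character(refs[[rt_ref]]))
  fam_names <- c("A", "B", "C", "D", "E", "F", "G", "H", "X", "Y",
                 paste0("Z", 1:10))[seq_len(n_families)]
  rts <- character(0)
  rows <- list()
  for (f in seq_len(n_families)) {
    founder <- mutate_seq(base, between_each, kappa,
                          derive_seed(seed, paste0("fam_", fam_names[f])))
    for (g in seq_len(n_genomes)) {
      for (m in seq_len(members_per_genome)) {
        id <- sprintf("g%d_%s_m%d", g, fam_names[f], m)
        rts[[id]] <- mutate_seq(founder, within_each, kappa, derive_seed(seed, id))
        rows[[id]] <- data.frame(id = id, genome = paste0("g", g),
                                 family = fam_names[f], stringsAsFactors = FALSE)
      }
    }
  }
  list(rts = rts, truth = do.call(rbind, rows))
}

#' Simulate a genome with planted elements under a scenario
#'
#' Convenience wrapper that lays out non-overlapping loci, draws ages, adds
#' fragments, optional nesting and an optional satellite array, then plants
#' everything. The default scenario emulates a repeat-poor chromosome arm
#' with a census of complete and decayed centromeric retroelements.
#'
#' @param bg_length background length in bp.
#' @param gc_fraction background GC content.
#' @param templates named list of templates (default [crc_templates()]).
#' @param n_complete number of complete insertions.
#' @param ages ages (years) to sample from, or a single max age (uniform).
#' @param n_fragments number of fragment insertions.
#' @param n_nested number of nested complete insertions.
#' @param min_spacing minimal distance between insertion loci.
#' @param satellite optional list(`monomer_len`, `n_copies`, `divergence`).
#' @param rate,kappa substitution process parameters.
#' @param seed integer seed.
#' @return list with `genome`, `truth`, `templates`, and `satellite` truth
#'   (or NULL).
#' @export
simulate_genome <- function(bg_length = 3e5, gc_fraction = 0.38,
                            templates = crc_templates(),
                            n_complete = 10, ages = 2e6, n_fragments = 4,
                            n_nested = 0, min_spacing = 25000,
                            satellite = NULL, rate = 1.3e-8, kappa = 2,
                            seed = 1L) {
  n_events <- n_complete + n_fragments
  with_seed(derive_seed(seed, "scenario"), {
    # jitter is bounded both by the spacing guarantee and by the room left
    # on the background once the event ladder is laid out
    j_fit <- as.integer(floor((bg_length - 20000 - (n_events - 1) * min_spacing) / 2))
    jitter_max <- max(1L, min(as.integer(floor((min_spacing - 8) / 2) - 4), j_fit))
    lo <- 10000 + jitter_max
    hi <- bg_length - 10000 - jitter_max
    if (hi - lo < (n_events - 1) * min_spacing) {
      stop("background too short for the requested number of spaced events")
    }
    base_loci <- seq(lo, hi, length.out = n_events)
    loci <- sort(as.integer(base_loci + sample(-jitter_max:jitter_max, n_events, TRUE)))
    # round-robin family assignment along sorted loci keeps same-family
    # copies farther apart than the maximal element length, so LTRs of
    # different insertions can never chain into one candidate
    fams <- rep(names(templates), length.out = n_events)
    age_pool <- if (length(ages) == 1) stats::runif(n_events, 0, ages) else
      sample(rep(ages, length.out = n_events))
    decay <- sample(c(rep("complete", n_complete), rep("fragment", n_fragments)))
    ev <- data.frame(id = sprintf("ev%03d", seq_len(n_events)),
                     template = fams, locus = loci,
                     age_years = round(age_pool), decay = decay,
                     nest_into = NA_character_,
                     fragment_fraction = ifelse(decay == "fragment",
                                                stats::runif(n_events, 0.15, 0.5), 1),
                     stringsAsFactors = FALSE)
    if (n_nested > 0) {
      hosts <- ev$id[ev$decay == "complete"][seq_len(n_nested)]
      nest <- data.frame(id = sprintf("nest%02d", seq_len(n_nested)),
                         template = rep(names(templates), length.out = n_nested),
                         locus = 0L, age_years = 0,
                         decay = "complete", nest_into = hosts,
                         fragment_fraction = 1, stringsAsFactors = FALSE)
      ev <- rbind(ev, nest)
    }
    bg <- make_background(bg_length, gc_fraction, derive_seed(seed, "background"))
    sat_truth <- NULL
    if (!is.null(satellite)) {
      # plant the array into the background first (at the left margin), so
      # its final coordinates are unaffected by later element insertions
      monomer <- make_background(satellite$monomer_len, 0.45,
                                 derive_seed(seed, "monomer"))
      sat <- plant_tandem_array(bg, monomer, satellite$n_copies, 2000L,
                                monomer_divergence = satellite$divergence %||% 0.02,
                                seed = derive_seed(seed, "satellite"))
      bg <- sat$genome
      sat_truth <- sat$truth
      ev$locus <- ev$locus + (sat$truth$end - sat$truth$start)
    }
    planted <- plant_elements(bg, templates, ev, rate = rate, kappa = kappa,
                              seed = derive_seed(seed, "plant"))
    list(genome = planted$genome, truth = planted$truth,
         templates = templates, satellite = sat_truth)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
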