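# Superfamily assignment from domain order, family definition from the RT
# phylogeny (neighbor joining with bootstrap support), between/within-group
# identity matrices, and non-autonomous element typing (TRIM/LARD/TR-GAG).

#' Assign a superfamily from the coding-domain layout
#'
#' Gypsy elements carry the integrase downstream of RNase H
#' (...RT-RH-INT...), Copia elements carry it upstream of RT
#' (...INT-RT-RH...). Elements with coding hits in an ambiguous order are
#' `unclassified_autonomous`; elements with no POL-region hits are
#' `non_autonomous`.
#'
#' @param hits domain hits data.frame (element orientation).
#' @return one of `"Gypsy"`, `"Copia"`, `"unclassified_autonomous"`,
#'   `"non_autonomous"`.
#' @export
assign_superfamily <- function(hits) {
  pos <- function(d) {
    h <- hits[hits$domain == d, , drop = FALSE]
    if (!nrow(h)) NA_integer_ else min(h$start)
  }
  if (!any(hits$domain %in% .POL_DOMAINS)) return("non_autonomous")
  int_p <- pos("INT"); rh_p <- pos("RH"); rt_p <- pos("RT")
  if (!is.na(int_p) && !is.na(rh_p) && int_p > rh_p) return("Gypsy")
  if (!is.na(int_p) && !is.na(rt_p) && int_p < rt_p) return("Copia")
  "unclassified_autonomous"
}

#' Pairwise RT nucleotide identity
#'
#' Global alignment; identity is matches over aligned columns with gap
#' columns counted in the denominator (the convention that the group
#' identity matrix depends on). Full precision is returned; round for
#' display.
#'
#' @param rt_a,rt_b nucleotide strings.
#' @return percent identity.
#' @export
pairwise_rt_identity <- function(rt_a, rt_b) {
  if (!nzchar(rt_a) || !nzchar(rt_b)) stop("empty RT sequence")
  aln <- nt_align(rt_a, rt_b, type = "global")
  aligned_identity(aln$p, aln$s, count_gaps = TRUE)
}

#' All-vs-all RT identity matrix
#'
#' @param rts named character vector of RT nucleotide sequences.
#' @return symmetric matrix of percent identities (100 on the diagonal).
#' @export
rt_identity_matrix <- function(rts) {
  n <- length(rts)
  m <- matrix(100, n, n, dimnames = list(names(rts), names(rts)))
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      m[i, j] <- m[j, i] <- pairwise_rt_identity(rts[[i]], rts[[j]])
    }
  }
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration on the Q criterion. Negative branch
#' lengths are clamped to zero with the deficit transferred to the sister
#' branch. Q ties are broken by the lexicographically smallest pair of
#' cluster labels, making the topology independent of input taxon order.
#'
#' @param dm symmetric distance matrix with row/column names (>= 3 taxa), or
#'   a `dist` object.
#' @return an unrooted `phylo` tree with branch lengths.
#' @export
neighbor_joining <- function(dm) {
  D <- as.matrix(dm)
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("t", seq_len(nrow(D)))
  if (nrow(D) < 3) stop("neighbor joining requires at least 3 taxa")
  nodes <- rownames(D)
  key <- rownames(D)
  dimnames(D) <- NULL
  while (length(key) > 3) {
    m <- length(key)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-9, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pk <- apply(cand, 1, function(ij) paste(sort(key[ij]), collapse = "\r"))
    pick <- cand[order(pk)[1], ]
    i <- pick[1]; j <- pick[2]
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- max(0, bi + bj); bj <- 0 }
    newnode <- sprintf("(%s:%.10g,%s:%.10g)", nodes[i], bi, nodes[j], bj)
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    dnew <- dnew[-c(i, j)]
    D <- D[-c(i, j), -c(i, j), drop = FALSE]
    D <- rbind(cbind(D, dnew, deparse.level = 0), c(dnew, 0), deparse.level = 0)
    nodes <- c(nodes[-c(i, j)], newnode)
    key <- c(key[-c(i, j)], min(key[c(i, j)]))
  }
  a <- D[1, 2]; b <- D[1, 3]; cc <- D[2, 3]
  bl <- c((a + b - cc) / 2, (a + cc - b) / 2, (b + cc - a) / 2)
  bl <- pmax(bl, 0)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 nodes[1], bl[1], nodes[2], bl[2], nodes[3], bl[3])
  ape::read.tree(text = nwk)
}

# Distance matrix (fraction, gaps-as-mismatch) from an alignment character
# matrix (rows = sequences). Columns where both sequences are gaps are
# excluded from the pair's denominator.
msa_distance <- function(M) {
  n <- nrow(M); m <- ncol(M)
  match_ct <- matrix(0, n, n)
  for (sym in c("A", "C", "G", "T")) {
    X <- (M == sym) * 1
    match_ct <- match_ct + tcrossprod(X)
  }
  G <- (M == "-") * 1
  denom <- m - tcrossprod(G)
  d <- 1 - match_ct / pmax(denom, 1)
  diag(d) <- 0
  dimnames(d) <- list(rownames(M), rownames(M))
  d
}

# Alignment as character matrix from a named character vector of sequences.
.aln_matrix <- function(aln) {
  if (is.matrix(aln)) return(aln)
  w <- nchar(aln)
  stopifnot(length(unique(w)) == 1)
  M <- do.call(rbind, strsplit(toupper(unname(aln)), ""))
  rownames(M) <- names(aln)
  M
}

#' Multiple alignment of RT sequences
#'
#' Aligns a set of nucleotide sequences with MAFFT (on the PATH), returning
#' the alignment as a named character vector of gapped sequences.
#'
#' @param rts named character vector of nucleotide sequences.
#' @return named character vector of aligned sequences (equal widths).
#' @export
align_rt_set <- function(rts) {
  if (!nzchar(Sys.which("mafft"))) stop("mafft not found on PATH")
  fin <- tempfile(fileext = ".fa"); fout <- tempfile(fileext = ".fa")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  x <- Biostrings::DNAStringSet(rts)
  Biostrings::writeXStringSet(x, fin)
  err <- system2("mafft", c("--quiet", "--retree", "2", fin), stdout = fout,
                 stderr = FALSE)
  if (err != 0) stop("mafft failed with status ", err)
  out <- Biostrings::readDNAStringSet(fout)
  stats::setNames(toupper(as.character(out)), names(out))
}

#' Bootstrap support for the RT neighbor-joining tree
#'
#' Alignment columns are resampled with replacement per replicate, distances
#' recomputed (gaps as mismatches), and a tree built per replicate. Support
#' of each internal bipartition of the full-alignment tree is the percent of
#' replicates containing it.
#'
#' @param rt_alignment named character vector of aligned sequences (or a
#'   character matrix).
#' @param n_reps number of replicates (>= 1; the study design used 1,000).
#' @param seed integer seed; same seed gives identical supports.
#' @return list with `tree` (`phylo`, node labels carry support %),
#'   `support` (numeric per internal node) and `n_reps`.
#' @export
bootstrap_groups <- function(rt_alignment, n_reps = 1000L, seed = 1L) {
  M <- .aln_matrix(rt_alignment)
  if (nrow(M) < 4) stop("bootstrap needs at least 4 sequences")
  stopifnot(n_reps >= 1)
  tree <- neighbor_joining(msa_distance(M))
  boots <- with_seed(seed, {
    lapply(seq_len(n_reps), function(i) {
      cols <- sample.int(ncol(M), ncol(M), replace = TRUE)
      neighbor_joining(msa_distance(M[, cols, drop = FALSE]))
    })
  })
  counts <- ape::prop.clades(tree, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- 100 * counts / n_reps
  tree$node.label <- formatC(support, format = "f", digits = 1)
  list(tree = tree, support = support, n_reps = n_reps)
}

# Tip-label sets of both sides of every internal edge of an unrooted phylo,
# with the bootstrap support of that edge.
.bipartitions <- function(tree, support) {
  tips <- tree$tip.label
  n <- length(tips)
  pp <- ape::prop.part(tree)
  sets <- list()
  for (k in seq_along(pp)) {
    node <- n + k
    mem <- tips[pp[[k]]]
    sup <- if (k == 1) 100 else support[k]   # root "clade" = full set
    sets[[length(sets) + 1L]] <- list(members = mem, support = sup)
    if (k > 1) {
      sets[[length(sets) + 1L]] <- list(members = setdiff(tips, mem), support = sup)
    }
  }
  sets
}

#' Define family groups from tree, support and RT identities
#'
#' Groups are maximal supported clades (bootstrap support at or above the
#' threshold) whose members all share pairwise RT identity at or above the
#' within-group floor. Singletons are allowed; every RT belongs to exactly
#' one group. The representative is the member with the highest mean
#' identity to its group.
#'
#' @param tree `phylo` from [bootstrap_groups()].
#' @param support per-internal-node support from [bootstrap_groups()].
#' @param rt_identities all-vs-all percent identity matrix
#'   ([rt_identity_matrix()]).
#' @param support_min minimal bootstrap support (default 70).
#' @param within_min minimal pairwise within-group identity (default 80).
#' @return list of groups, each a list with `name`, `members`,
#'   `representative`, `within_identity`.
#' @export
define_groups <- function(tree, support, rt_identities,
                          support_min = 70, within_min = 80) {
  tips <- tree$tip.label
  cands <- .bipartitions(tree, support)
  cands <- c(cands, lapply(tips, function(t) list(members = t, support = 100)))
  sizes <- vapply(cands, function(x) length(x$members), integer(1))
  ord <- order(-sizes, vapply(cands, function(x) min(x$members), character(1)))
  assigned <- character(0)
  groups <- list()
  for (i in ord) {
    cand <- cands[[i]]
    mem <- cand$members
    if (any(mem %in% assigned)) next
    if (cand$support < support_min) next
    if (length(mem) > 1) {
      sub <- rt_identities[mem, mem, drop = FALSE]
      if (min(sub[upper.tri(sub)]) < within_min) next
    }
    mean_id <- if (length(mem) == 1) 100 else
      vapply(mem, function(t) mean(rt_identities[t, setdiff(mem, t)]), numeric(1))
    rep_id <- mem[order(-mean_id, mem)][1]
    within <- if (length(mem) == 1) 100 else {
      sub <- rt_identities[mem, mem]
      mean(sub[upper.tri(sub)])
    }
    groups[[length(groups) + 1L]] <- list(name = NA_character_, members = mem,
                                          representative = rep_id,
                                          within_identity = within)
    assigned <- c(assigned, mem)
  }
  gs <- vapply(groups, function(g) length(g$members), integer(1))
  ord2 <- order(-gs, vapply(groups, function(g) min(g$members), character(1)))
  groups <- groups[ord2]
  for (i in seq_along(groups)) groups[[i]]$name <- sprintf("F%02d", i)
  groups
}

#' Representative-vs-representative group identity matrix
#'
#' The between/within-group identity table: integer percent RT identity of
#' each group representative against every other. With a `genome_of`
#' labelling, row/column names carry the genome of origin so that
#' genome-pair blocks can be read off directly. All-vs-all mean identities
#' are available as the `"all_vs_all"` attribute.
#'
#' @param groups list from [define_groups()].
#' @param rts named character vector of RT sequences.
#' @param genome_of optional named character vector mapping member id to
#'   genome label.
#' @return integer matrix of percent identities.
#' @export
group_identity_matrix <- function(groups, rts, genome_of = NULL) {
  if (!length(groups)) stop("at least one group required")
  reps <- vapply(groups, function(g) g$representative, character(1))
  labs <- vapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    if (is.null(genome_of)) g$name else
      paste0(g$name, "@", genome_of[[g$representative]])
  }, character(1))
  n <- length(reps)
  full <- matrix(100, n, n, dimnames = list(labs, labs))
  ava <- matrix(100, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      full[i, j] <- full[j, i] <- pairwise_rt_identity(rts[[reps[i]]], rts[[reps[j]]])
      pairs <- expand.grid(a = groups[[i]]$members, b = groups[[j]]$members,
                           stringsAsFactors = FALSE)
      ava[i, j] <- ava[j, i] <- mean(mapply(function(a, b)
        pairwise_rt_identity(rts[[a]], rts[[b]]), pairs$a, pairs$b))
    }
  }
  out <- round(full)
  attr(out, "full_precision") <- full
  attr(out, "all_vs_all") <- round(ava)
  out
}

#' Classify a non-autonomous element
#'
#' Decision table: TR-GAG when a GAG hit is present without any POL domain;
#' TRIM when there are no coding hits, total length is at most
#' `trim_max_len` and each LTR is at most `trim_max_ltr`; LARD when there
#' are no coding hits and total length is at least `lard_min_len`; otherwise
#' unclassified. Autonomous elements are rejected (pipeline wiring guard).
#'
#' @param element list with `length` (bp), `ltr_lengths` (numeric vector,
#'   may be empty) and `domains` (character vector of domain labels), or an
#'   `ltr_element` with `domains` filled in.
#' @param trim_max_len,trim_max_ltr,lard_min_len class bounds in bp.
#' @return list with `label` (one of `TRIM`, `LARD`, `TR_GAG`,
#'   `unclassified`) and `evidence` (the fired rule).
#' @export
classify_nonautonomous <- function(element, trim_max_len = 1500,
                                   trim_max_ltr = 250, lard_min_len = 4000) {
  if (inherits(element, "ltr_element")) {
    doms <- if (is.null(element$domains)) character(0) else element$domains$domain
    lens <- c(if (!is.null(element$ltr5)) element$ltr5[2] - element$ltr5[1],
              if (!is.null(element$ltr3)) element$ltr3[2] - element$ltr3[1])
    element <- list(length = element$end - element$start,
                    ltr_lengths = lens, domains = doms)
  }
  doms <- intersect(unique(element$domains), .CODING_DOMAINS)
  if (any(doms %in% .POL_DOMAINS)) {
    stop("autonomous element (POL domains present) passed to classify_nonautonomous")
  }
  has_gag <- "GAG" %in% doms
  if (has_gag) {
    return(list(label = "TR_GAG",
                evidence = "GAG present, no PR/RT/RH/INT"))
  }
  len <- element$length
  ltrs <- element$ltr_lengths
  if (len <= trim_max_len && (length(ltrs) == 0 || all(ltrs <= trim_max_ltr))) {
    return(list(label = "TRIM",
                evidence = sprintf("no coding, length %d <= %d, LTRs <= %d",
                                   as.integer(len), as.integer(trim_max_len),
                                   as.integer(trim_max_ltr))))
  }
  if (len >= lard_min_len) {
    return(list(label = "LARD",
                evidence = sprintf("no coding, length %d >= %d",
                                   as.integer(len), as.integer(lard_min_len))))
  }
  list(label = "unclassified", evidence = "no rule fired")
}

#' Sliding-window similarity profile of an alignment
#'
#' Mean pairwise column identity (gaps as mismatches) smoothed over a
#' sliding window of alignment columns, step 1. A window equal to the
#' alignment length returns the single overall mean identity.
#'
#' @param group_alignment named character vector of aligned sequences or a
#'   character matrix.
#' @param window_cols window width in columns (>= 1).
#' @return numeric vector of length `n_cols - window_cols + 1` (percent).
#' @export
similarity_profile <- function(group_alignment, window_cols) {
  M <- .aln_matrix(group_alignment)
  n <- nrow(M); m <- ncol(M)
  if (window_cols < 1 || window_cols > m) {
    stop("window must be within [1, alignment length]")
  }
  npairs <- n * (n - 1) / 2
  col_id <- vapply(seq_len(m), function(j) {
    tab <- table(M[, j][M[, j] %in% c("A", "C", "G", "T")])
    sum(tab * (tab - 1) / 2) / npairs * 100
  }, numeric(1))
  if (window_cols == 1) return(col_id)
  cs <- c(0, cumsum(col_id))
  (cs[(window_cols + 1):(m + 1)] - cs[1:(m - window_cols + 1)]) / window_cols
}
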