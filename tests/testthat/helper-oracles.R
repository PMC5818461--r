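# Independent oracles used across the suite. These deliberately avoid the
# code paths they check.

# Random nucleotide string (plain base R, independent of make_background).
rand_nt <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Substitute exactly k positions of a sequence (never back to the same base).
substitute_k <- function(s, k, seed = NULL, transitions_only = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  ch <- strsplit(s, "")[[1]]
  idx <- sample(length(ch), k)
  ts <- c(A = "G", G = "A", C = "T", T = "C")
  for (i in idx) {
    if (transitions_only) {
      ch[i] <- ts[[ch[i]]]
    } else {
      ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    }
  }
  paste(ch, collapse = "")
}

# Closed-form K2P from direct positionwise counting of two equal-length
# ungapped sequences.
k2p_oracle <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  stopifnot(length(x) == length(y))
  n <- length(x)
  diff <- x != y
  ts <- diff & ((x == "A" & y == "G") | (x == "G" & y == "A") |
                  (x == "C" & y == "T") | (x == "T" & y == "C"))
  P <- sum(ts) / n; Q <- sum(diff & !ts) / n
  K <- -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
  list(P = P, Q = Q, K = K)
}

# Exhaustive least-squares topology search over all unrooted topologies for
# 4-6 taxa. Returns the best topology as a phylo. Branch lengths fitted by
# ordinary least squares on the path-edge incidence system.
ls_best_topology <- function(D) {
  labs <- rownames(D)
  n <- length(labs)
  topos <- phangorn::allTrees(n, rooted = FALSE, tip.label = labs)
  pairs <- t(utils::combn(n, 2))
  d_vec <- D[pairs]
  best <- NULL; best_rss <- Inf
  for (ti in seq_along(topos)) {
    tr <- topos[[ti]]              # [[ restores compressed tip labels
    A <- path_edge_incidence(tr, pairs)
    fit <- stats::lm.fit(A, d_vec)
    rss <- sum(fit$residuals^2)
    if (rss < best_rss) { best_rss <- rss; best <- tr; best$edge.length <- fit$coefficients }
  }
  list(tree = best, rss = best_rss)
}

# Incidence of tree edges on tip-pair paths: an edge lies on path(i, j) iff
# deleting it separates i from j. Computed by flood fill from the child side
# of each edge without crossing it.
path_edge_incidence <- function(tr, pairs) {
  n_tip <- length(tr$tip.label)
  n_node <- n_tip + tr$Nnode
  adj <- vector("list", n_node)
  for (e in seq_len(nrow(tr$edge))) {
    u <- tr$edge[e, 1]; v <- tr$edge[e, 2]
    adj[[u]] <- c(adj[[u]], v); adj[[v]] <- c(adj[[v]], u)
  }
  A <- matrix(0, nrow(pairs), nrow(tr$edge))
  for (e in seq_len(nrow(tr$edge))) {
    u <- tr$edge[e, 1]; v <- tr$edge[e, 2]
    seen <- rep(FALSE, n_node); seen[c(u, v)] <- TRUE
    stack <- v; side <- v
    while (length(stack)) {
      x <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (y in adj[[x]]) if (!seen[y]) {
        seen[y] <- TRUE; side <- c(side, y); stack <- c(stack, y)
      }
    }
    tips_v <- side[side <= n_tip]
    in_v <- matrix(pairs %in% tips_v, ncol = 2)
    A[, e] <- as.numeric(xor(in_v[, 1], in_v[, 2]))
  }
  A
}

# Additive distance matrix from a random binary tree with positive branch
# lengths.
random_additive_matrix <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE, br = function(k) stats::runif(k, 0.1, 2))
  tr$tip.label <- sort(tr$tip.label)[order(order(tr$tip.label))]  # keep t1..tn
  D <- ape::cophenetic.phylo(tr)
  D <- D[sort(rownames(D)), sort(colnames(D))]
  list(D = D, tree = tr)
}

# Independent restatement of the non-autonomous decision table.
nonauto_oracle <- function(len, ltr_lens, domains,
                           trim_max_len = 1500, trim_max_ltr = 250,
                           lard_min_len = 4000) {
  coding <- intersect(domains, c("GAG", "PR", "RT", "RH", "INT"))
  if (any(coding %in% c("PR", "RT", "RH", "INT"))) return("ERROR")
  if ("GAG" %in% coding) return("TR_GAG")
  if (len <= trim_max_len &&
      (length(ltr_lens) == 0 || all(ltr_lens <= trim_max_ltr))) return("TRIM")
  if (len >= lard_min_len) return("LARD")
  "unclassified"
}

# Strict census thresholds, restated.
census_oracle <- function(cov, idv) {
  if (cov > 0.80 && idv > 0.80) return("complete")
  if (idv > 0.80 && cov > 0.10 && cov <= 0.80) return("fragment")
  "dropped"
}
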