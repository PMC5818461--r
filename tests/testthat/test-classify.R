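test_that("superfamily follows the coding-domain order", {
  mk <- function(doms, starts) data.frame(domain = doms, start = starts,
                                          end = starts + 300)
  expect_identical(assign_superfamily(
    mk(c("GAG", "PR", "RT", "RH", "INT"), c(0, 400, 800, 1700, 2200))), "Gypsy")
  expect_identical(assign_superfamily(
    mk(c("GAG", "PR", "INT", "RT", "RH"), c(0, 400, 800, 1700, 2200))), "Copia")
  expect_identical(assign_superfamily(mk(character(0), numeric(0))),
                   "non_autonomous")
  expect_identical(assign_superfamily(mk("GAG", 0)), "non_autonomous")
  expect_identical(assign_superfamily(mk(c("GAG", "RT"), c(0, 500))),
                   "unclassified_autonomous")
})

test_that("pairwise RT identity counts gaps as columns", {
  expect_equal(pairwise_rt_identity("ACGTACGTAC", "ACGTACGTAC"), 100)
  expect_equal(pairwise_rt_identity("ACGTACGTAC", "ACGTACGTTC"), 90)
  expect_error(pairwise_rt_identity("", "ACGT"), "empty")
  # within-group mutated pairs sit near 90%
  a <- rand_nt(800, seed = 2)
  b <- substitute_k(a, 80, seed = 3)
  expect_lt(abs(pairwise_rt_identity(a, b) - 90), 1)
})

test_that("neighbor joining resolves the frozen 4-taxon additive example", {
  D <- matrix(c(0, 2, 4, 5,
                2, 0, 4, 5,
                4, 4, 0, 3,
                5, 5, 3, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- neighbor_joining(D)
  # brute-force least-squares over all three unrooted topologies confirms
  # (AB)|(CD) with branch lengths A=1 B=1 C=1 D=2 internal=2
  oracle <- ls_best_topology(D)
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(oracle$tree)), 0,
               ignore_attr = TRUE)
  expect_equal(oracle$rss, 0, tolerance = 1e-20)
  d_fit <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
  expect_equal(d_fit, D, tolerance = 1e-9)
})

test_that("three taxa resolve by the closed three-point formulas", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["a"]], (3 + 4 - 5) / 2)
  expect_equal(bl[["b"]], (3 + 5 - 4) / 2)
  expect_equal(bl[["c"]], (4 + 5 - 3) / 2)
  expect_error(neighbor_joining(D[1:2, 1:2]), "at least 3")
})

test_that("NJ topology and lengths are invariant to taxon order", {
  res <- random_additive_matrix(6, seed = 10)
  tr1 <- neighbor_joining(res$D)
  perm <- c(4, 1, 6, 2, 5, 3)
  tr2 <- neighbor_joining(res$D[perm, perm])
  expect_equal(ape::dist.topo(tr1, tr2), 0, ignore_attr = TRUE)
  d1 <- ape::cophenetic.phylo(tr1); d2 <- ape::cophenetic.phylo(tr2)
  expect_equal(d1[rownames(res$D), rownames(res$D)],
               d2[rownames(res$D), rownames(res$D)], tolerance = 1e-9)
})

test_that("NJ recovers the least-squares topology on additive matrices", {
  for (seed in 1:12) {
    n <- 4 + seed %% 3
    res <- random_additive_matrix(n, seed = 100 + seed)
    tr <- neighbor_joining(res$D)
    oracle <- ls_best_topology(res$D)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(oracle$tree)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("clearly separated clades reach full bootstrap support", {
  set.seed(5)
  anc1 <- rand_nt(600); anc2 <- substitute_k(anc1, 300)
  seqs <- c(
    setNames(lapply(1:3, function(i) substitute_k(anc1, 30)), paste0("p", 1:3)),
    setNames(lapply(1:3, function(i) substitute_k(anc2, 30)), paste0("q", 1:3)))
  aln <- align_rt_set(unlist(seqs))
  bt <- bootstrap_groups(aln, n_reps = 100, seed = 9)
  # the p-vs-q bipartition must appear in every replicate
  expect_true(any(bt$support == 100))
  bt1 <- bootstrap_groups(aln, n_reps = 1, seed = 2)
  expect_true(all(bt1$support %in% c(0, 100)))
  bt2 <- bootstrap_groups(aln, n_reps = 20, seed = 9)
  bt3 <- bootstrap_groups(aln, n_reps = 20, seed = 9)
  expect_identical(bt2$support, bt3$support)
})

test_that("group definition recovers planted families and partitions the set", {
  fr <- simulate_family_rts(n_genomes = 2, n_families = 3,
                            members_per_genome = 3, seed = 6)
  idm <- rt_identity_matrix(fr$rts)
  aln <- align_rt_set(fr$rts)
  bt <- bootstrap_groups(aln, n_reps = 100, seed = 3)
  groups <- define_groups(bt$tree, bt$support, idm)
  expect_length(groups, 3)
  all_members <- unlist(lapply(groups, `[[`, "members"))
  expect_setequal(all_members, names(fr$rts))
  expect_equal(anyDuplicated(all_members), 0)
  for (g in groups) {
    fams <- unique(fr$truth$family[match(g$members, fr$truth$id)])
    expect_length(fams, 1)
    expect_true(g$representative %in% g$members)
  }
})

test_that("identical sequences collapse into a single group", {
  rts <- setNames(rep(rand_nt(400, seed = 2), 4), paste0("s", 1:4))
  idm <- rt_identity_matrix(rts)
  aln <- setNames(rep(rts[[1]], 4), names(rts))  # already 'aligned'
  bt <- bootstrap_groups(aln, n_reps = 10, seed = 1)
  groups <- define_groups(bt$tree, bt$support, idm)
  expect_length(groups, 1)
  expect_length(groups[[1]]$members, 4)
})

test_that("group identity matrix separates within from between bands", {
  fr <- simulate_family_rts(n_genomes = 2, n_families = 3,
                            members_per_genome = 2, seed = 8)
  idm <- rt_identity_matrix(fr$rts)
  aln <- align_rt_set(fr$rts)
  bt <- bootstrap_groups(aln, n_reps = 50, seed = 3)
  groups <- define_groups(bt$tree, bt$support, idm)
  genome_of <- setNames(fr$truth$genome, fr$truth$id)
  gim <- group_identity_matrix(groups, fr$rts, genome_of = genome_of)
  expect_true(all(diag(gim) == 100))
  expect_identical(gim, t(gim))
  off <- gim[upper.tri(gim)]
  expect_true(all(off >= 45 & off <= 70))
  expect_true(all(grepl("@g", rownames(gim))))
  expect_true(is.matrix(attr(gim, "all_vs_all")))
})

test_that("non-autonomous typing follows the decision table", {
  cls <- function(len, ltrs, doms)
    classify_nonautonomous(list(length = len, ltr_lengths = ltrs,
                                domains = doms))$label
  expect_identical(cls(900, c(150, 150), character(0)), "TRIM")
  expect_identical(cls(6500, c(700, 700), character(0)), "LARD")
  expect_identical(cls(3000, c(700, 700), "GAG"), "TR_GAG")
  expect_identical(cls(2500, c(300, 300), character(0)), "unclassified")
  expect_error(cls(5000, c(700, 700), c("GAG", "RT")), "autonomous")
})

test_that("non-autonomous typing matches the oracle on random cases", {
  set.seed(77)
  doms_pool <- c("GAG", "PR", "RT", "RH", "INT", "CHROMO")
  for (i in 1:500) {
    len <- sample(200:9000, 1)
    ltrs <- if (runif(1) < 0.2) numeric(0) else sample(80:900, 2, replace = TRUE)
    doms <- doms_pool[runif(6) < 0.25]
    want <- nonauto_oracle(len, ltrs, doms)
    if (want == "ERROR") {
      expect_error(classify_nonautonomous(list(length = len, ltr_lengths = ltrs,
                                               domains = doms)))
    } else {
      got <- classify_nonautonomous(list(length = len, ltr_lengths = ltrs,
                                         domains = doms))$label
      expect_identical(got, want)
    }
  }
})

test_that("similarity profiles are flat at 100 for identical sequences and dip
           over a divergent block", {
  s <- rand_nt(400, seed = 1)
  aln <- setNames(rep(s, 4), paste0("s", 1:4))
  prof <- similarity_profile(aln, 50)
  expect_length(prof, 400 - 50 + 1)
  expect_true(all(abs(prof - 100) < 1e-9))
  # diverge one block in two of the sequences
  block <- substitute_k(substr(s, 151, 250), 60, seed = 2)
  s2 <- paste0(substr(s, 1, 150), block, substr(s, 251, 400))
  aln2 <- c(aln[1:2], s3 = s2, s4 = s2)
  prof2 <- similarity_profile(aln2, 30)
  dip <- which.min(prof2)
  expect_gte(dip, 120); expect_lte(dip, 260)
  expect_lt(min(prof2), 80)
  # degenerate window = alignment length gives the overall mean
  whole <- similarity_profile(aln2, 400)
  expect_length(whole, 1)
  expect_equal(whole, mean(similarity_profile(aln2, 1)))
  expect_error(similarity_profile(aln2, 401), "window")
})
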