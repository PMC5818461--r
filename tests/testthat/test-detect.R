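test_that("a perfect young element is found with exact boundaries", {
  tmpl <- fix_templates(2)
  bg <- make_background(30000, 0.38, 2)
  ev <- data.frame(template = "A", locus = 12000, age_years = 0,
                   decay = "complete")
  pl <- plant_elements(bg, tmpl, ev, seed = 4)
  pairs <- find_ltr_pairs(pl$genome)
  expect_equal(nrow(pairs), 1)
  els <- detect_elements(pl$genome)
  expect_length(els, 1)
  tr <- pl$truth
  expect_equal(els[[1]]$start, tr$start)
  expect_equal(els[[1]]$end, tr$end)
  expect_equal(els[[1]]$ltr5, c(tr$ltr5_start, tr$ltr5_end))
  expect_equal(els[[1]]$ltr3, c(tr$ltr3_start, tr$ltr3_end))
  expect_identical(els[[1]]$tsd, tr$tsd)
  expect_equal(els[[1]]$ltr_pair_identity, 100)
})

test_that("detected pair identity of an aged element matches the truth alignment", {
  tmpl <- fix_templates(2)
  bg <- make_background(30000, 0.38, 7)
  ev <- data.frame(template = "B", locus = 12000, age_years = 3e6,
                   decay = "complete")
  pl <- plant_elements(bg, tmpl, ev, seed = 13)
  tr <- pl$truth
  # oracle: global alignment of the planted LTRs themselves
  a <- substr(pl$genome, tr$ltr5_start + 1, tr$ltr5_end)
  b <- substr(pl$genome, tr$ltr3_start + 1, tr$ltr3_end)
  truth_id <- 100 * mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  pairs <- find_ltr_pairs(pl$genome)
  expect_equal(nrow(pairs), 1)
  expect_lt(abs(pairs$identity - truth_id), 2)
})

test_that("random backgrounds yield no candidates at default thresholds", {
  for (seed in 1:5) {
    bg <- make_background(100000, 0.38, seed)
    expect_equal(nrow(find_ltr_pairs(bg)), 0)
  }
})

test_that("sequences shorter than the minimal element length give an empty set", {
  expect_equal(nrow(find_ltr_pairs(rand_nt(500, seed = 1))), 0)
})

test_that("a destroyed TSD leaves the element detected with tsd absent", {
  tmpl <- fix_templates(2)
  bg <- make_background(30000, 0.38, 2)
  ev <- data.frame(template = "A", locus = 12000, age_years = 0,
                   decay = "complete")
  pl <- plant_elements(bg, tmpl, ev, seed = 4)
  tr <- pl$truth
  g <- pl$genome
  # destroy the upstream TSD copy by complementing each of its bases
  wrecked <- chartr("ACGT", "TGCA", tr$tsd)
  broken <- paste0(substr(g, 1, tr$start - 5), wrecked,
                   substr(g, tr$start + 1, nchar(g)))
  els <- detect_elements(broken)
  expect_length(els, 1)
  expect_true(is.na(els[[1]]$tsd) || els[[1]]$tsd != tr$tsd)
  expect_lte(abs(els[[1]]$start - tr$start), 5)
})

test_that("seed-chain boundary errors are corrected by refinement", {
  tmpl <- fix_templates(2)
  bg <- make_background(30000, 0.38, 5)
  ev <- data.frame(template = "A", locus = 12000, age_years = 1e6,
                   decay = "complete")
  pl <- plant_elements(bg, tmpl, ev, seed = 6)
  tr <- pl$truth
  pairs <- find_ltr_pairs(pl$genome)
  # perturb the candidate by 3 bp on each side
  p <- pairs[1, ]
  p$ltr5_start <- p$ltr5_start + 3; p$ltr3_end <- p$ltr3_end - 3
  ref <- refine_boundaries(pl$genome, p)
  expect_equal(ref$ltr5[1], tr$start)
  expect_equal(ref$ltr3[2], tr$end)
})

test_that("LTR pair identity follows the gap-excluded convention", {
  a <- rand_nt(700, seed = 3)
  b <- substitute_k(a, 7, seed = 4)
  g <- paste0(rand_nt(100, seed = 5), a, rand_nt(5000, seed = 6), b,
              rand_nt(100, seed = 7))
  el <- list(ltr5 = c(100, 800), ltr3 = c(5800, 6500))
  expect_equal(ltr_pair_identity(el, g), 99, tolerance = 1e-6)
  expect_error(ltr_pair_identity(list(ltr5 = c(0, 10), ltr3 = NULL), g),
               "LTR pair")
})

test_that("age-0 elements qualify for the >= 99% careful-annotation subset", {
  tmpl <- fix_templates(2)
  bg <- make_background(30000, 0.38, 2)
  pl <- plant_elements(bg, tmpl, data.frame(template = "A", locus = 12000,
                                            age_years = 0, decay = "complete"),
                       seed = 4)
  els <- detect_elements(pl$genome)
  expect_gte(els[[1]]$ltr_pair_identity, 99)
})

test_that("PBS and PPT are recovered at their planted offsets", {
  tmpl <- fix_templates(2)
  bg <- make_background(30000, 0.38, 2)
  pl <- plant_elements(bg, tmpl, data.frame(template = "A", locus = 12000,
                                            age_years = 0, decay = "complete"),
                       seed = 4)
  els <- detect_elements(pl$genome)
  e <- els[[1]]
  expect_false(is.null(e$pbs))
  # template embeds a 14-bp PBS immediately downstream of the 5' LTR (the
  # matcher may extend by a base within its one-mismatch allowance)
  expect_equal(e$pbs[1], e$ltr5[2])
  expect_gte(e$pbs[2] - e$pbs[1], 14)
  expect_lte(e$pbs[2] - e$pbs[1], 18)
  expect_false(is.null(e$ppt))
  expect_lte(e$ltr3[1] - e$ppt[2], 30)
  expect_gte(e$ppt[2] - e$ppt[1], 10)
})

test_that("PPT detection respects orientation on minus-strand elements", {
  tmpl <- fix_templates(2)
  bg <- make_background(30000, 0.38, 2)
  pl <- plant_elements(bg, tmpl, data.frame(template = "A", locus = 12000,
                                            age_years = 0, decay = "complete"),
                       seed = 4)
  tr <- pl$truth
  n <- nchar(pl$genome)
  rc <- revcomp(pl$genome)
  el_rc <- list(strand = "-",
                ltr5 = sort(c(n - tr$ltr3_end, n - tr$ltr3_start)),
                ltr3 = sort(c(n - tr$ltr5_end, n - tr$ltr5_start)))
  el_rc <- detect_pbs_ppt(rc, el_rc)
  # oracle: detect on the forward strand and mirror the intervals
  el_fw <- detect_pbs_ppt(pl$genome,
                          list(strand = "+", ltr5 = c(tr$ltr5_start, tr$ltr5_end),
                               ltr3 = c(tr$ltr3_start, tr$ltr3_end)))
  expect_equal(sort(c(n - el_rc$ppt[2], n - el_rc$ppt[1])), el_fw$ppt)
  expect_equal(sort(c(n - el_rc$pbs[2], n - el_rc$pbs[1])), el_fw$pbs)
})

test_that("reverse-complementing the genome mirrors the detected intervals", {
  sim <- fix_small_sim()
  els_fw <- detect_elements(sim$genome)
  els_rc <- detect_elements(revcomp(sim$genome))
  n <- nchar(sim$genome)
  fw <- sort(vapply(els_fw, function(e) e$start, integer(1)))
  rc <- sort(vapply(els_rc, function(e) n - e$end, integer(1)))
  expect_equal(fw, rc)
})

test_that("detected intervals never overlap except through nesting", {
  sim <- fix_small_sim()
  els <- detect_elements(sim$genome)
  tab <- elements_table(els)
  tab <- tab[order(tab$start), ]
  if (nrow(tab) > 1) {
    for (i in seq_len(nrow(tab) - 1)) {
      nested <- tab$start[i + 1] >= tab$start[i] && tab$end[i + 1] <= tab$end[i]
      expect_true(tab$start[i + 1] >= tab$end[i] || nested)
    }
  }
})

test_that("an element nested inside a host is recovered by the masked second pass", {
  tmpl <- fix_templates(2)
  bg <- make_background(40000, 0.38, 3)
  ev <- data.frame(template = c("A", "B"), locus = c(15000, 0),
                   age_years = c(1e6, 0), decay = "complete",
                   nest_into = c(NA, "ev001"), id = c("ev001", "ev002"))
  pl <- plant_elements(bg, tmpl, ev, seed = 8)
  els <- detect_elements(pl$genome)
  tab <- elements_table(els)
  nest <- pl$truth[pl$truth$id == "ev002", ]
  host <- pl$truth[pl$truth$id == "ev001", ]
  expect_true(any(abs(tab$start - nest$start) <= 5 & abs(tab$end - nest$end) <= 5))
  expect_true(any(abs(tab$start - host$start) <= 5 & abs(tab$end - host$end) <= 5))
})
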