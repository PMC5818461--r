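# Orchestration: simulate -> detect -> annotate -> classify -> census ->
# date -> density -> report, each stage consuming the previous stage's files
# so any stage can be rerun standalone from intermediates. All randomness
# flows from the master seed via per-stage derived seeds.

#' Build a pipeline run configuration
#'
#' Every tunable threshold of every stage appears here with its default; a
#' completed run writes the fully resolved configuration next to its
#' outputs. With `genome_fasta = NULL` a synthetic genome is simulated under
#' `scenario`.
#'
#' @param outdir run directory (created if needed).
#' @param seed master integer seed.
#' @param genome_fasta optional input genome FASTA; NULL simulates.
#' @param scenario arguments passed to [simulate_genome()].
#' @param detection a [detection_config()].
#' @param domain a [domain_config()].
#' @param census a [census_config()].
#' @param groups list: `support_min`, `within_min`, `n_boot`.
#' @param density list: `window_bp`, `step_bp`.
#' @param rate substitution rate per site per year for dating.
#' @return list of class `run_config`.
#' @export
run_config <- function(outdir, seed = 1L, genome_fasta = NULL,
                       scenario = list(bg_length = 120000, n_complete = 6,
                                       n_fragments = 3, n_nested = 1,
                                       ages = 1.5e6, min_spacing = 11000,
                                       n_families = 6),
                       detection = detection_config(),
                       domain = domain_config(),
                       census = census_config(),
                       groups = list(support_min = 70, within_min = 80,
                                     n_boot = 100),
                       density = list(window_bp = 20000, step_bp = 5000),
                       rate = 1.3e-8) {
  structure(list(outdir = outdir, seed = as.integer(seed),
                 genome_fasta = genome_fasta, scenario = scenario,
                 detection = detection, domain = domain, census = census,
                 groups = groups, density = density, rate = rate),
            class = "run_config")
}

.log_line <- function(con, ...) {
  writeLines(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                     sprintf(...)), con)
  flush(con)
}

.read_genome <- function(dir) {
  g <- read_fasta(file.path(dir, "genome.fa"))
  list(seq = g[[1]], id = names(g)[1])
}

# Guard against corrupt or truncated intermediates: a stage must fail loudly
# when a file it consumes does not carry the expected columns.
.require_cols <- function(tab, cols, file) {
  miss <- setdiff(cols, names(tab))
  if (length(miss)) {
    stop("corrupt or incomplete ", file, ": missing column(s) ",
         paste(miss, collapse = ", "))
  }
  tab
}

# Reconstruct ltr_element objects from the detect-stage table.
.elements_from_table <- function(tab, genome_id = "genome") {
  lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    el <- new_ltr_element(r$id, genome_id, r$start, r$end,
                          if (is.na(r$ltr5_start)) NULL else c(r$ltr5_start, r$ltr5_end),
                          if (is.na(r$ltr3_start)) NULL else c(r$ltr3_start, r$ltr3_end),
                          strand = r$strand, tsd = r$tsd,
                          identity = r$ltr_pair_identity)
    el
  })
}

stage_simulate <- function(cfg) {
  dir <- cfg$outdir
  if (!is.null(cfg$genome_fasta)) {
    file.copy(cfg$genome_fasta, file.path(dir, "genome.fa"), overwrite = TRUE)
    return(invisible(NULL))
  }
  sc <- cfg$scenario
  nf <- sc$n_families %||% 10
  sc$n_families <- NULL
  sc$templates <- crc_templates(n_families = nf)
  sim <- do.call(simulate_genome, c(sc, list(seed = derive_seed(cfg$seed, "simulate"))))
  write_fasta(stats::setNames(sim$genome, "genome"), file.path(dir, "genome.fa"))
  write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  write_gff3(truth_records(sim$truth), file.path(dir, "truth.gff3"))
  reps <- vapply(sim$templates, function(t)
    paste0(t$ltr_seq, t$internal_seq, t$ltr_seq), character(1))
  write_fasta(reps, file.path(dir, "family_references.fa"))
  invisible(NULL)
}

stage_detect <- function(cfg) {
  dir <- cfg$outdir
  g <- .read_genome(dir)
  els <- detect_elements(g$seq, cfg$detection, genome_id = g$id)
  write_tsv(elements_table(els), file.path(dir, "elements.tsv"))
  write_gff3(element_records(els, g$id), file.path(dir, "elements.gff3"))
  invisible(NULL)
}

stage_annotate <- function(cfg) {
  dir <- cfg$outdir
  g <- .read_genome(dir)
  tab <- .require_cols(read_tsv(file.path(dir, "elements.tsv")),
                       c("id", "start", "end", "strand", "ltr5_start", "ltr5_end", "ltr3_start", "ltr3_end", "tsd", "ltr_pair_identity"), "elements.tsv")
  els <- .elements_from_table(tab, g$id)
  els <- annotate_elements(g$seq, els, cfg$domain)
  write_tsv(elements_table(els), file.path(dir, "elements_annotated.tsv"))
  dom_rows <- do.call(rbind, lapply(els, function(e) {
    if (is.null(e$domains) || !nrow(e$domains)) return(NULL)
    cbind(element = e$id, e$domains)
  }))
  if (is.null(dom_rows)) dom_rows <- data.frame(element = character())
  write_tsv(dom_rows, file.path(dir, "domains.tsv"))
  rts <- list()
  for (e in els) {
    el_seq <- subseq0(g$seq, e$start, e$end)
    if (e$strand == "-") el_seq <- revcomp(el_seq)
    rt <- extract_rt(el_seq, e$domains, cfg$domain)
    if (!is.null(rt)) rts[[e$id]] <- rt$nt
  }
  if (length(rts)) write_fasta(unlist(rts), file.path(dir, "rt_domains.fa"))
  write_gff3(element_records(els, g$id), file.path(dir, "elements_annotated.gff3"))
  invisible(NULL)
}

stage_classify <- function(cfg) {
  dir <- cfg$outdir
  tab <- .require_cols(read_tsv(file.path(dir, "elements_annotated.tsv")),
                       c("id", "start", "end", "strand", "ltr5_start", "ltr5_end", "ltr3_start", "ltr3_end", "tsd", "ltr_pair_identity"), "elements_annotated.tsv")
  doms <- .require_cols(read_tsv(file.path(dir, "domains.tsv")),
                        "element", "domains.tsv")
  # non-autonomous typing for elements without POL hits
  na_rows <- list()
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    el_doms <- doms$domain[doms$element == r$id]
    if (any(el_doms %in% .POL_DOMAINS)) next
    lens <- c(if (!is.na(r$ltr5_start)) r$ltr5_end - r$ltr5_start,
              if (!is.na(r$ltr3_start)) r$ltr3_end - r$ltr3_start)
    cls <- classify_nonautonomous(list(length = r$end - r$start,
                                       ltr_lengths = lens, domains = el_doms))
    na_rows[[length(na_rows) + 1L]] <- data.frame(
      id = r$id, label = cls$label, evidence = cls$evidence,
      stringsAsFactors = FALSE)
  }
  write_tsv(if (length(na_rows)) do.call(rbind, na_rows) else
    data.frame(id = character(), label = character(), evidence = character()),
    file.path(dir, "nonautonomous.tsv"))
  rt_path <- file.path(dir, "rt_domains.fa")
  if (!file.exists(rt_path)) return(invisible(NULL))
  rts <- read_fasta(rt_path)
  if (length(rts) < 4) return(invisible(NULL))
  idm <- rt_identity_matrix(rts)
  aln <- align_rt_set(rts)
  bt <- bootstrap_groups(aln, n_reps = cfg$groups$n_boot,
                         seed = derive_seed(cfg$seed, "bootstrap"))
  groups <- define_groups(bt$tree, bt$support, idm,
                          support_min = cfg$groups$support_min,
                          within_min = cfg$groups$within_min)
  ape::write.tree(bt$tree, file.path(dir, "rt_tree.nwk"))
  gtab <- do.call(rbind, lapply(groups, function(g) data.frame(
    group = g$name, member = g$members, representative = g$representative,
    within_identity = g$within_identity, stringsAsFactors = FALSE)))
  write_tsv(gtab, file.path(dir, "groups.tsv"))
  gim <- group_identity_matrix(groups, rts)
  write_tsv(cbind(group = rownames(gim), as.data.frame(gim)),
            file.path(dir, "group_identity_matrix.tsv"))
  invisible(NULL)
}

stage_census <- function(cfg) {
  dir <- cfg$outdir
  g <- .read_genome(dir)
  ref_path <- file.path(dir, "family_references.fa")
  if (!file.exists(ref_path)) {
    # fall back to detected group representatives
    gp <- file.path(dir, "groups.tsv")
    if (!file.exists(gp)) stop("no family references available for census")
    groups <- read_tsv(gp)
    tab <- read_tsv(file.path(dir, "elements.tsv"))
    reps <- unique(groups$representative)
    refs <- stats::setNames(vapply(reps, function(id) {
      r <- tab[tab$id == id, ]
      subseq0(g$seq, r$start, r$end)
    }, character(1)), reps)
  } else {
    refs <- read_fasta(ref_path)
  }
  idx <- kmer_table(g$seq, cfg$census$seed_kmer)
  hits <- do.call(rbind, lapply(names(refs), function(nm) {
    census_scan(refs[[nm]], g$seq, cfg$census, family = nm, genome_index = idx)
  }))
  if (is.null(hits)) hits <- census_scan(refs[[1]], g$seq, cfg$census)
  copies <- call_copies(hits, cfg$census)
  write_tsv(copies, file.path(dir, "copies.tsv"))
  if (nrow(copies)) {
    write_bed(data.frame(seqid = g$id, start = copies$start, end = copies$end,
                         name = paste0(copies$family, "_", copies$completeness),
                         score = round(100 * copies$identity),
                         strand = copies$strand),
              file.path(dir, "copies.bed"))
  }
  invisible(NULL)
}

stage_date <- function(cfg) {
  dir <- cfg$outdir
  g <- .read_genome(dir)
  tab <- .require_cols(read_tsv(file.path(dir, "elements.tsv")),
                       c("id", "start", "end", "strand", "ltr5_start", "ltr5_end", "ltr3_start", "ltr3_end", "tsd", "ltr_pair_identity"), "elements.tsv")
  els <- .elements_from_table(tab, g$id)
  ages <- date_elements(els, g$seq, r = cfg$rate)
  write_tsv(ages, file.path(dir, "ages.tsv"))
  invisible(NULL)
}

stage_density <- function(cfg) {
  dir <- cfg$outdir
  g <- .read_genome(dir)
  n <- nchar(g$seq)
  tab <- .require_cols(read_tsv(file.path(dir, "elements.tsv")),
                       c("start", "end"), "elements.tsv")
  tr_el <- density_profile(tab, n, cfg$density$window_bp, cfg$density$step_bp,
                           mode = "coverage")
  write_bedgraph(tr_el, file.path(dir, "density_elements.bedgraph"), g$id)
  cp <- file.path(dir, "copies.tsv")
  if (file.exists(cp)) {
    copies <- read_tsv(cp)
    # masking-style divergence cap applied to the census-hit track
    copies <- copies[copies$identity >= 1 - cfg$census$max_divergence_for_masking, ,
                     drop = FALSE]
    tr_cp <- density_profile(copies, n, cfg$density$window_bp,
                             cfg$density$step_bp, mode = "coverage")
    write_bedgraph(tr_cp, file.path(dir, "density_census.bedgraph"), g$id)
  }
  invisible(NULL)
}

stage_report <- function(cfg) {
  dir <- cfg$outdir
  g <- .read_genome(dir)
  n <- nchar(g$seq)
  tab <- read_tsv(file.path(dir, "elements.tsv"))
  ann <- data.frame(category = character(), start = integer(), end = integer())
  if (nrow(tab)) {
    ann <- rbind(ann, data.frame(category = "LTR_RT", start = tab$start,
                                 end = tab$end))
  }
  cp <- file.path(dir, "copies.tsv")
  if (file.exists(cp)) {
    copies <- read_tsv(cp)
    if (nrow(copies)) {
      ann <- rbind(ann,
                   data.frame(category = "TE_all", start = copies$start,
                              end = copies$end),
                   data.frame(category = paste0("family_", copies$family),
                              start = copies$start, end = copies$end))
    }
  }
  if (nrow(tab)) {
    ann <- rbind(ann, data.frame(category = "TE_all", start = tab$start,
                                 end = tab$end))
  }
  comp <- region_composition(ann, c(0, n))
  write_tsv(comp, file.path(dir, "composition.tsv"))
  arrays <- detect_tandem_arrays(g$seq, min_period = 50, max_period = 1000,
                                 min_copies = 5)
  write_tsv(arrays, file.path(dir, "tandem_arrays.tsv"))
  invisible(NULL)
}

#' Run the full pipeline
#'
#' Executes the stages in order, logging wall time and output hashes per
#' stage. A stage failure halts the run with an error naming the stage.
#' Two runs with the same configuration and seed produce byte-identical
#' non-log outputs.
#'
#' @param cfg a [run_config()].
#' @param stages subset of stages to run (default: all, in order).
#' @return the run directory, invisibly.
#' @export
run_pipeline <- function(cfg, stages = c("simulate", "detect", "annotate",
                                         "classify", "census", "date",
                                         "density", "report")) {
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(.serialize_config(cfg), file.path(cfg$outdir, "config_resolved.yaml"))
  log_con <- file(file.path(cfg$outdir, "run.log"), "a")
  on.exit(close(log_con))
  all_stage_fns <- list(simulate = stage_simulate, detect = stage_detect,
                        annotate = stage_annotate, classify = stage_classify,
                        census = stage_census, date = stage_date,
                        density = stage_density, report = stage_report)
  for (nm in stages) {
    fn <- all_stage_fns[[nm]]
    if (is.null(fn)) stop("unknown stage: ", nm)
    t0 <- proc.time()[3]
    before <- list.files(cfg$outdir, full.names = TRUE)
    tryCatch(fn(cfg), error = function(e) {
      .log_line(log_con, "stage %s FAILED: %s", nm, conditionMessage(e))
      stop(sprintf("stage '%s' failed: %s", nm, conditionMessage(e)),
           call. = FALSE)
    })
    outs <- setdiff(list.files(cfg$outdir, full.names = TRUE), before)
    hashes <- tools::md5sum(outs)
    .log_line(log_con, "stage %s ok (%.1fs) seed=%d outputs: %s", nm,
              proc.time()[3] - t0, derive_seed(cfg$seed, nm),
              paste(sprintf("%s=%s", basename(names(hashes)), hashes),
                    collapse = " "))
  }
  invisible(cfg$outdir)
}

.serialize_config <- function(cfg) {
  drop_class <- function(x) {
    if (is.list(x)) { x <- lapply(x, drop_class); attributes(x) <- list(names = names(x)) }
    x
  }
  drop_class(unclass(cfg))
}
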