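# Readers and writers for the standard formats the pipeline speaks. All
# in-memory coordinates are 0-based half-open; GFF3 is written 1-based
# inclusive, BED and bedGraph 0-based half-open, so conversion happens in
# exactly one place per format.

#' Read a FASTA file
#'
#' Accepts multi-record, line-wrapped, mixed-case files. Soft-masked
#' (lowercase) stretches are preserved in the returned uppercase sequence
#' and recorded as a per-record attribute. IUPAC ambiguity codes are kept.
#'
#' @param path FASTA file path.
#' @return named character vector of uppercase sequences; attribute
#'   `"softmasked_frac"` holds the per-record fraction of lowercase input.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  if (!length(x)) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(x))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  raw <- as.character(x)
  soft <- vapply(raw, function(s) {
    n <- nchar(s)
    if (n == 0) return(0)
    sum(utf8ToInt(s) >= 97L & utf8ToInt(s) <= 122L) / n
  }, numeric(1), USE.NAMES = FALSE)
  out <- stats::setNames(toupper(raw), ids)
  attr(out, "softmasked_frac") <- stats::setNames(soft, ids)
  out
}

#' Write sequences as FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @param width line width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

.gff_cols <- c("seqid", "source", "type", "start", "end", "score", "strand",
               "phase", "attributes")

.check_records <- function(records) {
  stopifnot(all(.gff_cols %in% names(records)))
  if (nrow(records) &&
      any(records$start < 0 | records$end <= records$start)) {
    stop("invalid coordinates: start must be >= 0 and end > start")
  }
  records
}

#' Write annotation records as GFF3
#'
#' @param records data.frame with columns `seqid`, `source`, `type`,
#'   `start`, `end` (0-based half-open), `score` (numeric or NA), `strand`,
#'   `phase`, `attributes` (GFF3 attribute string).
#' @param path output path.
#' @export
write_gff3 <- function(records, path) {
  records <- .check_records(records)
  records <- records[order(records$seqid, records$start), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(records)) {
    lines <- sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t%s\t%s",
                     records$seqid, records$source, records$type,
                     records$start + 1L, records$end,
                     ifelse(is.na(records$score), ".",
                            sprintf("%g", records$score)),
                     records$strand, records$phase, records$attributes)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a GFF3 file written by [write_gff3()]
#' @param path GFF3 path.
#' @return data.frame in the same layout (0-based half-open coordinates).
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(seqid = character(), source = character(),
                      type = character(), start = integer(), end = integer(),
                      score = numeric(), strand = character(),
                      phase = character(), attributes = character()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  out <- data.frame(
    seqid = vapply(f, `[`, "", 1), source = vapply(f, `[`, "", 2),
    type = vapply(f, `[`, "", 3),
    start = as.integer(vapply(f, `[`, "", 4)) - 1L,
    end = as.integer(vapply(f, `[`, "", 5)),
    score = suppressWarnings(as.numeric(vapply(f, `[`, "", 6))),
    strand = vapply(f, `[`, "", 7), phase = vapply(f, `[`, "", 8),
    attributes = vapply(f, `[`, "", 9), stringsAsFactors = FALSE)
  out
}

#' Write annotation records as BED
#' @param records data.frame with `seqid`, `start`, `end` (0-based
#'   half-open); optional `name`, `score`, `strand`.
#' @param path output path.
#' @export
write_bed <- function(records, path) {
  if (nrow(records) && any(records$start < 0 | records$end <= records$start)) {
    stop("invalid coordinates: start must be >= 0 and end > start")
  }
  nm <- if ("name" %in% names(records)) records$name else "."
  sc <- if ("score" %in% names(records)) records$score else 0
  st <- if ("strand" %in% names(records)) records$strand else "."
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", records$seqid, records$start,
                   records$end, nm, sc, st)
  writeLines(lines, path)
  invisible(path)
}

#' Write a density track as bedGraph
#' @param track data.frame with `start`, `end`, `value` ([density_profile()]).
#' @param path output path.
#' @param seqid sequence name.
#' @export
write_bedgraph <- function(track, path, seqid = "genome") {
  lines <- c("track type=bedGraph",
             sprintf("%s\t%d\t%d\t%g", seqid, track$start, track$end,
                     track$value))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a tab-separated table
#' @param x data.frame.
#' @param path file path.
#' @export
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA"))
}

#' Truth table as GFF3 records
#' @param truth data.frame from [plant_elements()].
#' @param genome_id sequence name.
#' @return records data.frame for [write_gff3()].
#' @export
truth_records <- function(truth, genome_id = "genome") {
  data.frame(seqid = genome_id, source = "crckit_sim",
             type = "LTR_retrotransposon",
             start = truth$start, end = truth$end, score = NA_real_,
             strand = "+", phase = ".",
             attributes = sprintf("ID=%s;family=%s;age=%g;decay=%s;nest_parent=%s",
                                  truth$id, truth$template, truth$age_years,
                                  truth$decay,
                                  ifelse(is.na(truth$nest_into), ".", truth$nest_into)),
             stringsAsFactors = FALSE)
}

#' Detected elements as GFF3 records (with LTR/TSD/PBS/PPT children)
#' @param elements list of `ltr_element`.
#' @param genome_id sequence name.
#' @return records data.frame for [write_gff3()].
#' @export
element_records <- function(elements, genome_id = "genome") {
  rows <- list()
  add <- function(type, s, e, strand, attrs) {
    rows[[length(rows) + 1L]] <<- data.frame(
      seqid = genome_id, source = "crckit", type = type, start = s, end = e,
      score = NA_real_, strand = strand, phase = ".", attributes = attrs,
      stringsAsFactors = FALSE)
  }
  for (el in elements) {
    add("LTR_retrotransposon", el$start, el$end, el$strand,
        sprintf("ID=%s;ltr_identity=%.2f;tsd=%s;superfamily=%s;motif=%s",
                el$id, el$ltr_pair_identity,
                ifelse(is.na(el$tsd), ".", el$tsd),
                el$labels$superfamily %||% ".", el$labels$motif %||% "."))
    if (!is.null(el$ltr5)) add("long_terminal_repeat", el$ltr5[1], el$ltr5[2],
                               el$strand, sprintf("Parent=%s", el$id))
    if (!is.null(el$ltr3)) add("long_terminal_repeat", el$ltr3[1], el$ltr3[2],
                               el$strand, sprintf("Parent=%s", el$id))
    if (!is.na(el$tsd)) {
      t <- nchar(el$tsd)
      add("target_site_duplication", el$start - t, el$start, el$strand,
          sprintf("Parent=%s", el$id))
      add("target_site_duplication", el$end, el$end + t, el$strand,
          sprintf("Parent=%s", el$id))
    }
    if (!is.null(el$pbs)) add("primer_binding_site", el$pbs[1], el$pbs[2],
                              el$strand, sprintf("Parent=%s", el$id))
    if (!is.null(el$ppt)) add("RR_tract", el$ppt[1], el$ppt[2], el$strand,
                              sprintf("Parent=%s", el$id))
  }
  if (!length(rows)) {
    return(data.frame(seqid = character(), source = character(),
                      type = character(), start = integer(), end = integer(),
                      score = numeric(), strand = character(),
                      phase = character(), attributes = character()))
  }
  do.call(rbind, rows)
}
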