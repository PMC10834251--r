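RMATS_COLS <- c("ID", "GeneID", "geneSymbol", "chr", "strand",
                "exonStart_0base", "exonEnd", "upstreamES", "upstreamEE",
                "downstreamES", "downstreamEE", "ID",
                "IJC_SAMPLE_1", "SJC_SAMPLE_1", "IJC_SAMPLE_2",
                "SJC_SAMPLE_2", "IncFormLen", "SkipFormLen",
                "PValue", "FDR", "IncLevel1", "IncLevel2",
                "IncLevelDifference")

.split_counts <- function(x, what, rows) {
  parts <- strsplit(x, ",", fixed = TRUE)
  n <- lengths(parts)
  if (length(unique(n)) != 1L)
    stop("inconsistent replicate count in column ", what)
  bad <- !vapply(parts, function(p) all(grepl("^[0-9]+$", p)), logical(1))
  if (any(bad))
    stop("non-integer count token in column ", what, " at row ",
         rows[which(bad)[1]])
  matrix(as.integer(unlist(parts)), nrow = length(x), ncol = n[1],
         byrow = TRUE)
}

.mean_inc_level <- function(x) {
  # comma-separated per-replicate inclusion ratios with "NA" for missing
  vapply(strsplit(x, ",", fixed = TRUE), function(p) {
    v <- suppressWarnings(as.numeric(p))
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
}

#' Read a junction-count differential-splicing table
#'
#' Ingests the tab-separated junction-count (JC) dialect produced by
#' splicing callers such as rMATS: one row per event, per-replicate
#' inclusion/skipping junction counts comma-separated within the
#' IJC/SJC columns, reported inclusion levels as ratios ("NA" for
#' missing) and reported PValue/FDR. Reported inclusion levels are
#' converted from ratios to percentages on ingest; reported statistics
#' are kept as row annotations (\code{reported_pvalue},
#' \code{reported_fdr}, \code{reported_mean_psi_g1/2},
#' \code{reported_delta_psi}) while the package's own test remains
#' available on the raw counts.
#'
#' @param path path to the tab-separated table.
#' @param event_type event-type code to stamp on the rows (the JC files
#'   are written per type): one of SE, RI, MXE, A5SS, A3SS.
#' @return A \linkS4class{PsiExperiment} with group1 samples labeled
#'   \code{"control"} and group2 samples \code{"case"}. Zero-row files
#'   yield a zero-row object.
#' @examples
#' f <- tempfile()
#' writeRmatsTable(simulateStudy(simConfig(n_events = 3, n_datasets = 1,
#'   seed = 1))$datasets[[1]], f)
#' pe <- readRmatsTable(f, "SE")
#' @export
readRmatsTable <- function(path, event_type = "SE") {
  if (!file.exists(path)) stop("file not found: ", path)
  event_type <- match.arg(event_type, VALID_EVENT_TYPES)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  miss <- setdiff(unique(RMATS_COLS), header)
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  tab <- utils::read.delim(path, colClasses = "character",
                           check.names = TRUE)
  nr <- nrow(tab)
  ev <- data.frame(
    event_id = tab$ID, gene_id = tab$GeneID, gene_symbol = tab$geneSymbol,
    chrom = tab$chr, strand = tab$strand,
    event_type = rep(event_type, nr),
    exon_start = as.integer(tab$exonStart_0base),
    exon_end = as.integer(tab$exonEnd),
    upstream_start = as.integer(tab$upstreamES),
    upstream_end = as.integer(tab$upstreamEE),
    downstream_start = as.integer(tab$downstreamES),
    downstream_end = as.integer(tab$downstreamEE),
    inc_form_len = as.integer(tab$IncFormLen),
    skip_form_len = as.integer(tab$SkipFormLen),
    stringsAsFactors = FALSE)
  ev$reported_pvalue <- suppressWarnings(as.numeric(tab$PValue))
  ev$reported_fdr <- suppressWarnings(as.numeric(tab$FDR))
  # ratio -> percentage convention
  ev$reported_mean_psi_g1 <- 100 * .mean_inc_level(tab$IncLevel1)
  ev$reported_mean_psi_g2 <- 100 * .mean_inc_level(tab$IncLevel2)
  ev$reported_delta_psi <-
    100 * suppressWarnings(as.numeric(tab$IncLevelDifference))
  ev$inc_level_1 <- tab$IncLevel1
  ev$inc_level_2 <- tab$IncLevel2

  if (nr == 0L) {
    pe <- PsiExperiment(matrix(integer(), 0, 0), matrix(integer(), 0, 0),
                        ev, data.frame(sample_id = character(),
                                       group = character()))
    return(pe)
  }
  rows <- seq_len(nr)
  i1 <- .split_counts(tab$IJC_SAMPLE_1, "IJC_SAMPLE_1", rows)
  s1 <- .split_counts(tab$SJC_SAMPLE_1, "SJC_SAMPLE_1", rows)
  i2 <- .split_counts(tab$IJC_SAMPLE_2, "IJC_SAMPLE_2", rows)
  s2 <- .split_counts(tab$SJC_SAMPLE_2, "SJC_SAMPLE_2", rows)
  if (!identical(dim(i1), dim(s1)) || !identical(dim(i2), dim(s2)))
    stop("IJC/SJC replicate counts differ in width")
  n1 <- ncol(i1); n2 <- ncol(i2)
  samples <- data.frame(
    sample_id = c(paste0("g1_rep", seq_len(n1)),
                  paste0("g2_rep", seq_len(n2))),
    group = rep(c("control", "case"), c(n1, n2)),
    stringsAsFactors = FALSE)
  PsiExperiment(cbind(i1, i2), cbind(s1, s2), ev, samples,
                metadata = list(source = path))
}

#' Write a PsiExperiment in the junction-count table dialect
#'
#' Inverse of \code{\link{readRmatsTable}}: counts and coordinates
#' round-trip bit-identically. For objects created by
#' \code{readRmatsTable} the reported statistics columns are re-emitted
#' verbatim; for simulated/native objects they are filled from computed
#' PSI (ratios) or NA.
#'
#' @param pe a \linkS4class{PsiExperiment} whose \code{group} column has
#'   the two levels given by \code{groups}.
#' @param path output path.
#' @param groups character(2): the groups written as SAMPLE_1 (control)
#'   and SAMPLE_2 (case).
#' @return \code{path}, invisibly.
#' @export
writeRmatsTable <- function(pe, path, groups = c("control", "case")) {
  rd <- as.data.frame(rowData(pe))
  g <- as.character(colData(pe)$group)
  j1 <- which(g == groups[1]); j2 <- which(g == groups[2])
  if (!length(j1) || !length(j2))
    stop("groups not found in colData(pe)$group: ",
         paste(groups, collapse = ", "))
  inc <- inclusionCounts(pe); skp <- skippingCounts(pe)
  join <- function(m) apply(m, 1, paste, collapse = ",")
  fmt_num <- function(x) ifelse(is.na(x), "NA", format(x, trim = TRUE))
  if (nrow(pe) > 0 && !is.null(rd$inc_level_1)) {
    il1 <- rd$inc_level_1; il2 <- rd$inc_level_2
    ild <- fmt_num(rd$reported_delta_psi / 100)
    pv <- fmt_num(rd$reported_pvalue); fd <- fmt_num(rd$reported_fdr)
  } else {
    psi <- psiValues(pe) / 100
    jr <- function(m) apply(round(m, 6), 1, function(r)
      paste(ifelse(is.na(r), "NA", format(r, trim = TRUE)), collapse = ","))
    il1 <- if (nrow(pe)) jr(psi[, j1, drop = FALSE]) else character()
    il2 <- if (nrow(pe)) jr(psi[, j2, drop = FALSE]) else character()
    m1 <- rowMeans(psi[, j1, drop = FALSE], na.rm = TRUE)
    m2 <- rowMeans(psi[, j2, drop = FALSE], na.rm = TRUE)
    ild <- fmt_num(round(m2 - m1, 6))
    pv <- rep("NA", nrow(pe)); fd <- rep("NA", nrow(pe))
  }
  out <- data.frame(
    ID = rd$event_id, GeneID = rd$gene_id, geneSymbol = rd$gene_symbol,
    chr = rd$chrom, strand = rd$strand,
    exonStart_0base = rd$exon_start, exonEnd = rd$exon_end,
    upstreamES = rd$upstream_start, upstreamEE = rd$upstream_end,
    downstreamES = rd$downstream_start, downstreamEE = rd$downstream_end,
    ID = rd$event_id,
    IJC_SAMPLE_1 = if (nrow(pe)) join(inc[, j1, drop = FALSE]) else character(),
    SJC_SAMPLE_1 = if (nrow(pe)) join(skp[, j1, drop = FALSE]) else character(),
    IJC_SAMPLE_2 = if (nrow(pe)) join(inc[, j2, drop = FALSE]) else character(),
    SJC_SAMPLE_2 = if (nrow(pe)) join(skp[, j2, drop = FALSE]) else character(),
    IncFormLen = rd$inc_form_len, SkipFormLen = rd$skip_form_len,
    PValue = pv, FDR = fd, IncLevel1 = il1, IncLevel2 = il2,
    IncLevelDifference = ild,
    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Canonical cross-dataset event key
#'
#' Builds a deterministic key from event type, chromosome, strand and
#' the full ordered coordinate tuple. Two events with identical
#' coordinates, type and strand compare equal regardless of their
#' identifiers or gene labels; any differing interval (e.g. the same
#' cassette exon with a different downstream flanking exon) yields a
#' distinct key, so the same exon misspliced in two flanking contexts
#' is kept as two events. Coordinates are used exactly as stored
#' (0-based starts, exclusive ends); no normalization or fuzzy matching.
#'
#' @param x a \linkS4class{PsiExperiment}, or an event-metadata
#'   data.frame with the standard columns.
#' @return character vector of keys, one per event.
#' @examples
#' eventKey(exampleEventTable(2))
#' @export
eventKey <- function(x) {
  rd <- if (is(x, "SummarizedExperiment")) as.data.frame(rowData(x))
        else as.data.frame(x)
  paste(rd$event_type, rd$chrom, rd$strand,
        rd$upstream_start, rd$upstream_end,
        rd$exon_start, rd$exon_end,
        rd$downstream_start, rd$downstream_end, sep = ":")
}

#' Read a dataset-metadata table
#'
#' Tab-separated with fixed header \code{study_id, comparison_id, model,
#' tissue, age, avg_read_depth, read_length, paired_end,
#' is_short_repeat_control}. \code{read_length}, \code{paired_end} and
#' \code{is_short_repeat_control} are optional; missing
#' \code{is_short_repeat_control} defaults to \code{FALSE}, missing
#' \code{paired_end} to \code{TRUE}, missing \code{read_length} to
#' \code{NA}.
#'
#' @param path path to the TSV.
#' @return data.frame, one row per comparison.
#' @export
readDatasetMeta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("study_id", "comparison_id", "model", "tissue", "age",
            "avg_read_depth")
  miss <- setdiff(need, colnames(m))
  if (length(miss))
    stop("metadata missing required column(s): ",
         paste(miss, collapse = ", "))
  m$avg_read_depth <- as.numeric(m$avg_read_depth)
  if (any(is.na(m$avg_read_depth)) || any(m$avg_read_depth < 0))
    stop("avg_read_depth must be non-negative numbers")
  if (is.null(m$is_short_repeat_control)) m$is_short_repeat_control <- FALSE
  m$is_short_repeat_control <- as.logical(m$is_short_repeat_control)
  m$is_short_repeat_control[is.na(m$is_short_repeat_control)] <- FALSE
  if (is.null(m$paired_end)) m$paired_end <- TRUE
  m$paired_end <- as.logical(m$paired_end)
  if (is.null(m$read_length)) m$read_length <- NA_integer_
  m$read_length <- suppressWarnings(as.integer(m$read_length))
  m
}

#' Study-inclusion read-depth gate
#'
#' Partitions metadata rows by the strict average-read-depth threshold:
#' a row (comparison) passes iff \code{avg_read_depth > threshold}
#' (ties fail); a study passes iff at least one of its rows passes.
#'
#' @param metadata data.frame from \code{\link{readDatasetMeta}}.
#' @param threshold read-depth threshold in reads (default 35 million).
#' @return list with \code{passing} and \code{failing} row subsets,
#'   \code{passing_studies} (distinct passing study_ids), and
#'   \code{n_comparisons}: the number of passing rows that are not
#'   short-repeat controls (disease-vs-control comparisons).
#' @examples
#' meta <- scaDatasetTable()
#' g <- readDepthFilter(meta)
#' length(g$passing_studies)  # 11
#' g$n_comparisons            # 29
#' @export
readDepthFilter <- function(metadata, threshold = 35e6) {
  stopifnot(threshold > 0)
  pass <- metadata$avg_read_depth > threshold
  passing <- metadata[pass, , drop = FALSE]
  failing <- metadata[!pass, , drop = FALSE]
  list(passing = passing, failing = failing,
       passing_studies = unique(passing$study_id),
       n_comparisons = sum(!passing$is_short_repeat_control))
}

#' Bundled study-metadata table
#'
#' The transcription of the published survey of CAG-expansion SCA mouse
#' RNA-seq studies (study accession, model, tissue, age, average read
#' depth, paired-end status, and whether the row is a short-repeat
#' control such as ATXN1[30Q] or YAC15Q). Read length is not part of
#' the printed table and is left NA.
#'
#' @return data.frame in \code{\link{readDatasetMeta}} format.
#' @export
scaDatasetTable <- function() {
  readDatasetMeta(system.file("extdata", "sca_datasets.tsv",
                              package = "spliceshift", mustWork = TRUE))
}
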