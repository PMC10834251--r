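#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames assay<- rowData colData rowData<- colData<-
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
NULL

VALID_EVENT_TYPES <- c("SE", "RI", "MXE", "A5SS", "A3SS")

REQUIRED_EVENT_COLS <- c(
  "event_id", "gene_id", "gene_symbol", "chrom", "strand", "event_type",
  "exon_start", "exon_end", "upstream_start", "upstream_end",
  "downstream_start", "downstream_end", "inc_form_len", "skip_form_len"
)

#' PsiExperiment: junction counts and PSI for alternative-splicing events
#'
#' A \linkS4class{SummarizedExperiment} subclass holding, for a set of
#' alternative-splicing events (rows) and samples (columns), the
#' inclusion-junction and skipping-junction read counts (assays
#' \code{"inclusion"} and \code{"skipping"}), and optionally a
#' \code{"psi"} assay of per cent spliced in values (0--100, \code{NA}
#' below the coverage floor) added by \code{\link{computePsi}}.
#'
#' Row metadata carries the event description: identifiers, gene labels,
#' event type (one of SE, RI, MXE, A5SS, A3SS), the coordinate triple of
#' the cassette/upstream/downstream intervals (0-based starts, exclusive
#' ends, the junction-count table convention), and the effective lengths
#' of the inclusion and skipping isoform forms used for length
#' normalization. Column metadata carries at least \code{sample_id} and
#' \code{group}.
#'
#' @export
setClass("PsiExperiment", contains = "SummarizedExperiment")

setValidity("PsiExperiment", function(object) {
  msg <- character()
  an <- assayNames(object)
  if (!all(c("inclusion", "skipping") %in% an))
    msg <- c(msg, "assays must include 'inclusion' and 'skipping'")
  else {
    inc <- assay(object, "inclusion")
    skp <- assay(object, "skipping")
    if (any(!is.na(inc) & inc < 0) || any(!is.na(skp) & skp < 0))
      msg <- c(msg, "junction counts must be non-negative")
  }
  rd <- rowData(object)
  miss <- setdiff(REQUIRED_EVENT_COLS, colnames(rd))
  if (length(miss))
    msg <- c(msg, paste0("rowData missing column(s): ",
                         paste(miss, collapse = ", ")))
  else if (nrow(rd) > 0) {
    if (!all(rd$event_type %in% VALID_EVENT_TYPES))
      msg <- c(msg, "event_type must be one of SE, RI, MXE, A5SS, A3SS")
    if (!all(rd$strand %in% c("+", "-")))
      msg <- c(msg, "strand must be '+' or '-'")
    ok_iv <- rd$exon_start < rd$exon_end &
      rd$upstream_start < rd$upstream_end &
      rd$downstream_start < rd$downstream_end
    if (!all(ok_iv)) msg <- c(msg, "every interval must have start < end")
    se <- rd$event_type == "SE"
    if (any(se)) {
      between <- rd$exon_start[se] >= rd$upstream_end[se] &
        rd$exon_end[se] <= rd$downstream_start[se]
      if (!all(between))
        msg <- c(msg, "SE cassette exon must lie between upstream end and downstream start")
    }
    if (any(rd$inc_form_len < 1) || any(rd$skip_form_len < 1))
      msg <- c(msg, "effective form lengths must be >= 1")
  }
  if (!"group" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain a 'group' column")
  if (length(msg)) msg else TRUE
})

#' Construct a PsiExperiment
#'
#' @param inclusion,skipping integer matrices (events x samples) of
#'   inclusion- and skipping-junction read counts.
#' @param events a data.frame (or DataFrame) of event metadata with the
#'   columns listed in \linkS4class{PsiExperiment}.
#' @param sampleData a data.frame with one row per sample; must contain
#'   \code{group} and, if absent, \code{sample_id} is filled from column
#'   names.
#' @param metadata optional list of experiment-level metadata.
#' @return A \linkS4class{PsiExperiment}.
#' @examples
#' inc <- matrix(c(10L, 12L), 1, 2)
#' skp <- matrix(c(5L, 6L), 1, 2)
#' ev <- exampleEventTable(1)
#' pe <- PsiExperiment(inc, skp, ev,
#'   sampleData = data.frame(sample_id = c("s1", "s2"),
#'                           group = c("control", "case")))
#' pe
#' @export
PsiExperiment <- function(inclusion, skipping, events, sampleData,
                          metadata = list()) {
  inclusion <- as.matrix(inclusion)
  skipping <- as.matrix(skipping)
  storage.mode(inclusion) <- "integer"
  storage.mode(skipping) <- "integer"
  if (!identical(dim(inclusion), dim(skipping)))
    stop("'inclusion' and 'skipping' must have identical dimensions")
  sampleData <- as.data.frame(sampleData)
  if (is.null(sampleData$sample_id)) {
    sampleData$sample_id <- if (!is.null(colnames(inclusion)))
      colnames(inclusion) else paste0("sample", seq_len(ncol(inclusion)))
  }
  rownames(sampleData) <- sampleData$sample_id
  colnames(inclusion) <- colnames(skipping) <- sampleData$sample_id
  events <- as.data.frame(events)
  rownames(inclusion) <- rownames(skipping) <- events$event_id
  se <- SummarizedExperiment(
    assays = list(inclusion = inclusion, skipping = skipping),
    rowData = DataFrame(events), colData = DataFrame(sampleData),
    metadata = metadata)
  new("PsiExperiment", se)
}

#' @describeIn PsiExperiment show method
#' @param object a PsiExperiment
#' @export
setMethod("show", "PsiExperiment", function(object) {
  comp <- table(factor(rowData(object)$event_type, VALID_EVENT_TYPES))
  cat("PsiExperiment:", nrow(object), "events x", ncol(object), "samples\n")
  cat("  event types:",
      paste(names(comp), comp, sep = "=", collapse = " "), "\n")
  cat("  groups:",
      paste(names(table(colData(object)$group)),
            table(colData(object)$group), sep = "=", collapse = " "), "\n")
  cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
})

#' Example event table (helper for documentation and tests)
#'
#' Returns a minimal valid event-metadata data.frame with \code{n}
#' skipped-exon events.
#'
#' @param n number of events.
#' @return data.frame with the required event columns.
#' @export
exampleEventTable <- function(n = 1) {
  base <- 1e6 + (seq_len(n) - 1) * 5000
  data.frame(
    event_id = paste0("ev", seq_len(n)),
    gene_id = paste0("ENSMUSG", seq_len(n)),
    gene_symbol = paste0("Gene", seq_len(n)),
    chrom = "chr1", strand = "+", event_type = "SE",
    exon_start = base + 300, exon_end = base + 400,
    upstream_start = base, upstream_end = base + 200,
    downstream_start = base + 500, downstream_end = base + 700,
    inc_form_len = 2L, skip_form_len = 1L,
    stringsAsFactors = FALSE)
}

#' Accessors for PsiExperiment assays
#'
#' \code{inclusionCounts} and \code{skippingCounts} return the junction
#' count matrices; \code{psiValues} returns the PSI assay (percent,
#' \code{NA} where coverage is below the floor), computing it with
#' default settings if it has not been added yet.
#'
#' @param x a \linkS4class{PsiExperiment}.
#' @return a matrix (events x samples).
#' @export
inclusionCounts <- function(x) assay(x, "inclusion")

#' @rdname inclusionCounts
#' @export
skippingCounts <- function(x) assay(x, "skipping")

#' @rdname inclusionCounts
#' @export
psiValues <- function(x) {
  if (!"psi" %in% assayNames(x)) x <- computePsi(x)
  assay(x, "psi")
}

#' AlleleReference: a two-allele reference with discriminating sites
#'
#' Holds the two allele contigs (as a \code{DNAStringSet} of length 2),
#' the table of discriminating sites between them (substitution columns
#' and indel runs from a pairwise alignment, with 0-based anchor
#' positions on each allele's ungapped coordinates), the read length the
#' reference is meant for, and the minimum number of sites a read must
#' cover to be assignable (default 3, the design rule that any read
#' overlapping the allele-discriminating region sees at least three
#' sequence differences).
#'
#' @slot alleleNames character(2), names of alleles A and B.
#' @slot contigs DNAStringSet of length 2.
#' @slot sites data.frame with columns pos_a, pos_b (0-based), base_a,
#'   base_b ("-" marks the gapped allele at an indel), cmp_a, cmp_b
#'   (anchor bases actually present on each contig), kind ("sub" or
#'   "indel"), informative (logical: anchor bases differ).
#' @slot readLength integer read length.
#' @slot minSites integer minimum covered sites for assignment.
#' @export
setClass("AlleleReference",
  representation(alleleNames = "character", contigs = "DNAStringSet",
                 sites = "data.frame", readLength = "integer",
                 minSites = "integer"))

setValidity("AlleleReference", function(object) {
  msg <- character()
  if (length(object@alleleNames) != 2L)
    msg <- c(msg, "alleleNames must have length 2")
  if (length(object@contigs) != 2L)
    msg <- c(msg, "contigs must contain exactly 2 sequences")
  if (length(object@readLength) != 1L || object@readLength < 1L)
    msg <- c(msg, "readLength must be a positive integer")
  if (length(object@minSites) != 1L || object@minSites < 0L)
    msg <- c(msg, "minSites must be a non-negative integer")
  s <- object@sites
  need <- c("pos_a", "pos_b", "base_a", "base_b", "cmp_a", "cmp_b",
            "kind", "informative")
  if (!all(need %in% colnames(s)))
    msg <- c(msg, "sites table lacks required columns")
  else if (nrow(s)) {
    sub <- s$kind == "sub"
    if (any(s$base_a[sub] == s$base_b[sub]))
      msg <- c(msg, "substitution sites must have base_a != base_b")
    if (is.unsorted(s$pos_a) || is.unsorted(s$pos_b))
      msg <- c(msg, "sites must be sorted by position")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn AlleleReference show method
#' @param object an AlleleReference
#' @export
setMethod("show", "AlleleReference", function(object) {
  cat("AlleleReference:", object@alleleNames[1], "vs",
      object@alleleNames[2], "\n")
  cat("  contig lengths:",
      paste(Biostrings::width(object@contigs), collapse = ", "), "\n")
  cat("  discriminating sites:", nrow(object@sites),
      sprintf("(%d sub, %d indel)", sum(object@sites$kind == "sub"),
              sum(object@sites$kind == "indel")), "\n")
  cat("  read length:", object@readLength,
      " min sites per read:", object@minSites, "\n")
})

#' Accessors for AlleleReference
#'
#' @param x an \linkS4class{AlleleReference}.
#' @return \code{alleleNames}: character(2); \code{alleleContigs}: a
#'   DNAStringSet; \code{discriminatingSites}: the site table.
#' @export
alleleNames <- function(x) x@alleleNames

#' @rdname alleleNames
#' @export
alleleContigs <- function(x) x@contigs

#' @rdname alleleNames
#' @export
discriminatingSites <- function(x) x@sites
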