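#' Discriminating sites between two aligned alleles
#'
#' Scans a pairwise alignment (two gapped sequences of equal length)
#' and reports one site per substitution column and exactly one site
#' per maximal gap run (anchored at the run's first column), so a long
#' repeat-length indel counts as a single sequence difference rather
#' than one per column. Positions are 0-based on each allele's
#' ungapped coordinates; at a gap column the position anchors to the
#' next real base of the gapped allele.
#'
#' @param aligned_a,aligned_b gapped sequences (character scalars or
#'   XString), equal length, "-" for gaps.
#' @return data.frame with columns pos_a, pos_b, base_a, base_b ("-"
#'   for the gapped allele at an indel), cmp_a, cmp_b (the anchor
#'   bases actually on each contig), kind ("sub"/"indel"),
#'   informative (anchor bases differ).
#' @examples
#' findDiscriminatingSites("ACGTACGT", "ACGAACGA")
#' @export
findDiscriminatingSites <- function(aligned_a, aligned_b) {
  a <- strsplit(toupper(as.character(aligned_a)), "")[[1]]
  b <- strsplit(toupper(as.character(aligned_b)), "")[[1]]
  if (length(a) != length(b))
    stop("aligned sequences must have equal (gapped) length")
  both_gap <- a == "-" & b == "-"
  a <- a[!both_gap]; b <- b[!both_gap]
  gap_a <- a == "-"; gap_b <- b == "-"
  # 0-based ungapped position of the base at (or next after) each column
  pos_a <- cumsum(!gap_a) - !gap_a
  pos_b <- cumsum(!gap_b) - !gap_b
  ua <- a[!gap_a]; ub <- b[!gap_b]
  sites <- list()
  sub_cols <- which(!gap_a & !gap_b & a != b)
  for (i in sub_cols)
    sites[[length(sites) + 1]] <- data.frame(
      col = i, pos_a = pos_a[i], pos_b = pos_b[i],
      base_a = a[i], base_b = b[i], kind = "sub",
      stringsAsFactors = FALSE)
  in_gap <- gap_a | gap_b
  if (any(in_gap)) {
    r <- rle(in_gap)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      i <- starts[k]
      sites[[length(sites) + 1]] <- data.frame(
        col = i, pos_a = pos_a[i], pos_b = pos_b[i],
        base_a = a[i], base_b = b[i], kind = "indel",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(sites))
    return(data.frame(pos_a = integer(), pos_b = integer(),
                      base_a = character(), base_b = character(),
                      cmp_a = character(), cmp_b = character(),
                      kind = character(), informative = logical()))
  out <- do.call(rbind, sites)
  out <- out[order(out$col), , drop = FALSE]
  # anchor bases actually present on each contig (for read comparison)
  out$cmp_a <- ua[pmin(out$pos_a + 1, length(ua))]
  out$cmp_b <- ub[pmin(out$pos_b + 1, length(ub))]
  out$informative <- out$cmp_a != out$cmp_b
  rownames(out) <- NULL
  out[, c("pos_a", "pos_b", "base_a", "base_b", "cmp_a", "cmp_b",
          "kind", "informative")]
}

#' Build a two-allele reference with discriminating sites
#'
#' From a pairwise alignment of the two allele sequences (pass gapped
#' sequences directly, or ungapped ones to be aligned globally with
#' \code{Biostrings::pairwiseAlignment}), records the discriminating
#' sites and packages everything into an
#' \linkS4class{AlleleReference} for a given read length, mirroring
#' the construction of minimal allele-specific reference contigs such
#' that reads of that length spanning the discriminating region see at
#' least \code{min_sites} sequence differences.
#'
#' @param seq_a,seq_b allele sequences (character or DNAString). If
#'   they contain "-" they are taken as already aligned.
#' @param read_length read length in bases.
#' @param min_sites minimum discriminating sites per read (default 3).
#' @param allele_names character(2).
#' @return an \linkS4class{AlleleReference}.
#' @export
buildAlleleReference <- function(seq_a, seq_b, read_length,
                                 min_sites = 3,
                                 allele_names = c("allele_a", "allele_b")) {
  sa <- toupper(as.character(seq_a)); sb <- toupper(as.character(seq_b))
  if (!grepl("-", sa, fixed = TRUE) && !grepl("-", sb, fixed = TRUE) &&
      nchar(sa) != nchar(sb)) {
    al <- Biostrings::pairwiseAlignment(Biostrings::DNAString(sa),
                                        Biostrings::DNAString(sb),
                                        type = "global")
    ga <- as.character(Biostrings::alignedPattern(al))
    gb <- as.character(Biostrings::alignedSubject(al))
  } else {
    ga <- sa; gb <- sb
  }
  sites <- findDiscriminatingSites(ga, gb)
  contigs <- DNAStringSet(c(gsub("-", "", ga, fixed = TRUE),
                            gsub("-", "", gb, fixed = TRUE)))
  names(contigs) <- allele_names
  if (read_length > min(Biostrings::width(contigs)))
    stop("read_length exceeds contig length")
  new("AlleleReference", alleleNames = allele_names, contigs = contigs,
      sites = sites, readLength = as.integer(read_length),
      minSites = as.integer(min_sites))
}

.span_windows <- function(pos, read_length) {
  # starts of read-length windows fully inside the discriminating span
  if (length(pos) == 0) return(integer())
  lo <- min(pos); hi <- max(pos)
  if (hi - lo + 1 < read_length) return(integer())
  lo:(hi - read_length + 1)
}

#' Validate an allele reference for a read length
#'
#' A reference is valid when every read-length window lying fully
#' inside the discriminating span (first to last site, on each
#' allele's own coordinates) covers at least \code{minSites}
#' discriminating sites -- the guarantee that any read contained in
#' the allele-discriminating region sees enough differences to be
#' assigned. When the span is shorter than the read length there is no
#' such window and the reference is trivially valid (a read then
#' either covers the whole span or is unassignable by the covered-site
#' rule). With \code{minSites = 0} every reference is valid.
#'
#' @param ref an \linkS4class{AlleleReference}.
#' @return list: \code{valid} (logical), and when invalid
#'   \code{allele} plus \code{window_start} of the leftmost violating
#'   window (0-based).
#' @export
validateReference <- function(ref) {
  L <- ref@readLength
  if (L > min(Biostrings::width(ref@contigs)))
    stop("read_length exceeds contig length")
  for (side in c("a", "b")) {
    pos <- ref@sites[[paste0("pos_", side)]]
    for (s in .span_windows(pos, L)) {
      covered <- sum(pos >= s & pos <= s + L - 1)
      if (covered < ref@minSites)
        return(list(valid = FALSE,
                    allele = ref@alleleNames[match(side, c("a", "b"))],
                    window_start = s))
    }
  }
  list(valid = TRUE, allele = NA_character_, window_start = NA_integer_)
}

#' Assign reads to alleles by discriminating sites
#'
#' Each read, placed at a 0-based offset on the framing contig, covers
#' some of the reference's discriminating sites. A read covering fewer
#' than \code{minSites} informative sites is \code{ambiguous}. A read
#' matching the anchor base of exactly one allele at every covered
#' informative site is assigned to that allele; a read consistent with
#' neither is \code{unassigned}. No mismatch at a covered site is
#' tolerated.
#'
#' Offsets are interpreted on the contig named by \code{on}; for
#' substitution-only (colinear) references the two framings coincide.
#'
#' @param reads character vector of read sequences.
#' @param offsets integer vector of 0-based start positions.
#' @param ref an \linkS4class{AlleleReference}.
#' @param on "a" or "b": which contig the offsets refer to.
#' @return factor with levels allele_a, allele_b, ambiguous,
#'   unassigned (first two renamed to the reference's allele names).
#' @export
assignReads <- function(reads, offsets, ref, on = c("a", "b")) {
  on <- match.arg(on)
  reads <- toupper(as.character(reads))
  offsets <- as.integer(offsets)
  contig_len <- Biostrings::width(ref@contigs)[match(on, c("a", "b"))]
  lens <- nchar(reads)
  if (any(offsets < 0) || any(offsets + lens > contig_len))
    stop("read offset out of range for contig ", on)
  sites <- ref@sites[ref@sites$informative, , drop = FALSE]
  pos <- sites[[paste0("pos_", on)]]
  lv <- c(ref@alleleNames, "ambiguous", "unassigned")
  out <- character(length(reads))
  for (i in seq_along(reads)) {
    cov <- which(pos >= offsets[i] & pos <= offsets[i] + lens[i] - 1)
    if (length(cov) < ref@minSites) { out[i] <- "ambiguous"; next }
    rb <- substring(reads[i], pos[cov] - offsets[i] + 1,
                    pos[cov] - offsets[i] + 1)
    m_a <- all(rb == sites$cmp_a[cov])
    m_b <- all(rb == sites$cmp_b[cov])
    out[i] <- if (m_a && !m_b) ref@alleleNames[1]
      else if (m_b && !m_a) ref@alleleNames[2]
      else if (m_a && m_b) "ambiguous"
      else "unassigned"
  }
  factor(out, levels = lv)
}

#' Transcripts per million
#'
#' Length-normalized relative abundance: rate_i = count_i / length_i,
#' TPM_i = 1e6 * rate_i / sum(rate). Sums to one million by
#' construction.
#'
#' @param counts non-negative counts per target (named vector).
#' @param lengths positive effective lengths (bases), recycled.
#' @return TPM per target.
#' @examples
#' tpmQuantify(c(A = 10, B = 30), c(100, 100))
#' @export
tpmQuantify <- function(counts, lengths) {
  if (any(lengths <= 0)) stop("effective lengths must be > 0")
  if (all(counts == 0)) stop("all counts zero: abundance undefined")
  rate <- counts / lengths
  1e6 * rate / sum(rate)
}

#' Percent reduction of a mean abundance
#'
#' 100 * (1 - mean_case / mean_control): the percentage by which the
#' case condition's mean expression falls below the control's.
#'
#' @param mean_control positive control mean abundance.
#' @param mean_case case mean abundance.
#' @return percent reduction.
#' @examples
#' relativeReduction(40.84, 18.77)  # ~54
#' @export
relativeReduction <- function(mean_control, mean_case) {
  if (any(mean_control <= 0)) stop("control mean must be > 0")
  100 * (1 - mean_case / mean_control)
}

#' Log2 fold change of mean abundances
#'
#' @param mean_case,mean_control positive mean abundances.
#' @return log2(mean_case / mean_control).
#' @export
log2FoldChange <- function(mean_case, mean_control) {
  if (any(mean_case <= 0) || any(mean_control <= 0))
    stop("means must be > 0")
  log2(mean_case / mean_control)
}

#' Relative quantification by the 2^-ddCt method
#'
#' ddCt = (Ct_target,case - Ct_reference,case) -
#' (Ct_target,control - Ct_reference,control); the returned fold
#' change is 2^-ddCt.
#'
#' @param ct_target_case,ct_reference_case,ct_target_control,ct_reference_control
#'   cycle-threshold values (finite).
#' @return fold change.
#' @examples
#' deltaDeltaCt(25, 20, 24, 20)  # 0.5
#' @export
deltaDeltaCt <- function(ct_target_case, ct_reference_case,
                         ct_target_control, ct_reference_control) {
  cts <- c(ct_target_case, ct_reference_case, ct_target_control,
           ct_reference_control)
  if (any(!is.finite(cts))) stop("Ct values must be finite")
  ddct <- (ct_target_case - ct_reference_case) -
    (ct_target_control - ct_reference_control)
  2^(-ddct)
}

#' Per-condition allele abundance summary
#'
#' Mean TPM with standard error across replicates, per allele and
#' condition.
#'
#' @param tpm numeric matrix, alleles (rows) x replicates (columns).
#' @return data.frame with allele, mean_tpm, se_tpm, n.
#' @export
alleleAbundanceSummary <- function(tpm) {
  tpm <- as.matrix(tpm)
  data.frame(
    allele = rownames(tpm),
    mean_tpm = rowMeans(tpm),
    se_tpm = apply(tpm, 1, stats::sd) / sqrt(ncol(tpm)),
    n = ncol(tpm), stringsAsFactors = FALSE)
}
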