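#' Length-normalized per cent spliced in
#'
#' PSI for inclusion/skipping junction counts I and S with effective
#' form lengths lI and lS:
#' \deqn{\psi = 100 \cdot \frac{I/l_I}{I/l_I + S/l_S}}
#' Vectorized; recycles scalar lengths.
#'
#' @param I,S non-negative junction read counts.
#' @param lI,lS effective lengths of the inclusion and skipping forms
#'   (>= 1). In junction-count mode a cassette exon has two inclusion
#'   junctions and one skipping junction, hence the defaults.
#' @return PSI in percent (0--100).
#' @examples
#' psiPoint(0, 10)   # 0
#' psiPoint(20, 0)   # 100
#' psiPoint(20, 10, 2, 1)  # 50
#' @export
psiPoint <- function(I, S, lI = 2, lS = 1) {
  if (any(I + S < 1)) stop("PSI undefined where I + S = 0; filter coverage first")
  if (any(lI < 1) || any(lS < 1)) stop("effective lengths must be >= 1")
  100 * (I / lI) / (I / lI + S / lS)
}

#' Add the PSI assay to a PsiExperiment
#'
#' Computes per-replicate PSI from the junction counts, masking cells
#' whose total coverage I + S falls below the floor (those cells are
#' NA, matching the rule that a PSI estimate needs a minimum number of
#' informative junction reads). A \code{"coverage"} assay (I + S) is
#' added alongside.
#'
#' @param pe a \linkS4class{PsiExperiment}.
#' @param min_coverage minimum I + S per replicate (default 10).
#' @return the object with \code{"psi"} and \code{"coverage"} assays.
#' @export
computePsi <- function(pe, min_coverage = 10) {
  stopifnot(min_coverage >= 1)
  inc <- inclusionCounts(pe); skp <- skippingCounts(pe)
  cov <- inc + skp
  rd <- rowData(pe)
  lI <- rd$inc_form_len; lS <- rd$skip_form_len
  num <- inc / lI
  psi <- 100 * num / (num + skp / lS)
  psi[cov < min_coverage] <- NA_real_
  assay(pe, "psi") <- psi
  assay(pe, "coverage") <- cov
  metadata(pe)$min_coverage <- min_coverage
  pe
}

.perm_tol <- 1e-9

.contrast_matrix <- function(n1, n2) {
  # rows: all assignments of n1 samples (of n1+n2) to group 1;
  # row %*% values = mean(group2) - mean(group1); identity first.
  n <- n1 + n2
  cmb <- utils::combn(n, n1)
  A <- matrix(1 / n2, ncol(cmb), n)
  for (j in seq_len(ncol(cmb))) A[j, cmb[, j]] <- -1 / n1
  id <- which(colSums(cmb == seq_len(n1)) == n1)
  list(A = A, identity = id[1], n_assignments = ncol(cmb))
}

#' Two-sample permutation test on replicate PSI
#'
#' Tests the absolute difference of group means. When the number of
#' distinct group-label assignments choose(n1+n2, n1) is at most
#' \code{max_exhaustive} the null distribution is enumerated exactly
#' and p is the exact proportion of assignments whose statistic is >=
#' the observed one (ties counted, with a 1e-9 numerical tolerance so
#' mathematically equal statistics such as an assignment and its
#' complement compare equal). Otherwise \code{n_perm} Monte-Carlo label
#' shuffles are drawn with the given seed and p uses the add-one
#' correction (k+1)/(n_perm+1), so p > 0 always.
#'
#' @param g1,g2 numeric vectors of replicate PSI (percent), each of
#'   length >= 2 after removing NA.
#' @param n_perm Monte-Carlo draws when not exhaustive.
#' @param seed integer seed (required in Monte-Carlo mode).
#' @param max_exhaustive assignment-count cap for exhaustive mode.
#' @return list with \code{delta_psi} (mean(g2) - mean(g1)),
#'   \code{p_value}, \code{method} ("exhaustive" or "monte-carlo") and
#'   \code{n_assignments}.
#' @examples
#' permutationTestPsi(c(10, 11, 12), c(90, 91, 92))  # p = 2/20
#' @export
permutationTestPsi <- function(g1, g2, n_perm = 10000, seed = NULL,
                               max_exhaustive = 20000) {
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  n1 <- length(g1); n2 <- length(g2)
  if (n1 < 2 || n2 < 2)
    stop("insufficient replicates: each group needs >= 2 non-missing values")
  x <- c(g1, g2)
  obs_delta <- mean(g2) - mean(g1)
  obs <- abs(obs_delta)
  n_assign <- choose(n1 + n2, n1)
  if (n_assign <= max_exhaustive) {
    cm <- .contrast_matrix(n1, n2)
    stats <- abs(drop(cm$A %*% x))
    p <- mean(stats >= obs - .perm_tol)
    list(delta_psi = obs_delta, p_value = p, method = "exhaustive",
         n_assignments = cm$n_assignments)
  } else {
    if (is.null(seed)) stop("seed is required for Monte-Carlo mode")
    set.seed(seed)
    n <- n1 + n2
    k <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n, n1)
      abs(mean(x[-idx]) - mean(x[idx])) >= obs - .perm_tol
    }, logical(1))
    list(delta_psi = obs_delta, p_value = (sum(k) + 1) / (n_perm + 1),
         method = "monte-carlo", n_assignments = n_assign)
  }
}

#' Benjamini-Hochberg adjustment
#'
#' Validated wrapper over the standard step-up false-discovery-rate
#' procedure; output is order-aligned with the input.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted values in [0, 1].
#' @export
bhAdjust <- function(p) {
  if (length(p) == 0) return(numeric())
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differential splicing across two groups
#'
#' For every event with at least two covered replicates in each group,
#' computes group-mean PSI (unweighted mean of per-replicate PSI),
#' delta PSI (case minus control, percentage points), a permutation
#' p-value on |mean difference| (\code{\link{permutationTestPsi}}), and
#' a Benjamini-Hochberg FDR computed across the tested events of each
#' event type. Events with fewer than two covered replicates in either
#' group are reported untested (\code{tested = FALSE}, NA statistics)
#' and excluded from the FDR denominator.
#'
#' When \code{use_reported = TRUE} and the object carries reported
#' statistics from an ingested table, those PValue/FDR/delta values are
#' used instead of the package's own test.
#'
#' @param pe a \linkS4class{PsiExperiment}.
#' @param groups character(2): control group then case group.
#' @param n_perm,seed,min_coverage see
#'   \code{\link{permutationTestPsi}} and \code{\link{computePsi}}.
#' @param fdr_max,p_max,dpsi_min dual significance thresholds, see
#'   \code{\link{callSignificant}}.
#' @param use_reported use ingested PValue/FDR annotations instead of
#'   the permutation test.
#' @return data.frame with one row per event: event_key, event_id,
#'   event_type, gene_id, gene_symbol, n1, n2, mean_psi_g1, mean_psi_g2,
#'   delta_psi, p_value, fdr, sig_primary, sig_secondary, tested.
#' @export
diffSplicing <- function(pe, groups = c("control", "case"),
                         n_perm = 10000, seed = 1, min_coverage = 10,
                         fdr_max = 0.1, p_max = 0.05, dpsi_min = 10,
                         use_reported = FALSE) {
  if (!"psi" %in% assayNames(pe) ||
      !identical(metadata(pe)$min_coverage, min_coverage))
    pe <- computePsi(pe, min_coverage)
  psi <- assay(pe, "psi")
  g <- as.character(colData(pe)$group)
  j1 <- which(g == groups[1]); j2 <- which(g == groups[2])
  if (!length(j1) || !length(j2))
    stop("groups not found: ", paste(groups, collapse = ", "))
  rd <- as.data.frame(rowData(pe))
  nev <- nrow(pe)
  res <- data.frame(
    event_key = eventKey(pe), event_id = rd$event_id,
    event_type = rd$event_type, gene_id = rd$gene_id,
    gene_symbol = rd$gene_symbol,
    n1 = NA_integer_, n2 = NA_integer_,
    mean_psi_g1 = NA_real_, mean_psi_g2 = NA_real_,
    delta_psi = NA_real_, p_value = NA_real_, fdr = NA_real_,
    sig_primary = FALSE, sig_secondary = FALSE, tested = FALSE,
    stringsAsFactors = FALSE)
  if (nev == 0) return(res)

  if (use_reported) {
    if (is.null(rd$reported_pvalue))
      stop("no reported statistics on this object")
    res$mean_psi_g1 <- rd$reported_mean_psi_g1
    res$mean_psi_g2 <- rd$reported_mean_psi_g2
    res$delta_psi <- rd$reported_delta_psi
    res$p_value <- rd$reported_pvalue
    res$fdr <- rd$reported_fdr
    res$tested <- !is.na(res$p_value)
    return(callSignificant(res, fdr_max, p_max, dpsi_min))
  }

  v1 <- psi[, j1, drop = FALSE]; v2 <- psi[, j2, drop = FALSE]
  res$n1 <- rowSums(!is.na(v1)); res$n2 <- rowSums(!is.na(v2))
  res$mean_psi_g1 <- rowMeans(v1, na.rm = TRUE)
  res$mean_psi_g2 <- rowMeans(v2, na.rm = TRUE)
  res$tested <- res$n1 >= 2 & res$n2 >= 2
  res$mean_psi_g1[res$n1 == 0] <- NA_real_
  res$mean_psi_g2[res$n2 == 0] <- NA_real_
  res$delta_psi <- res$mean_psi_g2 - res$mean_psi_g1
  # cache exhaustive contrast matrices by group-size pattern
  cm_cache <- new.env(parent = emptyenv())
  for (i in which(res$tested)) {
    a <- v1[i, ][!is.na(v1[i, ])]
    b <- v2[i, ][!is.na(v2[i, ])]
    n1 <- length(a); n2 <- length(b)
    if (choose(n1 + n2, n1) <= 20000) {
      key <- paste0(n1, "_", n2)
      cm <- cm_cache[[key]]
      if (is.null(cm)) {
        cm <- .contrast_matrix(n1, n2)
        cm_cache[[key]] <- cm
      }
      stats <- abs(drop(cm$A %*% c(a, b)))
      res$p_value[i] <- mean(stats >= stats[cm$identity] - .perm_tol)
    } else {
      pt <- permutationTestPsi(a, b, n_perm = n_perm,
                               seed = (seed + 1000003 * i) %% 2147483647)
      res$p_value[i] <- pt$p_value
    }
  }
  for (ty in unique(res$event_type[res$tested])) {
    sel <- res$tested & res$event_type == ty
    res$fdr[sel] <- bhAdjust(res$p_value[sel])
  }
  callSignificant(res, fdr_max, p_max, dpsi_min)
}

#' Dual significance calls
#'
#' Applies the two significance rules, all inequalities strict:
#' primary, FDR < \code{fdr_max} and |delta PSI| > \code{dpsi_min}
#' percentage points; secondary, p < \code{p_max} and the same delta
#' threshold. Delta PSI values exactly at the threshold are not called.
#'
#' @param results data.frame with \code{p_value}, \code{fdr} and
#'   \code{delta_psi} columns (percentage points).
#' @param fdr_max,p_max,dpsi_min thresholds (defaults 0.1, 0.05, 10).
#' @return the input with logical \code{sig_primary} and
#'   \code{sig_secondary} columns set.
#' @export
callSignificant <- function(results, fdr_max = 0.1, p_max = 0.05,
                            dpsi_min = 10) {
  ad <- abs(results$delta_psi)
  results$sig_primary <- !is.na(results$fdr) & !is.na(ad) &
    results$fdr < fdr_max & ad > dpsi_min
  results$sig_secondary <- !is.na(results$p_value) & !is.na(ad) &
    results$p_value < p_max & ad > dpsi_min
  results
}

#' Event-type composition of significant events
#'
#' Counts significant events per type and their share of the total,
#' reported over all five event classes.
#'
#' @param results a \code{\link{diffSplicing}} table, already filtered
#'   to the significant events of interest (or pass \code{sig} to pick
#'   a flag column).
#' @param sig optional name of a logical column to filter on
#'   ("sig_primary" or "sig_secondary").
#' @return data.frame with event_type, count, percent (percent sums to
#'   100 when any events exist, else all 0).
#' @export
eventTypeComposition <- function(results, sig = NULL) {
  if (!is.null(sig)) results <- results[isTRUE_vec(results[[sig]]), ]
  counts <- table(factor(results$event_type, VALID_EVENT_TYPES))
  total <- sum(counts)
  pct <- if (total > 0) 100 * as.numeric(counts) / total else rep(0, 5)
  data.frame(event_type = VALID_EVENT_TYPES,
             count = as.integer(counts), percent = pct,
             stringsAsFactors = FALSE)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Inclusion/exclusion direction summary
#'
#' For significant skipped-exon results, summarizes the split between
#' exon-inclusion events (delta PSI > 0: the exon is included more in
#' the case group) and exon-exclusion events (delta PSI < 0), with the
#' mean and maximum |delta PSI| within each direction. A direction with
#' no events is reported absent (NA), not zero.
#'
#' @param delta_psi numeric vector of significant delta PSI values
#'   (percentage points), or a results data.frame with a
#'   \code{delta_psi} column.
#' @return one-row data.frame: n, pct_inclusion, pct_exclusion,
#'   mean_abs_dpsi_inclusion, max_abs_dpsi_inclusion,
#'   mean_abs_dpsi_exclusion, max_abs_dpsi_exclusion.
#' @examples
#' directionSummary(c(20, 30, -25))
#' @export
directionSummary <- function(delta_psi) {
  if (is.data.frame(delta_psi)) delta_psi <- delta_psi$delta_psi
  delta_psi <- delta_psi[!is.na(delta_psi)]
  inc <- delta_psi[delta_psi > 0]; exc <- delta_psi[delta_psi < 0]
  n <- length(delta_psi)
  stat <- function(v, f) if (length(v)) f(abs(v)) else NA_real_
  data.frame(
    n = n,
    pct_inclusion = if (n) 100 * length(inc) / n else NA_real_,
    pct_exclusion = if (n) 100 * length(exc) / n else NA_real_,
    mean_abs_dpsi_inclusion = stat(inc, mean),
    max_abs_dpsi_inclusion = stat(inc, max),
    mean_abs_dpsi_exclusion = stat(exc, mean),
    max_abs_dpsi_exclusion = stat(exc, max))
}
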