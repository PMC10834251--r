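#' Cross-dataset sharing of significant events
#'
#' Builds the membership (upset) matrix of significant events across
#' comparisons and the sharing-degree histogram: for each distinct
#' event key, in how many comparisons it is significant.
#'
#' @param sig_sets named list; each element is the character vector of
#'   significant event keys for one comparison.
#' @return list with \code{membership} (logical matrix, events x
#'   comparisons, rows sorted by event key), \code{degree} (named
#'   integer row sums), and \code{histogram} (named integer vector:
#'   degree d -> number of events significant in exactly d
#'   comparisons; entries over all d sum to the number of distinct
#'   events).
#' @examples
#' sharedEventCounts(list(A = c("e1", "e2"), B = "e1",
#'                        C = c("e1", "e3")))$histogram
#' @export
sharedEventCounts <- function(sig_sets) {
  stopifnot(length(sig_sets) >= 1)
  if (is.null(names(sig_sets)))
    names(sig_sets) <- paste0("comparison", seq_along(sig_sets))
  events <- sort(unique(unlist(sig_sets, use.names = FALSE)))
  membership <- vapply(sig_sets, function(s) events %in% s,
                       logical(length(events)))
  if (length(events) == 1L)
    membership <- matrix(membership, nrow = 1,
                         dimnames = list(events, names(sig_sets)))
  else rownames(membership) <- events
  degree <- rowSums(membership)
  tab <- table(degree)
  histogram <- stats::setNames(as.integer(tab), names(tab))
  list(membership = membership, degree = degree, histogram = histogram)
}

#' Select events shared by at least a given number of comparisons
#'
#' @param membership logical membership matrix from
#'   \code{\link{sharedEventCounts}} (or the list itself).
#' @param min_datasets minimum sharing degree (>= 1).
#' @return character vector of event keys with degree >=
#'   \code{min_datasets}, sorted.
#' @export
selectShared <- function(membership, min_datasets = 2) {
  stopifnot(min_datasets >= 1)
  if (is.list(membership)) membership <- membership$membership
  deg <- rowSums(membership)
  sort(rownames(membership)[deg >= min_datasets])
}

#' PCA of a shared-event PSI matrix
#'
#' Principal component analysis with samples as observations and
#' events as variables. Missing cells are imputed with the event's
#' mean over non-missing samples; events observed in no sample are
#' dropped with a warning. Events are centered (mean over samples
#' subtracted) but not variance-scaled, since PSI is already on a
#' common 0--100 scale. Scores come from the singular value
#' decomposition of the centered matrix; each component's sign is
#' fixed by forcing its largest-magnitude event loading positive, so
#' results are reproducible across platforms.
#'
#' @param psi_matrix numeric matrix, events (rows) x samples
#'   (columns), PSI percentages with NA allowed.
#' @param n_components number of components to return (default all).
#' @return list of class \code{"psiPca"}: \code{scores} (samples x
#'   components), \code{loadings} (events x components),
#'   \code{var_explained} (percent, non-increasing, sums <= 100),
#'   \code{dropped_events}.
#' @export
psiPca <- function(psi_matrix, n_components = NULL) {
  psi_matrix <- as.matrix(psi_matrix)
  if (ncol(psi_matrix) < 2) stop("need >= 2 samples")
  if (nrow(psi_matrix) < 1) stop("need >= 1 event")
  all_na <- rowSums(!is.na(psi_matrix)) == 0
  dropped <- rownames(psi_matrix)[all_na]
  if (any(all_na)) {
    warning(sum(all_na), " event(s) missing in all samples dropped")
    psi_matrix <- psi_matrix[!all_na, , drop = FALSE]
    if (nrow(psi_matrix) == 0) stop("no events left after dropping")
  }
  rmeans <- rowMeans(psi_matrix, na.rm = TRUE)
  idx <- which(is.na(psi_matrix), arr.ind = TRUE)
  if (nrow(idx)) psi_matrix[idx] <- rmeans[idx[, 1]]
  x <- psi_matrix - rowMeans(psi_matrix)   # center each event
  sv <- svd(x)
  d2 <- sv$d^2
  ve <- if (sum(d2) > 0) 100 * d2 / sum(d2) else rep(0, length(d2))
  k <- if (is.null(n_components)) length(sv$d)
       else min(n_components, length(sv$d))
  loadings <- sv$u[, seq_len(k), drop = FALSE]
  scores <- sv$v[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  for (j in seq_len(k)) {
    top <- which.max(abs(loadings[, j]))
    if (loadings[top, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(scores) <- list(colnames(psi_matrix), paste0("PC", seq_len(k)))
  dimnames(loadings) <- list(rownames(psi_matrix), paste0("PC", seq_len(k)))
  structure(list(scores = scores, loadings = loadings,
                 var_explained = ve[seq_len(k)],
                 dropped_events = dropped),
            class = "psiPca")
}

#' @export
print.psiPca <- function(x, ...) {
  cat("PSI principal components:", ncol(x$scores), "components,",
      nrow(x$scores), "samples,", nrow(x$loadings), "events\n")
  cat("  variance explained (%):",
      paste(sprintf("%.1f", x$var_explained[seq_len(min(5, length(x$var_explained)))]),
            collapse = ", "), "\n")
  invisible(x)
}
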