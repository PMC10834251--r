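#' Read gene sets in GMT format
#'
#' Standard tab-separated GMT: set name, description, then member
#' genes. Gene symbols are upper-cased and deduplicated within a set.
#'
#' @param path path to the GMT file.
#' @return named list of gene sets; each element is a list with
#'   \code{name}, \code{description} and \code{genes}.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT format error at line ", i,
           ": need at least 3 tab-separated fields")
    genes <- unique(toupper(f[-(1:2)]))
    genes <- genes[nzchar(genes)]
    sets[[i]] <- list(name = f[1], description = f[2], genes = genes)
  }
  stats::setNames(sets, vapply(sets, `[[`, character(1), "name"))
}

#' Hypergeometric gene-set over-representation
#'
#' For each set, tests whether the query genes overlap it more than
#' expected by chance among the background: with background size N,
#' set-in-background size K, query size n and overlap k, p is the
#' upper-tail hypergeometric probability P[X >= k]. Sets are
#' intersected with the background before testing; the background
#' should be the genes that could have entered the query (e.g. all
#' genes carrying at least one testable event). BH adjustment across
#' all tested sets. Gene symbols are matched case-insensitively
#' (upper-cased).
#'
#' @param query character vector of query gene symbols, a subset of
#'   \code{background}.
#' @param background character vector of background gene symbols.
#' @param sets gene sets from \code{\link{readGmt}} (or a named list
#'   of character vectors).
#' @return data.frame ordered as the input sets: set_name,
#'   overlap_count, set_size (within background), query_size,
#'   background_size, p_value, fdr.
#' @export
hypergeomEnrich <- function(query, background, sets) {
  query <- unique(toupper(query))
  background <- unique(toupper(background))
  off <- setdiff(query, background)
  if (length(off))
    stop("query gene(s) absent from background: ",
         paste(utils::head(off, 5), collapse = ", "))
  genes_of <- function(s) if (is.list(s) && !is.null(s$genes)) s$genes else s
  N <- length(background); n <- length(query)
  rows <- lapply(seq_along(sets), function(i) {
    g <- intersect(unique(toupper(genes_of(sets[[i]]))), background)
    K <- length(g); k <- length(intersect(g, query))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = names(sets)[i] %||% paste0("set", i),
               overlap_count = k, set_size = K, query_size = n,
               background_size = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bhAdjust(out$p_value)
  out
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a) || !nzchar(a)) b else a
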