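# Fixtures built in code and independent brute-force oracles.

rmats_header <- paste(c("ID", "GeneID", "geneSymbol", "chr", "strand",
                        "exonStart_0base", "exonEnd", "upstreamES",
                        "upstreamEE", "downstreamES", "downstreamEE",
                        "ID", "IJC_SAMPLE_1", "SJC_SAMPLE_1",
                        "IJC_SAMPLE_2", "SJC_SAMPLE_2", "IncFormLen",
                        "SkipFormLen", "PValue", "FDR", "IncLevel1",
                        "IncLevel2", "IncLevelDifference"),
                      collapse = "\t")

write_rmats_fixture <- function(rows) {
  f <- tempfile(fileext = ".txt")
  writeLines(c(rmats_header, rows), f)
  f
}

one_row_fixture <- function(ijc1 = "10,12", sjc1 = "5,6",
                            ijc2 = "8,9", sjc2 = "4,5") {
  paste(c("ev1", "G1", "Gene1", "chr1", "+", "1300", "1400", "1000",
          "1200", "1500", "1700", "ev1", ijc1, sjc1, ijc2, sjc2, "2",
          "1", "0.5", "0.6", "0.8,0.8", "0.7,0.7", "-0.1"),
        collapse = "\t")
}

# independent step-up FDR oracle: direct transcription of the rule
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    v <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- v
    prev <- v
  }
  adj
}

# brute-force sharing-degree oracle over explicit sets
shared_oracle <- function(sets) {
  events <- sort(unique(unlist(sets)))
  deg <- vapply(events, function(e)
    sum(vapply(sets, function(s) e %in% s, logical(1))), integer(1))
  table(deg)
}

# exhaustive hypergeometric upper tail by enumerating draws
hyper_oracle <- function(k, K, N, n) {
  # P[X >= k] over all choose(N, n) draws
  total <- choose(N, n)
  num <- 0
  for (x in max(k, max(0, n - (N - K))):min(K, n))
    num <- num + choose(K, x) * choose(N - K, n - x)
  num / total
}

# direct transcription of the rescue classification rules
rescue_oracle <- function(ctrl, dis, tr, rescue_min = 10, delta_min = 5) {
  if (is.na(tr)) return("no_information")
  if (abs(tr - dis) <= delta_min) return("non_rescue")
  pr <- 100 * (tr - dis) / (ctrl - dis)
  if (pr > rescue_min) return("rescued")
  if (pr < -rescue_min) return("opposite_effect")
  "non_rescue"
}

# sliding-window site-count oracle (fully-inside-span windows)
window_oracle_valid <- function(pos, read_length, min_sites) {
  if (!length(pos)) return(TRUE)
  lo <- min(pos); hi <- max(pos)
  if (hi - lo + 1 < read_length) return(TRUE)
  for (s in lo:(hi - read_length + 1))
    if (sum(pos >= s & pos <= s + read_length - 1) < min_sites)
      return(FALSE)
  TRUE
}

# colinear two-allele pair differing by substitutions every `step` bases
make_sub_pair <- function(len = 300, step = 10) {
  set.seed(42)
  a <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  b <- a
  at <- seq(5, len - 5, by = step)
  for (i in at) b[i] <- setdiff(c("A", "C", "G", "T"), a[i])[1]
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""),
       positions0 = at - 1)
}
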