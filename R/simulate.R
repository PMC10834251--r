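#' Simulation configuration for multi-dataset junction-count studies
#'
#' Assembles and validates the generative parameters for
#' \code{\link{simulateStudy}}. The generator emulates the structure
#' the analysis assumes: several datasets with their own replicate
#' counts and junction coverage; five event classes dominated by
#' skipped exons; brain-region-specific baseline PSI; a configurable
#' fraction of events with repeat-length- and age-scaled delta-PSI
#' effects, split into events shared across datasets and
#' dataset-specific ones; replicate-level PSI scatter as a Beta
#' distribution with concentration kappa; and an optional treated arm
#' whose true PSI moves a fraction r of the way back from disease to
#' control.
#'
#' @param n_events number of events.
#' @param event_type_fractions named fractions over SE, RI, MXE, A5SS,
#'   A3SS summing to 1 (default SE-dominated: 0.6/0.1/0.1/0.1/0.1).
#' @param n_datasets number of datasets (used when \code{datasets} is
#'   NULL).
#' @param n_replicates replicates per group per dataset (default 4).
#' @param coverage mean junction reads per event per replicate
#'   (default 200; the surveyed studies span roughly 50--500).
#' @param datasets optional data.frame overriding the per-dataset
#'   design: columns dataset_id, region, replicates, coverage,
#'   repeat_multiplier (effect scaling, 0 for a short-repeat control,
#'   1 for a pathogenic repeat), age_multiplier.
#' @param baseline named list of per-region Beta parameters for the
#'   baseline inclusion ratio, e.g. \code{list(cerebellum = c(2, 2))};
#'   regions not listed fall back to the first entry.
#' @param affected_fraction fraction of events dysregulated.
#' @param effect_size true |delta PSI| for affected events, percentage
#'   points (default 20).
#' @param direction_prob probability an affected event shifts toward
#'   inclusion (default 0.5).
#' @param shared_prob probability an affected event is shared across
#'   all datasets rather than specific to one (default 0.5).
#' @param kappa Beta concentration of replicate-level PSI scatter
#'   (default 100, about +/-4 pp at PSI 50).
#' @param treatment include a treated arm (default FALSE).
#' @param rescue_fraction per-event rescue fraction r in [0, 1] for
#'   the treated arm (scalar, default 0.8).
#' @param inc_form_len,skip_form_len effective lengths used both to
#'   split counts and later to invert them (defaults 2 and 1: two
#'   inclusion junctions vs one skipping junction).
#' @param seed integer seed; all randomness flows from it.
#' @return validated config list of class \code{"simConfig"}.
#' @export
simConfig <- function(n_events = 1000,
                      event_type_fractions = c(SE = 0.6, RI = 0.1,
                                               MXE = 0.1, A5SS = 0.1,
                                               A3SS = 0.1),
                      n_datasets = 3, n_replicates = 4, coverage = 200,
                      datasets = NULL,
                      baseline = list(cerebellum = c(2, 2)),
                      affected_fraction = 0.1, effect_size = 20,
                      direction_prob = 0.5, shared_prob = 0.5,
                      kappa = 100, treatment = FALSE,
                      rescue_fraction = 0.8,
                      inc_form_len = 2L, skip_form_len = 1L,
                      seed = NULL) {
  if (is.null(datasets))
    datasets <- data.frame(
      dataset_id = paste0("dataset", seq_len(n_datasets)),
      region = names(baseline)[1], replicates = n_replicates,
      coverage = coverage, repeat_multiplier = 1, age_multiplier = 1,
      stringsAsFactors = FALSE)
  cfg <- list(n_events = as.integer(n_events),
              event_type_fractions = event_type_fractions,
              datasets = datasets, baseline = baseline,
              affected_fraction = affected_fraction,
              effect_size = effect_size,
              direction_prob = direction_prob,
              shared_prob = shared_prob, kappa = kappa,
              treatment = isTRUE(treatment),
              rescue_fraction = rescue_fraction,
              inc_form_len = as.integer(inc_form_len),
              skip_form_len = as.integer(skip_form_len),
              seed = seed)
  validateSimConfig(cfg)
  class(cfg) <- "simConfig"
  cfg
}

validateSimConfig <- function(cfg) {
  f <- cfg$event_type_fractions
  if (!setequal(names(f), VALID_EVENT_TYPES) || any(f < 0) ||
      abs(sum(f) - 1) > 1e-8)
    stop("event_type_fractions must be non-negative over the five ",
         "event types and sum to 1")
  probs <- c(cfg$affected_fraction, cfg$direction_prob,
             cfg$shared_prob, cfg$rescue_fraction)
  if (any(probs < 0 | probs > 1))
    stop("probabilities and rescue_fraction must lie in [0, 1]")
  if (cfg$kappa <= 0) stop("kappa must be > 0")
  if (cfg$n_events < 1) stop("n_events must be >= 1")
  if (cfg$effect_size < 0 || cfg$effect_size > 100)
    stop("effect_size is in PSI percentage points (0-100)")
  d <- cfg$datasets
  need <- c("dataset_id", "region", "replicates", "coverage",
            "repeat_multiplier", "age_multiplier")
  if (!all(need %in% colnames(d)))
    stop("datasets table missing column(s): ",
         paste(setdiff(need, colnames(d)), collapse = ", "))
  if (any(d$replicates < 2)) stop("each group needs >= 2 replicates")
  if (any(d$coverage <= 0)) stop("coverage must be > 0")
  invisible(TRUE)
}

.stream_seed <- function(seed, k) {
  # deterministic per-stream seed below 2^31
  as.integer((as.numeric(seed) * 48271 + k * 104729) %% 2147483629 + 1)
}

.clamp01 <- function(x, eps = 1e-4) pmin(pmax(x, eps), 1 - eps)

#' Simulate a multi-dataset junction-count study with ground truth
#'
#' Generates, for every dataset and condition, per-replicate
#' inclusion/skipping junction counts under the model: replicate PSI
#' psi_rep ~ Beta(mu*kappa, (1-mu)*kappa); total junction reads
#' n ~ Poisson(coverage); inclusion reads I ~ Binomial(n, q) with the
#' length-weighted inclusion probability
#' q = psi*lI / (psi*lI + (1-psi)*lS) (which inverts the PSI estimator
#' exactly, so the estimator is unbiased by construction); S = n - I.
#' Affected events shift the case-condition mean by the configured
#' effect size (scaled by each dataset's repeat-length and age
#' multipliers); with a treated arm, the treated mean is
#' mu_disease + r * (mu_control - mu_disease). All randomness derives
#' from the config seed through per-dataset streams, so each dataset
#' is reproducible in isolation.
#'
#' @param config a \code{\link{simConfig}} (its \code{seed} must be
#'   set).
#' @return list with \code{datasets}: named list of
#'   \linkS4class{PsiExperiment} objects (groups control/case and,
#'   with a treated arm, treated); \code{events}: the shared event
#'   table with affected/shared flags and per-event direction;
#'   \code{truth}: per dataset x event true means, effects and rescue
#'   fraction; \code{replicate_psi}: per dataset, the realized
#'   replicate-level Beta draws (events x replicates per condition),
#'   for estimator-accuracy checks.
#' @export
simulateStudy <- function(config) {
  validateSimConfig(config)
  if (is.null(config$seed)) stop("config$seed must be set")
  set.seed(.stream_seed(config$seed, 0))
  n <- config$n_events
  types <- sample(names(config$event_type_fractions), n, replace = TRUE,
                  prob = config$event_type_fractions)
  ev <- exampleEventTable(n)
  ev$event_type <- types
  ev$gene_symbol <- paste0("Gene", seq_len(n))
  ev$inc_form_len <- config$inc_form_len
  ev$skip_form_len <- config$skip_form_len
  ev$chrom <- paste0("chr", sample(1:19, n, replace = TRUE))
  ev$strand <- sample(c("+", "-"), n, replace = TRUE)
  affected <- stats::runif(n) < config$affected_fraction
  shared <- affected & stats::runif(n) < config$shared_prob
  specific_ds <- ifelse(affected & !shared,
                        sample.int(nrow(config$datasets), n, replace = TRUE),
                        NA_integer_)
  direction <- ifelse(stats::runif(n) < config$direction_prob, 1, -1)
  regions <- unique(config$datasets$region)
  base_mu <- matrix(NA_real_, n, length(regions),
                    dimnames = list(NULL, regions))
  for (r in regions) {
    pars <- config$baseline[[r]]
    if (is.null(pars)) pars <- config$baseline[[1]]
    base_mu[, r] <- stats::rbeta(n, pars[1], pars[2])
  }
  events <- cbind(ev, affected = affected, shared = shared,
                  specific_dataset = specific_ds, direction = direction)

  datasets <- list(); truth <- list(); rep_psi <- list()
  lI <- config$inc_form_len; lS <- config$skip_form_len
  for (d in seq_len(nrow(config$datasets))) {
    ds <- config$datasets[d, ]
    set.seed(.stream_seed(config$seed, d))
    mu0 <- .clamp01(base_mu[, ds$region])
    hit <- shared | (!is.na(specific_ds) & specific_ds == d)
    eff <- ifelse(hit,
                  direction * config$effect_size / 100 *
                    ds$repeat_multiplier * ds$age_multiplier, 0)
    mu_case <- .clamp01(mu0 + eff)
    true_dpsi <- 100 * (mu_case - mu0)
    conds <- list(control = mu0, case = mu_case)
    if (config$treatment) {
      r <- config$rescue_fraction
      conds$treated <- .clamp01(mu_case + r * (mu0 - mu_case))
    }
    nrep <- ds$replicates
    inc <- skp <- NULL; groups <- character(); ids <- character()
    psis <- list()
    for (cond in names(conds)) {
      mu <- conds[[cond]]
      p_rep <- matrix(stats::rbeta(n * nrep, rep(mu, nrep) * config$kappa,
                                   rep(1 - mu, nrep) * config$kappa),
                      n, nrep)
      tot <- matrix(stats::rpois(n * nrep, ds$coverage), n, nrep)
      q <- p_rep * lI / (p_rep * lI + (1 - p_rep) * lS)
      I <- matrix(stats::rbinom(n * nrep, as.vector(tot), as.vector(q)),
                  n, nrep)
      S <- tot - I
      inc <- cbind(inc, I); skp <- cbind(skp, S)
      groups <- c(groups, rep(cond, nrep))
      ids <- c(ids, paste0(ds$dataset_id, "_", cond, "_rep",
                           seq_len(nrep)))
      psis[[cond]] <- p_rep
    }
    pe <- PsiExperiment(inc, skp, ev,
                        data.frame(sample_id = ids, group = groups,
                                   stringsAsFactors = FALSE),
                        metadata = list(dataset_id = ds$dataset_id,
                                        region = ds$region,
                                        coverage = ds$coverage))
    datasets[[ds$dataset_id]] <- pe
    truth[[ds$dataset_id]] <- data.frame(
      dataset = ds$dataset_id, event_id = ev$event_id,
      event_key = eventKey(ev), event_type = ev$event_type,
      mu_control = mu0, mu_case = mu_case,
      mu_treated = if (config$treatment) conds$treated else NA_real_,
      affected = hit, true_dpsi = true_dpsi,
      shared = shared,
      rescue_fraction = if (config$treatment) config$rescue_fraction
                        else NA_real_,
      stringsAsFactors = FALSE)
    rep_psi[[ds$dataset_id]] <- psis
  }
  list(datasets = datasets, events = events,
       truth = do.call(rbind, truth), replicate_psi = rep_psi)
}

#' Write a simulated study to disk in the ingestible dialect
#'
#' One junction-count table per dataset (control vs case columns),
#' plus a design TSV and the truth manifest.
#'
#' @param sim result of \code{\link{simulateStudy}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
writeSimulatedStudy <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (id in names(sim$datasets)) {
    p <- file.path(dir, paste0(id, ".JC.txt"))
    writeRmatsTable(sim$datasets[[id]], p)
    paths <- c(paths, p)
    cd <- as.data.frame(colData(sim$datasets[[id]]))
    dp <- file.path(dir, paste0(id, ".design.tsv"))
    utils::write.table(cd, dp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, dp)
  }
  tp <- file.path(dir, "truth.tsv")
  utils::write.table(sim$truth, tp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, tp))
}

#' Simulate allele-tagged reads from a validated reference
#'
#' Draws Poisson(depth) reads per allele, start positions uniform over
#' the assignable windows (read-length windows fully inside the contig
#' that cover at least minSites informative sites), and applies
#' i.i.d. per-base substitution errors at rate \code{error_rate}. The
#' reference must be substitution-only (colinear alleles) so that read
#' offsets are shared between the two framings.
#'
#' @param ref a validated \linkS4class{AlleleReference} with no indel
#'   sites.
#' @param depth expected reads per allele.
#' @param error_rate per-base substitution error probability.
#' @param seed integer seed.
#' @return data.frame: read, offset (0-based), true_allele.
#' @export
simulateAlleleReads <- function(ref, depth, error_rate = 0, seed = 1) {
  v <- validateReference(ref)
  if (!v$valid) stop("reference fails the window rule at window ",
                     v$window_start, " on ", v$allele)
  if (any(ref@sites$kind == "indel"))
    stop("read simulation requires a substitution-only reference")
  L <- ref@readLength
  set.seed(.stream_seed(seed, 1))
  out <- list()
  for (side in 1:2) {
    contig <- as.character(ref@contigs[[side]])
    pos <- ref@sites[[c("pos_a", "pos_b")[side]]][ref@sites$informative]
    starts_all <- 0:(nchar(contig) - L)
    ncov <- vapply(starts_all, function(s)
      sum(pos >= s & pos <= s + L - 1), integer(1))
    valid_starts <- starts_all[ncov >= ref@minSites]
    if (!length(valid_starts))
      stop("no assignable window on allele ", ref@alleleNames[side])
    nr <- stats::rpois(1, depth)
    if (nr == 0) next
    s <- valid_starts[sample.int(length(valid_starts), nr, replace = TRUE)]
    reads <- substring(contig, s + 1, s + L)
    if (error_rate > 0) {
      m <- matrix(strsplit(paste(reads, collapse = ""), "")[[1]],
                  nrow = nr, byrow = TRUE)
      err <- matrix(stats::runif(nr * L) < error_rate, nr, L)
      if (any(err)) {
        alt <- vapply(m[err], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
        m[err] <- alt
      }
      reads <- apply(m, 1, paste, collapse = "")
    }
    out[[side]] <- data.frame(read = reads, offset = s,
                              true_allele = ref@alleleNames[side],
                              stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
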