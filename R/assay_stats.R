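#' Bead count table for an MBA assay condition
#'
#' One row per condition: how many beads were counted and how many of them
#' were aggregates, at a given analyte concentration, by a given counting
#' method (on-chip NLM microscopy or flow cytometry). The reference
#' protocol counts 100 beads per concentration.
#'
#' @param label Condition label(s) (e.g. analyte name).
#' @param concentration_mol_dm3 Analyte concentration(s), mol/dm^3.
#' @param n_total Total beads counted (> 0).
#' @param n_aggregate Aggregates among them (0 <= n_aggregate <= n_total).
#' @param method `"nlm"` or `"cytometry"`.
#' @return An `nlm_counts` data.frame.
#' @export
assay_counts <- function(label, concentration_mol_dm3, n_total = 100,
                         n_aggregate, method = c("nlm", "cytometry")) {
  method <- match.arg(method)
  d <- data.frame(label = label,
                  concentration_mol_dm3 = concentration_mol_dm3,
                  n_total = n_total, n_aggregate = n_aggregate,
                  method = method)
  if (any(d$n_total <= 0)) stop("n_total must be > 0")
  if (any(d$n_aggregate < 0 | d$n_aggregate > d$n_total))
    stop("n_aggregate must be in [0, n_total]")
  structure(d, class = c("nlm_counts", "data.frame"))
}

# Wilson 95% score interval for a binomial proportion (no continuity
# correction); returned on the proportion scale.
.wilson <- function(k, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, ctr - hw), upper = min(1, ctr + hw))
}

#' Aggregate fraction with a Wilson interval
#'
#' Point estimate `n_aggregate / n_total` as a percentage with a Wilson 95
#' percent score interval. The Wilson interval behaves sensibly at 0/n and
#' n/n, which bead counts routinely hit at the dose-response extremes.
#'
#' @param counts An [assay_counts()] table (any number of rows).
#' @param conf Confidence level.
#' @return A data.frame with `percent`, `lower_pct`, `upper_pct` appended
#'   to the count columns.
#' @examples
#' aggregate_fraction(assay_counts("BBSA", 1e-9, 100, 67))
#' @export
aggregate_fraction <- function(counts, conf = 0.95) {
  stopifnot(inherits(counts, "data.frame"))
  if (any(counts$n_total <= 0)) stop("n_total must be > 0")
  ci <- t(mapply(.wilson, counts$n_aggregate, counts$n_total,
                 MoreArgs = list(conf = conf)))
  out <- counts
  out$percent <- 100 * counts$n_aggregate / counts$n_total
  out$lower_pct <- 100 * ci[, "lower"]
  out$upper_pct <- 100 * ci[, "upper"]
  out
}

#' Summary of separation efficiencies
#'
#' Mean and sample standard deviation of `epsilon` across replicates or
#' conditions, the form in which separation performance is reported.
#'
#' @param results A list of `nlm_sep` objects, or a numeric vector of
#'   efficiencies.
#' @return List with `mean`, `sd` (NA, flagged, for a single value) and `n`.
#' @examples
#' efficiency_summary(c(0.91, 0.93, 0.95))
#' @export
efficiency_summary <- function(results) {
  eps <- if (is.numeric(results)) results
         else vapply(results, function(r) r$efficiency, numeric(1))
  if (length(eps) == 0) stop("no separation results supplied")
  list(mean = mean(eps),
       sd = if (length(eps) > 1) sd(eps) else NA_real_,
       sd_defined = length(eps) > 1,
       n = length(eps))
}

#' Synthetic bead population
#'
#' Seeded generator of a mixed monomer/dimer population placed on the
#' loading rows of an array, with optional nonspecific sticking: each
#' particle is independently immobilized with probability `stick_prob`
#' (a Bernoulli draw at protocol start, emulating nonspecific adhesion of
#' beads to the chip surface). Species are i.i.d. Bernoulli with the given
#' dimer fraction, so the empirical fraction converges to `dimer_fraction`.
#'
#' @param n Population size (> 0).
#' @param dimer_fraction Probability a particle is a dimer.
#' @param stick_prob Nonspecific sticking probability.
#' @param seed RNG seed (reproducible populations).
#' @param array Target [array_spec()]; particles start on the flux maxima
#'   of the first `start_cols` lattice columns.
#' @param ext External field (phase-0 maxima define the start offsets).
#' @param start_cols Number of loading columns.
#' @return Data frame with `species`, `x_um`, `y_um`, `phi`, `stuck` and
#'   attribute `dimer_fraction`.
#' @export
synth_population <- function(n, dimer_fraction, stick_prob = 0, seed = 1,
                             array = default_array("S"),
                             ext = external_field(), start_cols = 2) {
  if (n <= 0) stop("population size must be > 0")
  if (dimer_fraction < 0 || dimer_fraction > 1 ||
      stick_prob < 0 || stick_prob > 1)
    stop("fractions must lie in [0, 1]")
  set.seed(seed)
  species <- ifelse(runif(n) < dimer_fraction, "dimer", "monomer")
  map <- periodic_field_map(array)
  pk <- unname(.map_peak(map, ext, 0))
  col <- sample.int(start_cols, n, replace = TRUE) - 1
  d <- data.frame(species = species,
                  x_um = array$origin_um[1] + col * array$pitch_x_um + pk[1],
                  y_um = array$origin_um[2] + pk[2],
                  phi = pi / 2,
                  stuck = runif(n) < stick_prob)
  attr(d, "dimer_fraction") <- dimer_fraction
  attr(d, "seed") <- seed
  d
}

#' Dose-response table
#'
#' Orders assay counts by concentration and attaches aggregate percentages
#' with Wilson intervals. No monotonicity is imposed: bead-assembly
#' dose-response curves are non-monotone at high analyte concentration
#' (the hook effect, where excess analyte saturates binding sites).
#'
#' @param counts An [assay_counts()] table.
#' @return An `nlm_dose` data.frame sorted by concentration.
#' @export
dose_response <- function(counts) {
  out <- aggregate_fraction(counts)
  out <- out[order(out$concentration_mol_dm3), ]
  rownames(out) <- NULL
  structure(out, class = c("nlm_dose", "data.frame"))
}

#' Compare two dose-response tables (NLM vs flow cytometry)
#'
#' Per-condition difference in aggregate percentage with a two-proportion
#' score test (no continuity correction) and confidence interval. Labels
#' and concentrations must match one-to-one.
#'
#' @param a,b `nlm_dose` (or [assay_counts()]) tables with matching
#'   conditions, e.g. NLM and cytometer counts.
#' @param conf Confidence level.
#' @return Data frame of per-condition differences (`a` minus `b`,
#'   percentage points), interval bounds and p-values.
#' @export
method_comparison <- function(a, b, conf = 0.95) {
  key_a <- paste(a$label, signif(a$concentration_mol_dm3, 8))
  key_b <- paste(b$label, signif(b$concentration_mol_dm3, 8))
  if (!setequal(key_a, key_b) || anyDuplicated(key_a) || anyDuplicated(key_b)) {
    bad <- c(setdiff(key_a, key_b), setdiff(key_b, key_a))
    stop("condition labels do not match: ", paste(bad, collapse = "; "))
  }
  b <- b[match(key_a, key_b), ]
  rows <- lapply(seq_len(nrow(a)), function(i) {
    pt <- suppressWarnings(
      prop.test(c(a$n_aggregate[i], b$n_aggregate[i]),
                c(a$n_total[i], b$n_total[i]),
                conf.level = conf, correct = FALSE))
    data.frame(label = a$label[i],
               concentration_mol_dm3 = a$concentration_mol_dm3[i],
               diff_pct = 100 * (a$n_aggregate[i] / a$n_total[i] -
                                 b$n_aggregate[i] / b$n_total[i]),
               lower_pct = 100 * pt$conf.int[1],
               upper_pct = 100 * pt$conf.int[2],
               p_value = pt$p.value)
  })
  do.call(rbind, rows)
}

#' Packaged dose-response fixtures
#'
#' Loads the bundled bead-count tables for the reference MBA assays
#' (biotinylated BSA and an HSV-1 dsDNA fragment, counted on-chip). Counts
#' are stored as nearest-integer aggregates out of 100 beads; the
#' originally printed percentage and its printed plus/minus value are kept
#' verbatim in `printed_pct` / `printed_pm` metadata columns.
#'
#' @param assay `"bbsa"` or `"dsdna"`.
#' @return An [assay_counts()] table with metadata columns.
#' @export
load_assay_fixture <- function(assay = c("bbsa", "dsdna")) {
  assay <- match.arg(assay)
  path <- system.file("extdata", paste0(assay, "_nlm_counts.csv"),
                      package = "nlmag", mustWork = TRUE)
  d <- read.csv(path)
  out <- assay_counts(d$label, d$concentration_mol_dm3, d$n_total,
                      d$n_aggregate, method = "nlm")
  out$printed_pct <- d$printed_pct
  out$printed_pm <- d$printed_pm
  out
}

#' Write a count table as CSV
#'
#' @param counts An [assay_counts()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_csv <- function(counts, path) {
  write.csv(as.data.frame(counts), path, row.names = FALSE)
  invisible(path)
}
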