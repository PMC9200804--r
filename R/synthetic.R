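#' Default feature catalog and signature map for the six SMM subtypes
#'
#' A stylized 42-feature catalog whose names read like a myeloma driver
#' panel: per-subtype signature markers (SNVs, arm-level CNAs, five IgH/MYC
#' translocations), three background-only drivers, and the summative
#' `HYPERDIPLOIDY` flag that spans the four hyperdiploid-like subtypes.
#' Every subtype carries 6-7 signature features so planted structure is
#' identifiable; the map is an analog of the published subtype cards, not a
#' literal frequency table.
#'
#' @return list with `catalog` (feature ids), `signature_map` (subtype ->
#'   feature ids), `translocations` (sparse-background features).
#' @export
smm_signature_map <- function() {
  signature_map <- list(
    HL1 = c("NRAS", "TRAF3", "MAX", "EGR1", "gain9", "gain19"),
    HL2 = c("del16q", "del6q", "del1p", "del17p", "t(14;20)", "MAFB", "TP53"),
    TL1 = c("t(4;14)", "t(14;16)", "DIS3", "FGFR3", "MAF", "del14q", "del8p"),
    HL3 = c("KRAS", "NFKBIA", "t(8;14)", "SP140", "del20q", "gain7"),
    TL2 = c("t(11;14)", "CCND1", "gain11q", "IRF4", "XBP1", "HIST1H1E"),
    HL4 = c("NFKB2", "KLHL6", "gain2p", "gain1q", "PRKD2", "FAM46C")
  )
  background <- c("DUSP2", "LTB", "del13q")
  list(
    catalog = c(unlist(signature_map, use.names = FALSE), background,
                "HYPERDIPLOIDY"),
    signature_map = signature_map,
    translocations = c("t(14;20)", "t(4;14)", "t(14;16)", "t(8;14)", "t(11;14)")
  )
}

#' Default subtype -> risk-group map
#'
#' TL2 is low risk; HL1 and HL4 intermediate; HL2, TL1 and HL3 high. For
#' generic subtype names (not the six myeloma ones) risk groups are assigned
#' cyclically low / intermediate / high in subtype order.
#'
#' @param subtypes character vector of subtype names.
#' @return named character vector: subtype -> "low"/"intermediate"/"high".
#' @export
default_risk_map <- function(subtypes = names(smm_signature_map()$signature_map)) {
  myeloma <- c(TL2 = "low", HL1 = "intermediate", HL4 = "intermediate",
               HL2 = "high", TL1 = "high", HL3 = "high")
  if (all(subtypes %in% names(myeloma))) {
    return(myeloma[subtypes])
  }
  stats::setNames(rep(c("low", "intermediate", "high"),
                      length.out = length(subtypes)), subtypes)
}

#' Configuration of the synthetic SMM cohort generator
#'
#' The defaults are the study conditions the package is exercised under:
#' 214 patients in 6 subtypes; signature features at Bernoulli rate 0.7 in
#' their own subtype, background rate 0.05 elsewhere (0.005 for the sparse
#' translocations); the summative hyperdiploidy feature at 0.9 in the
#' hyperdiploid-like subtypes except 0.69 in HL2 and 0.1 in the
#' translocation-like ones; risk-group time-to-progression medians 11 / 5.2
#' / 2.6 years (low / intermediate / high); ~34% of patients censored; and
#' evolving-biomarker odds multipliers of 9.4 (eMP) and 5.3 (eHb) for the
#' high-risk group over a 5% base rate.
#'
#' @param n_patients cohort size.
#' @param n_subtypes number of planted subtypes. For any value other than 6
#'   a generic catalog is built (6 signature features per subtype named
#'   `S<k>.F<j>`, three background features, a summative hyperdiploidy flag).
#' @param mixing_proportions simplex over subtypes (default uniform).
#' @param signature_map named list subtype -> signature feature ids.
#' @param feature_catalog ordered feature ids (must contain all signatures).
#' @param p_signature in-subtype Bernoulli rate for signature features.
#' @param p_background rate of a non-signature feature.
#' @param p_background_tra background rate for translocation features.
#' @param translocations feature ids treated as sparse translocations.
#' @param hyperdiploid_rates named per-subtype rate for `HYPERDIPLOIDY`.
#' @param survival_medians_years named vector low/intermediate/high.
#' @param censoring_rate target censored fraction (0 disables censoring).
#' @param evolving_odds named odds multipliers `c(emp = , ehb = )` for the
#'   high-risk group.
#' @param base_evolving_prob evolving probability outside the high-risk group.
#' @param risk_map subtype -> risk group (default [default_risk_map()]).
#' @param seed master seed.
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 214L, n_subtypes = 6L,
                          mixing_proportions = NULL, signature_map = NULL,
                          feature_catalog = NULL,
                          p_signature = 0.7, p_background = 0.05,
                          p_background_tra = 0.005, translocations = NULL,
                          hyperdiploid_rates = NULL,
                          survival_medians_years = c(low = 11, intermediate = 5.2,
                                                     high = 2.6),
                          censoring_rate = 0.34,
                          evolving_odds = c(emp = 9.4, ehb = 5.3),
                          base_evolving_prob = 0.05,
                          risk_map = NULL, seed = 1L) {
  n_subtypes <- as.integer(n_subtypes)
  if (is.null(signature_map)) {
    if (n_subtypes == 6L) {
      defs <- smm_signature_map()
      signature_map <- defs$signature_map
      if (is.null(feature_catalog)) feature_catalog <- defs$catalog
      if (is.null(translocations)) translocations <- defs$translocations
    } else {
      subs <- paste0("S", seq_len(n_subtypes))
      signature_map <- stats::setNames(
        lapply(subs, function(s) paste0(s, ".F", 1:6)), subs)
      if (is.null(feature_catalog)) {
        feature_catalog <- c(unlist(signature_map, use.names = FALSE),
                             paste0("BG", 1:3), "HYPERDIPLOIDY")
      }
      if (is.null(translocations)) translocations <- character(0)
    }
  } else if (is.null(feature_catalog)) {
    feature_catalog <- c(unlist(signature_map, use.names = FALSE), "HYPERDIPLOIDY")
  }
  subtypes <- names(signature_map)
  if (length(subtypes) != n_subtypes) {
    stop("signature_map must have one entry per subtype")
  }
  missing_feats <- setdiff(unlist(signature_map), feature_catalog)
  if (length(missing_feats)) {
    stop("signature features not in catalog: ", paste(missing_feats, collapse = ", "))
  }
  if (is.null(mixing_proportions)) {
    mixing_proportions <- rep(1 / n_subtypes, n_subtypes)
  }
  if (abs(sum(mixing_proportions) - 1) > 1e-12) {
    stop("mixing proportions must sum to 1 (within 1e-12)")
  }
  if (is.null(hyperdiploid_rates)) {
    hyperdiploid_rates <- stats::setNames(
      ifelse(grepl("^HL", subtypes), 0.9, 0.1), subtypes)
    if ("HL2" %in% subtypes) hyperdiploid_rates["HL2"] <- 0.69
  }
  if (is.null(risk_map)) risk_map <- default_risk_map(subtypes)
  rates <- c(p_signature, p_background, p_background_tra,
             hyperdiploid_rates, censoring_rate, base_evolving_prob)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (any(survival_medians_years <= 0)) stop("survival medians must be > 0")
  if (!all(c("low", "intermediate", "high") %in% names(survival_medians_years))) {
    stop("survival_medians_years needs low/intermediate/high entries")
  }
  if (!all(subtypes %in% names(risk_map))) stop("risk_map must cover every subtype")
  structure(list(
    n_patients = as.integer(n_patients), n_subtypes = n_subtypes,
    subtypes = subtypes,
    mixing_proportions = stats::setNames(mixing_proportions, subtypes),
    signature_map = signature_map, feature_catalog = feature_catalog,
    p_signature = p_signature, p_background = p_background,
    p_background_tra = p_background_tra, translocations = translocations,
    hyperdiploid_rates = hyperdiploid_rates,
    survival_medians_years = survival_medians_years,
    censoring_rate = censoring_rate, evolving_odds = evolving_odds,
    base_evolving_prob = base_evolving_prob, risk_map = risk_map,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("cohort_config: %d patients, %d subtypes (%s)\n", x$n_patients,
              x$n_subtypes, paste(x$subtypes, collapse = ", ")))
  cat(sprintf("  %d features, p_signature %.2f, p_background %.2f (tra %.3f)\n",
              length(x$feature_catalog), x$p_signature, x$p_background,
              x$p_background_tra))
  cat(sprintf("  TTP medians (y): low %.1f / intermediate %.1f / high %.1f; censoring %.2f\n",
              x$survival_medians_years["low"], x$survival_medians_years["intermediate"],
              x$survival_medians_years["high"], x$censoring_rate))
  invisible(x)
}

# Bernoulli probability row for one patient of a given subtype
subtype_prob_row <- function(config, subtype) {
  p <- rep(config$p_background, length(config$feature_catalog))
  names(p) <- config$feature_catalog
  p[intersect(config$translocations, names(p))] <- config$p_background_tra
  p[config$signature_map[[subtype]]] <- config$p_signature
  if ("HYPERDIPLOIDY" %in% names(p)) {
    p["HYPERDIPLOIDY"] <- config$hyperdiploid_rates[[subtype]]
  }
  p
}

#' Simulate risk-group-specific times to progression
#'
#' Event times are exponential with rate `log(2) / median` for the
#' patient's risk group (memoryless: only the published medians are
#' available, one parameter per group). Censoring is independent uniform
#' administrative censoring on `[0, T_max]`, with `T_max` solved numerically
#' so the expected censored fraction over the cohort equals
#' `config$censoring_rate`; a rate of 0 disables censoring.
#'
#' @param true_labels character vector of subtype names.
#' @param risk_map subtype -> risk group; default from `config`.
#' @param config a [cohort_config()].
#' @param seed seed (default derived from `config$seed`).
#' @return data.frame: `ttp_months` (> 0), `progressed` (logical),
#'   `risk_group`.
#' @export
generate_survival <- function(true_labels, risk_map = NULL, config,
                              seed = derive_seed(config$seed, 101L)) {
  if (is.null(risk_map)) risk_map <- config$risk_map
  unmapped <- setdiff(unique(true_labels), names(risk_map))
  if (length(unmapped)) {
    stop("unmapped subtype label(s): ", paste(unmapped, collapse = ", "))
  }
  risk <- unname(risk_map[true_labels])
  medians_m <- config$survival_medians_years[risk] * 12
  rate <- log(2) / medians_m
  set.seed(seed)
  t_event <- stats::rexp(length(true_labels), rate = rate)
  if (config$censoring_rate > 0) {
    # E[censored] for one patient with rate r and C ~ U(0, tmax):
    #   P(C < T) = (1 - exp(-r tmax)) / (r tmax)  (1 as tmax -> 0, 0 as -> Inf)
    cens_frac <- function(tmax) {
      mean((1 - exp(-rate * tmax)) / (rate * tmax)) - config$censoring_rate
    }
    tmax <- stats::uniroot(cens_frac, c(1e-6, 1e7))$root
    c_time <- stats::runif(length(true_labels), 0, tmax)
    progressed <- t_event <= c_time
    ttp <- pmin(t_event, c_time)
  } else {
    progressed <- rep(TRUE, length(true_labels))
    ttp <- t_event
  }
  data.frame(ttp_months = pmax(ttp, 1e-3), progressed = progressed,
             risk_group = risk, stringsAsFactors = FALSE)
}

#' Simulate longitudinal M-protein / hemoglobin series with evolving flags
#'
#' Each patient is designated eMP-evolving with probability
#' `plogis(qlogis(base) + 1(high risk) * log(odds))` (same for eHb with its
#' own multiplier). Designated patients receive measurement series that
#' satisfy the corresponding evolving-biomarker rule of
#' [detect_evolving_biomarkers()]; all other series are constructed to
#' violate it (every M-protein excursion stays below the +0.5 g/dL absolute
#' minimum; every hemoglobin drop stays below 0.5 g/dL).
#'
#' @param true_labels subtype names per patient.
#' @param risk_map subtype -> risk group; default from `config`.
#' @param config a [cohort_config()].
#' @param mp_baseline,hb_baseline baseline values (g/dL); generated
#'   log-normally / normally when omitted.
#' @param seed seed (default derived from `config$seed`).
#' @return list: `flags` data.frame (emp, ehb, risk_group, baselines) and
#'   `series` long data.frame (patient_id, marker, month, value) with
#'   measurements at months 0, 3, 6, 9, 12.
#' @export
generate_evolving_flags <- function(true_labels, risk_map = NULL, config,
                                    mp_baseline = NULL, hb_baseline = NULL,
                                    seed = derive_seed(config$seed, 202L)) {
  if (is.null(risk_map)) risk_map <- config$risk_map
  risk <- unname(risk_map[true_labels])
  n <- length(true_labels)
  set.seed(seed)
  if (is.null(mp_baseline)) {
    meanlog <- ifelse(risk == "high", log(1.6),
                      ifelse(risk == "intermediate", log(1.3), log(0.7)))
    mp_baseline <- stats::rlnorm(n, meanlog, 0.5)
  }
  if (is.null(hb_baseline)) hb_baseline <- pmax(stats::rnorm(n, 13.5, 1.3), 6)
  high <- risk == "high"
  p_emp <- stats::plogis(stats::qlogis(config$base_evolving_prob) +
                           high * log(config$evolving_odds[["emp"]]))
  p_ehb <- stats::plogis(stats::qlogis(config$base_evolving_prob) +
                           high * log(config$evolving_odds[["ehb"]]))
  emp <- stats::runif(n) < p_emp
  ehb <- stats::runif(n) < p_ehb
  months <- c(0, 3, 6, 9, 12)
  nm <- length(months)
  pid <- names(true_labels)
  if (is.null(pid)) pid <- sprintf("P%03d", seq_len(n))
  ramp_mp <- c(0, 0.25, 0.5, 0.8, 1)
  ramp_hb <- c(0, 0.3, 0.6, 0.9, 1)
  # evolving series ramp to a final excursion clearing both eMP minima (or
  # the 0.5 g/dL eHb drop); stable series jitter within +/- 0.3 g/dL, below
  # the absolute minima by construction
  delta_mp <- pmax(0.5, 0.25 * mp_baseline) * stats::runif(n, 1.1, 1.6)
  jitter_mp <- matrix(stats::runif(n * (nm - 1), -0.3, 0.3), n)
  mp_mat <- mp_baseline + ifelse(emp, 1, 0) * outer(delta_mp, ramp_mp) +
    ifelse(emp, 0, 1) * cbind(0, jitter_mp)
  drop_hb <- 0.5 + stats::runif(n, 0.1, 0.8)
  jitter_hb <- matrix(stats::runif(n * (nm - 1), -0.3, 0.3), n)
  hb_mat <- hb_baseline - ifelse(ehb, 1, 0) * outer(drop_hb, ramp_hb) +
    ifelse(ehb, 0, 1) * cbind(0, jitter_hb)
  series <- data.frame(
    patient_id = rep(pid, each = nm, times = 2),
    marker = rep(c("mp", "hb"), each = n * nm),
    month = rep(months, n * 2),
    value = round(c(t(mp_mat), t(hb_mat)), 4),
    stringsAsFactors = FALSE)
  list(
    flags = data.frame(patient_id = pid, emp = emp, ehb = ehb,
                       risk_group = risk, mp_baseline = mp_baseline,
                       hb_baseline = hb_baseline, stringsAsFactors = FALSE),
    series = series
  )
}

#' Generate a complete synthetic SMM cohort
#'
#' Draws subtype labels from the mixing proportions, fills the alteration
#' matrix with conditionally independent Bernoulli features (signature rate
#' inside the subtype, background rate elsewhere, per-subtype rate for the
#' summative hyperdiploidy flag), then layers clinical baselines,
#' risk-group-specific survival and evolving-biomarker series on top. All
#' draws descend deterministically from `config$seed` via per-stage and
#' per-patient derived sub-seeds, so output is reproducible and independent
#' of patient evaluation order.
#'
#' @param config a [cohort_config()].
#' @return list of class `smm_cohort`: `matrix` ([alteration_matrix()]),
#'   `true_labels` (named character), `clinical` (one row per patient:
#'   staging inputs, ttp_months, progressed, subtype, risk_group, evolving
#'   flags), `series` (long biomarker measurements), `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  pid <- sprintf("P%03d", seq_len(n))
  set.seed(derive_seed(config$seed, 1L))
  labels <- sample(config$subtypes, n, replace = TRUE,
                   prob = config$mixing_proportions)
  names(labels) <- pid
  prob_rows <- vapply(config$subtypes, function(s) subtype_prob_row(config, s),
                      numeric(length(config$feature_catalog)))
  vals <- matrix(0L, n, length(config$feature_catalog),
                 dimnames = list(pid, config$feature_catalog))
  for (i in seq_len(n)) {
    set.seed(derive_seed(config$seed, 1000L + i))
    vals[i, ] <- stats::rbinom(ncol(vals), 1L, prob_rows[, labels[i]])
  }
  X <- alteration_matrix(vals)
  surv <- generate_survival(labels, config = config)
  evo <- generate_evolving_flags(labels, config = config)
  set.seed(derive_seed(config$seed, 303L))
  risk <- surv$risk_group
  flc <- stats::rlnorm(n, ifelse(risk == "high", log(15), log(8)), 1)
  bmpc <- 100 * stats::rbeta(n, ifelse(risk == "high", 2.8, 2), 8)
  clinical <- data.frame(
    patient_id = pid,
    m_protein_baseline = round(evo$flags$mp_baseline, 4),
    flc_ratio = round(flc, 4),
    bmpc_percent = round(bmpc, 2),
    hemoglobin_baseline = round(evo$flags$hb_baseline, 4),
    ttp_months = round(surv$ttp_months, 4),
    progressed = surv$progressed,
    subtype = unname(labels),
    risk_group = risk,
    emp = evo$flags$emp, ehb = evo$flags$ehb,
    stringsAsFactors = FALSE
  )
  structure(list(matrix = X, true_labels = labels, clinical = clinical,
                 series = evo$series, config = config),
            class = "smm_cohort")
}

#' @export
print.smm_cohort <- function(x, ...) {
  cat(sprintf("smm_cohort: %d patients x %d features, %d subtypes (seed %d)\n",
              x$config$n_patients, length(x$config$feature_catalog),
              x$config$n_subtypes, x$config$seed))
  print(table(x$true_labels))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits the alteration matrix (TSV, via [write_alteration_matrix()]), the
#' clinical table and the biomarker series (CSV) in the exact formats the
#' readers of this package expect.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return named character vector of the three paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "smm_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "alteration_matrix.tsv"),
             clinical = file.path(dir, "clinical.csv"),
             series = file.path(dir, "biomarker_series.csv"))
  write_alteration_matrix(cohort$matrix, paths["matrix"])
  utils::write.csv(cohort$clinical, paths["clinical"], row.names = FALSE)
  utils::write.csv(cohort$series, paths["series"], row.names = FALSE)
  invisible(paths)
}
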