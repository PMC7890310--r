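#' Generate a synthetic glioma cohort
#'
#' Draws the 17 categorical predictors from the configured marginals with the
#' deterministic consistency rules of the source series (IDH = IDH1 or IDH2;
#' 1p/19q codeletion = 1p deletion and 19q deletion; molecular group derived
#' from the three markers; glioblastoma if and only if WHO grade IV), then
#' simulates progression and death times from a proportional-hazards
#' mechanism in which only the configured causal parents carry effects.
#'
#' @param config A [cohort_config()].
#' @return A `cohort_table`: a data.frame with the columns of
#'   [cohort_columns()], plus attributes `config` and `provenance`.
#' @examples
#' co <- generate_cohort(cohort_config(n_patients = 200, seed = 7))
#' table(co$who_grade, co$histology)  # grade IV <=> glioblastoma
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_patients
  m <- config$marginals
  draw <- function(p) names(p)[sample.int(length(p), n, replace = TRUE,
                                          prob = p)]

  df <- data.frame(
    age_group    = draw(m$age_group),
    sex          = draw(m$sex),
    kps          = draw(m$kps),
    location     = draw(m$location),
    who_grade    = draw(m$who_grade),
    resection    = draw(m$resection),
    radiotherapy = draw(m$radiotherapy),
    chemotherapy = draw(m$chemotherapy),
    mol_group    = draw(m$mol_group),
    stringsAsFactors = FALSE
  )

  # histology: grade IV is glioblastoma by definition; lower grades split
  # between astrocytic and oligodendroglial tumors.
  df$histology <- ifelse(df$who_grade == "IV", "Glioblastoma",
                         draw(m$histology_low_grade))

  # markers consistent with the molecular group
  grp <- df$mol_group
  idh <- as.integer(grp %in% c("Triple-positive", "TERT+IDH", "IDH-only"))
  tert <- as.integer(grp %in% c("Triple-positive", "TERT+IDH", "TERT-only"))
  codel <- as.integer(grp == "Triple-positive")
  others <- which(grp == "Others")
  if (length(others)) {
    sub <- names(m$others_markers)[sample.int(3, length(others),
                                              replace = TRUE,
                                              prob = m$others_markers)]
    codel[others] <- 1L                      # every residual combo carries it
    idh[others] <- as.integer(sub == "IDH+codel")
    tert[others] <- as.integer(sub == "TERT+codel")
  }
  idh1 <- integer(n); idh2 <- integer(n)
  mut <- which(idh == 1)
  if (length(mut)) {
    is1 <- stats::runif(length(mut)) < m$idh1_given_idh[["IDH1"]]
    idh1[mut] <- as.integer(is1)
    idh2[mut] <- as.integer(!is1)
  }
  del1p <- codel; del19q <- codel
  intact <- which(codel == 0)
  if (length(intact)) {
    lone <- names(m$lone_deletions)[sample.int(3, length(intact),
                                               replace = TRUE,
                                               prob = m$lone_deletions)]
    del1p[intact] <- as.integer(lone == "1p-only")
    del19q[intact] <- as.integer(lone == "19q-only")
  }
  as_yn <- function(x) ifelse(x == 1L, "Yes", "No")
  df$idh1 <- as_yn(idh1); df$idh2 <- as_yn(idh2); df$idh <- as_yn(idh)
  df$del_1p <- as_yn(del1p); df$del_19q <- as_yn(del19q)
  df$codel_1p19q <- as_yn(codel); df$tert <- as_yn(tert)

  df <- coerce_cohort_levels(df[, glioma_features()])
  surv <- simulate_survival(df, config)
  out <- cbind(df, surv)
  attr(out, "config") <- config
  attr(out, "provenance") <- list(
    seed = config$seed,
    config_hash = config_hash(config),
    generated = TRUE
  )
  class(out) <- c("cohort_table", "data.frame")
  validate_cohort(out)
  out
}

#' Simulate censored progression and death times for a feature table
#'
#' Progression times follow a (piecewise-)exponential proportional-hazards
#' model: the log hazard is the baseline log hazard plus the sum of the
#' configured `effect_logits` over the causal parents only. Death occurs at
#' progression plus an independent exponential residual, which guarantees
#' OS >= PFS. Administrative censoring is uniform on
#' `[censor_horizon_months, admin_censor_max]`, so every patient has at least
#' 36 months of potential follow-up.
#'
#' @param features A data.frame holding (at least) the causal-parent columns.
#' @param config A [cohort_config()].
#' @return A data.frame with `pfs_months`, `pfs_event`, `os_months`,
#'   `os_event`. Uses the current RNG stream (seed it, or call via
#'   [generate_cohort()] which seeds everything).
#' @export
simulate_survival <- function(features, config) {
  n <- nrow(features)
  eta <- linear_predictor(features, config)
  t_prog <- sample_piecewise_exponential(n, config$baseline_hazard, exp(eta))
  resid <- if (config$os_residual_rate > 0) {
    stats::rexp(n, rate = config$os_residual_rate)
  } else rep(Inf, n)
  t_death <- t_prog + resid
  cens <- stats::runif(n, config$censor_horizon_months,
                       config$admin_censor_max)
  data.frame(
    pfs_months = pmin(t_prog, cens),
    pfs_event  = as.integer(t_prog <= cens),
    os_months  = pmin(t_death, cens),
    os_event   = as.integer(t_death <= cens)
  )
}

# Sum of per-level log-hazard contributions over causal parents only.
linear_predictor <- function(features, config) {
  eta <- numeric(nrow(features))
  for (par in config$causal_parents) {
    eff <- config$effect_logits[[par]]
    lev <- as.character(features[[par]])
    unknown <- setdiff(unique(lev), names(eff))
    if (length(unknown)) {
      stop(sprintf("no effect logit for level '%s' of '%s'",
                   unknown[1], par), call. = FALSE)
    }
    eta <- eta + unname(eff[lev])
  }
  eta
}

# Inverse-CDF sampling of event times under a piecewise-constant baseline
# hazard multiplied per subject by `mult`. H(t) = mult * H0(t);
# T = H0^{-1}(E / mult) with E ~ Exp(1). Zero overall hazard => Inf (never).
sample_piecewise_exponential <- function(n, baseline, mult) {
  e <- stats::rexp(n) / mult
  starts <- baseline$start
  rates <- baseline$rate
  k <- length(starts)
  # cumulative baseline hazard at the start of each piece
  H0 <- c(0, cumsum(rates[-k] * diff(starts)))
  # rightmost piece whose starting cumulative hazard does not exceed the
  # target; duplicates (flat pieces) resolve to the later piece
  j <- findInterval(e, H0)
  t <- starts[j] + ifelse(rates[j] > 0, (e - H0[j]) / rates[j], 0)
  # a flat final piece that the target overshoots is never reached
  t[rates[j] == 0 & e > H0[j]] <- Inf
  t
}

config_hash <- function(config) {
  # stable content hash without extra dependencies
  s <- paste(utils::capture.output(utils::str(config, digits.d = 12)),
             collapse = "\n")
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 977 + 1)) %% 2147483647
}

#' Validate the structural invariants of a cohort table
#'
#' Checks completeness, level membership, marker consistency (IDH = IDH1 or
#' IDH2, codeletion = 1p and 19q deletion, molecular group reproducible from
#' the markers), the grade IV <=> glioblastoma rule, OS >= PFS, and the
#' 36-month follow-up guarantee (no censoring before 36 months).
#'
#' @param cohort A cohort data.frame.
#' @return The cohort, invisibly; errors describe the first violation found.
#' @export
validate_cohort <- function(cohort) {
  miss <- setdiff(cohort_columns(), names(cohort))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
  if (anyNA(cohort[, cohort_columns()])) {
    bad <- which(rowSums(is.na(cohort[, cohort_columns()])) > 0)[1]
    stop("missing values (first at row ", bad, ")", call. = FALSE)
  }
  yn <- function(col) cohort[[col]] == "Yes"
  if (!all(yn("idh") == (yn("idh1") | yn("idh2")))) {
    stop("IDH must equal IDH1 OR IDH2", call. = FALSE)
  }
  if (!all(yn("codel_1p19q") == (yn("del_1p") & yn("del_19q")))) {
    stop("1p/19q codeletion must equal (1p deletion AND 19q deletion)",
         call. = FALSE)
  }
  derived <- derive_molecular_group(yn("idh"), yn("tert"), yn("codel_1p19q"))
  if (!all(as.character(derived) == as.character(cohort$mol_group))) {
    bad <- which(as.character(derived) !=
                   as.character(cohort$mol_group))[1]
    stop("molecular group inconsistent with markers at row ", bad,
         call. = FALSE)
  }
  gbm <- cohort$histology == "Glioblastoma"
  iv <- cohort$who_grade == "IV"
  if (!all(gbm == iv)) {
    stop("histology 'Glioblastoma' must coincide exactly with WHO grade IV",
         call. = FALSE)
  }
  if (any(cohort$os_months < cohort$pfs_months - 1e-9)) {
    stop("os_months must be >= pfs_months for every patient", call. = FALSE)
  }
  if (any(cohort$pfs_event == 0 & cohort$pfs_months < 36 - 1e-9) ||
      any(cohort$os_event == 0 & cohort$os_months < 36 - 1e-9)) {
    stop("censoring before 36 months violates the follow-up inclusion rule",
         call. = FALSE)
  }
  if (!all(cohort$pfs_event %in% 0:1) || !all(cohort$os_event %in% 0:1)) {
    stop("event indicators must be 0/1", call. = FALSE)
  }
  invisible(cohort)
}
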