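#' Configuration for the synthetic claims simulator
#'
#' Builds and validates the parameter set for [generate_cohort()]. The
#' simulator emulates the structure of German-style ambulatory claims:
#' diagnoses arrive quarterly, grouped into billing cases at places of
#' treatment; code frequencies are long-tailed; patients carry one to three
#' latent morbidity clusters ("diseases") whose severity drives the
#' outcomes (number of cases, emergency utilization, drug cost).
#'
#' @param n_patients number of patients to simulate.
#' @param n_diseases number of latent morbidity clusters.
#' @param codes_per_disease number of diagnosis codes specific to each cluster.
#' @param n_background_codes number of cluster-unspecific codes.
#' @param quarters ordered character vector of quarter labels, e.g.
#'   `quarter_seq("2016Q1", "2018Q4")`.
#' @param mean_entries_per_patient expected number of diagnosis entries per
#'   patient (before severity scaling).
#' @param zero_cost_fraction probability of a zero drug-cost year.
#' @param emergency_base_rate baseline emergency probability at average
#'   severity (the population marginal, available in closed form via
#'   [emergency_marginal()], is close to but not identical to this value).
#' @param p_background probability that an entry draws a background code
#'   rather than one of the patient's disease codes; forced to 0 when
#'   `n_background_codes` is 0.
#' @param zipf_exponent exponent of the rank-frequency power law for code
#'   draws within a pool.
#' @param nonconfirmed_rate fraction of entries flagged as not confirmed
#'   (exercises the confirmed-only inclusion filter downstream).
#' @param seed integer master seed; all randomness derives from it through
#'   per-patient substreams, so cohorts are reproducible and per-patient
#'   draws are order-independent.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_patients = 2000L,
                       n_diseases = 6L,
                       codes_per_disease = 10L,
                       n_background_codes = 60L,
                       quarters = quarter_seq("2016Q1", "2018Q4"),
                       mean_entries_per_patient = 30,
                       zero_cost_fraction = 0.21,
                       emergency_base_rate = 0.18,
                       p_background = 0.3,
                       zipf_exponent = 1.1,
                       nonconfirmed_rate = 0.05,
                       seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_diseases = as.integer(n_diseases),
              codes_per_disease = as.integer(codes_per_disease),
              n_background_codes = as.integer(n_background_codes),
              quarters = as.character(quarters),
              mean_entries_per_patient = as.numeric(mean_entries_per_patient),
              zero_cost_fraction = as.numeric(zero_cost_fraction),
              emergency_base_rate = as.numeric(emergency_base_rate),
              p_background = as.numeric(p_background),
              zipf_exponent = as.numeric(zipf_exponent),
              nonconfirmed_rate = as.numeric(nonconfirmed_rate),
              seed = as.integer(seed))
  if (cfg$n_background_codes == 0L) cfg$p_background <- 0
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  need_count <- c("n_patients", "n_diseases", "codes_per_disease")
  for (f in need_count) {
    v <- cfg[[f]]
    if (length(v) != 1L || is.na(v) || v < 1L)
      stop("sim_config: field '", f, "' must be a count >= 1", call. = FALSE)
  }
  if (length(cfg$n_background_codes) != 1L || is.na(cfg$n_background_codes) ||
      cfg$n_background_codes < 0L)
    stop("sim_config: field 'n_background_codes' must be a count >= 0",
         call. = FALSE)
  for (f in c("zero_cost_fraction", "emergency_base_rate", "p_background",
              "nonconfirmed_rate")) {
    v <- cfg[[f]]
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("sim_config: field '", f, "' must be a probability in [0,1]",
           call. = FALSE)
  }
  if (cfg$mean_entries_per_patient <= 0)
    stop("sim_config: field 'mean_entries_per_patient' must be positive",
         call. = FALSE)
  if (length(cfg$quarters) < 1L)
    stop("sim_config: field 'quarters' must be non-empty", call. = FALSE)
  qi <- quarter_index(cfg$quarters)
  if (anyNA(qi) || any(diff(qi) <= 0))
    stop("sim_config: field 'quarters' must be strictly ordered quarter labels",
         call. = FALSE)
  if (length(cfg$seed) != 1L || is.na(cfg$seed))
    stop("sim_config: field 'seed' must be an integer", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic claims configuration\n")
  cat(sprintf("  patients: %d, latent diseases: %d (x%d codes), background codes: %d\n",
              x$n_patients, x$n_diseases, x$codes_per_disease,
              x$n_background_codes))
  cat(sprintf("  quarters: %s..%s, mean entries/patient: %.1f, seed: %d\n",
              x$quarters[1], x$quarters[length(x$quarters)],
              x$mean_entries_per_patient, x$seed))
  invisible(x)
}

#' Quarter label helpers
#'
#' Quarter labels have the form `"2016Q1"`. `quarter_index()` maps labels to
#' sortable integers (year * 4 + quarter), `quarter_seq()` enumerates the
#' labels between two endpoints inclusive.
#'
#' @param q character vector of quarter labels.
#' @return `quarter_index()`: integer vector (NA for malformed labels);
#'   `quarter_seq()`: character vector of labels.
#' @export
quarter_index <- function(q) {
  ok <- grepl("^[0-9]{4}Q[1-4]$", q)
  out <- rep(NA_integer_, length(q))
  out[ok] <- as.integer(substr(q[ok], 1, 4)) * 4L +
    as.integer(substr(q[ok], 6, 6)) - 1L
  out
}

#' @rdname quarter_index
#' @param from,to quarter labels delimiting the window (inclusive).
#' @export
quarter_seq <- function(from, to) {
  i <- quarter_index(from); j <- quarter_index(to)
  if (is.na(i) || is.na(j) || j < i)
    stop("invalid quarter window ", from, ":", to, call. = FALSE)
  idx <- i:j
  sprintf("%04dQ%d", idx %/% 4L, idx %% 4L + 1L)
}

# --- deterministic global structure -----------------------------------------

# ICD-like token for global code id k: letter + 2 digits + "." + digit.
code_label <- function(k) {
  k0 <- k - 1L
  paste0(LETTERS[k0 %/% 1000L + 1L],
         sprintf("%02d", (k0 %% 1000L) %/% 10L), ".", k0 %% 10L)
}

# Fixed per-config disease attributes (no randomness: closed-form marginals
# below depend on these).
disease_table <- function(cfg) {
  d <- seq_len(cfg$n_diseases)
  log_sev <- if (cfg$n_diseases == 1L) 0 else
    seq(-0.5, 0.5, length.out = cfg$n_diseases)
  age_mean <- if (cfg$n_diseases == 1L) 45 else
    seq(12, 78, length.out = cfg$n_diseases)
  female_only <- rep(FALSE, cfg$n_diseases)
  if (cfg$n_diseases >= 2L) {     # a pregnancy-like, almost exclusively
    female_only[2L] <- TRUE       # female cluster for cohort analyses
    age_mean[2L] <- 30
  }
  prevalence <- d^-0.8
  prevalence <- prevalence / sum(prevalence)
  codes <- lapply(d, function(di)
    code_label((di - 1L) * cfg$codes_per_disease + seq_len(cfg$codes_per_disease)))
  list(id = d, log_sev = log_sev, age_mean = age_mean,
       female_only = female_only, prevalence = prevalence, codes = codes,
       background = if (cfg$n_background_codes > 0L)
         code_label(cfg$n_diseases * cfg$codes_per_disease +
                      seq_len(cfg$n_background_codes)) else character(0))
}

# Enumerate all latent disease sets of size 1..3 with their exact selection
# probabilities: size Zipf-weighted (1, 1/2, 1/3), diseases drawn sequentially
# without replacement proportional to prevalence.
disease_set_table <- function(cfg) {
  dt <- disease_table(cfg)
  D <- cfg$n_diseases
  kmax <- min(3L, D)
  pk <- (1 / seq_len(kmax)); pk <- pk / sum(pk)
  sets <- list(); probs <- numeric(0)
  add <- function(ids, p) {
    key <- paste(sort(ids), collapse = ",")
    i <- match(key, vapply(sets, function(s) paste(sort(s), collapse = ","), ""))
    if (is.na(i)) { sets[[length(sets) + 1L]] <<- sort(ids); probs[length(probs) + 1L] <<- p }
    else probs[i] <<- probs[i] + p
  }
  w <- dt$prevalence
  for (a in seq_len(D)) {
    pa <- w[a] / sum(w)
    add(a, pk[1] * pa)
    if (kmax >= 2L) for (b in seq_len(D)[-a]) {
      pb <- pa * w[b] / (sum(w) - w[a])
      add(c(a, b), pk[2] * pb)
      if (kmax >= 3L) for (cc in seq_len(D)[-c(a, b)]) {
        pc <- pb * w[cc] / (sum(w) - w[a] - w[b])
        add(c(a, b, cc), pk[3] * pc)
      }
    }
  }
  list(sets = sets, probs = probs, disease = dt)
}

# Per-set log-severity mean; sd is a fixed simulator constant.
SEV_SD <- 0.4
EMERGENCY_BETA <- 0.8
set_logsev_mean <- function(dt, ids) mean(dt$log_sev[ids]) + 0.15 * (length(ids) - 1)

# Population mean/sd of log severity implied by the set mixture.
logsev_moments <- function(st) {
  mu <- vapply(st$sets, function(s) set_logsev_mean(st$disease, s), 0)
  m0 <- sum(st$probs * mu)
  v0 <- sum(st$probs * (mu^2 + SEV_SD^2)) - m0^2
  c(mean = m0, sd = sqrt(v0))
}

#' Closed-form marginals of the simulator
#'
#' `expected_code_distribution()` returns the exact per-entry probability of
#' each diagnosis code implied by a [sim_config()] (mixing over latent
#' disease sets); `emergency_marginal()` returns the exact population
#' emergency probability (integrating the severity-dependent logit over the
#' latent severity mixture). Both are the analytic counterparts used to test
#' the Monte-Carlo generator.
#'
#' @param config a [sim_config()].
#' @return `expected_code_distribution()`: data.frame with columns `code`,
#'   `prob` (summing to 1); `emergency_marginal()`: a single probability.
#' @export
expected_code_distribution <- function(config) {
  st <- disease_set_table(config)
  dt <- st$disease
  zipf <- function(n) { w <- seq_len(n)^-config$zipf_exponent; w / sum(w) }
  wz <- zipf(config$codes_per_disease)
  probs <- setNames(numeric(0), character(0))
  for (i in seq_along(st$sets)) {
    S <- st$sets[[i]]
    for (d in S) {
      p <- (1 - config$p_background) * st$probs[i] * (1 / length(S)) * wz
      codes <- dt$codes[[d]]
      for (j in seq_along(codes))
        probs[codes[j]] <- (if (codes[j] %in% names(probs)) probs[codes[j]] else 0) + p[j]
    }
  }
  if (config$n_background_codes > 0L) {
    wb <- zipf(config$n_background_codes) * config$p_background
    for (j in seq_along(dt$background))
      probs[dt$background[j]] <- wb[j]
  }
  data.frame(code = names(probs), prob = unname(probs),
             stringsAsFactors = FALSE)
}

#' @rdname expected_code_distribution
#' @export
emergency_marginal <- function(config) {
  st <- disease_set_table(config)
  mom <- logsev_moments(st)
  b0 <- qlogis(config$emergency_base_rate)
  total <- 0
  for (i in seq_along(st$sets)) {
    mu <- set_logsev_mean(st$disease, st$sets[[i]])
    f <- function(z) plogis(b0 + EMERGENCY_BETA * (z - mom["mean"]) / mom["sd"]) *
      dnorm(z, mu, SEV_SD)
    total <- total + st$probs[i] *
      integrate(f, mu - 8 * SEV_SD, mu + 8 * SEV_SD)$value
  }
  total
}

# --- cohort generation ------------------------------------------------------

#' Generate a synthetic claims cohort
#'
#' Simulates `config$n_patients` patients. Each patient draws 1-3 latent
#' diseases (Zipf-weighted so clusters overlap), a log-normal severity around
#' the disease mix, and a quarterly stream of diagnosis entries grouped into
#' billing cases at places of treatment. Codes come from the patient's
#' disease-specific pools plus shared background codes, both with power-law
#' within-pool frequencies. Outcomes are coupled to severity: number of
#' cases is negative-binomial with mean increasing in severity, emergency is
#' Bernoulli with a logit increasing in severity, drug cost is zero-inflated
#' log-normal scaled by severity; age and gender depend on the disease mix
#' (one cluster is female-only). A small fraction of entries is flagged
#' non-confirmed. The function is a pure function of its config: identical
#' configs give identical cohorts.
#'
#' @param config a [sim_config()].
#' @return list with class `patvec_cohort`: `claims` (data.frame: patient_id,
#'   quarter, case_id, place_id, code, confirmed), `outcomes` (data.frame:
#'   patient_id, age, gender (1 = female), n_cases, emergency, drug_cost)
#'   and `latent` (data.frame: patient_id, disease_ids (comma-separated),
#'   severity) as ground truth for parameter-recovery tests.
#' @examples
#' cohort <- generate_cohort(sim_config(n_patients = 50, seed = 7))
#' head(cohort$claims)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  st <- disease_set_table(config)
  dt <- st$disease
  mom <- logsev_moments(st)
  kmax <- min(3L, config$n_diseases)
  pk <- (1 / seq_len(kmax)); pk <- pk / sum(pk)
  zipf <- function(n) { w <- seq_len(n)^-config$zipf_exponent; w / sum(w) }
  wz <- zipf(config$codes_per_disease)
  wb <- if (config$n_background_codes > 0L) zipf(config$n_background_codes) else numeric(0)
  nq <- length(config$quarters)
  b0 <- qlogis(config$emergency_base_rate)

  pts <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    pts[[i]] <- with_local_seed(mix_seed(config$seed, 7919L, i), {
      pid <- sprintf("P%06d", i)
      ndis <- sample.int(kmax, 1L, prob = pk)
      dis <- sort(sample.int(config$n_diseases, ndis, prob = dt$prevalence))
      z <- rnorm(1, set_logsev_mean(dt, dis), SEV_SD)
      zc <- (z - mom["mean"]) / mom["sd"]
      severity <- exp(z)

      # outcomes
      agem <- mean(dt$age_mean[dis])
      age <- min(100L, max(0L, as.integer(round(agem + rnorm(1, 0, 10)))))
      pfem <- if (any(dt$female_only[dis])) 0.98 else 0.5
      gender <- rbinom(1, 1, pfem)
      n_cases <- rnbinom(1, size = 3, mu = exp(log(6) + 0.5 * zc))
      emergency <- rbinom(1, 1, plogis(b0 + EMERGENCY_BETA * zc))
      drug_cost <- if (runif(1) < config$zero_cost_fraction) 0 else
        round(rlnorm(1, meanlog = 5 + 0.6 * zc, sdlog = 1), 2)

      # diagnosis entries
      n_entries <- 1L + rpois(1, max(0, (config$mean_entries_per_patient - 1) *
                                       exp(0.3 * zc)))
      own_codes <- unlist(dt$codes[dis], use.names = FALSE)
      own_w <- rep(wz, length(dis)) / length(dis)
      from_bg <- runif(n_entries) < config$p_background
      codes <- character(n_entries)
      if (any(!from_bg))
        codes[!from_bg] <- own_codes[sample.int(length(own_codes), sum(!from_bg),
                                                replace = TRUE, prob = own_w)]
      if (any(from_bg))
        codes[from_bg] <- dt$background[sample.int(length(wb), sum(from_bg),
                                                   replace = TRUE, prob = wb)]
      q <- config$quarters[sample.int(nq, n_entries, replace = TRUE)]
      # cases: per occupied quarter, 1 + Poisson(0.7) cases at random places
      case_id <- character(n_entries); place_id <- character(n_entries)
      for (qq in unique(q)) {
        sel <- which(q == qq)
        ncase <- 1L + rpois(1, 0.7)
        case_of <- sample.int(ncase, length(sel), replace = TRUE)
        places <- sprintf("S%03d", sample.int(500L, ncase, replace = TRUE))
        case_id[sel] <- sprintf("%s-%s-C%d", pid, qq, case_of)
        place_id[sel] <- places[case_of]
      }
      confirmed <- runif(n_entries) >= config$nonconfirmed_rate
      if (!any(confirmed)) confirmed[1L] <- TRUE

      list(claims = data.frame(patient_id = pid, quarter = q,
                               case_id = case_id, place_id = place_id,
                               code = codes, confirmed = confirmed,
                               stringsAsFactors = FALSE),
           outcomes = data.frame(patient_id = pid, age = age, gender = gender,
                                 n_cases = n_cases, emergency = emergency,
                                 drug_cost = drug_cost,
                                 stringsAsFactors = FALSE),
           latent = data.frame(patient_id = pid,
                               disease_ids = paste(dis, collapse = ","),
                               severity = severity, stringsAsFactors = FALSE))
    })
  }
  out <- list(claims = do.call(rbind, lapply(pts, `[[`, "claims")),
              outcomes = do.call(rbind, lapply(pts, `[[`, "outcomes")),
              latent = do.call(rbind, lapply(pts, `[[`, "latent")),
              config = config)
  rownames(out$claims) <- rownames(out$outcomes) <- rownames(out$latent) <- NULL
  class(out) <- "patvec_cohort"
  out
}

#' @export
print.patvec_cohort <- function(x, ...) {
  cat(sprintf("Synthetic claims cohort: %d patients, %d diagnosis entries (%.1f%% confirmed)\n",
              nrow(x$outcomes), nrow(x$claims),
              100 * mean(x$claims$confirmed)))
  cat(sprintf("  distinct codes: %d; quarters %s..%s\n",
              length(unique(x$claims$code)),
              min(x$claims$quarter), max(x$claims$quarter)))
  invisible(x)
}

#' Write / read a cohort as plain CSV files
#'
#' `write_cohort()` writes `claims.csv`, `outcomes.csv` and (if present)
#' `latent.csv` into `dir`; `read_claims()` / `read_outcomes()` read them
#' back with the schema checked.
#'
#' @param cohort a `patvec_cohort` (or a list with `claims`/`outcomes`).
#' @param dir output directory (created if missing).
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(cohort$claims, file.path(dir, "claims.csv"), row.names = FALSE)
  write.csv(cohort$outcomes, file.path(dir, "outcomes.csv"), row.names = FALSE)
  if (!is.null(cohort$latent))
    write.csv(cohort$latent, file.path(dir, "latent.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @param path path to a claims.csv / outcomes.csv file.
#' @export
read_claims <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "quarter", "case_id", "place_id", "code", "confirmed")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("claims file lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  x$confirmed <- as.logical(x$confirmed)
  x
}

#' @rdname write_cohort
#' @export
read_outcomes <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "age", "gender", "n_cases", "emergency", "drug_cost")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("outcomes file lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  x
}
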