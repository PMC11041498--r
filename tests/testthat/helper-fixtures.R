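# Shared fixtures, built once per test run and cached in this environment.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Small general-purpose cohort (fast; most structural tests).
small_cohort <- function() fixture("small_cohort", function()
  generate_cohort(sim_config(n_patients = 300, seed = 42)))

# Two well-separated latent diseases, no background codes: the cleanest
# setting for embedding-geometry tests.
two_disease_cohort <- function() fixture("two_disease_cohort", function()
  generate_cohort(sim_config(n_patients = 1500, n_diseases = 2,
                             n_background_codes = 0, seed = 9)))

two_disease_fit <- function() fixture("two_disease_fit", function()
  patvec(two_disease_cohort(),
         patvec_params(vector_size = 16, epochs = 5, min_count = 5,
                       negative = 5, alpha = 0.025, window = 5,
                       static_documents = TRUE)))

# Tiny hand-written claims table (3 patients / 4 codes).
toy_claims <- function() data.frame(
  patient_id = c("P1", "P1", "P1", "P2", "P3", "P3"),
  quarter = "2018Q1",
  case_id = c("c1", "c1", "c2", "c3", "c4", "c4"),
  place_id = "s1",
  code = c("a", "a", "b", "a", "b", "c"),
  confirmed = TRUE,
  stringsAsFactors = FALSE)

# Minimal vocabulary straight from counts (bypasses corpus building).
vocab_from_counts <- function(counts) {
  ord <- order(-counts, names(counts))
  structure(list(token = names(counts)[ord],
                 count = as.integer(counts[ord]),
                 index = seq_along(counts) - 1L,
                 min_count = 1L,
                 total_kept_tokens = sum(counts)),
            class = "patvec_vocab")
}

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# Mean pairwise cosine gap between within-disease and between-disease code
# vector pairs, given the simulator's ground-truth code pools.
code_cosine_gap <- function(fit, config) {
  dt <- patvec:::disease_table(config)
  cv <- coef(fit)
  cv <- cv / sqrt(rowSums(cv^2))
  grp <- rep(NA_integer_, nrow(cv))
  for (d in seq_along(dt$codes)) grp[rownames(cv) %in% dt$codes[[d]]] <- d
  keep <- !is.na(grp)
  S <- tcrossprod(cv[keep, , drop = FALSE])
  g <- grp[keep]
  same <- outer(g, g, "==")
  diag(S) <- NA
  mean(S[same], na.rm = TRUE) - mean(S[!same], na.rm = TRUE)
}
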