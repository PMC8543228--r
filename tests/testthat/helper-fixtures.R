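# In-code fixtures shared across tests.

# a minimal study_fit with given coefficients/covariance, as produced by
# the federation exchange (no subject-level fit object)
mk_fit <- function(gamma, vcov, study = "s", device = "hip",
                   measures_sleep = FALSE, n = 1000, n_events = 100) {
  if (is.null(dim(vcov))) vcov <- diag(vcov, length(gamma))
  dimnames(vcov) <- list(names(gamma), names(gamma))
  structure(list(study = study, device = device,
                 measures_sleep = measures_sleep, n = n,
                 n_events = n_events, gamma = gamma, beta = numeric(0),
                 vcov_gamma = vcov, vcov = NULL, fit = NULL),
            class = "study_fit")
}

# random strictly-positive compositions (rows), reproducible
rand_comps <- function(n, parts = 3, seed = 1, total = 960) {
  set.seed(seed)
  x <- matrix(exp(rnorm(n * parts, sd = 1)), n)
  colnames(x) <- if (parts == 4) c("sleep", "mvpa", "lipa", "sb")
                 else c("mvpa", "lipa", "sb")
  x * (total / rowSums(x))
}

# a small cohort with prescribed follow-up/event pattern and mild
# composition variation
mk_cohort <- function(followup, event, seed = 1, device = "hip") {
  n <- length(followup)
  comp <- rand_comps(n, 3, seed = seed)
  cohort(data.frame(id = as.character(seq_len(n)),
                    mvpa = comp[, "mvpa"], lipa = comp[, "lipa"],
                    sb = comp[, "sb"], followup = followup,
                    event = event, x = rnorm(n)),
         study = "toy", device = device)
}

hip_model <- function() published_pooled_model("hip")
wrist_model <- function() published_pooled_model("wrist")
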