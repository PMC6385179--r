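# Independent oracles used across tests. These deliberately avoid the
# package's closed-form code paths.

# brute-force superposition of `ndose` individual infusions (no geometric
# closed form); ndose large enough that the system is at steady state
oracle_superposition <- function(t, regimen, pk, ndose = 400) {
  k <- pk$clearance / pk$volume
  r0 <- regimen$dose / regimen$infusion_duration
  tinf <- regimen$infusion_duration
  out <- 0
  for (m in 0:(ndose - 1)) {
    tp <- t + m * regimen$interval_tau
    out <- out + r0 / (k * pk$volume) *
      (1 - exp(-k * pmin(tp, tinf))) * exp(-k * pmax(0, tp - tinf))
  }
  out
}

# fraction of the interval above mic by dense grid counting
oracle_fraction_above <- function(regimen, pk, mic, n_grid = 20000) {
  tt <- seq(0, regimen$interval_tau, length.out = n_grid + 1)[-(n_grid + 1)]
  mean(oracle_superposition(tt, regimen, pk) > mic)
}

# random but physiologically plausible regimen + PK pair
random_regimen_pk <- function() {
  tau <- sample(c(6, 8, 12), 1)
  reg <- drug_regimen("drug", sample(c("carbapenem", "penicillin",
                                       "cephalosporin"), 1),
                      dose = runif(1, 500, 4000),
                      infusion_duration = runif(1, 0.25, 2),
                      interval_tau = tau)
  pk <- pk_parameters(rlnorm(1, log(9), 0.4), rlnorm(1, log(18), 0.3))
  list(regimen = reg, pk = pk)
}

# per-group within sum of squares straight from the definition
oracle_ss_within <- function(dmat, labels) {
  s <- 0
  for (g in unique(labels)) {
    i <- which(labels == g)
    s <- s + sum(dmat[i, i]^2) / (2 * length(i))
  }
  s
}

oracle_pseudo_f <- function(dmat, labels) {
  n <- nrow(dmat)
  g <- length(unique(labels))
  sst <- sum(dmat^2) / (2 * n)
  ssw <- oracle_ss_within(dmat, labels)
  ((sst - ssw) / (g - 1)) / (ssw / (n - g))
}

# random count matrix with named samples/taxa
random_count_table <- function(n_samples = 12, n_taxa = 20, lambda = 8) {
  m <- matrix(rpois(n_samples * n_taxa, lambda), n_samples,
              dimnames = list(paste0("s", seq_len(n_samples)),
                              paste0("t", seq_len(n_taxa))))
  m
}
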