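# Shared fixtures: small parameter sets and designs used across tests.

bci_params <- function(p_common = 0.6, sigma_a = 4.5, sigma_v = 1.5,
                       sigma_p = 12) {
  observer_params("BCI-att_fixed", sigma_a = sigma_a, sigma_v = sigma_v,
                  sigma_p = sigma_p, p_common = p_common)
}

bci_att_params <- function() {
  observer_params("BCI-att_free",
    sigma_a = c(attA = 4.5, attV = 6), sigma_v = c(attA = 1.5, attV = 1.1),
    sigma_p = 12, p_common = 0.6
  )
}

ff_params <- function(sigma_a = 4.5, sigma_v = 1.5, sigma_p = 12) {
  observer_params("FF-att_fixed-rep_fixed", sigma_a = sigma_a,
                  sigma_v = sigma_v, sigma_p = sigma_p)
}

tiny_spec <- function(trials = 1, runs = 1, seed = 1) {
  design_spec(n_trials_per_condition = trials, n_runs = runs, seed = seed)
}

# one-condition trial table of arbitrary length
one_condition_trials <- function(n, aloc, vloc, attention = "A",
                                 report = "A") {
  tibble::tibble(
    participant = 1L, run = 1L, trial = seq_len(n),
    aloc = aloc, vloc = vloc, attention = attention, report = report,
    valid = attention == report, response = NA_real_
  )
}
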