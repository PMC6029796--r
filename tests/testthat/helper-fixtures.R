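# Published ledger figures used by the reproduction tests (AU$/yr).
published_ledger <- list(
  A1 = 439237, A2 = 48879, A = 488116,
  B1a = -790746, B1b = -2238554, B1 = -3029300,
  B2a = -3936270, B2b = -1588221, B2 = -5524491,
  B3 = -105997, B = -8659788, C = -8171671)

published_psa <- list(mean = -8444512, median = -8202676, sd = 2955346,
                    p2.5 = -15018055, p97.5 = -3358820)

# brute-force annuity oracle: sum of discounted unit payments
af_brute <- function(life, rate) {
  if (rate == 0) return(life)
  sum((1 + rate)^-(seq_len(life)))
}

rel_err <- function(x, ref) abs(x - ref) / abs(ref)

# a small catchment keeps per-test generation cheap
small_config <- function(seed = 42, ...) {
  generator_config(beds_per_catchment = 600, seed = seed, ...)
}

# minimal PSA-result shell for testing the variance attribution on
# analytically known toys
toy_psa_result <- function(draws, inputs) {
  structure(list(draws = draws, inputs = inputs), class = "hinh_psa_result")
}
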