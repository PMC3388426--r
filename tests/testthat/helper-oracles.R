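# Independent oracle for the annuity: the explicit discounted sum over whole
# years, never the closed form under test.
pv_oracle <- function(S, r, t) {
  stopifnot(t == round(t))
  if (t == 0) return(0)
  sum(S * (1 + r)^-(seq_len(t)))
}

# A records fixture with known composition: ages given explicitly.
records_of_ages <- function(ages) mortality_records(age = ages)

fiji_params <- function(...) economic_params(...)
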