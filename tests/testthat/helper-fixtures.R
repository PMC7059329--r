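# Shared fixture builders. Everything is generated in code at test time.

# Small separable synthetic feature table (continuous + bits).
make_sep_table <- function(n1 = 100, n0 = 100, d = 3, seed = 1) {
  gen_feature_table(synthetic_spec(
    n_inhibitors = n1, n_noninhibitors = n0,
    n_informative_continuous = 4, n_noise_continuous = 6,
    n_fingerprint_bits = 8, effect_size = d,
    bit_rate_inhibitor = 0.7, bit_rate_noninhibitor = 0.3, seed = seed))
}

# Exhaustive pair-counting AUC oracle (midrank ties).
auc_oracle <- function(y, p) {
  pos <- p[y == 1]
  neg <- p[y == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# Direct-formula metric oracles on plain arithmetic.
mcc_oracle <- function(tp, tn, fp, fn) {
  den <- sqrt(prod(c(tp + fn, tp + fp, fn + tn, tn + fp)))
  if (den == 0) 0 else (tp * tn - fn * fp) / den
}

# Scaffold SMILES used in fragment tests.
QUINAZOLINE <- "c1ccc2ncncc2c1"
MORPHOLINE <- "C1COCCN1"
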