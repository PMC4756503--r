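# internal helpers

# named-vector lookup defaulting to 0 for absent names (a SNP missing
# from a panel contributes nothing to its log odds)
lookup0 <- function(v, nm) {
  out <- unname(v[nm])
  out[is.na(out)] <- 0
  out
}
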