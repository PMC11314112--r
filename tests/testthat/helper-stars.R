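# independent star rule for cross-checking table annotation
significance_stars_ref <- function(p) {
  out <- rep("", length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out
}
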