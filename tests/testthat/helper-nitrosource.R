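# Shared fixtures built in code.

# Minimal valid isotope table around the study's sediment summary values.
make_isotope_table <- function() {
  tibble::tibble(
    sample_id = c("s1", "s2", "s3"),
    sample_type = "sediment",
    d18O = c(4.0, 4.6, 5.2),
    D17O = c(1.1, 1.3, 1.5)
  )
}

# Annotation table in which every default N-cycle process has signal except
# anammox (hzo/hzs all zero) -- the habitat condition the inventory module
# must call out.
make_anammox_free_table <- function(n = 3) {
  genes <- c("nifH", "amoA", "hao", "nxrB", "napA", "narG", "nirS", "nirK",
             "norB", "nosZ", "nrfA", "nasA", "nirA")
  cols <- stats::setNames(lapply(genes, function(g) rep(100, n)), genes)
  tibble::as_tibble(c(
    list(sample_id = sprintf("s%d", seq_len(n))),
    cols,
    list(hzo = rep(0, n), hzs = rep(0, n))
  ))
}

make_profile_pair <- function(shift = 0.01) {
  dens <- seq(1.69, 1.77, by = 0.01)
  ab <- stats::dnorm(dens, 1.72, 0.015)
  list(
    p12 = sip_profile(dens, ab, "12C", 4, "amoA"),
    p13 = sip_profile(dens + shift, ab, "13C", 4, "amoA")
  )
}
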