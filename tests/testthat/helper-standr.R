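# Shared fixtures and independent oracles for the suite.

S3FLAG <- "DYKDHDGDYKDHDIDYKDDDDK"
HA_TAG <- "YPYDVPDYA"

AA20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

random_peptide <- function(len, exclude = character(0)) {
  paste(sample(setdiff(AA20, exclude), len, replace = TRUE), collapse = "")
}

# Independent Henderson-Hasselbalch oracle: residue-by-residue loop, written
# without reference to the package internals.
hh_oracle <- function(seq, ph, n_term = TRUE, c_term = TRUE) {
  pka <- c(D = 4.4, E = 4.4, H = 6.5, C = 8.5, Y = 10, K = 10, R = 12)
  acid <- c("D", "E", "C", "Y")
  q <- 0
  for (aa in strsplit(seq, "")[[1]]) {
    if (!aa %in% names(pka)) next
    q <- q + if (aa %in% acid) -1 / (1 + 10^(pka[[aa]] - ph))
             else 1 / (1 + 10^(ph - pka[[aa]]))
  }
  if (n_term) q <- q + 1 / (1 + 10^(ph - 8.0))
  if (c_term) q <- q - 1 / (1 + 10^(3.1 - ph))
  q
}

# Exhaustive grid-scan pI oracle: pH of minimal |net charge| on a 1e-3 grid.
grid_pi <- function(seq, n_term = TRUE, c_term = TRUE) {
  grid <- seq(0, 14, by = 1e-3)
  q <- net_charge(seq, grid, n_term = n_term, c_term = c_term)
  grid[which.min(abs(q))]
}
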