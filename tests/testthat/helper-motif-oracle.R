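# Brute-force motif oracle: position-by-position check against hand-parsed
# pattern semantics (list of allowed-character vectors, NULL = any
# residue). Independent of the package's regex-based scanner.

RNP1_POSITIONS <- list(c("R", "K"), "G", c("F", "Y"), c("G", "A"),
                       c("F", "Y"), c("I", "L", "V", "M"), NULL, c("F", "Y"))
RNP2_POSITIONS <- list(c("I", "L", "V", "M"), c("F", "Y"),
                       c("I", "L", "V", "M"), NULL, "N", "L")

scan_oracle <- function(sequence, positions) {
  chars <- strsplit(sequence, "")[[1]]
  w <- length(positions)
  starts <- integer(0)
  if (length(chars) >= w) {
    for (s in seq_len(length(chars) - w + 1)) {
      ok <- TRUE
      for (i in seq_len(w)) {
        allowed <- positions[[i]]
        if (!is.null(allowed) && !(chars[s + i - 1] %in% allowed)) {
          ok <- FALSE
          break
        }
      }
      if (ok) starts <- c(starts, s - 1L)  # 0-based
    }
  }
  starts
}

random_aa <- function(len, x_frac = 0.05) {
  letters20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  paste(sample(c(letters20, if (x_frac > 0) "X"), len, replace = TRUE,
               prob = c(rep((1 - x_frac) / 20, 20), if (x_frac > 0) x_frac)),
        collapse = "")
}
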