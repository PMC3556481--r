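# Independent oracles, coded separately from the package implementation.

# Brute-force glycoform enumeration: iterate every integer 1..k^n - 1 and
# write its base-k digits (site 1 most significant). Returns a character set
# of digit strings for order-independent comparison.
oracle_enumerate <- function(n, k) {
  out <- character(k^n - 1)
  for (i in seq_len(k^n - 1)) {
    digits <- integer(n)
    x <- i
    for (j in n:1) {
      digits[j] <- x %% k
      x <- x %/% k
    }
    out[i] <- paste(digits, collapse = "")
  }
  out
}

# state-vector key of a glycoform, comparable to oracle_enumerate() output
glycoform_key <- function(gf) paste(gf$states, collapse = "")

# Independent monoisotopic residue masses (literature values, 6 dp),
# NOT derived from the package's atomic-mass tables.
ORACLE_RESIDUE_MONO <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047679, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)
ORACLE_WATER_MONO <- 18.0105646
ORACLE_HEXNAC <- 203.079373   # HexNAc residue, C8H13NO5
ORACLE_NEUAC <- 291.095417    # NeuAc residue, C11H17NO8

oracle_peptide_mass <- function(seq) {
  sum(ORACLE_RESIDUE_MONO[strsplit(seq, "")[[1]]]) + ORACLE_WATER_MONO
}

# random valid epitope for property tests: peptide with >= 1 S/T, a random
# subset of its S/T positions annotated with random alphabet states
random_epitope <- function(alphabet = alphabet_tn_stn()) {
  len <- sample(5:25, 1)
  repeat {
    pep <- paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N",
                          "P","Q","R","S","T","V","W","Y"),
                        len, replace = TRUE), collapse = "")
    st <- identify_glycosites(pep)
    if (nrow(st) > 0) break
  }
  n_ann <- sample.int(nrow(st), 1)
  pos <- sort(st$position[sample.int(nrow(st), n_ann)])
  states <- sample(state_names(alphabet)[-1], n_ann, replace = TRUE)
  epitope(pep, stats::setNames(states, pos))
}
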