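# Exhaustive enumeration of glycoforms: every base-k state vector over the
# n glycosylation sites of a repeat unit, excluding the all-zero (unmodified)
# vector. For the 5-site MUC1 unit this yields the 31 binary (Tn) and 242
# ternary (Tn / sialyl-Tn) glycoforms.

#' Locate candidate O-glycosylation sites
#'
#' Scans a peptide for serine and threonine residues, the attachment points
#' of mucin-type O-glycans.
#'
#' @param seq peptide sequence (one-letter codes)
#' @return data.frame with columns `position` (1-based, ascending) and
#'   `residue` ("S" or "T"); zero rows when the sequence has no S/T
#' @examples
#' identify_glycosites("RPAPGSTAPPAHGVTSAPDT")  # positions 6,7,15,16,20
#' @export
identify_glycosites <- function(seq) {
  validate_peptide(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- which(chars %in% c("S", "T"))
  data.frame(position = pos, residue = chars[pos], stringsAsFactors = FALSE)
}

#' Enumerate all glycoforms over a set of sites
#'
#' Generates every assignment of alphabet states to the n sites — all k^n
#' base-k digit vectors — and drops the all-zero vector, giving k^n - 1
#' glycoforms. Two orderings are supported:
#' \describe{
#'   \item{`"occupancy"`}{ascending number of occupied sites, ties broken
#'     lexicographically by state vector with site 1 most significant
#'     (the default; groups glycoforms by how many glycans they carry)}
#'   \item{`"counter"`}{plain base-k integer order, site 1 most significant —
#'     the literal digit-counting construction}
#' }
#' Counts and set membership are identical under both orders.
#'
#' A size guard refuses enumerations above `max_bits` total bits
#' (n_sites * log2(k), default 20, i.e. about 10^6 glycoforms) or with more
#' than `max_states` states per site, to prevent accidental combinatorial
#' explosion.
#'
#' @param sites glycosite data.frame ([identify_glycosites()]), a peptide
#'   string to scan, or a plain site count
#' @param alphabet a `glycan_alphabet` (default binary Tn)
#' @param order enumeration ordering policy
#' @param include_unmodified also include the all-zero glycoform (the naked
#'   peptide), first in the output; excluded by default
#' @param max_bits,max_states size-guard configuration
#' @return list of `glycoform` objects
#' @examples
#' sites <- identify_glycosites(muc1_unit())
#' length(enumerate_glycoforms(sites, alphabet_tn()))      # 31
#' length(enumerate_glycoforms(sites, alphabet_tn_stn()))  # 242
#' @export
enumerate_glycoforms <- function(sites, alphabet = alphabet_tn(),
                                 order = c("occupancy", "counter"),
                                 include_unmodified = FALSE,
                                 max_bits = 20, max_states = 5) {
  order <- match.arg(order)
  sites <- as_glycosites(sites)
  n <- nrow(sites)
  if (n < 1L) stop_validation("need at least one glycosylation site to enumerate")
  if (!inherits(alphabet, "glycan_alphabet")) {
    stop_validation("`alphabet` must be a glycan_alphabet")
  }
  k <- n_states(alphabet)
  if (k > max_states) {
    stop_validation("alphabet has %d states, above the size guard max_states = %d",
                    k, max_states)
  }
  bits <- n * log2(k)
  if (bits > max_bits) {
    stop_validation(
      "enumeration of %d sites x %d states spans %.1f bits (%.3g glycoforms), above the size guard max_bits = %s; raise `max_bits` deliberately if this is intended",
      n, k, bits, k^n, format(max_bits))
  }

  total <- k^n
  idx <- if (include_unmodified) 0:(total - 1) else 1:(total - 1)
  # digit j of i in base k, site 1 most significant
  mat <- matrix(0L, nrow = length(idx), ncol = n)
  for (j in seq_len(n)) {
    mat[, j] <- as.integer((idx %/% k^(n - j)) %% k)
  }
  if (order == "occupancy") {
    ord <- order(rowSums(mat > 0L), idx)
    mat <- mat[ord, , drop = FALSE]
  }
  lapply(seq_len(nrow(mat)), function(i) {
    glycoform(sites, mat[i, ], alphabet)
  })
}

#' Count positional isomers at a given occupancy
#'
#' Number of distinct glycoforms carrying exactly `m` glycans on `n_sites`
#' sites with a k-state alphabet: choose(n, m) * (k-1)^m. For the binary case
#' this is the binomial coefficient — 5, 10, 10, 5, 1 for one to five GalNAc
#' residues on the 5-site MUC1 repeat.
#'
#' @param n_sites number of glycosylation sites
#' @param m occupancy, 0 <= m <= n_sites
#' @param k alphabet size including UNOCCUPIED (default 2, binary)
#' @return integer count
#' @export
count_isomers <- function(n_sites, m, k = 2) {
  if (!is.numeric(n_sites) || n_sites < 1 || n_sites != as.integer(n_sites)) {
    stop_validation("`n_sites` must be a positive integer")
  }
  if (!is.numeric(k) || k < 2 || k != as.integer(k)) {
    stop_validation("`k` must be an integer >= 2")
  }
  if (!is.numeric(m) || any(m != as.integer(m)) || any(m < 0) ||
      any(m > n_sites)) {
    stop_validation("occupancy `m` must be an integer in [0, %d]", n_sites)
  }
  choose(n_sites, m) * (k - 1)^m
}

#' Build the sites x glycoforms occupancy matrix
#'
#' Stacks the state vectors of enumerated glycoforms column-wise: rows are
#' glycosylation sites, column j is glycoform j. The 31 binary glycoforms of
#' the 5-site MUC1 repeat give the 5 x 31 matrix; the ternary enumeration
#' gives 5 x 242.
#'
#' @param glycoforms non-empty list of `glycoform` objects over identical
#'   site lists and alphabets
#' @return integer matrix (n_sites x n_glycoforms) with rownames
#'   `"<residue><position>"`; the alphabet's state names are attached as
#'   attribute `state_names`
#' @export
occupancy_matrix <- function(glycoforms) {
  if (!is.list(glycoforms) || length(glycoforms) == 0L ||
      !all(vapply(glycoforms, inherits, logical(1L), what = "glycoform"))) {
    stop_validation("`glycoforms` must be a non-empty list of glycoform objects")
  }
  ref <- glycoforms[[1L]]
  same <- vapply(glycoforms, function(g) {
    identical(g$sites, ref$sites) &&
      identical(state_names(g$alphabet), state_names(ref$alphabet))
  }, logical(1L))
  if (!all(same)) {
    stop_validation("glycoforms have heterogeneous site lists or alphabets; cannot stack")
  }
  m <- vapply(glycoforms, function(g) g$states,
              integer(nrow(ref$sites)))
  m <- matrix(as.integer(m), nrow = nrow(ref$sites),
              dimnames = list(paste0(ref$sites$residue, ref$sites$position),
                              NULL))
  if (anyDuplicated(apply(m, 2L, paste, collapse = ","))) {
    stop_validation("duplicate glycoform columns in occupancy matrix")
  }
  attr(m, "state_names") <- state_names(ref$alphabet)
  m
}

#' Convert glycoforms to a long-format table
#'
#' One row per (glycoform, site) pair, suitable for CSV export and plotting.
#'
#' @param glycoforms list of `glycoform` objects (homogeneous sites/alphabet)
#' @return data.frame with columns `glycoform_id`, `site_position`,
#'   `site_residue`, `state`, `state_name`
#' @export
glycoforms_to_table <- function(glycoforms) {
  m <- occupancy_matrix(glycoforms)
  ref <- glycoforms[[1L]]
  nms <- state_names(ref$alphabet)
  data.frame(
    glycoform_id = rep(seq_len(ncol(m)), each = nrow(m)),
    site_position = rep(ref$sites$position, times = ncol(m)),
    site_residue = rep(ref$sites$residue, times = ncol(m)),
    state = as.integer(m),
    state_name = nms[as.integer(m) + 1L],
    stringsAsFactors = FALSE
  )
}
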