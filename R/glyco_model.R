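# Domain model: peptides, tandem-repeat proteins, glycosylation sites,
# glycans and glycan alphabets, glycoforms.
#
# Conventions used throughout the package:
#   * all user-facing coordinates are 1-based and inclusive;
#   * the unoccupied site is alphabet state 0, so a glycoform is exactly a
#     base-k digit vector over the sites (k = number of alphabet states);
#   * a composite glycan such as sialyl-Tn (NeuAc-GalNAc) is ONE alphabet
#     state, a single attached (oligo)saccharide.

#' The twenty one-letter amino-acid codes
#' @keywords internal
AA_CODES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Validate a peptide sequence
#'
#' Checks that `residues` is a single uppercase string over the 20 one-letter
#' amino-acid codes. The error names the first offending character and its
#' 1-based position (and the record id, when given), so FASTA-level problems
#' are traceable.
#'
#' @param residues character scalar, the sequence
#' @param id optional label used in error messages
#' @param allow_empty allow the empty string (used for repeat flanks)
#' @return `residues`, invisibly
#' @export
validate_peptide <- function(residues, id = NULL, allow_empty = FALSE) {
  if (!is.character(residues) || length(residues) != 1L || is.na(residues)) {
    stop_validation("peptide sequence must be a single character string")
  }
  n <- nchar(residues)
  if (n == 0L) {
    if (allow_empty) return(invisible(residues))
    stop_validation("peptide sequence%s must have length >= 1",
                    if (is.null(id)) "" else paste0(" '", id, "'"))
  }
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% AA_CODES)
  if (length(bad) > 0L) {
    stop_validation(
      "invalid amino-acid code '%s' at position %d%s",
      chars[bad[1L]], bad[1L],
      if (is.null(id)) "" else paste0(" in record '", id, "'")
    )
  }
  invisible(residues)
}

#' Construct a tandem-repeat protein
#'
#' Models a mucin-like protein as `prefix + unit * copies + suffix`. The MUC1
#' extracellular domain, for example, is a variable number (tens to >100) of
#' copies of a 20-residue unit carrying five potential O-glycosylation sites.
#'
#' @param unit repeat-unit sequence (one-letter codes)
#' @param copies number of tandem copies, >= 1
#' @param prefix,suffix optional flanking sequences (may be empty)
#' @param id optional label
#' @return an object of class `tandem_repeat`
#' @examples
#' p <- make_tandem_repeat("RPAPGSTAPPAHGVTSAPDT", copies = 3)
#' nchar(as.character(p))  # 60
#' @export
make_tandem_repeat <- function(unit, copies, prefix = "", suffix = "",
                               id = NULL) {
  validate_peptide(unit, id = "unit")
  if (!is.numeric(copies) || length(copies) != 1L || is.na(copies) ||
      copies != as.integer(copies) || copies < 1) {
    stop_validation("`copies` must be a single integer >= 1 (got %s)",
                    deparse(copies))
  }
  validate_peptide(prefix, id = "prefix", allow_empty = TRUE)
  validate_peptide(suffix, id = "suffix", allow_empty = TRUE)
  structure(
    list(prefix = prefix, unit = unit, copies = as.integer(copies),
         suffix = suffix, id = id),
    class = "tandem_repeat"
  )
}

#' @export
as.character.tandem_repeat <- function(x, ...) {
  paste0(x$prefix, strrep(x$unit, x$copies), x$suffix)
}

#' @export
print.tandem_repeat <- function(x, ...) {
  cat(sprintf("<tandem_repeat%s> %d x %s (%d aa total)\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              x$copies, x$unit, nchar(as.character(x))))
  invisible(x)
}

#' Re-derive a tandem-repeat decomposition from a plain sequence
#'
#' Inverse of rendering a [make_tandem_repeat()] object to a string: given the
#' full sequence plus the known unit and copy number, recovers the flanks.
#'
#' @param sequence full protein sequence
#' @param unit known repeat unit
#' @param copies known copy number
#' @param id optional label for the result
#' @return a `tandem_repeat` object
#' @export
parse_tandem_repeat <- function(sequence, unit, copies, id = NULL) {
  validate_peptide(sequence)
  validate_peptide(unit)
  block <- strrep(unit, copies)
  at <- regexpr(block, sequence, fixed = TRUE)
  if (at < 0L) {
    stop_validation("sequence does not contain %d consecutive copies of '%s'",
                    copies, unit)
  }
  make_tandem_repeat(
    unit, copies,
    prefix = substr(sequence, 1L, at - 1L),
    suffix = substr(sequence, at + nchar(block), nchar(sequence)),
    id = id
  )
}

# ---------------------------------------------------------------------------
# Glycans and alphabets

#' Define a glycan state
#'
#' A glycan state is a named (oligo)saccharide that can occupy one Ser/Thr
#' site. Its residue mass is the mass ADDED to the peptide on attachment
#' (the condensation water is already accounted for). Masses are computed
#' from the elemental composition whenever a formula is supplied; explicit
#' masses are accepted for states without a defined composition.
#'
#' @param name state name; must not contain whitespace or parentheses
#'   (it appears inside the `(Name)` epitope annotation syntax)
#' @param formula elemental formula, or a character vector of formula parts
#'   that are summed (e.g. `c("C8H13NO5", "C11H17NO8")` for sialyl-Tn)
#' @param mass_mono,mass_avg residue masses in Da; ignored when `formula`
#'   is given
#' @return an object of class `glycan`
#' @examples
#' glycan("GalNAc", "C8H13NO5")
#' @export
glycan <- function(name, formula = NULL, mass_mono = NULL, mass_avg = NULL) {
  if (!is.character(name) || length(name) != 1L || is.na(name) ||
      !nzchar(name) || grepl("[()[:space:]]", name)) {
    stop_validation("glycan name must be a non-empty string without whitespace or parentheses")
  }
  composition <- NULL
  if (!is.null(formula)) {
    composition <- parse_formula(formula)
    mass_mono <- formula_mass(formula, "mono")
    mass_avg <- formula_mass(formula, "avg")
  } else {
    if (is.null(mass_mono)) {
      stop_validation("glycan '%s': supply a formula or a monoisotopic mass", name)
    }
    if (is.null(mass_avg)) mass_avg <- mass_mono
  }
  if (!is.finite(mass_mono) || mass_mono <= 0) {
    stop_validation("glycan '%s': residue mass must be positive", name)
  }
  if (mass_avg < mass_mono - 1) {
    stop_validation("glycan '%s': average mass %.4f implausibly below monoisotopic %.4f",
                    name, mass_avg, mass_mono)
  }
  structure(
    list(name = name,
         formula = if (is.null(formula)) NULL else unname(formula),
         composition = composition,
         mass_mono = mass_mono, mass_avg = mass_avg),
    class = "glycan"
  )
}

#' @export
print.glycan <- function(x, ...) {
  cat(sprintf("<glycan> %s  mono %.4f Da  avg %.4f Da%s\n",
              x$name, x$mass_mono, x$mass_avg,
              if (is.null(x$formula)) "" else
                paste0("  [", paste(x$formula, collapse = " + "), "]")))
  invisible(x)
}

#' Built-in glycan states
#'
#' `glycan_galnac()` is the Tn antigen (a single alpha-GalNAc; HexNAc residue,
#' C8H13NO5). `glycan_neuac_galnac()` is sialyl-Tn (NeuAc alpha2-6 GalNAc,
#' one disaccharide state). `glycan_ac3galnac()` is 3,4,6-tri-O-acetylated
#' GalNAc, the protected synthetic precursor used in binding studies; each
#' acetylation adds C2H2O.
#'
#' @return a `glycan` object
#' @export
glycan_galnac <- function() glycan("GalNAc", "C8H13NO5")

#' @rdname glycan_galnac
#' @export
glycan_neuac_galnac <- function() {
  glycan("NeuAc-GalNAc", c("C8H13NO5", "C11H17NO8"))
}

#' @rdname glycan_galnac
#' @export
glycan_ac3galnac <- function() {
  glycan("Ac3GalNAc", c("C8H13NO5", "C2H2O", "C2H2O", "C2H2O"))
}

#' Construct a glycan alphabet
#'
#' The ordered set of states available at each glycosylation site. State 0 is
#' always UNOCCUPIED, so an alphabet of k states encodes every site as a
#' base-k digit: the binary Tn case is \[UNOCCUPIED, GalNAc\], the ternary
#' Tn/sialyl-Tn case \[UNOCCUPIED, GalNAc, NeuAc-GalNAc\].
#'
#' @param ... `glycan` objects (states 1..k-1, in digit order)
#' @return an object of class `glycan_alphabet`
#' @export
glycan_alphabet <- function(...) {
  glycans <- list(...)
  if (length(glycans) == 1L && is.list(glycans[[1L]]) &&
      !inherits(glycans[[1L]], "glycan")) {
    glycans <- glycans[[1L]]
  }
  if (length(glycans) < 1L) {
    stop_validation("a glycan alphabet needs at least one glycan state besides UNOCCUPIED")
  }
  ok <- vapply(glycans, inherits, logical(1L), what = "glycan")
  if (!all(ok)) stop_validation("all alphabet states must be `glycan` objects")
  nms <- vapply(glycans, function(g) g$name, character(1L))
  if (anyDuplicated(c("UNOCCUPIED", nms))) {
    stop_validation("glycan names within an alphabet must be unique")
  }
  structure(
    list(states = c(list(NULL), glycans),
         names = c("UNOCCUPIED", nms)),
    class = "glycan_alphabet"
  )
}

#' @export
print.glycan_alphabet <- function(x, ...) {
  cat(sprintf("<glycan_alphabet> k = %d states\n", n_states(x)))
  for (i in seq_along(x$names)) {
    cat(sprintf("  state %d: %s\n", i - 1L, x$names[i]))
  }
  invisible(x)
}

#' Number of states (k) in an alphabet
#' @param alphabet a `glycan_alphabet`
#' @return integer k >= 2
#' @export
n_states <- function(alphabet) {
  stopifnot(inherits(alphabet, "glycan_alphabet"))
  length(alphabet$names)
}

#' State names of an alphabet, in digit order (state 0 first)
#' @param alphabet a `glycan_alphabet`
#' @export
state_names <- function(alphabet) {
  stopifnot(inherits(alphabet, "glycan_alphabet"))
  alphabet$names
}

#' Look up a glycan state by name
#' @param alphabet a `glycan_alphabet`
#' @param name state name (not "UNOCCUPIED")
#' @return the `glycan` object
#' @export
alphabet_glycan <- function(alphabet, name) {
  stopifnot(inherits(alphabet, "glycan_alphabet"))
  i <- match(name, alphabet$names)
  if (is.na(i)) {
    stop_validation("unknown glycan state '%s' (alphabet states: %s)",
                    name, paste(alphabet$names, collapse = ", "))
  }
  if (i == 1L) stop_validation("state 'UNOCCUPIED' carries no glycan")
  alphabet$states[[i]]
}

#' Built-in alphabets
#'
#' `alphabet_tn()` is the binary case (UNOCCUPIED/GalNAc): 2^n - 1 glycoforms
#' over n sites. `alphabet_tn_stn()` adds sialyl-Tn as state 2 (ternary,
#' 3^n - 1 glycoforms). `alphabet_binding()` further includes Ac3GalNAc and is
#' intended for parsing binding-assay fixture labels, not for library design.
#'
#' @return a `glycan_alphabet`
#' @export
alphabet_tn <- function() glycan_alphabet(glycan_galnac())

#' @rdname alphabet_tn
#' @export
alphabet_tn_stn <- function() {
  glycan_alphabet(glycan_galnac(), glycan_neuac_galnac())
}

#' @rdname alphabet_tn
#' @export
alphabet_binding <- function() {
  glycan_alphabet(glycan_galnac(), glycan_neuac_galnac(), glycan_ac3galnac())
}

# ---------------------------------------------------------------------------
# Glycoforms

#' Construct a glycoform
#'
#' One assignment of a glycan state to each glycosylation site — a single
#' column of the sites x glycoforms occupancy matrix.
#'
#' @param sites data.frame with columns `position` (1-based) and `residue`
#'   ("S" or "T"), as returned by [identify_glycosites()]
#' @param states integer vector, one state digit in `[0, k-1]` per site
#' @param alphabet the `glycan_alphabet` the digits refer to
#' @return an object of class `glycoform`
#' @export
glycoform <- function(sites, states, alphabet) {
  sites <- as_glycosites(sites)
  if (!inherits(alphabet, "glycan_alphabet")) {
    stop_validation("`alphabet` must be a glycan_alphabet")
  }
  k <- n_states(alphabet)
  states <- as.integer(states)
  if (length(states) != nrow(sites)) {
    stop_validation("length(states) = %d but there are %d sites",
                    length(states), nrow(sites))
  }
  if (any(is.na(states)) || any(states < 0L) || any(states >= k)) {
    stop_validation("states must be integers in [0, %d]", k - 1L)
  }
  structure(
    list(sites = sites, states = states, alphabet = alphabet),
    class = "glycoform"
  )
}

#' Number of occupied sites of a glycoform
#' @param gf a `glycoform`
#' @return integer occupancy m, 0 <= m <= n_sites
#' @export
occupancy <- function(gf) {
  stopifnot(inherits(gf, "glycoform"))
  sum(gf$states > 0L)
}

#' @export
print.glycoform <- function(x, ...) {
  lab <- ifelse(
    x$states == 0L, ".",
    paste0(x$sites$residue, x$sites$position, ":",
           x$alphabet$names[x$states + 1L])
  )
  cat(sprintf("<glycoform> [%s] occupancy %d\n",
              paste(lab, collapse = " "), occupancy(x)))
  invisible(x)
}

# Coerce a sites specification to the canonical data.frame.
# Accepts: the data.frame itself; a peptide string (scanned for S/T); or a
# single integer n (placeholder serine sites at positions 1..n, for purely
# combinatorial work).
as_glycosites <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("position", "residue") %in% names(x))) {
      stop_validation("glycosite data.frame needs columns `position` and `residue`")
    }
    if (nrow(x) > 0L) {
      if (any(!x$residue %in% c("S", "T"))) {
        stop_validation("glycosite residues must be 'S' or 'T'")
      }
      if (any(x$position < 1L) || anyDuplicated(x$position) ||
          is.unsorted(x$position)) {
        stop_validation("glycosite positions must be unique, ascending, 1-based")
      }
    }
    return(data.frame(position = as.integer(x$position),
                      residue = as.character(x$residue),
                      stringsAsFactors = FALSE))
  }
  if (is.character(x) && length(x) == 1L) return(identify_glycosites(x))
  if (is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 &&
      x == as.integer(x)) {
    return(data.frame(position = seq_len(x), residue = "S",
                      stringsAsFactors = FALSE))
  }
  stop_validation("cannot interpret `sites`: give a glycosite data.frame, a peptide string, or a site count")
}

#' The MUC1 tandem-repeat unit
#'
#' The canonical 20-residue MUC1 repeat in its two commonly printed phases:
#' `"rp"` = RPAPGSTAPPAHGVTSAPDT, `"hg"` = HGVTSAPDTRPAPGSTAPPA. Both carry
#' the same five O-glycosylation sites.
#'
#' @param phase which circular phase of the repeat to return
#' @return a 20-character string
#' @export
muc1_unit <- function(phase = c("rp", "hg")) {
  switch(match.arg(phase),
         rp = "RPAPGSTAPPAHGVTSAPDT",
         hg = "HGVTSAPDTRPAPGSTAPPA")
}
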