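# Theoretical mass arithmetic for peptides and glycopeptides.
#
# All masses derive from a single table of atomic masses (monoisotopic from
# the IUPAC/CODATA recommended values; average from standard atomic weights)
# via elemental compositions; no residue mass is hard-coded as a decimal.
# Adduct model is protonation only, matching positive-ion ESI.

# versioned atomic-mass table (Da)
ATOMIC_MASS_MONO <- c(
  C = 12.0,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069
)
ATOMIC_MASS_AVG <- c(
  C = 12.0107,
  H = 1.00794,
  N = 14.0067,
  O = 15.9994,
  S = 32.065
)

#' Physical constants for mass spectrometry
#'
#' Proton mass in Da (CODATA), used as the charge carrier in the
#' protonation-only adduct model.
#' @keywords internal
PROTON_MASS <- 1.00727646688

# residue (i.e. water-free) elemental formulas of the 20 amino acids
AA_RESIDUE_FORMULA <- c(
  A = "C3H5NO",   R = "C6H12N4O",  N = "C4H6N2O2", D = "C4H5NO3",
  C = "C3H5NOS",  E = "C5H7NO3",   Q = "C5H8N2O2", G = "C2H3NO",
  H = "C6H7N3O",  I = "C6H11NO",   L = "C6H11NO",  K = "C6H12N2O",
  M = "C5H9NOS",  F = "C9H9NO",    P = "C5H7NO",   S = "C3H5NO2",
  T = "C4H7NO2",  W = "C11H10N2O", Y = "C9H9NO2",  V = "C5H9NO"
)

#' Parse an elemental formula into atom counts
#'
#' Accepts formulas over C, H, N, O, S such as `"C8H13NO5"`. A character
#' vector is treated as parts to be summed, so
#' `parse_formula(c("C8H13NO5", "C11H17NO8"))` is the sialyl-Tn disaccharide
#' residue.
#'
#' @param formula character vector of formula strings
#' @return named numeric vector of atom counts (C, H, N, O, S)
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) < 1L || any(is.na(formula))) {
    stop_validation("`formula` must be one or more formula strings")
  }
  counts <- c(C = 0, H = 0, N = 0, O = 0, S = 0)
  for (f in formula) {
    if (!grepl("^([CHNOS][0-9]*)+$", f)) {
      stop_validation("cannot parse elemental formula '%s' (elements C,H,N,O,S only)", f)
    }
    m <- gregexpr("[CHNOS][0-9]*", f)[[1L]]
    toks <- regmatches(f, list(m))[[1L]]
    for (tok in toks) {
      el <- substr(tok, 1L, 1L)
      n <- if (nchar(tok) > 1L) as.numeric(substr(tok, 2L, nchar(tok))) else 1
      counts[el] <- counts[el] + n
    }
  }
  counts
}

#' Mass of an elemental formula
#'
#' @param formula formula string(s), summed (see [parse_formula()])
#' @param kind `"mono"` (monoisotopic) or `"avg"` (average)
#' @return mass in Da
#' @examples
#' formula_mass("C8H13NO5")  # HexNAc residue, 203.0794
#' @export
formula_mass <- function(formula, kind = c("mono", "avg")) {
  kind <- match.arg(kind)
  counts <- parse_formula(formula)
  tab <- if (kind == "mono") ATOMIC_MASS_MONO else ATOMIC_MASS_AVG
  sum(counts * tab[names(counts)])
}

# residue-mass lookup tables, computed from composition at build time
AA_RESIDUE_MASS_MONO <- vapply(AA_RESIDUE_FORMULA, function(f) {
  sum(parse_formula(f) * ATOMIC_MASS_MONO)
}, numeric(1L))
AA_RESIDUE_MASS_AVG <- vapply(AA_RESIDUE_FORMULA, function(f) {
  sum(parse_formula(f) * ATOMIC_MASS_AVG)
}, numeric(1L))
WATER_MASS_MONO <- sum(parse_formula("H2O") * ATOMIC_MASS_MONO)
WATER_MASS_AVG <- sum(parse_formula("H2O") * ATOMIC_MASS_AVG)

water_mass <- function(kind) {
  if (kind == "mono") WATER_MASS_MONO else WATER_MASS_AVG
}

#' Neutral mass of a peptide
#'
#' Sum of residue masses plus one water (the termini). Additive under
#' concatenation minus one water.
#'
#' @param seq peptide sequence
#' @param kind `"mono"` or `"avg"`
#' @return mass in Da
#' @examples
#' peptide_mass("G")  # glycine, 75.03203 Da
#' @export
peptide_mass <- function(seq, kind = c("mono", "avg")) {
  kind <- match.arg(kind)
  validate_peptide(seq)
  tab <- if (kind == "mono") AA_RESIDUE_MASS_MONO else AA_RESIDUE_MASS_AVG
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  sum(tab[chars]) + water_mass(kind)
}

# residue mass a glycan state adds to the peptide
glycan_state_mass <- function(name, alphabet, kind) {
  g <- alphabet_glycan(alphabet, name)
  m <- if (kind == "mono") g$mass_mono else g$mass_avg
  if (!is.finite(m) || m <= 0) {
    stop_validation("glycan state '%s' has no usable %s mass configured", name, kind)
  }
  m
}

#' Neutral mass of a glycopeptide epitope
#'
#' Peptide mass plus the residue mass of every attached glycan state; an
#' unannotated epitope weighs exactly its peptide. An optional fixed-mass
#' tag (e.g. a biotin linker used for plate immobilisation) can be added as
#' `tag_mass`; it defaults to 0 and is pure mass bookkeeping, never part of
#' the epitope string.
#'
#' @param e a `glyco_epitope`
#' @param alphabet `glycan_alphabet` resolving the annotation names
#' @param kind `"mono"` or `"avg"`
#' @param tag_mass optional fixed tag mass in Da (default 0)
#' @return mass in Da
#' @export
glycopeptide_mass <- function(e, alphabet = alphabet_tn_stn(),
                              kind = c("mono", "avg"), tag_mass = 0) {
  kind <- match.arg(kind)
  stopifnot(inherits(e, "glyco_epitope"))
  base <- peptide_mass(e$peptide, kind)
  gly <- if (length(e$annotations) == 0L) 0 else {
    sum(vapply(e$annotations, glycan_state_mass, numeric(1L),
               alphabet = alphabet, kind = kind))
  }
  base + gly + tag_mass
}

#' Mass-to-charge ratio under protonation
#'
#' `(mass + z * proton) / z` for the \[M + zH\]^z+ ion.
#'
#' @param mass neutral mass in Da
#' @param z positive integer charge
#' @return m/z
#' @export
mz <- function(mass, z = 1L) {
  if (!is.numeric(z) || any(z != as.integer(z)) || any(z < 1L)) {
    stop_validation("charge `z` must be a positive integer")
  }
  (mass + z * PROTON_MASS) / z
}

# oxonium fragment definitions: base composition plus small-molecule losses.
# m/z = residue composition mass - losses + proton.
oxonium_defs <- function(has_hexnac, has_neuac) {
  defs <- list()
  if (has_hexnac) {
    hex <- "C8H13NO5"
    defs <- c(defs, list(
      list(label = "HexNAc",             parts = hex,  loss = character()),
      list(label = "HexNAc-H2O",         parts = hex,  loss = "H2O"),
      list(label = "HexNAc-2H2O",        parts = hex,  loss = c("H2O", "H2O")),
      list(label = "HexNAc-C2H2O-H2O",   parts = hex,  loss = c("C2H2O", "H2O")),
      list(label = "HexNAc-2H2O-CH2O",   parts = hex,  loss = c("H2O", "H2O", "CH2O")),
      list(label = "HexNAc-C2H2O-2H2O",  parts = hex,  loss = c("C2H2O", "H2O", "H2O"))
    ))
  }
  if (has_neuac) {
    neu <- "C11H17NO8"
    defs <- c(defs, list(
      list(label = "NeuAc",     parts = neu, loss = character()),
      list(label = "NeuAc-H2O", parts = neu, loss = "H2O")
    ))
    if (has_hexnac) {
      defs <- c(defs, list(
        list(label = "NeuAc-HexNAc", parts = c("C11H17NO8", "C8H13NO5"),
             loss = character())
      ))
    }
  }
  defs
}

#' Diagnostic fragment ions of a glycopeptide
#'
#' Theoretical b/y backbone series and glycan oxonium ions for CID spectra.
#' For every backbone cleavage whose fragment spans at least one annotated
#' site, two variants are produced: glycan-retained and glycan-lost (O-glycans
#' fragment readily, so both are observed). Oxonium ions are emitted for the
#' glycan families present: the HexNAc series (204.087 and its standard
#' water/ketene-loss secondaries) for GalNAc-type states, and the NeuAc
#' series for sialylated states; families are recognised by the state name
#' containing "GalNAc"/"HexNAc" or "NeuAc".
#'
#' @param e a `glyco_epitope`
#' @param series subset of `c("b", "y", "oxonium")`
#' @param alphabet `glycan_alphabet` resolving annotation names
#' @param z fragment charge (default 1)
#' @param kind `"mono"` or `"avg"`
#' @return data.frame with columns `series`, `index`, `glycans_retained`,
#'   `label`, `mz`
#' @export
fragment_ions <- function(e, series = c("b", "y", "oxonium"),
                          alphabet = alphabet_tn_stn(), z = 1L,
                          kind = c("mono", "avg")) {
  kind <- match.arg(kind)
  series <- match.arg(series, several.ok = TRUE)
  stopifnot(inherits(e, "glyco_epitope"))
  if (!is.numeric(z) || length(z) != 1L || z != as.integer(z) || z < 1L) {
    stop_validation("charge `z` must be a positive integer")
  }
  tab <- if (kind == "mono") AA_RESIDUE_MASS_MONO else AA_RESIDUE_MASS_AVG
  chars <- strsplit(e$peptide, "", fixed = TRUE)[[1]]
  n <- length(chars)
  res_mass <- unname(tab[chars])
  ann_pos <- as.integer(names(e$annotations))
  ann_mass <- if (length(ann_pos) == 0L) numeric() else {
    vapply(e$annotations, glycan_state_mass, numeric(1L),
           alphabet = alphabet, kind = kind)
  }
  frag_mz <- function(neutral) (neutral + z * PROTON_MASS) / z

  rows <- list()
  add_row <- function(ser, idx, retained, label, neutral) {
    rows[[length(rows) + 1L]] <<- data.frame(
      series = ser, index = idx, glycans_retained = retained,
      label = label, mz = frag_mz(neutral), stringsAsFactors = FALSE
    )
  }

  if ("b" %in% series && n >= 2L) {
    cum <- cumsum(res_mass)
    for (i in seq_len(n - 1L)) {
      bare <- cum[i]
      gly <- sum(ann_mass[ann_pos <= i])
      if (gly > 0) {
        add_row("b", i, TRUE, sprintf("b%d+glycans", i), bare + gly)
        add_row("b", i, FALSE, sprintf("b%d", i), bare)
      } else {
        add_row("b", i, FALSE, sprintf("b%d", i), bare)
      }
    }
  }
  if ("y" %in% series && n >= 2L) {
    cum_rev <- rev(cumsum(rev(res_mass)))
    for (j in seq_len(n - 1L)) {
      first <- n - j + 1L
      bare <- cum_rev[first] + water_mass(kind)
      gly <- sum(ann_mass[ann_pos >= first])
      if (gly > 0) {
        add_row("y", j, TRUE, sprintf("y%d+glycans", j), bare + gly)
        add_row("y", j, FALSE, sprintf("y%d", j), bare)
      } else {
        add_row("y", j, FALSE, sprintf("y%d", j), bare)
      }
    }
  }
  if ("oxonium" %in% series && length(e$annotations) > 0L) {
    states <- unique(unname(e$annotations))
    has_hexnac <- any(grepl("GalNAc|HexNAc", states))
    has_neuac <- any(grepl("NeuAc", states))
    for (d in oxonium_defs(has_hexnac, has_neuac)) {
      neutral <- formula_mass(d$parts, kind) -
        (if (length(d$loss)) formula_mass(d$loss, kind) else 0)
      # oxonium ions are singly charged by nature
      rows[[length(rows) + 1L]] <- data.frame(
        series = "oxonium", index = NA_integer_, glycans_retained = TRUE,
        label = d$label, mz = neutral + PROTON_MASS, stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(series = character(), index = integer(),
                      glycans_retained = logical(), label = character(),
                      mz = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Tabulate masses and charge states for an epitope library
#'
#' @param epitopes list of `glyco_epitope` objects
#' @param alphabet `glycan_alphabet` resolving annotations
#' @param charges integer vector of charge states for m/z columns
#' @param tag_mass optional fixed tag mass added to every epitope
#' @return data.frame with `epitope_id`, `rendered`, `mono_mass`, `avg_mass`
#'   and one `mz_z<z>` column per charge
#' @export
mass_table <- function(epitopes, alphabet = alphabet_tn_stn(),
                       charges = 1:3, tag_mass = 0) {
  if (length(epitopes) == 0L) {
    stop_validation("empty epitope list")
  }
  mono <- vapply(epitopes, glycopeptide_mass, numeric(1L),
                 alphabet = alphabet, kind = "mono", tag_mass = tag_mass)
  avg <- vapply(epitopes, glycopeptide_mass, numeric(1L),
                alphabet = alphabet, kind = "avg", tag_mass = tag_mass)
  out <- data.frame(
    epitope_id = seq_along(epitopes),
    rendered = vapply(epitopes, render_epitope, character(1L)),
    mono_mass = mono, avg_mass = avg, stringsAsFactors = FALSE
  )
  for (zz in charges) out[[sprintf("mz_z%d", zz)]] <- mz(mono, zz)
  out
}
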