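# File I/O: FASTA (via Biostrings), glycan alphabet definition files,
# matrix/library/mass exports, and the packaged reference tables.

#' Read protein sequences from a FASTA file
#'
#' Wraps `Biostrings::readAAStringSet()`. Record order is preserved; ids are
#' the description line up to the first whitespace; sequences are uppercased
#' and wrapped lines joined. Every sequence is validated against the 20
#' one-letter codes, with errors naming the record and position.
#'
#' @param path FASTA file path
#' @return named character vector of sequences (names = record ids)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) {
                    stop_validation("cannot read FASTA '%s': %s", path,
                                    conditionMessage(e))
                  })
  if (length(set) == 0L) {
    stop_validation("FASTA file '%s' contains no records", path)
  }
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  for (i in seq_along(seqs)) validate_peptide(seqs[i], id = ids[i])
  stats::setNames(unname(seqs), ids)
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs named character vector (names become record ids)
#' @param path output path
#' @param width line-wrap width
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (!is.character(seqs) || length(seqs) == 0L || is.null(names(seqs))) {
    stop_validation("`seqs` must be a non-empty named character vector")
  }
  for (i in seq_along(seqs)) validate_peptide(seqs[[i]], id = names(seqs)[i])
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs),
                              filepath = path, width = width)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Glycan alphabet definition files: one state per line, tab-separated,
#   name <TAB> formula            (formula parts joined by '+'), or
#   name <TAB> mono_mass <TAB> avg_mass
# '#' lines are comments. State order = line order; UNOCCUPIED (state 0) is
# implicit and never listed.

#' Read a glycan alphabet definition file
#'
#' @param path definition file (see Details in [write_alphabet()])
#' @return a `glycan_alphabet`
#' @export
read_alphabet <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    stop_validation("alphabet file '%s' defines no glycan states", path)
  }
  glycans <- lapply(lines, function(ln) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    fields <- trimws(fields)
    if (length(fields) < 2L) {
      stop_validation("malformed alphabet line '%s' (need name<TAB>formula or name<TAB>mono<TAB>avg)", ln)
    }
    name <- fields[1L]
    if (grepl("^[0-9.eE+-]+$", fields[2L])) {
      mono <- as.numeric(fields[2L])
      avg <- if (length(fields) >= 3L) as.numeric(fields[3L]) else mono
      glycan(name, mass_mono = mono, mass_avg = avg)
    } else {
      glycan(name, formula = strsplit(fields[2L], "+", fixed = TRUE)[[1L]])
    }
  })
  glycan_alphabet(glycans)
}

#' Write a glycan alphabet definition file
#'
#' File format: one non-UNOCCUPIED state per line in digit order,
#' `name<TAB>formula` (formula parts joined by `+`) when the state has an
#' elemental composition, otherwise `name<TAB>mono_mass<TAB>avg_mass`.
#' Serialising and re-reading preserves state indices.
#'
#' @param alphabet a `glycan_alphabet`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_alphabet <- function(alphabet, path) {
  stopifnot(inherits(alphabet, "glycan_alphabet"))
  lines <- c("# glycoforge glycan alphabet (state 0 = UNOCCUPIED, implicit)")
  for (g in alphabet$states[-1L]) {
    lines <- c(lines, if (!is.null(g$formula)) {
      sprintf("%s\t%s", g$name, paste(g$formula, collapse = "+"))
    } else {
      sprintf("%s\t%s\t%s", g$name,
              format(g$mass_mono, digits = 15), format(g$mass_avg, digits = 15))
    })
  }
  writeLines(lines, path)
  invisible(path)
}

# resolve a CLI-style alphabet argument: "builtin:tn", "builtin:tn-stn",
# "builtin:binding", or a definition-file path
resolve_alphabet <- function(spec) {
  if (inherits(spec, "glycan_alphabet")) return(spec)
  if (!is.character(spec) || length(spec) != 1L) {
    stop_validation("alphabet must be a glycan_alphabet, 'builtin:<name>' or a file path")
  }
  if (startsWith(spec, "builtin:")) {
    switch(sub("^builtin:", "", spec),
           "tn" = alphabet_tn(),
           "tn-stn" = alphabet_tn_stn(),
           "binding" = alphabet_binding(),
           stop_validation("unknown builtin alphabet '%s' (have tn, tn-stn, binding)", spec))
  } else {
    read_alphabet(spec)
  }
}

# ---------------------------------------------------------------------------
# Matrix and library exports

#' Write an occupancy matrix as TSV
#'
#' Sites as rows (first column `site`), glycoforms as columns `gf1..gfN`,
#' integer states as entries.
#'
#' @param m matrix from [occupancy_matrix()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_occupancy_matrix <- function(m, path) {
  if (!is.matrix(m)) stop_validation("`m` must be a matrix")
  df <- data.frame(site = rownames(m), m, stringsAsFactors = FALSE)
  names(df) <- c("site", sprintf("gf%d", seq_len(ncol(m))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an occupancy matrix written by [write_occupancy_matrix()]
#' @param path TSV path
#' @return integer matrix with site rownames
#' @export
read_occupancy_matrix <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1L]]
  colnames(m) <- NULL
  m
}

#' Export an epitope library as CSV
#'
#' Columns: `epitope_id`, `peptide` (bare sequence), `rendered` (annotated
#' string), `window_origin`, `occupancy`, `glycans` (semicolon-joined
#' `position:state` pairs).
#'
#' @param epitopes list of `glyco_epitope` objects
#' @param path output path
#' @return `path`, invisibly
#' @export
write_epitope_csv <- function(epitopes, path) {
  if (length(epitopes) == 0L) stop_validation("empty epitope list")
  df <- data.frame(
    epitope_id = seq_along(epitopes),
    peptide = vapply(epitopes, function(e) e$peptide, character(1L)),
    rendered = vapply(epitopes, render_epitope, character(1L)),
    window_origin = vapply(epitopes, function(e) e$window_origin, integer(1L)),
    occupancy = vapply(epitopes, function(e) length(e$annotations), integer(1L)),
    glycans = vapply(epitopes, function(e) {
      if (length(e$annotations) == 0L) return("")
      paste(sprintf("%s:%s", names(e$annotations), e$annotations),
            collapse = ";")
    }, character(1L)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an epitope library CSV back into epitope objects
#' @param path CSV from [write_epitope_csv()]
#' @param alphabet `glycan_alphabet` validating the state names
#' @return list of `glyco_epitope` objects
#' @export
read_epitope_csv <- function(path, alphabet = alphabet_tn_stn()) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    parse_epitope(df$rendered[i], alphabet = alphabet,
                  window_origin = df$window_origin[i])
  })
}

#' Export an epitope library as FASTA
#'
#' The bare peptide is the sequence; the description line carries the
#' annotated string.
#'
#' @param epitopes list of `glyco_epitope` objects
#' @param path output path
#' @return `path`, invisibly
#' @export
write_epitope_fasta <- function(epitopes, path) {
  if (length(epitopes) == 0L) stop_validation("empty epitope list")
  seqs <- vapply(epitopes, function(e) e$peptide, character(1L))
  names(seqs) <- sprintf("epi_%03d %s", seq_along(epitopes),
                         vapply(epitopes, render_epitope, character(1L)))
  write_fasta(seqs, path)
}

# ---------------------------------------------------------------------------
# Packaged reference tables (plain-text fixtures under inst/extdata)

#' Packaged immunohistochemistry staining table
#'
#' Ten breast-cancer patient samples scored +/- for receptor status and for
#' MUC1 glycopeptide-epitope staining by the 16A monoclonal antibody.
#'
#' @param path override the packaged file
#' @return data.frame
#' @export
read_ihc_table <- function(path = system.file("extdata", "ihc_staining.tsv",
                                              package = "glycoforge")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop_validation("IHC table not found")
  }
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = TRUE)
}

#' Packaged SPR rate-constant table
#'
#' Association/dissociation rate constants for the 14A and 16A monoclonal
#' antibodies binding three (glyco)peptide analytes, with the printed KD and
#' the vendor fit residual (chi2, metadata only — not recomputable without
#' raw sensorgrams). `KD_computed_nM` = [kd_from_rates()] applied to each row.
#'
#' @param path override the packaged file
#' @return data.frame with a `KD_computed_nM` column appended
#' @export
read_spr_table <- function(path = system.file("extdata", "spr_constants.csv",
                                              package = "glycoforge")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop_validation("SPR table not found")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$KD_computed_nM <- kd_from_rates(df$ka_1_per_Ms, df$kd_1_per_s)
  df
}
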