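# Glycopeptide epitopes: a peptide window plus per-position glycan
# annotations, rendered in the field's inline notation where "(StateName)"
# immediately follows the modified Ser/Thr, e.g. RPAPGS(GalNAc)TAPPAHG.

#' Construct a glycopeptide epitope
#'
#' @param peptide the peptide window sequence (one-letter codes)
#' @param annotations named character vector mapping 1-based positions within
#'   `peptide` (as names) to glycan state names; empty for a naked peptide
#' @param window_origin 1-based position of the window start within its
#'   parent protein (bookkeeping only)
#' @return an object of class `glyco_epitope`
#' @examples
#' e <- epitope("RPAPGSTAPPAHG", c("6" = "GalNAc"))
#' render_epitope(e)  # "RPAPGS(GalNAc)TAPPAHG"
#' @export
epitope <- function(peptide, annotations = character(), window_origin = 1L) {
  validate_peptide(peptide)
  annotations <- as.character(annotations) |>
    stats::setNames(names(annotations))
  if (length(annotations) > 0L) {
    if (is.null(names(annotations)) || any(!nzchar(names(annotations)))) {
      stop_validation("`annotations` must be named by 1-based positions")
    }
    pos <- suppressWarnings(as.integer(names(annotations)))
    if (any(is.na(pos)) || any(pos < 1L) || any(pos > nchar(peptide))) {
      stop_validation("annotation positions must be integers within the peptide")
    }
    if (anyDuplicated(pos)) {
      stop_validation("duplicate annotation positions")
    }
    res <- substring(peptide, pos, pos)
    bad <- which(!res %in% c("S", "T"))
    if (length(bad) > 0L) {
      stop_validation("annotation at position %d sits on '%s'; O-glycans attach only to S or T",
                      pos[bad[1L]], res[bad[1L]])
    }
    ord <- order(pos)
    annotations <- stats::setNames(annotations[ord], pos[ord])
  }
  structure(
    list(peptide = peptide, annotations = annotations,
         window_origin = as.integer(window_origin)),
    class = "glyco_epitope"
  )
}

#' @export
print.glyco_epitope <- function(x, ...) {
  cat(sprintf("<glyco_epitope> %s (origin %d, occupancy %d)\n",
              render_epitope(x), x$window_origin, length(x$annotations)))
  invisible(x)
}

#' Render an epitope as an annotated string
#'
#' Inserts `"(StateName)"` immediately after each modified residue:
#' an epitope of RPAPGSTAPPAHG with GalNAc on the serine at position 6
#' renders as `"RPAPGS(GalNAc)TAPPAHG"`. Deterministic; the inverse of
#' [parse_epitope()].
#'
#' @param e a `glyco_epitope`
#' @return character scalar
#' @export
render_epitope <- function(e) {
  stopifnot(inherits(e, "glyco_epitope"))
  if (length(e$annotations) == 0L) return(e$peptide)
  chars <- strsplit(e$peptide, "", fixed = TRUE)[[1]]
  pos <- as.integer(names(e$annotations))
  chars[pos] <- paste0(chars[pos], "(", e$annotations, ")")
  paste(chars, collapse = "")
}

#' Parse an annotated glycopeptide string
#'
#' Inverse of [render_epitope()]: reads strings like
#' `"PAHGVT(GalNAc)SAPD"` into a `glyco_epitope`. Each parenthesised state
#' name is attached to the residue immediately preceding it, which must be
#' S or T; the name must exist in `alphabet`.
#'
#' @param string annotated (or plain) peptide string
#' @param alphabet `glycan_alphabet` resolving the state names
#' @param window_origin carried through to the result
#' @return a `glyco_epitope`
#' @export
parse_epitope <- function(string, alphabet = alphabet_tn_stn(),
                          window_origin = 1L) {
  if (!is.character(string) || length(string) != 1L || is.na(string)) {
    stop_validation("`string` must be a single character string")
  }
  stripped <- gsub("\\(([^()]+)\\)", "", string)
  if (grepl("[()]", stripped)) {
    stop_validation("unbalanced or empty parentheses in '%s'", string)
  }
  m <- gregexpr("\\(([^()]+)\\)", string)[[1L]]
  ann <- character()
  if (m[1L] != -1L) {
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    nms <- substring(string, starts + 1L, starts + lens - 2L)
    known <- state_names(alphabet)[-1L]
    unknown <- setdiff(nms, known)
    if (length(unknown) > 0L) {
      stop_validation("unknown glycan state '%s' (alphabet states: %s)",
                      unknown[1L], paste(known, collapse = ", "))
    }
    # residue index = number of residue characters preceding the annotation
    pos <- vapply(starts, function(st) {
      nchar(gsub("\\([^()]*\\)", "", substr(string, 1L, st - 1L)))
    }, integer(1L))
    if (any(pos == 0L)) {
      stop_validation("annotation at the start of '%s' follows no residue", string)
    }
    if (anyDuplicated(pos)) {
      stop_validation("two annotations on the same residue in '%s'", string)
    }
    ann <- stats::setNames(nms, pos)
  }
  # epitope() re-validates residues and S/T placement
  epitope(stripped, ann, window_origin = window_origin)
}

#' Extract candidate epitope windows around occupied sites
#'
#' Applies a glycoform (defined over the repeat unit's sites) to every copy
#' of the unit in a tandem-repeat protein and cuts fixed-length peptide
#' windows:
#' \describe{
#'   \item{`"centered"`}{one window per occupied site occurrence, with the
#'     modified residue at window position `ceiling(window_len/2)`, shifted
#'     (not truncated) where the protein termini do not allow full centering}
#'   \item{`"tiled"`}{every window of `window_len` containing at least one
#'     occupied site}
#' }
#' Windows carry their 1-based origin in the full protein; all occupied
#' positions falling inside a window are annotated.
#'
#' @param protein a `tandem_repeat` (a plain string is treated as one copy)
#' @param gf a `glycoform` over the repeat unit's glycosites
#' @param window_len window length, `5 <= window_len <= nchar(protein)`
#' @param mode `"centered"` or `"tiled"`
#' @return list of `glyco_epitope` objects, origin-ascending
#' @export
extract_windows <- function(protein, gf, window_len = 13L,
                            mode = c("centered", "tiled")) {
  mode <- match.arg(mode)
  if (is.character(protein)) protein <- make_tandem_repeat(protein, 1L)
  if (!inherits(protein, "tandem_repeat")) {
    stop_validation("`protein` must be a tandem_repeat or a peptide string")
  }
  stopifnot(inherits(gf, "glycoform"))
  full <- as.character(protein)
  L <- nchar(full)
  if (!is.numeric(window_len) || length(window_len) != 1L ||
      window_len != as.integer(window_len) || window_len < 5L ||
      window_len > L) {
    stop_validation("`window_len` must be an integer in [5, %d]", L)
  }
  w <- as.integer(window_len)
  unit_len <- nchar(protein$unit)
  if (any(gf$sites$position > unit_len)) {
    stop_validation("glycoform sites exceed the repeat unit length (%d)", unit_len)
  }
  unit_res <- substring(protein$unit, gf$sites$position, gf$sites$position)
  if (!all(unit_res == gf$sites$residue)) {
    stop_validation("glycoform site residues do not match the repeat unit")
  }

  occ <- gf$states > 0L
  if (!any(occ)) return(list())
  nms <- state_names(gf$alphabet)
  prefix_len <- nchar(protein$prefix)
  # occupied positions in the full protein, one block per repeat copy
  offsets <- prefix_len + (seq_len(protein$copies) - 1L) * unit_len
  full_pos <- as.vector(outer(gf$sites$position[occ], offsets, `+`))
  full_state <- rep(nms[gf$states[occ] + 1L], times = protein$copies)
  ord <- order(full_pos)
  full_pos <- full_pos[ord]
  full_state <- full_state[ord]

  window_at <- function(start) {
    end <- start + w - 1L
    inside <- full_pos >= start & full_pos <= end
    epitope(substr(full, start, end),
            stats::setNames(full_state[inside], full_pos[inside] - start + 1L),
            window_origin = start)
  }

  if (mode == "centered") {
    starts <- pmin(pmax(full_pos - ceiling(w / 2) + 1L, 1L), L - w + 1L)
    lapply(starts, window_at)
  } else {
    starts <- seq_len(L - w + 1L)
    keep <- vapply(starts, function(s) {
      any(full_pos >= s & full_pos <= s + w - 1L)
    }, logical(1L))
    lapply(starts[keep], window_at)
  }
}

#' Deduplicate an epitope list
#'
#' Collapses epitopes whose rendered strings are identical — tandem-repeat
#' periodicity makes repeat-internal windows identical across copies — and
#' keeps the first occurrence (stable order). Epitopes differing only in
#' glycan state are distinct.
#'
#' @param epitopes list of `glyco_epitope` objects
#' @return the deduplicated list
#' @export
unique_epitopes <- function(epitopes) {
  if (length(epitopes) == 0L) return(epitopes)
  keys <- vapply(epitopes, render_epitope, character(1L))
  epitopes[!duplicated(keys)]
}

#' Build a deduplicated epitope library for a tandem-repeat protein
#'
#' Convenience wrapper: enumerates all glycoforms of the repeat unit under
#' `alphabet`, extracts windows for each, and deduplicates the union.
#'
#' @inheritParams extract_windows
#' @param alphabet `glycan_alphabet` used for enumeration
#' @param ... passed on to [enumerate_glycoforms()]
#' @return list of unique `glyco_epitope` objects
#' @export
epitope_library <- function(protein, alphabet = alphabet_tn(),
                            window_len = 13L,
                            mode = c("centered", "tiled"), ...) {
  mode <- match.arg(mode)
  if (is.character(protein)) protein <- make_tandem_repeat(protein, 1L)
  gfs <- enumerate_glycoforms(identify_glycosites(protein$unit),
                              alphabet = alphabet, ...)
  windows <- lapply(gfs, function(g) {
    extract_windows(protein, g, window_len = window_len, mode = mode)
  })
  unique_epitopes(do.call(c, windows))
}
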