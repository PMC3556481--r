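# Synthetic fixture generation: mucin-like tandem-repeat proteins and
# binding data with known ground truth, so every analysis path can be
# exercised offline and parameter recovery can be measured.

#' Generate a random mucin-like repeat unit
#'
#' Draws a repeat unit of the requested length with exactly `n_sites`
#' serine/threonine glycosylation sites at random non-adjacent positions
#' (mucin repeats space their sites); remaining positions are drawn from the
#' other 18 amino acids. Deterministic under `seed`; the caller's RNG state
#' is untouched.
#'
#' @param length unit length in residues
#' @param n_sites number of S/T sites; must fit non-adjacently,
#'   i.e. `n_sites <= ceiling(length / 2)`
#' @param seed RNG seed (required)
#' @return the unit sequence (character scalar)
#' @export
random_repeat_unit <- function(length = 20L, n_sites = 5L, seed) {
  if (missing(seed)) stop_validation("`seed` is required")
  if (n_sites < 1L || length < 1L) {
    stop_validation("`length` and `n_sites` must be positive")
  }
  if (n_sites > ceiling(length / 2)) {
    stop_validation("cannot place %d non-adjacent S/T sites in a %d-residue unit",
                    n_sites, length)
  }
  other <- setdiff(AA_CODES, c("S", "T"))
  with_seed(seed, {
    repeat {
      pos <- sort(sample.int(length, n_sites))
      if (n_sites < 2L || all(diff(pos) > 1L)) break
    }
    res <- sample(other, length, replace = TRUE)
    res[pos] <- sample(c("S", "T"), n_sites, replace = TRUE)
    paste(res, collapse = "")
  })
}

#' Default ground-truth parameters for binding fixtures
#'
#' SPR: ka = 5.6e4 1/(M s), kd = 0.028 1/s (KD = 500 nM, the magnitude seen
#' for anti-glycopeptide monoclonals by SPR), Rmax = 100 RU, 120 s
#' association / 200 s dissociation, analyte at KD x (0.1, 0.3, 1, 3, 10),
#' noise 2 RU. ELISA: bottom 0.05 OD, top 2.0 OD, EC50 9.278 ng/ml, hill 1,
#' 2-fold serial dilutions from 1000 ng/ml, noise 5% of span.
#'
#' @return nested list with `$spr` and `$elisa` components
#' @export
fixture_truth <- function() {
  spr <- list(ka = 5.6e4, kd = 0.028, rmax = 100,
              t_assoc = 120, t_total = 320, noise_sd = 2)
  spr$KD_M <- spr$kd / spr$ka
  spr$concs <- spr$KD_M * c(0.1, 0.3, 1, 3, 10)
  elisa <- list(bottom = 0.05, top = 2.0, ec50 = 9.278, hill = 1)
  elisa$concentrations <- 1000 / 2^(0:11)
  elisa$noise_sd <- 0.05 * (elisa$top - elisa$bottom)
  list(spr = spr, elisa = elisa)
}

#' Generate a complete synthetic fixture set
#'
#' Writes, under `dir`: `protein.fasta` (a random mucin-like tandem-repeat
#' protein), `elisa_curve.csv` (a dose-response curve simulated from known
#' 4PL parameters), `sensorgrams.csv` (long-format 1:1 Langmuir sensorgrams
#' at several analyte concentrations), and `truth.json` (the generating
#' parameters, for recovery tests). Byte-identical output for the same seed
#' and spec.
#'
#' @param dir output directory (created if missing)
#' @param seed master seed; sub-seeds for each stochastic component are
#'   derived as small offsets
#' @param unit_length,n_sites,copies repeat-protein geometry
#' @param truth generating parameters, as from [fixture_truth()]
#' @return invisibly, a list with the generated objects and file paths
#' @export
generate_fixture <- function(dir, seed = 1L, unit_length = 20L, n_sites = 5L,
                             copies = 3L, truth = fixture_truth()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  unit <- random_repeat_unit(unit_length, n_sites, seed = seed)
  protein <- make_tandem_repeat(unit, copies, id = "synthetic_mucin")
  fa <- file.path(dir, "protein.fasta")
  write_fasta(stats::setNames(as.character(protein), "synthetic_mucin"), fa)

  el <- truth$elisa
  curve <- simulate_elisa_curve(el$concentrations, el$bottom, el$top,
                                el$ec50, el$hill,
                                noise_sd = el$noise_sd, seed = seed + 1L)
  names(curve) <- c("concentration_ng_ml", "response")
  el_path <- file.path(dir, "elisa_curve.csv")
  utils::write.csv(curve, el_path, row.names = FALSE)

  sp <- truth$spr
  grams <- lapply(seq_along(sp$concs), function(i) {
    simulate_sensorgram(sp$ka, sp$kd, sp$concs[i], sp$rmax,
                        t_assoc = sp$t_assoc, t_total = sp$t_total,
                        noise_sd = sp$noise_sd, seed = seed + 1L + i)
  })
  long <- do.call(rbind, lapply(seq_along(grams), function(i) {
    g <- grams[[i]]
    data.frame(curve_id = i, conc_M = g$conc, time_s = g$time,
               response_RU = g$response)
  }))
  sg_path <- file.path(dir, "sensorgrams.csv")
  utils::write.csv(long, sg_path, row.names = FALSE)

  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(seed = seed, unit = unit, copies = copies,
         spr = sp[c("ka", "kd", "rmax", "t_assoc", "t_total", "noise_sd")],
         spr_KD_nM = kd_from_rates(sp$ka, sp$kd),
         elisa = el[c("bottom", "top", "ec50", "hill", "noise_sd")]),
    truth_path, auto_unbox = TRUE, digits = NA)

  invisible(list(
    unit = unit, protein = protein, elisa_curve = curve, sensorgrams = grams,
    truth = truth,
    paths = c(protein = fa, elisa = el_path, sensorgrams = sg_path,
              truth = truth_path)
  ))
}
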