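test_that("epitope rendering inserts (StateName) after the modified residue", {
  expect_equal(render_epitope(epitope("RPAPGSTAPPAHG", c("6" = "GalNAc"))),
               "RPAPGS(GalNAc)TAPPAHG")
  expect_equal(render_epitope(epitope("PAHGVTSAPD", c("6" = "GalNAc"))),
               "PAHGVT(GalNAc)SAPD")
  expect_equal(render_epitope(epitope("PAHGVTSAPD", c("7" = "GalNAc"))),
               "PAHGVTS(GalNAc)APD")
  expect_equal(render_epitope(epitope("RPAPGSTAPPAHG")), "RPAPGSTAPPAHG")
  # two adjacent sites, distinct states
  expect_equal(
    render_epitope(epitope("RPAPGSTAPPAHG",
                           c("6" = "GalNAc", "7" = "NeuAc-GalNAc"))),
    "RPAPGS(GalNAc)T(NeuAc-GalNAc)APPAHG")
})

test_that("annotations on non-S/T residues are rejected", {
  expect_error(epitope("RPAPGSTAPPAHG", c("1" = "GalNAc")),
               class = "glycoforge_validation_error")
  expect_error(parse_epitope("RP(GalNAc)APGSTAPPAHG"),
               class = "glycoforge_validation_error")
})

test_that("parsing recovers positions, states and the bare peptide", {
  e <- parse_epitope("PAHGVTS(GalNAc)APD")
  expect_equal(e$peptide, "PAHGVTSAPD")
  expect_equal(e$annotations, c("7" = "GalNAc"))
  bare <- parse_epitope("RPAPGSTAPPAHG")
  expect_length(bare$annotations, 0L)
  err <- expect_error(parse_epitope("RPAPGS(Foo)TAPPAHG"),
                      class = "glycoforge_validation_error")
  expect_match(conditionMessage(err), "'Foo'")
  expect_error(parse_epitope("RPAPGS(GalNAcTAPPAHG"),
               class = "glycoforge_validation_error")
  expect_error(parse_epitope("(GalNAc)RPAPGS"),
               class = "glycoforge_validation_error")
})

test_that("render and parse are mutual inverses on random epitopes", {
  set.seed(421)
  alpha <- alphabet_tn_stn()
  for (i in seq_len(2000)) {
    e <- random_epitope(alpha)
    p <- parse_epitope(render_epitope(e), alpha,
                       window_origin = e$window_origin)
    if (!identical(p, e)) {
      fail(sprintf("round-trip broke for '%s'", render_epitope(e)))
    }
  }
  succeed()
})

test_that("centered windows put the site near the window middle and clip by shifting", {
  tr <- make_tandem_repeat(muc1_unit(), 2)
  sites <- identify_glycosites(muc1_unit())
  gf <- glycoform(sites, c(1, 0, 0, 0, 0), alphabet_tn())
  w <- extract_windows(tr, gf, 13, "centered")
  expect_length(w, 2L)  # one per repeat copy
  rendered <- vapply(w, render_epitope, character(1))
  expect_true("RPAPGS(GalNAc)TAPPAHG" %in% rendered)  # terminus-clipped window
  expect_equal(w[[1]]$window_origin, 1L)
  # interior occurrence: modified residue lands at position ceiling(13/2) = 7
  expect_equal(w[[2]]$window_origin, 26L - 6L)
  expect_equal(names(w[[2]]$annotations), "7")

  two <- glycoform(sites, c(1, 0, 0, 1, 0), alphabet_tn())
  expect_length(extract_windows(make_tandem_repeat(muc1_unit(), 1), two,
                                13, "centered"), 2L)
})

test_that("a window of full protein length is the protein itself", {
  tr <- make_tandem_repeat(muc1_unit(), 1)
  gf <- glycoform(identify_glycosites(muc1_unit()), c(0, 1, 0, 0, 0),
                  alphabet_tn())
  w <- extract_windows(tr, gf, 20, "centered")
  expect_length(unique_epitopes(w), 1L)
  expect_equal(w[[1]]$peptide, muc1_unit())
  expect_error(extract_windows(tr, gf, 21), class = "glycoforge_validation_error")
  expect_error(extract_windows(tr, gf, 4), class = "glycoforge_validation_error")
})

test_that("tiled windows each contain at least one occupied site", {
  tr <- make_tandem_repeat(muc1_unit(), 2)
  gf <- glycoform(identify_glycosites(muc1_unit()), c(0, 0, 1, 0, 0),
                  alphabet_tn())
  w <- extract_windows(tr, gf, 9, "tiled")
  expect_true(all(vapply(w, function(e) length(e$annotations) > 0, logical(1))))
  origins <- vapply(w, function(e) e$window_origin, integer(1))
  expect_true(!is.unsorted(origins))
})

test_that("tandem-repeat periodicity makes the unique window set independent of copy number", {
  sites <- identify_glycosites(muc1_unit())
  gf <- glycoform(sites, c(1, 0, 1, 0, 1), alphabet_tn())
  lib3 <- unique_epitopes(extract_windows(make_tandem_repeat(muc1_unit(), 3),
                                          gf, 13, "tiled"))
  lib5 <- unique_epitopes(extract_windows(make_tandem_repeat(muc1_unit(), 5),
                                          gf, 13, "tiled"))
  expect_setequal(vapply(lib3, render_epitope, character(1)),
                  vapply(lib5, render_epitope, character(1)))
})

test_that("deduplication is stable and keeps state-distinct epitopes apart", {
  a <- epitope("RPAPGSTAPPAHG", c("6" = "GalNAc"), window_origin = 1L)
  b <- epitope("RPAPGSTAPPAHG", c("6" = "GalNAc"), window_origin = 21L)
  c_ <- epitope("RPAPGSTAPPAHG", c("6" = "NeuAc-GalNAc"))
  u <- unique_epitopes(list(a, b, c_))
  expect_length(u, 2L)
  expect_equal(u[[1]]$window_origin, 1L)  # first occurrence retained
  expect_length(unique_epitopes(list()), 0L)
})

test_that("a whole-unit window library has exactly k^n - 1 members", {
  tr <- make_tandem_repeat(muc1_unit(), 1)
  lib2 <- epitope_library(tr, alphabet_tn(), window_len = 20)
  expect_length(lib2, 2^5 - 1)
  lib3 <- epitope_library(tr, alphabet_tn_stn(), window_len = 20)
  expect_length(lib3, 3^5 - 1)
})
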