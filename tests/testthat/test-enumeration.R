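test_that("glycosite scan finds every S/T position in order", {
  s <- identify_glycosites("RPAPGSTAPPAHGVTSAPDT")
  expect_equal(s$position, c(6L, 7L, 15L, 16L, 20L))
  expect_equal(s$residue, c("S", "T", "T", "S", "T"))
  h <- identify_glycosites("HGVTSAPDTRPAPGSTAPPA")
  expect_equal(h$position, c(4L, 5L, 9L, 15L, 16L))
  expect_equal(h$residue, c("T", "S", "T", "S", "T"))
  expect_equal(nrow(identify_glycosites("AAAA")), 0L)
})

test_that("enumeration yields k^n - 1 glycoforms and matches the brute-force oracle", {
  sites5 <- identify_glycosites(muc1_unit())
  expect_length(enumerate_glycoforms(sites5, alphabet_tn()), 31L)
  expect_length(enumerate_glycoforms(sites5, alphabet_tn_stn()), 242L)
  expect_length(enumerate_glycoforms(1, alphabet_tn()), 1L)

  fake_k3 <- alphabet_tn_stn()
  fake_k4 <- alphabet_binding()
  for (n in 1:6) {
    for (alpha in list(alphabet_tn(), fake_k3, fake_k4)) {
      k <- n_states(alpha)
      gfs <- enumerate_glycoforms(n, alpha)
      keys <- vapply(gfs, glycoform_key, character(1))
      expect_length(gfs, k^n - 1)
      expect_false(anyDuplicated(keys) > 0)
      expect_setequal(keys, oracle_enumerate(n, k))
      expect_false(strrep("0", n) %in% keys)  # unmodified form excluded
    }
  }
})

test_that("the unmodified form is reportable via include_unmodified", {
  gfs <- enumerate_glycoforms(3, alphabet_tn(), include_unmodified = TRUE)
  expect_length(gfs, 8L)
  expect_equal(occupancy(gfs[[1]]), 0L)
})

test_that("counter order is literal base-k integer order and occupancy order groups by load", {
  gfs <- enumerate_glycoforms(3, alphabet_tn(), order = "counter")
  keys <- vapply(gfs, glycoform_key, character(1))
  expect_equal(keys, oracle_enumerate(3, 2))  # oracle iterates 1..k^n-1
  occ_gfs <- enumerate_glycoforms(4, alphabet_tn_stn(), order = "occupancy")
  occs <- vapply(occ_gfs, occupancy, integer(1))
  expect_true(!is.unsorted(occs))
  expect_setequal(vapply(occ_gfs, glycoform_key, character(1)),
                  oracle_enumerate(4, 3))
})

test_that("enumeration size is strictly monotone in sites and alphabet size", {
  sizes_n <- vapply(1:5, function(n) length(enumerate_glycoforms(n, alphabet_tn())),
                    integer(1))
  expect_true(all(diff(sizes_n) > 0))
  for (n in c(2, 4)) {
    expect_lt(length(enumerate_glycoforms(n, alphabet_tn())),
              length(enumerate_glycoforms(n, alphabet_tn_stn())))
    expect_lt(length(enumerate_glycoforms(n, alphabet_tn_stn())),
              length(enumerate_glycoforms(n, alphabet_binding())))
  }
})

test_that("size guard refuses combinatorial explosions and is configurable", {
  err <- expect_error(enumerate_glycoforms(25, alphabet_tn()),
                      class = "glycoforge_validation_error")
  expect_match(conditionMessage(err), "size guard")
  expect_error(enumerate_glycoforms(15, alphabet_tn_stn()),
               class = "glycoforge_validation_error")
  # both guard knobs are configuration, enforced independently
  expect_error(enumerate_glycoforms(4, alphabet_tn(), max_bits = 3),
               class = "glycoforge_validation_error")
  expect_length(enumerate_glycoforms(4, alphabet_tn(), max_bits = 4), 15L)
  expect_error(enumerate_glycoforms(3, alphabet_binding(), max_states = 3),
               class = "glycoforge_validation_error")
})

test_that("isomer counts follow choose(n, m) (k-1)^m and sum to k^n - 1", {
  expect_equal(count_isomers(5, 1, 2), 5)
  expect_equal(count_isomers(5, 2, 2), 10)
  expect_equal(count_isomers(5, 0, 3), 1)
  # brute-force cross-check: ternary vectors with exactly 2 nonzero digits
  keys <- oracle_enumerate(5, 3)
  nz <- vapply(strsplit(keys, ""), function(d) sum(d != "0"), integer(1))
  expect_equal(count_isomers(5, 2, 3), sum(nz == 2))  # 40
  for (n in 1:8) {
    for (k in 2:4) {
      expect_equal(sum(count_isomers(n, 1:n, k)), k^n - 1)
    }
  }
  expect_error(count_isomers(5, 6, 2), class = "glycoforge_validation_error")
  expect_error(count_isomers(5, -1, 2), class = "glycoforge_validation_error")
})

test_that("occupancy matrix stacks state vectors with unique, non-zero columns", {
  sites <- identify_glycosites(muc1_unit())
  bin <- enumerate_glycoforms(sites, alphabet_tn())
  m <- occupancy_matrix(bin)
  expect_equal(dim(m), c(5L, 31L))
  expect_true(all(m %in% 0:1))
  expect_equal(sort(unique(colSums(m))), 1:5)
  expect_false(any(colSums(m != 0) == 0))
  expect_equal(rownames(m), c("S6", "T7", "T15", "S16", "T20"))

  ter <- occupancy_matrix(enumerate_glycoforms(sites, alphabet_tn_stn()))
  expect_equal(dim(ter), c(5L, 242L))
  expect_true(all(colSums(ter != 0) >= 1))
  expect_equal(anyDuplicated(apply(ter, 2, paste, collapse = ",")), 0L)

  single <- occupancy_matrix(list(glycoform(sites, c(1, 0, 0, 0, 0), alphabet_tn())))
  expect_equal(dim(single), c(5L, 1L))
  expect_equal(sum(single != 0), 1L)

  other <- glycoform(identify_glycosites("APSAT"), c(1, 0), alphabet_tn())
  expect_error(occupancy_matrix(c(bin[1], list(other))),
               class = "glycoforge_validation_error")
})

test_that("long-format table carries one row per glycoform-site pair", {
  gfs <- enumerate_glycoforms(identify_glycosites(muc1_unit()), alphabet_tn())
  tab <- glycoforms_to_table(gfs)
  expect_equal(nrow(tab), 31L * 5L)
  expect_setequal(unique(tab$state_name), c("UNOCCUPIED", "GalNAc"))
  expect_equal(sum(tab$state), sum(occupancy_matrix(gfs)))
})
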