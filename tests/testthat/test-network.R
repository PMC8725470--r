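# parsing, CRNT matrix construction and the two rhs constructions

test_that("the Edelstein reaction list parses to the documented structure", {
  fx <- edelstein_fixture()
  expect_length(fx$net$species, 3L)
  expect_equal(nrow(fx$net$reactions), 6L)
  expect_length(fx$net$complexes, 5L)
  keys <- vapply(fx$net$complexes, crnbistab:::complex_key, character(1))
  expect_setequal(keys, c("1*A", "2*A", "1*A+1*B", "1*C", "1*B"))
  expect_equal(fx$m$s, 2L)
  expect_equal(fx$m$lam, 1L)
  # psi exponents follow the molecularity matrix
  expect_equal(fx$m$psi_exponents, t(fx$m$Y))
})

test_that("a minimal one-reaction network has the expected matrices", {
  net <- parse_network("A -> B")
  m <- build_crnt_matrices(net)
  expect_equal(length(net$species), 2L)
  expect_equal(unname(m$S[, 1]), c(-1, 1))
  expect_equal(m$s, 1L)
  expect_equal(m$lam, 1L)
})

test_that("reversible reactions expand forward-then-backward with fresh
           rate symbols, in text and SBML", {
  net <- parse_network(c("A <-> B"))
  expect_equal(nrow(net$reactions), 2L)
  expect_equal(net$reactions$rate, c("k1", "k2"))
  expect_equal(net$reactions$source, rev(net$reactions$target))
  sb <- parse_network(system.file("extdata", "edelstein_sbml.xml",
                                  package = "crnbistab"))
  txt <- edelstein_network()
  expect_equal(sb$species, txt$species)
  expect_equal(sb$reactions, txt$reactions)
  expect_equal(vapply(sb$complexes, crnbistab:::complex_key, character(1)),
               vapply(txt$complexes, crnbistab:::complex_key, character(1)))
})

test_that("complex identity is multiset equality, not string equality", {
  net <- parse_network(c("A + B -> C", "C -> B + A"))
  expect_length(net$complexes, 2L)
})

test_that("malformed input is rejected with informative errors", {
  expect_error(parse_network("A + -> B"), "dangling")
  expect_error(parse_network(" -> "), "empty|cannot parse")
  expect_error(parse_network("A -> A"), "identical source")
  expect_error(parse_network(character(0)), "no reactions")
})

test_that("the CRNT construction Y A psi equals the stoichiometric
           construction S times mass-action rates, and columns of A sum to
           zero", {
  nets <- c(list(edelstein_network(), futile_cycle_network()),
            lapply(1:6, function(s)
              generate_random_network(5L, 5L, seed = s)))
  for (net in nets) {
    m <- build_crnt_matrices(net)
    f_s <- crnbistab:::mass_action_rhs(m)
    f_ya <- crnbistab:::yapsi_rhs(m)
    for (i in seq_along(f_s))
      expect_true(crnbistab:::cp_equal(f_s[[i]], f_ya[[i]]))
    M <- ncol(m$Y)
    for (j in seq_len(M)) {
      colsum <- crnbistab:::cp_sum(lapply(seq_len(M), function(i)
        crnbistab:::cpm_get(m$A, i, j)))
      expect_true(crnbistab:::cp_is_zero(colsum))
    }
  }
})

test_that("exact rational rank agrees with a brute-force minor search", {
  set.seed(7)
  for (i in 1:15) {
    M <- matrix(sample(-2:2, 20, replace = TRUE), 4L, 5L)
    expect_equal(crnbistab:::rat_rank(M), minor_rank(M))
  }
})

test_that("matrix export writes labelled CSV files", {
  fx <- edelstein_fixture()
  dir <- withr::local_tempdir()
  paths <- export_crnt_csv(fx$m, dir)
  expect_true(all(file.exists(paths)))
  Yin <- utils::read.csv(file.path(dir, "Y.csv"), row.names = 1,
                         check.names = FALSE)
  expect_equal(rownames(Yin), fx$net$species)
  expect_equal(unname(as.matrix(Yin)), unname(fx$m$Y))
})
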