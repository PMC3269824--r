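test_that("descriptor counting matches the stated definitions", {
  d <- count_descriptors(toy_butane()$molecule)
  expect_equal(d, list(nha = 4L, rb = 1L, nara = 0L))

  d <- count_descriptors(toy_benzene()$molecule)
  expect_equal(d, list(nha = 6L, rb = 0L, nara = 0L))

  d <- count_descriptors(toy_cyclohexane()$molecule)
  expect_equal(d, list(nha = 6L, rb = 0L, nara = 6L))

  # amide C-N excluded from rb under the default convention
  # (N-methylacetamide: the C(=O)-N bond is non-terminal)
  nma <- molecule(c("C", "C", "O", "N", "C"),
                  data.frame(a1 = c(1, 2, 2, 4), a2 = c(2, 3, 4, 5),
                             order = c(1, 2, 1, 1)))
  expect_equal(count_descriptors(nma)$rb, 0L)
  cfg <- eligibility_config(exclude_amide_rb = FALSE)
  expect_equal(count_descriptors(nma, cfg)$rb, 1L)
})

test_that("effective rotor count follows rb + nara / 5 exactly", {
  expect_identical(effective_rotor_count(0, 0), 0)
  expect_identical(effective_rotor_count(11, 0), 11)
  expect_identical(effective_rotor_count(2, 5), 3)
  expect_error(effective_rotor_count(-1, 0), "non-negative")
})

linear_alkane <- function(n) {
  molecule(rep("C", n),
           if (n > 1) data.frame(a1 = seq_len(n - 1), a2 = 2:n, order = 1))
}

test_that("all six coverage rules are evaluated with exact boundaries", {
  expect_true(check_eligibility(toy_methane()$molecule)$eligible)

  # size boundary isolated from flexibility: 50 heavy atoms pass, 51 fail
  loose_rb <- eligibility_config(max_rb = 1000L)
  expect_true(check_eligibility(linear_alkane(50), loose_rb)$eligible)
  r51 <- check_eligibility(linear_alkane(51), loose_rb)
  expect_false(r51$eligible)
  expect_true("too_large" %in% r51$failed_rules[[1]])
  # under production thresholds the same chain is also too flexible
  r51d <- check_eligibility(linear_alkane(51))
  expect_setequal(r51d$failed_rules[[1]], c("too_large", "too_flexible"))

  boron <- molecule(c("B", "F", "F", "F"),
                    data.frame(a1 = 1, a2 = 2:4, order = 1))
  expect_true("unsupported_element" %in%
                check_eligibility(boron)$failed_rules[[1]])

  salt <- molecule(c("C", "C", "O", "O", "Na"),
                   data.frame(a1 = c(1, 2, 2), a2 = c(2, 3, 4),
                              order = c(1, 2, 1)),
                   formal_charge = c(0, 0, 0, -1, 1))
  expect_true("multi_component" %in%
                check_eligibility(salt)$failed_rules[[1]])

  # stereo boundary reads "fewer than six"
  m5 <- molecule(rep("C", 2), data.frame(a1 = 1, a2 = 2, order = 1),
                 undefined_stereo_count = 5)
  m6 <- molecule(rep("C", 2), data.frame(a1 = 1, a2 = 2, order = 1),
                 undefined_stereo_count = 6)
  expect_true(check_eligibility(m5)$eligible)
  expect_true("excess_undefined_stereo" %in%
                check_eligibility(m6)$failed_rules[[1]])

  # over-coordinated carbon fails force-field typing
  crowded <- molecule(rep("C", 6),
                      data.frame(a1 = 1, a2 = 2:6, order = 1))
  expect_true("unsupported_atom_type" %in%
                check_eligibility(crowded)$failed_rules[[1]])
})

test_that("er is monotone in chain growth", {
  ers <- vapply(3:10, function(n) {
    d <- count_descriptors(linear_alkane(n))
    effective_rotor_count(d$rb, d$nara)
  }, numeric(1))
  expect_true(all(diff(ers) >= 0))
})
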