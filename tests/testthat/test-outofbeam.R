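unit_raw <- function(organ = "Kidneys", value = 0.01) {
  data.frame(organ = organ, distance_cm = 10,
             boron_per_ppm = value / 75,  # so boron dose = value * t
             thermal_n = value, fast_n = value, gamma = value,
             mean_neutron_energy_ev = 1e3)
}

test_that("organ records weight components with the organ's tissue factors", {
  # kidney factors (1, 3.2, 1.3), unit components:
  # DEq = 1 + 3.2*2 + 1.3 = 8.7 per unit absorbed dose
  raw <- unit_raw(value = 0.01)
  tab <- assemble_organ_table(raw, t_irr = 1)
  expect_equal(tab$DEq_cGyEq, 0.01 * 8.7 * 100)
  expect_equal(tab$DB_cGy, 1)  # 0.01/75 * 75ppm * 1 min * 100
  expect_equal(tab$DW_cSv,
               (0.01 * 20 + 0.02 * neutron_wr(1e3) + 0.01) * 100)
  # zero components give an all-zero table
  z <- unit_raw(value = 0)
  tz <- assemble_organ_table(z, t_irr = 30)
  expect_equal(tz$DEq_cGyEq, 0)
  expect_equal(tz$DW_cSv, 0)
})

test_that("every record matches a per-record oracle on a 19-organ input", {
  raw <- generate_organ_doses(default_spectrum(), default_organ_set(),
                              dose_kernel_params())
  t_irr <- 24.5
  tab <- assemble_organ_table(raw, t_irr = t_irr)
  tissues <- default_tissue_table()
  for (i in seq_len(nrow(raw))) {
    tis <- bnctbeams:::lookup_tissue(raw$organ[i], tissues)
    deq <- (raw$gamma[i] * tis$rbe_gamma +
              (raw$thermal_n[i] + raw$fast_n[i]) * tis$rbe_neutron +
              raw$boron_per_ppm[i] * tis$boron_ppm * tis$cbe_boron) *
      t_irr * 100
    expect_equal(tab$DEq_cGyEq[i], deq)
  }
})

test_that("organ tables scale linearly with irradiation time", {
  raw <- generate_organ_doses(default_spectrum(), default_organ_set(),
                              dose_kernel_params())
  t1 <- assemble_organ_table(raw, t_irr = 10)
  t2 <- assemble_organ_table(raw, t_irr = 20)
  for (col in c("DN_cGy", "DB_cGy", "DH_cGy", "Dgamma_cGy", "DW_cSv",
                "DEq_cGyEq"))
    expect_equal(t2[[col]], 2 * t1[[col]])
})

test_that("uncertainties propagate in quadrature when relative errors are given", {
  raw <- unit_raw(value = 0.01)
  tab <- assemble_organ_table(raw, t_irr = 1,
                              rel_err = c(boron = 0.02, thermal_n = 0.02,
                                          fast_n = 0.02, gamma = 0.02))
  parts <- c(0.01 * 1.3, 0.01 * 3.2, 0.01 * 3.2, 0.01 * 1)
  expect_equal(tab$DEq_err_cGyEq, sqrt(sum((parts * 0.02)^2)) * 100)
  expect_true(is.na(assemble_organ_table(raw, t_irr = 1)$DEq_err_cGyEq))
})

test_that("out-of-field summary honors the in-field set and the statistic", {
  raw <- generate_organ_doses(default_spectrum(), default_organ_set(),
                              dose_kernel_params())
  tab <- assemble_organ_table(raw, t_irr = 24.5)
  in_field <- c("brain", "head", "pharynx", "thyroid")
  out <- tab[!(tolower(tab$organ) %in% in_field), ]
  expect_equal(out_of_field_summary(tab), sum(out$DEq_cGyEq))
  expect_equal(out_of_field_summary(tab, statistic = "max"),
               max(out$DEq_cGyEq))
  expect_equal(out_of_field_summary(tab, statistic = "mean"),
               mean(out$DEq_cGyEq))
  # a single out-of-field organ is its own summary
  one <- tab[tab$organ %in% c("Brain", "Bladder"), ]
  expect_equal(out_of_field_summary(one),
               one$DEq_cGyEq[one$organ == "Bladder"])
  expect_error(out_of_field_summary(one, in_field = tolower(one$organ)),
               "no out-of-field")
})

test_that("organ-wise dominance implies summary dominance for every statistic", {
  raw_a <- generate_organ_doses(
    default_spectrum(beam_model_params(total_flux = 5e8)),
    default_organ_set(), dose_kernel_params())
  raw_b <- generate_organ_doses(
    default_spectrum(beam_model_params(total_flux = 2e9)),
    default_organ_set(), dose_kernel_params())
  ta <- assemble_organ_table(raw_a, t_irr = 20)
  tb <- assemble_organ_table(raw_b, t_irr = 20)
  expect_true(all(ta$DEq_cGyEq <= tb$DEq_cGyEq))
  for (s in c("sum", "max", "mean"))
    expect_lte(out_of_field_summary(ta, statistic = s),
               out_of_field_summary(tb, statistic = s))
})

test_that("safest-beam selection is the argmin with documented tie-breaks", {
  expect_equal(select_safest_beam(c(only = 3.2)), "only")
  expect_equal(select_safest_beam(c(a = 10, b = 5, c = 7)), "b")
  # tie on the statistic: higher UTCP wins
  expect_equal(select_safest_beam(c(a = 5, b = 5),
                                  utcps = c(a = 0.4, b = 0.45)), "b")
  # full tie: lexicographic id
  expect_equal(select_safest_beam(c(b = 5, a = 5)), "a")
  expect_error(select_safest_beam(numeric(0)), "empty")
  # exhaustive oracle over a dominated synthetic set of 5 beams
  stats <- c(b1 = 9.1, b2 = 4.4, b3 = 6.0, b4 = 4.5, b5 = 12)
  expect_equal(select_safest_beam(stats),
               names(stats)[which.min(stats)])
})
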