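test_that("packaged meropenem config reproduces the published input values", {
  d <- tbl2_params$drug
  expect_equal(d$molecular_weight, 383.46)
  expect_equal(d$pka_acid, 3.47)
  expect_equal(d$pka_base, 9.39)
  expect_equal(d$logP, 1.25)
  expect_equal(d$water_solubility, 5.63)
  expect_equal(d$fu, 0.98)           # 98% unit-normalised to a fraction
  expect_identical(d$binding_partner, "albumin")
  expect_equal(d$gfr_fraction, 1.00)
  pr <- tbl2_params$processes
  expect_equal(pr$DPEP1$km, 3560)    # 3.56 mM -> umol/L
  expect_equal(pr$DPEP1$vmax, 79.34)
  expect_equal(pr$OAT3$km, 847)
  expect_equal(pr$OAT3$vmax, 18156.72)
  expect_equal(pr$NPT1$km, 755.89)
  expect_equal(pr$NPT1$vmax, 57.64)
  expect_identical(pr$OAT3$direction, "uptake_basolateral")
  expect_identical(pr$NPT1$direction, "efflux_apical")
  expect_identical(pr$DPEP1$direction, "metabolism_intracellular")
})

test_that("parameter validation rejects invalid kinetics and missing keys", {
  expect_error(mm_process("OAT3", km = 847, vmax = -1,
                          direction = "uptake_basolateral"),
               "vmax")
  expect_error(mm_process("OAT3", km = 0, vmax = 1,
                          direction = "uptake_basolateral"), "km")
  expect_error(drug_parameters(383, 3.5, 9.4, 1.2, 5.6, fu = 0), "fu")
  expect_error(drug_parameters(383, 3.5, 9.4, 1.2, 5.6, fu = 0.9,
                               gfr_fraction = -1), "gfr_fraction")
  cfg <- yaml::read_yaml(meropbpk_config("meropenem.yaml"))
  cfg$drug$fu <- NULL
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, tmp)
  expect_error(load_drug_parameters(tmp), "fu")
  expect_error(load_drug_parameters(tempfile()), "not found")
})

test_that("loading then serializing reproduces values to 6 significant digits", {
  tmp <- tempfile(fileext = ".yaml")
  write_drug_parameters(tbl2_params, tmp)
  back <- load_drug_parameters(tmp)
  for (f in c("molecular_weight", "pka_acid", "pka_base", "logP",
              "water_solubility", "fu", "gfr_fraction")) {
    expect_equal(back$drug[[f]], tbl2_params$drug[[f]], tolerance = 1e-6)
  }
  for (nm in names(tbl2_params$processes)) {
    expect_equal(back$processes[[nm]]$km, tbl2_params$processes[[nm]]$km,
                 tolerance = 1e-6)
    expect_equal(back$processes[[nm]]$vmax,
                 tbl2_params$processes[[nm]]$vmax, tolerance = 1e-6)
  }
})

test_that("reference adult matches its demographic and renal definition", {
  expect_equal(ref_phys$weight_kg, 73)
  expect_equal(ref_phys$height_cm, 176)
  expect_equal(ref_phys$age, 30)
  expect_equal(ref_phys$egfr_normalised, 106.78)
  # absolute GFR consistent with the normalised eGFR after BSA conversion
  expect_equal(ref_phys$gfr_mL_min,
               106.78 * bsa_dubois(73, 176) / 1.73)
  flows <- c(ref_phys$organs$blood_flow_L_min,
             ref_phys$kidney_blood_flow_L_min)
  expect_equal(sum(flows), ref_phys$cardiac_output_L_min,
               tolerance = 1e-9)
  expect_silent(validate_physiology(ref_phys))
})

test_that("partition coefficients follow the documented composition scheme", {
  # a neutral drug with logP 0 and fu 1 distributes into tissue water
  neutral <- drug_parameters(300, NA, NA, logP = 0, 5, fu = 1,
                             binding_partner = "none")
  kp <- partition_coefficients(neutral, ref_phys)
  expect_true(all(kp > 0))
  # coefficient tracks the total tissue water fraction (muscle: 0.76)
  expect_equal(unname(kp["muscle"]), 0.76 / 0.945, tolerance = 0.05)
  # halving fu halves every coefficient (unbound-driven scaling)
  half <- neutral; half$fu <- 0.5
  expect_equal(unname(partition_coefficients(half, ref_phys)),
               unname(kp) / 2, tolerance = 1e-12)
  # coefficients are scale-free in organ volumes
  phys2 <- ref_phys
  phys2$organs$volume_L <- phys2$organs$volume_L * 3
  expect_identical(partition_coefficients(cal_params$drug, phys2),
                   partition_coefficients(cal_params$drug, ref_phys))
  # fu = 0 is rejected (division by zero in unbound scaling)
  zero <- neutral; zero$fu <- 0
  expect_error(partition_coefficients(zero, ref_phys), "fu")
  # meropenem is almost fully ionised: near-extracellular distribution
  kp_mero <- partition_coefficients(cal_params$drug, ref_phys)
  expect_lt(kp_mero[["muscle"]], 0.2)
})
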