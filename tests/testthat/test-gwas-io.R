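test_that("read_gwas_table reads well-formed tables and normalizes alleles", {
  tbl <- assoc_tbl(c("rs1", "rs2"), ea = c("a", "T"), oa = c("g", "C"),
                   beta = c(0.1, -0.2), se = c(0.01, 0.02))
  path <- write_assoc_tsv(tbl)
  got <- read_gwas_table(path)
  expect_equal(nrow(got), 2)
  expect_equal(nrow(rejected_records(got)), 0)
  expect_equal(got$effect_allele, c("A", "T"))
  expect_equal(got$other_allele, c("G", "C"))
  expect_equal(got$beta, c(0.1, -0.2))
})

test_that("read_gwas_table applies a column map", {
  tbl <- tibble::tibble(SNP = "rs1", A1 = "A", A2 = "G", freq = 0.3,
                        b = 0.1, stderr = 0.01, p = 1e-8, N = 1000)
  path <- write_assoc_tsv(tbl)
  got <- read_gwas_table(path, column_map = c(
    variant_id = "SNP", effect_allele = "A1", other_allele = "A2",
    eaf = "freq", beta = "b", se = "stderr", pvalue = "p", n = "N"
  ))
  expect_equal(got$variant_id, "rs1")
  expect_equal(got$se, 0.01)
})

test_that("missing mandatory columns and non-numeric effects raise typed errors", {
  tbl <- tibble::tibble(SNP = "rs1", A1 = "A", A2 = "G", b = 0.1, s = 0.01)
  path <- write_assoc_tsv(tbl)
  expect_error(read_gwas_table(path), class = "tidymr_config_error")

  bad <- tibble::tibble(variant_id = "rs1", effect_allele = "A",
                        other_allele = "G", beta = "oops", se = "0.01")
  path2 <- write_assoc_tsv(bad, name = "bad.tsv")
  expect_error(read_gwas_table(path2), class = "tidymr_parse_error")
  expect_error(read_gwas_table(path2), "row 1")
})

test_that("rows violating invariants are rejected with reasons, not dropped silently", {
  tbl <- tibble::tibble(
    variant_id = c("rs1", "rs2", "rs3", "rs4"),
    effect_allele = c("A", "A", "A", "A"),
    other_allele = c("G", "G", "A", "G"),
    eaf = c(0.3, 0.3, 0.3, 1.2),
    beta = c(0.1, 0.1, 0.1, 0.1),
    se = c(0.01, 0, 0.01, 0.01)
  )
  path <- write_assoc_tsv(tbl)
  got <- read_gwas_table(path)
  rej <- rejected_records(got)
  expect_equal(got$variant_id, "rs1")
  expect_equal(rej$variant_id, c("rs2", "rs3", "rs4"))
  expect_equal(rej$reason[rej$variant_id == "rs2"], "nonpositive se")
  expect_equal(rej$reason[rej$variant_id == "rs3"], "identical alleles")
  expect_equal(rej$reason[rej$variant_id == "rs4"], "eaf outside [0,1]")
})

test_that("z/beta sign disagreement is rejected", {
  tbl <- tibble::tibble(
    variant_id = "rs1", effect_allele = "A", other_allele = "G",
    eaf = 0.3, beta = 0.1, se = 0.01, z = -10
  )
  got <- validate_associations(tbl)
  expect_equal(nrow(got), 0)
  expect_equal(rejected_records(got)$reason, "z and beta disagree in sign")
})

test_that("standardize_from_z matches the closed-form conversion", {
  # null z
  got <- standardize_from_z(0, 0.5, 1000)
  expect_equal(got$beta_sd, 0)
  expect_equal(got$se_sd, 1 / sqrt(500))
  # direct evaluation of the formula
  got2 <- standardize_from_z(5, 0.3, 10000)
  denom <- sqrt(2 * 0.3 * 0.7 * (10000 + 25))
  expect_equal(got2$beta_sd, 5 / denom)
  expect_equal(got2$beta_sd, 0.07706, tolerance = 1e-4)
  expect_equal(got2$se_sd, 0.015412, tolerance = 1e-4)
  # degenerate frequency
  expect_error(standardize_from_z(1, 0, 100),
               class = "tidymr_degenerate_frequency_error")
})

test_that("standardize_from_z preserves the z ratio for random inputs", {
  withr::with_seed(42, {
    for (i in 1:50) {
      z <- rnorm(1, 0, 8)
      eaf <- runif(1, 0.01, 0.99)
      n <- sample(100:1e6, 1)
      got <- standardize_from_z(z, eaf, n)
      expect_equal(got$beta_sd / got$se_sd, z, tolerance = 1e-12)
    }
  })
})

test_that("select_strongest_per_locus keeps the minimum-p record per locus", {
  tbl <- assoc_tbl(
    c("rs2472297", "rs4410790", "rs9999", "rs1111"),
    ea = "A", oa = "G", beta = 0.1, se = 0.01,
    pvalue = c(1.0e-20, 1.8e-13, 1e-8, 1e-12),
    locus = c("CYP1A2", "AHR", "LOC1", "LOC1")
  )
  got <- select_strongest_per_locus(tbl)
  # distinct loci are both retained; within LOC1 only the stronger signal
  expect_setequal(got$variant_id, c("rs2472297", "rs4410790", "rs1111"))

  # exact tie broken by smaller rsID
  tie <- assoc_tbl(c("rsB", "rsA"), ea = "A", oa = "G", beta = 0.1,
                   se = 0.01, pvalue = 1e-8, locus = "L")
  expect_equal(select_strongest_per_locus(tie)$variant_id, "rsA")

  # missing locus label errors
  nolocus <- dplyr::mutate(tbl, locus = NA_character_)
  expect_error(select_strongest_per_locus(nolocus),
               class = "tidymr_labelling_error")
})

test_that("harmonize_pair flips outcome effects reported on the other allele", {
  exposure <- assoc_tbl("rs1", ea = "T", oa = "C", beta = 0.05, se = 0.01,
                        eaf = 0.3)
  outcome <- assoc_tbl("rs1", ea = "C", oa = "T", beta = 0.02, se = 0.01,
                       eaf = 0.7)
  h <- harmonize_pair(exposure, outcome)
  expect_equal(nrow(h), 1)
  expect_equal(h$beta_outcome, -0.02)
  expect_equal(h$eaf_outcome, 0.3)
  expect_equal(h$effect_allele, "T")

  # strand-complement match: outcome reports A/G for exposure T/C
  outcome2 <- assoc_tbl("rs1", ea = "A", oa = "G", beta = 0.02, se = 0.01,
                        eaf = 0.3)
  h2 <- harmonize_pair(exposure, outcome2)
  expect_equal(h2$beta_outcome, 0.02)
})

test_that("ambiguous palindromic variants are dropped, informative ones aligned by frequency", {
  exposure <- assoc_tbl(c("rs1", "rs2"), ea = "A", oa = "T",
                        beta = 0.05, se = 0.01, eaf = c(0.50, 0.10))
  outcome <- assoc_tbl(c("rs1", "rs2"), ea = "A", oa = "T",
                       beta = 0.02, se = 0.01, eaf = c(0.50, 0.88))
  h <- harmonize_pair(exposure, outcome, palindrome_eaf_window = 0.08)
  drops <- dropped_variants(h)
  expect_equal(drops$variant_id, "rs1")
  expect_equal(drops$reason, "palindromic, ambiguous frequency")
  # rs2: exposure eaf 0.10 vs outcome 0.88 -> opposite sides of 0.5, flipped
  expect_equal(h$variant_id, "rs2")
  expect_equal(h$beta_outcome, -0.02)
})

test_that("irreconcilable alleles and unmatched variants are dropped with reasons", {
  exposure <- assoc_tbl(c("rs1", "rs2"), ea = c("A", "A"), oa = c("G", "G"),
                        beta = 0.05, se = 0.01)
  outcome <- assoc_tbl(c("rs1", "rs3"), ea = c("A", "A"), oa = c("C", "G"),
                       beta = 0.02, se = 0.01)
  h <- harmonize_pair(exposure, outcome)
  drops <- dropped_variants(h)
  expect_equal(nrow(h), 0)
  expect_setequal(drops$reason[drops$variant_id == "rs1"], "allele mismatch")
  expect_setequal(drops$variant_id[drops$reason == "unmatched"],
                  c("rs2", "rs3"))
  # no variant appears both retained and dropped
  expect_length(intersect(h$variant_id, drops$variant_id), 0)
})

test_that("harmonization is idempotent and coherent under outcome allele recoding", {
  sim <- simulate_two_sample(sim_config(n_snps = 40, theta = 0.1,
                                        flip_fraction = 0.5, seed = 11))
  h1 <- harmonize_pair(sim$exposure, sim$outcome)
  expect_equal(nrow(h1), 40)

  # idempotence: re-harmonizing the harmonized tables changes nothing
  tabs <- harmonized_to_tables(h1)
  h2 <- harmonize_pair(tabs$exposure, tabs$outcome)
  expect_equal(tibble::as_tibble(h2), tibble::as_tibble(h1))

  # sign coherence: recode every outcome row to the opposite allele
  recoded <- sim$outcome |>
    dplyr::mutate(
      tmp = .data$effect_allele,
      effect_allele = .data$other_allele,
      other_allele = .data$tmp,
      beta = -.data$beta,
      z = -.data$z,
      eaf = 1 - .data$eaf
    ) |>
    dplyr::select(-"tmp")
  h3 <- harmonize_pair(sim$exposure, recoded)
  expect_equal(tibble::as_tibble(h3), tibble::as_tibble(h1))
})
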