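# small in-code fixtures shared across test files

assoc_tbl <- function(variant_id, ea, oa, beta, se, eaf = 0.3,
                      pvalue = NULL, n = 10000, locus = variant_id) {
  tibble::tibble(
    variant_id = variant_id,
    effect_allele = ea, other_allele = oa,
    eaf = eaf, beta = beta, se = se,
    pvalue = pvalue %||% 2 * stats::pnorm(-abs(beta / se)),
    n = n, z = beta / se, locus = locus
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rebuild the raw exposure/outcome tables encoded in a harmonized set, for
# idempotence checks
harmonized_to_tables <- function(h) {
  list(
    exposure = tibble::tibble(
      variant_id = h$variant_id,
      effect_allele = h$effect_allele, other_allele = h$other_allele,
      eaf = h$eaf_exposure, beta = h$beta_exposure, se = h$se_exposure
    ),
    outcome = tibble::tibble(
      variant_id = h$variant_id,
      effect_allele = h$effect_allele, other_allele = h$other_allele,
      eaf = h$eaf_outcome, beta = h$beta_outcome, se = h$se_outcome
    )
  )
}

write_assoc_tsv <- function(tbl, dir = withr::local_tempdir(.local_envir = parent.frame()),
                            name = "table.tsv") {
  path <- file.path(dir, name)
  readr::write_tsv(tbl, path)
  path
}

# printed study-level odds ratios used in desk-reproduction tests:
# FinnGen 0.77 (0.70-0.85), DIAMANTE 0.84 (0.78-0.91)
t2d_printed_estimates <- function() {
  dplyr::bind_rows(
    dplyr::mutate(or_ci_to_log(0.77, 0.70, 0.85), study = "FinnGen"),
    dplyr::mutate(or_ci_to_log(0.84, 0.78, 0.91), study = "DIAMANTE")
  )
}
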