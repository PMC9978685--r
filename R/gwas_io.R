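#' Read a GWAS summary-statistic table
#'
#' Reads a delimited text file of per-variant association statistics into a
#' validated tibble with the standard column set used throughout tidymr:
#' `variant_id`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#' `pvalue`, `n`, and optionally `z` and `locus`. Rows violating basic
#' invariants (non-positive standard error, effect-allele frequency outside
#' \[0, 1\], identical alleles, p-value outside (0, 1\]) are removed from the
#' returned table but kept, with a reason, in the `rejected` attribute —
#' retrievable with [rejected_records()] — so that no record is silently lost.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector mapping standard names to the
#'   file's column names, e.g. `c(variant_id = "SNP", beta = "b")`. Standard
#'   names absent from the map are assumed to appear verbatim in the file.
#' @param delim Field delimiter, tab by default.
#' @return A tibble of validated associations (class `gwas_tbl`), alleles
#'   upper-cased, with attribute `rejected`: a tibble of
#'   (`row`, `variant_id`, `reason`).
#' @export
read_gwas_table <- function(path, column_map = NULL, delim = "\t") {
  raw <- readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  std <- c(
    "variant_id", "effect_allele", "other_allele", "eaf",
    "beta", "se", "pvalue", "n", "z", "locus"
  )
  map <- setNames(std, std)
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), std)
    if (length(unknown) > 0) {
      abort(paste0(
        "column_map names must be standard field names; unknown: ",
        paste(unknown, collapse = ", ")
      ), class = "tidymr_config_error")
    }
    map[names(column_map)] <- unname(column_map)
  }
  mandatory <- c("variant_id", "effect_allele", "other_allele", "beta", "se")
  missing <- mandatory[!map[mandatory] %in% names(raw)]
  if (length(missing) > 0) {
    abort(paste0(
      "mandatory column(s) not found in ", path, ": ",
      paste(map[missing], collapse = ", ")
    ), class = "tidymr_config_error")
  }

  out <- tibble::tibble(
    variant_id = raw[[map["variant_id"]]],
    effect_allele = toupper(raw[[map["effect_allele"]]]),
    other_allele = toupper(raw[[map["other_allele"]]])
  )
  num_field <- function(field, required = FALSE) {
    col <- map[[field]]
    if (!col %in% names(raw)) {
      if (required) abort(paste0("mandatory column not found: ", col),
                          class = "tidymr_config_error")
      return(rep(NA_real_, nrow(raw)))
    }
    x <- raw[[col]]
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & x != "" & is.na(v))
    if (length(bad) > 0 && field %in% c("beta", "se")) {
      abort(sprintf(
        "non-numeric value '%s' in column '%s' at data row %d",
        x[bad[1]], col, bad[1]
      ), class = "tidymr_parse_error")
    }
    v
  }
  out$eaf <- num_field("eaf")
  out$beta <- num_field("beta", required = TRUE)
  out$se <- num_field("se", required = TRUE)
  out$pvalue <- num_field("pvalue")
  out$n <- num_field("n")
  out$z <- num_field("z")
  out$locus <- if (map["locus"] %in% names(raw)) {
    raw[[map["locus"]]]
  } else {
    rep(NA_character_, nrow(raw))
  }
  validate_associations(out)
}

#' Validate a tibble of variant associations
#'
#' Applies the record-level invariants (positive SE, frequency in \[0, 1\],
#' distinct alleles, p-value in (0, 1\], sign agreement between `z` and
#' `beta`) and splits the input into valid records and rejected rows.
#'
#' @param df A tibble with the standard association columns.
#' @return The valid rows (class `gwas_tbl`) with attribute `rejected`.
#' @export
validate_associations <- function(df) {
  df <- tibble::as_tibble(df)
  for (col in c("eaf", "pvalue", "n", "z")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
  }
  if (!"locus" %in% names(df)) df$locus <- NA_character_
  df$effect_allele <- toupper(df$effect_allele)
  df$other_allele <- toupper(df$other_allele)

  reason <- rep(NA_character_, nrow(df))
  flag <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- why
  }
  flag(is.na(df$beta) | is.na(df$se), "missing effect or se")
  flag(df$se <= 0, "nonpositive se")
  flag(!is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1), "eaf outside [0,1]")
  flag(df$effect_allele == df$other_allele, "identical alleles")
  flag(!df$effect_allele %in% c("A", "C", "G", "T") |
         !df$other_allele %in% c("A", "C", "G", "T"), "non-ACGT allele")
  flag(!is.na(df$pvalue) & (df$pvalue <= 0 | df$pvalue > 1),
       "pvalue outside (0,1]")
  flag(!is.na(df$z) & !is.na(df$beta) & df$z * df$beta < 0,
       "z and beta disagree in sign")

  bad <- !is.na(reason)
  rejected <- tibble::tibble(
    row = which(bad),
    variant_id = df$variant_id[bad],
    reason = reason[bad]
  )
  ok <- df[!bad, , drop = FALSE]
  structure(ok, rejected = rejected, class = c("gwas_tbl", class(ok)))
}

#' Rows rejected during reading or validation
#'
#' @param x A table returned by [read_gwas_table()] or
#'   [validate_associations()].
#' @return A tibble with columns `row`, `variant_id`, `reason`.
#' @export
rejected_records <- function(x) {
  attr(x, "rejected") %||%
    tibble::tibble(row = integer(), variant_id = character(),
                   reason = character())
}

#' Convert a standardized z score to SD-unit effect and standard error
#'
#' Converts a GWAS z statistic to an effect size in standard-deviation units
#' of the trait per effect allele, using the summary-data conversion
#' `beta = z / sqrt(2 p (1 - p) (n + z^2))` with matching standard error
#' `se = 1 / sqrt(2 p (1 - p) (n + z^2))`, where `p` is the effect-allele
#' frequency and `n` the sample size. The ratio `beta_sd / se_sd` equals the
#' input `z` exactly.
#'
#' @param z Standardized score(s).
#' @param eaf Effect-allele frequency, strictly inside (0, 1).
#' @param n Sample size, positive.
#' @return A tibble with columns `beta_sd` and `se_sd`.
#' @export
standardize_from_z <- function(z, eaf, n) {
  if (any(eaf <= 0 | eaf >= 1)) {
    abort("eaf must lie strictly between 0 and 1",
          class = "tidymr_degenerate_frequency_error")
  }
  if (any(n <= 0)) abort("n must be positive", class = "tidymr_domain_error")
  denom <- sqrt(2 * eaf * (1 - eaf) * (n + z^2))
  tibble::tibble(beta_sd = z / denom, se_sd = 1 / denom)
}

#' Keep the strongest association signal at each locus
#'
#' Within each locus label, retains the record with the smallest p-value;
#' ties are broken deterministically by the lexicographically smallest
#' variant id. Used to thin correlated signals down to one instrument per
#' locus when no linkage-disequilibrium reference is available.
#'
#' @param df A tibble of associations with non-missing `locus` and `pvalue`.
#' @return A tibble with exactly one row per locus, in order of first
#'   appearance of each locus.
#' @export
select_strongest_per_locus <- function(df) {
  df <- tibble::as_tibble(df)
  if (!"locus" %in% names(df) || any(is.na(df$locus) | df$locus == "")) {
    abort("every record must carry a locus label",
          class = "tidymr_labelling_error")
  }
  df |>
    dplyr::mutate(.locus_order = match(.data$locus, unique(.data$locus))) |>
    dplyr::arrange(.data$.locus_order, .data$pvalue, .data$variant_id) |>
    dplyr::distinct(.data$locus, .keep_all = TRUE) |>
    dplyr::select(-".locus_order")
}

ALLELE_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) {
  unname(ALLELE_COMPLEMENT[a1] == a2)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Matches exposure and outcome association tables on `variant_id` and
#' aligns every outcome effect to the exposure's effect allele. When the
#' outcome reports the opposite allele (directly or as its strand
#' complement), the outcome beta is negated and its frequency replaced by
#' one minus itself. Palindromic variants (A/T or C/G) whose effect-allele
#' frequency is within `palindrome_eaf_window` of 0.5 in either study are
#' dropped as strand-ambiguous; palindromic variants with informative
#' frequencies are aligned so the two studies' frequencies fall on the same
#' side of 0.5. Variants present in only one table, or with irreconcilable
#' allele pairs, are dropped with a recorded reason — never sign-guessed.
#'
#' @param exposure,outcome Tibbles of variant associations (standard
#'   columns; see [read_gwas_table()]).
#' @param palindrome_eaf_window Half-width of the ambiguous frequency band
#'   around 0.5 for palindromic variants (default 0.08, i.e. eaf in
#'   \[0.42, 0.58\] is ambiguous).
#' @param exposure_name,outcome_name Trait labels carried in the result.
#' @return A tibble (class `mr_harmonized`) with one row per retained
#'   variant: `variant_id`, `effect_allele`, `other_allele`,
#'   `beta_exposure`, `se_exposure`, `eaf_exposure`, `beta_outcome`,
#'   `se_outcome`, `eaf_outcome`. Dropped variants are in the `dropped`
#'   attribute, retrievable with [dropped_variants()].
#' @export
harmonize_pair <- function(exposure, outcome, palindrome_eaf_window = 0.08,
                           exposure_name = "exposure",
                           outcome_name = "outcome") {
  exposure <- tibble::as_tibble(exposure)
  outcome <- tibble::as_tibble(outcome)
  if (anyDuplicated(exposure$variant_id) || anyDuplicated(outcome$variant_id)) {
    abort("variant_id must be unique within each table",
          class = "tidymr_domain_error")
  }

  dropped <- tibble::tibble(variant_id = character(), reason = character())
  add_drop <- function(ids, reason) {
    if (length(ids) > 0) {
      dropped <<- dplyr::bind_rows(
        dropped, tibble::tibble(variant_id = ids, reason = reason)
      )
    }
  }
  add_drop(setdiff(exposure$variant_id, outcome$variant_id), "unmatched")
  add_drop(setdiff(outcome$variant_id, exposure$variant_id), "unmatched")

  m <- dplyr::inner_join(
    exposure |>
      dplyr::select("variant_id", "effect_allele", "other_allele",
                    eaf_exposure = "eaf", beta_exposure = "beta",
                    se_exposure = "se"),
    outcome |>
      dplyr::select("variant_id", ea_out = "effect_allele",
                    oa_out = "other_allele", eaf_outcome = "eaf",
                    beta_outcome = "beta", se_outcome = "se"),
    by = "variant_id"
  )

  if (nrow(m) > 0) {
    ea_x <- m$effect_allele
    oa_x <- m$other_allele
    ea_y <- m$ea_out
    oa_y <- m$oa_out
    ea_yc <- unname(ALLELE_COMPLEMENT[ea_y])
    oa_yc <- unname(ALLELE_COMPLEMENT[oa_y])

    aligned <- (ea_y == ea_x & oa_y == oa_x) | (ea_yc == ea_x & oa_yc == oa_x)
    swapped <- (ea_y == oa_x & oa_y == ea_x) | (ea_yc == oa_x & oa_yc == ea_x)
    palin <- is_palindromic(ea_x, oa_x)

    status <- rep("mismatch", nrow(m))
    status[aligned] <- "aligned"
    status[!aligned & swapped] <- "swapped"

    # palindromic variants: allele letters cannot distinguish a strand flip
    # from an allele swap, so alignment is decided by allele frequency
    ambiguous <- palin & status != "mismatch" & (
      is.na(m$eaf_exposure) | is.na(m$eaf_outcome) |
        abs(m$eaf_exposure - 0.5) <= palindrome_eaf_window |
        abs(m$eaf_outcome - 0.5) <= palindrome_eaf_window
    )
    freq_flip <- palin & !ambiguous & status != "mismatch" &
      (m$eaf_exposure - 0.5) * (m$eaf_outcome - 0.5) < 0
    was_aligned <- status == "aligned"
    status[palin & was_aligned & freq_flip] <- "swapped"
    status[palin & !was_aligned & freq_flip] <- "aligned"

    add_drop(m$variant_id[status == "mismatch"], "allele mismatch")
    add_drop(m$variant_id[ambiguous & status != "mismatch"],
             "palindromic, ambiguous frequency")

    keep <- status != "mismatch" & !ambiguous
    flip <- status == "swapped" & keep
    m$beta_outcome[flip] <- -m$beta_outcome[flip]
    m$eaf_outcome[flip] <- 1 - m$eaf_outcome[flip]
    m <- m[keep, , drop = FALSE]
  }

  out <- m |>
    dplyr::select("variant_id", "effect_allele", "other_allele",
                  "beta_exposure", "se_exposure", "eaf_exposure",
                  "beta_outcome", "se_outcome", "eaf_outcome")
  structure(
    out,
    dropped = dropped,
    exposure_name = exposure_name,
    outcome_name = outcome_name,
    class = c("mr_harmonized", class(out))
  )
}

#' Variants dropped during harmonization
#'
#' @param x An `mr_harmonized` table from [harmonize_pair()].
#' @return A tibble with columns `variant_id` and `reason`.
#' @export
dropped_variants <- function(x) {
  attr(x, "dropped") %||%
    tibble::tibble(variant_id = character(), reason = character())
}

#' Write the dropped-variant audit table
#'
#' @param x An `mr_harmonized` table.
#' @param path Output path for a tab-separated audit file.
#' @return `path`, invisibly.
#' @export
write_dropped_report <- function(x, path) {
  readr::write_tsv(dropped_variants(x), path)
  invisible(path)
}
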