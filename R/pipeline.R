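#' Read a study run configuration from YAML
#'
#' @param path Path to a YAML configuration file; see [run_study()] for the
#'   expected structure.
#' @return The configuration list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

default_options <- function(opts) {
  defaults <- list(
    wald_order = "first",
    ivw_model = "fixed",
    n_boot = 1000,
    mediation_n_boot = 100000,
    seed = 1,
    n_outcomes = 8,
    alpha = 0.05,
    palindrome_eaf_window = 0.08
  )
  utils::modifyList(defaults, opts %||% list())
}

read_entry <- function(entry) {
  cm <- entry$column_map
  if (!is.null(cm)) cm <- unlist(cm)
  read_gwas_table(entry$file, column_map = cm)
}

#' Run a full two-sample MR study from a configuration
#'
#' Orchestrates the complete analysis: for every configured outcome the
#' exposure and outcome tables are harmonized, per-variant Wald ratios are
#' combined by inverse-variance weighting with Cochran heterogeneity, and
#' outcomes sharing a `group` label across two or more studies are pooled
#' by DerSimonian-Laird random-effects meta-analysis. Final per-outcome
#' estimates (pooled where grouped) are classified against the
#' Bonferroni-corrected threshold `alpha / n_outcomes`. When a mediator is
#' configured, the two-step network mediation analysis runs with a
#' parametric bootstrap. A failure in one outcome is recorded and does not
#' abort the others.
#'
#' @param config A list (or path handled by [read_run_config()]) with:
#'   * `exposure`: list with `file`, optional `column_map`, optional `name`,
#'     optional `select_per_locus` (apply [select_strongest_per_locus()]).
#'   * `outcomes`: list of entries with `name`, `file`, optional `binary`,
#'     optional `group`, optional `column_map`.
#'   * `mediator` (optional): list with `name`, `file` (mediator
#'     associations of the exposure instruments), `instruments_file`
#'     (mediator GWAS instrument effects), `outcome_file` (outcome
#'     associations of the mediator instruments), and `total_outcome` (the
#'     outcome or group name whose estimate is the total effect).
#'   * `options` (optional): `wald_order`, `ivw_model`, `n_boot`,
#'     `mediation_n_boot`, `seed`, `n_outcomes`, `alpha`,
#'     `palindrome_eaf_window`.
#'   * `out_dir` (optional): directory for tab-separated report files.
#' @return An object of class `mr_study`; `tidy()` returns the per-outcome
#'   estimate table.
#' @export
run_study <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(config$exposure) || is.null(config$outcomes)) {
    abort("config needs exposure and outcomes entries",
          class = "tidymr_config_error")
  }
  outcome_names <- purrr::map_chr(config$outcomes, "name")
  if (anyDuplicated(outcome_names)) {
    abort("outcome names must be unique", class = "tidymr_config_error")
  }
  opts <- default_options(config$options)

  exposure <- read_entry(config$exposure)
  if (isTRUE(config$exposure$select_per_locus)) {
    exposure <- select_strongest_per_locus(exposure)
  }
  exposure_name <- config$exposure$name %||% "exposure"

  estimates <- list()
  dropped_audit <- list()
  errors <- list()
  for (entry in config$outcomes) {
    res <- tryCatch({
      outcome_tbl <- read_entry(entry)
      h <- harmonize_pair(
        exposure, outcome_tbl,
        palindrome_eaf_window = opts$palindrome_eaf_window,
        exposure_name = exposure_name, outcome_name = entry$name
      )
      dropped_audit[[entry$name]] <- dropped_variants(h) |>
        dplyr::mutate(outcome = entry$name, .before = 1)
      if (nrow(h) == 0) {
        abort("no harmonized instruments remain",
              class = "tidymr_estimation_error")
      }
      ratios <- wald_ratios(h, order = opts$wald_order)
      est <- mr_ivw(ratios, model = opts$ivw_model)
      tidy(est) |>
        dplyr::mutate(
          outcome = entry$name,
          group = entry$group %||% NA_character_,
          q = est$q, q_pvalue = est$q_pvalue,
          .before = 1
        )
    }, error = function(e) {
      errors[[entry$name]] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(res)) estimates[[entry$name]] <- res
  }
  outcome_estimates <- dplyr::bind_rows(estimates)

  # cross-study pooling for outcome groups with at least two studies
  metas <- list()
  if (nrow(outcome_estimates) > 0) {
    groups <- outcome_estimates |>
      dplyr::filter(!is.na(.data$group)) |>
      dplyr::count(.data$group) |>
      dplyr::filter(.data$n >= 2)
    for (g in groups$group) {
      studies <- outcome_estimates |>
        dplyr::filter(.data$group == g) |>
        dplyr::select(study = "outcome", beta = "estimate",
                      se = "std.error")
      metas[[g]] <- meta_dl(studies)
    }
  }

  # final per-target estimates: pooled value for each full group,
  # study-level value for ungrouped outcomes
  finals <- list()
  if (nrow(outcome_estimates) > 0) {
    pooled_members <- outcome_estimates$outcome[
      outcome_estimates$group %in% names(metas)
    ]
    singles <- outcome_estimates |>
      dplyr::filter(!.data$outcome %in% pooled_members) |>
      dplyr::transmute(
        target = .data$outcome, beta = .data$estimate,
        se = .data$std.error, pvalue = .data$p.value,
        pooled = FALSE
      )
    pooled <- purrr::imap_dfr(metas, function(m, g) {
      tibble::tibble(target = g, beta = m$pooled_beta, se = m$pooled_se,
                     pvalue = m$pvalue, pooled = TRUE)
    })
    finals <- dplyr::bind_rows(singles, pooled) |>
      dplyr::mutate(
        significance = classify_significance(.data$pvalue,
                                             n_outcomes = opts$n_outcomes,
                                             alpha = opts$alpha)
      )
  } else {
    finals <- tibble::tibble(
      target = character(), beta = numeric(), se = numeric(),
      pvalue = numeric(), pooled = logical(), significance = character()
    )
  }

  mediation <- NULL
  if (!is.null(config$mediator)) {
    mediation <- tryCatch(
      run_mediation_stage(config$mediator, exposure, exposure_name, finals,
                          opts),
      error = function(e) {
        errors[["mediation"]] <<- conditionMessage(e)
        NULL
      }
    )
  }

  report <- structure(
    list(
      outcomes = outcome_estimates,
      meta = metas,
      final_estimates = finals,
      mediation = mediation,
      dropped = dplyr::bind_rows(dropped_audit),
      rejected_input_rows = rejected_records(exposure),
      errors = errors,
      provenance = list(
        seed = opts$seed,
        n_boot = opts$n_boot,
        mediation_n_boot = opts$mediation_n_boot,
        wald_order = opts$wald_order,
        ivw_model = opts$ivw_model,
        n_outcomes = opts$n_outcomes,
        alpha = opts$alpha,
        package_version = as.character(utils::packageVersion("tidymr")),
        config_hash = rlang::hash(config)
      )
    ),
    class = "mr_study"
  )
  if (!is.null(config$out_dir)) write_study_report(report, config$out_dir)
  report
}

run_mediation_stage <- function(mediator, exposure, exposure_name, finals,
                                opts) {
  needed <- c("file", "instruments_file", "outcome_file", "total_outcome")
  if (!all(needed %in% names(mediator))) {
    abort(paste("mediator config needs:", paste(needed, collapse = ", ")),
          class = "tidymr_config_error")
  }
  total_row <- finals[finals$target == mediator$total_outcome, ]
  if (nrow(total_row) != 1) {
    abort(paste0("total_outcome '", mediator$total_outcome,
                 "' not found among final estimates"),
          class = "tidymr_config_error")
  }
  mediator_name <- mediator$name %||% "mediator"

  h1 <- harmonize_pair(
    exposure, read_entry(mediator),
    palindrome_eaf_window = opts$palindrome_eaf_window,
    exposure_name = exposure_name, outcome_name = mediator_name
  )
  step1 <- mr_ivw(wald_ratios(h1, order = opts$wald_order),
                  model = opts$ivw_model)

  h2 <- harmonize_pair(
    read_entry(list(file = mediator$instruments_file,
                    column_map = mediator$column_map)),
    read_entry(list(file = mediator$outcome_file,
                    column_map = mediator$column_map)),
    palindrome_eaf_window = opts$palindrome_eaf_window,
    exposure_name = mediator_name, outcome_name = mediator$total_outcome
  )
  step2 <- estimate_step2_weighted_median(h2, n_boot = opts$n_boot,
                                          seed = opts$seed)

  bootstrap_mediation(
    total = list(beta = total_row$beta, se = total_row$se),
    step1 = list(beta = step1$beta, se = step1$se),
    step2 = list(beta = step2$beta, se = step2$se),
    n_boot = opts$mediation_n_boot,
    seed = opts$seed
  )
}

#' @export
print.mr_study <- function(x, ...) {
  cat("<mr_study>\n")
  cat("  outcomes analysed:", nrow(x$outcomes), "\n")
  cat("  groups pooled:", length(x$meta), "\n")
  if (nrow(x$final_estimates) > 0) {
    tab <- x$final_estimates
    for (i in seq_len(nrow(tab))) {
      cat(sprintf("  %-24s beta %8.4f (SE %.4f)  p %.3g  [%s]%s\n",
                  tab$target[i], tab$beta[i], tab$se[i], tab$pvalue[i],
                  tab$significance[i],
                  if (tab$pooled[i]) " pooled" else ""))
    }
  }
  if (!is.null(x$mediation)) {
    cat(sprintf("  mediation: proportion mediated %.1f%%\n",
                100 * x$mediation$proportion_mediated))
  }
  if (length(x$errors) > 0) {
    cat("  errors:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mr_study <- function(x, ...) {
  x$outcomes
}

#' @exportS3Method generics::glance
glance.mr_study <- function(x, ...) {
  tibble::tibble(
    n_outcomes = nrow(x$outcomes),
    n_groups_pooled = length(x$meta),
    n_significant = sum(x$final_estimates$significance == "significant"),
    n_dropped_variants = nrow(x$dropped),
    n_errors = length(x$errors),
    seed = x$provenance$seed
  )
}

#' Write the study report to a directory
#'
#' Emits tab-separated tables (`estimates.tsv`, `final_estimates.tsv`,
#' `meta_<group>.tsv` forest data, `mediation.tsv`, `dropped_variants.tsv`)
#' plus a machine-readable `summary.yaml` with the provenance block.
#'
#' @param report An `mr_study` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "mr_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(report$outcomes, file.path(dir, "estimates.tsv"))
  readr::write_tsv(report$final_estimates,
                   file.path(dir, "final_estimates.tsv"))
  for (g in names(report$meta)) {
    forest_data(report$meta[[g]],
                file.path(dir, paste0("meta_", g, ".tsv")))
  }
  if (!is.null(report$mediation)) {
    mediation_report(report$mediation, file.path(dir, "mediation.tsv"))
  }
  readr::write_tsv(report$dropped, file.path(dir, "dropped_variants.tsv"))
  summary <- list(
    provenance = report$provenance,
    final_estimates = purrr::transpose(as.list(report$final_estimates)),
    errors = report$errors
  )
  yaml::write_yaml(summary, file.path(dir, "summary.yaml"))
  invisible(dir)
}
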