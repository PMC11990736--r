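#' Read a long-format measurement table from CSV
#'
#' Expects a comma-separated, UTF-8, '.'-decimal file with a header
#' containing at least `subject_id`, `day`, `value`. Days must parse as
#' integers and values as numbers; unknown columns (including a
#' `latent_group` ground-truth column) are carried along as metadata and
#' never used by estimation.
#'
#' @param path File path.
#' @return Data frame of measurements.
#' @export
read_long_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("subject_id", "day", "value"), names(df))
  if (length(miss)) {
    stop("input is missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  val <- suppressWarnings(as.numeric(df$value))
  if (anyNA(val)) {
    stop("non-numeric value in 'value' at data row(s): ",
         paste(utils::head(which(is.na(val)), 5L), collapse = ", "),
         call. = FALSE)
  }
  day <- suppressWarnings(as.integer(df$day))
  if (anyNA(day)) {
    stop("non-integer day in 'day' at data row(s): ",
         paste(utils::head(which(is.na(day)), 5L), collapse = ", "),
         call. = FALSE)
  }
  df$value <- val
  df$day <- day
  df
}

#' Write a long-format measurement table to CSV
#'
#' @param data Data frame as produced by [generate_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects everything one end-to-end run needs: either an input CSV path or
#' the design/model pair to simulate from, the candidate group numbers and
#' polynomial order of the scan, the parsimony thresholds, fitting options,
#' the master seed and the output directory. The configuration serializes
#' losslessly to JSON ([jsonlite::write_json] with `digits = NA`), and the
#' run log records its hash so two runs are comparable.
#'
#' @param input Optional path to a long CSV; when `NULL` the cohort is
#'   simulated from `design` and `model`.
#' @param design A [study_design()] (used when simulating).
#' @param model A [generating_model()] (used when simulating).
#' @param k_values Candidate group counts for the scan.
#' @param order Polynomial order of all candidates.
#' @param thresholds Parsimony thresholds.
#' @param fit_options List passed to [fit_trajectories()].
#' @param bin_width Bin width (days) of the comparison stage.
#' @param seed Master seed; recorded in every output artifact.
#' @param out_dir Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(input = NULL,
                       design = study_design(),
                       model = generating_model(),
                       k_values = 1:4,
                       order = 2L,
                       thresholds = parsimony_thresholds(),
                       fit_options = list(),
                       bin_width = 5L,
                       seed = 1L,
                       out_dir = tempfile("trajmix_run_")) {
  structure(
    list(input = input, design = design, model = model,
         k_values = as.integer(k_values), order = as.integer(order),
         thresholds = thresholds, fit_options = fit_options,
         bin_width = as.integer(bin_width), seed = as.integer(seed),
         out_dir = out_dir),
    class = "run_config"
  )
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg <- config
  cfg$out_dir <- NULL # location must not change the hash
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full trajectory-analysis pipeline
#'
#' Executes the reference workflow end to end: obtain a cohort (read or
#' simulate), scan candidate group numbers, select the most parsimonious
#' model, classify subjects, and compare the classified groups (binned
#' summaries, two-way ANOVA with Tukey post hoc, phase labels, regimen
#' cross-tab). All stage outputs are written under `config$out_dir` as TSV /
#' JSON / CSV, together with a run log carrying the seed, the config hash and
#' per-stage status. Deterministic given the config.
#'
#' @param config A [run_config()].
#' @return A list with `cohort`, `selection`, `fit`, `assignment`,
#'   `summary`, `comparison`, `phases`, `crosstab`, `log` (also written to
#'   disk), invisibly printed stages along the way.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(seed = config$seed, config_hash = config_hash(config),
              stages = character(0L))
  stage <- function(name) log$stages <<- c(log$stages, name)

  # --- data stage
  cohort <- if (is.null(config$input)) {
    design <- config$design
    design$seed <- config$seed
    generate_cohort(design, config$model)
  } else {
    read_long_csv(config$input)
  }
  stage("data")
  write_long_csv(cohort, file.path(config$out_dir, "cohort.csv"))

  # --- scan and selection stage
  fit_opts <- utils::modifyList(list(seed = config$seed), config$fit_options)
  candidates <- do.call(scan_candidates,
                        c(list(data = cohort, k_values = config$k_values,
                               order = config$order,
                               thresholds = config$thresholds),
                          fit_opts))
  selection <- select_most_parsimonious(candidates, config$thresholds)
  stage("selection")
  write_tsv(cbind(seed = config$seed, selection$candidates),
            file.path(config$out_dir, "candidates.tsv"))
  jsonlite::write_json(
    list(seed = config$seed, config_hash = log$config_hash,
         selected_k = selection$selected_k,
         delta_bic_vs_k1 = selection$delta_bic_vs_k1,
         homogeneity_rejected = selection$homogeneity_rejected),
    file.path(config$out_dir, "selection.json"),
    auto_unbox = TRUE, digits = NA)

  fit <- selection$fit
  if (is.null(fit)) stop("selection stage produced no usable fit", call. = FALSE)
  est <- fit$estimates
  if (is.null(est)) est <- wald_tests(fit)
  footer <- data.frame(group = NA_integer_, parameter = c("L", "BIC(N=obs)",
                                                          "BIC(N=subj)", "AIC"),
                       estimate = c(fit$loglik, fit$bic_obs, fit$bic_subj,
                                    fit$aic),
                       se = NA_real_, t = NA_real_, p = NA_real_)
  write_tsv(cbind(seed = config$seed, rbind(est, footer)),
            file.path(config$out_dir, "estimates.tsv"))
  post <- data.frame(subject_id = rownames(fit$posterior),
                     unclass(fit$posterior),
                     assignment = fit$assignment, check.names = FALSE)
  write_tsv(cbind(seed = config$seed, post),
            file.path(config$out_dir, "posteriors.tsv"))
  stage("fit")

  # --- comparison stage (only meaningful with >= 2 groups)
  out <- list(cohort = cohort, selection = selection, fit = fit,
              assignment = fit$assignment)
  if (selection$selected_k >= 2L) {
    summ <- summarize_groups(cohort, fit$assignment, config$bin_width)
    sb <- subject_bin_means(cohort, fit$assignment, config$bin_width)
    comparison <- two_way_anova_tukey(sb)
    write_tsv(cbind(seed = config$seed, summ),
              file.path(config$out_dir, "binned_summary.tsv"))
    write_tsv(cbind(seed = config$seed, comparison$tukey),
              file.path(config$out_dir, "anova_tukey.tsv"))
    out$summary <- summ
    out$comparison <- comparison
    if (selection$selected_k >= 3L) {
      out$phases <- label_phases(comparison)
      write_tsv(cbind(seed = config$seed, out$phases),
                file.path(config$out_dir, "phases.tsv"))
    }
    if ("regimen" %in% names(cohort)) {
      reg <- cohort$regimen[!duplicated(cohort$subject_id)]
      names(reg) <- cohort$subject_id[!duplicated(cohort$subject_id)]
      ct <- regimen_crosstab(fit$assignment, reg[names(fit$assignment)])
      write_tsv(cbind(seed = config$seed,
                      data.frame(group = rownames(ct), unclass(ct),
                                 check.names = FALSE)),
                file.path(config$out_dir, "crosstab.tsv"))
      out$crosstab <- ct
    }
    stage("comparison")
  }

  jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  out$log <- log
  out
}
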