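# Orchestration: selection -> harmonization -> estimation -> sensitivity,
# in one or both directions, with provenance logging and plot-data exports.

#' Analysis configuration
#'
#' Bundles every tunable of the bidirectional pipeline. Defaults follow the
#' conventions of published two-sample MR analyses: genome-wide
#' significance 5e-8 forward, relaxed to 5e-6 in the reverse direction
#' where instruments are scarce; clumping at r2 0.001 within 10,000 kb;
#' confounder screen at p 5e-8 with proxies above r2 0.80; palindromic SNPs
#' dropped at intermediate allele frequencies (0.42-0.58); verdicts at
#' alpha 0.05.
#'
#' @param p_threshold_forward,p_threshold_reverse instrument significance
#'   thresholds per direction.
#' @param clump_r2,clump_window_kb LD clumping parameters.
#' @param confounder_traits character vector of confounder trait names
#'   (`NULL` disables the screen).
#' @param confounder_p,proxy_r2 confounder-screen thresholds.
#' @param palindrome_mode `"drop_intermediate"` or `"drop_all"`.
#' @param eaf_window intermediate-frequency window for palindromes.
#' @param n_boot,seed,phi bootstrap count, RNG seed, mode bandwidth factor.
#' @param presso_n_sim MR-PRESSO simulation count.
#' @param alpha significance level for causal verdicts.
#' @param trait_sd trait SD used by [variance_explained()].
#' @param se_order Wald-ratio SE order.
#' @return list of class `mr_analysis_config`.
#' @export
mr_config <- function(p_threshold_forward = 5e-8, p_threshold_reverse = 5e-6,
                      clump_r2 = 0.001, clump_window_kb = 10000,
                      confounder_traits = NULL, confounder_p = 5e-8,
                      proxy_r2 = 0.80,
                      palindrome_mode = "drop_intermediate",
                      eaf_window = c(0.42, 0.58),
                      n_boot = 1000, seed = 20230909, phi = 1,
                      presso_n_sim = 1000, alpha = 0.05, trait_sd = 1,
                      se_order = "first") {
  stopifnot(p_threshold_forward > 0, p_threshold_forward < 1,
            p_threshold_reverse > 0, p_threshold_reverse < 1,
            alpha > 0, alpha < 1, !is.null(seed))
  structure(as.list(environment()), class = "mr_analysis_config")
}

#' Read an analysis configuration from a JSON file
#'
#' Keys mirror the arguments of [mr_config()]; absent keys take defaults.
#'
#' @param path JSON file path.
#' @return An `mr_analysis_config`.
#' @export
read_analysis_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(vals), names(formals(mr_config)))
  if (length(unknown)) {
    stop("read_analysis_config: unknown key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(mr_config, vals)
}

.pipeline_fail <- function(stage, message) {
  stop(errorCondition(sprintf("[stage: %s] %s", stage, message),
                      stage = stage, class = "bimr_pipeline_error"))
}

.study_n <- function(x) {
  n <- x$n[!is.na(x$n)]
  if (length(n)) max(n) else NA_real_
}

#' Run a one-direction MR analysis
#'
#' Executes instrument selection ([build_instrument_set()]),
#' [harmonize()], the five estimators ([mr_all()]) and the sensitivity
#' suite ([cochran_q()], [pleiotropy_test()], [leave_one_out()],
#' [mr_presso()]); every stage is logged with counts. The IVW model for the
#' headline estimate is fixed-effect when Cochran Q's p-value is at least
#' `alpha` and multiplicative random-effects otherwise; both are stored.
#' Sensitivity analyses requiring more instruments than survive are
#' recorded as `NULL` with a note rather than failing the run. Fewer than
#' two surviving instruments raises a structured error (condition class
#' `bimr_pipeline_error`) naming the depleting stage.
#'
#' @param exposure,outcome [sumstats] tables.
#' @param ld an [ld_reference] for the exposure panel.
#' @param catalog optional [trait_catalog] for the confounder screen.
#' @param config an [mr_config()].
#' @param direction `"forward"` (default) or `"reverse"`; selects the
#'   significance threshold.
#' @param n_exposure exposure-study sample size for the F statistic;
#'   defaults to the largest per-record `n` in `exposure`.
#' @return list of class `mr_report` with components `direction`,
#'   `exposure`, `outcome`, `instruments`, `harmonized`, `estimates`,
#'   `ivw_fixed`, `ivw_random`, `heterogeneity`, `pleiotropy`, `presso`,
#'   `leave_one_out`, `verdict` (`"causal"`/`"not_causal"`), `notes`, `log`.
#' @export
run_mr <- function(exposure, outcome, ld, catalog = NULL,
                   config = mr_config(),
                   direction = c("forward", "reverse"),
                   n_exposure = .study_n(exposure)) {
  direction <- match.arg(direction)
  stopifnot(inherits(config, "mr_analysis_config"))
  p_thr <- if (direction == "forward") config$p_threshold_forward else
    config$p_threshold_reverse

  iset <- suppressWarnings(build_instrument_set(
    exposure, ld, catalog = catalog, n_exposure = n_exposure,
    p_threshold = p_thr, clump_r2 = config$clump_r2,
    clump_window_kb = config$clump_window_kb,
    confounder_traits = config$confounder_traits,
    confounder_p = config$confounder_p, proxy_r2 = config$proxy_r2,
    trait_sd = config$trait_sd))
  log <- lapply(iset$provenance, function(st) {
    list(stage = st$step, n_in = st$n_in, n_out = st$n_out,
         dropped = st$dropped$rsid)
  })
  if (iset$k < 2L) {
    depleting <- if (iset$k == 0L) "instrument_selection" else "instrument_selection"
    .pipeline_fail(depleting,
                   sprintf("only %d instrument(s) survive selection", iset$k))
  }

  h <- harmonize(iset, outcome, mode = config$palindrome_mode,
                 eaf_window = config$eaf_window)
  log <- c(log, list(list(stage = "harmonization", n_in = iset$k,
                          n_out = n_snps(h), dropped = h$exclusions$rsid)))
  if (n_snps(h) < 2L) {
    .pipeline_fail("harmonization",
                   sprintf("only %d pair(s) survive harmonization", n_snps(h)))
  }

  notes <- character(0)
  het <- cochran_q(h, se_order = config$se_order)
  ivw_model <- if (het$pvalue >= config$alpha) "fixed" else "random"
  ests <- mr_all(h, ivw_model = ivw_model, n_boot = config$n_boot,
                 seed = config$seed, phi = config$phi,
                 se_order = config$se_order)
  ivw_fixed <- mr_ivw(h, "fixed", se_order = config$se_order)
  ivw_random <- mr_ivw(h, "random", se_order = config$se_order)

  pleio <- NULL; loo <- NULL; presso <- NULL
  if (n_snps(h) >= 3L) {
    pleio <- pleiotropy_test(h)
    loo <- leave_one_out(h, se_order = config$se_order)
  } else {
    notes <- c(notes, "fewer than 3 instruments: Egger/leave-one-out skipped")
  }
  if (n_snps(h) >= 4L) {
    presso <- mr_presso(h, n_sim = config$presso_n_sim, seed = config$seed)
  } else {
    notes <- c(notes, "fewer than 4 instruments: MR-PRESSO skipped")
  }

  primary <- if (ivw_model == "fixed") ivw_fixed else ivw_random
  verdict <- if (primary$pvalue < config$alpha) "causal" else "not_causal"

  structure(list(direction = direction,
                 exposure = iset$exposure_label,
                 outcome = trait_label(outcome),
                 instruments = iset, harmonized = h, estimates = ests,
                 ivw_fixed = ivw_fixed, ivw_random = ivw_random,
                 ivw_model = ivw_model,
                 heterogeneity = het, pleiotropy = pleio, presso = presso,
                 leave_one_out = loo, verdict = verdict, notes = notes,
                 log = log, config = config),
            class = "mr_report")
}

#' @export
print.mr_report <- function(x, ...) {
  cat(sprintf("MR report (%s): %s -> %s [%s]\n", x$direction, x$exposure,
              x$outcome, x$verdict))
  print(x$instruments)
  print(x$harmonized)
  print(as.data.frame(x$estimates)[c("method", "n_snp", "or", "or_ci_low",
                                     "or_ci_high", "pvalue")])
  print(x$heterogeneity)
  if (!is.null(x$pleiotropy)) print(x$pleiotropy)
  if (!is.null(x$presso)) print(x$presso)
  invisible(x)
}

#' Run the full bidirectional analysis
#'
#' For every exposure table, runs the forward analysis (exposure ->
#' outcome, threshold `p_threshold_forward`) and the reverse analysis
#' (outcome -> exposure, threshold `p_threshold_reverse`). A failure in one
#' direction is captured and reported without aborting the others.
#'
#' @param exposures a named list of [sumstats] tables (or a single table).
#' @param outcome a [sumstats] table.
#' @param ld an [ld_reference] covering both panels.
#' @param catalog optional [trait_catalog].
#' @param config an [mr_config()].
#' @return list of class `mr_bidirectional` with `reports` (one `mr_report`
#'   or condition object per analysis, named `<exposure>-><outcome>`),
#'   `table` (the sensitivity summary via [mr_sensitivity_table()]) and
#'   `results` (all estimator rows combined).
#' @export
run_bidirectional <- function(exposures, outcome, ld, catalog = NULL,
                              config = mr_config()) {
  if (inherits(exposures, "sumstats")) {
    exposures <- stats::setNames(list(exposures), trait_label(exposures))
  }
  reports <- list()
  for (lab in names(exposures)) {
    key_f <- paste0(lab, "->", trait_label(outcome))
    reports[[key_f]] <- tryCatch(
      run_mr(exposures[[lab]], outcome, ld, catalog, config, "forward"),
      bimr_pipeline_error = function(e) e)
  }
  for (lab in names(exposures)) {
    key_r <- paste0(trait_label(outcome), "->", lab)
    reports[[key_r]] <- tryCatch(
      run_mr(outcome, exposures[[lab]], ld, catalog, config, "reverse"),
      bimr_pipeline_error = function(e) e)
  }
  ok <- Filter(function(r) inherits(r, "mr_report"), reports)
  structure(list(reports = reports,
                 table = mr_sensitivity_table(ok),
                 results = if (length(ok)) {
                   do.call(rbind, lapply(ok, function(r)
                     as.data.frame(r$estimates)))
                 } else NULL),
            class = "mr_bidirectional")
}

#' Sensitivity summary table across analyses
#'
#' One row per analysis with instrument count, Cochran Q and its p-value,
#' Egger intercept and its p-value, MR-PRESSO RSSobs and global p, and the
#' outlier list (`"None"` when empty) — the customary sensitivity summary
#' layout of published MR studies.
#'
#' @param reports a list of `mr_report` objects (or one).
#' @return data frame.
#' @export
mr_sensitivity_table <- function(reports) {
  if (inherits(reports, "mr_report")) reports <- list(reports)
  rows <- lapply(reports, function(r) {
    data.frame(
      exposure = r$exposure, outcome = r$outcome,
      n_iv = n_snps(r$harmonized),
      Q = r$heterogeneity$Q, Q_pvalue = r$heterogeneity$pvalue,
      egger_intercept = if (is.null(r$pleiotropy)) NA_real_ else
        r$pleiotropy$estimate,
      egger_pvalue = if (is.null(r$pleiotropy)) NA_real_ else
        r$pleiotropy$pvalue,
      rss_obs = if (is.null(r$presso)) NA_real_ else r$presso$rss_obs,
      presso_global_pvalue = if (is.null(r$presso)) NA_real_ else
        r$presso$global_pvalue,
      outliers = if (is.null(r$presso) || !length(r$presso$outliers)) "None"
        else paste(r$presso$outliers, collapse = ","),
      verdict = r$verdict,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.write_tsv <- function(df, path, digits_cols = NULL) {
  if (!is.null(digits_cols)) {
    for (col in digits_cols) df[[col]] <- sprintf("%.15g", df[[col]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Export plot-ready data tables for one analysis
#'
#' Writes the data behind the customary MR figures as TSVs (no figures are
#' rendered): `scatter.tsv` (per-SNP effect pairs), `scatter_lines.tsv`
#' (per-method fitted slope and intercept), `forest.tsv` (per-SNP Wald
#' estimates plus the per-method summary rows), `funnel.tsv` (Wald ratio
#' against its precision), `leave_one_out.tsv`, `results.tsv` (the
#' estimator table) and `provenance.jsonl` (stage-by-stage counts and
#' dropped rsids, one JSON object per line).
#'
#' @param report an `mr_report`.
#' @param outdir output directory (created if absent).
#' @return character vector of the files written, invisibly.
#' @export
export_plot_data <- function(report, outdir) {
  stopifnot(inherits(report, "mr_report"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- report$harmonized$pairs
  files <- character(0)

  files <- c(files, .write_tsv(
    p[c("rsid", "beta_exp", "se_exp", "beta_out", "se_out")],
    file.path(outdir, "scatter.tsv"),
    c("beta_exp", "se_exp", "beta_out", "se_out")))

  ests <- as.data.frame(report$estimates)
  lines <- data.frame(method = ests$method, slope = ests$beta,
                      intercept = 0, stringsAsFactors = FALSE)
  if (!is.null(attr(report$estimates, "egger_intercept"))) {
    lines$intercept[lines$method == "MR-Egger"] <-
      attr(report$estimates, "egger_intercept")$estimate
  }
  files <- c(files, .write_tsv(lines, file.path(outdir, "scatter_lines.tsv"),
                               c("slope", "intercept")))

  wr <- wald_ratio(p$beta_exp, p$se_exp, p$beta_out, p$se_out)
  snp_rows <- data.frame(label = p$rsid, type = "snp",
                         or = exp(wr$ratio),
                         or_ci_low = exp(wr$ratio - Z95 * wr$se),
                         or_ci_high = exp(wr$ratio + Z95 * wr$se),
                         stringsAsFactors = FALSE)
  method_rows <- data.frame(label = ests$method, type = "method",
                            or = ests$or, or_ci_low = ests$or_ci_low,
                            or_ci_high = ests$or_ci_high,
                            stringsAsFactors = FALSE)
  files <- c(files, .write_tsv(rbind(snp_rows, method_rows),
                               file.path(outdir, "forest.tsv"),
                               c("or", "or_ci_low", "or_ci_high")))

  files <- c(files, .write_tsv(
    data.frame(rsid = p$rsid, ratio = wr$ratio, precision = 1 / wr$se,
               stringsAsFactors = FALSE),
    file.path(outdir, "funnel.tsv"), c("ratio", "precision")))

  if (!is.null(report$leave_one_out)) {
    files <- c(files, .write_tsv(
      as.data.frame(report$leave_one_out), file.path(outdir, "leave_one_out.tsv"),
      c("beta", "se", "ci_low", "ci_high", "pvalue")))
  }
  files <- c(files, .write_tsv(ests, file.path(outdir, "results.tsv"),
                               c("beta", "se", "ci_low", "ci_high", "pvalue",
                                 "or", "or_ci_low", "or_ci_high")))

  log_path <- file.path(outdir, "provenance.jsonl")
  con <- file(log_path, "w")
  for (entry in report$log) {
    writeLines(jsonlite::toJSON(entry, auto_unbox = TRUE), con)
  }
  close(con)
  files <- c(files, log_path)
  invisible(files)
}
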