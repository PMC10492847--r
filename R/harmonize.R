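# Allele harmonization: align exposure instruments and outcome associations
# on a common effect allele; resolve swaps; handle palindromic SNPs.

#' Is an allele pair palindromic?
#'
#' A/T and C/G pairs read the same on both strands, so strand cannot be
#' resolved from the alleles alone.
#'
#' @param a1,a2 character vectors of single-base alleles (recycled).
#' @return logical vector.
#' @export
is_palindromic <- function(a1, a2) {
  a1 <- toupper(a1); a2 <- toupper(a2)
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Construct a harmonized exposure-outcome set
#'
#' Low-level constructor used both by [harmonize()] and to ingest
#' already-harmonized effect pairs (e.g. a published per-instrument table).
#'
#' @param pairs data frame with columns `rsid`, `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out` and optionally `eaf_exp`, `eaf_out`, `flipped`,
#'   `palindromic`.
#' @param exposure_label,outcome_label trait labels.
#' @param exclusions data frame with columns `rsid`, `reason` (may be empty).
#' @return A `harmonized_set` object.
#' @export
harmonized_set <- function(pairs, exposure_label, outcome_label,
                           exclusions = NULL) {
  stopifnot(is.data.frame(pairs),
            all(c("rsid", "beta_exp", "se_exp", "beta_out", "se_out") %in%
                  names(pairs)))
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (!"eaf_exp" %in% names(pairs)) pairs$eaf_exp <- NA_real_
  if (!"eaf_out" %in% names(pairs)) pairs$eaf_out <- NA_real_
  if (!"flipped" %in% names(pairs)) pairs$flipped <- FALSE
  if (!"palindromic" %in% names(pairs)) pairs$palindromic <- FALSE
  pairs <- pairs[c("rsid", "beta_exp", "se_exp", "beta_out", "se_out",
                   "eaf_exp", "eaf_out", "flipped", "palindromic")]
  if (nrow(pairs)) {
    stopifnot(all(pairs$se_exp > 0), all(pairs$se_out > 0),
              !anyDuplicated(pairs$rsid))
  }
  rownames(pairs) <- NULL
  if (is.null(exclusions)) {
    exclusions <- data.frame(rsid = character(0), reason = character(0),
                             stringsAsFactors = FALSE)
  }
  structure(list(exposure_label = exposure_label,
                 outcome_label = outcome_label,
                 pairs = pairs,
                 exclusions = exclusions),
            class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized set %s -> %s: %d SNP pairs, %d excluded\n",
              x$exposure_label, x$outcome_label, nrow(x$pairs),
              nrow(x$exclusions)))
  if (nrow(x$exclusions)) {
    tab <- table(x$exclusions$reason)
    for (r in names(tab)) cat(sprintf("  excluded %s: %d\n", r, tab[[r]]))
  }
  invisible(x)
}

#' Number of SNP pairs in a harmonized set
#' @param x a `harmonized_set`.
#' @return integer count.
#' @export
n_snps <- function(x) nrow(x$pairs)

#' Harmonize exposure instruments with outcome summary statistics
#'
#' Aligns each instrument with the outcome record of the same rsid on a
#' common effect allele. Per rsid: (i) absent from the outcome table ->
#' excluded (`missing_in_outcome`); (ii) same allele orientation -> kept
#' as-is; (iii) alleles swapped -> outcome beta sign-flipped and EAF
#' complemented, `flipped = TRUE`; (iv) incompatible allele sets ->
#' excluded. Palindromic SNPs (A/T, C/G) cannot be oriented from alleles
#' alone: under `mode = "drop_intermediate"` they are excluded when either
#' study's EAF falls inside `eaf_window` (ambiguous minor allele) or when
#' the outcome EAF is missing, and otherwise oriented so that the same
#' allele is minor in both studies; under `mode = "drop_all"` every
#' palindromic SNP is excluded.
#'
#' @param instruments an `instrument_set` or [sumstats] table of exposure
#'   instruments.
#' @param outcome a [sumstats] table for the outcome trait.
#' @param mode palindromic-SNP policy, `"drop_intermediate"` (default) or
#'   `"drop_all"`.
#' @param eaf_window numeric length-2, the open interval of "intermediate"
#'   allele frequencies (default `c(0.42, 0.58)`).
#' @return A [harmonized_set]; every excluded rsid is logged with a reason,
#'   so `nrow(pairs) + nrow(exclusions)` equals the instrument count.
#' @export
harmonize <- function(instruments, outcome,
                      mode = c("drop_intermediate", "drop_all"),
                      eaf_window = c(0.42, 0.58)) {
  mode <- match.arg(mode)
  exposure_label <- if (inherits(instruments, "instrument_set")) {
    instruments$exposure_label
  } else trait_label(instruments)
  exp_tab <- if (inherits(instruments, "instrument_set")) {
    instruments$instruments
  } else instruments
  stopifnot(inherits(exp_tab, "sumstats") || is.data.frame(exp_tab),
            inherits(outcome, "sumstats"))
  if (nrow(exp_tab) == 0L) stop("harmonize: no instruments supplied", call. = FALSE)
  stopifnot(length(eaf_window) == 2L, eaf_window[1] < eaf_window[2])

  out_idx <- match(exp_tab$rsid, outcome$rsid)
  pal <- is_palindromic(exp_tab$effect_allele, exp_tab$other_allele)

  keep <- list(); excl <- list()
  for (i in seq_len(nrow(exp_tab))) {
    rsid <- exp_tab$rsid[i]
    j <- out_idx[i]
    if (is.na(j)) {
      excl[[length(excl) + 1L]] <- c(rsid, "missing_in_outcome"); next
    }
    ea_x <- exp_tab$effect_allele[i]; oa_x <- exp_tab$other_allele[i]
    ea_y <- outcome$effect_allele[j]; oa_y <- outcome$other_allele[j]
    same <- ea_y == ea_x && oa_y == oa_x
    swapped <- ea_y == oa_x && oa_y == ea_x
    if (!same && !swapped) {
      excl[[length(excl) + 1L]] <- c(rsid, "incompatible_alleles"); next
    }
    beta_out <- outcome$beta[j]; eaf_out <- outcome$eaf[j]
    flipped <- FALSE
    if (pal[i]) {
      if (mode == "drop_all") {
        excl[[length(excl) + 1L]] <- c(rsid, "palindromic_all_mode"); next
      }
      # For a palindrome, "swapped" alleles are indistinguishable from a
      # strand flip; orientation must come from allele frequencies.
      eaf_x <- exp_tab$eaf[i]
      if (is.na(eaf_out) || is.na(eaf_x)) {
        excl[[length(excl) + 1L]] <- c(rsid, "palindromic_intermediate"); next
      }
      intermediate <- (eaf_x > eaf_window[1] & eaf_x < eaf_window[2]) ||
        (eaf_out > eaf_window[1] & eaf_out < eaf_window[2])
      if (intermediate) {
        excl[[length(excl) + 1L]] <- c(rsid, "palindromic_intermediate"); next
      }
      if ((eaf_x < 0.5) != (eaf_out < 0.5)) {
        beta_out <- -beta_out; eaf_out <- 1 - eaf_out; flipped <- TRUE
      }
    } else if (swapped) {
      beta_out <- -beta_out
      eaf_out <- if (is.na(eaf_out)) NA_real_ else 1 - eaf_out
      flipped <- TRUE
    }
    keep[[length(keep) + 1L]] <- data.frame(
      rsid = rsid,
      beta_exp = exp_tab$beta[i], se_exp = exp_tab$se[i],
      beta_out = beta_out, se_out = outcome$se[j],
      eaf_exp = exp_tab$eaf[i], eaf_out = eaf_out,
      flipped = flipped, palindromic = pal[i],
      stringsAsFactors = FALSE)
  }

  pairs <- if (length(keep)) do.call(rbind, keep) else
    data.frame(rsid = character(0), beta_exp = numeric(0), se_exp = numeric(0),
               beta_out = numeric(0), se_out = numeric(0),
               eaf_exp = numeric(0), eaf_out = numeric(0),
               flipped = logical(0), palindromic = logical(0),
               stringsAsFactors = FALSE)
  exclusions <- if (length(excl)) {
    m <- do.call(rbind, excl)
    data.frame(rsid = m[, 1], reason = m[, 2], stringsAsFactors = FALSE)
  } else NULL
  harmonized_set(pairs, exposure_label, trait_label(outcome), exclusions)
}

#' Read/write harmonized effect pairs as TSV
#'
#' The TSV layout (`rsid`, `beta_exp`, `se_exp`, `beta_out`, `se_out`,
#' `eaf_exp`, `eaf_out`, `flipped`, `palindromic`) doubles as the ingestion
#' format for re-running estimators on externally harmonized instrument
#' tables.
#'
#' @param x a [harmonized_set].
#' @param path file path.
#' @param exposure_label,outcome_label labels used on read.
#' @return `write_harmonized()` returns `path` invisibly;
#'   `read_harmonized()` returns a [harmonized_set].
#' @export
write_harmonized <- function(x, path) {
  stopifnot(inherits(x, "harmonized_set"))
  df <- x$pairs
  for (col in c("beta_exp", "se_exp", "beta_out", "se_out", "eaf_exp", "eaf_out")) {
    df[[col]] <- sprintf("%.15g", df[[col]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_harmonized
#' @export
read_harmonized <- function(path, exposure_label = "exposure",
                            outcome_label = "outcome") {
  df <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          showProgress = FALSE)
  harmonized_set(df, exposure_label, outcome_label)
}
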