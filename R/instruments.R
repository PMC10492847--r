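# Instrument selection: significance filter, greedy LD clumping, confounder
# screen, and instrument-strength metrics (R2, F).

.step_log <- function(step, n_in, n_out, dropped) {
  if (is.null(dropped)) {
    dropped <- data.frame(rsid = character(0), detail = character(0),
                          stringsAsFactors = FALSE)
  }
  stopifnot(n_in == n_out + nrow(dropped))
  list(step = step, n_in = n_in, n_out = n_out, dropped = dropped)
}

#' Filter SNPs by association p-value
#'
#' Keeps records with `pvalue < p_threshold` (strict), ordered by ascending
#' p-value. The dropped rsids are recorded in the step log (attribute
#' `"step_log"`), which [build_instrument_set()] collects into provenance.
#'
#' @param x a [sumstats] table.
#' @param p_threshold significance threshold in (0, 1); conventionally
#'   `5e-8` for genome-wide significance, relaxed (e.g. `5e-6`) when few
#'   instruments are available.
#' @return A [sumstats] table of the significant records.
#' @export
select_significant <- function(x, p_threshold) {
  stopifnot(inherits(x, "sumstats"),
            is.numeric(p_threshold), length(p_threshold) == 1L,
            p_threshold > 0, p_threshold < 1 || p_threshold == 1)
  keep <- x$pvalue < p_threshold
  out <- x[keep, , drop = FALSE]
  out <- out[order(out$pvalue, out$chrom, out$pos, out$rsid), , drop = FALSE]
  rownames(out) <- NULL
  dropped <- data.frame(rsid = x$rsid[!keep],
                        detail = sprintf("p=%.3g", x$pvalue[!keep]),
                        stringsAsFactors = FALSE)
  attr(out, "step_log") <- .step_log("significance", nrow(x), nrow(out), dropped)
  out
}

#' Greedy LD clumping
#'
#' Iterates records by ascending p-value (ties broken by chromosome,
#' position, then rsid, so the result is invariant to input row order) and
#' keeps a record unless it lies within `window_kb` of an already-kept
#' record on the same chromosome *and* has r-squared with it above `r2_max`.
#' SNPs without a position in the LD reference are retained as isolated and
#' noted in the step log, since an external panel cannot be assumed to cover
#' every variant.
#'
#' @param x a [sumstats] table.
#' @param ld an [ld_reference].
#' @param r2_max LD pruning threshold (default 0.001).
#' @param window_kb window half-width in kilobases around each kept index
#'   SNP (default 10,000 kb, i.e. +/- 10 Mb).
#' @return A [sumstats] table of approximately independent records; step log
#'   records each dropped rsid together with the index SNP that removed it.
#' @export
ld_clump <- function(x, ld, r2_max = 0.001, window_kb = 10000) {
  stopifnot(inherits(x, "sumstats"), inherits(ld, "ld_reference"),
            r2_max >= 0, window_kb > 0)
  ord <- order(x$pvalue, x$chrom, x$pos, x$rsid)
  d <- as.data.frame(x)[ord, , drop = FALSE]
  pos <- ld_positions(ld, d$rsid)
  no_pos <- is.na(pos$pos)
  window_bp <- window_kb * 1000

  kept <- logical(nrow(d))
  removed_by <- rep(NA_character_, nrow(d))
  for (i in seq_len(nrow(d))) {
    if (no_pos[i]) { kept[i] <- TRUE; next }
    prior <- which(kept & !no_pos & pos$chrom == pos$chrom[i] &
                     abs(pos$pos - pos$pos[i]) <= window_bp)
    if (length(prior)) {
      r2 <- ld_r2(ld, d$rsid[i], d$rsid[prior])
      hit <- which(r2 > r2_max)
      if (length(hit)) { removed_by[i] <- d$rsid[prior[hit[1L]]]; next }
    }
    kept[i] <- TRUE
  }

  out <- x[match(d$rsid[kept], x$rsid), , drop = FALSE]
  out <- out[order(out$pvalue, out$chrom, out$pos, out$rsid), , drop = FALSE]
  rownames(out) <- NULL
  dropped <- data.frame(rsid = d$rsid[!kept],
                        detail = sprintf("clumped_by=%s", removed_by[!kept]),
                        stringsAsFactors = FALSE)
  log <- .step_log("ld_clump", nrow(x), nrow(out), dropped)
  log$no_position <- d$rsid[no_pos & kept]
  attr(out, "step_log") <- log
  out
}

#' Screen instruments against confounder traits
#'
#' Removes any record that is itself associated — or has a proxy SNP with
#' r-squared above `proxy_r2` associated — with any listed confounder trait
#' at `pvalue < p_thr`, enforcing the independence assumption that
#' instruments must not act through confounders of the exposure-outcome
#' relationship.
#'
#' @param x a [sumstats] table.
#' @param catalog a [trait_catalog].
#' @param confounder_traits non-empty character vector of trait names to
#'   screen against.
#' @param p_thr association p-value threshold (default `5e-8`).
#' @param proxy_r2 minimum proxy r-squared (strict inequality; default 0.80).
#' @return A [sumstats] table of clean records; step log names the offending
#'   trait for every removal.
#' @export
screen_confounders <- function(x, catalog, confounder_traits,
                               p_thr = 5e-8, proxy_r2 = 0.80) {
  stopifnot(inherits(x, "sumstats"), inherits(catalog, "trait_catalog"),
            length(confounder_traits) >= 1L, p_thr > 0, p_thr < 1)
  assoc <- catalog$associations
  hits <- assoc[assoc$trait %in% confounder_traits & assoc$pvalue < p_thr, ,
                drop = FALSE]
  offending <- rep(NA_character_, nrow(x))
  if (nrow(hits)) {
    idx <- match(x$rsid, hits$rsid)
    offending <- ifelse(is.na(idx), NA_character_, hits$trait[idx])
    px <- catalog$proxies
    if (nrow(px)) {
      px <- px[px$r2 > proxy_r2, , drop = FALSE]
      for (i in which(is.na(offending))) {
        proxies_i <- px$proxy_rsid[px$rsid == x$rsid[i]]
        if (length(proxies_i)) {
          j <- match(proxies_i, hits$rsid)
          j <- j[!is.na(j)]
          if (length(j)) offending[i] <- paste0(hits$trait[j[1L]], " (proxy)")
        }
      }
    }
  }
  keep <- is.na(offending)
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  dropped <- data.frame(rsid = x$rsid[!keep], detail = offending[!keep],
                        stringsAsFactors = FALSE)
  attr(out, "step_log") <- .step_log("confounder_screen", nrow(x), nrow(out), dropped)
  out
}

#' Variance in the trait explained by a SNP
#'
#' `R2 = 2 * MAF * (1 - MAF) * (beta / trait_sd)^2` with
#' `MAF = min(eaf, 1 - eaf)`; for an additively coded biallelic SNP this is
#' the fraction of variance of a unit-SD trait explained by the variant.
#'
#' @param eaf effect-allele frequency in (0, 1); vectorised.
#' @param beta per-allele effect estimate; vectorised.
#' @param trait_sd standard deviation of the trait on beta's scale
#'   (default 1, i.e. beta already standardized / log-odds scale).
#' @return numeric vector of per-SNP R-squared values.
#' @export
variance_explained <- function(eaf, beta, trait_sd = 1) {
  if (!all(trait_sd > 0)) stop("variance_explained: trait_sd must be > 0",
                               call. = FALSE)
  stopifnot(all(eaf > 0 & eaf < 1))
  maf <- pmin(eaf, 1 - eaf)
  2 * maf * (1 - maf) * (beta / trait_sd)^2
}

#' Instrument-strength F statistic
#'
#' `F = ((N - k - 1) / k) * (R2 / (1 - R2))` for `k` instruments jointly
#' explaining a fraction `R2` of exposure variance in a sample of size `N`.
#' `F > 10` (strict) is the conventional threshold for a sufficiently strong
#' instrument; at or below 10 the instrument is considered weak.
#'
#' @param total_r2 total variance explained, in `[0, 1)`.
#' @param n exposure-study sample size; must exceed `k + 1`.
#' @param k number of instruments (>= 1).
#' @return The F statistic (nonnegative scalar).
#' @seealso [is_strong_instrument()]
#' @export
f_statistic <- function(total_r2, n, k) {
  stopifnot(k >= 1, total_r2 >= 0, total_r2 < 1)
  if (n <= k + 1) stop("f_statistic: require n > k + 1", call. = FALSE)
  ((n - k - 1) / k) * (total_r2 / (1 - total_r2))
}

#' @rdname f_statistic
#' @param f an F statistic.
#' @return `is_strong_instrument()`: `TRUE` iff `f > 10` (strict).
#' @export
is_strong_instrument <- function(f) f > 10

#' Build an instrument set by sequential quality control
#'
#' Applies [select_significant()], [ld_clump()] and (when a catalogue is
#' supplied) [screen_confounders()] in that order, then computes per-SNP and
#' total R-squared and the F statistic. The provenance log records counts in
#' and out of every step together with each dropped rsid and the reason.
#'
#' @param x a [sumstats] table for the exposure trait.
#' @param ld an [ld_reference].
#' @param catalog optional [trait_catalog]; `NULL` skips the screen.
#' @param n_exposure exposure-study sample size used by the F statistic
#'   (study-level; per-record `n` is not used).
#' @param p_threshold significance threshold (default `5e-8`).
#' @param clump_r2,clump_window_kb clumping parameters (defaults 0.001 and
#'   10,000 kb).
#' @param confounder_traits traits to screen against (required when
#'   `catalog` is given).
#' @param confounder_p,proxy_r2 screen thresholds (defaults `5e-8`, 0.80).
#' @param trait_sd trait SD for [variance_explained()] (default 1).
#' @return An `instrument_set`: list with `exposure_label`, `instruments`
#'   (a [sumstats] table), `per_snp_r2`, `total_r2`, `f_statistic`, `strong`,
#'   `n_exposure`, `k` and `provenance`. An empty final set is returned with
#'   a warning rather than an error; downstream estimators then refuse.
#' @export
build_instrument_set <- function(x, ld, catalog = NULL, n_exposure,
                                 p_threshold = 5e-8,
                                 clump_r2 = 0.001, clump_window_kb = 10000,
                                 confounder_traits = NULL,
                                 confounder_p = 5e-8, proxy_r2 = 0.80,
                                 trait_sd = 1) {
  stopifnot(inherits(x, "sumstats"))
  provenance <- list()
  cur <- select_significant(x, p_threshold)
  provenance <- c(provenance, list(attr(cur, "step_log")))
  cur <- ld_clump(cur, ld, r2_max = clump_r2, window_kb = clump_window_kb)
  provenance <- c(provenance, list(attr(cur, "step_log")))
  if (!is.null(catalog) && !is.null(confounder_traits)) {
    cur <- screen_confounders(cur, catalog, confounder_traits,
                              p_thr = confounder_p, proxy_r2 = proxy_r2)
    provenance <- c(provenance, list(attr(cur, "step_log")))
  }
  k <- nrow(cur)
  if (k == 0L) {
    warning("build_instrument_set: no instruments survive quality control",
            call. = FALSE)
    per_snp_r2 <- numeric(0); total_r2 <- 0; f <- NA_real_
  } else {
    per_snp_r2 <- stats::setNames(
      variance_explained(cur$eaf, cur$beta, trait_sd), cur$rsid)
    total_r2 <- sum(per_snp_r2)
    f <- if (n_exposure > k + 1) f_statistic(total_r2, n_exposure, k) else NA_real_
  }
  structure(list(exposure_label = trait_label(x),
                 instruments = cur,
                 per_snp_r2 = per_snp_r2,
                 total_r2 = total_r2,
                 f_statistic = f,
                 strong = if (is.na(f)) NA else is_strong_instrument(f),
                 n_exposure = n_exposure,
                 k = k,
                 provenance = provenance),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Instrument set for %s: k = %d, total R2 = %.4g, F = %.4g (%s)\n",
              x$exposure_label, x$k, x$total_r2, x$f_statistic,
              if (isTRUE(x$strong)) "strong" else "weak"))
  for (st in x$provenance) {
    cat(sprintf("  %-18s %d -> %d (%d dropped)\n",
                st$step, st$n_in, st$n_out, nrow(st$dropped)))
  }
  invisible(x)
}

#' Provenance of an instrument set as a data frame
#'
#' @param x an `instrument_set`.
#' @return data frame with columns `step`, `n_in`, `n_out`, `n_dropped`.
#' @export
provenance_table <- function(x) {
  stopifnot(inherits(x, "instrument_set"))
  do.call(rbind, lapply(x$provenance, function(st) {
    data.frame(step = st$step, n_in = st$n_in, n_out = st$n_out,
               n_dropped = nrow(st$dropped), stringsAsFactors = FALSE)
  }))
}
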