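# GWAS summary-statistics tables: construction, validation, delimited I/O.

SUMSTATS_COLS <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pvalue", "n")

# Column-name dialects recognised when no explicit column_map is given.
# Matching is case-insensitive; first hit wins.
.default_dialects <- list(
  rsid          = c("rsid", "snp", "id", "markername", "variant_id", "rs_id"),
  chrom         = c("chrom", "chr", "chromosome", "#chrom"),
  pos           = c("pos", "bp", "position", "base_pair_location", "pos_b37", "pos_b38"),
  effect_allele = c("effect_allele", "a1", "ea", "allele1", "alt", "effect.allele"),
  other_allele  = c("other_allele", "a2", "oa", "nea", "allele2", "ref", "non_effect_allele"),
  eaf           = c("eaf", "af", "effect_allele_frequency", "freq", "frq", "maf"),
  beta          = c("beta", "b", "effect", "effect_size", "logor"),
  se            = c("se", "standard_error", "stderr", "sebeta"),
  pvalue        = c("pvalue", "p", "pval", "p_value", "p.value"),
  n             = c("n", "samplesize", "n_total", "neff")
)

#' Construct a validated summary-statistics table
#'
#' Builds a `sumstats` object from a data frame of per-SNP associations.
#' Rows violating the per-record invariants (single-base A/C/G/T alleles,
#' distinct effect and other alleles, `se > 0`, `eaf` strictly inside (0,1),
#' `pvalue` in (0,1]) are rejected, not silently dropped: every rejection is
#' recorded with its reason and retrievable via [rejections()]. Duplicate
#' rsids are an integrity error because downstream instrument selection keys
#' on rsid.
#'
#' @param df data frame with columns `rsid`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pvalue` and optionally `n`
#'   (per-record sample size; may be `NA`).
#' @param trait_label short label for the trait (e.g. `"IBD"`).
#' @param source free-text provenance tag.
#' @param genome_build free-text build tag (metadata only; positions are
#'   1-based and never lifted over).
#' @return A `sumstats` object: a data frame with attributes `trait_label`,
#'   `source`, `genome_build` and `rejections`.
#' @export
sumstats <- function(df, trait_label, source = NA_character_,
                     genome_build = NA_character_) {
  stopifnot(is.data.frame(df), is.character(trait_label), length(trait_label) == 1L)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  required <- setdiff(SUMSTATS_COLS, "n")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("sumstats: missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"n" %in% names(df)) df$n <- NA_integer_
  df <- df[SUMSTATS_COLS]

  df$rsid <- as.character(df$rsid)
  df$chrom <- as.character(df$chrom)
  df$pos <- suppressWarnings(as.integer(df$pos))
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("eaf", "beta", "se", "pvalue")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  df$n <- suppressWarnings(as.integer(df$n))

  reason <- rep(NA_character_, nrow(df))
  flag <- function(bad, why) {
    bad[is.na(bad)] <- TRUE
    ifelse(is.na(reason) & bad, why, reason)
  }
  valid_base <- function(a) !is.na(a) & a %in% c("A", "C", "G", "T")
  reason <- flag(!valid_base(df$effect_allele) | !valid_base(df$other_allele),
                 "invalid_allele")
  reason <- flag(df$effect_allele == df$other_allele, "allele_equal")
  reason <- flag(is.na(df$rsid) | df$rsid == "", "missing_rsid")
  reason <- flag(is.na(df$pos) | df$pos < 1L, "invalid_position")
  reason <- flag(!(df$se > 0), "nonpositive_se")
  reason <- flag(!(df$eaf > 0 & df$eaf < 1), "eaf_out_of_range")
  reason <- flag(!(df$pvalue > 0 & df$pvalue <= 1), "pvalue_out_of_range")
  reason <- flag(is.na(df$beta), "missing_beta")

  bad <- !is.na(reason)
  rej <- data.frame(rsid = df$rsid[bad], row = which(bad),
                    reason = reason[bad], stringsAsFactors = FALSE)
  keep <- df[!bad, , drop = FALSE]
  rownames(keep) <- NULL

  dup <- keep$rsid[duplicated(keep$rsid)]
  if (length(dup)) {
    stop("sumstats: duplicate rsid(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }

  structure(keep,
            trait_label = trait_label,
            source = source,
            genome_build = genome_build,
            rejections = rej,
            class = c("sumstats", "data.frame"))
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%d SNPs, %d rejected rows)\n",
              trait_label(x), nrow(x), nrow(rejections(x))))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

#' Trait label and rejection log accessors
#'
#' @param x a `sumstats` object.
#' @return `trait_label()` the trait label; `rejections()` a data frame of
#'   rows rejected at validation with columns `rsid`, `row`, `reason`.
#' @export
trait_label <- function(x) attr(x, "trait_label", exact = TRUE)

#' @rdname trait_label
#' @export
rejections <- function(x) attr(x, "rejections", exact = TRUE)

#' @export
as.data.frame.sumstats <- function(x, ...) {
  out <- x
  class(out) <- "data.frame"
  for (a in c("trait_label", "source", "genome_build", "rejections")) {
    attr(out, a) <- NULL
  }
  out
}

# Keep sumstats attributes through row subsetting.
#' @export
`[.sumstats` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && identical(names(out), names(x))) {
    attributes_to_copy <- c("trait_label", "source", "genome_build", "rejections")
    for (a in attributes_to_copy) attr(out, a) <- attr(x, a, exact = TRUE)
    class(out) <- class(x)
  }
  out
}

.map_columns <- function(header, column_map = NULL) {
  lower <- tolower(header)
  out <- character(0)
  if (!is.null(column_map)) {
    stopifnot(is.character(column_map), !is.null(names(column_map)))
    unknown <- setdiff(names(column_map), SUMSTATS_COLS)
    if (length(unknown)) {
      stop("read_sumstats: unknown field(s) in column_map: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    for (field in names(column_map)) {
      hit <- match(tolower(column_map[[field]]), lower)
      if (is.na(hit)) {
        stop("read_sumstats: mapped column '", column_map[[field]],
             "' for field '", field, "' not present in file", call. = FALSE)
      }
      out[field] <- header[hit]
    }
  }
  for (field in setdiff(SUMSTATS_COLS, names(out))) {
    hit <- match(.default_dialects[[field]], lower)
    hit <- hit[!is.na(hit)]
    if (length(hit)) out[field] <- header[hit[1L]]
  }
  required <- setdiff(SUMSTATS_COLS, "n")
  missing_fields <- setdiff(required, names(out))
  if (length(missing_fields)) {
    stop("read_sumstats: could not resolve column(s) for field(s): ",
         paste(missing_fields, collapse = ", "),
         "; supply a column_map", call. = FALSE)
  }
  out
}

#' Read a GWAS summary-statistics file
#'
#' Reads a delimited text file (tab or comma, auto-detected) with a header
#' row into a validated [sumstats] table. Column names are resolved either
#' through `column_map` (internal field name -> file column name) or through
#' a built-in catalogue of common GWAS export dialects (`SNP`/`rsid`,
#' `BETA`/`b`, `P`/`pval`, ...).
#'
#' @inheritParams sumstats
#' @param path path to the delimited file.
#' @param column_map optional named character vector, names from
#'   `r paste(SUMSTATS_COLS, collapse = ", ")`.
#' @return A [sumstats] object. Rows failing validation are logged (see
#'   [rejections()]), never silently dropped.
#' @export
read_sumstats <- function(path, trait_label, column_map = NULL,
                          source = path, genome_build = NA_character_) {
  if (!file.exists(path)) stop("read_sumstats: no such file: ", path, call. = FALSE)
  raw <- data.table::fread(path, header = TRUE, data.table = FALSE,
                           colClasses = "character", showProgress = FALSE)
  cmap <- .map_columns(names(raw), column_map)
  df <- as.data.frame(lapply(cmap, function(col) raw[[col]]),
                      stringsAsFactors = FALSE)
  names(df) <- names(cmap)
  sumstats(df, trait_label = trait_label, source = source,
           genome_build = genome_build)
}

#' Write a summary-statistics table to tab-delimited text
#'
#' Floating-point fields are written with 15 significant digits so that a
#' write/read round trip reproduces the table to better than 12 significant
#' digits.
#'
#' @param x a [sumstats] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  stopifnot(inherits(x, "sumstats"))
  df <- as.data.frame(x)
  for (col in c("eaf", "beta", "se", "pvalue")) {
    df[[col]] <- sprintf("%.15g", df[[col]])
  }
  df$n <- ifelse(is.na(df$n), "NA", as.character(df$n))
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("write_sumstats: cannot write '", path, "': ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}
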