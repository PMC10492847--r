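# LD reference panels and confounder-trait catalogues (local stand-ins for
# an external LD panel and the PhenoScanner-style trait lookup).

.ld_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Construct an LD reference
#'
#' A symmetric pairwise r-squared lookup plus SNP positions. Unknown pairs
#' default to r2 = 0 (treated as unlinked); self-pairs are always 1.
#'
#' @param pairs data frame with columns `rsid_a`, `rsid_b`, `r2`
#'   (long format), or `NULL` for an empty (all-unlinked) reference.
#' @param positions data frame with columns `rsid`, `chrom`, `pos`.
#' @return An `ld_reference` object.
#' @export
ld_reference <- function(pairs = NULL, positions) {
  stopifnot(is.data.frame(positions),
            all(c("rsid", "chrom", "pos") %in% names(positions)))
  positions <- data.frame(rsid = as.character(positions$rsid),
                          chrom = as.character(positions$chrom),
                          pos = as.integer(positions$pos),
                          stringsAsFactors = FALSE)
  if (anyDuplicated(positions$rsid)) {
    stop("ld_reference: duplicate rsids in position table", call. = FALSE)
  }
  r2 <- numeric(0)
  if (!is.null(pairs) && nrow(pairs)) {
    stopifnot(all(c("rsid_a", "rsid_b", "r2") %in% names(pairs)))
    v <- as.numeric(pairs$r2)
    if (any(is.na(v) | v < 0 | v > 1)) {
      stop("ld_reference: r2 values must lie in [0, 1]", call. = FALSE)
    }
    r2 <- v
    names(r2) <- .ld_key(as.character(pairs$rsid_a), as.character(pairs$rsid_b))
    r2 <- r2[!duplicated(names(r2))]
  }
  structure(list(r2 = r2, positions = positions), class = "ld_reference")
}

#' Read an LD reference from long-format TSV files
#'
#' @param pairs_path TSV with columns `rsid_a`, `rsid_b`, `r2`; `NULL` for an
#'   all-unlinked reference.
#' @param positions_path TSV with columns `rsid`, `chrom`, `pos`.
#' @return An [ld_reference] object.
#' @export
read_ld_reference <- function(pairs_path = NULL, positions_path) {
  pos <- data.table::fread(positions_path, header = TRUE, data.table = FALSE,
                           showProgress = FALSE)
  pairs <- NULL
  if (!is.null(pairs_path)) {
    pairs <- data.table::fread(pairs_path, header = TRUE, data.table = FALSE,
                               showProgress = FALSE)
  }
  ld_reference(pairs, pos)
}

#' Pairwise r-squared lookup
#'
#' Vectorised over `a`/`b`. Symmetric; `ld_r2(x, s, s)` is 1; pairs absent
#' from the panel return 0.
#'
#' @param ld an [ld_reference].
#' @param a,b character vectors of rsids (recycled to a common length).
#' @return numeric vector of r-squared values.
#' @export
ld_r2 <- function(ld, a, b) {
  stopifnot(inherits(ld, "ld_reference"))
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  out <- unname(ld$r2[.ld_key(a, b)])
  out[is.na(out)] <- 0
  out[a == b] <- 1
  out
}

#' SNP positions from an LD reference
#'
#' @param ld an [ld_reference].
#' @param rsids rsids to look up.
#' @return data frame with `rsid`, `chrom`, `pos`; `NA` rows for SNPs absent
#'   from the reference.
#' @export
ld_positions <- function(ld, rsids) {
  stopifnot(inherits(ld, "ld_reference"))
  idx <- match(as.character(rsids), ld$positions$rsid)
  data.frame(rsid = as.character(rsids),
             chrom = ld$positions$chrom[idx],
             pos = ld$positions$pos[idx],
             stringsAsFactors = FALSE)
}

#' @export
print.ld_reference <- function(x, ...) {
  cat(sprintf("LD reference: %d SNP positions, %d stored r2 pairs\n",
              nrow(x$positions), length(x$r2)))
  invisible(x)
}

#' Construct a confounder-trait catalogue
#'
#' A local catalogue of SNP-trait associations (with optional proxy-SNP
#' links) used to screen instruments against known confounder traits, in the
#' role an external phenome-wide lookup service plays in published analyses.
#'
#' @param associations data frame with columns `rsid`, `trait`, `pvalue`, or
#'   `NULL` for an empty catalogue.
#' @param proxies optional data frame with columns `rsid`, `proxy_rsid`,
#'   `r2` linking instruments to correlated proxy SNPs.
#' @return A `trait_catalog` object.
#' @export
trait_catalog <- function(associations = NULL, proxies = NULL) {
  if (is.null(associations)) {
    associations <- data.frame(rsid = character(0), trait = character(0),
                               pvalue = numeric(0), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("rsid", "trait", "pvalue") %in% names(associations)))
  p <- as.numeric(associations$pvalue)
  if (length(p) && any(is.na(p) | p <= 0 | p > 1)) {
    stop("trait_catalog: association p-values must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(proxies)) {
    proxies <- data.frame(rsid = character(0), proxy_rsid = character(0),
                          r2 = numeric(0), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("rsid", "proxy_rsid", "r2") %in% names(proxies)))
  pr <- as.numeric(proxies$r2)
  if (length(pr) && any(is.na(pr) | pr < 0 | pr > 1)) {
    stop("trait_catalog: proxy r2 values must lie in [0, 1]", call. = FALSE)
  }
  structure(list(
    associations = data.frame(rsid = as.character(associations$rsid),
                              trait = as.character(associations$trait),
                              pvalue = p, stringsAsFactors = FALSE),
    proxies = data.frame(rsid = as.character(proxies$rsid),
                         proxy_rsid = as.character(proxies$proxy_rsid),
                         r2 = pr, stringsAsFactors = FALSE)
  ), class = "trait_catalog")
}

#' Read a confounder-trait catalogue from TSV files
#'
#' @param associations_path TSV with columns `rsid`, `trait`, `pvalue`.
#' @param proxies_path optional TSV with columns `rsid`, `proxy_rsid`, `r2`.
#' @return A [trait_catalog] object.
#' @export
read_trait_catalog <- function(associations_path, proxies_path = NULL) {
  assoc <- data.table::fread(associations_path, header = TRUE,
                             data.table = FALSE, showProgress = FALSE)
  proxies <- NULL
  if (!is.null(proxies_path)) {
    proxies <- data.table::fread(proxies_path, header = TRUE,
                                 data.table = FALSE, showProgress = FALSE)
  }
  trait_catalog(assoc, proxies)
}

#' @export
print.trait_catalog <- function(x, ...) {
  cat(sprintf("Trait catalogue: %d SNP-trait associations, %d proxy links\n",
              nrow(x$associations), nrow(x$proxies)))
  invisible(x)
}
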