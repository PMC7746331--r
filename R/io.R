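# Reading summary-statistics tables and pleiotropy exclusion lists.

.STANDARD_FIELDS <- c("rsid", "effect_allele", "other_allele", "eaf",
                      "beta", "se", "pvalue")
.REQUIRED_FIELDS <- c("rsid", "effect_allele", "other_allele", "beta", "se")

.inferSep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a GWAS summary-statistics table
#'
#' Reads a delimited text table with one row per variant and returns a
#' validated association data.frame with the standard columns
#' `rsid, effect_allele, other_allele, eaf, beta, se, pvalue`.  Columns are
#' located by name through `columnMap`, never by position, so column order in
#' the file is irrelevant; a missing mapped column is a configuration error.
#'
#' @param path path to a TSV (default) or CSV file with a header row.
#' @param columnMap named character vector or list mapping standard field
#'   names to the file's column headers, e.g.
#'   `c(rsid = "SNP", beta = "Effect", se = "StdErr", ...)`.  Fields omitted
#'   from the map are taken to use their standard names.  `eaf` and `pvalue`
#'   are optional and filled with `NA` when their column is absent.
#' @param sep field separator; default inferred from the file extension
#'   (`","` for `.csv`, tab otherwise).
#' @param permissive if `FALSE` (default) rows with missing beta or se abort
#'   with an error naming the offending variants; if `TRUE` such rows are
#'   dropped, counted in the `"n_dropped"` attribute, and reported via
#'   `message()`.
#' @return data.frame of per-variant associations; attribute `n_dropped`
#'   counts permissively dropped rows.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write.table(data.frame(rsid = c("rs1", "rs2"), effect_allele = c("A", "C"),
#'                        other_allele = c("G", "T"), eaf = c(0.3, 0.4),
#'                        beta = c(0.1, -0.05), se = c(0.01, 0.02),
#'                        pvalue = c(1e-9, 1e-8)),
#'             f, sep = "\t", row.names = FALSE, quote = FALSE)
#' readSummaryTable(f)
#' @export
readSummaryTable <- function(path, columnMap = NULL, sep = NULL,
                             permissive = FALSE) {
  if (!file.exists(path)) stop("summary table not found: ", path)
  if (is.null(sep)) sep <- .inferSep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", comment.char = "")
  cmap <- as.list(stats::setNames(.STANDARD_FIELDS, .STANDARD_FIELDS))
  if (!is.null(columnMap)) {
    columnMap <- as.list(columnMap)
    bad <- setdiff(names(columnMap), .STANDARD_FIELDS)
    if (length(bad))
      stop("unknown field(s) in columnMap: ", paste(bad, collapse = ", "))
    cmap[names(columnMap)] <- columnMap
  }
  for (fld in .REQUIRED_FIELDS) {
    if (!cmap[[fld]] %in% names(raw))
      stop(sprintf("required column '%s' (mapped from field '%s') not found in %s",
                   cmap[[fld]], fld, path))
  }
  out <- data.frame(rsid = as.character(raw[[cmap$rsid]]),
                    effect_allele = toupper(as.character(raw[[cmap$effect_allele]])),
                    other_allele = toupper(as.character(raw[[cmap$other_allele]])),
                    stringsAsFactors = FALSE)
  num <- function(fld) {
    col <- cmap[[fld]]
    if (!col %in% names(raw)) return(rep(NA_real_, nrow(raw)))
    suppressWarnings(as.numeric(raw[[col]]))
  }
  out$eaf <- num("eaf")
  out$beta <- num("beta")
  out$se <- num("se")
  out$pvalue <- num("pvalue")

  missing <- is.na(out$beta) | is.na(out$se)
  nDropped <- 0L
  if (any(missing)) {
    if (!permissive)
      stop("rows with missing beta or se: ",
           paste(out$rsid[missing], collapse = ", "),
           " (set permissive = TRUE to drop them)")
    nDropped <- sum(missing)
    message(sprintf("dropped %d row(s) with missing beta/se from %s",
                    nDropped, path))
    out <- out[!missing, , drop = FALSE]
  }
  badSe <- out$se <= 0
  if (any(badSe))
    stop("non-positive standard error for variant(s): ",
         paste(out$rsid[badSe], collapse = ", "))
  badAllele <- !(out$effect_allele %in% c("A", "C", "G", "T")) |
               !(out$other_allele %in% c("A", "C", "G", "T")) |
               out$effect_allele == out$other_allele
  if (any(badAllele))
    stop("invalid allele pair for variant(s): ",
         paste(out$rsid[badAllele], collapse = ", "))
  badEaf <- !is.na(out$eaf) & (out$eaf < 0 | out$eaf > 1)
  if (any(badEaf))
    stop("effect-allele frequency outside [0,1] for variant(s): ",
         paste(out$rsid[badEaf], collapse = ", "))
  rownames(out) <- NULL
  attr(out, "n_dropped") <- nDropped
  out
}

#' Read a pleiotropy exclusion list
#'
#' Two-column delimited text (header `rsid`, `reason`) listing variants to be
#' removed from the instrument set, e.g. the result of a phenome-wide look-up
#' flagging variants associated with other traits at genome-wide
#' significance.
#'
#' @param path path to the file (TSV default, CSV by extension).
#' @param sep field separator; inferred from the extension when `NULL`.
#' @return list with `rsids` (character vector) and `reasons` (named
#'   character vector keyed by rsid).
#' @export
readExclusionList <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("exclusion list not found: ", path)
  if (is.null(sep)) sep <- .inferSep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", comment.char = "")
  if (!"rsid" %in% names(raw))
    stop("exclusion list must have an 'rsid' column: ", path)
  reasons <- if ("reason" %in% names(raw)) as.character(raw$reason)
             else rep("excluded", nrow(raw))
  list(rsids = as.character(raw$rsid),
       reasons = stats::setNames(reasons, as.character(raw$rsid)))
}

#' Remove excluded variants from an instrument set
#'
#' Filters an association table against an exclusion list, preserving the
#' order of the kept records, and reports the disposition of every affected
#' rsid.  Excluding an rsid that is not present is a no-op, noted in the
#' report.
#'
#' @param records association data.frame as returned by
#'   [readSummaryTable()].
#' @param exclusions an exclusion list from [readExclusionList()], or a
#'   character vector of rsids (reasons default to "excluded").
#' @return list with `kept` (filtered data.frame, input order preserved) and
#'   `report` (data.frame: rsid, disposition in
#'   \{excluded, not_present\}, reason).
#' @examples
#' recs <- data.frame(rsid = paste0("rs", 1:7), beta = rnorm(7), se = 0.1)
#' res <- applyExclusions(recs, c("rs3"))
#' nrow(res$kept)  # 6
#' @export
applyExclusions <- function(records, exclusions) {
  if (is.character(exclusions))
    exclusions <- list(rsids = exclusions,
                       reasons = stats::setNames(rep("excluded",
                                                     length(exclusions)),
                                                 exclusions))
  rsids <- unique(exclusions$rsids)
  drop <- records$rsid %in% rsids
  reasonOf <- function(id) {
    r <- exclusions$reasons[id]
    ifelse(is.na(r), "excluded", r)
  }
  report <- data.frame(
    rsid = rsids,
    disposition = ifelse(rsids %in% records$rsid, "excluded", "not_present"),
    reason = unname(reasonOf(rsids)),
    stringsAsFactors = FALSE)
  list(kept = records[!drop, , drop = FALSE], report = report)
}
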