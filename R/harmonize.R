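# Allele harmonization between the exposure and outcome studies.

.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

.isPalindromic <- function(ea, oa) .COMPLEMENT[ea] == oa

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns two association tables so that every retained variant's exposure
#' and outcome effects refer to the same effect allele.  Variants absent from
#' the outcome study are dropped and reported.  When the outcome study lists
#' the alleles in swapped order the outcome beta sign is flipped (and the
#' allele frequency complemented); when the alleles match only after strand
#' complementation (A<->T, C<->G) the complemented orientation is used.
#'
#' Palindromic variants (A/T or C/G pairs), whose strand cannot be resolved
#' from allele labels, are handled per `palindromicPolicy`:
#' \describe{
#'   \item{`"infer_by_eaf"` (default)}{orient by allele frequency; variants
#'     whose exposure or outcome frequency falls in the ambiguous window
#'     `[eafThreshold, 1 - eafThreshold]` (or is missing) are dropped.}
#'   \item{`"drop"`}{remove all palindromic variants.}
#'   \item{`"keep"`}{assume both studies report the same strand and align by
#'     allele label only.}
#' }
#'
#' @param exposure,outcome association data.frames from
#'   [readSummaryTable()]; both must be non-empty.
#' @param palindromicPolicy one of `"infer_by_eaf"`, `"drop"`, `"keep"`.
#' @param eafThreshold lower edge of the ambiguous frequency window, in
#'   (0, 0.5); default 0.42 (window 0.42-0.58).
#' @param traitName,exposureScale labels stored on the result.
#' @return list with `data` (an [MRData-class] of the retained variants, in
#'   exposure order) and `report` (data.frame: one row per exposure rsid with
#'   disposition in \{kept, flipped, dropped\} and a reason for drops).
#' @examples
#' expo <- data.frame(rsid = "rs1", effect_allele = "A", other_allele = "G",
#'                    eaf = 0.3, beta = 0.10, se = 0.01, pvalue = 1e-9)
#' outc <- data.frame(rsid = "rs1", effect_allele = "G", other_allele = "A",
#'                    eaf = 0.7, beta = -0.05, se = 0.02, pvalue = 0.01)
#' harmonize(expo, outc)$data   # outcome beta becomes +0.05
#' @export
harmonize <- function(exposure, outcome,
                      palindromicPolicy = c("infer_by_eaf", "drop", "keep"),
                      eafThreshold = 0.42,
                      traitName = "exposure", exposureScale = "1-SD") {
  palindromicPolicy <- match.arg(palindromicPolicy)
  if (!is.data.frame(exposure) || nrow(exposure) == 0L)
    stop("exposure table is empty")
  if (!is.data.frame(outcome) || nrow(outcome) == 0L)
    stop("outcome table is empty")
  if (eafThreshold <= 0 || eafThreshold >= 0.5)
    stop("eafThreshold must lie in (0, 0.5)")

  n <- nrow(exposure)
  disposition <- character(n)
  reason <- rep(NA_character_, n)
  keep <- logical(n)
  outBeta <- rep(NA_real_, n)
  outSe <- rep(NA_real_, n)

  idx <- match(exposure$rsid, outcome$rsid)
  ambiguous <- function(f) is.na(f) | (f >= eafThreshold & f <= 1 - eafThreshold)

  for (i in seq_len(n)) {
    j <- idx[i]
    if (is.na(j)) {
      disposition[i] <- "dropped"; reason[i] <- "not found in outcome"
      next
    }
    ea <- exposure$effect_allele[i]; oa <- exposure$other_allele[i]
    EA <- outcome$effect_allele[j];  OA <- outcome$other_allele[j]
    flip <- NA  # NA = irreconcilable
    if (.isPalindromic(ea, oa)) {
      # label alignment first; strand is unresolvable from labels alone
      labFlip <- if (EA == ea && OA == oa) FALSE
                 else if (EA == oa && OA == ea) TRUE
                 else NA
      if (is.na(labFlip)) {
        disposition[i] <- "dropped"; reason[i] <- "allele mismatch"
        next
      }
      if (palindromicPolicy == "drop") {
        disposition[i] <- "dropped"; reason[i] <- "palindromic"
        next
      }
      if (palindromicPolicy == "keep") {
        flip <- labFlip
      } else {  # infer_by_eaf
        eafX <- exposure$eaf[i]
        eafY <- outcome$eaf[j]
        eafYAligned <- if (is.na(labFlip) || !labFlip) eafY else 1 - eafY
        if (ambiguous(eafX) || ambiguous(eafYAligned)) {
          disposition[i] <- "dropped"; reason[i] <- "palindromic ambiguous eaf"
          next
        }
        # discordant minor-allele side after label alignment => strands differ
        strandFlip <- (eafX < 0.5) != (eafYAligned < 0.5)
        flip <- xor(labFlip, strandFlip)
      }
    } else {
      cea <- .COMPLEMENT[ea]; coa <- .COMPLEMENT[oa]
      if (EA == ea && OA == oa)        flip <- FALSE
      else if (EA == oa && OA == ea)   flip <- TRUE
      else if (EA == cea && OA == coa) flip <- FALSE
      else if (EA == coa && OA == cea) flip <- TRUE
      if (is.na(flip)) {
        disposition[i] <- "dropped"; reason[i] <- "allele mismatch"
        next
      }
    }
    keep[i] <- TRUE
    disposition[i] <- if (flip) "flipped" else "kept"
    outBeta[i] <- if (flip) -outcome$beta[j] else outcome$beta[j]
    outSe[i] <- outcome$se[j]
  }

  report <- data.frame(rsid = exposure$rsid, disposition = disposition,
                       reason = reason, stringsAsFactors = FALSE)
  if (!any(keep))
    stop("no variants could be harmonized between the two studies")
  data <- MRData(exposure$rsid[keep], exposure$beta[keep], exposure$se[keep],
                 outBeta[keep], outSe[keep], traitName, exposureScale)
  list(data = data, report = report)
}

#' Orient all exposure effects positive
#'
#' Flips the sign of both the exposure and the outcome coefficient for every
#' variant whose exposure effect is negative, so that each instrument is
#' coded for its exposure-increasing allele.  Per-variant ratio estimates
#' beta_outcome / beta_exposure are unchanged.  This orientation is required
#' by MR-Egger regression, whose intercept is not invariant to allele coding.
#'
#' @param data an [MRData-class] object; no exposure coefficient may be
#'   exactly zero.
#' @return An [MRData-class] with all exposure coefficients > 0.
#' @export
orientPositive <- function(data) {
  stopifnot(is(data, "MRData"))
  zero <- data@betaExposure == 0
  if (any(zero))
    stop("zero exposure coefficient for variant(s): ",
         paste(data@snpIds[zero], collapse = ", "))
  s <- sign(data@betaExposure)
  MRData(data@snpIds, s * data@betaExposure, data@seExposure,
         s * data@betaOutcome, data@seOutcome,
         data@traitName, data@exposureScale)
}
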