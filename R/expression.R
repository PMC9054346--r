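#' Relative transcript level by the 2^-dCt method
#'
#' Converts qPCR cycle thresholds to a relative concentration against a
#' reference RNA (here typically 18S rRNA):
#' `2^-(Ct_target - Ct_reference)`. Replicate Ct values are averaged on the
#' cycle scale *before* exponentiation. The orientation of the difference
#' is configurable: the conventional `"target_minus_reference"` is the
#' default; `"reference_minus_target"` is the literal alternative reading
#' (which simply inverts the result).
#'
#' @param ct_target target-gene cycle threshold(s); replicates are averaged.
#' @param ct_reference reference (housekeeping) mean cycle threshold.
#' @param orientation direction of the delta-Ct difference.
#' @return Relative concentration (dimensionless).
#' @examples
#' relative_concentration(25, 25)            # 1
#' relative_concentration(25 + 3.321928, 25) # ~0.1
#' @export
relative_concentration <- function(ct_target, ct_reference,
                                   orientation = c("target_minus_reference",
                                                   "reference_minus_target")) {
  orientation <- match.arg(orientation)
  if (length(ct_reference) != 1L || is.na(ct_reference))
    stop_myomech("a single reference mean Ct is required")
  ct_target <- ct_target[!is.na(ct_target)]
  if (!length(ct_target)) stop_myomech("no target Ct value supplied")
  if (any(c(ct_target, ct_reference) <= 0 | c(ct_target, ct_reference) >= 45))
    stop_myomech("Ct values must lie in (0, 45) cycles")
  dct <- mean(ct_target) - ct_reference
  if (orientation == "reference_minus_target") dct <- -dct
  2^(-dct)
}

#' Relative levels for a table of qPCR records
#'
#' Applies [relative_concentration()] row-wise to a table with duplicate
#' wells. Duplicates whose spread exceeds `max_spread` cycles are flagged
#' (not removed).
#'
#' @param records data frame with columns `sample_id`, `gene`, `ct_rep1`,
#'   `ct_rep2`, `ct_18s_mean`.
#' @param max_spread allowed |ct_rep1 - ct_rep2| before flagging (cycles).
#' @param orientation passed to [relative_concentration()].
#' @return The input with added columns `ct_mean`, `relative_level`,
#'   `replicate_flag`.
#' @export
qpcr_table <- function(records, max_spread = 0.5,
                       orientation = c("target_minus_reference",
                                       "reference_minus_target")) {
  orientation <- match.arg(orientation)
  require_columns(records, c("sample_id", "gene", "ct_rep1", "ct_rep2",
                             "ct_18s_mean"), "qPCR table")
  records$ct_mean <- rowMeans(records[, c("ct_rep1", "ct_rep2")],
                              na.rm = TRUE)
  records$replicate_flag <-
    abs(records$ct_rep1 - records$ct_rep2) > max_spread
  records$relative_level <- vapply(seq_len(nrow(records)), function(i) {
    relative_concentration(c(records$ct_rep1[i], records$ct_rep2[i]),
                           records$ct_18s_mean[i], orientation = orientation)
  }, numeric(1))
  records
}
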