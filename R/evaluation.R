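#' Sorensen-Dice coefficient between two masks
#'
#' `2 |A intersect B| / (|A| + |B|)`. Defined as 1 when both masks are
#' empty (identity of indiscernibles). Symmetric, in `[0, 1]`.
#'
#' @param a,b [binary_mask()]s (or 0/1 matrices) of identical shape.
#' @return Dice fraction in `[0, 1]`.
#' @examples
#' m <- binary_mask(matrix(rep(0:1, each = 32), 8, 8))
#' dice(m, m)
#' @export
dice <- function(a, b) {
  pa <- as_pixels(a); pb <- as_pixels(b)
  if (!all(dim(pa) == dim(pb))) stop("dice: mask shapes differ")
  sa <- sum(pa); sb <- sum(pb)
  if (sa + sb == 0) return(1.0)
  2 * sum(pa * pb) / (sa + sb)
}

#' Tabulate evaluation records
#'
#' Summarizes per-image Dice records into mean/min/max per
#' (method, group, stage), mirroring the usual before/after-postprocessing
#' reporting layout.
#'
#' @param records data frame with columns `image_id`, `method`, `group`,
#'   `stage` (`"pre"`/`"post"`), `dice`.
#' @return data frame with columns `method`, `group`, `stage`, `n`,
#'   `mean_dice`, `min_dice`, `max_dice`.
#' @export
summarize_records <- function(records) {
  stopifnot(nrow(records) >= 1L,
            all(c("method", "group", "stage", "dice") %in% names(records)))
  if (any(records$dice < 0 | records$dice > 1))
    stop("summarize_records: dice values must lie in [0, 1]")
  agg <- stats::aggregate(dice ~ method + group + stage, data = records,
                          FUN = function(v) c(n = length(v), mean = mean(v),
                                              min = min(v), max = max(v)))
  out <- data.frame(method = agg$method, group = agg$group, stage = agg$stage,
                    n = agg$dice[, "n"], mean_dice = agg$dice[, "mean"],
                    min_dice = agg$dice[, "min"], max_dice = agg$dice[, "max"],
                    stringsAsFactors = FALSE)
  out[order(out$method, out$group, out$stage), , drop = FALSE]
}
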