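#' MTT absorbance as percent of control
#'
#' Expresses every well's absorbance as a percentage of the mean absorbance
#' of the control group, which therefore maps to exactly 100%. Optional
#' blank-well subtraction is applied to all wells first.
#'
#' @param absorbance numeric vector of well absorbances.
#' @param group character/factor vector of group labels, same length.
#' @param control_label label of the untreated control group.
#' @param blank optional scalar blank absorbance subtracted from every
#'   well.
#' @return numeric vector of percentages, aligned with `absorbance`.
#' @export
mtt_percent <- function(absorbance, group, control_label = "ctrl",
                        blank = NULL) {
  stopifnot(length(absorbance) == length(group), is.numeric(absorbance))
  if (!is.null(blank)) absorbance <- absorbance - blank
  ctrl <- absorbance[group == control_label]
  if (length(ctrl) == 0) stop("control group '", control_label, "' is empty")
  m <- mean(ctrl)
  if (!is.finite(m) || m <= 0) {
    stop("control group mean absorbance must be positive")
  }
  100 * absorbance / m
}

#' Per-replicate representative cell count
#'
#' The representative value for one biological replicate is the arithmetic
#' mean of the cell counts over all images acquired for it.
#'
#' @param counts_per_image numeric vector of per-image cell counts (>= 1
#'   image).
#' @return scalar mean count.
#' @export
replicate_cell_count <- function(counts_per_image) {
  if (length(counts_per_image) == 0) {
    stop("at least one image count is required")
  }
  stopifnot(is.numeric(counts_per_image), all(counts_per_image >= 0))
  mean(counts_per_image)
}

#' Tidy viability table from MTT and cell-count inputs
#'
#' @param mtt_df `data.frame` with columns `replicate`, `katp_level`,
#'   `rotenone`, `absorbance` (one row per well).
#' @param counts_df `data.frame` with columns `replicate`, `katp_level`,
#'   `rotenone`, `count` (one row per image).
#' @param control_katp,control_rotenone labels identifying the untreated
#'   control cells for MTT normalization.
#' @return `data.frame` with one row per (replicate, condition):
#'   `mtt_percent` (mean over the replicate's wells) and `cell_count`
#'   (mean over the replicate's images).
#' @export
viability_table <- function(mtt_df, counts_df, control_katp = "ctrl",
                            control_rotenone = "vehicle") {
  stopifnot(all(c("replicate", "katp_level", "rotenone", "absorbance") %in%
                  names(mtt_df)),
            all(c("replicate", "katp_level", "rotenone", "count") %in%
                  names(counts_df)))
  grp <- ifelse(mtt_df$katp_level == control_katp &
                  mtt_df$rotenone == control_rotenone, "ctrl", "treated")
  pct <- mtt_percent(mtt_df$absorbance, grp, "ctrl")
  mtt_agg <- aggregate(pct,
                       mtt_df[c("replicate", "katp_level", "rotenone")],
                       mean)
  names(mtt_agg)[4] <- "mtt_percent"
  cnt_agg <- aggregate(counts_df$count,
                       counts_df[c("replicate", "katp_level", "rotenone")],
                       replicate_cell_count)
  names(cnt_agg)[4] <- "cell_count"
  merge(mtt_agg, cnt_agg,
        by = c("replicate", "katp_level", "rotenone"), all = TRUE)
}
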