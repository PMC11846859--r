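## Group-level semi-quantification: pooling per-spectrum correlation scores
## from base-positive nucleus pixels, levels relative to control, the
## Z-DNA/B-DNA score, and Kruskal-Wallis / Dunn / Holm group statistics.
## The analysis unit is the spectrum (n = number of spectra correlated).

#' Pool per-spectrum modification scores for each group
#'
#' For each group, collects the raw correlation scores of the requested
#' reference over pixels that are (a) classified as nucleus and (b) positive
#' for the modification's base species (DNA for DNA-m and the two DNA
#' conformers, Lys for Lys-m/Lys-a, Arg for Arg-m); scores are pooled across
#' the group's maps. Base positivity comes from the status table, so the
#' nucleus filter is already applied.
#'
#' @param group_maps named list (one entry per group) of lists of per-map
#'   results; each per-map result needs `status` (a [call_status()] table)
#'   and `corr` (named list of [correlation_map()]s including the requested
#'   label).
#' @param label reference label to quantify (a modification, `Z-DNA` or
#'   `B-DNA`).
#' @param base base species whose positivity gates inclusion; defaults to
#'   [base_species()] for modifications and `DNA` for the conformers.
#' @return named list of `group_levels` objects (`group_label`,
#'   `modification`, `scores`, `n`).
#' @export
collect_levels <- function(group_maps, label,
                           base = if (label %in% c("Z-DNA", "B-DNA")) "DNA"
                                  else base_species(label)) {
  out <- list()
  for (g in names(group_maps)) {
    scores <- numeric(0)
    for (mp in group_maps[[g]]) {
      status <- mp$status
      if (!base %in% names(status))
        stop("status table lacks base label '", base, "' for group ", g)
      corr <- mp$corr[[label]]
      if (is.null(corr)) stop("group ", g, " lacks a correlation map for ", label)
      keep <- status[[base]] == 1L
      if (!any(keep)) next
      idx <- match(paste(status$x[keep], status$y[keep]),
                   paste(corr$x, corr$y))
      scores <- c(scores, corr$raw[idx])
    }
    if (!length(scores))
      stop("group '", g, "' has zero qualifying spectra for ", label)
    out[[g]] <- structure(list(group_label = g, modification = label,
                               scores = scores, n = length(scores)),
                          class = "group_levels")
  }
  out
}

level_stat <- function(scores, stat) {
  if (stat == "median") stats::median(scores) else mean(scores)
}

#' Modification levels relative to control
#'
#' The level of a group is the median (by default) of its per-spectrum
#' correlation scores; each group's level is reported as a ratio to the
#' control group's level, so the control's own ratio is exactly 1.
#'
#' @param groups named list of `group_levels` (see [collect_levels()]).
#' @param ctrl_label name of the control group.
#' @param stat `"median"` (default) or `"mean"`.
#' @return data frame with `group`, `modification`, `n`, `level`,
#'   `ratio_to_ctrl`, `iqr` (interquartile range on the ratio scale).
#' @export
relative_levels <- function(groups, ctrl_label = "CTRL",
                            stat = c("median", "mean")) {
  stat <- match.arg(stat)
  if (!ctrl_label %in% names(groups))
    stop("control group '", ctrl_label, "' not present")
  ctrl <- level_stat(groups[[ctrl_label]]$scores, stat)
  if (ctrl == 0) stop("undefined ratio: control level is zero")
  do.call(rbind, lapply(groups, function(g) {
    data.frame(group = g$group_label, modification = g$modification,
               n = g$n, level = level_stat(g$scores, stat),
               ratio_to_ctrl = level_stat(g$scores, stat) / ctrl,
               iqr = stats::IQR(g$scores) / ctrl,
               row.names = NULL)
  }))
}

#' Z-DNA score per group, relative to control
#'
#' A group's score is its Z-DNA level divided by its B-DNA level (levels =
#' median per-spectrum correlation scores over DNA-positive nucleus pixels),
#' expressed relative to the control group's Z/B ratio so the control scores
#' exactly 1.00.
#'
#' @param z_groups,b_groups named lists of `group_levels` for the Z-DNA and
#'   B-DNA references (same groups).
#' @param ctrl_label control group name.
#' @param stat `"median"` or `"mean"`.
#' @return data frame with `group`, `z_level`, `b_level`, `score`.
#' @export
zdna_score <- function(z_groups, b_groups, ctrl_label = "CTRL",
                       stat = c("median", "mean")) {
  stat <- match.arg(stat)
  if (!setequal(names(z_groups), names(b_groups)))
    stop("Z-DNA and B-DNA groups differ")
  if (!ctrl_label %in% names(z_groups))
    stop("control group '", ctrl_label, "' not present")
  zb <- vapply(names(z_groups), function(g) {
    b <- level_stat(b_groups[[g]]$scores, stat)
    if (b == 0) stop("undefined ratio: zero B-DNA level in group ", g)
    level_stat(z_groups[[g]]$scores, stat) / b
  }, numeric(1L))
  data.frame(group = names(z_groups),
             z_level = vapply(z_groups, function(g) level_stat(g$scores, stat), 0),
             b_level = vapply(b_groups, function(g) level_stat(g$scores, stat), 0),
             score = unname(zb / zb[[ctrl_label]]),
             row.names = NULL)
}

#' Kruskal-Wallis omnibus test with Dunn's post hoc and Holm adjustment
#'
#' The omnibus H test (with tie correction) runs over all groups; every
#' pairwise comparison is then tested with Dunn's z statistic and the raw
#' p-values are Holm-adjusted over the full pairwise family (one family per
#' modification).
#'
#' @param groups named list of `group_levels`, >= 2 groups with >= 2
#'   observations each.
#' @return list with `omnibus` (`H`, `df`, `p`) and `pairwise` (data frame
#'   `group1`, `group2`, `dunn_z`, `p`, `q`).
#' @export
group_tests <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  ns <- vapply(groups, `[[`, 0L, "n")
  if (any(ns < 2L)) stop("every group needs n >= 2")
  values <- unlist(lapply(groups, `[[`, "scores"), use.names = FALSE)
  glab <- factor(rep(names(groups), ns), levels = names(groups))
  if (length(unique(values)) == 1L)
    stop("degenerate test: all observations identical")
  kw <- stats::kruskal.test(values, glab)
  ## Dunn's z on pooled midranks with tie correction
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, glab, mean)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(names(groups), 2L)
  pw <- apply(pairs, 2L, function(pr) {
    i <- pr[1L]; j <- pr[2L]
    se <- sqrt((N * (N + 1) / 12 - tie_term) *
                 (1 / ns[[i]] + 1 / ns[[j]]))
    z <- (rbar[[i]] - rbar[[j]]) / se
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  pairwise <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                         dunn_z = pw["z", ], p = pw["p", ],
                         q = stats::p.adjust(pw["p", ], method = "holm"),
                         row.names = NULL)
  list(omnibus = list(H = unname(kw$statistic), df = unname(kw$parameter),
                      p = kw$p.value),
       pairwise = pairwise)
}
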