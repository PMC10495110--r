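#' Nested ("SuperPlot") two-group comparison on replicate means
#'
#' Unit-level observations (e.g., single vesicles or cells) are averaged
#' within each biological replicate (culture preparation), and the two
#' groups are compared with a two-tailed unpaired Student t-test on the
#' replicate means (equal variance, `df = n_a + n_b - 2`). This avoids
#' pseudo-replication from treating every unit as independent.
#'
#' @param data data frame with columns `group`, `replicate`, `unit`,
#'   `value`. Multiple rows per unit are averaged into the unit value first.
#' @param group_a,group_b the two group labels to compare.
#' @param var_equal use the pooled-variance Student t (default); `FALSE`
#'   gives Welch.
#' @return list with `replicate_means` (per group/replicate), `grand_means`,
#'   `t`, `df`, `p_value`.
#' @examples
#' d <- expand.grid(replicate = 1:3, unit = 1:5)
#' d <- rbind(cbind(d, group = "a", value = rnorm(15, 10)),
#'            cbind(d, group = "b", value = rnorm(15, 12)))
#' superplot_compare(d, "a", "b")$p_value
#' @export
superplot_compare <- function(data, group_a, group_b, var_equal = TRUE) {
  stopifnot(all(c("group", "replicate", "unit", "value") %in% names(data)))
  data <- data[data$group %in% c(group_a, group_b), ]
  unit_means <- stats::aggregate(
    value ~ group + replicate + unit, data, mean)
  rep_means <- stats::aggregate(value ~ group + replicate, unit_means, mean)
  a <- rep_means$value[rep_means$group == group_a]
  b <- rep_means$value[rep_means$group == group_b]
  if (length(a) < 2 || length(b) < 2)
    stop("need >= 2 replicates per group")
  tt <- stats::t.test(a, b, var.equal = var_equal)
  list(replicate_means = rep_means,
       grand_means = c(stats::setNames(mean(a), group_a),
                       stats::setNames(mean(b), group_b)),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Comparative-Ct (2^-ddCt) qRT-PCR fold changes
#'
#' Per sample, `dCt = Ct(target) - Ct(reference)`. Per pair of samples
#' (one per condition, matched by `pair`), `ddCt = dCt(condition) -
#' dCt(control)` and `FC = 2^-ddCt`. Fold changes are summarized by their
#' geometric mean and geometric SD, and tested with a two-tailed one-sample
#' t-test of log2 FC against 0 — statistics on the log scale, where Ct noise
#' is additive.
#'
#' @param table data frame with columns `sample`, `pair`, `condition`,
#'   `gene`, `ct`.
#' @param target_gene gene of interest.
#' @param reference_gene housekeeping gene (default `"Gapdh"`).
#' @param control_condition label of the reference condition.
#' @return list with `pairs` (per-pair `ddct`, `fc`, `log2_fc`),
#'   `geometric_mean_fc`, `geometric_sd_fc`, `t`, `df`, `p_value`
#'   (`t`/`p_value` are `NA` with `zero_variance = TRUE` when all pairs give
#'   the same FC). Pairs missing a target or reference Ct in either
#'   condition are dropped with a warning.
#' @examples
#' ct <- data.frame(sample = 1:4, pair = c(1, 1, 2, 2),
#'                  condition = c("ctrl", "ko", "ctrl", "ko"),
#'                  gene = "Bdnf", ct = c(24, 25, 24.2, 25.1))
#' ref <- transform(ct, gene = "Gapdh", ct = 18)
#' ddct_fold_change(rbind(ct, ref), "Bdnf", "Gapdh", "ctrl")
#' @export
ddct_fold_change <- function(table, target_gene, reference_gene = "Gapdh",
                             control_condition) {
  stopifnot(all(c("sample", "pair", "condition", "gene", "ct") %in%
                  names(table)))
  conds <- unique(table$condition)
  stopifnot(control_condition %in% conds, length(conds) == 2)
  test_condition <- setdiff(conds, control_condition)
  dct_of <- function(pair, condition) {
    sub <- table[table$pair == pair & table$condition == condition, ]
    tg <- sub$ct[sub$gene == target_gene]
    rf <- sub$ct[sub$gene == reference_gene]
    if (length(tg) != 1 || length(rf) != 1 || !is.finite(tg) ||
        !is.finite(rf)) return(NA_real_)
    tg - rf
  }
  pairs <- unique(table$pair)
  ddct <- vapply(pairs, function(p)
    dct_of(p, test_condition) - dct_of(p, control_condition), numeric(1))
  if (any(is.na(ddct))) {
    warning(sum(is.na(ddct)), " pair(s) dropped: missing target or ",
            "reference Ct")
    pairs <- pairs[!is.na(ddct)]
    ddct <- ddct[!is.na(ddct)]
  }
  if (!length(ddct)) stop("no complete sample pairs")
  fc <- 2^(-ddct)
  log2fc <- -ddct
  zero_var <- stats::sd(log2fc) == 0 || length(log2fc) < 2
  if (!zero_var) {
    tt <- stats::t.test(log2fc, mu = 0)
    t_stat <- unname(tt$statistic); df <- unname(tt$parameter)
    p <- tt$p.value
  } else {
    t_stat <- NA_real_; df <- length(log2fc) - 1; p <- NA_real_
  }
  list(pairs = data.frame(pair = pairs, ddct = ddct, fc = fc,
                          log2_fc = log2fc),
       geometric_mean_fc = 2^mean(log2fc),
       geometric_sd_fc = 2^stats::sd(log2fc),
       t = t_stat, df = df, p_value = p, zero_variance = zero_var)
}

#' Morphometry derivations from electron-microscopy summaries
#'
#' Derives the quantities reported alongside vesicle-diameter measurements:
#' the percent volume change implied by a mean-diameter change (spherical
#' vesicles, so volume scales with diameter cubed), the relative change of a
#' percentage (e.g., percent of synaptic sections containing a vesicle), and
#' optionally the fraction of diameters falling in half-open bins
#' `[lo, hi)`.
#'
#' @param d_control,d_test mean diameters, nm.
#' @param p_control,p_test percentages in `[0, 100]` (optional).
#' @param diameters optional vector of individual diameters, nm.
#' @param bin_edges optional bin edges for the diameter distribution, nm.
#' @return list with `volume_change_pct`
#'   (`100 * (1 - (d_test / d_control)^3)`), `relative_change_pct`
#'   (`100 * (1 - p_test / p_control)`, `NULL` when no percentages given)
#'   and `bin_fractions` (`NULL` when no diameters given).
#' @examples
#' morphometry_derive(71.52, 65.01)$volume_change_pct   # ~24.9
#' @export
morphometry_derive <- function(d_control, d_test, p_control = NULL,
                               p_test = NULL, diameters = NULL,
                               bin_edges = NULL) {
  if (d_control <= 0) stop("d_control must be positive")
  stopifnot(d_test > 0)
  out <- list(volume_change_pct = 100 * (1 - (d_test / d_control)^3))
  if (!is.null(p_control) && !is.null(p_test)) {
    stopifnot(p_control > 0, p_control <= 100, p_test >= 0, p_test <= 100)
    out$relative_change_pct <- 100 * (1 - p_test / p_control)
  }
  if (!is.null(diameters) && !is.null(bin_edges)) {
    stopifnot(all(diameters > 0), length(bin_edges) >= 2)
    idx <- findInterval(diameters, bin_edges)          # [lo, hi) bins
    n_bins <- length(bin_edges) - 1
    counts <- tabulate(idx[idx >= 1 & idx <= n_bins], nbins = n_bins)
    out$bin_fractions <- stats::setNames(
      counts / length(diameters),
      paste0("[", utils::head(bin_edges, -1), ",", bin_edges[-1], ")"))
  }
  out
}
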