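#' Group medians, IQRs and tests against a reference group
#'
#' Per group: n, median and interquartile range of one cell-table
#' parameter, plus a two-sided Mann-Whitney U test of each group against
#' the reference group. No multiple-testing correction is applied by
#' default (Holm available).
#'
#' @param table Cell table (`data.frame` with a `group` column).
#' @param parameter Column name to summarize.
#' @param reference_group Group tested against (default `"control"`).
#' @param p_adjust `"none"` (default) or `"holm"`.
#' @return `data.frame` of class `group_summary`: `group`, `n`, `median`,
#'   `q25`, `q75`, `p_value` (NA for the reference itself), `test`.
#' @export
compare_groups <- function(table, parameter, reference_group = "control",
                           p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  if (!parameter %in% names(table))
    stop("unknown parameter '", parameter, "'; available: ",
         paste(names(table), collapse = ", "))
  if (!"group" %in% names(table)) stop("table must have a 'group' column")
  tab <- table[is.finite(table[[parameter]]), c("group", parameter)]
  groups <- unique(tab$group)
  if (length(groups) < 2) stop("need at least 2 groups")
  if (!reference_group %in% groups)
    stop("reference group '", reference_group, "' not present")
  if (any(tapply(tab[[parameter]], tab$group, length) < 3))
    stop("each group needs at least 3 cells")
  ref <- tab[[parameter]][tab$group == reference_group]
  rows <- lapply(groups, function(g) {
    x <- tab[[parameter]][tab$group == g]
    p <- if (g == reference_group) NA_real_ else
      stats::wilcox.test(x, ref, exact = FALSE)$p.value
    data.frame(group = g, n = length(x), median = stats::median(x),
               q25 = unname(stats::quantile(x, 0.25)),
               q75 = unname(stats::quantile(x, 0.75)),
               p_value = p)
  })
  out <- do.call(rbind, rows)
  if (p_adjust == "holm")
    out$p_value <- stats::p.adjust(out$p_value, "holm")
  out$test <- "Mann-Whitney U vs reference"
  attr(out, "parameter") <- parameter
  class(out) <- c("group_summary", class(out))
  out
}

#' Correlation between two cell-table parameters
#'
#' Pearson by default (Spearman optional), with a two-sided p-value.
#'
#' @param table Cell table.
#' @param x_parameter,y_parameter Column names.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `r`, `p_value`, `n`, `method`.
#' @export
correlate <- function(table, x_parameter, y_parameter,
                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  for (p in c(x_parameter, y_parameter))
    if (!p %in% names(table))
      stop("unknown parameter '", p, "'; available: ",
           paste(names(table), collapse = ", "))
  x <- table[[x_parameter]]
  y <- table[[y_parameter]]
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) stop("need at least 3 paired finite values")
  ct <- stats::cor.test(x[ok], y[ok], method = method, exact = FALSE)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok),
       method = method)
}

#' Depth-binned medians of a parameter versus distance to the border
#'
#' Cells are binned by `border_distance_um`; the median and interquartile
#' range of the parameter are reported per bin. Bins holding fewer than 3
#' cells are flagged.
#'
#' @param table Cell table with a finite `border_distance_um` column.
#' @param parameter Column name to profile.
#' @param bin_width_um Depth bin width in micrometres.
#' @return `data.frame`: `depth_mid_um`, `depth_lo_um`, `depth_hi_um`, `n`,
#'   `median`, `q25`, `q75`, `low_n` flag.
#' @export
depth_profile <- function(table, parameter, bin_width_um = 10) {
  if (!parameter %in% names(table))
    stop("unknown parameter '", parameter, "'; available: ",
         paste(names(table), collapse = ", "))
  d <- table$border_distance_um
  if (is.null(d) || !any(is.finite(d)))
    stop("table has no finite border_distance_um values")
  ok <- is.finite(d) & is.finite(table[[parameter]])
  d <- d[ok]
  v <- table[[parameter]][ok]
  lo <- floor(d / bin_width_um) * bin_width_um
  out <- lapply(sort(unique(lo)), function(b) {
    x <- v[lo == b]
    data.frame(depth_mid_um = b + bin_width_um / 2, depth_lo_um = b,
               depth_hi_um = b + bin_width_um, n = length(x),
               median = stats::median(x),
               q25 = unname(stats::quantile(x, 0.25)),
               q75 = unname(stats::quantile(x, 0.75)),
               low_n = length(x) < 3)
  })
  do.call(rbind, out)
}
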