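# The behavioural screening statistics chain: Levene homoskedasticity check,
# Kruskal-Wallis followed by Dunn's post-hoc contrasts of every line against
# the control, and p-value adjustment (Benjamini-Hochberg FDR for the primary
# screen, Bonferroni for replication experiments).

#' Levene / Brown-Forsythe homoskedasticity check
#'
#' One-way ANOVA F on absolute deviations from group centres. The
#' Brown-Forsythe variant (median centres) is the default; `center = "mean"`
#' gives the classical Levene test.
#'
#' @param data Data frame.
#' @param value,group Column names (strings) of the response and grouping
#'   variable.
#' @param center `"median"` or `"mean"`.
#' @return Tibble with `statistic` (F), `df1`, `df2`, `p_value`, `center`.
#' @export
levene_check <- function(data, value = "pi", group = "line_id",
                         center = c("median", "mean")) {
  center <- match.arg(center)
  y <- data[[value]]
  g <- factor(data[[group]])
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) < 2)) stop("every group needs n >= 2", call. = FALSE)
  centre_fun <- if (center == "median") stats::median else mean
  ad <- abs(y - stats::ave(y, g, FUN = centre_fun))
  if (all(ad == 0)) {
    # every observation sits at its group centre: no dispersion to compare
    return(tibble::tibble(statistic = 0, df1 = nlevels(g) - 1L,
                          df2 = length(y) - nlevels(g), p_value = 1,
                          center = center))
  }
  ct <- car::leveneTest(y, g, center = centre_fun)
  tibble::tibble(statistic = ct[1, "F value"], df1 = ct[1, "Df"],
                 df2 = ct[2, "Df"], p_value = ct[1, "Pr(>F)"],
                 center = center)
}

#' Kruskal-Wallis with Dunn's contrasts against a control
#'
#' Pools all groups, computes the tie-corrected Kruskal-Wallis H, then for
#' each treatment line a Dunn z statistic against the control on the pooled
#' ranks,
#' \deqn{z_i = (\bar R_i - \bar R_0) / \sqrt{(N(N+1)/12 - T)(1/n_i + 1/n_0)}}
#' with tie correction \eqn{T = \sum_j (t_j^3 - t_j) / (12 (N - 1))}, and a
#' two-sided normal p-value per contrast (the screen detects attraction and
#' aversion alike).
#'
#' @param data Data frame of per-replicate values.
#' @param value,group Column names (strings).
#' @param control Label of the control group.
#' @return Tibble with one row per treatment line: `line_id`, `n`,
#'   `rank_mean`, `z`, `raw_p`. Kruskal-Wallis `H`, its df and p-value are
#'   attached as attributes `kruskal_H`, `kruskal_df`, `kruskal_p`.
#' @export
kruskal_dunn_vs_control <- function(data, value = "pi", group = "line_id",
                                    control = "empty_split") {
  y <- data[[value]]
  g <- as.character(data[[group]])
  if (!control %in% g) stop(sprintf("control '%s' not present", control),
                            call. = FALSE)
  ns <- table(g)
  if (any(ns < 2)) stop("every group needs n >= 2", call. = FALSE)
  if (length(unique(y)) == 1) {
    stop("all observations tied: ranks are degenerate", call. = FALSE)
  }
  r <- rank(y)
  N <- length(y)
  ties <- table(y)
  tie_H <- 1 - sum(ties^3 - ties) / (N^3 - N)
  rank_sums <- tapply(r, g, sum)
  rank_means <- tapply(r, g, mean)
  H <- (12 / (N * (N + 1)) * sum(rank_sums^2 / as.numeric(ns[names(rank_sums)])) -
          3 * (N + 1)) / tie_H
  df <- length(ns) - 1
  tie_T <- sum(ties^3 - ties) / (12 * (N - 1))
  treatments <- setdiff(names(ns), control)
  n0 <- as.numeric(ns[control])
  z <- vapply(treatments, function(tr) {
    ni <- as.numeric(ns[tr])
    (rank_means[[tr]] - rank_means[[control]]) /
      sqrt((N * (N + 1) / 12 - tie_T) * (1 / ni + 1 / n0))
  }, numeric(1))
  out <- tibble::tibble(line_id = treatments,
                        n = as.integer(ns[treatments]),
                        rank_mean = as.numeric(rank_means[treatments]),
                        z = unname(z),
                        raw_p = pmin(1, 2 * stats::pnorm(-abs(unname(z)))))
  attr(out, "kruskal_H") <- H
  attr(out, "kruskal_df") <- df
  attr(out, "kruskal_p") <- stats::pchisq(H, df, lower.tail = FALSE)
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1).
#'
#' @param p Numeric p-values in \[0, 1\].
#' @return Adjusted p-values, same order as input.
#' @export
adjust_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must be in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)` over the family of m tests.
#'
#' @inheritParams adjust_fdr
#' @return Adjusted p-values.
#' @export
adjust_bonferroni <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must be in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "bonferroni")
}

#' Run the full behavioural screen chain
#'
#' Levene check, Kruskal-Wallis, Dunn contrasts of every line against the
#' control, and p-value adjustment. The primary screen uses FDR control at
#' `fdr_level` with significance declared at adjusted p below `sig_level`;
#' replication experiments use Bonferroni.
#'
#' @inheritParams kruskal_dunn_vs_control
#' @param adjust `"fdr"` or `"bonferroni"`.
#' @param fdr_level Reported FDR control level, default 0.10.
#' @param sig_level Adjusted-p significance cutoff, default 0.05.
#' @return An `lh_screen_result` tibble: `line_id`, `n`, `z`, `raw_p`,
#'   `adjusted_p`, `method`, `significant`; Levene and Kruskal-Wallis results
#'   as attributes `levene` and `kruskal_H`/`kruskal_df`/`kruskal_p`.
#' @examples
#' screen <- generate_screen_data(n_lines = 8, effects = c(LH0001 = -0.6),
#'                                seed = 2)
#' screen_lines(screen)
#' @export
screen_lines <- function(data, value = "pi", group = "line_id",
                         control = "empty_split",
                         adjust = c("fdr", "bonferroni"),
                         fdr_level = 0.10, sig_level = 0.05) {
  adjust <- match.arg(adjust)
  lev <- levene_check(data, value, group)
  dunn <- kruskal_dunn_vs_control(data, value, group, control)
  adj <- if (adjust == "fdr") adjust_fdr(dunn$raw_p)
  else adjust_bonferroni(dunn$raw_p)
  out <- tibble::tibble(line_id = dunn$line_id, n = dunn$n, z = dunn$z,
                        raw_p = dunn$raw_p, adjusted_p = adj,
                        method = if (adjust == "fdr") "dunn_fdr"
                        else "dunn_bonferroni",
                        significant = adj < sig_level)
  attr(out, "levene") <- lev
  attr(out, "kruskal_H") <- attr(dunn, "kruskal_H")
  attr(out, "kruskal_df") <- attr(dunn, "kruskal_df")
  attr(out, "kruskal_p") <- attr(dunn, "kruskal_p")
  attr(out, "fdr_level") <- fdr_level
  attr(out, "sig_level") <- sig_level
  class(out) <- c("lh_screen_result", class(out))
  out
}

#' One-row summary of a screen
#' @param x An `lh_screen_result`.
#' @param ... Unused.
#' @return Tibble with line counts, Kruskal-Wallis H and p, and the number of
#'   significant lines.
#' @method glance lh_screen_result
#' @export
glance.lh_screen_result <- function(x, ...) {
  tibble::tibble(n_lines = nrow(x),
                 kruskal_H = attr(x, "kruskal_H"),
                 kruskal_p = attr(x, "kruskal_p"),
                 n_significant = sum(x$significant),
                 frac_significant = mean(x$significant))
}
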