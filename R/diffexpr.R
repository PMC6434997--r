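#' Two-sample pooled-variance Student t test
#'
#' Equal-variance two-sample t on log2 values with df = n1 + n2 - 2 and a
#' two-sided p value. Degenerate zero-pooled-variance inputs are resolved by
#' the means: equal means give t = 0, p = 1; unequal means give an infinite
#' t and p = 0, flagged with a warning.
#'
#' @param case_values,control_values Numeric vectors, length >= 2 each.
#' @return List with `t_stat` (case minus control direction) and `p_value`.
#' @export
student_t_test <- function(case_values, control_values) {
  if (length(case_values) < 2 || length(control_values) < 2) {
    stop("each group needs >= 2 values")
  }
  n1 <- length(case_values); n2 <- length(control_values)
  d <- mean(case_values) - mean(control_values)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(case_values) +
          (n2 - 1) * stats::var(control_values)) / df
  if (sp2 <= 0) {
    if (d == 0) return(list(t_stat = 0, p_value = 1))
    warning("zero pooled variance with unequal means; p = 0 (degenerate)")
    return(list(t_stat = sign(d) * Inf, p_value = 0))
  }
  t <- d / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t_stat = t, p_value = 2 * stats::pt(-abs(t), df))
}

# Vectorized pooled t over matrix rows (case/control column index sets).
.row_t <- function(vals, case_idx, ctrl_idx) {
  n1 <- length(case_idx); n2 <- length(ctrl_idx)
  x <- vals[, case_idx, drop = FALSE]
  y <- vals[, ctrl_idx, drop = FALSE]
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (n1 - 1)
  vy <- rowSums((y - my)^2) / (n2 - 1)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * vx + (n2 - 1) * vy) / df
  d <- mx - my
  t <- d / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(t), df)
  deg <- sp2 <= 0
  if (any(deg)) {
    t[deg] <- ifelse(d[deg] == 0, 0, sign(d[deg]) * Inf)
    p[deg] <- ifelse(d[deg] == 0, 1, 0)
  }
  list(t = t, p = p)
}

#' Per-gene fold changes and t statistics for one organ/strain contrast
#'
#' Selects the EAE and control samples of one organ and strain, computes
#' group means on the linear scale (2^log2, averaged) and their case/control
#' ratio, and a pooled-variance Student t test on the log2 values.
#'
#' @param mat An [expression_matrix()] containing the contrast's samples.
#' @param annotation A [sample_annotation()].
#' @param organ `"brain"` or `"spleen"`.
#' @param strain Strain label as it appears in the annotation.
#' @param adjust Optionally `"BH"` to append a Benjamini-Hochberg adjusted
#'   p column (`p_adj`); default `"none"`, matching a raw p < 0.05 screen.
#' @return Data frame with one row per gene: `gene_id`,
#'   `mean_control_linear`, `mean_case_linear`, `fold_change`, `log2_ratio`,
#'   `t_stat`, `p_value`, `n_case`, `n_control`.
#' @export
fold_change_table <- function(mat, annotation, organ, strain,
                              adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  ann <- annotation[annotation$organ == organ & annotation$strain == strain, ]
  if (nrow(ann) == 0) stop("no samples for organ=", organ, ", strain=", strain)
  ann <- ann[ann$sample_id %in% colnames(mat), ]
  case_ids <- ann$sample_id[ann$group == "EAE"]
  ctrl_ids <- ann$sample_id[ann$group == "control"]
  if (length(case_ids) < 2 || length(ctrl_ids) < 2) {
    stop("contrast needs >= 2 samples per group (got ", length(case_ids),
         " EAE, ", length(ctrl_ids), " control)")
  }
  vals <- unclass(mat)
  lin <- 2^vals
  mean_case <- rowMeans(lin[, case_ids, drop = FALSE])
  mean_ctrl <- rowMeans(lin[, ctrl_ids, drop = FALSE])
  fc <- mean_case / mean_ctrl
  tt <- .row_t(vals, match(case_ids, colnames(vals)),
               match(ctrl_ids, colnames(vals)))
  out <- data.frame(gene_id = rownames(mat),
                    mean_control_linear = mean_ctrl,
                    mean_case_linear = mean_case,
                    fold_change = fc,
                    log2_ratio = log2(fc),
                    t_stat = tt$t,
                    p_value = tt$p,
                    n_case = length(case_ids),
                    n_control = length(ctrl_ids),
                    row.names = NULL)
  if (adjust == "BH") out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Volcano classification of a differential table
#'
#' Labels each gene `up` (fold change strictly above `fc_threshold` and
#' p below `p_threshold`), `down` (fold change strictly below
#' 1 / `fc_threshold`, same p rule), or `neither`.
#'
#' @param table Output of [fold_change_table()].
#' @param fc_threshold Fold-change cutoff, > 1 (default 2).
#' @param p_threshold p-value cutoff in (0, 1) (default 0.05).
#' @return List with `table` (input plus a `label` column) and `counts`
#'   (named integer vector over up/down/neither).
#' @export
volcano_classify <- function(table, fc_threshold = 2, p_threshold = 0.05) {
  if (!(fc_threshold > 1)) stop("fc_threshold must exceed 1")
  if (!(p_threshold > 0 && p_threshold < 1)) stop("p_threshold must be in (0, 1)")
  sig <- table$p_value < p_threshold
  label <- ifelse(sig & table$fold_change > fc_threshold, "up",
                  ifelse(sig & table$fold_change < 1 / fc_threshold, "down",
                         "neither"))
  table$label <- label
  counts <- c(up = sum(label == "up"), down = sum(label == "down"),
              neither = sum(label == "neither"))
  list(table = table, counts = counts)
}

#' Top up- or down-regulated genes of a contrast
#'
#' Among genes passing the volcano filter in the requested direction, ranks
#' by fold change (descending for `up`, ascending for `down`); ties broken by
#' p value ascending, then gene id lexicographically.
#'
#' @param table Output of [fold_change_table()].
#' @param direction `"up"` or `"down"`.
#' @param n Maximum genes returned (default 20).
#' @param fc_threshold,p_threshold Volcano thresholds (defaults 2, 0.05).
#' @return Character vector of at most `n` gene ids.
#' @export
top_ranked_genes <- function(table, direction = c("up", "down"), n = 20,
                             fc_threshold = 2, p_threshold = 0.05) {
  direction <- match.arg(direction)
  vc <- volcano_classify(table, fc_threshold, p_threshold)
  t <- vc$table[vc$table$label == direction, , drop = FALSE]
  if (nrow(t) == 0) return(character(0))
  key_fc <- if (direction == "up") -t$fold_change else t$fold_change
  ord <- order(key_fc, t$p_value, t$gene_id, method = "radix")
  utils::head(t$gene_id[ord], n)
}
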