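#' Per-site structural feature table
#'
#' Computes, for every site with an available structure, the features
#' used to characterise functional versus non-functional sites: pLDDT
#' (raw 0-100 scale plus the confidence category: very low below 50,
#' low 50-70, confident 70-90, very high 90 and above), secondary
#' structure (8-state letter and the collapsed helix/strand/coil
#' class), contact-graph degree and eigenvector centrality (both on the
#' whole-protein contact graph). Sites whose protein is missing are
#' skipped with a warning.
#'
#' @param proteins Named list of [protein_record()].
#' @param sites Site data frame with a `functional_label` column.
#' @param graph_cfg A [graph_config()].
#' @return Data frame with one row per retained site.
#' @export
build_feature_table <- function(proteins, sites,
                                graph_cfg = graph_config()) {
  have <- sites$accession %in% names(proteins)
  if (any(!have)) {
    warning(sprintf("%d site(s) skipped: no structure", sum(!have)))
  }
  sites <- sites[have, , drop = FALSE]
  ctx <- list()
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    acc <- sites$accession[[i]]
    if (is.null(ctx[[acc]])) {
      ctx[[acc]] <<- protein_site_features(proteins[[acc]], graph_cfg)
    }
    p <- sites$position[[i]]
    ss8 <- ctx[[acc]]$ss[[p]]
    ss3_map <- c(H = "helix", G = "helix", I = "helix",
                 E = "strand", B = "strand", T = "coil", S = "coil",
                 C = "coil")
    data.frame(accession = acc, position = p,
               plddt = proteins[[acc]]$plddt[[p]],
               ss8 = ss8, ss3 = unname(ss3_map[[ss8]]),
               degree = ctx[[acc]]$degree[[p]],
               centrality = ctx[[acc]]$centrality[[p]],
               functional_label = sites$functional_label[[i]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$plddt_category <- cut(out$plddt, c(0, 50, 70, 90, 100),
                            right = FALSE, include.lowest = TRUE,
                            labels = c("very_low", "low", "confident",
                                       "very_high"))
  out
}

#' Compare a feature between functional and non-functional sites
#'
#' Two-tailed unpaired t-test on a numeric feature between the two
#' label groups; Welch's unequal-variance variant by default, with
#' `var_equal = TRUE` restoring the pooled-variance test. Two groups
#' that are both constant and equal give p = 1.
#'
#' @param table Feature table from [build_feature_table()].
#' @param feature Numeric column name.
#' @param var_equal Use the pooled-variance t-test.
#' @return List with `statistic`, `p_value`, `mean_functional`,
#'   `mean_nonfunctional`, `direction`.
#' @export
compare_groups <- function(table, feature, var_equal = FALSE) {
  x <- table[[feature]][table$functional_label == 1]
  y <- table[[feature]][table$functional_label == 0]
  if (length(x) < 2 || length(y) < 2) {
    stop_pf("both groups need at least 2 observations",
            "phosfusion_config_error")
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    same <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(statistic = if (same) 0 else Inf,
                p_value = if (same) 1 else 0,
                mean_functional = mean(x), mean_nonfunctional = mean(y),
                direction = if (same) "equal" else
                  if (mean(x) > mean(y)) "higher" else "lower"))
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       mean_functional = mean(x), mean_nonfunctional = mean(y),
       direction = if (mean(x) > mean(y)) "higher" else
         if (mean(x) < mean(y)) "lower" else "equal")
}

#' Class composition of a categorical feature by label group
#'
#' @param table Feature table.
#' @param feature Categorical column name (e.g. `"ss3"`).
#' @return Matrix of fractions (rows: functional / non-functional;
#'   columns: feature classes); each row sums to 1.
#' @export
class_composition <- function(table, feature) {
  f <- factor(table[[feature]])
  grp <- factor(table$functional_label, levels = c(1, 0),
                labels = c("functional", "nonfunctional"))
  tab <- table(grp, f)
  prop.table(tab, margin = 1)
}
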