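#' Mean ordinal symptom intensity
#'
#' Arithmetic mean of the non-missing ordinal entries (0 absent -- 3 severe)
#' of one variable within one group.
#'
#' @param table Subjects x variables ordinal matrix (`NA` = missing).
#' @param groups Group label per subject (row).
#' @param group Group to summarize.
#' @param variable Column name or index.
#' @return Mean ordinal intensity, or `NA` if all entries are missing.
#' @export
mean_ordinal_intensity <- function(table, groups, group, variable) {
  v <- table[groups == group, variable]
  if (all(is.na(v))) return(NA_real_)
  mean(v, na.rm = TRUE)
}

#' Select symptom variables by fold difference
#'
#' For every variable the relative mean ordinal intensity is computed per
#' group and the fold difference between `groupA` (severe ME by default) and
#' the reference `groupB` (MS) is `(meanA + eps) / (meanB + eps)` with a
#' pseudo-count `eps = 0.05` guarding zero denominators. Variables with fold
#' >= `fold_min` (1.5 by default) are included. Fisher exact tests of symptom
#' presence between the two groups with Benjamini--Hochberg adjustment are
#' attached (see [fisher_bh()]).
#'
#' @param table Ordinal symptom matrix.
#' @param groups Group label per subject.
#' @param groupA,groupB Compared group and reference group.
#' @param fold_min Inclusion threshold, default 1.5.
#' @param eps Pseudo-count, default 0.05.
#' @param presence_cut Ordinal cut for the Fisher presence dichotomy,
#'   default 1 ("mild" or worse).
#' @return Data frame of class `symptom_selection`: per-group means, fold,
#'   `included`, Fisher `p`, `p_adj`, `significant` (adj p < 0.05).
#' @export
select_symptoms <- function(table, groups, groupA = "SevME", groupB = "MS",
                            fold_min = 1.5, eps = 0.05, presence_cut = 1) {
  if (!groupA %in% groups || !groupB %in% groups)
    stop("both compared groups must be present")
  vars <- colnames(table)
  if (is.null(vars)) vars <- as.character(seq_len(ncol(table)))
  gm <- vapply(unique(groups), function(g)
    colMeans(table[groups == g, , drop = FALSE], na.rm = TRUE),
    numeric(ncol(table)))
  gm <- matrix(gm, ncol = length(unique(groups)),
               dimnames = list(vars, unique(groups)))
  fold <- (gm[, groupA] + eps) / (gm[, groupB] + eps)
  ft <- fisher_bh(table, groups, groupA, groupB, presence_cut)
  out <- data.frame(variable = vars,
                    mean_A = gm[, groupA], mean_B = gm[, groupB],
                    fold = fold, included = fold >= fold_min,
                    p = ft$p, p_adj = ft$p_adj,
                    significant = !is.na(ft$p_adj) & ft$p_adj < 0.05,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "group_means") <- gm
  class(out) <- c("symptom_selection", "data.frame")
  out
}

# two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration:
# sum the probabilities of all tables with the same margins whose probability
# does not exceed the observed one
fisher_exact_2x2 <- function(a, b, c, d) {
  m <- a + b          # group A total
  n <- c + d          # group B total
  k <- a + c          # presence total
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

#' Fisher exact tests of symptom presence with BH adjustment
#'
#' Per variable, subjects are dichotomized as symptom present (entry >=
#' `presence_cut`) or absent; missing entries are excluded pairwise. The
#' two-sided Fisher exact p-value is computed by full hypergeometric
#' enumeration of the 2x2 table and adjusted across variables with the
#' Benjamini--Hochberg step-up procedure. A variable with no non-missing
#' subjects in either group gets `NA` and is excluded from the adjustment
#' denominator.
#'
#' @inheritParams select_symptoms
#' @return Data frame: `variable`, `p`, `p_adj`.
#' @export
fisher_bh <- function(table, groups, groupA = "SevME", groupB = "MS",
                      presence_cut = 1) {
  vars <- colnames(table)
  if (is.null(vars)) vars <- as.character(seq_len(ncol(table)))
  p <- vapply(seq_len(ncol(table)), function(j) {
    va <- table[groups == groupA, j]; vb <- table[groups == groupB, j]
    va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
    if (length(va) == 0 || length(vb) == 0) return(NA_real_)
    a <- sum(va >= presence_cut); b <- length(va) - a
    c <- sum(vb >= presence_cut); d <- length(vb) - c
    min(fisher_exact_2x2(a, b, c, d), 1)
  }, numeric(1))
  p_adj <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  p_adj[ok] <- stats::p.adjust(p[ok], method = "BH")
  data.frame(variable = vars, p = p, p_adj = p_adj,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Heatmap-ready matrix of selected symptoms
#'
#' Included variables ordered by descending fold difference; subjects ordered
#' by group (HC, mild ME, moderate ME, severe ME, MS). Missing entries stay
#' `NA` so renderers can encode them distinctly.
#'
#' @param selection A [select_symptoms()] result.
#' @param table The ordinal symptom matrix.
#' @param groups Group label per subject.
#' @return List: `matrix` (variables x subjects), `variable_order`,
#'   `subject_order`, `annotations` (per-variable fold and significance).
#' @export
heatmap_matrix <- function(selection, table, groups) {
  sel <- selection[selection$included, ]
  sel <- sel[order(-sel$fold), ]
  subj_ord <- order(match(groups, c("HC", "MildME", "ModME", "SevME", "MS")))
  m <- t(table[subj_ord, sel$variable, drop = FALSE])
  list(matrix = m, variable_order = sel$variable,
       subject_order = rownames(table)[subj_ord],
       annotations = sel[, c("variable", "fold", "p_adj", "significant")])
}
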