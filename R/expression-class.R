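# Classification of F1 expression relative to the parents. Differential
# expression per parent uses a >= 2-fold gate on group means plus a Welch
# test on log2 replicate values; genes up (down) versus BOTH parents form
# the non-additive categories.

#' Genes expressed at a location
#'
#' The enrichment background: genes whose mean expression across all
#' samples at a location exceeds `min_level`. With `min_level = 0` a gene
#' needs any non-zero value.
#'
#' @param es an `expression_set` (see [simulate_expression()]) or a list
#'   with `values` matrix and `samples` metadata.
#' @param location location label; `NULL` pools all samples.
#' @param min_level expression threshold (strictly exceeded).
#' @return character vector of gene identifiers.
#' @export
detect_expressed <- function(es, location = NULL, min_level = 0) {
  v <- es$values
  if (!is.null(location))
    v <- v[, es$samples$location == location, drop = FALSE]
  rownames(v)[rowMeans(v) > min_level]
}

welch_log_test <- function(x, y, pseudocount) {
  lx <- log2(x + pseudocount); ly <- log2(y + pseudocount)
  if (stats::var(lx) == 0 && stats::var(ly) == 0)
    return(if (mean(lx) == mean(ly)) 1 else 0)
  stats::t.test(lx, ly)$p.value
}

#' Differential expression of the F1 against one parent
#'
#' Log2 fold change of the F1 group mean over the parent group mean, with
#' each mean floored at the pseudocount so zero means are defined.
#' Significance requires BOTH an at-least-twofold change
#' (|log2FC| >= log2(min_fold), inclusive) and a Welch two-sample test on
#' log2(value + pseudocount) across replicates with p below `alpha`.
#'
#' @param es an `expression_set`.
#' @param gene gene identifier.
#' @param comparison `"P1"` or `"P2"`: which parent the F1 is compared to.
#' @param location location label.
#' @param alpha replicate-test significance level.
#' @param min_fold fold-change gate (default 2).
#' @param pseudocount floor added on the log scale and applied to means.
#' @return a one-row data frame (class `differential_call`): gene,
#'   comparison, location, log2_fold_change, p_value, significant,
#'   direction.
#' @export
differential_call <- function(es, gene, comparison = c("P1", "P2"),
                              location, alpha = 0.05, min_fold = 2,
                              pseudocount = 1) {
  comparison <- match.arg(comparison)
  meta <- es$samples
  sel_f1 <- meta$genotype == "F1" & meta$location == location
  sel_p <- meta$genotype == comparison & meta$location == location
  if (sum(sel_f1) < 2 || sum(sel_p) < 2)
    stop("need >= 2 replicates per group", call. = FALSE)
  x <- es$values[gene, sel_f1]; y <- es$values[gene, sel_p]
  lfc <- log2(max(mean(x), pseudocount) / max(mean(y), pseudocount))
  p <- welch_log_test(x, y, pseudocount)
  sig <- abs(lfc) >= log2(min_fold) && p < alpha
  structure(data.frame(gene = gene, comparison = paste0("F1_vs_", comparison),
                       location = location, log2_fold_change = lfc,
                       p_value = p, significant = sig,
                       direction = if (!sig) "none"
                                   else if (lfc > 0) "up" else "down",
                       stringsAsFactors = FALSE),
            class = c("differential_call", "data.frame"))
}

#' All differential calls for one comparison at one location
#'
#' Vectorized version of [differential_call()] over every gene.
#'
#' @inheritParams differential_call
#' @param genes genes to test; default all.
#' @return data frame, one row per gene.
#' @export
differential_calls <- function(es, comparison = c("P1", "P2"), location,
                               genes = NULL, alpha = 0.05, min_fold = 2,
                               pseudocount = 1) {
  comparison <- match.arg(comparison)
  meta <- es$samples
  sel_f1 <- meta$genotype == "F1" & meta$location == location
  sel_p <- meta$genotype == comparison & meta$location == location
  if (sum(sel_f1) < 2 || sum(sel_p) < 2)
    stop("need >= 2 replicates per group", call. = FALSE)
  if (is.null(genes)) genes <- rownames(es$values)
  X <- es$values[genes, sel_f1, drop = FALSE]
  Y <- es$values[genes, sel_p, drop = FALSE]
  lfc <- log2(pmax(rowMeans(X), pseudocount) / pmax(rowMeans(Y), pseudocount))
  LX <- log2(X + pseudocount); LY <- log2(Y + pseudocount)
  mx <- rowMeans(LX); my <- rowMeans(LY)
  vx <- apply(LX, 1, stats::var); vy <- apply(LY, 1, stats::var)
  nx <- ncol(LX); ny <- ncol(LY)
  se2 <- vx / nx + vy / ny
  tstat <- (mx - my) / sqrt(se2)
  dfw <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(tstat), dfw)
  zero <- vx == 0 & vy == 0
  p[zero] <- ifelse(mx[zero] == my[zero], 1, 0)
  sig <- abs(lfc) >= log2(min_fold) & p < alpha
  data.frame(gene = genes, comparison = paste0("F1_vs_", comparison),
             location = location, log2_fold_change = lfc, p_value = p,
             significant = sig,
             direction = ifelse(!sig, "none", ifelse(lfc > 0, "up", "down")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify a gene's F1 category from its two parental calls
#'
#' Maps the pair of directions (versus parent 1, versus parent 2) onto
#' the category set: `above_both` / `below_both` (the non-additive
#' classes), the four single-parent classes, `crossover` (up versus one
#' parent and down versus the other; counted in neither non-additive
#' class) and `not_de`.
#'
#' @param call_p1,call_p2 one-row call data frames for the same gene and
#'   location (from [differential_call()] or rows of
#'   [differential_calls()]).
#' @return one-row data frame: gene, location, category, crossover.
#' @export
classify_gene_category <- function(call_p1, call_p2) {
  stopifnot(call_p1$gene == call_p2$gene,
            call_p1$location == call_p2$location)
  d1 <- call_p1$direction; d2 <- call_p2$direction
  category <- if (d1 == "up" && d2 == "up") "above_both"
    else if (d1 == "down" && d2 == "down") "below_both"
    else if (d1 == "up" && d2 == "down") "crossover"
    else if (d1 == "down" && d2 == "up") "crossover"
    else if (d1 == "up") "above_P1_only"
    else if (d1 == "down") "below_P1_only"
    else if (d2 == "up") "above_P2_only"
    else if (d2 == "down") "below_P2_only"
    else "not_de"
  data.frame(gene = call_p1$gene, location = call_p1$location,
             category = category, crossover = category == "crossover",
             stringsAsFactors = FALSE)
}

#' Classify every gene at a location
#'
#' @param calls_p1,calls_p2 data frames from [differential_calls()] for
#'   the two parents at the same location.
#' @return data frame with one row per gene: gene, location, category,
#'   crossover.
#' @export
classify_gene_categories <- function(calls_p1, calls_p2) {
  stopifnot(identical(calls_p1$gene, calls_p2$gene))
  d1 <- calls_p1$direction; d2 <- calls_p2$direction
  category <- rep("not_de", length(d1))
  category[d1 == "up" & d2 == "up"] <- "above_both"
  category[d1 == "down" & d2 == "down"] <- "below_both"
  category[(d1 == "up" & d2 == "down") | (d1 == "down" & d2 == "up")] <- "crossover"
  single <- d1 != "none" & d2 == "none"
  category[single & d1 == "up"] <- "above_P1_only"
  category[single & d1 == "down"] <- "below_P1_only"
  single <- d2 != "none" & d1 == "none"
  category[single & d2 == "up"] <- "above_P2_only"
  category[single & d2 == "down"] <- "below_P2_only"
  data.frame(gene = calls_p1$gene, location = calls_p1$location,
             category = category, crossover = category == "crossover",
             stringsAsFactors = FALSE)
}

#' Count-table of F1 expression classes
#'
#' Tabulates, per location, the counts of genes up/down versus each
#' parent and up/down versus both (the non-additive classes). By
#' construction `F1>both <= min(F1>P1, F1>P2)` where `F1>P1` counts all
#' genes significantly up versus parent 1 regardless of parent 2.
#'
#' @param calls_p1,calls_p2 call data frames as in
#'   [classify_gene_categories()].
#' @return one-row data frame: location, F1_gt_P1, F1_lt_P1, F1_gt_P2,
#'   F1_lt_P2, F1_gt_both, F1_lt_both.
#' @export
category_counts <- function(calls_p1, calls_p2) {
  loc <- if (nrow(calls_p1)) calls_p1$location[1] else NA_character_
  d1 <- calls_p1$direction; d2 <- calls_p2$direction
  data.frame(location = loc,
             F1_gt_P1 = sum(d1 == "up"), F1_lt_P1 = sum(d1 == "down"),
             F1_gt_P2 = sum(d2 == "up"), F1_lt_P2 = sum(d2 == "down"),
             F1_gt_both = sum(d1 == "up" & d2 == "up"),
             F1_lt_both = sum(d1 == "down" & d2 == "down"),
             stringsAsFactors = FALSE)
}

#' Cross-location concordance of differential calls
#'
#' Restricts to genes called significant at both locations for the same
#' comparison and reports the fraction with agreeing direction plus the
#' squared Pearson correlation of their log2 fold changes.
#'
#' @param calls_a,calls_b call data frames for the same comparison at two
#'   locations.
#' @return list: `shared_genes`, `direction_agreement`, `r_squared`
#'   (`NA` when fewer than 3 shared genes).
#' @export
cross_location_concordance <- function(calls_a, calls_b) {
  stopifnot(identical(unique(calls_a$comparison), unique(calls_b$comparison)))
  a <- calls_a[calls_a$significant, , drop = FALSE]
  b <- calls_b[calls_b$significant, , drop = FALSE]
  shared <- intersect(a$gene, b$gene)
  la <- a$log2_fold_change[match(shared, a$gene)]
  lb <- b$log2_fold_change[match(shared, b$gene)]
  agree <- if (length(shared)) mean(sign(la) == sign(lb)) else NA_real_
  r2 <- if (length(shared) >= 3) stats::cor(la, lb)^2 else NA_real_
  list(shared_genes = shared, direction_agreement = agree, r_squared = r2)
}
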