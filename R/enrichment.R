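# Singular enrichment analysis: one-sided upper-tail hypergeometric
# over-representation of annotation terms in a study gene set against an
# expressed-gene background, with Benjamini-Hochberg FDR alongside the
# raw p-values.

#' Hypergeometric term over-representation (SEA)
#'
#' For each term with at least `min_term_size` annotated background
#' genes, tests P(X >= k) where k of the n study genes carry the term,
#' K of the N background genes do. Study genes outside the background
#' are dropped (their count is reported as an attribute).
#'
#' @param study character vector of study gene identifiers.
#' @param background character vector of background gene identifiers
#'   (the expressed-gene universe).
#' @param annotation data frame with columns gene and term (flat map; no
#'   ontology-graph propagation is performed).
#' @param min_term_size smallest background term size tested.
#' @return data frame of class `sea_result`, sorted by p-value: term, k,
#'   n, K, N, p_value, fdr. Attribute `n_dropped` counts study genes not
#'   in the background.
#' @export
sea <- function(study, background, annotation, min_term_size = 5) {
  study <- unique(study); background <- unique(background)
  dropped <- setdiff(study, background)
  study <- intersect(study, background)
  ann <- annotation[annotation$gene %in% background, , drop = FALSE]
  ann <- unique(ann[, c("gene", "term")])
  N <- length(background); n <- length(study)
  if (n == 0) {
    out <- data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p_value = numeric(0),
                      fdr = numeric(0), stringsAsFactors = FALSE)
    attr(out, "n_dropped") <- length(dropped)
    class(out) <- c("sea_result", "data.frame")
    return(out)
  }
  Ktab <- table(ann$term)
  terms <- names(Ktab)[Ktab >= min_term_size]
  ktab <- table(factor(ann$term[ann$gene %in% study], levels = terms))
  K <- as.integer(Ktab[terms]); k <- as.integer(ktab)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term = terms, k = k, n = n, K = K, N = N,
                    p_value = p, fdr = stats::p.adjust(p, "BH"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- length(dropped)
  class(out) <- c("sea_result", "data.frame")
  out
}

#' @export
print.sea_result <- function(x, max_rows = 10, ...) {
  cat("SEA:", nrow(x), "terms tested; study n =",
      if (nrow(x)) x$n[1] else 0, "of background N =",
      if (nrow(x)) x$N[1] else 0, "\n")
  print.data.frame(utils::head(as.data.frame(x), max_rows), digits = 3)
  invisible(x)
}

#' Report enriched terms at an FDR (or raw p) cutoff
#'
#' @param results a `sea_result` from [sea()].
#' @param alpha significance cutoff.
#' @param use column the cutoff applies to: `"fdr"` or `"p_value"`
#'   (published SEA tables typically print raw p).
#' @param direction_label optional label describing the study set (e.g.
#'   `"F1>N7103"`), repeated on every row.
#' @param descriptions optional data frame (term, description) to join.
#' @return data frame of passing terms sorted by p-value; when none pass,
#'   a single row with term `"NONE"`.
#' @export
enrichment_report <- function(results, alpha = 0.05,
                              use = c("fdr", "p_value"),
                              direction_label = NA_character_,
                              descriptions = NULL) {
  use <- match.arg(use)
  pass <- results[results[[use]] <= alpha, , drop = FALSE]
  if (!nrow(pass)) {
    out <- data.frame(expression = direction_label, term = "NONE",
                      description = NA_character_, k = NA_integer_,
                      n = NA_integer_, K = NA_integer_, N = NA_integer_,
                      p_value = NA_real_, fdr = NA_real_,
                      stringsAsFactors = FALSE)
    return(out)
  }
  pass <- pass[order(pass$p_value, pass$term), , drop = FALSE]
  desc <- if (!is.null(descriptions))
    descriptions$description[match(pass$term, descriptions$term)]
  else NA_character_
  out <- data.frame(expression = direction_label, term = pass$term,
                    description = desc, pass[, c("k", "n", "K", "N",
                                                 "p_value", "fdr")],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
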