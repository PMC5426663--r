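# Parent-specific SNP calling and allele-expression-bias analysis.
# Sites within 2 bp of splice junctions are masked; a site is parent
# specific when exactly one parent is effectively homozygous for the
# alternative allele in every replicate at every location and the other
# parent homozygous reference; F1 allele fractions from pooled read
# counts are called biased when the majority allele exceeds the 73%
# threshold (strict) consistently across replicates.

#' Mask sites near splice junctions
#'
#' Removes sites within `margin` bases of any junction boundary on the
#' same chromosome; such positions are prone to misalignment. Junction
#' boundaries are 1-based positions of the last exonic base on each side
#' of a junction.
#'
#' @param sites data frame with at least chrom and pos (1-based).
#' @param junctions data frame with chrom and pos boundary columns (or
#'   `NULL`/empty for no masking).
#' @param margin masking distance in bases (default 2).
#' @return list with `kept` and `masked` data frames.
#' @export
mask_splice_proximal <- function(sites, junctions, margin = 2) {
  if (is.null(junctions) || !nrow(junctions))
    return(list(kept = sites, masked = sites[0, , drop = FALSE]))
  mism <- setdiff(unique(sites$chrom), unique(junctions$chrom))
  # junction-free chromosomes are normal; warn only if NO chromosome matches
  if (length(mism) == length(unique(sites$chrom)))
    warning("no chromosome shared between sites and junctions; no masking",
            call. = FALSE)
  masked <- logical(nrow(sites))
  for (chr in intersect(unique(sites$chrom), unique(junctions$chrom))) {
    jp <- sort(junctions$pos[junctions$chrom == chr])
    idx <- which(sites$chrom == chr)
    nearest <- findInterval(sites$pos[idx], jp)
    lo <- pmax(nearest, 1); hi <- pmin(nearest + 1, length(jp))
    d <- pmin(abs(sites$pos[idx] - jp[lo]), abs(sites$pos[idx] - jp[hi]))
    masked[idx] <- d <= margin
  }
  list(kept = sites[!masked, , drop = FALSE],
       masked = sites[masked, , drop = FALSE])
}

#' Convert BED junction intervals to 1-based boundary positions
#'
#' Junction intervals are the introns in BED convention (0-based,
#' half-open), so the last exonic base on the left flank is 1-based
#' position `start` and on the right flank `end + 1`. Both flanks of
#' each interval are emitted.
#'
#' @param bed data frame with columns chrom, start, end (BED convention).
#' @return data frame with chrom, pos (1-based boundaries).
#' @export
junctions_from_bed <- function(bed) {
  stopifnot(all(c("chrom", "start", "end") %in% names(bed)))
  data.frame(chrom = rep(bed$chrom, 2),
             pos = c(bed$start, bed$end + 1L),  # last exonic base each side
             stringsAsFactors = FALSE)
}

# genotype of one parental replicate at one site from its read counts:
# "alt" / "ref" when the minor-allele fraction is at most `het_tol` at
# depth >= min_depth, otherwise "het" (or "lowdepth").
parental_genotype <- function(ref_count, alt_count, min_depth, het_tol = 0.05) {
  depth <- ref_count + alt_count
  out <- rep("lowdepth", length(depth))
  frac_alt <- ifelse(depth > 0, alt_count / depth, NA)
  ok <- depth >= min_depth
  out[ok & frac_alt >= 1 - het_tol] <- "alt"
  out[ok & frac_alt <= het_tol] <- "ref"
  out[ok & frac_alt > het_tol & frac_alt < 1 - het_tol] <- "het"
  out
}

#' Call parent-specific SNPs
#'
#' Retains sites where, in every replicate of every location, exactly one
#' parent is effectively homozygous for the alternative allele and the
#' other parent effectively homozygous reference, with all parental
#' replicates at depth >= `min_depth`. "Effectively homozygous" allows a
#' minor-allele read fraction up to `het_tol`. A replicate with
#' insufficient depth fails the site (no exception).
#'
#' @param sites long data frame: chrom, pos, ref, alt, sample, ref_count,
#'   alt_count (already splice-masked).
#' @param samples sample sheet: sample, genotype, location, replicate.
#'   Parents are the two non-F1 genotypes.
#' @param min_depth minimum parental depth (default 8).
#' @param het_tol homozygosity tolerance on the minor-allele fraction.
#' @return data frame of parent-specific sites: chrom, pos, ref, alt,
#'   origin (the alt-carrying parent).
#' @export
call_parent_specific_snps <- function(sites, samples, min_depth = 8,
                                      het_tol = 0.05) {
  parents <- setdiff(unique(samples$genotype), "F1")
  stopifnot(length(parents) == 2)
  p_samples <- samples$sample[samples$genotype %in% parents]
  sub <- sites[sites$sample %in% p_samples, , drop = FALSE]
  sub$genotype <- samples$genotype[match(sub$sample, samples$sample)]
  sub$gt <- parental_genotype(sub$ref_count, sub$alt_count, min_depth, het_tol)
  key <- paste(sub$chrom, sub$pos)
  keys <- unique(key)
  origin <- character(0); keep_key <- character(0)
  for (k in keys) {
    s <- sub[key == k, , drop = FALSE]
    # every parental replicate must be confidently called
    if (nrow(s) < length(p_samples) || any(!s$gt %in% c("ref", "alt"))) next
    gt1 <- unique(s$gt[s$genotype == parents[1]])
    gt2 <- unique(s$gt[s$genotype == parents[2]])
    if (length(gt1) != 1 || length(gt2) != 1) next
    if (gt1 == "alt" && gt2 == "ref") org <- parents[1]
    else if (gt1 == "ref" && gt2 == "alt") org <- parents[2]
    else next
    keep_key <- c(keep_key, k); origin <- c(origin, org)
  }
  first <- sites[!duplicated(paste(sites$chrom, sites$pos)), , drop = FALSE]
  fk <- paste(first$chrom, first$pos)
  idx <- match(keep_key, fk)
  out <- first[idx, c("chrom", "pos", "ref", "alt"), drop = FALSE]
  out$origin <- origin
  rownames(out) <- NULL
  out
}

#' F1 allele fractions at a parent-specific SNP
#'
#' Per-replicate and pooled fractions of the origin-parent allele (the
#' alternative allele) among F1 reads at one location. Pooling sums read
#' counts over replicates passing the depth filter, so the pooled
#' fraction is the fraction of all reads carrying the origin allele.
#'
#' @param snp one row of the [call_parent_specific_snps()] output.
#' @param sites long allele-depth data frame.
#' @param samples sample sheet.
#' @param location location label.
#' @param min_depth minimum per-replicate F1 depth (default 8).
#' @return a one-row data frame of class `bias_call`: chrom, pos, origin,
#'   location, n_reps, pooled_fraction, total_depth, evaluable, plus the
#'   per-replicate fractions as the `replicate_fractions` attribute.
#' @export
f1_allele_fractions <- function(snp, sites, samples, location, min_depth = 8) {
  f1s <- samples$sample[samples$genotype == "F1" & samples$location == location]
  s <- sites[sites$chrom == snp$chrom & sites$pos == snp$pos &
               sites$sample %in% f1s, , drop = FALSE]
  depth <- s$ref_count + s$alt_count
  pass <- depth >= min_depth
  fr <- (s$alt_count / depth)[pass]
  tot_alt <- sum(s$alt_count[pass]); tot <- sum(depth[pass])
  out <- data.frame(chrom = snp$chrom, pos = snp$pos, origin = snp$origin,
                    location = location, n_reps = sum(pass),
                    pooled_fraction = if (tot > 0) tot_alt / tot else NA_real_,
                    total_depth = tot, evaluable = sum(pass) > 0,
                    stringsAsFactors = FALSE)
  attr(out, "replicate_fractions") <- fr
  class(out) <- c("bias_call", "data.frame")
  out
}

#' Classify a bias call against the threshold
#'
#' A SNP shows allele bias at a location when the majority allele
#' accounts for strictly more than `threshold` of the pooled reads AND
#' every depth-passing replicate's fraction falls on the same side of 0.5
#' as the pooled fraction (the consistency rule). The favored allele's
#' parent of origin is recorded: the origin parent when the alternative
#' (origin) allele is in the majority, the other parent when the
#' reference allele is.
#'
#' @param call a `bias_call` from [f1_allele_fractions()].
#' @param threshold majority-allele fraction that must be exceeded
#'   (default 0.73, strict).
#' @param other_parent label reported when the reference allele is
#'   favored.
#' @return the call with `biased` and `favored_allele` columns set.
#' @export
classify_bias <- function(call, threshold = 0.73, other_parent = "other") {
  stopifnot(inherits(call, "bias_call"))
  fr <- attr(call, "replicate_fractions")
  p <- call$pooled_fraction
  if (!isTRUE(call$evaluable) || is.na(p)) {
    call$biased <- NA; call$favored_allele <- NA_character_
    return(call)
  }
  maj <- max(p, 1 - p)
  same_side <- if (p == 0.5) FALSE else all(sign(fr - 0.5) == sign(p - 0.5))
  call$biased <- maj > threshold && same_side
  call$favored_allele <- if (!call$biased) NA_character_
    else if (p > 0.5) call$origin else other_parent
  call
}

#' Bias calls for every parent-specific SNP at one location
#'
#' @param snps output of [call_parent_specific_snps()].
#' @inheritParams f1_allele_fractions
#' @inheritParams classify_bias
#' @param samples sample sheet with an `F1` genotype and two parents.
#' @return data frame of classified `bias_call` rows.
#' @export
bias_calls <- function(snps, sites, samples, location, threshold = 0.73,
                       min_depth = 8) {
  parents <- setdiff(unique(samples$genotype), "F1")
  rows <- lapply(seq_len(nrow(snps)), function(i) {
    call <- f1_allele_fractions(snps[i, , drop = FALSE], sites, samples,
                                location, min_depth)
    classify_bias(call, threshold,
                  other_parent = setdiff(parents, call$origin)[1])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Empirical bias threshold from the fraction distribution
#'
#' Returns 0.5 + 2 standard deviations of the pooled allele fractions
#' (floored at 0.5), the data-driven analogue of the fixed 73% cut: in
#' the motivating experiment 2 SD of the fraction distribution sat at
#' 0.23 above one half. Requires at least 30 fractions; with fewer it
#' falls back to `fallback` with a warning.
#'
#' @param fractions numeric vector of pooled fractions in `[0, 1]`.
#' @param fallback threshold returned when fewer than 30 fractions.
#' @return threshold on the majority-allele scale.
#' @export
empirical_threshold <- function(fractions, fallback = 0.73) {
  fractions <- fractions[is.finite(fractions)]
  if (length(fractions) < 30) {
    warning("fewer than 30 fractions; falling back to fixed threshold",
            call. = FALSE)
    return(fallback)
  }
  max(0.5, 0.5 + 2 * stats::sd(fractions))
}

#' Cross-location concordance of allele fractions
#'
#' @param calls_a,calls_b classified bias-call data frames from two
#'   locations; SNPs are matched on (chrom, pos).
#' @return list: `r_squared_all` (pooled fractions, all matched
#'   evaluable SNPs), `r_squared_biased` (SNPs biased at either
#'   location), `switched` (count of SNPs biased at both locations with
#'   opposite favored alleles), `n_matched`.
#' @export
cross_location_bias_concordance <- function(calls_a, calls_b) {
  key_a <- paste(calls_a$chrom, calls_a$pos)
  key_b <- paste(calls_b$chrom, calls_b$pos)
  common <- intersect(key_a, key_b)
  a <- calls_a[match(common, key_a), , drop = FALSE]
  b <- calls_b[match(common, key_b), , drop = FALSE]
  ok <- a$evaluable & b$evaluable
  a <- a[ok, , drop = FALSE]; b <- b[ok, , drop = FALSE]
  r2 <- function(x, y) if (length(x) >= 3) stats::cor(x, y)^2 else NA_real_
  either <- (a$biased %in% TRUE) | (b$biased %in% TRUE)
  both <- (a$biased %in% TRUE) & (b$biased %in% TRUE)
  switched <- sum(both & a$favored_allele != b$favored_allele)
  list(r_squared_all = r2(a$pooled_fraction, b$pooled_fraction),
       r_squared_biased = r2(a$pooled_fraction[either],
                             b$pooled_fraction[either]),
       switched = switched, n_matched = sum(ok))
}

#' Summarize bias calls per gene
#'
#' @param calls classified bias-call data frame.
#' @param snp_genes data frame mapping chrom, pos to gene; unmapped SNPs
#'   are grouped under `"<unmapped>"`.
#' @return data frame per gene: gene, n_snps, n_biased, n_directions,
#'   consistent (at most one favored allele among its biased SNPs).
#' @export
summarize_gene_bias <- function(calls, snp_genes) {
  key <- paste(calls$chrom, calls$pos)
  gk <- paste(snp_genes$chrom, snp_genes$pos)
  gene <- snp_genes$gene[match(key, gk)]
  gene[is.na(gene)] <- "<unmapped>"
  sp <- split(seq_len(nrow(calls)), gene)
  out <- do.call(rbind, lapply(names(sp), function(g) {
    i <- sp[[g]]
    b <- calls$biased[i] %in% TRUE
    dirs <- unique(calls$favored_allele[i][b])
    data.frame(gene = g, n_snps = length(i), n_biased = sum(b),
               n_directions = length(dirs), consistent = length(dirs) <= 1,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Methylation-associated substitution-class test
#'
#' Classifies each SNP as methylation-associated iff its (ref, alt) pair
#' is C-to-T or G-to-A (the classes produced by deamination of
#' methylcytosine) and tests association between bias status and class
#' with Fisher's exact test.
#'
#' @param biased_snps,unbiased_snps data frames with ref and alt columns.
#' @return list: `table` (2x2: bias status x class), `p_value`,
#'   `degenerate` (TRUE when a margin is empty; p = 1 then).
#' @export
substitution_class_test <- function(biased_snps, unbiased_snps) {
  is_meth <- function(d) (d$ref == "C" & d$alt == "T") |
                         (d$ref == "G" & d$alt == "A")
  tab <- rbind(biased = c(meth = sum(is_meth(biased_snps)),
                          other = sum(!is_meth(biased_snps))),
               unbiased = c(meth = sum(is_meth(unbiased_snps)),
                            other = sum(!is_meth(unbiased_snps))))
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  p <- if (degenerate) 1 else stats::fisher.test(tab)$p.value
  list(table = tab, p_value = p, degenerate = degenerate)
}

#' Histogram of allele fractions by origin parent
#'
#' Bins the pooled origin-allele fractions into `n_bins` half-open bins
#' `[lo, hi)` (last bin closed) and reports, per origin-parent panel,
#' counts as a percentage of that panel's SNPs.
#'
#' @param calls classified bias-call data frame (needs pooled_fraction
#'   and origin).
#' @param n_bins number of bins over `[0, 1]`.
#' @return data frame: origin, bin_lo, bin_hi, count, percent. Percents
#'   sum to 100 within each panel.
#' @export
bias_histogram <- function(calls, n_bins = 20) {
  edges <- seq(0, 1, length.out = n_bins + 1)
  out <- do.call(rbind, lapply(split(calls, calls$origin), function(d) {
    f <- d$pooled_fraction[is.finite(d$pooled_fraction)]
    idx <- pmin(findInterval(f, edges, rightmost.closed = TRUE), n_bins)
    cnt <- tabulate(idx, nbins = n_bins)
    data.frame(origin = d$origin[1], bin_lo = edges[-length(edges)],
               bin_hi = edges[-1], count = cnt,
               percent = if (sum(cnt)) 100 * cnt / sum(cnt) else cnt,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
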