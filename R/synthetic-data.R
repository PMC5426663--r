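# Truth-parameterized generators for field-trial, expression and
# allele-depth data. Every generator is deterministic given its seed and
# returns both the simulated data and the truth record used to make it,
# so downstream stages can be tested by parameter recovery.

#' Truth parameters for a simulated field trial
#'
#' Describes the data-generating process of a randomized complete block
#' design (RCBD) trial at one or more locations: fixed genotype means, an
#' additive mid-parent heterosis shift for the F1, Gaussian block effects,
#' polynomial row/column field trends and Gaussian residual noise.
#'
#' The F1 mean is always derived as `midparent(parent1, parent2) +
#' heterosis_shift`; an F1 entry in `genotype_means` is ignored. The F2
#' mean, if absent, defaults to the mid-parent value plus half the
#' heterosis shift (the expectation under dominance with one round of
#' selfing).
#'
#' @param genotype_means named numeric vector of trait means (trait units).
#'   Must contain entries named by `parent1` and `parent2`.
#' @param heterosis_shift additive shift of the F1 above the mid-parent
#'   value (trait units).
#' @param block_sd,residual_sd non-negative standard deviations of the
#'   random block effects and the plot residuals.
#' @param row_poly,col_poly numeric coefficient vectors (length <= 5,
#'   constant term first) of the planted row/column field trends,
#'   evaluated at the centred integer plot positions.
#' @param n_blocks number of complete blocks per location (>= 2).
#' @param reps_per_block named integer vector: plots of each entry per
#'   block. Defaults mirror a two-parent heterosis trial: 1 F1, 3 F2 and
#'   6 plots of each parent per block.
#' @param locations character vector of location labels.
#' @param parent1,parent2,f1,f2 genotype labels of the two parents and
#'   their progeny generations.
#' @param trait name of the simulated trait column.
#' @param seed integer RNG seed.
#' @return an object of class `trial_truth`.
#' @export
trial_truth <- function(genotype_means = c(N7103 = 2100, NMS4 = 1950, F2 = 2050),
                        heterosis_shift = 200,
                        block_sd = 100, residual_sd = 150,
                        row_poly = numeric(0), col_poly = numeric(0),
                        n_blocks = 5,
                        reps_per_block = c(F1 = 1, F2 = 3, N7103 = 6, NMS4 = 6),
                        locations = c("Kinston", "Clayton"),
                        parent1 = "N7103", parent2 = "NMS4",
                        f1 = "F1", f2 = "F2",
                        trait = "yield", seed = 1L) {
  stopifnot(residual_sd >= 0, block_sd >= 0,
            length(row_poly) <= 5, length(col_poly) <= 5,
            n_blocks >= 2, length(locations) >= 1)
  if (!all(c(parent1, parent2) %in% names(genotype_means)))
    stop("genotype_means must name both parents", call. = FALSE)
  mp <- (genotype_means[[parent1]] + genotype_means[[parent2]]) / 2
  means <- genotype_means
  means[[f1]] <- mp + heterosis_shift
  if (!f2 %in% names(means)) means[[f2]] <- mp + heterosis_shift / 2
  miss <- setdiff(names(reps_per_block), names(means))
  if (length(miss))
    stop("unknown genotype label(s) in design: ", paste(miss, collapse = ", "),
         call. = FALSE)
  structure(list(genotype_means = means, heterosis_shift = heterosis_shift,
                 block_sd = block_sd, residual_sd = residual_sd,
                 row_poly = row_poly, col_poly = col_poly,
                 n_blocks = as.integer(n_blocks),
                 reps_per_block = reps_per_block, locations = locations,
                 parent1 = parent1, parent2 = parent2, f1 = f1, f2 = f2,
                 trait = trait, seed = as.integer(seed)),
            class = "trial_truth")
}

#' Simulate a randomized complete block field trial
#'
#' Lays plots on a grid (one column band per block, entries randomized
#' within block) and draws trait values as genotype mean + block effect +
#' row/column polynomial trend + Gaussian noise.
#'
#' @param truth a [trial_truth()] object.
#' @return a data frame of plot observations (location, block, row, column,
#'   genotype, entry_class, trait) with the truth attached as
#'   `attr(, "truth")`.
#' @export
simulate_trial <- function(truth) {
  stopifnot(inherits(truth, "trial_truth"))
  withr_seed(truth$seed)
  entries <- rep(names(truth$reps_per_block), truth$reps_per_block)
  out <- list()
  for (loc in truth$locations) {
    for (b in seq_len(truth$n_blocks)) {
      geno <- sample(entries)
      n <- length(geno)
      row <- seq_len(n)
      col <- rep(b, n)
      blk <- rnorm(1, 0, truth$block_sd)
      val <- unlist(truth$genotype_means[geno]) + blk +
        eval_poly(truth$row_poly, row - (n + 1) / 2) +
        eval_poly(truth$col_poly, col - (truth$n_blocks + 1) / 2) +
        rnorm(n, 0, truth$residual_sd)
      out[[length(out) + 1L]] <- data.frame(
        location = loc, block = paste0("B", b), row = row, column = col,
        genotype = geno,
        entry_class = entry_class_of(geno, truth),
        trait = val, stringsAsFactors = FALSE)
    }
  }
  plots <- do.call(rbind, out)
  names(plots)[names(plots) == "trait"] <- truth$trait
  rownames(plots) <- NULL
  attr(plots, "truth") <- truth
  plots
}

entry_class_of <- function(geno, truth) {
  cls <- rep("check", length(geno))
  cls[geno == truth$parent1] <- "parent1"
  cls[geno == truth$parent2] <- "parent2"
  cls[geno == truth$f1] <- "F1"
  cls[geno == truth$f2] <- "F2"
  cls
}

eval_poly <- function(coef, x) {
  if (!length(coef)) return(numeric(length(x)))
  drop(outer(x, seq_along(coef) - 1, `^`) %*% coef)
}

#' Truth parameters for a simulated expression study
#'
#' Gene categories describe the F1 mean relative to the parents:
#' `null` (all three genotypes equal), `additive` (F1 at the parent
#' average of parents that differ `fold`-fold), `parent_dominant` (F1
#' equal to the high parent), `above_both` (parents equal, F1 `fold`
#' times higher) and `below_both` (parents equal, F1 `fold` times lower).
#' Replicate values are log-normal around the genotype-by-location mean
#' with coefficient of variation `replicate_cv`; a log-normal
#' location effect (sd `location_effect_sd` on the natural-log scale)
#' scales each gene within a location.
#'
#' @param n_genes number of genes.
#' @param prop named numeric vector of category proportions; names from
#'   `c("null","additive","parent_dominant","above_both","below_both")`.
#' @param baseline_mean,fold positive scalars: baseline expression level
#'   and fold separation used by the non-null categories (fold >= 1).
#' @param replicate_cv coefficient of variation of replicate noise.
#' @param location_effect_sd sd of the per-gene location effect (log scale).
#' @param n_reps replicates per genotype per location.
#' @param locations location labels.
#' @param seed integer RNG seed.
#' @return an object of class `expression_truth`.
#' @export
expression_truth <- function(n_genes = 2000,
                             prop = c(null = 0.9, additive = 0.04,
                                      parent_dominant = 0.03,
                                      above_both = 0.015, below_both = 0.015),
                             baseline_mean = 20, fold = 4,
                             replicate_cv = 0.2, location_effect_sd = 0.1,
                             n_reps = 4, locations = c("Kinston", "Clayton"),
                             seed = 1L) {
  stopifnot(n_genes >= 1, fold >= 1, baseline_mean > 0,
            replicate_cv >= 0, location_effect_sd >= 0, n_reps >= 2,
            abs(sum(prop) - 1) < 1e-8)
  structure(list(n_genes = as.integer(n_genes), prop = prop,
                 baseline_mean = baseline_mean, fold = fold,
                 replicate_cv = replicate_cv,
                 location_effect_sd = location_effect_sd,
                 n_reps = as.integer(n_reps), locations = locations,
                 seed = as.integer(seed)),
            class = "expression_truth")
}

#' Simulate a gene-by-sample expression matrix
#'
#' @param truth an [expression_truth()] object.
#' @return a list of class `expression_set` with elements `values` (gene x
#'   sample matrix of FPKM-like values), `samples` (metadata data frame
#'   with genotype, location, replicate) and `truth_labels` (per-gene
#'   planted category).
#' @export
simulate_expression <- function(truth) {
  stopifnot(inherits(truth, "expression_truth"))
  if (truth$n_genes == 0) stop("n_genes must be positive", call. = FALSE)
  withr_seed(truth$seed)
  cats <- names(truth$prop)
  n_per <- floor(truth$prop * truth$n_genes)
  n_per[1] <- n_per[1] + truth$n_genes - sum(n_per)
  category <- sample(rep(cats, n_per))
  genes <- sprintf("gene%05d", seq_len(truth$n_genes))
  b <- truth$baseline_mean; f <- truth$fold
  gm <- matrix(b, truth$n_genes, 3, dimnames = list(genes, c("P1", "P2", "F1")))
  gm[category == "additive", ] <- rep(c(b, b * f, b * (1 + f) / 2),
                                      each = sum(category == "additive"))
  gm[category == "parent_dominant", ] <- rep(c(b, b * f, b * f),
                                             each = sum(category == "parent_dominant"))
  gm[category == "above_both", "F1"] <- b * f
  gm[category == "below_both", "F1"] <- b / f
  samples <- expand.grid(replicate = seq_len(truth$n_reps),
                         genotype = c("P1", "P2", "F1"),
                         location = truth$locations,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples <- samples[, c("genotype", "location", "replicate")]
  samples$sample <- with(samples, paste(genotype, location, replicate, sep = "_"))
  sig <- sqrt(log(1 + truth$replicate_cv^2))
  vals <- matrix(0, truth$n_genes, nrow(samples),
                 dimnames = list(genes, samples$sample))
  loc_eff <- matrix(rnorm(truth$n_genes * length(truth$locations),
                          0, truth$location_effect_sd),
                    truth$n_genes, length(truth$locations),
                    dimnames = list(genes, truth$locations))
  for (j in seq_len(nrow(samples))) {
    mu <- gm[, samples$genotype[j]] * exp(loc_eff[, samples$location[j]])
    if (sig > 0) {
      vals[, j] <- mu * exp(rnorm(truth$n_genes, -sig^2 / 2, sig))
    } else {
      vals[, j] <- mu
    }
  }
  structure(list(values = vals, samples = samples,
                 truth_labels = data.frame(gene = genes, category = category,
                                           stringsAsFactors = FALSE),
                 truth = truth),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat("expression_set:", nrow(x$values), "genes x", ncol(x$values), "samples\n")
  cat("genotypes:", paste(unique(x$samples$genotype), collapse = ", "),
      "| locations:", paste(unique(x$samples$location), collapse = ", "), "\n")
  invisible(x)
}

#' Truth parameters for simulated allele-depth data
#'
#' Emulates the read-depth data at candidate parent-specific SNPs: each
#' site has one parent fixed for the alternative allele (its
#' `parent_of_origin`) and the other fixed for the reference; F1 alt
#' depths are binomial (optionally beta-binomial) around 0.5 for unbiased
#' sites and around `bias_level` (in favour of the origin-parent allele)
#' for the planted biased fraction. A fraction of sites sits within 2 bp
#' of a splice junction, and replicates of the partially inbred
#' NMS4-like parent are switched to heterozygous with probability
#' `residual_het_rate` (the expected residual heterozygosity of an
#' F4-derived line is 12.5%).
#'
#' @param n_snps number of biallelic sites.
#' @param biased_fraction fraction of sites with a planted allele bias.
#' @param bias_level origin-allele fraction at biased sites (in (0.5, 1]).
#' @param depth_mean mean sequencing depth per sample per site (Poisson).
#' @param residual_het_rate per-(site, NMS4-replicate) probability of
#'   heterozygous contamination.
#' @param splice_proximal_fraction fraction of sites placed within 2 bp of
#'   a splice-junction boundary.
#' @param overdispersion beta-binomial intraclass correlation rho for F1
#'   allele counts; 0 gives pure binomial sampling.
#' @param n_reps replicates per genotype per location.
#' @param locations location labels.
#' @param genes_per_snp mean number of SNPs per gene used when assigning
#'   sites to gene models (controls multi-SNP genes).
#' @param seed integer RNG seed.
#' @return an object of class `ase_truth`.
#' @export
ase_truth <- function(n_snps = 500, biased_fraction = 0.1, bias_level = 0.9,
                      depth_mean = 50, residual_het_rate = 0.125,
                      splice_proximal_fraction = 0.05, overdispersion = 0,
                      n_reps = 4, locations = c("Kinston", "Clayton"),
                      genes_per_snp = 1.25, seed = 1L) {
  if (depth_mean <= 0) stop("depth_mean must be positive", call. = FALSE)
  stopifnot(n_snps >= 1, biased_fraction >= 0, biased_fraction <= 1,
            bias_level > 0.5, bias_level <= 1,
            residual_het_rate >= 0, residual_het_rate <= 1,
            splice_proximal_fraction >= 0, splice_proximal_fraction <= 1,
            overdispersion >= 0, overdispersion < 1)
  structure(list(n_snps = as.integer(n_snps), biased_fraction = biased_fraction,
                 bias_level = bias_level, depth_mean = depth_mean,
                 residual_het_rate = residual_het_rate,
                 splice_proximal_fraction = splice_proximal_fraction,
                 overdispersion = overdispersion, n_reps = as.integer(n_reps),
                 locations = locations, genes_per_snp = genes_per_snp,
                 seed = as.integer(seed)),
            class = "ase_truth")
}

rbetabinom <- function(n, size, prob, rho) {
  if (rho <= 0) return(rbinom(n, size, prob))
  ab <- (1 - rho) / rho
  p <- rbeta(n, prob * ab, (1 - prob) * ab)
  rbinom(n, size, p)
}

#' Simulate allele-depth tables at parent-specific SNP candidates
#'
#' @param truth an [ase_truth()] object.
#' @return a list of class `ase_sim` with elements `sites` (long data
#'   frame: chrom, pos, ref, alt, sample, ref_count, alt_count), `samples`
#'   (sample sheet: sample, genotype, location, replicate), `junctions`
#'   (data frame of 1-based junction boundary positions), `snp_genes`
#'   (site-to-gene map) and `truth_labels` (per-site planted origin, bias
#'   and splice proximity).
#' @export
simulate_allele_counts <- function(truth) {
  stopifnot(inherits(truth, "ase_truth"))
  withr_seed(truth$seed)
  n <- truth$n_snps
  bases <- c("A", "C", "G", "T")
  chrom <- paste0("Gm", sprintf("%02d", sample(1:20, n, replace = TRUE)))
  pos <- sample(1000:5e6, n, replace = TRUE)
  key <- paste(chrom, pos)
  while (anyDuplicated(key)) {        # unique (chrom, pos)
    dup <- duplicated(key)
    pos[dup] <- pos[dup] + sample(1:100, sum(dup), replace = TRUE)
    key <- paste(chrom, pos)
  }
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  origin <- sample(c("N7103", "NMS4"), n, replace = TRUE)
  biased <- rep(FALSE, n)
  biased[sample.int(n, round(truth$biased_fraction * n))] <- TRUE
  splice <- rep(FALSE, n)
  splice[sample.int(n, round(truth$splice_proximal_fraction * n))] <- TRUE
  junctions <- data.frame(chrom = chrom[splice],
                          pos = pos[splice] + sample(-2:2, sum(splice), replace = TRUE))
  # decoy junctions far from any site
  if (nrow(junctions) < 5)
    junctions <- rbind(junctions, data.frame(chrom = "Gm01", pos = c(10, 20, 30)))
  genes <- sprintf("Glyma.%05d", cumsum(runif(n) < 1 / truth$genes_per_snp) + 1L)
  snp_genes <- data.frame(chrom = chrom, pos = pos, gene = genes,
                          stringsAsFactors = FALSE)

  samples <- expand.grid(replicate = seq_len(truth$n_reps),
                         genotype = c("N7103", "NMS4", "F1"),
                         location = truth$locations,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples$sample <- with(samples, paste(genotype, location, replicate, sep = "_"))
  samples <- samples[, c("sample", "genotype", "location", "replicate")]

  recs <- vector("list", nrow(samples))
  for (j in seq_len(nrow(samples))) {
    g <- samples$genotype[j]
    depth <- rpois(n, truth$depth_mean)
    if (g == "F1") {
      p_alt <- ifelse(biased, truth$bias_level, 0.5)
      # bias favours the origin-parent allele, which is always alt here
      a <- rbetabinom(n, depth, p_alt, truth$overdispersion)
    } else {
      hom_alt <- origin == g
      a <- ifelse(hom_alt, depth, 0L)
      if (g == "NMS4" && truth$residual_het_rate > 0) {
        het <- runif(n) < truth$residual_het_rate
        a[het] <- rbinom(sum(het), depth[het], 0.5)
      }
    }
    recs[[j]] <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                            sample = samples$sample[j],
                            ref_count = depth - a, alt_count = a,
                            stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, recs)
  rownames(sites) <- NULL
  structure(list(sites = sites, samples = samples, junctions = junctions,
                 snp_genes = snp_genes,
                 truth_labels = data.frame(chrom = chrom, pos = pos,
                                           origin = origin, biased = biased,
                                           splice_proximal = splice,
                                           gene = genes,
                                           stringsAsFactors = FALSE),
                 truth = truth),
            class = "ase_sim")
}

#' @export
print.ase_sim <- function(x, ...) {
  cat("ase_sim:", nrow(x$truth_labels), "sites x", nrow(x$samples),
      "samples;", sum(x$truth_labels$biased), "planted biased\n")
  invisible(x)
}

#' Simulate a flat gene-to-GO annotation map
#'
#' Assigns each gene a Poisson number of terms drawn from a skewed term
#' frequency distribution, the shape typical of GO slims.
#'
#' @param genes character vector of gene identifiers.
#' @param n_terms number of distinct terms.
#' @param mean_terms_per_gene mean annotations per gene.
#' @param seed integer RNG seed.
#' @return data frame with columns gene, term.
#' @export
simulate_annotation <- function(genes, n_terms = 50, mean_terms_per_gene = 2,
                                seed = 1L) {
  withr_seed(seed)
  terms <- sprintf("GO:%07d", seq_len(n_terms))
  w <- 1 / seq_len(n_terms)           # Zipf-ish term sizes
  k <- rpois(length(genes), mean_terms_per_gene)
  idx <- rep(seq_along(genes), k)
  data.frame(gene = genes[idx],
             term = sample(terms, sum(k), replace = TRUE, prob = w),
             stringsAsFactors = FALSE)
}

# All generators draw from a seeded stream so identical truth records give
# byte-identical output.
withr_seed <- function(seed) set.seed(as.integer(seed) %% .Machine$integer.max)
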