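# Fixture builders shared across tests. All randomness is seeded locally.

# 30-plot single-location fixture with genotype, block and grid positions
make_plot_fixture <- function(n = 30, seed = 42, sd = 5) {
  set.seed(seed)
  data.frame(location = "Loc1",
             block = rep(c("B1", "B2"), each = n / 2),
             row = seq_len(n),
             column = rep(1:5, length.out = n),
             genotype = rep(c("A", "B", "C"), length.out = n),
             entry_class = rep(c("parent1", "parent2", "F1"), length.out = n),
             yield = 100 + rep(c(0, 5, 10), length.out = n) + rnorm(n, 0, sd),
             stringsAsFactors = FALSE)
}

# degenerate one-plot-per-genotype table from published-style means
means_fixture <- function(location, means) {
  # means: named list genotype -> c(trait values); roles in fixed order
  roles <- c(F1 = "F1", F2 = "F2", parent2 = "NMS4-44-329", parent1 = "N7103")
  do.call(rbind, lapply(names(roles), function(r) {
    g <- roles[[r]]
    data.frame(location = location, block = "B1",
               row = match(r, names(roles)), column = 1,
               genotype = g, entry_class = r,
               as.data.frame(as.list(means[[g]])),
               stringsAsFactors = FALSE)
  }))
}

table2_plots <- function() {
  kin <- list(
    "F1"          = c(yield = 2204, protein = 46.0, harvestable_protein = 941),
    "F2"          = c(yield = 2045, protein = 46.1, harvestable_protein = 873),
    "NMS4-44-329" = c(yield = 1934, protein = 44.1, harvestable_protein = 791),
    "N7103"       = c(yield = 2096, protein = 45.7, harvestable_protein = 889))
  cla <- list(
    "F1"          = c(yield = 2618, protein = 44.1, harvestable_protein = 1057),
    "F2"          = c(yield = 2529, protein = 44.1, harvestable_protein = 1053),
    "NMS4-44-329" = c(yield = 2479, protein = 42.2, harvestable_protein = 971),
    "N7103"       = c(yield = 2311, protein = 43.7, harvestable_protein = 943))
  rbind(means_fixture("Kinston", kin), means_fixture("Clayton", cla))
}

# tiny long-format allele-depth table builder: counts is a named list
# sample -> c(ref, alt) and site coordinates are fixed
ad_row <- function(chrom, pos, ref, alt, sample, rc, ac) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, sample = sample,
             ref_count = rc, alt_count = ac, stringsAsFactors = FALSE)
}

# standard 2-parent x 2-replicate x 2-location + F1 sample sheet
toy_sample_sheet <- function(n_reps = 2, locations = c("L1", "L2")) {
  g <- expand.grid(replicate = seq_len(n_reps),
                   genotype = c("N7103", "NMS4", "F1"),
                   location = locations,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$sample <- with(g, paste(genotype, location, replicate, sep = "_"))
  g[, c("sample", "genotype", "location", "replicate")]
}

# build a toy site: per-sample (ref, alt) counts supplied as a named list
toy_site <- function(chrom, pos, ref, alt, counts) {
  do.call(rbind, lapply(names(counts), function(s)
    ad_row(chrom, pos, ref, alt, s, counts[[s]][1], counts[[s]][2])))
}

# independent brute-force evaluation of the parent-specific criteria:
# a site passes iff every parental replicate has depth >= min_depth and
# one parent has alt fraction >= 1 - tol in all replicates while the
# other has alt fraction <= tol in all replicates
oracle_parent_specific <- function(sites, samples, min_depth = 8, tol = 0.05) {
  parents <- setdiff(unique(samples$genotype), "F1")
  keys <- unique(paste(sites$chrom, sites$pos))
  out <- data.frame(chrom = character(0), pos = integer(0),
                    origin = character(0), stringsAsFactors = FALSE)
  for (k in keys) {
    s <- sites[paste(sites$chrom, sites$pos) == k, ]
    verdict <- NULL
    for (org in parents) {
      other <- setdiff(parents, org)
      ok <- TRUE
      for (p in parents) {
        ps <- samples$sample[samples$genotype == p]
        rows <- s[s$sample %in% ps, ]
        if (nrow(rows) < length(ps)) { ok <- FALSE; break }
        depth <- rows$ref_count + rows$alt_count
        if (any(depth < min_depth)) { ok <- FALSE; break }
        fa <- rows$alt_count / depth
        want_alt <- p == org
        if (want_alt && any(fa < 1 - tol)) { ok <- FALSE; break }
        if (!want_alt && any(fa > tol)) { ok <- FALSE; break }
      }
      if (ok) verdict <- c(verdict, org)
    }
    if (length(verdict) == 1)
      out <- rbind(out, data.frame(chrom = s$chrom[1], pos = s$pos[1],
                                   origin = verdict, stringsAsFactors = FALSE))
  }
  out
}
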