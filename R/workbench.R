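# File formats and the end-to-end pipeline driver. All tabular outputs
# are plain TSV/CSV; the run manifest is JSON. A single global seed
# drives per-stage substreams so any stage can be rerun reproducibly.

plot_required_cols <- c("location", "block", "row", "column", "genotype",
                        "entry_class")

#' Read a plot-observation table
#'
#' CSV with required design columns (location, block, row, column,
#' genotype, entry_class) and one numeric column per trait. Rows with
#' unparseable trait cells are reported; a lodging column must lie in
#' the 1 (erect) to 5 (prostrate) scoring range.
#'
#' @param path CSV file path.
#' @return data frame of plot observations.
#' @export
read_plot_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(plot_required_cols, names(df))
  if (length(missing))
    stop("plot table missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  traits <- setdiff(names(df), plot_required_cols)
  for (tr in traits) {
    v <- suppressWarnings(as.numeric(df[[tr]]))
    bad <- which(is.na(v) & !is.na(df[[tr]]) & df[[tr]] != "")
    if (length(bad))
      stop("unparseable values in trait '", tr, "' at row(s): ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    df[[tr]] <- v
  }
  if ("lodging" %in% names(df)) {
    bad <- which(!is.na(df$lodging) & (df$lodging < 1 | df$lodging > 5))
    if (length(bad))
      stop("lodging outside the 1-5 scoring range at row(s): ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  df$row <- as.integer(df$row); df$column <- as.integer(df$column)
  df
}

#' Write a plot-observation table
#' @param plots data frame from [simulate_trial()] or [read_plot_table()].
#' @param path output CSV path.
#' @export
write_plot_table <- function(plots, path) {
  utils::write.csv(as.data.frame(plots), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an expression matrix with sample metadata
#'
#' @param expr_path gene x sample TSV (first column gene identifiers).
#' @param meta_path sample-sheet TSV with columns sample, genotype,
#'   location, replicate.
#' @return an `expression_set` list (values, samples).
#' @export
read_expression_matrix <- function(expr_path, meta_path) {
  m <- utils::read.delim(expr_path, check.names = FALSE)
  vals <- as.matrix(m[, -1, drop = FALSE])
  rownames(vals) <- m[[1]]
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  need <- c("sample", "genotype", "location", "replicate")
  if (!all(need %in% names(meta)))
    stop("sample sheet missing column(s): ",
         paste(setdiff(need, names(meta)), collapse = ", "), call. = FALSE)
  if (!all(colnames(vals) %in% meta$sample))
    stop("samples in matrix absent from sheet: ",
         paste(setdiff(colnames(vals), meta$sample), collapse = ", "),
         call. = FALSE)
  meta <- meta[match(colnames(vals), meta$sample), , drop = FALSE]
  structure(list(values = vals, samples = meta), class = "expression_set")
}

#' Write an expression set as TSV pair
#' @param es an `expression_set`.
#' @param expr_path,meta_path output TSV paths.
#' @export
write_expression_matrix <- function(es, expr_path, meta_path) {
  df <- data.frame(gene = rownames(es$values), es$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, expr_path, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(es$samples, meta_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(expr_path)
}

#' Read an allele-depth table (TSV or minimal VCF)
#'
#' The TSV dialect has columns chrom, pos, ref, alt, sample, ref_count,
#' alt_count. The VCF dialect must carry per-sample allelic depths in an
#' `AD` FORMAT field (`ref,alt`). Only biallelic SNVs are kept; indel
#' and multi-allelic records are skipped and counted in the `skipped`
#' attribute. Every sample in the file must appear in the sheet.
#'
#' @param path `.vcf` or `.tsv` file.
#' @param samples sample sheet data frame (sample, genotype, location,
#'   replicate).
#' @return long data frame of per-sample site depths with attribute
#'   `skipped` = c(indel = ..., multiallelic = ...).
#' @export
read_allele_depth <- function(path, samples) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    out <- read_allele_depth_vcf(path)
  } else {
    out <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "pos", "ref", "alt", "sample", "ref_count", "alt_count")
    if (!all(need %in% names(out)))
      stop("allele-depth TSV missing column(s): ",
           paste(setdiff(need, names(out)), collapse = ", "), call. = FALSE)
    snv <- nchar(out$ref) == 1 & nchar(out$alt) == 1 &
      !grepl(",", out$alt, fixed = TRUE)
    attr_skip <- c(indel = length(unique(paste(out$chrom, out$pos)[
      nchar(out$ref) > 1 | nchar(out$alt) > 1])),
      multiallelic = length(unique(paste(out$chrom, out$pos)[
        grepl(",", out$alt, fixed = TRUE)])))
    out <- out[snv, , drop = FALSE]
    attr(out, "skipped") <- attr_skip
  }
  unmatched <- setdiff(unique(out$sample), samples$sample)
  if (length(unmatched))
    stop("sample(s) in file absent from sheet: ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  rownames(out) <- NULL
  out
}

read_allele_depth_vcf <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) {
    warning("empty VCF: ", path, call. = FALSE)
    return(structure(data.frame(chrom = character(0), pos = integer(0),
                                ref = character(0), alt = character(0),
                                sample = character(0),
                                ref_count = integer(0), alt_count = integer(0),
                                stringsAsFactors = FALSE),
                     skipped = c(indel = 0L, multiallelic = 0L)))
  }
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("no #CHROM header line in VCF", call. = FALSE)
  cols <- strsplit(sub("^#", "", lines[hdr[1]]), "\t")[[1]]
  vcf_samples <- cols[-(1:9)]
  body <- lines[-seq_len(hdr[1])]
  body <- body[nzchar(body)]
  skipped <- c(indel = 0L, multiallelic = 0L)
  recs <- vector("list", length(body))
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    ref <- f[4]; alt <- f[5]
    if (grepl(",", alt, fixed = TRUE)) { skipped["multiallelic"] <-
      skipped["multiallelic"] + 1L; next }
    if (nchar(ref) != 1 || nchar(alt) != 1) { skipped["indel"] <-
      skipped["indel"] + 1L; next }
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    ad_i <- match("AD", fmt)
    if (is.na(ad_i)) stop("VCF FORMAT lacks AD field", call. = FALSE)
    ad <- vapply(f[-(1:9)], function(s)
      strsplit(s, ":", fixed = TRUE)[[1]][ad_i], "")
    parts <- do.call(rbind, strsplit(ad, ",", fixed = TRUE))
    recs[[i]] <- data.frame(chrom = f[1], pos = as.integer(f[2]),
                            ref = ref, alt = alt, sample = vcf_samples,
                            ref_count = as.integer(parts[, 1]),
                            alt_count = as.integer(parts[, 2]),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs)
  if (is.null(out))
    out <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      sample = character(0), ref_count = integer(0),
                      alt_count = integer(0), stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}

#' Write an allele-depth table as a minimal VCF
#'
#' One record per site, per-sample `AD` (ref,alt) fields, samples in
#' sheet order.
#'
#' @param sites long allele-depth data frame.
#' @param samples sample sheet.
#' @param path output path.
#' @export
write_allele_depth_vcf <- function(sites, samples, path) {
  key <- paste(sites$chrom, sites$pos)
  usite <- sites[!duplicated(key), c("chrom", "pos", "ref", "alt")]
  usite <- usite[order(usite$chrom, usite$pos), , drop = FALSE]
  sm <- samples$sample
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", sm), collapse = "\t")), con)
  idx <- split(seq_len(nrow(sites)), key)
  for (i in seq_len(nrow(usite))) {
    k <- paste(usite$chrom[i], usite$pos[i])
    s <- sites[idx[[k]], , drop = FALSE]
    ad <- paste(s$ref_count[match(sm, s$sample)],
                s$alt_count[match(sm, s$sample)], sep = ",")
    writeLines(paste(c(usite$chrom[i], usite$pos[i], ".", usite$ref[i],
                       usite$alt[i], ".", "PASS", ".", "AD", ad),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Pipeline configuration
#'
#' @param seed global integer seed; per-stage substreams are derived
#'   from it.
#' @param out_dir output directory (created if absent).
#' @param stages stages to run, in fixed order, from
#'   `c("simulate", "trial", "de", "ase", "enrich")`.
#' @param alpha DE replicate-test level. @param min_fold DE fold gate.
#' @param bias_threshold allele-bias cut (strictly exceeded).
#' @param min_depth depth filter for parental and F1 replicates.
#' @param margin splice-proximity mask distance (bases).
#' @param min_level expressed-gene background threshold.
#' @param trial,expression,ase named lists of overrides passed to
#'   [trial_truth()], [expression_truth()] and [ase_truth()].
#' @param paths named list of input file paths used when `"simulate"` is
#'   not among the stages: plots, expr, expr_meta, sites, sample_sheet,
#'   junctions_bed, snp_genes, annotation.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("heterosim_run_"),
                            stages = c("simulate", "trial", "de", "ase",
                                       "enrich"),
                            alpha = 0.05, min_fold = 2, bias_threshold = 0.73,
                            min_depth = 8, margin = 2, min_level = 1,
                            trial = list(), expression = list(), ase = list(),
                            paths = list()) {
  stages <- match.arg(stages, several.ok = TRUE)
  stopifnot(alpha > 0, alpha < 1, min_fold >= 1,
            bias_threshold > 0.5, bias_threshold < 1,
            min_depth >= 0, margin >= 0)
  structure(list(seed = as.integer(seed), out_dir = out_dir, stages = stages,
                 alpha = alpha, min_fold = min_fold,
                 bias_threshold = bias_threshold, min_depth = min_depth,
                 margin = margin, min_level = min_level, trial = trial,
                 expression = expression, ase = ase, paths = paths),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys mirror [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

stage_seed <- function(seed, stage) {
  # distinct, stable substream per stage
  offs <- c(simulate = 101L, trial = 211L, de = 307L, ase = 401L,
            enrich = 503L)
  (seed * 1009L + offs[[stage]]) %% 2147483647L
}

wt <- function(df, dir, name) {
  utils::write.table(df, file.path(dir, name), sep = "\t",
                     row.names = FALSE, quote = FALSE)
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order — simulate, field-trial
#' contrasts, differential-expression classification, allele-bias
#' calling, enrichment — writing every stage output as TSV/CSV in
#' `config$out_dir` plus a JSON run manifest with resolved settings and
#' telescoping filter counts. Rerunning with the same configuration
#' yields byte-identical analytic outputs.
#'
#' @param config a [pipeline_config()].
#' @return the manifest list, invisibly; stage outputs live on disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = config[setdiff(names(config), "")],
                   counts = list(), stages_run = character(0))
  sim <- NULL
  paths <- config$paths

  if ("simulate" %in% config$stages) {
    s <- stage_seed(config$seed, "simulate")
    tt <- do.call(trial_truth, utils::modifyList(list(seed = s), config$trial))
    et <- do.call(expression_truth,
                  utils::modifyList(list(seed = s + 1L), config$expression))
    at <- do.call(ase_truth, utils::modifyList(list(seed = s + 2L), config$ase))
    plots <- simulate_trial(tt)
    es <- simulate_expression(et)
    ase <- simulate_allele_counts(at)
    ann <- simulate_annotation(rownames(es$values), seed = s + 3L)
    write_plot_table(plots, file.path(config$out_dir, "plots.csv"))
    write_expression_matrix(es, file.path(config$out_dir, "expression.tsv"),
                            file.path(config$out_dir, "expression_samples.tsv"))
    wt(ase$sites, config$out_dir, "sites.tsv")
    wt(ase$samples, config$out_dir, "ase_samples.tsv")
    wt(ase$junctions, config$out_dir, "junctions.tsv")
    wt(ase$snp_genes, config$out_dir, "snp_genes.tsv")
    wt(ann, config$out_dir, "annotation.tsv")
    wt(es$truth_labels, config$out_dir, "expression_truth.tsv")
    wt(ase$truth_labels, config$out_dir, "ase_truth.tsv")
    sim <- list(plots = plots, es = es, ase = ase, ann = ann)
    manifest$counts$simulate <- list(plots = nrow(plots),
                                     genes = nrow(es$values),
                                     sites = nrow(ase$truth_labels))
    manifest$stages_run <- c(manifest$stages_run, "simulate")
  }

  get_plots <- function() {
    if (!is.null(sim)) sim$plots else read_plot_table(paths$plots)
  }
  get_es <- function() {
    if (!is.null(sim)) sim$es
    else read_expression_matrix(paths$expr, paths$expr_meta)
  }
  get_ase <- function() {
    if (!is.null(sim)) sim$ase else {
      samples <- utils::read.delim(paths$sample_sheet, stringsAsFactors = FALSE)
      sites <- read_allele_depth(paths$sites, samples)
      junctions <- if (!is.null(paths$junctions_bed))
        junctions_from_bed(utils::read.delim(paths$junctions_bed,
                                             header = FALSE,
                                             col.names = c("chrom", "start",
                                                           "end")))
      else utils::read.delim(paths$junctions, stringsAsFactors = FALSE)
      snp_genes <- if (!is.null(paths$snp_genes))
        utils::read.delim(paths$snp_genes, stringsAsFactors = FALSE) else NULL
      list(sites = sites, samples = samples, junctions = junctions,
           snp_genes = snp_genes)
    }
  }

  if ("trial" %in% config$stages) {
    plots <- get_plots()
    rep_tab <- heterosis_report(plots)
    wt(format(as.data.frame(rep_tab), digits = 10), config$out_dir,
       "trial_contrasts.tsv")
    manifest$counts$trial <- list(plots = nrow(plots),
                                  contrasts = nrow(rep_tab))
    manifest$stages_run <- c(manifest$stages_run, "trial")
  }

  de_out <- NULL
  if ("de" %in% config$stages) {
    es <- get_es()
    locs <- unique(es$samples$location)
    cats <- list(); counts <- list(); calls <- list()
    for (loc in locs) {
      c1 <- differential_calls(es, "P1", loc, alpha = config$alpha,
                               min_fold = config$min_fold)
      c2 <- differential_calls(es, "P2", loc, alpha = config$alpha,
                               min_fold = config$min_fold)
      cats[[loc]] <- classify_gene_categories(c1, c2)
      counts[[loc]] <- category_counts(c1, c2)
      calls[[loc]] <- list(P1 = c1, P2 = c2)
    }
    categories <- do.call(rbind, cats)
    wt(categories, config$out_dir, "de_categories.tsv")
    wt(do.call(rbind, counts), config$out_dir, "de_category_counts.tsv")
    if (length(locs) >= 2) {
      cc <- cross_location_concordance(calls[[1]]$P1, calls[[2]]$P1)
      manifest$counts$de_concordance <-
        list(shared = length(cc$shared_genes),
             direction_agreement = cc$direction_agreement,
             r_squared = cc$r_squared)
    }
    de_out <- list(es = es, categories = categories, calls = calls)
    manifest$counts$de <- list(genes = nrow(es$values),
                               locations = length(locs))
    manifest$stages_run <- c(manifest$stages_run, "de")
  }

  if ("ase" %in% config$stages) {
    a <- get_ase()
    n_in <- length(unique(paste(a$sites$chrom, a$sites$pos)))
    m <- mask_splice_proximal(a$sites, a$junctions, config$margin)
    n_masked_sites <- n_in -
      length(unique(paste(m$kept$chrom, m$kept$pos)))
    snps <- call_parent_specific_snps(m$kept, a$samples, config$min_depth)
    locs <- unique(a$samples$location)
    all_calls <- list()
    for (loc in locs)
      all_calls[[loc]] <- bias_calls(snps, m$kept, a$samples, loc,
                                     config$bias_threshold, config$min_depth)
    calls <- do.call(rbind, all_calls)
    wt(calls, config$out_dir, "ase_bias_calls.tsv")
    if (!is.null(a$snp_genes))
      wt(summarize_gene_bias(calls[calls$evaluable, , drop = FALSE],
                             a$snp_genes),
         config$out_dir, "ase_gene_bias.tsv")
    if (length(locs) >= 2) {
      conc <- cross_location_bias_concordance(all_calls[[1]], all_calls[[2]])
      manifest$counts$ase_concordance <- conc[c("r_squared_all",
                                                "r_squared_biased",
                                                "switched", "n_matched")]
    }
    manifest$counts$ase <- list(
      sites_in = n_in, splice_masked = n_masked_sites,
      after_mask = n_in - n_masked_sites,
      parent_specific = nrow(snps),
      evaluable = sum(calls$evaluable) %/% max(length(locs), 1),
      biased = sum(calls$biased %in% TRUE))
    manifest$stages_run <- c(manifest$stages_run, "ase")
  }

  if ("enrich" %in% config$stages) {
    if (is.null(de_out))
      stop("enrich stage needs the de stage (study and background sets)",
           call. = FALSE)
    ann <- if (!is.null(sim)) sim$ann
      else utils::read.delim(paths$annotation, stringsAsFactors = FALSE)
    es <- de_out$es
    reports <- list()
    for (loc in unique(es$samples$location)) {
      background <- detect_expressed(es, loc, config$min_level)
      cat_loc <- de_out$categories[de_out$categories$location == loc, ]
      for (set_name in c("above_both", "below_both")) {
        study <- cat_loc$gene[cat_loc$category == set_name]
        res <- sea(study, background, ann)
        reports[[paste(loc, set_name)]] <-
          cbind(location = loc,
                enrichment_report(res, alpha = 0.05, use = "p_value",
                                  direction_label = set_name))
      }
    }
    wt(do.call(rbind, reports), config$out_dir, "enrichment.tsv")
    manifest$stages_run <- c(manifest$stages_run, "enrich")
  }

  manifest$timestamp <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}
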