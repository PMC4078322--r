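#' Pipeline configuration
#'
#' Resolves every stage's parameters and seeds up front so a run is fully
#' reproducible from its config alone. Stage seeds are derived from the one
#' top-level seed.
#'
#' @param zone A [zone_config()] describing the synthetic dataset (its seed
#'   is overridden by `seed`).
#' @param stages Stages to execute, in dependency order; a subset of
#'   `c("simulate", "type_mtdna", "qc", "admixture", "cline_mt", "cline_q",
#'   "compare", "dating", "phenotype")`.
#' @param seed Top-level integer seed.
#' @param out_dir Parent directory for the run directory (`NULL` = no files
#'   written).
#' @param admixture An [admixture_config()] (seed overridden).
#' @param qc_permutations Monte-Carlo replicates for the QC tests.
#' @param mt_dispersal,nuc_dispersal [dispersal_spec()]s used for contact
#'   dating (defaults: female 1.5-5 km for mtDNA; male-female average
#'   0.5-3 km for nuclear).
#' @param dating_variant See [time_since_contact()].
#' @param fit_args Extra arguments passed to [fit_mh()] via
#'   [model_select()].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(zone = zone_config(),
                            stages = c("simulate", "type_mtdna", "qc",
                                       "admixture", "cline_mt", "cline_q",
                                       "compare", "dating", "phenotype"),
                            seed = 1L, out_dir = NULL,
                            admixture = admixture_config(),
                            qc_permutations = 999,
                            mt_dispersal = dispersal_spec(1.5, 5.0, "female"),
                            nuc_dispersal = dispersal_spec(0.5, 3.0, "male-female average"),
                            dating_variant = "formula",
                            fit_args = list()) {
  all_stages <- c("simulate", "type_mtdna", "qc", "admixture", "cline_mt",
                  "cline_q", "compare", "dating", "phenotype")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  zone$seed <- as.integer(seed)
  admixture$seed <- as.integer(seed + 1000L)
  structure(list(zone = zone, stages = stages, seed = as.integer(seed),
                 out_dir = out_dir, admixture = admixture,
                 qc_permutations = qc_permutations,
                 mt_dispersal = mt_dispersal, nuc_dispersal = nuc_dispersal,
                 dating_variant = dating_variant, fit_args = fit_args),
            class = "pipeline_config")
}

#' Run the full hybrid-zone analysis pipeline
#'
#' Executes the selected stages in dependency order on a synthetic contact
#' zone: simulation, mtDNA typing, genotype QC, admixture inference, mtDNA
#' and nuclear (site-mean Q) cline model selection, reciprocal width
#' comparison, neutral-diffusion contact dating, and phenotype-ancestry
#' regression. When `out_dir` is set, a fresh run directory (never
#' overwriting an earlier one) receives per-stage tables and a consolidated
#' report; every file name is stable and the report carries the config hash
#' and seed so reruns are byte-comparable.
#'
#' @param config A [pipeline_config()].
#' @return List of per-stage results (class `pipeline_result`), invisibly
#'   including `run_dir` when files were written.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  st <- config$stages
  res <- list(config = config, config_hash = rlang::hash(unclass(config)))
  need <- function(what, stage) {
    if (is.null(res[[what]]))
      stop("stage '", stage, "' needs upstream stage producing '", what,
           "'; add it to `stages`", call. = FALSE)
    res[[what]]
  }

  if ("simulate" %in% st) {
    ds <- simulate_zone(config$zone)
    ds <- simulate_sequences(ds)
    res$dataset <- ds
  }

  if ("type_mtdna" %in% st) {
    ds <- need("dataset", "type_mtdna")
    calls <- digest_all(ds$sequences)
    counts <- site_haplotype_counts(calls$call, ds$individuals$site)
    sites_mt <- merge(ds$sites[, c("site_id", "distance")], counts,
                      by = "site_id", sort = FALSE)
    res$mt_calls <- calls
    res$sites_mt <- as_tibble(sites_mt[order(sites_mt$distance), ])
  }

  if ("qc" %in% st) {
    ds <- need("dataset", "qc")
    rep <- qc_report(ds$genotypes, n_permutations = config$qc_permutations,
                     seed = config$seed + 2000L)
    res$qc <- rep
    res$loci_retained <- flag_loci(rep)
  }

  if ("admixture" %in% st) {
    ds <- need("dataset", "admixture")
    fit <- fit_admixture(ds$genotypes, config$admixture)
    # orient on the interior cluster: ancestry must rise along the transect
    smq <- site_mean_q(fit, ds$individuals$site, focal_cluster = 1)
    ord <- match(smq$site_id, ds$sites$site_id)
    focal <- if (cor(ds$sites$distance[ord], smq$mean_q) >= 0) 1L else 2L
    res$admixture <- fit
    res$focal_cluster <- focal
    smq <- site_mean_q(fit, ds$individuals$site, focal_cluster = focal)
    sites_q <- merge(ds$sites[, c("site_id", "distance")], smq,
                     by = "site_id", sort = FALSE)
    res$sites_q <- as_tibble(sites_q[order(sites_q$distance), ])
  }

  if ("cline_mt" %in% st) {
    sm <- need("sites_mt", "cline_mt")
    res$cline_mt <- do.call(model_select,
      c(list(sites = sm, data_kind = "mt_frequency", seed = config$seed + 3000L),
        config$fit_args))
  }

  if ("cline_q" %in% st) {
    sq <- need("sites_q", "cline_q")
    res$cline_q <- do.call(model_select,
      c(list(sites = sq, data_kind = "q_mean", seed = config$seed + 4000L),
        config$fit_args))
  }

  if ("compare" %in% st) {
    a <- need("cline_mt", "compare")$winner
    b <- need("cline_q", "compare")$winner
    res$compare_width <- compare_clines(a, b, "width")
    res$compare_center <- compare_clines(a, b, "center")
  }

  if ("dating" %in% st) {
    a <- need("cline_mt", "dating")$winner
    b <- need("cline_q", "dating")$winner
    res$dating_mt <- contact_range(unname(a$point_estimate["width"]),
                                   config$mt_dispersal, config$dating_variant)
    res$dating_nuc <- contact_range(unname(b$point_estimate["width"]),
                                    config$nuc_dispersal, config$dating_variant)
    res$dating_overlap <- ranges_overlap(res$dating_mt, res$dating_nuc)
  }

  if ("phenotype" %in% st) {
    ds <- need("dataset", "phenotype")
    res$phenotype <- phenotype_assoc_table(ds$phenotypes)
  }

  if (!is.null(config$out_dir)) res$run_dir <- write_run(res, config)
  class(res) <- "pipeline_result"
  invisible(res)
}

write_run <- function(res, config) {
  base <- file.path(config$out_dir, sprintf("run_seed%d_%s", config$seed,
                                            substr(res$config_hash, 1, 8)))
  dir <- base
  i <- 0
  while (dir.exists(dir)) {
    i <- i + 1
    dir <- sprintf("%s-%d", base, i)
  }
  dir.create(dir, recursive = TRUE)
  if (!is.null(res$dataset)) {
    write_genotypes(res$dataset$genotypes, file.path(dir, "genotypes.tsv"))
    write_sites(res$dataset$sites, file.path(dir, "sites.tsv"))
    write_fasta(res$dataset$sequences, file.path(dir, "sequences.fasta"))
    write_zone_config(res$dataset$truth, file.path(dir, "truth.yaml"))
  }
  if (!is.null(res$sites_mt)) write_sites(res$sites_mt, file.path(dir, "sites_mt.tsv"))
  if (!is.null(res$sites_q)) write_sites(res$sites_q, file.path(dir, "sites_q.tsv"))
  if (!is.null(res$qc)) {
    write.table(res$qc$hwe, file.path(dir, "qc_hwe_pvalues.tsv"),
                sep = "\t", quote = FALSE)
  }
  if (!is.null(res$admixture)) {
    q <- data.frame(individual = rownames(res$admixture$Q), res$admixture$Q)
    write.table(q, file.path(dir, "qmatrix.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  for (nm in c("cline_mt", "cline_q")) {
    if (!is.null(res[[nm]]))
      write.table(as.data.frame(res[[nm]]$table), file.path(dir, paste0(nm, "_aicc.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(pipeline_report(res, config), file.path(dir, "report.txt"))
  dir
}

pipeline_report <- function(res, config) {
  ln <- c(sprintf("hybrid-zone pipeline report (seed %d, config %s)",
                  config$seed, res$config_hash),
          sprintf("stages: %s", paste(config$stages, collapse = ", ")))
  fmt_est <- function(fit, par) {
    ci <- ci_2ll(fit, par)
    sprintf("%.6g (%.6g - %.6g)", unname(fit$point_estimate[par]), ci[1], ci[2])
  }
  if (!is.null(res$cline_mt))
    ln <- c(ln, sprintf("mtDNA cline [%s]: width %s km, center %s km",
                        res$cline_mt$winner_name,
                        fmt_est(res$cline_mt$winner, "width"),
                        fmt_est(res$cline_mt$winner, "center")))
  if (!is.null(res$cline_q))
    ln <- c(ln, sprintf("nuclear cline [%s]: width %s km, center %s km",
                        res$cline_q$winner_name,
                        fmt_est(res$cline_q$winner, "width"),
                        fmt_est(res$cline_q$winner, "center")))
  if (!is.null(res$compare_width)) {
    cmp <- res$compare_width
    narrower <- if (cmp$point_a < cmp$point_b) "mtDNA narrower than nuclear"
                else "nuclear narrower than mtDNA"
    ln <- c(ln, sprintf("width comparison: %s; reciprocal 2-LL non-overlap: %s",
                        narrower,
                        ifelse(cmp$significantly_different,
                               "significantly different", "not significant")))
  }
  if (!is.null(res$dating_mt))
    ln <- c(ln, sprintf("contact date mtDNA (%s): %.6g - %.6g generations (~%g - %g)",
                        res$dating_mt$variant, res$dating_mt$t_min,
                        res$dating_mt$t_max, res$dating_mt$rounded[1],
                        res$dating_mt$rounded[2]),
            sprintf("contact date nuclear (%s): %.6g - %.6g generations (~%g - %g); overlap: %s",
                    res$dating_nuc$variant, res$dating_nuc$t_min,
                    res$dating_nuc$t_max, res$dating_nuc$rounded[1],
                    res$dating_nuc$rounded[2], res$dating_overlap))
  if (!is.null(res$loci_retained))
    ln <- c(ln, sprintf("QC: %d loci retained, %d dropped, %d borderline",
                        length(res$loci_retained$retained),
                        length(res$loci_retained$dropped),
                        length(res$loci_retained$borderline)))
  ln
}

#' @export
print.pipeline_result <- function(x, ...) {
  writeLines(pipeline_report(x, x$config))
  invisible(x)
}
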